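#' Assemble a targeted spectral sub-library
#'
#' Filters two source assay libraries down to a target protein set:
#' project-specific entries (`lib_a`) win on peptide overlap, peptides
#' mapping to more than one target protein are excluded as
#' non-proteotypic, and each surviving peptide keeps at most its `top_n`
#' most intense transitions (ties broken by ascending product m/z).
#' Assembly is idempotent.
#'
#' @param lib_a,lib_b data.frames with columns `peptide_seq`,
#'   `protein_id`, `precursor_mz`, `fragment`, `product_mz`,
#'   `rel_intensity`.
#' @param targets protein ids to retain.
#' @param top_n transitions kept per peptide (default 6).
#' @return data.frame of the assembled library with a `source` column
#'   (`"lib_a"`/`"lib_b"`); attribute `n_nonproteotypic` counts excluded
#'   peptides.
#' @export
assemble_targeted_library <- function(lib_a, lib_b, targets, top_n = 6) {
  need <- c("peptide_seq", "protein_id", "precursor_mz", "fragment",
            "product_mz", "rel_intensity")
  prep <- function(lib, src) {
    lib <- as.data.frame(lib, stringsAsFactors = FALSE)
    missing_cols <- setdiff(need, names(lib))
    if (length(missing_cols))
      stop("library is missing columns: ",
           paste(missing_cols, collapse = ", "))
    keep_cols <- c(need, if ("source" %in% names(lib)) "source")
    lib <- lib[lib$protein_id %in% targets, keep_cols, drop = FALSE]
    if (!"source" %in% names(lib))  # provenance survives re-assembly
      lib$source <- rep_len(src, nrow(lib))
    lib
  }
  a <- prep(lib_a, "lib_a")
  b <- prep(lib_b, "lib_b")
  ## project-specific assays take precedence on peptide overlap
  b <- b[!(b$peptide_seq %in% a$peptide_seq), , drop = FALSE]
  lib <- rbind(a, b)
  ## proteotypic rule: a peptide must map to exactly one target protein
  nprot <- tapply(lib$protein_id, lib$peptide_seq,
                  function(x) length(unique(x)))
  shared <- names(nprot)[nprot > 1]
  lib <- lib[!(lib$peptide_seq %in% shared), , drop = FALSE]
  ## top-n most intense transitions per peptide, ties by ascending m/z
  lib <- lib[order(lib$peptide_seq, -lib$rel_intensity, lib$product_mz), ,
             drop = FALSE]
  rank_in_pep <- stats::ave(seq_len(nrow(lib)), lib$peptide_seq,
                            FUN = seq_along)
  lib <- lib[rank_in_pep <= top_n, , drop = FALSE]
  rownames(lib) <- NULL
  attr(lib, "n_nonproteotypic") <- length(shared)
  lib
}

#' Permutation estimate of the FDR of a filtered sub-library
#'
#' Builds two virtual library matrices of the stated sizes, each seeded
#' with `floor(fp_rate * size)` false-positive targets, then repeatedly
#' draws random sub-libraries of `sub_size` entries (uniform, without
#' replacement) from the pool and records each draw's empirical FDR. The
#' defaults mirror a large pan-human assay resource (139,449 peptide
#' assays) next to a project library of roughly 30,000, both calibrated
#' to 1% false targets. An alternative `mode = "label_permutation"`
#' permutes the false-target labels over the pool before each draw
#' (equivalent in distribution for uniform draws; exposed for
#' completeness).
#'
#' @param size_a,size_b virtual library sizes (defaults 139449 and 30000).
#' @param sub_size entries in the filtered sub-library (default 3593).
#' @param fp_rate calibrated false-positive fraction in \[0, 1)
#'   (default 0.01).
#' @param n_perm random samplings (default 100).
#' @param seed RNG seed.
#' @param bound FDR bound for the exceedance probability (default 0.02).
#' @param mode `"subsample"` (default) or `"label_permutation"`.
#' @return list: `fdr` (per-draw empirical FDRs), `mean`, `sd`,
#'   `quantiles` (incl. the 95th percentile), `p_exceed` (one-sided
#'   normal probability that the FDR exceeds `bound`),
#'   `frac_exceed` (empirical fraction of draws above `bound`).
#' @export
estimate_fdr_permutation <- function(size_a = 139449, size_b = 30000,
                                     sub_size = 3593, fp_rate = 0.01,
                                     n_perm = 100, seed = 1L, bound = 0.02,
                                     mode = c("subsample",
                                              "label_permutation")) {
  mode <- match.arg(mode)
  if (fp_rate < 0 || fp_rate >= 1) stop("fp_rate must lie in [0, 1)")
  pool_size <- size_a + size_b
  if (sub_size > pool_size)
    stop("sub_size exceeds the pooled library size")
  n_false <- floor(fp_rate * size_a) + floor(fp_rate * size_b)
  set.seed(seed)
  is_false <- c(rep(TRUE, n_false), rep(FALSE, pool_size - n_false))
  fdr <- vapply(seq_len(n_perm), function(i) {
    labels <- if (mode == "label_permutation") sample(is_false) else is_false
    draw <- sample.int(pool_size, sub_size)
    sum(labels[draw]) / sub_size
  }, numeric(1))
  qs <- stats::quantile(fdr, c(0.05, 0.25, 0.5, 0.75, 0.95))
  mu <- mean(fdr)
  sdv <- stats::sd(fdr)
  p_exceed <- if (sdv > 0) stats::pnorm(bound, mu, sdv, lower.tail = FALSE)
  else as.numeric(mu > bound)
  list(fdr = fdr, mean = mu, sd = sdv, quantiles = qs,
       p_exceed = p_exceed, frac_exceed = mean(fdr > bound),
       n_false_in_pool = n_false, bound = bound)
}
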