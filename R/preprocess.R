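#' Selection criteria for internal standard peptides
#'
#' The five filters that admit a peptide into the internal-standard set:
#' membership of the housekeeping/cytoskeletal candidate list, near-complete
#' detection, variance equality between extracts, strong paired correlation
#' between extracts, and a minimum sequence length ("more than 7 residues"
#' read strictly as length >= 8).
#'
#' @param candidate_ids protein ids of the housekeeping/cytoskeletal
#'   candidates.
#' @param max_missing_frac maximum tolerated fraction of runs in which the
#'   peptide is unobserved (default 0.05).
#' @param f_test_min_p minimum two-sided F-test p-value for equality of the
#'   peptide's depleted-run and total-run log2 variances (default 0.2;
#'   larger p = more stable).
#' @param pearson_min_r,pearson_max_p paired total-vs-depleted Pearson
#'   correlation thresholds (defaults r > 0.6, p < 0.05).
#' @param min_peptide_len minimum sequence length in residues (default 8).
#' @return classed `"isp_criteria"` list.
#' @export
isp_criteria <- function(candidate_ids, max_missing_frac = 0.05,
                         f_test_min_p = 0.2, pearson_min_r = 0.6,
                         pearson_max_p = 0.05, min_peptide_len = 8) {
  stopifnot(length(candidate_ids) >= 1,
            max_missing_frac >= 0, max_missing_frac <= 1,
            f_test_min_p >= 0, f_test_min_p <= 1,
            pearson_min_r >= -1, pearson_min_r <= 1,
            pearson_max_p >= 0, pearson_max_p <= 1,
            min_peptide_len >= 1)
  structure(list(candidate_ids = candidate_ids,
                 max_missing_frac = max_missing_frac,
                 f_test_min_p = f_test_min_p,
                 pearson_min_r = pearson_min_r,
                 pearson_max_p = pearson_max_p,
                 min_peptide_len = min_peptide_len),
            class = "isp_criteria")
}

run_id <- function(sample_id, extract) paste(sample_id, extract, sep = "|")

## peptide x run matrix of log2 summed-transition intensities
peptide_run_matrix <- function(quant) {
  q <- drop_decoys(quant)
  pep <- paste(q$protein_id, q$peptide_seq, sep = "\r")
  runs <- run_id(q$sample_id, q$extract)
  obs <- !is.na(q$intensity)
  sums <- tapply(q$intensity[obs],
                 list(pep = pep[obs], run = runs[obs]), sum)
  all_runs <- sort(unique(runs))
  m <- matrix(NA_real_, nrow = length(unique(pep)), ncol = length(all_runs),
              dimnames = list(sort(unique(pep)), all_runs))
  m[rownames(sums), colnames(sums)] <- sums
  log2(m)
}

#' Select internal standard peptides
#'
#' Applies the five filters of [isp_criteria] to the paired table. The
#' variance and correlation screens operate on quantile-normalized log2
#' peptide intensities (quantile normalization is internal to this
#' pre-screen, not a user-facing normalization mode). The F-test is
#' two-sided with the larger variance in the numerator; the Pearson screen
#' pairs the depleted and total values of the same sample.
#'
#' @param quant a [paired_quant] table with both extracts present.
#' @param criteria an [isp_criteria] object.
#' @return classed `"isp_set"` data.frame (`protein_id`, `peptide_seq`) of
#'   selected peptides; errors if no peptide survives, since without an
#'   internal-standard reference the noise distribution -- and hence KS
#'   gating -- is undefined.
#' @export
select_isp <- function(quant, criteria) {
  stopifnot(inherits(criteria, "isp_criteria"))
  m <- peptide_run_matrix(quant)
  keys <- do.call(rbind, strsplit(rownames(m), "\r", fixed = TRUE))
  prot <- keys[, 1]
  seqs <- keys[, 2]

  is_candidate <- prot %in% criteria$candidate_ids
  long_enough <- nchar(seqs) >= criteria$min_peptide_len
  missing_ok <- rowMeans(is.na(m)) < criteria$max_missing_frac

  mq <- limma::normalizeQuantiles(m)
  run_extract <- sub("^.*\\|", "", colnames(mq))
  run_sample <- sub("\\|.*$", "", colnames(mq))
  dep_cols <- which(run_extract == "depleted")
  tot_cols <- which(run_extract == "total")
  dep_cols <- dep_cols[order(run_sample[dep_cols])]
  tot_cols <- tot_cols[order(run_sample[tot_cols])]
  shared <- intersect(run_sample[dep_cols], run_sample[tot_cols])
  dep_cols <- dep_cols[run_sample[dep_cols] %in% shared]
  tot_cols <- tot_cols[run_sample[tot_cols] %in% shared]
  if (!length(shared)) stop("no samples with both extracts present")

  idx <- which(is_candidate & long_enough & missing_ok)
  stable <- correlated <- logical(nrow(mq))
  for (i in idx) {
    d <- mq[i, dep_cols]
    t <- mq[i, tot_cols]
    dv <- d[!is.na(d)]
    tv <- t[!is.na(t)]
    if (length(dv) >= 3 && length(tv) >= 3 &&
          stats::var(dv) > 0 && stats::var(tv) > 0) {
      f <- max(stats::var(dv), stats::var(tv)) /
        min(stats::var(dv), stats::var(tv))
      n1 <- if (stats::var(dv) >= stats::var(tv)) length(dv) else length(tv)
      n2 <- if (stats::var(dv) >= stats::var(tv)) length(tv) else length(dv)
      p_f <- min(1, 2 * stats::pf(f, n1 - 1, n2 - 1, lower.tail = FALSE))
      stable[i] <- p_f > criteria$f_test_min_p
    }
    ok <- !is.na(d) & !is.na(t)
    if (sum(ok) >= 4 && stats::sd(d[ok]) > 0 && stats::sd(t[ok]) > 0) {
      ct <- stats::cor.test(t[ok], d[ok], method = "pearson")
      correlated[i] <- ct$estimate > criteria$pearson_min_r &&
        ct$p.value < criteria$pearson_max_p
    }
  }

  pass <- is_candidate & long_enough & missing_ok & stable & correlated
  if (!any(pass))
    stop("no peptide passed the internal-standard filters: ",
         "no ISP reference; KS gating impossible")
  out <- data.frame(protein_id = prot[pass], peptide_seq = seqs[pass],
                    stringsAsFactors = FALSE)
  out <- out[order(out$protein_id, out$peptide_seq), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- unique(c("isp_set", class(out)))
  out
}

isp_feature_rows <- function(quant, isp) {
  paste(quant$protein_id, quant$peptide_seq, sep = "\r") %in%
    paste(isp$protein_id, isp$peptide_seq, sep = "\r")
}

#' Normalize intensities to the internal-standard peptides
#'
#' Per MS run (sample-by-extract), subtracts the run's deviation of its
#' internal-standard median log2 intensity from the global
#' internal-standard median, i.e. multiplies the run's linear intensities
#' by a single constant. After normalization every run's ISP median equals
#' the global median; within-run intensity ranks are untouched.
#'
#' @param quant a [paired_quant] table.
#' @param isp an `isp_set` from [select_isp].
#' @return the normalized [paired_quant] table.
#' @export
normalize_by_isp <- function(quant, isp) {
  is_isp <- isp_feature_rows(quant, isp) & !is.na(quant$intensity)
  runs <- run_id(quant$sample_id, quant$extract)
  all_runs <- unique(runs)
  med <- tapply(log2(quant$intensity[is_isp]), runs[is_isp], stats::median)
  no_isp <- setdiff(all_runs, names(med))
  if (length(no_isp))
    stop("run(s) without any internal-standard feature: ",
         paste(no_isp, collapse = ", "))
  shift <- stats::setNames(as.vector(med) - stats::median(med), names(med))
  quant$intensity <- quant$intensity * as.vector(2^(-shift[runs]))
  quant
}

#' Impute missing intensities from the protein's low-abundance tail
#'
#' Each missing value is replaced by a draw from
#' `Normal(0.9 * min(observed), 0.5 * sd(observed))`, computed over the
#' protein's observed intensities in the same extract, floored at 0. This
#' targets left-censored low-intensity dropout: draws sit just below the
#' protein's detection floor. Observed values are never altered, and the
#' result is reproducible from `seed`.
#'
#' @param quant a [paired_quant] table (normalize first).
#' @param seed RNG seed.
#' @param scale `"linear"` (default) applies the rule to raw intensities;
#'   `"log2"` applies it on the log2 scale and back-transforms.
#' @return the completed [paired_quant] table.
#' @export
impute_missing <- function(quant, seed = 1L, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!anyNA(quant$intensity)) return(quant)
  set.seed(seed)
  vals <- if (scale == "linear") quant$intensity else log2(quant$intensity)
  grp <- paste(quant$protein_id, quant$extract, sep = "\r")
  obs <- !is.na(vals)
  gmin <- tapply(vals[obs], grp[obs], min)
  gsd <- tapply(vals[obs], grp[obs], stats::sd)
  global_min <- min(vals[obs])
  global_sd <- stats::sd(vals[obs])
  miss <- which(!obs)
  mg <- grp[miss]
  mu <- 0.9 * unname(gmin[mg])
  sd_i <- 0.5 * unname(gsd[mg])
  orphan <- !(mg %in% names(gmin))
  if (any(orphan)) {
    warning(length(unique(mg[orphan])),
            " protein/extract group(s) without any observed value; ",
            "imputing from the global minimum")
    mu[orphan] <- 0.9 * global_min
    sd_i[orphan] <- 0.5 * global_sd
  }
  sd_i[is.na(sd_i)] <- 0  # single observed value: no spread estimate
  draws <- stats::rnorm(length(miss), mu, sd_i)
  if (scale == "linear") draws <- pmax(draws, 0) else draws <- 2^draws
  quant$intensity[miss] <- draws
  quant
}

#' Summarize transitions to protein abundances by median polish
#'
#' Tukey median polish of each protein's transition-by-sample log2 matrix;
#' the protein's per-sample abundance is the overall effect plus the sample
#' (column) effect -- a robust summary resistant to a minority of outlier
#' transitions. Single-transition proteins pass through unchanged.
#'
#' @param quant a [paired_quant] table (normalized, imputed).
#' @param extract which extract to summarize (default `"total"`).
#' @return numeric matrix, proteins x samples, of log2 abundances.
#' @export
summarize_protein <- function(quant, extract = c("total", "depleted")) {
  extract <- match.arg(extract)
  q <- drop_decoys(quant)
  q <- q[q$extract == extract, , drop = FALSE]
  samples <- sort(unique(q$sample_id))
  proteins <- sort(unique(q$protein_id))
  out <- matrix(NA_real_, nrow = length(proteins), ncol = length(samples),
                dimnames = list(proteins, samples))
  empty <- character()
  for (p in proteins) {
    sub <- q[q$protein_id == p, , drop = FALSE]
    if (all(is.na(sub$intensity))) {
      empty <- c(empty, p)
      next
    }
    m <- tapply(log2(sub$intensity),
                list(paste(sub$peptide_seq, sub$transition_id),
                     factor(sub$sample_id, levels = samples)), mean)
    if (nrow(m) == 1L) {
      out[p, ] <- m[1L, ]
    } else {
      mp <- stats::medpolish(m, na.rm = TRUE, trace.iter = FALSE,
                             maxiter = 20L)
      out[p, ] <- mp$overall + mp$col
    }
  }
  if (length(empty)) {
    warning("protein(s) without observed values excluded: ",
            paste(empty, collapse = ", "))
    out <- out[setdiff(proteins, empty), , drop = FALSE]
  }
  out
}
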