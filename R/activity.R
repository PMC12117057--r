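#' Depletion ratios for all proteins across samples
#'
#' For every protein and sample, sums the intensities of transitions
#' observed in both extracts of that sample (only matched transitions are
#' comparable) and forms the depletion ratio
#' `log2(sum depleted) - log2(sum total)`. Multiplying both extracts of a
#' sample by a constant leaves its ratios unchanged.
#'
#' @param quant a [paired_quant] table.
#' @param proteins optional subset of protein ids.
#' @param level `"protein"` sums all of a protein's matched transitions;
#'   `"peptide"` returns one ratio per (protein, peptide), rownames
#'   `protein\\rpeptide`.
#' @return list with `ratio` (features x samples log2-delta matrix; `NA`
#'   where nothing matched, flagged `NA` where the total sum is zero),
#'   `n_transitions` and `k_peptides` count matrices.
#' @export
depletion_matrix <- function(quant, proteins = NULL,
                             level = c("protein", "peptide")) {
  level <- match.arg(level)
  q <- drop_decoys(quant)
  if (!is.null(proteins))
    q <- q[q$protein_id %in% proteins, , drop = FALSE]
  samples <- sort(unique(q$sample_id))
  q <- q[!is.na(q$intensity), , drop = FALSE]
  fkey <- paste(q$protein_id, q$peptide_seq, q$transition_id, q$sample_id,
                sep = "\r")
  is_tot <- q$extract == "total"
  common <- intersect(fkey[is_tot], fkey[!is_tot])
  tot <- q[is_tot, , drop = FALSE][match(common, fkey[is_tot]), , drop = FALSE]
  dep <- q[!is_tot, , drop = FALSE][match(common, fkey[!is_tot]), , drop = FALSE]

  feature <- if (level == "protein") tot$protein_id else
    paste(tot$protein_id, tot$peptide_seq, sep = "\r")
  feats <- sort(unique(feature))
  gsum <- function(v) {
    m <- tapply(v, list(factor(feature, levels = feats),
                        factor(tot$sample_id, levels = samples)), sum)
    m
  }
  tot_sum <- gsum(tot$intensity)
  dep_sum <- gsum(dep$intensity)
  ratio <- log2(dep_sum) - log2(tot_sum)
  ratio[!is.na(tot_sum) & tot_sum == 0] <- NA_real_  # undefined denominator
  cnt <- tapply(rep(1L, nrow(tot)),
                list(factor(feature, levels = feats),
                     factor(tot$sample_id, levels = samples)), sum)
  kpep <- tapply(paste(tot$protein_id, tot$peptide_seq),
                 list(factor(feature, levels = feats),
                      factor(tot$sample_id, levels = samples)),
                 function(x) length(unique(x)))
  list(ratio = ratio, n_transitions = cnt, k_peptides = kpep)
}

#' Depletion ratio of one enzyme in one sample
#'
#' @param quant a [paired_quant] table.
#' @param enzyme_id,sample_id the cell to compute.
#' @return one-row data.frame: `enzyme_id`, `sample_id`, `log2_delta_int`
#'   (`NA` when no transition matched -- missing is propagated, never
#'   coerced to zero), `k_peptides`, `matched_transitions`.
#' @export
compute_depletion_ratio <- function(quant, enzyme_id, sample_id) {
  dm <- depletion_matrix(quant, proteins = enzyme_id)
  in_mat <- enzyme_id %in% rownames(dm$ratio) &&
    sample_id %in% colnames(dm$ratio)
  r <- if (in_mat) dm$ratio[enzyme_id, sample_id] else NA_real_
  n <- if (in_mat) dm$n_transitions[enzyme_id, sample_id] else NA_integer_
  k <- if (in_mat) dm$k_peptides[enzyme_id, sample_id] else NA_integer_
  data.frame(enzyme_id = enzyme_id, sample_id = sample_id,
             log2_delta_int = unname(r),
             k_peptides = ifelse(is.na(k), 0L, unname(k)),
             matched_transitions = ifelse(is.na(n), 0L, unname(n)),
             stringsAsFactors = FALSE)
}

#' Active fraction from a depletion ratio
#'
#' `RADDi = 1 - 2^(log2 delta Int)`, clamped to \[0, 1\]: apparent
#' enrichment (a positive ratio) is treated as noise and mapped to 0, not
#' to a negative activity. Strictly decreasing in the ratio on the
#' depletion side.
#'
#' @param log2_delta_int depletion ratio(s); `NA` propagates.
#' @return active fraction(s) in \[0, 1\].
#' @export
raddi_from_ratio <- function(log2_delta_int) {
  pmin(pmax(1 - 2^log2_delta_int, 0), 1)
}

#' Internal-standard reference distribution of depletion ratios
#'
#' Pools the per-ISP-protein, per-sample depletion ratios of the given
#' samples: the empirical distribution of the technical noise that an
#' undepleted protein exhibits between paired extracts. Granularity
#' matches the enzyme side of the KS comparison (one value per protein per
#' sample).
#'
#' @param quant a [paired_quant] table.
#' @param isp an `isp_set` from [select_isp].
#' @param condition_samples sample ids belonging to the condition.
#' @return numeric vector of reference ratios (warning below 20 values:
#'   little KS power).
#' @export
isp_reference_distribution <- function(quant, isp, condition_samples) {
  if (!length(condition_samples))
    stop("no samples supplied for the reference distribution")
  q <- quant[quant$sample_id %in% condition_samples &
               isp_feature_rows(quant, isp), , drop = FALSE]
  dm <- depletion_matrix(q)
  ref <- as.vector(dm$ratio)
  ref <- ref[!is.na(ref)]
  if (length(ref) < 20)
    warning("fewer than 20 internal-standard reference ratios; ",
            "the KS gate will have little power")
  ref
}

## one-sided D+ = sup_t [F_x(t) - F_ref(t)]; large when x sits below ref
ks_d_plus <- function(x, ref) {
  z <- sort(unique(c(x, ref)))
  max(stats::ecdf(x)(z) - stats::ecdf(ref)(z))
}

#' One-sided Kolmogorov-Smirnov gate against the noise reference
#'
#' Tests whether the enzyme's depletion ratios are stochastically smaller
#' (more depleted) than the internal-standard reference, using
#' `D+ = sup_t [F_enzyme(t) - F_ref(t)]` -- the orientation of R's
#' `ks.test(x, y, alternative = "greater")`. The default p-value is the
#' one-sided asymptotic bound `exp(-2 m n D+^2 / (m + n))`, conservative
#' for small samples; `exact = TRUE` uses the exact Smirnov distribution.
#'
#' @param enzyme_ratios per-sample depletion ratios of one enzyme in one
#'   condition (`NA` dropped).
#' @param reference pooled internal-standard ratios
#'   ([isp_reference_distribution]).
#' @param alpha gate level (default 0.05).
#' @param min_samples minimum enzyme sample size; below it the gate stays
#'   closed and the p-value is `NA`.
#' @param exact use the exact small-sample null distribution.
#' @return list: `statistic` (D+), `p`, `gated`, `m`, `n`.
#' @export
ks_gate <- function(enzyme_ratios, reference, alpha = 0.05,
                    min_samples = 3, exact = FALSE) {
  x <- enzyme_ratios[!is.na(enzyme_ratios)]
  if (!length(reference)) stop("empty reference distribution")
  m <- length(x)
  n <- length(reference)
  if (m < min_samples)
    return(list(statistic = NA_real_, p = NA_real_, gated = FALSE,
                m = m, n = n))
  d <- ks_d_plus(x, reference)
  p <- if (exact) {
    suppressWarnings(stats::ks.test(x, reference,
                                    alternative = "greater",
                                    exact = TRUE)$p.value)
  } else {
    min(1, exp(-2 * m * n * d^2 / (m + n)))
  }
  list(statistic = d, p = p, gated = p <= alpha, m = m, n = n)
}

#' Fit per-enzyme activity profiles (RADDi) with KS gating
#'
#' The core dd-ABPP estimator. Per enzyme and condition, the per-sample
#' depletion ratios are compared with the internal-standard noise
#' reference by the one-sided KS gate; where the gate opens, the
#' per-sample active fraction is `RADDi = 1 - 2^ratio` (clamped to
#' \[0, 1\]); where the depletion signal stays within the noise range, the
#' activity is set to 0.
#'
#' @param quant a [paired_quant] table (normalized; imputation optional --
#'   ratios only use matched observed transitions).
#' @param design a [cohort_design].
#' @param isp an `isp_set` from [select_isp].
#' @param catalog an [enzyme_catalog]; only catalogued, catalytically
#'   plausible enzymes are profiled.
#' @param alpha KS gate level (default 0.05).
#' @param min_samples minimum per-condition sample size for gating.
#' @param exact exact KS null (see [ks_gate]).
#' @param pool KS input granularity: `"sample"` (default) uses one ratio
#'   per enzyme per sample; `"peptide"` pools per-peptide ratios across
#'   the condition's samples.
#' @return object of class `"ddabpp"`: list with `raddi` and `log2_delta`
#'   (enzyme x sample matrices), `gates` (per enzyme x condition KS
#'   results), `condition_means` (enzyme x condition mean RADDi),
#'   `reference` (per-condition ISP ratio pools), `design`, `alpha`.
#' @seealso [summary.ddabpp()], [coef.ddabpp()], [plot.ddabpp()]
#' @export
ddabpp <- function(quant, design, isp, catalog, alpha = 0.05,
                   min_samples = 3, exact = FALSE,
                   pool = c("sample", "peptide")) {
  pool <- match.arg(pool)
  stopifnot(inherits(catalog, "enzyme_catalog"),
            inherits(design, "cohort_design"))
  enzymes <- catalog$protein_id[catalog$catalytic_ok]
  enzymes <- intersect(enzymes, unique(quant$protein_id))
  if (!length(enzymes)) stop("no catalogued enzyme present in the table")
  conditions <- sort(unique(design$condition))

  dm <- depletion_matrix(quant, proteins = enzymes)
  ratio <- dm$ratio[enzymes[enzymes %in% rownames(dm$ratio)], , drop = FALSE]
  pep_ratio <- if (pool == "peptide")
    depletion_matrix(quant, proteins = enzymes, level = "peptide")$ratio
  else NULL

  reference <- lapply(conditions, function(cn) {
    isp_reference_distribution(quant, isp,
                               design$sample_id[design$condition == cn])
  })
  names(reference) <- conditions

  gates <- expand.grid(enzyme_id = rownames(ratio), condition = conditions,
                       stringsAsFactors = FALSE)
  gates$m <- NA_integer_
  gates$statistic <- NA_real_
  gates$ks_p <- NA_real_
  gates$gated <- FALSE
  for (i in seq_len(nrow(gates))) {
    cn <- gates$condition[i]
    e <- gates$enzyme_id[i]
    cs <- design$sample_id[design$condition == cn]
    cs <- intersect(cs, colnames(ratio))
    x <- if (pool == "sample") ratio[e, cs] else {
      rows <- grepl(paste0("^", e, "\r"), rownames(pep_ratio))
      as.vector(pep_ratio[rows, cs, drop = FALSE])
    }
    g <- ks_gate(x, reference[[cn]], alpha = alpha,
                 min_samples = min_samples, exact = exact)
    gates$m[i] <- g$m
    gates$statistic[i] <- g$statistic
    gates$ks_p[i] <- g$p
    gates$gated[i] <- g$gated
  }

  raddi <- ratio
  raddi[] <- NA_real_
  for (cn in conditions) {
    cs <- intersect(design$sample_id[design$condition == cn], colnames(ratio))
    open <- gates$enzyme_id[gates$condition == cn & gates$gated]
    raddi[, cs] <- 0
    if (length(open))
      raddi[open, cs] <- raddi_from_ratio(ratio[open, cs, drop = FALSE])
  }
  raddi[is.na(ratio)] <- NA_real_  # unmeasured cells stay missing, not 0

  cond_means <- vapply(conditions, function(cn) {
    cs <- intersect(design$sample_id[design$condition == cn], colnames(raddi))
    rowMeans(raddi[, cs, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(raddi)))
  if (is.null(dim(cond_means)))
    cond_means <- matrix(cond_means, nrow = nrow(raddi),
                         dimnames = list(rownames(raddi), conditions))

  structure(list(raddi = raddi, log2_delta = ratio, gates = gates,
                 condition_means = cond_means, reference = reference,
                 design = design, alpha = alpha, pool = pool,
                 call = match.call()),
            class = "ddabpp")
}

#' @rdname ddabpp
#' @param ... arguments passed to [ddabpp()].
#' @export
build_activity_matrix <- function(...) ddabpp(...)

#' @export
print.ddabpp <- function(x, ...) {
  cat("dd-ABPP activity profile\n")
  cat("  enzymes:   ", nrow(x$raddi), "\n")
  cat("  samples:   ", ncol(x$raddi), "\n")
  cat("  conditions:", paste(colnames(x$condition_means), collapse = ", "),
      "\n")
  n_gated <- length(unique(x$gates$enzyme_id[x$gates$gated]))
  cat("  enzymes passing the KS gate (p <= ", x$alpha, ") in >= 1 condition: ",
      n_gated, "\n", sep = "")
  invisible(x)
}

#' Summarize a fitted activity profile
#'
#' @param object a `"ddabpp"` fit.
#' @param ... unused.
#' @return data.frame, one row per enzyme x condition: mean RADDi within
#'   the condition, KS p and gate status.
#' @export
summary.ddabpp <- function(object, ...) {
  g <- object$gates
  g$mean_raddi <- object$condition_means[cbind(g$enzyme_id, g$condition)]
  g[order(g$enzyme_id, g$condition), c("enzyme_id", "condition", "m",
                                       "statistic", "ks_p", "gated",
                                       "mean_raddi")]
}

#' Extract the RADDi matrix from a fit
#'
#' @param object a `"ddabpp"` fit.
#' @param what `"raddi"` (gated active fractions) or `"log2_delta"`
#'   (raw depletion ratios).
#' @param ... unused.
#' @return enzyme x sample numeric matrix.
#' @export
coef.ddabpp <- function(object, what = c("raddi", "log2_delta"), ...) {
  what <- match.arg(what)
  object[[what]]
}

#' Dot plot of per-condition mean activities
#'
#' Mirrors the condition-dot display of activity profiles: one dot per
#' enzyme and condition, dot position = mean RADDi within the condition.
#'
#' @param x a `"ddabpp"` fit.
#' @param top plot at most this many enzymes (by maximum mean RADDi).
#' @param ... passed to [graphics::dotchart()].
#' @export
plot.ddabpp <- function(x, top = 30, ...) {
  cm <- x$condition_means
  keep <- order(apply(cm, 1, max), decreasing = TRUE)[seq_len(min(top,
                                                                  nrow(cm)))]
  graphics::dotchart(cm[rev(keep), , drop = FALSE],
                     xlab = "mean RADDi (active fraction)", xlim = c(0, 1),
                     ...)
  invisible(x)
}
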