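#' Specification of a differential GLM
#'
#' Each data layer gets the family the measurement scale calls for:
#' Gaussian (identity link) for log2 protein abundances, quasibinomial with
#' probit link for RADDi active fractions (a zero-inflated proportion;
#' dispersion estimated by Pearson chi-square / df), and Poisson (log link)
#' for spectral counts.
#'
#' @param family `"gaussian"`, `"quasibinomial_probit"` or `"poisson"`.
#' @param covariates subset of `c("age", "sex", "smoking",
#'   "tumor_cell_pct")` to adjust for; sex and smoking are 0/1 categorical.
#' @param contrasts list of condition pairs `c(group_a, group_b)` to test
#'   (estimate = a minus b); `NULL` means all pairwise contrasts.
#' @param posthoc multiple-contrast adjustment within a feature when more
#'   than one contrast is tested: `"single-step"` max-t (default),
#'   `"bonferroni"`, or `"none"`.
#' @return classed `"glm_spec"` list.
#' @export
glm_spec <- function(family = c("gaussian", "quasibinomial_probit",
                                "poisson"),
                     covariates = character(),
                     contrasts = NULL,
                     posthoc = c("single-step", "bonferroni", "none")) {
  family <- match.arg(family)
  posthoc <- match.arg(posthoc)
  bad <- setdiff(covariates, c("age", "sex", "smoking", "tumor_cell_pct"))
  if (length(bad))
    stop("unknown covariate(s): ", paste(bad, collapse = ", "))
  structure(list(family = family, covariates = covariates,
                 contrasts = contrasts, posthoc = posthoc),
            class = "glm_spec")
}

#' Fit a differential GLM for one feature
#'
#' Fits `y ~ condition + covariates` with the family from the [glm_spec]
#' and reports a Wald test per requested condition contrast. RADDi
#' responses exactly 0 or 1 are nudged by 1e-6 before the probit fit to
#' avoid infinite working responses. Degenerate fits (zero residual
#' variance, separation) yield `NA` p-values flagged in the result rather
#' than an error; perfect collinearity between a covariate and the
#' condition raises a rank-deficiency error.
#'
#' @param y numeric response vector, one value per design row (RADDi in
#'   \[0, 1\] for the quasibinomial layer; non-negative integers for
#'   Poisson).
#' @param design a [cohort_design].
#' @param spec a [glm_spec].
#' @param feature_id label copied into the result.
#' @return data.frame, one row per contrast: `feature_id`, `contrast`,
#'   `estimate`, `se`, `p` (raw), `p_adj` (post-hoc across the feature's
#'   contrasts), `degenerate`. Raw p-values are always reported alongside
#'   any adjustment.
#' @export
fit_glm <- function(y, design, spec, feature_id = "feature") {
  stopifnot(inherits(spec, "glm_spec"), length(y) == nrow(design))
  dat <- data.frame(y = y, condition = factor(design$condition),
                    design[, intersect(spec$covariates, names(design)),
                           drop = FALSE])
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  groups <- levels(droplevels(dat$condition))
  if (length(groups) < 2) stop("need at least two contrasted groups")
  if (min(table(droplevels(dat$condition))) < 2)
    stop("need >= 2 samples per contrasted group")
  dat$condition <- droplevels(dat$condition)

  fam <- switch(spec$family,
                gaussian = stats::gaussian(),
                quasibinomial_probit = stats::quasibinomial(link = "probit"),
                poisson = stats::poisson())
  if (spec$family == "quasibinomial_probit") {
    if (any(dat$y < 0 | dat$y > 1)) stop("proportion responses must be in [0, 1]")
    dat$y <- pmin(pmax(dat$y, 1e-6), 1 - 1e-6)
  }
  if (spec$family == "poisson" &&
        (any(dat$y < 0) || any(dat$y != round(dat$y))))
    stop("poisson family requires non-negative integer counts")

  form <- stats::as.formula(paste("y ~ condition",
                                  paste(c("", spec$covariates), collapse = " + ")))
  fit <- suppressWarnings(stats::glm(form, family = fam, data = dat))
  if (any(is.na(stats::coef(fit)))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient fit (aliased: ", paste(aliased, collapse = ", "),
         "); a covariate is collinear with the condition")
  }

  contrasts <- spec$contrasts
  if (is.null(contrasts)) {
    cc <- utils::combn(groups, 2, simplify = FALSE)
    contrasts <- lapply(cc, function(p) c(p[2], p[1]))
  }
  cn <- names(stats::coef(fit))
  K <- t(vapply(contrasts, function(ct) {
    k <- stats::setNames(numeric(length(cn)), cn)
    for (s in c(1, -1)) {
      g <- ct[if (s == 1) 1 else 2]
      if (!g %in% groups)
        stop("contrast group not present in design: ", g)
      term <- paste0("condition", g)
      if (term %in% cn) k[term] <- k[term] + s
    }
    k
  }, numeric(length(cn))))
  rownames(K) <- vapply(contrasts, paste, character(1), collapse = " - ")

  V <- suppressWarnings(stats::vcov(fit))
  est <- as.vector(K %*% stats::coef(fit))
  se <- sqrt(pmax(diag(K %*% V %*% t(K)), 0))
  degenerate <- !is.finite(se) | se < 1e-12
  stat <- est / se
  df_resid <- fit$df.residual
  use_t <- spec$family != "poisson"
  p <- if (use_t) 2 * stats::pt(abs(stat), df_resid, lower.tail = FALSE)
  else 2 * stats::pnorm(abs(stat), lower.tail = FALSE)
  p[degenerate] <- NA_real_

  p_adj <- p
  if (length(p) > 1 && spec$posthoc != "none") {
    if (spec$posthoc == "bonferroni") {
      p_adj <- pmin(1, p * sum(!is.na(p)))
    } else {
      gl <- try(multcomp::glht(fit, linfct = K), silent = TRUE)
      if (!inherits(gl, "try-error")) {
        sm <- try(summary(gl, test = multcomp::adjusted("single-step")),
                  silent = TRUE)
        if (!inherits(sm, "try-error"))
          p_adj <- as.vector(sm$test$pvalues)
      }
      p_adj[degenerate] <- NA_real_
    }
  }
  data.frame(feature_id = feature_id, contrast = rownames(K),
             estimate = est, se = se, p = p, p_adj = p_adj,
             degenerate = degenerate, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR control across a family of tests; missing p-values stay
#' missing and do not count toward the family size.
#'
#' @param pvals p-values in \[0, 1\], `NA` allowed.
#' @return adjusted values, same length and order.
#' @export
adjust_bh <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) stop("p-values must be in [0, 1]")
  out <- rep(NA_real_, length(pvals))
  out[ok] <- stats::p.adjust(pvals[ok], method = "BH")
  out
}

#' Spearman screen of activities against continuous covariates
#'
#' Rank correlation of each enzyme's per-sample activity with each
#' covariate (e.g. tissue metal concentrations), flagging strong
#' monotone associations: `|rho| > rho_min` and two-sided p (from the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`) below `p_max`.
#'
#' @param activity enzyme x sample matrix (e.g. `coef(fit)` of a
#'   [ddabpp] fit).
#' @param covariates sample x variable numeric matrix (shared sample ids).
#' @param rho_min,p_max flagging thresholds (defaults 0.6 and 0.05).
#' @param min_n minimum paired observations per pair (default 4).
#' @return data.frame: `enzyme_id`, `covariate`, `n`, `rho`, `p`,
#'   `flagged`; constant pairs are skipped with a `note`.
#' @export
spearman_screen <- function(activity, covariates, rho_min = 0.6,
                            p_max = 0.05, min_n = 4) {
  shared <- intersect(colnames(activity), rownames(covariates))
  if (length(shared) < min_n)
    stop("fewer than ", min_n, " shared samples")
  res <- list()
  for (e in rownames(activity)) {
    for (v in colnames(covariates)) {
      x <- activity[e, shared]
      y <- covariates[shared, v]
      ok <- !is.na(x) & !is.na(y)
      note <- ""
      rho <- p <- NA_real_
      if (sum(ok) < min_n) {
        note <- "too few pairs"
      } else if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        note <- "constant vector"
      } else {
        rho <- stats::cor(x[ok], y[ok], method = "spearman")
        n <- sum(ok)
        tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
        p <- 2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE)
      }
      res[[length(res) + 1L]] <- data.frame(
        enzyme_id = e, covariate = v, n = sum(ok), rho = rho, p = p,
        flagged = !is.na(rho) && abs(rho) > rho_min && !is.na(p) && p < p_max,
        note = note, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

#' Fisher co-occurrence of gene mutations with an anchor oncogene
#'
#' Per gene, a one-sided Fisher exact test of the 2x2 table (gene mutated
#' vs not) x (anchor mutated vs not): does the anchor mutate more often
#' among patients carrying the gene than the cohort background anchor
#' fraction suggests? P-values are BH-adjusted across genes. The
#' descriptive mutation rate is scaled by protein length (mutated patients
#' per residue) to remove the gene-length bias.
#'
#' @param mut binary patient x gene matrix (see [simulate_mutation_table]).
#' @param anchor_gene column name of the anchor.
#' @param protein_lengths named vector of protein lengths in residues
#'   (optional; enables the length-scaled rate).
#' @return data.frame per gene mutated at least once: counts,
#'   `cooccurrence_frac`, `rate_per_residue`, `p`, `q`.
#' @export
fisher_cooccurrence <- function(mut, anchor_gene, protein_lengths = NULL) {
  if (!anchor_gene %in% colnames(mut)) stop("anchor gene not in table")
  anchor <- mut[, anchor_gene] == 1
  genes <- setdiff(colnames(mut), anchor_gene)
  rows <- lapply(genes, function(g) {
    gm <- mut[, g] == 1
    n_mut <- sum(gm)
    if (n_mut == 0) return(NULL)  # never mutated: excluded
    tab <- matrix(c(sum(gm & anchor), sum(gm & !anchor),
                    sum(!gm & anchor), sum(!gm & !anchor)), nrow = 2)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    rate <- if (!is.null(protein_lengths) && g %in% names(protein_lengths))
      n_mut / protein_lengths[[g]] else NA_real_
    data.frame(gene = g, n_mutated = n_mut,
               n_comutated = sum(gm & anchor),
               cooccurrence_frac = sum(gm & anchor) / n_mut,
               rate_per_residue = rate, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no gene is mutated in any patient")
  out$q <- adjust_bh(out$p)
  rownames(out) <- NULL
  out
}
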