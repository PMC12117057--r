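#' Call co-depleted background proteins
#'
#' A non-enzyme protein that is significantly lost from the depleted
#' extract is interpreted as physically associated with a captured active
#' enzyme. Per protein, a TWO-sided two-sample KS test compares its
#' per-sample depletion ratios with the internal-standard reference, per
#' condition and pooled across all samples; calls are made at two strata
#' (p < 0.05 and the more stringent p < 0.01, the second nested inside the
#' first by construction).
#'
#' @param quant a [paired_quant] table (normalized).
#' @param isp an `isp_set` from [select_isp].
#' @param design a [cohort_design].
#' @param proteins proteins to test (default: everything except the ISP
#'   proteins themselves).
#' @param min_samples minimum ratio count per test (default 3).
#' @return data.frame: `protein_id`, `condition` (including `"pooled"`),
#'   `n`, `ks_p_two_sided`, `depleted_p05`, `depleted_p01`, and the mean
#'   depletion ratio `mean_log2_delta`.
#' @export
call_codepleted <- function(quant, isp, design, proteins = NULL,
                            min_samples = 3) {
  if (is.null(proteins))
    proteins <- setdiff(unique(quant$protein_id), isp$protein_id)
  dm <- depletion_matrix(quant, proteins = proteins)
  conditions <- sort(unique(design$condition))
  refs <- lapply(conditions, function(cn)
    isp_reference_distribution(quant, isp,
                               design$sample_id[design$condition == cn]))
  names(refs) <- conditions
  refs$pooled <- unlist(refs, use.names = FALSE)

  rows <- list()
  for (pr in rownames(dm$ratio)) {
    for (cn in c(conditions, "pooled")) {
      cs <- if (cn == "pooled") design$sample_id
      else design$sample_id[design$condition == cn]
      x <- dm$ratio[pr, intersect(cs, colnames(dm$ratio))]
      x <- x[!is.na(x)]
      p <- NA_real_
      if (length(x) >= min_samples)
        p <- suppressWarnings(stats::ks.test(x, refs[[cn]])$p.value)
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = pr, condition = cn, n = length(x),
        ks_p_two_sided = p,
        depleted_p05 = !is.na(p) && p < 0.05,
        depleted_p01 = !is.na(p) && p < 0.01,
        mean_log2_delta = if (length(x)) mean(x) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

.adjacency <- function(graph) {
  e <- as.data.frame(graph)
  split(c(e$protein_b, e$protein_a), c(e$protein_a, e$protein_b))
}

.neighbors <- function(adj, nodes) {
  unique(unlist(adj[intersect(nodes, names(adj))], use.names = FALSE))
}

#' Annotate called proteins by interactor degree
#'
#' Labels each called protein as a 1st-degree enzyme interactor (direct
#' neighbor of any catalogued enzyme in the reference graph), 2nd degree
#' (neighbor of a 1st-degree interactor without being one itself; 1st
#' takes precedence), or unannotated. Invariant to edge ordering and
#' duplication.
#'
#' @param called protein ids of interest (e.g. co-depletion calls).
#' @param graph an [interaction_set].
#' @param sh_set enzyme protein ids.
#' @return named character vector over `called` with values `"1st"`,
#'   `"2nd"`, `"unannotated"`.
#' @export
annotate_degree <- function(called, graph, sh_set) {
  adj <- .adjacency(graph)
  first <- setdiff(.neighbors(adj, sh_set), sh_set)
  second <- setdiff(.neighbors(adj, first), union(first, sh_set))
  out <- ifelse(called %in% first, "1st",
                ifelse(called %in% second, "2nd", "unannotated"))
  stats::setNames(out, called)
}

#' Random-interactome null for co-depletion overlap
#'
#' Is the overlap between the depleted proteome and the enzymes'
#' 1st-degree neighborhood larger than chance? The null draws `n_sh`
#' pseudo-target proteins from the quantified universe (without
#' replacement), collects their 1st-degree neighborhoods and counts the
#' overlap with the depleted set; the one-tailed p-value is
#' `P(Z > (observed - null mean) / null sd)` under a normal fit of the
#' null counts.
#'
#' @param observed_overlap observed count of depleted proteins in the real
#'   enzyme neighborhood.
#' @param graph an [interaction_set].
#' @param universe quantified protein ids to sample pseudo-targets from.
#' @param n_sh number of pseudo-targets per iteration (match the real
#'   enzyme count).
#' @param depleted depleted protein ids (must be inside `universe`).
#' @param n_iter null iterations (default 200; at least 2).
#' @param seed RNG seed.
#' @return list: `z`, `p` (one-tailed, enrichment), `null_mean`,
#'   `null_sd`, `null` (the simulated counts), `observed`.
#' @export
random_interactome_null <- function(observed_overlap, graph, universe,
                                    n_sh, depleted, n_iter = 200,
                                    seed = 1L) {
  if (n_iter < 2) stop("n_iter must be at least 2 to estimate a null")
  if (length(setdiff(depleted, universe)))
    stop("depleted set contains proteins outside the universe")
  if (n_sh > length(universe)) stop("n_sh exceeds the universe")
  adj <- .adjacency(graph)
  set.seed(seed)
  null <- vapply(seq_len(n_iter), function(i) {
    targets <- sample(universe, n_sh)
    length(intersect(.neighbors(adj, targets), depleted))
  }, numeric(1))
  mu <- mean(null)
  sdv <- stats::sd(null)
  if (sdv == 0) {
    warning("degenerate null (sd = 0); p reported as boundary")
    p <- if (observed_overlap > mu) 0 else 1
    return(list(z = NA_real_, p = p, null_mean = mu, null_sd = sdv,
                null = null, observed = observed_overlap))
  }
  z <- (observed_overlap - mu) / sdv
  list(z = z, p = stats::pnorm(z, lower.tail = FALSE), null_mean = mu,
       null_sd = sdv, null = null, observed = observed_overlap)
}

#' Correlation-selected enzyme-protein pairs
#'
#' Pearson correlation of each enzyme's activity with each depleted
#' protein's depletion across shared samples; pairs with `|r| > r_min`
#' and two-sided p < `p_max` (from `t = r * sqrt(n - 2) / sqrt(1 - r^2)`)
#' are retained. The same selection rule applies to the latent-variable
#' associations from [pairwise_association].
#'
#' @param activity enzyme x sample matrix (RADDi).
#' @param depletion protein x sample matrix (depletion ratios).
#' @param r_min,p_max retention thresholds (defaults 0.4 and 0.05).
#' @param evidence_graph optional [interaction_set]; marks pairs backed by
#'   an experimental-evidence edge.
#' @return data.frame: `enzyme_id`, `protein_id`, `n`, `correlation`,
#'   `p`, `retained`, `physical_evidence`.
#' @export
correlation_pairs <- function(activity, depletion, r_min = 0.4,
                              p_max = 0.05, evidence_graph = NULL) {
  shared <- intersect(colnames(activity), colnames(depletion))
  if (length(shared) < 4) stop("need at least 4 shared samples")
  A <- t(activity[, shared, drop = FALSE])
  D <- t(depletion[, shared, drop = FALSE])
  r <- suppressWarnings(stats::cor(A, D, use = "pairwise.complete.obs"))
  nmat <- crossprod(!is.na(A), !is.na(D))
  edges <- if (!is.null(evidence_graph)) {
    g <- filter_evidence(evidence_graph, "experimental")
    paste(pmin(g$protein_a, g$protein_b), pmax(g$protein_a, g$protein_b))
  } else character()
  out <- expand.grid(enzyme_id = rownames(r), protein_id = colnames(r),
                     stringsAsFactors = FALSE)
  out$n <- nmat[cbind(out$enzyme_id, out$protein_id)]
  out$correlation <- r[cbind(out$enzyme_id, out$protein_id)]
  tt <- out$correlation * sqrt(pmax(out$n - 2, 0)) /
    sqrt(pmax(1 - out$correlation^2, .Machine$double.eps))
  out$p <- 2 * stats::pt(abs(tt), pmax(out$n - 2, 1), lower.tail = FALSE)
  out$p[out$n < 4 | is.na(out$correlation)] <- NA_real_
  out$retained <- !is.na(out$correlation) & abs(out$correlation) > r_min &
    !is.na(out$p) & out$p < p_max
  out$physical_evidence <- paste(pmin(out$enzyme_id, out$protein_id),
                                 pmax(out$enzyme_id, out$protein_id)) %in%
    edges
  out
}

#' Physical-evidence null for retained pairs
#'
#' How many retained enzyme-protein pairs are backed by an
#' experimental-evidence edge, against a null in which each paired
#' protein is replaced by a random quantified protein (random subsets of
#' the same size)? One-tailed normal p for enrichment.
#'
#' @param pairs data.frame from [correlation_pairs], retained rows.
#' @param evidence_graph an [interaction_set] (experimental tier used).
#' @param universe quantified protein ids.
#' @param n_iter null iterations (default 100).
#' @param seed RNG seed.
#' @return list as in [random_interactome_null].
#' @export
physical_overlap_null <- function(pairs, evidence_graph, universe,
                                  n_iter = 100, seed = 1L) {
  pairs <- pairs[pairs$retained, , drop = FALSE]
  if (!nrow(pairs)) stop("empty pair set")
  if (n_iter < 2) stop("n_iter must be at least 2 to estimate a null")
  g <- filter_evidence(evidence_graph, "experimental")
  edges <- paste(pmin(g$protein_a, g$protein_b),
                 pmax(g$protein_a, g$protein_b))
  count_evidence <- function(prot) {
    sum(paste(pmin(pairs$enzyme_id, prot),
              pmax(pairs$enzyme_id, prot)) %in% edges)
  }
  observed <- count_evidence(pairs$protein_id)
  prot_levels <- unique(pairs$protein_id)
  set.seed(seed)
  null <- vapply(seq_len(n_iter), function(i) {
    repl <- stats::setNames(sample(universe, length(prot_levels)),
                            prot_levels)
    count_evidence(unname(repl[pairs$protein_id]))
  }, numeric(1))
  mu <- mean(null)
  sdv <- stats::sd(null)
  if (sdv == 0) {
    warning("degenerate null (sd = 0); p reported as boundary")
    p <- if (observed > mu) 0 else 1
    return(list(z = NA_real_, p = p, null_mean = mu, null_sd = sdv,
                null = null, observed = observed))
  }
  z <- (observed - mu) / sdv
  list(z = z, p = stats::pnorm(z, lower.tail = FALSE), null_mean = mu,
       null_sd = sdv, null = null, observed = observed)
}
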