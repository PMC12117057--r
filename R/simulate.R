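#' Simulation parameters for a paired dd-ABPP cohort
#'
#' Bundles and validates the generator settings. The defaults emulate the
#' discovery-cohort layout: 12 patients each contributing one tumor and one
#' adjacent-tissue sample, split into long- and short-survival halves, i.e.
#' four tissue-by-survival conditions of six samples.
#'
#' @param n_patients number of patients; each yields a T and an N sample.
#' @param n_enzymes number of probe-targeted hydrolases (`SH...` ids).
#' @param n_background number of background proteins (`BG...` ids).
#' @param n_isp number of stable housekeeping proteins (`HK...` ids), the
#'   internal-standard candidates; their active fraction is identically 0
#'   and their measurement noise is halved.
#' @param peptides_per_protein,transitions_per_peptide feature depth.
#' @param alpha planted active fractions: a condition-by-enzyme matrix in
#'   \[0, 1\] (rownames = conditions, colnames = enzyme ids) or `NULL` to
#'   draw defaults (half the enzymes inactive, the rest with
#'   condition-specific fractions uniform on \[0.1, 0.9\]).
#' @param noise_sd_log2 sd of the independent per-transition, per-run
#'   multiplicative noise (log2 scale), applied to both extracts.
#' @param biological_sd_log2 sd of the per-protein, per-specimen abundance
#'   effect (log2). Both extracts of a sample are aliquots of one lysate,
#'   so they share it; it cancels exactly in depletion ratios but gives
#'   paired extracts the strong total-vs-depleted correlation that real
#'   tissue shows.
#' @param run_effect_sd sd of the additive per-run log2 shift (LC-MS drift;
#'   what internal-standard normalization removes).
#' @param missing_rate fraction of records set missing.
#' @param missing_mode `"mcar"` (completely at random) or `"censored"`
#'   (records below the `missing_rate` quantile of log2 intensity go
#'   missing, mimicking left-censored low-intensity dropout).
#' @param codepletion_couplings data.frame (`enzyme`, `partner`, `strength`)
#'   linking background proteins to enzymes: a partner is depleted by the
#'   factor `1 - strength * alpha(enzyme, condition)`.
#' @param n_diff_proteins,diff_log2fc number of background proteins given a
#'   tumor-vs-normal abundance offset (both extracts) and its size in log2
#'   units.
#' @param baseline_log2_mean,baseline_log2_sd log-normal abundance baseline
#'   (log2 mean 14, sd 2 spans the DIA dynamic range).
#' @param seed integer RNG seed; the whole cohort is reproducible from it.
#' @return classed `"sim_params"` list.
#' @export
sim_params <- function(n_patients = 12, n_enzymes = 50, n_background = 100,
                       n_isp = 20, peptides_per_protein = 3,
                       transitions_per_peptide = 3, alpha = NULL,
                       noise_sd_log2 = 0.2, biological_sd_log2 = 1,
                       run_effect_sd = 0.3,
                       missing_rate = 0.05, missing_mode = c("mcar", "censored"),
                       codepletion_couplings = NULL,
                       n_diff_proteins = 10, diff_log2fc = 1,
                       baseline_log2_mean = 14, baseline_log2_sd = 2,
                       seed = 1L) {
  missing_mode <- match.arg(missing_mode)
  stopifnot(n_patients >= 1, n_patients %% 2 == 0, n_enzymes >= 1,
            n_isp >= 1, peptides_per_protein >= 1,
            transitions_per_peptide >= 1, noise_sd_log2 >= 0,
            biological_sd_log2 >= 0,
            run_effect_sd >= 0, missing_rate >= 0, missing_rate < 1)
  if (!is.null(alpha)) {
    if (any(alpha < 0 | alpha > 1))
      stop("alpha values must lie in [0, 1]")
  }
  if (!is.null(codepletion_couplings)) {
    codepletion_couplings <- as.data.frame(codepletion_couplings,
                                           stringsAsFactors = FALSE)
    stopifnot(all(c("enzyme", "partner", "strength") %in%
                    names(codepletion_couplings)))
    if (any(codepletion_couplings$strength < 0 |
              codepletion_couplings$strength > 1))
      stop("coupling strengths must lie in [0, 1]")
  }
  structure(list(n_patients = n_patients, n_enzymes = n_enzymes,
                 n_background = n_background, n_isp = n_isp,
                 peptides_per_protein = peptides_per_protein,
                 transitions_per_peptide = transitions_per_peptide,
                 alpha = alpha, noise_sd_log2 = noise_sd_log2,
                 biological_sd_log2 = biological_sd_log2,
                 run_effect_sd = run_effect_sd, missing_rate = missing_rate,
                 missing_mode = missing_mode,
                 codepletion_couplings = codepletion_couplings,
                 n_diff_proteins = n_diff_proteins, diff_log2fc = diff_log2fc,
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 seed = as.integer(seed)),
            class = "sim_params")
}

.AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Simulate a paired total/depleted dd-ABPP cohort with known ground truth
#'
#' Generates the two aliquots of each tissue lysate: the total extract
#' carries a log-normal transition baseline, a per-run shift and
#' multiplicative noise; the depleted extract is the same clean signal
#' scaled by `1 - alpha` for active enzymes (and by
#' `1 - strength * alpha` for coupled interaction partners), with its own
#' run shift and noise. Housekeeping (`HK`) proteins are never depleted and
#' carry half the noise, making them usable internal standards.
#'
#' @param params a [sim_params] object.
#' @return list with elements `quant` ([paired_quant]), `design`
#'   ([cohort_design]), `truth` (list: `alpha` condition-by-enzyme matrix,
#'   `coupled_pairs`, `class_effects`, feature bookkeeping), `catalog`
#'   ([enzyme_catalog]) and `isp_candidates` (HK protein ids).
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  set.seed(p$seed)

  ## design: half the patients long-survival, each with a T and an N sample
  patients <- sprintf("P%02d", seq_len(p$n_patients))
  survival <- rep(c("long", "short"), each = p$n_patients / 2)
  design <- data.frame(
    sample_id = c(paste0(patients, "_T"), paste0(patients, "_N")),
    patient_id = rep(patients, 2),
    tissue = rep(c("T", "N"), each = p$n_patients),
    survival = rep(survival, 2),
    age = rep(round(stats::rnorm(p$n_patients, 65, 8)), 2),
    sex = rep(stats::rbinom(p$n_patients, 1, 0.5), 2),
    smoking = rep(stats::rbinom(p$n_patients, 1, 0.6), 2),
    stringsAsFactors = FALSE)
  design$tumor_cell_pct <- ifelse(design$tissue == "T",
                                  round(stats::runif(nrow(design), 60, 100)),
                                  NA_real_)
  design <- cohort_design(design)
  conditions <- sort(unique(design$condition))

  enzymes <- sprintf("SH%03d", seq_len(p$n_enzymes))
  background <- if (p$n_background > 0)
    sprintf("BG%03d", seq_len(p$n_background)) else character()
  isp <- sprintf("HK%03d", seq_len(p$n_isp))
  proteins <- c(enzymes, background, isp)

  ## planted active fractions
  if (is.null(p$alpha)) {
    alpha <- matrix(0, nrow = length(conditions), ncol = p$n_enzymes,
                    dimnames = list(conditions, enzymes))
    active <- seq_len(ceiling(p$n_enzymes / 2))
    alpha[, active] <- round(stats::runif(length(conditions) * length(active),
                                          0.1, 0.9), 3)
  } else {
    alpha <- p$alpha
    if (is.null(dim(alpha)))
      alpha <- matrix(rep(alpha, each = length(conditions)),
                      nrow = length(conditions),
                      dimnames = list(conditions, enzymes))
    stopifnot(identical(sort(rownames(alpha)), conditions),
              ncol(alpha) == p$n_enzymes)
    alpha <- alpha[conditions, , drop = FALSE]
    colnames(alpha) <- enzymes
  }

  ## per-protein, per-condition depletion fraction
  dep_frac <- matrix(0, nrow = length(conditions), ncol = length(proteins),
                     dimnames = list(conditions, proteins))
  dep_frac[, enzymes] <- alpha
  cp <- p$codepletion_couplings
  if (!is.null(cp)) {
    if (!all(cp$enzyme %in% enzymes) || !all(cp$partner %in% background))
      stop("codepletion couplings must link a simulated enzyme to a ",
           "background protein")
    for (i in seq_len(nrow(cp))) {
      keep <- (1 - dep_frac[, cp$partner[i]]) *
        (1 - cp$strength[i] * alpha[, cp$enzyme[i]])
      dep_frac[, cp$partner[i]] <- 1 - keep
    }
  }

  ## tumor-vs-normal abundance offsets on a subset of background proteins
  class_eff <- matrix(0, nrow = length(conditions), ncol = length(proteins),
                      dimnames = list(conditions, proteins))
  n_diff <- min(p$n_diff_proteins, length(background))
  if (n_diff > 0) {
    diff_prot <- background[seq_len(n_diff)]
    class_eff[grepl("^T", conditions), diff_prot] <- p$diff_log2fc
  }

  ## feature table: proteins x peptides x transitions with fixed baselines
  n_pep <- p$peptides_per_protein
  n_tr <- p$transitions_per_peptide
  pep_seq <- vapply(seq_len(length(proteins) * n_pep), function(i)
    paste(sample(.AA, sample(9:15, 1), replace = TRUE), collapse = ""),
    character(1))
  feat <- data.frame(
    protein_id = rep(proteins, each = n_pep * n_tr),
    peptide_seq = rep(pep_seq, each = n_tr),
    transition_id = paste0(rep(pep_seq, each = n_tr), "_y",
                           rep(seq_len(n_tr), length(pep_seq)) + 3L),
    stringsAsFactors = FALSE)
  prot_base <- stats::rnorm(length(proteins), p$baseline_log2_mean,
                            p$baseline_log2_sd)
  names(prot_base) <- proteins
  pep_off <- rep(stats::rnorm(length(pep_seq), 0, 0.7), each = n_tr)
  tr_off <- stats::rnorm(nrow(feat), 0, 1)
  feat$clean_log2 <- prot_base[feat$protein_id] + pep_off + tr_off

  ## expand over samples and extracts
  n_feat <- nrow(feat)
  samples <- design$sample_id
  cond_of <- stats::setNames(design$condition, design$sample_id)
  long <- feat[rep(seq_len(n_feat), times = length(samples)), 1:4]
  long$sample_id <- rep(samples, each = n_feat)
  cond_idx <- match(cond_of[long$sample_id], conditions)
  prot_idx <- match(long$protein_id, proteins)
  ## specimen-level abundance, shared by both aliquots of a lysate
  bio <- matrix(stats::rnorm(length(proteins) * length(samples), 0,
                             p$biological_sd_log2),
                nrow = length(proteins),
                dimnames = list(proteins, samples))
  base <- long$clean_log2 +
    class_eff[cbind(cond_idx, prot_idx)] +
    bio[cbind(prot_idx, match(long$sample_id, samples))]

  run_eff <- matrix(stats::rnorm(2 * length(samples), 0, p$run_effect_sd),
                    nrow = length(samples), ncol = 2,
                    dimnames = list(samples, .EXTRACT_LEVELS))
  noise_sd <- ifelse(grepl("^HK", long$protein_id),
                     p$noise_sd_log2 / 2, p$noise_sd_log2)
  tot_log2 <- base + run_eff[cbind(long$sample_id, "total")] +
    stats::rnorm(nrow(long), 0, 1) * noise_sd
  d <- dep_frac[cbind(cond_idx, prot_idx)]
  dep_log2 <- base + log2(1 - d) + run_eff[cbind(long$sample_id, "depleted")] +
    stats::rnorm(nrow(long), 0, 1) * noise_sd

  quant <- rbind(
    data.frame(long[c("protein_id", "peptide_seq", "transition_id",
                      "sample_id")],
               extract = "total", intensity = 2^tot_log2,
               stringsAsFactors = FALSE),
    data.frame(long[c("protein_id", "peptide_seq", "transition_id",
                      "sample_id")],
               extract = "depleted", intensity = 2^dep_log2,
               stringsAsFactors = FALSE))

  if (p$missing_rate > 0) {
    if (p$missing_mode == "mcar") {
      drop <- stats::runif(nrow(quant)) < p$missing_rate
    } else {
      drop <- log2(quant$intensity) <
        stats::quantile(log2(quant$intensity), p$missing_rate)
    }
    quant$intensity[drop] <- NA_real_
  }
  quant <- paired_quant(quant)

  catalog <- enzyme_catalog(data.frame(
    protein_id = enzymes,
    class = rep_len(c("metabolic_SH", "serine_protease"), length(enzymes)),
    stringsAsFactors = FALSE))

  list(quant = quant, design = design,
       truth = list(alpha = alpha, coupled_pairs = cp,
                    class_effects = class_eff, depletion_fraction = dep_frac,
                    features = feat),
       catalog = catalog, isp_candidates = isp)
}

#' Simulate a random interactome with optional planted edges
#'
#' Erdos-Renyi-style graph: `n_edges` distinct unordered pairs drawn
#' uniformly from all pairs of `nodes`, plus any planted edges (always
#' present regardless of seed). This is the generator behind the
#' random-interactome null model used to judge co-depletion enrichment.
#'
#' @param n_nodes,n_edges graph size; `n_edges` may not exceed
#'   `n_nodes * (n_nodes - 1) / 2`.
#' @param planted data.frame (`protein_a`, `protein_b`) of edges that must
#'   be present; nodes must be known.
#' @param seed RNG seed.
#' @param nodes node names (default `P0001...`).
#' @param evidence evidence tier stamped on the edges.
#' @return an [interaction_set].
#' @export
simulate_interactome <- function(n_nodes, n_edges, planted = NULL, seed = 1L,
                                 nodes = NULL, evidence = "experimental") {
  if (is.null(nodes)) nodes <- sprintf("P%04d", seq_len(n_nodes))
  stopifnot(length(nodes) == n_nodes)
  max_edges <- n_nodes * (n_nodes - 1) / 2
  if (n_edges > max_edges)
    stop("n_edges exceeds the number of distinct pairs (", max_edges, ")")
  set.seed(seed)
  idx <- sample.int(max_edges, n_edges)
  ## map linear index over the upper triangle to an (i, j) pair
  i <- ceiling(n_nodes - 0.5 - sqrt((n_nodes - 0.5)^2 - 2 * idx))
  j <- idx - (i - 1) * n_nodes + i * (i - 1) / 2 + i
  edges <- data.frame(protein_a = nodes[i], protein_b = nodes[j],
                      evidence = evidence, stringsAsFactors = FALSE)
  if (!is.null(planted)) {
    planted <- as.data.frame(planted, stringsAsFactors = FALSE)
    unknown <- setdiff(c(planted$protein_a, planted$protein_b), nodes)
    if (length(unknown))
      stop("planted edge references unknown node(s): ",
           paste(unknown, collapse = ", "))
    planted$evidence <- evidence
    edges <- rbind(edges, planted[c("protein_a", "protein_b", "evidence")])
  }
  graph <- interaction_set(edges)
  attr(graph, "nodes") <- nodes
  graph
}

#' Simulate a binary patient-by-gene mutation table
#'
#' An anchor oncogene (KRAS stand-in) mutates at `anchor_rate`; each other
#' gene mutates at its own rate, boosted among anchor-mutated patients and
#' damped among the rest by `cooccurrence_boost` (rate `min(1, p * boost)`
#' vs `p / boost`), so `boost = 1` gives independence and `boost -> Inf`
#' confines the gene to anchor-mutated patients.
#'
#' @param n_patients number of patients (rows).
#' @param anchor_rate anchor mutation probability.
#' @param gene_rates named vector of per-gene baseline mutation rates.
#' @param cooccurrence_boost named vector of boosts (default 1 for all).
#' @param seed RNG seed.
#' @param anchor_gene column name of the anchor.
#' @return integer 0/1 matrix, patients x (anchor + genes).
#' @export
simulate_mutation_table <- function(n_patients, anchor_rate, gene_rates,
                                    cooccurrence_boost = NULL, seed = 1L,
                                    anchor_gene = "ANCHOR") {
  stopifnot(anchor_rate >= 0, anchor_rate <= 1,
            all(gene_rates >= 0 & gene_rates <= 1))
  genes <- names(gene_rates)
  if (is.null(genes)) stop("gene_rates must be named")
  boost <- stats::setNames(rep(1, length(genes)), genes)
  if (!is.null(cooccurrence_boost))
    boost[names(cooccurrence_boost)] <- cooccurrence_boost
  if (any(boost < 1)) stop("cooccurrence boosts must be >= 1")
  set.seed(seed)
  anchor <- stats::rbinom(n_patients, 1, anchor_rate)
  m <- vapply(genes, function(g) {
    rate <- ifelse(anchor == 1, pmin(1, gene_rates[[g]] * boost[[g]]),
                   gene_rates[[g]] / boost[[g]])
    stats::rbinom(n_patients, 1, rate)
  }, integer(n_patients))
  out <- cbind(anchor, m)
  colnames(out) <- c(anchor_gene, genes)
  rownames(out) <- sprintf("PT%04d", seq_len(n_patients))
  out
}
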