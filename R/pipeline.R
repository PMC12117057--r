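#' Default pipeline configuration
#'
#' Nested key/value configuration for [run_pipeline]. Thresholds default
#' to the analysis conventions used throughout the package: KS gate at
#' 0.05, co-depletion strata 0.05/0.01, Spearman screen |rho| > 0.6,
#' correlation pairing |r| > 0.4, 200 random interactomes, 100 random
#' physical-evidence subsets, 5 CV folds. Every stochastic stage derives
#' its seed from `seed` and records it in the run manifest.
#'
#' @param out_dir artifact directory.
#' @param seed master seed.
#' @return nested list; can also be written as / read from YAML.
#' @export
default_config <- function(out_dir = tempfile("ddabpp_run_"), seed = 1L) {
  list(
    out_dir = out_dir,
    seed = as.integer(seed),
    simulate = list(),  # sim_params() arguments; NULL entries use defaults
    inputs = list(quant = NULL, design = NULL, catalog = NULL,
                  isp_candidates = NULL, edges = NULL),
    thresholds = list(ks_alpha = 0.05, codepletion_strata = c(0.05, 0.01),
                      rho_min = 0.6, cor_min = 0.4, cor_p = 0.05,
                      n_random_interactome = 200, n_random_physical = 100,
                      folds = 5),
    differential = list(covariates = c("age", "sex", "smoking")),
    classify = list(ncomp_max = NULL)
  )
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  path
}

.merge_config <- function(user, base) {
  for (k in names(user)) {
    base[[k]] <- if (is.list(user[[k]]) && is.list(base[[k]]))
      .merge_config(user[[k]], base[[k]]) else user[[k]]
  }
  base
}

#' Run the full dd-ABPP analysis pipeline
#'
#' Chains simulate (or load) -> select-isp -> normalize -> impute ->
#' raddi -> differential -> interactome -> classify, writing each stage's
#' output table under `out_dir` together with a manifest (stage list,
#' seeds, parameter echo, md5 checksums). A stage failure aborts with the
#' failing stage named; outputs of completed stages are retained. The
#' same configuration reproduces byte-identical outputs.
#'
#' @param config a [default_config]-style list, or the path of a YAML
#'   file holding one (flags given in the list override the defaults).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- .merge_config(config, default_config())
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds
  seed <- as.integer(config$seed)
  stages <- character()
  files <- character()
  res <- list()

  run_stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    stages <<- c(stages, name)
    out
  }

  ## 1. simulate (or load user inputs)
  res$sim <- run_stage("simulate", {
    if (!is.null(config$inputs$quant)) {
      if (is.null(config$inputs$design) || is.null(config$inputs$catalog))
        stop("quant input given without design/catalog")
      list(quant = read_quant_table(config$inputs$quant),
           design = read_design(config$inputs$design),
           catalog = read_catalog(config$inputs$catalog),
           isp_candidates = if (!is.null(config$inputs$isp_candidates))
             readLines(config$inputs$isp_candidates),
           truth = NULL)
    } else {
      params <- do.call(sim_params,
                        c(config$simulate[!vapply(config$simulate, is.null,
                                                  logical(1))],
                          if (is.null(config$simulate$seed))
                            list(seed = seed)))
      sim <- simulate_cohort(params)
      files <- c(files,
                 .write_tsv(as.data.frame(sim$quant),
                             file.path(out_dir, "quant.tsv")),
                  .write_tsv(as.data.frame(sim$design),
                             file.path(out_dir, "design.tsv")),
                  .write_tsv(data.frame(condition = rownames(sim$truth$alpha),
                                        sim$truth$alpha,
                                        check.names = FALSE),
                             file.path(out_dir, "truth_alpha.tsv")))
      sim
    }
  })
  quant <- res$sim$quant
  design <- res$sim$design

  ## 2. internal-standard selection
  res$isp <- run_stage("select_isp", {
    if (is.null(res$sim$isp_candidates) || !length(res$sim$isp_candidates))
      stop("no ISP candidate ids available; supply inputs$isp_candidates ",
           "(one housekeeping/cytoskeletal protein id per line) -- without ",
           "candidates no noise reference can be selected")
    isp <- select_isp(quant, isp_criteria(res$sim$isp_candidates))
    files <- c(files, .write_tsv(as.data.frame(isp),
                                 file.path(out_dir, "isp.tsv")))
    isp
  })

  ## 3-4. normalization and imputation
  quant_n <- run_stage("normalize", normalize_by_isp(quant, res$isp))
  files <- c(files, .write_tsv(as.data.frame(quant_n),
                               file.path(out_dir, "quant_normalized.tsv")))
  quant_i <- run_stage("impute",
                       suppressWarnings(impute_missing(quant_n,
                                                       seed = seed + 1L)))

  ## 5. activity estimation (ratios intentionally use observed, matched
  ## transitions of the normalized table; imputed table feeds abundances)
  res$fit <- run_stage("raddi", {
    fit <- ddabpp(quant_n, design, res$isp, res$sim$catalog,
                  alpha = th$ks_alpha)
    act <- summary(fit)
    long <- expand.grid(enzyme_id = rownames(fit$raddi),
                        sample_id = colnames(fit$raddi),
                        stringsAsFactors = FALSE)
    long$log2_delta_int <- fit$log2_delta[cbind(long$enzyme_id,
                                                long$sample_id)]
    long$raddi <- fit$raddi[cbind(long$enzyme_id, long$sample_id)]
    long$condition <- design$condition[match(long$sample_id,
                                             design$sample_id)]
    key <- paste(long$enzyme_id, long$condition)
    gkey <- paste(fit$gates$enzyme_id, fit$gates$condition)
    long$ks_p <- fit$gates$ks_p[match(key, gkey)]
    long$gated <- fit$gates$gated[match(key, gkey)]
    files <- c(files, .write_tsv(long, file.path(out_dir, "activity.tsv")))
    fit
  })

  ## 6. differential activity (quasibinomial probit on RADDi)
  res$differential <- run_stage("differential", {
    spec <- glm_spec("quasibinomial_probit",
                     covariates = config$differential$covariates)
    raddi <- coef(res$fit)
    rows <- list()
    for (e in rownames(raddi)) {
      y <- raddi[e, design$sample_id]
      if (all(is.na(y)) || stats::sd(y, na.rm = TRUE) == 0) next
      tr <- try(fit_glm(y, design, spec, feature_id = e), silent = TRUE)
      if (!inherits(tr, "try-error")) rows[[e]] <- tr
    }
    out <- do.call(rbind, rows)
    if (!is.null(out)) {
      out$q <- NA_real_
      for (ct in unique(out$contrast))
        out$q[out$contrast == ct] <- adjust_bh(out$p[out$contrast == ct])
      files <- c(files, .write_tsv(out, file.path(out_dir,
                                                  "differential.tsv")))
    }
    out
  })

  ## 7. co-depletion interactome
  res$interactome <- run_stage("interactome", {
    proteins <- setdiff(unique(quant$protein_id),
                        c(res$isp$protein_id, res$sim$catalog$protein_id))
    graph <- if (!is.null(config$inputs$edges))
      read_interactions(config$inputs$edges)
    else {
      planted <- if (!is.null(res$sim$truth$coupled_pairs))
        data.frame(protein_a = res$sim$truth$coupled_pairs$enzyme,
                   protein_b = res$sim$truth$coupled_pairs$partner,
                   stringsAsFactors = FALSE) else NULL
      nodes <- unique(quant$protein_id)
      simulate_interactome(length(nodes),
                           n_edges = min(5L * length(nodes),
                                         length(nodes) * (length(nodes) - 1) / 2),
                           planted = planted, seed = seed + 2L,
                           nodes = nodes)
    }
    calls <- call_codepleted(quant_n, res$isp, design, proteins = proteins)
    called <- unique(calls$protein_id[calls$condition == "pooled" &
                                        calls$depleted_p05])
    degree <- annotate_degree(called, graph, res$sim$catalog$protein_id)
    universe <- unique(quant$protein_id)
    first_deg <- setdiff(.neighbors(.adjacency(graph),
                                    res$sim$catalog$protein_id),
                         res$sim$catalog$protein_id)
    null1 <- random_interactome_null(length(intersect(called, first_deg)),
                                     graph, universe,
                                     n_sh = nrow(res$sim$catalog),
                                     depleted = called,
                                     n_iter = th$n_random_interactome,
                                     seed = seed + 3L)
    dm <- depletion_matrix(quant_n, proteins = called)
    pairs <- correlation_pairs(coef(res$fit), dm$ratio, r_min = th$cor_min,
                               p_max = th$cor_p, evidence_graph = graph)
    null2 <- if (any(pairs$retained))
      physical_overlap_null(pairs, graph, universe,
                            n_iter = th$n_random_physical,
                            seed = seed + 4L) else NULL
    files <- c(files,
               .write_tsv(calls, file.path(out_dir, "codepletion.tsv")),
               .write_tsv(data.frame(protein_id = names(degree),
                                     degree = unname(degree)),
                          file.path(out_dir, "interactor_degree.tsv")),
               .write_tsv(pairs, file.path(out_dir, "pairs.tsv")))
    jsonlite::write_json(list(
      interactome_null = null1[c("observed", "null_mean", "null_sd", "z",
                                 "p")],
      physical_null = if (!is.null(null2))
        null2[c("observed", "null_mean", "null_sd", "z", "p")]),
      file.path(out_dir, "interactome_null.json"), auto_unbox = TRUE,
      digits = NA)
    files <- c(files, file.path(out_dir, "interactome_null.json"))
    list(calls = calls, degree = degree, null_interactome = null1,
         pairs = pairs, null_physical = null2)
  })

  ## 8. consensus classification
  res$consensus <- run_stage("classify", {
    raddi <- coef(res$fit)
    raddi <- raddi[apply(raddi, 1, function(x) all(is.na(x)) == FALSE &&
                           stats::sd(x, na.rm = TRUE) > 0), , drop = FALSE]
    raddi[is.na(raddi)] <- 0
    called <- unique(res$interactome$calls$protein_id[
      res$interactome$calls$condition == "pooled" &
        res$interactome$calls$depleted_p05])
    dm <- depletion_matrix(impute_missing(quant_n, seed = seed + 5L),
                           proteins = if (length(called) >= 2) called
                           else unique(quant$protein_id))
    dep <- dm$ratio
    dep <- dep[stats::complete.cases(dep), , drop = FALSE]
    if (nrow(raddi) < 2 || nrow(dep) < 2)
      stop("too few informative features for classification")
    y <- design$condition[match(colnames(raddi), design$sample_id)]
    cm <- tune_cv(list(activity = t(raddi), depletion = t(dep[, colnames(raddi),
                                                              drop = FALSE])),
                  y, folds = th$folds, seed = seed + 6L,
                  scale = c(FALSE, TRUE))
    files <- c(files,
               .write_tsv(data.frame(block = rep(names(cm$selected),
                                                 lengths(cm$selected)),
                                     feature = unlist(cm$selected)),
                          file.path(out_dir, "classifiers.tsv")))
    jsonlite::write_json(list(cv_error = cm$cv_error, folds = cm$folds,
                              n_components = cm$n_components,
                              n_classifiers = sum(lengths(cm$selected))),
                         file.path(out_dir, "consensus_model.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, file.path(out_dir, "consensus_model.json"))
    cm
  })

  manifest <- list(
    stages = stages,
    seed = seed,
    stage_seeds = list(simulate = seed, impute = seed + 1L,
                       interactome_graph = seed + 2L,
                       interactome_null = seed + 3L,
                       physical_null = seed + 4L,
                       classify_impute = seed + 5L, tune_cv = seed + 6L),
    thresholds = th,
    parameters = config$simulate,
    checksums = {
      f <- sort(unique(files))
      stats::setNames(as.list(unname(tools::md5sum(f))), basename(f))
    })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
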