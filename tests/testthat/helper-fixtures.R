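# In-code fixtures shared across test files.

# 6-row toy table: 1 protein x 1 peptide x 3 transitions x 1 sample x 2
# extracts
toy_quant_df <- function() {
  data.frame(
    protein_id = "SH001",
    peptide_seq = "LVDELKSAGK",
    transition_id = paste0("LVDELKSAGK_y", 4:6),
    sample_id = "S1",
    extract = rep(c("total", "depleted"), each = 3),
    intensity = c(200, 600, 100, 100, 300, 25),
    stringsAsFactors = FALSE)
}

toy_design_df <- function(n_patients = 12) {
  patients <- sprintf("P%02d", seq_len(n_patients))
  data.frame(
    sample_id = c(paste0(patients, "_T"), paste0(patients, "_N")),
    patient_id = rep(patients, 2),
    tissue = rep(c("T", "N"), each = n_patients),
    survival = rep(rep(c("long", "short"), each = n_patients / 2), 2),
    age = 60, sex = 0, smoking = 1,
    stringsAsFactors = FALSE)
}

# small noisy cohort reused by several files (computed once per session)
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_cohort(sim_params(n_enzymes = 10,
                                           n_background = 20,
                                           seed = 101L))
    cache
  }
})

# vectors with an exact sample Pearson correlation r
exact_cor_pair <- function(n, r, seed = 1) {
  set.seed(seed)
  x <- as.vector(scale(stats::rnorm(n)))
  e <- stats::rnorm(n)
  e <- stats::residuals(stats::lm(e ~ x))
  e <- as.vector(scale(e))
  list(x = x, y = r * x + sqrt(1 - r^2) * e)
}

cli_main_for_tests <- function(args) ddabpp:::cli_main(args)

# independent step-up BH oracle
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    prev <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- prev
  }
  q
}
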