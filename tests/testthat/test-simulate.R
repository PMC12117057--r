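test_that("noiseless depletion is exact by construction", {
  al <- matrix(0, nrow = 4, ncol = 3,
               dimnames = list(c("N_long", "N_short", "T_long", "T_short"),
                               sprintf("SH%03d", 1:3)))
  al[c("T_long", "T_short"), "SH001"] <- 0.7
  sim <- simulate_cohort(sim_params(n_patients = 4, n_enzymes = 3,
                                    n_background = 2, n_isp = 2,
                                    alpha = al, noise_sd_log2 = 0,
                                    run_effect_sd = 0, missing_rate = 0,
                                    seed = 3L))
  q <- sim$quant
  t_samples <- sim$design$sample_id[sim$design$tissue == "T"]
  for (s in t_samples) {
    tot <- sum(q$intensity[q$protein_id == "SH001" & q$sample_id == s &
                             q$extract == "total"])
    dep <- sum(q$intensity[q$protein_id == "SH001" & q$sample_id == s &
                             q$extract == "depleted"])
    expect_equal(dep / tot, 0.3, tolerance = 1e-12)
  }
})

test_that("alpha = 0 with zero noise makes both extracts identical", {
  sim <- simulate_cohort(sim_params(n_patients = 2, n_enzymes = 2,
                                    n_background = 2, n_isp = 2,
                                    alpha = matrix(0, 4, 2,
                                                   dimnames = list(
                                                     c("N_long", "N_short",
                                                       "T_long", "T_short"),
                                                     NULL)),
                                    noise_sd_log2 = 0, run_effect_sd = 0,
                                    missing_rate = 0, seed = 5L))
  q <- sim$quant
  tot <- q[q$extract == "total", ]
  dep <- q[q$extract == "depleted", ]
  key <- function(x) paste(x$protein_id, x$transition_id, x$sample_id)
  expect_identical(dep$intensity[order(key(dep))],
                   tot$intensity[order(key(tot))])
})

test_that("the generator is byte-deterministic under its seed", {
  p <- sim_params(n_patients = 4, n_enzymes = 3, n_background = 3,
                  n_isp = 2, seed = 9L)
  expect_identical(simulate_cohort(p), simulate_cohort(p))
  expect_false(identical(
    simulate_cohort(p)$quant$intensity,
    simulate_cohort(sim_params(n_patients = 4, n_enzymes = 3,
                               n_background = 3, n_isp = 2,
                               seed = 10L))$quant$intensity))
})

test_that("parameter validation rejects out-of-range settings", {
  expect_error(sim_params(alpha = matrix(1.2, 4, 2)), "\\[0, 1\\]")
  expect_error(sim_params(missing_rate = 1), "missing_rate")
  expect_error(
    simulate_cohort(sim_params(
      n_patients = 2, n_enzymes = 2, n_background = 2, n_isp = 2,
      codepletion_couplings = data.frame(enzyme = "SH001",
                                         partner = "XXX",
                                         strength = 0.5))),
    "background protein")
})

test_that("random interactomes honour size, planting and mean degree", {
  g <- simulate_interactome(4, 6, seed = 1)
  expect_equal(nrow(g), 6L)  # complete graph on 4 nodes

  planted <- data.frame(protein_a = "P0001", protein_b = "P0002")
  for (s in 1:5) {
    gs <- simulate_interactome(20, 10, planted = planted, seed = s)
    expect_true(any(gs$protein_a == "P0001" & gs$protein_b == "P0002"))
  }
  expect_error(simulate_interactome(4, 7), "distinct pairs")
  expect_error(simulate_interactome(10, 5,
                                    planted = data.frame(protein_a = "Q1",
                                                         protein_b = "P0001")),
               "unknown node")

  # mean degree over 200 seeds approximates 2E/N
  degs <- vapply(1:200, function(s) {
    gs <- simulate_interactome(30, 60, seed = s)
    mean(table(factor(c(gs$protein_a, gs$protein_b),
                      levels = attr(gs, "nodes"))))
  }, numeric(1))
  expect_equal(mean(degs), 2 * 60 / 30, tolerance = 0.02)
})

test_that("mutation tables reproduce their planted co-occurrence", {
  # infinite boost confines the gene to anchor-mutated patients
  m <- simulate_mutation_table(500, 0.3, c(G = 0.4),
                               cooccurrence_boost = c(G = 1e9), seed = 2)
  expect_true(all(m[m[, "G"] == 1, "ANCHOR"] == 1))

  # boost 1: independence, so Fisher calls at 0.05 stay near/below nominal
  pvals <- vapply(1:200, function(s) {
    mt <- simulate_mutation_table(150, 0.3, c(G = 0.3), seed = 1000 + s)
    fisher_cooccurrence(mt, "ANCHOR")$p
  }, numeric(1))
  expect_lte(mean(pvals < 0.05), 0.07)
  expect_gt(mean(pvals), 0.4)  # conservative discrete null, not enriched
})

test_that("RADDi error shrinks as feature depth grows", {
  al <- matrix(0.5, 4, 5, dimnames = list(c("N_long", "N_short", "T_long",
                                            "T_short"), NULL))
  mae <- function(k_pep, k_tr, seed) {
    sim <- simulate_cohort(sim_params(n_patients = 6, n_enzymes = 5,
                                      n_background = 2, n_isp = 4,
                                      peptides_per_protein = k_pep,
                                      transitions_per_peptide = k_tr,
                                      alpha = al, noise_sd_log2 = 0.3,
                                      run_effect_sd = 0, missing_rate = 0,
                                      seed = seed))
    dm <- depletion_matrix(sim$quant, proteins = colnames(sim$truth$alpha))
    mean(abs(raddi_from_ratio(dm$ratio) - 0.5), na.rm = TRUE)
  }
  shallow <- mean(vapply(1:3, function(s) mae(1, 1, s), numeric(1)))
  deep <- mean(vapply(1:3, function(s) mae(3, 4, s), numeric(1)))
  expect_lt(deep, shallow)
})
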