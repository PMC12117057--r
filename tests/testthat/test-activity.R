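test_that("depletion ratios follow the matched-transition sum formula", {
  q <- paired_quant(data.frame(
    protein_id = "SH001", peptide_seq = c("AAAAKAAAK", "CCCCKCCCK"),
    transition_id = c("t1", "t2"), sample_id = "S1",
    extract = rep(c("depleted", "total"), each = 2),
    intensity = c(100, 300, 200, 600), stringsAsFactors = FALSE))
  r <- compute_depletion_ratio(q, "SH001", "S1")
  expect_equal(r$log2_delta_int, log2(400) - log2(800))  # exactly -1
  expect_equal(r$k_peptides, 2L)
  expect_equal(r$matched_transitions, 2L)

  # depleted identical to total -> 0; quartered per transition -> -2
  q2 <- as.data.frame(q)
  q2$intensity[q2$extract == "depleted"] <- q2$intensity[q2$extract ==
                                                           "total"]
  expect_equal(compute_depletion_ratio(paired_quant(q2), "SH001",
                                       "S1")$log2_delta_int, 0)
  q3 <- as.data.frame(q)
  q3$intensity[q3$extract == "depleted"] <-
    0.25 * q3$intensity[q3$extract == "total"]
  expect_equal(compute_depletion_ratio(paired_quant(q3), "SH001",
                                       "S1")$log2_delta_int, -2)

  # unmatched transitions are excluded; none matched -> NA, not zero
  q4 <- as.data.frame(q)[-1, ]
  r4 <- compute_depletion_ratio(paired_quant(q4), "SH001", "S1")
  expect_equal(r4$matched_transitions, 1L)
  q5 <- as.data.frame(q)[q$extract == "total", ]
  expect_true(is.na(compute_depletion_ratio(paired_quant(q5), "SH001",
                                            "S1")$log2_delta_int))
})

test_that("ratios are invariant to per-sample rescaling of both extracts", {
  sim <- small_cohort()
  dm1 <- depletion_matrix(sim$quant)
  q <- as.data.frame(sim$quant)
  q$intensity[q$sample_id == "P03_T"] <- 7 * q$intensity[q$sample_id ==
                                                           "P03_T"]
  dm2 <- depletion_matrix(paired_quant(q))
  expect_equal(dm1$ratio, dm2$ratio, tolerance = 1e-12)
})

test_that("RADDi transform clamps enrichment and decreases in the ratio", {
  expect_equal(raddi_from_ratio(-1), 0.5)
  expect_equal(raddi_from_ratio(0), 0)
  expect_equal(raddi_from_ratio(0.5), 0)   # apparent enrichment is noise
  expect_true(is.na(raddi_from_ratio(NA)))
  grid <- seq(-10, 0, by = 0.1)
  expect_true(all(diff(raddi_from_ratio(grid)) < 0))
  expect_equal(raddi_from_ratio(5), 0)              # clamp above
  expect_equal(raddi_from_ratio(-50), 1, tolerance = 1e-9)
})

test_that("the ISP reference captures the pairing noise model", {
  conds <- c("N_long", "N_short", "T_long", "T_short")
  # noiseless: every reference ratio is exactly zero
  sim0 <- simulate_cohort(sim_params(n_patients = 4, n_enzymes = 2,
                                     n_background = 2, n_isp = 6,
                                     alpha = matrix(0, 4, 2,
                                                    dimnames = list(conds,
                                                                    NULL)),
                                     noise_sd_log2 = 0, run_effect_sd = 0,
                                     missing_rate = 0, seed = 21))
  isp0 <- data.frame(protein_id = sim0$isp_candidates,
                     peptide_seq = NA)
  isp0 <- unique(as.data.frame(sim0$quant)[
    sim0$quant$protein_id %in% sim0$isp_candidates,
    c("protein_id", "peptide_seq")])
  ref0 <- isp_reference_distribution(sim0$quant, isp0,
                                     sim0$design$sample_id)
  expect_equal(ref0, rep(0, length(ref0)), tolerance = 1e-12)

  # independent noise in both extracts: ratio sd = noise_sd * sqrt(2);
  # one transition per protein makes the relation exact (HK noise is
  # halved by the generator, so noise 0.4 puts the reference at 0.2)
  sim1 <- simulate_cohort(sim_params(n_patients = 12, n_enzymes = 2,
                                     n_background = 2, n_isp = 20,
                                     peptides_per_protein = 1,
                                     transitions_per_peptide = 1,
                                     alpha = matrix(0, 4, 2,
                                                    dimnames = list(conds,
                                                                    NULL)),
                                     noise_sd_log2 = 0.4,
                                     run_effect_sd = 0, missing_rate = 0,
                                     seed = 22))
  isp1 <- unique(as.data.frame(sim1$quant)[
    sim1$quant$protein_id %in% sim1$isp_candidates,
    c("protein_id", "peptide_seq")])
  ref1 <- isp_reference_distribution(sim1$quant, isp1,
                                     sim1$design$sample_id)
  expect_equal(sd(ref1), 0.2 * sqrt(2), tolerance = 0.1)

  expect_error(isp_reference_distribution(sim1$quant, isp1, character()),
               "no samples")
})

test_that("the one-sided KS gate matches its closed form and R", {
  # fully separated samples, m = n = 6: D+ = 1, p = exp(-6)
  g <- ks_gate(rep(-3, 6), rep(0, 6))
  expect_equal(g$statistic, 1)
  expect_equal(g$p, exp(-6))
  expect_true(g$gated)

  # undersized enzyme sample: not gated, p missing
  g2 <- ks_gate(c(-3, -3), rep(0, 6))
  expect_false(g2$gated)
  expect_true(is.na(g2$p))

  # agreement with stats::ks.test on continuous data, both variants
  set.seed(31)
  x <- rnorm(8, -0.5)
  y <- rnorm(40)
  expect_equal(ks_gate(x, y)$p,
               ks.test(x, y, alternative = "greater",
                       exact = FALSE)$p.value)
  expect_equal(ks_gate(x, y, exact = TRUE)$p,
               ks.test(x, y, alternative = "greater",
                       exact = TRUE)$p.value)
  expect_error(ks_gate(x, numeric(0)), "empty reference")
})

test_that("activity fitting recovers planted fractions and gates nulls", {
  conds <- c("N_long", "N_short", "T_long", "T_short")
  al <- matrix(rep(c(0, 0.3, 0.7, 0.9, 0, 0.5, 0, 0.8, 0.2, 0),
                   each = 4), 4, 10, dimnames = list(conds, NULL))
  sim <- simulate_cohort(sim_params(n_patients = 12, n_enzymes = 10,
                                    n_background = 5, n_isp = 10,
                                    alpha = al, noise_sd_log2 = 0,
                                    missing_rate = 0, seed = 33))
  isp <- select_isp(sim$quant, isp_criteria(sim$isp_candidates))
  qn <- normalize_by_isp(sim$quant, isp)
  fit <- ddabpp(qn, sim$design, isp, sim$catalog)
  expect_s3_class(fit, "ddabpp")

  g <- summary(fit)
  gated <- g[g$gated, ]
  planted <- sim$truth$alpha[cbind(gated$condition, gated$enzyme_id)]
  expect_true(all(planted > 0))           # no null enzyme opens the gate
  expect_equal(gated$mean_raddi, planted, tolerance = 1e-12)
  # every enzyme with planted activity is gated in every condition
  expect_equal(nrow(gated), sum(sim$truth$alpha > 0))

  # accessors and methods
  expect_identical(coef(fit), fit$raddi)
  expect_identical(coef(fit, "log2_delta"), fit$log2_delta)
  expect_output(print(fit), "dd-ABPP activity profile")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("peptide-level pooling is available behind a flag", {
  sim <- small_cohort()
  isp <- select_isp(sim$quant, isp_criteria(sim$isp_candidates))
  qn <- normalize_by_isp(sim$quant, isp)
  fit_s <- ddabpp(qn, sim$design, isp, sim$catalog, pool = "sample")
  fit_p <- ddabpp(qn, sim$design, isp, sim$catalog, pool = "peptide")
  expect_identical(fit_s$log2_delta, fit_p$log2_delta)
  expect_gt(mean(fit_p$gates$m, na.rm = TRUE),
            mean(fit_s$gates$m, na.rm = TRUE))
})
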