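design24 <- cohort_design(toy_design_df())

test_that("the Gaussian GLM reproduces the two-sample t-test", {
  sub <- design24[design24$tissue == "T", ]
  set.seed(11)
  for (i in 1:5) {
    y <- rnorm(nrow(sub), mean = ifelse(sub$survival == "short", 0.4, 0))
    r <- fit_glm(y, sub, glm_spec("gaussian",
                                  contrasts = list(c("T_short", "T_long"))))
    tt <- t.test(y[sub$condition == "T_short"],
                 y[sub$condition == "T_long"], var.equal = TRUE)
    expect_equal(r$p, tt$p.value, tolerance = 1e-12)
    expect_equal(r$estimate, unname(diff(rev(tt$estimate))),
                 tolerance = 1e-12)
  }

  # identical response vectors in both groups: estimate 0, p ~ 1
  yc <- rep(rep(c(1, 2, 3), 2), 2)
  r0 <- fit_glm(yc, sub, glm_spec("gaussian",
                                  contrasts = list(c("T_short", "T_long"))))
  expect_equal(r0$estimate, 0)
  expect_gt(r0$p, 0.99)
})

test_that("probit quasibinomial fits detect planted activity contrasts", {
  sub <- design24[design24$tissue == "T", ]
  spec <- glm_spec("quasibinomial_probit",
                   contrasts = list(c("T_short", "T_long")))
  # planted 0.6 vs 0.1, n = 6 vs 6, noise sd 0.05: significant in >= 90%
  hits <- vapply(1:300, function(s) {
    set.seed(s)
    y <- pmin(pmax(ifelse(sub$survival == "short", 0.6, 0.1) +
                     rnorm(12, 0, 0.05), 0), 1)
    fit_glm(y, sub, spec)$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # fitted group means match noiseless proportions (probit is exact there)
  y <- ifelse(sub$survival == "short", 0.6, 0.1)
  r <- fit_glm(y, sub, spec)
  expect_equal(r$estimate, qnorm(0.6) - qnorm(0.1), tolerance = 1e-4)

  # responses outside [0, 1] and non-integer Poisson counts are rejected
  expect_error(fit_glm(c(rep(1.2, 6), rep(0.1, 6)), sub, spec), "\\[0, 1\\]")
  expect_error(fit_glm(rep(c(0.5, 2), 6), sub,
                       glm_spec("poisson")), "integer")
})

test_that("covariate adjustment works and collinearity is caught", {
  spec <- glm_spec("gaussian", covariates = c("age", "sex", "smoking"))
  d <- design24
  set.seed(3)
  d$age <- rep(round(rnorm(12, 65, 8)), 2)
  d$sex <- rep(rbinom(12, 1, 0.5), 2)
  d$smoking <- rep(rbinom(12, 1, 0.6), 2)
  y <- 0.05 * d$age + rnorm(24, 0, 0.2)
  r <- fit_glm(y, d, spec)
  expect_equal(nrow(r), 6L)        # all pairwise contrasts of 4 conditions
  expect_true(all(r$p_adj >= r$p - 1e-12, na.rm = TRUE))

  d2 <- d
  d2$smoking <- as.integer(d2$tissue == "T")  # collinear with condition
  expect_error(fit_glm(y, d2, spec), "collinear")
})

test_that("BH adjustment matches an independent step-up oracle", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(adjust_bh(0.04), 0.04)
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  set.seed(19)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))^sample(1:3, 1)
    expect_equal(adjust_bh(p), bh_oracle(p), tolerance = 1e-12)
  }
  # missing p-values stay missing and shrink the family
  p <- c(0.01, NA, 0.04)
  q <- adjust_bh(p)
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], bh_oracle(p[c(1, 3)]))
})

test_that("the Spearman screen flags strong monotone associations only", {
  act <- matrix(NA_real_, 2, 12,
                dimnames = list(c("SH001", "SH002"), paste0("S", 1:12)))
  act[1, ] <- 1:12                      # strictly monotone with covariate
  act[2, ] <- rep(0.5, 12)              # constant: skipped
  covs <- matrix((1:12)^2, 12, 1, dimnames = list(paste0("S", 1:12), "Cd"))
  res <- spearman_screen(act, covs)
  expect_true(res$flagged[res$enzyme_id == "SH001"])
  expect_equal(res$rho[res$enzyme_id == "SH001"], 1)
  expect_equal(res$note[res$enzyme_id == "SH002"], "constant vector")

  # rho about 0.5 at n = 12 sits below the 0.6 cutoff: not flagged
  pair <- exact_cor_pair(12, 0.5, seed = 2)
  act2 <- matrix(rank(pair$x), 1, 12,
                 dimnames = list("SH001", paste0("S", 1:12)))
  cv2 <- matrix(rank(pair$y), 12, 1,
                dimnames = list(paste0("S", 1:12), "Cd"))
  res2 <- spearman_screen(act2, cv2)
  expect_false(res2$flagged)

  # null flag rate matches a direct simulation of the same rule
  n <- 12
  flags <- vapply(1:1000, function(s) {
    set.seed(s)
    rho <- cor(rnorm(n), rnorm(n), method = "spearman")
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    abs(rho) > 0.6 && 2 * pt(abs(tt), n - 2, lower.tail = FALSE) < 0.05
  }, logical(1))
  screened <- vapply(1:1000, function(s) {
    set.seed(s)
    a <- matrix(rnorm(n), 1, dimnames = list("E", paste0("S", 1:n)))
    cv <- matrix(rnorm(n), n, 1, dimnames = list(paste0("S", 1:n), "V"))
    spearman_screen(a, cv)$flagged
  }, logical(1))
  expect_identical(mean(screened), mean(flags))
})

test_that("Fisher co-occurrence equals the hypergeometric tail", {
  # gene mutated in 20 patients, 15 anchor-positive, background 30/100
  mut <- matrix(0L, 100, 2, dimnames = list(NULL, c("KRAS", "G")))
  mut[1:30, "KRAS"] <- 1L
  mut[c(1:15, 31:35), "G"] <- 1L
  res <- fisher_cooccurrence(mut, "KRAS", protein_lengths = c(G = 400))
  # brute-force tail enumeration of the 2x2 with fixed margins
  tail_p <- sum(vapply(15:20, function(k)
    choose(30, k) * choose(70, 20 - k) / choose(100, 20), numeric(1)))
  expect_equal(res$p, tail_p, tolerance = 1e-12)
  expect_equal(res$rate_per_residue, 20 / 400)
  expect_equal(res$cooccurrence_frac, 15 / 20)

  # perfect co-occurrence approaches the minimal attainable p
  m2 <- simulate_mutation_table(300, 0.3, c(G = 0.4),
                                cooccurrence_boost = c(G = 1e9), seed = 5)
  res2 <- fisher_cooccurrence(m2, "ANCHOR")
  k <- res2$n_mutated
  anchors <- sum(m2[, "ANCHOR"])
  min_p <- choose(anchors, k) / choose(300, k)
  expect_equal(res2$p, min_p, tolerance = 1e-9)

  # never-mutated genes are excluded
  m3 <- cbind(m2, ZERO = 0L)
  expect_false("ZERO" %in% fisher_cooccurrence(m3, "ANCHOR")$gene)
})
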