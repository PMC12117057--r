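make_isp_cohort <- function() {
  simulate_cohort(sim_params(n_patients = 8, n_enzymes = 4,
                             n_background = 10, n_isp = 8, seed = 77L))
}

test_that("the five internal-standard filters behave as specified", {
  sim <- make_isp_cohort()
  isp <- select_isp(sim$quant, isp_criteria(sim$isp_candidates))
  expect_s3_class(isp, "isp_set")
  expect_gt(nrow(isp), 0)
  expect_true(all(isp$protein_id %in% sim$isp_candidates))
  expect_true(all(nchar(isp$peptide_seq) >= 8))

  # clone a selected peptide with a 7-residue sequence: rejected by length
  q <- as.data.frame(sim$quant)
  pick <- isp[1, ]
  clone <- q[q$protein_id == pick$protein_id &
               q$peptide_seq == pick$peptide_seq, ]
  clone$peptide_seq <- "SHORTAA"  # 7 residues
  clone$transition_id <- paste0("SHORTAA_", seq_len(nrow(clone)))
  isp2 <- select_isp(paired_quant(rbind(q, clone)),
                     isp_criteria(sim$isp_candidates))
  expect_false("SHORTAA" %in% isp2$peptide_seq)

  # same clone with a legal length but >5% missingness: rejected
  clone$peptide_seq <- "SHORTAAK"
  clone$transition_id <- paste0("SHORTAAK_", seq_len(nrow(clone)))
  runs <- unique(paste(clone$sample_id, clone$extract))
  drop_runs <- runs[seq_len(ceiling(0.1 * length(runs)))]
  clone$intensity[paste(clone$sample_id, clone$extract) %in% drop_runs] <- NA
  isp3 <- select_isp(paired_quant(rbind(q, clone)),
                     isp_criteria(sim$isp_candidates))
  expect_false("SHORTAAK" %in% isp3$peptide_seq)

  # non-candidates never pass, and zero survivors is a hard error
  expect_error(select_isp(sim$quant, isp_criteria("NOT_A_PROTEIN")),
               "no ISP reference")
})

test_that("internal-standard selection is row-order independent", {
  sim <- make_isp_cohort()
  isp_a <- select_isp(sim$quant, isp_criteria(sim$isp_candidates))
  set.seed(1)
  shuffled <- paired_quant(as.data.frame(sim$quant)[
    sample(nrow(sim$quant)), ])
  isp_b <- select_isp(shuffled, isp_criteria(sim$isp_candidates))
  expect_equal(isp_a, isp_b, ignore_attr = TRUE)
})

test_that("ISP normalization equalizes run medians and preserves ranks", {
  # two-run toy with ISP medians 10 and 12 -> both become 11
  mk <- function(sample, extract, shift) {
    data.frame(protein_id = "HK1", peptide_seq = "AAAAKAAAK",
               transition_id = paste0("t", 1:3), sample_id = sample,
               extract = extract, intensity = 2^(c(9, 10, 11) + shift),
               stringsAsFactors = FALSE)
  }
  q <- paired_quant(rbind(mk("S1", "total", 0), mk("S1", "depleted", 2)))
  isp <- data.frame(protein_id = "HK1", peptide_seq = "AAAAKAAAK")
  out <- normalize_by_isp(q, isp)
  med <- tapply(log2(out$intensity), out$extract, median)
  expect_equal(as.vector(med), c(11, 11))

  # idempotence on already-equalized runs
  out2 <- normalize_by_isp(out, isp)
  expect_equal(out2$intensity, out$intensity)

  # within-run differences (ranks and log-ratios) survive normalization
  sim <- small_cohort()
  ispc <- select_isp(sim$quant, isp_criteria(sim$isp_candidates))
  qn <- normalize_by_isp(sim$quant, ispc)
  r1 <- sim$quant[sim$quant$sample_id == "P01_T" &
                    sim$quant$extract == "total", "intensity"]
  r2 <- qn[qn$sample_id == "P01_T" & qn$extract == "total", "intensity"]
  expect_equal(log2(r1) - log2(r1)[1], log2(r2) - log2(r2)[1],
               tolerance = 1e-12)

  # a run without ISP features is an error naming the run
  qq <- as.data.frame(q)
  qq$intensity[qq$extract == "depleted"] <- NA
  expect_error(normalize_by_isp(paired_quant(qq), isp), "S1\\|depleted")
})

test_that("imputation draws from the protein's low-intensity tail", {
  # protein with min 1000, sd 100 -> draws from Normal(900, 50)
  set.seed(8)
  obs <- rnorm(200, 1500, 100)
  obs <- obs - min(obs) + 1000  # exact floor at 1000
  sdv <- sd(obs)
  df <- data.frame(protein_id = "P1", peptide_seq = "AAAAKAAAK",
                   transition_id = paste0("t", seq_len(700)),
                   sample_id = "S1", extract = "total",
                   intensity = c(obs, rep(NA, 500)),
                   stringsAsFactors = FALSE)
  out <- impute_missing(paired_quant(df), seed = 4)
  draws <- out$intensity[is.na(df$intensity)]
  expect_equal(mean(draws), 0.9 * 1000, tolerance = 0.02)
  expect_equal(sd(draws), 0.5 * sdv, tolerance = 0.1)

  # observed cells untouched; same seed identical; no-missing identity
  expect_identical(out$intensity[!is.na(df$intensity)], obs)
  expect_identical(impute_missing(paired_quant(df), seed = 4), out)
  complete <- paired_quant(df[!is.na(df$intensity), ])
  expect_identical(impute_missing(complete, seed = 4), complete)

  # fully missing protein falls back to the global minimum with a warning
  df2 <- rbind(df[1:10, ],
               data.frame(protein_id = "P2", peptide_seq = "CCCCKCCCK",
                          transition_id = "u1", sample_id = "S1",
                          extract = "total", intensity = NA_real_))
  expect_warning(out2 <- impute_missing(paired_quant(df2), seed = 1),
                 "global minimum")
  expect_false(anyNA(out2$intensity))
})

test_that("median-polish protein summaries are robust and exact", {
  # perfectly additive 2-transition x 2-sample block reproduced exactly
  df <- expand.grid(transition_id = c("t1", "t2"),
                    sample_id = c("S1", "S2"), stringsAsFactors = FALSE)
  df$protein_id <- "P1"
  df$peptide_seq <- "AAAAKAAAK"
  df$extract <- "total"
  tr_eff <- c(t1 = 0, t2 = 1)
  s_eff <- c(S1 = 0, S2 = 2)
  df$intensity <- 2^(10 + tr_eff[df$transition_id] + s_eff[df$sample_id])
  m <- summarize_protein(paired_quant(df))
  expect_equal(m["P1", "S2"] - m["P1", "S1"], 2, tolerance = 1e-10)

  # a single-transition protein passes through
  one <- paired_quant(df[df$transition_id == "t1", ])
  m1 <- summarize_protein(one)
  expect_equal(unname(m1["P1", ]), log2(df$intensity[df$transition_id ==
                                                       "t1"]))

  # one outlier among 5 transitions barely moves the summary
  df5 <- expand.grid(transition_id = paste0("t", 1:5),
                     sample_id = paste0("S", 1:4), stringsAsFactors = FALSE)
  df5$protein_id <- "P1"
  df5$peptide_seq <- "AAAAKAAAK"
  df5$extract <- "total"
  df5$intensity <- 2^(12 + rep(c(0, 1, 2, 3), each = 5))
  clean <- summarize_protein(paired_quant(df5))
  df5$intensity[df5$transition_id == "t3" & df5$sample_id == "S2"] <-
    df5$intensity[df5$transition_id == "t3" & df5$sample_id == "S2"] * 2^4
  dirty <- summarize_protein(paired_quant(df5))
  expect_lt(max(abs(dirty - clean)), 0.1)
})
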