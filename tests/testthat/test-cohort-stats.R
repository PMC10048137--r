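test_that("diagnostic yield is plain percentage arithmetic", {
  expect_equal(round(diagnostic_yield(114, 398), 1), 28.6)
  expect_equal(round(diagnostic_yield(7, 76), 1), 9.2)
  expect_equal(diagnostic_yield(0, 100), 0)
  expect_error(diagnostic_yield(1, 0), "total")
  expect_error(diagnostic_yield(5, 4), "exceed")
})

test_that("Yates-corrected 2x2 chi-square reproduces frozen values", {
  # expected values computed with stats::chisq.test before freezing
  r1 <- chi2_2x2_yates(contingency_2x2(107, 215, 7, 69))
  expect_equal(r1$p_value, 5.697264e-05, tolerance = 1e-6)
  r2 <- chi2_2x2_yates(contingency_2x2(61, 186, 53, 98))
  expect_equal(r2$p_value, 0.034576075, tolerance = 1e-6)
  r3 <- chi2_2x2_yates(contingency_2x2(10, 10, 10, 10))
  expect_equal(r3$statistic, 0)
  expect_equal(r3$p_value, 1)
  expect_error(chi2_2x2_yates(contingency_2x2(0, 0, 5, 5)), "margin")
})

test_that("uncorrected goodness-of-fit chi-square reproduces frozen values", {
  r1 <- chi2_gof_equal(c(247, 151))
  expect_equal(r1$statistic, 23.155779, tolerance = 1e-6)
  expect_equal(r1$p_value, 1.4939356e-06, tolerance = 1e-6)
  r2 <- chi2_gof_equal(c(50, 50))
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p_value, 1)
  # (30-20)^2/20 + (10-20)^2/20 = 10 by hand
  expect_equal(chi2_gof_equal(c(30, 10))$statistic, 10)
})

test_that("phi coefficient formula and degenerate cases", {
  expect_equal(phi_coefficient(contingency_2x2(10, 0, 0, 10)), 1)
  expect_equal(phi_coefficient(contingency_2x2(0, 10, 10, 0)), -1)
  expect_equal(phi_coefficient(contingency_2x2(5, 5, 5, 5)), 0)
  expect_error(phi_coefficient(contingency_2x2(5, 5, 0, 0)), "margin")
})

test_that("phi^2 * n equals the uncorrected chi-square statistic", {
  set.seed(99)
  for (i in seq_len(1000)) {
    tab <- contingency_2x2(sample.int(50, 1), sample.int(50, 1),
                           sample.int(50, 1), sample.int(50, 1))
    phi <- phi_coefficient(tab)
    chi <- suppressWarnings(chi2_2x2_yates(tab, correct = FALSE))
    expect_equal(phi^2 * sum(tab), chi$statistic, tolerance = 1e-10)
  }
})

test_that("Yates statistic never exceeds the uncorrected one", {
  set.seed(7)
  for (i in seq_len(200)) {
    tab <- contingency_2x2(1 + sample.int(40, 1), 1 + sample.int(40, 1),
                           1 + sample.int(40, 1), 1 + sample.int(40, 1))
    y <- suppressWarnings(chi2_2x2_yates(tab)$statistic)
    u <- suppressWarnings(chi2_2x2_yates(tab, correct = FALSE)$statistic)
    expect_lte(y, u + 1e-12)
  }
})

test_that("Glass rank-biserial: closed forms and U equivalence", {
  # complete separation -> +1 / -1
  expect_equal(glass_rank_biserial(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  expect_equal(glass_rank_biserial(c(10, 11, 1, 2, 3), c(0, 0, 1, 1, 1)), -1)
  # identical rank distributions -> 0
  expect_equal(glass_rank_biserial(c(1, 2, 1, 2), c(0, 0, 1, 1)), 0)
  expect_error(glass_rank_biserial(1:4, c(1, 1, 1, 1)), "non-empty")
  # tie-free samples: r = 1 - 2U0/(n1*n0) with U0 the group-0 wins
  set.seed(12)
  for (i in 1:50) {
    n1 <- sample(3:12, 1); n0 <- sample(3:12, 1)
    x <- sample(seq_len(200), n1 + n0)   # no ties
    g <- c(rep(1, n1), rep(0, n0))
    u0 <- sum(outer(x[g == 1], x[g == 0], ">"))
    expect_equal(glass_rank_biserial(x, g),
                 2 * u0 / (n1 * n0) - 1, tolerance = 1e-12)
  }
})

test_that("rank-biserial is invariant under strictly monotone transforms", {
  set.seed(5)
  x <- rnorm(60); g <- rbinom(60, 1, 0.4)
  r0 <- glass_rank_biserial(x, g)
  expect_equal(glass_rank_biserial(exp(x), g), r0)
  expect_equal(glass_rank_biserial(x^3, g), r0)
  expect_equal(glass_rank_biserial(rank(x), g), r0)
})

test_that("build_summary reproduces the published table layout", {
  # patient/variant fixture with the printed marginal counts:
  # 398 patients (247 M / 151 F), 322 ID/GDD, 76 ASD (7 diagnosed),
  # 114 diagnosed, 115 P/LP variants (one patient carries two)
  p <- data.frame(patient_id = sprintf("P%03d", 1:398),
                  sex = rep(c("M", "F"), c(247, 151)),
                  subset = "ID_GDD", diagnosed = FALSE)
  p$subset[c(1:67, 248:256)] <- "ASD"          # 67 M + 9 F
  p$diagnosed[c(1:7, 68:167, 257:263)] <- TRUE # 7 ASD + 107 ID/GDD = 114
  v <- data.frame(
    patient_id = c(sprintf("P%03d", c(1:7, 68:167, 257:263)), "P068"),
    inheritance = rep(c("de_novo", "inherited", "uncertain_na"),
                      c(85, 12, 18)),
    x_linked = rep(c(FALSE, TRUE, FALSE), c(80, 19, 16)),
    var_type = rep(c("lof", "missense", "inframe", "cryptic_splice",
                     "cnv_del", "cnv_dup"), c(62, 41, 5, 2, 3, 2)))
  s <- build_summary(p, v)
  expect_equal(s$yield$all$yield, 28.6)
  expect_equal(s$yield$asd$yield, 9.2)
  expect_equal(s$variant_type$percent$lof, 53.9)
  expect_equal(s$inheritance$percent$de_novo, 73.9)
  expect_equal(s$inheritance$x_linked$percent, 16.5)
  # percentages sum to ~100 within each block
  expect_equal(Reduce(`+`, s$inheritance$percent), 100, tolerance = 0.2)
  expect_equal(Reduce(`+`, s$variant_type$percent), 100, tolerance = 0.2)
  # inconsistent rows are refused
  bad <- v; bad$patient_id[1] <- "P398"  # undiagnosed patient
  expect_error(build_summary(p, bad), "not flagged diagnosed")
  bad2 <- v; bad2$patient_id[1] <- "NOPE"
  expect_error(build_summary(p, bad2), "unknown patient")
})

test_that("empty cohorts produce an all-zero summary", {
  p <- data.frame(patient_id = "P1", sex = "M", subset = "ID_GDD",
                  diagnosed = FALSE)
  s <- build_summary(p, data.frame(patient_id = character(),
                                   inheritance = character(),
                                   x_linked = logical(),
                                   var_type = character()))
  expect_equal(s$yield$all$yield, 0)
  expect_equal(s$variant_type$n_variants, 0L)
})
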