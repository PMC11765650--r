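test_that("stratum summaries use the sample conventions", {
  s <- stratum_summary(c(1, 2, 3), "x")
  expect_equal(s$mean, 2)
  expect_equal(s$median, 2)
  expect_equal(s$sd, 1)
  expect_equal(stratum_summary(c(1, 3))$median, 2)  # even-n midpoint
  one <- stratum_summary(5)
  expect_equal(one$mean, 5)
  expect_equal(one$sd, 0)
  expect_true(one$sd_degenerate)
  expect_error(stratum_summary(5, strict = TRUE), "single observation")
  expect_error(stratum_summary(numeric(0)), "no non-missing")
})

test_that("Mann-Whitney matches exact enumeration on a tie-free case", {
  # oracle: enumerate all C(6,3) assignments of ranks to group a and count
  # those with a rank sum at least as extreme (two-sided)
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  combos <- combn(6, 3)
  w_obs <- sum(rank(c(a, b))[1:3])
  w_all <- colSums(matrix(seq_len(6)[combos], nrow = 3))
  p_exact <- mean(abs(w_all - 10.5) >= abs(w_obs - 10.5))
  res <- mann_whitney(a, b)
  expect_equal(res$u_statistic, 0)
  expect_equal(res$p_value, p_exact)
  expect_equal(p_exact, 0.1)
  expect_identical(res$method, "exact")
})

test_that("Mann-Whitney degenerate and mirror properties", {
  x <- c(1, 2, 2, 3, 4, 5, 5, 6, 7)
  same <- mann_whitney(x, x)
  expect_equal(same$u_statistic, length(x)^2 / 2)
  expect_gte(same$p_value, 0.99)
  expect_equal(mann_whitney(1, 2)$u_statistic, 0)
  # U of one orientation plus its mirror equals n1 * n2
  withr::local_seed(99)
  for (i in 1:20) {
    a <- round(rnorm(sample(2:12, 1)), 1)
    b <- round(rnorm(sample(2:12, 1)), 1)
    expect_equal(mann_whitney(a, b)$u_statistic +
                   mann_whitney(b, a)$u_statistic,
                 length(a) * length(b))
  }
  expect_error(mann_whitney(numeric(0), 1), "at least one")
})

test_that("Kruskal-Wallis matches the rank-formula oracle and handles ties", {
  groups <- list(c(1, 2), c(3, 4), c(5, 6))
  # direct evaluation of H on ranks 1..6, no ties
  n <- 6
  rbar <- c(1.5, 3.5, 5.5)
  h_oracle <- 12 / (n * (n + 1)) * sum(2 * (rbar - (n + 1) / 2)^2)
  res <- kruskal_wallis(groups)
  expect_equal(res$chi2, h_oracle)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, pchisq(h_oracle, 2, lower.tail = FALSE))

  same <- kruskal_wallis(list(c(1, 1), c(1, 1), c(1, 1)))
  expect_equal(same$chi2, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$df, 2)
  expect_error(kruskal_wallis(list(1, numeric(0), 3)), "at least one")
})

test_that("two-group Kruskal-Wallis agrees with the normal Mann-Whitney p", {
  withr::local_seed(52)
  for (i in 1:25) {
    a <- round(rnorm(sample(5:15, 1)), 1)
    b <- round(rnorm(sample(5:15, 1), 0.3), 1)
    kw <- kruskal_wallis(list(a, b))$p_value
    mw <- suppressWarnings(
      wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value)
    expect_equal(kw, mw, tolerance = 1e-10)
  }
})

test_that("post-hoc pairwise comparisons behave across methods", {
  for (method in c("dscf", "dunn")) {
    flat <- posthoc_pairwise(list(a = rep(1, 6), b = rep(1, 6), c = rep(1, 6)),
                             method = method)
    expect_equal(nrow(flat), 3)
    expect_true(all(flat$p_value >= 0.99))

    withr::local_seed(7)
    shifted <- posthoc_pairwise(
      list(a = rnorm(12), b = rnorm(12), c = rnorm(12, 10)),
      method = method)
    expect_equal(nrow(shifted), 3)
    expect_true(all(shifted$p_value >= 0 & shifted$p_value <= 1))
    key <- paste(shifted$group1, shifted$group2)
    p_ab <- shifted$p_value[key == "a b"]
    expect_true(all(shifted$p_value[key != "a b"] < p_ab))
  }
})

test_that("DSCF on two groups collapses to the normal rank-sum test", {
  withr::local_seed(11)
  for (i in 1:10) {
    a <- round(rnorm(9), 1); b <- round(rnorm(11, 0.4), 1)
    ph <- posthoc_pairwise(list(a = a, b = b), method = "dscf")
    wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = FALSE))
    expect_equal(ph$p_value, wt$p.value, tolerance = 1e-9)
  }
})

test_that("sex comparison report covers the 15 analysis variables in order", {
  cohort <- simulate_cohort(synth_config(n_per_cell = 5, seed = 10))$cohort
  tab <- sex_comparison(cohort)
  expect_equal(nrow(tab), 15)
  expect_equal(tab$variable,
               c("sof_iof_r", "sof_iof_l", "sof_iof_fa1", "sof_iof_fa2",
                 "iof_mfo_r", "iof_mfo_l", "iof_mfo_fa1", "iof_mfo_fa2",
                 "sof_mfo_r", "sof_mfo_l", "sof_mfo_fa1", "sof_mfo_fa2",
                 "iof_iof", "sof_sof", "mfo_mfo"))
  expect_true(all(tab$f_n == 15) && all(tab$m_n == 15))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))

  # identical sexes: nothing significant
  dup <- cohort
  dup$sex <- rep(c("F", "M"), length.out = nrow(dup))
  half <- dup[dup$sex == "F", ]
  mirror <- half; mirror$sex <- "M"
  mirror$subject_id <- paste0(mirror$subject_id, "-m")
  same <- as_fa_cohort(rbind(as.data.frame(half), as.data.frame(mirror)))
  expect_true(all(sex_comparison(same)$p_value >= 0.99))

  onesex <- cohort[cohort$sex == "F", ]
  class(onesex) <- class(cohort)
  expect_error(sex_comparison(onesex), "both sexes")
})

test_that("a strong male-only offset on one horizontal trait is the top hit", {
  base <- default_baselines()
  base["mfo_mfo", "M"] <- base["mfo_mfo", "M"] + 2
  cohort <- simulate_cohort(synth_config(n_per_cell = 8, trait_baseline = base,
                                         seed = 5))$cohort
  tab <- sex_comparison(cohort)
  expect_equal(tab$variable[which.min(tab$p_value)], "mfo_mfo")
})

test_that("group comparison reports chi-squared on 2 df for every variable", {
  cohort <- simulate_cohort(synth_config(n_per_cell = 5, seed = 12))$cohort
  tab <- group_comparison(cohort)
  expect_equal(nrow(tab), 15)
  expect_true(all(tab$df == 2))
  expect_true(all(tab$chi2 >= 0))
  ph <- as.matrix(tab[, c("p_control_he", "p_control_ch", "p_he_ch")])
  expect_true(all(ph >= 0 & ph <= 1))

  noctrl <- cohort[cohort$group != "CONTROL", ]
  class(noctrl) <- class(cohort)
  expect_error(group_comparison(noctrl), "three groups")
})

test_that("elevated CH asymmetry drives FA rows, not raw side measurements", {
  # mirrors the expected structure: group differences live in the FA indices
  cohort <- simulate_cohort(synth_config(n_per_cell = 15, seed = 2024))$cohort
  tab <- group_comparison(cohort)
  fa_rows <- grepl("_fa[12]$", tab$variable)
  expect_true(all(tab$p_value[fa_rows] < 0.05))
  expect_gt(median(tab$p_value[!fa_rows]), 0.05)
})

test_that("both rank tests keep their nominal size under the null (property)", {
  withr::local_seed(314)
  n_rep <- 1000
  rej_mw <- rej_kw <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    a <- rnorm(15); b <- rnorm(15)
    rej_mw[i] <- mann_whitney(a, b)$p_value <= 0.05
    g <- list(rnorm(10), rnorm(10), rnorm(10))
    rej_kw[i] <- kruskal_wallis(g)$p_value <= 0.05
  }
  expect_gte(mean(rej_mw), 0.03); expect_lte(mean(rej_mw), 0.07)
  expect_gte(mean(rej_kw), 0.03); expect_lte(mean(rej_kw), 0.07)
})
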