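test_that("ROC AUC matches forced and brute-force pair-counting cases", {
  roc <- roc_curve(c(0.3, 0.4, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(roc$auc, 1)                            # perfect separation
  expect_equal(roc_curve(rep(1, 6), rep(c(TRUE, FALSE), 3))$auc, 0.5)  # ties
  expect_equal(roc_curve(c(0.3, 0.15, 0.1, 0.2),
                         c(TRUE, TRUE, FALSE, FALSE))$auc, 0.75)
  expect_equal(pair_count_auc(c(0.3, 0.15), c(0.1, 0.2)), 0.75)
  expect_error(roc_curve(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("curve endpoints and monotonicity invariants hold", {
  withr::local_seed(8)
  scores <- sample(round(rnorm(15), 1))
  labels <- rnorm(15) > 0
  roc <- roc_curve(scores, labels)
  p <- roc$points
  expect_equal(p$sensitivity[1], 0)                   # +Inf sentinel
  expect_equal(p$specificity[1], 1)
  expect_equal(p$sensitivity[nrow(p)], 1)             # min threshold
  expect_equal(p$specificity[nrow(p)], 0)
  expect_true(all(diff(p$sensitivity) >= 0))          # thresholds descending
  expect_true(all(diff(p$specificity) <= 0))
})

test_that("pair-count AUC equals trapezoidal AUC and respects symmetries", {
  withr::local_seed(12021)
  for (i in 1:200) {
    n <- sample(4:12, 1)
    scores <- round(rnorm(n), sample(0:1, 1))         # force ties often
    labels <- c(TRUE, FALSE, rnorm(n - 2) > 0)
    roc <- roc_curve(scores, labels)
    expect_equal(roc$auc, trapezoid_auc(roc), tolerance = 1e-12)
    expect_equal(roc$auc,
                 pair_count_auc(scores[labels], scores[!labels]),
                 tolerance = 1e-12)
    # invariance under strictly increasing transforms
    expect_equal(roc_curve(exp(2 * scores), labels)$auc, roc$auc)
    # label reversal maps AUC to its complement
    expect_equal(roc_curve(scores, !labels)$auc, 1 - roc$auc)
  }
})

test_that("implementation AUC agrees with an independent ROC library", {
  skip_if_not_installed("pROC")
  withr::local_seed(77)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    scores <- round(rnorm(n), 1)
    labels <- c(TRUE, FALSE, rnorm(n - 2) > 0)
    ref <- as.numeric(pROC::auc(pROC::roc(response = labels,
                                          predictor = scores,
                                          levels = c(FALSE, TRUE),
                                          direction = "<", quiet = TRUE)))
    expect_equal(roc_curve(scores, labels)$auc, ref, tolerance = 1e-12)
  }
})

test_that("confusion counts follow the score >= cutpoint rule", {
  scores <- c(0.3, 0.15, 0.1, 0.2)
  labels <- c(TRUE, TRUE, FALSE, FALSE)
  below <- confusion_at(scores, labels, 0)
  expect_equal(unname(below[c("fn", "tn")]), c(0, 0))
  above <- confusion_at(scores, labels, 10)
  expect_equal(unname(above[c("tp", "fp")]), c(0, 0))
  mid <- confusion_at(scores, labels, 0.15)
  expect_equal(mid, c(tp = 2L, fp = 1L, tn = 1L, fn = 0L))
  # conservation of class totals at arbitrary cutpoints
  withr::local_seed(5)
  for (ct in runif(10, -1, 1)) {
    cc <- confusion_at(scores, labels, ct)
    expect_equal(cc[["tp"]] + cc[["fn"]], 2)
    expect_equal(cc[["tn"]] + cc[["fp"]], 2)
  }
})

test_that("screening metrics reproduce hand-computed values and identities", {
  m <- screen_metrics(c(tp = 9, fp = 2, tn = 18, fn = 1))
  expect_equal(unname(m["sensitivity"]), 0.9)
  expect_equal(unname(m["specificity"]), 0.9)
  expect_equal(unname(m["ppv"]), 9 / 11)
  expect_equal(unname(m["npv"]), 18 / 19)
  expect_equal(unname(m["youden"]), 0.8)
  # youden identity over random counts
  withr::local_seed(31)
  for (i in 1:50) {
    cc <- c(tp = sample(0:9, 1), fp = sample(0:9, 1),
            tn = sample(0:9, 1), fn = sample(0:9, 1))
    if (cc["tp"] + cc["fn"] == 0 || cc["tn"] + cc["fp"] == 0) next
    mm <- screen_metrics(cc)
    expect_equal(unname(mm["youden"]),
                 unname(mm["sensitivity"] + mm["specificity"] - 1))
  }
  expect_error(screen_metrics(c(tp = 0, fp = 1, tn = 1, fn = 0)),
               "no positive")
  expect_error(screen_metrics(c(tp = 1, fp = 0, tn = 0, fn = 1)),
               "no negative")
  # undefined PPV is flagged, not thrown
  expect_true(is.na(screen_metrics(c(tp = 0, fp = 0, tn = 2, fn = 2))["ppv"]))
})

test_that("the optimal cutpoint maximises Youden with screening tie-breaks", {
  sep <- optimal_cutpoint(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(sep$youden, 1)
  expect_equal(sep$sensitivity, 1)
  expect_equal(sep$specificity, 1)

  flat <- optimal_cutpoint(rep(2, 6), rep(c(TRUE, FALSE), 3))
  expect_equal(flat$youden, 0)

  mixed <- optimal_cutpoint(c(0.3, 0.15, 0.1, 0.2),
                            c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(mixed$youden, 0.5)
  expect_equal(mixed$cutpoint, 0.15)   # ties broken towards sensitivity
  expect_equal(mixed$sensitivity, 1)
  expect_equal(mixed$specificity, 0.5)
})

test_that("scanned Youden equals an exhaustive oracle over midpoints too", {
  withr::local_seed(6060)
  for (i in 1:200) {
    n <- sample(4:12, 1)
    scores <- round(rnorm(n), 1)
    labels <- c(TRUE, FALSE, rnorm(n - 2) > 0)
    fit <- optimal_cutpoint(scores, labels)
    u <- sort(unique(scores))
    cand <- sort(c(u, u - 1e-9, (head(u, -1) + tail(u, -1)) / 2))
    oracle <- max(vapply(cand, function(ct) {
      m <- screen_metrics(confusion_at(scores, labels, ct))
      unname(m["youden"])
    }, numeric(1)))
    expect_equal(fit$youden, oracle, tolerance = 1e-12)
  }
})

test_that("the screening report enumerates all eight FA predictors", {
  cohort <- simulate_cohort(synth_config(n_per_cell = 5, seed = 9))$cohort
  tab <- screening_report(fa_indices(cohort))
  expect_equal(nrow(tab), 8)
  expect_equal(tab$predictor,
               c("IOF-MFO FA1", "IOF-MFO FA2", "SOF-MFO FA1", "SOF-MFO FA2",
                 "SOF-IOF FA2", "SOF-IOF FA1", "Total FA2", "Total FA1"))
  expect_true(all(tab$n_pos == 10 & tab$n_neg == 20))
  expect_true(all(tab$auc >= 0 & tab$auc <= 1))
  expect_equal(tab$youden, tab$sensitivity + tab$specificity - 1)

  neg_only <- fa_indices(cohort)
  neg_only$group <- "CONTROL"
  expect_error(screening_report(neg_only), "absent")
  pos_only <- fa_indices(cohort)
  pos_only$group <- "CH"
  expect_error(screening_report(pos_only), "no negative")
})

test_that("the FA2 composite outperforms its weakest component at scale", {
  cohort <- simulate_cohort(synth_config(n_per_cell = 50, seed = 1234))$cohort
  cohort <- cohort[cohort$group != "HE", ]
  class(cohort) <- c("fa_cohort", "data.frame")
  tab <- screening_report(fa_indices(cohort))
  total <- tab$auc[tab$predictor == "Total FA2"]
  weakest <- tab$auc[tab$predictor == "SOF-IOF FA2"]
  expect_gt(total, weakest)
  expect_gt(total, 0.9)
})
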