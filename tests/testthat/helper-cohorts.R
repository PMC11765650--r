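# Small hand-built cohorts used across tests.

tiny_cohort_df <- function() {
  data.frame(
    subject_id = c("S01", "S02", "S03", "S04", "S05", "S06"),
    sex = c("F", "M", "F", "M", "F", "M"),
    group = c("CH", "CH", "HE", "HE", "CONTROL", "CONTROL"),
    sof_iof_r = c(4.72, 4.70, 4.60, 4.80, 4.55, 4.73),
    sof_iof_l = c(4.67, 4.95, 4.62, 4.78, 4.56, 4.74),
    iof_mfo_r = c(6.22, 6.80, 6.30, 6.70, 6.19, 6.79),
    iof_mfo_l = c(6.52, 6.35, 6.28, 6.72, 6.20, 6.80),
    sof_mfo_r = c(10.57, 11.30, 10.70, 11.20, 10.59, 11.36),
    sof_mfo_l = c(10.83, 11.80, 10.68, 11.22, 10.60, 11.37),
    sof_sof = c(5.22, 5.69, 5.18, 5.70, 5.18, 5.69),
    iof_iof = c(5.20, 5.56, 5.21, 5.55, 5.21, 5.56),
    mfo_mfo = c(4.76, 4.95, 4.78, 4.94, 4.78, 4.95),
    stringsAsFactors = FALSE)
}

tiny_cohort <- function() as_fa_cohort(tiny_cohort_df(), provenance = "test")

# brute-force AUC: explicit loop over every (positive, negative) score pair
pair_count_auc <- function(pos, neg) {
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

# trapezoidal area under the empirical ROC step curve
trapezoid_auc <- function(roc) {
  fpr <- 1 - roc$points$specificity
  tpr <- roc$points$sensitivity
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}
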