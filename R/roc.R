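#' Empirical ROC curve
#'
#' Builds the exact empirical ROC curve of a continuous score for a binary
#' outcome under the classification rule "score >= threshold is positive"
#' (larger asymmetry indices indicate condylar hyperplasia). Thresholds are
#' the sorted unique observed scores plus a `+Inf` sentinel, so the curve
#' always includes the (sensitivity 0, specificity 1) and (1, 0) endpoints.
#' The AUC is the Mann-Whitney pair-counting probability: the fraction of
#' (positive, negative) score pairs with the positive scored higher, ties
#' counted half — identical to the trapezoidal area under the step curve.
#'
#' @param scores numeric predictor values, one per subject.
#' @param labels parallel vector of class labels (logical, or anything
#'   comparable to `positive`).
#' @param positive the label counted as the positive class (default `"CH"`;
#'   ignored when `labels` is logical).
#' @return An object of class `"fa_roc"`: list with `points` (data.frame of
#'   `threshold`, `sensitivity`, `specificity`), `auc`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels, positive = "CH") {
  pos <- as_positive(labels, positive, length(scores))
  keep <- !is.na(scores) & !is.na(pos)
  scores <- scores[keep]; pos <- pos[keep]
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to build a ROC curve", call. = FALSE)
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!pos] < t), numeric(1))
  # midrank formulation of the pair-counting probability
  r <- rank(scores)
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  structure(list(points = data.frame(threshold = thr, sensitivity = sens,
                                     specificity = spec),
                 auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "fa_roc")
}

as_positive <- function(labels, positive, n) {
  if (length(labels) != n) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  if (is.logical(labels)) labels else labels == positive
}

#' @export
print.fa_roc <- function(x, ...) {
  cat(sprintf("Empirical ROC curve: %d positives vs %d negatives, AUC = %.3f\n",
              x$n_pos, x$n_neg, x$auc))
  invisible(x)
}

#' Confusion counts at a cutpoint
#'
#' Applies the rule "score >= cutpoint is positive" and tabulates the result
#' against the true labels.
#'
#' @inheritParams roc_curve
#' @param cutpoint classification threshold.
#' @return Named integer vector with elements `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_at <- function(scores, labels, cutpoint, positive = "CH") {
  pos <- as_positive(labels, positive, length(scores))
  keep <- !is.na(scores) & !is.na(pos)
  scores <- scores[keep]; pos <- pos[keep]
  if (!any(pos) || all(pos)) {
    stop("both classes must be present", call. = FALSE)
  }
  call_pos <- scores >= cutpoint
  c(tp = sum(call_pos & pos), fp = sum(call_pos & !pos),
    tn = sum(!call_pos & !pos), fn = sum(!call_pos & pos))
}

#' Screening metrics from confusion counts
#'
#' Sensitivity, specificity, positive and negative predictive value, and
#' Youden's index (sensitivity + specificity - 1) from the four cells of a
#' confusion matrix. PPV/NPV are `NA` (flagged, not an error) when no
#' subject is called positive/negative.
#'
#' @param counts named vector with `tp`, `fp`, `tn`, `fn` (as returned by
#'   [confusion_at()]), or the four counts given separately.
#' @param fp,tn,fn individual counts when `counts` is given as `tp`.
#' @return Named numeric vector: `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `youden`, all on the 0-1 scale.
#' @export
screen_metrics <- function(counts, fp = NULL, tn = NULL, fn = NULL) {
  if (!is.null(fp)) counts <- c(tp = counts, fp = fp, tn = tn, fn = fn)
  counts <- counts[c("tp", "fp", "tn", "fn")]
  if (anyNA(counts) || any(counts < 0)) {
    stop("counts must be named non-negative values tp/fp/tn/fn", call. = FALSE)
  }
  tp <- counts[["tp"]]; fpn <- counts[["fp"]]
  tn <- counts[["tn"]]; fnn <- counts[["fn"]]
  if (tp + fnn == 0) stop("no positive subjects: sensitivity undefined", call. = FALSE)
  if (tn + fpn == 0) stop("no negative subjects: specificity undefined", call. = FALSE)
  sens <- tp / (tp + fnn)
  spec <- tn / (tn + fpn)
  c(sensitivity = sens, specificity = spec,
    ppv = if (tp + fpn == 0) NA_real_ else tp / (tp + fpn),
    npv = if (tn + fnn == 0) NA_real_ else tn / (tn + fnn),
    youden = sens + spec - 1)
}

#' Youden-optimal cutpoint for a screening predictor
#'
#' Scans every observed score as a candidate cutpoint (rule: score >=
#' cutpoint is positive) and selects the one maximising Youden's index.
#' Ties are broken towards higher sensitivity first and then towards the
#' lower cutpoint — a screening-oriented convention that favours catching
#' true positives.
#'
#' @inheritParams roc_curve
#' @param predictor name recorded in the report.
#' @return A one-row data.frame of class `"cutpoint_report"`: `predictor`,
#'   `cutpoint`, `sensitivity`, `specificity`, `ppv`, `npv`, `youden`,
#'   `auc`, `n_pos`, `n_neg`.
#' @export
optimal_cutpoint <- function(scores, labels, positive = "CH",
                             predictor = "score") {
  pos <- as_positive(labels, positive, length(scores))
  keep <- !is.na(scores) & !is.na(pos)
  scores <- scores[keep]; pos <- pos[keep]
  if (!any(pos) || all(pos)) {
    stop("both classes must be present to select a cutpoint", call. = FALSE)
  }
  roc <- roc_curve(scores, pos)
  cand <- sort(unique(scores))
  best <- NULL
  for (ct in cand) {
    m <- screen_metrics(confusion_at(scores, pos, ct))
    better <- is.null(best) ||
      m[["youden"]] > best$youden + 1e-12 ||
      (abs(m[["youden"]] - best$youden) <= 1e-12 &&
         (m[["sensitivity"]] > best$sensitivity + 1e-12))
    # equal youden and sensitivity: keep the earlier (lower) cutpoint
    if (better) {
      best <- list(cutpoint = ct, youden = m[["youden"]],
                   sensitivity = m[["sensitivity"]],
                   specificity = m[["specificity"]],
                   ppv = m[["ppv"]], npv = m[["npv"]])
    }
  }
  out <- data.frame(predictor = predictor, cutpoint = best$cutpoint,
                    sensitivity = best$sensitivity,
                    specificity = best$specificity,
                    ppv = best$ppv, npv = best$npv, youden = best$youden,
                    auc = roc$auc, n_pos = roc$n_pos, n_neg = roc$n_neg,
                    stringsAsFactors = FALSE)
  class(out) <- c("cutpoint_report", "data.frame")
  out
}

# predictor layout of the screening report: reference report ordering for
# the six single-trait indices and the FA2 composite, FA1 composite appended
screening_predictors <- function() {
  c("iof_mfo_fa1", "iof_mfo_fa2", "sof_mfo_fa1", "sof_mfo_fa2",
    "sof_iof_fa2", "sof_iof_fa1", "total_fa2", "total_fa1")
}

predictor_label <- function(x) {
  lab <- c(sof_iof = "SOF-IOF", iof_mfo = "IOF-MFO", sof_mfo = "SOF-MFO",
           total = "Total")
  parts <- regmatches(x, regexec("^(.*)_(fa[12])$", x))[[1]]
  paste(lab[[parts[2]]], toupper(parts[3]))
}

#' Screening report over all FA predictors
#'
#' One Youden-optimal [optimal_cutpoint()] row per predictor: FA1 and FA2 of
#' each paired trait plus the composite sums Total FA1 and Total FA2
#' (8 predictors). Subjects missing a predictor are dropped from that
#' predictor's row only.
#'
#' @param fa_tab FA index table from [fa_indices()].
#' @param positive group label treated as the positive (screened-for) class;
#'   default `"CH"`, all other groups pooled as negatives.
#' @return A data.frame of class `"screening_report"` with one
#'   `cutpoint_report` row per predictor.
#' @export
screening_report <- function(fa_tab, positive = "CH") {
  if (!positive %in% fa_tab$group) {
    stop("positive class ", dQuote(positive), " absent from the data", call. = FALSE)
  }
  if (all(fa_tab$group == positive)) {
    stop("no negative subjects: screening needs both classes", call. = FALSE)
  }
  labels <- fa_tab$group == positive
  rows <- lapply(screening_predictors(), function(pr) {
    optimal_cutpoint(fa_tab[[pr]], labels, predictor = predictor_label(pr))
  })
  out <- do.call(rbind, rows)
  out$positive_class <- positive
  class(out) <- c("screening_report", "data.frame")
  out
}
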