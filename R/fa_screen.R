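#' Fit the fluctuating-asymmetry screening model
#'
#' The main entry point of the package. From a cohort of inter-foramina
#' distance measurements it computes per-subject FA1/FA2 indices and their
#' composites, fits a Youden-optimal screening cutpoint for every predictor
#' against the chosen positive diagnostic class, and retains the empirical
#' ROC curves. The fitted object supports `print`, `summary` (which adds the
#' sex- and group-comparison tables), `coef` (the fitted cutpoints),
#' `predict` (classify new subjects) and `plot` (ROC curves).
#'
#' @param cohort an `fa_cohort` (see [read_cohort()], [as_fa_cohort()],
#'   [simulate_cohort()]).
#' @param positive group label screened for (default `"CH"`, condylar
#'   hyperplasia); all other groups are pooled as negatives.
#' @param posthoc post-hoc method used by [summary.fa_screen()];
#'   `"dscf"` or `"dunn"`.
#' @return An object of class `"fa_screen"`.
#' @examples
#' fit <- fa_screen(simulate_cohort(synth_config(seed = 42))$cohort)
#' fit
#' coef(fit)
#' @export
fa_screen <- function(cohort, positive = "CH", posthoc = c("dscf", "dunn")) {
  stopifnot(inherits(cohort, "fa_cohort"))
  posthoc <- match.arg(posthoc)
  fa_tab <- fa_indices(cohort, strict = FALSE)
  report <- screening_report(fa_tab, positive = positive)
  labels <- fa_tab$group == positive
  rocs <- lapply(stats::setNames(screening_predictors(),
                                 vapply(screening_predictors(),
                                        predictor_label, character(1))),
                 function(pr) roc_curve(fa_tab[[pr]], labels))
  structure(list(cohort = cohort, fa_table = fa_tab, report = report,
                 roc = rocs, positive = positive, posthoc = posthoc,
                 call = match.call()),
            class = "fa_screen")
}

#' @export
print.fa_screen <- function(x, digits = 3, ...) {
  cat("Fluctuating-asymmetry screening fit\n")
  cat(sprintf("  %d subjects, positive class %s (%d positive / %d negative)\n",
              nrow(x$fa_table), x$positive, x$report$n_pos[1],
              x$report$n_neg[1]))
  cat("  Youden-optimal cutpoints:\n")
  shown <- x$report[, c("predictor", "cutpoint", "sensitivity", "specificity",
                        "youden", "auc")]
  shown[-1] <- lapply(shown[-1], round, digits)
  print(shown, row.names = FALSE)
  invisible(x)
}

#' @export
coef.fa_screen <- function(object, ...) {
  stats::setNames(object$report$cutpoint, object$report$predictor)
}

#' Summarise a screening fit
#'
#' Adds the two comparison tables to the fit: per-variable sex descriptives
#' with Mann-Whitney p-values, and the Kruskal-Wallis group comparison with
#' post-hoc pairwise p-values.
#'
#' @param object an `fa_screen` fit.
#' @param ... unused.
#' @return An object of class `"summary.fa_screen"` with elements `fit`,
#'   `sex_table` and `group_table`.
#' @export
summary.fa_screen <- function(object, ...) {
  structure(list(fit = object,
                 sex_table = sex_comparison(object$cohort, object$fa_table),
                 group_table = group_comparison(object$cohort, object$fa_table,
                                                posthoc = object$posthoc)),
            class = "summary.fa_screen")
}

#' @export
print.summary.fa_screen <- function(x, digits = 3, ...) {
  print(x$fit, digits = digits)
  cat("\nSex comparison (Mann-Whitney):\n")
  st <- x$sex_table[, c("variable", "f_mean", "m_mean", "u_statistic",
                        "p_value", "significant")]
  st[2:5] <- lapply(st[2:5], round, digits)
  print(st, row.names = FALSE)
  cat("\nGroup comparison (Kruskal-Wallis + ", toupper(x$fit$posthoc),
      " post-hoc):\n", sep = "")
  gt <- x$group_table
  gt[, sapply(gt, is.numeric)] <- round(gt[, sapply(gt, is.numeric)], digits)
  print(gt, row.names = FALSE)
  invisible(x)
}

#' Classify new subjects with fitted cutpoints
#'
#' Applies the fitted rule "index >= cutpoint is positive" of the requested
#' predictor to new data.
#'
#' @param object an `fa_screen` fit.
#' @param newdata an `fa_cohort` or an FA index table from [fa_indices()];
#'   defaults to the training table.
#' @param predictor internal predictor name (one of
#'   `"sof_iof_fa1"`, ..., `"total_fa2"`); default the FA2 composite.
#' @param type `"class"` for positive/negative calls, `"score"` for the raw
#'   index values.
#' @param ... unused.
#' @return Character vector of calls (or numeric scores), named by subject.
#' @export
predict.fa_screen <- function(object, newdata = NULL,
                              predictor = "total_fa2",
                              type = c("class", "score"), ...) {
  type <- match.arg(type)
  predictor <- match.arg(predictor, screening_predictors())
  tab <- if (is.null(newdata)) {
    object$fa_table
  } else if (inherits(newdata, "fa_cohort")) {
    fa_indices(newdata, strict = FALSE)
  } else {
    newdata
  }
  scores <- stats::setNames(tab[[predictor]], tab$subject_id)
  if (type == "score") return(scores)
  ct <- object$report$cutpoint[object$report$predictor ==
                                 predictor_label(predictor)]
  ifelse(scores >= ct, object$positive, paste0("not-", object$positive))
}

#' Plot fitted ROC curves
#'
#' Draws the empirical ROC step curves of one or more fitted predictors in
#' 1 - specificity / sensitivity space, with AUCs in the legend.
#'
#' @param x an `fa_screen` fit.
#' @param predictors labels of the predictors to draw (default: the FA2
#'   composite and the per-trait FA2 indices).
#' @param ... passed to [graphics::plot()].
#' @export
plot.fa_screen <- function(x, predictors = c("Total FA2", "SOF-IOF FA2",
                                             "IOF-MFO FA2", "SOF-MFO FA2"),
                           ...) {
  predictors <- intersect(predictors, names(x$roc))
  if (length(predictors) == 0) stop("no matching predictor", call. = FALSE)
  graphics::plot(c(0, 1), c(0, 1), type = "n",
                 xlab = "1 - specificity", ylab = "Sensitivity",
                 main = paste("ROC:", x$positive, "vs rest"), ...)
  graphics::abline(0, 1, lty = 3, col = "grey60")
  cols <- seq_along(predictors) + 1
  for (i in seq_along(predictors)) {
    p <- x$roc[[predictors[i]]]$points
    o <- order(1 - p$specificity, p$sensitivity)
    graphics::lines(1 - p$specificity[o], p$sensitivity[o], type = "s",
                    col = cols[i], lwd = 2)
  }
  graphics::legend("bottomright", bty = "n", col = cols, lwd = 2,
                   legend = sprintf("%s (AUC %.3f)", predictors,
                                    vapply(x$roc[predictors], `[[`,
                                           numeric(1), "auc")))
  invisible(x)
}
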