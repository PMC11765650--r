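#' Run the full screening analysis end-to-end
#'
#' Orchestrates validate -> FA indices -> sex comparison -> group comparison
#' -> screening report and writes every artefact (CSV and JSON) plus a run
#' manifest with checksums, so that identical inputs and configuration
#' yield identical outputs. A stage that cannot run on the given data (e.g.
#' a missing diagnostic group) is recorded as a warning in the manifest and
#' does not abort the stages that can.
#'
#' @param input path to a cohort CSV, an `fa_cohort`, or a [synth_config()]
#'   (in which case the cohort is generated and written alongside).
#' @param outdir output directory, created if needed.
#' @param positive positive diagnostic class (default `"CH"`).
#' @param posthoc post-hoc method, `"dscf"` or `"dunn"`.
#' @param alpha significance threshold used for marking (default 0.05,
#'   inclusive).
#' @param strict abort on invalid measurements while reading (default TRUE).
#' @return The run manifest (class `"run_manifest"`), invisibly: tool
#'   version, configuration echo, input checksum, per-stage row counts,
#'   warnings, and per-file checksums.
#' @export
run_fa_pipeline <- function(input, outdir, positive = "CH",
                            posthoc = c("dscf", "dunn"), alpha = 0.05,
                            strict = TRUE) {
  posthoc <- match.arg(posthoc)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (!positive %in% group_levels()) {
    stop("positive class must be one of ",
         paste(group_levels(), collapse = "/"), call. = FALSE)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  warnings <- character()
  input_path <- NA_character_
  if (inherits(input, "synth_config")) {
    cohort <- simulate_cohort(input)$cohort
    input_path <- file.path(outdir, "cohort.csv")
    write_cohort(cohort, input_path)
  } else if (inherits(input, "fa_cohort")) {
    cohort <- input
  } else {
    input_path <- input
    cohort <- read_cohort(input, strict = strict)
  }
  findings <- validate_cohort(cohort)
  hard <- findings[findings$rule != "missing", , drop = FALSE]
  if (strict && nrow(hard) > 0) {
    stop("validation stage: ", nrow(hard), " invariant violation(s); first: ",
         hard$message[1], call. = FALSE)
  }
  if (nrow(findings) > 0) {
    warnings <- c(warnings, sprintf("validation: %d finding(s)", nrow(findings)))
  }

  files <- character()
  emit <- function(obj, stem) {
    csv <- file.path(outdir, paste0(stem, ".csv"))
    utils::write.csv(obj, csv, row.names = FALSE)
    jsn <- file.path(outdir, paste0(stem, ".json"))
    jsonlite::write_json(obj, jsn, dataframe = "rows", digits = NA,
                         na = "null", pretty = TRUE)
    files <<- c(files, csv, jsn)
  }

  fa_tab <- fa_indices(cohort, strict = FALSE)
  emit(fa_tab, "fa_table")
  counts <- list(subjects = nrow(cohort), fa_rows = nrow(fa_tab))

  stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e) {
      warnings <<- c(warnings,
                     sprintf("stage %s skipped: %s", name, conditionMessage(e)))
      NULL
    })
    out
  }
  sex_tab <- stage("sex_comparison", {
    tab <- sex_comparison(cohort, fa_tab)
    tab$significant <- tab$p_value <= alpha
    tab
  })
  if (!is.null(sex_tab)) { emit(sex_tab, "sex_report"); counts$sex_rows <- nrow(sex_tab) }
  grp_tab <- stage("group_comparison", {
    tab <- group_comparison(cohort, fa_tab, posthoc = posthoc)
    tab$significant <- tab$p_value <= alpha
    tab
  })
  if (!is.null(grp_tab)) { emit(grp_tab, "group_report"); counts$group_rows <- nrow(grp_tab) }
  scr_tab <- stage("screening", screening_report(fa_tab, positive = positive))
  if (!is.null(scr_tab)) {
    emit(as.data.frame(scr_tab), "screening_report")
    counts$screening_rows <- nrow(scr_tab)
  }

  manifest <- structure(list(
    tool = paste0("asymscreen ",
                  as.character(utils::packageVersion("asymscreen"))),
    config = list(positive = positive, posthoc = posthoc, alpha = alpha,
                  strict = strict),
    input = input_path,
    input_checksum = if (is.na(input_path)) NA_character_ else
      unname(tools::md5sum(input_path)),
    counts = counts,
    warnings = warnings,
    outputs = as.list(tools::md5sum(files))),
    class = "run_manifest")
  jsonlite::write_json(unclass(manifest), file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(x$tool, "run manifest\n")
  cat("  input:", x$input, "\n")
  cat("  counts:", paste(names(x$counts), unlist(x$counts), sep = "=",
                         collapse = ", "), "\n")
  if (length(x$warnings)) cat("  warnings:\n", paste("   -", x$warnings,
                                                     collapse = "\n"), "\n")
  cat("  outputs:", length(x$outputs), "file(s)\n")
  invisible(x)
}

#' Render a report as a formatted text table
#'
#' Human-readable rendering mirroring the conventional layout of
#' morphometric reports: means to 4 decimals, chi-squared statistics to 3,
#' percentages to 2, and an asterisk marking p-values at or below the
#' significance threshold (inclusive: p = 0.05 is marked).
#'
#' @param report a table from [sex_comparison()], [group_comparison()] or
#'   [screening_report()].
#' @param type `"sex"`, `"group"` or `"screening"`.
#' @param alpha marking threshold (default 0.05).
#' @return A character matrix (also printed) suitable for fixed-width display.
#' @export
render_table <- function(report, type = c("screening", "sex", "group"),
                         alpha = 0.05) {
  type <- match.arg(type)
  if (nrow(report) == 0) {
    out <- matrix(character(), nrow = 0,
                  ncol = switch(type, screening = 8, sex = 8, group = 7))
    return(invisible(out))
  }
  mark <- function(p) paste0(formatC(p, digits = 3, format = "f"),
                             ifelse(p <= alpha, " *", ""))
  out <- switch(type,
    screening = cbind(
      Predictor = report$predictor,
      Cutpoint = formatC(report$cutpoint, digits = 3, format = "g"),
      `Sensitivity (%)` = formatC(100 * report$sensitivity, digits = 2, format = "f"),
      `Specificity (%)` = formatC(100 * report$specificity, digits = 2, format = "f"),
      `PPV (%)` = formatC(100 * report$ppv, digits = 2, format = "f"),
      `NPV (%)` = formatC(100 * report$npv, digits = 2, format = "f"),
      `Youden's Index` = formatC(report$youden, digits = 3, format = "f"),
      AUC = formatC(report$auc, digits = 3, format = "f")),
    sex = cbind(
      Variable = report$variable,
      `F mean` = formatC(report$f_mean, digits = 4, format = "f"),
      `F median` = formatC(report$f_median, digits = 4, format = "f"),
      `F SD` = formatC(report$f_sd, digits = 4, format = "f"),
      `M mean` = formatC(report$m_mean, digits = 4, format = "f"),
      `M median` = formatC(report$m_median, digits = 4, format = "f"),
      `M SD` = formatC(report$m_sd, digits = 4, format = "f"),
      p = mark(report$p_value)),
    group = cbind(
      Variable = report$variable,
      `Chi-sq` = formatC(report$chi2, digits = 3, format = "f"),
      df = as.character(report$df),
      p = mark(report$p_value),
      `p CONTROL-HE` = mark(report$p_control_he),
      `p CONTROL-CH` = mark(report$p_control_ch),
      `p HE-CH` = mark(report$p_he_ch)))
  rownames(out) <- NULL
  out
}
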