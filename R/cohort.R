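#' Trait vocabularies
#'
#' The measurement design has exactly three bilaterally paired vertical
#' distances (each measured on the right and left side) and three unpaired
#' horizontal inter-foramina distances:
#'
#' * `paired_traits()`: `"sof_iof"` (supraorbital to infraorbital foramen),
#'   `"iof_mfo"` (infraorbital to mental foramen), `"sof_mfo"` (supraorbital
#'   to mental foramen).
#' * `horizontal_traits()`: `"sof_sof"`, `"iof_iof"`, `"mfo_mfo"` — the
#'   distances between the left and right foramen of each kind.
#'
#' All distances are lengths in centimetres. Only the paired traits admit a
#' fluctuating-asymmetry index; the horizontal traits enter descriptive and
#' between-group statistics directly.
#'
#' @return A character vector of trait names.
#' @export
paired_traits <- function() c("sof_iof", "iof_mfo", "sof_mfo")

#' @rdname paired_traits
#' @export
horizontal_traits <- function() c("sof_sof", "iof_iof", "mfo_mfo")

# canonical column order of the cohort table
cohort_columns <- function() {
  c("subject_id", "sex", "group",
    as.vector(t(outer(paired_traits(), c("r", "l"), paste, sep = "_"))),
    horizontal_traits())
}

measurement_columns <- function() setdiff(cohort_columns(), c("subject_id", "sex", "group"))

sex_levels <- function() c("F", "M")
group_levels <- function() c("CONTROL", "HE", "CH")

#' Construct a cohort of subject-level foramina measurements
#'
#' A cohort is a plain `data.frame` with class `"fa_cohort"` and a fixed
#' column set: `subject_id`, `sex` (`"F"`/`"M"`), `group`
#' (`"CONTROL"`/`"HE"`/`"CH"`), the six side-specific paired distances
#' (`sof_iof_r`, `sof_iof_l`, `iof_mfo_r`, `iof_mfo_l`, `sof_mfo_r`,
#' `sof_mfo_l`) and the three horizontal distances (`sof_sof`, `iof_iof`,
#' `mfo_mfo`), all in centimetres. `NA` marks a missing measurement.
#'
#' @param df data.frame holding at least the cohort columns.
#' @param provenance free-text label recording where the data came from.
#' @param validate if `TRUE` (default) abort when [validate_cohort()] reports
#'   structural findings other than missingness.
#' @return An `fa_cohort` data.frame.
#' @export
as_fa_cohort <- function(df, provenance = "unspecified", validate = TRUE) {
  missing_cols <- setdiff(cohort_columns(), names(df))
  if (length(missing_cols) > 0) {
    stop("cohort table lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)[, cohort_columns()]
  df$subject_id <- as.character(df$subject_id)
  df$sex <- as.character(df$sex)
  df$group <- as.character(df$group)
  for (col in measurement_columns()) df[[col]] <- as.numeric(df[[col]])
  rownames(df) <- NULL
  class(df) <- c("fa_cohort", "data.frame")
  attr(df, "provenance") <- provenance
  if (validate) {
    findings <- validate_cohort(df)
    hard <- findings[findings$rule != "missing", , drop = FALSE]
    if (nrow(hard) > 0) {
      stop("invalid cohort: ", nrow(hard), " finding(s), first: ",
           hard$message[1], call. = FALSE)
    }
  }
  df
}

#' Read a cohort table from a CSV file
#'
#' The file must be comma-separated UTF-8 with the documented header
#' (see [as_fa_cohort()]); empty cells are missing values. In strict mode any
#' invalid measurement (non-numeric or non-positive) aborts with an error
#' naming the subject and column; in lenient mode the offending value becomes
#' missing and a warning is emitted. Unknown sex or group codes and duplicate
#' subject ids are errors in either mode.
#'
#' @param path path to the CSV file.
#' @param strict abort on any invalid measurement (default `TRUE`).
#' @return An `fa_cohort` data.frame.
#' @export
read_cohort <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = "", fileEncoding = "UTF-8")
  missing_cols <- setdiff(cohort_columns(), names(raw))
  if (length(missing_cols) > 0) {
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw <- raw[, cohort_columns(), drop = FALSE]
  bad_sex <- !is.na(raw$sex) & !(raw$sex %in% sex_levels())
  if (any(bad_sex)) {
    stop("validation error: unknown sex code ",
         dQuote(raw$sex[bad_sex][1]), " for subject ",
         raw$subject_id[bad_sex][1], call. = FALSE)
  }
  bad_group <- !is.na(raw$group) & !(raw$group %in% group_levels())
  if (any(bad_group)) {
    stop("validation error: unknown group code ",
         dQuote(raw$group[bad_group][1]), " for subject ",
         raw$subject_id[bad_group][1], call. = FALSE)
  }
  for (col in measurement_columns()) {
    txt <- raw[[col]]
    num <- suppressWarnings(as.numeric(txt))
    invalid <- (!is.na(txt) & is.na(num)) | (!is.na(num) & num <= 0)
    if (any(invalid)) {
      who <- raw$subject_id[invalid][1]
      if (strict) {
        stop("validation error: subject ", who, ", column ", col,
             ": measurement must be a positive number (got ",
             dQuote(txt[invalid][1]), ")", call. = FALSE)
      }
      warning(sum(invalid), " invalid value(s) in column ", col,
              " set to missing (first: subject ", who, ")", call. = FALSE)
      num[invalid] <- NA_real_
    }
    raw[[col]] <- num
  }
  if (anyDuplicated(raw$subject_id)) {
    stop("validation error: duplicate subject_id ",
         raw$subject_id[duplicated(raw$subject_id)][1], call. = FALSE)
  }
  as_fa_cohort(raw, provenance = path, validate = FALSE)
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort()]: measurement fields survive a
#' write/read round trip exactly (values are written with full precision);
#' missing measurements become empty cells.
#'
#' @param cohort an `fa_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "fa_cohort"))
  out <- as.data.frame(cohort)
  for (col in measurement_columns()) {
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         formatC(out[[col]], digits = 17, format = "g"))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Validate a cohort against its invariants
#'
#' Checks, without throwing: unique subject ids, known sex/group codes,
#' positive finite measurements, and flags missing cells. Returns one row per
#' violation.
#'
#' @param cohort an `fa_cohort` (or coercible data.frame with the cohort
#'   columns).
#' @return A data.frame with columns `subject_id`, `column`, `rule`,
#'   `message`; zero rows iff every invariant holds and no value is missing.
#' @export
validate_cohort <- function(cohort) {
  findings <- list()
  note <- function(subject, column, rule, message) {
    findings[[length(findings) + 1]] <<- data.frame(
      subject_id = subject, column = column, rule = rule, message = message,
      stringsAsFactors = FALSE)
  }
  dup <- unique(cohort$subject_id[duplicated(cohort$subject_id)])
  for (d in dup) note(d, "subject_id", "unique_id",
                      paste0("duplicate subject_id ", dQuote(d)))
  for (i in seq_len(nrow(cohort))) {
    id <- cohort$subject_id[i]
    if (is.na(cohort$sex[i]) || !(cohort$sex[i] %in% sex_levels()))
      note(id, "sex", "sex_domain", paste0("sex must be one of F/M for ", id))
    if (is.na(cohort$group[i]) || !(cohort$group[i] %in% group_levels()))
      note(id, "group", "group_domain",
           paste0("group must be one of CONTROL/HE/CH for ", id))
    for (col in measurement_columns()) {
      v <- cohort[[col]][i]
      if (is.na(v)) {
        note(id, col, "missing", paste0(col, " missing for ", id))
      } else if (!is.finite(v) || v <= 0) {
        note(id, col, "positive",
             paste0(col, " must be a positive finite length for ", id,
                    " (got ", v, ")"))
      }
    }
  }
  if (length(findings) == 0) {
    return(data.frame(subject_id = character(), column = character(),
                      rule = character(), message = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, findings)
}

#' @export
print.fa_cohort <- function(x, ...) {
  cat("Inter-foramina distance cohort: ", nrow(x), " subject(s)\n", sep = "")
  if (nrow(x) > 0) {
    cat("  groups: ",
        paste(sprintf("%s=%d", names(table(x$group)), table(x$group)),
              collapse = ", "),
        "; sexes: ",
        paste(sprintf("%s=%d", names(table(x$sex)), table(x$sex)),
              collapse = ", "), "\n", sep = "")
  }
  prov <- attr(x, "provenance")
  if (!is.null(prov)) cat("  provenance: ", prov, "\n", sep = "")
  NextMethod()
}
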