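#' Fluctuating-asymmetry indices for a bilateral pair
#'
#' For a bilateral trait measured on the right (`r`) and left (`l`) side,
#' `fa1()` is the absolute side difference \eqn{|R - L|} (same units as the
#' measurement) and `fa2()` is that difference normalised by the bilateral
#' mean, \eqn{|R - L| / ((R + L)/2)}, a dimensionless index that corrects for
#' individual size so that subjects with larger faces are not scored as more
#' asymmetric. Both are symmetric in their arguments; `fa2()` is invariant
#' under a common rescaling of both sides and lies in \eqn{[0, 2)} for
#' positive sides.
#'
#' @param r,l right- and left-side measurements; positive finite numerics,
#'   vectorised.
#' @return Numeric vector of index values.
#' @examples
#' fa1(6, 4)  # 2
#' fa2(6, 4)  # 0.4
#' @export
fa1 <- function(r, l) {
  check_pair(r, l)
  abs(r - l)
}

#' @rdname fa1
#' @export
fa2 <- function(r, l) {
  check_pair(r, l)
  abs(r - l) / ((r + l) / 2)
}

check_pair <- function(r, l) {
  if (length(r) != length(l)) stop("r and l must have equal length", call. = FALSE)
  bad <- (!is.na(r) & (!is.finite(r) | r <= 0)) |
         (!is.na(l) & (!is.finite(l) | l <= 0))
  if (any(bad)) {
    stop("bilateral measurements must be positive and finite (offending pair: r = ",
         r[bad][1], ", l = ", l[bad][1], ")", call. = FALSE)
  }
  invisible(NULL)
}

#' Per-subject FA index set
#'
#' Computes FA1 and FA2 for every non-missing paired trait of a single
#' subject, plus the composite sums over the traits that were available.
#' A trait is skipped (and excluded from the composites) when either side is
#' missing; `traits_used` records which traits entered the sums.
#'
#' @param record one-row `fa_cohort` (or a list/data.frame carrying the six
#'   side-specific columns).
#' @return A list of class `"fa_index_set"` with elements `fa1`, `fa2`
#'   (named numeric vectors over [paired_traits()], `NA` where missing),
#'   `total_fa1`, `total_fa2` and `traits_used`.
#' @export
fa_index_set <- function(record) {
  traits <- paired_traits()
  v1 <- v2 <- stats::setNames(rep(NA_real_, length(traits)), traits)
  for (tr in traits) {
    r <- as.numeric(record[[paste0(tr, "_r")]])
    l <- as.numeric(record[[paste0(tr, "_l")]])
    if (length(r) != 1 || length(l) != 1)
      stop("fa_index_set expects a single subject record", call. = FALSE)
    if (is.na(r) || is.na(l)) next
    v1[tr] <- fa1(r, l)
    v2[tr] <- fa2(r, l)
  }
  used <- traits[!is.na(v1)]
  if (length(used) == 0) {
    stop("all paired traits missing: no FA index can be computed", call. = FALSE)
  }
  structure(list(fa1 = v1, fa2 = v2,
                 total_fa1 = sum(v1[used]), total_fa2 = sum(v2[used]),
                 traits_used = used),
            class = "fa_index_set")
}

#' @export
print.fa_index_set <- function(x, ...) {
  cat("FA indices over", length(x$traits_used), "paired trait(s):\n")
  print(rbind(fa1 = x$fa1, fa2 = x$fa2))
  cat(sprintf("total FA1 = %.4g cm, total FA2 = %.4g\n",
              x$total_fa1, x$total_fa2))
  invisible(x)
}

#' Cohort-level FA index table
#'
#' One row per subject, in input order, with per-trait FA1/FA2 columns
#' (`sof_iof_fa1`, `sof_iof_fa2`, ...), the composites `total_fa1` /
#' `total_fa2`, and `n_traits_used`. In strict mode a subject with all three
#' paired traits missing is an error; otherwise such a subject gets an
#' all-`NA` row with a warning.
#'
#' @param cohort an `fa_cohort`.
#' @param strict abort when a subject has no computable paired trait
#'   (default `TRUE`).
#' @return A data.frame keyed by `subject_id`, carrying `sex` and `group`
#'   through for downstream grouping.
#' @export
fa_indices <- function(cohort, strict = TRUE) {
  stopifnot(inherits(cohort, "fa_cohort"))
  traits <- paired_traits()
  cols <- c(paste0(rep(traits, each = 2), c("_fa1", "_fa2")),
            "total_fa1", "total_fa2")
  out <- data.frame(subject_id = cohort$subject_id, sex = cohort$sex,
                    group = cohort$group, stringsAsFactors = FALSE)
  for (col in cols) out[[col]] <- rep(NA_real_, nrow(cohort))
  out$n_traits_used <- rep(0L, nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    set <- tryCatch(fa_index_set(cohort[i, ]), error = function(e) e)
    if (inherits(set, "error")) {
      if (strict) {
        stop("subject ", cohort$subject_id[i], ": ", conditionMessage(set),
             call. = FALSE)
      }
      warning("subject ", cohort$subject_id[i],
              " excluded from FA table: ", conditionMessage(set),
              call. = FALSE)
      next
    }
    for (tr in traits) {
      out[[paste0(tr, "_fa1")]][i] <- set$fa1[tr]
      out[[paste0(tr, "_fa2")]][i] <- set$fa2[tr]
    }
    out$total_fa1[i] <- set$total_fa1
    out$total_fa2[i] <- set$total_fa2
    out$n_traits_used[i] <- length(set$traits_used)
  }
  out
}
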