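#' Descriptive summary of one stratum
#'
#' Arithmetic mean, sample median (midpoint convention for even n) and the
#' n-1 sample standard deviation, as reported per sex stratum in
#' morphometric summary tables.
#'
#' @param values numeric vector, `NA`s dropped.
#' @param label stratum label (e.g. `"F"`).
#' @param variable variable name.
#' @param strict if `TRUE`, a single observation (undefined SD) is an error;
#'   otherwise SD is reported as 0 with `sd_degenerate = TRUE`.
#' @return A one-row data.frame: `variable`, `stratum`, `n`, `mean`,
#'   `median`, `sd`, `sd_degenerate`.
#' @export
stratum_summary <- function(values, label = "all", variable = "value",
                            strict = FALSE) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("no non-missing values to summarise", call. = FALSE)
  degen <- length(values) == 1
  if (degen && strict) {
    stop("standard deviation undefined for a single observation", call. = FALSE)
  }
  data.frame(variable = variable, stratum = label, n = length(values),
             mean = mean(values), median = stats::median(values),
             sd = if (degen) 0 else stats::sd(values),
             sd_degenerate = degen, stringsAsFactors = FALSE)
}

#' Mann-Whitney U test between two groups
#'
#' Rank-sum comparison of two independent samples. The U statistic is
#' reported for the first sample. The two-sided p-value is exact when both
#' samples have at most 8 observations and the pooled data are tie-free;
#' otherwise the tie-corrected normal approximation with continuity
#' correction is used — the regime common statistical packages apply to
#' samples of the size seen in sex comparisons (15 vs 15 with ties).
#'
#' @param a,b numeric vectors (first and second group), `NA`s dropped.
#' @param groups length-2 character labels for the two samples.
#' @return A one-row data.frame: `group1`, `group2`, `n1`, `n2`,
#'   `u_statistic`, `p_value`, `method`.
#' @export
mann_whitney <- function(a, b, groups = c("a", "b")) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 1 || length(b) < 1) {
    stop("both groups must contain at least one observation", call. = FALSE)
  }
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- length(a) <= 8 && length(b) <= 8 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  data.frame(group1 = groups[1], group2 = groups[2],
             n1 = length(a), n2 = length(b),
             u_statistic = unname(wt$statistic),
             p_value = min(1, wt$p.value),
             method = if (exact) "exact" else "normal approximation",
             stringsAsFactors = FALSE)
}

#' Kruskal-Wallis test across diagnostic groups
#'
#' Tie-corrected Kruskal-Wallis H with the chi-squared approximation on
#' k - 1 degrees of freedom. The fully degenerate case (every observation
#' identical) is defined as H = 0, p = 1 rather than an error.
#'
#' @param groups named list of numeric vectors, one per group; `NA`s dropped.
#' @return A one-row data.frame: `chi2`, `df`, `p_value`, `n`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- lapply(groups, function(v) v[!is.na(v)])
  if (any(lengths(groups) < 1)) {
    stop("every group must contain at least one observation", call. = FALSE)
  }
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  k <- length(groups)
  if (length(unique(x)) == 1) {
    return(data.frame(chi2 = 0, df = k - 1L, p_value = 1, n = length(x)))
  }
  kt <- stats::kruskal.test(x, g)
  data.frame(chi2 = unname(kt$statistic), df = unname(kt$parameter),
             p_value = unname(kt$p.value), n = length(x),
             stringsAsFactors = FALSE)
}

#' Pairwise post-hoc comparisons after Kruskal-Wallis
#'
#' All-pairs rank comparisons. The default method is
#' Dwass-Steel-Critchlow-Fligner (DSCF): each pair is re-ranked jointly, the
#' tie-corrected standardised rank-sum statistic is referred to the
#' Studentized range distribution with k means, giving family-wise control
#' built into the reference distribution. The alternative, `"dunn"`, uses
#' Dunn's z tests on the mean ranks of the full joint ranking with Holm
#' adjustment.
#'
#' @param groups named list of numeric vectors (k >= 2), `NA`s dropped.
#' @param method `"dscf"` (default) or `"dunn"`.
#' @return A data.frame with one row per unordered group pair: `group1`,
#'   `group2`, `statistic`, `p_value`, `method`.
#' @export
posthoc_pairwise <- function(groups, method = c("dscf", "dunn")) {
  method <- match.arg(method)
  groups <- lapply(groups, function(v) v[!is.na(v)])
  if (any(lengths(groups) < 1)) {
    stop("every group must contain at least one observation", call. = FALSE)
  }
  k <- length(groups)
  if (k < 2) stop("need at least two groups", call. = FALSE)
  nm <- names(groups)
  if (is.null(nm)) nm <- as.character(seq_len(k))
  pairs <- utils::combn(k, 2)
  if (method == "dscf") {
    res <- apply(pairs, 2, function(ij) dscf_pair(groups[[ij[1]]], groups[[ij[2]]], k))
  } else {
    res <- dunn_pairs(groups, pairs)
  }
  out <- data.frame(group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]],
                    statistic = res["statistic", ], p_value = res["p_value", ],
                    method = method, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# DSCF: pairwise Wilcoxon rank sum on the jointly re-ranked pair, standardised
# with tie correction, referred to the Studentized range with k means.
dscf_pair <- function(x, y, k) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  tab <- table(r)
  tie_term <- sum(tab^3 - tab)
  sig2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sig2 <= 0) return(c(statistic = 0, p_value = 1))
  z <- (w - mu) / sqrt(sig2)
  c(statistic = z,
    p_value = stats::ptukey(sqrt(2) * abs(z), nmeans = k, df = Inf,
                            lower.tail = FALSE))
}

# Dunn's z on joint mean ranks with tie correction; Holm-adjusted p-values.
dunn_pairs <- function(groups, pairs) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  tab <- table(r)
  tie_corr <- sum(tab^3 - tab) / (12 * (n - 1))
  v0 <- n * (n + 1) / 12 - tie_corr
  z <- p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se2 <- v0 * (1 / lengths(groups)[i1] + 1 / lengths(groups)[i2])
    z[j] <- if (se2 <= 0) 0 else (rbar[i1] - rbar[i2]) / sqrt(se2)
    p[j] <- 2 * stats::pnorm(abs(z[j]), lower.tail = FALSE)
  }
  rbind(statistic = z, p_value = stats::p.adjust(p, method = "holm"))
}

# variable layout of the sex / group report tables: side-specific paired
# measurements interleaved with their FA indices, horizontal distances last
report_variables <- function(fa_tab, cohort) {
  vars <- list()
  for (tr in paired_traits()) {
    vars[[paste0(tr, "_r")]] <- cohort[[paste0(tr, "_r")]]
    vars[[paste0(tr, "_l")]] <- cohort[[paste0(tr, "_l")]]
    vars[[paste0(tr, "_fa1")]] <- fa_tab[[paste0(tr, "_fa1")]]
    vars[[paste0(tr, "_fa2")]] <- fa_tab[[paste0(tr, "_fa2")]]
  }
  for (tr in c("iof_iof", "sof_sof", "mfo_mfo")) vars[[tr]] <- cohort[[tr]]
  vars
}

#' Sex-comparison report
#'
#' For each of the 15 analysis variables (right and left side of the three
#' paired distances, their FA1/FA2 indices, and the three horizontal
#' distances) computes per-sex mean/median/SD and a Mann-Whitney p-value,
#' female stratum first.
#'
#' @param cohort an `fa_cohort` containing both sexes.
#' @param fa_tab FA index table from [fa_indices()]; computed if omitted.
#' @return A data.frame with one row per variable: per-sex descriptives
#'   (`f_n`, `f_mean`, `f_median`, `f_sd`, `m_*`), `u_statistic`, `p_value`,
#'   `significant` (p <= 0.05).
#' @export
sex_comparison <- function(cohort, fa_tab = fa_indices(cohort, strict = FALSE)) {
  stopifnot(inherits(cohort, "fa_cohort"))
  if (!all(sex_levels() %in% cohort$sex)) {
    stop("both sexes must be present for a sex comparison", call. = FALSE)
  }
  vars <- report_variables(fa_tab, cohort)
  rows <- lapply(names(vars), function(v) {
    f <- vars[[v]][cohort$sex == "F"]
    m <- vars[[v]][cohort$sex == "M"]
    sf <- stratum_summary(f, "F", v)
    sm <- stratum_summary(m, "M", v)
    mw <- mann_whitney(f, m, groups = c("F", "M"))
    data.frame(variable = v,
               f_n = sf$n, f_mean = sf$mean, f_median = sf$median, f_sd = sf$sd,
               m_n = sm$n, m_mean = sm$mean, m_median = sm$median, m_sd = sm$sd,
               u_statistic = mw$u_statistic, p_value = mw$p_value,
               significant = mw$p_value <= 0.05, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Group-comparison report
#'
#' Kruskal-Wallis test of each analysis variable across the CONTROL, HE and
#' CH groups, with all-pairs post-hoc p-values (see [posthoc_pairwise()]).
#'
#' @param cohort an `fa_cohort` containing all three groups.
#' @param fa_tab FA index table from [fa_indices()]; computed if omitted.
#' @param posthoc post-hoc method, `"dscf"` (default) or `"dunn"`.
#' @return A data.frame with one row per variable: `chi2`, `df`, `p_value`,
#'   `significant`, and post-hoc columns `p_control_he`, `p_control_ch`,
#'   `p_he_ch`.
#' @export
group_comparison <- function(cohort,
                             fa_tab = fa_indices(cohort, strict = FALSE),
                             posthoc = c("dscf", "dunn")) {
  stopifnot(inherits(cohort, "fa_cohort"))
  posthoc <- match.arg(posthoc)
  if (!all(group_levels() %in% cohort$group)) {
    stop("all three groups (CONTROL, HE, CH) must be present", call. = FALSE)
  }
  vars <- report_variables(fa_tab, cohort)
  rows <- lapply(names(vars), function(v) {
    by_group <- split(vars[[v]], factor(cohort$group, levels = group_levels()))
    kw <- kruskal_wallis(by_group)
    ph <- posthoc_pairwise(by_group, method = posthoc)
    key <- tolower(paste0("p_", ph$group1, "_", ph$group2))
    ps <- stats::setNames(ph$p_value, key)
    data.frame(variable = v, chi2 = kw$chi2, df = kw$df, p_value = kw$p_value,
               significant = kw$p_value <= 0.05,
               p_control_he = unname(ps["p_control_he"]),
               p_control_ch = unname(ps["p_control_ch"]),
               p_he_ch = unname(ps["p_he_ch"]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
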