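#' Percentage of a count
#'
#' @param n Count in the category.
#' @param total Denominator.
#' @param digits Rounding digits (default 0, matching the usual
#'   baseline-characteristics table format).
#' @return `100 * n / total`, rounded.
#' @export
count_pct <- function(n, total, digits = 0) {
  stopifnot(total > 0, n >= 0, n <= total)
  round(100 * n / total, digits)
}

#' Format a count with its percentage
#'
#' @inheritParams count_pct
#' @return A string `"n (pct)"`, e.g. `format_count_pct(68, 127)` is
#'   `"68 (54)"`.
#' @export
format_count_pct <- function(n, total, digits = 0) {
  sprintf("%d (%s)", n, format(count_pct(n, total, digits)))
}

#' Baseline characteristics table of a cohort
#'
#' Summarises the mothers' covariates by disease status in the standard
#' "Table 1" layout: min/max/mean (sd) for the continuous covariates and
#' count (percent) rows for each categorical level, with a pooled Total
#' column.
#'
#' @param cohort An `scfa_cohort`.
#' @return A character data frame with one row per summary line and
#'   columns `characteristic`, `statistic`, `control`, `case`, `total`.
#' @export
baseline_table <- function(cohort) {
  m <- cohort$mothers
  grp <- list(control = m[m$group == "control", ],
              case = m[m$group == "case", ], total = m)
  rows <- list()
  addrow <- function(char, stat, vals) {
    rows[[length(rows) + 1L]] <<- data.frame(
      characteristic = char, statistic = stat,
      control = vals[1], case = vals[2], total = vals[3],
      stringsAsFactors = FALSE)
  }
  for (v in c("bmi", "age")) {
    addrow(v, "min", vapply(grp, function(g)
      sprintf("%.2f", min(g[[v]])), character(1)))
    addrow(v, "max", vapply(grp, function(g)
      sprintf("%.2f", max(g[[v]])), character(1)))
    addrow(v, "mean (sd)", vapply(grp, function(g)
      sprintf("%.2f (%.2f)", mean(g[[v]]), stats::sd(g[[v]])), character(1)))
  }
  for (v in c("income", "fetus_sex", "education")) {
    for (lev in levels(m[[v]])) {
      addrow(v, lev, vapply(grp, function(g)
        format_count_pct(sum(g[[v]] == lev), nrow(g)), character(1)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
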