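.covariate_names <- c("bmi", "age", "income", "fetus_sex", "education")

#' Per-mother temporal change table
#'
#' For every mother retained at both timepoints, computes the change
#' (second timepoint minus first) of each analyte concentration. Mothers
#' with only one surviving timepoint are excluded and counted in the
#' `n_excluded` attribute.
#'
#' @param analysis An `scfa_analysis` table.
#' @return A data frame of class `scfa_change`: `mother_id`, group label,
#'   covariates, and one change column per analyte.
#' @export
temporal_change <- function(analysis) {
  stopifnot(inherits(analysis, "scfa_analysis"))
  tps <- attr(analysis, "timepoints")
  if (length(tps) != 2)
    stop("temporal change requires exactly two timepoints")
  a <- attr(analysis, "analytes")
  t1 <- analysis[analysis$timepoint == tps[1], , drop = FALSE]
  t2 <- analysis[analysis$timepoint == tps[2], , drop = FALSE]
  ids <- intersect(t1$mother_id, t2$mother_id)
  if (length(ids) == 0)
    stop("no mother has samples at both timepoints")
  t1 <- t1[match(ids, t1$mother_id), , drop = FALSE]
  t2 <- t2[match(ids, t2$mother_id), , drop = FALSE]
  out <- t1[c("mother_id", "group", .covariate_names)]
  for (x in a) out[[x]] <- t2[[x]] - t1[[x]]
  rownames(out) <- NULL
  n_total <- length(unique(analysis$mother_id))
  structure(out, analytes = a, n_excluded = n_total - length(ids),
            class = c("scfa_change", "data.frame"))
}

#' Build a design matrix and response for one association model
#'
#' The response is the named column restricted to one timepoint (or to the
#' per-mother change table when `stratum = "change"`). Predictors are an
#' intercept and a case indicator (control as reference), plus — when
#' `adjusted` — continuous BMI and age, dummy-coded income and education
#' with the lowest category as reference, and a male-first-fetus indicator.
#' Rows with a missing covariate are dropped and counted; a factor
#' covariate observed at a single level is dropped from the design with a
#' warning (its dummy block would be constant).
#'
#' @param analysis An `scfa_analysis` table (metrics columns welcome).
#' @param response Name of the response column.
#' @param stratum A timepoint label, or `"change"`.
#' @param adjusted Include the covariates? `FALSE` gives the two-column
#'   (intercept, case) design of the unadjusted sensitivity model.
#' @return List with `X` (design matrix), `y` (response), `n_dropped`,
#'   `collapsed` (covariates removed as single-level), `response`,
#'   `stratum`, `adjusted`.
#' @export
build_design <- function(analysis, response, stratum, adjusted = TRUE) {
  if (identical(stratum, "change")) {
    tab <- if (inherits(analysis, "scfa_change")) analysis
           else temporal_change(analysis)
  } else {
    if (!stratum %in% attr(analysis, "timepoints"))
      stop("unknown stratum '", stratum, "'")
    tab <- analysis[analysis$timepoint == stratum, , drop = FALSE]
  }
  if (!response %in% names(tab))
    stop("response column '", response, "' not found")
  covs <- if (adjusted) .covariate_names else character(0)
  keep <- stats::complete.cases(tab[c("group", response, covs)])
  n_dropped <- sum(!keep)
  tab <- tab[keep, , drop = FALSE]
  tab$group <- factor(tab$group, levels = .groups)

  collapsed <- character(0)
  terms <- "group"
  for (v in covs) {
    x <- tab[[v]]
    if (is.factor(x)) {
      x <- droplevels(x)
      if (nlevels(x) < 2) {
        collapsed <- c(collapsed, v)
        next
      }
      tab[[v]] <- x
    }
    terms <- c(terms, v)
  }
  if (length(collapsed))
    warning("covariate(s) with a single observed level dropped from the ",
            "design: ", paste(collapsed, collapse = ", "))
  f <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  X <- stats::model.matrix(f, data = tab)
  list(X = X, y = tab[[response]], n_dropped = n_dropped,
       collapsed = collapsed, response = response, stratum = stratum,
       adjusted = adjusted)
}

#' Fit one association model and extract the disease-status effect
#'
#' Ordinary least squares of the response on the design; the reported
#' estimate is the case-indicator coefficient (case minus control, in
#' response units) with its standard error and the two-sided p-value from
#' the t distribution on the residual degrees of freedom.
#'
#' @param design A list from [build_design()].
#' @param response Optional response vector overriding `design$y`.
#' @return One-row data frame: `response`, `stratum`, `adjusted`,
#'   `estimate`, `se`, `p_value`, `n_used`, `status` (`"ok"`,
#'   `"degenerate"` for a zero-variance response).
#' @export
fit_association <- function(design, response = design$y) {
  X <- design$X
  y <- response
  n <- length(y)
  if (n <= ncol(X))
    stop("need more observations (", n, ") than parameters (", ncol(X), ")")
  case_col <- "groupcase"
  if (!case_col %in% colnames(X))
    stop("design has no case indicator column")
  if (stats::var(y) == 0) {
    return(.assoc_row(design, estimate = 0, se = NA_real_,
                      p_value = NA_real_, n_used = n, status = "degenerate"))
  }
  fit <- stats::lm(y ~ 0 + X)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("rank-deficient design; aliased column(s): ",
         paste(sub("^X", "", names(cf)[is.na(cf)]), collapse = ", "))
  sm <- stats::coef(summary(fit))
  row <- sm[paste0("X", case_col), ]
  .assoc_row(design, estimate = unname(row["Estimate"]),
             se = unname(row["Std. Error"]),
             p_value = unname(row["Pr(>|t|)"]), n_used = n, status = "ok")
}

.assoc_row <- function(design, estimate, se, p_value, n_used, status) {
  data.frame(response = design$response, stratum = design$stratum,
             adjusted = design$adjusted, estimate = estimate, se = se,
             p_value = p_value, n_used = n_used, status = status,
             stringsAsFactors = FALSE)
}

#' Fit the full battery of disease-status association models
#'
#' Runs the covariate-adjusted linear model
#' `response ~ status + BMI + age + income + first-fetus sex + education`
#' for every response in the analysis plan: total concentration and Shannon
#' index at each timepoint, each analyte concentration at each timepoint,
#' and each analyte's temporal change (second timepoint minus first).
#' Optional sensitivity blocks refit the same responses without covariate
#' adjustment (`unadjusted = TRUE`) and fit the per-timepoint CLR
#' coordinates unadjusted (`clr = TRUE`). P-values are reported raw; set
#' `bh = TRUE` to append a Benjamini-Hochberg adjusted column (computed
#' across the whole battery).
#'
#' A model that fails (e.g. through rank deficiency) yields a result row
#' with `status = "failed"` rather than aborting the batch.
#'
#' @param analysis An `scfa_analysis` table from [impute_half_loq()].
#' @param unadjusted Add the unadjusted sensitivity block?
#' @param clr Add the CLR-transformed unadjusted sensitivity block?
#' @param bh Append a BH-adjusted p-value column?
#' @return An object of class `scfa_assoc`; see [summary.scfa_assoc()].
#' @export
scfa_associations <- function(analysis, unadjusted = FALSE, clr = FALSE,
                              bh = FALSE) {
  stopifnot(inherits(analysis, "scfa_analysis"))
  if (!"total" %in% names(analysis)) analysis <- add_profile_metrics(analysis)
  a <- attr(analysis, "analytes")
  tps <- attr(analysis, "timepoints")
  change <- temporal_change(analysis)

  plan <- list()
  add <- function(response, stratum, adjusted) {
    plan[[length(plan) + 1L]] <<- list(response = response, stratum = stratum,
                                       adjusted = adjusted)
  }
  for (t in tps) for (r in c("total", "shannon", a)) add(r, t, TRUE)
  for (r in a) add(r, "change", TRUE)
  if (unadjusted) {
    for (t in tps) for (r in c("total", "shannon", a)) add(r, t, FALSE)
    for (r in a) add(r, "change", FALSE)
  }
  if (clr) for (t in tps) for (r in paste0("clr_", a)) add(r, t, FALSE)

  rows <- lapply(plan, function(p) {
    tab <- if (identical(p$stratum, "change")) change else analysis
    tryCatch(
      fit_association(build_design(tab, p$response, p$stratum, p$adjusted)),
      error = function(e) {
        r <- .assoc_row(p, estimate = NA_real_, se = NA_real_,
                        p_value = NA_real_, n_used = 0L, status = "failed")
        attr(r, "message") <- conditionMessage(e)
        r
      })
  })
  results <- do.call(rbind, rows)
  if (bh) results$p_bh <- stats::p.adjust(results$p_value, method = "BH")
  structure(list(results = results, analysis = analysis, change = change,
                 n_change_excluded = attr(change, "n_excluded")),
            class = "scfa_assoc")
}

#' @export
print.scfa_assoc <- function(x, digits = 3, ...) {
  r <- x$results
  cat("SCFA disease-status association battery\n")
  cat(sprintf("  %d models (%d adjusted, %d unadjusted); %d mothers in the change analysis\n",
              nrow(r), sum(r$adjusted), sum(!r$adjusted),
              nrow(x$change)))
  adj <- r[r$adjusted, c("response", "stratum", "estimate", "se", "p_value",
                         "n_used")]
  cat("  adjusted models (estimate = case - control):\n")
  print(format(adj, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Summarise an association battery
#'
#' @param object An `scfa_assoc` object.
#' @param alpha Highlighting threshold for the printed summary.
#' @param ... Unused.
#' @return The full results data frame, invisibly classed for printing.
#' @export
summary.scfa_assoc <- function(object, alpha = 0.05, ...) {
  r <- object$results
  r$signif <- ifelse(!is.na(r$p_value) & r$p_value < alpha, "*", "")
  structure(list(results = r, alpha = alpha), class = "summary.scfa_assoc")
}

#' @export
print.summary.scfa_assoc <- function(x, digits = 3, ...) {
  cat(sprintf("Association results (raw p-values; '*' marks p < %g)\n",
              x$alpha))
  print(format(x$results, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
coef.scfa_assoc <- function(object, ...) {
  r <- object$results
  stats::setNames(r$estimate,
                  paste0(r$response, "@", r$stratum,
                         ifelse(r$adjusted, "", " (unadj)")))
}

#' Box plots of responses by disease status
#'
#' Draws, for each requested response and stratum, a group-wise box plot
#' with jittered points and the model p-value in the panel title —
#' a functional reproduction of the usual case-control panel figure.
#'
#' @param x An `scfa_assoc` object.
#' @param responses Response names to draw (default: total and Shannon).
#' @param strata Strata to draw (default: the two timepoints).
#' @param adjusted Which block's p-values to annotate.
#' @param ... Passed to [graphics::boxplot()].
#' @export
plot.scfa_assoc <- function(x, responses = c("total", "shannon"),
                            strata = attr(x$analysis, "timepoints"),
                            adjusted = TRUE, ...) {
  panels <- expand.grid(response = responses, stratum = strata,
                        stringsAsFactors = FALSE)
  old <- graphics::par(mfrow = grDevices::n2mfrow(nrow(panels)),
                       mar = c(3, 4, 3, 1))
  on.exit(graphics::par(old))
  for (i in seq_len(nrow(panels))) {
    resp <- panels$response[i]; st <- panels$stratum[i]
    tab <- if (identical(st, "change")) x$change
           else x$analysis[x$analysis$timepoint == st, , drop = FALSE]
    r <- x$results
    hit <- r$response == resp & r$stratum == st & r$adjusted == adjusted
    p <- if (any(hit)) r$p_value[hit][1] else NA_real_
    graphics::boxplot(tab[[resp]] ~ tab$group, xlab = "", ylab = resp,
                      main = sprintf("%s @ %s (p = %.3g)", resp, st, p),
                      col = c("indianred1", "skyblue"), ...)
    graphics::points(jitter(as.integer(tab$group), amount = 0.12),
                     tab[[resp]], pch = 16, cex = 0.5,
                     col = grDevices::adjustcolor("black", 0.4))
  }
  invisible(x)
}
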