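#' Paired per-group correlation matrices
#'
#' For each disease-status group and each timepoint, the Pearson
#' correlation matrix of analyte concentrations over the mothers of that
#' group who are retained at *both* timepoints, so a group's two matrices
#' are backed by the identical mother set.
#'
#' @param analysis An `scfa_analysis` table.
#' @return An object of class `scfa_corr_panel`: `r[[group]][[timepoint]]`
#'   correlation matrices plus the per-group paired-mother counts.
#' @export
correlation_panel <- function(analysis) {
  pd <- .paired_data(analysis)
  tps <- attr(analysis, "timepoints")
  r <- lapply(.groups, function(g) {
    idx <- pd$group == g
    stats::setNames(lapply(tps, function(t)
      stats::cor(pd$x[[t]][idx, , drop = FALSE])), tps)
  })
  names(r) <- .groups
  structure(list(r = r, n = table(pd$group),
                 analytes = attr(analysis, "analytes"), timepoints = tps),
            class = "scfa_corr_panel")
}

# mothers with both timepoints: aligned concentration matrices + group labels
.paired_data <- function(analysis) {
  stopifnot(inherits(analysis, "scfa_analysis"))
  tps <- attr(analysis, "timepoints")
  if (length(tps) != 2) stop("correlation analysis requires two timepoints")
  a <- attr(analysis, "analytes")
  t1 <- analysis[analysis$timepoint == tps[1], , drop = FALSE]
  t2 <- analysis[analysis$timepoint == tps[2], , drop = FALSE]
  ids <- intersect(t1$mother_id, t2$mother_id)
  t1 <- t1[match(ids, t1$mother_id), , drop = FALSE]
  t2 <- t2[match(ids, t2$mother_id), , drop = FALSE]
  group <- factor(t1$group, levels = .groups)
  if (any(table(group) < 3))
    stop("need at least 3 mothers with both timepoints in each group")
  x <- stats::setNames(list(as.matrix(t1[a]), as.matrix(t2[a])), tps)
  for (g in .groups) for (t in tps) {
    sds <- apply(x[[t]][group == g, , drop = FALSE], 2, stats::sd)
    if (any(sds == 0))
      stop("zero-variance analyte column(s) in group ", g, " at ", t, ": ",
           paste(a[sds == 0], collapse = ", "))
  }
  list(x = x, group = group, ids = ids, analytes = a, timepoints = tps)
}

#' Difference-in-differences of one correlation pair
#'
#' `[r_case(t2) - r_case(t1)] - [r_ctrl(t2) - r_ctrl(t1)]` for one analyte
#' pair: the between-group difference in the temporal change of the
#' pairwise Pearson correlation.
#'
#' @param panel An `scfa_corr_panel` from [correlation_panel()].
#' @param pair Character vector of two analyte names.
#' @return The difference-in-differences statistic (in `[-4, 4]`).
#' @export
didiff_statistic <- function(panel, pair) {
  stopifnot(inherits(panel, "scfa_corr_panel"), length(pair) == 2)
  if (!all(pair %in% panel$analytes))
    stop("unknown analyte(s): ",
         paste(setdiff(pair, panel$analytes), collapse = ", "))
  tps <- panel$timepoints
  d <- function(g) panel$r[[g]][[tps[2]]][pair[1], pair[2]] -
    panel$r[[g]][[tps[1]]][pair[1], pair[2]]
  d("case") - d("control")
}

.didiff_matrix <- function(x1, x2, is_case) {
  (stats::cor(x2[is_case, , drop = FALSE]) -
     stats::cor(x1[is_case, , drop = FALSE])) -
    (stats::cor(x2[!is_case, , drop = FALSE]) -
       stats::cor(x1[!is_case, , drop = FALSE]))
}

#' Subject-level permutation test of one correlation pair
#'
#' Computes the observed difference-in-differences for the pair, then
#' shuffles case/control labels across mothers `n_perm` times — each
#' mother's two timepoints travel together, preserving group sizes and
#' within-subject dependence — and recomputes the statistic under every
#' relabelling. The two-sided p-value uses the add-one convention
#' `p = (1 + #\{|d*| >= |d_obs|\}) / (n_perm + 1)`, so `p >= 1/(n_perm+1)`.
#'
#' @param analysis An `scfa_analysis` table.
#' @param pair Character vector of two analyte names.
#' @param n_perm Number of label permutations (default 9999).
#' @param seed Optional integer seed for reproducibility.
#' @return One-row data frame: `analyte_j`, `analyte_k`, `delta_case`,
#'   `delta_ctrl`, `didiff`, `p_value`, `n_perm`.
#' @export
didiff_test <- function(analysis, pair, n_perm = 9999, seed = NULL) {
  stopifnot(length(pair) == 2, n_perm >= 1)
  a <- attr(analysis, "analytes")
  if (!all(pair %in% a))
    stop("unknown analyte(s): ", paste(setdiff(pair, a), collapse = ", "))
  sub <- as.data.frame(analysis)[c("mother_id", "timepoint", "group", pair)]
  attr(sub, "analytes") <- pair
  attr(sub, "timepoints") <- attr(analysis, "timepoints")
  class(sub) <- c("scfa_analysis", "data.frame")
  scr <- .didiff_screen(sub, n_perm = n_perm, seed = seed)
  scr$results
}

.didiff_screen <- function(analysis, n_perm, seed = NULL) {
  pd <- .paired_data(analysis)
  if (!is.null(seed)) set.seed(as.integer(seed))
  x1 <- pd$x[[1]]; x2 <- pd$x[[2]]
  is_case <- pd$group == "case"
  d_case <- stats::cor(x2[is_case, , drop = FALSE]) -
    stats::cor(x1[is_case, , drop = FALSE])
  d_ctrl <- stats::cor(x2[!is_case, , drop = FALSE]) -
    stats::cor(x1[!is_case, , drop = FALSE])
  obs <- d_case - d_ctrl
  count <- matrix(0L, nrow(obs), ncol(obs))
  for (b in seq_len(n_perm)) {
    d <- .didiff_matrix(x1, x2, sample(is_case))
    count <- count + (abs(d) >= abs(obs))
  }
  pmat <- (1 + count) / (n_perm + 1)
  pairs <- utils::combn(pd$analytes, 2)
  results <- data.frame(
    analyte_j = pairs[1, ], analyte_k = pairs[2, ],
    delta_case = d_case[t(pairs)], delta_ctrl = d_ctrl[t(pairs)],
    didiff = obs[t(pairs)], p_value = pmat[t(pairs)],
    n_perm = as.integer(n_perm), stringsAsFactors = FALSE)
  list(results = results, obs = obs, pmat = pmat,
       d_case = d_case, d_ctrl = d_ctrl, n = table(pd$group))
}

#' Screen all analyte pairs for correlation-dynamics differences
#'
#' Runs the subject-level permutation test of the correlation
#' difference-in-differences for every unordered analyte pair
#' (`K*(K-1)/2` pairs), sharing one permutation stream across pairs.
#' P-values are reported raw; set `bh = TRUE` for a Benjamini-Hochberg
#' column across the pairs.
#'
#' @param analysis An `scfa_analysis` table.
#' @param n_perm Number of label permutations (default 9999).
#' @param seed Optional integer seed.
#' @param bh Append a BH-adjusted p-value column?
#' @return An object of class `scfa_didiff` with a `results` data frame
#'   (one row per pair), the per-group correlation-change matrices, and the
#'   paired-mother counts. `plot()` draws the pairwise heatmap.
#' @export
scfa_didiff <- function(analysis, n_perm = 9999, seed = NULL, bh = FALSE) {
  stopifnot(n_perm >= 1)
  scr <- .didiff_screen(analysis, n_perm = n_perm, seed = seed)
  if (bh) scr$results$p_bh <- stats::p.adjust(scr$results$p_value, "BH")
  structure(list(results = scr$results, didiff = scr$obs,
                 delta_case = scr$d_case, delta_ctrl = scr$d_ctrl,
                 n = scr$n, n_perm = as.integer(n_perm), seed = seed,
                 analytes = attr(analysis, "analytes"),
                 timepoints = attr(analysis, "timepoints")),
            class = "scfa_didiff")
}

#' @export
print.scfa_didiff <- function(x, digits = 3, ...) {
  cat("Correlation difference-in-differences permutation screen\n")
  cat(sprintf("  %d analyte pairs; %s permutations; paired mothers: %s\n",
              nrow(x$results), format(x$n_perm, big.mark = ","),
              paste(sprintf("%s=%d", names(x$n), x$n), collapse = ", ")))
  r <- x$results[order(x$results$p_value), ]
  print(format(r, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
summary.scfa_didiff <- function(object, alpha = 0.05, ...) {
  r <- object$results
  cat(sprintf("Pairs with permutation p < %g: %d of %d\n", alpha,
              sum(r$p_value < alpha), nrow(r)))
  top <- r[which.min(r$p_value), ]
  cat(sprintf("Smallest p: %s-%s (didiff = %.3f, p = %.4g)\n",
              top$analyte_j, top$analyte_k, top$didiff, top$p_value))
  invisible(r)
}

#' Heatmap of per-pair correlation change
#'
#' One cell per analyte pair: the upper triangle shows the case group's
#' correlation change (second timepoint minus first), the lower triangle
#' the control group's; cells whose difference-in-differences permutation
#' p-value falls below `alpha` are outlined.
#'
#' @param x An `scfa_didiff` object.
#' @param alpha Highlighting threshold (default 0.05).
#' @param ... Unused.
#' @export
plot.scfa_didiff <- function(x, alpha = 0.05, ...) {
  a <- x$analytes
  k <- length(a)
  m <- matrix(NA_real_, k, k, dimnames = list(a, a))
  m[upper.tri(m)] <- t(x$delta_case)[upper.tri(m)]
  m[lower.tri(m)] <- t(x$delta_ctrl)[lower.tri(m)]
  pal <- grDevices::hcl.colors(101, "Blue-Red 2")
  old <- graphics::par(mar = c(6, 6, 3, 1))
  on.exit(graphics::par(old))
  graphics::image(seq_len(k), seq_len(k), t(m[k:1, , drop = FALSE]),
                  zlim = c(-1, 1) * max(abs(m), na.rm = TRUE),
                  col = pal, axes = FALSE, xlab = "", ylab = "",
                  main = "Change in pairwise correlation (upper: case, lower: control)")
  graphics::axis(1, at = seq_len(k), labels = a, las = 2)
  graphics::axis(2, at = seq_len(k), labels = rev(a), las = 1)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    v <- m[k + 1 - j, i]
    if (is.na(v)) next
    graphics::text(i, j, sprintf("%.2f", v), cex = 0.7)
  }
  sig <- x$results[x$results$p_value < alpha, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    ji <- match(sig$analyte_j[i], a); ki <- match(sig$analyte_k[i], a)
    for (cell in list(c(ki, k + 1 - ji), c(ji, k + 1 - ki))) {
      graphics::rect(cell[1] - 0.5, cell[2] - 0.5, cell[1] + 0.5,
                     cell[2] + 0.5, border = "darkgreen", lwd = 2)
    }
  }
  invisible(x)
}
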