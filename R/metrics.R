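#' Total concentration of a sample's SCFA profile
#'
#' @param x Positive numeric vector of analyte concentrations, or a matrix
#'   with one sample per row.
#' @return The per-sample arithmetic sum of concentrations.
#' @export
total_concentration <- function(x) {
  .check_positive(x)
  if (is.matrix(x)) rowSums(x) else sum(x)
}

#' Shannon diversity index of a concentration profile
#'
#' Computes `H = -sum(p_i * log(p_i))` in nats, where `p_i` are the
#' within-sample relative abundances `x_i / sum(x)`. `H` ranges from 0 (all
#' mass on one analyte) to `log(K)` (uniform profile) and is invariant to
#' rescaling the profile.
#'
#' @inheritParams total_concentration
#' @return The per-sample Shannon index in nats.
#' @export
shannon_index <- function(x) {
  .check_positive(x)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  p <- x / rowSums(x)
  h <- -rowSums(p * log(p))
  if (length(h) == 1) h[[1]] else h
}

#' Centered log-ratio transform
#'
#' Maps a positive composition to `clr_i = log(x_i) - mean(log(x))`;
#' each transformed sample sums to zero and rescaling the input leaves the
#' output unchanged. Requires strictly positive entries, which half-LOQ
#' imputation guarantees.
#'
#' @inheritParams total_concentration
#' @return Numeric vector (or matrix, one sample per row) of CLR
#'   coordinates.
#' @export
clr_transform <- function(x) {
  .check_positive(x)
  if (is.matrix(x)) {
    lx <- log(x)
    lx - rowMeans(lx)
  } else {
    lx <- log(x)
    lx - mean(lx)
  }
}

.check_positive <- function(x) {
  if (!is.numeric(x)) stop("concentrations must be numeric")
  if (anyNA(x) || any(x <= 0))
    stop("all concentrations must be positive; impute below-LOQ values first")
  invisible(TRUE)
}

#' Append composition metrics to an analysis table
#'
#' Adds per-sample `total` and `shannon` columns and one `clr_<analyte>`
#' column per retained analyte, all computed across the retained analyte
#' set only.
#'
#' @param analysis An `scfa_analysis` table from [impute_half_loq()].
#' @return The table with metric columns appended.
#' @export
add_profile_metrics <- function(analysis) {
  stopifnot(inherits(analysis, "scfa_analysis"))
  a <- attr(analysis, "analytes")
  m <- as.matrix(analysis[a])
  analysis$total <- total_concentration(m)
  analysis$shannon <- shannon_index(m)
  clr <- clr_transform(m)
  colnames(clr) <- paste0("clr_", a)
  for (j in colnames(clr)) analysis[[j]] <- clr[, j]
  analysis
}
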