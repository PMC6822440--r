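#' Two-way ANOVA mean squares for an items x raters matrix
#'
#' Exact two-way crossed decomposition without replicates.  With grand mean
#' `m`, row means `r_i` and column means `c_j`:
#' `SSR = k * sum((r_i - m)^2)`, `SSC = n * sum((c_j - m)^2)`,
#' `SSE = sum((x_ij - r_i - c_j + m)^2)`, and the mean squares divide by
#' `n - 1`, `k - 1` and `(n - 1)(k - 1)` respectively.  These are the
#' quantities the two-way random-effects single-rater ICC definitions are
#' built from.
#'
#' Missing cells are handled by complete-case row deletion (the count of
#' dropped rows is returned), or rejected outright with
#' `missing_policy = "error"`.
#'
#' @param matrix numeric items x raters matrix (see [pivot_matrix()]).
#' @param missing_policy `"complete_case"` (default) or `"error"`.
#' @return list with `msr`, `msc`, `mse`, `n` (rows kept), `k` (columns) and
#'   `n_dropped_rows`.
#' @export
anova_mean_squares <- function(matrix, missing_policy = c("complete_case", "error")) {
  missing_policy <- match.arg(missing_policy)
  x <- unclass(matrix)
  if (!is.matrix(x) || !is.numeric(x)) stop("input must be a numeric matrix")
  n_dropped <- 0L
  if (anyNA(x)) {
    if (missing_policy == "error") stop("matrix contains missing cells")
    keep <- stats::complete.cases(x)
    n_dropped <- sum(!keep)
    x <- x[keep, , drop = FALSE]
  }
  n <- nrow(x)
  k <- ncol(x)
  if (n < 2 || k < 2) {
    stop(sprintf("need at least 2 complete rows and 2 columns (have %d x %d)", n, k))
  }
  m <- mean(x)
  r <- rowMeans(x)
  cm <- colMeans(x)
  ssr <- k * sum((r - m)^2)
  ssc <- n * sum((cm - m)^2)
  resid <- x - outer(r, rep(1, k)) - outer(rep(1, n), cm) + m
  sse <- sum(resid^2)
  list(msr = ssr / (n - 1),
       msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)),
       n = n, k = k, n_dropped_rows = n_dropped)
}

icc_result <- function(estimate, definition, ms) {
  structure(list(estimate = estimate, definition = definition,
                 msr = ms$msr, msc = ms$msc, mse = ms$mse,
                 n_subjects = ms$n, k_raters = ms$k,
                 n_dropped_rows = ms$n_dropped_rows),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(%s, single rater) = %.4f  [%s]\n",
              if (x$definition == "consistency") "C,1" else "A,1",
              x$estimate, interpret_icc(x$estimate)))
  cat(sprintf("  n = %d subjects, k = %d raters (%d rows dropped)\n",
              x$n_subjects, x$k_raters, x$n_dropped_rows))
  invisible(x)
}

#' Intraclass correlation, consistency definition
#'
#' Two-way random effects, single rater/measurement, consistency form:
#' `(MSR - MSE) / (MSR + (k - 1) * MSE)`.  Additive shifts between raters do
#' not count against it -- it asks whether raters' scores are correlated in
#' an additive manner.
#'
#' @param matrix items x raters numeric matrix.
#' @param missing_policy passed to [anova_mean_squares()].
#' @return an `icc_result`.
#' @export
icc_consistency <- function(matrix, missing_policy = "complete_case") {
  ms <- anova_mean_squares(matrix, missing_policy)
  denom <- ms$msr + (ms$k - 1) * ms$mse
  if (denom == 0) stop("ICC undefined: zero variance matrix")
  icc_result((ms$msr - ms$mse) / denom, "consistency", ms)
}

#' Intraclass correlation, absolute agreement definition
#'
#' Two-way random effects, single rater/measurement, absolute-agreement
#' form: `(MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))`.
#' Unlike the consistency form it penalizes systematic shifts between
#' raters (or between a crowd method and a gold method).
#'
#' @inheritParams icc_consistency
#' @return an `icc_result`.
#' @export
icc_agreement <- function(matrix, missing_policy = "complete_case") {
  ms <- anova_mean_squares(matrix, missing_policy)
  denom <- ms$msr + (ms$k - 1) * ms$mse + (ms$k / ms$n) * (ms$msc - ms$mse)
  if (denom == 0) stop("ICC undefined: zero variance matrix")
  icc_result((ms$msr - ms$mse) / denom, "agreement", ms)
}

#' Map an ICC estimate to a qualitative band
#'
#' The conventional reading used in reliability reporting: `>= .75` is
#' excellent, `>= .4` fair, below that poor.  Thresholds are configurable.
#'
#' @param estimate finite ICC value.
#' @param thresholds named vector `c(fair = .4, excellent = .75)`.
#' @return `"excellent"`, `"fair"` or `"poor"`.
#' @export
interpret_icc <- function(estimate, thresholds = c(fair = 0.4, excellent = 0.75)) {
  stopifnot(is.finite(estimate))
  if (estimate >= thresholds[["excellent"]]) "excellent"
  else if (estimate >= thresholds[["fair"]]) "fair"
  else "poor"
}
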