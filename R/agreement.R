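#' Aggregate crowd labels from simulated runs
#'
#' The crowd label of a picture is the mean over `n_runs` simulated runs of
#' the k-rating run mean (numerically the grand mean of the sampled
#' ratings).  The conventional choice `k = 8` matches the number of raters
#' behind typical normative gold labels.
#'
#' @param pool items x raters matrix.
#' @param k ratings per picture per run (default 8).
#' @param n_runs number of simulated runs (default 30).
#' @param seed integer seed.
#' @return named numeric vector of per-picture crowd means.
#' @export
aggregate_crowd <- function(pool, k = 8, n_runs = 30, seed = 1) {
  rs <- simulate_runs(pool, k, n_runs, seed)
  rowMeans(rs$means)
}

# pictures x 2 matrix (crowd, gold) for one dimension, with id checking
crowd_gold_matrix <- function(crowd, gold, dimension) {
  g <- gold[gold$dimension == dimension, ]
  miss <- setdiff(names(crowd), g$picture)
  if (length(miss) > 0) {
    stop("pictures without a gold entry for ", dimension, ": ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  cbind(crowd = crowd, gold = g$mean[match(names(crowd), g$picture)])
}

#' Absolute agreement between crowd and gold labels
#'
#' Builds the pictures x 2 matrix of crowd means and gold means and returns
#' its absolute-agreement ICC (single measurement): systematic shifts of
#' the crowd relative to the gold labels lower it, unlike the consistency
#' form.
#'
#' @param crowd named per-picture crowd means (see [aggregate_crowd()]).
#' @param gold a [gold_table()].
#' @param dimension SAM dimension.
#' @return an `icc_result`.
#' @export
agreement_with_gold <- function(crowd, gold, dimension) {
  icc_agreement(crowd_gold_matrix(crowd, gold, dimension))
}

#' Flag pictures deviating from their gold label
#'
#' @param crowd named per-picture crowd means.
#' @param gold a [gold_table()].
#' @param dimension SAM dimension.
#' @param threshold absolute deviation (scale points) at which a picture is
#'   flagged (default 1.5).
#' @return data frame `picture, crowd_mean, gold_mean, delta`, sorted by
#'   `|delta|` descending; empty when nothing deviates.
#' @export
deviation_flags <- function(crowd, gold, dimension, threshold = 1.5) {
  m <- crowd_gold_matrix(crowd, gold, dimension)
  delta <- m[, "crowd"] - m[, "gold"]
  out <- data.frame(picture = names(crowd), crowd_mean = m[, "crowd"],
                    gold_mean = m[, "gold"], delta = delta,
                    stringsAsFactors = FALSE)
  out <- out[abs(out$delta) >= threshold, , drop = FALSE]
  out <- out[order(-abs(out$delta), out$picture), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Paired location test of crowd versus gold means
#'
#' Per dimension, a paired two-sided test of the per-picture crowd means
#' against the gold means (paired t-test by default, Wilcoxon signed-rank
#' as an alternative), with Bonferroni correction across the dimensions
#' tested.  Detects systematic shifts such as a crowd population rating
#' arousal consistently higher than the normative labels.
#'
#' @param crowd_by_dim named list mapping dimension to per-picture crowd
#'   mean vectors.
#' @param gold a [gold_table()].
#' @param test `"t"` (paired t-test) or `"wilcoxon"`.
#' @param correction only `"bonferroni"` is offered; the family size is the
#'   number of dimensions tested.
#' @return data frame `dimension, mean_diff, direction, p_raw, p_corrected,
#'   test`.
#' @export
mean_shift_test <- function(crowd_by_dim, gold, test = c("t", "wilcoxon"),
                            correction = "bonferroni") {
  test <- match.arg(test)
  correction <- match.arg(correction, "bonferroni")
  dims <- names(crowd_by_dim)
  stopifnot(length(dims) >= 1)
  rows <- lapply(dims, function(d) {
    m <- crowd_gold_matrix(crowd_by_dim[[d]], gold, d)
    if (nrow(m) < 2) stop("need at least 2 matched pictures for ", d)
    diffs <- m[, "crowd"] - m[, "gold"]
    if (stats::var(diffs) == 0) {
      stop("degenerate test for ", d, ": zero variance of differences")
    }
    p <- if (test == "t") stats::t.test(diffs)$p.value
         else stats::wilcox.test(diffs, exact = FALSE)$p.value
    data.frame(dimension = d, mean_diff = mean(diffs),
               direction = if (mean(diffs) > 0) "crowd higher" else "crowd lower",
               p_raw = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_corrected <- pmin(1, out$p_raw * length(dims))
  out$test <- if (test == "t") "paired t-test" else "Wilcoxon signed-rank"
  out
}
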