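#' Hartigan's dip statistic
#'
#' The dip of a sample is the smallest sup-norm distance between its
#' empirical CDF and the class of unimodal (convex-then-concave)
#' distribution functions.  Large values indicate multimodality.  Tied
#' observations are treated as infinitesimally separated order statistics,
#' so `dip >= 1/(2n)` for every sample of `n` points, with equality for
#' perfectly unimodal configurations (a constant sample, evenly spaced
#' points) and `dip = 1/2` for a single observation.
#'
#' The computation collapses the sample to distinct values, then bisects on
#' the band half-width `d`, deciding feasibility of a band-constrained
#' unimodal CDF exactly for every candidate mode placement (compiled code;
#' see the package vignette for the construction).
#'
#' @param x numeric sample (sorted internally).
#' @return the dip statistic, a scalar `>= 1/(2 * length(x))`.
#' @export
dip_statistic <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 0) stop("empty sample")
  if (anyNA(x)) stop("sample contains NA")
  .dip_stat_cpp(x)
}

# Monte-Carlo null tables are expensive (n_replicates dips per distinct n);
# cache them per (n, n_replicates, seed) for the lifetime of the session.
.dip_cache <- new.env(parent = emptyenv())

#' Monte-Carlo null distribution of the dip
#'
#' Replicate dips of samples of size `n` drawn from the uniform distribution
#' on (0, 1), the asymptotically least favourable unimodal null.
#'
#' @param n sample size.
#' @param n_replicates number of null replicates (>= 100).
#' @param seed integer seed; the table is deterministic given
#'   `(n, n_replicates, seed)`.
#' @return numeric vector of `n_replicates` dip values.
#' @export
dip_null <- function(n, n_replicates = 2000, seed = 1) {
  stopifnot(n >= 1, n_replicates >= 100)
  key <- sprintf("n%d_r%d_s%d", n, n_replicates, as.integer(seed))
  hit <- .dip_cache[[key]]
  if (!is.null(hit)) return(hit)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, paste0("dip_null_", n)))
  m <- matrix(stats::runif(n * n_replicates), nrow = n)
  val <- .dip_stat_batch_cpp(m)
  assign(key, val, envir = .dip_cache)
  val
}

# save/restore the global RNG state so null-table generation does not
# disturb the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Monte-Carlo p-value for an observed dip
#'
#' Add-one estimator against the uniform null:
#' `p = (1 + #(null dips >= observed)) / (n_replicates + 1)`.
#'
#' @param dip observed dip statistic.
#' @param n sample size the dip was computed on (>= 2).
#' @param n_replicates Monte-Carlo null size (>= 100; default 2000).
#' @param seed integer seed for the null table.
#' @return p-value in (0, 1].
#' @export
dip_pvalue <- function(dip, n, n_replicates = 2000, seed = 1) {
  stopifnot(n >= 2)
  null <- dip_null(n, n_replicates, seed)
  (1 + sum(null >= dip)) / (n_replicates + 1)
}

#' Classify a rating sample as unimodal or multimodal
#'
#' Computes the dip and its Monte-Carlo p-value and calls the sample
#' multimodal when `p < alpha`.  Ratings on the discrete 9-point scale are
#' heavily tied; the default `tie_policy = "jitter"` adds uniform noise in
#' (-0.5, 0.5) -- the usual remedy for scale data -- under a seed derived
#' deterministically from `seed`, so the call is reproducible.  `"raw"`
#' computes on the discrete values as-is.
#'
#' @param x numeric ratings (n >= 4 for a meaningful call).
#' @param alpha significance level for the multimodality call.
#' @param tie_policy `"jitter"` or `"raw"`.
#' @param seed integer seed for the jitter.
#' @param n_replicates Monte-Carlo null size.
#' @param null_seed seed of the null table (defaults to `seed`); callers
#'   classifying many samples of the same size can share one null table by
#'   fixing it while varying `seed`.
#' @return a `dip_result` list: `dip`, `p_value`, `n`, `n_replicates`,
#'   `call`, `alpha`, `tie_policy`.
#' @export
classify_modality <- function(x, alpha = 0.05, tie_policy = c("jitter", "raw"),
                              seed = 1, n_replicates = 2000,
                              null_seed = seed) {
  tie_policy <- match.arg(tie_policy)
  x <- as.numeric(x[!is.na(x)])
  n <- length(x)
  if (n < 4) stop("need at least 4 ratings for a modality call")
  if (tie_policy == "jitter") {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(derive_seed(seed, "modality_jitter"))
    x <- x + stats::runif(n, -0.5, 0.5)
  }
  d <- dip_statistic(x)
  p <- dip_pvalue(d, n, n_replicates, null_seed)
  structure(list(dip = d, p_value = p, n = n, n_replicates = n_replicates,
                 call = if (p < alpha) "multimodal" else "unimodal",
                 alpha = alpha, tie_policy = tie_policy),
            class = "dip_result")
}

#' @export
print.dip_result <- function(x, ...) {
  cat(sprintf("dip = %.4f, p = %.4f (n = %d, %d replicates, %s ties) -> %s\n",
              x$dip, x$p_value, x$n, x$n_replicates, x$tie_policy, x$call))
  invisible(x)
}
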