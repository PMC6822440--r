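#' Configuration for reliability simulations
#'
#' @param k_range integer vector of rating sizes (default `1:15`).
#' @param runs_per_k simulated runs per rating size (default 30).
#' @param n_replicates independent run-set replicates per k used for the
#'   dispersion estimate (default 10).
#' @param sampling `"per_picture_ratings"` draws k ratings per picture
#'   (guarantees exact counts); `"per_run_workers"` draws whole workers
#'   until every picture is covered k times (sensitivity mode, since page
#'   structure means whole-worker sampling cannot guarantee exact counts).
#' @param seed integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(k_range = 1:15, runs_per_k = 30, n_replicates = 10,
                       sampling = c("per_picture_ratings", "per_run_workers"),
                       seed = 1) {
  sampling <- match.arg(sampling)
  stopifnot(min(k_range) >= 1, runs_per_k >= 2, n_replicates >= 1)
  structure(list(k_range = sort(unique(as.integer(k_range))),
                 runs_per_k = as.integer(runs_per_k),
                 n_replicates = as.integer(n_replicates),
                 sampling = sampling, seed = as.integer(seed)),
            class = "sim_config")
}

# pack the non-missing ratings of each picture to the left; rows = pictures
pack_pool <- function(pool) {
  x <- unclass(pool)
  counts <- rowSums(!is.na(x))
  packed <- matrix(NA_real_, nrow(x), max(counts))
  for (i in seq_len(nrow(x))) {
    v <- x[i, !is.na(x[i, ])]
    if (length(v)) packed[i, seq_along(v)] <- v
  }
  list(packed = packed, counts = as.integer(counts),
       pictures = rownames(x))
}

#' Simulate crowdsourcing runs of k ratings per picture
#'
#' Each run draws, independently of other runs, `k` ratings per picture
#' uniformly without replacement from that picture's rating pool, and
#' records the per-run per-picture mean and SD.  Runs may overlap in sampled
#' ratings: a pool of 30-50 ratings cannot support 30 disjoint runs of up
#' to 15.
#'
#' @param pool items x raters matrix (see [pivot_matrix()]); `NA` cells are
#'   simply absent from the pool.
#' @param k ratings per picture per run.
#' @param n_runs number of runs.
#' @param seed integer seed; results are deterministic given it.
#' @return a `run_set`: list with `k`, `means` and `sds`
#'   (pictures x runs matrices).
#' @export
simulate_runs <- function(pool, k, n_runs, seed = 1) {
  pk <- pack_pool(pool)
  short <- pk$counts < k
  if (any(short)) {
    stop(sprintf("picture(s) with fewer than k = %d ratings: %s", k,
                 paste(utils::head(pk$pictures[short], 5), collapse = ", ")))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, sprintf("runs_k%d", k)))
  res <- .sim_run_stats_cpp(pk$packed, pk$counts, as.integer(k),
                            as.integer(n_runs))
  rownames(res$means) <- rownames(res$sds) <- pk$pictures
  structure(list(k = as.integer(k), means = res$means, sds = res$sds),
            class = "run_set")
}

# whole-worker sampling variant: add random workers until every picture has
# at least k ratings, then subsample k per picture from the covered pool
simulate_runs_workers <- function(pool, k, n_runs, seed = 1) {
  x <- unclass(pool)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, sprintf("wruns_k%d", k)))
  np <- nrow(x)
  means <- sds <- matrix(NA_real_, np, n_runs, dimnames = list(rownames(x), NULL))
  for (r in seq_len(n_runs)) {
    ord <- sample.int(ncol(x))
    got <- integer(np)
    used <- 0L
    while (any(got < k) && used < ncol(x)) {
      used <- used + 1L
      got <- got + !is.na(x[, ord[used]])
    }
    if (any(got < k)) stop("worker pool cannot cover k = ", k, " ratings per picture")
    sub <- x[, ord[seq_len(used)], drop = FALSE]
    for (i in seq_len(np)) {
      v <- sub[i, !is.na(sub[i, ])]
      v <- v[sample.int(length(v), k)]
      means[i, r] <- mean(v)
      sds[i, r] <- stats::sd(v)
    }
  }
  structure(list(k = as.integer(k), means = means, sds = sds), class = "run_set")
}

#' Across-run consistency ICC
#'
#' Treats the pictures x runs grid of run means as a subjects x raters
#' matrix and returns its consistency ICC: the reliability of the mean
#' ratings of a k-rating crowdsourcing run.
#'
#' @param runset a `run_set` from [simulate_runs()].
#' @return an `icc_result`.
#' @export
across_run_icc <- function(runset) {
  stopifnot(inherits(runset, "run_set"))
  icc_consistency(runset$means)
}

#' Closed-form across-run ICC under the additive homoscedastic model
#'
#' If picture effects have variance `sigma2_picture` and individual ratings
#' have within-picture variance `sigma2_within`, the mean of k ratings has
#' error variance `sigma2_within / k`, so the consistency ICC of run means
#' converges to `sigma2_picture / (sigma2_picture + sigma2_within / k)`.
#' Used as the testing oracle for the simulation.
#'
#' @param sigma2_picture between-picture variance (>= 0).
#' @param sigma2_within within-picture rating variance (>= 0).
#' @param k ratings per picture per run.
#' @return the limiting ICC.
#' @export
analytic_icc <- function(sigma2_picture, sigma2_within, k) {
  stopifnot(sigma2_picture >= 0, sigma2_within >= 0, k >= 1)
  if (sigma2_picture == 0 && sigma2_within == 0) {
    stop("ICC undefined when both variance components are zero")
  }
  sigma2_picture / (sigma2_picture + sigma2_within / k)
}

#' Additive homoscedastic rating pool
#'
#' A continuous pool with planted variance components, used to test the
#' reliability simulation against [analytic_icc()]: picture means are drawn
#' `N(center, sqrt(sigma2_picture))` and each rating adds independent
#' `N(0, sqrt(sigma2_within))` noise.  No rounding or clipping, so the
#' planted components are exact.
#'
#' @param n_pictures,pool_size pool dimensions.
#' @param sigma2_picture,sigma2_within planted variance components.
#' @param center grand mean of the picture effects.
#' @param seed integer seed.
#' @return a pictures x ratings numeric matrix.
#' @export
make_additive_pool <- function(n_pictures, pool_size, sigma2_picture,
                               sigma2_within, center = 5, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, "additive_pool"))
  mu <- stats::rnorm(n_pictures, center, sqrt(sigma2_picture))
  m <- mu + matrix(stats::rnorm(n_pictures * pool_size, 0, sqrt(sigma2_within)),
                   n_pictures, pool_size)
  rownames(m) <- sprintf("pic%04d", seq_len(n_pictures))
  m
}

#' Reliability curve over rating sizes
#'
#' For every k in the configured range, builds `n_replicates` independent
#' run sets of `runs_per_k` runs, computes the across-run consistency ICC of
#' each, and records their mean and SD.  Rating sizes the pool cannot
#' support are dropped with a warning (or an error with `strict = TRUE`).
#'
#' @param pool items x raters matrix.
#' @param config a [sim_config()].
#' @param strict error instead of truncating unsupported rating sizes.
#' @return a `reliability_curve` data frame with columns `k`, `icc`,
#'   `icc_sd`, `n_runs`, `band` (interpretation of `icc`).
#' @export
reliability_curve <- function(pool, config = sim_config(), strict = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  counts <- rowSums(!is.na(unclass(pool)))
  kmax <- min(counts)
  ks <- config$k_range
  if (any(ks > kmax)) {
    msg <- sprintf("pool supports at most k = %d ratings per picture", kmax)
    if (strict) stop(msg)
    warning(msg, "; truncating k range")
    ks <- ks[ks <= kmax]
  }
  if (length(ks) == 0) stop("no feasible rating sizes in k_range")
  sim_one <- if (config$sampling == "per_picture_ratings") simulate_runs
             else simulate_runs_workers
  rows <- lapply(ks, function(k) {
    iccs <- vapply(seq_len(config$n_replicates), function(r) {
      rs <- sim_one(pool, k, config$runs_per_k,
                    seed = derive_seed(config$seed, sprintf("rep%d", r)))
      across_run_icc(rs)$estimate
    }, 0)
    data.frame(k = k, icc = mean(iccs),
               icc_sd = if (length(iccs) > 1) stats::sd(iccs) else NA_real_,
               n_runs = config$runs_per_k)
  })
  out <- do.call(rbind, rows)
  out$band <- vapply(out$icc, interpret_icc, "")
  structure(out, class = c("reliability_curve", "data.frame"),
            sampling = config$sampling)
}

#' Minimum number of ratings for a target reliability
#'
#' The smallest rating size whose across-run ICC reaches the threshold.
#'
#' @param curve a [reliability_curve()].
#' @param threshold reliability target in (0, 1); `.75` is the conventional
#'   "excellent" bound, `.4` the "fair" bound.
#' @return the smallest qualifying `k`, or `NA` if the threshold is never
#'   reached within the curve's range.
#' @export
min_ratings <- function(curve, threshold = 0.75) {
  stopifnot(nrow(curve) >= 1, threshold > 0, threshold < 1)
  ok <- curve$k[curve$icc >= threshold]
  if (length(ok) == 0) NA_integer_ else min(ok)
}
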