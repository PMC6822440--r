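#' Configuration for the synthetic crowd generator
#'
#' The generator emulates the statistical structure of a crowdsourced SAM
#' annotation campaign: 60 pictures organized in pages of 20, two worker
#' populations of different noise levels, 30-50 ratings per picture and
#' population, heteroscedastic rating noise that peaks at the neutral
#' midpoint of the scale, and a subset of pictures with two latent opinion
#' subgroups whose membership persists across pictures of the same theme.
#'
#' @param n_pictures number of pictures (default 60).
#' @param page_size pictures per page (default 20); workers rate whole pages.
#' @param n_workers available workers per population.
#' @param populations named numeric vector mapping population tag to a noise
#'   multiplier; the specialized population is less noisy than the general
#'   one.
#' @param pool_range integer range for the target number of ratings per
#'   picture and population (drawn per page).
#' @param dimensions subset of the SAM dimensions to generate.
#' @param mean_range interval within `[1, 9]` true unimodal picture means
#'   are drawn from (uniformly); the default leaves headroom at the scale
#'   ends so that clipping stays rare.
#' @param mm_mean_range interval the centres of multimodal (polarizing)
#'   pictures are drawn from; polarizing content sits near the neutral
#'   midpoint, and the subgroup locations `mu +- delta` must stay on
#'   scale.
#' @param sigma_min,sigma_max residual rating SD at the scale extremes and
#'   at the neutral midpoint: `sigma(mu) = sigma_min + (sigma_max -
#'   sigma_min) * (1 - abs(mu - 5) / 4)`, scaled by the population
#'   multiplier.
#' @param rater_bias_sd SD of the per-worker additive bias.
#' @param multimodal_fraction proportion of pictures given a two-subgroup
#'   opinion structure (locations `mu - delta` and `mu + delta`).
#' @param separation half-distance `delta` between the subgroup means.
#' @param n_themes number of themes over which a worker's subgroup
#'   membership persists.
#' @param n_gold_raters size of the independent reference sample behind the
#'   gold labels.
#' @param seed master integer seed; all internal streams derive from it.
#' @return a validated `generator_config` list.
#' @export
generator_config <- function(n_pictures = 60,
                             page_size = 20,
                             n_workers = 120,
                             populations = c(specialized = 1.0, general = 1.3),
                             pool_range = c(30, 50),
                             dimensions = SAM_DIMENSIONS,
                             mean_range = c(2, 8),
                             mm_mean_range = c(3.5, 6.5),
                             sigma_min = 0.35,
                             sigma_max = 0.55,
                             rater_bias_sd = 0.3,
                             multimodal_fraction = 0.25,
                             separation = 2,
                             n_themes = 3,
                             n_gold_raters = 200,
                             seed = 1) {
  cfg <- list(n_pictures = as.integer(n_pictures), page_size = as.integer(page_size),
              n_workers = as.integer(n_workers), populations = populations,
              pool_range = as.integer(pool_range), dimensions = dimensions,
              mean_range = mean_range, mm_mean_range = mm_mean_range,
              sigma_min = sigma_min, sigma_max = sigma_max,
              rater_bias_sd = rater_bias_sd,
              multimodal_fraction = multimodal_fraction, separation = separation,
              n_themes = as.integer(n_themes), n_gold_raters = as.integer(n_gold_raters),
              seed = as.integer(seed))
  stopifnot(cfg$n_pictures >= 1, cfg$page_size >= 1, cfg$n_workers >= 1,
            length(cfg$pool_range) == 2, cfg$pool_range[1] <= cfg$pool_range[2],
            cfg$pool_range[1] >= 1,
            all(cfg$dimensions %in% SAM_DIMENSIONS), length(cfg$dimensions) >= 1,
            length(cfg$mean_range) == 2,
            cfg$mean_range[1] >= 1, cfg$mean_range[2] <= 9,
            cfg$mean_range[1] <= cfg$mean_range[2],
            length(cfg$mm_mean_range) == 2,
            cfg$mm_mean_range[1] >= 1, cfg$mm_mean_range[2] <= 9,
            cfg$mm_mean_range[1] <= cfg$mm_mean_range[2],
            cfg$sigma_min >= 0, cfg$sigma_min <= cfg$sigma_max,
            cfg$rater_bias_sd >= 0,
            cfg$multimodal_fraction >= 0, cfg$multimodal_fraction <= 1,
            cfg$separation >= 0, cfg$n_themes >= 1, cfg$n_gold_raters >= 2)
  if (is.null(names(cfg$populations)) || any(names(cfg$populations) == "")) {
    stop("populations must be a named vector of noise multipliers")
  }
  n_pages <- ceiling(cfg$n_pictures / cfg$page_size)
  if (cfg$pool_range[2] > cfg$n_workers ||
      3L * cfg$n_workers < n_pages * cfg$pool_range[2]) {
    stop("pool size exceeds worker capacity: increase n_workers or lower pool_range")
  }
  class(cfg) <- "generator_config"
  cfg
}

# sigma(mu): residual SD peaking at the neutral midpoint 5, linear in |mu-5|
sigma_at <- function(mu, sigma_min, sigma_max) {
  sigma_min + (sigma_max - sigma_min) * (1 - pmin(abs(mu - 5), 4) / 4)
}

# Assign workers of one population to pages: each worker takes 1-3 whole
# pages, always those with the highest remaining demand, until every page
# has met its target number of ratings.
assign_pages <- function(n_workers, demand) {
  pages_of <- vector("list", n_workers)
  for (w in seq_len(n_workers)) {
    open <- which(demand > 0)
    if (length(open) == 0) break
    n_take <- min(sample.int(3L, 1, prob = c(0.45, 0.35, 0.2)), length(open))
    take <- open[order(-demand[open], open)][seq_len(n_take)]
    pages_of[[w]] <- take
    demand[take] <- demand[take] - 1L
  }
  # top-up pass: let earlier workers take further pages, up to 3 each
  while (any(demand > 0)) {
    progress <- FALSE
    for (w in seq_len(n_workers)) {
      if (length(pages_of[[w]]) >= 3L) next
      open <- setdiff(which(demand > 0), pages_of[[w]])
      if (length(open) == 0) next
      take <- open[order(-demand[open], open)][1]
      pages_of[[w]] <- c(pages_of[[w]], take)
      demand[take] <- demand[take] - 1L
      progress <- TRUE
      if (all(demand <= 0)) break
    }
    if (!progress) stop("worker pool exhausted before rating targets were met")
  }
  do.call(rbind, lapply(seq_len(n_workers), function(w) {
    if (length(pages_of[[w]]) == 0) return(NULL)
    data.frame(worker = w, page = pages_of[[w]])
  }))
}

#' Generate a synthetic crowdsourcing campaign
#'
#' Produces a ratings table, the latent truth behind it, and a gold table
#' whose means/SDs come from an independent large simulated reference sample
#' (mimicking normative lab values, which are themselves finite-sample
#' means).  A rating by worker `w` on picture `p` is
#' `round(clip(mu_p + group_shift + bias_w + eps, 1, 9))` with
#' `eps ~ N(0, sigma(mu_p) * multiplier)`; `group_shift` is
#' `sign(w, theme(p)) * delta` for multimodal pictures and 0 otherwise.
#' Rounding uses R's round-half-even convention.  Identical configurations
#' (including the seed) give identical output.
#'
#' @param config a [generator_config()].
#' @return list of class `crowd_synthesis` with elements `ratings`
#'   ([ratings_table()]), `truth` (per-picture latent parameters, per-worker
#'   biases and subgroup signs, clipping frequency), and `gold`
#'   ([gold_table()]).
#' @export
generate_crowd <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)

  pictures <- sprintf("pic%03d", seq_len(cfg$n_pictures))
  n_pages <- ceiling(cfg$n_pictures / cfg$page_size)
  page_of <- rep(seq_len(n_pages), each = cfg$page_size)[seq_len(cfg$n_pictures)]

  # --- latent truth ------------------------------------------------------
  set.seed(derive_seed(cfg$seed, "truth"))
  mu <- matrix(stats::runif(cfg$n_pictures * length(cfg$dimensions),
                            cfg$mean_range[1], cfg$mean_range[2]),
               nrow = cfg$n_pictures,
               dimnames = list(pictures, cfg$dimensions))
  n_multi <- round(cfg$multimodal_fraction * cfg$n_pictures)
  multi_set <- sort(sample.int(cfg$n_pictures, n_multi))
  if (n_multi > 0) {
    mu[multi_set, ] <- stats::runif(n_multi * length(cfg$dimensions),
                                    cfg$mm_mean_range[1], cfg$mm_mean_range[2])
  }
  theme <- rep(NA_integer_, cfg$n_pictures)
  if (n_multi > 0) theme[multi_set] <- rep_len(seq_len(cfg$n_themes), n_multi)[
    sample.int(n_multi)]

  # --- workers -----------------------------------------------------------
  set.seed(derive_seed(cfg$seed, "workers"))
  pops <- names(cfg$populations)
  workers <- list()
  for (pop in pops) {
    ids <- sprintf("%s_w%04d", pop, seq_len(cfg$n_workers))
    bias <- stats::rnorm(cfg$n_workers, 0, cfg$rater_bias_sd)
    signs <- matrix(sample(c(-1, 1), cfg$n_workers * cfg$n_themes, replace = TRUE),
                    nrow = cfg$n_workers)
    sizes <- seq(cfg$pool_range[1], cfg$pool_range[2])
    demand <- if (length(sizes) == 1) rep(sizes, n_pages)
              else sample(sizes, n_pages, replace = TRUE)
    asg <- assign_pages(cfg$n_workers, demand)
    workers[[pop]] <- list(ids = ids, bias = bias, signs = signs,
                           assignment = asg, multiplier = cfg$populations[[pop]])
  }

  # --- ratings -----------------------------------------------------------
  set.seed(derive_seed(cfg$seed, "ratings"))
  blocks <- list()
  n_clipped <- 0L
  n_total <- 0L
  for (pop in pops) {
    wk <- workers[[pop]]
    # expand worker-page assignment to worker-picture rows
    pics_per_page <- split(seq_len(cfg$n_pictures), page_of)
    idx <- do.call(rbind, lapply(seq_len(nrow(wk$assignment)), function(i) {
      p <- pics_per_page[[wk$assignment$page[i]]]
      cbind(worker = wk$assignment$worker[i], pic = p)
    }))
    for (dim_name in cfg$dimensions) {
      mu_p <- mu[idx[, "pic"], dim_name]
      shift <- ifelse(is.na(theme[idx[, "pic"]]), 0,
                      wk$signs[cbind(idx[, "worker"],
                                     ifelse(is.na(theme[idx[, "pic"]]), 1L,
                                            theme[idx[, "pic"]]))] * cfg$separation)
      sig <- sigma_at(mu_p, cfg$sigma_min, cfg$sigma_max) * wk$multiplier
      raw <- mu_p + shift + wk$bias[idx[, "worker"]] +
        stats::rnorm(nrow(idx), 0, sig)
      n_clipped <- n_clipped + sum(raw < 1 | raw > 9)
      n_total <- n_total + nrow(idx)
      blocks[[paste(pop, dim_name)]] <- data.frame(
        worker = wk$ids[idx[, "worker"]],
        picture = pictures[idx[, "pic"]],
        dimension = dim_name,
        rating = as.integer(round(pmin(9, pmax(1, raw)))),
        population = pop,
        batch = sprintf("page%d", page_of[idx[, "pic"]]),
        stringsAsFactors = FALSE)
    }
  }
  ratings <- ratings_table(do.call(rbind, blocks),
                           provenance = sprintf("generator seed %d", cfg$seed))

  # --- gold reference sample (independent stream) ------------------------
  set.seed(derive_seed(cfg$seed, "gold"))
  ng <- cfg$n_gold_raters
  gold_rows <- list()
  g_bias <- stats::rnorm(ng, 0, cfg$rater_bias_sd)
  g_signs <- matrix(sample(c(-1, 1), ng * cfg$n_themes, replace = TRUE), nrow = ng)
  for (dim_name in cfg$dimensions) {
    for (p in seq_len(cfg$n_pictures)) {
      shift <- if (is.na(theme[p])) 0 else g_signs[, theme[p]] * cfg$separation
      sig <- sigma_at(mu[p, dim_name], cfg$sigma_min, cfg$sigma_max)
      r <- round(pmin(9, pmax(1, mu[p, dim_name] + shift + g_bias +
                                stats::rnorm(ng, 0, sig))))
      gold_rows[[paste(dim_name, p)]] <- data.frame(
        picture = pictures[p], dimension = dim_name,
        mean = mean(r), sd = stats::sd(r), n = ng, stringsAsFactors = FALSE)
    }
  }
  gold <- gold_table(do.call(rbind, gold_rows),
                     provenance = sprintf("generator gold reference seed %d", cfg$seed))

  truth <- list(
    config = cfg,
    pictures = data.frame(picture = pictures, page = page_of,
                          multimodal = seq_len(cfg$n_pictures) %in% multi_set,
                          theme = theme, stringsAsFactors = FALSE),
    mu = mu,
    workers = lapply(workers, function(w)
      list(ids = w$ids, bias = w$bias, signs = w$signs)),
    clip_frequency = n_clipped / n_total)

  structure(list(ratings = ratings, truth = truth, gold = gold),
            class = "crowd_synthesis")
}

#' Empirical SD profile check for the generator
#'
#' Self-validation of the heteroscedastic noise model: bins unimodal
#' pictures by the distance of their true mean from the neutral midpoint 5
#' and reports the mean per-picture sample SD in each bin.  With
#' `sigma_max > sigma_min` the profile is non-increasing in expectation from
#' the neutral bin to the extreme bins.
#'
#' @param table a [ratings_table()] produced by [generate_crowd()].
#' @param truth the matching truth object.
#' @param dimension dimension to profile.
#' @param n_bins number of equal-width bins over `|mu - 5|` in `[0, 4]`.
#' @return data frame with `bin`, `mid` (bin midpoint), `mean_sd`,
#'   `n_pictures`.
#' @export
empirical_sd_check <- function(table, truth, dimension = "valence", n_bins = 4) {
  stopifnot(inherits(table, "ratings_table"), n_bins >= 1)
  uni <- truth$pictures$picture[!truth$pictures$multimodal]
  sub <- table[table$dimension == dimension & table$picture %in% uni, ]
  if (nrow(sub) == 0) stop("no unimodal pictures for dimension ", dimension)
  sds <- tapply(sub$rating, sub$picture, stats::sd)
  dist <- pmin(abs(truth$mu[names(sds), dimension] - 5), 4)
  edges <- seq(0, 4, length.out = n_bins + 1)
  bin <- pmin(findInterval(dist, edges, rightmost.closed = TRUE), n_bins)
  out <- data.frame(bin = seq_len(n_bins),
                    mid = (edges[-1] + edges[-(n_bins + 1)]) / 2)
  out$mean_sd <- vapply(seq_len(n_bins),
                        function(b) if (any(bin == b)) mean(sds[bin == b]) else NA_real_,
                        0)
  out$n_pictures <- vapply(seq_len(n_bins), function(b) sum(bin == b), 0L)
  out
}
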