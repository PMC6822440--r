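#' Default analysis configuration
#'
#' Flat key-value settings for the full pipeline, mirroring the design
#' constants of a typical campaign analysis: rating sizes 1-15 with 30 runs
#' each, k = 8 for the gold comparison, reliability thresholds .4 / .75,
#' and a 0.05 level with 2000 Monte-Carlo replicates for modality calls.
#' Values can be overridden from a YAML file or a named list.
#'
#' @param overrides named list (or path to a YAML file) of settings to
#'   override.
#' @return named list of settings.
#' @export
analysis_config <- function(overrides = NULL) {
  cfg <- list(
    k_min = 1L, k_max = 15L, runs_per_k = 30L, curve_replicates = 10L,
    agreement_k = 8L, agreement_runs = 30L,
    threshold_excellent = 0.75, threshold_fair = 0.4,
    alpha = 0.05, n_replicates = 2000L, tie_policy = "jitter",
    deviation_threshold = 1.5, sd_bins = 4L,
    transfer_dimension = "arousal",
    seed = 1L)
  if (is.character(overrides)) overrides <- yaml::read_yaml(overrides)
  if (!is.null(overrides)) {
    unknown <- setdiff(names(overrides), c(names(cfg), "generator"))
    if (length(unknown) > 0) {
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    }
    cfg[names(overrides)] <- overrides
  }
  cfg
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' Simulate a campaign and write its artifact bundle
#'
#' Runs the synthetic generator and writes `ratings.csv`, `gold.csv` and
#' `truth.json` (configuration echo plus per-picture latent parameters) to
#' the output directory.  Identical configuration and seed give
#' byte-identical outputs.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [generator_config()], a named list of its arguments, or
#'   a path to a YAML file holding them under the key `generator`.
#' @param seed optional master seed overriding the configured one.
#' @return invisible named list of the written paths.
#' @export
cmd_simulate <- function(out_dir, config = NULL, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)$generator
  if (is.list(config) && !inherits(config, "generator_config")) {
    config <- do.call(generator_config, config)
  }
  if (is.null(config)) config <- generator_config()
  if (!is.null(seed)) {
    args <- unclass(config)
    args$seed <- as.integer(seed)
    config <- do.call(generator_config, args)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  syn <- generate_crowd(config)
  paths <- list(ratings = file.path(out_dir, "ratings.csv"),
                gold = file.path(out_dir, "gold.csv"),
                truth = file.path(out_dir, "truth.json"))
  write_ratings(syn$ratings, paths$ratings)
  utils::write.csv(as.data.frame(syn$gold), paths$gold,
                   row.names = FALSE, quote = FALSE)
  cfg <- unclass(config)
  cfg$populations <- as.list(cfg$populations)
  write_json_file(list(
    config = cfg,
    clip_frequency = syn$truth$clip_frequency,
    pictures = cbind(syn$truth$pictures,
                     as.data.frame(syn$truth$mu[syn$truth$pictures$picture, ,
                                                drop = FALSE]))),
    paths$truth)
  invisible(paths)
}

run_stage <- function(name, strict, errors, expr) {
  tryCatch(expr, error = function(e) {
    if (strict) stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    errors[[name]] <- conditionMessage(e)
    NULL
  })
}

#' Analyze a ratings bundle and write the consolidated report
#'
#' Runs every analysis stage per dimension and population: the reliability
#' curve with minimum-ratings recommendations, the modality summary, the SD
#' profile, the opinion-transfer table over multimodal picture pairs, the
#' gold-label agreement at the configured aggregation size, and the
#' corrected mean-shift test.  Stage outputs are written as CSV/JSON files
#' plus a consolidated `report.json`.  In lenient mode (default) failing
#' stages are recorded in the report's `errors` field; with
#' `strict = TRUE` the first failure aborts.
#'
#' @param ratings_path ratings CSV (see [read_ratings()]).
#' @param gold_path gold CSV (see [read_gold()]).
#' @param out_dir output directory.
#' @param config an [analysis_config()] list, overrides for it, or a YAML
#'   path.
#' @param strict abort on the first stage failure.
#' @return invisible report list (also written to `report.json`).
#' @export
cmd_analyze <- function(ratings_path, gold_path, out_dir, config = NULL,
                        strict = FALSE) {
  cfg <- if (is.list(config) && !is.null(config$k_min)) config
         else analysis_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  table <- read_ratings(ratings_path, strict = strict)
  gold <- read_gold(gold_path)
  pops <- unique(table$population)
  dims <- intersect(SAM_DIMENSIONS, unique(table$dimension))
  errors <- new.env(parent = emptyenv())

  curve_rows <- list(); modality_rows <- list(); sd_rows <- list()
  sd_bin_rows <- list(); agreement <- list(); recommendations <- list()
  fractions <- list(); transfer_rows <- list()
  crowd_store <- new.env(parent = emptyenv())

  for (pop in pops) {
    for (dim_name in dims) {
      key <- paste(dim_name, pop, sep = ".")
      pool <- run_stage(paste0("pivot.", key), strict, errors,
                        pivot_matrix(table, dim_name, pop))
      if (is.null(pool)) next

      cv <- run_stage(paste0("reliability.", key), strict, errors, {
        sc <- sim_config(k_range = cfg$k_min:cfg$k_max,
                         runs_per_k = cfg$runs_per_k,
                         n_replicates = cfg$curve_replicates,
                         seed = derive_seed(cfg$seed, paste0("curve.", key)))
        suppressWarnings(reliability_curve(pool, sc))
      })
      if (!is.null(cv)) {
        curve_rows[[key]] <- cbind(dimension = dim_name, population = pop, cv)
        recommendations[[key]] <- list(
          dimension = dim_name, population = pop,
          min_k_excellent = min_ratings(cv, cfg$threshold_excellent),
          min_k_fair = min_ratings(cv, cfg$threshold_fair))
      }

      ms <- run_stage(paste0("modality.", key), strict, errors,
                      modality_summary(table, dim_name, pop, alpha = cfg$alpha,
                                       seed = derive_seed(cfg$seed, "modality"),
                                       tie_policy = cfg$tie_policy,
                                       n_replicates = cfg$n_replicates))
      if (!is.null(ms)) {
        modality_rows[[key]] <- cbind(dimension = dim_name, population = pop,
                                      ms$calls)
        fractions[[key]] <- list(dimension = dim_name, population = pop,
                                 fraction_unimodal = ms$fraction_unimodal)
        if (dim_name == cfg$transfer_dimension) {
          tr <- run_stage(paste0("transfer.", key), strict, errors, {
            pairs <- multimodal_pairs(ms$calls)
            if (nrow(pairs) > 0) {
              do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
                tc <- transfer_counts(table, pairs$picture_a[i],
                                      pairs$picture_b[i], dim_name)
                data.frame(dimension = dim_name, population = pop,
                           picture_a = tc$picture_a, picture_b = tc$picture_b,
                           n00 = tc$n00, n11 = tc$n11, n_change = tc$n_change,
                           n_excluded = tc$n_excluded, n_both = tc$n_both,
                           stringsAsFactors = FALSE)
              }))
            } else NULL
          })
          if (!is.null(tr)) transfer_rows[[key]] <- tr
        }
      }

      sp <- run_stage(paste0("sdprofile.", key), strict, errors,
                      sd_profile(pool, n_bins = cfg$sd_bins))
      if (!is.null(sp)) {
        sd_rows[[key]] <- cbind(dimension = dim_name, population = pop,
                                sp$per_picture)
        sd_bin_rows[[key]] <- cbind(dimension = dim_name, population = pop,
                                    sp$binned)
      }

      ag <- run_stage(paste0("agreement.", key), strict, errors, {
        crowd <- aggregate_crowd(pool, k = cfg$agreement_k,
                                 n_runs = cfg$agreement_runs,
                                 seed = derive_seed(cfg$seed, paste0("agg.", key)))
        assign(key, crowd, envir = crowd_store)
        cg <- crowd_gold_matrix(crowd, gold, dim_name)
        dev <- deviation_flags(crowd, gold, dim_name, cfg$deviation_threshold)
        list(dimension = dim_name, population = pop, k = cfg$agreement_k,
             icc_agreement = icc_agreement(cg)$estimate,
             icc_consistency = icc_consistency(cg)$estimate,
             deviations = dev)
      })
      if (!is.null(ag)) agreement[[key]] <- ag
    }
  }

  shift <- list()
  for (pop in pops) {
    crowd_by_dim <- list()
    for (dim_name in dims) {
      key <- paste(dim_name, pop, sep = ".")
      if (!is.null(crowd_store[[key]])) crowd_by_dim[[dim_name]] <- crowd_store[[key]]
    }
    if (length(crowd_by_dim) >= 1) {
      shift[[pop]] <- run_stage(paste0("mean_shift.", pop), strict, errors,
                                mean_shift_test(crowd_by_dim, gold))
    }
  }

  write_stage_csv <- function(rows, file) {
    if (length(rows) > 0) {
      utils::write.csv(do.call(rbind, unname(rows)), file.path(out_dir, file),
                       row.names = FALSE, quote = FALSE)
    }
  }
  write_stage_csv(curve_rows, "reliability_curve.csv")
  write_stage_csv(modality_rows, "modality.csv")
  write_stage_csv(sd_rows, "sd_per_picture.csv")
  write_stage_csv(sd_bin_rows, "sd_binned.csv")
  write_stage_csv(transfer_rows, "transfer.csv")

  deviations <- lapply(agreement, function(a) a$deviations)
  report <- list(
    package = "crowdaffect",
    seed = cfg$seed,
    dimensions = dims,
    populations = pops,
    min_ratings = unname(recommendations),
    fraction_unimodal = unname(fractions),
    agreement = unname(lapply(agreement, function(a)
      a[c("dimension", "population", "k", "icc_agreement", "icc_consistency")])),
    mean_shift = shift,
    n_deviating_pictures = sum(vapply(deviations, nrow, 0L)),
    errors = as.list(errors))
  write_json_file(report, file.path(out_dir, "report.json"))
  invisible(report)
}
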