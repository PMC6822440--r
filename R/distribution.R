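#' Per-picture SD versus rating extremity
#'
#' Computes each picture's sample mean and SD and summarizes the SDs in
#' bins of the mean's distance from the neutral midpoint 5.  In crowdsourced
#' affect data the SD tends to be higher around the neutral range of the
#' scale and lower at the extremes; this is the profile that shows it.
#'
#' @param matrix items x raters matrix (see [pivot_matrix()]).
#' @param n_bins number of equal-width bins over `|mean - 5|` in `[0, 4]`.
#' @return list with `per_picture` (picture, n, mean, sd; pictures with
#'   fewer than 2 ratings are excluded and counted) and `binned`
#'   (bin, mid, mean_sd, n_pictures).
#' @export
sd_profile <- function(matrix, n_bins = 4) {
  stopifnot(n_bins >= 1)
  x <- unclass(matrix)
  n <- rowSums(!is.na(x))
  per <- data.frame(picture = rownames(x), n = n,
                    mean = rowMeans(x, na.rm = TRUE),
                    sd = apply(x, 1, stats::sd, na.rm = TRUE),
                    stringsAsFactors = FALSE)
  excluded <- sum(per$n < 2)
  per <- per[per$n >= 2, , drop = FALSE]
  if (nrow(per) == 0) stop("no picture has at least 2 ratings")
  rownames(per) <- NULL
  dist <- pmin(abs(per$mean - 5), 4)
  edges <- seq(0, 4, length.out = n_bins + 1)
  bin <- pmin(findInterval(dist, edges, rightmost.closed = TRUE), n_bins)
  binned <- data.frame(bin = seq_len(n_bins),
                       mid = (edges[-1] + edges[-(n_bins + 1)]) / 2)
  binned$mean_sd <- vapply(seq_len(n_bins), function(b)
    if (any(bin == b)) mean(per$sd[bin == b]) else NA_real_, 0)
  binned$n_pictures <- vapply(seq_len(n_bins), function(b) sum(bin == b), 0L)
  list(per_picture = per, binned = binned, n_excluded = excluded)
}

#' Modality summary for one dimension and population
#'
#' Runs [classify_modality()] on every picture's rating distribution and
#' reports the fraction called unimodal together with the per-picture
#' results.  Reproducible bit-exactly under a fixed seed and tie policy.
#'
#' @param table a [ratings_table()].
#' @param dimension SAM dimension.
#' @param population population tag or `"all"`.
#' @param alpha significance level of the multimodality call.
#' @param seed integer seed (jitter and null tables).
#' @param tie_policy `"jitter"` (default) or `"raw"`; see
#'   [classify_modality()].
#' @param n_replicates Monte-Carlo null size.
#' @param min_n pictures with fewer ratings are reported as `NA` calls.
#' @return list with `fraction_unimodal`, `calls` (data frame: picture, n,
#'   dip, p_value, call) and the parameters used.
#' @export
modality_summary <- function(table, dimension, population = "all",
                             alpha = 0.05, seed = 1,
                             tie_policy = c("jitter", "raw"),
                             n_replicates = 2000, min_n = 4) {
  tie_policy <- match.arg(tie_policy)
  m <- pivot_matrix(table, dimension, population)
  x <- unclass(m)
  rows <- lapply(seq_len(nrow(x)), function(i) {
    v <- x[i, !is.na(x[i, ])]
    if (length(v) < min_n) {
      return(data.frame(picture = rownames(x)[i], n = length(v),
                        dip = NA_real_, p_value = NA_real_,
                        call = NA_character_, stringsAsFactors = FALSE))
    }
    # per-picture jitter seed; one shared null table per sample size
    r <- classify_modality(v, alpha = alpha, tie_policy = tie_policy,
                           seed = derive_seed(seed, rownames(x)[i]),
                           n_replicates = n_replicates, null_seed = seed)
    data.frame(picture = rownames(x)[i], n = r$n, dip = r$dip,
               p_value = r$p_value, call = r$call, stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, rows)
  ok <- !is.na(calls$call)
  if (!any(ok)) stop("no picture with enough ratings for a modality call")
  list(fraction_unimodal = mean(calls$call[ok] == "unimodal"),
       calls = calls, dimension = dimension, population = population,
       alpha = alpha, tie_policy = tie_policy, seed = seed,
       n_replicates = n_replicates)
}

#' Binarize a rating around the neutral value
#'
#' `0` below neutral, `1` above, `"excluded"` at the neutral value itself:
#' the transform only defines sides below and above the midpoint, so exactly
#' neutral ratings are excluded rather than assigned a side.
#'
#' @param rating integer rating(s) in `[1, 9]`.
#' @param neutral the neutral scale value (default 5).
#' @return character vector over `"0"`, `"1"`, `"excluded"`.
#' @export
binarize <- function(rating, neutral = 5) {
  if (any(is.na(rating) | rating < 1 | rating > 9)) {
    stop("rating outside the 9-point scale")
  }
  ifelse(rating < neutral, "0", ifelse(rating > neutral, "1", "excluded"))
}

#' Opinion transfer between two pictures
#'
#' Over workers who rated both pictures on the given dimension, counts
#' those rating both below neutral (`n00`), both above (`n11`), switching
#' sides (`n_change`), and those excluded because either rating was exactly
#' neutral (`n_excluded`).  `n00 + n11 + n_change + n_excluded` equals the
#' number of workers who rated both pictures; workers missing either
#' picture are not counted at all.
#'
#' @param table a [ratings_table()].
#' @param picture_a,picture_b picture ids.
#' @param dimension SAM dimension.
#' @param neutral neutral scale value.
#' @return a `transfer_counts` list with the four counts, the picture ids
#'   and `n_both`.
#' @export
transfer_counts <- function(table, picture_a, picture_b, dimension,
                            neutral = 5) {
  stopifnot(inherits(table, "ratings_table"))
  sub <- table[table$dimension == dimension &
                 table$picture %in% c(picture_a, picture_b), ]
  a <- sub[sub$picture == picture_a, ]
  b <- sub[sub$picture == picture_b, ]
  if (nrow(a) == 0 || nrow(b) == 0) {
    stop("picture absent for dimension ", dimension, ": ",
         if (nrow(a) == 0) picture_a else picture_b)
  }
  common <- intersect(a$worker, b$worker)
  ra <- a$rating[match(common, a$worker)]
  rb <- b$rating[match(common, b$worker)]
  ba <- binarize(ra, neutral)
  bb <- binarize(rb, neutral)
  excl <- ba == "excluded" | bb == "excluded"
  structure(list(picture_a = picture_a, picture_b = picture_b,
                 dimension = dimension,
                 n00 = sum(!excl & ba == "0" & bb == "0"),
                 n11 = sum(!excl & ba == "1" & bb == "1"),
                 n_change = sum(!excl & ba != bb),
                 n_excluded = sum(excl),
                 n_both = length(common)),
            class = "transfer_counts")
}

#' All pairs of multimodal pictures
#'
#' @param calls per-picture calls data frame from [modality_summary()].
#' @return data frame of unordered pairs (`picture_a`, `picture_b`) of
#'   pictures called multimodal; empty if fewer than 2.
#' @export
multimodal_pairs <- function(calls) {
  mm <- calls$picture[!is.na(calls$call) & calls$call == "multimodal"]
  if (length(mm) < 2) {
    return(data.frame(picture_a = character(0), picture_b = character(0),
                      stringsAsFactors = FALSE))
  }
  idx <- utils::combn(length(mm), 2)
  data.frame(picture_a = mm[idx[1, ]], picture_b = mm[idx[2, ]],
             stringsAsFactors = FALSE)
}
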