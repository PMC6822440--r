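#' Construct and validate a ratings table
#'
#' A ratings table is the long-format record of a crowdsourcing campaign:
#' one row per (worker, picture, dimension) with the integer rating the
#' worker gave on the 9-point SAM scale, plus the worker's population tag
#' (e.g. `"specialized"` or `"general"`) and an optional batch (page)
#' identifier.
#'
#' Invariants enforced: ratings are integers in `[1, 9]`;
#' `(worker, picture, dimension)` is unique; dimensions are SAM dimensions.
#'
#' @param records data frame with columns `worker`, `picture`, `dimension`,
#'   `rating` and optionally `population` (default `"all"`) and `batch`
#'   (default `""`).
#' @param provenance free-text origin of the data (file path or generator
#'   configuration digest).
#' @param strict if `TRUE` any invariant violation is an error; otherwise
#'   offending rows are dropped and counted in the `n_dropped` attribute.
#' @return a `ratings_table` (a data frame subclass) with attributes
#'   `provenance` and `n_dropped`.
#' @export
ratings_table <- function(records, provenance = "", strict = TRUE) {
  required <- c("worker", "picture", "dimension", "rating")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("ratings table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- data.frame(
    worker = as.character(records$worker),
    picture = as.character(records$picture),
    dimension = as.character(records$dimension),
    rating = suppressWarnings(as.numeric(records$rating)),
    population = if ("population" %in% names(records)) {
      pop <- as.character(records$population)
      ifelse(is.na(pop) | pop == "", "all", pop)
    } else "all",
    batch = if ("batch" %in% names(records)) {
      b <- as.character(records$batch)
      ifelse(is.na(b), "", b)
    } else "",
    stringsAsFactors = FALSE
  )

  bad_dim <- !(df$dimension %in% SAM_DIMENSIONS)
  bad_rating <- is.na(df$rating) | df$rating != round(df$rating) |
    df$rating < 1 | df$rating > 9
  dup <- duplicated(df[, c("worker", "picture", "dimension")])
  bad <- bad_dim | bad_rating | dup

  if (strict && any(bad)) {
    i <- which(bad)[1]
    reason <- if (bad_dim[i]) "unknown dimension" else
      if (bad_rating[i]) "rating outside the 9-point integer scale" else
        "duplicate (worker, picture, dimension)"
    stop(sprintf("invalid rating record at row %d: %s (worker=%s picture=%s rating=%s)",
                 i, reason, df$worker[i], df$picture[i],
                 as.character(records$rating[i])))
  }
  n_dropped <- sum(bad)
  df <- df[!bad, , drop = FALSE]
  rownames(df) <- NULL
  df$rating <- as.integer(df$rating)
  structure(df,
            provenance = provenance,
            n_dropped = n_dropped,
            class = c("ratings_table", "data.frame"))
}

#' Read a ratings CSV
#'
#' Expects comma-separated UTF-8 with a header naming at least
#' `worker,picture,dimension,rating`; `population` and `batch` are optional.
#'
#' @param path file path.
#' @param strict abort on any invalid row (`TRUE`) or drop-and-count
#'   (`FALSE`).
#' @return a [ratings_table()].
#' @export
read_ratings <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("ratings file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character", check.names = TRUE)
  ratings_table(df, provenance = path, strict = strict)
}

#' Write a ratings table to CSV
#'
#' The on-disk dialect is `worker,picture,dimension,rating,population,batch`;
#' reading the file back reproduces the table record for record.
#'
#' @param table a [ratings_table()].
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(table, path) {
  stopifnot(inherits(table, "ratings_table"))
  utils::write.csv(as.data.frame(table)[, c("worker", "picture", "dimension",
                                            "rating", "population", "batch")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gold-label CSV
#'
#' Gold labels are reference per-picture statistics from a normative study
#' (mean, SD and number of raters per picture and dimension), the role the
#' IAPS norms play for affect annotation.
#'
#' @param path CSV with columns `picture,dimension,mean,sd,n`.
#' @return a `gold_table` data frame, one row per (picture, dimension).
#' @export
read_gold <- function(path) {
  if (!file.exists(path)) stop("gold file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  gold_table(df, provenance = path)
}

#' Construct and validate a gold table
#'
#' @param df data frame with columns `picture,dimension,mean,sd,n`.
#' @param provenance free-text origin.
#' @return a `gold_table`.
#' @export
gold_table <- function(df, provenance = "") {
  required <- c("picture", "dimension", "mean", "sd", "n")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("gold table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- data.frame(picture = as.character(df$picture),
                   dimension = as.character(df$dimension),
                   mean = as.numeric(df$mean),
                   sd = as.numeric(df$sd),
                   n = as.integer(df$n),
                   stringsAsFactors = FALSE)
  key <- paste(df$picture, df$dimension)
  if (anyDuplicated(key)) {
    stop("duplicate (picture, dimension) in gold table: ",
         key[duplicated(key)][1])
  }
  if (any(!(df$dimension %in% SAM_DIMENSIONS))) {
    stop("unknown dimension in gold table")
  }
  if (any(is.na(df$mean) | df$mean < 1 | df$mean > 9)) {
    stop("gold mean outside the 9-point scale [1, 9]")
  }
  if (any(is.na(df$sd) | df$sd < 0)) stop("gold sd must be >= 0")
  if (any(is.na(df$n) | df$n < 1)) stop("gold n must be a positive integer")
  rownames(df) <- NULL
  structure(df, provenance = provenance,
            class = c("gold_table", "data.frame"))
}

#' Pivot a ratings table to an items x raters matrix
#'
#' Produces the subjects-by-raters layout that the two-way ICC decomposition
#' consumes: one row per picture, one column per worker, `NA` for cells the
#' worker did not rate (missing cells are never imputed at this layer).  Row
#' order follows first appearance of the picture in the table, column order
#' first appearance of the worker, so the pivot is deterministic.
#'
#' @param table a [ratings_table()].
#' @param dimension one of `"valence"`, `"arousal"`, `"dominance"`.
#' @param population population tag to filter on, or `"all"` to keep every
#'   worker.
#' @return numeric matrix with `dimnames` (pictures, workers) and attributes
#'   `dimension` and `population`.
#' @export
pivot_matrix <- function(table, dimension, population = "all") {
  stopifnot(inherits(table, "ratings_table"))
  dimension <- match.arg(dimension, SAM_DIMENSIONS)
  sel <- table$dimension == dimension
  if (!identical(population, "all")) sel <- sel & table$population == population
  sub <- table[sel, , drop = FALSE]
  if (nrow(sub) == 0) {
    stop(sprintf("no records for dimension '%s' and population '%s'",
                 dimension, population))
  }
  pictures <- unique(sub$picture)
  workers <- unique(sub$worker)
  m <- matrix(NA_real_, nrow = length(pictures), ncol = length(workers),
              dimnames = list(pictures, workers))
  m[cbind(match(sub$picture, pictures), match(sub$worker, workers))] <- sub$rating
  structure(m, dimension = dimension, population = population,
            class = c("ratings_matrix", class(m)))
}
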