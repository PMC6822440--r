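# Independent oracles used across the suite.

# Brute-force two-way ANOVA: materializes every (i, j) deviation explicitly
# with scalar loops; shares no code with anova_mean_squares().
oracle_mean_squares <- function(x) {
  n <- nrow(x)
  k <- ncol(x)
  g <- mean(x)
  ssr <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (mean(x[i, ]) - g)^2
  ssc <- 0
  for (j in seq_len(k)) ssc <- ssc + n * (mean(x[, j]) - g)^2
  sse <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      sse <- sse + (x[i, j] - mean(x[i, ]) - mean(x[, j]) + g)^2
    }
  }
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)), n = n, k = k)
}

oracle_icc_consistency <- function(x) {
  ms <- oracle_mean_squares(x)
  (ms$msr - ms$mse) / (ms$msr + (ms$k - 1) * ms$mse)
}

oracle_icc_agreement <- function(x) {
  ms <- oracle_mean_squares(x)
  (ms$msr - ms$mse) /
    (ms$msr + (ms$k - 1) * ms$mse + (ms$k / ms$n) * (ms$msc - ms$mse))
}

# Exact-LP dip oracle (scipy/HiGHS): minimizes the band half-width directly
# as a linear program per candidate mode, a computational path disjoint
# from the package's bisection-plus-reachable-set implementation.
dip_lp_oracle <- function(samples) {
  script <- test_path("dip-lp-oracle.py")
  infile <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(lapply(samples, as.numeric), digits = NA), infile)
  out <- system2("python", shQuote(script), stdout = TRUE, stdin = infile)
  unlist(jsonlite::fromJSON(paste(out, collapse = "")))
}

random_matrix <- function(n, k) {
  matrix(sample(1:9, n * k, replace = TRUE) + stats::runif(n * k, -0.2, 0.2),
         n, k)
}
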