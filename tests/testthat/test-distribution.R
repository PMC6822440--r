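test_that("SD profile handles flat and heteroscedastic pools", {
  pool <- matrix(rep(c(2, 5, 8), 10), 3, 10,
                 dimnames = list(paste0("p", 1:3), NULL))
  sp <- sd_profile(pool, n_bins = 2)
  expect_true(all(sp$per_picture$sd == 0))
  # single bin: overall mean SD equals the average of per-picture SDs
  set.seed(1)
  pool2 <- matrix(runif(60, 1, 9), 6, 10,
                  dimnames = list(paste0("p", 1:6), NULL))
  sp2 <- sd_profile(pool2, n_bins = 1)
  expect_equal(sp2$binned$mean_sd, mean(sp2$per_picture$sd))
  # pictures with < 2 ratings are excluded and counted
  pool3 <- pool2
  pool3[1, 2:10] <- NA
  sp3 <- sd_profile(pool3)
  expect_identical(sp3$n_excluded, 1L)

  # generated heteroscedastic pool: neutral bin SD above extreme bin SD
  cfg <- generator_config(n_pictures = 120, page_size = 20, n_workers = 150,
                          pool_range = c(40, 40), sigma_min = 0.3,
                          sigma_max = 1.2, rater_bias_sd = 0,
                          multimodal_fraction = 0, dimensions = "valence",
                          mean_range = c(1.5, 8.5),
                          populations = c(specialized = 1), seed = 6)
  syn <- generate_crowd(cfg)
  m <- pivot_matrix(syn$ratings, "valence")
  sp4 <- sd_profile(m, n_bins = 3)
  expect_gt(sp4$binned$mean_sd[1], sp4$binned$mean_sd[3])
})

test_that("binarization splits the scale at the neutral value", {
  expect_identical(binarize(2), "0")
  expect_identical(binarize(8), "1")
  expect_identical(binarize(5), "excluded")
  expect_identical(binarize(c(1, 5, 9)), c("0", "excluded", "1"))
  expect_error(binarize(10), "scale")
})

transfer_fixture <- function() {
  # 6 workers rate both pictures low, 4 both high, 1 switches, 1 neutral
  w <- sprintf("w%02d", 1:12)
  ratings <- rbind(
    data.frame(worker = w[1:6], picture = "a", rating = 2),
    data.frame(worker = w[1:6], picture = "b", rating = 2),
    data.frame(worker = w[7:10], picture = "a", rating = 8),
    data.frame(worker = w[7:10], picture = "b", rating = 8),
    data.frame(worker = w[11], picture = "a", rating = 2),
    data.frame(worker = w[11], picture = "b", rating = 8),
    data.frame(worker = w[12], picture = "a", rating = 5),
    data.frame(worker = w[12], picture = "b", rating = 7))
  ratings$dimension <- "arousal"
  ratings_table(ratings)
}

test_that("transfer counts partition the common raters", {
  tab <- transfer_fixture()
  tc <- transfer_counts(tab, "a", "b", "arousal")
  expect_identical(tc$n00, 6L)
  expect_identical(tc$n11, 4L)
  expect_identical(tc$n_change, 1L)
  expect_identical(tc$n_excluded, 1L)
  expect_identical(tc$n00 + tc$n11 + tc$n_change + tc$n_excluded, tc$n_both)
  # symmetry in the pair
  tc2 <- transfer_counts(tab, "b", "a", "arousal")
  expect_identical(tc2$n00, tc$n00)
  expect_identical(tc2$n11, tc$n11)
  expect_identical(tc2$n_change, tc$n_change)
  expect_identical(tc2$n_excluded, tc$n_excluded)
  expect_error(transfer_counts(tab, "a", "zz", "arousal"), "absent")
})

test_that("same-theme pairs switch sides less than cross-theme pairs", {
  cfg <- generator_config(n_pictures = 24, page_size = 24, n_workers = 60,
                          pool_range = c(40, 40), multimodal_fraction = 0.5,
                          separation = 2, n_themes = 2,
                          sigma_min = 0.3, sigma_max = 0.5,
                          dimensions = "arousal",
                          populations = c(specialized = 1),
                          mm_mean_range = c(4.5, 5.5), seed = 17)
  syn <- generate_crowd(cfg)
  tp <- syn$truth$pictures
  mm <- tp[tp$multimodal, ]
  same <- cross <- c(0, 0)  # (changes, decided)
  for (i in seq_len(nrow(mm) - 1)) {
    for (j in seq(i + 1, nrow(mm))) {
      tc <- transfer_counts(syn$ratings, mm$picture[i], mm$picture[j], "arousal")
      dec <- tc$n00 + tc$n11 + tc$n_change
      tgt <- if (mm$theme[i] == mm$theme[j]) "same" else "cross"
      if (tgt == "same") same <- same + c(tc$n_change, dec)
      else cross <- cross + c(tc$n_change, dec)
    }
  }
  expect_lt(same[1] / same[2], cross[1] / cross[2])
})

test_that("multimodal pair enumeration is C(m, 2)", {
  calls <- data.frame(picture = sprintf("p%d", 1:6),
                      call = c("multimodal", "multimodal", "multimodal",
                               "unimodal", NA, "unimodal"),
                      stringsAsFactors = FALSE)
  expect_identical(nrow(multimodal_pairs(calls)), 3L)
  calls$call <- "unimodal"
  expect_identical(nrow(multimodal_pairs(calls)), 0L)
  calls$call <- "multimodal"
  expect_identical(nrow(multimodal_pairs(calls)), 15L)
})

test_that("modality summaries are bit-reproducible under a fixed seed", {
  syn <- generate_crowd(generator_config(n_pictures = 10, page_size = 10,
                                         n_workers = 40, pool_range = c(20, 20),
                                         dimensions = "valence", seed = 3))
  a <- modality_summary(syn$ratings, "valence", "specialized", seed = 5,
                        n_replicates = 300)
  b <- modality_summary(syn$ratings, "valence", "specialized", seed = 5,
                        n_replicates = 300)
  expect_identical(a$fraction_unimodal, b$fraction_unimodal)
  expect_identical(a$calls, b$calls)
  expect_error(modality_summary(syn$ratings, "dominance", "specialized"),
               "no records")
})
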