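test_that("nitrogen content follows the protein conversion identity", {
  expect_equal(compute_nc(7.44, 11.49), 136.77, tolerance = 1e-4)
  expect_equal(compute_nc(0, 12), 0)
  expect_equal(compute_nc(1, 6.25), 10)  # conversion factors cancel
  expect_error(compute_nc(-1, 10), "negative")
  expect_error(compute_nc(1, 101), "outside")
  # bilinear in GY and PC
  gy <- c(2, 5, 9); pc <- c(8, 11, 14)
  expect_equal(compute_nc(2 * gy, pc), 2 * compute_nc(gy, pc))
  expect_equal(compute_nc(gy, pc) + compute_nc(gy, 3), compute_nc(gy, pc + 3))
})

test_that("descriptive stats use the sample standard deviation", {
  df <- data.frame(gy = c(2, 4, 6))
  s <- descriptive_stats(df, "gy")
  expect_equal(s$n, 3)
  expect_equal(s$sd, 2)
  expect_equal(descriptive_stats(data.frame(x = rep(5, 4)), "x")$sd, 0)
  expect_error(descriptive_stats(data.frame(x = NA_real_), "x"), "no non-missing")
  expect_error(descriptive_stats(df, "nope"), "no column")
})

test_that("depth intervals follow the 0.2 m default bins", {
  r <- data.frame(depth_m = c(1.3, 2.05, 0.45, 1.2, 2.0, 0.3))
  out <- assign_depth_intervals(r)
  expect_equal(out$analysis_interval, c(1L, NA, NA, 1L, 4L, NA))
  expect_equal(out$interval[3], 1L)       # 0.45 m is in facility bin 1
  expect_true(is.na(out$interval[6]))     # above all bins
  expect_error(assign_depth_intervals(r, edges = c(1, 1, 2)), "increase")

  # interval counts match a brute-force histogram on uniform depths
  d <- semifieldgp:::with_seed(9, runif(500, 0.2, 2.3))
  out <- assign_depth_intervals(data.frame(depth_m = d))
  edges <- default_depth_edges()
  brute <- table(cut(d, edges, right = FALSE))
  got <- table(factor(out$interval, levels = 1:8))
  # cut() puts 2.0 in no bin with right=FALSE; align by the closed last bin
  brute[8] <- brute[8] + sum(d == 2.0)
  expect_equal(as.integer(got), as.integer(brute))
})

test_that("root editing matches a brute-force filter and reports retention", {
  tubes <- data.frame(bed = "B1", tube = sprintf("T%02d", 1:20),
                      camera = rep(1:4, 5),
                      line = rep(sprintf("L%02d", 1:10), 2))
  imgs <- simulate_root_images(tubes, seed = 21)
  genotyped <- sprintf("L%02d", 1:8)   # two lines lack genotypes
  ed <- edit_root_images(imgs, lines_with_genotype = genotyped)

  # brute force, same printed order
  b <- imgs[imgs$valid & !is.na(imgs$length_cm), ]
  b <- assign_depth_intervals(b)
  b <- b[!is.na(b$analysis_interval) & b$depth_m >= 1.2 & b$depth_m <= 2.0, ]
  keep <- rep(TRUE, nrow(b))
  for (iv in 1:4) {
    x <- b$length_cm[b$analysis_interval == iv]
    keep[b$analysis_interval == iv] <-
      abs(b$length_cm[b$analysis_interval == iv] - mean(x)) <= 3 * sd(x)
  }
  b <- b[keep, ]
  b <- b[b$line %in% genotyped, ]
  expect_equal(ed$length_cm, b$length_cm)
  expect_equal(ed$tube, b$tube)

  ret <- attr(ed, "retention")
  expect_equal(ret$step, c("input", "1_remove_failures", "2_depth_window",
                           "3_outliers", "4_genotyped"))
  expect_true(all(diff(ret$kept) <= 0))

  # boundary: a record at 1.05 m depth is removed at step 2
  one <- data.frame(bed = "B1", tube = "T01", camera = 1,
                    depth_m = c(1.05, 1.3), length_cm = c(1, 1),
                    valid = TRUE, line = "L01")
  expect_equal(nrow(edit_root_images(one)), 1L)

  # re-editing with the first pass's thresholds is exactly idempotent;
  # recomputing them on the filtered output may tighten the 3-sd band, so
  # full-recompute idempotence is not guaranteed (and indeed fails here)
  ed2 <- edit_root_images(ed, lines_with_genotype = genotyped,
                          outlier_stats = attr(ed, "outlier_stats"))
  expect_equal(ed2$length_cm, ed$length_cm)
  expect_equal(nrow(ed2), nrow(ed))

  # all-clean input: everything retained
  clean <- data.frame(bed = "B1", tube = rep(c("T1", "T2"), each = 3),
                      camera = 1, depth_m = rep(c(1.25, 1.55, 1.95), 2),
                      length_cm = c(1, 2, 3, 4, 5, 6), valid = TRUE,
                      line = "L01")
  expect_equal(nrow(edit_root_images(clean, "L01")), 6L)
  expect_error(edit_root_images(clean[1, ][-1, ]), "survive")
})

test_that("TRL/IRL aggregation conserves totals and matches groupby sums", {
  recs <- data.frame(bed = "B1", tube = "T1", camera = 1,
                     depth_m = c(1.25, 1.3, 1.35), length_cm = c(1, 2.5, 0.5),
                     valid = TRUE, line = "L1")
  ed <- edit_root_images(recs)
  agg <- aggregate_root_traits(ed)
  expect_equal(agg$trl$value, 4)
  expect_equal(agg$irl$value, 4)  # single interval

  tubes <- data.frame(bed = "B1", tube = sprintf("T%02d", 1:12),
                      camera = rep(1:4, 3), line = sprintf("L%02d", 1:12))
  imgs <- simulate_root_images(tubes, seed = 33)
  ed <- edit_root_images(imgs)
  agg <- aggregate_root_traits(ed)
  # conservation: each tube's IRL values sum to its TRL
  irl_sum <- tapply(agg$irl$value, agg$irl$tube, sum)
  expect_equal(as.numeric(irl_sum[agg$trl$tube]), agg$trl$value)
  # brute-force groupby
  expect_equal(agg$trl$value,
               as.numeric(tapply(ed$length_cm, ed$tube, sum)))
  # a tube with no retained images emits no record
  ed2 <- ed[ed$tube != "T01", ]
  expect_false("T01" %in% aggregate_root_traits(ed2)$trl$tube)
})
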