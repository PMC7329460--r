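make_rows <- function(beds, rows_per_bed, lines) {
  do.call(rbind, lapply(seq_len(beds), function(b)
    data.frame(bed = paste0("B", b), row = seq_len(rows_per_bed),
               line = rep_len(lines, rows_per_bed))))
}

test_that("layout sizes match the facility arithmetic", {
  ly <- build_layout(make_rows(2, 150, sprintf("L%02d", 1:75)))
  expect_equal(ly$field_size, 310)          # 150 x 2 beds + 2 x 5 virtual
  ly2 <- build_layout(make_rows(1, 10, c("A", "B")))
  expect_equal(ly2$field_size, 20)          # 10 + 2 x 5
  expect_error(build_layout(rbind(make_rows(1, 5, "A"),
                                  data.frame(bed = "B1", row = 5, line = "B"))),
               "duplicate")
  rt <- make_rows(1, 5, "A"); rt$position <- c(1, 2, 3, 5, 6)
  expect_error(build_layout(rt), "gaps")
})

test_that("neighbor map is adjacency within the bed pair and consistent", {
  ly <- build_layout(make_rows(2, 4, LETTERS[1:8]))
  rt <- ly$rows
  mid <- rt[rt$position == 3, ]
  expect_equal(mid$west_line, rt$line[rt$position == 2])
  expect_equal(mid$east_line, rt$line[rt$position == 4])
  # ends of the pair have one missing neighbor
  expect_true(is.na(rt$west_line[rt$position == 1]))
  expect_true(is.na(rt$east_line[rt$position == 8]))
  # mutual consistency: A east of B <=> B west of A
  for (p in 1:7) {
    expect_equal(rt$east_line[rt$position == p],
                 rt$line[rt$position == p + 1])
    expect_equal(rt$west_line[rt$position == p + 1],
                 rt$line[rt$position == p])
  }
  # the pair junction is contiguous by default, broken by segment_breaks
  ly2 <- build_layout(make_rows(2, 4, LETTERS[1:8]), segment_breaks = 4.5)
  expect_true(is.na(ly2$rows$east_line[ly2$rows$position == 4]))
  expect_true(is.na(ly2$rows$west_line[ly2$rows$position == 5]))
})

test_that("neighbor incidence counts west+east carriers", {
  rows <- data.frame(bed = "B1", row = 1:5,
                     line = c("A", "B", "A", "A", "C"))
  ly <- build_layout(rows)
  recs <- data.frame(bed = "B1", row = 1:5)
  Z <- neighbor_incidence(ly, recs, line_ids = c("A", "B", "C"))
  expect_equal(Z[2, ], c(A = 2, B = 0, C = 0))   # both neighbors are A
  expect_equal(Z[4, ], c(A = 1, B = 0, C = 1))   # west A, east C
  expect_equal(Z[1, ], c(A = 0, B = 1, C = 0))   # westmost: east only
  expect_true(all(rowSums(Z) %in% c(1, 2)))
  expect_error(neighbor_incidence(ly, data.frame(bed = "B9", row = 1)),
               "unknown rows")
})

test_that("spatial incidence is an 11-wide running window with virtual ends", {
  ly <- build_layout(make_rows(2, 10, LETTERS[1:5]))   # field 20 + 10
  recs <- data.frame(bed = rep(c("B1", "B2"), each = 10), row = rep(1:10, 2),
                     area = "wet")
  Z <- spatial_incidence(ly, recs, area = "wet")
  expect_equal(ncol(Z), ly$field_size)
  expect_equal(unname(rowSums(Z)), rep(11, 20))
  # interior position p covers columns p-5..p+5 (offset by the margin)
  p <- 8
  expect_equal(unname(which(Z[p, ] == 1)), (p - 5):(p + 5) + ly$n_virtual)
  # westmost real position leans on 5 virtual columns
  expect_equal(unname(which(Z[1, ] == 1)), 1:11)
  # other-area records get zero rows
  recs$area[3] <- "dry"
  Zw <- spatial_incidence(ly, recs, area = "wet")
  expect_equal(sum(Zw[3, ]), 0)
})

test_that("window-overlap covariance counts match brute force", {
  ly <- build_layout(make_rows(2, 12, LETTERS[1:6]))
  recs <- data.frame(bed = rep(c("B1", "B2"), each = 12), row = rep(1:12, 2),
                     area = "wet")
  Z <- spatial_incidence(ly, recs, area = "wet")
  S <- Z %*% t(Z)
  pos <- ly$rows$position[semifieldgp:::layout_index(ly, recs)]
  D <- abs(outer(pos, pos, "-"))
  expected <- ifelse(D <= 10, 11 - D, 0)
  expect_equal(unname(S), expected)
})

test_that("model assembly has the documented dimensions and structure", {
  cfg <- small_grain_config(seed = 2)
  ds <- simulate_trait(cfg)
  b1 <- assemble_model("GM1", ds$records, ds$layout, ds$G)
  expect_equal(ncol(b1$X), 4)              # 2 beds x 2 areas cell means
  expect_equal(vapply(b1$random, `[[`, "", "label"),
               c("g", "l", "r", "s_wet", "s_dry"))
  # g and l share the same incidence: a single 1 at the record's line
  expect_identical(b1$random[[1]]$Z, b1$random[[2]]$Z)
  expect_true(all(rowSums(b1$random[[1]]$Z) == 1))
  expect_equal(ncol(b1$random[[3]]$Z), 40)  # all 2 x 20 rows
  expect_equal(ncol(b1$random[[4]]$Z), ds$layout$field_size)

  b2 <- assemble_model("GM2", ds$records, ds$layout, ds$G)
  expect_equal(vapply(b2$random, `[[`, "", "label"),
               c("g", "l", "g_n", "l_n", "r", "s_wet", "s_dry"))
  expect_false(is.null(b2$random[[3]]$K))   # g_n carries G
  expect_true(is.null(b2$random[[4]]$K))    # l_n identity
  expect_true(all(rowSums(b2$random[[3]]$Z) %in% 0:2))

  cfgr <- sim_config(trait_kind = "root", n_lines = 10, n_markers = 80,
                     beds = 2, rows_per_bed = 12, seed = 3)
  dsr <- simulate_trait(cfgr)
  br <- assemble_model("RM2", dsr$records, dsr$layout, dsr$G)
  expect_equal(ncol(br$X), 1 + 3 + 3)      # beds + camera + interval contrasts
  expect_equal(vapply(br$random, `[[`, "", "label"), c("g", "l", "r", "s"))
  expect_equal(ncol(br$random[[4]]$Z), dsr$layout$root_field_size)
  expect_equal(unname(rowSums(br$random[[4]]$Z)), rep(11, nrow(dsr$records)))
})

test_that("design matrices export as readable MatrixMarket text", {
  cfg <- small_grain_config(seed = 6, n_lines = 6, rows_per_bed = 8,
                            n_markers = 50)
  ds <- simulate_trait(cfg)
  b <- assemble_model("GM1", ds$records, ds$layout, ds$G)
  f <- withr::local_tempfile(fileext = ".mtx")
  write_incidence_mm(b, "s_wet", f)
  Z <- as.matrix(Matrix::readMM(f)) * 1   # pattern file reads as logical
  expect_equal(Z, unname(b$random[[4]]$Z))
  expect_error(write_incidence_mm(b, "nope", f), "no term")
})

test_that("record order does not change the fitted likelihood", {
  cfg <- small_grain_config(seed = 4, n_lines = 8, rows_per_bed = 10,
                            n_markers = 60)
  ds <- simulate_trait(cfg)
  vcs <- c(g = .3, l = .3, r = .2, s_wet = .05, s_dry = .05, e = 1)
  b <- assemble_model("GM1", ds$records, ds$layout, ds$G)
  perm <- semifieldgp:::with_seed(1, sample(nrow(ds$records)))
  bp <- assemble_model("GM1", ds$records[perm, ], ds$layout, ds$G)
  expect_equal(reml_loglik(b, vcs), reml_loglik(bp, vcs), tolerance = 1e-9)
})
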