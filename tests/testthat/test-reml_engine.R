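test_that("likelihood matches the balanced one-way closed form", {
  b <- one_way_bundle(a = 8, k = 4, s2b = 3, s2e = 1.5, seed = 2)
  grp <- b$meta$line
  for (v in list(c(b = 1, e = 1), c(b = 4.2, e = 0.7), c(b = 0.01, e = 3))) {
    expect_equal(reml_loglik(b, v),
                 one_way_loglik_closed_form(b$y, grp, 4, v[["b"]], v[["e"]]),
                 tolerance = 1e-10)
  }
})

test_that("MME and direct V-based evaluations agree on a mixed toy", {
  cfg <- small_grain_config(seed = 8, n_lines = 6, rows_per_bed = 8,
                            n_markers = 50)
  ds <- simulate_trait(cfg)
  recs <- ds$records[1:30, ]
  b <- assemble_model("GM2", recs, ds$layout, ds$G)
  vcs <- c(g = .4, l = .3, g_n = .05, l_n = .05, r = .2,
           s_wet = .04, s_dry = .08, e = 1.2)
  expect_equal(reml_loglik(b, vcs, "mme"), reml_loglik(b, vcs, "direct"),
               tolerance = 1e-8)
})

test_that("zero-variance limit reduces to the OLS residual likelihood", {
  b <- one_way_bundle(a = 6, k = 3, seed = 5)
  n <- length(b$y); p <- 1
  tiny <- 1e-12
  for (s2e in c(0.5, 2)) {
    ll <- reml_loglik(b, c(b = tiny, e = s2e))
    rss <- sum((b$y - mean(b$y))^2)
    ols <- -0.5 * ((n - p) * log(2 * pi) + (n - p) * log(s2e) + log(n) +
                     rss / s2e)
    expect_equal(ll, ols, tolerance = 1e-6)
  }
})

test_that("AI-REML matches the one-way ANOVA closed form", {
  b <- one_way_bundle(a = 10, k = 5, s2b = 4, s2e = 1, seed = 3)
  fit <- reml_fit(b)
  cf <- one_way_reml_closed_form(b$y, b$meta$line, 5)
  expect_true(fit$converged)
  expect_equal(unname(fit$vcs["b"]), unname(cf["b"]), tolerance = 1e-6)
  expect_equal(unname(fit$vcs["e"]), unname(cf["e"]), tolerance = 1e-6)
  expect_true(all(diff(fit$trajectory) > -1e-8))   # likelihood ascent
})

test_that("constant response drives all non-residual components to the floor", {
  b <- one_way_bundle(a = 5, k = 3, seed = 1)
  b$y <- rep(7, length(b$y)) + rnorm(length(b$y), 0, 1e-8)
  fit <- reml_fit(b)
  expect_lt(fit$vcs[["b"]], 1e-10)
})

test_that("BLUPs satisfy the single-term GBLUP closed form", {
  sim <- simulate_markers(5, 40, seed = 13)
  G <- vanraden_G(impute_and_filter(sim))
  n <- 15
  lines <- rep(G$line_ids, 3)
  Z <- 1 * outer(lines, G$line_ids, "==")
  colnames(Z) <- G$line_ids
  y <- semifieldgp:::with_seed(14, rnorm(n, 10, 1))
  bundle <- structure(list(
    y = y, X = matrix(1, n, 1, dimnames = list(NULL, "mu")),
    random = list(list(label = "g", Z = Z, K = G$G, ids = G$line_ids)),
    meta = data.frame(line = lines, area = "all", row = lines, bed = "B",
                      position = 1),
    spec = list(name = "toy", kind = "grain"), g_bar = G$mean_diagonal),
    class = "model_bundle")
  s2g <- 0.8; s2e <- 1.1
  sol <- blup_solve(bundle, c(g = s2g, e = s2e))
  V <- s2g * Z %*% G$G %*% t(Z) + diag(s2e, n)
  Vi <- solve(V)
  X <- bundle$X
  bhat <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  ghat <- s2g * G$G %*% t(Z) %*% Vi %*% (y - X %*% bhat)
  expect_equal(unname(sol$blups$g), as.numeric(ghat), tolerance = 1e-8)
  expect_equal(unname(sol$blues), as.numeric(bhat), tolerance = 1e-8)

  # sigma2_g -> 0: BLUPs vanish
  sol0 <- blup_solve(bundle, c(g = 1e-12, e = s2e))
  expect_lt(max(abs(sol0$blups$g)), 1e-8)

  # translation invariance: +c moves only the fixed effect
  bundle2 <- bundle; bundle2$y <- y + 5
  sol2 <- blup_solve(bundle2, c(g = s2g, e = s2e))
  expect_equal(sol2$blups$g, sol$blups$g, tolerance = 1e-8)
  expect_equal(unname(sol2$blues), unname(sol$blues) + 5, tolerance = 1e-8)
})

test_that("scaling y by c scales all variances by c^2", {
  cfg <- small_grain_config(seed = 12, n_lines = 8, rows_per_bed = 10,
                            n_markers = 60)
  ds <- simulate_trait(cfg)
  b <- assemble_model("GM1", ds$records, ds$layout, ds$G)
  fit1 <- reml_fit(b)
  b2 <- b; b2$y <- 3 * b$y
  fit2 <- reml_fit(b2)
  expect_equal(fit2$vcs, 9 * fit1$vcs, tolerance = 1e-3)
})

test_that("identity-G makes g and l exchangeable and gets flagged", {
  n_lines <- 6
  lines <- sprintf("L%d", 1:n_lines)
  Gid <- structure(list(G = diag(n_lines), mean_diagonal = 1,
                        line_ids = lines, denominator = 1),
                   class = "genomic_relationship")
  ly <- build_layout(data.frame(bed = "B1", row = 1:12,
                                line = rep(lines, 2)))
  recs <- do.call(rbind, lapply(c("wet", "dry"), function(a)
    data.frame(bed = "B1", row = 1:12, area = a, line = rep(lines, 2))))
  recs$value <- semifieldgp:::with_seed(3, rnorm(24, 10, 1))
  b <- assemble_model("GM1", recs, ly, Gid)
  expect_warning(fit <- reml_fit(b), "confounded")
  expect_true(any(grepl("g~l", fit$confounded)))
})

test_that("variance-component SEs follow the asymptotic closed form", {
  b <- one_way_bundle(a = 40, k = 8, s2b = 2, s2e = 1, seed = 6)
  fit <- reml_fit(b)
  ses <- vc_standard_errors(fit)
  # within-stratum df: a(k-1); SE(s2e) ~ sqrt(2 s2e^2 / (a(k-1)))
  closed <- sqrt(2 * fit$vcs[["e"]]^2 / (40 * 7))
  expect_equal(ses[["e"]], closed, tolerance = 0.1)
  # delta method with identity function reproduces the direct SE
  d <- vc_standard_errors(fit, function(v) v[["b"]])
  expect_equal(d$se, ses[["b"]], tolerance = 1e-6)
  expect_equal(d$value, fit$vcs[["b"]])
})

test_that("Wald intervals for the genetic variance have near-nominal coverage", {
  # one-way random-group design at 200 groups: the asymptotic regime the
  # AI-matrix SEs are meant for; 100 replicates, truth s2b = 2
  hits <- 0L
  for (r in 1:100) {
    b <- one_way_bundle(a = 200, k = 3, s2b = 2, s2e = 1, seed = 1000 + r)
    fit <- reml_fit(b)
    se <- vc_standard_errors(fit)[["b"]]
    hits <- hits + (abs(fit$vcs[["b"]] - 2) <= 1.96 * se)
  }
  expect_gte(hits, 88)
})
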