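# Shared fixture builders. Everything is generated in code at test time.

# a small grain world: cheap enough for repeated REML fits
small_grain_config <- function(seed, n_lines = 12, beds = 2, rows_per_bed = 20,
                               n_markers = 120, variances = NULL,
                               n_founders = 16) {
  sim_config(trait_kind = "grain", n_lines = n_lines, n_markers = n_markers,
             beds = beds, rows_per_bed = rows_per_bed,
             variances = variances, n_founders = n_founders, seed = seed)
}

# balanced one-way bundle: a groups x k reps, intercept-only fixed design
one_way_bundle <- function(a = 10, k = 5, s2b = 4, s2e = 1, seed = 1) {
  with_seed <- semifieldgp:::with_seed
  with_seed(seed, {
    grp <- rep(sprintf("g%02d", seq_len(a)), each = k)
    y <- 10 + rep(rnorm(a, 0, sqrt(s2b)), each = k) + rnorm(a * k, 0, sqrt(s2e))
    lv <- sort(unique(grp))
    Z <- 1 * outer(grp, lv, "==")
    colnames(Z) <- lv
    structure(list(
      y = y, X = matrix(1, a * k, 1, dimnames = list(NULL, "mu")),
      random = list(list(label = "b", Z = Z, K = NULL, ids = lv)),
      meta = data.frame(line = grp, area = "all", row = grp, bed = "B",
                        position = seq_len(a * k)),
      spec = list(name = "oneway", kind = "grain"), g_bar = 1),
      class = "model_bundle")
  })
}

# closed-form REML for the balanced one-way design (independent oracle)
one_way_reml_closed_form <- function(y, grp, k) {
  a <- length(unique(grp))
  gm <- tapply(y, grp, mean)
  MSB <- k * var(gm)
  MSW <- sum((y - ave(y, grp))^2) / (a * (k - 1))
  c(b = (MSB - MSW) / k, e = MSW)
}

# closed-form REML log-likelihood for the balanced one-way design with
# intercept-only X (textbook decomposition into between/within strata)
one_way_loglik_closed_form <- function(y, grp, k, s2b, s2e) {
  a <- length(unique(grp))
  n <- a * k
  lam <- s2e + k * s2b
  gm <- tapply(y, grp, mean)
  SSW <- sum((y - ave(y, grp))^2)
  SSB <- k * sum((gm - mean(y))^2)
  logdetV <- a * ((k - 1) * log(s2e) + log(lam))
  logdetXVX <- log(n / lam)
  yPy <- SSW / s2e + SSB / lam
  -0.5 * ((n - 1) * log(2 * pi) + logdetV + logdetXVX + yPy)
}
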