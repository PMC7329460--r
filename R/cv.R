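#' Corrected phenotypes from a full-data fit
#'
#' Subtracts the estimated fixed effects from every record
#' (`y_c = y - X b_hat`) and averages per line, pooling a line's records
#' over all harvest areas.
#'
#' @param full_fit a [reml_fit()] (or [blup_solve()]) result on `bundle`.
#' @param bundle the [assemble_model()] result the fit came from.
#' @return List with `records` (data frame `line`, `y_c`) and `line_means`
#'   (named vector of per-line averages).
#' @export
correct_phenotypes <- function(full_fit, bundle) {
  blues <- full_fit$blues
  if (length(blues) != ncol(bundle$X))
    stop_domain("fit and bundle fixed designs disagree")
  yc <- bundle$y - as.numeric(bundle$X %*% blues)
  means <- tapply(yc, bundle$meta$line, mean)
  list(records = data.frame(line = bundle$meta$line, y_c = yc),
       line_means = stats::setNames(as.numeric(means), names(means)))
}

#' Leave-one-line-out genomic prediction
#'
#' For each line in turn, all of its records are removed, the model is
#' refitted on the remaining records, and the held-out line's genomic value
#' is predicted through the G matrix (its incidence columns are empty, but
#' the eigen-parameterisation propagates information from relatives).
#' Neighbor and spatial incidences of the retained records are unchanged:
#' the held-out line still appears as a neighbor level.
#'
#' @param records trait records (see [assemble_model()]).
#' @param layout a [build_layout()] result.
#' @param G a `genomic_relationship` covering every line.
#' @param spec a [model_spec()] or preset name.
#' @param reestimate_vcs re-estimate variance components in every fold
#'   (default `TRUE`, warm-started from the full-data estimates); when
#'   `FALSE` the full-data components are plugged in and each fold is a
#'   single mixed-model solve.
#' @param full_fit optional precomputed full-data [reml_fit()], reused for
#'   warm starts / plug-in components.
#' @param max_iter per-fold REML iteration cap.
#' @return Data frame `line`, `gebv`, `converged` (one row per line with
#'   records), with the full-data fit attached as attribute `full_fit`.
#' @export
loo_cv_gebv <- function(records, layout, G, spec, reestimate_vcs = TRUE,
                        full_fit = NULL, max_iter = 100L) {
  if (is.character(spec)) spec <- model_spec(spec)
  records <- as.data.frame(records)
  records <- records[!is.na(records$value), , drop = FALSE]
  if (is.null(full_fit)) {
    bundle <- assemble_model(spec, records, layout, G)
    full_fit <- reml_fit(bundle, max_iter = max_iter)
  }
  lines <- sort(unique(as.character(records$line)))
  out <- data.frame(line = lines, gebv = NA_real_, converged = NA)
  if (reestimate_vcs) {
    for (i in seq_along(lines)) {
      keep <- records$line != lines[i]
      fold <- assemble_model(spec, records[keep, , drop = FALSE], layout, G)
      fit <- reml_fit(fold, init = full_fit$vcs, max_iter = max_iter)
      out$gebv[i] <- fit$blups$g[[lines[i]]]
      out$converged[i] <- fit$converged
    }
  } else {
    # plug-in components: each fold is one mixed-model solve; removing a
    # line's records is a rank-k downdate of the full normal equations,
    # so nothing is reassembled per fold
    bundle <- assemble_model(spec, records, layout, G)
    eng <- prepare_engine(bundle)
    theta <- theta_from_vcs(eng, full_fit$vcs)
    gk <- match("g", eng$labels)
    gix <- eng$starts[gk]:eng$ends[gk]
    Lg <- eng$terms[[gk]]$L
    gids <- eng$terms[[gk]]$ids
    for (i in seq_along(lines)) {
      rows_i <- which(bundle$meta$line == lines[i])
      Wi <- eng$W[rows_i, , drop = FALSE]
      yi <- eng$y[rows_i]
      sub <- eng
      sub$WtW <- eng$WtW - crossprod(Wi)
      sub$Wty <- eng$Wty - as.numeric(crossprod(Wi, yi))
      sub$yty <- eng$yty - sum(yi^2)
      sub$n <- eng$n - length(rows_i)
      a_g <- engine_eval(sub, theta)$sol[gix]
      g_all <- if (is.null(Lg)) a_g else as.numeric(Lg %*% a_g)
      out$gebv[i] <- g_all[match(lines[i], gids)]
      out$converged[i] <- TRUE
    }
  }
  attr(out, "full_fit") <- full_fit
  out
}

#' Prediction accuracy on the true-breeding-value scale
#'
#' `ACC = sign(cor) * sqrt(cor(ybar_c, gebv)^2 / h2)`: the correlation
#' between corrected phenotypic line means and GEBVs, scaled by the square
#' root of the line-mean heritability, estimating the correlation between
#' GEBVs and true breeding values for lines without own records. Values
#' above 1 are reported with a warning, never clipped.
#'
#' @param ybar_c named per-line corrected means (see [correct_phenotypes()]).
#' @param gebv named per-line GEBVs (see [loo_cv_gebv()]).
#' @param h2_used line-mean heritability entering the scaling (> 0).
#' @return List `acc`, `cor`, `h2_used`.
#' @export
prediction_accuracy <- function(ybar_c, gebv, h2_used) {
  common <- intersect(names(ybar_c), names(gebv))
  if (length(common) < 3L) stop_domain("need >= 3 lines with both values")
  if (!is.numeric(h2_used) || h2_used <= 0) stop_domain("h2_used must be > 0")
  a <- ybar_c[common]; b <- gebv[common]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop_domain("zero variance: accuracy undefined")
  r <- stats::cor(a, b)
  acc <- sign(r) * sqrt(r^2 / h2_used)
  if (abs(acc) > 1)
    warning(sprintf("ACC %.3f exceeds 1 (cor %.3f, h2 %.3f)", acc, r, h2_used))
  list(acc = acc, cor = r, h2_used = h2_used)
}

#' Inflation of genomic predictions
#'
#' Ordinary least-squares regression of corrected line means on GEBVs (with
#' intercept). A slope of 1 means no inflation; the two-sided t-test is
#' against that value.
#'
#' @param ybar_c named per-line corrected means.
#' @param gebv named per-line GEBVs.
#' @return List `slope`, `se`, `t_vs_1`, `p`, `n`.
#' @export
prediction_inflation <- function(ybar_c, gebv) {
  common <- intersect(names(ybar_c), names(gebv))
  if (length(common) < 3L) stop_domain("need >= 3 lines")
  g <- gebv[common]
  if (stats::var(g) == 0) stop_domain("degenerate regressor: slope undefined")
  fit <- stats::lm(ybar_c[common] ~ g)
  sm <- summary(fit)$coefficients
  slope <- sm["g", "Estimate"]
  se <- sm["g", "Std. Error"]
  tval <- (slope - 1) / se
  df <- length(common) - 2L
  list(slope = slope, se = se, t_vs_1 = tval,
       p = 2 * stats::pt(-abs(tval), df), n = length(common))
}
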