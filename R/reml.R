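# Mixed-model engine.
#
# Every random term u_k ~ N(0, K_k sigma2_k) is reparameterised as
# u_k = L_k a_k with K_k = L_k L_k' (symmetric eigendecomposition, near-zero
# eigenvalues dropped), so the working model only carries identity-structured
# effects a_k with transformed incidence Z_k L_k. This handles singular G
# matrices (VanRaden G with observed frequencies always has a zero
# eigenvalue) without ridge inflation, and BLUPs map back as u_hat = L a_hat,
# which also yields genomic predictions for lines with no records.
#
# REML quantities come from the mixed-model equations in residual scaling:
#   C = W'W / sigma2_e + diag(0_p, I/sigma2_k), W = [X, Z*_1, ..., Z*_K]
#   log|V| + log|X'V^-1 X| = n log sigma2_e + sum_k r_k log sigma2_k + log|C|
#   y'Py = y'y/sigma2_e - s' W'y/sigma2_e,  s = C^-1 W'y/sigma2_e
# and C^-1 supplies the trace terms of the REML scores and the EM updates.

prepare_engine <- function(bundle) {
  stopifnot(inherits(bundle, "model_bundle"))
  y <- bundle$y
  X <- bundle$X
  n <- length(y)
  p <- ncol(X)
  if (n <= p) stop_domain("more fixed-effect columns than records")
  terms <- lapply(bundle$random, function(b) {
    if (is.null(b$K)) {
      list(label = b$label, Zt = b$Z, L = NULL, r = ncol(b$Z), ids = b$ids)
    } else {
      K <- (b$K + t(b$K)) / 2
      eig <- eigen(K, symmetric = TRUE)
      if (min(eig$values) < -1e-8 * sum(diag(K)))
        stop_domain("covariance for term '", b$label,
                    "' is not positive semi-definite")
      keep <- eig$values > max(eig$values) * 1e-10
      L <- eig$vectors[, keep, drop = FALSE] %*%
        diag(sqrt(eig$values[keep]), sum(keep))
      list(label = b$label, Zt = b$Z %*% L, L = L, r = sum(keep), ids = b$ids)
    }
  })
  labels <- vapply(terms, `[[`, "", "label")
  # exchangeable-term diagnostic: identical incidence and identical (or both
  # identity) covariance means only the sum of the two terms is identified
  confounded <- character(0)
  ident_like <- vapply(bundle$random, function(b) {
    is.null(b$K) || (nrow(b$K) == ncol(b$K) &&
                       max(abs(b$K - diag(nrow(b$K)))) < 1e-8)
  }, logical(1))
  nb <- length(bundle$random)
  if (nb > 1L) for (i in seq_len(nb - 1L)) for (j in (i + 1L):nb) {
    bi <- bundle$random[[i]]; bj <- bundle$random[[j]]
    if (ident_like[i] && ident_like[j] &&
        all(dim(bi$Z) == dim(bj$Z)) && max(abs(bi$Z - bj$Z)) == 0)
      confounded <- c(confounded, paste(bi$label, bj$label, sep = "~"))
  }
  W <- do.call(cbind, c(list(X), lapply(terms, `[[`, "Zt")))
  r_k <- vapply(terms, `[[`, 0L, "r")
  ends <- p + cumsum(r_k)
  starts <- c(p + 1L, utils::head(ends, -1L) + 1L)
  list(y = y, X = X, n = n, p = p, W = W, WtW = crossprod(W),
       Wty = crossprod(W, y)[, 1L], yty = sum(y * y), terms = terms,
       labels = labels, r_k = r_k, starts = starts, ends = ends,
       confounded = confounded)
}

chol_solve <- function(ch, b) backsolve(ch, backsolve(ch, b, transpose = TRUE))

# One REML evaluation at theta = (sigma2_1..sigma2_K, sigma2_e).
# `derivs` additionally returns C^-1-based scores, EM updates and AI matrix.
# For speed the factorisation works on B = sigma2_e * C = W'W + sigma2_e *
# diag(0_p, I/sigma2_k): one matrix copy per evaluation, with the sigma2_e
# scaling folded into the scalar formulas.
engine_eval <- function(eng, theta, derivs = FALSE) {
  K <- length(eng$r_k)
  sk <- theta[seq_len(K)]
  se <- theta[K + 1L]
  m <- nrow(eng$WtW)
  dpen <- c(rep(0, eng$p), rep(se / sk, times = eng$r_k))
  B <- eng$WtW
  dpos <- seq_len(m) + (seq_len(m) - 1L) * m
  B[dpos] <- B[dpos] + dpen
  ch <- tryCatch(chol(B), error = function(e) {
    B[dpos] <- B[dpos] + max(B[dpos]) * 1e-10
    chol(B)
  })
  s <- chol_solve(ch, eng$Wty)                 # = C^-1 W'y / sigma2_e
  yPy <- (eng$yty - sum(s * eng$Wty)) / se
  logdetC <- 2 * sum(log(diag(ch))) - m * log(se)
  ll <- -0.5 * ((eng$n - eng$p) * log(2 * pi) + eng$n * log(se) +
                  sum(eng$r_k * log(sk)) + logdetC + yPy)
  out <- list(loglik = ll, sol = s, yPy = yPy)
  if (!derivs) return(out)
  Binv <- chol2inv(ch)                          # C^-1 = sigma2_e * Binv
  dBinv <- Binv[dpos]
  e <- eng$y - as.numeric(eng$W %*% s)
  uu <- Tk <- numeric(K)
  for (k in seq_len(K)) {
    ix <- eng$starts[k]:eng$ends[k]
    uu[k] <- sum(s[ix]^2)
    Tk[k] <- se * sum(dBinv[ix])
  }
  trPZ <- (eng$r_k - Tk / sk) / sk          # tr(P Z_k K_k Z_k')
  trP <- (eng$n - eng$p - sum(eng$r_k - Tk / sk)) / se
  score <- c(-0.5 * (trPZ - uu / sk^2),
             -0.5 * (trP - sum(e^2) / se^2))
  # average information: f_i = dV/dtheta_i P y, AI_ij = f_i' P f_j / 2
  Fm <- matrix(0, eng$n, K + 1L)
  for (k in seq_len(K)) {
    ix <- eng$starts[k]:eng$ends[k]
    Fm[, k] <- eng$W[, ix, drop = FALSE] %*% s[ix] / sk[k]
  }
  Fm[, K + 1L] <- e / se
  PF <- (Fm - eng$W %*% (Binv %*% crossprod(eng$W, Fm))) / se
  AI <- crossprod(Fm, PF) / 2
  AI <- (AI + t(AI)) / 2
  em <- c((uu + Tk) / eng$r_k,                       # EM update sigma2_k
          (eng$yty - sum(s * eng$Wty)) / (eng$n - eng$p))  # EM sigma2_e
  c(out, list(e = e, uu = uu, Tk = Tk, score = score, AI = AI, em = em))
}

theta_from_vcs <- function(eng, vcs) {
  need <- c(eng$labels, "e")
  if (!all(need %in% names(vcs)))
    stop_domain("variance components must be named: ",
                paste(need, collapse = ", "))
  theta <- as.numeric(vcs[need])
  if (any(theta < 0) || theta[length(theta)] <= 0)
    stop_domain("variances must be >= 0 with residual > 0")
  theta
}

#' REML log-likelihood of a model at given variance components
#'
#' The criterion is `-[log|V| + log|X'V^-1 X| + y'Py]/2` minus the usual
#' `(n-p) log(2*pi)/2` constant, with `V = sum_k sigma2_k Z_k K_k Z_k' +
#' sigma2_e I`. Two independent routes are implemented: `"mme"` evaluates it
#' through the mixed-model equations (the production path), `"direct"`
#' builds the n x n covariance `V` explicitly (an oracle for testing; O(n^3)
#' in the number of records).
#'
#' @param bundle a [assemble_model()] result.
#' @param vcs named numeric vector of variance components: one entry per
#'   random-term label plus `"e"` for the residual.
#' @param method `"mme"` or `"direct"`.
#' @return Scalar log-likelihood.
#' @export
reml_loglik <- function(bundle, vcs, method = c("mme", "direct")) {
  method <- match.arg(method)
  if (method == "mme") {
    eng <- prepare_engine(bundle)
    return(engine_eval(eng, theta_from_vcs(eng, vcs))$loglik)
  }
  y <- bundle$y; X <- bundle$X
  n <- length(y); p <- ncol(X)
  se <- as.numeric(vcs[["e"]])
  V <- diag(se, n)
  for (b in bundle$random) {
    sk <- as.numeric(vcs[[b$label]])
    Kz <- if (is.null(b$K)) tcrossprod(b$Z) else b$Z %*% b$K %*% t(b$Z)
    V <- V + sk * Kz
  }
  chV <- chol(V)
  Vi_y <- chol_solve(chV, y)
  Vi_X <- chol_solve(chV, X)
  M <- crossprod(X, Vi_X)
  chM <- chol(M)
  XVy <- crossprod(X, Vi_y)
  yPy <- sum(y * Vi_y) - sum(XVy * chol_solve(chM, XVy))
  -0.5 * ((n - p) * log(2 * pi) + 2 * sum(log(diag(chV))) +
            2 * sum(log(diag(chM))) + yPy)
}

#' Estimate variance components by AI-REML with EM fallback
#'
#' Average-information updates of all variance parameters, with step halving
#' and an EM-REML fallback whenever a quasi-Newton step would leave the
#' parameter space or decrease the restricted likelihood; accepted
#' iterations therefore never decrease the likelihood. Components hitting
#' the lower boundary are pinned at `boundary_eps * var(y)` and released
#' automatically if a later update points inward.
#'
#' @param bundle a [assemble_model()] result.
#' @param init optional named starting values (see [reml_loglik()] for
#'   naming); default is an equal split of `var(y)` across all components.
#' @param max_iter maximum iterations (default 100).
#' @param tol convergence tolerance on the likelihood change (default 1e-8);
#'   parameters must also be stable (`max |d theta|/(theta+1) < 1e-6`).
#' @param boundary_eps lower-boundary fraction of `var(y)` (default 1e-8).
#' @param verbose print the iteration trace.
#' @return An object of class `mixed_model_fit`: `vcs` (named variances),
#'   `blues`, `blups` (per term, full level set incl. lines without
#'   records), `loglik`, `ai_matrix`, `score`, `iterations`, `converged`,
#'   `trajectory`, `boundary`, `confounded`, `n`, `p`, `labels`.
#' @export
reml_fit <- function(bundle, init = NULL, max_iter = 100L, tol = 1e-8,
                     boundary_eps = 1e-8, verbose = FALSE) {
  eng <- prepare_engine(bundle)
  if (length(eng$confounded) > 0L)
    warning("confounded random terms (only their sum is identified): ",
            paste(eng$confounded, collapse = ", "))
  K <- length(eng$labels)
  vary <- stats::var(eng$y)
  floor_k <- boundary_eps * vary
  theta <- if (is.null(init)) rep(vary / (K + 1), K + 1L)
           else theta_from_vcs(eng, init)
  theta <- pmax(theta, floor_k)
  ev <- engine_eval(eng, theta, derivs = TRUE)
  traj <- ev$loglik
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    # active set: components pinned at the boundary with an outward-pointing
    # score are held there and excluded from the Newton system; they are
    # released as soon as their score points back inside
    pinned <- theta <= floor_k * (1 + 1e-10) & ev$score < 0
    free <- which(!pinned)
    step <- rep(0, K + 1L)
    stepf <- tryCatch(
      solve(ev$AI[free, free, drop = FALSE], ev$score[free]),
      error = function(e) NULL)
    accepted <- FALSE
    if (!is.null(stepf)) {
      step[free] <- stepf
      fac <- 1
      for (h in seq_len(8L)) {
        cand <- pmax(theta + fac * step, floor_k)
        cand[pinned] <- floor_k
        evc <- tryCatch(engine_eval(eng, cand),
                        error = function(e) NULL)
        if (!is.null(evc) && evc$loglik >= ev$loglik - 1e-12) {
          accepted <- TRUE; break
        }
        fac <- fac / 2
      }
    }
    if (!accepted) {   # EM-REML fallback step (monotone, always in-space)
      cand <- pmax(ev$em, floor_k)
      cand[pinned] <- floor_k
      evc <- engine_eval(eng, cand)
      if (evc$loglik < ev$loglik - 1e-8) {
        # numerically stuck: stop at the current point
        converged <- TRUE
        break
      }
    }
    evc <- engine_eval(eng, cand, derivs = TRUE)
    dll <- evc$loglik - ev$loglik
    dth <- max(abs(cand - theta) / (theta + 1))
    theta <- cand; ev <- evc
    traj <- c(traj, ev$loglik)
    if (verbose)
      message(sprintf("iter %2d  logL %.8f  dll %.2e  dtheta %.2e  %s",
                      iter, ev$loglik, dll, dth,
                      if (any(pinned)) paste0("pinned: ",
                        paste(which(pinned), collapse = ",")) else ""))
    if (abs(dll) < tol && dth < 1e-6) { converged <- TRUE; break }
  }
  names(theta) <- c(eng$labels, "e")
  sol <- ev$sol
  blues <- stats::setNames(sol[seq_len(eng$p)], colnames(eng$X))
  blups <- list()
  for (k in seq_len(K)) {
    a <- sol[eng$starts[k]:eng$ends[k]]
    tk <- eng$terms[[k]]
    u <- if (is.null(tk$L)) a else as.numeric(tk$L %*% a)
    blups[[tk$label]] <- stats::setNames(u, tk$ids)
  }
  ai <- ev$AI
  dimnames(ai) <- list(names(theta), names(theta))
  structure(list(vcs = theta, blues = blues, blups = blups,
                 loglik = ev$loglik, ai_matrix = ai,
                 score = stats::setNames(ev$score, names(theta)),
                 iterations = iter, converged = converged, trajectory = traj,
                 boundary = stats::setNames(theta <= floor_k * (1 + 1e-12),
                                            names(theta)),
                 confounded = eng$confounded, n = eng$n, p = eng$p,
                 labels = eng$labels),
            class = "mixed_model_fit")
}

#' @export
print.mixed_model_fit <- function(x, ...) {
  cat(sprintf("<mixed_model_fit> logL %.4f after %d iterations (%s)\n",
              x$loglik, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  print(round(x$vcs, 6))
  invisible(x)
}

#' Solve mixed-model equations at fixed variance components
#'
#' @param bundle a [assemble_model()] result.
#' @param vcs named variance components (see [reml_loglik()]).
#' @return List with `blues` and `blups` (per term, back-transformed to the
#'   original level set).
#' @export
blup_solve <- function(bundle, vcs) {
  eng <- prepare_engine(bundle)
  theta <- theta_from_vcs(eng, vcs)
  ev <- engine_eval(eng, theta)
  sol <- ev$sol
  blues <- stats::setNames(sol[seq_len(eng$p)], colnames(eng$X))
  blups <- list()
  for (k in seq_along(eng$terms)) {
    a <- sol[eng$starts[k]:eng$ends[k]]
    tk <- eng$terms[[k]]
    u <- if (is.null(tk$L)) a else as.numeric(tk$L %*% a)
    blups[[tk$label]] <- stats::setNames(u, tk$ids)
  }
  list(blues = blues, blups = blups)
}

#' Standard errors of variance components and smooth functions of them
#'
#' Uses the inverse average-information matrix as the asymptotic covariance
#' of the REML estimates. For a function of the components, the gradient is
#' taken by central differences (relative step 1e-6) and the delta method
#' applied.
#'
#' @param fit a [reml_fit()] result.
#' @param fun optional function of the named component vector returning a
#'   scalar; when given, the delta-method SE of `fun(vcs)` is returned.
#' @return Named vector of SEs, or a list `(value, se)` when `fun` is given.
#'   If the AI matrix is not invertible the SEs are `NA` with a warning.
#' @export
vc_standard_errors <- function(fit, fun = NULL) {
  stopifnot(inherits(fit, "mixed_model_fit"))
  V <- tryCatch(solve(fit$ai_matrix), error = function(e) NULL)
  if (is.null(V)) {
    warning("AI matrix not invertible; SEs undefined")
    if (is.null(fun)) return(stats::setNames(rep(NA_real_, length(fit$vcs)),
                                             names(fit$vcs)))
    return(list(value = fun(fit$vcs), se = NA_real_))
  }
  if (is.null(fun))
    return(stats::setNames(sqrt(pmax(diag(V), 0)), names(fit$vcs)))
  th <- fit$vcs
  g <- numeric(length(th))
  for (i in seq_along(th)) {
    h <- 1e-6 * (abs(th[i]) + 1e-12)
    up <- th; up[i] <- up[i] + h
    dn <- th; dn[i] <- dn[i] - h
    g[i] <- (fun(up) - fun(dn)) / (2 * h)
  }
  list(value = fun(th), se = sqrt(max(0, as.numeric(t(g) %*% V %*% g))))
}
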