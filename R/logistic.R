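# Internal Newton-Raphson engine for (weighted) logistic regression.
#
# All model fitting in the package funnels through this one routine: the
# available-data transition fits use unit weights, the EM M-step uses the
# fractional completion weights. Convergence follows the package contract:
# max |gradient| < tol_grad or relative log-likelihood change < tol_loglik,
# at most max_iter iterations, starting from the zero vector unless a
# warm start is supplied.

log1pexp <- function(x) {
  # numerically stable log(1 + exp(x))
  out <- x
  small <- x <= 18
  out[small] <- log1p(exp(x[small]))
  big <- x > 18 & x <= 33.3
  out[big] <- x[big] + exp(-x[big])
  out
}

bernoulli_loglik <- function(eta, y, w = NULL) {
  ll <- y * eta - log1pexp(eta)
  if (!is.null(w)) ll <- w * ll
  sum(ll)
}

#' @noRd
fit_wlogit <- function(X, y, w = NULL,
                       tol_grad = 1e-8, tol_loglik = 1e-10,
                       max_iter = 100L, start = NULL,
                       ridge_on_separation = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (is.null(w)) w <- rep(1, n)
  stopifnot(length(y) == n, length(w) == n, all(w >= 0))

  keep <- w > 0
  qrX <- qr(X[keep, , drop = FALSE] * sqrt(w[keep]))
  ridged <- FALSE
  if (qrX$rank < p) {
    if (!ridge_on_separation) {
      bad <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, p)]]
      stop("design matrix is rank deficient; offending column(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    ridged <- TRUE # degenerate expanded design: proceed with ridged steps
  }

  beta <- if (is.null(start)) rep(0, p) else as.numeric(start)
  eta <- drop(X %*% beta)
  ll <- bernoulli_loglik(eta, y, w)
  converged <- FALSE
  iter <- 0L

  while (iter < max_iter) {
    iter <- iter + 1L
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(X, w * (y - mu)))
    if (max(abs(grad)) < tol_grad) {
      converged <- TRUE
      break
    }
    wt <- w * mu * (1 - mu)
    H <- crossprod(X, X * wt)
    if (ridged) H <- H + diag(1e-4 * max(diag(H), 1), p)
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      if (!ridge_on_separation) {
        stop("logistic fit failed: information matrix is singular ",
             "(possible separation)", call. = FALSE)
      }
      ridged <- TRUE
      H <- H + diag(1e-4 * max(diag(H), 1), p)
      step <- solve(H, grad)
    }
    # step-halving safeguard: never accept a step that lowers the likelihood
    lam <- 1
    repeat {
      beta_new <- beta + lam * step
      eta_new <- drop(X %*% beta_new)
      ll_new <- bernoulli_loglik(eta_new, y, w)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-10) break
    }
    rel_change <- abs(ll_new - ll) / (abs(ll) + 1e-10)
    beta <- beta_new
    eta <- eta_new
    ll <- ll_new
    if (rel_change < tol_loglik) {
      converged <- TRUE
      break
    }
  }
  if (!converged && max(abs(beta)) > 30) {
    if (ridge_on_separation) {
      warning("possible separation: coefficients drifting to +/-Inf; ",
              "ridge-stabilised step used", call. = FALSE)
      ridged <- TRUE
    } else {
      stop("logistic fit did not converge; possible separation ",
           "(|coefficient| > 30)", call. = FALSE)
    }
  }

  mu <- stats::plogis(eta)
  H <- crossprod(X, X * (w * mu * (1 - mu)))
  if (ridged) H <- H + diag(1e-4 * max(diag(H), 1), p)
  vc <- tryCatch(solve(H), error = function(e) matrix(NA_real_, p, p))
  nm <- colnames(X)
  names(beta) <- nm
  dimnames(vc) <- list(nm, nm)
  list(coefficients = beta, vcov = vc, loglik = ll,
       n_obs = n, sum_weights = sum(w),
       converged = converged, iterations = iter, ridged = ridged)
}
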