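#' Fit the paired logistic transition models to available pairs
#'
#' Maximum likelihood for the two conditional logistic regressions of a
#' first-order two-state Markov chain: the abstinence submodel
#' `logit P(Y_t = 0 | Y_{t-1} = 1) = x' beta1` on pairs whose previous
#' state is smoking, and the relapse submodel
#' `logit P(Y_t = 1 | Y_{t-1} = 0) = x' beta0` on pairs whose previous
#' state is abstinent. The submodels share no parameters, so the joint
#' MLE is obtained by two independent Newton-Raphson fits; the reported
#' log-likelihood is their sum. Only consecutive pairs of observed
#' outcomes contribute (available-data analysis), and a pair missing a
#' covariate required by its submodel is dropped from that submodel only.
#'
#' @param data A `smoke_panel` (pairs are extracted with
#'   [extract_pairs()]) or a tibble of transition pairs.
#' @param spec A [model_spec()].
#' @return An object of class `transition_fit`: submodel coefficient
#'   vectors, model-based covariances (inverse observed information),
#'   the summed log-likelihood and pair counts. Supports `coef()`,
#'   `vcov()`, `logLik()`, [tidy()], [glance()] and `print()`.
#' @seealso [fit_em()] for the joint outcome/non-response fit,
#'   [odds_ratio()], [wald_test()], [bic()].
#' @export
fit_transition <- function(data, spec) {
  stopifnot(inherits(spec, "transition_spec"))
  pairs <- if (inherits(data, "smoke_panel")) extract_pairs(data) else
    tibble::as_tibble(data)
  if (nrow(pairs) == 0) stop("no transition pairs to fit", call. = FALSE)

  fit_sub <- function(rows, terms, response) {
    X <- build_design(rows, terms)
    ok <- stats::complete.cases(X)
    res <- fit_wlogit(X[ok, , drop = FALSE], response[ok])
    res$terms <- terms
    res$n_dropped <- sum(!ok)
    res
  }
  abst_rows <- pairs[pairs$y_prev == 1L, , drop = FALSE]
  rel_rows <- pairs[pairs$y_prev == 0L, , drop = FALSE]
  abst <- fit_sub(abst_rows, spec$abstinence, 1L - abst_rows$y_curr)
  rel <- if (nrow(rel_rows) > 0) {
    fit_sub(rel_rows, spec$relapse, rel_rows$y_curr)
  } else {
    NULL
  }

  n_used <- abst$n_obs - abst$n_dropped +
    if (is.null(rel)) 0L else rel$n_obs - rel$n_dropped
  structure(
    list(abstinence = abst, relapse = rel, spec = spec,
         loglik = abst$loglik + (rel$loglik %||% 0),
         n_pairs = n_used,
         converged = abst$converged && (rel$converged %||% TRUE)),
    class = "transition_fit"
  )
}

submodels <- function(fit) {
  Filter(Negate(is.null), fit[intersect(c("abstinence", "relapse", "missing"),
                                        names(fit))])
}

#' @export
coef.transition_fit <- function(object, ...) {
  subs <- submodels(object)
  unlist(lapply(names(subs), function(nm) {
    cf <- subs[[nm]]$coefficients
    stats::setNames(cf, paste(nm, names(cf), sep = ":"))
  }))
}

#' @export
vcov.transition_fit <- function(object, ...) {
  subs <- submodels(object)
  vcs <- lapply(subs, `[[`, "vcov")
  p <- vapply(vcs, nrow, 0L)
  V <- matrix(0, sum(p), sum(p))
  nm <- character(sum(p))
  at <- 0L
  for (i in seq_along(vcs)) {
    idx <- at + seq_len(p[i])
    V[idx, idx] <- vcs[[i]]
    nm[idx] <- paste(names(subs)[i], colnames(vcs[[i]]), sep = ":")
    at <- at + p[i]
  }
  dimnames(V) <- list(nm, nm)
  V
}

#' @export
logLik.transition_fit <- function(object, ...) {
  structure(object$loglik, df = length(coef(object)), class = "logLik")
}

#' @export
tidy.transition_fit <- function(x, ...) {
  subs <- submodels(x)
  purrr::map_dfr(names(subs), function(nm) {
    s <- subs[[nm]]
    est <- s$coefficients
    se <- sqrt(diag(s$vcov))
    z <- est / se
    tibble::tibble(
      model = nm, term = names(est), estimate = unname(est),
      std.error = unname(se), statistic = unname(z),
      p.value = 2 * stats::pnorm(-abs(unname(z))),
      or = exp(unname(est))
    )
  })
}

#' @export
glance.transition_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, n_pairs = x$n_pairs,
    n_params = length(coef(x)), BIC = bic(x),
    converged = x$converged
  )
}

#' @export
print.transition_fit <- function(x, digits = 3, ...) {
  cat("<transition_fit> paired logistic Markov transition model\n")
  cat("  pairs used:", x$n_pairs,
      "| logLik:", format(x$loglik, digits = 7),
      "| converged:", x$converged, "\n\n")
  td <- tidy(x)
  for (m in unique(td$model)) {
    cat(switch(m,
               abstinence = "Abstinence model  P(quit | smoking):",
               relapse = "Relapse model  P(smoke | abstinent):",
               missing = "Missing model  P(respond):"), "\n")
    sub <- as.data.frame(td[td$model == m,
                            c("term", "estimate", "std.error", "p.value")])
    sub[-1] <- lapply(sub[-1], round, digits)
    print(sub, row.names = FALSE)
    cat("\n")
  }
  invisible(x)
}

#' Odds ratio for a linear combination of coefficients
#'
#' Computes `exp(c' beta)` for a named contrast over the fitted
#' coefficients, with a delta-method standard error on the log scale and
#' a Wald p-value. A single coefficient's OR is the special case of a
#' unit contrast; comparing two arms uses e.g. `c(HDM = 1, MDM = -1)`.
#'
#' @param fit A `transition_fit` or `em_fit`.
#' @param contrast Named numeric vector. With `model` given, names are
#'   submodel terms (e.g. `"HDM"`); otherwise fully qualified
#'   `"model:term"` names.
#' @param model Optional submodel name (`"abstinence"`, `"relapse"`,
#'   `"missing"`).
#' @return One-row tibble: `contrast`, `log_or`, `or`, `std.error` (of
#'   the log OR), `p.value`.
#' @export
#' @examples
#' # a coefficient of 0.392 corresponds to OR = 1.48
odds_ratio <- function(fit, contrast, model = NULL) {
  if (!is.null(model)) {
    names(contrast) <- paste(model, names(contrast), sep = ":")
  }
  cf <- coef(fit)
  unknown <- setdiff(names(contrast), names(cf))
  if (length(unknown)) {
    stop("unknown coefficient name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cvec <- stats::setNames(rep(0, length(cf)), names(cf))
  cvec[names(contrast)] <- contrast
  lo <- sum(cvec * cf)
  V <- vcov(fit)
  se <- sqrt(drop(t(cvec) %*% V %*% cvec))
  tibble::tibble(
    contrast = paste(names(contrast), "*", unname(contrast), collapse = " + "),
    log_or = lo, or = exp(lo), std.error = se,
    p.value = if (is.finite(se) && se > 0) 2 * stats::pnorm(-abs(lo / se))
              else NA_real_
  )
}

#' Wald tests of coefficient contrasts
#'
#' A single-row contrast gives a z test with a two-sided normal p-value.
#' A multi-row contrast matrix gives the quadratic-form F statistic
#' `(C b)' (C V C')^{-1} (C b) / rank(C)` with numerator df `rank(C)`
#' and, by convention, denominator df equal to the number of transition
#' pairs in the combined fit (the convention used by mixed-procedure
#' software for this model); the asymptotic chi-square p-value is also
#' reported.
#'
#' @param fit A `transition_fit` or `em_fit`.
#' @param contrast Named numeric vector (one row) or a matrix whose
#'   column names are coefficient names (`"model:term"`, or submodel
#'   terms when `model` is given).
#' @param model Optional submodel name qualifying the contrast names.
#' @return One-row tibble: `type`, `statistic`, `df_num`, `df_den`,
#'   `p.value` and (for F tests) `p.chisq`.
#' @export
wald_test <- function(fit, contrast, model = NULL) {
  if (is.null(dim(contrast))) {
    contrast <- matrix(contrast, nrow = 1,
                       dimnames = list(NULL, names(contrast)))
  }
  if (!is.null(model)) {
    colnames(contrast) <- paste(model, colnames(contrast), sep = ":")
  }
  cf <- coef(fit)
  unknown <- setdiff(colnames(contrast), names(cf))
  if (length(unknown)) {
    stop("unknown coefficient name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  C <- matrix(0, nrow(contrast), length(cf),
              dimnames = list(NULL, names(cf)))
  C[, colnames(contrast)] <- contrast
  if (qr(C)$rank < nrow(C)) {
    stop("contrast matrix is rank deficient", call. = FALSE)
  }
  V <- vcov(fit)
  Cb <- drop(C %*% cf)
  if (nrow(C) == 1L) {
    se <- sqrt(drop(C %*% V %*% t(C)))
    z <- Cb / se
    return(tibble::tibble(type = "Wald-z", statistic = z,
                          df_num = 1L, df_den = Inf,
                          p.value = 2 * stats::pnorm(-abs(z))))
  }
  q <- nrow(C)
  Fstat <- drop(t(Cb) %*% solve(C %*% V %*% t(C), Cb)) / q
  df_den <- fit$n_pairs
  tibble::tibble(
    type = "Wald-F", statistic = Fstat, df_num = q, df_den = df_den,
    p.value = stats::pf(Fstat, q, df_den, lower.tail = FALSE),
    p.chisq = stats::pchisq(q * Fstat, q, lower.tail = FALSE)
  )
}

#' Bayesian Information Criterion for a transition fit
#'
#' `-2 logLik + p log(n)` with `p` the total coefficient count across
#' submodels and `n`, by default, the number of transition pairs used in
#' the fit (the analysis units of the conditional likelihood); pass `n`
#' explicitly to use e.g. the subject count instead. Lower is better.
#'
#' @param fit A `transition_fit` or `em_fit`.
#' @param n Sample size for the penalty; defaults to the pair count.
#' @return Scalar BIC.
#' @export
bic <- function(fit, n = NULL) {
  n <- n %||% fit$n_pairs
  -2 * fit$loglik + length(coef(fit)) * log(n)
}

#' Rank candidate model specifications by BIC
#'
#' Fits each candidate spec to the same panel with [fit_transition()]
#' and ranks by [bic()].
#'
#' @param panel A `smoke_panel`.
#' @param specs Named list of [model_spec()] objects.
#' @return A tibble sorted by BIC (best first).
#' @export
compare_bic <- function(panel, specs) {
  stopifnot(is.list(specs), length(specs) > 0)
  if (is.null(names(specs))) names(specs) <- paste0("spec", seq_along(specs))
  purrr::map_dfr(names(specs), function(nm) {
    f <- fit_transition(panel, specs[[nm]])
    tibble::tibble(spec = nm, logLik = f$loglik,
                   n_params = length(coef(f)), BIC = bic(f))
  }) |>
    dplyr::arrange(.data$BIC)
}
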