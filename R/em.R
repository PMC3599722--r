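# Joint selection model for the transition process and non-response,
# estimated by EM with full enumeration of missing-outcome completions.
# With T follow-ups a subject has at most 2^T completions (16 when T = 4),
# so the E-step is exact.

theta_names <- function(spec) {
  list(abstinence = c("(Intercept)", spec$abstinence),
       relapse = c("(Intercept)", spec$relapse),
       missing = c("(Intercept)", spec$missing))
}

check_theta <- function(theta, spec) {
  nm <- theta_names(spec)
  for (m in names(nm)) {
    if (is.null(theta[[m]]) || !setequal(names(theta[[m]]), nm[[m]])) {
      stop("theta$", m, " must be a named vector over: ",
           paste(nm[[m]], collapse = ", "), call. = FALSE)
    }
    theta[[m]] <- theta[[m]][nm[[m]]]
  }
  theta
}

#' Complete-data log-likelihood of one subject
#'
#' The log of the subject's contribution to the complete-data likelihood:
#' for each follow-up occasion, a Bernoulli term for the response
#' indicator under the non-response logit (evaluated at the completed
#' outcomes) plus the log transition probability of the move from the
#' previous to the current state. An event with probability zero under
#' `theta` yields `-Inf`.
#'
#' @param y Completed outcome vector of length `T + 1` (no `NA`;
#'   `y[1] = 1`, the baseline smoking status).
#' @param r Response indicator vector for the follow-ups, length `T`
#'   (baseline response is 1 by design and not included).
#' @param covariates Named numeric vector (or single-row data frame) of
#'   the subject's baseline covariates.
#' @param theta List with named coefficient vectors `abstinence`,
#'   `relapse`, `missing` (each including `"(Intercept)"`).
#' @param spec A [model_spec()].
#' @return Scalar log-likelihood.
#' @export
complete_data_loglik <- function(y, r, covariates, theta, spec) {
  stopifnot(!anyNA(y), y[1] == 1, length(r) == length(y) - 1L,
            all(y %in% 0:1), all(r %in% 0:1))
  theta <- check_theta(theta, spec)
  Tn <- length(r)
  cov_df <- if (length(covariates)) {
    as.data.frame(as.list(covariates))
  } else {
    data.frame(row.names = 1L)
  }
  bern <- function(eta, z) if (z == 1) -log1pexp(-eta) else -log1pexp(eta)
  ll <- 0
  for (t in seq_len(Tn)) {
    row <- cov_df
    row$time <- t
    row$r_prev <- if (t == 1) 1 else r[t - 1]
    row$y_prev <- y[t]
    row$y_curr <- y[t + 1]
    # response term
    xm <- build_design(row, spec$missing)
    ll <- ll + bern(drop(xm %*% theta$missing), r[t])
    # transition term
    if (y[t] == 1) {
      xa <- build_design(row, spec$abstinence)
      ll <- ll + bern(drop(xa %*% theta$abstinence), 1 - y[t + 1])
    } else {
      xr <- build_design(row, spec$relapse)
      ll <- ll + bern(drop(xr %*% theta$relapse), y[t + 1])
    }
  }
  ll
}

# Expand a panel into the completion-level pseudo-data used by the EM.
# The expansion is fixed across iterations; only the weights move.
em_structure <- function(panel, spec) {
  Tn <- attr(panel, "n_times")
  covs <- attr(panel, "covariates")
  used <- setdiff(unique(c(spec$abstinence, spec$relapse, spec$missing)),
                  c("r_prev", "y_prev", "y_curr"))
  used <- used[!grepl("^time[0-9]+$", used)]
  bad <- setdiff(used, covs)
  if (length(bad)) {
    stop("model terms not found in the panel: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }

  wide <- panel |>
    dplyr::arrange(.data$id, .data$time) |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(y = list(.data$status), .groups = "drop")
  covtab <- panel[panel$time == 0L,
                  c("id", used), drop = FALSE]
  wide <- dplyr::left_join(wide, covtab, by = "id")
  ok <- stats::complete.cases(wide[used])
  n_excluded <- sum(!ok)
  if (n_excluded > 0) {
    message(n_excluded, " subject(s) excluded from the joint fit: ",
            "missing baseline covariate(s) required by the model")
    wide <- wide[ok, , drop = FALSE]
  }
  if (nrow(wide) == 0) stop("no subjects left to fit", call. = FALSE)

  per_subject <- lapply(seq_len(nrow(wide)), function(i) {
    y <- wide$y[[i]]
    r <- as.integer(!is.na(y[-1]))
    mis <- which(is.na(y[-1]))             # follow-up times 1..T
    k <- length(mis)
    comps <- if (k == 0) {
      matrix(y, nrow = 1)
    } else {
      grid <- as.matrix(expand.grid(rep(list(0:1), k)))
      m <- matrix(rep(y, each = 2^k), nrow = 2^k)
      m[, mis + 1L] <- grid
      m
    }
    nc <- nrow(comps)
    rows <- tibble::tibble(
      sub = i,
      comp_local = rep(seq_len(nc), each = Tn),
      time = rep(seq_len(Tn), nc),
      y_prev = as.vector(t(comps[, seq_len(Tn), drop = FALSE])),
      y_curr = as.vector(t(comps[, seq_len(Tn) + 1L, drop = FALSE])),
      r_prev = rep(c(1L, r[-Tn]), nc),
      r_curr = rep(r, nc)
    )
    for (cv in used) rows[[cv]] <- wide[[cv]][i]
    list(rows = rows, n_comp = nc, completions = comps, id = wide$id[i])
  })

  rows <- dplyr::bind_rows(lapply(per_subject, `[[`, "rows"))
  n_comp <- vapply(per_subject, `[[`, 0L, "n_comp")
  offset <- cumsum(c(0L, n_comp[-length(n_comp)]))
  rows$comp <- offset[rows$sub] + rows$comp_local

  is_a <- rows$y_prev == 1L
  list(
    Xa = build_design(rows[is_a, ], spec$abstinence),
    za = 1L - rows$y_curr[is_a],
    cid_a = rows$comp[is_a],
    Xr = build_design(rows[!is_a, ], spec$relapse),
    zr = rows$y_curr[!is_a],
    cid_r = rows$comp[!is_a],
    Xm = build_design(rows, spec$missing),
    zm = rows$r_curr,
    cid_m = rows$comp,
    comp_subject = rep(seq_along(n_comp), n_comp),
    n_comp = n_comp,
    n_total_comp = sum(n_comp),
    ids = vapply(per_subject, function(s) as.character(s$id), ""),
    completions = lapply(per_subject, `[[`, "completions"),
    n_subjects = length(per_subject),
    n_times = Tn,
    rows = rows
  )
}

row_loglik <- function(X, z, beta) {
  eta <- drop(X %*% beta)
  z * eta - log1pexp(eta)
}

# completion-level log-likelihoods and E-step weights at theta
e_step_core <- function(st, theta) {
  comp_ll <- numeric(st$n_total_comp)
  add <- function(ll, cid) {
    s <- rowsum(ll, cid)
    comp_ll[as.integer(rownames(s))] <<- comp_ll[as.integer(rownames(s))] + s
  }
  if (nrow(st$Xa)) add(row_loglik(st$Xa, st$za, theta$abstinence), st$cid_a)
  if (nrow(st$Xr)) add(row_loglik(st$Xr, st$zr, theta$relapse), st$cid_r)
  add(row_loglik(st$Xm, st$zm, theta$missing), st$cid_m)

  # per-subject softmax (log-sum-exp) over completions
  mx <- tapply(comp_ll, st$comp_subject, max)[st$comp_subject]
  ex <- exp(comp_ll - mx)
  tot <- tapply(ex, st$comp_subject, sum)
  w <- ex / tot[st$comp_subject]
  obs_ll <- sum(log(tot) + tapply(comp_ll, st$comp_subject, max))
  list(weights = as.numeric(w), comp_ll = comp_ll, obs_loglik = obs_ll)
}

#' E-step completion weights
#'
#' Enumerates every completion of each subject's missing outcomes and
#' returns its posterior probability given the observed outcomes and the
#' full response pattern: the complete-data likelihood at `theta`,
#' normalised within subject by log-sum-exp. A subject with no missing
#' outcomes has a single completion with weight 1.
#'
#' @param panel A `smoke_panel`.
#' @param theta Parameter list as in [complete_data_loglik()].
#' @param spec A [model_spec()].
#' @return A tibble with one row per subject and completion: `id`,
#'   `completion` (list-column, the completed outcome vector of length
#'   `T + 1`) and `weight`. Weights sum to 1 within subject.
#' @export
e_step <- function(panel, theta, spec) {
  theta <- check_theta(theta, spec)
  st <- em_structure(panel, spec)
  es <- e_step_core(st, theta)
  tibble::tibble(
    id = st$ids[st$comp_subject],
    completion = purrr::flatten(lapply(st$completions, function(m) {
      lapply(seq_len(nrow(m)), function(i) m[i, ])
    })),
    weight = es$weights
  )
}

m_step_core <- function(st, w, theta) {
  fit_part <- function(X, z, cid, start) {
    if (nrow(X) == 0 || sum(w[cid]) == 0) {
      # no pseudo-data for this submodel (e.g. no abstinent states yet)
      return(list(coefficients = start,
                  vcov = matrix(NA_real_, length(start), length(start),
                                dimnames = list(names(start), names(start))),
                  loglik = 0, n_obs = 0L, converged = TRUE, iterations = 0L))
    }
    fit_wlogit(X, z, w = w[cid], start = start, ridge_on_separation = TRUE)
  }
  fit_a <- fit_part(st$Xa, st$za, st$cid_a, theta$abstinence)
  fit_r <- fit_part(st$Xr, st$zr, st$cid_r, theta$relapse)
  fit_m <- fit_part(st$Xm, st$zm, st$cid_m, theta$missing)
  list(theta = list(abstinence = fit_a$coefficients,
                    relapse = fit_r$coefficients,
                    missing = fit_m$coefficients),
       fits = list(abstinence = fit_a, relapse = fit_r, missing = fit_m))
}

#' Control parameters for the EM algorithm
#'
#' @param tol_param Convergence on `max |theta change|`.
#' @param tol_loglik Convergence on the relative change in the observed
#'   -data log-likelihood; both conditions must hold.
#' @param max_iter Maximum EM iterations.
#' @param identifiability Compute the condition number of the numerical
#'   observed-information matrix at the optimum? Joint outcome/missing
#'   models are prone to near-flat likelihood directions, which make the
#'   missing-model coefficients unreliable even when the transition
#'   estimates are stable.
#' @return A list of control values.
#' @export
em_control <- function(tol_param = 1e-6, tol_loglik = 1e-9,
                       max_iter = 500L, identifiability = TRUE) {
  list(tol_param = tol_param, tol_loglik = tol_loglik,
       max_iter = as.integer(max_iter), identifiability = identifiability)
}

pack_theta <- function(theta) unlist(theta, use.names = FALSE)
unpack_theta <- function(par, spec) {
  nm <- theta_names(spec)
  sizes <- lengths(nm)
  split_at <- rep(names(nm), sizes)
  out <- split(par, factor(split_at, levels = names(nm)))
  purrr::imap(out, function(v, m) stats::setNames(v, nm[[m]]))
}

#' Joint selection-model fit by the EM algorithm
#'
#' Maximises the observed-data likelihood of the joint model — Markov
#' transition logits for the outcome process, a logistic non-response
#' model in which response may depend on the current (possibly
#' unobserved) outcome — by alternating exact E-steps (completion
#' weights, [e_step()]) and M-steps (three weighted logistic
#' Newton-Raphson fits over the completion-expanded pseudo-data).
#' When the non-response model makes the mechanism ignorable (no
#' dependence on outcomes), the transition estimates coincide with the
#' available-data fit.
#'
#' @param panel A `smoke_panel`.
#' @param spec A [model_spec()]; `spec$missing` defines the non-response
#'   linear predictor.
#' @param init Optional starting `theta`. Default: transition
#'   coefficients from [fit_transition()], missing-model coefficients
#'   from a logistic fit of response on its outcome-free terms with the
#'   outcome coefficients started at zero.
#' @param control See [em_control()].
#' @return An object of class `em_fit` (also `transition_fit`): submodel
#'   coefficients, the observed-data log-likelihood and its per-iteration
#'   trace (non-decreasing by the EM ascent property), iteration count,
#'   convergence flag, missing-mechanism classification, and — when
#'   `control$identifiability` is `TRUE` — the condition number of the
#'   numerical observed information with an `interpret_with_caution`
#'   flag for the missing-model estimates.
#' @export
fit_em <- function(panel, spec, init = NULL, control = em_control()) {
  stopifnot(inherits(spec, "transition_spec"))
  st <- em_structure(panel, spec)
  nm <- theta_names(spec)

  if (is.null(init)) {
    avail <- fit_transition(panel, spec)
    outcome_free <- setdiff(nm$missing, c("y_prev", "y_curr"))
    # one row per actual subject-occasion; outcome columns are unused here
    keep_cols <- match(outcome_free, colnames(st$Xm))
    obs_rows <- st$rows$comp_local == 1L
    init_m <- fit_wlogit(st$Xm[obs_rows, keep_cols, drop = FALSE],
                         st$zm[obs_rows], ridge_on_separation = TRUE)
    alpha0 <- stats::setNames(rep(0, length(nm$missing)), nm$missing)
    alpha0[outcome_free] <- init_m$coefficients
    beta_rel <- if (is.null(avail$relapse)) {
      stats::setNames(rep(0, length(nm$relapse)), nm$relapse)
    } else {
      avail$relapse$coefficients
    }
    init <- list(abstinence = avail$abstinence$coefficients,
                 relapse = beta_rel,
                 missing = alpha0)
  }
  theta <- check_theta(init, spec)

  trace <- numeric(0)
  converged <- FALSE
  fits <- NULL
  iter <- 0L
  repeat {
    iter <- iter + 1L
    es <- e_step_core(st, theta)
    trace <- c(trace, es$obs_loglik)
    ms <- m_step_core(st, es$weights, theta)
    delta <- max(abs(pack_theta(ms$theta) - pack_theta(theta)))
    theta <- ms$theta
    fits <- ms$fits
    rel <- if (length(trace) > 1) {
      abs(trace[iter] - trace[iter - 1L]) / (abs(trace[iter - 1L]) + 1e-10)
    } else {
      Inf
    }
    if (delta < control$tol_param && rel < control$tol_loglik) {
      converged <- TRUE
      break
    }
    if (iter >= control$max_iter) break
  }
  es <- e_step_core(st, theta)
  trace <- c(trace, es$obs_loglik)

  kappa_info <- NA_real_
  if (isTRUE(control$identifiability)) {
    negll <- function(par) {
      -e_step_core(st, unpack_theta(par, spec))$obs_loglik
    }
    H <- tryCatch(stats::optimHess(pack_theta(theta), negll),
                  error = function(e) NULL)
    if (!is.null(H)) kappa_info <- kappa(H, exact = TRUE)
  }
  caution <- is.na(kappa_info) || kappa_info > 1e6

  for (m in names(fits)) fits[[m]]$terms <- nm[[m]][-1]
  structure(
    list(abstinence = fits$abstinence, relapse = fits$relapse,
         missing = fits$missing,
         loglik = es$obs_loglik, loglik_trace = trace,
         em_iterations = iter, converged = converged,
         n_pairs = st$n_subjects * st$n_times,
         n_subjects = st$n_subjects,
         mechanism = classify_mechanism(theta$missing),
         information_condition = kappa_info,
         interpret_with_caution = caution,
         spec = spec),
    class = c("em_fit", "transition_fit")
  )
}

#' @export
print.em_fit <- function(x, digits = 3, ...) {
  cat("<em_fit> joint transition + non-response selection model\n")
  cat("  subjects:", x$n_subjects,
      "| EM iterations:", x$em_iterations,
      "| converged:", x$converged, "\n")
  cat("  observed-data logLik:", format(x$loglik, digits = 8),
      "| mechanism:", x$mechanism, "\n")
  if (isTRUE(x$interpret_with_caution)) {
    cat("  NOTE: observed information is ill-conditioned (kappa = ",
        format(x$information_condition, digits = 3),
        "); missing-model estimates may be weakly identified — ",
        "interpret with caution.\n", sep = "")
  }
  cat("\n")
  td <- tidy(x)
  for (m in unique(td$model)) {
    cat(switch(m,
               abstinence = "Abstinence model  P(quit | smoking):",
               relapse = "Relapse model  P(smoke | abstinent):",
               missing = "Missing model  P(respond):"), "\n")
    sub <- as.data.frame(td[td$model == m, c("term", "estimate", "or")])
    sub[-1] <- lapply(sub[-1], round, digits)
    print(sub, row.names = FALSE)
    cat("\n")
  }
  cat("Standard errors for EM fits come from bootstrap_fit().\n")
  invisible(x)
}

#' @export
#' @rdname fit_em
#' @param x An `em_fit`.
#' @param boot Optional `transition_boot` from [bootstrap_fit()]; its
#'   SEs and normal-approximation p-values are merged into the output.
#' @param ... Unused.
tidy.em_fit <- function(x, boot = NULL, ...) {
  subs <- submodels(x)
  out <- purrr::map_dfr(names(subs), function(nm) {
    est <- subs[[nm]]$coefficients
    tibble::tibble(model = nm, term = names(est), estimate = unname(est),
                   or = exp(unname(est)))
  })
  if (!is.null(boot)) {
    full <- paste(out$model, out$term, sep = ":")
    out$std.error <- unname(boot$se[full])
    pv <- bootstrap_p(boot, estimate = stats::setNames(out$estimate, full),
                      sided = "two")
    out$p.value <- pv$p.value[match(full, pv$parameter)]
  }
  out
}

#' @export
glance.em_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, n_subjects = x$n_subjects,
    n_params = length(coef(x)), em_iterations = x$em_iterations,
    converged = x$converged, mechanism = x$mechanism,
    information_condition = x$information_condition
  )
}

#' @export
#' @rdname fit_em
#' @param object An `em_fit`.
autoplot.em_fit <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$loglik_trace),
                       loglik = object$loglik_trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$loglik)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(y = "observed-data log-likelihood",
                  title = "EM ascent")
}

#' Classify the missing-data mechanism from the non-response model
#'
#' In the non-response logit, dependence on the current (possibly
#' unobserved) outcome makes the mechanism not missing at random (NMAR);
#' dependence only on the previous, observed-when-responding outcome is
#' MAR; dependence on neither is MCAR.
#'
#' @param alpha Named coefficient vector of the missing model; absent
#'   terms count as zero.
#' @param tol Coefficients within `tol` of zero are treated as zero.
#' @return `"MCAR"`, `"MAR"` or `"NMAR"`.
#' @export
#' @examples
#' classify_mechanism(c(`(Intercept)` = -0.5, r_prev = 3.2, y_curr = -0.4))
classify_mechanism <- function(alpha, tol = 0) {
  a2 <- if ("y_prev" %in% names(alpha)) alpha[["y_prev"]] else 0
  a3 <- if ("y_curr" %in% names(alpha)) alpha[["y_curr"]] else 0
  if (abs(a3) > tol) "NMAR" else if (abs(a2) > tol) "MAR" else "MCAR"
}
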