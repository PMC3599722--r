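#' Nonparametric bootstrap for transition-model fits
#'
#' Resamples whole subjects with replacement (N out of N — a subject's
#' entire outcome trajectory travels together), refits the requested
#' estimator on each replicate, and reports the standard deviation of
#' the replicate estimates as the bootstrap standard error, together
#' with 2.5/97.5 percentile intervals. This is the inferential route for
#' EM fits, whose model-based information understates the uncertainty
#' lost to missing data. The full pipeline is reproducible given `seed`.
#'
#' @param panel A `smoke_panel`.
#' @param spec A [model_spec()].
#' @param fitter `"available"` ([fit_transition()]) or `"em"`
#'   ([fit_em()]).
#' @param B Number of bootstrap replicates (at least 2; 1000 for
#'   publication-grade standard errors).
#' @param seed Integer seed.
#' @param ... Passed to the fitter (e.g. `control` for the EM).
#' @return An object of class `transition_boot`: `replicates` (a
#'   `(B - n_failed) x p` tibble of estimates), `se`, `ci` (percentile
#'   2.5/97.5), `estimate` (full-data fit), `n_failed`, `B`, `seed`.
#' @export
bootstrap_fit <- function(panel, spec, fitter = c("available", "em"),
                          B = 1000L, seed = 1L, ...) {
  fitter <- match.arg(fitter)
  B <- as.integer(B)
  if (B < 2) stop("B must be at least 2", call. = FALSE)
  pattrs <- panel_attrs(panel)
  dots <- list(...)
  if (fitter == "em" && is.null(dots$control)) {
    dots$control <- em_control(identifiability = FALSE)
  }
  fit_fun <- switch(fitter,
                    available = function(p) fit_transition(p, spec),
                    em = function(p) do.call(fit_em, c(list(p, spec), dots)))

  full_fit <- fit_fun(panel)
  est <- coef(full_fit)

  # panel rows are sorted by (id, time): each subject is a contiguous
  # block of T+1 rows, so a replicate is a single row-index lookup
  base <- tibble::as_tibble(panel)
  block <- pattrs$n_times + 1L
  n <- nrow(base) / block
  stopifnot(n == dplyr::n_distinct(base$id))

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))
  set.seed(seed)

  reps <- vector("list", B)
  n_failed <- 0L
  for (b in seq_len(B)) {
    take <- sample.int(n, n, replace = TRUE)
    rows <- rep((take - 1L) * block, each = block) + seq_len(block)
    boot_df <- base[rows, , drop = FALSE]
    boot_df$id <- rep(seq_len(n), each = block)
    bp <- structure(boot_df,
                    class = c("smoke_panel", class(tibble::tibble())),
                    n_times = pattrs$n_times,
                    time_unit_label = pattrs$time_unit_label,
                    covariates = pattrs$covariates)
    res <- tryCatch(suppressMessages(fit_fun(bp)), error = function(e) NULL)
    if (is.null(res) || !res$converged) {
      n_failed <- n_failed + 1L
    } else {
      reps[[b]] <- coef(res)
    }
  }
  reps <- do.call(rbind, Filter(Negate(is.null), reps))
  if (is.null(reps) || nrow(reps) == 0) {
    stop("all bootstrap replicates failed", call. = FALSE)
  }
  if (n_failed > 0.01 * B) {
    warning(n_failed, " of ", B, " bootstrap replicates failed to ",
            "converge and were dropped", call. = FALSE)
  }
  se <- apply(reps, 2, stats::sd)
  ci <- t(apply(reps, 2, stats::quantile, probs = c(0.025, 0.975),
                names = FALSE))
  colnames(ci) <- c("lower", "upper")
  structure(
    list(replicates = tibble::as_tibble(reps), se = se,
         ci = tibble::as_tibble(ci, rownames = NULL) |>
           dplyr::mutate(parameter = colnames(reps), .before = 1),
         estimate = est, n_failed = n_failed, B = B, seed = seed,
         fitter = fitter),
    class = "transition_boot"
  )
}

#' @export
print.transition_boot <- function(x, digits = 3, ...) {
  cat("<transition_boot> ", x$B, " replicates (", x$n_failed,
      " failed), fitter = ", x$fitter, ", seed = ", x$seed, "\n", sep = "")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @export
tidy.transition_boot <- function(x, ...) {
  tibble::tibble(
    parameter = names(x$se),
    estimate = unname(x$estimate[names(x$se)]),
    std.error = unname(x$se),
    conf.low = x$ci$lower, conf.high = x$ci$upper
  )
}

#' @export
#' @rdname bootstrap_fit
#' @param object A `transition_boot`.
autoplot.transition_boot <- function(object, ...) {
  long <- tidyr::pivot_longer(object$replicates,
                              dplyr::everything(),
                              names_to = "parameter", values_to = "estimate")
  ggplot2::ggplot(long, ggplot2::aes(.data$estimate)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(title = "bootstrap replicate distributions")
}

#' Normal-approximation bootstrap p-values
#'
#' Computes `z = estimate / SE` with the bootstrap standard error and a
#' one- or two-sided normal p-value. The default is two-sided; the
#' one-sided variant (`P(Z > |z|)`) is also offered because selection
#' -model tables in the applied literature are sometimes reported that
#' way.
#'
#' @param boot A `transition_boot`.
#' @param estimate Named vector of point estimates; defaults to the
#'   full-data estimates stored in `boot`.
#' @param sided `"two"` (default) or `"one"`.
#' @return A tibble: `parameter`, `estimate`, `std.error`, `statistic`,
#'   `p.value`. A zero standard error yields an `NA` p-value with a
#'   warning.
#' @export
bootstrap_p <- function(boot, estimate = NULL, sided = c("two", "one")) {
  sided <- match.arg(sided)
  estimate <- estimate %||% boot$estimate
  se <- boot$se[names(estimate)]
  if (any(is.na(se))) {
    stop("estimate names not found among bootstrap parameters: ",
         paste(names(estimate)[is.na(se)], collapse = ", "), call. = FALSE)
  }
  z <- estimate / se
  if (any(se == 0)) {
    warning("zero bootstrap SE for: ",
            paste(names(se)[se == 0], collapse = ", "),
            "; p-value undefined", call. = FALSE)
    z[se == 0] <- NA_real_
  }
  p <- if (sided == "two") 2 * stats::pnorm(-abs(z)) else stats::pnorm(-abs(z))
  tibble::tibble(parameter = names(estimate),
                 estimate = unname(estimate), std.error = unname(se),
                 statistic = unname(z), p.value = unname(p),
                 sided = sided)
}
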