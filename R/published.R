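#' Published KanQuit transition-model estimates
#'
#' The coefficient table reported for the KanQuit trial (750 rural
#' smokers, three disease-management arms, smoking status every 6 months
#' for 2 years): the available-data fit and two selection-model
#' sensitivity analyses (missingness depending on previous response and
#' previous/current smoking status, without and with time and arm
#' terms). The individual-level trial data are not public, so these
#' numbers are shipped as a reference table: they let the odds-ratio and
#' Wald arithmetic be applied to the published coefficients, and they
#' are the default generating truth of [kanquit_truth()].
#'
#' Selection-model standard errors are bootstrap-based (1,000 resamples
#' of subjects) in the source analysis.
#'
#' @return A tibble with columns `analysis` (`"available"`,
#'   `"selection1"`, `"selection2"`), `model` (`"abstinence"`,
#'   `"relapse"`, `"missing"`), `term`, `estimate`, `std.error`.
#' @export
kanquit_estimates <- function() {
  row <- function(analysis, model, term, estimate, std.error) {
    tibble::tibble(analysis = analysis, model = model, term = term,
                   estimate = estimate, std.error = std.error)
  }
  ab_terms <- c("(Intercept)", "MDM", "HDM", "male", "cpd",
                "motivation", "confidence", "sqa")
  rl_terms <- c("(Intercept)", "time3", "time4", "MDM", "HDM",
                "income_gt40k", "dep5min")
  dplyr::bind_rows(
    row("available", "abstinence", ab_terms,
        c(-3.348, 0.056, 0.392, 0.504, -0.033, 0.144, 0.083, 0.295),
        c(0.456, 0.166, 0.158, 0.137, 0.008, 0.040, 0.026, 0.146)),
    row("available", "relapse", rl_terms,
        c(-0.939, 0.763, -0.029, -0.708, -0.409, -0.564, 0.588),
        c(0.338, 0.318, 0.342, 0.331, 0.305, 0.259, 0.269)),
    row("selection1", "abstinence", ab_terms,
        c(-3.381, -0.026, 0.322, 0.461, -0.035, 0.150, 0.083, 0.333),
        c(0.503, 0.193, 0.177, 0.158, 0.009, 0.044, 0.028, 0.164)),
    row("selection1", "relapse", rl_terms,
        c(-0.979, 0.792, -0.012, -0.624, -0.366, -0.575, 0.600),
        c(0.376, 0.306, 0.331, 0.372, 0.361, 0.308, 0.322)),
    row("selection1", "missing",
        c("(Intercept)", "r_prev", "y_prev", "y_curr"),
        c(-0.527, 3.240, 0.013, -0.428),
        c(0.339, 0.191, 0.319, 0.532)),
    row("selection2", "abstinence", ab_terms,
        c(-3.382, -0.022, 0.329, 0.462, -0.035, 0.150, 0.083, 0.332),
        c(0.502, 0.188, 0.171, 0.157, 0.009, 0.044, 0.028, 0.164)),
    row("selection2", "relapse", rl_terms,
        c(-0.977, 0.788, -0.009, -0.629, -0.371, -0.576, 0.601),
        c(0.377, 0.301, 0.332, 0.375, 0.363, 0.307, 0.322)),
    row("selection2", "missing",
        c("(Intercept)", "time2", "time3", "time4", "MDM", "HDM",
          "r_prev", "y_prev", "y_curr"),
        c(-0.626, 0.366, 0.072, 0.597, -0.416, -0.496, 3.367, 0.067, -0.402),
        c(0.432, 0.196, 0.176, 0.193, 0.164, 0.173, 0.194, 0.287, 0.443))
  )
}

#' Build a fit-like object from a coefficient table
#'
#' Wraps a table of estimates and standard errors (such as one analysis
#' column of [kanquit_estimates()]) in a `transition_fit` shell so that
#' [odds_ratio()] and single-contrast [wald_test()] arithmetic can be
#' applied to published coefficients. The covariance is diagonal (only
#' marginal SEs are published), so multi-row contrasts that need
#' covariances are approximate.
#'
#' @param estimates Tibble with columns `model`, `term`, `estimate`,
#'   `std.error`, covering a single analysis.
#' @param n_pairs Pair count used for F-test denominator df.
#' @return A `transition_fit`-classed object (no log-likelihood).
#' @export
#' @examples
#' pub <- dplyr::filter(kanquit_estimates(), analysis == "available")
#' odds_ratio(as_transition_fit(pub), c(HDM = 1), model = "abstinence")
as_transition_fit <- function(estimates, n_pairs = NA_integer_) {
  stopifnot(all(c("model", "term", "estimate", "std.error") %in%
                  names(estimates)))
  if ("analysis" %in% names(estimates) &&
      dplyr::n_distinct(estimates$analysis) > 1) {
    stop("`estimates` covers more than one analysis; filter first",
         call. = FALSE)
  }
  subs <- lapply(split(estimates, estimates$model), function(d) {
    cf <- stats::setNames(d$estimate, d$term)
    V <- diag(d$std.error^2, nrow = nrow(d))
    dimnames(V) <- list(d$term, d$term)
    list(coefficients = cf, vcov = V, loglik = NA_real_,
         n_obs = NA_integer_, converged = TRUE, terms = setdiff(d$term,
                                                                "(Intercept)"))
  })
  structure(
    list(abstinence = subs$abstinence, relapse = subs$relapse,
         missing = subs$missing,
         loglik = NA_real_, n_pairs = n_pairs, converged = TRUE),
    class = "transition_fit"
  )
}
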