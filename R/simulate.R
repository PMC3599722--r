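# Synthetic-cohort generator: the package's test bed. It emulates the
# design of a three-arm rural smoking-cessation trial (750 smokers, three
# equal disease-management arms, five assessments six months apart) with
# known truth, so estimators can be checked against the coefficients that
# generated the data.

#' Define the generating truth for a synthetic cohort
#'
#' A truth object bundles everything [simulate_cohort()] needs: the
#' transition coefficients, the non-response coefficients, covariate
#' generators, and the design constants `N` and `T`.
#'
#' @param N Number of subjects.
#' @param n_times Number of follow-up occasions.
#' @param beta_abstinence,beta_relapse Named coefficient vectors
#'   (including `"(Intercept)"`; time dummies `"time<k>"` allowed).
#' @param alpha Named non-response coefficients over
#'   `"(Intercept)"`, `"r_prev"`, `"y_prev"`, `"y_curr"`, time dummies
#'   and covariates. `alpha = NULL` disables missingness entirely.
#' @param covariates Named list of generator functions `function(n)`
#'   returning `n` numeric draws; arm indicators `MDM`/`HDM` are created
#'   automatically (balanced randomisation) and must not be listed.
#' @param time_unit_label Display label for one step.
#' @return An object of class `cohort_truth`.
#' @seealso [kanquit_truth()] for the calibrated default.
#' @export
cohort_truth <- function(N, n_times,
                         beta_abstinence, beta_relapse,
                         alpha = NULL,
                         covariates = list(),
                         time_unit_label = "6 months") {
  known <- c(names(covariates), "MDM", "HDM")
  needed <- function(v) {
    tm <- setdiff(names(v), c("(Intercept)", "r_prev", "y_prev", "y_curr"))
    tm[!grepl("^time[0-9]+$", tm)]
  }
  for (v in list(beta_abstinence, beta_relapse, alpha)) {
    if (is.null(v)) next
    bad <- setdiff(needed(v), known)
    if (length(bad)) {
      stop("truth references covariate(s) without a generator: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(N = as.integer(N), n_times = as.integer(n_times),
                 beta_abstinence = beta_abstinence,
                 beta_relapse = beta_relapse,
                 alpha = alpha, covariates = covariates,
                 time_unit_label = time_unit_label),
            class = "cohort_truth")
}

rbern <- function(n, p) stats::rbinom(n, 1L, p)

truncnorm_left <- function(n, mean, sd, lower) {
  # inverse-CDF draw from N(mean, sd) truncated to [lower, Inf)
  p0 <- stats::pnorm(lower, mean, sd)
  stats::qnorm(stats::runif(n, p0, 1), mean, sd)
}

clipnorm <- function(n, mean, sd, lo, hi) {
  pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))
}

#' Calibrated KanQuit-style generating truth
#'
#' The default study conditions of the simulator: 750 subjects in three
#' equal arms followed over four six-monthly assessments, baseline
#' covariates drawn independently from the trial's published marginals
#' (age N(47.2, 13.1); male with probability 0.415; income > 40K with
#' probability 0.386; cigarettes/day N(23.7, 10.4) truncated at 10 or
#' more; first cigarette within 5 minutes with probability 0.380;
#' motivation N(8.6, 2.1) and confidence N(6.1, 2.7), both clipped to
#' 0-10; serious quit attempt with probability 0.240), transition logits
#' set to the published available-data estimates, and a non-response
#' logit whose coefficients are the published selection-model estimates
#' — response depends strongly on having responded before and, making
#' the mechanism NMAR, on the current (possibly unobserved) status. This
#' produces roughly 15% missing follow-up outcomes, the level seen in
#' the trial.
#'
#' @param N,n_times Design size overrides.
#' @param missingness `"nmar"` (default), `"mcar"` (outcome coefficients
#'   zeroed), or `"none"` (fully observed panel).
#' @return A [cohort_truth()] object.
#' @export
kanquit_truth <- function(N = 750L, n_times = 4L,
                          missingness = c("nmar", "mcar", "none")) {
  missingness <- match.arg(missingness)
  alpha <- switch(
    missingness,
    nmar = c(`(Intercept)` = -0.527, r_prev = 3.240,
             y_prev = 0.013, y_curr = -0.428),
    mcar = c(`(Intercept)` = -0.527, r_prev = 3.240,
             y_prev = 0, y_curr = 0),
    none = NULL
  )
  cohort_truth(
    N = N, n_times = n_times,
    beta_abstinence = c(`(Intercept)` = -3.348, MDM = 0.056, HDM = 0.392,
                        male = 0.504, cpd = -0.033, motivation = 0.144,
                        confidence = 0.083, sqa = 0.295),
    beta_relapse = c(`(Intercept)` = -0.939, time3 = 0.763, time4 = -0.029,
                     MDM = -0.708, HDM = -0.409, income_gt40k = -0.564,
                     dep5min = 0.588),
    alpha = alpha,
    covariates = list(
      age = function(n) stats::rnorm(n, 47.2, 13.1),
      male = function(n) rbern(n, 1 - 0.585),
      income_gt40k = function(n) rbern(n, 1 - 0.614),
      cpd = function(n) truncnorm_left(n, 23.7, 10.4, 10),
      dep5min = function(n) rbern(n, 0.380),
      motivation = function(n) clipnorm(n, 8.6, 2.1, 0, 10),
      confidence = function(n) clipnorm(n, 6.1, 2.7, 0, 10),
      sqa = function(n) rbern(n, 0.240)
    )
  )
}

linear_predictor <- function(df, coefs) {
  terms <- setdiff(names(coefs), "(Intercept)")
  X <- build_design(df, terms)
  drop(X %*% coefs[colnames(X)])
}

#' Simulate a synthetic smoking-cessation cohort
#'
#' Draws baseline covariates from the truth's generators, assigns arms
#' by balanced randomisation, starts every subject smoking, evolves the
#' outcome forward through the transition logits (abstinence logit when
#' the previous state is smoking, relapse logit — including its time
#' dummies — when abstinent), then draws each follow-up's response
#' indicator from the non-response logit *after* the current outcome is
#' realised (the selection-model factorisation) and masks the outcome
#' where the subject did not respond. The latent chain keeps evolving
#' from the true, unmasked states.
#'
#' @param truth A [cohort_truth()].
#' @param seed Integer seed; identical truth and seed give an identical
#'   panel.
#' @return A `smoke_panel` with the generating truth attached as
#'   attribute `"truth"`.
#' @export
#' @examples
#' panel <- simulate_cohort(kanquit_truth(N = 200), seed = 7)
#' missing_fraction(panel)
simulate_cohort <- function(truth, seed = NULL) {
  stopifnot(inherits(truth, "cohort_truth"))
  if (!is.null(seed)) set.seed(seed)
  N <- truth$N
  Tn <- truth$n_times

  cov_df <- tibble::tibble(.rows = N)
  for (nm in names(truth$covariates)) {
    cov_df[[nm]] <- truth$covariates[[nm]](N)
  }
  arm <- sample(rep_len(c("PM", "MDM", "HDM"), N))
  cov_df$MDM <- as.numeric(arm == "MDM")
  cov_df$HDM <- as.numeric(arm == "HDM")

  Y <- matrix(NA_integer_, N, Tn + 1L)
  R <- matrix(1L, N, Tn + 1L)
  Y[, 1] <- 1L
  for (t in seq_len(Tn)) {
    df_t <- cov_df
    df_t$time <- t
    y_prev <- Y[, t]
    smoking <- y_prev == 1L
    p_quit <- stats::plogis(linear_predictor(df_t, truth$beta_abstinence))
    p_relapse <- stats::plogis(linear_predictor(df_t, truth$beta_relapse))
    y_curr <- integer(N)
    y_curr[smoking] <- 1L - rbern(sum(smoking), p_quit[smoking])
    y_curr[!smoking] <- rbern(sum(!smoking), p_relapse[!smoking])
    Y[, t + 1L] <- y_curr
    if (!is.null(truth$alpha)) {
      df_t$r_prev <- R[, t]
      df_t$y_prev <- y_prev
      df_t$y_curr <- y_curr
      lam <- stats::plogis(linear_predictor(df_t, truth$alpha))
      R[, t + 1L] <- rbern(N, lam)
    }
  }

  status <- as.vector(t(Y))
  resp <- as.vector(t(R))
  status[resp == 0L] <- NA_integer_
  long <- tibble::tibble(
    id = rep(seq_len(N), each = Tn + 1L),
    time = rep(0:Tn, N),
    status = status
  )
  for (nm in names(cov_df)) long[[nm]] <- rep(cov_df[[nm]], each = Tn + 1L)
  panel <- as_smoke_panel(long, n_times = Tn,
                          time_unit_label = truth$time_unit_label)
  attr(panel, "truth") <- truth
  panel
}

#' Implied quantities of a generating truth
#'
#' Reports what the truth's coefficients mean on the probability scale:
#' the implied transition probabilities at the mean covariate vector for
#' each follow-up occasion, the missing-data mechanism class of the
#' non-response model, and the expected missing fraction estimated by
#' Monte Carlo simulation.
#'
#' @param truth A [cohort_truth()].
#' @param n_sim Subjects used for the Monte Carlo covariate means and
#'   missing-fraction estimate.
#' @param seed Seed for the Monte Carlo step.
#' @return A list: `transition` (tibble of implied probabilities by
#'   occasion), `mechanism`, `expected_missing_fraction`,
#'   `covariate_means`.
#' @export
truth_report <- function(truth, n_sim = 5000L, seed = 1L) {
  stopifnot(inherits(truth, "cohort_truth"))
  panel <- simulate_cohort(cohort_truth(
    N = n_sim, n_times = truth$n_times,
    beta_abstinence = truth$beta_abstinence,
    beta_relapse = truth$beta_relapse,
    alpha = truth$alpha, covariates = truth$covariates,
    time_unit_label = truth$time_unit_label
  ), seed = seed)
  covs <- attr(panel, "covariates")
  base <- panel[panel$time == 0L, covs, drop = FALSE]
  mu <- colMeans(base)

  imp <- purrr::map_dfr(seq_len(truth$n_times), function(t) {
    df <- tibble::as_tibble(as.list(mu))
    df$time <- t
    tibble::tibble(
      time = t,
      p_quit = stats::plogis(linear_predictor(df, truth$beta_abstinence)),
      p_relapse = stats::plogis(linear_predictor(df, truth$beta_relapse))
    )
  })
  mech <- if (is.null(truth$alpha)) "none" else
    classify_mechanism(truth$alpha)
  list(
    transition = imp,
    mechanism = mech,
    expected_missing_fraction = missing_fraction(panel),
    covariate_means = mu
  )
}
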