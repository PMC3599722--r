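test_that("complete-data log-likelihood: symmetric null gives log(1/2) per factor", {
  # T = 1, all coefficients zero: response prob and transition prob both 1/2
  spec <- model_spec(missing = c("r_prev", "y_prev", "y_curr"))
  theta <- list(abstinence = c(`(Intercept)` = 0),
                relapse = c(`(Intercept)` = 0),
                missing = c(`(Intercept)` = 0, r_prev = 0, y_prev = 0,
                            y_curr = 0))
  for (y1 in 0:1) {
    expect_equal(complete_data_loglik(c(1, y1), r = 1, covariates = NULL,
                                      theta, spec),
                 2 * log(0.5), tolerance = 1e-12)
  }
})

test_that("complete-data log-likelihood matches the hand-computed oracle", {
  spec <- toy_spec()
  theta <- toy_theta()
  cases <- list(
    list(y = c(1, 1, 0), r = c(1, 1)),
    list(y = c(1, 0, 1), r = c(0, 1)),
    list(y = c(1, 0, 0), r = c(1, 0))
  )
  for (cs in cases) {
    got <- complete_data_loglik(cs$y, cs$r, covariates = c(x = 0.7),
                                theta, spec)
    want <- log(oracle_subject_lik(cs$y, cs$r, list(x = 0.7), theta, spec))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("the likelihood kernel defines a proper joint distribution", {
  # summing exp(loglik) over all completions x response patterns gives 1
  spec <- toy_spec()
  theta <- toy_theta()
  tot <- 0
  for (y1 in 0:1) for (y2 in 0:1) for (r1 in 0:1) for (r2 in 0:1) {
    tot <- tot + exp(complete_data_loglik(c(1, y1, y2), c(r1, r2),
                                          c(x = -0.4), theta, spec))
  }
  expect_equal(tot, 1, tolerance = 1e-12)
})

test_that("E-step weights: trivial, symmetric, and Bayes-oracle cases", {
  spec <- toy_spec()
  theta <- toy_theta()

  # fully observed subject: single completion with weight one
  p_obs <- as_smoke_panel(tibble::tibble(id = 1, time = 0:2,
                                         status = c(1, 1, 0), x = 0.3))
  w <- e_step(p_obs, theta, spec)
  expect_equal(nrow(w), 1)
  expect_equal(w$weight, 1)

  # symmetric parameters make both completions of one missing slot equal
  theta0 <- list(abstinence = c(`(Intercept)` = 0, x = 0),
                 relapse = c(`(Intercept)` = 0, x = 0),
                 missing = c(`(Intercept)` = 0.3, r_prev = 0, y_prev = 0,
                             y_curr = 0))
  p_mis <- as_smoke_panel(tibble::tibble(id = 1, time = 0:2,
                                         status = c(1, NA, 1), x = 0.3))
  w0 <- e_step(p_mis, theta0, spec)
  expect_equal(w0$weight, c(0.5, 0.5))

  # arbitrary theta: weights equal the brute-force Bayes posterior
  w1 <- e_step(p_mis, theta, spec)
  en <- oracle_completions(c(1, NA, 1), list(x = 0.3), theta, spec)
  want <- en$lik / sum(en$lik)
  got <- w1$weight[match(en$comps[, 2], sapply(w1$completion, `[`, 2))]
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("E-step weights normalise to one within subject on random instances", {
  spec <- toy_spec()
  set.seed(42)
  for (rep in 1:5) {
    p <- simulate_cohort(kanquit_truth(N = 20), seed = rep)
    th <- list(
      abstinence = setNames(rnorm(8, 0, 0.5),
                            c("(Intercept)", kanquit_spec()$abstinence)),
      relapse = setNames(rnorm(7, 0, 0.5),
                         c("(Intercept)", kanquit_spec()$relapse)),
      missing = setNames(rnorm(4, 0, 0.5),
                         c("(Intercept)", "r_prev", "y_prev", "y_curr"))
    )
    w <- e_step(p, th, kanquit_spec())
    sums <- tapply(w$weight, w$id, sum)
    expect_true(all(abs(sums - 1) < 1e-12))
  }
})

test_that("with no missing data the EM reduces to the available-data fit", {
  p <- simulate_cohort(kanquit_truth(N = 200, missingness = "none"), seed = 6)
  spec <- kanquit_spec()
  fa <- fit_transition(p, spec)
  # the missing model is degenerate on fully observed data (all responses 1);
  # the transition part is what must coincide, and it settles immediately
  fe <- fit_em(p, spec, control = em_control(max_iter = 25,
                                             identifiability = FALSE))
  expect_equal(fe$abstinence$coefficients, fa$abstinence$coefficients,
               tolerance = 1e-8)
  expect_equal(fe$relapse$coefficients, fa$relapse$coefficients,
               tolerance = 1e-8)
})

test_that("EM ascends: the observed-data log-likelihood trace is non-decreasing", {
  p <- simulate_cohort(kanquit_truth(N = 150), seed = 12)
  fe <- fit_em(p, kanquit_spec(), control = em_control(identifiability = FALSE))
  expect_true(all(diff(fe$loglik_trace) >= -1e-8))
  expect_true(fe$converged)
  # the reported observed-data log-likelihood matches brute-force enumeration
  theta <- list(abstinence = fe$abstinence$coefficients,
                relapse = fe$relapse$coefficients,
                missing = fe$missing$coefficients)
  expect_equal(fe$loglik, oracle_obs_loglik(p, theta, kanquit_spec()),
               tolerance = 1e-8)
})

test_that("EM solution matches direct maximisation of the enumerated likelihood", {
  # intermittent and terminal gaps make the enumeration non-trivial, while
  # every parameter stays identified (an interior maximum exists)
  p <- small_em_panel()
  spec <- model_spec(abstinence = "x", relapse = character(),
                     missing = "r_prev")
  fe <- fit_em(p, spec, control = em_control(tol_param = 1e-9,
                                             tol_loglik = 1e-12,
                                             max_iter = 2000,
                                             identifiability = FALSE))
  nm <- list(abstinence = c("(Intercept)", "x"),
             relapse = "(Intercept)",
             missing = c("(Intercept)", "r_prev"))
  negll <- function(par) {
    th <- list(abstinence = setNames(par[1:2], nm$abstinence),
               relapse = setNames(par[3], nm$relapse),
               missing = setNames(par[4:5], nm$missing))
    -oracle_obs_loglik(p, th, spec)
  }
  o <- optim(rep(0, 5), negll, method = "BFGS",
             control = list(maxit = 2000, reltol = 1e-14))
  em_par <- c(fe$abstinence$coefficients, fe$relapse$coefficients,
              fe$missing$coefficients)
  expect_equal(unname(em_par), o$par, tolerance = 1e-4)
  expect_equal(fe$loglik, -o$value, tolerance = 1e-8)
})

test_that("ignorable monotone dropout leaves the transition estimates unchanged", {
  truth <- kanquit_truth(N = 200)
  truth$alpha <- c(`(Intercept)` = -17, r_prev = 19) # monotone dropout, MCAR
  p <- simulate_cohort(truth, seed = 9)
  spec <- kanquit_spec(missing = "rprev")
  fa <- fit_transition(p, spec)
  fe <- suppressWarnings(
    fit_em(p, spec, control = em_control(max_iter = 300,
                                         identifiability = FALSE))
  )
  expect_equal(fe$abstinence$coefficients, fa$abstinence$coefficients,
               tolerance = 1e-6)
  expect_equal(fe$relapse$coefficients, fa$relapse$coefficients,
               tolerance = 1e-6)
})

test_that("missing-mechanism taxonomy follows the selection-model coefficients", {
  expect_equal(classify_mechanism(c(`(Intercept)` = 1, r_prev = 2)), "MCAR")
  expect_equal(classify_mechanism(c(y_prev = 0.5, y_curr = 0)), "MAR")
  expect_equal(classify_mechanism(c(y_prev = 0, y_curr = -0.4)), "NMAR")
  expect_equal(classify_mechanism(c(y_prev = 0.01, y_curr = 0.02), tol = 0.05),
               "MCAR")
})

test_that("subjects lacking a model covariate are excluded from the joint fit", {
  p <- simulate_cohort(kanquit_truth(N = 60), seed = 30)
  df <- tibble::as_tibble(p)
  df$cpd[df$id == 1] <- NA
  p2 <- as_smoke_panel(df)
  expect_message(
    fit_em(p2, kanquit_spec(missing = "rprev"),
           control = em_control(max_iter = 5, identifiability = FALSE)),
    "excluded"
  )
})
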