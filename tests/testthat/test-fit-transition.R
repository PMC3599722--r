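test_that("intercept-only abstinence model recovers the logit of the proportion", {
  # 3 quits, 9 stays: intercept = log(3/9)
  pr <- tibble::tibble(id = 1:12, time = 1L, y_prev = 1L,
                       y_curr = rep(c(0L, 1L), c(3, 9)))
  f <- fit_transition(pr, model_spec())
  expect_equal(unname(f$abstinence$coefficients), log(3 / 9),
               tolerance = 1e-9)
  expect_true(f$converged)
})

test_that("Newton-Raphson matches glm on a simulated cohort", {
  p <- simulate_cohort(kanquit_truth(N = 500, missingness = "none"), seed = 8)
  f <- fit_transition(p, kanquit_spec())
  pr <- extract_pairs(p)
  ab <- pr[pr$y_prev == 1, ]
  g_ab <- glm(I(1 - y_curr) ~ MDM + HDM + male + cpd + motivation +
                confidence + sqa, family = binomial, data = ab)
  expect_equal(unname(f$abstinence$coefficients), unname(coef(g_ab)),
               tolerance = 1e-7)
  expect_equal(unname(sqrt(diag(f$abstinence$vcov))),
               unname(sqrt(diag(vcov(g_ab)))), tolerance = 1e-6)
  rl <- pr[pr$y_prev == 0, ]
  g_rl <- glm(y_curr ~ I(time == 3) + I(time == 4) + MDM + HDM +
                income_gt40k + dep5min, family = binomial, data = rl)
  expect_equal(unname(f$relapse$coefficients), unname(coef(g_rl)),
               tolerance = 1e-7)
  expect_equal(f$loglik, as.numeric(logLik(g_ab) + logLik(g_rl)),
               tolerance = 1e-8)
})

test_that("the joint MLE agrees with a derivative-free optimiser on toy data", {
  p <- as_smoke_panel(tibble::tibble(
    id = rep(1:6, each = 3), time = rep(0:2, 6),
    status = c(1, 1, 0,  1, 0, 0,  1, 1, 1,  1, 0, 1,  1, 1, 0,  1, 1, 1),
    x = rep(c(-1, 0.5, 1, -0.3, 0.2, 0.8), each = 3)
  ))
  spec <- model_spec(abstinence = "x", relapse = character())
  f <- fit_transition(p, spec)
  pr <- extract_pairs(p)
  negll <- function(par) {
    ll <- 0
    for (i in seq_len(nrow(pr))) {
      if (pr$y_prev[i] == 1) {
        pq <- plogis(par[1] + par[2] * pr$x[i])
        ll <- ll + log(if (pr$y_curr[i] == 0) pq else 1 - pq)
      } else {
        prl <- plogis(par[3])
        ll <- ll + log(if (pr$y_curr[i] == 1) prl else 1 - prl)
      }
    }
    -ll
  }
  o <- optim(rep(0, 3), negll, method = "Nelder-Mead",
             control = list(maxit = 5000, reltol = 1e-14))
  est <- c(f$abstinence$coefficients, f$relapse$coefficients)
  expect_equal(unname(est), o$par, tolerance = 1e-5)
  expect_equal(f$loglik, -o$value, tolerance = 1e-8)
})

test_that("the reported optimum is a local maximum of the log-likelihood", {
  p <- simulate_cohort(kanquit_truth(N = 150, missingness = "none"), seed = 21)
  spec <- kanquit_spec()
  f <- fit_transition(p, spec)
  pr <- extract_pairs(p)
  ab <- pr[pr$y_prev == 1, ]
  Xa <- markovquit:::build_design(ab, spec$abstinence)
  za <- 1 - ab$y_curr
  rl <- pr[pr$y_prev == 0, ]
  Xr <- markovquit:::build_design(rl, spec$relapse)
  zr <- rl$y_curr
  ll_at <- function(ba, br) {
    ea <- drop(Xa %*% ba); er <- drop(Xr %*% br)
    sum(za * ea - log(1 + exp(ea))) + sum(zr * er - log(1 + exp(er)))
  }
  ll0 <- ll_at(f$abstinence$coefficients, f$relapse$coefficients)
  expect_equal(ll0, f$loglik, tolerance = 1e-8)
  set.seed(99)
  for (k in 1:25) {
    pa <- f$abstinence$coefficients + rnorm(ncol(Xa), 0, 0.05)
    prl <- f$relapse$coefficients + rnorm(ncol(Xr), 0, 0.05)
    expect_lt(ll_at(pa, prl), ll0 + 1e-10)
  }
})

test_that("pairs missing a required covariate are excluded per-submodel", {
  p <- simulate_cohort(kanquit_truth(N = 80, missingness = "none"), seed = 4)
  df <- tibble::as_tibble(p)
  df$income_gt40k[df$id %in% 1:2] <- NA # term used by the relapse model only
  p2 <- as_smoke_panel(df)
  f_full <- fit_transition(p, kanquit_spec())
  f_miss <- fit_transition(p2, kanquit_spec())
  expect_equal(f_miss$abstinence$n_dropped, 0)
  pr <- extract_pairs(p2)
  expect_equal(f_miss$relapse$n_dropped,
               sum(pr$y_prev == 0 & pr$id %in% 1:2))
  expect_equal(f_miss$n_pairs, f_full$n_pairs - sum(pr$id %in% 1:2 &
                                                      pr$y_prev == 0))
})

test_that("rank-deficient designs raise an error naming the column", {
  pr <- tibble::tibble(id = 1:10, time = 1L, y_prev = 1L,
                       y_curr = rep(c(0L, 1L), 5), x = 1)
  expect_error(fit_transition(pr, model_spec(abstinence = "x")),
               "rank deficient.*x")
})

test_that("odds ratios reproduce the exp(contrast) arithmetic", {
  pub <- dplyr::filter(kanquit_estimates(), analysis == "available")
  f <- as_transition_fit(pub)
  expect_equal(round(odds_ratio(f, c(HDM = 1), model = "abstinence")$or, 2),
               1.48)
  expect_equal(round(odds_ratio(f, c(HDM = 1, MDM = -1),
                                model = "abstinence")$or, 2), 1.40)
  expect_equal(odds_ratio(f, c(HDM = 0), model = "abstinence")$or, 1)
  expect_error(odds_ratio(f, c(nope = 1), model = "abstinence"),
               "unknown coefficient")
})

test_that("Wald z tests give two-sided normal p-values", {
  pub <- dplyr::filter(kanquit_estimates(), analysis == "available")
  f <- as_transition_fit(pub)
  w <- wald_test(f, c(HDM = 1), model = "abstinence")
  expect_equal(w$type, "Wald-z")
  expect_equal(round(w$p.value, 3), 0.013)
  # a zero estimate has p = 1 regardless of its SE
  f0 <- as_transition_fit(tibble::tibble(
    model = "abstinence", term = c("(Intercept)", "z"),
    estimate = c(-1, 0), std.error = c(0.5, 0.4)
  ))
  expect_equal(wald_test(f0, c(z = 1), model = "abstinence")$p.value, 1)
})

test_that("multi-row Wald F equals the quadratic form computed directly", {
  p <- simulate_cohort(kanquit_truth(N = 300, missingness = "none"), seed = 17)
  f <- fit_transition(p, kanquit_spec())
  w <- wald_test(f, rbind(c(MDM = 1, HDM = 0), c(MDM = 0, HDM = 1)),
                 model = "abstinence")
  # independent quadratic-form computation from coef/vcov
  cf <- coef(f)
  V <- vcov(f)
  idx <- c("abstinence:MDM", "abstinence:HDM")
  b <- cf[idx]
  Fref <- drop(t(b) %*% solve(V[idx, idx]) %*% b) / 2
  expect_equal(w$statistic, Fref, tolerance = 1e-10)
  expect_equal(w$df_num, 2L)
  expect_equal(w$df_den, f$n_pairs)
  expect_equal(w$p.value, pf(Fref, 2, f$n_pairs, lower.tail = FALSE))
  expect_error(wald_test(f, rbind(c(MDM = 1), c(MDM = 2)), model = "abstinence"),
               "rank deficient")
})

test_that("BIC arithmetic and model ranking behave as defined", {
  fake <- list(loglik = -100, n_pairs = 100L,
               abstinence = list(coefficients = c(a = 1, b = 2, c = 3),
                                 vcov = diag(3)))
  class(fake) <- "transition_fit"
  expect_equal(bic(fake), 200 + 3 * log(100), tolerance = 1e-10)
  expect_equal(bic(fake), 213.8155, tolerance = 1e-4)
  # identical specs give identical BIC through the comparison helper
  p <- simulate_cohort(kanquit_truth(N = 100, missingness = "none"), seed = 2)
  s <- kanquit_spec()
  cmp <- compare_bic(p, list(a = s, b = s))
  expect_equal(cmp$BIC[1], cmp$BIC[2])
})

test_that("adding a pure-noise covariate usually raises BIC", {
  base_truth <- cohort_truth(
    N = 150, n_times = 2,
    beta_abstinence = c(`(Intercept)` = -1, x = 0.8),
    beta_relapse = c(`(Intercept)` = -0.5),
    covariates = list(x = function(n) rnorm(n),
                      noise = function(n) rnorm(n))
  )
  s_true <- model_spec(abstinence = "x", relapse = character())
  s_noise <- model_spec(abstinence = c("x", "noise"), relapse = character())
  set.seed(314)
  worse <- vapply(1:100, function(i) {
    p <- simulate_cohort(base_truth)
    f1 <- fit_transition(p, s_true)
    f2 <- fit_transition(p, s_noise)
    bic(f2) > bic(f1)
  }, logical(1))
  expect_gte(mean(worse), 0.8)
})
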