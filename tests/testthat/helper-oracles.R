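# Independent oracle implementations used to cross-check the package.
# Deliberately written as plain loops over probabilities, sharing no code
# with the package's vectorised/log-space implementations.

# linear predictor for one occasion, written out by hand
oracle_lp <- function(coefs, covs, time = NULL, extra = NULL) {
  lp <- coefs[["(Intercept)"]]
  for (nm in names(coefs)) {
    if (nm == "(Intercept)") next
    val <- if (grepl("^time[0-9]+$", nm)) {
      as.numeric(time == as.integer(sub("time", "", nm)))
    } else if (!is.null(extra) && nm %in% names(extra)) {
      extra[[nm]]
    } else {
      covs[[nm]]
    }
    lp <- lp + coefs[[nm]] * val
  }
  lp
}

# complete-data likelihood (not log) of one subject by direct products
oracle_subject_lik <- function(y, r, covs, theta, spec) {
  Tn <- length(y) - 1L
  lik <- 1
  for (t in seq_len(Tn)) {
    r_prev <- if (t == 1) 1 else r[t - 1]
    lam <- plogis(oracle_lp(theta$missing, covs, time = t,
                            extra = list(r_prev = r_prev,
                                         y_prev = y[t], y_curr = y[t + 1])))
    lik <- lik * if (r[t] == 1) lam else (1 - lam)
    if (y[t] == 1) {
      pq <- plogis(oracle_lp(theta$abstinence, covs, time = t))
      lik <- lik * if (y[t + 1] == 0) pq else (1 - pq)
    } else {
      pr <- plogis(oracle_lp(theta$relapse, covs, time = t))
      lik <- lik * if (y[t + 1] == 1) pr else (1 - pr)
    }
  }
  lik
}

# enumerate completions of one subject; returns likelihood per completion
oracle_completions <- function(y, covs, theta, spec) {
  Tn <- length(y) - 1L
  r <- as.integer(!is.na(y[-1]))
  mis <- which(is.na(y[-1]))
  if (length(mis) == 0) {
    return(list(comps = matrix(y, 1), lik = oracle_subject_lik(y, r, covs,
                                                               theta, spec)))
  }
  grid <- as.matrix(expand.grid(rep(list(0:1), length(mis))))
  comps <- matrix(rep(y, each = nrow(grid)), nrow = nrow(grid))
  comps[, mis + 1L] <- grid
  lik <- apply(comps, 1, oracle_subject_lik, r = r, covs = covs,
               theta = theta, spec = spec)
  list(comps = comps, lik = lik)
}

# observed-data log-likelihood of a panel by brute-force enumeration
oracle_obs_loglik <- function(panel, theta, spec) {
  Tn <- attr(panel, "n_times")
  covs <- attr(panel, "covariates")
  total <- 0
  for (sid in unique(panel$id)) {
    rows <- panel[panel$id == sid, ]
    rows <- rows[order(rows$time), ]
    y <- rows$status
    cv <- as.list(rows[1, covs, drop = FALSE])
    en <- oracle_completions(y, cv, theta, spec)
    total <- total + log(sum(en$lik))
  }
  total
}

# small deterministic fixture: 3 subjects, T = 2, one missing outcome
toy_panel <- function() {
  as_smoke_panel(tibble::tibble(
    id = rep(c("a", "b", "c"), each = 3),
    time = rep(0:2, 3),
    status = c(1, 1, 0,
               1, 0, 1,
               1, NA, 1),
    x = rep(c(-0.5, 0.2, 1.1), each = 3)
  ))
}

toy_theta <- function() {
  list(abstinence = c(`(Intercept)` = -0.4, x = 0.3),
       relapse = c(`(Intercept)` = -1.0, x = -0.2),
       missing = c(`(Intercept)` = 0.5, r_prev = 1.0,
                   y_prev = -0.3, y_curr = -0.6))
}

toy_spec <- function() {
  model_spec(abstinence = "x", relapse = "x",
             missing = c("r_prev", "y_prev", "y_curr"))
}

# deterministic 10-subject, T = 2 panel with scattered missingness for the
# direct-maximisation comparison
small_em_panel <- function() {
  status <- c(1, 1, 1,
              1, 1, 0,
              1, 0, 0,
              1, 0, 1,
              1, NA, 1,
              1, NA, NA,
              1, 1, NA,
              1, 0, NA,
              1, 1, 1,
              1, 0, 0)
  as_smoke_panel(tibble::tibble(
    id = rep(1:10, each = 3),
    time = rep(0:2, 10),
    status = status,
    x = rep(c(0.8, -1.2, 0.3, 1.5, -0.7, 0.1, 0.9, -0.4, -1.0, 0.6),
            each = 3)
  ))
}
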