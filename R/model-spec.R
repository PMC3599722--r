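#' Specify the three linear predictors of the joint model
#'
#' A model spec names the covariates entering each of the three logistic
#' submodels: the abstinence model (probability of quitting given smoking
#' at the previous assessment), the relapse model (probability of smoking
#' given abstinent), and the non-response model. An intercept is always
#' included and never listed.
#'
#' Term syntax:
#' * any baseline covariate column name in the panel (e.g. `"HDM"`,
#'   `"cpd"`);
#' * `"time<k>"` — a time dummy, the indicator `I(time == k)`; the
#'   reference occasion is whichever times carry no dummy;
#' * in the missing model only: `"r_prev"` (response indicator at the
#'   previous occasion), `"y_prev"` and `"y_curr"` (previous and current
#'   smoking status, the latter possibly unobserved — its coefficient is
#'   what makes the mechanism non-ignorable).
#'
#' @param abstinence,relapse Character vectors of terms for the two
#'   transition submodels. They may differ: covariates are allowed
#'   different effects in the two directions.
#' @param missing Character vector of terms for the non-response model.
#' @param time_ref Reference time index for display purposes (default 1,
#'   the first follow-up).
#' @return An object of class `transition_spec`.
#' @export
#' @examples
#' model_spec(abstinence = c("HDM", "MDM"), relapse = c("time3", "time4"))
model_spec <- function(abstinence = character(),
                       relapse = character(),
                       missing = c("r_prev", "y_prev", "y_curr"),
                       time_ref = 1L) {
  chk <- function(x, nm) {
    if (!is.character(x)) stop("`", nm, "` must be a character vector",
                               call. = FALSE)
    if (anyDuplicated(x)) stop("duplicate terms in `", nm, "`", call. = FALSE)
    x
  }
  special <- c("r_prev", "y_prev", "y_curr")
  for (nm in c("abstinence", "relapse")) {
    x <- get(nm)
    if (any(x %in% special)) {
      stop("term(s) ", paste(intersect(x, special), collapse = ", "),
           " are only meaningful in the missing model", call. = FALSE)
    }
  }
  structure(list(abstinence = chk(abstinence, "abstinence"),
                 relapse = chk(relapse, "relapse"),
                 missing = chk(missing, "missing"),
                 time_ref = as.integer(time_ref)),
            class = "transition_spec")
}

#' @export
print.transition_spec <- function(x, ...) {
  cat("<transition_spec>\n")
  for (nm in c("abstinence", "relapse", "missing")) {
    cat("  ", format(nm, width = 10), ": 1",
        if (length(x[[nm]])) paste(" +", paste(x[[nm]], collapse = " + ")),
        "\n", sep = "")
  }
  invisible(x)
}

#' Read a model spec from a YAML file
#'
#' The file holds up to four keys: `abstinence`, `relapse` and `missing`
#' (lists of term names) and `time_ref` (an integer).
#'
#' @param path Path to a YAML file.
#' @return A [model_spec()] object.
#' @export
read_model_spec <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  model_spec(
    abstinence = as.character(y$abstinence %||% character()),
    relapse = as.character(y$relapse %||% character()),
    missing = as.character(y$missing %||% c("r_prev", "y_prev", "y_curr")),
    time_ref = y$time_ref %||% 1L
  )
}

#' The default KanQuit-style model specification
#'
#' The specification selected by BIC for a three-arm disease-management
#' cessation trial: arm indicators plus gender, cigarettes per day,
#' motivation, confidence and serious quit attempt in the abstinence
#' model; time dummies for the third and fourth follow-up plus arm,
#' income and nicotine-dependence indicators in the relapse model (no
#' relapse is possible at the first follow-up because everyone smokes at
#' baseline, and the second follow-up is the reference); previous
#' response and previous/current smoking status in the missing model.
#'
#' @param missing One of `"outcome"` (response depends on previous
#'   response and previous/current smoking status), `"outcome+design"`
#'   (additionally on time dummies and arm), or `"rprev"` (previous
#'   response only — an ignorable mechanism).
#' @return A [model_spec()] object.
#' @export
kanquit_spec <- function(missing = c("outcome", "outcome+design", "rprev")) {
  missing <- match.arg(missing)
  mis <- switch(missing,
    "rprev" = "r_prev",
    "outcome" = c("r_prev", "y_prev", "y_curr"),
    "outcome+design" = c("time2", "time3", "time4", "MDM", "HDM",
                         "r_prev", "y_prev", "y_curr")
  )
  model_spec(
    abstinence = c("MDM", "HDM", "male", "cpd", "motivation",
                   "confidence", "sqa"),
    relapse = c("time3", "time4", "MDM", "HDM", "income_gt40k", "dep5min"),
    missing = mis,
    time_ref = 1L
  )
}

# Build the design matrix for one submodel from a data frame that carries
# the covariate columns, a `time` column for the time dummies, and (for
# the missing model) r_prev / y_prev / y_curr columns.
build_design <- function(data, terms) {
  n <- nrow(data)
  cols <- list("(Intercept)" = rep(1, n))
  for (tm in terms) {
    if (grepl("^time[0-9]+$", tm)) {
      k <- as.integer(sub("^time", "", tm))
      cols[[tm]] <- as.numeric(data$time == k)
    } else if (tm %in% names(data)) {
      cols[[tm]] <- as.numeric(data[[tm]])
    } else {
      stop("unknown model term `", tm, "`: not a panel column or time dummy",
           call. = FALSE)
    }
  }
  do.call(cbind, cols)
}
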