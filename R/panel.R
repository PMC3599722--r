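#' Construct a validated smoking-status panel
#'
#' A smoking panel is a long-format tibble with one row per subject and
#' assessment time, holding a binary smoking status (1 = smoking,
#' 0 = abstinent, `NA` = non-response) and baseline covariates repeated
#' down each subject's rows. Every subject must be observed smoking at
#' enrollment (`time == 0`), the design assumption of a cessation trial
#' that enrolls current smokers only.
#'
#' @param data A data frame with columns `id`, `time`, `status`, plus any
#'   number of numeric baseline covariate columns (e.g. arm indicators
#'   `MDM`/`HDM`, demographics, smoking characteristics).
#' @param n_times Number of follow-up occasions `T`; defaults to
#'   `max(data$time)`. Each subject must have exactly the rows
#'   `time = 0, 1, ..., n_times`.
#' @param time_unit_label Label for one time step (display only).
#'
#' @return A tibble of class `smoke_panel`, sorted by `id` then `time`,
#'   with attributes `n_times`, `time_unit_label` and `covariates` (the
#'   covariate column names).
#' @export
#' @examples
#' df <- tibble::tibble(
#'   id = rep(1:2, each = 3), time = rep(0:2, 2),
#'   status = c(1, 0, 0, 1, 1, NA), arm = rep(c(0, 1), each = 3)
#' )
#' as_smoke_panel(df)
as_smoke_panel <- function(data, n_times = NULL, time_unit_label = "6 months") {
  data <- tibble::as_tibble(data)
  need <- c("id", "time", "status")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("panel is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(data$time) || any(data$time %% 1 != 0)) {
    stop("`time` must be integer-valued", call. = FALSE)
  }
  data$time <- as.integer(data$time)
  bad_status <- !is.na(data$status) & !data$status %in% c(0, 1)
  if (any(bad_status)) {
    stop("`status` must be 0, 1 or NA; offending row(s): ",
         paste(utils::head(which(bad_status), 5), collapse = ", "),
         call. = FALSE)
  }
  data$status <- as.integer(data$status)
  if (is.null(n_times)) n_times <- max(data$time)
  n_times <- as.integer(n_times)
  if (n_times < 1) stop("need at least one follow-up occasion", call. = FALSE)

  dup <- duplicated(data[c("id", "time")])
  if (any(dup)) {
    stop("duplicate (id, time) row(s), e.g. id=",
         data$id[which(dup)[1]], " time=", data$time[which(dup)[1]],
         call. = FALSE)
  }
  counts <- dplyr::count(data, .data$id)
  slots <- dplyr::summarise(
    dplyr::group_by(data, .data$id),
    ok = length(.data$time) == n_times + 1L &&
      setequal(.data$time, 0:n_times),
    .groups = "drop"
  )
  if (any(!slots$ok)) {
    stop("subject(s) without exactly the time slots 0..", n_times, ": ",
         paste(utils::head(slots$id[!slots$ok], 5), collapse = ", "),
         call. = FALSE)
  }

  base <- data[data$time == 0L, ]
  bad0 <- is.na(base$status) | base$status != 1L
  if (any(bad0)) {
    stop("baseline (time 0) status must be observed and equal 1: all ",
         "participants are smokers at enrollment. Offending subject(s): ",
         paste(utils::head(base$id[bad0], 5), collapse = ", "),
         call. = FALSE)
  }

  covs <- setdiff(names(data), need)
  for (cv in covs) {
    if (!is.numeric(data[[cv]])) {
      stop("covariate `", cv, "` must be numeric (code factors as 0/1 ",
           "indicators)", call. = FALSE)
    }
    rng <- dplyr::summarise(
      dplyr::group_by(data, .data$id),
      varying = dplyr::n_distinct(.data[[cv]]) > 1L, .groups = "drop"
    )
    if (any(rng$varying)) {
      stop("covariate `", cv, "` varies within subject; only baseline ",
           "(time-constant) covariates are supported — time effects are ",
           "expressed through time dummies in the model spec", call. = FALSE)
    }
  }
  if (all(c("MDM", "HDM") %in% covs)) {
    both <- data$MDM == 1 & data$HDM == 1
    if (any(both, na.rm = TRUE)) {
      stop("arm indicators MDM and HDM must be mutually exclusive",
           call. = FALSE)
    }
  }

  out <- dplyr::arrange(data, .data$id, .data$time)
  structure(out,
            class = c("smoke_panel", class(tibble::tibble())),
            n_times = n_times,
            time_unit_label = time_unit_label,
            covariates = covs)
}

#' @export
print.smoke_panel <- function(x, ...) {
  nt <- attr(x, "n_times")
  cat("<smoke_panel> ", dplyr::n_distinct(x$id), " subjects, T = ", nt,
      " follow-ups (", attr(x, "time_unit_label"), " apart), ",
      "missing follow-up fraction ", sprintf("%.3f", missing_fraction(x)),
      "\n", sep = "")
  NextMethod()
}

# dplyr verbs strip attributes; re-derive them when we need a panel again
panel_attrs <- function(panel) {
  list(n_times = attr(panel, "n_times"),
       time_unit_label = attr(panel, "time_unit_label"),
       covariates = attr(panel, "covariates"))
}

#' Read a long-format smoking panel from CSV
#'
#' Expected columns: a subject identifier, an integer time index starting
#' at 0, a smoking status, and optional numeric baseline covariates.
#' Missing statuses may be blank fields or the literal token `NA`.
#'
#' @param path Path to a CSV file.
#' @param schema Named character vector mapping the canonical names
#'   `id`, `time`, `status` to the column names used in the file.
#' @param status_map Named vector mapping the file's status codes to the
#'   internal convention 1 = smoking, 0 = abstinent.
#' @param n_times,time_unit_label Passed to [as_smoke_panel()].
#'
#' @return A validated [as_smoke_panel()] tibble.
#' @export
read_panel <- function(path,
                       schema = c(id = "id", time = "time", status = "status"),
                       status_map = c(`0` = 0, `1` = 1),
                       n_times = NULL, time_unit_label = "6 months") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, na = c("", "NA"), show_col_types = FALSE,
                         progress = FALSE)
  miss <- setdiff(unname(schema), names(raw))
  if (length(miss)) {
    stop("CSV lacks required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  names(raw)[match(unname(schema), names(raw))] <- names(schema)
  st <- as.character(raw$status)
  unknown <- !is.na(st) & !st %in% names(status_map)
  if (any(unknown)) {
    stop("unrecognised status value(s) in row(s): ",
         paste(utils::head(which(unknown) + 1L, 5), collapse = ", "),
         " (add them to `status_map`)", call. = FALSE)
  }
  raw$status <- unname(status_map[st])
  as_smoke_panel(raw, n_times = n_times, time_unit_label = time_unit_label)
}

#' Write a smoking panel to CSV
#'
#' Missing statuses are written as empty fields, the format [read_panel()]
#' reads back; a write/read cycle round-trips the panel exactly.
#'
#' @param panel A `smoke_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  readr::write_csv(tibble::as_tibble(panel), path, na = "", progress = FALSE)
  invisible(path)
}

#' Fraction of missing follow-up outcomes
#'
#' The proportion of the `N * T` scheduled follow-up assessments with no
#' response. Baseline is excluded from both numerator and denominator
#' because it is observed by design.
#'
#' @param panel A `smoke_panel`.
#' @return A proportion in `[0, 1]`.
#' @export
#' @examples
#' truth <- kanquit_truth(N = 100)
#' missing_fraction(simulate_cohort(truth, seed = 1))
missing_fraction <- function(panel) {
  fu <- panel[panel$time > 0L, ]
  mean(is.na(fu$status))
}

#' Extract consecutive transition pairs from a panel
#'
#' Emits one record per consecutive pair of *observed* outcomes
#' (available-data analysis): an intermittent missing value breaks both
#' pairs it touches. Pairs with a smoking previous state feed the
#' abstinence (cessation) submodel; pairs with an abstinent previous
#' state feed the relapse submodel.
#'
#' @param panel A `smoke_panel`.
#' @return A tibble with columns `id`, `time` (time of the current
#'   outcome, 1..T), `y_prev`, `y_curr`, and the panel's baseline
#'   covariate columns.
#' @export
#' @examples
#' df <- tibble::tibble(id = 1, time = 0:2, status = c(1, 1, 0))
#' extract_pairs(as_smoke_panel(df))
extract_pairs <- function(panel) {
  covs <- attr(panel, "covariates")
  out <- panel |>
    dplyr::arrange(.data$id, .data$time) |>
    dplyr::mutate(
      y_prev = dplyr::lag(.data$status),
      same_subject = dplyr::lag(.data$id) == .data$id
    ) |>
    dplyr::filter(.data$time > 0L, .data$same_subject,
                  !is.na(.data$status), !is.na(.data$y_prev)) |>
    dplyr::rename(y_curr = "status") |>
    dplyr::select(dplyr::all_of(c("id", "time", "y_prev", "y_curr", covs)))
  out
}

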