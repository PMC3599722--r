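#' Render a multi-column coefficient report
#'
#' Assembles one or more fitted models into the familiar three-column
#' sensitivity-analysis layout (one column per analysis; estimate, SE,
#' p-value per row; odds ratios alongside, rounded to 2 decimals for
#' display) plus optional crude transition matrices. Rendering is pure:
#' every number is read from the fitted objects, never recomputed, and
#' the machine-readable formats keep full precision while rounding is
#' applied in the text rendering only.
#'
#' @param fits A single fit or a named list of `transition_fit` /
#'   `em_fit` objects (the columns).
#' @param boot Optional named list of `transition_boot` objects,
#'   parallel to `fits`, supplying SEs/p-values for EM columns.
#' @param matrices Optional `transition_matrix` to append.
#' @param format `"text"`, `"csv"` or `"json"`.
#' @param file Optional path; when given, the rendered artifact is
#'   written there.
#' @return A `markov_report`: list with the long `table` tibble, the
#'   matrices, and the rendered `text` lines. When `format = "json"`
#'   the JSON string round-trips to numerically identical values.
#' @export
render_report <- function(fits, boot = NULL, matrices = NULL,
                          format = c("text", "csv", "json"), file = NULL) {
  format <- match.arg(format)
  if (inherits(fits, "transition_fit")) fits <- list(fit = fits)
  stopifnot(length(fits) >= 1)
  if (is.null(names(fits))) names(fits) <- paste0("fit", seq_along(fits))

  col_tidy <- function(nm) {
    f <- fits[[nm]]
    b <- if (!is.null(boot)) boot[[nm]]
    td <- if (inherits(f, "em_fit")) tidy(f, boot = b) else tidy(f)
    td$analysis <- nm
    td
  }
  long <- purrr::map_dfr(names(fits), col_tidy)

  # transition submodels must agree across columns for a side-by-side table
  for (m in c("abstinence", "relapse")) {
    sets <- lapply(split(long[long$model == m, ], long$analysis[long$model == m]),
                   function(d) d$term)
    sets <- Filter(length, sets)
    if (length(sets) > 1 &&
        !all(vapply(sets[-1], setequal, TRUE, y = sets[[1]]))) {
      stop("conflicting ", m, " parameter sets across report columns",
           call. = FALSE)
    }
  }

  txt <- render_text(long, names(fits), matrices)
  out <- structure(list(table = long, matrices = matrices, text = txt,
                        format = format),
                   class = "markov_report")
  if (!is.null(file)) {
    switch(format,
      text = writeLines(txt, file),
      csv = readr::write_csv(long, file, progress = FALSE),
      json = jsonlite::write_json(
        list(table = long,
             matrices = if (!is.null(matrices))
               tibble::as_tibble(matrices)),
        file, digits = NA, auto_unbox = TRUE)
    )
  }
  out
}

fmt_num <- function(x, digits = 3) {
  ifelse(is.na(x), "--", formatC(x, digits = digits, format = "f"))
}

render_text <- function(long, columns, matrices) {
  lines <- c("Transition model estimates (estimate / SE / p; OR in brackets)",
             strrep("=", 64))
  has_se <- "std.error" %in% names(long)
  has_p <- "p.value" %in% names(long)
  for (m in intersect(c("abstinence", "relapse", "missing"),
                      unique(long$model))) {
    lines <- c(lines, "", switch(m,
      abstinence = "From smoking to abstinent (abstinence model)",
      relapse = "From abstinent to smoking (relapse model)",
      missing = "Missing model"))
    terms <- unique(long$term[long$model == m])
    for (tm in terms) {
      cells <- vapply(columns, function(cl) {
        d <- long[long$model == m & long$term == tm & long$analysis == cl, ]
        if (nrow(d) == 0) return("   --")
        paste0(
          fmt_num(d$estimate),
          if (has_se) paste0(" / ", fmt_num(d$std.error)),
          if (has_p) paste0(" / ", fmt_num(d$p.value)),
          " [OR ", fmt_num(exp(d$estimate), 2), "]"
        )
      }, "")
      lines <- c(lines, sprintf("  %-14s %s", tm,
                                paste(cells, collapse = "  | ")))
    }
  }
  if (!is.null(matrices)) {
    lines <- c(lines, "", "Crude transition matrices",
               utils::capture.output(print(matrices)))
  }
  lines
}

#' @export
print.markov_report <- function(x, ...) {
  writeLines(x$text)
  invisible(x)
}
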