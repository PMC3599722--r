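#' Crude transition matrices from observed pairs
#'
#' Counts observed transitions between the two states and converts each
#' row of counts to probabilities. With `by_time = TRUE` a separate
#' matrix is produced per follow-up interval (the time-inhomogeneous
#' description of the chain); an optional grouping column (e.g. a
#' treatment-arm label) crosses the tabulation further. Rows with no
#' observations get `NA` probabilities (undefined, not 0/0): at the first
#' follow-up the abstinent row is always empty because every subject
#' smokes at baseline.
#'
#' @param pairs A tibble of transition pairs from [extract_pairs()].
#' @param by_time Tabulate each follow-up interval separately?
#' @param by Optional name of a grouping column present in `pairs`.
#' @return A tibble of class `transition_matrix` with columns
#'   (optionally `time` and the grouping column) `from`, `to`, `n`,
#'   `prob`.
#' @export
#' @examples
#' p <- tibble::tibble(id = 1:4, time = 1, y_prev = 1,
#'                     y_curr = c(1, 1, 1, 0))
#' crude_matrix(p)
crude_matrix <- function(pairs, by_time = FALSE, by = NULL) {
  if (nrow(pairs) == 0) stop("no transition pairs supplied", call. = FALSE)
  keys <- c(if (!is.null(by)) by, if (by_time) "time")
  if (!is.null(by) && !by %in% names(pairs)) {
    stop("grouping column `", by, "` not found", call. = FALSE)
  }
  out <- pairs |>
    dplyr::count(dplyr::across(dplyr::all_of(keys)),
                 from = .data$y_prev, to = .data$y_curr) |>
    tidyr::complete(
      tidyr::nesting(!!!rlang::syms(keys)),
      from = c(0L, 1L), to = c(0L, 1L),
      fill = list(n = 0L)
    ) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "from")))) |>
    dplyr::mutate(
      prob = if (sum(.data$n) > 0) .data$n / sum(.data$n) else NA_real_
    ) |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(keys, "from", "to"))))
  class(out) <- c("transition_matrix", class(out))
  out
}

state_label <- function(s) ifelse(s == 0, "abstinent", "smoking")

#' @export
print.transition_matrix <- function(x, digits = 3, ...) {
  keys <- setdiff(names(x), c("from", "to", "n", "prob"))
  groups <- if (length(keys)) {
    split(x, x[keys], drop = TRUE)
  } else {
    list(x)
  }
  if (any(vapply(groups, nrow, 0L) != 4L)) {
    # not a complete set of 2x2 cells (e.g. a filtered subset): plain print
    NextMethod()
    return(invisible(x))
  }
  for (g in groups) {
    if (length(keys)) {
      hdr <- paste(keys, vapply(g[1, keys, drop = FALSE], as.character, ""),
                   sep = " = ", collapse = ", ")
      cat(hdr, "\n")
    }
    m <- matrix(g$prob[order(g$from, g$to)], 2, 2, byrow = TRUE,
                dimnames = list(paste("from", state_label(0:1)),
                                paste("to", state_label(0:1))))
    und <- apply(is.na(m), 1, all)
    print(round(m, digits))
    if (any(und)) {
      cat("  (", paste(rownames(m)[und], collapse = ", "),
          ": no observations, row undefined)\n", sep = "")
    }
    cat("\n")
  }
  invisible(x)
}

#' @rdname crude_matrix
#' @param object,x A `transition_matrix`.
#' @param ... Unused.
#' @export
autoplot.transition_matrix <- function(object, ...) {
  keys <- setdiff(names(object), c("from", "to", "n", "prob"))
  p <- ggplot2::ggplot(
    object,
    ggplot2::aes(x = state_label(.data$to), y = state_label(.data$from),
                 fill = .data$prob)
  ) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$prob), "--", sprintf("%.2f", .data$prob))
    )) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1), na.value = "grey90") +
    ggplot2::labs(x = "current state", y = "previous state",
                  fill = "probability")
  if (length(keys)) {
    p <- p + ggplot2::facet_wrap(keys)
  }
  p
}
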