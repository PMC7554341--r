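# Broom-style tidiers and plots for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a propagation result
#'
#' One row per component: `status` is `"frozen"`, `"free"` or `"input"`
#' (unclamped inputs), `level` the frozen level (`NA` otherwise) and
#' `residual` the simplified rule text of free non-input components.
#'
#' @param x A `propagation_result`.
#' @param ... Unused.
#' @return A tibble with columns `component`, `status`, `level`, `residual`.
#' @exportS3Method generics::tidy
tidy.propagation_result <- function(x, ...) {
  model <- x$model
  comps <- component_names(model)
  ml <- max_levels(model)
  inputs <- input_names(model)
  status <- ifelse(comps %in% names(x$frozen), "frozen",
    ifelse(comps %in% inputs, "input", "free")
  )
  tibble::tibble(
    component = comps,
    status = status,
    level = vapply(comps, function(cn) {
      if (cn %in% names(x$frozen)) x$frozen[[cn]] else NA_integer_
    }, integer(1), USE.NAMES = FALSE),
    residual = vapply(comps, function(cn) {
      if (cn %in% names(x$residuals)) {
        deparse_function(x$residuals[[cn]], ml[[cn]])
      } else {
        NA_character_
      }
    }, character(1), USE.NAMES = FALSE)
  )
}

#' Summarise a propagation result
#'
#' @param x A `propagation_result`.
#' @param ... Unused.
#' @return One-row tibble: clamp count plus the [tally_propagation()] counts
#'   over non-input components.
#' @exportS3Method generics::glance
glance.propagation_result <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(n_clamps = length(x$clamps)), tally_propagation(x))
}

#' Tidy a differential propagation comparison
#'
#' @param x A `propagation_comparison`.
#' @param ... Unused.
#' @return A tibble with one row per component: `input`, the frozen level
#'   under each condition (`NA` = free) and the differential `category`.
#' @exportS3Method generics::tidy
tidy.propagation_comparison <- function(x, ...) x$components

#' Summarise a differential comparison
#'
#' @param x A `propagation_comparison`.
#' @param ... Unused.
#' @return The 3x3 [comparison_table()] pivoted to one row.
#' @exportS3Method generics::glance
glance.propagation_comparison <- function(x, ...) {
  tab <- comparison_table(x)
  out <- as.list(stats::setNames(
    c(tab$A, tab$B, tab$intersection),
    c(paste0(tab$impact, "_a"), paste0(tab$impact, "_b"), paste0(tab$impact, "_both"))
  ))
  tibble::as_tibble(out)
}

#' Plot a differential propagation comparison
#'
#' Bar chart of component counts per differential category, coloured with the
#' same palette as the annotated graph export.
#'
#' @param object A `propagation_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.propagation_comparison <- function(object, ...) {
  d <- dplyr::count(object$components, .data$category)
  d$category <- factor(d$category, levels = names(CATEGORY_FILL))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$n, fill = .data$category)) +
    ggplot2::geom_col(colour = "gray30", show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = CATEGORY_FILL, drop = FALSE) +
    ggplot2::scale_x_discrete(drop = FALSE) +
    ggplot2::labs(
      x = NULL, y = "components",
      title = "Differential impact of two propagated perturbations"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 35, hjust = 1))
}

#' Tidy a verification report
#'
#' @param x A `verification_report`.
#' @param ... Unused.
#' @return A tibble with one row per case: `case`, `status`, `n_solutions`,
#'   and the first failure reason (`NA` for passing cases).
#' @exportS3Method generics::tidy
tidy.verification_report <- function(x, ...) {
  tibble::tibble(
    case = vapply(x$results, `[[`, character(1), "name"),
    status = vapply(x$results, `[[`, character(1), "status"),
    n_solutions = vapply(x$results, `[[`, integer(1), "n_solutions"),
    reason = vapply(x$results, function(r) {
      if (nrow(r$diagnostics)) r$diagnostics$reason[[1L]] else NA_character_
    }, character(1))
  )
}

#' Summarise a verification report
#'
#' @param x A `verification_report`.
#' @param ... Unused.
#' @return One-row tibble with `pass`, `fail`, `vacuous`, `error`, `total`.
#' @exportS3Method generics::glance
glance.verification_report <- function(x, ...) report_totals(x)

#' Plot a verification report
#'
#' @param object A `verification_report`.
#' @param ... Unused.
#' @return A ggplot object: one tile per case, coloured by status.
#' @exportS3Method ggplot2::autoplot
autoplot.verification_report <- function(object, ...) {
  d <- tidy(object)
  d$case <- factor(d$case, levels = rev(d$case))
  d$status <- factor(d$status, levels = c("pass", "fail", "vacuous", "error"))
  ggplot2::ggplot(d, ggplot2::aes(x = 1, y = .data$case, fill = .data$status)) +
    ggplot2::geom_tile(colour = "white", linewidth = 1) +
    ggplot2::scale_fill_manual(
      values = c(pass = "#2e7d32", fail = "#c62828", vacuous = "#f9a825", error = "#6a1b9a"),
      drop = FALSE
    ) +
    ggplot2::labs(x = NULL, y = NULL, fill = "status", title = object$suite) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
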