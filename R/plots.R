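#' Plot the exclusion tally of a cohort build
#'
#' Horizontal bars of the attrition flow: the input count, each exclusion
#' criterion in application order, and the included count.
#'
#' @param object A `cohort`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cohort <- function(object, ...) {
  flow <- bind_rows(
    tibble(step = "input patients", n = object$n_input),
    object$exclusions |> transmute(step = .data$criterion, n = .data$n),
    tibble(step = "included", n = nrow(object$members))) |>
    mutate(step = factor(.data$step, levels = rev(.data$step)))
  ggplot2::ggplot(flow, ggplot2::aes(x = .data$n, y = .data$step)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), hjust = -0.1,
                       size = 3) +
    ggplot2::labs(x = "patients", y = NULL,
                  title = paste0(object$spec$disease, " cohort ('",
                                 object$profile$name, "')")) +
    ggplot2::theme_minimal()
}

#' Plot the frequency tables of a cohort description
#' @param object A `cohort_description`.
#' @param ... Unused.
#' @return A ggplot faceted by variable.
#' @export
autoplot.cohort_description <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$level, y = .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~variable, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "% of cohort",
                  title = paste0(object$disease, " cohort at ",
                                 format(object$index_date))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot the age-at-first-mention distribution by sex
#' @param cohort A `cohort`, or a precomputed distribution from
#'   [age_at_first_mention_distribution()].
#' @param ... Passed to [age_at_first_mention_distribution()] when a
#'   cohort is given.
#' @return A ggplot.
#' @export
plot_age_at_first_mention <- function(cohort, ...) {
  dist <- if (inherits(cohort, "cohort")) {
    age_at_first_mention_distribution(cohort, ...)
  } else {
    cohort
  }
  ggplot2::ggplot(dist, ggplot2::aes(x = .data$age, y = .data$proportion,
                                     colour = .data$sex)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "age at first mention (years)",
                  y = "% of sex stratum", colour = NULL) +
    ggplot2::theme_minimal()
}
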