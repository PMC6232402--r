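#' Step plot of survival curves by mortality dataset version
#'
#' Overlays Kaplan-Meier curves — typically the stepwise composite
#' versions plus the gold standard — to visualise how incomplete mortality
#' capture inflates survival.
#'
#' @param curves Named list of `"mort_km"` curves.
#' @param time_unit `"months"` (days / 30.4375) or `"days"`.
#' @param censor_marks Draw tick marks at censoring times.
#' @return A ggplot object.
#' @export
plot_km_curves <- function(curves, time_unit = c("months", "days"),
                           censor_marks = FALSE) {
  time_unit <- match.arg(time_unit)
  div <- if (time_unit == "months") 30.4375 else 1
  df <- purrr::imap(curves, function(cv, label) {
    tibble(dataset = label, time = c(0, cv$time) / div,
           surv = c(1, cv$surv),
           n_censor = c(0, cv$n_censor))
  }) %>%
    bind_rows() %>%
    mutate(dataset = factor(.data$dataset, levels = names(curves)))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$surv,
                                        colour = .data$dataset)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = sprintf("Time from advanced diagnosis (%s)", time_unit),
                  y = "Overall survival", colour = "Mortality data") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
  if (censor_marks) {
    p <- p + ggplot2::geom_point(data = df %>% filter(.data$n_censor > 0),
                                 shape = 3, size = 1)
  }
  p
}

#' @export
autoplot.mort_km <- function(object, ...) {
  plot_km_curves(list(curve = object), ...)
}

#' Boxplot of per-practice sensitivity
#'
#' One box per summary (pass a named list to compare dataset versions),
#' hinges at the 25th/75th percentiles, whiskers at 1.5 IQR, outliers as
#' points — the standard display for practice-level variability in
#' mortality capture.
#'
#' @param summaries A `"mort_practice_summary"` or a named list of them.
#' @return A ggplot object.
#' @export
plot_practice_sensitivity <- function(summaries) {
  if (inherits(summaries, "mort_practice_summary")) {
    summaries <- list(composite = summaries)
  }
  df <- purrr::imap(summaries, function(s, label) {
    s$per_practice %>% mutate(dataset = label)
  }) %>%
    bind_rows() %>%
    mutate(dataset = factor(.data$dataset, levels = names(summaries)))
  ggplot2::ggplot(df, ggplot2::aes(.data$dataset, .data$sensitivity)) +
    ggplot2::geom_boxplot(coef = 1.5) +
    ggplot2::labs(x = NULL, y = "Per-practice sensitivity") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
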