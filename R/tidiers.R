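agreement_col <- function(w) {
  ifelse(w == 0, "date_agreement_exact", sprintf("date_agreement_%d", w))
}

#' Tidy a validation result
#'
#' One row per quantity: the four accuracy metrics with Wald interval
#' bounds, followed by the windowed date-agreement proportions (no
#' interval).
#'
#' @param x A `"mort_validation"` object.
#' @param ... Unused.
#' @return A tibble with `metric`, `estimate`, `conf.low`, `conf.high`.
#' @export
tidy.mort_validation <- function(x, ...) {
  bind_rows(
    x$metrics %>% select("metric", "estimate", "conf.low", "conf.high"),
    x$agreement %>%
      dplyr::transmute(metric = agreement_col(.data$window_days),
                       estimate = .data$agreement,
                       conf.low = NA_real_, conf.high = NA_real_)
  )
}

#' Glance at a validation result
#'
#' A one-row summary in published-table layout: contingency counts, the
#' four metrics with `.low`/`.high` bounds, and one column per agreement
#' window. All values are proportions.
#'
#' @param x A `"mort_validation"` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.mort_validation <- function(x, ...) {
  ct <- x$contingency
  m <- x$metrics
  wide <- setNames(as.list(m$estimate), m$metric)
  wide <- c(wide,
            setNames(as.list(m$conf.low), paste0(m$metric, ".low")),
            setNames(as.list(m$conf.high), paste0(m$metric, ".high")))
  agr <- setNames(as.list(x$agreement$agreement),
                  agreement_col(x$agreement$window_days))
  ord <- c(rbind(m$metric, paste0(m$metric, ".low"), paste0(m$metric, ".high")))
  tibble(version = x$label, n = ct$n, A = ct$A, B = ct$B, C = ct$C,
         D = ct$D, !!!wide[ord], !!!agr)
}

#' Tidy a per-practice sensitivity summary
#'
#' @param x A `"mort_practice_summary"` object.
#' @param ... Unused.
#' @return The per-practice tibble (`practice_id`, `n_patients`,
#'   `n_gold_deaths`, `sensitivity`).
#' @export
tidy.mort_practice_summary <- function(x, ...) x$per_practice

#' Glance at a per-practice sensitivity summary
#'
#' @param x A `"mort_practice_summary"` object.
#' @param ... Unused.
#' @return One-row tibble of boxplot statistics plus practice and outlier
#'   counts.
#' @export
glance.mort_practice_summary <- function(x, ...) {
  x$stats %>%
    mutate(n_practices = nrow(x$per_practice),
           n_outliers = length(x$outliers))
}
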