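#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy model and curve results
#'
#' Broom-style accessors: `tidy()` returns one row per term (odds or hazard
#' ratio scale with Wald 95% CIs) or per curve step; `glance()` returns a
#' one-row model summary.
#'
#' @param x a `crclot_logistic`, `crclot_cox` or `crclot_km` object.
#' @param ... unused.
#' @return a tibble.
#' @name crclot_tidiers
NULL

#' @rdname crclot_tidiers
#' @export
tidy.crclot_logistic <- function(x, ...) x$estimates

#' @rdname crclot_tidiers
#' @export
tidy.crclot_cox <- function(x, ...) x$estimates

#' @rdname crclot_tidiers
#' @export
tidy.crclot_km <- function(x, ...) x$curve

#' @rdname crclot_tidiers
#' @export
glance.crclot_logistic <- function(x, ...) {
  tibble::tibble(n_used = x$n_used, n_excluded = x$n_excluded,
                 converged = x$converged, aic = stats::AIC(x$model))
}

#' @rdname crclot_tidiers
#' @export
glance.crclot_cox <- function(x, ...) {
  tibble::tibble(n_used = x$n_used, n_excluded = x$n_excluded,
                 n_events = x$n_events,
                 concordance = unname(summary(x$model)$concordance[1]))
}

#' @rdname crclot_tidiers
#' @export
glance.crclot_km <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events,
                 median_days = x$median,
                 median_conf_low = x$median_conf_low,
                 median_conf_high = x$median_conf_high,
                 median_months = days_to_months(x$median),
                 rmean_days = x$rmean, rmean_se = x$rmean_se,
                 largest_censored = x$largest_censored)
}
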