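#' Tidiers for SMTI result objects
#'
#' `tidy()` returns a one-row-per-component tibble, `glance()` a one-row
#' summary, following the broom conventions.
#'
#' @param x An SMTI result object.
#' @param ... Unused.
#' @return A tibble.
#' @name smti_tidiers
NULL

#' @rdname smti_tidiers
#' @export
tidy.smti_mw_test <- function(x, ...) {
  tibble::tibble(
    arc = x$arc, statistic = x$u, p.value = x$p_value,
    n.a = x$n_a, n.b = x$n_b, method = x$method
  )
}

#' @rdname smti_tidiers
#' @export
glance.smti_mw_test <- function(x, ...) tidy(x)

#' @rdname smti_tidiers
#' @export
tidy.smti_pre_post <- function(x, ...) {
  tibble::tibble(
    window = c("baseline", "response"),
    t_start_s = c(x$baseline_window[1], x$response_window[1]),
    t_end_s = c(x$baseline_window[2], x$response_window[2]),
    rate_per_s = c(x$baseline_rate_per_s, x$response_rate_per_s)
  )
}

#' @rdname smti_tidiers
#' @export
glance.smti_pre_post <- function(x, ...) {
  tibble::tibble(
    baseline_rate_per_s = x$baseline_rate_per_s,
    response_rate_per_s = x$response_rate_per_s,
    fold_change = x$fold_change,
    undefined = x$undefined
  )
}

#' @rdname smti_tidiers
#' @export
tidy.smti_validation <- function(x, ...) {
  tibble::tibble(
    recall = x$recall, precision = x$precision, rmse_nm = x$rmse_nm,
    rate_error = x$rate_error, n_true = x$n_true,
    n_detected = x$n_detected, n_matched = x$n_matched
  )
}

#' @rdname smti_tidiers
#' @export
glance.smti_validation <- function(x, ...) tidy(x)
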