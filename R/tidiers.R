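#' Tidy a Cox fit
#'
#' @param x An `hfmos_cox` object.
#' @param ... Unused.
#' @return Tibble with one row per term: `term`, `estimate` (log-HR), `hr`,
#'   `se`, `robust_se`, `conf_low`, `conf_high`, `p_value`.
#' @export
tidy.hfmos_cox <- function(x, ...) x$tidy

#' @rdname tidy.hfmos_cox
#' @export
glance.hfmos_cox <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events, loglik = x$loglik,
         robust = x$robust, conf_level = x$conf_level)
}

#' Tidy the trend model
#'
#' @param x An `hfmos_lmm` object.
#' @param ... Unused.
#' @return Fixed-effect tibble (`term`, `estimate`, `se`, `conf_low`,
#'   `conf_high`).
#' @export
tidy.hfmos_lmm <- function(x, ...) x$fixed

#' @rdname tidy.hfmos_lmm
#' @export
glance.hfmos_lmm <- function(x, ...) {
  tibble(n_patients = x$n_patients, n_obs = x$n_obs,
         sd_intercept = x$sd_intercept, sd_slope = x$sd_slope,
         cor_intercept_slope = x$cor_intercept_slope,
         sd_resid = x$sd_resid, loglik = x$loglik,
         uncorrelated_refit = x$uncorrelated_refit)
}
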