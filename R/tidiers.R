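#' Tidy a collective-diffusion fit
#'
#' @param x A `dn_fit` from [diffusion_coefficient()].
#' @param ... Unused.
#' @return One row per MSD lag used in the fit.
#' @export
tidy.dn_fit <- function(x, ...) x$msd

#' @describeIn tidy.dn_fit One-row fit summary.
#' @export
glance.dn_fit <- function(x, ...) {
  tibble::tibble(D_n = x$D_n, slope = x$slope, intercept = x$intercept,
                 fit_r2 = x$fit_r2,
                 fit_window_lo_ps = x$fit_window_ps[1],
                 fit_window_hi_ps = x$fit_window_ps[2],
                 n_frames = x$n_frames)
}

#' Tidy a pf estimate
#'
#' @param x A `pf_estimate`.
#' @param ... Unused.
#' @return A one-row tibble: monomer, `D_n` (1/ps), `pf` (cm^3/s), water
#'   volume and fit quality.
#' @export
tidy.pf_estimate <- function(x, ...) {
  tibble::tibble(monomer = x$monomer, D_n = x$D_n, pf = x$pf, v_w = x$v_w,
                 fit_r2 = x$fit$fit_r2)
}

#' @describeIn tidy.pf_estimate Same one-row summary (a pf estimate has no
#'   per-component breakdown).
#' @export
glance.pf_estimate <- function(x, ...) tidy.pf_estimate(x)
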