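#' Collective diffusion coordinate of channel waters
#'
#' The collective coordinate n(t) accumulates, frame pair by frame pair, the
#' summed axial displacements of the waters that are inside the channel
#' cylinder in *both* frames, divided by the channel length L:
#' `dn = sum_i dz_i / L`. A net collective displacement of 1 corresponds to
#' one effective water volume transported through the channel. Its
#' mean-square displacement grows as `2 D_n tau`, and `pf = v_w D_n`.
#'
#' @param traj A trajectory (at least 2 frames).
#' @param cylinder A `channel_cylinder`.
#' @param waters Water [atom_selection()]; defaults to [water_selection()].
#' @param L Channel length used to scale displacements; defaults to the
#'   cylinder full length.
#' @return A tibble of class `collective_coordinate` with columns `frame`,
#'   `time_ps` and `n` (`n[1] = 0`), carrying `L` (Angstrom) and `dt` (ps)
#'   as attributes.
#' @export
collective_coordinate <- function(traj, cylinder, waters = NULL, L = NULL) {
  waters <- waters %||% water_selection(traj$topology)
  idx <- as.integer(waters)
  nf <- n_frames(traj)
  stopifnot(nf >= 2)
  L <- L %||% (2 * cylinder$half_length)
  ax <- cylinder$axis

  ## axial position (relative to the per-frame centre) and interior flag
  z_rel <- matrix(NA_real_, nf, length(idx))
  inside <- matrix(FALSE, nf, length(idx))
  cshift <- numeric(nf) # axial centre position, to undo recentring in dz
  for (f in seq_len(nf)) {
    cf <- cylinder_frame_coords(cylinder, frame_coords(traj, f, idx), f)
    z_rel[f, ] <- cf$z
    inside[f, ] <- cf$r <= cylinder$radius & abs(cf$z) <= cylinder$half_length
    cshift[f] <- sum(cylinder_center(cylinder, f) * ax)
  }
  if (!any(inside)) warn("no waters ever inside the cylinder: n(t) is all zero")

  box_ax <- as.numeric(traj$box %*% abs(ax))
  dz_abs <- diff(z_rel) + diff(cshift)           # absolute water displacement
  dz_abs <- min_image(dz_abs, box_ax[-1])        # unwrap periodic jumps
  both <- inside[-nf, , drop = FALSE] & inside[-1, , drop = FALSE]
  dn <- rowSums(dz_abs * both) / L

  out <- tibble::tibble(frame = seq_len(nf), time_ps = traj$times,
                        n = c(0, cumsum(dn)))
  structure(out, L = L, dt = traj$dt,
            class = c("collective_coordinate", class(out)))
}

#' Collective diffusion coefficient from n(t)
#'
#' Computes the mean-square displacement of the collective coordinate over
#' all time origins, `MSD(tau) = <(n(t + tau) - n(t))^2>`, and fits a line
#' over an intermediate lag window (default 10 to 50 percent of the maximum
#' lag, skipping short-lag noise and long-lag poor statistics). The
#' diffusion coefficient is half the fitted slope.
#'
#' @param cc A `collective_coordinate` (>= 10 frames).
#' @param window Fit window as fractions of the maximum lag, default
#'   `c(0.1, 0.5)`.
#' @param max_points At most this many lag values are evaluated (evenly
#'   spaced); keeps long series cheap without changing the fit materially.
#' @return An object of class `dn_fit`: `D_n` (1/ps), fit diagnostics and
#'   the MSD table. A non-positive fitted slope is clamped to `D_n = 0`
#'   with a warning.
#' @export
diffusion_coefficient <- function(cc, window = c(0.1, 0.5), max_points = 400) {
  n <- cc$n
  nf <- length(n)
  stopifnot(nf >= 10, length(window) == 2, window[1] < window[2], window[1] >= 0)
  dt <- attr(cc, "dt")
  if (is.na(dt)) dt <- mean(diff(cc$time_ps))
  max_lag <- nf - 1
  lo <- max(1L, floor(window[1] * max_lag))
  hi <- max(lo + 1L, floor(window[2] * max_lag))
  lags <- unique(round(seq(lo, hi, length.out = min(max_points, hi - lo + 1L))))
  msd <- vapply(lags, function(m) mean(diff(n, lag = m)^2), numeric(1))
  tau <- lags * dt
  fit <- lm(msd ~ tau)
  slope <- unname(coef(fit)[2])
  ## a constant MSD (e.g. frozen waters) is fit perfectly by a flat line
  r2 <- if (sd(msd) == 0) 1 else summary(fit)$r.squared
  if (sd(msd) == 0) slope <- 0
  D_n <- slope / 2
  if (!is.finite(D_n) || D_n < 0) {
    warn("non-positive MSD slope: D_n clamped to 0")
    D_n <- 0
  }
  structure(list(D_n = D_n, slope = slope, intercept = unname(coef(fit)[1]),
                 fit_r2 = r2, window = window, fit_window_ps = range(tau),
                 msd = tibble::tibble(lag = lags, tau_ps = tau, msd = msd),
                 n_frames = nf, dt = dt, L = attr(cc, "L")),
            class = "dn_fit")
}

#' @export
print.dn_fit <- function(x, ...) {
  cat(sprintf("<dn_fit> D_n = %.4g /ps (fit r2 = %.3f, window %.0f-%.0f ps)\n",
              x$D_n, x$fit_r2, x$fit_window_ps[1], x$fit_window_ps[2]))
  invisible(x)
}

#' Osmotic permeability coefficient from D_n
#'
#' `pf = v_w * D_n`, converted from 1/ps to 1/s. The default single-water
#' volume is 2.99e-23 cm^3 (18.07 cm^3/mol over Avogadro's number).
#'
#' @param D_n Collective diffusion coefficient (1/ps), >= 0.
#' @param v_w Single-water volume in cm^3.
#' @return pf in cm^3/s.
#' @examples
#' osmotic_permeability(1e-3)  # ~3e-14 cm^3/s
#' @export
osmotic_permeability <- function(D_n, v_w = 2.99e-23) {
  stopifnot(all(D_n >= 0))
  v_w * D_n * 1e12
}

#' One-call pf estimate for a trajectory
#'
#' Convenience wrapper: collective coordinate, MSD fit, unit conversion.
#'
#' @inheritParams collective_coordinate
#' @inheritParams diffusion_coefficient
#' @param v_w Single-water volume in cm^3 (see [osmotic_permeability()]).
#' @return An object of class `pf_estimate` with elements `D_n` (1/ps),
#'   `pf` (cm^3/s), `v_w`, and the underlying `dn_fit`.
#' @export
pf_estimate <- function(traj, cylinder, waters = NULL, window = c(0.1, 0.5),
                        v_w = 2.99e-23, L = NULL) {
  cc <- collective_coordinate(traj, cylinder, waters, L = L)
  fit <- diffusion_coefficient(cc, window = window)
  structure(list(monomer = cylinder$monomer, D_n = fit$D_n,
                 pf = osmotic_permeability(fit$D_n, v_w), v_w = v_w,
                 fit = fit),
            class = "pf_estimate")
}

#' @export
print.pf_estimate <- function(x, ...) {
  cat(sprintf("<pf_estimate> monomer %s: D_n = %.4g /ps, pf = %.4g cm^3/s (r2 = %.3f)\n",
              x$monomer, x$D_n, x$pf, x$fit$fit_r2))
  invisible(x)
}
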