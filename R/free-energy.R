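#' Water density profile along the pore axis
#'
#' Slices the pore axis into uniform half-open bins (default width 0.5
#' Angstrom), counts cylinder-interior waters per slice per frame, averages
#' over frames, and divides by the slice volume `pi R^2 w`. Axial positions
#' are measured relative to the per-frame cylinder centre, so protein drift
#' does not smear the profile. The profile extends beyond the channel
#' section (default 1.5x the half-length on each side): the slices outside
#' the channel but inside the extended cylinder supply the default bulk
#' density estimate.
#'
#' @param traj A trajectory (>= 1 frame).
#' @param cylinder A `channel_cylinder`.
#' @param waters Water [atom_selection()]; defaults to [water_selection()].
#' @param slice_width Bin width in Angstrom (default 0.5).
#' @param z_range Profile extent, length-2 (Angstrom, relative to the
#'   centre); default `c(-1.5, 1.5) * half_length`.
#' @param bulk_density Override the bulk density (waters/Angstrom^3). By
#'   default it is the mean density over slices whose centres lie outside
#'   the channel section (`|z| > half_length`).
#' @return A tibble of class `density_profile` with columns `z_low`,
#'   `z_high`, `z_mid`, `count_mean`, `density`, carrying `bulk_density`,
#'   `n_frames`, `slice_width` and `radius` as attributes.
#' @export
density_profile <- function(traj, cylinder, waters = NULL, slice_width = 0.5,
                            z_range = NULL, bulk_density = NULL) {
  stopifnot(slice_width > 0)
  waters <- waters %||% water_selection(traj$topology)
  idx <- as.integer(waters)
  nf <- n_frames(traj)
  if (nf < 1) abort("density_profile needs at least one frame")
  H <- cylinder$half_length
  z_range <- z_range %||% (c(-1.5, 1.5) * H)
  n_bins <- max(1L, round(diff(z_range) / slice_width))
  edges <- z_range[1] + slice_width * (0:n_bins)

  counts <- numeric(n_bins)
  for (f in seq_len(nf)) {
    cf <- cylinder_frame_coords(cylinder, frame_coords(traj, f, idx), f)
    keep <- cf$r <= cylinder$radius & cf$z >= edges[1] & cf$z < edges[n_bins + 1]
    if (any(keep)) {
      b <- findInterval(cf$z[keep], edges, left.open = FALSE)
      counts <- counts + tabulate(b, nbins = n_bins)
    }
  }
  count_mean <- counts / nf
  vol <- pi * cylinder$radius^2 * slice_width
  z_mid <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  density <- count_mean / vol

  if (is.null(bulk_density)) {
    outer_bins <- abs(z_mid) > H
    if (!any(outer_bins))
      abort("z_range does not extend beyond the channel section; supply bulk_density")
    bulk_density <- mean(density[outer_bins])
    if (bulk_density <= 0)
      abort("estimated bulk density is zero; supply bulk_density explicitly")
  }
  stopifnot(bulk_density > 0)

  out <- tibble::tibble(z_low = edges[-(n_bins + 1)], z_high = edges[-1],
                        z_mid = z_mid, count_mean = count_mean,
                        density = density)
  structure(out, bulk_density = bulk_density, n_frames = nf,
            slice_width = slice_width, radius = cylinder$radius,
            class = c("density_profile", class(out)))
}

#' Gibbs free-energy profile by Boltzmann inversion
#'
#' `G(z) = -kB T ln(rho(z) / rho_bulk)` with `kB = 0.0083145` kJ/(mol K).
#' Empty slices are masked (`G = NA`) rather than set to infinity. Slices at
#' bulk density have `G = 0` by construction.
#'
#' @param dp A [density_profile()].
#' @param temperature Absolute temperature in K (default 303.15).
#' @return A tibble of class `free_energy_profile` with columns `z_mid`,
#'   `density`, `G` (kJ/mol) and `masked`; attributes `temperature` and
#'   `bulk_density`.
#' @export
free_energy_profile <- function(dp, temperature = 303.15) {
  stopifnot(temperature > 0)
  bulk <- attr(dp, "bulk_density")
  masked <- dp$density <= 0
  G <- ifelse(masked, NA_real_, -.kB * temperature * log(dp$density / bulk))
  out <- tibble::tibble(z_mid = dp$z_mid, density = dp$density,
                        G = G, masked = masked)
  structure(out, temperature = temperature, bulk_density = bulk,
            class = c("free_energy_profile", class(out)))
}
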