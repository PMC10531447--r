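#' Define the per-monomer channel cylinder
#'
#' The analysis region is a cylinder centred on the centre of geometry of the
#' NPA-motif asparagine alpha carbons, aligned with the pore axis (+z by
#' default), of radius 15 Angstrom and full length 30 Angstrom by default —
#' wide and long enough to encompass the whole transmembrane channel section
#' of an aquaporin monomer. With `per_frame = TRUE` (the default) the centre
#' is recomputed from the NPA atoms in every frame, so protein drift does not
#' move the channel out of its analysis region.
#'
#' @param traj A trajectory.
#' @param npa_selection An [atom_selection()] of the NPA-defining atoms
#'   (typically the two asparagine Calpha of one monomer). All selected
#'   atoms must belong to one chain unless `allow_multichain = TRUE`.
#' @param radius Cylinder radius in Angstrom (default 15).
#' @param length Cylinder full length in Angstrom (default 30).
#' @param axis Unit pore-axis vector (default `c(0, 0, 1)`).
#' @param per_frame Recompute the centre every frame (default `TRUE`).
#' @param monomer Label for the monomer; defaults to the chain of the NPA
#'   selection.
#' @param allow_multichain Permit an NPA selection spanning several chains.
#' @return An object of class `channel_cylinder` holding the radius,
#'   half-length, axis and an `n_frames x 3` matrix of centres.
#' @export
define_cylinder <- function(traj, npa_selection, radius = 15, length = 30,
                            axis = c(0, 0, 1), per_frame = TRUE,
                            monomer = NULL, allow_multichain = FALSE) {
  idx <- as.integer(npa_selection)
  if (length(idx) == 0) abort("NPA selection is empty; cannot centre the cylinder")
  chains <- unique(traj$topology$chain[idx])
  if (length(chains) > 1 && !allow_multichain)
    abort(sprintf("NPA selection spans chains %s; pass allow_multichain = TRUE if intended",
                  paste(chains, collapse = ", ")))
  stopifnot(radius > 0, length > 0)
  axis <- axis / sqrt(sum(axis^2))
  nf <- n_frames(traj)
  if (per_frame) {
    centers <- t(vapply(seq_len(nf),
                        function(f) colMeans(frame_coords(traj, f, idx)),
                        numeric(3)))
  } else {
    centers <- matrix(colMeans(frame_coords(traj, 1, idx)),
                      nrow = nf, ncol = 3, byrow = TRUE)
  }
  structure(list(monomer = monomer %||% chains[1], axis = axis,
                 centers = centers, radius = radius, half_length = length / 2,
                 per_frame = per_frame),
            class = "channel_cylinder")
}

#' Define a cylinder at a fixed point
#'
#' Fixed-centre variant of [define_cylinder()], useful for synthetic
#' trajectories whose channel does not drift.
#'
#' @param center Length-3 centre (Angstrom).
#' @param radius,length,axis As in [define_cylinder()].
#' @param monomer Monomer label (default `"A"`).
#' @return A `channel_cylinder`.
#' @export
fixed_cylinder <- function(center = c(0, 0, 0), radius = 15, length = 30,
                           axis = c(0, 0, 1), monomer = "A") {
  stopifnot(radius > 0, length > 0)
  axis <- axis / sqrt(sum(axis^2))
  structure(list(monomer = monomer, axis = axis,
                 centers = matrix(center, nrow = 1), radius = radius,
                 half_length = length / 2, per_frame = FALSE),
            class = "channel_cylinder")
}

#' @export
print.channel_cylinder <- function(x, ...) {
  cat(sprintf("<channel_cylinder> monomer %s, radius %g A, length %g A, %s centre\n",
              x$monomer, x$radius, 2 * x$half_length,
              if (nrow(x$centers) > 1) "per-frame" else "fixed"))
  invisible(x)
}

cylinder_center <- function(cyl, frame) {
  if (nrow(cyl$centers) == 1) cyl$centers[1, ] else cyl$centers[frame, ]
}

## Axial and radial coordinates of a coordinate matrix relative to the
## cylinder at a given frame.
cylinder_frame_coords <- function(cyl, xyz, frame) {
  rel <- sweep(xyz, 2, cylinder_center(cyl, frame))
  z <- as.numeric(rel %*% cyl$axis)
  r2 <- pmax(rowSums(rel^2) - z^2, 0)
  list(z = z, r = sqrt(r2))
}

#' Count complete water crossings through the channel cylinder
#'
#' One permeation event is a water molecule that enters the cylinder through
#' one flat face and leaves through the opposite face. The event automaton is
#' strict: a water entering radially (through the curved wall), or first
#' observed already inside, has no entry face and cannot complete an event
#' until it leaves and re-enters through a face; a water leaving through its
#' entry face, or radially, is reset without an event. A position exactly on
#' a face or wall counts as inside (closed interval). Apparent per-frame
#' displacements along the axis larger than half the box edge are treated as
#' periodic wraps: the water's state is re-initialised from its new position
#' and no faces are deemed crossed.
#'
#' @param traj A trajectory.
#' @param cylinder A `channel_cylinder`.
#' @param waters An [atom_selection()] of single position atoms per water
#'   (oxygens); defaults to [water_selection()] on the topology.
#' @param strict_faces Reset a water that leaves radially mid-channel
#'   (default `TRUE`). With `FALSE`, a radial excursion is forgiven and the
#'   entry face remembered while the water stays axially inside.
#' @return A tibble of permeation events with columns `water_id` (residue id
#'   of the water), `monomer`, `entry_frame`, `exit_frame`, `entry_ps`,
#'   `exit_ps` and `direction` (+1 along the axis, -1 against it).
#' @export
track_crossings <- function(traj, cylinder, waters = NULL,
                            strict_faces = TRUE) {
  waters <- waters %||% water_selection(traj$topology)
  idx <- as.integer(waters)
  nf <- n_frames(traj)
  empty <- tibble::tibble(water_id = integer(0), monomer = character(0),
                          entry_frame = integer(0), exit_frame = integer(0),
                          entry_ps = numeric(0), exit_ps = numeric(0),
                          direction = integer(0))
  if (nf < 2) {
    warn("trajectory has a single frame: dt undefined, no crossings counted")
    return(empty)
  }
  if (length(idx) == 0) {
    warn("water selection is empty")
    return(empty)
  }
  H <- cylinder$half_length
  R <- cylinder$radius
  water_id <- traj$topology$resid[idx]

  nw <- length(idx)
  inside_state <- logical(nw)      # currently inside the cylinder
  entry_face <- rep(NA_integer_, nw)
  entry_frame <- rep(NA_integer_, nw)
  last_side <- rep(NA_integer_, nw)  # -1 below low face, +1 above high, NA lateral

  ev_water <- integer(0); ev_entry <- integer(0); ev_exit <- integer(0)
  ev_dir <- integer(0)

  cf <- cylinder_frame_coords(cylinder, frame_coords(traj, 1, idx), 1)
  z_prev <- cf$z
  init_from_position <- function(w, z, r) {
    inside <- r[w] <= R & abs(z[w]) <= H
    inside_state[w] <<- inside
    entry_face[w] <<- NA_integer_
    entry_frame[w] <<- NA_integer_
    last_side[w] <<- ifelse(inside, NA_integer_,
                            ifelse(z[w] < -H, -1L, ifelse(z[w] > H, 1L, NA_integer_)))
  }
  init_from_position(seq_len(nw), cf$z, cf$r)
  ## frame-1 waters found inside get no entry face (unbiased start)
  entry_frame[inside_state] <- 1L

  ## axial box edge for wrap detection: projection of the box onto the axis
  ax_abs <- abs(cylinder$axis)
  for (f in 2:nf) {
    xyz <- frame_coords(traj, f, idx)
    cf <- cylinder_frame_coords(cylinder, xyz, f)
    z <- cf$z; r <- cf$r
    box_ax <- sum(traj$box[f, ] * ax_abs)
    dz_abs <- (z - z_prev) +
      as.numeric((cylinder_center(cylinder, f) -
                    cylinder_center(cylinder, max(1, f - 1))) %*% cylinder$axis)
    wrapped <- abs(dz_abs) > box_ax / 2

    inside_now <- r <= R & abs(z) <= H

    w_wrap <- which(wrapped)
    if (length(w_wrap) > 0) {
      init_from_position(w_wrap, z, r)
      entry_frame[w_wrap[inside_now[w_wrap]]] <- f
    }
    normal <- !wrapped

    ## outside -> inside: entry face is the last face-side seen. Waters with
    ## a retained entry face (forgiven radial excursions, non-strict mode)
    ## resume their crossing instead.
    w_in <- which(normal & !inside_state & inside_now & is.na(entry_face))
    if (length(w_in) > 0) {
      inside_state[w_in] <- TRUE
      entry_face[w_in] <- last_side[w_in]
      entry_frame[w_in] <- f
    }
    w_back <- which(normal & !inside_state & inside_now & !is.na(entry_face))
    if (length(w_back) > 0) inside_state[w_back] <- TRUE

    ## inside -> outside: event if exiting the face opposite the entry face
    w_out <- which(normal & inside_state & !inside_now)
    if (length(w_out) > 0) {
      exit_face <- ifelse(z[w_out] < -H, -1L, ifelse(z[w_out] > H, 1L, NA_integer_))
      complete <- !is.na(exit_face) & !is.na(entry_face[w_out]) &
        exit_face == -entry_face[w_out]
      if (any(complete)) {
        wc <- w_out[complete]
        ev_water <- c(ev_water, wc)
        ev_entry <- c(ev_entry, entry_frame[wc])
        ev_exit <- c(ev_exit, rep(f, length(wc)))
        ev_dir <- c(ev_dir, exit_face[complete])
      }
      radial_exit <- is.na(exit_face)
      if (!strict_faces && any(radial_exit)) {
        ## forgive the radial excursion: entry face stays armed
        wr <- w_out[radial_exit]
        inside_state[wr] <- FALSE
        last_side[wr] <- NA_integer_
        w_reset <- w_out[!radial_exit]
      } else {
        w_reset <- w_out
      }
      inside_state[w_reset] <- FALSE
      entry_face[w_reset] <- NA_integer_
      entry_frame[w_reset] <- NA_integer_
      last_side[w_reset] <- ifelse(z[w_reset] < -H, -1L,
                                   ifelse(z[w_reset] > H, 1L, NA_integer_))
    }

    ## outside -> outside: refresh the face side (lateral region clears it)
    w_off <- which(normal & !inside_state & !inside_now)
    if (length(w_off) > 0) {
      last_side[w_off] <- ifelse(z[w_off] < -H, -1L,
                                 ifelse(z[w_off] > H, 1L, NA_integer_))
      ## an armed (non-strict) water that drifts past a face disarms
      beyond <- w_off[abs(z[w_off]) > H]
      entry_face[beyond] <- NA_integer_
      entry_frame[beyond] <- NA_integer_
    }

    z_prev <- z
  }

  if (length(ev_water) == 0) return(empty)
  tibble::tibble(
    water_id = water_id[ev_water],
    monomer = cylinder$monomer,
    entry_frame = ev_entry,
    exit_frame = ev_exit,
    entry_ps = traj$times[ev_entry],
    exit_ps = traj$times[ev_exit],
    direction = ev_dir
  ) |> dplyr::arrange(.data$exit_frame, .data$water_id)
}

#' Cumulative permeation counts over time
#'
#' Turns an event table into the cumulative-crossings step series plotted in
#' permeation figures: at each trajectory time, the number of events whose
#' exit lies at or before that time, per monomer.
#'
#' @param events Event tibble from [track_crossings()] (possibly several
#'   monomers bound together).
#' @param times Numeric vector of frame times (ps).
#' @return A tibble with columns `monomer`, `time_ps`, `cumulative`;
#'   non-decreasing in time within each monomer, ending at the event total.
#' @export
cumulative_counts <- function(events, times) {
  monomers <- unique(events$monomer)
  if (length(monomers) == 0) monomers <- "A"
  purrr::map_dfr(monomers, function(m) {
    ex <- sort(events$exit_ps[events$monomer == m])
    tibble::tibble(monomer = m, time_ps = times,
                   cumulative = findInterval(times, ex))
  })
}
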