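#' Construct a trajectory
#'
#' A trajectory bundles a topology with an ordered set of frames. Coordinates
#' are stored as a numeric array of dimension `n_frames x n_atoms x 3`
#' (Angstrom); each frame carries a time stamp (ps) and an orthorhombic box
#' (three edge lengths, Angstrom). The frame spacing `dt` is inferred from
#' the time stamps; trajectories whose spacing is non-uniform beyond a
#' relative tolerance of 1e-6 are flagged irregular and `dt` is `NA`.
#'
#' @param topology A [topology()] tibble.
#' @param coords Numeric array `n_frames x n_atoms x 3`, or a single
#'   `n_atoms x 3` matrix for a one-frame trajectory.
#' @param times Numeric vector of frame times in ps (default `0, 1, ...`).
#' @param box Numeric length-3 vector, or `n_frames x 3` matrix of
#'   orthorhombic box edges in Angstrom.
#' @return An object of class `trajectory`.
#' @export
new_trajectory <- function(topology, coords, times = NULL, box = c(100, 100, 100)) {
  topology <- validate_topology(topology)
  if (is.matrix(coords)) {
    coords <- array(coords, dim = c(1L, nrow(coords), 3L))
  }
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  nf <- dim(coords)[1]
  if (dim(coords)[2] != nrow(topology))
    abort(sprintf("coordinate count (%d atoms) does not match topology (%d atoms)",
                  dim(coords)[2], nrow(topology)))
  if (nf < 1) abort("a trajectory needs at least one frame")
  times <- times %||% as.numeric(seq_len(nf) - 1)
  if (length(times) != nf) abort("length(times) must equal the frame count")
  if (is.unsorted(times)) abort("frame times must be non-decreasing")
  if (is.null(dim(box))) box <- matrix(box, nrow = nf, ncol = 3, byrow = TRUE)
  stopifnot(nrow(box) == nf, ncol(box) == 3)
  if (any(box <= 0)) abort("box edge lengths must be positive")
  obj <- structure(
    list(topology = topology, coords = coords, times = as.numeric(times),
         box = box),
    class = "trajectory")
  obj$dt <- infer_dt(times)
  obj
}

infer_dt <- function(times) {
  if (length(times) < 2) return(NA_real_)
  d <- diff(times)
  if (any(d <= 0)) return(NA_real_)
  if (max(d) - min(d) <= 1e-6 * max(abs(d))) mean(d) else NA_real_
}

#' @export
n_frames <- function(x) UseMethod("n_frames")

#' @export
n_frames.trajectory <- function(x) dim(x$coords)[1]

#' @export
n_atoms.trajectory <- function(x) dim(x$coords)[2]

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms, t = [%g, %g] ps, dt = %s ps\n",
              n_frames(x), n_atoms(x), x$times[1], x$times[n_frames(x)],
              if (is.na(x$dt)) "irregular/undefined" else format(x$dt)))
  invisible(x)
}

#' Extract one frame's coordinates
#'
#' @param traj A trajectory.
#' @param frame Frame index (1-based).
#' @param selection Optional atom indices.
#' @return An `n x 3` coordinate matrix.
#' @export
frame_coords <- function(traj, frame, selection = NULL) {
  m <- traj$coords[frame, , , drop = FALSE]
  dim(m) <- dim(traj$coords)[2:3]
  if (!is.null(selection)) m <- m[as.integer(selection), , drop = FALSE]
  m
}

#' Restrict a trajectory to a time window
#'
#' @param traj A trajectory.
#' @param window Length-2 numeric, `[start, end)` in ps. Frames with
#'   `start <= time < end` are kept (the final trajectory frame is kept when
#'   `end` equals the last time stamp plus one step).
#' @return A trajectory.
#' @export
traj_window <- function(traj, window) {
  stopifnot(length(window) == 2, window[2] > window[1])
  keep <- which(traj$times >= window[1] & traj$times < window[2])
  if (length(keep) == 0) abort("no frames fall inside the requested window")
  new_trajectory(traj$topology,
                 traj$coords[keep, , , drop = FALSE],
                 times = traj$times[keep],
                 box = traj$box[keep, , drop = FALSE])
}

#' Keep a subset of frames by index
#' @param traj A trajectory.
#' @param frames Integer frame indices, in increasing order.
#' @return A trajectory.
#' @export
traj_subset <- function(traj, frames) {
  frames <- as.integer(frames)
  stopifnot(all(frames >= 1), all(frames <= n_frames(traj)), !is.unsorted(frames))
  new_trajectory(traj$topology, traj$coords[frames, , , drop = FALSE],
                 times = traj$times[frames], box = traj$box[frames, , drop = FALSE])
}

## Minimum-image displacement for orthorhombic boxes: component-wise.
min_image <- function(d, box_edge) d - box_edge * round(d / box_edge)
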