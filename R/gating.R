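#' Charged-group heavy-atom names for salt-bridge analysis
#'
#' Conventional heavy-atom name sets for the charged moieties met in gating
#' analyses: the phosphoserine phosphoryl oxygens, arginine guanidinium
#' nitrogens, lysine amine, and the aspartate/glutamate carboxylates.
#'
#' @return A tibble with columns `residue`, `resname`, `atoms`.
#' @export
charged_group_atoms <- function() {
  tibble::tibble(
    residue = c("phosphoserine", "arginine", "lysine", "aspartate", "glutamate"),
    resname = c("SEP", "ARG", "LYS", "ASP", "GLU"),
    atoms = list(c("O1P", "O2P", "O3P", "OG"),
                 c("NH1", "NH2", "NE"),
                 "NZ",
                 c("OD1", "OD2"),
                 c("OE1", "OE2"))
  )
}

## all-pairs minimum distance between two coordinate sets, optionally with
## minimum-image convention per component
pairwise_min_dist <- function(a, b, box = NULL) {
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  dz <- outer(a[, 3], b[, 3], "-")
  if (!is.null(box)) {
    dx <- min_image(dx, box[1]); dy <- min_image(dy, box[2])
    dz <- min_image(dz, box[3])
  }
  sqrt(min(dx^2 + dy^2 + dz^2))
}

#' Minimal inter-group distance series
#'
#' Per frame, the minimum over all atom pairs of the (minimum-image)
#' Euclidean distance between two selections — the quantity used to monitor
#' the widening of the intracellular vestibule between loop D and the
#' N-terminus, or any other contact.
#'
#' @param traj A trajectory.
#' @param a,b Disjoint, non-empty [atom_selection()]s.
#' @param pbc Apply the minimum-image convention (default `TRUE`).
#' @return A tibble of class `distance_series` with columns `frame`,
#'   `time_ps`, `distance` (Angstrom); group provenance kept as attributes.
#' @export
min_distance_series <- function(traj, a, b, pbc = TRUE) {
  ia <- as.integer(a); ib <- as.integer(b)
  if (length(ia) == 0 || length(ib) == 0) abort("both selections must be non-empty")
  if (length(intersect(ia, ib)) > 0)
    abort("selections overlap; minimal distance between them is degenerate")
  nf <- n_frames(traj)
  d <- vapply(seq_len(nf), function(f) {
    pairwise_min_dist(frame_coords(traj, f, ia), frame_coords(traj, f, ib),
                      box = if (pbc) traj$box[f, ] else NULL)
  }, numeric(1))
  out <- tibble::tibble(frame = seq_len(nf), time_ps = traj$times, distance = d)
  structure(out,
            group_a = attr(a, "expression"), group_b = attr(b, "expression"),
            class = c("distance_series", class(out)))
}

#' Running-mean smoothing of a distance series
#'
#' Plotting convenience mirroring the common 1-ns running mean; statistics
#' should always use the raw per-frame minima.
#'
#' @param ds A `distance_series`.
#' @param window_ps Smoothing window in ps (default 1000).
#' @return The series with an added `smoothed` column.
#' @export
smooth_distance_series <- function(ds, window_ps = 1000) {
  dt <- infer_dt(ds$time_ps)
  k <- if (is.na(dt)) 1L else max(1L, round(window_ps / dt))
  if (k %% 2 == 0) k <- k + 1L
  sm <- stats::filter(ds$distance, rep(1 / k, k), sides = 2)
  ds$smoothed <- as.numeric(sm)
  ## shrink the window at the edges instead of dropping them
  na_idx <- which(is.na(ds$smoothed))
  for (i in na_idx) {
    h <- min(i - 1, nrow(ds) - i, (k - 1) %/% 2)
    ds$smoothed[i] <- mean(ds$distance[(i - h):(i + h)])
  }
  ds
}

#' Salt-bridge distance and formation series
#'
#' Minimum heavy-atom distance between two charged groups per frame, with a
#' boolean `formed = distance <= cutoff` layered on top (the raw distances
#' are always retained; the default 4 Angstrom cutoff is the common
#' literature convention for charged-group heavy atoms).
#'
#' @param traj A trajectory.
#' @param acidic_group,basic_group [atom_selection()]s of charged-moiety
#'   heavy atoms (e.g. phosphoryl oxygens vs guanidinium nitrogens).
#' @param cutoff Formation cutoff in Angstrom (default 4.0, closed
#'   interval: a distance exactly at the cutoff counts as formed).
#' @param pbc Apply the minimum-image convention (default `TRUE`).
#' @return A tibble of class `salt_bridge_series` with columns `frame`,
#'   `time_ps`, `distance`, `formed`; attributes `cutoff` and
#'   `formed_fraction`.
#' @export
salt_bridge_series <- function(traj, acidic_group, basic_group, cutoff = 4,
                               pbc = TRUE) {
  if (length(acidic_group) == 0 || length(basic_group) == 0)
    abort("charged groups must be non-empty")
  ds <- min_distance_series(traj, acidic_group, basic_group, pbc = pbc)
  ds$formed <- ds$distance <= cutoff
  structure(ds, cutoff = cutoff, formed_fraction = mean(ds$formed),
            group_a = attr(ds, "group_a"), group_b = attr(ds, "group_b"),
            class = c("salt_bridge_series", class(ds)[-1]))
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the rotation and translation minimising the RMSD between the fit
#' atoms of a mobile and a reference coordinate set (SVD solution, proper
#' rotation enforced), applies it to all mobile atoms, and reports the
#' post-fit RMSD over the fit atoms.
#'
#' @param mobile,reference `n x 3` coordinate matrices (equal atom counts
#'   within the fit selection).
#' @param fit Optional indices of the atoms used for fitting (default all).
#' @return A list of class `superposition`: `rotation` (3x3), giving
#'   `fitted = (mobile - com_mobile) %*% rotation + com_reference`,
#'   `translation`, `rmsd` (Angstrom, post-fit over fit atoms) and `coords`
#'   (all mobile atoms transformed).
#' @export
superpose <- function(mobile, reference, fit = NULL) {
  fit <- if (is.null(fit)) seq_len(nrow(mobile)) else as.integer(fit)
  P <- mobile[fit, , drop = FALSE]
  Q <- reference[fit, , drop = FALSE]
  if (nrow(P) != nrow(Q)) abort("fit selections must have equal atom counts")
  if (nrow(P) < 3) abort("superposition needs at least 3 fit atoms")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  sv_check <- svd(Pc)$d
  if (sv_check[2] < 1e-8 * max(sv_check[1], 1))
    abort("degenerate (collinear) fit geometry")
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)   # right-multiplication rotation
  fitted_fit <- Pc %*% R
  rmsd <- sqrt(mean(rowSums((fitted_fit - Qc)^2)))
  coords <- sweep(sweep(mobile, 2, cp) %*% R, 2, cq, "+")
  structure(list(rotation = R, translation = cq - as.numeric(cp %*% R),
                 rmsd = rmsd, coords = coords, fit = fit),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> RMSD = %.4f A over %d fit atoms\n",
              x$rmsd, length(x$fit)))
  invisible(x)
}

#' @export
glance.superposition <- function(x, ...) {
  tibble::tibble(rmsd = x$rmsd, n_fit_atoms = length(x$fit))
}

## superpose every frame of a coordinate array onto a reference, fitting on
## fit_idx (indices into the atom dimension); returns the fitted array
fit_frames <- function(coords, reference, fit_idx) {
  nf <- dim(coords)[1]
  out <- coords
  for (f in seq_len(nf)) {
    m <- coords[f, , ]
    dim(m) <- dim(coords)[2:3]
    sp <- superpose(m, reference, fit = fit_idx)
    out[f, , ] <- sp$coords
  }
  out
}

#' Per-atom root mean square fluctuation
#'
#' Two-pass procedure: frames are first superposed onto the initial frame on
#' the fit selection, the mean structure is computed, frames are refit onto
#' that mean, and `RMSF_i = sqrt(<|r_i - <r_i>|^2>)` is reported for the
#' analysis selection. Global rigid-body motion is thereby removed; a rigid
#' trajectory has RMSF identically zero.
#'
#' @param traj A trajectory (>= 2 frames).
#' @param selection Atoms to report (default all).
#' @param fit_selection Atoms used for the rigid-body fits (default
#'   `selection`).
#' @return A tibble of class `rmsf_profile`: `index`, `name`, `resname`,
#'   `resid`, `chain`, `rmsf` (Angstrom).
#' @export
rmsf <- function(traj, selection = NULL, fit_selection = NULL) {
  stopifnot(n_frames(traj) >= 2)
  sel <- as.integer(selection %||% atom_selection(seq_len(n_atoms(traj))))
  fit_sel <- as.integer(fit_selection %||% sel)
  ref0 <- frame_coords(traj, 1)
  pass1 <- fit_frames(traj$coords, ref0, fit_sel)
  mean1 <- apply(pass1, c(2, 3), mean)
  pass2 <- fit_frames(traj$coords, mean1, fit_sel)
  mean2 <- apply(pass2, c(2, 3), mean)
  dev2 <- sweep(pass2, c(2, 3), mean2)
  msf <- apply(dev2^2, 2, sum) / n_frames(traj)   # summed over x,y,z
  out <- traj$topology[sel, c("index", "name", "resname", "resid", "chain")]
  out$rmsf <- sqrt(msf[sel])
  structure(tibble::as_tibble(out),
            class = c("rmsf_profile", class(tibble::tibble())))
}

#' Windowed average structure
#'
#' Frames inside a `[start, end)` ps window are superposed onto the window's
#' first frame on the fit selection and averaged arithmetically — the
#' standard way to compare a sub-trajectory's typical conformation with a
#' crystallographic reference.
#'
#' @param traj A trajectory.
#' @param window Length-2 ps range, `[start, end)`.
#' @param fit_selection Atoms used for fitting (default all).
#' @return A list of class `average_structure`: `topology`, `coords` (mean,
#'   Angstrom), `window`, `n_frames`.
#' @export
average_structure <- function(traj, window, fit_selection = NULL) {
  sub <- traj_window(traj, window)
  fit_sel <- as.integer(fit_selection %||% atom_selection(seq_len(n_atoms(traj))))
  ref <- frame_coords(sub, 1)
  fitted <- fit_frames(sub$coords, ref, fit_sel)
  structure(list(topology = traj$topology,
                 coords = apply(fitted, c(2, 3), mean),
                 window = window, n_frames = n_frames(sub)),
            class = "average_structure")
}

#' @export
print.average_structure <- function(x, ...) {
  cat(sprintf("<average_structure> %d frames over [%g, %g) ps, %d atoms\n",
              x$n_frames, x$window[1], x$window[2], nrow(x$coords)))
  invisible(x)
}
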