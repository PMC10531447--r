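#' Axial harmonic barrier potential
#'
#' An inverted-parabola barrier `U(z) = height * (1 - ((z - center)/half_width)^2)`
#' for `|z - center| <= half_width`, zero outside — a smooth stand-in for the
#' free-energy barrier a closed gate presents to channel waters.
#'
#' @param height Barrier height in kJ/mol.
#' @param half_width Barrier half-width in Angstrom.
#' @param center Barrier centre along z (Angstrom, default 0).
#' @return A vectorised function `U(z)` (kJ/mol) carrying its parameters in
#'   the `"spec"` attribute (serialised into fixture sidecars).
#' @export
harmonic_barrier <- function(height, half_width, center = 0) {
  stopifnot(height >= 0, half_width > 0)
  f <- function(z) {
    u <- height * (1 - ((z - center) / half_width)^2)
    ifelse(abs(z - center) <= half_width, u, 0)
  }
  attr(f, "spec") <- list(type = "harmonic_barrier", height = height,
                          half_width = half_width, center = center)
  f
}

## Boltzmann sampling of the axial stationary density by rejection
## (requires U >= 0 so exp(-U/kT) <= 1, true for the barrier potentials here)
sample_boltzmann_z <- function(n, zlim, potential, kT) {
  if (is.null(potential)) return(runif(n, zlim[1], zlim[2]))
  out <- numeric(0)
  while (length(out) < n) {
    z <- runif(2 * n, zlim[1], zlim[2])
    acc <- runif(2 * n) < exp(-potential(z) / kT)
    out <- c(out, z[acc])
  }
  out[seq_len(n)]
}

## reflect positions into [lo, hi]
reflect_into <- function(z, lo, hi) {
  span <- hi - lo
  z <- (z - lo) %% (2 * span)
  z <- ifelse(z > span, 2 * span - z, z)
  z + lo
}

#' Simulate Brownian channel waters with known ground truth
#'
#' Overdamped Brownian dynamics of non-interacting water particles in a
#' periodic orthorhombic box containing a cylindrical channel region.
#' Axial moves are Gaussian with variance `2 D dt` and are accepted by a
#' Metropolis criterion on the axial potential `U(z)` (plain Brownian motion
#' when `U` is `NULL`), which makes the stationary axial density exactly
#' Boltzmann — the property the free-energy recovery analysis relies on.
#' Particles reflect at the box z-faces. Lateral positions are drawn
#' uniformly in the channel cross-section disc and kept fixed (the analysis
#' code, not single-file water physics, is what these fixtures exercise).
#' Starting positions are drawn from the stationary axial density, so no
#' burn-in is needed. Output is bit-reproducible for a given seed.
#'
#' @param n_waters Number of water particles (default 80).
#' @param box Orthorhombic box edges in Angstrom (default `c(40, 40, 60)`).
#' @param radius,length Channel cylinder radius / full length in Angstrom
#'   (defaults 15 / 30, centred at the origin).
#' @param D Axial diffusion coefficient in Angstrom^2/ps (default 0.3).
#' @param potential `NULL` for free diffusion, or a non-negative axial
#'   potential function such as [harmonic_barrier()] (kJ/mol).
#' @param temperature Kelvin (default 303.15).
#' @param dt Frame spacing in ps (default 2).
#' @param n_frames Number of frames (default 5000).
#' @param seed Mandatory integer seed.
#' @return A [new_trajectory()] of TIP3 oxygen pseudo-atoms (chain `"W"`),
#'   with the generating parameters attached as attribute `"ground_truth"`.
#' @export
simulate_channel_waters <- function(n_waters = 80, box = c(40, 40, 60),
                                    radius = 15, length = 30, D = 0.3,
                                    potential = NULL, temperature = 303.15,
                                    dt = 2, n_frames = 5000, seed) {
  stopifnot(n_waters > 0, all(box > 0), radius > 0, length > 0, D >= 0,
            temperature > 0, dt > 0, n_frames >= 1)
  if (missing(seed)) abort("a seed is mandatory (reproducibility)")
  kT <- .kB * temperature
  zlim <- c(-box[3] / 2, box[3] / 2)
  sd_step <- sqrt(2 * D * dt)

  sim <- withr::with_seed(as.integer(seed), {
    ## lateral positions: uniform in the channel disc
    u <- runif(n_waters); th <- runif(n_waters, 0, 2 * pi)
    rr <- radius * sqrt(u) * 0.999
    xs <- rr * cos(th); ys <- rr * sin(th)
    z <- sample_boltzmann_z(n_waters, zlim, potential, kT)
    zmat <- matrix(NA_real_, n_frames, n_waters)
    zmat[1, ] <- z
    n_acc <- 0; n_try <- 0
    if (n_frames > 1 && D > 0) {
      for (f in 2:n_frames) {
        prop <- reflect_into(z + rnorm(n_waters, 0, sd_step), zlim[1], zlim[2])
        if (is.null(potential)) {
          z <- prop
        } else {
          dU <- potential(prop) - potential(z)
          acc <- runif(n_waters) < exp(-dU / kT)
          z <- ifelse(acc, prop, z)
          n_acc <- n_acc + sum(acc); n_try <- n_try + n_waters
        }
        zmat[f, ] <- z
      }
    } else if (n_frames > 1) {
      for (f in 2:n_frames) zmat[f, ] <- z
    }
    list(xs = xs, ys = ys, zmat = zmat,
         acceptance = if (n_try > 0) n_acc / n_try else NA_real_)
  })

  if (!is.na(sim$acceptance) && sim$acceptance < 0.5)
    warn(sprintf("Metropolis acceptance %.2f < 0.5: dt too large for this potential",
                 sim$acceptance))

  top <- topology(name = rep("OH2", n_waters), resname = "TIP3",
                  resid = seq_len(n_waters), chain = "W", element = "O")
  coords <- array(NA_real_, dim = c(n_frames, n_waters, 3))
  coords[, , 1] <- matrix(sim$xs, n_frames, n_waters, byrow = TRUE)
  coords[, , 2] <- matrix(sim$ys, n_frames, n_waters, byrow = TRUE)
  coords[, , 3] <- sim$zmat
  traj <- new_trajectory(top, coords, times = (seq_len(n_frames) - 1) * dt,
                         box = box)
  attr(traj, "ground_truth") <- list(
    kind = "channel_waters",
    n_waters = n_waters, box = box, radius = radius, length = length,
    D = D, potential = if (is.null(potential)) NULL else attr(potential, "spec"),
    temperature = temperature, dt = dt, n_frames = n_frames,
    seed = as.integer(seed), acceptance = sim$acceptance)
  traj
}

#' Simulate a gating scaffold with scheduled open/closed states
#'
#' A toy protein scaffold for exercising the gating-geometry analyses with
#' known ground truth: ten fixed "N-ter" pseudo-Calpha (chain D, resid
#' 21-30), sixteen mobile "loop D" pseudo-Calpha (chain D, resid 185-200)
#' whose separation from the N-ter group switches between a closed and an
#' open target per schedule, a phosphoserine (SEP 188) phosphoryl-oxygen
#' group riding on the loop, and arginine guanidinium groups (ARG 187/190)
#' whose distance to the phosphoryl group is small in the open state and
#' large in the closed state, so salt-bridge series flip with the schedule.
#' Gaussian jitter of width `jitter` is added to every mobile atom.
#'
#' @param closed_sep,open_sep Loop-D-to-N-ter minimal separations (Angstrom)
#'   in the closed / open state (defaults 6 / 20).
#' @param bridge_near,bridge_far Phosphoryl-to-guanidinium minimal distances
#'   (Angstrom) in the open / closed state (defaults 2.8 / 8).
#' @param schedule A data frame `time_ps`, `state` (`"open"`/`"closed"`)
#'   with increasing times; each row sets the state from its time onward.
#'   Default: closed for the first half, open after.
#' @param jitter Gaussian jitter sigma per coordinate in Angstrom
#'   (default 0.3).
#' @param dt Frame spacing, ps (default 100).
#' @param n_frames Number of frames (default 2000).
#' @param seed Mandatory integer seed.
#' @return A trajectory (box 200 Angstrom cube, so PBC is inert), with the
#'   schedule and targets attached as attribute `"ground_truth"`.
#' @export
simulate_gating_scaffold <- function(closed_sep = 6, open_sep = 20,
                                     bridge_near = 2.8, bridge_far = 8,
                                     schedule = NULL, jitter = 0.3,
                                     dt = 100, n_frames = 2000, seed) {
  stopifnot(closed_sep > 0, open_sep > 0, jitter >= 0, dt > 0, n_frames >= 1)
  if (missing(seed)) abort("a seed is mandatory (reproducibility)")
  total <- n_frames * dt
  schedule <- schedule %||%
    data.frame(time_ps = c(0, total / 2), state = c("closed", "open"))
  stopifnot(all(c("time_ps", "state") %in% names(schedule)),
            !is.unsorted(schedule$time_ps),
            all(schedule$state %in% c("open", "closed")))

  ## topology: N-ter CA (resid 21-30), loop D CA (185-200), SEP phosphoryl
  ## oxygens (188), ARG guanidinium nitrogens (187, 190) — all chain D
  nter_x <- (0:9) * 3.8
  loop_x <- (0:15) * 3.8 - 2 * 3.8   # overlaps the N-ter x-grid
  top <- topology(
    name = c(rep("CA", 10), rep("CA", 16),
             "O1P", "O2P", "O3P",
             "NH1", "NH2", "NE", "NH1", "NH2", "NE"),
    resname = c(rep("GLY", 10), rep("GLY", 16),
                rep("SEP", 3), rep("ARG", 3), rep("ARG", 3)),
    resid = c(21:30, 185:200, rep(188L, 3), rep(187L, 3), rep(190L, 3)),
    chain = "D",
    element = c(rep("C", 26), rep("O", 3), rep("N", 6)))

  times <- (seq_len(n_frames) - 1) * dt
  state_idx <- findInterval(times, schedule$time_ps)
  state_idx[state_idx == 0] <- 1
  is_open <- schedule$state[state_idx] == "open"
  sep_t <- ifelse(is_open, open_sep, closed_sep)
  bridge_t <- ifelse(is_open, bridge_near, bridge_far)

  na <- nrow(top)
  base <- matrix(0, na, 3)
  base[1:10, 1] <- nter_x                       # N-ter: fixed at z = 0
  base[11:26, 1] <- loop_x                      # loop D: moves along +z
  ## phosphoryl oxygens around loop residue 188 (atom row 11 + 3 = index 14)
  phos_anchor <- c(loop_x[4], 0, 0)
  base[27:29, ] <- matrix(phos_anchor, 3, 3, byrow = TRUE) +
    rbind(c(0.6, 0.6, 0), c(-0.6, 0.6, 0), c(0, -0.8, 0))
  ## guanidinium groups offset from the phosphoryl along +y by bridge_t
  guan_template <- rbind(c(0.5, 0, 0.3), c(-0.5, 0, 0.3), c(0, 0, -0.5))

  coords <- array(NA_real_, dim = c(n_frames, na, 3))
  coords_noise <- withr::with_seed(as.integer(seed),
                                   array(rnorm(n_frames * na * 3, 0, jitter),
                                         dim = c(n_frames, na, 3)))
  coords_noise[, 1:10, ] <- 0                   # N-ter stays rigid
  for (f in seq_len(n_frames)) {
    m <- base
    m[11:29, 3] <- m[11:29, 3] + sep_t[f]       # loop + phosphoryl ride loop
    g1 <- sweep(guan_template, 2, c(phos_anchor[1], bridge_t[f], sep_t[f]), "+")
    g2 <- sweep(guan_template, 2, c(phos_anchor[1] + 1.2, bridge_t[f] + 0.4,
                                    sep_t[f]), "+")
    m[30:32, ] <- g1
    m[33:35, ] <- g2
    coords[f, , ] <- m
  }
  coords <- coords + coords_noise

  traj <- new_trajectory(top, coords, times = times, box = c(200, 200, 200))
  attr(traj, "ground_truth") <- list(
    kind = "gating_scaffold",
    closed_sep = closed_sep, open_sep = open_sep,
    bridge_near = bridge_near, bridge_far = bridge_far,
    schedule = as.data.frame(schedule), jitter = jitter, dt = dt,
    n_frames = n_frames, seed = as.integer(seed),
    open_fraction = mean(is_open))
  traj
}

#' Write a self-describing fixture bundle
#'
#' Writes a topology PDB, an XYZ-per-frame trajectory and a JSON
#' ground-truth sidecar (generating parameters including the seed) so every
#' recovery analysis can be re-run from the files alone.
#'
#' @param traj A trajectory from one of the simulators.
#' @param out_dir Output directory (created if needed).
#' @param name Basename for the three files (default `"fixture"`).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture_bundle <- function(traj, out_dir, name = "fixture") {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(topology = file.path(out_dir, paste0(name, ".pdb")),
             trajectory = file.path(out_dir, paste0(name, ".xyz")),
             truth = file.path(out_dir, paste0(name, "_truth.json")))
  write_structure(traj$topology, frame_coords(traj, 1), paths["topology"],
                  box = traj$box[1, ])
  write_trajectory(traj, paths["trajectory"], dialect = "xyz")
  truth <- attr(traj, "ground_truth") %||% list(kind = "unknown")
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

#' Read a fixture bundle back
#'
#' @param out_dir Directory holding the bundle.
#' @param name Basename used when writing (default `"fixture"`).
#' @return A trajectory with the sidecar parameters re-attached as
#'   attribute `"ground_truth"`.
#' @export
read_fixture_bundle <- function(out_dir, name = "fixture") {
  top <- read_structure(file.path(out_dir, paste0(name, ".pdb")))$topology
  traj <- read_trajectory(top, file.path(out_dir, paste0(name, ".xyz")),
                          dialect = "xyz")
  truth_path <- file.path(out_dir, paste0(name, "_truth.json"))
  if (file.exists(truth_path))
    attr(traj, "ground_truth") <- jsonlite::read_json(truth_path,
                                                      simplifyVector = TRUE)
  traj
}

#' Synthetic open / closed channel presets
#'
#' The two end-to-end study conditions: `"open"` is free axial diffusion
#' (no barrier) and `"closed"` adds a 5 kJ/mol harmonic barrier across the
#' channel section — the gate's free-energy signature — with everything
#' else identical (80 waters, 40 x 40 x 60 Angstrom box, D = 0.3
#' Angstrom^2/ps, 303.15 K, dt = 2 ps, 50000 frames = 100 ns, i.e. ten
#' 10-ns blocks). The matching analysis cylinder is [fixed_cylinder()] at
#' the origin with the default 15/30 Angstrom geometry.
#'
#' @param preset `"open"` or `"closed"`.
#' @param seed Mandatory integer seed.
#' @param n_frames,dt Override the trajectory length (default 50000 frames
#'   at 2 ps).
#' @return A trajectory (see [simulate_channel_waters()]).
#' @export
channel_preset <- function(preset = c("open", "closed"), seed,
                           n_frames = 50000, dt = 2) {
  preset <- match.arg(preset)
  pot <- if (preset == "closed") harmonic_barrier(5, 7.5) else NULL
  traj <- simulate_channel_waters(n_waters = 80, box = c(40, 40, 60),
                                  radius = 15, length = 30, D = 0.3,
                                  potential = pot, temperature = 303.15,
                                  dt = dt, n_frames = n_frames, seed = seed)
  attr(traj, "ground_truth")$preset <- preset
  traj
}
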