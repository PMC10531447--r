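## Independent brute-force oracles and small fixture builders. These
## deliberately re-derive results with the simplest possible code (per-water
## loops, all-pairs scans, grid searches) so the streaming implementations
## have something external to agree with.

## --- crossing automaton replayed per water in isolation -------------------
oracle_crossings_one <- function(z, r, H, R) {
  state <- "OUT"; face <- NA_integer_; side <- NA_integer_; entry <- NA_integer_
  ev <- list()
  side_of <- function(zz) if (zz < -H) -1L else if (zz > H) 1L else NA_integer_
  for (f in seq_along(z)) {
    inside <- r[f] <= R && abs(z[f]) <= H
    if (f == 1) {
      if (inside) { state <- "IN"; face <- NA_integer_; entry <- 1L }
      else side <- side_of(z[f])
      next
    }
    if (state == "OUT") {
      if (inside) { state <- "IN"; face <- side; entry <- f }
      else side <- side_of(z[f])
    } else if (!inside) {
      exit_face <- side_of(z[f])
      if (!is.na(exit_face) && !is.na(face) && exit_face == -face)
        ev[[length(ev) + 1L]] <- c(entry = entry, exit = f, dir = exit_face)
      state <- "OUT"; face <- NA_integer_; entry <- NA_integer_
      side <- exit_face
    }
  }
  if (length(ev) == 0)
    return(data.frame(entry = integer(0), exit = integer(0), dir = integer(0)))
  as.data.frame(do.call(rbind, ev))
}

oracle_crossings <- function(traj, cyl, water_idx) {
  out <- list()
  for (w in seq_along(water_idx)) {
    zz <- numeric(n_frames(traj)); rr <- numeric(n_frames(traj))
    for (f in seq_len(n_frames(traj))) {
      p <- frame_coords(traj, f, water_idx[w])
      rel <- p - matrix(if (nrow(cyl$centers) == 1) cyl$centers[1, ]
                        else cyl$centers[f, ], 1)
      zz[f] <- sum(rel * cyl$axis)
      rr[f] <- sqrt(max(sum(rel^2) - zz[f]^2, 0))
    }
    e <- oracle_crossings_one(zz, rr, cyl$half_length, cyl$radius)
    if (nrow(e) > 0) {
      e$water_id <- traj$topology$resid[water_idx[w]]
      out[[length(out) + 1L]] <- e
    }
  }
  if (length(out) == 0)
    return(data.frame(water_id = integer(0), entry = integer(0),
                      exit = integer(0), dir = integer(0)))
  res <- do.call(rbind, out)
  res[order(res$exit, res$water_id), c("water_id", "entry", "exit", "dir")]
}

## --- per-water collective coordinate --------------------------------------
oracle_collective <- function(traj, cyl, water_idx, L) {
  nf <- n_frames(traj)
  n <- numeric(nf)
  for (f in 2:nf) {
    dn <- 0
    for (w in water_idx) {
      p1 <- frame_coords(traj, f - 1, w); p2 <- frame_coords(traj, f, w)
      c1 <- if (nrow(cyl$centers) == 1) cyl$centers[1, ] else cyl$centers[f - 1, ]
      c2 <- if (nrow(cyl$centers) == 1) cyl$centers[1, ] else cyl$centers[f, ]
      z1 <- sum((p1 - c1) * cyl$axis); z2 <- sum((p2 - c2) * cyl$axis)
      r1 <- sqrt(max(sum((p1 - c1)^2) - z1^2, 0))
      r2 <- sqrt(max(sum((p2 - c2)^2) - z2^2, 0))
      in1 <- r1 <= cyl$radius && abs(z1) <= cyl$half_length
      in2 <- r2 <= cyl$radius && abs(z2) <= cyl$half_length
      if (in1 && in2) {
        dz <- (z2 + sum(c2 * cyl$axis)) - (z1 + sum(c1 * cyl$axis))
        bz <- sum(traj$box[f, ] * abs(cyl$axis))
        dz <- dz - bz * round(dz / bz)
        dn <- dn + dz / L
      }
    }
    n[f] <- n[f - 1] + dn
  }
  n
}

## --- all-pairs minimum distance -------------------------------------------
oracle_min_dist <- function(a, b, box = NULL) {
  best <- Inf
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    d <- a[i, ] - b[j, ]
    if (!is.null(box)) d <- d - box * round(d / box)
    best <- min(best, sqrt(sum(d^2)))
  }
  best
}

## --- grid-refined rotation search for minimum RMSD ------------------------
euler_rot <- function(a, b, c) {
  Rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, byrow = TRUE)
  Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, byrow = TRUE)
  Rz2 <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3, byrow = TRUE)
  Rz1 %*% Ry %*% Rz2
}

oracle_min_rmsd <- function(mobile, reference) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  rmsd_of <- function(a, b, c) {
    R <- euler_rot(a, b, c)
    sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
  }
  best <- c(0, 0, 0); best_val <- rmsd_of(0, 0, 0)
  step <- pi / 12
  grid <- expand.grid(a = seq(0, 2 * pi, by = step),
                      b = seq(0, pi, by = step),
                      c = seq(0, 2 * pi, by = step))
  for (k in seq_len(nrow(grid))) {
    v <- rmsd_of(grid$a[k], grid$b[k], grid$c[k])
    if (v < best_val) { best_val <- v; best <- as.numeric(grid[k, ]) }
  }
  for (lvl in 1:6) {
    step <- step / 3
    loc <- expand.grid(a = best[1] + step * (-3:3),
                       b = best[2] + step * (-3:3),
                       c = best[3] + step * (-3:3))
    for (k in seq_len(nrow(loc))) {
      v <- rmsd_of(loc$a[k], loc$b[k], loc$c[k])
      if (v < best_val) { best_val <- v; best <- as.numeric(loc[k, ]) }
    }
  }
  best_val
}

## --- fixture builders ------------------------------------------------------
## single-particle trajectory following a prescribed z path at fixed (x, y)
path_trajectory <- function(z, x = 0, y = 0, box = c(60, 60, 60), dt = 1) {
  top <- topology(name = "OH2", resname = "TIP3", resid = 1, chain = "W",
                  element = "O")
  coords <- array(NA_real_, dim = c(length(z), 1, 3))
  coords[, 1, 1] <- x; coords[, 1, 2] <- y; coords[, 1, 3] <- z
  new_trajectory(top, coords, times = (seq_along(z) - 1) * dt, box = box)
}

## four chains (A-D) x n_res residues x 1 CA each, on a grid
abcd_topology <- function(n_res = 10) {
  topology(name = rep("CA", 4 * n_res),
           resname = "GLY",
           resid = rep(seq_len(n_res), 4),
           chain = rep(c("A", "B", "C", "D"), each = n_res),
           element = "C")
}

## random multi-frame trajectory over a topology (uniform in box)
random_trajectory <- function(top, n_frames, box = c(50, 50, 50), dt = 1,
                              seed = 1) {
  withr::with_seed(seed, {
    coords <- array(runif(n_frames * nrow(top) * 3, -20, 20),
                    dim = c(n_frames, nrow(top), 3))
    new_trajectory(top, coords, times = (seq_len(n_frames) - 1) * dt, box = box)
  })
}
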