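## two-group trajectory with prescribed coordinates per frame
two_group_traj <- function(frames_a, frames_b, box = c(100, 100, 100)) {
  na <- nrow(frames_a[[1]]); nb <- nrow(frames_b[[1]])
  top <- topology(name = rep("CA", na + nb), resname = "GLY",
                  resid = seq_len(na + nb), chain = c(rep("A", na), rep("B", nb)))
  nf <- length(frames_a)
  coords <- array(NA_real_, dim = c(nf, na + nb, 3))
  for (f in seq_len(nf))
    coords[f, , ] <- rbind(frames_a[[f]], frames_b[[f]])
  new_trajectory(top, coords, box = box)
}

test_that("minimal distance reproduces hand-computed geometry", {
  tr <- two_group_traj(list(matrix(c(0, 0, 0), 1)),
                       list(matrix(c(3, 4, 0), 1)))
  a <- select_atoms(tr$topology, "chain A")
  b <- select_atoms(tr$topology, "chain B")
  expect_equal(min_distance_series(tr, a, b)$distance, 5)

  ## min over a set at distances 7, 5, 9 along x
  tr2 <- two_group_traj(list(matrix(c(0, 0, 0), 1)),
                        list(matrix(c(7, 0, 0, 5, 0, 0, 9, 0, 0), 3,
                                    byrow = TRUE)))
  expect_equal(min_distance_series(tr2,
                                   select_atoms(tr2$topology, "chain A"),
                                   select_atoms(tr2$topology, "chain B"))$distance,
               5)
})

test_that("minimal distance equals the all-pairs oracle, with and without PBC", {
  withr::with_seed(11, {
    for (rep in 1:3) {
      fa <- lapply(1:10, function(f) matrix(runif(20 * 3, -30, 30), 20))
      fb <- lapply(1:10, function(f) matrix(runif(20 * 3, -30, 30), 20))
      tr <- two_group_traj(fa, fb, box = c(50, 50, 50))
      a <- select_atoms(tr$topology, "chain A")
      b <- select_atoms(tr$topology, "chain B")
      with_pbc <- min_distance_series(tr, a, b, pbc = TRUE)
      no_pbc <- min_distance_series(tr, a, b, pbc = FALSE)
      for (f in 1:10) {
        expect_equal(with_pbc$distance[f],
                     oracle_min_dist(fa[[f]], fb[[f]], box = c(50, 50, 50)))
        expect_equal(no_pbc$distance[f], oracle_min_dist(fa[[f]], fb[[f]]))
      }
    }
  })
})

test_that("minimal distance is symmetric and rigid-motion invariant", {
  withr::with_seed(21, {
    fa <- list(matrix(runif(15, -10, 10), 5))
    fb <- list(matrix(runif(24, -10, 10), 8))
    tr <- two_group_traj(fa, fb)
    a <- select_atoms(tr$topology, "chain A")
    b <- select_atoms(tr$topology, "chain B")
    d_ab <- min_distance_series(tr, a, b)$distance
    d_ba <- min_distance_series(tr, b, a)$distance
    expect_equal(d_ab, d_ba)

    ## rotate + translate both groups rigidly
    th <- 0.7
    R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
                byrow = TRUE)
    shift <- c(3, -2, 5)
    tr2 <- tr
    tr2$coords[1, , ] <- sweep(tr$coords[1, , ] %*% t(R), 2, shift, "+")
    d_moved <- min_distance_series(tr2, a, b)$distance
    expect_equal(d_moved, d_ab, tolerance = 1e-9)
  })
})

test_that("overlapping or empty selections are refused", {
  tr <- two_group_traj(list(matrix(0, 2, 3)), list(matrix(1, 2, 3)))
  expect_error(min_distance_series(tr, atom_selection(1:2), atom_selection(2:3)),
               "overlap")
  expect_error(min_distance_series(tr, atom_selection(integer(0)),
                                   atom_selection(1)), "non-empty")
})

test_that("salt-bridge formation uses a closed cutoff and reports the fraction", {
  mk <- function(dists) {
    fa <- lapply(dists, function(d) matrix(c(0, 0, 0), 1))
    fb <- lapply(dists, function(d) matrix(c(d, 0, 0), 1))
    two_group_traj(fa, fb)
  }
  tr <- mk(c(2.8))
  a <- select_atoms(tr$topology, "chain A")
  b <- select_atoms(tr$topology, "chain B")
  expect_true(salt_bridge_series(tr, a, b, cutoff = 4)$formed)
  expect_true(salt_bridge_series(mk(4.0), a, b, cutoff = 4)$formed)  # boundary
  expect_false(salt_bridge_series(mk(4.001), a, b, cutoff = 4)$formed)

  ## oscillating fixture: exactly half the frames at/below the cutoff
  osc <- mk(rep(c(3, 5), 10))
  sb <- salt_bridge_series(osc, a, b, cutoff = 4)
  expect_equal(attr(sb, "formed_fraction"), 0.5)

  ## formed fraction is monotone non-decreasing in the cutoff
  fr <- vapply(c(2, 3.5, 4.5, 6), function(co)
    attr(salt_bridge_series(osc, a, b, cutoff = co), "formed_fraction"),
    numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("superposition removes rigid motion and matches the grid oracle", {
  withr::with_seed(5, {
    ref <- matrix(runif(50 * 3, -10, 10), 50)
    ## identity
  sp0 <- superpose(ref, ref)
    expect_equal(sp0$rmsd, 0, tolerance = 1e-10)
    expect_equal(sp0$rotation, diag(3), tolerance = 1e-8)
    ## 90-degree rotation about z plus a shift
    Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE)
    mob <- sweep(ref %*% t(Rz), 2, c(5, -3, 2), "+")
    expect_equal(superpose(mob, ref)$rmsd, 0, tolerance = 1e-9)
    ## two unrelated clouds: optimal RMSD equals a grid-refined search
    cloud <- matrix(runif(50 * 3, -10, 10), 50)
    sp <- superpose(cloud, ref)
    expect_equal(sp$rmsd, oracle_min_rmsd(cloud, ref), tolerance = 1e-3)
    ## symmetry
    expect_equal(superpose(cloud, ref)$rmsd, superpose(ref, cloud)$rmsd,
                 tolerance = 1e-6)
    ## invariance under pre-rotation of the mobile set
    pre <- sweep(cloud %*% t(Rz), 2, c(1, 2, 3), "+")
    expect_equal(superpose(pre, ref)$rmsd, sp$rmsd, tolerance = 1e-9)
  })
})

test_that("superposition RMSD agrees with bio3d's independent fit", {
  withr::with_seed(27, {
    ref <- matrix(runif(30 * 3, -10, 10), 30)
    mob <- ref + matrix(rnorm(90, 0, 1.5), 30)
    own <- superpose(mob, ref)
    fitted <- bio3d::fit.xyz(fixed = as.vector(t(ref)),
                             mobile = as.vector(t(mob)),
                             fixed.inds = bio3d::atom2xyz(1:30),
                             mobile.inds = bio3d::atom2xyz(1:30))
    bio3d_rmsd <- sqrt(mean(rowSums((matrix(fitted, ncol = 3,
                                            byrow = TRUE) - ref)^2)))
    expect_equal(own$rmsd, bio3d_rmsd, tolerance = 1e-6)
  })
})

test_that("superposition refuses degenerate geometry", {
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line + 1), "collinear")
  expect_error(superpose(matrix(0, 2, 3), matrix(0, 2, 3)), "3 fit atoms")
})

test_that("RMSF is zero for rigid motion and sigma*sqrt(3) under jitter", {
  withr::with_seed(9, {
    base <- matrix(runif(30 * 3, -10, 10), 30)
    ## rigid trajectory: same structure rotated/translated every frame
    nf <- 50
    coords <- array(NA_real_, dim = c(nf, 30, 3))
    for (f in 1:nf) {
      th <- runif(1, 0, 2 * pi)
      R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
                  byrow = TRUE)
      coords[f, , ] <- sweep(base %*% t(R), 2, runif(3, -5, 5), "+")
    }
    top <- topology(name = rep("CA", 30), resname = "GLY", resid = 1:30)
    rigid <- new_trajectory(top, coords)
    expect_lt(max(rmsf(rigid)$rmsf), 1e-8)

    ## isotropic Gaussian jitter sigma = 0.5 A on mobile atoms, rigid scaffold
    sigma <- 0.5
    nf2 <- 10000
    coords2 <- array(rep(base, each = nf2), dim = c(nf2, 30, 3))
    coords2[, 16:30, ] <- coords2[, 16:30, ] + rnorm(nf2 * 15 * 3, 0, sigma)
    jit <- new_trajectory(top, coords2)
    prof <- rmsf(jit, fit_selection = atom_selection(1:15))
    expect_lt(max(abs(prof$rmsf[16:30] - sigma * sqrt(3)) / (sigma * sqrt(3))),
              0.03)
    ## mobile atoms fluctuate strictly more than the scaffold
    expect_gt(min(prof$rmsf[16:30]), max(prof$rmsf[1:15]))
  })
})

test_that("average structure is the frame for 1-frame windows and the midpoint
           for a balanced two-state flip-flop", {
  withr::with_seed(13, {
    A <- matrix(runif(20 * 3, -10, 10), 20)
    B <- A + matrix(rnorm(60, 0, 2), 20)
    nf <- 40
    coords <- array(NA_real_, dim = c(nf, 20, 3))
    for (f in 1:nf) coords[f, , ] <- if (f %% 2 == 0) A else B
    top <- topology(name = rep("CA", 20), resname = "GLY", resid = 1:20)
    tr <- new_trajectory(top, coords, times = 0:(nf - 1))

    one <- average_structure(tr, c(0, 1))
    expect_equal(one$coords, coords[1, , ], tolerance = 1e-10)
    expect_equal(one$n_frames, 1)

    avg <- average_structure(tr, c(0, nf))
    ## exact linearity of the mean: with frames alternating between B (the
    ## window's first frame) and A, the average is the midpoint of B and
    ## A-superposed-onto-B ...
    fitted_A <- superpose(A, B)$coords
    expect_equal(avg$coords, (B + fitted_A) / 2, tolerance = 1e-9)
    ## ... which is close to the raw A/B midpoint (jitter carries no net
    ## rigid motion)
    expect_lt(max(abs(avg$coords - (A + B) / 2)), 0.5)
    expect_error(average_structure(tr, c(500, 600)), "window")
  })
})

test_that("charged-group table covers the residues used in bridge analysis", {
  tab <- charged_group_atoms()
  expect_true(all(c("SEP", "ARG") %in% tab$resname))
  expect_setequal(tab$atoms[[which(tab$resname == "ARG")]],
                  c("NH1", "NH2", "NE"))
})
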