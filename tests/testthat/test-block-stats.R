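test_that("block partitioning floors to whole blocks and drops remainders", {
  b <- partition_blocks(c(0, 200000))            # 200 ns, 10-ns blocks
  expect_equal(nrow(b), 20)
  expect_equal(b$start_ps, seq(0, 190000, 10000))
  expect_equal(b$end_ps, seq(10000, 200000, 10000))

  b5 <- partition_blocks(c(0, 500000))           # 500 ns
  expect_equal(nrow(b5), 50)                     # x 4 monomers = 200 samples

  expect_warning(b2 <- partition_blocks(c(0, 25000)), "remainder")
  expect_equal(nrow(b2), 2)
  expect_error(partition_blocks(c(0, 5000)), "shorter")
})

test_that("four monomers over 500 ns yield 200 block samples", {
  tr <- simulate_channel_waters(n_waters = 10, box = c(40, 40, 60), D = 0.3,
                                dt = 500, n_frames = 1001, seed = 55)
  blocks <- partition_blocks(c(0, 500000))
  samples <- purrr::map_dfr(c("A", "B", "C", "D"), function(m)
    per_block_metric(tr, blocks, "count",
                     cylinder = fixed_cylinder(monomer = m),
                     condition = "open"))
  expect_equal(nrow(samples), 200)
  expect_equal(unique(table(samples$monomer)), 50L)
})

test_that("block count samples sum to the full-trajectory event total", {
  tr <- simulate_channel_waters(n_waters = 30, box = c(40, 40, 60), D = 0.4,
                                dt = 2, n_frames = 10000, seed = 66)
  cyl <- fixed_cylinder()
  events <- track_crossings(tr, cyl)
  blocks <- partition_blocks(c(0, 20000), 2000)
  samples <- per_block_metric(tr, blocks, "count", cylinder = cyl,
                              condition = "x")
  expect_equal(sum(samples$value), nrow(events))
})

test_that("events are assigned to blocks by exit time", {
  ## crossings completing at ~3, ~12 and ~19 ns; 10-ns blocks -> (1, 2)
  z <- rep(-20, 201)                      # 100-ps frames over 20 ns
  cross_at <- function(z, f) { z[f] <- 0; z[f + 1] <- 20; z }
  z <- cross_at(z, 30); z <- cross_at(z, 120); z <- cross_at(z, 190)
  tr <- path_trajectory(z, dt = 100)
  cyl <- fixed_cylinder()
  expect_equal(track_crossings(tr, cyl)$exit_ps, c(3000, 12000, 19000))
  samples <- per_block_metric(tr, partition_blocks(c(0, 20000)), "count",
                              cylinder = cyl, condition = "x")
  expect_equal(samples$value, c(1, 2))
})

test_that("undefined block metrics are flagged NA with a warning", {
  tr <- simulate_channel_waters(n_waters = 5, box = c(40, 40, 60), D = 0.3,
                                dt = 1000, n_frames = 25, seed = 4)
  blocks <- partition_blocks(c(0, 24000), 6000)  # 6 frames per block
  expect_warning(
    samples <- per_block_metric(tr, blocks, "pf", cylinder = fixed_cylinder(),
                                condition = "x"),
    "undefined")
  expect_true(all(is.na(samples$value)))
})

test_that("mean_min_distance blocks average the per-frame minima", {
  tr <- simulate_gating_scaffold(seed = 6, n_frames = 100, dt = 100,
                                 jitter = 0)
  a <- select_atoms(tr$topology, "resid 185-200 and name CA")
  b <- select_atoms(tr$topology, "resid 21-30 and name CA")
  samples <- per_block_metric(tr, partition_blocks(c(0, 10000), 5000),
                              "mean_min_distance", sel_a = a, sel_b = b,
                              condition = "x", pbc = FALSE)
  expect_equal(samples$value, c(6, 20))  # closed then open target separation
})

test_that("the gate chooses Student t for clean normal samples and p ~ 1 for
           identical groups", {
  x <- withr::with_seed(100, rnorm(50, 10, 2))
  samples <- tibble::tibble(condition = rep(c("a", "b"), each = 50),
                            value = c(x, x))
  res <- compare_conditions(samples)
  expect_true(res$parametric)
  expect_equal(res$test, "Student t-test")
  expect_gt(res$p_values$p, 0.9)
  expect_equal(glance(res)$min_p, res$p_values$p)
})

test_that("a 10-SD shift is detected at p < 1e-6", {
  withr::with_seed(101, {
    a <- rnorm(20); b <- rnorm(20) + 10
    samples <- tibble::tibble(condition = rep(c("a", "b"), each = 20),
                              value = c(a, b))
    expect_lt(compare_conditions(samples)$p_values$p, 1e-6)
  })
})

test_that("non-normal samples are routed to Mann-Whitney", {
  withr::with_seed(102, {
    a <- rexp(30)^3; b <- rexp(30)^3 * 2
    res <- compare_conditions(tibble::tibble(
      condition = rep(c("a", "b"), each = 30), value = c(a, b)))
    expect_false(res$parametric)
    expect_equal(res$test, "Mann-Whitney")
    expect_false(all(res$shapiro$normal))
  })
})

test_that("three normal groups use ANOVA/Tukey; skewed groups use
           Bonferroni-corrected pairwise Wilcoxon with p >= uncorrected", {
  withr::with_seed(103, {
    g <- rep(c("a", "b", "c"), each = 25)
    x_norm <- rnorm(75) + rep(c(0, 0.5, 2), each = 25)
    res_p <- compare_conditions(tibble::tibble(condition = g, value = x_norm))
    expect_equal(res_p$test, "one-way ANOVA + Tukey HSD")
    expect_equal(nrow(res_p$p_values), 3)

    x_skew <- rexp(75)^3 * rep(c(1, 1.5, 6), each = 25)
    res_np <- compare_conditions(tibble::tibble(condition = g, value = x_skew))
    expect_equal(res_np$test, "pairwise Wilcoxon rank-sum + Bonferroni")
    expect_equal(res_np$correction, "Bonferroni")
    for (i in seq_len(nrow(res_np$p_values))) {
      raw <- suppressWarnings(wilcox.test(
        x_skew[g == res_np$p_values$group1[i]],
        x_skew[g == res_np$p_values$group2[i]])$p.value)
      expect_gte(res_np$p_values$p[i] + 1e-12, raw)
      expect_lte(res_np$p_values$p[i], 1)
    }
  })
})

test_that("the decision trail is deterministic given the samples", {
  samples <- tibble::tibble(condition = rep(c("a", "b"), each = 15),
                            value = withr::with_seed(7, rnorm(30)))
  r1 <- compare_conditions(samples)
  r2 <- compare_conditions(samples)
  expect_identical(tidy(r1), tidy(r2))
  expect_identical(glance(r1), glance(r2))
  expect_identical(r1$shapiro, r2$shapiro)
})

test_that("degenerate inputs are refused", {
  expect_error(compare_conditions(tibble::tibble(condition = "a",
                                                 value = 1:5)), "two")
  expect_error(compare_conditions(tibble::tibble(
    condition = c("a", "a", "b", "b"), value = 1:4)), "3 samples")
})
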