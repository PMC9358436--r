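test_that("sample_glv_model is seed-deterministic and honors bookkeeping", {
  m1 <- sample_glv_model(3, 2, connectance_target = 0.5, seed = 11)
  m2 <- sample_glv_model(3, 2, connectance_target = 0.5, seed = 11)
  expect_identical(m1, m2)
  expect_equal(m1$kingdoms, c(rep("bacteria", 3), rep("fungi", 2)))
  expect_equal(m1$n, 5)
  expect_true(all(diag(m1$A) < 0))

  m0 <- sample_glv_model(4, 3, connectance_target = 0, seed = 2)
  off <- m0$A; diag(off) <- 0
  expect_true(all(off == 0))

  expect_error(sample_glv_model(1, 0), "at least 2")
  expect_error(sample_glv_model(3, 2, connectance_target = 2), "\\[0, 1\\]")
  expect_error(sample_glv_model(3, 2, strength_scale = -1), "positive")
  expect_error(sample_glv_model(3, 2, sign_mix = c(competition = 0.7)),
               "summing to 1")
})

test_that("realized connectance approximates the target", {
  m <- sample_glv_model(20, 10, connectance_target = 0.2, seed = 3)
  off <- m$A; diag(off) <- 0
  interacting <- sum(off[upper.tri(off)] != 0 | t(off)[upper.tri(off)] != 0)
  expect_equal(interacting / choose(30, 2), 0.2, tolerance = 0.02)
})

test_that("glv_derivative matches the hand formula", {
  m <- glv_model("s", "bacteria", r = 1, A = matrix(-1, 1, 1))
  expect_equal(glv_derivative(m, 0), 0)
  expect_equal(glv_derivative(m, 1), 0)
  expect_equal(glv_derivative(m, 0.5), 0.25)

  m2 <- sample_glv_model(3, 2, connectance_target = 0.5, seed = 4)
  expect_equal(glv_derivative(m2, rep(0, 5)), rep(0, 5))
  x <- c(0.2, 0.5, 0.1, 0.3, 0.4)
  expect_equal(glv_derivative(m2, x),
               as.numeric(x * (m2$r + m2$A %*% x)))
  expect_error(glv_derivative(m2, 1:3), "length")
})

test_that("steady-state integration reaches known fixed points", {
  m1 <- glv_model("s", "bacteria", r = 1, A = matrix(-1, 1, 1))
  xs <- integrate_to_steady_state(m1, 0.1)
  expect_equal(as.numeric(xs), 1, tolerance = 1e-6)
  expect_true(attr(xs, "converged"))

  # symmetric 2-species competition: r + A x = 0 at (2/3, 2/3)
  m2 <- glv_model(c("a", "b"), rep("bacteria", 2), c(1, 1),
                  rbind(c(-1, -0.5), c(-0.5, -1)))
  xs2 <- integrate_to_steady_state(m2, c(0.1, 0.1))
  expect_equal(as.numeric(xs2), c(2 / 3, 2 / 3), tolerance = 1e-6)

  # absent species cannot appear
  xs3 <- integrate_to_steady_state(m2, c(0.1, 0))
  expect_identical(as.numeric(xs3)[2], 0)
  expect_equal(as.numeric(xs3)[1], 1, tolerance = 1e-6)
})

test_that("interior steady states satisfy the fixed-point residual bound", {
  rel_tol <- 1e-6
  for (seed in 1:5) {
    m <- competitive_model(4, 2, seed = seed)
    xs <- integrate_to_steady_state(m, rep(0.1, m$n), rel_tol = rel_tol)
    expect_true(attr(xs, "converged"))
    expect_true(all(xs >= 0))
    s <- which(as.numeric(xs) > 0)
    resid <- max(abs(m$r[s] + (m$A %*% as.numeric(xs))[s]))
    expect_lt(resid, 10 * rel_tol * max(abs(m$r)))
  }
})

test_that("integration reports blow-up instead of clipping divergence", {
  # obligate mutualists stronger than self-limitation diverge
  m <- glv_model(c("a", "b"), rep("bacteria", 2), c(1, 1),
                 rbind(c(-0.1, 2), c(2, -0.1)))
  expect_error(integrate_to_steady_state(m, c(1, 1)), "blew up")
})

test_that("subset profiles respect masks and the diagonal-only closed form", {
  m <- sample_glv_model(4, 2, connectance_target = 0, seed = 6)
  prof <- simulate_subset_profiles(m, 12, inclusion_prob = 0.5, seed = 9)
  expect_equal(nrow(prof$profiles), 12)
  expect_true(all(prof$profiles[prof$subset_masks == 0] == 0))
  expect_true(all(prof$converged))
  # no interactions: every included species sits at its carrying capacity
  cc <- -m$r / diag(m$A)
  for (s in 1:12) {
    inc <- which(prof$subset_masks[s, ] == 1)
    expect_equal(prof$profiles[s, inc], cc[inc], tolerance = 1e-6)
  }
})

test_that("inclusion_prob 1 gives identical profiles for a stable community", {
  m <- competitive_model(3, 2, seed = 8)
  prof <- simulate_subset_profiles(m, 5, inclusion_prob = 1, seed = 2)
  for (s in 2:5)
    expect_equal(prof$profiles[s, ], prof$profiles[1, ], tolerance = 1e-8)
})

test_that("read sampling conserves depth and zeros, and converges at high depth", {
  m <- competitive_model(4, 2, seed = 3)
  prof <- simulate_subset_profiles(m, 10, seed = 4)
  tab <- sample_reads(prof, depth = 500, seed = 5)
  expect_true(all(rowSums(tab$values) == 500))
  expect_true(all(tab$values[prof$profiles[prof$converged, ] == 0] == 0))

  tab2 <- sample_reads(prof, depth = 500, seed = 5)
  expect_identical(tab$values, tab2$values)

  deep <- sample_reads(prof, depth = 1e6, seed = 6)
  truth <- prof$profiles / rowSums(prof$profiles)
  est <- deep$values / 1e6
  expect_lt(max(abs(est - truth)), 0.01)
})

test_that("time-series simulation matches the deterministic limit and seeds", {
  m <- glv_model(c("a", "b"), rep("bacteria", 2), c(1, 1),
                 rbind(c(-1, -0.5), c(-0.5, -1)))
  times <- seq(0, 20, by = 0.5)
  tr0 <- simulate_time_series(m, c(0.1, 0.1), times, process_noise_sd = 0)
  expect_identical(tr0$abundances[1, ], c(a = 0.1, b = 0.1))
  expect_equal(as.numeric(tr0$abundances[nrow(tr0$abundances), ]),
               c(2 / 3, 2 / 3), tolerance = 1e-5)
  expect_true(all(tr0$abundances >= 0))

  tr1 <- simulate_time_series(m, c(0.1, 0.1), times, 0.1, seed = 7)
  tr2 <- simulate_time_series(m, c(0.1, 0.1), times, 0.1, seed = 7)
  expect_identical(tr1$abundances, tr2$abundances)
  expect_false(identical(tr0$abundances, tr1$abundances))

  expect_error(simulate_time_series(m, c(0.1, 0.1), c(0, 1, 0.5)),
               "strictly increasing")
})
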