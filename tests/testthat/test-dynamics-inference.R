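test_that("noise-free logistic series recovers r and a within 5%", {
  m <- glv_model("s", "bacteria", r = 1, A = matrix(-1, 1, 1))
  tr <- simulate_time_series(m, 0.05, seq(0, 8, by = 0.05))
  fit <- infer_glv(tr, ridge_lambda = 1e-6)
  expect_gt(fit$r_hat, 0.95); expect_lt(fit$r_hat, 1.05)
  expect_gt(fit$A_hat[1, 1], -1.05); expect_lt(fit$A_hat[1, 1], -0.95)
})

test_that("a huge ridge penalty shrinks interaction estimates to zero", {
  m <- sample_glv_model(3, 0, connectance_target = 0.5,
                        sign_mix = c(competition = 1, predation = 0,
                                     mutualism = 0, commensalism = 0,
                                     amensalism = 0),
                        strength_scale = 0.3, seed = 2)
  tr <- simulate_time_series(m, rep(0.1, 3), seq(0, 20, by = 0.2))
  fit <- infer_glv(tr, ridge_lambda = 1e6)
  expect_true(all(abs(fit$A_hat) < 1e-3))
})

test_that("3-species sign pattern is recovered from a noisy series", {
  A <- rbind(c(-1.0, 0.3, -0.4),
             c(-0.2, -1.0, 0.5),
             c(0.1, -0.3, -1.0))
  m <- glv_model(paste0("s", 1:3), rep("bacteria", 3), c(0.8, 1.0, 0.6), A)
  # low inoculum + dense sampling keeps the informative growth transient
  # in the data; post-equilibrium samples carry no signal
  tr <- simulate_time_series(m, rep(0.05, 3), seq(0, 25, length.out = 100),
                             process_noise_sd = 0.02, seed = 42)
  fit <- infer_glv(tr, ridge_lambda = 1e-3)
  agree <- sum(sign(fit$A_hat) == sign(A))
  expect_gte(agree, 7)
})

test_that("interaction-matrix error shrinks as noise goes to zero", {
  A <- rbind(c(-1.0, 0.3, -0.4),
             c(-0.2, -1.0, 0.5),
             c(0.1, -0.3, -1.0))
  m <- glv_model(paste0("s", 1:3), rep("bacteria", 3), c(0.8, 1.0, 0.6), A)
  err <- sapply(c(0.1, 0.02, 0), function(sd) {
    tr <- simulate_time_series(m, rep(0.2, 3), seq(0, 25, by = 0.25),
                               process_noise_sd = sd, seed = 13)
    fit <- infer_glv(tr, ridge_lambda = 1e-4)
    median(abs(fit$A_hat - A))
  })
  expect_true(all(diff(err) < 0))
})

test_that("absent species are excluded with zeroed interaction estimates", {
  m <- glv_model(c("a", "b"), rep("bacteria", 2), c(1, 1),
                 rbind(c(-1, 0), c(0, -1)))
  tr <- simulate_time_series(m, c(0.1, 0), seq(0, 8, by = 0.1))
  expect_warning(fit <- infer_glv(tr), "absent")
  expect_identical(fit$excluded, "b")
  expect_true(is.na(fit$r_hat["b"]))
  expect_true(all(fit$A_hat["b", ] == 0) && all(fit$A_hat[, "b"] == 0))
  expect_equal(unname(fit$r_hat["a"]), 1, tolerance = 0.05)
})

test_that("pooling replicate series sharpens the estimates", {
  A <- rbind(c(-1.0, 0.3, -0.4), c(-0.2, -1.0, 0.5), c(0.1, -0.3, -1.0))
  m <- glv_model(paste0("s", 1:3), rep("bacteria", 3), c(0.8, 1.0, 0.6), A)
  series <- lapply(1:3, function(k)
    simulate_time_series(m, c(0.05, 0.1, 0.02)[c(k, k %% 3 + 1,
                                                 (k + 1) %% 3 + 1)],
                         seq(0, 20, length.out = 80),
                         process_noise_sd = 0.05, seed = 300 + k))
  fit1 <- infer_glv(series[[1]], ridge_lambda = 1e-3)
  fit3 <- infer_glv(series, ridge_lambda = 1e-3)
  expect_lte(median(abs(fit3$A_hat - A)), median(abs(fit1$A_hat - A)))
  # pooled fit with zero noise is near-exact
  clean <- lapply(1:3, function(k)
    simulate_time_series(m, c(0.05, 0.1, 0.02)[c(k, k %% 3 + 1,
                                                 (k + 1) %% 3 + 1)],
                         seq(0, 20, length.out = 80)))
  fitc <- infer_glv(clean, ridge_lambda = 1e-6)
  expect_lt(max(abs(fitc$A_hat - A)), 0.05)
})

test_that("infer_glv rejects series that are too short", {
  m <- glv_model("s", "bacteria", 1, matrix(-1, 1, 1))
  tr <- simulate_time_series(m, 0.1, c(0, 1))
  expect_error(infer_glv(tr), "3 time points")
})

test_that("classify_interaction implements the sign table", {
  # ODE convention: effect of i on j is A[j, i]
  eff <- function(e_ij, e_ji) {
    A <- diag(c(-1, -1))
    A[2, 1] <- e_ij; A[1, 2] <- e_ji
    as.character(classify_interaction(A, 1, 2, tol = 1e-9))
  }
  expect_equal(eff(-0.5, 0.5), "predation_i_on_j")
  expect_equal(eff(0.5, -0.5), "predation_j_on_i")
  expect_equal(eff(-0.5, -0.5), "competition")
  expect_equal(eff(0.5, 0.5), "mutualism")
  expect_equal(eff(0.5, 0), "commensalism")
  expect_equal(eff(0, -0.5), "amensalism")
  expect_equal(eff(0, 0), "neutral")
  expect_equal(eff(1e-12, -1e-12), "neutral")  # sub-tolerance effects
})

test_that("classification is role-symmetric and scale-invariant", {
  set.seed(21)
  for (rep in 1:20) {
    A <- matrix(rnorm(9), 3, 3); diag(A) <- -1
    lab12 <- as.character(classify_interaction(A, 1, 2))
    lab21 <- as.character(classify_interaction(A, 2, 1))
    swap <- c(mutualism = "mutualism", competition = "competition",
              predation_i_on_j = "predation_j_on_i",
              predation_j_on_i = "predation_i_on_j",
              commensalism = "commensalism", amensalism = "amensalism",
              neutral = "neutral")
    expect_equal(unname(swap[lab12]), lab21)
    expect_equal(as.character(classify_interaction(3.7 * A, 1, 2)), lab12)
  }
  expect_error(classify_interaction(diag(2) * -1, 1, 1), "differ")
  expect_error(classify_interaction(diag(2) * -1, 1, 5), "out of range")
})

test_that("classify_interactions tabulates every unordered pair", {
  A <- rbind(c(-1, 0.5, 0), c(-0.4, -1, 0), c(0, 0, -1))
  tab <- classify_interactions(A, tol = 1e-9)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$label[tab$i == "1" & tab$j == "2"], "predation_i_on_j")
  expect_equal(tab$label[tab$i == "1" & tab$j == "3"], "neutral")
})
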