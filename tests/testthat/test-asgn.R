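test_that("norm test arithmetic is exact", {
  nt <- norm_test(c(1, 0), list(c(1, 1), c(1, -1)), gamma = 1)
  expect_equal(nt$V2, 1)
  expect_true(nt$pass)                      # boundary is inclusive
  expect_false(norm_test(c(1, 0), list(c(1, 1), c(1, -1)), 0.99)$pass)
  # zero spread
  nt0 <- norm_test(c(2, 3), list(c(2, 3), c(2, 3)), gamma = 1e-6)
  expect_equal(nt0$V2, 0)
  expect_true(nt0$pass)
  # scale invariance (degree-zero homogeneity)
  for (cc in c(0.1, 7)) {
    nt_s <- norm_test(cc * c(1, 0), list(cc * c(1, 1), cc * c(1, -1)), 1)
    expect_equal(nt_s$V2, 1, tolerance = 1e-14)
  }
  expect_error(norm_test(c(0, 0), list(c(1, 1)), 1), "zero")
})

test_that("packet-count update follows the variance ratio", {
  expect_identical(update_packet_count(1000, 1, 1), 1000)   # boundary pass
  expect_identical(update_packet_count(1000, 4, 1), 4000)
  expect_identical(update_packet_count(1000, 2.5, 1), 2500)
  expect_identical(update_packet_count(1000, 2.5, 1, cap = 2000), 2000)
  expect_identical(update_packet_count(1000, 0.1, 1), 1000)
  # rounding is upward
  expect_identical(update_packet_count(999, 1.0001, 0.5),
                   ceiling(999 * 1.0001 / 0.25))
})

test_that("identical samples collapse the ensemble", {
  prob <- surrogate_problem(K = 4L, M = 8L, noise_scale = 1)
  ens <- direction_ensemble(prob, prob$prior_scaled$mean, P = 100, L = 3L,
                            seeds = rep(5, 3))
  for (d in ens$delta) expect_equal(d, ens$delta_bar, tolerance = 1e-12)
})

test_that("the averaged direction is not the average of directions", {
  # J enters the solve nonlinearly, so averaging (Y, J) first differs from
  # averaging the per-sample directions
  pr <- build_ou_prior(matrix(c(0, 0), ncol = 2), 1, 1, 0.5, 0, 0)
  pr$precision <- prior_precision(pr)
  meas <- structure(list(values = 1, sigma = 0.1, eta = 0),
                    class = "ot_measurement")
  Js <- list(matrix(c(1, 0), 1), matrix(c(3, 0), 1))
  forward <- function(x, P, seed) {
    J <- Js[[seed]]
    list(y = as.numeric(J %*% x), J = J)
  }
  prob <- structure(list(meas = meas, prior_scaled = pr,
                         transform = scaling_transform(1, 1), K = 1L,
                         g = 0.9, forward = forward), class = "ot_problem")
  ens <- direction_ensemble(prob, c(0, 0), P = 1, L = 2L, seeds = c(1, 2))
  mean_dir <- (ens$delta[[1]] + ens$delta[[2]]) / 2
  expect_gt(sum(abs(ens$delta_bar - mean_dir)), 1e-3)
})

test_that("ensemble spread scales inversely with the packet budget", {
  prob <- surrogate_problem(K = 4L, M = 8L, noise_scale = 1)
  v2_at <- function(P, seed) {
    ens <- direction_ensemble(prob, prob$prior_scaled$mean, P, L = 6L,
                              seeds = seed + 1:6)
    norm_test(ens$delta_bar, ens$delta, 1)$V2
  }
  v_small <- mean(vapply(1:20, function(s) v2_at(200, 1000 * s), numeric(1)))
  v_large <- mean(vapply(1:20, function(s) v2_at(800, 5000 * s), numeric(1)))
  expect_gt(v_large / v_small, 0.15)
  expect_lt(v_large / v_small, 0.4)
})

test_that("a noise-free model keeps the budget flat and matches plain GN", {
  prob <- surrogate_problem(K = 4L, M = 8L, noise_scale = 0)
  ra <- run_asgn(prob, L = 3L, gamma = 1, P_init = 10, P_cap = 1e6,
                 iterations = 4L, seed = 2, positivity_floor = NULL,
                 final_objective = FALSE)
  expect_true(all(ra$history$V2 == 0))
  expect_true(all(ra$history$pass))
  expect_true(all(ra$history$P == 10))
  rs <- run_sgn(prob, P = 10, iterations = 4L, seed = 2,
                positivity_floor = NULL, final_objective = FALSE)
  expect_equal(ra$x, rs$x, tolerance = 1e-12)
})

test_that("budgets never decrease and runs are reproducible", {
  prob <- surrogate_problem(K = 4L, M = 8L, noise_scale = 2)
  a <- suppressWarnings(
    run_asgn(prob, L = 4L, gamma = 0.3, P_init = 20, P_cap = 1e5,
             iterations = 6L, seed = 3, positivity_floor = NULL,
             final_objective = FALSE))
  expect_true(all(diff(a$history$P) >= 0))
  expect_equal(a$history$cum_packets,
               cumsum(4 * a$history$P))
  expect_equal(a$history$cum_packets_single, cumsum(a$history$P))
  b <- suppressWarnings(
    run_asgn(prob, L = 4L, gamma = 0.3, P_init = 20, P_cap = 1e5,
             iterations = 6L, seed = 3, positivity_floor = NULL,
             final_objective = FALSE))
  expect_identical(a$history, b$history)
  expect_identical(a$x, b$x)
})

test_that("hitting the packet cap warns and continues", {
  prob <- surrogate_problem(K = 4L, M = 8L, noise_scale = 5)
  expect_warning(
    run_asgn(prob, L = 4L, gamma = 0.05, P_init = 20, P_cap = 100,
             iterations = 4L, seed = 1, positivity_floor = NULL,
             final_objective = FALSE),
    "cap")
})

test_that("a larger ensemble converges in fewer iterations", {
  prob <- surrogate_problem(K = 5L, M = 10L, noise_scale = 4)
  run_L <- function(L) suppressWarnings(
    run_asgn(prob, L = L, gamma = 0.5, P_init = 10,
             P_cap = 1e9, iterations = 8L, seed = 4,
             positivity_floor = NULL, final_objective = FALSE))
  r5 <- run_L(3L)
  r20 <- run_L(12L)
  thresh <- max(min(r5$history$u), min(r20$history$u)) * 1.05
  first_below <- function(r) which(r$history$u <= thresh)[1]
  expect_lte(first_below(r20), first_below(r5))
  # larger ensembles burn more packets per iteration
  expect_gt(r20$history$cum_packets[1], r5$history$cum_packets[1])
})
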