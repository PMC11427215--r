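test_that("relative errors follow the Euclidean definition", {
  g <- 0.9
  t1 <- optical_field(c(1, 1), c(2, 2), g)
  expect_equal(relative_error(t1, t1), c(E_mua = 0, E_mus = 0))
  est <- optical_field(1.1 * t1$mua, 1.1 * t1$mus, g)
  expect_equal(relative_error(est, t1), c(E_mua = 10, E_mus = 10),
               tolerance = 1e-12)
  e2 <- optical_field(c(2, 0), c(2, 2), g)
  expect_equal(unname(relative_error(e2, t1)["E_mua"]), 100,
               tolerance = 1e-12)
  expect_error(relative_error(est, optical_field(c(0, 0), c(0, 0), g)),
               "zero-norm")
})

test_that("truth projection is value-preserving and piecewise constant", {
  fine <- coarse_mesh()
  f <- make_phantom("circles", fine)
  # identical meshes give the identity map
  same <- project_truth(f, fine, fine)
  expect_equal(same$mua, f$mua)
  expect_equal(same$mus, f$mus)
  # homogeneous fields project to homogeneous fields
  hom <- homogeneous_field(fine, 0.02, 0.3)
  recon <- tiny_mesh()
  ph <- project_truth(hom, fine, recon)
  expect_true(all(ph$mua == 0.02) && all(ph$mus == 0.3))
  # projection introduces no new values
  pf <- project_truth(f, fine, recon)
  expect_true(all(pf$mua %in% unique(f$mua)))
  expect_true(all(pf$mus %in% unique(f$mus)))
})

test_that("simulated datasets have the advertised shape and noise", {
  ds <- fixture("small_ds", function()
    simulate_dataset("circles", edge_length = 0.8, packets = 4e4,
                     seed = 3, n_sources = 2L, n_detectors = 3L,
                     mc_error_model = FALSE))
  expect_equal(dim(ds$Y), c(2L, 3L))
  expect_length(ds$noiseless$values, 12L)   # 2 x (2 sources x 3 detectors)
  expect_length(ds$noisy$values, 12L)
  expect_equal(ds$noisy$sigma, 0.01 * abs(ds$noiseless$values))
  # data vector matches the complex exitance it was built from
  expect_equal(ds$noiseless$values, exitance_to_data(ds$Y))
  # the default noise model additionally carries the MC sampling error
  dse <- simulate_dataset("circles", edge_length = 0.8, packets = 4e4,
                          seed = 3, n_sources = 2L, n_detectors = 3L)
  expect_true(all(dse$noisy$sigma >= 0.01 * abs(dse$noiseless$values)))
  expect_gt(max(dse$noisy$sigma / (0.01 * abs(dse$noiseless$values))), 1.05)
  ds0 <- simulate_dataset("circles", edge_length = 0.8, packets = 4e4,
                          seed = 3, n_sources = 2L, n_detectors = 3L,
                          noise_level = 0)
  expect_identical(ds0$noisy$values, ds0$noiseless$values)
})

test_that("measurements, fields and configs round-trip through disk", {
  ds <- fixture("small_ds", function()
    simulate_dataset("circles", edge_length = 0.8, packets = 4e4,
                     seed = 3, n_sources = 2L, n_detectors = 3L))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_measurements(ds$noisy, p)
  back <- read_measurements(p)
  expect_equal(back$values, ds$noisy$values)
  expect_equal(back$sigma, ds$noisy$sigma)

  f <- ds$field
  pf <- withr::local_tempfile(fileext = ".tsv")
  write_field(f, pf)
  f2 <- read_field(pf)
  expect_equal(f2$mua, f$mua)
  expect_equal(f2$mus, f$mus)
  expect_equal(f2$g, f$g)

  mc <- mc_simulate(homogeneous_field(tiny_mesh(), mus = 0.4), tiny_mesh(),
                    ref_domain(),
                    place_sources_detectors(ref_domain(), tiny_mesh(),
                                            2L, 2L, 0.5),
                    1L, 2000, seed = 4)
  mcp <- withr::local_tempfile(fileext = ".txt")
  write_mc_result(mc, mcp)
  lines <- readLines(mcp)
  expect_true(any(startsWith(lines, "exitance")))
  expect_true(any(startsWith(lines, "S_a")))
  expect_true(any(startsWith(lines, "S_s")))
  ex <- utils::read.delim(text = lines[3:(2 + 1 + length(mc$Y))])
  expect_equal(complex(real = ex$re, imaginary = ex$im), as.vector(mc$Y))

  cfgp <- withr::local_tempfile(fileext = ".yaml")
  cfg <- list(sigma_mua = 0.0067, sigma_mus = 0.033, tau = 0.5,
              eta_mua = 0.01, eta_mus = 0.1, noise_level = 0.01, seed = 7L)
  write_config(cfg, cfgp)
  expect_equal(read_config(cfgp), cfg)
})

surrogate_problem_with_truth <- function() {
  prob <- surrogate_problem(K = 3L, M = 6L, noise_scale = 0)
  prob$truth <- optical_field(abs(prob$x_true[1:3]), abs(prob$x_true[4:6]),
                              0.9)
  prob$prior$mean <- prob$prior_scaled$mean
  prob
}

test_that("repeat_study summarizes per-run metrics exactly", {
  prob <- surrogate_problem(K = 4L, M = 8L, noise_scale = 1)
  prob$truth <- optical_field(abs(prob$x_true[1:4]), abs(prob$x_true[5:8]),
                              0.9)
  prob$prior$mean <- prob$prior_scaled$mean
  st <- repeat_study(prob, method = "sgn",
                     config = list(P = 100, iterations = 3L,
                                   positivity_floor = NULL),
                     n_repeats = 3L, seed = 5)
  expect_equal(nrow(st$runs), 3L)
  expect_equal(st$summary$mean[st$summary$metric == "E_mua"],
               mean(st$runs$E_mua), tolerance = 1e-14)
  expect_equal(st$summary$mean[st$summary$metric == "u"],
               mean(st$runs$u), tolerance = 1e-14)
  # deterministic surrogate: identical seeds give zero spread
  st0 <- repeat_study(surrogate_problem_with_truth(),
                      method = "sgn",
                      config = list(P = 10, iterations = 2L,
                                    positivity_floor = NULL),
                      n_repeats = 2L, seed = 1)
  expect_equal(st0$summary$sd[st0$summary$metric == "u"], 0,
               tolerance = 1e-12)
})

test_that("experiment presets carry the reference solver settings", {
  d <- otmc_preset("desk", "circles")
  expect_equal(d$config$gamma, 1)
  expect_equal(d$config$P_init, 1000)
  expect_equal(d$config$iterations, 10L)
  h <- otmc_preset("paper", "high_scattering")
  expect_equal(h$config$gamma, 0.6)
  expect_equal(h$config$P_init, 1e4)
  expect_equal(h$data$packets, 1e9)
  p <- otmc_preset("paper", "circles")
  expect_equal(p$data$packets, 1e10)
  expect_equal(p$config$L, 10L)
})
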