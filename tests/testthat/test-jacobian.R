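test_that("single-path accumulators reproduce the estimator algebra", {
  # one packet, weight w, path l_k in element k, exit on detector b
  w <- complex(real = 0.6, imaginary = -0.2)
  P <- 1; A <- c(0.5, 0.7)
  S_a <- matrix(0 + 0i, nrow = 2, ncol = 3)
  S_s <- matrix(0 + 0i, nrow = 2, ncol = 3)
  lk <- 1.3; nk <- 2; mus_k <- 0.8
  S_a[1, 2] <- lk * w
  S_s[1, 2] <- (nk / mus_k - lk) * w
  mc <- structure(list(S_a = S_a, S_s = S_s, P = P, A = A),
                  class = "mc_result")
  da <- complex_dY_dmua(mc)
  expect_equal(da[1, 2], -lk * w / (P * A[1]))
  expect_identical(da[2, 3], 0 + 0i)  # element never visited
  ds <- complex_dY_dmus(mc, NULL)
  expect_equal(ds[1, 2], (nk / mus_k - lk) * w / (P * A[1]))
})

test_that("perturbation reweighting has the exact closed form", {
  w <- complex(real = 0.4, imaginary = 0.3)
  # identity perturbation
  expect_identical(perturbed_weight(w, 0.5, 0.5, 3, 2.2), w)
  # no scattering events: pure exponential factor
  expect_equal(perturbed_weight(w, 0.5, 0.6, 0, 2), w * exp(-0.1 * 2))
  # derivative at the unperturbed point matches the Jacobian integrand
  mus <- 0.5; ns <- 4; L <- 3.1; h <- 1e-7
  num <- (perturbed_weight(w, mus, mus + h, ns, L) -
          perturbed_weight(w, mus, mus - h, ns, L)) / (2 * h)
  expect_equal(num, (ns / mus - L) * w, tolerance = 1e-6)
  expect_error(perturbed_weight(w, 0, 0.1, 2, 1), "mus = 0")
})

test_that("amplitude/phase chain rule matches finite differences", {
  Y <- complex(real = c(0.3, -0.1), imaginary = c(0.2, 0.4))
  # pure rotation: amplitude unchanged, phase slope one
  J <- assemble_jacobian(matrix(1i * Y, ncol = 1), matrix(0i, 2, 1), Y)
  expect_equal(J[1:2, 1], c(0, 0), tolerance = 1e-14)
  expect_equal(J[3:4, 1], c(1, 1), tolerance = 1e-14)
  # pure scaling: amplitude slope |Y|, no phase change
  J2 <- assemble_jacobian(matrix(Y, ncol = 1), matrix(0i, 2, 1), Y)
  expect_equal(J2[1:2, 1], Mod(Y), tolerance = 1e-14)
  expect_equal(J2[3:4, 1], c(0, 0), tolerance = 1e-14)
  # generic complex direction vs finite differences
  set.seed(33)
  dY <- complex(real = stats::rnorm(2), imaginary = stats::rnorm(2))
  J3 <- assemble_jacobian(matrix(dY, ncol = 1), matrix(0i, 2, 1), Y)
  eps <- 1e-7
  fd_amp <- (Mod(Y + eps * dY) - Mod(Y - eps * dY)) / (2 * eps)
  fd_phs <- (Arg(Y + eps * dY) - Arg(Y - eps * dY)) / (2 * eps)
  expect_equal(J3[1:2, 1], fd_amp, tolerance = 1e-6)
  expect_equal(J3[3:4, 1], fd_phs, tolerance = 1e-6)
  expect_error(assemble_jacobian(matrix(dY, ncol = 1), matrix(0i, 2, 1),
                                 c(0 + 0i, Y[2])), "zero sampled exitance")
})

test_that("absorption derivatives equal frozen-path finite differences", {
  dom <- ref_domain()
  m <- fan_mesh()
  K <- nrow(m$triangles)
  lay <- place_sources_detectors(dom, m, 4L, 4L, 3)
  f <- optical_field(rep(0.01, K), rep(0.5, K), g = 0.9)
  P <- 2e4
  mc <- mc_simulate(f, m, dom, lay, 1L, P, seed = 11)
  dYa <- complex_dY_dmua(mc)
  h <- 1e-5
  ks <- c(2L, 9L, 17L, 25L)
  fd <- vapply(ks, function(k) {
    fp <- f; fm <- f
    fp$mua[k] <- fp$mua[k] + h
    fm$mua[k] <- fm$mua[k] - h
    Yp <- mc_simulate(fp, m, dom, lay, 1L, P, seed = 11,
                      record_jacobian = FALSE)$Y
    Ym <- mc_simulate(fm, m, dom, lay, 1L, P, seed = 11,
                      record_jacobian = FALSE)$Y
    Re((Yp - Ym) / (2 * h))
  }, numeric(4L))
  # with common random numbers the paths are identical, so agreement is
  # limited only by the finite-difference truncation
  expect_gt(stats::cor(as.vector(fd), as.vector(Re(dYa[, ks]))), 0.9999)
  expect_lt(max(abs(fd - Re(dYa[, ks]))) / max(abs(fd)), 1e-6)
})

test_that("perturbation reweighting predicts a perturbed-medium run", {
  dom <- ref_domain()
  m <- fan_mesh()
  K <- nrow(m$triangles)
  lay <- place_sources_detectors(dom, m, 4L, 4L, 3)
  f <- optical_field(rep(0.01, K), rep(0.5, K), g = 0.9)
  P <- 2e5
  kp <- 7L
  mus_new <- 0.5 * 1.01
  mc <- mc_simulate(f, m, dom, lay, 1L, P, seed = 21,
                    perturb = list(element = kp, mus = mus_new))
  # derivative-based prediction of the same perturbation
  dYs <- complex_dY_dmus(mc, f)
  pred <- mc$Y + dYs[, kp] * (mus_new - 0.5)
  expect_lt(max(Mod(mc$Y_pert - pred)) / max(Mod(mc$Y)), 1e-4)
  # independent re-simulation of the perturbed medium
  f2 <- f; f2$mus[kp] <- mus_new
  reps <- sapply(1:6, function(s)
    mc_simulate(f2, m, dom, lay, 1L, P, seed = 300 + s,
                record_jacobian = FALSE)$Y)
  resim <- rowMeans(reps)
  se <- apply(reps, 1, function(z) stats::sd(Re(z))) / sqrt(6)
  pm_se <- se * sqrt(1 + 6)  # reweighted estimate carries its own MC error
  expect_true(all(abs(Re(mc$Y_pert) - Re(resim)) < 4 * pm_se))
})

test_that("Jacobian entries tighten as one over the square root of P", {
  dom <- ref_domain()
  m <- fan_mesh()
  K <- nrow(m$triangles)
  lay <- place_sources_detectors(dom, m, 4L, 4L, 3)
  f <- optical_field(rep(0.01, K), rep(0.5, K), g = 0.9)
  entry_sd <- function(P) {
    v <- vapply(1:10, function(s) {
      mc <- mc_simulate(f, m, dom, lay, 1L, P, seed = 500 + s)
      Re(complex_dY_dmus(mc, f)[2, 5])
    }, numeric(1L))
    stats::sd(v)
  }
  r <- entry_sd(2e3) / entry_sd(8e3)
  expect_gt(r, 1.3)
  expect_lt(r, 3)
})

test_that("absorption-amplitude sensitivity concentrates between the pair", {
  dom <- ref_domain()
  m <- coarse_mesh()
  K <- nrow(m$triangles)
  lay <- ref_layout()
  f <- optical_field(rep(0.01, K), rep(0.5, K), g = 0.9)
  mc <- mc_simulate(f, m, dom, lay, 1L, 1e6, seed = 8)
  sj <- stochastic_jacobian(list(mc), f)
  # source 1 sits at angle 0; detector 4 is a moderate-separation pair
  b <- 4L
  row <- sj$J[b, 1:K]  # amplitude row w.r.t. absorption
  expect_true(all(row <= 1e-6 * max(abs(row))))
  mid <- (lay$source_centers[1] + lay$detector_centers[b]) / 2
  nrm <- c(cos(mid), sin(mid))
  in_half <- (m$centroids %*% nrm) > 0
  expect_gte(sum(abs(row[in_half])) / sum(abs(row)), 0.95)
})
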