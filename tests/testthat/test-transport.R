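test_that("Henyey-Greenstein sampling matches its density", {
  # normalization by quadrature
  for (g in c(-0.5, 0, 0.5, 0.9)) {
    expect_equal(stats::integrate(hg_density, -pi, pi, g = g,
                                  rel.tol = 1e-12)$value, 1,
                 tolerance = 1e-10)
  }
  # g = 0 reduces to the uniform angle distribution
  set.seed(101)
  th0 <- sample_hg_angle(0, stats::runif(1e5))
  ks <- suppressWarnings(stats::ks.test(th0, "punif", -pi, pi))
  expect_gt(ks$p.value, 0.01)
  # mean cosine equals g (anisotropy definition), 3 standard errors
  for (g in c(0.5, 0.9)) {
    set.seed(202)
    ct <- cos(sample_hg_angle(g, stats::runif(2e5)))
    se <- stats::sd(ct) / sqrt(length(ct))
    expect_lt(abs(mean(ct) - g), 3 * se)
  }
  expect_error(sample_hg_angle(1, 0.5), "anisotropy")
})

test_that("free-path sampling is exponential and respects interfaces", {
  dom <- ref_domain()
  m <- tiny_mesh()
  K <- nrow(m$triangles)
  # effectively infinite medium: mean free path far below the radius
  mus0 <- 5
  f <- optical_field(rep(0, K), rep(mus0, K), g = 0.9)
  set.seed(7)
  n <- 4000
  us <- stats::runif(n)
  lens <- vapply(seq_len(n), function(i) {
    r <- sample_scattering_site(f, m, c(0, 0), c(cos(i), sin(i)), u = us[i])
    expect_true(r$scattered)
    r$s_tot
  }, numeric(1L))
  se <- stats::sd(lens) / sqrt(n)
  expect_lt(abs(mean(lens) - 1 / mus0), 3 * se)

  # mus = 0: always exits along the full chord
  f0 <- optical_field(rep(0, K), rep(0, K), g = 0.9)
  r <- sample_scattering_site(f0, m, c(-3, 0), c(1, 0), u = 0.99)
  expect_false(r$scattered)
  expect_true(r$exited)
  expect_equal(sum(r$lengths), r$s_tot)

  # piecewise-constant depth accounting across elements
  fv <- optical_field(rep(0, K), 0.05 + seq_len(K) / K, g = 0.9)
  depth <- 0.8
  r2 <- sample_scattering_site(fv, m, c(-2.5, 0.3), c(1, 0.2), depth = depth)
  if (r2$scattered)
    expect_equal(sum(fv$mus[r2$elements] * r2$lengths), depth,
                 tolerance = 1e-10)
  else
    expect_lt(sum(fv$mus[r2$elements] * r2$lengths), depth)
})

test_that("packet weights follow the attenuation and phase law exactly", {
  dom <- ref_domain()
  m <- coarse_mesh()
  K <- nrow(m$triangles)
  # Beer-Lambert on a straight chord (no scattering)
  mua0 <- 0.07
  f <- optical_field(rep(mua0, K), rep(0, K), g = 0.9)
  pp <- propagate_packet(f, m, dom, c(-3.9, 0.4), c(1, 0), seed = 5)
  expect_true(pp$exited)
  L <- pp$s_tot
  expect_equal(Mod(pp$w), exp(-mua0 * L), tolerance = 1e-14)
  ph <- (-dom$omega_over_c * L) %% (2 * pi)
  if (ph > pi) ph <- ph - 2 * pi
  expect_equal(Arg(pp$w), ph, tolerance = 1e-12)

  # heterogeneous absorption: log|w| = -sum mua_k l_k from the recorded path
  set.seed(9)
  fv <- optical_field(stats::runif(K, 0, 0.3), rep(0.8, K), g = 0.6)
  pv <- propagate_packet(fv, m, dom, c(0.3, -0.2), c(0.6, 0.8), seed = 12,
                         termination_threshold = 0)
  expect_equal(log(Mod(pv$w)),
               -sum(fv$mua[pv$elements] * pv$lengths), tolerance = 1e-10)
  expect_equal(sum(pv$lengths), pv$s_tot, tolerance = 1e-10)

  # no absorption, zero frequency: unit weight no matter the path
  dom0 <- cw_domain()
  f0 <- optical_field(rep(0, K), rep(1, K), g = 0.9)
  p0 <- propagate_packet(f0, m, dom0, c(0, 0), c(1, 1), seed = 3,
                         termination_threshold = 0)
  expect_equal(Mod(p0$w), 1, tolerance = 1e-14)
})

test_that("boundary exit weight is conserved without absorption", {
  dom0 <- cw_domain()
  m <- tiny_mesh()
  f <- homogeneous_field(m, mua = 0, mus = 0.5, g = 0.9)
  lay <- place_sources_detectors(dom0, m, 4L, 4L, 0.5)
  P <- 1e5
  mc <- mc_simulate(f, m, dom0, lay, 1L, P, seed = 1,
                    termination_threshold = 0, record_jacobian = FALSE)
  expect_equal(Re(mc$total_exit_weight), P, tolerance = 1e-13)
  expect_identical(Im(mc$total_exit_weight), 0)
  expect_identical(mc$n_exit + mc$n_terminated, P)
})

test_that("single-packet tally matches the exitance estimator", {
  dom <- ref_domain()
  m <- tiny_mesh()
  f <- homogeneous_field(m)
  lay <- place_sources_detectors(dom, m, 4L, 4L, 2)
  mc <- mc_simulate(f, m, dom, lay, 1L, 1, seed = 6,
                    record_jacobian = FALSE)
  hit <- which(Mod(mc$W) > 0)
  expect_lte(length(hit), 1L)
  if (length(hit) == 1L)
    expect_equal(mc$Y[hit], mc$W[hit] / (1 * lay$A[hit]))
})

test_that("simulations are bit-reproducible for a fixed seed", {
  dom <- ref_domain()
  m <- tiny_mesh()
  f <- homogeneous_field(m, mus = 0.4)
  lay <- place_sources_detectors(dom, m, 4L, 4L, 0.5)
  a <- mc_simulate(f, m, dom, lay, 2L, 5000, seed = 42)
  b <- mc_simulate(f, m, dom, lay, 2L, 5000, seed = 42)
  expect_identical(a$Y, b$Y)
  expect_identical(a$S_a, b$S_a)
  expect_identical(a$S_s, b$S_s)
  c_ <- mc_simulate(f, m, dom, lay, 2L, 5000, seed = 43)
  expect_false(identical(a$Y, c_$Y))
})

test_that("Monte Carlo error decays as one over the square root of P", {
  dom <- ref_domain()
  m <- tiny_mesh()
  f <- homogeneous_field(m, mus = 0.3)
  lay <- place_sources_detectors(dom, m, 4L, 4L, 1.5)
  Ps <- c(1e3, 1e4, 1e5)
  sds <- vapply(Ps, function(P) {
    ys <- vapply(1:12, function(s)
      Re(mc_simulate(f, m, dom, lay, 1L, P, seed = 1000 + s,
                     record_jacobian = FALSE)$Y[2]), numeric(1L))
    stats::sd(ys)
  }, numeric(1L))
  slope <- stats::coef(stats::lm(log(sds) ~ log(Ps)))[2]
  expect_lt(abs(slope + 0.5), 0.15)
})

test_that("estimator is consistent between many small and one large run", {
  dom <- ref_domain()
  m <- tiny_mesh()
  f <- homogeneous_field(m, mus = 0.3)
  lay <- place_sources_detectors(dom, m, 4L, 4L, 1.5)
  small <- vapply(1:20, function(s)
    Re(mc_simulate(f, m, dom, lay, 1L, 5e3, seed = 2000 + s,
                   record_jacobian = FALSE)$Y[3]), numeric(1L))
  big <- Re(mc_simulate(f, m, dom, lay, 1L, 2e5, seed = 77,
                        record_jacobian = FALSE)$Y[3])
  se_small <- stats::sd(small) / sqrt(length(small))
  se_big <- stats::sd(small) / sqrt(40)  # 2e5 = 40 x 5e3 packets
  expect_lt(abs(mean(small) - big), 3 * sqrt(se_small^2 + se_big^2))
})
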