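# Shared fixtures, built once per test run.  All geometry is generated in
# code; sizes are kept small so the full suite runs in minutes.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- build()
  fixture_env[[name]]
}

ref_domain <- function() fixture("domain", function() circular_domain())
cw_domain <- function() fixture("cw_domain", function()
  circular_domain(frequency = 0))

# coarse disk mesh (a few hundred elements)
coarse_mesh <- function() fixture("coarse", function()
  build_circular_mesh(ref_domain(), 0.6, seed = 11L))

# very coarse validation mesh (tens of elements)
tiny_mesh <- function() fixture("tiny", function()
  build_circular_mesh(ref_domain(), 1.6, seed = 5L))

# single-ring fan mesh (26 large elements) for Jacobian oracles
fan_mesh <- function() fixture("fan", function()
  build_circular_mesh(ref_domain(), 3.5, seed = 4L))

ref_layout <- function() fixture("layout", function()
  place_sources_detectors(ref_domain(), coarse_mesh()))

homogeneous_field <- function(mesh, mua = 0.01, mus = 0.1, g = 0.9) {
  K <- nrow(mesh$triangles)
  optical_field(rep(mua, K), rep(mus, K), g = g)
}

# deterministic linear surrogate forward model: y = A x + noise(seed)/sqrt(P),
# J = A.  noise_scale = 0 gives a noise-free model.
linear_surrogate <- function(A, noise_scale = 0) {
  force(A); force(noise_scale)
  function(x_scaled, P, seed) {
    y <- as.numeric(A %*% x_scaled)
    if (noise_scale > 0) {
      z <- local_noise(length(y), seed)
      y <- y + noise_scale * z / sqrt(P)
    }
    list(y = y, J = A)
  }
}

local_noise <- function(n, seed) {
  state <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(state)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", state, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2^31))
  stats::rnorm(n)
}

# small synthetic inverse problem driven by the linear surrogate
surrogate_problem <- function(K = 6L, M = 10L, noise_scale = 0,
                              seed = 99L) {
  set.seed(seed)
  centroids <- matrix(stats::runif(2 * K, -2, 2), ncol = 2)
  prior <- build_ou_prior(centroids, sigma_mua = 0.3, sigma_mus = 0.4,
                          tau = 0.5, mean_mua = 1, mean_mus = 1)
  A <- matrix(stats::rnorm(M * 2 * K), nrow = M) / sqrt(M)
  x_true <- as.numeric(prior_sample(prior, 1, seed = seed + 1))
  y <- as.numeric(A %*% x_true)
  sigma <- rep(0.05, M)
  meas <- structure(list(values = y + 0.05 * local_noise(M, seed + 2),
                         sigma = sigma, eta = 0,
                         n_sources = NA, n_detectors = NA),
                    class = "ot_measurement")
  prior$precision <- prior_precision(prior)
  prob <- list(meas = meas, prior_scaled = prior, prior = prior,
               transform = scaling_transform(1, 1), K = K, g = 0.9,
               forward = linear_surrogate(A, noise_scale))
  class(prob) <- "ot_problem"
  prob$A <- A
  prob$x_true <- x_true
  prob
}
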