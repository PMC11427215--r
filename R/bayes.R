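#' Measurement vector with its noise model
#'
#' The real data vector stacks all amplitudes then all phases of the
#' complex exitance, source-major and detector-minor, so a layout with S
#' sources and B detectors yields `M = 2 S B` components.
#'
#' @param values real data vector (amplitudes then phases).
#' @param sigma per-component noise standard deviations (same length), or
#'   `NULL` if not yet attached.
#' @param n_sources,n_detectors layout dimensions.
#' @param eta mean of the noise (default 0).
#' @return An `ot_measurement` object.
#' @export
measurement_vector <- function(values, sigma = NULL, n_sources, n_detectors,
                               eta = 0) {
  M <- length(values)
  if (M != 2L * n_sources * n_detectors)
    stop("data length does not match 2 * n_sources * n_detectors")
  if (!is.null(sigma)) {
    if (length(sigma) != M) stop("sigma length mismatch")
    if (any(sigma <= 0)) stop("sigma must be positive componentwise")
  }
  structure(list(values = as.numeric(values), sigma = sigma,
                 n_sources = as.integer(n_sources),
                 n_detectors = as.integer(n_detectors),
                 eta = eta), class = "ot_measurement")
}

#' Convert complex exitance to the amplitude/phase data vector
#'
#' @param Y complex matrix (sources x detectors).
#' @return numeric vector: all amplitudes, then all phases (source-major).
#' @export
exitance_to_data <- function(Y) {
  yv <- as.vector(t(Y))  # source-major, detector-minor
  c(Mod(yv), Arg(yv))
}

#' Relative noise model
#'
#' Standard deviation of each data component set to `level` times its
#' magnitude (the 1% relative noise model applied to both amplitude and
#' phase channels).
#'
#' @param values real data components.
#' @param level relative noise level (fraction, e.g. 0.01).
#' @return per-component standard deviations.
#' @export
make_noise_model <- function(values, level = 0.01) {
  if (level <= 0) stop("noise level must be positive")
  if (any(values == 0))
    stop("a data component is exactly zero; cannot form a relative noise model")
  level * abs(values)
}

#' Add measurement noise
#'
#' Independent zero-mean Gaussian noise with standard deviation
#' `level * |component|` added to every data component; `level = 0` returns
#' the input unchanged.  Deterministic per seed.  With
#' `phase_absolute = TRUE` the phase channels instead receive noise with an
#' absolute standard deviation `level` (radians), the alternative reading
#' of a relative-amplitude noise specification.
#'
#' @param meas an `ot_measurement` (noiseless).
#' @param level relative noise level.
#' @param seed integer seed.
#' @param phase_absolute use an absolute phase noise std instead.
#' @return a noisy `ot_measurement` carrying the noise model in `sigma`.
#' @export
add_noise <- function(meas, level = 0.01, seed = 1L, phase_absolute = FALSE) {
  if (level == 0) return(meas)
  M <- length(meas$values)
  sigma <- make_noise_model(meas$values, level)
  if (phase_absolute) {
    ph <- (M / 2 + 1):M
    sigma[ph] <- level
  }
  z <- local_rnorm(M, seed)
  measurement_vector(meas$values + sigma * z, sigma,
                     meas$n_sources, meas$n_detectors, eta = meas$eta)
}

local_rnorm <- function(n, seed) {
  state <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(state)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", state, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  stats::rnorm(n)
}

#' Ornstein-Uhlenbeck Gaussian prior
#'
#' Block-diagonal prior over the 2K coefficients: within each coefficient
#' block the covariance between elements i and j is
#' `sigma^2 exp(-||r_i - r_j|| / tau)` with r the element centroids; the
#' absorption and scattering blocks are independent.  The prior encodes the
#' expected smoothness of the coefficient fields; `tau` matches the radius
#' of the structures one expects to resolve.
#'
#' @param centroids element centroid coordinates (K x 2, mm).
#' @param sigma_mua,sigma_mus marginal standard deviations (mm^-1).
#' @param tau characteristic length (mm).
#' @param mean_mua,mean_mus prior means (mm^-1).
#' @return An `ot_prior` with the block covariances, their upper Cholesky
#'   factors `R` (Gamma = R'R), inverses, and the whitening operator
#'   `L = R^-T` satisfying `Gamma^-1 = L'L`.
#' @export
build_ou_prior <- function(centroids, sigma_mua, sigma_mus, tau,
                           mean_mua, mean_mus) {
  if (tau <= 0) stop("tau must be positive")
  if (sigma_mua <= 0 || sigma_mus <= 0) stop("sigma must be positive")
  D <- as.matrix(stats::dist(centroids))
  corr <- exp(-D / tau)
  K <- nrow(centroids)
  block <- function(sigma) {
    G <- sigma^2 * corr
    dimnames(G) <- NULL
    R <- tryCatch(chol(G), error = function(e)
      stop("prior covariance factorization failed: ", conditionMessage(e)))
    list(Gamma = G, R = R, Ginv = chol2inv(R))
  }
  ba <- block(sigma_mua)
  bs <- block(sigma_mus)
  structure(list(
    mean = c(rep(mean_mua, K), rep(mean_mus, K)),
    sigma_mua = sigma_mua, sigma_mus = sigma_mus, tau = tau, K = K,
    block_a = ba, block_s = bs), class = "ot_prior")
}

#' Apply the prior whitening operator
#'
#' Computes `L (v - eta)` per block, so that its squared norm is the prior
#' quadratic form `(v - eta)' Gamma^-1 (v - eta)`.
#'
#' @param prior an `ot_prior`.
#' @param v coefficient vector of length 2K.
#' @return whitened residual vector.
#' @export
prior_whiten <- function(prior, v) {
  K <- prior$K
  r <- v - prior$mean
  c(forwardsolve(t(prior$block_a$R), r[1:K]),
    forwardsolve(t(prior$block_s$R), r[(K + 1):(2 * K)]))
}

#' Draw samples from the prior
#'
#' @param prior an `ot_prior`.
#' @param n sample count.
#' @param seed integer seed.
#' @return matrix (2K x n) of coefficient draws.
#' @export
prior_sample <- function(prior, n, seed = 1L) {
  K <- prior$K
  z <- matrix(local_rnorm(2L * K * n, seed), nrow = 2L * K)
  xa <- t(prior$block_a$R) %*% z[1:K, , drop = FALSE]
  xs <- t(prior$block_s$R) %*% z[(K + 1):(2 * K), , drop = FALSE]
  rbind(xa, xs) + prior$mean
}

#' Block-diagonal prior precision matrix
#'
#' @param prior an `ot_prior`.
#' @return dense 2K x 2K matrix `Gamma^-1`.
#' @export
prior_precision <- function(prior) {
  K <- prior$K
  P <- matrix(0, 2 * K, 2 * K)
  P[1:K, 1:K] <- prior$block_a$Ginv
  P[(K + 1):(2 * K), (K + 1):(2 * K)] <- prior$block_s$Ginv
  P
}

#' Coefficient scaling transform
#'
#' The change of variables `mua -> mua / eta_mua`, `mus -> mus / eta_mus`
#' that puts both coefficient blocks on a common O(1) scale, required for a
#' meaningful joint norm test in the adaptive solver.
#'
#' @param eta_mua,eta_mus positive scaling means (mm^-1).
#' @return an `ot_scaling`.
#' @export
scaling_transform <- function(eta_mua, eta_mus) {
  if (eta_mua <= 0 || eta_mus <= 0) stop("scaling means must be positive")
  structure(list(eta_mua = eta_mua, eta_mus = eta_mus),
            class = "ot_scaling")
}

#' @rdname scaling_transform
#' @param x coefficient vector (2K, unscaled) or scaled vector for
#'   [unscale_coefficients()].
#' @param transform an `ot_scaling`.
#' @export
scale_coefficients <- function(x, transform) {
  K <- length(x) / 2L
  c(x[1:K] / transform$eta_mua, x[(K + 1):(2 * K)] / transform$eta_mus)
}

#' @rdname scaling_transform
#' @export
unscale_coefficients <- function(x, transform) {
  K <- length(x) / 2L
  c(x[1:K] * transform$eta_mua, x[(K + 1):(2 * K)] * transform$eta_mus)
}

#' @rdname scaling_transform
#' @param J Jacobian with columns over the 2K unscaled coefficients.
#' @export
scale_jacobian <- function(J, transform) {
  K <- ncol(J) / 2L
  J[, 1:K] <- J[, 1:K] * transform$eta_mua
  J[, (K + 1):(2 * K)] <- J[, (K + 1):(2 * K)] * transform$eta_mus
  J
}

#' Scale a prior to the transformed variables
#'
#' @param prior an `ot_prior` in physical units.
#' @param transform an `ot_scaling`.
#' @return an `ot_prior` over the scaled coefficients.
#' @export
scale_prior <- function(prior, transform) {
  K <- prior$K
  sc <- function(block, eta) {
    list(Gamma = block$Gamma / eta^2, R = block$R / eta,
         Ginv = block$Ginv * eta^2)
  }
  structure(list(
    mean = scale_coefficients(prior$mean, transform),
    sigma_mua = prior$sigma_mua / transform$eta_mua,
    sigma_mus = prior$sigma_mus / transform$eta_mus,
    tau = prior$tau, K = K,
    block_a = sc(prior$block_a, transform$eta_mua),
    block_s = sc(prior$block_s, transform$eta_mus)), class = "ot_prior")
}

#' The MAP objective
#'
#' `u(x) = 1/2 ||Le (y_meas - y_model - eta_e)||^2 + 1/2 ||Lx (x - eta_x)||^2`
#' with `Le = diag(1/sigma_e)` from the measurement noise model and `Lx`
#' the prior whitening operator.  The coefficient vector and prior must be
#' in the same (scaled or unscaled) variables; the value of `u` is
#' invariant under the linear change of variables when both are transformed
#' consistently.
#'
#' @param x coefficient vector (2K).
#' @param y_model model-predicted data vector.
#' @param meas an `ot_measurement` with its `sigma`.
#' @param prior an `ot_prior` matching the variables of `x`.
#' @return nonnegative scalar.
#' @export
objective <- function(x, y_model, meas, prior) {
  if (length(y_model) != length(meas$values))
    stop("model/data dimension mismatch")
  if (is.null(meas$sigma)) stop("measurement has no noise model")
  if (length(x) != 2L * prior$K) stop("coefficient/prior dimension mismatch")
  r <- (meas$values - y_model - meas$eta) / meas$sigma
  0.5 * sum(r^2) + 0.5 * sum(prior_whiten(prior, x)^2)
}
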