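#' Inverse-problem bundle
#'
#' Packages everything the (adaptive) stochastic Gauss-Newton iteration
#' needs: the reconstruction mesh and layout, the measured data with its
#' noise model, the Ornstein-Uhlenbeck prior, and the coefficient scaling.
#' The stochastic forward map (Monte Carlo exitance + Jacobian, in scaled
#' variables) is attached as a function `forward(x_scaled, P, seed)` and can
#' be overridden, e.g. with a deterministic surrogate in tests.
#'
#' @param domain an [circular_domain()].
#' @param mesh reconstruction `ot_mesh`.
#' @param layout `ot_layout` on `mesh`.
#' @param meas noisy `ot_measurement` with its `sigma`.
#' @param prior `ot_prior` in physical units on the mesh centroids.
#' @param transform `ot_scaling`; defaults to the prior means.
#' @param g anisotropy used in the forward model.
#' @param termination_threshold packet termination threshold.
#' @param forward optional replacement forward map returning
#'   `list(y = data vector, J = scaled Jacobian)`.
#' @param dead_channels what to do when a sampled exitance is exactly zero
#'   (no packets reached a detector, typical at small photon budgets for
#'   the near-source detectors under forward-peaked scattering):
#'   `"zero"` treats the channel as uninformative for that sample
#'   (amplitude 0, phase 0, zero Jacobian rows, counted in the iteration
#'   log), `"error"` aborts advising a larger packet count.
#' @return An `ot_problem`.
#' @export
ot_problem <- function(domain, mesh, layout, meas, prior, transform = NULL,
                       g = 0.9, termination_threshold = 1e-6,
                       forward = NULL, dead_channels = c("zero", "error")) {
  dead_channels <- match.arg(dead_channels)
  K <- nrow(mesh$triangles)
  if (prior$K != K) stop("prior and mesh element counts differ")
  if (is.null(transform)) {
    mm <- prior$mean
    transform <- scaling_transform(mm[1L], mm[K + 1L])
  }
  prior_scaled <- scale_prior(prior, transform)
  prior_scaled$precision <- prior_precision(prior_scaled)
  prob <- list(domain = domain, mesh = mesh, layout = layout, meas = meas,
               prior = prior, prior_scaled = prior_scaled,
               transform = transform, g = g, K = K,
               termination_threshold = termination_threshold,
               dead_channels = dead_channels)
  if (is.null(forward)) {
    prob$forward <- function(x_scaled, P, seed) {
      mc_forward(prob, x_scaled, P, seed)
    }
  } else {
    prob$forward <- forward
  }
  class(prob) <- "ot_problem"
  prob
}

# Monte Carlo forward map in scaled variables: exitance data vector plus
# the scaled stochastic Jacobian at the same evaluation (same packets).
# Channels that no packet reached carry no information in this sample;
# depending on the problem setting they are zeroed out or raise an error.
mc_forward <- function(prob, x_scaled, P, seed) {
  x <- unscale_coefficients(x_scaled, prob$transform)
  K <- prob$K
  field <- optical_field(pmax(x[1:K], 0), pmax(x[(K + 1):(2 * K)], 0),
                         g = prob$g)
  fw <- forward_exitance(field, prob$mesh, prob$domain, prob$layout, P,
                         seed = seed, record_jacobian = TRUE,
                         termination_threshold = prob$termination_threshold)
  Y <- unlist(lapply(fw$runs, `[[`, "Y"))
  dead <- which(Mod(Y) == 0)
  if (length(dead) && identical(prob$dead_channels, "error"))
    stop(sprintf(
      "zero sampled exitance on %d channel(s) at P = %g; increase the packet count",
      length(dead), P))
  runs <- fw$runs
  if (length(dead)) {
    # substitute a unit exitance for the chain rule, then null the rows
    B <- prob$layout$n_detectors
    for (ch in dead) {
      s <- (ch - 1L) %/% B + 1L
      b <- (ch - 1L) %% B + 1L
      runs[[s]]$Y[b] <- complex(real = 1)
    }
  }
  sj <- stochastic_jacobian(runs, field)
  y <- c(Mod(Y), Arg(Y))
  J <- sj$J
  if (length(dead)) {
    M2 <- length(Y)
    J[c(dead, M2 + dead), ] <- 0
  }
  list(y = y, J = scale_jacobian(J, prob$transform), Y = Y,
       n_dead = length(dead))
}

#' Gauss-Newton minimization direction
#'
#' Solves the regularized normal equations
#' `(J' Ge^-1 J + Gx^-1) delta = J' Ge^-1 r - Gx^-1 (x - eta_x)` with a
#' direct dense solve, where `Ge = diag(sigma^2)` is the noise covariance
#' and `Gx` the prior covariance in the same variables as `x`.  The
#' relative residual of the linear solve is verified to be at most 1e-8
#' (one step of iterative refinement is applied if needed).
#'
#' @param J Jacobian (M x 2K), same variables as `x`.
#' @param residual data residual `y_meas - y_model - eta_e` (length M).
#' @param x current iterate (length 2K).
#' @param prior `ot_prior` in the variables of `x`.
#' @param sigma noise standard deviations (length M).
#' @return the direction `delta` (length 2K).
#' @export
gn_direction <- function(J, residual, x, prior, sigma) {
  Ginv <- prior$precision
  if (is.null(Ginv)) Ginv <- prior_precision(prior)
  Jw <- J / sigma
  H <- crossprod(Jw) + Ginv
  rhs <- crossprod(J, residual / sigma^2) - Ginv %*% (x - prior$mean)
  delta <- tryCatch(solve(H, rhs), error = function(e)
    stop("Gauss-Newton system is singular: ", conditionMessage(e)))
  nr <- sqrt(sum(rhs^2))
  if (nr > 0) {
    rel <- sqrt(sum((H %*% delta - rhs)^2)) / nr
    if (rel > 1e-8) {
      delta <- delta + solve(H, rhs - H %*% delta)
      rel <- sqrt(sum((H %*% delta - rhs)^2)) / nr
      if (rel > 1e-6)
        stop(sprintf("linear solve residual %.2e exceeds tolerance", rel))
    }
  }
  as.numeric(delta)
}

# derived, collision-free within a run; kept below 2^53 for exact doubles
iteration_seed <- function(root, iteration, sample) {
  as.numeric(root) + 1000003 * iteration + 7919 * sample
}

apply_update <- function(x, delta, step_length, transform, positivity_floor) {
  x <- x + step_length * delta
  if (!is.null(positivity_floor) && positivity_floor >= 0) {
    xu <- unscale_coefficients(x, transform)
    x <- scale_coefficients(pmax(xu, positivity_floor), transform)
  }
  x
}

#' Stochastic Gauss-Newton reconstruction at a fixed packet count
#'
#' Iterates `x_{i+1} = x_i + alpha delta_P(x_i)` in scaled variables from
#' the scaled prior mean, with the direction solved from the stochastic
#' forward model and Jacobian evaluated with `P` packets per source (fresh
#' packet seeds each iteration).  The objective `u(x_i)` is logged at every
#' iterate using the same Monte Carlo run as the direction.
#'
#' @param problem an `ot_problem`.
#' @param P photon packets per source (fixed).
#' @param iterations Gauss-Newton iterations.
#' @param seed root seed; runs are bit-reproducible given the seed.
#' @param step_length step parameter alpha (constant).
#' @param positivity_floor unscaled lower bound applied after each update
#'   (the Monte Carlo model requires non-negative coefficients); `NULL`
#'   disables it.
#' @param final_objective evaluate `u` at the returned iterate with one
#'   extra forward run.
#' @return An `sgn_result`: final scaled iterate `x`, the unscaled
#'   `ot_field` estimate, the per-iteration `history` data frame, and
#'   `u_final`.
#' @export
run_sgn <- function(problem, P, iterations = 10L, seed = 1L,
                    step_length = 1, positivity_floor = 1e-6,
                    final_objective = TRUE) {
  x <- problem$prior_scaled$mean
  hist <- vector("list", iterations)
  cum <- 0
  for (i in seq_len(iterations)) {
    fw <- problem$forward(x, P, iteration_seed(seed, i, 1L))
    u_i <- objective(x, fw$y, problem$meas, problem$prior_scaled)
    residual <- problem$meas$values - fw$y - problem$meas$eta
    delta <- gn_direction(fw$J, residual, x, problem$prior_scaled,
                          problem$meas$sigma)
    x <- apply_update(x, delta, step_length, problem$transform,
                      positivity_floor)
    cum <- cum + P
    hist[[i]] <- data.frame(iteration = i, u = u_i, P = P,
                            cum_packets = cum,
                            delta_norm = sqrt(sum(delta^2)))
  }
  history <- if (iterations > 0) do.call(rbind, hist) else
    data.frame(iteration = integer(), u = numeric(), P = numeric(),
               cum_packets = numeric(), delta_norm = numeric())
  u_final <- NA_real_
  if (final_objective && iterations > 0) {
    fw <- problem$forward(x, P, iteration_seed(seed, iterations + 1L, 1L))
    u_final <- objective(x, fw$y, problem$meas, problem$prior_scaled)
  }
  xu <- unscale_coefficients(x, problem$transform)
  K <- problem$K
  structure(list(
    x = x,
    field = optical_field(pmax(xu[1:K], 0), pmax(xu[(K + 1):(2 * K)], 0),
                          g = problem$g),
    history = history,
    u_final = u_final,
    method = "sgn",
    P = P, iterations = iterations, seed = seed,
    cum_packets = cum), class = "sgn_result")
}

#' @export
print.sgn_result <- function(x, ...) {
  cat(sprintf("%s reconstruction: %d iterations, final u = %.4g\n",
              toupper(x$method), x$iterations,
              if (is.na(x$u_final)) utils::tail(x$history$u, 1L) else x$u_final))
  cat(sprintf("  cumulative packets per source: %.3g\n", x$cum_packets))
  invisible(x)
}
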