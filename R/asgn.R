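#' Ensemble of stochastic Gauss-Newton directions
#'
#' Draws `L` independent stochastic forward/Jacobian samples at the current
#' iterate with `P` packets per source, solves one minimization direction
#' per sample, and a reference direction from the sample-averaged forward
#' solution and Jacobian (the ensemble surrogate for the exact direction).
#' Note the reference direction is computed from the averaged `(Y, J)`,
#' which is not the average of the per-sample directions.
#'
#' @param problem an `ot_problem`.
#' @param x current scaled iterate.
#' @param P packets per source and sample.
#' @param L sample count (>= 2).
#' @param seeds integer seeds, one per sample.
#' @return A list: `delta` (list of per-sample directions), `delta_bar`,
#'   the averaged data vector `y_bar` and Jacobian `J_bar`.
#' @export
direction_ensemble <- function(problem, x, P, L, seeds) {
  if (L < 2L) stop("ensemble needs L >= 2 samples")
  if (length(seeds) != L) stop("need one seed per sample")
  meas <- problem$meas
  prior <- problem$prior_scaled
  deltas <- vector("list", L)
  y_bar <- NULL
  J_bar <- NULL
  y1 <- NULL; J1 <- NULL
  all_same <- TRUE
  for (l in seq_len(L)) {
    fw <- problem$forward(x, P, seeds[l])
    deltas[[l]] <- gn_direction(fw$J, meas$values - fw$y - meas$eta, x,
                                prior, meas$sigma)
    if (l == 1L) { y1 <- fw$y; J1 <- fw$J }
    else if (all_same &&
             !(identical(fw$y, y1) && identical(fw$J, J1))) all_same <- FALSE
    y_bar <- if (is.null(y_bar)) fw$y / L else y_bar + fw$y / L
    J_bar <- if (is.null(J_bar)) fw$J / L else J_bar + fw$J / L
  }
  if (all_same) {
    # identical samples average to themselves exactly (no roundoff drift,
    # so the deterministic limit yields a zero norm-test statistic)
    y_bar <- y1
    J_bar <- J1
    delta_bar <- deltas[[1L]]
  } else {
    delta_bar <- gn_direction(J_bar, meas$values - y_bar - meas$eta, x,
                              prior, meas$sigma)
  }
  list(delta = deltas, delta_bar = delta_bar, y_bar = y_bar, J_bar = J_bar)
}

#' Norm test for the stochastic direction
#'
#' Estimates the expected squared relative error of the stochastic
#' minimization direction,
#' `V^2 = E ||delta_bar - delta^(l)||^2 / ||delta_bar||^2` (sample mean
#' over the ensemble), and passes when `V^2 <= gamma^2`.
#'
#' @param delta_bar reference direction.
#' @param deltas list of per-sample directions.
#' @param gamma threshold (> 0).
#' @return list with `V2` and logical `pass`.
#' @export
norm_test <- function(delta_bar, deltas, gamma) {
  if (gamma <= 0) stop("gamma must be positive")
  nb2 <- sum(delta_bar^2)
  if (nb2 == 0) stop("reference direction is zero; norm test undefined")
  V2 <- mean(vapply(deltas, function(d) sum((delta_bar - d)^2), numeric(1L))) / nb2
  list(V2 = V2, pass = V2 <= gamma^2)
}

#' Photon-packet budget update
#'
#' When the norm test fails, the packet count is increased proportionally
#' to the measured excess variance, `P <- ceil((V^2 / gamma^2) P)`, capped
#' at `cap`; when it passes, the count is kept.
#'
#' @param P current packets per source.
#' @param V2 norm-test statistic.
#' @param gamma threshold.
#' @param cap hard upper bound on the packet count.
#' @return updated packet count.
#' @export
update_packet_count <- function(P, V2, gamma, cap = Inf) {
  if (V2 <= gamma^2) return(P)
  min(cap, ceiling((V2 / gamma^2) * P))
}

#' Adaptive stochastic Gauss-Newton reconstruction
#'
#' Runs the Gauss-Newton iteration with an adaptively controlled photon
#' budget: on every iteration an `L`-sample direction ensemble is computed
#' at the current budget `P_i`, the iterate is updated with the
#' ensemble-averaged direction (constant step length), and the norm test
#' decides whether the next iteration may keep `P_i` or must increase it.
#' The budget therefore stays low while the functional is large and grows
#' as the iterates approach the minimum.  An increased budget takes effect
#' at the next iteration.
#'
#' Cumulative packet usage is logged in both accountings: `cum_packets`
#' counts every launched packet (`L * P_i` per iteration per source) and
#' `cum_packets_single` counts `P_i` only.
#'
#' @param problem an `ot_problem`.
#' @param L ensemble sample count.
#' @param gamma norm-test threshold.
#' @param P_init initial packets per source.
#' @param P_cap packet-count cap (warning when reached, iteration
#'   continues at the cap).
#' @param iterations Gauss-Newton iterations.
#' @param seed root seed.
#' @param step_length constant step parameter.
#' @param positivity_floor see [run_sgn()].
#' @param final_objective evaluate `u` at the returned iterate.
#' @return An `sgn_result` whose `history` additionally carries `V2`,
#'   `pass` and `P_next`.
#' @export
run_asgn <- function(problem, L = 10L, gamma = 1, P_init = 1000,
                     P_cap = 1e9, iterations = 10L, seed = 1L,
                     step_length = 1, positivity_floor = 1e-6,
                     final_objective = TRUE) {
  if (L < 2L) stop("L must be >= 2")
  if (P_init < 1) stop("P_init must be >= 1")
  x <- problem$prior_scaled$mean
  P <- P_init
  cumL <- 0; cum1 <- 0
  capped <- FALSE
  hist <- vector("list", iterations)
  for (i in seq_len(iterations)) {
    seeds <- iteration_seed(seed, i, seq_len(L))
    ens <- direction_ensemble(problem, x, P, L, seeds)
    u_i <- objective(x, ens$y_bar, problem$meas, problem$prior_scaled)
    nt <- norm_test(ens$delta_bar, ens$delta, gamma)
    x <- apply_update(x, ens$delta_bar, step_length, problem$transform,
                      positivity_floor)
    P_next <- update_packet_count(P, nt$V2, gamma, cap = P_cap)
    if (!nt$pass && P_next == P_cap && !capped) {
      warning("packet-count cap reached; continuing at the cap")
      capped <- TRUE
    }
    cumL <- cumL + L * P
    cum1 <- cum1 + P
    hist[[i]] <- data.frame(iteration = i, u = u_i, P = P, V2 = nt$V2,
                            pass = nt$pass, P_next = P_next,
                            cum_packets = cumL, cum_packets_single = cum1,
                            delta_norm = sqrt(sum(ens$delta_bar^2)))
    P <- P_next
  }
  history <- if (iterations > 0) do.call(rbind, hist) else
    data.frame(iteration = integer(), u = numeric(), P = numeric(),
               V2 = numeric(), pass = logical(), P_next = numeric(),
               cum_packets = numeric(), cum_packets_single = numeric(),
               delta_norm = numeric())
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
    method = "asgn",
    L = L, gamma = gamma, P_init = P_init, P_cap = P_cap,
    iterations = iterations, seed = seed,
    P_final = P,
    cum_packets = cumL,
    cum_packets_single = cum1), class = "sgn_result")
}
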