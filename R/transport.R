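#' Sample the 2D Henyey-Greenstein scattering angle
#'
#' Exact inverse-CDF sampling of the two-dimensional Henyey-Greenstein
#' density `(1/2pi) (1-g^2) / (1 + g^2 - 2 g cos(theta))` on `(-pi, pi]`.
#' The mean cosine of the sampled angle equals `g`.
#'
#' @param g anisotropy, -1 < g < 1.
#' @param u uniform(0, 1) deviates.
#' @return angles in radians, same length as `u`.
#' @export
sample_hg_angle <- function(g, u) {
  if (abs(g) >= 1) stop("anisotropy must satisfy -1 < g < 1")
  if (any(u < 0 | u >= 1)) stop("u must lie in [0, 1)")
  if (g == 0) return(2 * pi * (u - 0.5))
  2 * atan(((1 - g) / (1 + g)) * tan(pi * (u - 0.5)))
}

#' 2D Henyey-Greenstein density
#'
#' @param theta angle in radians.
#' @param g anisotropy.
#' @return density values; integrates to 1 over `(-pi, pi]`.
#' @export
hg_density <- function(theta, g) {
  (1 - g^2) / (2 * pi * (1 + g^2 - 2 * g * cos(theta)))
}

#' Sample a scattering site along a ray
#'
#' Draws the optical depth `t = -log(1 - u)` and marches the ray across the
#' piecewise-constant elements, accumulating `mus * dl`, until either the
#' depth is spent (a scattering site) or the boundary is reached (an exit).
#' This is exact sampling of the free-path density
#' `f(l) = mus(l) exp(-int_0^l mus)` in piecewise-constant media.
#'
#' @param field an `ot_field`.
#' @param mesh an `ot_mesh`.
#' @param position length-2 start point (inside the domain).
#' @param direction length-2 direction (normalized internally).
#' @param u uniform(0,1) deviate; alternatively pass `depth` directly.
#' @param depth optional optical depth overriding `u`.
#' @return A list: `scattered`, `exited`, `site`, `elements`, `lengths`,
#'   `s_tot`.
#' @export
sample_scattering_site <- function(field, mesh, position, direction, u = NULL,
                                   depth = NULL) {
  if (is.null(depth)) {
    if (is.null(u)) stop("provide u or depth")
    depth <- -log(1 - u)
  }
  loc <- locate_points(mesh, matrix(position, ncol = 2L))
  if (!loc$inside[1L]) stop("start position is outside the domain")
  cpp_trace_to_depth(mesh$nodes, mesh$triangles - 1L, mesh$adjacency - 1L,
                     2 * mesh$radius, field$mus, loc$element[1L] - 1L,
                     as.numeric(position), as.numeric(direction),
                     depth, 1e6)
}

#' Propagate a single photon packet
#'
#' Follows one packet from an interior starting point until it exits the
#' domain or its weight modulus falls below the termination threshold.  The
#' complex weight is `w0 * exp(-sum_h mua_h l_h) * exp(-i omega s_tot / c)`,
#' with the per-element path lengths `l_h` and scattering counts recorded.
#'
#' @param field,mesh,domain model components.
#' @param position,direction packet start (direction normalized internally).
#' @param seed integer RNG substream seed.
#' @param w0 initial weight.
#' @param termination_threshold relative weight below which the packet is
#'   dismissed; `0` disables termination (for conservation checks).
#' @return A list describing the packet path: visited `elements`, their
#'   `lengths` and `n_scatter` counts, `s_tot`, the final complex weight
#'   `w`, and exit information.
#' @export
propagate_packet <- function(field, mesh, domain, position, direction,
                             seed = 1L, w0 = 1,
                             termination_threshold = 1e-6) {
  loc <- locate_points(mesh, matrix(position, ncol = 2L))
  if (!loc$inside[1L]) stop("start position is outside the domain")
  res <- cpp_propagate_one(mesh$nodes, mesh$triangles - 1L,
                           mesh$adjacency - 1L, 2 * mesh$radius,
                           field$mua, field$mus, field$g,
                           domain$omega_over_c, w0, termination_threshold,
                           loc$element[1L] - 1L, as.numeric(position),
                           as.numeric(direction), as.numeric(seed), 1e6)
  if (res$lost)
    stop("packet failed to advance (geometric degeneracy)")
  if (!is.finite(res$s_tot) || !is.finite(Mod(res$w)))
    stop("non-finite packet weight")
  res
}

#' Monte Carlo boundary exitance for one source
#'
#' Launches `P` photon packets from the given source arc (position uniform
#' along the arc, emission angle cosine-distributed about the inward
#' normal) and tallies the complex exitance `Y_b = W_b / (P A_b)` on every
#' detector arc, together with the per-(detector, element) accumulators
#' needed by the absorption and scattering Jacobians.  Runs are
#' deterministic given `(seed, P)`; distinct sources use independent RNG
#' substreams.
#'
#' @param field,mesh,domain,layout model components.
#' @param source_index which source arc to fire (1-based).
#' @param P number of photon packets.
#' @param seed root RNG seed.
#' @param record_jacobian tally the Jacobian accumulators (`S_a`, `S_s`).
#' @param w0 initial packet weight.
#' @param termination_threshold relative weight cutoff (0 disables).
#' @param perturb optional `list(element =, mus =)`: additionally tally the
#'   perturbation-Monte-Carlo reweighted exitance `Y_pert` that the same
#'   photon paths predict for a modified scattering coefficient in one
#'   element (no re-simulation).
#' @return An `mc_result`: complex `Y` (per detector), its per-quadrature
#'   standard errors `Y_se_re`/`Y_se_im`, raw weight sums `W`, accumulators
#'   `S_a` and `S_s` (detectors x elements), the total boundary-exit weight
#'   over all edges, and the packet bookkeeping.
#' @export
mc_simulate <- function(field, mesh, domain, layout, source_index, P,
                        seed = 1L, record_jacobian = TRUE, w0 = 1,
                        termination_threshold = 1e-6, perturb = NULL) {
  if (P < 1) stop("P must be >= 1")
  src <- layout$sources[[source_index]]
  pert_element <- if (is.null(perturb)) -1L else as.integer(perturb$element) - 1L
  pert_mus <- if (is.null(perturb)) 0 else perturb$mus
  res <- cpp_simulate(mesh$nodes, mesh$triangles - 1L, mesh$adjacency - 1L,
                      2 * mesh$radius, field$mua, field$mus, field$g,
                      domain$omega_over_c, w0, termination_threshold,
                      src$segments,
                      layout$detector_centers,
                      vapply(layout$detectors, `[[`, numeric(1L), "half"),
                      as.numeric(P), as.numeric(seed),
                      as.integer(source_index), record_jacobian, 1e6,
                      pert_element, pert_mus)
  if (res$n_lost > 0)
    stop(sprintf("%d packets failed to advance (geometric degeneracy)",
                 res$n_lost))
  # standard error of the exitance estimator per quadrature component
  var_re <- pmax(res$W2_re - Re(res$W)^2 / P, 0) / max(P - 1, 1)
  var_im <- pmax(res$W2_im - Im(res$W)^2 / P, 0) / max(P - 1, 1)
  out <- list(
    Y = res$W / (P * layout$A),
    Y_se_re = sqrt(var_re / P) / layout$A,
    Y_se_im = sqrt(var_im / P) / layout$A,
    Y_pert = if (!is.null(res$W_pert)) res$W_pert / (P * layout$A),
    W = res$W,
    S_a = res$S_a,
    S_s = res$S_s,
    total_exit_weight = res$total_exit_weight,
    n_exit = res$n_exit,
    n_terminated = res$n_terminated,
    P = P,
    A = layout$A,
    source_index = source_index,
    seed = seed)
  class(out) <- "mc_result"
  out
}

#' Forward exitance for all sources
#'
#' Runs [mc_simulate()] for every source arc and collects the complex
#' exitance into a sources x detectors matrix.
#'
#' @inheritParams mc_simulate
#' @param P packets per source.
#' @param record_jacobian keep the per-source accumulators.
#' @return A list with the complex matrix `Y` (sources x detectors) and,
#'   when requested, the per-source `mc_result` list `runs`.
#' @export
forward_exitance <- function(field, mesh, domain, layout, P, seed = 1L,
                             record_jacobian = TRUE,
                             termination_threshold = 1e-6) {
  S <- layout$n_sources
  B <- layout$n_detectors
  Y <- matrix(complex(real = 0, imaginary = 0), nrow = S, ncol = B)
  se_re <- matrix(0, nrow = S, ncol = B)
  se_im <- matrix(0, nrow = S, ncol = B)
  runs <- if (record_jacobian) vector("list", S) else NULL
  for (s in seq_len(S)) {
    mc <- mc_simulate(field, mesh, domain, layout, s, P, seed,
                      record_jacobian = record_jacobian,
                      termination_threshold = termination_threshold)
    Y[s, ] <- mc$Y
    se_re[s, ] <- mc$Y_se_re
    se_im[s, ] <- mc$Y_se_im
    if (record_jacobian) runs[[s]] <- mc
  }
  list(Y = Y, se_re = se_re, se_im = se_im, runs = runs)
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf(
    "MC run: source %d, P = %g packets (%g exited, %g terminated)\n",
    x$source_index, x$P, x$n_exit, x$n_terminated))
  cat(sprintf("  |Y| in [%.3g, %.3g]\n", min(Mod(x$Y)), max(Mod(x$Y))))
  invisible(x)
}
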