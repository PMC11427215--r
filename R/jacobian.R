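#' Exitance derivatives with respect to absorption
#'
#' Direct differentiation of the packet-weight estimator: the derivative of
#' the complex exitance on detector `b` with respect to the absorption
#' coefficient of element `k` is `-1/(P A_b) * sum_phot l_k w_phot`, read
#' off from the path-length accumulator of the unperturbed simulation.
#'
#' @param mc an `mc_result` with Jacobian accumulators.
#' @return complex matrix (detectors x elements).
#' @export
complex_dY_dmua <- function(mc) {
  if (is.null(mc$S_a))
    stop("mc_result has no Jacobian accumulators; rerun with record_jacobian = TRUE")
  -mc$S_a / (mc$P * mc$A)
}

#' Perturbation Monte Carlo reweighting
#'
#' Predicts the weight a stored photon path would have under a perturbed
#' scattering coefficient without re-simulation:
#' `w * (mus_perturbed / mus)^n_s * exp(-(mus_perturbed - mus) * L_tot)`,
#' where `n_s` counts the scattering events inside the perturbed region and
#' `L_tot` is the path length travelled there.
#'
#' @param w unperturbed (complex) weight.
#' @param mus,mus_perturbed scattering coefficient before/after (mm^-1).
#' @param n_s scattering events in the perturbed region.
#' @param L_tot path length in the perturbed region (mm).
#' @return perturbed weight(s).
#' @export
perturbed_weight <- function(w, mus, mus_perturbed, n_s, L_tot) {
  if (any(mus_perturbed < 0)) stop("mus_perturbed must be >= 0")
  if (any(mus <= 0 & n_s > 0))
    stop("a path with scattering events cannot arise where mus = 0")
  ratio <- ifelse(n_s > 0, (mus_perturbed / mus)^n_s, 1)
  w * ratio * exp(-(mus_perturbed - mus) * L_tot)
}

#' Exitance derivatives with respect to scattering
#'
#' Perturbation Monte Carlo derivative: differentiating the reweighting
#' factor of [perturbed_weight()] at the unperturbed coefficient gives the
#' per-path integrand `(n_s / mus_k - l_k) w`, accumulated during the
#' simulation, so the entry `(b, k)` is `S_s[b, k] / (P A_b)`.  Elements
#' with `mus_k = 0` (where no scattering can occur) contribute only their
#' `-l_k` path term.
#'
#' @param mc an `mc_result` with Jacobian accumulators.
#' @param field the `ot_field` the simulation was run with.
#' @return complex matrix (detectors x elements).
#' @export
complex_dY_dmus <- function(mc, field) {
  if (is.null(mc$S_s))
    stop("mc_result has no Jacobian accumulators; rerun with record_jacobian = TRUE")
  mc$S_s / (mc$P * mc$A)
}

#' Assemble the real Jacobian for amplitude and phase data
#'
#' Maps complex exitance derivatives to derivatives of the measured data
#' types by the chain rule: for a channel with complex exitance `Y`,
#' `dA = Re(conj(Y) dY) / |Y|` and `dphi = Im(dY / Y)`.  Rows are ordered
#' as all amplitudes then all phases (source-major); columns as all
#' absorption then all scattering parameters.
#'
#' @param dY_dmua,dY_dmus complex derivative matrices (channels x elements),
#'   channels stacked source-major over all source-detector pairs.
#' @param Y complex exitance vector for the same channels.
#' @return dense real matrix (2 channels x 2 elements dimensions).
#' @export
assemble_jacobian <- function(dY_dmua, dY_dmus, Y) {
  if (length(Y) != nrow(dY_dmua) || length(Y) != nrow(dY_dmus))
    stop("channel count mismatch between Y and the derivative matrices")
  dead <- which(Mod(Y) == 0)
  if (length(dead))
    stop(sprintf(
      "zero sampled exitance on channel(s) %s; increase the packet count",
      paste(utils::head(dead, 5L), collapse = ", ")))
  amp_rows <- function(dY) Re(Conj(Y) * dY) / Mod(Y)
  phs_rows <- function(dY) Im(dY / Y)
  J <- rbind(cbind(amp_rows(dY_dmua), amp_rows(dY_dmus)),
             cbind(phs_rows(dY_dmua), phs_rows(dY_dmus)))
  if (any(!is.finite(J))) stop("non-finite Jacobian entries")
  J
}

#' Stochastic Jacobian of the forward model
#'
#' Runs (or reuses) the per-source Monte Carlo simulations and assembles
#' the full real Jacobian with rows over all source-detector amplitude and
#' phase channels and columns over the 2K coefficients.
#'
#' @param runs list of per-source `mc_result`s (one per source, in order).
#' @param field evaluation-point field.
#' @return list with the real matrix `J` and the complex channel vector `Y`
#'   (source-major).
#' @export
stochastic_jacobian <- function(runs, field) {
  dYa <- do.call(rbind, lapply(runs, complex_dY_dmua))
  dYs <- do.call(rbind, lapply(runs, function(r) complex_dY_dmus(r, field)))
  Y <- unlist(lapply(runs, `[[`, "Y"))
  list(J = assemble_jacobian(dYa, dYs, Y), Y = Y)
}
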