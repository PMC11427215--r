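#' Simulate a measurement dataset
#'
#' Builds the data-simulation mesh and phantom, runs the Monte Carlo
#' forward model for every source, assembles all source-detector pairs
#' into the amplitude/phase data vector, and adds relative Gaussian noise.
#' The data mesh is intentionally distinct from any reconstruction mesh
#' (different edge length and ring phases) to avoid an inverse crime.
#'
#' @param phantom phantom name, see [make_phantom()].
#' @param domain an [circular_domain()].
#' @param edge_length data-mesh target edge length (mm).
#' @param packets photon packets per source.
#' @param noise_level relative noise level (fraction).
#' @param seed root seed (mesh phases, packets and noise draw from it).
#' @param n_sources,n_detectors,width boundary layout.
#' @param g anisotropy.
#' @param mc_error_model include the Monte Carlo standard error of the
#'   simulated data in the attached noise model, `sigma^2 =
#'   (level |y|)^2 + SE_MC^2`.  At the full-scale budget (1e10 packets) the
#'   sampling error is negligible against the added noise, but at reduced
#'   budgets it is comparable, and a noise model that omits it makes every
#'   solver overfit the data's own sampling noise.
#' @return A list: `mesh`, `field` (truth), `layout`, complex `Y`
#'   (sources x detectors), `noiseless` and `noisy` measurement vectors
#'   (the noisy one carries the noise model in `sigma`).
#' @export
simulate_dataset <- function(phantom = "circles", domain = circular_domain(),
                             edge_length = 0.29, packets = 1e6,
                             noise_level = 0.01, seed = 1L,
                             n_sources = 16L, n_detectors = 16L,
                             width = 0.5, g = 0.9, mc_error_model = TRUE) {
  mesh <- build_circular_mesh(domain, edge_length, seed = seed + 101L)
  field <- make_phantom(phantom, mesh, g = g)
  layout <- place_sources_detectors(domain, mesh, n_sources, n_detectors,
                                    width)
  fw <- forward_exitance(field, mesh, domain, layout, packets, seed = seed,
                         record_jacobian = FALSE)
  if (any(Mod(fw$Y) == 0))
    stop("dead measurement channel(s) in the simulated data; increase packets")
  noiseless <- measurement_vector(exitance_to_data(fw$Y),
                                  n_sources = n_sources,
                                  n_detectors = n_detectors)
  noisy <- if (noise_level > 0) {
    add_noise(noiseless, noise_level, seed = seed + 31L)
  } else noiseless
  if (mc_error_model && !is.null(noisy$sigma)) {
    se <- exitance_se_data(fw$Y, fw$se_re, fw$se_im)
    noisy$sigma <- sqrt(noisy$sigma^2 + se^2)
  }
  list(phantom = phantom, domain = domain, mesh = mesh, field = field,
       layout = layout, Y = fw$Y, noiseless = noiseless, noisy = noisy,
       packets = packets, noise_level = noise_level, seed = seed)
}

# delta-method standard errors of the amplitude/phase data components
# from the per-quadrature exitance standard errors
exitance_se_data <- function(Y, se_re, se_im) {
  yv <- as.vector(t(Y))
  sr <- as.vector(t(se_re))
  si <- as.vector(t(se_im))
  a <- Mod(yv)
  cr <- Re(yv) / a
  ci <- Im(yv) / a
  se_amp <- sqrt((cr * sr)^2 + (ci * si)^2)
  se_phs <- sqrt((Im(yv) * sr)^2 + (Re(yv) * si)^2) / a^2
  c(se_amp, se_phs)
}

#' Project a fine-mesh field onto a reconstruction mesh
#'
#' Each reconstruction element takes the fine-mesh value at its centroid
#' (a piecewise-constant restriction that introduces no new values).
#' Centroids falling outside the fine triangulation -- possible near the
#' polygonal boundary -- use the nearest fine element and are reported.
#'
#' @param field `ot_field` on `fine_mesh`.
#' @param fine_mesh,recon_mesh meshes over the same domain.
#' @return `ot_field` on `recon_mesh`.
#' @export
project_truth <- function(field, fine_mesh, recon_mesh) {
  loc <- locate_points(fine_mesh, recon_mesh$centroids)
  n_out <- sum(!loc$inside)
  if (n_out > 0)
    message(sprintf(
      "project_truth: %d centroid(s) outside the fine mesh; nearest element used",
      n_out))
  optical_field(field$mua[loc$element], field$mus[loc$element], g = field$g)
}

#' Relative reconstruction errors
#'
#' Euclidean-norm relative errors in percent, separately per coefficient:
#' `E = ||estimate - truth|| / ||truth|| * 100`.
#'
#' @param estimate,truth `ot_field`s on the same mesh.
#' @return named vector `c(E_mua = , E_mus = )` in percent.
#' @export
relative_error <- function(estimate, truth) {
  if (length(estimate$mua) != length(truth$mua))
    stop("fields live on different meshes")
  na <- sqrt(sum(truth$mua^2)); ns <- sqrt(sum(truth$mus^2))
  if (na == 0 || ns == 0) stop("zero-norm truth field")
  c(E_mua = sqrt(sum((estimate$mua - truth$mua)^2)) / na * 100,
    E_mus = sqrt(sum((estimate$mus - truth$mus)^2)) / ns * 100)
}

#' Build the reconstruction problem for a simulated dataset
#'
#' Creates the (coarser) reconstruction mesh and layout, the
#' Ornstein-Uhlenbeck prior with the phantom's Table of prior settings
#' (mean = background, std = a third of the inclusion contrast,
#' tau = 0.5 mm), and bundles them with the noisy data.
#'
#' @param dataset output of [simulate_dataset()].
#' @param recon_edge_length reconstruction-mesh edge length (mm); must
#'   differ from the data mesh.
#' @param tau prior correlation length (mm).
#' @param mesh_seed seed for the reconstruction-mesh ring phases.
#' @return An `ot_problem` with the projected truth attached as `truth`.
#' @export
reconstruction_problem <- function(dataset, recon_edge_length = 0.41,
                                   tau = 0.5, mesh_seed = 977L) {
  if (abs(recon_edge_length - dataset$mesh$target_edge_length) < 1e-12)
    stop("reconstruction mesh must differ from the data mesh (inverse crime)")
  domain <- dataset$domain
  mesh <- build_circular_mesh(domain, recon_edge_length, seed = mesh_seed)
  layout <- place_sources_detectors(domain, mesh,
                                    dataset$layout$n_sources,
                                    dataset$layout$n_detectors,
                                    dataset$layout$width)
  ps <- phantom_settings(dataset$phantom)
  prior <- build_ou_prior(mesh$centroids, ps$sigma_mua, ps$sigma_mus, tau,
                          ps$eta_mua, ps$eta_mus)
  prob <- ot_problem(domain, mesh, layout, dataset$noisy, prior,
                     g = dataset$field$g)
  prob$truth <- project_truth(dataset$field, dataset$mesh, mesh)
  prob
}

#' Run one reconstruction
#'
#' @param problem an `ot_problem` with `truth` attached (see
#'   [reconstruction_problem()]).
#' @param method `"sgn"` or `"asgn"`.
#' @param config method configuration: for SGN `list(P=, iterations=)`;
#'   for ASGN `list(L=, gamma=, P_init=, P_cap=, iterations=)`.
#' @param seed root seed.
#' @return the `sgn_result` with a `metrics` element (final and
#'   initial-guess relative errors, final u, packet totals).
#' @export
reconstruct <- function(problem, method = c("asgn", "sgn"),
                        config = list(), seed = 1L) {
  method <- match.arg(method)
  res <- if (method == "sgn") {
    do.call(run_sgn, c(list(problem = problem, seed = seed), config))
  } else {
    do.call(run_asgn, c(list(problem = problem, seed = seed), config))
  }
  if (!is.null(problem$truth)) {
    err <- relative_error(res$field, problem$truth)
    K <- problem$K
    init <- optical_field(rep(problem$prior$mean[1L], K),
                          rep(problem$prior$mean[K + 1L], K),
                          g = problem$g)
    err0 <- relative_error(init, problem$truth)
    res$metrics <- list(
      E_mua = unname(err["E_mua"]), E_mus = unname(err["E_mus"]),
      E_mua_init = unname(err0["E_mua"]), E_mus_init = unname(err0["E_mus"]),
      u_final = res$u_final,
      u_initial = res$history$u[1L],
      Ptot = res$cum_packets)
  }
  res
}

#' Repeated-run statistics
#'
#' Repeats a reconstruction with independent root seeds and summarizes the
#' minimized functional, the relative errors and the packet totals as
#' mean and standard deviation.
#'
#' @param problem an `ot_problem` with `truth`.
#' @param method,config as in [reconstruct()].
#' @param n_repeats number of repetitions (>= 2 for a standard deviation).
#' @param seed base seed; repeat r uses `seed + (r-1) * 1299709`.
#' @return A list with the per-run data frame `runs` and the `summary`
#'   data frame (mean, sd per metric).
#' @export
repeat_study <- function(problem, method = "asgn", config = list(),
                         n_repeats = 10L, seed = 1L) {
  if (n_repeats < 1L) stop("n_repeats must be >= 1")
  rows <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    res <- reconstruct(problem, method, config,
                       seed = seed + (r - 1L) * 1299709)
    m <- res$metrics
    rows[[r]] <- data.frame(repeat_index = r, u = m$u_final,
                            E_mua = m$E_mua, E_mus = m$E_mus,
                            Ptot = m$Ptot)
  }
  runs <- do.call(rbind, rows)
  summarize <- function(v) c(mean = mean(v),
                             sd = if (n_repeats > 1L) stats::sd(v) else 0)
  summary <- data.frame(
    metric = c("u", "E_mua", "E_mus", "Ptot"),
    mean = c(mean(runs$u), mean(runs$E_mua), mean(runs$E_mus),
             mean(runs$Ptot)),
    sd = if (n_repeats > 1L)
      c(stats::sd(runs$u), stats::sd(runs$E_mua), stats::sd(runs$E_mus),
        stats::sd(runs$Ptot))
    else rep(0, 4L))
  list(runs = runs, summary = summary)
}

#' Experiment presets
#'
#' Bundled problem sizes: `"desk"` is a reduced-scale study that runs in
#' minutes on one CPU (coarser meshes, 1e6 data packets, ASGN with L = 5
#' and a 1e6 packet cap); `"paper"` uses the full-scale settings of the
#' reference study (fine meshes, 1e10 data packets, L = 10) and is
#' long-running.  The highly scattering target swaps in its own threshold
#' and initial budget (gamma = 0.6, P1 = 1e4, 1e9 data packets).
#'
#' @param preset `"desk"` or `"paper"`.
#' @param phantom phantom name.
#' @return A list of [simulate_dataset()], [reconstruction_problem()] and
#'   [reconstruct()] arguments.
#' @export
otmc_preset <- function(preset = c("desk", "paper"), phantom = "circles") {
  preset <- match.arg(preset)
  high <- phantom == "high_scattering"
  if (preset == "desk") {
    list(phantom = phantom,
         data = list(edge_length = 0.29, packets = 1e6, noise_level = 0.01),
         recon = list(recon_edge_length = 0.41, tau = 0.5),
         method = "asgn",
         config = list(L = 5L, gamma = if (high) 0.6 else 1,
                       P_init = if (high) 1e4 else 1000,
                       P_cap = 1e6, iterations = 10L))
  } else {
    list(phantom = phantom,
         data = list(edge_length = 0.15,
                     packets = if (high) 1e9 else 1e10,
                     noise_level = 0.01),
         recon = list(recon_edge_length = 0.19, tau = 0.5),
         method = "asgn",
         config = list(L = 10L, gamma = if (high) 0.6 else 1,
                       P_init = if (high) 1e4 else 1000,
                       P_cap = 1e9, iterations = 10L))
  }
}

#' Run a preset experiment end to end
#'
#' Convenience driver: simulate the dataset, build the reconstruction
#' problem, and reconstruct (optionally repeated).
#'
#' @param preset,phantom see [otmc_preset()].
#' @param seed root seed.
#' @param n_repeats repetitions (1 = a single reconstruction).
#' @param overrides named list merged over the preset (e.g.
#'   `list(config = list(iterations = 5))`).
#' @return For one repeat the `sgn_result`; otherwise the [repeat_study()]
#'   output.  The problem bundle is attached as attribute `"problem"`.
#' @export
run_experiment <- function(preset = "desk", phantom = "circles", seed = 1L,
                           n_repeats = 1L, overrides = list()) {
  sp <- otmc_preset(preset, phantom)
  sp <- utils::modifyList(sp, overrides)
  ds <- do.call(simulate_dataset,
                c(list(phantom = sp$phantom, seed = seed), sp$data))
  prob <- do.call(reconstruction_problem, c(list(dataset = ds), sp$recon))
  out <- if (n_repeats == 1L) {
    reconstruct(prob, sp$method, sp$config, seed = seed)
  } else {
    repeat_study(prob, sp$method, sp$config, n_repeats = n_repeats,
                 seed = seed)
  }
  attr(out, "problem") <- prob
  attr(out, "dataset") <- ds
  out
}
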