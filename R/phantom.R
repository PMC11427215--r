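#' Optical coefficient field
#'
#' Piecewise-constant absorption and scattering coefficients on a mesh plus
#' the global Henyey-Greenstein anisotropy factor.
#'
#' @param mua,mus per-element coefficients (mm^-1), length = element count.
#' @param g anisotropy, -1 < g < 1.
#' @return An `ot_field` object.
#' @export
optical_field <- function(mua, mus, g = 0.9) {
  if (length(mua) != length(mus))
    stop("mua and mus must have the same length")
  if (any(mua < 0) || any(mus < 0))
    stop("optical coefficients must be non-negative")
  if (abs(g) >= 1) stop("anisotropy must satisfy -1 < g < 1")
  structure(list(mua = as.numeric(mua), mus = as.numeric(mus), g = g),
            class = "ot_field")
}

#' Simulation phantoms
#'
#' Generates the three study targets as piecewise-constant fields on a mesh.
#' Backgrounds follow the prior means (`circles` and `low_scattering_layer`:
#' mua = 0.01, mus = 0.1 mm^-1; `high_scattering`: mua = 0.01,
#' mus = 10 mm^-1) and inclusion peaks sit three prior standard deviations
#' above the background.  Inclusions are disks of radius 0.5 mm; element
#' membership is decided by a centroid-in-circle test so the field stays
#' exactly piecewise constant.
#'
#' Default geometry (configurable through `inclusions` / `layer`):
#' * `circles`: three absorbing and three scattering inclusions alternating
#'   at 60 degree spacing on a ring of radius 2 mm;
#' * `low_scattering_layer`: an annular layer (radii 2.6-3.4 mm) with
#'   mus = 0.01 mm^-1, enclosing one absorbing and one scattering inclusion;
#' * `high_scattering`: two absorbing and two scattering inclusions on the
#'   2 mm ring in a strongly scattering background.
#'
#' @param name phantom name.
#' @param mesh an `ot_mesh`.
#' @param g anisotropy factor of the medium.
#' @param inclusions optional data frame overriding the inclusion set, with
#'   columns `x`, `y`, `r`, `mua`, `mus` (NA = keep background).
#' @param layer optional list `list(inner=, outer=, mus=)` overriding the
#'   low-scattering layer.
#' @return An `ot_field` on `mesh`.
#' @export
make_phantom <- function(name = c("circles", "low_scattering_layer",
                                  "high_scattering"),
                         mesh, g = 0.9, inclusions = NULL, layer = NULL) {
  name <- match.arg(name)
  s <- phantom_settings(name)
  K <- nrow(mesh$triangles)
  mua <- rep(s$bg_mua, K)
  mus <- rep(s$bg_mus, K)
  cx <- mesh$centroids[, 1L]
  cy <- mesh$centroids[, 2L]

  if (name == "low_scattering_layer") {
    if (is.null(layer)) layer <- s$layer
    rr <- sqrt(cx^2 + cy^2)
    mus[rr >= layer$inner & rr <= layer$outer] <- layer$mus
  }
  if (is.null(inclusions)) inclusions <- s$inclusions
  for (i in seq_len(nrow(inclusions))) {
    inc <- inclusions[i, ]
    hit <- (cx - inc$x)^2 + (cy - inc$y)^2 <= inc$r^2
    if (!is.na(inc$mua)) mua[hit] <- inc$mua
    if (!is.na(inc$mus)) mus[hit] <- inc$mus
  }
  optical_field(mua, mus, g = g)
}

#' Study settings per phantom
#'
#' Background values, inclusion tables, and the matching prior mean /
#' standard deviation per coefficient (prior mean = background, standard
#' deviation = one third of the inclusion-background contrast).
#'
#' @param name phantom name as in [make_phantom()].
#' @return A list with `bg_mua`, `bg_mus`, `inclusions`, optional `layer`,
#'   and prior settings `eta_mua`, `sigma_mua`, `eta_mus`, `sigma_mus`.
#' @export
phantom_settings <- function(name = c("circles", "low_scattering_layer",
                                      "high_scattering")) {
  name <- match.arg(name)
  ring <- function(angles_deg, radius = 2) {
    a <- angles_deg * pi / 180
    cbind(x = radius * cos(a), y = radius * sin(a))
  }
  if (name == "circles") {
    sigma_mua <- 0.0067; sigma_mus <- 0.033
    pa <- ring(c(90, 210, 330)); ps <- ring(c(30, 150, 270))
    inclusions <- data.frame(
      x = c(pa[, 1L], ps[, 1L]), y = c(pa[, 2L], ps[, 2L]), r = 0.5,
      mua = c(rep(0.01 + 3 * sigma_mua, 3L), rep(NA_real_, 3L)),
      mus = c(rep(NA_real_, 3L), rep(0.1 + 3 * sigma_mus, 3L)))
    list(bg_mua = 0.01, bg_mus = 0.1, inclusions = inclusions,
         eta_mua = 0.01, sigma_mua = sigma_mua,
         eta_mus = 0.1, sigma_mus = sigma_mus)
  } else if (name == "low_scattering_layer") {
    sigma_mua <- 0.0067; sigma_mus <- 0.033
    inclusions <- data.frame(
      x = c(0, 0), y = c(1.5, -1.5), r = 0.5,
      mua = c(0.01 + 3 * sigma_mua, NA_real_),
      mus = c(NA_real_, 0.1 + 3 * sigma_mus))
    list(bg_mua = 0.01, bg_mus = 0.1, inclusions = inclusions,
         layer = list(inner = 2.6, outer = 3.4, mus = 0.01),
         eta_mua = 0.01, sigma_mua = sigma_mua,
         eta_mus = 0.1, sigma_mus = sigma_mus)
  } else {
    sigma_mua <- 0.013; sigma_mus <- 3.3
    pa <- ring(c(45, 225)); ps <- ring(c(135, 315))
    inclusions <- data.frame(
      x = c(pa[, 1L], ps[, 1L]), y = c(pa[, 2L], ps[, 2L]), r = 0.5,
      mua = c(rep(0.01 + 3 * sigma_mua, 2L), rep(NA_real_, 2L)),
      mus = c(rep(NA_real_, 2L), rep(10 + 3 * sigma_mus, 2L)))
    list(bg_mua = 0.01, bg_mus = 10, inclusions = inclusions,
         eta_mua = 0.01, sigma_mua = sigma_mua,
         eta_mus = 10, sigma_mus = sigma_mus)
  }
}

#' @export
print.ot_field <- function(x, ...) {
  cat(sprintf(
    "Optical field: %d elements, mua in [%.3g, %.3g], mus in [%.3g, %.3g] mm^-1, g = %g\n",
    length(x$mua), min(x$mua), max(x$mua), min(x$mus), max(x$mus), x$g))
  invisible(x)
}
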