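#' Circular imaging domain
#'
#' Defines the circular 2D domain on whose boundary sources and detectors
#' sit, together with the optical environment constants: refractive index
#' and the intensity-modulation frequency of the frequency-domain setup.
#'
#' @param radius domain radius in mm.
#' @param refractive_index refractive index `n` of the medium (dimensionless);
#'   the speed of light inside is `c = c0 / n`.
#' @param frequency modulation frequency in Hz.
#'
#' @return An object of class `ot_domain` with fields `radius`, `n`,
#'   `frequency`, and the derived `c` (mm/ns), `omega` (rad/ns) and
#'   `omega_over_c` (rad/mm).
#' @export
circular_domain <- function(radius = 4, refractive_index = 1,
                            frequency = 100e6) {
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("radius must be a positive scalar (mm)")
  if (refractive_index <= 0) stop("refractive_index must be > 0")
  if (frequency < 0) stop("frequency must be >= 0")
  c0 <- 299.792458                 # vacuum speed of light, mm/ns
  cc <- c0 / refractive_index
  omega <- 2 * pi * frequency * 1e-9   # rad/ns
  structure(list(
    radius = radius,
    n = refractive_index,
    frequency = frequency,
    c0 = c0,
    c = cc,
    omega = omega,
    omega_over_c = omega / cc), class = "ot_domain")
}

#' @export
print.ot_domain <- function(x, ...) {
  cat(sprintf(
    "Circular domain: radius %g mm, n = %g, f = %g MHz (omega/c = %.4g rad/mm)\n",
    x$radius, x$n, x$frequency / 1e6, x$omega_over_c))
  invisible(x)
}
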