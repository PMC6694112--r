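#' Confocal point-spread function
#'
#' Constructs the characteristic point-spread function (PSF) of a single-focus
#' confocal microscope: the combined excitation/detection efficiency profile
#' that maps a molecule's position (relative to the centre of the confocal
#' volume, in micrometres) to its relative photon-detection efficiency.
#' Values are unitless, normalised to 1 at the origin, so that the molecular
#' brightness parameter is the detected photon rate of a molecule sitting
#' exactly at the centre.
#'
#' Three variants are supported:
#' \describe{
#'   \item{\code{gaussian3d}}{\eqn{\exp(-2(x^2+y^2)/\omega_{xy}^2 -
#'     2z^2/\omega_z^2)}; the standard ellipsoidal confocal volume.}
#'   \item{\code{gaussian_cylindrical}}{\eqn{\exp(-2(x^2+y^2)/\omega_{xy}^2)};
#'     axially unbounded (no dependence on \code{z}), appropriate for strongly
#'     elongated detection volumes. \code{omega_z} is unused.}
#'   \item{\code{gaussian_lorentzian}}{the focused-beam profile with
#'     z-dependent waist \eqn{\omega(z) = \omega_{xy}\sqrt{1+(z/\omega_z)^2}}:
#'     \eqn{(\omega_{xy}/\omega(z))^2 \exp(-2(x^2+y^2)/\omega(z)^2)}.}
#' }
#'
#' @param variant one of \code{"gaussian3d"}, \code{"gaussian_cylindrical"},
#'   \code{"gaussian_lorentzian"}.
#' @param omega_xy lateral 1/e^2 radius, micrometres (> 0).
#' @param omega_z axial parameter, micrometres (> 0; ignored by the
#'   cylindrical variant).
#' @return an object of class \code{confocal_psf}.
#' @examples
#' psf <- confocal_psf("gaussian3d", omega_xy = 0.3, omega_z = 1.5)
#' evaluate_psf(psf, 0.3, 0, 0)   # exp(-2)
#' @export
confocal_psf <- function(variant = c("gaussian3d", "gaussian_cylindrical",
                                     "gaussian_lorentzian"),
                         omega_xy, omega_z = NA_real_) {
  variant <- match.arg(variant)
  if (!is.numeric(omega_xy) || length(omega_xy) != 1L ||
      !is.finite(omega_xy) || omega_xy <= 0)
    stop("'omega_xy' must be a single positive number (micrometres)")
  if (variant != "gaussian_cylindrical") {
    if (!is.numeric(omega_z) || length(omega_z) != 1L ||
        !is.finite(omega_z) || omega_z <= 0)
      stop("'omega_z' must be a single positive number (micrometres)")
  }
  structure(list(variant = variant,
                 omega_xy = as.numeric(omega_xy),
                 omega_z = as.numeric(omega_z)),
            class = "confocal_psf")
}

#' @export
print.confocal_psf <- function(x, ...) {
  cat("Confocal PSF [", x$variant, "]  omega_xy =", x$omega_xy, "um",
      if (x$variant != "gaussian_cylindrical")
        paste(" omega_z =", x$omega_z, "um"),
      "\n")
  invisible(x)
}

psf_variant_code <- function(psf) {
  match(psf$variant,
        c("gaussian3d", "gaussian_cylindrical", "gaussian_lorentzian"))
}

# omega_z slot passed to C++ must be a real number even when unused
psf_wz <- function(psf) if (is.na(psf$omega_z)) 1.0 else psf$omega_z

#' Evaluate a confocal PSF at given coordinates
#'
#' @param psf a \code{\link{confocal_psf}}.
#' @param x,y,z coordinates in micrometres (vectors are recycled to common
#'   length). The origin is the centre of the confocal volume, \code{z} along
#'   the optical axis.
#' @return relative detection efficiencies in \code{[0, 1]}.
#' @export
evaluate_psf <- function(psf, x, y, z = 0) {
  stopifnot(inherits(psf, "confocal_psf"))
  n <- max(length(x), length(y), length(z))
  x <- rep_len(as.numeric(x), n)
  y <- rep_len(as.numeric(y), n)
  z <- rep_len(as.numeric(z), n)
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(!is.finite(z)))
    stop("PSF coordinates must be finite")
  cpp_psf_values(cbind(x, y, z), psf_variant_code(psf),
                 psf$omega_xy, psf_wz(psf))
}

# PSF values for a K x 3 position matrix (internal fast path)
psf_values <- function(psf, pos) {
  cpp_psf_values(pos, psf_variant_code(psf), psf$omega_xy, psf_wz(psf))
}

#' Effective volume of a 3D Gaussian confocal PSF
#'
#' The standard FCS effective volume
#' \eqn{V_{eff} = \pi^{3/2}\,\omega_{xy}^2\,\omega_z}, which converts a
#' fluorophore concentration into the mean number of molecules contributing
#' appreciably to the signal.
#'
#' @param psf a \code{\link{confocal_psf}} with variant \code{gaussian3d}.
#' @return effective volume in cubic micrometres.
#' @examples
#' effective_volume(confocal_psf("gaussian3d", 0.3, 1.5))  # ~0.7517
#' @export
effective_volume <- function(psf) {
  stopifnot(inherits(psf, "confocal_psf"))
  if (psf$variant != "gaussian3d")
    stop("effective volume is not defined for PSF variant '", psf$variant, "'")
  pi^(3 / 2) * psf$omega_xy^2 * psf$omega_z
}

#' Stokes-Einstein diffusion coefficient
#'
#' \eqn{D = k_B T / (3\pi\eta d)} for a sphere of diameter \code{d} in a fluid
#' of viscosity \code{eta}, returned in micrometres squared per second.
#' Defaults correspond to water at 25 degrees Celsius.
#'
#' @param diameter_um sphere diameter, micrometres.
#' @param temperature_K absolute temperature, kelvin.
#' @param viscosity_Pa_s dynamic viscosity, pascal-seconds
#'   (8.9e-4 for water at 25 C).
#' @return diffusion coefficient, um^2/s.
#' @examples
#' stokes_einstein(0.046)  # ~10.7 um^2/s: a 46 nm bead in water
#' @export
stokes_einstein <- function(diameter_um, temperature_K = 298.15,
                            viscosity_Pa_s = 8.9e-4) {
  stopifnot(diameter_um > 0, temperature_K > 0, viscosity_Pa_s > 0)
  kB <- 1.380649e-23  # J/K
  d_m <- diameter_um * 1e-6
  D_m2s <- kB * temperature_K / (3 * pi * viscosity_Pa_s * d_m)
  D_m2s * 1e12  # m^2/s -> um^2/s
}
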