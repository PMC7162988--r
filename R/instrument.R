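#' Photophysical instrument model
#'
#' Bundles the photophysical and instrumental parameters that determine the
#' expected signal in the three acquisition channels for given per-pixel
#' fluorophore numbers and FRET probability: excitation intensities
#' \code{L_D}, \code{L_A}; absorption cross sections \code{sigma_Dex_D}
#' (donor at donor excitation), \code{sigma_Dex_A} (acceptor at donor
#' excitation, responsible for direct excitation), \code{sigma_Aex_A}
#' (acceptor at acceptor excitation); quantum yields \code{phi_D},
#' \code{phi_A}; and detection efficiencies \code{eta_Ddet_Dem} (donor
#' photons in donor channel), \code{eta_Adet_Dem} (donor photons bleeding
#' into the acceptor channel) and \code{eta_Adet_Aem} (acceptor photons in
#' acceptor channel).
#'
#' All parameters are strictly positive except \code{eta_Adet_Dem} and
#' \code{sigma_Dex_A}, which may be zero (an idealized crosstalk-free
#' instrument). Quantum yields and detection efficiencies must lie in
#' \code{[0, 1]}.
#'
#' @param L_D,L_A excitation intensity at the donor/acceptor wavelength
#'   (arbitrary power units).
#' @param sigma_Dex_D,sigma_Dex_A,sigma_Aex_A absorption cross sections
#'   (area units, arbitrary common scale).
#' @param phi_D,phi_A fluorescence quantum yields, in \code{[0, 1]}.
#' @param eta_Ddet_Dem,eta_Adet_Dem,eta_Adet_Aem detection efficiencies,
#'   in \code{[0, 1]}.
#' @return An object of class \code{instrument_model}.
#' @seealso [true_correction_factors()], [expected_intensities()],
#'   [instrument_from_factors()]
#' @export
#' @examples
#' inst <- instrument_model()          # unit instrument, no crosstalk
#' true_correction_factors(inst)
instrument_model <- function(L_D = 1, L_A = 1,
                             sigma_Dex_D = 1, sigma_Dex_A = 0, sigma_Aex_A = 1,
                             phi_D = 1, phi_A = 1,
                             eta_Ddet_Dem = 1, eta_Adet_Dem = 0,
                             eta_Adet_Aem = 1) {
  inst <- list(L_D = L_D, L_A = L_A,
               sigma_Dex_D = sigma_Dex_D, sigma_Dex_A = sigma_Dex_A,
               sigma_Aex_A = sigma_Aex_A,
               phi_D = phi_D, phi_A = phi_A,
               eta_Ddet_Dem = eta_Ddet_Dem, eta_Adet_Dem = eta_Adet_Dem,
               eta_Adet_Aem = eta_Adet_Aem)
  for (nm in names(inst)) {
    v <- inst[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop("instrument parameter '", nm, "' must be a finite scalar")
    lo_ok <- if (nm %in% c("eta_Adet_Dem", "sigma_Dex_A")) v >= 0 else v > 0
    if (!lo_ok)
      stop("instrument parameter '", nm, "' must be ",
           if (nm %in% c("eta_Adet_Dem", "sigma_Dex_A")) "non-negative"
           else "strictly positive")
    if (grepl("^(phi|eta)", nm) && v > 1)
      stop("instrument parameter '", nm, "' must lie in [0, 1]")
  }
  structure(inst, class = "instrument_model")
}

#' @export
print.instrument_model <- function(x, ...) {
  cat("<instrument_model>\n")
  cat(sprintf("  excitation:  L_D = %g, L_A = %g\n", x$L_D, x$L_A))
  cat(sprintf("  cross sect.: sigma_Dex_D = %g, sigma_Dex_A = %g, sigma_Aex_A = %g\n",
              x$sigma_Dex_D, x$sigma_Dex_A, x$sigma_Aex_A))
  cat(sprintf("  yields:      phi_D = %g, phi_A = %g\n", x$phi_D, x$phi_A))
  cat(sprintf("  detection:   eta_Ddet_Dem = %g, eta_Adet_Dem = %g, eta_Adet_Aem = %g\n",
              x$eta_Ddet_Dem, x$eta_Adet_Dem, x$eta_Adet_Aem))
  f <- true_correction_factors(x)
  cat(sprintf("  derived:     alpha_BT = %.4g, delta_DE = %.4g, gamma_M = %.4g, beta_X = %.4g\n",
              f$alpha_BT, f$delta_DE, f$gamma_M, f$beta_X))
  invisible(x)
}

#' True correction factors of an instrument model
#'
#' Computes the four correction factors implied by the photophysical
#' parameters:
#' \deqn{\alpha^{BT} = \eta_{Adet}^{Dem} / \eta_{Ddet}^{Dem}, \quad
#'       \delta^{DE} = L_D \sigma_{Dex}^A / (L_A \sigma_{Aex}^A),}
#' \deqn{\gamma^{M} = \phi_A \eta_{Adet}^{Aem} / (\phi_D \eta_{Ddet}^{Dem}),
#'       \quad
#'       \beta^{X} = L_A \sigma_{Aex}^A / (L_D \sigma_{Dex}^D).}
#' These are the ground-truth values a perfect calibration must recover.
#'
#' @param inst an [instrument_model()].
#' @return A list with elements \code{alpha_BT}, \code{delta_DE},
#'   \code{gamma_M}, \code{beta_X}.
#' @export
true_correction_factors <- function(inst) {
  stopifnot(inherits(inst, "instrument_model"))
  den <- c(eta = inst$eta_Ddet_Dem,
           LsA = inst$L_A * inst$sigma_Aex_A,
           phi = inst$phi_D * inst$eta_Ddet_Dem,
           LsD = inst$L_D * inst$sigma_Dex_D)
  if (any(den == 0))
    stop("zero denominator in correction-factor definition")
  list(alpha_BT = inst$eta_Adet_Dem / inst$eta_Ddet_Dem,
       delta_DE = inst$L_D * inst$sigma_Dex_A / (inst$L_A * inst$sigma_Aex_A),
       gamma_M  = inst$phi_A * inst$eta_Adet_Aem /
                    (inst$phi_D * inst$eta_Ddet_Dem),
       beta_X   = inst$L_A * inst$sigma_Aex_A / (inst$L_D * inst$sigma_Dex_D))
}

#' Construct an instrument model realizing given correction factors
#'
#' Builds a concrete parameter set whose derived correction factors equal the
#' requested values. The construction is not unique (twelve photophysical
#' parameters map onto four factors); this helper fixes a convenient gauge
#' with realistic quantum yields and detection efficiencies. \code{scale}
#' multiplies all excitation intensities and sets the expected photon yield
#' per fluorophore, i.e. the brightness of the simulation.
#'
#' @param alpha_BT,delta_DE,gamma_M,beta_X target correction factors;
#'   \code{gamma_M}, \code{beta_X} strictly positive, crosstalks
#'   non-negative.
#' @param scale overall brightness multiplier applied to \code{L_D} and
#'   \code{L_A} (default 1).
#' @return An [instrument_model()] whose [true_correction_factors()] equal
#'   the arguments (to floating-point precision).
#' @export
#' @examples
#' inst <- instrument_from_factors(0.421, 0.110, 2.10, 1.167)
#' unlist(true_correction_factors(inst))
instrument_from_factors <- function(alpha_BT = 0.421, delta_DE = 0.110,
                                    gamma_M = 2.10, beta_X = 1.167,
                                    scale = 1) {
  stopifnot(alpha_BT >= 0, delta_DE >= 0, gamma_M > 0, beta_X > 0, scale > 0)
  phi_D <- 0.5; eta_DD <- 0.5
  # gamma_M = phi_A * eta_AA / (phi_D * eta_DD); split the product so both
  # stay in (0, 1] over the practical gamma range
  pa <- gamma_M * phi_D * eta_DD
  phi_A  <- min(0.95, sqrt(pa))
  eta_AA <- pa / phi_A
  if (eta_AA > 1) { eta_AA <- 0.95; phi_A <- pa / eta_AA }
  if (phi_A > 1)
    stop("gamma_M too large to realize with physical yields in this gauge")
  eta_AD <- alpha_BT * eta_DD
  if (eta_AD > 1) stop("alpha_BT too large for this gauge")
  instrument_model(L_D = scale, L_A = scale,
                   sigma_Dex_D = 1, sigma_Aex_A = beta_X,
                   sigma_Dex_A = delta_DE * beta_X,
                   phi_D = phi_D, phi_A = phi_A,
                   eta_Ddet_Dem = eta_DD, eta_Adet_Dem = eta_AD,
                   eta_Adet_Aem = eta_AA)
}

#' Expected noise-free channel intensities
#'
#' Evaluates the photophysical signal model for the three channels. With
#' \code{n_D}, \code{n_A} the per-pixel donor and acceptor fluorophore
#' numbers and \code{E} the FRET probability:
#' \deqn{I_{AA} = n_A L_A \sigma_{Aex}^A \phi_A \eta_{Adet}^{Aem}}
#' \deqn{I_{DD} = n_D L_D \sigma_{Dex}^D (1 - E) \phi_D \eta_{Ddet}^{Dem}}
#' \deqn{I_{DA} = n_D L_D \sigma_{Dex}^D E \phi_A \eta_{Adet}^{Aem}
#'   + n_D L_D \sigma_{Dex}^D (1 - E) \phi_D \eta_{Adet}^{Dem}
#'   + n_A L_D \sigma_{Dex}^A \phi_A \eta_{Adet}^{Aem}}
#' The three \code{I_DA} terms are, in order: sensitized emission (FRET),
#' donor bleedthrough, and acceptor direct excitation.
#'
#' @param n_D,n_A non-negative fluorophore counts (vectors or matrices,
#'   recycled together).
#' @param E FRET probability in \code{[0, 1]}, same shape.
#' @param inst an [instrument_model()].
#' @return A list with components \code{I_DD}, \code{I_DA}, \code{I_AA},
#'   each shaped like the inputs.
#' @export
expected_intensities <- function(n_D, n_A, E, inst) {
  stopifnot(inherits(inst, "instrument_model"))
  if (any(n_D < 0, na.rm = TRUE) || any(n_A < 0, na.rm = TRUE))
    stop("fluorophore counts must be non-negative")
  if (any(E < 0 | E > 1, na.rm = TRUE))
    stop("FRET probability E must lie in [0, 1]")
  exc_D <- inst$L_D * inst$sigma_Dex_D          # donor excitation rate
  I_AA <- n_A * inst$L_A * inst$sigma_Aex_A * inst$phi_A * inst$eta_Adet_Aem
  I_DD <- n_D * exc_D * (1 - E) * inst$phi_D * inst$eta_Ddet_Dem
  I_DA <- n_D * exc_D * E * inst$phi_A * inst$eta_Adet_Aem +
          n_D * exc_D * (1 - E) * inst$phi_D * inst$eta_Adet_Dem +
          n_A * inst$L_D * inst$sigma_Dex_A * inst$phi_A * inst$eta_Adet_Aem
  list(I_DD = I_DD, I_DA = I_DA, I_AA = I_AA)
}
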