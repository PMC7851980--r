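#' Complex spectrum container
#'
#' A frequency grid with complex-valued samples of one of the quantities the
#' package computes. The sign convention is the engineering \eqn{+j\omega}
#' Fourier convention throughout, so a passive dielectric has a nonnegative
#' loss factor \eqn{-\mathrm{Im}\,\varepsilon_r(\omega) \ge 0}.
#'
#' @param omega angular frequencies in rad/s, strictly increasing.
#'   \eqn{\omega = 0} is allowed only for permittivity-type quantities, not
#'   for impedance or the step charge spectrum (both have a \eqn{1/j\omega}
#'   pole).
#' @param values complex samples, same length as \code{omega}.
#' @param quantity one of \code{"relative_permittivity"},
#'   \code{"normalized_permittivity"}, \code{"capacitance_F"},
#'   \code{"impedance_ohm"}, \code{"step_current_spectrum"},
#'   \code{"step_charge_spectrum"}.
#' @return An object of class \code{"complex_spectrum"}.
#' @export
complex_spectrum <- function(omega, values,
                             quantity = c("relative_permittivity",
                                          "normalized_permittivity",
                                          "capacitance_F", "impedance_ohm",
                                          "step_current_spectrum",
                                          "step_charge_spectrum")) {
  quantity <- match.arg(quantity)
  zero_ok <- quantity %in% c("relative_permittivity", "normalized_permittivity",
                             "capacitance_F", "step_current_spectrum")
  omega <- check_grid(omega, "omega", allow_zero = zero_ok)
  if (!is.complex(values)) values <- as.complex(values)
  if (length(values) != length(omega))
    stop("omega and values lengths differ", call. = FALSE)
  structure(list(omega = omega, values = values, quantity = quantity),
            class = "complex_spectrum")
}

#' @export
print.complex_spectrum <- function(x, ...) {
  cat(sprintf("<complex_spectrum: %s, %d frequencies in [%g, %g] rad/s>\n",
              x$quantity, length(x$omega), min(x$omega), max(x$omega)))
  invisible(x)
}

#' @export
as.data.frame.complex_spectrum <- function(x, ...) {
  data.frame(omega_rad_s = x$omega, real = Re(x$values), imag = Im(x$values),
             quantity = x$quantity, stringsAsFactors = FALSE)
}

# principal-branch (j omega tau)^alpha = (omega tau)^alpha exp(j alpha pi/2),
# the only branch consistent with causality/passivity here
jwta <- function(omega, tau, alpha) {
  (omega * tau)^alpha * exp(1i * alpha * pi / 2)
}

#' Complex relative permittivity
#'
#' Evaluates \eqn{\varepsilon_r(\omega) = \varepsilon_\infty +
#' (\varepsilon_s-\varepsilon_\infty)/(1+(j\omega\tau)^\alpha)^\beta} with
#' principal-branch complex powers. At \eqn{\omega = 0} the value is exactly
#' \eqn{\varepsilon_s} (defined by continuity).
#'
#' @param params a [dielectric_params()] object.
#' @param omega angular frequency grid, rad/s, \eqn{\ge 0}, strictly increasing.
#' @return a [complex_spectrum()] with quantity \code{"relative_permittivity"}.
#' @examples
#' p <- dielectric_params("debye", eps_s = 2, eps_inf = 1, tau = 1)
#' permittivity(p, 1)  # 1.5 - 0.5i at omega * tau = 1
#' @export
permittivity <- function(params, omega) {
  stopifnot(inherits(params, "dielectric_params"))
  omega <- check_grid(omega, "omega", allow_zero = TRUE)
  vals <- params$eps_inf + (params$eps_s - params$eps_inf) * eps_norm(params, omega)
  complex_spectrum(omega, vals, "relative_permittivity")
}

# normalized permittivity kernel 1/(1 + (j w tau)^a)^b, exact 1 at omega = 0
eps_norm <- function(params, omega) {
  out <- complex(length(omega))
  z <- omega == 0
  out[z] <- 1 + 0i
  if (any(!z))
    out[!z] <- (1 + jwta(omega[!z], params$tau, params$alpha))^(-params$beta)
  out
}

#' Normalized permittivity
#'
#' \eqn{(\varepsilon_r - \varepsilon_\infty)/(\varepsilon_s - \varepsilon_\infty)
#'  = 1/(1+(j\omega\tau)^\alpha)^\beta}; exactly 1 at \eqn{\omega = 0}.
#'
#' @inheritParams permittivity
#' @return a [complex_spectrum()] with quantity \code{"normalized_permittivity"}.
#' @export
normalized_permittivity <- function(params, omega) {
  stopifnot(inherits(params, "dielectric_params"))
  omega <- check_grid(omega, "omega", allow_zero = TRUE)
  complex_spectrum(omega, eps_norm(params, omega), "normalized_permittivity")
}

#' Electric susceptibility from relative permittivity
#'
#' \eqn{\chi = \varepsilon_0(\varepsilon_r - 1)}, the material-response side of
#' the constitutive relation \eqn{D = \varepsilon_0\varepsilon_r E =
#' \varepsilon_0 E + \chi E = \varepsilon_0 E + P}, where \eqn{P = \chi E} is
#' the polarization charge density.
#'
#' @param eps_r complex (or real) relative permittivity value(s).
#' @param eps0_val vacuum permittivity, F/m; the fixed constant [eps0] by default.
#' @return susceptibility in F/m, same shape as \code{eps_r}.
#' @export
susceptibility_from_permittivity <- function(eps_r, eps0_val = eps0) {
  eps0_val * (eps_r - 1)
}

#' Complex capacitance of a dielectric-filled parallel-plate cell
#'
#' \eqn{C(\omega) = (A/d)\,\varepsilon_0\,\varepsilon_r(\omega)}.
#'
#' @inheritParams permittivity
#' @param geometry a [cell_geometry()] object.
#' @return a [complex_spectrum()] with quantity \code{"capacitance_F"}.
#' @export
capacitance <- function(params, geometry, omega) {
  stopifnot(inherits(geometry, "cell_geometry"))
  eps <- permittivity(params, omega)
  complex_spectrum(eps$omega,
                   geometry$area / geometry$distance * geometry$eps0 * eps$values,
                   "capacitance_F")
}

#' Complex impedance of the cell
#'
#' \eqn{Z(\omega) = 1/(j\omega C(\omega))}. Unbounded at \eqn{\omega = 0},
#' which is therefore rejected. For any passive parameter set
#' \eqn{\mathrm{Re}\,Z \ge 0}.
#'
#' @inheritParams capacitance
#' @return a [complex_spectrum()] with quantity \code{"impedance_ohm"}.
#' @export
impedance <- function(params, geometry, omega) {
  omega <- check_grid(omega, "omega", allow_zero = FALSE)
  C <- capacitance(params, geometry, omega)
  complex_spectrum(omega, 1 / (1i * omega * C$values), "impedance_ohm")
}

#' Constant-phase-element limit of the Cole-Cole capacitance
#'
#' For \eqn{(\omega\tau)^\alpha \gg 1} and \eqn{\varepsilon_\infty = 0} the
#' Cole-Cole capacitance approaches the constant phase element
#' \eqn{C \approx (A/d)\,\varepsilon_0\,\varepsilon_s\,(j\omega\tau)^{-\alpha}},
#' whose impedance phase is \eqn{-\alpha\pi/2} at every frequency. A warning
#' (not an error) is emitted where \eqn{(\omega\tau)^\alpha < 10}, where the
#' approximation is poor.
#'
#' @inheritParams capacitance
#' @return a [complex_spectrum()] with quantity \code{"capacitance_F"}.
#' @seealso [cpe_onset_omega_tau()] for how large \eqn{\omega\tau} must be.
#' @export
cpe_limit_capacitance <- function(params, geometry, omega) {
  stopifnot(inherits(params, "dielectric_params"),
            inherits(geometry, "cell_geometry"))
  if (params$eps_inf != 0)
    stop("cpe_limit_capacitance requires eps_inf = 0", call. = FALSE)
  omega <- check_grid(omega, "omega", allow_zero = FALSE)
  wta <- (omega * params$tau)^params$alpha
  if (any(wta < 10))
    warning("(omega*tau)^alpha < 10 at some frequencies: CPE limit is a poor ",
            "approximation there", call. = FALSE)
  vals <- geometry$area / geometry$distance * geometry$eps0 * params$eps_s *
    wta^(-1) * exp(-1i * params$alpha * pi / 2)
  complex_spectrum(omega, vals, "capacitance_F")
}

#' Frequency where the CPE factor reaches a given size
#'
#' Solves \eqn{(\omega\tau)^\alpha = \mathrm{factor}} for \eqn{\omega\tau},
#' i.e. \eqn{\omega\tau = \mathrm{factor}^{1/\alpha}}. For a nearly ideal
#' capacitor with \eqn{\alpha = 0.01} the factor reaches 10 only at
#' \eqn{\omega\tau = 10^{100}}, which is why real capacitors can follow the
#' Curie-von Schweidler small-time law for days.
#'
#' @param alpha fractional order in \eqn{(0, 1]}.
#' @param factor target size of \eqn{(\omega\tau)^\alpha}, default 10.
#' @return the dimensionless product \eqn{\omega\tau} (may overflow to
#'   \code{Inf} for tiny \code{alpha}; use \code{log10 = TRUE} to get
#'   \eqn{\log_{10}(\omega\tau)} instead).
#' @param log10 if \code{TRUE} return \eqn{\log_{10}(\omega\tau)}.
#' @examples
#' cpe_onset_omega_tau(0.01)               # 1e100
#' cpe_onset_omega_tau(0.01, log10 = TRUE) # 100
#' @export
cpe_onset_omega_tau <- function(alpha, factor = 10, log10 = FALSE) {
  stopifnot(alpha > 0, alpha <= 1, factor > 0)
  lg <- log10(factor) / alpha
  if (log10) lg else 10^lg
}

#' Step-voltage current and charge spectra
#'
#' For a unit voltage step the current spectrum is
#' \eqn{I_{step}(\omega) = \varepsilon_0 (A/d)\, \varepsilon_r(\omega)} and the
#' charge-density spectrum is
#' \eqn{Q_{step}(\omega) = \varepsilon_0\, \varepsilon_r(\omega)/(d\, j\omega)}.
#' The charge spectrum has an explicit \eqn{1/j\omega} pole, so
#' \eqn{\omega = 0} is rejected.
#'
#' @inheritParams capacitance
#' @return a list with components \code{current} and \code{charge}, each a
#'   [complex_spectrum()].
#' @export
step_spectra <- function(params, geometry, omega) {
  omega <- check_grid(omega, "omega", allow_zero = FALSE)
  eps <- permittivity(params, omega)
  list(
    current = complex_spectrum(
      omega, geometry$eps0 * geometry$area / geometry$distance * eps$values,
      "step_current_spectrum"),
    charge = complex_spectrum(
      omega, geometry$eps0 * eps$values / (geometry$distance * 1i * omega),
      "step_charge_spectrum")
  )
}

#' Write / read the spectrum CSV interchange format
#'
#' Plain UTF-8 comma-separated text with header
#' \code{omega_rad_s,real,imag,quantity} and all numbers at 17 significant
#' digits so that a write/read round trip is lossless in double precision.
#'
#' @param x a [complex_spectrum()].
#' @param path file path.
#' @return \code{write_spectrum_csv} returns \code{path} invisibly;
#'   \code{read_spectrum_csv} returns a [complex_spectrum()].
#' @export
write_spectrum_csv <- function(x, path) {
  stopifnot(inherits(x, "complex_spectrum"))
  lines <- c("omega_rad_s,real,imag,quantity",
             sprintf("%.17g,%.17g,%.17g,%s",
                     x$omega, Re(x$values), Im(x$values), x$quantity))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("omega_rad_s", "real", "imag", "quantity")
  if (!all(need %in% names(df)))
    stop("malformed spectrum CSV: expected header omega_rad_s,real,imag,quantity",
         call. = FALSE)
  complex_spectrum(df$omega_rad_s, complex(real = df$real, imaginary = df$imag),
                   unique(df$quantity))
}
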