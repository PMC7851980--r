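#' Vacuum permittivity (F/m)
#'
#' The 2018 CODATA value of the electric constant \eqn{\varepsilon_0}, used
#' throughout when converting relative permittivity to capacitance, current
#' or charge.
#'
#' @export
eps0 <- 8.8541878128e-12

#' Dielectric relaxation model parameters
#'
#' Constructs and validates the parameter vector of a relaxation model of the
#' Havriliak-Negami family,
#' \deqn{\varepsilon_r(\omega) = \varepsilon_\infty +
#'   \frac{\varepsilon_s - \varepsilon_\infty}{(1 + (j\omega\tau)^\alpha)^\beta},}
#' with the usual nested special cases: \code{"debye"} (\eqn{\alpha=\beta=1}),
#' \code{"cole_cole"} (\eqn{\beta=1}), \code{"cole_davidson"} (\eqn{\alpha=1}),
#' and the general \code{"havriliak_negami"}.
#'
#' @param model model family; one of \code{"cole_cole"}, \code{"debye"},
#'   \code{"cole_davidson"}, \code{"havriliak_negami"}.
#' @param eps_s static (zero-frequency) relative permittivity; must exceed
#'   \code{eps_inf}.
#' @param eps_inf infinite-frequency relative permittivity, \eqn{\ge 0}.
#' @param tau characteristic relaxation time in seconds, \eqn{> 0}.
#' @param alpha fractional order in \eqn{(0, 1]}. For \code{"debye"} and
#'   \code{"cole_davidson"} it must be 1 (the default is then used).
#' @param beta second exponent in \eqn{(0, 1]}; must be 1 for \code{"debye"}
#'   and \code{"cole_cole"}.
#'
#' @return An object of class \code{"dielectric_params"}.
#' @seealso [alpha_from_em_convention()] for the \eqn{\alpha' = 1 - \alpha}
#'   exponent convention used in parts of the electromagnetics literature.
#' @examples
#' dielectric_params("cole_cole", eps_s = 100, eps_inf = 10, tau = 1e-6, alpha = 0.7)
#' @export
dielectric_params <- function(model = c("cole_cole", "debye", "cole_davidson",
                                        "havriliak_negami"),
                              eps_s, eps_inf, tau, alpha = 1, beta = 1) {
  model <- match.arg(model)
  stopifnot(is.numeric(eps_s), length(eps_s) == 1L, is.finite(eps_s),
            is.numeric(eps_inf), length(eps_inf) == 1L, is.finite(eps_inf),
            is.numeric(tau), length(tau) == 1L, is.finite(tau),
            is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(beta), length(beta) == 1L, is.finite(beta))
  if (!(eps_inf >= 0 && eps_s > eps_inf))
    stop("require eps_s > eps_inf >= 0", call. = FALSE)
  if (tau <= 0) stop("require tau > 0", call. = FALSE)
  if (!(alpha > 0 && alpha <= 1)) stop("require 0 < alpha <= 1", call. = FALSE)
  if (!(beta > 0 && beta <= 1)) stop("require 0 < beta <= 1", call. = FALSE)
  if (model == "debye" && (alpha != 1 || beta != 1))
    stop("debye model requires alpha = 1 and beta = 1", call. = FALSE)
  if (model == "cole_cole" && beta != 1)
    stop("cole_cole model requires beta = 1", call. = FALSE)
  if (model == "cole_davidson" && alpha != 1)
    stop("cole_davidson model requires alpha = 1", call. = FALSE)
  structure(list(model = model, eps_s = eps_s, eps_inf = eps_inf,
                 tau = tau, alpha = alpha, beta = beta),
            class = "dielectric_params")
}

#' @export
print.dielectric_params <- function(x, ...) {
  cat(sprintf("<dielectric_params: %s>\n", x$model))
  cat(sprintf("  eps_s = %g, eps_inf = %g, tau = %g s, alpha = %g, beta = %g\n",
              x$eps_s, x$eps_inf, x$tau, x$alpha, x$beta))
  invisible(x)
}

#' Convert the electromagnetics exponent convention
#'
#' Some of the electromagnetics literature writes the Cole-Cole exponent as
#' \eqn{1 - \alpha'} so that \eqn{\alpha' = 0} is the Debye model. This helper
#' converts to the convention used throughout this package, where the exponent
#' is \eqn{\alpha = 1 - \alpha'} and \eqn{\alpha = 1} is Debye.
#'
#' @param alpha_prime exponent in the primed convention, in \eqn{[0, 1)}.
#' @return \eqn{\alpha = 1 - \alpha'}.
#' @export
alpha_from_em_convention <- function(alpha_prime) {
  stopifnot(is.numeric(alpha_prime), all(alpha_prime >= 0 & alpha_prime < 1))
  1 - alpha_prime
}

#' Parallel-plate measurement cell geometry
#'
#' @param area plate area in m^2, \eqn{> 0}.
#' @param distance plate spacing in m, \eqn{> 0}.
#' @return An object of class \code{"cell_geometry"} with the fixed vacuum
#'   permittivity [eps0] attached.
#' @examples
#' cell_geometry(area = 1e-4, distance = 1e-3)
#' @export
cell_geometry <- function(area, distance) {
  stopifnot(is.numeric(area), length(area) == 1L, is.finite(area),
            is.numeric(distance), length(distance) == 1L, is.finite(distance))
  if (area <= 0) stop("require area > 0", call. = FALSE)
  if (distance <= 0) stop("require distance > 0", call. = FALSE)
  structure(list(area = area, distance = distance, eps0 = eps0),
            class = "cell_geometry")
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf("<cell_geometry: A = %g m^2, d = %g m>\n", x$area, x$distance))
  invisible(x)
}

# internal: validate a positive, strictly increasing grid
check_grid <- function(x, name, allow_zero = FALSE) {
  if (!is.numeric(x) || length(x) < 1L || anyNA(x) || any(!is.finite(x)))
    stop(sprintf("%s must be a finite numeric vector", name), call. = FALSE)
  if (allow_zero) {
    if (any(x < 0)) stop(sprintf("%s must be >= 0", name), call. = FALSE)
  } else if (any(x <= 0)) stop(sprintf("%s must be > 0", name), call. = FALSE)
  if (length(x) > 1L && any(diff(x) <= 0))
    stop(sprintf("%s must be strictly increasing", name), call. = FALSE)
  x
}

#' Logarithmically spaced grid
#'
#' Convenience constructor for the log-spaced frequency and time grids used
#' throughout: power-law responses are resolved far better per point on a
#' geometric grid than on a linear one.
#'
#' @param from,to positive endpoints.
#' @param n total number of points (default 200).
#' @return strictly increasing numeric vector of length \code{n}.
#' @export
log_grid <- function(from, to, n = 200L) {
  stopifnot(from > 0, to > from, n >= 2L)
  exp(seq(log(from), log(to), length.out = n))
}
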