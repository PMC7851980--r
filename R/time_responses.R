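#' Debye response function
#'
#' \eqn{\varphi(t) = (1/\tau) e^{-t/\tau}}: the inverse transform of the
#' normalized Debye permittivity, i.e. the shape of the current tail after a
#' voltage step.
#'
#' @param tau relaxation time, s.
#' @param t times, s, \eqn{\ge 0}.
#' @return numeric vector of \eqn{\varphi(t)} in 1/s.
#' @export
debye_response_function <- function(tau, t) {
  stopifnot(tau > 0, is.numeric(t), all(t >= 0))
  exp(-t / tau) / tau
}

#' Debye relaxation function
#'
#' \eqn{\psi(t) = e^{-t/\tau}}, the normalized approach of the stored charge
#' to its static value (decreasing from 1 to 0).
#'
#' @inheritParams debye_response_function
#' @return numeric vector of \eqn{\psi(t)} (dimensionless).
#' @export
debye_relaxation_function <- function(tau, t) {
  stopifnot(tau > 0, is.numeric(t), all(t >= 0))
  exp(-t / tau)
}

# accept debye as the alpha = 1 special case of cole_cole for time responses
check_cc_params <- function(params) {
  stopifnot(inherits(params, "dielectric_params"))
  if (!params$model %in% c("cole_cole", "debye"))
    stop("closed-form time responses exist only for the debye and cole_cole ",
         "models; use invert_normalized_model() for the others", call. = FALSE)
  invisible(params)
}

#' Cole-Cole response function
#'
#' \eqn{\varphi_{CC}(t) = (1/\tau)(t/\tau)^{\alpha-1}
#' E_{\alpha,\alpha}(-(t/\tau)^\alpha)}. Positive and strictly decreasing; for
#' \eqn{\alpha < 1} it has an integrable \eqn{t^{\alpha-1}} singularity at the
#' origin, so \eqn{t = 0} is rejected in that case. At \eqn{\alpha = 1} it
#' reduces exactly to the Debye exponential.
#'
#' @param params [dielectric_params()] of the \code{"cole_cole"} (or
#'   \code{"debye"}) family.
#' @param t times, s; strictly positive when \eqn{\alpha < 1}.
#' @return numeric vector of \eqn{\varphi(t)} in 1/s.
#' @export
cc_response_function <- function(params, t) {
  check_cc_params(params)
  stopifnot(is.numeric(t))
  if (params$alpha < 1 && any(t <= 0))
    stop("cc_response_function: t must be > 0 for alpha < 1 (integrable ",
         "singularity at t = 0)", call. = FALSE)
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  u <- (t / params$tau)^params$alpha
  (t / params$tau)^(params$alpha - 1) *
    mittag_leffler(params$alpha, params$alpha, u) / params$tau
}

#' Cole-Cole relaxation function
#'
#' \eqn{\psi_{CC}(t) = E_\alpha(-(t/\tau)^\alpha)}; completely monotone,
#' \eqn{\psi(0) = 1}.
#'
#' @inheritParams cc_response_function
#' @param t times, s, \eqn{\ge 0}.
#' @return numeric vector (dimensionless).
#' @export
cc_relaxation_function <- function(params, t) {
  check_cc_params(params)
  stopifnot(is.numeric(t), all(t >= 0))
  mittag_leffler(params$alpha, 1, (t / params$tau)^params$alpha)
}

# |Gamma(-alpha)| for 0 < alpha < 1 via the reflection formula, avoiding the
# pole-adjacent cancellation of a direct gamma() call
abs_gamma_neg <- function(alpha) {
  pi / (sinpi(alpha) * gamma(1 + alpha))
}

#' Power-law asymptotes of the Cole-Cole response function
#'
#' The small-time branch is the Curie-von Schweidler law
#' \eqn{\varphi \sim (1/\tau)(t/\tau)^{\alpha-1}/\Gamma(\alpha)} (a
#' \eqn{t^{-\alpha'}} current with \eqn{\alpha' = 1-\alpha}); the large-time
#' branch is the algebraic tail
#' \eqn{\varphi \sim (1/\tau)(t/\tau)^{-\alpha-1}/|\Gamma(-\alpha)|}. Since
#' \eqn{\Gamma(-\alpha) < 0} for \eqn{0 < \alpha < 1} while \eqn{\varphi > 0},
#' the positive magnitude is returned, with \eqn{|\Gamma(-\alpha)|} evaluated
#' through the reflection formula. The Debye model (\eqn{\alpha = 1}) has no
#' power-law tail (\eqn{\Gamma(-1)} pole), so the large-time branch is
#' rejected there.
#'
#' @inheritParams cc_response_function
#' @param branch \code{"small_time"} or \code{"large_time"}.
#' @return numeric vector in 1/s.
#' @export
response_asymptote <- function(params, t, branch = c("small_time", "large_time")) {
  check_cc_params(params)
  branch <- match.arg(branch)
  stopifnot(is.numeric(t), all(t > 0))
  u <- t / params$tau
  a <- params$alpha
  if (branch == "small_time") {
    u^(a - 1) / (gamma(a) * params$tau)
  } else {
    if (a == 1)
      stop("large_time response asymptote undefined at alpha = 1 (Gamma(-1) ",
           "pole): the Debye model has an exponential, not power-law, tail",
           call. = FALSE)
    u^(-a - 1) / (abs_gamma_neg(a) * params$tau)
  }
}

#' Asymptotes of the Cole-Cole relaxation function
#'
#' The small-time branch is the Kohlrausch-Williams-Watts stretched
#' exponential \eqn{\exp[-(t/\tau)^\alpha/\Gamma(1+\alpha)]}; the large-time
#' branch is the power law \eqn{(t/\tau)^{-\alpha}/\Gamma(1-\alpha)}.
#'
#' @inheritParams response_asymptote
#' @return numeric vector (dimensionless).
#' @export
relaxation_asymptote <- function(params, t, branch = c("small_time", "large_time")) {
  check_cc_params(params)
  branch <- match.arg(branch)
  stopifnot(is.numeric(t), all(t >= 0))
  u <- t / params$tau
  a <- params$alpha
  if (branch == "small_time") {
    exp(-u^a / gamma(1 + a))
  } else {
    if (any(t == 0))
      stop("large_time relaxation asymptote diverges at t = 0", call. = FALSE)
    # rgamma_recip handles alpha = 1 (Gamma(0) pole) by returning exactly 0:
    # the exponential has no power-law tail
    u^(-a) * rgamma_recip(1 - a)
  }
}

#' Kohlrausch (stretched-exponential) parameters matching a Cole-Cole model
#'
#' Matching \eqn{\exp[-(t/\tau)^\alpha/\Gamma(1+\alpha)]} with the stretched
#' exponential \eqn{\exp[-(t/\tau^*)^\alpha]} gives
#' \eqn{\tau^* = \tau\,\Gamma(1+\alpha)^{1/\alpha}}. At \eqn{\alpha = 1},
#' \eqn{\tau^* = \tau}.
#'
#' @inheritParams cc_response_function
#' @return an object of class \code{"kww_params"}: list with \code{tau_star}
#'   (s) and \code{alpha}.
#' @export
kww_from_cole <- function(params) {
  check_cc_params(params)
  structure(list(tau_star = params$tau * gamma(1 + params$alpha)^(1 / params$alpha),
                 alpha = params$alpha),
            class = "kww_params")
}

#' @export
print.kww_params <- function(x, ...) {
  cat(sprintf("<kww_params: tau_star = %g s, alpha = %g>\n", x$tau_star, x$alpha))
  invisible(x)
}

#' Crossover time of the two asymptote branches
#'
#' Locates the intersection of the small- and large-time asymptotes. For the
#' response function the crossing is closed-form:
#' \eqn{t/\tau = (\Gamma(\alpha)/|\Gamma(-\alpha)|)^{1/(2\alpha)}}. For the
#' relaxation function the equation
#' \eqn{\exp[-(t/\tau)^\alpha/\Gamma(1+\alpha)] = (t/\tau)^{-\alpha}/\Gamma(1-\alpha)}
#' is solved by a bracketed root search on \eqn{t/\tau \in [10^{-6}, 10^{6}]}
#' to relative tolerance 1e-10.
#'
#' @inheritParams cc_response_function
#' @param which \code{"response"} or \code{"relaxation"}.
#' @return crossover time in seconds.
#' @export
asymptote_crossover_time <- function(params, which = c("response", "relaxation")) {
  check_cc_params(params)
  which <- match.arg(which)
  a <- params$alpha
  if (!(a > 0 && a < 1))
    stop("asymptote crossover defined only for 0 < alpha < 1", call. = FALSE)
  if (which == "response") {
    params$tau * (gamma(a) / abs_gamma_neg(a))^(1 / (2 * a))
  } else {
    # log-difference of the two branches; roots are branch intersections.
    # The branches need not intersect at all (for alpha near 0.7 the KWW
    # branch stays just below the power-law branch), in which case a
    # no-bracket error is raised.
    g <- function(u) -u^a / gamma(1 + a) + a * log(u) + log(gamma(1 - a))
    u <- 10^seq(-6, 6, length.out = 961L)
    gv <- g(u)
    ix <- which(diff(sign(gv)) != 0)
    if (!length(ix))
      stop("relaxation asymptote branches do not cross in [1e-6, 1e6] tau ",
           "for alpha = ", a, call. = FALSE)
    roots <- vapply(ix, function(i)
      stats::uniroot(g, c(u[i], u[i + 1]), tol = 1e-10)$root, numeric(1))
    params$tau * roots[which.min(abs(log(roots)))]
  }
}

#' Step-voltage current response in the time domain
#'
#' For a unit voltage step the current is an impulse
#' \eqn{\varepsilon_0 (A/d)\varepsilon_\infty\,\delta(t)} (instantaneous
#' charging of the high-frequency capacitance) followed by the tail
#' \eqn{\varepsilon_0 (A/d)(\varepsilon_s-\varepsilon_\infty)\,\varphi(t)}.
#' The delta cannot be sampled, so the result carries the impulse weight (in
#' coulombs) separately from the sampled tail (in amperes).
#'
#' @inheritParams cc_response_function
#' @param geometry a [cell_geometry()].
#' @return An object of class \code{"step_current_response"}: list with
#'   \code{impulse_weight} (C), \code{t} (s), \code{tail} (A), and the
#'   generating \code{params} and \code{geometry}.
#' @export
assemble_step_current <- function(params, geometry, t) {
  check_cc_params(params)
  stopifnot(inherits(geometry, "cell_geometry"))
  scale <- geometry$eps0 * geometry$area / geometry$distance
  tail <- scale * (params$eps_s - params$eps_inf) *
    cc_response_function(params, t)
  structure(list(impulse_weight = scale * params$eps_inf,
                 t = t, tail = tail,
                 params = params, geometry = geometry),
            class = "step_current_response")
}

#' @export
print.step_current_response <- function(x, ...) {
  cat(sprintf("<step_current_response: impulse %g C + %d tail samples>\n",
              x$impulse_weight, length(x$t)))
  invisible(x)
}

#' Step-voltage charge response in the time domain
#'
#' Surface charge density for a unit voltage step,
#' \eqn{Q_{step}(t) = (\varepsilon_0/d)[\varepsilon_s -
#' (\varepsilon_s-\varepsilon_\infty)\,\psi(t)]} in C/m^2. It starts at
#' \eqn{(\varepsilon_0/d)\varepsilon_\infty} (the integrated impulse) and
#' rises monotonically to \eqn{(\varepsilon_0/d)\varepsilon_s}. The
#' integration constant that fixes the initial value is
#' \eqn{K = \varepsilon_s - \varepsilon_\infty} (in units of
#' \eqn{\varepsilon_0/d} per volt).
#'
#' @inheritParams assemble_step_current
#' @param t times, s, \eqn{\ge 0} (t = 0 allowed).
#' @return An object of class \code{"step_charge_response"}: list with
#'   \code{t}, \code{values} (C/m^2), \code{integration_constant}, and the
#'   generating \code{params} and \code{geometry}.
#' @export
assemble_step_charge <- function(params, geometry, t) {
  check_cc_params(params)
  stopifnot(inherits(geometry, "cell_geometry"), is.numeric(t), all(t >= 0))
  psi <- cc_relaxation_function(params, t)
  vals <- geometry$eps0 / geometry$distance *
    (params$eps_s - (params$eps_s - params$eps_inf) * psi)
  structure(list(t = t, values = vals,
                 integration_constant = params$eps_s - params$eps_inf,
                 params = params, geometry = geometry),
            class = "step_charge_response")
}

#' @export
print.step_charge_response <- function(x, ...) {
  cat(sprintf("<step_charge_response: %d samples, Q(0) = %g C/m^2>\n",
              length(x$t), x$values[1]))
  invisible(x)
}

#' Write / read the time-series CSV interchange format
#'
#' Header \code{t_s,value,quantity}; numbers at 17 significant digits. A step
#' current response additionally writes its delta-function weight as a
#' \code{# impulse_weight_C=<value>} comment line (the impulse is metadata,
#' never a sample).
#'
#' @param t,value,quantity columns to write (recycled quantity tag).
#' @param path file path.
#' @param impulse_weight optional impulse weight in coulombs, written as a
#'   comment line.
#' @return \code{write_timeseries_csv} returns \code{path} invisibly;
#'   \code{read_timeseries_csv} returns a data frame with the comment (if any)
#'   in attribute \code{"impulse_weight_C"}.
#' @export
write_timeseries_csv <- function(t, value, quantity, path, impulse_weight = NULL) {
  header <- "t_s,value,quantity"
  lines <- sprintf("%.17g,%.17g,%s", t, value, quantity)
  pre <- if (!is.null(impulse_weight))
    sprintf("# impulse_weight_C=%.17g", impulse_weight)
  writeLines(c(pre, header, lines), path)
  invisible(path)
}

#' @rdname write_timeseries_csv
#' @export
read_timeseries_csv <- function(path) {
  first <- readLines(path, n = 1L)
  iw <- NULL
  if (startsWith(first, "# impulse_weight_C="))
    iw <- as.numeric(sub("# impulse_weight_C=", "", first, fixed = TRUE))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("t_s", "value", "quantity") %in% names(df)))
    stop("malformed time-series CSV: expected header t_s,value,quantity",
         call. = FALSE)
  attr(df, "impulse_weight_C") <- iw
  df
}
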