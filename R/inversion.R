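#' Numerical inverse Laplace transform (fixed Talbot contour)
#'
#' Abate-Valko fixed-Talbot rule: the Bromwich integral is deformed onto the
#' contour \eqn{s(\theta) = r\theta(\cot\theta + i)} with \eqn{r = 2M/(5t)}
#' and evaluated with the midpoint rule in \eqn{\theta}. Accuracy grows with
#' \eqn{M} until double-precision rounding (amplified by \eqn{e^{rt} =
#' e^{2M/5}}) takes over, so \eqn{M} in the 20-50 range is the useful window.
#'
#' @param Fs vectorized function of a complex Laplace variable.
#' @param t positive time(s) at which to invert.
#' @param M number of contour nodes (default 24).
#' @return numeric vector \eqn{f(t)}.
#' @export
invlap_talbot <- function(Fs, t, M = 24L) {
  stopifnot(all(t > 0), M >= 8L)
  vapply(t, function(ti) {
    r <- 2 * M / (5 * ti)
    k <- seq_len(M - 1L)
    th <- k * pi / M
    ct <- cos(th) / sin(th)
    s <- r * th * (ct + 1i)
    sig <- th + (th * ct - 1) * ct
    terms <- Re(exp(ti * s) * Fs(s) * (1 + 1i * sig))
    (r / M) * (0.5 * Re(Fs(r + 0i)) * exp(r * ti) + sum(terms))
  }, numeric(1))
}

#' Numerical inverse Laplace transform (Fourier series with epsilon acceleration)
#'
#' Trapezoidal discretization of the Bromwich integral (Durbin's Fourier-series
#' form) on the line \eqn{\mathrm{Re}\,s = \gamma},
#' \deqn{f(t) \approx \frac{e^{\gamma t}}{T}\Big[\tfrac12 F(\gamma) +
#'  \sum_{k\ge1} \mathrm{Re}\big(F(\gamma + ik\pi/T)\,e^{ik\pi t/T}\big)\Big],}
#' with \eqn{T = 2t} and \eqn{\gamma = -\ln(\epsilon_a)/(2T)} so the aliasing
#' error is about \eqn{\epsilon_a}. The slowly converging oscillatory series is
#' summed with Wynn's epsilon algorithm applied to its partial sums.
#'
#' @inheritParams invlap_talbot
#' @param M number of series terms (default 64).
#' @param alias_tol aliasing level \eqn{\epsilon_a} (default 1e-10).
#' @return numeric vector \eqn{f(t)}.
#' @export
invlap_fourier <- function(Fs, t, M = 64L, alias_tol = 1e-10) {
  stopifnot(all(t > 0), M >= 8L)
  vapply(t, function(ti) {
    Tp <- 2 * ti
    g <- -log(alias_tol) / (2 * Tp)
    k <- seq_len(M)
    terms <- Fs(g + 1i * k * pi / Tp) * exp(1i * k * pi * ti / Tp)
    S <- 0.5 * Re(Fs(g + 0i)) + cumsum(terms)
    nacc <- min(41L, M)                   # accelerate the tail partial sums
    est <- wynn_epsilon(S[(M - nacc + 1L):M])
    exp(g * ti) / Tp * Re(est)
  }, numeric(1))
}

# Wynn's epsilon algorithm; returns the highest even-column estimate
wynn_epsilon <- function(S) {
  n <- length(S)
  em1 <- rep(0 + 0i, n + 1L)  # epsilon_{-1}
  e0 <- S                     # epsilon_0
  best <- S[n]
  col <- 0L
  while (length(e0) >= 2L) {
    d <- diff(e0)
    d[d == 0] <- 1e-300 + 0i  # guard exact ties
    e1 <- em1[2:(length(e0))] + 1 / d
    em1 <- e0
    e0 <- e1
    col <- col + 1L
    if (col %% 2L == 0L) best <- e0[length(e0)]
  }
  best
}

#' Invert the normalized frequency-domain model numerically
#'
#' Recovers the response function \eqn{\varphi(t)} (inverse transform of the
#' normalized permittivity \eqn{\hat\varepsilon(s) = 1/(1+(s\tau)^\alpha)^\beta})
#' or the relaxation function \eqn{\psi(t)} (inverse transform of
#' \eqn{(1-\hat\varepsilon(s))/s}) by numerical Laplace inversion. The
#' frequency-domain definitions are one-sided Fourier transforms; for these
#' causal completely monotone responses the Laplace inversion with
#' \eqn{s = j\omega} continued to the complex plane is equivalent and far
#' better conditioned — an equivalence the test-suite asserts against the
#' Debye closed form rather than assumes.
#'
#' This is the only time-domain route for the Cole-Davidson and
#' Havriliak-Negami families, which have no elementary closed form, and it is
#' the package's independent cross-check of the Mittag-Leffler based closed
#' forms for Debye and Cole-Cole.
#'
#' @param params a [dielectric_params()] (any of the four families).
#' @param t positive times, s.
#' @param method \code{"talbot_contour"} or \code{"fourier_series"}.
#' @param n_nodes nodes/terms for the chosen method (\eqn{\ge 16}); defaults:
#'   16 for Talbot (doubled to 32, inside the method's accurate window), 64
#'   for the Fourier series.
#' @param target \code{"response_phi"} or \code{"relaxation_psi"}.
#' @param check if \code{TRUE} (default) the inversion is repeated with twice
#'   the nodes and a convergence failure is raised when the two disagree
#'   beyond \code{check_tol}.
#' @param check_tol node-doubling agreement tolerance (relative; default 1e-6).
#' @return numeric vector of \eqn{\varphi(t)} (1/s) or \eqn{\psi(t)}.
#' @export
invert_normalized_model <- function(params, t,
                                    method = c("talbot_contour", "fourier_series"),
                                    n_nodes = NULL,
                                    target = c("response_phi", "relaxation_psi"),
                                    check = TRUE, check_tol = 1e-6) {
  stopifnot(inherits(params, "dielectric_params"), is.numeric(t), all(t > 0))
  method <- match.arg(method)
  target <- match.arg(target)
  if (is.null(n_nodes)) n_nodes <- if (method == "talbot_contour") 16L else 64L
  if (n_nodes < 16L) stop("n_nodes must be >= 16", call. = FALSE)
  epshat <- function(s) (1 + (s * params$tau)^params$alpha)^(-params$beta)
  Fs <- if (target == "response_phi") epshat
        else function(s) (1 - epshat(s)) / s
  run <- function(m) switch(method,
    talbot_contour = invlap_talbot(Fs, t, M = m),
    fourier_series = invlap_fourier(Fs, t, M = m))
  f2 <- run(2L * n_nodes)
  if (check) {
    f1 <- run(n_nodes)
    # additive floor: below ~1e-10 of the curve scale these double-precision
    # methods only deliver absolute, not relative, accuracy (e.g. the
    # exponentially small Debye tail), so agreement there is not demanded
    fl <- 1e-10 * max(abs(f2))
    if (any(abs(f1 - f2) > check_tol * abs(f2) + fl))
      stop("invert_normalized_model: node doubling changed the result beyond ",
           "check_tol; inversion did not converge", call. = FALSE)
  }
  f2
}

#' Complete-monotonicity check by repeated divided differences
#'
#' A completely monotone function (a continuous mixture of decaying
#' exponentials, the signature of a physically realizable relaxation) is
#' nonnegative with derivatives alternating in sign: \eqn{f \ge 0},
#' \eqn{f' \le 0}, \eqn{f'' \ge 0}, ... The check estimates derivatives 0
#' through \code{n_orders} by m-th divided differences over sliding windows of
#' the supplied grid (by the mean value theorem each divided difference has
#' the sign of \eqn{f^{(m)}/m!} somewhere in its window) and asserts the sign
#' pattern \eqn{(-1)^m f^{(m)} \ge 0} up to a rounding-noise floor propagated
#' through the same recursion. A warning is emitted if differencing leaves
#' fewer than ~8 significant digits at some order.
#'
#' @param f function of one positive argument, vectorized.
#' @param t_grid strictly increasing positive grid (a log grid is natural for
#'   relaxation kernels).
#' @param n_orders highest derivative order to test, at most 4.
#' @return An object of class \code{"cm_check"}: data frame with one row per
#'   order (\code{order}, \code{min_signed} worst-case signed margin,
#'   \code{noise} floor, \code{pass}) plus attribute \code{"pass"} for the
#'   overall verdict.
#' @examples
#' r <- complete_monotonicity_check(function(t) exp(-t), log_grid(0.01, 100, 80))
#' attr(r, "pass")
#' @export
complete_monotonicity_check <- function(f, t_grid, n_orders = 4L) {
  stopifnot(is.function(f), n_orders >= 1L, n_orders <= 4L)
  t_grid <- check_grid(t_grid, "t_grid")
  if (length(t_grid) < n_orders + 4L) stop("t_grid too short", call. = FALSE)
  fv <- f(t_grid)
  if (anyNA(fv) || any(!is.finite(fv)))
    stop("f returned non-finite values on the grid", call. = FALSE)
  scale <- max(abs(fv))
  out <- data.frame(order = 0:n_orders, min_signed = NA_real_,
                    noise = NA_real_, pass = NA)
  warn_noise <- FALSE
  d <- fv
  nz <- rep(.Machine$double.eps * scale, length(fv))
  for (m in 0:n_orders) {
    if (m > 0) {
      gaps <- t_grid[(1 + m):length(t_grid)] - t_grid[1:(length(t_grid) - m)]
      d <- diff(d) / gaps
      nz <- (nz[-1] + nz[-length(nz)]) / gaps
    }
    signed <- (-1)^m * d
    floor_m <- 8 * max(nz)
    out$min_signed[m + 1] <- min(signed)
    out$noise[m + 1] <- floor_m
    out$pass[m + 1] <- all(signed >= -floor_m)
    if (max(abs(d)) > 0 && max(nz) > 1e-8 * max(abs(d))) warn_noise <- TRUE
  }
  if (warn_noise)
    warning("complete_monotonicity_check: differencing lost more than 8 ",
            "significant digits at some order; margins are noise-limited",
            call. = FALSE)
  structure(out, class = c("cm_check", "data.frame"), pass = all(out$pass))
}

#' @export
print.cm_check <- function(x, ...) {
  cat(sprintf("<cm_check: overall %s>\n",
              if (attr(x, "pass")) "PASS" else "FAIL"))
  print.data.frame(x)
  invisible(x)
}
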