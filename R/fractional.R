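#' Grunwald-Letnikov fractional derivative on a uniform grid
#'
#' Discrete fractional derivative of order \eqn{\alpha \in (0, 1]},
#' \deqn{D^\alpha f(t_n) \approx h^{-\alpha} \sum_{k=0}^{n} w_k f(t_{n-k}),}
#' with binomial weights \eqn{w_0 = 1},
#' \eqn{w_k = w_{k-1}\,(1 - (\alpha+1)/k)}. The scheme assumes \eqn{f = 0}
#' before the first sample, reduces to the backward first difference at
#' \eqn{\alpha = 1}, and is first-order accurate in \eqn{h}. The causal
#' convolution is evaluated with an FFT, so long records stay cheap.
#'
#' @param f samples on a uniform grid.
#' @param order fractional order in \eqn{(0, 1]}.
#' @param h grid step, s.
#' @return numeric vector of the same length as \code{f}.
#' @export
gl_fractional_derivative <- function(f, order, h) {
  stopifnot(is.numeric(f), length(f) >= 2L, is.numeric(h), h > 0)
  if (!(is.numeric(order) && length(order) == 1L && order > 0 && order <= 1))
    stop("gl_fractional_derivative: require order in (0, 1]", call. = FALSE)
  n <- length(f)
  w <- gl_weights(order, n)
  h^(-order) * causal_convolve(w, f)
}

# w_0 = 1, w_k = w_{k-1} * (1 - (order + 1)/k): the (-1)^k binomial(order, k)
gl_weights <- function(order, n) {
  if (n == 1L) return(1)
  cumprod(c(1, 1 - (order + 1) / seq_len(n - 1L)))
}

# first n terms of the causal (one-sided) convolution of two equal-length
# vectors, via zero-padded FFT
causal_convolve <- function(w, f) {
  n <- length(f)
  m <- stats::nextn(2L * n)
  wf <- stats::fft(c(w, rep(0, m - n)))
  ff <- stats::fft(c(f, rep(0, m - n)))
  Re(stats::fft(wf * ff, inverse = TRUE))[seq_len(n)] / m
}

#' Caputo-consistent fractional derivative
#'
#' The Grunwald-Letnikov derivative applied to \eqn{f - f(t_1)}: the standard
#' correction that makes the discrete operator consistent with the Caputo
#' derivative for functions with a nonzero initial value, so that a constant
#' differentiates to zero and step responses with \eqn{\psi(0) = 1} carry no
#' spurious singular boundary term.
#'
#' @inheritParams gl_fractional_derivative
#' @return numeric vector of the same length as \code{f}.
#' @export
caputo_derivative <- function(f, order, h) {
  gl_fractional_derivative(f - f[1L], order, h)
}

#' Electric and displacement fields for a unit step in E
#'
#' Builds the field pair of the constitutive relation \eqn{D = \varepsilon_0
#' \varepsilon_r E}: a unit electric-field step \eqn{E(t) = 1} V/m for
#' \eqn{t \ge 0} and the resulting displacement (charge density)
#' \eqn{D(t) = \varepsilon_0[\varepsilon_s -
#' (\varepsilon_s-\varepsilon_\infty)\psi(t)]}, which rises from
#' \eqn{\varepsilon_0 \varepsilon_\infty} at \eqn{t = 0^+} to
#' \eqn{\varepsilon_0 \varepsilon_s}.
#'
#' @inheritParams cc_response_function
#' @param t uniform time grid, s (uniformity checked to 1e-12 relative).
#' @return An object of class \code{"field_pair"}: list with \code{t},
#'   \code{E} (V/m), \code{D} (C/m^2), step \code{h} and \code{params}.
#' @export
fields_from_step <- function(params, t) {
  check_cc_params(params)
  stopifnot(is.numeric(t), length(t) >= 8L)
  h <- check_uniform(t)
  psi <- cc_relaxation_function(params, t)
  D <- eps0 * (params$eps_s - (params$eps_s - params$eps_inf) * psi)
  structure(list(t = t, E = rep(1, length(t)), D = D, h = h, params = params),
            class = "field_pair")
}

check_uniform <- function(t) {
  d <- diff(t)
  h <- d[1L]
  # 1e-12 relative, floored at a few ulps of the largest time: consecutive
  # differences of an exactly uniform grid already jitter by that much
  tol <- max(1e-12 * h, 4 * .Machine$double.eps * max(abs(t)))
  if (h <= 0 || any(abs(d - h) > tol))
    stop("grid must be uniform (within 1e-12 relative)", call. = FALSE)
  h
}

#' Residual of the (fractional) Zener constitutive law
#'
#' Checks how well a field pair satisfies
#' \deqn{D(t) + \tau^\alpha \frac{d^\alpha D}{dt^\alpha} =
#'   \varepsilon_0 \varepsilon_s E(t) +
#'   \tau^\alpha \varepsilon_0 \varepsilon_\infty \frac{d^\alpha E}{dt^\alpha},}
#' the Cole-Cole generalization of the standard linear solid (Zener) model,
#' using the Caputo-consistent discrete derivative. At \eqn{\alpha = 1} this is
#' the ordinary first-order Zener equation of the Debye model. The residual is
#' normalized by \eqn{\varepsilon_0 \varepsilon_s} so reports are dimensionless
#' and comparable across parameter sets; for fields that satisfy the law it
#' vanishes at first order as \eqn{h \to 0}.
#'
#' @param pair a [fields_from_step()] result (or a compatible list with
#'   uniform \code{t}, \code{E}, \code{D}).
#' @param params a [dielectric_params()].
#' @param burn_in number of initial samples excluded from the residual norms;
#'   the one-sided startup error of the discrete operator dominates there.
#'   Default 32.
#' @param window optional numeric length-2 time window \code{c(t_lo, t_hi)}
#'   retained for the norms (applied after \code{burn_in}).
#' @return An object of class \code{"zener_residual"}: list with
#'   \code{max_rel}, \code{rms_rel}, \code{n_used}, \code{h} and the raw
#'   \code{residual} samples (normalized).
#' @export
constitutive_residual <- function(pair, params, burn_in = 32L, window = NULL) {
  stopifnot(inherits(params, "dielectric_params"),
            is.list(pair), !is.null(pair$t), !is.null(pair$E), !is.null(pair$D))
  h <- check_uniform(pair$t)
  n <- length(pair$t)
  if (n <= burn_in + 8L) stop("grid too short for the requested burn-in",
                              call. = FALSE)
  a <- params$alpha
  ta <- params$tau^a
  dD <- caputo_derivative(pair$D, a, h)
  dE <- caputo_derivative(pair$E, a, h)
  r <- (pair$D + ta * dD) - (eps0 * params$eps_s * pair$E +
                               ta * eps0 * params$eps_inf * dE)
  keep <- seq_len(n) > burn_in
  if (!is.null(window)) keep <- keep & pair$t >= window[1] & pair$t <= window[2]
  if (sum(keep) < 8L) stop("retained window too short", call. = FALSE)
  rn <- r[keep] / (eps0 * params$eps_s)
  structure(list(max_rel = max(abs(rn)), rms_rel = sqrt(mean(rn^2)),
                 n_used = sum(keep), h = h, residual = rn),
            class = "zener_residual")
}

#' @export
print.zener_residual <- function(x, ...) {
  cat(sprintf("<zener_residual: max %.3e, rms %.3e over %d samples (h = %g s)>\n",
              x$max_rel, x$rms_rel, x$n_used, x$h))
  invisible(x)
}
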