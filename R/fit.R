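#' Noise model for synthetic data
#'
#' @param kind \code{"proportional_gaussian"} (component standard deviation
#'   \eqn{\sigma|\varepsilon(\omega)|/\sqrt2}, so the RMS magnitude of the
#'   complex perturbation is \eqn{\sigma|\varepsilon|}) or
#'   \code{"additive_gaussian"} (component standard deviation \eqn{\sigma} in
#'   data units).
#' @param sigma nonnegative noise level (dimensionless for proportional).
#' @param seed integer RNG seed; the generator is R's default Mersenne
#'   twister, and replicate \code{r} of a Monte-Carlo run uses
#'   \code{seed + r}.
#' @return An object of class \code{"noise_model"}.
#' @export
noise_model <- function(kind = c("proportional_gaussian", "additive_gaussian"),
                        sigma, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma >= 0,
            is.numeric(seed), length(seed) == 1L, is.finite(seed))
  structure(list(kind = kind, sigma = sigma, seed = as.integer(seed)),
            class = "noise_model")
}

# run expr with a private, seeded RNG stream; global .Random.seed untouched
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Synthetic complex permittivity spectrum
#'
#' The exact model spectrum plus independent Gaussian noise on the real and
#' imaginary parts; deterministic given the seed in \code{noise}.
#'
#' @inheritParams permittivity
#' @param noise a [noise_model()]; \code{sigma = 0} returns the exact spectrum.
#' @return a [complex_spectrum()] with quantity \code{"relative_permittivity"}.
#' @export
synth_spectrum <- function(params, omega, noise = noise_model(sigma = 0)) {
  stopifnot(inherits(noise, "noise_model"))
  eps <- permittivity(params, omega)
  if (noise$sigma == 0) return(eps)
  n <- length(eps$omega)
  sd_comp <- switch(noise$kind,
    proportional_gaussian = noise$sigma * Mod(eps$values) / sqrt(2),
    additive_gaussian = rep(noise$sigma, n))
  vals <- with_seed(noise$seed, {
    eps$values + complex(real = stats::rnorm(n, 0, sd_comp),
                         imaginary = stats::rnorm(n, 0, sd_comp))
  })
  complex_spectrum(eps$omega, vals, "relative_permittivity")
}

#' Synthetic relaxation record
#'
#' Samples of the relaxation function \eqn{\psi(t)} (a normalized discharge
#' record of the Kohlrausch type) plus Gaussian noise; deterministic given the
#' seed.
#'
#' @inheritParams cc_response_function
#' @param noise a [noise_model()]; for \code{"proportional_gaussian"} the
#'   standard deviation is \eqn{\sigma|\psi(t)|}.
#' @return data frame with columns \code{t} and \code{value}.
#' @export
synth_relaxation <- function(params, t, noise = noise_model(sigma = 0)) {
  stopifnot(inherits(noise, "noise_model"))
  psi <- cc_relaxation_function(params, t)
  if (noise$sigma > 0) {
    sd_v <- switch(noise$kind,
      proportional_gaussian = noise$sigma * abs(psi),
      additive_gaussian = rep(noise$sigma, length(psi)))
    psi <- with_seed(noise$seed, psi + stats::rnorm(length(psi), 0, sd_v))
  }
  data.frame(t = t, value = psi)
}

#' Fit a dielectric relaxation model
#'
#' The package's central estimator. Fits a model of the Havriliak-Negami
#' family by bounded nonlinear least squares, either to a complex permittivity
#' spectrum (a [complex_spectrum()]; real and imaginary residuals are stacked
#' and minimized jointly, unweighted) or to a normalized relaxation record (a
#' data frame with columns \code{t} and \code{value}, fitted through the
#' Mittag-Leffler relaxation function \eqn{\psi(t;\tau,\alpha)}).
#'
#' Frequency-domain initialization: \eqn{\varepsilon_s} from the low-frequency
#' plateau of \eqn{\mathrm{Re}\,\varepsilon}, \eqn{\varepsilon_\infty} from the
#' high-frequency plateau, \eqn{\tau} from the loss-peak frequency, and
#' \eqn{\alpha} from the Cole-Cole loss-peak height identity
#' \eqn{\max(-\mathrm{Im}\,\varepsilon) = \frac{\Delta\varepsilon}{2}
#' \tan(\alpha\pi/4)}, clipped to \eqn{(0.05, 1]}. Internally \eqn{\tau} is
#' fitted on the log scale and \eqn{\varepsilon_s} through
#' \eqn{\Delta\varepsilon = \varepsilon_s - \varepsilon_\infty > 0}, so the
#' parameter invariants hold by construction; remaining box bounds are
#' enforced by the optimizer.
#'
#' Relaxation-record fits also report the best Kohlrausch stretched-exponential
#' fit \eqn{\exp[-(t/\tau^*)^\alpha]} for comparison (component \code{kww}).
#'
#' When the data span less than one decade of frequency the fit is flagged
#' \code{narrowband} and the parameter uncertainty proxies are typically wide;
#' interpret such fits with caution.
#'
#' @param data a [complex_spectrum()] with quantity
#'   \code{"relative_permittivity"}, or a data frame with columns \code{t} and
#'   \code{value}.
#' @param model model family to fit (see [dielectric_params()]).
#' @param init optional named list of starting values overriding the heuristic
#'   (\code{eps_s}, \code{eps_inf}, \code{tau}, \code{alpha}, \code{beta}).
#' @param bounds optional named list with elements \code{lower} and/or
#'   \code{upper}, each a named numeric vector on the same names as
#'   \code{init}, overriding the default box.
#' @param tau_scale time scale used only to normalize the relaxation-record
#'   \eqn{\tau} search (default: geometric mean of the data times); has no
#'   effect on spectrum fits.
#' @return An object of class \code{"cole_fit"}; see Details. Key fields:
#'   \code{params_hat} (a [dielectric_params()]), \code{residual_rms},
#'   \code{n_iter}, \code{converged}, \code{covariance_proxy} (approximate
#'   standard errors), \code{bounds_hit}, \code{narrowband}, and for
#'   relaxation fits \code{kww}.
#' @seealso [fit_spectrum()], [fit_relaxation()], [synth_spectrum()],
#'   [synth_relaxation()]
#' @examples
#' p <- dielectric_params("cole_cole", 100, 10, 1, alpha = 0.7)
#' sp <- synth_spectrum(p, log_grid(1e-3, 1e3, 50))
#' fit <- cole_fit(sp)
#' coef(fit)
#' @export
cole_fit <- function(data, model = c("cole_cole", "debye", "cole_davidson",
                                     "havriliak_negami"),
                     init = NULL, bounds = NULL, tau_scale = NULL) {
  model <- match.arg(model)
  if (inherits(data, "complex_spectrum"))
    fit_spectrum_impl(data, model, init, bounds)
  else if (is.data.frame(data) && all(c("t", "value") %in% names(data)))
    fit_relaxation_impl(data, model, init, bounds, tau_scale)
  else stop("data must be a complex_spectrum or a data frame with columns ",
            "t and value", call. = FALSE)
}

#' Fit a complex permittivity spectrum
#'
#' Thin wrapper: [cole_fit()] on a [complex_spectrum()].
#' @inheritParams cole_fit
#' @return a \code{"cole_fit"} object.
#' @export
fit_spectrum <- function(data, model = "cole_cole", init = NULL, bounds = NULL) {
  stopifnot(inherits(data, "complex_spectrum"))
  cole_fit(data, model = model, init = init, bounds = bounds)
}

#' Fit a normalized relaxation record
#'
#' Thin wrapper: [cole_fit()] on a data frame of \eqn{(t, \psi)} samples.
#' @inheritParams cole_fit
#' @return a \code{"cole_fit"} object (with a \code{kww} comparison component).
#' @export
fit_relaxation <- function(data, model = "cole_cole", init = NULL,
                           bounds = NULL, tau_scale = NULL) {
  cole_fit(as.data.frame(data), model = model, init = init, bounds = bounds,
           tau_scale = tau_scale)
}

fd_jacobian <- function(resid_fn, th, rel = 1e-6) {
  r0 <- resid_fn(th)
  J <- matrix(0, length(r0), length(th))
  for (j in seq_along(th)) {
    h <- rel * max(abs(th[j]), 1e-3)
    tp <- th; tp[j] <- tp[j] + h
    tm <- th; tm[j] <- tm[j] - h
    J[, j] <- (resid_fn(tp) - resid_fn(tm)) / (2 * h)
  }
  J
}

# which free parameters each family has (on the internal scale)
family_free <- function(model) {
  switch(model,
    debye = c("d_eps", "eps_inf", "log_tau"),
    cole_cole = c("d_eps", "eps_inf", "log_tau", "alpha"),
    cole_davidson = c("d_eps", "eps_inf", "log_tau", "beta"),
    havriliak_negami = c("d_eps", "eps_inf", "log_tau", "alpha", "beta"))
}

theta_to_params <- function(theta, model) {
  a <- if ("alpha" %in% names(theta)) unname(theta["alpha"]) else 1
  b <- if ("beta" %in% names(theta)) unname(theta["beta"]) else 1
  # clamp: finite-difference probes of the optimizer may step one ulp past
  # the box faces, which must not abort a residual evaluation
  dielectric_params(model,
                    eps_s = max(unname(theta["d_eps"]), 1e-12) +
                      max(unname(theta["eps_inf"]), 0),
                    eps_inf = max(unname(theta["eps_inf"]), 0),
                    tau = exp(unname(theta["log_tau"])),
                    alpha = min(max(a, 1e-6), 1),
                    beta = min(max(b, 1e-6), 1))
}

default_box <- function(free) {
  lower <- c(d_eps = 1e-9, eps_inf = 0, log_tau = -60, alpha = 1e-3, beta = 1e-3)
  upper <- c(d_eps = Inf, eps_inf = Inf, log_tau = 60, alpha = 1, beta = 1)
  list(lower = lower[free], upper = upper[free])
}

apply_user_box <- function(box, bounds, free) {
  if (is.null(bounds)) return(box)
  fix <- function(side, vec) {
    if (is.null(vec)) return(box[[side]])
    v <- box[[side]]
    for (nm in names(vec)) {
      tr <- switch(nm, eps_s = NULL, tau = "log_tau", nm)
      if (identical(nm, "tau")) v["log_tau"] <- log(vec[[nm]])
      else if (nm %in% names(v)) v[nm] <- vec[[nm]]
    }
    v
  }
  list(lower = fix("lower", bounds$lower), upper = fix("upper", bounds$upper))
}

spectrum_init <- function(omega, vals, model) {
  re <- Re(vals); im <- -Im(vals)
  eps_s0 <- max(mean(re[seq_len(min(3L, length(re)))]), 1e-6)
  eps_inf0 <- max(mean(re[seq(length(re) - min(2L, length(re) - 1L), length(re))]), 0)
  if (eps_inf0 >= eps_s0) eps_inf0 <- 0.5 * eps_s0
  ipk <- which.max(im)
  tau0 <- 1 / omega[ipk]
  d0 <- eps_s0 - eps_inf0
  a0 <- if (max(im) > 0) (4 / pi) * atan(pmin(2 * max(im) / d0, 50)) else 0.9
  a0 <- min(max(a0, 0.05), 1)
  th <- c(d_eps = d0, eps_inf = eps_inf0, log_tau = log(tau0),
          alpha = a0, beta = min(max(a0, 0.05), 1))
  th[family_free(model)]
}

run_nlslm <- function(resid_fn, theta0, box) {
  ctl <- minpack.lm::nls.lm.control(maxiter = 400, ftol = 1e-15, ptol = 1e-15,
                                    epsfcn = 1e-10)
  # a start pinned exactly on a box face stalls the bounded LM step; nudge in
  lo <- box$lower; up <- box$upper
  span <- ifelse(is.finite(up - lo), up - lo, pmax(1, abs(theta0)))
  theta0 <- pmin(pmax(theta0, lo + ifelse(is.finite(lo), 1e-4 * span, 0)),
                 up - ifelse(is.finite(up), 1e-4 * span, 0))
  ft <- minpack.lm::nls.lm(par = theta0, lower = lo, upper = up,
                           fn = resid_fn, control = ctl)
  # restart from the solution: a fresh trust region routinely polishes the
  # last couple of digits lost to finite-difference Jacobian noise
  start2 <- pmin(pmax(coef(ft), lo + ifelse(is.finite(lo), 1e-8, 0)),
                 up - ifelse(is.finite(up), 1e-8, 0))
  ft2 <- minpack.lm::nls.lm(par = start2, lower = lo, upper = up,
                            fn = resid_fn, control = ctl)
  best <- if (sum(ft2$fvec^2) <= sum(ft$fvec^2)) ft2 else ft
  # an overshooting path can leave an exponent pinned on a box face (one-sided
  # derivative information vanishes there); try once more from a point pulled
  # inward and keep it only on strict improvement
  thb <- coef(best)
  pin <- intersect(names(thb)[(is.finite(up) & abs(thb - up) < 1e-10) |
                                (is.finite(lo) & abs(thb - lo) < 1e-10)],
                   c("alpha", "beta"))
  if (length(pin)) {
    th3 <- thb
    for (nm in pin)
      th3[nm] <- if (abs(thb[nm] - up[nm]) < 1e-10) up[nm] - 0.07
                 else lo[nm] + 0.07
    ft3 <- minpack.lm::nls.lm(par = th3, lower = lo, upper = up,
                              fn = resid_fn, control = ctl)
    if (sum(ft3$fvec^2) < sum(best$fvec^2) * (1 - 1e-10)) best <- ft3
  }
  best
}

fit_spectrum_impl <- function(data, model, init, bounds) {
  if (data$quantity != "relative_permittivity")
    stop("fit expects a relative_permittivity spectrum", call. = FALSE)
  omega <- data$omega[data$omega > 0]
  vals <- data$values[data$omega > 0]
  if (length(unique(omega)) < 2L)
    stop("degenerate data: all frequencies identical", call. = FALSE)
  if (length(omega) < length(family_free(model)) + 1L)
    stop("too few frequencies for the requested model", call. = FALSE)
  free <- family_free(model)
  theta0 <- spectrum_init(omega, vals, model)
  theta0 <- override_init(theta0, init)
  box <- apply_user_box(default_box(free), bounds, free)
  theta0 <- pmin(pmax(theta0, box$lower), box$upper)
  resid_fn <- function(th) {
    p <- theta_to_params(th, model)
    m <- permittivity(p, omega)$values
    c(Re(m) - Re(vals), Im(m) - Im(vals))
  }
  ft <- run_nlslm(resid_fn, theta0, box)
  build_cole_fit(ft, model, box, domain = "frequency",
                 data = list(omega = omega, values = vals),
                 n_resid = 2L * length(omega),
                 narrowband = (max(omega) / min(omega)) < 10,
                 resid_fn = resid_fn)
}

fit_relaxation_impl <- function(data, model, init, bounds, tau_scale) {
  if (!model %in% c("debye", "cole_cole"))
    stop("relaxation-record fits support the debye and cole_cole families",
         call. = FALSE)
  t <- data$t; y <- data$value
  if (any(t <= 0)) stop("relaxation record times must be > 0", call. = FALSE)
  if (length(t) < 4L) stop("too few samples", call. = FALSE)
  if (is.null(tau_scale)) tau_scale <- exp(mean(log(t)))
  free <- setdiff(family_free(model), c("d_eps", "eps_inf"))
  a0 <- 0.8
  theta0 <- c(log_tau = log(tau_scale), alpha = a0)[free]
  theta0 <- override_init(theta0, init)
  box <- apply_user_box(default_box(free), bounds, free)
  theta0 <- pmin(pmax(theta0, box$lower), box$upper)
  # eps_s/eps_inf are irrelevant for the normalized psi; carry neutral values
  mk <- function(th) {
    a <- if ("alpha" %in% names(th)) unname(th["alpha"]) else 1
    a <- min(max(a, 1e-6), 1)   # tolerate FD probes one ulp past the box
    dielectric_params(if (a == 1 && model == "debye") "debye" else "cole_cole",
                      eps_s = 1, eps_inf = 0, tau = exp(unname(th["log_tau"])),
                      alpha = if (model == "debye") 1 else a)
  }
  resid_fn <- function(th) cc_relaxation_function(mk(th), t) - y
  ft <- run_nlslm(resid_fn, theta0, box)
  out <- build_cole_fit(ft, model, box, domain = "time",
                        data = list(t = t, values = y),
                        n_resid = length(t),
                        narrowband = (max(t) / min(t)) < 10,
                        param_builder = mk, resid_fn = resid_fn)
  # companion stretched-exponential (KWW) fit for comparison
  kwwres <- function(th) exp(-(t / exp(th["log_tau_star"]))^th["alpha"]) - y
  kf <- run_nlslm(kwwres, c(log_tau_star = log(tau_scale), alpha = 0.8),
                  list(lower = c(log_tau_star = -60, alpha = 1e-3),
                       upper = c(log_tau_star = 60, alpha = 1)))
  out$kww <- structure(list(tau_star = exp(unname(coef(kf)["log_tau_star"])),
                            alpha = unname(coef(kf)["alpha"])),
                       class = "kww_params")
  out$kww_residual_rms <- sqrt(mean(kf$fvec^2))
  out
}

override_init <- function(theta0, init) {
  if (is.null(init)) return(theta0)
  for (nm in names(init)) {
    v <- init[[nm]]
    if (nm == "tau") theta0["log_tau"] <- log(v)
    else if (nm == "eps_s") {
      if ("eps_inf" %in% names(init)) theta0["d_eps"] <- v - init$eps_inf
      else theta0["d_eps"] <- v - theta0["eps_inf"]
    } else if (nm %in% names(theta0)) theta0[nm] <- v
  }
  theta0
}

build_cole_fit <- function(ft, model, box, domain, data, n_resid,
                           narrowband, param_builder = NULL,
                           resid_fn = NULL) {
  th <- coef(ft)
  params_hat <- if (is.null(param_builder)) theta_to_params(th, model)
                else param_builder(th)
  rss <- sum(ft$fvec^2)
  dof <- max(n_resid - length(th), 1L)
  sig2 <- rss / dof
  jtj <- ft$hessian / 2
  cov_proxy <- tryCatch({
    se <- sqrt(pmax(diag(sig2 * solve(jtj)), 0))
    names(se) <- names(th)
    se
  }, error = function(e) NULL)
  if (is.null(cov_proxy) && !is.null(resid_fn)) {
    # an immediately-converged LM run can return a degenerate hessian;
    # rebuild J'J from a central-difference Jacobian at the solution
    J <- fd_jacobian(resid_fn, th)
    cov_proxy <- tryCatch({
      se <- sqrt(pmax(diag(sig2 * solve(crossprod(J))), 0))
      names(se) <- names(th)
      se
    }, error = function(e) NULL)
  }
  if (is.null(cov_proxy))
    cov_proxy <- stats::setNames(rep(Inf, length(th)), names(th))
  at_bound <- (abs(th - box$lower) < 1e-10 * pmax(abs(th), 1)) |
              (abs(th - box$upper) < 1e-10 * pmax(abs(th), 1))
  # log_tau at its huge default box edge is meaningless; report per parameter
  structure(list(params_hat = params_hat,
                 model = model,
                 theta = th,
                 residual_rms = sqrt(rss / n_resid),
                 n_iter = ft$niter,
                 converged = ft$info %in% 1:4,
                 info = ft$info,
                 message = ft$message,
                 covariance_proxy = cov_proxy,
                 bounds_hit = at_bound,
                 narrowband = narrowband,
                 domain = domain,
                 data = data),
            class = "cole_fit")
}

#' @export
print.cole_fit <- function(x, ...) {
  p <- x$params_hat
  cat(sprintf("Dielectric relaxation fit (%s, %s domain)\n", x$model, x$domain))
  cat(sprintf("  eps_s = %.6g  eps_inf = %.6g  tau = %.6g s  alpha = %.4g  beta = %.4g\n",
              p$eps_s, p$eps_inf, p$tau, p$alpha, p$beta))
  cat(sprintf("  residual RMS %.4g, %d iterations, converged: %s%s\n",
              x$residual_rms, x$n_iter, x$converged,
              if (x$narrowband) "  [narrowband data: < 1 decade]" else ""))
  if (!is.null(x$kww))
    cat(sprintf("  KWW comparison: tau* = %.6g s, alpha = %.4g (RMS %.4g)\n",
                x$kww$tau_star, x$kww$alpha, x$kww_residual_rms))
  invisible(x)
}

#' @export
summary.cole_fit <- function(object, ...) {
  print(object)
  cat("\nInternal parameters (with uncertainty proxy, bound flags):\n")
  print(data.frame(estimate = object$theta,
                   se_proxy = object$covariance_proxy,
                   at_bound = object$bounds_hit))
  invisible(object)
}

#' @export
coef.cole_fit <- function(object, ...) {
  p <- object$params_hat
  c(eps_s = p$eps_s, eps_inf = p$eps_inf, tau = p$tau,
    alpha = p$alpha, beta = p$beta)
}

#' Model predictions from a fit
#'
#' @param object a \code{"cole_fit"}.
#' @param newdata for frequency-domain fits, angular frequencies (rad/s); for
#'   time-domain fits, times (s). Defaults to the fitted grid.
#' @param ... unused.
#' @return complex permittivity values (frequency domain) or \eqn{\psi(t)}
#'   samples (time domain).
#' @export
predict.cole_fit <- function(object, newdata = NULL, ...) {
  if (object$domain == "frequency") {
    om <- if (is.null(newdata)) object$data$omega else newdata
    permittivity(object$params_hat, om)$values
  } else {
    t <- if (is.null(newdata)) object$data$t else newdata
    cc_relaxation_function(object$params_hat, t)
  }
}

#' @export
fitted.cole_fit <- function(object, ...) predict(object)

#' @export
residuals.cole_fit <- function(object, ...) {
  if (object$domain == "frequency") object$data$values - fitted(object)
  else object$data$values - fitted(object)
}

#' Simulate replicate data sets from a fitted model
#'
#' Parametric simulation at the fitted parameters with Gaussian noise matched
#' to the residual RMS, seeded for reproducibility.
#'
#' @param object a \code{"cole_fit"}.
#' @param nsim number of replicates.
#' @param seed integer seed; replicate \code{r} uses \code{seed + r}.
#' @param ... unused.
#' @return a list of [complex_spectrum()] objects (frequency domain) or of
#'   data frames (time domain).
#' @export
simulate.cole_fit <- function(object, nsim = 1, seed = 1L, ...) {
  s <- object$residual_rms
  lapply(seq_len(nsim), function(r) {
    nm <- noise_model("additive_gaussian", sigma = s, seed = seed + r)
    if (object$domain == "frequency")
      synth_spectrum(object$params_hat, object$data$omega, nm)
    else
      synth_relaxation(object$params_hat, object$data$t, nm)
  })
}

#' Plot a dielectric relaxation fit
#'
#' Frequency-domain fits draw the Cole-Cole arc (\eqn{\mathrm{Re}\,\varepsilon}
#' vs the loss \eqn{-\mathrm{Im}\,\varepsilon}) with the fitted curve;
#' time-domain fits draw the relaxation record and fit on log-log axes.
#'
#' @param x a \code{"cole_fit"}.
#' @param ... passed to the base plotting calls.
#' @return \code{x}, invisibly.
#' @export
plot.cole_fit <- function(x, ...) {
  if (x$domain == "frequency") {
    om <- x$data$omega
    fine <- log_grid(min(om), max(om), 400)
    mv <- permittivity(x$params_hat, fine)$values
    graphics::plot(Re(x$data$values), -Im(x$data$values),
                   xlab = expression(Re ~ epsilon[r]),
                   ylab = expression(-Im ~ epsilon[r]),
                   main = sprintf("Cole-Cole arc (%s fit)", x$model), ...)
    graphics::lines(Re(mv), -Im(mv), col = "red3")
  } else {
    graphics::plot(x$data$t, x$data$values, log = "xy",
                   xlab = "t [s]", ylab = expression(psi(t)),
                   main = sprintf("Relaxation record (%s fit)", x$model), ...)
    fine <- log_grid(min(x$data$t), max(x$data$t), 400)
    graphics::lines(fine, cc_relaxation_function(x$params_hat, fine),
                    col = "red3")
  }
  invisible(x)
}

#' Serialize a fit to JSON
#'
#' All scalar fields of the fit (parameters, residual RMS, iteration count,
#' convergence flag, uncertainty proxies, bound flags) in a flat JSON object.
#'
#' @param x a \code{"cole_fit"}.
#' @param path optional file; if omitted the JSON string is returned.
#' @return JSON string (invisibly when written to \code{path}).
#' @export
fit_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "cole_fit"))
  obj <- list(model = x$model, domain = x$domain,
              params = as.list(coef(x)),
              residual_rms = x$residual_rms,
              n_iter = x$n_iter, converged = x$converged,
              covariance_proxy = as.list(x$covariance_proxy),
              bounds_hit = as.list(x$bounds_hit),
              narrowband = x$narrowband)
  if (!is.null(x$kww))
    obj$kww <- list(tau_star = x$kww$tau_star, alpha = x$kww$alpha,
                    residual_rms = x$kww_residual_rms)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
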