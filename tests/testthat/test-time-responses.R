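test_that("Debye response and relaxation functions are the exponentials", {
  expect_equal(debye_response_function(2, 2), exp(-1) / 2, tolerance = 1e-15)
  expect_equal(debye_response_function(2, 0), 0.5, tolerance = 1e-15)
  expect_equal(integrate(function(t) debye_response_function(1, t), 0, 5)$value,
               1 - exp(-5), tolerance = 1e-9)
  expect_identical(debye_relaxation_function(3, 0), 1)
  expect_equal(debye_relaxation_function(3, 3), exp(-1), tolerance = 1e-15)
  expect_equal(debye_relaxation_function(1, 3), exp(-3), tolerance = 1e-15)
})

test_that("Cole-Cole responses reduce to Debye at alpha = 1 within 1e-12", {
  p1 <- dielectric_params("cole_cole", 100, 10, 2, alpha = 1)
  t <- 10^seq(-2, 1.3, by = 0.25) # exp representable throughout
  expect_lt(max(rel_err(cc_response_function(p1, t),
                        debye_response_function(2, t))), 1e-12)
  expect_lt(max(rel_err(cc_relaxation_function(p1, t),
                        debye_relaxation_function(2, t))), 1e-12)
  g <- cell_geometry(1, 1)
  sc <- assemble_step_current(p1, g, t)
  expect_lt(max(rel_err(sc$tail, eps0 * 90 * exp(-t / 2) / 2)), 1e-12)
  qc <- assemble_step_charge(p1, g, t)
  expect_lt(max(rel_err(qc$values, eps0 * (100 - 90 * exp(-t / 2)))), 1e-12)
})

test_that("Cole-Cole response function matches the Mittag-Leffler values", {
  p <- cc_params(tau = 2)
  expect_equal(cc_response_function(p, 2), ml_ref(0.7, 0.7, 1) / 2,
               tolerance = 1e-10)
  expect_error(cc_response_function(p, c(0, 1)), "t must be > 0")
  # small-time behavior approaches the Curie-von Schweidler branch
  expect_lt(rel_err(cc_response_function(p, 2e-4),
                    response_asymptote(p, 2e-4, "small_time")), 5e-3)
  # positive, strictly decreasing
  v <- cc_response_function(p, 10^seq(-3, 3, by = 0.2))
  expect_true(all(v > 0) && all(diff(v) < 0))
})

test_that("Cole-Cole relaxation function matches the Mittag-Leffler values", {
  p <- cc_params()
  expect_identical(cc_relaxation_function(p, 0), 1)
  expect_equal(cc_relaxation_function(p, 1), ml_ref(0.7, 1, 1),
               tolerance = 1e-10)
  p1 <- dielectric_params("cole_cole", 2, 1, 1, alpha = 1)
  expect_equal(cc_relaxation_function(p1, 1), exp(-1), tolerance = 1e-12)
  v <- cc_relaxation_function(p, 10^seq(-3, 3, by = 0.2))
  expect_true(all(v > 0) && all(diff(v) < 0) && all(v <= 1))
})

test_that("response asymptotes evaluate the stated formulas with correct sign", {
  p <- cc_params()
  expect_equal(response_asymptote(p, 0.01, "small_time"),
               0.01^(-0.3) / gamma(0.7), tolerance = 1e-14)
  # Gamma(-alpha) < 0: the returned large-time branch is the positive magnitude
  g_neg <- pi / (sin(pi * 0.7) * gamma(1.7))   # |Gamma(-0.7)| by reflection
  expect_equal(response_asymptote(p, 100, "large_time"),
               100^(-1.7) / g_neg, tolerance = 1e-14)
  expect_gt(response_asymptote(p, 100, "large_time"), 0)
  # alpha = 1 small-time branch is the constant 1/tau; large-time is undefined
  p1 <- dielectric_params("cole_cole", 2, 1, 4, alpha = 1)
  expect_equal(response_asymptote(p1, c(1, 2), "small_time"), c(0.25, 0.25))
  expect_error(response_asymptote(p1, 1, "large_time"), "alpha = 1")
})

test_that("relaxation asymptotes are the KWW and power-law branches", {
  p <- cc_params()
  expect_identical(relaxation_asymptote(p, 0, "small_time"), 1)
  expect_equal(relaxation_asymptote(p, 2, "small_time"),
               exp(-2^0.7 / gamma(1.7)), tolerance = 1e-14)
  # alpha = 1 recovers the exact Debye exponential (Gamma(2) = 1)
  p1 <- dielectric_params("cole_cole", 2, 1, 2, alpha = 1)
  t <- c(0.5, 1, 4)
  expect_equal(relaxation_asymptote(p1, t, "small_time"), exp(-t / 2),
               tolerance = 1e-14)
  expect_equal(relaxation_asymptote(p, 1000, "large_time"),
               1000^(-0.7) / gamma(0.3), tolerance = 1e-14)
})

test_that("KWW time constant matches tau Gamma(1+alpha)^(1/alpha)", {
  expect_equal(kww_from_cole(dielectric_params("cole_cole", 2, 1, 3,
                                               alpha = 1))$tau_star, 3)
  expect_equal(kww_from_cole(cc_params(alpha = 0.5, tau = 2))$tau_star,
               2 * pi / 4, tolerance = 1e-14)
  expect_equal(kww_from_cole(cc_params(tau = 1))$tau_star,
               gamma(1.7)^(1 / 0.7), tolerance = 1e-14)
})

test_that("asymptote crossover times are located correctly", {
  # closed form: alpha = 0.5 gives t = 0.5 tau
  p <- cc_params(alpha = 0.5, tau = 3)
  expect_equal(asymptote_crossover_time(p, "response"), 1.5, tolerance = 1e-12)
  # toward the Debye limit the power-law tail collapses (1/|Gamma(-a)| -> 0),
  # so the branch intersection moves monotonically toward t = 0:
  # t/tau = (Gamma(a)/|Gamma(-a)|)^(1/2a) with a base that vanishes as a -> 1
  expect_lt(asymptote_crossover_time(cc_params(alpha = 0.9), "response"),
            asymptote_crossover_time(cc_params(alpha = 0.5), "response"))
  expect_lt(asymptote_crossover_time(cc_params(alpha = 0.99), "response"),
            asymptote_crossover_time(cc_params(alpha = 0.9), "response"))
  # relaxation branches never cross at alpha = 0.7 (near-tangency): no-bracket
  expect_error(asymptote_crossover_time(cc_params(), "relaxation"),
               "do not cross")
  # at alpha = 0.9 they do; the root satisfies branch equality
  p9 <- cc_params(alpha = 0.9)
  tc <- asymptote_crossover_time(p9, "relaxation")
  expect_lt(rel_err(relaxation_asymptote(p9, tc, "small_time"),
                    relaxation_asymptote(p9, tc, "large_time")), 1e-8)
})

test_that("step current carries the impulse weight separately from the tail", {
  g <- cell_geometry(1, 1)
  p <- debye_params()
  t <- c(0.5, 1, 2)
  sc <- assemble_step_current(p, g, t)
  expect_equal(sc$impulse_weight, eps0)
  expect_equal(sc$tail, eps0 * exp(-t), tolerance = 1e-14)
  expect_true(all(diff(sc$tail) < 0) && all(sc$tail > 0))
  # no dispersion: tail identically ~0
  pf <- dielectric_params("debye", eps_s = 5, eps_inf = 5 - 1e-13, tau = 1)
  expect_lt(max(abs(assemble_step_current(pf, g, t)$tail)), 1e-24)
  # Cole-Cole tail at t = tau against the Mittag-Leffler oracle
  pc <- cc_params()
  expect_equal(assemble_step_current(pc, g, 1)$tail,
               eps0 * 90 * ml_ref(0.7, 0.7, 1), tolerance = 1e-10)
})

test_that("step charge rises from eps_inf to eps_s scaled by eps0/d", {
  g <- cell_geometry(1, 0.5)
  p <- cc_params()
  qc <- assemble_step_charge(p, g, c(0, 1, 1e8))
  expect_equal(qc$values[1], eps0 / 0.5 * 10, tolerance = 1e-12)
  expect_lt(rel_err(qc$values[3], eps0 / 0.5 * 100), 1e-4)
  expect_true(all(diff(qc$values) > 0))
  expect_equal(qc$integration_constant, 90)
  # Debye at t = tau: closed form
  qd <- assemble_step_charge(debye_params(), cell_geometry(1, 1), 1)
  expect_equal(qd$values, eps0 * (2 - exp(-1)), tolerance = 1e-14)
})

test_that("time-series CSV round-trips with the impulse-weight comment", {
  f <- withr::local_tempfile(fileext = ".csv")
  t <- log_grid(1e-2, 1e2, 25)
  v <- cc_response_function(cc_params(), t)
  write_timeseries_csv(t, v, "response_exact", f, impulse_weight = 1.25e-11)
  back <- read_timeseries_csv(f)
  expect_identical(back$t_s, t)
  expect_identical(back$value, v)
  expect_identical(attr(back, "impulse_weight_C"), 1.25e-11)
})

test_that("each asymptote branch error is monotone toward its limit", {
  p <- cc_params()
  small_t <- 10^seq(-4, -1, by = 0.25)
  large_t <- 10^seq(1, 4, by = 0.25)
  e_resp_s <- rel_err(response_asymptote(p, small_t, "small_time"),
                      cc_response_function(p, small_t))
  e_resp_l <- rel_err(response_asymptote(p, large_t, "large_time"),
                      cc_response_function(p, large_t))
  e_rel_s <- rel_err(relaxation_asymptote(p, small_t, "small_time"),
                     cc_relaxation_function(p, small_t))
  e_rel_l <- rel_err(relaxation_asymptote(p, large_t, "large_time"),
                     cc_relaxation_function(p, large_t))
  expect_true(all(diff(e_resp_s) > 0))   # grows away from t -> 0
  expect_true(all(diff(e_rel_s) > 0))
  expect_true(all(diff(e_resp_l) < 0))   # shrinks toward t -> Inf
  expect_true(all(diff(e_rel_l) < 0))
})

test_that("phi = -dpsi/dt to 1e-6 relative (Richardson-extrapolated)", {
  for (a in c(0.5, 0.7, 0.9, 1)) {
    p <- if (a == 1) dielectric_params("cole_cole", 2, 1, 1, alpha = 1)
         else cc_params(alpha = a, eps_s = 2, eps_inf = 1, tau = 1)
    tg <- 10^seq(-2, 2, by = 0.25)
    D <- function(h) (cc_relaxation_function(p, tg * (1 + h)) -
                        cc_relaxation_function(p, tg * (1 - h))) / (2 * tg * h)
    dpsi <- (4 * D(1e-4) - D(2e-4)) / 3
    expect_lt(max(rel_err(-dpsi, cc_response_function(p, tg))), 1e-6)
  }
})

test_that("integral of phi over [0, T] equals 1 - psi(T) to 1e-8", {
  for (a in c(0.5, 0.7, 0.9, 1)) {
    p <- if (a == 1) dielectric_params("cole_cole", 2, 1, 1, alpha = 1)
         else cc_params(alpha = a, eps_s = 2, eps_inf = 1, tau = 1)
    for (Tend in c(0.3, 3.7)) {
      # substitute u = (t/tau)^alpha: integrand E_{a,a}(-u)/a is smooth
      I <- integrate(function(u) mittag_leffler(a, a, u), 0, Tend^a,
                     rel.tol = 1e-11)$value / a
      expect_lt(abs(I - (1 - cc_relaxation_function(p, Tend))), 1e-8)
    }
  }
})
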