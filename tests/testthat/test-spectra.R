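test_that("permittivity matches direct complex arithmetic", {
  # Debye at omega*tau = 1: 1 + 1/(1+j) = 1.5 - 0.5j
  d <- permittivity(debye_params(), 1)
  expect_equal(d$values, complex(real = 1.5, imaginary = -0.5),
               tolerance = 1e-15)
  # Cole-Cole at omega = 0 returns eps_s exactly
  cc <- permittivity(cc_params(), 0)
  expect_identical(cc$values, 100 + 0i)
  # Cole-Cole at omega*tau = 1: principal branch j^0.7 = e^{j 0.35 pi}
  v <- permittivity(cc_params(), 1)$values
  expect_equal(v, 10 + 90 / (1 + complex(real = cos(0.35 * pi),
                                         imaginary = sin(0.35 * pi))),
               tolerance = 1e-15)
  expect_error(permittivity(cc_params(), c(-1, 1)), "omega")
})

test_that("normalized permittivity is the unit-amplitude kernel", {
  expect_equal(normalized_permittivity(debye_params(), 1)$values,
               complex(real = 0.5, imaginary = -0.5), tolerance = 1e-15)
  expect_identical(normalized_permittivity(cc_params(), 0)$values, 1 + 0i)
  v <- normalized_permittivity(cc_params(alpha = 0.5), 1)$values
  expect_equal(v, 1 / (1 + complex(real = cos(pi / 4), imaginary = sin(pi / 4))),
               tolerance = 1e-15)
})

test_that("susceptibility conversion is eps0 (eps_r - 1)", {
  expect_identical(susceptibility_from_permittivity(1), 0)
  expect_equal(susceptibility_from_permittivity(81), 80 * eps0)
  expect_equal(susceptibility_from_permittivity(10 - 2i), eps0 * (9 - 2i))
})

test_that("capacitance and impedance follow the cell geometry", {
  g <- cell_geometry(1, 1)
  # vacuum-like: eps_r = 1 gives C = eps0 for A/d = 1
  pv <- dielectric_params("debye", eps_s = 1 + 1e-12, eps_inf = 1, tau = 1)
  expect_equal(Re(capacitance(pv, g, 1)$values), eps0, tolerance = 1e-9)
  # omega = 0: C = (A/d) eps0 eps_s
  expect_equal(capacitance(debye_params(), g, 0)$values, eps0 * 2 + 0i,
               tolerance = 1e-15)
  # ideal capacitor: phase of Z exactly -90 degrees
  z <- impedance(pv, g, 10)$values
  expect_equal(Arg(z), -pi / 2, tolerance = 1e-9)
  expect_error(impedance(debye_params(), g, 0), "omega")
  # Debye at omega*tau = 1: direct complex arithmetic
  zd <- impedance(debye_params(), g, 1)$values
  expect_equal(zd, 1 / (1i * 1 * eps0 * (1.5 - 0.5i)), tolerance = 1e-14)
})

test_that("constant-phase-element limit has frequency-independent phase", {
  g <- cell_geometry(2, 1e-3)
  p <- dielectric_params("cole_cole", eps_s = 50, eps_inf = 0, tau = 1,
                         alpha = 0.7)
  om <- 10^seq(2, 6)
  cpe <- cpe_limit_capacitance(p, g, om)
  # arg(j omega C) = pi/2 - alpha pi/2 at every frequency
  expect_equal(Arg(1i * om * cpe$values), rep(pi / 2 - 0.7 * pi / 2, 5),
               tolerance = 1e-12)
  # alpha = 1 reduces to the static capacitance scaled by (j omega tau)^{-1}
  p1 <- dielectric_params("cole_cole", eps_s = 50, eps_inf = 0, tau = 1,
                          alpha = 1)
  cpe1 <- cpe_limit_capacitance(p1, g, 10)
  expect_equal(cpe1$values, 2e3 * eps0 * 50 / (1i * 10), tolerance = 1e-14)
  # relative deviation from the full model vanishes as (omega tau)^alpha grows
  full <- capacitance(p, g, om)
  devs <- rel_err(cpe$values, full$values)
  expect_true(all(diff(devs) < 0))
  expect_lt(devs[5], 1e-4)
  # poor-approximation warning below (omega tau)^alpha = 10
  expect_warning(cpe_limit_capacitance(p, g, 1), "poor")
  expect_error(cpe_limit_capacitance(cc_params(), g, 10), "eps_inf")
})

test_that("a nearly ideal capacitor needs omega*tau = 1e100 to reach factor 10", {
  expect_equal(cpe_onset_omega_tau(0.01, 10, log10 = TRUE), 100)
  expect_equal(cpe_onset_omega_tau(0.01, 10), 1e100)
  expect_equal(cpe_onset_omega_tau(1, 10), 10)
})

test_that("step spectra compose permittivity with the step transform", {
  g <- cell_geometry(3, 2)
  om <- 10^seq(-2, 2)
  ss <- step_spectra(debye_params(), g, om)
  ref <- eps0 * 1.5 * (1 + 1 / (1 + 1i * om))
  expect_equal(ss$current$values, ref, tolerance = 1e-14)
  expect_equal(ss$charge$values, ref / (3 * 1i * om), tolerance = 1e-14)
  # no-dispersion limit: flat current spectrum
  pflat <- dielectric_params("debye", eps_s = 5, eps_inf = 5 - 1e-13, tau = 1)
  sc <- step_spectra(pflat, g, om)$current$values
  expect_equal(sc, rep(eps0 * 1.5 * 5 + 0i, length(om)), tolerance = 1e-12)
  expect_error(step_spectra(debye_params(), g, c(0, 1)), "omega")
  # cole_cole value against the permittivity oracle
  sc2 <- step_spectra(cc_params(), g, 1)$current$values
  expect_equal(sc2, eps0 * 1.5 * permittivity(cc_params(), 1)$values,
               tolerance = 1e-14)
})

test_that("model families nest bit-for-bit", {
  om <- 10^seq(-3, 3, by = 0.5)
  hn_b1 <- dielectric_params("havriliak_negami", 100, 10, 2, alpha = 0.7,
                             beta = 1)
  cc <- dielectric_params("cole_cole", 100, 10, 2, alpha = 0.7)
  expect_identical(permittivity(hn_b1, om)$values, permittivity(cc, om)$values)
  hn_a1 <- dielectric_params("havriliak_negami", 100, 10, 2, alpha = 1,
                             beta = 0.6)
  cd <- dielectric_params("cole_davidson", 100, 10, 2, beta = 0.6)
  expect_identical(permittivity(hn_a1, om)$values, permittivity(cd, om)$values)
  cc_a1 <- dielectric_params("cole_cole", 100, 10, 2, alpha = 1)
  db <- dielectric_params("debye", 100, 10, 2)
  expect_identical(permittivity(cc_a1, om)$values, permittivity(db, om)$values)
})

test_that("random valid models are passive: loss >= 0 and Re Z >= 0", {
  set.seed(42)
  g <- cell_geometry(1, 1)
  om <- 10^seq(-4, 4, by = 0.25)
  for (i in 1:25) {
    model <- sample(c("debye", "cole_cole", "cole_davidson",
                      "havriliak_negami"), 1)
    a <- if (model %in% c("debye", "cole_davidson")) 1 else runif(1, 0.05, 1)
    b <- if (model %in% c("debye", "cole_cole")) 1 else runif(1, 0.05, 1)
    p <- dielectric_params(model, eps_s = runif(1, 2, 500),
                           eps_inf = runif(1, 0, 1.5),
                           tau = 10^runif(1, -6, 3), alpha = a, beta = b)
    eps <- permittivity(p, om)$values
    expect_true(all(-Im(eps) >= -1e-13 * Mod(eps)))
    z <- impedance(p, g, om)$values
    expect_true(all(Re(z) >= -1e-13 * Mod(z)))
  }
})

test_that("the Cole-Cole locus is a circular arc", {
  p <- cc_params(alpha = 0.6, eps_s = 80, eps_inf = 5, tau = 1e-3)
  # circle through three points; a fourth must satisfy the same equation
  om <- c(10, 300, 5e3, 2e5)
  e <- permittivity(p, om)$values
  x <- Re(e); y <- -Im(e)
  # solve x^2 + y^2 + D x + E y + F = 0 from the first three points
  A <- cbind(x[1:3], y[1:3], 1)
  coefc <- solve(A, -(x[1:3]^2 + y[1:3]^2))
  res4 <- x[4]^2 + y[4]^2 + coefc[1] * x[4] + coefc[2] * y[4] + coefc[3]
  expect_lt(abs(res4) / (x[4]^2 + y[4]^2), 1e-9)
})

test_that("permittivity approaches eps_inf at high frequency", {
  # dispersion comparable to eps_inf: |eps - eps_inf| ~ d_eps (omega tau)^-a
  for (a in c(0.5, 0.7, 1)) {
    p <- if (a == 1) debye_params(2, 1, 1)
         else cc_params(alpha = a, eps_s = 2, eps_inf = 1)
    v <- permittivity(p, 1e8)$values
    expect_lt(rel_err(Mod(v), p$eps_inf), 1e-4)
  }
})

test_that("spectrum CSV round-trips losslessly", {
  p <- cc_params()
  sp <- permittivity(p, log_grid(1e-3, 1e3, 40))
  f <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(sp, f)
  back <- read_spectrum_csv(f)
  expect_identical(back$omega, sp$omega)
  expect_identical(back$values, sp$values)
  expect_identical(back$quantity, sp$quantity)
  expect_error(read_spectrum_csv(withr::local_tempfile(lines = "a,b\n1,2")),
               "malformed")
})
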