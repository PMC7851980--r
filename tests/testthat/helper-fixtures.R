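# shared fixtures and small helpers; all data are built in code

rel_err <- function(x, y) abs(x - y) / abs(y)

cc_params <- function(alpha = 0.7, eps_s = 100, eps_inf = 10, tau = 1)
  dielectric_params("cole_cole", eps_s = eps_s, eps_inf = eps_inf,
                    tau = tau, alpha = alpha)

debye_params <- function(eps_s = 2, eps_inf = 1, tau = 1)
  dielectric_params("debye", eps_s = eps_s, eps_inf = eps_inf, tau = tau)

# frozen 50-digit arbitrary-precision reference values for E_{a,b}(-x)
# (two independent high-precision routes, agreeing to >= 30 digits)
ml_ref_table <- function() {
  read.csv(system.file("extdata", "ml_reference_values.csv",
                       package = "colecole"))
}

ml_ref <- function(a, b, x) {
  tb <- ml_ref_table()
  v <- tb$value[abs(tb$alpha - a) < 1e-12 & abs(tb$beta - b) < 1e-12 &
                  abs(tb$x - x) < 1e-9 * max(x, 1)]
  stopifnot(length(v) >= 1L)   # a few grid points also appear as spot checks
  v[1L]
}
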