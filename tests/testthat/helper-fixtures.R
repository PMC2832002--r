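# shared fixtures built in code

perfused_params <- function(...) group_scheme_params("perfused", ...)
ischemic_params <- function(...) group_scheme_params("ischemic", ...)

# noiseless mono-exponential rise as a force_trace
exp_rise_trace <- function(rate = 22, f_inf = 50, f0 = 0, duration = 0.5,
                           rate_hz = 1000, kind = "CA_JUMP") {
  t <- seq(0, duration, by = 1 / rate_hz)
  force_trace(t, f_inf - (f_inf - f0) * exp(-rate * t),
              protocol_kind = kind, pCa = 4.5, pi_mM = 0, rate_hz = rate_hz)
}

hill_force <- function(ca_uM, fmax, ec50, n = 2) {
  fmax * ca_uM^n / (ec50^n + ca_uM^n)
}

random_valid_params <- function() {
  scheme_params(k1 = stats::runif(1, 5, 60),
                k_minus1 = stats::runif(1, 5, 80),
                K2 = stats::runif(1, 5, 80),
                g_off = stats::runif(1, 0.1, 1),
                f_scale = stats::runif(1, 20, 80))
}
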