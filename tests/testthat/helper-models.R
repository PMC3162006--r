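# Shared fixtures, built in code.

# Toy pathway with B recast as an implicit algebraic state (its residual is
# the quasi-steady-state balance), exercising the DAE integration path.
toy_dae_model <- function() {
  network_model(
    "toy_dae", states = c("A", "B", "C"),
    kind = c(A = "ode", B = "implicit_algebraic", C = "ode"),
    params = c(k1 = 0, k2 = 1, k3 = 10, k4 = 1),
    rates = list(A = quote(k1 - k2 * A), C = quote(k3 * B - k4 * C)),
    residuals = list(B = quote(k2 * A - k3 * B)))
}

# Reversible binding E + S <-> ES with conserved enzyme total; S is an
# input parameter switched by the protocol.
binding_model <- function() {
  network_model(
    "binding", states = c("E", "ES"),
    kind = c(E = "ode", ES = "ode"),
    params = c(kon = 1, koff = 0.1, S = 0, Etot = 1),
    rates = list(E = quote(koff * ES - kon * S * E),
                 ES = quote(kon * S * E - koff * ES)),
    conserved = list(list(total = "Etot", members = c("E", "ES"))),
    init = c(E = 1, ES = 0))
}

binding_protocol <- function(n_out = 400) {
  stimulus_protocol("S", on_value = 2, off_value = 0,
                    t_off = 40, t_end = 80, n_out = n_out)
}

hill_curve <- function(x, y_max, K, h) y_max * x^h / (K^h + x^h)

# Synthetic clamp-curve stand-in for fitting tests.
fake_curve <- function(x, y) {
  structure(list(clamp = "x", record = "y", values = x, responses = y,
                 flagged = numeric(), conservation_ok = TRUE),
            class = "clamp_curve")
}

# Random closed loop inside the unit square (for invariance properties).
random_loop <- function(n = 50) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, 0.1, 0.5)
  phase_loop(pmin(pmax(0.5 + r * cos(th), 0), 1),
             pmin(pmax(0.5 + r * sin(th), 0), 1))
}

expect_phaseloop_error <- function(object, class) {
  expect_error(object, class = class)
}
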