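# Internal numerical helpers shared across modules.

# Central finite-difference Jacobian with per-component adaptive step
# h_j = eps^(1/3) * max(|x_j|, 1).
num_jacobian <- function(f, x, rel_step = .Machine$double.eps^(1/3)) {
  f0 <- f(x)
  n <- length(x)
  J <- matrix(NA_real_, length(f0), n)
  step <- rel_step * pmax(abs(x), 1)
  for (j in seq_len(n)) {
    xp <- x
    xm <- x
    xp[j] <- x[j] + step[j]
    xm[j] <- x[j] - step[j]
    J[, j] <- (f(xp) - f(xm)) / (2 * step[j])
  }
  J
}

# Damped Newton root solve with numerical Jacobian and backtracking line
# search. Returns the last iterate even on non-convergence so callers can
# decide how to proceed.
newton_solve <- function(f, x0, tol = 1e-12, maxit = 60L) {
  x <- x0
  fx <- f(x)
  if (!all(is.finite(fx))) {
    return(list(x = x, f = fx, converged = FALSE))
  }
  for (it in seq_len(maxit)) {
    if (max(abs(fx)) < tol) break
    J <- num_jacobian(f, x)
    dx <- tryCatch(
      solve(J, -fx),
      error = function(e) {
        qrJ <- qr(J, LAPACK = TRUE)
        tryCatch(qr.coef(qrJ, -fx), error = function(e2) NULL)
      }
    )
    if (is.null(dx) || !all(is.finite(dx))) {
      return(list(x = x, f = fx, converged = FALSE))
    }
    lambda <- 1
    improved <- FALSE
    while (lambda >= 1e-7) {
      xn <- x + lambda * dx
      fn <- f(xn)
      if (all(is.finite(fn)) && sum(fn^2) < sum(fx^2)) {
        x <- xn
        fx <- fn
        improved <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!improved) break
  }
  list(x = x, f = fx, converged = max(abs(fx)) < tol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_phaseloop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "phaseloop_error"),
                      call = call))
}

# Deterministic numeric formatting used by all CSV writers so reruns are
# byte-identical.
fmt_num <- function(x) {
  formatC(x, digits = 15, format = "g")
}
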