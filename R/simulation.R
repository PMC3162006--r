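#' Transient stimulus protocol
#'
#' A single on/off switch of one input parameter: the parameter takes
#' `on_value` on \[t_on, t_off\] and `off_value` on (t_off, t_end\].
#' Simulations start from the resting steady state computed with the input
#' at `off_value` and integrate the two segments separately with the
#' parameter switched between them, which keeps stiff solvers away from the
#' discontinuity.
#'
#' @param parameter name of the switched input parameter.
#' @param on_value,off_value parameter values during/outside the stimulus
#'   window (input units, typically µM or µM s⁻¹).
#' @param t_on,t_off,t_end stimulus start, stimulus end and simulation end
#'   (s); `0 <= t_on < t_off <= t_end`.
#' @param n_out number of output samples over \[t_on, t_end\] (>= 3);
#'   default 2000, dense enough that phase-loop areas are grid-converged to
#'   below 1e-3.
#' @return an object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(parameter, on_value, off_value = 0,
                              t_on = 0, t_off, t_end = t_off, n_out = 2000) {
  if (!(t_on >= 0 && t_on < t_off && t_off <= t_end)) {
    stop_phaseloop("need 0 <= t_on < t_off <= t_end", "phaseloop_protocol_error")
  }
  if (n_out < 3) {
    stop_phaseloop("n_out must be >= 3", "phaseloop_protocol_error")
  }
  structure(list(parameter = parameter, on_value = on_value,
                 off_value = off_value, t_on = t_on, t_off = t_off,
                 t_end = t_end, n_out = as.integer(n_out)),
            class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf("stimulus_protocol: %s = %g on [%g, %g] s, %g on (%g, %g] s, %d samples\n",
              x$parameter, x$on_value, x$t_on, x$t_off,
              x$off_value, x$t_off, x$t_end, x$n_out))
  invisible(x)
}

# Integrate the dynamic states of a model over `times` with fixed params.
# Pure-ODE systems use lsoda; systems with implicit algebraic states are
# treated as semi-explicit index-1 DAEs via daspk, after making the
# algebraic states consistent at the initial time by a Newton solve.
integrate_segment <- function(model, x0, times, params,
                              rtol = 1e-8, atol = 1e-10) {
  dyn <- dynamic_states(model)
  ode_states <- intersect(dyn, names(model$rates))
  imp_states <- intersect(dyn, names(model$residuals))
  x0 <- x0[dyn]
  if (!length(imp_states)) {
    fn <- function(t, y, p) {
      names(y) <- dyn
      list(eval_derivs(model, t, y, params))
    }
    out <- deSolve::ode(y = x0, times = times, func = fn, parms = NULL,
                        method = "lsoda", rtol = rtol, atol = atol)
  } else {
    x0[imp_states] <- consistent_algebraic(model, x0, params, times[1])
    resfun <- function(t, y, dy, p) {
      names(y) <- dyn
      d <- eval_derivs(model, t, y, params)
      r <- eval_residuals(model, y, params, t)
      list(c(dy[match(ode_states, dyn)] - d[ode_states], r[imp_states]))
    }
    dy0 <- rep(0, length(dyn))
    names(dy0) <- dyn
    d0 <- eval_derivs(model, times[1], x0, params)
    dy0[ode_states] <- d0[ode_states]
    out <- deSolve::daspk(y = x0, dy = dy0, times = times, res = resfun,
                          parms = NULL, rtol = rtol, atol = atol)
  }
  if (attr(out, "istate")[1] < 0 || nrow(out) < length(times)) {
    t_fail <- if (nrow(out)) out[nrow(out), 1] else times[1]
    stop_phaseloop(sprintf("integrator failed for model '%s' near t = %g s",
                           model$name, t_fail),
                   "phaseloop_integration_error")
  }
  out
}

# Solve the implicit algebraic states to consistency at fixed ode values.
consistent_algebraic <- function(model, xdyn, params, t = 0) {
  imp <- intersect(dynamic_states(model), names(model$residuals))
  f <- function(z) {
    xdyn[imp] <- z
    eval_residuals(model, xdyn, params, t)
  }
  sol <- newton_solve(f, xdyn[imp], tol = 1e-12)
  if (!sol$converged) {
    stop_phaseloop(sprintf("could not find consistent values for implicit states: %s",
                           paste(imp, collapse = ", ")),
                   "phaseloop_integration_error")
  }
  stats::setNames(sol$x, imp)
}

#' Find a steady state of a model
#'
#' Locates a state where every ode derivative and algebraic residual
#' vanishes, using the scale-free criterion
#' `max |dx/dt| / max(|x|, 1 µM) < tol`. By default a damped Newton polish
#' from the initial guess is attempted first (fast and exact for the
#' well-behaved systems handled here); if it fails or lands on a negative
#' concentration, the system is integrated over doubling horizons until the
#' criterion holds and then polished.
#'
#' @param model a [network_model()].
#' @param overrides named list/vector of parameter overrides (e.g. the
#'   stimulus input held at a fixed value).
#' @param x0 named initial guess for the dynamic states (defaults to the
#'   model's `init`, else zeros).
#' @param tol steady-state tolerance on the normalized rates (s⁻¹).
#' @param method `"auto"` (Newton first, integration fallback),
#'   `"integrate"` or `"newton"`.
#' @param t_max maximum integration horizon before giving up (s).
#' @return named numeric vector over all model states (explicit and
#'   parameterized states included), with attribute `"dynamic"` holding the
#'   dynamic sub-vector.
#' @export
find_steady_state <- function(model, overrides = list(), x0 = NULL,
                              tol = 1e-8, method = c("auto", "integrate", "newton"),
                              t_max = 1e7) {
  method <- match.arg(method)
  params <- override_params(model$params, overrides)
  dyn <- dynamic_states(model)
  if (is.null(x0)) {
    x0 <- stats::setNames(rep(0, length(dyn)), dyn)
    if (!is.null(model$init)) {
      shared <- intersect(names(model$init), dyn)
      x0[shared] <- model$init[shared]
    }
  } else {
    x0 <- x0[dyn]
  }
  rate_fn <- function(x) eval_dynamics(model, 0, x, params)
  normalized_rate <- function(x) {
    r <- rate_fn(x)
    if (!length(r)) return(0)
    max(abs(r) / pmax(abs(x), 1))
  }
  polish <- function(x) {
    sol <- newton_solve(function(z) rate_fn(stats::setNames(z, dyn)), x,
                        tol = 1e-13)
    stats::setNames(sol$x, dyn)
  }
  x <- x0
  done <- FALSE
  if (method %in% c("auto", "newton")) {
    xn <- polish(x)
    ok <- all(is.finite(xn)) && normalized_rate(xn) < tol &&
      all(xn > -1e-9)
    if (ok) {
      x <- xn
      done <- TRUE
    } else if (method == "newton") {
      stop_phaseloop("Newton steady-state solve did not converge",
                     "phaseloop_steady_state_error")
    }
  }
  if (!done) {
    horizon <- 100
    total <- 0
    repeat {
      seg <- integrate_segment(model, x, c(0, horizon / 2, horizon), params)
      x <- seg[nrow(seg), dyn]
      total <- total + horizon
      if (any(abs(x) > 1e12)) {
        stop_phaseloop(sprintf("steady-state search diverged for model '%s'",
                               model$name),
                       "phaseloop_steady_state_error")
      }
      if (normalized_rate(x) < 10 * tol) break
      if (total > t_max) {
        stop_phaseloop(sprintf("no steady state within horizon %g s for model '%s'",
                               t_max, model$name),
                       "phaseloop_steady_state_error")
      }
      horizon <- horizon * 4
    }
    xn <- polish(x)
    if (all(is.finite(xn)) && normalized_rate(xn) <= normalized_rate(x)) {
      x <- xn
    }
    if (normalized_rate(x) >= tol) {
      stop_phaseloop(sprintf("steady state not reached to tolerance %g for model '%s'",
                             tol, model$name),
                     "phaseloop_steady_state_error")
    }
  }
  fs <- full_state(model, x, params)
  attr(fs, "dynamic") <- x
  fs
}

override_params <- function(params, overrides) {
  overrides <- unlist(overrides) %||% numeric()
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(params))
    if (length(unknown)) {
      stop_phaseloop(sprintf("unknown parameter override(s): %s",
                             paste(unknown, collapse = ", ")),
                     "phaseloop_model_error")
    }
    params[names(overrides)] <- overrides
  }
  params
}

#' Simulate a model under a transient stimulus
#'
#' Computes the resting steady state with the input at `off_value`, then
#' integrates the stimulus segment \[t_on, t_off\] with the input at
#' `on_value` and the washout segment \[t_off, t_end\] with the input back
#' at `off_value`. Implicit algebraic residuals are verified at every
#' output time, and conservation constraints are checked to a relative
#' tolerance of 1e-6.
#'
#' @param model a [network_model()].
#' @param protocol a [stimulus_protocol()].
#' @param overrides additional fixed parameter overrides applied in both
#'   segments (scenario context).
#' @param init optional dynamic initial state; defaults to the resting
#'   steady state at `off_value`, which is what makes the on/off loop close.
#' @param rtol,atol integrator tolerances.
#' @return a `time_course_set`: list with `time` (s), `values` (matrix,
#'   one column per state, µM) and `provenance`.
#' @export
simulate_transient <- function(model, protocol, overrides = list(),
                               init = NULL, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  base <- override_params(model$params, overrides)
  if (!protocol$parameter %in% names(base)) {
    stop_phaseloop(sprintf("protocol parameter '%s' is not a parameter of model '%s'",
                           protocol$parameter, model$name),
                   "phaseloop_protocol_error")
  }
  p_on <- base
  p_on[protocol$parameter] <- protocol$on_value
  p_off <- base
  p_off[protocol$parameter] <- protocol$off_value

  if (is.null(init)) {
    rest <- find_steady_state(model, overrides = as.list(p_off))
    init <- attr(rest, "dynamic")
  }
  dyn <- dynamic_states(model)
  grid <- seq(protocol$t_on, protocol$t_end, length.out = protocol$n_out)

  t1 <- grid[grid <= protocol$t_off]
  seg1_times <- unique(c(t1, protocol$t_off))
  seg1 <- integrate_segment(model, init, seg1_times, p_on, rtol, atol)
  x_switch <- seg1[nrow(seg1), dyn]

  rows <- seg1[seg1[, 1] %in% t1, , drop = FALSE]
  if (protocol$t_end > protocol$t_off) {
    t2 <- grid[grid > protocol$t_off]
    seg2_times <- unique(c(protocol$t_off, t2))
    seg2 <- integrate_segment(model, x_switch, seg2_times, p_off, rtol, atol)
    rows <- rbind(rows, seg2[seg2[, 1] %in% t2, , drop = FALSE])
  }
  time <- rows[, 1]
  xdyn <- rows[, dyn, drop = FALSE]

  # residual verification at output times
  if (length(model$residuals)) {
    for (i in seq_along(time)) {
      p <- if (time[i] <= protocol$t_off) p_on else p_off
      r <- eval_residuals(model, xdyn[i, ], p, time[i])
      if (max(abs(r)) > 1e-6) {
        worst <- names(model$residuals)[which.max(abs(r))]
        stop_phaseloop(sprintf("algebraic residual violated for state '%s' at t = %g s (|r| = %g)",
                               worst, time[i], max(abs(r))),
                       "phaseloop_integration_error")
      }
    }
  }

  values <- matrix(NA_real_, length(time), length(model$states),
                   dimnames = list(NULL, model$states))
  for (i in seq_along(time)) {
    p <- if (time[i] <= protocol$t_off) p_on else p_off
    values[i, ] <- full_state(model, xdyn[i, ], p, time[i])
  }

  check_conservation(model, values)

  structure(list(time = time, values = values,
                 provenance = list(model = model$name, protocol = protocol,
                                   overrides = overrides)),
            class = "time_course_set")
}

# Relative conservation check at every output time.
check_conservation <- function(model, values, rel_tol = 1e-6,
                               skip_states = character()) {
  for (cc in model$conserved) {
    if (any(cc$members %in% skip_states)) next
    total <- model$params[[cc$total]]
    s <- rowSums(values[, cc$members, drop = FALSE])
    dev <- max(abs(s - total))
    if (dev > rel_tol * max(abs(total), 1e-12)) {
      warning(sprintf("conservation violated: |%s - %s| up to %g",
                      paste(cc$members, collapse = "+"), cc$total, dev),
              call. = FALSE)
      return(invisible(FALSE))
    }
  }
  invisible(TRUE)
}

#' @export
print.time_course_set <- function(x, ...) {
  cat(sprintf("time_course_set: %d states x %d samples over [%g, %g] s (model '%s')\n",
              ncol(x$values), length(x$time), min(x$time), max(x$time),
              x$provenance$model %||% "?"))
  invisible(x)
}

#' @export
as.data.frame.time_course_set <- function(x, ...) {
  data.frame(time_s = x$time, x$values, check.names = FALSE)
}

#' Normalize timecourses to the unit interval
#'
#' Each state's trace x(t) is rescaled by
#' x_norm(t) = (x(t) − x_min)/(x_max − x_min), so every non-constant trace
#' attains exactly 0 at its minimum sample and 1 at its maximum. This makes
#' phase loops comparable across species whose concentrations differ by
#' orders of magnitude. Constant traces (range below `static_tol` relative
#' to the trace magnitude) cannot be normalized; they are flagged static
#' and excluded from phase analysis.
#'
#' @param tc a `time_course_set` from [simulate_transient()] or
#'   [read_timecourses()].
#' @param static_tol relative range below which a trace counts as static.
#' @return a `normalized_time_course_set`: `time`, `values` (non-static
#'   states only, each in \[0, 1\]), `ranges` (2-row matrix of the
#'   (x_min, x_max) recorded for every state, for de-normalization) and
#'   `static` (names of excluded states).
#' @export
normalize_timecourses <- function(tc, static_tol = 1e-8) {
  stopifnot(inherits(tc, "time_course_set"))
  v <- tc$values
  xmin <- apply(v, 2, min)
  xmax <- apply(v, 2, max)
  rng <- xmax - xmin
  static <- colnames(v)[rng <= static_tol * pmax(abs(xmax), 1)]
  keep <- setdiff(colnames(v), static)
  vn <- sapply(keep, function(s) (v[, s] - xmin[s]) / (xmax[s] - xmin[s]))
  vn <- matrix(vn, nrow = nrow(v), dimnames = list(NULL, keep))
  structure(list(time = tc$time, values = vn,
                 ranges = rbind(x_min = xmin, x_max = xmax),
                 static = static, provenance = tc$provenance),
            class = "normalized_time_course_set")
}

#' @rdname normalize_timecourses
#' @param ntc a `normalized_time_course_set`.
#' @return `denormalize_timecourses`: the original-scale `time_course_set`
#'   (non-static states only).
#' @export
denormalize_timecourses <- function(ntc) {
  stopifnot(inherits(ntc, "normalized_time_course_set"))
  keep <- colnames(ntc$values)
  v <- sapply(keep, function(s) {
    ntc$ranges["x_min", s] +
      ntc$values[, s] * (ntc$ranges["x_max", s] - ntc$ranges["x_min", s])
  })
  structure(list(time = ntc$time,
                 values = matrix(v, nrow = nrow(ntc$values),
                                 dimnames = list(NULL, keep)),
                 provenance = ntc$provenance),
            class = "time_course_set")
}

#' @export
print.normalized_time_course_set <- function(x, ...) {
  cat(sprintf("normalized_time_course_set: %d states x %d samples; static: %s\n",
              ncol(x$values), length(x$time),
              if (length(x$static)) paste(x$static, collapse = ", ") else "none"))
  invisible(x)
}

#' Read and write timecourse tables
#'
#' The on-disk format is a delimited text table whose first column is
#' `time_s` and remaining columns are one state each (µM), with a header
#' row of state names. The reader accepts comma- or tab-separated input
#' (sniffed from the header line); the writer emits comma-separated output
#' with deterministic formatting. This is also the entry point for
#' experimental multichannel kinetic data: a table read here can be fed
#' straight into [normalize_timecourses()] and the phase analysis without
#' any model.
#'
#' @param file path to a delimited text file.
#' @return `read_timecourses`: a `time_course_set`.
#' @export
read_timecourses <- function(file) {
  header <- readLines(file, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "time_s") {
    stop_phaseloop("first column must be 'time_s'", "phaseloop_io_error")
  }
  time <- df[[1]]
  if (is.unsorted(time, strictly = TRUE)) {
    stop_phaseloop("time grid must be strictly increasing", "phaseloop_io_error")
  }
  if (anyNA(df)) {
    stop_phaseloop("timecourse table has missing entries", "phaseloop_io_error")
  }
  structure(list(time = time,
                 values = as.matrix(df[, -1, drop = FALSE]),
                 provenance = list(model = basename(file), protocol = NULL)),
            class = "time_course_set")
}

#' @rdname read_timecourses
#' @param tc a `time_course_set`.
#' @export
write_timecourses <- function(tc, file) {
  stopifnot(inherits(tc, "time_course_set"))
  df <- as.data.frame(tc)
  lines <- c(paste(names(df), collapse = ","),
             apply(df, 1, function(r) paste(fmt_num(as.numeric(r)), collapse = ",")))
  writeLines(lines, file)
  invisible(file)
}
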