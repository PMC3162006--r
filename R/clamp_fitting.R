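#' Freeze a state at a fixed concentration
#'
#' Returns a copy of the model in which `state` is `parameterized` at
#' `value`: its differential equation (or algebraic equation) is removed
#' and its value held constant wherever it appears in other expressions —
#' the literal "held constant" of a concentration clamp.
#'
#' @param model a [network_model()].
#' @param state state to freeze.
#' @param value fixed concentration (µM).
#' @return a new `network_model`.
#' @export
clamp_state <- function(model, state, value) {
  if (!state %in% model$states) {
    stop_phaseloop(sprintf("unknown state '%s'", state), "phaseloop_model_error")
  }
  m <- model
  m$kind[state] <- "parameterized"
  m$rates[[state]] <- NULL
  m$residuals[[state]] <- NULL
  m$explicit[[state]] <- NULL
  m$fixed <- c(m$fixed[setdiff(names(m$fixed), state)],
               stats::setNames(value, state))
  m$name <- sprintf("%s[%s clamped]", model$name, state)
  m
}

#' Concentration-clamp sweep
#'
#' Holds one species constant at each value of a sweep, runs the remaining
#' system to steady state, and records the steady-state value of a second
#' species. Sweeping the clamp traces the steady-state input–response
#' relationship between the two species, over a wider dynamic range than
#' any single transient explores. Conservation constraints not involving
#' the clamped state are monitored at every converged point; violations
#' are recorded, never silently dropped, and non-convergent sweep points
#' are flagged with `NA` responses.
#'
#' @param model a [network_model()].
#' @param clamp state to hold constant.
#' @param values sweep of clamp concentrations (µM); sorted increasing. By
#'   default (`NULL`) the sweep is `sweep_points` linearly spaced values
#'   from 0 to 1.5 times the clamped state's maximum over the reference
#'   transient of `protocol` (requires `protocol`).
#' @param record state whose steady-state response is recorded.
#' @param context named parameter overrides defining the operating
#'   condition (e.g. the stimulus input held at its "on" value).
#' @param protocol optional [stimulus_protocol()] used only to derive the
#'   default sweep range.
#' @param sweep_points number of sweep values for the default sweep.
#' @param log_spacing use logarithmic spacing for the default sweep.
#' @return a `clamp_curve`: list with `clamp`, `record`, `values`,
#'   `responses` (µM, `NA` where flagged), `flagged` (non-convergent sweep
#'   values), `conservation_ok` and `context`.
#' @export
concentration_clamp <- function(model, clamp, values = NULL, record,
                                context = list(), protocol = NULL,
                                sweep_points = 25L, log_spacing = FALSE) {
  if (!clamp %in% model$states || !record %in% model$states) {
    stop_phaseloop("clamp and record must be model states", "phaseloop_model_error")
  }
  if (is.null(values)) {
    if (is.null(protocol)) {
      stop_phaseloop("either `values` or `protocol` (for the default sweep) is required",
                     "phaseloop_clamp_error")
    }
    tc <- simulate_transient(model, protocol, overrides = context)
    top <- 1.5 * max(tc$values[, clamp])
    values <- if (log_spacing) {
      exp(seq(log(max(top * 1e-3, 1e-9)), log(top), length.out = sweep_points))
    } else {
      seq(0, top, length.out = sweep_points)
    }
  }
  values <- sort(unique(as.numeric(values)))
  if (any(!is.finite(values))) {
    stop_phaseloop("sweep values must be finite", "phaseloop_clamp_error")
  }
  responses <- rep(NA_real_, length(values))
  flagged <- numeric()
  conservation_ok <- TRUE
  x_prev <- NULL
  for (i in seq_along(values)) {
    cm <- clamp_state(model, clamp, values[i])
    ss <- tryCatch(
      find_steady_state(cm, overrides = context, x0 = x_prev),
      phaseloop_error = function(e) NULL)
    if (is.null(ss)) {
      flagged <- c(flagged, values[i])
      next
    }
    x_prev <- attr(ss, "dynamic")
    responses[i] <- ss[[record]]
    if (length(model$conserved)) {
      ok <- withCallingHandlers(
        check_conservation(cm, matrix(ss, 1, dimnames = list(NULL, names(ss))),
                           skip_states = clamp),
        warning = function(w) invokeRestart("muffleWarning"))
      conservation_ok <- conservation_ok && isTRUE(ok)
    }
  }
  if (all(is.na(responses))) {
    stop_phaseloop("no sweep point reached steady state", "phaseloop_clamp_error")
  }
  structure(list(clamp = clamp, record = record, values = values,
                 responses = responses, flagged = flagged,
                 conservation_ok = conservation_ok, context = context,
                 model = model$name),
            class = "clamp_curve")
}

#' @export
print.clamp_curve <- function(x, ...) {
  cat(sprintf("clamp_curve: %s clamped over [%g, %g] µM (%d points%s), recording %s\n",
              x$clamp, min(x$values), max(x$values), length(x$values),
              if (length(x$flagged)) sprintf(", %d flagged", length(x$flagged)) else "",
              x$record))
  invisible(x)
}

#' @rdname concentration_clamp
#' @param curve a `clamp_curve`.
#' @param file output path.
#' @export
write_clamp_curve <- function(curve, file) {
  lines <- c("clamp_value,response",
             paste(fmt_num(curve$values), fmt_num(curve$responses), sep = ","))
  writeLines(lines, file)
  invisible(file)
}

# ---- candidate algebraic forms -------------------------------------------

relation_forms <- function() c("hill", "linear", "exponential", "power")

relation_fun <- function(form) {
  # hill and power take fractional powers: clamp the abscissa at zero so a
  # solver's rounding excursion below 0 uM cannot produce NaN
  switch(form,
    hill = function(x, p) {
      x <- pmax(x, 0)
      p[["y_max"]] * x^p[["h"]] / (p[["K"]]^p[["h"]] + x^p[["h"]])
    },
    linear = function(x, p) p[["slope"]] * x + p[["intercept"]],
    exponential = function(x, p) p[["amplitude"]] * exp(p[["rate"]] * x) + p[["offset"]],
    power = function(x, p) p[["coefficient"]] * pmax(x, 0)^p[["exponent"]],
    stop_phaseloop(sprintf("unknown relation form '%s'", form),
                   "phaseloop_fit_error"))
}

# Expression tree for a fitted relation applied to a parent-state symbol;
# used when reduced states are rewritten as explicit algebraic equations.
relation_expr <- function(fit, parent) {
  p <- as.list(fit$parameters)
  sym <- as.name(parent)
  clamped <- call("pmax", sym, 0)   # fractional powers of ~-1e-12 are NaN
  switch(fit$form,
    hill = substitute(y_max * x^h / (K^h + x^h),
                      c(p, list(x = clamped))),
    linear = substitute(slope * x + intercept, c(p, list(x = sym))),
    exponential = substitute(amplitude * exp(rate * x) + offset,
                             c(p, list(x = sym))),
    power = substitute(coefficient * x^exponent, c(p, list(x = clamped))))
}

fit_one_form <- function(form, x, y) {
  n <- length(x)
  rmse_of <- function(p) {
    r <- y - relation_fun(form)(x, p)
    sqrt(mean(r^2))
  }
  if (form == "linear") {
    fit <- stats::lm(y ~ x)
    p <- c(slope = unname(stats::coef(fit)[2]),
           intercept = unname(stats::coef(fit)[1]))
    return(list(parameters = p, rmse = rmse_of(p)))
  }
  nls_try <- function(formula, start, lower = NULL, data) {
    tryCatch({
      fit <- if (is.null(lower)) {
        minpack.lm::nlsLM(formula, data = data, start = start,
                          control = minpack.lm::nls.lm.control(maxiter = 200,
                                                               ftol = 1e-14,
                                                               ptol = 1e-14))
      } else {
        minpack.lm::nlsLM(formula, data = data, start = start, lower = lower,
                          control = minpack.lm::nls.lm.control(maxiter = 200,
                                                               ftol = 1e-14,
                                                               ptol = 1e-14))
      }
      stats::coef(fit)
    }, error = function(e) NULL)
  }
  dat <- data.frame(x = x, y = y)
  best <- NULL
  consider <- function(p) {
    if (is.null(p) || any(!is.finite(p))) return()
    r <- rmse_of(p)
    if (is.finite(r) && (is.null(best) || r < best$rmse)) {
      best <<- list(parameters = p, rmse = r)
    }
  }
  if (form == "hill") {
    y_max0 <- max(y)
    half <- y_max0 / 2
    K0 <- x[which.min(abs(y - half))]
    if (!is.finite(K0) || K0 <= 0) K0 <- stats::median(x[x > 0])
    for (h0 in c(1, 0.5, 2, 4)) {
      consider(nls_try(y ~ y_max * x^h / (K^h + x^h),
                       start = list(y_max = y_max0, K = K0, h = h0),
                       lower = c(y_max = 0, K = 1e-12, h = 1e-6), data = dat))
      if (!is.null(best) && best$rmse < 1e-12 * max(abs(y), 1)) break
    }
  } else if (form == "exponential") {
    xr <- max(x) - min(x)
    rng <- max(y) - min(y)
    starts <- list()
    # log-linear seed against both plausible offsets
    for (off0 in c(min(y) - 1e-3 * max(rng, 1e-12),
                   max(y) + 1e-3 * max(rng, 1e-12))) {
      shift <- y - off0
      sgn <- sign(stats::median(shift))
      z <- sgn * shift
      if (all(z > 0)) {
        lf <- stats::lm(log(z) ~ x)
        starts[[length(starts) + 1L]] <-
          list(amplitude = sgn * exp(unname(stats::coef(lf)[1])),
               rate = unname(stats::coef(lf)[2]), offset = off0)
      }
    }
    # coarse sign/rate grid as fallback
    amp0 <- max(rng, 1e-12)
    for (sa in c(1, -1)) for (r0 in c(1, -1) / max(xr, 1e-9)) {
      starts[[length(starts) + 1L]] <-
        list(amplitude = sa * amp0, rate = r0, offset = min(y))
    }
    for (st in starts) {
      consider(nls_try(y ~ amplitude * exp(rate * x) + offset, start = st,
                       data = dat))
      if (!is.null(best) && best$rmse < 1e-12 * max(abs(y), 1)) break
    }
  } else if (form == "power") {
    pos <- x > 0 & y != 0
    if (sum(pos) >= 3) {
      lf <- stats::lm(log(abs(y[pos])) ~ log(x[pos]))
      b0 <- unname(stats::coef(lf)[2])
      a0 <- sign(mean(y[pos])) * exp(unname(stats::coef(lf)[1]))
    } else {
      b0 <- 1
      a0 <- if (any(x > 0)) mean(y[x > 0] / x[x > 0]) else 1
    }
    datp <- dat[x > 0, , drop = FALSE]
    if (nrow(datp) >= 3) {
      p <- nls_try(y ~ coefficient * x^exponent,
                   start = list(coefficient = a0, exponent = b0),
                   lower = c(coefficient = -Inf, exponent = 1e-6),
                   data = datp)
      if (!is.null(p) && all(is.finite(relation_fun("power")(x, p)))) consider(p)
    }
  }
  best
}

#' Fit an explicit algebraic relation to a clamp curve
#'
#' Fits each candidate form to the sweep by nonlinear least squares and
#' returns the form with the smallest root-mean-square error, automating
#' the form-selection step (a specific form can be forced by passing a
#' single candidate). Candidates:
#' \describe{
#'   \item{hill}{`y = y_max * x^h / (K^h + x^h)` (baseline 0); y_max in µM,
#'     K in µM, h dimensionless, both constrained positive.}
#'   \item{linear}{`y = slope * x + intercept`.}
#'   \item{exponential}{`y = amplitude * exp(rate * x) + offset`.}
#'   \item{power}{`y = coefficient * x^exponent` (fitted on x > 0).}
#' }
#' Starts follow the half-max heuristic (y_max = max response, K at
#' half-max, h = 1) with multi-start over h in {0.5, 1, 2, 4}.
#'
#' @param curve a `clamp_curve` (or any list with `values`/`responses`).
#' @param forms character vector of candidate forms.
#' @return a `fitted_relation`: `form`, `parameters`, `rmse` (µM),
#'   `domain` (sweep range of validity), `n_points`, and the per-form rmse
#'   table in `$candidates`.
#' @export
fit_relation <- function(curve, forms = relation_forms()) {
  ok <- is.finite(curve$responses)
  x <- curve$values[ok]
  y <- curve$responses[ok]
  if (length(x) < 4) {
    stop_phaseloop("need at least 4 valid sweep points to fit", "phaseloop_fit_error")
  }
  forms <- match.arg(forms, relation_forms(), several.ok = TRUE)
  npar <- c(hill = 3, linear = 2, exponential = 3, power = 2)
  forms <- forms[npar[forms] < length(x)]
  fits <- list()
  for (f in forms) {
    ft <- fit_one_form(f, x, y)
    if (!is.null(ft)) fits[[f]] <- ft
  }
  if (!length(fits)) {
    stop_phaseloop("no candidate form converged", "phaseloop_fit_error")
  }
  cand <- data.frame(form = names(fits),
                     rmse = vapply(fits, function(f) f$rmse, numeric(1)),
                     n_par = npar[names(fits)], row.names = NULL)
  # least rmse wins; near-ties (within 1e-9 relative) go to the simpler
  # form, with a fixed preference order among forms of equal complexity
  simplicity <- match(cand$form, c("linear", "power", "hill", "exponential"))
  ord <- order(cand$rmse, cand$n_par, simplicity)
  cand <- cand[ord, ]
  best_rmse <- cand$rmse[1]
  tied <- which(cand$rmse <= best_rmse * (1 + 1e-9) + 1e-15)
  pick <- cand$form[tied[order(cand$n_par[tied], simplicity[ord][tied])[1]]]
  ft <- fits[[pick]]
  structure(list(form = pick, parameters = ft$parameters, rmse = ft$rmse,
                 domain = range(x), n_points = length(x),
                 clamp = curve$clamp %||% NA_character_,
                 record = curve$record %||% NA_character_,
                 candidates = cand),
            class = "fitted_relation")
}

#' @export
print.fitted_relation <- function(x, ...) {
  cat(sprintf("fitted_relation: %s ~ %s(%s); %s; rmse = %.4g over [%g, %g]\n",
              x$record, x$form, x$clamp,
              paste(sprintf("%s = %.6g", names(x$parameters), x$parameters),
                    collapse = ", "),
              x$rmse, x$domain[1], x$domain[2]))
  invisible(x)
}

#' Evaluate a fitted relation
#'
#' @param object a `fitted_relation`.
#' @param x abscissa values (µM).
#' @param extrapolate `"flag"` (default: evaluate but attach an
#'   `extrapolated` attribute marking points outside the fitted domain),
#'   `"allow"`, or `"error"`.
#' @param ... unused.
#' @return predicted responses (µM).
#' @export
predict.fitted_relation <- function(object, x, extrapolate = c("flag", "allow", "error"),
                                    ...) {
  extrapolate <- match.arg(extrapolate)
  outside <- x < object$domain[1] | x > object$domain[2]
  if (any(outside) && extrapolate == "error") {
    stop_phaseloop(sprintf("%d point(s) outside the fitted domain [%g, %g]",
                           sum(outside), object$domain[1], object$domain[2]),
                   "phaseloop_fit_error")
  }
  y <- relation_fun(object$form)(x, as.list(object$parameters))
  if (extrapolate == "flag") attr(y, "extrapolated") <- outside
  y
}

#' Serialize clamp curves and fitted relations
#'
#' Writes a structured JSON file carrying the form, parameters, units,
#' fitted domain and rmse (and the sweep itself for curves), so fitted
#' relations are reviewable and reloadable.
#'
#' @param object a `clamp_curve` or `fitted_relation` (or list of them).
#' @param file output path.
#' @export
write_relation_json <- function(object, file) {
  to_list <- function(o) {
    if (inherits(o, "fitted_relation")) {
      list(type = "fitted_relation", form = o$form,
           parameters = as.list(o$parameters),
           units = list(y_max = "uM", K = "uM", slope = "dimensionless",
                        intercept = "uM", amplitude = "uM", rate = "per_uM",
                        offset = "uM", coefficient = "uM", exponent = "dimensionless",
                        h = "dimensionless")[names(o$parameters)],
           rmse_uM = o$rmse, domain_uM = o$domain,
           clamp = o$clamp, record = o$record)
    } else if (inherits(o, "clamp_curve")) {
      list(type = "clamp_curve", clamp = o$clamp, record = o$record,
           values_uM = o$values, responses_uM = o$responses,
           flagged = o$flagged, conservation_ok = o$conservation_ok)
    } else {
      lapply(o, to_list)
    }
  }
  jsonlite::write_json(to_list(object), file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

#' Deviation between a phase loop and its clamp curve
#'
#' Normalizes the clamp curve with the loop's recorded (min, max) ranges,
#' interpolates it at each loop abscissa and reports the absolute
#' deviations in normalized units. For a fast pair the loop hugs the
#' steady-state curve, so the mean deviation is small (of the same order
#' as the loop area); slower pairs deviate more.
#'
#' @param curve a `clamp_curve` for the pair (clamp = X state, record = Y
#'   state).
#' @param loop the [phase_loop()] of the same pair, carrying `x_range` and
#'   `y_range`.
#' @return list with `mean`, `max` (normalized deviations) and
#'   `extrapolated_fraction` (share of loop abscissae outside the clamp
#'   domain, where the curve value is held at its end point).
#' @export
compare_clamp_to_loop <- function(curve, loop) {
  if (is.null(loop$x_range) || is.null(loop$y_range)) {
    stop_phaseloop("loop lacks normalization ranges", "phaseloop_clamp_error")
  }
  if (!identical(sort(c(curve$clamp, curve$record)), sort(loop$states))) {
    stop_phaseloop("curve and loop refer to different state pairs",
                   "phaseloop_clamp_error")
  }
  swap <- !identical(c(curve$clamp, curve$record), loop$states)
  lx <- if (swap) loop$y else loop$x
  ly <- if (swap) loop$x else loop$y
  xr <- if (swap) loop$y_range else loop$x_range
  yr <- if (swap) loop$x_range else loop$y_range
  ok <- is.finite(curve$responses)
  cx <- (curve$values[ok] - xr[1]) / (xr[2] - xr[1])
  cy <- (curve$responses[ok] - yr[1]) / (yr[2] - yr[1])
  outside <- lx < min(cx) | lx > max(cx)
  yhat <- stats::approx(cx, cy, xout = lx, rule = 2, ties = "ordered")$y
  dev <- abs(ly - yhat)
  list(mean = mean(dev), max = max(dev),
       extrapolated_fraction = mean(outside))
}
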