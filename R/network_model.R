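#' Construct a biochemical network model
#'
#' A `network_model` is an executable description of a (differential-)
#' algebraic reaction system. Every state variable belongs to exactly one of
#' four kinds: `ode` states evolve by a rate expression, `implicit_algebraic`
#' states are pinned by a residual equation that must vanish along the
#' solution, `explicit_algebraic` states are computed directly from other
#' states, and `parameterized` states are frozen at a fixed value (this is
#' how concentration clamps are realised). Rate, residual and explicit
#' expressions are stored as R expression trees over the state names,
#' parameter names and `t`, so that downstream tooling (direct-pair
#' detection, reduction, declarative file output) can inspect and rewrite
#' them.
#'
#' Units follow the usual single-cell signalling conventions: concentrations
#' in µM, time in s, first-order rates in s⁻¹, bimolecular rates in
#' µM⁻¹s⁻¹ and zeroth-order sources in µM s⁻¹.
#'
#' @param name model name (used in provenance records).
#' @param states ordered character vector of state-variable names.
#' @param kind named character vector mapping each state to one of
#'   `"ode"`, `"implicit_algebraic"`, `"explicit_algebraic"`,
#'   `"parameterized"`. Unnamed states default to `"ode"` when `kind` is
#'   omitted.
#' @param params named numeric vector of parameter values.
#' @param rates named list of expressions (or strings) giving d(state)/dt
#'   for every `ode` state.
#' @param residuals named list of expressions giving the residual for every
#'   `implicit_algebraic` state; the solver drives these to zero.
#' @param explicit named list of expressions for every `explicit_algebraic`
#'   state. Explicit states may reference each other acyclically.
#' @param fixed named numeric vector of values for `parameterized` states.
#' @param conserved list of conservation constraints, each a
#'   `list(total = <parameter name>, members = <character vector of states>)`;
#'   the sum of the members must equal the total parameter along any
#'   trajectory.
#' @param init optional named numeric vector of initial values (defaults to
#'   zero for dynamic states).
#'
#' @return an object of class `network_model`.
#' @seealso [make_toy_model()], [generate_cascade()], [read_model_file()]
#' @export
network_model <- function(name, states, kind = NULL, params = numeric(),
                          rates = list(), residuals = list(),
                          explicit = list(), fixed = numeric(),
                          conserved = list(), init = NULL) {
  states <- as.character(states)
  if (anyDuplicated(states)) {
    stop_phaseloop("duplicate state names", "phaseloop_model_error")
  }
  if (is.null(kind)) {
    kind <- stats::setNames(rep("ode", length(states)), states)
  }
  kind <- kind[states]
  names(kind) <- states
  valid_kinds <- c("ode", "implicit_algebraic", "explicit_algebraic",
                   "parameterized")
  if (anyNA(kind) || !all(kind %in% valid_kinds)) {
    stop_phaseloop("every state needs a kind in ode/implicit_algebraic/explicit_algebraic/parameterized",
                   "phaseloop_model_error")
  }
  as_lang <- function(x) {
    lapply(x, function(e) if (is.character(e)) str2lang(e) else e)
  }
  rates <- as_lang(rates)
  residuals <- as_lang(residuals)
  explicit <- as_lang(explicit)

  ode_states <- states[kind == "ode"]
  imp_states <- states[kind == "implicit_algebraic"]
  exp_states <- states[kind == "explicit_algebraic"]
  par_states <- states[kind == "parameterized"]

  if (!setequal(names(rates), ode_states)) {
    stop_phaseloop("rates must name exactly the ode states",
                   "phaseloop_model_error")
  }
  if (!setequal(names(residuals), imp_states)) {
    stop_phaseloop("residuals must name exactly the implicit_algebraic states",
                   "phaseloop_model_error")
  }
  if (!setequal(names(explicit), exp_states)) {
    stop_phaseloop("explicit must name exactly the explicit_algebraic states",
                   "phaseloop_model_error")
  }
  if (!all(par_states %in% names(fixed))) {
    stop_phaseloop("parameterized states need values in `fixed`",
                   "phaseloop_model_error")
  }

  known <- c(states, names(params), "t", "pi")
  for (s in c(names(rates), names(residuals), names(explicit))) {
    e <- rates[[s]] %||% residuals[[s]] %||% explicit[[s]]
    bad <- setdiff(all.vars(e), known)
    if (length(bad)) {
      stop_phaseloop(sprintf("expression for state '%s' references unknown symbols: %s",
                             s, paste(bad, collapse = ", ")),
                     "phaseloop_model_error")
    }
  }
  for (cc in conserved) {
    if (!is.list(cc) || !all(c("total", "members") %in% names(cc))) {
      stop_phaseloop("conserved entries need $total and $members",
                     "phaseloop_model_error")
    }
    if (!cc$total %in% names(params)) {
      stop_phaseloop(sprintf("conserved total '%s' is not a parameter", cc$total),
                     "phaseloop_model_error")
    }
    if (!all(cc$members %in% states)) {
      stop_phaseloop("conserved members must be states", "phaseloop_model_error")
    }
  }

  model <- structure(
    list(name = name, states = states, kind = kind,
         params = unlist(params) %||% numeric(),
         rates = rates[ode_states], residuals = residuals[imp_states],
         explicit = explicit[order_explicit(explicit, exp_states)],
         fixed = if (length(par_states)) fixed[par_states] else numeric(),
         conserved = conserved,
         init = init),
    class = "network_model")
  model
}

# Topologically order explicit-state definitions by their mutual references;
# cycles among explicit states are rejected.
order_explicit <- function(explicit, exp_states) {
  if (!length(exp_states)) return(character())
  deps <- lapply(explicit[exp_states], function(e) {
    intersect(all.vars(e), exp_states)
  })
  ordered <- character()
  remaining <- exp_states
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(s) {
      all(setdiff(deps[[s]], s) %in% ordered)
    }, logical(1))]
    if (!length(ready)) {
      stop_phaseloop(sprintf("cyclic dependency among explicit states: %s",
                             paste(remaining, collapse = " -> ")),
                     "phaseloop_model_error")
    }
    ordered <- c(ordered, ready)
    remaining <- setdiff(remaining, ready)
  }
  ordered
}

#' @export
print.network_model <- function(x, ...) {
  tab <- table(factor(x$kind, levels = c("ode", "implicit_algebraic",
                                         "explicit_algebraic", "parameterized")))
  cat(sprintf("network_model '%s': %d states (%d ode, %d implicit, %d explicit, %d parameterized), %d parameters\n",
              x$name, length(x$states), tab[["ode"]],
              tab[["implicit_algebraic"]], tab[["explicit_algebraic"]],
              tab[["parameterized"]], length(x$params)))
  if (length(x$conserved)) {
    for (cc in x$conserved) {
      cat(sprintf("  conserved: %s = %s\n", cc$total,
                  paste(cc$members, collapse = " + ")))
    }
  }
  invisible(x)
}

#' Model state and parameter accessors
#'
#' @param model a [network_model()].
#' @param kind optional kind filter for `model_states`.
#' @return `model_states`: character vector of state names;
#'   `model_params`: named numeric vector; `dynamic_states`: the ode +
#'   implicit-algebraic states that carry the model's dynamics.
#' @export
model_states <- function(model, kind = NULL) {
  if (is.null(kind)) return(model$states)
  model$states[model$kind %in% kind]
}

#' @rdname model_states
#' @export
model_params <- function(model) model$params

#' @rdname model_states
#' @export
dynamic_states <- function(model) {
  model$states[model$kind %in% c("ode", "implicit_algebraic")]
}

# Evaluation environment holding parameters, frozen states, the dynamic
# state values and t; explicit states are filled in evaluation order.
model_env <- function(model, xdyn, params, t = 0) {
  e <- new.env(parent = baseenv())
  for (nm in names(params)) assign(nm, params[[nm]], envir = e)
  for (nm in names(model$fixed)) assign(nm, model$fixed[[nm]], envir = e)
  for (nm in names(xdyn)) assign(nm, xdyn[[nm]], envir = e)
  assign("t", t, envir = e)
  for (nm in names(model$explicit)) {
    assign(nm, eval(model$explicit[[nm]], e), envir = e)
  }
  e
}

# Full named state vector (all kinds) at given dynamic values.
full_state <- function(model, xdyn, params = model$params, t = 0) {
  e <- model_env(model, xdyn, params, t)
  vapply(model$states, function(s) get(s, envir = e), numeric(1))
}

eval_derivs <- function(model, t, xdyn, params) {
  e <- model_env(model, xdyn, params, t)
  vapply(names(model$rates), function(s) eval(model$rates[[s]], e),
         numeric(1))
}

eval_residuals <- function(model, xdyn, params, t = 0) {
  if (!length(model$residuals)) return(numeric())
  e <- model_env(model, xdyn, params, t)
  vapply(names(model$residuals), function(s) eval(model$residuals[[s]], e),
         numeric(1))
}

# Stacked dynamic system in dynamic-state order: each ode state
# contributes its derivative, each implicit state its residual.
eval_dynamics <- function(model, t, xdyn, params) {
  e <- model_env(model, xdyn, params, t)
  vapply(dynamic_states(model), function(s) {
    eval((model$rates[[s]] %||% model$residuals[[s]]), e)
  }, numeric(1))
}

#' Executable right-hand side, residual and explicit-state functions
#'
#' These close over the model and satisfy the evaluation contracts used by
#' the integrators: `model_rhs` maps `(t, state, params)` to the time
#' derivatives of the ode states, `model_residuals` maps `(state, params)`
#' to the residual vector of the implicit-algebraic states, and
#' `model_explicit` maps `(state, params)` to the values of the
#' explicit-algebraic states. `state` is the named vector of dynamic
#' (ode + implicit) states.
#'
#' @param model a [network_model()].
#' @return a function; see Details.
#' @export
model_rhs <- function(model) {
  function(t, state, params = model$params) eval_derivs(model, t, state, params)
}

#' @rdname model_rhs
#' @export
model_residuals <- function(model) {
  function(state, params = model$params) eval_residuals(model, state, params)
}

#' @rdname model_rhs
#' @export
model_explicit <- function(model) {
  function(state, params = model$params) {
    fs <- full_state(model, state, params)
    fs[model$kind[names(fs)] == "explicit_algebraic"]
  }
}

# Expression defining a state, whatever its kind (NULL for parameterized).
state_expr <- function(model, state) {
  model$rates[[state]] %||% model$residuals[[state]] %||%
    model$explicit[[state]]
}

#' The three-species toy pathway
#'
#' A linear irreversible pathway source → A → B → C → sink with first-order
#' mass-action kinetics: dA/dt = k1 − k2·A, dB/dt = k2·A − k3·B,
#' dC/dt = k3·B − k4·C. The stimulus is the zeroth-order source `k1`
#' (µM s⁻¹), switched between 100 during the stimulus window and 0 outside
#' it by the protocol; k2 = 1, k3 = 10, k4 = 1 s⁻¹. During sustained
#' stimulus the steady state is A = k1/k2 = 100 µM, B = (k2/k3)·A = 10 µM,
#' C = (k3/k4)·B = 100 µM, so B tracks one tenth of A — the A–B pair
#' equilibrates fast while C lags.
#'
#' @return a [network_model()] with states A, B, C.
#' @export
make_toy_model <- function() {
  network_model(
    name = "toy",
    states = c("A", "B", "C"),
    kind = c(A = "ode", B = "ode", C = "ode"),
    params = c(k1 = 0, k2 = 1, k3 = 10, k4 = 1),
    rates = list(A = quote(k1 - k2 * A),
                 B = quote(k2 * A - k3 * B),
                 C = quote(k3 * B - k4 * C)),
    init = c(A = 0, B = 0, C = 0))
}

#' @rdname make_toy_model
#' @param t_off end of the stimulus window (s).
#' @param t_end end of the simulated window (s).
#' @param n_out number of output samples.
#' @return `toy_protocol`: the matching [stimulus_protocol()] switching `k1`
#'   to 100 µM s⁻¹ on \[0, t_off\] and back to 0.
#' @export
toy_protocol <- function(t_off = 10, t_end = 20, n_out = 2000) {
  stimulus_protocol("k1", on_value = 100, off_value = 0,
                    t_on = 0, t_off = t_off, t_end = t_end, n_out = n_out)
}

#' Generate a synthetic linear mass-action cascade
#'
#' Builds a chain source → S1 → S2 → … → Sn → sink with first-order rates
#' `rate_ladder` and a switchable zeroth-order source feeding S1. The
#' Jacobian of the chain is lower bidiagonal with eigenvalues
#' `-rate_ladder`, so the timescale structure is known analytically; the
#' ratio of consecutive rates sets the timescale separation of each
#' adjacent pair. When `rate_ladder` is omitted the rates are drawn
#' log-uniformly from \[0.1, 100\] s⁻¹ under `seed`, which makes the
#' generator a reproducible source of cascades with mixed fast/medium
#' adjacent pairs.
#'
#' @param n_species number of chain species.
#' @param rate_ladder first-order rate constants, one per species (s⁻¹);
#'   must be positive.
#' @param input_magnitude source strength during stimulus (µM s⁻¹).
#' @param seed integer seed for the random rate draw (required when
#'   `rate_ladder` is omitted). The draw is isolated from the caller's RNG
#'   state.
#' @return a [network_model()] with states S1…Sn, rate parameters r1…rn and
#'   source parameter `input` (0 at rest).
#' @export
generate_cascade <- function(n_species, rate_ladder = NULL,
                             input_magnitude = 1, seed = NULL) {
  if (n_species < 1) {
    stop_phaseloop("n_species must be >= 1", "phaseloop_model_error")
  }
  if (is.null(rate_ladder)) {
    if (is.null(seed)) {
      stop_phaseloop("seed is required when rate_ladder is not given",
                     "phaseloop_model_error")
    }
    rate_ladder <- with_seed(seed, 10^stats::runif(n_species, -1, 2))
  }
  if (length(rate_ladder) != n_species) {
    stop_phaseloop("rate_ladder must have one rate per species",
                   "phaseloop_model_error")
  }
  if (any(!is.finite(rate_ladder)) || any(rate_ladder <= 0)) {
    stop_phaseloop("rate_ladder entries must be positive", "phaseloop_model_error")
  }
  states <- paste0("S", seq_len(n_species))
  rpar <- paste0("r", seq_len(n_species))
  params <- c(stats::setNames(rate_ladder, rpar), input = 0)
  rates <- vector("list", n_species)
  names(rates) <- states
  rates[[1L]] <- str2lang(sprintf("input - r1 * S1"))
  if (n_species > 1) {
    for (i in 2:n_species) {
      rates[[i]] <- str2lang(sprintf("r%d * %s - r%d * %s",
                                     i - 1L, states[i - 1L], i, states[i]))
    }
  }
  m <- network_model(
    name = sprintf("cascade%d", n_species),
    states = states, kind = stats::setNames(rep("ode", n_species), states),
    params = params, rates = rates,
    init = stats::setNames(rep(0, n_species), states))
  attr(m, "input_magnitude") <- input_magnitude
  attr(m, "rate_ladder") <- rate_ladder
  m
}

#' @rdname generate_cascade
#' @param model a cascade model from `generate_cascade`.
#' @param n_out number of output samples.
#' @return `cascade_protocol`: a [stimulus_protocol()] switching `input` to
#'   the cascade's `input_magnitude`, with the window scaled to 8 times the
#'   slowest chain timescale so every species equilibrates and relaxes.
#' @export
cascade_protocol <- function(model, n_out = 2000) {
  rates <- attr(model, "rate_ladder")
  if (is.null(rates)) {
    stop_phaseloop("not a generated cascade model", "phaseloop_model_error")
  }
  tau <- 1 / min(rates)
  stimulus_protocol("input",
                    on_value = attr(model, "input_magnitude"), off_value = 0,
                    t_on = 0, t_off = 8 * tau, t_end = 16 * tau, n_out = n_out)
}

# Evaluate code with a temporary RNG seed, restoring the caller's state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Direct species relationships of a model
#'
#' A pair (u, v) is *direct* when one state's defining expression (rate,
#' residual or explicit definition) references the other: these are the
#' adjacent, mechanistically coupled pairs that are meaningful for
#' reduction, as opposed to indirect pairs linked only through
#' intermediates.
#'
#' @param model a [network_model()].
#' @return data frame with columns `a`, `b` (state names, `a` < `b` in
#'   model order), `a_to_b`/`b_to_a` (logical: does b's expression reference
#'   a, and vice versa) and `downstream` (`"a"`, `"b"` or `"both"` — the
#'   state(s) computed from the other).
#' @export
direct_pairs <- function(model) {
  states <- model$states
  refs <- lapply(states, function(s) {
    e <- state_expr(model, s)
    if (is.null(e)) character() else setdiff(intersect(all.vars(e), states), s)
  })
  names(refs) <- states
  out <- list()
  for (i in seq_along(states)) {
    for (j in seq_along(states)) {
      if (j <= i) next
      a <- states[i]
      b <- states[j]
      a_to_b <- a %in% refs[[b]]   # b computed from a
      b_to_a <- b %in% refs[[a]]
      if (a_to_b || b_to_a) {
        downstream <- if (a_to_b && b_to_a) "both" else if (a_to_b) "b" else "a"
        out[[length(out) + 1L]] <- data.frame(
          a = a, b = b, a_to_b = a_to_b, b_to_a = b_to_a,
          downstream = downstream, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(a = character(), b = character(),
                      a_to_b = logical(), b_to_a = logical(),
                      downstream = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
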