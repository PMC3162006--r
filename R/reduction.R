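#' Reduction actions and plans
#'
#' A `reduction_action` records what happens to one state when the model
#' is reduced. The vocabulary mirrors the reduction ledger of the method:
#' \describe{
#'   \item{keep_ode}{state retained unchanged (differential or implicit).}
#'   \item{ode_to_algebraic}{a fast ode state is replaced by a fitted
#'     explicit relation of its `parent` state (requires a
#'     [fit_relation()] result at apply time).}
#'   \item{implicit_to_explicit}{an implicit algebraic state is replaced by
#'     a fitted explicit relation of its `parent`.}
#'   \item{conservation_eliminate}{state solved analytically from a
#'     conservation total: `state = total − sum(other members)`.}
#'   \item{free_equals_total}{state approximated by its total-concentration
#'     parameter (free ≈ total).}
#'   \item{assume_negligible}{state set to zero (negligible pool).}
#'   \item{assume_equal}{state set equal to another state.}
#' }
#' The last four encode model-specific knowledge and are supplied by the
#' user; only the fitted conversions are proposed automatically from
#' phase-loop areas.
#'
#' @param state target state name.
#' @param action one of the action names above.
#' @param parent parent state for fitted conversions.
#' @param total,members conservation total parameter and member states for
#'   `conservation_eliminate` (members include `state`).
#' @param param total parameter for `free_equals_total`.
#' @param other state for `assume_equal`.
#' @param justification free text.
#' @param area phase-loop area backing the decision (NA for user actions).
#' @return a `reduction_action`.
#' @export
reduction_action <- function(state,
                             action = c("keep_ode", "ode_to_algebraic",
                                        "implicit_to_explicit",
                                        "conservation_eliminate",
                                        "free_equals_total",
                                        "assume_negligible", "assume_equal"),
                             parent = NULL, total = NULL, members = NULL,
                             param = NULL, other = NULL,
                             justification = "", area = NA_real_) {
  action <- match.arg(action)
  if (action %in% c("ode_to_algebraic", "implicit_to_explicit") &&
      is.null(parent)) {
    stop_phaseloop(sprintf("action '%s' needs a parent state", action),
                   "phaseloop_plan_error")
  }
  if (action == "conservation_eliminate" && (is.null(total) || is.null(members))) {
    stop_phaseloop("conservation_eliminate needs total and members",
                   "phaseloop_plan_error")
  }
  if (action == "free_equals_total" && is.null(param)) {
    stop_phaseloop("free_equals_total needs the total parameter name",
                   "phaseloop_plan_error")
  }
  if (action == "assume_equal" && is.null(other)) {
    stop_phaseloop("assume_equal needs the other state", "phaseloop_plan_error")
  }
  structure(list(state = state, action = action, parent = parent,
                 total = total, members = members, param = param,
                 other = other, justification = justification, area = area),
            class = "reduction_action")
}

#' @rdname reduction_action
#' @param actions list of `reduction_action`s, at most one per state.
#' @param threshold the area threshold that produced the plan.
#' @export
reduction_plan <- function(actions, threshold = NA_real_) {
  states <- vapply(actions, function(a) a$state, character(1))
  if (anyDuplicated(states)) {
    stop_phaseloop(sprintf("state(s) with more than one action: %s",
                           paste(unique(states[duplicated(states)]),
                                 collapse = ", ")),
                   "phaseloop_plan_error")
  }
  names(actions) <- states
  structure(list(actions = actions, threshold = threshold),
            class = "reduction_plan")
}

#' @export
print.reduction_plan <- function(x, ...) {
  kinds <- vapply(x$actions, function(a) a$action, character(1))
  cat(sprintf("reduction_plan (threshold %s): %d actions, %d reductions\n",
              format(x$threshold), length(x$actions),
              sum(kinds != "keep_ode")))
  for (a in x$actions) {
    if (a$action == "keep_ode") next
    extra <- switch(a$action,
                    ode_to_algebraic = ,
                    implicit_to_explicit = sprintf(" <- fit(%s)", a$parent),
                    conservation_eliminate = sprintf(" = %s - sum(others)", a$total),
                    free_equals_total = sprintf(" = %s", a$param),
                    assume_equal = sprintf(" = %s", a$other),
                    "")
    cat(sprintf("  %s: %s%s%s\n", a$state, a$action, extra,
                if (is.finite(a$area)) sprintf(" [area %.3f]", a$area) else ""))
  }
  invisible(x)
}

# Walk parent links among reduced states; a revisit is a cycle.
check_plan_cycles <- function(plan) {
  parents <- list()
  for (a in plan$actions) {
    p <- switch(a$action,
                ode_to_algebraic = ,
                implicit_to_explicit = a$parent,
                assume_equal = a$other,
                NULL)
    if (!is.null(p)) parents[[a$state]] <- p
  }
  for (v in names(parents)) {
    seen <- v
    u <- parents[[v]]
    while (!is.null(u) && u %in% names(parents)) {
      if (u %in% seen) {
        stop_phaseloop(sprintf("cyclic reduction dependency: %s -> %s",
                               paste(seen, collapse = " -> "), u),
                       "phaseloop_plan_error")
      }
      seen <- c(seen, u)
      u <- parents[[u]]
    }
  }
  invisible(TRUE)
}

#' Propose a reduction plan from phase-loop areas
#'
#' Every direct pair whose hysteresis area is at or below `threshold`
#' marks its downstream state (the one computed from the other) as
#' reducible: ode states become `ode_to_algebraic`, implicit algebraic
#' states become `implicit_to_explicit`, each in terms of the upstream
#' parent. When a state has several fast parents the smallest-area pair
#' wins. All remaining dynamic states `keep_ode`. Conservation
#' eliminations and total/negligible approximations encode model-specific
#' knowledge and are passed in as `user_actions`, which take precedence.
#' Mutually dependent reductions (two states each reduced in terms of the
#' other) are rejected with the cycle reported; supply `prefer_parent` to
#' break such ties.
#'
#' @param am an `area_matrix` from [pairwise_area_matrix()].
#' @param classes classification from [classify_pairs()] (used for the
#'   recorded justification; the numeric decision uses `threshold`).
#' @param model the [network_model()] the areas were computed from.
#' @param threshold area at or below which a direct relationship is
#'   reduced.
#' @param user_actions list of [reduction_action()]s supplied by the user.
#' @param prefer_parent named character vector, `state = parent`, breaking
#'   direction ties for mutually coupled pairs.
#' @return a [reduction_plan()].
#' @export
propose_plan <- function(am, classes, model, threshold = 0.05,
                         user_actions = list(), prefer_parent = NULL) {
  dp <- direct_pairs(model)
  dyn <- dynamic_states(model)
  candidates <- list()   # state -> data.frame(parent, area)
  add_candidate <- function(v, u, area) {
    if (!v %in% dyn) return()
    candidates[[v]] <<- rbind(candidates[[v]],
                              data.frame(parent = u, area = area))
  }
  for (i in seq_len(nrow(dp))) {
    a <- dp$a[i]
    b <- dp$b[i]
    if (!(a %in% rownames(am) && b %in% rownames(am))) next
    area <- am[a, b]
    if (area > threshold) next
    if (dp$downstream[i] %in% c("b", "both")) add_candidate(b, a, area)
    if (dp$downstream[i] %in% c("a", "both")) add_candidate(a, b, area)
  }
  # a preference `state = parent` picks the direction of a mutual pair:
  # keep only that parent for `state` and drop the reverse reduction
  if (!is.null(prefer_parent)) {
    for (v in names(prefer_parent)) {
      u <- prefer_parent[[v]]
      if (!is.null(candidates[[v]])) {
        candidates[[v]] <- candidates[[v]][candidates[[v]]$parent == u, ,
                                           drop = FALSE]
        if (!nrow(candidates[[v]])) candidates[[v]] <- NULL
      }
      if (!is.null(candidates[[u]])) {
        candidates[[u]] <- candidates[[u]][candidates[[u]]$parent != v, ,
                                           drop = FALSE]
        if (!nrow(candidates[[u]])) candidates[[u]] <- NULL
      }
    }
  }
  user_states <- vapply(user_actions, function(x) x$state, character(1))
  actions <- user_actions
  for (v in names(candidates)) {
    if (v %in% user_states) next
    cand <- candidates[[v]]
    best <- cand[which.min(cand$area), ]
    act <- if (model$kind[[v]] == "implicit_algebraic")
      "implicit_to_explicit" else "ode_to_algebraic"
    actions[[length(actions) + 1L]] <- reduction_action(
      v, act, parent = best$parent, area = best$area,
      justification = sprintf("direct pair (%s, %s) area %.4f <= %.4f",
                              best$parent, v, best$area, threshold))
  }
  done <- vapply(actions, function(a) a$state, character(1))
  for (v in setdiff(dyn, done)) {
    actions[[length(actions) + 1L]] <- reduction_action(v, "keep_ode")
  }
  plan <- reduction_plan(actions, threshold = threshold)
  check_plan_cycles(plan)
  plan
}

#' Fit the explicit relations a plan requires
#'
#' Runs a concentration-clamp sweep for every fitted conversion in the
#' plan (clamping the parent, recording the target, with the stimulus
#' input held at its "on" value) and fits the candidate forms.
#'
#' @param model the original [network_model()].
#' @param plan a [reduction_plan()].
#' @param protocol the reference [stimulus_protocol()]; its on-value
#'   defines the clamp context and its transient defines the default
#'   sweep range (0 to 1.5 times the parent's maximum).
#' @param sweep_points sweep size.
#' @param forms candidate forms for [fit_relation()].
#' @return named list of `fitted_relation`s (by target state), with the
#'   clamp curves attached as attribute `"curves"`.
#' @export
fit_plan_relations <- function(model, plan, protocol, sweep_points = 25L,
                               forms = relation_forms()) {
  context <- stats::setNames(list(protocol$on_value), protocol$parameter)
  tc <- simulate_transient(model, protocol)
  fits <- list()
  curves <- list()
  for (a in plan$actions) {
    if (!a$action %in% c("ode_to_algebraic", "implicit_to_explicit")) next
    top <- 1.5 * max(tc$values[, a$parent])
    cur <- concentration_clamp(model, clamp = a$parent,
                               values = seq(0, top, length.out = sweep_points),
                               record = a$state, context = context)
    fits[[a$state]] <- fit_relation(cur, forms = forms)
    curves[[a$state]] <- cur
  }
  attr(fits, "curves") <- curves
  fits
}

#' Apply a reduction plan to a model
#'
#' Rewrites the model according to the plan: fitted conversions turn the
#' target state into an explicit algebraic state evaluating the fitted
#' relation of its parent, conservation eliminations and the
#' total/negligible/equal approximations become the corresponding explicit
#' expressions, and everything else is untouched. Reduced species are
#' still predicted by the reduced model — as explicit algebraic variables
#' rather than differential or implicit ones. Parameters no longer
#' referenced by any remaining expression are pruned, which is what makes
#' a reduced model structurally insensitive to perturbations of
#' parameters it no longer uses.
#'
#' @param model the original [network_model()].
#' @param plan a [reduction_plan()].
#' @param fits named list of `fitted_relation`s for every fitted
#'   conversion (see [fit_plan_relations()]).
#' @return a new [network_model()].
#' @export
apply_plan <- function(model, plan, fits = list()) {
  check_plan_cycles(plan)
  m <- model
  n_red <- 0L
  for (a in plan$actions) {
    if (!a$state %in% model$states) {
      stop_phaseloop(sprintf("plan action for unknown state '%s'", a$state),
                     "phaseloop_plan_error")
    }
    if (a$action == "keep_ode") next
    expr <- switch(a$action,
      ode_to_algebraic = ,
      implicit_to_explicit = {
        fit <- fits[[a$state]]
        if (is.null(fit)) {
          stop_phaseloop(sprintf("missing fitted relation for state '%s'", a$state),
                         "phaseloop_plan_error")
        }
        relation_expr(fit, a$parent)
      },
      conservation_eliminate = {
        others <- setdiff(a$members, a$state)
        Reduce(function(l, r) call("-", l, as.name(r)), others,
               init = as.name(a$total))
      },
      free_equals_total = as.name(a$param),
      assume_negligible = quote(0),
      assume_equal = as.name(a$other))
    n_red <- n_red + as.integer(m$kind[[a$state]] %in%
                                  c("ode", "implicit_algebraic"))
    m$kind[a$state] <- "explicit_algebraic"
    m$rates[[a$state]] <- NULL
    m$residuals[[a$state]] <- NULL
    m$explicit[[a$state]] <- expr
    m$fixed <- m$fixed[setdiff(names(m$fixed), a$state)]
  }
  used <- unique(unlist(lapply(c(m$rates, m$residuals, m$explicit), all.vars)))
  keep_par <- union(intersect(names(m$params), used),
                    vapply(m$conserved, function(cc) cc$total, character(1)))
  params <- m$params[intersect(names(m$params), keep_par)]
  out <- network_model(
    name = sprintf("%s_reduced%d", model$name,
                   sum(m$kind == "ode")),
    states = m$states, kind = m$kind, params = params,
    rates = m$rates, residuals = m$residuals, explicit = m$explicit,
    fixed = m$fixed, conserved = m$conserved, init = m$init)
  n_dyn_orig <- length(dynamic_states(model))
  n_dyn_new <- length(dynamic_states(out))
  stopifnot(n_dyn_new == n_dyn_orig - n_red)
  attr(out, "plan") <- plan
  out
}

#' Score a reduced model against the original
#'
#' Simulates both models under the same protocol and reports, per species,
#' the mean error (%) of the reduced trajectory: the time-averaged
#' absolute difference divided by the original state's dynamic range over
#' the protocol (its max minus min), times 100. Range normalization is
#' the same convention used to normalize the phase loops; a pointwise
#' relative metric (`metric = "relative"`, difference over
#' `max(|x_orig|, atol)`) is available as an alternative. The overall
#' error is the arithmetic mean over included species. Species fixed
#' under the protocol (original dynamic range below `static_tol`) cannot
#' be range-normalized and are excluded automatically, alongside any
#' states named in `excluded` or absent from either model.
#'
#' @param original,reduced [network_model()]s sharing state names.
#' @param protocol a [stimulus_protocol()].
#' @param overrides scenario parameter overrides; entries naming
#'   parameters a model does not carry are skipped for that model and
#'   reported as structurally insensitive.
#' @param excluded states excluded from scoring (with reasons as names,
#'   optionally).
#' @param metric `"range"` (default) or `"relative"`.
#' @param static_tol relative range below which a species counts as fixed.
#' @return an `error_report`: data frame (`species`, `mean_error_pct`)
#'   with attributes `overall` (mean %), `excluded`, `insensitive_params`
#'   and `protocol`.
#' @export
score_reduction <- function(original, reduced, protocol, overrides = list(),
                            excluded = character(),
                            metric = c("range", "relative"),
                            static_tol = 1e-8) {
  metric <- match.arg(metric)
  ov <- unlist(overrides) %||% numeric()
  split_ov <- function(model) {
    ok <- names(ov) %in% names(model$params)
    list(use = as.list(ov[ok]), missing = names(ov)[!ok])
  }
  ov_o <- split_ov(original)
  ov_r <- split_ov(reduced)
  insensitive <- unique(c(ov_o$missing, ov_r$missing))
  sim <- function(model, use) {
    if (!protocol$parameter %in% names(model$params)) {
      # stimulus input eliminated during reduction: the model cannot
      # respond; simulate it at rest (flat trajectories)
      flat <- stimulus_protocol(names(model$params)[1],
                                on_value = model$params[[1]],
                                off_value = model$params[[1]],
                                t_on = protocol$t_on, t_off = protocol$t_off,
                                t_end = protocol$t_end, n_out = protocol$n_out)
      return(simulate_transient(model, flat, overrides = use))
    }
    simulate_transient(model, protocol, overrides = use)
  }
  tc_o <- sim(original, ov_o$use)
  tc_r <- sim(reduced, ov_r$use)
  common <- intersect(colnames(tc_o$values), colnames(tc_r$values))
  lost <- setdiff(union(colnames(tc_o$values), colnames(tc_r$values)), common)
  species <- setdiff(common, excluded)
  err <- rep(NA_real_, length(species))
  names(err) <- species
  auto_excluded <- character()
  nonfinite <- character()
  for (s in species) {
    xo <- tc_o$values[, s]
    xr <- tc_r$values[, s]
    if (any(!is.finite(xo)) || any(!is.finite(xr))) {
      nonfinite <- c(nonfinite, s)
      warning(sprintf("state '%s' has non-finite values and is excluded from scoring", s),
              call. = FALSE)
      next
    }
    rng <- max(xo) - min(xo)
    if (metric == "range") {
      if (rng <= static_tol * max(abs(xo), 1)) {
        auto_excluded <- c(auto_excluded, s)
        next
      }
      err[s] <- mean(abs(xr - xo)) / rng * 100
    } else {
      err[s] <- mean(abs(xr - xo) / pmax(abs(xo), 1e-12)) * 100
    }
  }
  keep <- !is.na(err)
  report <- data.frame(species = species[keep],
                       mean_error_pct = unname(err[keep]),
                       stringsAsFactors = FALSE)
  structure(report,
            overall = mean(report$mean_error_pct),
            excluded = list(user = excluded, fixed = auto_excluded,
                            nonfinite = nonfinite, unmapped = lost),
            insensitive_params = insensitive,
            protocol = protocol, metric = metric,
            class = c("error_report", "data.frame"))
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("error_report (%s metric): overall mean %.3f%% over %d species\n",
              attr(x, "metric"), attr(x, "overall"), nrow(x)))
  print.data.frame(cbind(x["species"],
                         mean_error_pct = round(x$mean_error_pct, 3)),
                   row.names = FALSE)
  ins <- attr(x, "insensitive_params")
  if (length(ins)) {
    cat(sprintf("structurally insensitive to: %s\n", paste(ins, collapse = ", ")))
  }
  invisible(x)
}

#' Perturbation scenario
#'
#' A named stimulus condition: a protocol (which parameter is switched on
#' and off, and when) plus additional fixed parameter overrides.
#'
#' @param name scenario name.
#' @param protocol a [stimulus_protocol()].
#' @param overrides named parameter overrides applied throughout.
#' @return a `scenario` object.
#' @export
scenario <- function(name, protocol, overrides = list()) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  structure(list(name = name, protocol = protocol, overrides = overrides),
            class = "scenario")
}

#' Score a reduced model across perturbation scenarios
#'
#' Runs [score_reduction()] once per scenario. A scenario parameter that a
#' reduced model no longer carries is reported in that report's
#' `insensitive_params` — the reduced model is structurally insensitive to
#' the perturbation, which is itself a diagnostic outcome (the model
#' cannot respond because the mechanism was eliminated), not an error.
#'
#' @param original,reduced [network_model()]s.
#' @param scenarios list of [scenario()]s.
#' @param ... passed to [score_reduction()].
#' @return named list of `error_report`s.
#' @export
run_perturbation_suite <- function(original, reduced, scenarios, ...) {
  out <- list()
  for (sc in scenarios) {
    rep <- score_reduction(original, reduced, sc$protocol,
                           overrides = sc$overrides, ...)
    attr(rep, "scenario") <- sc$name
    out[[sc$name]] <- rep
  }
  out
}

#' One-call reduction pipeline
#'
#' Convenience wrapper chaining the full workflow on one model: simulate
#' the transient, normalize, compute the pairwise area matrix, classify
#' direct pairs, propose the plan at `threshold`, run the concentration
#' clamps and fits, apply the plan and score the result.
#'
#' @param model a [network_model()].
#' @param protocol a [stimulus_protocol()].
#' @param threshold reduction area threshold.
#' @param user_actions,prefer_parent passed to [propose_plan()].
#' @param sweep_points clamp sweep size.
#' @param excluded states excluded from scoring.
#' @return list with `reduced` (the reduced model), `plan`, `fits`,
#'   `area_matrix`, `classes`, `report` (an `error_report`) and `ntc`.
#' @export
reduce_model <- function(model, protocol, threshold = 0.05,
                         user_actions = list(), prefer_parent = NULL,
                         sweep_points = 25L, excluded = character()) {
  tc <- simulate_transient(model, protocol)
  ntc <- normalize_timecourses(tc)
  am <- pairwise_area_matrix(ntc)
  classes <- classify_pairs(am, direct = direct_pairs(model))
  plan <- propose_plan(am, classes, model, threshold = threshold,
                       user_actions = user_actions,
                       prefer_parent = prefer_parent)
  fits <- fit_plan_relations(model, plan, protocol,
                             sweep_points = sweep_points)
  reduced <- apply_plan(model, plan, fits)
  report <- score_reduction(model, reduced, protocol, excluded = excluded)
  list(reduced = reduced, plan = plan, fits = fits, area_matrix = am,
       classes = classes, report = report, ntc = ntc)
}

#' Serialize a reduction plan or error report
#'
#' Plans serialize to JSON; error reports render either as JSON or as a
#' summary-table CSV (`species,mean_error_pct`, or a two-model comparison
#' when a second report is given).
#'
#' @param plan a [reduction_plan()].
#' @param file output path.
#' @export
write_plan_json <- function(plan, file) {
  acts <- lapply(plan$actions, function(a) {
    Filter(Negate(is.null),
           list(state = a$state, action = a$action, parent = a$parent,
                total = a$total, members = a$members, param = a$param,
                other = a$other, area = if (is.finite(a$area)) a$area,
                justification = if (nzchar(a$justification)) a$justification))
  })
  jsonlite::write_json(list(threshold = plan$threshold,
                            actions = unname(acts)),
                       file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}

#' @rdname write_plan_json
#' @param report an `error_report`.
#' @param report2 optional second `error_report` (e.g. a further-reduced
#'   model) written as an extra column.
#' @param labels column labels for the one or two reports.
#' @export
write_error_report_csv <- function(report, file, report2 = NULL,
                                   labels = c("mean_error_pct", "mean_error_pct_2")) {
  if (is.null(report2)) {
    lines <- c(paste(c("species", labels[1]), collapse = ","),
               paste(report$species, fmt_num(report$mean_error_pct), sep = ","),
               paste("overall_mean", fmt_num(attr(report, "overall")), sep = ","))
  } else {
    sp <- union(report$species, report2$species)
    e1 <- report$mean_error_pct[match(sp, report$species)]
    e2 <- report2$mean_error_pct[match(sp, report2$species)]
    lines <- c(paste(c("species", labels), collapse = ","),
               paste(sp, fmt_num(e1), fmt_num(e2), sep = ","),
               paste("overall_mean", fmt_num(attr(report, "overall")),
                     fmt_num(attr(report2, "overall")), sep = ","))
  }
  writeLines(lines, file)
  invisible(file)
}
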