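test_that("toy reduction replaces B by its steady-state relation and tracks the full model", {
  toy <- make_toy_model()
  res <- reduce_model(toy, toy_protocol(), threshold = 0.1)
  acts <- vapply(res$plan$actions, function(a) a$action, character(1))
  expect_identical(unname(acts[match("B", names(res$plan$actions))]),
                   "ode_to_algebraic")
  expect_identical(sum(acts != "keep_ode"), 1L)
  expect_identical(sort(model_states(res$reduced, "ode")), c("A", "C"))
  expect_identical(model_states(res$reduced, "explicit_algebraic"), "B")
  # B = (k2/k3) A fitted from clamps
  expect_equal(unname(res$fits$B$parameters[["slope"]]), 0.1, tolerance = 1e-6)
  # A's equation is untouched; B and C carry a small nonzero error
  errs <- setNames(res$report$mean_error_pct, res$report$species)
  expect_lt(errs[["A"]], 1e-4)
  expect_gt(errs[["B"]], 1e-3)
  expect_lt(errs[["C"]], 2)
  expect_lt(attr(res$report, "overall"), 2)
})

test_that("threshold 0 yields the identity plan and an identical model", {
  toy <- make_toy_model()
  ntc <- normalize_timecourses(simulate_transient(toy, toy_protocol()))
  am <- pairwise_area_matrix(ntc)
  cl <- classify_pairs(am, direct = direct_pairs(toy))
  plan <- propose_plan(am, cl, toy, threshold = 0)
  expect_true(all(vapply(plan$actions, function(a) a$action, character(1)) ==
                    "keep_ode"))
  m0 <- apply_plan(toy, plan)
  tc1 <- simulate_transient(toy, toy_protocol(n_out = 300))
  tc2 <- simulate_transient(m0, toy_protocol(n_out = 300))
  expect_identical(tc1$values, tc2$values)
})

test_that("scoring a model against itself gives zero errors", {
  toy <- make_toy_model()
  rep <- score_reduction(toy, toy, toy_protocol(n_out = 300))
  expect_equal(rep$mean_error_pct, rep(0, 3))
  expect_identical(attr(rep, "overall"), 0)
  # overall mean is the arithmetic mean of the per-state errors
  res <- reduce_model(toy, toy_protocol(), threshold = 0.1)
  expect_equal(attr(res$report, "overall"), mean(res$report$mean_error_pct))
})

test_that("ode-state count drops by exactly the number of reductions", {
  for (s in c(5, 9)) {
    m <- generate_cascade(4, seed = s)
    res <- reduce_model(m, cascade_protocol(m, n_out = 600), threshold = 0.5)
    n_red <- sum(vapply(res$plan$actions, function(a) a$action != "keep_ode",
                        logical(1)))
    expect_identical(sum(res$reduced$kind == "ode"),
                     sum(m$kind == "ode") - n_red)
  }
})

test_that("user-declared actions rewrite states as documented", {
  bind <- binding_model()
  plan <- reduction_plan(list(
    reduction_action("E", "conservation_eliminate", total = "Etot",
                     members = c("E", "ES")),
    reduction_action("ES", "keep_ode")))
  red <- apply_plan(bind, plan)
  expect_identical(red$kind[["E"]], "explicit_algebraic")
  tc1 <- simulate_transient(bind, binding_protocol())
  tc2 <- simulate_transient(red, binding_protocol())
  expect_equal(tc2$values, tc1$values, tolerance = 1e-6)

  m <- network_model("lr", states = c("L", "R"),
                     kind = c(L = "ode", R = "ode"),
                     params = c(kon = 0.2, Ltot = 3, kin = 1),
                     rates = list(L = quote(kin * (Ltot - L)),
                                  R = quote(kon * L - kon * R)),
                     init = c(L = 0, R = 0))
  planL <- reduction_plan(list(
    reduction_action("L", "free_equals_total", param = "Ltot"),
    reduction_action("R", "keep_ode")))
  redL <- apply_plan(m, planL)
  ss <- find_steady_state(redL)
  expect_equal(unname(ss[["L"]]), 3)

  planN <- reduction_plan(list(reduction_action("L", "assume_negligible"),
                               reduction_action("R", "keep_ode")))
  redN <- apply_plan(m, planN)
  expect_equal(unname(find_steady_state(redN)[["L"]]), 0)

  planE <- reduction_plan(list(reduction_action("L", "assume_equal", other = "R"),
                               reduction_action("R", "keep_ode")))
  redE <- apply_plan(m, planE)
  ssE <- find_steady_state(redE, x0 = c(R = 1))
  expect_equal(unname(ssE[["L"]]), unname(ssE[["R"]]))
})

test_that("cyclic reduction dependencies are rejected with the cycle reported", {
  plan <- reduction_plan(list(
    reduction_action("E", "ode_to_algebraic", parent = "ES"),
    reduction_action("ES", "ode_to_algebraic", parent = "E")))
  err <- tryCatch(phaseloop:::check_plan_cycles(plan), condition = identity)
  expect_s3_class(err, "phaseloop_plan_error")
  expect_match(conditionMessage(err), "E")
  expect_match(conditionMessage(err), "ES")
  expect_phaseloop_error(apply_plan(binding_model(), plan, fits = list()),
                         "phaseloop_plan_error")
})

test_that("mutually fast pairs require a direction preference", {
  bind <- binding_model()
  pr <- binding_protocol()
  ntc <- normalize_timecourses(simulate_transient(bind, pr))
  am <- pairwise_area_matrix(ntc)
  cl <- classify_pairs(am, direct = direct_pairs(bind))
  if (am["E", "ES"] <= 0.5) {
    expect_phaseloop_error(propose_plan(am, cl, bind, threshold = 0.5),
                           "phaseloop_plan_error")
    plan <- propose_plan(am, cl, bind, threshold = 0.5,
                         prefer_parent = c(ES = "E"))
    expect_identical(plan$actions[["ES"]]$action, "ode_to_algebraic")
    expect_identical(plan$actions[["E"]]$action, "keep_ode")
  }
})

test_that("missing fitted relations are reported", {
  toy <- make_toy_model()
  plan <- reduction_plan(list(
    reduction_action("B", "ode_to_algebraic", parent = "A"),
    reduction_action("A", "keep_ode"), reduction_action("C", "keep_ode")))
  expect_phaseloop_error(apply_plan(toy, plan, fits = list()),
                         "phaseloop_plan_error")
})

test_that("reduction soundness: milder thresholds never score worse on cascades", {
  errs <- sapply(1:4, function(s) {
    m <- generate_cascade(4, seed = 20 + s)
    pr <- cascade_protocol(m, n_out = 600)
    e1 <- attr(reduce_model(m, pr, threshold = 0.05)$report, "overall")
    e2 <- attr(reduce_model(m, pr, threshold = 0.5)$report, "overall")
    c(e1, e2)
  })
  expect_true(all(errs[1, ] <= errs[2, ] + 1e-9))
})

test_that("reduced cascades preserve the full model's clamped-input steady state", {
  m <- generate_cascade(3, rate_ladder = c(1, 40, 80), input_magnitude = 1)
  pr <- cascade_protocol(m, n_out = 600)
  res <- reduce_model(m, pr, threshold = 0.05)
  ss_full <- find_steady_state(m, overrides = list(input = pr$on_value))
  ss_red <- find_steady_state(res$reduced, overrides = list(input = pr$on_value))
  total_rmse <- sum(vapply(res$fits, function(f) f$rmse, numeric(1)))
  for (s in m$states) {
    expect_lt(abs(ss_red[[s]] - ss_full[[s]]), max(1e-6, 3 * total_rmse))
  }
})

test_that("perturbation suite detects structural insensitivity and matches training", {
  m <- generate_cascade(2, rate_ladder = c(1, 60), input_magnitude = 1)
  pr <- cascade_protocol(m, n_out = 500)
  res <- reduce_model(m, pr, threshold = 0.05)
  expect_identical(model_states(res$reduced, "explicit_algebraic"), "S2")
  expect_false("r2" %in% names(res$reduced$params))  # mechanism eliminated

  scenarios <- list(
    scenario("training", pr),
    scenario("half_input", stimulus_protocol("input", on_value = 0.5,
                                             off_value = 0, t_on = 0,
                                             t_off = pr$t_off, t_end = pr$t_end,
                                             n_out = pr$n_out)),
    scenario("r2_knockdown", pr, overrides = list(r2 = 30)))
  reps <- run_perturbation_suite(m, res$reduced, scenarios)

  expect_equal(attr(reps$training, "overall"), attr(res$report, "overall"),
               tolerance = 1e-10)
  # reduced model still tracks under the halved input
  expect_lt(attr(reps$half_input, "overall"),
            10 * max(attr(res$report, "overall"), 0.1))
  # the reduced model no longer carries r2: flagged, and its S2 trajectory
  # is identical to the unperturbed one
  expect_identical(attr(reps$r2_knockdown, "insensitive_params"), "r2")
  tc_pert <- simulate_transient(res$reduced, pr)   # r2 override inapplicable
  tc_base <- simulate_transient(res$reduced, pr)
  expect_identical(tc_pert$values[, "S2"], tc_base$values[, "S2"])
})

test_that("plans and error reports serialize", {
  toy <- make_toy_model()
  res <- reduce_model(toy, toy_protocol(n_out = 600), threshold = 0.1)
  fp <- withr::local_tempfile(fileext = ".json")
  write_plan_json(res$plan, fp)
  parsed <- jsonlite::read_json(fp)
  expect_equal(parsed$threshold, 0.1)
  states <- vapply(parsed$actions, function(a) a$state, character(1))
  expect_setequal(states, c("A", "B", "C"))
  fr <- withr::local_tempfile(fileext = ".csv")
  write_error_report_csv(res$report, fr, report2 = res$report,
                         labels = c("err6", "err4"))
  got <- readLines(fr)
  expect_identical(got[1], "species,err6,err4")
  expect_match(got[length(got)], "^overall_mean,")
})
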