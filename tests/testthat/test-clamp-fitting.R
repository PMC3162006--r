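test_that("toy concentration clamps recover the analytic steady-state relations", {
  toy <- make_toy_model()
  ccAB <- concentration_clamp(toy, clamp = "A", values = seq(0, 150, length.out = 25),
                              record = "B", context = list(k1 = 100))
  # B_ss = (k2/k3) A = 0.1 A at every sweep point
  expect_equal(ccAB$responses, 0.1 * ccAB$values, tolerance = 1e-8)
  expect_length(ccAB$flagged, 0)

  ccBC <- concentration_clamp(toy, clamp = "B", values = seq(0, 15, length.out = 25),
                              record = "C", context = list(k1 = 100))
  # C_ss = (k3/k4) B = 10 B
  expect_equal(ccBC$responses, 10 * ccBC$values, tolerance = 1e-7)

  # clamping at the full model's own steady state reproduces it
  ss <- find_steady_state(toy, overrides = list(k1 = 100))
  cc0 <- concentration_clamp(toy, clamp = "A", values = ss[["A"]],
                             record = "B", context = list(k1 = 100))
  expect_equal(cc0$responses, unname(ss[["B"]]), tolerance = 1e-6)
})

test_that("clamping works for implicit algebraic states", {
  dae <- toy_dae_model()
  cc <- concentration_clamp(dae, clamp = "B", values = seq(0, 12, length.out = 10),
                            record = "C", context = list(k1 = 100))
  expect_equal(cc$responses, 10 * cc$values, tolerance = 1e-7)
})

test_that("exact Hill data are recovered to high precision and the Michaelian limit holds", {
  x <- seq(0.05, 5, length.out = 20)
  truth <- c(y_max = 5, K = 1, h = 2)
  fit <- fit_relation(fake_curve(x, hill_curve(x, 5, 1, 2)))
  expect_identical(fit$form, "hill")
  expect_lt(max(abs(fit$parameters[names(truth)] - truth) / truth), 1e-6)
  expect_lt(fit$rmse, 1e-10)

  # h = 1 reproduces the Michaelis-Menten closed form
  fit1 <- fit_relation(fake_curve(x, 3 * x / (0.5 + x)), forms = "hill")
  expect_equal(unname(fit1$parameters[c("y_max", "K", "h")]), c(3, 0.5, 1),
               tolerance = 1e-6)
})

test_that("the toy A->B clamp is won by the linear form with slope k2/k3", {
  toy <- make_toy_model()
  cc <- concentration_clamp(toy, clamp = "A", values = seq(0, 150, length.out = 25),
                            record = "B", context = list(k1 = 100))
  fit <- fit_relation(cc)
  expect_identical(fit$form, "linear")
  expect_equal(unname(fit$parameters[["slope"]]), 0.1, tolerance = 1e-6)
  expect_equal(unname(fit$parameters[["intercept"]]), 0, tolerance = 1e-6)
})

test_that("exponential and power forms are recovered on matching data", {
  x <- seq(0, 4, length.out = 25)
  fe <- fit_relation(fake_curve(x, 2 * exp(-0.7 * x) + 0.3))
  expect_identical(fe$form, "exponential")
  expect_equal(unname(fe$parameters[c("amplitude", "rate", "offset")]),
               c(2, -0.7, 0.3), tolerance = 1e-5)
  xp <- seq(0.1, 5, length.out = 25)
  fp <- fit_relation(fake_curve(xp, 1.7 * xp^0.6))
  expect_identical(fp$form, "power")
  expect_equal(unname(fp$parameters[c("coefficient", "exponent")]),
               c(1.7, 0.6), tolerance = 1e-5)
})

test_that("fitting preconditions and prediction domain flags are enforced", {
  expect_phaseloop_error(fit_relation(fake_curve(1:3, 1:3)), "phaseloop_fit_error")
  x <- seq(0.05, 5, length.out = 20)
  fit <- fit_relation(fake_curve(x, hill_curve(x, 5, 1, 2)))
  y <- predict(fit, c(0.5, 10))
  expect_identical(attr(y, "extrapolated"), c(FALSE, TRUE))
  expect_phaseloop_error(predict(fit, 10, extrapolate = "error"),
                         "phaseloop_fit_error")
  # hill predictions are nondecreasing for h > 0
  xs <- seq(0, 8, length.out = 200)
  expect_true(all(diff(predict(fit, xs, extrapolate = "allow")) >= 0))
})

test_that("fitted parameters sit at a local least-squares minimum", {
  x <- seq(0.05, 5, length.out = 20)
  set.seed(3)
  y <- hill_curve(x, 5, 1, 2) * (1 + rnorm(20, sd = 0.02))
  fit <- fit_relation(fake_curve(x, y), forms = "hill")
  rmse_at <- function(p) sqrt(mean((y - hill_curve(x, p[1], p[2], p[3]))^2))
  p0 <- unname(fit$parameters[c("y_max", "K", "h")])
  expect_equal(rmse_at(p0), fit$rmse, tolerance = 1e-10)
  for (i in 1:3) {
    for (d in c(0.99, 1.01)) {
      p <- p0
      p[i] <- p[i] * d
      expect_gte(rmse_at(p), fit$rmse - 1e-12)
    }
  }
})

test_that("clamp curves agree with fast loops and deviations order by area", {
  toy <- make_toy_model()
  ntc <- normalize_timecourses(simulate_transient(toy, toy_protocol()))
  ccAB <- concentration_clamp(toy, clamp = "A", values = seq(0, 150, length.out = 25),
                              record = "B", context = list(k1 = 100))
  lpAB <- phaseloop:::pair_loop(ntc, "A", "B")
  devAB <- compare_clamp_to_loop(ccAB, lpAB)
  ccBC <- concentration_clamp(toy, clamp = "B", values = seq(0, 15, length.out = 25),
                              record = "C", context = list(k1 = 100))
  lpBC <- phaseloop:::pair_loop(ntc, "B", "C")
  devBC <- compare_clamp_to_loop(ccBC, lpBC)
  expect_lt(devAB$mean, devBC$mean)   # faster pair hugs its clamp curve
  expect_lt(devAB$mean, 0.05)
  expect_identical(devAB$extrapolated_fraction, 0)

  # a loop generated directly from the clamp curve deviates by 0
  xr <- range(ccAB$values)
  yr <- range(ccAB$responses)
  lp0 <- phase_loop((ccAB$values - xr[1]) / diff(xr),
                    (ccAB$responses - yr[1]) / diff(yr),
                    states = c("A", "B"), x_range = xr, y_range = yr)
  dev0 <- compare_clamp_to_loop(ccAB, lp0)
  expect_lt(dev0$max, 1e-10)

  expect_phaseloop_error(compare_clamp_to_loop(ccAB, lpBC), "phaseloop_clamp_error")
})

test_that("fast pairs in toy and cascades satisfy the clamp/loop consistency bound", {
  cases <- list(
    list(model = generate_cascade(2, rate_ladder = c(1, 60), input_magnitude = 1),
         pair = c("S1", "S2")),
    list(model = generate_cascade(3, rate_ladder = c(1, 40, 80), input_magnitude = 1),
         pair = c("S2", "S3")))
  for (cs in cases) {
    m <- cs$model
    pr <- cascade_protocol(m, n_out = 800)
    ntc <- normalize_timecourses(simulate_transient(m, pr))
    lp <- phaseloop:::pair_loop(ntc, cs$pair[1], cs$pair[2])
    a <- loop_area(lp)
    expect_lt(a, 0.05)
    context <- setNames(list(pr$on_value), pr$parameter)
    cc <- concentration_clamp(m, clamp = cs$pair[1],
                              values = seq(0, 1.5 * max(ntc$ranges["x_max", cs$pair[1]]),
                                           length.out = 25),
                              record = cs$pair[2], context = context)
    dev <- compare_clamp_to_loop(cc, lp)
    expect_lt(dev$mean, 0.05)
  }
})

test_that("clamp curves and relations serialize to JSON and CSV", {
  toy <- make_toy_model()
  cc <- concentration_clamp(toy, clamp = "A", values = seq(0, 100, length.out = 6),
                            record = "B", context = list(k1 = 100))
  fit <- fit_relation(cc)
  fj <- withr::local_tempfile(fileext = ".json")
  write_relation_json(list(cc, fit), fj)
  parsed <- jsonlite::read_json(fj)
  expect_identical(parsed[[1]]$type, "clamp_curve")
  expect_identical(parsed[[2]]$form, "linear")
  fc <- withr::local_tempfile(fileext = ".csv")
  write_clamp_curve(cc, fc)
  got <- read.csv(fc)
  expect_identical(names(got), c("clamp_value", "response"))
  expect_equal(got$response, cc$responses, tolerance = 1e-12)
})
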