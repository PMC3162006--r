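test_that("loop area matches closed-form oracles", {
  square <- phase_loop(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(loop_area(square), 1.0)

  up <- seq(0, 1, length.out = 20)
  diagonal <- phase_loop(c(up, rev(up)), c(up, rev(up)))
  expect_equal(loop_area(diagonal), 0, tolerance = 1e-12)

  th <- seq(0, 2 * pi, length.out = 1001)[-1001]
  circle <- phase_loop(0.5 + 0.5 * cos(th), 0.5 + 0.5 * sin(th))
  expect_equal(loop_area(circle), pi / 4, tolerance = 1e-3)
})

test_that("loop area is invariant under axis swap and cyclic rotation", {
  set.seed(42)
  for (rep in 1:20) {
    lp <- random_loop(40)
    a <- loop_area(lp)
    expect_lte(a, 1 + 1e-6)
    swapped <- phase_loop(lp$y, lp$x)
    expect_equal(loop_area(swapped), a, tolerance = 1e-12)
    k <- sample(length(lp$x) - 1, 1)
    rot <- phase_loop(c(lp$x[-(1:k)], lp$x[1:k]), c(lp$y[-(1:k)], lp$y[1:k]))
    expect_equal(loop_area(rot), a, tolerance = 1e-12)
  }
})

test_that("loop construction and area reject degenerate input", {
  expect_phaseloop_error(phase_loop(c(0, 1), c(0, 1)), "phaseloop_loop_error")
  expect_phaseloop_error(phase_loop(c(0, 1, 2), c(0, 1, 0)), "phaseloop_loop_error")
  expect_phaseloop_error(phase_loop(c(0, 1, NA), c(0, 1, 0)), "phaseloop_loop_error")
  expect_phaseloop_error(loop_area(list(x = c(0, 1), y = c(0, 1))),
                         "phaseloop_loop_error")
})

test_that("figure-eight loops: signed areas cancel, split mode sums sub-loops", {
  bowtie <- list(x = c(0, 1, 1, 0), y = c(0, 1, 0, 1))
  expect_equal(loop_area(bowtie), 0, tolerance = 1e-12)
  expect_equal(loop_area(bowtie, method = "split"), 0.5, tolerance = 1e-9)
  # a simple loop is unaffected by the split mode
  sq <- phase_loop(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(loop_area(sq, method = "split"), 1.0)
})

test_that("pairwise area matrix is symmetric, bounded, and excludes static states", {
  toy <- make_toy_model()
  ntc <- normalize_timecourses(simulate_transient(toy, toy_protocol()))
  am <- pairwise_area_matrix(ntc)
  expect_equal(unclass(am), t(unclass(am)))
  expect_equal(unname(diag(am)), rep(0, 3))
  expect_true(all(am >= 0 & am <= 1 + 1e-6))
  # the fast A-B pair encloses less area than the lagging B-C pair
  expect_lt(am["A", "B"], am["B", "C"])

  # static state exclusion
  v <- cbind(ntc$values, NULL)
  tc2 <- structure(list(time = ntc$time,
                        values = cbind(denormalize_timecourses(ntc)$values,
                                       fixed = rep(3, length(ntc$time))),
                        provenance = ntc$provenance),
                   class = "time_course_set")
  am2 <- pairwise_area_matrix(normalize_timecourses(tc2))
  expect_identical(attr(am2, "excluded"), "fixed")
  expect_false("fixed" %in% rownames(am2))

  allstatic <- structure(list(time = 0:3,
                              values = cbind(a = rep(1, 4), b = rep(2, 4)),
                              provenance = list()),
                         class = "time_course_set")
  expect_phaseloop_error(pairwise_area_matrix(normalize_timecourses(allstatic)),
                         "phaseloop_loop_error")
})

test_that("toy areas are grid-converged", {
  toy <- make_toy_model()
  am1 <- pairwise_area_matrix(normalize_timecourses(
    simulate_transient(toy, toy_protocol(n_out = 2000))))
  am2 <- pairwise_area_matrix(normalize_timecourses(
    simulate_transient(toy, toy_protocol(n_out = 4000))))
  expect_lt(max(abs(am1 - am2)), 1e-3)
})

test_that("adjacent-pair area decreases monotonically with downstream rate", {
  areas <- vapply(c(1, 3, 10, 30, 100), function(k) {
    m <- generate_cascade(2, rate_ladder = c(1, k), input_magnitude = 1)
    ntc <- normalize_timecourses(simulate_transient(m, cascade_protocol(m, n_out = 800)))
    loop_area(phaseloop:::pair_loop(ntc, "S1", "S2"))
  }, numeric(1))
  expect_true(all(diff(areas) < 0))
})

test_that("classification maps areas to the printed speed modes", {
  thr <- speed_thresholds()
  am <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  am["a", "b"] <- am["b", "a"] <- 0.03
  am["a", "c"] <- am["c", "a"] <- 0.2
  am["a", "d"] <- am["d", "a"] <- 0.7
  am["b", "c"] <- am["c", "b"] <- 0.05
  am["b", "d"] <- am["d", "b"] <- 0.5
  am["c", "d"] <- am["d", "c"] <- 0.51
  class(am) <- c("area_matrix", "matrix")
  cl <- classify_pairs(am, thr)
  got <- setNames(cl$class, paste(cl$a, cl$b))
  expect_identical(unname(got[c("a b", "a c", "a d")]),
                   c("fast", "medium", "slow"))
  # boundary convention: closed lower bins
  expect_identical(unname(got[c("b c", "b d", "c d")]),
                   c("fast", "medium", "slow"))
  expect_phaseloop_error(speed_thresholds(0.6, 0.5), "phaseloop_threshold_error")
})

test_that("direct-pair restriction is carried through classification", {
  toy <- make_toy_model()
  ntc <- normalize_timecourses(simulate_transient(toy, toy_protocol()))
  am <- pairwise_area_matrix(ntc)
  cl <- classify_pairs(am, direct = direct_pairs(toy))
  expect_identical(sum(cl$direct), 2L)                 # A-B and B-C
  expect_identical(nrow(attr(cl, "direct_only")), 2L)
  expect_false(cl$direct[cl$a == "A" & cl$b == "C"])
})

test_that("area histogram conserves pair counts", {
  m <- generate_cascade(4, rate_ladder = c(100, 100, 1, 1), input_magnitude = 1)
  ntc <- normalize_timecourses(simulate_transient(m, cascade_protocol(m, n_out = 600)))
  am <- pairwise_area_matrix(ntc)
  h <- area_histogram(am, bin_width = 0.05)
  n <- nrow(am)
  expect_identical(sum(h$count), (n * (n - 1L)) %/% 2L)
  # adjacent-pair areas separate into a low group (the equal-rate steps)
  # and a high group (the 100x -> 1x handoff)
  adj <- sort(c(am["S1", "S2"], am["S2", "S3"], am["S3", "S4"]))
  expect_lt(adj[2], 0.6)
  expect_gt(adj[3], 0.9)
  expect_gt(adj[3] - adj[2], 0.3)

  one <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  class(one) <- c("area_matrix", "matrix")
  h0 <- area_histogram(one, 0.1)
  expect_identical(sum(h0$count), 1L)
  expect_identical(h0$count[1], 1L)
  expect_phaseloop_error(area_histogram(one, 0), "phaseloop_threshold_error")
})

test_that("area matrix exports to square and long CSV", {
  toy <- make_toy_model()
  ntc <- normalize_timecourses(simulate_transient(toy, toy_protocol(n_out = 300)))
  am <- pairwise_area_matrix(ntc)
  f1 <- withr::local_tempfile(fileext = ".csv")
  write_area_matrix(am, f1)
  sq <- read.csv(f1, check.names = FALSE)
  expect_identical(names(sq), c("state", "A", "B", "C"))
  expect_equal(sq$B[1], am["A", "B"], tolerance = 1e-12)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_area_matrix(am, f2, long = TRUE, direct = direct_pairs(toy))
  lg <- read.csv(f2)
  expect_identical(nrow(lg), 3L)
  expect_identical(names(lg), c("state_a", "state_b", "area", "class", "direct_flag"))
})
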