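test_that("toy Jacobian is the hand-differentiated bidiagonal rate matrix", {
  toy <- make_toy_model()
  ss <- find_steady_state(toy, overrides = list(k1 = 100))
  J <- jacobian_at(toy, ss, overrides = list(k1 = 100))
  J_hand <- matrix(c(-1, 1, 0, 0, -10, 10, 0, 0, -1), 3, 3,
                   dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_equal(J, J_hand, tolerance = 1e-8)
  # linear model: Jacobian independent of the evaluation state
  J2 <- jacobian_at(toy, c(A = 1, B = 2, C = 3), overrides = list(k1 = 100),
                    check_steady = FALSE)
  expect_equal(J2, J_hand, tolerance = 1e-8)
})

test_that("finite differences match the analytic cascade Jacobian", {
  rates <- c(2, 0.3, 7, 1.5)
  m <- generate_cascade(4, rate_ladder = rates, input_magnitude = 1)
  ss <- find_steady_state(m, overrides = list(input = 1))
  J <- jacobian_at(m, ss, overrides = list(input = 1))
  J_hand <- diag(-rates)
  J_hand[cbind(2:4, 1:3)] <- rates[1:3]
  expect_lt(max(abs(J - J_hand)), 1e-6)
  # eigenvalues of the chain are minus the rate ladder
  expect_equal(sort(Re(eigen(J)$values)), sort(-rates), tolerance = 1e-6)
})

test_that("the steady-state precondition and finiteness are enforced", {
  toy <- make_toy_model()
  expect_phaseloop_error(
    jacobian_at(toy, c(A = 1, B = 2, C = 3), overrides = list(k1 = 100)),
    "phaseloop_jacobian_error")
})

test_that("modal decomposition reports the toy timescales and flags its defect", {
  toy <- make_toy_model()
  ss <- find_steady_state(toy, overrides = list(k1 = 100))
  J <- jacobian_at(toy, ss, overrides = list(k1 = 100))
  rep <- modal_decomposition(J)
  expect_equal(rep$timescales, c(1, 1, 0.1), tolerance = 1e-6)
  # the repeated eigenvalue -1 has a single eigenvector: J is defective
  expect_true(rep$defective)
  # the isolated fast mode is reliable and dominated by B
  fast <- rep$modes[which.min(rep$modes$tau_s), ]
  expect_true(fast$reliable)
  expect_match(fast$dominant_species, "B")
})

test_that("eigen-decomposition reconstructs well-conditioned Jacobians", {
  m <- generate_cascade(3, rate_ladder = c(1, 10, 1.5), input_magnitude = 100)
  ss <- find_steady_state(m, overrides = list(input = 100))
  J <- jacobian_at(m, ss, overrides = list(input = 100))
  rep <- modal_decomposition(J)
  expect_false(rep$defective)
  recon <- rep$M %*% diag(rep$eigenvalues) %*% solve(rep$M)
  expect_lt(norm(Re(recon) - J, "F") / norm(J, "F"), 1e-8)
  expect_lt(Mod(sum(rep$eigenvalues) - sum(diag(J))) / abs(sum(diag(J))), 1e-8)
  # modal rows are unit-normalized
  expect_equal(unname(rowSums(Mod(rep$modal_rows)^2)), rep(1, 3),
               tolerance = 1e-12)
})

test_that("cascade steady states are stable (all eigenvalues in the left half-plane)", {
  for (s in 1:3) {
    m <- generate_cascade(4, seed = 30 + s)
    ss <- find_steady_state(m, overrides = list(input = 1))
    J <- jacobian_at(m, ss, overrides = list(input = 1))
    expect_true(all(Re(eigen(J)$values) < 0))
  }
})

test_that("diagonal Jacobians give single-species modes", {
  J <- diag(c(-0.2, -5, -50))
  dimnames(J) <- list(c("x", "y", "z"), c("x", "y", "z"))
  rep <- modal_decomposition(J)
  expect_equal(rep$modes$tau_s, c(5, 0.2, 0.02), tolerance = 1e-12)
  expect_identical(rep$modes$dominant_species, c("x", "y", "z"))
})

test_that("complex pairs fold into one mode and millisecond modes are labelled algebraic", {
  J <- rbind(c(-1, -5, 0), c(5, -1, 0), c(0, 0, -2000))
  dimnames(J) <- list(c("u", "v", "w"), c("u", "v", "w"))
  rep <- modal_decomposition(J)
  expect_identical(nrow(rep$modes), 2L)
  osc <- rep$modes[rep$modes$im_lambda > 0, ]
  expect_identical(osc$multiplicity, 2L)
  expect_equal(osc$tau_s, 1, tolerance = 1e-10)
  expect_identical(rep$modes$mode_type[rep$modes$tau_s < 1e-3], "algebraic")
})

test_that("phase-plane and Jacobian methods agree on the toy's fast species", {
  toy <- make_toy_model()
  ss <- find_steady_state(toy, overrides = list(k1 = 100))
  J <- jacobian_at(toy, ss, overrides = list(k1 = 100))
  jrep <- modal_decomposition(J)
  ntc <- normalize_timecourses(simulate_transient(toy, toy_protocol()))
  am <- pairwise_area_matrix(ntc)
  cl <- classify_pairs(am, speed_thresholds(fast_max = 0.1),
                       direct = direct_pairs(toy))
  cmp <- compare_methods(jrep, am, cl)
  rowB <- cmp[cmp$species == "B", ]
  expect_true(rowB$jacobian_fast)
  expect_true(rowB$phase_fast)
  expect_true(rowB$agree)
})

test_that("a dominant fast step is flagged fast by both methods in a cascade", {
  m <- generate_cascade(3, rate_ladder = c(1, 100, 2), input_magnitude = 1)
  pr <- cascade_protocol(m, n_out = 800)
  ss <- find_steady_state(m, overrides = list(input = 1))
  J <- jacobian_at(m, ss, overrides = list(input = 1))
  jrep <- modal_decomposition(J)
  ntc <- normalize_timecourses(simulate_transient(m, pr))
  am <- pairwise_area_matrix(ntc)
  cl <- classify_pairs(am, direct = direct_pairs(m))
  cmp <- compare_methods(jrep, am, cl)
  s2 <- cmp[cmp$species == "S2", ]   # downstream of the 100x faster step
  expect_true(s2$jacobian_fast)
  expect_true(s2$phase_fast)
  expect_true(s2$agree)
})

test_that("a single-species model trivially agrees across methods", {
  m <- generate_cascade(1, rate_ladder = 2, input_magnitude = 1)
  ss <- find_steady_state(m, overrides = list(input = 1))
  J <- jacobian_at(m, ss, overrides = list(input = 1))
  jrep <- modal_decomposition(J)
  expect_equal(jrep$modes$tau_s, 0.5, tolerance = 1e-10)
  # no pairs exist: neither method can call anything fast
  cl <- data.frame(a = character(), b = character(), area = numeric(),
                   class = character(), direct = logical())
  cmp <- compare_methods(jrep, matrix(0, 1, 1, dimnames = list("S1", "S1")), cl)
  expect_true(all(cmp$agree))
  expect_false(any(cmp$jacobian_fast))
})

test_that("the timescale table exports in CSV form", {
  m <- generate_cascade(3, rate_ladder = c(1, 10, 1.5), input_magnitude = 1)
  ss <- find_steady_state(m, overrides = list(input = 1))
  rep <- modal_decomposition(jacobian_at(m, ss, overrides = list(input = 1)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_jacobian_report(rep, f)
  got <- read.csv(f)
  expect_identical(names(got), c("timescale_s", "dominant_species"))
  expect_equal(got$timescale_s, rep$modes$tau_s, tolerance = 1e-12)
})
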