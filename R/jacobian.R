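#' Jacobian of the combined dynamic system at a steady state
#'
#' Central finite-difference Jacobian (adaptive step
#' `eps^(1/3) * max(|x_j|, 1)`) of the stacked function
#' `F(x) = (d/dt of the ode states, residuals of the implicit states)`
#' with respect to the dynamic states, evaluated at a steady state. For a
#' linear mass-action chain this reproduces the lower-bidiagonal rate
#' matrix exactly (to finite-difference accuracy) and is independent of
#' the evaluation state.
#'
#' @param model a [network_model()].
#' @param state named state vector (full or dynamic); must satisfy the
#'   steady-state criterion to `ss_tol` unless `check_steady = FALSE`.
#' @param overrides parameter overrides defining the operating condition.
#' @param ss_tol tolerance on the normalized rates for the steady-state
#'   precondition.
#' @param check_steady verify the precondition (default TRUE).
#' @return square matrix (s⁻¹) with dynamic-state dimnames.
#' @export
jacobian_at <- function(model, state, overrides = list(), ss_tol = 1e-6,
                        check_steady = TRUE) {
  params <- override_params(model$params, overrides)
  dyn <- dynamic_states(model)
  x <- state[dyn]
  if (anyNA(x)) {
    stop_phaseloop("state must cover all dynamic states", "phaseloop_jacobian_error")
  }
  f <- function(z) eval_dynamics(model, 0, stats::setNames(z, dyn), params)
  fx <- f(as.numeric(x))
  if (check_steady && length(fx) &&
      max(abs(fx) / pmax(abs(x), 1)) > ss_tol) {
    stop_phaseloop(sprintf("state is not a steady state to tolerance %g", ss_tol),
                   "phaseloop_jacobian_error")
  }
  J <- num_jacobian(f, as.numeric(x))
  if (any(!is.finite(J))) {
    stop_phaseloop("non-finite Jacobian entries", "phaseloop_jacobian_error")
  }
  dimnames(J) <- list(dyn, dyn)
  J
}

#' Modal timescale decomposition of a Jacobian
#'
#' Eigen-decomposes `J = M Λ M⁻¹` and reports each mode's timescale
#' `τ = −1/Re(λ)` with the species that dominate it, sorted slowest to
#' fastest. The modal matrix `M⁻¹` holds one relaxing mode per row; rows
#' are obtained as left eigenvectors matched to the eigenvalues (equal to
#' the rows of `M⁻¹` up to scale when `J` is diagonalizable), normalized
#' to unit Euclidean length, and a species dominates a mode when the
#' magnitude of its entry exceeds `magnitude_threshold` (default 0.09).
#' Complex-conjugate eigenvalue pairs share a timescale and are reported
#' once with the union of their dominant species. Modes with τ at or
#' below 1 ms are labelled algebraic-relationship modes. A defective or
#' near-defective `J` (eigenvector condition number above `cond_cap`) is
#' flagged, and modes belonging to a near-degenerate eigenvalue cluster
#' are marked unreliable.
#'
#' @param J square Jacobian matrix (s⁻¹), dimnames = species.
#' @param magnitude_threshold modal-row magnitude above which a species is
#'   reported for the mode.
#' @param cond_cap condition-number cap above which the decomposition is
#'   flagged defective.
#' @param algebraic_tau timescale (s) at or below which a mode is labelled
#'   an algebraic relationship.
#' @return a `jacobian_report`: list with `eigenvalues`, `timescales`
#'   (slow to fast), `modal_rows` (unit-normalized, one per reported
#'   mode), `modes` (data frame: `tau_s`, `dominant_species`, `mode_type`,
#'   `reliable`), `M`, `defective`, `condition`.
#' @export
modal_decomposition <- function(J, magnitude_threshold = 0.09,
                                cond_cap = 1e8, algebraic_tau = 1e-3) {
  species <- rownames(J) %||% paste0("x", seq_len(nrow(J)))
  eg <- eigen(J)
  lambda <- eg$values
  M <- eg$vectors
  condM <- tryCatch(norm(M, "2") * norm(solve(M), "2"),
                    error = function(e) Inf)
  defective <- !is.finite(condM) || condM > cond_cap
  # modal rows as matched left eigenvectors: robust also when M is
  # ill-conditioned in a degenerate cluster
  egl <- eigen(t(J))
  left_idx <- match_eigenvalues(lambda, egl$values)
  W <- t(egl$vectors[, left_idx, drop = FALSE])
  W <- W / sqrt(rowSums(Mod(W)^2))
  # reliability: eigenvalues in a near-degenerate cluster with nearly
  # parallel right eigenvectors cannot be separated
  scale_l <- max(Mod(lambda), 1e-300)
  reliable <- rep(TRUE, length(lambda))
  for (i in seq_along(lambda)) {
    for (j in seq_along(lambda)) {
      if (j == i) next
      if (Mod(lambda[i] - lambda[j]) < 1e-8 * scale_l) {
        par_ij <- Mod(sum(Conj(M[, i]) * M[, j])) /
          (sqrt(sum(Mod(M[, i])^2)) * sqrt(sum(Mod(M[, j])^2)))
        if (par_ij > 1 - 1e-8) reliable[i] <- FALSE
      }
    }
  }
  tau <- -1 / Re(lambda)
  # fold complex-conjugate pairs: group by (Re, |Im|)
  keygrp <- paste(signif(Re(lambda), 12), signif(abs(Im(lambda)), 12))
  groups <- split(seq_along(lambda), factor(keygrp, levels = unique(keygrp)))
  rows <- list()
  for (g in groups) {
    i0 <- g[1]
    dom <- species[Mod(W[i0, ]) > magnitude_threshold]
    if (length(g) > 1) {
      for (k in g[-1]) {
        dom <- union(dom, species[Mod(W[k, ]) > magnitude_threshold])
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      tau_s = tau[i0],
      re_lambda = Re(lambda[i0]), im_lambda = abs(Im(lambda[i0])),
      multiplicity = length(g),
      dominant_species = paste(dom, collapse = ","),
      mode_type = if (is.finite(tau[i0]) && tau[i0] > 0 &&
                      tau[i0] <= algebraic_tau) "algebraic" else "dynamic",
      reliable = all(reliable[g]),
      stringsAsFactors = FALSE)
  }
  modes <- do.call(rbind, rows)
  ord <- order(-modes$tau_s)
  modes <- modes[ord, , drop = FALSE]
  rownames(modes) <- NULL
  structure(list(eigenvalues = lambda, timescales = sort(tau, decreasing = TRUE),
                 modal_rows = W, M = M, species = species,
                 modes = modes, defective = defective, condition = condM,
                 magnitude_threshold = magnitude_threshold),
            class = "jacobian_report")
}

# Greedy one-to-one matching of two eigenvalue multisets by distance.
match_eigenvalues <- function(a, b) {
  n <- length(a)
  idx <- integer(n)
  free <- rep(TRUE, n)
  for (i in seq_len(n)) {
    d <- Mod(a[i] - b)
    d[!free] <- Inf
    j <- which.min(d)
    idx[i] <- j
    free[j] <- FALSE
  }
  idx
}

#' @export
print.jacobian_report <- function(x, ...) {
  cat(sprintf("jacobian_report: %d modes%s\n", nrow(x$modes),
              if (x$defective) sprintf(" (DEFECTIVE, cond(M) = %.3g)", x$condition)
              else ""))
  print.data.frame(data.frame(timescale_s = signif(x$modes$tau_s, 4),
                              dominant_species = x$modes$dominant_species,
                              type = x$modes$mode_type,
                              reliable = x$modes$reliable),
                   row.names = FALSE)
  invisible(x)
}

#' @rdname modal_decomposition
#' @param report a `jacobian_report`.
#' @param file output path for the timescale table CSV
#'   (`timescale_s,dominant_species`).
#' @export
write_jacobian_report <- function(report, file) {
  lines <- c("timescale_s,dominant_species",
             sprintf("%s,\"%s\"", fmt_num(report$modes$tau_s),
                     report$modes$dominant_species))
  writeLines(lines, file)
  invisible(file)
}

#' Concordance of Jacobian and phase-loop timescale calls
#'
#' For every species, compares "fast by the Jacobian" (the species
#' dominates at least one mode with timescale below `fast_tau`) against
#' "fast by the phase planes" (the species belongs to at least one direct
#' pair classified fast). The two methods answer different questions —
#' modes are linear combinations of species at one steady state, loops
#' are nonlinear pairwise dynamics — so partial agreement is the expected
#' outcome, and this table makes the comparison explicit.
#'
#' @param report a `jacobian_report`.
#' @param am an `area_matrix` (used for the species list).
#' @param classes classification from [classify_pairs()] computed with
#'   `direct` pairs.
#' @param fast_tau timescale cut (s) for "fast by the Jacobian"; default
#'   is the geometric mean of the slowest and fastest reliable positive
#'   timescales.
#' @return data frame: `species`, `jacobian_fast`, `jacobian_tau_min`,
#'   `phase_fast`, `phase_min_area`, `agree`.
#' @export
compare_methods <- function(report, am, classes, fast_tau = NULL) {
  species <- report$species
  tau <- report$modes$tau_s
  pos <- tau[is.finite(tau) & tau > 0]
  if (is.null(fast_tau)) {
    fast_tau <- if (length(pos)) exp(mean(log(range(pos)))) else Inf
  }
  dom <- strsplit(report$modes$dominant_species, ",", fixed = TRUE)
  tau_min <- vapply(species, function(s) {
    hit <- vapply(dom, function(d) s %in% d, logical(1))
    if (any(hit)) min(tau[hit]) else NA_real_
  }, numeric(1))
  direct_cl <- if (isTRUE(any(classes$direct))) {
    classes[classes$direct, , drop = FALSE]
  } else {
    classes
  }
  min_area <- vapply(species, function(s) {
    rows <- direct_cl$a == s | direct_cl$b == s
    if (any(rows)) min(direct_cl$area[rows]) else NA_real_
  }, numeric(1))
  fast_cl <- vapply(species, function(s) {
    rows <- (direct_cl$a == s | direct_cl$b == s) & direct_cl$class == "fast"
    any(rows)
  }, logical(1))
  jac_fast <- !is.na(tau_min) & tau_min < fast_tau
  data.frame(species = species,
             jacobian_fast = jac_fast, jacobian_tau_min = unname(tau_min),
             phase_fast = unname(fast_cl), phase_min_area = unname(min_area),
             agree = jac_fast == unname(fast_cl),
             stringsAsFactors = FALSE)
}
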