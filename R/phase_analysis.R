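#' Phase loop of a normalized species pair
#'
#' The ordered sequence of normalized points (X_i, Y_i) traced by two
#' species over the combined stimulus-on + stimulus-off trajectory. Because
#' the simulation starts and ends at the resting steady state, the sequence
#' is treated as a closed polygon (the last point connects back to the
#' first). The enclosed (hysteresis) area quantifies timescale separation:
#' 0 means the pair moves along a single steady-state curve, 1 means
#' complete separation.
#'
#' @param x,y normalized coordinates in \[0, 1\], equal length >= 3.
#' @param states length-2 character vector naming the X and Y species.
#' @param x_range,y_range optional (min, max) ranges (µM) used in the
#'   normalization, retained so clamp curves can be compared on the same
#'   scale.
#' @return an object of class `phase_loop`.
#' @export
phase_loop <- function(x, y, states = c("X", "Y"),
                       x_range = NULL, y_range = NULL) {
  if (length(x) != length(y)) {
    stop_phaseloop("x and y must have equal length", "phaseloop_loop_error")
  }
  if (length(x) < 3) {
    stop_phaseloop("a phase loop needs at least 3 points", "phaseloop_loop_error")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop_phaseloop("phase-loop coordinates must be finite", "phaseloop_loop_error")
  }
  eps <- 1e-9
  if (min(x) < -eps || max(x) > 1 + eps || min(y) < -eps || max(y) > 1 + eps) {
    stop_phaseloop("phase-loop coordinates must lie in [0, 1]", "phaseloop_loop_error")
  }
  structure(list(x = as.numeric(x), y = as.numeric(y), states = states,
                 x_range = x_range, y_range = y_range),
            class = "phase_loop")
}

# Extract the loop for one pair from a normalized timecourse set.
pair_loop <- function(ntc, a, b) {
  stopifnot(inherits(ntc, "normalized_time_course_set"))
  missing <- setdiff(c(a, b), colnames(ntc$values))
  if (length(missing)) {
    stop_phaseloop(sprintf("state(s) not available for phase analysis (static or unknown): %s",
                           paste(missing, collapse = ", ")),
                   "phaseloop_loop_error")
  }
  phase_loop(ntc$values[, a], ntc$values[, b], states = c(a, b),
             x_range = ntc$ranges[, a], y_range = ntc$ranges[, b])
}

#' Hysteresis area of a closed phase loop
#'
#' Computes the line integral |∮ y dx| around the closed polygonal loop
#' with the midpoint rule on the ordinates,
#' `|Σ_i (Y_{i+1} + Y_i)/2 · (X_{i+1} − X_i)|`, wrapping the last segment
#' back to the first point. This is the shoelace area for simple polygons,
#' is exact for polygons, requires no uniform spacing in X, Y or time, and
#' handles loops that switch concavity. It is invariant under cyclic
#' rotation of the point sequence and under swapping the two axes.
#'
#' For self-intersecting (figure-eight) loops the signed contributions of
#' the sub-loops cancel under the default `method = "signed"`; with
#' `method = "split"` segment crossings are detected, the loop is split at
#' each crossing and the absolute sub-loop areas are summed.
#'
#' @param loop a [phase_loop()] (or any list with `x` and `y`).
#' @param method `"signed"` (default, the literal closed line integral) or
#'   `"split"` (sum of absolute sub-loop areas).
#' @return dimensionless area in \[0, 1\] for normalized coordinates.
#' @export
loop_area <- function(loop, method = c("signed", "split")) {
  method <- match.arg(method)
  x <- loop$x
  y <- loop$y
  if (length(x) < 3) {
    stop_phaseloop("a phase loop needs at least 3 points", "phaseloop_loop_error")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop_phaseloop("phase-loop coordinates must be finite", "phaseloop_loop_error")
  }
  if (method == "signed") {
    return(abs(signed_area(x, y)))
  }
  split_area(x, y, depth = 0L)
}

signed_area <- function(x, y) {
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  sum((yn + y) / 2 * (xn - x))
}

# Split a self-intersecting polygon at its first crossing and sum absolute
# sub-areas recursively.
split_area <- function(x, y, depth) {
  n <- length(x)
  if (n < 3 || depth > 25L) return(abs(signed_area(x, y)))
  cross <- find_first_crossing(x, y)
  if (is.null(cross)) return(abs(signed_area(x, y)))
  i <- cross$i
  j <- cross$j
  px <- cross$px
  py <- cross$py
  idx_in <- if (i + 1 <= j) (i + 1):j else integer()
  x1 <- c(px, x[idx_in])
  y1 <- c(py, y[idx_in])
  idx_out <- setdiff(seq_len(n), idx_in)
  # keep original ordering, insert the crossing point after segment i
  pos <- which(idx_out == i)
  x2 <- append(x[idx_out], px, after = pos)
  y2 <- append(y[idx_out], py, after = pos)
  split_area(x1, y1, depth + 1L) + split_area(x2, y2, depth + 1L)
}

# First pair of non-adjacent closed-polygon segments that properly cross.
find_first_crossing <- function(x, y) {
  n <- length(x)
  nx <- c(x[-1], x[1])
  ny <- c(y[-1], y[1])
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    js <- js[!(i == 1L & js == n)]          # wrap-adjacent
    if (!length(js)) next
    hit <- segment_intersections(x[i], y[i], nx[i], ny[i],
                                 x[js], y[js], nx[js], ny[js])
    k <- which(hit$cross)[1]
    if (!is.na(k)) {
      return(list(i = i, j = js[k], px = hit$px[k], py = hit$py[k]))
    }
  }
  NULL
}

# Vectorized proper-intersection test of one segment against many.
segment_intersections <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  rpx <- bx - ax
  rpy <- by - ay
  spx <- dx - cx
  spy <- dy - cy
  denom <- rpx * spy - rpy * spx
  tnum <- (cx - ax) * spy - (cy - ay) * spx
  unum <- (cx - ax) * rpy - (cy - ay) * rpx
  tt <- ifelse(abs(denom) > 1e-14, tnum / denom, NA_real_)
  uu <- ifelse(abs(denom) > 1e-14, unum / denom, NA_real_)
  eps <- 1e-10
  cross <- !is.na(tt) & tt > eps & tt < 1 - eps & uu > eps & uu < 1 - eps
  list(cross = cross, px = ax + tt * rpx, py = ay + tt * rpy)
}

#' Pairwise hysteresis-area matrix
#'
#' Computes the phase-loop area for every unordered pair of non-static
#' states in a normalized timecourse set — the "global phase portrait" of
#' the system. Static states (flagged during normalization) are excluded
#' and listed.
#'
#' @param ntc a `normalized_time_course_set`.
#' @param method area method passed to [loop_area()].
#' @return an `area_matrix`: symmetric numeric matrix with zero diagonal,
#'   `dimnames` the non-static state names, and attribute `excluded`
#'   listing static states.
#' @export
pairwise_area_matrix <- function(ntc, method = "signed") {
  stopifnot(inherits(ntc, "normalized_time_course_set"))
  states <- colnames(ntc$values)
  if (length(states) < 2) {
    stop_phaseloop("need at least 2 non-static states for phase analysis",
                   "phaseloop_loop_error")
  }
  n <- length(states)
  am <- matrix(0, n, n, dimnames = list(states, states))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- loop_area(pair_loop(ntc, states[i], states[j]), method = method)
      am[i, j] <- a
      am[j, i] <- a
    }
  }
  structure(am, excluded = ntc$static, class = c("area_matrix", "matrix"))
}

#' @export
print.area_matrix <- function(x, ...) {
  cat(sprintf("area_matrix: %d states, %d pairs", nrow(x),
              nrow(x) * (nrow(x) - 1) / 2))
  exc <- attr(x, "excluded")
  if (length(exc)) cat(sprintf(" (excluded static: %s)", paste(exc, collapse = ", ")))
  cat("\n")
  print(round(unclass(x)[, , drop = FALSE], 4))
  invisible(x)
}

#' Speed-classification thresholds
#'
#' Phase-loop areas fall into three modes: fast (area <= `fast_max`),
#' medium (`fast_max` < area <= `slow_min`) and slow (area > `slow_min`).
#' The defaults 0.05 and 0.5 are the boundaries of the trimodal area
#' histogram; the boundary value 0.05 itself is binned as fast (closed
#' lower bin), which is the conservative side for reduction risk and is
#' configurable here.
#'
#' @param fast_max upper area bound of the fast mode.
#' @param slow_min lower area bound of the slow mode.
#' @return a `speed_thresholds` object.
#' @export
speed_thresholds <- function(fast_max = 0.05, slow_min = 0.5) {
  if (!(fast_max > 0 && fast_max < slow_min && slow_min < 1)) {
    stop_phaseloop("need 0 < fast_max < slow_min < 1", "phaseloop_threshold_error")
  }
  structure(list(fast_max = fast_max, slow_min = slow_min),
            class = "speed_thresholds")
}

#' Classify species pairs as fast, medium or slow
#'
#' Labels every unordered pair in the area matrix by its hysteresis area.
#' When the model's direct pairs are supplied, the classification is also
#' restricted to those mechanistically coupled pairs — the subset that
#' drives reduction decisions.
#'
#' @param am an `area_matrix` from [pairwise_area_matrix()].
#' @param thresholds a [speed_thresholds()].
#' @param direct optional data frame of direct pairs (from
#'   [direct_pairs()]) or a 2-column matrix/data frame of state-name pairs.
#' @return data frame with columns `a`, `b`, `area`, `class` and `direct`
#'   (logical; `NA` when `direct` not given). The direct-only subset is
#'   available via `attr(, "direct_only")`.
#' @export
classify_pairs <- function(am, thresholds = speed_thresholds(), direct = NULL) {
  states <- rownames(am)
  idx <- which(upper.tri(am), arr.ind = TRUE)
  out <- data.frame(a = states[idx[, 1]], b = states[idx[, 2]],
                    area = am[idx], stringsAsFactors = FALSE)
  out$class <- ifelse(out$area <= thresholds$fast_max, "fast",
                      ifelse(out$area <= thresholds$slow_min, "medium", "slow"))
  if (is.null(direct)) {
    out$direct <- NA
  } else {
    dp <- if (is.data.frame(direct)) direct[, c("a", "b")] else
      as.data.frame(direct)[, 1:2]
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    out$direct <- key(out$a, out$b) %in% key(dp[[1]], dp[[2]])
    attr(out, "direct_only") <- out[out$direct, , drop = FALSE]
  }
  out
}

#' Histogram of phase-loop areas
#'
#' Bins all pairwise areas over \[0, 1\]; with well-separated timescales
#' the distribution is trimodal, motivating the fast/medium/slow
#' thresholds.
#'
#' @param am an `area_matrix`.
#' @param bin_width bin width (default 0.05, matching the fast threshold).
#' @return data frame with `bin_lo`, `bin_hi`, `count`; counts sum to the
#'   number of unordered pairs.
#' @export
area_histogram <- function(am, bin_width = 0.05) {
  if (!is.finite(bin_width) || bin_width <= 0) {
    stop_phaseloop("bin_width must be positive", "phaseloop_threshold_error")
  }
  areas <- am[upper.tri(am)]
  if (!length(areas)) {
    stop_phaseloop("area matrix has no pairs", "phaseloop_threshold_error")
  }
  nbin <- max(1L, ceiling((max(areas, 1) - 1e-12) / bin_width))
  breaks <- seq(0, nbin * bin_width, by = bin_width)
  cuts <- cut(areas, breaks = breaks, include.lowest = TRUE, right = TRUE)
  counts <- as.integer(table(cuts))
  data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
             count = counts)
}

#' Export an area matrix to CSV
#'
#' @param am an `area_matrix`.
#' @param file output path.
#' @param long if `TRUE`, writes the long format
#'   (`state_a,state_b,area,class,direct_flag`) using `thresholds` and
#'   `direct`; otherwise the square matrix with a header row/column of
#'   state names.
#' @param thresholds,direct passed to [classify_pairs()] for the long
#'   format.
#' @export
write_area_matrix <- function(am, file, long = FALSE,
                              thresholds = speed_thresholds(), direct = NULL) {
  if (!long) {
    states <- rownames(am)
    lines <- c(paste(c("state", states), collapse = ","),
               vapply(states, function(s) {
                 paste(c(s, fmt_num(am[s, ])), collapse = ",")
               }, character(1)))
    writeLines(lines, file)
  } else {
    cl <- classify_pairs(am, thresholds, direct)
    lines <- c("state_a,state_b,area,class,direct_flag",
               apply(cl, 1, function(r) {
                 paste(c(r[["a"]], r[["b"]], fmt_num(as.numeric(r[["area"]])),
                         r[["class"]], tolower(as.character(r[["direct"]]))),
                       collapse = ",")
               }))
    writeLines(lines, file)
  }
  invisible(file)
}

#' Grid of phase-portrait panels
#'
#' Draws every requested pair's normalized loop with its hysteresis area
#' printed above the panel, in the style of a global phase portrait. With
#' `file` the figure is written as vector graphics (PDF or SVG by
#' extension).
#'
#' @param ntc a `normalized_time_course_set`.
#' @param am optional precomputed `area_matrix` (computed if omitted).
#' @param pairs optional data frame / 2-column matrix of pairs to draw
#'   (default: all).
#' @param file optional output path ending in `.pdf` or `.svg`.
#' @param max_panels cap on panels drawn.
#' @export
plot_phase_grid <- function(ntc, am = NULL, pairs = NULL, file = NULL,
                            max_panels = 49L) {
  if (is.null(am)) am <- pairwise_area_matrix(ntc)
  if (is.null(pairs)) {
    states <- rownames(am)
    idx <- which(upper.tri(am), arr.ind = TRUE)
    pairs <- data.frame(a = states[idx[, 1]], b = states[idx[, 2]])
  }
  pairs <- utils::head(as.data.frame(pairs), max_panels)
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    switch(ext,
           pdf = grDevices::pdf(file, width = 9, height = 9),
           svg = grDevices::svg(file, width = 9, height = 9),
           stop_phaseloop("figure file must end in .pdf or .svg",
                          "phaseloop_io_error"))
    on.exit(grDevices::dev.off())
  }
  k <- nrow(pairs)
  nc <- ceiling(sqrt(k))
  nr <- ceiling(k / nc)
  op <- graphics::par(mfrow = c(nr, nc), mar = c(2.2, 2.2, 1.6, 0.4),
                      mgp = c(1.2, 0.3, 0), tcl = -0.25)
  # restore pars before any file device closes, or the restore itself
  # would open a default device
  on.exit(graphics::par(op), add = TRUE, after = FALSE)
  for (i in seq_len(k)) {
    a <- pairs[i, 1]
    b <- pairs[i, 2]
    lp <- pair_loop(ntc, a, b)
    graphics::plot(lp$x, lp$y, type = "l", xlim = c(0, 1), ylim = c(0, 1),
                   xlab = a, ylab = b, cex.axis = 0.7, cex.lab = 0.8)
    graphics::title(main = sprintf("area = %.3f", am[a, b]),
                    cex.main = 0.85, font.main = 1)
  }
  invisible(am)
}
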