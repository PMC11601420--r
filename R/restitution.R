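#' Build a restitution map from (DI, APD) points
#'
#' Fits a natural interpolating cubic spline `F(DI)` through the measured
#' points (a smoothing spline is available for noisy tissue-derived sets).
#' Outside the sampled DI domain the map is clamped to its endpoint values,
#' which prevents spurious fixed points from polynomial extrapolation.
#'
#' @param points data.frame with columns `di` and `apd` (ms), strictly
#'   increasing `di`, at least 4 rows; or a [s1s2_restitution()] result
#'   (blocked points dropped).
#' @param dimin_block conduction-block threshold (ms): map iteration
#'   terminates with status `"block"` once `DI` falls below it.  Use 0 for
#'   single-cell maps, ~25 ms for tissue-derived maps.
#' @param smoothing if `TRUE`, fit `stats::smooth.spline` instead of an
#'   interpolating spline.
#' @return object of class `restitution_map`: callable pieces `F` (function),
#'   `domain`, `dimin_block`, `knots`.
#' @export
fit_restitution_spline <- function(points, dimin_block = 0,
                                   smoothing = FALSE) {
  if (inherits(points, "restitution_points"))
    points <- points[!points$blocked & !is.na(points$di), ]
  di <- points$di
  apd <- points$apd
  if (anyDuplicated(di)) stop("invalid input: duplicate DI values")
  o <- order(di)
  di <- di[o]; apd <- apd[o]
  if (length(di) < 4) stop("need at least 4 (DI, APD) points")
  if (smoothing) {
    sm <- stats::smooth.spline(di, apd)
    f0 <- function(x) stats::predict(sm, x)$y
  } else {
    f0 <- splinefun(di, apd, method = "natural")
  }
  lo <- di[1]; hi <- di[length(di)]
  F <- function(x) f0(pmin(pmax(x, lo), hi))
  structure(list(F = F, domain = c(lo, hi), dimin_block = dimin_block,
                 knots = data.frame(di = di, apd = apd)),
            class = "restitution_map")
}

#' @export
print.restitution_map <- function(x, ...) {
  cat("<restitution_map> ", nrow(x$knots), " knots, DI domain [",
      round(x$domain[1], 1), ", ", round(x$domain[2], 1),
      "] ms, block below ", x$dimin_block, " ms\n", sep = "")
  invisible(x)
}

#' Iterate the APD map at fixed pacing period
#'
#' The beat-to-beat map is `A[n+1] = F(DI[n])`, `DI[n+1] = T - A[n+1]`.  The
#' trajectory terminates with status `"block"` when the next DI falls below
#' the map's block threshold (or below 0).  After `n_max` iterations the
#' trajectory is classified `"period1"` when the last two DIs agree within
#' `tol`, `"period2"` when alternate iterates agree within `tol`, otherwise
#' `"max_iter"`.
#'
#' @param map a [fit_restitution_spline()] result.
#' @param T pacing period (ms).
#' @param DI0 initial diastolic interval (ms), inside the map domain.
#' @param n_max maximum iterations (default 100).
#' @param tol period classification tolerance (ms, default 1e-3).
#' @return list of class `map_trajectory`: `apd`, `di` (sequences; `di[1]` is
#'   `DI0`), `status`.
#' @export
iterate_map <- function(map, T, DI0, n_max = 100, tol = 1e-3) {
  stopifnot(inherits(map, "restitution_map"))
  if (DI0 < map$domain[1] - 1e-9 || DI0 > map$domain[2] + 1e-9)
    stop("invalid input: DI0 outside map domain")
  di <- numeric(n_max + 1)
  a <- numeric(n_max)
  di[1] <- DI0
  status <- NULL
  n_done <- 0
  for (n in seq_len(n_max)) {
    a[n] <- map$F(di[n])
    di[n + 1] <- T - a[n]
    n_done <- n
    if (di[n + 1] < max(map$dimin_block, 0)) {
      status <- "block"
      break
    }
  }
  if (is.null(status)) {
    # classification from the trajectory tail
    if (abs(di[n_max + 1] - di[n_max]) < tol) status <- "converged_period1"
    else if (n_max >= 2 && abs(di[n_max + 1] - di[n_max - 1]) < tol)
      status <- "period2"
    else status <- "max_iter"
  }
  structure(list(apd = a[seq_len(n_done)], di = di[seq_len(n_done + 1)],
                 status = status, T = T),
            class = "map_trajectory")
}

# G(DI) = T - F(DI), the single-variable form of the map
map_G <- function(map, T) function(x) T - map$F(x)

#' Fixed points of the second-iterate map
#'
#' Finds all roots of `G2(DI) - DI = 0` with `G(DI) = T - F(DI)` and
#' `G2 = G(G(.))` by sign-change bracketing on a dense DI grid followed by
#' bisection.  Roots that also satisfy `G(DI) = DI` are tagged `"period1"`;
#' the others come in pairs forming period-2 orbits.  Stability is read from
#' `|dG2/dDI|` at the root (< 1 stable), evaluated by central differences.
#'
#' @param map a `restitution_map`.
#' @param T pacing period (ms).
#' @param n_grid grid resolution (default 2000).
#' @param tol bisection tolerance (ms, default 1e-6).
#' @return data.frame with `di`, `stability` (`"stable"`/`"unstable"`),
#'   `type` (`"period1"`/`"period2-member"`), `slope` (dG2/dDI).  May be
#'   empty.
#' @export
second_iterate_fixed_points <- function(map, T, n_grid = 2000, tol = 1e-6) {
  G <- map_G(map, T)
  G2 <- function(x) G(G(x))
  h <- function(x) G2(x) - x
  lo <- map$domain[1]; hi <- map$domain[2]
  xs <- seq(lo, hi, length.out = n_grid)
  hs <- h(xs)
  roots <- numeric(0)
  for (i in seq_len(n_grid - 1)) {
    if (is.na(hs[i]) || is.na(hs[i + 1])) next
    if (hs[i] == 0) roots <- c(roots, xs[i])
    else if (hs[i] * hs[i + 1] < 0) {
      r <- uniroot(h, c(xs[i], xs[i + 1]), tol = tol)$root
      roots <- c(roots, r)
    }
  }
  if (length(hs) && hs[n_grid] == 0) roots <- c(roots, xs[n_grid])
  if (!length(roots))
    return(data.frame(di = numeric(0), stability = character(0),
                      type = character(0), slope = numeric(0)))
  roots <- sort(roots)
  keep <- c(TRUE, diff(roots) > 10 * tol)
  roots <- roots[keep]
  eps <- max(1e-4, tol * 10)
  slope <- vapply(roots, function(r) {
    (G2(min(r + eps, hi)) - G2(max(r - eps, lo))) /
      (min(r + eps, hi) - max(r - eps, lo))
  }, numeric(1))
  is_p1 <- vapply(roots, function(r) abs(G(r) - r) < 1e-3, logical(1))
  data.frame(di = roots,
             stability = ifelse(abs(slope) < 1, "stable", "unstable"),
             type = ifelse(is_p1, "period1", "period2-member"),
             slope = slope)
}

#' Bifurcation diagram of the map under a period sweep
#'
#' Iterates the map to steady state at each period in `T_range`, carrying the
#' final DI forward as the next period's initial condition (resetting to the
#' domain midpoint after a block), in the requested direction(s).  The
#' steady-state APD values (last `record` iterates after `settle` settling
#' iterates) are recorded per period; the hysteresis interval is the set of
#' periods classified period-2 in one direction only.
#'
#' @param map a `restitution_map`.
#' @param T_range periods to sweep (ms).
#' @param direction `"up"`, `"down"`, or `"both"`.
#' @param DI0 initial DI for the first period (default: domain midpoint).
#' @param settle,record settling / recorded iterates per period.
#' @return list of class `map_bifurcation`: `data` (direction, T, apd),
#'   `status` (per T), `hysteresis` (period interval or NULL).
#' @export
map_bifurcation_diagram <- function(map, T_range, direction = c("both", "up", "down"),
                                    DI0 = NULL, settle = 300, record = 8) {
  direction <- match.arg(direction)
  dirs <- switch(direction, both = c("up", "down"), up = "up", down = "down")
  DI0 <- DI0 %||% mean(map$domain)
  out <- list(); st <- list()
  for (d in dirs) {
    Ts <- if (d == "up") sort(T_range) else sort(T_range, decreasing = TRUE)
    di <- DI0
    for (T in Ts) {
      tr <- iterate_map(map, T, di, n_max = settle + record)
      k <- length(tr$apd)
      apds <- if (tr$status == "block") NA_real_
              else unique(round(tail(tr$apd, record), 6))
      out[[length(out) + 1]] <- data.frame(direction = d, T = T, apd = apds)
      st[[length(st) + 1]] <- data.frame(direction = d, T = T,
                                         status = tr$status)
      di_last <- tail(tr$di, 1)
      di <- if (tr$status == "block" ||
                di_last < map$domain[1] || di_last > map$domain[2])
              mean(map$domain) else di_last
    }
  }
  data <- do.call(rbind, out)
  status <- do.call(rbind, st)
  hyst <- NULL
  if (length(dirs) == 2) {
    p2 <- function(d) sort(status$T[status$direction == d &
                                    status$status == "period2"])
    up2 <- p2("up"); dn2 <- p2("down")
    both <- union(setdiff(up2, dn2), setdiff(dn2, up2))
    if (length(both)) hyst <- range(both)
  }
  structure(list(data = data, status = status, hysteresis = hyst),
            class = "map_bifurcation")
}

#' Phase diagram over (T, DI0)
#'
#' Classifies the long-run behaviour of the map for every combination of
#' pacing period and initial DI: `"period1"`, `"period2"`, or `"block"`
#' (the trajectory reached a DI below the block threshold at some point).
#' Each cell is independent, so the result does not depend on traversal
#' order.
#'
#' @param map a `restitution_map`.
#' @param T_grid pacing periods (ms).
#' @param DI0_grid initial DIs (ms), within the map domain.
#' @param n_iter iterations per cell (default 100).
#' @return character matrix (rows: `DI0_grid`, cols: `T_grid`) of class
#'   `map_phase_diagram`, with dimnames.
#' @export
phase_diagram <- function(map, T_grid, DI0_grid, n_iter = 100) {
  lab <- matrix(NA_character_, length(DI0_grid), length(T_grid),
                dimnames = list(DI0 = signif(DI0_grid, 8),
                                T = signif(T_grid, 8)))
  for (j in seq_along(T_grid))
    for (i in seq_along(DI0_grid)) {
      tr <- iterate_map(map, T_grid[j], DI0_grid[i], n_max = n_iter)
      lab[i, j] <- switch(tr$status,
                          block = "block",
                          converged_period1 = "period1",
                          period2 = "period2",
                          max_iter = "period2")
    }
  structure(lab, class = c("map_phase_diagram", class(lab)))
}

#' Cobweb polyline for graphical iteration
#'
#' Builds the alternating vertical/diagonal polyline that traces the map
#' iteration in the (DI, APD) plane: from `(DI_n, A_n)` vertically to the
#' curve `(DI_n, F(DI_n))`, then across to `(DI_{n+1}, F(DI_n))`.
#'
#' @param map a `restitution_map`.
#' @param T pacing period (ms).
#' @param DI0 initial DI (ms).
#' @param n iterations.
#' @return data.frame with `di`, `apd` polyline vertices (2 segments per
#'   iteration; a fixed-point start yields a degenerate polyline).
#' @export
cobweb_trajectory <- function(map, T, DI0, n) {
  tr <- iterate_map(map, T, DI0, n_max = n)
  k <- length(tr$apd)
  di <- numeric(2 * k + 1)
  ap <- numeric(2 * k + 1)
  di[1] <- tr$di[1]; ap[1] <- T - tr$di[1]  # start on the pacing diagonal
  for (i in seq_len(k)) {
    di[2 * i] <- tr$di[i];     ap[2 * i] <- tr$apd[i]
    di[2 * i + 1] <- tr$di[i + 1]; ap[2 * i + 1] <- tr$apd[i]
  }
  data.frame(di = di, apd = ap)
}
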