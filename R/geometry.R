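#' Generate an Archimedean spiral
#'
#' Samples the polar form `r = (spacing / 2 pi) * theta` uniformly in
#' `theta` over `[0, 2 pi * turns]`, starting at the center. Clockwise is
#' the screen-native orientation (y grows downward); counter-clockwise
#' spirals are the mirror image about the vertical axis through the center.
#'
#' @param center numeric length-2, spiral center in pixels.
#' @param spacing_px radial gap between consecutive turns (pixels), > 0.
#' @param turns number of full turns, > 0.
#' @param direction `"cw"` or `"ccw"`.
#' @param n_points number of sample points (>= 2).
#' @return a `cogscreen_curve` tibble with columns `x`, `y`.
#' @export
generate_spiral <- function(center = c(0, 0), spacing_px = 100, turns = 3,
                            direction = c("cw", "ccw"), n_points = 256L) {
  direction <- match.arg(direction)
  if (spacing_px <= 0 || turns <= 0) abort_domain("spacing_px and turns must be positive")
  if (n_points < 2) abort_domain("n_points must be >= 2")
  theta <- seq(0, 2 * pi * turns, length.out = n_points)
  r <- spacing_px / (2 * pi) * theta
  x <- r * cos(theta)
  if (direction == "ccw") x <- -x
  curve2d(center[1] + x, center[2] + r * sin(theta))
}

#' @rdname generate_spiral
#' @param x,y point coordinates (pixels).
#' @export
curve2d <- function(x, y) {
  if (length(x) < 1L) abort_domain("a curve needs at least one point")
  if (length(x) != length(y)) abort_validation("x and y must have equal length")
  if (!all(is.finite(x)) || !all(is.finite(y))) abort_domain("curve coordinates must be finite")
  out <- tibble::tibble(x = as.numeric(x), y = as.numeric(y))
  class(out) <- c("cogscreen_curve", class(out))
  out
}

as_curve <- function(obj) {
  if (inherits(obj, "cogscreen_curve")) return(obj)
  if (is_trajectory(obj)) return(curve2d(obj$x_px, obj$y_px))
  if (is.matrix(obj)) return(curve2d(obj[, 1], obj[, 2]))
  if (is.data.frame(obj)) {
    xn <- intersect(c("x", "x_px"), names(obj))[1]
    yn <- intersect(c("y", "y_px"), names(obj))[1]
    return(curve2d(obj[[xn]], obj[[yn]]))
  }
  abort_validation("cannot interpret object as a 2-D curve")
}

# resample a curve to at most n points, uniformly by cumulative arc length
resample_curve <- function(curve, n = 512L) {
  curve <- as_curve(curve)
  m <- nrow(curve)
  if (m <= n) return(curve)
  seg <- sqrt(diff(curve$x)^2 + diff(curve$y)^2)
  s <- c(0, cumsum(seg))
  if (s[m] == 0) return(curve[1, ])
  target <- seq(0, s[m], length.out = n)
  curve2d(stats::approx(s, curve$x, xout = target, ties = "ordered")$y,
          stats::approx(s, curve$y, xout = target, ties = "ordered")$y)
}

#' Discrete Frechet distance
#'
#' Minimum over monotone couplings of two point sequences of the maximum
#' pairwise Euclidean distance (the "dog-leash" distance), computed by the
#' standard dynamic program. Long trajectories are first resampled by arc
#' length to at most `max_points` points to bound the quadratic cost.
#'
#' @param a,b curves: `cogscreen_curve`, trajectory, two-column matrix or
#'   data frame with `x`/`y` columns.
#' @param max_points resampling bound (default 512).
#' @return non-negative scalar distance in pixels.
#' @export
discrete_frechet <- function(a, b, max_points = 512L) {
  a <- resample_curve(as_curve(a), max_points)
  b <- resample_curve(as_curve(b), max_points)
  .frechet_dp(cbind(a$x, a$y), cbind(b$x, b$y))
}

#' Percentage match of a drawn curve against a reference
#'
#' Fraction of drawn points whose nearest reference point lies within
#' `radius_px` (Euclidean distance).
#'
#' @param drawn,reference curves (see [discrete_frechet()] for accepted forms).
#' @param radius_px positive tolerance radius in pixels.
#' @return a fraction in `[0, 1]`.
#' @export
percentage_match <- function(drawn, reference, radius_px) {
  if (radius_px <= 0) abort_domain("radius_px must be positive")
  drawn <- as_curve(drawn); reference <- as_curve(reference)
  r2 <- radius_px^2
  hit <- vapply(seq_len(nrow(drawn)), function(i) {
    d2 <- (reference$x - drawn$x[i])^2 + (reference$y - drawn$y[i])^2
    min(d2) <= r2
  }, logical(1))
  mean(hit)
}

#' Angle between two line slopes
#'
#' `atan(|m1 - m2| / |1 + m1 m2|)` in degrees; perpendicular pairs
#' (`1 + m1 m2 = 0`) give 90, two vertical lines give 0, and a vertical
#' line against slope `m` gives `90 - |atan(m)|`.
#'
#' @param m1,m2 slopes; pass `Inf` (or set the flags) for vertical lines.
#' @param v1,v2 logical vertical-line flags.
#' @return angle in degrees in `[0, 90]`.
#' @export
parallel_angle <- function(m1, m2, v1 = is.infinite(m1), v2 = is.infinite(m2)) {
  if (v1 && v2) return(0)
  if (v1 || v2) {
    m <- if (v1) m2 else m1
    return(90 - abs(atan(m)) * 180 / pi)
  }
  den <- 1 + m1 * m2
  if (abs(den) < .Machine$double.eps^0.5 * (1 + abs(m1 * m2))) return(90)
  atan(abs(m1 - m2) / abs(den)) * 180 / pi
}

#' Total-least-squares line slope of a stroke
#'
#' First principal axis of the point cloud; robust to the y-down screen
#' orientation and to steep strokes.
#'
#' @param curve a curve or trajectory.
#' @return list with `slope` (possibly `Inf`) and `vertical` flag.
#' @export
fit_line_slope <- function(curve) {
  curve <- as_curve(curve)
  if (nrow(curve) < 2) abort_domain("need >= 2 points to fit a line")
  cx <- curve$x - mean(curve$x); cy <- curve$y - mean(curve$y)
  cv <- crossprod(cbind(cx, cy)) / max(1, nrow(curve) - 1)
  ev <- eigen(cv, symmetric = TRUE)$vectors[, 1]
  if (abs(ev[1]) < 1e-9 * abs(ev[2])) list(slope = Inf, vertical = TRUE)
  else list(slope = ev[2] / ev[1], vertical = FALSE)
}

#' Parallel-pair score over fitted edge slopes
#'
#' For each configured edge pair, computes the slope angle and counts pairs
#' within the tolerance; the task passes when the within-tolerance fraction
#' reaches `match_pct`.
#'
#' @param slopes list of slope fits as returned by [fit_line_slope()] (or
#'   numeric slopes), indexed by edge.
#' @param pairs list (or 2-column matrix) of edge index pairs.
#' @param angle_tol_deg tolerance in degrees (default 10).
#' @param match_pct required fraction of parallel pairs (default 0.5).
#' @return list with `fraction`, `pass`, and per-pair `angles`.
#' @export
parallel_pairs_score <- function(slopes, pairs, angle_tol_deg = 10, match_pct = 0.5) {
  if (is.matrix(pairs)) pairs <- asplit(pairs, 1)
  if (!length(pairs)) abort_domain("pair list must be non-empty")
  norm_slope <- function(s) if (is.list(s)) s else list(slope = s, vertical = is.infinite(s))
  angles <- vapply(pairs, function(p) {
    s1 <- norm_slope(slopes[[p[1]]]); s2 <- norm_slope(slopes[[p[2]]])
    parallel_angle(s1$slope, s2$slope, s1$vertical, s2$vertical)
  }, numeric(1))
  fraction <- mean(angles < angle_tol_deg)
  list(fraction = fraction, pass = fraction >= match_pct, angles = angles)
}

#' Resolve which layout nodes a stroke touches
#'
#' Returns node ids whose centers come within `hit_radius_px` of any stroke
#' point, in first-touch order, deduplicated.
#'
#' @param stroke a trajectory or curve.
#' @param layout a [graph_layout()].
#' @param hit_radius_px hit radius; defaults to the layout's node radius.
#' @return character vector of node ids (possibly empty).
#' @export
resolve_stroke_nodes <- function(stroke, layout, hit_radius_px = layout$node_radius_px) {
  if (hit_radius_px <= 0) abort_domain("hit_radius_px must be positive")
  pts <- as_curve(stroke)
  r2 <- hit_radius_px^2
  first_touch <- vapply(seq_len(nrow(layout$nodes)), function(k) {
    d2 <- (pts$x - layout$nodes$x_px[k])^2 + (pts$y - layout$nodes$y_px[k])^2
    idx <- which(d2 <= r2)
    if (length(idx)) idx[1] else NA_integer_
  }, integer(1))
  hit <- which(!is.na(first_touch))
  layout$nodes$node_id[hit[order(first_touch[hit])]]
}

## ---- assignment + neighbor matching ------------------------------------

# O(n^3) Hungarian algorithm; returns for each row the assigned column of a
# minimum-cost perfect matching (rows <= cols).
hungarian_min <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n > m) abort_domain("cost matrix must have nrow <= ncol")
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1); v <- numeric(m + 1)
  p <- integer(m + 1); way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i; j0 <- 0
    minv <- rep(INF, m + 1); used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- INF; j1 <- 0
      for (j in seq_len(m)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:m) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]; p[j0 + 1] <- p[j1 + 1]; j0 <- j1
      if (j0 == 0) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(m)) if (p[j + 1] > 0) assignment[p[j + 1]] <- j
  assignment
}

# maximum-total-similarity assignment value for a similarity matrix in [0,1]
assignment_max <- function(sim) {
  transposed <- nrow(sim) > ncol(sim)
  if (transposed) sim <- t(sim)
  cols <- hungarian_min(1 - sim)
  sum(sim[cbind(seq_len(nrow(sim)), cols)])
}

adjacency_list <- function(layout) {
  ids <- layout$nodes$node_id
  adj <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) adj[[id]] <- character()
  if (nrow(layout$edges)) {
    for (k in seq_len(nrow(layout$edges))) {
      a <- layout$edges$from[k]; b <- layout$edges$to[k]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  adj
}

#' Neighbor-matching graph similarity
#'
#' Iterative node-similarity refinement: the similarity of a node pair is
#' the optimally assigned similarity of their neighbors, divided by the
#' larger degree (pairs of isolated nodes count as fully similar). The
#' fixed point is reached when no entry moves by more than `eps`. The graph
#' similarity is the mean optimal node-assignment similarity across the two
#' node sets (unmatched nodes of the larger graph count as zero), so it is
#' 1 exactly for isomorphic graphs and is invariant to node relabeling.
#'
#' @param g1,g2 [graph_layout()] objects (edges matter; positions do not).
#' @param eps convergence threshold on the max entry change (default 1e-4).
#' @param max_iter iteration cap (default 100).
#' @return similarity in `[0, 1]`.
#' @export
neighbor_matching_similarity <- function(g1, g2, eps = 1e-4, max_iter = 100L) {
  n1 <- nrow(g1$nodes); n2 <- nrow(g2$nodes)
  if (n1 == 0 || n2 == 0) abort_domain("graphs must be non-empty")
  a1 <- adjacency_list(g1); a2 <- adjacency_list(g2)
  d1 <- lengths(a1); d2 <- lengths(a2)
  idx1 <- stats::setNames(seq_len(n1), g1$nodes$node_id)
  idx2 <- stats::setNames(seq_len(n2), g2$nodes$node_id)
  x <- matrix(1, n1, n2)
  for (iter in seq_len(max_iter)) {
    xn <- matrix(0, n1, n2)
    for (i in seq_len(n1)) {
      ni <- idx1[a1[[i]]]
      for (j in seq_len(n2)) {
        nj <- idx2[a2[[j]]]
        dmax <- max(d1[i], d2[j])
        if (dmax == 0) {
          xn[i, j] <- 1  # two isolated nodes are indistinguishable
        } else if (length(ni) == 0 || length(nj) == 0) {
          xn[i, j] <- 0
        } else {
          xn[i, j] <- assignment_max(x[ni, nj, drop = FALSE]) / dmax
        }
      }
    }
    delta <- max(abs(xn - x))
    x <- xn
    if (delta < eps) break
  }
  assignment_max(x) / max(n1, n2)
}

## ---- point in polygon ---------------------------------------------------

# even-odd ray casting; points on an edge count as inside
point_in_polygon <- function(px, py, poly_x, poly_y) {
  n <- length(poly_x)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly_x[i]; yi <- poly_y[i]; xj <- poly_x[j]; yj <- poly_y[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
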