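#' Polylines and points
#'
#' A polyline is an n x 2 numeric matrix of finite (x, y) coordinates, one row
#' per vertex, in an obstacle-free plane with dimensionless continuous
#' coordinates. A point is a numeric vector of length 2. Consecutive duplicate
#' vertices are permitted and contribute zero length.
#'
#' @param points a matrix coercible to n x 2 numeric, or a list of length-2
#'   numeric vectors
#' @return `as_polyline()` returns the validated n x 2 matrix with columns
#'   `x`, `y`.
#' @examples
#' as_polyline(rbind(c(0, 0), c(3, 0), c(3, 4)))
#' @export
as_polyline <- function(points) {
  if (is.list(points)) points <- do.call(rbind, lapply(points, as.numeric))
  if (is.numeric(points) && is.null(dim(points)) && length(points) == 2L)
    points <- matrix(points, nrow = 1L)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (nrow(points) < 1L || ncol(points) != 2L)
    stop("a polyline needs at least one (x, y) point", call. = FALSE)
  if (!all(is.finite(points)))
    stop("polyline coordinates must be finite", call. = FALSE)
  dimnames(points) <- list(NULL, c("x", "y"))
  points
}

#' Arclength of a polyline
#'
#' The cost of a trajectory is its Euclidean arclength: the sum of segment
#' lengths between consecutive vertices. A single point has arclength 0.
#'
#' @param p a polyline (see [as_polyline()])
#' @return nonnegative scalar
#' @examples
#' arclength(rbind(c(0, 0), c(3, 0), c(3, 4))) # 7
#' @export
arclength <- function(p) {
  p <- as_polyline(p)
  if (nrow(p) == 1L) return(0)
  sum(sqrt(rowSums(diff(p)^2)))
}

# cumulative arclength at every vertex (first entry 0)
cum_arclength <- function(p) {
  if (nrow(p) == 1L) return(0)
  c(0, cumsum(sqrt(rowSums(diff(p)^2))))
}

#' Cost of the optimal path between two points
#'
#' In an obstacle-free plane the optimal (rational) plan between two points is
#' the straight segment, so the optimal cost is the Euclidean distance.
#'
#' @param a,b points (length-2 numeric)
#' @return nonnegative scalar; symmetric; zero iff `a == b`
#' @examples
#' optimal_cost(c(0, 0), c(-3, 4)) # 5
#' @export
optimal_cost <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != 2L || length(b) != 2L || !all(is.finite(c(a, b))))
    stop("optimal_cost() expects two finite 2D points", call. = FALSE)
  sqrt(sum((a - b)^2))
}

#' Last point of a polyline
#'
#' @param t a polyline
#' @return length-2 numeric vector
#' @export
last_point <- function(t) {
  t <- as_polyline(t)
  t[nrow(t), ]
}

# per-segment geometry of a polyline, precomputed once per query:
# segment origins (ax, ay), extents (dx, dy), squared lengths, lengths, and
# cumulative arclength at each segment origin
.seg_stats <- function(t) {
  n <- nrow(t)
  x <- t[, 1]; y <- t[, 2]
  if (n == 1L)
    return(list(ax = x, ay = y, dx = 0, dy = 0, len2 = 0, slen = 0, cs0 = 0))
  ax <- x[-n]; ay <- y[-n]
  dx <- x[-1L] - ax; dy <- y[-1L] - ay
  len2 <- dx * dx + dy * dy
  slen <- sqrt(len2)
  list(ax = ax, ay = ay, dx = dx, dy = dy, len2 = len2, slen = slen,
       cs0 = cumsum(c(0, slen[-length(slen)])))
}

# closest point on the polyline (given its .seg_stats) to a single point;
# returns c(x, y, distance, arclength position)
.closest_single <- function(px, py, ss) {
  u <- ((px - ss$ax) * ss$dx + (py - ss$ay) * ss$dy) /
    pmax(ss$len2, .Machine$double.xmin)
  u[u < 0] <- 0; u[u > 1] <- 1
  cx <- ss$ax + u * ss$dx
  cy <- ss$ay + u * ss$dy
  d2 <- (px - cx)^2 + (py - cy)^2
  j <- which.min(d2)
  c(cx[j], cy[j], sqrt(d2[j]), ss$cs0[j] + u[j] * ss$slen[j])
}

#' Closest point on a polyline
#'
#' Finds the point on polyline `t` (segment interiors allowed, not only
#' vertices) minimizing the Euclidean distance to `p`. When the minimum
#' distance exceeds `cutoff` no point is returned.
#'
#' @param p a point
#' @param t a polyline
#' @param cutoff positive scalar or `Inf` (default): maximum distance beyond
#'   which the query reports no close point
#' @return a list with `point` (length-2 numeric or `NULL`), `distance`, and
#'   `s` (arclength position of the closest point along `t`, or `NA`)
#' @examples
#' closest_point(c(0, 2), rbind(c(0, 0), c(-3, 4)))
#' @export
closest_point <- function(p, t, cutoff = Inf) {
  p <- as.numeric(p)
  t <- as_polyline(t)
  r <- .closest_single(p[1], p[2], .seg_stats(t))
  if (r[3] > cutoff) return(list(point = NULL, distance = r[3], s = NA_real_))
  list(point = c(x = r[1], y = r[2]), distance = r[3], s = r[4])
}

#' Arclength prefix of a polyline
#'
#' The initial sub-polyline whose arclength equals `fraction` times the full
#' arclength, interpolating inside a segment when the target length falls
#' between vertices. `fraction = 0` gives the single start point and
#' `fraction = 1` the full polyline.
#'
#' @param t a polyline with at least 2 points (or any polyline when
#'   `fraction = 0`)
#' @param fraction scalar in \[0, 1\]
#' @return a polyline
#' @examples
#' polyline_prefix(rbind(c(0, 0), c(10, 0)), 0.25) # ends at (2.5, 0)
#' @export
polyline_prefix <- function(t, fraction) {
  t <- as_polyline(t)
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction < 0 || fraction > 1)
    stop("fraction must be a scalar in [0, 1]", call. = FALSE)
  if (fraction == 0) return(t[1L, , drop = FALSE])
  if (fraction == 1) return(t)
  cs <- cum_arclength(t)
  target <- fraction * cs[length(cs)]
  if (target <= 0) return(t[1L, , drop = FALSE])
  k <- findInterval(target, cs, rightmost.closed = TRUE)  # segment index
  # skip zero-length segments sitting exactly at the target
  while (k < nrow(t) - 1L && cs[k + 1L] <= target) k <- k + 1L
  seg <- t[k + 1L, ] - t[k, ]
  seg_len <- cs[k + 1L] - cs[k]
  end <- if (seg_len > 0) t[k, ] + seg * (target - cs[k]) / seg_len else t[k, ]
  out <- rbind(t[seq_len(k), , drop = FALSE], end)
  dimnames(out) <- list(NULL, c("x", "y"))
  out
}

#' Is one polyline a spatial prefix of another?
#'
#' `o` is a spatial prefix of `t` when every point of `o` lies within `tol`
#' of the polyline `t` AND the points of `o` can be projected onto `t` at
#' non-decreasing arclength positions starting from the start of `t`. The
#' monotone-progression requirement distinguishes a genuine prefix from an
#' observation that merely stays near `t` (for example a curl that doubles
#' back over a straight plan).
#'
#' @param o,t polylines
#' @param tol nonnegative match tolerance, in coordinate units
#' @return `TRUE` or `FALSE`
#' @export
prefix_match <- function(o, t, tol) {
  o <- as_polyline(o)
  t <- as_polyline(t)
  if (!is.numeric(tol) || length(tol) != 1L || is.na(tol) || tol < 0)
    stop("tol must be a nonnegative scalar", call. = FALSE)
  tol2 <- tol^2 * (1 + 1e-12)
  # o must take off from the start of t
  if (sum((o[1L, ] - t[1L, ])^2) > tol2) return(FALSE)
  ss <- .seg_stats(t)
  # cheap necessary condition first: the last point of o is the one most
  # likely to have left the tol-tube
  if (.closest_single(o[nrow(o), 1], o[nrow(o), 2], ss)[3]^2 > tol2)
    return(FALSE)
  # greedy monotone assignment: for each point of o take the smallest
  # admissible arclength position on t not behind the previous one
  s_prev <- 0
  for (i in seq_len(nrow(o))) {
    px <- o[i, 1]; py <- o[i, 2]
    u <- ((px - ss$ax) * ss$dx + (py - ss$ay) * ss$dy) /
      pmax(ss$len2, .Machine$double.xmin)
    u[u < 0] <- 0; u[u > 1] <- 1
    d2 <- (px - (ss$ax + u * ss$dx))^2 + (py - (ss$ay + u * ss$dy))^2
    within <- d2 <= tol2
    if (!any(within)) return(FALSE)
    cand <- (ss$cs0 + u * ss$slen)[within]
    cand <- cand[cand >= s_prev - tol]
    if (length(cand) == 0L) return(FALSE)
    s_prev <- max(s_prev, min(cand))
  }
  TRUE
}
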