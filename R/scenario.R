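#' Two-goal reaching scenarios with curvature-ranked plan libraries
#'
#' A scenario holds a start point, an ordered set of goal points, and a plan
#' library partitioned by goal: `library[[g]]` is the list of trajectories
#' known to end at goal `g`. Each trajectory carries its discretized polyline,
#' its goal id and a curvature index.
#'
#' @name scenario
NULL

#' Construct trajectories and scenarios by hand
#'
#' Low-level constructors for building scenarios directly, e.g. small
#' fixtures; [make_berkovitz_scenario()] is the usual entry point.
#'
#' @param points polyline of the trajectory
#' @param goal_id 1-based goal index
#' @param curve_index curvature rank of the trajectory among its goal's plans
#' @param start start point
#' @param goals matrix of goal points (one row per goal)
#' @param library list over goal ids of lists of trajectories (defaults to an
#'   empty library)
#' @return a `trajectory` / `scenario` object
#' @export
trajectory <- function(points, goal_id, curve_index = 1L) {
  structure(
    list(points = as_polyline(points), goal_id = as.integer(goal_id),
         curve_index = as.integer(curve_index)),
    class = "trajectory")
}

#' @rdname trajectory
#' @export
scenario <- function(start, goals, library = NULL) {
  goals <- as_polyline(goals)
  if (is.null(library)) library <- rep(list(list()), nrow(goals))
  structure(list(start = as.numeric(start), goals = goals,
                 library = library),
            class = "scenario")
}

new_trajectory <- trajectory
new_scenario <- scenario

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory %d to goal %d: %d points, arclength %.4g>\n",
              x$curve_index, x$goal_id, nrow(x$points), arclength(x$points)))
  invisible(x)
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("Two-dimensional goal-recognition scenario\n"))
  cat(sprintf("  start: (%g, %g)\n", x$start[1], x$start[2]))
  for (g in seq_len(nrow(x$goals)))
    cat(sprintf("  goal %d: (%g, %g), %d library trajectories\n",
                g, x$goals[g, 1], x$goals[g, 2], length(x$library[[g]])))
  invisible(x)
}

#' @export
plot.scenario <- function(x, ...) {
  pts <- do.call(rbind, lapply(flatten_library(x$library),
                               function(t) t$points))
  graphics::plot(pts[, 1], pts[, 2], type = "n", xlab = "x", ylab = "y", ...)
  for (g in seq_len(nrow(x$goals)))
    for (t in x$library[[g]])
      graphics::lines(t$points, col = g + 1)
  graphics::points(rbind(x$start), pch = 16)
  graphics::points(x$goals, pch = 8, col = seq_len(nrow(x$goals)) + 1)
  invisible(x)
}

#' All trajectories of a library partition as one flat list
#'
#' @param lib a library partition (list over goal ids of trajectory lists)
#' @return a flat list of `trajectory` objects
#' @export
flatten_library <- function(lib) {
  do.call(c, lib)
}

# largest pairwise extent of the scenario's geometry; used to scale the
# default match tolerance
scenario_diameter <- function(s) {
  pts <- rbind(matrix(s$start, ncol = 2), s$goals,
               do.call(rbind, lapply(flatten_library(s$library),
                                     function(t) t$points)))
  sqrt(sum((apply(pts, 2, max) - apply(pts, 2, min))^2))
}

#' Default prefix-match tolerance for a scenario
#'
#' One part in 10^6 of the scenario diameter (the diagonal of the bounding box
#' of all scenario geometry): tight enough that only genuinely shared
#' segments match, loose enough to absorb floating-point interpolation error.
#'
#' @param s a scenario
#' @return positive scalar
#' @export
default_tol <- function(s) {
  1e-6 * scenario_diameter(s)
}

# quadratic Bezier from a through control c to b, discretized at n points
# uniformly in the curve parameter
quad_bezier <- function(a, c, b, n) {
  u <- seq(0, 1, length.out = n)
  cbind((1 - u)^2 * a[1] + 2 * u * (1 - u) * c[1] + u^2 * b[1],
        (1 - u)^2 * a[2] + 2 * u * (1 - u) * c[2] + u^2 * b[2])
}

# mean distance of a trajectory's points from a goal point; the curvature
# ranking statistic
mean_distance_from <- function(points, goal) {
  mean(sqrt((points[, 1] - goal[1])^2 + (points[, 2] - goal[2])^2))
}

#' Generate a two-goal scenario in the style of Berkovitz's reaching study
#'
#' Builds the layout used in Berkovitz's human-robot goal-recognition
#' experiment: one start point at the origin and two goals equidistant from
#' it, with `n_per_goal` trajectories per goal ranging from the straight
#' (optimal) plan to increasingly curved, inefficient plans. Curved
#' trajectories are quadratic Bezier arcs whose control points bow
#' progressively to the left, so each goal has exactly one straight
#' trajectory. Trajectories are numbered by their mean distance from the
#' distractor (other) goal: index 1 is closest to the distractor and index
#' `n_per_goal` farthest, which places the straight plan at index 1 for the
#' left goal and at index `n_per_goal` for the right goal.
#'
#' When `overlap = TRUE` (and `n_per_goal >= 3`) one strongly curved
#' trajectory to the right goal is rebuilt to share an exact initial segment
#' with a moderately curved trajectory to the left goal, then continue to its
#' own goal along a tangent-continuous Bezier arc. This reproduces the
#' cross-goal initial overlaps of the original layout (where, e.g., a
#' mid-curvature trajectory to one goal initially coincides with a
#' low-index trajectory to the other), the feature that makes early
#' observation prefixes genuinely ambiguous.
#'
#' @param span horizontal separation between the two goals (length units)
#' @param depth vertical distance from the start to the goal line
#' @param n_per_goal trajectories per goal (default 7, giving the study's 14)
#' @param curvature_scale lateral control-point offset between consecutive
#'   curvature steps
#' @param n_points vertices per discretized trajectory
#' @param overlap engineer one exact cross-goal initial overlap?
#' @param overlap_fraction arclength fraction of the donor trajectory copied
#'   into the overlapping one
#' @return a `scenario` object
#' @examples
#' s <- make_berkovitz_scenario()
#' s
#' @export
make_berkovitz_scenario <- function(span = 6, depth = 10, n_per_goal = 7,
                                    curvature_scale = 1, n_points = 200,
                                    overlap = n_per_goal >= 3,
                                    overlap_fraction = 0.2) {
  if (!is.numeric(span) || span <= 0 || !is.numeric(depth) || depth <= 0)
    stop("span and depth must be positive", call. = FALSE)
  if (n_per_goal < 1) stop("n_per_goal must be >= 1", call. = FALSE)
  if (n_points < 100) stop("n_points must be >= 100", call. = FALSE)
  start <- c(0, 0)
  goals <- rbind(c(-span / 2, depth), c(span / 2, depth))

  raw <- vector("list", 2L)
  for (g in 1:2) {
    goal <- goals[g, ]
    raw[[g]] <- lapply(seq_len(n_per_goal) - 1L, function(k) {
      if (k == 0L) {
        # the straight, optimal plan
        u <- seq(0, 1, length.out = n_points)
        cbind(start[1] + u * (goal[1] - start[1]),
              start[2] + u * (goal[2] - start[2]))
      } else {
        ctrl <- (start + goal) / 2 + c(-k * curvature_scale, 0)
        quad_bezier(start, ctrl, goal, n_points)
      }
    })
  }

  if (overlap) {
    if (n_per_goal < 3)
      stop("overlap requires n_per_goal >= 3", call. = FALSE)
    # donor: a moderately curved plan to goal 1; recipient: a strongly curved
    # plan to goal 2 that will initially coincide with it
    donor <- raw[[1]][[max(2L, round((n_per_goal + 1) / 2))]]
    recipient_k <- n_per_goal - 1L
    shared <- polyline_prefix(donor, overlap_fraction)
    j <- nrow(shared)
    tangent <- shared[j, ] - shared[j - 1L, ]
    tangent <- tangent / sqrt(sum(tangent^2))
    goal <- goals[2, ]
    reach <- sqrt(sum((goal - shared[j, ])^2))
    ctrl <- shared[j, ] + tangent * reach / 2
    cont <- quad_bezier(shared[j, ], ctrl, goal, n_points - j + 1L)
    raw[[2]][[recipient_k]] <- rbind(shared, cont[-1L, , drop = FALSE])
  }

  library <- vector("list", 2L)
  for (g in 1:2) {
    distractor <- goals[3 - g, ]
    md <- vapply(raw[[g]], mean_distance_from, numeric(1), goal = distractor)
    ord <- order(md)
    library[[g]] <- lapply(seq_along(ord), function(i)
      new_trajectory(raw[[g]][[ord[i]]], g, i))
  }
  new_scenario(start, goals, library)
}

#' Sample a random sub-library
#'
#' Draws `size` trajectories uniformly at random from the scenario's library
#' with one trajectory excluded (the one to be observed), rejection-sampling
#' until every goal is represented by at least one trajectory. Used by the
#' library-size robustness experiments.
#'
#' @param s a scenario
#' @param size number of trajectories to keep
#' @param exclude the held-out trajectory (a `trajectory` object from
#'   `s$library`)
#' @param seed integer seed; the draw is reproducible given the seed
#' @return a library partition: list over goal ids of lists of trajectories
#' @export
sample_library <- function(s, size, exclude, seed) {
  pool <- flatten_library(s$library)
  keep <- !vapply(pool, function(t)
    t$goal_id == exclude$goal_id && t$curve_index == exclude$curve_index,
    logical(1))
  pool <- pool[keep]
  n_goals <- nrow(s$goals)
  if (size < n_goals)
    stop("size must be at least the number of goals so every goal can be represented",
         call. = FALSE)
  if (size > length(pool))
    stop("size exceeds the library size minus the excluded trajectory",
         call. = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  repeat {
    idx <- sample.int(length(pool), size)
    gids <- vapply(pool[idx], function(t) t$goal_id, integer(1))
    if (length(unique(gids)) == n_goals) break
  }
  out <- rep(list(list()), n_goals)
  for (i in idx) out[[pool[[i]]$goal_id]] <- c(out[[pool[[i]]$goal_id]],
                                               list(pool[[i]]))
  out
}

#' Incremental observation prefixes of a trajectory
#'
#' Prefixes of the trajectory at arclength fractions `step_fraction`,
#' `2 * step_fraction`, ..., 1; the final element is always the full
#' trajectory. These emulate watching the agent's motion unfold.
#'
#' @param t a `trajectory` or a polyline
#' @param step_fraction scalar in (0, 1]
#' @return list with `fractions` (numeric vector) and `prefixes` (list of
#'   polylines)
#' @export
generate_observations <- function(t, step_fraction = 0.02) {
  if (!is.numeric(step_fraction) || step_fraction <= 0 || step_fraction > 1)
    stop("step_fraction must be in (0, 1]", call. = FALSE)
  pts <- if (inherits(t, "trajectory")) t$points else as_polyline(t)
  fractions <- seq(step_fraction, 1, by = step_fraction)
  if (fractions[length(fractions)] < 1) fractions <- c(fractions, 1)
  list(fractions = fractions,
       prefixes = lapply(fractions, function(f) polyline_prefix(pts, f)))
}
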