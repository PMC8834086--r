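#' Library-based rational goal recognition (LRGR)
#'
#' LRGR marries plan-library matching with rationality-based recognition.
#' For every library trajectory `t` leading to goal `g` it computes a
#' matching score `M(t)`:
#'
#' * if the observation is a direct spatial prefix of `t`, `M(t) = 1`;
#' * otherwise an ad-hoc plan is hypothesized that follows the observation,
#'   detours to the closest point `w` on `t`, and continues optimally from
#'   `w` to the goal. Its cost is
#'   `C = arclength(o) + optimal_cost(last(o), w) + optimal_cost(w, g)`, and
#'   `M(t) = optimal_cost(start, g) / C` — the rationality of the
#'   hypothesized plan relative to the optimal plan for the goal.
#'
#' When no close trajectory exists (the goal's library is empty, or every
#' point of `t` is farther than `cutoff` from the last observation), the
#' closest plan is taken to be the observation itself: `w = last(o)` with a
#' zero approach cost, which reduces the score to the mirroring cost ratio.
#'
#' A goal's score is the maximum `M(t)` over its library trajectories, and
#' the posterior is the normalization of the goal scores. An observation
#' lying on trajectories to several goals gives all of them a score of 1 and
#' hence a flatter — more confused — posterior.
#'
#' @param s a scenario
#' @param lib a library partition (list over goal ids of trajectory lists),
#'   e.g. `s$library` or the output of [sample_library()]
#' @param g goal id
#' @param t a `trajectory` belonging to `lib[[g]]`
#' @param o observed polyline anchored at the scenario start
#' @param cutoff maximum distance for the closest-point query (default
#'   unbounded)
#' @param tol prefix-match tolerance
#' @return `matching_score()`: a list with `M` (score in (0, 1\]), `via`
#'   (the closest-point waypoint, or `NULL` for a direct match or fallback),
#'   and `direct` (logical). `lrgr_posterior()`: a goal posterior with
#'   attribute `scores`.
#' @export
matching_score <- function(s, lib, g, t, o, cutoff = Inf,
                           tol = default_tol(s)) {
  o <- .check_anchored(s, o, tol)
  in_lib <- any(vapply(lib[[g]], function(x)
    x$goal_id == t$goal_id && x$curve_index == t$curve_index, logical(1)))
  if (!in_lib)
    stop("trajectory is not in the library partition for this goal",
         call. = FALSE)
  .matching_score_impl(s, g, t, o, cutoff, tol)
}

# core score without the membership check; len_o and n (the observation's
# arclength and last point) may be precomputed by callers scoring many
# library trajectories against the same observation
.matching_score_impl <- function(s, g, t, o, cutoff, tol,
                                 len_o = arclength(o), n = last_point(o)) {
  goal <- s$goals[g, ]
  opt <- optimal_cost(s$start, goal)
  if (prefix_match(o, t$points, tol))
    return(list(M = 1, via = NULL, direct = TRUE))
  cp <- closest_point(n, t$points, cutoff)
  if (is.null(cp$point)) {
    cost <- len_o + optimal_cost(n, goal)
    return(list(M = opt / cost, via = NULL, direct = FALSE))
  }
  cost <- len_o + optimal_cost(n, cp$point) + optimal_cost(cp$point, goal)
  list(M = opt / cost, via = cp$point, direct = FALSE)
}

#' @rdname matching_score
#' @param include_optimal also score the straight optimal plan to each goal as
#'   a virtual library member when the goal's library is nonempty (sensitivity
#'   analysis; default `FALSE`, the literal reading of the algorithm, which
#'   only scores actual library trajectories)
#' @export
lrgr_posterior <- function(s, lib, o, cutoff = Inf, tol = default_tol(s),
                           include_optimal = FALSE) {
  o <- .check_anchored(s, o, tol)
  n_goals <- nrow(s$goals)
  len_o <- arclength(o)
  last_o <- last_point(o)
  scores <- numeric(n_goals)
  for (g in seq_len(n_goals)) {
    cand <- lib[[g]]
    if (include_optimal && length(cand) > 0L)
      cand <- c(cand, list(new_trajectory(rbind(s$start, s$goals[g, ]), g, 0L)))
    if (length(cand) == 0L) {
      # empty-library fallback: the closest plan is the observation itself,
      # giving exactly the mirroring ratio for this goal
      scores[g] <- optimal_cost(s$start, s$goals[g, ]) /
        (len_o + optimal_cost(last_o, s$goals[g, ]))
    } else {
      scores[g] <- max(vapply(cand, function(t)
        .matching_score_impl(s, g, t, o, cutoff, tol, len_o, last_o)$M,
        numeric(1)))
    }
  }
  p <- new_posterior(scores)
  attr(p, "scores") <- scores
  p
}
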