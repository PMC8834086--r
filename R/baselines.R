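#' Idealized library-based plan recognizer
#'
#' The classic plan-recognition baseline that relies purely on the plan
#' library. Let K be the set of goals with at least one library trajectory
#' of which the observation is a spatial prefix (within `tol`). Each goal in
#' K receives likelihood `1/|K|` — 1 for a unique match, 0.5 when the
#' observation matches trajectories to two goals — and every other goal
#' receives 0. When the observation matches no known trajectory every goal
#' receives 0: the output is deliberately left unnormalized in that regime
#' and is treated by the convergence detector as "not yet decided".
#'
#' @param lib a library partition (list over goal ids of trajectory lists)
#' @param o observed polyline
#' @param tol prefix-match tolerance
#' @return a goal posterior (values in `{0, 1/|K|}`) with attribute
#'   `n_matched` = |K|
#' @export
ideal_posterior <- function(lib, o, tol) {
  o <- as_polyline(o)
  matched <- vapply(seq_along(lib), function(g)
    any(vapply(lib[[g]], function(t) prefix_match(o, t$points, tol),
               logical(1))),
    logical(1))
  k <- sum(matched)
  values <- if (k > 0) ifelse(matched, 1 / k, 0) else numeric(length(lib))
  names(values) <- paste0("goal", seq_along(lib))
  attr(values, "n_matched") <- k
  values
}
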