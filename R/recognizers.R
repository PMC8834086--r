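#' Goal posteriors
#'
#' Every recognizer returns a goal posterior: a named numeric vector with one
#' probability per scenario goal, summing to 1 after normalization. Some
#' recognizers carry additional information in attributes (raw un-normalized
#' values, matched-goal counts).
#'
#' @name goal_posterior
NULL

# exponent guard: costs are exponentiated, and a pathological scenario could
# overflow; clip to +-500 before exp()
.clip_exp <- function(x) exp(pmin(pmax(x, -500), 500))

new_posterior <- function(values, raw = NULL) {
  names(values) <- paste0("goal", seq_along(values))
  total <- sum(values)
  p <- if (total > 0) values / total else values
  if (!is.null(raw)) {
    names(raw) <- names(values)
    attr(p, "raw") <- raw
  }
  p
}

.check_anchored <- function(s, o, tol) {
  o <- as_polyline(o)
  if (optimal_cost(o[1L, ], s$start) > tol)
    stop("observation must start at the scenario start point", call. = FALSE)
  o
}

#' Cost of the cheapest plan through the observations
#'
#' The optimal plan for goal `g` constrained to pass through the observed
#' motion: follow the observation, then continue optimally (straight) from
#' its last point to the goal. Its cost is
#' `C(g, O) = arclength(o) + optimal_cost(last(o), g)`.
#'
#' @param s a scenario
#' @param g goal id (index into `s$goals`)
#' @param o observed polyline, anchored at the scenario start
#' @param tol anchoring tolerance (defaults to the scenario's match tolerance)
#' @return nonnegative scalar
#' @export
cost_matching <- function(s, g, o, tol = default_tol(s)) {
  o <- .check_anchored(s, o, tol)
  arclength(o) + optimal_cost(last_point(o), s$goals[g, ])
}

#' Ramirez-Geffner cost-difference recognizer
#'
#' Scores each goal by `exp(-(C(g, O) - C(g, not-O)))`, the exponentiated
#' difference between the cost of the optimal plan constrained to match the
#' observations and the optimal plan constrained not to match them, then
#' normalizes over goals.
#'
#' In an obstacle-free continuous plane a plan "not matching the
#' observations" has no canonical cost, so the implementation uses a declared
#' convention: when the observation is not a prefix of the straight plan to
#' `g`, the optimal plan already fails to match and `C(g, not-O)` is the
#' optimal cost itself; when it is a prefix, the cheapest non-matching plan
#' is charged a minimal detour of twice the match tolerance. This preserves
#' the sign behavior of the original discrete formulation and is an
#' approximation of it.
#'
#' @inheritParams cost_matching
#' @param o observed polyline anchored at the start
#' @return a goal posterior
#' @export
ramirez_geffner <- function(s, o, tol = default_tol(s)) {
  o <- .check_anchored(s, o, tol)
  n_goals <- nrow(s$goals)
  score <- numeric(n_goals)
  for (g in seq_len(n_goals)) {
    straight <- rbind(s$start, s$goals[g, ])
    c_not <- optimal_cost(s$start, s$goals[g, ]) +
      if (prefix_match(o, straight, tol)) 2 * tol else 0
    score[g] <- .clip_exp(-(cost_matching(s, g, o, tol) - c_not))
  }
  new_posterior(score)
}

#' Mirroring cost-ratio recognizer
#'
#' Scores each goal by the ratio `C(g) / C(g, O)` of the optimal plan cost to
#' the cost of the cheapest plan through the observations, then normalizes.
#' The ratio equals 1 exactly when the observation lies on the straight plan
#' to the goal.
#'
#' @inheritParams ramirez_geffner
#' @return a goal posterior
#' @export
mirroring <- function(s, o, tol = default_tol(s)) {
  o <- .check_anchored(s, o, tol)
  score <- vapply(seq_len(nrow(s$goals)), function(g)
    optimal_cost(s$start, s$goals[g, ]) / cost_matching(s, g, o, tol),
    numeric(1))
  new_posterior(score)
}

#' Masters-Sardina last-observation recognizer
#'
#' Depends only on the last observed point N. Each goal's raw likelihood is
#' the sigmoid
#' `exp(-(C(g,N) - C(g,S))) / (1 + exp(-(C(g,N) - C(g,S))))`
#' of the difference between the optimal cost from N to the goal and from
#' the start S to the goal. Raw values do not sum to 1 across goals; the
#' returned posterior is normalized for cross-algorithm comparison and the
#' raw sigmoids are kept in the `"raw"` attribute.
#'
#' @inheritParams ramirez_geffner
#' @return a goal posterior with attribute `raw`
#' @export
masters_sardina <- function(s, o, tol = default_tol(s)) {
  o <- .check_anchored(s, o, tol)
  n <- last_point(o)
  raw <- vapply(seq_len(nrow(s$goals)), function(g) {
    d <- optimal_cost(n, s$goals[g, ]) - optimal_cost(s$start, s$goals[g, ])
    e <- .clip_exp(-d)
    e / (1 + e)
  }, numeric(1))
  new_posterior(raw, raw = raw)
}

#' Dragan legibility-model goal posterior
#'
#' The per-prefix posterior underlying the legibility score:
#' `P(g | O)` proportional to
#' `exp(-(C(O) + C(xi*_{Q->g}))) / exp(-C(xi*_{S->g}))`, i.e.
#' `exp(-(arclength(o) + optimal_cost(last(o), g) - optimal_cost(S, g)))`,
#' normalized over goals. It measures how efficient reaching the goal through
#' the observed motion is relative to the optimal plan.
#'
#' @inheritParams ramirez_geffner
#' @return a goal posterior
#' @export
dragan_posterior <- function(s, o, tol = default_tol(s)) {
  o <- .check_anchored(s, o, tol)
  len <- arclength(o)
  n <- last_point(o)
  score <- vapply(seq_len(nrow(s$goals)), function(g)
    .clip_exp(-(len + optimal_cost(n, s$goals[g, ]) -
                  optimal_cost(s$start, s$goals[g, ]))),
    numeric(1))
  new_posterior(score)
}

#' Legibility of a trajectory
#'
#' The legibility of a trajectory toward its true goal: the weighted average
#' over the motion of the probability the Dragan posterior assigns to the
#' true goal, with earlier portions weighted more heavily via
#' `f(tau) = T - tau` (T the total arclength). Approximated by a midpoint
#' rule over `n_steps` equal arclength cells, which converges quadratically
#' for the smooth integrands arising here.
#'
#' @param s a scenario
#' @param t a `trajectory` (or polyline) ending at `true_goal`
#' @param true_goal goal id
#' @param n_steps quadrature resolution
#' @param tol match tolerance
#' @return scalar in \[0, 1\]
#' @export
legibility_score <- function(s, t, true_goal, n_steps = 50,
                             tol = default_tol(s)) {
  pts <- if (inherits(t, "trajectory")) t$points else as_polyline(t)
  total <- arclength(pts)
  fr <- (seq_len(n_steps) - 0.5) / n_steps     # cell midpoints
  w <- total - fr * total                      # f(tau) = T - tau
  p <- vapply(fr, function(f)
    dragan_posterior(s, polyline_prefix(pts, f), tol)[true_goal],
    numeric(1))
  sum(p * w) / sum(w)
}

# ---- recognizer registry ----------------------------------------------------

# Every recognizer is registered under a short name with the uniform contract
# function(scenario, lib, o, tol, cutoff) -> goal posterior. Library-free
# recognizers ignore `lib`.
.registry <- new.env(parent = emptyenv())

register_recognizer <- function(name, fn) {
  assign(name, fn, envir = .registry)
  invisible(name)
}

#' Look up a recognizer by name
#'
#' Registered names: `"rg"` (Ramirez-Geffner), `"mirroring"`, `"ms"`
#' (Masters-Sardina), `"dragan"`, `"lrgr"`, `"ideal"`.
#'
#' @param name recognizer name
#' @return a function `(scenario, lib, o, tol, cutoff) -> goal posterior`
#' @export
get_recognizer <- function(name) {
  if (!exists(name, envir = .registry, inherits = FALSE))
    stop(sprintf("unknown recognizer '%s'; available: %s", name,
                 paste(sort(list_recognizers()), collapse = ", ")),
         call. = FALSE)
  get(name, envir = .registry, inherits = FALSE)
}

#' @rdname get_recognizer
#' @export
list_recognizers <- function() ls(.registry)
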