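#' Run a recognizer over incrementally revealed observations
#'
#' Feeds every observation prefix of a trajectory (at arclength fractions
#' `step_fraction, 2*step_fraction, ..., 1`) to a registered recognizer and
#' records the resulting goal posterior, emulating an observer watching the
#' motion unfold.
#'
#' @param algorithm recognizer name (see [list_recognizers()])
#' @param s a scenario
#' @param lib library partition available to library-based recognizers;
#'   library-free recognizers ignore it
#' @param t the observed `trajectory`
#' @param step_fraction observation grid step in (0, 1]
#' @param tol prefix-match tolerance
#' @param cutoff closest-point cutoff for LRGR
#' @return a `posterior_series`: data frame with column `fraction` and one
#'   probability column per goal; attributes `algorithm`, `goal_id`,
#'   `curve_index`
#' @export
run_series <- function(algorithm, s, lib, t, step_fraction = 0.02,
                       tol = default_tol(s), cutoff = Inf) {
  fn <- get_recognizer(algorithm)
  obs <- generate_observations(t, step_fraction)
  post <- t(vapply(obs$prefixes, function(o) as.numeric(fn(s, lib, o, tol, cutoff)),
                   numeric(nrow(s$goals))))
  out <- data.frame(fraction = obs$fractions, post)
  names(out) <- c("fraction", paste0("goal", seq_len(nrow(s$goals))))
  structure(out, algorithm = algorithm,
            goal_id = if (inherits(t, "trajectory")) t$goal_id else NA_integer_,
            curve_index = if (inherits(t, "trajectory")) t$curve_index else NA_integer_,
            class = c("posterior_series", "data.frame"))
}

#' @export
print.posterior_series <- function(x, ...) {
  cat(sprintf("Posterior series: algorithm '%s', trajectory %s to goal %s, %d prefixes\n",
              attr(x, "algorithm"), attr(x, "curve_index"),
              attr(x, "goal_id"), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 6), row.names = FALSE)
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6))
  invisible(x)
}

#' @export
plot.posterior_series <- function(x, ...) {
  cols <- setdiff(names(x), "fraction")
  graphics::matplot(x$fraction, as.matrix(x[cols]), type = "l", lty = 1,
                    ylim = c(0, 1), xlab = "observed fraction of trajectory",
                    ylab = "goal probability", ...)
  graphics::abline(h = 0.5, lty = 3)
  graphics::legend("topleft", legend = cols, lty = 1,
                   col = seq_along(cols), bty = "n")
  invisible(x)
}

#' Decision-convergence point of a posterior series
#'
#' The earliest observed fraction at which the probability of the correct
#' goal exceeds 0.5 AND never falls back to 0.5 or below at any later grid
#' point — the point where the recognizer commits to the correct goal, the
#' computational analogue of a human response time. A probability of exactly
#' 0.5 does not count as a decision.
#'
#' @param series a `posterior_series` (or data frame with a `fraction`
#'   column and goal probability columns)
#' @param correct the correct goal id
#' @return the convergence fraction, or `NA` if the series never commits
#' @export
convergence_point <- function(series, correct) {
  p <- series[[paste0("goal", correct)]]
  if (is.null(p)) stop("series has no column for the correct goal", call. = FALSE)
  if (length(p) == 0L) stop("empty posterior series", call. = FALSE)
  low <- which(p <= 0.5)
  k <- if (length(low) == 0L) 0L else max(low)
  if (k >= length(p)) return(NA_real_)
  series$fraction[k + 1L]
}

#' Leave-one-out convergence experiment
#'
#' For each trajectory in the scenario: the plan library is all other
#' trajectories, observations are generated from the held-out one, and the
#' convergence point of the recognizer is recorded. With the default
#' 14-trajectory scenario this yields the 14 recognition problems of the
#' leave-one-out design. Library-free recognizers give the same rows as with
#' the full library, since they ignore it.
#'
#' @inheritParams run_series
#' @return data frame with one row per trajectory: `algorithm`, `goal_id`,
#'   `curve_index`, `library_size`, `repeat_seed`, `convergence_fraction`
#' @export
leave_one_out <- function(algorithm, s, step_fraction = 0.02,
                          tol = default_tol(s), cutoff = Inf) {
  trajs <- flatten_library(s$library)
  rows <- lapply(trajs, function(t) {
    lib <- lapply(seq_len(nrow(s$goals)), function(g)
      Filter(function(x) !(x$goal_id == t$goal_id &&
                             x$curve_index == t$curve_index),
             s$library[[g]]))
    ser <- run_series(algorithm, s, lib, t, step_fraction, tol, cutoff)
    data.frame(algorithm = algorithm, goal_id = t$goal_id,
               curve_index = t$curve_index,
               library_size = length(trajs) - 1L,
               repeat_seed = NA_integer_,
               convergence_fraction = convergence_point(ser, t$goal_id))
  })
  do.call(rbind, rows)
}

#' Library-size robustness sweep
#'
#' For each library size, each trajectory is held out in turn and a random
#' sub-library of that size is drawn (with both goals always represented);
#' the recognizer's convergence on the held-out trajectory is recorded. Each
#' (size, trajectory) cell is repeated `repeats` times with fresh seeds, so a
#' scenario with 14 trajectories and 20 repeats yields 280 problems per size.
#' The whole sweep is reproducible given `seed`.
#'
#' @inheritParams run_series
#' @param sizes integer vector of library sizes (each at most the full
#'   library size minus one)
#' @param repeats random sub-library draws per (size, trajectory) cell
#' @param seed integer base seed; each draw uses a deterministic offset of it
#' @return long data frame: `algorithm`, `goal_id`, `curve_index`,
#'   `library_size`, `repeat_seed`, `convergence_fraction`
#' @export
library_size_sweep <- function(algorithm, s, sizes, repeats = 20, seed = 1,
                               step_fraction = 0.02, tol = default_tol(s),
                               cutoff = Inf) {
  trajs <- flatten_library(s$library)
  if (any(sizes > length(trajs) - 1L))
    stop("sizes cannot exceed the library size minus the held-out trajectory",
         call. = FALSE)
  rows <- vector("list", length(sizes) * length(trajs) * repeats)
  i <- 0L
  counter <- 0L
  for (size in sizes) {
    for (t in trajs) {
      for (r in seq_len(repeats)) {
        counter <- counter + 1L
        rep_seed <- as.integer(seed) + counter
        lib <- sample_library(s, size, exclude = t, seed = rep_seed)
        ser <- run_series(algorithm, s, lib, t, step_fraction, tol, cutoff)
        i <- i + 1L
        rows[[i]] <- data.frame(
          algorithm = algorithm, goal_id = t$goal_id,
          curve_index = t$curve_index, library_size = size,
          repeat_seed = rep_seed,
          convergence_fraction = convergence_point(ser, t$goal_id))
      }
    }
  }
  do.call(rbind, rows)
}
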