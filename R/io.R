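#' Scenario JSON serialization
#'
#' A scenario is stored as a JSON document with fields:
#' \preformatted{
#' {
#'   "start": [x, y],
#'   "goals": [[x, y], [x, y], ...],
#'   "trajectories": [
#'     {"goal_id": 1, "curve_index": 1, "points": [[x, y], ...]},
#'     ...
#'   ]
#' }
#' }
#' Polylines are arrays of `[x, y]` pairs. `goal_id` is 1-based into
#' `goals`. Reading validates the schema and reports every offending field;
#' writing preserves full double precision so a write/read round trip is an
#' identity.
#'
#' @param path file path
#' @param s a scenario
#' @return `read_scenario()` returns a `scenario`; `write_scenario()`
#'   returns `path` invisibly.
#' @export
read_scenario <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = TRUE)
  problems <- character(0)
  ok_point <- function(p) is.numeric(p) && length(p) == 2L && all(is.finite(p))
  if (!ok_point(doc$start)) problems <- c(problems, "start: expected [x, y]")
  if (is.null(doc$goals) || !is.numeric(unlist(doc$goals)))
    problems <- c(problems, "goals: expected array of [x, y] pairs")
  if (is.null(doc$trajectories))
    problems <- c(problems, "trajectories: missing")
  if (length(problems) == 0L) {
    goals <- if (is.matrix(doc$goals)) doc$goals else do.call(rbind, doc$goals)
    if (ncol(goals) != 2L || nrow(goals) < 2L)
      problems <- c(problems, "goals: need >= 2 points of 2 coordinates")
    for (i in seq_along(doc$trajectories)) {
      tr <- doc$trajectories[[i]]
      where <- sprintf("trajectories[%d]", i)
      if (is.null(tr$goal_id))
        problems <- c(problems, paste0(where, ".goal_id: missing"))
      else if (!is.numeric(tr$goal_id) || tr$goal_id < 1 ||
                 tr$goal_id > nrow(goals))
        problems <- c(problems, paste0(where, ".goal_id: not a valid goal index"))
      if (is.null(tr$curve_index))
        problems <- c(problems, paste0(where, ".curve_index: missing"))
      if (is.null(tr$points) || !is.numeric(unlist(tr$points)))
        problems <- c(problems, paste0(where, ".points: expected array of [x, y] pairs"))
    }
  }
  if (length(problems) > 0L)
    stop("invalid scenario document:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  library <- rep(list(list()), nrow(goals))
  for (tr in doc$trajectories) {
    pts <- if (is.matrix(tr$points)) tr$points else do.call(rbind, tr$points)
    g <- as.integer(tr$goal_id)
    library[[g]] <- c(library[[g]],
                      list(new_trajectory(pts, g, tr$curve_index)))
  }
  # keep curvature order within each goal
  for (g in seq_along(library))
    library[[g]] <- library[[g]][order(vapply(library[[g]],
                                              function(t) t$curve_index,
                                              integer(1)))]
  new_scenario(doc$start, goals, library)
}

#' @rdname read_scenario
#' @export
write_scenario <- function(s, path) {
  stopifnot(inherits(s, "scenario"))
  doc <- list(
    start = s$start,
    goals = unname(s$goals),
    trajectories = lapply(flatten_library(s$library), function(t)
      list(goal_id = t$goal_id, curve_index = t$curve_index,
           points = unname(t$points))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

# short content hash (FNV-1a over the serialized config) for provenance
# headers; not cryptographic. 32-bit state is kept in a double, so the xor
# touches only the low byte and the modular product is split into 16-bit
# halves to stay inside exact double-precision integers
config_hash <- function(config) {
  txt <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(txt))
  p <- 16777619
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    h0 <- h %% 65536
    h1 <- (h - h0) / 65536
    h <- (h0 * p + ((h1 * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run configuration
#'
#' A plain serializable list of the knobs that determine a run. Embedded (as
#' a hash plus seed) in the header of every CSV the harness writes, so any
#' output can be traced to the configuration that produced it.
#'
#' @param ... named configuration entries (scenario parameters, algorithm,
#'   step_fraction, tol, cutoff, sizes, repeats, seed, paths, ...)
#' @return a `run_config` list
#' @export
run_config <- function(...) {
  structure(list(...), class = "run_config")
}

pkg_version <- function() {
  as.character(utils::packageVersion("goalrec"))
}

#' Results CSV with a provenance header
#'
#' Writes a data frame as CSV preceded by `#`-comment lines recording the
#' package version, a hash of the run configuration, and the seed.
#' `read_results_csv()` skips the header.
#'
#' @param df data frame of results
#' @param path output file
#' @param config a [run_config()] (or any serializable list)
#' @param seed the run's seed (recorded in the header)
#' @export
write_results_csv <- function(df, path, config = run_config(), seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# goalrec %s", pkg_version()),
    sprintf("# config_hash: %s", config_hash(unclass(config))),
    sprintf("# seed: %s", seed)), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, qmethod = "double")
  invisible(path)
}

#' @rdname write_results_csv
#' @export
read_results_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}
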