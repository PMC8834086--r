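#' goalrec: goal recognition from partial 2D motion trajectories
#'
#' Tools for studying how quickly and reliably the goal of an observed agent
#' can be inferred from incrementally revealed motion in the plane:
#' rationality-based recognizers, plan-library matchers, a hybrid
#' library-based rational recognizer (LRGR), a two-goal scenario generator,
#' and an evaluation harness built around the decision-convergence metric.
#'
#' @keywords internal
"_PACKAGE"

# recognizer registry entries share the contract
# function(scenario, lib, o, tol, cutoff) -> goal posterior
.onLoad <- function(libname, pkgname) {
  register_recognizer("rg", function(s, lib, o, tol, cutoff)
    ramirez_geffner(s, o, tol))
  register_recognizer("mirroring", function(s, lib, o, tol, cutoff)
    mirroring(s, o, tol))
  register_recognizer("ms", function(s, lib, o, tol, cutoff)
    masters_sardina(s, o, tol))
  register_recognizer("dragan", function(s, lib, o, tol, cutoff)
    dragan_posterior(s, o, tol))
  register_recognizer("lrgr", function(s, lib, o, tol, cutoff)
    lrgr_posterior(s, lib, o, cutoff, tol))
  register_recognizer("ideal", function(s, lib, o, tol, cutoff)
    ideal_posterior(lib, o, tol))
}
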