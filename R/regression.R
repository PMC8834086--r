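#' Simple linear regression with R-squared and F-test
#'
#' Ordinary least squares of `y` on `x`, reporting the coefficient of
#' determination and the p-value of the standard F-test for R-squared
#' (F with 1 and n-2 degrees of freedom). Used to relate algorithm
#' convergence points to response-time data.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`; `x` must not be
#'   constant
#' @return a `regression_stats` list: `r2`, `p_value`, `slope`, `intercept`,
#'   `n`
#' @examples
#' linear_fit_r2(1:10, 2 * (1:10) + 1)$r2 # 1
#' @export
linear_fit_r2 <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("x and y must not contain NA", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::var(x) == 0) stop("x is constant; the fit is undefined", call. = FALSE)
  if (stats::var(y) == 0)
    # a constant response carries no explainable variance
    return(structure(list(r2 = 0, p_value = 1, slope = 0,
                          intercept = mean(y), n = n),
                     class = "regression_stats"))
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  r2 <- sm$r.squared
  p <- stats::pf(sm$fstatistic[["value"]], sm$fstatistic[["numdf"]],
                 sm$fstatistic[["dendf"]], lower.tail = FALSE)
  structure(list(r2 = r2, p_value = p,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]), n = n),
            class = "regression_stats")
}

#' @export
print.regression_stats <- function(x, ...) {
  cat(sprintf("OLS fit (n = %d): y = %.4g + %.4g x\n  R^2 = %.4f, F-test p = %.4g\n",
              x$n, x$intercept, x$slope, x$r2, x$p_value))
  invisible(x)
}

#' Synthetic response times from convergence points
#'
#' Generates stand-in response times linearly related to convergence
#' fractions with Gaussian noise:
#' `rt_i = intercept + slope * conv_i + N(0, noise_sd)`. A replacement for
#' human response-time tables when exercising the regression stage; real
#' data, when available, can be supplied to [linear_fit_r2()] directly.
#'
#' @param conv numeric vector of convergence fractions (no missing values)
#' @param slope,intercept linear relation parameters
#' @param noise_sd Gaussian noise standard deviation (same units as the
#'   response times)
#' @param seed integer seed; the draw is reproducible
#' @return numeric vector of response times, same length as `conv`
#' @export
synth_response_times <- function(conv, slope = 1, intercept = 0,
                                 noise_sd = 0, seed = 1) {
  conv <- as.numeric(conv)
  if (anyNA(conv)) stop("all convergence fractions must be present", call. = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  intercept + slope * conv + stats::rnorm(length(conv), 0, noise_sd)
}
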