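# shared fixtures and independent oracles

# the default 14-trajectory scenario, built once per test session
.fixtures <- new.env()
default_scenario <- function() {
  if (is.null(.fixtures$s)) .fixtures$s <- make_berkovitz_scenario()
  .fixtures$s
}

# the 3-4-5 hand scenario used throughout the recognizer examples:
# start at the origin, goals at (-3, 4) and (3, 4)
hand_scenario <- function(library = NULL) {
  scenario(c(0, 0), rbind(c(-3, 4), c(3, 4)), library)
}

# random wiggly polyline anchored at `from`
random_polyline <- function(n, from = c(0, 0), scale = 1) {
  steps <- matrix(stats::rnorm(2 * (n - 1), sd = scale), ncol = 2)
  as_polyline(rbind(from, from + apply(steps, 2, cumsum)))
}

# dense-sampling closest-point oracle: resample the polyline at `n` equal
# arclength steps by linear interpolation, take the nearest sample, then
# refine with a second dense pass around it (minima at sharp vertices are
# only first-order accurate in the sample spacing)
closest_oracle <- function(p, t, n = 1e4) {
  cs <- c(0, cumsum(sqrt(rowSums(diff(t)^2))))
  total <- cs[length(cs)]
  sample_at <- function(ss) {
    x <- stats::approx(cs, t[, 1], xout = ss, ties = "ordered")$y
    y <- stats::approx(cs, t[, 2], xout = ss, ties = "ordered")$y
    d <- sqrt((x - p[1])^2 + (y - p[2])^2)
    j <- which.min(d)
    list(point = c(x[j], y[j]), distance = d[j], s = ss[j])
  }
  coarse <- sample_at(seq(0, total, length.out = n))
  step <- total / (n - 1)
  fine <- sample_at(seq(max(0, coarse$s - step), min(total, coarse$s + step),
                        length.out = n))
  fine
}

# brute-force convergence scan: first index whose probability exceeds 0.5
# with every later index also above 0.5
convergence_oracle <- function(fractions, p) {
  for (i in seq_along(p))
    if (p[i] > 0.5 && all(p[i:length(p)] > 0.5)) return(fractions[i])
  NA_real_
}

# textbook closed-form simple OLS with the F-test for R^2
ols_oracle <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  sse <- sum((y - intercept - slope * x)^2)
  sst <- sum((y - my)^2)
  r2 <- 1 - sse / sst
  f <- (sst - sse) / (sse / (n - 2))
  list(r2 = r2, p_value = stats::pf(f, 1, n - 2, lower.tail = FALSE),
       slope = slope, intercept = intercept)
}

# mirror a scenario and a polyline across the vertical axis, swapping the
# two goals' order
reflect_scenario <- function(s) {
  scenario(s$start * c(-1, 1), s$goals[2:1, ] * cbind(c(-1, -1), c(1, 1)),
           list(
             lapply(s$library[[2]], function(t)
               trajectory(t$points %*% diag(c(-1, 1)), 1L, t$curve_index)),
             lapply(s$library[[1]], function(t)
               trajectory(t$points %*% diag(c(-1, 1)), 2L, t$curve_index))))
}

reflect_polyline <- function(o) as_polyline(o) %*% diag(c(-1, 1))

# cross-goal trajectory pairs whose early prefixes truly overlap
overlapping_pairs <- function(s, frac = 0.15, tol = default_tol(s)) {
  out <- list()
  for (ti in s$library[[1]])
    for (tj in s$library[[2]])
      if (prefix_match(polyline_prefix(ti$points, frac), tj$points, tol))
        out <- c(out, list(list(g1 = ti, g2 = tj)))
  out
}
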