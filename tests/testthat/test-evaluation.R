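test_that("run_series evaluates a registered recognizer on the observation grid", {
  s <- default_scenario()
  t <- s$library[[1]][[1]] # straight plan to goal 1
  ser <- run_series("mirroring", s, s$library, t, step_fraction = 0.02)
  expect_s3_class(ser, "posterior_series")
  expect_equal(nrow(ser), ceiling(1 / 0.02))
  expect_equal(ser$fraction[nrow(ser)], 1)
  expect_true(all(diff(ser$fraction) > 0))
  # observing the straight plan keeps its goal's cost ratio at its maximum
  expect_true(all(ser$goal1 >= 0.5))
  # uneven steps still end with the full trajectory
  ser3 <- run_series("mirroring", s, s$library, t, step_fraction = 0.3)
  expect_equal(nrow(ser3), ceiling(1 / 0.3))
  expect_error(run_series("bogus", s, s$library, t), "unknown recognizer")
})

test_that("masters-sardina series depend only on prefix endpoints", {
  s <- hand_scenario()
  straight <- trajectory(rbind(c(0, 0), c(-3, 4)), 1L)
  zigzag_pts <- rbind(c(0, 0), c(-0.3, 0.2), c(-0.1, 0.9), c(-1, 1.5), c(-3, 4))
  ser_a <- run_series("ms", s, s$library, straight, step_fraction = 0.25)
  # compare at identical endpoints rather than identical fractions
  ends <- lapply(generate_observations(straight, 0.25)$prefixes, last_point)
  for (i in seq_along(ends)) {
    o_zig <- rbind(c(0, 0), c(0.4, 0.1), ends[[i]])
    p <- masters_sardina(s, o_zig)
    expect_equal(as.numeric(p), c(ser_a$goal1[i], ser_a$goal2[i]),
                 tolerance = 1e-12)
  }
})

test_that("convergence_point applies both decision conditions on the grid", {
  mk <- function(p) data.frame(fraction = seq_along(p) / length(p),
                               goal1 = p, goal2 = 1 - p)
  expect_equal(convergence_point(mk(rep(0.9, 4)), 1), 0.25)
  # a first rise cancelled by a fall to <= 0.5 moves convergence later
  expect_equal(convergence_point(mk(c(0.6, 0.4, 0.7, 0.8)), 1), 0.75)
  expect_true(is.na(convergence_point(mk(c(0.9, 0.9, 0.5)), 1)))
  # exactly 0.5 never counts as decided
  expect_true(is.na(convergence_point(mk(rep(0.5, 3)), 1)))
  expect_error(convergence_point(mk(c(0.6)), 3), "no column")
})

test_that("convergence detector agrees with the brute-force scan on random series", {
  set.seed(101)
  for (i in 1:1000) {
    n <- sample(3:30, 1)
    p <- stats::runif(n)
    fr <- seq_len(n) / n
    ser <- data.frame(fraction = fr, goal1 = p, goal2 = 1 - p)
    expect_identical(convergence_point(ser, 1), convergence_oracle(fr, p))
  }
})

test_that("leave_one_out produces one row per held-out trajectory", {
  s <- default_scenario()
  loo <- leave_one_out("mirroring", s, step_fraction = 0.1)
  expect_equal(nrow(loo), 14)
  expect_setequal(loo$curve_index[loo$goal_id == 1], 1:7)
  expect_true(all(loo$library_size == 13))
  # library-free recognizers give identical rows with the full library
  full <- vapply(flatten_library(s$library), function(t)
    convergence_point(run_series("mirroring", s, s$library, t, 0.1),
                      t$goal_id), numeric(1))
  expect_equal(loo$convergence_fraction, full)
})

test_that("library-size sweep has the promised shape and determinism", {
  s <- default_scenario()
  sw <- library_size_sweep("ideal", s, sizes = c(6L, 3L), repeats = 2,
                           seed = 42, step_fraction = 0.1)
  expect_equal(nrow(sw), 2 * 14 * 2)
  expect_equal(unname(table(sw$library_size)), c(28L, 28L), ignore_attr = TRUE)
  sw2 <- library_size_sweep("ideal", s, sizes = c(6L, 3L), repeats = 2,
                            seed = 42, step_fraction = 0.1)
  expect_identical(sw, sw2)
  # size 13 leaves no sampling freedom: every repeat equals leave-one-out
  sw13 <- library_size_sweep("mirroring", s, sizes = 13L, repeats = 2,
                             seed = 7, step_fraction = 0.1)
  loo <- leave_one_out("mirroring", s, step_fraction = 0.1)
  # repeats are contiguous per held-out trajectory and all equal the
  # leave-one-out value since size 13 leaves no sampling freedom
  expect_equal(sw13$convergence_fraction,
               rep(loo$convergence_fraction, each = 2))
  expect_error(library_size_sweep("ideal", s, sizes = 14L, repeats = 1),
               "sizes")
})

test_that("linear_fit_r2 matches the closed-form OLS oracle", {
  x <- 1:10
  expect_equal(linear_fit_r2(x, 2 * x + 1)$r2, 1)
  flat <- linear_fit_r2(x, rep(3.2, 10))
  expect_equal(flat$r2, 0)
  expect_equal(flat$p_value, 1)
  expect_error(linear_fit_r2(rep(1, 5), 1:5), "constant")
  expect_error(linear_fit_r2(1:2, 1:2), "at least 3")
  set.seed(55)
  x <- stats::rnorm(14); y <- 0.7 * x + stats::rnorm(14, sd = 0.5)
  fit <- linear_fit_r2(x, y)
  oracle <- ols_oracle(x, y)
  expect_equal(fit$r2, oracle$r2, tolerance = 1e-9)
  expect_equal(fit$p_value, oracle$p_value, tolerance = 1e-9)
  expect_equal(fit$slope, oracle$slope, tolerance = 1e-9)
  expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-9)
})

test_that("synthetic response times are reproducible and track convergence", {
  conv <- seq(0.1, 0.9, length.out = 14)
  rt0 <- synth_response_times(conv, slope = 2, intercept = 1, noise_sd = 0)
  expect_equal(rt0, 1 + 2 * conv)
  expect_equal(linear_fit_r2(conv, rt0)$r2, 1)
  a <- synth_response_times(conv, noise_sd = 0.3, seed = 9)
  b <- synth_response_times(conv, noise_sd = 0.3, seed = 9)
  expect_identical(a, b)
  expect_error(synth_response_times(c(0.1, NA)), "present")
  # permuted responses carry no signal on average
  set.seed(17)
  r2s <- replicate(200, {
    rt <- synth_response_times(conv, noise_sd = 0.1, seed = sample.int(1e6, 1))
    linear_fit_r2(conv, sample(rt))$r2
  })
  expect_lt(mean(r2s), 0.2)
})

test_that("the three rationality recognizers share convergence while LRGR hesitates on overlaps", {
  s <- default_scenario()
  tol <- default_tol(s)
  trajs <- flatten_library(s$library)
  conv <- sapply(c("rg", "mirroring", "ms", "lrgr"), function(a)
    vapply(trajs, function(t)
      convergence_point(run_series(a, s, s$library, t, 0.1, tol = tol),
                        t$goal_id), numeric(1)))
  expect_equal(conv[, "rg"], conv[, "mirroring"])
  expect_equal(conv[, "rg"], conv[, "ms"])
  # on overlapping trajectories LRGR cannot commit while the observation
  # still matches plans to both goals, so where the rationality methods
  # commit immediately LRGR commits at-or-later; and per goal the index-7
  # trajectory is the quickest under LRGR
  pair <- overlapping_pairs(s)[[1]]
  is_overlap <- vapply(trajs, function(t)
    (t$goal_id == pair$g1$goal_id && t$curve_index == pair$g1$curve_index) ||
      (t$goal_id == pair$g2$goal_id && t$curve_index == pair$g2$curve_index),
    logical(1))
  immediate <- conv[, "rg"] == min(conv[, "rg"])
  expect_true(any(is_overlap & immediate))
  expect_true(all(conv[is_overlap & immediate, "lrgr"] >
                    conv[is_overlap & immediate, "rg"]))
  ci <- vapply(trajs, function(t) t$curve_index, integer(1))
  for (g in 1:2) {
    gi <- vapply(trajs, function(t) t$goal_id, integer(1)) == g
    expect_equal(unname(conv[gi & ci == 7, "lrgr"]),
                 min(conv[gi, "lrgr"]))
  }
})
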