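step_trace <- function(high = 0.5, t_drop = 10, duration = 30, dt = 0.5) {
  t <- seq(0, duration, by = dt)
  structure(list(time_min = t, od600 = ifelse(t <= t_drop, high, 0.05),
                 replicate = 1L, truth = NULL),
            class = "turbidity_trace")
}

test_that("lifetime and longevity interpolate the last downward crossing", {
  tr <- step_trace(high = 0.5, t_drop = 10)
  # linear interpolation from 0.5 at t=10 to 0.05 at t=10.5
  expect_equal(lifetime(tr), 10 + 0.5 * (0.5 - 0.12) / (0.5 - 0.05),
               tolerance = 1e-12)
  expect_equal(longevity(tr), 10 + 0.5 * (0.5 - 0.2) / (0.5 - 0.05),
               tolerance = 1e-12)
  expect_true(is.na(lifetime(step_trace(high = 0.0, t_drop = 10))))
  # trace peaking between the two thresholds: longevity NA, lifetime defined
  mid <- step_trace(high = 0.15, t_drop = 10)
  expect_true(is.na(longevity(mid)))
  expect_false(is.na(lifetime(mid)))
  # noisy dip below threshold before the real dissolution: last crossing wins
  tr$od600[8] <- 0.10
  expect_gt(lifetime(tr), 10)
  expect_equal(lifetime(tr, crossing = "first"),
               downward <- tr$time_min[7] +
                 0.5 * (tr$od600[7] - 0.12) / (tr$od600[7] - tr$od600[8]),
               tolerance = 1e-12)
})

test_that("longevity never exceeds lifetime on decaying traces", {
  set.seed(55)
  for (i in 1:100) {
    tr <- simulate_turbidity(A = runif(1, 0.25, 0.8), tau_r = runif(1, 0.2, 1),
                             t_d = runif(1, 5, 20), w = runif(1, 0.05, 1),
                             noise_sd = 0)
    lt <- lifetime(tr); lg <- longevity(tr)
    if (!is.na(lg)) expect_lte(lg, lt)
  }
})

test_that("critical salt recovers a constructed linear crossing exactly", {
  # od600 = 0.5, 0.4, 0.3, 0.2 at 0, 10, 20, 30 mM extrapolates to 0.1 at 40
  s <- structure(list(conc_mM = c(0, 10, 20, 30),
                      od600 = c(0.5, 0.4, 0.3, 0.2), mode = "salt",
                      truth = NULL), class = "titration_series")
  res <- critical_salt(s)
  expect_equal(res$critical_mM, 40, tolerance = 1e-9)
  triple <- critical_salt(list(s, s, s))
  expect_equal(triple$sd_mM, 0)
  # synthetic noiseless dissolution recovers the planted crossing to 1e-9
  sim <- simulate_titration("salt", seq(0, 150, 10), od0 = 0.5, slope = 0.005)
  expect_lt(abs(critical_salt(sim)$critical_mM - sim$truth$critical), 1e-9)
  # aggregate-style series that never dissolves linearly: fallback rule
  agg <- structure(list(conc_mM = c(0, 300, 600, 900),
                        od600 = c(0.5, 0.45, 0.44, 0.09), mode = "salt",
                        truth = NULL), class = "titration_series")
  expect_warning(res <- critical_salt(agg), "fallback")
  expect_equal(res$critical_mM, 900)
})

test_that("critical fuel is the first upward crossing of 0.1", {
  s <- simulate_titration("fuel", c(2.5, 5, 7.5, 10), onset = 9)
  expect_equal(critical_fuel(s), 10)
  first <- structure(list(conc_mM = c(2.5, 5), od600 = c(0.2, 0.3),
                          mode = "fuel", truth = NULL),
                     class = "titration_series")
  expect_equal(critical_fuel(first), 2.5)
  never <- structure(list(conc_mM = c(2.5, 5), od600 = c(0.02, 0.03),
                          mode = "fuel", truth = NULL),
                     class = "titration_series")
  expect_true(is.na(critical_fuel(never)))
  expect_error(critical_fuel(simulate_titration("salt", c(0, 10))), "fuel")
})

test_that("welch_test matches the textbook formula and is scale invariant", {
  a <- c(1, 2, 3); b <- c(1, 2, 3, 4, 5)
  got <- welch_test(a, b)
  want <- oracle_welch(a, b)
  expect_equal(got$t_statistic, want$t, tolerance = 1e-12)
  expect_equal(got$df, want$df, tolerance = 1e-12)
  expect_equal(got$p_two_sided, want$p, tolerance = 1e-12)
  scaled <- welch_test(10 * a, 10 * b)
  expect_equal(scaled$t_statistic, got$t_statistic, tolerance = 1e-12)
  expect_equal(scaled$p_two_sided, got$p_two_sided, tolerance = 1e-12)
  same <- welch_test(c(2, 2, 2), c(2, 2))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_two_sided, 1)
  degen <- welch_test(c(2, 2), c(3, 3))
  expect_equal(degen$status, "degenerate")
})

test_that("crossing time is non-increasing in the threshold", {
  tr <- simulate_turbidity(A = 0.6, tau_r = 0.5, t_d = 12, w = 0.5,
                           noise_sd = 0)
  times <- vapply(c(0.1, 0.2, 0.3, 0.4, 0.5),
                  function(th) lifetime(tr, threshold = th), numeric(1))
  expect_true(all(diff(times) <= 0))
})

test_that("trace TSV round trip preserves the analysis result", {
  tr <- simulate_turbidity(0.5, 0.5, 10, 0.3, noise_sd = 0.005, seed = 61)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_trace_tsv(tr, p)
  back <- read_trace_tsv(p)
  expect_equal(lifetime(back), lifetime(tr), tolerance = 1e-6)
  ti <- simulate_titration("fuel", seq(2.5, 30, 2.5), onset = 9)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_trace_tsv(ti, p2)
  expect_equal(critical_fuel(read_trace_tsv(p2, mode = "fuel")),
               critical_fuel(ti))
})
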