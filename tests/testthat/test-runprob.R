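test_that("degenerate and hand-enumerable run probabilities are exact", {
  # forced run: P(A) = 1 everywhere
  degen <- base_profile(matrix(rep(c(1, 0, 0, 0), each = 30), 30, 4,
                               dimnames = list(NULL, c("A", "C", "G", "T"))))
  expect_equal(exact_probability(degen, run_condition("A", 30)), 1)
  expect_equal(exact_probability(degen, run_condition("A", 7, anchor_d = 1)), 1)
  # uniform L = 3, run of >= 2 A anywhere: 7 of the 64 sequences
  expect_equal(exact_probability(uniform_profile(3), run_condition("A", 2)),
               7 / 64)
  # condition longer than the sequence is probability 0, not an error
  expect_equal(exact_probability(uniform_profile(5), run_condition("A", 6)), 0)
})

test_that("transfer DP equals probability-weighted exhaustive enumeration", {
  profiles <- function(L) list(
    uniform = make_uniform_probs(L),
    biased = make_biased_probs(L),
    degenerate = matrix(rep(c(1, 0, 0, 0), each = L), L, 4,
                        dimnames = list(NULL, BASES))
  )
  cases <- list(
    list(list(base = "A", min_len = 2, anchor_d = NULL)),
    list(list(base = "A", min_len = 3, anchor_d = NULL)),
    list(list(base = "A", min_len = 2, anchor_d = 0)),
    list(list(base = "A", min_len = 3, anchor_d = 1)),
    list(list(base = "G", min_len = 2, anchor_d = 2)),
    list(list(base = "A", min_len = 2, anchor_d = 1),
         list(base = "G", min_len = 2, anchor_d = NULL)),
    list(list(base = "A", min_len = 2, anchor_d = NULL),
         list(base = "A", min_len = 4, anchor_d = 0))
  )
  for (L in c(3L, 5L, 8L)) {
    for (pname in names(profiles(L))) {
      probs <- profiles(L)[[pname]]
      for (conds in cases) {
        expected <- oracle_enum_probability(probs, conds)
        cset <- condition_set(lapply(conds, function(k) {
          run_condition(k$base, k$min_len, anchor_d = k$anchor_d)
        }))
        got <- exact_probability(base_profile(probs), cset)
        expect_lt(abs(got - expected), 1e-12,
                  label = sprintf("|DP - enumeration| L=%d %s", L, pname))
      }
    }
  }
})

test_that("window-mode anchoring coincides with maximal-run anchoring", {
  # a min_len stretch inside the terminal window forces the maximal run's
  # start or end into the anchor region, and conversely; both DP branches
  # must agree
  for (prof in list(uniform_profile(10), biased_profile(10, "A"))) {
    for (m in c(2L, 4L)) {
      for (d in c(0L, 1L, 2L)) {
        p_max <- exact_probability(prof, run_condition("A", m, anchor_d = d))
        p_win <- exact_probability(prof, run_condition("A", m, anchor_d = d,
                                                       anchor_mode = "window"))
        expect_equal(p_win, p_max, tolerance = 1e-12)
      }
    }
  }
})

test_that("run probabilities are monotone in run length, base probability and anchoring", {
  L <- 20L
  p_by_m <- vapply(2:8, function(m) {
    exact_probability(uniform_profile(L), run_condition("A", m))
  }, numeric(1))
  expect_true(all(diff(p_by_m) <= 0))
  p_by_bias <- vapply(c(0.25, 0.4, 0.6, 0.76), function(p) {
    exact_probability(biased_profile(L, "A", p), run_condition("A", 5))
  }, numeric(1))
  expect_true(all(diff(p_by_bias) >= 0))
  for (m in c(3L, 5L)) {
    anchored <- exact_probability(uniform_profile(L),
                                  run_condition("A", m, anchor_d = 1))
    free <- exact_probability(uniform_profile(L), run_condition("A", m))
    expect_lte(anchored, free)
  }
})

test_that("OR of conditions is subadditive, additive for disjoint windows", {
  prof <- uniform_profile(12)
  a <- run_condition("A", 3)
  g <- run_condition("G", 3)
  p_or <- exact_probability(prof, condition_set(a, g))
  p_a <- exact_probability(prof, a)
  p_g <- exact_probability(prof, g)
  expect_lte(p_or, p_a + p_g)
  # disjoint determining windows: a whole-sequence run of A vs of G
  a_all <- run_condition("A", 12)
  g_all <- run_condition("G", 12)
  expect_equal(exact_probability(prof, condition_set(a_all, g_all)),
               exact_probability(prof, a_all) + exact_probability(prof, g_all))
})

test_that("Monte Carlo estimate agrees with the DP and is seed-deterministic", {
  prof <- uniform_profile(15)
  cset <- condition_set(run_condition("A", 3, anchor_d = 1))
  exact <- exact_probability(prof, cset)
  mc1 <- mc_probability(prof, cset, n = 20000, seed = 42)
  mc2 <- mc_probability(prof, cset, n = 20000, seed = 42)
  expect_identical(mc1$estimate, mc2$estimate)
  expect_lte(abs(mc1$estimate - exact), 4 * max(mc1$se, 1e-4))
  # degenerate profile: estimate 1 with zero standard error
  degen <- base_profile(matrix(rep(c(1, 0, 0, 0), each = 10), 10, 4,
                               dimnames = list(NULL, c("A", "C", "G", "T"))))
  mcd <- mc_probability(degen, run_condition("A", 2), n = 1000, seed = 1)
  expect_equal(mcd$estimate, 1)
  expect_equal(mcd$se, 0)
})

test_that("count_in_pool follows maximal-run anchored semantics", {
  pool <- read_set(c(strrep("A", 30), strrep("T", 30),
                     paste0("TT", strrep("A", 7), strrep("T", 21)),
                     paste0("T", strrep("A", 7), strrep("T", 22))))
  anch <- condition_set(run_condition("A", 7, anchor_d = 1))
  # all-A and the run starting at position 2 qualify; the run starting at
  # position 3 does not (start > d + 1, end < L - d)
  expect_equal(count_in_pool(pool, anch), 2L)
  expect_equal(count_in_pool(pool, condition_set(run_condition("A", 7))), 3L)
  # agreement with the rle oracle on a random pool
  set.seed(11)
  seqs <- replicate(300, paste(sample(BASES, 12, TRUE, prob = c(0.5, 0.2, 0.2, 0.1)),
                               collapse = ""))
  pool <- read_set(seqs)
  for (cond in list(run_condition("A", 3), run_condition("A", 4, anchor_d = 1),
                    run_condition("G", 2, anchor_d = 0))) {
    expected <- sum(vapply(strsplit(seqs, ""), oracle_condition_met,
                           logical(1), cond$base, cond$min_len, cond$anchor_d))
    expect_equal(count_in_pool(pool, cond), expected,
                 label = format(cond))
  }
})

test_that("pool frequencies converge to the exact DP probability", {
  prof <- uniform_profile(30)
  lib <- generate_library(prof, 20000, seed = 99)
  for (m in c(2L, 4L)) {
    p_exact <- exact_probability(prof, run_condition("A", m))
    p_obs <- count_in_pool(lib, run_condition("A", m)) / length(lib)
    se <- sqrt(p_exact * (1 - p_exact) / length(lib))
    expect_lte(abs(p_obs - p_exact), 4 * se)
  }
})
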