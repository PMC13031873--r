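test_that("library generation is seed-deterministic and matches its profile", {
  degen <- base_profile(matrix(rep(c(1, 0, 0, 0), each = 30), 30, 4,
                               dimnames = list(NULL, BASES)))
  lib <- generate_library(degen, 5, seed = 1)
  expect_identical(lib$sequences, rep(strrep("A", 30), 5))

  prof <- uniform_profile(30)
  a <- generate_library(prof, 500, seed = 7)
  b <- generate_library(prof, 500, seed = 7)
  expect_identical(a$sequences, b$sequences)
  expect_false(identical(a$sequences,
                         generate_library(prof, 500, seed = 8)$sequences))

  n <- 100000L
  lib <- generate_library(prof, n, seed = 3)
  chars <- unlist(strsplit(lib$sequences, ""), use.names = FALSE)
  frac_a <- mean(chars == "A")
  se <- sqrt(0.25 * 0.75 / (n * 30))
  expect_lte(abs(frac_a - 0.25), 3 * se)
})

test_that("biased library longest-A-run matches an independent Monte Carlo oracle", {
  n <- 50000L
  lib <- generate_library(biased_profile(30, "A"), n, seed = 5)
  mat <- matrix(unlist(strsplit(lib$sequences, ""), use.names = FALSE),
                ncol = 30, byrow = TRUE)
  longest <- apply(mat, 1, function(ch) {
    r <- rle(ch == "A")
    if (any(r$values)) max(r$lengths[r$values]) else 0L
  })
  # independent oracle: plain sample() + rle, no package code
  set.seed(123)
  oracle <- replicate(50000, {
    ch <- sample(BASES, 30, TRUE, prob = c(0.76, 0.08, 0.08, 0.08))
    r <- rle(ch == "A")
    max(r$lengths[r$values])
  })
  se <- sqrt(var(oracle) / length(oracle) + var(longest) / n)
  expect_lte(abs(mean(longest) - mean(oracle)), 3 * se)
})

test_that("profile validation rejects malformed probability rows", {
  bad <- matrix(0.25, 10, 4, dimnames = list(NULL, BASES))
  bad[3, 1] <- 0.3
  expect_error(base_profile(bad), "sum to 1")
  expect_error(base_profile(matrix(c(-0.1, 0.4, 0.4, 0.3), 1, 4)), "\\[0, 1\\]")
})

test_that("structure proxy equals brute-force substring-pair search", {
  expect_equal(structure_proxy(strrep("A", 10)), 0L)
  expect_equal(structure_proxy("GGGGCCCC"), 4L)
  expect_equal(structure_proxy(strrep("ACGT", 3)),
               oracle_structure_proxy(strrep("ACGT", 3)))
  set.seed(21)
  for (i in 1:25) {
    s <- paste(sample(BASES, sample(8:14, 1), TRUE), collapse = "")
    expect_equal(structure_proxy(s), oracle_structure_proxy(s), label = s)
  }
  expect_error(structure_proxy("ACGN"), "A, C, G, T")
})

test_that("null recruitment splits the pool evenly and keeps pools exchangeable", {
  lib <- generate_library(uniform_profile(30), 20000, seed = 2)
  pools <- recruit(lib, recruitment_model(), seed = 4)
  expect_identical(pools$droplet$label, "droplet")
  expect_identical(pools$supernatant$label, "supernatant")
  expect_equal(length(pools$droplet) + length(pools$supernatant), 20000L)
  se <- sqrt(0.25 * 20000)
  expect_lte(abs(length(pools$droplet) - 10000), 4 * se)
  # every read lands in exactly one pool
  expect_identical(sort(c(pools$droplet$sequences, pools$supernatant$sequences)),
                   sort(lib$sequences))
})

test_that("planted recruitment enriches long A runs and terminal Gs in the droplet pool", {
  lib <- generate_library(uniform_profile(30), 50000, seed = 6)
  pools <- recruit(lib, recruitment_model(intercept = -2, coef_longest_a = 1),
                   seed = 8)
  k_d <- count_in_pool(pools$droplet, run_condition("A", 7))
  k_s <- count_in_pool(pools$supernatant, run_condition("A", 7))
  p <- oracle_fisher_one_sided(k_d, length(pools$droplet),
                               k_s, length(pools$supernatant))
  expect_lt(p, 0.01)

  pools_g <- recruit(lib, recruitment_model(intercept = -1, coef_terminal_g = 1),
                     seed = 9)
  diff_g <- positional_difference(composition(pools_g$droplet),
                                  composition(pools_g$supernatant))[, "G"]
  expect_gt(min(diff_g[c(1, 2, 29, 30)]), max(diff_g[10:21]))
})

test_that("FASTQ emission round-trips through the cleaning pipeline", {
  a5 <- "ACACGACGCTCTTCCGATCT"
  a3 <- "AGATCGGAAGAGCACACGTC"
  lib <- generate_library(uniform_profile(30), 1000, seed = 10)
  path <- withr::local_tempfile(fileext = ".fastq")
  emit_fastq(lib, a5, a3, polyg_tail_prob = 0.3, seed = 12, path = path)
  raw <- read_fastq(path)
  expect_equal(length(raw), 1000L)
  clean <- process_reads(raw, a3, adapter5 = a5)
  expect_identical(sort(clean$reads$sequences), sort(lib$sequences))

  # forced polyG artifact: every record ends in the configured run
  one <- read_set("ACGTACGTAC")
  p2 <- withr::local_tempfile(fileext = ".fastq")
  emit_fastq(one, a5, a3, polyg_tail_prob = 1, seed = 1, path = p2,
             polyg_len = 8L)
  rec <- readLines(p2)
  expect_length(rec, 4L)
  expect_true(endsWith(rec[2], strrep("G", 8)))
  expect_true(grepl(paste0(a5, "ACGTACGTAC", a3), rec[2], fixed = TRUE))
})

test_that("gzipped FASTQ output reads back identically", {
  lib <- generate_library(uniform_profile(30), 50, seed = 14)
  plain <- withr::local_tempfile(fileext = ".fastq")
  gz <- withr::local_tempfile(fileext = ".fastq.gz")
  emit_fastq(lib, "ACGTACGTAC", "TTGGCCAATT", 0, seed = 1, path = plain)
  emit_fastq(lib, "ACGTACGTAC", "TTGGCCAATT", 0, seed = 1, path = gz)
  expect_identical(read_fastq(plain)$sequences, read_fastq(gz)$sequences)
})

test_that("simulated turbidity traces cross thresholds at the planted times", {
  # sharp shut-off at t_d = 10 min
  tr <- simulate_turbidity(A = 0.5, tau_r = 0.3, t_d = 10, w = 0.02,
                           noise_sd = 0)
  expect_lte(abs(lifetime(tr) - 10), 0.5)
  # noisy trace still recovers within one sampling interval
  trn <- simulate_turbidity(A = 0.5, tau_r = 0.3, t_d = 10, w = 0.02,
                            noise_sd = 0.005, seed = 31)
  expect_lte(abs(lifetime(trn) - 10), 0.5)
  # a trace that never turns turbid has no lifetime
  flat <- simulate_turbidity(A = 0.05, tau_r = 0.3, t_d = 10, w = 0.5,
                             noise_sd = 0)
  expect_true(is.na(lifetime(flat)))
  # determinism
  t1 <- simulate_turbidity(0.5, 0.3, 10, 0.5, noise_sd = 0.01, seed = 3)
  t2 <- simulate_turbidity(0.5, 0.3, 10, 0.5, noise_sd = 0.01, seed = 3)
  expect_identical(t1$od600, t2$od600)
})

test_that("simulated FRAP channels invert the double normalization exactly", {
  tr <- simulate_frap(0.8, log(2), 0.1, radius = 1, noise_sd = 0)
  f <- frap_normalize(tr)
  pre <- seq_len(tr$n_prebleach)
  expect_equal(f[pre], rep(1, length(pre)), tolerance = 1e-12)
  post <- (tr$n_prebleach + 1):length(tr$t)
  tp <- tr$t[post] - tr$t[post[1]]
  expect_equal(f[post], 0.8 * (1 - exp(-log(2) * tp)) + 0.1,
               tolerance = 1e-12)
})
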