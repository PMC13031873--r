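#' Generate a random oligonucleotide library
#'
#' Draws `n` sequences from a [base_profile()], each position independently
#' from that position's categorical distribution. With the default designs
#' this emulates the unbiased N30 library (25% per base) and the biased
#' libraries (76% favored base, 8% each of the rest).
#'
#' @param profile a [base_profile()].
#' @param n number of sequences (>= 1).
#' @param seed RNG seed; identical seed gives identical output.
#' @return a [read_set()] labeled `"library"`.
#' @export
generate_library <- function(profile, n, seed) {
  if (!inherits(profile, "base_profile")) stopf("`profile` must be a base_profile")
  n <- check_count(n, "n")
  mat <- with_seed(seed, sample_profile_matrix(profile, n))
  read_set(matrix_to_seqs(mat), label = "library")
}

#' Self-structure proxy: longest reverse-complement stem
#'
#' A dependency-free stand-in for folding propensity: the largest `k` such
#' that some length-`k` substring of the sequence equals the reverse
#' complement of another, non-overlapping substring (the longest stem a
#' hairpin could form). Values below 2 are reported as 0 (a single
#' complementary base pair is not a stem). This score is monotone with
#' hairpin-forming ability but is not comparable in absolute value to a
#' thermodynamic minimum-free-energy calculation.
#'
#' @param seq a single DNA string over A, C, G, T.
#' @return a non-negative integer stem length.
#' @export
#' @examples
#' structure_proxy("GGGGCCCC")  # 4
#' structure_proxy(strrep("A", 10))  # 0
structure_proxy <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L) stopf("`seq` must be one string")
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq)) stopf("`seq` may only contain A, C, G, T")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  structure_proxy_chars(chars)
}

# Pairing DP: H[i, j] = consecutive complementary pairs starting at (i, j)
# and moving inward; a stem of k pairs needs the substrings disjoint, i.e.
# k <= floor((j - i + 1) / 2).
#' @noRd
structure_proxy_chars <- function(chars) {
  L <- length(chars)
  if (L < 4L) return(0L)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  P <- outer(chars, chars, function(a, b) comp[a] == b)
  H <- matrix(0L, L, L)
  H[L, ] <- P[L, ] * 1L
  for (i in (L - 1L):1L) {
    H[i, 1L] <- P[i, 1L] * 1L
    H[i, 2:L] <- ifelse(P[i, 2:L], 1L + H[i + 1L, 1:(L - 1L)], 0L)
  }
  best <- 0L
  for (i in seq_len(L - 1L)) {
    j <- (i + 1L):L
    k <- pmin(H[i, j], (j - i + 1L) %/% 2L)
    best <- max(best, k)
  }
  if (best < 2L) 0L else as.integer(best)
}

#' Sequence-recruitment model for droplet partitioning
#'
#' A generative stand-in for the observed droplet recruitment: each sequence
#' joins the droplet pool with logistic probability
#' `plogis(intercept + g * terminal-G-run + a * longest-A-run + s * structure)`,
#' where terminal-G-run is the sum of the maximal 5' and 3' G-run lengths,
#' longest-A-run the longest A homopolymer anywhere, and structure the
#' [structure_proxy()] score. Positive `g` and `a` plant terminal-G and
#' long-A enrichment in the droplet pool; negative `s` depletes
#' self-structured sequences, the qualitative signatures that sequencing of
#' droplet versus supernatant pools revealed. With all coefficients 0 the two
#' pools are exchangeable.
#'
#' @param intercept baseline log-odds of recruitment.
#' @param coef_terminal_g per-base weight of the terminal G-run lengths.
#' @param coef_longest_a per-base weight of the longest A run.
#' @param coef_structure per-unit weight of the structure proxy.
#' @return a `recruitment_model` object.
#' @export
recruitment_model <- function(intercept = 0, coef_terminal_g = 0,
                              coef_longest_a = 0, coef_structure = 0) {
  for (v in c(intercept, coef_terminal_g, coef_longest_a, coef_structure)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stopf("model coefficients must be single finite numbers")
    }
  }
  structure(list(intercept = intercept, coef_terminal_g = coef_terminal_g,
                 coef_longest_a = coef_longest_a,
                 coef_structure = coef_structure),
            class = "recruitment_model")
}

#' Partition a library into droplet and supernatant pools
#'
#' Assigns every read of `reads` to exactly one pool by an independent
#' Bernoulli draw with the logistic probability given by `model` (see
#' [recruitment_model()]). This emulates the physical step sequencing
#' compares: DNA harvested from the combined droplets phase versus the
#' supernatant.
#'
#' @param reads a non-empty [read_set()] of equal-length sequences.
#' @param model a [recruitment_model()].
#' @param seed RNG seed.
#' @return list with elements `droplet` and `supernatant`, both [read_set()]s.
#' @export
recruit <- function(reads, model, seed) {
  if (!inherits(reads, "read_set")) stopf("`reads` must be a read_set")
  if (!inherits(model, "recruitment_model")) stopf("`model` must be a recruitment_model")
  if (!length(reads$sequences)) stopf("`reads` must be non-empty")
  mat <- seq_matrix(reads$sequences)
  eta <- rep(model$intercept, nrow(mat))
  if (model$coef_terminal_g != 0) {
    eta <- eta + model$coef_terminal_g * terminal_run_lengths(mat, "G")
  }
  if (model$coef_longest_a != 0) {
    eta <- eta + model$coef_longest_a * longest_run_lengths(mat, "A")
  }
  if (model$coef_structure != 0) {
    sc <- apply(mat, 1L, structure_proxy_chars)
    eta <- eta + model$coef_structure * sc
  }
  p <- stats::plogis(eta)
  in_droplet <- with_seed(seed, stats::runif(length(p)) < p)
  list(
    droplet = read_set(reads$sequences[in_droplet], label = "droplet"),
    supernatant = read_set(reads$sequences[!in_droplet], label = "supernatant")
  )
}

# Sum of 5' and 3' maximal runs of `base` per row.
#' @noRd
terminal_run_lengths <- function(mat, base) {
  is_base <- mat == base
  L <- ncol(is_base)
  five <- integer(nrow(mat)); alive <- rep(TRUE, nrow(mat))
  for (j in seq_len(L)) {
    alive <- alive & is_base[, j]
    if (!any(alive)) break
    five <- five + alive
  }
  three <- integer(nrow(mat)); alive <- rep(TRUE, nrow(mat))
  for (j in rev(seq_len(L))) {
    alive <- alive & is_base[, j]
    if (!any(alive)) break
    three <- three + alive
  }
  # an all-`base` sequence has one run, not two
  all_base <- rowSums(is_base) == L
  out <- five + three
  out[all_base] <- L
  out
}

#' @noRd
longest_run_lengths <- function(mat, base) {
  R <- runlen_matrix(mat == base)
  apply(R, 1L, max)
}

#' Write a pool as adapter-flanked FASTQ
#'
#' Emits one FASTQ record per read: `adapter5 + insert + adapter3`, optionally
#' followed by a polyG tail (the artifact of two-color sequencing chemistry)
#' with probability `polyg_tail_prob` per read. Qualities are a constant
#' placeholder (`"I"`); no quality model is used downstream. Writing goes
#' through `Biostrings::writeXStringSet`; a `.gz` path triggers compression.
#'
#' @param reads a [read_set()].
#' @param adapter5,adapter3 non-empty adapter sequences.
#' @param polyg_tail_prob per-read probability of appending the polyG tail.
#' @param seed RNG seed for the tail draws.
#' @param path output FASTQ path (`.fastq` or `.fastq.gz`).
#' @param polyg_len tail length when a tail is appended (default 12).
#' @return `path`, invisibly.
#' @export
emit_fastq <- function(reads, adapter5, adapter3, polyg_tail_prob = 0,
                       seed = NULL, path, polyg_len = 12L) {
  if (!inherits(reads, "read_set")) stopf("`reads` must be a read_set")
  if (!nzchar(adapter5) || !nzchar(adapter3)) stopf("adapters must be non-empty")
  if (polyg_tail_prob < 0 || polyg_tail_prob > 1) {
    stopf("`polyg_tail_prob` must be a probability")
  }
  n <- length(reads$sequences)
  tail_on <- if (n) with_seed(seed, stats::runif(n) < polyg_tail_prob) else logical(0)
  full <- paste0(adapter5, reads$sequences, adapter3,
                 ifelse(tail_on, strrep("G", polyg_len), ""))
  dna <- Biostrings::DNAStringSet(full)
  names(dna) <- sprintf("%s_read_%d", reads$label, seq_len(n))
  quals <- Biostrings::BStringSet(strrep("I", nchar(full)))
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = quals,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Simulate a turbidity trace with known ground truth
#'
#' Parametric rise-plateau-decay model of droplet turbidity:
#' `OD(t) = A * (1 - exp(-t / tau_r)) * S((t_d - t) / w)` with `S` the
#' logistic function, sampled every 30 s (the plate-reader cadence), plus
#' i.i.d. Gaussian noise. The dissolution midpoint `t_d` and shut-off width
#' `w` give traces whose threshold-crossing times are analytically known in
#' the noiseless case.
#'
#' @param A plateau OD600 (> 0).
#' @param tau_r rise time constant, minutes (> 0).
#' @param t_d dissolution midpoint, minutes.
#' @param w shut-off width, minutes (> 0).
#' @param duration trace length, minutes (default 30, the assay duration).
#' @param dt sampling interval, minutes (default 0.5 = 30 s).
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed RNG seed.
#' @param replicate replicate identifier stored on the trace.
#' @return a `turbidity_trace`: list with `time_min`, `od600`, `replicate`,
#'   and the ground-truth parameters in `truth`.
#' @export
simulate_turbidity <- function(A, tau_r, t_d, w, duration = 30, dt = 0.5,
                               noise_sd = 0, seed = NULL, replicate = 1L) {
  if (A <= 0 || tau_r <= 0 || w <= 0) stopf("A, tau_r and w must be positive")
  if (noise_sd < 0) stopf("`noise_sd` must be >= 0")
  t <- seq(0, duration, by = dt)
  od <- A * (1 - exp(-t / tau_r)) * stats::plogis((t_d - t) / w)
  if (noise_sd > 0) od <- od + with_seed(seed, stats::rnorm(length(t), 0, noise_sd))
  structure(list(time_min = t, od600 = od, replicate = replicate,
                 truth = list(A = A, tau_r = tau_r, t_d = t_d, w = w,
                              noise_sd = noise_sd, seed = seed)),
            class = "turbidity_trace")
}

#' Simulate a titration series with known ground truth
#'
#' Salt mode emulates droplet dissolution: OD600 falls linearly with added
#' NaCl from `od0` with slope `-slope`, floored at `od_floor`; the
#' ground-truth critical concentration is where the line crosses 0.1.
#' Fuel mode emulates droplet formation during EDC titration: OD600 is
#' `od_floor` below the true onset concentration and jumps to `od_high` at
#' and above it.
#'
#' @param mode `"salt"` or `"fuel"`.
#' @param conc added concentrations, mM, strictly increasing.
#' @param od0 salt-mode OD at zero added salt.
#' @param slope salt-mode dissolution slope, OD per mM (> 0).
#' @param onset fuel-mode true onset concentration, mM.
#' @param od_high fuel-mode OD above onset.
#' @param od_floor baseline OD.
#' @param noise_sd Gaussian noise sd (>= 0).
#' @param seed RNG seed.
#' @return a `titration_series`: list with `conc_mM`, `od600`, `mode`, `truth`.
#' @export
simulate_titration <- function(mode = c("salt", "fuel"), conc,
                               od0 = 0.5, slope = 0.005, onset = 10,
                               od_high = 0.4, od_floor = 0.02,
                               noise_sd = 0, seed = NULL) {
  mode <- match.arg(mode)
  if (is.unsorted(conc, strictly = TRUE)) stopf("`conc` must be strictly increasing")
  if (noise_sd < 0) stopf("`noise_sd` must be >= 0")
  if (mode == "salt") {
    od <- pmax(od0 - slope * conc, od_floor)
    truth <- list(critical = (od0 - 0.1) / slope, od0 = od0, slope = slope)
  } else {
    od <- ifelse(conc >= onset, od_high, od_floor)
    truth <- list(critical = conc[match(TRUE, conc >= onset)], onset = onset)
  }
  if (noise_sd > 0) od <- od + with_seed(seed, stats::rnorm(length(od), 0, noise_sd))
  structure(list(conc_mM = conc, od600 = od, mode = mode,
                 truth = c(truth, list(noise_sd = noise_sd, seed = seed))),
            class = "titration_series")
}

#' Simulate raw FRAP ROI channels with known recovery parameters
#'
#' Builds bleached-ROI (`I`), reference-ROI (`N`) and background (`B`)
#' intensity series whose double normalization recovers the target curve:
#' pre-bleach frames at normalized intensity 1, post-bleach recovery
#' `F(t) = a * (1 - exp(-b t)) + c` (t re-zeroed at the first post-bleach
#' frame) plus Gaussian noise. `N` and `B` are constant; `I` is constructed
#' from `F` by inverting the normalization, so the round trip is exact at
#' zero noise.
#'
#' @param a mobile amplitude (> 0).
#' @param b recovery rate, per second (> 0).
#' @param c bleach floor (>= 0; `a + c <= 1.05`).
#' @param radius bleach-spot radius, micrometers.
#' @param n_prebleach number of pre-bleach frames (>= 1).
#' @param n_post number of post-bleach frames.
#' @param dt frame interval, seconds.
#' @param noise_sd Gaussian noise sd on the normalized scale (>= 0).
#' @param seed RNG seed.
#' @return a [frap_trace()] with `truth` attached.
#' @export
simulate_frap <- function(a, b, c, radius, n_prebleach = 10L, n_post = 100L,
                          dt = 0.1342, noise_sd = 0, seed = NULL) {
  if (a <= 0 || b <= 0 || c < 0) stopf("need a > 0, b > 0, c >= 0")
  if (a + c > 1.05) stopf("a + c must be <= 1.05 (normalized scale)")
  if (noise_sd < 0) stopf("`noise_sd` must be >= 0")
  n_prebleach <- check_count(n_prebleach, "n_prebleach")
  n_post <- check_count(n_post, "n_post", min = 5L)
  n <- n_prebleach + n_post
  t <- (seq_len(n) - 1L) * dt
  t_post <- t[(n_prebleach + 1L):n] - t[n_prebleach + 1L]
  f <- c(rep(1, n_prebleach), a * (1 - exp(-b * t_post)) + c)
  if (noise_sd > 0) {
    f <- f + with_seed(seed, stats::rnorm(n, 0, noise_sd))
  }
  B <- rep(10, n); N <- rep(110, n)
  I <- B + f * (N - B)     # pre-bleach means make the second factor 1
  tr <- frap_trace(t = t, I = I, N = N, B = B,
                   n_prebleach = n_prebleach, radius = radius)
  tr$truth <- list(a = a, b = b, c = c, noise_sd = noise_sd, seed = seed)
  tr
}

#' Write a turbidity or titration object as TSV
#'
#' @param x a `turbidity_trace` or `titration_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace_tsv <- function(x, path) {
  if (inherits(x, "turbidity_trace")) {
    write_tsv(data.frame(time_min = x$time_min, od600 = x$od600), path)
  } else if (inherits(x, "titration_series")) {
    write_tsv(data.frame(conc_mM = x$conc_mM, od600 = x$od600), path)
  } else {
    stopf("`x` must be a turbidity_trace or titration_series")
  }
}
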