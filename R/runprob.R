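#' Exact homopolymer-run probability under a per-position base model
#'
#' Computes, exactly, the probability that a sequence drawn from a
#' [base_profile()] (independent categorical draws per position) satisfies
#' the OR of the homopolymer-run conditions in `cset`. The computation is a
#' transfer (automaton) dynamic program over positions whose state tracks the
#' current run of each target base (length capped at the largest `min_len`
#' needed), the run's start position (capped, for anchored conditions), and a
#' satisfaction bit per condition; anchored satisfaction is resolved when a
#' maximal run terminates or at the sequence end.
#'
#' A condition whose `min_len` exceeds the profile length contributes
#' probability 0 (it is not an error).
#'
#' @param profile a [base_profile()].
#' @param cset a [condition_set()] or single [run_condition()].
#' @return the event probability, a number in `[0, 1]`.
#' @export
#' @examples
#' # uniform 30-mers: "within one base of either end" A-run of >= 7, OR
#' # >= 20 consecutive A anywhere
#' cs <- condition_set(run_condition("A", 7, anchor_d = 1),
#'                     run_condition("A", 20))
#' exact_probability(uniform_profile(30), cs)
exact_probability <- function(profile, cset) {
  if (!inherits(profile, "base_profile")) stopf("`profile` must be a base_profile")
  cset <- as_condition_set(cset)
  conds <- cset$conditions
  L <- profile$length
  probs <- profile$probs
  nc <- length(conds)
  if (nc > 30L) stopf("at most 30 conditions per set (bitmask state)")

  tbases <- unique(vapply(conds, `[[`, character(1), "base"))
  cap <- vapply(tbases, function(b) {
    max(vapply(conds, function(k) if (k$base == b) k$min_len else 0L, integer(1)))
  }, integer(1))
  # largest start-position distinction needed per base (maximal-anchor only)
  dmax <- vapply(tbases, function(b) {
    ds <- vapply(conds, function(k) {
      if (k$base == b && !is.null(k$anchor_d) && k$anchor_mode == "maximal")
        k$anchor_d else -1L
    }, integer(1))
    max(ds)
  }, integer(1))

  bit <- bitwShiftL(1L, seq_len(nc) - 1L)

  # satisfaction checks while a run is open at `pos` with run length r,
  # capped start s (maximal anchors need s; window anchors need pos)
  resolve_open <- function(mask, ti, r, s, pos) {
    b <- tbases[ti]
    for (ci in seq_len(nc)) {
      if (bitwAnd(mask, bit[ci]) != 0L) next
      k <- conds[[ci]]
      if (k$base != b || r < k$min_len) next
      sat <- if (is.null(k$anchor_d)) {
        TRUE
      } else if (k$anchor_mode == "window") {
        pos <= k$min_len + k$anchor_d || pos >= L - k$anchor_d
      } else {
        s <= k$anchor_d + 1L
      }
      if (sat) mask <- bitwOr(mask, bit[ci])
    }
    mask
  }
  # a maximal run of `ti` with capped length r, capped start s ended at endpos
  resolve_closed <- function(mask, ti, r, s, endpos) {
    b <- tbases[ti]
    for (ci in seq_len(nc)) {
      if (bitwAnd(mask, bit[ci]) != 0L) next
      k <- conds[[ci]]
      if (k$base != b || r < k$min_len) next
      # window-mode satisfaction is fully credited position-by-position in
      # resolve_open; closure adds nothing for it
      if (!is.null(k$anchor_d) && k$anchor_mode == "window") next
      if (!is.null(k$anchor_d) && k$anchor_mode == "maximal" &&
          !(s <= k$anchor_d + 1L || endpos >= L - k$anchor_d)) next
      mask <- bitwOr(mask, bit[ci])
    }
    mask
  }

  key0 <- "0|0|0|0"
  cur <- new.env(parent = emptyenv())
  assign(key0, 1.0, envir = cur)
  for (pos in seq_len(L)) {
    nxt <- new.env(parent = emptyenv())
    for (key in ls(cur)) {
      p0 <- get(key, envir = cur)
      st <- as.integer(strsplit(key, "|", fixed = TRUE)[[1]])
      cb <- st[1]; r <- st[2]; s <- st[3]; mask <- st[4]
      for (bi in 1:4) {
        pb <- probs[pos, bi]
        if (pb == 0) next
        ti <- match(DNA_BASES[bi], tbases)
        if (!is.na(ti) && cb == ti) {               # run continues
          r2 <- min(r + 1L, cap[ti])
          m2 <- resolve_open(mask, ti, r2, s, pos)
          k2 <- paste(ti, r2, s, m2, sep = "|")
        } else {                                     # previous run (if any) closes
          m2 <- mask
          if (cb > 0L) m2 <- resolve_closed(m2, cb, r, s, pos - 1L)
          if (!is.na(ti)) {                          # new run opens at `pos`
            s2 <- min(pos, dmax[ti] + 2L)
            m2 <- resolve_open(m2, ti, 1L, s2, pos)
            k2 <- paste(ti, 1L, s2, m2, sep = "|")
          } else {
            k2 <- paste(0L, 0L, 0L, m2, sep = "|")
          }
        }
        old <- if (exists(k2, envir = nxt, inherits = FALSE))
          get(k2, envir = nxt) else 0
        assign(k2, old + p0 * pb, envir = nxt)
      }
    }
    cur <- nxt
  }
  total <- 0
  for (key in ls(cur)) {
    st <- as.integer(strsplit(key, "|", fixed = TRUE)[[1]])
    mask <- st[4]
    if (st[1] > 0L) mask <- resolve_closed(mask, st[1], st[2], st[3], L)
    if (mask != 0L) total <- total + get(key, envir = cur)
  }
  min(max(total, 0), 1)
}

#' Monte Carlo estimate of a run-event probability
#'
#' Bernoulli estimate of the same event as [exact_probability()], by drawing
#' `n` sequences from the profile and counting satisfying ones with the same
#' maximal-run matching machinery used for observed pools.
#'
#' @inheritParams exact_probability
#' @param n number of simulated sequences (>= 1000).
#' @param seed RNG seed; the same seed gives the identical estimate.
#' @param block sequences simulated per memory block.
#' @return list with `estimate`, `se` (`sqrt(p(1-p)/n)`) and `n`.
#' @export
mc_probability <- function(profile, cset, n, seed, block = 200000L) {
  if (!inherits(profile, "base_profile")) stopf("`profile` must be a base_profile")
  cset <- as_condition_set(cset)
  n <- check_count(n, "n", min = 1000L)
  hits <- with_seed(seed, {
    h <- 0L
    left <- n
    while (left > 0L) {
      nb <- min(left, block)
      mat <- sample_profile_matrix(profile, nb)
      h <- h + sum(cset_hits(mat, cset))
      left <- left - nb
    }
    h
  })
  p <- hits / n
  list(estimate = p, se = sqrt(p * (1 - p) / n), n = n)
}

# Draw n sequences from a base_profile as an n x L character matrix.
# Column-wise inverse-CDF sampling keeps this fast for large n.
#' @noRd
sample_profile_matrix <- function(profile, n) {
  L <- profile$length
  mat <- matrix("", n, L)
  for (j in seq_len(L)) {
    cdf <- cumsum(profile$probs[j, ])
    idx <- findInterval(stats::runif(n), cdf, left.open = TRUE) + 1L
    mat[, j] <- DNA_BASES[idx]
  }
  mat
}
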