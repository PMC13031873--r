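# Independent oracles used to freeze expected values. These deliberately
# avoid the package's matching/DP code paths: run events are judged from an
# rle() decomposition, probabilities by exhaustive enumeration, exact tail
# probabilities by direct summation.

BASES <- c("A", "C", "G", "T")

# rle-based judgment of one run condition on a character vector of bases
oracle_condition_met <- function(chars, base, min_len, anchor_d = NULL) {
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  L <- length(chars)
  hit <- r$values == base & r$lengths >= min_len
  if (!is.null(anchor_d)) {
    hit <- hit & (starts <= anchor_d + 1L | ends >= L - anchor_d)
  }
  any(hit)
}

# all length-L base-index combinations as an integer matrix (4^L rows)
oracle_all_seqs <- function(L) {
  as.matrix(expand.grid(rep(list(1:4), L)))[, L:1, drop = FALSE]
}

# probability-weighted enumeration of P(OR of conditions) under a profile;
# conds: list of list(base, min_len, anchor_d)
oracle_enum_probability <- function(probs, conds) {
  L <- nrow(probs)
  idx <- oracle_all_seqs(L)
  w <- rep(1, nrow(idx))
  for (j in seq_len(L)) w <- w * probs[j, idx[, j]]
  sat <- vapply(seq_len(nrow(idx)), function(i) {
    chars <- BASES[idx[i, ]]
    any(vapply(conds, function(k) {
      oracle_condition_met(chars, k$base, k$min_len, k$anchor_d)
    }, logical(1)))
  }, logical(1))
  sum(w[sat])
}

# brute-force longest reverse-complement stem: all disjoint substring pairs
oracle_structure_proxy <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  revcomp <- function(x) rev(unname(comp[x]))
  best <- 0L
  for (k in 2:max(2L, L %/% 2L)) {
    if (2L * k > L) break
    for (i in 1:(L - k + 1L)) {
      for (j in 1:(L - k + 1L)) {
        if (i + k - 1L < j || j + k - 1L < i) {
          if (identical(chars[i:(i + k - 1L)],
                        revcomp(chars[j:(j + k - 1L)]))) {
            best <- max(best, k)
          }
        }
      }
    }
  }
  best
}

# one-sided hypergeometric tail P(X >= k_d) for a 2x2 table by direct
# summation of the hypergeometric pmf
oracle_fisher_one_sided <- function(k_d, n_d, k_s, n_s) {
  m <- k_d + k_s          # white balls: run-bearing sequences
  total <- n_d + n_s
  kk <- k_d:min(m, n_d)
  sum(exp(lchoose(m, kk) + lchoose(total - m, n_d - kk) -
            lchoose(total, n_d)))
}

# textbook Welch statistic, Welch-Satterthwaite df, two-sided p
oracle_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

make_uniform_probs <- function(L) matrix(0.25, L, 4, dimnames = list(NULL, BASES))
make_biased_probs <- function(L, base = "A", p = 0.76) {
  m <- matrix((1 - p) / 3, L, 4, dimnames = list(NULL, BASES))
  m[, base] <- p
  m
}
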