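#' Homopolymer-run conditions
#'
#' A `run_condition` describes a homopolymer-run event in a fixed-length
#' sequence: the presence of a maximal run of at least `min_len` consecutive
#' copies of `base`, either anywhere in the sequence (`anchor_d = NULL`) or
#' anchored near a terminus. An anchored condition is satisfied by a maximal
#' run of length >= `min_len` whose start position is <= `anchor_d + 1` or
#' whose end position is >= `L - anchor_d` (1-based); `anchor_d = 1`
#' formalises "within one base of either end". Runs are always maximal: they
#' are bounded by a different base or by a sequence boundary.
#'
#' `condition_set` combines conditions with logical OR ("fulfilling either
#' condition"); OR is the only combiner.
#'
#' @param base target base, one of A, C, G, T.
#' @param min_len minimum run length (>= 1).
#' @param anchor_d `NULL` for an unanchored run, or a non-negative integer
#'   distance from either end.
#' @param anchor_mode how an anchored run is judged: `"maximal"` (default;
#'   the maximal run's start/end must fall within `anchor_d` of a terminus)
#'   or `"window"` (some `min_len`-long stretch of the run must lie entirely
#'   within the first or last `min_len + anchor_d` positions). The two
#'   readings coincide for most pools; `"maximal"` is the default throughout.
#' @return a `run_condition` object.
#' @export
#' @examples
#' a20 <- run_condition("A", 20)
#' a7end <- run_condition("A", 7, anchor_d = 1)
#' cs <- condition_set(a7end, a20)
run_condition <- function(base, min_len, anchor_d = NULL,
                          anchor_mode = c("maximal", "window")) {
  check_base(base)
  min_len <- check_count(min_len, "min_len")
  anchor_mode <- match.arg(anchor_mode)
  if (!is.null(anchor_d)) anchor_d <- check_count(anchor_d, "anchor_d", min = 0L)
  structure(list(base = base, min_len = min_len, anchor_d = anchor_d,
                 anchor_mode = anchor_mode),
            class = "run_condition")
}

#' @rdname run_condition
#' @param ... `run_condition` objects (or a single list of them).
#' @export
condition_set <- function(...) {
  conds <- list(...)
  if (length(conds) == 1L && !inherits(conds[[1]], "run_condition")) {
    conds <- conds[[1]]
  }
  if (!length(conds)) stopf("a condition_set needs at least one condition")
  ok <- vapply(conds, inherits, logical(1), "run_condition")
  if (!all(ok)) stopf("all elements must be run_condition objects")
  structure(list(conditions = conds, combine = "or"), class = "condition_set")
}

#' @export
format.run_condition <- function(x, ...) {
  anc <- if (is.null(x$anchor_d)) "any" else sprintf("end:%d", x$anchor_d)
  sprintf("%s>=%d:%s", x$base, x$min_len, anc)
}

#' @export
print.run_condition <- function(x, ...) {
  cat("run_condition", format(x), "\n")
  invisible(x)
}

#' @export
print.condition_set <- function(x, ...) {
  cat("condition_set (OR):",
      paste(vapply(x$conditions, format, character(1)), collapse = " | "), "\n")
  invisible(x)
}

#' @noRd
as_condition_set <- function(x) {
  if (inherits(x, "condition_set")) return(x)
  if (inherits(x, "run_condition")) return(condition_set(x))
  if (is.list(x)) return(condition_set(x))
  stopf("expected a run_condition or condition_set")
}

# Running-run-length matrix: R[i, j] = length of the run of `base` ending at
# position j of sequence i (0 when position j is a different base).
#' @noRd
runlen_matrix <- function(is_base) {
  n <- nrow(is_base); L <- ncol(is_base)
  R <- matrix(0L, n, L)
  prev <- integer(n)
  for (j in seq_len(L)) {
    prev <- ifelse(is_base[, j], prev + 1L, 0L)
    R[, j] <- prev
  }
  R
}

# Which sequences (rows of an n x L character/base matrix) satisfy one
# run_condition. Shared by count_in_pool, run_frequency and mc_probability,
# and the semantics mirror the exact DP.
#' @noRd
condition_hits <- function(mat, cond) {
  L <- ncol(mat)
  if (cond$min_len > L) return(logical(nrow(mat)))
  is_base <- mat == cond$base
  R <- runlen_matrix(is_base)
  m <- cond$min_len
  if (is.null(cond$anchor_d)) {
    return(matrixStats_rowAny(R >= m))
  }
  d <- cond$anchor_d
  if (cond$anchor_mode == "window") {
    # some m-long stretch inside the first or last m+d positions:
    # a stretch ending at j starts at j-m+1, so j <= m+d (start side) or
    # j >= L-d (end side)
    ok <- (R >= m) &
      matrix(rep(seq_len(L) <= m + d | seq_len(L) >= L - d, each = nrow(mat)),
             nrow(mat), L)
    return(matrixStats_rowAny(ok))
  }
  # maximal-run reading: a maximal run ends at j when position j carries the
  # base and j is the last position or j+1 does not
  ends <- is_base
  if (L > 1L) ends[, seq_len(L - 1L)] <- is_base[, seq_len(L - 1L)] & !is_base[, 2:L]
  hit <- logical(nrow(mat))
  for (j in seq_len(L)) {
    e <- ends[, j] & R[, j] >= m
    if (!any(e)) next
    start <- j - R[, j] + 1L
    hit <- hit | (e & (start <= d + 1L | j >= L - d))
  }
  hit
}

#' @noRd
matrixStats_rowAny <- function(m) rowSums(m) > 0L

# Logical OR over the set's conditions, vectorised over the pool matrix.
#' @noRd
cset_hits <- function(mat, cset) {
  cset <- as_condition_set(cset)
  hit <- logical(nrow(mat))
  for (cond in cset$conditions) hit <- hit | condition_hits(mat, cond)
  hit
}

#' Count sequences satisfying a run-condition set
#'
#' Counts the sequences in a pool that satisfy the OR of the given
#' homopolymer-run conditions, using maximal-run semantics identical to the
#' exact dynamic program in [exact_probability()].
#'
#' @param reads a [read_set()] of equal-length sequences.
#' @param cset a [condition_set()] (or a single [run_condition()]).
#' @return integer count of satisfying sequences.
#' @export
count_in_pool <- function(reads, cset) {
  if (!inherits(reads, "read_set")) stopf("`reads` must be a read_set")
  if (!length(reads$sequences)) return(0L)
  sum(cset_hits(seq_matrix(reads$sequences), cset))
}
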