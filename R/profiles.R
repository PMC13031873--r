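#' Per-position categorical base model
#'
#' A `base_profile` describes an oligonucleotide library in which every
#' position is drawn independently from its own categorical distribution over
#' A, C, G, T. The two designs used throughout are the unbiased library
#' (25% per base at every position) and the biased libraries in which one
#' base is incorporated with 76% probability and each of the remaining three
#' with 8%.
#'
#' @param probs numeric matrix with one row per position and four columns
#'   named A, C, G, T; every row must sum to 1 (tolerance 1e-12) and all
#'   entries must lie in `[0, 1]`.
#' @return an object of class `base_profile` with fields `length` and `probs`.
#' @export
#' @examples
#' p <- uniform_profile(30)
#' b <- biased_profile(30, "A")
base_profile <- function(probs) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4L) stopf("`probs` must have 4 columns (A, C, G, T)")
  if (nrow(probs) < 1L) stopf("`probs` must have at least one row")
  if (is.null(colnames(probs))) colnames(probs) <- DNA_BASES
  probs <- probs[, DNA_BASES, drop = FALSE]
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stopf("all probabilities must be finite and in [0, 1]")
  }
  bad <- which(abs(rowSums(probs) - 1) > 1e-12)
  if (length(bad)) {
    stopf("probability rows must sum to 1 (row %d sums to %.15g)",
          bad[1], rowSums(probs)[bad[1]])
  }
  structure(list(length = nrow(probs), probs = probs), class = "base_profile")
}

#' @rdname base_profile
#' @param length number of positions in the oligomer (default 30).
#' @export
uniform_profile <- function(length = 30L) {
  length <- check_count(length, "length")
  base_profile(matrix(0.25, length, 4, dimnames = list(NULL, DNA_BASES)))
}

#' @rdname base_profile
#' @param favored the base incorporated with probability `p_major`.
#' @param p_major incorporation probability of the favored base (default 0.76,
#'   the biased-library design; the other three bases share the remainder
#'   equally).
#' @export
biased_profile <- function(length = 30L, favored = "A", p_major = 0.76) {
  length <- check_count(length, "length")
  check_base(favored)
  if (!is.numeric(p_major) || p_major <= 0 || p_major >= 1) {
    stopf("`p_major` must be in (0, 1)")
  }
  m <- matrix((1 - p_major) / 3, length, 4, dimnames = list(NULL, DNA_BASES))
  m[, favored] <- p_major
  base_profile(m)
}

#' @export
print.base_profile <- function(x, ...) {
  cat(sprintf("base_profile: %d positions\n", x$length))
  cat("first-row probabilities:",
      paste(sprintf("%s=%.3g", DNA_BASES, x$probs[1, ]), collapse = " "), "\n")
  invisible(x)
}

#' Labeled pool of DNA sequences
#'
#' A `read_set` is a pool of DNA strings carrying a provenance label:
#' the input `library`, or the `droplet` / `supernatant` phase after the
#' recruitment step that sequencing compares.
#'
#' @param sequences character vector of sequences over A, C, G, T (N is
#'   tolerated for raw reads).
#' @param label one of `"library"`, `"droplet"`, `"supernatant"`.
#' @param counts optional positive-integer multiplicity per sequence.
#' @return an object of class `read_set`.
#' @export
read_set <- function(sequences, label = "library", counts = NULL) {
  label <- match.arg(label, c("library", "droplet", "supernatant"))
  sequences <- toupper(as.character(sequences))
  if (length(sequences) && any(grepl("[^ACGTN]", sequences))) {
    stopf("sequences may only contain A, C, G, T, N")
  }
  if (!is.null(counts)) {
    if (length(counts) != length(sequences) || any(counts < 1) ||
        any(counts != floor(counts))) {
      stopf("`counts` must be positive integers, one per sequence")
    }
    counts <- as.integer(counts)
  }
  structure(list(sequences = sequences, label = label, counts = counts),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set [%s]: %d sequences\n", x$label, length(x$sequences)))
  invisible(x)
}

#' @export
length.read_set <- function(x) length(x$sequences)
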