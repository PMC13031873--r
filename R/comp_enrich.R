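#' Overall and positional base composition of a pool
#'
#' @param reads a [read_set()] of equal-length sequences over A, C, G, T.
#' @return a `composition_profile`: list with `n_sequences`, `overall`
#'   (named base fractions summing to 1) and `positional` (L x 4 fraction
#'   matrix, one row per position).
#' @export
composition <- function(reads) {
  if (!inherits(reads, "read_set")) stopf("`reads` must be a read_set")
  if (!length(reads$sequences)) stopf("`reads` must be non-empty")
  if (any(grepl("N", reads$sequences, fixed = TRUE))) {
    stopf("composition assumes the {A,C,G,T} alphabet; filter N-containing reads first")
  }
  mat <- seq_matrix(reads$sequences)
  n <- nrow(mat); L <- ncol(mat)
  positional <- vapply(DNA_BASES, function(b) colSums(mat == b) / n,
                       numeric(L))
  positional <- matrix(positional, nrow = L, ncol = 4L,
                       dimnames = list(NULL, DNA_BASES))
  overall <- colSums(positional * n) / (n * L)
  structure(list(n_sequences = n, overall = overall, positional = positional),
            class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf("composition_profile: %d sequences x %d positions\n",
              x$n_sequences, nrow(x$positional)))
  cat("overall:", paste(sprintf("%s=%.3f", names(x$overall), x$overall),
                        collapse = " "), "\n")
  invisible(x)
}

#' Per-position composition difference between two pools
#'
#' Returns `a - b` per position, in percentage points (the scale the
#' droplet-minus-supernatant comparison is read on). Each row sums to 0.
#'
#' @param a,b `composition_profile`s of equal length.
#' @return L x 4 signed matrix, percentage points.
#' @export
positional_difference <- function(a, b) {
  if (!inherits(a, "composition_profile") || !inherits(b, "composition_profile")) {
    stopf("`a` and `b` must be composition_profile objects")
  }
  if (nrow(a$positional) != nrow(b$positional)) stopf("profiles differ in length")
  100 * (a$positional - b$positional)
}

#' Fraction of sequences containing a homopolymer run
#'
#' Fraction of sequences in the pool with at least `min_len` consecutive
#' copies of `base` anywhere; each sequence counts at most once.
#'
#' @param reads a [read_set()].
#' @param base target base.
#' @param min_len minimum run length.
#' @return a fraction in `[0, 1]`.
#' @export
run_frequency <- function(reads, base, min_len) {
  if (!inherits(reads, "read_set")) stopf("`reads` must be a read_set")
  if (!length(reads$sequences)) stopf("`reads` must be non-empty")
  cond <- run_condition(base, min_len)
  count_in_pool(reads, cond) / length(reads$sequences)
}

#' Composition conditional on a terminal anchor run
#'
#' Restricts the pool to sequences whose `anchor_run` terminal bases at the
#' chosen end all equal `anchor_base` (e.g. sequences starting with GGG) and
#' computes the composition of the remaining, non-anchor positions. Used to
#' ask whether G-prefixed sequences carry more G in the rest of the
#' sequence. When no sequence satisfies the anchor an empty-profile sentinel
#' (`n_sequences = 0`, `NA` tables) is returned rather than an error.
#'
#' @param reads a [read_set()] of equal-length sequences.
#' @param anchor_base the anchoring base.
#' @param anchor_run number of terminal positions required to equal it.
#' @param end `"5p"` or `"3p"`.
#' @return a `composition_profile` over the non-anchor positions.
#' @export
conditional_composition <- function(reads, anchor_base, anchor_run,
                                    end = c("5p", "3p")) {
  if (!inherits(reads, "read_set")) stopf("`reads` must be a read_set")
  end <- match.arg(end)
  check_base(anchor_base)
  mat <- seq_matrix(reads$sequences)
  L <- ncol(mat)
  anchor_run <- check_count(anchor_run, "anchor_run")
  if (anchor_run >= L) stopf("`anchor_run` must be smaller than the read length")
  anchor_cols <- if (end == "5p") seq_len(anchor_run) else (L - anchor_run + 1L):L
  sel <- rowSums(mat[, anchor_cols, drop = FALSE] == anchor_base) == anchor_run
  if (!any(sel)) {
    return(structure(list(n_sequences = 0L, overall = NULL, positional = NULL),
                     class = "composition_profile"))
  }
  rest <- mat[sel, -anchor_cols, drop = FALSE]
  composition(read_set(matrix_to_seqs(rest), label = reads$label))
}

#' Run-motif enrichment between droplet and supernatant pools
#'
#' For each run condition, builds the 2x2 table (sequence has the run or
#' not, by pool), computes the one-sided exact p for enrichment in the
#' droplet pool (hypergeometric tail, via `stats::fisher.test` with
#' `alternative = "greater"`), the sample odds ratio (Haldane-Anscombe 0.5
#' correction when any cell is zero) and the e-value
#' `p * number of conditions tested` (the Bonferroni-style correction used
#' with the 0.05 significance cutoff). Records are sorted by e-value.
#'
#' @param droplet,supernatant non-empty [read_set()]s.
#' @param conditions list of [run_condition()]s (default:
#'   [default_run_conditions()]).
#' @param alternative `"greater"` tests droplet enrichment (default);
#'   `"two.sided"` is available.
#' @return data.frame with one row per condition: `condition`,
#'   `count_droplet`, `total_droplet`, `count_supernatant`,
#'   `total_supernatant`, `odds_ratio`, `p_one_sided`, `e_value`.
#' @export
run_enrichment <- function(droplet, supernatant,
                           conditions = default_run_conditions(),
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (!inherits(droplet, "read_set") || !inherits(supernatant, "read_set")) {
    stopf("`droplet` and `supernatant` must be read_set objects")
  }
  if (!length(droplet$sequences) || !length(supernatant$sequences)) {
    stopf("both pools must be non-empty")
  }
  if (!length(conditions)) stopf("`conditions` must be non-empty")
  n_d <- length(droplet$sequences)
  n_s <- length(supernatant$sequences)
  mat_d <- seq_matrix(droplet$sequences)
  mat_s <- seq_matrix(supernatant$sequences)
  rows <- lapply(conditions, function(cond) {
    k_d <- sum(condition_hits(mat_d, cond))
    k_s <- sum(condition_hits(mat_s, cond))
    tab <- matrix(c(k_d, n_d - k_d, k_s, n_s - k_s), 2L)
    p <- stats::fisher.test(tab, alternative = alternative)$p.value
    or <- if (any(tab == 0)) {
      (tab[1, 1] + 0.5) * (tab[2, 2] + 0.5) /
        ((tab[1, 2] + 0.5) * (tab[2, 1] + 0.5))
    } else {
      tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1])
    }
    data.frame(condition = format(cond), count_droplet = k_d,
               total_droplet = n_d, count_supernatant = k_s,
               total_supernatant = n_s, odds_ratio = or, p_one_sided = p)
  })
  out <- do.call(rbind, rows)
  out$e_value <- out$p_one_sided * length(conditions)
  out[order(out$e_value), , drop = FALSE]
}

#' Default homopolymer-run condition catalog
#'
#' Runs of 5, 7 and 9 of each base, unanchored, plus runs of 5 and 7 of A
#' and G anchored within one base of either end — the explicit run catalog
#' that replaces de-novo motif discovery.
#'
#' @return list of [run_condition()]s.
#' @export
default_run_conditions <- function() {
  unanchored <- unlist(lapply(DNA_BASES, function(b) {
    lapply(c(5L, 7L, 9L), function(m) run_condition(b, m))
  }), recursive = FALSE)
  anchored <- unlist(lapply(c("A", "G"), function(b) {
    lapply(c(5L, 7L), function(m) run_condition(b, m, anchor_d = 1L))
  }), recursive = FALSE)
  c(unanchored, anchored)
}

#' Write composition / difference / enrichment tables as TSV
#'
#' @param x a `composition_profile`, a positional-difference matrix, or the
#'   [run_enrichment()] data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(x, path) {
  if (inherits(x, "composition_profile")) {
    df <- data.frame(position = seq_len(nrow(x$positional)), x$positional)
  } else if (is.matrix(x)) {
    df <- data.frame(position = seq_len(nrow(x)), x)
  } else {
    df <- x
  }
  write_tsv(df, path)
}
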