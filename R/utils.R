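DNA_BASES <- c("A", "C", "G", "T")

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Run `expr` under `seed` without disturbing the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stopf("`seed` must be a single integer")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' @noRd
check_base <- function(base) {
  if (!is.character(base) || length(base) != 1L || !base %in% DNA_BASES) {
    stopf("`base` must be one of %s", paste(DNA_BASES, collapse = ", "))
  }
  base
}

#' @noRd
check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stopf("`%s` must be a single integer >= %d", name, min)
  }
  as.integer(x)
}

# Split equal-length sequences into an n x L character matrix.
#' @noRd
seq_matrix <- function(sequences) {
  L <- unique(nchar(sequences))
  if (length(L) != 1L) stopf("sequences must all have equal length")
  matrix(unlist(strsplit(sequences, "", fixed = TRUE), use.names = FALSE),
         ncol = L, byrow = TRUE)
}

# Collapse an n x L character matrix back to strings (column-wise paste0 is
# far faster than apply() for large pools).
#' @noRd
matrix_to_seqs <- function(mat) {
  do.call(paste0, lapply(seq_len(ncol(mat)), function(j) mat[, j]))
}

#' @noRd
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
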