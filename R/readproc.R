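#' Read a FASTQ file into a read pool
#'
#' Parses standard 4-line FASTQ records (plain or gzipped). For paired-end
#' input give a vector of two paths and select the mate; analysis retains
#' only R1 (R2 is the reverse complement of the library strand and is
#' discarded). For single-file input all records are returned. Bases are
#' uppercased. A malformed record (a trailing non-4-line block, or missing
#' `@`/`+` markers) raises an error naming the record index.
#'
#' @param path one FASTQ path, or two (R1, R2) paths.
#' @param mate which mate to keep when two paths are given (1 or 2).
#' @param label pool label for the resulting [read_set()].
#' @return a [read_set()].
#' @export
read_fastq <- function(path, mate = 1L, label = "library") {
  mate <- check_count(mate, "mate")
  if (!mate %in% 1:2) stopf("`mate` must be 1 or 2")
  if (length(path) == 2L) path <- path[[mate]]
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path)   # file() dispatches on gzip magic transparently
  if (length(lines) %% 4L != 0L) {
    stopf("malformed FASTQ: record %d is truncated (file has %d lines)",
          length(lines) %/% 4L + 1L, length(lines))
  }
  n <- length(lines) %/% 4L
  if (n) {
    heads <- lines[seq(1L, by = 4L, length.out = n)]
    plus <- lines[seq(3L, by = 4L, length.out = n)]
    bad <- which(!startsWith(heads, "@") | !startsWith(plus, "+"))
    if (length(bad)) stopf("malformed FASTQ: record %d lacks @/+ markers", bad[1])
  }
  seqs <- toupper(lines[seq(2L, by = 4L, length.out = n)])
  read_set(seqs, label = label)
}

#' @noRd
trim_report <- function(reads_in, adapter_trimmed = 0L, polyg_trimmed = 0L,
                        length_filtered_out = 0L) {
  structure(list(reads_in = as.integer(reads_in),
                 adapter_trimmed = as.integer(adapter_trimmed),
                 polyg_trimmed = as.integer(polyg_trimmed),
                 length_filtered_out = as.integer(length_filtered_out),
                 reads_out = as.integer(reads_in - length_filtered_out)),
            class = "trim_report")
}

#' @export
print.trim_report <- function(x, ...) {
  cat(sprintf(paste0("trim_report: in=%d adapter_trimmed=%d polyg_trimmed=%d ",
                     "length_filtered_out=%d out=%d\n"),
              x$reads_in, x$adapter_trimmed, x$polyg_trimmed,
              x$length_filtered_out, x$reads_out))
  invisible(x)
}

#' Trim the 3' adapter and everything downstream
#'
#' Locates the first occurrence of `adapter3` in each read, allowing up to
#' `max_mismatch` substitutions (no indels; matching via
#' `Biostrings::vmatchPattern`), and deletes the adapter together with
#' everything downstream of it. Reads without a match pass through
#' unchanged. An optional 5' constant region is removed first when
#' `adapter5` is given (anchored pre-trim).
#'
#' @param reads a [read_set()].
#' @param adapter3 adapter sequence, length >= 6.
#' @param max_mismatch allowed substitutions (default 1).
#' @param adapter5 optional 5' constant region to strip (anchored at
#'   position 1, same mismatch tolerance) before the 3' search.
#' @return list of `reads` (trimmed [read_set()]) and `report`
#'   (a `trim_report`).
#' @export
trim_adapters <- function(reads, adapter3, max_mismatch = 1L, adapter5 = NULL) {
  if (!inherits(reads, "read_set")) stopf("`reads` must be a read_set")
  if (nchar(adapter3) < 6L) stopf("`adapter3` must be at least 6 bases")
  max_mismatch <- check_count(max_mismatch, "max_mismatch", min = 0L)
  seqs <- reads$sequences
  n_in <- length(seqs)
  if (!n_in) {
    return(list(reads = read_set(character(0), reads$label),
                report = trim_report(0L), trimmed = logical(0)))
  }
  if (!is.null(adapter5)) {
    dna <- Biostrings::DNAStringSet(seqs)
    m5 <- Biostrings::vmatchPattern(adapter5, dna, max.mismatch = max_mismatch,
                                    with.indels = FALSE)
    st5 <- vapply(seq_along(seqs), function(i) {
      s <- BiocGenerics::start(m5[[i]])
      if (length(s) && any(s == 1L)) nchar(adapter5) + 1L else 1L
    }, integer(1))
    seqs <- substr(seqs, st5, nchar(seqs))
  }
  dna <- Biostrings::DNAStringSet(seqs)
  m3 <- Biostrings::vmatchPattern(adapter3, dna, max.mismatch = max_mismatch,
                                  with.indels = FALSE)
  cut_at <- vapply(seq_along(seqs), function(i) {
    s <- BiocGenerics::start(m3[[i]])
    s <- s[s >= 1L]
    if (length(s)) min(s) else NA_integer_
  }, integer(1))
  trimmed <- !is.na(cut_at)
  out <- ifelse(trimmed, substr(seqs, 1L, ifelse(is.na(cut_at), 0L, cut_at) - 1L),
                seqs)
  list(reads = read_set(out, label = reads$label),
       report = trim_report(n_in, adapter_trimmed = sum(trimmed)),
       trimmed = trimmed)
}

#' Remove terminal polyG tails
#'
#' Strips a run of at least `min_tail` G's at the 3' end of each read — the
#' artifact of two-color sequencing chemistry, where a dark signal is read
#' as G. Internal and 5' G runs are untouched. Reads flagged in `exempt`
#' pass through unchanged: the chemistry tail lies downstream of the 3'
#' adapter, so a read whose adapter has already been located and removed
#' cannot still carry one, and trimming its own trailing G's would eat
#' template ([process_reads()] exempts adapter-trimmed reads this way).
#'
#' @param reads a [read_set()].
#' @param min_tail minimum tail length to strip (>= 3).
#' @param exempt optional logical vector marking reads to pass through.
#' @return list of `reads` and `report`.
#' @export
trim_polyg <- function(reads, min_tail = 5L, exempt = NULL) {
  if (!inherits(reads, "read_set")) stopf("`reads` must be a read_set")
  min_tail <- check_count(min_tail, "min_tail", min = 3L)
  seqs <- reads$sequences
  pat <- sprintf("G{%d,}$", min_tail)
  out <- sub(pat, "", seqs)
  if (!is.null(exempt)) {
    if (length(exempt) != length(seqs)) {
      stopf("`exempt` must have one entry per read")
    }
    out[exempt] <- seqs[exempt]
  }
  list(reads = read_set(out, label = reads$label),
       report = trim_report(length(seqs), polyg_trimmed = sum(out != seqs)))
}

#' Keep only reads of an exact length
#'
#' Retains exactly the sequences whose length equals `length` — the
#' exact-30-nt filter of the cleaning pipeline. Reads still containing N are
#' discarded here too (by default), since all downstream statistics assume
#' the {A,C,G,T} alphabet.
#'
#' @param reads a [read_set()].
#' @param length required read length.
#' @param drop_n discard reads containing N (default `TRUE`).
#' @return list of `reads` and `report`.
#' @export
filter_exact_length <- function(reads, length = 30L, drop_n = TRUE) {
  if (!inherits(reads, "read_set")) stopf("`reads` must be a read_set")
  length <- check_count(length, "length")
  seqs <- reads$sequences
  keep <- nchar(seqs) == length
  if (drop_n) keep <- keep & !grepl("N", seqs, fixed = TRUE)
  list(reads = read_set(seqs[keep], label = reads$label),
       report = trim_report(base::length(seqs),
                            length_filtered_out = sum(!keep)))
}

#' Run the full read-cleaning pipeline
#'
#' Fixed composition, applied identically to every pool compared:
#' adapter trim, then polyG-tail trim, then the exact-length filter.
#' The pipeline is idempotent on its own output.
#'
#' @inheritParams trim_adapters
#' @inheritParams trim_polyg
#' @inheritParams filter_exact_length
#' @return list of `reads` (the cleaned [read_set()]) and `reports`
#'   (one `trim_report` per stage, in order).
#' @export
process_reads <- function(reads, adapter3, max_mismatch = 1L, adapter5 = NULL,
                          min_tail = 5L, length = 30L, drop_n = TRUE) {
  s1 <- trim_adapters(reads, adapter3, max_mismatch = max_mismatch,
                      adapter5 = adapter5)
  s2 <- trim_polyg(s1$reads, min_tail = min_tail, exempt = s1$trimmed)
  s3 <- filter_exact_length(s2$reads, length = length, drop_n = drop_n)
  list(reads = s3$reads,
       reports = list(adapter = s1$report, polyg = s2$report,
                      length = s3$report))
}
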