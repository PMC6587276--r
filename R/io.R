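#' Small-RNA read sets
#'
#' A `ReadSet` holds a collapsed small-RNA library: one row per distinct
#' sequence with its copy number. `total_count` is the summed copy number
#' over all retained records.
#'
#' @param reads `data.frame` with columns `sequence` (uppercase DNA) and
#'   `count` (positive integer).
#' @param provenance Free-text label describing the origin of the reads.
#' @return An object of class `ReadSet`: a list with elements `reads`
#'   (data.frame with `sequence`, `count`, `length`), `total_count` and
#'   `provenance`.
#' @export
read_set <- function(reads, provenance = "") {
  stopifnot(is.data.frame(reads), all(c("sequence", "count") %in% names(reads)))
  reads$sequence <- normalize_seq(as.character(reads$sequence))
  assert_dna(reads$sequence, "read")
  reads$count <- as.integer(reads$count)
  if (any(reads$count < 1L)) stop("read counts must be >= 1")
  if (anyDuplicated(reads$sequence)) {
    cnt <- tapply(reads$count, reads$sequence, sum)
    reads <- data.frame(sequence = names(cnt), count = as.integer(cnt),
                        stringsAsFactors = FALSE)
  }
  reads <- reads[order(reads$sequence), c("sequence", "count"), drop = FALSE]
  rownames(reads) <- NULL
  reads$length <- nchar(reads$sequence)
  structure(list(reads = reads,
                 total_count = sum(reads$count),
                 provenance = provenance),
            class = "ReadSet")
}

#' @export
print.ReadSet <- function(x, ...) {
  cat(sprintf("ReadSet: %d distinct sequences, total count %d%s\n",
              nrow(x$reads), x$total_count,
              if (nzchar(x$provenance)) paste0(" [", x$provenance, "]") else ""))
  if (nrow(x$reads) > 0L) {
    rng <- range(x$reads$length)
    cat(sprintf("  lengths %d-%d nt\n", rng[1], rng[2]))
  }
  invisible(x)
}

sniff_format <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) return("empty")
    if (nzchar(trimws(line))) break
  }
  c1 <- substr(trimws(line), 1L, 1L)
  if (c1 == ">") return("fasta")
  if (c1 == "@") return("fastq")
  stop(sprintf("cannot determine read format of '%s' (first record starts with '%s')",
               path, c1), call. = FALSE)
}

#' Load and collapse a small-RNA library
#'
#' Reads a FASTA or FASTQ file (format auto-detected), normalizes sequences
#' to the uppercase DNA alphabet (U converted to T), drops reads outside the
#' size window, and collapses identical sequences with summed copy numbers.
#'
#' Collapsed-FASTA input: when `counts_in_header = TRUE`, a header of the
#' form `>id_N` contributes N copies; headers without a trailing `_N` count 1.
#' Otherwise every record counts 1, so `total_count` equals the number of
#' retained input records.
#'
#' Reads containing N are retained (library accounting) but are never mapped
#' downstream.
#'
#' @param path FASTA/FASTQ file.
#' @param min_len,max_len Inclusive size-selection window in nt. The
#'   conventional piRNA window is 23-29 nt; use 18-30 nt to keep the whole
#'   sequenced library (e.g. for the RPM normalization denominator).
#' @param counts_in_header Interpret `>id_N` headers as copy number N.
#' @param provenance Label stored in the result; defaults to the file name.
#' @return A [read_set()] object.
#' @export
load_reads <- function(path, min_len = 1L, max_len = .Machine$integer.max,
                       counts_in_header = FALSE,
                       provenance = basename(path)) {
  stopifnot(min_len >= 1L, min_len <= max_len)
  fmt <- sniff_format(path)
  if (fmt == "empty") {
    warning(sprintf("'%s' contains no reads", path))
    return(read_set(data.frame(sequence = character(0), count = integer(0)),
                    provenance))
  }
  x <- tryCatch(
    Biostrings::readBStringSet(path, format = fmt),
    error = function(e) stop(sprintf("malformed %s record in '%s': %s",
                                     fmt, path, conditionMessage(e)),
                             call. = FALSE))
  seqs <- normalize_seq(as.character(x))
  assert_dna(seqs, sprintf("record in '%s':", path))
  counts <- rep(1L, length(seqs))
  if (counts_in_header) {
    m <- regmatches(names(x), regexpr("_([0-9]+)$", names(x)))
    has <- lengths(regmatches(names(x), gregexpr("_([0-9]+)$", names(x)))) > 0
    counts[has] <- as.integer(sub("^_", "", m))
  }
  len <- nchar(seqs)
  keep <- len >= min_len & len <= max_len
  if (!any(keep)) {
    warning(sprintf("no reads in [%d, %d] nt retained from '%s'",
                    min_len, max_len, path))
  }
  read_set(data.frame(sequence = seqs[keep], count = counts[keep],
                      stringsAsFactors = FALSE),
           provenance)
}

#' Write a collapsed read set as FASTA
#'
#' Headers carry the copy number in the `>readNNNNNN_count` dialect, so the
#' file round-trips through `load_reads(..., counts_in_header = TRUE)`.
#'
#' @param rs A [read_set()].
#' @param path Output FASTA file.
#' @return Invisibly, `path`.
#' @export
write_reads <- function(rs, path) {
  stopifnot(inherits(rs, "ReadSet"))
  ids <- sprintf("read%06d_%d", seq_len(nrow(rs$reads)), rs$reads$count)
  writeLines(paste0(">", ids, "\n", rs$reads$sequence), path)
  invisible(path)
}

#' Remove reads derived from a contaminant sequence
#'
#' Drops every read whose sequence is an exact substring of the contaminant
#' or of its reverse complement (e.g. 2S rRNA depletion). Matching is exact;
#' no mismatches are tolerated.
#'
#' @param rs A [read_set()].
#' @param contaminant Non-empty DNA string.
#' @return A new [read_set()] without the contaminant-derived reads.
#' @export
filter_exact_contaminant <- function(rs, contaminant) {
  stopifnot(inherits(rs, "ReadSet"), nzchar(contaminant))
  contaminant <- normalize_seq(contaminant)
  rcc <- revcomp(contaminant)
  hit <- vapply(rs$reads$sequence, function(s) {
    grepl(s, contaminant, fixed = TRUE) || grepl(s, rcc, fixed = TRUE)
  }, logical(1), USE.NAMES = FALSE)
  if (any(hit)) {
    msg("filter_exact_contaminant: removed %d distinct sequences (%d copies)",
        sum(hit), sum(rs$reads$count[hit]))
  }
  read_set(rs$reads[!hit, c("sequence", "count"), drop = FALSE],
           rs$provenance)
}

#' Load reference sequences from FASTA
#'
#' @param path FASTA file of genome contigs or TE consensus sequences.
#' @return Named character vector of uppercase DNA sequences.
#' @export
load_reference <- function(path) {
  x <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(x) == 0L) stop(sprintf("'%s' contains no sequences", path))
  seqs <- normalize_seq(as.character(x))
  assert_dna(seqs, sprintf("reference in '%s':", path))
  nm <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(nm)) stop("duplicate reference names in ", path)
  stats::setNames(seqs, nm)
}

#' Write reference sequences as FASTA
#'
#' @param refs Named character vector of DNA sequences.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_reference <- function(refs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(refs), path)
  invisible(path)
}

#' Load genomic intervals from BED
#'
#' Parses BED3+ annotations (piRNA clusters, TE copies) into a `GRanges`.
#' BED coordinates are 0-based half-open on disk; the returned `GRanges`
#' follows the Bioconductor 1-based inclusive convention. Records with
#' `start >= end` are rejected with an error; duplicate names are allowed
#' but reported.
#'
#' @param path BED3/BED6 file.
#' @return A [GenomicRanges::GRanges] with `name` metadata when present.
#' @export
load_intervals <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0L) return(GenomicRanges::GRanges())
  flds <- strsplit(lines, "\t")
  starts <- suppressWarnings(as.numeric(vapply(flds, `[`, "", 2L)))
  ends <- suppressWarnings(as.numeric(vapply(flds, `[`, "", 3L)))
  if (anyNA(starts) || anyNA(ends) ||
      any(starts != floor(starts)) || any(ends != floor(ends))) {
    stop(sprintf("non-integer coordinates in '%s'", path), call. = FALSE)
  }
  bad <- which(starts >= ends)
  if (length(bad) > 0L) {
    stop(sprintf("BED record %d in '%s' has start >= end (%d >= %d)",
                 bad[1L], path, starts[bad[1L]], ends[bad[1L]]), call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(gr$name) && anyDuplicated(stats::na.omit(gr$name))) {
    msg("load_intervals: duplicate interval names in '%s'", path)
  }
  gr
}
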