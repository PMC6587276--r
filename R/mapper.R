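#' Gap-free k-mismatch read mapping
#'
#' Maps every read of a [read_set()] against each reference sequence,
#' reporting all full-length, gap-free placements (forward or
#' reverse-complement strand) with Hamming distance at most `max_mismatches`.
#' Indels are not modelled: "k mismatches" means substitutions only, the
#' standard convention for 23-29 nt piRNA mapping. An N in either read or
#' reference never matches (it counts as a mismatch), and reads containing N
#' are not mapped at all.
#'
#' Placements are found by pigeonhole seeding: each read is split into
#' `max_mismatches + 1` disjoint seeds, seeds are exact-matched through a
#' reference k-mer index, and candidate placements are verified by a full
#' Hamming comparison. The search is exact (lossless) for substitution-only
#' matching.
#'
#' Coordinates are 0-based half-open. `five_prime` is the genomic coordinate
#' of the read's 5' end: `start` on the plus strand, `end - 1` on minus.
#'
#' @param reads A [read_set()].
#' @param refs Named character vector of reference sequences
#'   (see [load_reference()]).
#' @param max_mismatches Maximum Hamming distance, 0-3 by convention.
#' @param report `"all"` reports every placement within the threshold;
#'   `"best"` only placements at the read's minimal distance.
#' @return A `MappingResult`: list with
#'   \describe{
#'     \item{alignments}{data.frame with `sequence`, `reference`, `start`,
#'       `end`, `strand`, `mismatches`, `five_prime`, `count`, ordered by
#'       (sequence, reference, start, strand).}
#'     \item{status}{data.frame with per-read `status` in
#'       `unmapped`/`unique`/`multi` at the stated threshold.}
#'     \item{mapped_total}{summed copy number of reads with >= 1 placement.}
#'     \item{max_mismatches, report, references}{run parameters.}
#'   }
#' @export
map_reads <- function(reads, refs, max_mismatches = 3L,
                      report = c("all", "best")) {
  report <- match.arg(report)
  stopifnot(inherits(reads, "ReadSet"),
            max_mismatches >= 0L)
  if (length(refs) == 0L) stop("empty reference set")
  if (is.null(names(refs)) || any(!nzchar(names(refs))))
    stop("references must be named")
  if (nrow(reads$reads) == 0L) stop("empty read set")
  raw <- pigeonhole_map_cpp(reads$reads$sequence, unname(refs),
                            as.integer(max_mismatches))
  build_mapping_result(reads, refs, raw, max_mismatches, report)
}

#' Brute-force reference mapper
#'
#' Position-by-position Hamming scan over every offset and both strands.
#' Same placement semantics as [map_reads()], but computed by exhaustive
#' enumeration with no seeding or indexing; intended as an independent
#' reference implementation for validating the production mapper on small
#' inputs.
#'
#' @inheritParams map_reads
#' @return A `MappingResult`, as for [map_reads()].
#' @export
brute_force_map <- function(reads, refs, max_mismatches = 3L,
                            report = c("all", "best")) {
  report <- match.arg(report)
  stopifnot(inherits(reads, "ReadSet"), max_mismatches >= 0L)
  if (length(refs) == 0L) stop("empty reference set")
  raw <- brute_scan_cpp(reads$reads$sequence, unname(refs),
                        as.integer(max_mismatches))
  build_mapping_result(reads, refs, raw, max_mismatches, report)
}

build_mapping_result <- function(reads, refs, raw, max_mismatches, report) {
  rdf <- reads$reads
  aln <- data.frame(
    sequence = rdf$sequence[raw$read],
    reference = names(refs)[raw$ref],
    start = raw$start,
    strand = ifelse(raw$strand == 0L, "+", "-"),
    mismatches = raw$mismatches,
    count = rdf$count[raw$read],
    stringsAsFactors = FALSE)
  aln$end <- aln$start + nchar(aln$sequence)
  aln$five_prime <- ifelse(aln$strand == "+", aln$start, aln$end - 1L)
  if (report == "best" && nrow(aln) > 0L) {
    best <- tapply(aln$mismatches, aln$sequence, min)
    aln <- aln[aln$mismatches == best[aln$sequence], , drop = FALSE]
  }
  ref_rank <- match(aln$reference, names(refs))
  ord <- order(aln$sequence, ref_rank, aln$start, aln$strand)
  aln <- aln[ord, c("sequence", "reference", "start", "end", "strand",
                    "mismatches", "five_prime", "count"), drop = FALSE]
  rownames(aln) <- NULL
  nplace <- table(factor(aln$sequence, levels = rdf$sequence))
  status <- data.frame(
    sequence = rdf$sequence,
    count = rdf$count,
    n_placements = as.integer(nplace),
    status = ifelse(nplace == 0L, "unmapped",
                    ifelse(nplace == 1L, "unique", "multi")),
    stringsAsFactors = FALSE)
  structure(list(alignments = aln,
                 status = status,
                 mapped_total = sum(status$count[status$n_placements > 0L]),
                 max_mismatches = as.integer(max_mismatches),
                 report = report,
                 references = names(refs)),
            class = "MappingResult")
}

#' @export
print.MappingResult <- function(x, ...) {
  cat(sprintf(
    "MappingResult: %d placements (<=%d mm, report=%s), %d/%d reads mapped, mass %d\n",
    nrow(x$alignments), x$max_mismatches, x$report,
    sum(x$status$n_placements > 0L), nrow(x$status), x$mapped_total))
  invisible(x)
}

#' Genome mapping and uniqueness at zero mismatches
#'
#' Maps reads to the genome with 0 mismatches, reporting all placements, and
#' classifies each read as `unmapped`, `unique` (exactly one zero-mismatch
#' placement) or `multi`. `mapped_total` of the result is the total number of
#' genome-mapped reads (no mismatch) used as the reads-per-million
#' normalization denominator.
#'
#' @param reads A [read_set()].
#' @param genome Named character vector of genome contigs.
#' @return A `MappingResult` (see [map_reads()]) at 0 mismatches.
#' @export
genome_unique_status <- function(reads, genome) {
  map_reads(reads, genome, max_mismatches = 0L, report = "all")
}

#' Reduce a mapping to one placement per read
#'
#' For per-TE statistics each read contributes its full copy number exactly
#' once, assigned to its best placement (fewest mismatches; ties broken by
#' reference order, then lowest start, then plus strand). This prevents
#' multi-site double counting in overlap and density statistics.
#'
#' @param x A `MappingResult`.
#' @return data.frame of alignments, one row per mapped read.
#' @export
primary_placements <- function(x) {
  stopifnot(inherits(x, "MappingResult"))
  aln <- x$alignments
  if (nrow(aln) == 0L) return(aln)
  ref_rank <- match(aln$reference, x$references)
  ord <- order(aln$sequence, aln$mismatches, ref_rank, aln$start,
               aln$strand)  # "+" < "-" lexicographically
  aln <- aln[ord, , drop = FALSE]
  aln <- aln[!duplicated(aln$sequence), , drop = FALSE]
  rownames(aln) <- NULL
  aln
}

#' Export alignments as TSV and/or BED6
#'
#' The TSV carries all alignment columns including `mismatches` and
#' `five_prime` (0-based). The BED6 uses the read sequence as name and the
#' copy number as score.
#'
#' @param x A `MappingResult`.
#' @param tsv,bed Output paths; either may be `NULL`.
#' @return Invisibly, the alignment data.frame.
#' @export
export_alignments <- function(x, tsv = NULL, bed = NULL) {
  stopifnot(inherits(x, "MappingResult"))
  aln <- x$alignments
  if (!is.null(tsv)) {
    con <- file(tsv, "w")
    writeLines("# gap-free alignments; start/end 0-based half-open", con)
    utils::write.table(aln, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
  }
  if (!is.null(bed) && nrow(aln) > 0L) {
    gr <- GenomicRanges::GRanges(
      seqnames = aln$reference,
      ranges = IRanges::IRanges(start = aln$start + 1L, end = aln$end),
      strand = aln$strand,
      name = aln$sequence,
      score = aln$count)
    rtracklayer::export(gr, bed, format = "BED")
  }
  invisible(aln)
}
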