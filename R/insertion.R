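# Non-reference TE insertion detection from chimeric (junction) reads and
# discordant read pairs. Coordinates are 0-based half-open internally;
# exported tables carry 1-based inclusive columns alongside.

# map plain character sequences (no ReadSet) and return a raw placement table
map_seqs <- function(seqs, refs, max_mm) {
  raw <- pigeonhole_map_cpp(unname(seqs), unname(refs), as.integer(max_mm))
  data.frame(read = raw$read,
             reference = names(refs)[raw$ref],
             start = raw$start,
             strand = ifelse(raw$strand == 0L, "+", "-"),
             mismatches = raw$mismatches,
             stringsAsFactors = FALSE)
}

#' Find chimeric junction reads at TE termini
#'
#' Scans reads that are not uniquely mappable to the genome full-length at
#' zero mismatches for chimeras joining genomic sequence to a TE terminus. A
#' read qualifies iff (in either orientation) a prefix or suffix of at least
#' `min_te_match` nt matches the TE consensus anchored at its 5' or 3' end
#' (at most `max_mm_te` mismatches) and the remaining flank of at least
#' `min_flank` nt maps to the genome (gap-free, at most `max_mm_flank`
#' mismatches). The TE portion is stripped and every genomic placement of the
#' flank is reported; multi-mapping flanks (repeat context) yield one row per
#' placement.
#'
#' Each placement implies a breakpoint coordinate `bp` (0-based; the
#' insertion lies between `bp - 1` and `bp`) and a `genome_side`: `"left"`
#' when the flank is the genomic sequence to the left of the insertion,
#' `"right"` otherwise.
#'
#' @param reads Named character vector of read sequences (mates may simply be
#'   concatenated; names are read ids).
#' @param te TE consensus sequence (single string, or named vector of one).
#' @param genome Named character vector of genome contigs.
#' @param min_te_match Minimum TE terminus match length (default 20).
#' @param min_flank Minimum genomic flank length (default 20).
#' @param max_mm_te,max_mm_flank Mismatch tolerance per segment (default 1).
#' @param unmappable `"not_unique"` (default) keeps all reads without a
#'   unique full-length zero-mismatch genome placement, including
#'   multi-mappers; `"unmapped"` keeps only reads with none.
#' @return data.frame, one row per (junction read, flank placement): `id`,
#'   `te_side` (`5prime`/`3prime`), `orientation`, `te_match_len`,
#'   `breakpoint_offset` (position in the oriented read where the TE portion
#'   begins/ends), `flank_seq`, `contig`, `flank_start`, `flank_end`,
#'   `flank_strand`, `flank_mm`, `bp`, `genome_side`, `n_placements`.
#' @export
find_junction_reads <- function(reads, te, genome,
                                min_te_match = 20L, min_flank = 20L,
                                max_mm_te = 1L, max_mm_flank = 1L,
                                unmappable = c("not_unique", "unmapped")) {
  unmappable <- match.arg(unmappable)
  te <- unname(te)[1L]
  if (nchar(te) < min_te_match) stop("TE consensus shorter than min_te_match")
  if (is.null(names(reads))) names(reads) <- sprintf("read%06d", seq_along(reads))
  empty <- data.frame(id = character(0), te_side = character(0),
                      orientation = character(0), te_match_len = integer(0),
                      breakpoint_offset = integer(0), flank_seq = character(0),
                      contig = character(0), flank_start = integer(0),
                      flank_end = integer(0), flank_strand = character(0),
                      flank_mm = integer(0), bp = integer(0),
                      genome_side = character(0), n_placements = integer(0),
                      stringsAsFactors = FALSE)
  if (length(reads) == 0L) return(empty)

  g0 <- map_seqs(reads, genome, 0L)
  nplace <- tabulate(g0$read, nbins = length(reads))
  keep <- if (unmappable == "not_unique") nplace != 1L else nplace == 0L
  cand <- reads[keep]
  if (length(cand) == 0L) return(empty)

  js <- junction_scan_cpp(unname(cand), te, as.integer(min_te_match),
                          as.integer(min_flank), as.integer(max_mm_te))
  if (nrow(js) == 0L) return(empty)

  qseq <- ifelse(js$orient == 1L, revcomp(unname(cand)[js$read]),
                 unname(cand)[js$read])
  L <- nchar(qseq)
  flank <- ifelse(js$side == 0L,
                  substr(qseq, 1L, L - js$te_match_len),
                  substr(qseq, js$te_match_len + 1L, L))
  fmap <- map_seqs(flank, genome, max_mm_flank)
  if (nrow(fmap) == 0L) return(empty)

  i <- fmap$read  # row of js
  flen <- nchar(flank)[i]
  side <- js$side[i]
  fstrand <- fmap$strand
  fend <- fmap$start + flen
  # breakpoint and genomic side implied by each placement
  left <- (side == 0L & fstrand == "+") | (side == 1L & fstrand == "-")
  bp <- ifelse(left, fend, fmap$start)
  out <- data.frame(
    id = names(cand)[js$read[i]],
    te_side = ifelse(side == 0L, "5prime", "3prime"),
    orientation = ifelse(js$orient[i] == 1L, "rc", "fwd"),
    te_match_len = js$te_match_len[i],
    breakpoint_offset = ifelse(side == 0L, flen, js$te_match_len[i]),
    flank_seq = flank[i],
    contig = fmap$reference,
    flank_start = fmap$start,
    flank_end = fend,
    flank_strand = fstrand,
    flank_mm = fmap$mismatches,
    bp = bp,
    genome_side = ifelse(left, "left", "right"),
    stringsAsFactors = FALSE)
  out$n_placements <- as.integer(table(out$id)[out$id])
  out <- out[order(out$id, out$contig, out$bp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find discordant read pairs
#'
#' Reports pairs with one mate placed full-length on the TE consensus and the
#' other full-length on the genome (and not on the TE-bearing side both
#' ways): evidence of a non-reference insertion near the genomic mate. The
#' genomic mate's interval extended by the insert-size prior defines the
#' implied insertion window.
#'
#' @param mate1,mate2 Parallel named character vectors of mate sequences.
#' @param te,genome As in [find_junction_reads()].
#' @param insert_mean,insert_sd Insert-size prior in bp (defaults 350/50).
#' @param max_mm Mismatch tolerance for full-length placements (default 3).
#' @return data.frame, one row per (discordant pair, genome placement of the
#'   genomic mate): `pair_id`, `te_mate` (`"1"`/`"2"`), `te_start`,
#'   `te_strand`, `contig`, `g_start`, `g_end`, `g_strand`, `g_mm`,
#'   `window_lo`, `window_hi`, `point` (window midpoint used for
#'   clustering). In repeat context a genomic mate maps to several
#'   homologous positions and contributes one row (hence one implied
#'   window) per placement.
#' @export
find_discordant_pairs <- function(mate1, mate2, te, genome,
                                  insert_mean = 350, insert_sd = 50,
                                  max_mm = 3L) {
  stopifnot(length(mate1) == length(mate2))
  te <- stats::setNames(unname(te)[1L], "TE")
  if (is.null(names(mate1))) names(mate1) <- sprintf("pair%06d", seq_along(mate1))
  empty <- data.frame(pair_id = character(0), te_mate = character(0),
                      te_start = integer(0), te_strand = character(0),
                      contig = character(0), g_start = integer(0),
                      g_end = integer(0), g_strand = character(0),
                      g_mm = integer(0),
                      window_lo = integer(0), window_hi = integer(0),
                      point = integer(0), stringsAsFactors = FALSE)
  if (length(mate1) == 0L) return(empty)

  best1 <- function(df) df[!duplicated(df$read), , drop = FALSE]
  t1 <- map_seqs(mate1, te, max_mm); t2 <- map_seqs(mate2, te, max_mm)
  g1 <- map_seqs(mate1, genome, max_mm); g2 <- map_seqs(mate2, genome, max_mm)
  n <- length(mate1)
  on_te1 <- tabulate(t1$read, n) > 0L; on_te2 <- tabulate(t2$read, n) > 0L
  on_g1 <- tabulate(g1$read, n) > 0L;  on_g2 <- tabulate(g2$read, n) > 0L
  d1 <- on_te1 & on_g2 & !on_g1   # mate1 in TE, mate2 genomic
  d2 <- on_te2 & on_g1 & !on_g2
  if (!any(d1 | d2)) return(empty)

  reach <- insert_mean + 2 * insert_sd
  rows <- function(sel, te_map, g_map, which_mate, glen) {
    if (!any(sel)) return(empty)
    idx <- which(sel)
    tb <- best1(te_map[order(te_map$mismatches, te_map$start), , drop = FALSE])
    # keep every genome placement: homologous repeat copies are genuine
    # alternative insertion neighbourhoods
    gbi <- g_map[g_map$read %in% idx, , drop = FALSE]
    gbi <- gbi[order(gbi$read, gbi$reference, gbi$start), , drop = FALSE]
    tbi <- tb[match(gbi$read, tb$read), , drop = FALSE]
    ge <- gbi$start + glen[gbi$read]
    plus <- gbi$strand == "+"
    lo <- ifelse(plus, ge, pmax(0L, gbi$start - reach))
    hi <- ifelse(plus, ge + reach, gbi$start)
    data.frame(pair_id = names(mate1)[gbi$read],
               te_mate = which_mate,
               te_start = tbi$start, te_strand = tbi$strand,
               contig = gbi$reference,
               g_start = gbi$start, g_end = ge, g_strand = gbi$strand,
               g_mm = gbi$mismatches,
               window_lo = as.integer(lo), window_hi = as.integer(hi),
               point = as.integer(round((lo + hi) / 2)),
               stringsAsFactors = FALSE)
  }
  out <- rbind(rows(d1, t1, g2, "1", nchar(mate2)),
               rows(d2, t2, g1, "2", nchar(mate1)))
  out <- out[order(out$pair_id, out$contig, out$g_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call insertion candidates from junction and discordant evidence
#'
#' Clusters evidence coordinates per contig (single linkage, gap threshold
#' `cluster_distance`). Within each cluster the modal left-side and
#' right-side junction breakpoints define the breakpoint interval `[lo, hi)`;
#' when both sides are present and the left coordinate exceeds the right by
#' 1-`tsd_max` bp, the intervening genomic bases are reported as the
#' target-site duplication (TSD). When junction flanks or discordant genomic
#' mates multi-map (repeat context) the same reads support several clusters:
#' candidates sharing supporting junction reads or discordant pairs are
#' linked into one `ambiguity_group`.
#' Candidates are ranked by total support (distinct junction reads plus
#' discordant pairs) and filtered at `min_support`.
#'
#' @param junctions Output of [find_junction_reads()].
#' @param discordants Output of [find_discordant_pairs()], or `NULL`.
#' @param genome Named character vector (used to extract the TSD string);
#'   optional.
#' @param cluster_distance Evidence clustering distance in bp (default 500).
#' @param min_support Minimum total support per candidate (default 2).
#' @param tsd_max Longest TSD considered (default 20).
#' @return data.frame of class `insertion_calls`: `contig`, `lo`, `hi`
#'   (0-based half-open breakpoint interval), `start_1based`, `end_1based`,
#'   `support_total`, `support_junction`, `support_junction_5p`,
#'   `support_junction_3p`, `support_discordant`, `tsd_len`, `tsd`,
#'   `ambiguity_group`, `junction_ids`, `discordant_ids`.
#' @export
call_insertions <- function(junctions, discordants = NULL, genome = NULL,
                            cluster_distance = 500L, min_support = 2L,
                            tsd_max = 20L) {
  empty <- data.frame(contig = character(0), lo = integer(0), hi = integer(0),
                      start_1based = integer(0), end_1based = integer(0),
                      support_total = integer(0), support_junction = integer(0),
                      support_junction_5p = integer(0),
                      support_junction_3p = integer(0),
                      support_discordant = integer(0), tsd_len = integer(0),
                      tsd = character(0), ambiguity_group = character(0),
                      junction_ids = character(0),
                      discordant_ids = character(0), stringsAsFactors = FALSE)
  class(empty) <- c("insertion_calls", "data.frame")
  ev <- rbind(
    if (!is.null(junctions) && nrow(junctions) > 0L)
      data.frame(contig = junctions$contig, pos = junctions$bp,
                 type = "junction", row = seq_len(nrow(junctions)),
                 stringsAsFactors = FALSE),
    if (!is.null(discordants) && nrow(discordants) > 0L)
      data.frame(contig = discordants$contig, pos = discordants$point,
                 type = "discordant", row = seq_len(nrow(discordants)),
                 stringsAsFactors = FALSE))
  if (is.null(ev) || nrow(ev) == 0L) return(empty)

  cands <- list()
  for (ctg in unique(ev$contig)) {
    e <- ev[ev$contig == ctg, , drop = FALSE]
    e <- e[order(e$pos), , drop = FALSE]
    brk <- c(0L, cumsum(diff(e$pos) > cluster_distance))
    for (g in split(e, brk)) {
      j <- junctions[g$row[g$type == "junction"], , drop = FALSE]
      d <- if (is.null(discordants)) NULL
           else discordants[g$row[g$type == "discordant"], , drop = FALSE]
      jl <- j$bp[j$genome_side == "left"]
      jr <- j$bp[j$genome_side == "right"]
      if (nrow(j) > 0L) {
        hi <- if (length(jl) > 0L) mode_int(jl) else NA_integer_
        lo <- if (length(jr) > 0L) mode_int(jr) else NA_integer_
        if (is.na(hi)) hi <- lo
        if (is.na(lo)) lo <- hi
      } else {
        lo <- hi <- mode_int(g$pos)
      }
      tsd_len <- hi - lo
      tsd <- NA_character_
      if (!is.na(tsd_len) && tsd_len >= 1L && tsd_len <= tsd_max) {
        if (!is.null(genome) && ctg %in% names(genome)) {
          tsd <- substr(genome[[ctg]], lo + 1L, hi)
        }
      } else {
        tsd_len <- if (!is.na(tsd_len) && tsd_len == 0L) 0L else NA_integer_
      }
      ilo <- min(lo, hi)
      ihi <- max(ilo + 1L, max(lo, hi))
      jid <- unique(j$id)
      did <- if (is.null(d)) character(0) else unique(d$pair_id)
      nd <- length(did)
      cands[[length(cands) + 1L]] <- data.frame(
        contig = ctg, lo = ilo, hi = ihi,
        start_1based = ilo + 1L, end_1based = ihi,
        support_total = length(jid) + nd,
        support_junction = length(jid),
        support_junction_5p = length(unique(j$id[j$te_side == "5prime"])),
        support_junction_3p = length(unique(j$id[j$te_side == "3prime"])),
        support_discordant = nd,
        tsd_len = tsd_len, tsd = tsd,
        ambiguity_group = NA_character_,
        junction_ids = paste(sort(jid), collapse = ","),
        discordant_ids = paste(sort(did), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, cands)
  out <- out[out$support_total >= min_support, , drop = FALSE]
  if (nrow(out) == 0L) return(empty)

  # ambiguity: connected components of candidates sharing supporting reads
  # (junction reads, or discordant pairs whose genomic mate multi-maps)
  split_ids <- function(x, prefix) {
    lapply(strsplit(x, ",", fixed = TRUE),
           function(v) paste0(prefix, v[nzchar(v)]))
  }
  idsets <- Map(c, split_ids(out$junction_ids, "j:"),
                split_ids(out$discordant_ids, "d:"))
  n <- nrow(out)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      if (length(idsets[[i]]) > 0L && length(idsets[[j]]) > 0L &&
          length(intersect(idsets[[i]], idsets[[j]])) > 0L) {
        parent[find(j)] <- find(i)
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  sizes <- table(comp)
  multi <- names(sizes)[sizes > 1L]
  lab <- stats::setNames(sprintf("ag%d", seq_along(multi)), multi)
  out$ambiguity_group <- ifelse(as.character(comp) %in% multi,
                                lab[as.character(comp)], NA_character_)
  out <- out[order(-out$support_total, out$contig, out$lo), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("insertion_calls", "data.frame")
  out
}

#' Annotate insertion candidates with overlapping intervals
#'
#' Labels each candidate with every annotation interval (e.g. piRNA cluster)
#' overlapping its breakpoint interval.
#'
#' @param calls Output of [call_insertions()].
#' @param annotation A `GRanges` (see [load_intervals()]).
#' @return `calls` with an added `annotations` column (`;`-separated names,
#'   empty string when none overlap).
#' @export
annotate_candidates <- function(calls, annotation) {
  calls$annotations <- rep("", nrow(calls))
  if (nrow(calls) == 0L || length(annotation) == 0L) return(calls)
  nm <- if (!is.null(annotation$name)) annotation$name
        else as.character(seq_along(annotation))
  gr <- GenomicRanges::GRanges(
    seqnames = calls$contig,
    ranges = IRanges::IRanges(start = calls$lo + 1L,
                              end = pmax(calls$hi, calls$lo + 1L)))
  hits <- GenomicRanges::findOverlaps(gr, annotation)
  if (length(hits) > 0L) {
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    ann <- tapply(nm[s], q, function(v) paste(unique(v), collapse = ";"))
    calls$annotations[as.integer(names(ann))] <- as.character(ann)
  }
  calls
}

#' Write insertion candidates as TSV and BED6
#'
#' The TSV carries both 0-based half-open (`lo`, `hi`) and 1-based inclusive
#' (`start_1based`, `end_1based`) coordinates, as stated in its header. The
#' BED carries the candidate rank as name and total support as score.
#'
#' @param calls Output of [call_insertions()] (optionally annotated).
#' @param tsv,bed Output paths; either may be `NULL`.
#' @return Invisibly, `calls`.
#' @export
export_insertions <- function(calls, tsv = NULL, bed = NULL) {
  if (!is.null(tsv)) {
    con <- file(tsv, "w")
    writeLines(c("# insertion candidates",
                 "# lo/hi: 0-based half-open; start_1based/end_1based: 1-based inclusive"),
               con)
    utils::write.table(as.data.frame(calls), con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
  }
  if (!is.null(bed) && nrow(calls) > 0L) {
    gr <- GenomicRanges::GRanges(
      seqnames = calls$contig,
      ranges = IRanges::IRanges(start = calls$lo + 1L,
                                end = pmax(calls$hi, calls$lo + 1L)),
      name = sprintf("candidate%d", seq_len(nrow(calls))),
      score = calls$support_total)
    rtracklayer::export(gr, bed, format = "BED")
  }
  invisible(calls)
}
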