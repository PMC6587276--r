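#' Density-profile window presets
#'
#' Window sizes (nt) conventionally used for per-TE density profiles,
#' proportional to element size: flamenco 428, ZAM 91, Burdock 80, Pifo 87,
#' Phidippo 85.
#'
#' @format Named integer vector.
#' @export
window_presets <- c(flamenco = 428L, ZAM = 91L, Burdock = 80L,
                    Pifo = 87L, Phidippo = 85L)

# Accept a MappingResult (reduced to primary placements) or an alignment
# data.frame restricted to one reference; return the alignment table.
as_one_ref_alignments <- function(x) {
  aln <- if (inherits(x, "MappingResult")) primary_placements(x) else x
  stopifnot(is.data.frame(aln),
            all(c("sequence", "strand", "five_prime", "count") %in% names(aln)))
  if (nrow(aln) > 0L && length(unique(aln$reference)) > 1L) {
    stop("alignments span multiple references; restrict to one TE/region")
  }
  aln
}

# count mass at each 5' position (index p+1 holds mass at 0-based coord p)
position_mass <- function(aln, ref_length) {
  ms <- numeric(ref_length)
  ma <- numeric(ref_length)
  s <- aln$strand == "+"
  if (any(s)) {
    t1 <- tapply(aln$count[s], aln$five_prime[s], sum)
    ms[as.integer(names(t1)) + 1L] <- as.numeric(t1)
  }
  if (any(!s)) {
    t2 <- tapply(aln$count[!s], aln$five_prime[!s], sum)
    ma[as.integer(names(t2)) + 1L] <- as.numeric(t2)
  }
  list(sense = ms, antisense = ma)
}

infer_ref_length <- function(aln, ref_length) {
  if (!is.null(ref_length)) return(as.integer(ref_length))
  if (nrow(aln) == 0L) return(1L)
  as.integer(max(aln$end))
}

#' 5'-overlap histogram between sense and antisense reads
#'
#' For every (sense, antisense) read pair on one reference, the overlap
#' length is `five_prime(antisense) - five_prime(sense) + 1`. Pairs with an
#' overlap of 1..`k_max` nt contribute `count(sense) * count(antisense)` to
#' that overlap length; proportions are normalized by the total contributing
#' pair mass. A 10-nt overlap is the ping-pong signature.
#'
#' With `distinct_pairs = TRUE` each distinct sequence pair contributes
#' weight 1 instead of the product of copy numbers.
#'
#' @param x A `MappingResult` (reduced internally to one placement per read
#'   via [primary_placements()]) or an alignment data.frame on one reference.
#' @param ref_length Reference length in nt (inferred from alignment ends
#'   when omitted).
#' @param k_max Largest overlap length tabulated (default 28).
#' @param distinct_pairs Weight pairs by distinct sequence instead of copy
#'   number product.
#' @return An `OverlapHistogram`: list with `proportions` (named vector over
#'   overlap lengths 1..k_max), `pair_mass`, `k_max`.
#' @export
overlap_histogram <- function(x, ref_length = NULL, k_max = 28L,
                              distinct_pairs = FALSE) {
  aln <- as_one_ref_alignments(x)
  L <- infer_ref_length(aln, ref_length)
  if (distinct_pairs) aln$count <- rep(1, nrow(aln))
  m <- position_mass(aln, L)
  w <- numeric(k_max)
  for (k in seq_len(k_max)) {
    if (k > L) break
    idx <- seq_len(L - k + 1L)
    w[k] <- sum(m$sense[idx] * m$antisense[idx + k - 1L])
  }
  pair_mass <- sum(w)
  p <- if (pair_mass > 0) w / pair_mass else rep(0, k_max)
  if (pair_mass == 0) msg("overlap_histogram: no overlapping pairs")
  structure(list(proportions = stats::setNames(p, seq_len(k_max)),
                 pair_mass = pair_mass,
                 k_max = as.integer(k_max)),
            class = "OverlapHistogram")
}

#' @export
print.OverlapHistogram <- function(x, ...) {
  cat(sprintf("OverlapHistogram: pair mass %.0f, p_10 = %.4f\n",
              x$pair_mass, x$proportions[["10"]]))
  invisible(x)
}

#' Ping-pong Z-score
#'
#' Standardized excess of the 10-nt-overlap proportion over the background
#' overlap-length proportions: `z = (p_10 - mean(B)) / sd(B)` where `B` is
#' the set of proportions over the background overlap range (default 1-23 nt,
#' excluding the tested length 10 itself; set `include_self = TRUE` to keep
#' it in). The sample (n-1) standard deviation is used by default. The score
#' is significant above 1.96. When the background has zero spread (e.g. a
#' single perfect pair, or a uniform histogram) the score is undefined (`NA`)
#' and not significant.
#'
#' @param h An [overlap_histogram()].
#' @param background Overlap lengths forming the background (default `1:23`).
#' @param include_self Keep the tested overlap length in the background.
#' @param test_k Overlap length tested (default 10).
#' @param sd_type `"sample"` (n-1) or `"population"` (n).
#' @return List with `z` (numeric or `NA`) and `significant` (logical).
#' @export
pingpong_zscore <- function(h, background = 1:23, include_self = FALSE,
                            test_k = 10L, sd_type = c("sample", "population")) {
  stopifnot(inherits(h, "OverlapHistogram"))
  sd_type <- match.arg(sd_type)
  if (h$k_max < max(background)) {
    stop("histogram k_max smaller than the background range")
  }
  if (h$pair_mass == 0) return(list(z = NA_real_, significant = FALSE))
  p <- h$proportions
  bk <- if (include_self) background else setdiff(background, test_k)
  b <- p[as.character(bk)]
  s <- stats::sd(b)
  if (sd_type == "population") s <- s * sqrt((length(b) - 1) / length(b))
  if (is.na(s) || s == 0) return(list(z = NA_real_, significant = FALSE))
  z <- (p[[as.character(test_k)]] - mean(b)) / s
  list(z = z, significant = z > 1.96)
}

# logical PPP membership per alignment row (exact `overlap`-nt 5' overlap
# with at least one opposite-strand read)
ppp_membership <- function(aln, L, overlap = 10L) {
  m <- position_mass(aln, L)
  fp <- aln$five_prime
  sense <- aln$strand == "+"
  member <- logical(nrow(aln))
  # sense read at p pairs with antisense at p + overlap - 1
  idx <- fp[sense] + overlap  # (p + overlap - 1) + 1 for 1-based vector
  ok <- idx >= 1L & idx <= L
  member[sense][ok] <- m$antisense[idx[ok]] > 0
  # antisense read at q pairs with sense at q - overlap + 1
  idx2 <- fp[!sense] - overlap + 2L
  ok2 <- idx2 >= 1L & idx2 <= L
  member[!sense][ok2] <- m$sense[idx2[ok2]] > 0
  member
}

#' Ping-pong partner (PPP) percentages
#'
#' A read is a ping-pong partner iff at least one opposite-strand read
#' overlaps its 5' end by exactly `overlap` nt (default 10). Percentages are
#' the share of TE-mapped read mass belonging to PPP members, overall and per
#' strand. Both count-weighted and per-distinct-sequence percentages are
#' reported.
#'
#' @inheritParams overlap_histogram
#' @param overlap Exact 5'-overlap length defining partnership (default 10).
#' @return List with `ppp_percent_total`, `ppp_percent_sense`,
#'   `ppp_percent_antisense` (count-weighted), their `_distinct` variants,
#'   and the underlying masses.
#' @export
ppp_stats <- function(x, ref_length = NULL, overlap = 10L) {
  aln <- as_one_ref_alignments(x)
  L <- infer_ref_length(aln, ref_length)
  empty <- list(ppp_percent_total = 0, ppp_percent_sense = 0,
                ppp_percent_antisense = 0,
                ppp_percent_total_distinct = 0,
                ppp_percent_sense_distinct = 0,
                ppp_percent_antisense_distinct = 0,
                mass_total = 0, mass_ppp = 0)
  if (nrow(aln) == 0L) return(empty)
  member <- ppp_membership(aln, L, overlap)
  pct <- function(w, sel) {
    tot <- sum(w[sel])
    if (tot == 0) 0 else 100 * sum(w[sel & member]) / tot
  }
  w <- aln$count
  d <- rep(1, nrow(aln))
  all <- rep(TRUE, nrow(aln))
  sense <- aln$strand == "+"
  list(ppp_percent_total = pct(w, all),
       ppp_percent_sense = pct(w, sense),
       ppp_percent_antisense = pct(w, !sense),
       ppp_percent_total_distinct = pct(d, all),
       ppp_percent_sense_distinct = pct(d, sense),
       ppp_percent_antisense_distinct = pct(d, !sense),
       mass_total = sum(w), mass_ppp = sum(w[member]))
}

#' Positional nucleotide frequencies and 1U/10A bias
#'
#' Count-weighted nucleotide frequencies over the first `P` positions of
#' each read in its sequenced (5'->3') orientation. `bias_1U` is the
#' percentage of read mass with T (uridine in the RNA) at position 1;
#' `bias_10A` the percentage with A at position 10. The `subset` argument
#' restricts the computation to ping-pong partners of one strand, matching
#' the convention of reporting 1U on antisense and 10A on sense partners.
#'
#' @inheritParams ppp_stats
#' @param P Number of 5' positions profiled (default 10).
#' @param subset `"all"` reads, or only ping-pong partners on the sense
#'   (`"ppp_sense"`) or antisense (`"ppp_antisense"`) strand.
#' @return A `NucleotideMatrix`: list with `matrix` (P x 4 frequency matrix,
#'   rows positions, columns A/C/G/T, each row summing to 1), `bias_1U`,
#'   `bias_10A`, and the read `mass` used.
#' @export
nucleotide_bias <- function(x, ref_length = NULL, P = 10L,
                            subset = c("all", "ppp_sense", "ppp_antisense"),
                            overlap = 10L) {
  subset <- match.arg(subset)
  aln <- as_one_ref_alignments(x)
  L <- infer_ref_length(aln, ref_length)
  if (subset != "all" && nrow(aln) > 0L) {
    member <- ppp_membership(aln, L, overlap)
    keep <- if (subset == "ppp_sense") member & aln$strand == "+"
            else member & aln$strand == "-"
    aln <- aln[keep, , drop = FALSE]
  }
  short <- nrow(aln) > 0L && any(nchar(aln$sequence) < P)
  if (short) {
    warning(sprintf("dropping %d reads shorter than %d nt",
                    sum(nchar(aln$sequence) < P), P))
    aln <- aln[nchar(aln$sequence) >= P, , drop = FALSE]
  }
  bases <- c("A", "C", "G", "T")
  f <- matrix(NA_real_, nrow = P, ncol = 4,
              dimnames = list(position = seq_len(P), base = bases))
  if (nrow(aln) == 0L) {
    warning("nucleotide_bias: empty read subset")
    return(structure(list(matrix = f, bias_1U = NA_real_, bias_10A = NA_real_,
                          mass = 0, subset = subset),
                     class = "NucleotideMatrix"))
  }
  w <- aln$count
  for (i in seq_len(P)) {
    b <- substr(aln$sequence, i, i)
    tot <- tapply(w, factor(b, levels = bases), sum)
    tot[is.na(tot)] <- 0
    f[i, ] <- tot / sum(tot)
  }
  structure(list(matrix = f,
                 bias_1U = 100 * f[1L, "T"],
                 bias_10A = if (P >= 10L) 100 * f[10L, "A"] else NA_real_,
                 mass = sum(w), subset = subset),
            class = "NucleotideMatrix")
}

#' @export
print.NucleotideMatrix <- function(x, ...) {
  cat(sprintf("NucleotideMatrix (%s, mass %.0f): 1U = %.1f%%, 10A = %.1f%%\n",
              x$subset, x$mass, x$bias_1U, x$bias_10A))
  invisible(x)
}

#' Sense/antisense density profile in reads per million
#'
#' Tiles the reference into windows of `window_size` nt (the last window may
#' be short), assigns each read to exactly one window by its 5'-end
#' coordinate, and reports per-window read mass in reads per million (RPM):
#' `1e6 * mass / normalization_total`, split by strand. The denominator is
#' conventionally the total number of genome-mapped reads at zero mismatches
#' (see [genome_unique_status()]), so profiles are comparable across
#' libraries. Single-window assignment by 5' end keeps mass conservation
#' exact: `sum(RPM) * normalization_total / 1e6` equals the profiled read
#' mass.
#'
#' @inheritParams overlap_histogram
#' @param window_size Window width in nt (see [window_presets]).
#' @param normalization_total Zero-mismatch genome-mapped read mass.
#' @return A `DensityProfile`: list with `windows` (data.frame of `window`,
#'   `start`, `end`, `sense_rpm`, `antisense_rpm`), `window_size`,
#'   `normalization_total`, `ref_length`.
#' @export
density_profile <- function(x, window_size, normalization_total,
                            ref_length = NULL) {
  stopifnot(window_size >= 1L, normalization_total >= 1)
  aln <- as_one_ref_alignments(x)
  L <- infer_ref_length(aln, ref_length)
  nwin <- ceiling(L / window_size)
  starts <- (seq_len(nwin) - 1L) * window_size
  ends <- pmin(starts + window_size, L)
  sense_rpm <- numeric(nwin)
  anti_rpm <- numeric(nwin)
  if (nrow(aln) > 0L) {
    win <- aln$five_prime %/% window_size + 1L
    s <- aln$strand == "+"
    acc <- function(sel) {
      v <- numeric(nwin)
      if (any(sel)) {
        t1 <- tapply(aln$count[sel], win[sel], sum)
        v[as.integer(names(t1))] <- as.numeric(t1)
      }
      v
    }
    sense_rpm <- 1e6 * acc(s) / normalization_total
    anti_rpm <- 1e6 * acc(!s) / normalization_total
  }
  structure(list(windows = data.frame(window = seq_len(nwin), start = starts,
                                      end = ends, sense_rpm = sense_rpm,
                                      antisense_rpm = anti_rpm),
                 window_size = as.integer(window_size),
                 normalization_total = normalization_total,
                 ref_length = L),
            class = "DensityProfile")
}

#' @export
print.DensityProfile <- function(x, ...) {
  cat(sprintf(
    "DensityProfile: %d windows of %d nt over %d nt, total %.2f RPM\n",
    nrow(x$windows), x$window_size, x$ref_length,
    sum(x$windows$sense_rpm) + sum(x$windows$antisense_rpm)))
  invisible(x)
}

#' piRNA-cluster composition of genome-unique mappers
#'
#' Assigns each genome-unique zero-mismatch read to the annotated interval
#' (piRNA cluster) its alignment overlaps by at least 1 bp. A read
#' overlapping several intervals is assigned to the one with the larger
#' overlap (ties to the first interval in BED order). Shares are computed
#' over the cluster-assigned read mass; with `include_unassigned = TRUE` an
#' explicit `unassigned` bucket makes shares sum to 1 over all unique reads.
#'
#' @param x A `MappingResult` from [genome_unique_status()] (0 mismatches).
#' @param clusters A `GRanges` of cluster intervals (see [load_intervals()]).
#' @param include_unassigned Add a bucket for unique reads outside every
#'   interval.
#' @return data.frame with `cluster`, `mass`, `share`, ordered by decreasing
#'   share.
#' @export
cluster_composition <- function(x, clusters, include_unassigned = FALSE) {
  stopifnot(inherits(x, "MappingResult"))
  if (x$max_mismatches != 0L) {
    stop("cluster composition requires a zero-mismatch mapping ",
         "(use genome_unique_status())")
  }
  if (length(clusters) == 0L) stop("empty cluster annotation")
  uniq <- x$status$sequence[x$status$status == "unique"]
  aln <- x$alignments[x$alignments$sequence %in% uniq, , drop = FALSE]
  cl_names <- if (!is.null(clusters$name)) clusters$name
              else as.character(seq_along(clusters))
  if (nrow(aln) == 0L) {
    return(data.frame(cluster = character(0), mass = numeric(0),
                      share = numeric(0)))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = aln$reference,
    ranges = IRanges::IRanges(start = aln$start + 1L, end = aln$end))
  hits <- GenomicRanges::findOverlaps(gr, clusters, minoverlap = 1L)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(gr)[q], IRanges::ranges(clusters)[s]))
  # larger overlap wins; ties to first interval in annotation order
  ord <- order(q, -ov, s)
  q <- q[ord]; s <- s[ord]
  first <- !duplicated(q)
  multi <- sum(!first)
  if (multi > 0L) msg("cluster_composition: %d multi-cluster placements resolved", multi)
  assign <- s[first]
  qq <- q[first]
  mass <- tapply(aln$count[qq], factor(cl_names[assign], levels = unique(cl_names)),
                 sum)
  mass[is.na(mass)] <- 0
  out <- data.frame(cluster = names(mass), mass = as.numeric(mass),
                    stringsAsFactors = FALSE)
  if (include_unassigned) {
    out <- rbind(out, data.frame(cluster = "unassigned",
                                 mass = sum(aln$count) - sum(out$mass)))
  }
  denom <- sum(out$mass)
  out$share <- if (denom > 0) out$mass / denom else 0
  out <- out[order(-out$share, out$cluster), , drop = FALSE]
  rownames(out) <- NULL
  out
}
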