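# Seeded simulators with machine-readable truth, so every pipeline stage can
# be validated offline. All randomness runs inside withr::with_seed, so the
# global RNG state is untouched and identical seeds give identical output.

#' Simulate a piRNA library with a ping-pong structure
#'
#' Emits a small-RNA library over a random TE consensus embedded in a
#' simulated genome:
#' \itemize{
#'   \item antisense \emph{primary} piRNAs with 5' ends drawn along the TE;
#'     with probability `p1U` a primary's 5' position is drawn from TE
#'     positions whose antisense base is T (uridine), realizing the 1U bias
#'     while keeping every read an exact genome substring (so reads stay
#'     0-mismatch genome-mappable);
#'   \item for each primary, with probability `f_pp` a sense \emph{secondary}
#'     read whose 5' end satisfies the ping-pong rule
#'     `five_prime(antisense) - five_prime(sense) + 1 == 10`. By
#'     complementarity its 10th base is A exactly when the partner's first
#'     base is T, so the realized 10A rate is mechanically coupled to `p1U`
#'     (as in the ping-pong cycle itself); `p10A` must equal `p1U`;
#'   \item uniform-position background reads on both strands, permitted to
#'     create chance 10-nt overlaps. The truth record therefore reports
#'     \emph{realized} ping-pong partnership, recomputed from the emitted 5'
#'     positions, not the nominal `f_pp`.
#' }
#' Copy numbers are geometric with mean `count_mean`. The genome embeds the
#' TE inside a host cluster interval plus a decoy cluster, so genome mapping
#' and cluster composition are exercised end to end.
#'
#' @param seed Mandatory integer seed.
#' @param n_antisense_primary Number of distinct primary draws.
#' @param f_pp Ping-pong fraction: probability that a primary has a sense
#'   partner at exact 10-nt 5'-overlap.
#' @param p1U Probability of uridine at position 1 of primaries.
#' @param p10A Probability of adenine at position 10 of secondaries; realized
#'   through complementarity, must equal `p1U`.
#' @param n_background_sense,n_background_antisense Background draws with
#'   uniform 5' positions.
#' @param te_length TE consensus length in nt (default 8400, ZAM-sized).
#' @param read_lengths Candidate read lengths (default 23:29, uniform).
#' @param count_mean Mean copy number per distinct draw (geometric).
#' @return A `pirna_library_sim`: list with `records` (one row per distinct
#'   read draw: id, sequence, count, origin, strand, five-prime TE coordinate
#'   `fp`, length, `ppp_realized`), `te`, `genome` (named vectors), `clusters`
#'   (`GRanges`), `te_offset` (0-based genome offset of the TE), `config`.
#' @export
simulate_pirna_library <- function(seed,
                                   n_antisense_primary = 3000L,
                                   f_pp = 0.4,
                                   p1U = 0.9,
                                   p10A = p1U,
                                   n_background_sense = 150L,
                                   n_background_antisense = 150L,
                                   te_length = 8400L,
                                   read_lengths = 23:29,
                                   count_mean = 2) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            f_pp >= 0, f_pp <= 1, p1U >= 0, p1U <= 1,
            te_length >= 200L, count_mean >= 1)
  if (!isTRUE(all.equal(p10A, p1U))) {
    stop("p10A is realized through base-pairing with the primary's first ",
         "position and must equal p1U")
  }
  withr::with_seed(as.integer(seed), {
    te <- random_dna(te_length)
    te_chars <- strsplit(te, "")[[1]]
    lmax <- max(read_lengths)
    # valid antisense 5' positions leave room for the read and its partner
    valid <- (lmax - 1L):(te_length - lmax - 9L)
    a_pos <- valid[te_chars[valid + 1L] == "A"]   # antisense 5' base is T
    o_pos <- valid[te_chars[valid + 1L] != "A"]

    rec <- list()
    n_p <- as.integer(n_antisense_primary)
    if (n_p > 0L) {
      is_u <- stats::rbinom(n_p, 1L, p1U) == 1L
      fp_a <- integer(n_p)
      fp_a[is_u] <- sample(a_pos, sum(is_u), replace = TRUE)
      fp_a[!is_u] <- sample(o_pos, sum(!is_u), replace = TRUE)
      len_a <- sample(read_lengths, n_p, replace = TRUE)
      seq_a <- revcomp(substr(rep(te, n_p), fp_a - len_a + 2L, fp_a + 1L))
      rec$primary <- data.frame(sequence = seq_a, origin = "primary",
                                strand = "-", fp = fp_a, length = len_a,
                                stringsAsFactors = FALSE)
      has_sec <- stats::rbinom(n_p, 1L, f_pp) == 1L
      n_s <- sum(has_sec)
      if (n_s > 0L) {
        fp_s <- fp_a[has_sec] - 9L
        len_s <- sample(read_lengths, n_s, replace = TRUE)
        seq_s <- substr(rep(te, n_s), fp_s + 1L, fp_s + len_s)
        rec$secondary <- data.frame(sequence = seq_s, origin = "secondary",
                                    strand = "+", fp = fp_s, length = len_s,
                                    stringsAsFactors = FALSE)
      }
    }
    bg <- function(n, strand) {
      if (n <= 0L) return(NULL)
      len <- sample(read_lengths, n, replace = TRUE)
      if (strand == "+") {
        fp <- vapply(len, function(l) sample.int(te_length - l + 1L, 1L) - 1L,
                     integer(1))
        sq <- substr(rep(te, n), fp + 1L, fp + len)
        org <- "background_sense"
      } else {
        fp <- vapply(len, function(l) sample.int(te_length - l + 1L, 1L) + l - 2L,
                     integer(1))
        sq <- revcomp(substr(rep(te, n), fp - len + 2L, fp + 1L))
        org <- "background_antisense"
      }
      data.frame(sequence = sq, origin = org, strand = strand, fp = fp,
                 length = len, stringsAsFactors = FALSE)
    }
    rec$bg_sense <- bg(as.integer(n_background_sense), "+")
    rec$bg_anti <- bg(as.integer(n_background_antisense), "-")
    records <- do.call(rbind, rec)
    rownames(records) <- NULL
    records$id <- sprintf("sim%06d", seq_len(nrow(records)))
    records$count <- stats::rgeom(nrow(records), prob = 1 / count_mean) + 1L

    # realized ping-pong partnership from emitted positions
    sense_fp <- unique(records$fp[records$strand == "+"])
    anti_fp <- unique(records$fp[records$strand == "-"])
    records$ppp_realized <- ifelse(
      records$strand == "+",
      (records$fp + 9L) %in% anti_fp,
      (records$fp - 9L) %in% sense_fp)

    # genome: flank + TE (inside host cluster) + spacer with a decoy cluster
    flank <- 2000L
    spacer <- 4000L
    genome_seq <- paste0(random_dna(flank), te, random_dna(spacer))
    genome <- stats::setNames(genome_seq, "chr_sim")
    clusters <- GenomicRanges::GRanges(
      seqnames = "chr_sim",
      ranges = IRanges::IRanges(
        start = c(flank - 200L + 1L, flank + te_length + 1000L + 1L),
        end = c(flank + te_length + 200L, flank + te_length + 2500L)),
      name = c("cluster_host", "cluster_decoy"))
    structure(list(records = records[, c("id", "sequence", "count", "origin",
                                         "strand", "fp", "length",
                                         "ppp_realized")],
                   te = stats::setNames(te, "TE_sim"),
                   genome = genome,
                   clusters = clusters,
                   te_offset = flank,
                   config = list(seed = as.integer(seed),
                                 n_antisense_primary = n_p, f_pp = f_pp,
                                 p1U = p1U, p10A = p10A,
                                 n_background_sense = as.integer(n_background_sense),
                                 n_background_antisense = as.integer(n_background_antisense),
                                 te_length = as.integer(te_length),
                                 read_lengths = read_lengths,
                                 count_mean = count_mean)),
              class = "pirna_library_sim")
  })
}

#' Convert simulated library records to a ReadSet
#'
#' Collapses the simulated records exactly as [load_reads()] would after
#' writing/reading them to FASTQ.
#'
#' @param sim A [simulate_pirna_library()] result.
#' @return A [read_set()].
#' @export
sim_read_set <- function(sim) {
  stopifnot(inherits(sim, "pirna_library_sim"))
  read_set(sim$records[, c("sequence", "count")], provenance = "simulated")
}

#' Write simulated library files
#'
#' Writes `reads.fastq` (one record per copy, constant 'I' qualities),
#' `te.fa`, `genome.fa`, `clusters.bed` and `truth.tsv` under `dir`.
#'
#' @param sim A [simulate_pirna_library()] result.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths.
#' @export
write_library <- function(sim, dir) {
  stopifnot(inherits(sim, "pirna_library_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(reads = file.path(dir, "reads.fastq"),
             te = file.path(dir, "te.fa"),
             genome = file.path(dir, "genome.fa"),
             clusters = file.path(dir, "clusters.bed"),
             truth = file.path(dir, "truth.tsv"))
  r <- sim$records
  idx <- rep(seq_len(nrow(r)), r$count)
  copy <- sequence(r$count)
  writeLines(paste0("@", r$id[idx], ".", copy, "\n", r$sequence[idx], "\n+\n",
                    strrep("I", nchar(r$sequence[idx]))),
             paths[["reads"]])
  write_reference(sim$te, paths[["te"]])
  write_reference(sim$genome, paths[["genome"]])
  rtracklayer::export(sim$clusters, paths[["clusters"]], format = "BED")
  utils::write.table(r, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}

#' Simulate a paired-end readset around a planted TE insertion
#'
#' Builds a random reference genome carrying a multi-copy repeat family,
#' plants a TE insertion with a target-site duplication (TSD) into a donor
#' haplotype, and samples Illumina-like paired-end reads from the donor.
#'
#' The donor is `G[0, site) + TE + G[site - tsd_length, end)` (0-based), so
#' the `tsd_length` bases left of `site` are duplicated on both sides of the
#' TE. The truth record lists the insertion site, the TSD string, the ids of
#' reads spanning either junction with at least `junction_margin` nt on both
#' sides, the ids of truly discordant pairs (one mate fully inside the TE,
#' the other fully genomic), and - when the site falls inside a repeat copy -
#' the homologous coordinates in the other copies (the expected ambiguity
#' group).
#'
#' @param seed Mandatory integer seed.
#' @param genome_length Reference length in bp.
#' @param repeat_unit_length,repeat_copies,repeat_divergence Repeat family:
#'   unit size, copy number, per-base divergence between copies.
#' @param te_length TE consensus length.
#' @param insertion_site 0-based insertion coordinate on the reference, or
#'   `NULL` for no insertion (TE-free readset). The helper
#'   [repeat_copy_site()] returns a coordinate inside a chosen repeat copy.
#' @param tsd_length TSD length in bp (default 4; 0 for none).
#' @param read_length,insert_mean,insert_sd,coverage,error_rate Read
#'   sampling model (defaults 101 bp, 350/50 bp insert, 15x, 0.001
#'   substitutions per base).
#' @param junction_margin Minimum bases on each side of a junction for a
#'   read to be listed as junction-spanning truth (default 20).
#' @return An `insertion_sim`: list with `mate1`, `mate2` (named vectors),
#'   `genome`, `te`, `clusters`, `truth` (list: `site`, `tsd`,
#'   `junction_ids`, `discordant_ids`, `ambiguity_sites`), `config`.
#' @export
simulate_insertion_readset <- function(seed,
                                       genome_length = 20000L,
                                       repeat_unit_length = 600L,
                                       repeat_copies = 3L,
                                       repeat_divergence = 0.02,
                                       te_length = 3000L,
                                       insertion_site = 5000L,
                                       tsd_length = 4L,
                                       read_length = 101L,
                                       insert_mean = 350,
                                       insert_sd = 50,
                                       coverage = 15,
                                       error_rate = 0.001,
                                       junction_margin = 20L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, coverage > 0,
            tsd_length >= 0L, read_length >= 2L * junction_margin)
  withr::with_seed(as.integer(seed), {
    g <- strsplit(random_dna(genome_length), "")[[1]]
    # plant diverged repeat copies, evenly spaced in the second half
    copy_starts <- integer(0)
    if (repeat_copies > 0L && repeat_unit_length > 0L) {
      unit <- strsplit(random_dna(repeat_unit_length), "")[[1]]
      gap <- (genome_length %/% 2L - repeat_unit_length) %/% max(1L, repeat_copies)
      copy_starts <- genome_length %/% 2L +
        (seq_len(repeat_copies) - 1L) * (repeat_unit_length + gap)
      for (s in copy_starts) {
        cp <- unit
        mut <- which(stats::runif(repeat_unit_length) < repeat_divergence)
        if (length(mut) > 0L) {
          cp[mut] <- vapply(cp[mut], function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
        }
        g[(s + 1L):(s + repeat_unit_length)] <- cp
      }
    }
    genome_seq <- paste(g, collapse = "")
    genome <- stats::setNames(genome_seq, "chr_sim")
    te <- random_dna(te_length)
    clusters <- GenomicRanges::GRanges(
      seqnames = "chr_sim",
      ranges = IRanges::IRanges(
        start = max(1L, genome_length %/% 2L - 400L),
        end = min(genome_length,
                  if (length(copy_starts) > 0L)
                    max(copy_starts) + repeat_unit_length + 400L
                  else genome_length %/% 2L + 400L)),
      name = "cluster_sim")

    tsd <- ""
    site <- insertion_site
    ambiguity <- integer(0)
    if (!is.null(site)) {
      site <- as.integer(site)
      if (site < read_length || site > genome_length - read_length) {
        stop("insertion_site too close to a contig end")
      }
      tsd <- substr(genome_seq, site - tsd_length + 1L, site)
      donor <- paste0(substr(genome_seq, 1L, site), te,
                      substr(genome_seq, site - tsd_length + 1L, genome_length))
      in_copy <- which(site > copy_starts & site <= copy_starts + repeat_unit_length)
      if (length(in_copy) == 1L) {
        ambiguity <- sort(copy_starts + (site - copy_starts[in_copy]))
      }
    } else {
      donor <- genome_seq
    }
    dlen <- nchar(donor)

    n_pairs <- as.integer(round(coverage * dlen / (2 * read_length)))
    isize <- pmin(dlen, pmax(2L * read_length,
                             as.integer(round(stats::rnorm(n_pairs, insert_mean,
                                                           insert_sd)))))
    frag <- vapply(isize, function(s) sample.int(dlen - s + 1L, 1L) - 1L,
                   integer(1))
    m1 <- substr(rep(donor, n_pairs), frag + 1L, frag + read_length)
    m2_start <- frag + isize - read_length
    m2 <- revcomp(substr(rep(donor, n_pairs), m2_start + 1L,
                         m2_start + read_length))
    ids <- sprintf("frag%06d", seq_len(n_pairs))
    names(m1) <- names(m2) <- ids

    add_errors <- function(seqs) {
      ch <- strsplit(seqs, "")
      for (i in seq_along(ch)) {
        mut <- which(stats::runif(length(ch[[i]])) < error_rate)
        if (length(mut) > 0L) {
          ch[[i]][mut] <- vapply(ch[[i]][mut], function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
        }
      }
      vapply(ch, paste, "", collapse = "")
    }
    m1 <- stats::setNames(add_errors(m1), ids)
    m2 <- stats::setNames(add_errors(m2), ids)

    junction_ids <- character(0)
    discordant_ids <- character(0)
    if (!is.null(site)) {
      j1 <- site                       # donor coordinate of the left junction
      j2 <- site + te_length           # right junction
      spans <- function(a, b, j) a <= j - junction_margin & b >= j + junction_margin
      r1a <- frag; r1b <- frag + read_length
      r2a <- m2_start; r2b <- m2_start + read_length
      jr <- spans(r1a, r1b, j1) | spans(r1a, r1b, j2) |
            spans(r2a, r2b, j1) | spans(r2a, r2b, j2)
      junction_ids <- ids[jr]
      in_te <- function(a, b) a >= j1 & b <= j2
      in_gen <- function(a, b) b <= j1 | a >= j2
      disc <- (in_te(r1a, r1b) & in_gen(r2a, r2b)) |
              (in_te(r2a, r2b) & in_gen(r1a, r1b))
      discordant_ids <- ids[disc]
    }
    structure(list(mate1 = m1, mate2 = m2, genome = genome,
                   te = stats::setNames(te, "TE_sim"), clusters = clusters,
                   truth = list(site = if (is.null(site)) NA_integer_ else site,
                                tsd = tsd,
                                junction_ids = junction_ids,
                                discordant_ids = discordant_ids,
                                ambiguity_sites = ambiguity),
                   config = list(seed = as.integer(seed),
                                 genome_length = as.integer(genome_length),
                                 repeat_unit_length = as.integer(repeat_unit_length),
                                 repeat_copies = as.integer(repeat_copies),
                                 repeat_divergence = repeat_divergence,
                                 te_length = as.integer(te_length),
                                 insertion_site = site,
                                 tsd_length = as.integer(tsd_length),
                                 read_length = as.integer(read_length),
                                 insert_mean = insert_mean,
                                 insert_sd = insert_sd,
                                 coverage = coverage,
                                 error_rate = error_rate,
                                 copy_starts = copy_starts)),
              class = "insertion_sim")
  })
}

#' Coordinate inside a repeat copy
#'
#' Returns the 0-based reference coordinate at a given offset inside repeat
#' copy `copy` of the family planted by [simulate_insertion_readset()] with
#' the same geometry parameters, for use as `insertion_site`.
#'
#' @param genome_length,repeat_unit_length,repeat_copies Family geometry, as
#'   passed to the simulator.
#' @param copy Which copy (1-based).
#' @param offset Offset into the copy (default: the middle).
#' @return Integer coordinate.
#' @export
repeat_copy_site <- function(genome_length = 20000L, repeat_unit_length = 600L,
                             repeat_copies = 3L, copy = 2L,
                             offset = repeat_unit_length %/% 2L) {
  gap <- (genome_length %/% 2L - repeat_unit_length) %/% max(1L, repeat_copies)
  starts <- genome_length %/% 2L +
    (seq_len(repeat_copies) - 1L) * (repeat_unit_length + gap)
  as.integer(starts[copy] + offset)
}

#' Write simulated insertion readset files
#'
#' Writes `mate1.fastq`, `mate2.fastq`, `genome.fa`, `te.fa`, `clusters.bed`
#' and `truth.tsv` under `dir`.
#'
#' @param sim A [simulate_insertion_readset()] result.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths.
#' @export
write_insertion_readset <- function(sim, dir) {
  stopifnot(inherits(sim, "insertion_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(mate1 = file.path(dir, "mate1.fastq"),
             mate2 = file.path(dir, "mate2.fastq"),
             genome = file.path(dir, "genome.fa"),
             te = file.path(dir, "te.fa"),
             clusters = file.path(dir, "clusters.bed"),
             truth = file.path(dir, "truth.tsv"))
  fq <- function(seqs, path, mate) {
    writeLines(paste0("@", names(seqs), "/", mate, "\n", seqs, "\n+\n",
                      strrep("I", nchar(seqs))), path)
  }
  fq(sim$mate1, paths[["mate1"]], 1L)
  fq(sim$mate2, paths[["mate2"]], 2L)
  write_reference(sim$genome, paths[["genome"]])
  write_reference(sim$te, paths[["te"]])
  rtracklayer::export(sim$clusters, paths[["clusters"]], format = "BED")
  tr <- sim$truth
  utils::write.table(
    data.frame(key = c("site", "tsd", "junction_ids", "discordant_ids",
                       "ambiguity_sites"),
               value = c(tr$site, tr$tsd,
                         paste(tr$junction_ids, collapse = ","),
                         paste(tr$discordant_ids, collapse = ","),
                         paste(tr$ambiguity_sites, collapse = ","))),
    paths[["truth"]], sep = "\t", quote = FALSE, row.names = FALSE)
  paths
}
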