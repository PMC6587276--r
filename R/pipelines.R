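# End-to-end drivers composing the module functions, with TSV reports and a
# JSON run manifest so every report is reproducible from its inputs.

as_refs <- function(x) {
  if (is.character(x) && length(x) == 1L && is.null(names(x)) && file.exists(x))
    load_reference(x)
  else x
}

as_reads <- function(x, ...) {
  if (inherits(x, "ReadSet")) x else load_reads(x, ...)
}

as_clusters <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) load_intervals(x)
  else x
}

write_manifest <- function(path, inputs, params, counts) {
  jsonlite::write_json(
    list(package = "pingpongr",
         version = as.character(utils::packageVersion("pingpongr")),
         inputs = inputs, parameters = params, counts = counts),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the full piRNA signature pipeline
#'
#' Stages: load and collapse reads (18-30 nt window by default), optional
#' exact contaminant depletion, genome mapping at 0 mismatches (the RPM
#' denominator and uniqueness statuses), size selection of 23-29 nt piRNAs,
#' TE mapping at up to 3 mismatches, overlap histogram / Z-score / ping-pong
#' partners / nucleotide bias, density profile, and cluster composition of
#' genome-unique piRNAs. All tables are written as TSV under `out_dir`
#' together with a JSON manifest of inputs, parameters and per-stage counts.
#'
#' @param reads A [read_set()] or FASTA/FASTQ path.
#' @param genome,te Named character vectors or FASTA paths; `te` must hold a
#'   single consensus.
#' @param clusters A `GRanges`, a BED path, or `NULL` to skip cluster
#'   composition.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param min_len,max_len piRNA size selection (default 23-29 nt).
#' @param load_min,load_max Library load window used for the normalization
#'   denominator (default 18-30 nt).
#' @param max_mismatches_te TE mapping tolerance (default 3).
#' @param window_size Profile window in nt, or a name from [window_presets].
#' @param contaminant Optional contaminant sequence for exact depletion.
#' @param counts_in_header Passed to [load_reads()].
#' @return List with `histogram`, `zscore`, `ppp`, `bias_all`,
#'   `bias_ppp_sense`, `bias_ppp_antisense`, `profile`, `composition`,
#'   `normalization_total`, `counts`, `files`.
#' @export
run_signature_pipeline <- function(reads, genome, te, clusters = NULL,
                                   out_dir = NULL,
                                   min_len = 23L, max_len = 29L,
                                   load_min = 18L, load_max = 30L,
                                   max_mismatches_te = 3L,
                                   window_size = 91L,
                                   contaminant = NULL,
                                   counts_in_header = FALSE) {
  if (is.character(window_size)) {
    if (!window_size %in% names(window_presets))
      stop("unknown window preset '", window_size, "'")
    window_size <- window_presets[[window_size]]
  }
  input_label <- if (is.character(reads)) reads else "ReadSet"
  rs <- as_reads(reads, min_len = load_min, max_len = load_max,
                 counts_in_header = counts_in_header)
  genome <- as_refs(genome)
  te <- as_refs(te)
  clusters <- as_clusters(clusters)
  if (length(te) != 1L) stop("te must hold a single consensus sequence")
  counts <- list(loaded_total = rs$total_count,
                 loaded_distinct = nrow(rs$reads))
  if (!is.null(contaminant)) {
    rs <- filter_exact_contaminant(rs, contaminant)
    counts$after_depletion <- rs$total_count
  }
  g0 <- genome_unique_status(rs, genome)
  norm_total <- g0$mapped_total
  counts$genome_mapped_0mm <- norm_total

  keep <- rs$reads$length >= min_len & rs$reads$length <= max_len
  pirna <- read_set(rs$reads[keep, c("sequence", "count")], rs$provenance)
  counts$pirna_total <- pirna$total_count

  te_map <- map_reads(pirna, te, max_mismatches = max_mismatches_te,
                      report = "best")
  aln <- primary_placements(te_map)
  counts$te_mapped_mass <- sum(aln$count)
  te_len <- nchar(te[[1L]])

  h <- overlap_histogram(aln, ref_length = te_len)
  z <- pingpong_zscore(h)
  ppp <- ppp_stats(aln, ref_length = te_len)
  bias_all <- nucleotide_bias(aln, ref_length = te_len, subset = "all")
  bias_ps <- nucleotide_bias(aln, ref_length = te_len, subset = "ppp_sense")
  bias_pa <- nucleotide_bias(aln, ref_length = te_len, subset = "ppp_antisense")
  prof <- density_profile(aln, window_size = window_size,
                          normalization_total = max(1, norm_total),
                          ref_length = te_len)
  comp <- NULL
  if (!is.null(clusters) && length(clusters) > 0L) {
    pirna_g0 <- genome_unique_status(pirna, genome)
    comp <- cluster_composition(pirna_g0, clusters)
  }

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(x) file.path(out_dir, x)
    utils::write.table(
      data.frame(overlap = seq_len(h$k_max), proportion = unname(h$proportions)),
      fp("overlap_histogram.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(te = names(te), z_score = z$z, significant = z$significant,
                 ppp_percent_total = round(ppp$ppp_percent_total, 1),
                 ppp_percent_sense = round(ppp$ppp_percent_sense, 1),
                 ppp_percent_antisense = round(ppp$ppp_percent_antisense, 1),
                 bias_1U_ppp_antisense = round(bias_pa$bias_1U, 1),
                 bias_10A_ppp_sense = round(bias_ps$bias_10A, 1)),
      fp("signature_report.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      as.data.frame.table(bias_all$matrix, responseName = "frequency"),
      fp("nucleotide_matrix.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(prof$windows, fp("density_profile.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(comp)) {
      utils::write.table(comp, fp("cluster_composition.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    write_manifest(fp("manifest.json"),
                   inputs = list(reads = input_label,
                                 te = names(te), genome = names(genome)),
                   params = list(min_len = min_len, max_len = max_len,
                                 load_min = load_min, load_max = load_max,
                                 max_mismatches_te = max_mismatches_te,
                                 window_size = window_size,
                                 contaminant = !is.null(contaminant)),
                   counts = counts)
    files <- list.files(out_dir, full.names = TRUE)
  }
  list(histogram = h, zscore = z, ppp = ppp, bias_all = bias_all,
       bias_ppp_sense = bias_ps, bias_ppp_antisense = bias_pa,
       profile = prof, composition = comp,
       normalization_total = norm_total, counts = counts, files = files)
}

#' Run the insertion-detection pipeline
#'
#' Stages: junction-read detection, discordant-pair detection, candidate
#' calling, annotation, TSV/BED reports and a JSON manifest.
#'
#' @param mate1,mate2 Named character vectors of mate sequences, or FASTQ
#'   paths.
#' @param genome,te Named character vectors or FASTA paths.
#' @param clusters Optional `GRanges` or BED path for annotation.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param min_te_match,min_flank,max_mm_te,max_mm_flank See
#'   [find_junction_reads()].
#' @param insert_mean,insert_sd,max_mm_pair See [find_discordant_pairs()].
#' @param cluster_distance,min_support See [call_insertions()].
#' @return List with `junctions`, `discordants`, `calls`, `counts`, `files`.
#' @export
run_insertion_pipeline <- function(mate1, mate2, genome, te, clusters = NULL,
                                   out_dir = NULL,
                                   min_te_match = 20L, min_flank = 20L,
                                   max_mm_te = 1L, max_mm_flank = 1L,
                                   insert_mean = 350, insert_sd = 50,
                                   max_mm_pair = 3L,
                                   cluster_distance = 500L, min_support = 2L) {
  read_fq <- function(x) {
    if (is.character(x) && length(x) == 1L && file.exists(x) && is.null(names(x))) {
      b <- Biostrings::readBStringSet(x, format = sniff_format(x))
      stats::setNames(normalize_seq(as.character(b)),
                      sub("[/ ].*$", "", names(b)))
    } else x
  }
  m1 <- read_fq(mate1); m2 <- read_fq(mate2)
  genome <- as_refs(genome); te <- as_refs(te)
  clusters <- as_clusters(clusters)
  jn <- find_junction_reads(c(m1, m2), te, genome,
                            min_te_match = min_te_match, min_flank = min_flank,
                            max_mm_te = max_mm_te, max_mm_flank = max_mm_flank)
  dc <- find_discordant_pairs(m1, m2, te, genome, insert_mean = insert_mean,
                              insert_sd = insert_sd, max_mm = max_mm_pair)
  calls <- call_insertions(jn, dc, genome = genome,
                           cluster_distance = cluster_distance,
                           min_support = min_support)
  if (!is.null(clusters)) calls <- annotate_candidates(calls, clusters)
  counts <- list(pairs = length(m1), junction_reads = length(unique(jn$id)),
                 discordant_pairs = length(unique(dc$pair_id)),
                 candidates = nrow(calls))
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    export_insertions(calls, tsv = file.path(out_dir, "insertions.tsv"),
                      bed = file.path(out_dir, "insertions.bed"))
    write_manifest(file.path(out_dir, "manifest.json"),
                   inputs = list(pairs = length(m1), te = names(te),
                                 genome = names(genome)),
                   params = list(min_te_match = min_te_match,
                                 min_flank = min_flank, max_mm_te = max_mm_te,
                                 max_mm_flank = max_mm_flank,
                                 insert_mean = insert_mean,
                                 insert_sd = insert_sd,
                                 max_mm_pair = max_mm_pair,
                                 cluster_distance = cluster_distance,
                                 min_support = min_support),
                   counts = counts)
    files <- list.files(out_dir, full.names = TRUE)
  }
  list(junctions = jn, discordants = dc, calls = calls, counts = counts,
       files = files)
}
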