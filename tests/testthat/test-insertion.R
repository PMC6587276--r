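test_that("a constructed chimeric read is resolved into TE and flank parts", {
  withr::with_seed(201, {
    genome <- c(chr = rand_dna(8000))
    te <- c(TE = rand_dna(1500))
  })
  flank <- substr(genome[[1]], 5001, 5030)        # 0-based [5000, 5030)
  read <- paste0(flank, substr(te[[1]], 1, 71))   # genome | TE 5' terminus
  jn <- find_junction_reads(c(j1 = read), te, genome)
  expect_equal(nrow(jn), 1L)
  expect_equal(jn$te_side, "5prime")
  expect_equal(jn$breakpoint_offset, 30L)
  expect_equal(jn$te_match_len, 71L)
  expect_equal(jn$flank_start, 5000L)
  expect_equal(jn$bp, 5030L)
  expect_equal(jn$genome_side, "left")
  # the same read in reverse complement gives the same breakpoint
  jn_rc <- find_junction_reads(c(j1 = revcomp(read)), te, genome)
  expect_equal(jn_rc$bp, 5030L)
  expect_equal(jn_rc$genome_side, "left")
  # a read entirely within the TE has no flank and is rejected
  inside <- substr(te[[1]], 301, 401)
  expect_equal(nrow(find_junction_reads(c(x = inside), te, genome)), 0L)
  # a plain genomic read is uniquely mappable and skipped
  plain <- substr(genome[[1]], 1001, 1101)
  expect_equal(nrow(find_junction_reads(c(y = plain), te, genome)), 0L)
})

test_that("detected junction reads equal the simulator truth without errors", {
  gs <- simulate_insertion_readset(seed = 211, coverage = 6, error_rate = 0)
  reads <- c(gs$mate1, gs$mate2)
  names(reads) <- c(names(gs$mate1), names(gs$mate2))
  jn <- find_junction_reads(reads, gs$te, gs$genome)
  expect_setequal(unique(jn$id), gs$truth$junction_ids)
})

test_that("discordant pairs are detected and equal the truth set", {
  withr::with_seed(221, {
    genome <- c(chr = rand_dna(9000))
    te <- c(TE = rand_dna(1500))
  })
  m1 <- c(p1 = substr(te[[1]], 1001, 1101),      # TE mate
          p2 = substr(genome[[1]], 2001, 2101))  # concordant-ish pair
  m2 <- c(p1 = revcomp(substr(genome[[1]], 4701, 4801)),
          p2 = revcomp(substr(genome[[1]], 2301, 2401)))
  dc <- find_discordant_pairs(m1, m2, te, genome)
  expect_equal(dc$pair_id, "p1")
  expect_equal(dc$te_mate, "1")
  expect_equal(dc$g_start, 4700L)
  expect_equal(dc$g_strand, "-")
  # implied window lies upstream of the reverse-strand genomic mate
  expect_equal(dc$window_hi, 4700L)
  expect_equal(dc$window_lo, 4700L - (350L + 100L))
  # simulator truth equality at zero error rate
  gs <- simulate_insertion_readset(seed = 222, coverage = 5, error_rate = 0)
  dc2 <- find_discordant_pairs(gs$mate1, gs$mate2, gs$te, gs$genome)
  expect_setequal(unique(dc2$pair_id), gs$truth$discordant_ids)
})

test_that("candidate calling reports breakpoint interval and TSD", {
  # two left-side junctions at 5030 and two right-side at 5026 -> TSD 4
  withr::with_seed(231, genome <- c(chr = rand_dna(6000)))
  jn <- data.frame(
    id = c("a", "b", "c", "d"),
    te_side = c("5prime", "5prime", "3prime", "3prime"),
    orientation = "fwd", te_match_len = 50L, breakpoint_offset = 50L,
    flank_seq = "x", contig = "chr",
    flank_start = c(4980L, 4975L, 5026L, 5026L),
    flank_end = c(5030L, 5030L, 5076L, 5080L),
    flank_strand = "+", flank_mm = 0L,
    bp = c(5030L, 5030L, 5026L, 5026L),
    genome_side = c("left", "left", "right", "right"),
    n_placements = 1L, stringsAsFactors = FALSE)
  calls <- call_insertions(jn, NULL, genome = genome)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$lo, 5026L)
  expect_equal(calls$hi, 5030L)
  expect_equal(calls$tsd_len, 4L)
  expect_equal(calls$tsd, substr(genome[[1]], 5027, 5030))
  expect_equal(calls$support_junction_5p, 2L)
  expect_equal(calls$support_junction_3p, 2L)
  # a single junction read does not reach min_support = 2
  expect_equal(nrow(call_insertions(jn[1, ], NULL, genome = genome)), 0L)
})

test_that("candidate annotation lists every overlapping interval", {
  ann <- GenomicRanges::GRanges(
    seqnames = "chr",
    ranges = IRanges::IRanges(start = c(1001, 2001), end = c(2000, 3000)),
    name = c("cluster9", "cluster10"))
  calls <- data.frame(contig = "chr", lo = c(1500L, 4000L, 1995L),
                      hi = c(1504L, 4004L, 2005L))
  out <- annotate_candidates(calls, ann)
  expect_equal(out$annotations,
               c("cluster9", "", "cluster9;cluster10"))
})

test_that("an insertion inside a 3-copy repeat yields one ambiguity group of 3", {
  site <- repeat_copy_site(copy = 2)
  gs <- simulate_insertion_readset(seed = 241, insertion_site = site)
  res <- run_insertion_pipeline(gs$mate1, gs$mate2, gs$genome, gs$te,
                                clusters = gs$clusters)
  calls <- res$calls
  expect_true(all(!is.na(calls$ambiguity_group)))
  expect_equal(length(unique(calls$ambiguity_group)), 1L)
  expect_equal(nrow(calls), 3L)
  # the true site is among the candidates, top-ranked by support
  expect_equal(calls$hi[1], site)
  expect_true(all(calls$hi %in% gs$truth$ambiguity_sites))
  expect_true(all(calls$annotations == "cluster_sim"))
})

test_that("candidate tables are byte-identical across repeated runs", {
  gs <- simulate_insertion_readset(seed = 251, coverage = 8)
  r1 <- run_insertion_pipeline(gs$mate1, gs$mate2, gs$genome, gs$te)
  r2 <- run_insertion_pipeline(gs$mate1, gs$mate2, gs$genome, gs$te)
  expect_identical(r1$calls, r2$calls)
})
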