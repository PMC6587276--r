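test_that("planted reads map at the expected coordinates and strands", {
  withr::with_seed(3, ref <- c(te = rand_dna(1000)))
  fwd <- substr(ref[[1]], 101, 126)          # 0-based [100, 126)
  rev <- revcomp(substr(ref[[1]], 85, 110))  # 0-based [84, 110) on minus
  rs <- read_set(data.frame(sequence = c(fwd, rev), count = 1))
  m <- map_reads(rs, ref, max_mismatches = 0)
  a <- m$alignments
  af <- a[a$sequence == fwd, ]
  expect_equal(unlist(af[, c("start", "end", "mismatches", "five_prime")]),
               c(start = 100, end = 126, mismatches = 0, five_prime = 100))
  expect_equal(af$strand, "+")
  ar <- a[a$sequence == rev, ]
  expect_equal(unlist(ar[, c("start", "end", "five_prime")]),
               c(start = 84, end = 110, five_prime = 109))
  expect_equal(ar$strand, "-")
})

test_that("pigeonhole mapping equals the brute-force scan at k = 0..3", {
  for (i in 1:6) {
    withr::with_seed(100 + i,
                     fx <- random_mapping_fixture(ref_len = 3000, n_reads = 60))
    for (k in 0:3) {
      expect_same_alignments(map_reads(fx$reads, fx$ref, k),
                             brute_force_map(fx$reads, fx$ref, k))
    }
  }
})

test_that("mapping agrees with Biostrings::matchPattern on both strands", {
  withr::with_seed(17, {
    ref <- c(g = rand_dna(2000))
    fx <- random_mapping_fixture(ref_len = 2000, n_reads = 15)
  })
  m <- map_reads(fx$reads, fx$ref, max_mismatches = 2)
  subj <- Biostrings::DNAString(fx$ref[[1]])
  for (s in fx$reads$reads$sequence) {
    fwd_hits <- Biostrings::matchPattern(s, subj, max.mismatch = 2,
                                         with.indels = FALSE)
    rev_hits <- Biostrings::matchPattern(revcomp(s), subj, max.mismatch = 2,
                                         with.indels = FALSE)
    a <- m$alignments[m$alignments$sequence == s, ]
    expect_setequal(a$start[a$strand == "+"],
                    Biostrings::start(fwd_hits) - 1L)
    expect_setequal(a$start[a$strand == "-"],
                    Biostrings::start(rev_hits) - 1L)
  }
})

test_that("strand symmetry: mapping revcomp(r) mirrors mapping r", {
  withr::with_seed(23, fx <- random_mapping_fixture(ref_len = 2000, n_reads = 40))
  m1 <- map_reads(fx$reads, fx$ref, 2)
  rc_rs <- read_set(data.frame(sequence = revcomp(fx$reads$reads$sequence),
                               count = fx$reads$reads$count))
  m2 <- map_reads(rc_rs, fx$ref, 2)
  key <- function(m, flip) {
    a <- m$alignments
    seqs <- if (flip) revcomp(a$sequence) else a$sequence
    strands <- if (flip) c("+" = "-", "-" = "+")[a$strand] else a$strand
    fp <- ifelse(strands == "+", a$start, a$end - 1L)
    sort(paste(seqs, a$start, strands, a$mismatches, fp))
  }
  expect_identical(key(m1, FALSE), key(m2, TRUE))
})

test_that("alignment sets are monotone in the mismatch threshold", {
  withr::with_seed(31, fx <- random_mapping_fixture(ref_len = 2500, n_reads = 50))
  key <- function(m) {
    a <- m$alignments
    paste(a$sequence, a$start, a$strand)
  }
  prev <- character(0)
  for (k in 0:3) {
    cur <- key(map_reads(fx$reads, fx$ref, k))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("uniqueness status distinguishes single- and multi-site reads", {
  withr::with_seed(41, {
    a <- rand_dna(400); b <- rand_dna(25); c_ <- rand_dna(400)
  })
  genome <- c(chr = paste0(a, b, c_, b, rand_dna(100)))
  uniq_read <- substr(a, 101, 126)
  multi_read <- b
  rs <- read_set(data.frame(sequence = c(uniq_read, multi_read), count = c(1, 5)))
  g0 <- genome_unique_status(rs, genome)
  st <- setNames(g0$status$status, g0$status$sequence)
  expect_equal(st[[uniq_read]], "unique")
  expect_equal(st[[multi_read]], "multi")
  expect_equal(g0$mapped_total, 6)
})

test_that("edge cases: long reads, N reads, empty references", {
  rs <- read_set(data.frame(sequence = strrep("ACGT", 20), count = 1))
  m <- map_reads(rs, c(short = "ACGTACGT"), 0)
  expect_equal(m$status$status, "unmapped")
  expect_equal(m$mapped_total, 0)
  rsN <- read_set(data.frame(sequence = paste0(strrep("A", 12), "N",
                                               strrep("C", 12)), count = 1))
  mN <- map_reads(rsN, c(r = strrep("AC", 200)), 3)
  expect_equal(mN$status$status, "unmapped")
  expect_error(map_reads(rs, character(0), 0), "empty reference")
})

test_that("best-placement reduction keeps one placement per read", {
  withr::with_seed(53, seg <- rand_dna(30))
  genome <- c(chr = paste0(rand_dna(100), seg, rand_dna(100), seg,
                           rand_dna(50)))
  rs <- read_set(data.frame(sequence = substr(seg, 3, 28), count = 2))
  m <- map_reads(rs, genome, 1, report = "all")
  expect_gte(nrow(m$alignments), 2L)
  pp <- primary_placements(m)
  expect_equal(nrow(pp), 1L)
  expect_equal(pp$start, min(m$alignments$start))  # lowest start wins ties
})
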