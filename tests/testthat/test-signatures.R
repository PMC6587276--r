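test_that("a single exact ping-pong pair gives p_10 = 1 and PPP = 100%", {
  aln <- rbind(aln_row(100, "+"), aln_row(109, "-"))
  h <- overlap_histogram(aln, ref_length = 300)
  expect_equal(unname(h$proportions[["10"]]), 1)
  expect_equal(sum(h$proportions), 1)
  expect_equal(h$pair_mass, 1)
  z <- pingpong_zscore(h)
  expect_true(is.na(z$z))          # degenerate all-zero background
  expect_false(z$significant)
  pp <- ppp_stats(aln, ref_length = 300)
  expect_equal(pp$ppp_percent_total, 100)
  expect_equal(pp$ppp_percent_sense, 100)
  expect_equal(pp$ppp_percent_antisense, 100)
})

test_that("one-strand libraries yield zero pair mass and zero PPP", {
  aln <- rbind(aln_row(10, "+"), aln_row(50, "+", count = 3))
  h <- suppressMessages(overlap_histogram(aln, ref_length = 200))
  expect_equal(h$pair_mass, 0)
  expect_true(all(h$proportions == 0))
  expect_true(is.na(pingpong_zscore(h)$z))
  expect_equal(ppp_stats(aln, ref_length = 200)$ppp_percent_total, 0)
})

test_that("a uniform overlap histogram has an undefined Z-score", {
  # one pair at every overlap length 1..23, equal weight
  rows <- list()
  for (k in 1:23) {
    rows[[length(rows) + 1L]] <- aln_row(200L * k, "+")
    rows[[length(rows) + 1L]] <- aln_row(200L * k + k - 1L, "-")
  }
  h <- overlap_histogram(do.call(rbind, rows), ref_length = 5000)
  expect_true(all(abs(h$proportions[1:23] - 1 / 23) < 1e-12))
  z <- pingpong_zscore(h, include_self = TRUE)
  expect_true(is.na(z$z))
  expect_false(z$significant)
})

test_that("Z-score matches a hand computation on a graded fixture", {
  # pair weight k at overlap k (k != 10), weight 100 at overlap 10
  rows <- list()
  for (k in 1:23) {
    w <- if (k == 10L) 100L else k
    rows[[length(rows) + 1L]] <- aln_row(200L * k, "+")
    rows[[length(rows) + 1L]] <- aln_row(200L * k + k - 1L, "-", count = w)
  }
  h <- overlap_histogram(do.call(rbind, rows), ref_length = 5000)
  w <- c(1:9, 100, 11:23)
  p <- w / sum(w)
  b <- p[-10]
  mb <- sum(b) / 22
  sdb <- sqrt(sum((b - mb)^2) / 21)
  z_hand <- (p[10] - mb) / sdb
  z <- pingpong_zscore(h)
  expect_equal(unname(z$z), z_hand, tolerance = 1e-12)
  expect_true(z$significant)
  # with the tested length kept in the background
  b2 <- p[1:23]
  z2_hand <- (p[10] - mean(b2)) / stats::sd(b2)
  expect_equal(unname(pingpong_zscore(h, include_self = TRUE)$z), z2_hand,
               tolerance = 1e-12)
})

test_that("histogram and PPP match all-pairs enumeration on simulated data", {
  sim <- simulate_pirna_library(seed = 13, n_antisense_primary = 120,
                                f_pp = 0.4, n_background_sense = 40,
                                n_background_antisense = 40, te_length = 2000)
  tm <- map_reads(sim_read_set(sim), sim$te, 3, report = "best")
  aln <- primary_placements(tm)
  h <- overlap_histogram(aln, ref_length = 2000)
  expect_equal(unname(h$proportions), oracle_overlap_histogram(aln),
               tolerance = 1e-12)
  expect_true(h$proportions[["10"]] == max(h$proportions))
  expect_equal(sum(h$proportions), 1)
  pp <- ppp_stats(aln, ref_length = 2000)
  expect_equal(pp$ppp_percent_total, oracle_ppp_percent(aln),
               tolerance = 1e-12)
})

test_that("count weighting and distinct-pair weighting differ as configured", {
  aln <- rbind(aln_row(100, "+", count = 9), aln_row(109, "-", count = 1),
               aln_row(300, "+", count = 1), aln_row(304, "-", count = 1))
  h_w <- overlap_histogram(aln, ref_length = 500)
  h_d <- overlap_histogram(aln, ref_length = 500, distinct_pairs = TRUE)
  expect_equal(unname(h_w$proportions[["10"]]), 0.9)
  expect_equal(unname(h_d$proportions[["10"]]), 0.5)
})

test_that("nucleotide bias reports 1U/10A and normalized rows", {
  aln <- rbind(
    aln_row(100, "-", count = 3, sequence = paste0("T", strrep("G", 24))),
    aln_row(140, "-", count = 1, sequence = paste0("T", strrep("C", 24))))
  nb <- nucleotide_bias(aln, ref_length = 400, subset = "all")
  expect_equal(nb$bias_1U, 100)
  expect_true(all(abs(rowSums(nb$matrix) - 1) < 1e-12))
  # equal masses of each starting base
  aln2 <- do.call(rbind, lapply(c("A", "C", "G", "T"), function(b)
    aln_row(100, "+", count = 2, sequence = paste0(b, strrep("A", 22)))))
  nb2 <- nucleotide_bias(aln2, ref_length = 400)
  expect_equal(unname(nb2$matrix[1, ]), rep(0.25, 4))
  expect_equal(nb2$bias_10A, 100)
})

test_that("simulated 1U bias is recovered within sampling error", {
  sim <- simulate_pirna_library(seed = 29, n_antisense_primary = 10000,
                                f_pp = 0, p1U = 0.9,
                                n_background_sense = 0,
                                n_background_antisense = 0)
  tm <- map_reads(sim_read_set(sim), sim$te, 3, report = "best")
  nb <- nucleotide_bias(primary_placements(tm), ref_length = 8400)
  expect_lt(abs(nb$bias_1U - 90), 3)
})

test_that("density profiles conserve mass and honour window presets", {
  # single read, count 1, denominator one million -> 1 RPM in its window
  aln <- aln_row(250, "+")
  pr <- density_profile(aln, window_size = 100, normalization_total = 1e6,
                        ref_length = 1000)
  expect_equal(nrow(pr$windows), 10L)
  expect_equal(pr$windows$sense_rpm[3], 1.0)
  expect_equal(sum(pr$windows$sense_rpm) + sum(pr$windows$antisense_rpm), 1.0)
  # window covering the whole target
  pr1 <- density_profile(aln, window_size = 1000, normalization_total = 1e6,
                         ref_length = 1000)
  expect_equal(nrow(pr1$windows), 1L)
  # ZAM-sized target with the ZAM preset
  sim <- simulate_pirna_library(seed = 37, n_antisense_primary = 400,
                                f_pp = 0.4, n_background_sense = 50,
                                n_background_antisense = 50)
  aln2 <- primary_placements(map_reads(sim_read_set(sim), sim$te, 3,
                                       report = "best"))
  pr2 <- density_profile(aln2, window_size = window_presets[["ZAM"]],
                         normalization_total = 12345, ref_length = 8400)
  expect_equal(nrow(pr2$windows), 93L)
  mass <- sum(pr2$windows$sense_rpm + pr2$windows$antisense_rpm) * 12345 / 1e6
  expect_equal(mass, sum(aln2$count), tolerance = 1e-9)
  # direct per-window tally
  tal <- tapply(aln2$count[aln2$strand == "+"],
                aln2$five_prime[aln2$strand == "+"] %/% 91 + 1, sum)
  got <- pr2$windows$sense_rpm * 12345 / 1e6
  expect_equal(got[as.integer(names(tal))], as.vector(tal), tolerance = 1e-9)
})

test_that("cluster composition splits unique read mass by interval", {
  withr::with_seed(61, genome <- c(chr = rand_dna(10000)))
  clusters <- GenomicRanges::GRanges(
    seqnames = "chr",
    ranges = IRanges::IRanges(start = c(1001, 5001), end = c(2000, 6000)),
    name = c("clusterA", "clusterB"))
  # 39 reads x2 copies from A, 11 x2 from B: shares 0.78 / 0.22
  pos_a <- seq(1010, 1970, length.out = 39)
  pos_b <- seq(5010, 5900, length.out = 11)
  seqs <- substring(genome[[1]], c(pos_a, pos_b), c(pos_a, pos_b) + 24)
  rs <- read_set(data.frame(sequence = seqs, count = 2))
  g0 <- genome_unique_status(rs, genome)
  comp <- cluster_composition(g0, clusters)
  expect_equal(comp$share[comp$cluster == "clusterA"], 0.78, tolerance = 1e-9)
  expect_equal(comp$share[comp$cluster == "clusterB"], 0.22, tolerance = 1e-9)
  expect_equal(sum(comp$share), 1)
  # all reads in one interval
  rs1 <- read_set(data.frame(sequence = seqs[1:10], count = 1))
  comp1 <- cluster_composition(genome_unique_status(rs1, genome), clusters)
  expect_equal(comp1$share[comp1$cluster == "clusterA"], 1)
  # a non-zero-mismatch mapping is rejected
  m3 <- map_reads(rs1, genome, 3)
  expect_error(cluster_composition(m3, clusters), "zero-mismatch")
  expect_error(cluster_composition(g0, GenomicRanges::GRanges()), "empty")
})
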