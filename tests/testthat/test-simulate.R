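test_that("forced ping-pong with no background gives 100% partnership", {
  sim <- simulate_pirna_library(seed = 71, n_antisense_primary = 10,
                                f_pp = 1, p1U = 1, p10A = 1,
                                n_background_sense = 0,
                                n_background_antisense = 0)
  tr <- sim$records
  expect_true(all(tr$ppp_realized))
  # every secondary's 10th base pairs with a forced-1U primary
  sec <- tr[tr$origin == "secondary", ]
  expect_equal(nrow(sec), 10L)
  expect_true(all(substr(sec$sequence, 10, 10) == "A"))
  expect_true(all(substr(tr$sequence[tr$origin == "primary"], 1, 1) == "T"))
  pp <- ppp_stats(primary_placements(
    map_reads(sim_read_set(sim), sim$te, 3, report = "best")),
    ref_length = 8400)
  expect_equal(pp$ppp_percent_total, 100)
})

test_that("f_pp = 0 emits no secondary reads", {
  sim <- simulate_pirna_library(seed = 73, n_antisense_primary = 200, f_pp = 0,
                                n_background_sense = 50,
                                n_background_antisense = 50)
  expect_equal(sum(sim$records$origin == "secondary"), 0L)
})

test_that("realized ping-pong fraction tracks f_pp within sampling error", {
  sim <- simulate_pirna_library(seed = 7, n_antisense_primary = 3000,
                                f_pp = 0.4, n_background_sense = 100,
                                n_background_antisense = 100)
  n_sec <- sum(sim$records$origin == "secondary")
  # binomial(3000, 0.4): 3 sd ~ 0.027
  expect_lt(abs(n_sec / 3000 - 0.4), 0.03)
})

test_that("library simulation is reproducible byte for byte", {
  s1 <- simulate_pirna_library(seed = 99, n_antisense_primary = 100, f_pp = 0.3)
  s2 <- simulate_pirna_library(seed = 99, n_antisense_primary = 100, f_pp = 0.3)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$genome, s2$genome)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  p1 <- write_library(s1, d1); p2 <- write_library(s2, d2)
  for (k in names(p1)) {
    expect_identical(unname(tools::md5sum(p1[[k]])),
                     unname(tools::md5sum(p2[[k]])))
  }
  s3 <- simulate_pirna_library(seed = 100, n_antisense_primary = 100, f_pp = 0.3)
  expect_false(identical(s1$records$sequence, s3$records$sequence))
})

test_that("read emission matches configured totals and coverage", {
  sim <- simulate_pirna_library(seed = 81, n_antisense_primary = 150, f_pp = 0,
                                n_background_sense = 30,
                                n_background_antisense = 20)
  expect_equal(nrow(sim$records), 200L)
  gs <- simulate_insertion_readset(seed = 82, coverage = 5)
  donor_len <- gs$config$genome_length + gs$config$te_length +
    gs$config$tsd_length
  expect_lte(abs(length(gs$mate1) - 5 * donor_len / (2 * 101)), 1)
  expect_equal(names(gs$mate1), names(gs$mate2))
})

test_that("the donor carries the TSD and junction truth is genuine", {
  gs <- simulate_insertion_readset(seed = 83, coverage = 4, error_rate = 0,
                                   tsd_length = 4)
  expect_equal(nchar(gs$truth$tsd), 4L)
  s <- gs$truth$site
  expect_equal(gs$truth$tsd, substr(gs$genome[[1]], s - 3, s))
  # every truth junction read contains a TE terminus joined to genome sequence
  te <- gs$te[[1]]
  te5 <- substr(te, 1, 20); te3 <- substr(te, nchar(te) - 19, nchar(te))
  for (id in gs$truth$junction_ids) {
    reads <- c(gs$mate1[[id]], gs$mate2[[id]], revcomp(gs$mate1[[id]]),
               revcomp(gs$mate2[[id]]))
    hit <- any(vapply(reads, function(r)
      grepl(te5, r, fixed = TRUE) || grepl(te3, r, fixed = TRUE), logical(1)))
    expect_true(hit)
  }
  # tsd_length = 0 plants no duplication
  gs0 <- simulate_insertion_readset(seed = 84, coverage = 2, tsd_length = 0)
  expect_equal(gs0$truth$tsd, "")
})

test_that("an insertion in a repeat copy lists all homologous coordinates", {
  site <- repeat_copy_site(copy = 2)
  gs <- simulate_insertion_readset(seed = 85, insertion_site = site,
                                   coverage = 2)
  expect_equal(length(gs$truth$ambiguity_sites), 3L)
  expect_true(site %in% gs$truth$ambiguity_sites)
  off <- site - repeat_copy_site(copy = 2, offset = 0)
  expect_equal(gs$truth$ambiguity_sites,
               sort(vapply(1:3, function(k)
                 repeat_copy_site(copy = k, offset = off), integer(1))))
})

test_that("insertion sites near contig ends are rejected", {
  expect_error(simulate_insertion_readset(seed = 86, insertion_site = 50),
               "contig end")
})
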