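# Fixture builders shared across tests. All randomness is locally seeded.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a random reference plus reads that are (possibly mutated) substrings of it,
# mixed with fully random reads
random_mapping_fixture <- function(ref_len = 5000L, n_reads = 100L,
                                   read_lens = 18:30, n_mut = 0:3) {
  ref <- c(ref1 = rand_dna(ref_len))
  seqs <- character(n_reads)
  for (i in seq_len(n_reads)) {
    L <- sample(read_lens, 1L)
    if (i %% 4L == 0L) {
      seqs[i] <- rand_dna(L)  # mostly unmappable
    } else {
      st <- sample.int(ref_len - L + 1L, 1L)
      s <- substr(ref[[1L]], st, st + L - 1L)
      k <- sample(n_mut, 1L)
      if (k > 0L) {
        ch <- strsplit(s, "")[[1L]]
        pos <- sample.int(L, k)
        ch[pos] <- vapply(ch[pos], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
        s <- paste(ch, collapse = "")
      }
      if (i %% 2L == 0L) s <- revcomp(s)
      seqs[i] <- s
    }
  }
  counts <- sample(1:4, n_reads, replace = TRUE)
  list(ref = ref,
       reads = read_set(data.frame(sequence = seqs, count = counts)))
}

# write a FASTQ with constant qualities
write_fastq <- function(seqs, path, ids = sprintf("r%04d", seq_along(seqs))) {
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n",
                    strrep("I", nchar(seqs))), path)
  path
}

# alignment row constructor for signature-level fixtures (one reference)
aln_row <- function(five_prime, strand, count = 1, len = 25,
                    reference = "TE", sequence = NULL) {
  if (is.null(sequence)) sequence <- strrep("A", len)
  start <- ifelse(strand == "+", five_prime, five_prime - len + 1L)
  data.frame(sequence = sequence, reference = reference,
             start = start, end = start + len, strand = strand,
             mismatches = 0L, five_prime = five_prime, count = count,
             stringsAsFactors = FALSE)
}

# O(n^2) oracle: overlap histogram by enumerating every sense/antisense pair
oracle_overlap_histogram <- function(aln, k_max = 28L) {
  s <- aln[aln$strand == "+", , drop = FALSE]
  a <- aln[aln$strand == "-", , drop = FALSE]
  w <- numeric(k_max)
  for (i in seq_len(nrow(s))) {
    for (j in seq_len(nrow(a))) {
      k <- a$five_prime[j] - s$five_prime[i] + 1L
      if (k >= 1L && k <= k_max) w[k] <- w[k] + s$count[i] * a$count[j]
    }
  }
  if (sum(w) > 0) w / sum(w) else w
}

# O(n^2) oracle: count-weighted ping-pong-partner percentage
oracle_ppp_percent <- function(aln, overlap = 10L) {
  member <- logical(nrow(aln))
  for (i in seq_len(nrow(aln))) {
    for (j in seq_len(nrow(aln))) {
      if (aln$strand[i] == aln$strand[j]) next
      k <- if (aln$strand[i] == "+") aln$five_prime[j] - aln$five_prime[i] + 1L
           else aln$five_prime[i] - aln$five_prime[j] + 1L
      if (k == overlap) { member[i] <- TRUE; break }
    }
  }
  100 * sum(aln$count[member]) / sum(aln$count)
}

expect_same_alignments <- function(a, b) {
  key <- function(x) {
    x <- x$alignments
    sort(paste(x$sequence, x$reference, x$start, x$strand, x$mismatches))
  }
  expect_identical(key(a), key(b))
}
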