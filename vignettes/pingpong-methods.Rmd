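---
title: "Ping-pong signatures and transposon insertion detection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ping-pong signatures and transposon insertion detection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pingpongr)
```

## Scope and model

`pingpongr` implements the small-RNA analyses used to characterise
transposable-element (TE) silencing by PIWI-interacting RNAs (piRNAs) in the
*Drosophila* ovary, together with a paired-end DNA approach for locating
non-reference TE insertions inside repetitive piRNA clusters. The biological
model is the ping-pong amplification cycle: in germline cells, an antisense
piRNA bound to Aub cleaves a sense TE transcript and thereby generates a
sense piRNA whose 5' end lies exactly 10 nt inside the antisense piRNA's 5'
end; the sense piRNA reciprocally generates antisense piRNAs. The cycle
leaves three measurable marks on a TE-derived piRNA population:

* an excess of sense/antisense read pairs with an exact 10-nt 5' overlap;
* a uridine bias at position 1 (1U) of primary (mostly antisense) piRNAs;
* an adenine bias at position 10 (10A) of secondary (sense) piRNAs, which is
  the Watson-Crick shadow of the partner's 1U across the 10-nt overlap.

## Statistics

**Overlap histogram.** For all reads mapped to one TE consensus (gap-free,
up to 3 mismatches, each read counted once at its best placement), every
(sense, antisense) pair contributes `count(sense) * count(antisense)` to the
overlap length `five_prime(antisense) - five_prime(sense) + 1`. Proportions
`p_k` are tabulated for `k = 1..28` and normalised over the contributing
pair mass.

**Z-score.** `z = (p_10 - mean(B)) / sd(B)` with background
`B = {p_k : k in 1..23, k != 10}` and the sample (n-1) standard deviation;
`z > 1.96` is called significant. Design choices here were genuinely open:
whether the tested length belongs to the background, and which standard
deviation to use. Excluding `k = 10` is the default because including the
tested value inflates the background spread and deflates the score; both
behaviours are available (`include_self`, `sd_type`). When `sd(B) = 0`
(no overlapping pairs, or a degenerate single-pair/uniform histogram) the
score is reported as `NA` and not significant rather than infinite.

**Ping-pong partners (PPP).** A read is a partner iff at least one
opposite-strand read overlaps its 5' end by exactly 10 nt. Percentages are
count-weighted by default; per-distinct-sequence percentages are reported
alongside because published bar plots do not always state the weighting.

**Nucleotide bias.** Count-weighted base frequencies over the first 10
positions of each read in its sequenced orientation; `bias_1U` and
`bias_10A` are the position-1 T and position-10 A percentages. The
biologically interpretable subsets are antisense partners for 1U and sense
partners for 10A.

**Density profiles.** Reads are assigned to fixed windows by their 5'-end
coordinate and window masses are scaled to reads per million (RPM) using the
zero-mismatch genome-mapped mass of the whole post-depletion 18-30 nt
library as denominator. The denominator deliberately precedes the 23-29 nt
piRNA size selection, so that libraries with different size compositions
remain comparable; it is configurable. Window presets follow the
conventional per-TE values (`window_presets`: flamenco 428 nt, ZAM 91 nt,
Burdock 80 nt, Pifo 87 nt, Phidippo 85 nt). No generating rule for these
values is published beyond being "dependent on TE size", so the window is a
required parameter with those names as presets. Assignment by 5' end (not
read span) makes mass conservation exact:
`sum(RPM) * denominator / 1e6` equals the profiled read mass.

**Cluster composition.** Genome-unique zero-mismatch piRNAs are assigned to
annotated cluster intervals by >= 1 bp overlap; a read overlapping two
intervals goes to the larger overlap (ties to the first interval in
annotation order, logged). Shares are reported over the cluster-assigned
mass, with an optional explicit `unassigned` bucket.

## The mapper

Mapping is full-length, gap-free Hamming matching on both strands —
substitutions only, the standard convention for 23-29 nt reads, since indel
alignment would silently change every downstream statistic. The production
path uses pigeonhole seeding (`max_mismatches + 1` disjoint seeds,
exact-matched through a reference k-mer index, candidates verified by full
comparison), which is lossless for substitution-only search. A naive
brute-force scan over every offset (`brute_force_map()`) is kept as an
independent reference implementation, and the test suite additionally
cross-checks placements against `Biostrings::matchPattern`. An `N` never
matches, even against another `N`; reads containing `N` are retained in
library accounting but never mapped. Multi-mapping reads contribute their
full copy number once, at their best placement (fewest mismatches, then
lowest start, then plus strand) — published methods do not state how
multi-mappers are counted on a TE consensus, and this rule prevents
double-counting in density profiles.

## Insertion detection

Two complementary evidence types locate a non-reference TE insertion:

* **Junction (chimeric) reads.** Reads without a unique full-length
  zero-mismatch genome placement are scanned for a prefix/suffix of at least
  20 nt matching the TE consensus anchored at either terminus (at most 1
  mismatch), in either orientation, with a genomic flank of at least 20 nt.
  The TE portion is stripped and every gap-free flank placement (at most 1
  mismatch) is reported, each implying a breakpoint coordinate and a side
  (genome left/right of the insertion). Published descriptions of this
  strategy give no match lengths or tolerances; all are exposed parameters
  with these defaults.
* **Discordant pairs.** Pairs with one mate full-length on the TE and the
  other full-length on the genome; the genomic mate's interval extended by
  the insert-size prior (mean + 2 sd; supplied, defaults 350/50) implies an
  insertion window.

Evidence is clustered per contig at a 500 bp single-linkage distance. The
modal left-side and right-side junction coordinates define the breakpoint
interval; when the left coordinate exceeds the right by 1-20 bp the
intervening reference bases are reported as the target-site duplication
(TSD). Modal (not extreme) coordinates make the interval robust to the
occasional mismapped flank. In repeat context a junction flank or a
discordant genomic mate maps to several copies, so the same reads support
several clusters; the caller keeps every placement (not just the best one)
precisely because the homologous positions are genuine alternative
insertion sites, and candidates sharing supporting junction reads or
discordant pairs are linked into one `ambiguity_group` by connected
components. Identical-evidence grouping would be too strict — with 2%
per-copy repeat divergence (about 4% pairwise) and a 1-mismatch flank
budget, short flanks often map to a strict subset of copies — while
shared-evidence components reliably reproduce the expected "one true site
among its homologous copies" structure. No de-novo breakpoint assembly is attempted, and candidate
ranking is by total support with `min_support = 2` by default.

## The simulators

**piRNA library.** Antisense primaries are drawn along a random TE
consensus; with probability `p1U` a primary's 5' position is drawn from
positions whose antisense base is T. Realising the 1U bias by *position
selection* rather than by mutating the read keeps every simulated read an
exact genome substring, so reads stay zero-mismatch genome-mappable — which
the RPM denominator and cluster composition require. Each primary receives,
with probability `f_pp`, a sense partner at the exact 10-nt overlap; the
partner's 10th base is the complement of the primary's first base, so the
realised 10A rate is mechanistically coupled to `p1U` exactly as in the
ping-pong cycle (the simulator validates `p10A == p1U`). Background reads
with uniform 5' positions are emitted on both strands and may create chance
10-nt overlaps; the truth record therefore stores *realised* partnership,
recomputed from the emitted positions, and tests compare against that truth
rather than nominal `f_pp`. Copy numbers are geometric (mean 2), lengths
uniform over 23-29 nt, and the genome embeds the TE in a host cluster with
a decoy cluster nearby.

Two systematic effects of this design are worth knowing when reading
estimates. First, the uniform background (default 150 reads per strand
against 3350 primaries, about 4% per strand — a realistic contamination
level for a TE-mapped population) dilutes the all-antisense 1U estimate by
about 2.8 points below the nominal 90%. Second, because 1U primaries are
confined to the TE's "A" positions (about a quarter of the sequence), they
collide on positions more often and therefore share partners more often, so
the partnered-antisense subset is 1U-*enriched* (about 93%). Both estimators
recover their own realised truth to machine precision; which population to
quote depends on the question being asked.

**Insertion readset.** A random reference genome receives a planted repeat
family (default 3 copies, 600 nt, 2% divergence). The donor haplotype is
`G[0, site) + TE + G[site - tsd, end)`, duplicating the `tsd` bases on both
sides of the TE. Illumina-like pairs (101 bp, insert 350 +/- 50, uniform
substitution errors at 0.001) are sampled at the requested coverage. Truth
lists the site, the TSD string, every junction-spanning read (>= 20 nt on
each side), every truly discordant pair, and — when the site falls inside a
repeat copy — the homologous coordinates in the other copies.

What the simulators do *not* emulate: adapter read-through, quality decay,
PCR duplicates, transcription-level precursor structure, indel errors, and
genome-wide repeat landscapes beyond the planted family. Passing tests
therefore demonstrate correctness of the statistics and the caller under the
stated generative model, not end-to-end performance on real sequencing data.

## Numerical and degenerate-input choices

* All internal arithmetic is double precision; percentages are rounded to
  one decimal only in written reports.
* Empty inputs degrade explicitly: zero pair mass flags the histogram and
  yields `NA` Z; empty read subsets yield an `NA` frequency matrix with a
  warning; an empty junction set yields zero candidates and exit status 0.
* Exact-substring contaminant depletion (e.g. 2S rRNA) uses no mismatch
  tolerance: no published tolerance exists, and exactness is reproducible.
* All simulator randomness runs through `withr::with_seed`, so identical
  configurations and seeds give byte-identical FASTQ/FASTA/BED/truth files
  and reports.

## Problem sizes used in the test suite

The suite validates the mapper on 50 random fixtures (references 2-10 kb,
100-500 reads, 0-3 mismatches) against the brute-force scan; Z-score
calibration on 100 null libraries of 2,000 background reads (observed
false-positive rate about 5% at the nominal 2.5%, bounded at 10%); power and
recovery on 100 libraries of about 5,000 reads at `f_pp = 0.4`; and
insertion recovery on 50 replicates at 15x coverage over a 20 kb genome,
plus 20 TE-free replicates for false calls. These sizes give stable
pass/fail behaviour at desk scale while exercising every code path; the
published analyses themselves run on deposited sequencing libraries and a
full genome, which this package can process but the test suite does not
download.
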