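---
title: "Discovering centromere islands from CENP-A ChIP-seq: models and methods"
author: "cenisland"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering centromere islands from CENP-A ChIP-seq: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In many genomes the functional centromere — the chromatin domain marked
by the histone H3 variant CENP-A — sits inside megabase-scale fields of
simple tandem satellite DNA. Short reads from satellite arrays map
everywhere and nowhere, so conventional peak calling cannot say *where*
within the satellite sea the centromere lives. The island model offers a
way in: candidate centromeres are "islands" of complex DNA — mostly
retroelement copies, with one family recurring at every centromere —
embedded in the satellite arrays. Complex DNA is mappable, so CENP-A
enrichment over islands can be measured even when the flanking arrays
cannot be resolved.

`cenisland` implements this strategy as four complementary ChIP-seq
analyses plus supporting Hi-C, chromatin-fiber and qPCR modules, and —
because the approach is easy to fool — a seeded synthetic-data generator
that plants islands with known ground truth so every stage is tested end
to end.

## The synthetic study design

`default_genome_spec()` builds a ~2.4 Mb genome: five island contigs
(a 9–12 kb island of retroelement copies flanked on both sides by
12–14 kb satellite arrays) and twenty decoy contigs that contain
satellites and element copies but never a satellite-flanked island.
Five satellite families flank islands (`AATAT`, `AAGAG`, `AAGAT`,
`AATAG` and a 12-bp unit, `satXII`); a sixth (`AATAC`) is planted only
on decoys and receives no ChIP enrichment — the negative control for the
k-mer analysis. One element family (`retroA`) occurs in every island
and keeps roughly two thirds of its copies there, emulating a
retroelement family concentrated at centromeres; other families are
mostly non-centromeric. Decoy satellite amounts are chosen so each
flanking family keeps roughly 30–40% of its genomic copies at island
flanks; with the island/flank/background occupancy weights below this
places every flanking family's normalized ChIP/input ratio above 1 and
the control's below 1 — the planted truth the recovery tests assert.

Element copies are drawn from a per-family consensus with 5% per-copy
substitution divergence (as real transposon insertions diverge) and a
fraction (default 0.4) are 5'-truncated, keeping the 3' end as non-LTR
retroelement insertions do. The divergence is load-bearing: it is what
makes island reads uniquely placeable and assembled contigs uniquely
projectable, while the exact-repeat satellite arrays remain ambiguous —
the synthetic analog of a mapping-quality filter.

Read simulation (`simulate_chip_reads()`) draws paired-end fragments
with start probability proportional to a per-region occupancy weight:
islands 10, flanking satellites 3, everything else (including the
control satellite) 1. Input channels are uniform. Defaults are 4
replicates, 150 bp reads, 300 bp fragments, 30-fold coverage per
channel. Reads are error-free by default (`error_rate` is a parameter):
the object under test is the enrichment logic, not aligner robustness.
The true CENP-A occupancy over flanking satellite arrays is unknown in
real genomes, so the flank weight is a free simulation parameter, not a
claim about biology.

What the generator deliberately does **not** model: sequencing errors
and quality scores, PCR library chemistry, restriction-site-aware Hi-C
fragments, and assembly errors in the reference. Passing tests
therefore demonstrate that the statistical machinery recovers planted
structure under clean sampling noise — not that it is robust to every
artifact of real libraries.

## Approach 1: tandem k-mer enrichment (`count_kmers`, `kmer_enrichment`)

Reads are scanned for maximal tandem runs of units up to 20 bp. A run
must contain at least 3 whole unit copies (inside a 150-bp read this
also bounds the usable unit length); it is attributed to its primitive
unit (an `AAAA…` stretch is an `A` run, never `AA`), and overlapping
runs of different units are resolved longest-span-first. Counts are
aggregated by the canonical unit — the lexicographic minimum over all
rotations of the unit and of its reverse complement — so any phase and
either strand of an array count together. The per-replicate ratio is
`(chip count / chip mapped total) / (input count / input mapped total)`
and a unit is called enriched when the input count is at least 10 in
every replicate and the median ratio across replicates exceeds 1 (the
median of four is the mean of the middle two). The detector is verified
against an independent brute-force scanner on thousands of random
reads; the minimum-copy and canonicalization conventions are this
package's documented choices, validated only against that oracle.

## Approach 2: repeat-library assignment (`assign_reads`, `family_enrichment`)

Each read is scored against every family consensus on both strands by
its best ungapped alignment over exact 20-mer seed candidates; bases
hanging off a consensus end count as mismatches, and the default
tolerance is 4% of the read length. A read tied between two or more
families is ambiguous; ambiguous reads are excluded from family counts
but counted in totals (mimicking quality-filtered unique mapping).
Satellite units are internally expanded into arrays longer than the
read so every repeat phase aligns. A family is called enriched when its
normalized ratio ranks strictly above the 80th percentile among all
scored families in **every** replicate; tied ratios share the mean rank
and boundary ties are conservatively not enriched. The ranking universe
(all families vs. complex repeats only) is exposed as the `universe`
argument and defaults to all families scored.
`consensus_profile()` reports per-position chip/input depth ratios from
uniquely assigned reads only, masking positions whose input depth falls
below a floor (default 5 reads — a stability choice, since a ratio over
a near-zero denominator is noise).

## Approach 3: ChIPtigs (`assemble_chiptigs`, `chiptig_enrichment`, `place_chiptigs`)

ChIP reads are assembled without a reference on a de Bruijn graph of
canonical 31-mers with multiplicity ≥ 3; maximal non-branching paths
become contigs and short tips (< 2k with a single dead end) are
clipped. No bubble popping or error correction is attempted — synthetic
reads are error-free, and assembly correctness is property-tested
(exact reconstruction of repeat-free sources, idempotence) rather than
benchmark-chased. Reads can be deterministically subsampled first; the
end-to-end driver assembles 120,000 reads per replicate, which keeps
island k-mer coverage high while bounding graph size.

Enrichment is computed post hoc: ChIP and input reads are assigned back
to the ChIPtigs with the same seeded matcher and the Poisson peak
caller below runs with each ChIPtig as a contig. ChIPtigs are then
projected onto the assembly by seed-and-extend; a placement is unique
when its score strictly exceeds the best score at any other locus, and
placements below 95% identity or 90% query coverage are discarded (the
analog of removing potentially misassembled contigs; both floors are
parameters). The headline summary takes the top-N significant ChIPtigs
by strongest signal (largest peak fold enrichment) and reports the
fraction that place uniquely within candidate contigs; non-unique
placements never count toward the numerator. Projected intervals are
reported as-is, without any post-projection adjustment of peak regions.

## Approach 4: peak calling and candidate classification

`build_coverage()` turns fragment placements into per-base pileups
after masking duplicate fragments (identical contig and start) and
dropping non-uniquely placeable fragments — in synthetic space, a
fragment is uniquely placeable when it overlaps at least 20 bp of
non-satellite sequence.

`call_peaks()` is a Poisson scan with a local background: the input
track is scaled to the ChIP total, and the rate at each base is the
maximum of the scaled input mean over 1 kb, 5 kb and 10 kb centred
windows, the contig mean, and the collection-wide mean. Per-base
upper-tail Poisson p-values are corrected by Benjamini–Hochberg over
all bases exceeding their local background; significant bases within
one fragment length merge into peaks, and peaks narrower than one
fragment length are discarded. Two of these rules deserve comment.
The collection-wide floor matters when the "contigs" are short de novo
assemblies: a 200-bp contig that happens to catch no input reads would
otherwise earn an unbounded fold enrichment from the pseudocount alone.
The minimum width matters because base-level BH is a base-level
guarantee: once a true peak occupies the top thousand ranks, isolated
single-base noise spikes can slip under the adjusted threshold; a real
fragment pileup is never one base wide, so the width rule removes
exactly the artifacts. Fold enrichment is reported at the summit with a
pseudocount of 0.1.

Quality control uses strand cross-correlation
(`cross_correlation()`): one read per fragment, split by strand, and
the profile at shift d is the observed/expected coincidence ratio of
plus-strand 5' ends at x with minus-strand 5' ends at x + d. This
ratio is a monotone transform of the Pearson correlation of the two
count vectors with the practical advantage that its null value is 1 —
a raw Pearson profile under uniform sampling fluctuates around 0, and a
peak-to-background ratio of two near-zero numbers is unstable. The
fragment-length estimate is the profile argmax outside a ±10 bp
exclusion zone around the read length (the phantom peak); NSC is the
fragment-length peak over the profile minimum and RSC is the
fragment-length peak over the read-length value, the peak-ratio
definitions. With only one strand present the profile is returned but
NSC/RSC are flagged undefined.

Reproducibility replaces a full irreproducible-discovery-rate analysis
with a transparent surrogate serving the same role: a peak is
reproducible when it overlaps a peak in every other replicate, and the
Spearman correlation of log fold enrichment over matched peaks is
reported per replicate pair. `detect_islands()` finds maximal runs of
non-satellite annotation (≥ 1 kb by default, tolerating internal
satellite interruptions ≤ 2 kb — real islands range from under 2 kb to
over 100 kb, so both bounds are exposed parameters, not claims) and
records each side's flanking satellite family or the contig edge
(an island can fill its whole contig). `classify_candidates()` scores
each island by the fraction of its bases covered by reproducible peaks,
calls islands above 0.25 coverage candidates, ranks by coverage, and
flags whether at least one flanking satellite unit was itself called
enriched by the k-mer rule. Candidate scoring deliberately uses island
bases only — assembly-space evidence inside simple satellite arrays is
not trusted.

## Hi-C category statistics

Valid pairs are located in a category map (centromere, proximal
heterochromatin, distal heterochromatin, euchromatin). Each pair
increments one symmetric category-pair cell; in addition every pair
with an end in a centromere credits that centromere unit's (unit,
partner-category) cell — a centromere–centromere pair credits both
units, so each unit's values describe its own contacts. Counts are
normalized to region sizes per 100 kb as `N × (10^5)^2 / (L_A × L_B)`
(an additive `N × 10^5 / (L_A + L_B)` variant is selectable); for
per-unit cells `L_A` is the unit's own length and `L_B` the partner
category's total length, including the unit itself when the partner is
its own category — the crediting rule counts ordered ends (a
within-unit pair credits both ends), whose expectation under uniform
contacts is exactly proportional to `L_A × L_B` inclusive, so this
convention keeps per-unit values unbiased across partner categories.
Significance uses a Kruskal–Wallis test
with Dunn's post hoc z tests (implemented from the rank sums with tie
correction) and pairwise Wilcoxon rank-sum tests, both FDR-adjusted;
a category pair is declared significant **only when the omnibus
Kruskal–Wallis rejects and both post hoc tests agree** at α = 0.05.
The unit of replication is the per-(centromere, partner region)
normalized value — one observation per centromere and per category-map
row — which gives the rank tests realistic sample sizes; mirrored
centromere–centromere cells are deduplicated because (u, u′) and
(u′, u) count the same pairs and would otherwise inflate the apparent
sample (measurably raising the null rejection rate above its nominal
level). So configured, a 5× centromere contact excess at 10^5 pairs is
detected in every seeded run, while the uniform model rejects at the
nominal 5% level (the null assertion is therefore statistical — a
binomial bound over seeded runs — because a calibrated 5%-level test
must occasionally reject).

## Fibers and qPCR

Fiber-FISH calibration converts probe signal lengths of known genomic
size into a stretching factor: each probe contributes
`true kb / mean(µm)` and the global factor is the unweighted mean over
probes (weighting by fiber count is a flag); between-probe equality is
tested by Welch's one-way test on the per-fiber implied factors.
Simulated fiber lengths use unit-mean lognormal noise — lengths are
positive and stretching is multiplicative. Domain sizing reports means
and across-fiber SDs of CENP-A and probe signal lengths in kb, and the
percent overlap is the ratio of mean lengths (a per-fiber-ratio mode is
available). Domain comparisons are Welch unpaired t tests.
ChIP-qPCR fold enrichment is `100 × E^(Ct_input − Ct_ip)` with the
primer efficiency `E ∈ (1, 2]`, optionally normalized by a
non-centromeric control locus; relative expression is the mean
`2^−(Ct_target − Ct_reference)` over replicates. The qPCR simulator
inverts the fold formula exactly, so measurement round-trips are exact.

## Probe design

Oligo probes for repeat-rich targets cannot demand alignment
uniqueness — nothing in a centromere island is unique enough. Instead,
every start offset and length 35–41 nt in the target region is a
candidate (overlap mode; accepted probes may overlap), and a candidate
is accepted when its melting temperature lies in 42–47 °C and no 18-mer
it contains occurs more than 5 times genome-wide (6+ occurrences
reject). Tm is nearest-neighbor thermodynamics under the unified
parameter set with the `0.368 (N−1) ln[Na+]` salt-entropy correction
and a linear 0.65 °C/% formamide depression; the fixed conditions
(25 nM strands, 390 mM Na+, 50% formamide) describe an Oligopaint-style
hybridization and are validated against an independent published-
parameter implementation, not against any specific design script's
internals. k-mers are strand-collapsed. On the synthetic islands the
18-mer cap alone keeps accepted probes out of the flanking arrays —
satellite 18-mers occur thousands of times. A density report
(`probe_density()`) is emitted for manual review; no automatic density
rejection is performed.

## Numerical and testing choices

* Coordinates are 0-based half-open everywhere; BED-style output.
* All generators are seeded; the same seed gives byte-identical
  genomes, reads and tables. The end-to-end driver derives per-
  replicate, per-channel seeds from one master seed.
* The test suite runs the full planted design once (2.4 Mb, 4
  replicates at 30×, ~6 minutes) and shares it across the end-to-end
  assertions; unit tests use small constructed fixtures and independent
  brute-force oracles (tandem detection, probe tiling, Poisson tail
  p-values, Dunn's z from the explicit formula, frozen reference Tm
  values).
* The peak-caller null bound is derived from BH: under the complete
  null the probability of any discovery per run is at most q = 0.01, so
  the mean peak count over 50 seeded 100-kb null runs is asserted below
  `0.01 + 3·sqrt(0.01·0.99/50)`.
* The cross-correlation QC simulation uses punctate 150-bp occupied
  footprints (nucleosome-scale) rather than broad islands: a
  fragment-length estimate is only meaningful when binding is narrow
  relative to the fragment, and broad-domain profiles are flat-topped.

## Known limitations

* The seeded assigner is ungapped; indel-divergent repeat copies would
  need a gapped aligner.
* The de Bruijn assembler has no error correction; it is not intended
  for high-error real reads.
* The IDR surrogate preserves the role (filtering irreproducible
  peaks) but not the calibrated IDR score scale.
* Hi-C simulation draws independent pairs from category rates; it has
  no distance decay, so it validates category bookkeeping and the test
  stack, not polymer physics.
* The percentile rule's behaviour depends on the family universe; with
  few families the 80th percentile is coarse.
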