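---
title: "Phasing and crossover calling from single gametes: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasing and crossover calling from single gametes: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gamcross)
```

This vignette is the package's account of its science: the models behind
each stage, the assumptions they rest on, the parameters that matter, the
numerical choices, and what the synthetic-data tests do and do not show
about real data.

## Setting

A diploid donor carries two haplotypes per chromosome. Each haploid gamete
inherits one of them, interrupted by a small number of meiotic crossovers.
Sequencing many gametes individually (cell-barcoded droplet libraries, or
bulk-like per-cell libraries) gives, at each heterozygous SNP (hetSNP) a
gamete covers, a read count supporting the reference or alternative allele.
Two facts drive everything here:

* **Crossovers are rare per site.** Between two nearby hetSNPs, almost no
  gamete recombines, so short-range allele linkage observed across gametes
  reflects the donor's haplotype essentially without error.
* **Coverage is low and noisy.** At ~0.5 reads per SNP per cell, most
  cell/SNP entries are empty, and a small fraction of reads report the
  wrong allele (mapping artefacts, amplification and base-calling errors).

The pipeline is: allele counting → donor phasing → switch-error repair →
per-gamete crossover decoding → landscape statistics. Everything runs per
chromosome; chromosomes are independent and users parallelise across them.

## Allele counting

`count_alleles()` counts, per listed cell barcode (CB tag) and per hetSNP,
reads whose base matches the reference or alternative allele. Duplicate,
secondary, supplementary and unmapped reads are excluded, as are reads
below `min_mapq` (default 20), bases below `min_baseq` (default 13), reads
without a usable barcode, and bases matching neither allele (deletions and
Ns carry no allele evidence). The defaults are ordinary pileup hygiene;
both are exposed as arguments and CLI flags. Counts are kept as sparse
cells × SNPs matrices and written as MatrixMarket coordinate-integer files,
the natural interchange format at this sparsity.

## Phasing by co-segregation

### Genotype layer

`call_genotypes()` reduces counts to per-cell genotypes: the majority
allele where total coverage ≥ `min_total` (default 1) and majority purity ≥
`min_purity` (default 0.8); ties and everything else are missing. At one
read per covered SNP this is mostly a relabelling; the purity rule matters
only for multi-read SNPs.

### Template selection

A gamete with no crossover on the chromosome carries a parental haplotype
intact. `select_template()` looks for evidence that such a gamete exists:
for every cell pair with ≥ `min_shared` (default 30) co-covered SNPs it
computes genotype concordance, maximised over the two orientations —
identical and fully complementary sequences are the *same* haplotype read
with opposite labels, so both count as agreement. A pair reaching
`min_concordance` (default 0.99) pins down two crossover-free cells (two
gametes with different crossovers cannot agree near-perfectly along a whole
chromosome); the member covering more SNPs becomes the template. The exact
pairing statistic is a design point deliberately kept behind this one
function: any rule that finds "two cells with the same genotype sequence"
can be swapped in.

When no pair qualifies — typical when every gamete carries crossovers, as
in the crossover-dense simulation below — the most-covered single cell is
used and the selection is flagged (`fallback_used`). The template then
almost certainly contains crossovers; repairing the resulting switch errors
is exactly the job of the next stage, which is why the fallback is safe.

Ties anywhere break toward the lowest cell index, making runs
deterministic.

### Imputation of missing template SNPs

For each missing SNP *t*, each gamete covering *t* is classified by its
local concordance with the current haplotype over the nearest `window`
(default 10) phased SNPs it covers on each side (≥ 2 co-covered required):
concordance ≥ `link_threshold` (default 0.8) means the cell locally carries
the same orientation and votes its own allele at *t*; concordance whose
*complement* reaches the threshold votes the complementary allele; anything
in between abstains — the cell may recombine inside the window. The
majority allele is assigned when ≥ `min_link_cells` (default 2) votes agree
and the majority fraction reaches `link_threshold`. Passes repeat until a
fixed point; phased entries are never overwritten, so the phased set grows
monotonically and termination is guaranteed.

Both orientation tests compare integer match counts against
`threshold × n` rather than a fraction against `1 − threshold`; this keeps
the rule exactly label-swap symmetric in floating point (complement in,
complement out), a property the tests assert.

The assumption that breaks this model is long runs of homozygosity or very
sparse hetSNPs: with no informative flank within the window, SNPs simply
stay missing (reduced completeness, not wrong phase).

## Switch-error repair

A switch error complements the inferred haplotype from some SNP onward.
Candidate sites (`candidate_sites()`) are phased SNPs whose adjacent-pair
linkage support — the fraction of covering cells whose genotype pair is
haplotype-consistent — drops below `link_ratio_threshold` (default 0.7), or
where fewer than two cells cover the pair.

The switch score at candidate *k* treats each cell's flanking genotypes as
independent Bernoulli observations with genotype error rate ε
(`epsilon`, default 0.1 — deliberately generous so that a few real errors
cannot dominate): a flank of *n* genotypes with *m* haplotype matches has
log-likelihood *m* ln(1−ε) + (*n*−*m*) ln ε under the same orientation, with
*m* and *n*−*m* exchanged under the complement. Per cell the score takes
the best "orientation flips at *k*" configuration minus the best "no flip"
configuration; summed over cells, positive totals favour a switch. The
threshold `min_score = ln 10⁴` (~9.21) demands 10,000:1 evidence.

Repair is iterative (`correct_switches()`): accept the single
best-supported switch, apply it, recompute candidates and scores, repeat.
One switch changes the evidence at every other site, and the score track
around a true switch has broad shoulders (the flanks span ~2×`window`
covered SNPs); rescoring after each acceptance prevents a shoulder from
being read as a second switch. Accepted positions are not revisited within
`min_gap` (default 20) SNPs. `find_switches()` itself — greedy
non-maximum suppression on a static track — is kept as a pure function for
diagnostic use and testing.

`autophase_gametes()` composes phasing and repair; its output is identical
to running the two stages (or the two CLI subcommands) sequentially.

## Crossover decoding

### Model

For one gamete, consider its covered phased SNPs in order, with read counts
re-expressed as (hap1-supporting, hap2-supporting) through the inferred
haplotype. Hidden states are H1 and H2, the haplotype of origin. Emissions
are full binomial pmfs: with n = h1 + h2 reads,

* state H1: h1 ~ Binomial(n, θ₂), default θ₂ = 0.9,
* state H2: h1 ~ Binomial(n, θ₁), default θ₁ = 0.1.

The θ defaults leave 10% read-level contradiction inside a state, which
absorbs miscalls and mapping artefacts without breaking segments. The
binomial coefficient is included (proper probabilities); it cancels in every
comparison and ratio, so the choice affects only reported likelihood
scales.

Transitions between consecutive covered SNPs separated by `gap_bp` use

> p = clamp(gap_bp × cmPmb × 1e−8, p_min, p_max)

with `cmPmb` the assumed recombination rate in cM/Mb (default 0.1,
mammalian-genome scale), `p_min = 1e-10`, `p_max = 0.25`: the gap in Mb
times cM/Mb gives centiMorgans, and 1 cM = 1% recombination probability.
Zero-coverage SNPs carry no evidence and are omitted from the chain rather
than modelled as missing emissions; this matches the sparse data
representation and costs nothing, since an uncovered SNP would contribute
equal emission terms to both states.

### Decoding and confidence

`viterbi_cell()` maximises the path log-probability in log space; ties
break toward staying in the previous state (no transition), so ambiguous
stretches do not fragment. Each maximal same-state segment gets a
log-likelihood ratio (`segment_and_score()`): the full-path log-likelihood
minus the full path with every SNP in the segment flipped to the other
state. Only the segment's emission terms, the transition terms at its
boundaries, and (for the first segment) the initial-distribution term
differ, so those are what is summed; the initial distribution is uniform by
default and then cancels. Including the boundary transition terms makes the
ratio an exact two-path likelihood difference — the tests verify this
against brute-force recomputation over all paths.

A state change between segments is a crossover, localised to the interval
between the flanking covered SNPs. One consequence of the distance-scaled
transition is worth knowing: when the SNP adjacent to a crossover carries a
single read, the MAP path can place the transition one covered SNP over,
into a larger gap (the log-transition difference between two gaps can
exceed one read's emission contrast). At 0.5 reads/SNP/cell this shifts
roughly 5–10% of boundaries by one covered SNP (a few kb here); calls still
match their true crossovers unambiguously, but exact containment of the
breakpoint in the reported interval is not guaranteed. Callers wanting
strict containment should thicken intervals by one covered SNP.

`call_crossovers_dataset()` (saved counts + haplotype) and
`call_crossovers_bam()` (BAM + phased VCF) run the same core and emit
byte-identical segment tables on equivalent inputs — the xo/sxo contract.

## Landscape statistics

`crossovers_from_segments()` applies two layers of filtering. Whole cells
are dropped for poor SNP coverage (`min_cell_snps`, default 200) or
implausibly many raw crossovers (`max_raw_co`, default 10 per chromosome —
library artefacts and aneuploid cells produce such patterns). Then
segments failing `min_seg_snps` (3), `min_seg_llr` (10) or `min_seg_bp`
(1e5) are merged away, lowest-LLR first: an interior failing segment is
absorbed with its two (same-state) neighbours into one segment; an edge
segment into its single neighbour. Only segment-level summaries exist at
this stage, so the merged segment's LLR is the sum of the neighbours' LLRs
— the absorbed segment's own (sub-threshold) evidence is discarded, a
deliberately conservative bookkeeping. Each surviving state change is a
crossover with confidence `min` of the flanking LLRs.

`min_seg_bp` must suit the data's scale: 100 kb is reasonable for a
mammalian chromosome with ~1 crossover expected per 100 Mb bin, but a 5 Mb
region carrying six crossovers has true segments down to ~24 kb, and the
analyses of the simulation below therefore use `min_seg_bp = 1e4`.

`count_cos()` spreads each crossover's unit mass over bins proportionally
to the overlap of its uncertainty interval (midpoint assignment is
available behind a flag). `cal_genetic_dist()` converts per-bin, per-group
mass to a recombination fraction r = mass / n_cells and maps it to
centiMorgans (Kosambi by default, Haldane as the no-interference
alternative). Mapping functions are undefined at r ≥ 0.5; bins must be
fine enough to stay below that, and the clamp option exists only to keep
resampling statistics finite.

`bootstrap_dist()` resamples cells with replacement within groups and
reports the percentile 95% CI of the difference in total map length;
`permute_dist()` permutes labels and reports the two-sided
empirical p-value (1 + #{|perm| ≥ |obs|}) / (B + 1), always in (0, 1]. Both
are seeded and reproducible. A known limitation: percentile intervals
undercover for small groups (observed ~90–92% at 30 cells/group in null
simulations); coverage is nominal by ~100 cells/group. The permutation
test is exact at any group size and is the better small-sample choice.

`phasing_accuracy()` orients the inferred haplotype to a truth haplotype by
whole-chromosome majority (labels are arbitrary) and reports overall and
binned concordance (default 100-SNP bins); `caf_bins()` summarises
contradictory-allele read frequencies in 1000-SNP bins — the fraction of a
bin's reads supporting the minority haplotype, a reference-free phasing
diagnostic (≤ 0.5 by construction).

## The synthetic-gamete generator

`simulate_gametes()` emulates the regime the methods are designed for:

* a hetSNP ladder of `n_snps` distinct uniform positions over `region_bp`;
* a donor haplotype with uniform random allele assignment;
* per gamete, `crossovers_per_cell` breakpoints at SNP gaps, state
  alternating from a fair coin;
* per cell/SNP read counts Poisson(`coverage_mean`), each read reporting
  the wrong allele with probability `miscall_rate`;
* optional template switch errors inserted at known positions.

Defaults (100 cells, 21,000 SNPs, 5 Mb, 6 crossovers/cell, coverage 0.5,
miscall 0.005) are the package's flagship validation scenario: a
crossover-dense stress case in a low-coverage droplet-like regime, in which
no crossover-free template exists and the fallback-plus-repair path is
exercised end to end.

Crossover placement draws uniformly *subject to a minimum separation*
(`min_co_gap_snps`, default 100 gaps), applied between crossovers and to
the region ends. This emulates crossover interference (real crossovers on
one chromatid are strongly spaced) and keeps every inserted crossover
identifiable: a breakpoint a few gaps from the region end leaves a flanking
segment with essentially no covered reads at Poisson(0.5) coverage, which
no method could call. Setting `min_co_gap_snps = 0` gives unconstrained
uniform placement. All outputs are byte-reproducible from the seed.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: non-uniform coverage (amplification bias,
mappability), locally correlated miscalls from mis-mapping (the binomial
noise here is independent per read), barcode collisions and doublets,
hetSNP call errors in the input VCF, segregation abnormalities, and
chromatid interference beyond the minimum-spacing proxy. The cell-level
filters in the landscape stage exist precisely for the artefacts the
generator leaves out.

## Test and validation sizes

The test suite validates the decoder against exhaustive path enumeration
(200 random instances, ≤ 10 SNPs, 1e-9 tolerance), the selection and
scoring rules against brute-force oracles, and the pipeline end to end on
the flagship scenario for three seeds — recovering all 600 inserted
crossovers in each run with ≤ 95 of ~21,000 hetSNPs phased discordantly
(observed 25–46). Switch repair is validated on 50 replicates of a
100-cell, 1000-SNP, 0.3-coverage dataset with one inserted switch
(detected within 5 phased SNPs and repaired to ≥ 99.9% accuracy in ≥ 95%
of replicates; observed 50/50). Permutation type-I error is checked over
400 null simulations at B = 199 (observed 0.0525 at α = 0.05). These sizes
were chosen to exercise the intended regime while keeping the default test
run fast; the full suite completes in about a minute.

## Known limitations

* Diploid donors only; polyploid phasing is out of scope.
* Phasing needs reasonably dense hetSNPs; long homozygous runs reduce
  completeness and, in the extreme, can leave switch errors undetectable.
* Crossover intervals can miss the true breakpoint by one covered SNP
  under the distance-scaled transition model (see above).
* Percentile bootstrap CIs undercover for small groups; prefer the
  permutation test below ~50 cells per group.
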