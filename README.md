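# gamcross

Haplotype phasing and meiotic crossover mapping from single-gamete DNA
sequencing.

## The problem

Sequencing many haploid gametes (sperm, pollen, eggs) from one diploid donor
reveals, cell by cell, which parental haplotype each chromosome segment was
inherited from. Two things follow: the donor's chromosome-scale haplotypes
can be assembled *without* a reference panel, because co-segregation of
nearby heterozygous SNPs (hetSNPs) across gametes is almost never broken by
the rare meiotic crossovers; and each gamete's crossovers can be located as
the points where its alleles switch haplotype. The difficulty is coverage:
droplet single-cell protocols yield well below one read per SNP per cell, so
individual genotypes are sparse and noisy and both tasks must pool evidence
across cells. `gamcross` implements this end to end for barcoded BAMs
(CB-tagged reads), a hetSNP VCF and a cell-barcode list, and ships a
synthetic-gamete generator so the whole pipeline is testable with known
truth.

It is aimed at researchers building personalised recombination maps —
comparing crossover rates and placements between individuals, genotypes, or
experimental groups.

## Methods at a glance

**Phasing.** Per-cell genotypes are called from allele counts (majority
allele, purity ≥ 0.8 by default). A *template* gamete — one that putatively
inherited no crossover — is picked by searching all cell pairs for the
highest genotype concordance, taken as the maximum over the two label
orientations (a haplotype and its complement are the same object). The
template's genotype sequence seeds the haplotype; missing SNPs are filled by
an orientation-aware majority vote: a cell whose local flanking concordance
with the current haplotype is ≥ 0.8 votes its own allele, ≤ 0.2 votes the
complement, in between it abstains.

**Switch-error correction.** If no crossover-free template exists the
backbone carries switch errors. For candidate sites with weak adjacent-pair
linkage, a switch score contrasts per-cell flank likelihoods under
"orientation flips at *k*" versus "same orientation", with flank
log-likelihoods *m* ln(1−ε) + (*n*−*m*) ln ε. The best-supported switch
(score ≥ ln 10⁴) is applied and the track re-scored, iteratively.

**Crossover calling.** A two-state HMM over a gamete's covered hetSNPs:
hidden states are the two haplotypes; the emission for (hap1-reads,
hap2-reads) is Binomial(n, θ) with θ = 0.9 in state H1 and 0.1 in state H2;
the per-gap transition probability is `gap_bp × cmPmb × 1e-8` (clamped),
with cmPmb the assumed cM/Mb rate. Viterbi decoding gives the state path;
each same-state segment gets a log-likelihood-ratio confidence — the
full-path log-likelihood minus the same path with the segment's states
reversed. A state change between segments is a crossover.

**Landscapes.** Crossovers are filtered (per-cell SNP coverage, raw-call
caps, flanking-segment SNPs/LLR/span), counted over genomic bins with
fractional overlap mass, converted to centiMorgans by the Kosambi
25 ln((1+2r)/(1−2r)) or Haldane −50 ln(1−2r) map functions, and compared
between groups with bootstrap CIs and permutation tests.

## Worked example

Simulate 100 gametes over ~21,000 hetSNPs in a 5 Mb region, six crossovers
per gamete, 0.5 reads/SNP/cell and a 0.5% allele miscall rate; then phase,
repair switches, call crossovers and build the map:

```r
library(gamcross)

cfg <- sim_config(n_cells = 100, n_snps = 21000, region_bp = 5e6,
                  crossovers_per_cell = 6, coverage_mean = 0.5,
                  miscall_rate = 0.005, seed = 1)
sim <- simulate_gametes(cfg)
sim$counts
#> allele_counts: 100 cells x 21000 SNPs (chrS), 414064 / 413699 nonzero ref/alt entries

ph <- autophase_gametes(sim$counts)
ph$selection
#> template_selection: fallback to most-covered cell 21
length(ph$switch_correction$switches$positions)
#> [1] 6
```

Every gamete here carries six crossovers, so no crossover-free template
exists: phasing falls back to the most-covered cell and the switch-error
module finds and repairs that cell's six crossovers in the backbone.
Against the simulation truth:

```r
acc <- phasing_accuracy(ph$hap, sim$truth$hap_truth)
c(phased = acc$n_phased, discordant = acc$n_discordant)
#>     phased discordant
#>      20816         25
```

20,816 of 21,000 hetSNPs phased, 25 discordant. Crossover calling and the
genetic map:

```r
xo  <- call_crossovers_dataset(sim$counts, ph$hap)
cos <- crossovers_from_segments(xo$segments, filter_params(min_seg_bp = 1e4))
table(table(cos$crossovers$cell))
#>   6
#> 100

m <- count_cos(cos, tile_bins("chrS", 1, 5e6, 1e5),
               cos$qc$cell[!cos$qc$dropped])
sum(cal_genetic_dist(m)$cM)
#> [1] 614.9182
```

All 100 cells yield exactly six crossover calls (≈ 615 cM for the region,
as expected for six crossovers per meiosis plus the Kosambi correction).
Randomly split cells show no spurious group difference:

```r
set.seed(2)
labels <- sample(rep(c("g1", "g2"), 50))
permute_dist(m, labels, B = 999, seed = 3)
#> group_comparison: observed diff 0.2307 cM, permutation p = 0.9220 (999 resamples)
```

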