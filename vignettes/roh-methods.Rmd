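---
title: "Methods: ROH calling, profiling and error-aware benchmarking"
author: "rohprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ROH calling, profiling and error-aware benchmarking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohprofiler)
```

# The problem

Runs of homozygosity (ROH) are contiguous stretches of a diploid genome where
both haplotypes are identical, typically because they descend from a single
recent ancestral copy (autozygosity). Per-individual ROH statistics — the
segment count NROH, the cumulative length SROH, and the genomic inbreeding
coefficient $F_{ROH} = \mathrm{SROH}/L_{auto}$ — are standard population-genetic
summaries. Two practical forces distort them:

* **Genotyping error.** High-coverage WGS mis-calls homozygotes as
  heterozygotes at a non-trivial rate (on the order of 4–5 spurious
  heterozygotes per Mb in published East-Asian cohorts). A single spurious
  heterozygote can split one long ROH into two short ones, deflating the long
  class (NROH$_{\ge 1.5\mathrm{Mb}}$) while inflating the short classes.
* **Marker density.** Restricting WGS calls to SNP-array positions (or
  comparing cohorts genotyped at different densities) removes the markers
  that reveal short ROH, so short-class counts fall while the long class is
  comparatively robust.

This package implements both detection families used in that literature — a
two-state autozygosity hidden Markov model and a PLINK-style sliding-window
scanner — together with the profiling statistics, ROH-island detection,
pedigree-based Mendelian QC, and a cohort simulator that provides planted
ground truth so every claimed behaviour is measurable.

# The autozygosity HMM

Hidden states are `HW` (non-autozygous) and `AZ` (autozygous). At a site with
alternate-allele frequency $f$, the true-genotype priors are

* HW: $(1-f)^2,\; 2f(1-f),\; f^2$ for dosages 0/1/2,
* AZ: $(1-f),\; 0,\; f$ — heterozygotes are impossible when the two
  haplotypes coalesce.

Observed genotypes pass through a symmetric error channel: the true dosage is
kept with probability $1-e$ and each wrong dosage is emitted with probability
$e/2$, where $e = 10^{-\mathrm{phred}/10}$. The default `gt_error_phred = 30`
($e = 10^{-3}$) is the conventional setting for absorbing WGS heterozygote
errors: an isolated heterozygote inside a long homozygous run costs
$\log(e/2) - \log 2f(1-f) \approx -6.7$ nats, far less than the
$\approx -17$ nats of leaving and re-entering `AZ`, so the run is *not*
split; with $e = 0$ it must split. This is exactly the mechanism by which the
error parameter protects the long-ROH class, and it is asserted in the test
suite.

Transitions follow an exponential kernel in distance,
$P(\mathrm{HW}\to\mathrm{AZ}) = 1 - \exp(-\lambda_{HA} d)$ and symmetrically
with $\lambda_{AH}$, with defaults $\lambda_{HA} = 6.7\times10^{-8}$ and
$\lambda_{AH} = 5\times10^{-9}$ per bp — the documented defaults of the
canonical autozygosity-HMM implementation, since only the error parameter is
pinned by the study design this package emulates. When a genetic map is
supplied, $d$ is the map gap in cM converted to bp-equivalents at the
fallback rate (default 1 cM/Mb), so recombination-hot regions behave as if
physically longer. Decoding is Viterbi by default (matching regional output
of the reference tool); per-site max-posterior decoding is available via
`hmm_params(viterbi = FALSE)` for diagnostics, and forward–backward
posteriors can be attached to segments as a quality score. The initial
distribution is the stationary distribution of the two intensities. Segment
coordinates are the outermost decoded site positions — unambiguous, but a
small negative length bias at wide marker spacing (see the pruning
discussion below).

# The sliding-window scanner

A window of `window_snp` consecutive SNPs is *homozygous* when it contains at
most `window_het` heterozygous and `window_missing` missing calls. Each SNP
is scored by the proportion of windows containing it that are homozygous
(computed by an O(n) rolling count and verified against naive re-enumeration);
SNPs at or above `hit_threshold` are eligible, and maximal eligible runs
become segments subject to `min_snp`, `min_length_kb`, `max_gap_kb` and
`density_kb_per_snp`. Defaults (50/1/5/0.05/100/100/1000/50) mirror the
canonical scanner. `window_het` (the `Het_1..Het_4` sweep in `het_sweep()`)
is the error-absorption dial: with errors present, raising it monotonically
recovers the long-ROH class.

**Density scaling.** The canonical defaults assume array-like density
(~1 SNP / 4 kb). At other densities the window span (`window_snp` × mean
marker spacing) must stay below the minimal segment length sought, and
`min_snp` should scale proportionally — otherwise short ROH are structurally
undetectable regardless of data quality. The acceptance benchmarks, run at
100 sites/Mb, therefore use `window_snp = 20`, `min_snp = 10`; and on
error-free input `window_het = 0`, since any allowance only permits spurious
boundary extension when there are no errors to forgive.

# Profiling

`nroh_sroh()` applies minimal-length classes (100 Kb / 300 Kb / 1.5 Mb by
convention) inclusively; `length_bins()` uses half-open `[lo, hi)` bins with
an explicit underflow bucket so totals are conserved (the bin-edge convention
is not fixed by the literature; half-open is documented here once and used
everywhere). `f_roh()` divides SROH by the analyzed autosomal length; for
synthetic genomes the self-consistent denominator is the simulated genome
length, while comparisons with published values should pass the full
autosomal length those studies used.

# ROH islands

`overlap_track()` counts, at every analyzed site, the number of *individuals*
(not segments) covered by an ROH. `call_islands()` thresholds that track at
the nearest-rank percentile (99.9th or 99.5th by convention) computed over
all analyzed sites, zero-count sites included; ties at the threshold are
included, and zero-count sites can never qualify — this combination
satisfies both the "sole hot site is the sole island" and the "all-zero
track has no islands" requirements, which a bare nearest-rank threshold
cannot do simultaneously. Qualifying sites merge when adjacent in the
analyzed site list (`max_merge_gap_bp` optionally bridges larger physical
gaps). `annotate_genes()` reports any ≥1 bp overlap with gene intervals from
BED/GFF3. Pathway enrichment is deliberately out of scope: the deliverable
is the ranked per-island gene list.

# Pedigree-based Mendelian QC

`trio_check()` classifies each parent–parent–child dosage triple;
12 of the 27 ordered combinations are impossible under biallelic
transmission (verified against exhaustive gamete enumeration).
`site_error_scan()` decomposes multi-generation families into their
constituent trios and flags sites where inconsistencies recur — at least
`recurrence_min = 2` inconsistent trios or an inconsistency rate of
`rate_min = 0.05`, a disjunction. Both thresholds are design choices (the
motivating study says only "common" error sites) and are exposed as
arguments. `remove_flagged_sites()` prunes by (chrom, pos), so a report from
a pedigreed cohort can clean a different cohort sharing the site panel.
Errors that do not violate Mendelian rules (e.g. a heterozygote error in a
founder compatible with both parents being unobserved) are Mendelian-silent;
recall is therefore *measured* on simulations rather than assumed.

# The cohort simulator: what it states, and what it does not

The generator's defaults are the stated world of the benchmarks:

* **Sites**: fixed count `round(length × density)` per chromosome (default
  100 sites/Mb — desk-scale, ~30× sparser than real WGS), uniform positions,
  alternate-allele frequencies from Beta(2, 2) — a mid-frequency spectrum
  matching a panel already AF-filtered to [0.05, 0.95], and the law under
  which segment recovery is meaningfully testable at this density.
* **Planted autozygosity**: per founder, 10 short segments with lengths
  uniform on [100 Kb, 1.5 Mb] and 3 long segments of 1.5 Mb + Exp(2 Mb),
  created by copying one haplotype over the other, so truth intervals are
  exact. The true length law of human ROH is not pinned by the motivating
  study; these laws are placeholders chosen once and exposed in
  `sim_config()`.
* **Pedigrees**: trio/septet/octet templates (3/7/8 members; a septet is four
  grandparents, two parents, one grandchild), mirroring a three-generation
  cohort design. Transmission is Haldane: crossover counts
  Poisson(cM/100), positions uniform in cM — interference is irrelevant at
  the scales analyzed.
* **Errors**: spurious heterozygotes at 4.5/Mb per sample (the published
  WGS rate for the emulated population), drawn uniformly over homozygous
  sites; plus systematic bad sites (a configurable fraction of sites where
  each genotype flips hom↔het with a configurable probability), which
  create the recurrent Mendelian inconsistencies the QC module targets. The
  pedigree benchmark uses a 10% bad-site fraction at flip probability 0.3,
  chosen a priori for statistical identifiability at desk scale (≈10 flips
  per long segment per sample; 48 trios give ≳0.9 power to see ≥2
  inconsistent trios per bad site).
* **Array mask**: a uniform random subsample of sites (default 25%) —
  density-realistic, but without the real array's non-random placement.

What the simulator does **not** emulate: linkage disequilibrium and
haplotype sharing between founders (no coalescent), X/Y/MT, read-level
error processes, or non-random array design. A green recovery test
therefore establishes correctness of the callers' mechanics and their
stated error/density responses — not calibrated real-data performance.

# Numerical and design choices

* Coordinates are 1-based inclusive internally; BED conversion happens only
  at I/O boundaries. Segment length is `end − start + 1`.
* AF filter bounds are inclusive on both ends, matching the quoted
  command-line semantics of the emulated workflow; missingness is
  cohort-wide.
* Chromosome arms: excluded regions (e.g. centromeres) drop their sites and
  split each chromosome into analysis units, so no segment spans an
  exclusion; acrocentric chromosomes degrade to a single unit.
* Viterbi ties are broken toward staying in the current state; with
  continuous emissions, exact ties occur with probability zero and the
  brute-force equivalence tests never hit one.
* Iteration seeds in `density_prune_run()` are `seed + iteration`, so any
  single iteration reproduces in isolation; averaging is within iteration
  across individuals first, then across iterations (the emulated workflow is
  ambiguous; this order is fixed and documented).
* Pruning benchmark: sparse markers push called boundaries outward to the
  nearest retained site, a small systematic upward bias on long-class counts
  at 30% density. The benchmark therefore asserts the pattern the motivating
  comparison actually shows — a marked short-class drop with a long class
  whose relative change is strictly smaller — rather than literal
  within-noise equality, which that comparison's own published numbers would
  fail.
* Genotype code `-1` (missing) is legal in the containers and the window
  caller; the HMM requires missingness to be filtered first (matching its
  upstream filter `-g ^miss`).

# Known limitations

* Pure-R dynamic programming: fine at desk scale (5,000 sites × 50 samples
  decode in ~1 s), not at biobank scale.
* The HMM uses hard genotypes, not genotype likelihoods; `gt_error_phred`
  is a single global error rate.
* The window caller implements the windowing/eligibility core; PLINK's
  secondary trimming heuristics are not reproduced.
* `F_ROH` comparability across studies depends on the denominator
  convention; the package makes it an explicit argument rather than a
  constant.
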