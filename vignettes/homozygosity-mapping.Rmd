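---
title: "Homozygosity mapping with rohmap: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homozygosity mapping with rohmap: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohmap)
```

## The problem

A run of homozygosity (ROH) is a stretch of consecutive homozygous SNP
calls. Long runs arise when the two chromosomes of an individual descend
from a recent common ancestor (autozygosity), so the genome-wide ROH
burden measures inbreeding, the length distribution of runs dates it
(recombination erodes long runs within a few generations, while 1–4 Mb
runs persist for tens of generations), and regions where many
individuals carry overlapping runs — ROH islands — point at directional
selection. `rohmap` implements this pipeline for dense SNP-array
genotypes of dogs (38 autosomes), from PED/MAP ingress through QC, ROH
detection, inbreeding coefficients and island extraction, together with
a simulator that plants autozygous tracts with known ground truth.

## Quality control

Three filters precede detection, in a fixed order:

1. **Autosome restriction.** Only chromosomes "1"–"38" are kept; X, Y
   and MT calls follow different inheritance and are excluded.
2. **Call-rate filters.** Individuals with more than 10% missing calls
   are dropped first, then SNPs with more than 5% missingness among the
   remaining individuals (`qc_params()`, PLINK's `--mind 0.10` /
   `--geno 0.05`). The order matters — a failing sample can push a SNP
   over its threshold — and is therefore fixed and tested. No minor
   allele frequency, Hardy–Weinberg or LD pruning is applied: rare and
   out-of-equilibrium markers carry exactly the homozygosity signal the
   scan looks for.
3. **Relatedness screening.** `estimate_relatedness()` computes the
   Purcell method-of-moments IBD decomposition from IBS counts and
   sample allele frequencies, with the standard finite-sample bias
   corrections; `PI_HAT = P(IBD=2) + P(IBD=1)/2`. Negative moment
   estimates are clipped to zero and the triple renormalized. Loci that
   are monomorphic, or have fewer than four sampled alleles, contribute
   nothing (the corrections divide by $N-1$, $N-2$, $N-3$ allele
   counts). Pairs above the 0.4 threshold are *reported, never
   auto-removed*: which member of a related pair to exclude (if any) is
   a study decision, so the CLI exposes it as an explicit
   `--drop-related` flag that keeps the member with the higher call
   rate.

Allele frequencies for the IBD expectations are taken from the matrix
as supplied, which in the pipeline is the post-call-rate-filter,
autosomal matrix.

## ROH detection

The caller reproduces the overlapping sliding-window semantics of the
classical SNP-array scanners. Per individual and chromosome:

1. Every window of `window_snp = 50` consecutive SNPs is judged
   homozygous when it has at most `window_het_allow = 1` heterozygous
   and at most `window_missing_allow = 1` missing calls.
2. Each SNP receives a hit fraction: homozygous windows containing it
   over windows containing it. SNPs near chromosome ends belong to
   fewer windows, so the denominator is the count of windows that
   actually contain the SNP — the natural resolution of the
   end-of-chromosome ambiguity, and the one we adopt. A chromosome with
   fewer SNPs than one window yields all-zero fractions.
3. SNPs with fraction ≥ `window_threshold = 0.05` are marked; maximal
   runs of marked SNPs become candidate segments.
4. Runs are split where adjacent SNPs are more than `max_gap_kb = 1000`
   apart, then trimmed so both ends sit on non-missing homozygous
   calls. Interior heterozygous or missing calls survive only through
   the window allowances; without end-trimming a run could start on a
   heterozygote and inflate its boundary.
5. Surviving runs are kept when they have at least `min_snp` SNPs, are
   at least `min_length_kb = 1000` long, and average at most
   `max_density_kb_per_snp = 50` per SNP. Length is
   `end_bp − start_bp + 1`; the `+1` is immaterial at Mb scale but
   fixed for determinism. Density is evaluated on the final segment,
   not per window.

The 1 Mb length floor deliberately excludes short runs that commonly
reflect shared haplotypes inherited without recent common ancestry
rather than autozygosity.

**The minimum SNP count** is not a free parameter: `compute_min_snp()`
sets it so that the expected number of chance runs across the dataset
stays below a false-positive rate $\alpha$,

$$ L \;=\; \frac{\ln\!\big(\alpha / (n_s\, n_i)\big)}{\ln(1-\bar h)}, $$

with $n_s$ SNPs, $n_i$ individuals and mean SNP heterozygosity
$\bar h$ (computed after QC as the mean observed heterozygote
fraction). The result is floored and clamped to ≥ 1; $\alpha$ defaults
to 0.05 and is exposed as a flag. For a post-QC matrix of ~130k SNPs ×
39 dogs at $\bar h \approx 0.36$ this gives $L \approx 42$.

Only the window-level heterozygote cap is enforced; no additional het
limit is applied inside assembled segments. The window allowance is
what tolerates genotyping error inside true autozygous tracts, and a
segment-level cap would re-penalize exactly those errors.

## Summaries and F_ROH

Runs are tabulated in the conventional length classes 1–2, 2–4, 4–8,
8–16 and >16 Mb. Bins are left-closed/right-open — a run of exactly
2 Mb falls in 2–4 Mb — because the conventional class labels do not
state a boundary rule and a deterministic one is required.

Class genome coverage is computed from summary quantities (mean runs
per animal × mean run length / genome size × 100,
`class_genome_coverage()`), matching how such tables are conventionally
built rather than summing raw base pairs.

`froh()` implements the McQuillan-style inbreeding coefficient
$F_{ROH} = \sum L_{ROH} / L_{genome}$. Two denominator conventions
exist in the literature and `froh_table()` supports both explicitly:

* **assembly** — divide by assembly length (the package constant
  `dog_genome_mb = 2396.86` genome-wide, or per-chromosome assembly
  lengths). This is the default for genome-wide $F_{ROH}$.
* **snp_span** — divide by the span actually covered by genotyped SNPs
  (last minus first SNP position), common for per-chromosome displays,
  where array coverage varies by chromosome.

The shipped per-chromosome autosome table (`dog_autosomes()`) is
approximate, at the scale of current dog assemblies; for exact
per-chromosome work against a specific assembly, pass your own table.

`generation_length_life_history()` is a small life-history utility kept
with the summaries: generation length as age at first estrus plus one
inter-estrus interval plus gestation, months summed and converted to
years. Its defaults (9 + 9 + 2 months = 1.7 years) describe the Tazy
sighthound. Pedigree-based generation-length estimation is out of
scope: averaging lifespans over partially known pedigrees is not
reproducible as an algorithm.

## ROH islands

`snp_incidence()` counts, per locus, the individuals whose runs cover
it. `call_islands()` selects loci whose carrier fraction reaches a
threshold (0.5 by default — "at least half the cohort", implemented as
`fraction >= threshold`, which for 39 individuals means at least
⌈0.5·39⌉ = 20 carriers) and merges consecutive selected loci,
splitting where adjacent selected loci are more than `max_gap_kb`
apart. The merge gap defaults to the detector's 1000 kb, as no separate
convention exists for islands; it is exposed as a flag.

Two conventions are worth making explicit:

* **Island span** is reported as `end_bp − start_bp`, a position
  difference, matching how island sizes are conventionally tabulated in
  breed studies (not a `+1` base count).
* **Supporting individuals** (`n_dogs`) defaults to individuals whose
  single ROH covers the *entire* island extent; the looser
  any-overlap definition is available via `n_dog_rule = "overlap"`,
  since published island tables are ambiguous on this point.

## The simulator

`sim_config()` defaults describe a 39-dog cohort on the 38 dog
autosomes with exponential inter-marker spacing of mean 14 kb (~157k
markers — the scale of post-QC canine array panels), minor allele
frequencies uniform on (0.05, 0.5), five planted autozygous tracts per
dog with lengths log-uniform on 1–40 Mb, a 0.5% probability that a
tract genotype is misread as heterozygous, and 2% uniform missingness.
Background genotypes are Hardy–Weinberg draws; inside a tract a single
allele is drawn by frequency and doubled. A single global RNG stream is
keyed by the mandatory seed, so a config reproduces its dataset
exactly.

The **shared island** is planted as a fixed 2 Mb core carried by
⌈carrier_fraction · n⌉ randomly chosen dogs; each carrier's tract
extends beyond the core by independent exponential flanks (mean 1 Mb
per side). This mirrors how a selected core sits inside IBD haplotypes
of varying extent in real data: the island is the stable intersection
of longer overlapping runs, not a set of identical segments. It also
matters statistically — a carrier tract exactly equal to a 2 Mb core is
marginal under the 50-SNP window rules (one unlucky heterozygote pair
can erase a carrier), whereas flanked tracts are detected essentially
always, so island recovery reflects the carrier fraction rather than
per-carrier detection noise.

What the simulator does **not** emulate: linkage disequilibrium between
background markers (loci are independent), non-uniform marker density,
batch- or cluster-structured missingness, and sex chromosomes. The
window-based detector does not exploit LD, and pipelines of this kind
apply no LD pruning, so independent loci are adequate for validating
the detector's operating characteristics — but passing recovery tests
here says nothing about, e.g., allelic-match ROH callers that do model
LD, and background "chance" homozygosity in real data is patchier than
the independent-locus model produces.

`score_recovery()` reports base-pair precision (called bases inside
truth / called bases) and recall (true bases called / true bases, for
tracts at least the detector's 1 Mb floor), plus segment-level
precision/recall at a reciprocal-overlap fraction (default 0.95). An
empty call set has recall 0 and precision 1: it makes no false claim,
and the zero denominator is resolved in its favour.

On simulated cohorts at the default scale, the full pipeline (autosome
restriction, call-rate QC, detection with $L$ from the formula)
recovers planted tracts with bp-recall ≈ 0.97 and bp-precision ≈ 0.99.
Running detection *without* the SNP call-rate filter drops recall to
≈ 0.89: under 2% missingness, the one-missing-per-window rule erases
marking over stretches where missing calls cluster, and the call-rate
filter removes exactly those markers. QC before detection is therefore
not optional bookkeeping but part of the method's operating
characteristics.

## Numerical and degenerate-input choices

* Allele 1 at each locus is the lexicographically smaller observed
  allele symbol; PED carries no ref/alt orientation, so a deterministic
  rule is required for stable coding and lossless round-trips.
  Half-missing genotypes (`0 G`) are treated as missing. A locus with
  more than two observed alleles is rejected by name.
* Loci are sorted by (chromosome, position) on load; positions must be
  strictly increasing within a chromosome. The MAP's genetic-distance
  column is read and carried but unused (the pipeline is
  physical-distance based).
* Window hit fractions compare `fraction >= threshold`; both sides are
  exact binary rationals at the default threshold, so no epsilon is
  needed.
* `froh()` refuses overlapping segments and values above 1 rather than
  silently clipping; both indicate an upstream contract violation.
* Sample standard deviation of per-individual counts is reported as 0
  for a single individual, where it is undefined.
* With zero individuals or zero usable (polymorphic, sufficiently
  sampled) loci, relatedness estimation raises an error rather than
  returning NaNs.

## Problem sizes in the test suite

Unit tests run on constructed vectors and small simulated cohorts (12
dogs, 4 chromosomes, study-like 14 kb marker spacing). Equivalence
against brute-force window/run enumeration uses >100 randomized
instances of up to 500 SNPs. Recovery and island tests run the full
pipeline on default-scale cohorts (39 dogs, 38 autosomes, ~157k
markers), which takes a few seconds per cohort; relatedness checks use
50k independent loci, where the moment estimator's sampling error is
comfortably below the asserted tolerances (±0.02 for unrelated pairs,
±0.05 for parent–offspring). These sizes were chosen as the smallest
at which the asserted properties are stable across seeds.

## Known limitations

* The detector is the window-based family; likelihood/HMM callers
  (genotype-likelihood aware) are out of scope, as are LD-aware
  methods.
* PLINK text PED/MAP is the only genotype format; binary BED and VCF
  are not parsed.
* The shipped autosome length table is approximate; exact
  per-chromosome denominators require a user-supplied table.
* Gene annotation of islands, enrichment analysis and effective
  population-size inference from ROH lengths are interpretive steps
  outside the package.
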