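# rohmap

Homozygosity mapping for dense SNP-array genotypes, built for breed
studies in dogs and other livestock-scale cohorts. Starting from PLINK
text PED/MAP files, `rohmap` runs the classical pipeline:

1. **QC** — autosome restriction, per-sample and per-SNP call-rate
   filters, and pairwise relatedness screening by the method-of-moments
   IBD decomposition (`PI_HAT = P(IBD=2) + P(IBD=1)/2`, mirroring PLINK
   `--genome`);
2. **ROH detection** — the overlapping sliding-window scan (50-SNP
   windows, ≤1 heterozygous and ≤1 missing call per window, hit
   fraction ≥ 0.05), run assembly with a 1000 kb gap split, a 1 Mb
   length floor and a 50 kb/SNP density cap, with the minimum run size
   set by the Lencz/Purfield rule
   `L = ln(α / (n_s·n_i)) / ln(1 − h̄)`;
3. **summaries** — length classes (1–2, 2–4, 4–8, 8–16, >16 Mb), class
   genome coverage, and McQuillan inbreeding coefficients
   `F_ROH = Σ L_ROH / L_genome` per dog and per chromosome;
4. **islands** — per-SNP ROH incidence across the cohort and extraction
   of extreme ROH islands (eROHi), regions carried by at least a chosen
   fraction of individuals, a signature of directional selection.

A synthetic-genotype simulator plants autozygous tracts (and a shared
island) with known ground truth, so the detector's precision and recall
can be measured rather than assumed.

## Worked example

Simulate a 39-dog cohort at canine-array scale, run the pipeline, and
compare calls against the planted truth:

```r
library(rohmap)

sim <- simulate_genotypes(sim_config(seed = 11))
sim
#> sim_result: 39 dogs x 157707 loci; 214 planted tracts (20 shared-island carriers)

gm <- restrict_to_autosomes(sim$genotypes)
gm <- filter_by_call_rate(gm, qc_params())$genotypes
gm
#> genotype_matrix: 39 individuals x 128606 loci
#>   chromosomes: 38  missing calls: 1.13%

L <- compute_min_snp(n_loci(gm), n_individuals(gm), mean_heterozygosity(gm))
L
#> [1] 41

roh <- call_roh(gm, window_params(), segment_params(min_snp = L))
summary(roh)
#> ROH summary: 326 segments, 39 individuals
#>   runs per individual: mean 8.36 +/- 2.28 (sd)
#>   length classes (genome 2396.86 Mb):
#>  class  n percent mean_length_mb mean_count_per_animal coverage_pct ...
#>    1-2 71    21.8           1.46                 1.821        0.111
#>    2-4 82    25.2           2.89                 2.103        0.253
#>    4-8 81    24.8           5.71                 2.077        0.495
#>   8-16 63    19.3          11.03                 1.615        0.743
#>    >16 29     8.9          24.16                 0.744        0.750

mean(froh_table(roh)$genome$froh)
#> [1] 0.0235

track <- snp_incidence(roh, gm$loci)
call_islands(track, roh, threshold = 0.5)
#>   chrom start_bp  end_bp span_bp n_snp n_dogs
#> 1    18  1516849 3116974 1600125    94     19

score_recovery(roh, sim$truth$tracts)[c("bp_recall", "bp_precision")]
#> $bp_recall    [1] 0.968
#> $bp_precision [1] 0.994
```

Reading left to right: after QC the cohort keeps 128,606 autosomal
SNPs; the false-positive-controlled minimum run size is 41 SNPs; the
caller finds 326 runs whose length-class table shows counts, share of
all runs, class genome coverage (mean runs/animal × mean length /
2396.86 Mb × 100) and the spread of per-dog `F_ROH` restricted to each
class. The island call recovers the planted shared region on
chromosome 18 (carried by 20 of 39 dogs; 19 carry the full recovered
extent), and 96.8% of planted autozygous bases are recovered with
99.4% of called bases inside true tracts.

The same stages are scriptable from a shell via the thin CLI installed
at `exec/rohmap` (`simulate`, `qc`, `detect`, `summary`, `islands`;
each stage writes TSVs plus its resolved configuration and a log).

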