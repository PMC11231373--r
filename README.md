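# panelsnp

Design and evaluation of target-capture genotyping panels (GBTS
"liquid-phase chips") in R.

Breeding programs increasingly genotype germplasm with a fixed panel of
hybridization probes that capture a few tens of thousands of genomic
fragments for deep sequencing, instead of resequencing whole genomes.
Building such a panel is a pipeline of well-defined decisions: which
polymorphic sites are informative and technically capturable, how to space
them evenly across chromosomes, how to design the capture oligos, and how
to judge the panel once real samples have been hybridized. `panelsnp`
implements that pipeline end to end for diploid species, modeled on a
45,389-probe pepper panel, for panel designers, breeders and
population-genetics analysts.

## What it computes

**Core-site selection.** From a multi-sample VCF, a site survives when
(per site, over non-missing calls): mean depth ≥ 10X; MAF
min(p, 1 − p) > 0.05 with p = (2·hom_alt + het)/(2n); missing fraction
< 0.20; heterozygosity het/n < 0.05; genotypic LD r² < 0.4 after windowed
greedy pruning; and its probe region is free of microsatellites and N.
Strand-ambiguous A/T and C/G SNPs (indistinguishable under strand flips,
hence needing two oligos) are demoted in priority rather than dropped.

**Panel layout.** Trait-linked foreground sites are placed first; vacant
intervals of ≥ 70 kb are filled greedily from the background pool (largest
sub-gap, site nearest its midpoint) until spacing falls under the
threshold.

**Probe design.** One 110 bp window per site, variant centered, GC in
[30, 80]%, shifted up to ±40 bp to escape local constraint violations; a
±200 bp single-copy test by seeded exact-match extension (secondary locus
at ≥ 80% identity over ≥ 50% of the segment disqualifies).

**Evaluation.** Per-sample capture ratios with inclusive 70% retention,
per-site detection ratios, post-capture marker filtering (remove MAF
< 0.05, missing > 0.1, het > 0.8), phenotype-stratified allele-presence
tables, VanRaden kinship K = ZᵀZ / Σ 2pⱼ(1−pⱼ) with summary fractions, a
simplified allelic chi-square association scan with Bonferroni
thresholding, single-linkage QTL grouping and ±2 Mb candidate-gene
windows.

**Synthetic data.** Seeded generators for genomes (planted SSRs and
duplications), populations (true MAFs, LD blocks, missingness, inbreeding,
het excess, negative-binomial depth), capture count matrices and
phenotypes — every planted feature is recoverable by the corresponding
pipeline stage, which is how the test suite validates the whole chain.

## Worked example

```r
library(panelsnp)

sim <- simulate_genome(c(chr1 = 400000L), gc_target = 0.45, seed = 1)
pop <- simulate_population(sim$genome, n_samples = 100, n_sites = 120,
                           maf = 0.3, depth_mean = 40, seed = 2)

core <- select_core_sites(pop$gm, sim$genome)
nrow(core$core)
#> [1] 115
head(core$ledger, 3)
#>            id       stage reasons
#> 1 chr1_120004 hard_filter     het
#> 2 chr1_146441 hard_filter     het
#> 3 chr1_242083 hard_filter     het

pool <- pop$gm$sites[match(core$core$id, pop$gm$sites$id), ]
catalog <- data.frame(trait = "fruit_shape", contig = "chr1",
                      pos = 150000L, ref = "A", alt = "G")
panel <- build_panel(catalog, pool, sim$genome,
                     panel_config(check_single_copy = FALSE))
panel
#> probe_panel: 7 sites (1 foreground, 0 functional segments, 6 background)
#>   flagged foreground sites: 0; residual gaps: 0
panel$spacing
#>   contig n_sites mean_spacing median_spacing max_spacing
#> 1   chr1       7     48279.17          50484       64265
```

120 simulated sites shrink to 115 core sites (five fail the
heterozygosity cap by sampling noise), and the layout stage needs only six
background sites beyond the one foreground marker to hold every adjacent
interval of the 400 kb contig under 70 kb — mean spacing 48.3 kb, maximum
64.3 kb.

```r
cm <- simulate_capture(panel$probes$id, pop$gm$samples, dropout = 0.02,
                       depth_mean = 100, seed = 3)
capture_report(cm)
#> capture_report: 100 samples, mean capture ratio 0.9829, 100 retained at >= 70%
```

With 2% probe dropout planted, the mean capture ratio comes back at 0.98
and all 100 samples clear the 70% retention bound. Probe windows export
through `write_probe_bed()` (BED6, 0-based half-open) and
`write_probe_fasta()` (110-mers; strand-ambiguous sites emit `_fw`/`_rc`
record pairs).

A command-line wrapper over the same pipeline ships in
`inst/scripts/design_panel.R`
(`--genome`, `--vcf`, `--catalog`, `--min-maf`, `--max-missing`,
`--max-het`, `--min-depth`, `--max-r2`, `--gap-threshold`).

## Documentation

See the methods vignette (`vignettes/panel-design-methods.Rmd`) for the
statistical definitions, every tunable parameter with its default and
rationale, the synthetic-data model and its limits, and known
limitations.
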