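---
title: "Designing and evaluating target-capture genotyping panels with panelsnp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and evaluating target-capture genotyping panels with panelsnp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelsnp)
```

## The problem

Genotyping by target sequencing (GBTS) replaces whole-genome resequencing
with deep sequencing of a fixed set of genomic fragments pulled down by
hybridization probes ("baits") in solution. A useful panel needs markers
that are informative in the breeding population, technically capturable,
and spread evenly enough over the genome to support background selection,
kinship estimation and association scans. `panelsnp` implements the full
computational side of building and evaluating such a panel — modeled on a
45K-probe liquid-phase chip for pepper, but applicable to any diploid
species with a reference genome and population variant calls.

The pipeline has four stages:

1. **Core-site selection** (`select_core_sites`): from a multi-sample VCF,
   keep biallelic SNPs and small indels that satisfy, per site:
   mean depth $\ge$ 10X, minor allele frequency $> 0.05$, missing-call
   fraction $< 0.20$, heterozygosity ratio $< 0.05$, pairwise LD
   $r^2 < 0.4$ after windowed pruning, and a probe region free of
   microsatellites (SSRs) and ambiguous bases. A/T and C/G SNPs are
   *demoted*, not removed: they read identically on both strands, so they
   need two probe oligos instead of one and are simply more expensive.
2. **Panel layout** (`find_gaps`, `fill_gaps`, `build_panel`): place the
   trait-linked foreground sites, detect vacant intervals of 70 kb or more,
   and fill them greedily from the background pool to approach even
   genome-wide spacing.
3. **Probe design** (`design_probe_window`, `single_copy_check`): a 110 bp
   window per site with GC content in [30, 80]%, no N, no SSR, and a
   single-copy $\pm$200 bp context genome-wide.
4. **Evaluation** (`capture_report`, `post_capture_filter`,
   `allele_presence_table`, `vanraden_kinship`, `binary_assoc_scan`,
   `group_qtls`): capture-efficiency QC, post-capture marker filtering,
   phenotype-stratified genotype tables, kinship summaries, and a
   simplified marker-trait association scan with Bonferroni thresholding,
   QTL grouping and $\pm$2 Mb candidate-gene windows.

## Statistical definitions

For a site with $n$ non-missing diploid calls of which $n_{het}$ are
heterozygous and $n_{alt}$ homozygous-alternate, the alternate allele
frequency is $p = (2 n_{alt} + n_{het}) / 2n$, the MAF is
$\min(p, 1-p)$, and the heterozygosity ratio is $n_{het}/n$. Boundary
semantics follow the selection criteria wording exactly: depth is
inclusive ($\ge 10$), the rest strict. The post-capture marker filter uses
the complementary removal wording (remove when MAF $< 0.05$, missing
$> 0.1$, het $> 0.8$), so boundary values are kept there.

LD is the squared Pearson correlation of unphased allele dosages (0/1/2)
over samples non-missing at both sites — the genotypic $r^2$, appropriate
because input genotypes are unphased. Pruning is windowed (50 sites, step
5 by default) and greedy: the worst pair at or above the threshold loses
its lower-MAF member (ties: the site at the larger position). The
procedure is deterministic and, with the window spanning the whole
instance, identical to an exhaustive single-window pruner — which is how
the test suite verifies it.

Kinship is the VanRaden genomic relationship,
$K = Z^\top Z / \sum_j 2 p_j (1 - p_j)$ with $Z$ the per-marker
mean-imputed, $2p_j$-centered dosage matrix. Values are deliberately left
unnormalized, so inbred duplicates can exceed 1 — matching how such
panels summarize germplasm relatedness (fractions of pairs in [0, 0.5]
and above 1.0).

The association scan is a deliberately *simplified* single-marker allelic
chi-square: a 2$\times$2 allele-by-phenotype table per marker, Pearson
statistic with 1 df, no continuity correction, optional Fisher fallback
when an expected cell is below 5. There is no mixed model and no
structure/kinship correction; the scan exists to validate panel
informativeness on synthetic truth, not to replace a production GWAS.
Because the allelic test assumes the two alleles of an individual are
independent draws, it is anticonservative in inbred material (variance
inflation $\approx 1 + F$); its type-I calibration therefore holds for
outbred populations and its use on selfed germplasm should be treated as
a ranking, not a calibrated test.

## Tunable parameters

| Parameter | Default | Where | Meaning |
|---|---|---|---|
| `min_depth` | 10 (X) | `filter_thresholds` | minimum mean per-site depth |
| `min_maf` | 0.05 | both filters | informativeness floor |
| `max_missing` | 0.20 / 0.10 | selection / post-capture | missingness caps |
| `max_het` | 0.05 / 0.80 | selection / post-capture | heterozygosity caps |
| `max_r2` | 0.4 | `ld_prune` | LD pruning threshold |
| SSR copies | 8/5/4/4/4/4 | `ssr_spec` | min copies, motif length 1–6 |
| `probe_length` | 110 bp | `panel_config` | capture oligo length |
| `gc_min`, `gc_max` | 30, 80 (%) | `panel_config` | inclusive GC bounds |
| `max_shift` | 40 bp | `panel_config` | window search radius |
| `gap_threshold` | 70,000 bp | `panel_config` | vacant-interval trigger |
| `flank` | 200 bp | `panel_config` | single-copy segment flank |
| `min_identity`, `min_cov` | 0.80, 0.50 | `panel_config` | duplication call |
| retention | 0.70 | `retain_samples` | per-sample capture bound (inclusive) |
| `merge_dist` | 10 Mb | `group_qtls` | QTL single-linkage distance |
| `flank` | 2 Mb | `candidate_window` | candidate-gene extension |

The SSR copy thresholds are not fixed by the design brief ("free of simple
sequence repeats"); the defaults follow common microsatellite-survey
conventions and are fully configurable. The 10 Mb QTL merge distance is a
declared stand-in for whatever linkage criterion the original analysis
used: it reproduces the published grouping of the nine helical-fruit
markers (largest within-group span 11.5 Mb with a 6.9 Mb largest internal
gap, smallest between-group distance $\approx$168 Mb) and is exposed as a
parameter.

## Design choices where the brief was open

**Probe window placement.** The brief fixes length and GC bounds but not
where the variant sits in the 110-mer. We center it (0-based offset 55)
and, when the centered window violates a constraint, scan shifts
$-1, +1, -2, +2, \dots$ up to $\pm$40 bp, taking the first valid window —
nearest-first so the variant stays as central as possible, negative first
so ties resolve toward the lower coordinate. Windows are clipped at
contig ends with the variant kept strictly inside.

**Single-copy testing.** The original workflow calls BLAST on each
$\pm$200 bp segment. We implement the same decision with a seeded
exact-match search: exact 21-mers sampled every 10 bp along the segment
are located genome-wide on both strands and each hit is extended without
gaps to an implied full-segment alignment; a secondary locus at $\ge$80%
identity over $\ge$50% of the segment disqualifies the site. Ungapped
extension cannot chase diverged, indel-riddled paralogs the way
Smith-Waterman would, but it is exact for the recent, high-identity
duplications that actually break capture probes, and it has zero false
negatives on planted exact duplications (a property the test suite
enforces).

**Gap filling.** The brief states the goal (balanced distribution) and
the 70 kb trigger, not an algorithm. We repeatedly take the largest
remaining sub-gap and add the unused pool site nearest its midpoint
(ties: lower coordinate) until every sub-gap is below the threshold or no
candidate remains; unfillable sub-gaps are reported as residual. The rule
is deterministic and never increases the maximum adjacent distance.

**Multiallelic records** are split into one biallelic site per ALT
allele, each genotype recoded against that ALT; this keeps all filter
arithmetic biallelic. Split sites at one position get `contig_pos_alt`
ids. Only diploid GT is accepted; phased separators are treated as
unphased.

**Foreground sites are never dropped.** A trait-linked site that fails
probe design or the single-copy test is flagged and excluded from spacing
statistics, but stays in the panel table: trait coverage outranks spacing
aesthetics, and silent loss of a foreground marker is the one failure a
panel designer cannot tolerate. "Functional segments" are carried as
foreground-role sites with a segment tag — the minimal faithful model, as
the brief never defines them operationally.

## The synthetic-data generator

Every input the pipeline consumes can be generated with recorded ground
truth: genomes (i.i.d. bases at a target GC with planted SSRs and
segmental duplications), populations (true MAFs, LD blocks via latent
block haplotypes copied with fidelity $\sqrt{r^2_{target}}$, independent
missingness, negative-binomial depth), capture count matrices
(per-probe dropout, zero-truncated negative-binomial counts), and binary
or categorical phenotypes driven by planted causal sites.

Two generator choices deserve comment:

* **Inbreeding (default 0.95).** Pepper germplasm collections are
  predominantly selfed lines, which is the only regime in which a
  heterozygosity cap of 5% makes sense as a *quality* filter — under
  outbred Hardy-Weinberg at MAF 0.3 every site carries $\approx$42%
  heterozygotes and the filter would reject the entire genome. The
  generator therefore makes 95% of samples fully homozygous selfed lines
  by default; the `het_excess` knob then creates the paralog-collapse
  offenders the het filter exists to catch.
* **Negative-binomial depth** (not Poisson), so the 10X depth filter is
  exercised against realistically overdispersed coverage.

What the generator does **not** emulate: recombination maps and
coalescent LD decay (blocks are rectangular), allele-frequency spectra
shaped by demography, reference bias, or capture chemistry (GC-dependent
efficiency). Passing tests therefore demonstrate the pipeline's
decision logic and statistical calibration, not field performance on any
real germplasm collection.

## Numerical conventions and degenerate inputs

* Coordinates: VCF and internal sites are 1-based; BED and probe windows
  are 0-based half-open; gene/window overlap uses half-open semantics.
* A site with every call missing has undefined statistics and fails
  filtering with reason `no_data`; a monomorphic pair has undefined
  $r^2$ and is never pruned; a monomorphic marker gets statistic 0 and
  p = 1 in the association scan and is excluded from the kinship scaling
  sum.
* SSR reports cover the full maximal periodic run (including a trailing
  partial copy); `copies` counts full copies; the motif is the
  lexicographically least rotation of the primitive unit, so one run is
  never double-reported under different phases or motif multiples.
* All simulation functions take a mandatory integer seed and are
  reproducible to the byte; the panel builder is deterministic, so
  identical inputs and configuration give byte-identical BED/FASTA
  outputs.

## Validation scale

The test suite validates each primitive against an independent oracle at
sizes where the oracle is exact: the LD pruner against a brute-force
single-window pruner on 50 instances of 20–60 sites; the SSR scanner
against a naive $O(n^2)$ scanner on 1,000 random 110-mers; window/gene
overlap against a naive scan on 200 random windows; kinship against the
direct formula. Statistical guarantees use simulated populations of
200–500 samples (420 — the evaluated germplasm count — for filter
recovery), 10–2,001 sites, with 100 seeds for causal-marker recovery
(n = 400, penetrances 0.9/0.1, 2,000 null markers) and 200 seeds for
null calibration of the scan (n = 200, 1,000 markers, outbred). Genomes
of 0.05–1.5 Mb keep the exhaustive checks exact while exercising every
code path; nothing in the pipeline is scale-dependent beyond linear cost
in sites and samples.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_genome(c(chr1 = 400000L), gc_target = 0.45, seed = 1)
pop <- simulate_population(sim$genome, n_samples = 100, n_sites = 120,
                           maf = 0.3, depth_mean = 40, seed = 2)
core <- select_core_sites(pop$gm, sim$genome)
pool <- pop$gm$sites[match(core$core$id, pop$gm$sites$id), ]
catalog <- data.frame(trait = "fruit_shape", contig = "chr1",
                      pos = 150000L, ref = "A", alt = "G")
panel <- build_panel(catalog, pool, sim$genome,
                     panel_config(check_single_copy = FALSE))
panel
write_probe_bed(panel, "panel.bed")
write_probe_fasta(panel, sim$genome, "panel.fa")
```

## Known limitations

* No oligo thermodynamics: Tm, hairpins and cross-hybridization are out
  of scope; the GC window is the only hybridization proxy.
* The association scan is uncorrected for structure or kinship and
  anticonservative under inbreeding; it is a validation instrument.
* The single-copy test is ungapped; use a full aligner if diverged
  paralog families matter for your genome.
* QTL "contribution rates" (phenotypic variance explained) come from
  mixed-model fits in the original analyses; `panelsnp` ingests them for
  reporting and provides the allele-frequency difference as a model-free
  effect proxy, but does not estimate variance explained.
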