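---
title: "Methods: testing CLIP binding-site enrichment at alternative splicing events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: testing CLIP binding-site enrichment at alternative splicing events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clipsplice)
```

## The question and the statistical model

RNA-binding proteins such as SRSF2 and HNRNPC leave footprints on the
transcriptome that CLIP-seq experiments report as genomic intervals
(binding clusters or crosslink sites). Differential alternative-splicing
(AS) analyses of RNA-seq — skipped exons (SE), retained introns (RI),
mutually exclusive exons (MXE), alternative 5′/3′ splice sites
(A5SS/A3SS) — report per-event coordinates, inclusion levels (Ψ), their
between-condition difference (ΔΨ) and a BH-adjusted FDR. The question this
package answers quantitatively: do a factor's binding sites co-locate with
regulated splice events more often than chance placement would predict?

The test statistic is an overlap count. Each significant event contributes
its splicing-associated regions (target exon or intron plus flanking
exons), every region is expanded by a flank (default 200 bp, so binding
*near* a splice site counts, not only binding directly on it), and sites
are intersected strand-aware. Two statistics are exposed: the number of
sites hitting any region (`stat = "sites"`, the default, matching a null
that shuffles sites) and the number of events hit (`stat = "events"`, the
event-centric proportion usually quoted alongside).

The null model is an empirical, constrained permutation:

1. Sites are classified **exonic** or **intronic** against merged exon and
   intron annotations. Sites touching both are *ambiguous* and randomly
   assigned; sites touching neither (intergenic) cannot be placed by the
   null and are excluded from shuffling (but retained in the observed
   count, and tallied in the result so the discrepancy is visible).
2. Each iteration re-places every site uniformly at random among all
   positions that preserve its **length**, **chromosome**, **strand** and
   **feature context**, lie fully inside one feature interval of that
   context, and do not overlap the original coordinates.
3. The overlap statistic is recomputed per iteration; over `n_iter`
   iterations (default 500) this yields a null distribution and the
   one-sided Monte Carlo p-value with the add-one correction,
   p = (1 + #{null ≥ observed}) / (n_iter + 1), which is never zero and is
   the standard estimator for resampled nulls. Ties count as exceedances.

Fold enrichment is the observed statistic over the null mean (undefined
when the null mean is zero).

## Numerical and design choices

Choices the contract left open, decided here once:

* **Coordinates.** Everything is 0-based half-open (BED convention;
  rMATS's `*_0base` columns are copied verbatim). Book-ended intervals
  merge, as in the default `bedtools merge`. A 1-bp overlap is an overlap;
  book-ended intervals share no base.
* **Intron definition.** Introns are the gaps between consecutive exons of
  a single gene; where genes overlap, exonic bases win (per chromosome and
  strand), so the shuffle's placement domain is a disjoint partition.
* **Ambiguous-site assignment** uses the exonic fraction among
  *unambiguous* sites (0.5 when there are none): the stated goal is to
  preserve the original composition, and the unambiguous fraction is its
  only unbiased estimate. Assignment is drawn once per run (classification
  precedes shuffling); per-iteration redraws are available via
  `reclassify_each_iter`.
* **Exact placement instead of rejection sampling.** The admissible start
  space is computed exactly — candidate feature intervals shrunk to valid
  starts for the site length, minus the exclusion footprint widened by
  length − 1 in start space — and the draw is uniform over what remains.
  This is the same distribution a rejection sampler targets, but a single
  admissible slot is found with certainty and a site is skipped (with a
  warning and a tally) only when no admissible placement exists at all.
* **Shuffled sites may overlap each other**; only overlap with the
  original coordinates is forbidden. The null preserves site count, length
  distribution, chromosome, strand and feature-type composition — not
  inter-site spacing, GC content or mappability.
* **Strict thresholds.** Significance filters are strict inequalities
  (FDR < 0.05, |ΔΨ| > threshold, padj < 0.05, |log2FC| > 0.58 ≈ 1.5-fold),
  so boundary values are excluded. Set logic defaults to FDR-only event
  lists; the ΔΨ > 0.1 filter is applied for heatmap export.
* **Unstranded data is never dropped**: under strand-aware intersection an
  unstranded site matches either strand.
* **Consensus recipes** read "intersected across biological repeats"
  strictly: an interval must overlap a retained interval in *every* other
  replicate (for triplicates, pairwise-any would be more permissive; the
  stricter reading is reproducible and conservative). PAR-CLIP filtering
  (ReadCount ≥ 40) happens before the cross-replicate step; FLASH-CLIP
  merges within replicates summing PCR-duplicate scores before its
  score ≥ 10 filter. Thresholds keep their boundary values (≥, unlike the
  strict significance filters, matching the stated recipes).
* **qPCR conventions.** ΔCt = reference Ct − target Ct; relative
  expression 2^ΔCt; inclusion/exclusion ratio 2^(ΔCt_inc − ΔCt_exc);
  percent of input 100 · input_fraction · 2^(Ct_input − Ct_IP), with the
  input dilution made an explicit user-supplied fraction because identity
  cases (equal Cts, fraction f ⇒ 100·f %) pin the convention.
  Amplification efficiency is fixed at 2 (no efficiency correction).
  Technical replicates average on the Ct scale; SD > 0.5 cycles warns but
  drops nothing. Group comparisons delegate to standard routines: Welch
  t-test for two groups, one-way ANOVA with Šidák-adjusted pairwise
  p-values (1 − (1 − p)^m on pooled-variance t statistics) otherwise.
* **Reproducibility.** Every stochastic stage takes one master seed and
  derives per-iteration/per-stage sub-seeds from it, so serial reruns are
  bit-for-bit identical; result files embed their seed.

## What the synthetic data emulates — and what it does not

The generators produce the *processed forms* the pipeline consumes, never
reads: a toy genome of non-overlapping multi-exon genes (default 3
chromosomes × 1 Mb, 300 genes, 4–10 exons of 80–300 bp separated by
0.1–1 kb introns); per-contrast event tables (default 500 events,
SE-dominated) whose replicate Ψ values are logit-normal (SD 0.05) around
group means, with a 30% signal fraction shifted by ±0.3 Ψ in the contrasts
where the event fires; replicated CLIP files built from a common site set
(default 1000 sites of 20–50 bp) with small start jitter and
replicate-private noise sites, scores drawn so the ReadCount ≥ 40 and
score ≥ 10 filters genuinely bite (negative-binomial ReadCounts, mean 80,
dispersion 2; shifted-Poisson duplicate counts); DEG tables with
Gaussian-null log2 fold changes (σ = 0.2) and 10σ planted effects; and Ct
tables whose noiseless values embed an exact planted inclusion/exclusion
ratio under 0.2-cycle well noise.

Event p-values come from a two-sample t-test on logit-Ψ — the splicing
caller's junction-count likelihood is deliberately not re-implemented
(only its output dialect is), so simulated p-values are honest but not
rMATS's. Signal events fire per contrast independently (probability 0.7,
at least one contrast), giving the Venn machinery non-trivial regions.

A green test therefore establishes that the *statistical machinery* is
correct and calibrated on data satisfying its assumptions: uniform
placement within feature space, independent sites, clean annotations. It
does not establish robustness to real-data pathologies — mappability and
GC biases, clustered crosslinking, annotation errors, overlapping
transcript isoforms — which the permutation null does not model.

## Verification design

The package is verified against independent brute-force oracles rather
than against itself: per-base occupancy vectors for merge/overlap/
expand/feature-space, exhaustive enumeration for Venn partitions, a
hand-written BH implementation, and hand-computed consensus results on
bundled toy replicate files (including both threshold boundaries).
Statistical behaviour is checked end-to-end: on 200 null datasets (no
planted enrichment) the Monte Carlo p rejects at 5% between 2% and 10% of
the time; with 30% of 300 sites planted into regions covering ~3% of the
feature space, p < 0.05 in at least 95% of 50 seeded runs; shuffle
placements pass a chi-square uniformity test over a two-interval space.
Simulation sizes in the suite are scaled down from the defaults to keep
the full run within a CI budget; the properties tested are
size-independent.

## Limitations

* The null is conditional on the annotation: feature intervals too short
  to host a site silently shrink its placement space, and a site longer
  than every interval of its context is skipped (warned and tallied).
* Excluding intergenic sites from the shuffle while keeping them in the
  observed count makes the test slightly conservative-to-anticonservative
  depending on where those sites fall; the tallies in the result let the
  user judge.
* p-values are lower-bounded at 1/(n_iter + 1); claims below ~0.002
  need more than the default 500 iterations.
* No analytic (hypergeometric/GAT-style) alternative is provided, by
  scope: the empirical null is the method under study.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
cfg <- sim_config(n_chrom = 2, chrom_length = 2e5, n_genes = 50,
                  n_events = c(SE = 40, RI = 10, MXE = 5, A5SS = 5,
                               A3SS = 5),
                  n_sites = 80, enrichment = 0.2)
genome <- simulate_genome(cfg, seed = 1)
space <- build_feature_space(genome$genes)
ev <- simulate_events(genome$genes, cfg, "inhibitor", seed = 2)
sig <- filter_events(ev$tables$inhibitor)          # FDR < 0.05
regions <- gi_expand(event_regions(sig), genome$sizes, 200)
clip <- simulate_clip(space, regions, cfg, seed = 3)
consensus <- consensus_hitsclip(clip$replicates)
permutation_enrichment(sig, consensus, space, genome$sizes,
                       n_iter = 500, seed = 4)
```
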