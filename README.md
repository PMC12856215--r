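# clipsplice

Do a splicing factor's binding sites co-locate with regulated alternative
splicing (AS) events more often than chance would allow? `clipsplice` is
an R package for analysts who have (i) replicated CLIP-seq binding-site or
crosslink-site interval files and (ii) rMATS-style differential-splicing
result tables (plus, optionally, DESeq2-style differential-expression
tables and qPCR Ct measurements), and who want the complete downstream
workflow: replicate consensus building, significance filtering,
splicing-region extraction, a constrained permutation test with Monte
Carlo p-values, condition-dependency set logic, and Ct-based validation
statistics. A synthetic-data module generates every input with known
ground truth, so the whole pipeline runs and is tested without any
external download.

## The statistic at its core

For significant events (FDR < 0.05, optionally |ΔΨ| > 0.1) the
splicing-associated regions — target exon/intron plus flanking exons — are
expanded by ±200 bp and intersected with consensus binding sites,
strand-aware. The observed overlap count *O* (sites hitting regions, or
events hit) is compared with a null in which every site is re-placed
uniformly at random subject to keeping its **length**, **chromosome**,
**strand** and **feature type** (exonic sites stay inside merged exons,
intronic inside merged introns; ambiguous sites are randomly assigned to
preserve the observed composition) while never overlapping the original
coordinates. With null counts *O\*₁ … O\*ₙ* (default n = 500),

    p = (1 + #{ O*ᵢ ≥ O }) / (n + 1),      fold = O / mean(O*)

Replicate consensus follows three recipes: PAR-CLIP clusters are filtered
by ReadCount ≥ 40 then required to overlap every other replicate;
HITS-CLIP crosslink sites are merged within replicates first; FLASH-CLIP
sites are merged summing PCR-duplicate scores and filtered at score ≥ 10.
Differential sets use strict thresholds (padj < 0.05 and |log2FC| > 0.58
for expression). qPCR statistics use ΔCt = Ct(reference) − Ct(target),
relative expression 2^ΔCt, exon inclusion/exclusion ratio
2^(ΔCt_inc − ΔCt_exc), and ChIP/RIP percent of input
100 · f · 2^(Ct_input − Ct_IP).

## A worked example

```r
library(clipsplice)

cfg <- sim_config(n_chrom = 2, chrom_length = 2e5, n_genes = 50,
                  n_events = c(SE = 40, RI = 10, MXE = 5, A5SS = 5,
                               A3SS = 5),
                  n_sites = 80, enrichment = 0.2)
genome <- simulate_genome(cfg, seed = 1)
space  <- build_feature_space(genome$genes)
space
#> feature space: 350 exonic intervals ( 66,589 bp ), 300 intronic intervals ( 166,505 bp )

ev  <- simulate_events(genome$genes, cfg, "inhibitor", seed = 2)
sig <- filter_events(ev$tables$inhibitor)     # FDR < 0.05, strict
nrow(sig)
#> [1] 29

regions <- gi_expand(event_regions(sig), genome$sizes, 200)
clip    <- simulate_clip(space, regions, cfg, seed = 3)
cons    <- consensus_hitsclip(clip$replicates)

permutation_enrichment(sig, cons, space, genome$sizes,
                       n_iter = 500, seed = 4)
#> permutation enrichment (sites statistic, 500 iterations)
#>   observed: 25   null mean: 13.35 (sd 3.00)
#>   fold enrichment: 1.87   Monte Carlo p = 0.001996
```

Read: 25 consensus sites overlap the expanded regions of the 29
significant events; random feature-preserving placement yields ~13.4 on
average; none of the 500 shuffles reached 25, so p hits its lower bound
1/501 ≈ 0.002 and binding is ~1.9-fold enriched at regulated events.

The same run end to end, from the command line:

```sh
inst/cli/clipsplice run --out-dir results/demo --seed 1
```

writes the simulated inputs, consensus BED, `enrichment.json`,
`sets.json` (Venn/co-dependency partitions), the ΔΨ matrix and a manifest
with checksums and per-stage timings. Subcommands `clip`, `events`,
`enrich`, `sets`, `qpcr` and `simulate` operate on user-supplied files;
see `inst/cli/clipsplice --help`.

## Layout

- `R/intervals.R`, `R/genes.R`, `R/io.R` — BED-convention interval
  algebra, gene models, feature space, promoter windows, readers/writers
- `R/clip.R` — the three replicate-consensus recipes
- `R/splice_events.R` — rMATS dialects, filters, regions, observed overlap
- `R/enrichment.R` — classification, constrained shuffle, permutation test
- `R/differential_sets.R` — DEG filters, Venn partition, co-dependency
- `R/qpcr.R` — Ct statistics and group comparisons
- `R/simulate.R` — synthetic genome/events/CLIP/DEG/Ct generators
- `R/pipeline.R`, `R/cli.R`, `inst/cli/clipsplice` — driver and CLI
- `vignettes/clip-splice-enrichment.Rmd` — the methods vignette
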