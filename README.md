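# FractionSeq

Subcellular RNA fractionation analysis of mRNA-processing efficiency, for
transcriptomics researchers studying why some expressed genes produce
little mature mRNA.

Chromatin-associated RNA mixes nascent transcripts with transcripts
retained on chromatin; nucleoplasmic RNA has been processed and released.
FractionSeq classifies genes by comparing **exonic** read counts between
the two fractions with a self-contained negative-binomial Wald test:

* **nucleoplasm-enriched** — log2FC(nucleoplasm/chromatin) > 1, BH-adjusted
  p < 0.05
* **chromatin-enriched** — log2FC < −1, adjusted p < 0.05
* **non-enriched** — everything else

and then quantifies the RNA-processing features that explain the
classification:

* **Splicing-efficiency index** per transcript:
  `se_raw = n_spliced / n_total` over transcript-overlapping read pairs
  (a pair is spliced when a mate's CIGAR contains an `N` gap), normalized
  by exon count, `se_norm = se_raw / n_exons`.
* **Read-through index** per gene: `RTI = log2(GB/TES + c)`, with `GB` the
  strand-specific signal summed TSS→poly(A) site, `TES` the signal over a
  window downstream of the poly(A) site, and `c` half the minimum positive
  `GB/TES` of the cohort. Low RTI means more transcription past the
  poly(A) site (weak cleavage/polyadenylation).
* **Chromatin-association index**: log2 enrichment of chromatin RNA over
  nascent-transcription exonic signal.
* **Expression-matched gene subsets** by iterative stratified
  subsampling (fixed n or fraction mode), matched until no pairwise
  Wilcoxon rank-sum test on the covariate is significant.
* **Scale-regions metagene profiles** (2.5 kb flanks, 4 kb scaled body,
  10 bp bins → 900 bins) and ratio profiles (e.g. IP/Input).

A synthetic-data module generates gene models (GTF), fraction count
matrices (TSV), paired-end alignments (SAM) and strand-specific signal
tracks (bedGraph) with known per-gene ground truth — expression,
enrichment effect, splicing probability, read-through fraction — so the
whole pipeline is testable without any external download.

## Worked example

```r
library(FractionSeq)

cfg   <- simulationConfig(nGenes = 600, seed = 1)
paths <- simulateDataset(cfg, "sim_data")

pc  <- pipelineConfig(
  annotation = paths$annotation, alignments = paths$alignments,
  trackFwd = paths$trackFwd, trackRev = paths$trackRev,
  counts = paths$counts, truth = paths$truth,
  outputDir = "results_run", seed = 1)
res <- runFractionationAnalysis(pc)

res$summary$se_norm$medians
#> chromatin-enriched   non-enriched   nucleoplasm-enriched
#>             0.0455         0.0636                 0.0822
```

Chromatin-enriched genes (simulated with junction splicing probability
0.5 against 0.7 / 0.9) show the lowest exon-normalized splicing index,
non-enriched genes sit in the middle, nucleoplasm-enriched genes splice
best — the group ordering the classification predicts. `res$summary$rti`
holds the analogous read-through medians and pairwise Wilcoxon p-values
(chromatin-enriched genes have the lowest RTI, i.e. the most signal past
the poly(A) site), and `results_run/` contains the per-gene TSVs
(enrichment calls, association index, splicing indices, RTI, matched
subsets, metagene profiles), each with a provenance header; re-running
the same config reproduces them byte for byte.

## Documentation

The methods vignette (`vignettes/fractionation-analysis.Rmd`) describes
the statistical model, every tunable parameter with its default and
rationale, what the synthetic data do and do not emulate, and the known
limitations. All exported functions carry full help pages.
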