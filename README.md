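# promark

Integration of promoter histone-mark dynamics with differential gene
expression across a developmental time course.

## The problem

H3K27me3 is a repressive chromatin mark laid down in broad, diffuse domains.
In developmental series, losing H3K27me3 over a promoter frequently
accompanies transcriptional activation of that gene, and gaining it
accompanies silencing. Given (i) aligned ChIP fragments for an IP and an
input channel per stage and replicate, (ii) a gene-level RNA-seq count
matrix across the same stages, and (iii) gene models, `promark` finds the
genes at this regulatory intersection: **HDEGs** — differentially expressed
genes carrying a significant promoter H3K27me3 domain whose promoter-signal
change opposes their expression change in at least one stage transition.

It is aimed at epigenomics analysts who want a transparent, testable,
end-to-end route from fragments and counts to that gene set, plus the
standard surrounding analyses: TPM expression classes, TSS metagene
profiles, peak annotation, and gene-set enrichment.

## The method

- **Broad-domain calling (island model).** Fragments (midpoint rule) are
  counted in w = 200 bp windows. A window with count k is *eligible* when
  P(X >= k | Pois(lambda_w)) <= 0.2, with lambda_w the genome-wide IP rate per
  window. Eligible windows merge across gaps of up to 3 windows. Each
  candidate island is scored by p = P(X >= n_IP | Pois(E)) with
  E = max(n_input * L_IP/L_input, len x genome-wide IP rate); islands with
  BH q <= 0.05 and fold = n_IP/E > 1 are retained.
- **Promoter signal.** Promoter = strand-resolved TSS +/- 5 kb. Level =
  mean over replicate pairs of (RPKM_IP + 0.1)/(RPKM_input + 0.1).
- **Differential expression.** Moderated negative-binomial Wald test:
  median-of-ratios size factors, method-of-moments dispersions shrunk
  toward a fitted mean-dispersion trend with weight df/(df + 20), Wald z on
  the log2 ratio of normalized stage means (pseudocount 0.5), BH across
  genes. DEG: padj <= 0.05 and |log2FC| >= 1 (inclusive).
- **Integration.** Per transition, cluster 1/3 = upregulated DEGs with
  falling promoter level, cluster 2/4 = downregulated DEGs with rising
  level; the union over transitions (negative-correlation set) intersected
  with the across-stage promoter-modified union gives the HDEGs.
- **Enrichment.** Hypergeometric ORA with fold enrichment (k/n)/(K/N), and
  a weighted running-sum GSEA with a gene-label permutation null.

A built-in synthetic generator plants broad domains (8-fold over a Poisson
background), negative-binomial fold changes, 100 anti-coupled true HDEGs and
100 decoys into a miniature 4 x 2.5 Mb genome, with full ground truth, so
every stage of the pipeline is testable without external data.

## Worked example

```r
library(promark)
run <- run_pipeline(run_config(synthetic = list(), seed = 1,
                               out_dir = "promark_out"), quiet = TRUE)
unlist(run$summary[c("n_deg", "n_negcorr", "n_modified", "n_hdeg")])
#>      n_deg  n_negcorr n_modified     n_hdeg
#>        154        132        718        100
unlist(run$recovery[c("sensitivity", "fdp")])
#> sensitivity         fdp
#>           1           0
run$summary$peak_counts
#> d33 d65 d90
#> 254 256 254
```

Reading: of 154 DEGs, 132 change opposite to their promoter mark in some
transition; 718 genes carry a promoter island at some stage; their
intersection recovers all 100 planted HDEGs with no false discoveries.
Per-stage peak counts track the planted domain load. `promark_out/`
holds the generated GTF, fragment BEDs, island BEDs, DE tables, the
per-gene integration table and `summary.json`.

A thin CLI wraps the same entry point:

```sh
inst/cli/promark run --config run.yaml --seed 1 --out results/
```

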