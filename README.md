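# hmcReg

Gene-regulation analysis from 5-hydroxymethylcytosine (5hmC)
enrichment. 5hmC, the TET-oxidation product of 5mC, accumulates over
the bodies of actively transcribed genes (with a dip at the TSS) and
at active enhancers. hmcReg turns a 5hmC IP/input track pair into:

* **Expression-state prediction** — a fully connected rectifier
  network (230 → 200 → 100 → 50 → 1, dropout 0.15, Adam at 1e-4)
  over a fixed 230-bin per-gene featurization
  (log2 IP/input RPKM ratios, z-scored), classifying genes as
  High/Low relative to the sample's median TPM, evaluated on
  held-out chromosomes.
* **Per-bin attribution** — DeepLift (Rescale) decoding of the
  trained network against a neutral constant reference, with exact
  summation-to-delta: Σ_b score_b = logit(x) − logit(ref).
* **Enhancer prioritization** — (i) Activity-by-Contact scores
  S(e,g) = A_e·C_eg / Σ_e' A_e'·C_e'g with 5hmC as the pluggable
  activity signal, power-law–scaled 10 kb Hi-C contacts, summit±250 bp
  candidates; (ii) a GraphSAGE classifier on a top-10 contact graph of
  10 kb windows (ICE-balanced, diagonal-median distance-normalized),
  decoded with a GNNExplainer-style edge mask to rank the
  interactions behind each gene's prediction.
* **Seeded synthetic data** — generators that plant every structure
  above (labels, body enrichment, enhancer loops, distance-decaying
  contacts) so the whole pipeline is testable without downloads.

Who it is for: epigenomics groups with 5hmC IP/input coverage
(CMS-IP, hMeDIP, hMe-Seal, ...), RNA-seq TPMs, ATAC peaks and
optionally Hi-C, who want expression-state calls and candidate
enhancer–gene links from 5hmC alone.

## Worked example

Everything below runs in about two minutes on a laptop from a fresh
session, using the synthetic genome (4 × 10 Mb chromosomes, 400
genes, planted effect size d = 2):

```r
library(hmcReg)

cfg    <- synthConfig(seed = 7)
gen    <- synthGenome(cfg)                    # genes, TPMs, enhancers
tracks <- synthTracks(cfg, gen)               # IP / input / ATAC + peaks

fm <- featurizeSample(gen$genes, tracks$ip, tracks$input)
fm <- labelFeatureMatrix(fm, gen$tpm)
fm
#> FeatureMatrix: 230 bins x 400 genes ( 400 labeled ); unstandardized

fit <- trainFcdnn(fm, testChrom = "chr4", valChrom = "chr3",
                  config = mlpConfig(seed = 7))
rep <- evaluateFcdnn(fit)
round(c(auc = rep$auc, accuracy = rep$accuracy), 3)
#>      auc accuracy
#>    1.000    0.990
```

An AUC of 1.0 on the held-out chromosome says the planted gene-body
enrichment (4-fold at its peak) is fully recoverable — the synthetic
genome is an oracle, not a benchmark. Decoding the model shows where
the signal lives:

```r
X   <- fit$samples[[1]]$features
ref <- findNeutralReference(fit$model, range(X))
round(ref$p, 4)                                # ~0.50: non-saturated
#> 0.5
sc   <- deepliftScores(fit$model, X[fit$samples[[1]]$folds$test, ],
                       ref$reference)
prof <- summarizeContributions(sc, fit$samples[[1]]$labels
                               [fit$samples[[1]]$folds$test])
head(order(-abs(prof$High$mean)), 5)           # strongest bins
#> [1] 123  76 153 168 130
```

Bins 116–125 are the first 10% of the gene body and 66–115 the
promoter bins downstream of the TSS — the top-ranked bins sit there,
matching where the generator plants its enrichment peak. Enhancer
prioritization on the same data:

```r
hic      <- synthHic(cfg, gen)
balanced <- lapply(hic$maps, function(m) iceNormalize(m)$map)

cand <- candidateRegions(tracks$peaks)         # summit±250, merged
cand$activity <- elementActivity(cand, tracks$atac, tracks$ip)
fits <- lapply(balanced, fitPowerlaw)
round(fits$chr1$gamma, 2)                      # recovers the planted decay
#> 1
pred <- abcScores(cand, gen$genes, balanced, fits, threshold = 0.02)
nrow(pred)                                     # thresholded element-gene pairs
#> [1] 3078
```

The graph route — contact graph, GraphSAGE, edge-mask explanation:

```r
maps  <- lapply(balanced, distanceNormalize)
graph <- buildGenomeGraph(maps, tracks$ip, tracks$input,
                          gen$genes, gen$tpm, k = 10, seed = 7)
sage  <- trainSage(graph, sageConfig(seed = 7))
pr    <- predictSage(sage, graph)
te    <- pr[pr$fold == "test", ]
round(evaluate(te$score, te$label)$auc, 2)
#> 0.99

imp <- explainNode(sage, graph, te$node[1], seed = 7)
topInteractions(imp, graph, 3)[, c("rank", "chrom", "start", "mask")]
```

`topInteractions()` lists the 10 kb windows whose edges most support
the node's predicted label; on the synthetic genome the planted
enhancer window appears in the top-10 for >90% of High genes.

A thin command-line wrapper over the same functions ships at
`inst/cli/hmcreg.R` (subcommands `synth`, `featurize`, `train-dnn`,
`eval`, `attribute`, `hic-normalize`, `graph-build`, `ghmcn-train`,
`ghmcn-predict`, `explain`, `abc-score`, `compare-regions`); every
run writes a resolved-config JSON next to its outputs.

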