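# enhloop

Linking non-coding GWAS variants to their target genes through
enhancer chromatin states, eQTL evidence, differential-expression
enrichment, and Hi-C-derived chromatin topology.

Most trait-associated SNPs fall in non-coding DNA. `enhloop` is for
researchers in regulatory genomics who want to ask, reproducibly and
with statistics they can audit: *is this variant in an enhancer, which
genes does it regulate, and does the 3D genome support that link?* The
package implements the full evidence cascade — catalog filtering,
region classification, 25-state enhancer annotation, eQTL joining with
Storey q-values, DEG enrichment, contact-matrix construction with
iterative correction, maximum-likelihood TAD segmentation, and
4C-style viewpoint loop calling — together with a synthetic-data module
that generates every input with planted ground truth, so the whole
pipeline is validated end-to-end.

## The statistics at the core

* **Enhancer annotation** — a non-coding SNP counts as an enhancer SNP
  when it lies in one of the six enhancer states (EnhA1, EnhA2, EnhAF,
  EnhW1, EnhW2, EnhAc) of a 25-state chromatin-state segmentation in at
  least one of the annotated epigenomes.
* **eQTL control** — Storey q-values with single-lambda
  $\hat\pi_0 = \min(1, \#\{p > \lambda\}/(G(1-\lambda)))$, corrected
  within chromosome-wise families; retained at q < 0.05 after removing
  cross-chromosome pairs and pseudogenes.
* **DEG overlap** — for overlap x between m DEGs and n eQTL genes in a
  universe of N analyzed genes,
  $P = \sum_{k \ge x} \binom{m}{k}\binom{N-m}{n-k}/\binom{N}{n}$,
  expected overlap $E = mn/N$, fold enrichment ratio $FER = x/E$.
* **TADs** — block-diagonal Gaussian model solved exactly per block
  count by dynamic programming on 2-D prefix sums; block count chosen
  by a slope heuristic on the RSS curve.
* **Loops** — upper-tail Poisson test of viewpoint contact counts
  against an isotonic distance-decay background, BH-adjusted at
  FDR 0.05, window of one fragment.

## Worked example

Generate the packaged synthetic scenario and run the cascade:

```r
library(enhloop)
sc  <- generate_scenario("demo", seed = 1)
res <- run_cascade(sc$config)
writeLines(write_report(res))
```

```
SNPs retained after catalog filter: 42
Non-coding: 37 (88.1%)
In enhancers (>=1 epigenome): 18 (48.6% of non-coding)
In brain enhancers: 14 (37.8% of non-coding)
With >=1 eQTL gene: 11 (eQTL genes: 24)
With >=1 differentially expressed eQTL gene: 8 (72.7%)
TAD co-localized with >=1 eQTL gene: 5 (45.5%)
Genes contacted by viewpoint loops: 3
```

Reading the funnel: of 42 retained associations, 37 variants are
non-coding; 18 of those sit in enhancer states in at least one
epigenome (14 in a brain epigenome); 11 enhancer SNPs have at least
one same-chromosome eQTL gene at q < 0.05 (24 genes in all); 8 of the
11 have an eQTL gene that is differentially expressed in at least one
case/control dataset; 5 co-localize with an eQTL gene inside the same
called TAD; and the configured viewpoint SNP's significant chromatin
loops land within 5 kb of 3 gene TSSs. Every one of these numbers
equals the scenario's planted truth — that equality is an acceptance
test.

The same cascade runs from the shell:

```sh
Rscript inst/cli/enhloop.R simulate --dir demo --seed 1
Rscript inst/cli/enhloop.R run --config demo/scenario.yaml
```

The enrichment statistic is also usable standalone:

```r
hypergeometric_enrichment(x = 18, m = 60, n = 24, N = 500)
#> overlap x = 18 of m = 60 vs n = 24 in N = 500; E = 2.880, FER = 6.25, p = 1.69e-13
```

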