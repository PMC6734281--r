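---
title: "From non-coding variants to target genes: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From non-coding variants to target genes: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enhloop)
```

# The problem

Most disease-associated SNPs from GWAS lie in non-coding DNA — introns
and intergenic space — where their mechanism is invisible to a
protein-centric reading of the genome. A recurring explanation is that
such variants sit in *enhancers* and perturb the expression of genes
that may be hundreds of kilobases away, reached physically through
chromatin loops inside topologically associating domains (TADs).
`enhloop` implements that interpretive cascade as a tested pipeline:

1. filter a GWAS-catalog association table by trait and p-value;
2. classify each variant's genomic region against gene models;
3. annotate non-coding variants with chromatin states across epigenomes
   and keep those inside enhancer states;
4. join variants to their eQTL target genes with FDR control;
5. test whether those targets are enriched among case/control
   differentially expressed genes (DEGs);
6. build contact matrices from Hi-C-style read pairs, balance them,
   segment TADs, and test SNP-gene TAD co-localization;
7. call significant viewpoint (4C-style) interactions and ask which
   gene promoters they reach.

Every stage is exercised end-to-end on synthetic data with planted
ground truth; the generators are first-class, tested code.

# Models and statistics

## Catalog filtering and region classes

Rows are kept when the trait matches a pattern **and** the association
p-value is strictly below the suggestive threshold `1e-6`; an explicit
include-list overrides the threshold, modeling a confirmed-SNP panel.
Strictness at the boundary follows the usual reading of "less than".
Duplicate rsIDs collapse to their smallest p — one association record
per variant, conservatively. Region classes use feature precedence
CDS > UTR > intron on 0-based half-open intervals (catalog positions are
1-based and converted on entry); the non-coding set is
\{intronic, utr, intergenic\}. UTR counts as non-coding because the
coding set is defined as missense plus synonymous variants only.

## Chromatin states

Segmentations use the 25-mnemonic vocabulary of the imputation-based
chromatin-state model; the six enhancer states are
`EnhA1, EnhA2, EnhAF, EnhW1, EnhW2, EnhAc`. Both sets are arguments, not
constants, since releases rename states. A variant "is in an enhancer"
when its position falls in an enhancer-state interval in at least one
epigenome; counts are tallied overall and over a configurable brain
subset, and a variant in both brain and non-brain enhancers reports as
brain. Positions exactly on a segment boundary belong to the segment
containing the 0-based position.

## eQTL control: Storey q-values

Raw eQTL p-values are corrected within each chromosome-wise family (all
retained associations whose SNP is on one chromosome), with the
single-lambda Storey estimator
$\hat\pi_0 = \min(1,\; \#\{p_i > \lambda\} / (G(1-\lambda)))$ at
$\lambda = 0.5$ and the step-up rule
$q_{(i)} = \min_{j \ge i} \hat\pi_0\, G\, p_{(j)} / j$. The
single-lambda variant is used because nothing in the method depends on
the spline-smoothed refinement; $\lambda$ is an argument. Associations
are retained at $q < 0.05$ after dropping cross-chromosome pairs and
pseudogene targets; a SNP's eQTL gene set is the union of its retained
genes across tissues (an "any-tissue" reading — the natural choice when
tissue provenance is heterogeneous).

## DEG calling

Three per-gene model types mirror how public expression datasets are
commonly reanalyzed: covariate-adjusted linear regression (RNA-seq
style), Welch t-tests, and covariate-adjusted logistic regression where
the likelihood-ratio test replaces the Wald test because quasi-separated
genes would otherwise lose power exactly where the effect is strongest.
FDR control across genes is Benjamini-Hochberg — the DEG stage specifies
only "FDR-adjusted", and BH is the default convention for that phrase.
A gene is a DEG at adjusted p strictly below 0.05. Expression is assumed
log-scale as provided; no normalization is added.

## Overlap statistic

For a dataset stratum with universe size $N$ (genes analyzed there),
$m$ DEGs, $n$ eQTL genes present in the universe, and overlap $x$:

$$P = \sum_{k=x}^{\min(m,n)} \frac{\binom{m}{k}\binom{N-m}{n-k}}{\binom{N}{n}},
\qquad E = \frac{mn}{N}, \qquad \mathrm{FER} = \frac{x}{E}.$$

The p-value is the one-sided upper tail (the question is
over-representation), evaluated on log binomial coefficients. The
universe is gene count, not probe count: probe-level duplication would
inflate $N$ with entries that cannot enter $x$. Genes absent from a
platform drop out of $m$, $n$ and $N$.

## Hi-C core

Read pairs are assigned to restriction fragments (HindIII `A^AGCTT`;
a motif at 0-based position $s$ cuts at $s+1$), canonicalized to
`frag1 <= frag2`, and filtered in a fixed order: exact duplicates, then
same-fragment pairs (self-ligation/dangling ends), then fragments above
the 99.5th coverage percentile. Each rule is switchable and the QC
report conserves counts. Matrices are binned at 100 kb by fragment
midpoint — fragment resolution is the data's native unit, so midpoints,
not read positions, define bin membership. The diagonal is stored once
and counted twice in marginals (`sum + trace = 2 x cis pairs`).

Balancing is classical equal-visibility iterative correction: divide by
relative marginals until the maximum deviation is below `tol` (default
`1e-7`, capped at 2000 sweeps), masking all-zero rows. The acceptance
surface is the balancing contract (equal marginals; exact recovery of
separable biases), not parity with any particular package's variant.

## TAD segmentation

The normalized matrix is modeled as block-diagonal under Gaussian
noise: entries in diagonal block $k$ share mean $\bar x_k$, all
off-block entries share one mean $\mu_0$. With $\mu_0$ fixed, the
least-squares cost of a segmentation is additive over blocks, so exact
optima for every block count $K \le K_{max}$ come from dynamic
programming with O(1) per-block cost via 2-D prefix sums; DP ties break
toward leftmost boundaries. $\mu_0$ is re-estimated from the off-block
entries of the current optimum (2 rounds by default; the estimate moves
negligibly afterwards).

$K$ is chosen by a slope heuristic: normalize the RSS-vs-$K$ curve and
take the point of maximum discrete curvature, requiring it to clear a
floor of 0.25 (else $K = 1$). A fixed BIC-style weight was piloted first
and rejected: residual distance decay inside blocks makes the per-$K$
improvement scale with matrix structure, so no single weight transfers
between a 60-bin and a 400-bin matrix, while the normalized-curvature
rule selects the planted $K$ in both regimes. The BIC rule remains
available via `penalty = "bic"`. Blocks are half-open in bin index;
a SNP or TSS in a boundary bin belongs to the block containing that bin.

## Viewpoint interactions

The viewpoint of a SNP is the fragment containing it plus the two
fragments sharing its flanking cut sites (a SNP exactly on a cut site
yields the two fragments meeting there). The background is a
distance-decay model: observed counts pooled in 25 log-spaced distance
bins divided by the number of possible fragment pairs per bin — the
Poisson maximum-likelihood rate per pair (a geometric mean would be
annihilated by the zeros that dominate fragment-resolution data) —
then made non-increasing by weighted isotonic regression. For each cis
fragment outside the viewpoint, the observed count (optionally a
centered rolling window; default window 1) is tested against the summed
decay expectation with an upper-tail Poisson probability, BH-adjusted;
calls are significant at adjusted p < 0.05. This explicit
Poisson-with-decay null replaces rank/permutation schemes: it makes the
null checkable (the suite verifies the empirical call rate under the
generator's null) while preserving the window parameter and FDR cut.
When loops are called in the cascade, the viewpoint profile skips the
top-coverage filter: targeted capture enriches exactly those fragments,
and the cut would remove the viewpoint itself.

# The synthetic scenario

`generate_scenario()` writes every input the cascade reads and returns
the planted truth. Default study conditions: two 5-Mb chromosomes,
70 genes (10% pseudogenes), 70 main-trait SNPs with log-uniform
p-values over $[10^{-9}, 10^{-4}]$ straddling the 1e-6 threshold (plus
trait decoys and two confirmed-list SNPs above the threshold), 8
epigenomes with 3 designated brain, three expression datasets of 20
cases vs 20 controls with a 2-SD planted DEG shift (one per model
type), CTCF/RNAPII peak tracks over 10 and 6 cell types, and two
120,000-pair Hi-C libraries per scenario with decay exponent -1,
intra-TAD fold 3, planted TAD widths of 5-12 bins at 100 kb, and
viewpoint loops of fold 15 under 40x capture enrichment (TCC with
target enrichment motivates the capture factor). Sizes were chosen so
the whole suite runs in minutes on one core while every stage keeps
non-trivial counts.

Design features that make the planted truth exact rather than
approximate:

* planted enhancer SNPs are carved into background tilings that use
  only non-enhancer states, and all other SNP positions are kept clear
  of enhancer states in every epigenome;
* decoy eQTL p-values are uniform on $[0.1, 1]$, clear of the
  significance region, so q-value control retains exactly the planted
  pairs; cross-chromosome and pseudogene decoys carry small p-values to
  prove those filters do the work;
* a fraction of eQTL SNPs receive target genes absent from the
  expression platforms (emulating real platform coverage gaps), making
  the per-SNP DEG-overlap flag deterministic: SNPs with measured genes
  always include a planted DEG, SNPs without measured genes cannot
  acquire one through a false positive;
* SNPs and gene TSSs are placed at least two bins away from planted TAD
  boundaries, so block membership is insensitive to boundary calls off
  by one bin;
* per-generator child seeds mean adding a generator never perturbs the
  others, and identical seeds give byte-identical data files.

What the generator does **not** emulate: realistic sequence content,
LD structure between SNPs, correlated expression modules, hierarchical
(nested) TADs, trans contacts beyond a tally, and read-level ChIP-seq
(peaks are emitted directly as intervals). Passing tests therefore show
that the pipeline's logic and statistics behave as specified under a
faithful forward model, not that any particular biological dataset
would yield particular numbers.

# Numerical choices and degenerate inputs

* All interval logic is 0-based half-open; 1-based point positions
  convert on entry. Overlap is strict (`[10,20)` does not meet
  `[20,30)`).
* `hypergeometric_enrichment` reports FER as missing with p = 1 when
  E = 0; constant genes get p = 1 with a warning; rank-deficient
  covariate designs abort naming the collinear columns.
* A chromosome with no cut site becomes one whole-chromosome fragment
  (warning); unknown chromosomes drop pairs into a QC tally.
* ICE masks all-zero rows and excludes them from convergence; the final
  rescaling keeps the total signal constant.
* Decay-model bins with no possible pairs fall back to the nearest
  informative bin at prediction time; expectations are strictly
  positive wherever data exist.
* Report percentages are computed from the same counts they accompany
  and printed at one decimal.

# Problem sizes

The test suite segments ~400-bin matrices for boundary recovery (20
planted TADs), checks DP optimality exhaustively at 12 bins, runs 100
null and 100 planted-loop viewpoint libraries of 60,000 pairs over
~1000 fragments, and one full scenario cascade; it completes in a few
minutes on a single core. The acceptance script re-generates the
scenario from its `--seed`, reruns the cascade, and recomputes recall,
error control, power and balancing contracts at the same sizes.

# Limitations

The TAD model is single-level block-diagonal Gaussian — no nested
domains, and likelihood parity with any specific segmentation package
is out of scope. The viewpoint null assumes Poisson counts around a
smooth decay; overdispersion in real libraries would make the FDR
anti-conservative and would motivate a negative-binomial extension.
The eQTL stage consumes association tables as given (no genotype-level
mapping), and probe-to-gene collapsing is expected upstream. Liftover
between genome builds and LD-based tag-SNP expansion are deliberately
absent.
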