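---
title: "Tracing the geographic origin of Bactrocera dorsalis specimens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing the geographic origin of Bactrocera dorsalis specimens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The oriental fruit fly (*Bactrocera dorsalis*) is a quarantine pest that is
regularly trapped in surveillance programmes or intercepted as larvae in
imported fruit far outside its established range. When a specimen turns up,
the first actionable question is *where it came from* — at minimum whether
it carries an African or an Asian genetic signature, since that narrows the
plausible introduction pathway (direct trade from Africa, re-exported Asian
produce, traveller luggage, and so on).

`flytrace` implements three complementary evidence streams for that
question, plus the consensus logic that combines them per specimen:

1. **Nuclear structure from genotype likelihoods** (`gl_covariance`,
   `nj_tree`): a sample-by-sample covariance matrix estimated directly from
   Beagle-format genotype likelihoods, usable even for specimens whose DNA
   was too degraded for confident hard genotype calls. PCA and a
   neighbour-joining tree of the same matrix place queries among reference
   populations.
2. **A diagnostic nuclear SNP panel** (`rfe_select`,
   `build_decision_tree`, `classify_specimen`): recursive feature
   elimination with a random-forest learner distils genome-wide genotypes
   down to a handful of strongly diagnostic SNPs, which are then compiled
   into a CART decision tree — the blueprint for a cheap targeted assay.
3. **COI barcode DAPC** (`find_clusters`, `fit_dapc`, `assign_barcode`,
   `region_profile`): mitochondrial barcodes are clustered into haplotype
   groups; a discriminant-analysis-of-principal-components model assigns
   queries to a cluster with a membership posterior, and each cluster's
   normalized regional profile converts the cluster into an origin call.

Because mitochondria are maternally inherited, streams 1/2 (nuclear) and 3
(mitochondrial) can genuinely disagree — mitonuclear discordance — and the
consensus layer (`combine_calls`) is deliberately conservative about that:
any disagreement, or any ambiguous barcode profile, blocks consensus.

## The models, in brief

### Genotype-likelihood covariance

For individual $i$ and biallelic site $j$ with likelihood triple
$L_{ij}(g)$, $g \in \{0,1,2\}$ alternate-allele copies, the estimator
iterates:

* site frequencies $f_j$ initialised from likelihood-weighted expected
  dosages;
* posterior expected dosages $E[g_{ij}]$ under a Hardy–Weinberg prior at
  the current *individual* allele frequency $\pi_{ij}$ (initially $f_j$);
* the standardized residual
  $R_{ij} = (E[g_{ij}] - 2f_j)/\sqrt{2f_j(1-f_j)}$ and covariance
  $C = RR^\top / M$;
* an update of $\pi$ from the rank-$k$ SVD of $R$, mapped back to
  frequency scale and truncated to $[\varepsilon, 1-\varepsilon]$.

Iteration stops when $\max|\Delta C| < 10^{-5}$ or after 100 sweeps
(`tol`, `max_iter`; $\varepsilon = 10^{-4}$). These defaults follow the
conventions of likelihood-based PCA tools for low-depth data; the methods
literature does not prescribe sharper values and results are insensitive
within an order of magnitude. Missing data contribute their posterior
expectation — never an imputed hard call — which is precisely why the
formulation tolerates specimens with very low coverage. With degenerate
(one-hot) likelihoods and no missingness the estimator converges in two
sweeps to the classical standardized-genotype covariance, a property the
test suite checks against an independent hard-call oracle.

The NJ tree is built from the covariance-implied Euclidean distance
$d_{ij} = \sqrt{c_{ii} + c_{jj} - 2c_{ij}}$, so PCA and tree are two views
of one matrix. The NJ implementation is the classic Saitou–Nei
agglomeration; a negative branch length is clamped to zero and its deficit
shifted to the sister edge, keeping all edges non-negative while
preserving the joined pair's path length (exactness on additive matrices
is unaffected and is tested).

Cluster membership on the PCA is, in practice, assessed by inspection; the
package automates only the simplest defensible rule (nearest per-origin
reference centroid on PC1–PC2, `pca_origin_call`) and otherwise accepts
externally supplied structure calls in the consensus layer.

### Diagnostic SNP panel

Reference genotypes are filtered (per-site missingness ≤ 1%, minor allele
frequency > 5%, mean depth in [8, 12] — thresholds chosen for a reference
panel standardised to roughly 10× coverage), then imputed. Imputation is a
deterministic class-conditional mode (ties to the lower dosage, global
mode as fallback) rather than the stochastic proximity-based routine
common in random-forest workflows: at a ≤ 1% missingness ceiling the two
agree except on ties, and determinism makes every downstream ranking
reproducible.

RFE holds out a stratified 30% for internal validation, then ranks sites
by mean decrease in Gini impurity within repeated stratified k-fold
cross-validation, scoring panel sizes along a grid (1, 2, 5, …, 200 by
default). The forest uses 500 trees and the learner's default √p feature
sampling. The best panel is refit and validated over repeated 75/25
splits, reporting per-class accuracy mean ± SD.

The final panel is distilled into a CART tree over allele dosages. Because
dosages are integers in {0, 1, 2}, the only meaningful split thresholds
are 0.5 and 1.5, so the tree search is exact over that set with Gini
impurity, growing until leaves are pure or smaller than `min_leaf`
(default 5, in line with common CART minimum-bucket practice).
Classification of a query is deliberately conservative: if *any* site the
tree uses is missing, absent, or covered below 6 reads (boundary
inclusive: depth 6 passes), the specimen is returned as `NA` rather than
risking a call through allelic dropout at a heterozygous site.

### COI barcode DAPC

Aligned barcodes are curated (internal stop codons under the invertebrate
mitochondrial code, in which only TAA/TAG terminate; sequences with more
than `max_ambiguous` ambiguity characters; gaps private to fewer than
`gap_consistency` of sequences), optionally trimmed to the window spanned
by a reference row (default 658 reference positions, the classic barcode
fragment), and one-hot encoded: each polymorphic alignment column
contributes one indicator per observed base, with gaps and ambiguity
codes treated as missing. Indicators within a column are ordered major
allele first.

Unsupervised clustering runs k-means (10 seeded restarts) on the leading
principal components (fewest PCs reaching 90% variance by default; a
fixed count is also supported since either convention appears in
practice) for $k = 1..k_{\max}$, scoring each solution with
$\mathrm{BIC}(k) = n\ln(\mathrm{WSS}_k/n) + k\ln n$. The number of
clusters follows the diffNgroup heuristic: successive BIC decreases are
split into two groups by 1-D Ward clustering and $k$ is one past the last
"large-decrease" member; if the BIC curve never decreases the minimum
(i.e. $k = 1$) is returned. Both the BIC formula and the two-group rule
are exposed as code rather than config because they *are* the selection
criterion; sensitivity can be assessed through the returned `bic_curve`.

The retained-PC count for the final model is chosen by repeated
stratified 90/10 cross-validation (30 repeats by default), maximizing
mean test-set assignment accuracy with ties broken toward fewer PCs. The
DAPC itself is Fisher discriminant analysis on the PC scores with
$k - 1$ axes scaled to unit pooled within-class variance, so Euclidean
distance in discriminant space equals the usual LDA Mahalanobis
distance; membership posteriors are a distance softmax under equal priors
and an identity covariance in that space,
$P(g \mid z) \propto \exp(-\tfrac12\lVert z - \mu_g\rVert^2)$. On balanced
training data this reproduces classical LDA posteriors exactly (tested
against an independent implementation).

Each cluster's **regional profile** corrects for unequal sampling effort:
for cluster $c$ and region $r$ with $n_r$ reference barcodes of known
origin, the raw proportion $p_{cr} = \mathrm{count}_{cr}/n_r$ is
renormalized across regions to sum to one. Profiles are mapped to origins
through a fixed region → origin map in which the Mascarene islands count
as *Asian* — their populations are genetically aligned with Asia despite
the geographic proximity to Africa. A cluster is called for an origin
when that origin's summed share reaches the dominance threshold (default
0.90); otherwise the call is `ambiguous:` followed by every origin at or
above the minor floor (default 0.05), in descending share. The defaults
are set so that a cluster with ≈ 95% of one origin is called cleanly
while a 70/25 mixture yields an ambiguous call — the behaviour needed to
reproduce published worked examples of both kinds.

### Consensus

Per specimen, `combine_calls` ignores `NA` calls, treats any ambiguous
barcode profile as blocking (even when its candidate set contains the
nuclear origin — the strictness is required to reproduce the published
"no consensus" verdict for exactly such a case), and otherwise requires
all remaining calls to agree. Disagreement yields `final_origin =
"discordant"`. The package ships the transcribed per-method call table
for the 22 Belgian trap/interception specimens
(`read_interception_table()`) as a worked example and regression fixture.

## What the synthetic data emulates — and what it does not

`simulate_genotypes` draws neutral loci from a Balding–Nichols model: a
shared ancestral frequency per locus, population frequencies beta-drawn
around it with concentration set by the target differentiation (the
`divergence` parameter, approximately the expected FST; default 0.1 — a
deliberately moderate two-continent split, since no quantitative
Africa–Asia FST is established for reference panels of this kind).
Planted sites with explicit frequency pairs emulate the near-fixed
diagnostic differences the panel search is supposed to find. Depth is
negative-binomial with mean 10 (matching the ~10× standardisation of
real reference libraries) and moderate overdispersion; genotypes are
masked at the configured missingness and wherever depth is zero.

`simulate_barcodes` draws each individual's haplotype from its region's
pool over a shared haplotype set (two private haplotypes per region by
default), then applies independent per-site substitutions. A configurable
fraction of individuals draw their *mitochondrial* haplotype from a
different region's pool while keeping their nuclear label — planted
mitonuclear discordance, reproducing in silico the phenomenon where a
specimen's barcode contradicts its nuclear origin.

Features of real data the generator does **not** emulate: linkage
disequilibrium and recombination (loci are independent), codon structure
in barcodes (simulated sequences are not constrained to be stop-free, so
stop-codon curation applies to real coding alignments, not to synthetic
ones), haplotype sharing between regions beyond what the pools specify,
reference mislabeling, and cross-species introgression. Passing tests on
synthetic data therefore demonstrate the *mechanics* of recovery
(clustering, ranking, assignment, masking) under known truth — not the
field accuracy of any particular reference panel.

## Numerical choices and degenerate inputs

* Likelihood triples are renormalized on read (Beagle exports are often
  scaled); an all-zero triple is rejected.
* A genotype is forced missing wherever depth is 0, so zero-coverage
  cells cannot enter allele-frequency sums.
* k-means candidate $k$ is capped at the number of distinct score rows;
  zero within-cluster sums of squares are floored at machine epsilon
  inside the BIC log.
* A singular within-class scatter in the discriminant step (e.g. pure
  duplicated training rows) gets a small ridge, with a warning.
* Imputation ties break toward the lower dosage; indicator columns tie
  toward alphabetical base order after allele count.
* Queries sharing fewer than half of a DAPC model's indicator columns are
  declined (`insufficient_overlap`) rather than imputed into a guess.
* `nj_tree` clamps negative branch lengths to zero, shifting the deficit
  to the sister edge.

## Problem sizes used in the test and acceptance suites

The shipped suites run entirely on synthetic data at desk scale, chosen
as the smallest sizes at which each property is comfortably
non-marginal: covariance oracles at 40–50 individuals × 200–500 sites;
cluster recovery at 120 barcodes over six pools; RFE recovery at 100+100
individuals with 2 planted sites among 200–500 neutral loci
(cross-validation folds and repeats are reduced below the full defaults
of 10×10, which target reference panels hundreds of individuals strong);
end-to-end barcode assignment at 135 barcodes with 15 held-out queries.
`scripts/acceptance.R` re-runs the same study conditions from a single
seed and writes the resulting accuracies and counts as JSON.

## Known limitations

* Resolution is continental by design (Africa / Asia / Pacific);
  finer-grained origin calls need denser regional reference sampling.
* The barcode stream inherits every caveat of mitochondrial markers:
  introgression, incomplete lineage sorting and shared haplotypes can
  misdirect a call even when the posterior is high — which is exactly why
  the consensus layer treats the nuclear streams as co-equal and refuses
  consensus on conflict.
* `curate_alignment` implements automatable proxies (stop codons,
  ambiguity load, private gaps) for what is, in practice, partly manual
  curation; it will not catch chimeric or mislabeled reference sequences.
* The visual step of calling population membership from a PCA/NJ plot is
  not automated beyond the nearest-centroid helper.
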