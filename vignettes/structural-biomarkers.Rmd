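---
title: "Structural network biomarkers: models, measures and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural network biomarkers: models, measures and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structmark)
```

## The idea

A conventional diagnostic biomarker is a gene (or gene set) whose expression
level separates disease states. `structmark` implements the alternative idea
of *structural* biomarkers: infer a gene-association network per condition,
expand each network into a population of gene-set-induced subgraphs, and use
quantitative graph invariants — numbers computed from the network topology
alone — as the feature vector for supervised classification. A biomarker is
then a property of the *system* (say, the graph energy of a pathway
subnetwork), not of any individual gene.

The pipeline has six stages, each independently usable:

1. **simulate** — synthetic two-condition expression data and gene sets;
2. **infer** — one C3NET association network per condition;
3. **extract** — gene-set-induced subgraph populations;
4. **measure** — eigenvalue- and entropy-based descriptor batteries;
5. **classify** — polynomial-kernel SVM under stratified cross-validation,
   for three arms: eigenvalue descriptors, entropy descriptors, and raw
   gene-expression biomarkers;
6. **uniqueness** — descriptor degeneracy (ndv) analysis.

## Graph model and the distance-scope rule

Graphs are undirected, simple and vertex-labelled, with vertices kept in
sorted order so that all matrix views, spectra and file outputs are
byte-reproducible. From a graph \(G\) with \(n\) vertices and \(m\) edges we
derive the adjacency matrix \(A\), the Laplacian \(L = \mathrm{diag}(d) - A\)
and the shortest-path distance matrix \(D\).

C3NET networks and induced subgraphs are usually disconnected, and \(D\) is
only finite on a connected graph. The package-wide rule — a design choice,
since the original analysis does not state one — is: **distance-based
quantities are computed on the largest connected component**, ties broken by
the lexicographically smallest vertex label; \(A\) and \(L\) always cover the
full graph. A caller who prefers hard failure can request
`distance_scope = "require_connected"`. When the largest component is a
single vertex (an edgeless graph), distance-based descriptors are undefined
and returned as `NaN`; `feature_table()` then drops and logs such rows, and
the pipeline's degeneracy stage excludes them.

## The eigenvalue battery (11 measures)

For a symmetric matrix \(M \in \{A, D, L\}\) with spectrum
\(\lambda_1 \ge \dots \ge \lambda_n\):

* adjacency: graph energy \(\sum_i |\lambda_i|\), Estrada index
  \(\sum_i e^{\lambda_i}\), spectral radius \(\lambda_1\), spectral gap
  \(\lambda_1 - \lambda_2\);
* distance: distance energy, distance Estrada index, distance spectral
  radius, smallest distance eigenvalue;
* Laplacian (\(\mu_i\)): Laplacian energy \(\sum_i |\mu_i - 2m/n|\),
  Laplacian Estrada index, algebraic connectivity (second-smallest
  \(\mu\)).

The concrete 11-measure battery is a reconstruction from the cited measure
families (energy, Estrada index, Laplacian energy and their distance
variants); the battery is a configuration argument so alternates can be
swapped in. Eigenvalues always come from a symmetric eigensolver —
characteristic-polynomial root finding is numerically unstable and never
used. Estrada indices are computed in log-sum-exp form; beyond an exponent
of 700 the natural value would overflow double precision, so the log-domain
value is reported and flagged (`estrada_log_scale` attribute).

## The entropy battery (10 measures)

All entropies are in bits (base-2 logarithm; the base is a package
convention, not prescribed by the measure definitions). Two constructions
are used:

**Information functionals.** A positive vertex weighting \(f(v)\) is turned
into a distribution \(p_v = f(v)/\sum_u f(u)\), whose Shannon entropy is the
descriptor. The two presets are \(f^V(v) = (n-1)/\sum_u d(v,u)\) (closeness
centrality — "vertex centrality" made concrete) and
\(f^P(v) = \sum_{j=1}^{\rho} c_j\,|S_j(v)|\) over the \(j\)-spheres
\(S_j(v)\), with the linearly decreasing coefficient preset
\(c_j = \rho - j + 1\) (\(\rho\) = diameter). Both are deterministic,
parameter-light defaults for functional families whose exact published forms
admit many variants; the `coefficients` argument keeps the sphere weighting
swappable.

**Partition entropies.** Entropy of the block-size distribution of a
partition: vertex orbits of the automorphism group (topological information
content), distance degrees, unordered endpoint-degree pairs of edges (the
configurable stand-in for the cited edge-equality criterion), the distance
value distribution over vertex pairs, plus the magnitude-weighted variant
\(W\log_2 W - \sum_i k_i\, d_i \log_2 d_i\) (with \(W\) the Wiener sum and
\(k_i\) pairs at distance \(d_i\)), the mean vertex distance-profile entropy,
the Balaban index
\(J = \frac{m}{\mu+1}\sum_{(u,v) \in E}(s_u s_v)^{-1/2}\) (\(s_v\) distance
degree, \(\mu = m-n+1\)), and an entropic symmetry index, reconstructed as
\(\log_2|\mathrm{Aut}(G)| + \sum_i (|O_i|/n)\log_2|O_i|\) over the vertex
orbits \(O_i\) (zero exactly on asymmetric graphs).

Orbits and automorphism group order are exact (BLISS canonical-labelling
search with union-find closure of the generators, via igraph), never a 1-WL
approximation — topological information content is defined on true orbits.
The test suite cross-checks every one of the ten measures against literal
brute-force enumeration (all \(n!\) vertex permutations, Floyd–Warshall
distances, explicit sphere counting) on *every* connected graph with up to
six vertices.

## C3NET inference

For each gene pair, mutual information is estimated; the default estimator
is the Gaussian one, \(\mathrm{MI} = -\tfrac12\ln(1-r^2)\) with the sample
correlation clipped to \(|r| \le 1 - 10^{-12}\) (a binned plug-in estimator
is retained for non-Gaussian stress tests). Each gene contributes at most
one edge — to its maximum-MI partner, kept only if that MI is significant —
so the network never has more edges than genes. Ties in the argmax go to the
lexicographically smallest partner.

Significance uses a permutation null. The default (`null = "max"`) records
the **maximum** MI over all pairs for each of `n_permutations` sample-label
permutations and thresholds at the \((1-\alpha)\) quantile of these maxima.
This controls the family-wise error of the whole edge set, which is what
makes "about \(\alpha\)-level false positives" true for the *network*: a
pooled per-pair null (`null = "pooled"`, also available) would let each
gene's maximum over dozens of null MIs exceed the pairwise threshold almost
surely, flooding the network with false edges. This is the one place the
package deliberately departs from a literal per-pair reading of the
threshold rule; the false-edge acceptance benchmark (planted \(r = 0.95\)
pairs among noise genes: 100% recall, well under 5% false edges) only holds
under family-wise control.

## Subgraph extraction and the two populations

Gene sets (GMT format, standing in for GO biological-process terms) induce
vertex subgraphs on each condition network; subgraphs with fewer than
`min_genes` (default 5, always explicit in pipeline configs — the original
threshold is not recoverable) present genes are dropped. Induced subgraphs
may be disconnected and are kept; only the size filter applies. The two
resulting populations — benign-derived and cancer-derived subgraphs — are
the classification instances of the structural arms, and their sizes may
legitimately differ between conditions.

## Classification

Features are ranked by information gain (mutual information between the
feature discretised into `n_bins = 10` equal-frequency bins and the class
label); the biomarker arm keeps the top 10 genes. The classifier is a
soft-margin SVM with polynomial kernel
\((\gamma x^\top y + c_0)^d\), trained by a deterministic SMO solver
implemented in the package (no SVM library is available in the declared
dependency set; the solver uses the maximal-\(|E_i - E_j|\) second-choice
heuristic with a bounded fallback scan instead of random working-set
selection, so fits are reproducible).

Cross-validation is stratified; **feature selection, z-scoring and grid
search are all refit inside each training fold**, so no statistic of a
held-out row ever reaches training. A dedicated canary test verifies both
directions: selecting features on all rows before CV inflates accuracy on
pure-noise data to ~0.7, while the in-fold pipeline stays at chance.
Hyperparameters are chosen by exhaustive search (default grid
\(d \in \{1,2,3,4\}\), \(C \in \{0.1,1,10,100\}\),
\(\gamma \in \{0.001,0.01,0.1,1\}\)) scored by inner-fold accuracy; whether
the original analysis used nested or single-level selection is ambiguous,
and the nested (inner-training-split) variant was chosen because it is the
leak-free reading. Metrics are macro-averaged over the two classes, which
forces sensitivity = specificity = recall on any binary confusion matrix —
the structural explanation for duplicated rows in published error tables.
The reported uncertainty is the standard error (fold SD / \(\sqrt{k}\)).

## Degeneracy (ndv)

For each descriptor and network group, `ndv` counts networks whose value
collides with at least one other network's value, within relative tolerance
`tol` (default \(10^{-10}\); exact equality would understate degeneracy for
analytically equal values reached by different floating-point paths).
Equality groups are formed by single linkage on the sorted values. The
relative column is ndv divided by group size; Konstantinova's sensitivity
\((N - \mathrm{ndv})/N\) is reported alongside. Groups must be pairwise
non-isomorphic for the analysis to be meaningful — `uniqueness_report()`
errors on duplicates, and the pipeline removes isomorphic duplicates within
each condition first (logged). Pooled ("all") counts can exceed the
subgroup counts because structurally identical subgraphs may exist *across*
conditions; that is expected and is why the per-group columns are the
informative ones on synthetic data.

## What the generator emulates — and what it does not

`simulate_expression()` draws module genes from a one-factor
equicorrelation model (\(x_g = \sqrt{\rho} z_m + \sqrt{1-\rho}\,\epsilon\)),
the minimal covariance structure that makes per-gene maximum-MI selection
meaningful. The two conditions differ by *re-wiring*: a fraction (default
0.5) of each module's membership is re-assigned in the cancer condition, so
the conditions differ in network topology — mirroring the premise that the
two disease states have different network structure — rather than merely in
correlation strength. Differential expression is a mean shift (default 10
genes at 2 within-gene SDs) in the cancer condition. Defaults (120 genes,
50 samples per condition, 8 modules of 5 at \(\rho = 0.8\), 60 gene sets of
5–20 genes, half module-aligned) are desk-scale stand-ins for seven
microarray studies with 4–56 samples per condition; they were fixed before
the acceptance outcomes were measured and are not tuned.

Not emulated: microarray platform and batch effects, probe-to-gene mapping,
heavy-tailed or non-Gaussian expression marginals, hub-dominated scale-free
topology, and cross-study merging (a shared gene universe stands in for the
intersection-of-genes step). A green benchmark therefore establishes that
the pipeline recovers *planted* structure of this stated kind — it does not
certify performance on real microarray populations.

One empirical consequence, reported by the acceptance suite rather than
asserted: on this synthetic world the entropy arm classifies *better* than
the eigenvalue arm (roughly 0.84 vs 0.68 accuracy at the default
configuration), the reverse of the published real-data ordering. The
comparison is data-dependent; the acceptance criterion records the observed
ordering and requires only that both arms beat chance.

## Numerical choices and degenerate inputs

* Eigen-decomposition: LAPACK symmetric solver; spectra sorted
  non-increasing; relabelling invariance asserted at \(10^{-9}\) relative.
* \(0 \log 0 := 0\) throughout; probability vectors validated to sum to 1
  within \(10^{-9}\).
* Estrada overflow: log-domain above exponent 700, flagged.
* Edgeless graphs: distance-scope collapses to one vertex; distance-based
  descriptors are `NaN`, dropped (with a message) at feature-table
  assembly.
* MI clipping at \(|r| = 1 - 10^{-12}\) keeps duplicated genes finite.
* All stochastic stages take explicit integer seeds and restore the
  caller's RNG state; reruns are byte-identical.

## Worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(output_dir = "run1", seed = 1,
                       grid = svm_grid(degree = 1:3, cost = c(1, 10),
                                       gamma = c(0.01, 0.1)))
res <- run_pipeline(cfg)
res$cv$eigenvalue   # six error measures, mean and standard error
res$uniqueness      # ndv / sensitivity per descriptor and group
```

## Known limitations

* The SMO solver is sized for hundreds of rows (the scale this pipeline
  produces), not tens of thousands.
* Exact automorphism search is capped (default 500 vertices).
* Only undirected simple graphs; weighted and directed variants of the
  descriptors are out of scope.
* The eigenvalue and entropy batteries are reconstructions of measure
  families; both are configuration-driven so alternate definitions can be
  swapped in without touching the pipeline.
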