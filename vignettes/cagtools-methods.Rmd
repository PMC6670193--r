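---
title: "Co-abundance gene groups: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-abundance gene groups: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cagtools)
```

## The problem

Shotgun metagenomes yield abundance estimates for millions of microbial
genes, but genes are not independent observations: genes carried by the
same genome, plasmid, or operon share an abundance trajectory across
samples. `cagtools` groups genes into Co-Abundant Gene groups (CAGs) and
performs disease-association inference at the CAG level. This vignette
records the models, the parameters that matter, and the design decisions
taken where more than one reasonable choice existed.

## Clustering model

Gene profiles are compared with the cosine distance on their
relative-abundance vectors across samples. Cosine is scale-invariant per
gene — multiplying a gene's whole profile by a constant changes nothing —
which is the right property when genes of one genetic element differ by
length and mappability biases but share a trajectory. Note what cosine is
*not* invariant to: per-sample depth differences. That is why columns are
sum-normalized to relative abundance before any distance is computed.

Clustering is agglomerative average linkage (UPGMA): the distance between
clusters is the mean cosine distance over all member pairs, and the tree
is cut at a fixed cophenetic height `max_dist`. The cut is inclusive
(`<= max_dist`), fixing a boundary case the method description leaves
open. Consequently the mean pairwise distance inside every resulting CAG
is at most `max_dist`, which the tests assert on the oracle output.

### Exact search at ANN cost

The all-pairs distance matrix is infeasible at millions of genes, so
`find_cags()` proposes neighbors with an HNSW cosine index and verifies
every proposed pair exactly. Pairs at or below `max_dist` define a graph;
its connected components can be clustered independently because a UPGMA
merge below the cut implies at least one member pair below the cut — a
merge can never bridge two components of the threshold graph. Within each
component exact UPGMA runs and is cut; subsequent rounds repeat the
search over the resulting clusters until no merges occur.

Two facts make the scheme exact rather than approximate once the
candidate search is exhaustive. First, the mean member-pair distance
between clusters A and B has a closed form,
`1 − (S_A · S_B) / (|A||B|)`, where `S_X` is the sum of the unit-norm
member profiles — so cross-round merge tests are exact at any cluster
size and no centroid approximation is ever needed. Second,
`stats::hclust(..., method = "average", members = sizes)` performs
size-weighted average linkage, which on mean member-pair inputs is
exactly UPGMA over the underlying genes. When `ann_k >= n − 1` the
neighbor search switches to brute force (the exact limit of the ANN
contract), and the tests require the iterative result to be *identical*
to `exact_average_linkage()` on 20 random fixtures; with the default
`ann_k = 100` the agreement requirement is ARI ≥ 0.95. Determinism is a
feature here: candidate ordering and canonical CAG labeling (dense ids
by decreasing size, ties by smallest member id) make reruns and
relabeled inputs produce literally identical catalogs.

### Tunable parameters

* `max_dist = 0.3` — cophenetic cosine threshold; the published pipeline
  setting. Raising it can only merge, never split, oracle clusters
  (asserted as a monotonicity test).
* `min_samples = 10` — a gene must be detected (> 0) in at least this
  many samples. Detection is scale-invariant, so the filter is applied
  to raw depths first and the retained genes are then sum-normalized;
  this ordering keeps the "normalized columns sum to 1" invariant true
  of the matrix actually clustered. Filtered genes are omitted from the
  catalog rather than forced into singletons: they lack the evidence the
  method requires, and they are reported in the `excluded` attribute.
* `ann_k = 100`, `ann_M = 16`, `ann_ef = 200` — HNSW retrieval breadth
  and graph parameters; defaults trade recall against index cost and are
  checked against the oracle in the tests.
* Single-gene clusters are kept in the catalog; `cag_size_summary()`
  reports the singleton count so analyses that define CAGs as size ≥ 2
  can read off either convention.

## Association model

CAG abundance is the sum of member relative abundances — additive in
depth units, so singleton CAGs equal their gene and per-sample totals
are conserved. The centered log-ratio transform (natural log) addresses
compositionality; zeros are first replaced by half the smallest non-zero
value in their sample, the standard multiplicative replacement that
keeps geometric means finite. CLR values sum to zero per sample by
construction (tolerance 1e-9 in tests).

Disease status is coded 0 = disease, 1 = healthy, so positive
coefficients mean more abundant in health. Coefficients are natural-log
CLR differences; any log10 reading elsewhere differs only by the
constant 1/ln 10. When any subject contributes more than one sample the
model is a linear mixed model with a subject random intercept
(`lme4::lmer`, Wald z against a normal reference — no small-sample
correction is claimed, and calibration at the simulated n is verified by
simulation); otherwise ordinary least squares. The mixed fit is allowed
at the singular boundary so that forcing the mixed model on unreplicated
subjects reproduces the fixed fit (agreement to 1e-6, tested). Fits that
fail return NA p-values and are excluded from q-value estimation.

Multiple testing uses Storey q-values with the smoother pi0 estimate
(lambda grid 0.05–0.95, cubic smoothing spline, evaluated at the largest
lambda, clamped to (0, 1]); with pi0 fixed at 1 the estimator reduces
exactly to Benjamini–Hochberg, which is also the automatic fallback
below 10 p-values where the smoother is unstable. Discovery uses
q ≤ 0.2 (inclusive, "0.2 or less"). Validation recomputes q-values
within the discovered subset only — only those CAGs are being re-tested
— and requires sign agreement. The conservative global-null bound
Pr(Binomial(C1, ½) ≥ C2) is evaluated in log space so quantities far
below double precision still report exact log10 values; the classical
normal approximation with denominator `√(C1/2)` is reported alongside.
That denominator is larger than the binomial standard deviation
`√(C1)/2`, making the approximation extra conservative; whether that was
intentional in the original description is unknowable, so both variants
are exposed and the exact tail is the headline number.

## The synthetic cohorts

The generator plants the structure every downstream stage needs:

* Latent CAG abundances are log-normal per sample (heavy-tailed relative
  abundances without claiming a published generative law), with CAG-level
  mean spread `cag_level_sd = 1` and per-sample variation
  `sample_sd = 1.5` (natural-log units; abundances ranging over orders of
  magnitude across samples, as real organisms do).
* Disease effects are additive shifts of magnitude `effect_size` on the
  log latent abundance of `effect_cags` randomly-signed CAGs, applied
  *before* closure, so compositional distortion is present in fixtures:
  the CLR-scale truth for an effect CAG is its shift minus the mean
  shift across CAGs, and the parameter-recovery tests target exactly
  that quantity.
* Subjects carry a normal random intercept (`subject_sd = 0.3`) shared
  by their 1–3 samples, exercising the mixed-model path.
* Member genes scatter around their CAG profile with multiplicative
  log-normal noise (`gene_noise_sd`), and sequencing draws Poisson
  counts at `depth` expected reads — producing realistic detection
  sparsity for the `min_samples` filter. `depth = Inf` disables count
  noise so the zero-noise case has exactly proportional member profiles
  (cosine distance 0), which the trivial-recovery tests rely on.
* Distinct planted CAGs are kept co-abundance distinct: if two latent
  profiles fall closer than `min_separation = 0.45` cosine after
  closure, the offending CAG's sample noise is redrawn. Heavy-tailed
  draws otherwise occasionally place two "distinct" CAGs inside the 0.3
  clustering threshold, which would make exact recovery of the planted
  partition a seed lottery rather than a property of the method. This
  calibration serves recoverability of planted structure only; it is not
  a claim about real data.

What the fixtures do *not* emulate: taxonomic composition, read-level
artifacts, assembly chimerism, strain mosaicism, or between-CAG
correlation structure (real organisms co-occur). Passing tests therefore
demonstrate correctness of the algorithms and calibration of the
statistics under the stated model, not performance on any particular
real cohort.

## Single-cell co-occurrence

The statistic counts (cell, gene) detections with at least one same-CAG
companion in the same cell — per detection, so one gene seen in two
cells can count twice. The null permutes the gene-to-CAG assignment over
the catalog's full gene universe, preserving the CAG size multiset
exactly; genes detected in cells but absent from the catalog are dropped
before counting, with the dropped count reported so the choice is
auditable. The enrichment ratio is observed over mean permuted count
(1000 replicates by default). Null fixtures in the tests use catalogs of
many small CAGs and 300 cells × 25 genes, sized so the ratio's sampling
error is a few percent and the [0.9, 1.1] null band is informative.

## Problem sizes and estimators used in the checks

The verification suite uses cohorts of 40–60 samples, 15–60 CAGs of
2–50 genes (≤ 700 genes), 20-seed oracle-equivalence sweeps, a
100-replicate global-null calibration, and 1000-replicate permutation
tests. Under the global null, the sign-agreement fraction is estimated
by pooling C2 and C1 across replicates: individual replicates discover
0–3 CAGs, so per-replicate ratios are nearly Bernoulli and only the
pooled fraction estimates the null value ½ usefully. Replicates with no
discoveries contribute a conservative bound of 1.

## Limitations

* The HDF5 store schema (`abund`, `cags`, `stats`, `metadata`, plus a
  completion marker) is original to this package; no external layout is
  claimed.
* Wald normal reference for mixed models is a large-sample choice;
  at very small cohort sizes a Satterthwaite correction would be more
  accurate than what is implemented.
* Mean member-pair linkage across rounds is exact, but HNSW recall below
  the exhaustive limit means very close clusters can be missed at
  default settings; the ARI ≥ 0.95 oracle agreement quantifies this.
* Upstream steps (assembly, gene catalog construction, alignment,
  annotation) are out of scope; the package starts from a gene × sample
  matrix.
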