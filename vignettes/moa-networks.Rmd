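---
title: "Methods: AOP-based mechanism-of-action networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AOP-based mechanism-of-action networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its science: the model and
its assumptions, the parameters that matter, what the synthetic-data
generator does and does not emulate, the numerical conventions, and the
design decisions that were genuinely open.

## 1. The model

An adverse outcome pathway (AOP) expresses toxicity as a causal chain of
events — a molecular initiating event (MIE), intermediate key events
(KEs), and an adverse outcome (AO). Merging all pathways on shared events
yields one directed event network; with a curated KE→gene annotation it
becomes a bridge between omics data and phenotype. `moanet` reconstructs,
for one exposure, the sub-network of that bridge supported by the
transcriptomic response:

1. an exposure is represented as a **gene co-expression network** over the
   most deregulated genes, with edges defined by a pairwise statistical
   test rather than correlation (see §2);
2. KEs whose annotated genes sit **unusually close together** on that
   network are called enriched (§3);
3. plausible MIEs and AOs are **prioritized** around the enriched KEs by
   molecular evidence and AOP proximity, and the induced AOP subgraph is
   the mechanism-of-action (MOA) network (§4).

The key assumption is that coordinated expression change is informative
beyond marginal differential expression: genes acting in one mechanism
respond together, so their pairwise relationships — and their proximity
on the inferred network — carry mechanism-level signal.

## 2. Co-expression by pairwise Hotelling T²

With only three replicates per condition, per-pair correlation estimates
are hopeless, but a difference of *bivariate means* is testable. For a
gene pair, the two conditions give two clouds of replicate points in the
plane; the two-sample Hotelling statistic

\[ T^2 = \frac{n_1 n_2}{n_1+n_2}\, \mathbf{d}' S^{-1} \mathbf{d}, \qquad
   F = \frac{n_1+n_2-3}{2\,(n_1+n_2-2)}\,T^2 \sim F_{2,\,n_1+n_2-3} \]

tests whether the pair moved jointly. Properties that matter here:

* it is affine invariant (scale-free across platforms);
* the Mahalanobis metric *discounts* displacement along directions of
  high pooled covariance — a pair whose shift is parallel to its shared
  noise gets less credit. This interacts with the data generator (§6);
* with \(n_1=n_2=3\), \(F_{2,3}\) has heavy tails: null pairs occasionally
  reach very large statistics, which is why the framework selects edges
  by the *percentile* of the p distribution rather than a fixed cutoff.

Edges keep pairs with raw p strictly below the 5th percentile of all
tested pairs. BH-adjusted p-values are computed and stored on every edge
for auditability, but the operative selection is the percentile cut on
raw p (the two orderings are identical; only the implied count differs,
and the percentile rule is what fixes the count). Degenerate pairs
(singular pooled covariance, e.g. a constant gene) are excluded from both
testing and the percentile distribution. Seed genes are the `k` best per
fold-change sign under a composite rank (mean of the |logFC|-descending
and p-ascending ranks, ties broken lexicographically); genes with logFC
exactly 0 sit on neither side.

## 3. Topological enrichment of key events

For a KE with ≥ 2 annotated genes present in the network, the multiset of
finite pairwise shortest-path lengths among those genes is compared with
`n_draws` random node sets of the same size drawn from the network's node
universe: one Welch t-test per draw between the two multisets, `p_avg` =
mean of the draw p-values, and `ratio` = KE mean path over the mean of
the random-set means. Conventions:

* **Unreachable pairs are excluded** from path multisets (infinite
  lengths would otherwise dominate every mean); an event or a draw with
  fewer than two reachable pairs is skipped, with the reason recorded.
* **Draws sample the network's nodes**, not the genome: this conditions
  on network size and composition, so the null asks "are *these* genes
  closer than a random subset of the same network".
* **Welch, not pooled**: clustered sets have much smaller path-length
  variance than random ones.
* Each event's draws come from an **RNG stream derived from (seed, gene
  set)**, so a record is a pure function of the network, the gene set and
  the seed — two events with identical annotations get identical records,
  and iteration order is irrelevant.
* The pipeline's `enriched` call requires both `ratio < 1` *and*
  BH-adjusted `p_avg` ≤ α; the bare ratio rule is reported alongside
  (`enriched_raw`). This reconciles a ratio-based enrichment definition
  with a downstream FDR filter without applying either twice.

The enrichment filter then applies, in order: (1) drop events with more
than 1000 annotated genes (hub events carry little specific meaning) or
adjusted p above 0.05 or ratio ≥ 1; (2) keep events with `p_avg` at or
below the 5th percentile of the survivors' `p_avg`; (3) drop events none
of whose annotated in-network genes reaches |logFC| ≥ 0.58 (maximum
aggregation by default — one strongly responsive gene makes an event
biologically live; mean aggregation is available). Stage 2 is
deliberately *inclusive* (≤ rather than <): with a strict cut a lone
stage-1 survivor could never pass its own percentile, which would make
the percentile filter an accidental veto in sparse worlds; with 40
distinct survivors both readings keep the same two events.

## 4. Terminal prioritization and MOA assembly

Candidate MIEs and AOs are events of those types with at least one
annotated gene passing the DEG filter (p < 0.05, |logFC| > 0.58).
Each candidate is scored within its type by the mean of two ranks:

* `best_gene_p` — the *minimum* contrast p over annotated genes (a single
  responsive gene suffices to make an event plausible; a Fisher
  combination would instead penalize large, partially responsive sets);
* `dist_to_enriched` — minimum shortest-path distance on the *undirected*
  AOP graph to any enriched KE. Undirected, because MIEs are prioritized
  upstream and AOs downstream of enriched KEs, which requires walking
  against edge direction for one of the two.

Ties break toward smaller annotated gene sets (prefer specific events),
then lexicographic event id; at most 20 per type are kept. The MOA is the
induced subgraph of the AOP network on enriched KEs plus terminals,
directions preserved, isolated events retained — they are exactly what
the connectivity score counts. Connector events on paths *between*
included events are not auto-added: the published layout draws such links
by hand, and inserting unenriched events would fabricate evidence.

## 5. Scores

* **Completeness** (transitivity, mean betweenness, mean shortest path
  over connected pairs, diameter; undirected): all-zero conventions for
  empty/edgeless graphs make every comparison total. Network A is "more
  complete" than B if strictly higher on ≥ 3 of the 4.
* **KE connectivity** = (#events with degree ≥ 1)/(max(#isolated, 1)):
  "isolated nodes" is read literally as degree 0; the denominator floor
  keeps the ratio finite while preserving the ordering (more isolated ⇒
  lower score).
* **Biological-system similarity** = mean of four [0,1] components:
  1 − |n_A − n_B|/N for enriched-KE counts against the AOP's total KE
  count, node Jaccard, edge Jaccard, and min/max largest-component
  diameter ratio (1 when both diameters are 0; empty-vs-empty set
  overlaps count as 1 so identical MOAs score exactly 1). Both MOAs must
  come from the same AOP network (checked by signature).
* **Cohort comparison**: the five edge measures (Jaccard similarity and
  distance, Hamming and simple matching over the union edge universe,
  Kendall τ of common edges ranked by edge betweenness) are oriented as
  distances, min–max normalized per component, and averaged; over a
  common universe normalized Hamming and 1−SMC coincide, which is kept
  as-is to mirror the five published measures (the consensus just weights
  that information twice). Pairs with < 3 common edges drop the Kendall
  component. Consensus clustering runs hierarchical, PAM and a
  deterministic affinity propagation (preference = median similarity,
  damping 0.9, no noise injection), then cuts the co-association matrix;
  `k = n` returns singletons directly. MOA collections cluster by
  1 − mean(node Jaccard, edge Jaccard) under Ward-D2.
* **Edge-set enrichment**: background edges of a pathway are all gene
  pairs co-annotated to it; the ranked input edges get a weighted KS
  running sum with hit weights ∝ −log10 p (weight exponent 1); the
  permutation shuffles *set membership* (which ranked edges are hits),
  preserving set size and ranking, so p has resolution 1/(n_perm+1). When
  every ranked edge is a hit the permutation null is degenerate and p = 1
  by construction — the score (ES = 1) is informative, the p-value is
  honestly uninformative. Fisher's sumlog combines per-exposure edge
  p-values.

## 6. The synthetic world

`fixture_spec()` states the world once: a 500-gene universe; one planted
MIE→KE→AO chain whose KE carries a 20-gene module, with the MIE and AO
annotated with disjoint 6-gene subsets of that module (responsive
terminals that are not near-duplicates of the KE — Jaccard 0.3 stays
under the 0.8 merge threshold); six decoy chains annotated with 10
unshifted genes each; 3 replicates per condition; exposed module genes
shifted by `effect_size = 2` on the log2 scale against replicate noise
`noise_sd = 0.3`; and a shared per-replicate module factor with
`latent_sd = 0.1` inducing co-deregulation.

Two generator choices deserve explanation:

* **latent_sd < noise_sd.** The shared factor adds pooled covariance
  exactly along the direction of the mean shift, and the Hotelling metric
  discounts shifts along high-covariance directions — a strong common
  factor would *mask* the very co-deregulation it encodes. 0.1 keeps the
  correlation real but subordinate to the mean-shift signal.
* **module_size = 20 with k = 60 seeds/side in pipeline tests.** The
  enrichment t-tests operate on path-length multisets, so statistical
  resolution grows with the number of module pairs (C(20,2) = 190); and
  the 5% edge cut must retain enough noise edges to give the background
  graph realistic path lengths (if nearly all retained edges are module
  edges, random node sets inherit the module's short paths and the ratio
  collapses toward 1). Both values were fixed by design exploration of
  the generator before the recovery tests were frozen.

What the generator does *not* emulate: platform noise models, correlated
background co-expression, dose/time structure in the planted effect,
hub-like annotation overlap between events, or genome-scale universes. A
green planted-recovery test therefore establishes that the pipeline
detects a coherent co-deregulated module tied to a chain under realistic
replicate noise — not that it would rank mechanisms correctly in the
presence of confounded, overlapping annotations.

## 7. Benchmark-dose input route

The dose-series filter fits {linear, power, exponential, Hill} by least
squares under constant variance, selects by AIC, sets BMR = 1.349 × the
df-corrected residual SD (1.349 SDs ≈ a 10% deviation from control under
normality), and inverts |f(bmd) − f(0)| = BMR two-sidedly on the dose
range. BMDL/BMDU come from a seeded nonparametric bootstrap (replicates
resampled within dose levels, the selected model refit, 250 resamples) —
chosen over profile likelihood because it is uniform across the model
family and exactly reproducible; lack of fit is the standard pure-error F
test. Quality filters: lack-of-fit p > 0.01; all three estimates defined;
BMD and BMDU within the tested range; BMD/BMDL ≤ 20, BMDU/BMD ≤ 20,
BMDU/BMDL ≤ 40. The model family is intentionally small; the filters,
not the model zoo, are the contract.

## 8. Numerical conventions and degenerate inputs

* Percentile cuts use type-7 quantiles; edge selection is strict (<),
  the enrichment stage-2 cut inclusive (≤) — see §3 for why.
* Zero residual variance with a nonzero contrast reports the smallest
  representable positive p and a `degenerate` flag; p-values are clamped
  into (0, 1] everywhere (1e-300 floor in Welch tests, warning-clamp of
  zeros in sumlog).
* Singular 2×2 pooled covariances are detected against a relative
  determinant threshold (scale-free, so affine invariance survives).
* Redundant-KE merging iterates single-linkage merge passes to a fixed
  point, because unions of gene sets can newly exceed the threshold;
  this makes the operation idempotent by construction. Merged ids are
  deterministic functions of the sorted member ids.
* All tabular outputs carry a provenance header (package version, config
  hash over non-path keys, seed), so identically configured runs are
  byte-identical even from different directories.

## 9. Known limitations

* The Hotelling route requires ≥ 3 replicates per condition and exactly
  pairs (dimension 2); no shrinkage covariance variant is provided.
* Enrichment p_avg averages dependent t-tests (draws share the KE
  multiset); it is a ranking statistic, calibrated empirically under the
  null in the test suite, not a frequentist p-value.
* The consensus distance is a premetric (symmetric, zero diagonal,
  nonnegative); the triangle inequality is not guaranteed after
  averaging normalized components.
* Dose and time enter only as metadata; the MOA model itself is
  dose-agnostic, and in vitro–in vivo extrapolation is explicitly out of
  scope.
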