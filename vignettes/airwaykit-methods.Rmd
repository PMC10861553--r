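---
title: "Methods: gene-content clustering and community typing of airway bacteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-content clustering and community typing of airway bacteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airwaykit)
```

## Scope

`airwaykit` implements the computational chain that relates a collection of
cultured, whole-genome-sequenced airway bacterial isolates to 16S rRNA
amplicon surveys of airway communities:

1. clustering isolates by binary KEGG Orthology (KO) gene content;
2. scoring cluster-specific KOs with contingency odds ratios;
3. preparing OTU tables (read/prevalence filtering, contaminant flagging,
   rarefaction) and computing the alpha/beta-diversity statistics used in
   dysbiosis analyses;
4. typing communities with a Dirichlet-multinomial mixture (DMM);
5. mapping OTU representative sequences onto isolate 16S genes by binned
   percent identity; and
6. projecting community abundances onto isolate gene content
   ("functional potentials").

Upstream steps (genome assembly and annotation, OTU picking, taxonomy
assignment) are out of scope: KO calls, OTU counts and 16S sequences are
taken as given. Every stage has a seeded synthetic generator with known
ground truth, so the whole chain is testable offline.

## KO gene-content clustering

Isolates are rows of a binary matrix `K` (1 = KO annotated in the genome).
The preparation order is fixed: zero-variance KOs (present in all or no
isolates) are removed first, then KO columns with identical presence/absence
profiles are collapsed to a single representative (first in file order, a
deterministic choice), and Manhattan distances are computed on the collapsed
matrix. For binary rows the Manhattan distance is the Hamming distance: the
number of KO columns on which two isolates disagree. Complete-linkage
agglomeration (via `stats::hclust`) then gives a monotone dendrogram.

Collapsing duplicates before computing distances means each distinct
gene-content *pattern* contributes once, rather than being weighted by how
many KOs share it. One consequence matters for simulation studies: in a
noiseless planted-cluster simulation all of a cluster's signature KOs are
identical columns, so the collapse reduces them to one column and erases the
planted signal. Planted-recovery checks for noiseless data therefore
exercise the distance → linkage → cut chain directly; with realistic
annotation noise (flip rates of a few percent) the full pipeline recovers
planted clusters essentially perfectly (see the test suite).

### The adaptive tree cut

No single cut height extracts sensible clusters from gene-content
dendrograms: clades differ in both size and tightness. `cut_tree_dynamic()`
is this package's variant of the dynamic hybrid tree cut of Langfelder,
Zhang and Horvath (2008, *Bioinformatics* 24:719-720). Branches are examined
in merge order and declared clusters when, at their merge height `h`:

* they contain at least `min_cluster_size` members (default 3, sized for a
  ~126-isolate collection in which the smallest genus groups have 3-4
  members);
* their *core scatter* (mean attachment height of the earliest-joining
  core members) is below a ceiling interpolated between the 5th-percentile
  and maximum merge heights, with the interpolation fractions
  (0.64-0.95 over `deep_split` levels 0-4) taken from the reference
  algorithm's parametrisation;
* the gap `h - r` above the branch's own root height `r` exceeds a floor
  derived from the same interpolation; and
* the **separation z-score** of the two merging branches,
  `(mean between-branch distance - mean within-branch distance) / sd(within-branch distances)`,
  exceeds a `deep_split`-dependent threshold (5, 4.25, 3.5, 2.75, 2).

The z-score criterion is this implementation's own addition, and it does the
work the first three criteria cannot. Gene-content profiles share a large
random background, so all pairwise distances carry a large additive offset;
ratio- or silhouette-style split statistics are diluted towards zero by that
offset, while height-gap statistics are spuriously *inflated* on homogeneous
data, whose merge heights span a narrow band. The z-score is invariant to
the offset and calibrated by the within-branch spread, so genuinely
unstructured data (where chance separations rarely exceed ~3 standard
deviations) stays in a single cluster while planted or phylogenetic
structure (separations of 10+ standard deviations at realistic signature
sizes) is split. When a small branch merges into a region containing
established clusters it is compared against the *nearest* established
cluster only; pooling distances across distinct clusters would corrupt the
within-group spread.

Members of branches that never qualify are assigned to the nearest cluster
when their mean distance to it is within 1.2x the cluster's radius (the
largest member-to-cluster mean distance), and are otherwise labelled 0
(unassigned). Labels are renumbered by decreasing cluster size. The
assignment-stage tolerance and the z-score thresholds were fixed against
simulated regimes (planted blocks with and without flip noise, homogeneous
backgrounds, collection-scale uneven cluster sizes) before being frozen.

`split_cluster()` implements the one manual refinement step the analysis
needs: dividing a detected cluster in two on external (16S similarity)
evidence, preserving all other labels.

### Enrichment scoring

For cluster *i* and KO *j*, the 2x2 table (a: in-cluster with KO, b:
in-cluster without, c: out-of-cluster with, d: out-of-cluster without;
unassigned isolates excluded from both margins) yields `OR = ad/bc`,
summarised as `log10(OR)`. Cells equal to zero are replaced by 0.5 - the
Haldane-Anscombe idea applied *only to zero cells*, which follows the
analysis this package reproduces rather than the classical all-cells form;
`correction = "all_cells"` gives the classical variant and `"none"` disables
it. Scores are descriptive ranks, not tests, so no p-values or multiple-
testing corrections are attached. KOs collapsed as duplicate profiles
inherit their representative's score. Ranking covers the full signed range
(over- and under-representation); users wanting over-represented KOs only
can filter on sign.

## Community preparation and diversity

`filter_low_count_otus()` removes OTUs with fewer than 20 total reads *or*
presence in fewer than 2% of samples. These two rules are stated jointly in
the source analysis; the OR combination is the conservative reading and both
thresholds are exposed.

`flag_biomass_contaminants()` operationalises the low-biomass contamination
mechanism: a reagent contaminant contributes a roughly constant absolute
input, so its share of reads falls as true biomass rises. Per-OTU Spearman
correlations between relative abundance and qPCR biomass are BH-adjusted;
flags require adjusted p < 0.05 and rho ≤ -0.2. The magnitude threshold is
applied in the negative direction because that is the direction the
mechanism predicts; `direction = "both"` flags either sign for users who
prefer the agnostic reading. OTUs with constant relative abundance get no
correlation and are never flagged.

`rarefy_counts()` subsamples each sample without replacement (multivariate
hypergeometric) to a common depth - by default the smallest retained total
after discarding samples under `min_sample_reads = 1000` reads. The
1000-read floor is a defensible default for airway amplicon data, not a
published constant, and is exposed. Rarefaction is a single seeded draw per
sample.

Shannon diversity uses natural logarithms (the ecology default; base
exposed), richness counts non-zero OTUs, and Pielou evenness `H / ln(S)` is
undefined (`NA`) for single-OTU samples. Bray-Curtis dissimilarities
(`vegan::vegdist`) are computed on relative abundances by default; the
triangle inequality is *not* asserted anywhere because Bray-Curtis can
violate it. PCoA is classical scaling; negative eigenvalues are reported but
contribute no coordinates, and a fully degenerate (all-zero) configuration
returns all-zero coordinates. PERMANOVA is `vegan::adonis2` behind a
validated surface, with `p = (1 + #{F* >= F}) / (1 + n_perm)` so p is never
zero; the default 999 permutations make 0.001 the smallest attainable
p-value.

## Dirichlet-multinomial community typing

Community types ("pulmotypes", by analogy with gut enterotypes) are
components of a finite mixture of Dirichlet-multinomial distributions
fitted to genus-binned counts. The DM log-likelihood is computed entirely
in log-gamma space. Counts, not proportions, are the natural input: the DM
is a distribution over counts, and binning to genus level precedes fitting.
The rarefaction depth at which typing is performed is left to the user;
the acceptance analyses fit unrarefied genus counts, since the DM's
depth-dependence is part of the model.

EM details: responsibilities from the current weights and component
likelihoods (E-step); weights as mean responsibilities and each component's
`alpha` maximised by L-BFGS-B on `log(alpha)` with the analytic digamma
gradient, bounded below at 1e-8 (M-step). Initialisation is k-means on
proportion vectors; 5 seeded restarts by default, best log-likelihood kept;
a restart whose component loses essentially all responsibility mass (< 1
sample equivalent) is discarded. Convergence is a log-likelihood gain below
1e-6; the trace is stored and is non-decreasing, which the tests assert.
Components are reported in decreasing-weight order, ties in posterior
assignment go to the lower index and are flagged.

### Model selection

Three criteria are computed for every fit: BIC, AIC, and a Laplace-style
negative log model evidence using responsibility-weighted per-component
Hessians over `log(alpha)` (a rank-one update of a diagonal, so the
determinant is cheap) with the mixture weights penalised at BIC rate.
**The default selection rule is BIC.** In repeated simulations at realistic
scales (two well-separated components, 200-900 samples, depths around
1000), the Laplace approximation as computed here systematically preferred
k one or two above the generating value - the responsibility-weighted
block Hessian underestimates the curvature penalty for weakly-supported
extra components - while BIC recovered the generating k in every run and
correctly chose k = 1 on single-component and degenerate (identical-sample)
data. The Laplace criterion remains available (`criterion = "laplace"`)
with this caveat documented, and `select_k()` always returns the full
criterion curve so the evidence shape can be inspected.

`congruence_test()` is a Pearson chi-square (no continuity correction) on
the contingency table of a metadata factor against assigned type, used to
confirm that samples from the same donor or site are typed consistently.

## 16S identity mapping and barcodes

OTU representative sequences are aligned against isolate-derived 16S genes
with a semi-global (overlap) dynamic-programming alignment - free end gaps,
match +1, mismatch -1, linear gap -2 - via `Biostrings::pairwiseAlignment`.
Identity is identical aligned bases over alignment columns; `N` never
counts as a match (conservative). A full database-search engine with
e-values is deliberately not reproduced: for ~250-1500 nt 16S comparisons a
deterministic pairwise DP is adequate, and the e-value filter is replaced by
a minimum alignment length (default 206 columns, the amplicon-scale floor).
Hits are binned `[95,97)`, `[97,99)`, `[99,100]`; the top bin is ">=99"
rather than exactly 100 because mapping at 99% identity is what tolerates
the within-genome 16S copy variation that makes these relationships
many-to-many. The resulting OTU x isolate matrices of bin codes (0-3) form
"barcodes" that can discriminate taxa - notably streptococci - whose
individual 16S sequences are nearly identical.

## Functional projection

`abundance_to_isolates()` distributes each OTU's relative abundance equally
across its admissible isolate hits (identity-weighted splitting is an
option); how a real analysis should apportion an OTU across several matching
genomes is genuinely underdetermined, and the equal split is the explicit,
documented choice. Abundance of unmapped OTUs is reported as an unmapped
fraction, never renormalised, so projected values remain comparable across
samples. `project_functional_potential()` is then the exact matrix product
`F = A K`; it is linear in `A`, bounded by 1 when `A` rows are proportions,
and commutes with KO subsetting - all asserted as properties in the tests.

## Synthetic data: what it does and does not emulate

The generators are pure functions of (parameters, seed); each draws from a
named substream derived via `substream_seed()`, so adding a generator never
perturbs existing draws.

* `simulate_ko_matrix()`: iid Bernoulli(0.5) background plus disjoint
  cluster signatures and optional flip noise. Real gene content is
  phylogenetically correlated, not iid; what the planted model shares with
  real data is the property the cut must exploit - within-clade distances
  systematically below between-clade distances. The collection-scale
  defaults used in the acceptance analysis (15 clusters with sizes
  30, 12, 10, ... 4 totalling 126 isolates; ~4000 background KOs; 250-KO
  signatures; 2% flip noise) encode genus-scale separation: bacterial
  genera typically differ in hundreds of gene families.
* `simulate_airway_cohort()`: 888 samples in two community types with
  weights 410/478, sharing their top two driver genera and differing in the
  third - the qualitative driver structure of airway community types -
  with donors contributing 1-3 samples of a shared type and log-uniform
  depths (2000-20000). Taxa are named generically; no real taxon
  abundances are imitated.
* `simulate_contaminated_community()`: biomass log-uniform over a 100-fold
  gradient (1e5-1e7 16S copies, the airway range between bronchial
  brushings and throat swabs), a constant contaminant input of 1e4 copies,
  and depth independent of biomass.
* `random_16s()`/`mutate_16s()`: uniform random sequences with exact
  substitution counts; identity recovery is therefore exact arithmetic,
  and no real 16S phylogenetic structure is claimed.

Passing tests on these generators demonstrates algorithmic correctness
under known truth; they do not demonstrate robustness to the correlated
annotation errors, compositional effects and batch structure of real data.

## Numerical choices and limitations

* All mixture and likelihood computations are in log space; no overflow up
  to depths of ~1e6 reads.
* Distance validation requires symmetry (tolerance 1e-8), zero diagonal
  and non-negativity; `hclust`'s deterministic tie handling stands in for
  an explicit lexicographic tie-break rule.
* The tree cut's thresholds are interpretable but heuristic; collections
  with genuinely continuous (non-clustered) gene-content variation will be
  returned as a single cluster rather than forced apart.
* The DMM's k-means initialisation can, on pathological data, leave EM in
  a local optimum; restarts mitigate but do not eliminate this.
* Problem sizes in the tests and the acceptance script (126 isolates x
  ~7750 KOs; 888-sample cohorts; 500-replicate null simulations) were
  chosen as the smallest scales at which the statistical claims are
  meaningful.
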