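---
title: "Methods: cross-domain co-occurrence networks from paired amplicon data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-domain co-occurrence networks from paired amplicon data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Benthic habitats along a salinity gradient are typically surveyed with
two marker genes over the same samples: a general-eukaryote 18S amplicon
capturing the diatom-dominated microphytobenthos, and a fungal LSU
amplicon capturing potential parasites, notably chytrids. The ecological
question — which fungi co-occur with which algal hosts? — cannot be
answered by correlating the two count tables directly. Sequencing counts
are compositional: each sample's total is an artefact of library size,
so any correlation across tables confounds shared structure with closure
effects. `pairnet` follows the indirect route: estimate sparse
correlations *within* each view, cluster each view's ASVs into
co-occurrence modules, summarise modules by one profile per sample, and
compare only those summaries across views.

## Pipeline and assumptions

### Filtering

Singletons (ASVs with a total count of 0 or 1) are removed before any
analysis. Before network inference, ASVs with prevalence below 10 % *or*
present in fewer than 3 samples are removed. The published description of
this rule is ambiguous about whether the two criteria are conjunctive;
the default removes an ASV failing either criterion (with 17 samples the
3-sample rule binds), and a `rule = "both"` mode is provided. When a
taxonomy keep-list is active (e.g. Kingdom = Fungi for an LSU table with
non-specific primers), ASVs unclassified at the filtering rank are
dropped, since only positively classified taxa can be justified as
in-scope. The taxonomy filter runs before the prevalence filter by
default so that prevalence is assessed on the community actually
analysed; the order is configurable.

### Diversity and ordination

Alpha diversity is computed without rarefaction: richness *S*, Shannon
*H = −Σ pᵢ ln pᵢ* (natural log, so that Pielou's *J = H / ln S* is
consistent; *J* is undefined and reported as missing at *S* = 1).
Bray–Curtis dissimilarities are computed on relative abundances —
library sizes are uneven and nothing is rarefied, so raw-count
dissimilarities would partly measure depth. NMDS uses Kruskal stress-1
with monotone regression (via `vegan::monoMDS`), k = 2, one metric-MDS
start plus 20 random restarts, tolerance 1e-6; the best configuration is
returned and runs are deterministic given the seed. PERMANOVA is the
standard one-way partition of squared distances with a pseudo-F;
p-values count the observed statistic in the null set,
p = (1 + #{F* ≥ F}) / (1 + m), so with 999 permutations the attainable
floor is 0.001. An `exact = TRUE` mode enumerates all label orderings
for small n. Pairwise follow-ups rerun PERMANOVA per group pair and
Bonferroni-multiply by the number of pairs. Only one-way tests are
implemented; habitat and sample type are tested separately.

### SparCC

The basis-correlation estimator works on log-ratio variances
T\_ij = var log(fᵢ/fⱼ), which are well defined on compositions. Under a
sparsity assumption the row sums of T are linear in the unknown basis
variances ω, giving a d×d linear system; correlations follow as
ρᵢⱼ = (ωᵢ + ωⱼ − Tᵢⱼ) / (2√(ωᵢωⱼ)), clipped to [−1, 1]. Strongly
correlated pairs violate sparsity, so the strongest pair with
|ρ| > 0.1 is excluded from the system and the solution iterated, one
pair per round, up to 10 rounds — the sequential scheme of the original
algorithm, which is deterministic. Fractions are resampled 20 times from
Dirichlet(counts + 1) and the final estimate is the element-wise median.
These defaults mirror common FastSpar practice and are all exposed as
arguments, since field studies rarely report them. Negative basis-variance solutions (possible
under heavy sparsity violation) are clipped to 1e-6 with a warning
rather than aborting. Bootstrap p-values are not computed: downstream
steps consume coefficients only.

### Modules

Correlations become adjacencies (default unsigned, |ρ|^β with β = 1 —
no soft-threshold selection is performed, since none is reported for
this design), then a topological overlap matrix; 1 − TOM is clustered by
average linkage. Module extraction is a dynamic tree-shape cut designed
around one observation: on TOM dissimilarities at realistic sample
sizes, background taxa merge in a near-continuous chain, while a genuine
module forms a branch that completes its internal merges low and then
stays untouched until far above. A branch with top merge height *h*,
joining the rest at height *p*, qualifies as a module when (i) it has at
least `minModuleSize` leaves, (ii) *h* lies in the lower part of the
merge-height distribution (below the 5th percentile plus 90 % of the
range up to the cut, which rejects chain tops), and (iii) the isolation
ratio (min(p, cut) − h) / (cut − h) exceeds r_min, with the cut at 0.99
of the maximum merge height. `deepSplit` 0–4 maps to r_min =
0.50/0.40/0.30/0.22/0.15; the default 2 (r_min = 0.30) was calibrated
on simulated planted-module data, where it recovers partitions with
adjusted Rand index ≈ 1 while more aggressive settings begin to carve
spurious modules out of background. A branch containing two or more
qualifying sub-branches is split into them; one containing at most one
is kept whole, so a tight core does not shatter its module. The
published hybrid cut variant (which re-assigns singletons using the
dissimilarity matrix) is out of scope.

The two views' ASV sets are disjoint, so an element-wise-minimum
consensus TOM across them is undefined; `consensus_tom()` exists for
matched node sets (e.g. replicate runs), and the pipeline detects
modules per view, matching the separate per-dataset module sets the
design implies.

Each module is summarised by its eigenprofile: member counts are
clr-transformed (pseudocount 0.5 — the log-ratio view matches SparCC's
model; a log10 option exists), standardised per taxon, and the first
left singular vector of the samples × members matrix is taken, sign-
oriented so the mean correlation with members is positive. Module
membership is the absolute Pearson correlation between a member's
standardised profile and its module eigenprofile — absolute, so that MM
lies in [0, 1] as the cross-domain score requires. Constant profiles are
dropped from the SVD with MM = 0. Unassigned taxa (label 0) never enter
eigenprofiles or cross-domain scores.

### Cross-domain scores

Module eigenprofiles are compared across views by Spearman rank
correlation over shared samples (≥ 5 required; average ranks on ties).
Each cross-view ASV pair (i in module M, j in module N) receives the
weight ρ_MN × MM_i × MM_j, so within a module pair the strongest edge
joins the two highest-membership ASVs and |weight| ≤ |ρ_MN| always.
Edges are thresholded on |weight| by default (a "positive" mode keeps
only positive weights, since it is not stated whether negative module
correlations were displayed in the source design); 0.5 is the core
threshold and 0.2 the display superset. Only cross-view edges are
emitted — the product score is defined between datasets, not within.
Networks are written as edge TSV and GraphML (Cytoscape-loadable), with
nodes annotated by dataset, module and taxonomy string.

## The synthetic world

The generator emulates the study design rather than raw sequencing: 17
samples in three habitat groups (9 marine, 3 brackish, 5 limnic), two
views over disjoint taxon sets (120 and 60 ASVs) with identical samples,
fixed depth 5 000 reads, three planted modules per view, and one
cross-view module pair coupled at r = 0.8. Each module has one standard
normal factor per sample; a member's log-abundance is
√w·factor + √(1−w)·noise, so member pairs have latent correlation w
(`within_module_corr`, default 0.8; 0.9 in recovery benchmarks).
Coupled modules draw their factors from a bivariate normal with the
configured correlation. Habitat mean-shifts (SD 1 on the log scale) are
applied to background taxa only: this gives the ordination/PERMANOVA
stage its habitat signal while keeping module factors habitat-neutral,
so coupling estimates test the coupling parameter and nothing else.
Counts are multinomial draws from the softmax-closed exponentiated
latents — exactly the generative model SparCC assumes — so row sums
equal the depth exactly and all randomness flows from one seed.
Dispersion (log-scale SD, default 1) is the only overdispersion
mechanism; no Dirichlet-multinomial, PCR bias, chimeras or taxonomy
errors are simulated. A green recovery test therefore establishes that
the pipeline recovers structure *under its own model assumptions*, not
that it is robust to denoising artefacts or classification error.

Recovery benchmarks use a single-habitat design (the habitat shifts
would otherwise act as a confounder unrelated to the parameter under
test) with n = 150 samples for module recovery and n = 100 for coupling
detection; benchmark modules have ≥ 10 members in both views, since the
isolation criterion is not expected to resolve 6-member modules at
these sample sizes.

## Numerical choices and degenerate inputs

* Zero-sum samples are an error naming the sample; all-zero taxa must be
  filtered before SparCC.
* SparCC requires ≥ 4 taxa (identifiability of the basis system); the
  exclusion loop stops early if further exclusions make the system
  singular.
* Fewer nodes than `minModuleSize` yields an all-unassigned partition
  with a warning; an all-zero dissimilarity matrix yields one module.
* NMDS on ≤ k+1 points embeds exactly (stress ≈ 0); `cmdscale` starts
  are jittered when rank-deficient.
* p-value conventions everywhere include the observed statistic.
* Seeds: every user-facing stochastic function takes `seed`; the
  pipeline derives per-stage child seeds below 2³¹ from the master seed.

## Known limitations

* The 17-sample default world is honest about its size: module
  correlation estimates shrink noticeably (a planted r = 0.8 appears as
  ≈ 0.57), and the 0.5 edge threshold can retain nothing at n = 17 —
  the 0.2 display threshold is then the informative network.
* SparCC's sparsity assumption degrades when a large fraction of taxa
  is co-regulated; with 32 of 120 taxa in modules, closure still induces
  mild negative cross-module correlation that the unsigned adjacency
  treats as similarity.
* The dynamic cut is a tree-shape method; it does not use the
  dissimilarity matrix to re-assign borderline taxa, so module
  boundaries are only as good as the dendrogram.
* Two-way or stratified PERMANOVA, ANOSIM, module merging, soft-
  threshold selection and module preservation statistics are not
  implemented.
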