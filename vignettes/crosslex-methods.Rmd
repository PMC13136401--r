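---
title: "Methods: cross-linguistic semantic spaces, universality benchmarks, and environmental representational similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-linguistic semantic spaces, universality benchmarks, and environmental representational similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosslex)
```

# The problem

Word-embedding spaces trained separately per language live in arbitrary
coordinate systems: the vector for *moon* in Japanese cannot be compared
coordinate-wise with the vector for *luna* in Spanish. `crosslex`
implements a projection-based solution and the statistical machinery
around it:

1. **Anchor-word projection** re-expresses every concept as its cosine
   similarities to fixed sets of anchor words, which is invariant to any
   orthogonal transformation of the embedding space and therefore
   comparable across languages.
2. **Universality metrics** quantify how similar the resulting semantic
   structures are across languages (or raters), benchmarked against
   permutation null models.
3. **Colexification topology** tests whether the structure generalizes to
   languages without embeddings, via weighted concept graphs built from
   cross-linguistic colexification counts.
4. **Representational similarity regression** relates between-language
   semantic (or neural) distances to environmental distances — climate,
   geography, linguistic history, culture — with crossed random intercepts
   for language families, plus hierarchical increments and commonality
   (variance partitioning) analysis.
5. A **climate principal-component projection** summarizes which semantic
   dimensions strengthen toward which climate pole.

A seeded synthetic-world generator with planted effect sizes stands in for
the external resources (multilingual embeddings, colexification databases,
bioclim rasters, rating and fMRI datasets) and makes every stage testable
by parameter recovery.

# Semantic models

The **neurocognitive model** uses 13 anchor dimensions motivated by the
neurocognitive literature (seven sensory-motor: color, shape, taste,
smell, sound, touch, motor; six cognitive: time, space, number, cognition,
emotion, social); entry \((c,d)\) of a language's space is the mean cosine
between concept \(c\)'s vector and the anchor vectors of dimension \(d\).
Concepts that appear in any anchor list are excluded as targets so no
concept is scored against itself; anchors without vectors are averaged
over, never imputed.

Alternatives constructed on the same interface: the **global
distributional model** (cosines to all other target concepts, self
excluded), the **local distributional model** (per concept, cosines to its
top-\(k\) nearest concepts, transferred across a language pair by
translation-equivalent concept identity and symmetrized by averaging the
two directions; \(k = 100\) by default), and the **feature model**
(cosines to the top-\(n\) ranked feature words, default 100).

Two statistical controls calibrate what "high commonality" means:

* **Random-word model** — 13 anchors sampled from the concept list, the
  same identities reused in every language within an iteration (default
  13; the reference description varies between 13 and 100 across
  sections, so the count is an exposed parameter).
* **Random-dimension model** — a dimensionality-matched control: 100
  sampled words grouped into 13 pseudo-dimensions by K-means on a
  designated reference language's vectors, the grouping transferred by
  concept identity. Clustering in one reference language is the only
  construction that yields aligned columns across languages.

# Universality metrics

The **inter-language correlation (ILC)** between two spaces is the
per-concept Pearson correlation between the two languages' projection
rows, Fisher z-transformed (correlations clipped to \(\pm(1-10^{-7})\)
before `atanh`, so perfect correlations map to a large finite value) and
averaged over concepts. Model comparisons over the same language pairs use
two-sided Wilcoxon signed-rank tests (exact below \(n=25\)) with
Benjamini–Hochberg correction across the declared family.

**PCA universality** reshapes each language's concept-by-dimension matrix
into a vector, treats languages as features and cells as samples, and
reports the PC1 explained-variance share of a correlation PCA (columns
centred and unit-scaled; this choice makes the share approach \(1/L\)
exactly for independent languages, which is tested).

**Permutation nulls** draw `n_iters` statistics from a null generator and
report the one-tailed \(p = (1 + \#\{null \ge observed\})/(n_{iters}+1)\),
never exactly zero. The reference analysis used 10,000 iterations for
embedding nulls and 1,000 for colexification nulls; those are the function
defaults, while the package's tests and the acceptance script use 99–199
iterations, which is ample to resolve \(p < 0.05\) decisions.

For rating studies, the **inter-subject correlation matrix** is the raw
Pearson correlation between participants' full concept-by-dimension rating
vectors. The **QC filter** is a single pass: each participant is
correlated with the within-language group mean (computed over all
participants, including the candidate) and excluded below 0.5. Note the
self-inclusion matters at small samples: with six raters the candidate
contributes 1/6 of the group mean and a pure-noise rater can sit right at
the 0.5 boundary; from about ten raters per language the filter behaves as
intended. **Variance components** decompose ratings into a universal
(grand concept-by-dimension pattern), language-specific, and
participant-residual share by expected mean squares with the harmonic mean
of group sizes for unbalanced designs; negative estimates are truncated at
zero and flagged.

# Colexification topology

A colexification graph has concepts as nodes and edges weighted by the
number of languages expressing both concepts with one wordform. Four
metrics capture first-order, second-order and global structure: edge
weight; weighted common neighbours (the bounded, symmetric
\(\sum_z \min(w(a,z), w(b,z))\) convention, with the product convention
behind a flag, since no formula is standard); and Louvain and Infomap
community co-membership (fraction of seeded runs in which a pair shares a
community, 10 runs by default). The metrics live on incommensurable
scales, so each is min–max normalized over all pairs before averaging —
a constant metric contributes 0.5 uniformly and is flagged (on small dense
graphs Infomap often returns a single community; the flag makes that
visible rather than silent). The combined distance is 1 − combined
similarity; non-edges enter with weight 0, i.e. maximal first-order
distance. Generalization is scored per language as the Spearman
correlation between anchor-space semantic distances (1 − Pearson between
concept rows) and topology distances, averaged over languages, and
benchmarked against the random-dimension null.

# Environmental distances

* **Climate** — each of the 19 bioclim-style variables z-scored across
  languages, then Euclidean distance; missing values exclude the language
  (no imputation); constant variables are dropped with a warning.
* **Geography** — haversine great-circle distance on a sphere of radius
  6371.0088 km; the WGS84 ellipsoidal alternative differs by under 0.6%
  and is irrelevant after standardization.
* **Linguistic history** — tree-step distance on a family tree: steps
  from each leaf to the lowest common ancestor, summed (a metric;
  max-steps behind a flag).
* **Demographics** — language-level means of age, proportion-coded
  gender, education and SES, z-scored, Euclidean.
* Culture and cognate-based history distances are consumed as labelled
  CSV matrices.

# Mixed representational similarity regression

The response is the lower triangle of a response RDM; the semantic RDM
between languages is \(1 - \mathrm{atanh}(r)\) where \(r\) is the Pearson
correlation between flattened concept-by-dimension matrices. This is the
literal reading of "1 − correlation, Fisher z-transformed"; it can be
negative for strongly correlated pairs, which is harmless because every
column of the pair table — response included — is standardized before
fitting, making the coefficients standardized effects.

The primary model is
\[
y_{ij} = \beta_0 + \beta_1 \mathrm{Climate}_{ij} + \dots +
(1\mid \mathrm{Family}_i) + (1\mid \mathrm{Family}_j) + \varepsilon_{ij},
\]
fitted by REML (`lme4`), with Wald 95% intervals and two-sided
normal-approximation p-values; variance estimates at the zero boundary are
permitted and flagged, and a rank-deficient design is an error naming the
collinear columns. Language-level crossed intercepts are available via
`random_structure = "language"` (or `"both"`).

Per-ROI and per-dimension fits apply Benjamini–Hochberg correction across
their families (12 ROIs, 13 dimensions by default). The per-dimension RDM
defaults to the correlation form on the dimension's concept vector;
`method = "euclidean"` is the variant sensitive to pure per-dimension
rescaling, which a correlation cannot see — the planted-dimension recovery
analysis therefore uses the Euclidean form.

**Hierarchical regression** reports the OLS \(R^2\) of a first block
(e.g. demographic distance), the increment from a second block (the four
environmental variables), and the Spearman correlation between fitted and
observed distances. **Commonality analysis** partitions the full model's
\(R^2\): unique(semantic) \(= R^2_{full} - R^2_{clim}\),
unique(climate) \(= R^2_{full} - R^2_{sem}\), common
\(= R^2_{sem} + R^2_{clim} - R^2_{full}\); shares divide by
\(R^2_{full}\) and sum to one by construction, negative components
(suppression) are flagged, and confidence intervals come from a cluster
bootstrap that resamples languages (not pairs) and rebuilds the pair
table, respecting the dependence structure.

# Climate principal components and semantic projection

Climate PCA z-scores the variables and orients each component so its
largest-|loading| variable loads positively (signs are otherwise
arbitrary). Projection multiplies each language's space — scaled by its
own standard deviation, deliberately *without* centring — by the
language's PC score and averages across languages. Centring would make
every map exactly mean-zero, which forces the association ratio (summed
mass in one direction over total mass) to 0.5 for the full map and for any
complete partition of it; uncentred scaling preserves the sign structure
of the cosine associations, keeps the ratio informative, and localizes a
planted climate-sensitive dimension just as reliably. The ratio's two
directions sum to one exactly.

# The synthetic world

`generate_world()` produces, from parameters and a single seed, a complete
ground-truth world:

* a family tree (5 families × 6 languages by default) with families at
  depth 1, so within-family tree-step distances always undercut
  between-family ones;
* a latent concept × 13 loading matrix with sparse block structure (each
  concept loads high on 1–3 dimensions) plus, per dimension, anchor
  concepts whose loading is concentrated on that dimension, so the anchor
  specification is recoverable by construction;
* **nuisance dimensions** (12 by default, loading scale 0.3,
  cross-language stability 0.7): shared non-neurocognitive structure of
  the kind real embeddings carry (topical and distributional variance)
  that is *less stable* across languages than the dimensional core.
  Without it, the random-dimension control's K-means simply rediscovers
  the 13 true dimensions — the only structure in the world — and the
  control loses its meaning;
* climate profiles generated from two family-correlated latent factors
  (temperature-like and precipitation-like) with uniform loadings and
  residual noise, mirroring the strong low-rank structure of real bioclim
  tables, where the first two components dominate;
* per-language dimension scalings
  \(s_{l,d} = \exp(\beta_{scale}\, w_d\, c_l + \text{family} +
  \text{noise})\), where \(c_l\) is the standardized first climate PC and
  \(w_d\) a per-dimension sensitivity (set \(w\) to a basis vector to make
  a single dimension climate-sensitive);
* embeddings: each concept's scaled latent row plus nuisance loadings,
  corrupted by Gaussian noise *in the latent subspace*, zero-padded and
  rotated by a per-language orthogonal matrix. The noise level `noise_sd`
  is relative — a multiple of the per-coordinate standard deviation of
  the latent signal — so it is comparable across loading scales and
  embedding dimensionalities. (Cosine projections are exactly invariant
  to the rotations; they model the incomparability of raw coordinates.)

Because correlation-based distances are invariant to common rescalings and
respond nonlinearly to the exp-link, the chain from scalings to pairwise
semantic distance does not carry an analytically known standardized
coefficient. The world therefore *also* plants a distance-level semantic
response directly:
\(t_{ij} = \beta\, x_{ij} + u_{f(i)} + u_{f(j)} + \varepsilon_{ij}\)
with \(x\) the standardized climate distance, family intercepts of
variance `family_variance`, and residual variance derived as
\(1 - \beta^2 - 2\,\sigma^2_{fam}\) so that the planted \(\beta\) *is* the
standardized coefficient. Parameter-recovery, coverage and type-I-error
analyses use this response; the embedding chain drives the universality,
colexification and projection analyses, where what matters is structure
against a null rather than a specific coefficient.

Ratings map each language's true pattern affinely onto the 1–5 band of the
0–6 scale *per language* — raters anchor a bounded response scale within
their own language, and correlation-based downstream analyses are
invariant to per-language affine maps — then add participant noise, with
optional planted "careless" (pure-noise) raters. Neural RDMs mix the
planted semantic response and the climate RDM into one "r-ATL-like" ROI
and fill the remaining ROIs (12 total) with noise.

What the generator deliberately does **not** emulate: lexical phonology,
realistic geography or spatial autocorrelation beyond family clustering,
corpus-derived frequency effects, polysemy within a language, and
rater-specific response styles. Passing recovery tests on these worlds
shows the estimators do what they claim under the stated model; it does
not show that real cross-linguistic variation satisfies that model.

# Problem sizes and numerical choices

Defaults were chosen so a full test run and the acceptance script complete
comfortably on a single CPU: 30 languages in 5 families, 60 target
concepts, 4 anchors per dimension, embedding dimension 50, permutation
nulls of 99–199 iterations (10,000/1,000 remain the function defaults for
full-scale use), 50-world recovery batches, and a random-dimension control
of `floor(n_concepts/2)` = 30 sampled words at this concept-pool size (the
100-word default assumes a concept pool an order of magnitude larger).

Other numerical conventions: correlations clipped at
\(\pm(1 - 10^{-7})\) before Fisher transformation; permutation p-values
use the +1 convention; ties in Spearman correlations take average ranks;
K-means for the random-dimension control retries on empty clusters up to a
cap; min–max normalization of topology metrics with the constant-metric
0.5 rule; all tabular outputs serialized at 10 significant digits, making
pipeline runs byte-reproducible for a fixed config and seed.

# Known limitations

* **Pair dependence beyond crossed intercepts.** The \(L(L-1)/2\) rows of
  a pair table are built from only \(L\) languages. Additive family or
  language intercepts absorb part of that dependence, but distances are
  not additive in their endpoints, and for distance types with strong
  language-level structure (notably Euclidean per-dimension distances
  under multiplicative scaling) the family-only model is anti-conservative
  for nulls: false-discovery control at the per-dimension level holds
  under the correlation metric with language-level intercepts, not under
  the Euclidean metric with family intercepts. Dimension-level inference
  on real data should prefer `random_structure = "language"` and treat
  family-model per-dimension p-values as descriptive.
* **REML boundary behaviour.** On worlds with truly zero family variance,
  REML sometimes estimates a small positive variance; fixed effects then
  deviate from OLS by up to a few hundredths of a standardized unit. The
  OLS-equivalence guarantee applies when the variance estimates land at
  the boundary.
* **QC self-inclusion.** The single-pass group mean includes the
  candidate; below ~8 raters per language the 0.5 threshold loses power
  against careless raters.
* **Association ratios.** Only meaningful for uncentred projections or
  for subsets/summaries; any mean-zero map yields exactly 0.5.
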