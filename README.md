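# crosslex

Cross-linguistic semantic spaces, universality benchmarks, and
environmental representational similarity analysis.

## What it is for

Word embeddings trained separately per language live in arbitrary
coordinate systems, so the geometry of meaning cannot be compared across
languages directly. `crosslex` is for researchers in cross-linguistic
semantics and computational cognitive neuroscience who want to ask two
linked questions:

1. **How much semantic structure do languages share?** Concepts are
   projected onto anchor words — the core model uses 13 neurocognitive
   dimensions (color, shape, taste, smell, sound, touch, motor; time,
   space, number, cognition, emotion, social), with entry *(c, d)* the
   mean cosine similarity between concept *c* and dimension *d*'s anchor
   vectors. Because cosines are rotation-invariant, the projected spaces
   are comparable across languages. Commonality is measured by Fisher-z
   inter-language correlations (ILC) and by the PC1 share of a
   languages-as-features PCA, and benchmarked against two permutation
   nulls: random anchor words, and a dimensionality-matched random
   grouping of anchor words (K-means into 13 pseudo-dimensions).
   Generalization beyond embedding-bearing languages is tested against
   colexification-network topology (edge weight, weighted common
   neighbours, Louvain and Infomap co-membership, averaged after min-max
   normalization).

2. **What explains the variation that remains?** Between-language
   semantic, behavioural-rating, or neural distances (RDMs) are regressed
   on environmental distance matrices — climate (19 bioclim variables,
   z-scored Euclidean), geography (great-circle km), linguistic history
   (family-tree steps), culture, demographics — with crossed random
   intercepts for the language families of both pair members:

   ```
   y_ij = b0 + b1*Climate_ij + b2*Culture_ij + b3*Geography_ij
        + b4*LinguisticHistory_ij + (1|Family_i) + (1|Family_j) + e_ij
   ```

   All columns are standardized, so the `b`s are standardized effects.
   Hierarchical regression increments, per-dimension and per-ROI fits
   with Benjamini-Hochberg correction, competing-structure and
   peak-distance controls, commonality variance partitioning with a
   cluster bootstrap, and a climate principal-component semantic
   projection complete the toolbox.

A seeded synthetic-world generator (`generate_world()`) with planted
effect sizes stands in for the external datasets and supports
parameter-recovery and calibration tests of every stage; see the methods
vignette (`vignettes/crosslex-methods.Rmd`) for the generative model and
the reasoning behind each design choice.

## Worked example

```r
library(crosslex)

world      <- generate_world(n_families = 4, langs_per_family = 4,
                             n_concepts = 50, seed = 42)
embeddings <- emit_embeddings(world)
spaces     <- lapply(embeddings, neurocognitive_space,
                     anchors = world$anchor_spec)
spaces[[1]]
#> <semantic_space> neurocognitive model, language lang01: 50 concepts x 13 dims

ilcm <- ilc_matrix(spaces)
sprintf("mean inter-language correlation (Fisher z): %.3f", ilcm$mean_ilc)
#> mean inter-language correlation (Fisher z): 0.958

set.seed(1)
null_benchmark(ilcm$mean_ilc, function(i) {
  anchors <- sample_random_anchors(world$target_concepts, 13)
  ilc_matrix(lapply(embeddings, random_word_space, anchor_ids = anchors,
                    targets = world$target_concepts))$mean_ilc
}, n_iters = 99, statistic = "mean_ILC")
#> <null_distribution> mean_ILC: observed 0.9575 vs 99 nulls (95th pct 0.6722), one-tailed p = 0.01

env <- list(climate   = world$climate_rdm,
            geography = geodesic_distance(world$coordinates),
            history   = tree_distance_matrix(world$family_tree))
pairs <- make_pair_table(world$semantic_rdm_true, env, world$families)
fit_env_model(pairs)
#> <mixed_fit> 120 pairs; family variances 0.02502 / 0.05052; marginal R2 0.360
#>          term  estimate      se   ci_lo  ci_hi         p
#> 1 (Intercept)  0.004574 0.16951 -0.3277 0.3368 9.785e-01
#> 2     climate  0.591010 0.07449  0.4450 0.7370 2.119e-15
#> 3   geography  0.072141 0.12036 -0.1638 0.3080 5.489e-01
#> 4     history -0.010529 0.12386 -0.2533 0.2322 9.323e-01
```

Reading the output: the anchor-projected spaces of the 16 synthetic
languages correlate strongly (mean Fisher-z 0.96), far above the 95th
percentile of the random-word null (0.67, permutation p = 0.01) — the
commonality is carried by the anchor structure, not by projection per se.
The mixed model then attributes the residual between-language variation to
climate (standardized beta 0.59, 95% CI [0.45, 0.74]; this world planted a
climate effect of 0.5 on the standardized scale), while geography and
linguistic history are correctly flat.

`run_pipeline(run_config(out_dir, seed = 7))` chains every stage —
fixture emission, projection, ILC with both nulls, PCA, colexification
topology, environmental RDMs, mixed-model fits, commonality partition,
climate-PC projection — and writes a manifest with the seed and the md5
of every artifact; identical config and seed give byte-identical outputs.

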