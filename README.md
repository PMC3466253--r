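# phylorisk

Phylogenetic and taxonomic selectivity of plant extinction risk.

`phylorisk` is an R package for conservation biologists and comparative
ecologists who want to ask whether IUCN threat status is non-randomly
distributed over a flora — across its families, and across its phylogeny —
and what that structure implies. It covers the standard workflow for a
red-listed species checklist in a region where most species have never been
sequenced:

1. **Tree assembly** — graft species without phylogenetic placements onto a
   taxonomy-labelled backbone at their genus (else family) node
   (Phylomatic-style), date the nodes by even interpolation between anchors
   of known age (BLADJ-style), and extract maximally resolved "thinned"
   subtrees to check robustness to polytomies.
2. **Taxonomic selectivity** — per-family randomization test of the
   proportion of threatened species, permuting binary threat labels while
   holding family sizes fixed.
3. **Phylogenetic signal** — the Fritz–Purvis *D* statistic for a binary
   trait, scaled between a tip-shuffle null and a Brownian-threshold null:

   *D* = (Σd_obs − mean Σd_Brownian) / (mean Σd_random − mean Σd_Brownian)

   where Σd is the sum of sister-clade differences of nodal trait values.
   *D* ≈ 1 for phylogenetically random traits, ≈ 0 under a Brownian
   threshold model, < 0 for strongly conserved traits, > 1 for
   overdispersed ones.
4. **Within-category structure** — NRI and NTI (negated standardized effect
   sizes of mean pairwise distance and mean nearest-taxon distance) for the
   species of each threat category, under a phylogeny-pool null; positive
   values mean phylogenetic clustering.
5. **Evolutionary models of risk** — maximum-likelihood fit of a symmetric
   two-state Markov (Mk2) model of threat status on branch-length-transformed
   trees — `delta` (node depths raised to a power), `linearChange`
   (linearly time-varying rate), `twoRate` (abrupt rate shift at a
   breakpoint) and the constant-rate `null` — compared by AIC.
6. **Geography of risk** — log–log OLS regressions of threatened-species
   richness per forest block on elevation (minimum, maximum, mean, range)
   and climate (temperature, rainfall), with and without block area as a
   covariate, ranked by AICc.

Seeded generators (`sim_yule_tree()`, `sim_threat()`, `sim_taxonomy()`,
`sim_blocks()`) produce synthetic inputs with known structure, so every
stage is testable without external data, and `run_pipeline()` executes the
whole analysis under one master seed with a reproducibility manifest.

## Worked example

A small synthetic dataset ships with the package: a genus/family-labelled
backbone tree, a node-age table, a 90-species red-list table, and a
13-block environment table (all generated, as the filenames say).

```r
library(phylorisk)

extdata  <- system.file("extdata", package = "phylorisk")
species  <- file.path(extdata, "synthetic_species.csv")
backbone <- file.path(extdata, "synthetic_backbone.nwk")
ages     <- file.path(extdata, "synthetic_ages.csv")
blocks   <- file.path(extdata, "synthetic_blocks.csv")

res <- run_pipeline(list(species = species, backbone = backbone, ages = ages,
                         blocks = blocks, seed = 1,
                         n_perm = 1000, n_null = 1000, n_rand = 1000,
                         thin_replicates = 25))

print(binarize_risk(read_species_table(species)))
#> Risk table: 90 species
#>   threatened (EX+CR+EN+VU):      49 (54.44%)
#>   not threatened (LR/CD+NT+LC):  40 (44.44%)
#>   excluded (DD):                 1

print(res$dstat)
#> Phylogenetic signal (binary trait), 89 tips, prevalence 49
#>   D = 0.9869  (sum d obs = 41.021; null means: shuffle 41.251, Brownian 23.679)
#>   P(no more clumped than random)   = 0.3956
#>   P(Brownian at least as dispersed) = 0.0010
```

The 90 synthetic species carry categories drawn independently of the tree,
and the analysis says exactly that: *D* = 0.99 is indistinguishable from
the tip-shuffle expectation of 1 (p = 0.40), and far more dispersed than a
Brownian threshold trait (p = 0.001). The binarization partitions the
checklist into threatened (EX+CR+EN+VU), not threatened (LR/CD+NT+LC) and
excluded (DD) species, and every downstream stage consumes that partition.

```r
print(res$community)
#>   category SR  mpd_obs  mntd_obs        NRI        NTI     p_NRI     p_NTI ...
#> 1       VU 33 236.4583  80.00000 -0.3243192 -0.3255445 0.5894106 0.6373626
#> 2       EN 13 240.7179  89.07692 -0.5667512  0.9146412 0.6783217 0.1828172
#> 3       CR  3 230.0000 180.00000  0.1505258  0.4259830 0.4225774 0.4125874

head(as.data.frame(res$regressions), 3)
#>                    model       type       predictor      slope      p_value ...
#> 1        Elevation range univariate Elevation range 1.24624129 2.208977e-06
#> 2 Area + Elevation range  bivariate            Area 0.09483485 2.439210e-01
#> 3 Area + Elevation range  bivariate Elevation range 1.21087658 5.516171e-06
```

No threat category is phylogenetically clustered (all NRI/NTI p > 0.05, as
expected for random labels), while the block regressions recover the
elevation-range effect built into the synthetic block table (slope 1.25 on
the log–log scale, ranked first by AICc with adjusted R² = 0.87). With
`out_dir =` set, `run_pipeline()` also writes every stage's table plus a
`manifest.json` recording seeds and input checksums; rerunning with the
same config and seed reproduces all stochastic outputs bit-exactly.

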