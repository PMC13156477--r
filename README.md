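# phylopatch

Community phylogenetics of patch colonization and extinction.

## The problem

Habitat size and predation are two of the strongest drivers of local
diversity, but observational surveys alone cannot say *how* they act: a
species-poor patch may be small because few species colonize it, or
because many go locally extinct there. `phylopatch` implements a
patch-dynamics analysis of this question for invertebrate communities
assembled in discrete aquatic habitat patches (tank bromeliads), where a
natural survey is paired with two experiments that isolate the
colonization stage (empty plants left to be colonized across a habitat-size
gradient, with or without caged predators) and the extinction stage
(netted plants seeded with a standardized community, survival scored
under the same size x predator design).

The package is aimed at community ecologists who want to run that whole
workflow — or calibrate it on simulated data — without re-deriving any of
its statistics.

## What it computes

**Relatedness metrics and standardized effect sizes.** For each
community, the mean pairwise patristic distance (MPD) and mean
nearest-taxon distance (MNTD), unweighted or abundance-weighted with
weights `a_i = n_i^e` (a compressive exponent `e = 0.5` by default for
natural and colonizing communities, `e = 1` for extinction data, where
every individual is an extinction event). Each observed value is
standardized against a *taxa-labels* null — species labels shuffled over
the pool, preserving each community's richness — giving

```
NRI = -(MPD_obs - mean(MPD_null)) / sd(MPD_null)
NTI = -(MNTD_obs - mean(MNTD_null)) / sd(MNTD_null)
```

so positive values mean phylogenetic clustering. Small pools can be
solved by exhaustive enumeration of the null instead of Monte-Carlo
sampling. Faith's PD and its correlation with richness are provided to
justify dropping PD as a redundant response.

**Species response indices.** Per-species z-scores comparing an observed
distribution statistic to a constructed assembly null: mean habitat size
of colonists vs. uniform placement (size preference), fraction of
colonists in predator-free plants vs. a binomial null (predator
avoidance), and the analogous statistics over surviving individuals under
a fixed-survivor-count hypergeometric null (size and predator
sensitivity). All four have closed-form nulls, with Monte-Carlo as a
cross-check; |z| >= 1.96 flags significance.

**Phylogenetic signal.** Blomberg's K with tip-shuffle permutation tests
(Pagel's lambda as an option), run per response index at nested taxonomic
scales (all invertebrates; insects, excluding the deep annelid lineage;
dipterans only), with low-power flags for small pools.

**Model selection.** OLS models of each standardized diversity metric on
habitat size (log10 water capacity, centered), its square, predator
biomass/treatment, their interaction and (surveys only) detrital mass;
all marginality-respecting subsets compared by
`AICc = -2 lnL + 2k + 2k(k+1)/(n-k-1)`, ties within 2 units resolved to
the fewest terms; per-term partial R², signs and t-tests feed a
heatmap-ready contribution table.

**A study simulator.** Yule trees with a deep outgroup clade, Brownian
(conserved) or white-noise (convergent) response traits, and generative
models of all three datasets with tunable size, avoidance and predation
effects — the basis of the package's null-calibration and
parameter-recovery guarantees.

## Worked example

A two-species cherry community on a balanced four-tip tree, standardized
against the exhaustive taxa-labels null:

```r
library(phylopatch)
tr <- readPhylogeny("((A:1,B:1):1,(C:1,D:1):1);")
cnt <- matrix(c(1, 1, 0, 0), 1, 4, dimnames = list("b1", c("A", "B", "C", "D")))
be <- BromeliadExperiment(cnt, meta = data.frame(row.names = "b1",
        capacity_ml = 150, predator_present = FALSE), role = "survey")
sesMetric(be, patristicDistances(tr), metric = "mpd", method = "exhaustive")
#>  bromeliad metric  weighting observed null_mean null_sd    ses nri_or_nti
#>         b1    mpd unweighted        2     3.333  0.9428 -1.414      1.414
```

The six equally likely relabelings of a 2-species community have MPD
{2, 2, 4, 4, 4, 4}; the observed cherry (MPD = 2) sits 1.414 population
SDs below that mean, i.e. NRI = sqrt(2): the two co-occurring species are
maximally clustered on this tree.

A simulated study under conserved habitat filtering, analysed end to end:

```r
st <- simulateStudy(conservedFilterConfig(seed = 42, nSpecies = 30))
sub <- subsetTaxonomicScale(st@colonization, st@tree, "insecta")
meta <- bromeliadMeta(sub$be)
fitCandidates(data.frame(size = meta$log_size,
                         pred = as.numeric(meta$predator_present)),
              rowSums(communityMatrix(sub$be) > 0),
              role = "colonization", transform = "none")
#> AICc model selection over 8 candidates (n = 20 )
#> chosen: size
#>      estimate partial_r2 p
#> size   2.1412     0.9199 0
```

Colonizing richness rises with habitat size (standardized slope 2.14,
partial R² 0.92), recovering the simulated filter. The species-level
indices behind it, and their phylogenetic signal:

```r
idx <- sizePreference(st@colonization)
head(idx[order(-idx$z), c("species", "z", "significant", "n_events")], 3)
#>  species    z significant n_events
#>    sp004 6.25        TRUE       24
#>    sp002 5.92        TRUE       29
#>    sp011 5.63        TRUE       19
z <- setNames(idx$z[!idx$degenerate], idx$species[!idx$degenerate])
blombergK(st@tree, z, nPerm = 999, seed = 1)[c("K", "p_perm")]
#> $K [1] 0.281      $p_perm [1] 0.001
```

`runPipeline(study = st, outdir = "out")` runs every role x scale x
metric cell and writes `metrics.csv`, `models.csv`, `indices.csv`,
`signal.csv`, `heatmap.csv` and a checksummed `manifest.json`.

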