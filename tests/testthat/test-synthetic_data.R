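test_that("tree simulation is deterministic, ultrametric, and outgrouped", {
  cfg <- simulationConfig(seed = 101, nSpecies = 20)
  t1 <- simulateTree(cfg)
  t2 <- simulateTree(cfg)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))

  # ingroup-only tree is ultrametric
  cfg0 <- simulationConfig(seed = 102, nSpecies = 10, outgroupSize = 0,
                           nColeoptera = 0)
  tr0 <- simulateTree(cfg0)
  expect_equal(length(tr0$tip.label), 10)
  depths <- ape::node.depth.edgelength(tr0)[1:10]
  expect_lt(diff(range(depths)), 1e-9)

  # outgroup tips are farther from every ingroup tip than any ingroup pair
  d <- patristicDistances(t1)
  cl <- attr(t1, "clades")
  out <- names(cl)[cl == "Annelida"]
  ing <- setdiff(names(cl), out)
  expect_length(out, 3)
  expect_gt(min(d[out, ing]), max(d[ing, ing]))
})

test_that("clade labels partition the pool into the three analysis groups", {
  cfg <- simulationConfig(seed = 103, nSpecies = 30)
  tr <- simulateTree(cfg)
  cl <- attr(tr, "clades")
  expect_setequal(names(cl), tr$tip.label)
  expect_setequal(unique(cl), c("Annelida", "Coleoptera", "Diptera"))
  # Coleoptera forms a clade (monophyletic in the ingroup)
  col <- names(cl)[cl == "Coleoptera"]
  expect_true(ape::is.monophyletic(tr, col))
})

test_that("trait simulation is standardized and respects the model switch", {
  cfg <- simulationConfig(seed = 104, nSpecies = 30)
  tr <- simulateTree(cfg)
  traits <- simulateTraits(tr, cfg, seed = 1)
  expect_setequal(rownames(traits), tr$tip.label)
  for (v in colnames(traits)) {
    expect_lt(abs(mean(traits[[v]])), 1e-10)
    expect_equal(sd(traits[[v]]), 1, tolerance = 1e-10)
  }
  # sigma 0 collapses to a constant
  cfg0 <- simulationConfig(seed = 104, nSpecies = 10,
                           traitModels = list(pref = list(model = "BM", sigma = 0),
                                              avoid = list(model = "WN", sigma = 1),
                                              tol = list(model = "BM", sigma = 1),
                                              vuln = list(model = "WN", sigma = 1)))
  tr0 <- simulateTree(cfg0)
  tt <- simulateTraits(tr0, cfg0, seed = 2)
  expect_equal(var(tt$pref), 0)
})

test_that("whole-study simulation is reproducible from its seed", {
  a <- simulateStudy(simulationConfig(seed = 105, nSpecies = 15))
  b <- simulateStudy(simulationConfig(seed = 105, nSpecies = 15))
  expect_identical(ape::write.tree(a@tree), ape::write.tree(b@tree))
  expect_identical(communityMatrix(a@survey), communityMatrix(b@survey))
  expect_identical(communityMatrix(a@colonization), communityMatrix(b@colonization))
  expect_identical(introducedCounts(a@extinction), introducedCounts(b@extinction))
})

test_that("the experimental design crosses 10 size levels with 2 predator arms", {
  st <- simulateStudy(simulationConfig(seed = 106, nSpecies = 15))
  for (be in list(st@colonization, st@extinction)) {
    meta <- bromeliadMeta(be)
    expect_equal(nrow(meta), 20)
    expect_equal(length(unique(meta$capacity_ml)), 10)
    expect_equal(sum(meta$predator_present), 10)
    # each size level has one plant per arm
    expect_true(all(table(meta$capacity_ml, meta$predator_present) == 1))
  }
  rng_c <- range(bromeliadMeta(st@colonization)$capacity_ml)
  expect_equal(rng_c, c(45, 1050), tolerance = 1e-6)
  expect_equal(range(bromeliadMeta(st@extinction)$capacity_ml), c(40, 490),
               tolerance = 1e-6)
  rng_s <- range(bromeliadMeta(st@survey)$capacity_ml)
  expect_gte(rng_s[1], 22); expect_lte(rng_s[2], 1446)
})

test_that("extinction tables satisfy introduced >= surviving and null survival is 50%", {
  st <- simulateStudy(simulationConfig(seed = 107, nSpecies = 20))
  intro <- introducedCounts(st@extinction)
  surv <- communityMatrix(st@extinction)
  expect_true(all(intro >= surv))
  expect_equal(nrow(st@extinction), 10)   # designed 10-species community
  rate <- sum(surv) / sum(intro)
  se <- sqrt(0.25 / sum(intro))
  expect_lt(abs(rate - 0.5), 4 * se + 0.01)
  # introduced counts scale with capacity (log-log slope 1)
  meta <- bromeliadMeta(st@extinction)
  expect_gt(cor(log10(intro[, 1]), meta$log_size), 0.99)
})

test_that("the designed extinction community mirrors the field mix of clades", {
  st <- simulateStudy(simulationConfig(seed = 108, nSpecies = 30))
  cl <- cladeLabels(st@extinction)
  expect_equal(sum(cl == "Annelida"), 1)
  expect_equal(sum(cl == "Coleoptera"), 1)
  expect_equal(sum(cl == "Diptera"), 8)
})

test_that("zero-effect colonization places colonists uniformly", {
  set.seed(1)
  cfg <- simulationConfig(seed = 109, nSpecies = 40, lambdaCol = 30)
  st <- simulateStudy(cfg)
  m <- communityMatrix(st@colonization)
  # per-species totals are Poisson(30): mean near 30
  totals <- colSums(m)
  expect_lt(abs(mean(totals) - 30), 3 * sqrt(30 / 40))
  # occupancy should not trend with size: correlation near zero
  meta <- bromeliadMeta(st@colonization)
  r <- cor(meta$log_size, rowSums(m))
  expect_lt(abs(r), 0.6)
})

test_that("strong predator mortality depresses richness in the predator arm", {
  hits <- vapply(1:20, function(i) {
    st <- simulateStudy(simulationConfig(seed = 1100 + i, nSpecies = 30,
                                         gammaPred = 2))
    m <- communityMatrix(st@extinction)
    meta <- bromeliadMeta(st@extinction)
    mean(rowSums(m[meta$predator_present, ] > 0)) <
      mean(rowSums(m[!meta$predator_present, ] > 0))
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("survey covariates scale with habitat size as constructed", {
  st <- simulateStudy(simulationConfig(seed = 110, nSpecies = 20))
  meta <- bromeliadMeta(st@survey)
  expect_true(all(c("predator_biomass", "detritus_mass",
                    "microhabitat_flag") %in% colnames(meta)))
  pres <- meta$predator_biomass > 0
  expect_gt(cor(meta$log_size, meta$detritus_mass, method = "spearman"), 0.5)
  if (sum(pres) >= 5)
    expect_gt(cor(meta$log_size[pres], meta$predator_biomass[pres],
                  method = "spearman"), 0)
})

test_that("strong conserved size preference drives richness up with size", {
  hits <- vapply(1:15, function(i) {
    st <- simulateStudy(conservedFilterConfig(seed = 1200 + i, nSpecies = 30))
    m <- communityMatrix(st@survey)
    meta <- bromeliadMeta(st@survey)
    cor(meta$log_size, rowSums(m > 0)) > 0
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("scenario YAML files reproduce the scenario constructors", {
  path <- system.file("extdata", "conserved_filter.yaml", package = "phylopatch")
  cfg <- readScenario(path, seed = 5)
  ref <- conservedFilterConfig(seed = 5, nSpecies = 124)
  expect_equal(cfg$betaSize, ref$betaSize)
  expect_equal(cfg$traitModels, ref$traitModels)
  expect_identical(ape::write.tree(simulateTree(cfg)),
                   ape::write.tree(simulateTree(ref)))
})
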