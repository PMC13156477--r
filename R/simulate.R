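#' Configuration for the study simulator
#'
#' Defaults emulate the field design: a species pool of 124 invertebrates
#' on an unbalanced tree with a deep 3-tip Annelida outgroup and a small
#' Coleoptera clade (the rest Diptera); 20 bromeliads per dataset;
#' experiments cross 10 habitat-size levels with two predator arms;
#' water capacities span 22-1446 mL (survey, log-uniform), 45-1050 mL
#' (colonization) and 40-490 mL (extinction); the designed extinction
#' community holds 10 species (one annelid, one coleopteran, eight
#' dipterans). Effect sizes default to zero (the null configuration);
#' log-log scaling slopes for introduced biomass, detritus and predator
#' biomass default to 1 and are realism placeholders, not fitted values.
#'
#' @param seed integer seed; the whole study is reproducible from
#'   (config, seed).
#' @param nSpecies species-pool size (>= 4), including the outgroup.
#' @param outgroupSize,outgroupStemMultiplier deep outgroup clade: number
#'   of tips (0 disables) and stem length as a multiple of the ingroup
#'   root-to-tip depth.
#' @param nColeoptera approximate size of the Coleoptera clade.
#' @param yuleRate birth rate of the pure-birth ingroup tree.
#' @param traitModels per-trait evolution model, a named list over
#'   \code{pref} (size preference), \code{avoid} (predator avoidance),
#'   \code{tol} (size tolerance) and \code{vuln} (predator vulnerability);
#'   each entry \code{list(model = "BM"|"WN", sigma = ...)}. BM gives
#'   phylogenetically conserved traits, white noise convergent/labile
#'   ones. Simulated traits are standardized across the pool.
#' @param nBromeliads bromeliads per dataset.
#' @param nSizeLevels discrete size levels in the experiments.
#' @param capacityRange named list of c(min, max) capacities (mL) per role.
#' @param lambdaCol expected colonists per species (Poisson mean).
#' @param betaSize,gammaAvoid colonization effects: attraction to large
#'   plants (log-odds per SD of log size, scaled by the species' pref
#'   trait) and oviposition deterrence by predators (scaled by avoid).
#' @param alphaSurvival,gammaSize,gammaPred extinction effects: baseline
#'   survival log-odds, survival benefit of large plants (times tol) and
#'   predator-induced mortality (times vuln).
#' @param nExtinctionSpecies size of the designed extinction community.
#' @param introBase introduced individuals per species in the smallest
#'   bromeliad; counts scale as capacity^introducedSlope.
#' @param introducedSlope,detritusSlope,predatorSlope log-log scaling
#'   slopes.
#' @param predatorNoiseSd lognormal noise SD on survey predator biomass
#'   and detritus.
#' @param traitShifts named numeric vector of community-wide offsets added
#'   to the standardized traits inside the assembly rules. Size preference
#'   and predator vulnerability default to +1: when their effect sizes are
#'   switched on, most species prefer larger plants (the species-area
#'   direction) and most are killed, not protected, by the predator, while
#'   the trait still supplies (possibly conserved) variation around the
#'   community mean. Avoidance and size tolerance are centered.
#' @return a list of class \code{"phylopatchSimConfig"}.
#' @export
simulationConfig <- function(seed = 1L,
                             nSpecies = 124L,
                             outgroupSize = 3L,
                             outgroupStemMultiplier = 3,
                             nColeoptera = 3L,
                             yuleRate = 1,
                             traitModels = list(
                               pref = list(model = "BM", sigma = 1),
                               avoid = list(model = "BM", sigma = 1),
                               tol = list(model = "BM", sigma = 1),
                               vuln = list(model = "BM", sigma = 1)),
                             nBromeliads = 20L,
                             nSizeLevels = 10L,
                             capacityRange = list(survey = c(22, 1446),
                                                  colonization = c(45, 1050),
                                                  extinction = c(40, 490)),
                             lambdaCol = 20,
                             betaSize = 0, gammaAvoid = 0,
                             alphaSurvival = 0, gammaSize = 0, gammaPred = 0,
                             nExtinctionSpecies = 10L,
                             introBase = 3L,
                             introducedSlope = 1, detritusSlope = 1,
                             predatorSlope = 1,
                             predatorNoiseSd = 0.3,
                             traitShifts = c(pref = 1, avoid = 0,
                                             tol = 0, vuln = 1)) {
  cfg <- as.list(environment())
  if (cfg$nSpecies < 4L) stop("nSpecies must be >= 4")
  if (cfg$yuleRate <= 0) stop("yuleRate must be positive")
  if (any(unlist(cfg$capacityRange) <= 0)) stop("capacities must be positive")
  if (cfg$nBromeliads %% 2L && cfg$nSizeLevels * 2L == cfg$nBromeliads)
    stop("experiments need balanced predator arms")
  class(cfg) <- "phylopatchSimConfig"
  cfg
}

#' Simulate the species-pool phylogeny
#'
#' A pure-birth (Yule) ultrametric ingroup with an optional deep outgroup
#' clade attached on a long stem (stem = multiplier x ingroup root-to-tip
#' depth), emulating an unbalanced empirical tree in which a few deep
#' lineages carry long branches. Tips are labelled and clades assigned:
#' outgroup tips are Annelida, one small ingroup clade is Coleoptera, the
#' remainder Diptera; labels are stored in \code{attr(tree, "clades")}.
#'
#' @param config a [simulationConfig()].
#' @param seed seed (default the config seed); \code{NULL} uses the
#'   current RNG stream.
#' @return an \code{ape::phylo} with a \code{clades} attribute.
#' @export
simulateTree <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  m <- config$outgroupSize
  nIn <- config$nSpecies - m
  if (nIn < 3L) stop("ingroup too small after outgroup allocation")
  ing <- ape::rphylo(nIn, birth = config$yuleRate, death = 0)
  depth <- max(ape::node.depth.edgelength(ing))
  ing$tip.label <- sprintf("sp%03d", seq_len(nIn))
  if (m > 0L) {
    stem <- config$outgroupStemMultiplier * depth
    if (m >= 2L) {
      og <- ape::rphylo(m, birth = config$yuleRate, death = 0)
      og$edge.length <- og$edge.length *
        depth / max(ape::node.depth.edgelength(og))
      og$tip.label <- sprintf("ann%02d", seq_len(m))
      ognwk <- sub(";$", "", ape::write.tree(og))
      ogpart <- sprintf("%s:%.10f", ognwk, stem)
    } else {
      ogpart <- sprintf("ann01:%.10f", stem + depth)
    }
    ingnwk <- sub(";$", "", ape::write.tree(ing))
    tree <- ape::read.tree(text = sprintf("(%s:0,%s);", ingnwk, ogpart))
  } else {
    tree <- ing
  }
  clades <- stats::setNames(rep("Diptera", length(tree$tip.label)),
                            tree$tip.label)
  clades[grep("^ann", names(clades))] <- "Annelida"
  if (config$nColeoptera >= 2L && nIn > config$nColeoptera + 2L) {
    parts <- ape::prop.part(ing)
    sizes <- lengths(parts)
    cand <- which(sizes >= 2 & sizes <= max(2, 2 * config$nColeoptera) &
                  sizes < nIn)
    if (length(cand)) {
      best <- cand[which.min(abs(sizes[cand] - config$nColeoptera))]
      clades[ing$tip.label[parts[[best]]]] <- "Coleoptera"
    }
  }
  attr(tree, "clades") <- clades
  tree
}

#' Simulate latent response traits on the tree
#'
#' Brownian motion (\code{"BM"}) along branches produces phylogenetically
#' conserved traits (Blomberg's K near 1 by construction); white noise
#' (\code{"WN"}) produces convergent/labile ones. Each trait is
#' standardized to mean 0, SD 1 across the pool so the simulator's effect
#' sizes are per-SD and comparable across models.
#'
#' @param tree phylogeny from [simulateTree()].
#' @param config a [simulationConfig()].
#' @param seed optional seed.
#' @return data.frame of traits (rows = species).
#' @export
simulateTraits <- function(tree, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$tip.label)
  out <- lapply(config$traitModels, function(tm) {
    x <- if (identical(tm$model, "BM"))
      ape::rTraitCont(tree, model = "BM", sigma = tm$sigma)
    else
      stats::setNames(stats::rnorm(n, 0, tm$sigma), tree$tip.label)
    if (tm$sigma == 0) x else (x - mean(x)) / stats::sd(x)
  })
  df <- as.data.frame(out)
  rownames(df) <- tree$tip.label
  df
}

# capacities for an experimental role: 10 log-spaced levels x 2 arms
.experiment_meta <- function(config, role) {
  rng <- config$capacityRange[[role]]
  lv <- 10^seq(log10(rng[1]), log10(rng[2]), length.out = config$nSizeLevels)
  cap <- rep(lv, each = 2L)
  pred <- rep(c(FALSE, TRUE), times = config$nSizeLevels)
  data.frame(row.names = sprintf("%s%02d", substr(role, 1, 3), seq_along(cap)),
             capacity_ml = cap, log_size = log10(cap),
             predator_present = pred)
}

.zscale <- function(x) (x - mean(x)) / stats::sd(x)

# multinomial colonist placement shared by the colonization and survey sims
.place_colonists <- function(species, traits, meta, config) {
  zl <- .zscale(meta$log_size)
  pred <- as.numeric(meta$predator_present)
  cnt <- matrix(0, nrow(meta), length(species),
                dimnames = list(rownames(meta), species))
  sh <- config$traitShifts
  for (s in species) {
    n <- stats::rpois(1, config$lambdaCol)
    if (n == 0) next
    lw <- config$betaSize * (sh[["pref"]] + traits[s, "pref"]) * zl -
      config$gammaAvoid * (sh[["avoid"]] + traits[s, "avoid"]) * pred
    p <- exp(lw - max(lw))
    cnt[, s] <- stats::rmultinom(1, n, p / sum(p))
  }
  cnt
}

# binomial survival thinning shared by the extinction and survey sims
.survive <- function(intro, traits, meta, config) {
  zl <- .zscale(meta$log_size)
  pred <- as.numeric(meta$predator_present)
  surv <- intro
  sh <- config$traitShifts
  for (s in colnames(intro)) {
    p <- stats::plogis(config$alphaSurvival +
                       config$gammaSize * (sh[["tol"]] + traits[s, "tol"]) * zl -
                       config$gammaPred * (sh[["vuln"]] + traits[s, "vuln"]) * pred)
    surv[, s] <- stats::rbinom(nrow(intro), intro[, s], p)
  }
  surv
}

.species_meta <- function(species, clades) {
  data.frame(row.names = species, clade = unname(clades[species]),
             morphospecies = species)
}

#' Simulate the colonization experiment
#'
#' 20 empty bromeliads (10 log-spaced size levels x 2 predator arms, with
#' caged predators contributing only chemical cues). Each species draws a
#' Poisson number of colonists which land independently on bromeliads with
#' probability proportional to
#' \code{exp(betaSize * pref * zlog_size - gammaAvoid * avoid * predator)};
#' with all effects zero, placement is uniform.
#'
#' @inheritParams simulateTraits
#' @param traits data.frame from [simulateTraits()].
#' @return a [BromeliadExperiment-class] with role \code{"colonization"}.
#' @export
simulateColonization <- function(tree, traits, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  meta <- .experiment_meta(config, "colonization")
  cnt <- .place_colonists(tree$tip.label, traits, meta, config)
  BromeliadExperiment(cnt, meta = meta, role = "colonization",
                      speciesMeta = .species_meta(tree$tip.label,
                                                  attr(tree, "clades")))
}

#' Simulate the extinction experiment
#'
#' 20 netted bromeliads seeded with a designed community of
#' \code{nExtinctionSpecies} (one annelid, one coleopteran, the rest
#' dipterans, mirroring a standardized common-prey community). Introduced
#' counts scale with capacity through the configured log-log slope; each
#' individual then survives independently with probability
#' \code{plogis(alpha + gammaSize * tol * zlog_size - gammaPred * vuln *
#' predator)} — 50\% everywhere in the null configuration.
#'
#' @inheritParams simulateColonization
#' @return a [BromeliadExperiment-class] with role \code{"extinction"} and
#'   an \code{"introduced"} assay.
#' @export
simulateExtinction <- function(tree, traits, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  clades <- attr(tree, "clades")
  nsp <- config$nExtinctionSpecies
  ann <- names(clades)[clades == "Annelida"]
  col <- names(clades)[clades == "Coleoptera"]
  dip <- names(clades)[clades == "Diptera"]
  species <- c(if (length(ann)) sample(ann, 1L),
               if (length(col)) sample(col, 1L))
  species <- c(species, sample(dip, min(nsp - length(species), length(dip))))
  meta <- .experiment_meta(config, "extinction")
  relcap <- meta$capacity_ml / min(meta$capacity_ml)
  perBrom <- pmax(1L, round(config$introBase * relcap^config$introducedSlope))
  intro <- matrix(rep(perBrom, length(species)), nrow(meta), length(species),
                  dimnames = list(rownames(meta), species))
  surv <- .survive(intro, traits, meta, config)
  BromeliadExperiment(surv, meta = meta, role = "extinction",
                      speciesMeta = .species_meta(species, clades),
                      introduced = intro)
}

#' Simulate the natural survey
#'
#' 20 bromeliads with capacities log-uniform over the survey range.
#' Predator occupancy covaries with habitat size (damselflies are absent
#' from small plants and their biomass increases with size, lognormal
#' noise); detrital mass follows a noisy log-log rule. Community
#' composition is a colonization process followed by an extinction
#' process on the same plants, so every configured effect acts through
#' the stage it belongs to.
#'
#' @inheritParams simulateColonization
#' @return a [BromeliadExperiment-class] with role \code{"survey"} and
#'   metadata columns capacity_ml, log_size, predator_present,
#'   predator_biomass, detritus_mass, microhabitat_flag.
#' @export
simulateSurvey <- function(tree, traits, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rng <- config$capacityRange$survey
  cap <- sort(10^stats::runif(config$nBromeliads, log10(rng[1]), log10(rng[2])))
  zl <- .zscale(log10(cap))
  present <- stats::runif(config$nBromeliads) < stats::plogis(2 * zl)
  relcap <- cap / min(cap)
  biomass <- ifelse(present,
    relcap^config$predatorSlope *
      exp(stats::rnorm(config$nBromeliads, 0, config$predatorNoiseSd)), 0)
  detritus <- relcap^config$detritusSlope *
    exp(stats::rnorm(config$nBromeliads, 0, config$predatorNoiseSd))
  meta <- data.frame(
    row.names = sprintf("sur%02d", seq_along(cap)),
    capacity_ml = cap, log_size = log10(cap),
    predator_present = present, predator_biomass = biomass,
    detritus_mass = detritus, microhabitat_flag = FALSE)
  cnt <- .place_colonists(tree$tip.label, traits, meta, config)
  cnt <- .survive(cnt, traits, meta, config)
  BromeliadExperiment(cnt, meta = meta, role = "survey",
                      speciesMeta = .species_meta(tree$tip.label,
                                                  attr(tree, "clades")))
}

#' Simulate a complete survey + two-experiment study
#'
#' Generates the phylogeny, the latent response traits, and the three
#' datasets from one seed; the ground-truth configuration travels with the
#' result for parameter-recovery checks.
#'
#' @param config a [simulationConfig()].
#' @return a [SimulatedStudy-class].
#' @examples
#' st <- simulateStudy(simulationConfig(seed = 7, nSpecies = 20))
#' st
#' @export
simulateStudy <- function(config = simulationConfig()) {
  set.seed(config$seed)
  tree <- simulateTree(config, seed = NULL)
  traits <- simulateTraits(tree, config)
  st <- new("SimulatedStudy",
    tree = tree, traits = traits,
    survey = simulateSurvey(tree, traits, config),
    colonization = simulateColonization(tree, traits, config),
    extinction = simulateExtinction(tree, traits, config),
    config = unclass(config))
  st
}
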