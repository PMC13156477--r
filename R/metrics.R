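#' Mean pairwise phylogenetic distance of a community
#'
#' Unweighted MPD is the mean patristic distance over all unordered pairs
#' of community members; it reflects clustering across the whole depth of
#' the phylogeny. The abundance-weighted form averages pair distances with
#' weights \eqn{a_i a_j}, where \eqn{a = \mathrm{count}^{\mathrm{exponent}}}.
#' A compressive exponent (default 0.5 for natural and colonizing
#' communities) keeps species with large clutch sizes from overwhelming the
#' contribution of other species; extinction analyses use exponent 1 since
#' extinction events occur at the individual level.
#'
#' @param dist patristic distance matrix restricted to (at least) the
#'   community's species.
#' @param species character vector of community members; defaults to the
#'   names of \code{abund} or all rows of \code{dist}.
#' @param abund named nonnegative abundance vector; \code{NULL} for the
#'   unweighted metric. Zero-abundance species are dropped.
#' @param exponent power applied to counts before weighting (> 0).
#' @return the metric value, or \code{NA} with attribute
#'   \code{degenerate = TRUE} when richness < 2.
#' @export
mpd <- function(dist, species = NULL, abund = NULL, exponent = 1) {
  cs <- .community_slots(dist, species, abund, exponent)
  if (is.null(cs)) return(.degenerate_value())
  d <- cs$d
  if (is.null(cs$a)) return(mean(d[upper.tri(d)]))
  w <- outer(cs$a, cs$a)
  ut <- upper.tri(d)
  sum(w[ut] * d[ut]) / sum(w[ut])
}

#' Mean nearest taxon distance of a community
#'
#' For each member, the patristic distance to its closest co-occurring
#' relative; the (abundance-weighted) mean over members. Sensitive to
#' structure near the tips of the phylogeny where MPD is dominated by deep
#' splits.
#'
#' @inheritParams mpd
#' @export
mntd <- function(dist, species = NULL, abund = NULL, exponent = 1) {
  cs <- .community_slots(dist, species, abund, exponent)
  if (is.null(cs)) return(.degenerate_value())
  d <- cs$d
  diag(d) <- Inf
  nn <- apply(d, 1L, min)
  if (is.null(cs$a)) mean(nn) else sum(cs$a * nn) / sum(cs$a)
}

.community_slots <- function(dist, species, abund, exponent) {
  if (is.null(species))
    species <- if (!is.null(abund)) names(abund) else rownames(dist)
  if (!is.null(abund)) {
    abund <- abund[species]
    species <- species[abund > 0]
    abund <- abund[abund > 0]
  }
  if (length(species) < 2L) return(NULL)
  if (!all(species %in% rownames(dist)))
    stop("community species missing from distance matrix")
  if (!is.null(abund) && exponent <= 0) stop("exponent must be > 0")
  list(d = dist[species, species],
       a = if (is.null(abund)) NULL else unname(abund^exponent))
}

.degenerate_value <- function() structure(NA_real_, degenerate = TRUE)

#' Faith's phylogenetic diversity
#'
#' Total branch length of the minimal subtree spanning the community's
#' tips, by convention including the path to the root
#' (\code{includeRoot = TRUE}), so a single-species community scores its
#' root-to-tip path length.
#'
#' @param tree \code{ape::phylo} tree with branch lengths.
#' @param species community members (tips of \code{tree}).
#' @param includeRoot include the path from the community's MRCA up to the
#'   root.
#' @return total branch length (numeric scalar).
#' @export
faithPD <- function(tree, species, includeRoot = TRUE) {
  species <- unique(species)
  if (!length(species)) stop("empty community")
  if (!all(species %in% tree$tip.label))
    stop("species not in tree: ",
         paste(setdiff(species, tree$tip.label), collapse = ", "))
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  below <- numeric(nnode)
  below[match(species, tr$tip.label)] <- 1
  for (i in seq_len(nrow(tr$edge))) {
    par <- tr$edge[i, 1L]; child <- tr$edge[i, 2L]
    below[par] <- below[par] + below[child]
  }
  S <- length(species)
  nb <- below[tr$edge[, 2L]]
  keep <- nb >= 1 & (includeRoot | nb < S)
  sum(tr$edge.length[keep])
}

#' Standardized effect sizes of relatedness metrics (NRI / NTI)
#'
#' For each bromeliad community, compares the observed MPD or MNTD to its
#' distribution under the taxa-labels null ([taxaLabelsShuffle()]), which
#' preserves the community's richness and abundance structure while drawing
#' its members at random from the species pool. The standardized effect
#' size is \eqn{(obs - \bar{null})/sd(null)}; the net relatedness index
#' (NRI, from MPD) and nearest taxon index (NTI, from MNTD) are its
#' negation, so positive values mean phylogenetic clustering.
#'
#' Monte-Carlo nulls use \code{nRuns} shuffles and the sample (n-1) SD;
#' \code{method = "exhaustive"} enumerates every relabeling (all k-subsets
#' of the pool for unweighted metrics, all injections for weighted ones)
#' and uses the population SD of the complete null distribution — feasible
#' only for small pools and the reference for correctness tests.
#'
#' A community is flagged degenerate when its richness is < 2 or the null
#' SD is zero (e.g. the community equals the entire pool, when every
#' relabeling returns the same value); degenerate rows carry \code{NA}
#' effect sizes and are excluded from downstream model fitting.
#'
#' @param be a [BromeliadExperiment-class].
#' @param dist patristic distance matrix covering the pool.
#' @param metric \code{"mpd"} or \code{"mntd"}.
#' @param weighting \code{"unweighted"} or \code{"weighted"}.
#' @param exponent abundance exponent for weighted metrics; default 0.5
#'   for survey/colonization roles and 1 for extinction.
#' @param pool species pool (default [buildPool()]).
#' @param nRuns number of null randomizations (>= 99).
#' @param method \code{"montecarlo"} or \code{"exhaustive"}.
#' @param seed optional integer seed for reproducible ensembles.
#' @return data.frame with one row per bromeliad: observed, null_mean,
#'   null_sd, ses, nri_or_nti (= -ses), richness, n_runs, degenerate.
#' @examples
#' tr <- readPhylogeny("((A:1,B:1):1,(C:1,D:1):1);")
#' cnt <- matrix(c(1, 1, 0, 0), 1, 4,
#'               dimnames = list("b1", c("A", "B", "C", "D")))
#' be <- BromeliadExperiment(cnt, role = "survey")
#' sesMetric(be, patristicDistances(tr), metric = "mpd",
#'           method = "exhaustive")$nri_or_nti  # sqrt(2)
#' @export
sesMetric <- function(be, dist, metric = c("mpd", "mntd"),
                      weighting = c("unweighted", "weighted"),
                      exponent = NULL, pool = buildPool(be),
                      nRuns = 999, method = c("montecarlo", "exhaustive"),
                      seed = NULL) {
  metric <- match.arg(metric)
  weighting <- match.arg(weighting)
  method <- match.arg(method)
  if (method == "montecarlo" && nRuns < 99) stop("nRuns must be >= 99")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(exponent))
    exponent <- if (datasetRole(be) == "extinction") 1 else 0.5
  if (!all(pool %in% rownames(dist)))
    stop("pool species missing from distance matrix")
  m <- communityMatrix(be)
  extra <- setdiff(colnames(m)[colSums(m) > 0], pool)
  if (length(extra))
    stop("community species outside the pool: ", paste(extra, collapse = ", "))
  D <- dist[pool, pool]
  fun <- if (metric == "mpd") mpd else mntd
  cache <- new.env(parent = emptyenv())  # unweighted nulls depend on richness only

  rows <- lapply(rownames(m), function(b) {
    ab <- m[b, ]
    ab <- ab[ab > 0]
    k <- length(ab)
    if (k < 2L)
      return(data.frame(bromeliad = b, metric = metric, weighting = weighting,
                        observed = NA_real_, null_mean = NA_real_,
                        null_sd = NA_real_, ses = NA_real_,
                        nri_or_nti = NA_real_, richness = k,
                        n_runs = 0L, degenerate = TRUE))
    wab <- if (weighting == "weighted") ab else NULL
    obs <- fun(D, species = names(ab), abund = wab, exponent = exponent)
    if (method == "exhaustive") {
      nulls <- .exhaustive_nulls(D, k, wab, exponent, fun)
      nm <- mean(nulls); nsd <- sqrt(mean((nulls - nm)^2))
    } else {
      key <- as.character(k)
      if (weighting == "unweighted" && !is.null(cache[[key]])) {
        nulls <- cache[[key]]
      } else {
        nulls <- vapply(seq_len(nRuns), function(i) {
          labs <- sample(pool, k)
          fun(D, species = labs, abund = if (is.null(wab)) NULL else
                stats::setNames(unname(wab), labs), exponent = exponent)
        }, numeric(1))
        if (weighting == "unweighted") cache[[key]] <- nulls
      }
      nm <- mean(nulls); nsd <- stats::sd(nulls)
    }
    degen <- !is.finite(nsd) || nsd < 1e-10 * max(1, abs(nm))
    ses <- if (degen) NA_real_ else (obs - nm) / nsd
    data.frame(bromeliad = b, metric = metric, weighting = weighting,
               observed = obs, null_mean = nm,
               null_sd = nsd, ses = ses, nri_or_nti = -ses,
               richness = k, n_runs = length(nulls), degenerate = degen)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# complete taxa-labels null: all k-subsets (unweighted) or injections (weighted)
.exhaustive_nulls <- function(D, k, wab, exponent, fun) {
  pool <- rownames(D)
  subsets <- utils::combn(pool, k, simplify = FALSE)
  if (is.null(wab)) {
    vapply(subsets, function(s) fun(D, species = s), numeric(1))
  } else {
    if (choose(length(pool), k) * factorial(k) > 100000)
      stop("exhaustive weighted null too large; use method = 'montecarlo'")
    a <- unname(wab)
    unlist(lapply(subsets, function(s) {
      perms <- .permutations(s)
      vapply(perms, function(p)
        fun(D, species = p, abund = stats::setNames(a, p),
            exponent = exponent), numeric(1))
    }))
  }
}

.permutations <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    out <- c(out, lapply(.permutations(x[-i]), function(p) c(x[i], p)))
  out
}

#' Correlation between species richness and Faith's PD
#'
#' PD is a joint function of richness and phylogenetic dispersion; when the
#' two are nearly collinear across communities (the usual case), PD adds
#' little to richness as a response variable and is dropped from model
#' fitting. Returns the Pearson correlation across communities.
#'
#' @param be a [BromeliadExperiment-class] (>= 3 communities).
#' @param tree phylogeny covering the species.
#' @param includeRoot passed to [faithPD()].
#' @return Pearson r (numeric scalar).
#' @export
richnessPDCorrelation <- function(be, tree, includeRoot = TRUE) {
  m <- communityMatrix(be)
  occ <- m > 0
  keep <- rowSums(occ) >= 1
  if (sum(keep) < 3L) stop("need at least 3 non-empty communities")
  rich <- rowSums(occ[keep, , drop = FALSE])
  pd <- vapply(which(keep), function(i)
    faithPD(tree, colnames(m)[occ[i, ]], includeRoot = includeRoot),
    numeric(1))
  if (stats::sd(rich) == 0 || stats::sd(pd) == 0)
    stop("zero variance in richness or PD")
  stats::cor(rich, pd)
}
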