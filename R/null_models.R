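#' Taxa-labels shuffle of a distance matrix
#'
#' The randomization behind the standardized relatedness indices: species
#' labels are permuted uniformly at random over the species pool while
#' community membership (which matrix cells are occupied) is untouched, so
#' each community keeps its richness and abundance structure but draws a
#' random set of relatives. Operationally the rows/columns of the patristic
#' distance matrix are permuted; the multiset of off-diagonal distances is
#' invariant.
#'
#' @param dist square patristic distance matrix over the pool.
#' @param pool character vector of pool species; must match the dimnames
#'   of \code{dist} (order defines the shuffle domain).
#' @return a distance matrix of identical dimnames in which species i
#'   carries the distances of a uniformly random other species.
#' @export
taxaLabelsShuffle <- function(dist, pool) {
  if (!setequal(rownames(dist), pool) || length(pool) != nrow(dist))
    stop("pool does not match distance matrix labels")
  dist <- dist[pool, pool]
  perm <- sample(pool)
  out <- dist[perm, perm]
  dimnames(out) <- list(pool, pool)
  out
}

#' Species pool for a dataset role
#'
#' The pool defines the domain of the taxa-labels shuffle and differs by
#' assembly stage: for surveys it is every species recorded at the site;
#' for the colonization experiment, the species that actually colonized
#' (at least one individual anywhere); for the extinction experiment, the
#' designed introduction list regardless of survival.
#'
#' @param be a [BromeliadExperiment-class].
#' @return character vector of species ids.
#' @export
buildPool <- function(be) {
  m <- communityMatrix(be)
  pool <- switch(datasetRole(be),
    survey = colnames(m),
    colonization = colnames(m)[colSums(m) > 0],
    extinction = {
      intro <- introducedCounts(be)
      colnames(intro)[colSums(intro) > 0]
    }
  )
  if (!length(pool)) stop("empty species pool")
  pool
}

#' Randomize molecular identities within morphospecies
#'
#' When cryptic diversity is resolved after fieldwork, individuals that were
#' not sequenced are only known to morphospecies. Each unsequenced
#' individual is independently assigned a molecular identity drawn among the
#' molecular species of its morphospecies (uniformly by default, or
#' weighted by the sequenced frequencies); sequenced counts are unchanged
#' and per-bromeliad totals are conserved.
#'
#' @param be a [BromeliadExperiment-class] whose counts are the sequenced
#'   individuals per molecular species.
#' @param unsequenced bromeliad x morphospecies matrix of unsequenced
#'   individual counts.
#' @param speciesMeta data.frame with columns \code{species} (molecular id,
#'   matching rows of \code{be}) and \code{morphospecies}; each molecular
#'   species belongs to exactly one morphospecies.
#' @param weightByFrequency if TRUE, assignment probabilities are
#'   proportional to each molecular species' sequenced total (plus one
#'   pseudo-count) instead of uniform.
#' @return a \code{BromeliadExperiment} with the unsequenced individuals
#'   added to the counts of randomly drawn molecular species.
#' @export
randomizeMorphospecies <- function(be, unsequenced, speciesMeta,
                                   weightByFrequency = FALSE) {
  cnt <- communityMatrix(be)
  sm <- as.data.frame(speciesMeta)
  if (!all(c("species", "morphospecies") %in% colnames(sm)))
    stop("speciesMeta needs 'species' and 'morphospecies' columns")
  if (anyDuplicated(sm$species))
    stop("a molecular species maps to more than one morphospecies")
  members <- split(as.character(sm$species), as.character(sm$morphospecies))
  unsequenced <- as.matrix(unsequenced)
  for (ms in colnames(unsequenced)) {
    mols <- intersect(members[[ms]], colnames(cnt))
    if (!length(mols))
      stop("morphospecies '", ms, "' has no molecular members")
    w <- if (weightByFrequency) colSums(cnt[, mols, drop = FALSE]) + 1 else
         rep(1, length(mols))
    for (b in rownames(unsequenced)) {
      n <- unsequenced[b, ms]
      if (n > 0) {
        draw <- if (length(mols) == 1L) stats::setNames(n, mols) else
          table(factor(sample(mols, n, replace = TRUE, prob = w), levels = mols))
        cnt[b, mols] <- cnt[b, mols] + as.numeric(draw)
      }
    }
  }
  BromeliadExperiment(cnt, meta = bromeliadMeta(be), role = datasetRole(be),
                      speciesMeta = as.data.frame(rowData(be)))
}
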