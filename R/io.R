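#' Read and validate a rooted phylogeny
#'
#' Parses a single rooted Newick tree with branch lengths and applies the
#' invariants the downstream metrics rely on: unique tip labels, a branch
#' length on every edge, and no negative lengths.
#'
#' @param path path to a Newick file, or a Newick string.
#' @return an \code{ape::phylo} tree.
#' @examples
#' tr <- readPhylogeny("((A:1,B:1):1,C:2);")
#' tr$tip.label
#' @export
readPhylogeny <- function(path) {
  tr <- if (grepl("\\(", path)) ape::read.tree(text = path)
        else ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick input")
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L) stop("expected a single tree, found ", length(tr))
    tr <- tr[[1L]]
  }
  validatePhylogeny(tr)
  tr
}

#' Check the invariants required of an input phylogeny
#'
#' @param tree an \code{ape::phylo} object.
#' @return the tree, invisibly, or an error naming the violated invariant
#'   (and where possible the offending tip or node).
#' @export
validatePhylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup))
    stop("duplicate tip labels: ", paste(unique(dup), collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; patristic distances are undefined")
  if (anyNA(tree$edge.length))
    stop("missing branch lengths on ", sum(is.na(tree$edge.length)), " edge(s)")
  bad <- which(tree$edge.length < 0)
  if (length(bad)) {
    node <- tree$edge[bad[1L], 2L]
    lab <- if (node <= length(tree$tip.label)) tree$tip.label[node]
           else paste0("internal node ", node)
    stop("negative branch length on edge to ", lab)
  }
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  invisible(tree)
}

#' Patristic distance matrix
#'
#' Sum of branch lengths along the unique tree path between every pair of
#' tips; the distance that MPD, MNTD and the relatedness indices are built
#' on. Symmetric with a zero diagonal.
#'
#' @param tree a validated \code{ape::phylo} tree with branch lengths.
#' @return square numeric matrix with tip labels as dimnames.
#' @export
patristicDistances <- function(tree) {
  validatePhylogeny(tree)
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}

#' Subset a dataset and its tree to a taxonomic scale
#'
#' Relatedness metrics can be dominated by deep, long-branched lineages, so
#' analyses are repeated at nested taxonomic scales: all invertebrates, the
#' insects only (dropping Annelida), and the dipterans only (additionally
#' dropping Coleoptera and any other non-Diptera insects). The tree is
#' pruned to the retained tips; degree-2 nodes created by pruning are
#' collapsed with summed branch lengths so patristic distances among
#' retained tips are unchanged.
#'
#' @param be a [BromeliadExperiment-class] whose rowData has a \code{clade}
#'   column covering every species.
#' @param tree phylogeny over (at least) the species of \code{be}.
#' @param scale \code{"invertebrates"} (identity), \code{"insecta"} or
#'   \code{"diptera"}.
#' @return list with elements \code{be} and \code{tree}, both subset.
#' @export
subsetTaxonomicScale <- function(be, tree,
                                 scale = c("invertebrates", "insecta", "diptera")) {
  scale <- match.arg(scale)
  clades <- cladeLabels(be)
  if (anyNA(clades)) stop("clade labels must cover all species")
  keep <- switch(scale,
    invertebrates = names(clades),
    insecta = names(clades)[clades != "Annelida"],
    diptera = names(clades)[clades == "Diptera"]
  )
  if (length(keep) < 2L)
    stop("degenerate pool: scale '", scale, "' retains ", length(keep),
         " species (< 2)")
  be2 <- be[keep, ]
  tips <- intersect(tree$tip.label, keep)
  tree2 <- if (length(tips) == length(tree$tip.label)) tree
           else ape::keep.tip(tree, tips)
  list(be = be2, tree = tree2)
}

#' Apply the survey data-cleaning filters
#'
#' Removes bromeliads flagged as belonging to a different microhabitat and
#' species classes excluded from survey analyses (accidental terrestrial
#' species; large predators other than damselflies). Counts are otherwise
#' untouched. Exclusion ids not present in the data raise a warning, not an
#' error, and every removal is recorded in a log attached to the result's
#' metadata.
#'
#' @param be a survey [BromeliadExperiment-class].
#' @param excludeBromeliads character vector of bromeliad ids to drop
#'   (e.g. the microhabitat-flagged plants).
#' @param excludeSpecies character vector of species ids to drop.
#' @return the filtered \code{BromeliadExperiment}; the removal log is in
#'   \code{metadata(result)$filter_log}.
#' @export
applySurveyFilters <- function(be, excludeBromeliads = character(),
                               excludeSpecies = character()) {
  log <- character()
  missB <- setdiff(excludeBromeliads, colnames(be))
  if (length(missB))
    warning("bromeliad exclusion id(s) not present: ",
            paste(missB, collapse = ", "))
  missS <- setdiff(excludeSpecies, rownames(be))
  if (length(missS))
    warning("species exclusion id(s) not present: ",
            paste(missS, collapse = ", "))
  dropB <- intersect(excludeBromeliads, colnames(be))
  dropS <- intersect(excludeSpecies, rownames(be))
  for (b in dropB) log <- c(log, paste0("removed bromeliad ", b))
  for (s in dropS) {
    n <- sum(assay(be, "counts")[s, ])
    log <- c(log, sprintf("removed species %s (%d individuals)", s, n))
  }
  be2 <- be[setdiff(rownames(be), dropS), setdiff(colnames(be), dropB)]
  md <- metadata(be2)
  md$filter_log <- c(md$filter_log, log)
  metadata(be2) <- md
  be2
}

#' Read / write community tables as CSV
#'
#' The on-disk format is a UTF-8 CSV with bromeliads as rows (first column
#' \code{bromeliad}) and species as columns; metadata travels in separate
#' CSVs keyed by bromeliad or species id.
#'
#' @param path CSV file path.
#' @param meta,speciesMeta optional metadata data.frames or CSV paths.
#' @param role dataset role, see [BromeliadExperiment()].
#' @param introducedPath optional CSV of introduced counts (extinction).
#' @return [BromeliadExperiment-class] (read) or the path, invisibly (write).
#' @export
readCommunityTable <- function(path, meta = NULL, role = "survey",
                               speciesMeta = NULL, introducedPath = NULL) {
  tab <- utils::read.csv(path, check.names = FALSE)
  if (!"bromeliad" %in% colnames(tab))
    stop("community CSV must have a 'bromeliad' first column")
  rn <- as.character(tab$bromeliad)
  cnt <- as.matrix(tab[, setdiff(colnames(tab), "bromeliad"), drop = FALSE])
  rownames(cnt) <- rn
  if (is.character(meta)) meta <- utils::read.csv(meta, check.names = FALSE)
  if (is.character(speciesMeta))
    speciesMeta <- utils::read.csv(speciesMeta, check.names = FALSE)
  intro <- NULL
  if (!is.null(introducedPath)) {
    itab <- utils::read.csv(introducedPath, check.names = FALSE)
    intro <- as.matrix(itab[, setdiff(colnames(itab), "bromeliad"), drop = FALSE])
    rownames(intro) <- as.character(itab$bromeliad)
    intro <- intro[rownames(cnt), colnames(cnt), drop = FALSE]
  }
  BromeliadExperiment(cnt, meta = meta, role = role,
                      speciesMeta = speciesMeta, introduced = intro)
}

#' @rdname readCommunityTable
#' @param be a [BromeliadExperiment-class] to write.
#' @param assay assay to write, \code{"counts"} or \code{"introduced"}.
#' @export
writeCommunityTable <- function(be, path, assay = "counts") {
  m <- communityMatrix(be, assay = assay)
  df <- data.frame(bromeliad = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
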