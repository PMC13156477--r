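#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames colData rowData
NULL

.VALID_ROLES <- c("survey", "colonization", "extinction")
.VALID_SCALES <- c("invertebrates", "insecta", "diptera")

#' BromeliadExperiment: a community table with patch metadata
#'
#' S4 container for a bromeliad invertebrate community dataset. Extends
#' \linkS4class{SummarizedExperiment}: the \code{"counts"} assay holds
#' nonnegative integer abundances with species as rows and bromeliads
#' (habitat patches) as columns; \code{colData} carries per-bromeliad
#' metadata (water capacity in mL, its base-10 logarithm \code{log_size},
#' predator biomass or presence, detrital mass, microhabitat flag);
#' \code{rowData} carries species metadata (clade label, morphospecies id).
#' Extinction-experiment datasets additionally carry an \code{"introduced"}
#' assay recording the designed initial counts, cell-wise at least as large
#' as the surviving counts.
#'
#' @slot role character, one of \code{"survey"}, \code{"colonization"},
#'   \code{"extinction"}; which stage of community assembly the table
#'   represents and hence which null models and indices apply.
#'
#' @seealso [BromeliadExperiment()] the constructor,
#'   [communityMatrix()], [bromeliadMeta()], [datasetRole()],
#'   [introducedCounts()]
#' @export
setClass("BromeliadExperiment",
  contains = "SummarizedExperiment",
  slots = c(role = "character")
)

setValidity("BromeliadExperiment", function(object) {
  msg <- character()
  if (length(object@role) != 1L || !object@role %in% .VALID_ROLES)
    msg <- c(msg, sprintf("role must be one of %s",
                          paste(.VALID_ROLES, collapse = ", ")))
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "a 'counts' assay is required")
  else {
    cnt <- assay(object, "counts")
    if (any(is.na(cnt)))
      msg <- c(msg, "counts must not contain NA")
    else {
      if (any(cnt < 0)) msg <- c(msg, "counts must be nonnegative")
      if (any(cnt != round(cnt)))
        msg <- c(msg, "counts must be integer-valued (individuals)")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
      msg <- c(msg, "species (row) names must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
      msg <- c(msg, "bromeliad (column) names must be present and unique")
  }
  if (identical(object@role, "extinction")) {
    if (!"introduced" %in% assayNames(object))
      msg <- c(msg, "extinction datasets require an 'introduced' assay")
    else {
      intro <- assay(object, "introduced")
      cnt <- assay(object, "counts")
      if (any(intro < 0) || any(intro != round(intro)))
        msg <- c(msg, "introduced counts must be nonnegative integers")
      else if (any(intro < cnt))
        msg <- c(msg, "introduced counts must be >= surviving counts in every cell")
    }
  }
  cd <- colData(object)
  if ("capacity_ml" %in% colnames(cd) && any(cd$capacity_ml <= 0, na.rm = TRUE))
    msg <- c(msg, "capacity_ml must be positive")
  if ("log_size" %in% colnames(cd) && any(!is.finite(cd$log_size)))
    msg <- c(msg, "log_size must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a BromeliadExperiment
#'
#' @param counts bromeliad x species matrix or data.frame of nonnegative
#'   integer counts (rows = bromeliads, columns = species, matching the
#'   on-disk CSV orientation), or an already species x bromeliad matrix with
#'   \code{transpose = FALSE}.
#' @param meta data.frame of per-bromeliad metadata, one row per bromeliad
#'   (matched by rowname or a \code{bromeliad} column). If it has a
#'   \code{capacity_ml} column and no \code{log_size}, \code{log_size} is
#'   derived as \code{log10(capacity_ml)}.
#' @param role dataset role: \code{"survey"}, \code{"colonization"} or
#'   \code{"extinction"}.
#' @param speciesMeta optional data.frame of per-species metadata (clade,
#'   morphospecies), matched by rowname or a \code{species} column.
#' @param introduced for the extinction role, a matrix of designed initial
#'   counts in the same orientation as \code{counts}.
#' @param transpose logical; is \code{counts} bromeliad x species (the
#'   analysis and file convention) rather than species x bromeliad?
#' @return a validated [BromeliadExperiment-class] object.
#' @examples
#' cnt <- matrix(c(2, 0, 1, 3), 2, 2,
#'               dimnames = list(c("b1", "b2"), c("spA", "spB")))
#' be <- BromeliadExperiment(cnt,
#'   meta = data.frame(row.names = c("b1", "b2"),
#'                     capacity_ml = c(100, 500),
#'                     predator_present = c(TRUE, FALSE)),
#'   role = "colonization")
#' communityMatrix(be)
#' @export
BromeliadExperiment <- function(counts, meta = NULL,
                                role = c("survey", "colonization", "extinction"),
                                speciesMeta = NULL, introduced = NULL,
                                transpose = TRUE) {
  role <- match.arg(role)
  counts <- as.matrix(counts)
  if (transpose) counts <- t(counts)
  storage.mode(counts) <- "double"
  assays <- list(counts = counts)
  if (!is.null(introduced)) {
    introduced <- as.matrix(introduced)
    if (transpose) introduced <- t(introduced)
    storage.mode(introduced) <- "double"
    introduced <- introduced[rownames(counts), colnames(counts), drop = FALSE]
    assays$introduced <- introduced
  }
  cd <- .align_meta(meta, colnames(counts), "bromeliad")
  if (!is.null(cd) && "capacity_ml" %in% colnames(cd) &&
      !"log_size" %in% colnames(cd))
    cd$log_size <- log10(cd$capacity_ml)
  rd <- .align_meta(speciesMeta, rownames(counts), "species")
  se <- SummarizedExperiment(
    assays = assays,
    colData = if (is.null(cd)) DataFrame(row.names = colnames(counts)) else DataFrame(cd),
    rowData = if (is.null(rd)) DataFrame(row.names = rownames(counts)) else DataFrame(rd)
  )
  new("BromeliadExperiment", se, role = role)
}

# match a metadata data.frame to `ids` by rowname or an id column
.align_meta <- function(meta, ids, idcol) {
  if (is.null(meta)) return(NULL)
  meta <- as.data.frame(meta)
  if (idcol %in% colnames(meta)) {
    rownames(meta) <- as.character(meta[[idcol]])
    meta[[idcol]] <- NULL
  }
  missing <- setdiff(ids, rownames(meta))
  if (length(missing))
    stop("metadata missing entries for: ", paste(missing, collapse = ", "))
  meta[ids, , drop = FALSE]
}

#' SimulatedStudy: one synthetic survey + two-experiment study
#'
#' Bundle returned by [simulateStudy()]: a phylogeny over the species pool,
#' the true (latent) per-species response traits, the three community
#' datasets with their metadata, and the ground-truth parameter record.
#'
#' @slot tree an \code{ape::phylo} tree over the species pool.
#' @slot traits data.frame of latent species traits (size preference,
#'   predator avoidance, size tolerance, predator vulnerability).
#' @slot survey,colonization,extinction [BromeliadExperiment-class] datasets.
#' @slot config the [simulationConfig()] list that generated the study.
#' @export
setClass("SimulatedStudy",
  slots = c(tree = "ANY", traits = "data.frame",
            survey = "ANY", colonization = "ANY", extinction = "ANY",
            config = "list")
)

setValidity("SimulatedStudy", function(object) {
  if (!inherits(object@tree, "phylo")) return("tree must be an ape phylo object")
  for (slot in c("survey", "colonization", "extinction")) {
    be <- slot(object, slot)
    if (!is(be, "BromeliadExperiment"))
      return(sprintf("%s must be a BromeliadExperiment", slot))
    if (!all(rownames(be) %in% object@tree$tip.label))
      return(sprintf("all %s species must be tips of the tree", slot))
  }
  TRUE
})
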