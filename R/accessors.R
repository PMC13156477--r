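#' @describeIn BromeliadExperiment-class dataset role accessor
#' @param x,object a \code{BromeliadExperiment}
#' @export
setGeneric("datasetRole", function(x) standardGeneric("datasetRole"))

#' @export
setMethod("datasetRole", "BromeliadExperiment", function(x) x@role)

#' Community matrix in analysis orientation
#'
#' Returns the abundance table as a bromeliad x species matrix (rows are
#' habitat patches), the orientation used by all community metrics and by
#' the on-disk CSV format.
#'
#' @param x a [BromeliadExperiment-class]
#' @param assay which assay, \code{"counts"} (default) or
#'   \code{"introduced"}.
#' @return numeric matrix, bromeliads x species.
#' @export
setGeneric("communityMatrix", function(x, assay = "counts")
  standardGeneric("communityMatrix"))

#' @export
setMethod("communityMatrix", "BromeliadExperiment", function(x, assay = "counts") {
  t(assay(x, assay))
})

#' Per-bromeliad metadata as a data.frame
#' @param x a [BromeliadExperiment-class]
#' @export
setGeneric("bromeliadMeta", function(x) standardGeneric("bromeliadMeta"))

#' @export
setMethod("bromeliadMeta", "BromeliadExperiment", function(x)
  as.data.frame(colData(x)))

#' Designed introduction counts (extinction experiments)
#' @param x a [BromeliadExperiment-class] with role \code{"extinction"}
#' @return bromeliad x species matrix of introduced counts.
#' @export
setGeneric("introducedCounts", function(x) standardGeneric("introducedCounts"))

#' @export
setMethod("introducedCounts", "BromeliadExperiment", function(x) {
  if (!"introduced" %in% assayNames(x))
    stop("no 'introduced' assay: not an extinction dataset")
  t(assay(x, "introduced"))
})

#' Clade labels of the species in a dataset
#' @param x a [BromeliadExperiment-class] whose rowData has a \code{clade}
#'   column.
#' @return named character vector, species -> clade.
#' @export
setGeneric("cladeLabels", function(x) standardGeneric("cladeLabels"))

#' @export
setMethod("cladeLabels", "BromeliadExperiment", function(x) {
  rd <- rowData(x)
  if (!"clade" %in% colnames(rd))
    stop("species metadata has no 'clade' column")
  stats::setNames(as.character(rd$clade), rownames(x))
})

#' @export
setMethod("show", "BromeliadExperiment", function(object) {
  cnt <- assay(object, "counts")
  cat(sprintf("BromeliadExperiment (%s): %d species x %d bromeliads\n",
              object@role, nrow(cnt), ncol(cnt)))
  cat(sprintf("  total individuals: %d; occupied cells: %d\n",
              as.integer(sum(cnt)), sum(cnt > 0)))
  if ("introduced" %in% assayNames(object))
    cat(sprintf("  introduced individuals: %d\n",
                as.integer(sum(assay(object, "introduced")))))
  cd <- colData(object)
  if (ncol(cd))
    cat("  bromeliad metadata:", paste(colnames(cd), collapse = ", "), "\n")
})

#' @export
setMethod("show", "SimulatedStudy", function(object) {
  cat(sprintf("SimulatedStudy: %d species pool (seed %s)\n",
              length(object@tree$tip.label),
              format(object@config$seed)))
  for (slot in c("survey", "colonization", "extinction")) {
    be <- slot(object, slot)
    cat(sprintf("  %-12s %3d species x %d bromeliads\n", slot,
                nrow(be), ncol(be)))
  }
})
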