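#' Run the full community-phylogenetics analysis
#'
#' Orchestrates the whole analysis over one survey and two experimental
#' datasets: survey filtering (if configured), taxonomic-scale subsetting,
#' richness and standardized relatedness metrics (NRI/NTI) under the
#' taxa-labels null, AICc model selection of habitat-size and predator
#' effects for every (role x scale x metric x weighting) cell, species
#' response indices for the experimental roles, and phylogenetic-signal
#' tests of those indices across scales. Returns all result tables plus a
#' run manifest; with \code{outdir} set, writes metrics.csv, models.csv,
#' indices.csv, signal.csv, heatmap.csv and manifest.json (the manifest
#' carries md5 checksums, so reruns with the same inputs and seed are
#' verifiably identical).
#'
#' @param study a [SimulatedStudy-class], or \code{NULL} if the three
#'   datasets and tree are given individually.
#' @param tree,survey,colonization,extinction individual inputs used when
#'   \code{study} is \code{NULL}.
#' @param scales taxonomic scales to analyse.
#' @param weightings abundance weightings for the relatedness metrics.
#' @param nRuns null-model randomizations per community.
#' @param seed master seed for all randomized stages.
#' @param transform response transformation policy for model fitting
#'   (see [transformResponse()]).
#' @param outdir optional output directory.
#' @return list of class \code{"phylopatchRun"} with elements
#'   \code{metrics}, \code{models}, \code{indices}, \code{signal},
#'   \code{heatmap}, \code{manifest}.
#' @export
runPipeline <- function(study = NULL, tree = NULL, survey = NULL,
                        colonization = NULL, extinction = NULL,
                        scales = c("invertebrates", "insecta", "diptera"),
                        weightings = c("unweighted", "weighted"),
                        nRuns = 999, seed = 1L, transform = "auto",
                        outdir = NULL) {
  if (!is.null(study)) {
    tree <- study@tree
    datasets <- list(survey = study@survey, colonization = study@colonization,
                     extinction = study@extinction)
  } else {
    datasets <- Filter(Negate(is.null),
                       list(survey = survey, colonization = colonization,
                            extinction = extinction))
    if (!length(datasets) || is.null(tree))
      stop("provide a study or a tree plus at least one dataset")
  }
  set.seed(seed)
  warnings <- character()
  metrics <- list(); models <- list(); indices <- list(); signal <- list()

  for (role in names(datasets)) {
    be <- datasets[[role]]
    for (sc in scales) {
      sub <- tryCatch(subsetTaxonomicScale(be, tree, sc), error = function(e) e)
      if (inherits(sub, "error")) {
        warnings <- c(warnings, sprintf("%s/%s: %s", role, sc,
                                        conditionMessage(sub)))
        next
      }
      dist <- patristicDistances(sub$tree)
      pool <- tryCatch(buildPool(sub$be), error = function(e) e)
      if (inherits(pool, "error")) {
        warnings <- c(warnings, sprintf("%s/%s: %s", role, sc,
                                        conditionMessage(pool)))
        next
      }
      m <- communityMatrix(sub$be)
      rich <- data.frame(bromeliad = rownames(m), metric = "richness",
                         weighting = "unweighted",
                         observed = rowSums(m > 0), null_mean = NA_real_,
                         null_sd = NA_real_, ses = NA_real_,
                         nri_or_nti = NA_real_,
                         richness = rowSums(m > 0), n_runs = 0L,
                         degenerate = FALSE)
      cell <- list(rich)
      for (met in c("mpd", "mntd")) for (w in weightings)
        cell[[length(cell) + 1L]] <-
          sesMetric(sub$be, dist, metric = met, weighting = w,
                    pool = pool, nRuns = nRuns)
      celldf <- do.call(rbind, cell)
      celldf <- cbind(role = role, scale = sc, celldf)
      metrics[[paste(role, sc)]] <- celldf
      nd <- sum(celldf$degenerate)
      if (nd)
        warnings <- c(warnings,
          sprintf("%s/%s: %d degenerate SES value(s) excluded from models",
                  role, sc, nd))
      models[[paste(role, sc)]] <-
        .fit_cell_models(celldf, sub$be, role, sc, weightings, transform,
                         warn = function(msg)
                           warnings <<- c(warnings, msg))
    }
    if (role %in% c("colonization", "extinction")) {
      kinds <- if (role == "colonization")
        c("size_preference", "predator_avoidance")
      else c("size_sensitivity", "predator_sensitivity")
      idx <- lapply(kinds, function(k) responseIndex(be, kind = k))
      skipped <- unlist(lapply(idx, attr, "log"))
      if (length(skipped))
        warnings <- c(warnings, paste0(role, "/indices: ", skipped))
      idx <- do.call(rbind, idx)
      indices[[role]] <- cbind(role = role, idx)
      signal[[role]] <- cbind(role = role,
        signalByScale(tree, idx, cladeLabels(be), scales = scales,
                      nPerm = nRuns))
    }
  }
  metrics <- do.call(rbind, metrics)
  models <- do.call(rbind, models)
  indices <- if (length(indices)) do.call(rbind, indices) else NULL
  signal <- if (length(signal)) do.call(rbind, signal) else NULL
  rownames(metrics) <- rownames(models) <- NULL
  if (!is.null(indices)) rownames(indices) <- NULL
  if (!is.null(signal)) rownames(signal) <- NULL
  heatmap <- summarizeHeatmap(models)
  manifest <- list(
    seed = seed, n_runs = nRuns,
    roles = names(datasets), scales = scales, weightings = weightings,
    rows = list(metrics = nrow(metrics), models = nrow(models),
                indices = if (is.null(indices)) 0L else nrow(indices),
                signal = if (is.null(signal)) 0L else nrow(signal)),
    warnings = warnings)
  out <- structure(list(metrics = metrics, models = models, indices = indices,
                        signal = signal, heatmap = heatmap,
                        manifest = manifest),
                   class = "phylopatchRun")
  if (!is.null(outdir)) .write_run(out, outdir)
  out
}

# model selection for every (metric x weighting) response in one cell,
# emitting one row per candidate predictor (included or not)
.fit_cell_models <- function(celldf, be, role, sc, weightings, transform,
                             warn) {
  meta <- bromeliadMeta(be)
  dat <- data.frame(size = meta$log_size,
                    pred = if (role == "survey") meta$predator_biomass
                           else as.numeric(meta$predator_present))
  if (role == "survey" && "detritus_mass" %in% colnames(meta))
    dat$detritus <- meta$detritus_mass
  terms <- candidateTerms(role)
  responses <- list(list(metric = "richness", weighting = "unweighted"))
  for (met in c("mpd", "mntd")) for (w in weightings)
    responses[[length(responses) + 1L]] <- list(metric = met, weighting = w)
  rows <- lapply(responses, function(r) {
    sub <- celldf[celldf$metric == r$metric & celldf$weighting == r$weighting, ]
    y <- if (r$metric == "richness") sub$observed else sub$nri_or_nti
    label <- switch(r$metric, richness = "SR", mpd = "NRI", mntd = "NTI")
    sel <- tryCatch(
      fitCandidates(dat, y, terms = terms, role = role, transform = transform),
      error = function(e) e)
    if (inherits(sel, "error")) {
      warn(sprintf("%s/%s/%s: model fitting failed: %s", role, sc, label,
                   conditionMessage(sel)))
      return(NULL)
    }
    data.frame(role = role, scale = sc, metric = label,
               weighting = r$weighting, term = terms,
               in_best_model = terms %in% sel$chosen,
               estimate = ifelse(terms %in% sel$chosen,
                                 sel$coefficients[terms], NA_real_),
               partial_r2 = ifelse(terms %in% sel$chosen,
                                   sel$partial_r2[terms], NA_real_),
               sign = ifelse(terms %in% sel$chosen,
                             sign(sel$coefficients[terms]), NA_real_),
               p_value = ifelse(terms %in% sel$chosen,
                                sel$p_value[terms], NA_real_),
               n = sel$n)
  })
  do.call(rbind, rows)
}

#' Long-format heatmap table of model contributions
#'
#' One row per (dataset role, taxonomic scale, diversity metric,
#' predictor): whether the predictor entered the best AICc model, its
#' partial R-squared and effect direction if it did, and an \code{ns}
#' flag for included-but-nonsignificant terms (t-test, alpha = 0.05) —
#' the machine-readable analogue of a contribution heatmap in which
#' empty intersections mean the predictor is not in the best model.
#'
#' @param models the \code{models} table of a [runPipeline()] result.
#' @return data.frame with columns panel, scale, metric, weighting,
#'   predictor, included, partial_r2, direction, ns_flag.
#' @export
summarizeHeatmap <- function(models) {
  if (is.null(models) || !nrow(models)) {
    warning("no model results to summarize")
    return(data.frame(panel = character(), scale = character(),
                      metric = character(), weighting = character(),
                      predictor = character(), included = logical(),
                      partial_r2 = numeric(), direction = numeric(),
                      ns_flag = logical()))
  }
  data.frame(panel = models$role, scale = models$scale,
             metric = models$metric, weighting = models$weighting,
             predictor = models$term, included = models$in_best_model,
             partial_r2 = models$partial_r2, direction = models$sign,
             ns_flag = ifelse(models$in_best_model,
                              models$p_value >= 0.05, NA))
}

.write_run <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- c(metrics = "metrics.csv", models = "models.csv",
             indices = "indices.csv", signal = "signal.csv",
             heatmap = "heatmap.csv")
  written <- character()
  for (nm in names(files)) {
    if (is.null(run[[nm]])) next
    path <- file.path(outdir, files[[nm]])
    utils::write.csv(run[[nm]], path, row.names = FALSE)
    written <- c(written, path)
  }
  sums <- tools::md5sum(written)
  run$manifest$files <- stats::setNames(as.list(unname(sums)),
                                        basename(written))
  jsonlite::write_json(run$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(run)
}

#' @rdname runPipeline
#' @param x a \code{phylopatchRun}.
#' @param ... ignored.
#' @export
print.phylopatchRun <- function(x, ...) {
  cat("phylopatch pipeline run\n")
  for (nm in c("metrics", "models", "indices", "signal"))
    if (!is.null(x[[nm]]))
      cat(sprintf("  %-8s %4d rows\n", nm, nrow(x[[nm]])))
  if (length(x$manifest$warnings))
    cat("  warnings:", length(x$manifest$warnings), "\n")
  invisible(x)
}
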