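#' Species-level response indices for assembly experiments
#'
#' Each index is a z-score comparing a statistic of a species' observed
#' distribution over experimental bromeliads to its distribution under a
#' null assembly model:
#'
#' \describe{
#'   \item{size_preference}{(colonization) mean \code{log_size} over the
#'     species' colonist individuals vs. a null in which each individual
#'     lands independently and uniformly among all bromeliads ("bromeliad
#'     choice arbitrary"). Positive z: found in larger plants than chance.}
#'   \item{predator_avoidance}{(colonization) fraction of colonists in
#'     predator-free bromeliads vs. a binomial null with p = proportion of
#'     predator-free plants. Positive z: avoidance.}
#'   \item{size_sensitivity}{(extinction) mean \code{log_size} over
#'     surviving individuals vs. random persistence: with the species'
#'     survivor total k fixed, which of its introduced individuals survive
#'     is drawn uniformly without replacement (multivariate hypergeometric
#'     across bromeliads). Positive z: survival concentrated in larger
#'     plants.}
#'   \item{predator_sensitivity}{(extinction) fraction of survivors in
#'     predator-free bromeliads under the same fixed-survivor-count null.
#'     Positive z: higher survival away from predators, i.e. more
#'     predator-sensitive.}
#' }
#'
#' The null mean and SD have closed forms (uniform placement / binomial /
#' finite-population sampling without replacement), used by default;
#' \code{method = "montecarlo"} estimates them by simulation instead and is
#' the cross-check route. Significance is two-sided at |z| >= 1.96 with no
#' multiple-testing correction by default, with a Benjamini-Hochberg option.
#'
#' Colonization indices require at least \code{minEvents} (default 2)
#' colonist individuals; extinction indices require at least one survivor
#' and one death. Species failing these, or whose null SD is zero (e.g.
#' introduced into a single bromeliad, or no predator-free plants), are
#' flagged degenerate/skipped with a log entry in \code{attr(, "log")}.
#'
#' @param be a [BromeliadExperiment-class] with role \code{"colonization"}
#'   (size_preference, predator_avoidance) or \code{"extinction"}
#'   (size_sensitivity, predator_sensitivity); its metadata must have
#'   \code{log_size} and logical \code{predator_present} columns.
#' @param kind which index to compute.
#' @param method \code{"exact"} closed-form null or \code{"montecarlo"}.
#' @param nNull Monte-Carlo null draws (default 9999).
#' @param seed optional seed for the Monte-Carlo route.
#' @param minEvents minimum colonist individuals for colonization indices.
#' @param pAdjust \code{"none"} (|z| >= 1.96, mirroring the study design)
#'   or \code{"BH"}.
#' @return data.frame (species, index_kind, observed, null_mean, null_sd,
#'   z, significant, n_events, degenerate) with skipped-species log lines
#'   in \code{attr(, "log")}.
#' @export
responseIndex <- function(be,
                          kind = c("size_preference", "predator_avoidance",
                                   "size_sensitivity", "predator_sensitivity"),
                          method = c("exact", "montecarlo"),
                          nNull = 9999, seed = NULL, minEvents = 2,
                          pAdjust = c("none", "BH")) {
  kind <- match.arg(kind)
  method <- match.arg(method)
  pAdjust <- match.arg(pAdjust)
  if (!is.null(seed)) set.seed(seed)
  meta <- bromeliadMeta(be)
  if (!all(c("log_size", "predator_present") %in% colnames(meta)))
    stop("metadata must provide log_size and predator_present")
  colo <- kind %in% c("size_preference", "predator_avoidance")
  if (colo && datasetRole(be) != "colonization")
    stop(kind, " requires a colonization dataset")
  if (!colo && datasetRole(be) != "extinction")
    stop(kind, " requires an extinction dataset")
  m <- communityMatrix(be)
  value_of <- if (kind %in% c("size_preference", "size_sensitivity"))
    meta$log_size else as.numeric(!meta$predator_present)
  log <- character()
  rows <- list()
  for (sp in colnames(m)) {
    if (colo) {
      counts <- m[, sp]
      n <- sum(counts)
      if (n < minEvents) {
        if (n > 0)
          log <- c(log, sprintf("%s: skipped (%d occurrence%s < %d)",
                                sp, n, if (n == 1) "" else "s", minEvents))
        next
      }
      res <- .uniform_placement_null(counts, value_of, method, nNull)
    } else {
      intro <- introducedCounts(be)[, sp]
      surv <- m[, sp]
      N <- sum(intro); k <- sum(surv)
      if (N == 0) next
      if (k == 0 || k == N) {
        rows[[sp]] <- .index_row(sp, kind,
          obs = if (k) sum(surv * value_of) / k else NA_real_,
          nm = sum(intro * value_of) / N, nsd = 0, n = k, degenerate = TRUE)
        log <- c(log, sprintf("%s: degenerate (%s)", sp,
                              if (k == 0) "no survivors" else "all survived"))
        next
      }
      res <- .hypergeom_null(intro, surv, value_of, method, nNull)
    }
    degen <- !is.finite(res$nsd) || res$nsd < 1e-12
    if (degen)
      log <- c(log, sprintf("%s: degenerate (null SD = 0)", sp))
    rows[[sp]] <- .index_row(sp, kind, res$obs, res$nm, res$nsd, res$n, degen)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    .index_row(character(0), kind, numeric(0), numeric(0), numeric(0),
               integer(0), logical(0))
  rownames(out) <- NULL
  out$z <- ifelse(out$degenerate, NA_real_,
                  (out$observed - out$null_mean) / out$null_sd)
  if (pAdjust == "BH") {
    p <- 2 * stats::pnorm(-abs(out$z))
    out$significant <- !is.na(out$z) & stats::p.adjust(p, "BH") < 0.05
  } else {
    out$significant <- !is.na(out$z) & abs(out$z) >= 1.96
  }
  attr(out, "log") <- log
  out
}

.index_row <- function(sp, kind, obs, nm, nsd, n, degenerate) {
  data.frame(species = sp, index_kind = kind, observed = obs,
             null_mean = nm, null_sd = nsd, z = NA_real_,
             significant = NA, n_events = n, degenerate = degenerate)
}

# each of n individuals placed independently, uniformly over bromeliads
.uniform_placement_null <- function(counts, values, method, nNull) {
  n <- sum(counts)
  obs <- sum(counts * values) / n
  if (method == "exact") {
    mu <- mean(values)
    v1 <- mean((values - mu)^2)            # per-individual variance
    list(obs = obs, nm = mu, nsd = sqrt(v1 / n), n = n)
  } else {
    B <- length(values)
    draws <- matrix(values[sample.int(B, n * nNull, replace = TRUE)], nNull, n)
    nulls <- rowMeans(draws)
    list(obs = obs, nm = mean(nulls), nsd = stats::sd(nulls), n = n)
  }
}

# k of the N introduced individuals survive, uniformly without replacement
.hypergeom_null <- function(intro, surv, values, method, nNull) {
  popn <- rep(values, intro)
  N <- length(popn); k <- sum(surv)
  obs <- sum(surv * values) / k
  if (method == "exact") {
    mu <- mean(popn)
    v1 <- mean((popn - mu)^2)
    list(obs = obs, nm = mu,
         nsd = sqrt(v1 / k * (N - k) / (N - 1)), n = k)
  } else {
    nulls <- vapply(seq_len(nNull), function(i)
      mean(popn[sample.int(N, k)]), numeric(1))
    list(obs = obs, nm = mean(nulls), nsd = stats::sd(nulls), n = k)
  }
}

#' @rdname responseIndex
#' @param ... passed on to [responseIndex()].
#' @export
sizePreference <- function(be, ...) responseIndex(be, "size_preference", ...)

#' @rdname responseIndex
#' @export
predatorAvoidance <- function(be, ...) responseIndex(be, "predator_avoidance", ...)

#' @rdname responseIndex
#' @export
sizeSensitivity <- function(be, ...) responseIndex(be, "size_sensitivity", ...)

#' @rdname responseIndex
#' @export
predatorSensitivity <- function(be, ...) responseIndex(be, "predator_sensitivity", ...)
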