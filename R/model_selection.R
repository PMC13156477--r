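#' Standardize a response vector
#'
#' Centers and scales to sample SD 1 so regression coefficients are
#' comparable across diversity metrics. \code{NA} entries (degenerate
#' standardized effect sizes) are preserved in place and dropped pairwise
#' with their design rows at fit time.
#'
#' @param y numeric vector with >= 2 non-missing values.
#' @return standardized vector of the same length.
#' @export
standardizeResponse <- function(y) {
  ok <- is.finite(y)
  if (sum(ok) < 2L) stop("need >= 2 non-missing values")
  s <- stats::sd(y[ok])
  if (s == 0) stop("zero variance: cannot standardize")
  (y - mean(y[ok])) / s
}

.bc <- function(y, lambda)
  if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda

.yj <- function(y, lambda) {
  out <- numeric(length(y))
  pos <- y >= 0
  out[pos] <- if (abs(lambda) < 1e-12) log1p(y[pos]) else
    ((y[pos] + 1)^lambda - 1) / lambda
  if (any(!pos))
    out[!pos] <- if (abs(lambda - 2) < 1e-12) -log1p(-y[!pos]) else
      -((-y[!pos] + 1)^(2 - lambda) - 1) / (2 - lambda)
  out
}

#' Power-transform a response when model diagnostics fail
#'
#' Box-Cox (positive responses) or Yeo-Johnson (any sign) transformation
#' with the exponent chosen by profile maximum likelihood on a fixed grid
#' (default -2..2, step 0.01). In \code{"auto"} mode the response is left
#' untransformed unless the full model fails residual normality
#' (Shapiro-Wilk) or homoscedasticity (Breusch-Pagan) at alpha = 0.05, in
#' which case Box-Cox is used when all values are positive and
#' Yeo-Johnson otherwise.
#'
#' @param y numeric response.
#' @param X optional design matrix / data.frame of the full model used for
#'   the profile likelihood and diagnostics; intercept-only if omitted.
#' @param method \code{"auto"}, \code{"box_cox"}, \code{"yeo_johnson"} or
#'   \code{"none"}.
#' @param lambdaGrid grid of candidate exponents.
#' @param alpha significance level for the diagnostics in auto mode.
#' @return list with \code{y} (transformed), \code{lambda}, \code{method}
#'   (the method actually applied) and \code{diagnostics}
#'   (\code{shapiro_p}, \code{bp_p} on the untransformed full model).
#' @export
transformResponse <- function(y, X = NULL,
                              method = c("auto", "box_cox", "yeo_johnson", "none"),
                              lambdaGrid = seq(-2, 2, by = 0.01),
                              alpha = 0.05) {
  method <- match.arg(method)
  ok <- is.finite(y)
  fitfun <- function(z) {
    if (is.null(X)) stats::lm(z[ok] ~ 1)
    else stats::lm(z[ok] ~ ., data = as.data.frame(X)[ok, , drop = FALSE])
  }
  fit0 <- fitfun(y)
  sw <- tryCatch(stats::shapiro.test(stats::residuals(fit0))$p.value,
                 error = function(e) NA_real_)
  bp <- tryCatch(lmtest::bptest(fit0)$p.value, error = function(e) NA_real_)
  diagnostics <- list(shapiro_p = unname(sw), bp_p = unname(bp))
  if (method == "auto") {
    fails <- (!is.na(sw) && sw < alpha) || (!is.na(bp) && bp < alpha)
    method <- if (!fails) "none"
              else if (all(y[ok] > 0)) "box_cox" else "yeo_johnson"
  }
  if (method == "none")
    return(list(y = y, lambda = NA_real_, method = "none",
                diagnostics = diagnostics))
  if (method == "box_cox" && any(y[ok] <= 0))
    stop("box_cox requires positive responses (shift the data or use yeo_johnson)")
  trans <- if (method == "box_cox") .bc else .yj
  jacobian <- if (method == "box_cox")
    function(l) (l - 1) * sum(log(y[ok]))
  else
    function(l) (l - 1) * sum(sign(y[ok]) * log1p(abs(y[ok])))
  n <- sum(ok)
  ll <- vapply(lambdaGrid, function(l) {
    z <- trans(y, l)
    sse <- sum(stats::residuals(fitfun(z))^2)
    -n / 2 * log(sse / n) + jacobian(l)
  }, numeric(1))
  lambda <- lambdaGrid[which.max(ll)]
  list(y = trans(y, lambda), lambda = lambda, method = method,
       diagnostics = diagnostics)
}

#' Candidate term sets for a dataset role
#'
#' Survey models may include habitat size (log10 capacity, centered), its
#' square, continuous predator biomass, the size-by-predator interaction,
#' and detrital biomass as a covariate; experiment models use a binary
#' predator treatment and no detritus (both were scaled with habitat size
#' by design). All subsets respecting marginality (quadratic only with the
#' linear term, interaction only with both mains) are candidates, including
#' the intercept-only null model.
#'
#' @param role \code{"survey"}, \code{"colonization"} or
#'   \code{"extinction"}.
#' @return character vector of term names.
#' @export
candidateTerms <- function(role = c("survey", "colonization", "extinction")) {
  role <- match.arg(role)
  if (role == "survey") c("size", "size2", "pred", "size_pred", "detritus")
  else c("size", "size2", "pred", "size_pred")
}

# all subsets of `terms` respecting marginality
.enumerate_candidates <- function(terms) {
  n <- length(terms)
  subsets <- lapply(0:(2^n - 1), function(bits)
    terms[bitwAnd(bits, 2^(seq_len(n) - 1)) > 0])
  ok <- vapply(subsets, function(s) {
    (!"size2" %in% s || "size" %in% s) &&
    (!"size_pred" %in% s || all(c("size", "pred") %in% s))
  }, logical(1))
  subsets[ok]
}

.term_deps <- list(size = c("size2", "size_pred"), pred = "size_pred",
                   size2 = character(), size_pred = character(),
                   detritus = character())

.build_design <- function(data) {
  sz <- data$size - mean(data$size)        # centered to tame collinearity
  d <- data.frame(size = sz, size2 = sz^2, pred = as.numeric(data$pred),
                  size_pred = sz * as.numeric(data$pred))
  if (!is.null(data$detritus)) d$detritus <- data$detritus
  d
}

.fit_terms <- function(design, y, terms) {
  f <- if (length(terms)) stats::reformulate(terms, response = "y")
       else y ~ 1
  stats::lm(f, data = cbind(design, y = y))
}

#' AICc model selection over the candidate family
#'
#' Fits every marginality-respecting subset of \code{terms} by ordinary
#' least squares and selects by the corrected Akaike information
#' criterion, AICc = -2 lnL + 2k + 2k(k+1)/(n-k-1), where the Gaussian
#' log-likelihood uses the ML variance estimate and k counts the
#' intercept, slopes and residual variance. When several models fall
#' within 2 AICc units of the best, the one with the fewest terms is
#' chosen (ties broken by AICc). Candidates with too few residual degrees
#' of freedom are dropped with a log entry, as are rows with missing
#' responses (degenerate effect sizes).
#'
#' @param data data.frame with columns \code{size} (log10 habitat size),
#'   \code{pred} (binary treatment or continuous biomass) and optionally
#'   \code{detritus}.
#' @param y numeric response, already transformed/standardized as desired
#'   (see [transformResponse()], [standardizeResponse()]).
#' @param terms candidate terms (default [candidateTerms()] for
#'   \code{role}).
#' @param role used only to pick default \code{terms}.
#' @param standardize standardize \code{y} before fitting (default TRUE).
#' @param transform passed to [transformResponse()] before
#'   standardization.
#' @return object of class \code{"phylopatchModelSelection"}: a list with
#'   the AICc \code{candidates} table, \code{chosen} terms, the fitted
#'   \code{fit}, per-term \code{partial_r2}, \code{sign} and t-test
#'   \code{p_value}, \code{n}, dropped-row count and a \code{log}.
#' @examples
#' set.seed(1)
#' d <- data.frame(size = runif(30, 1, 3), pred = rep(0:1, 15))
#' y <- 2 * d$size + rnorm(30, sd = 0.2)
#' sel <- fitCandidates(d, y, role = "colonization")
#' sel$chosen
#' @export
fitCandidates <- function(data, y, terms = NULL,
                          role = c("survey", "colonization", "extinction"),
                          standardize = TRUE,
                          transform = "none") {
  role <- match.arg(role)
  if (is.null(terms)) terms <- candidateTerms(role)
  log <- character()
  design <- .build_design(data)
  design <- design[, intersect(colnames(design), terms), drop = FALSE]
  ok <- is.finite(y) & stats::complete.cases(design)
  if (any(!ok))
    log <- c(log, sprintf("dropped %d observation(s) with missing response/design",
                          sum(!ok)))
  if (sum(ok) < 5L)
    stop("too few non-missing responses (n = ", sum(ok),
         "); cannot fit candidate models")
  design <- design[ok, , drop = FALSE]
  yv <- y[ok]
  tinfo <- transformResponse(yv, X = design, method = transform)
  yv <- tinfo$y
  if (standardize) yv <- standardizeResponse(yv)
  n <- length(yv)
  cands <- .enumerate_candidates(terms)
  tab <- lapply(cands, function(tm) {
    k <- length(tm) + 2L                   # intercept + slopes + sigma
    if (n - k - 1 <= 0) return(NULL)
    fit <- .fit_terms(design, yv, tm)
    if (fit$rank < length(tm) + 1L) return(NULL)   # rank-deficient
    llk <- stats::logLik(fit)
    aicc <- -2 * as.numeric(llk) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
    data.frame(terms = paste(tm, collapse = "+"), n_terms = length(tm),
               k = k, logLik = as.numeric(llk), AICc = aicc)
  })
  dropped <- vapply(tab, is.null, logical(1))
  if (any(dropped))
    log <- c(log, sprintf("dropped %d candidate(s) (n too small or rank-deficient)",
                          sum(dropped)))
  tab <- do.call(rbind, tab[!dropped])
  cands <- cands[!dropped]
  if (is.null(tab) || !nrow(tab)) stop("no fittable candidate models")
  tab$dAICc <- tab$AICc - min(tab$AICc)
  within <- which(tab$dAICc <= 2)
  pick <- within[order(tab$n_terms[within], tab$AICc[within])][1L]
  chosen <- cands[[pick]]
  fit <- .fit_terms(design, yv, chosen)
  coefs <- stats::coef(fit)
  pr2 <- .partial_r2(design, yv, chosen)
  pvals <- summary(fit)$coefficients
  term_p <- stats::setNames(rep(NA_real_, length(chosen)), chosen)
  for (tm in chosen)
    if (tm %in% rownames(pvals)) term_p[tm] <- pvals[tm, 4]
  structure(list(
    candidates = tab[order(tab$AICc), ],
    chosen = chosen, fit = fit,
    coefficients = coefs,
    partial_r2 = pr2,
    sign = sign(coefs[chosen]),
    p_value = term_p,
    transform = tinfo[c("method", "lambda", "diagnostics")],
    n = n, n_dropped = sum(!ok), log = log
  ), class = "phylopatchModelSelection")
}

# partial R^2 per term of the chosen model, respecting marginality:
# dropping a main effect also drops its quadratic/interaction dependents
.partial_r2 <- function(design, y, chosen) {
  if (!length(chosen)) return(stats::setNames(numeric(0), character(0)))
  sse_full <- sum(stats::residuals(.fit_terms(design, y, chosen))^2)
  vapply(stats::setNames(chosen, chosen), function(tm) {
    drop <- c(tm, intersect(.term_deps[[tm]], chosen))
    reduced <- setdiff(chosen, drop)
    sse_red <- sum(stats::residuals(.fit_terms(design, y, reduced))^2)
    (sse_red - sse_full) / sse_red
  }, numeric(1))
}

#' @rdname fitCandidates
#' @param x a \code{phylopatchModelSelection} object.
#' @param ... ignored.
#' @export
print.phylopatchModelSelection <- function(x, ...) {
  cat("AICc model selection over", nrow(x$candidates), "candidates (n =",
      x$n, ")\n")
  cat("chosen:", if (length(x$chosen)) paste(x$chosen, collapse = " + ")
      else "(null model)", "\n")
  if (length(x$chosen)) {
    tab <- data.frame(estimate = x$coefficients[x$chosen],
                      partial_r2 = x$partial_r2,
                      p = x$p_value)
    print(round(tab, 4))
  }
  invisible(x)
}
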