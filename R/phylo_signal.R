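#' Blomberg's K with a permutation test
#'
#' Quantifies phylogenetic signal in a continuous trait: the ratio of the
#' observed mean squared error of tip values around the phylogenetic
#' (GLS) mean, computed with and without the tree's variance-covariance
#' structure, scaled by its expectation under Brownian motion so that
#' K = 1 indicates as much signal as BM on the given tree, K < 1 less,
#' K > 1 more. Significance comes from shuffling trait values across tips:
#' smaller phylogenetically-corrected MSE than the shuffles means related
#' species resemble each other more than chance.
#'
#' @param tree \code{ape::phylo}; tips without trait values are pruned
#'   (pruning never alters distances among retained tips).
#' @param trait named numeric vector, species -> value.
#' @param nPerm number of tip-label shuffles (default 999).
#' @param seed optional seed for the permutations.
#' @return list with \code{K}, \code{p_perm} (rank of the observed MSE
#'   among shuffles; in (0, 1]), \code{n_species}, \code{n_perm} and
#'   \code{flag} (\code{""}, \code{"skipped_n<4"} or
#'   \code{"constant_trait"}; skipped/constant results carry \code{NA}).
#' @export
blombergK <- function(tree, trait, nPerm = 999, seed = NULL) {
  trait <- trait[is.finite(trait)]
  tips <- intersect(tree$tip.label, names(trait))
  if (length(tips) < 4L)
    return(list(K = NA_real_, p_perm = NA_real_, n_species = length(tips),
                n_perm = 0L, flag = "skipped_n<4"))
  x <- trait[tips]
  if (stats::sd(x) == 0)
    return(list(K = NA_real_, p_perm = NA_real_, n_species = length(tips),
                n_perm = 0L, flag = "constant_trait"))
  if (!is.null(seed)) set.seed(seed)
  tr <- if (length(tips) < length(tree$tip.label))
    ape::keep.tip(tree, tips) else tree
  x <- x[tr$tip.label]
  n <- length(x)
  C <- ape::vcv(tr)
  invC <- solve(C)
  s <- sum(invC)
  w <- colSums(invC)                       # 1' C^-1
  mse_of <- function(X) {
    # r' C^-1 r with r = x - GLS mean, vectorized over columns of X
    quad <- colSums(X * (invC %*% X))
    t1 <- drop(w %*% X)
    (quad - t1^2 / s) / (n - 1)
  }
  X <- matrix(x, n, 1)
  mse_obs <- mse_of(X)
  ahat <- sum(w * x) / s
  mse0_obs <- sum((x - ahat)^2) / (n - 1)
  expected <- (sum(diag(C)) - n / s) / (n - 1)   # BM expectation of MSE0/MSE
  K <- (mse0_obs / mse_obs) / expected
  perms <- vapply(seq_len(nPerm), function(i) sample.int(n), integer(n))
  mse_perm <- mse_of(matrix(x[perms], n, nPerm))
  p <- (1 + sum(mse_perm <= mse_obs)) / (nPerm + 1)
  list(K = unname(K), p_perm = p, n_species = n, n_perm = nPerm, flag = "")
}

#' Pagel's lambda by maximum likelihood
#'
#' Alternative signal statistic: the off-diagonal scaling of the BM
#' variance-covariance matrix that maximizes the GLS likelihood, with a
#' likelihood-ratio test against lambda = 0.
#'
#' @inheritParams blombergK
#' @return list with \code{lambda}, \code{logL}, \code{logL0} (lambda = 0)
#'   and \code{p_lr} (chi-squared, 1 df).
#' @export
pagelLambda <- function(tree, trait) {
  trait <- trait[is.finite(trait)]
  tips <- intersect(tree$tip.label, names(trait))
  if (length(tips) < 4L) stop("need >= 4 species with trait values")
  tr <- if (length(tips) < length(tree$tip.label))
    ape::keep.tip(tree, tips) else tree
  x <- trait[tr$tip.label]
  n <- length(x)
  C <- ape::vcv(tr)
  ll <- function(lambda) {
    Cl <- lambda * C
    diag(Cl) <- diag(C)
    ch <- chol(Cl)
    invCl <- chol2inv(ch)
    a <- sum(invCl %*% x) / sum(invCl)
    r <- x - a
    s2 <- drop(t(r) %*% invCl %*% r) / n
    -0.5 * (n * log(2 * pi * s2) + 2 * sum(log(diag(ch))) + n)
  }
  opt <- stats::optimize(ll, c(0, 1), maximum = TRUE)
  l0 <- ll(0)
  list(lambda = opt$maximum, logL = opt$objective, logL0 = l0,
       p_lr = stats::pchisq(2 * (opt$objective - l0), 1, lower.tail = FALSE))
}

#' Phylogenetic signal of response indices across taxonomic scales
#'
#' Runs the signal test on each response index at each taxonomic scale.
#' Scales with fewer species than \code{minFormalN} are still summarized
#' descriptively but flagged as too small for a formal test (as with the
#' 10-species extinction pool).
#'
#' @param tree phylogeny over the species pool.
#' @param indices data.frame from [responseIndex()] (columns species,
#'   index_kind, z), possibly with several index kinds stacked.
#' @param clades named character vector species -> clade label, used for
#'   scale subsetting as in [subsetTaxonomicScale()].
#' @param scales taxonomic scales to test.
#' @param nPerm permutations per test.
#' @param minFormalN minimum species for a formal (unflagged) test.
#' @param seed optional seed.
#' @return data.frame (trait, scale, method, statistic, p_perm, n_species,
#'   n_perm, flag).
#' @export
signalByScale <- function(tree, indices, clades,
                          scales = c("invertebrates", "insecta", "diptera"),
                          nPerm = 999, minFormalN = 12, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (kind in unique(indices$index_kind)) {
    sub <- indices[indices$index_kind == kind & !indices$degenerate, ]
    trait <- stats::setNames(sub$z, sub$species)
    for (sc in scales) {
      keep <- switch(sc,
        invertebrates = names(trait),
        insecta = names(trait)[clades[names(trait)] != "Annelida"],
        diptera = names(trait)[clades[names(trait)] == "Diptera"])
      res <- blombergK(tree, trait[keep], nPerm = nPerm)
      flag <- res$flag
      if (flag == "" && res$n_species < minFormalN)
        flag <- "low_power"
      out[[paste(kind, sc)]] <- data.frame(
        trait = kind, scale = sc, method = "blomberg_k",
        statistic = res$K, p_perm = res$p_perm,
        n_species = res$n_species, n_perm = res$n_perm, flag = flag)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
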