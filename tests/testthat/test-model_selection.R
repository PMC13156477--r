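test_that("response standardization centers and scales, preserving NA", {
  expect_equal(standardizeResponse(c(1, 2, 3)), c(-1, 0, 1))
  z <- standardizeResponse(c(1, NA, 2, 3))
  expect_true(is.na(z[2]))
  expect_lt(abs(mean(z, na.rm = TRUE)), 1e-12)
  expect_error(standardizeResponse(c(2, 2, 2)), "zero variance")
  expect_error(standardizeResponse(c(1, NA, NA)), "non-missing")
})

test_that("the AICc small-sample correction is exact", {
  set.seed(6)
  d <- data.frame(size = runif(20, 1, 3), pred = rep(0:1, 10))
  y <- 2 * d$size + rnorm(20, sd = 0.3)
  sel <- fitCandidates(d, y, role = "colonization", transform = "none")
  tab <- sel$candidates
  i <- which(tab$k == 3)[1]   # intercept + slope + sigma, n = 20
  aic <- -2 * tab$logLik[i] + 2 * 3
  expect_equal(tab$AICc[i] - aic, 2 * 3 * 4 / (20 - 3 - 1))  # = 1.5
  expect_equal(tab$AICc[i] - aic, 1.5)
})

test_that("ties within 2 AICc go to the model with fewest terms", {
  set.seed(8)
  d <- data.frame(size = runif(40, 1, 3), pred = rep(0:1, 20))
  y <- 2 * d$size + rnorm(40, sd = 0.3)
  sel <- fitCandidates(d, y, role = "colonization", transform = "none")
  tab <- sel$candidates
  within <- tab[tab$dAICc <= 2, ]
  expect_equal(length(sel$chosen), min(within$n_terms))
  # direct consequence of the rule: chosen model is among the within-2 set
  expect_true(paste(sel$chosen, collapse = "+") %in% within$terms)
})

test_that("marginality restricts the candidate family", {
  cands <- phylopatch:::.enumerate_candidates(c("size", "size2", "pred",
                                                "size_pred"))
  for (s in cands) {
    if ("size2" %in% s) expect_true("size" %in% s)
    if ("size_pred" %in% s) expect_true(all(c("size", "pred") %in% s))
  }
  # {}, size, pred, size+pred, size+size2, size+size2+pred,
  # size+pred+size_pred, full
  expect_true(any(lengths(cands) == 0))  # null model present
  expect_length(cands, 8)
})

test_that("partial R2 matches hand SSE arithmetic on a 3-point regression", {
  # y = {1,2,4} on x = {0,1,2}: SSE(full) = 1/6, SSE(null) = 14/3
  design <- data.frame(size = c(0, 1, 2) - 1)
  y <- c(1, 2, 4)
  pr2 <- phylopatch:::.partial_r2(design, y, "size")
  expect_equal(unname(pr2), (14 / 3 - 1 / 6) / (14 / 3))
  expect_equal(unname(pr2), 27 / 28)
})

test_that("partial R2 hits the boundary cases", {
  # single predictor explaining everything -> 1
  design <- data.frame(size = 1:10 - 5.5)
  expect_equal(unname(phylopatch:::.partial_r2(design, 2 * design$size, "size")),
               1, tolerance = 1e-12)
  # orthogonal term with zero coefficient -> ~0
  set.seed(12)
  design2 <- data.frame(size = rep(c(-1, 1), 20), pred = rep(c(-1, -1, 1, 1), 10))
  y <- 3 * design2$size + rnorm(40, sd = 0.05)
  pr2 <- phylopatch:::.partial_r2(design2, y, c("size", "pred"))
  expect_lt(pr2[["pred"]], 0.1)
  expect_gt(pr2[["size"]], 0.99)
})

test_that("dropping a main effect drops its dependents in partial R2", {
  set.seed(14)
  design <- phylopatch:::.build_design(
    data.frame(size = runif(30, 1, 3), pred = rep(0:1, 15)))
  y <- design$size + 0.5 * design$size2 + rnorm(30, sd = 0.2)
  pr2 <- phylopatch:::.partial_r2(design, y, c("size", "size2"))
  # reduced model for "size" is the intercept-only model: large partial R2
  expect_gt(pr2[["size"]], pr2[["size2"]])
})

test_that("Box-Cox limits: lambda 1 is affine, lambda 0 is the log", {
  y <- c(1, 2, 5, 10)
  expect_equal(phylopatch:::.bc(y, 1), y - 1)
  expect_equal(phylopatch:::.bc(y, 0), log(y))
  expect_equal(phylopatch:::.yj(y, 0), log1p(y))
  expect_equal(phylopatch:::.yj(-y, 2), -log1p(y))
})

test_that("profile-ML lambda agrees with the MASS reference for Box-Cox", {
  skip_if_not_installed("MASS")
  set.seed(15)
  x <- runif(100, 0, 2)
  y <- exp(1 + x + rnorm(100, sd = 0.3))    # log-normal: lambda near 0
  tf <- transformResponse(y, X = data.frame(x = x), method = "box_cox")
  bx <- MASS::boxcox(y ~ x, lambda = seq(-2, 2, 0.01), plotit = FALSE)
  expect_equal(tf$lambda, bx$x[which.max(bx$y)], tolerance = 0.011)
  expect_lt(abs(tf$lambda), 0.3)
})

test_that("Yeo-Johnson leaves symmetric normal data nearly untransformed", {
  set.seed(16)
  y <- rnorm(200)
  tf <- transformResponse(y, method = "yeo_johnson")
  expect_lt(abs(tf$lambda - 1), 0.2)
})

test_that("auto transformation triggers only when diagnostics fail", {
  set.seed(18)
  x <- runif(60, 0, 2)
  ok <- transformResponse(1 + x + rnorm(60, sd = 0.2),
                          X = data.frame(x = x), method = "auto")
  expect_equal(ok$method, "none")
  skewed <- transformResponse(exp(2 + 2 * x + rnorm(60, sd = 0.6)),
                              X = data.frame(x = x), method = "auto")
  expect_equal(skewed$method, "box_cox")
  expect_error(transformResponse(c(-1, 1, 2), method = "box_cox"), "positive")
})

test_that("selection recovers a linear size effect consistently", {
  hits <- vapply(1:200, function(i) {
    set.seed(900 + i)
    d <- data.frame(size = runif(20, 1, 3), pred = rep(0:1, 10))
    y <- 2 * d$size + rnorm(20, sd = 0.2)
    sel <- fitCandidates(d, y, terms = c("size", "size2"),
                         role = "colonization", transform = "none")
    identical(sel$chosen, "size")
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("pure-noise responses mostly select the null model", {
  hits <- vapply(1:100, function(i) {
    set.seed(1300 + i)
    d <- data.frame(size = runif(20, 1, 3), pred = rep(0:1, 10))
    sel <- fitCandidates(d, rnorm(20), role = "colonization",
                         transform = "none")
    length(sel$chosen) == 0
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})

test_that("selection is invariant to response standardization", {
  set.seed(19)
  d <- data.frame(size = runif(25, 1, 3), pred = rep(0:1, length.out = 25))
  y <- 1 + d$size + 0.5 * d$pred + rnorm(25, sd = 0.4)
  a <- fitCandidates(d, y, role = "colonization", standardize = TRUE,
                     transform = "none")
  b <- fitCandidates(d, y, role = "colonization", standardize = FALSE,
                     transform = "none")
  expect_identical(a$chosen, b$chosen)
  expect_equal(a$candidates$dAICc[order(a$candidates$terms)],
               b$candidates$dAICc[order(b$candidates$terms)], tolerance = 1e-8)
})

test_that("AICc converges to AIC for large n", {
  k <- 3; n <- 10000
  expect_lt(2 * k * (k + 1) / (n - k - 1), 0.01)
})

test_that("missing responses are dropped with a log and small n fails clearly", {
  set.seed(20)
  d <- data.frame(size = runif(12, 1, 3), pred = rep(0:1, 6))
  y <- 2 * d$size + rnorm(12, sd = 0.2)
  y[1:3] <- NA
  sel <- fitCandidates(d, y, role = "colonization", transform = "none")
  expect_equal(sel$n, 9)
  expect_equal(sel$n_dropped, 3)
  expect_match(sel$log, "dropped 3", all = FALSE)
  expect_error(fitCandidates(d, c(1, 2, rep(NA, 10)), role = "colonization"),
               "too few")
})
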