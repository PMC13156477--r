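test_that("MPD matches hand computations, weighted and unweighted", {
  d <- patristicDistances(tree3())
  expect_equal(mpd(d), 10 / 3)                         # (2+4+4)/3
  ab <- c(A = 2, B = 1, C = 1)
  expect_equal(mpd(d, abund = ab, exponent = 1), 16 / 5)  # (2*2 + 2*4 + 4)/5
  # single species: degenerate
  expect_true(isTRUE(attr(mpd(d[1, 1, drop = FALSE]), "degenerate")))
})

test_that("MNTD matches hand computations", {
  d <- patristicDistances(tree3())
  expect_equal(mntd(d), 8 / 3)                         # (2+2+4)/3
  expect_equal(mntd(d, species = c("A", "B")), 2)
  # weighted with equal counts equals unweighted
  expect_equal(mntd(d, abund = c(A = 3, B = 3, C = 3), exponent = 1), mntd(d))
  expect_equal(mpd(d, abund = c(A = 3, B = 3, C = 3), exponent = 0.5), mpd(d))
})

test_that("metrics ignore species order and zero-count species", {
  d <- patristicDistances(tree4())
  expect_equal(mpd(d, species = c("D", "A", "C")),
               mpd(d, species = c("A", "C", "D")))
  ab <- c(A = 2, B = 1, C = 0, D = 3)
  expect_equal(mpd(d, abund = ab), mpd(d, abund = ab[ab > 0]))
  expect_equal(mntd(d, abund = ab), mntd(d, abund = ab[ab > 0]))
})

test_that("Faith's PD sums the spanning subtree, with and without the root", {
  tr <- tree3()
  expect_equal(faithPD(tr, c("A", "B", "C")), 5)       # total tree length
  tr4 <- tree4()
  expect_equal(faithPD(tr4, c("A", "B"), includeRoot = TRUE), 3)
  expect_equal(faithPD(tr4, c("A", "B"), includeRoot = FALSE), 2)
  expect_equal(faithPD(tr3 <- tree3(), "A", includeRoot = TRUE), 2)
  expect_error(faithPD(tr, character(0)), "empty community")
})

test_that("metrics agree with the picante reference implementation", {
  skip_if_not_installed("picante")
  set.seed(21)
  tr <- rand_tree(15, 21)
  d <- patristicDistances(tr)
  m <- matrix(rpois(5 * 15, 1), 5, 15,
              dimnames = list(sprintf("b%d", 1:5), tr$tip.label))
  m[1, ] <- c(rep(1, 4), rep(0, 11))  # make sure one richness-4 community
  ref_mpd <- picante::mpd(m, d)
  ref_mntd <- picante::mntd(m, d)
  ref_pd <- picante::pd(m, tr)
  for (i in seq_len(nrow(m))) {
    sp <- colnames(m)[m[i, ] > 0]
    if (length(sp) < 2) next
    expect_equal(mpd(d, species = sp), ref_mpd[i], tolerance = 1e-10)
    expect_equal(mntd(d, species = sp), ref_mntd[i], tolerance = 1e-10)
    expect_equal(faithPD(tr, sp), ref_pd$PD[i], tolerance = 1e-10)
  }
  # abundance-weighted MPD: picante averages over ordered pairs including
  # the zero-distance diagonal; ours over unordered distinct pairs. The two
  # differ exactly by the diagonal weight in the denominator.
  i <- which(rowSums(m > 0) >= 2)[1]
  a <- m[i, ][m[i, ] > 0]
  w_all <- sum(outer(a, a))
  w_off <- w_all - sum(a^2)
  expect_equal(mpd(d, abund = m[i, ], exponent = 1),
               picante::mpd(m[i, , drop = FALSE], d,
                            abundance.weighted = TRUE) * w_all / w_off,
               tolerance = 1e-10)
})

test_that("exhaustive SES reproduces the cherry-community worked case", {
  be <- cherry_be()
  d <- patristicDistances(tree4())
  for (met in c("mpd", "mntd")) {
    r <- sesMetric(be, d, metric = met, method = "exhaustive")
    expect_false(r$degenerate)
    expect_equal(r$null_mean, 10 / 3)
    expect_equal(r$null_sd, 2 * sqrt(2) / 3)
    expect_equal(r$nri_or_nti, sqrt(2), tolerance = 1e-12)
  }
})

test_that("a community equal to the entire pool is degenerate", {
  be <- cherry_be(c("A", "B", "C", "D"))
  d <- patristicDistances(tree4())
  r <- sesMetric(be, d, "mpd", method = "exhaustive")
  expect_true(r$degenerate)
  expect_true(is.na(r$ses))
  r2 <- sesMetric(be, d, "mpd", nRuns = 199, seed = 1)
  expect_true(r2$degenerate)
})

test_that("Monte-Carlo SES converges to the exhaustive value", {
  set.seed(31)
  for (seed in c(31, 32)) {
    tr <- rand_tree(6, seed)
    cnt <- matrix(0, 1, 6, dimnames = list("b1", tr$tip.label))
    cnt[1, sample(6, 3)] <- c(2, 1, 1)
    be <- make_be(cnt, capacity = 100, predator = FALSE)
    d <- patristicDistances(tr)
    for (w in c("unweighted", "weighted")) {
      ex <- sesMetric(be, d, "mpd", weighting = w, method = "exhaustive")
      mc <- sesMetric(be, d, "mpd", weighting = w, nRuns = 9999, seed = seed)
      se <- sqrt((1 + ex$ses^2 / 2) / 9999)
      expect_lt(abs(mc$ses - ex$ses), 3 * se + 0.02)
    }
  }
})

test_that("weighted SES uses compressive exponent by default, 1 for extinction", {
  # exponent routing: survey/colonization 0.5, extinction 1
  cnt <- matrix(c(4, 1, 1, 0), 1, 4,
                dimnames = list("b1", c("A", "B", "C", "D")))
  be_s <- make_be(cnt, capacity = 100, predator = FALSE, role = "survey")
  d <- patristicDistances(tree4())
  r <- sesMetric(be_s, d, "mpd", weighting = "weighted", method = "exhaustive")
  expect_equal(r$observed, mpd(d, abund = cnt[1, ], exponent = 0.5))
  intro <- matrix(5, 1, 4, dimnames = dimnames(cnt))
  be_x <- make_be(cnt, capacity = 100, predator = FALSE, role = "extinction",
                  introduced = intro)
  rx <- sesMetric(be_x, d, "mpd", weighting = "weighted", method = "exhaustive")
  expect_equal(rx$observed, mpd(d, abund = cnt[1, ], exponent = 1))
})

test_that("richness-PD correlation behaves on near-star nested communities", {
  # effectively a star tree (negligible internal branches): PD is linear in
  # richness, so nested communities give r = 1
  tr <- readPhylogeny(
    "((((a:1,b:1):0.000000001,c:1):0.000000001,d:1):0.000000001,e:1);")
  cnt <- matrix(0, 4, 5, dimnames = list(sprintf("b%d", 1:4), letters[1:5]))
  for (i in 1:4) cnt[i, seq_len(i + 1)] <- 1
  be <- make_be(cnt)
  expect_equal(richnessPDCorrelation(be, tr), 1, tolerance = 1e-5)
  expect_error(richnessPDCorrelation(make_be(cnt[1:2, ]), tr), "at least 3")
})

test_that("PD is collinear with richness across simulated richness gradients", {
  # the collinearity that justifies dropping PD from model fitting emerges
  # once habitat filtering generates a richness gradient
  rs <- vapply(1:3, function(i) {
    st <- simulateStudy(conservedFilterConfig(seed = 360 + i, nSpecies = 60))
    richnessPDCorrelation(st@survey, st@tree)
  }, numeric(1))
  expect_gt(mean(rs), 0.8)
})
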