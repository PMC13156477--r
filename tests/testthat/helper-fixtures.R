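# small programmatic fixtures shared across test files

# 3-tip caterpillar: d(A,B)=2, d(A,C)=d(B,C)=4, total length 5
tree3 <- function() readPhylogeny("((A:1,B:1):1,C:2);")

# balanced 4-tip tree: cherries (A,B) and (C,D), all cross distances 4
tree4 <- function() readPhylogeny("((A:1,B:1):1,(C:1,D:1):1);")

# bromeliad x species BromeliadExperiment from a counts matrix
make_be <- function(counts, capacity = NULL, predator = NULL,
                    role = "survey", introduced = NULL, speciesMeta = NULL) {
  nb <- nrow(counts)
  if (is.null(capacity)) capacity <- 10^seq(1, 3, length.out = nb)
  if (is.null(predator)) predator <- rep(c(FALSE, TRUE), length.out = nb)
  meta <- data.frame(row.names = rownames(counts),
                     capacity_ml = capacity, predator_present = predator)
  BromeliadExperiment(counts, meta = meta, role = role,
                      introduced = introduced, speciesMeta = speciesMeta)
}

# one-community experiment over the 4-tip tree pool
cherry_be <- function(species = c("A", "B")) {
  cnt <- matrix(0, 1, 4, dimnames = list("b1", c("A", "B", "C", "D")))
  cnt[1, species] <- 1
  make_be(cnt, capacity = 100, predator = FALSE)
}

# random Yule tree with uniquely labelled tips
rand_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rphylo(n, birth = 1, death = 0)
  tr$tip.label <- sprintf("t%02d", seq_len(n))
  tr
}
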