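random_profiles <- function(n_taxa, n_cols, symbols = c("A", "C", "G", "T")) {
  matrix(sample(symbols, n_taxa * n_cols, TRUE), n_taxa, n_cols,
         dimnames = list(paste0("t", seq_len(n_taxa)),
                         paste0("c", seq_len(n_cols))))
}

test_that("SNP distances are literal Hamming counts", {
  m <- rbind(a = c("A", "C", "G"), b = c("A", "C", "G"), c = c("A", "R", "G"))
  colnames(m) <- paste0("c", 1:3)
  D <- snp_distance_matrix(m)
  expect_equal(D["a", "b"], 0L)
  expect_equal(D["a", "c"], 1L)   # A vs R is a difference

  withr::local_seed(51)
  m2 <- random_profiles(6, 20)
  D2 <- snp_distance_matrix(m2)
  for (i in 1:5) for (j in (i + 1):6) {
    brute <- sum(vapply(1:20, function(k) m2[i, k] != m2[j, k], logical(1)))
    expect_equal(D2[i, j], brute)
  }
  expect_true(isSymmetric(D2))
  expect_true(all(diag(D2) == 0))
})

test_that("UPGMA merges two taxa at half their distance", {
  D <- matrix(c(0, 4, 4, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  den <- upgma(D)
  expect_equal(den$hclust$height, 2)
  expect_equal(den$cophenetic_r, 1)
})

test_that("UPGMA reconstructs ultrametric trees with cophenetic r = 1", {
  # ((a,b):3,(c,d):1): cophenetic distances 2, 6, 6 in SNP units
  labs <- c("a", "b", "c", "d")
  D <- matrix(c(0, 2, 6, 6,
                2, 0, 6, 6,
                6, 6, 0, 2,
                6, 6, 2, 0), 4, 4, dimnames = list(labs, labs))
  den <- upgma(D)
  expect_equal(den$cophenetic_r, 1)
  # cophenetic distances (heights are d/2) reproduce D exactly
  expect_equal(2 * as.matrix(stats::cophenetic(den$hclust))[labs, labs],
               D, ignore_attr = TRUE)
  # a and b are sisters
  expect_true(ape::is.monophyletic(ape::root(den$phylo, "c"), c("a", "b")))
})

test_that("UPGMA agrees with average-linkage hclust on tie-free matrices", {
  withr::local_seed(61)
  for (i in 1:10) {
    n <- sample(5:8, 1)
    d <- stats::dist(matrix(runif(n * 4), n))  # continuous: ties negligible
    D <- as.matrix(d)
    dimnames(D) <- list(paste0("t", 1:n), paste0("t", 1:n))
    den <- upgma(D)
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    expect_equal(unname(as.matrix(stats::cophenetic(den$hclust))),
                 unname(as.matrix(stats::cophenetic(hc)) / 2),
                 tolerance = 1e-12)
  }
})

test_that("Fitch scores match brute-force parsimony and phangorn", {
  tree <- ape::read.tree(text = "((A1,A2),(B1,B2));")
  X0 <- matrix(c("A", "A", "B", "B"), 4, 1,
               dimnames = list(c("A1", "A2", "B1", "B2"), "c1"))
  expect_equal(fitch_score(tree, X0), 1L)
  Xsame <- matrix("A", 4, 1, dimnames = list(c("A1", "A2", "B1", "B2"), "c1"))
  expect_equal(fitch_score(tree, Xsame), 0L)

  withr::local_seed(71)
  for (i in 1:8) {
    X <- random_profiles(6, 10)
    tr <- ape::rtree(6, tip.label = rownames(X))
    want <- oracle_parsimony(tr, X)
    expect_equal(fitch_score(tr, X), want)
    # cross-check against phangorn's Fitch implementation
    pd <- phangorn::phyDat(X, type = "USER", levels = c("A", "C", "G", "T"))
    expect_equal(unname(phangorn::parsimony(tr, pd)), want)
  }

  expect_error(fitch_score(ape::rtree(4, tip.label = paste0("x", 1:4)),
                           random_profiles(4, 3)),
               "unknown leaf")
})

test_that("Fitch score is invariant under leaf relabelling", {
  withr::local_seed(73)
  X <- random_profiles(6, 12)
  tr <- ape::rtree(6, tip.label = rownames(X))
  s0 <- fitch_score(tr, X)
  perm <- sample(rownames(X))
  tr2 <- tr
  tr2$tip.label <- perm[match(tr$tip.label, rownames(X))]
  X2 <- X
  rownames(X2) <- perm
  expect_equal(fitch_score(tr2, X2), s0)
})

test_that("exhaustive search finds the global minimum; annealing never beats it", {
  withr::local_seed(81)
  X <- random_profiles(6, 12)
  ex <- mp_search(X, mode = "exhaustive")
  # oracle: minimum Sankoff score over every enumerated topology
  trees <- phangorn::allTrees(6, rooted = FALSE, tip.label = rownames(X))
  want <- min(vapply(trees, function(tr) oracle_parsimony(tr, X), numeric(1)))
  expect_equal(ex$score, want)
  expect_equal(fitch_score(ex$tree, X), ex$score)

  for (s in 1:5) {
    an <- mp_search(X, mode = "anneal", seed = s,
                    control = anneal_control(t0 = 2, n_per_temp = 30,
                                             alpha = 0.9, t_min = 0.05))
    expect_gte(an$score, ex$score)
  }
  expect_error(mp_search(random_profiles(10, 5), mode = "exhaustive"),
               "<= 9 taxa")
})

test_that("four-taxon annealing hits the exhaustive optimum", {
  withr::local_seed(83)
  X <- random_profiles(4, 8)
  ex <- mp_search(X, mode = "exhaustive")
  an <- mp_search(X, mode = "anneal", seed = 7)
  expect_equal(an$score, ex$score)
})

test_that("bootstrap gives near-certain support to a 10-column split and is seeded", {
  withr::local_seed(91)
  X <- rbind(matrix("A", 4, 10), matrix("G", 4, 10))
  rownames(X) <- c(paste0("a", 1:4), paste0("b", 1:4))
  colnames(X) <- paste0("c", 1:10)
  # add a few uninformative columns
  X <- cbind(X, matrix(sample(c("A", "C"), 16, TRUE), 8, 2))
  mp <- mp_search(X, mode = "anneal", seed = 1)
  ctrl <- anneal_control(t0 = 1, alpha = 0.85, n_per_temp = 10, t_min = 0.05)
  supp <- mp_bootstrap(X, mp$tree, n_reps = 100, seed = 2, control = ctrl)
  # the a|b bipartition is in the MP tree and must be supported >= 99%
  grp <- ape::prop.part(mp$tree)
  split_node <- which(vapply(grp, function(g)
    setequal(mp$tree$tip.label[g], paste0("a", 1:4)) ||
      setequal(mp$tree$tip.label[g], paste0("b", 1:4)), logical(1)))
  expect_true(length(split_node) >= 1)
  expect_gte(max(supp[split_node]), 99)

  supp2 <- mp_bootstrap(X, mp$tree, n_reps = 100, seed = 2, control = ctrl)
  expect_equal(unclass(supp)[], unclass(supp2)[], ignore_attr = TRUE)
})
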