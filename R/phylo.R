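## Trees from concatenated SNP profiles: Hamming distances, UPGMA with
## cophenetic correlation, Fitch parsimony, simulated-annealing topology
## search and column bootstrap.

#' Pairwise SNP distance matrix
#'
#' `d(i, j)` = number of SNP columns at which the two allele vectors differ;
#' IUPAC heterozygote codes are compared literally (`A` vs `R` is a
#' difference).
#'
#' @param profiles character matrix of allele symbols (taxa x SNP columns).
#' @return Symmetric integer matrix with the profile row names.
#' @export
snp_distance_matrix <- function(profiles) {
  stopifnot(is.matrix(profiles))
  n <- nrow(profiles)
  D <- matrix(0L, n, n, dimnames = list(rownames(profiles), rownames(profiles)))
  if (n < 2) return(D)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sum(profiles[i, ] != profiles[j, ])
    D[i, j] <- d; D[j, i] <- d
  }
  D
}

#' UPGMA dendrogram with cophenetic correlation
#'
#' Standard unweighted pair-group average-linkage agglomeration: the closest
#' pair of clusters is merged at height `d/2`, and the distance from the
#' merged cluster to any other is the member-count-weighted average (i.e. the
#' unweighted average over original leaves). Ties are broken by the
#' lexicographically lowest cluster-index pair, so runs are reproducible.
#'
#' @param D symmetric distance matrix (SNP units).
#' @param labels leaf labels (default: `rownames(D)`).
#' @return An `upgma_dendrogram`: `hclust` (merge heights in `d/2` units),
#'   `phylo` (the [ape::as.phylo()] conversion), `cophenetic_r` (Pearson
#'   correlation between input distances and dendrogram cophenetic
#'   distances).
#' @export
upgma <- function(D, labels = rownames(D)) {
  n <- nrow(D)
  if (n < 2) stop("UPGMA needs at least 2 taxa")
  stopifnot(isTRUE(all.equal(D, t(D))), all(diag(D) == 0))
  if (is.null(labels)) labels <- paste0("t", seq_len(n))

  cur <- D + 0.0
  sizes <- rep(1L, n)
  ids <- -seq_len(n)                 # hclust codes: negative = singleton
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(ids)
    best <- c(NA_integer_, NA_integer_); bestd <- Inf
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      if (cur[i, j] < bestd) { bestd <- cur[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    merge[step, ] <- ids[c(i, j)]
    height[step] <- bestd / 2
    ni <- sizes[i]; nj <- sizes[j]
    newd <- (ni * cur[i, ] + nj * cur[j, ]) / (ni + nj)
    cur[i, ] <- newd; cur[, i] <- newd; cur[i, i] <- 0
    keep <- setdiff(seq_len(k), j)
    cur <- cur[keep, keep, drop = FALSE]
    sizes[i] <- ni + nj; sizes <- sizes[keep]
    ids[i] <- step; ids <- ids[keep]
  }

  leaf_order <- function(row) {
    unlist(lapply(merge[row, ], function(id)
      if (id < 0) -id else leaf_order(id)))
  }
  hc <- structure(list(merge = merge, height = height,
                       order = leaf_order(n - 1L), labels = labels,
                       method = "average", dist.method = "snp_hamming",
                       call = match.call()),
                  class = "hclust")
  coph <- stats::cophenetic(hc)
  dvec <- stats::as.dist(D)
  # degenerate cases (2 taxa, or all distances equal) have no variance to
  # correlate; the dendrogram is exact there iff cophenetic == input
  sdd <- stats::sd(dvec); sdc <- stats::sd(coph)   # NA for a single pair
  r <- if (is.na(sdd) || is.na(sdc) || sdd == 0 || sdc == 0) {
    if (isTRUE(all.equal(as.numeric(2 * coph), as.numeric(dvec)))) 1 else NA_real_
  } else {
    stats::cor(dvec, coph)
  }
  structure(list(hclust = hc, phylo = ape::as.phylo(hc), cophenetic_r = r),
            class = "upgma_dendrogram")
}

#' @export
print.upgma_dendrogram <- function(x, ...) {
  cat(sprintf("<UPGMA dendrogram: %d leaves, cophenetic r = %.4f>\n",
              length(x$hclust$labels), x$cophenetic_r))
  invisible(x)
}

# Encode a character matrix as per-column bitmask matrices for Fitch.
encode_states <- function(X) {
  out <- matrix(0L, nrow(X), ncol(X), dimnames = dimnames(X))
  for (j in seq_len(ncol(X))) {
    lev <- unique(X[, j])
    out[, j] <- bitwShiftL(1L, match(X[, j], lev) - 1L)
  }
  out
}

#' Fitch small-parsimony score of a topology
#'
#' Sum over character columns of the Fitch state-change count on the given
#' topology. Characters are categorical: every distinct symbol is its own
#' state. Unrooted/multifurcating inputs are resolved to an equivalent
#' rooted binary tree first (the Fitch count of an unrooted binary topology
#' does not depend on the rooting).
#'
#' @param tree a `phylo` whose tip labels match `rownames(X)`.
#' @param X character matrix (taxa x characters), or the pre-encoded bitmask
#'   matrix from the internal encoder (integer matrix).
#' @return Integer parsimony score.
#' @export
fitch_score <- function(tree, X) {
  if (!all(tree$tip.label %in% rownames(X)))
    stop("unknown leaf label(s): ",
         paste(setdiff(tree$tip.label, rownames(X)), collapse = ","))
  S0 <- if (is.integer(X)) X else encode_states(X)
  if (!ape::is.binary(tree) || !ape::is.rooted(tree))
    tree <- ape::multi2di(tree)
  tree <- stats::reorder(tree, "postorder")
  E <- tree$edge
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  nc <- ncol(S0)
  S <- matrix(0L, ntip + nnode, nc)
  S[seq_len(ntip), ] <- S0[tree$tip.label, , drop = FALSE]
  seen <- logical(ntip + nnode)
  changes <- 0L
  for (k in seq_len(nrow(E))) {
    par <- E[k, 1]; ch <- E[k, 2]
    if (!seen[par]) {
      S[par, ] <- S[ch, ]; seen[par] <- TRUE
    } else {
      inter <- bitwAnd(S[par, ], S[ch, ])
      zero <- inter == 0L
      changes <- changes + sum(zero)
      S[par, ] <- ifelse(zero, bitwOr(S[par, ], S[ch, ]), inter)
    }
  }
  changes
}

# Insert a new tip on edge `edge_idx` of an unrooted phylo (edge-matrix surgery).
insert_tip <- function(tree, edge_idx, label) {
  E <- tree$edge
  ntip <- length(tree$tip.label)
  E[E > ntip] <- E[E > ntip] + 1L      # shift internal ids for the new tip
  newtip <- ntip + 1L
  newnode <- max(E) + 1L
  p <- E[edge_idx, 1]; ch <- E[edge_idx, 2]
  E[edge_idx, ] <- c(p, newnode)
  E <- rbind(E, c(newnode, ch), c(newnode, newtip))
  structure(list(edge = E, tip.label = c(tree$tip.label, label),
                 Nnode = tree$Nnode + 1L),
            class = "phylo")
}

# One uniformly chosen nearest-neighbour-interchange move: pick a random
# internal edge (p, q) and swap a random child subtree of q with a random
# sibling subtree hanging off p. Edge-matrix surgery, O(edges).
random_nni <- function(tree) {
  E <- tree$edge
  ntip <- length(tree$tip.label)
  int_edges <- which(E[, 2] > ntip)
  if (length(int_edges) == 0) return(tree)
  k <- int_edges[sample.int(length(int_edges), 1L)]
  p <- E[k, 1]; q <- E[k, 2]
  children_q <- which(E[, 1] == q)
  c_row <- children_q[sample.int(length(children_q), 1L)]
  sibs <- setdiff(which(E[, 1] == p), k)
  s_row <- sibs[sample.int(length(sibs), 1L)]
  tmp <- E[s_row, 2]
  E[s_row, 2] <- E[c_row, 2]
  E[c_row, 2] <- tmp
  tree$edge <- E
  attr(tree, "order") <- NULL
  tree
}

# Random-addition starting tree: taxa added in random order, each on the
# edge that minimizes the Fitch score.
random_addition_tree <- function(taxa, S) {
  ord <- sample(taxa)
  tree <- structure(list(edge = cbind(4L, 1:3), tip.label = ord[1:3],
                         Nnode = 1L),
                    class = "phylo")
  for (tx in ord[-(1:3)]) {
    cands <- lapply(seq_len(nrow(tree$edge)), insert_tip, tree = tree,
                    label = tx)
    scores <- vapply(cands, function(tr) fitch_score(tr, S), numeric(1))
    tree <- cands[[which.min(scores)]]
  }
  tree
}

#' Annealing schedule for the parsimony search
#'
#' Geometric cooling: temperature starts at `t0`, is multiplied by `alpha`
#' after every `n_per_temp` NNI proposals, and the search stops below
#' `t_min`.
#'
#' @param t0 starting temperature (score units).
#' @param alpha geometric cooling factor in (0, 1).
#' @param n_per_temp NNI proposals per temperature.
#' @param t_min stopping temperature.
#' @return A list of schedule parameters.
#' @export
anneal_control <- function(t0 = 5, alpha = 0.95, n_per_temp = 100,
                           t_min = 0.01) {
  stopifnot(t0 > 0, alpha > 0, alpha < 1, n_per_temp >= 1, t_min > 0)
  list(t0 = t0, alpha = alpha, n_per_temp = n_per_temp, t_min = t_min)
}

#' Maximum-parsimony tree search
#'
#' `exhaustive` mode enumerates every unrooted topology (allowed up to 9
#' taxa) and returns a global minimum. `anneal` mode starts from a
#' random-addition tree and performs simulated annealing over
#' nearest-neighbour-interchange moves with geometric cooling, returning the
#' best topology encountered. The rooted form places the root on the deepest
#' branch (midpoint-style rooting with unit edge lengths — the longest-path
#' interpretation of a maximum-branch-length root).
#'
#' @param X character matrix (taxa x characters).
#' @param mode `"anneal"` or `"exhaustive"`.
#' @param seed integer seed (anneal mode).
#' @param control an [anneal_control()].
#' @return A `parsimony_result`: `tree` (unrooted `phylo`), `rooted`
#'   (rooted form), `score`, `mode`.
#' @export
mp_search <- function(X, mode = c("anneal", "exhaustive"), seed = NULL,
                      control = anneal_control()) {
  mode <- match.arg(mode)
  taxa <- rownames(X)
  n <- length(taxa)
  stopifnot(n >= 3)
  S <- encode_states(X)

  if (mode == "exhaustive") {
    if (n > 9) stop("exhaustive search allowed only for <= 9 taxa")
    trees <- phangorn::allTrees(n, rooted = FALSE, tip.label = taxa)
    scores <- vapply(trees, function(tr) fitch_score(tr, S), numeric(1))
    best <- trees[[which.min(scores)]]
    score <- min(scores)
  } else {
    if (!is.null(seed)) withr::local_seed(seed)
    cur <- random_addition_tree(taxa, S)
    cur_score <- fitch_score(cur, S)
    best <- cur; score <- cur_score
    if (n >= 4) {
      temp <- control$t0
      while (temp >= control$t_min) {
        for (it in seq_len(control$n_per_temp)) {
          cand <- random_nni(cur)
          cand_score <- fitch_score(cand, S)
          delta <- cand_score - cur_score
          if (delta <= 0 || stats::runif(1) < exp(-delta / temp)) {
            cur <- cand; cur_score <- cand_score
            if (cur_score < score) { best <- cur; score <- cur_score }
          }
        }
        temp <- temp * control$alpha
      }
    }
  }
  best <- ape::unroot(best)
  rooted <- root_deepest(best)
  structure(list(tree = best, rooted = rooted, score = score, mode = mode),
            class = "parsimony_result")
}

# Root on the deepest branch: midpoint rooting with unit edge lengths.
root_deepest <- function(tree) {
  t2 <- tree
  t2$edge.length <- rep(1, nrow(t2$edge))
  phangorn::midpoint(t2)
}

#' @export
print.parsimony_result <- function(x, ...) {
  cat(sprintf("<parsimony_result (%s): %d taxa, score %d>\n", x$mode,
              length(x$tree$tip.label), x$score))
  invisible(x)
}

#' Column bootstrap support for a parsimony tree
#'
#' Resamples character columns with replacement `n_reps` times, re-runs the
#' annealing search on each replicate, and reports for every internal branch
#' of the reference topology the percentage of replicate trees containing the
#' same bipartition.
#'
#' @param X character matrix (taxa x characters), at least 4 taxa.
#' @param tree reference topology (`phylo`, e.g. `mp_search(X)$tree`).
#' @param n_reps number of bootstrap replicates.
#' @param seed integer seed.
#' @param control annealing schedule per replicate (default: a lightened
#'   schedule, since each replicate only needs a local refit).
#' @return Numeric vector of percentages, one per internal node of `tree`
#'   (in [ape::prop.clades()] node order); attribute `"trees"` holds the
#'   replicate topologies.
#' @export
mp_bootstrap <- function(X, tree, n_reps = 1000, seed = NULL,
                         control = anneal_control(t0 = 2, alpha = 0.90,
                                                  n_per_temp = 20,
                                                  t_min = 0.05)) {
  stopifnot(nrow(X) >= 4)
  if (!is.null(seed)) withr::local_seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  boots <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(ncol(X), ncol(X), replace = TRUE)
    boots[[b]] <- mp_search(X[, cols, drop = FALSE], mode = "anneal",
                            seed = rep_seeds[b], control = control)$tree
  }
  class(boots) <- "multiPhylo"
  counts <- ape::prop.clades(tree, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- 100 * counts / n_reps
  attr(support, "trees") <- boots
  support
}
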