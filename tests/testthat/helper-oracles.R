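# Independent brute-force oracles and small fixture builders used across the
# suite. Every oracle recomputes its quantity by direct enumeration, not by
# calling the implementation under test.

# A quality_read with the given per-base qualities (bases random ACGT).
make_read <- function(qv, bases = NULL, frac = NULL, second = NULL,
                      direction = "forward", id = "r1") {
  n <- length(qv)
  if (is.null(bases))
    bases <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  structure(list(read_id = id, sample_id = "S", locus_id = "L",
                 individual = 1L, direction = direction, bases = bases,
                 qv = as.integer(qv),
                 secondary_fraction = frac %||% numeric(n),
                 second_base = second %||% rep(NA_character_, n)),
            class = "quality_read")
}

random_quality_read <- function(n = 300) {
  qv <- pmin(60L, pmax(0L, as.integer(round(rnorm(n, 35, 15)))))
  bases <- sample(c("A", "C", "G", "T", "N"), n, TRUE,
                  prob = c(rep(0.245, 4), 0.02))
  make_read(qv, bases = paste(bases, collapse = ""))
}

# Brute-force trimming oracle: recheck every candidate start/end by direct
# window counting.
oracle_trim <- function(read, window = 25L, qv_floor = 25L, max_bad = 3L) {
  n <- nchar(read$bases)
  if (n == 0) return(NULL)
  ch <- strsplit(read$bases, "")[[1]]
  bad <- read$qv < qv_floor | !(ch %in% c("A", "C", "G", "T"))
  w <- min(window, n)
  start <- NA
  for (s in 1:(n - w + 1)) {
    if (sum(bad[s:(s + w - 1)]) < max_bad) { start <- s; break }
  }
  if (is.na(start)) return(NULL)
  w2 <- min(window, n - start + 1)
  end <- NA
  for (e in n:(start + w2 - 1)) {
    if (sum(bad[(e - w2 + 1):e]) < max_bad) { end <- e; break }
  }
  if (is.na(end) || start > end) return(NULL)
  c(start = start, end = end)
}

# Brute-force CRL oracle: smoothed mean by explicit per-position loops, run
# lengths by scanning every (i, j) run.
oracle_crl <- function(read, qv_threshold = 20, window = 20) {
  qv <- read$qv
  n <- length(qv)
  if (n == 0) return(0L)
  half_lo <- floor((window - 1) / 2)
  half_hi <- ceiling((window - 1) / 2)
  sm <- numeric(n)
  for (i in 1:n) {
    lo <- max(1, i - half_lo); hi <- min(n, i + half_hi)
    sm[i] <- mean(qv[lo:hi])
  }
  ok <- sm > qv_threshold
  best <- 0L
  i <- 1L
  while (i <= n) {
    if (ok[i]) {
      j <- i
      while (j < n && ok[j + 1]) j <- j + 1L
      best <- max(best, j - i + 1L)
      i <- j + 1L
    } else i <- i + 1L
  }
  best
}

# Unit-cost Sankoff small parsimony by dynamic programming over a rooted
# binary tree (independent of the bitmask Fitch implementation).
oracle_parsimony <- function(tree, X) {
  tree <- ape::multi2di(tree)
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  total <- 0
  for (j in seq_len(ncol(X))) {
    states <- sort(unique(X[, j]))
    ns <- length(states)
    cost <- matrix(Inf, ntip + tree$Nnode, ns)
    for (i in seq_len(ntip))
      cost[i, match(X[tree$tip.label[i], j], states)] <- 0
    for (k in seq_len(nrow(tree$edge))) {
      par <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
      add <- vapply(seq_len(ns), function(s)
        min(cost[ch, ] + (seq_len(ns) != s)), numeric(1))
      if (all(is.infinite(cost[par, ]))) cost[par, ] <- add
      else cost[par, ] <- cost[par, ] + add
    }
    root <- tree$edge[nrow(tree$edge), 1]
    total <- total + min(cost[root, ])
  }
  total
}

# All labelled trees on n nodes via Pruefer sequences; minimum spanning-tree
# weight by exhaustive enumeration (n <= 8).
pruefer_to_edges <- function(pr, n) {
  degree <- rep(1L, n)
  for (v in pr) degree[v] <- degree[v] + 1L
  edges <- matrix(0L, 0, 2)
  for (v in pr) {
    leaf <- which(degree == 1L)[1]
    edges <- rbind(edges, c(leaf, v))
    degree[leaf] <- degree[leaf] - 1L
    degree[v] <- degree[v] - 1L
  }
  rest <- which(degree == 1L)
  rbind(edges, rest)
}

oracle_mst_weight <- function(D) {
  n <- nrow(D)
  if (n == 2) return(D[1, 2])
  prs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- Inf
  for (r in seq_len(nrow(prs))) {
    e <- pruefer_to_edges(prs[r, ], n)
    w <- sum(D[e])
    if (w < best) best <- w
  }
  best
}

# Profile matrix with a designated founder row and k single-SNP variants.
star_profiles <- function(k = 4, n_cols = 10) {
  base <- rep("A", n_cols)
  m <- matrix(rep(base, k + 1), nrow = k + 1, byrow = TRUE)
  for (i in seq_len(k)) m[i + 1, i] <- "G"
  rownames(m) <- c("founder", paste0("v", seq_len(k)))
  colnames(m) <- paste0("c", seq_len(n_cols))
  m
}

# Small noiseless panel for fast end-to-end checks: two loci, no failure mode.
small_panel <- function(seed = 11, n_snps = c(L1 = 4L, L2 = 2L),
                        species = c(A = 6L, C = 3L)) {
  make_panel(species,
             list(locus_spec("L1", 400), locus_spec("L2", 350)),
             n_snps, seed = seed)
}
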