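## Minimum spanning tree over SNP genotypes with the n-locus-variant priority
## rule (n = 1 weight 10000, n = 2 weight 10), zero-distance collapsing,
## <= 2-SNP grouping and founder-genotype ranking.

#' Collapse identical profiles into ST nodes
#'
#' One node per distinct profile (ST); node size is the number of member
#' samples.
#'
#' @param profiles character matrix (samples x SNP columns).
#' @return List with `nodes` (data frame `st`, `size`, `members`),
#'   `profiles` (one representative row per ST) and the `st_registry`.
#' @export
collapse_identical <- function(profiles) {
  reg <- assign_sts(profiles)
  nodes <- data.frame(
    st = seq_along(reg$members),
    size = lengths(reg$members),
    members = vapply(reg$members, paste, character(1), collapse = ","),
    row.names = NULL)
  list(nodes = nodes, profiles = reg$profiles, registry = reg)
}

#' Minimum spanning tree with the n-locus-variant priority rule
#'
#' Prim-style growth over the complete graph of ST nodes with edge weights
#' equal to SNP differences. At each step the minimum-weight candidate edge
#' is added; among tied candidates, the edge whose already-included endpoint
#' has the highest priority score wins, where
#' `score = w1 x (single-SNP variants) + w2 x (double-SNP variants)` counted
#' over the full distance matrix (default weights `1: 10000, 2: 10`).
#' Remaining ties prefer the larger attaching node, then the lowest ST id.
#' The priority rule only resolves ties: total weight equals that of an
#' unconstrained minimum spanning tree.
#'
#' @param nodes node table from [collapse_identical()] (`st`, `size`,
#'   `members`).
#' @param D symmetric SNP-difference matrix over the nodes (ST order).
#' @param priority_weights numeric vector `c(slv, dlv)` of priority weights
#'   for single- and double-SNP variant counts.
#' @return An `mst_graph`: `nodes` (with `priority` column), `edges`
#'   (`from`, `to`, `weight` in ST ids), `total_weight`.
#' @export
build_mst <- function(nodes, D, priority_weights = c(10000, 10)) {
  n <- nrow(nodes)
  stopifnot(nrow(D) == n, ncol(D) == n)
  slv <- rowSums(D == 1) - (diag(D) == 1)
  dlv <- rowSums(D == 2)
  priority <- priority_weights[1] * slv + priority_weights[2] * dlv
  nodes$priority <- priority

  if (n == 1) {
    return(structure(list(nodes = nodes,
                          edges = data.frame(from = integer(0), to = integer(0),
                                             weight = integer(0)),
                          total_weight = 0),
                     class = "mst_graph"))
  }

  start <- order(-priority, -nodes$size, nodes$st)[1]
  included <- start
  edges <- data.frame(from = integer(0), to = integer(0), weight = integer(0))
  while (length(included) < n) {
    out <- setdiff(seq_len(n), included)
    cand <- expand.grid(u = included, v = out)
    cand$w <- D[cbind(cand$u, cand$v)]
    cand <- cand[order(cand$w, -priority[cand$u], -nodes$size[cand$v],
                       nodes$st[cand$v], nodes$st[cand$u]), , drop = FALSE]
    pick <- cand[1, ]
    edges <- rbind(edges, data.frame(from = nodes$st[pick$u],
                                     to = nodes$st[pick$v],
                                     weight = pick$w))
    included <- c(included, pick$v)
  }
  structure(list(nodes = nodes, edges = edges,
                 total_weight = sum(edges$weight)),
            class = "mst_graph")
}

#' @export
print.mst_graph <- function(x, ...) {
  cat(sprintf("<mst_graph: %d ST nodes, total weight %d>\n", nrow(x$nodes),
              x$total_weight))
  if (!is.null(x$groups))
    cat(sprintf("  %d group(s) under the <=%d-SNP rule\n",
                length(unique(stats::na.omit(x$groups))),
                attr(x$groups, "max_diff") %||% 2L))
  invisible(x)
}

#' Partition STs into groups by the <= max_diff SNP rule
#'
#' Groups are connected components of the subgraph of MST edges whose weight
#' is at most `max_diff`; components with at least `min_size` STs are groups,
#' smaller components are ungrouped singletons.
#'
#' @param graph an `mst_graph`.
#' @param max_diff maximum SNP difference for a grouping edge (default 2).
#' @param min_size minimum number of STs in a group (default 2).
#' @return The `mst_graph` with a `groups` element: integer group id per ST
#'   (named by ST id; `NA` = ungrouped), numbered by lowest member ST.
#' @export
find_groups <- function(graph, max_diff = 2L, min_size = 2L) {
  sts <- graph$nodes$st
  comp <- stats::setNames(seq_along(sts), sts)   # start: every ST alone
  e <- graph$edges[graph$edges$weight <= max_diff, , drop = FALSE]
  for (k in seq_len(nrow(e))) {                  # union components
    a <- comp[as.character(e$from[k])]; b <- comp[as.character(e$to[k])]
    if (a != b) comp[comp == b] <- a
  }
  sizes <- table(comp)
  groups <- rep(NA_integer_, length(sts)); names(groups) <- sts
  gid <- 0L
  for (cc in names(sort(vapply(split(sts, comp), min, numeric(1))))) {
    members <- names(comp)[comp == cc]
    if (length(members) >= min_size) {
      gid <- gid + 1L
      groups[members] <- gid
    }
  }
  attr(groups, "max_diff") <- max_diff
  graph$groups <- groups
  graph
}

#' Rank founder-genotype candidates
#'
#' Nodes ranked by their number of single-SNP MST neighbours (descending),
#' then node size (descending), mirroring the rationale that an ancestor
#' genotype sits at the MST centre with many single-SNP descendants and a
#' large membership.
#'
#' @param graph an `mst_graph`.
#' @return The node table with `slv_neighbours` and `founder_rank` columns,
#'   ordered by rank; the top-ranked ST(s) are the founder candidate(s).
#' @export
founder_candidates <- function(graph) {
  nodes <- graph$nodes
  slv_n <- vapply(nodes$st, function(s) {
    e <- graph$edges
    sum(e$weight == 1 & (e$from == s | e$to == s))
  }, numeric(1))
  nodes$slv_neighbours <- slv_n
  ord <- order(-slv_n, -nodes$size, nodes$st)
  nodes <- nodes[ord, , drop = FALSE]
  key <- paste(nodes$slv_neighbours, nodes$size)
  nodes$founder_rank <- cumsum(!duplicated(key))
  rownames(nodes) <- NULL
  nodes
}
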