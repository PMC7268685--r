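# Quartet support of a fixed species tree against gene trees: the
# quartet-frequency triples (q1, q2, q3) around every internal edge that
# annotate coalescent species trees as pie charts. This is a scoring
# re-implementation only: no species-tree search.

# adjacency list of an unrooted tree
.adjacency <- function(tree) {
  nn <- length(tree$tip.label) + tree$Nnode
  adj <- vector("list", nn)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# leaves reachable from `start` without crossing `block`
.leafset <- function(adj, ntip, start, block) {
  seen <- logical(length(adj))
  seen[block] <- TRUE
  stack <- start
  leaves <- integer(0)
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    if (seen[v]) next
    seen[v] <- TRUE
    if (v <= ntip) leaves <- c(leaves, v) else stack <- c(stack, adj[[v]])
  }
  leaves
}

#' Quadripartitions around the internal edges of a species tree
#'
#' For each internal edge of the (unrooted) binary species tree, the four
#' parts are the leaf sets of the four subtrees incident to the edge's
#' endpoints, ordered so that the species-tree arrangement is (A,B | C,D).
#' Edges whose endpoints are polytomies are skipped with a warning.
#'
#' @param species_tree an `ape::phylo`; rooted trees are unrooted first.
#' @return list of entries `list(edge = c(u, v), parts = list(A, B, C, D))`
#'   with parts as character vectors of leaf labels.
#' @export
quadripartitions <- function(species_tree) {
  tr <- ape::collapse.singles(species_tree)
  if (ape::is.rooted(tr)) tr <- ape::unroot(tr)
  ntip <- length(tr$tip.label)
  adj <- .adjacency(tr)
  internal <- which(tr$edge[, 1] > ntip & tr$edge[, 2] > ntip)
  if (length(internal) == 0L)
    warning("tree has no internal edges (star tree)")
  out <- list()
  skipped <- 0L
  for (e in internal) {
    u <- tr$edge[e, 1]; v <- tr$edge[e, 2]
    nu <- setdiff(adj[[u]], v); nv <- setdiff(adj[[v]], u)
    if (length(nu) != 2L || length(nv) != 2L) { skipped <- skipped + 1L; next }
    parts <- list(.leafset(adj, ntip, nu[1], u), .leafset(adj, ntip, nu[2], u),
                  .leafset(adj, ntip, nv[1], v), .leafset(adj, ntip, nv[2], v))
    out[[length(out) + 1L]] <- list(edge = c(u, v),
                                    parts = lapply(parts, function(i) tr$tip.label[i]))
  }
  if (skipped > 0L)
    warning(sprintf("%d internal edge(s) at polytomies skipped", skipped))
  out
}

# topological leaf-distance matrix of one gene tree
.topo_dist <- function(tree) {
  tr <- tree
  tr$edge.length <- rep(1, nrow(tr$edge))
  ntip <- length(tr$tip.label)
  d <- ape::dist.nodes(tr)[seq_len(ntip), seq_len(ntip)]
  dimnames(d) <- list(tr$tip.label, tr$tip.label)
  d
}

# classify quartet (a,b | c,d expected): 1/2/3 for the three arrangements,
# 0 for unresolved (tie under the four-point condition => polytomy)
.classify_quartet <- function(d, a, b, c_, dd) {
  s <- c(d[a, b] + d[c_, dd], d[a, c_] + d[b, dd], d[a, dd] + d[b, c_])
  mn <- min(s)
  w <- which(s == mn)
  if (length(w) != 1L) 0L else w
}

#' Per-edge quartet support of a species tree from gene trees
#'
#' For every internal species-tree edge, samples up to `cap_per_edge`
#' quartets (one leaf per quadripartition part; full enumeration if small
#' enough) and classifies the induced quartet in each gene tree as
#' arrangement 1 (the species-tree split), 2 or 3, or unresolved; gene trees
#' lacking any of the four leaves count as missing. `q_i` is the fraction of
#' resolved observations in arrangement i (topology-only: branch lengths and
#' rooting of gene trees are irrelevant).
#'
#' @param species_tree an `ape::phylo` (binary; unrooted internally).
#' @param gene_trees an `ape::multiPhylo` or list of `phylo`.
#' @param cap_per_edge maximum quartets sampled per edge (default 1000).
#' @param seed integer seed.
#' @return list of class `edge_quartet_support`: `edges` (data.frame with
#'   q1,q2,q3 and counts), `quadripartitions`, `tree` (the unrooted species
#'   tree with `q1|q2|q3` node labels at each edge's far endpoint).
#' @export
edge_quartet_support <- function(species_tree, gene_trees,
                                 cap_per_edge = 1000L, seed = 1L) {
  quads <- quadripartitions(species_tree)
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)
  dists <- lapply(gene_trees, .topo_dist)
  rows <- vector("list", length(quads))
  for (qi in seq_along(quads)) {
    parts <- quads[[qi]]$parts
    idx <- sample_product(lengths(parts), cap_per_edge,
                          substream_seed(seed, paste0("edge-", qi)))
    counts <- c(0L, 0L, 0L)
    unresolved <- 0L
    missing <- 0L
    for (r in seq_len(nrow(idx))) {
      a <- parts[[1]][idx[r, 1]]; b <- parts[[2]][idx[r, 2]]
      c_ <- parts[[3]][idx[r, 3]]; dd <- parts[[4]][idx[r, 4]]
      for (d in dists) {
        if (!all(c(a, b, c_, dd) %in% rownames(d))) { missing <- missing + 1L; next }
        cl <- .classify_quartet(d, a, b, c_, dd)
        if (cl == 0L) unresolved <- unresolved + 1L
        else counts[cl] <- counts[cl] + 1L
      }
    }
    resolved <- sum(counts)
    q <- if (resolved > 0L) counts / resolved else rep(NA_real_, 3L)
    rows[[qi]] <- data.frame(edge_u = quads[[qi]]$edge[1],
                             edge_v = quads[[qi]]$edge[2],
                             q1 = q[1], q2 = q[2], q3 = q[3],
                             n_quartets = nrow(idx),
                             sampled = nrow(idx) * length(gene_trees),
                             resolved = resolved, unresolved = unresolved,
                             missing = missing,
                             undefined = resolved == 0L)
  }
  edges <- do.call(rbind, rows)
  tr <- ape::collapse.singles(species_tree)
  if (ape::is.rooted(tr)) tr <- ape::unroot(tr)
  ntip <- length(tr$tip.label)
  lab <- rep("", tr$Nnode)
  for (qi in seq_along(quads)) {
    v <- quads[[qi]]$edge[2] - ntip
    lab[v] <- sprintf("q1=%.3f|q2=%.3f|q3=%.3f",
                      edges$q1[qi], edges$q2[qi], edges$q3[qi])
  }
  tr$node.label <- lab
  structure(list(edges = edges, quadripartitions = quads, tree = tr),
            class = "edge_quartet_support")
}

#' @export
print.edge_quartet_support <- function(x, ...) {
  cat(sprintf("<edge_quartet_support> %d internal edges, mean q1 = %.3f\n",
              nrow(x$edges), mean(x$edges$q1, na.rm = TRUE)))
  invisible(x)
}
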