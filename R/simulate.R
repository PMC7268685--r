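# Seeded generators for every input class the pipeline consumes, with the
# statistical structure the diagnostics are designed to detect: partitioned
# alignments with gamma rate variation, lineage-specific compositional
# shifts (SRH violations), non-random taxon x partition occupancy, gene
# trees with NNI discordance, and discrete characters evolved under Mk.
# All randomness derives from a master seed via named substreams.

#' Simulate a Yule species tree scaled to a target height
#'
#' Pure-birth topology with exponential waiting times (via `ape::rphylo`),
#' rescaled so the root-to-tip depth equals `height` (substitutions/site for
#' sequence simulation; arbitrary time units for chronograms).
#'
#' @param n_taxa number of tips (>= 2); @param birth birth rate;
#' @param height target tree height (default 1); @param seed integer seed.
#' @return an `ape::phylo` with tip labels `t1..tn`.
#' @export
simulate_tree <- function(n_taxa, birth = 1, height = 1, seed = 1L) {
  stopifnot(n_taxa >= 2L)
  tr <- with_seed(seed, ape::rphylo(n_taxa, birth = birth, death = 0))
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * (height / depth)
  tr
}

#' Simulate a partitioned alignment on a tree
#'
#' Sites evolve independently under the model's discrete-gamma rate mixture.
#' A compositional shift (the simplest violation of the stationarity/
#' homogeneity assumptions that symmetry tests screen for) replaces the
#' transition matrices on the terminal branches of `shift$taxa` by those of
#' a model with equilibrium frequencies pulled toward `shift$freqs` with
#' mixing weight `shift$weight`. An occupancy mask (per taxon x partition
#' retention probabilities, plus optional per-site dropout) then overwrites
#' masked cells with the missing symbol, emulating non-random data coverage.
#'
#' @param tree `ape::phylo` with branch lengths in substitutions/site.
#' @param partition_lengths named integer vector of partition lengths.
#' @param model a [subst_model()]; default poisson+G4(alpha = 1), uniform
#'   frequencies.
#' @param shift `NULL` or `list(taxa =, freqs =, weight = 1)`; applies to
#'   the listed taxa's terminal branches, optionally per-partition via
#'   `partitions` (names) inside the list.
#' @param occupancy retention probability: scalar, or taxa x partitions
#'   matrix; cells are retained independently (default 1 = complete data).
#' @param site_dropout additional per-cell dropout probability (default 0).
#' @param missing_symbol symbol written into masked cells (default `"-"`).
#' @param seed integer seed.
#' @return a [phylo_alignment()] with the partition scheme attached.
#' @export
simulate_alignment <- function(tree, partition_lengths, model = NULL,
                               shift = NULL, occupancy = 1, site_dropout = 0,
                               missing_symbol = "-", seed = 1L) {
  if (is.null(model)) model <- subst_model("AA", shape = 1, ncat = 4L)
  if (is.null(names(partition_lengths)))
    names(partition_lengths) <- sprintf("p%d", seq_along(partition_lengths))
  taxa <- tree$tip.label
  ntaxa <- length(taxa)
  shift_model <- NULL
  shift_edges <- integer(0)
  po <- .postorder_edges(tree)
  if (!is.null(shift)) {
    w <- shift$weight %||% 1
    pi_eff <- (1 - w) * model$pi + w * (shift$freqs / sum(shift$freqs))
    exch <- matrix(1, model$k, model$k); diag(exch) <- 0
    shift_model <- subst_model(model$alphabet, exch, pi_eff, model$shape,
                               model$ncat, name = "shifted")
    tip_ids <- match(shift$taxa, po$tip.label)
    if (anyNA(tip_ids))
      stop_phylocong("shift taxa not in tree", "phylocong_unknown_taxon_error")
    shift_edges <- which(po$edge[, 2] %in% tip_ids)
  }
  if (is.matrix(occupancy)) {
    stopifnot(nrow(occupancy) == ntaxa,
              ncol(occupancy) == length(partition_lengths))
  } else {
    occupancy <- matrix(occupancy, ntaxa, length(partition_lengths))
  }
  mats <- vector("list", length(partition_lengths))
  for (p in seq_along(partition_lengths)) {
    L <- partition_lengths[p]
    pseed <- substream_seed(seed, paste0("partition-", names(partition_lengths)[p]))
    mats[[p]] <- with_seed(pseed, {
      cat_of_site <- sample.int(length(model$rates), L, replace = TRUE)
      states <- matrix(0L, po$nnode_total, L)
      root <- po$edge[nrow(po$edge), 1]
      states[root, ] <- sample.int(model$k, L, replace = TRUE, prob = model$pi)
      shifted_here <- is.null(shift$partitions) ||
        names(partition_lengths)[p] %in% shift$partitions
      for (e in rev(seq_len(nrow(po$edge)))) {  # preorder
        m_e <- if (length(shift_edges) && shifted_here && e %in% shift_edges)
          shift_model else model
        for (cc in seq_along(model$rates)) {
          js <- which(cat_of_site == cc)
          if (!length(js)) next
          P <- transition_matrix(m_e, po$len[e], model$rates[cc])
          ps <- states[po$edge[e, 1], js]
          cs <- integer(length(js))
          for (s in unique(ps)) {
            i <- which(ps == s)
            cs[i] <- sample.int(model$k, length(i), replace = TRUE, prob = P[s, ])
          }
          states[po$edge[e, 2], js] <- cs
        }
      }
      sym <- matrix(model$states[states[seq_len(po$ntip), , drop = FALSE]],
                    po$ntip, L, dimnames = list(po$tip.label, NULL))
      keep_taxon <- runif(po$ntip) <= occupancy[match(po$tip.label, taxa), p]
      sym[!keep_taxon, ] <- missing_symbol
      if (site_dropout > 0) {
        drop <- matrix(runif(length(sym)) < site_dropout, nrow(sym), ncol(sym))
        sym[drop] <- missing_symbol
      }
      sym[taxa, , drop = FALSE]
    })
  }
  mat <- do.call(cbind, mats)
  ends <- cumsum(partition_lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  scheme <- partition_scheme(lapply(seq_along(partition_lengths), function(p)
    list(name = names(partition_lengths)[p], ranges = cbind(starts[p], ends[p]))))
  phylo_alignment(mat, model$alphabet, partitions = scheme)
}

#' Simulate gene trees with NNI discordance around a species tree
#'
#' Each gene tree equals the species tree with probability `1 - eps` and is
#' otherwise replaced by a random nearest-neighbour-interchange neighbour
#' (one NNI move). A deliberately simple discordance generator: sufficient
#' to exercise quartet scoring, without multispecies-coalescent machinery.
#'
#' @param species_tree `ape::phylo`; @param eps replacement probability;
#' @param n number of gene trees; @param seed integer seed.
#' @return `ape::multiPhylo` with attribute `replaced` (logical vector).
#' @export
simulate_gene_trees <- function(species_tree, eps, n, seed = 1L) {
  stopifnot(eps >= 0, eps <= 1)
  with_seed(seed, {
    replaced <- runif(n) < eps
    trees <- lapply(seq_len(n), function(i) {
      if (replaced[i]) phangorn::rNNI(species_tree, 1L) else species_tree
    })
    class(trees) <- "multiPhylo"
    attr(trees, "replaced") <- replaced
    trees
  })
}

#' Simulate discrete characters under an Mk model on a fixed tree
#'
#' Characters evolve independently: the root state is drawn from the model's
#' root prior and states propagate down the tree through the transition
#' probabilities of each branch.
#'
#' @param tree `ape::phylo` with branch lengths; @param model an
#'   [mk_model()]; @param n number of characters; @param seed integer seed.
#' @return a [character_matrix()] over the tips; the full node-state matrix
#'   is attached as attribute `node_states` for verification.
#' @export
simulate_characters <- function(tree, model, n, seed = 1L) {
  po <- .postorder_edges(tree)
  with_seed(seed, {
    states <- matrix(0L, po$nnode_total, n)
    root <- po$edge[nrow(po$edge), 1]
    states[root, ] <- sample.int(model$k, n, replace = TRUE, prob = model$pi)
    Ps <- lapply(seq_along(po$len), function(e) transition_matrix(model, po$len[e]))
    for (e in rev(seq_len(nrow(po$edge)))) {
      ps <- states[po$edge[e, 1], ]
      cs <- integer(n)
      for (s in unique(ps)) {
        i <- which(ps == s)
        cs[i] <- sample.int(model$k, length(i), replace = TRUE, prob = Ps[[e]][s, ])
      }
      states[po$edge[e, 2], ] <- cs
    }
    mat <- matrix(model$states[states[seq_len(po$ntip), , drop = FALSE]],
                  po$ntip, n,
                  dimnames = list(po$tip.label, sprintf("char%d", seq_len(n))))
    cm <- character_matrix(mat, states = rep(list(model$states), n))
    attr(cm, "node_states") <- states
    cm
  })
}

#' Derive a four-group taxon assignment from an internal species-tree split
#'
#' Picks the quadripartition around an internal edge (by default the one
#' maximising the smallest part, i.e. the most balanced split) and uses its
#' four parts as likelihood-mapping groups, so the generating topology for
#' every sampled quartet is arrangement 1.
#'
#' @param tree `ape::phylo`; @param aln alignment supplying the taxon
#'   universe; @param edge index into [quadripartitions()] order, or `NULL`
#'   for the most balanced; @param label hypothesis label.
#' @return a [taxon_grouping()].
#' @export
groups_from_split <- function(tree, aln, edge = NULL, label = "true-split") {
  quads <- quadripartitions(tree)
  if (length(quads) == 0L)
    stop_phylocong("tree has no internal edges", "phylocong_argument_error")
  if (is.null(edge))
    edge <- which.max(vapply(quads, function(q) min(lengths(q$parts)), 0L))
  parts <- quads[[edge]]$parts
  names(parts) <- paste0("g", 1:4)
  taxon_grouping(parts, aln, label = label)
}

#' Fix the length of one internal branch defining a quadripartition
#'
#' Selects an internal edge of the (unrooted) tree -- by default the most
#' balanced quadripartition -- and sets its branch length, returning the
#' modified tree together with the four parts. Used to construct simulation
#' conditions where one split carries a known amount of signal.
#'
#' @param tree `ape::phylo`; @param edge index into [quadripartitions()]
#'   order, `NULL` for the most balanced; @param internal_length new length
#'   of that edge (substitutions/site).
#' @return list: `tree` (unrooted, modified), `edge`, `parts`.
#' @export
strengthen_split <- function(tree, edge = NULL, internal_length = 0.3) {
  tr <- ape::collapse.singles(tree)
  if (ape::is.rooted(tr)) tr <- ape::unroot(tr)
  quads <- quadripartitions(tr)
  if (length(quads) == 0L)
    stop_phylocong("tree has no internal edges", "phylocong_argument_error")
  if (is.null(edge))
    edge <- which.max(vapply(quads, function(q) min(lengths(q$parts)), 0L))
  uv <- quads[[edge]]$edge
  row <- which(tr$edge[, 1] == uv[1] & tr$edge[, 2] == uv[2])
  tr$edge.length[row] <- internal_length
  list(tree = tr, edge = edge, parts = quads[[edge]]$parts)
}
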