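# shared pruning-likelihood machinery used by FcLM and the Mk engine

# compress alignment columns to unique site patterns
pattern_compress <- function(codes) {
  key <- apply(codes, 2L, paste, collapse = ",")
  u <- !duplicated(key)
  idx <- match(key, key[u])
  list(pat = codes[, u, drop = FALSE],
       w = as.numeric(tabulate(idx, nbins = sum(u))),
       map = idx)
}

# postorder edge matrix + lengths; validates ape postorder contiguity
.postorder_edges <- function(tree) {
  if (is.null(tree$edge.length))
    stop_phylocong("tree must have branch lengths", "phylocong_branch_error")
  tr <- ape::reorder.phylo(tree, "postorder")
  list(edge = tr$edge, len = tr$edge.length, ntip = length(tr$tip.label),
       nnode_total = length(tr$tip.label) + tr$Nnode, tip.label = tr$tip.label)
}

# P cube with slice layout (edge - 1) * ncat + cat, matching prune_loglik_cpp
.build_P_cube <- function(model, lens, rates) {
  k <- model$k
  ncat <- length(rates)
  P <- array(0, dim = c(k, k, length(lens) * ncat))
  for (e in seq_along(lens)) for (c in seq_len(ncat))
    P[, , (e - 1L) * ncat + c] <- transition_matrix(model, lens[e], rates[c])
  P
}

#' Phylogenetic log-likelihood by Felsenstein pruning
#'
#' Computes the log-likelihood of an alignment (or encoded state matrix) on a
#' fixed tree under a substitution or Mk model, with per-node rescaling,
#' discrete-gamma rate mixing, and missing states entering as uninformative
#' (all-ones) partial likelihoods. The root is weighted by the model's
#' equilibrium/prior frequencies; for a reversible model the value is
#' independent of root placement.
#'
#' @param tree `ape::phylo` with branch lengths; leaves must be a subset of
#'   the alignment's taxa.
#' @param aln a `phylo_aln`, or an integer state matrix (taxa x sites,
#'   values 1..k, 0 = missing) with rownames.
#' @param model a [subst_model()] or [mk_model()].
#' @return list of class `likelihood_result`: `loglik`, `site_loglik`,
#'   `n_patterns`.
#' @export
pruning_loglik <- function(tree, aln, model) {
  codes <- if (inherits(aln, "phylo_aln")) encode_states(aln) else aln
  stopifnot(is.matrix(codes))
  missing_tips <- setdiff(tree$tip.label, rownames(codes))
  if (length(missing_tips))
    stop_phylocong(sprintf("leaf without sequence: %s",
                           paste(missing_tips, collapse = ", ")),
                   "phylocong_unknown_taxon_error")
  po <- .postorder_edges(tree)
  tipdata <- codes[po$tip.label, , drop = FALSE]
  pc <- pattern_compress(tipdata)
  P <- .build_P_cube(model, po$len, model$rates)
  patll <- prune_loglik_cpp(po$edge, P, pc$pat, model$pi,
                            rep(1 / length(model$rates), length(model$rates)),
                            po$ntip, po$nnode_total)
  site_ll <- patll[pc$map]
  structure(list(loglik = sum(pc$w * patll), site_loglik = site_ll,
                 n_patterns = length(pc$w)),
            class = "likelihood_result")
}

#' @export
print.likelihood_result <- function(x, ...) {
  cat(sprintf("logL = %.6f over %d sites (%d patterns)\n",
              x$loglik, length(x$site_loglik), x$n_patterns))
  invisible(x)
}

# fast path used by the quartet optimizer: pattern data already prepared;
# reversible models go through the spectral kernel (P built in C++)
.loglik_patterns <- function(po, pat, w, model, lens) {
  catw <- rep(1 / length(model$rates), length(model$rates))
  patll <- if (!is.null(model$eig)) {
    prune_loglik_eig_cpp(po$edge, model$eig$V, model$eig$W, model$eig$lambda,
                         lens, model$rates, pat, model$pi, catw,
                         po$ntip, po$nnode_total)
  } else {
    P <- .build_P_cube(model, lens, model$rates)
    prune_loglik_cpp(po$edge, P, pat, model$pi, catw, po$ntip, po$nnode_total)
  }
  sum(w * patll)
}
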