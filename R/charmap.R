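# Ancestral reconstruction of discrete characters on a fixed tree:
# Sankoff parsimony with an apomorphy list, Mk maximum likelihood with
# model selection, exact marginal reconstruction, and stochastic character
# mapping (sampled histories conditioned on the tips).

.char_vector <- function(x, char = 1L) {
  if (inherits(x, "char_matrix")) setNames(x$mat[, char], x$taxa) else x
}

#' Sankoff (generalised) parsimony for one discrete character
#'
#' Dynamic programming over per-node cost vectors under an arbitrary
#' state-change cost matrix (unit costs by default, where the minimum total
#' cost is the parsimony change count). Missing tips allow every state.
#' Node state sets contain the states attained in at least one
#' most-parsimonious reconstruction (computed by an inside-outside pass);
#' a branch carries an unambiguous change iff both endpoint sets are
#' singletons and differ, so every reconstruction implies that same change.
#'
#' @param tree `ape::phylo` (branch lengths ignored).
#' @param states named character vector of tip states (`NA` = missing), or a
#'   `char_matrix` together with `char`.
#' @param char character id/index when `states` is a `char_matrix`.
#' @param state_list ordered state labels; default sorted observed states.
#' @param cost k x k cost matrix (default unit off-diagonal).
#' @return list of class `parsimony_result`: `score`, `node_sets` (list over
#'   ape node ids), `changes` (data.frame of unambiguous branch changes),
#'   `state_list`.
#' @export
sankoff <- function(tree, states, char = 1L, state_list = NULL, cost = NULL) {
  states <- .char_vector(states, char)
  miss <- setdiff(tree$tip.label, names(states))
  if (length(miss))
    stop_phylocong(sprintf("tip(s) without character data: %s",
                           paste(miss, collapse = ", ")),
                   "phylocong_unknown_taxon_error")
  obs <- states[tree$tip.label]
  if (is.null(state_list)) state_list <- sort(unique(obs[!is.na(obs)]))
  bad <- setdiff(unique(obs[!is.na(obs)]), state_list)
  if (length(bad))
    stop_phylocong(sprintf("tip state(s) outside the state list: %s",
                           paste(bad, collapse = ", ")), "phylocong_state_error")
  k <- length(state_list)
  if (is.null(cost)) { cost <- matrix(1, k, k); diag(cost) <- 0 }
  stopifnot(nrow(cost) == k, ncol(cost) == k)

  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nn <- ntip + tr$Nnode
  root <- tr$edge[nrow(tr$edge), 1]
  S <- matrix(0, nn, k)  # inside (below-node) costs
  for (i in seq_len(ntip)) {
    s <- obs[tr$tip.label[i]]
    if (!is.na(s)) S[i, ] <- ifelse(state_list == s, 0, Inf)
  }
  children <- vector("list", nn)
  for (e in seq_len(nrow(tr$edge)))
    children[[tr$edge[e, 1]]] <- c(children[[tr$edge[e, 1]]], tr$edge[e, 2])
  # M[v, s]: cost of v's subtree given parent state s (edge change included)
  M <- matrix(0, nn, k)
  for (e in seq_len(nrow(tr$edge))) {
    ch <- tr$edge[e, 2]
    M[ch, ] <- apply(cost + rep(S[ch, ], each = k), 1L, min)
    S[tr$edge[e, 1], ] <- S[tr$edge[e, 1], ] + M[ch, ]
  }
  score <- min(S[root, ])
  # outside costs
  U <- matrix(Inf, nn, k)
  U[root, ] <- 0
  for (e in rev(seq_len(nrow(tr$edge)))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    sib <- setdiff(children[[p]], ch)
    # above[s]: best cost of everything outside ch's subtree with p in state s
    above <- U[p, ] + if (length(sib)) colSums(M[sib, , drop = FALSE]) else 0
    U[ch, ] <- apply(cost + above, 2L, min)
  }
  total <- S + U
  node_sets <- lapply(seq_len(nn), function(v)
    state_list[abs(total[v, ] - score) < 1e-9])
  changes <- list()
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    sp <- node_sets[[p]]; sc <- node_sets[[ch]]
    if (length(sp) == 1L && length(sc) == 1L && sp != sc)
      changes[[length(changes) + 1L]] <-
        data.frame(parent = p, child = ch,
                   child_label = if (ch <= ntip) tr$tip.label[ch] else NA_character_,
                   from = sp, to = sc)
  }
  changes <- if (length(changes)) do.call(rbind, changes) else
    data.frame(parent = integer(0), child = integer(0),
               child_label = character(0), from = character(0), to = character(0))
  structure(list(score = score, node_sets = node_sets, changes = changes,
                 state_list = state_list, tree = tr),
            class = "parsimony_result")
}

#' @export
print.parsimony_result <- function(x, ...) {
  cat(sprintf("Sankoff: %g change(s), %d unambiguous branch change(s)\n",
              x$score, nrow(x$changes)))
  invisible(x)
}

#' Sankoff parsimony over every character of a matrix
#'
#' @param tree `ape::phylo`; @param cm a `char_matrix`;
#' @param cost optional shared cost matrix (unit default, per-character size).
#' @return list: `per_character` (list of [sankoff()] results), `scores`,
#'   `total_score`, `apomorphies` (row-bound change lists with a `character`
#'   column).
#' @export
sankoff_matrix <- function(tree, cm, cost = NULL) {
  stopifnot(inherits(cm, "char_matrix"))
  res <- lapply(cm$characters, function(ch)
    sankoff(tree, cm, char = ch, state_list = cm$states[[ch]], cost = cost))
  names(res) <- cm$characters
  apo <- do.call(rbind, lapply(cm$characters, function(ch) {
    d <- res[[ch]]$changes
    if (nrow(d)) cbind(character = ch, d) else NULL
  }))
  scores <- vapply(res, `[[`, 0, "score")
  list(per_character = res, scores = scores, total_score = sum(scores),
       apomorphies = apo)
}

# integer tip-state matrix (0 = missing) from a char_matrix or vector
.encode_chars <- function(tree, x, state_list = NULL) {
  if (inherits(x, "char_matrix")) {
    mat <- x$mat[tree$tip.label, , drop = FALSE]
  } else {
    mat <- matrix(x[tree$tip.label], ncol = 1L,
                  dimnames = list(tree$tip.label, "char1"))
  }
  if (is.null(state_list))
    state_list <- sort(unique(as.vector(mat[!is.na(mat)])))
  codes <- matrix(match(mat, state_list), nrow(mat), ncol(mat),
                  dimnames = dimnames(mat))
  if (any(is.na(codes) & !is.na(mat)))
    stop_phylocong("tip state outside the state list", "phylocong_state_error")
  codes[is.na(codes)] <- 0L
  list(codes = codes, state_list = state_list)
}

#' Fit an Mk model of discrete character evolution by maximum likelihood
#'
#' Maximizes the pruning likelihood over the rate parameters (in log-space,
#' bounded quasi-Newton) on a fixed tree with branch lengths; the rate
#' absorbs the branch-length scale, so chronogram (time) units are fine.
#' Multiple characters are treated as independent replicates sharing one
#' rate matrix. Reports AIC and AICc (sample size = number of characters).
#' If all tips share one state the likelihood is monotone in the rate and
#' the MLE sits at the lower bound; this is flagged.
#'
#' @param tree `ape::phylo` with branch lengths > 0.
#' @param x a `char_matrix` or named tip-state vector.
#' @param structure `"ER"`, `"SYM"` or `"ARD"`.
#' @param state_list optional shared state list.
#' @param root_prior prior on the root state (default uniform).
#' @param start optional start values for the rates.
#' @return an [mk_model()] with `logL`, `AIC`, `AICc`, `at_bound`,
#'   `convergence` filled in.
#' @export
mk_fit <- function(tree, x, structure = c("ER", "SYM", "ARD"),
                   state_list = NULL, root_prior = NULL, start = NULL) {
  structure <- match.arg(structure)
  enc <- .encode_chars(tree, x, state_list)
  k <- length(enc$state_list)
  if (k < 2L)
    stop_phylocong("need at least 2 states to fit an Mk model",
                   "phylocong_state_error")
  np <- switch(structure, ER = 1L, SYM = k * (k - 1L) / 2L, ARD = k * (k - 1L))
  if (is.null(start)) {
    # parsimony-informed initial rate: changes per unit total branch length
    tot_changes <- sum(vapply(seq_len(ncol(enc$codes)), function(j) {
      v <- enc$state_list[enc$codes[, j]]
      v <- setNames(ifelse(enc$codes[, j] == 0L, NA, v), rownames(enc$codes))
      sankoff(tree, v, state_list = enc$state_list)$score
    }, 0))
    r0 <- max(tot_changes / (sum(tree$edge.length) * ncol(enc$codes)), 1e-3)
    start <- rep(r0, np)
  }
  lower <- log(1e-8); upper <- log(1e3)
  nll <- function(logr) {
    m <- mk_model(enc$state_list, structure, exp(logr), root_prior)
    -pruning_loglik(tree, enc$codes, m)$loglik
  }
  opt <- optim(pmin(pmax(log(start), lower), upper), nll, method = "L-BFGS-B",
               lower = lower, upper = upper, control = list(maxit = 500L))
  fit <- mk_model(enc$state_list, structure, exp(opt$par), root_prior)
  n <- ncol(enc$codes)
  fit$logL <- -opt$value
  fit$AIC <- 2 * np + 2 * opt$value
  fit$AICc <- fit$AIC + if (n - np - 1 > 0) 2 * np * (np + 1) / (n - np - 1) else Inf
  fit$at_bound <- any(opt$par <= lower + 1e-6)
  fit$convergence <- opt$convergence
  fit$n_characters <- n
  fit
}

#' Compare ER, SYM and ARD fits of an Mk model
#'
#' Fits the nested structures with warm starts (SYM starts at the ER
#' optimum, ARD at the SYM optimum), guaranteeing the likelihood ordering
#' ER <= SYM <= ARD, and tabulates logL, AIC and AICc.
#'
#' @inheritParams mk_fit
#' @return list: `fits` (named list of models), `table` (data.frame),
#'   `best_aic`, `best_aicc` (structure names).
#' @export
mk_model_select <- function(tree, x, state_list = NULL, root_prior = NULL) {
  enc <- .encode_chars(tree, x, state_list)
  k <- length(enc$state_list)
  er <- mk_fit(tree, x, "ER", enc$state_list, root_prior)
  sym <- mk_fit(tree, x, "SYM", enc$state_list, root_prior,
                start = rep(er$Q[1, 2], k * (k - 1L) / 2L))
  ard_start <- t(sym$Q)[t(row(sym$Q) != col(sym$Q))]  # row-major off-diagonals
  ard <- mk_fit(tree, x, "ARD", enc$state_list, root_prior,
                start = pmax(ard_start, 1e-8))
  fits <- list(ER = er, SYM = sym, ARD = ard)
  tab <- data.frame(structure = names(fits),
                    n_params = vapply(fits, `[[`, 0L, "n_params"),
                    logL = vapply(fits, `[[`, 0, "logL"),
                    AIC = vapply(fits, `[[`, 0, "AIC"),
                    AICc = vapply(fits, `[[`, 0, "AICc"))
  list(fits = fits, table = tab,
       best_aic = tab$structure[which.min(tab$AIC)],
       best_aicc = tab$structure[which.min(tab$AICc)])
}

# inside (below-node) partials, normalized per node; returns list(D, po)
.down_partials <- function(tree, codes_vec, model) {
  po <- .postorder_edges(tree)
  k <- model$k
  nn <- po$nnode_total
  D <- matrix(1, nn, k)
  for (i in seq_len(po$ntip)) {
    s <- codes_vec[po$tip.label[i]]
    if (s != 0L) D[i, ] <- ifelse(seq_len(k) == s, 1, 0)
  }
  Ps <- lapply(seq_along(po$len), function(e) transition_matrix(model, po$len[e]))
  for (e in seq_along(po$len)) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    contrib <- as.vector(Ps[[e]] %*% D[ch, ])
    D[p, ] <- D[p, ] * contrib
    m <- max(D[p, ])
    if (m > 0) D[p, ] <- D[p, ] / m
  }
  list(D = D, po = po, Ps = Ps)
}

#' Exact marginal ancestral state probabilities under an Mk model
#'
#' Standard inside-outside computation: for every node, the posterior
#' probability of each state given all tip data and the model (root prior
#' included). Serves as the exact reference that stochastic character
#' mapping converges to.
#'
#' @param tree `ape::phylo` with branch lengths.
#' @param states named tip-state vector (or `char_matrix` + `char`).
#' @param model a fitted or constructed [mk_model()].
#' @param char character id when `states` is a `char_matrix`.
#' @return matrix (nodes x states; ape node ids as rows) of posterior
#'   probabilities.
#' @export
marginal_ancestral <- function(tree, states, model, char = 1L) {
  states <- .char_vector(states, char)
  enc <- .encode_chars(tree, states, model$states)
  dp <- .down_partials(tree, enc$codes[, 1L], model)
  po <- dp$po; D <- dp$D; Ps <- dp$Ps
  nn <- po$nnode_total
  k <- model$k
  root <- po$edge[nrow(po$edge), 1]
  U <- matrix(0, nn, k)
  U[root, ] <- model$pi
  edge_of_child <- integer(nn)
  edge_of_child[po$edge[, 2]] <- seq_len(nrow(po$edge))
  children <- vector("list", nn)
  for (e in seq_len(nrow(po$edge)))
    children[[po$edge[e, 1]]] <- c(children[[po$edge[e, 1]]], po$edge[e, 2])
  for (e in rev(seq_len(nrow(po$edge)))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    sib <- setdiff(children[[p]], ch)
    above <- U[p, ]
    for (b in sib)
      above <- above * as.vector(Ps[[edge_of_child[b]]] %*% D[b, ])
    U[ch, ] <- as.vector(above %*% Ps[[e]])
    m <- max(U[ch, ])
    if (m > 0) U[ch, ] <- U[ch, ] / m
  }
  post <- U * D
  post <- post / rowSums(post)
  rownames(post) <- seq_len(nn)
  colnames(post) <- model$states
  post
}

#' Stochastic character mapping: sampled histories conditioned on the tips
#'
#' Samples `n_histories` full character histories under an Mk model: node
#' states are drawn jointly (root from its posterior, then pre-order
#' conditional sampling), and each branch's substitution path is drawn
#' conditioned on its endpoints by rejection sampling (forward simulation,
#' per-branch attempt cap) with a uniformization fallback. Node-state
#' frequencies across histories estimate the marginal ancestral posteriors;
#' transition counts and dwell times summarise the inferred history of
#' change.
#'
#' @param tree `ape::phylo` with branch lengths.
#' @param states named tip-state vector (or `char_matrix` + `char`).
#' @param model a fitted [mk_model()].
#' @param n_histories number of sampled histories (default 10000, the
#'   published protocol's count).
#' @param seed integer seed; identical seeds give identical summaries.
#' @param char character id when `states` is a `char_matrix`.
#' @param reject_cap forward-simulation attempts per branch before the
#'   uniformization fallback (default 1000).
#' @return list of class `scm_result`: `n_histories`, `node_freq`
#'   (nodes x states), `trans_expected` (k x k expected counts per history),
#'   `trans_per_branch` (edge-indexed list), `dwell_expected`,
#'   `jumps_per_history`, `n_fallbacks`, `seed`.
#' @export
scm_sample <- function(tree, states, model, n_histories = 10000L, seed = 1L,
                       char = 1L, reject_cap = 1000L) {
  states <- .char_vector(states, char)
  enc <- .encode_chars(tree, states, model$states)
  dp <- .down_partials(tree, enc$codes[, 1L], model)
  po <- dp$po; D <- dp$D; Ps <- dp$Ps
  k <- model$k
  nn <- po$nnode_total
  root <- po$edge[nrow(po$edge), 1]
  n <- as.integer(n_histories)
  node_states <- matrix(0L, nn, n)
  trans_sum <- matrix(0, k, k, dimnames = list(model$states, model$states))
  dwell_sum <- setNames(numeric(k), model$states)
  jumps <- integer(n)
  per_branch <- vector("list", nrow(po$edge))
  fallbacks <- 0L
  with_seed(seed, {
    pr <- model$pi * D[root, ]
    node_states[root, ] <- sample.int(k, n, replace = TRUE, prob = pr / sum(pr))
    for (e in rev(seq_len(nrow(po$edge)))) {  # reverse postorder = preorder
      p <- po$edge[e, 1]; ch <- po$edge[e, 2]
      ps <- node_states[p, ]
      cs <- integer(n)
      for (s in seq_len(k)) {
        i <- which(ps == s)
        if (!length(i)) next
        w <- Ps[[e]][s, ] * D[ch, ]
        cs[i] <- sample.int(k, length(i), replace = TRUE, prob = w / sum(w))
      }
      node_states[ch, ] <- cs
    }
    for (e in seq_len(nrow(po$edge))) {
      bp <- branch_paths_cpp(model$Q, node_states[po$edge[e, 1], ],
                             node_states[po$edge[e, 2], ], po$len[e],
                             as.integer(reject_cap))
      trans_sum <- trans_sum + bp$trans
      dwell_sum <- dwell_sum + as.vector(bp$dwell)
      jumps <- jumps + as.integer(bp$jumps)
      fallbacks <- fallbacks + bp$fallbacks
      per_branch[[e]] <- bp$trans / n
    }
  })
  node_freq <- t(apply(node_states, 1L, tabulate, nbins = k)) / n
  dimnames(node_freq) <- list(seq_len(nn), model$states)
  structure(list(n_histories = n, node_freq = node_freq,
                 trans_expected = trans_sum / n,
                 trans_per_branch = per_branch,
                 dwell_expected = dwell_sum / n,
                 jumps_per_history = jumps, n_fallbacks = fallbacks,
                 seed = seed, edge = po$edge, tip_label = po$tip.label),
            class = "scm_result")
}

#' @export
print.scm_result <- function(x, ...) {
  cat(sprintf("<scm_result> %d histories, E[transitions] = %.3f, fallbacks = %d\n",
              x$n_histories, sum(x$trans_expected), x$n_fallbacks))
  invisible(x)
}
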