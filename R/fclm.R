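# Four-cluster likelihood mapping: evaluate sampled quartets (one taxon per
# group) under the three unrooted quartet topologies, map softmax support to
# the 2-simplex and assign one of seven regions.

# fixed rooted shape for a quartet (A,B | C,D): tips 1..4 = A,B,C,D,
# root = 5, internal = 6; postorder edge list with branch order
# (t3, t4, t1, t2, t5) where t5 is the internal branch
.quartet_po <- local({
  edge <- matrix(c(6L, 3L, 6L, 4L, 5L, 1L, 5L, 2L, 5L, 6L),
                 ncol = 2L, byrow = TRUE)
  list(edge = edge, ntip = 4L, nnode_total = 6L)
})

# tip permutations mapping (g1,g2,g3,g4) onto (A,B,C,D) for the topologies
# T1 = (g1,g2|g3,g4), T2 = (g1,g3|g2,g4), T3 = (g1,g4|g2,g3)
.topo_perms <- list(c(1L, 2L, 3L, 4L), c(1L, 3L, 2L, 4L), c(1L, 4L, 2L, 3L))

#' Enumerate or sample quartets from a four-group taxon assignment
#'
#' The full Cartesian product (one taxon per group) when it has at most
#' `cap` elements, otherwise a seeded uniform sample of `cap` distinct
#' quartets.
#'
#' @param grouping a [taxon_grouping()].
#' @param cap maximum number of quartets (default 20000).
#' @param seed integer seed for the subsample.
#' @return character matrix (n x 4), columns ordered by group.
#' @export
enumerate_quartets <- function(grouping, cap = 20000L, seed = 1L) {
  sizes <- lengths(grouping$groups)
  idx <- sample_product(sizes, cap, seed)
  out <- matrix("", nrow(idx), 4L)
  for (g in 1:4) out[, g] <- grouping$groups[[g]][idx[, g]]
  colnames(out) <- names(grouping$groups)
  out
}

# index tuples from a product space, full enumeration or seeded uniform
# sample without replacement
sample_product <- function(sizes, cap, seed) {
  N <- prod(as.numeric(sizes))
  dec <- function(v) {  # decode 0-based linear index, first factor fastest
    out <- matrix(0L, length(v), length(sizes))
    for (g in seq_along(sizes)) {
      out[, g] <- as.integer(v %% sizes[g]) + 1L
      v <- v %/% sizes[g]
    }
    out
  }
  if (N <= cap) return(dec(seq_len(N) - 1))
  with_seed(seed, {
    if (N < 2^31) {
      dec(sample.int(as.integer(N), cap) - 1)
    } else {  # rejection sampling of distinct tuples
      seen <- new.env(hash = TRUE)
      picks <- numeric(0)
      while (length(picks) < cap) {
        v <- floor(runif(cap, 0, N))
        for (x in v) {
          kx <- sprintf("%.0f", x)
          if (is.null(seen[[kx]])) { seen[[kx]] <- TRUE; picks <- c(picks, x) }
          if (length(picks) == cap) break
        }
      }
      dec(picks)
    }
  })
}

#' Assign a support vector to one of the seven likelihood-mapping regions
#'
#' Nearest-prototype rule on the 2-simplex: corners (1,0,0), (0,1,0),
#' (0,0,1) map to `C1`, `C2`, `C3`; edge midpoints to `E12`, `E13`, `E23`;
#' the barycentre to `CTR`. Ties break in the order C1, C2, C3, E12, E13,
#' E23, CTR. Headline "% of quartets supporting topology i" counts corners
#' only.
#'
#' @param p1,p2,p3 topology weights; must sum to 1 within `1e-6`.
#' @return one of `"C1","C2","C3","E12","E13","E23","CTR"`.
#' @export
assign_region <- function(p1, p2, p3) {
  p <- c(p1, p2, p3)
  if (abs(sum(p) - 1) > 1e-6)
    stop_phylocong("weights must lie on the simplex", "phylocong_argument_error")
  proto <- rbind(C1 = c(1, 0, 0), C2 = c(0, 1, 0), C3 = c(0, 0, 1),
                 E12 = c(.5, .5, 0), E13 = c(.5, 0, .5), E23 = c(0, .5, .5),
                 CTR = c(1, 1, 1) / 3)
  d <- rowSums(sweep(proto, 2L, p)^2)
  rownames(proto)[which.min(d)]  # which.min takes the first => stated tie order
}

REGIONS <- c("C1", "C2", "C3", "E12", "E13", "E23", "CTR")

#' Evaluate one quartet under the three unrooted topologies
#'
#' Sites are restricted to columns where all four taxa are non-missing
#' (per-quartet complete deletion); quartets with fewer than `min_sites`
#' usable sites are skipped. For each topology the five branch lengths are
#' optimized in log-space (bounded quasi-Newton, `n_starts` seeded random
#' restarts); weights are the softmax of the optimized log-likelihoods.
#'
#' @param aln a `phylo_aln`.
#' @param quartet character vector of four taxa, ordered by group.
#' @param model a [subst_model()].
#' @param min_sites minimum usable sites (default 30).
#' @param n_starts optimizer restarts (default 3).
#' @param seed seed for the restarts.
#' @return list of class `quartet_evaluation`: `taxa`, `n_sites`, `l`
#'   (log-likelihoods), `p` (weights), `region`, `skipped`, `reason`.
#' @export
evaluate_quartet <- function(aln, quartet, model, min_sites = 30L,
                             n_starts = 3L, seed = 1L) {
  stopifnot(length(quartet) == 4L)
  sub <- subset_taxa(aln, quartet)
  keep <- colSums(missing_mask(sub)) == 0L
  out <- list(taxa = quartet, n_sites = sum(keep), l = rep(NA_real_, 3L),
              p = rep(NA_real_, 3L), region = NA_character_,
              skipped = FALSE, reason = NA_character_)
  class(out) <- "quartet_evaluation"
  if (out$n_sites < min_sites) {
    out$skipped <- TRUE
    out$reason <- "insufficient sites"
    return(out)
  }
  codes <- encode_states(sub)[, keep, drop = FALSE]
  l <- with_seed(seed, vapply(1:3, function(m) {
    pc <- pattern_compress(codes[.topo_perms[[m]], , drop = FALSE])
    best <- -Inf
    for (s in seq_len(n_starts)) {
      start <- runif(5L, log(0.02), log(1))
      opt <- try(optim(start, function(lv)
        -.loglik_patterns(.quartet_po, pc$pat, pc$w, model, exp(lv)),
        method = "L-BFGS-B", lower = log(1e-8), upper = log(10),
        control = list(maxit = 200L)), silent = TRUE)
      if (!inherits(opt, "try-error")) best <- max(best, -opt$value)
    }
    best
  }, 0))
  if (any(!is.finite(l))) {
    out$skipped <- TRUE
    out$reason <- "optimizer failure"
    return(out)
  }
  out$l <- l
  out$p <- exp(l - logsumexp(l))
  out$region <- assign_region(out$p[1], out$p[2], out$p[3])
  out
}

# gamma-shape estimate on a quartet subsample: for each quartet fix the
# topology and branch lengths fitted at alpha = 1, then profile alpha
# through the rate mixture alone
.estimate_alpha <- function(aln, quartets, base_model, n_quartets = 50L,
                            min_sites = 30L, seed = 1L) {
  n <- min(n_quartets, nrow(quartets))
  pick <- with_seed(substream_seed(seed, "alpha-subsample"),
                    sample.int(nrow(quartets), n))
  fixed <- list()
  for (i in pick) {
    sub <- subset_taxa(aln, quartets[i, ])
    keep <- colSums(missing_mask(sub)) == 0L
    if (sum(keep) < min_sites) next
    codes <- encode_states(sub)[, keep, drop = FALSE]
    best <- NULL
    with_seed(substream_seed(seed, paste0("alpha-fit-", i)), {
      for (m in 1:3) {
        pc <- pattern_compress(codes[.topo_perms[[m]], , drop = FALSE])
        opt <- try(optim(runif(5L, log(0.02), log(1)), function(lv)
          -.loglik_patterns(.quartet_po, pc$pat, pc$w, base_model, exp(lv)),
          method = "L-BFGS-B", lower = log(1e-8), upper = log(10),
          control = list(maxit = 200L)), silent = TRUE)
        if (!inherits(opt, "try-error") &&
            (is.null(best) || -opt$value > best$l))
          best <- list(l = -opt$value, lens = exp(opt$par), pc = pc)
      }
    })
    if (!is.null(best)) fixed[[length(fixed) + 1L]] <- best
  }
  if (length(fixed) == 0L) return(1)
  f <- function(log_alpha) {
    m <- base_model
    m$shape <- exp(log_alpha)
    m$rates <- discrete_gamma_rates(m$shape, m$ncat)
    sum(vapply(fixed, function(b)
      .loglik_patterns(.quartet_po, b$pc$pat, b$pc$w, m, b$lens), 0))
  }
  exp(optimize(f, c(log(0.05), log(50)), maximum = TRUE, tol = 0.02)$maximum)
}

#' Run four-cluster likelihood mapping for one hypothesis
#'
#' Samples quartets (one taxon per group), evaluates each under the three
#' topologies, and summarises region occupancy. The default model is uniform
#' ("poisson") exchangeabilities with alignment-wide empirical frequencies
#' and four gamma categories whose shape is estimated once on a quartet
#' subsample and then fixed, so all quartets are scored under one coherent
#' model. Deterministic given `seed`.
#'
#' @param aln a `phylo_aln`.
#' @param grouping a [taxon_grouping()].
#' @param model a [subst_model()], or `NULL` for the default above.
#' @param cap maximum quartets (default 20000).
#' @param seed master seed.
#' @param min_sites per-quartet usable-site minimum (default 30).
#' @param shape gamma shape; `NULL` (default) estimates it on a subsample,
#'   only used when `model` is `NULL`.
#' @param alpha_subsample quartets used for the shape estimate (default 50).
#' @return list of class `fclm_summary`: `label`, `n_sampled`,
#'   `n_evaluated`, `n_skipped`, `region_counts`, `region_pct`,
#'   `corner_pct`, `alpha`, `quartets` (per-quartet data.frame).
#' @export
run_hypothesis <- function(aln, grouping, model = NULL, cap = 20000L,
                           seed = 1L, min_sites = 30L, shape = NULL,
                           alpha_subsample = 50L) {
  quartets <- enumerate_quartets(grouping, cap, substream_seed(seed, "quartets"))
  alpha <- shape
  if (is.null(model)) {
    base <- subst_model(aln$alphabet, freqs = state_freqs(aln), name = "poisson+F")
    if (is.null(alpha))
      alpha <- .estimate_alpha(aln, quartets, base, alpha_subsample,
                               min_sites, seed)
    model <- subst_model(aln$alphabet, freqs = state_freqs(aln), shape = alpha,
                         name = "poisson+F+G4")
  } else alpha <- model$shape
  evs <- lapply(seq_len(nrow(quartets)), function(i)
    evaluate_quartet(aln, quartets[i, ], model, min_sites = min_sites,
                     seed = substream_seed(seed, paste0("quartet-", i))))
  df <- data.frame(t1 = quartets[, 1], t2 = quartets[, 2], t3 = quartets[, 3],
                   t4 = quartets[, 4],
                   n_sites = vapply(evs, `[[`, 0L, "n_sites"),
                   l1 = vapply(evs, function(e) e$l[1], 0),
                   l2 = vapply(evs, function(e) e$l[2], 0),
                   l3 = vapply(evs, function(e) e$l[3], 0),
                   p1 = vapply(evs, function(e) e$p[1], 0),
                   p2 = vapply(evs, function(e) e$p[2], 0),
                   p3 = vapply(evs, function(e) e$p[3], 0),
                   region = vapply(evs, `[[`, "", "region"),
                   skipped = vapply(evs, `[[`, TRUE, "skipped"),
                   reason = vapply(evs, `[[`, "", "reason"))
  evaluated <- !df$skipped
  counts <- table(factor(df$region[evaluated], levels = REGIONS))
  pct <- if (any(evaluated)) 100 * as.numeric(counts) / sum(evaluated) else
    rep(NA_real_, 7L)
  names(pct) <- REGIONS
  structure(list(label = grouping$label, n_sampled = nrow(df),
                 n_evaluated = sum(evaluated), n_skipped = sum(df$skipped),
                 region_counts = setNames(as.integer(counts), REGIONS),
                 region_pct = pct,
                 corner_pct = pct[c("C1", "C2", "C3")],
                 alpha = alpha, seed = seed, quartets = df),
            class = "fclm_summary")
}

#' @export
print.fclm_summary <- function(x, ...) {
  cat(sprintf("<fclm_summary> '%s': %d sampled, %d evaluated, %d skipped\n",
              x$label, x$n_sampled, x$n_evaluated, x$n_skipped))
  cat(sprintf("  corners C1/C2/C3: %.2f%% / %.2f%% / %.2f%%  (alpha = %.3g)\n",
              x$corner_pct[1], x$corner_pct[2], x$corner_pct[3], x$alpha))
  cat(sprintf("  edges+centre: E12 %.2f%%, E13 %.2f%%, E23 %.2f%%, CTR %.2f%%\n",
              x$region_pct["E12"], x$region_pct["E13"], x$region_pct["E23"],
              x$region_pct["CTR"]))
  invisible(x)
}
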