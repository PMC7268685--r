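# Signal-destroying permutation schemes. All schemes preserve the shape,
# taxon order, partition scheme and missing-cell coordinates bit-identically,
# and operate within partitions so partition-level structure is respected.

.permute_over_partitions <- function(aln, seed, fun) {
  scheme <- effective_scheme(aln)
  out <- aln$mat
  miss <- missing_mask(aln)
  with_seed(seed, {
    for (e in scheme$entries) {
      s <- partition_sites(e)
      out[, s] <- fun(aln$mat[, s, drop = FALSE], miss[, s, drop = FALSE])
    }
  })
  res <- aln
  res$mat <- out
  res
}

#' Column-wise residue permutation (phylogenetic signal eliminated)
#'
#' Within each partition, the non-missing residues of every column are
#' randomly permuted among exactly the taxa covered in that column; missing
#' cells stay in place. This preserves the missing-data mask and every
#' column's state multiset (hence the site-rate profile) while destroying
#' shared ancestry signal and lineage-specific composition — the permutation
#' used to re-run likelihood mapping on signal-free data.
#'
#' @param aln a `phylo_aln`; @param seed integer seed.
#' @return a `phylo_aln` of identical shape.
#' @export
scheme_columnwise <- function(aln, seed = 1L) {
  .permute_over_partitions(aln, seed, function(m, miss) {
    for (j in seq_len(ncol(m))) {
      i <- which(!miss[, j])
      if (length(i) > 1L) m[i, j] <- m[i[sample.int(length(i))], j]
    }
    m
  })
}

#' Row-wise residue permutation (composition preserved, signal destroyed)
#'
#' Within each partition, each taxon's non-missing residues are permuted
#' across its own covered sites. Preserves the mask and every taxon's
#' per-partition composition (hence compositional-heterogeneity structure,
#' which matched-pairs symmetry tests respond to) while destroying shared
#' site patterns.
#'
#' @inheritParams scheme_columnwise
#' @export
scheme_rowwise <- function(aln, seed = 1L) {
  .permute_over_partitions(aln, seed, function(m, miss) {
    for (i in seq_len(nrow(m))) {
      j <- which(!miss[i, ])
      if (length(j) > 1L) m[i, j] <- m[i, j[sample.int(length(j))]]
    }
    m
  })
}

#' Mask-only randomization (only the coverage pattern preserved)
#'
#' Every non-missing cell is replaced by an i.i.d. draw from the
#' partition-wide pooled state frequencies; the mask is untouched. Destroys
#' all signal and all compositional heterogeneity, isolating whatever
#' structure the non-random distribution of data coverage alone can induce.
#'
#' @inheritParams scheme_columnwise
#' @export
scheme_mask_only <- function(aln, seed = 1L) {
  states <- aln$states
  .permute_over_partitions(aln, seed, function(m, miss) {
    obs <- !miss
    v <- m[obs]
    tab <- tabulate(match(v, states), nbins = length(states))
    if (sum(tab) > 0L)
      m[obs] <- sample(states, length(v), replace = TRUE, prob = tab / sum(tab))
    m
  })
}
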