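#' Bowker's matched-pairs test of symmetry for one taxon pair
#'
#' Tests whether the substitution process separating two sequences is
#' symmetric (a necessary consequence of the stationarity, reversibility and
#' homogeneity assumptions of standard models). Only columns where neither
#' taxon is missing/ambiguous are compared (pairwise deletion). With
#' divergence counts `n_ab` (state a in taxon i, b in taxon j),
#' `B = sum_{a<b} (n_ab - n_ba)^2 / (n_ab + n_ba)` over cell pairs with a
#' positive denominator; `df` is the number of such pairs and `p` the
#' upper-tail chi-square probability. `df = 0` (e.g. identical sequences)
#' returns `B = 0, p = 1`; zero comparable sites is flagged and `p` is `NA`.
#'
#' @param aln a `phylo_aln`; @param taxon_i,taxon_j taxon labels.
#' @return list of class `bowker_result`: `taxa`, `B`, `df`, `p`, `n_sites`,
#'   `insufficient`.
#' @export
bowker_test <- function(aln, taxon_i, taxon_j) {
  for (t in c(taxon_i, taxon_j))
    if (!t %in% aln$taxa)
      stop_phylocong(sprintf("taxon '%s' not in alignment", t),
                     "phylocong_unknown_taxon_error")
  miss <- missing_mask(aln)
  ok <- !miss[taxon_i, ] & !miss[taxon_j, ]
  res <- list(taxa = c(taxon_i, taxon_j), B = 0, df = 0L, p = NA_real_,
              n_sites = sum(ok), insufficient = FALSE)
  class(res) <- "bowker_result"
  if (res$n_sites == 0L) {
    res$insufficient <- TRUE
    return(res)
  }
  k <- length(aln$states)
  tab <- table(factor(aln$mat[taxon_i, ok], levels = aln$states),
               factor(aln$mat[taxon_j, ok], levels = aln$states))
  upper <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  nab <- tab[upper]
  nba <- t(tab)[upper]
  tot <- nab + nba
  use <- tot > 0
  res$df <- sum(use)
  if (res$df == 0L) {
    res$p <- 1
    return(res)
  }
  res$B <- sum((nab[use] - nba[use])^2 / tot[use])
  res$p <- pchisq(res$B, df = res$df, lower.tail = FALSE)
  res
}

#' @export
print.bowker_result <- function(x, ...) {
  cat(sprintf("Bowker %s vs %s: B = %.4g, df = %d, p = %.4g (n = %d)\n",
              x$taxa[1], x$taxa[2], x$B, x$df, x$p, x$n_sites))
  invisible(x)
}

#' All pairwise Bowker tests plus the median pairwise p-value
#'
#' Evaluates every unordered taxon pair and summarises by the median of the
#' defined p-values (pairs with zero comparable sites are excluded from the
#' median and counted in `n_undefined`), the scalar reported per supermatrix
#' in the study design this package supports.
#'
#' @param aln a `phylo_aln` with at least two taxa.
#' @return list of class `pairwise_symmetry`: `p_matrix`, `B_matrix`,
#'   `df_matrix`, `pairs` (data.frame), `median_p`, `n_undefined`.
#' @export
pairwise_symmetry <- function(aln) {
  if (n_taxa(aln) < 2L)
    stop_phylocong("pairwise symmetry needs at least 2 taxa", "phylocong_argument_error")
  tx <- aln$taxa
  n <- length(tx)
  P <- B <- matrix(NA_real_, n, n, dimnames = list(tx, tx))
  D <- matrix(NA_integer_, n, n, dimnames = list(tx, tx))
  rows <- vector("list", n * (n - 1L) / 2L)
  r <- 0L
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    b <- bowker_test(aln, tx[i], tx[j])
    P[i, j] <- P[j, i] <- b$p
    B[i, j] <- B[j, i] <- b$B
    D[i, j] <- D[j, i] <- b$df
    r <- r + 1L
    rows[[r]] <- data.frame(taxon_i = tx[i], taxon_j = tx[j], B = b$B,
                            df = b$df, p = b$p, n_sites = b$n_sites,
                            insufficient = b$insufficient)
  }
  pairs <- do.call(rbind, rows)
  pv <- pairs$p[!is.na(pairs$p)]
  structure(list(p_matrix = P, B_matrix = B, df_matrix = D, pairs = pairs,
                 median_p = if (length(pv)) median(pv) else NA_real_,
                 n_undefined = sum(is.na(pairs$p))),
            class = "pairwise_symmetry")
}

#' @export
print.pairwise_symmetry <- function(x, ...) {
  cat(sprintf("<pairwise_symmetry> %d pairs, median p = %.4g (%d undefined)\n",
              nrow(x$pairs), x$median_p, x$n_undefined))
  invisible(x)
}

#' Relative composition frequency variation (RCFV) of one partition
#'
#' With `A_sj` the relative frequency of state `s` among taxon `j`'s
#' non-missing characters inside the partition and `Abar_s` the mean over
#' the `n` taxa that have data there,
#' `RCFV = sum_s sum_j |A_sj - Abar_s| / n`. Taxa with no observed character
#' in the partition are excluded from `n`. RCFV is 0 iff all taxa share the
#' same composition, and grows with lineage-specific compositional bias.
#'
#' @param aln a `phylo_aln`; @param partition partition name, or `NULL` for
#'   the whole alignment.
#' @param threshold masking threshold; the partition is flagged when
#'   `RCFV >= threshold` (inclusive bound).
#' @return list of class `rcfv_report`: `partition`, `rcfv`, `per_taxon`
#'   (per-taxon summed absolute deviation), `deviations` (taxa x states),
#'   `n_taxa_with_data`, `masked`, `insufficient`.
#' @export
rcfv <- function(aln, partition = NULL, threshold = 0.1) {
  if (is.null(partition)) {
    sites <- seq_len(n_sites(aln))
    pname <- "<all>"
  } else {
    scheme <- effective_scheme(aln)
    idx <- match(partition, partition_names(scheme))
    if (is.na(idx))
      stop_phylocong(sprintf("unknown partition '%s'", partition),
                     "phylocong_unknown_partition_error")
    sites <- partition_sites(scheme$entries[[idx]])
    pname <- partition
  }
  sub <- aln$mat[, sites, drop = FALSE]
  obs <- !(sub %in% aln$missing)
  dim(obs) <- dim(sub)
  has_data <- rowSums(obs) > 0L
  out <- list(partition = pname, rcfv = NA_real_, per_taxon = NULL,
              deviations = NULL, n_taxa_with_data = sum(has_data),
              masked = NA, insufficient = FALSE)
  class(out) <- "rcfv_report"
  if (!any(has_data)) {
    out$insufficient <- TRUE
    return(out)
  }
  A <- t(vapply(which(has_data), function(i) {
    v <- sub[i, obs[i, ]]
    tab <- tabulate(match(v, aln$states), nbins = length(aln$states))
    tab / sum(tab)
  }, numeric(length(aln$states))))
  dimnames(A) <- list(aln$taxa[has_data], aln$states)
  abar <- colMeans(A)
  dev <- abs(sweep(A, 2L, abar))
  n <- nrow(A)
  out$rcfv <- sum(dev) / n
  out$per_taxon <- rowSums(dev) / n
  out$deviations <- dev
  out$masked <- out$rcfv >= threshold
  out
}

#' @export
print.rcfv_report <- function(x, ...) {
  cat(sprintf("RCFV[%s] = %.4g (n = %d taxa)%s\n", x$partition, x$rcfv,
              x$n_taxa_with_data, if (isTRUE(x$masked)) " [masked]" else ""))
  invisible(x)
}

#' Filtering thresholds for masking and decisiveness
#'
#' Defaults follow the published protocol: partitions are masked when RCFV is
#' at or above 0.1; a partition is "decisive" when every taxon has data,
#' strictly less than 30% of its cells are ambiguous, and it is at least
#' 500 sites long.
#'
#' @param require_all_taxa require every taxon to have >=1 observed character.
#' @param max_ambiguous_fraction strict upper bound on the ambiguous-cell
#'   fraction (default 0.30).
#' @param min_sites inclusive minimum partition length (default 500).
#' @param rcfv_threshold inclusive RCFV masking bound (default 0.1).
#' @export
filter_criteria <- function(require_all_taxa = TRUE,
                            max_ambiguous_fraction = 0.30,
                            min_sites = 500L,
                            rcfv_threshold = 0.1) {
  stopifnot(max_ambiguous_fraction >= 0, max_ambiguous_fraction <= 1,
            min_sites >= 1L, rcfv_threshold >= 0)
  structure(list(require_all_taxa = isTRUE(require_all_taxa),
                 max_ambiguous_fraction = max_ambiguous_fraction,
                 min_sites = as.integer(min_sites),
                 rcfv_threshold = rcfv_threshold),
            class = "filter_criteria")
}

#' Mask partitions whose RCFV is at or above the threshold
#'
#' Removes all sites of every partition with `RCFV >= rcfv_threshold`
#' (inclusive, matching the published rule), re-indexes the surviving
#' scheme, and reports what was removed.
#'
#' @param aln a `phylo_aln` with a partition scheme.
#' @param criteria a [filter_criteria()].
#' @return list: `alignment` (masked), `report` (data.frame with per-partition
#'   RCFV, length, masked flag).
#' @export
mask_by_rcfv <- function(aln, criteria = filter_criteria()) {
  scheme <- effective_scheme(aln)
  rep_rows <- lapply(scheme$entries, function(e) {
    r <- rcfv(aln, e$name, threshold = criteria$rcfv_threshold)
    data.frame(partition = e$name, n_sites = length(partition_sites(e)),
               rcfv = r$rcfv, masked = isTRUE(r$masked))
  })
  report <- do.call(rbind, rep_rows)
  keep <- !report$masked
  if (!any(keep))
    stop_phylocong("all partitions masked: empty alignment", "phylocong_empty_error")
  new_entries <- list()
  keep_sites <- integer(0)
  offset <- 0L
  for (i in which(keep)) {
    s <- partition_sites(scheme$entries[[i]])
    keep_sites <- c(keep_sites, s)
    new_entries[[length(new_entries) + 1L]] <-
      list(name = scheme$entries[[i]]$name,
           ranges = cbind(offset + 1L, offset + length(s)),
           model = scheme$entries[[i]]$model)
    offset <- offset + length(s)
  }
  out <- subset_sites(aln, keep_sites)
  out <- set_partitions(out, partition_scheme(new_entries))
  list(alignment = out, report = report)
}

#' Alignment completeness scores
#'
#' `C_a` is the overall proportion of non-ambiguous cells; `C_r` the
#' per-taxon proportion; `C_ij` the pairwise proportion of sites where both
#' taxa are unambiguous.
#'
#' @param aln a `phylo_aln`.
#' @return list of class `completeness_report`: `C_a`, `C_r`, `C_ij`.
#' @export
completeness <- function(aln) {
  obs <- !missing_mask(aln)
  Cij <- (obs %*% t(obs)) / n_sites(aln)
  structure(list(C_a = mean(obs), C_r = rowMeans(obs), C_ij = Cij),
            class = "completeness_report")
}

#' @export
print.completeness_report <- function(x, ...) {
  cat(sprintf("C_a = %.4f (per-taxon range %.4f-%.4f)\n",
              x$C_a, min(x$C_r), max(x$C_r)))
  invisible(x)
}

#' Decisive-subset filter over partitions
#'
#' Keeps partitions where (a) every taxon has at least one non-missing
#' character, (b) the fraction of ambiguous cells is strictly below
#' `max_ambiguous_fraction`, and (c) the length is at least `min_sites`.
#'
#' @param aln a `phylo_aln` with a partition scheme.
#' @param criteria a [filter_criteria()].
#' @return list: `surviving` (character vector of partition names), `report`
#'   (per-partition data.frame with the three checks).
#' @export
decisive_filter <- function(aln, criteria = filter_criteria()) {
  scheme <- effective_scheme(aln)
  miss <- missing_mask(aln)
  rows <- lapply(scheme$entries, function(e) {
    s <- partition_sites(e)
    m <- miss[, s, drop = FALSE]
    all_taxa <- all(rowSums(!m) > 0L)
    amb_frac <- mean(m)
    data.frame(partition = e$name, n_sites = length(s),
               all_taxa = all_taxa, ambiguous_fraction = amb_frac,
               pass_all_taxa = !criteria$require_all_taxa || all_taxa,
               pass_ambiguity = amb_frac < criteria$max_ambiguous_fraction,
               pass_length = length(s) >= criteria$min_sites)
  })
  report <- do.call(rbind, rows)
  report$decisive <- report$pass_all_taxa & report$pass_ambiguity & report$pass_length
  list(surviving = report$partition[report$decisive], report = report)
}
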