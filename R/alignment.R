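#' Construct a partitioned alignment
#'
#' The central data container: a taxa x sites character matrix over a
#' declared alphabet, an ambiguity (missing) set, and an optional partition
#' scheme. All downstream diagnostics consume this object.
#'
#' @param mat character matrix, rownames are taxon labels.
#' @param alphabet `"AA"` or `"NT"`.
#' @param partitions a [partition_scheme()] or `NULL` (single partition
#'   spanning all sites is implied where needed).
#' @param missing override for the ambiguity set; default from
#'   [alphabet_def()].
#' @param strict reject symbols outside states+missing (`TRUE`, default) or
#'   coerce them to the missing symbol.
#' @return an object of class `phylo_aln` with fields `mat`, `taxa`,
#'   `alphabet`, `states`, `missing`, `partitions`.
#' @export
phylo_alignment <- function(mat, alphabet = c("AA", "NT"), partitions = NULL,
                            missing = NULL, strict = TRUE) {
  alphabet <- match.arg(alphabet)
  if (!is.matrix(mat) || !is.character(mat))
    stop_phylocong("alignment must be a character matrix", "phylocong_type_error")
  if (ncol(mat) < 1L)
    stop_phylocong("alignment must have at least one site", "phylocong_empty_error")
  taxa <- rownames(mat)
  if (is.null(taxa) || anyNA(taxa) || any(taxa == ""))
    stop_phylocong("alignment rows must be named by taxa", "phylocong_taxa_error")
  if (anyDuplicated(taxa))
    stop_phylocong(sprintf("duplicate taxon label(s): %s",
                           paste(unique(taxa[duplicated(taxa)]), collapse = ", ")),
                   "phylocong_duplicate_taxon_error")
  def <- alphabet_def(alphabet)
  if (!is.null(missing)) def$missing <- toupper(missing)
  mat[] <- toupper(mat)
  legal <- c(def$states, def$missing)
  bad <- !(mat %in% legal)
  if (any(bad)) {
    if (strict) {
      stop_phylocong(sprintf("illegal symbol(s) for %s alphabet: %s", alphabet,
                             paste(unique(mat[bad]), collapse = ", ")),
                     "phylocong_alphabet_error")
    } else {
      mat[bad] <- def$missing[1L]
    }
  }
  obj <- structure(list(mat = mat, taxa = taxa, alphabet = alphabet,
                        states = def$states, missing = def$missing,
                        partitions = NULL),
                   class = "phylo_aln")
  if (!is.null(partitions)) obj <- set_partitions(obj, partitions)
  obj
}

#' @export
print.phylo_aln <- function(x, ...) {
  np <- if (is.null(x$partitions)) 0L else length(x$partitions$entries)
  cat(sprintf("<phylo_aln> %d taxa x %d sites (%s), %d partition(s)\n",
              nrow(x$mat), ncol(x$mat), x$alphabet, np))
  invisible(x)
}

n_sites <- function(aln) ncol(aln$mat)
n_taxa <- function(aln) nrow(aln$mat)

#' Logical matrix marking missing/ambiguous cells
#' @param aln a `phylo_aln`.
#' @return logical matrix, `TRUE` where the cell is ambiguous or missing.
#' @export
missing_mask <- function(aln) {
  m <- matrix(aln$mat %in% aln$missing, nrow(aln$mat), ncol(aln$mat))
  dimnames(m) <- dimnames(aln$mat)
  m
}

#' Restrict an alignment to a subset of sites (partition scheme dropped)
#' @param aln a `phylo_aln`; @param sites integer site indices (1-based).
#' @export
subset_sites <- function(aln, sites) {
  sites <- as.integer(sites)
  if (length(sites) == 0L)
    stop_phylocong("cannot create an alignment with zero sites", "phylocong_empty_error")
  stopifnot(all(sites >= 1L & sites <= n_sites(aln)))
  phylo_alignment(aln$mat[, sites, drop = FALSE], aln$alphabet,
                  missing = aln$missing)
}

#' Restrict an alignment to a subset of taxa (keeps partitions)
#' @param aln a `phylo_aln`; @param taxa character taxon labels.
#' @export
subset_taxa <- function(aln, taxa) {
  miss <- setdiff(taxa, aln$taxa)
  if (length(miss))
    stop_phylocong(sprintf("taxa not in alignment: %s", paste(miss, collapse = ", ")),
                   "phylocong_unknown_taxon_error")
  out <- aln
  out$mat <- aln$mat[taxa, , drop = FALSE]
  out$taxa <- taxa
  out
}

# integer encoding: 1..k for observed states, 0L for missing/ambiguous
encode_states <- function(aln) {
  code <- match(aln$mat, aln$states)
  code[is.na(code)] <- 0L
  matrix(as.integer(code), nrow(aln$mat), ncol(aln$mat),
         dimnames = dimnames(aln$mat))
}

#' Empirical state frequencies of an alignment
#'
#' Counts observed (non-missing) states with a pseudocount per state, so tiny
#' sub-alignments never produce zero frequencies.
#'
#' @param aln a `phylo_aln`; @param pseudocount added to every state count.
#' @return named numeric vector on the simplex.
#' @export
state_freqs <- function(aln, pseudocount = 1) {
  cnt <- table(factor(aln$mat[!missing_mask(aln)], levels = aln$states))
  f <- as.numeric(cnt) + pseudocount
  setNames(f / sum(f), aln$states)
}

#' Extract one codon position from every partition
#'
#' For nucleotide alignments whose partitions are in frame (each partition's
#' first site is codon position 1 and its length is divisible by 3), returns
#' the alignment restricted to the requested codon position, with the
#' partition scheme re-indexed onto the reduced coordinates. This is the
#' masking step used to analyse second codon positions alone, the positions
#' whose composition is most homogeneous across taxa.
#'
#' @param aln a `phylo_aln` with NT alphabet and a partition scheme.
#' @param position codon position, 1, 2 or 3.
#' @return a `phylo_aln` with one third of the sites.
#' @export
extract_codon_positions <- function(aln, position) {
  if (aln$alphabet != "NT")
    stop_phylocong("codon positions require a nucleotide alignment", "phylocong_alphabet_error")
  stopifnot(position %in% 1:3)
  scheme <- aln$partitions
  if (is.null(scheme))
    scheme <- partition_scheme(list(list(name = "all", ranges = cbind(1L, n_sites(aln)))))
  keep <- integer(0)
  new_entries <- list()
  offset <- 0L
  for (e in scheme$entries) {
    sites <- partition_sites(e)
    if (length(sites) %% 3L != 0L)
      stop_phylocong(sprintf("partition '%s' length %d not divisible by 3",
                             e$name, length(sites)), "phylocong_frame_error")
    sel <- sites[seq(position, length(sites), by = 3L)]
    keep <- c(keep, sel)
    new_entries[[length(new_entries) + 1L]] <-
      list(name = e$name,
           ranges = cbind(offset + 1L, offset + length(sel)),
           stride = NA_integer_, model = e$model %||% NA_character_)
    offset <- offset + length(sel)
  }
  out <- subset_sites(aln, keep)
  set_partitions(out, partition_scheme(new_entries))
}
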