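#' Read a multiple sequence alignment
#'
#' Supports FASTA and relaxed sequential PHYLIP (header `ntaxa nsites`, then
#' one whitespace-delimited `label sequence` record per taxon, the sequence
#' possibly wrapped over following lines). Characters are upper-cased and
#' validated against the declared alphabet; in strict mode (default) illegal
#' symbols are an error, otherwise they are coerced to missing.
#'
#' @param path file path.
#' @param format `"fasta"` or `"phylip"`; default guesses from the first
#'   non-blank character (`>` means FASTA).
#' @param alphabet `"AA"` or `"NT"`.
#' @param strict reject illegal symbols (default `TRUE`).
#' @param missing optional override of the ambiguity set.
#' @return a [phylo_alignment()].
#' @export
read_alignment <- function(path, format = c("guess", "fasta", "phylip"),
                           alphabet = c("AA", "NT"), strict = TRUE,
                           missing = NULL) {
  format <- match.arg(format)
  alphabet <- match.arg(alphabet)
  if (format == "guess") {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(trimws(first), ">")) "fasta" else "phylip"
  }
  recs <- if (format == "fasta") .read_fasta_records(path) else .read_phylip_records(path)
  lens <- vapply(recs, nchar, 1L)
  if (length(unique(lens)) != 1L)
    stop_phylocong(sprintf("sequences differ in length (%s)",
                           paste(unique(lens), collapse = ", ")),
                   "phylocong_length_error")
  mat <- do.call(rbind, lapply(recs, function(s) strsplit(s, "")[[1]]))
  rownames(mat) <- names(recs)
  phylo_alignment(mat, alphabet, strict = strict, missing = missing)
}

# verbatim FASTA reader: keeps every residue symbol so that alphabet
# validation (strict vs lenient) happens in one place, in phylo_alignment()
.read_fasta_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- startsWith(lines, ">")
  if (!any(hdr) || !hdr[1])
    stop_phylocong("no sequences in FASTA file", "phylocong_parse_error")
  rec_id <- cumsum(hdr)
  labels <- vapply(strsplit(sub("^>", "", lines[hdr]), "\\s+"), `[[`, "", 1L)
  if (anyDuplicated(labels))
    stop_phylocong("duplicate taxon labels in FASTA", "phylocong_duplicate_taxon_error")
  seqs <- vapply(split(lines[!hdr], rec_id[!hdr]), function(v)
    toupper(gsub("\\s", "", paste(v, collapse = ""))), "")
  if (length(seqs) != length(labels) || any(!nzchar(seqs)))
    stop_phylocong("FASTA record without sequence", "phylocong_parse_error")
  setNames(seqs, labels)
}

.read_phylip_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]]))
  if (length(hdr) != 2L || anyNA(hdr))
    stop_phylocong("malformed PHYLIP header", "phylocong_parse_error")
  ntax <- hdr[1]; nsite <- hdr[2]
  body <- lines[-1]
  recs <- character(0)
  i <- 1L
  while (length(recs) < ntax) {
    if (i > length(body))
      stop_phylocong("PHYLIP file truncated", "phylocong_parse_error")
    toks <- strsplit(trimws(body[i]), "\\s+")[[1]]
    label <- toks[1]
    seq <- paste(toks[-1], collapse = "")
    i <- i + 1L
    while (nchar(seq) < nsite && i <= length(body)) {
      seq <- paste0(seq, gsub("\\s", "", body[i]))
      i <- i + 1L
    }
    if (nchar(seq) != nsite)
      stop_phylocong(sprintf("sequence '%s' has %d sites, header says %d",
                             label, nchar(seq), nsite), "phylocong_length_error")
    recs[label] <- toupper(seq)
  }
  if (length(recs) != ntax || anyDuplicated(names(recs)))
    stop_phylocong("taxon count/labels inconsistent with PHYLIP header",
                   "phylocong_parse_error")
  recs
}

#' Write an alignment in canonical FASTA or relaxed sequential PHYLIP
#'
#' Canonical formatting: FASTA as `>label` followed by the full sequence on
#' one line; PHYLIP as `ntaxa nsites` then `label sequence` records. Reading
#' a written file back yields a byte-identical rewrite.
#'
#' @param aln a `phylo_aln`; @param path output; @param format
#'   `"fasta"` or `"phylip"`.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  seqs <- apply(aln$mat, 1L, paste, collapse = "")
  lines <- if (format == "fasta") {
    as.vector(rbind(paste0(">", aln$taxa), seqs))
  } else {
    c(sprintf("%d %d", n_taxa(aln), n_sites(aln)),
      sprintf("%s %s", aln$taxa, seqs))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read one or several Newick trees
#' @param path file with one Newick string.
#' @return an `ape::phylo`.
#' @export
read_tree <- function(path) {
  tr <- ape::read.tree(path)
  if (inherits(tr, "multiPhylo")) tr <- tr[[1L]]
  if (is.null(tr)) stop_phylocong("could not parse Newick file", "phylocong_parse_error")
  .validate_tree(tr)
}

#' @rdname read_tree
#' @return for `read_trees`, an `ape::multiPhylo` list.
#' @export
read_trees <- function(path) {
  tr <- ape::read.tree(path)
  if (inherits(tr, "phylo")) tr <- c(tr)
  if (is.null(tr)) stop_phylocong("could not parse Newick file", "phylocong_parse_error")
  for (t in tr) .validate_tree(t)
  tr
}

.validate_tree <- function(tr) {
  if (anyDuplicated(tr$tip.label))
    stop_phylocong("duplicate leaf labels in tree", "phylocong_duplicate_taxon_error")
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    stop_phylocong("negative branch length in tree", "phylocong_branch_error")
  tr
}

#' Read a discrete character matrix (TSV)
#'
#' First column taxon labels, remaining columns one character each; cells are
#' single state symbols, with `?` or `-` for missing.
#'
#' @param path TSV file with a header row of character ids.
#' @return object of class `char_matrix`: list with `taxa`, `characters`,
#'   `states` (per-character observed state list), `mat` (character matrix,
#'   missing as `NA`).
#' @export
read_character_matrix <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                   check.names = FALSE)
  if (ncol(df) < 2L)
    stop_phylocong("character matrix needs taxon column + >=1 character",
                   "phylocong_parse_error")
  taxa <- df[[1L]]
  if (anyDuplicated(taxa))
    stop_phylocong("duplicate taxa in character matrix", "phylocong_duplicate_taxon_error")
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- taxa
  mat[mat %in% c("?", "-", "")] <- NA_character_
  character_matrix(mat)
}

#' Construct a character matrix object from a state matrix
#' @param mat character matrix (taxa x characters), `NA` for missing.
#' @param states optional named list of per-character state sets; default is
#'   the sorted observed states of each character.
#' @export
character_matrix <- function(mat, states = NULL) {
  stopifnot(is.matrix(mat))
  if (is.null(colnames(mat))) colnames(mat) <- paste0("char", seq_len(ncol(mat)))
  if (is.null(states))
    states <- lapply(seq_len(ncol(mat)), function(j) sort(unique(mat[!is.na(mat[, j]), j])))
  names(states) <- colnames(mat)
  for (j in seq_len(ncol(mat))) {
    obs <- mat[!is.na(mat[, j]), j]
    bad <- setdiff(unique(obs), states[[j]])
    if (length(bad))
      stop_phylocong(sprintf("character '%s' has state(s) outside its state list: %s",
                             colnames(mat)[j], paste(bad, collapse = ", ")),
                     "phylocong_state_error")
  }
  structure(list(taxa = rownames(mat), characters = colnames(mat),
                 states = states, mat = mat), class = "char_matrix")
}

#' Write a character matrix as TSV
#' @param cm a `char_matrix`; @param path output file.
#' @export
write_character_matrix <- function(cm, path) {
  out <- cm$mat
  out[is.na(out)] <- "?"
  df <- data.frame(taxon = cm$taxa, out, check.names = FALSE)
  colnames(df) <- c("taxon", cm$characters)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a four-group taxon assignment for likelihood mapping
#'
#' TSV with columns `group` and `taxon`; exactly four distinct group names,
#' disjoint and non-empty, all taxa present in `aln`.
#'
#' @param path TSV file; @param aln alignment whose taxa validate the file.
#' @param label hypothesis label; default the file base name.
#' @return a `taxon_grouping`.
#' @export
read_grouping <- function(path, aln, label = NULL) {
  df <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character")
  if (!all(c("group", "taxon") %in% names(df)))
    stop_phylocong("grouping file needs 'group' and 'taxon' columns",
                   "phylocong_parse_error")
  groups <- split(df$taxon, factor(df$group, levels = unique(df$group)))
  taxon_grouping(groups, aln,
                 label = label %||% tools::file_path_sans_ext(basename(path)))
}

#' Construct and validate a four-group taxon assignment
#' @param groups named list of four character vectors of taxon labels.
#' @param aln alignment the taxa must belong to.
#' @param label hypothesis label.
#' @export
taxon_grouping <- function(groups, aln, label = "hypothesis") {
  if (length(groups) != 4L)
    stop_phylocong(sprintf("need exactly 4 groups, got %d", length(groups)),
                   "phylocong_grouping_error")
  if (any(vapply(groups, length, 1L) == 0L))
    stop_phylocong("groups must be non-empty", "phylocong_grouping_error")
  all_t <- unlist(groups)
  if (anyDuplicated(all_t))
    stop_phylocong("groups must be pairwise disjoint", "phylocong_disjointness_error")
  unk <- setdiff(all_t, aln$taxa)
  if (length(unk))
    stop_phylocong(sprintf("taxa not in alignment: %s", paste(unk, collapse = ", ")),
                   "phylocong_unknown_taxon_error")
  if (is.null(names(groups))) names(groups) <- paste0("g", 1:4)
  structure(list(groups = groups, label = label), class = "taxon_grouping")
}

#' Write a taxon grouping as TSV
#' @param grp a `taxon_grouping`; @param path output file.
#' @export
write_grouping <- function(grp, path) {
  df <- data.frame(group = rep(names(grp$groups), lengths(grp$groups)),
                   taxon = unlist(grp$groups, use.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
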