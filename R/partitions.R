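#' Construct a partition scheme
#'
#' Entries are ordered; each holds a name, one or more 1-based inclusive site
#' intervals, an optional codon stride (1, 2 or 3; NT data only) and the model
#' token from the partition file (kept as annotation only).
#'
#' @param entries list of lists with fields `name`, `ranges` (2-column integer
#'   matrix of inclusive 1-based intervals), optional `stride`, `model`.
#' @return object of class `partition_scheme`.
#' @export
partition_scheme <- function(entries) {
  stopifnot(is.list(entries), length(entries) > 0L)
  entries <- lapply(entries, function(e) {
    stopifnot(!is.null(e$name), !is.null(e$ranges))
    r <- matrix(as.integer(e$ranges), ncol = 2L)
    if (any(r[, 1L] > r[, 2L]) || any(r < 1L))
      stop_phylocong(sprintf("invalid interval in partition '%s'", e$name),
                     "phylocong_bounds_error")
    list(name = as.character(e$name), ranges = r,
         stride = if (is.null(e$stride) || is.na(e$stride)) NA_integer_ else as.integer(e$stride),
         model = e$model %||% NA_character_)
  })
  nm <- vapply(entries, `[[`, "", "name")
  if (anyDuplicated(nm))
    stop_phylocong("partition names must be unique", "phylocong_duplicate_partition_error")
  all_sites <- unlist(lapply(entries, partition_sites))
  if (anyDuplicated(all_sites))
    stop_phylocong("partitions overlap", "phylocong_overlap_error")
  structure(list(entries = entries), class = "partition_scheme")
}

#' @export
print.partition_scheme <- function(x, ...) {
  cat(sprintf("<partition_scheme> %d entries\n", length(x$entries)))
  invisible(x)
}

#' Sites covered by a partition entry (after applying any codon stride)
#' @param entry one element of `scheme$entries`.
#' @return integer vector of 1-based site indices.
#' @export
partition_sites <- function(entry) {
  s <- unlist(lapply(seq_len(nrow(entry$ranges)), function(i)
    seq.int(entry$ranges[i, 1L], entry$ranges[i, 2L])))
  if (!is.na(entry$stride)) s <- s[seq(entry$stride, length(s), by = 3L)]
  s
}

partition_names <- function(scheme) vapply(scheme$entries, `[[`, "", "name")

#' Attach a partition scheme to an alignment, validating bounds
#' @param aln a `phylo_aln`; @param scheme a [partition_scheme()].
#' @export
set_partitions <- function(aln, scheme) {
  stopifnot(inherits(scheme, "partition_scheme"))
  L <- n_sites(aln)
  for (e in scheme$entries) {
    if (max(e$ranges) > L)
      stop_phylocong(sprintf("partition '%s' extends beyond alignment length %d",
                             e$name, L), "phylocong_bounds_error")
    if (!is.na(e$stride) && aln$alphabet != "NT")
      stop_phylocong("codon stride is only valid for nucleotide alignments",
                     "phylocong_alphabet_error")
  }
  aln$partitions <- scheme
  aln
}

# scheme covering all sites; used when an alignment has no explicit scheme
effective_scheme <- function(aln) {
  aln$partitions %||%
    partition_scheme(list(list(name = "all", ranges = cbind(1L, n_sites(aln)))))
}

#' Read a RAxML-style partition file
#'
#' Lines of the form `MODEL, name = a-b[, c-d][\3]`; the model token is kept
#' as annotation only. A `\\k` suffix on an interval declares a codon stride
#' (every third site starting from position k of the interval). Lines without
#' a model token (`name = a-b`) are accepted.
#'
#' @param path file path.
#' @return a [partition_scheme()].
#' @export
read_partitions <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  entries <- lapply(lines, function(ln) {
    eq <- regmatches(ln, regexec("^(?:([^,=]+),)?\\s*([^=]+?)\\s*=\\s*(.+)$", ln))[[1]]
    if (length(eq) == 0L)
      stop_phylocong(sprintf("cannot parse partition line: '%s'", ln),
                     "phylocong_parse_error")
    model <- trimws(eq[2]); name <- trimws(eq[3]); spec <- trimws(eq[4])
    stride <- NA_integer_
    pieces <- trimws(strsplit(spec, ",")[[1]])
    ranges <- t(vapply(pieces, function(p) {
      m <- regmatches(p, regexec("^(\\d+)\\s*-\\s*(\\d+)(?:\\\\(\\d))?$", p))[[1]]
      if (length(m) == 0L) {
        m1 <- regmatches(p, regexec("^(\\d+)$", p))[[1]]
        if (length(m1)) return(c(as.integer(m1[2]), as.integer(m1[2])))
        stop_phylocong(sprintf("cannot parse interval '%s' in line '%s'", p, ln),
                       "phylocong_parse_error")
      }
      if (nzchar(m[4])) stride <<- as.integer(m[4])
      c(as.integer(m[2]), as.integer(m[3]))
    }, integer(2)))
    list(name = name, ranges = ranges, stride = stride,
         model = if (nzchar(model)) model else NA_character_)
  })
  partition_scheme(entries)
}

#' Write a partition scheme in RAxML dialect
#' @param scheme a [partition_scheme()]; @param path output file.
#' @export
write_partitions <- function(scheme, path) {
  lines <- vapply(scheme$entries, function(e) {
    spec <- paste(sprintf("%d-%d%s", e$ranges[, 1L], e$ranges[, 2L],
                          ifelse(rep(!is.na(e$stride), nrow(e$ranges)),
                                 sprintf("\\%d", e$stride), "")),
                  collapse = ", ")
    sprintf("%s, %s = %s",
            if (is.na(e$model)) "MODEL" else e$model, e$name, spec)
  }, "")
  writeLines(lines, path)
  invisible(path)
}
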