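# in-code fixtures shared across test files

# alignment from per-taxon sequence strings
aln_from_strings <- function(seqs, alphabet = "AA", ...) {
  mat <- do.call(rbind, lapply(seqs, function(s) strsplit(s, "")[[1]]))
  rownames(mat) <- names(seqs)
  phylo_alignment(mat, alphabet, ...)
}

quartet_tree <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

# a 7-partition fixture for the decisive filter: partitions violating one
# criterion each plus two fully compliant ones (3 taxa)
decisive_fixture <- function() {
  taxa <- c("t1", "t2", "t3", "t4")  # 4 taxa so one absent taxon stays <30% ambiguous
  blocks <- list(
    ok1      = list(len = 500L, absent = NULL,  amb = 0.10),
    ok2      = list(len = 600L, absent = NULL,  amb = 0.00),
    no_taxon = list(len = 500L, absent = "t4",  amb = 0.00),
    too_amb  = list(len = 500L, absent = NULL,  amb = 0.40),
    short1   = list(len = 499L, absent = NULL,  amb = 0.00),
    amb_edge = list(len = 500L, absent = NULL,  amb = 0.30),  # exactly 30%: fails strict rule
    short2   = list(len = 100L, absent = NULL,  amb = 0.00))
  set.seed(404)
  mats <- lapply(blocks, function(b) {
    m <- matrix(sample(c("A", "C", "D", "E"), 4 * b$len, TRUE), 4, b$len,
                dimnames = list(taxa, NULL))
    n_amb <- round(b$amb * length(m))
    if (n_amb > 0) m[seq_len(n_amb)] <- "X"  # fills column-major, spread over taxa
    if (!is.null(b$absent)) m[b$absent, ] <- "X"
    m
  })
  lens <- vapply(blocks, `[[`, 0L, "len")
  ends <- cumsum(lens)
  starts <- c(1L, head(ends, -1L) + 1L)
  scheme <- partition_scheme(lapply(seq_along(blocks), function(i)
    list(name = names(blocks)[i], ranges = cbind(starts[i], ends[i]))))
  phylo_alignment(do.call(cbind, mats), "AA", partitions = scheme)
}
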