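test_that("FASTA reading validates shape, labels and alphabet", {
  tf <- tempfile(fileext = ".fa")
  writeLines(c(">s1", "ACDE", ">s2", "ACDF"), tf)
  aln <- read_alignment(tf, alphabet = "AA")
  expect_equal(dim(aln$mat), c(2L, 4L))
  expect_equal(aln$taxa, c("s1", "s2"))

  writeLines(c(">s1", "ACDE", ">s2", "ACDFF"), tf)
  expect_error(read_alignment(tf, alphabet = "AA"),
               class = "phylocong_length_error")

  writeLines(c(">s1", "ACDE", ">s1", "ACDF"), tf)
  expect_error(read_alignment(tf, alphabet = "AA"),
               class = "phylocong_duplicate_taxon_error")

  writeLines(c(">s1", "ACJE", ">s2", "ACDF"), tf)  # J is not an amino acid
  expect_error(read_alignment(tf, alphabet = "AA"),
               class = "phylocong_alphabet_error")
  lenient <- read_alignment(tf, alphabet = "AA", strict = FALSE)
  expect_equal(unname(lenient$mat["s1", 3]), "X")
})

test_that("relaxed sequential PHYLIP parses and round-trips byte-identically", {
  tf <- tempfile(fileext = ".phy")
  writeLines(c("3 6", "taxA ACDEFG", "taxB ACDEFH", "taxC ACDEYH"), tf)
  aln <- read_alignment(tf, format = "phylip", alphabet = "AA")
  expect_equal(dim(aln$mat), c(3L, 6L))
  out <- tempfile()
  write_alignment(aln, out, "phylip")
  aln2 <- read_alignment(out, format = "phylip", alphabet = "AA")
  out2 <- tempfile()
  write_alignment(aln2, out2, "phylip")
  expect_identical(readLines(out), readLines(out2))
})

test_that("write-read is identity on random alignments for both formats", {
  set.seed(11)
  for (rep in 1:5) {
    alphabet <- sample(c("AA", "NT"), 1)
    def <- alphabet_def(alphabet)
    nt <- sample(2:8, 1); L <- sample(5:40, 1)
    mat <- matrix(sample(c(def$states, "-", "?"), nt * L, TRUE,
                         prob = c(rep(1, length(def$states)), .3, .2)),
                  nt, L, dimnames = list(paste0("tx", seq_len(nt)), NULL))
    aln <- phylo_alignment(mat, alphabet)
    for (fmt in c("fasta", "phylip")) {
      f <- tempfile()
      write_alignment(aln, f, fmt)
      back <- read_alignment(f, format = fmt, alphabet = alphabet)
      expect_identical(back$mat, aln$mat)
    }
  }
})

test_that("partition files parse the RAxML dialect including codon stride", {
  tf <- tempfile()
  writeLines(c("WAG, p1 = 1-100", "GTR, p2 = 101-199\\3", "p3 = 200-250"), tf)
  ps <- read_partitions(tf)
  expect_equal(length(ps$entries), 3L)
  expect_equal(ps$entries[[1]]$ranges, cbind(1L, 100L))
  expect_equal(ps$entries[[1]]$model, "WAG")
  expect_equal(ps$entries[[2]]$stride, 3L)
  # \3 selects every third site of the interval, starting at its 3rd site
  expect_equal(head(partition_sites(ps$entries[[2]]), 3), c(103L, 106L, 109L))
  expect_true(is.na(ps$entries[[3]]$model))

  writeLines(c("M, p1 = 1-100", "M, p3 = 90-110"), tf)
  expect_error(read_partitions(tf), class = "phylocong_overlap_error")

  writeLines("M, p1 = 1-100", tf)
  ps2 <- read_partitions(tf)
  tiny <- phylo_alignment(matrix("A", 2, 50,
                                 dimnames = list(c("a", "b"), NULL)), "AA")
  expect_error(set_partitions(tiny, ps2), class = "phylocong_bounds_error")
})

test_that("codon-position extraction slices frames and re-indexes partitions", {
  mat <- matrix(rep(strsplit("ACGTTGCAT", "")[[1]], 2), 2, 9, byrow = TRUE,
                dimnames = list(c("a", "b"), NULL))
  aln <- phylo_alignment(mat, "NT",
                         partitions = partition_scheme(list(
                           list(name = "x", ranges = cbind(1, 9)))))
  pos2 <- extract_codon_positions(aln, 2)
  expect_equal(unname(pos2$mat[1, ]), c("C", "T", "A"))  # original sites 2,5,8

  two <- phylo_alignment(matrix("A", 2, 12, dimnames = list(c("a", "b"), NULL)),
                         "NT", partitions = partition_scheme(list(
                           list(name = "p1", ranges = cbind(1, 6)),
                           list(name = "p2", ranges = cbind(7, 12)))))
  pos3 <- extract_codon_positions(two, 3)
  expect_equal(ncol(pos3$mat), 4L)
  expect_equal(vapply(pos3$partitions$entries, function(e)
    length(partition_sites(e)), 0L), c(2L, 2L))

  # the three positions tile the site set exactly
  m1 <- extract_codon_positions(aln, 1)$mat
  m2 <- extract_codon_positions(aln, 2)$mat
  m3 <- extract_codon_positions(aln, 3)$mat
  expect_equal(ncol(m1) + ncol(m2) + ncol(m3), ncol(aln$mat))
  expect_equal(sort(c(m1[1, ], m2[1, ], m3[1, ])), sort(aln$mat[1, ]))

  bad <- phylo_alignment(matrix("A", 2, 8, dimnames = list(c("a", "b"), NULL)),
                         "NT", partitions = partition_scheme(list(
                           list(name = "p", ranges = cbind(1, 8)))))
  expect_error(extract_codon_positions(bad, 1), class = "phylocong_frame_error")
  aa <- phylo_alignment(matrix("A", 2, 9, dimnames = list(c("a", "b"), NULL)), "AA")
  expect_error(extract_codon_positions(aa, 1), class = "phylocong_alphabet_error")
})

test_that("trees, character matrices and groupings validate their inputs", {
  tf <- tempfile()
  writeLines("((A:1,B:1):1,(C:1,D:1):1);", tf)
  tr <- read_tree(tf)
  expect_equal(ape::Ntip(tr), 4L)
  expect_equal(tr$Nnode, 3L)

  cmf <- tempfile()
  writeLines(c("taxon\tc1\tc2", "A\t0\t1", "B\t1\t?", "C\t0\t0"), cmf)
  cm <- read_character_matrix(cmf)
  expect_equal(cm$characters, c("c1", "c2"))
  expect_true(is.na(cm$mat["B", "c2"]))

  aln <- aln_from_strings(c(A = "ACDE", B = "ACDE", C = "ACDE", D = "ACDE",
                            E = "ACDE"))
  gf <- tempfile()
  writeLines(c("group\ttaxon", "g1\tA", "g1\tB", "g2\tC", "g3\tD", "g4\tE"), gf)
  grp <- read_grouping(gf, aln)
  expect_equal(lengths(grp$groups), c(g1 = 2L, g2 = 1L, g3 = 1L, g4 = 1L))

  writeLines(c("group\ttaxon", "g1\tA", "g2\tC", "g3\tD", "g4\tZ"), gf)
  expect_error(read_grouping(gf, aln), class = "phylocong_unknown_taxon_error")

  expect_error(taxon_grouping(list(g1 = "A", g2 = "A", g3 = "C", g4 = "D"), aln),
               class = "phylocong_disjointness_error")
  expect_error(taxon_grouping(list(g1 = "A", g2 = "B", g3 = "C"), aln),
               class = "phylocong_grouping_error")
})
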