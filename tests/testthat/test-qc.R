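test_that("Bowker statistic matches the closed form and handles edge cases", {
  # single informative off-diagonal pair: n_AC = 3, n_CA = 0 -> B = 3, df = 1
  a <- aln_from_strings(c(x = "AAACC", y = "CCCCC"))
  b <- bowker_test(a, "x", "y")
  expect_equal(b$B, 3)
  expect_equal(b$df, 1L)
  expect_equal(b$p, pchisq(3, 1, lower.tail = FALSE), tolerance = 1e-7)
  expect_equal(round(b$p, 4), 0.0833)

  # identical sequences: df = 0 => B = 0, p = 1
  id <- bowker_test(aln_from_strings(c(x = "AAAA", y = "AAAA")), "x", "y")
  expect_equal(id$B, 0)
  expect_equal(id$df, 0L)
  expect_equal(id$p, 1)

  # exactly symmetric divergence table: B = 0, p = 1
  s <- bowker_test(aln_from_strings(c(x = "ACAC", y = "CACA")), "x", "y")
  expect_equal(s$B, 0)
  expect_equal(s$p, 1)

  # zero comparable sites: flagged, p missing (not 1)
  z <- bowker_test(aln_from_strings(c(x = "A-A-", y = "-C-C")), "x", "y")
  expect_true(z$insufficient)
  expect_true(is.na(z$p))

  # pair-swap invariance
  set.seed(21)
  m <- matrix(sample(c("A", "C", "G", "T", "-"), 400, TRUE), 2, 200,
              dimnames = list(c("u", "v"), NULL))
  al <- phylo_alignment(m, "NT")
  b1 <- bowker_test(al, "u", "v"); b2 <- bowker_test(al, "v", "u")
  expect_equal(b1$B, b2$B)
  expect_equal(b1$df, b2$df)
})

test_that("Bowker agrees with the McNemar-Bowker test on a dense table", {
  set.seed(3)
  m <- matrix(sample(c("A", "C", "G", "T"), 2000, TRUE,
                     prob = c(.4, .3, .2, .1)), 2, 1000,
              dimnames = list(c("u", "v"), NULL))
  al <- phylo_alignment(m, "NT")
  b <- bowker_test(al, "u", "v")
  tab <- table(factor(m[1, ], levels = c("A", "C", "G", "T")),
               factor(m[2, ], levels = c("A", "C", "G", "T")))
  mc <- stats::mcnemar.test(tab, correct = FALSE)
  expect_equal(b$B, unname(mc$statistic), tolerance = 1e-12)
  expect_equal(b$df, unname(mc$parameter))
  expect_equal(b$p, unname(mc$p.value), tolerance = 1e-12)
})

test_that("pairwise symmetry summarises the median p and flags undefined pairs", {
  al <- aln_from_strings(c(a = "ACDE", b = "ACDE", c = "ACDE"))
  ps <- pairwise_symmetry(al)
  expect_equal(nrow(ps$pairs), 3L)
  expect_equal(ps$median_p, 1)
  expect_error(pairwise_symmetry(aln_from_strings(c(a = "ACDE"))),
               class = "phylocong_argument_error")
})

test_that("RCFV matches hand computations and its invariances", {
  # identical composition -> 0
  expect_equal(rcfv(aln_from_strings(c(a = "ACACAC", b = "CACACA")))$rcfv, 0)
  # binary two-taxon extreme: per-state mean 0.5, |dev| = 0.5 each,
  # RCFV = (0.5+0.5)*2/2 = 1
  r <- rcfv(aln_from_strings(c(t1 = "AAAAAAAAAA", t2 = "RRRRRRRRRR")))
  expect_equal(r$rcfv, 1.0)
  expect_true(r$masked)  # inclusive bound at the default 0.1 threshold

  # invariance under taxon reordering and state relabeling
  set.seed(31)
  m <- matrix(sample(c("A", "C", "G", "T"), 5 * 60, TRUE,
                     prob = c(.4, .3, .2, .1)), 5, 60,
              dimnames = list(paste0("t", 1:5), NULL))
  v1 <- rcfv(phylo_alignment(m, "NT"))$rcfv
  v2 <- rcfv(phylo_alignment(m[sample(5), ], "NT"))$rcfv
  relab <- chartr("ACGT", "TGCA", m)
  v3 <- rcfv(phylo_alignment(relab, "NT"))$rcfv
  expect_equal(v1, v2)
  expect_equal(v1, v3)

  # taxa without data are excluded from n
  m2 <- rbind(t1 = rep("A", 6), t2 = rep("R", 6), t3 = rep("-", 6))
  expect_equal(rcfv(phylo_alignment(m2, "AA"))$n_taxa_with_data, 2L)
  expect_equal(rcfv(phylo_alignment(m2, "AA"))$rcfv, 1.0)
})

test_that("RCFV masking removes exactly the flagged partitions", {
  # three partitions; p2 engineered heterogeneous (opposite compositions);
  # homogeneous blocks long enough that sampling noise stays below 0.1
  set.seed(17)
  hom1 <- matrix(sample(c("A", "C", "G", "T"), 4 * 600, TRUE), 4, 600)
  het <- rbind(matrix(sample(c("A", "C"), 2 * 100, TRUE, prob = c(.9, .1)), 2, 100),
               matrix(sample(c("G", "T"), 2 * 100, TRUE, prob = c(.9, .1)), 2, 100))
  hom2 <- matrix(sample(c("A", "C", "G", "T"), 4 * 500, TRUE), 4, 500)
  m <- cbind(hom1, het, hom2)
  rownames(m) <- paste0("t", 1:4)
  aln <- phylo_alignment(m, "NT", partitions = partition_scheme(list(
    list(name = "p1", ranges = cbind(1, 600)),
    list(name = "p2", ranges = cbind(601, 700)),
    list(name = "p3", ranges = cbind(701, 1200)))))
  res <- mask_by_rcfv(aln)
  expect_equal(res$report$masked, c(FALSE, TRUE, FALSE))
  expect_equal(ncol(res$alignment$mat), 1100L)
  expect_equal(vapply(res$alignment$partitions$entries, `[[`, "", "name"),
               c("p1", "p3"))
  # survivors are all below threshold
  surv <- vapply(res$alignment$partitions$entries, function(e)
    rcfv(res$alignment, e$name)$rcfv, 0)
  expect_true(all(surv < 0.1))
  # all partitions masked -> clean error
  crit0 <- filter_criteria(rcfv_threshold = 0)
  expect_error(mask_by_rcfv(aln, crit0), class = "phylocong_empty_error")
})

test_that("completeness scores count unambiguous cells", {
  full <- aln_from_strings(c(a = "ACDE", b = "ACDE"))
  expect_equal(completeness(full)$C_a, 1.0)
  two <- aln_from_strings(c(a = "AC-E", b = "A-DE"))
  cp <- completeness(two)
  expect_equal(cp$C_a, 0.75)
  expect_equal(unname(cp$C_r), c(0.75, 0.75))
  disj <- aln_from_strings(c(a = "AC--", b = "--DE"))
  expect_equal(unname(completeness(disj)$C_ij["a", "b"]), 0)
})

test_that("decisive filter keeps exactly the compliant partitions", {
  aln <- decisive_fixture()
  res <- decisive_filter(aln)
  expect_setequal(res$surviving, c("ok1", "ok2"))
  expect_equal(sum(res$report$decisive), 2L)
  # boundary semantics: 499 sites fails, 500 passes; exactly 30% ambiguous fails
  expect_false(res$report$decisive[res$report$partition == "short1"])
  expect_false(res$report$decisive[res$report$partition == "amb_edge"])
  expect_true(res$report$pass_length[res$report$partition == "ok1"])
})
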