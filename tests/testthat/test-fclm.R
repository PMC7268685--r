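make_grouping <- function(aln, sizes) {
  taxa <- aln$taxa
  idx <- split(taxa[seq_len(sum(sizes))], rep(1:4, sizes))
  names(idx) <- paste0("g", 1:4)
  taxon_grouping(idx, aln)
}

test_that("quartet enumeration is the product when small, a seeded sample when large", {
  aln <- aln_from_strings(setNames(rep("ACDE", 12), paste0("t", 1:12)))
  g1 <- make_grouping(aln, c(1, 1, 1, 1))
  expect_equal(nrow(enumerate_quartets(g1, 100, 1)), 1L)
  g2 <- make_grouping(aln, c(2, 3, 1, 1))
  q2 <- enumerate_quartets(g2, 100, 1)
  expect_equal(nrow(q2), 6L)
  expect_equal(anyDuplicated(apply(q2, 1, paste, collapse = "|")), 0L)
  g3 <- make_grouping(aln, c(3, 3, 3, 3))
  q3a <- enumerate_quartets(g3, 50, 42)
  q3b <- enumerate_quartets(g3, 50, 42)
  expect_identical(q3a, q3b)
  expect_equal(nrow(q3a), 50L)
  expect_equal(anyDuplicated(apply(q3a, 1, paste, collapse = "|")), 0L)
  q3c <- enumerate_quartets(g3, 50, 43)
  expect_false(identical(q3a, q3c))
})

test_that("simplex regions follow the nearest-prototype rule", {
  expect_equal(assign_region(1, 0, 0), "C1")
  expect_equal(assign_region(0, 1, 0), "C2")
  expect_equal(assign_region(0, 0, 1), "C3")
  expect_equal(assign_region(1/3, 1/3, 1/3), "CTR")
  expect_equal(assign_region(0.5, 0.5, 0), "E12")
  expect_equal(assign_region(0.5, 0, 0.5), "E13")
  expect_equal(assign_region(0.9, 0.05, 0.05), "C1")
  expect_equal(assign_region(0.4, 0.35, 0.25), "CTR")
  expect_error(assign_region(0.5, 0.5, 0.5), class = "phylocong_argument_error")
})

test_that("quartet evaluation recovers a perfectly supported topology", {
  set.seed(1)
  g1 <- sample(c("A", "C", "G", "T"), 200, TRUE)
  g2 <- sample(c("A", "C", "G", "T"), 200, TRUE)
  aln <- phylo_alignment(rbind(a = g1, b = g1, c = g2, d = g2), "NT")
  m <- subst_model("NT", freqs = state_freqs(aln))
  ev <- evaluate_quartet(aln, c("a", "b", "c", "d"), m, seed = 5)
  expect_false(ev$skipped)
  expect_gt(ev$p[1], 0.99)
  expect_equal(ev$region, "C1")
  expect_equal(sum(ev$p), 1, tolerance = 1e-10)

  # constant sites: full symmetry -> centre
  cm <- matrix("A", 4, 50, dimnames = list(c("a", "b", "c", "d"), NULL))
  ev2 <- evaluate_quartet(phylo_alignment(cm, "NT"), c("a", "b", "c", "d"),
                          m, seed = 5)
  expect_equal(ev2$p, rep(1/3, 3), tolerance = 1e-6)
  expect_equal(ev2$region, "CTR")

  # no usable columns -> skipped
  gap <- phylo_alignment(rbind(a = c("A", "-"), b = c("-", "A"),
                               c = c("A", "A"), d = c("A", "A")), "NT")
  ev3 <- evaluate_quartet(gap, c("a", "b", "c", "d"), m)
  expect_true(ev3$skipped)
  expect_equal(ev3$reason, "insufficient sites")
})

test_that("relabeling groups 3 and 4 permutes topologies 2 and 3", {
  set.seed(2)
  # shallow tree: unsaturated data gives a sharp optimum, so both labelings
  # converge to the same maxima
  tr <- simulate_tree(8, height = 0.4, seed = 31)
  aln <- simulate_alignment(tr, c(p = 250L), subst_model("NT"), seed = 32)
  g <- taxon_grouping(list(g1 = tr$tip.label[1:2], g2 = tr$tip.label[3:4],
                           g3 = tr$tip.label[5:6], g4 = tr$tip.label[7:8]), aln)
  m <- subst_model("NT", freqs = state_freqs(aln))
  q <- enumerate_quartets(g, 100, 7)
  qs <- q[, c(1, 2, 4, 3)]
  for (i in c(1, 5, 9)) {
    e1 <- evaluate_quartet(aln, q[i, ], m, seed = 99)
    e2 <- evaluate_quartet(aln, qs[i, ], m, seed = 99)
    expect_equal(e1$l[1], e2$l[1], tolerance = 1e-4)
    expect_equal(e1$l[2:3], e2$l[3:2], tolerance = 1e-4)
    expect_equal(e1$p[2:3], e2$p[3:2], tolerance = 1e-3)
  }
})

test_that("hypothesis runs are deterministic and aggregate to 100%", {
  tr <- simulate_tree(10, height = 0.5, seed = 51)
  sp <- strengthen_split(tr, internal_length = 0.3)
  aln <- simulate_alignment(sp$tree, c(p = 300L), subst_model("NT"), seed = 52)
  grp <- taxon_grouping(setNames(sp$parts, paste0("g", 1:4)), aln)
  r1 <- run_hypothesis(aln, grp, cap = 25L, seed = 5L, shape = 1)
  r2 <- run_hypothesis(aln, grp, cap = 25L, seed = 5L, shape = 1)
  expect_identical(r1$quartets, r2$quartets)
  expect_equal(sum(r1$region_pct), 100, tolerance = 1e-9)
  expect_equal(r1$n_sampled, r1$n_evaluated + r1$n_skipped)
  # the generating split dominates
  expect_gt(r1$region_pct["C1"], 50)
  expect_error(taxon_grouping(list(g1 = character(0), g2 = "a", g3 = "b",
                                   g4 = "c"), aln),
               class = "phylocong_grouping_error")
})

test_that("star-tree simulations spread support over all three corners", {
  # internal branch of length zero: no topology should dominate
  tr <- simulate_tree(12, seed = 61)
  sp <- strengthen_split(tr, internal_length = 0)
  aln <- simulate_alignment(sp$tree, c(p = 150L), subst_model("NT"), seed = 62)
  grp <- taxon_grouping(setNames(sp$parts, paste0("g", 1:4)), aln)
  res <- run_hypothesis(aln, grp, cap = 60L, seed = 8L, shape = 1)
  expect_true(all(res$corner_pct < 65))
})
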