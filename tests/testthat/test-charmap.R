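test_that("Sankoff matches hand-computed dynamic programming", {
  tr <- quartet_tree()
  s1 <- sankoff(tr, c(A = "0", B = "0", C = "1", D = "1"))
  expect_equal(s1$score, 1)
  expect_setequal(s1$node_sets[[5]], c("0", "1"))  # root is ambiguous

  s2 <- sankoff(tr, c(A = "0", B = "1", C = "0", D = "1"))
  expect_equal(s2$score, 2)

  s3 <- sankoff(tr, c(A = "0", B = "0", C = "0", D = "0"))
  expect_equal(s3$score, 0)
  expect_true(all(vapply(s3$node_sets, identical, TRUE, "0")))
  expect_equal(nrow(s3$changes), 0L)

  # missing tips allow all states
  s4 <- sankoff(tr, c(A = "0", B = "0", C = NA, D = "1"),
                state_list = c("0", "1"))
  expect_equal(s4$score, 1)

  expect_error(sankoff(tr, c(A = "0", B = "0", C = "1", D = "2"),
                       state_list = c("0", "1")),
               class = "phylocong_state_error")
})

test_that("unambiguous branch changes appear exactly where every MPR agrees", {
  tr <- ape::read.tree(text = "(((A:1,B:1):1,C:1):1,(D:1,E:1):1);")
  # A,B = 1, everything else 0: single change on the (A,B) stem
  s <- sankoff(tr, c(A = "1", B = "1", C = "0", D = "0", E = "0"))
  expect_equal(s$score, 1)
  expect_equal(nrow(s$changes), 1L)
  expect_equal(s$changes$from, "0")
  expect_equal(s$changes$to, "1")
})

test_that("Sankoff with unit costs equals Fitch parsimony on binary trees", {
  set.seed(55)
  for (rep in 1:10) {
    tr <- ape::rtree(sample(4:12, 1))
    k <- sample(2:4, 1)
    st <- setNames(sample(as.character(0:(k - 1)), ape::Ntip(tr), TRUE),
                   tr$tip.label)
    ours <- sankoff(tr, st, state_list = as.character(0:(k - 1)))$score
    pd <- phangorn::phyDat(cbind(st[tr$tip.label]), type = "USER",
                           levels = as.character(0:(k - 1)))
    expect_equal(ours, phangorn::parsimony(tr, pd, method = "fitch"))
  }
})

test_that("Mk ER fit matches a grid-search oracle on a two-leaf tree", {
  tr <- ape::read.tree(text = "(A:0.7,B:0.8);")
  f <- mk_fit(tr, c(A = "0", B = "1"), "ER")
  grid <- vapply(seq(log(1e-4), log(900), length.out = 3000), function(lq) {
    m <- mk_model(c("0", "1"), "ER", exp(lq))
    pruning_loglik(tr, rbind(A = 1L, B = 2L), m)$loglik
  }, 0)
  expect_gte(f$logL + 1e-4, max(grid))
  # same-state tips at rate -> 0 give log(1/k) per character and a bound flag
  tr2 <- quartet_tree()
  f2 <- mk_fit(tr2, c(A = "0", B = "0", C = "0", D = "0"),
               state_list = c("0", "1"), structure = "ER")
  expect_true(f2$at_bound)
  expect_equal(f2$logL, log(1/2), tolerance = 1e-5)
})

test_that("Mk fit agrees with an independent implementation", {
  skip_if_not_installed("phytools")
  set.seed(66)
  tr <- ape::rphylo(15, 1, 0)
  m_true <- mk_model(c("a", "b", "c"), "ER", 0.6)
  cm <- simulate_characters(tr, m_true, 1, seed = 8)
  st <- setNames(cm$mat[, 1], cm$taxa)
  ours <- mk_fit(tr, st, "ER")
  ref <- phytools::fitMk(tr, st, model = "ER", pi = "equal")
  expect_equal(ours$logL, ref$logLik, tolerance = 1e-3)
  expect_equal(ours$Q[1, 2], ref$rates[1], tolerance = 0.02)
})

test_that("model selection preserves the nested likelihood ordering", {
  set.seed(77)
  tr <- ape::rphylo(20, 1, 0)
  m_true <- mk_model(c("0", "1", "2"), "ER", 0.8)
  cm <- simulate_characters(tr, m_true, 15, seed = 9)
  sel <- mk_model_select(tr, cm)
  expect_lte(sel$fits$ER$logL, sel$fits$SYM$logL + 1e-6)
  expect_lte(sel$fits$SYM$logL, sel$fits$ARD$logL + 1e-6)
  expect_equal(sel$fits$ER$n_params, 1L)
  expect_equal(sel$fits$SYM$n_params, 3L)
  expect_equal(sel$fits$ARD$n_params, 6L)
  expect_equal(sel$table$AIC,
               2 * sel$table$n_params - 2 * sel$table$logL, tolerance = 1e-9)
})

test_that("marginal reconstruction matches enumeration and its limits", {
  tr3 <- ape::read.tree(text = "((A:0.3,B:0.5):0.4,C:0.9);")
  m3 <- mk_model(c("0", "1", "2"), "ER", 0.7)
  post <- marginal_ancestral(tr3, c(A = "0", B = "1", C = "1"), m3)
  # direct enumeration over the two internal nodes
  po <- ape::reorder.phylo(tr3, "postorder")
  Ps <- lapply(seq_len(nrow(po$edge)), function(e)
    transition_matrix(m3, po$edge.length[e]))
  tipst <- c(A = 1, B = 2, C = 2)
  joint <- matrix(0, 3, 3)
  for (x in 1:3) for (y in 1:3) {
    p <- m3$pi[x]
    for (e in seq_len(nrow(po$edge))) {
      pa <- po$edge[e, 1]; ch <- po$edge[e, 2]
      aval <- function(n) if (n == 4) x else y
      p <- p * if (ch <= 3) Ps[[e]][aval(pa), tipst[po$tip.label[ch]]] else
        Ps[[e]][aval(pa), aval(ch)]
    }
    joint[x, y] <- p
  }
  expect_equal(unname(post["4", ]), rowSums(joint) / sum(joint), tolerance = 1e-10)
  expect_equal(unname(post["5", ]), colSums(joint) / sum(joint), tolerance = 1e-10)
  # tips are point masses on their observed state
  expect_equal(unname(post["1", ]), c(1, 0, 0))
  # rate -> 0 with equal tips: root posterior concentrates on that state
  m0 <- mk_model(c("0", "1"), "ER", 1e-9)
  p0 <- marginal_ancestral(quartet_tree(),
                           c(A = "0", B = "0", C = "0", D = "0"), m0)
  expect_equal(unname(p0["5", "0"]), 1, tolerance = 1e-6)
})

test_that("stochastic mapping is seeded, exact in limits, and parsimony-bounded", {
  tr <- quartet_tree()
  m0 <- mk_model(c("0", "1"), "ER", 1e-9)
  s0 <- scm_sample(tr, c(A = "0", B = "0", C = "0", D = "0"), m0,
                   n_histories = 200, seed = 4)
  expect_true(all(s0$node_freq[, "0"] == 1))
  expect_equal(sum(s0$trans_expected), 0)

  m <- mk_model(c("0", "1"), "ER", 0.4)
  s1 <- scm_sample(tr, c(A = "0", B = "0", C = "1", D = "1"), m,
                   n_histories = 500, seed = 11)
  s2 <- scm_sample(tr, c(A = "0", B = "0", C = "1", D = "1"), m,
                   n_histories = 500, seed = 11)
  expect_identical(s1$node_freq, s2$node_freq)
  expect_identical(s1$trans_expected, s2$trans_expected)
  expect_equal(rowSums(s1$node_freq), rep(1, nrow(s1$node_freq)),
               ignore_attr = TRUE)
  # every sampled history has at least the parsimony minimum of changes
  pars <- sankoff(tr, c(A = "0", B = "0", C = "1", D = "1"))$score
  expect_true(all(s1$jumps_per_history >= pars))
})

test_that("stochastic-map node frequencies converge to the exact marginals", {
  set.seed(88)
  tr <- ape::rphylo(10, 1, 0)
  m <- mk_model(c("0", "1", "2"), "ER", 0.5)
  cm <- simulate_characters(tr, m, 5, seed = 12)
  # first character with tip variation (constant ones make the check trivial)
  j <- which(apply(cm$mat, 2, function(v) length(unique(v))) > 1)[1]
  st <- setNames(cm$mat[, j], cm$taxa)
  fit <- mk_fit(tr, st, "ER", state_list = m$states)
  exact <- marginal_ancestral(tr, st, fit)
  scm <- scm_sample(tr, st, fit, n_histories = 4000, seed = 13)
  se <- sqrt(exact * (1 - exact) / scm$n_histories)
  dev <- abs(scm$node_freq - exact)
  expect_true(all(dev <= 3 * se + 1e-9))
})
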