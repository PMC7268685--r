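test_that("transition matrices are stochastic and match the JC closed form", {
  jc <- subst_model("NT")
  expect_equal(transition_matrix(jc, 0), diag(4), tolerance = 1e-12)
  P <- transition_matrix(jc, 0.1)
  expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-10)
  off <- (1 - exp(-4 * 0.1 / 3)) / 4
  expect_equal(P[1, 2], off, tolerance = 1e-10)
  expect_equal(P[1, 1], 1 - 3 * off, tolerance = 1e-10)
  # stationarity limit
  expect_equal(transition_matrix(jc, 500), matrix(0.25, 4, 4), tolerance = 1e-8)
  expect_error(transition_matrix(jc, -1), class = "phylocong_argument_error")
})

test_that("rate matrices satisfy detailed balance and unit mean rate", {
  set.seed(5)
  ex <- matrix(runif(16, 0.2, 2), 4, 4); ex <- (ex + t(ex)) / 2; diag(ex) <- 0
  f <- c(.4, .3, .2, .1)
  m <- subst_model("NT", ex, f, name = "gtr")
  expect_equal(rowSums(m$Q), rep(0, 4), tolerance = 1e-12)
  expect_equal(-sum(f * diag(m$Q)), 1, tolerance = 1e-12)
  # pi_a Q_ab = pi_b Q_ba
  expect_equal(diag(f) %*% m$Q, t(diag(f) %*% m$Q), tolerance = 1e-12)
  # spectral P agrees with a direct matrix exponential
  P1 <- transition_matrix(m, 0.37)
  P2 <- as.matrix(Matrix::expm(m$Q * 0.37))
  expect_equal(P1, P2, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("discrete-gamma multipliers have mean one and match quadrature", {
  r <- discrete_gamma_rates(1, 4)
  expect_equal(mean(r), 1, tolerance = 1e-8)
  # oracle: conditional means of the quartile segments of Gamma(alpha, alpha)
  oracle <- vapply(1:4, function(i) {
    lo <- qgamma((i - 1) / 4, 1, 1); hi <- qgamma(i / 4, 1, 1)
    integrate(function(x) x * dgamma(x, 1, 1), lo, hi)$value * 4
  }, 0)
  expect_equal(r, oracle, tolerance = 1e-6)
  expect_equal(discrete_gamma_rates(1, 1), 1)
  expect_equal(discrete_gamma_rates(1e9, 4), rep(1, 4))
  r5 <- discrete_gamma_rates(0.3, 8)
  expect_equal(mean(r5), 1, tolerance = 1e-8)
  expect_true(all(diff(r5) > 0))
})

test_that("PAML-format exchangeability files are read correctly", {
  # tiny synthetic file in PAML layout: 19 lower-triangle rows + frequencies
  S <- matrix(0, 20, 20)
  set.seed(9)
  S[lower.tri(S)] <- round(runif(190, 0.1, 5), 4)
  S <- S + t(S)
  f <- round(runif(20, 1, 5), 4); f <- f / sum(f)
  tf <- tempfile(fileext = ".dat")
  con <- file(tf, "w")
  for (i in 2:20) writeLines(paste(S[i, 1:(i - 1)], collapse = " "), con)
  writeLines(paste(round(f, 6), collapse = " "), con)
  close(con)
  got <- read_paml_matrix(tf)
  expect_equal(unname(got$exchange), S, tolerance = 1e-12)
  expect_equal(sum(got$freqs), 1, tolerance = 1e-9)
  m <- subst_model("AA", got$exchange, got$freqs, name = "custom")
  expect_equal(unname(rowSums(m$Q)), rep(0, 20), tolerance = 1e-10)
})

test_that("pruning equals brute-force enumeration over internal states", {
  set.seed(7)
  tr <- ape::rtree(5)
  m <- subst_model("NT", shape = 1, ncat = 4)
  mat <- matrix(sample(c("A", "C", "G", "T", "N", "-"), 5 * 30, TRUE,
                       prob = c(.22, .22, .22, .22, .06, .06)), 5, 30)
  rownames(mat) <- tr$tip.label
  aln <- phylo_alignment(mat, "NT")
  res <- pruning_loglik(tr, aln, m)
  expect_equal(sum(res$site_loglik), res$loglik, tolerance = 1e-9)

  codes <- matrix(match(mat, c("A", "C", "G", "T"), nomatch = 0L), 5, 30,
                  dimnames = dimnames(mat))
  po <- ape::reorder.phylo(tr, "postorder")
  naive_site <- function(j) {
    tot <- 0
    for (r in m$rates) {
      Ps <- lapply(seq_len(nrow(po$edge)), function(e)
        transition_matrix(m, po$edge.length[e], r))
      grid <- as.matrix(expand.grid(rep(list(1:4), tr$Nnode)))
      s <- 0
      for (row in seq_len(nrow(grid))) {
        af <- integer(5 + tr$Nnode)
        af[6:(5 + tr$Nnode)] <- grid[row, ]
        p <- m$pi[af[6]]
        for (e in seq_len(nrow(po$edge))) {
          pa <- po$edge[e, 1]; ch <- po$edge[e, 2]
          if (ch <= 5) {
            obs <- codes[match(po$tip.label[ch], rownames(mat)), j]
            if (obs != 0) p <- p * Ps[[e]][af[pa], obs]
          } else p <- p * Ps[[e]][af[pa], af[ch]]
        }
        s <- s + p
      }
      tot <- tot + s / length(m$rates)
    }
    log(tot)
  }
  naive <- vapply(1:30, naive_site, 0)
  expect_equal(res$site_loglik, naive, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("pruning handles the hand-checkable degenerate cases", {
  tr <- quartet_tree()
  tr$edge.length[] <- 0
  jc <- subst_model("NT")
  a <- aln_from_strings(c(A = "A", B = "A", C = "A", D = "A"), "NT")
  expect_equal(pruning_loglik(tr, a, jc)$loglik, log(0.25), tolerance = 1e-10)
  miss <- aln_from_strings(c(A = "N", B = "N", C = "N", D = "N"), "NT")
  expect_equal(pruning_loglik(tr, miss, jc)$loglik, 0, tolerance = 1e-10)
  expect_error(pruning_loglik(quartet_tree(),
                              aln_from_strings(c(A = "A", B = "A", C = "A"), "NT"),
                              jc),
               class = "phylocong_unknown_taxon_error")
})

test_that("likelihood is invariant to root placement under reversibility", {
  set.seed(13)
  for (rep in 1:3) {
    tr <- ape::rtree(6)
    m <- subst_model("NT", shape = 0.7)
    mat <- matrix(sample(c("A", "C", "G", "T"), 6 * 40, TRUE), 6, 40,
                  dimnames = list(tr$tip.label, NULL))
    aln <- phylo_alignment(mat, "NT")
    un <- ape::unroot(tr)
    l0 <- pruning_loglik(un, aln, m)$loglik
    for (og in tr$tip.label[1:3]) {
      rr <- ape::root(un, outgroup = og, resolve.root = TRUE)
      expect_equal(pruning_loglik(rr, aln, m)$loglik, l0, tolerance = 1e-8)
    }
  }
})
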