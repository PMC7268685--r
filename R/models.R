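#' Construct a time-reversible substitution model
#'
#' A GTR-family model: symmetric exchangeabilities `S`, equilibrium
#' frequencies `pi`, rate matrix `Q = S diag(pi)` with the diagonal set so
#' rows sum to zero, rescaled to one expected substitution per unit branch
#' length (`sum_s pi_s * -Q_ss = 1`). Among-site rate variation uses the
#' discrete-gamma approximation with `ncat` equal-probability categories.
#' The default exchangeabilities are uniform ("poisson"), the
#' dependency-free choice for amino-acid data; empirical matrices can be
#' supplied via [read_paml_matrix()].
#'
#' @param alphabet `"AA"` or `"NT"`.
#' @param exchange symmetric non-negative matrix of exchangeabilities with
#'   zero diagonal, or `NULL` for uniform.
#' @param freqs equilibrium frequencies (simplex), or `NULL` for uniform.
#' @param shape gamma shape `alpha` (`NULL` disables rate variation).
#' @param ncat number of gamma categories (default 4).
#' @param name model tag.
#' @return object of class `subst_model` with `states`, `k`, `Q`, `pi`,
#'   `rates`, `shape`, plus a cached spectral decomposition.
#' @export
subst_model <- function(alphabet = c("AA", "NT"), exchange = NULL,
                        freqs = NULL, shape = NULL, ncat = 4L,
                        name = "poisson") {
  alphabet <- match.arg(alphabet)
  states <- alphabet_def(alphabet)$states
  k <- length(states)
  if (is.null(exchange)) {
    exchange <- matrix(1, k, k); diag(exchange) <- 0
  }
  stopifnot(nrow(exchange) == k, ncol(exchange) == k)
  if (max(abs(exchange - t(exchange))) > 1e-12)
    stop_phylocong("exchangeability matrix must be symmetric", "phylocong_model_error")
  if (any(exchange < 0) || any(diag(exchange) != 0))
    stop_phylocong("exchangeabilities must be non-negative with zero diagonal",
                   "phylocong_model_error")
  if (is.null(freqs)) freqs <- rep(1 / k, k)
  stopifnot(length(freqs) == k)
  if (abs(sum(freqs) - 1) > 1e-8 || any(freqs <= 0))
    stop_phylocong("frequencies must be positive and sum to 1", "phylocong_model_error")
  freqs <- freqs / sum(freqs)
  Q <- exchange %*% diag(freqs)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))
  Q <- Q / mu
  obj <- list(alphabet = alphabet, states = states, k = k, Q = Q, pi = freqs,
              shape = shape, ncat = as.integer(ncat), name = name,
              reversible = TRUE)
  obj$rates <- if (is.null(shape)) 1 else discrete_gamma_rates(shape, ncat)
  obj <- .add_spectral(obj)
  class(obj) <- "subst_model"
  obj
}

# cache P(t) = V diag(exp(lambda t)) W for a reversible Q via the symmetric
# similarity diag(pi)^{1/2} Q diag(pi)^{-1/2}
.add_spectral <- function(obj) {
  d <- sqrt(obj$pi)
  Bs <- diag(d) %*% obj$Q %*% diag(1 / d)
  Bs <- (Bs + t(Bs)) / 2
  eg <- eigen(Bs, symmetric = TRUE)
  obj$eig <- list(lambda = eg$values,
                  V = diag(1 / d) %*% eg$vectors,
                  W = t(eg$vectors) %*% diag(d))
  obj
}

#' @export
print.subst_model <- function(x, ...) {
  cat(sprintf("<subst_model> %s (%s, k = %d)%s\n", x$name, x$alphabet, x$k,
              if (is.null(x$shape)) "" else
                sprintf(", +G%d alpha = %.3g", x$ncat, x$shape)))
  invisible(x)
}

#' Transition probability matrix P(t) = exp(Q t r)
#'
#' @param model a `subst_model` or `mk_model`.
#' @param t branch length (>= 0); @param rate category rate multiplier.
#' @return a stochastic matrix (rows sum to 1).
#' @export
transition_matrix <- function(model, t, rate = 1) {
  if (t < 0) stop_phylocong("branch length must be >= 0", "phylocong_argument_error")
  if (!is.null(model$eig)) {
    e <- model$eig
    P <- e$V %*% (exp(e$lambda * t * rate) * e$W)
  } else {
    P <- as.matrix(Matrix::expm(model$Q * (t * rate)))
  }
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Discrete-gamma rate multipliers (mean of equal-probability categories)
#'
#' Category boundaries are the `i/k` quantiles of Gamma(shape, rate = shape)
#' (mean 1); each multiplier is the exact conditional mean of its segment, so
#' the multipliers average to 1.
#'
#' @param alpha gamma shape (> 0); @param k number of categories.
#' @export
discrete_gamma_rates <- function(alpha, k = 4L) {
  stopifnot(alpha > 0, k >= 1L)
  if (k == 1L) return(1)
  if (alpha > 1e8) return(rep(1, k))
  b <- qgamma(seq(0, 1, length.out = k + 1L), shape = alpha, rate = alpha)
  r <- k * diff(pgamma(b, shape = alpha + 1, rate = alpha))
  r / mean(r)  # renormalize away tail-quadrature round-off
}

#' Read a PAML-format amino-acid exchangeability file
#'
#' The standard `.dat` layout: the lower triangle of the 20x20
#' exchangeability matrix (19 rows) followed by the 20 equilibrium
#' frequencies.
#'
#' @param path file path.
#' @return list with `exchange` (symmetric 20x20) and `freqs`.
#' @export
read_paml_matrix <- function(path) {
  toks <- scan(path, what = numeric(), quiet = TRUE, comment.char = "#")
  need <- 190L + 20L
  if (length(toks) < need)
    stop_phylocong("PAML matrix file too short", "phylocong_parse_error")
  S <- matrix(0, 20, 20)
  pos <- 1L
  for (i in 2:20) {
    S[i, 1:(i - 1)] <- toks[pos:(pos + i - 2L)]
    pos <- pos + i - 1L
  }
  S <- S + t(S)
  freqs <- toks[pos:(pos + 19L)]
  dimnames(S) <- list(AA_STATES, AA_STATES)
  list(exchange = S, freqs = setNames(freqs / sum(freqs), AA_STATES))
}

#' Construct an Mk model for discrete characters
#'
#' Continuous-time Markov model with `k` states and structure ER (one rate),
#' SYM (symmetric rates) or ARD (all rates different). The rate matrix is
#' not normalised: the rate parameters carry the scale relative to the
#' tree's branch-length units (e.g. changes per Myr on a chronogram). The
#' root prior defaults to uniform.
#'
#' @param states character vector of state labels.
#' @param structure `"ER"`, `"SYM"` or `"ARD"`.
#' @param rates numeric vector of rate parameters: length 1 (ER),
#'   `k(k-1)/2` (SYM, row-wise upper triangle) or `k(k-1)` (ARD, row-major
#'   off-diagonals).
#' @param root_prior prior over states at the root (default uniform).
#' @return object of class `mk_model` with `Q`, `pi` (root prior), `k`.
#' @export
mk_model <- function(states, structure = c("ER", "SYM", "ARD"), rates = 1,
                     root_prior = NULL) {
  structure <- match.arg(structure)
  k <- length(states)
  stopifnot(k >= 2L)
  np <- as.integer(switch(structure, ER = 1L, SYM = k * (k - 1L) / 2L,
                          ARD = k * (k - 1L)))
  if (length(rates) != np)
    stop_phylocong(sprintf("%s with %d states needs %d rate(s), got %d",
                           structure, k, np, length(rates)),
                   "phylocong_model_error")
  if (any(rates < 0))
    stop_phylocong("rates must be non-negative", "phylocong_model_error")
  Q <- matrix(0, k, k, dimnames = list(states, states))
  if (structure == "ER") {
    Q[] <- rates[1L]
  } else if (structure == "SYM") {
    Q[upper.tri(Q)] <- rates
    Q[lower.tri(Q)] <- t(Q)[lower.tri(Q)]
  } else {
    idx <- which(row(Q) != col(Q), arr.ind = TRUE)  # row-major off-diagonals
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    Q[idx] <- rates
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  pi <- root_prior %||% rep(1 / k, k)
  stopifnot(length(pi) == k)
  pi <- pi / sum(pi)
  obj <- list(states = states, k = k, Q = Q, pi = pi, structure = structure,
              rates = 1, shape = NULL, ncat = 1L, n_params = np,
              logL = NA_real_, AIC = NA_real_, AICc = NA_real_)
  # symmetric Q with uniform prior diagonalises exactly; ARD falls back to expm
  if (max(abs(Q - t(Q))) < 1e-12) {
    eg <- eigen((Q + t(Q)) / 2, symmetric = TRUE)
    obj$eig <- list(lambda = eg$values, V = eg$vectors, W = t(eg$vectors))
  } else obj$eig <- NULL
  class(obj) <- "mk_model"
  obj
}

#' @export
print.mk_model <- function(x, ...) {
  cat(sprintf("<mk_model> %s, k = %d%s\n", x$structure, x$k,
              if (is.na(x$logL)) "" else
                sprintf(", logL = %.4f, AIC = %.4f", x$logL, x$AIC)))
  invisible(x)
}
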