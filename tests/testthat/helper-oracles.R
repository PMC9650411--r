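# Independent oracles used across tests.  Each is a deliberately naive
# implementation (enumeration, brute force, generalized eigenproblem) kept
# separate from the package's computational path.

# hypergeometric upper tail P(X >= L) by explicit enumeration over choose()
enum_sharing_pvalue <- function(N, M, K, L) {
  if (L == 0) return(1)
  i <- 0:(L - 1)
  1 - sum(choose(M, i) * choose(N - M, K - i)) / choose(N, K)
}

# TOM by the triple loop straight from its definition
brute_tom <- function(a) {
  n <- nrow(a)
  diag(a) <- 0
  k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- sum(a[i, -c(i, j)] * a[-c(i, j), j]) + a[i, j]
    tom[i, j] <- num / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(tom) <- dimnames(a)
  tom
}

# AUC by counting all case-control pairs, ties worth 0.5
brute_auc <- function(values, labels) {
  pos <- values[labels == 1]
  neg <- values[labels == 0]
  s <- 0
  for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  s / (length(pos) * length(neg))
}

# first canonical correlation by the generalized eigenproblem on the full
# covariance matrices
eigen_cc <- function(x, y) {
  xs <- scale(x); ys <- scale(y); n <- nrow(xs)
  sxx <- crossprod(xs) / (n - 1)
  syy <- crossprod(ys) / (n - 1)
  sxy <- crossprod(xs, ys) / (n - 1)
  m <- solve(sxx) %*% sxy %*% solve(syy) %*% t(sxy)
  sqrt(max(0, max(Re(eigen(m, only.values = TRUE)$values))))
}

# Benjamini-Hochberg step-up, written out
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# one-module simulation spec used by several sponge/null tests
one_module_spec <- function(beta, seed, n_samples = 200, n_lnc = 5,
                            n_mr = 15, q = 3, alpha = 1) {
  simulation_spec(
    n_samples = n_samples, n_mrna = n_mr + 5, n_lncrna = n_lnc + 1,
    n_mirna = q, background_target_density = 0,
    modules = list(module_spec(n_lnc, n_mr, q, alpha, beta)),
    seed = seed
  )
}

# mean pairwise correlation among a module's genes in an expression matrix
mean_intramodular_cor <- function(expr, genes) {
  cc <- stats::cor(t(expr[genes, , drop = FALSE]))
  mean(cc[upper.tri(cc)])
}
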