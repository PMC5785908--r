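# Independent oracles and fixture builders shared across the suite.

# truncated power series for exp(S)
expm_series <- function(S, nterms = 20L) {
  out <- diag(nrow(S))
  term <- diag(nrow(S))
  for (k in seq_len(nterms)) {
    term <- term %*% S / k
    out <- out + term
  }
  out
}

# Neumann series for (I + alpha L)^-1, convergent when alpha * rho(L) < 1
neumann_series <- function(L, alpha, nterms = 30L) {
  out <- diag(nrow(L))
  term <- diag(nrow(L))
  for (k in seq_len(nterms)) {
    term <- term %*% (-alpha * L)
    out <- out + term
  }
  out
}

# generic simplex-constrained QP oracle: min g'Qg - 2 g'b over the simplex
qp_simplex_oracle <- function(Q, b) {
  m <- nrow(Q)
  r <- pracma::quadprog(2 * Q, -2 * b,
                        Aeq = matrix(1, 1, m), beq = 1, lb = rep(0, m))
  list(x = r$xmin, objective = r$fval)
}

# oracle for the balanced problem: min (1-lam) g'YKYg + lam g'g over the
# product of the positive and negative simplices
qp_easymkl_oracle <- function(K_sum, y, lam) {
  N <- nrow(K_sum)
  m <- sum(y > 0)
  YKY <- K_sum * tcrossprod(y)
  C <- 2 * ((1 - lam) * YKY + lam * diag(N))
  Aeq <- rbind(as.numeric(y > 0), as.numeric(y < 0))
  r <- pracma::quadprog(C, rep(0, N), Aeq = Aeq, beq = c(1, 1),
                        lb = rep(0, N))
  list(x = r$xmin, objective = r$fval)
}

# strict-tie pairwise AUC oracle: P(pos score > neg score)
pairwise_auc <- function(pos, neg) mean(outer(pos, neg, `>`))

# Erdos-Renyi gene network
er_network <- function(n, p, seed) {
  genes <- sprintf("g%03d", seq_len(n))
  set.seed(seed)
  A <- matrix(0, n, n, dimnames = list(genes, genes))
  ut <- upper.tri(A)
  A[ut] <- as.numeric(runif(sum(ut)) < p)
  A <- A + t(A)
  gene_network(NULL, genes = genes) -> net
  net$adjacency <- A
  net
}

# random PSD kernel with gene dimnames (rank d features)
random_psd_kernel <- function(genes, d = 2L * length(genes), seed = 1L) {
  set.seed(seed)
  X <- matrix(rnorm(length(genes) * d), length(genes), d)
  K <- tcrossprod(X) / d
  dimnames(K) <- list(genes, genes)
  K
}

# random PU instance over synthetic kernels, for solver/oracle comparisons
random_instance <- function(m, n, R, seed) {
  genes <- sprintf("t%03d", seq_len(m + n))
  kernels <- lapply(seq_len(R), function(r)
    random_psd_kernel(genes, d = m + n + 5L, seed = seed * 100L + r))
  bank <- as_kernel_bank(kernels)
  sets <- labeled_gene_sets(genes[seq_len(m)], genes[m + seq_len(n)])
  list(bank = bank, sets = sets, genes = genes)
}

path_network <- function(ids) {
  gene_network(data.frame(from = ids[-length(ids)], to = ids[-1L]))
}
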