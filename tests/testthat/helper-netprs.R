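# Shared fixtures and independent oracles for the test suite.

# Random correlation matrix (PD) for solver tests.
rand_corr <- function(m, jitter = 0.5) {
  A <- matrix(rnorm(m * m), m)
  cov2cor(crossprod(A) + diag(m) * jitter)
}

# Independent convex oracle: accelerated proximal gradient (FISTA) on
# f(b) = 1/2 b'Rb - bt'b + sum(tau |b|). Deliberately shares no code with
# the coordinate-descent path.
fista_lasso <- function(bt, R, tau, iters = 20000) {
  L <- max(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  b <- numeric(length(bt)); y <- b; t <- 1
  for (i in seq_len(iters)) {
    g <- drop(R %*% y) - bt
    u <- y - g / L
    bn <- sign(u) * pmax(abs(u) - tau / L, 0)
    tn <- (1 + sqrt(1 + 4 * t^2)) / 2
    y <- bn + ((t - 1) / tn) * (bn - b)
    b <- bn; t <- tn
  }
  b
}

lasso_objective <- function(b, bt, R, tau) {
  0.5 * drop(crossprod(b, R %*% b)) - sum(bt * b) + sum(tau * abs(b))
}

# Brute-force bipartite betweenness from an M x K adjacency matrix:
# enumerate trait pairs and shared neighbours.
brute_betweenness <- function(A) {
  K <- ncol(A)
  b <- numeric(nrow(A))
  if (K < 2) return(b)
  for (k in seq_len(K - 1)) {
    for (s in (k + 1):K) {
      shared <- which(A[, k] & A[, s])
      if (length(shared) > 0) b[shared] <- b[shared] + 1 / length(shared)
    }
  }
  b
}

# Small reference panel with metadata, built from the genotype simulator.
make_panel <- function(n = 100, m = 20, seed = 1, ld_rho = 0.5,
                       ld_block_size = 10) {
  g <- simulate_genotypes(n, m, ld_block_size = ld_block_size,
                          ld_rho = ld_rho, seed = seed)
  bim <- data.frame(chrom = "1", snp_id = colnames(g$genotypes),
                    pos = seq_len(m), a1 = "A", a2 = "G",
                    stringsAsFactors = FALSE)
  ref_panel(g$genotypes, bim)
}

# Identity-LD ld_matrix (one singleton block per SNP).
identity_ld <- function(m, snp_id = NULL) {
  ld_from_blocks(rep(list(matrix(1, 1, 1)), m), snp_id = snp_id)
}

# gpn object with prescribed p-value topology (pvals < 0.05 are edges at
# the default alpha); betas default to +1.
gpn_from_pvals <- function(P, edge_alpha = 0.05, betas = NULL) {
  M <- nrow(P); K <- ncol(P)
  if (is.null(betas)) betas <- matrix(1, M, K)
  ids <- paste0("snp", seq_len(M))
  stats_list <- lapply(seq_len(K), function(k) {
    sumstats(snp_id = ids, beta = betas[, k], se = 1, pval = P[, k], n = 100)
  })
  names(stats_list) <- paste0("trait", seq_len(K))
  build_gpn(stats_list, edge_alpha = edge_alpha)
}
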