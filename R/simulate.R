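#' Configuration for the multi-trait phenotype simulator
#'
#' Validates and stores the parameters of the matrix-normal multi-trait
#' model `Y = XB + E`: per-causal-SNP effect rows are drawn with
#' cross-trait covariance `Sigma_g / (p m)` where
#' `Sigma_g[k,s] = rg_ks sqrt(h2_k h2_s)` (diagonal `h2_k`), and noise rows
#' with covariance `Sigma_e` (diagonal `1 - h2_k`, off-diagonal `re`).
#' Heritability is defined on the standardized-genotype scale, so realized
#' `Var(XB) / Var(Y)` is approximately `h2` without rescaling.
#'
#' @param n_traits Number of traits K (trait 1 is the target).
#' @param n_samples GWAS sample size N per trait.
#' @param n_snps Number of SNPs M.
#' @param causal_prop Proportion of causal SNPs `p` in `(0, 1]`; exactly
#'   `ceiling(p * M)` rows of B are nonzero.
#' @param h2 Per-trait heritability in `[0, 1)` (recycled to K).
#' @param rg Genetic correlation: scalar (common off-diagonal) or K x K
#'   correlation matrix.
#' @param re Environmental covariance between traits on overlapping
#'   individuals: scalar or K x K matrix (off-diagonals). Default 0.1.
#' @param overlap Sample-overlap scheme: `"none"`, `"partial"`, or
#'   `"complete"`.
#' @param n_shared Number of shared individuals for `overlap = "partial"`
#'   (default `2000`).
#' @param maf_range Minor-allele-frequency range, within `(0, 0.5]`.
#' @param ld_block_size,ld_rho Genotype LD structure: within-block AR(1)
#'   correlation of the latent Gaussians over blocks of `ld_block_size`
#'   SNPs. `ld_rho` is either a scalar (same strength everywhere) or a
#'   range `c(lo, hi)` from which per-block strengths are drawn, giving
#'   heterogeneous LD (and hence LD-score variation) across the genome.
#' @param seed RNG seed.
#' @return A validated list of class `sim_config` (includes the implied
#'   `Sigma_g` and `Sigma_e`).
#' @export
sim_config <- function(n_traits = 5, n_samples = 5000, n_snps = 5000,
                       causal_prop = 0.01, h2 = 0.6, rg = 0.6, re = 0.1,
                       overlap = c("none", "partial", "complete"),
                       n_shared = 2000, maf_range = c(0.05, 0.5),
                       ld_block_size = 50, ld_rho = 0.5, seed = NULL) {
  overlap <- match.arg(overlap)
  K <- n_traits
  h2 <- rep_len(h2, K)
  if (any(h2 < 0 | h2 >= 1)) stop("h2 must be in [0, 1)")
  if (causal_prop <= 0 || causal_prop > 1) stop("causal_prop must be in (0, 1]")
  if (any(maf_range <= 0) || any(maf_range > 0.5)) {
    stop("maf_range must lie in (0, 0.5]")
  }
  if (any(ld_rho < 0) || any(ld_rho >= 1)) stop("ld_rho must be in [0, 1)")
  if (overlap == "partial" && n_shared > n_samples) {
    stop("n_shared exceeds n_samples")
  }
  expand_cor <- function(x, diag_vals, label) {
    if (is.matrix(x)) {
      if (!all(dim(x) == K)) stop(label, " matrix must be K x K")
      M <- x
    } else {
      if (abs(x) > 1) stop(label, " entries must be in [-1, 1]")
      M <- matrix(x, K, K)
    }
    diag(M) <- diag_vals
    M
  }
  rg_mat <- expand_cor(rg, 1, "rg")
  if (any(abs(rg_mat) > 1)) stop("rg entries must be in [-1, 1]")
  sigma_g <- rg_mat * tcrossprod(sqrt(h2))
  sigma_e <- expand_cor(re, 1 - h2, "re")
  if (min(eigen(sigma_g, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("implied genetic covariance Sigma_g is not positive semidefinite")
  }
  if (min(eigen(sigma_e, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("implied environmental covariance Sigma_e is not positive semidefinite")
  }
  structure(list(n_traits = K, n_samples = n_samples, n_snps = n_snps,
                 causal_prop = causal_prop, h2 = h2, rg = rg_mat,
                 re = sigma_e, sigma_g = sigma_g, sigma_e = sigma_e,
                 overlap = overlap, n_shared = n_shared,
                 maf_range = maf_range, ld_block_size = ld_block_size,
                 ld_rho = ld_rho, seed = seed),
            class = "sim_config")
}

# PSD matrix factor for multivariate normal draws.
mvn_factor <- function(S) {
  ev <- eigen(S, symmetric = TRUE)
  ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
}

#' Simulate genotype dosages with blockwise AR(1) LD
#'
#' Gaussian-copula Hardy-Weinberg genotypes: two latent haplotype layers of
#' blockwise AR(1) standard normals are thresholded at the allele-frequency
#' quantile and summed, giving dosages in {0, 1, 2} with expected frequency
#' `maf` and LD controlled by `ld_rho` within blocks (zero between blocks).
#'
#' @param n Number of individuals.
#' @param m Number of SNPs.
#' @param maf_range MAF range for uniform draws (ignored if `maf` given).
#' @param ld_block_size,ld_rho LD structure (block larger than `m` means a
#'   single block).
#' @param seed Optional RNG seed.
#' @param maf Optional fixed per-SNP allele frequencies (length m) to draw
#'   additional cohorts from the same population.
#' @param block_rho Optional fixed per-block AR(1) strengths (same purpose
#'   as `maf`: redraw cohorts from an identical population).
#' @return List: `genotypes` (n x m, columns `snp1..snpm`), `maf` (the
#'   generating frequencies), `freq` (realized a1 frequencies),
#'   `block_rho` (per-block LD strengths used).
#' @export
simulate_genotypes <- function(n, m, maf_range = c(0.05, 0.5),
                               ld_block_size = 50, ld_rho = 0.5,
                               seed = NULL, maf = NULL, block_rho = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(maf)) maf <- runif(m, maf_range[1], maf_range[2])
  stopifnot(length(maf) == m)
  q <- qnorm(maf, lower.tail = FALSE)  # upper-tail threshold per SNP
  starts <- seq(1L, m, by = max(1L, as.integer(ld_block_size)))
  # per-block AR(1) strength: scalar, or a range to draw from (heterogeneous
  # LD across the genome, as in real data)
  rho_blk <- if (!is.null(block_rho)) {
    stopifnot(length(block_rho) == length(starts))
    block_rho
  } else if (length(ld_rho) == 2L) {
    runif(length(starts), ld_rho[1], ld_rho[2])
  } else rep(ld_rho, length(starts))
  haplo <- function() {
    U <- matrix(rnorm(n * m), n, m)
    for (bi in seq_along(starts)) {
      rho <- rho_blk[bi]
      if (rho == 0) next
      st <- starts[bi]
      end <- min(st + ld_block_size - 1L, m)
      if (end > st) {
        s <- sqrt(1 - rho^2)
        for (j in (st + 1L):end) U[, j] <- rho * U[, j - 1L] + s * U[, j]
      }
    }
    U
  }
  G <- (haplo() > rep(q, each = n)) + (haplo() > rep(q, each = n))
  storage.mode(G) <- "double"
  colnames(G) <- paste0("snp", seq_len(m))
  list(genotypes = G, maf = maf, freq = colMeans(G) / 2,
       block_rho = rho_blk)
}

#' Simulate the M x K genetic effect matrix
#'
#' Draws `ceiling(p * m)` causal SNPs uniformly without replacement; each
#' causal row is i.i.d. multivariate normal with covariance
#' `Sigma_g / (p m)`, so the per-trait genetic variance sums to `h2_k`.
#' Non-causal rows are exactly zero.
#'
#' @param m Number of SNPs.
#' @param config A `sim_config`.
#' @param seed Optional RNG seed.
#' @return List: `B` (m x K), `causal` (sorted causal indices).
#' @export
simulate_effects <- function(m, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- config$n_traits
  p <- config$causal_prop
  m_causal <- ceiling(p * m)
  causal <- sort(sample.int(m, m_causal))
  B <- matrix(0, m, K)
  Lg <- mvn_factor(config$sigma_g / (p * m))
  B[causal, ] <- matrix(rnorm(m_causal * K), m_causal, K) %*% t(Lg)
  list(B = B, causal = causal)
}

standardize_cols <- function(X) {
  mu <- colMeans(X)
  sds <- sqrt(colMeans(X^2) - mu^2)
  if (any(sds == 0)) sds[sds == 0] <- 1
  sweep(sweep(X, 2, mu, "-"), 2, sds, "/")
}

#' Simulate a multi-trait GWAS cohort
#'
#' Generates per-trait genotype matrices under the configured overlap
#' scheme (shared individuals reference the same dosages), draws the
#' effect matrix B, and builds phenotypes `Y_k = X*_k B_k + E_k` on
#' standardized genotypes. Environmental noise is correlated across traits
#' only on overlapping rows (covariance `Sigma_e`); non-overlapping
#' individuals receive independent noise with variance `1 - h2_k`.
#'
#' @param config A `sim_config`.
#' @return A list of class `sim_cohort`: `genotypes` (list of K dosage
#'   matrices), `Y` (list of K phenotype vectors), `B`, `causal`,
#'   `genetic` (list of K genetic-component vectors `X* B_k`), `maf`,
#'   `config`.
#' @export
simulate_traits <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  K <- config$n_traits; N <- config$n_samples; M <- config$n_snps
  n_shared <- switch(config$overlap, none = 0L, complete = N,
                     partial = as.integer(config$n_shared))

  # population parameters drawn once and shared by every cohort draw
  maf <- runif(M, config$maf_range[1], config$maf_range[2])
  n_blocks <- length(seq(1L, M, by = max(1L, as.integer(config$ld_block_size))))
  block_rho <- if (length(config$ld_rho) == 2L) {
    runif(n_blocks, config$ld_rho[1], config$ld_rho[2])
  } else rep(config$ld_rho, n_blocks)
  gen <- function(n) {
    if (n == 0) return(NULL)
    simulate_genotypes(n, M, ld_block_size = config$ld_block_size,
                       maf = maf, block_rho = block_rho)$genotypes
  }
  shared_X <- gen(n_shared)
  genotypes <- vector("list", K)
  if (config$overlap == "complete") {
    for (k in seq_len(K)) genotypes[[k]] <- shared_X
  } else {
    for (k in seq_len(K)) {
      own <- gen(N - n_shared)
      genotypes[[k]] <- if (n_shared > 0) rbind(shared_X, own) else own
    }
  }

  eff <- simulate_effects(M, config)

  # noise: correlated across traits on shared rows, independent elsewhere
  E <- matrix(0, N, K)
  if (n_shared > 0) {
    Le <- mvn_factor(config$sigma_e)
    E[seq_len(n_shared), ] <- matrix(rnorm(n_shared * K), n_shared, K) %*% t(Le)
  }
  if (n_shared < N) {
    rows <- (n_shared + 1L):N
    for (k in seq_len(K)) {
      E[rows, k] <- rnorm(length(rows), sd = sqrt(1 - config$h2[k]))
    }
  }

  Y <- vector("list", K)
  genetic <- vector("list", K)
  for (k in seq_len(K)) {
    Xs <- standardize_cols(genotypes[[k]])
    g <- drop(Xs %*% eff$B[, k])
    genetic[[k]] <- g
    Y[[k]] <- g + E[, k]
  }
  names(genotypes) <- names(Y) <- names(genetic) <- paste0("trait", seq_len(K))
  structure(list(genotypes = genotypes, Y = Y, B = eff$B,
                 causal = eff$causal, genetic = genetic, maf = maf,
                 block_rho = block_rho, config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("sim_cohort:", x$config$n_traits, "traits,", x$config$n_samples,
      "individuals,", x$config$n_snps, "SNPs (", length(x$causal),
      "causal ), overlap =", x$config$overlap, "\n")
  invisible(x)
}

#' Per-SNP marginal association tests
#'
#' Simple linear regression of the phenotype on each dosage column (with
#' intercept): effect size, residual-based standard error on `n - 2`
#' degrees of freedom, and a two-sided t-test p-value. Constant dosage
#' columns are dropped with a warning.
#'
#' @param x n x M dosage matrix (column names become snp ids).
#' @param y Phenotype vector.
#' @param bim Optional SNP metadata (`chrom, snp_id, pos, a1, a2`) to carry
#'   through; defaults to positional metadata with alleles A/G.
#' @return A `sumstats` table.
#' @export
marginal_gwas <- function(x, y, bim = NULL) {
  n <- length(y)
  if (n < 3) stop("need at least 3 individuals")
  stopifnot(nrow(x) == n)
  xc <- sweep(x, 2, colMeans(x), "-")
  yc <- y - mean(y)
  sxx <- colSums(xc^2)
  keep <- sxx > 0
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " constant dosage column(s)")
    xc <- xc[, keep, drop = FALSE]
    sxx <- sxx[keep]
  }
  sxy <- drop(crossprod(xc, yc))
  beta <- sxy / sxx
  sse <- sum(yc^2) - beta^2 * sxx
  sse[sse < 0] <- 0
  se <- sqrt(sse / (n - 2) / sxx)
  se[se == 0] <- 1e-300  # numerically perfect fit; keep the record valid
  tstat <- beta / se
  pval <- pmax(2 * pt(-abs(tstat), df = n - 2), 1e-300)
  ids <- colnames(x)[keep]
  if (is.null(ids)) ids <- paste0("snp", which(keep))
  if (is.null(bim)) {
    sumstats(snp_id = ids, beta = beta, se = se, pval = pval, n = n,
             pos = which(keep))
  } else {
    b <- bim[keep, , drop = FALSE]
    sumstats(snp_id = b$snp_id, beta = beta, se = se, pval = pval, n = n,
             chrom = b$chrom, pos = b$pos, a1 = b$a1, a2 = b$a2)
  }
}
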