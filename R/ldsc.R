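#' @name ldsc
#' @title LD score regression on GWAS z-scores
#'
#' @description
#' Moment-based estimation of SNP heritability and cross-trait genetic
#' covariance by regressing (products of) z-scores on LD scores. Under the
#' polygenic model, `E[z1j z2j | lj] = sqrt(N1 N2) rho_g lj / M +
#' rho Ns / sqrt(N1 N2)`: the slope recovers the genetic covariance `rho_g`
#' while the free intercept absorbs phenotypic correlation among `Ns`
#' overlapping samples, so no overlap bookkeeping is needed. The univariate
#' special case (`z1 = z2`) estimates heritability. Standard errors come
#' from a delete-one block jackknife over contiguous SNP blocks; p-values
#' use the normal approximation.
NULL

# OLS (optionally 1/l weighted) slope/intercept with delete-one block
# jackknife; blocks are contiguous in SNP order.
ldsc_regress <- function(y, x, n_blocks, weights = NULL) {
  m <- length(y)
  stopifnot(length(x) == m, n_blocks >= 2)
  if (m < 10 * n_blocks) stop("need at least 10 SNPs per jackknife block")
  if (var(x) == 0) stop("LD-score regressor has zero variance")
  if (is.null(weights)) weights <- rep(1, m)
  fit_wls <- function(idx) {
    w <- weights[idx]; xx <- x[idx]; yy <- y[idx]
    sw <- sum(w); mx <- sum(w * xx) / sw; my <- sum(w * yy) / sw
    sxx <- sum(w * (xx - mx)^2)
    slope <- sum(w * (xx - mx) * (yy - my)) / sxx
    c(slope = slope, intercept = my - slope * mx)
  }
  full <- fit_wls(seq_len(m))
  block_of <- ceiling(seq_len(m) / (m / n_blocks))
  block_of[block_of > n_blocks] <- n_blocks
  jk <- vapply(seq_len(n_blocks),
               function(b) fit_wls(which(block_of != b)), numeric(2))
  jk_se <- sqrt((n_blocks - 1) / n_blocks *
                  rowSums((jk - rowMeans(jk))^2))
  list(slope = unname(full["slope"]), intercept = unname(full["intercept"]),
       slope_se = unname(jk_se[1]), intercept_se = unname(jk_se[2]),
       n_blocks = n_blocks, block_of = block_of)
}

#' @rdname ldsc
#' @param z,z1,z2 Per-SNP z-scores on a common SNP set, in genomic order.
#' @param l Per-SNP LD scores (see [compute_ld_scores()]).
#' @param n,n1,n2 GWAS sample sizes.
#' @param n_blocks Number of contiguous jackknife blocks. Default 200.
#' @param weighted Weight observations by `1/l`? Default `FALSE`
#'   (plain least squares).
#' @return A list of class `ldsc_fit`: `slope`, `intercept`, `se`
#'   (jackknife SE of the slope), `pval` (normal-approximation two-sided p
#'   for slope = 0), `n_blocks`, and `h2` (univariate) or `rho_g`
#'   (cross-trait).
#' @export
univariate_ldsc <- function(z, l, n, n_blocks = 200, weighted = FALSE) {
  m <- length(z)
  r <- ldsc_regress(z^2, n * l / m, n_blocks,
                    weights = if (weighted) 1 / l else NULL)
  structure(list(slope = r$slope, intercept = r$intercept, h2 = r$slope,
                 se = r$slope_se, intercept_se = r$intercept_se,
                 pval = 2 * pnorm(-abs(r$slope / r$slope_se)),
                 n_blocks = n_blocks),
            class = "ldsc_fit")
}

#' @rdname ldsc
#' @export
cross_trait_ldsc <- function(z1, z2, l, n1, n2, n_blocks = 200,
                             weighted = FALSE) {
  m <- length(z1)
  stopifnot(length(z2) == m, length(l) == m)
  r <- ldsc_regress(z1 * z2, sqrt(n1 * n2) * l / m, n_blocks,
                    weights = if (weighted) 1 / l else NULL)
  structure(list(slope = r$slope, intercept = r$intercept, rho_g = r$slope,
                 se = r$slope_se, intercept_se = r$intercept_se,
                 pval = 2 * pnorm(-abs(r$slope / r$slope_se)),
                 n_blocks = n_blocks),
            class = "ldsc_fit")
}

#' @export
print.ldsc_fit <- function(x, ...) {
  lab <- if (!is.null(x$rho_g)) "rho_g" else "h2"
  cat("ldsc_fit:", lab, "=", signif(x$slope, 4), "(se", signif(x$se, 3),
      ", p", signif(x$pval, 3), "); intercept", signif(x$intercept, 4), "\n")
  invisible(x)
}

#' Genetic correlation with jackknife standard error
#'
#' `rg = rho_g / sqrt(h1^2 h2^2)` where the three slopes come from the
#' cross-trait and the two univariate LD score regressions on the same SNPs;
#' the delete-one block jackknife is applied to the ratio itself so its SE
#' reflects the correlated uncertainty of all three slopes.
#'
#' @inheritParams cross_trait_ldsc
#' @return List with `rg`, `se`, `pval`, `n_blocks`.
#' @export
ldsc_rg <- function(z1, z2, l, n1, n2, n_blocks = 200, weighted = FALSE) {
  m <- length(z1)
  x1 <- n1 * l / m; x2 <- n2 * l / m; x12 <- sqrt(n1 * n2) * l / m
  wts <- if (weighted) 1 / l else rep(1, m)
  slope_of <- function(x, y, idx) {
    w <- wts[idx]; sw <- sum(w)
    mx <- sum(w * x[idx]) / sw; my <- sum(w * y[idx]) / sw
    sum(w * (x[idx] - mx) * (y[idx] - my)) / sum(w * (x[idx] - mx)^2)
  }
  # floor the heritability slopes away from zero so leave-one-out
  # replicates cannot blow the ratio up when a slope crosses zero
  rg_of <- function(idx) {
    h1 <- slope_of(x1, z1^2, idx); h2 <- slope_of(x2, z2^2, idx)
    cov12 <- slope_of(x12, z1 * z2, idx)
    cov12 / sqrt(max(h1, 0.01) * max(h2, 0.01))
  }
  full <- rg_of(seq_len(m))
  block_of <- ceiling(seq_len(m) / (m / n_blocks))
  block_of[block_of > n_blocks] <- n_blocks
  jk <- vapply(seq_len(n_blocks),
               function(b) rg_of(which(block_of != b)), numeric(1))
  se <- sqrt((n_blocks - 1) / n_blocks * sum((jk - mean(jk))^2))
  list(rg = full, se = se, pval = 2 * pnorm(-abs(full / se)),
       n_blocks = n_blocks)
}

#' Select traits genetically correlated with the target
#'
#' Runs cross-trait LD score regression of the target trait against each
#' candidate and returns the candidates whose genetic-covariance p-value
#' passes the Bonferroni threshold `alpha / K` (K = number of candidates),
#' ordered by ascending p.
#'
#' @param z_target Per-SNP z-scores of the target trait.
#' @param z_candidates Named list of candidate z-score vectors on the same
#'   SNP set.
#' @param l LD scores.
#' @param n_target Target GWAS sample size.
#' @param n_candidates Candidate sample sizes (recycled if scalar).
#' @param alpha Family-wise significance level. Default 0.05.
#' @param n_blocks Jackknife blocks. Default 200.
#' @return data.frame `(trait, rho_g, se, pval, selected)` ordered by
#'   ascending p, with the per-candidate `ldsc_fit`s as attribute `fits`.
#' @export
select_relevant_traits <- function(z_target, z_candidates, l, n_target,
                                   n_candidates, alpha = 0.05,
                                   n_blocks = 200) {
  K <- length(z_candidates)
  if (K == 0) stop("no candidate traits supplied")
  n_candidates <- rep_len(n_candidates, K)
  traits <- names(z_candidates)
  if (is.null(traits)) traits <- paste0("trait", seq_len(K))
  fits <- lapply(seq_len(K), function(k) {
    cross_trait_ldsc(z_target, z_candidates[[k]], l, n_target,
                     n_candidates[k], n_blocks = n_blocks)
  })
  tab <- data.frame(trait = traits,
                    rho_g = vapply(fits, `[[`, numeric(1), "rho_g"),
                    se = vapply(fits, `[[`, numeric(1), "se"),
                    pval = vapply(fits, `[[`, numeric(1), "pval"),
                    stringsAsFactors = FALSE)
  tab$selected <- tab$pval < alpha / K
  ord <- order(tab$pval)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits[ord]
  tab
}
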