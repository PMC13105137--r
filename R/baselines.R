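#' Clumping + thresholding baseline
#'
#' Greedy LD clumping followed by p-value thresholding: SNPs are visited by
#' ascending p-value and kept as index SNPs unless an already-kept SNP in
#' the same LD block has `r^2 > r2_max` with them. For each p-value
#' threshold the weight vector equals the standardized marginal effect for
#' kept SNPs passing the threshold and zero elsewhere.
#'
#' @param stats A harmonized `sumstats` table.
#' @param ld An `ld_matrix` on the same SNPs, same order.
#' @param r2_max Clumping r-squared threshold. Default 0.1.
#' @param p_grid P-value thresholds. Default
#'   `c(5e-8, 1e-6, 1e-4, 1e-3, 0.01, 0.05, 0.1, 0.5, 1)`.
#' @return List of class `baseline_result`: `method = "ct"`, `weights`
#'   (M x length(p_grid) matrix, one column per threshold), `p_grid`,
#'   `kept` (index-SNP positions).
#' @export
clump_threshold <- function(stats, ld, r2_max = 0.1,
                            p_grid = c(5e-8, 1e-6, 1e-4, 1e-3, 0.01, 0.05,
                                       0.1, 0.5, 1)) {
  if (length(p_grid) == 0) stop("empty p_grid")
  m <- nrow(stats)
  stopifnot(length(ld$snp_id) == m)
  bt <- standardized_marginal_effects(stats)
  block_of <- integer(m)
  for (b in seq_along(ld$index)) block_of[ld$index[[b]]] <- b
  kept <- logical(m)
  for (j in order(stats$pval)) {
    b <- block_of[j]
    ix <- ld$index[[b]]
    others <- ix[kept[ix]]
    if (length(others) == 0 ||
        all(ld$blocks[[b]][match(j, ix), match(others, ix)]^2 <= r2_max)) {
      kept[j] <- TRUE
    }
  }
  W <- vapply(p_grid, function(thr) {
    ifelse(kept & stats$pval < thr, unname(bt), 0)
  }, numeric(m))
  dim(W) <- c(m, length(p_grid))
  dimnames(W) <- list(stats$snp_id, paste0("p<", format(p_grid)))
  structure(list(method = "ct", weights = W, p_grid = p_grid,
                 kept = which(kept)),
            class = "baseline_result")
}

#' Infinitesimal-model posterior mean effects
#'
#' Closed-form posterior mean under an infinitesimal genetic architecture
#' with LD: per block, `w = (R + (m / (n h2)) I)^{-1} beta_tilde`, where
#' `m` is the total SNP count and `h2` the assumed heritability. With
#' identity LD this reduces to uniform shrinkage
#' `beta_tilde / (1 + m / (n h2))`.
#'
#' @param beta_tilde Standardized marginal effects.
#' @param ld An `ld_matrix`.
#' @param h2 Assumed SNP heritability in `(0, 1)` (values above 1 are
#'   accepted for analytic limit checks).
#' @param n GWAS sample size.
#' @param m Total SNP count. Default `length(beta_tilde)`.
#' @return List of class `baseline_result`: `method = "ldpred_inf"`,
#'   `weights` (named vector), `h2`.
#' @export
ldpred_inf <- function(beta_tilde, ld, h2, n, m = length(beta_tilde)) {
  if (h2 <= 0) stop("h2 must be positive")
  stopifnot(length(ld$snp_id) == length(beta_tilde))
  ridge <- m / (n * h2)
  w <- numeric(length(beta_tilde))
  for (b in seq_along(ld$blocks)) {
    ix <- ld$index[[b]]
    A <- ld$blocks[[b]]
    diag(A) <- diag(A) + ridge
    w[ix] <- tryCatch(drop(solve(A, unname(beta_tilde[ix]))),
                      error = function(e) {
                        stop("singular LD system in block ", b,
                             " despite ridge ", signif(ridge, 3))
                      })
  }
  structure(list(method = "ldpred_inf",
                 weights = setNames(w, ld$snp_id), h2 = h2),
            class = "baseline_result")
}

#' Plain summary-statistic lasso baseline
#'
#' Lasso regression on standardized marginal effects with reference-panel
#' LD: delegates to [fit_netprs()] with `lambda1 = 0` and uniform
#' annotation (`s = 1`), fitting every `lambda` in the grid with warm
#' starts along the decreasing path.
#'
#' @param beta_tilde Standardized marginal effects.
#' @param ld An `ld_matrix`.
#' @param lambda_grid L1 penalty values.
#' @param tol,max_iter Passed to [fit_netprs()].
#' @return List of class `baseline_result`: `method = "lasso"`, `weights`
#'   (M x length(lambda_grid)), `lambda_grid`, `models`.
#' @export
lasso_sumstats <- function(beta_tilde, ld, lambda_grid, tol = 1e-4,
                           max_iter = 1000) {
  if (length(lambda_grid) == 0) stop("empty lambda_grid")
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  m <- length(beta_tilde)
  models <- vector("list", length(lambda_grid))
  W <- matrix(0, m, length(lambda_grid),
              dimnames = list(ld$snp_id, paste0("lambda=", signif(lambda_grid, 3))))
  warm <- NULL
  for (i in seq_along(lambda_grid)) {
    pen <- penalty_config(lambda_grid[i], 0, s = NULL, m = m)
    fit <- fit_netprs(beta_tilde, ld, pen, tol = tol, max_iter = max_iter,
                      beta_init = warm)
    warm <- unname(fit$beta_hat)
    models[[i]] <- fit
    W[, i] <- fit$beta_hat
  }
  structure(list(method = "lasso", weights = W, lambda_grid = lambda_grid,
                 models = models),
            class = "baseline_result")
}

#' @export
print.baseline_result <- function(x, ...) {
  cat("baseline_result (", x$method, "): ",
      if (is.matrix(x$weights)) paste(dim(x$weights), collapse = " x ")
      else length(x$weights), " weights\n", sep = "")
  invisible(x)
}
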