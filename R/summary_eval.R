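#' Per-SNP X'y from summary statistics
#'
#' On the standardized genotype/trait scale,
#' `X_m'y = n_m * beta_tilde_m = sqrt(n_m) * z_m`: the marginal statistic a
#' full individual-level regression would have produced, recoverable from
#' the summary table alone.
#'
#' @param stats A harmonized `sumstats` table with per-SNP `n`.
#' @return Numeric vector named by snp_id.
#' @export
estimate_xty <- function(stats) {
  if (is.null(stats$n) || any(!is.finite(stats$n))) {
    stop("per-SNP sample size n is required")
  }
  z <- stats$beta / stats$se
  setNames(sqrt(stats$n) * z, stats$snp_id)
}

#' Partition summary statistics into pseudo train/validation/test sets
#'
#' Draws a training-set statistic from the conditional distribution of
#' `X_tr'y_tr` given the full-sample `X'y` under random subsampling of
#' individuals: mean `(n_tr / N) * X'y` and covariance
#' `n_tr (N - n_tr) / N * Sigma`, where `Sigma` is the per-observation
#' covariance of `x_j y` (approximated blockwise by the reference-panel LD
#' matrix with unit diagonal on the standardized scale). The test statistic
#' is drawn the same way from the remainder, and the validation statistic
#' is the residual, so the three parts sum to the full statistic exactly.
#'
#' @param xty_full Per-SNP `X'y` vector (see [estimate_xty()]).
#' @param N Total GWAS sample size.
#' @param fractions Train/validation/test fractions, positive, summing
#'   to 1. Default `c(0.6, 0.2, 0.2)`.
#' @param ld An `ld_matrix` (required for `sigma_mode = "block"`).
#' @param seed Optional RNG seed for reproducible draws.
#' @param sigma_mode `"block"` (LD blocks, default), `"diagonal"` (identity
#'   per-observation covariance), or `"zero"` (deterministic split).
#' @param scaling `"corrected"` (default; conditional mean `n/N * X'y`,
#'   covariance `n (N - n)/N * Sigma`) or `"literal"` (mean and covariance
#'   both scaled by `(N - n)/N`).
#' @return A list of class `sumstat_partition`: `xty_full`, `xty_train`,
#'   `xty_valid`, `xty_test`, `n_train`, `n_valid`, `n_test`, `N`, `seed`.
#' @export
subsample_sumstats <- function(xty_full, N, fractions = c(0.6, 0.2, 0.2),
                               ld = NULL, seed = NULL,
                               sigma_mode = c("block", "diagonal", "zero"),
                               scaling = c("corrected", "literal")) {
  sigma_mode <- match.arg(sigma_mode)
  scaling <- match.arg(scaling)
  if (length(fractions) != 3 || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    stop("fractions must be three positive values summing to 1")
  }
  if (sigma_mode == "block" && is.null(ld)) stop("ld required for block mode")
  if (!is.null(seed)) set.seed(seed)
  m <- length(xty_full)
  n_train <- round(fractions[1] * N)
  n_test <- round(fractions[3] * N)
  n_valid <- N - n_train - n_test
  stopifnot(n_train > 0, n_valid > 0, n_test > 0)

  draw <- function(xty, n_sub, n_tot) {
    if (scaling == "corrected") {
      mu <- (n_sub / n_tot) * xty
      scale2 <- n_sub * (n_tot - n_sub) / n_tot
    } else {
      mu <- ((n_tot - n_sub) / n_tot) * xty
      scale2 <- (n_tot - n_sub) / n_tot
    }
    if (sigma_mode == "zero" || scale2 == 0) return(mu)
    noise <- if (sigma_mode == "diagonal") {
      rnorm(m)
    } else {
      eps <- numeric(m)
      for (b in seq_along(ld$blocks)) {
        L <- ld_block_factor(ld$blocks[[b]])
        eps[ld$index[[b]]] <- drop(L %*% rnorm(nrow(L)))
      }
      eps
    }
    mu + sqrt(scale2) * noise
  }

  xty_train <- draw(xty_full, n_train, N)
  remainder <- xty_full - xty_train
  xty_test <- draw(remainder, n_test, N - n_train)
  xty_valid <- remainder - xty_test
  structure(list(xty_full = xty_full, xty_train = xty_train,
                 xty_valid = xty_valid, xty_test = xty_test,
                 n_train = n_train, n_valid = n_valid, n_test = n_test,
                 N = N, seed = seed),
            class = "sumstat_partition")
}

#' @export
print.sumstat_partition <- function(x, ...) {
  cat("sumstat_partition:", length(x$xty_full), "SNPs; n =", x$n_train,
      "/", x$n_valid, "/", x$n_test, "(train/valid/test)\n")
  invisible(x)
}

#' Summary-statistic approximation of prediction R-squared
#'
#' Approximates the squared correlation between the phenotype and the PRS
#' built from weights `w` on an evaluation partition, using only marginal
#' statistics:
#' `R2 = [(1/n_eval) sum_m w_m xty_m]^2 / (var_y * var_prs)` with
#' `var_y = N * max_m(SE_m^2 sigma2_m)` and
#' `var_prs = sum_m w_m^2 sigma2_m` (no LD term). `sigma2_m` is a
#' MAF-based estimate of `E[X_m^2]` (`2 f (1-f)` on the allelic scale, 1 on
#' the standardized scale).
#'
#' @param w Weight vector aligned with the partition.
#' @param xty_eval Evaluation-partition `X'y` vector.
#' @param n_eval Evaluation-partition sample size.
#' @param N Total GWAS sample size.
#' @param se Per-SNP marginal-effect standard errors (on the same scale as
#'   `w`); defaults to `1/sqrt(N)`, the standardized-scale value.
#' @param sigma2 Per-SNP genotype variance proxy. Default 1 (standardized).
#' @param trim Optional quantile in `(0, 1)`: use this quantile of
#'   `SE^2 sigma2` instead of the maximum, guarding outlier SEs.
#' @return List of class `r2_estimate`: `value`, `n_eval`, `numerator`,
#'   `var_y`, `var_prs`.
#' @export
approx_r2 <- function(w, xty_eval, n_eval, N, se = NULL, sigma2 = 1,
                      trim = NULL) {
  m <- length(w)
  stopifnot(length(xty_eval) == m)
  if (is.null(se)) se <- rep(1 / sqrt(N), m)
  sigma2 <- rep_len(sigma2, m)
  if (all(w == 0)) {
    warning("all-zero weight vector; R2 is 0")
    return(structure(list(value = 0, n_eval = n_eval, numerator = 0,
                          var_y = NA_real_, var_prs = 0),
                     class = "r2_estimate"))
  }
  se2s <- se^2 * sigma2
  var_y <- N * if (is.null(trim)) max(se2s) else
    unname(stats::quantile(se2s, trim))
  var_prs <- sum(w^2 * sigma2)
  numerator <- (sum(w * xty_eval) / n_eval)^2
  structure(list(value = numerator / (var_y * var_prs), n_eval = n_eval,
                 numerator = numerator, var_y = var_y, var_prs = var_prs),
            class = "r2_estimate")
}

#' @export
print.r2_estimate <- function(x, ...) {
  cat("approximate R2:", signif(x$value, 4), "(n_eval =", x$n_eval, ")\n")
  invisible(x)
}

#' Repeated summary-statistic tuning and evaluation
#'
#' Repeats the subsample / fit-on-train / tune-on-validation /
#' evaluate-on-test cycle with distinct sub-seeds and reports the mean and
#' SD of the test R² across repeats.
#'
#' @param fit_fun `function(beta_tilde_train, n_train, validate)` returning
#'   a weight vector; `validate(w)` gives the approximate validation R² the
#'   procedure may use for internal tuning.
#' @param xty_full,N,fractions,ld,sigma_mode,scaling As in
#'   [subsample_sumstats()].
#' @param n_repeats Number of random splits. Default 10.
#' @param seed Base seed; repeat r uses `seed + r`.
#' @param se,sigma2 Passed to [approx_r2()].
#' @return List: `mean`, `sd`, `r2` (per-repeat values; failed repeats are
#'   `NA` and excluded from the mean with a warning).
#' @export
evaluate_repeated <- function(fit_fun, xty_full, N,
                              fractions = c(0.6, 0.2, 0.2), ld = NULL,
                              n_repeats = 10, seed = 1, se = NULL,
                              sigma2 = 1,
                              sigma_mode = c("block", "diagonal", "zero"),
                              scaling = c("corrected", "literal")) {
  sigma_mode <- match.arg(sigma_mode)
  scaling <- match.arg(scaling)
  r2 <- rep(NA_real_, n_repeats)
  for (r in seq_len(n_repeats)) {
    r2[r] <- tryCatch({
      part <- subsample_sumstats(xty_full, N, fractions, ld,
                                 seed = seed + r, sigma_mode = sigma_mode,
                                 scaling = scaling)
      bt_train <- part$xty_train / part$n_train
      validate <- function(w) {
        approx_r2(w, part$xty_valid, part$n_valid, N, se = se,
                  sigma2 = sigma2)$value
      }
      w <- fit_fun(bt_train, part$n_train, validate)
      approx_r2(w, part$xty_test, part$n_test, N, se = se,
                sigma2 = sigma2)$value
    }, error = function(e) NA_real_)
  }
  if (anyNA(r2)) warning(sum(is.na(r2)), " repeat(s) failed; mean over the rest")
  list(mean = mean(r2, na.rm = TRUE),
       sd = if (sum(!is.na(r2)) > 1) sd(r2, na.rm = TRUE) else 0,
       r2 = r2)
}
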