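#' Soft-thresholding operator
#'
#' Proximal map of the L1 penalty: `S(w, tau) = 0` when `|w| <= tau`, else
#' `sign(w) (|w| - tau)`.
#'
#' @param w Numeric value(s).
#' @param tau Threshold(s), `>= 0`.
#' @return Shrunken value(s).
#' @export
soft_threshold <- function(w, tau) {
  if (any(tau < 0)) stop("tau must be >= 0")
  sign(w) * pmax(abs(w) - tau, 0)
}

#' Annotation-weighted L1 penalty configuration
#'
#' The per-SNP threshold is `tau_m = lambda0 + lambda1 / s_m`: a baseline
#' penalty `lambda0` shared by all SNPs plus an annotation-dependent term
#' that shrinks SNPs with weak network support (small `s_m`) harder. SNPs
#' with strong pleiotropic connections (`s_m` near 1) receive close to the
#' baseline penalty only. `penalty_form = "times"` selects the alternative
#' reading `tau_m = lambda0 + lambda1 * s_m` for sensitivity analyses.
#'
#' @param lambda0 Baseline penalty, `>= 0`.
#' @param lambda1 Annotation penalty, `>= 0`.
#' @param s Normalized annotation: an `annotation` from
#'   [normalize_annotation()], a numeric vector in `(0, 1]`, or `NULL` for
#'   `s = 1` (uniform lasso).
#' @param m Number of SNPs (needed only when `s` is `NULL` or scalar).
#' @param penalty_form `"inverse"` (default) or `"times"`.
#' @return A list of class `penalty_config` with `lambda0`, `lambda1`, `s`,
#'   `tau`.
#' @export
penalty_config <- function(lambda0, lambda1 = 0, s = NULL, m = NULL,
                           penalty_form = c("inverse", "times")) {
  penalty_form <- match.arg(penalty_form)
  if (lambda0 < 0 || lambda1 < 0) stop("lambda0 and lambda1 must be >= 0")
  if (inherits(s, "annotation")) {
    if (is.null(s$s)) stop("annotation is not normalized; run normalize_annotation()")
    s <- unname(s$s)
  }
  if (is.null(s)) {
    if (is.null(m)) stop("m required when s is NULL")
    s <- rep(1, m)
  } else if (length(s) == 1L && !is.null(m)) {
    s <- rep(s, m)
  }
  if (any(s <= 0 | s > 1)) stop("s must lie in (0, 1]")
  tau <- if (penalty_form == "inverse") lambda0 + lambda1 / s
         else lambda0 + lambda1 * s
  structure(list(lambda0 = lambda0, lambda1 = lambda1, s = s, tau = tau,
                 penalty_form = penalty_form),
            class = "penalty_config")
}

#' Fit the annotation-weighted summary-statistic lasso
#'
#' Minimizes `f(beta) = 1/2 beta' R beta - beta_tilde' beta +
#' sum_m tau_m |beta_m|` by cyclic coordinate descent with
#' soft-thresholding, where `R` is the blockwise reference-panel LD matrix
#' and `beta_tilde` the standardized marginal effects. This is the
#' summary-statistic form of the penalized least-squares objective: the
#' coordinate update is `beta_m <- S(beta_tilde_m - sum_{l != m} rho_lm
#' beta_l, tau_m)`, with the LD sum running within `m`'s block (cross-block
#' LD is zero by construction). Coordinates are visited in genomic order;
#' with PSD blocks each sweep is an exact blockwise minimization, so the
#' recorded objective is non-increasing.
#'
#' @param beta_tilde Standardized marginal effects (see
#'   [standardized_marginal_effects()]).
#' @param ld An `ld_matrix` on the same SNPs, in the same order.
#' @param penalty A `penalty_config` (its `tau` must match `beta_tilde`'s
#'   length).
#' @param tol Convergence threshold on the maximum absolute coordinate
#'   change per sweep. Default 1e-4.
#' @param max_iter Sweep cap. Default 1000.
#' @param beta_init Optional warm-start coefficients.
#' @return A list of class `netprs_model`: `beta_hat` (named), `penalty`,
#'   `n_iter`, `converged`, `objective_trace`, `snp_id`.
#' @export
fit_netprs <- function(beta_tilde, ld, penalty, tol = 1e-4, max_iter = 1000,
                       beta_init = NULL) {
  m <- length(beta_tilde)
  if (length(ld$snp_id) != m) stop("beta_tilde and ld disagree on SNP count")
  if (length(penalty$tau) != m) stop("penalty tau and beta_tilde disagree on SNP count")
  if (is.null(beta_init)) beta_init <- numeric(m)
  beta <- numeric(m)
  traces <- vector("list", length(ld$blocks))
  iters <- integer(length(ld$blocks))
  conv <- logical(length(ld$blocks))
  for (b in seq_along(ld$blocks)) {
    ix <- ld$index[[b]]
    r <- .cd_block(unname(beta_tilde[ix]), ld$blocks[[b]],
                   penalty$tau[ix], tol, max_iter, beta_init[ix])
    beta[ix] <- r$beta
    traces[[b]] <- r$trace
    iters[b] <- r$n_iter
    conv[b] <- r$converged
  }
  # global per-sweep objective: blocks are separable, so pad each block's
  # trace with its final (converged) value and sum across blocks
  n_sweeps <- max(iters)
  padded <- vapply(traces, function(tr) {
    c(tr, rep(tr[length(tr)], n_sweeps - length(tr)))
  }, numeric(n_sweeps))
  trace <- rowSums(matrix(padded, nrow = n_sweeps))
  structure(list(beta_hat = setNames(beta, ld$snp_id), penalty = penalty,
                 n_iter = n_sweeps, converged = all(conv),
                 objective_trace = trace, snp_id = ld$snp_id),
            class = "netprs_model")
}

#' @export
print.netprs_model <- function(x, ...) {
  cat("netprs_model: ", sum(x$beta_hat != 0), "/", length(x$beta_hat),
      " nonzero effects; lambda0=", signif(x$penalty$lambda0, 3),
      " lambda1=", signif(x$penalty$lambda1, 3),
      if (x$converged) "; converged" else "; NOT converged",
      " in ", x$n_iter, " sweep(s)\n", sep = "")
  invisible(x)
}

#' Score individuals with a fitted model
#'
#' `PRS_i = sum_m x*_im beta_hat_m`, where `x*` is the dosage standardized
#' with reference allele frequencies (mean `2f`, variance `2f(1-f)`);
#' missing dosages are imputed to the mean (standardized 0). Genotype
#' columns must cover the model's SNPs; named columns are matched by
#' `snp_id`, unnamed matrices are assumed aligned.
#'
#' @param genotypes n x M dosage matrix (counts of the model's effect
#'   allele).
#' @param model A `netprs_model`, or a bare named/unnamed weight vector.
#' @param freq Reference allele frequencies for the model SNPs.
#' @return Numeric score per individual.
#' @export
score_prs <- function(genotypes, model, freq) {
  w <- if (inherits(model, "netprs_model")) model$beta_hat else model
  ids <- names(w)
  if (!is.null(ids) && !is.null(colnames(genotypes))) {
    miss <- setdiff(ids, colnames(genotypes))
    if (length(miss) > 0) {
      stop("genotypes lack model SNP(s): ",
           paste(head(miss, 5), collapse = ", "),
           if (length(miss) > 5) " ..." else "")
    }
    genotypes <- genotypes[, ids, drop = FALSE]
  } else if (ncol(genotypes) != length(w)) {
    stop("genotype columns do not match model SNPs")
  }
  stopifnot(length(freq) == length(w))
  Xs <- sweep(genotypes, 2, 2 * freq, "-")
  Xs <- sweep(Xs, 2, sqrt(2 * freq * (1 - freq)), "/")
  Xs[is.na(Xs)] <- 0
  drop(Xs %*% w)
}

#' Default penalty grids for tuning
#'
#' The baseline grid is a set of fractions of `max |beta_tilde|` (the
#' smallest penalty that zeroes every coordinate at the first sweep); the
#' annotation grid is expressed through the extra penalty placed on the
#' weakest-annotated SNP: `lambda1 = mult * min(s) * lambda0_ref`, so
#' `mult = 1` roughly doubles the penalty on floor-annotation SNPs while
#' leaving top-annotation SNPs nearly untouched.
#'
#' @param beta_tilde Standardized marginal effects.
#' @param s Normalized annotation vector (or `NULL` for uniform).
#' @param lambda0_fracs Fractions of `max |beta_tilde|`.
#' @param lambda1_mults Multipliers for the annotation penalty (0 = plain
#'   lasso included).
#' @return List with `lambda0` and `lambda1` grids.
#' @export
default_lambda_grids <- function(beta_tilde, s = NULL,
                                 lambda0_fracs = c(0.8, 0.5, 0.3, 0.18, 0.1, 0.05),
                                 lambda1_mults = c(0, 0.5, 1, 2)) {
  lmax <- max(abs(beta_tilde))
  lambda0 <- sort(lmax * lambda0_fracs, decreasing = TRUE)
  s_min <- if (is.null(s)) 1 else min(s)
  lambda0_ref <- stats::median(lambda0)
  list(lambda0 = lambda0, lambda1 = sort(lambda1_mults) * s_min * lambda0_ref)
}

#' Tune the penalty over a (lambda0, lambda1) grid
#'
#' Fits every grid cell (warm-starting along the decreasing-`lambda0` path
#' within each `lambda1`) and returns the model maximizing the supplied
#' validation criterion. Ties are broken toward larger `lambda0`, then
#' larger `lambda1` (the sparser model). Cells whose evaluation fails are
#' excluded from the argmax.
#'
#' @param beta_tilde,ld As in [fit_netprs()].
#' @param s Normalized annotation vector (or `NULL` for uniform lasso).
#' @param lambda0_grid,lambda1_grid Numeric grids (non-empty).
#' @param evaluator `function(model)` returning a validation R² (scalar;
#'   `NA` or an error marks the cell invalid).
#' @param tol,max_iter Passed to [fit_netprs()].
#' @param penalty_form Passed to [penalty_config()].
#' @return List of class `netprs_tune`: `best` (a `netprs_model`), `grid`
#'   (data.frame `lambda0, lambda1, r2, n_nonzero, converged`), `best_cell`.
#' @export
tune_grid <- function(beta_tilde, ld, s, lambda0_grid, lambda1_grid,
                      evaluator, tol = 1e-4, max_iter = 1000,
                      penalty_form = c("inverse", "times")) {
  penalty_form <- match.arg(penalty_form)
  if (length(lambda0_grid) == 0 || length(lambda1_grid) == 0) {
    stop("empty penalty grid")
  }
  m <- length(beta_tilde)
  lambda0_grid <- sort(lambda0_grid, decreasing = TRUE)
  grid <- expand.grid(lambda0 = lambda0_grid, lambda1 = lambda1_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$r2 <- NA_real_; grid$n_nonzero <- NA_integer_; grid$converged <- NA
  models <- vector("list", nrow(grid))
  cell <- 0L
  for (l1 in lambda1_grid) {
    warm <- NULL
    for (l0 in lambda0_grid) {
      cell <- cell + 1L
      pen <- penalty_config(l0, l1, s = s, m = m, penalty_form = penalty_form)
      fit <- fit_netprs(beta_tilde, ld, pen, tol = tol, max_iter = max_iter,
                        beta_init = warm)
      warm <- unname(fit$beta_hat)
      models[[cell]] <- fit
      grid$n_nonzero[cell] <- sum(fit$beta_hat != 0)
      grid$converged[cell] <- fit$converged
      r2 <- tryCatch(evaluator(fit), error = function(e) NA_real_)
      grid$r2[cell] <- if (is.numeric(r2) && length(r2) == 1 && is.finite(r2))
        r2 else NA_real_
    }
  }
  if (all(is.na(grid$r2))) stop("validation failed on every grid cell")
  # argmax with ties toward larger lambda0, then larger lambda1
  ord <- order(grid$r2, grid$lambda0, grid$lambda1, decreasing = TRUE,
               na.last = TRUE)
  best_cell <- ord[1]
  structure(list(best = models[[best_cell]], grid = grid,
                 best_cell = best_cell),
            class = "netprs_tune")
}

#' @export
print.netprs_tune <- function(x, ...) {
  b <- x$grid[x$best_cell, ]
  cat("netprs_tune: best lambda0=", signif(b$lambda0, 3), " lambda1=",
      signif(b$lambda1, 3), " validation R2=", signif(b$r2, 4), " (",
      nrow(x$grid), " cells)\n", sep = "")
  invisible(x)
}
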