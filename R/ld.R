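#' Blockwise LD matrix from a reference panel
#'
#' Estimates linkage disequilibrium as Pearson correlations of mean-imputed,
#' standardized dosages within contiguous SNP blocks; correlations between
#' SNPs in different blocks are treated as exactly zero. Blocks never span
#' chromosomes. Off-diagonal entries are shrunk toward zero by
#' `(1 - shrinkage)`, which keeps the unit diagonal and makes each block
#' strictly positive definite for `shrinkage > 0` (a convex combination of a
#' PSD sample correlation matrix with the identity); any residual negative
#' eigenvalues from round-off are clipped at zero.
#'
#' @param panel A `ref_panel`.
#' @param window Block extent: number of SNPs (`window_type = "snp"`,
#'   default 250) or a base-pair span (`window_type = "bp"`).
#' @param shrinkage Off-diagonal shrinkage factor in `[0, 1]`. Default 0.1.
#' @param window_type `"snp"` or `"bp"`.
#' @return A list of class `ld_matrix`: `blocks` (list of correlation
#'   matrices), `index` (list of SNP-column index vectors), `snp_id`,
#'   `shrinkage`, `n` (panel size).
#' @export
compute_ld <- function(panel, window = 250, shrinkage = 0.1,
                       window_type = c("snp", "bp")) {
  window_type <- match.arg(window_type)
  stopifnot(window > 0, shrinkage >= 0, shrinkage <= 1)
  X <- panel$genotypes
  if (nrow(X) < 2) stop("need at least 2 individuals for LD estimation")
  # mean-impute missing dosages, then standardize
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- mu[j]
  }
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    stop("monomorphic SNP(s) in panel: ",
         paste(head(panel$bim$snp_id[sds == 0], 5), collapse = ", "))
  }
  index <- ld_block_index(panel$bim, window, window_type)
  blocks <- lapply(index, function(ix) {
    R <- cor(X[, ix, drop = FALSE])
    if (shrinkage > 0) {
      R <- (1 - shrinkage) * R
      diag(R) <- 1
    }
    psd_clip(R)
  })
  structure(list(blocks = blocks, index = index, snp_id = panel$bim$snp_id,
                 shrinkage = shrinkage, n = nrow(X)),
            class = "ld_matrix")
}

# Contiguous block boundaries: at most `window` SNPs (or a base-pair span)
# per block, never crossing a chromosome boundary.
ld_block_index <- function(bim, window, window_type) {
  m <- nrow(bim)
  out <- list()
  start <- 1L
  for (j in seq_len(m)) {
    new_block <- FALSE
    if (j > start) {
      if (bim$chrom[j] != bim$chrom[start]) new_block <- TRUE
      else if (window_type == "snp" && (j - start + 1L) > window) new_block <- TRUE
      else if (window_type == "bp" && (bim$pos[j] - bim$pos[start]) > window) new_block <- TRUE
    }
    if (new_block) {
      out[[length(out) + 1L]] <- start:(j - 1L)
      start <- j
    }
  }
  out[[length(out) + 1L]] <- start:m
  out
}

# Clip negative eigenvalues at zero (numerical backstop; restores the unit
# diagonal, whose drift after clipping is at round-off level).
psd_clip <- function(R) {
  if (nrow(R) == 1L) return(matrix(1, 1, 1, dimnames = dimnames(R)))
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) >= 0) return(R)
  v <- pmax(ev$values, 0)
  R2 <- ev$vectors %*% (v * t(ev$vectors))
  R2 <- (R2 + t(R2)) / 2
  diag(R2) <- 1
  dimnames(R2) <- dimnames(R)
  R2
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat("ld_matrix:", length(x$snp_id), "SNPs in", length(x$blocks),
      "block(s); shrinkage", x$shrinkage, "\n")
  invisible(x)
}

#' Expand a blockwise LD matrix to a dense matrix
#'
#' Intended for small problems (tests, diagnostics); cross-block entries are
#' zero by construction.
#' @param ld An `ld_matrix`.
#' @return Dense M x M matrix.
#' @export
ld_as_matrix <- function(ld) {
  m <- length(ld$snp_id)
  R <- matrix(0, m, m, dimnames = list(ld$snp_id, ld$snp_id))
  for (b in seq_along(ld$blocks)) {
    ix <- ld$index[[b]]
    R[ix, ix] <- ld$blocks[[b]]
  }
  R
}

#' Construct an `ld_matrix` from explicit blocks
#'
#' Low-level constructor used by the solver tests and by callers that
#' already have block correlation matrices.
#' @param blocks List of symmetric correlation matrices with unit diagonal.
#' @param snp_id Optional SNP ids (defaults to `snp1..snpM`).
#' @param n Nominal panel size (used by LD-score adjustment); default `Inf`.
#' @return An `ld_matrix`.
#' @export
ld_from_blocks <- function(blocks, snp_id = NULL, n = Inf) {
  sizes <- vapply(blocks, nrow, integer(1))
  m <- sum(sizes)
  if (is.null(snp_id)) snp_id <- paste0("snp", seq_len(m))
  ends <- cumsum(sizes)
  index <- mapply(function(s, e) s:e, ends - sizes + 1L, ends, SIMPLIFY = FALSE)
  structure(list(blocks = blocks, index = index, snp_id = snp_id,
                 shrinkage = 0, n = n),
            class = "ld_matrix")
}

#' Per-SNP LD scores
#'
#' `l_j = sum_k r2_jk` over SNP `j`'s block, including the self term (so
#' `l_j >= 1` unadjusted). With `adjust = TRUE` the small-sample correction
#' `r2 - (1 - r2) / (n - 2)` is applied to every term (the self term is
#' unaffected), removing the upward `1/n` bias of squared sample
#' correlations.
#'
#' @param ld An `ld_matrix`.
#' @param adjust Apply the small-sample adjustment? Default `FALSE`.
#' @return Numeric vector of LD scores, named by snp_id.
#' @export
compute_ld_scores <- function(ld, adjust = FALSE) {
  m <- length(ld$snp_id)
  l <- numeric(m)
  for (b in seq_along(ld$blocks)) {
    r2 <- ld$blocks[[b]]^2
    if (adjust) {
      if (!is.finite(ld$n) || ld$n <= 2) stop("panel size needed for adjustment")
      r2 <- r2 - (1 - r2) / (ld$n - 2)
    }
    l[ld$index[[b]]] <- rowSums(r2)
  }
  setNames(l, ld$snp_id)
}

# Symmetric PSD factor L with L %*% t(L) = block; eigen-based so exactly
# singular (clipped) blocks factor cleanly.
ld_block_factor <- function(R) {
  if (nrow(R) == 1L) return(matrix(sqrt(max(R[1, 1], 0)), 1, 1))
  ev <- eigen(R, symmetric = TRUE)
  ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
}
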