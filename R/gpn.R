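#' Signed edge weight between a SNP and a trait
#'
#' The association strength in the genotype-phenotype network is the signed
#' 1-df chi-square quantile of the association p-value:
#' `T = sign(beta) * Q_chi2_1(1 - p)`, which recovers `z^2` with the sign of
#' the effect. `p = 1` yields 0. P-values are clamped below at 1e-300; at
#' the clamp boundary the quantile is replaced by `(beta/se)^2` when `se`
#' is supplied, avoiding quantile saturation for extreme associations.
#'
#' @param beta Signed effect size(s).
#' @param pval P-value(s) in `(0, 1]`.
#' @param se Optional standard error(s), used only for clamped p-values.
#' @param magnitude `"chisq"` (the quantile itself, default) or `"z"` (its
#'   square root, i.e. `|z|`).
#' @return Signed association strength(s).
#' @export
edge_weight <- function(beta, pval, se = NULL, magnitude = c("chisq", "z")) {
  magnitude <- match.arg(magnitude)
  if (any(pval <= 0 | pval > 1)) stop("pval must be in (0, 1]")
  p <- pmax(pval, 1e-300)
  q <- qchisq(p, df = 1, lower.tail = FALSE)
  clamped <- pval < 1e-300
  if (any(clamped) && !is.null(se)) {
    q[clamped] <- (beta[clamped] / se[clamped])^2
  }
  if (magnitude == "z") q <- sqrt(q)
  sgn <- ifelse(beta >= 0, 1, -1)
  ifelse(pval == 1, 0, sgn * q)
}

#' Build the signed genotype-phenotype bipartite network
#'
#' Assembles the M x K signed association-strength matrix `T` from K traits'
#' harmonized summary statistics sharing a common SNP set, along with the
#' p-value matrix that defines the binarized topology (an edge between SNP m
#' and trait k exists iff `p_mk < edge_alpha`).
#'
#' @param stats_list Named list of `sumstats` tables on an identical SNP set
#'   (same ids, same order — harmonize against a common panel first).
#' @param edge_alpha P-value threshold for the binarized topology.
#'   Default 0.05.
#' @param magnitude Edge magnitude convention, see [edge_weight()].
#' @return A list of class `gpn`: `T` (M x K signed strengths), `P` (M x K
#'   p-values), `snp_id`, `traits`, `edge_alpha`.
#' @export
build_gpn <- function(stats_list, edge_alpha = 0.05,
                      magnitude = c("chisq", "z")) {
  magnitude <- match.arg(magnitude)
  stopifnot(length(stats_list) >= 1)
  ids <- stats_list[[1]]$snp_id
  for (k in seq_along(stats_list)) {
    if (!identical(stats_list[[k]]$snp_id, ids)) {
      stop("trait SNP sets differ; intersect/harmonize traits to a common ",
           "SNP set first")
    }
  }
  traits <- names(stats_list)
  if (is.null(traits)) traits <- paste0("trait", seq_along(stats_list))
  Tm <- vapply(stats_list, function(st) {
    edge_weight(st$beta, st$pval, se = st$se, magnitude = magnitude)
  }, numeric(length(ids)))
  Pm <- vapply(stats_list, function(st) st$pval, numeric(length(ids)))
  dim(Tm) <- dim(Pm) <- c(length(ids), length(stats_list))
  dimnames(Tm) <- dimnames(Pm) <- list(ids, traits)
  structure(list(T = Tm, P = Pm, snp_id = ids, traits = traits,
                 edge_alpha = edge_alpha),
            class = "gpn")
}

#' @export
print.gpn <- function(x, ...) {
  cat("gpn:", length(x$snp_id), "SNPs x", length(x$traits),
      "traits; edge_alpha", x$edge_alpha, "\n")
  invisible(x)
}

new_annotation <- function(raw, s, kind, snp_id) {
  structure(list(raw = setNames(raw, snp_id), s = if (is.null(s)) NULL
                 else setNames(s, snp_id), kind = kind),
            class = "annotation")
}

#' Weighted degree centrality of SNPs in the network
#'
#' `d_m = sum_k |T_mk|`: the aggregate association strength of SNP m across
#' all traits. High-degree SNPs are connected strongly to many traits and
#' are candidate pleiotropic variants. The absolute value prevents opposing
#' effect directions from cancelling; `signed = TRUE` gives the raw signed
#' sum for sensitivity analyses.
#'
#' @param gpn A `gpn` object.
#' @param signed Use the signed sum instead of `sum |T|`? Default `FALSE`.
#' @return An `annotation` with `kind = "degree"` (unnormalized).
#' @export
degree_centrality <- function(gpn, signed = FALSE) {
  d <- if (signed) rowSums(gpn$T) else rowSums(abs(gpn$T))
  new_annotation(d, NULL, "degree", gpn$snp_id)
}

#' Approximate betweenness centrality of SNPs in the network
#'
#' On the binarized bipartite graph (edge iff `p_mk < edge_alpha`), any
#' shortest path between two traits has length 2 and passes through a SNP
#' adjacent to both. With `sigma_ks` the number of such shared SNPs,
#' `b_m = sum_{k<s} I(m adjacent to both) / max(sigma_ks, 1)`. Each
#' connected trait pair distributes total mass 1 over its connector SNPs.
#'
#' @param gpn A `gpn` object (its `edge_alpha` defines the topology).
#' @return An `annotation` with `kind = "betweenness"` (unnormalized).
#' @export
betweenness_centrality <- function(gpn) {
  A <- gpn$P < gpn$edge_alpha   # M x K adjacency
  K <- ncol(A)
  b <- numeric(nrow(A))
  if (K >= 2) {
    storage.mode(A) <- "numeric"
    for (k in seq_len(K - 1)) {
      for (s in (k + 1):K) {
        shared <- A[, k] * A[, s]
        n_shared <- sum(shared)
        if (n_shared > 0) b <- b + shared / n_shared
      }
    }
  }
  new_annotation(b, NULL, "betweenness", gpn$snp_id)
}

#' Normalize an annotation to penalty weights in (0, 1]
#'
#' Scales raw centrality scores by their maximum and floors them at
#' `floor`, so the reciprocal penalty `1/s_m` is always defined. When every
#' raw score is zero the annotation carries no information and all weights
#' are set to 1, reducing the annotation-weighted penalty to a uniform
#' lasso.
#'
#' @param raw An `annotation` (or numeric vector of nonnegative scores).
#' @param floor Lower floor for the normalized score, in `(0, 1]`.
#'   Default 0.01.
#' @return An `annotation` with the `s` field populated.
#' @export
normalize_annotation <- function(raw, floor = 0.01) {
  if (floor <= 0 || floor > 1) stop("floor must be in (0, 1]")
  if (is.numeric(raw)) raw <- new_annotation(raw, NULL, "custom", names(raw))
  r <- raw$raw
  if (any(r < 0)) stop("raw annotation scores must be >= 0")
  mx <- max(r)
  s <- if (mx > 0) pmax(r / mx, floor) else rep(1, length(r))
  raw$s <- setNames(s, names(r))
  raw
}

#' @export
print.annotation <- function(x, ...) {
  cat("annotation (", x$kind, "): ", length(x$raw), " SNPs",
      if (!is.null(x$s)) ", normalized" else ", raw only", "\n", sep = "")
  invisible(x)
}

#' Export annotations as a table
#'
#' @param gpn A `gpn` object.
#' @param floor Normalization floor, see [normalize_annotation()].
#' @return data.frame with snp_id, raw and normalized degree and
#'   betweenness scores.
#' @export
annotation_table <- function(gpn, floor = 0.01) {
  d <- normalize_annotation(degree_centrality(gpn), floor)
  b <- normalize_annotation(betweenness_centrality(gpn), floor)
  data.frame(snp_id = gpn$snp_id,
             raw_degree = unname(d$raw), raw_betweenness = unname(b$raw),
             s_degree = unname(d$s), s_betweenness = unname(b$s),
             stringsAsFactors = FALSE)
}
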