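#' One simulated PRS analysis from GWAS to test R-squared
#'
#' Runs the full workflow on one simulated multi-trait cohort: simulate
#' genotypes and K correlated traits (trait 1 is the target), run per-trait
#' marginal GWAS, select relevant traits by cross-trait LD score
#' regression, build the genotype-phenotype network and SNP annotations
#' from the selected traits, then fit and tune the annotation-weighted
#' lasso (and requested baselines) on the target trait. Evaluation runs in
#' one or both of two modes: `"individual"` (random 60/20/20 split of the
#' target cohort; GWAS on the training split, tuning and testing on held
#' out individuals) and `"sumstat"` (GWAS on the full cohort; conditional
#' subsampling of `X'y` into pseudo train/validation/test partitions with
#' reference-panel LD, tuning and testing via the summary-statistic R²
#' approximation).
#'
#' @param K,h2,rg,N,M,causal_prop,re,overlap,n_shared Simulation settings
#'   (see [sim_config()]); `n_shared` defaults to 40% of N.
#' @param seed RNG seed for the whole run.
#' @param n_ref Reference-panel size for LD estimation. Default 500.
#' @param annotation `"degree"`, `"betweenness"`, or `"flat"` (uniform
#'   `s = 1`).
#' @param methods Subset of `c("netprs", "lasso", "netprs_flat")`;
#'   `"netprs_flat"` is the annotation-weighted model run with `s = 1`
#'   (inert annotation).
#' @param modes Subset of `c("individual", "sumstat")`.
#' @param edge_alpha,floor GPN topology threshold and annotation floor.
#' @param ld_window,shrinkage LD estimation settings.
#' @param select_alpha Family-wise level for relevant-trait selection.
#' @param trait_selection `"ldsc"` (keep only candidates passing the
#'   Bonferroni genetic-correlation test) or `"all"` (use every candidate
#'   trait as relevant). At small SNP counts the LD score regression has
#'   little power and `"all"` is the appropriate choice when the
#'   candidates are relevant by design.
#' @param fractions Train/validation/test fractions.
#' @return data.frame with one row per method x mode: `method`, `mode`,
#'   `r2` (test R²), `lambda0`, `lambda1`, `n_nonzero`; the fitted objects
#'   are attached as attribute `details`.
#' @export
prs_study <- function(K = 5, h2 = 0.6, rg = 0.6, N = 2000, M = 1000,
                      causal_prop = 0.01, re = 0.1, overlap = "partial",
                      n_shared = round(0.4 * N), seed = 1, n_ref = 500,
                      annotation = c("degree", "betweenness", "flat"),
                      methods = c("netprs", "lasso"),
                      modes = c("individual", "sumstat"),
                      edge_alpha = 0.05, floor = 0.01, ld_window = 250,
                      shrinkage = 0.1, select_alpha = 0.05,
                      trait_selection = c("ldsc", "all"),
                      fractions = c(0.6, 0.2, 0.2)) {
  annotation <- match.arg(annotation)
  trait_selection <- match.arg(trait_selection)
  modes <- match.arg(modes, several.ok = TRUE)
  cfg <- sim_config(n_traits = K, n_samples = N, n_snps = M,
                    causal_prop = causal_prop, h2 = h2, rg = rg, re = re,
                    overlap = overlap, n_shared = n_shared, seed = seed)
  cohort <- simulate_traits(cfg)

  # reference panel from the same population (same MAFs and LD structure)
  ref <- simulate_genotypes(n_ref, M, ld_block_size = cfg$ld_block_size,
                            maf = cohort$maf, block_rho = cohort$block_rho)
  bim <- data.frame(chrom = "1", snp_id = colnames(ref$genotypes),
                    pos = seq_len(M), a1 = "A", a2 = "G",
                    stringsAsFactors = FALSE)
  panel <- ref_panel(ref$genotypes, bim)
  ld <- compute_ld(panel, window = ld_window, shrinkage = shrinkage)

  # full-sample GWAS per trait
  stats <- lapply(seq_len(K), function(k) {
    marginal_gwas(cohort$genotypes[[k]], cohort$Y[[k]], bim = bim)
  })
  names(stats) <- names(cohort$Y)

  # relevant traits by cross-trait LDSC (target = trait 1)
  s_vec <- NULL
  selection <- NULL
  if (annotation != "flat" && K >= 2) {
    if (trait_selection == "ldsc") {
      l_adj <- compute_ld_scores(ld, adjust = TRUE)
      nb <- max(2, min(200, base::floor(M / 10)))  # >= 10 SNPs per block
      zs <- lapply(stats, function(st) st$beta / st$se)
      selection <- select_relevant_traits(zs[[1]], zs[-1], l_adj, N, N,
                                          alpha = select_alpha, n_blocks = nb)
      relevant <- selection$trait[selection$selected]
    } else {
      relevant <- names(stats)[-1]
    }
    if (length(relevant) > 0) {
      gpn <- build_gpn(stats[relevant], edge_alpha = edge_alpha)
      ann <- if (annotation == "degree") degree_centrality(gpn)
             else betweenness_centrality(gpn)
      s_vec <- unname(normalize_annotation(ann, floor = floor)$s)
    }
  }

  s_of <- function(method) {
    if (method == "netprs") s_vec else NULL  # lasso / netprs_flat: uniform
  }
  l1_of <- function(method, grids) {
    if (method == "lasso") 0 else grids$lambda1
  }

  rows <- list()
  details <- list()
  for (mode in modes) {
    if (mode == "individual") {
      idx <- sample(N)
      n_tr <- round(fractions[1] * N); n_te <- round(fractions[3] * N)
      i_tr <- idx[seq_len(n_tr)]
      i_va <- idx[(n_tr + 1):(N - n_te)]
      i_te <- idx[(N - n_te + 1):N]
      st_tr <- marginal_gwas(cohort$genotypes[[1]][i_tr, , drop = FALSE],
                             cohort$Y[[1]][i_tr], bim = bim)
      bt <- unname(standardized_marginal_effects(st_tr))
      for (method in methods) {
        s_m <- s_of(method)
        grids <- default_lambda_grids(bt, s_m)
        evalr <- function(model) {
          prs <- score_prs(cohort$genotypes[[1]][i_va, , drop = FALSE],
                           model, panel$freq)
          if (sd(prs) == 0) return(0)
          cor(prs, cohort$Y[[1]][i_va])^2
        }
        tuned <- tune_grid(bt, ld, s_m, grids$lambda0,
                           l1_of(method, grids), evalr)
        prs_te <- score_prs(cohort$genotypes[[1]][i_te, , drop = FALSE],
                            tuned$best, panel$freq)
        r2 <- if (sd(prs_te) == 0) 0 else cor(prs_te, cohort$Y[[1]][i_te])^2
        rows[[length(rows) + 1L]] <- data.frame(
          method = method, mode = mode, r2 = r2,
          lambda0 = tuned$best$penalty$lambda0,
          lambda1 = tuned$best$penalty$lambda1,
          n_nonzero = sum(tuned$best$beta_hat != 0),
          stringsAsFactors = FALSE)
        details[[paste(method, mode, sep = ".")]] <- tuned
      }
    } else {
      xty <- unname(estimate_xty(stats[[1]]))
      part <- subsample_sumstats(xty, N, fractions, ld)
      bt <- part$xty_train / part$n_train
      for (method in methods) {
        s_m <- s_of(method)
        grids <- default_lambda_grids(bt, s_m)
        evalr <- function(model) {
          approx_r2(unname(model$beta_hat), part$xty_valid, part$n_valid,
                    N)$value
        }
        tuned <- tune_grid(bt, ld, s_m, grids$lambda0,
                           l1_of(method, grids), evalr)
        r2 <- approx_r2(unname(tuned$best$beta_hat), part$xty_test,
                        part$n_test, N)$value
        rows[[length(rows) + 1L]] <- data.frame(
          method = method, mode = mode, r2 = r2,
          lambda0 = tuned$best$penalty$lambda0,
          lambda1 = tuned$best$penalty$lambda1,
          n_nonzero = sum(tuned$best$beta_hat != 0),
          stringsAsFactors = FALSE)
        details[[paste(method, mode, sep = ".")]] <- tuned
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "details") <- details
  attr(out, "selection") <- selection
  attr(out, "causal") <- cohort$causal
  out
}

#' Concordance between individual-level and summary-statistic evaluation
#'
#' For each simulation setting, averages the tuned model's test R² over
#' repeated cohorts twice — once from individual-level 60/20/20 splits and
#' once from conditional subsampling of the summary statistics — and
#' reports the Pearson correlation of the paired per-setting averages.
#'
#' @param settings data.frame with columns `K`, `h2`, `rg` (one row per
#'   setting); defaults to the 2 x 2 x 2 factorial over K in {5, 10},
#'   h² in {0.2, 0.6}, genetic correlation in {0.1, 0.6}.
#' @param n_repeats Cohort replicates per setting. Default 5.
#' @param N,M Cohort and SNP sizes. Defaults 2000 and 1000.
#' @param seed Base seed; replicate r of setting i uses
#'   `seed + (i - 1) * n_repeats + r`.
#' @param method Method to evaluate. Default `"netprs"`.
#' @param ... Further arguments to [prs_study()].
#' @return List: `settings` (with `r2_individual`, `r2_sumstat` columns),
#'   `correlation` (Pearson), `per_repeat` (long data.frame).
#' @export
concordance_study <- function(settings = NULL, n_repeats = 5, N = 2000,
                              M = 1000, seed = 1, method = "netprs",
                              trait_selection = "all", ...) {
  if (is.null(settings)) {
    settings <- expand.grid(K = c(5, 10), h2 = c(0.2, 0.6),
                            rg = c(0.1, 0.6), KEEP.OUT.ATTRS = FALSE)
  }
  per <- list()
  for (i in seq_len(nrow(settings))) {
    for (r in seq_len(n_repeats)) {
      res <- prs_study(K = settings$K[i], h2 = settings$h2[i],
                       rg = settings$rg[i], N = N, M = M,
                       seed = seed + (i - 1) * n_repeats + r,
                       methods = method, trait_selection = trait_selection,
                       modes = c("individual", "sumstat"), ...)
      res$setting <- i
      res$repeat_id <- r
      per[[length(per) + 1L]] <- res
    }
  }
  per <- do.call(rbind, per)
  agg <- function(mode) {
    vapply(seq_len(nrow(settings)), function(i) {
      mean(per$r2[per$setting == i & per$mode == mode])
    }, numeric(1))
  }
  settings$r2_individual <- agg("individual")
  settings$r2_sumstat <- agg("sumstat")
  list(settings = settings,
       correlation = cor(settings$r2_individual, settings$r2_sumstat),
       per_repeat = per)
}
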