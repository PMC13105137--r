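#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a tab- (or whitespace-) delimited summary-statistic table with a
#' header, maps column names onto the canonical fields via configurable
#' aliases, drops rows violating basic validity rules, and returns the table
#' sorted by genomic position.
#'
#' Rows are dropped (with a message giving the count) when any of
#' `beta`, `se`, `pval`, `n` is missing or non-finite, `se <= 0`,
#' `pval` is outside `(0, 1]`, or `n < 2`. Duplicate `snp_id`s beyond the
#' first occurrence are dropped as well.
#'
#' @param path Path to the text file.
#' @param aliases Named list mapping each canonical field
#'   (`snp_id`, `chrom`, `pos`, `a1`, `a2`, `beta`, `se`, `pval`, `n`)
#'   to the column names accepted for it (case-insensitive). Defaults cover
#'   common conventions (`rsid`, `bp`, `effect_allele`, `p`, ...).
#' @return A `data.frame` of class `sumstats` with columns
#'   `snp_id, chrom, pos, a1, a2, beta, se, pval, n`, sorted by
#'   `(chrom, pos)`.
#' @export
read_sumstats <- function(path, aliases = sumstats_aliases()) {
  if (!file.exists(path)) stop("summary-statistic file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (nrow(dt) == 0L) stop("summary-statistic file is empty: ", path)
  nm <- tolower(names(dt))
  mandatory <- c("snp_id", "a1", "a2", "beta", "se", "pval", "n")
  col_of <- function(field) {
    hits <- which(nm %in% tolower(aliases[[field]]))
    if (length(hits) == 0L) return(NA_integer_)
    hits[1L]
  }
  idx <- vapply(names(aliases), col_of, integer(1))
  missing_cols <- setdiff(mandatory, names(idx)[!is.na(idx)])
  if (length(missing_cols) > 0L) {
    stop("summary-statistic file lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(
    snp_id = as.character(dt[[idx[["snp_id"]]]]),
    chrom  = if (!is.na(idx[["chrom"]])) as.character(dt[[idx[["chrom"]]]]) else "1",
    pos    = if (!is.na(idx[["pos"]])) as.integer(dt[[idx[["pos"]]]]) else seq_len(nrow(dt)),
    a1     = toupper(as.character(dt[[idx[["a1"]]]])),
    a2     = toupper(as.character(dt[[idx[["a2"]]]])),
    beta   = as.numeric(dt[[idx[["beta"]]]]),
    se     = as.numeric(dt[[idx[["se"]]]]),
    pval   = as.numeric(dt[[idx[["pval"]]]]),
    n      = as.numeric(dt[[idx[["n"]]]]),
    stringsAsFactors = FALSE
  )
  ok <- is.finite(out$beta) & is.finite(out$se) & is.finite(out$pval) &
    is.finite(out$n) & out$se > 0 & out$pval > 0 & out$pval <= 1 & out$n >= 2 &
    !is.na(out$snp_id) & !duplicated(out$snp_id)
  n_drop <- sum(!ok)
  if (n_drop > 0L) message("read_sumstats: dropped ", n_drop, " invalid row(s)")
  out <- out[ok, , drop = FALSE]
  if (nrow(out) == 0L) stop("no valid rows remain in ", path)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sumstats", "data.frame")
  out
}

#' Default column-name aliases for summary-statistic tables
#' @return Named list of accepted column names per canonical field.
#' @export
sumstats_aliases <- function() {
  list(
    snp_id = c("snp", "snp_id", "rsid", "id", "marker", "markername"),
    chrom  = c("chr", "chrom", "chromosome"),
    pos    = c("pos", "bp", "position", "base_pair_location"),
    a1     = c("a1", "effect_allele", "alt", "ea"),
    a2     = c("a2", "other_allele", "ref", "oa", "nea"),
    beta   = c("beta", "effect", "b", "effect_size"),
    se     = c("se", "stderr", "standard_error"),
    pval   = c("p", "pval", "p_value", "pvalue"),
    n      = c("n", "samplesize", "sample_size", "neff")
  )
}

#' Construct a summary-statistic table in memory
#'
#' Convenience constructor applying the same validity rules as
#' [read_sumstats()]; used by the simulator and in tests.
#'
#' @param snp_id,chrom,pos,a1,a2,beta,se,pval,n Per-SNP vectors (recycled
#'   where scalar).
#' @return A `sumstats` data.frame sorted by `(chrom, pos)`.
#' @export
sumstats <- function(snp_id, beta, se, pval, n,
                     chrom = "1", pos = seq_along(snp_id),
                     a1 = "A", a2 = "G") {
  out <- data.frame(snp_id = as.character(snp_id), chrom = as.character(chrom),
                    pos = as.integer(pos), a1 = toupper(a1), a2 = toupper(a2),
                    beta = as.numeric(beta), se = as.numeric(se),
                    pval = as.numeric(pval), n = as.numeric(n),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$snp_id)) stop("duplicate snp_id")
  if (any(out$se <= 0)) stop("se must be > 0")
  if (any(out$pval <= 0 | out$pval > 1)) stop("pval must be in (0, 1]")
  if (any(out$n < 2)) stop("n must be >= 2")
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sumstats", "data.frame")
  out
}

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) {
  a1 %in% names(COMPLEMENT) & unname(COMPLEMENT[a1]) == a2
}

#' Harmonize summary statistics against a reference panel
#'
#' Restricts a summary-statistic table to SNPs present in the reference
#' panel, aligns the effect allele to the panel's `a1` (flipping the sign of
#' `beta` where the alleles are swapped), optionally drops strand-ambiguous
#' palindromic SNPs (A/T, C/G), and reorders the rows to the panel's SNP
#' order. SNPs whose allele pair cannot be reconciled with the panel's are
#' dropped and counted.
#'
#' @param stats A `sumstats` table.
#' @param panel A `ref_panel` object (see [ref_panel()]).
#' @param drop_ambiguous Drop palindromic SNPs? Default `TRUE`.
#' @return A harmonized `sumstats` table in panel SNP order, with attributes
#'   `n_flipped`, `n_mismatch`, `n_ambiguous`.
#' @export
harmonize <- function(stats, panel, drop_ambiguous = TRUE) {
  bim <- panel$bim
  idx <- match(bim$snp_id, stats$snp_id)
  keep_panel <- which(!is.na(idx))
  if (length(keep_panel) == 0L) stop("no SNPs shared between stats and panel")
  st <- stats[idx[keep_panel], , drop = FALSE]
  pa1 <- toupper(bim$a1[keep_panel]); pa2 <- toupper(bim$a2[keep_panel])

  same <- st$a1 == pa1 & st$a2 == pa2
  swapped <- st$a1 == pa2 & st$a2 == pa1
  ambiguous <- is_palindromic(st$a1, st$a2)

  st$beta[swapped] <- -st$beta[swapped]
  tmp <- st$a1[swapped]
  st$a1[swapped] <- st$a2[swapped]
  st$a2[swapped] <- tmp

  ok <- same | swapped
  n_mismatch <- sum(!ok)
  n_ambiguous <- 0L
  if (drop_ambiguous) {
    n_ambiguous <- sum(ambiguous & ok)
    ok <- ok & !ambiguous
  }
  if (!any(ok)) stop("no SNPs survive harmonization")
  out <- st[ok, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sumstats", "data.frame")
  attr(out, "n_flipped") <- sum(swapped & ok)
  attr(out, "n_mismatch") <- n_mismatch
  attr(out, "n_ambiguous") <- n_ambiguous
  out
}

#' Standardized marginal effect sizes
#'
#' Converts per-allele marginal effects to the standardized-genotype,
#' standardized-trait scale used by the solver:
#' `beta_tilde_m = (beta_m / se_m) / sqrt(n_m)`, i.e. the z-score scaled by
#' the per-SNP sample size. On standardized data this equals the marginal
#' covariance `(1/n) sum_i x_im y_i` up to O(1/n).
#'
#' @param stats A (harmonized) `sumstats` table.
#' @return Numeric vector of standardized marginal effects, named by snp_id.
#' @export
standardized_marginal_effects <- function(stats) {
  if (any(stats$n <= 0)) stop("non-positive sample size n")
  bt <- (stats$beta / stats$se) / sqrt(stats$n)
  if (!all(is.finite(bt))) stop("non-finite standardized effect")
  setNames(bt, stats$snp_id)
}
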