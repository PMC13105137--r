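test_that("read_sumstats parses, validates and sorts a table", {
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(SNP = c("rs3", "rs1", "rs2"), CHR = 1,
                    BP = c(300, 100, 200), A1 = "A", A2 = "G",
                    BETA = c(0.1, -0.2, 0.3), SE = c(0.05, 0.04, 0.06),
                    P = c(0.04, 0.001, 0.6), N = 1000)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  st <- read_sumstats(path)
  expect_s3_class(st, "sumstats")
  expect_equal(nrow(st), 3)
  expect_equal(st$snp_id, c("rs1", "rs2", "rs3"))   # sorted by position
  expect_equal(st$beta, c(-0.2, 0.3, 0.1))
})

test_that("read_sumstats drops invalid rows with a count and errors on contract violations", {
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(snp = c("rs1", "rs2", "rs3"), a1 = "A", a2 = "G",
                    beta = c(0.1, 0.2, 0.3), se = c(0.05, 0, 0.06),
                    pval = c(0.5, 0.5, 0.5), n = 1000)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(st <- read_sumstats(path), "dropped 1 invalid row")
  expect_equal(nrow(st), 2)
  expect_false("rs2" %in% st$snp_id)

  # missing mandatory column is named in the error
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab[, setdiff(names(tab), "se")], path2, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_sumstats(path2), "se")

  # empty file
  path3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("snp\ta1\ta2\tbeta\tse\tpval\tn", path3)
  expect_error(read_sumstats(path3), "empty")
})

make_harmonize_fixture <- function() {
  g <- matrix(rbinom(5 * 4, 2, 0.4), 5, 4)
  bim <- data.frame(chrom = "1", snp_id = paste0("rs", 1:4), pos = 1:4,
                    a1 = c("A", "C", "A", "A"), a2 = c("G", "A", "T", "G"),
                    stringsAsFactors = FALSE)
  ref_panel(g, bim)
}

test_that("harmonize flips swapped alleles and drops ambiguous or irreconcilable SNPs", {
  set.seed(11)
  panel <- make_harmonize_fixture()
  st <- sumstats(snp_id = c("rs1", "rs2", "rs3", "rs4"),
                 beta = c(0.1, 0.3, 0.2, 0.4), se = 0.05, pval = 0.1,
                 n = 1000, a1 = c("A", "A", "A", "A"),
                 a2 = c("G", "C", "T", "C"))
  h <- harmonize(st, panel, drop_ambiguous = TRUE)
  # rs2: stats a1/a2 = A/C but panel C/A -> swapped, beta flipped
  expect_equal(h$beta[h$snp_id == "rs2"], -0.3)
  expect_equal(h$a1[h$snp_id == "rs2"], "C")
  # rs3 is palindromic A/T -> dropped
  expect_false("rs3" %in% h$snp_id)
  expect_equal(attr(h, "n_ambiguous"), 1L)
  # rs4: A/C vs panel A/G -> irreconcilable, dropped and counted
  expect_false("rs4" %in% h$snp_id)
  expect_equal(attr(h, "n_mismatch"), 1L)
  # output follows panel order
  expect_equal(h$snp_id, c("rs1", "rs2"))
})

test_that("harmonize is idempotent and sign-flip invariant", {
  set.seed(12)
  panel <- make_panel(n = 60, m = 10, seed = 3)
  st <- sumstats(snp_id = panel$bim$snp_id, beta = rnorm(10), se = 0.05,
                 pval = runif(10), n = 500,
                 a1 = panel$bim$a1, a2 = panel$bim$a2)
  h1 <- harmonize(st, panel)
  h2 <- harmonize(h1, panel)
  expect_equal(as.data.frame(h2), as.data.frame(h1))

  # flipping alleles+sign upstream gives the same standardized effects
  flipped <- st
  flipped$beta <- -st$beta
  flipped$a1 <- st$a2; flipped$a2 <- st$a1
  hf <- harmonize(flipped, panel)
  expect_equal(standardized_marginal_effects(hf),
               standardized_marginal_effects(h1))
})

test_that("standardized marginal effects are z / sqrt(n)", {
  st <- sumstats(snp_id = c("a", "b"), beta = c(0.5, 0), se = c(0.1, 0.2),
                 pval = 0.5, n = 100)
  expect_equal(unname(standardized_marginal_effects(st)), c(0.5, 0))
  st_bad <- st; st_bad$n <- c(100, 0)
  expect_error(standardized_marginal_effects(st_bad), "sample size")
})

test_that("standardized effects equal the X'y/n dot product on standardized data", {
  set.seed(21)
  n <- 2000; m <- 15
  X <- scale(matrix(rnorm(n * m), n, m)) * sqrt(n / (n - 1))
  y <- drop(scale(rnorm(n))) * sqrt(n / (n - 1))
  dot <- drop(crossprod(X, y)) / n
  # exact identity when SE is the known-variance value 1/sqrt(n)
  st_known <- sumstats(snp_id = paste0("s", 1:m), beta = dot,
                       se = 1 / sqrt(n), pval = 0.5, n = n)
  expect_equal(unname(standardized_marginal_effects(st_known)), dot,
               tolerance = 1e-12)
  # OLS-derived summary statistics approximate it (residual-variance and
  # df corrections enter at O(beta^3 + beta/n))
  st_ols <- marginal_gwas(X, y)
  expect_equal(unname(standardized_marginal_effects(st_ols)), dot,
               tolerance = 5e-3)
})

test_that("blockwise LD equals the dense correlation matrix within blocks", {
  set.seed(31)
  panel <- make_panel(n = 50, m = 10, seed = 31, ld_rho = 0.6,
                      ld_block_size = 10)
  ld <- compute_ld(panel, window = 10, shrinkage = 0)
  dense <- cor(panel$genotypes)
  expect_equal(unname(ld_as_matrix(ld)), unname(dense), tolerance = 1e-10)

  # banding: pairs beyond the window are exactly zero
  ld2 <- compute_ld(panel, window = 5, shrinkage = 0)
  R2 <- ld_as_matrix(ld2)
  expect_true(all(R2[1:5, 6:10] == 0))
  expect_equal(unname(R2[1:5, 1:5]), unname(dense[1:5, 1:5]),
               tolerance = 1e-10)
})

test_that("LD shrinkage scales off-diagonals, keeps the unit diagonal, and blocks stay PSD", {
  panel <- make_panel(n = 80, m = 12, seed = 32, ld_rho = 0.8,
                      ld_block_size = 12)
  ld0 <- compute_ld(panel, window = 12, shrinkage = 0)
  ld <- compute_ld(panel, window = 12, shrinkage = 0.1)
  R0 <- ld0$blocks[[1]]; R <- ld$blocks[[1]]
  expect_equal(diag(R), rep(1, 12), ignore_attr = TRUE)
  off <- upper.tri(R)
  expect_equal(R[off], 0.9 * R0[off], tolerance = 1e-12)
  for (b in ld$blocks) {
    expect_gte(min(eigen(b, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
})

test_that("duplicated genotype columns give unit correlation and monomorphic columns error", {
  set.seed(33)
  g <- matrix(rbinom(40 * 3, 2, 0.4), 40, 3)
  g <- cbind(g, g[, 1])  # perfect proxy of column 1
  bim <- data.frame(chrom = "1", snp_id = paste0("s", 1:4), pos = 1:4,
                    a1 = "A", a2 = "G")
  panel <- ref_panel(g, bim)
  ld <- compute_ld(panel, window = 4, shrinkage = 0)
  expect_equal(ld$blocks[[1]][1, 4], 1)

  g2 <- g; g2[, 2] <- 1  # constant heterozygote: freq 0.5 but zero variance
  panel2 <- ref_panel(g2, bim)
  expect_error(compute_ld(panel2, window = 4), "monomorphic")
})

test_that("LD scores are within-block row sums of squared correlations", {
  # self term only
  ld_id <- identity_ld(3)
  expect_equal(unname(compute_ld_scores(ld_id)), rep(1, 3))
  # perfect proxy -> l = 2
  ld_proxy <- ld_from_blocks(list(matrix(c(1, 1, 1, 1), 2, 2)))
  expect_equal(unname(compute_ld_scores(ld_proxy)), c(2, 2))
  # dense oracle on a random block
  set.seed(34)
  panel <- make_panel(n = 60, m = 10, seed = 34, ld_rho = 0.7,
                      ld_block_size = 10)
  ld <- compute_ld(panel, window = 10, shrinkage = 0)
  expect_equal(unname(compute_ld_scores(ld)),
               unname(rowSums(cor(panel$genotypes)^2)), tolerance = 1e-10)
  # adjusted scores subtract (1 - r2) / (n - 2) per term
  l_adj <- compute_ld_scores(ld, adjust = TRUE)
  r2 <- cor(panel$genotypes)^2
  expect_equal(unname(l_adj),
               unname(rowSums(r2 - (1 - r2) / (60 - 2))), tolerance = 1e-10)
})
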