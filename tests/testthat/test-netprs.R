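test_that("soft-thresholding shrinks toward zero and preserves sign", {
  expect_equal(soft_threshold(0.5, 1.0), 0)
  expect_equal(soft_threshold(2.0, 0.5), 1.5)
  expect_equal(soft_threshold(-3.0, 1.0), -2.0)
  expect_error(soft_threshold(1, -0.1), "tau")
})

test_that("penalty thresholds decrease in the annotation score", {
  pen <- penalty_config(0.1, 0.02, s = c(0.01, 0.5, 1))
  expect_equal(pen$tau, 0.1 + 0.02 / c(0.01, 0.5, 1))
  expect_true(all(pen$tau >= pen$lambda0))
  expect_true(all(diff(pen$tau) <= 0))
  pen_t <- penalty_config(0.1, 0.02, s = c(0.01, 0.5, 1),
                          penalty_form = "times")
  expect_equal(pen_t$tau, 0.1 + 0.02 * c(0.01, 0.5, 1))
  expect_error(penalty_config(-1, 0, s = 1, m = 1), "lambda0")
  expect_error(penalty_config(0.1, 0, s = 2, m = 1), "\\(0, 1\\]")
})

test_that("single-coordinate fit has the soft-threshold closed form", {
  ld <- identity_ld(1)
  fit <- fit_netprs(0.3, ld, penalty_config(0.1, 0, m = 1))
  expect_equal(unname(fit$beta_hat), 0.2)
  expect_true(fit$converged)
})

test_that("identity LD gives the elementwise closed form and full shrinkage zeroes everything", {
  set.seed(61)
  m <- 20
  bt <- rnorm(m, 0, 0.5)
  tau <- runif(m, 0, 0.4)
  ld <- identity_ld(m)
  pen <- structure(list(lambda0 = 0, lambda1 = 0, s = rep(1, m), tau = tau),
                   class = "penalty_config")
  fit <- fit_netprs(bt, ld, pen)
  expect_equal(unname(fit$beta_hat), soft_threshold(bt, tau),
               tolerance = 1e-12)
  # tau >= |bt| everywhere -> all zero
  fit0 <- fit_netprs(bt, ld, penalty_config(max(abs(bt)), 0, m = m))
  expect_true(all(fit0$beta_hat == 0))
})

test_that("coordinate descent matches an independent convex solver on random instances", {
  set.seed(62)
  for (rep in 1:10) {
    m <- sample(2:8, 1)
    R <- rand_corr(m)
    bt <- rnorm(m, 0, 0.5)
    tau <- runif(m, 0, 0.3)
    ld <- ld_from_blocks(list(R))
    pen <- structure(list(lambda0 = 0, lambda1 = 0, s = rep(1, m), tau = tau),
                     class = "penalty_config")
    fit <- fit_netprs(bt, ld, pen, tol = 1e-9, max_iter = 10000)
    oracle <- fista_lasso(bt, R, tau)
    expect_equal(unname(fit$beta_hat), oracle, tolerance = 1e-5)
    expect_true(all(diff(fit$objective_trace) <= 1e-10))
  }
})

test_that("multi-block fits are separable across blocks", {
  set.seed(63)
  R1 <- rand_corr(4); R2 <- rand_corr(3)
  bt <- rnorm(7, 0, 0.5)
  ld <- ld_from_blocks(list(R1, R2))
  pen <- penalty_config(0.05, 0, m = 7)
  fit <- fit_netprs(bt, ld, pen, tol = 1e-9)
  f1 <- fit_netprs(bt[1:4], ld_from_blocks(list(R1)),
                   penalty_config(0.05, 0, m = 4), tol = 1e-9)
  f2 <- fit_netprs(bt[5:7], ld_from_blocks(list(R2)),
                   penalty_config(0.05, 0, m = 3), tol = 1e-9)
  expect_equal(unname(fit$beta_hat), c(unname(f1$beta_hat),
                                       unname(f2$beta_hat)),
               tolerance = 1e-12)
})

test_that("raising the annotation score weakly increases the fitted effect", {
  bt <- 0.5
  ld <- identity_ld(1)
  s_grid <- c(0.05, 0.2, 0.5, 1)
  betas <- vapply(s_grid, function(s) {
    unname(fit_netprs(bt, ld, penalty_config(0.05, 0.01, s = s, m = 1))$beta_hat)
  }, numeric(1))
  expect_true(all(diff(betas) >= 0))
})

test_that("scoring standardizes dosages by reference frequency and mean-imputes", {
  set.seed(64)
  g <- matrix(rbinom(30, 2, 0.3), 10, 3,
              dimnames = list(NULL, c("s1", "s2", "s3")))
  freq <- c(0.3, 0.4, 0.2)
  w <- setNames(c(0, 1, 0), colnames(g))
  sc <- score_prs(g, w, freq)
  expect_equal(sc, (g[, 2] - 0.8) / sqrt(2 * 0.4 * 0.6))
  # all-zero weights -> all-zero scores
  expect_equal(score_prs(g, setNames(numeric(3), colnames(g)), freq),
               rep(0, 10))
  # missing dosages standardize to zero contribution
  g2 <- g; g2[1, 2] <- NA
  sc2 <- score_prs(g2, w, freq)
  expect_equal(sc2[1], 0)
  # missing model SNPs are reported
  expect_error(score_prs(g[, 1:2], setNames(1:3, c("s1", "s2", "s9")),
                         freq), "s9")
})

test_that("PRS from the true effects tracks the simulated genetic component", {
  cfg <- sim_config(n_traits = 1, n_samples = 1500, n_snps = 300,
                    causal_prop = 0.05, h2 = 0.6, seed = 65)
  co <- simulate_traits(cfg)
  sc <- score_prs(co$genotypes[[1]], setNames(co$B[, 1],
                                              colnames(co$genotypes[[1]])),
                  co$maf)
  expect_gt(cor(sc, co$genetic[[1]]), 0.99)
})

test_that("tune_grid honors the argmax contract and tie-breaking", {
  set.seed(66)
  m <- 10
  bt <- rnorm(m, 0, 0.3)
  ld <- identity_ld(m)
  # 1x1 grid returns that fit
  one <- tune_grid(bt, ld, NULL, 0.05, 0, evaluator = function(mod) 0.5)
  expect_equal(one$best$penalty$lambda0, 0.05)
  # degenerate all-zero cell loses to a cell with positive R2
  ev <- function(mod) if (all(mod$beta_hat == 0)) 0 else 0.4
  tg <- tune_grid(bt, ld, NULL, c(10, 0.01), 0, evaluator = ev)
  expect_equal(tg$best$penalty$lambda0, 0.01)
  # constant evaluator: ties break toward larger lambda0 then lambda1
  tg2 <- tune_grid(bt, ld, rep(0.5, m), c(0.01, 0.02), c(0, 0.001),
                   evaluator = function(mod) 1)
  expect_equal(tg2$best$penalty$lambda0, 0.02)
  expect_equal(tg2$best$penalty$lambda1, 0.001)
  # every cell failing is an error
  expect_error(tune_grid(bt, ld, NULL, 0.05, 0,
                         evaluator = function(mod) stop("no")),
               "every grid cell")
})

test_that("informative annotations let tuning pick a positive lambda1", {
  set.seed(67)
  n_pos <- 0
  for (rep in 1:10) {
    m <- 300; n <- 2000
    X <- matrix(rnorm(n * m), n, m)
    causal <- 1:15
    b <- numeric(m); b[causal] <- rnorm(15, 0, sqrt(0.5 / 15))
    y <- drop(X %*% b) + rnorm(n, 0, sqrt(0.5))
    i_tr <- 1:1200; i_va <- 1201:1600
    Xtr <- X[i_tr, ]
    bt <- drop(crossprod(scale(Xtr), scale(y[i_tr]))) / length(i_tr)
    s <- rep(0.02, m); s[causal] <- 1  # causal SNPs carry top annotation
    ld <- identity_ld(m)
    grids <- default_lambda_grids(bt, s)
    ev <- function(mod) {
      pr <- drop(scale(X[i_va, ]) %*% mod$beta_hat)
      if (sd(pr) == 0) 0 else cor(pr, y[i_va])^2
    }
    tg <- tune_grid(bt, ld, s, grids$lambda0, grids$lambda1, ev)
    if (tg$best$penalty$lambda1 > 0) n_pos <- n_pos + 1
  }
  expect_gt(n_pos, 5)
})

test_that("strong causal effects are recovered in the tuned support", {
  set.seed(68)
  hits <- 0
  for (rep in 1:10) {
    m <- 500; n <- 5000
    X <- matrix(rnorm(n * m), n, m)
    causal <- sort(sample.int(m, 10))
    b <- numeric(m); b[causal] <- sample(c(-1, 1), 10, TRUE) *
      sqrt(0.5 / 10)
    y <- drop(X %*% b) + rnorm(n, 0, sqrt(0.5))
    i_tr <- 1:3000; i_va <- 3001:4000
    bt <- drop(crossprod(scale(X[i_tr, ]), scale(y[i_tr]))) / 3000
    ld <- identity_ld(m)
    grids <- default_lambda_grids(bt)
    ev <- function(mod) {
      pr <- drop(scale(X[i_va, ]) %*% mod$beta_hat)
      if (sd(pr) == 0) 0 else cor(pr, y[i_va])^2
    }
    tg <- tune_grid(bt, ld, NULL, grids$lambda0, 0, ev)
    if (all(causal %in% which(tg$best$beta_hat != 0))) hits <- hits + 1
  }
  expect_gte(hits, 9)
})
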