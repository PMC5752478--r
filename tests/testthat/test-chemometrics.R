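test_that("preprocessing implements half-min imputation, scaling and sum norm", {
  om <- make_om(rbind(c(4, 8, NA), c(1, 2, 3)), layer = "metabolite")
  out <- preprocess(om, preprocess_spec(scaling = "none", centering = FALSE))
  expect_equal(unname(out$values[1, 3]), 2)  # half of the observed min 4

  # centering only: all feature means 0
  om2 <- make_om(matrix(rnorm(50, 8, 2), 10, 5), layer = "metabolite")
  cen <- preprocess(om2, preprocess_spec(scaling = "none"))
  expect_lt(max(abs(rowMeans(cen$values))), 1e-12)

  # unit-variance scaling: every feature variance 1
  uv <- preprocess(om2, preprocess_spec(scaling = "uv"))
  expect_equal(unname(apply(uv$values, 1, var)), rep(1, 10))

  # pareto divides by sqrt(sd)
  par <- preprocess(om2, preprocess_spec(scaling = "pareto"))
  sds <- apply(om2$values - rowMeans(om2$values), 1, sd)
  expect_equal(par$values, (om2$values - rowMeans(om2$values)) / sqrt(sds))

  # sum normalization equalizes linear-scale column totals
  sn <- preprocess(om2, preprocess_spec(normalization = "sum",
                                        scaling = "none", centering = FALSE))
  expect_lt(diff(range(colSums(2^sn$values))), 1e-9)

  all_na <- make_om(rbind(c(NA, NA, NA), c(1, 2, 3)), layer = "metabolite")
  expect_error(preprocess(all_na), "f1")
})

test_that("PCA via SVD explains, reconstructs and orients deterministically", {
  # rank-1 input: first component carries all variance
  t_ <- rnorm(8)
  X1 <- outer(t_, c(1, 2, 3))
  p1 <- pca_fit(X1, n_comp = 3)
  expect_equal(p1$explained[1], 1, tolerance = 1e-12)

  # full-rank reconstruction is exact
  set.seed(41)
  X <- matrix(rnorm(60), 6, 10)
  pc <- pca_fit(X, n_comp = 6)
  recon <- pc$scores %*% t(pc$loadings) + rep(pc$center, each = 6)
  expect_equal(recon, X, tolerance = 1e-8)
  # loadings orthonormal
  expect_equal(crossprod(pc$loadings), diag(6), tolerance = 1e-8)
  expect_lte(sum(pc$explained), 1 + 1e-12)

  # points exactly on y = x: first loading is (1,1)/sqrt(2)
  tt <- seq(-2, 2, length.out = 9)
  pxy <- pca_fit(cbind(tt, tt), n_comp = 1)
  expect_equal(unname(pxy$loadings[, 1]), c(1, 1) / sqrt(2), tolerance = 1e-12)
})

test_that("NIPALS PLS1 recovers pure structure and matches a regression oracle", {
  set.seed(17)
  y <- rep(c(-1, 1), each = 5)
  # single X column proportional to y: one component, R2Y = 1
  X <- matrix(2.5 * y, ncol = 1)
  fit <- pls1_fit(X, y, 1)
  expect_equal(fit$R2Y, 1, tolerance = 1e-12)
  expect_equal(fit$fitted, y, tolerance = 1e-10)

  # y orthogonal to every column: q ~ 0, R2Y ~ 0
  z <- rnorm(10); z <- z - mean(z)
  z <- z - y * sum(z * y) / sum(y * y)
  Xo <- cbind(z, 2 * z)
  fito <- pls1_fit(Xo, y, 1)
  expect_lt(abs(fito$q[1]), 1e-10)
  expect_lt(fito$R2Y, 1e-12)

  # fitted values equal least squares on the scores (2 comps, random 8 x 5)
  X2 <- matrix(rnorm(40), 8, 5)
  y2 <- rnorm(8)
  fit2 <- pls1_fit(X2, y2, 2)
  ls <- lm.fit(cbind(1, fit2$T), y2)
  expect_equal(fit2$fitted, unname(cbind(1, fit2$T) %*% ls$coefficients)[, 1],
               tolerance = 1e-8)
})

test_that("O-PLS separates orthogonal variation and collapses to PLS1", {
  set.seed(19)
  y <- rep(c(-1, 1), each = 6)
  X <- matrix(rnorm(12 * 8), 12, 8)

  # n_ortho = 0 reproduces one-component PLS1 exactly
  op0 <- opls_fit(X, y, n_ortho = 0)
  pl1 <- pls1_fit(X, y, 1)
  expect_equal(op0$fitted, pl1$fitted, tolerance = 1e-10)
  expect_equal(op0$w_p, pl1$W[, 1], tolerance = 1e-10)

  # pure predictive structure: orthogonal loop stops early, keeps 0
  Xp <- outer(y, c(1, -2, 0.5))
  expect_message(opp <- opls_fit(Xp, y, n_ortho = 1), "stopping early")
  expect_identical(opp$n_ortho, 0L)

  # a strong y-orthogonal direction: filtering improves the predictive fit
  z <- rnorm(12); z <- z - mean(z); z <- z - y * sum(z * y) / sum(y * y)
  w1 <- c(1, 0, 0, 0); w2 <- c(0.8, 0.6, 0, 0)
  Xoz <- outer(y, w1) + 4 * outer(z, w2) + matrix(rnorm(48, 0, 0.05), 12, 4)
  r2_pls <- pls1_fit(Xoz, y, 1)$R2Y
  op1 <- opls_fit(Xoz, y, n_ortho = 1)
  expect_gte(op1$R2Y, r2_pls)

  # every orthogonal score is uncorrelated with y
  sim <- matrix(rnorm(12 * 30), 12, 30)
  op2 <- opls_fit(sim, y, n_ortho = 2)
  for (a in seq_len(op2$n_ortho))
    expect_lt(abs(cor(op2$T_o[, a], y)), 1e-8)
  # orthogonal weights are unit norm and orthogonal to the predictive weight
  for (a in seq_len(op2$n_ortho)) {
    expect_equal(sum(op2$W_o[, a]^2), 1, tolerance = 1e-10)
  }
  expect_equal(sum(op2$w_p^2), 1, tolerance = 1e-10)

  # prediction on the training data reproduces the fitted values
  expect_equal(predict(op2, sim), op2$fitted, tolerance = 1e-10)
})

test_that("VIP scores satisfy their normalization and degenerate cases", {
  y <- rep(c(-1, 1), each = 4)
  # single variable: VIP is exactly 1
  X1 <- matrix(y + rnorm(8, 0, 0.1), ncol = 1)
  expect_equal(unname(vip_scores(pls1_fit(X1, y, 1))), 1, tolerance = 1e-12)

  # identical variables: equal weights, all VIP = 1
  base <- y + rnorm(8, 0, 0.1)
  Xe <- cbind(base, base, base)
  expect_equal(unname(vip_scores(pls1_fit(Xe, y, 1))), rep(1, 3),
               tolerance = 1e-10)

  # sum of squared VIPs equals the number of variables
  set.seed(23)
  for (i in 1:10) {
    n <- sample(6:14, 1); J <- sample(3:25, 1)
    X <- matrix(rnorm(n * J), n, J)
    yy <- rnorm(n)
    v <- vip_scores(pls1_fit(X, yy, min(2, n - 1)))
    expect_equal(sum(v^2), J, tolerance = 1e-6 * J)
    vo <- vip_scores(opls_fit(X, yy, n_ortho = 1))
    expect_equal(sum(vo^2), J, tolerance = 1e-6 * J)
  }
})

test_that("cross-validated Q2 separates signal from permuted labels", {
  set.seed(7)
  n <- 20; J <- 10
  y <- rep(c(-1, 1), each = n / 2)
  X <- outer(y, rnorm(J)) + matrix(rnorm(n * J, 0, 0.2), n, J)
  q2 <- q2_cv(X, y, n_ortho = 1, folds = 7, seed = 1)
  expect_gt(q2, 0.9)
  expect_identical(q2, q2_cv(X, y, n_ortho = 1, folds = 7, seed = 1))

  hits <- 0L
  for (s in 1:10) {
    set.seed(500 + s)
    yp <- sample(y)
    if (q2_cv(X, yp, n_ortho = 1, folds = 7, seed = s) <= 0.2) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("VIP selection is strict, ranked and id-tie-broken", {
  vip <- c(f1 = 8.5, f2 = 7.9, f3 = 9.1)
  sel <- select_by_vip(vip, 8)
  expect_identical(sel$feature_id, c("f3", "f1"))
  expect_identical(nrow(select_by_vip(vip, 10)), 0L)
  ties <- c(b = 2, a = 2, c = 1)
  expect_identical(select_by_vip(ties, 0.5)$feature_id, c("a", "b", "c"))
})

test_that("planted discriminant metabolites dominate the VIP ranking (seed 1)", {
  sim <- simulate_triomics(sim_config(seed = 1))
  fit <- run_opls(sim$matrices$metabolite, sim$meta,
                  contrast("model", "treated"), seed = 1)
  planted <- c(sim$truth$metabolite$up, sim$truth$metabolite$down)
  ranks <- match(planted, names(sort(fit$vip, decreasing = TRUE)))
  expect_true(all(ranks <= 15))
})
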