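# Oracle checks for the AI-REML engine: closed forms, grid search, and
# structure recovery.

test_that("balanced one-way variance components match the ANOVA closed form and lme4", {
  set.seed(1)
  g <- 5; r <- 4
  f <- rep(seq_len(g), each = r)
  y <- 10 + rnorm(g, 0, 2)[f] + rnorm(g * r, 0, 1)
  dat <- data.frame(grp = factor(f))
  fit <- reml_fit(y, matrix(1, g * r), dat, list(grp = rt_iid("grp")))
  aovt <- anova(lm(y ~ factor(f)))
  ms_b <- aovt$`Mean Sq`[1]; ms_w <- aovt$`Mean Sq`[2]
  expect_true(fit$converged)
  expect_equal(fit$theta$grp, (ms_b - ms_w) / r, tolerance = 1e-6)
  expect_equal(fit$sigma_e, ms_w, tolerance = 1e-6)

  lfit <- lme4::lmer(y ~ 1 + (1 | grp), data = dat, REML = TRUE)
  expect_equal(fit$theta$grp, as.numeric(lme4::VarCorr(lfit)$grp),
               tolerance = 1e-5)
})

test_that("with K = identity the solution equals the ridge-BLUP closed form", {
  set.seed(2)
  n <- 60; q <- 20
  gf <- sample(q, n, replace = TRUE)
  K <- diag(q); dimnames(K) <- list(paste0("G", 1:q), paste0("G", 1:q))
  y <- 5 + rnorm(q, 0, 1.5)[gf] + rnorm(n)
  dat <- data.frame(geno = paste0("G", gf))
  fit <- reml_fit(y, matrix(1, n), dat, list(g = rt_known("geno", K)))
  lam <- fit$sigma_e / fit$theta$g
  Z <- matrix(0, n, q); Z[cbind(1:n, gf)] <- 1
  r <- y - rep(fit$beta, n)
  u_ridge <- solve(crossprod(Z) + lam * diag(q), crossprod(Z, r))
  expect_equal(unname(blup_predict(fit, "g")), drop(u_ridge), tolerance = 1e-8)
})

test_that("REML estimates match a dense likelihood grid on a 2-parameter toy", {
  set.seed(3)
  q <- 6; n <- 24
  gf <- rep(1:q, each = 4)
  K <- diag(q); dimnames(K) <- list(paste0("G", 1:q), paste0("G", 1:q))
  y <- 3 + rnorm(q, 0, 1)[gf] + rnorm(n, 0, 0.7)
  dat <- data.frame(geno = paste0("G", gf))
  fit <- reml_fit(y, matrix(1, n), dat, list(g = rt_known("geno", K)))
  X <- matrix(1, n)
  rll <- function(sg, se) {
    V <- sg * K[gf, gf] + se * diag(n)
    R <- chol(V); Vi <- chol2inv(R)
    C <- crossprod(X, Vi) %*% X
    P <- Vi - Vi %*% X %*% solve(C) %*% crossprod(X, Vi)
    -0.5 * (2 * sum(log(diag(R))) + log(C[1, 1]) + drop(t(y) %*% P %*% y))
  }
  grid <- expand.grid(sg = seq(0.02, 3, length.out = 200),
                      se = seq(0.02, 3, length.out = 200))
  best <- grid[which.max(mapply(rll, grid$sg, grid$se)), ]
  res_g <- diff(seq(0.02, 3, length.out = 200)[1:2])
  expect_lt(abs(fit$theta$g - best$sg), res_g)
  expect_lt(abs(fit$sigma_e - best$se), res_g)
})

test_that("the restricted likelihood is invariant to the fixed-effects basis", {
  # REML logL is invariant under orthonormal recombinations of X (a general
  # linear reparameterisation X T shifts it by the constant log|det T|)
  set.seed(4)
  n <- 50
  f <- factor(sample(letters[1:4], n, TRUE))
  g <- factor(sample(1:8, n, TRUE))
  y <- rnorm(4)[as.integer(f)] + rnorm(8, 0, 1.2)[as.integer(g)] + rnorm(n)
  dat <- data.frame(g = g)
  X1 <- model.matrix(~ f)
  Q <- qr.Q(qr(matrix(rnorm(16), 4)))           # random orthogonal 4 x 4
  X2 <- X1 %*% Q
  f1 <- reml_fit(y, X1, dat, list(g = rt_iid("g")))
  f2 <- reml_fit(y, X2, dat, list(g = rt_iid("g")))
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-6)
  expect_equal(f1$theta$g, f2$theta$g, tolerance = 1e-5)
  expect_equal(drop(X1 %*% f1$beta), drop(X2 %*% f2$beta), tolerance = 1e-5)

  # non-orthonormal contrast change: same variance estimates and fit, logL
  # shifted by the constant log|det T|
  X3 <- model.matrix(~ f, contrasts.arg = list(f = "contr.sum"))
  f3 <- reml_fit(y, X3, dat, list(g = rt_iid("g")))
  expect_equal(f1$theta$g, f3$theta$g, tolerance = 1e-5)
  expect_equal(f1$sigma_e, f3$sigma_e, tolerance = 1e-5)
  Tm <- qr.solve(X1, X3)
  expect_equal(f3$logLik, f1$logLik - log(abs(det(Tm))), tolerance = 1e-5)
})

test_that("doubling the weights with a compensating residual scale leaves the fit unchanged", {
  set.seed(5)
  n <- 40
  g <- factor(sample(1:10, n, TRUE))
  w <- runif(n, 0.5, 2)
  y <- rnorm(10, 0, 1.3)[as.integer(g)] + rnorm(n, 0, sqrt(1 / w))
  dat <- data.frame(g = g)
  f1 <- reml_fit(y, matrix(1, n), dat, list(g = rt_iid("g")), weights = w)
  f2 <- reml_fit(y, matrix(1, n), dat, list(g = rt_iid("g")), weights = 2 * w)
  # residual variance sigma_e/w is identical when sigma_e doubles
  expect_equal(f2$sigma_e, 2 * f1$sigma_e, tolerance = 1e-4)
  expect_equal(f1$theta$g, f2$theta$g, tolerance = 1e-4)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-6)
})

test_that("accepted-iterate likelihood sequence is non-decreasing", {
  set.seed(6)
  ng <- 60; ne <- 6
  K <- diag(ng); dimnames(K) <- list(paste0("G", 1:ng), paste0("G", 1:ng))
  cells <- expand.grid(geno = paste0("G", 1:ng), env = paste0("E", 1:ne),
                       stringsAsFactors = FALSE)
  y <- rnorm(ne, 0, 2)[as.integer(factor(cells$env))] +
    rnorm(ng)[as.integer(factor(cells$geno))] + rnorm(nrow(cells))
  fit <- reml_fit(y, model.matrix(~ env, cells), cells,
                  list(g = rt_known("geno", K)))
  expect_true(all(diff(fit$trace$logL) > -1e-8))
})

test_that("FA(2) recovers a true rank-2 environment covariance (Frobenius, after the shared-scale split)", {
  set.seed(7)
  ng <- 300; ne <- 10
  K <- diag(ng); dimnames(K) <- list(paste0("G", 1:ng), paste0("G", 1:ng))
  L <- cbind(rnorm(ne, 1, 0.3), c(0, rnorm(ne - 1, 0, 0.6)))
  SE <- tcrossprod(L)
  cells <- expand.grid(geno = paste0("G", 1:ng), env = paste0("E", 1:ne),
                       stringsAsFactors = FALSE)
  GE <- matrix(rnorm(ng * 2), ng) %*% t(L)
  y <- rnorm(ne, 0, 2)[as.integer(factor(cells$env))] +
    GE[cbind(as.integer(factor(cells$geno)), as.integer(factor(cells$env)))] +
    rnorm(nrow(cells), 0, 0.8)
  fit <- reml_fit(y, model.matrix(~ env, cells), cells,
                  list(ge = rt_fa("env", "geno", K, q = 2)), maxit = 150)
  SEh <- fa_env_cov(fit, "ge")
  expect_true(fit$converged)
  expect_lt(norm(SEh - SE, "F") / norm(SE, "F"), 0.25)
  # implied covariance must be PSD
  expect_gte(min(eigen(SEh, symmetric = TRUE)$values), -1e-8)
})

test_that("random-regression term recovers intercepts, slopes and omega", {
  set.seed(8)
  ng <- 100; ne <- 10
  K <- diag(ng); dimnames(K) <- list(paste0("G", 1:ng), paste0("G", 1:ng))
  ec <- rnorm(ne)
  cells <- expand.grid(geno = paste0("G", 1:ng), env = 1:ne)
  cells$x <- ec[cells$env]
  Om <- matrix(c(1, 0.3, 0.3, 0.5), 2)
  Cf <- matrix(rnorm(ng * 2), ng) %*% chol(Om)
  gi <- as.integer(factor(cells$geno))
  y <- 2 + 1.5 * cells$x + Cf[gi, 1] + Cf[gi, 2] * cells$x +
    rnorm(nrow(cells), 0, 0.6)
  fit <- reml_fit(y, cbind(1, cells$x), cells,
                  list(rr = rt_rrm("geno", K, "x")))
  Ch <- blup_predict(fit, "rr")
  expect_gt(cor(Ch[, 1], Cf[, 1]), 0.9)
  expect_gt(cor(Ch[, 2], Cf[, 2]), 0.9)
  Omh <- rrm_omega(fit, "rr")
  expect_lt(norm(Omh - Om, "F") / norm(Om, "F"), 0.35)
  expect_gte(min(eigen(Omh, symmetric = TRUE)$values), -1e-8)
})

test_that("blup_predict borrows information through K and returns prior PEV for isolated levels", {
  set.seed(9)
  q <- 12; n <- 40
  # G12 unphenotyped; correlated with G1 through K
  K <- diag(q)
  K[1, 12] <- K[12, 1] <- 0.8
  dimnames(K) <- list(paste0("G", 1:q), paste0("G", 1:q))
  gf <- sample(11, n, replace = TRUE)     # only G1..G11 observed
  y <- rnorm(11, 0, 2)[gf] + rnorm(n, 0, 0.5)
  dat <- data.frame(geno = paste0("G", gf))
  fit <- reml_fit(y, matrix(1, n), dat, list(g = rt_known("geno", K)))
  bp <- blup_predict(fit, "g", pev = TRUE)
  # unphenotyped relative: nonzero prediction, tracks its relative
  expect_gt(abs(bp$blup["G12"]), 1e-6)
  expect_equal(sign(bp$blup["G12"]), sign(bp$blup["G1"]), ignore_attr = TRUE)

  # a level with no data and no covariance: prediction 0, PEV = prior
  K2 <- diag(q); dimnames(K2) <- dimnames(K)
  fit2 <- reml_fit(y, matrix(1, n), dat, list(g = rt_known("geno", K2)))
  bp2 <- blup_predict(fit2, "g", pev = TRUE)
  expect_equal(unname(bp2$blup["G12"]), 0)
  expect_equal(unname(bp2$pev["G12", "G12"]), fit2$theta$g, tolerance = 1e-10)
})

test_that("a non-PSD known covariance is bent with a warning", {
  K <- matrix(c(1, 1.2, 1.2, 1), 2)
  dimnames(K) <- list(c("a", "b"), c("a", "b"))
  expect_warning(rt_known("g", K), "bending")
  K2 <- suppressWarnings(rt_known("g", K))$K
  expect_gte(min(eigen(K2, symmetric = TRUE)$values), 0)
})

test_that("aliased fixed-effect columns are dropped with a warning", {
  set.seed(10)
  n <- 30
  g <- factor(sample(1:5, n, TRUE))
  X <- cbind(1, as.integer(g == "1"), as.integer(g != "1"))  # col3 aliased
  y <- rnorm(n)
  expect_warning(
    fit <- reml_fit(y, X, data.frame(g = g), list(g = rt_iid("g"))),
    "aliased")
  expect_length(fit$beta, 2)
})
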