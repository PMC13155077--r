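# Stage-2 model wrappers: closed-form anchors, nesting, equivariance,
# new-environment prediction and forward stepwise EC selection.

# small shared stage-2 dataset with a known structure
toy_stage2 <- function(seed = 1, ng = 40, ne = 8, sg = 4, sge = 1, se = 1) {
  set.seed(seed)
  K <- diag(ng)
  dimnames(K) <- list(sprintf("G%02d", 1:ng), sprintf("G%02d", 1:ng))
  cells <- expand.grid(genotype = sprintf("G%02d", 1:ng),
                       environment = paste0("E", 1:ne),
                       stringsAsFactors = FALSE)
  cells$trial <- paste0(cells$environment, "_T1")
  g <- rnorm(ng, 0, sqrt(sg)); names(g) <- rownames(K)
  envm <- rnorm(ne, 0, 3); names(envm) <- paste0("E", 1:ne)
  cells$blue <- envm[cells$environment] + g[cells$genotype] +
    rnorm(nrow(cells), 0, sqrt(sge + se))
  cells$weight <- 1
  list(stage2 = cells, K = K, g = g, envm = envm)
}

test_that("with K = I and balanced data GBLUP genotype predictions are shrunken genotype means", {
  tw <- toy_stage2()
  m <- fit_gblup(tw$stage2, tw$K, free_resid = TRUE)
  fit <- m$fit
  # closed form: u_i = sg * ne * (cell-residual mean) / (sg * ne + s_cell)
  # where s_cell lumps the iid ge and weighted residual variances
  d <- tw$stage2
  ctr <- d$blue - ave(d$blue, d$environment)
  gm <- tapply(ctr, d$genotype, mean)
  pred <- predict_cells(m, d)
  # predictions constant within genotype, monotone in the genotype means
  pg <- tapply(pred, d$genotype, unique)
  expect_length(unlist(pg), length(gm))
  expect_gt(cor(unlist(pg)[names(gm)], gm), 0.999)
  # and recover the simulated genotype effects well at this signal level
  expect_gt(cor(unlist(pg)[names(tw$g)], tw$g), 0.85)
})

test_that("a random-regression term with no covariates is exactly the GBLUP genotype term", {
  tw <- toy_stage2(seed = 2, ng = 25, ne = 5)
  d <- as.data.frame(tw$stage2)
  X <- stats::model.matrix(~ environment, d)
  f_known <- reml_fit(d$blue, X, d, list(g = rt_known("genotype", tw$K)))
  f_rr <- reml_fit(d$blue, X, d,
                   list(g = rt_rrm("genotype", tw$K, character(0))))
  expect_equal(f_rr$logLik, f_known$logLik, tolerance = 1e-6)
  expect_equal(unname(f_rr$theta$g), unname(f_known$theta$g),
               tolerance = 1e-4)
})

test_that("an FA term with zero loadings and equal specifics reduces to IID GEI (nested models)", {
  tw <- toy_stage2(seed = 3, ng = 30, ne = 6)
  d <- as.data.frame(tw$stage2)
  d$ge_cell <- paste(d$genotype, d$environment)
  X <- stats::model.matrix(~ environment, d)
  # reference: iid GEI at fixed variances
  sge <- 0.8; se <- 1.1
  f_iid <- reml_fit(d$blue, X, d, list(ge = rt_iid("ge_cell")),
                    init = list(terms = list(sge), resid = se), maxit = 0)
  # FA with specifics, Lambda = 0, psi_j = sge: Sigma_E = sge * I, and the
  # cell kernel K = I makes it the same iid covariance
  ne <- 6
  th_fa <- c(rep(0, ne + ne - 1), rep(sge, ne))   # loadings (q=2), then psi
  f_fa <- reml_fit(d$blue, X, d,
                   list(ge = rt_fa("environment", "genotype", tw$K, q = 2,
                                   specifics = TRUE)),
                   init = list(terms = list(th_fa), resid = se), maxit = 0)
  expect_equal(f_fa$logLik, f_iid$logLik, tolerance = 1e-8)
})

test_that("truth model values behave like genotypic values", {
  pl <- default_pipeline()
  tv <- memo("default_truth", function() fit_truth(pl$blues, pl$K))
  sim <- pl$sim
  # linearity: doubling the response doubles the truth values at fixed theta
  d <- tv$model$stage2
  th <- tv$model$fit$theta
  d2 <- d; d2$blue <- 2 * d$blue
  tv2 <- fit_truth(d2, pl$K, init = list(terms = unname(th), resid = 1),
                   maxit = 0)
  expect_equal(tv2$values$truth, 2 * tv$values$truth, tolerance = 1e-6)
  # agreement with the generative genotypic values on the default dataset
  gt <- sim$truth$cells
  pos <- match(paste(tv$values$genotype, tv$values$trial),
               paste(gt$genotype, gt$trial))
  expect_gt(cor(tv$values$truth, gt$genvalue[pos], use = "complete"), 0.75)
})

test_that("truth values are nearly constant across trials when the data have no GEI", {
  vf <- c(year = 0.1, location = 0.02, sowing = 0.01, env = 0.12,
          fixed_ec = 0, trial = 0.05, rep = 0.01, block = 0.01,
          intercept = 0.30, slope = 0, ge = 0, resid = 0.38)
  cfg <- sim_config(seed = 21, n_genotypes = 80, n_loci = 200, n_founders = 12,
                    years = 2017:2019, var_frac = vf)
  sim <- simulate_dataset(cfg)
  s1 <- fit_trials(sim$pheno)
  K <- vanraden_grm(qc_markers(sim$markers))
  tv <- suppressWarnings(fit_truth(s1$blues, K, maxit = 120))
  v <- tv$values
  sds <- tapply(v$truth, v$genotype, sd)
  gsd <- sd(tapply(v$truth, v$genotype, mean))
  counts <- table(v$genotype)
  expect_lt(median(sds[names(counts)[counts >= 3]], na.rm = TRUE) / gsd, 0.35)
})

test_that("RRM slope estimates scale inversely with the EC unit when standardisation is off", {
  tw <- toy_stage2(seed = 5, ng = 30, ne = 6)
  d <- tw$stage2
  set.seed(5)
  ecv <- rnorm(6); names(ecv) <- paste0("E", 1:6)
  ecm <- data.frame(genotype = d$genotype, trial = d$trial,
                    environment = d$environment,
                    VTmax = ecv[d$environment])
  class(ecm) <- c("ECMatrix", "data.frame")
  slope <- rnorm(30, 0, 1.5); names(slope) <- rownames(tw$K)
  d$blue <- d$blue + slope[d$genotype] * ecm$VTmax
  m1 <- fit_rrm(d, tw$K, ecm, "VTmax", standardize = FALSE)
  # exact equivariance: evaluate the 10x-EC model at the transformed
  # parameters (omega scaled by D = diag(1, 1/10)); same restricted
  # likelihood, slopes divided by 10, identical cell predictions
  ecm10 <- ecm; ecm10$VTmax <- 10 * ecm$VTmax
  Om1 <- rrm_omega(m1$fit, "rr")
  D <- diag(c(1, 1 / 10))
  th10 <- list(
    rr = ecrrm:::omega_pack(m1$fit$terms[[1]], D %*% Om1 %*% D),
    ge = m1$fit$theta$ge, trial = m1$fit$theta$trial)
  m10 <- fit_rrm(d, tw$K, ecm10, "VTmax", standardize = FALSE,
                 init = list(terms = unname(th10), resid = m1$fit$sigma_e),
                 maxit = 0)
  # the fixed design gains a factor-10 column: REML logL shifts by log 10
  expect_equal(m10$fit$logLik, m1$fit$logLik - log(10), tolerance = 1e-8)
  C1 <- blup_predict(m1$fit, "rr"); C10 <- blup_predict(m10$fit, "rr")
  expect_equal(C10[, "VTmax"], C1[, "VTmax"] / 10, tolerance = 1e-8)
  expect_equal(predict_cells(m10, d, ecm10), predict_cells(m1, d, ecm),
               tolerance = 1e-8)
})

test_that("new-environment prediction interpolates and is ranking-invariant to EC shifts", {
  tw <- toy_stage2(seed = 6, ng = 30, ne = 6)
  d <- tw$stage2
  set.seed(6)
  ecv <- rnorm(6); names(ecv) <- paste0("E", 1:6)
  slope <- rnorm(30, 0, 1.5); names(slope) <- rownames(tw$K)
  ecm <- data.frame(genotype = d$genotype, trial = d$trial,
                    environment = d$environment, VTmax = ecv[d$environment])
  class(ecm) <- c("ECMatrix", "data.frame")
  d$blue <- d$blue + slope[d$genotype] * ecm$VTmax
  m <- fit_rrm(d, tw$K, ecm, "VTmax")

  # a "new" environment with ECs identical to E3's rows predicts the same
  new_cells <- d[d$environment == "E3", c("genotype", "trial", "environment")]
  p_train <- predict_cells(m, new_cells, ecm)
  ecm_new <- ecm[ecm$environment == "E3", ]
  ecm_new$trial <- "NEW_T1"; ecm_new$environment <- "NEW"
  class(ecm_new) <- c("ECMatrix", "data.frame")
  nc <- data.frame(genotype = new_cells$genotype, trial = "NEW_T1")
  p_new <- predict_new_environment(m, nc, ecm_new)
  expect_equal(unname(p_new), unname(p_train), tolerance = 1e-10)

  # a constant added to the fixed part shifts every genotype equally:
  # within-environment ranking is untouched
  p_shift <- p_new + 123.4
  expect_equal(order(p_shift), order(p_new))

  # missing EC rows are dropped with a warning
  nc_bad <- rbind(nc, data.frame(genotype = "GXX", trial = "NEW_T1"))
  expect_warning(p3 <- predict_new_environment(m, nc_bad, ecm_new), "dropping")
  expect_length(p3, nrow(nc))
})

test_that("forward stepwise picks the truly active EC first and logs its score table", {
  tw <- toy_stage2(seed = 7, ng = 36, ne = 8, sg = 2)
  d <- tw$stage2
  set.seed(7)
  ecs <- data.frame(genotype = d$genotype, trial = d$trial,
                    environment = d$environment)
  for (nm in c("VTmax", "RPP", "VPP"))
    ecs[[nm]] <- rnorm(8)[as.integer(factor(d$environment))]
  ecs$DUP <- ecs$VTmax                     # exact duplicate of the active EC
  class(ecs) <- c("ECMatrix", "data.frame")
  slope <- rnorm(36, 0, 2); names(slope) <- rownames(tw$K)
  d$blue <- d$blue + slope[d$genotype] * ecs$VTmax
  tv <- fit_truth(d, tw$K)
  # identity-K toy: CV1-masked genotypes would be unpredictable (no
  # relatives), so the stepwise protocol scores under CV2
  fs <- forward_stepwise(d, tw$K, ecs, c("VTmax", "RPP", "VPP"), tv,
                         scheme = "CV2", n_iter = 1, seed = 3, max_size = 2)
  expect_equal(fs$path[1], "VTmax")
  # score table has one row per candidate per step
  expect_equal(sum(fs$scores$size == 1), 3L)
  expect_equal(sum(fs$scores$size == 2), 2L)

  # a duplicated EC scores identically (tie broken by name) and its later
  # addition never improves on the single-copy model
  fs2 <- forward_stepwise(d, tw$K, ecs, c("VTmax", "DUP"), tv,
                          scheme = "CV2", n_iter = 1, seed = 3, max_size = 2)
  s2 <- fs2$scores
  expect_true(fs2$path[1] %in% c("VTmax", "DUP"))
  s1_scores <- s2$median_ability[s2$size == 1]
  expect_equal(s1_scores[1], s1_scores[2], tolerance = 1e-6)
  second <- s2$median_ability[s2$size == 2]
  # adding the identical copy either fails to fit (recorded NA) or does not
  # improve on the single-copy model
  if (length(second) && !is.na(second))
    expect_lte(second, max(s1_scores) + 0.05)
})
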