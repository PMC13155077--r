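# The breeding-program generator: determinism, marginal distributions,
# degenerate limits, and the generative identities of the reaction-norm truth.

test_that("generators are fully deterministic under the seed", {
  cfg <- sim_config(seed = 42, n_genotypes = 40, n_loci = 60, n_founders = 8,
                    years = 2019:2020)
  m1 <- simulate_markers(cfg)$dosage
  m2 <- simulate_markers(cfg)$dosage
  expect_identical(m1, m2)
  s1 <- simulate_program(cfg)
  s2 <- simulate_program(cfg)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  w1 <- simulate_weather(s1, cfg)
  w2 <- simulate_weather(s2, cfg)
  expect_identical(as.data.frame(w1), as.data.frame(w2))
})

test_that("marker dosages have the configured support and mean", {
  cfg <- sim_config(seed = 7, n_genotypes = 50, n_loci = 10,
                    maf_range = c(0.05, 0.5))
  M <- simulate_markers(cfg)$dosage
  expect_true(all(M %in% c(0, 1, 2)))

  # p fixed at 0.5, outbred HWE draw: mean dosage within 3 SE of 1
  cfg2 <- sim_config(seed = 8, n_genotypes = 30, n_loci = 1e4,
                     n_founders = 0, inbreeding = 0,
                     maf_range = c(0.5, 0.5))
  M2 <- simulate_markers(cfg2)$dosage
  se <- sqrt(0.5 / length(M2))            # var(binom(2,.5))/2 = 0.5
  expect_lt(abs(mean(M2) - 1), 3 * se)
  # and heterozygosity matches HWE when outbred
  expect_lt(abs(mean(M2 == 1) - 0.5), 0.05)

  # inbred lines have low heterozygosity (passes the QC filter)
  cfg3 <- sim_config(seed = 9, n_genotypes = 60, n_loci = 500)
  M3 <- simulate_markers(cfg3)$dosage
  expect_lt(mean(M3 == 1), 0.10)
})

test_that("program turnover controls year-to-year genotype sharing", {
  base <- list(n_genotypes = 120, n_loci = 20, years = 2017:2020)
  sk0 <- simulate_program(do.call(sim_config, c(list(seed = 1, turnover = 0),
                                                base)))
  sets0 <- tapply(sk0$genotype, sk0$year, unique)
  for (i in 2:length(sets0)) expect_setequal(sets0[[i]], sets0[[1]])

  cfg5 <- do.call(sim_config, c(list(seed = 2, turnover = 0.5), base))
  sk5 <- simulate_program(cfg5)
  sets5 <- tapply(sk5$genotype, sk5$year, unique)
  A <- length(sets5[[1]])
  for (i in 2:length(sets5)) {
    shared <- length(intersect(sets5[[i - 1]], sets5[[i]]))
    # binomial 99% bounds around (1 - turnover) * A
    bound <- 2.58 * sqrt(A * 0.25)
    expect_gt(shared, 0.5 * A - bound - 1)
    expect_lt(shared, 0.5 * A + bound + 1)
  }

  # environment grid: 2 years x 2 locations x 1 window -> 4 environments
  cfgE <- sim_config(seed = 3, n_genotypes = 60, n_loci = 20,
                     years = 2019:2020, locations = c("LE", "YG"),
                     sowing_periods = "OPT")
  skE <- simulate_program(cfgE)
  expect_equal(nrow(attr(skE, "environments")), 4L)
  expect_equal(length(unique(skE$environment)), 4L)
  # generated skeletons pass the data-model validators by construction
  expect_s3_class(phenotype_table(as.data.frame(skE)), "PhenotypeTable")
})

test_that("weather degenerates correctly and respects its invariants", {
  cfg <- sim_config(seed = 4, n_genotypes = 30, n_loci = 20,
                    years = 2019, sowing_periods = "OPT",
                    diurnal_amplitude = 0, temp_noise_sd = 0)
  sk <- simulate_program(cfg)
  w <- simulate_weather(sk, cfg)
  expect_equal(w$tmax, w$tmean, tolerance = 1e-12)
  expect_equal(w$tmin, w$tmean, tolerance = 1e-12)

  cfg2 <- sim_config(seed = 4, n_genotypes = 30, n_loci = 20,
                     years = 2019, sowing_periods = "OPT", wet_day_prob = 0)
  w2 <- simulate_weather(simulate_program(cfg2), cfg2)
  expect_equal(sum(w2$prcp), 0)

  # general case satisfies the WeatherTable invariants (validated inside)
  cfg3 <- sim_config(seed = 5, n_genotypes = 30, n_loci = 20, years = 2019)
  w3 <- simulate_weather(simulate_program(cfg3), cfg3)
  expect_true(all(w3$tmin <= w3$tmean & w3$tmean <= w3$tmax))
  expect_true(all(w3$prcp >= 0 & w3$et >= 0 & w3$srad > 0))
})

test_that("phenology masks the configured fraction and respects variance limits", {
  cfg <- sim_config(seed = 6, n_genotypes = 150, n_loci = 100,
                    heading_miss_frac = 0.3)
  sk <- simulate_program(cfg)
  ms <- simulate_markers(cfg, ids = sort(unique(sk$genotype)))
  phn <- simulate_phenology(sk, ms, cfg)
  n <- nrow(phn$truth)
  nmask <- sum(phn$truth$masked)
  expect_lt(abs(nmask - 0.3 * n), 3 * sqrt(n * 0.3 * 0.7) + 1)

  # all variances zero: every genotype heads on the trial mean day
  cfg0 <- sim_config(seed = 6, n_genotypes = 40, n_loci = 20, years = 2019,
                     heading_var = c(geno = 0, year = 0, location = 0,
                                     gy = 0, gl = 0, resid = 0),
                     heading_period_shift = c(PRE = 0, OPT = 0, POS = 0))
  sk0 <- simulate_program(cfg0)
  phn0 <- simulate_phenology(sk0, simulate_markers(cfg0, sort(unique(sk0$genotype))),
                             cfg0)
  per_trial <- tapply(phn0$truth$heading_days, phn0$truth$trial,
                      function(x) length(unique(x)))
  expect_true(all(per_trial == 1))

  # strong genotypic control: heading repeatability across trials > 0.9
  cfgh <- sim_config(seed = 7, n_genotypes = 100, n_loci = 200,
                     heading_var = c(geno = 49, year = 4, location = 1,
                                     gy = 1, gl = 0.5, resid = 1))
  skh <- simulate_program(cfgh)
  phnh <- simulate_phenology(skh, simulate_markers(cfgh, sort(unique(skh$genotype))),
                             cfgh)
  tr <- phnh$truth
  tr$dev <- tr$heading_days - ave(tr$heading_days, tr$trial)
  counts <- table(tr$genotype)
  multi <- names(counts)[counts >= 4]
  icc <- summary(aov(dev ~ genotype, tr[tr$genotype %in% multi, ]))
  ms_b <- icc[[1]]$`Mean Sq`[1]; ms_w <- icc[[1]]$`Mean Sq`[2]
  k <- mean(counts[multi])
  rep_icc <- (ms_b - ms_w) / (ms_b + (k - 1) * ms_w)
  expect_gt(rep_icc, 0.9)
})

test_that("degenerate yield configs reproduce their closed-form limits", {
  # all variance in the environment effect: yields constant within environment
  vf0 <- c(year = 0, location = 0, sowing = 0, env = 1, fixed_ec = 0,
           trial = 0, rep = 0, block = 0, intercept = 0, slope = 0,
           ge = 0, resid = 0)
  cfg <- sim_config(seed = 8, n_genotypes = 40, n_loci = 20, years = 2019,
                    var_frac = vf0)
  sim <- simulate_dataset(cfg)
  within_env_sd <- tapply(sim$pheno$yield, sim$pheno$environment, sd)
  # a hair of jitter (~1e-3 kg/ha) comes from the PSD guard on omega*
  expect_lt(max(within_env_sd), 0.01)

  # noise-free single-EC reaction norm: the yield difference of a genotype
  # between two trials is exactly slope x delta(EC) + delta(environment part)
  vf1 <- c(year = 0, location = 0, sowing = 0, env = 0, fixed_ec = 0,
           trial = 0, rep = 0, block = 0, intercept = 0.3, slope = 0.7,
           ge = 0, resid = 0)
  cfg1 <- sim_config(seed = 9, n_genotypes = 40, n_loci = 50, years = 2019:2020,
                     var_frac = vf1, active_ecs = "VTmax")
  sim1 <- simulate_dataset(cfg1)
  tr <- sim1$truth
  ec <- tr$ec_matrix
  ecz <- (ec$VTmax - tr$ec_center["VTmax"]) / tr$ec_scale["VTmax"]
  pred <- tr$coefficients[ec$genotype, "(Intercept)"] +
    tr$coefficients[ec$genotype, "VTmax"] * ecz
  # plot yields equal mean + cell genetic value exactly (no other terms)
  d <- as.data.frame(sim1$pheno)
  pos <- match(paste(d$genotype, d$trial), paste(ec$genotype, ec$trial))
  expect_equal(d$yield, unname(cfg1$mean_yield + pred[pos]), tolerance = 1e-8)
})

test_that("realised coefficient covariance converges to the K-weighted omega_star", {
  cfg <- sim_config(seed = 10, n_genotypes = 2000, n_loci = 300,
                    n_founders = 100, years = 2019, active_ecs = c("VTmax", "RPP"))
  ids <- geno_ids(cfg$n_genotypes)
  ms <- simulate_markers(cfg, ids)
  K <- vanraden_grm(qc_markers(ms, maf_min = 0, het_max = 1, miss_max = 1))
  # reproduce the coefficient draw exactly as simulate_yield does
  V <- cfg$var_total; fr <- cfg$var_frac; nact <- 2
  omega_star <- diag(c(fr["intercept"], rep(fr["slope"] / nact, nact)),
                     1 + nact) * V
  with_stream <- ecrrm:::with_stream
  Cmat <- with_stream(cfg$seed + 5L, {
    Lk <- chol(K + diag(1e-6, nrow(K)))
    Z <- matrix(rnorm(nrow(K) * 3), nrow(K))
    crossprod(Lk, Z) %*% chol(omega_star + diag(1e-12 * V, 3))
  })
  # E[C'C]/n = mean(diag(K)) * omega_star
  emp <- crossprod(Cmat) / nrow(Cmat)
  expect_lt(norm(emp - mean(diag(K)) * omega_star, "F") /
              norm(mean(diag(K)) * omega_star, "F"), 0.15)
})

test_that("simulated datasets round-trip through the plain-text writers", {
  cfg <- sim_config(seed = 11, n_genotypes = 30, n_loci = 20, years = 2019,
                    sowing_periods = "OPT")
  sim <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_dataset(sim, dir)
  ph <- read_phenotypes(file.path(dir, "phenotypes.csv"))
  expect_equal(nrow(ph), nrow(sim$pheno))
  expect_equal(sort(unique(ph$environment)), sort(unique(sim$pheno$environment)))
  w <- read_weather(file.path(dir, "weather.csv"))
  expect_equal(nrow(w), nrow(sim$weather))
  m <- read_markers(file.path(dir, "markers.tsv"))
  expect_equal(m$dosage, sim$markers$dosage)
  expect_true(file.exists(file.path(dir, "truth.json")))
})
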