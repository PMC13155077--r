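# Shared fixtures, memoised so expensive objects are built once per session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (!exists(name, .fixture_cache)) assign(name, build(), .fixture_cache)
  get(name, .fixture_cache)
}

# Desk-scale default synthetic dataset (the study conditions).
default_sim <- function() memo("default_sim", function() {
  simulate_dataset(sim_config(seed = 11))
})

# Stage-1 + GRM + ECs derived from the default dataset.
default_pipeline <- function() memo("default_pipeline", function() {
  sim <- default_sim()
  ph <- suppressMessages(filter_environments(sim$pheno, 25))
  ph <- predict_heading(ph)
  ecm <- build_ec_matrix(ph, sim$weather, policy = "clip")
  s1 <- fit_trials(ph)
  K <- vanraden_grm(qc_markers(sim$markers))
  list(sim = sim, pheno = ph, ecm = ecm, blues = s1$blues, h2 = s1$h2, K = K)
})

# Small constant-weather table for EC unit tests.
toy_weather <- function(env = "2019_LE_OPT", start = as.Date("2019-05-20"),
                        days = 160, tmin = 5, tmax = 15, prcp = 2,
                        srad = 12, et = 2, rh = 70, wind = 3, cloud = 40) {
  dates <- start + seq_len(days) - 1
  weather_table(data.frame(
    environment = env, date = dates, prcp = prcp, tmax = tmax, tmin = tmin,
    tmean = (tmin + tmax) / 2, rh = rh, srad = srad, wind = wind, et = et,
    cloud = cloud))
}

# Tiny balanced RCBD phenotype table.
toy_rcbd <- function(yields, genotypes = NULL, reps = NULL,
                     trial = "2019_LE_OPT_EYT") {
  g <- length(unique(genotypes)); r <- length(yields) / g
  df <- data.frame(
    genotype = genotypes, location = "LE", trial = trial,
    replicate = reps, sowing_date = as.Date("2019-05-20"),
    harvest_date = as.Date("2019-11-10"), yield = yields)
  phenotype_table(df)
}

# Heading-date regime of the study system: highly heritable heading with
# year/location structure dominating the window shift and noise.
heading_regime_config <- function(seed = 13) {
  sim_config(seed = seed,
             heading_var = c(geno = 36, year = 16, location = 4,
                             gy = 3, gl = 1, resid = 2),
             heading_period_shift = c(PRE = 2, OPT = 0, POS = -2))
}

# Masked-cell heading prediction correlation for a config.
heading_recovery <- function(cfg) {
  sk <- simulate_program(cfg)
  ms <- simulate_markers(cfg, ids = sort(unique(sk$genotype)))
  phn <- suppressWarnings(simulate_phenology(sk, ms, cfg))
  filled <- predict_heading(phn$pheno)
  cells <- unique(as.data.frame(filled)[, c("genotype", "trial",
                                            "sowing_date", "heading_date")])
  tr <- phn$truth
  pos <- match(paste(tr$genotype, tr$trial), paste(cells$genotype, cells$trial))
  pred <- as.numeric(cells$heading_date[pos] - cells$sowing_date[pos])
  cor(pred[tr$masked], tr$heading_days[tr$masked])
}

# Misspecified-GEI dataset and its stage-2 pieces (for the CV2 ordering).
misspec_pipeline <- function() memo("misspec_pipeline", function() {
  sim <- simulate_dataset(sim_config(seed = 11, fa_gei = TRUE))
  ph <- suppressMessages(filter_environments(sim$pheno, 25))
  ph <- predict_heading(ph)
  ecm <- build_ec_matrix(ph, sim$weather, policy = "clip")
  s1 <- fit_trials(ph)
  K <- vanraden_grm(qc_markers(sim$markers))
  list(sim = sim, ecm = ecm, blues = s1$blues, K = K)
})
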