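# ---------------------------------------------------------------------------
# Synthetic multi-year breeding-program generator.
#
# The generative yield model is deliberately the random-regression reaction
# norm read forward -- plot yield = environment/design terms + fixed EC
# regression + genotype intercept + genotype slopes x standardised ECs +
# IID genotype-by-environment effect + plot error, with (intercept, slopes)
# drawn matrix-normal with genotype covariance K (from the simulated markers)
# and coefficient covariance Omega* -- so that parameter recovery by the
# fitted models is a well-posed check. A misspecification switch (`fa_gei`)
# converts part of the IID GEI into low-rank (factor-style) GEI that no EC
# explains.
#
# Every generator draws from its own RNG stream, seeded from the master seed
# by a fixed offset, so adding one generator never perturbs the others.
# ---------------------------------------------------------------------------

with_stream <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed %% .Machine$integer.max)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  expr
}

#' Configuration of the synthetic breeding program
#'
#' Defaults describe a desk-scale program patterned on a national wheat
#' breeding system: ~300 genotypes cycling through three trial stages
#' (preliminary, advanced, elite) over 5 years x 2 locations x 2 sowing
#' windows (20 environments), 50% genotype turnover per year, heritable
#' heading dates, seasonal southern-hemisphere daily weather, and plot yields
#' from a known intercept+slope reaction-norm truth. `var_frac` gives the
#' plot-level variance shares (must sum to 1): the genetic share is
#' `intercept + slope`, and the slope share is split equally over the
#' `active_ecs` -- with the default three active ECs each slope carries 30%
#' of the genetic variance and the intercept the remaining 10%, a strongly
#' GEI-driven genetic architecture.
#'
#' @param seed master seed (mandatory; every generator derives its stream
#'   from it).
#' @param n_genotypes target number of distinct genotypes over the program.
#' @param n_loci number of biallelic SNP loci.
#' @param n_founders founder lines of the crossing program; each simulated
#'   genotype is an inbred line derived from a biparental founder cross, so
#'   lines sharing a founder are related (half of real breeding-program
#'   relatedness structure that GBLUP exploits).
#' @param years,locations,sowing_periods the environment grid.
#' @param turnover fraction of active genotypes replaced each year, in \[0,1).
#' @param maf_range allele-frequency range for simulated loci.
#' @param inbreeding inbreeding coefficient F of the simulated lines; wheat
#'   breeding lines are near-fully inbred, so residual heterozygosity is
#'   `2p(1-p)(1-F)` per locus (well under the 10% QC threshold).
#' @param mean_yield overall mean (kg/ha).
#' @param var_total plot-level phenotypic variance ((kg/ha)^2).
#' @param var_frac named variance fractions (year, location, sowing, env,
#'   fixed_ec, trial, rep, block, intercept, slope, ge, resid).
#' @param active_ecs EC columns carrying true genotype slopes.
#' @param fa_gei if TRUE (the model-misspecification switch), the generator
#'   describes a world where the chosen ECs under-describe the GEI: two
#'   thirds of the slope share, two thirds of the `ge` share and 0.04 taken
#'   from the residual become rank-2 factor-style GEI that no EC explains,
#'   leaving the ECs with roughly a fifth of the structured GEI.
#' @param heading_var heading-date variance components (days^2): geno, year,
#'   location, gy, gl, resid.
#' @param heading_base mean days from sowing to heading in the optimal window.
#' @param heading_period_shift named per-window shift (days) of the trial
#'   mean heading; kept small by default, mirroring systems where heading is
#'   highly predictable from genotype, year and location.
#' @param heading_miss_mode `"uniform"` masks a flat fraction of
#'   genotype-trial records at random; `"by_trial"` reproduces the breeding-
#'   record pattern where 20-90% of genotypes go unscored in a fraction of
#'   trials.
#' @param heading_miss_frac overall masked fraction (uniform mode).
#' @param heading_miss_trial_frac fraction of trials with missing heading
#'   (by_trial mode).
#' @param heading_miss_range range of the per-trial missing fraction
#'   (by_trial mode).
#' @param season_length days from sowing to harvest.
#' @param diurnal_amplitude mean daily Tmax - Tmin (deg C).
#' @param temp_noise_sd AR(1) day-to-day temperature noise SD.
#' @param wet_day_prob daily probability of rain.
#' @param reps_rcbd,reps_alpha,n_blocks design constants for elite (RCBD) and
#'   preliminary/advanced (alpha-lattice) trials.
#' @return a validated `SimulationConfig` list.
#' @export
sim_config <- function(seed,
                       n_genotypes = 300,
                       n_loci = 1000,
                       n_founders = 25,
                       years = 2016:2020,
                       locations = c("LE", "YG"),
                       sowing_periods = c("OPT", "POS"),
                       turnover = 0.5,
                       maf_range = c(0.05, 0.5),
                       inbreeding = 0.95,
                       mean_yield = 4800,
                       var_total = 1.3e6,
                       var_frac = c(year = 0.22, location = 0.04,
                                    sowing = 0.02, env = 0.12,
                                    fixed_ec = 0.20, trial = 0.06,
                                    rep = 0.012, block = 0.013,
                                    intercept = 0.012, slope = 0.102,
                                    ge = 0.036, resid = 0.165),
                       active_ecs = c("VTmax", "RPP", "VPP"),
                       fa_gei = FALSE,
                       heading_var = c(geno = 25, year = 16, location = 4,
                                       gy = 6, gl = 2, resid = 4),
                       heading_base = 95,
                       heading_period_shift = c(PRE = 4, OPT = 0, POS = -4),
                       heading_miss_mode = c("uniform", "by_trial"),
                       heading_miss_frac = 0.3,
                       heading_miss_trial_frac = 0.3,
                       heading_miss_range = c(0.2, 0.9),
                       season_length = 178,
                       diurnal_amplitude = 10,
                       temp_noise_sd = 2.5,
                       wet_day_prob = 0.35,
                       reps_rcbd = 3, reps_alpha = 2, n_blocks = 6) {
  if (missing(seed)) stop("seed is mandatory (no implicit entropy)")
  heading_miss_mode <- match.arg(heading_miss_mode)
  stopifnot(turnover >= 0, turnover < 1,
            all(var_frac >= 0), all(heading_var >= 0),
            abs(sum(var_frac) - 1) < 1e-8,
            season_length >= 60,
            all(active_ecs %in% ec_names()))
  cfg <- as.list(environment())
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Simulate biallelic marker dosages
#'
#' Per-locus allele frequency uniform in `maf_range`. A panel of
#' `n_founders` fully inbred founders is drawn first (haplotype =
#' Bernoulli(p) per locus); each simulated genotype is then an inbred line
#' from a biparental founder cross: at every locus it carries one of its two
#' founders' alleles (chosen independently, i.e. free recombination) and is
#' autozygous with probability `inbreeding`, heterozygous otherwise. Lines
#' sharing founders are therefore genuinely related, as in a breeding
#' program. With `n_founders = 0` unrelated lines are drawn directly.
#'
#' @param config a [sim_config()].
#' @param ids optional genotype ids (default `G001...G<n_genotypes>`).
#' @return a `MarkerSet`.
#' @export
simulate_markers <- function(config, ids = NULL) {
  stopifnot(config$n_loci >= 10)
  if (is.null(ids)) ids <- geno_ids(config$n_genotypes)
  if (min(config$maf_range) <= 0 || max(config$maf_range) >= 1)
    warning("allele-frequency range touches 0/1; monomorphic loci possible")
  with_stream(config$seed + 1L, {
    nl <- config$n_loci
    p <- stats::runif(nl, config$maf_range[1], config$maf_range[2])
    Fi <- config$inbreeding
    ng <- length(ids)
    nf <- config$n_founders
    if (nf >= 2) {
      founders <- vapply(p, function(pp) stats::rbinom(nf, 1, pp),
                         numeric(nf))              # nf x nl haplotypes
      par1 <- sample(nf, ng, replace = TRUE)
      par2 <- sample(nf, ng, replace = TRUE)
      pick1 <- matrix(stats::runif(ng * nl) < 0.5, ng, nl)
      hapA <- founders[par1, , drop = FALSE]
      hapB <- founders[par2, , drop = FALSE]
      a1 <- ifelse(pick1, hapA, hapB)              # inherited allele
      auto <- matrix(stats::runif(ng * nl) < Fi, ng, nl)
      M <- ifelse(auto, 2 * a1, hapA + hapB)
    } else {
      M <- vapply(p, function(pp) {
        auto <- stats::runif(ng) < Fi
        ifelse(auto, 2 * stats::rbinom(ng, 1, pp), stats::rbinom(ng, 2, pp))
      }, numeric(ng))
    }
    dimnames(M) <- list(ids, sprintf("M%05d", seq_len(nl)))
    marker_set(M)
  })
}

geno_ids <- function(n) sprintf("G%04d", seq_len(n))

#' Simulate the trial skeleton of an unbalanced breeding program
#'
#' Each year keeps a random (1 - turnover) fraction of the active genotypes
#' and fills back to size with new entries; stage is age within the program
#' (1 = preliminary, 2 = advanced, >= 3 = elite). Preliminary trials run only
#' at the first location/first sowing window, advanced trials at every
#' location of the first window, elite trials in every environment.
#' Elite trials are RCBDs; earlier stages are alpha-lattices with incomplete
#' blocks nested in replicates.
#'
#' @param config a [sim_config()].
#' @return a `PhenotypeTable` skeleton (yield and heading `NA`), with the
#'   environment table attached as `attr(, "environments")`.
#' @export
simulate_program <- function(config) {
  cfg <- config
  ny <- length(cfg$years)
  A <- max(20L, round(cfg$n_genotypes / (1 + (ny - 1) * cfg$turnover)))
  with_stream(cfg$seed + 2L, {
    pool_n <- 0L
    draw_new <- function(k) {
      ids <- sprintf("G%04d", pool_n + seq_len(k))
      pool_n <<- pool_n + k
      ids
    }
    active <- draw_new(A)
    age <- sample(1:3, A, replace = TRUE, prob = c(0.45, 0.3, 0.25))
    envs <- expand.grid(location = cfg$locations, period = cfg$sowing_periods,
                        year = cfg$years, stringsAsFactors = FALSE)
    envs$sowing_date <- sowing_date_for(envs$year, envs$period)
    envs$harvest_date <- envs$sowing_date + cfg$season_length
    envs$environment <- environment_id(envs$year, envs$location, envs$period)

    rows <- list()
    for (yi in seq_len(ny)) {
      yr <- cfg$years[yi]
      if (yi > 1) {
        keep <- stats::runif(length(active)) >= cfg$turnover
        active <- active[keep]; age <- pmin(age[keep] + 1L, 3L)
        n_new <- A - length(active)
        if (n_new > 0) {
          active <- c(active, draw_new(n_new))
          age <- c(age, rep(1L, n_new))
        }
      }
      stage <- c("PYT", "AYT", "EYT")[age]
      for (st in c("PYT", "AYT", "EYT")) {
        gset <- active[stage == st]
        if (!length(gset)) next
        host <- switch(st,
          PYT = envs[envs$year == yr & envs$location == cfg$locations[1] &
                       envs$period == cfg$sowing_periods[1], , drop = FALSE],
          AYT = envs[envs$year == yr & envs$period == cfg$sowing_periods[1], ,
                     drop = FALSE],
          EYT = envs[envs$year == yr, , drop = FALSE])
        for (h in seq_len(nrow(host))) {
          ev <- host[h, ]
          trial <- paste(ev$environment, st, sep = "_")
          if (st == "EYT") {
            nrep <- cfg$reps_rcbd
            for (r in seq_len(nrep))
              rows[[length(rows) + 1L]] <- data.frame(
                genotype = sample(gset), year = ev$year,
                location = ev$location, sowing_period = ev$period,
                trial = trial, replicate = paste0("R", r),
                block = NA_character_, stringsAsFactors = FALSE)
          } else {
            nrep <- cfg$reps_alpha
            nb <- min(cfg$n_blocks, length(gset))
            for (r in seq_len(nrep)) {
              ord <- sample(gset)
              blk <- paste0("B", rep(seq_len(nb),
                                     each = ceiling(length(ord) / nb))[seq_along(ord)])
              rows[[length(rows) + 1L]] <- data.frame(
                genotype = ord, year = ev$year, location = ev$location,
                sowing_period = ev$period, trial = trial,
                replicate = paste0("R", r), block = blk,
                stringsAsFactors = FALSE)
            }
          }
        }
      }
    }
    sk <- do.call(rbind, rows)
    sk$sowing_date <- envs$sowing_date[match(
      environment_id(sk$year, sk$location, sk$sowing_period), envs$environment)]
    sk$harvest_date <- sk$sowing_date + cfg$season_length
    sk$yield <- NA_real_
    sk$heading_date <- as.Date(NA)
    out <- phenotype_table(sk)
    if (any(tapply(out$genotype, out$environment, length) == 0))
      stop("configuration produced an environment with zero genotypes")
    attr(out, "environments") <- envs
    attr(out, "seed") <- cfg$seed
    out
  })
}

sowing_date_for <- function(year, period) {
  anchor <- c(PRE = "-04-28", OPT = "-05-22", POS = "-06-22")
  jit <- c(PRE = 10, OPT = 12, POS = 10)
  as.Date(paste0(year, anchor[period])) +
    floor(stats::runif(length(year), 0, jit[period] + 1))
}

#' Simulate daily weather per environment
#'
#' Daily mean temperature follows a seasonal harmonic (southern hemisphere:
#' coldest in July) plus year/location shifts and AR(1) noise; Tmax/Tmin are
#' Tmean +/- half the diurnal amplitude with non-negative half-range noise so
#' Tmin <= Tmean <= Tmax always holds. Precipitation is a wet-day process
#' with gamma amounts; solar radiation follows the inverse seasonal cycle
#' damped on wet days; relative humidity, cloud cover and wind are generated
#' in plausible ranges; evapotranspiration uses a Hargreaves-style form,
#' increasing in radiation and temperature.
#'
#' @param environments the environment table (see
#'   `attr(simulate_program(...), "environments")`) or a `PhenotypeTable`
#'   skeleton.
#' @param config a [sim_config()].
#' @return a `WeatherTable` covering sowing-5 .. harvest+5 days per
#'   environment.
#' @export
simulate_weather <- function(environments, config) {
  cfg <- config
  if (inherits(environments, "PhenotypeTable"))
    environments <- attr(environments, "environments")
  stopifnot(cfg$season_length >= 60)
  with_stream(cfg$seed + 3L, {
    yr_shift <- stats::rnorm(length(cfg$years), 0, 1.2)
    names(yr_shift) <- as.character(cfg$years)
    loc_shift <- seq(0, 0.8, length.out = max(length(cfg$locations), 2))
    names(loc_shift)[seq_along(cfg$locations)] <- cfg$locations
    out <- lapply(seq_len(nrow(environments)), function(i) {
      ev <- environments[i, ]
      dates <- seq(ev$sowing_date - 5, ev$harvest_date + 5, by = "day")
      nd <- length(dates)
      doy <- as.integer(format(dates, "%j"))
      seas <- cos(2 * pi * (doy - 15) / 365)
      ar <- stats::filter(stats::rnorm(nd, 0, cfg$temp_noise_sd * sqrt(1 - 0.7^2)),
                          0.7, method = "recursive")
      tmean <- 17 + 8 * seas + yr_shift[as.character(ev$year)] +
        loc_shift[ev$location] + as.numeric(ar)
      half_up <- pmax(0, cfg$diurnal_amplitude / 2 +
                        stats::rnorm(nd, 0, 0.15 * cfg$diurnal_amplitude))
      half_dn <- pmax(0, cfg$diurnal_amplitude / 2 +
                        stats::rnorm(nd, 0, 0.15 * cfg$diurnal_amplitude))
      tmax <- tmean + half_up
      tmin <- tmean - half_dn
      wet <- stats::runif(nd) < cfg$wet_day_prob
      prcp <- ifelse(wet, stats::rgamma(nd, shape = 0.8, scale = 15), 0)
      srad <- pmax(1, 17 + 9 * seas - 0.55 * (17 + 9 * seas) * wet +
                     stats::rnorm(nd, 0, 2))
      cloud <- pmin(100, pmax(0, 30 + 50 * wet + stats::rnorm(nd, 0, 10)))
      rh <- pmin(100, pmax(20, 62 + 22 * wet - 0.5 * (tmean - 15) +
                             stats::rnorm(nd, 0, 8)))
      wind <- stats::rlnorm(nd, log(3), 0.4)
      ta <- tmax - tmin
      et <- pmax(0, 0.0023 * (tmean + 17.8) * sqrt(pmax(ta, 0)) * srad * 0.5)
      data.frame(environment = ev$environment, date = dates, prcp = prcp,
                 tmax = tmax, tmin = tmin, tmean = tmean, rh = rh,
                 srad = srad, wind = wind, et = et, cloud = cloud,
                 stringsAsFactors = FALSE)
    })
    weather_table(do.call(rbind, out))
  })
}

#' Simulate heading dates (and mask a fraction as missing)
#'
#' Heading (days from sowing) = trial mean + genotype effect (multivariate
#' normal with GRM covariance) + genotype-by-year + genotype-by-location +
#' residual, rounded to whole days and clipped into the window that keeps the
#' three phenological phases valid. A fraction of trials then has a random
#' 20-90% of its genotypes' heading dates masked to `NA`, emulating breeding
#' records where heading is scored in some trials only.
#'
#' @param skeleton output of [simulate_program()].
#' @param markers a `MarkerSet` covering the skeleton's genotypes.
#' @param config a [sim_config()].
#' @return list: `pheno` (skeleton with masked heading dates filled in),
#'   `truth` (per genotype-trial true heading days), `n_clipped`,
#'   `masked_trials`.
#' @export
simulate_phenology <- function(skeleton, markers, config) {
  cfg <- config
  hv <- cfg$heading_var
  cells <- unique(as.data.frame(skeleton)[, c("genotype", "trial",
                                              "environment", "year",
                                              "location", "sowing_period")])
  K <- vanraden_grm(qc_markers(markers, maf_min = 0, het_max = 1, miss_max = 1))
  with_stream(cfg$seed + 4L, {
    gids <- rownames(K)
    g <- if (hv["geno"] > 0)
      drop(crossprod(chol(K + diag(1e-6, nrow(K))),
                     stats::rnorm(nrow(K)))) * sqrt(hv["geno"])
    else rep(0, nrow(K))
    names(g) <- gids
    yru <- sort(unique(cells$year)); locu <- sort(unique(cells$location))
    ayr <- stats::rnorm(length(yru), 0, sqrt(hv["year"])); names(ayr) <- yru
    aloc <- stats::rnorm(length(locu), 0, sqrt(hv["location"])); names(aloc) <- locu
    gy_key <- unique(paste(cells$genotype, cells$year))
    gl_key <- unique(paste(cells$genotype, cells$location))
    gy <- stats::rnorm(length(gy_key), 0, sqrt(hv["gy"])); names(gy) <- gy_key
    gl <- stats::rnorm(length(gl_key), 0, sqrt(hv["gl"])); names(gl) <- gl_key
    shift <- cfg$heading_period_shift
    mu <- cfg$heading_base + shift[cells$sowing_period] +
      ayr[as.character(cells$year)] + aloc[cells$location]
    hd <- round(mu + g[cells$genotype] +
                  gy[paste(cells$genotype, cells$year)] +
                  gl[paste(cells$genotype, cells$location)] +
                  stats::rnorm(nrow(cells), 0, sqrt(hv["resid"])))
    lo <- 22; hi <- cfg$season_length - 12
    n_clipped <- sum(hd < lo | hd > hi)
    if (n_clipped)
      warning(n_clipped, " heading date(s) clipped into the valid window")
    hd <- pmin(pmax(hd, lo), hi)
    cells$heading_days <- hd

    cells$masked <- FALSE
    if (cfg$heading_miss_mode == "uniform") {
      masked_trials <- character(0)
      nmask <- round(cfg$heading_miss_frac * nrow(cells))
      cells$masked[sample(nrow(cells), nmask)] <- TRUE
    } else {
      trials <- unique(cells$trial)
      masked_trials <- sample(trials, round(cfg$heading_miss_trial_frac *
                                              length(trials)))
      for (tr in masked_trials) {
        idx <- which(cells$trial == tr)
        frac <- stats::runif(1, cfg$heading_miss_range[1],
                             cfg$heading_miss_range[2])
        cells$masked[sample(idx, round(frac * length(idx)))] <- TRUE
      }
    }
    key <- paste(skeleton$genotype, skeleton$trial)
    ck <- paste(cells$genotype, cells$trial)
    pos <- match(key, ck)
    out <- skeleton
    out$heading_date <- out$sowing_date + cells$heading_days[pos]
    out$heading_date[cells$masked[pos]] <- NA
    class(out) <- class(skeleton)
    attr(out, "environments") <- attr(skeleton, "environments")
    list(pheno = out,
         truth = cells[, c("genotype", "trial", "environment",
                           "heading_days", "masked")],
         n_clipped = n_clipped, masked_trials = masked_trials)
  })
}

#' Simulate plot yields from the reaction-norm truth
#'
#' @param skeleton output of [simulate_program()].
#' @param markers a `MarkerSet`.
#' @param weather a `WeatherTable` from [simulate_weather()].
#' @param phenology output of [simulate_phenology()] (its *true* heading
#'   dates drive each genotype's EC windows).
#' @param config a [sim_config()].
#' @return list: `pheno` (complete `PhenotypeTable` with yields and the
#'   masked heading dates) and `truth` (a `GroundTruth` list: coefficients,
#'   `omega_star`, fixed EC effects, all drawn design effects, the realised
#'   standardised EC matrix, per-cell true genotypic values, and the heading
#'   truth).
#' @export
simulate_yield <- function(skeleton, markers, weather, phenology, config) {
  cfg <- config
  V <- cfg$var_total; fr <- cfg$var_frac
  fr_lr <- 0
  if (cfg$fa_gei) {
    # misspecification switch: move 2/3 of the slope share, 2/3 of the iid
    # GEI and 0.04 of the residual into rank-2 GEI unexplained by any EC
    stopifnot(fr["resid"] >= 0.04)
    fr_lr <- unname(2 / 3 * fr["slope"] + 2 / 3 * fr["ge"] + 0.04)
    fr["slope"] <- fr["slope"] / 3
    fr["ge"] <- fr["ge"] / 3
    fr["resid"] <- fr["resid"] - 0.04
  }
  nact <- length(cfg$active_ecs)

  # ECs from the true phenology
  ph_true <- skeleton
  key <- paste(skeleton$genotype, skeleton$trial)
  tr_key <- paste(phenology$truth$genotype, phenology$truth$trial)
  ph_true$heading_date <- ph_true$sowing_date +
    phenology$truth$heading_days[match(key, tr_key)]
  class(ph_true) <- class(skeleton)
  ecm <- build_ec_matrix(ph_true, weather)
  ecv <- as.matrix(as.data.frame(ecm)[, ec_names()])
  ec_center <- colMeans(ecv); ec_scale <- apply(ecv, 2, stats::sd)
  ec_scale[ec_scale == 0] <- 1
  ecz <- sweep(sweep(ecv, 2, ec_center), 2, ec_scale, "/")
  Phi <- ecz[, cfg$active_ecs, drop = FALSE]

  K <- vanraden_grm(qc_markers(markers, maf_min = 0, het_max = 1, miss_max = 1))
  gids <- rownames(K)

  with_stream(cfg$seed + 5L, {
    # genotype intercepts and slopes: C ~ MN(0, K, Omega*)
    omega_star <- diag(c(fr["intercept"],
                         rep(fr["slope"] / max(nact, 1), nact)), 1 + nact) * V
    dimnames(omega_star) <- list(c("(Intercept)", cfg$active_ecs),
                                 c("(Intercept)", cfg$active_ecs))
    eo <- eigen(omega_star, symmetric = TRUE)
    if (min(eo$values) < -1e-8) stop("omega_star is not PSD")
    Lk <- chol(K + diag(1e-6, nrow(K)))
    Z <- matrix(stats::rnorm(nrow(K) * (1 + nact)), nrow(K))
    Cmat <- crossprod(Lk, Z) %*% chol(omega_star + diag(1e-12 * V, 1 + nact))
    dimnames(Cmat) <- list(gids, colnames(omega_star))

    beta <- stats::rnorm(nact, 0, 1)
    if (nact) beta <- beta / sqrt(mean(beta^2)) * sqrt(fr["fixed_ec"] * V / nact)

    envs <- attr(skeleton, "environments")
    yru <- as.character(cfg$years)
    eff <- list(
      year = stats::setNames(stats::rnorm(length(yru), 0, sqrt(fr["year"] * V)), yru),
      location = stats::setNames(stats::rnorm(length(cfg$locations), 0,
                                              sqrt(fr["location"] * V)),
                                 cfg$locations),
      sowing = stats::setNames(stats::rnorm(length(cfg$sowing_periods), 0,
                                            sqrt(fr["sowing"] * V)),
                               cfg$sowing_periods),
      env = stats::setNames(stats::rnorm(nrow(envs), 0, sqrt(fr["env"] * V)),
                            envs$environment))
    trials <- unique(skeleton$trial)
    eff$trial <- stats::setNames(stats::rnorm(length(trials), 0,
                                              sqrt(fr["trial"] * V)), trials)
    repkey <- unique(paste(skeleton$trial, skeleton$replicate))
    eff$rep <- stats::setNames(stats::rnorm(length(repkey), 0,
                                            sqrt(fr["rep"] * V)), repkey)
    blkkey <- unique(paste(skeleton$trial, skeleton$replicate,
                           skeleton$block)[!is.na(skeleton$block)])
    eff$block <- stats::setNames(stats::rnorm(length(blkkey), 0,
                                              sqrt(fr["block"] * V)), blkkey)

    # GEI: IID per genotype-environment cell, optionally part low-rank
    gekey <- unique(paste(skeleton$genotype, skeleton$environment))
    if (cfg$fa_gei) {
      v_lr <- fr_lr * V
      lam <- matrix(stats::rnorm(2 * nrow(envs)), nrow(envs))
      lam <- lam / sqrt(mean(rowSums(lam^2)))
      rownames(lam) <- envs$environment
      Fg <- crossprod(Lk, matrix(stats::rnorm(nrow(K) * 2), nrow(K))) *
        sqrt(v_lr / mean(diag(K)))
      rownames(Fg) <- gids
    } else {
      lam <- NULL; Fg <- NULL
    }
    eff$ge <- stats::setNames(stats::rnorm(length(gekey), 0,
                                           sqrt(fr["ge"] * V)), gekey)

    # assemble per-cell genotypic value, then per-plot yield
    cell_key <- paste(ecm$genotype, ecm$trial)
    gen_cell <- Cmat[ecm$genotype, 1] +
      if (nact) rowSums(Phi * Cmat[ecm$genotype, -1, drop = FALSE]) else 0
    ge_cell <- eff$ge[paste(ecm$genotype, ecm$environment)]
    if (cfg$fa_gei)
      ge_cell <- ge_cell + rowSums(lam[ecm$environment, , drop = FALSE] *
                                     Fg[ecm$genotype, , drop = FALSE])
    fixed_cell <- if (nact) drop(Phi %*% beta) else 0
    truth_cells <- data.frame(
      genotype = ecm$genotype, trial = ecm$trial,
      environment = ecm$environment,
      genvalue = gen_cell + ge_cell, stringsAsFactors = FALSE)

    pos <- match(key, cell_key)
    env_part <- eff$year[as.character(skeleton$year)] +
      eff$location[skeleton$location] + eff$sowing[skeleton$sowing_period] +
      eff$env[skeleton$environment]
    blk_part <- ifelse(is.na(skeleton$block), 0,
                       eff$block[paste(skeleton$trial, skeleton$replicate,
                                       skeleton$block)])
    yield <- cfg$mean_yield + env_part + eff$trial[skeleton$trial] +
      eff$rep[paste(skeleton$trial, skeleton$replicate)] + blk_part +
      fixed_cell[pos] + gen_cell[pos] + ge_cell[pos] +
      stats::rnorm(nrow(skeleton), 0, sqrt(fr["resid"] * V))

    out <- phenology$pheno
    out$yield <- as.numeric(yield)
    class(out) <- class(skeleton)
    attr(out, "environments") <- attr(skeleton, "environments")
    attr(out, "seed") <- cfg$seed

    truth <- structure(list(
      coefficients = Cmat, omega_star = omega_star, beta_fixed = beta,
      active_ecs = cfg$active_ecs, ec_center = ec_center, ec_scale = ec_scale,
      ec_matrix = ecm, effects = eff, fa_loadings = lam, fa_scores = Fg,
      cells = truth_cells, heading = phenology$truth,
      var_frac = fr, var_total = V, config = cfg), class = "GroundTruth")
    list(pheno = out, truth = truth)
  })
}

#' Simulate a complete synthetic dataset
#'
#' Orchestrates [simulate_program()], [simulate_markers()],
#' [simulate_weather()], [simulate_phenology()] and [simulate_yield()].
#'
#' @param config a [sim_config()].
#' @return list: `pheno` (plot-level `PhenotypeTable` with yields and partly
#'   masked heading dates), `weather`, `markers`, `truth` (`GroundTruth`),
#'   `config`.
#' @export
simulate_dataset <- function(config) {
  skeleton <- simulate_program(config)
  markers <- simulate_markers(config, ids = sort(unique(skeleton$genotype)))
  weather <- simulate_weather(skeleton, config)
  phen <- simulate_phenology(skeleton, markers, config)
  yld <- simulate_yield(skeleton, markers, weather, phen, config)
  list(pheno = yld$pheno, weather = weather, markers = markers,
       truth = yld$truth, config = config)
}

#' Write a simulated dataset to plain-text files
#'
#' Writes `phenotypes.csv`, `weather.csv`, `markers.tsv` and `truth.json`
#' (ground-truth coefficients and variance settings) under `dir`.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_phenotypes(sim$pheno, file.path(dir, "phenotypes.csv"),
                   meta = list(seed = sim$config$seed))
  write_weather(sim$weather, file.path(dir, "weather.csv"))
  write_markers(sim$markers, file.path(dir, "markers.tsv"))
  tr <- sim$truth
  jsonlite::write_json(
    list(omega_star = tr$omega_star, beta_fixed = tr$beta_fixed,
         active_ecs = tr$active_ecs, var_frac = as.list(tr$var_frac),
         var_total = tr$var_total, seed = sim$config$seed,
         coefficients = data.frame(genotype = rownames(tr$coefficients),
                                   tr$coefficients, check.names = FALSE)),
    file.path(dir, "truth.json"), dataframe = "rows", digits = NA)
  invisible(dir)
}
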