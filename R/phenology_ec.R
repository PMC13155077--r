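# ---------------------------------------------------------------------------
# Genotype-specific phenological windows and environmental covariates.
#
# Anthesis is proxied by heading date (offset HEADING_TO_ANTHESIS, 0 days by
# default); the reproductive window is the 31-day critical period from 20
# days before to 10 days after heading, inclusive. The vegetative phase runs
# from sowing to the day before the reproductive window, and grain filling
# from the day after it to harvest, so the three phases tile the season.
# ---------------------------------------------------------------------------

#' Offset (days) from heading to assumed anthesis
#' @export
HEADING_TO_ANTHESIS <- 0L

#' Catalogue of the 15 environmental covariates
#'
#' Per phenological phase the same 15 summaries of the daily weather are
#' computed, giving 45 ECs per genotype-trial. `aggregator` is one of
#' `sum` (cumulative flux), `mean` (average of a daily series) or `count`
#' (days meeting a threshold).
#'
#' @return data frame with columns `code`, `aggregator`, `description`.
#' @export
ec_catalogue <- function() {
  data.frame(
    code = c("PP", "CC", "ET", "FD", "Tmax", "Tmean", "T25", "Tmin",
             "T15", "T4", "Q", "RH", "SR", "TA", "WS"),
    aggregator = c("sum", "mean", "sum", "count", "mean", "mean", "count",
                   "mean", "count", "count", "mean", "mean", "mean", "mean",
                   "mean"),
    description = c(
      "cumulative precipitation (mm)",
      "mean cloud coverage (%)",
      "cumulative evapotranspiration (mm)",
      "number of frost days (Tmin <= 0 C)",
      "mean daily maximum temperature (C)",
      "mean daily mean temperature (C)",
      "number of days with Tmax > 25 C",
      "mean daily minimum temperature (C)",
      "number of days with Tmin < 15 C",
      "number of days with Tmin < 4 C",
      "photothermal quotient: mean daily SR/Tmean (days Tmean <= 0 excluded)",
      "mean relative humidity (%)",
      "mean solar radiation (MJ m-2 d-1)",
      "mean thermal amplitude Tmax - Tmin (C)",
      "mean wind speed (m s-1)"),
    stringsAsFactors = FALSE)
}

#' Names of the 45 EC columns in canonical order
#'
#' Vegetative block first, then reproductive, then grain filling; catalogue
#' order within each block (e.g. `VPP`, ..., `VWS`, `RPP`, ..., `GWS`).
#' @return character vector of length 45.
#' @export
ec_names <- function() {
  codes <- ec_catalogue()$code
  as.vector(vapply(c("V", "R", "G"), function(ph) paste0(ph, codes),
                   character(length(codes))))
}

#' Predict missing heading dates from a genotype/year/location mixed model
#'
#' Fits days-from-sowing-to-heading with independent random effects for
#' genotype, year, location, genotype-by-year and genotype-by-location
#' (REML, via lme4), per maturity class when `maturity_class` names a column.
#' Missing heading dates are replaced by the conditional prediction
#' \eqn{\hat\mu + \hat g + \hat a + \hat l + \hat{ga} + \hat{gl}} (terms for
#' unobserved levels contribute 0); observed records are untouched.
#'
#' @param pheno a `PhenotypeTable`.
#' @param maturity_class optional column name grouping genotypes into
#'   maturity classes; the model is fitted separately per class.
#' @return the `PhenotypeTable` with `heading_date` filled; a fill report
#'   (counts and per-trial breakdown) is attached as `attr(, "fill_report")`.
#' @export
predict_heading <- function(pheno, maturity_class = NULL) {
  classes <- if (is.null(maturity_class)) rep("all", nrow(pheno))
             else as.character(pheno[[maturity_class]])
  hd <- as.numeric(pheno$heading_date - pheno$sowing_date)
  filled <- hd
  n_filled <- 0L
  for (cl in unique(classes)) {
    sel <- classes == cl
    obs <- sel & !is.na(hd)
    mis <- sel & is.na(hd)
    if (!any(mis)) next
    if (!any(obs)) stop("no observed heading dates in class ", cl)
    d <- data.frame(hd = hd[sel], genotype = pheno$genotype[sel],
                    year = factor(pheno$year[sel]),
                    location = pheno$location[sel])
    dobs <- d[!is.na(d$hd), ]
    if (length(unique(dobs$year)) < 2 || length(unique(dobs$location)) < 2)
      stop("heading-date model needs >= 2 observed years and locations",
           if (cl != "all") paste0(" in class ", cl))
    fit <- lme4::lmer(
      hd ~ (1 | genotype) + (1 | year) + (1 | location) +
        (1 | genotype:year) + (1 | genotype:location),
      data = dobs, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore",
                                  calc.derivs = FALSE))
    re <- lme4::ranef(fit)
    lookup <- function(tab, keys) {
      v <- tab[keys, 1]
      v[is.na(v)] <- 0
      v
    }
    dm <- d[is.na(d$hd), ]
    pred <- lme4::fixef(fit)[["(Intercept)"]] +
      lookup(re$genotype, dm$genotype) +
      lookup(re$year, as.character(dm$year)) +
      lookup(re$location, dm$location) +
      lookup(re$`genotype:year`, paste(dm$genotype, dm$year, sep = ":")) +
      lookup(re$`genotype:location`, paste(dm$genotype, dm$location, sep = ":"))
    filled[mis] <- round(pred)
    n_filled <- n_filled + sum(mis)
  }
  out <- pheno
  out$heading_date <- out$sowing_date + filled
  report <- list(n_missing = sum(is.na(hd)), n_filled = n_filled,
                 by_trial = table(pheno$trial[is.na(hd)]))
  attr(out, "fill_report") <- report
  class(out) <- class(pheno)
  out
}

#' Genotype-specific phenological windows
#'
#' Day-offset windows from sowing: vegetative `V = [0, heading - 21]`,
#' reproductive `R = [heading - 20, heading + 10]` (the 31-day critical
#' period around heading, the anthesis proxy), grain filling
#' `G = [heading + 11, harvest]`. All intervals are closed; the three windows
#' tile `[0, harvest]` with no gaps or overlaps.
#'
#' @param sowing,heading,harvest `Date` vectors (recycled), or `heading` /
#'   `harvest` given directly as day offsets from sowing.
#' @return data frame with columns `V_start, V_end, R_start, R_end, G_start,
#'   G_end` (integer day offsets from sowing).
#' @export
define_phases <- function(sowing, heading, harvest) {
  hd <- if (inherits(heading, "Date")) as.numeric(heading - sowing)
        else as.numeric(heading)
  hv <- if (inherits(harvest, "Date")) as.numeric(harvest - sowing)
        else as.numeric(harvest)
  bad_early <- !is.na(hd) & hd - 20 <= 0
  bad_late <- !is.na(hd) & !is.na(hv) & hd + 10 >= hv
  if (any(bad_early, na.rm = TRUE))
    stop("heading too close to sowing (needs heading - 20 > 0) for record(s): ",
         paste(utils::head(which(bad_early)), collapse = ", "))
  if (any(bad_late, na.rm = TRUE))
    stop("heading too close to harvest (needs heading + 10 < harvest) for record(s): ",
         paste(utils::head(which(bad_late)), collapse = ", "))
  data.frame(V_start = 0L, V_end = as.integer(hd - 21),
             R_start = as.integer(hd - 20), R_end = as.integer(hd + 10),
             G_start = as.integer(hd + 11), G_end = as.integer(hv))
}

#' Aggregate one environmental covariate over a window of daily weather
#'
#' Reference (direct) implementation of the 15 EC definitions on a slice of
#' daily rows; [build_ec_matrix()] computes the same quantities through
#' cumulative sums and is cross-checked against this function.
#'
#' @param daily data frame of consecutive daily rows (see [weather_table()]),
#'   already sliced to the window.
#' @param variable one of the catalogue codes (see [ec_catalogue()]).
#' @return scalar EC value.
#' @export
compute_ec <- function(daily, variable) {
  switch(variable,
    PP = sum(daily$prcp),
    ET = sum(daily$et),
    CC = mean(daily$cloud),
    Tmax = mean(daily$tmax),
    Tmean = mean(daily$tmean),
    Tmin = mean(daily$tmin),
    RH = mean(daily$rh),
    SR = mean(daily$srad),
    WS = mean(daily$wind),
    TA = mean(daily$tmax - daily$tmin),
    Q = {
      ok <- daily$tmean > 0
      if (!any(ok)) NA_real_ else mean(daily$srad[ok] / daily$tmean[ok])
    },
    FD = sum(daily$tmin <= 0),
    T25 = sum(daily$tmax > 25),
    T15 = sum(daily$tmin < 15),
    T4 = sum(daily$tmin < 4),
    stop("unknown EC code: ", variable))
}

# Per-environment cumulative arrays so any [a, b] day window aggregates in
# O(1). Day index 1 corresponds to `start_date`.
ec_accumulator <- function(daily) {
  daily <- daily[order(daily$date), ]
  series <- list(
    PP = daily$prcp, ET = daily$et, CC = daily$cloud, Tmax = daily$tmax,
    Tmean = daily$tmean, Tmin = daily$tmin, RH = daily$rh, SR = daily$srad,
    WS = daily$wind, TA = daily$tmax - daily$tmin,
    Qnum = ifelse(daily$tmean > 0, daily$srad / daily$tmean, 0),
    Qok = as.numeric(daily$tmean > 0),
    FD = as.numeric(daily$tmin <= 0), T25 = as.numeric(daily$tmax > 25),
    T15 = as.numeric(daily$tmin < 15), T4 = as.numeric(daily$tmin < 4))
  list(start_date = daily$date[1], n = nrow(daily),
       cum = lapply(series, function(x) cumsum(c(0, x))))
}

ec_window <- function(acc, i0, i1) {
  # i0, i1: 1-based day indices into the accumulator, inclusive
  len <- i1 - i0 + 1
  rng <- function(v) acc$cum[[v]][i1 + 1] - acc$cum[[v]][i0]
  qok <- rng("Qok")
  c(PP = rng("PP"), CC = rng("CC") / len, ET = rng("ET"), FD = rng("FD"),
    Tmax = rng("Tmax") / len, Tmean = rng("Tmean") / len, T25 = rng("T25"),
    Tmin = rng("Tmin") / len, T15 = rng("T15"), T4 = rng("T4"),
    Q = if (qok > 0) rng("Qnum") / qok else NA_real_,
    RH = rng("RH") / len, SR = rng("SR") / len, TA = rng("TA") / len,
    WS = rng("WS") / len)
}

#' Build the 45-column EC matrix for every genotype-trial
#'
#' For each genotype in each trial, computes the 15 catalogue ECs over the
#' genotype's vegetative, reproductive and grain-filling windows (anchored on
#' its observed or predicted heading date) from the environment's daily
#' weather. Column order is fixed: V block, R block, G block, catalogue order
#' within each.
#'
#' @param pheno a `PhenotypeTable` with heading dates complete (run
#'   [predict_heading()] first if needed).
#' @param weather a `WeatherTable` covering each environment's season.
#' @param policy what to do with records whose phase windows are invalid
#'   (heading too close to sowing or harvest): `"error"`, `"drop"` (with a
#'   summary attribute), or `"clip"` (clamp heading into the valid range).
#' @return data frame of class `ECMatrix`: key columns `genotype`, `trial`,
#'   `environment` plus the 45 EC columns; `attr(, "catalogue")` records each
#'   column's aggregator.
#' @export
build_ec_matrix <- function(pheno, weather, policy = c("error", "drop", "clip")) {
  policy <- match.arg(policy)
  cells <- unique(as.data.frame(
    pheno[, c("genotype", "trial", "environment", "sowing_date",
              "heading_date", "harvest_date")]))
  if (anyNA(cells$heading_date))
    stop("heading dates incomplete; run predict_heading() first")
  hd <- as.numeric(cells$heading_date - cells$sowing_date)
  hv <- as.numeric(cells$harvest_date - cells$sowing_date)
  invalid <- hd - 20 <= 0 | hd + 10 >= hv
  n_clipped <- 0L
  if (any(invalid)) {
    if (policy == "error") {
      stop(sum(invalid), " record(s) with invalid phase windows; ",
           "use policy = 'drop' or 'clip'")
    } else if (policy == "drop") {
      cells <- cells[!invalid, ]; hd <- hd[!invalid]; hv <- hv[!invalid]
    } else {
      hd <- pmin(pmax(hd, 21), hv - 11)
      n_clipped <- sum(invalid)
    }
  }
  accs <- lapply(split(as.data.frame(weather), weather$environment),
                 ec_accumulator)
  nms <- ec_names()
  out <- matrix(NA_real_, nrow(cells), 45, dimnames = list(NULL, nms))
  for (r in seq_len(nrow(cells))) {
    acc <- accs[[cells$environment[r]]]
    if (is.null(acc)) stop("no weather for environment ", cells$environment[r])
    # day offset d from sowing -> accumulator index
    off <- as.integer(cells$sowing_date[r] - acc$start_date) + 1L
    idx <- function(d) off + as.integer(d)
    if (idx(0) < 1 || idx(hv[r]) > acc$n)
      stop("weather does not cover sowing..harvest for environment ",
           cells$environment[r], " (missing dates at the season edges)")
    v <- c(ec_window(acc, idx(0), idx(hd[r] - 21)),
           ec_window(acc, idx(hd[r] - 20), idx(hd[r] + 10)),
           ec_window(acc, idx(hd[r] + 11), idx(hv[r])))
    out[r, ] <- v
  }
  res <- cbind(cells[, c("genotype", "trial", "environment")],
               as.data.frame(out))
  rownames(res) <- NULL
  cat <- ec_catalogue()
  attr(res, "catalogue") <- data.frame(
    column = nms, phase = rep(c("V", "R", "G"), each = 15),
    code = rep(cat$code, 3), aggregator = rep(cat$aggregator, 3))
  attr(res, "n_clipped") <- n_clipped
  class(res) <- c("ECMatrix", "data.frame")
  res
}

#' Write an EC matrix with its column-metadata sidecar
#' @param ecs an `ECMatrix`.
#' @param path output CSV path; metadata goes to `<path>.meta.json`.
#' @export
write_ec_matrix <- function(ecs, path) {
  utils::write.csv(as.data.frame(ecs), path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(attr(ecs, "catalogue"), paste0(path, ".meta.json"),
                       dataframe = "rows")
  invisible(path)
}
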