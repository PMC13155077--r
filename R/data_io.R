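# ---------------------------------------------------------------------------
# Data model: plot-level phenotypes, marker dosages, daily weather.
#
# An *environment* is the (year, location, sowing period) triple; a trial is
# nested in exactly one environment. Sowing periods follow the month-day
# cutoffs of the southern-hemisphere wheat season: PRE before May 15, OPT
# May 15 - June 15 (inclusive), POS after June 15.
# ---------------------------------------------------------------------------

PHENO_REQUIRED <- c("genotype", "location", "trial", "replicate",
                    "sowing_date", "harvest_date", "yield")
PHENO_DATES <- c("sowing_date", "heading_date", "harvest_date")

#' Sowing period from sowing date
#'
#' Classifies sowing dates into the pre-optimal (PRE, before May 15), optimal
#' (OPT, May 15 to June 15 inclusive) and post-optimal (POS, after June 15)
#' windows of the record's calendar year.
#'
#' @param dates a `Date` vector.
#' @return character vector of `"PRE"`, `"OPT"`, `"POS"`.
#' @export
sowing_period <- function(dates) {
  stopifnot(inherits(dates, "Date"))
  if (length(dates) == 0) return(character(0))
  yr <- as.integer(format(dates, "%Y"))
  lo <- as.Date(paste0(yr, "-05-15"))
  hi <- as.Date(paste0(yr, "-06-15"))
  ifelse(dates < lo, "PRE", ifelse(dates <= hi, "OPT", "POS"))
}

environment_id <- function(year, location, period) {
  paste(year, location, period, sep = "_")
}

#' Construct and validate a plot-level phenotype table
#'
#' Validates the invariants of the data model: every trial maps to exactly one
#' environment, and (genotype, trial, replicate, block) keys are unique.
#' Derives `sowing_period`, `year` and `environment` when absent.
#'
#' @param df data frame with at least the columns
#'   `genotype, location, trial, replicate, sowing_date, harvest_date, yield`;
#'   optional `block`, `heading_date`, `year`, `sowing_period`.
#' @return the validated data frame with class `PhenotypeTable`.
#' @export
phenotype_table <- function(df) {
  miss <- setdiff(PHENO_REQUIRED, names(df))
  if (length(miss))
    stop("missing required phenotype column(s): ", paste(miss, collapse = ", "))
  for (dc in intersect(PHENO_DATES, names(df))) {
    if (!inherits(df[[dc]], "Date")) {
      parsed <- as.Date(as.character(df[[dc]]), format = "%Y-%m-%d")
      bad <- which(!is.na(df[[dc]]) & df[[dc]] != "" & is.na(parsed))
      if (length(bad))
        stop("unparseable ", dc, " (ISO-8601 expected) in row(s): ",
             paste(utils::head(bad, 10), collapse = ", "))
      df[[dc]] <- parsed
    }
  }
  if (is.null(df$heading_date)) df$heading_date <- as.Date(NA)
  if (is.null(df$block)) df$block <- NA_character_
  if (is.null(df$year)) df$year <- as.integer(format(df$sowing_date, "%Y"))
  if (is.null(df$sowing_period)) df$sowing_period <- sowing_period(df$sowing_date)
  df$environment <- environment_id(df$year, df$location, df$sowing_period)

  if (nrow(df)) {
    env_per_trial <- tapply(df$environment, df$trial,
                            function(x) length(unique(x)))
    if (any(env_per_trial > 1))
      stop("trial(s) mapped to more than one environment: ",
           paste(names(env_per_trial)[env_per_trial > 1], collapse = ", "))
    key <- paste(df$genotype, df$trial, df$replicate, df$block, sep = "|")
    if (anyDuplicated(key))
      stop("duplicate (genotype, trial, replicate, block) key(s): ",
           paste(utils::head(unique(key[duplicated(key)]), 5), collapse = "; "))
  }
  class(df) <- c("PhenotypeTable", "data.frame")
  df
}

#' Read a plot-level phenotype file
#'
#' Comma-delimited with a header; dates ISO-8601. The environment of each row
#' is derived from (year, location, sowing window); see [sowing_period()].
#'
#' @param path path to a CSV file.
#' @return a `PhenotypeTable`.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  phenotype_table(df)
}

#' Write a phenotype table with a metadata sidecar
#'
#' Writes `<path>` as CSV and `<path>.meta.json` recording provenance
#' (filters applied so far and the generating seed, when known).
#'
#' @param pheno a `PhenotypeTable`.
#' @param path output CSV path.
#' @param meta optional named list merged into the sidecar.
#' @export
write_phenotypes <- function(pheno, path, meta = list()) {
  df <- as.data.frame(pheno)
  df$environment <- NULL       # derived; recomputed on read
  for (dc in intersect(PHENO_DATES, names(df)))
    df[[dc]] <- format(df[[dc]], "%Y-%m-%d")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  side <- c(list(written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                 n_rows = nrow(df),
                 filters = attr(pheno, "filters"),
                 seed = attr(pheno, "seed")), meta)
  jsonlite::write_json(side, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Markers
# ---------------------------------------------------------------------------

#' Construct a marker set
#'
#' @param dosage numeric matrix, genotypes in rows, loci in columns; entries
#'   0/1/2 counts of the alternate allele, `NA` for missing calls.
#' @param map optional data frame (locus, chrom, pos, ref, alt).
#' @param skipped number of non-biallelic records skipped during parsing.
#' @return an object of class `MarkerSet`.
#' @export
marker_set <- function(dosage, map = NULL, skipped = 0L) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (is.null(rownames(dosage)) || anyDuplicated(rownames(dosage)))
    stop("dosage matrix needs unique genotype rownames")
  if (is.null(colnames(dosage)) || anyDuplicated(colnames(dosage)))
    stop("dosage matrix needs unique locus colnames")
  ok <- is.na(dosage) | (dosage >= 0 & dosage <= 2)
  if (!all(ok)) stop("dosage entries must be in [0, 2] or missing")
  structure(list(dosage = dosage, map = map,
                 n_missing = sum(is.na(dosage)), skipped = as.integer(skipped)),
            class = "MarkerSet")
}

#' @exportS3Method
#' @noRd
print.MarkerSet <- function(x, ...) {
  cat("MarkerSet:", nrow(x$dosage), "genotypes x", ncol(x$dosage), "loci;",
      x$n_missing, "missing calls")
  if (x$skipped) cat(";", x$skipped, "non-biallelic record(s) skipped")
  cat("\n")
  invisible(x)
}

#' Read genotype markers from VCF or a plain dosage matrix
#'
#' VCF mode (requires the `vcfR` package) keeps biallelic SNPs only and codes
#' dosage as the count of the alternate allele from the GT field; records with
#' more than one ALT allele are skipped with a warning and counted. Matrix
#' mode reads a tab-delimited table, genotypes in rows (first column holds the
#' genotype id), loci in columns.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"vcf"` or `"matrix"`.
#' @return a `MarkerSet` (missing genotypes flagged as `NA`, not imputed).
#' @export
read_markers <- function(path, format = c("auto", "vcf", "matrix")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "matrix"
  if (format == "vcf") {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("reading VCF requires the 'vcfR' package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    bi <- vcfR::is.biallelic(v)
    nskip <- sum(!bi)
    if (nskip) {
      warning("skipping ", nskip, " non-biallelic record(s)")
      v <- v[bi, ]
    }
    gt <- vcfR::extract.gt(v, element = "GT")
    count_alt <- function(g) {
      ifelse(is.na(g) | g %in% c(".", "./.", ".|."), NA_real_,
             vapply(strsplit(g, "[/|]"), function(a)
               sum(a == "1"), numeric(1)))
    }
    dos <- apply(gt, 2, count_alt)
    if (is.null(dim(dos))) dos <- matrix(dos, nrow = 1,
                                         dimnames = list(rownames(gt), colnames(gt)))
    loci <- paste0(v@fix[, "CHROM"], "_", v@fix[, "POS"])
    map <- data.frame(locus = loci, chrom = v@fix[, "CHROM"],
                      pos = as.integer(v@fix[, "POS"]),
                      ref = v@fix[, "REF"], alt = v@fix[, "ALT"],
                      row.names = NULL)
    dos <- t(dos)                            # genotypes in rows
    colnames(dos) <- loci
    marker_set(dos, map, skipped = nskip)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    dos <- as.matrix(tab[, -1, drop = FALSE])
    rownames(dos) <- tab[[1]]
    marker_set(dos)
  }
}

#' Write a marker set as a tab-delimited dosage matrix
#' @param markers a `MarkerSet`.
#' @param path output path.
#' @export
write_markers <- function(markers, path) {
  df <- data.frame(genotype = rownames(markers$dosage),
                   markers$dosage, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Marker quality control
#'
#' Discards loci with minor allele frequency below `maf_min`, heterozygosity
#' (fraction of dosage-1 calls) above `het_max`, or a missing fraction above
#' `miss_max`; remaining missing calls are imputed by the per-locus mean
#' dosage. The removal report is attached as `attr(, "qc")` with one count per
#' rule (a locus failing several rules is counted under each).
#'
#' @param markers a `MarkerSet`.
#' @param maf_min,het_max,miss_max thresholds in \[0, 1\].
#' @return the filtered, imputed `MarkerSet`.
#' @export
qc_markers <- function(markers, maf_min = 0.05, het_max = 0.10,
                       miss_max = 0.80) {
  stopifnot(inherits(markers, "MarkerSet"),
            maf_min >= 0, maf_min <= 1, het_max >= 0, het_max <= 1,
            miss_max >= 0, miss_max <= 1)
  M <- markers$dosage
  miss <- colMeans(is.na(M))
  p <- colMeans(M, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  het <- colMeans(M == 1, na.rm = TRUE)
  fail_maf <- maf < maf_min
  fail_het <- het > het_max
  fail_miss <- miss > miss_max
  # loci with zero calls have undefined maf/het: treat as fully missing
  allmiss <- miss >= 1
  fail_maf[allmiss] <- FALSE; fail_het[allmiss] <- FALSE
  fail_miss[allmiss] <- TRUE
  drop <- fail_maf | fail_het | fail_miss
  report <- list(maf = sum(fail_maf), het = sum(fail_het),
                 missing = sum(fail_miss), removed = sum(drop),
                 retained = sum(!drop))
  if (all(drop))
    stop("all loci removed by QC (maf: ", report$maf, ", het: ", report$het,
         ", missing: ", report$missing, ")")
  M <- M[, !drop, drop = FALSE]
  # mean-dosage imputation of the survivors
  if (anyNA(M)) {
    mu <- colMeans(M, na.rm = TRUE)
    idx <- which(is.na(M), arr.ind = TRUE)
    M[idx] <- mu[idx[, 2]]
  }
  out <- marker_set(M, markers$map[match(colnames(M), markers$map$locus), ],
                    skipped = markers$skipped)
  attr(out, "qc") <- report
  out
}

# ---------------------------------------------------------------------------
# Weather
# ---------------------------------------------------------------------------

WEATHER_VARS <- c("prcp", "tmax", "tmin", "tmean", "rh", "srad", "wind",
                  "et", "cloud")

#' Construct and validate a daily weather table
#'
#' One row per (environment, date) with precipitation (mm), daily maximum /
#' minimum / mean temperature (deg C), relative humidity (%), solar radiation
#' (MJ m-2 d-1), wind speed (m s-1), evapotranspiration (mm) and cloud cover
#' (%). Dates must be contiguous within each environment and
#' `tmin <= tmean <= tmax` on every row.
#'
#' @param df data frame with columns `environment`, `date` and the nine daily
#'   variables.
#' @return the validated data frame with class `WeatherTable`.
#' @export
weather_table <- function(df) {
  need <- c("environment", "date", WEATHER_VARS)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing weather column(s): ", paste(miss, collapse = ", "))
  if (!inherits(df$date, "Date")) df$date <- as.Date(as.character(df$date))
  key <- paste(df$environment, df$date)
  if (anyDuplicated(key)) stop("duplicate (environment, date) row(s)")
  bad <- df$tmin > df$tmean + 1e-9 | df$tmean > df$tmax + 1e-9
  if (any(bad))
    stop("tmin <= tmean <= tmax violated on ", sum(bad), " row(s)")
  for (e in unique(df$environment)) {
    d <- sort(df$date[df$environment == e])
    if (length(d) > 1 && any(diff(as.integer(d)) != 1))
      stop("dates not contiguous for environment ", e)
  }
  class(df) <- c("WeatherTable", "data.frame")
  df
}

#' Read a daily weather CSV
#' @param path CSV with header columns `environment, date` plus the nine
#'   daily variables (see [weather_table()]).
#' @return a `WeatherTable`.
#' @export
read_weather <- function(path) {
  weather_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a weather table
#' @param weather a `WeatherTable`.
#' @param path output CSV path.
#' @export
write_weather <- function(weather, path) {
  df <- as.data.frame(weather)
  df$date <- format(df$date, "%Y-%m-%d")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Dataset-level filters and summaries
# ---------------------------------------------------------------------------

#' Drop environments with too few genotypes
#'
#' Environments whose number of distinct genotypes is strictly less than
#' `min_genotypes` are removed entirely (an environment with exactly the
#' threshold count is retained).
#'
#' @param pheno a `PhenotypeTable`.
#' @param min_genotypes minimum distinct genotype count (default 25).
#' @return the filtered `PhenotypeTable`; dropped environments are messaged
#'   and recorded under `attr(, "filters")`.
#' @export
filter_environments <- function(pheno, min_genotypes = 25) {
  stopifnot(min_genotypes >= 1)
  counts <- tapply(pheno$genotype, pheno$environment,
                   function(x) length(unique(x)))
  drop <- names(counts)[counts < min_genotypes]
  for (e in drop)
    message("dropping environment ", e, " (", counts[e], " genotypes < ",
            min_genotypes, ")")
  out <- pheno[!pheno$environment %in% drop, , drop = FALSE]
  if (nrow(out) == 0 || length(unique(out$environment)) == 0)
    stop("no environments left after filtering at threshold ", min_genotypes)
  attr(out, "filters") <- c(attr(pheno, "filters"),
                            list(min_genotypes = min_genotypes,
                                 dropped_environments = drop))
  attr(out, "seed") <- attr(pheno, "seed")
  class(out) <- class(pheno)
  out
}

#' Genotype connectivity between sites and between years
#'
#' Counts genotypes shared by each pair of sites (location x sowing window)
#' and by each pair of years; diagonals hold the per-site / per-year genotype
#' counts.
#'
#' @param pheno a `PhenotypeTable`.
#' @return list with symmetric integer matrices `site` and `year`.
#' @export
connectivity_summary <- function(pheno) {
  if (nrow(pheno) == 0) stop("empty phenotype table")
  shared <- function(f) {
    sets <- tapply(pheno$genotype, f, function(x) unique(x), simplify = FALSE)
    k <- length(sets)
    M <- matrix(0L, k, k, dimnames = list(names(sets), names(sets)))
    for (i in seq_len(k)) for (j in i:k)
      M[i, j] <- M[j, i] <- length(intersect(sets[[i]], sets[[j]]))
    M
  }
  list(site = shared(paste(pheno$location, pheno$sowing_period, sep = "_")),
       year = shared(as.character(pheno$year)))
}
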