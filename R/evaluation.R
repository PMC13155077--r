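# ---------------------------------------------------------------------------
# Cross-validation schemes and predictive-ability evaluation.
#
# CV1 masks whole genotypes (new-genotype scenario), CV2 masks genotype x
# environment cells (incompletely observed environments), CV0 masks one
# whole environment at a time (new-environment scenario). Predictions of
# masked cells are scored by Pearson correlation against the full-data truth
# model values, within trial-within-environment groups for GBLUP/RRM and
# within environment groups for the FA model.
# ---------------------------------------------------------------------------

#' Masking keys for a CV scheme
#'
#' @param scheme `"CV0"`, `"CV1"` or `"CV2"`.
#' @param stage2 stage-2 BLUE table.
#' @return character vector of keys: environments (CV0), genotypes (CV1) or
#'   genotype-by-environment cells (CV2, `"genotype|environment"`).
#' @export
cv_keys <- function(scheme, stage2) {
  switch(toupper(scheme),
         CV0 = sort(unique(stage2$environment)),
         CV1 = sort(unique(stage2$genotype)),
         CV2 = sort(unique(paste(stage2$genotype, stage2$environment,
                                 sep = "|"))),
         stop("unknown scheme: ", scheme))
}

#' Build cross-validation fold plans
#'
#' For CV1/CV2, each iteration partitions the keys into `n_folds` folds of
#' near-equal size (each key masked exactly once per iteration). For CV0 the
#' plans are leave-one-environment-out: one plan per environment, `n_folds`
#' and `n_iter` ignored.
#'
#' @param scheme `"CV0"`, `"CV1"` or `"CV2"`.
#' @param keys key universe (see [cv_keys()]).
#' @param n_folds folds per iteration (default 5, i.e. 20% masked per fold).
#' @param n_iter number of iterations (re-randomised partitions).
#' @param seed RNG seed; plans are fully determined by it.
#' @return list of plans: each `list(scheme, iter, fold, masked)`.
#' @export
make_folds <- function(scheme, keys, n_folds = 5, n_iter = 1, seed = 1) {
  scheme <- toupper(scheme)
  stopifnot(length(keys) >= 1)
  if (scheme == "CV0") {
    return(lapply(seq_along(keys), function(i)
      list(scheme = "CV0", iter = 1L, fold = i, masked = keys[i])))
  }
  if (length(keys) < n_folds)
    stop("fewer keys (", length(keys), ") than folds (", n_folds, ")")
  plans <- list()
  with_stream(seed + 7L, {
    for (it in seq_len(n_iter)) {
      shuffled <- sample(keys)
      fold_of <- rep(seq_len(n_folds), length.out = length(keys))
      for (f in seq_len(n_folds)) {
        plans[[length(plans) + 1L]] <- list(
          scheme = scheme, iter = it, fold = f,
          masked = sort(shuffled[fold_of == f]))
      }
    }
  })
  plans
}

masked_rows <- function(plan, stage2) {
  switch(plan$scheme,
         CV0 = stage2$environment %in% plan$masked,
         CV1 = stage2$genotype %in% plan$masked,
         CV2 = paste(stage2$genotype, stage2$environment, sep = "|") %in%
           plan$masked)
}

#' Per-group predictive ability
#'
#' Pearson correlation between predictions and reference values within each
#' group (trial for GBLUP/RRM, environment for the FA path). With
#' `centered = TRUE` both vectors are centred by their group means first
#' (this is how the FA path guards pooled summaries against common
#' environmental effects; within-group correlations are unchanged by it).
#' Groups with fewer than `min_n` pairs, or zero variance in either vector,
#' are skipped with a flag.
#'
#' @param pred,truth numeric vectors.
#' @param group grouping labels.
#' @param centered centre by group means before correlating.
#' @param min_n minimum pairs per group (default 3).
#' @return data frame: `group`, `ability`, `n`, `skipped`.
#' @export
predictive_ability <- function(pred, truth, group, centered = FALSE,
                               min_n = 3) {
  stopifnot(length(pred) == length(truth), length(pred) == length(group))
  out <- lapply(split(seq_along(pred), as.character(group)), function(i) {
    p <- pred[i]; t <- truth[i]
    ok <- is.finite(p) & is.finite(t)
    p <- p[ok]; t <- t[ok]
    if (length(p) < min_n || stats::sd(p) == 0 || stats::sd(t) == 0)
      return(data.frame(ability = NA_real_, n = length(p), skipped = TRUE))
    if (centered) { p <- p - mean(p); t <- t - mean(t) }
    data.frame(ability = stats::cor(p, t), n = length(p), skipped = FALSE)
  })
  res <- do.call(rbind, out)
  data.frame(group = names(out), res, row.names = NULL)
}

#' Run cross-validation for a set of models
#'
#' For every plan, refits each model on the training rows, predicts the
#' masked cells, and scores them against the (full-data, precomputed) truth
#' values. The FA model is scored per environment with centring; GBLUP and
#' RRM per trial within environment. Under CV0 only GBLUP and RRM are
#' admissible (the FA model has no correlation structure for an unobserved
#' environment); the RRM predicts the held-out environment through its EC
#' values. Model fits that fail or do not converge are recorded and their
#' plan's cells scored as missing.
#'
#' @param stage2 stage-2 BLUE table.
#' @param K genomic relationship matrix.
#' @param ec_matrix `ECMatrix` covering all cells (needed for RRM).
#' @param models subset of `c("gblup", "fa", "rrm")`.
#' @param plans from [make_folds()].
#' @param truth a `TruthValues` object.
#' @param rrm_ecs EC names for the RRM.
#' @param fa_q FA factors (default 2).
#' @param reml_args list of extra arguments for [reml_fit()]. The default
#'   caps each training refit at 100 AI iterations; fits still short of the
#'   tolerance there are treated as non-converged (logged, scored missing).
#' @return list of class `CVResult`: `results` (scheme, model, iter, fold,
#'   group, ability, n), `failures` (model/plan pairs that did not fit).
#' @export
run_cv <- function(stage2, K, ec_matrix = NULL, models = c("gblup", "fa", "rrm"),
                   plans, truth, rrm_ecs = NULL, fa_q = 2,
                   reml_args = list(maxit = 100)) {
  stopifnot(inherits(truth, "TruthValues"))
  models <- match.arg(models, c("gblup", "fa", "rrm"), several.ok = TRUE)
  scheme <- plans[[1]]$scheme
  if (scheme == "CV0" && "fa" %in% models) {
    warning("FA model is not admissible under CV0; dropping it")
    models <- setdiff(models, "fa")
  }
  if ("rrm" %in% models && (is.null(ec_matrix) || is.null(rrm_ecs)))
    stop("RRM needs ec_matrix and rrm_ecs")
  tv <- truth$values
  tkey <- paste(tv$genotype, tv$trial)

  # one full-data fit per model supplies variance-parameter starting values
  # for every training refit (the REML solution of a refit depends only on
  # its training rows; warm starts only shorten the optimizer's path)
  warm <- list()
  for (mod in models) {
    wf <- tryCatch(switch(mod,
      gblup = do.call(fit_gblup, c(list(stage2, K), reml_args)),
      fa = do.call(fit_gblup_fa, c(list(stage2, K, q = fa_q), reml_args)),
      rrm = do.call(fit_rrm, c(list(stage2, K, ec_matrix, rrm_ecs),
                               reml_args))),
      error = function(e) NULL)
    if (!is.null(wf))
      warm[[mod]] <- list(terms = unname(wf$fit$theta),
                          resid = wf$fit$sigma_e)
  }

  results <- list(); failures <- list()
  for (plan in plans) {
    m <- masked_rows(plan, stage2)
    if (!any(m) || all(m)) next
    train <- stage2[!m, , drop = FALSE]
    test <- stage2[m, , drop = FALSE]
    test$truth <- tv$truth[match(paste(test$genotype, test$trial), tkey)]
    for (mod in models) {
      margs <- reml_args
      if (!is.null(warm[[mod]])) margs$init <- warm[[mod]]
      one_fit <- function(args) tryCatch(switch(mod,
        gblup = do.call(fit_gblup, c(list(train, K), args)),
        fa = do.call(fit_gblup_fa, c(list(train, K, q = fa_q), args)),
        rrm = do.call(fit_rrm, c(list(train, K, ec_matrix, rrm_ecs), args))),
        error = function(e) e)
      fit <- one_fit(margs)
      if (inherits(fit, "error") && !is.null(margs$init))
        fit <- one_fit(reml_args)   # e.g. a fold lost an environment level
      if (inherits(fit, "error") || !fit$fit$converged) {
        failures[[length(failures) + 1L]] <- list(
          model = mod, iter = plan$iter, fold = plan$fold,
          message = if (inherits(fit, "error")) conditionMessage(fit)
                    else "not converged")
        next
      }
      pred <- predict_cells(fit, test, ec_matrix)
      grp <- if (mod == "fa") test$environment else test$trial
      pa <- predictive_ability(pred, test$truth, grp,
                               centered = mod == "fa")
      ok <- pa[!pa$skipped, c("group", "ability", "n")]
      if (nrow(ok))
        results[[length(results) + 1L]] <- data.frame(
          scheme = plan$scheme, model = mod, iter = plan$iter,
          fold = plan$fold, ok, row.names = NULL)
    }
  }
  res <- if (length(results)) do.call(rbind, results) else
    data.frame(scheme = character(), model = character(), iter = integer(),
               fold = integer(), group = character(), ability = numeric(),
               n = integer())
  n_plans <- length(plans)
  for (mod in models) {
    nfail <- sum(vapply(failures, function(f) f$model == mod, logical(1)))
    if (nfail > 0.5 * n_plans)
      stop("model '", mod, "' failed in ", nfail, "/", n_plans, " plans")
  }
  structure(list(results = res, failures = failures, scheme = scheme),
            class = "CVResult")
}

#' Median predictive ability per model
#' @param cv a `CVResult`.
#' @return named numeric vector of medians over all groups/folds/iterations.
#' @export
cv_medians <- function(cv) {
  vapply(split(cv$results$ability, cv$results$model),
         stats::median, numeric(1), na.rm = TRUE)
}

#' Deviation of each model from the GBLUP baseline
#'
#' Per evaluation unit (group x iteration x fold), the difference in
#' predictive ability from the baseline model, plus the count of units where
#' each model beats the baseline.
#'
#' @param cv a `CVResult`.
#' @param baseline baseline model name (default `"gblup"`).
#' @return list: `deviations` (unit-aligned data frame with column
#'   `deviation`), `summary` (per model: median deviation, n_units,
#'   n_better).
#' @export
baseline_deviation <- function(cv, baseline = "gblup") {
  res <- cv$results
  if (!baseline %in% res$model) stop("baseline '", baseline, "' not in results")
  unit <- function(d) paste(d$iter, d$fold, d$group, sep = "|")
  base <- res[res$model == baseline, ]
  bmap <- stats::setNames(base$ability, unit(base))
  oth <- res[res$model != baseline, ]
  oth$baseline_ability <- bmap[unit(oth)]
  missing_units <- is.na(oth$baseline_ability)
  if (any(missing_units))
    message(sum(missing_units), " unit(s) missing in the baseline; excluded")
  oth <- oth[!missing_units, ]
  oth$deviation <- oth$ability - oth$baseline_ability
  summ <- do.call(rbind, lapply(split(oth, oth$model), function(d)
    data.frame(model = d$model[1],
               median_deviation = stats::median(d$deviation, na.rm = TRUE),
               n_units = nrow(d),
               n_better = sum(d$deviation > 0, na.rm = TRUE))))
  rownames(summ) <- NULL
  list(deviations = oth, summary = summ)
}

#' Characterize the dataset: variance components and year groups
#'
#' Fits the plot-level variance-component model (all terms random: genotype,
#' year, location, sowing period, trial, replicate and block nested in their
#' parents, genotype-by-year, genotype-by-location, genotype-by-sowing, and
#' genotype-by-environment) by REML via lme4, reports each component as a
#' percentage of the total, and groups years into high- and low-yielding
#' clusters by k-means (k = 2, 25 restarts, seeded) on year-mean yields.
#'
#' @param pheno a plot-level `PhenotypeTable` with yields.
#' @param ecs optional `ECMatrix`; when given, per-group means of
#'   `ec_columns` are reported.
#' @param ec_columns EC columns to summarise per year group.
#' @param seed seed for the k-means restarts.
#' @return list of class `VarianceReport`: `varcomp` (component, variance,
#'   percent), `year_groups` (year, group, mean_yield), `group_ecs`.
#' @export
characterize <- function(pheno, ecs = NULL, ec_columns = NULL, seed = 1) {
  d <- as.data.frame(pheno)
  d <- d[!is.na(d$yield), ]
  d$year <- factor(d$year)
  d$rep_in_trial <- interaction(d$trial, d$replicate, drop = TRUE)
  # RCBD rows carry no incomplete block: give them one pseudo-block per
  # replicate so lme4 keeps the rows (their block term is absorbed by rep)
  d$blk_in_rep <- if (any(!is.na(d$block)))
    interaction(d$trial, d$replicate,
                ifelse(is.na(d$block), "none", d$block), drop = TRUE)
    else NULL
  d$genv <- interaction(d$genotype, d$environment, drop = TRUE)
  # random terms whose factor has a single observed level are dropped (e.g.
  # a one-location or one-window dataset)
  nlev <- function(x) length(unique(x))
  terms <- c(
    if (nlev(d$genotype) > 1) "(1 | genotype)",
    if (nlev(d$year) > 1) "(1 | year)",
    if (nlev(d$location) > 1) "(1 | location)",
    if (nlev(d$sowing_period) > 1) "(1 | sowing_period)",
    if (nlev(d$trial) > 1) "(1 | trial)",
    if (nlev(d$rep_in_trial) > 1) "(1 | rep_in_trial)",
    if (nlev(d$year) > 1) "(1 | genotype:year)",
    if (nlev(d$location) > 1) "(1 | genotype:location)",
    if (nlev(d$sowing_period) > 1) "(1 | genotype:sowing_period)",
    if (nlev(d$genv) > 1) "(1 | genv)",
    if (!is.null(d$blk_in_rep) && nlev(d$blk_in_rep) > 1) "(1 | blk_in_rep)")
  form <- stats::as.formula(paste("yield ~", paste(terms, collapse = " + ")))
  fit <- lme4::lmer(form, data = d, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore",
                                                calc.derivs = FALSE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- data.frame(component = vc$grp, variance = vc$vcov)
  varcomp$percent <- 100 * varcomp$variance / sum(varcomp$variance)

  ymeans <- tapply(d$yield, as.character(d$year), mean)
  km <- with_stream(seed + 8L,
                    stats::kmeans(matrix(ymeans, ncol = 1), centers = 2,
                                  nstart = 25))
  hi <- which.max(km$centers)
  groups <- data.frame(year = names(ymeans),
                       group = ifelse(km$cluster == hi, "high", "low"),
                       mean_yield = as.numeric(ymeans), row.names = NULL)

  group_ecs <- NULL
  if (!is.null(ecs) && !is.null(ec_columns)) {
    em <- as.data.frame(ecs)
    em$year <- sub("_.*", "", em$environment)
    em$group <- groups$group[match(em$year, groups$year)]
    group_ecs <- do.call(rbind, lapply(split(em, em$group), function(g)
      data.frame(group = g$group[1], t(colMeans(g[, ec_columns, drop = FALSE])),
                 check.names = FALSE)))
    rownames(group_ecs) <- NULL
  }
  structure(list(varcomp = varcomp, year_groups = groups,
                 group_ecs = group_ecs, model = fit),
            class = "VarianceReport")
}
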