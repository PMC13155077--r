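# ---------------------------------------------------------------------------
# Stage-2 genomic prediction models on the two-stage weighted BLUEs.
#
# All four models share the cell layout (one row per genotype x trial, trial
# nested in environment) and the weighted residual sigma_e^2 * diag(SE_i^2)
# carried over from stage 1. The truth model (FA2 GEI + genotype-by-trial)
# defines the reference genotypic values; GBLUP, the factor-analytic GxE
# model and the EC random-regression model are the predictors compared under
# CV0/CV1/CV2.
# ---------------------------------------------------------------------------

stage2_check <- function(stage2) {
  need <- c("genotype", "trial", "environment", "blue", "weight")
  miss <- setdiff(need, names(stage2))
  if (length(miss)) stop("stage-2 table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(!is.finite(stage2$weight) | stage2$weight <= 0))
    stop("stage-2 weights must be positive and finite")
  stage2
}

gp_wrap <- function(kind, fit, stage2, K, extra = list()) {
  structure(c(list(kind = kind, fit = fit, stage2 = stage2, K = K), extra),
            class = "gp_model")
}

#' @exportS3Method
#' @noRd
print.gp_model <- function(x, ...) {
  cat("gp_model '", x$kind, "': n = ", nrow(x$stage2),
      ", logLik = ", format(x$fit$logLik),
      if (!x$fit$converged) " (NOT converged)", "\n", sep = "")
  invisible(x)
}

#' Fit the truth model: FA2 GEI reference genotypic values
#'
#' Weighted two-stage model on the full data with fixed environment effects;
#' random genotype (GRM), genotype-by-environment with a reduced-rank
#' factor-analytic covariance across environments (Kronecker with the GRM),
#' trial within environment, and genotype-by-trial. The conditional genotypic
#' value of each genotype-by-trial cell (genotype + GEI + genotype-by-trial
#' BLUPs) is the reference ("truth") against which cross-validated
#' predictions are scored.
#'
#' @param stage2 stage-1 BLUE table (`genotype, trial, environment, blue,
#'   weight`), see [fit_trials()].
#' @param K genomic relationship matrix covering the genotypes.
#' @param q number of FA factors (default 2).
#' @param free_resid estimate a free residual scale over the stage-1 weights
#'   instead of fixing it at 1 (default FALSE: with per-cell GEI or
#'   genotype-by-trial terms in the model, a free scale on the weighted
#'   residual is barely identified and slows REML badly).
#' @param ... passed to [reml_fit()].
#' @return list of class `TruthValues`: `values` (per-cell data frame with
#'   column `truth`), and the underlying `model` (`gp_model`).
#' @export
fit_truth <- function(stage2, K, q = 2, free_resid = FALSE, ...) {
  stage2 <- stage2_check(stage2)
  ne <- length(unique(stage2$environment))
  if (ne < 2 * q + 2)
    stop("FA", q, " truth model needs more environments (have ", ne,
         "); consider q = ", max(1, (ne - 2) %/% 2))
  d <- as.data.frame(stage2)
  d$cell <- paste(d$genotype, d$trial)
  X <- stats::model.matrix(~ environment, d)
  fit <- reml_fit(d$blue, X, d, list(
    g = rt_known("genotype", K, label = "g"),
    ge = rt_fa("environment", "genotype", K, q = q, label = "ge"),
    trial = rt_iid("trial"),
    gtrial = rt_iid("cell", label = "g:trial")),
    weights = d$weight, fix_resid_scale = !free_resid, ...)
  if (!fit$converged)
    warning("truth model did not reach the convergence tolerance")
  g <- blup_predict(fit, "g")
  ge <- blup_predict(fit, "ge")
  gt <- blup_predict(fit, "gtrial")
  vals <- data.frame(
    genotype = d$genotype, trial = d$trial, environment = d$environment,
    truth = g[d$genotype] + ge[cbind(d$genotype, d$environment)] +
      gt[d$cell],
    row.names = NULL)
  structure(list(values = vals,
                 model = gp_wrap("truth", fit, d, K)),
            class = "TruthValues")
}

#' Fit the GBLUP baseline model
#'
#' Fixed environment; random genotype (GRM), IID genotype-by-environment,
#' trial within environment; weighted residual.
#'
#' @inheritParams fit_truth
#' @return a `gp_model`.
#' @export
fit_gblup <- function(stage2, K, free_resid = FALSE, ...) {
  stage2 <- stage2_check(stage2)
  d <- as.data.frame(stage2)
  d$ge_cell <- paste(d$genotype, d$environment)
  X <- stats::model.matrix(~ environment, d)
  fit <- reml_fit(d$blue, X, d, list(
    g = rt_known("genotype", K, label = "g"),
    ge = rt_iid("ge_cell", label = "ge"),
    trial = rt_iid("trial")),
    weights = d$weight, fix_resid_scale = !free_resid, ...)
  gp_wrap("gblup", fit, d, K)
}

#' Fit the factor-analytic genotype-by-environment model
#'
#' The GBLUP model with the IID GEI term replaced by a reduced-rank
#' factor-analytic covariance across environments, Kronecker with the GRM.
#'
#' @inheritParams fit_truth
#' @param q number of factors (default 2).
#' @return a `gp_model`.
#' @export
fit_gblup_fa <- function(stage2, K, q = 2, free_resid = FALSE, ...) {
  stage2 <- stage2_check(stage2)
  d <- as.data.frame(stage2)
  X <- stats::model.matrix(~ environment, d)
  fit <- reml_fit(d$blue, X, d, list(
    g = rt_known("genotype", K, label = "g"),
    ge = rt_fa("environment", "genotype", K, q = q, label = "ge"),
    trial = rt_iid("trial")),
    weights = d$weight, fix_resid_scale = !free_resid, ...)
  gp_wrap("fa", fit, d, K, list(q = q))
}

#' Fit the EC random-regression (reaction-norm) model
#'
#' Fixed overall mean and global EC regressions; per-genotype random
#' intercept and slopes with coefficient covariance \eqn{\Omega} Kronecker
#' with the GRM, plus IID genotype-by-environment and trial-within-
#' environment terms (making the model comparable with GBLUP and the FA
#' model); weighted residual. EC columns are centred and unit-scaled on the
#' data used for fitting (the constants are stored in the model so held-out
#' cells are standardised with training constants only).
#'
#' @inheritParams fit_truth
#' @param ec_matrix an `ECMatrix` covering at least the fitted cells.
#' @param ecs character vector of EC column names (1-5).
#' @param standardize centre/scale the EC columns (default TRUE).
#' @return a `gp_model` carrying `ecs`, `ec_center`, `ec_scale`.
#' @export
fit_rrm <- function(stage2, K, ec_matrix, ecs, standardize = TRUE,
                    free_resid = FALSE, ...) {
  stage2 <- stage2_check(stage2)
  if (length(ecs) < 1 || length(ecs) > 5)
    stop("the random-regression model takes 1-5 ECs")
  stopifnot(all(ecs %in% names(ec_matrix)))
  d <- as.data.frame(stage2)
  d$ge_cell <- paste(d$genotype, d$environment)
  ecd <- ec_lookup(ec_matrix, d$genotype, d$trial, ecs)
  ctr <- if (standardize) colMeans(ecd) else rep(0, length(ecs))
  scl <- if (standardize) apply(ecd, 2, stats::sd) else rep(1, length(ecs))
  scl[scl == 0] <- 1
  names(ctr) <- names(scl) <- ecs
  ecz <- sweep(sweep(ecd, 2, ctr), 2, scl, "/")
  d[ecs] <- as.data.frame(ecz)
  X <- cbind(`(Intercept)` = 1, as.matrix(d[, ecs, drop = FALSE]))
  fit <- reml_fit(d$blue, X, d, list(
    rr = rt_rrm("genotype", K, ecs, label = "rr"),
    ge = rt_iid("ge_cell", label = "ge"),
    trial = rt_iid("trial")),
    weights = d$weight, fix_resid_scale = !free_resid, ...)
  gp_wrap("rrm", fit, d, K,
          list(ecs = ecs, ec_center = ctr, ec_scale = scl))
}

ec_lookup <- function(ec_matrix, genotype, trial, ecs) {
  key <- paste(ec_matrix$genotype, ec_matrix$trial)
  pos <- match(paste(genotype, trial), key)
  if (anyNA(pos))
    stop("EC matrix lacks ", sum(is.na(pos)), " genotype-trial cell(s)")
  as.matrix(as.data.frame(ec_matrix)[pos, ecs, drop = FALSE])
}

#' Predict genotype-by-trial cells from a fitted stage-2 model
#'
#' Returns the genotype-specific part of the prediction for each requested
#' cell (environment/trial main effects are omitted: predictive ability is
#' scored within trial or environment groups, where they are constant).
#' GBLUP predicts the genotype BLUP; the FA model adds the GEI BLUP of the
#' cell's environment (borrowing through the estimated environment
#' covariance, so cells in observed environments get genotype-specific GEI
#' even when masked); the RRM predicts fixed EC part + intercept + slopes x
#' ECs with the cell's own (genotype-specific) EC values.
#'
#' @param model a `gp_model`.
#' @param cells data frame with `genotype`, `trial`, `environment`.
#' @param ec_matrix an `ECMatrix` (required for RRM predictions; may include
#'   cells never seen in fitting, e.g. a held-out environment).
#' @return numeric vector of predictions aligned with `cells`.
#' @export
predict_cells <- function(model, cells, ec_matrix = NULL) {
  stopifnot(inherits(model, "gp_model"))
  kind <- model$kind
  if (kind == "gblup") {
    g <- blup_predict(model$fit, "g")
    return(unname(g[cells$genotype]))
  }
  if (kind %in% c("fa", "truth")) {
    g <- blup_predict(model$fit, "g")
    ge <- blup_predict(model$fit, "ge")
    known_env <- cells$environment %in% colnames(ge)
    out <- unname(g[cells$genotype])
    out[known_env] <- out[known_env] +
      ge[cbind(cells$genotype[known_env], cells$environment[known_env])]
    return(out)
  }
  if (kind == "rrm") {
    if (is.null(ec_matrix)) stop("RRM prediction needs the EC matrix")
    ecd <- ec_lookup(ec_matrix, cells$genotype, cells$trial, model$ecs)
    ecz <- sweep(sweep(ecd, 2, model$ec_center), 2, model$ec_scale, "/")
    C <- blup_predict(model$fit, "rr")
    beta <- model$fit$beta
    fixed <- drop(ecz %*% beta[model$ecs])
    rand <- C[cells$genotype, 1] +
      rowSums(ecz * C[cells$genotype, -1, drop = FALSE])
    return(unname(fixed + rand))
  }
  stop("unknown model kind: ", kind)
}

#' Predict genotypes in a new (un-phenotyped) environment
#'
#' For a random-regression model, prediction in an environment with no yield
#' data needs only the genotypes' EC values there (computable from the new
#' environment's weather and each genotype's phenology): fixed EC part +
#' genotype intercept + slopes x ECs. The new environment's own mean and IID
#' GEI effect are unknowable and set to 0, which leaves within-environment
#' genotype ranking unaffected.
#'
#' @param model an RRM `gp_model`.
#' @param cells data frame with `genotype` and `trial` rows of the new
#'   environment.
#' @param ec_matrix an `ECMatrix` containing those cells.
#' @return named numeric vector of per-genotype predictions; genotypes with
#'   missing EC values are dropped with a warning.
#' @export
predict_new_environment <- function(model, cells, ec_matrix) {
  stopifnot(inherits(model, "gp_model"), model$kind == "rrm")
  key <- paste(ec_matrix$genotype, ec_matrix$trial)
  pos <- match(paste(cells$genotype, cells$trial), key)
  if (anyNA(pos)) {
    warning("dropping ", sum(is.na(pos)),
            " genotype(s) without EC values in the target environment")
    cells <- cells[!is.na(pos), , drop = FALSE]
  }
  out <- predict_cells(model, cells, ec_matrix)
  names(out) <- cells$genotype
  out
}

#' Forward stepwise EC addition for the random-regression model
#'
#' Starting from the empty set, adds at each size the candidate EC whose
#' RRM attains the best median cross-validated predictive ability under the
#' supplied protocol (default CV1), up to `max_size` ECs. Candidate fits
#' that do not converge are recorded and skipped.
#'
#' @param stage2,K,ec_matrix as in [fit_rrm()].
#' @param candidates candidate EC names.
#' @param truth a `TruthValues` (from the full data, computed once).
#' @param scheme CV scheme used for scoring (default `"CV1"`).
#' @param n_iter,n_folds,seed folds of the scoring protocol.
#' @param max_size largest EC set (default 5).
#' @param ... passed to the model fits.
#' @return list: `path` (ordered selected ECs), `specs` (best EC set of each
#'   size), `scores` (full score table: size, candidate, median ability,
#'   converged), `failed` (EC combinations that failed to converge).
#' @export
forward_stepwise <- function(stage2, K, ec_matrix, candidates, truth,
                             scheme = "CV1", n_iter = 1, n_folds = 5,
                             seed = 1, max_size = 5, ...) {
  stopifnot(length(candidates) >= 1)
  selected <- character(0)
  scores <- list(); failed <- list(); specs <- list()
  keys <- cv_keys(scheme, stage2)
  plans <- make_folds(scheme, keys, n_folds = n_folds, n_iter = n_iter,
                      seed = seed)
  for (size in seq_len(min(max_size, length(candidates)))) {
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    step_scores <- rep(NA_real_, length(remaining))
    names(step_scores) <- remaining
    for (cand in remaining) {
      ecs <- c(selected, cand)
      med <- tryCatch({
        cv <- run_cv(stage2, K, ec_matrix, models = "rrm", plans = plans,
                     truth = truth, rrm_ecs = ecs, ...)
        stats::median(cv$results$ability, na.rm = TRUE)
      }, error = function(e) NA_real_)
      step_scores[cand] <- med
      scores[[length(scores) + 1L]] <- data.frame(
        size = size, candidate = cand,
        ecs = paste(ecs, collapse = "+"),
        median_ability = med, converged = !is.na(med))
      if (is.na(med))
        failed[[length(failed) + 1L]] <- ecs
    }
    if (all(is.na(step_scores))) {
      warning("all size-", size, " candidates failed; stopping at size ",
              size - 1L)
      break
    }
    best <- names(step_scores)[order(-step_scores, names(step_scores))][1]
    selected <- c(selected, best)
    specs[[size]] <- selected
  }
  list(path = selected, specs = specs,
       scores = do.call(rbind, scores), failed = failed)
}
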