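# ---------------------------------------------------------------------------
# Stage 1 of the two-stage analysis: per-trial fits.
#
# Genotype is fixed to produce BLUEs with standard errors (the stage-2 weights
# are 1/SE^2); a companion fit with genotype random provides the genotypic
# variance and BLUP prediction-error variances for Cullis' H^2. Randomized
# complete block designs carry a random replicate effect; resolvable alpha
# designs add a random incomplete block nested in replicate.
# ---------------------------------------------------------------------------

#' Fit one trial: genotype BLUEs, variance components, Cullis heritability
#'
#' @param trial_pheno rows of a `PhenotypeTable` belonging to a single trial,
#'   with non-missing yield.
#' @param h2_pairs_max maximum number of genotype pairs used for the average
#'   BLUP-difference prediction-error variance; above this the mean is taken
#'   over a deterministic evenly-spaced subsample of pairs.
#' @return a `TrialFit` list: `trial`, `design` (`"rcbd"` or `"alpha"`),
#'   `blues` (data frame genotype/blue/se/weight), `varcomp`, `h2`,
#'   `h2_flag` (TRUE when the genotypic variance hit its boundary and the
#'   heritability expression is undefined), `converged`.
#' @export
fit_trial <- function(trial_pheno, h2_pairs_max = 2000) {
  d <- as.data.frame(trial_pheno)
  d <- d[!is.na(d$yield), ]
  if (length(unique(d$trial)) != 1) stop("fit_trial expects a single trial")
  if (length(unique(d$replicate)) < 2) stop("trial needs >= 2 replicates")
  d$genotype <- factor(d$genotype)
  d$rep <- factor(d$replicate)
  alpha <- any(!is.na(d$block))
  d$blk <- if (alpha) interaction(d$rep, d$block, drop = TRUE) else NA

  X <- stats::model.matrix(~ 0 + genotype, d)
  colnames(X) <- levels(d$genotype)
  rand <- list(rep = rt_iid("rep"))
  if (alpha) rand$block <- rt_iid("blk", label = "block(rep)")
  fit <- reml_fit(d$yield, X, d, rand)
  blue <- fit$beta
  se <- sqrt(diag(fit$beta_cov))
  blues <- data.frame(genotype = names(blue), blue = unname(blue),
                      se = unname(se), weight = unname(1 / se^2),
                      row.names = NULL)

  # companion fit, genotype random, for sigma_g^2 and Cullis H^2
  rand2 <- c(list(genotype = rt_iid("genotype")), rand)
  fit2 <- reml_fit(d$yield, matrix(1, nrow(d), 1,
                                   dimnames = list(NULL, "(Intercept)")),
                   d, rand2,
                   init = list(terms = c(list(stats::var(blue)),
                                         fit$theta),
                               resid = fit$sigma_e))
  h2 <- cullis_h2(fit2, term = "genotype", pairs_max = h2_pairs_max)

  varcomp <- c(unlist(fit$theta), resid = fit$sigma_e)
  varcomp_random <- c(unlist(fit2$theta), resid = fit2$sigma_e)
  structure(list(trial = as.character(d$trial[1]), design = if (alpha) "alpha" else "rcbd",
                 blues = blues, varcomp = varcomp,
                 varcomp_random = varcomp_random,
                 sigma_g2 = fit2$theta$genotype,
                 h2 = h2$h2, h2_flag = h2$flag,
                 converged = fit$converged && fit2$converged),
            class = "TrialFit")
}

#' Cullis heritability from a genotype-random fit
#'
#' \eqn{H^2 = 1 - \bar v_\Delta^{BLUP} / (2\hat\sigma_g^2)} with
#' \eqn{\bar v_\Delta^{BLUP}} the mean prediction-error variance of BLUP
#' differences over genotype pairs. With `m` genotypes and PEV matrix `V`,
#' the exact pair mean is \eqn{2(m\,\mathrm{tr}V - \mathbf{1}^\top V
#' \mathbf{1})/(m(m-1))}; beyond `pairs_max` pairs an evenly spaced
#' deterministic subsample of pairs is averaged instead.
#'
#' @param fit a [reml_fit()] with a random genotype term.
#' @param term name or index of the genotype term in `fit`.
#' @param pairs_max pair budget before subsampling.
#' @return list with `h2`, `vbar`, and `flag` (TRUE when
#'   \eqn{\hat\sigma_g^2} is at the boundary and `h2` is reported as 0).
#' @export
cullis_h2 <- function(fit, term = "genotype", pairs_max = 2000) {
  if (is.character(term)) term <- match(term, fit$term_names)
  sg2 <- fit$theta[[term]]
  bp <- blup_predict(fit, term, pev = TRUE)
  V <- bp$pev
  m <- nrow(V)
  if (m < 2) stop("need >= 2 genotypes")
  npairs <- m * (m - 1) / 2
  if (npairs <= pairs_max) {
    vbar <- 2 * (m * sum(diag(V)) - sum(V)) / (m * (m - 1))
  } else {
    pr <- utils::combn(m, 2)
    keep <- unique(round(seq(1, ncol(pr), length.out = pairs_max)))
    pr <- pr[, keep, drop = FALSE]
    vbar <- mean(V[cbind(pr[1, ], pr[1, ])] + V[cbind(pr[2, ], pr[2, ])] -
                   2 * V[cbind(pr[1, ], pr[2, ])])
  }
  if (sg2 < 1e-8 * stats::var(fit$y)) {
    return(list(h2 = 0, vbar = vbar, flag = TRUE))
  }
  list(h2 = max(0, min(1, 1 - vbar / (2 * sg2))), vbar = vbar, flag = FALSE)
}

#' Stage-1 analysis of every trial
#'
#' @param pheno a `PhenotypeTable`.
#' @return list with `blues` (genotype, trial, environment, blue, se, weight)
#'   and `h2` (trial, environment, design, sigma_g2, h2, h2_flag, converged)
#'   data frames, plus the per-trial `fits`.
#' @export
fit_trials <- function(pheno) {
  trials <- split(as.data.frame(pheno), pheno$trial)
  fits <- lapply(trials, fit_trial)
  env_of <- vapply(trials, function(d) as.character(d$environment[1]),
                   character(1))
  blues <- do.call(rbind, lapply(names(fits), function(tr) {
    b <- fits[[tr]]$blues
    data.frame(genotype = b$genotype, trial = tr, environment = env_of[tr],
               blue = b$blue, se = b$se, weight = b$weight,
               row.names = NULL)
  }))
  h2 <- data.frame(
    trial = names(fits), environment = unname(env_of),
    design = vapply(fits, `[[`, character(1), "design"),
    sigma_g2 = vapply(fits, `[[`, numeric(1), "sigma_g2"),
    h2 = vapply(fits, `[[`, numeric(1), "h2"),
    h2_flag = vapply(fits, `[[`, logical(1), "h2_flag"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    row.names = NULL)
  list(blues = blues, h2 = h2, fits = fits)
}
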