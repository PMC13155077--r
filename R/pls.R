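# ---------------------------------------------------------------------------
# Partial least squares (univariate response, NIPALS) and VIP-based selection
# of environmental covariates.
# ---------------------------------------------------------------------------

#' Univariate-response PLS regression (NIPALS)
#'
#' Fits the standard PLS1 decomposition: predictors are centred (and by
#' default unit-scaled); at each component the X-weight vector is
#' \eqn{w_a = X_a^\top y / \|X_a^\top y\|}, scores \eqn{t_a = X_a w_a},
#' X-loadings \eqn{p_a = X_a^\top t_a / t_a^\top t_a}, y-loading
#' \eqn{q_a = y^\top t_a / t_a^\top t_a}, with deflation of X and y. The
#' per-component explained sum of squares of y is \eqn{SSY_a = q_a^2
#' t_a^\top t_a}.
#'
#' When `ncomp = NULL` the number of components is chosen by k-fold
#' cross-validation (deterministic systematic folds) minimising the root mean
#' squared error of prediction, capped at `max_comp`.
#'
#' @param X numeric predictor matrix (rows = observations); constant columns
#'   are dropped with a warning.
#' @param y numeric response.
#' @param ncomp number of components, or `NULL` to choose by CV.
#' @param scale unit-scale the columns of X?
#' @param max_comp cap on the number of components.
#' @param cv_folds folds for the component-number CV.
#' @return object of class `PLSFit` with weights `W`, scores `Tm`, loadings
#'   `P`, y-loadings `q`, per-component `ssy`, the centring/scaling constants
#'   and `ncomp`.
#' @export
pls_fit <- function(X, y, ncomp = NULL, scale = TRUE, max_comp = 10,
                    cv_folds = 10) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  sds <- apply(X, 2, stats::sd)
  const <- sds == 0 | !is.finite(sds)
  if (any(const)) {
    warning("dropping ", sum(const), " constant column(s): ",
            paste(utils::head(colnames(X)[const]), collapse = ", "))
    X <- X[, !const, drop = FALSE]
    sds <- sds[!const]
  }
  if (ncol(X) == 0) stop("no non-constant predictors")
  rk <- qr(scale(X, scale = FALSE))$rank
  cap <- min(max_comp, rk, nrow(X) - 1)
  if (!is.null(ncomp) && ncomp > cap) {
    warning("ncomp reduced from ", ncomp, " to ", cap, " (rank/size limit)")
    ncomp <- cap
  }
  if (is.null(ncomp)) {
    folds <- (seq_len(nrow(X)) - 1L) %% cv_folds + 1L
    press <- matrix(NA_real_, cv_folds, cap)
    for (f in seq_len(cv_folds)) {
      tr <- folds != f
      if (sum(tr) < 2) next
      fit <- pls_core(X[tr, , drop = FALSE], y[tr], min(cap, sum(tr) - 1), scale)
      for (a in seq_len(fit$ncomp)) {
        pred <- pls_predict_core(fit, X[!tr, , drop = FALSE], a)
        press[f, a] <- mean((y[!tr] - pred)^2)
      }
    }
    rmsep <- sqrt(colMeans(press, na.rm = TRUE))
    ncomp <- which.min(rmsep)
  }
  fit <- pls_core(X, y, ncomp, scale)
  fit
}

pls_core <- function(X, y, ncomp, scale) {
  xm <- colMeans(X)
  xs <- if (scale) apply(X, 2, stats::sd) else rep(1, ncol(X))
  xs[xs == 0] <- 1
  Xc <- sweep(sweep(X, 2, xm), 2, xs, "/")
  ym <- mean(y)
  yc <- y - ym
  p <- ncol(Xc)
  W <- P <- matrix(0, p, ncomp, dimnames = list(colnames(X), NULL))
  Tm <- matrix(0, nrow(X), ncomp)
  q <- ssy <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-10 * max(sqrt(sum(yc^2)), 1)) {
      if (a > 1L) { ncomp <- a - 1L; break }
      # response orthogonal to every predictor: keep one degenerate
      # component with (near-)zero explained sum of squares
      w <- c(1, rep(0, p - 1))
      nw <- 1
    }
    w <- w / nw
    t <- drop(Xc %*% w)
    tt <- sum(t^2)
    pa <- drop(crossprod(Xc, t)) / tt
    qa <- sum(yc * t) / tt
    Xc <- Xc - tcrossprod(t, pa)
    yc <- yc - qa * t
    W[, a] <- w; P[, a] <- pa; Tm[, a] <- t; q[a] <- qa
    ssy[a] <- qa^2 * tt
  }
  if (ncomp == 0) stop("response is orthogonal to all predictors at scale 0")
  keep <- seq_len(ncomp)
  structure(list(W = W[, keep, drop = FALSE], P = P[, keep, drop = FALSE],
                 Tm = Tm[, keep, drop = FALSE], q = q[keep], ssy = ssy[keep],
                 x_center = xm, x_scale = xs, y_center = ym,
                 ncomp = as.integer(ncomp)),
            class = "PLSFit")
}

pls_predict_core <- function(fit, newX, ncomp = fit$ncomp) {
  Xc <- sweep(sweep(as.matrix(newX), 2, fit$x_center), 2, fit$x_scale, "/")
  keep <- seq_len(ncomp)
  # W* = W (P'W)^-1, regression coefficients b = W* q
  Ws <- fit$W[, keep, drop = FALSE] %*%
    solve(crossprod(fit$P[, keep, drop = FALSE], fit$W[, keep, drop = FALSE]))
  b <- Ws %*% fit$q[keep]
  drop(Xc %*% b) + fit$y_center
}

#' Predict from a PLS fit
#' @param fit a `PLSFit`.
#' @param newX matrix with the same columns as the training X.
#' @param ncomp number of components to use (default all fitted).
#' @export
pls_predict <- function(fit, newX, ncomp = fit$ncomp) {
  pls_predict_core(fit, newX[, rownames(fit$W), drop = FALSE], ncomp)
}

#' Variable importance in projection (VIP) scores
#'
#' \deqn{VIP_j = \sqrt{p \sum_a SSY_a (w_{ja}/\|w_a\|)^2 / \sum_a SSY_a}}
#' so that the mean squared VIP over the `p` predictors is exactly 1.
#'
#' @param fit a `PLSFit`.
#' @return object of class `VIPResult`: `scores` (named, descending order
#'   preserved in `ranking`).
#' @export
vip_scores <- function(fit) {
  if (sum(fit$ssy) <= 0) stop("zero explained sum of squares; VIP undefined")
  p <- nrow(fit$W)
  wnorm2 <- colSums(fit$W^2)
  contrib <- sweep(fit$W^2, 2, wnorm2, "/")      # (w_ja / ||w_a||)^2
  v <- sqrt(p * drop(contrib %*% fit$ssy) / sum(fit$ssy))
  names(v) <- rownames(fit$W)
  structure(list(scores = v,
                 ranking = names(sort(v, decreasing = TRUE))),
            class = "VIPResult")
}

#' Select the top-k predictors by VIP score
#'
#' Ties at the selection boundary are broken by lexicographic column name
#' (messaged).
#'
#' @param vip a `VIPResult`.
#' @param k number of predictors to keep (default 7).
#' @return character vector of selected column names, highest VIP first.
#' @export
select_top <- function(vip, k = 7) {
  v <- vip$scores
  stopifnot(k <= length(v))
  ord <- order(-v, names(v))                     # ties: lexicographic
  sel <- names(v)[ord][seq_len(k)]
  if (k < length(v)) {
    cut_score <- v[ord][k]
    tied <- names(v)[v == cut_score]
    if (length(tied) > 1 && any(!tied %in% sel))
      message("VIP tie at the selection boundary (", signif(cut_score, 6),
              "): kept ", paste(intersect(tied, sel), collapse = ", "),
              " by name order")
  }
  sel
}

#' Leave-one-environment-out EC selection
#'
#' Refits PLS + VIP with each environment's rows excluded and reports, per
#' fold, the top-`k` set; ECs entering any fold's selection but absent from
#' the full-data selection are flagged (these are covariates whose relevance
#' is masked by single environments).
#'
#' @param X EC value matrix (rows = genotype-trial cells).
#' @param y response aligned with `X`.
#' @param env environment label per row.
#' @param k selection size.
#' @param ... passed to [pls_fit()].
#' @return list: `full` (full-data selection), `folds` (named list of per-
#'   left-out-environment selections), `extra` (ECs appearing in some fold
#'   but not in `full`).
#' @export
loeo_select <- function(X, y, env, k = 7, ...) {
  env <- as.character(env)
  envs <- unique(env)
  if (length(envs) < 3) stop("leave-one-environment-out needs >= 3 environments")
  frac <- max(table(env)) / length(env)
  if (frac > 0.5)
    warning("one environment holds ", round(100 * frac), "% of rows; ",
            "leave-one-out folds will be very unbalanced")
  full <- select_top(vip_scores(pls_fit(X, y, ...)), k)
  folds <- lapply(envs, function(e) {
    keep <- env != e
    select_top(vip_scores(pls_fit(X[keep, , drop = FALSE], y[keep], ...)), k)
  })
  names(folds) <- envs
  extra <- setdiff(unique(unlist(folds)), full)
  list(full = full, folds = folds, extra = extra)
}
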