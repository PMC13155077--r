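# ---------------------------------------------------------------------------
# Random-term constructors
#
# Every random term is described at the level of the data rows ("cells"): the
# term contributes an n x n covariance block Gamma(theta) to
#   V = sum_k Gamma_k(theta_k) + sigma_e^2 * diag(1/w).
# Derivatives dGamma/dtheta are never materialised as n x n matrices; each
# term class knows how to return tr(P dGamma) and dGamma %*% Py from small
# structured pieces, which is what average-information REML needs.
# ---------------------------------------------------------------------------

#' Independent and identically distributed random term
#'
#' A random effect with one level per value of `factor` and covariance
#' \eqn{\sigma^2 I}. Used for replicates, blocks, trials within environment,
#' IID genotype-by-environment effects, and genotype effects when no
#' relationship matrix is wanted.
#'
#' @param factor name of a column in the model data (coerced to factor).
#' @param label optional label used in parameter names.
#' @return a random-term specification for [reml_fit()].
#' @export
rt_iid <- function(factor, label = factor) {
  structure(list(factor = factor, label = label), class = c("rt_iid", "ecrrm_rt"))
}

#' Random term with a known covariance matrix
#'
#' A random effect \eqn{u \sim N(0, \sigma^2 K)} with `K` known (typically a
#' genomic relationship matrix). Levels of `factor` must appear in
#' `rownames(K)`; `K` may contain additional (unphenotyped) levels, which can
#' then be predicted by [blup_predict()].
#'
#' @param factor name of the grouping column in the model data.
#' @param K symmetric covariance matrix with row/column names.
#' @param label optional parameter label.
#' @export
rt_known <- function(factor, K, label = factor) {
  K <- bend_psd(K)
  structure(list(factor = factor, K = K, label = label),
            class = c("rt_known", "ecrrm_rt"))
}

#' Factor-analytic genotype-by-environment random term
#'
#' Genotype-by-environment effects \eqn{ge \sim N(0, \Sigma_E \otimes K)} with
#' \eqn{\Sigma_E = \Lambda \Lambda^\top (+ \Psi)} a factor-analytic covariance
#' of rank `q` across the levels of `env`, and `K` a known genotype
#' covariance. The default is the reduced-rank form (\eqn{\Psi = 0});
#' `specifics = TRUE` adds environment-specific variances.
#'
#' @param env,geno names of the environment and genotype columns.
#' @param K known genotype covariance (e.g. VanRaden GRM).
#' @param q number of factors.
#' @param specifics add specific variances \eqn{\Psi}?
#' @export
rt_fa <- function(env, geno, K, q = 2, specifics = FALSE, label = "fa") {
  K <- bend_psd(K)
  structure(list(env = env, geno = geno, K = K, q = q,
                 specifics = specifics, label = label),
            class = c("rt_fa", "ecrrm_rt"))
}

#' Random-regression (reaction-norm) coefficient term
#'
#' Per-genotype random intercepts and slopes on covariates: the effect on a
#' cell is \eqn{\phi_c^\top C_{g(c)}} with coefficient rows
#' \eqn{C \sim MN(0, K, \Omega)} (matrix normal: genotype covariance `K`,
#' coefficient covariance \eqn{\Omega}, dimension 1 + number of covariates).
#' All of the genetic scale is carried by \eqn{\Omega}; `K` enters unscaled.
#'
#' @param geno name of the genotype column.
#' @param K known genotype covariance.
#' @param covariates character vector of covariate column names (the random
#'   intercept is always included first).
#' @export
rt_rrm <- function(geno, K, covariates, label = "rrm") {
  stopifnot(length(covariates) >= 0)
  K <- bend_psd(K)
  structure(list(geno = geno, K = K, covariates = covariates, label = label),
            class = c("rt_rrm", "ecrrm_rt"))
}

# Bend a symmetric matrix to PSD by flooring eigenvalues at
# 1e-6 * mean(diag); warns only when bending actually changes the matrix.
bend_psd <- function(K) {
  K <- (K + t(K)) / 2
  e <- eigen(K, symmetric = TRUE)
  floor_ev <- 1e-6 * mean(diag(K))
  if (min(e$values) >= -1e-8 * max(abs(e$values), 1)) {
    if (min(e$values) >= floor_ev) return(K)
  } else {
    warning("covariance matrix is not PSD; bending eigenvalues up to ",
            signif(floor_ev, 3))
  }
  ev <- pmax(e$values, floor_ev)
  K2 <- e$vectors %*% (ev * t(e$vectors))
  dimnames(K2) <- dimnames(K)
  K2
}

# --- internal per-term protocol ---------------------------------------------

rt_setup <- function(rt, data) UseMethod("rt_setup")
rt_npar <- function(st) UseMethod("rt_npar")
rt_parnames <- function(st) UseMethod("rt_parnames")
rt_init <- function(st, vshare, resid) UseMethod("rt_init")
rt_gamma <- function(st, th) UseMethod("rt_gamma")
rt_derivs <- function(st, th, P, Py) UseMethod("rt_derivs")
rt_constrain <- function(st, th, floor) UseMethod("rt_constrain")
rt_isscale <- function(st) UseMethod("rt_isscale")   # which params are >= 0 scales

#' @exportS3Method
#' @noRd
rt_isscale.rt_iid <- function(st) TRUE
#' @exportS3Method
#' @noRd
rt_isscale.rt_known <- function(st) TRUE
#' @exportS3Method
#' @noRd
rt_isscale.rt_fa <- function(st) rep(FALSE, rt_npar(st))
#' @exportS3Method
#' @noRd
rt_isscale.rt_rrm <- function(st) rep(FALSE, rt_npar(st))

# iid ------------------------------------------------------------------------
#' @exportS3Method
#' @noRd
rt_setup.rt_iid <- function(rt, data) {
  f <- factor(data[[rt$factor]])
  rt$f <- as.integer(f); rt$levels <- levels(f); rt$n <- length(f)
  rt$same <- outer(rt$f, rt$f, "==")          # fixed kernel Z Z^T
  rt$bidx <- split(seq_len(rt$n), rt$f)       # rows per level
  rt
}
#' @exportS3Method
#' @noRd
rt_npar.rt_iid <- function(st) 1L
#' @exportS3Method
#' @noRd
rt_parnames.rt_iid <- function(st) paste0("var(", st$label, ")")
#' @exportS3Method
#' @noRd
rt_init.rt_iid <- function(st, vshare, resid) vshare
#' @exportS3Method
#' @noRd
rt_gamma.rt_iid <- function(st, th) th * st$same
#' @exportS3Method
#' @noRd
rt_derivs.rt_iid <- function(st, th, P, Py) {
  # tr(P Z Z^T) = sum of within-level blocks of P: O(sum n_l^2), not O(n^2 q)
  tr <- sum(vapply(st$bidx, function(i) sum(P[i, i]), numeric(1)))
  s <- tapply_sum(Py, st$f, length(st$levels))[st$f]   # Z Z^T Py
  list(tr = tr, S = matrix(s, ncol = 1))
}
#' @exportS3Method
#' @noRd
rt_constrain.rt_iid <- function(st, th, floor) max(th, floor)

# known K --------------------------------------------------------------------
#' @exportS3Method
#' @noRd
rt_setup.rt_known <- function(rt, data) {
  g <- as.character(data[[rt$factor]])
  if (!all(g %in% rownames(rt$K)))
    stop("levels of '", rt$factor, "' missing from rownames(K): ",
         paste(utils::head(setdiff(g, rownames(rt$K))), collapse = ", "))
  gi <- match(g, rownames(rt$K))
  rt$gi <- gi
  rt$Kc <- rt$K[gi, gi, drop = FALSE]      # cell-level kernel
  rt$n <- length(gi)
  rt
}
#' @exportS3Method
#' @noRd
rt_npar.rt_known <- function(st) 1L
#' @exportS3Method
#' @noRd
rt_parnames.rt_known <- function(st) paste0("var(", st$label, ")")
#' @exportS3Method
#' @noRd
rt_init.rt_known <- function(st, vshare, resid) vshare / mean(diag(st$Kc))
#' @exportS3Method
#' @noRd
rt_gamma.rt_known <- function(st, th) th * st$Kc
#' @exportS3Method
#' @noRd
rt_derivs.rt_known <- function(st, th, P, Py) {
  list(tr = sum(P * st$Kc), S = matrix(st$Kc %*% Py, ncol = 1))
}
#' @exportS3Method
#' @noRd
rt_constrain.rt_known <- function(st, th, floor) max(th, floor)

# factor-analytic ------------------------------------------------------------
#' @exportS3Method
#' @noRd
rt_setup.rt_fa <- function(rt, data) {
  g <- as.character(data[[rt$geno]])
  if (!all(g %in% rownames(rt$K)))
    stop("levels of '", rt$geno, "' missing from rownames(K)")
  gi <- match(g, rownames(rt$K))
  e <- factor(data[[rt$env]])
  rt$gi <- gi
  rt$Kc <- rt$K[gi, gi, drop = FALSE]
  rt$ei <- as.integer(e); rt$envs <- levels(e); rt$ne <- nlevels(e)
  if (rt$ne < 2 * rt$q + 1)
    stop("FA(", rt$q, ") needs at least ", 2 * rt$q + 1, " environments, got ",
         rt$ne)
  rt$n <- length(gi)
  rt
}
#' @exportS3Method
#' @noRd
rt_npar.rt_fa <- function(st) {
  # identifiability: upper-triangular zeros in Lambda (lambda_{j,r} = 0, j < r)
  nl <- st$ne * st$q - (st$q * (st$q - 1L)) %/% 2L
  as.integer(nl + if (st$specifics) st$ne else 0L)
}
#' @exportS3Method
#' @noRd
rt_parnames.rt_fa <- function(st) {
  nm <- character(0)
  for (r in seq_len(st$q))
    nm <- c(nm, paste0("lam(", st$label, ")[", seq(r, st$ne), ",", r, "]"))
  if (st$specifics) nm <- c(nm, paste0("psi(", st$label, ")[", seq_len(st$ne), "]"))
  nm
}
fa_unpack <- function(st, th) {
  L <- matrix(0, st$ne, st$q)
  pos <- 1L
  for (r in seq_len(st$q)) {
    len <- st$ne - r + 1L
    L[seq(r, st$ne), r] <- th[pos:(pos + len - 1L)]
    pos <- pos + len
  }
  psi <- if (st$specifics) th[pos:(pos + st$ne - 1L)] else rep(0, st$ne)
  list(L = L, psi = psi)
}
fa_sigma_e <- function(st, th) {
  u <- fa_unpack(st, th)
  tcrossprod(u$L) + diag(u$psi, st$ne)
}
#' @exportS3Method
#' @noRd
rt_init.rt_fa <- function(st, vshare, resid) {
  # initial loadings from the leading eigenvectors of a crude environment
  # covariance of the working residuals (cells matched on genotype)
  SE <- crude_env_cov(resid, st$gi, st$ei, st$ne)
  sc <- vshare / max(mean(diag(SE)), 1e-8) / max(mean(diag(st$Kc)), 1e-8)
  SE <- SE * sc
  e <- eigen(SE, symmetric = TRUE)
  L <- e$vectors[, seq_len(st$q), drop = FALSE] %*%
    diag(sqrt(pmax(e$values[seq_len(st$q)], 1e-3 * mean(diag(SE)))), st$q)
  # sign convention + identifiability zeros
  for (r in seq_len(st$q)) {
    if (L[r, r] < 0) L[, r] <- -L[, r]
    if (r > 1) L[seq_len(r - 1), r] <- 0
  }
  th <- numeric(0)
  for (r in seq_len(st$q)) th <- c(th, L[seq(r, st$ne), r])
  if (st$specifics) th <- c(th, rep(0.05 * mean(diag(SE)), st$ne))
  th
}
crude_env_cov <- function(resid, gi, ei, ne) {
  # covariance across environments of genotype-matched residuals; missing
  # pairs filled with the average covariance, diagonal kept positive
  gl <- sort(unique(gi))
  M <- matrix(NA_real_, length(gl), ne)
  idx <- cbind(match(gi, gl), ei)
  M[idx] <- resid      # if duplicates (multiple trials), last one wins - fine
  S <- stats::cov(M, use = "pairwise.complete.obs")
  dg <- diag(S); dg[!is.finite(dg) | dg <= 0] <- stats::var(resid)
  off <- S[upper.tri(S)]
  fill <- mean(off[is.finite(off)], na.rm = TRUE)
  if (!is.finite(fill)) fill <- 0.5 * mean(dg)
  S[!is.finite(S)] <- fill
  diag(S) <- dg
  (S + t(S)) / 2
}
#' @exportS3Method
#' @noRd
rt_gamma.rt_fa <- function(st, th) {
  SE <- fa_sigma_e(st, th)
  SE[st$ei, st$ei] * st$Kc
}
#' @exportS3Method
#' @noRd
rt_derivs.rt_fa <- function(st, th, P, Py) {
  u <- fa_unpack(st, th)
  W <- P * st$Kc
  Se <- indicator_matrix(st$ei, st$ne)
  Tm <- crossprod(Se, W %*% Se)            # ne x ne: env-block sums of P*K
  # Mv[c, j'] = sum_{c' in env j'} K[c,c'] Py[c']
  PyE <- Se * Py                           # n x ne, Py masked by env
  Mv <- st$Kc %*% PyE
  tr <- numeric(rt_npar(st)); S <- matrix(0, st$n, rt_npar(st))
  pos <- 1L
  for (r in seq_len(st$q)) {
    lam <- u$L[, r]
    Tl <- Tm %*% lam                       # ne vector
    Ml <- Mv %*% lam                       # n vector: sum_j' lam_j' Mv[c,j']
    for (j in seq(r, st$ne)) {
      tr[pos] <- 2 * Tl[j]
      S[, pos] <- (st$ei == j) * Ml + lam[st$ei] * Mv[, j]
      pos <- pos + 1L
    }
  }
  if (st$specifics) {
    for (j in seq_len(st$ne)) {
      tr[pos] <- Tm[j, j]
      S[, pos] <- (st$ei == j) * Mv[, j]
      pos <- pos + 1L
    }
  }
  list(tr = tr, S = S)
}
#' @exportS3Method
#' @noRd
rt_constrain.rt_fa <- function(st, th, floor) {
  if (st$specifics) {
    npsi <- st$ne
    i <- seq(length(th) - npsi + 1L, length(th))
    th[i] <- pmax(th[i], 0)
  }
  th
}

# random regression ----------------------------------------------------------
#' @exportS3Method
#' @noRd
rt_setup.rt_rrm <- function(rt, data) {
  g <- as.character(data[[rt$geno]])
  if (!all(g %in% rownames(rt$K)))
    stop("levels of '", rt$geno, "' missing from rownames(K)")
  gi <- match(g, rownames(rt$K))
  rt$gi <- gi
  rt$Kc <- rt$K[gi, gi, drop = FALSE]
  miss <- setdiff(rt$covariates, colnames(data))
  if (length(miss)) stop("covariate columns not in data: ",
                         paste(miss, collapse = ", "))
  Phi <- cbind(`(Intercept)` = 1,
               as.matrix(data[, rt$covariates, drop = FALSE]))
  storage.mode(Phi) <- "double"
  rt$Phi <- Phi
  rt$d <- ncol(Phi)
  rt$n <- length(gi)
  rt
}
#' @exportS3Method
#' @noRd
rt_npar.rt_rrm <- function(st) as.integer((st$d * (st$d + 1L)) %/% 2L)
#' @exportS3Method
#' @noRd
rt_parnames.rt_rrm <- function(st) {
  nm <- colnames(st$Phi)
  out <- character(0)
  for (a in seq_len(st$d)) for (b in a:st$d)
    out <- c(out, paste0("omega(", st$label, ")[", nm[a], ",", nm[b], "]"))
  out
}
omega_unpack <- function(st, th) {
  Om <- matrix(0, st$d, st$d)
  pos <- 1L
  for (a in seq_len(st$d)) for (b in a:st$d) {
    Om[a, b] <- Om[b, a] <- th[pos]; pos <- pos + 1L
  }
  dimnames(Om) <- list(colnames(st$Phi), colnames(st$Phi))
  Om
}
omega_pack <- function(st, Om) {
  th <- numeric(0)
  for (a in seq_len(st$d)) for (b in a:st$d) th <- c(th, Om[a, b])
  th
}
#' @exportS3Method
#' @noRd
rt_init.rt_rrm <- function(st, vshare, resid) {
  # split the share between intercept and slopes; covariates are expected to
  # be standardised so equal slope variances are a neutral start
  kbar <- max(mean(diag(st$Kc)), 1e-8)
  v0 <- vshare / kbar
  Om <- diag(c(0.7 * v0, rep(0.3 * v0 / max(st$d - 1, 1), st$d - 1)), st$d)
  omega_pack(st, Om)
}
#' @exportS3Method
#' @noRd
rt_gamma.rt_rrm <- function(st, th) {
  Om <- omega_unpack(st, th)
  (st$Phi %*% Om %*% t(st$Phi)) * st$Kc
}
#' @exportS3Method
#' @noRd
rt_derivs.rt_rrm <- function(st, th, P, Py) {
  W <- P * st$Kc
  WPhi <- W %*% st$Phi                     # n x d
  Q <- st$Kc %*% (st$Phi * Py)             # n x d : K (phi_a o Py)
  npar <- rt_npar(st)
  tr <- numeric(npar); S <- matrix(0, st$n, npar)
  pos <- 1L
  for (a in seq_len(st$d)) for (b in a:st$d) {
    if (a == b) {
      tr[pos] <- sum(st$Phi[, a] * WPhi[, a])
      S[, pos] <- st$Phi[, a] * Q[, a]
    } else {
      tr[pos] <- 2 * sum(st$Phi[, a] * WPhi[, b])
      S[, pos] <- st$Phi[, a] * Q[, b] + st$Phi[, b] * Q[, a]
    }
    pos <- pos + 1L
  }
  list(tr = tr, S = S)
}
#' @exportS3Method
#' @noRd
rt_constrain.rt_rrm <- function(st, th, floor) {
  Om <- omega_unpack(st, th)
  e <- eigen(Om, symmetric = TRUE)
  if (min(e$values) < 0) {
    ev <- pmax(e$values, 1e-8 * max(sum(abs(e$values)), floor))
    Om <- e$vectors %*% (ev * t(e$vectors))
  }
  omega_pack(st, Om)
}

# small helpers ---------------------------------------------------------------
indicator_matrix <- function(f, q) {
  n <- length(f)
  M <- matrix(0, n, q)
  M[cbind(seq_len(n), f)] <- 1
  M
}
tapply_sum <- function(x, f, q) {
  out <- numeric(q)
  s <- rowsum(x, f)
  out[as.integer(rownames(s))] <- s
  out
}

# ---------------------------------------------------------------------------
# AI-REML
# ---------------------------------------------------------------------------

#' Restricted maximum likelihood for Gaussian linear mixed models
#'
#' Fits \eqn{y = X\beta + \sum_k u_k + e} where each random term contributes a
#' structured covariance ([rt_iid()], [rt_known()], [rt_fa()], [rt_rrm()]) and
#' \eqn{e \sim N(0, \sigma_\epsilon^2\, \mathrm{diag}(1/w))}. Variance
#' parameters are estimated by average-information REML with step-halving:
#' a proposed update is halved until the updated covariance is positive
#' definite and the restricted log-likelihood does not decrease, so the
#' accepted likelihood sequence is monotone. Scale parameters are floored at
#' \code{1e-10 * var(y)} and factor-analytic / unstructured blocks are kept
#' positive semi-definite by eigenvalue projection.
#'
#' @param y numeric response.
#' @param X fixed-effects design matrix (aliased columns are dropped with a
#'   warning).
#' @param data data frame holding the columns referenced by the random terms.
#' @param random list of random-term specifications.
#' @param weights positive residual weights \eqn{w}; the residual variance of
#'   row i is \eqn{\sigma_\epsilon^2 / w_i}. Default all 1.
#' @param fix_resid_scale logical; if TRUE the residual scale is held at 1
#'   (strict known-weights mode), otherwise it is a free parameter.
#' @param init optional named list of starting values per term (and
#'   `resid`); defaults partition the phenotypic variance equally.
#' @param maxit maximum iterations (`maxit = 0` evaluates at `init` without
#'   updating, e.g. to obtain BLUPs at fixed variance parameters).
#' @param tol_l,tol_p convergence tolerances on the relative log-likelihood
#'   change and maximum relative parameter change.
#' @param verbose print the iteration trace.
#' @return an object of class `reml_fit`: fixed effects (`beta`, `beta_cov`),
#'   variance parameters (`theta`, named per term), `logLik`, `converged`,
#'   iteration `trace`, and the pieces needed by [blup_predict()].
#' @export
reml_fit <- function(y, X, data, random, weights = NULL,
                     fix_resid_scale = FALSE, init = NULL,
                     maxit = 200, tol_l = 1e-8, tol_p = 1e-6,
                     verbose = FALSE) {
  y <- as.numeric(y)
  n <- length(y)
  X <- as.matrix(X)
  if (nrow(X) != n) stop("nrow(X) != length(y)")
  if (is.null(weights)) weights <- rep(1, n)
  if (any(!is.finite(weights) | weights <= 0)) stop("weights must be positive")
  if (nrow(data) != n) stop("nrow(data) != length(y)")

  # drop aliased fixed-effect columns (later columns dropped first)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- sort(qrX$pivot[seq_len(qrX$rank)])
    warning("dropping ", ncol(X) - qrX$rank, " aliased fixed-effect column(s): ",
            paste(colnames(X)[setdiff(seq_len(ncol(X)), keep)], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  p <- ncol(X)
  if (n <= p) stop("need n > rank(X)")

  sts <- lapply(random, rt_setup, data = data)
  nterm <- length(sts)
  np_term <- vapply(sts, rt_npar, integer(1))
  free_resid <- !fix_resid_scale
  npar <- sum(np_term) + as.integer(free_resid)

  # starting values
  ols <- stats::lm.fit(X, y)
  vtot <- stats::var(ols$residuals)
  floor_v <- 1e-10 * stats::var(y)
  vshare <- vtot / (nterm + 1)
  # init: optional list(terms = list(...), resid = scalar)
  theta <- vector("list", nterm)
  for (k in seq_len(nterm)) {
    theta[[k]] <- if (!is.null(init$terms) && !is.null(init$terms[[k]]))
      init$terms[[k]] else rt_init(sts[[k]], vshare, ols$residuals)
    if (length(theta[[k]]) != np_term[k]) stop("bad init length for term ", k)
  }
  sig_e <- if (!is.null(init$resid)) init$resid
           else if (fix_resid_scale) 1 else vshare
  rinv_w <- 1 / weights

  build_V <- function(theta, sig_e) {
    V <- diag(sig_e * rinv_w, n)
    for (k in seq_len(nterm)) V <- V + rt_gamma(sts[[k]], theta[[k]])
    V
  }

  eval_at <- function(theta, sig_e) {
    V <- build_V(theta, sig_e)
    R <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    ldV <- 2 * sum(log(diag(R)))
    Vi <- chol2inv(R)
    XtVi <- crossprod(X, Vi)
    C <- XtVi %*% X
    Rc <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(Rc)) return(NULL)
    ldC <- 2 * sum(log(diag(Rc)))
    Ci <- chol2inv(Rc)
    ViX <- t(XtVi)
    P <- Vi - ViX %*% Ci %*% XtVi
    Py <- drop(P %*% y)
    logL <- -0.5 * (ldV + ldC + sum(y * Py))
    list(logL = logL, P = P, Py = Py, Ci = Ci, XtVi = XtVi, Vi = Vi)
  }

  cur <- eval_at(theta, sig_e)
  if (is.null(cur)) stop("starting values give a non-PD covariance")

  pack <- function(theta, sig_e)
    c(unlist(theta), if (free_resid) sig_e)
  unpack <- function(v) {
    th <- vector("list", nterm); pos <- 1L
    for (k in seq_len(nterm)) {
      th[[k]] <- v[pos:(pos + np_term[k] - 1L)]
      pos <- pos + np_term[k]
    }
    se <- if (free_resid) v[pos] else sig_e
    list(theta = th, sig_e = se)
  }
  constrain <- function(th, se) {
    for (k in seq_len(nterm)) th[[k]] <- rt_constrain(sts[[k]], th[[k]], floor_v)
    se <- max(se, if (fix_resid_scale) se else floor_v)
    list(theta = th, sig_e = se)
  }

  is_scale <- c(unlist(lapply(sts, rt_isscale)), if (free_resid) TRUE)

  trace <- data.frame(iter = 0L, logL = cur$logL, step = NA_real_)
  converged <- FALSE
  iter <- 0L
  n_flat <- 0L   # consecutive accepted iterations with a flat likelihood
  while (iter < maxit) {
    iter <- iter + 1L
    # scores and AI matrix
    S <- matrix(0, n, npar); tr <- numeric(npar)
    pos <- 1L
    for (k in seq_len(nterm)) {
      d <- rt_derivs(sts[[k]], theta[[k]], cur$P, cur$Py)
      idx <- pos:(pos + np_term[k] - 1L)
      tr[idx] <- d$tr; S[, idx] <- d$S
      pos <- pos + np_term[k]
    }
    if (free_resid) {
      tr[pos] <- sum(diag(cur$P) * rinv_w)
      S[, pos] <- rinv_w * cur$Py
    }
    score <- -0.5 * (tr - drop(crossprod(S, cur$Py)))
    PS <- cur$P %*% S
    AI <- 0.5 * crossprod(S, PS)

    # freeze non-negative scale parameters pinned at the floor whose score
    # pushes them further out of the feasible region
    old <- pack(theta, sig_e)
    frozen <- is_scale & old <= floor_v * 1.01 & score < 0
    free <- which(!frozen)
    delta <- numeric(npar)
    if (length(free)) {
      A <- AI[free, free, drop = FALSE]
      ridge <- 1e-8 * max(diag(A), 1)
      delta[free] <- tryCatch(
        solve(A + diag(ridge, length(free)), score[free]),
        error = function(e) score[free] / pmax(diag(A), 1))
    }

    step <- 1
    accepted <- FALSE
    for (h in seq_len(30)) {
      cand <- unpack(old + step * delta)
      cand <- constrain(cand$theta, cand$sig_e)
      ev <- eval_at(cand$theta, cand$sig_e)
      if (!is.null(ev) && ev$logL >= cur$logL - 1e-10) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (accepted && step == 1) {
      # the AI step can be systematically short along weakly identified
      # valleys; extend the line search by doubling while it keeps paying
      repeat {
        if (step >= 64) break
        cand2 <- unpack(old + 2 * step * delta)
        cand2 <- constrain(cand2$theta, cand2$sig_e)
        ev2 <- eval_at(cand2$theta, cand2$sig_e)
        if (is.null(ev2) || ev2$logL <= ev$logL + 1e-10) break
        step <- 2 * step; cand <- cand2; ev <- ev2
      }
    }
    if (!accepted) {
      # no improving direction left: treat as converged at a (possibly
      # boundary) stationary point rather than failing
      converged <- TRUE
      break
    }

    dl <- ev$logL - cur$logL
    newv <- pack(cand$theta, cand$sig_e)
    dp <- max(abs(newv - old) / pmax(abs(old), 1e-4 * stats::var(y)))
    theta <- cand$theta; sig_e <- cand$sig_e; cur <- ev
    trace <- rbind(trace, data.frame(iter = iter, logL = cur$logL, step = step))
    if (verbose)
      message(sprintf("it %3d  logL %.6f  step %.3g", iter, cur$logL, step))
    # converged when the restricted likelihood is flat on a (near-)full AI
    # step, when the parameters have stopped moving, or when the likelihood
    # has stayed flat over several consecutive damped steps (a boundary or
    # ridge direction along which logL no longer changes)
    flat <- abs(dl) / (abs(cur$logL) + 1) < tol_l
    n_flat <- if (flat) n_flat + 1L else 0L
    if (flat && (step >= 0.5 || dp < tol_p || n_flat >= 3L)) {
      converged <- TRUE
      break
    }
  }
  if (maxit == 0) converged <- TRUE   # evaluation-only mode

  beta <- drop(cur$Ci %*% (cur$XtVi %*% y))
  names(beta) <- colnames(X)
  names(theta) <- vapply(seq_len(nterm), function(k)
    if (!is.null(names(random)) && nzchar(names(random)[k])) names(random)[k]
    else paste0("term", k), character(1))
  parn <- unlist(lapply(sts, rt_parnames))

  structure(list(beta = beta, beta_cov = cur$Ci, theta = theta,
                 sigma_e = sig_e, par_names = parn,
                 logLik = cur$logL, converged = converged, n_iter = iter,
                 trace = trace, terms = sts, term_names = names(theta),
                 Py = cur$Py, P = cur$P, weights = weights, y = y, X = X),
            class = "reml_fit")
}

#' @exportS3Method
#' @noRd
print.reml_fit <- function(x, ...) {
  cat("AI-REML fit: n =", length(x$y), " logLik =", format(x$logLik),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  for (k in seq_along(x$theta)) {
    cat("  ", x$term_names[k], ": ",
        paste(signif(x$theta[[k]], 4), collapse = ", "), "\n", sep = "")
  }
  cat("   residual scale:", signif(x$sigma_e, 4), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# BLUPs and prediction-error variances
# ---------------------------------------------------------------------------

#' Best linear unbiased predictions for a fitted random term
#'
#' Conditional means of a random term's effects given the data at the REML
#' estimates. For [rt_known()] terms, all levels of `K` are predicted,
#' including unphenotyped ones (information is borrowed through `K`); levels
#' carrying no information shrink to 0. For [rt_fa()] the full genotype x
#' environment matrix of interaction effects is returned; for [rt_rrm()] the
#' genotype x coefficient matrix (intercept and slopes).
#'
#' @param fit a [reml_fit()] object.
#' @param term index or name of the random term.
#' @param pev logical; also return prediction-error variances (supported for
#'   `rt_iid` and `rt_known` terms).
#' @return named vector or matrix of BLUPs; with `pev = TRUE`, a list with
#'   elements `blup` and `pev` (full PEV matrix).
#' @export
blup_predict <- function(fit, term = 1, pev = FALSE) {
  if (is.character(term)) term <- match(term, fit$term_names)
  st <- fit$terms[[term]]
  th <- fit$theta[[term]]
  Py <- fit$Py
  if (inherits(st, "rt_iid")) {
    q <- length(st$levels)
    u <- th * tapply_sum(Py, st$f, q)
    names(u) <- st$levels
    if (!pev) return(u)
    Tm <- indicator_matrix(st$f, q)
    B <- crossprod(Tm, fit$P %*% Tm)
    PEV <- diag(th, q) - th^2 * B
    dimnames(PEV) <- list(st$levels, st$levels)
    return(list(blup = u, pev = PEV))
  }
  if (inherits(st, "rt_known")) {
    obs <- sort(unique(st$gi))
    agg <- rowsum(Py, st$gi)               # ordered by sort(unique(gi))
    u <- th * drop(st$K[, obs, drop = FALSE] %*% agg)
    names(u) <- rownames(st$K)
    if (!pev) return(u)
    f <- match(st$gi, obs)
    Tm <- indicator_matrix(f, length(obs))
    B <- crossprod(Tm, fit$P %*% Tm)
    Kobs <- st$K[, obs, drop = FALSE]
    PEV <- th * st$K - th^2 * Kobs %*% B %*% t(Kobs)
    dimnames(PEV) <- list(rownames(st$K), rownames(st$K))
    return(list(blup = u, pev = PEV))
  }
  if (inherits(st, "rt_fa")) {
    SE <- fa_sigma_e(st, th)
    A <- matrix(0, nrow(st$K), st$ne,
                dimnames = list(rownames(st$K), st$envs))
    agg <- rowsum(cbind(Py), interaction(st$gi, st$ei, drop = TRUE))
    key <- do.call(rbind, strsplit(rownames(agg), ".", fixed = TRUE))
    A[cbind(as.integer(key[, 1]), as.integer(key[, 2]))] <- agg
    GE <- st$K %*% A %*% SE
    dimnames(GE) <- list(rownames(st$K), st$envs)
    if (pev) stop("PEV not implemented for FA terms")
    return(GE)
  }
  if (inherits(st, "rt_rrm")) {
    Om <- omega_unpack(st, th)
    M <- (st$Phi %*% Om) * Py              # n x d
    agg <- rowsum(M, st$gi)
    obs <- as.integer(rownames(agg))
    C <- st$K[, obs, drop = FALSE] %*% agg
    dimnames(C) <- list(rownames(st$K), colnames(st$Phi))
    if (pev) stop("PEV not implemented for random-regression terms")
    return(C)
  }
  stop("unknown term class")
}

#' Estimated environment covariance of a factor-analytic term
#'
#' @param fit a [reml_fit()] object containing an [rt_fa()] term.
#' @param term index or name of the FA term.
#' @return the estimated \eqn{\Sigma_E = \Lambda\Lambda^\top + \Psi}.
#' @export
fa_env_cov <- function(fit, term) {
  if (is.character(term)) term <- match(term, fit$term_names)
  st <- fit$terms[[term]]
  stopifnot(inherits(st, "rt_fa"))
  SE <- fa_sigma_e(st, fit$theta[[term]])
  dimnames(SE) <- list(st$envs, st$envs)
  SE
}

#' Estimated coefficient covariance of a random-regression term
#'
#' @param fit a [reml_fit()] object containing an [rt_rrm()] term.
#' @param term index or name of the term.
#' @return the estimated \eqn{\Omega} ((1 + n_EC) square, symmetric).
#' @export
rrm_omega <- function(fit, term) {
  if (is.character(term)) term <- match(term, fit$term_names)
  st <- fit$terms[[term]]
  stopifnot(inherits(st, "rt_rrm"))
  omega_unpack(st, fit$theta[[term]])
}
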