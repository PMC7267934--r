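#' Sample covariance matrix of a subject table
#'
#' Centers are not modeled: all fitting is done on the covariance matrix,
#' computed with the N - 1 divisor (paired with the (N - 1) chi-square
#' multiplier).  Rows with missing values are dropped listwise with a
#' message.
#'
#' @param table data.frame or matrix of numeric variables (subjects x
#'   variables).
#' @return list with \code{S} (covariance matrix) and \code{N} (rows used).
#' @export
sample_moments <- function(table) {
  x <- as.matrix(as.data.frame(table))
  if (!is.numeric(x)) stop("'table' must be numeric")
  keep <- stats::complete.cases(x)
  if (any(!keep))
    message(sum(!keep), " row(s) removed by listwise deletion")
  x <- x[keep, , drop = FALSE]
  if (nrow(x) <= ncol(x))
    stop("need more observations (", nrow(x), ") than variables (",
         ncol(x), ")")
  S <- stats::cov(x)
  v <- diag(S)
  if (any(v <= 0))
    stop("zero-variance column(s): ",
         paste(colnames(S)[v <= 0], collapse = ", "))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-12 * max(ev))
    warning("sample covariance matrix is (near) singular")
  list(S = S, N = nrow(x))
}

#' Normal-theory maximum-likelihood discrepancy
#'
#' \deqn{F_{ML} = \ln|\Sigma| + tr(S\Sigma^{-1}) - \ln|S| - m}
#' which is nonnegative and zero exactly when \eqn{\Sigma = S}.
#'
#' @param S,Sigma symmetric positive-definite matrices of the same order.
#' @return the discrepancy value.
#' @export
f_ml <- function(S, Sigma) {
  S <- as.matrix(S); Sigma <- as.matrix(Sigma)
  if (!isTRUE(all.equal(dim(S), dim(Sigma))))
    stop("S and Sigma must have the same order")
  Rs <- tryCatch(chol(S), error = function(e) stop("S is not positive definite"))
  Rg <- tryCatch(chol(Sigma),
                 error = function(e) stop("Sigma is not positive definite"))
  Sinv_g <- chol2inv(Rg)
  2 * sum(log(diag(Rg))) + sum(S * Sinv_g) - 2 * sum(log(diag(Rs))) - nrow(S)
}

# Precomputed fitting context: fixed matrices, free-cell index maps and the
# sample-moment pieces, so objective/gradient evaluations avoid per-call
# bookkeeping.
.make_ctx <- function(spec, S) {
  ft <- spec$free_table
  m <- length(spec$indicators); q <- length(spec$predictors)
  n_lat <- length(spec$latents)
  phi <- if (q && spec$phi_mode == "sample")
    S[(m + 1):(m + q), (m + 1):(m + q), drop = FALSE] else NULL
  L0 <- spec$lambda_pattern; L0[is.na(L0)] <- 0
  sel <- function(block) which(ft$block == block)
  cells <- function(k) cbind(ft$row[k], ft$col[k])
  iL <- sel("lambda"); iG <- sel("gamma"); iP <- sel("psi")
  iT <- sel("theta"); iF <- sel("phi")
  ipsi <- cells(iP)
  tot <- m + q
  list(spec = spec, ft = ft, m = m, q = q, n_lat = n_lat, tot = tot,
       S = S, phi = phi,
       logdetS = as.numeric(determinant(S, logarithm = TRUE)$modulus),
       L0 = unname(L0), lg = which(ft$log),
       iL = iL, cL = cells(iL), iG = iG, cG = cells(iG),
       iP = iP, cP = ipsi, cPt = ipsi[, 2:1, drop = FALSE],
       iT = iT, rT = ft$row[iT], iF = iF, cF = cells(iF),
       cFt = cells(iF)[, 2:1, drop = FALSE],
       pen = which(ft$block == "gamma" & ft$penalized),
       yy = seq_len(m), xx = if (q) (m + 1):tot else integer(),
       dyy = (seq_len(m) - 1L) * m + seq_len(m),       # diag idx in m x m
       dSyy = (seq_len(m) - 1L) * tot + seq_len(m),    # diag idx in Sigma
       psi_fixed_diag = spec$identification == "unit_variance")
}

.ctx_nat <- function(ctx, tv) {
  tv[ctx$lg] <- exp(pmin(tv[ctx$lg], 700))
  tv
}

.ctx_matrices <- function(ctx, nat) {
  L <- ctx$L0
  if (length(ctx$iL)) L[ctx$cL] <- nat[ctx$iL]
  G <- matrix(0, ctx$n_lat, ctx$q)
  if (length(ctx$iG)) G[ctx$cG] <- nat[ctx$iG]
  Psi <- diag(1, ctx$n_lat)
  if (length(ctx$iP)) { Psi[ctx$cP] <- nat[ctx$iP]; Psi[ctx$cPt] <- nat[ctx$iP] }
  Th <- numeric(ctx$m); Th[ctx$rT] <- nat[ctx$iT]
  P <- ctx$phi
  if (length(ctx$iF)) {
    P <- matrix(0, ctx$q, ctx$q)
    P[ctx$cF] <- nat[ctx$iF]; P[ctx$cFt] <- nat[ctx$iF]
  }
  list(L = L, G = G, Psi = Psi, Th = Th, P = P)
}

.ctx_sigma <- function(ctx, mats) {
  if (ctx$q) {
    GP <- mats$G %*% mats$P
    B <- GP %*% t(mats$G) + mats$Psi
  } else B <- mats$Psi
  Syy <- mats$L %*% B %*% t(mats$L)
  Syy[ctx$dyy] <- Syy[ctx$dyy] + mats$Th
  if (ctx$q) {
    Syx <- mats$L %*% GP
    Sg <- matrix(0, ctx$tot, ctx$tot)
    Sg[ctx$yy, ctx$yy] <- Syy
    Sg[ctx$yy, ctx$xx] <- Syx
    Sg[ctx$xx, ctx$yy] <- t(Syx)
    Sg[ctx$xx, ctx$xx] <- mats$P
  } else Sg <- Syy
  list(Sigma = Sg, B = B)
}

.f_obj <- function(tv, ctx, big = 1e10) {
  mats <- .ctx_matrices(ctx, .ctx_nat(ctx, tv))
  Sigma <- .ctx_sigma(ctx, mats)$Sigma
  R <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(R)) return(big)
  Sinv <- chol2inv(R)
  2 * sum(log(diag(R))) + sum(ctx$S * Sinv) - ctx$logdetS - nrow(ctx$S)
}

# Objective and gradient in one pass (shared decomposition); used by the
# proximal path optimizer.
.f_objgrad <- function(tv, ctx, big = 1e10) {
  nat <- .ctx_nat(ctx, tv)
  mats <- .ctx_matrices(ctx, nat)
  sg <- .ctx_sigma(ctx, mats)
  R <- tryCatch(chol(sg$Sigma), error = function(e) NULL)
  if (is.null(R)) return(list(F = big, g = rep(0, length(tv))))
  Sinv <- chol2inv(R)
  Fv <- 2 * sum(log(diag(R))) + sum(ctx$S * Sinv) - ctx$logdetS -
    nrow(ctx$S)
  list(F = Fv, g = .f_grad_core(tv, nat, mats, sg, Sinv, ctx))
}

# Analytic gradient of F in the transformed parameterization.
.f_grad <- function(tv, ctx) {
  nat <- .ctx_nat(ctx, tv)
  mats <- .ctx_matrices(ctx, nat)
  sg <- .ctx_sigma(ctx, mats)
  R <- tryCatch(chol(sg$Sigma), error = function(e) NULL)
  if (is.null(R)) return(rep(0, length(tv)))
  Sinv <- chol2inv(R)
  .f_grad_core(tv, nat, mats, sg, Sinv, ctx)
}

.f_grad_core <- function(tv, nat, mats, sg, Sinv, ctx) {
  W <- Sinv - Sinv %*% (ctx$S %*% Sinv)
  m <- ctx$m; q <- ctx$q
  Wyy <- W[1:m, 1:m, drop = FALSE]
  Wyx <- if (q) W[1:m, (m + 1):(m + q), drop = FALSE] else NULL
  L <- mats$L; G <- mats$G; P <- mats$P
  WyyL <- Wyy %*% L
  gL <- 2 * (WyyL %*% sg$B)
  if (q) gL <- gL + 2 * (Wyx %*% P %*% t(G))
  M <- t(L) %*% WyyL
  gPsi <- 2 * M; diag(gPsi) <- diag(M)
  g <- numeric(length(tv))
  if (length(ctx$iL)) g[ctx$iL] <- gL[ctx$cL]
  if (length(ctx$iG)) {
    gG <- 2 * (M %*% G %*% P) + 2 * (t(L) %*% Wyx %*% P)
    g[ctx$iG] <- gG[ctx$cG]
  }
  if (length(ctx$iP)) g[ctx$iP] <- gPsi[ctx$cP]
  g[ctx$iT] <- diag(Wyy)[ctx$rT]
  if (length(ctx$iF)) {
    Wxx <- W[(m + 1):(m + q), (m + 1):(m + q), drop = FALSE]
    M2 <- t(G) %*% M %*% G
    C <- t(Wyx) %*% L %*% G
    gPhi <- 2 * M2 + 2 * (C + t(C)) + 2 * Wxx
    diag(gPhi) <- diag(M2) + 2 * diag(C) + diag(Wxx)
    g[ctx$iF] <- gPhi[ctx$cF]
  }
  g[ctx$lg] <- g[ctx$lg] * nat[ctx$lg]
  g
}

# Quasi-Newton minimization of F with restarts and a final Newton polish,
# so independently converged fits agree to well below the convergence
# tolerance.
.ml_optimize <- function(tv, ctx, tol, maxit) {
  n_iter <- 0L; gnorm <- Inf
  for (round in 1:8) {
    res <- stats::optim(tv, .f_obj, .f_grad, ctx = ctx, method = "BFGS",
                        control = list(maxit = maxit, reltol = 1e-15))
    tv <- res$par
    n_iter <- n_iter + res$counts[1L]
    g_new <- max(abs(.f_grad(tv, ctx)))
    stalled <- round > 1L && g_new >= gnorm * 0.5
    gnorm <- g_new
    if (gnorm < tol * 1e-2 || n_iter >= maxit * 3L ||
        (gnorm < tol && stalled)) break
  }
  if (gnorm < 1e-2) {
    tv <- .newton_polish(tv, ctx)
    gnorm <- max(abs(.f_grad(tv, ctx)))
  }
  list(tv = tv, gnorm = gnorm, n_iter = n_iter, F = .f_obj(tv, ctx))
}

# Indices (in tv) of residual-variance coordinates that collapsed towards
# the boundary: fitted variance below 1% of the observed one.  The log
# parameterization turns the theta = 0 boundary into a spurious stationary
# point, so optimizers restart once with collapsed entries reset.
.collapsed_theta <- function(tv, ctx) {
  obs <- diag(ctx$S)[ctx$rT]
  ctx$iT[exp(pmin(tv[ctx$iT], 700)) < 1e-2 * obs]
}

.reset_collapsed <- function(tv, ctx, idx) {
  obs <- diag(ctx$S)[ctx$rT]
  tv[idx] <- log(0.5 * obs[match(idx, ctx$iT)])
  tv
}

# Newton polish on the smooth objective: a few damped Newton steps using a
# finite-difference Hessian of the analytic gradient, to push the gradient
# norm far below the quasi-Newton stopping level.
.newton_polish <- function(tv, ctx, max_steps = 5L, target = 1e-11) {
  n <- length(tv)
  f0 <- .f_obj(tv, ctx)
  for (s in seq_len(max_steps)) {
    g <- .f_grad(tv, ctx)
    if (max(abs(g)) < target) break
    H <- matrix(0, n, n)
    h <- 1e-5
    for (k in seq_len(n)) {
      e <- numeric(n); e[k] <- h
      H[, k] <- (.f_grad(tv + e, ctx) - .f_grad(tv - e, ctx)) / (2 * h)
    }
    H <- (H + t(H)) / 2
    step <- tryCatch(solve(H + diag(1e-10, n), g), error = function(e) NULL)
    if (is.null(step)) break
    ok <- FALSE
    for (damp in c(1, 0.5, 0.25, 0.1)) {
      f1 <- .f_obj(tv - damp * step, ctx)
      if (f1 <= f0 + 1e-12) { tv <- tv - damp * step; f0 <- f1; ok <- TRUE
                              break }
    }
    if (!ok) break
  }
  tv
}

# Starting values: marker indicators' observed variances split 50/50
# between latent and residual, structural coefficients at zero, free
# loadings scaled by sd ratios.
.start_values <- function(spec, S) {
  ft <- spec$free_table
  m <- length(spec$indicators)
  sds <- sqrt(diag(S)[seq_len(m)])
  marker <- integer(length(spec$latents))
  for (l in seq_along(spec$latents)) {
    in_lat <- which(spec$lambda_pattern[, l] != 0 |
                    is.na(spec$lambda_pattern[, l]))
    marker[l] <- in_lat[1L]
  }
  tv <- numeric(nrow(ft))
  for (k in seq_len(nrow(ft))) {
    i <- ft$row[k]; j <- ft$col[k]
    tv[k] <- switch(ft$block[k],
      lambda = if (spec$identification == "marker")
                 sds[i] / sds[marker[j]] else sqrt(0.5) * sds[i],
      gamma  = 0,
      psi    = if (i == j) log(0.5 * sds[marker[i]]^2)
               else 0.1 * if (spec$identification == "marker")
                 sqrt(0.5 * sds[marker[i]]^2 * 0.5 * sds[marker[j]]^2) else 1,
      theta  = log(0.5 * sds[i]^2),
      phi    = if (i == j) log(S[m + i, m + i]) else S[m + i, m + j])
  }
  tv
}

#' Fit a MIMIC / CFA model by maximum likelihood
#'
#' Quasi-Newton (BFGS) minimization of the ML discrepancy on a transformed
#' parameterization (variances on the log scale, so residual variances stay
#' positive).  Convergence requires the gradient infinity-norm to fall
#' below \code{tol}; non-convergence is reported in the result, not raised.
#'
#' @param S sample covariance over (indicators, predictors); rows/columns
#'   matched by name when dimnames are present, otherwise assumed in spec
#'   order.
#' @param N sample size.
#' @param spec a \code{mimic_spec}.
#' @param data optional raw subject table; when supplied (and df > 0) the
#'   Satorra-Bentler scaling factor is computed from its fourth-order
#'   moments.
#' @param multiplier chi-square convention, \code{"N-1"} (default, Wishart)
#'   or \code{"N"}.
#' @param tol gradient infinity-norm tolerance (default 1e-7).
#' @param maxit iteration cap (default 500).
#' @param start optional transformed start vector (internal use).
#' @return an object of class \code{mimic_fit}: estimates, discrepancy,
#'   chi-square / df / p, RMSEA with 90\% interval, CFI, SRMR, BIC,
#'   indicator R-squared, convergence information.
#' @export
fit_ml <- function(S, N, spec, data = NULL, multiplier = c("N-1", "N"),
                   tol = 1e-7, maxit = 500L, start = NULL) {
  multiplier <- match.arg(multiplier)
  vars <- c(spec$indicators, spec$predictors)
  S <- as.matrix(S)
  if (!is.null(rownames(S))) {
    if (!all(vars %in% rownames(S)))
      stop("S is missing variables: ",
           paste(setdiff(vars, rownames(S)), collapse = ", "))
    S <- S[vars, vars, drop = FALSE]
  } else if (nrow(S) != length(vars)) {
    stop("S has order ", nrow(S), " but the spec names ", length(vars),
         " variables")
  }
  m <- length(spec$indicators); q <- length(spec$predictors)
  ctx <- .make_ctx(spec, S)
  phi <- ctx$phi
  df <- count_df(spec)
  k_free <- count_free_parameters(spec)

  if (length(spec$latents) == 0L) {
    # baseline-type model: closed-form MLE, residual variances = s_ii
    est <- mimic_params(matrix(0, m, 0L), matrix(0, 0L, q),
                        matrix(0, 0L, 0L), diag(S)[1:m], phi)
    Fval <- f_ml(S, implied_moments(spec, est))
    conv <- TRUE; n_iter <- 0L; gnorm <- 0
    tv <- log(diag(S)[1:m])
  } else {
    tv <- if (is.null(start)) .start_values(spec, S) else start
    sol <- .ml_optimize(tv, ctx, tol, maxit)
    # a collapsed residual variance may be a spurious log-scale optimum:
    # retry once with it reset and keep the better fit
    coll <- .collapsed_theta(sol$tv, ctx)
    if (length(coll)) {
      sol2 <- .ml_optimize(.reset_collapsed(sol$tv, ctx, coll), ctx, tol,
                           maxit)
      if (sol2$F < sol$F) sol <- sol2
    }
    tv <- sol$tv; gnorm <- sol$gnorm; n_iter <- sol$n_iter
    conv <- gnorm < tol
    est <- vector_to_params(.ctx_nat(ctx, tv), spec, phi = phi)
    Fval <- .f_obj(tv, ctx)
  }

  Sigma <- implied_moments(spec, est)
  mult <- if (multiplier == "N-1") N - 1 else N
  chisq <- mult * Fval
  p <- if (df > 0) stats::pchisq(chisq, df, lower.tail = FALSE) else NA_real_
  rms <- if (df > 0) rmsea(chisq, df, N, multiplier = multiplier)
         else c(point = NA, lo = NA, hi = NA)
  base <- .baseline_fit(S, N, spec, multiplier)
  cfi_v <- cfi(chisq, df, base$chisq, base$df)
  srmr_v <- srmr(S, Sigma, n_fixed_x = q)
  p_tot <- m + q
  loglik <- -(N / 2) * (p_tot * log(2 * pi) +
                        as.numeric(determinant(Sigma, TRUE)$modulus) +
                        sum(S * solve(Sigma)))
  bic_v <- if (conv) bic(loglik, k_free, N) else NA_real_
  # residual variance within 1% of zero marks a boundary (Heywood) solution
  theta_rel <- est$theta / diag(Sigma)[1:m]
  heywood <- any(theta_rel < 1e-2)
  fit <- structure(
    list(estimates = est, spec_labels = spec$free_table$label,
         theta_vec = if (length(spec$latents)) {
           nat <- tv; nat[spec$free_table$log] <- exp(nat[spec$free_table$log])
           nat
         } else exp(tv),
         f_ml = Fval, loglik = loglik, chi_square = chisq, df = df,
         p_value = p, rmsea = rms, cfi = cfi_v, srmr = srmr_v, bic = bic_v,
         sb_c = NA_real_, r_squared = r_squared_internal(est, Sigma, spec),
         converged = conv, n_iter = as.integer(n_iter), grad_norm = gnorm,
         heywood = heywood, N = N, S = S, multiplier = multiplier,
         baseline = base),
    class = "mimic_fit")
  if (!is.null(data) && df > 0)
    fit$sb_c <- satorra_bentler_c(data, fit, spec)
  fit
}

# Independence baseline: indicators mutually uncorrelated (free variances),
# uncorrelated with the predictors; predictor block untouched (fixed).
.baseline_fit <- function(S, N, spec, multiplier) {
  m <- length(spec$indicators); q <- length(spec$predictors)
  Sigma_b <- S
  Sigma_b[1:m, ] <- 0; Sigma_b[, 1:m] <- 0
  diag(Sigma_b)[1:m] <- diag(S)[1:m]
  Fb <- f_ml(S, Sigma_b)
  df_b <- m * (m + 1) / 2 + m * q - m
  mult <- if (multiplier == "N-1") N - 1 else N
  list(chisq = mult * Fb, df = df_b, f_ml = Fb)
}

#' @rdname fit_ml
#' @param fit a \code{mimic_fit} (for \code{baseline_model}, a
#'   \code{mimic_spec}).
#' @details \code{baseline_model(spec)} returns the independence baseline
#'   specification used by the CFI: all indicators mutually uncorrelated
#'   (only residual variances free), predictors untouched.
#' @export
baseline_model <- function(spec) {
  m <- length(spec$indicators)
  base <- structure(
    list(indicators = spec$indicators, predictors = spec$predictors,
         latents = character(0),
         lambda_pattern = matrix(0, m, 0L,
                                 dimnames = list(spec$indicators, NULL)),
         gamma_pattern = matrix(NA_real_, 0L, length(spec$predictors)),
         penalized = matrix(FALSE, 0L, length(spec$predictors)),
         identification = spec$identification, phi_mode = spec$phi_mode),
    class = "mimic_spec")
  base$free_table <- do.call(rbind, lapply(seq_len(m), function(i)
    data.frame(block = "theta", row = i, col = i, penalized = FALSE,
               log = TRUE, label = paste0("var(e.", spec$indicators[i], ")"))))
  base
}

#' Chi-square statistic and p value
#'
#' \code{chi_square} scales the ML discrepancy by (N - 1) (classic Wishart
#' convention; \code{multiplier = "N"} gives the alternative), and
#' \code{p_value} refers it to the central chi-square upper tail.
#'
#' @param F discrepancy value from [f_ml()].
#' @param N sample size.
#' @param multiplier \code{"N-1"} or \code{"N"}.
#' @return the statistic / p value.
#' @export
chi_square <- function(F, N, multiplier = c("N-1", "N")) {
  multiplier <- match.arg(multiplier)
  (if (multiplier == "N-1") N - 1 else N) * F
}

#' @rdname chi_square
#' @param chisq chi-square statistic.
#' @param df degrees of freedom.
#' @export
p_value <- function(chisq, df) stats::pchisq(chisq, df, lower.tail = FALSE)

#' Root mean square error of approximation with confidence interval
#'
#' Point estimate \eqn{\sqrt{\max(\chi^2 - df, 0) / (df (N-1))}}; interval
#' endpoints solve the noncentral chi-square coverage equations
#' \eqn{P(\chi^2_{df}(\delta) \le \chi^2) = (1+level)/2} (lower) and
#' \eqn{(1-level)/2} (upper), truncated at zero.
#'
#' @param chisq,df,N statistic, degrees of freedom, sample size.
#' @param level interval coverage (default 0.90).
#' @param multiplier convention for the denominator, matching the
#'   chi-square multiplier.
#' @return named vector (point, lo, hi).
#' @export
rmsea <- function(chisq, df, N, level = 0.90, multiplier = c("N-1", "N")) {
  multiplier <- match.arg(multiplier)
  if (df <= 0) stop("RMSEA is undefined for df = 0")
  n_eff <- if (multiplier == "N-1") N - 1 else N
  point <- sqrt(max(chisq - df, 0) / (df * n_eff))
  ncp_for <- function(target) {
    # largest ncp with pchisq(chisq, df, ncp) >= target is the solution of
    # pchisq(chisq, df, ncp) == target (pchisq decreasing in ncp)
    if (stats::pchisq(chisq, df, ncp = 0) < target) return(0)
    upper <- max(chisq * 2, df * 2, 10)
    while (stats::pchisq(chisq, df, ncp = upper) > target) upper <- upper * 2
    stats::uniroot(function(nc) stats::pchisq(chisq, df, ncp = nc) - target,
                   c(0, upper), tol = 1e-10)$root
  }
  lo <- sqrt(ncp_for((1 + level) / 2) / (df * n_eff))
  hi <- sqrt(ncp_for((1 - level) / 2) / (df * n_eff))
  c(point = point, lo = lo, hi = hi)
}

#' Comparative fit index
#'
#' \eqn{CFI = 1 - \max(\chi^2 - df, 0) / \max(\chi^2_b - df_b,
#' \chi^2 - df, 0)} against the independence baseline.
#'
#' @param chisq,df model statistic and df.
#' @param chisq_base,df_base baseline statistic and df.
#' @return value in [0, 1].
#' @export
cfi <- function(chisq, df, chisq_base, df_base) {
  num <- max(chisq - df, 0)
  den <- max(chisq_base - df_base, chisq - df, 0)
  if (den == 0) return(1)
  1 - num / den
}

#' Standardized root mean square residual
#'
#' Root mean square of the standardized residuals
#' \eqn{s_{ij}/\sqrt{s_{ii}s_{jj}} - \sigma_{ij}/\sqrt{\sigma_{ii}\sigma_{jj}}}
#' over the lower triangle including the diagonal.  When the last
#' \code{n_fixed_x} variables are exogenous predictors fixed at their sample
#' covariance, their within-block (zero) residuals are excluded.
#'
#' @param S,Sigma sample and implied covariance matrices.
#' @param n_fixed_x number of trailing fixed exogenous variables.
#' @return the SRMR value.
#' @export
srmr <- function(S, Sigma, n_fixed_x = 0) {
  S <- as.matrix(S); Sigma <- as.matrix(Sigma)
  p <- nrow(S); m <- p - n_fixed_x
  Rs <- S / sqrt(tcrossprod(diag(S)))
  Rg <- Sigma / sqrt(tcrossprod(diag(Sigma)))
  resid <- Rs - Rg
  idx <- which(lower.tri(resid, diag = TRUE), arr.ind = TRUE)
  keep <- idx[, "col"] <= m          # drop the fixed x-x block
  sqrt(mean(resid[idx[keep, , drop = FALSE]]^2))
}

#' Bayesian information criterion
#'
#' \eqn{BIC = -2 \log L + k \log N}, with the full multivariate-normal
#' log-likelihood (constants included); the best model attains the lowest
#' value.
#'
#' @param loglik log-likelihood at the estimate.
#' @param k_free number of free parameters.
#' @param N sample size.
#' @return the BIC value.
#' @export
bic <- function(loglik, k_free, N) -2 * loglik + k_free * log(N)

#' Satorra-Bentler scaling factor
#'
#' Kurtosis-based correction constant for the ML chi-square under
#' non-normality: \eqn{c = tr(U \Gamma_N) / df} with \eqn{\Gamma_N} the
#' empirical asymptotic covariance of the half-vectorized sample covariance,
#' \eqn{W = \frac12 D'(\hat\Sigma^{-1} \otimes \hat\Sigma^{-1}) D} (D the
#' duplication matrix), \eqn{\Delta = \partial vech(\Sigma)/\partial\theta}
#' at the estimate, and \eqn{U = W - W\Delta(\Delta'W\Delta)^{-1}\Delta'W}.
#' Values near 1 indicate multivariate normality; excess kurtosis pushes c
#' above 1.
#'
#' @param data raw subject table (fourth-order moments are needed).
#' @param fit a converged \code{mimic_fit}.
#' @param spec the \code{mimic_spec} that was fitted.
#' @return the scaling factor.
#' @export
satorra_bentler_c <- function(data, fit, spec) {
  if (fit$df <= 0) stop("Satorra-Bentler factor is undefined for df = 0")
  vars <- c(spec$indicators, spec$predictors)
  x <- as.matrix(as.data.frame(data)[, vars, drop = FALSE])
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x); p <- ncol(x)
  xc <- scale(x, center = TRUE, scale = FALSE)
  vech_idx <- which(lower.tri(diag(p), diag = TRUE))
  # d_i = vech(x_i x_i') - mean  -> Gamma_N = empirical covariance
  dmat <- t(apply(xc, 1L, function(z) tcrossprod(z)[vech_idx]))
  dbar <- colMeans(dmat)
  Gamma_N <- crossprod(sweep(dmat, 2L, dbar)) / n
  Sigma <- implied_moments(spec, fit$estimates)
  Sinv <- solve(Sigma)
  D <- duplication_matrix(p)
  W <- 0.5 * t(D) %*% (Sinv %x% Sinv) %*% D
  jac <- implied_moments_jacobian(spec, fit$estimates, include_phi = TRUE)
  Delta <- vapply(jac, function(M) M[vech_idx], numeric(length(vech_idx)))
  WD <- W %*% Delta
  H <- crossprod(Delta, WD)
  Hc <- tryCatch(chol(H), error = function(e)
    stop("singular Delta' W Delta; model not locally identified"))
  U <- W - WD %*% chol2inv(Hc) %*% t(WD)
  sum(U * t(Gamma_N)) / fit$df
}

# Duplication matrix: vec(A) = D vech(A) for symmetric A of order p.
duplication_matrix <- function(p) {
  pos <- matrix(0L, p, p)
  pos[lower.tri(pos, diag = TRUE)] <- seq_len(p * (p + 1) / 2)
  pos <- pos + t(pos) - diag(diag(pos))
  D <- matrix(0, p * p, p * (p + 1) / 2)
  D[cbind(seq_len(p * p), as.vector(pos))] <- 1
  D
}

r_squared_internal <- function(est, Sigma, spec) {
  m <- length(spec$indicators)
  out <- 1 - est$theta / diag(Sigma)[1:m]
  names(out) <- spec$indicators
  out
}

#' Indicator R-squared
#'
#' Proportion of each indicator's implied variance explained by its latent
#' variable: \eqn{1 - \Theta_{ii} / \hat\Sigma_{ii}}.
#'
#' @param fit a \code{mimic_fit}.
#' @param spec the fitted \code{mimic_spec}.
#' @return named vector over indicators.
#' @export
r_squared <- function(fit, spec) {
  r_squared_internal(fit$estimates, implied_moments(spec, fit$estimates),
                     spec)
}

#' Fit a model to raw data
#'
#' Convenience wrapper: [sample_moments()] then [fit_ml()], computing the
#' Satorra-Bentler factor from the raw table when df > 0.
#'
#' @param data subject table containing the spec's indicators and
#'   predictors.
#' @param spec a \code{mimic_spec}.
#' @param ... passed to [fit_ml()].
#' @return a \code{mimic_fit}.
#' @export
fit_mimic <- function(data, spec, ...) {
  vars <- c(spec$indicators, spec$predictors)
  miss <- setdiff(vars, colnames(as.data.frame(data)))
  if (length(miss))
    stop("data is missing variables: ", paste(miss, collapse = ", "))
  sm <- sample_moments(as.data.frame(data)[, vars, drop = FALSE])
  fit_ml(sm$S, sm$N, spec, data = data, ...)
}

#' @export
print.mimic_fit <- function(x, digits = 3, ...) {
  cat("MIMIC/CFA maximum-likelihood fit",
      if (!x$converged) "(NOT converged)" else "", "\n")
  cat(sprintf("  chi-square = %.3f, df = %d, p = %.3f\n",
              x$chi_square, x$df, x$p_value))
  if (!is.na(x$rmsea["point"]))
    cat(sprintf("  RMSEA = %.3f (%.3f-%.3f)\n",
                x$rmsea["point"], x$rmsea["lo"], x$rmsea["hi"]))
  cat(sprintf("  CFI = %.3f, SRMR = %.3f, BIC = %.3f\n",
              x$cfi, x$srmr, x$bic))
  if (!is.na(x$sb_c))
    cat(sprintf("  Satorra-Bentler scaling factor = %.3f\n", x$sb_c))
  cat("  R-squared:",
      paste(sprintf("%s %.3f", names(x$r_squared), x$r_squared),
            collapse = ", "), "\n")
  if (x$heywood) cat("  WARNING: Heywood case (residual variance at zero)\n")
  invisible(x)
}
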