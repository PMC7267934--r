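#' Elastic-net path configuration
#'
#' @param lambda penalty grid; default 35 equally spaced values from 0 to
#'   0.35, matching the study design.  Must be sorted ascending and start
#'   at 0.
#' @param alpha mixing weight in [0, 1]: \code{alpha = 1} is pure lasso,
#'   \code{alpha = 0} pure ridge; default 0.5 (equal proportion).
#' @param sparsify_tol penalized estimates with absolute value below this
#'   threshold are reported as exactly zero after convergence (default
#'   1e-3).
#' @param tol stationarity tolerance for the penalized optimizer.
#' @param max_outer cap on the alternating optimization rounds per grid
#'   point.
#' @return an object of class \code{reg_config}.
#' @export
reg_config <- function(lambda = seq(0, 0.35, length.out = 35), alpha = 0.5,
                       sparsify_tol = 1e-3, tol = 1e-7, max_outer = 200L) {
  if (any(lambda < 0)) stop("lambda values must be nonnegative")
  if (is.unsorted(lambda)) stop("lambda grid must be sorted ascending")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  structure(list(lambda = lambda, alpha = alpha,
                 sparsify_tol = sparsify_tol, tol = tol,
                 max_outer = as.integer(max_outer)),
            class = "reg_config")
}

#' Elastic-net penalized discrepancy
#'
#' \eqn{F_{ML}(S, \Sigma(\theta)) + \lambda \sum_{j \in pen}
#' (\alpha |\theta_j| + (1-\alpha)\theta_j^2)} over the penalized structural
#' coefficients flagged in the specification.
#'
#' @param params a \code{mimic_params}.
#' @param S sample covariance (spec variable order).
#' @param lambda penalty value (nonnegative).
#' @param config a \code{reg_config} (only \code{alpha} is used).
#' @param spec the \code{mimic_spec}.
#' @return objective value.
#' @export
penalized_objective <- function(params, S, lambda, config, spec) {
  if (lambda < 0) stop("lambda must be nonnegative")
  Fv <- f_ml(S, implied_moments(spec, params))
  ft <- spec$free_table
  pen <- ft$block == "gamma" & ft$penalized
  g <- params_to_vector(params, spec)[pen]
  Fv + lambda * sum(config$alpha * abs(g) + (1 - config$alpha) * g^2)
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

# One penalized fit at a fixed lambda: alternate BFGS over the smooth
# (non-penalized) coordinates with FISTA proximal-gradient steps over the
# penalized structural coefficients, until joint stationarity.
.fit_one_lambda <- function(tv, ctx, lambda, alpha, tol, max_outer,
                            rescue = TRUE) {
  pen <- ctx$pen
  smo <- setdiff(seq_along(tv), pen)
  lam1 <- lambda * alpha          # l1 weight
  lam2 <- lambda * (1 - alpha)    # ridge weight
  Lip <- 1                        # running Lipschitz estimate for FISTA

  obj <- function(v) .f_obj(v, ctx) +
    lam1 * sum(abs(v[pen])) + lam2 * sum(v[pen]^2)
  stationarity <- function(v) {
    g <- .f_grad(v, ctx)
    g[pen] <- g[pen] + 2 * lam2 * v[pen]
    r <- abs(g[smo])
    gp <- g[pen]; x <- v[pen]
    rp <- ifelse(x != 0, abs(gp + lam1 * sign(x)), pmax(abs(gp) - lam1, 0))
    max(c(r, rp, 0))
  }

  n_iter <- 0L
  fy_v <- function(gv) { v <- tv; v[pen] <- gv
    .f_obj(v, ctx) + lam2 * sum(gv^2) }
  fg_v <- function(gv) { v <- tv; v[pen] <- gv
    og <- .f_objgrad(v, ctx)
    list(F = og$F + lam2 * sum(gv^2), g = og$g[pen] + 2 * lam2 * gv) }
  for (outer in seq_len(max_outer)) {
    # (1) joint quasi-Newton over the smooth block plus the active
    # (nonzero, fixed-sign) penalized coordinates; the l1 term is linear
    # on a fixed orthant, so the surrogate is smooth there.  Running this
    # before the proximal pass keeps cold starts on the same trajectory as
    # a plain ML fit (structural coefficients enter only once the
    # measurement block is fitted).
    act <- pen[tv[pen] != 0]
    sgn <- sign(tv[act])
    free <- c(smo, act)
    na <- length(act); ns <- length(smo)
    fn_j <- function(vs) {
      v <- tv; v[free] <- vs
      a <- v[act]
      .f_obj(v, ctx) + lam1 * sum(sgn * a) + lam2 * sum(a^2)
    }
    gr_j <- function(vs) {
      v <- tv; v[free] <- vs
      g <- .f_grad(v, ctx)[free]
      if (na) g[ns + seq_len(na)] <- g[ns + seq_len(na)] + lam1 * sgn +
          2 * lam2 * v[act]
      g
    }
    rs <- stats::optim(tv[free], fn_j, gr_j, method = "BFGS",
                       control = list(maxit = 150L, reltol = 1e-15))
    vs <- rs$par
    # coordinates that crossed the orthant boundary fall back to zero;
    # the next proximal pass re-examines them
    if (na) {
      a <- vs[ns + seq_len(na)]
      a[sign(a) != sgn & a != 0] <- 0
      vs[ns + seq_len(na)] <- a
    }
    tv[free] <- vs
    n_iter <- n_iter + rs$counts[1L]
    # (2) FISTA over the penalized block: progress + support identification
    if (length(pen)) {
      g_cur <- tv[pen]; y <- g_cur; tk <- 1
      for (it in seq_len(60L)) {
        fg <- fg_v(y); fy <- fg$F; gy <- fg$g
        repeat {
          g_new <- soft_threshold(y - gy / Lip, lam1 / Lip)
          dlt <- g_new - y
          if (fy_v(g_new) <= fy + sum(gy * dlt) + Lip / 2 * sum(dlt^2) +
              1e-14) break
          Lip <- Lip * 2
          if (Lip > 1e12) break
        }
        t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
        y <- g_new + ((tk - 1) / t_new) * (g_new - g_cur)
        moved <- max(abs(g_new - g_cur))
        g_cur <- g_new; tk <- t_new
        n_iter <- n_iter + 1L
        Lip <- max(Lip * 0.9, 1e-4)
        if (moved < 1e-11 && it > 2L) break
      }
      tv[pen] <- g_cur
    }
    res <- stationarity(tv)
    if (res < tol) break
  }
  # spurious boundary optimum of the log-variance parameterization: retry
  # once from a start with the collapsed residual variance reset
  coll <- .collapsed_theta(tv, ctx)
  if (rescue && length(coll)) {
    alt <- .fit_one_lambda(.reset_collapsed(tv, ctx, coll), ctx, lambda,
                           alpha, tol, max_outer, rescue = FALSE)
    if (alt$objective < obj(tv)) {
      alt$n_iter <- alt$n_iter + n_iter
      return(alt)
    }
  }
  list(tv = tv, stationarity = stationarity(tv), n_iter = n_iter,
       converged = stationarity(tv) < tol, objective = obj(tv))
}

# Unpenalized ML refit of a sparsified model: the penalized coordinates in
# `zero_idx_pen` (positions within ctx$pen) are frozen at 0, everything
# else is free.
.refit_support <- function(tv, ctx, zero_idx_pen) {
  frozen <- ctx$pen[zero_idx_pen]
  free <- setdiff(seq_along(tv), frozen)
  tv[frozen] <- 0
  fn <- function(v) { w <- tv; w[free] <- v; .f_obj(w, ctx) }
  gr <- function(v) { w <- tv; w[free] <- v; .f_grad(w, ctx)[free] }
  run <- function(v0) {
    res <- stats::optim(v0, fn, gr, method = "BFGS",
                        control = list(maxit = 500L, reltol = 1e-14))
    res$par
  }
  tv[free] <- run(tv[free])
  coll <- .collapsed_theta(tv, ctx)
  if (length(coll)) {
    tv2 <- tv
    tv2[free] <- run(.reset_collapsed(tv, ctx, coll)[free])
    if (.f_obj(tv2, ctx) < .f_obj(tv, ctx)) tv <- tv2
  }
  list(tv = tv, F = .f_obj(tv, ctx))
}

#' Fit the elastic-net regularization path
#'
#' Fits the penalized model at every value of the lambda grid with warm
#' starts, sparsifies converged penalized estimates below
#' \code{sparsify_tol} to exact zeros, and scores every grid point with the
#' regularized BIC \eqn{(N-1) F_{ML} + k \log N}, where k counts the free
#' non-penalized parameters plus the surviving penalized ones and
#' \eqn{F_{ML}} is the discrepancy of the sparsified model refit by
#' unpenalized ML with its zero pattern held fixed (a relaxed fit) — so
#' model selection scores the structure each lambda proposes rather than
#' the shrinkage it applied.
#'
#' Because the penalty is not scale-invariant, inputs are standardized
#' internally before path fitting: by default the predictors (the causes of
#' the MIMIC model), so penalized coefficients are on the scale of
#' standardized predictors and marker-identified latents;
#' \code{standardize = "all"} also standardizes the indicators.  Estimates
#' are reported on both the fitting and the original scale.
#'
#' @param x subject table (data.frame/matrix) or a list with elements
#'   \code{S} (covariance) and \code{N}.
#' @param spec a \code{mimic_spec} with penalized structural edges.
#' @param config a \code{reg_config}.
#' @param standardize \code{"predictors"} (default) or \code{"all"}.
#' @return an object of class \code{mimic_path}: per-lambda entries
#'   (estimates on both scales, penalized coefficient vector, n_nonzero,
#'   F, bic_reg, convergence), the selected index and selected edge list.
#' @export
fit_path <- function(x, spec, config = reg_config(),
                     standardize = c("predictors", "all")) {
  standardize <- match.arg(standardize)
  if (is.list(x) && !is.data.frame(x) && !is.null(x$S)) {
    S_raw <- as.matrix(x$S); N <- x$N
  } else {
    sm <- sample_moments(as.data.frame(x)[, c(spec$indicators,
                                              spec$predictors),
                                          drop = FALSE])
    S_raw <- sm$S; N <- sm$N
  }
  vars <- c(spec$indicators, spec$predictors)
  if (!is.null(rownames(S_raw))) S_raw <- S_raw[vars, vars]
  sds <- sqrt(diag(S_raw))
  if (standardize == "predictors")
    sds[seq_along(spec$indicators)] <- 1
  S <- S_raw / tcrossprod(sds)
  ctx <- .make_ctx(spec, S)
  phi <- ctx$phi
  ft <- spec$free_table
  pen <- ctx$pen

  tv <- .start_values(spec, S)
  entries <- vector("list", length(config$lambda))
  refit_cache <- new.env(parent = emptyenv())
  for (i in seq_along(config$lambda)) {
    lam <- config$lambda[i]
    # the unpenalized endpoint is polished harder so it reproduces a plain
    # ML fit to high accuracy
    sol <- .fit_one_lambda(tv, ctx, lam, config$alpha,
                           if (lam == 0) config$tol * 1e-2 else config$tol,
                           config$max_outer)
    tv <- sol$tv
    if (lam == 0 && sol$stationarity < 1e-2)
      tv <- .newton_polish(tv, ctx)
    tvs <- tv
    tvs[pen][abs(tvs[pen]) < config$sparsify_tol] <- 0
    nat <- .ctx_nat(ctx, tvs)
    est <- vector_to_params(nat, spec, phi = phi)
    Fs <- .f_obj(tvs, ctx)
    coef <- nat[pen]; names(coef) <- ft$label[pen]
    n_nonzero <- sum(coef != 0)
    k <- (nrow(ft) - length(pen)) + n_nonzero
    # regularized BIC: discrepancy of the sparsified model refit by
    # unpenalized ML with the zero pattern held fixed (relaxed fit), so the
    # criterion scores the selected structure, not the shrinkage
    key <- paste0("s", paste(which(coef != 0), collapse = ","))
    if (is.null(refit_cache[[key]])) {
      rf <- .refit_support(tvs, ctx, which(coef == 0))
      refit_cache[[key]] <- rf
    }
    rf <- refit_cache[[key]]
    entries[[i]] <- list(
      lambda = lam, estimates = est,
      estimates_raw = rescale_params(est, sds, spec),
      coef = coef, n_nonzero = n_nonzero, f_ml = Fs,
      f_ml_refit = rf$F, estimates_refit = vector_to_params(
        .ctx_nat(ctx, rf$tv), spec, phi = phi),
      bic_reg = (N - 1) * rf$F + k * log(N),
      converged = sol$stationarity < config$tol,
      stationarity = sol$stationarity,
      objective = sol$objective)
  }
  path <- structure(list(entries = entries, lambda = config$lambda,
                         spec = spec, config = config, N = N, sds = sds,
                         S_std = S),
                    class = "mimic_path")
  sel <- select_model(path, N)
  path$selected_index <- sel$index
  path$selected_edges <- sel$edges
  path
}

# Back-transform standardized-scale estimates to the original variable
# scales.  With marker identification the latent inherits its marker's
# scale; with unit-variance identification the latent stays standardized.
rescale_params <- function(est, sds, spec) {
  m <- length(spec$indicators); q <- length(spec$predictors)
  s_y <- sds[seq_len(m)]; s_x <- if (q) sds[m + seq_len(q)] else numeric()
  if (spec$identification == "marker") {
    s_lat <- vapply(seq_along(spec$latents), function(l) {
      in_lat <- which(spec$lambda_pattern[, l] != 0 |
                      is.na(spec$lambda_pattern[, l]))
      s_y[in_lat[1L]]
    }, numeric(1))
  } else s_lat <- rep(1, length(spec$latents))
  L <- est$lambda * outer(s_y, 1 / s_lat)
  G <- if (q) est$gamma * outer(s_lat, 1 / s_x) else est$gamma
  Psi <- est$psi * tcrossprod(s_lat)
  Theta <- est$theta * s_y^2
  Phi <- if (q) est$phi * tcrossprod(s_x) else NULL
  mimic_params(L, G, Psi, Theta, Phi)
}

#' Select the model along a fitted path
#'
#' Returns the grid entry attaining the lowest regularized BIC; ties are
#' broken towards the largest lambda (the sparser model).
#'
#' @param path a \code{mimic_path}.
#' @param N sample size (defaults to the one stored in the path).
#' @return list with \code{index}, \code{entry}, and \code{edges}: a
#'   data.frame (predictor, latent, coefficient) of the surviving
#'   structural edges at the selected lambda, on the standardized scale.
#' @export
select_model <- function(path, N = path$N) {
  bics <- vapply(path$entries, `[[`, numeric(1), "bic_reg")
  idx <- max(which(bics <= min(bics) + 1e-12))
  entry <- path$entries[[idx]]
  coef <- entry$coef[entry$coef != 0]
  edges <- if (length(coef)) {
    parts <- strsplit(names(coef), "->", fixed = TRUE)
    data.frame(predictor = vapply(parts, `[[`, "", 1L),
               latent = vapply(parts, `[[`, "", 2L),
               coefficient = unname(coef))
  } else data.frame(predictor = character(), latent = character(),
                    coefficient = numeric())
  list(index = idx, entry = entry, edges = edges)
}

#' Export coefficient trajectories
#'
#' One row per lambda, one column per penalized coefficient (standardized
#' scale) plus the regularized BIC: the data behind the classic trajectory
#' plot.
#'
#' @param path a \code{mimic_path}.
#' @param file optional CSV destination; values are written with 17
#'   significant digits so the table round-trips losslessly.
#' @return data.frame with columns \code{lambda}, one per penalized edge,
#'   and \code{bic_reg}.
#' @export
export_trajectories <- function(path, file = NULL) {
  coefs <- t(vapply(path$entries, `[[`,
                    numeric(length(path$entries[[1]]$coef)), "coef"))
  out <- data.frame(lambda = path$lambda, coefs, check.names = FALSE)
  out$bic_reg <- vapply(path$entries, `[[`, numeric(1), "bic_reg")
  if (!is.null(file)) {
    fmt <- out
    fmt[] <- lapply(out, function(v) sprintf("%.17g", v))
    utils::write.csv(fmt, file, row.names = FALSE, quote = FALSE)
  }
  out
}

#' @export
print.mimic_path <- function(x, ...) {
  cat("Regularized MIMIC path:", length(x$lambda), "lambda values in [",
      min(x$lambda), ",", max(x$lambda), "]\n")
  i <- x$selected_index
  cat(sprintf("  selected lambda = %.4f (regularized BIC = %.3f)\n",
              x$lambda[i], x$entries[[i]]$bic_reg))
  if (nrow(x$selected_edges)) {
    cat("  selected structural edges:\n")
    for (k in seq_len(nrow(x$selected_edges)))
      cat(sprintf("    %s -> %s  (%.3f)\n", x$selected_edges$predictor[k],
                  x$selected_edges$latent[k], x$selected_edges$coefficient[k]))
  } else cat("  no structural edges survive\n")
  invisible(x)
}
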