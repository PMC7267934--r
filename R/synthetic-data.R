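#' Configuration for the subject-table simulator
#'
#' The defaults encode the study conditions the generator emulates: ten
#' exchangeably correlated tract-FA predictors (mean 0.45, sd 0.03,
#' correlation 0.3 — plausible adult-tract values, documented defaults),
#' age drawn from a truncated normal with mean 35.03, sd 10.27 on [18, 69],
#' a sparse structural layer with standardized effects of magnitude 0.3 on
#' the edges age->FI (+), age->CI (-), Fmn->CI (+), SLF->FI (-), and
#' indicator reliabilities calibrated so the population R-squared of
#' PO, PS, VC, WM are 0.856, 0.408, 0.756, 0.483.
#'
#' @param n number of subjects (default 1000).
#' @param true_gamma data.frame(predictor, latent, effect) of standardized
#'   structural effects.
#' @param rho exchangeable correlation of the FA predictors, in
#'   (-1/9, 1).
#' @param fa_mean,fa_sd FA scale of the tract columns.
#' @param age_mean,age_sd,age_range truncated-normal age distribution.
#' @param target_r2 named vector of population indicator R-squared targets
#'   in (0, 1).
#' @param assignment latent -> indicator map (default FI: PO,PS;
#'   CI: VC,WM).
#' @param disturbance_cor correlation of the latent disturbances.
#' @param indicator_scale named list of \code{mean}/\code{sd} vectors used
#'   to put the indicators on the WAIS-III index scale.
#' @return object of class \code{sem_sim_config}.
#' @export
sem_sim_config <- function(
    n = 1000L,
    true_gamma = data.frame(
      predictor = c("age", "age", "Fmn", "SLF"),
      latent = c("FI", "CI", "CI", "FI"),
      effect = c(0.3, -0.3, 0.3, -0.3)),
    rho = 0.3, fa_mean = 0.45, fa_sd = 0.03,
    age_mean = 35.03, age_sd = 10.27, age_range = c(18, 69),
    target_r2 = c(PO = 0.856, PS = 0.408, VC = 0.756, WM = 0.483),
    assignment = list(FI = c("PO", "PS"), CI = c("VC", "WM")),
    disturbance_cor = 0.7,
    indicator_scale = list(
      mean = c(PO = 27.71, PS = 16.63, VC = 29.39, WM = 26.17),
      sd = c(PO = 6.77, PS = 4.97, VC = 7.42, WM = 5.77))) {
  if (n < 10) stop("n must be at least 10")
  if (rho <= -1 / 9 || rho >= 1)
    stop("rho must lie in (-1/9, 1) for a valid exchangeable correlation")
  if (any(target_r2 <= 0) || any(target_r2 >= 1))
    stop("infeasible R-squared targets: must lie strictly in (0, 1)")
  indicators <- unlist(assignment, use.names = FALSE)
  if (!setequal(names(target_r2), indicators))
    stop("target_r2 must name exactly the indicators of 'assignment'")
  structure(list(n = as.integer(n), true_gamma = true_gamma, rho = rho,
                 fa_mean = fa_mean, fa_sd = fa_sd, age_mean = age_mean,
                 age_sd = age_sd, age_range = age_range,
                 target_r2 = target_r2, assignment = assignment,
                 disturbance_cor = disturbance_cor,
                 indicator_scale = indicator_scale),
            class = "sem_sim_config")
}

# sd of a normal(mean, sd) truncated to [lo, hi]
.truncnorm_sd <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd; b <- (hi - mean) / sd
  Z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  sd * sqrt(1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
}

.rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Simulate a study-shaped subject table
#'
#' Draws correlated FA predictors and age, forms latent variables
#' \eqn{\eta = \Gamma x + \zeta} on the standardized scale (unit latent
#' variances), and produces indicators \eqn{y = \Lambda\eta + \epsilon}
#' with loadings and residual variances solved analytically so that each
#' indicator's population R-squared equals its target exactly:
#' \eqn{\lambda_j = \sqrt{R^2_j}}, \eqn{\theta_j = 1 - R^2_j} under unit
#' latent and indicator variances.  Indicators are then affinely rescaled
#' to the WAIS-III index scale (which leaves R-squared untouched).
#'
#' @param config a \code{sem_sim_config}.
#' @param seed integer seed; the generator is a pure function of
#'   (config, seed).
#' @return data.frame with columns subject id, the ten tract FA values,
#'   age, and PO, PS, VC, WM.  Attributes: \code{truth} (the generating
#'   \code{mimic_params} on the standardized scale), \code{latents} (the
#'   drawn latent scores), \code{spec} (the matching \code{mimic_spec}).
#' @export
simulate_subject_table <- function(config = sem_sim_config(), seed = 1L) {
  set.seed(seed)
  n <- config$n
  q_fa <- length(tract_names)
  R_fa <- matrix(config$rho, q_fa, q_fa); diag(R_fa) <- 1
  z_fa <- MASS::mvrnorm(n, mu = rep(0, q_fa), Sigma = R_fa)
  fa <- config$fa_mean + config$fa_sd * z_fa
  colnames(fa) <- tract_names
  age <- .rtruncnorm(n, config$age_mean, config$age_sd,
                     config$age_range[1], config$age_range[2])
  age_pop_mean <- {
    a <- (config$age_range[1] - config$age_mean) / config$age_sd
    b <- (config$age_range[2] - config$age_mean) / config$age_sd
    Z <- stats::pnorm(b) - stats::pnorm(a)
    config$age_mean + config$age_sd * (stats::dnorm(a) - stats::dnorm(b)) / Z
  }
  age_pop_sd <- .truncnorm_sd(config$age_mean, config$age_sd,
                              config$age_range[1], config$age_range[2])
  predictors <- c(tract_names, "age")
  x_std <- cbind(z_fa, (age - age_pop_mean) / age_pop_sd)
  colnames(x_std) <- predictors
  R_x <- diag(q_fa + 1)
  R_x[1:q_fa, 1:q_fa] <- R_fa

  latents <- names(config$assignment)
  G <- matrix(0, length(latents), q_fa + 1,
              dimnames = list(latents, predictors))
  tg <- config$true_gamma
  if (nrow(tg)) for (k in seq_len(nrow(tg))) {
    if (!tg$latent[k] %in% latents || !tg$predictor[k] %in% predictors)
      stop("true_gamma names unknown latent or predictor")
    G[tg$latent[k], tg$predictor[k]] <- tg$effect[k]
  }
  # disturbance covariance giving unit-variance latents with the requested
  # disturbance correlation
  explained <- G %*% R_x %*% t(G)
  zeta_var <- 1 - diag(explained)
  if (any(zeta_var <= 0))
    stop("structural effects explain >= 100% of a latent's variance")
  Psi <- diag(zeta_var, length(latents))
  if (length(latents) > 1)
    for (i in seq_along(latents)) for (j in seq_along(latents))
      if (i != j)
        Psi[i, j] <- config$disturbance_cor * sqrt(zeta_var[i] * zeta_var[j])
  zeta <- MASS::mvrnorm(n, mu = rep(0, length(latents)), Sigma = Psi)
  eta <- x_std %*% t(G) + zeta
  colnames(eta) <- latents

  indicators <- unlist(config$assignment, use.names = FALSE)
  r2 <- config$target_r2[indicators]
  lam <- sqrt(r2); thr <- 1 - r2
  Lam <- matrix(0, length(indicators), length(latents),
                dimnames = list(indicators, latents))
  for (l in seq_along(latents))
    Lam[match(config$assignment[[l]], indicators), l] <-
      lam[config$assignment[[l]]]
  eps <- matrix(stats::rnorm(n * length(indicators)), n) %*%
    diag(sqrt(thr), length(indicators))
  y_std <- eta %*% t(Lam) + eps
  sc <- config$indicator_scale
  y <- sweep(sweep(y_std, 2L, sc$sd[indicators], `*`), 2L,
             sc$mean[indicators], `+`)
  colnames(y) <- indicators

  out <- data.frame(id = sprintf("S%04d", seq_len(n)), fa, age = age, y)
  attr(out, "truth") <- mimic_params(Lam, G, Psi, thr, R_x)
  attr(out, "latents") <- eta
  attr(out, "spec") <- mimic_spec(config$assignment, predictors = predictors)
  out
}

#' Phantom specification
#'
#' Describes a synthetic diffusion-tensor volume: one or more bundles of
#' prolate (cigar-shaped) tensors oriented along a polyline path, embedded
#' in an isotropic background that fails the tracking start criteria.  Two
#' ROI masks per bundle are placed at 25\% and 75\% of arc length.
#'
#' @param shape grid dimensions (nx, ny, nz).
#' @param bundles list of bundle descriptors: each a list with \code{path}
#'   (matrix of voxel-coordinate waypoints), \code{radius} (voxels),
#'   \code{fa}, \code{trace}.
#' @param background_fa,background_trace isotropic background; the default
#'   trace 0.0021 mm^2/s and FA 0 fail both start criteria.
#' @param noise sd of additive Gaussian perturbation on tensor components,
#'   as a fraction of trace/3 (0 = noise-free).
#' @param roi_radius ROI sphere radius in voxels (default bundle radius
#'   + 1).
#' @param allow_crossing set \code{TRUE} to permit bundles overlapping with
#'   incompatible orientations (the later bundle wins in the overlap).
#' @return object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(shape = c(20L, 20L, 20L), bundles = list(),
                         background_fa = 0, background_trace = 0.0021,
                         noise = 0, roi_radius = NULL,
                         allow_crossing = FALSE) {
  stopifnot(length(shape) == 3L, all(shape >= 5L))
  structure(list(shape = as.integer(shape), bundles = bundles,
                 background_fa = background_fa,
                 background_trace = background_trace, noise = noise,
                 roi_radius = roi_radius, allow_crossing = allow_crossing),
            class = "phantom_spec")
}

# Prolate tensor components with exact FA and trace, principal axis along
# the unit vector `axis`: eigenvalues T/3 + 2*delta, T/3 - delta (twice)
# with delta = FA * T / sqrt(27 - 18 FA^2).
prolate_tensor <- function(fa, trace, axis) {
  axis <- axis / sqrt(sum(axis^2))
  delta <- fa * trace / sqrt(27 - 18 * fa^2)
  l1 <- trace / 3 + 2 * delta; l2 <- trace / 3 - delta
  Tm <- l2 * diag(3) + (l1 - l2) * tcrossprod(axis)
  .components_from_tensor(Tm)
}

# Sample a polyline at fine resolution; returns points and unit tangents.
.polyline_points <- function(path, step = 0.2) {
  pts <- NULL; tans <- NULL
  for (s in seq_len(nrow(path) - 1L)) {
    a <- path[s, ]; b <- path[s + 1L, ]
    len <- sqrt(sum((b - a)^2))
    tt <- seq(0, 1, by = step / len)
    seg <- outer(1 - tt, a) + outer(tt, b)
    tan <- (b - a) / len
    pts <- rbind(pts, seg)
    tans <- rbind(tans, matrix(tan, nrow(seg), 3, byrow = TRUE))
  }
  list(points = pts, tangents = tans)
}

#' Build a diffusion-tensor phantom
#'
#' Fills a voxel grid with isotropic background tensors, then paints each
#' bundle: voxels within \code{radius} of the bundle path receive a prolate
#' tensor with the requested FA and trace, oriented along the local path
#' tangent.  ROI masks are placed at 25\% and 75\% of each bundle's arc
#' length, and the ground-truth mTBFA per bundle is recorded before noise.
#'
#' @param spec a \code{phantom_spec}.
#' @param seed seed for the (optional) noise draw.
#' @return list with \code{volume} (a \code{tensor_volume}), \code{fa_map},
#'   \code{rois} (per bundle: list of two logical masks), \code{truth}
#'   (per-bundle noise-free mTBFA), \code{bundle_voxels}.
#' @export
make_dti_phantom <- function(spec, seed = 1L) {
  d <- spec$shape
  n <- prod(d)
  dat <- array(0, c(d, 6L))
  bg <- prolate_tensor(spec$background_fa, spec$background_trace, c(1, 0, 0))
  if (spec$background_fa == 0)
    bg <- .components_from_tensor(diag(spec$background_trace / 3, 3))
  for (k in 1:6) dat[, , , k] <- bg[k]

  centers <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                                   z = seq_len(d[3])))
  owner <- integer(n)            # which bundle painted each voxel
  axis_of <- matrix(NA_real_, n, 3)
  rois <- list(); truth <- numeric(); bundle_voxels <- list()
  for (b in seq_along(spec$bundles)) {
    bd <- spec$bundles[[b]]
    pl <- .polyline_points(as.matrix(bd$path))
    # nearest sampled path point per voxel (coarse but exact enough at
    # step 0.2 voxels)
    idx <- which(vapply(seq_len(n), function(i) {
      dd <- sqrt(colSums((t(pl$points) - centers[i, ])^2))
      min(dd) <= bd$radius
    }, TRUE))
    for (i in idx) {
      dd <- sqrt(colSums((t(pl$points) - centers[i, ])^2))
      j <- which.min(dd)
      tangent <- pl$tangents[j, ]
      if (owner[i] != 0L && !spec$allow_crossing) {
        prev_axis <- axis_of[i, ]
        ang <- acos(min(1, abs(sum(prev_axis * tangent)))) * 180 / pi
        if (ang > 15)
          stop("bundles overlap with incompatible orientations; set ",
               "allow_crossing = TRUE to build a crossing phantom")
      }
      owner[i] <- b
      axis_of[i, ] <- tangent
      vox <- centers[i, ]
      dat[vox[1], vox[2], vox[3], ] <- prolate_tensor(bd$fa, bd$trace,
                                                      tangent)
    }
    bundle_voxels[[b]] <- centers[owner == b, , drop = FALSE]
    truth[b] <- bd$fa
    # ROI masks at 25% / 75% arc length
    arc <- c(0, cumsum(sqrt(rowSums(diff(pl$points)^2))))
    rr <- if (is.null(spec$roi_radius)) bd$radius + 1 else spec$roi_radius
    mk_roi <- function(frac) {
      ctr <- pl$points[which.min(abs(arc - frac * max(arc))), ]
      m <- array(FALSE, d)
      near <- sqrt(colSums((t(centers) - ctr)^2)) <= rr
      m[centers[near, , drop = FALSE]] <- TRUE
      m
    }
    rois[[b]] <- list(mk_roi(0.25), mk_roi(0.75))
  }
  if (spec$noise > 0) {
    set.seed(seed)
    scale <- spec$noise * mean(vapply(spec$bundles, `[[`, numeric(1),
                                      "trace")) / 3
    dat <- dat + array(stats::rnorm(length(dat), sd = scale), dim(dat))
    # re-symmetrization is implicit: components storage is symmetric
  }
  vol <- tensor_volume(dat)
  maps <- tensor_maps(vol)
  attr(vol, "maps") <- maps
  names(truth) <- names(rois) <- names(bundle_voxels) <-
    vapply(seq_along(spec$bundles), function(b) {
      nm <- spec$bundles[[b]]$label
      if (is.null(nm)) paste0("bundle", b) else nm
    }, "")
  list(volume = vol, fa_map = maps$fa, rois = rois, truth = truth,
       bundle_voxels = bundle_voxels)
}

#' Tie the phantoms to the subject table
#'
#' Builds a per-subject phantom for selected tracts whose bundle FA is the
#' subject's simulated tract value, runs brute-force tracking, multi-ROI
#' selection and mTBFA extraction, and replaces those predictor columns of
#' the subject table with the measured values — an end-to-end desk-scale
#' version of the imaging-to-model pipeline with ground truth retained at
#' both levels.
#'
#' @param sem_config a \code{sem_sim_config} (keep \code{n} small: one
#'   phantom is tracked per subject and tract).
#' @param tracts character vector of tract columns to measure via phantoms
#'   (default \code{c("Fmn", "SLF")}).
#' @param shape phantom grid dimensions.
#' @param seed integer seed.
#' @param params a \code{tracking_params}.
#' @return the subject table with measured mTBFA in the selected columns;
#'   attributes \code{injected} (the generated FA values) and
#'   \code{measured}.
#' @export
end_to_end_dataset <- function(sem_config = sem_sim_config(n = 10L),
                               tracts = c("Fmn", "SLF"),
                               shape = c(16L, 16L, 16L), seed = 1L,
                               params = tracking_params()) {
  tab <- simulate_subject_table(sem_config, seed = seed)
  injected <- as.matrix(tab[, tracts, drop = FALSE])
  measured <- injected * NA
  for (s in seq_len(nrow(tab))) for (t in seq_along(tracts)) {
    fa_true <- injected[s, t]
    ps <- phantom_spec(
      shape = shape,
      bundles = list(list(path = rbind(c(2, shape[2] / 2, shape[3] / 2),
                                       c(shape[1] - 1, shape[2] / 2,
                                         shape[3] / 2)),
                          radius = 1.5, fa = fa_true, trace = 0.0012,
                          label = tracts[t])))
    ph <- make_dti_phantom(ps, seed = seed + s)
    sl <- brute_force_tracking(ph$volume, params)
    tr <- select_tract(sl, ph$rois[[1]], label = tracts[t])
    measured[s, t] <- mean_tract_fa(tr, ph$fa_map)
  }
  tab[, tracts] <- measured
  attr(tab, "injected") <- injected
  attr(tab, "measured") <- measured
  tab
}
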