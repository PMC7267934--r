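# Shared model builders and small generators used across the suite.

one_factor_spec <- function() mimic_spec(list(g = wais_indices))

two_factor_spec <- function()
  mimic_spec(list(FI = c("PO", "PS"), CI = c("VC", "WM")))

# Two-correlated-factor indicator data (normal), unit variances.
gen_two_factor <- function(n, seed, lam = c(0.9, 0.6, 0.85, 0.7),
                           psi12 = 0.5) {
  set.seed(seed)
  eta <- MASS::mvrnorm(n, c(0, 0), matrix(c(1, psi12, psi12, 1), 2))
  Lam <- rbind(c(lam[1], 0), c(lam[2], 0), c(0, lam[3]), c(0, lam[4]))
  y <- eta %*% t(Lam) +
    matrix(stats::rnorm(n * 4), n) %*% diag(sqrt(1 - lam^2))
  colnames(y) <- wais_indices
  as.data.frame(y)
}

# One-common-factor normal data.
gen_one_factor <- function(n, seed, lam = c(0.9, 0.6, 0.85, 0.7)) {
  set.seed(seed)
  y <- outer(stats::rnorm(n), lam) +
    matrix(stats::rnorm(n * 4), n) %*% diag(sqrt(1 - lam^2))
  colnames(y) <- wais_indices
  as.data.frame(y)
}

# Elliptical heavy-tailed indicators: one-factor structure scaled by a
# shared chi-square mixing variable (multivariate t with 5 df, unit
# variances).
gen_one_factor_t5 <- function(n, seed, lam = c(0.9, 0.6, 0.85, 0.7)) {
  set.seed(seed)
  z <- outer(stats::rnorm(n), lam) +
    matrix(stats::rnorm(n * 4), n) %*% diag(sqrt(1 - lam^2))
  y <- z / sqrt(stats::rchisq(n, 5) / 5) * sqrt(3 / 5)
  colnames(y) <- wais_indices
  as.data.frame(y)
}

straight_phantom <- function(fa = 0.7, shape = c(20L, 20L, 20L)) {
  make_dti_phantom(phantom_spec(
    shape = shape,
    bundles = list(list(path = rbind(c(2, 10, 10), c(shape[1] - 1, 10, 10)),
                        radius = 1.5, fa = fa, trace = 0.0012,
                        label = "straight"))))
}

arc_phantom <- function(fa = 0.65) {
  th <- seq(0, pi / 2, length.out = 40)
  make_dti_phantom(phantom_spec(
    shape = c(24L, 24L, 24L),
    bundles = list(list(path = cbind(4 + 14 * sin(th), 4 + 14 * cos(th), 12),
                        radius = 1.5, fa = fa, trace = 0.0012,
                        label = "arc"))))
}

crossing_phantom <- function() {
  make_dti_phantom(phantom_spec(
    shape = c(24L, 24L, 24L), allow_crossing = TRUE,
    bundles = list(
      list(path = rbind(c(2, 12, 12), c(14, 12, 12)), radius = 1.5,
           fa = 0.7, trace = 0.0012, label = "along_x"),
      list(path = rbind(c(14, 12, 12), c(14, 23, 12)), radius = 1.5,
           fa = 0.7, trace = 0.0012, label = "along_y"))))
}

# Predictor-standardized sample covariance for a subject table, matching
# the scale fit_path() uses by default.
predictor_std_moments <- function(tab, spec) {
  sm <- sample_moments(tab[, c(spec$indicators, spec$predictors)])
  d <- sqrt(diag(sm$S))
  d[seq_along(spec$indicators)] <- 1
  list(S = sm$S / tcrossprod(d), N = sm$N)
}

edge_labels <- function(edges) sort(paste0(edges$predictor, "->",
                                           edges$latent))

random_rotation <- function() {
  qr_d <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
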