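test_that("sample moments use the N-1 divisor and validate input", {
  toy <- data.frame(a = c(1, 2, 4), b = c(2, 1, 3))
  sm <- sample_moments(toy)
  # hand-computed covariance: means (7/3, 2); cross products (0 + 1/3 +
  # 5/3)/2 = 1
  expect_equal(unname(sm$S),
               rbind(c(7 / 3, 1), c(1, 1)))
  expect_equal(sm$N, 3L)
  expect_warning(sample_moments(data.frame(a = c(1, 2, 3, 4),
                                           b = c(1, 2, 3, 4) * 2,
                                           c = c(0, 1, 5, 2))),
                 "singular")
  expect_error(sample_moments(data.frame(a = c(1, 1, 1), b = c(0, 1, 5))),
               "zero-variance")
  expect_message(sm2 <- sample_moments(data.frame(a = c(1, 2, NA, 4, 3),
                                                  b = c(2, 1, 3, 0, 2))),
                 "listwise")
  expect_equal(sm2$N, 4L)
  expect_error(sample_moments(data.frame(a = 1:2, b = 2:1, c = c(1, 3))),
               "more observations")
})

test_that("ML discrepancy has its closed-form values and properties", {
  S <- matrix(c(2, 0.5, 0.5, 1), 2)
  expect_equal(f_ml(S, S), 0)
  expect_equal(f_ml(diag(2), 2 * diag(2)), 2 * log(2) - 1)
  expect_error(f_ml(diag(2), matrix(c(1, 2, 2, 1), 2)), "positive definite")
  set.seed(9)
  for (r in 1:50) {
    A <- matrix(stats::rnorm(9), 3); B <- matrix(stats::rnorm(9), 3)
    expect_gte(f_ml(crossprod(A) + diag(0.1, 3), crossprod(B) + diag(0.1, 3)),
               0)
  }
})

test_that("a just-identified model fits perfectly", {
  tab <- gen_one_factor(200, seed = 3)[, 1:3]
  colnames(tab) <- c("a", "b", "c")
  fit <- fit_mimic(tab, mimic_spec(list(g = c("a", "b", "c"))))
  expect_equal(fit$df, 0L)
  expect_lt(fit$f_ml, 1e-10)
  expect_lt(fit$chi_square, 1e-7)
})

test_that("free parameters are recovered from a large simulated sample", {
  tab <- simulate_subject_table(sem_sim_config(n = 1e5), seed = 31)
  spec <- build_watershed_spec()
  # fit on fully standardized variables so estimates live on the truth's
  # scale up to the marker convention
  sm <- sample_moments(tab[, c(spec$indicators, spec$predictors)])
  fit <- fit_ml(stats::cov2cor(sm$S), sm$N, spec)
  expect_true(fit$converged)
  truth <- attr(tab, "truth")
  # convert the generating parameters (unit-variance latents) to the
  # marker-identified scale used by the fit
  s_lat <- truth$lambda[c(1, 3), ] |> diag()
  L_true <- truth$lambda %*% diag(1 / s_lat)
  G_true <- diag(s_lat) %*% truth$gamma
  Psi_true <- diag(s_lat) %*% truth$psi %*% diag(s_lat)
  expect_lt(max(abs(fit$estimates$lambda - L_true)), 0.02)
  expect_lt(max(abs(fit$estimates$gamma - G_true)), 0.02)
  expect_lt(max(abs(fit$estimates$psi - Psi_true)), 0.02)
  expect_lt(max(abs(fit$estimates$theta - truth$theta)), 0.02)
})

test_that("fit statistics are invariant to rescaling one variable", {
  tab <- gen_two_factor(400, seed = 11)
  fit1 <- fit_mimic(tab, two_factor_spec())
  tab2 <- tab; tab2$PO <- tab2$PO * 3
  fit2 <- fit_mimic(tab2, two_factor_spec())
  expect_equal(fit2$chi_square, fit1$chi_square, tolerance = 1e-6)
  expect_equal(fit2$rmsea, fit1$rmsea, tolerance = 1e-5)
  expect_equal(fit2$cfi, fit1$cfi, tolerance = 1e-6)
  expect_equal(fit2$srmr, fit1$srmr, tolerance = 1e-6)
  # marker loading absorbs the scale: latent variance scales by 9
  expect_equal(fit2$estimates$psi[1, 1], 9 * fit1$estimates$psi[1, 1],
               tolerance = 1e-4)
})

test_that("the one-factor model never fits better than the two-factor", {
  for (seed in c(2, 7, 19)) {
    tab <- gen_two_factor(300, seed = seed)
    f1 <- fit_mimic(tab, one_factor_spec())
    f2 <- fit_mimic(tab, two_factor_spec())
    expect_gte(f1$chi_square, f2$chi_square - 1e-8)
  }
})

test_that("chi-square, p and RMSEA follow their defining equations", {
  expect_equal(chi_square(0.5, 101), 50)
  expect_equal(chi_square(0.5, 100, multiplier = "N"), 50)
  expect_equal(p_value(0, 2), 1)
  # the one-factor statistic reported for the study sample
  expect_equal(p_value(5.589, 2), 0.061, tolerance = 5e-3)
  # chi-square equal to its df: p checked against the distribution
  expect_equal(p_value(2, 2), stats::pchisq(2, 2, lower.tail = FALSE))
  r <- rmsea(5.589, 2, 83)
  expect_equal(unname(r["point"]), sqrt((5.589 - 2) / (2 * 82)),
               tolerance = 1e-10)
  # interval endpoints solve the noncentral coverage equations
  ncp_lo <- r[["lo"]]^2 * 2 * 82
  ncp_hi <- r[["hi"]]^2 * 2 * 82
  if (ncp_lo > 0)
    expect_equal(stats::pchisq(5.589, 2, ncp = ncp_lo), 0.95,
                 tolerance = 1e-6)
  expect_equal(stats::pchisq(5.589, 2, ncp = ncp_hi), 0.05, tolerance = 1e-6)
  expect_equal(unname(rmsea(1.5, 2, 83)[c("point", "lo")]), c(0, 0))
  expect_error(rmsea(3, 0, 83), "df = 0")
  expect_true(r["lo"] <= r["point"] && r["point"] <= r["hi"])
})

test_that("CFI arithmetic and baseline construction are correct", {
  expect_equal(cfi(5, 5, 80, 6), 1)
  expect_equal(cfi(10, 5, 100, 6), 1 - 5 / 94)
  expect_equal(cfi(100, 6, 100, 6), 0)
  base <- baseline_model(two_factor_spec())
  expect_equal(length(base$latents), 0L)
  expect_equal(count_free_parameters(base), 4L)
  # a baseline fit of its own baseline has CFI 0
  tab <- gen_two_factor(150, seed = 4)
  fit <- fit_mimic(tab, two_factor_spec())
  expect_equal(cfi(fit$baseline$chisq, fit$baseline$df,
                   fit$baseline$chisq, fit$baseline$df), 0)
})

test_that("SRMR matches hand arithmetic and is scale-free", {
  S <- matrix(c(1, 0.1, 0.1, 1), 2)
  expect_equal(srmr(S, S), 0)
  expect_equal(srmr(S, diag(2)), sqrt(0.01 / 3))
  # joint rescaling of a variable leaves SRMR unchanged
  D <- diag(c(5, 1))
  expect_equal(srmr(D %*% S %*% D, D %*% diag(2) %*% D), sqrt(0.01 / 3))
})

test_that("BIC is the penalized log-likelihood", {
  expect_equal(bic(-400, 0, 83), 800)
  expect_equal(bic(-400, 9, 83), 800 + 9 * log(83))
  expect_equal(bic(-400, 9, 83), 839.7696, tolerance = 1e-4)
})

test_that("indicator R-squared follows the residual-variance identity", {
  spec <- mimic_spec(list(f = c("y1", "y2")))
  par <- mimic_params(lambda = matrix(c(1, 1), 2, 1),
                      psi = matrix(0.8, 1, 1), theta = c(0.2, 0.2))
  fake_fit <- list(estimates = par)
  r2 <- r_squared(fake_fit, spec)
  expect_equal(unname(r2), c(0.8, 0.8))
  # zero loading means zero explained variance
  par0 <- mimic_params(lambda = matrix(c(1, 0), 2, 1),
                       psi = matrix(0.8, 1, 1), theta = c(0.2, 0.2))
  expect_equal(unname(r_squared(list(estimates = par0), spec))[2], 0)
})

test_that("chi-square test holds its nominal size under the null", {
  # data generated from the fitted two-factor structure; rejection rate of
  # the df = 1 test at alpha = .05 stays near nominal
  n_rep <- 500
  rej <- 0L
  spec <- two_factor_spec()
  for (r in seq_len(n_rep)) {
    tab <- gen_two_factor(500, seed = 10000 + r)
    sm <- sample_moments(tab)
    fit <- fit_ml(sm$S, sm$N, spec)
    rej <- rej + (fit$p_value < 0.05)
  }
  expect_gte(rej / n_rep, 0.03)
  expect_lte(rej / n_rep, 0.07)
})

test_that("Heywood cases are flagged", {
  set.seed(21)
  eta <- stats::rnorm(400)
  tab <- data.frame(PO = eta + stats::rnorm(400, sd = 1e-4),
                    PS = 0.6 * eta + stats::rnorm(400, sd = 0.8),
                    VC = 0.7 * eta + stats::rnorm(400, sd = 0.7),
                    WM = 0.5 * eta + stats::rnorm(400, sd = 0.9))
  fit <- fit_mimic(tab, one_factor_spec())
  expect_true(fit$heywood)
})
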