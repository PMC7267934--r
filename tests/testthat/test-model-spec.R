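test_that("watershed spec wires every predictor to every latent", {
  spec <- build_watershed_spec()
  expect_equal(length(spec$indicators), 4L)
  expect_equal(length(spec$predictors), 11L)
  # congeneric measurement: each indicator loads on exactly one latent
  loads_on <- rowSums(is.na(spec$lambda_pattern) | spec$lambda_pattern != 0)
  expect_true(all(loads_on == 1))
  # 22 structural edges, all penalized by default
  expect_equal(sum(is.na(spec$gamma_pattern)), 22L)
  expect_true(all(spec$penalized))
  # age can be exempted from the penalty
  spec2 <- build_watershed_spec(exempt = "age")
  expect_false(any(spec2$penalized[, "age"]))
  expect_true(all(spec2$penalized[, tract_names]))
})

test_that("constructor rejects malformed assignments", {
  expect_error(mimic_spec(list(g = c("PO", "PO"))), "duplicate")
  expect_error(mimic_spec(list(g = c("PO", "PS"), h = character())),
               "at least one indicator")
  expect_error(mimic_spec(list(g = c("PO", "PS")), predictors = "PO"),
               "duplicate")
})

test_that("degrees of freedom match the measurement-model counts", {
  expect_equal(count_df(one_factor_spec()), 2L)
  expect_equal(count_free_parameters(one_factor_spec()), 8L)
  expect_equal(count_df(two_factor_spec()), 1L)
  expect_equal(count_free_parameters(two_factor_spec()), 9L)
  # three-indicator one-factor model is just-identified
  expect_equal(count_df(mimic_spec(list(g = c("a", "b", "c")))), 0L)
  # two indicators, one factor: under-identified
  expect_error(count_df(mimic_spec(list(g = c("a", "b")))),
               "under-identified")
})

test_that("df equals a brute-force moment-minus-parameter count", {
  specs <- list(one_factor_spec(), two_factor_spec(), build_watershed_spec(),
                mimic_spec(list(g = c("a", "b", "c", "d", "e"))),
                mimic_spec(list(FI = c("PO", "PS"), CI = c("VC", "WM")),
                           predictors = c("x1", "x2", "x3")))
  for (spec in specs) {
    m <- length(spec$indicators); q <- length(spec$predictors)
    # enumerate distinct sample moments: all (i <= j) indicator pairs plus
    # every indicator x predictor cell (predictor block is fixed)
    moments <- 0L
    for (i in seq_len(m)) for (j in i:m) moments <- moments + 1L
    moments <- moments + m * q
    # enumerate free slots directly from the patterns
    free <- sum(is.na(spec$lambda_pattern)) + sum(is.na(spec$gamma_pattern))
    n_lat <- length(spec$latents)
    free <- free + n_lat * (n_lat - 1L) / 2L +          # psi off-diagonal
      (if (spec$identification == "marker") n_lat else 0L) +  # psi diagonal
      m                                                  # theta
    expect_equal(count_df(spec), moments - free)
  }
})

test_that("implied moments reproduce hand-computed covariance algebra", {
  spec <- mimic_spec(list(f = c("y1", "y2")), predictors = "x")
  par <- mimic_params(lambda = matrix(c(1, 0.5), 2, 1),
                      gamma = matrix(0.8, 1, 1),
                      psi = matrix(0.36, 1, 1), theta = c(0.2, 0.2),
                      phi = matrix(1, 1, 1))
  Sig <- implied_moments(spec, par)
  # B = 0.8^2 * 1 + 0.36 = 1; Syy = Lam B Lam' + Theta; Syx = Lam * 0.8
  expect_equal(unname(Sig),
               rbind(c(1.2, 0.5, 0.8),
                     c(0.5, 0.45, 0.4),
                     c(0.8, 0.4, 1.0)))
  expect_identical(Sig, t(Sig))   # exact, not merely numerical, symmetry
})

test_that("implied moments match a simulation from the generative model", {
  spec <- mimic_spec(list(f = c("y1", "y2", "y3")), predictors = c("x1", "x2"))
  par <- mimic_params(lambda = matrix(c(1, 0.7, 1.3), 3, 1),
                      gamma = matrix(c(0.5, -0.3), 1, 2),
                      psi = matrix(0.5, 1, 1),
                      theta = c(0.3, 0.5, 0.4),
                      phi = matrix(c(1, 0.4, 0.4, 1), 2))
  Sig <- implied_moments(spec, par)
  set.seed(42)
  n <- 2e5
  x <- MASS::mvrnorm(n, c(0, 0), par$phi)
  eta <- x %*% t(par$gamma) + stats::rnorm(n, sd = sqrt(par$psi[1, 1]))
  y <- eta %*% t(par$lambda) +
    matrix(stats::rnorm(n * 3), n) %*% diag(sqrt(par$theta))
  emp <- stats::cov(cbind(y, x))
  expect_lt(max(abs(emp - Sig)), 0.02)
})

test_that("renaming and reordering permute implied moments consistently", {
  par1 <- mimic_params(lambda = rbind(c(1, 0), c(0.8, 0), c(0, 1), c(0, 0.6)),
                       gamma = rbind(c(0.4, -0.2), c(0.1, 0.3)),
                       psi = matrix(c(0.5, 0.2, 0.2, 0.7), 2),
                       theta = c(0.3, 0.4, 0.2, 0.5),
                       phi = matrix(c(1, 0.3, 0.3, 1), 2))
  spec1 <- mimic_spec(list(FI = c("PO", "PS"), CI = c("VC", "WM")),
                      predictors = c("x1", "x2"))
  # swap latent order, indicator blocks and predictor order
  spec2 <- mimic_spec(list(CI = c("VC", "WM"), FI = c("PO", "PS")),
                      predictors = c("x2", "x1"))
  par2 <- mimic_params(lambda = par1$lambda[c(3, 4, 1, 2), c(2, 1)],
                       gamma = par1$gamma[c(2, 1), c(2, 1)],
                       psi = par1$psi[c(2, 1), c(2, 1)],
                       theta = par1$theta[c(3, 4, 1, 2)],
                       phi = par1$phi[c(2, 1), c(2, 1)])
  S1 <- implied_moments(spec1, par1)
  S2 <- implied_moments(spec2, par2)
  perm <- c("VC", "WM", "PO", "PS", "x2", "x1")
  expect_equal(S2, S1[perm, perm])
})

test_that("free-parameter vector round-trips through a parameter set", {
  spec <- build_watershed_spec()
  set.seed(1)
  v <- stats::rnorm(count_free_parameters(spec))
  v[spec$free_table$log] <- abs(v[spec$free_table$log]) + 0.1
  phi <- diag(11)
  par <- wmimic:::vector_to_params(v, spec, phi = phi)
  expect_equal(wmimic:::params_to_vector(par, spec), v)
  # fixed entries hold exactly: marker loadings are 1
  expect_equal(par$lambda[1, 1], 1)
  expect_equal(par$lambda[3, 2], 1)
})

test_that("model specifications round-trip through YAML", {
  spec <- build_watershed_spec(exempt = "age")
  txt <- spec_to_yaml(spec)
  back <- spec_from_yaml(txt)
  expect_equal(back$indicators, spec$indicators)
  expect_equal(back$predictors, spec$predictors)
  expect_equal(back$latents, spec$latents)
  expect_equal(back$penalized, spec$penalized)
  expect_equal(back$identification, spec$identification)
  f <- tempfile(fileext = ".yaml")
  spec_to_yaml(spec, f)
  expect_equal(spec_from_yaml(f)$penalized, spec$penalized)
})

test_that("moment jacobian matches finite differences", {
  spec <- mimic_spec(list(FI = c("PO", "PS"), CI = c("VC", "WM")),
                     predictors = c("x1", "x2"))
  set.seed(5)
  v <- stats::rnorm(count_free_parameters(spec), sd = 0.3)
  v[spec$free_table$log] <- abs(v[spec$free_table$log]) + 0.5
  phi <- matrix(c(1, 0.3, 0.3, 1), 2)
  par <- wmimic:::vector_to_params(v, spec, phi = phi)
  jac <- wmimic:::implied_moments_jacobian(spec, par)
  h <- 1e-6
  for (k in seq_along(v)) {
    vp <- v; vm <- v
    vp[k] <- vp[k] + h; vm[k] <- vm[k] - h
    fd <- (implied_moments(spec, wmimic:::vector_to_params(vp, spec, phi)) -
           implied_moments(spec, wmimic:::vector_to_params(vm, spec, phi))) /
      (2 * h)
    expect_lt(max(abs(unname(fd) - jac[[k]])), 1e-6)
  }
})
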