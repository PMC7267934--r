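#' White-matter tract abbreviations
#'
#' The ten major white-matter fascicles whose mean tract-based fractional
#' anisotropy (mTBFA) enters the watershed MIMIC model, by their standard
#' abbreviations: anterior thalamic radiation (ATR), cingulum/cingulate
#' (CGC), cingulum/hippocampal (CGH), corticospinal tract (CST), forceps
#' major (Fmj), forceps minor (Fmn), inferior fronto-occipital fasciculus
#' (IFO), inferior longitudinal fasciculus (ILF), superior longitudinal
#' fasciculus (SLF), uncinate fasciculus (UNC).
#'
#' @export
tract_names <- c("ATR", "CGC", "CGH", "CST", "Fmj", "Fmn",
                 "IFO", "ILF", "SLF", "UNC")

#' WAIS-III index abbreviations
#'
#' Perceptual Organization (PO), Processing Speed (PS), Verbal Comprehension
#' (VC) and Working Memory (WM), the four index scores used as indicators of
#' the fluid (FI: PO, PS) and crystallized (CI: VC, WM) latent variables.
#'
#' @export
wais_indices <- c("PO", "PS", "VC", "WM")

#' Declare a MIMIC / CFA model
#'
#' A MIMIC model has observed causes (predictors) feeding latent variables
#' which in turn produce observed indicators.  With an empty predictor list
#' the model reduces to a confirmatory factor analysis.  The measurement
#' structure is congeneric: every indicator loads on exactly one latent.
#'
#' @param assignment named list mapping each latent variable name to the
#'   character vector of its indicators.
#' @param predictors character vector of observed causes (may be empty).
#' @param identification \code{"marker"} (first indicator's loading per
#'   latent fixed at 1, latent variances free) or \code{"unit_variance"}
#'   (latent variances fixed at 1, all loadings free).
#' @param penalize_all logical; if \code{TRUE} every structural edge carries
#'   the elastic-net penalty flag.
#' @param exempt character vector of predictors whose edges are never
#'   penalized (e.g. \code{"age"} if age should be kept unpenalized).
#' @param phi_mode \code{"sample"} fixes the exogenous covariance at the
#'   sample covariance of the predictors (conditional-on-x formulation);
#'   \code{"free"} estimates it.
#'
#' @return an object of class \code{mimic_spec}.
#' @seealso [build_watershed_spec()] for the study's full layered model.
#' @export
mimic_spec <- function(assignment, predictors = character(),
                       identification = c("marker", "unit_variance"),
                       penalize_all = TRUE, exempt = character(),
                       phi_mode = c("sample", "free")) {
  identification <- match.arg(identification)
  phi_mode <- match.arg(phi_mode)
  if (length(assignment) == 0L)
    stop("'assignment' must name at least one latent variable")
  latents <- names(assignment)
  if (is.null(latents) || any(!nzchar(latents)))
    stop("'assignment' must be a named list (latent -> indicators)")
  indicators <- unlist(assignment, use.names = FALSE)
  if (any(vapply(assignment, length, 1L) == 0L))
    stop("every latent variable needs at least one indicator")
  nms <- c(indicators, predictors, latents)
  if (anyDuplicated(nms))
    stop("duplicate variable names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))

  n_ind <- length(indicators)
  n_lat <- length(latents)
  n_pre <- length(predictors)

  # loading pattern: NA = free, finite = fixed at that value, 0 = absent
  lambda <- matrix(0, n_ind, n_lat, dimnames = list(indicators, latents))
  for (l in seq_len(n_lat)) {
    idx <- match(assignment[[l]], indicators)
    lambda[idx, l] <- NA_real_
    if (identification == "marker") lambda[idx[1L], l] <- 1
  }
  gamma <- matrix(NA_real_, n_lat, n_pre, dimnames = list(latents, predictors))
  penalized <- matrix(penalize_all, n_lat, n_pre,
                      dimnames = list(latents, predictors))
  if (length(exempt)) penalized[, colnames(penalized) %in% exempt] <- FALSE

  spec <- structure(
    list(indicators = indicators, predictors = predictors, latents = latents,
         lambda_pattern = lambda, gamma_pattern = gamma,
         penalized = penalized, identification = identification,
         phi_mode = phi_mode),
    class = "mimic_spec")
  spec$free_table <- free_param_table(spec)
  spec
}

#' The layered watershed specification
#'
#' Builds the hierarchical MIMIC model in which every predictor (the ten
#' tract mTBFA values plus age) sends a penalized structural edge to every
#' latent variable, and the latents produce the WAIS-III indices through a
#' congeneric measurement model.
#'
#' @param assignment named list latent -> indicators; default
#'   \code{list(FI = c("PO","PS"), CI = c("VC","WM"))}.
#' @param predictors default: the ten tracts plus \code{"age"}.
#' @param ... passed to [mimic_spec()] (identification, exempt, phi_mode).
#'
#' @return a \code{mimic_spec} with one penalized structural edge per
#'   (predictor, latent) pair.
#' @examples
#' spec <- build_watershed_spec()
#' count_df(spec)
#' @export
build_watershed_spec <- function(assignment = list(FI = c("PO", "PS"),
                                                   CI = c("VC", "WM")),
                                 predictors = c(tract_names, "age"), ...) {
  mimic_spec(assignment, predictors = predictors, ...)
}

# Enumerate the free parameter slots of a spec, in the canonical vector
# order used by the optimizer: lambda (column-major), gamma (column-major),
# psi (diagonal then lower off-diagonal), theta.  log = TRUE marks entries
# optimized on the log scale (variances).
free_param_table <- function(spec) {
  rows <- list()
  lp <- spec$lambda_pattern
  for (j in seq_len(ncol(lp))) for (i in seq_len(nrow(lp)))
    if (is.na(lp[i, j]))
      rows[[length(rows) + 1L]] <- data.frame(
        block = "lambda", row = i, col = j, penalized = FALSE, log = FALSE,
        label = paste0(spec$latents[j], "=~", spec$indicators[i]))
  gp <- spec$gamma_pattern
  if (length(gp)) for (j in seq_len(ncol(gp))) for (i in seq_len(nrow(gp)))
    if (is.na(gp[i, j]))
      rows[[length(rows) + 1L]] <- data.frame(
        block = "gamma", row = i, col = j,
        penalized = spec$penalized[i, j], log = FALSE,
        label = paste0(spec$predictors[j], "->", spec$latents[i]))
  n_lat <- length(spec$latents)
  if (spec$identification == "marker")
    for (l in seq_len(n_lat))
      rows[[length(rows) + 1L]] <- data.frame(
        block = "psi", row = l, col = l, penalized = FALSE, log = TRUE,
        label = paste0("var(", spec$latents[l], ")"))
  if (n_lat > 1L)
    for (j in seq_len(n_lat - 1L)) for (i in seq((j + 1L), n_lat))
      rows[[length(rows) + 1L]] <- data.frame(
        block = "psi", row = i, col = j, penalized = FALSE, log = FALSE,
        label = paste0("cov(", spec$latents[i], ",", spec$latents[j], ")"))
  for (i in seq_along(spec$indicators))
    rows[[length(rows) + 1L]] <- data.frame(
      block = "theta", row = i, col = i, penalized = FALSE, log = TRUE,
      label = paste0("var(e.", spec$indicators[i], ")"))
  if (spec$phi_mode == "free" && length(spec$predictors)) {
    q <- length(spec$predictors)
    for (j in seq_len(q)) for (i in seq(j, q))
      rows[[length(rows) + 1L]] <- data.frame(
        block = "phi", row = i, col = j, penalized = FALSE, log = i == j,
        label = paste0("phi(", spec$predictors[i], ",",
                       spec$predictors[j], ")"))
  }
  do.call(rbind, rows)
}

#' Number of free parameters of a specification
#'
#' Free loadings, structural coefficients, latent disturbance (co)variances,
#' indicator residual variances, and — only when \code{phi_mode = "free"} —
#' the exogenous covariance entries.
#'
#' @param spec a \code{mimic_spec}.
#' @return integer count.
#' @export
count_free_parameters <- function(spec) nrow(spec$free_table)

#' Model degrees of freedom
#'
#' Under the conditional-on-predictors convention the counted sample moments
#' are the indicator-indicator covariances (m(m+1)/2 for m indicators) plus
#' the indicator-predictor cross-covariances (m q); the predictor block is
#' fixed at its sample value and excluded from both the moment and the
#' parameter count.  df = moments - free parameters.
#'
#' @param spec a \code{mimic_spec}.
#' @return integer df (errors if negative: the model is under-identified).
#' @examples
#' count_df(mimic_spec(list(g = c("PO", "PS", "VC", "WM"))))  # 2
#' @export
count_df <- function(spec) {
  m <- length(spec$indicators)
  q <- length(spec$predictors)
  moments <- m * (m + 1L) / 2L + m * q
  if (spec$phi_mode == "free" && q) moments <- moments + q * (q + 1L) / 2L
  df <- moments - count_free_parameters(spec)
  if (df < 0)
    stop("model is under-identified: df = ", df)
  as.integer(df)
}

#' Assemble a parameter set
#'
#' Bundles the MIMIC parameter matrices: loadings \code{lambda}
#' (indicators x latents), structural coefficients \code{gamma}
#' (latents x predictors), latent disturbance covariance \code{psi},
#' indicator residual variances \code{theta} (vector, diagonal), and the
#' exogenous covariance \code{phi}.
#'
#' @param lambda,gamma,psi,theta,phi conforming matrices / vector.
#' @return object of class \code{mimic_params}.
#' @export
mimic_params <- function(lambda, gamma, psi, theta, phi) {
  lambda <- as.matrix(lambda)
  psi <- as.matrix(psi)
  if (missing(gamma) || is.null(gamma))
    gamma <- matrix(0, nrow(psi), 0L)
  gamma <- as.matrix(gamma)
  if (missing(phi) || is.null(phi)) phi <- matrix(0, 0L, 0L)
  phi <- as.matrix(phi)
  stopifnot(isSymmetric(unname(psi), tol = 1e-10),
            ncol(phi) == 0L || isSymmetric(unname(phi), tol = 1e-10),
            length(theta) == nrow(lambda),
            ncol(lambda) == nrow(psi), nrow(gamma) == nrow(psi),
            ncol(gamma) == nrow(phi))
  structure(list(lambda = lambda, gamma = gamma, psi = (psi + t(psi)) / 2,
                 theta = as.numeric(theta),
                 phi = if (length(phi)) (phi + t(phi)) / 2 else phi),
            class = "mimic_params")
}

# Map a natural-scale free-parameter vector into a mimic_params, starting
# from the fixed pattern of `spec`; `phi` supplies the fixed exogenous
# covariance when phi_mode == "sample".
vector_to_params <- function(theta_vec, spec, phi = NULL) {
  ft <- spec$free_table
  stopifnot(length(theta_vec) == nrow(ft))
  n_ind <- length(spec$indicators); n_lat <- length(spec$latents)
  q <- length(spec$predictors)
  lambda <- spec$lambda_pattern
  lambda[is.na(lambda)] <- 0
  gamma <- matrix(0, n_lat, q, dimnames = dimnames(spec$gamma_pattern))
  psi <- diag(1, n_lat)   # unit-variance identification: fixed diagonal
  dimnames(psi) <- list(spec$latents, spec$latents)
  theta <- numeric(n_ind)
  phi_m <- if (spec$phi_mode == "free" && q) matrix(0, q, q) else phi
  for (k in seq_len(nrow(ft))) {
    v <- theta_vec[k]
    switch(ft$block[k],
      lambda = { lambda[ft$row[k], ft$col[k]] <- v },
      gamma  = { gamma[ft$row[k], ft$col[k]] <- v },
      psi    = { psi[ft$row[k], ft$col[k]] <- v
                 psi[ft$col[k], ft$row[k]] <- v },
      theta  = { theta[ft$row[k]] <- v },
      phi    = { phi_m[ft$row[k], ft$col[k]] <- v
                 phi_m[ft$col[k], ft$row[k]] <- v })
  }
  if (q && is.null(phi_m))
    stop("phi must be supplied when phi_mode == 'sample'")
  mimic_params(lambda, gamma, psi, theta, phi_m)
}

params_to_vector <- function(params, spec) {
  ft <- spec$free_table
  vapply(seq_len(nrow(ft)), function(k) {
    switch(ft$block[k],
      lambda = params$lambda[ft$row[k], ft$col[k]],
      gamma  = params$gamma[ft$row[k], ft$col[k]],
      psi    = params$psi[ft$row[k], ft$col[k]],
      theta  = params$theta[ft$row[k]],
      phi    = params$phi[ft$row[k], ft$col[k]])
  }, numeric(1))
}

#' Model-implied covariance matrix
#'
#' Standard MIMIC covariance algebra over the joint vector
#' (indicators, predictors):
#' \deqn{\Sigma_{yy} = \Lambda(\Gamma\Phi\Gamma' + \Psi)\Lambda' + \Theta,
#'   \quad \Sigma_{yx} = \Lambda\Gamma\Phi, \quad \Sigma_{xx} = \Phi.}
#'
#' @param spec a \code{mimic_spec}.
#' @param params a conforming \code{mimic_params}.
#' @return symmetric covariance matrix of order
#'   (n indicators + n predictors), rows/columns named.
#' @export
implied_moments <- function(spec, params) {
  n_ind <- length(spec$indicators); q <- length(spec$predictors)
  if (nrow(params$lambda) != n_ind || nrow(params$psi) != length(spec$latents)
      || ncol(params$gamma) != q)
    stop("parameter dimensions do not match the specification")
  L <- params$lambda; G <- params$gamma; P <- params$phi
  if (q == 0L) P <- matrix(0, 0L, 0L)
  B <- if (q) G %*% P %*% t(G) + params$psi else params$psi
  Syy <- L %*% B %*% t(L) + diag(params$theta, n_ind)
  if (q) {
    Syx <- L %*% G %*% P
    S <- rbind(cbind(Syy, Syx), cbind(t(Syx), P))
  } else S <- Syy
  S <- (S + t(S)) / 2
  dimnames(S) <- list(c(spec$indicators, spec$predictors),
                      c(spec$indicators, spec$predictors))
  S
}

# Analytic derivative matrices dSigma/dtheta_k (natural scale) for every
# free parameter; returns a list of full (m+q) x (m+q) matrices.  Used by
# the Satorra-Bentler correction and verified in tests against finite
# differences of implied_moments.
implied_moments_jacobian <- function(spec, params, include_phi = FALSE) {
  ft <- spec$free_table
  m <- length(spec$indicators); q <- length(spec$predictors)
  n_lat <- length(spec$latents)
  L <- params$lambda; G <- params$gamma; P <- params$phi
  B <- if (q) G %*% P %*% t(G) + params$psi else params$psi
  tot <- m + q
  pad <- function(dyy = NULL, dyx = NULL, dxx = NULL) {
    M <- matrix(0, tot, tot)
    if (!is.null(dyy)) M[1:m, 1:m] <- dyy
    if (q && !is.null(dyx)) {
      M[1:m, (m + 1):tot] <- dyx
      M[(m + 1):tot, 1:m] <- t(dyx)
    }
    if (q && !is.null(dxx)) M[(m + 1):tot, (m + 1):tot] <- dxx
    M
  }
  out <- vector("list", nrow(ft))
  for (k in seq_len(nrow(ft))) {
    i <- ft$row[k]; j <- ft$col[k]
    out[[k]] <- switch(ft$block[k],
      lambda = {
        # dSyy = J B L' + L B J',  dSyx = J G P  with J = e_i e_j'
        v <- B[j, , drop = FALSE] %*% t(L)             # 1 x m
        dyy <- matrix(0, m, m)
        dyy[i, ] <- dyy[i, ] + v
        dyy[, i] <- dyy[, i] + as.numeric(v)
        dyx <- if (q) { z <- matrix(0, m, q)
                        z[i, ] <- G[j, , drop = FALSE] %*% P; z } else NULL
        pad(dyy, dyx)
      },
      gamma = {
        # dB = J P G' + G P J'  with J = e_i e_j' (latent i, predictor j)
        w <- P[j, , drop = FALSE] %*% t(G)             # 1 x n_lat
        dB <- matrix(0, n_lat, n_lat)
        dB[i, ] <- dB[i, ] + w
        dB[, i] <- dB[, i] + as.numeric(w)
        dyx <- { z <- matrix(0, n_lat, q); z[i, ] <- P[j, ]; L %*% z }
        pad(L %*% dB %*% t(L), dyx)
      },
      psi = {
        E <- matrix(0, n_lat, n_lat); E[i, j] <- E[j, i] <- 1
        pad(L %*% E %*% t(L))
      },
      theta = {
        dyy <- matrix(0, m, m); dyy[i, i] <- 1
        pad(dyy)
      },
      phi = {
        E <- matrix(0, q, q); E[i, j] <- E[j, i] <- 1
        pad(L %*% (G %*% E %*% t(G)) %*% t(L), L %*% G %*% E, E)
      })
  }
  names(out) <- ft$label
  if (include_phi && spec$phi_mode == "sample" && q) {
    extra <- list()
    for (j in seq_len(q)) for (i in seq(j, q)) {
      E <- matrix(0, q, q); E[i, j] <- E[j, i] <- 1
      extra[[paste0("phi(", i, ",", j, ")")]] <-
        pad(L %*% (G %*% E %*% t(G)) %*% t(L), L %*% G %*% E, E)
    }
    out <- c(out, extra)
  }
  out
}

#' Serialize a model specification to YAML
#'
#' Round-trips the declarative blocks (indicators, predictors, latents,
#' measurement assignment, penalty exemptions, identification mode).
#'
#' @param spec a \code{mimic_spec}.
#' @param path file to write; with \code{path = NULL} the YAML string is
#'   returned.
#' @return the YAML string, invisibly when written to a file.
#' @export
spec_to_yaml <- function(spec, path = NULL) {
  assignment <- lapply(seq_along(spec$latents), function(l)
    spec$indicators[spec$lambda_pattern[, l] != 0 |
                    is.na(spec$lambda_pattern[, l])])
  names(assignment) <- spec$latents
  exempt <- if (length(spec$predictors))
    spec$predictors[colSums(spec$penalized) == 0] else character()
  obj <- list(latents = assignment,
              predictors = as.list(spec$predictors),
              identification = spec$identification,
              phi_mode = spec$phi_mode,
              exempt = as.list(exempt))
  txt <- yaml::as.yaml(obj)
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

#' @rdname spec_to_yaml
#' @param x YAML string or path to a YAML file.
#' @export
spec_from_yaml <- function(x) {
  obj <- if (file.exists(x)) yaml::read_yaml(x) else yaml::yaml.load(x)
  mimic_spec(lapply(obj$latents, unlist),
             predictors = as.character(unlist(obj$predictors)),
             identification = obj$identification,
             exempt = as.character(unlist(obj$exempt)),
             phi_mode = obj$phi_mode)
}

#' @export
print.mimic_spec <- function(x, ...) {
  cat("MIMIC model specification\n")
  cat("  latents    :", paste(x$latents, collapse = ", "), "\n")
  cat("  indicators :", paste(x$indicators, collapse = ", "), "\n")
  if (length(x$predictors))
    cat("  predictors :", paste(x$predictors, collapse = ", "), "\n")
  cat("  identification:", x$identification,
      "| free parameters:", count_free_parameters(x),
      "| df:", count_df(x), "\n")
  invisible(x)
}
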