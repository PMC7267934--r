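#' Tracking parameters
#'
#' Start/stop criteria of the deterministic FACT tracker: tracking starts
#' only in voxels with FA >= \code{fa_start} and trace <= \code{tr_start}
#' (units mm^2/s), propagates along per-voxel principal eigenvectors, and
#' stops on FA < \code{fa_stop}, trace > \code{tr_stop}, a turning angle
#' above \code{angle_max} degrees, or on leaving the grid.  Streamlines
#' visiting fewer than \code{min_length} voxels are discarded.
#'
#' @param fa_start,tr_start,fa_stop,tr_stop,angle_max,min_length defaults
#'   are the study values: 0.15 / 0.0016 / 0.10 / 0.002 / 53.1 degrees /
#'   5 voxels.
#' @return object of class \code{tracking_params}.
#' @export
tracking_params <- function(fa_start = 0.15, tr_start = 0.0016,
                            fa_stop = 0.10, tr_stop = 0.002,
                            angle_max = 53.1, min_length = 5L) {
  stopifnot(fa_stop <= fa_start, tr_start <= tr_stop,
            angle_max > 0, angle_max < 90, min_length >= 1)
  structure(list(fa_start = fa_start, tr_start = tr_start,
                 fa_stop = fa_stop, tr_stop = tr_stop,
                 angle_max = angle_max, min_length = as.integer(min_length)),
            class = "tracking_params")
}

#' Construct a tensor volume
#'
#' A voxel grid of 3x3 symmetric diffusion tensors stored as a 4D array
#' with 6 lower-triangular components in (xx, yx, yy, zx, zy, zz) order,
#' plus voxel size (mm) and a voxel-to-world affine.
#'
#' @param data 4D array (nx, ny, nz, 6).
#' @param voxel_size scalar voxel edge length in mm.
#' @param affine 4x4 voxel-to-world matrix (default: scaled identity).
#' @return object of class \code{tensor_volume}.
#' @export
tensor_volume <- function(data, voxel_size = 1,
                          affine = diag(c(rep(voxel_size, 3), 1))) {
  stopifnot(length(dim(data)) == 4L, dim(data)[4L] == 6L, voxel_size > 0)
  structure(list(data = data, dim = dim(data)[1:3],
                 voxel_size = voxel_size, affine = affine),
            class = "tensor_volume")
}

.tensor_from_components <- function(v) {
  matrix(c(v[1], v[2], v[4],
           v[2], v[3], v[5],
           v[4], v[5], v[6]), 3, 3)
}

.components_from_tensor <- function(Tm) {
  c(Tm[1, 1], Tm[2, 1], Tm[2, 2], Tm[3, 1], Tm[3, 2], Tm[3, 3])
}

#' Per-voxel tensor metrics
#'
#' Eigen-decomposition of a symmetric diffusion tensor: ordered eigenvalues
#' \eqn{\lambda_1 \ge \lambda_2 \ge \lambda_3}, principal eigenvector (sign
#' convention: its largest-magnitude component is nonnegative), fractional
#' anisotropy
#' \deqn{FA = \sqrt{\tfrac12}\;\sqrt{\frac{(\lambda_1-\lambda_2)^2 +
#'   (\lambda_2-\lambda_3)^2 + (\lambda_3-\lambda_1)^2}
#'   {\lambda_1^2+\lambda_2^2+\lambda_3^2}}}
#' and trace.  The all-zero tensor has FA defined as 0.
#'
#' @param tensor 3x3 symmetric matrix, or length-6 component vector in
#'   (xx, yx, yy, zx, zy, zz) order.
#' @return list with \code{evals}, \code{e1}, \code{fa}, \code{trace}.
#' @export
tensor_metrics <- function(tensor) {
  Tm <- if (is.matrix(tensor)) tensor else .tensor_from_components(tensor)
  if (max(abs(Tm - t(Tm))) > 1e-8 * max(1, max(abs(Tm))))
    stop("tensor must be symmetric")
  Tm <- (Tm + t(Tm)) / 2
  e <- eigen(Tm, symmetric = TRUE)
  ev <- e$values
  ss <- sum(ev^2)
  fa <- if (ss == 0) 0 else
    sqrt(0.5 * ((ev[1] - ev[2])^2 + (ev[2] - ev[3])^2 +
                (ev[3] - ev[1])^2) / ss)
  v <- e$vectors[, 1L]
  if (v[which.max(abs(v))] < 0) v <- -v
  list(evals = ev, e1 = v, fa = min(fa, 1), trace = sum(ev))
}

# Precompute FA / trace / principal-direction maps for a whole volume.
tensor_maps <- function(volume) {
  d <- volume$dim
  n <- prod(d)
  fa <- numeric(n); tr <- numeric(n); e1 <- matrix(0, n, 3)
  flat <- matrix(volume$data, n, 6)
  for (i in seq_len(n)) {
    tm <- tensor_metrics(flat[i, ])
    fa[i] <- tm$fa; tr[i] <- tm$trace; e1[i, ] <- tm$e1
  }
  list(fa = array(fa, d), trace = array(tr, d), e1 = e1, dim = d)
}

.vox_linear <- function(v, d) {
  (v[3] - 1) * d[1] * d[2] + (v[2] - 1) * d[1] + v[1]
}

# One tracking direction from a seed.  Continuous position in voxel
# coordinates (voxel i occupies [i - 0.5, i + 0.5]); within each voxel the
# path follows that voxel's principal eigenvector until it exits through a
# face, and the turning angle is measured between the directions followed
# in consecutive voxels.
.track_one_way <- function(seed, d0, maps, params, max_steps = 100000L) {
  d <- maps$dim
  cur <- seed
  p <- as.numeric(seed)
  dir <- d0
  visited <- matrix(seed, 1L, 3L)
  cosmax <- cos(params$angle_max * pi / 180)
  for (step in seq_len(max_steps)) {
    tmin <- Inf; axis <- 0L
    for (a in 1:3) {
      if (dir[a] == 0) next
      face <- cur[a] + 0.5 * sign(dir[a])
      t_a <- (face - p[a]) / dir[a]
      if (t_a < tmin) { tmin <- t_a; axis <- a }
    }
    if (axis == 0L) break
    p <- p + tmin * dir
    nxt <- cur
    nxt[axis] <- nxt[axis] + sign(dir[axis])
    if (any(nxt < 1L) || any(nxt > d)) break
    li <- .vox_linear(nxt, d)
    if (maps$fa[li] < params$fa_stop || maps$trace[li] > params$tr_stop)
      break
    dn <- maps$e1[li, ]
    dp <- sum(dn * dir)
    if (dp < 0) { dn <- -dn; dp <- -dp }
    if (dp < cosmax) break
    visited <- rbind(visited, nxt)
    cur <- nxt
    dir <- dn
  }
  visited
}

#' Deterministic FACT tracking from one seed voxel
#'
#' Fiber Assignment by Continuous Tracking: starts at the seed voxel center
#' (only if the seed meets the start criteria), propagates bidirectionally
#' following each voxel's principal eigenvector (sign chosen to continue
#' the previous heading) with exit-face stepping, and terminates per the
#' stop criteria.  Returns \code{NULL} when the seed does not qualify or
#' fewer than \code{min_length} voxels are visited.
#'
#' @param seed_voxel integer vector (i, j, k), 1-based voxel index.
#' @param volume a \code{tensor_volume}; precomputed maps may be attached
#'   as \code{attr(volume, "maps")} to avoid recomputation.
#' @param params a \code{tracking_params}.
#' @return a streamline: list with \code{voxels} (matrix of visited voxel
#'   indices, ordered along the fiber) and \code{points} (their voxel-center
#'   coordinates), or \code{NULL}.
#' @export
fact_track <- function(seed_voxel, volume, params = tracking_params()) {
  maps <- attr(volume, "maps")
  if (is.null(maps)) maps <- tensor_maps(volume)
  d <- maps$dim
  seed_voxel <- as.integer(seed_voxel)
  if (any(seed_voxel < 1L) || any(seed_voxel > d))
    stop("seed voxel outside the grid")
  li <- .vox_linear(seed_voxel, d)
  if (maps$fa[li] < params$fa_start || maps$trace[li] > params$tr_start)
    return(NULL)
  d0 <- maps$e1[li, ]
  fwd <- .track_one_way(seed_voxel, d0, maps, params)
  bwd <- .track_one_way(seed_voxel, -d0, maps, params)
  vox <- rbind(bwd[rev(seq_len(nrow(bwd)))[-nrow(bwd)], , drop = FALSE], fwd)
  if (nrow(unique(vox)) < params$min_length) return(NULL)
  list(voxels = unname(vox), points = unname(vox) * volume$voxel_size,
       seed = seed_voxel)
}

#' Brute-force whole-volume tracking
#'
#' Calls [fact_track()] once from every voxel satisfying the start
#' criteria and returns the duplicate-free set of streamlines (streamlines
#' visiting an identical voxel set are collapsed).
#'
#' @param volume a \code{tensor_volume}.
#' @param params a \code{tracking_params}.
#' @return list of streamlines.
#' @export
brute_force_tracking <- function(volume, params = tracking_params()) {
  maps <- attr(volume, "maps")
  if (is.null(maps)) {
    maps <- tensor_maps(volume)
    attr(volume, "maps") <- maps
  }
  qualifying <- which(maps$fa >= params$fa_start &
                      maps$trace <= params$tr_start, arr.ind = TRUE)
  out <- list(); seen <- character()
  if (nrow(qualifying)) for (r in seq_len(nrow(qualifying))) {
    s <- fact_track(qualifying[r, ], volume, params)
    if (is.null(s)) next
    v <- s$voxels[order(s$voxels[, 1], s$voxels[, 2], s$voxels[, 3]), ,
                  drop = FALSE]
    key <- paste(t(v), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- s
  }
  out
}

.streamline_hits <- function(streamline, mask) {
  any(mask[streamline$voxels])
}

#' Multi-ROI tract selection
#'
#' Keeps the streamlines that visit at least one voxel of every inclusion
#' ROI and no voxel of any exclusion ROI (the reproducible stand-in for
#' manual pruning of anatomically implausible fibers).
#'
#' @param streamlines list of streamlines from the tracker.
#' @param inclusion_rois nonempty list of logical 3D masks.
#' @param exclusion_rois list of logical 3D masks (may be empty).
#' @param label tract label (e.g. a Table-1 abbreviation).
#' @param hemisphere optional hemisphere tag.
#' @return object of class \code{tract_set}.
#' @export
select_tract <- function(streamlines, inclusion_rois,
                         exclusion_rois = list(), label = NA_character_,
                         hemisphere = NA_character_) {
  if (length(inclusion_rois) == 0L)
    stop("at least one inclusion ROI is required")
  inclusion_rois <- lapply(inclusion_rois, function(m) array(m != 0, dim(m)))
  exclusion_rois <- lapply(exclusion_rois, function(m) array(m != 0, dim(m)))
  keep <- vapply(streamlines, function(s) {
    all(vapply(inclusion_rois, function(m) .streamline_hits(s, m), TRUE)) &&
      !any(vapply(exclusion_rois, function(m) .streamline_hits(s, m), TRUE))
  }, TRUE)
  structure(list(streamlines = streamlines[keep], label = label,
                 hemisphere = hemisphere),
            class = "tract_set")
}

#' Mean tract-based fractional anisotropy
#'
#' Averages the FA map over the superposition (union) of the unique voxels
#' visited by a tract's streamlines; \code{weighted = TRUE} instead weights
#' each voxel by its visit count across streamlines.
#'
#' @param tract a \code{tract_set} with at least one streamline.
#' @param fa_map 3D FA array on the same grid.
#' @param weighted logical (default FALSE: plain union average).
#' @return mean FA value.
#' @export
mean_tract_fa <- function(tract, fa_map, weighted = FALSE) {
  if (length(tract$streamlines) == 0L)
    stop("empty tract: no streamlines to average over")
  vox <- do.call(rbind, lapply(tract$streamlines, `[[`, "voxels"))
  if (!weighted) vox <- unique(vox)
  mean(fa_map[vox])
}

#' Bilateral tract average
#'
#' Arithmetic mean of the left and right mTBFA of a tract; if one side is
#' missing the other is returned with a warning.
#'
#' @param mtbfa_left,mtbfa_right per-hemisphere values (NA = missing).
#' @return the averaged value.
#' @export
bilateral_average <- function(mtbfa_left, mtbfa_right) {
  l_ok <- !is.null(mtbfa_left) && !is.na(mtbfa_left)
  r_ok <- !is.null(mtbfa_right) && !is.na(mtbfa_right)
  if (l_ok && r_ok) return((mtbfa_left + mtbfa_right) / 2)
  if (l_ok) { warning("right-hemisphere value missing; returning left")
              return(mtbfa_left) }
  if (r_ok) { warning("left-hemisphere value missing; returning right")
              return(mtbfa_right) }
  stop("both hemisphere values are missing")
}

#' Read/write tensor volumes, maps and masks as NIfTI
#'
#' Tensor volumes are stored as 4D NIfTI with 6 volumes holding the
#' lower-triangular components in (xx, yx, yy, zx, zy, zz) order; FA maps
#' and ROI masks are plain 3D volumes on the same grid (no resampling is
#' performed).
#'
#' @param volume a \code{tensor_volume}.
#' @param path file path (.nii or .nii.gz).
#' @return \code{read_tensor_volume} returns a \code{tensor_volume};
#'   the writers return \code{path} invisibly.
#' @export
write_tensor_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$data,
                         pixdim = c(rep(volume$voxel_size, 3), 1))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_tensor_volume
#' @export
read_tensor_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vx <- RNifti::pixdim(img)[1]
  tensor_volume(array(as.numeric(img), dim(img)), voxel_size = vx)
}

#' @rdname write_tensor_volume
#' @param x 3D array (FA map or 0/1 mask).
#' @param voxel_size voxel edge length in mm.
#' @export
write_volume_3d <- function(x, path, voxel_size = 1) {
  RNifti::writeNifti(RNifti::asNifti(x, pixdim = rep(voxel_size, 3)), path)
  invisible(path)
}

#' @rdname write_tensor_volume
#' @export
read_volume_3d <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim(img))
}

#' Write streamlines as line-delimited JSON
#'
#' One JSON object per line with the tract label and the ordered voxel
#' indices; a plain-text interchange format for tracked fibers.
#'
#' @param streamlines list of streamlines (or a \code{tract_set}).
#' @param path output file.
#' @param label optional label stored with each line.
#' @return \code{path}, invisibly.
#' @export
write_streamlines_json <- function(streamlines, path, label = NA_character_) {
  if (inherits(streamlines, "tract_set")) {
    label <- streamlines$label
    streamlines <- streamlines$streamlines
  }
  con <- file(path, "w"); on.exit(close(con))
  for (s in streamlines)
    writeLines(jsonlite::toJSON(list(label = label, voxels = s$voxels),
                                auto_unbox = TRUE, digits = NA), con)
  invisible(path)
}

#' @rdname write_streamlines_json
#' @export
read_streamlines_json <- function(path) {
  lapply(readLines(path), function(ln) {
    obj <- jsonlite::fromJSON(ln)
    list(voxels = matrix(as.integer(obj$voxels), ncol = 3),
         label = obj$label)
  })
}
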