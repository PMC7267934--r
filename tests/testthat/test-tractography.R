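test_that("tensor metrics recover the closed-form FA and trace", {
  iso <- tensor_metrics(diag(3) * 1e-3)
  expect_equal(iso$fa, 0)
  expect_equal(iso$trace, 3e-3)
  stick <- tensor_metrics(diag(c(1, 0, 0)))
  expect_equal(stick$fa, 1)
  expect_equal(tensor_metrics(matrix(0, 3, 3))$fa, 0)
  # direct evaluation of the FA formula for a generic prolate-ish tensor
  ev <- c(1.7, 0.3, 0.2) * 1e-3
  fa_ref <- sqrt(0.5) * sqrt(((ev[1] - ev[2])^2 + (ev[2] - ev[3])^2 +
                              (ev[3] - ev[1])^2) / sum(ev^2))
  tm <- tensor_metrics(diag(ev))
  expect_equal(tm$fa, fa_ref, tolerance = 1e-12)
  expect_equal(tm$evals, ev)
  expect_error(tensor_metrics(matrix(c(1, 2, 0, 0, 1, 0, 0, 0, 1), 3)),
               "symmetric")
})

test_that("FA and trace are rotation invariant", {
  set.seed(17)
  base <- diag(c(1.7, 0.3, 0.2) * 1e-3)
  ref <- tensor_metrics(base)
  for (r in 1:100) {
    Q <- random_rotation()
    tm <- tensor_metrics(Q %*% base %*% t(Q))
    expect_lt(abs(tm$fa - ref$fa), 1e-10)
    expect_lt(abs(tm$trace - ref$trace), 1e-10)
  }
})

test_that("the eigenvector sign convention is deterministic", {
  tm <- tensor_metrics(diag(c(1, 0.2, 0.2)))
  expect_equal(tm$e1, c(1, 0, 0))
  expect_equal(sqrt(sum(tm$e1^2)), 1)
})

test_that("tracking spans a uniform bundle and rejects isotropic seeds", {
  ph <- straight_phantom()
  s <- fact_track(c(10, 10, 10), ph$volume)
  expect_equal(range(s$voxels[, 1]), c(1, 20))
  expect_true(all(s$voxels[, 2] == 10) && all(s$voxels[, 3] == 10))
  # reversing the initial heading yields the same voxel set
  maps <- attr(ph$volume, "maps")
  fwd <- wmimic:::.track_one_way(c(10L, 10L, 10L), maps$e1[
    wmimic:::.vox_linear(c(10, 10, 10), maps$dim), ], maps,
    tracking_params())
  bwd <- wmimic:::.track_one_way(c(10L, 10L, 10L), -maps$e1[
    wmimic:::.vox_linear(c(10, 10, 10), maps$dim), ], maps,
    tracking_params())
  both <- unique(rbind(fwd, bwd))
  expect_setequal(apply(s$voxels, 1, paste, collapse = ","),
                  apply(both, 1, paste, collapse = ","))
  # isotropic background seed fails the start criterion
  expect_null(fact_track(c(2, 2, 2), ph$volume))
  expect_error(fact_track(c(0, 5, 5), ph$volume), "outside")
})

test_that("brute-force tracking is deterministic and duplicate-free", {
  ph <- straight_phantom()
  s1 <- brute_force_tracking(ph$volume)
  s2 <- brute_force_tracking(ph$volume)
  expect_identical(s1, s2)
  expect_gt(length(s1), 0)
  keys <- vapply(s1, function(s) {
    v <- s$voxels[order(s$voxels[, 1], s$voxels[, 2], s$voxels[, 3]), ,
                  drop = FALSE]
    paste(t(v), collapse = ",")
  }, "")
  expect_equal(anyDuplicated(keys), 0L)
  # every retained streamline respects the minimum length
  expect_true(all(vapply(s1, function(s) nrow(unique(s$voxels)), 1L) >= 5L))
  # an isotropic volume yields nothing
  bg <- make_dti_phantom(phantom_spec(shape = c(8L, 8L, 8L)))
  expect_length(brute_force_tracking(bg$volume), 0L)
})

test_that("a 90-degree crossing stops the track at the interface", {
  ph <- crossing_phantom()
  s <- fact_track(c(4, 12, 12), ph$volume)
  # the x-aligned arm is tracked; the y-aligned bundle (starting near
  # x = 14) is never entered because the turn would exceed 53.1 degrees
  expect_true(all(s$voxels[, 2] == 12))
  expect_lt(max(s$voxels[, 1]), 13)
})

test_that("multi-ROI selection keeps exactly the bundle's streamlines", {
  ph <- straight_phantom()
  sl <- brute_force_tracking(ph$volume)
  tr <- select_tract(sl, ph$rois[[1]], label = "straight")
  expect_equal(length(tr$streamlines), length(sl))
  # an off-bundle ROI excludes everything
  off <- array(FALSE, dim(ph$fa_map)); off[2, 2, 2] <- TRUE
  expect_length(select_tract(sl, list(off))$streamlines, 0L)
  # an exclusion mask covering a full cross-section empties the tract
  excl <- array(FALSE, dim(ph$fa_map)); excl[10, , ] <- TRUE
  kept <- select_tract(sl, ph$rois[[1]], exclusion_rois = list(excl))
  expect_length(kept$streamlines, 0L)
  expect_error(select_tract(sl, list()), "inclusion")
})

test_that("mean tract FA averages the union of visited voxels", {
  ph <- straight_phantom(fa = 0.7)
  sl <- brute_force_tracking(ph$volume)
  tr <- select_tract(sl, ph$rois[[1]], label = "straight")
  expect_equal(mean_tract_fa(tr, ph$fa_map), 0.7, tolerance = 1e-9)
  # hand case: two voxels with FA 0.2 and 0.4
  fa_map <- array(0, c(4, 4, 4))
  fa_map[1, 1, 1] <- 0.2; fa_map[2, 1, 1] <- 0.4
  tract <- structure(list(streamlines = list(
    list(voxels = rbind(c(1, 1, 1), c(2, 1, 1)))), label = "toy"),
    class = "tract_set")
  expect_equal(mean_tract_fa(tract, fa_map), 0.3)
  # duplicating a streamline cannot change the union average
  tract2 <- tract; tract2$streamlines <- c(tract$streamlines,
                                           tract$streamlines)
  expect_equal(mean_tract_fa(tract2, fa_map), 0.3)
  # but it does change the visit-weighted variant's denominator, not value
  expect_equal(mean_tract_fa(tract2, fa_map, weighted = TRUE), 0.3)
  empty <- structure(list(streamlines = list()), class = "tract_set")
  expect_error(mean_tract_fa(empty, fa_map), "empty")
})

test_that("bilateral averaging handles missing hemispheres", {
  expect_equal(bilateral_average(0.4, 0.6), 0.5)
  expect_equal(bilateral_average(0.37, 0.37), 0.37)
  expect_warning(v <- bilateral_average(0.4, NA), "missing")
  expect_equal(v, 0.4)
  expect_warning(v2 <- bilateral_average(NA, 0.52), "missing")
  expect_equal(v2, 0.52)
  expect_error(suppressWarnings(bilateral_average(NA, NA)), "both")
})

test_that("tensor volumes, maps and streamlines round-trip through disk", {
  ph <- straight_phantom(shape = c(10L, 10L, 10L))
  f <- tempfile(fileext = ".nii.gz")
  write_tensor_volume(ph$volume, f)
  back <- read_tensor_volume(f)
  expect_equal(back$data, ph$volume$data, tolerance = 1e-7)
  expect_equal(back$voxel_size, ph$volume$voxel_size)
  f2 <- tempfile(fileext = ".nii.gz")
  write_volume_3d(ph$fa_map, f2)
  expect_equal(read_volume_3d(f2), ph$fa_map, tolerance = 1e-7)
  sl <- brute_force_tracking(ph$volume)
  f3 <- tempfile(fileext = ".jsonl")
  write_streamlines_json(sl, f3, label = "straight")
  back_sl <- read_streamlines_json(f3)
  expect_equal(length(back_sl), length(sl))
  expect_equal(back_sl[[1]]$voxels, sl[[1]]$voxels)
  expect_equal(back_sl[[1]]$label, "straight")
})
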