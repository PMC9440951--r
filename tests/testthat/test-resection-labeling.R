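test_that("photo scale calibration uses the median pitch ratio", {
  expect_equal(calibrate_scale(50, pitch_mm = 10), 0.2)
  expect_equal(calibrate_scale(c(48, 50, 52), pitch_mm = 10), 0.2)
  expect_error(calibrate_scale(numeric(0)), "at least one")
})

test_that("signed distance is exact on an axis-aligned square", {
  sq <- unit_square_mm()
  expect_equal(signed_distance_2d(5, 5, sq), -5)
  expect_equal(signed_distance_2d(15, 5, sq), 5)
  expect_equal(signed_distance_2d(5, 12, sq), 2)
  expect_equal(signed_distance_2d(0, 5, sq), 0)
  expect_equal(signed_distance_2d(13, 14, sq), 5)  # corner distance
})

test_that("signed distance agrees with a dense boundary-sampling oracle", {
  poly <- resection_outline(rbind(c(0, 0), c(22, -3), c(30, 14), c(16, 26),
                                  c(-4, 18)))
  set.seed(11)
  px <- runif(1000, -10, 40)
  py <- runif(1000, -12, 32)
  got <- signed_distance_2d(px, py, poly)
  pts <- poly_boundary_points(poly$vertices, step = 0.008)
  want <- vapply(seq_along(px),
                 function(i) poly_distance_oracle(px[i], py[i], poly$vertices,
                                                  pts),
                 numeric(1))
  expect_lt(max(abs(got - want)), 0.01)
})

test_that("self-intersecting outlines are rejected", {
  expect_error(resection_outline(rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10))),
               "self-intersecting")
  expect_error(resection_outline(rbind(c(0, 0), c(1, 1))), "3 vertices")
})

test_that("classification thresholds follow the disc-overlap and edge-band rules", {
  # place single contacts at controlled signed distances from the square
  sq <- unit_square_mm()
  at <- function(x, y, r = 2) {
    classify_2d(electrode_plan("E1", x, y, radius = r), sq)
  }
  deep <- at(5, 5)            # d = -5, fully interior
  expect_true(deep$resected); expect_false(deep$edge)

  on_edge <- at(10, 5)        # d = 0, partly on top
  expect_true(on_edge$resected); expect_true(on_edge$edge)

  near <- at(16, 5)           # d = +6, gap 4 <= 5
  expect_false(near$resected); expect_true(near$edge)

  far <- at(18, 5)            # d = +8, gap 6 > 5
  expect_false(far$resected); expect_false(far$edge)

  # inclusive threshold: gap exactly 5 mm is edge, epsilon beyond is not
  exact <- at(17, 5)          # d = +7, gap exactly 5
  expect_true(exact$edge)
  beyond <- at(17.001, 5)
  expect_false(beyond$edge)
})

test_that("cavity membership suppresses resected and edge", {
  sq <- unit_square_mm()
  cav <- resection_outline(rbind(c(4, 4), c(6, 4), c(6, 6), c(4, 6)))
  plan <- electrode_plan(c("A", "B"), x = c(5, 2), y = c(5, 2))
  labels <- classify_2d(plan, sq, cavities = list(cav))
  expect_true(labels$cavity[1])
  expect_false(labels$resected[1]); expect_false(labels$edge[1])
  expect_false(labels$cavity[2]); expect_true(labels$resected[2])
})

test_that("moving a contact inward never loses the resected label", {
  poly <- resection_outline(rbind(c(0, 0), c(30, 0), c(30, 20), c(0, 20)))
  centroid <- c(15, 10)
  for (start in list(c(-4, 10), c(15, 27), c(34, 10))) {
    steps <- seq(0, 1, by = 0.05)
    resected_seq <- vapply(steps, function(a) {
      p <- (1 - a) * start + a * centroid
      classify_2d(electrode_plan("E", p[1], p[2]), poly)$resected
    }, logical(1))
    expect_true(all(diff(resected_seq) >= 0))  # FALSE -> TRUE only
  }
})

test_that("3D classification matches sphere geometry within a voxel diagonal", {
  n <- 30L; vox <- 2
  ax <- (seq_len(n) - 1) * vox
  grid <- expand.grid(x = ax, y = ax, z = ax)
  center <- c(29, 29, 29); radius <- 20
  inside <- (grid$x - center[1])^2 + (grid$y - center[2])^2 +
    (grid$z - center[3])^2 <= radius^2
  mask <- resection_mask(array(inside, c(n, n, n)), diag(c(vox, vox, vox, 1)))

  labels <- classify_3d("deep", matrix(center, 1), mask)
  expect_true(labels$resected); expect_false(labels$edge)

  # 4 mm outside the surface with r = 1: gap 3 mm <= 5 -> edge
  p_out <- center + c(radius + 4, 0, 0)
  lab2 <- classify_3d("near", matrix(p_out, 1), mask, radius = 1)
  expect_false(lab2$resected); expect_true(lab2$edge)
  d <- signed_distance_3d(matrix(p_out, 1), mask)
  expect_lt(abs(d - 4), sqrt(3) * vox)

  cavity <- (grid$x - 9)^2 + (grid$y - 9)^2 + (grid$z - 9)^2 <= 36
  mask2 <- resection_mask(array(inside, c(n, n, n)), diag(c(vox, vox, vox, 1)),
                          cavity_masks = list(array(cavity, c(n, n, n))))
  lab3 <- classify_3d("cav", matrix(c(9, 9, 9), 1), mask2)
  expect_true(lab3$cavity); expect_false(lab3$resected)
})

test_that("an extruded polygon mask reproduces the 2D labels in its mid-plane", {
  poly <- resection_outline(rbind(c(6, 6), c(34, 6), c(34, 26), c(6, 26)))
  n <- 30L; vox <- 2
  ax <- (seq_len(n) - 1) * vox
  inside2d <- outer(ax, ax, Vectorize(function(x, y) {
    signed_distance_2d(x, y, poly) < 0
  }))
  vol <- array(FALSE, c(n, n, n))
  for (k in 5:25) vol[, , k] <- inside2d
  mask <- resection_mask(vol, diag(c(vox, vox, vox, 1)))

  plan <- grid_plan_4x5()
  plan$x <- plan$x + 1; plan$y <- plan$y + 1  # avoid exact-boundary ties
  lab2d <- classify_2d(plan, poly)
  z_mid <- 15 * vox
  lab3d <- classify_3d(plan$label, cbind(plan$x, plan$y, z_mid), mask)
  expect_equal(lab3d$resected, lab2d$resected)
  expect_equal(lab3d$cavity, lab2d$cavity)
})

test_that("outlines round-trip through GeoJSON", {
  poly <- resection_outline(rbind(c(0, 0), c(12.5, -1), c(15, 9), c(2, 11)),
                            provenance = "sit1A_photo.jpg")
  f <- withr::local_tempfile(fileext = ".geojson")
  write_outline_geojson(poly, f)
  back <- read_outline_geojson(f)
  expect_equal(back$vertices, poly$vertices)
  expect_equal(back$provenance, "sit1A_photo.jpg")
})

test_that("NIfTI resection volumes load with their affine", {
  n <- 12L
  arr <- array(0L, c(n, n, n)); arr[4:9, 4:9, 4:9] <- 1L
  img <- RNifti::asNifti(arr)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, f)
  mask <- read_mask_nifti(f)
  expect_true(is.logical(mask$voxels))
  expect_equal(sum(mask$voxels), 6L^3)
  lab <- classify_3d("mid", matrix(c(6, 6, 6), 1), mask)
  expect_true(lab$resected)
})
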