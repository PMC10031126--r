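test_that("plane construction yields a right-handed orthonormal basis", {
  pl <- define_plane(c(0, 0, 0), c(0, 0, 2), c(0, 1, 0))
  expect_equal(pl$normal, c(0, 0, 1))
  expect_equal(pl$u_axis, c(1, 0, 0))
  expect_equal(pl$v_axis, c(0, 1, 0))

  # up with a normal-parallel component reduces to its orthogonal part
  pl2 <- define_plane(c(0, 0, 0), c(0, 0, 1), c(0, 1, 5))
  expect_equal(pl2$v_axis, c(0, 1, 0), tolerance = 1e-12)

  set.seed(17)
  for (rep in 1:20) {
    n <- stats::rnorm(3); up <- stats::rnorm(3)
    pl3 <- define_plane(stats::rnorm(3), n, up)
    expect_lt(abs(sum(pl3$u_axis * pl3$v_axis)), 1e-12)
    expect_lt(abs(sum(pl3$u_axis * pl3$normal)), 1e-12)
    expect_lt(abs(sum(pl3$v_axis * pl3$normal)), 1e-12)
    expect_equal(stcube:::cross3(pl3$u_axis, pl3$v_axis), pl3$normal,
                 tolerance = 1e-12)
  }
  expect_error(define_plane(c(0, 0, 0), c(0, 0, 0)), class = "stcValidationError")
  expect_error(define_plane(c(0, 0, 0), c(0, 0, 1), c(0, 0, -3)),
               class = "stcValidationError")
})

test_that("the fitted frame is the union of per-time cross-section bounds", {
  pl <- define_plane(c(0, 0, 0), c(0, 0, 1))
  static <- sphere_dataset(list(list(c(0, 0, 0))), list(1L), subdiv = 3L)
  fr <- fit_frame(static, pl, c(64L, 64L), margin_fraction = 0)
  expect_equal(fr$width, 2, tolerance = 0.01)   # analytic circle bound
  expect_equal(fr$height, 2, tolerance = 0.01)

  moving <- sphere_dataset(list(list(c(0, 0, 0)), list(c(1.5, 0, 0))),
                           list(1L, 1L), subdiv = 3L)
  fr2 <- fit_frame(moving, pl, c(64L, 64L), margin_fraction = 0)
  expect_equal(fr2$width, 2 + 1.5, tolerance = 0.01)

  fr3 <- fit_frame(static, pl, c(64L, 64L), margin_fraction = 0.02)
  expect_equal(fr3$width / fr$width, 1.04, tolerance = 1e-6)

  off_plane <- define_plane(c(0, 0, 50), c(0, 0, 1))
  expect_error(fit_frame(static, off_plane, c(64L, 64L)),
               class = "stcEmptyFrameError")
})

test_that("filled-mode rasterization matches the analytic disc", {
  pl <- define_plane(c(0, 0, 0), c(0, 0, 1))
  ds <- sphere_dataset(list(list(c(0, 0, 0))), list(7L), subdiv = 3L)
  fr <- fit_frame(ds, pl, c(128L, 128L), margin_fraction = 0.05)
  img <- rasterize_cross_section(ds, 0L, pl, fr, "filled")
  area <- sum(img == 7L) * fr$pixel_size^2
  expect_lt(abs(area - pi) / pi, 0.02)

  # dense point-in-sphere sampling oracle on the same pixel lattice
  grid <- as.matrix(expand.grid(i = 1:128, j = 1:128))
  ctrs <- pixel_centers(fr, grid[, 1L], grid[, 2L])
  inside <- rowSums(ctrs^2) < 1
  agree <- mean((unclass(img)[grid] == 7L) == inside)
  expect_gt(agree, 0.99)
})

test_that("membrane mode labels an annulus with an empty interior", {
  pl <- define_plane(c(0, 0, 0), c(0, 0, 1))
  ds <- sphere_dataset(list(list(c(0, 0, 0))), list(7L), subdiv = 3L)
  fr <- fit_frame(ds, pl, c(128L, 128L), margin_fraction = 0.05)
  img <- rasterize_cross_section(ds, 0L, pl, fr, "membrane")
  expect_gt(sum(img == 7L), 0)
  grid <- as.matrix(expand.grid(i = 1:128, j = 1:128))
  r <- sqrt(rowSums(pixel_centers(fr, grid[, 1L], grid[, 2L])^2))
  interior <- grid[r < 1 - 2 * fr$pixel_size, , drop = FALSE]
  expect_identical(sum(unclass(img)[interior]), 0L)
  # labeled pixels sit near the surface (distance-to-surface oracle)
  lab <- grid[unclass(img)[grid] == 7L, , drop = FALSE]
  delta <- max(fr$eps, fr$pixel_size * sqrt(2) / 2)
  expect_true(all(abs(r[unclass(img)[grid] == 7L] - 1) < delta + 0.02))
})

test_that("contested pixels go to the smallest id", {
  pl <- define_plane(c(0, 0, 0), c(0, 0, 1))
  ds <- sphere_dataset(list(list(c(-0.4, 0, 0), c(0.4, 0, 0))),
                       list(c(3L, 9L)), subdiv = 2L)
  fr <- fit_frame(ds, pl, c(96L, 96L))
  img <- rasterize_cross_section(ds, 0L, pl, fr, "filled")
  only3 <- sphere_dataset(list(list(c(-0.4, 0, 0))), list(3L), subdiv = 2L)
  only9 <- sphere_dataset(list(list(c(0.4, 0, 0))), list(9L), subdiv = 2L)
  img3 <- rasterize_cross_section(only3, 0L, pl, fr, "filled")
  img9 <- rasterize_cross_section(only9, 0L, pl, fr, "filled")
  contested <- img3 == 3L & img9 == 9L
  expect_gt(sum(contested), 0)
  expect_true(all(img[contested] == 3L))
})

test_that("a frame not touched by any object rasterizes to background", {
  pl <- define_plane(c(0, 0, 0), c(0, 0, 1))
  ds <- sphere_dataset(list(list(c(0, 0, 0)), list(c(0, 0, 5))),
                       list(1L, 1L), subdiv = 2L)
  fr <- fit_frame(ds, pl, c(32L, 32L))
  img <- rasterize_cross_section(ds, 1L, pl, fr, "filled")
  expect_true(all(img == 0L))
})

test_that("non-watertight meshes are skipped with a warning in filled mode", {
  s <- icosphere(2L)
  holed <- stc_mesh(s$vertices, s$faces[-1L, ])
  ds <- suppressWarnings(temporal_dataset(list(list(labeled_object(1L, holed)))))
  pl <- define_plane(c(0, 0, 0), c(0, 0, 1))
  fr <- fit_frame(ds, pl, c(32L, 32L))
  expect_warning(img <- rasterize_cross_section(ds, 0L, pl, fr, "filled"),
                 "not watertight")
  expect_true(all(img == 0L))
})

test_that("the STC stacks slices that are bit-identical to direct rasterization", {
  sim <- cached_sim()
  pl <- define_plane(c(0, 0, 0), c(0.2, 0.1, 1))
  stc <- build_stc(sim$dataset, pl, c(48L, 48L), "membrane")
  for (k in seq_along(sim$dataset$times)) {
    direct <- rasterize_cross_section(sim$dataset, sim$dataset$times[k], pl,
                                      stc$frame, "membrane")
    expect_identical(stc$labels[, , k], strip_label(direct))
  }
})

test_that("a static sphere projects to a cylinder and T = 1 to a single slice", {
  pl <- define_plane(c(0, 0, 0), c(0, 0, 1))
  ds10 <- sphere_dataset(rep(list(list(c(0, 0, 0))), 10L),
                         rep(list(1L), 10L), subdiv = 2L)
  stc <- build_stc(ds10, pl, c(48L, 48L), "filled")
  expect_identical(dim(stc$labels), c(48L, 48L, 10L))
  for (k in 2:10)
    expect_identical(stc$labels[, , k], stc$labels[, , 1L])

  ds1 <- sphere_dataset(list(list(c(0, 0, 0))), list(1L), subdiv = 2L)
  expect_identical(dim(build_stc(ds1, pl, c(16L, 16L), "filled")$labels)[3L], 1L)
})

test_that("the default resolution over 100 frames yields a 256 x 256 x 100 volume", {
  pl <- define_plane(c(0, 0, 0), c(0, 0, 1))
  ds <- sphere_dataset(rep(list(list(c(0, 0, 0))), 100L),
                       rep(list(1L), 100L), subdiv = 2L)
  stc <- build_stc(ds, pl, mode = "filled")
  expect_identical(dim(stc$labels), c(256L, 256L, 100L))
})

test_that("pixel-center geometry introduces no spatial distortion", {
  sim <- cached_sim()
  pl <- define_plane(c(0.1, -0.2, 0), c(1, 2, 0.5), c(0, 0, 1))
  fr <- fit_frame(sim$dataset, pl, c(64L, 64L))
  set.seed(31)
  for (rep in 1:50) {
    ij <- matrix(sample(64L, 4L, replace = TRUE), 2L)
    p <- pixel_centers(fr, ij[, 1L], ij[, 2L])
    world_d <- sqrt(sum((p[1L, ] - p[2L, ])^2))
    grid_d <- sqrt(sum((ij[1L, ] - ij[2L, ])^2)) * fr$pixel_size
    expect_lt(abs(world_d - grid_d), 1e-9)
  }
})

test_that("enlarging the slab never removes a membrane pixel", {
  sim <- cached_sim()
  pl <- define_plane(c(0, 0, 0), c(0, 0, 1))
  fr1 <- fit_frame(sim$dataset, pl, c(48L, 48L), eps = 0.02)
  fr2 <- fr1; fr2$eps <- 0.1
  img1 <- rasterize_cross_section(sim$dataset, 6L, pl, fr1, "membrane")
  img2 <- rasterize_cross_section(sim$dataset, 6L, pl, fr2, "membrane")
  expect_true(all(img2[img1 != 0L] != 0L))
  expect_gte(sum(img2 != 0L), sum(img1 != 0L))
})

test_that("label-volume datasets are resampled by nearest neighbor", {
  vol <- array(0L, c(10L, 10L, 10L))
  vol[3:7, 3:7, 4:6] <- 5L
  vol[8:9, 8:9, 4:6] <- 2L
  ds <- label_volume_dataset(list(vol), origin = c(0, 0, 0),
                             spacing = c(1, 1, 1))
  pl <- define_plane(c(5, 5, 5), c(0, 0, 1))
  fr <- fit_frame(ds, pl, c(40L, 40L), margin_fraction = 0)
  img <- rasterize_cross_section(ds, 0L, pl, fr, "filled")
  expect_setequal(setdiff(unique(as.vector(img)), 0L), c(5L, 2L))
  # label at an interior pixel equals the enclosing voxel's label exactly
  grid <- as.matrix(expand.grid(i = 1:40, j = 1:40))
  ctr <- pixel_centers(fr, grid[, 1L], grid[, 2L])
  vox <- floor(ctr) + 1
  ok <- vox[, 1L] >= 1 & vox[, 1L] <= 10 & vox[, 2L] >= 1 & vox[, 2L] <= 10
  expected <- integer(nrow(grid))
  expected[ok] <- vol[cbind(vox[ok, 1L], vox[ok, 2L], vox[ok, 3L])]
  expect_identical(as.integer(unclass(img)[grid]), expected)
})

test_that("the projection is deterministic", {
  sim <- cached_sim()
  pl <- define_plane(c(0, 0, 0), c(0.3, -0.1, 1))
  a <- build_stc(sim$dataset, pl, c(32L, 32L), "membrane")
  b <- build_stc(sim$dataset, pl, c(32L, 32L), "membrane")
  expect_identical(serialize(a, NULL), serialize(b, NULL))
})
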