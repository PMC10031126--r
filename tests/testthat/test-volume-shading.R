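test_that("normals vanish on uniform volumes and align with a step edge", {
  empty <- wrap_stc(array(0L, c(8L, 8L, 8L)))
  n0 <- compute_normals(empty)
  expect_true(all(n0 == 0))

  # half-space occupied for k <= 4: the only gradient is along the time axis
  half <- array(0L, c(8L, 8L, 8L)); half[, , 1:4] <- 1L
  nh <- compute_normals(wrap_stc(half))
  lens <- sqrt(nh[, , , 1L]^2 + nh[, , , 2L]^2 + nh[, , , 3L]^2)
  nz <- which(lens > 0, arr.ind = TRUE)
  expect_gt(nrow(nz), 0)
  expect_true(all(nh[cbind(nz, 1L)] == 0))
  expect_true(all(nh[cbind(nz, 2L)] == 0))
  expect_true(all(abs(abs(nh[cbind(nz, 3L)]) - 1) < 1e-12))
  # outward orientation: normals at the boundary point into the empty side
  boundary <- nz[nz[, 3L] == 5L, , drop = FALSE]
  expect_true(all(nh[cbind(boundary, 3L)] > 0))
})

test_that("normal unit-length invariant holds and complementation flips signs", {
  sim <- cached_sim()
  pl <- define_plane(c(0, 0, 0), c(0, 0, 1))
  stc <- build_stc(sim$dataset, pl, c(32L, 32L), "filled")
  n1 <- compute_normals(stc)
  lens <- sqrt(n1[, , , 1L]^2 + n1[, , , 2L]^2 + n1[, , , 3L]^2)
  expect_true(all(abs(lens[lens > 0] - 1) < 1e-6))

  flipped <- stc
  flipped$labels <- array(ifelse(stc$labels == 0L, 1L, 0L), dim(stc$labels))
  n2 <- compute_normals(flipped)
  expect_equal(unclass(n2), -unclass(n1), tolerance = 1e-9)
})

test_that("value lookups map range endpoints, missing entries and categories stably", {
  ann <- annotation_table(data.frame(
    property = "volume", id = c(1L, 2L, 3L), t = 0L, value = c(10, 55, 100)))
  lk <- build_lookup(ann, "volume", colormap = "viridis")
  pal <- grDevices::hcl.colors(256L, "viridis")
  expect_identical(lookup_color(lk, 1L, 0L), pal[1L])
  expect_identical(lookup_color(lk, 3L, 0L), pal[256L])
  expect_identical(lookup_color(lk, 9L, 5L), lk$sentinel)
  expect_true(is.na(lookup_value(lk, 9L, 5L)))
  expect_error(build_lookup(ann, "no_such_property"), class = "stcNotFoundError")

  cat_ann <- annotation_table(data.frame(
    property = "fate", id = c(1L, 2L), t = 0L,
    value = c("endoderm", "ectoderm"), stringsAsFactors = FALSE))
  a <- build_lookup(cat_ann, "fate")
  b <- build_lookup(cat_ann, "fate")
  expect_identical(a$colors, b$colors)
  expect_false(lookup_color(a, 1L, 0L) == lookup_color(a, 2L, 0L))
})

test_that("switching the mapped property leaves the STC and normals untouched", {
  sim <- cached_sim()
  pl <- define_plane(c(0, 0, 0), c(0, 0, 1))
  stc <- build_stc(sim$dataset, pl, c(24L, 24L), "filled")
  nrm <- compute_normals(stc)
  before <- list(serialize(stc, NULL), serialize(nrm, NULL))
  lk1 <- build_lookup(sim$annotations, "volume")
  lk2 <- build_lookup(sim$annotations, "remaining_lifespan")
  expect_false(identical(lk1$values, lk2$values))
  expect_identical(serialize(stc, NULL), before[[1L]])
  expect_identical(serialize(nrm, NULL), before[[2L]])
})

test_that("a lit step face shades to (ka + kd) * C exactly", {
  labels <- array(0L, c(5L, 5L, 6L)); labels[, , 1:3] <- 4L
  stc <- wrap_stc(labels)
  nrm <- compute_normals(stc)
  ann <- annotation_table(data.frame(property = "p", id = 4L,
                                     t = 0:5, value = 1))
  lk <- build_lookup(ann, "p")
  C <- unname(grDevices::col2rgb(lookup_color(lk, 4L, 2L))[, 1L] / 255)
  set <- render_settings(view_dir = c(0, 0, -1), image_size = c(5L, 5L),
                         light = c(2.5, 2.5, 100), ks = 0)
  img <- render_stc(stc, nrm, lk, set)
  # center pixel: hit on the k = 3 face, normal +z, light head-on
  got <- img[3L, 3L, ]
  expect_equal(got, pmin((set$ka + set$kd) * C, 1), tolerance = 1e-9)
})

test_that("the renderer's first hit matches a brute-force fine-step marcher", {
  set.seed(1234)
  labels <- array(0L, c(16L, 16L, 16L))
  labels[sample(length(labels), 500L)] <- sample.int(9L, 500L, replace = TRUE)
  stc <- wrap_stc(labels)
  settings <- render_settings(view_dir = c(0, 0, -1), image_size = c(16L, 16L))
  fh <- first_hit_map(stc, settings)
  oracle <- brute_first_hit(labels)
  for (i in 1:16) for (j in 1:16)
    expect_identical(fh$voxel[(j - 1L) * 16L + i, ], oracle[i, j, ])
})

test_that("opacity: voxels behind the first hit never change the image", {
  set.seed(77)
  labels <- array(0L, c(12L, 12L, 12L))
  labels[sample(length(labels), 300L)] <- sample.int(5L, 300L, replace = TRUE)
  stc <- wrap_stc(labels)
  nrm <- compute_normals(stc)
  settings <- render_settings(view_dir = c(0, 0, -1), image_size = c(12L, 12L))
  img <- render_stc(stc, nrm, settings = settings)
  fh <- attr(img, "hits")
  hit <- fh$voxel[!is.na(fh$voxel[, 1L]), , drop = FALSE]
  mutated <- labels
  for (q in seq_len(nrow(hit))) {
    v <- hit[q, ]
    if (v[3L] > 1L) mutated[v[1L], v[2L], seq_len(v[3L] - 1L)] <- 3L
  }
  stc2 <- stc; stc2$labels <- mutated
  img2 <- render_stc(stc2, nrm, settings = settings)
  expect_identical(as.vector(img), as.vector(img2))
})

test_that("moving the light changes shading but not the hit map", {
  sim <- cached_sim()
  pl <- define_plane(c(0, 0, 0), c(0, 0, 1))
  stc <- build_stc(sim$dataset, pl, c(24L, 24L), "filled")
  nrm <- compute_normals(stc)
  s1 <- render_settings(view_dir = c(-0.4, -0.3, -0.9),
                        image_size = c(24L, 24L), light = c(50, 10, 40))
  s2 <- render_settings(view_dir = c(-0.4, -0.3, -0.9),
                        image_size = c(24L, 24L), light = c(-40, 60, -10))
  i1 <- render_stc(stc, nrm, settings = s1)
  i2 <- render_stc(stc, nrm, settings = s2)
  expect_identical(attr(i1, "hits")$voxel, attr(i2, "hits")$voxel)
  expect_false(identical(as.vector(i1), as.vector(i2)))
})

test_that("cuts zero exactly the discarded half-space", {
  set.seed(5)
  labels <- array(sample(0:3, 6 * 5 * 7, replace = TRUE), c(6L, 5L, 7L))
  stc <- wrap_stc(labels)

  far <- cut_spec(c(-100, 0, 0), c(1, 0, 0), "positive")
  expect_identical(cut_stc(stc, far)$labels, labels)

  tc <- cut_spec(c(0, 0, 4), c(0, 0, -1), "positive")  # keep slices k <= 4
  cut <- cut_stc(stc, tc)
  expect_identical(cut$labels[, , 1:4], labels[, , 1:4])
  expect_true(all(cut$labels[, , 5:7] == 0L))

  obl <- cut_spec(c(3, 2.5, 3.5), c(1, -0.7, 0.4), "negative")
  got <- cut_stc(stc, obl)$labels
  for (i in 1:6) for (j in 1:5) for (k in 1:7) {
    d <- sum((c(i, j, k) - 0.5 - obl$point) * obl$normal)
    expect_identical(got[i, j, k], if (d < 0) labels[i, j, k] else 0L)
  }
  # idempotence and complement partition
  expect_identical(cut_stc(cut_stc(stc, obl), obl)$labels, got)
  comp <- cut_spec(obl$point, obl$normal, "positive")
  got_c <- cut_stc(stc, comp)$labels
  expect_true(all((got != 0L) + (got_c != 0L) == (labels != 0L)))
})

test_that("voxel queries report object, value and lineage context", {
  sim <- cached_sim()
  pl <- define_plane(c(0, 0, 0), c(0, 0, 1))
  stc <- build_stc(sim$dataset, pl, c(32L, 32L), "filled")
  lk <- build_lookup(sim$annotations, "volume")
  root_vox <- which(stc$labels == 1L, arr.ind = TRUE)[1L, ]
  rec <- query_voxel(stc, root_vox, lookup = lk, lineage = sim$lineage,
                     annotations = sim$annotations)
  expect_false(rec$background)
  expect_identical(rec$id, 1L)
  expect_identical(rec$time, stc$times[root_vox[3L]])
  expect_identical(sort(rec$children), c(2L, 3L))
  truth <- sim$annotations$table
  expect_equal(rec$value,
               truth$value[truth$property == "volume" & truth$id == 1L &
                             truth$t == rec$time])

  bg <- which(stc$labels == 0L, arr.ind = TRUE)[1L, ]
  expect_true(query_voxel(stc, bg)$background)
  expect_error(query_voxel(stc, c(0L, 1L, 1L)), class = "stcValidationError")
})

test_that("render settings validate their coefficients", {
  expect_error(render_settings(view_dir = c(0, 0, 0)), class = "stcValidationError")
  expect_error(render_settings(ka = -0.1), class = "stcValidationError")
  expect_error(render_settings(ka = 0.9, kd = 0.9), class = "stcValidationError")
  expect_s3_class(render_settings(ka = 0.9, kd = 0.9, override_energy = TRUE),
                  "stc_render_settings")
})
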