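test_that("upsampling doubles every axis, interpolates, and halves the voxel", {
  set.seed(11)
  v <- ct_volume(array(runif(10 * 20 * 30), c(10, 20, 30)), 50)
  up <- upsample2x(v)
  expect_equal(dim(up), c(20L, 40L, 60L))
  expect_equal(length(up) / length(v), 8)
  expect_equal(voxel_size_um(up), 25)

  const <- upsample2x(ct_volume(array(7, c(3, 3, 3)), 50))
  expect_true(all(const == 7))

  ramp <- ct_volume(array(c(0, 2, 4), c(1, 1, 3)), 50)
  expect_true(all(c(1, 3) %in% as.vector(upsample2x(ramp))))
})

test_that("Sobel magnitude matches hand-computed step and ramp values", {
  const <- sobel_edges2d(ct_volume(array(9, c(2, 6, 6)), 10))
  expect_true(all(const[, 2:5, 2:5] == 0))

  h <- 7
  m <- array(0, c(1, 5, 6)); m[1, , 4:6] <- h       # vertical step edge
  g <- sobel_edges2d(ct_volume(m, 10))
  expect_equal(as.vector(g[1, 2:4, 3]), rep(4 * h, 3))
  expect_equal(as.vector(g[1, 2:4, 4]), rep(4 * h, 3))
  expect_true(all(g[1, 2:4, c(2, 5)] == 0))

  s <- 3
  r <- array(rep((0:5) * s, each = 5), c(1, 5, 6))  # ramp along x
  gr <- sobel_edges2d(ct_volume(r, 10))
  expect_equal(as.vector(gr[1, 2:4, 2:5]), rep(8 * s, 12))
})

test_that("isodata threshold satisfies the intermeans fixed point", {
  expect_equal(isodata_threshold(c(rep(0, 900), rep(100, 100))), 50)
  expect_equal(isodata_threshold(c(10, 30)), 20)
  expect_error(isodata_threshold(rep(5, 10)), "degenerate")

  for (seed in 1:5) {
    set.seed(seed)
    v <- c(rnorm(800, 20, 5), rnorm(200, 80, 10))
    t <- isodata_threshold(v)
    expect_lt(intermeans_residual(v, t), 0.5)
    # brute-force scan: no candidate threshold sits at a fixed point far away
    grid <- seq(min(v), max(v), length.out = 400)
    fixed <- grid[vapply(grid, function(g) intermeans_residual(v, g), 0) < 0.5]
    expect_lt(min(abs(fixed - t)), diff(range(v)) / 100)
  }
  # the histogram-accumulated large-input path agrees with the exact one
  set.seed(99)
  big <- c(rnorm(9e5, 20, 5), rnorm(3e5, 80, 10))
  expect_lt(abs(isodata_threshold(big) - isodata_threshold(big[seq(1, 12e5)])), 1e-9)
  expect_lt(intermeans_residual(big, isodata_threshold(big)), 0.5)
})

test_that("the PVE mask excludes sharp interfaces but not subtle ones", {
  expect_equal(sum(pve_mask(sobel_edges2d(ct_volume(array(5, c(2, 8, 8)), 10)))), 0)

  # one sharp (air/soil) and one subtle (root/soil) step in each slice
  m <- array(30000, c(4, 9, 30))
  m[, , 1:8] <- 5000          # air band: contrast 25000 at column 8/9
  m[, , 20:30] <- 22000       # root band: contrast 8000 at column 19/20
  g <- sobel_edges2d(ct_volume(m, 10))
  mask <- pve_mask(g)
  expect_true(all(mask[, 3:7, 8:9] == 1))    # sharp edge masked
  expect_true(all(mask[, 3:7, 19:20] == 0))  # subtle edge kept
  t <- attr(mask, "threshold_used")
  expect_equal(sum(mask), sum(unclass(g) > t))  # oracle recount
})

test_that("bilevel threshold uses inclusive bounds and honors the mask", {
  v <- ct_volume(array(c(17999, 18000, 22000, 26000, 26001, 30000),
                       c(6, 1, 1)), 65)
  b <- bilevel_threshold(v, c(18000, 26000))
  expect_equal(as.vector(b), c(0L, 1L, 1L, 1L, 0L, 0L))

  mask <- ct_binary(array(c(0L, 1L, 0L, 0L, 0L, 0L), c(6, 1, 1)), 65)
  class(mask) <- c("pve_mask", class(mask))
  bm <- bilevel_threshold(v, c(18000, 26000), mask)
  expect_equal(as.vector(bm), c(0L, 0L, 1L, 1L, 0L, 0L))

  set.seed(12)
  r <- ct_volume(array(runif(1000, 0, 100), c(10, 10, 10)), 65)
  br <- bilevel_threshold(r, c(30, 60))
  expect_equal(sum(br), sum(unclass(r) >= 30 & unclass(r) <= 60))
})

test_that("median3d matches the brute-force majority vote", {
  lone <- array(0L, c(7, 7, 7)); lone[4, 4, 4] <- 1L
  expect_equal(sum(median3d(ct_binary(lone, 65))), 0)

  cube <- array(0L, c(9, 9, 9)); cube[3:7, 3:7, 3:7] <- 1L
  out <- median3d(ct_binary(cube, 65))
  expect_true(all(out[4:6, 4:6, 4:6] == 1))

  for (seed in 1:4) {
    a <- rand_binary(c(12, 10, 11), 0.5, seed)
    expect_equal(unclass(median3d(ct_binary(a, 65))), oracle_median3d(a),
                 ignore_attr = TRUE)
  }
  a20 <- rand_binary(c(20, 20, 20), 0.4, 55)
  expect_equal(unclass(median3d(ct_binary(a20, 65))), oracle_median3d(a20),
               ignore_attr = TRUE)
})

test_that("erode3d matches the brute-force cross erosion", {
  a <- rand_binary(c(10, 10, 10), 0.6, 20)
  expect_equal(unclass(erode3d(ct_binary(a, 65), 0)), a, ignore_attr = TRUE)

  fil <- array(0L, c(12, 5, 5)); fil[2:11, 3, 3] <- 1L
  expect_equal(sum(erode3d(ct_binary(fil, 65), 1)), 0)

  ball <- array(0L, c(15, 15, 15))
  for (z in 1:15) for (y in 1:15) for (x in 1:15)
    if ((z - 8)^2 + (y - 8)^2 + (x - 8)^2 <= 25) ball[z, y, x] <- 1L
  expect_equal(unclass(erode3d(ct_binary(ball, 65), 1)), oracle_erode_cross(ball),
               ignore_attr = TRUE)
  for (seed in 5:7) {
    a <- rand_binary(c(14, 13, 12), 0.7, seed)
    expect_equal(unclass(erode3d(ct_binary(a, 65), 1)), oracle_erode_cross(a),
                 ignore_attr = TRUE)
  }
  # cube kernel is strictly stronger than the cross
  a <- rand_binary(c(12, 12, 12), 0.8, 30)
  expect_true(all(erode3d(ct_binary(a, 65), 1, "cube") <=
                  erode3d(ct_binary(a, 65), 1, "cross")))
})

test_that("seeded extraction matches a brute-force flood fill", {
  two <- array(0L, c(10, 10, 10))
  two[2:4, 2:4, 2:4] <- 1L
  two[7:9, 7:9, 7:9] <- 1L
  got <- extract_connected(ct_binary(two, 65), c(3, 3, 3))
  expect_equal(sum(got), 27)
  expect_true(all(got[7:9, 7:9, 7:9] == 0))

  expect_error(extract_connected(ct_binary(two, 65), c(6, 6, 6)),
               "background.*nearest foreground")

  corner <- array(0L, c(4, 4, 4))
  corner[1, 1, 1] <- 1L; corner[2, 2, 2] <- 1L   # touch only at a corner
  expect_equal(sum(extract_connected(ct_binary(corner, 65), c(1, 1, 1))), 2)
  expect_equal(sum(extract_connected(ct_binary(corner, 65), c(1, 1, 1),
                                     connectivity = 6)), 1)

  for (seed in 8:10) {
    a <- rand_binary(c(10, 10, 10), 0.3, seed)
    fg <- which(a == 1L, arr.ind = TRUE)
    s <- fg[1, ]
    expect_equal(unclass(extract_connected(ct_binary(a, 65), s)),
                 oracle_flood26(a, s), ignore_attr = TRUE)
  }
})

test_that("bin_max keeps any-foreground blocks and doubles the voxel size", {
  a <- array(0L, c(4, 4, 4)); a[1, 2, 2] <- 1L
  out <- bin_max(ct_binary(a, 32.5))
  expect_equal(dim(out), c(2L, 2L, 2L))
  expect_equal(as.vector(out[1, 1, 1]), 1L)
  expect_equal(sum(out), 1)
  expect_equal(voxel_size_um(out), 65)

  # odd dimensions pad with background
  b <- array(1L, c(3, 3, 3))
  expect_equal(dim(bin_max(ct_binary(b, 10))), c(2L, 2L, 2L))

  for (seed in 11:13) {
    a <- rand_binary(c(8, 8, 8), 0.2, seed)
    bin <- ct_binary(a, 65)
    up <- upsample2x(ct_volume(array(as.double(a), dim(a)), 65))
    rebinned <- bin_max(ct_binary(array(as.integer(up >= 1), dim(up)), 32.5))
    expect_true(all(unclass(rebinned) >= a))   # superset of the original
  }
})

test_that("stages pass empty volumes through and never invent foreground", {
  empty <- ct_binary(array(0L, c(8, 8, 8)), 65)
  expect_equal(sum(median3d(empty)), 0)
  expect_equal(sum(erode3d(empty, 2)), 0)
  expect_equal(sum(bin_max(empty)), 0)
  expect_equal(sum(skeletonize3d(empty)), 0)
  expect_error(extract_connected(empty, c(1, 1, 1)), "no foreground")

  a <- rand_binary(c(10, 10, 10), 0.15, 40)
  med <- median3d(ct_binary(a, 65))
  for (v in which(med == 1L & a == 0L)) {
    idx <- arrayInd(v, dim(a))
    zz <- pmin(pmax(idx[1] + (-1:1), 1), 10)
    yy <- pmin(pmax(idx[2] + (-1:1), 1), 10)
    xx <- pmin(pmax(idx[3] + (-1:1), 1), 10)
    expect_gt(sum(a[zz, yy, xx]), 0)
  }
})

test_that("the full pipeline recovers a 4-voxel root and erosion is monotone", {
  spec <- small_root_phantom(dims = c(64L, 48L, 48L), diameter_um = 400,
                             seed = 21)
  vol <- render_phantom(spec)
  params <- segmentation_params(18000, 26000, c(32, 24, 24))
  res <- run_pipeline(vol, params)
  expect_s3_class(res$report, "tbl_df")
  expect_equal(rootct:::count_components(res$root), 1L)
  zs <- range(which(apply(unclass(res$root), 1, sum) > 0))
  span <- diff(zs) + 1
  expect_gte(span, 0.9 * (64 - 2 * 15))   # spans >=90% of the root slices

  fg <- sum(res$root)
  for (it in 1:2) {
    p2 <- segmentation_params(18000, 26000, c(32, 24, 24),
                              erosion_iterations = it)
    fg2 <- sum(run_pipeline(vol, p2)$root)
    expect_lte(fg2, fg)
    fg <- fg2
  }
})

test_that("a 1-voxel root is below the detection limit", {
  spec <- small_root_phantom(dims = c(64L, 48L, 48L), diameter_um = 100,
                             seed = 22)
  vol <- render_phantom(spec)
  params <- segmentation_params(18000, 26000, c(32, 24, 24))
  rec <- tryCatch({
    res <- run_pipeline(vol, params)
    skel <- classify_voxels(skeletonize3d(res$root))
    total_length(branch_decompose(skel)) * 10
  }, error = function(e) 0)
  expect_lt(rec / 3.4, 0.5)   # true length 3.4 mm; essentially unrecoverable
})
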