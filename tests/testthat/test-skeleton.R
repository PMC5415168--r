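test_that("thin structures are preserved and cylinders reduce to centerlines", {
  line <- array(0L, c(12, 5, 5)); line[2:11, 3, 3] <- 1L
  sk <- skeletonize3d(ct_binary(line, 27))
  expect_equal(unclass(sk), line, ignore_attr = TRUE)

  cyl <- make_cylinder(60, 17, 17, z_from = 6, z_to = 55, radius = 3)
  sk2 <- skeletonize3d(ct_binary(cyl, 27))
  expect_true(all(unclass(sk2) <= cyl))           # subset of the input
  cl <- classify_voxels(sk2)
  br <- branch_decompose(cl)
  steps <- sum(br$length_um) / 27
  expect_lt(abs(steps - 49) / 49, 0.05)           # within 5% of 49 steps
  # roughly centered: all skeleton voxels near the axis
  w <- cl$voxels
  expect_true(all(abs(w$y - 9) <= 1 & abs(w$x - 9) <= 1))
})

test_that("thinning preserves component count on mixed fixtures", {
  a <- array(0L, c(20, 12, 12))
  a[2:18, 3:5, 3:5] <- 1L          # a bar
  a[10:19, 8:11, 8:11] <- 1L       # a separate block
  before <- rootct:::count_components(ct_binary(a, 10))
  sk <- skeletonize3d(ct_binary(a, 10))
  expect_equal(rootct:::count_components(sk), before)

  for (seed in 1:3) {
    set.seed(seed)
    b <- array(0L, c(16, 16, 16))
    p <- c(8, 8, 8)
    for (i in 1:120) {                      # random-walk blob: connected
      b[p[1], p[2], p[3]] <- 1L
      p <- pmin(pmax(p + sample(c(-1, 0, 1), 3, TRUE), 1), 16)
    }
    bb <- ct_binary(b, 10)
    expect_equal(rootct:::count_components(skeletonize3d(bb)),
                 rootct:::count_components(bb))
  }
})

test_that("voxel classification counts tips, slabs and junctions", {
  line <- array(0L, c(12, 5, 5)); line[2:11, 3, 3] <- 1L
  cl <- classify_voxels(ct_binary(line, 27))
  expect_equal(sum(cl$voxels$class == "tip"), 2)
  expect_equal(sum(cl$voxels$class == "slab"), 8)
  expect_equal(sum(cl$voxels$class == "junction"), 0)

  # Y: three straight arms meeting at one voxel
  y <- array(0L, c(13, 13, 13))
  y[7:12, 7, 7] <- 1L                       # downward arm
  for (k in 1:6) { y[7 - k, 7 - k, 7] <- 1L; y[7 - k, 7 + k, 7] <- 1L }
  cl2 <- classify_voxels(ct_binary(y, 27))
  expect_equal(sum(cl2$voxels$class == "junction"), 1)
  expect_equal(sum(cl2$voxels$class == "tip"), 3)
  jc <- cl2$voxels[cl2$voxels$class == "junction", ]
  expect_equal(c(jc$z, jc$y, jc$x), c(7, 7, 7))

  lone <- array(0L, c(5, 5, 5)); lone[3, 3, 3] <- 1L
  expect_message(cl3 <- classify_voxels(ct_binary(lone, 27)), "isolated")
  expect_equal(cl3$voxels$class, "tip")
})

test_that("branch lengths follow calibrated Euclidean step sums", {
  ax <- array(0L, c(13, 3, 3)); ax[2:12, 2, 2] <- 1L
  br <- branch_decompose(classify_voxels(ct_binary(ax, 27)))
  expect_equal(nrow(br), 1)
  expect_equal(br$length_um, 10 * 27)

  dg <- array(0L, c(7, 7, 3))
  for (k in 1:5) dg[k + 1, k + 1, 2] <- 1L
  brd <- branch_decompose(classify_voxels(ct_binary(dg, 27)))
  expect_equal(brd$length_um, 4 * sqrt(2) * 27)

  # count mode reproduces plain voxel counting
  brc <- branch_decompose(classify_voxels(ct_binary(dg, 27)),
                          length_mode = "count")
  expect_equal(brc$length_um, 4 * 27)

  empty <- classify_voxels(ct_binary(array(0L, c(4, 4, 4)), 27))
  expect_equal(nrow(branch_decompose(empty)), 0)
})

test_that("branch decomposition partitions slab voxels exactly", {
  y <- array(0L, c(13, 13, 13))
  y[7:12, 7, 7] <- 1L
  for (k in 1:6) { y[7 - k, 7 - k, 7] <- 1L; y[7 - k, 7 + k, 7] <- 1L }
  cl <- classify_voxels(ct_binary(y, 27))
  br <- branch_decompose(cl)
  expect_equal(nrow(br), 3)
  slabs <- cl$voxels[cl$voxels$class == "slab", c("z", "y", "x")]
  slab_keys <- paste(slabs$z, slabs$y, slabs$x)
  path_keys <- unlist(lapply(br$path, function(p) paste(p[, 1], p[, 2], p[, 3])))
  tab <- table(path_keys)
  # every slab voxel appears exactly once across all branch paths
  expect_true(all(slab_keys %in% names(tab)))
  expect_true(all(tab[slab_keys] == 1))
})

test_that("total length is a permutation-invariant sum in cm", {
  br <- tibble::tibble(length_um = c(270, 1523, 88))
  expect_equal(total_length(br), sum(br$length_um) / 1e4)
  expect_equal(total_length(br[c(3, 1, 2), ]), total_length(br))
})

test_that("length is conserved across branches, depth profile and RLD map", {
  y <- array(0L, c(26, 26, 26))
  y[13:24, 13, 13] <- 1L
  for (k in 1:11) { y[13 - k, 13 - k, 13] <- 1L; y[13 - k, 13 + k, 13] <- 1L }
  y[20, 13, 13:20] <- 1L                     # a horizontal side branch
  cl <- classify_voxels(ct_binary(y, 200))   # 200 um voxels
  br <- branch_decompose(cl)
  tot_um <- sum(br$length_um)

  prof <- depth_profile(cl, column_cross_section_mm2 = 26^2 * 0.2^2,
                        branches = br)
  expect_lt(abs(sum(prof$length_mm) * 1000 - tot_um) / tot_um, 1e-6)

  rm_ <- rld_map(cl, bin_size_mm = 1, branches = br)
  mass_cm <- attr(rm_, "total_length_cm")
  expect_lt(abs(mass_cm * 1e4 - tot_um) / tot_um, 1e-6)
  expect_equal(sum(rm_) * (0.1)^3, mass_cm, tolerance = 1e-9)
})

test_that("depth profiles localize horizontal and vertical structures", {
  vert <- array(0L, c(10, 5, 5)); vert[1:10, 3, 3] <- 1L
  clv <- classify_voxels(ct_binary(vert, 1000))
  pv <- depth_profile(clv, column_cross_section_mm2 = 25)
  # interior slices get two half-steps each; end slices one half-step
  expect_equal(pv$length_mm[2:9], rep(1, 8))
  expect_equal(pv$length_mm[c(1, 10)], c(0.5, 0.5))
  expect_equal(sum(pv$length_mm), 9)

  hor <- array(0L, c(10, 5, 9)); hor[4, 3, 2:8] <- 1L
  clh <- classify_voxels(ct_binary(hor, 1000))
  ph <- depth_profile(clh, column_cross_section_mm2 = 45)
  expect_equal(ph$length_mm[4], 6)
  expect_true(all(ph$length_mm[-4] == 0))
  # RLD definition: length (cm) over slab volume (cm^3)
  slab_cm3 <- (45 / 100) * (1000 / 1000 / 10)
  expect_equal(ph$rld[4], 0.6 / slab_cm3)
})

test_that("RLD map concentrates a short root in its single bin", {
  # straight 4 mm root inside one 5 mm bin; voxel 100 um
  a <- array(0L, c(45, 20, 20)); a[3:43, 10, 10] <- 1L
  cl <- classify_voxels(ct_binary(a, 100))
  rm_ <- rld_map(cl, bin_size_mm = 5)
  expect_equal(attr(rm_, "total_length_cm"), 0.4)
  expect_equal(length(which(rm_ > 0)), 1L)
  expect_equal(max(rm_), 0.4 / 0.125, tolerance = 1e-9)  # 3.2 cm/cm^3

  empty <- classify_voxels(ct_binary(array(0L, c(8, 8, 8)), 100))
  expect_true(all(rld_map(empty, 2) == 0))
  expect_error(rld_map(cl, bin_size_mm = 0.05), "smaller than a voxel")
})

test_that("length outputs scale linearly with the voxel calibration", {
  dg <- array(0L, c(9, 9, 9))
  for (k in 1:7) dg[k, k, 5] <- 1L
  l1 <- sum(branch_decompose(classify_voxels(ct_binary(dg, 10)))$length_um)
  l3 <- sum(branch_decompose(classify_voxels(ct_binary(dg, 30)))$length_um)
  expect_equal(l3, 3 * l1)
})
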