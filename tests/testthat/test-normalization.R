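test_that("histograms conserve the voxel count and tally exactly", {
  v <- ct_volume(array(rep(c(10, 200), c(700, 300)), c(10, 10, 10)), 65)
  h <- grey_histogram(v, 2)
  expect_equal(h$counts, c(700L, 300L))
  expect_equal(sum(h$counts), 1000L)

  const <- ct_volume(array(42, c(5, 5, 5)), 65)
  hc <- grey_histogram(const, 64)
  expect_equal(sum(hc$counts), 125L)
  expect_equal(sum(hc$counts > 0), 1L)

  set.seed(4)
  r <- ct_volume(array(rnorm(4000, 0, 10), c(40, 10, 10)), 65)
  expect_equal(sum(grey_histogram(r, 77)$counts), 4000L)
})

test_that("peak detection finds the soil mode and honors the window", {
  set.seed(5)
  v <- ct_volume(array(round(rnorm(200000, 30000, 1000)), c(200, 100, 10)), 65)
  h <- grey_histogram(v, 128)
  bw <- diff(h$bin_edges)[1]
  pk <- find_peak(h)
  expect_lte(abs(pk$peak_grey - 30000), bw)
  expect_gte(pk$prominence, 0)

  # bimodal: low mode much larger, but the window restricts to the high one
  vals <- c(round(rnorm(40000, 5000, 300)), round(rnorm(8000, 30000, 300)))
  vb <- ct_volume(array(vals, c(48, 100, 10)), 65)
  hb <- grey_histogram(vb, 512)
  pb <- find_peak(hb, search_window = c(20000, 40000))
  expect_lte(abs(pb$peak_grey - 30000), 2 * diff(hb$bin_edges)[1])
  expect_true(pb$peak_grey >= 20000 && pb$peak_grey <= 40000)
})

test_that("peak ties break toward the lower grey and monotone counts error", {
  vals <- c(0, rep(10, 500), rep(12, 500), 22)
  v <- ct_volume(array(vals, c(length(vals), 1, 1)), 65)
  h <- grey_histogram(v, 12)
  pk <- find_peak(h, smooth_width = 1)
  expect_lt(pk$peak_grey, 11)

  mono <- ct_volume(array(rep(1:10, times = 1:10), c(55, 1, 1)), 65)
  hm <- grey_histogram(mono, 10)
  expect_error(find_peak(hm, smooth_width = 1), "no peak")
})

test_that("peak alignment is an exact shift and align+stitch invert the split", {
  set.seed(6)
  base <- array(round(rnorm(32 * 24 * 24, 30000, 800)), c(32, 24, 24))
  ref <- ct_volume(base, 65)
  offs <- ct_volume(base + 500, 65)
  al <- align_peaks(list(ref, offs), target_grey = 30000)
  # identical integer data offset by a constant: outputs must agree exactly
  expect_equal(unclass(al[[1]]), unclass(al[[2]]), ignore_attr = TRUE)
  expect_equal(attr(al[[1]], "grey_shift") - attr(al[[2]], "grey_shift"), 500)

  # histogram shape is preserved: counts are a pure shift
  h0 <- grey_histogram(ref, 128)$counts
  h1 <- grey_histogram(al[[1]], 128)$counts
  expect_equal(sort(h1), sort(h0))

  # drifted overlapping sub-scans: align + stitch reproduce the original.
  # 256 bins keep the soil peak well sampled for this small test column
  # (~100 voxels per bin; the 1024-bin default targets full-size scans).
  spec <- small_root_phantom(dims = c(48L, 24L, 24L), seed = 11)
  vol <- render_phantom(spec)
  scans <- split_scans(vol, 2, overlap_slices = 8, drifts = c(500, -300))
  al2 <- align_peaks(scans, target_grey = 30000, n_bins = 256)
  st <- stitch(al2[[1]], al2[[2]], max_overlap = 12)
  expect_equal(attr(st, "overlap"), 8)
  expect_equal(dim(st), dim(vol))
  bw <- diff(grey_histogram(vol, 256)$bin_edges)[1]
  reference <- align_peaks(vol, target_grey = 30000, n_bins = 256)
  expect_lt(max(abs(unclass(st) - unclass(reference))), bw + 1e-9)
  # stitched histogram has a single soil peak at the target grey
  pk <- find_peak(grey_histogram(st, 256))
  expect_lte(abs(pk$peak_grey - 30000), bw)
})

test_that("stitch finds exact and noisy duplicated overlaps, errors otherwise", {
  set.seed(7)
  col <- array(rnorm(40 * 16 * 16, 30000, 1000), c(40, 16, 16))
  a <- ct_volume(col[1:25, , ], 65)
  b <- ct_volume(col[16:40, , ], 65)     # 10 duplicated slices
  st <- stitch(a, b, max_overlap = 15)
  expect_equal(attr(st, "overlap"), 10)
  expect_equal(unclass(st), col, ignore_attr = TRUE)

  # noise on B's copy of the overlap: correct k still recovered
  bn <- unclass(b)
  set.seed(8)
  bn <- bn + rnorm(length(bn), 0, 0.01 * diff(range(col)))
  st2 <- stitch(a, ct_volume(bn, 65), max_overlap = 15, min_similarity = 0.8)
  expect_equal(attr(st2, "overlap"), 10)

  set.seed(9)
  r1 <- ct_volume(array(rnorm(20 * 16 * 16), c(20, 16, 16)), 65)
  r2 <- ct_volume(array(rnorm(20 * 16 * 16), c(20, 16, 16)), 65)
  expect_error(stitch(r1, r2, max_overlap = 10, min_similarity = 0.9),
               "no overlap detected")
})

test_that("sequential stitching reassembles a column cut into three scans", {
  set.seed(10)
  col <- array(rnorm(60 * 12 * 12, 30000, 900), c(60, 12, 12))
  vol <- ct_volume(col, 65)
  scans <- split_scans(vol, 3, overlap_slices = 6, drifts = c(0, 0, 0))
  st <- stitch(stitch(scans[[1]], scans[[2]], 10), scans[[3]], 10)
  expect_equal(dim(st), dim(vol))
  expect_equal(unclass(st), col, ignore_attr = TRUE)
})

test_that("split_scans applies drifts exactly and keeps the identity case", {
  v <- ct_volume(array(rnorm(30 * 8 * 8, 100, 5), c(30, 8, 8)), 65)
  one <- split_scans(v, 1, 1, drifts = 0)
  expect_equal(unclass(one[[1]]), unclass(v), ignore_attr = TRUE)
  two <- split_scans(v, 2, 4, drifts = c(250, -100))
  expect_equal(mean(two[[1]]) - mean(v[1:dim(two[[1]])[1], , ]), 250)
  expect_error(split_scans(v, 2, 29, drifts = c(0, 0)), "overlap too large")
})
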