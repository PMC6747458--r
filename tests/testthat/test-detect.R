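test_that("projection reduces stacks by mean or max with calibration kept", {
  m <- matrix(runif(64), 8)
  st <- zstack(list(m, m, m), pixel_size = 1.5, layer = "OPL")
  expect_equal(project(st, "mean")$pixels, m)
  st2 <- zstack(list(matrix(0, 4, 4), matrix(10, 4, 4)), pixel_size = 2)
  expect_equal(project(st2, "mean")$pixels, matrix(5, 4, 4))
  s <- lapply(1:3, function(i) matrix(runif(36), 6))
  st3 <- zstack(s, pixel_size = 1)
  expect_equal(project(st3, "mean")$pixels, (s[[1]] + s[[2]] + s[[3]]) / 3)
  expect_equal(project(st3, "max")$pixels, pmax(s[[1]], s[[2]], s[[3]]))
  expect_equal(project(st3, "mean")$pixel_size, 1)
  expect_error(zstack(list(), 1), "at least one")
})

test_that("peak normalization maps the peak to 1 and preserves order", {
  f <- field(matrix(c(0, 100, 250, 500), 2), 1)
  n <- normalize_peak(f)
  expect_equal(max(n$pixels), 1)
  expect_equal(n$pixels, f$pixels / 500)
  # already normalized input is unchanged
  expect_equal(normalize_peak(n)$pixels, n$pixels)
  # scale invariance
  f2 <- field(f$pixels * 37.5, 1)
  expect_equal(normalize_peak(f2)$pixels, n$pixels)
  expect_error(normalize_peak(field(matrix(0, 3, 3), 1)), "all-zero")
})

test_that("threshold zeroes values below the cut and retains the rest verbatim", {
  vals <- c(0, 0.1, 0.19, 0.199999, 0.2, 0.200001, 0.5, 1)
  f <- field(matrix(vals, 2), 1)
  t <- threshold_floor(f, 0.2)
  expect_equal(as.numeric(t$pixels),
               ifelse(vals < 0.2, 0, vals))
  # a pixel exactly at the threshold is retained, not binarized
  expect_equal(t$pixels[1, 3], 0.2)
  # threshold 0 is the identity
  expect_equal(threshold_floor(f, 0)$pixels, f$pixels)
  # a constant field below the cut goes entirely to zero
  expect_equal(threshold_floor(field(matrix(0.5, 3, 3), 1), 0.6)$pixels,
               matrix(0, 3, 3))
  expect_error(threshold_floor(f, 1), "low_threshold")
})

test_that("segmentation separates blobs and honours connectivity", {
  m <- matrix(0, 5, 5)
  m[1:2, 1:2] <- 1; m[4:5, 4:5] <- 0.5
  seg <- segment_field(field(m, 1), 8)
  expect_equal(nrow(seg$segments), 2)
  # diagonal-touching pixels: joined under 8, split under 4
  d <- matrix(0, 4, 4); d[1, 1] <- 1; d[2, 2] <- 1
  expect_equal(nrow(segment_field(field(d, 1), 8)$segments), 1)
  expect_equal(nrow(segment_field(field(d, 1), 4)$segments), 2)
})

test_that("segment centres of mass are intensity weighted", {
  m <- matrix(0, 5, 5)
  m[3, 2] <- 1; m[3, 3] <- 3   # COM pulled toward the brighter pixel
  seg <- segment_field(field(m, 2), 8)$segments
  expect_equal(nrow(seg), 1)
  expect_equal(seg$x_um, ((1 * 1.5 + 3 * 2.5) / 4) * 2)
  expect_equal(seg$y_um, 2.5 * 2)
})

test_that("segment counts match the flood-fill oracle on random fields", {
  set.seed(42)
  for (i in 1:25) {
    m <- matrix(rbinom(400, 1, 0.3), 20)
    for (conn in c(4, 8)) {
      seg <- segment_field(field(m, 1), conn)
      expect_equal(nrow(seg$segments), max(oracle_flood_fill(m, conn)))
    }
  }
})

test_that("4-connectivity labeling agrees with EBImage::bwlabel", {
  set.seed(7)
  for (i in 1:5) {
    m <- matrix(rbinom(900, 1, 0.35), 30)
    seg <- segment_field(field(m, 1), 4)
    expect_equal(nrow(seg$segments), max(EBImage::bwlabel(m)))
  }
})

test_that("dedupe merges by the strict < min_distance closure", {
  one <- dedupe_centroids(rbind(c(0, 0), c(5, 0)), 10)
  expect_equal(nrow(one$representatives), 1)
  expect_equal(one$representatives[1, ], c(2.5, 0))
  two <- dedupe_centroids(rbind(c(0, 0), c(15, 0)), 10)
  expect_equal(nrow(two$representatives), 2)
  # exactly at min_distance: "closer than" is strict, so not merged
  border <- dedupe_centroids(rbind(c(0, 0), c(10, 0)), 10)
  expect_equal(nrow(border$representatives), 2)
  # chains merge transitively
  chain <- dedupe_centroids(rbind(c(0, 0), c(8, 0), c(16, 0)), 10)
  expect_equal(nrow(chain$representatives), 1)
})

test_that("dedupe cluster counts match the union-find oracle", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(10:60, 1)
    centers <- cbind(runif(n, 0, 100), runif(n, 0, 100))
    md <- runif(1, 5, 20)
    dd <- dedupe_centroids(centers, md)
    oracle <- oracle_union_find(centers, md)
    expect_equal(nrow(dd$representatives), length(unique(oracle)))
    # same partition, not just the same count
    expect_equal(length(unique(paste(dd$cluster, oracle))),
                 length(unique(oracle)))
  }
})

test_that("count_cells recovers well-separated planted cells precisely", {
  g <- field_geometry(px = 256)
  side <- g$px * g$pixel_size
  set.seed(3)
  ctrs <- rbind(c(80, 80), c(200, 90), c(140, 260))
  f <- field(matrix(0, g$px, g$px), g$pixel_size, layer = "OPL")
  for (i in 1:3) {
    tips <- cbind(ctrs[i, 1] + 20 * cos(1:5), ctrs[i, 2] + 20 * sin(1:5))
    f <- render_cell(f, cell_truth(ctrs[i, ], 4.5, tips, peak = 0.9))
  }
  det <- count_cells(f, detection_params(min_distance = 12))
  expect_equal(det$count, 3)
  d <- apply(ctrs, 1, function(p)
    min(sqrt((det$centroids[, 1] - p[1])^2 +
             (det$centroids[, 2] - p[2])^2)))
  expect_lt(max(d), 1)
})

test_that("the noise-floor guard reports blank fields as empty", {
  set.seed(5)
  blank <- field(pmax(matrix(rnorm(128^2, 0.05, 0.01), 128), 0), 1.5)
  det <- count_cells(blank, detection_params(noise_floor = 0.1))
  expect_equal(det$count, 0)
  expect_true(det$guard_triggered)
  # without the guard the noise would normalize to full range
  det2 <- count_cells(blank, detection_params(noise_floor = 0))
  expect_false(det2$guard_triggered)
})

test_that("a cell at 0.15 of the brightest peak is removed by the threshold", {
  g <- field_geometry(px = 256)
  f <- field(matrix(0, g$px, g$px), g$pixel_size)
  f <- render_cell(f, cell_truth(c(100, 100), 4.5, peak = 1))
  f <- render_cell(f, cell_truth(c(280, 280), 4.5, peak = 0.15))
  det <- count_cells(f, detection_params(noise_floor = 0.01))
  expect_equal(det$count, 1)
  expect_lt(sqrt(sum((det$centroids[1, ] - c(100, 100))^2)), 1)
})

test_that("count is non-increasing in min_distance and low_threshold", {
  gen <- generate_layer_field(20, geometry = field_geometry(px = 192),
                              seed = 17)
  counts_md <- vapply(c(4, 8, 12, 20, 40), function(md)
    count_cells(gen$field, detection_params(min_distance = md))$count,
    numeric(1))
  expect_true(all(diff(counts_md) <= 0))
  counts_thr <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.6), function(th)
    count_cells(gen$field, detection_params(low_threshold = th))$count,
    numeric(1))
  expect_true(all(diff(counts_thr) <= 0))
})

test_that("area fraction matches direct pixel counting exactly", {
  z <- field(matrix(0, 10, 10), 1)
  expect_equal(area_fraction(z, 0.5)$percent_area, 0)
  half <- field(matrix(rep(c(0, 1), 50), 10), 1)
  expect_equal(area_fraction(half, 0.5)$percent_area, 50)
  set.seed(9)
  m <- matrix(runif(400), 20)
  af <- area_fraction(field(m, 1), 0.37)
  norm <- m / max(m)
  expect_identical(af$percent_area, 100 * sum(norm >= 0.37) / 400)
  expect_equal(af$n_pixels_above, sum(norm >= 0.37))
})

test_that("area fraction is invariant under monotone intensity rescaling", {
  set.seed(10)
  m <- matrix(runif(400), 20)
  a1 <- area_fraction(field(m, 1), 0.4)$percent_area
  # positive scalar multiples normalize identically
  a2 <- area_fraction(field(7.3 * m, 1), 0.4)$percent_area
  expect_identical(a1, a2)
})

test_that("otsu-thresholded area fraction reports the threshold used", {
  gen <- generate_layer_field(10, geometry = field_geometry(px = 192),
                              layer = "NFL-GCL", seed = 19)
  af <- area_fraction(gen$field)
  expect_true(af$threshold_used > 0 && af$threshold_used < 1)
  expect_true(af$percent_area > 0 && af$percent_area < 100)
})

test_that("spot counting uses spot-scale dedupe", {
  g <- field_geometry(px = 192)
  sp <- generate_vertical_spots(12, geometry = g, seed = 23)
  expect_equal(count_spots(sp$field)$count, 12)
  # two spots closer than the spot min_distance count once
  f <- field(matrix(0, g$px, g$px), g$pixel_size)
  f <- render_cell(f, cell_truth(c(100, 100), 1.5, peak = 0.8,
                                 kind = "vertical_spot"))
  f <- render_cell(f, cell_truth(c(102.5, 100), 1.5, peak = 0.8,
                                 kind = "vertical_spot"))
  expect_equal(count_spots(f, spot_params(min_distance = 4,
                                          noise_floor = 0.01))$count, 1)
  # zero spots with the guard
  set.seed(2)
  blank <- field(pmax(matrix(rnorm(192^2, 0.05, 0.01), 192), 0),
                 g$pixel_size)
  expect_equal(count_spots(blank)$count, 0)
})
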