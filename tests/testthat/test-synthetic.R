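small_geom <- field_geometry(px = 128, area_mm2 = 0.1502)

test_that("field constructor validates calibration and computes area", {
  f <- field(matrix(1, 10, 10), pixel_size = 2)
  expect_equal(field_area_mm2(f), 100 * 4 / 1e6)
  expect_error(field(matrix(-1, 2, 2), 1), "non-negative")
  expect_error(field(matrix(Inf, 2, 2), 1), "finite")
  expect_error(field(matrix(1, 2, 2), 0), "positive")
})

test_that("default geometry hits the protocol field area of 0.1502 mm^2", {
  g <- field_geometry()
  expect_equal(g$px, 1024L)
  f <- field(matrix(0, g$px, g$px), g$pixel_size)
  expect_lt(abs(field_area_mm2(f) - 0.1502) / 0.1502, 0.01)
  gen <- generate_layer_field(5, geometry = small_geom, seed = 1)
  expect_lt(abs(field_area_mm2(gen$field) - 0.1502) / 0.1502, 0.01)
})

test_that("cell_truth enforces its invariants", {
  expect_error(cell_truth(c(0, 0), -1), "positive")
  expect_error(cell_truth(c(0, 0), 5, matrix(c(3, 0), 1)), "outside the soma")
  expect_error(cell_truth(c(0, 0), 3, matrix(c(9, 0), 1),
                          kind = "rgc_nucleus"), "no processes")
  tr <- cell_truth(c(10, 10), 4, matrix(c(30, 10), 1))
  expect_equal(tr$n_processes, 1L)
})

test_that("rendering is additive and centred", {
  g <- field_geometry(px = 128, area_mm2 = 0.01)
  tr <- cell_truth(c(50, 50), 5, peak = 1)
  f0 <- field(matrix(0, g$px, g$px), g$pixel_size)
  f1 <- render_cell(f0, tr)
  # brightest pixel within one pixel of the planted centre
  idx <- which(f1$pixels == max(f1$pixels), arr.ind = TRUE)[1, ]
  ctr_px <- c(50, 50) / g$pixel_size + 0.5
  expect_lt(max(abs(idx[c(2, 1)] - ctr_px)), 1.5)
  expect_true(all(f1$pixels >= f0$pixels))
  # rendering twice doubles the contribution exactly
  f2 <- render_cell(f1, tr)
  expect_equal(f2$pixels, 2 * f1$pixels)
})

test_that("half-peak pixel count of a rendered soma recovers pi r^2", {
  g <- field_geometry(px = 256, area_mm2 = 0.01)
  for (r in c(3, 5, 7)) {
    tr <- cell_truth(c(50, 50), r, peak = 0.8)
    f <- render_cell(field(matrix(0, g$px, g$px), g$pixel_size), tr)
    area_px <- sum(f$pixels >= max(f$pixels) / 2) * g$pixel_size^2
    expect_lt(abs(area_px - pi * r^2) / (pi * r^2), 0.15)
  }
})

test_that("generator plants exactly n cells in a mosaic", {
  gen <- generate_layer_field(30, geometry = field_geometry(px = 128),
                              seed = 5)
  expect_equal(nrow(gen$truth), 30)
  d <- as.matrix(dist(gen$truth[, c("x_um", "y_um")]))
  spacing <- 2 * cell_defaults()$microglia$arbor_radius
  expect_gte(min(d[upper.tri(d)]), spacing)
})

test_that("mosaic holds under an activated profile with scaled spacing", {
  pr <- profile_oht()
  gen <- generate_layer_field(30, pr, geometry = field_geometry(px = 128),
                              seed = 6)
  d <- as.matrix(dist(gen$truth[, c("x_um", "y_um")]))
  spacing <- 2 * cell_defaults()$microglia$arbor_radius * pr$arbor
  expect_gte(min(d[upper.tri(d)]), spacing)
})

test_that("infeasible packings fail loudly instead of truncating", {
  expect_error(
    generate_layer_field(500, geometry = field_geometry(px = 64),
                         seed = 1),
    "packing infeasible")
})

test_that("soma_factor scales planted soma radii by the planted ratio", {
  base <- generate_layer_field(25, geometry = small_geom, seed = 7)
  act <- generate_layer_field(
    25, activation_profile(soma = 1.5), geometry = small_geom, seed = 7)
  ratio <- mean(act$truth$soma_radius_um) / mean(base$truth$soma_radius_um)
  expect_lt(abs(ratio - 1.5), 0.05)
})

test_that("identical seeds give identical pixels, different seeds differ", {
  a <- generate_layer_field(10, geometry = small_geom, seed = 3)
  b <- generate_layer_field(10, geometry = small_geom, seed = 3)
  c <- generate_layer_field(10, geometry = small_geom, seed = 4)
  expect_identical(a$field$pixels, b$field$pixels)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$field$pixels, c$field$pixels))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(generate_layer_field(5, geometry = small_geom,
                                                seed = 9))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("vertical spot fields: empty, counted maxima, and size bound", {
  g <- field_geometry(px = 192)
  empty <- generate_vertical_spots(0, geometry = g, seed = 1)
  expect_equal(nrow(empty$truth), 0)
  expect_lt(max(empty$field$pixels), 0.15)   # background + noise only
  sp <- generate_vertical_spots(12, geometry = g, seed = 2)
  expect_equal(nrow(sp$truth), 12)
  # spots are smaller than microglial somata by construction
  expect_lt(max(sp$truth$soma_radius_um),
            min(cell_defaults()$microglia$soma_radius))
  # each planted spot is a local maximum above the noise floor
  px <- sp$field$pixels
  for (i in seq_len(12)) {
    ci <- round(sp$truth$y_um[i] / g$pixel_size)
    cj <- round(sp$truth$x_um[i] / g$pixel_size)
    patch <- px[max(1, ci - 2):min(nrow(px), ci + 2),
                max(1, cj - 2):min(ncol(px), cj + 2)]
    expect_gt(max(patch), 0.3)
  }
})

test_that("rgc fields plant dense round process-free nuclei", {
  gen <- generate_layer_field(100, kind = "rgc_nucleus",
                              geometry = field_geometry(px = 192),
                              layer = "NFL-GCL", seed = 8)
  expect_equal(nrow(gen$truth), 100)
  expect_true(all(gen$truth$n_processes == 0))
  d <- as.matrix(dist(gen$truth[, c("x_um", "y_um")]))
  expect_gte(min(d[upper.tri(d)]), cell_defaults()$rgc_nucleus$min_spacing)
})

test_that("z-stacks share shape and mean-project to the in-focus pattern", {
  gen <- generate_layer_field(8, geometry = field_geometry(px = 128),
                              seed = 11)
  st <- as_zstack(gen, n_sections = 5, seed = 12)
  expect_s3_class(st$field, "rq_zstack")
  expect_length(st$field$sections, 5)
  expect_equal(st$field$z_spacing, 2)
  proj <- project(st$field, "mean")
  # central section carries full weight; projection correlates strongly
  # with the single-plane rendering
  expect_gt(cor(as.numeric(proj$pixels), as.numeric(gen$field$pixels)),
            0.9)
})

test_that("fields round-trip through 16-bit TIFF with sidecar scale", {
  gen <- generate_layer_field(5, geometry = field_geometry(px = 64),
                              seed = 13)
  tmp <- file.path(tempdir(), "f.tif")
  write_field(gen$field, tmp)
  back <- read_field(tmp)
  expect_equal(back$pixel_size, gen$field$pixel_size)
  expect_equal(back$layer, gen$field$layer)
  expect_lt(max(abs(back$pixels - gen$field$pixels)), 1e-3)
  st <- as_zstack(gen, seed = 14)
  tmp2 <- file.path(tempdir(), "s.tif")
  write_field(st$field, tmp2)
  back2 <- read_field(tmp2)
  expect_s3_class(back2, "rq_zstack")
  expect_length(back2$sections, 5)
  unlink(c(tmp, tmp2, paste0(c(tmp, tmp2), ".json")))
})

test_that("density monotonicity: more requested cells, never fewer planted", {
  counts <- vapply(c(5, 10, 20, 30), function(n) {
    nrow(generate_layer_field(n, geometry = small_geom, seed = 21)$truth)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})
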