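#' Single-channel fluorescence field
#'
#' A `field` is the unit consumed by every detector and measure in the
#' package: one 2-D grayscale intensity grid together with its physical
#' calibration (microns per pixel) and, optionally, the retinal layer and
#' zone it was imaged in.
#'
#' Physical coordinates follow the pixel-center convention: the pixel in
#' row `i`, column `j` (1-based, as stored in R) is centred at
#' `x = (j - 0.5) * pixel_size`, `y = (i - 0.5) * pixel_size`, with `x`
#' running along columns and `y` along rows.
#'
#' @param pixels numeric matrix of non-negative, finite intensities.
#' @param pixel_size physical pixel size in microns per pixel (> 0).
#' @param layer retinal layer label, one of [rq_layers()] or `NA`.
#' @param zone retinal zone label, one of [rq_zones()] or `NA`.
#' @return an object of class `rq_field`.
#' @examples
#' f <- field(matrix(runif(64), 8), pixel_size = 1.5, layer = "OPL")
#' field_area_mm2(f)
#' @export
field <- function(pixels, pixel_size, layer = NA_character_,
                  zone = NA_character_) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (!all(is.finite(pixels)))
    stop("field intensities must be finite")
  if (any(pixels < 0))
    stop("field intensities must be non-negative")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number (um/pixel)")
  if (!is.na(layer)) layer <- match.arg(layer, rq_layers())
  if (!is.na(zone)) zone <- match.arg(zone, rq_zones())
  structure(
    list(pixels = pixels, pixel_size = pixel_size,
         layer = layer, zone = zone),
    class = "rq_field"
  )
}

#' Ordered z-stack of fields
#'
#' Equally spaced optical sections through the tissue, reducible to a
#' single [field()] by [project()]. All sections must share shape; the
#' default section spacing is 2 um.
#'
#' @param sections list of same-shaped numeric matrices (or `rq_field`s).
#' @param pixel_size microns per pixel; taken from the first section if it
#'   is an `rq_field`.
#' @param z_spacing section spacing in microns.
#' @inheritParams field
#' @return an object of class `rq_zstack`.
#' @export
zstack <- function(sections, pixel_size = NULL, z_spacing = 2,
                   layer = NA_character_, zone = NA_character_) {
  if (length(sections) < 1) stop("a z-stack needs at least one section")
  first <- sections[[1]]
  if (inherits(first, "rq_field")) {
    if (is.null(pixel_size)) pixel_size <- first$pixel_size
    if (is.na(layer)) layer <- first$layer
    if (is.na(zone)) zone <- first$zone
    sections <- lapply(sections, function(s) {
      if (inherits(s, "rq_field")) s$pixels else s
    })
  }
  if (is.null(pixel_size)) stop("`pixel_size` is required")
  dims <- vapply(sections, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all sections of a z-stack must share the same shape")
  if (z_spacing <= 0) stop("`z_spacing` must be positive")
  structure(
    list(sections = sections, pixel_size = pixel_size,
         z_spacing = z_spacing, layer = layer, zone = zone),
    class = "rq_zstack"
  )
}

#' @export
print.rq_field <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<rq_field> %d x %d px, %.4f um/px (%.4f mm^2), layer=%s, zone=%s\n",
    d[1], d[2], x$pixel_size, field_area_mm2(x),
    x$layer, x$zone))
  invisible(x)
}

#' @export
print.rq_zstack <- function(x, ...) {
  d <- dim(x$sections[[1]])
  cat(sprintf(
    "<rq_zstack> %d sections of %d x %d px, dz=%g um, layer=%s, zone=%s\n",
    length(x$sections), d[1], d[2], x$z_spacing, x$layer, x$zone))
  invisible(x)
}

#' Retinal layer and zone vocabularies
#'
#' The four whole-mount strata in which distinct microglial populations are
#' quantified (photoreceptor outer segments, outer and inner plexiform
#' layers, nerve fibre + ganglion cell layer), the OPL/OS interface plane
#' where vertical processes appear as spots, and the four retinal zones.
#'
#' @return character vector of labels.
#' @export
rq_layers <- function() c("OS", "OPL", "IPL", "NFL-GCL", "OPL-OS")

#' @rdname rq_layers
#' @export
rq_zones <- function() c("superior", "inferior", "nasal", "temporal")

#' Field geometry
#'
#' Square field geometry with a given physical area. The default area is
#' 0.1502 mm^2, the area covered by one 20x photomicrograph in the whole
#' mount protocol this package emulates; at the default 1024 x 1024 pixels
#' this gives a pixel size of about 0.3786 um.
#'
#' @param px side length in pixels.
#' @param area_mm2 physical field area in mm^2.
#' @return list with elements `px` and `pixel_size` (um/pixel).
#' @export
field_geometry <- function(px = 1024, area_mm2 = 0.1502) {
  if (px < 8) stop("`px` too small")
  if (area_mm2 <= 0) stop("`area_mm2` must be positive")
  side_um <- sqrt(area_mm2 * 1e6)
  list(px = as.integer(px), pixel_size = side_um / px)
}

#' Physical field area
#'
#' @param x an `rq_field` or `rq_zstack`.
#' @return area in mm^2 (`rows * cols * pixel_size^2 / 1e6`).
#' @export
field_area_mm2 <- function(x) {
  d <- if (inherits(x, "rq_zstack")) dim(x$sections[[1]]) else dim(x$pixels)
  d[1] * d[2] * x$pixel_size^2 / 1e6
}

#' Read and write fields as 16-bit TIFF with a JSON sidecar
#'
#' Intensities are scaled so the image maximum maps to the top of the
#' 16-bit range; the scale factor, pixel size and labels are recorded in a
#' `<path>.json` sidecar so the physical intensities round-trip.
#' Z-stacks are written as multi-page TIFFs.
#'
#' @param x an `rq_field` or `rq_zstack`.
#' @param path output TIFF path.
#' @return `write_field()` returns `path` invisibly; `read_field()` returns
#'   the reconstructed `rq_field` or `rq_zstack`.
#' @export
write_field <- function(x, path) {
  stack <- inherits(x, "rq_zstack")
  mats <- if (stack) x$sections else list(x$pixels)
  peak <- max(vapply(mats, max, numeric(1)))
  scale <- if (peak > 0) peak else 1
  scaled <- lapply(mats, function(m) m / scale)
  if (stack) {
    tiff::writeTIFF(scaled, path, bits.per.sample = 16)
  } else {
    tiff::writeTIFF(scaled[[1]], path, bits.per.sample = 16)
  }
  meta <- list(
    pixel_size = x$pixel_size, scale = scale,
    layer = x$layer, zone = x$zone,
    z_spacing = if (stack) x$z_spacing else NULL,
    n_sections = if (stack) length(mats) else 1L
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path))
    stop("missing sidecar metadata: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  pages <- lapply(pages, function(m) m * meta$scale)
  layer <- if (is.null(meta$layer) || is.na(meta$layer)) NA_character_ else meta$layer
  zone <- if (is.null(meta$zone) || is.na(meta$zone)) NA_character_ else meta$zone
  if (!is.null(meta$n_sections) && meta$n_sections > 1) {
    zstack(pages, pixel_size = meta$pixel_size,
           z_spacing = meta$z_spacing, layer = layer, zone = zone)
  } else {
    field(pages[[1]], pixel_size = meta$pixel_size,
          layer = layer, zone = zone)
  }
}

# pixel-center physical coordinates of every pixel in a matrix
.pixel_coords <- function(nr, nc, pixel_size) {
  list(x = (seq_len(nc) - 0.5) * pixel_size,
       y = (seq_len(nr) - 0.5) * pixel_size)
}

# evaluate an expression with a temporary RNG state seeded from `seed`,
# restoring the caller's state afterwards
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic 31-bit sub-seed from a base seed and a key string
derive_seed <- function(seed, ...) {
  key <- paste(c(...), collapse = "/")
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147483629
  as.integer(h)
}
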