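#' Detection parameters
#'
#' Parameters of the automatic segmentation/distance-control counting
#' algorithm. `low_threshold` is the fraction of the image peak below
#' which normalized pixel values are zeroed (the remaining values are
#' retained, not binarized). `min_distance` is the minimum separation, in
#' microns, below which segment centres of mass are considered the same
#' cell; its value is a parameter of the method (defaults: 12 um for
#' microglia, about a soma diameter; 8 um for RGC nuclei; 4 um for
#' vertical-process spots). `noise_floor` is an absolute intensity guard:
#' a field whose raw peak is below it is reported as empty rather than
#' peak-normalized, which would amplify pure noise to full scale.
#'
#' @param low_threshold fraction of peak in `[0, 1)`.
#' @param min_distance minimum inter-cell distance in um (> 0).
#' @param connectivity pixel connectivity for segmentation, 8 or 4.
#' @param projection z-stack reduction mode, `"mean"` or `"max"`.
#' @param noise_floor absolute pre-normalization intensity floor.
#' @return an object of class `rq_params`.
#' @export
detection_params <- function(low_threshold = 0.2, min_distance = 12,
                             connectivity = 8,
                             projection = c("mean", "max"),
                             noise_floor = 0.1) {
  projection <- match.arg(projection)
  if (low_threshold < 0 || low_threshold >= 1)
    stop("`low_threshold` must be in [0, 1)")
  if (min_distance <= 0) stop("`min_distance` must be positive")
  if (!connectivity %in% c(4L, 8L)) stop("`connectivity` must be 4 or 8")
  structure(list(low_threshold = low_threshold,
                 min_distance = min_distance,
                 connectivity = as.integer(connectivity),
                 projection = projection, noise_floor = noise_floor),
            class = "rq_params")
}

#' @rdname detection_params
#' @export
rgc_params <- function(min_distance = 8, ...) {
  detection_params(min_distance = min_distance, ...)
}

#' @rdname detection_params
#' @export
spot_params <- function(min_distance = 4, ...) {
  detection_params(min_distance = min_distance, ...)
}

#' Project a z-stack to a single field
#'
#' Averages (or takes the per-pixel maximum of) the ordered sections of a
#' z-stack, preserving calibration and labels.
#'
#' @param stack an `rq_zstack` (an `rq_field` passes through unchanged).
#' @param mode `"mean"` or `"max"`.
#' @return an `rq_field`.
#' @export
project <- function(stack, mode = c("mean", "max")) {
  mode <- match.arg(mode)
  if (inherits(stack, "rq_field")) return(stack)
  stopifnot(inherits(stack, "rq_zstack"))
  acc <- Reduce(if (mode == "mean") `+` else pmax, stack$sections)
  if (mode == "mean") acc <- acc / length(stack$sections)
  field(acc, pixel_size = stack$pixel_size,
        layer = stack$layer, zone = stack$zone)
}

#' Normalize a field to its peak pixel
#'
#' Divides by the maximum pixel so values fall in `[0, 1]` with the peak
#' at exactly 1; pixel ordering is preserved. An all-zero field has no
#' defined normalization and raises an error.
#'
#' @param fld an `rq_field`.
#' @return the normalized `rq_field`.
#' @export
normalize_peak <- function(fld) {
  stopifnot(inherits(fld, "rq_field"))
  peak <- max(fld$pixels)
  if (peak <= 0) stop("cannot peak-normalize an all-zero field")
  fld$pixels <- fld$pixels / peak
  fld
}

#' Zero sub-threshold pixels, retaining the rest
#'
#' All values below `low_threshold` are set to 0; values at or above it
#' are retained verbatim (the image is not binarized), preserving the
#' intensity weighting used later for centres of mass.
#'
#' @param fld a peak-normalized `rq_field`.
#' @param low_threshold threshold in `[0, 1)`.
#' @return the thresholded `rq_field`.
#' @export
threshold_floor <- function(fld, low_threshold = 0.2) {
  stopifnot(inherits(fld, "rq_field"))
  if (low_threshold < 0 || low_threshold >= 1)
    stop("`low_threshold` must be in [0, 1)")
  fld$pixels[fld$pixels < low_threshold] <- 0
  fld
}

#' Segment the positive support into connected components
#'
#' Labels the strictly positive pixels of a (thresholded) field under the
#' requested connectivity and reports, per segment, its pixel count and
#' intensity-weighted centre of mass in physical coordinates.
#'
#' @param fld an `rq_field` (typically after [threshold_floor()]).
#' @param connectivity 8 (default) or 4.
#' @return list with `labels` (integer matrix, 0 = background) and
#'   `segments` (data frame: `label`, `n_pixels`, `x_um`, `y_um`).
#' @export
segment_field <- function(fld, connectivity = 8) {
  stopifnot(inherits(fld, "rq_field"))
  labels <- .cc_label(fld$pixels, as.integer(connectivity))
  k <- max(labels)
  if (k == 0) {
    segs <- data.frame(label = integer(), n_pixels = integer(),
                       x_um = numeric(), y_um = numeric())
    return(list(labels = labels, segments = segs))
  }
  idx <- which(labels > 0)
  lab <- labels[idx]
  w <- fld$pixels[idx]
  nr <- nrow(fld$pixels)
  ri <- ((idx - 1) %% nr) + 1
  ci <- ((idx - 1) %/% nr) + 1
  px <- fld$pixel_size
  wsum <- rowsum(w, lab)
  segs <- data.frame(
    label = sort(unique(lab)),
    n_pixels = as.integer(rowsum(rep(1L, length(lab)), lab)),
    x_um = as.numeric(rowsum(w * (ci - 0.5) * px, lab) / wsum),
    y_um = as.numeric(rowsum(w * (ri - 0.5) * px, lab) / wsum)
  )
  list(labels = labels, segments = segs)
}

#' De-duplicate candidate cell centres by minimum distance
#'
#' Points closer to each other than `min_distance` are considered the same
#' cell: the centres are partitioned by the transitive closure of the
#' strict "distance < min_distance" relation and one representative is
#' emitted per cluster (the unweighted centroid of the member centres).
#' Because closure can chain, output representatives of different clusters
#' are themselves guaranteed distinct, but not guaranteed to be farther
#' apart than `min_distance` in pathological chain configurations.
#'
#' Output is ordered deterministically: clusters are sorted by the pixel
#' count of their largest member segment (decreasing) when `sizes` is
#' given, then by (y, x) of the representative.
#'
#' @param centers numeric matrix with columns (x, y) in um.
#' @param min_distance merging distance in um (> 0).
#' @param sizes optional per-centre segment pixel counts, used for
#'   deterministic tie-breaking of output order.
#' @return list with `representatives` (matrix of cluster centroids) and
#'   `cluster` (integer cluster id per input row).
#' @export
dedupe_centroids <- function(centers, min_distance, sizes = NULL) {
  if (min_distance <= 0) stop("`min_distance` must be positive")
  centers <- matrix(as.numeric(centers), ncol = 2)
  n <- nrow(centers)
  if (n == 0) {
    return(list(representatives = centers, cluster = integer()))
  }
  # transitive closure by BFS over the strict-inequality distance graph
  d <- as.matrix(stats::dist(centers))
  cluster <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (cluster[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    cluster[i] <- cur
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(d[v, ] < min_distance & cluster == 0L)
      cluster[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  reps <- cbind(
    as.numeric(rowsum(centers[, 1], cluster) / tabulate(cluster)),
    as.numeric(rowsum(centers[, 2], cluster) / tabulate(cluster))
  )
  max_size <- if (is.null(sizes)) rep(0, max(cluster)) else
    as.numeric(tapply(sizes, cluster, max))
  ord <- order(-max_size, reps[, 2], reps[, 1])
  reps <- reps[ord, , drop = FALSE]
  remap <- match(seq_along(ord), ord)
  list(representatives = reps, cluster = remap[cluster])
}

#' Count cells in a field or z-stack
#'
#' The full automatic counting chain: z-stacks are reduced by projection
#' (mean by default); the image is normalized to its peak pixel so values
#' fall in `[0, 1]`; values below `low_threshold` are zeroed and the rest
#' retained; the remaining support is segmented into connected components;
#' each segment's intensity-weighted centre of mass is computed; and
#' centres closer than `min_distance` are merged so a cell split across
#' adjacent segments is counted only once.
#'
#' A field whose raw peak is below `params$noise_floor` is reported as
#' containing zero cells (blank-field guard); peak normalization of a
#' pure-noise image would otherwise rescale noise to full range.
#'
#' @param image an `rq_field` or `rq_zstack`.
#' @param params a [detection_params()].
#' @return an object of class `rq_detection`: list with `count`,
#'   `centroids` (matrix of (x, y) um), `segments`, `params`.
#' @export
count_cells <- function(image, params = detection_params()) {
  stopifnot(inherits(params, "rq_params"))
  fld <- project(image, params$projection)
  if (max(fld$pixels) < params$noise_floor) {
    res <- list(count = 0L, centroids = matrix(numeric(0), ncol = 2),
                segments = data.frame(label = integer(),
                                      n_pixels = integer(),
                                      x_um = numeric(), y_um = numeric()),
                params = params, guard_triggered = TRUE)
    return(structure(res, class = "rq_detection"))
  }
  fld <- normalize_peak(fld)
  fld <- threshold_floor(fld, params$low_threshold)
  seg <- segment_field(fld, params$connectivity)
  dd <- dedupe_centroids(as.matrix(seg$segments[, c("x_um", "y_um")]),
                         params$min_distance,
                         sizes = seg$segments$n_pixels)
  structure(
    list(count = nrow(dd$representatives),
         centroids = dd$representatives,
         segments = cbind(seg$segments, cluster = dd$cluster),
         params = params, guard_triggered = FALSE),
    class = "rq_detection"
  )
}

#' @export
print.rq_detection <- function(x, ...) {
  cat(sprintf("<rq_detection> %d cells (%d segments)%s\n", x$count,
              nrow(x$segments),
              if (isTRUE(x$guard_triggered)) " [noise-floor guard]" else ""))
  invisible(x)
}

#' Percent of field area above an intensity threshold
#'
#' The percent-area measure used for microglial coverage in the NFL-GCL
#' (percentage of retinal area occupied by marker-positive signal). The
#' threshold is applied to the peak-normalized image; `"otsu"` (default)
#' chooses it automatically by Otsu's method, mirroring the manual
#' threshold-tool adjustment of the original protocol, and the threshold
#' actually used is always reported.
#'
#' @param fld an `rq_field` (or `rq_zstack`, mean-projected first).
#' @param threshold `"otsu"` or a numeric threshold on the normalized
#'   `[0, 1]` scale.
#' @return an object of class `rq_area_fraction`: list with
#'   `percent_area`, `threshold_used`, `n_pixels_above`, `n_pixels`.
#' @export
area_fraction <- function(fld, threshold = "otsu") {
  fld <- project(fld, "mean")
  if (max(fld$pixels) <= 0) {
    # a blank field has no labelled area at any positive threshold
    thr <- if (identical(threshold, "otsu")) NA_real_ else
      as.numeric(threshold)
    return(structure(
      list(percent_area = 0, threshold_used = thr,
           n_pixels_above = 0L, n_pixels = length(fld$pixels)),
      class = "rq_area_fraction"))
  }
  norm <- normalize_peak(fld)
  thr <- if (identical(threshold, "otsu")) {
    EBImage::otsu(EBImage::Image(norm$pixels), range = c(0, 1))
  } else {
    as.numeric(threshold)
  }
  n_above <- sum(norm$pixels >= thr)
  n_total <- length(norm$pixels)
  structure(
    list(percent_area = 100 * n_above / n_total, threshold_used = thr,
         n_pixels_above = as.integer(n_above), n_pixels = n_total),
    class = "rq_area_fraction"
  )
}

#' @export
print.rq_area_fraction <- function(x, ...) {
  cat(sprintf("<rq_area_fraction> %.2f%% above threshold %.4f\n",
              x$percent_area, x$threshold_used))
  invisible(x)
}

#' Count vertical-process spots
#'
#' Runs [count_cells()] with spot-scale parameters on an interface-plane
#' field (the plane between the OPL and the photoreceptor outer segments,
#' where processes crossing vertically appear as bright puncta).
#'
#' @param fld an `rq_field`.
#' @param params a [spot_params()].
#' @return an `rq_detection`.
#' @export
count_spots <- function(fld, params = spot_params()) {
  count_cells(fld, params)
}
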