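#' Planted-cell ground truth record
#'
#' Describes one synthetic cell: its centre and soma radius in microns,
#' the coordinates of its process tips, its peak intensity (relative
#' units in (0, 1]) and its kind. This is the oracle against which
#' detection and morphometry are validated.
#'
#' @param center numeric length-2, (x, y) in um.
#' @param soma_radius soma radius in um (> 0).
#' @param process_tips numeric matrix with columns (x, y) in um, one row
#'   per process tip; every tip must lie farther from the centre than
#'   `soma_radius`. May have zero rows.
#' @param peak peak intensity in (0, 1].
#' @param kind one of `"microglia"`, `"rgc_nucleus"`, `"vertical_spot"`;
#'   the latter two carry no processes.
#' @return an object of class `rq_cell`.
#' @export
cell_truth <- function(center, soma_radius, process_tips = NULL,
                       peak = 1, kind = c("microglia", "rgc_nucleus",
                                          "vertical_spot")) {
  kind <- match.arg(kind)
  if (soma_radius <= 0) stop("`soma_radius` must be positive")
  if (peak <= 0 || peak > 1) stop("`peak` must be in (0, 1]")
  if (is.null(process_tips)) process_tips <- matrix(numeric(0), ncol = 2)
  process_tips <- matrix(as.numeric(process_tips), ncol = 2)
  if (kind != "microglia" && nrow(process_tips) > 0)
    stop(kind, " cells carry no processes")
  if (nrow(process_tips) > 0) {
    d <- sqrt((process_tips[, 1] - center[1])^2 +
              (process_tips[, 2] - center[2])^2)
    if (any(d <= soma_radius))
      stop("every process tip must lie outside the soma")
  }
  structure(
    list(center = as.numeric(center), soma_radius = soma_radius,
         n_processes = nrow(process_tips), process_tips = process_tips,
         peak = peak, kind = kind),
    class = "rq_cell"
  )
}

#' Microglial activation profile
#'
#' Positive multipliers, relative to the resting (baseline) state, for the
#' morphological changes that accompany microglial activation: cell
#' density, soma radius, arbor radius, and the number of vertical
#' processes crossing between the OPL and the photoreceptor outer
#' segments. `rgc_survival` scales the planted RGC density in the
#' ganglion cell layer (1 = no loss) and `superior_rgc` applies an extra
#' multiplier in the superior zone only. The baseline profile has all
#' factors equal to 1.
#'
#' The preset magnitudes returned by [profile_oht()] and friends are
#' illustrative configuration, not measured values: the study this
#' package emulates reports its effects only as figure histograms.
#'
#' @param density,soma,arbor,spots positive multipliers.
#' @param rgc_survival,superior_rgc positive multipliers for the RGC arm.
#' @return an object of class `rq_profile`.
#' @export
activation_profile <- function(density = 1, soma = 1, arbor = 1,
                               spots = 1, rgc_survival = 1,
                               superior_rgc = 1) {
  v <- c(density = density, soma = soma, arbor = arbor, spots = spots,
         rgc_survival = rgc_survival, superior_rgc = superior_rgc)
  if (any(v <= 0)) stop("all profile factors must be positive")
  structure(as.list(v), class = "rq_profile")
}

#' @rdname activation_profile
#' @export
profile_baseline <- function() activation_profile()

#' @rdname activation_profile
#' @export
profile_oht <- function() {
  activation_profile(density = 1.3, soma = 1.5, arbor = 0.7, spots = 1.4,
                     rgc_survival = 0.75, superior_rgc = 0.85)
}

#' @rdname activation_profile
#' @export
profile_oht_contralateral <- function() {
  activation_profile(density = 1.1, soma = 1.15, arbor = 0.9, spots = 1.6,
                     rgc_survival = 0.97)
}

#' @rdname activation_profile
#' @export
profile_saffron_oht <- function() {
  activation_profile(density = 1.1, soma = 1.15, arbor = 0.9, spots = 1.3,
                     rgc_survival = 0.95, superior_rgc = 0.9)
}

#' @rdname activation_profile
#' @export
profile_saffron_contralateral <- function() {
  activation_profile(density = 1.02, soma = 1.03, arbor = 0.97,
                     spots = 1.1, rgc_survival = 1)
}

#' Morphology defaults for the synthetic cell classes
#'
#' Baseline (resting-state) morphology parameters used by the generators.
#' All sizes are in microns; per-cell values are drawn around these means.
#' The values are illustrative and documented as such: soma radius ~4.5 um
#' and arbor radius ~22 um give the ramified, tiled appearance of
#' plexiform-layer microglia at realistic mosaic spacing; RGC nuclei are
#' smaller compact blobs; vertical-process spots are smaller still
#' (spot diameter < microglial soma diameter by construction).
#'
#' @return named list of morphology parameters.
#' @export
cell_defaults <- function() {
  list(
    microglia = list(soma_radius = 4.5, soma_sd = 0.5,
                     arbor_radius = 22, arbor_sd = 2.5,
                     n_processes = 4:6, peak = c(0.7, 1)),
    rgc_nucleus = list(soma_radius = 3.2, soma_sd = 0.35,
                       peak = c(0.6, 1), min_spacing = 9),
    vertical_spot = list(soma_radius = 1.5, soma_sd = 0.2,
                         peak = c(0.5, 0.9))
  )
}

# supergaussian radial profile: value = peak at d = 0, peak/2 at d = r
.soma_profile <- function(d, r, peak) peak * 2^(-(d / r)^6)

#' Render one cell additively into a field
#'
#' The soma is rendered as a smooth bright disc whose intensity falls to
#' half its peak exactly at `soma_radius`; each process is a tapering
#' ridge running from the soma edge to its tip, always dimmer than the
#' soma: 0.42 of the cell peak at its base, decaying rapidly to a distal
#' plateau of 0.12 so that only the proximal stub survives a global
#' 20%-of-peak threshold while the full arbor remains measurable per
#' cell above background. The
#' rendering is purely additive, so rendering the same cell twice doubles
#' its contribution and the returned field is everywhere >= the input.
#'
#' @param fld an [field()] to draw into.
#' @param truth an [cell_truth()]; its centre must lie inside the field
#'   (process tips may clip at the border).
#' @return the field with the cell added.
#' @export
render_cell <- function(fld, truth) {
  stopifnot(inherits(fld, "rq_field"), inherits(truth, "rq_cell"))
  px <- fld$pixel_size
  nr <- nrow(fld$pixels); nc <- ncol(fld$pixels)
  cx <- truth$center[1]; cy <- truth$center[2]
  if (cx < 0 || cy < 0 || cx > nc * px || cy > nr * px)
    stop("cell centre lies outside the field")
  r <- truth$soma_radius

  # soma: crop to 2.2 r around the centre
  half <- 2.2 * r
  j0 <- max(1L, floor((cx - half) / px)); j1 <- min(nc, ceiling((cx + half) / px))
  i0 <- max(1L, floor((cy - half) / px)); i1 <- min(nr, ceiling((cy + half) / px))
  xs <- (j0:j1 - 0.5) * px; ys <- (i0:i1 - 0.5) * px
  d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, "+"))
  fld$pixels[i0:i1, j0:j1] <- fld$pixels[i0:i1, j0:j1] +
    .soma_profile(d, r, truth$peak)

  if (truth$n_processes > 0) {
    for (k in seq_len(truth$n_processes)) {
      tip <- truth$process_tips[k, ]
      u <- tip - c(cx, cy)
      len <- sqrt(sum(u^2)); u <- u / len
      base <- c(cx, cy) + u * r          # process starts at the soma edge
      seg <- tip - base
      seg_len <- sqrt(sum(seg^2))
      if (seg_len <= 0) next
      # ridge half-width (um) at base; never narrower than the sampling
      # grid, so processes stay connected at coarse pixel sizes
      w0 <- max(1.2, 1.1 * px)
      pad <- 3 * w0
      jj0 <- max(1L, floor((min(base[1], tip[1]) - pad) / px))
      jj1 <- min(nc, ceiling((max(base[1], tip[1]) + pad) / px))
      ii0 <- max(1L, floor((min(base[2], tip[2]) - pad) / px))
      ii1 <- min(nr, ceiling((max(base[2], tip[2]) + pad) / px))
      if (jj1 < jj0 || ii1 < ii0) next
      xs <- (jj0:jj1 - 0.5) * px; ys <- (ii0:ii1 - 0.5) * px
      gx <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
      gy <- matrix(ys, nrow = length(ys), ncol = length(xs))
      # projection parameter along the segment, clamped to [0, 1]
      t <- ((gx - base[1]) * seg[1] + (gy - base[2]) * seg[2]) / seg_len^2
      t <- pmin(pmax(t, 0), 1)
      qx <- base[1] + t * seg[1]; qy <- base[2] + t * seg[2]
      dp <- sqrt((gx - qx)^2 + (gy - qy)^2)
      # bright at the soma, decaying fast to a dim distal plateau: the
      # proximal stub survives a global 20%-of-peak threshold, the distal
      # arbor does not (it is recovered by per-cell morphometry instead)
      amp <- truth$peak * (0.12 + 0.30 * exp(-6 * t))
      w <- pmax(w0 * (1 - 0.35 * t), 0.8 * px)
      fld$pixels[ii0:ii1, jj0:jj1] <- fld$pixels[ii0:ii1, jj0:jj1] +
        amp * exp(-0.5 * (dp / w)^2)
    }
  }
  fld
}

# random non-overlapping centres by rejection sampling; strict failure if
# the packing is infeasible within the attempt budget
.place_centers <- function(n, side_um, min_spacing, margin) {
  if (n == 0) return(matrix(numeric(0), ncol = 2))
  lo <- margin; hi <- side_um - margin
  if (hi <= lo) stop("field too small for the requested margin")
  centers <- matrix(NA_real_, n, 2)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 300L * n
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop(sprintf(
        "could not place %d cells at spacing %.1f um in a %.0f um field (mosaic packing infeasible)",
        n, min_spacing, side_um))
    p <- runif(2, lo, hi)
    if (placed > 0L) {
      d2 <- (centers[seq_len(placed), 1] - p[1])^2 +
            (centers[seq_len(placed), 2] - p[2])^2
      if (min(d2) < min_spacing^2) next
    }
    placed <- placed + 1L
    centers[placed, ] <- p
  }
  centers
}

# draw one microglial truth at a given centre
.draw_microglia <- function(center, profile, defs) {
  p <- defs$microglia
  r <- max(1.5, rnorm(1, p$soma_radius * profile$soma, p$soma_sd))
  arbor <- max(2.2 * r, rnorm(1, p$arbor_radius * profile$arbor, p$arbor_sd))
  npr <- sample(p$n_processes, 1)
  ang <- runif(1, 0, 2 * pi) + seq(0, 2 * pi, length.out = npr + 1)[-(npr + 1)] +
    rnorm(npr, 0, 0.15)
  tip_r <- arbor * runif(npr, 0.85, 1)
  tips <- cbind(center[1] + tip_r * cos(ang), center[2] + tip_r * sin(ang))
  cell_truth(center, r, tips, peak = runif(1, p$peak[1], p$peak[2]),
             kind = "microglia")
}

.truth_df <- function(truths) {
  if (length(truths) == 0) {
    return(data.frame(kind = character(), x_um = numeric(), y_um = numeric(),
                      soma_radius_um = numeric(), n_processes = integer(),
                      tips_json = character(), peak = numeric(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    kind = vapply(truths, function(t) t$kind, character(1)),
    x_um = vapply(truths, function(t) t$center[1], numeric(1)),
    y_um = vapply(truths, function(t) t$center[2], numeric(1)),
    soma_radius_um = vapply(truths, function(t) t$soma_radius, numeric(1)),
    n_processes = vapply(truths, function(t) t$n_processes, integer(1)),
    tips_json = vapply(truths, function(t)
      as.character(jsonlite::toJSON(t$process_tips, digits = NA)),
      character(1)),
    peak = vapply(truths, function(t) t$peak, numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' Generate one synthetic layer field with ground truth
#'
#' Places exactly `n_cells` cells in a non-overlapping mosaic (pairwise
#' centre distances at least the mosaic spacing, which defaults to twice
#' the profile-scaled mean arbor radius for microglia), renders them, and
#' adds a low uniform background with additive Gaussian noise clipped at
#' zero. For `kind = "rgc_nucleus"` (the NFL-GCL in the RGC-counting arm)
#' dense round process-free blobs are planted at nucleus-scale spacing
#' instead.
#'
#' Placement failure under the mosaic constraint raises an error after a
#' bounded number of rejection-sampling attempts; cells are never silently
#' dropped.
#'
#' @param n_cells number of cells to plant.
#' @param profile an [activation_profile()].
#' @param layer,zone labels stored on the field.
#' @param kind `"microglia"` or `"rgc_nucleus"`.
#' @param geometry a [field_geometry()].
#' @param noise_level standard deviation of the additive Gaussian noise.
#' @param background uniform background level (relative units).
#' @param seed integer seed; the generator never touches global RNG state.
#' @return list with elements `field` (an `rq_field`) and `truth` (a
#'   data frame, one row per planted cell).
#' @export
generate_layer_field <- function(n_cells, profile = profile_baseline(),
                                 layer = "OPL", zone = "superior",
                                 kind = c("microglia", "rgc_nucleus"),
                                 geometry = field_geometry(),
                                 noise_level = 0.01, background = 0.05,
                                 seed = 1) {
  kind <- match.arg(kind)
  defs <- cell_defaults()
  side_um <- geometry$px * geometry$pixel_size
  with_seed(seed, {
    if (kind == "microglia") {
      spacing <- 2 * defs$microglia$arbor_radius * profile$arbor
      margin <- defs$microglia$soma_radius * profile$soma * 2
      centers <- .place_centers(n_cells, side_um, spacing, margin)
      truths <- lapply(seq_len(n_cells), function(i)
        .draw_microglia(centers[i, ], profile, defs))
    } else {
      p <- defs$rgc_nucleus
      spacing <- p$min_spacing
      centers <- .place_centers(n_cells, side_um, spacing, 2 * p$soma_radius)
      truths <- lapply(seq_len(n_cells), function(i) {
        r <- max(1.2, rnorm(1, p$soma_radius, p$soma_sd))
        cell_truth(centers[i, ], r, NULL,
                   peak = runif(1, p$peak[1], p$peak[2]),
                   kind = "rgc_nucleus")
      })
    }
    fld <- field(matrix(0, geometry$px, geometry$px),
                 pixel_size = geometry$pixel_size, layer = layer, zone = zone)
    for (t in truths) fld <- render_cell(fld, t)
    fld$pixels <- pmax(fld$pixels + background +
                         matrix(rnorm(geometry$px^2, 0, noise_level),
                                geometry$px, geometry$px), 0)
    list(field = fld, truth = .truth_df(truths))
  })
}

#' Generate a field of vertical-process spots
#'
#' Emulates the bright puncta seen in the interface plane between the OPL
#' and the photoreceptor outer segments, where microglial processes cross
#' vertically between the two strata. Spots are small compact blobs with
#' no processes; by default their diameter is well below the microglial
#' soma diameter.
#'
#' @param n_spots number of spots (0 gives a noise-only field and empty
#'   truth).
#' @inheritParams generate_layer_field
#' @return list with `field` and `truth` as in [generate_layer_field()].
#' @export
generate_vertical_spots <- function(n_spots, zone = "superior",
                                    geometry = field_geometry(),
                                    noise_level = 0.01, background = 0.05,
                                    seed = 1) {
  defs <- cell_defaults()$vertical_spot
  side_um <- geometry$px * geometry$pixel_size
  with_seed(seed, {
    centers <- .place_centers(n_spots, side_um, 6, 2 * defs$soma_radius)
    truths <- lapply(seq_len(n_spots), function(i) {
      r <- max(0.8, rnorm(1, defs$soma_radius, defs$soma_sd))
      cell_truth(centers[i, ], r, NULL,
                 peak = runif(1, defs$peak[1], defs$peak[2]),
                 kind = "vertical_spot")
    })
    fld <- field(matrix(0, geometry$px, geometry$px),
                 pixel_size = geometry$pixel_size, layer = "OPL-OS",
                 zone = zone)
    for (t in truths) fld <- render_cell(fld, t)
    fld$pixels <- pmax(fld$pixels + background +
                         matrix(rnorm(geometry$px^2, 0, noise_level),
                                geometry$px, geometry$px), 0)
    list(field = fld, truth = .truth_df(truths))
  })
}

#' Spread a rendered field over a short z-stack
#'
#' Emulates optical sectioning at fixed spacing: the cells' in-plane
#' pattern is shared across sections with a triangular intensity profile
#' peaking at the central section, and each section receives independent
#' background noise. This makes the mean projection meaningful: averaging
#' recovers the in-focus pattern at reduced noise.
#'
#' @param gen output of [generate_layer_field()] (noise-free structure is
#'   reconstructed internally from the noisy field minus background, so
#'   pass `background` and `noise_level` matching the generation call).
#' @param n_sections odd number of sections (default 5).
#' @param z_spacing section spacing in um (default 2).
#' @inheritParams generate_layer_field
#' @return the input list with `field` replaced by an `rq_zstack`.
#' @export
as_zstack <- function(gen, n_sections = 5, z_spacing = 2,
                      noise_level = 0.01, background = 0.05, seed = 1) {
  stopifnot(inherits(gen$field, "rq_field"))
  structure_px <- pmax(gen$field$pixels - background, 0)
  k <- (n_sections + 1) / 2
  weights <- 1 - abs(seq_len(n_sections) - k) / k   # triangular, peak 1
  d <- dim(structure_px)
  sections <- with_seed(seed, lapply(weights, function(w) {
    pmax(structure_px * w + background +
           matrix(rnorm(prod(d), 0, noise_level), d[1], d[2]), 0)
  }))
  gen$field <- zstack(sections, pixel_size = gen$field$pixel_size,
                      z_spacing = z_spacing, layer = gen$field$layer,
                      zone = gen$field$zone)
  gen
}
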