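#' Soma area of one detected cell
#'
#' Automated proxy for the hand-drawn soma contour: the area of the
#' connected pixel region around the cell centroid whose intensity is at
#' least `soma_fraction` of the cell's own peak, converted to square
#' microns. The default fraction of 0.5 is the half-maximum convention,
#' making the measure invariant to global intensity scale.
#'
#' The cell is measured in isolation inside a crop window around its
#' centroid; pixels nearer to a competing centroid are masked out first.
#'
#' @param fld an `rq_field`.
#' @param centroid numeric (x, y) in um, from an `rq_detection`.
#' @param soma_fraction fraction of the cell peak, in (0, 1].
#' @param window_um side of the isolation window in um.
#' @param others optional matrix of competing centroids (x, y) um.
#' @return soma area in um^2.
#' @export
soma_area <- function(fld, centroid, soma_fraction = 0.5, window_um = 70,
                      others = NULL) {
  m <- .measure_cell(fld, centroid, soma_fraction = soma_fraction,
                     window_um = window_um, others = others,
                     want_arbor = FALSE)
  m$soma_area_um2
}

#' Arbor area of one detected cell
#'
#' Automated proxy for the hand-drawn polygon connecting the distal-most
#' process tips: the cell's above-threshold support is skeletonized, the
#' skeleton endpoints (pixels with exactly one skeleton neighbour) are
#' found, and the convex-hull area of the endpoints together with the
#' soma boundary is returned in um^2. A process-free cell (no endpoints
#' beyond the soma) degrades gracefully to the hull of the soma boundary,
#' so arbor area >= soma area always. The convex hull is an upper
#' envelope of the hand-drawn simple polygon it replaces.
#'
#' @inheritParams soma_area
#' @param arbor_fraction support threshold as a fraction of the cell peak
#'   after background subtraction; low enough (default 0.08) that dim
#'   tapering process ends are retained.
#' @return list with `arbor_area_um2` and `tips` (matrix of endpoint
#'   coordinates in um).
#' @export
arbor_area <- function(fld, centroid, arbor_fraction = 0.08,
                       soma_fraction = 0.5, window_um = 70,
                       others = NULL) {
  m <- .measure_cell(fld, centroid, soma_fraction = soma_fraction,
                     arbor_fraction = arbor_fraction,
                     window_um = window_um, others = others,
                     want_arbor = TRUE)
  list(arbor_area_um2 = m$arbor_area_um2, tips = m$tips)
}

# shoelace polygon area (vertices in order)
.polygon_area <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# core per-cell measurement: crop, mask competitors, threshold, measure
.measure_cell <- function(fld, centroid, soma_fraction = 0.5,
                          arbor_fraction = 0.08, window_um = 70,
                          others = NULL, want_arbor = TRUE) {
  stopifnot(inherits(fld, "rq_field"))
  px <- fld$pixel_size
  nr <- nrow(fld$pixels); nc <- ncol(fld$pixels)
  half <- window_um / 2
  j0 <- max(1L, floor((centroid[1] - half) / px))
  j1 <- min(nc, ceiling((centroid[1] + half) / px))
  i0 <- max(1L, floor((centroid[2] - half) / px))
  i1 <- min(nr, ceiling((centroid[2] + half) / px))
  crop <- fld$pixels[i0:i1, j0:j1, drop = FALSE]
  xs <- (j0:j1 - 0.5) * px
  ys <- (i0:i1 - 0.5) * px
  # mask pixels closer to any competing centroid than to this cell
  removed <- matrix(FALSE, nrow(crop), ncol(crop))
  crop0 <- crop
  if (!is.null(others) && nrow(others) > 0) {
    gx <- matrix(xs, nrow(crop), ncol(crop), byrow = TRUE)
    gy <- matrix(ys, nrow(crop), ncol(crop))
    own <- (gx - centroid[1])^2 + (gy - centroid[2])^2
    for (k in seq_len(nrow(others))) {
      comp <- (gx - others[k, 1])^2 + (gy - others[k, 2])^2
      removed <- removed | (comp < own)
    }
    crop[removed] <- 0
  }
  # estimate and subtract the flat background so the per-cell thresholds
  # track the cell's own signal, not the camera offset
  bg <- stats::median(crop)
  crop <- pmax(crop - bg, 0)
  peak <- max(crop)
  if (peak <= 0) stop("cell centroid lies on zero intensity")

  # pixel of the centroid within the crop (clamped)
  ci <- min(max(1L, round(centroid[2] / px - i0 + 1)), nrow(crop))
  cj <- min(max(1L, round(centroid[1] / px - j0 + 1)), ncol(crop))

  region_containing <- function(mask) {
    lab <- .cc_label(mask * 1, 8L)
    l <- lab[ci, cj]
    if (l == 0) {
      # centroid pixel below threshold (can happen for weighted centres):
      # snap to the nearest above-threshold pixel
      idx <- which(mask)
      if (length(idx) == 0) return(matrix(FALSE, nrow(mask), ncol(mask)))
      rr <- ((idx - 1) %% nrow(mask)) + 1
      cc <- ((idx - 1) %/% nrow(mask)) + 1
      k <- which.min((rr - ci)^2 + (cc - cj)^2)
      l <- lab[rr[k], cc[k]]
    }
    lab == l
  }

  soma_mask <- region_containing(crop >= soma_fraction * peak)
  soma_n <- sum(soma_mask)
  out <- list(soma_area_um2 = soma_n * px^2)

  if (want_arbor) {
    support <- region_containing(crop >= arbor_fraction * peak)
    skel <- .zs_thin(support)
    # endpoints: skeleton pixels with exactly one 8-neighbour on the skeleton
    nb <- matrix(0L, nrow(skel), ncol(skel))
    s <- skel * 1L
    shift <- function(m, di, dj) {
      r <- nrow(m); c <- ncol(m)
      out <- matrix(0L, r, c)
      ri <- max(1, 1 + di):min(r, r + di)
      ci2 <- max(1, 1 + dj):min(c, c + dj)
      out[ri, ci2] <- m[ri - di, ci2 - dj]
      out
    }
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      nb <- nb + shift(s, di, dj)
    }
    ends <- skel & nb == 1
    # endpoints created by the isolation mask (the structure continues
    # into a neighbouring cell's territory) are truncation artifacts,
    # not process tips: drop any endpoint touching removed signal
    if (any(removed)) {
      removed_signal <- removed & (pmax(crop0 - bg, 0) >=
                                     arbor_fraction * peak)
      near_cut <- removed_signal
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        near_cut <- near_cut | shift(removed_signal * 1L, di, dj) > 0
      }
      ends <- ends & !near_cut
    }
    end_idx <- which(ends)
    # thinning retracts blunt arm ends by a few pixels: snap each
    # endpoint outward to the distal-most support pixel within 3.5 um
    if (length(end_idx) > 0) {
      snap2 <- (3.5 / px)^2
      sup_idx <- which(support)
      sr <- ((sup_idx - 1) %% nrow(crop)) + 1
      sc <- ((sup_idx - 1) %/% nrow(crop)) + 1
      end_idx <- vapply(end_idx, function(e) {
        er <- ((e - 1) %% nrow(crop)) + 1
        ec <- ((e - 1) %/% nrow(crop)) + 1
        near <- (sr - er)^2 + (sc - ec)^2 <= snap2
        cand <- sup_idx[near]
        cr <- sr[near]; cc2 <- sc[near]
        cand[which.max((cr - ci)^2 + (cc2 - cj)^2)]
      }, numeric(1))
    }
    soma_idx <- which(soma_mask)
    pts_idx <- c(end_idx, soma_idx)
    rr <- ((pts_idx - 1) %% nrow(crop)) + 1
    cc <- ((pts_idx - 1) %/% nrow(crop)) + 1
    pts <- cbind(xs[cc], ys[rr])
    hull_area <- if (nrow(pts) >= 3) {
      h <- grDevices::chull(pts)
      .polygon_area(pts[h, , drop = FALSE])
    } else 0
    out$arbor_area_um2 <- max(hull_area, out$soma_area_um2)
    tr <- ((end_idx - 1) %% nrow(crop)) + 1
    tc <- ((end_idx - 1) %/% nrow(crop)) + 1
    out$tips <- cbind(x_um = xs[tc], y_um = ys[tr])
    out$n_tips <- length(end_idx)
  }
  out
}

#' Morphometry for every detected cell in a field
#'
#' Applies [soma_area()] and [arbor_area()] to each centroid of a
#' detection result, masking competing cells by nearest-centroid
#' assignment so cells are measured individually.
#'
#' @param fld the `rq_field` the detection was run on.
#' @param detection an `rq_detection` from [count_cells()].
#' @param max_cells optionally measure only the first `max_cells`
#'   centroids (detection order is deterministic).
#' @inheritParams arbor_area
#' @return data frame with one row per measured cell: `cell_id`,
#'   `x_um`, `y_um`, `soma_area_um2`, `arbor_area_um2`, `n_tips`.
#' @export
measure_cells <- function(fld, detection, soma_fraction = 0.5,
                          arbor_fraction = 0.08, window_um = 70,
                          max_cells = Inf) {
  cents <- detection$centroids
  n <- min(nrow(cents), max_cells)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    m <- .measure_cell(fld, cents[i, ], soma_fraction = soma_fraction,
                       arbor_fraction = arbor_fraction,
                       window_um = window_um,
                       others = cents[-i, , drop = FALSE],
                       want_arbor = TRUE)
    rows[[i]] <- data.frame(cell_id = i, x_um = cents[i, 1],
                            y_um = cents[i, 2],
                            soma_area_um2 = m$soma_area_um2,
                            arbor_area_um2 = m$arbor_area_um2,
                            n_tips = m$n_tips)
  }
  if (n == 0) {
    return(data.frame(cell_id = integer(), x_um = numeric(),
                      y_um = numeric(), soma_area_um2 = numeric(),
                      arbor_area_um2 = numeric(), n_tips = integer()))
  }
  do.call(rbind, rows)
}
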