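# Independent brute-force oracles used to validate the production code
# paths. These are deliberately naive implementations.

# recursive-free flood fill over the strictly positive support
oracle_flood_fill <- function(mat, connectivity = 8) {
  nr <- nrow(mat); nc <- ncol(mat)
  lab <- matrix(0L, nr, nc)
  nbrs <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  }
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (mat[i, j] <= 0 || lab[i, j] != 0L) next
    cur <- cur + 1L
    frontier <- list(c(i, j))
    lab[i, j] <- cur
    while (length(frontier) > 0) {
      p <- frontier[[1]]; frontier <- frontier[-1]
      for (k in seq_len(nrow(nbrs))) {
        qi <- p[1] + nbrs[k, 1]; qj <- p[2] + nbrs[k, 2]
        if (qi < 1 || qi > nr || qj < 1 || qj > nc) next
        if (mat[qi, qj] > 0 && lab[qi, qj] == 0L) {
          lab[qi, qj] <- cur
          frontier[[length(frontier) + 1]] <- c(qi, qj)
        }
      }
    }
  }
  lab
}

# O(n^2) union-find on the strict "< min_distance" graph
oracle_union_find <- function(centers, min_distance) {
  n <- nrow(centers)
  if (n == 0) return(integer())
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((centers[i, ] - centers[j, ])^2))
    if (d < min_distance) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# shoelace area of a polygon given unordered points via their hull
oracle_hull_area <- function(pts) {
  h <- grDevices::chull(pts)
  xy <- pts[h, , drop = FALSE]
  n <- nrow(xy)
  if (n < 3) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# build a single centred microglia-like cell on a clean field
make_centred_cell <- function(px = 256, side_um = 100, soma_radius = 4.5,
                              tip_radii = NULL, n_tips = 5, peak = 0.9,
                              seed = 1) {
  geom <- field_geometry(px = px, area_mm2 = side_um^2 / 1e6)
  set.seed(seed)
  if (is.null(tip_radii)) tip_radii <- 22 * runif(n_tips, 0.85, 1)
  ang <- runif(1, 0, 2 * pi) +
    seq(0, 2 * pi, length.out = length(tip_radii) + 1)[-(length(tip_radii) + 1)]
  ctr <- c(side_um / 2, side_um / 2)
  tips <- cbind(ctr[1] + tip_radii * cos(ang), ctr[2] + tip_radii * sin(ang))
  truth <- cell_truth(ctr, soma_radius, tips, peak = peak)
  fld <- render_cell(field(matrix(0, geom$px, geom$px), geom$pixel_size),
                     truth)
  list(field = fld, truth = truth, center = ctr, tips = tips)
}

# brute-force enumeration of the two-sided exact Mann-Whitney p-value
oracle_mwu_exact <- function(x, y) {
  nx <- length(x); n <- nx + length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(n, nx)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# brute-force enumeration of the two-sided exact signed-rank p-value
oracle_signed_rank_exact <- function(x, y) {
  d <- (x - y)[x != y]
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  m <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  w_all <- as.numeric(signs %*% r)
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}
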