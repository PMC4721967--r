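# Rendering: rasterization, tip dilation, scan artifacts -----------------
#
# Coordinate convention: physical x (nm) runs along columns, y along rows;
# the centre of pixel (row i, col j), 1-based, is at
# x = (j - 0.5) * px, y = (i - 0.5) * px. Lengths are always converted via
# the pixel size of the scan spec.

# nearest pixel (row, col) of physical points; may fall outside the grid
points_to_pixels <- function(xy, px) {
  cbind(row = round(xy[, 2] / px + 0.5), col = round(xy[, 1] / px + 0.5))
}

# stamp offsets within physical radius r_nm of a pixel centre
disk_offsets <- function(r_nm, px) {
  r_px <- r_nm / px
  k <- ceiling(r_px)
  dd <- expand.grid(di = -k:k, dj = -k:k)
  dd[sqrt(dd$di^2 + dd$dj^2) <= r_px + 1e-12, , drop = FALSE]
}

# rasterize one geometry onto a height grid (combining with pmax)
rasterize_geometry <- function(grid, geom, scan) {
  px <- pixel_size(scan)
  n <- nrow(grid)
  stamp <- disk_offsets(scan$ridge_halfwidth_nm, px)
  touched <- integer(0)

  put <- function(grid, rows, cols, h) {
    ok <- rows >= 1L & rows <= n & cols >= 1L & cols <= ncol(grid)
    if (!any(ok)) return(list(grid = grid, idx = integer(0)))
    idx <- cbind(rows[ok], cols[ok])
    lin <- (idx[, 2] - 1L) * n + idx[, 1]
    lin <- unique(lin)
    grid[lin] <- pmax(grid[lin], h)
    list(grid = grid, idx = lin)
  }

  for (p in geom$polylines) {
    xy <- p$xy
    if (nrow(xy) < 2L) next
    # densely resample the polyline so consecutive stamps are 8-connected
    seg <- sqrt(rowSums((xy[-1L, , drop = FALSE] -
                         xy[-nrow(xy), , drop = FALSE])^2))
    total <- sum(seg)
    ns <- max(2L, ceiling(total / (0.3 * px)))
    cl <- c(0, cumsum(seg))
    s <- seq(0, total, length.out = ns)
    ix <- pmin(pmax(findInterval(s, cl, rightmost.closed = TRUE), 1L),
               nrow(xy) - 1L)
    f <- (s - cl[ix]) / pmax(seg[ix], 1e-12)
    pts <- xy[ix, , drop = FALSE] + f * (xy[ix + 1L, , drop = FALSE] -
                                         xy[ix, , drop = FALSE])
    pp <- points_to_pixels(pts, px)
    for (k in seq_len(nrow(stamp))) {
      res <- put(grid, pp[, 1] + stamp$di[k], pp[, 2] + stamp$dj[k],
                 p$height)
      grid <- res$grid
      touched <- c(touched, res$idx)
    }
  }

  for (d in geom$disks) {
    ctr_px <- points_to_pixels(matrix(d$center, 1L), px)
    off <- disk_offsets(d$radius, px)
    if (!nrow(off)) next
    r_frac <- pmin(sqrt(off$di^2 + off$dj^2) * px / d$radius, 1)
    h <- d$height * sqrt(pmax(1 - r_frac^2, 0))   # spherical-ish cap
    rows <- ctr_px[1] + off$di
    cols <- ctr_px[2] + off$dj
    ok <- rows >= 1L & rows <= n & cols >= 1L & cols <= ncol(grid)
    if (any(ok)) {
      lin <- (cols[ok] - 1L) * n + rows[ok]
      grid[lin] <- pmax(grid[lin], h[ok])
      touched <- c(touched, lin)
    }
  }

  list(grid = grid, footprint = sort(unique(touched)))
}

#' Dilate a height map with a spherical probe tip
#'
#' AFM images are (to first order) the grayscale dilation of the true
#' surface by the reflected tip shape: the apparent height at a pixel is the
#' maximum over the tip footprint of the surface height plus the (negative)
#' tip profile \eqn{b(u) = \sqrt{R^2 - |u|^2} - R}. The maximum height of an
#' isolated convex feature is unchanged (`b(0) = 0`) while lateral widths
#' broaden monotonically with the tip radius.
#'
#' @param heights Numeric matrix of surface heights (nm).
#' @param pixel_size_nm Lateral pixel size (nm).
#' @param tip_radius_nm Tip radius of curvature (nm); 0 returns the input.
#' @return Matrix of apparent heights, same dimensions.
#' @export
tip_dilate <- function(heights, pixel_size_nm, tip_radius_nm) {
  if (tip_radius_nm < 0) stop("tip_radius_nm must be >= 0", call. = FALSE)
  if (tip_radius_nm == 0) return(heights)
  off <- disk_offsets(tip_radius_nm, pixel_size_nm)
  r <- sqrt(off$di^2 + off$dj^2) * pixel_size_nm
  b <- sqrt(pmax(tip_radius_nm^2 - r^2, 0)) - tip_radius_nm
  nr <- nrow(heights); nc <- ncol(heights)
  out <- heights                       # offset (0,0), b = 0
  for (k in seq_len(nrow(off))) {
    di <- off$di[k]; dj <- off$dj[k]
    if (di == 0L && dj == 0L) next
    # out[i, j] gets heights[i + di, j + dj] + b
    ri <- max(1L, 1L - di):min(nr, nr - di)
    cj <- max(1L, 1L - dj):min(nc, nc - dj)
    out[ri, cj] <- pmax(out[ri, cj], heights[ri + di, cj + dj] + b[k])
  }
  out
}

# place geometries uniformly at random in the field, rejecting candidate
# positions whose footprint overlaps existing molecules by more than 60%
place_geometries <- function(geoms, scan, max_tries = 60L) {
  n <- scan$resolution_px
  px <- pixel_size(scan)
  field <- scan$field_size_nm
  occupied <- logical(n * n)
  placed <- vector("list", length(geoms))
  meta <- vector("list", length(geoms))

  footprint_of <- function(geom) {
    res <- rasterize_geometry(matrix(0, n, n), geom, scan)
    res$footprint
  }

  for (i in seq_along(geoms)) {
    g0 <- geoms[[i]]
    pts0 <- geometry_points(g0)
    ctr <- colMeans(pts0)
    best <- NULL
    for (try in seq_len(max_tries)) {
      rot <- stats::runif(1, 0, 2 * pi)
      shift <- stats::runif(2, 0, field)
      g <- transform_geometry(g0, rot, shift - ctr)
      pts <- geometry_points(g)
      if (any(pts < -field) || any(pts > 2 * field)) next
      fp <- footprint_of(g)
      if (!length(fp)) next
      ov <- sum(occupied[fp]) / length(fp)
      touches <- any(pts < 0) || any(pts > field)
      cand <- list(geom = g, fp = fp, overlap = ov, touches = touches,
                   anchor = shift, rot = rot)
      if (is.null(best) || ov < best$overlap) best <- cand
      if (ov <= 0.6) break
    }
    if (is.null(best)) stop("placement failed", call. = FALSE)
    occupied_before <- sum(occupied[best$fp]) > 0L
    occupied[best$fp] <- TRUE
    placed[[i]] <- best$geom
    meta[[i]] <- list(anchor = best$anchor, rot = best$rot,
                      touches_border = best$touches,
                      overlaps_other = occupied_before,
                      footprint = best$fp)
  }
  list(geoms = placed, meta = meta)
}

#' Render one scan field from placed molecule geometries
#'
#' Rasterizes the polylines as ridges and the globules as caps, applies
#' probe-tip dilation, then adds the scan artifacts: a tilted plane,
#' per-scan-line offsets and per-pixel Gaussian noise. With a zero-radius
#' tip and all artifact amplitudes zero the output equals the ideal
#' rasterized height map exactly.
#'
#' @param geoms List of molecule geometries (already in field coordinates).
#' @param scan A [scan_spec()].
#' @param truths Optional ground-truth table (one row per geometry) to carry
#'   through with placement flags filled in.
#' @return List with `topograph` (provenance `"raw"`), `truth`, and
#'   `footprints` (per-molecule linear pixel indices of the ideal raster).
#' @export
render_topograph <- function(geoms, scan, truths = NULL) {
  validate_scan_spec(scan)
  n <- scan$resolution_px
  px <- pixel_size(scan)
  grid <- matrix(0, n, n)
  footprints <- vector("list", length(geoms))
  for (i in seq_along(geoms)) {
    pts <- geometry_points(geoms[[i]])
    if (any(pts < -scan$field_size_nm) ||
        any(pts > 2 * scan$field_size_nm)) {
      stop("geometry lies outside twice the field size", call. = FALSE)
    }
    res <- rasterize_geometry(grid, geoms[[i]], scan)
    grid <- res$grid
    footprints[[i]] <- res$footprint
  }
  ideal <- grid
  grid <- tip_dilate(grid, px, scan$tip_radius_nm)
  if (scan$slant_plane_gradient_nm_per_px != 0) {
    g <- scan$slant_plane_gradient_nm_per_px
    grid <- grid + outer(seq_len(n) * g, seq_len(n) * g, "+")
  }
  if (scan$slant_row_sd_nm > 0) {
    grid <- grid + stats::rnorm(n, 0, scan$slant_row_sd_nm)  # recycles by row
  }
  if (scan$noise_sd_nm > 0) {
    grid <- grid + matrix(stats::rnorm(n * n, 0, scan$noise_sd_nm), n, n)
  }
  tp <- topograph(grid, px, provenance = "raw",
                  metadata = list(tip_radius_nm = scan$tip_radius_nm,
                                  z_range_nm = scan$z_range_nm))
  list(topograph = tp, truth = truths, footprints = footprints,
       ideal = ideal)
}

#' Generate a seeded population of synthetic scan fields
#'
#' Draws `n_molecules` molecules from the population spec (each molecule on
#' its own deterministic RNG substream of the root seed, so populations are
#' reproducible regardless of evaluation order), places them
#' `molecules_per_field` at a time into scan fields, and renders each field.
#'
#' @param pop A [population_spec()] (or preset from [population_preset()]).
#' @param scan A [scan_spec()].
#' @return List with `fields` (list of [render_topograph()] results, each
#'   with its `truth` rows filled in) and `truth` (the combined ground-truth
#'   table, one row per molecule).
#' @export
#' @examples
#' pop <- population_preset("wt", n_molecules = 4, seed = 7)
#' sc <- scan_spec(resolution_px = 128, field_size_nm = 300)
#' out <- generate_population(pop, sc)
#' out$truth$class_label
generate_population <- function(pop, scan = scan_spec()) {
  validate_population_spec(pop)
  validate_scan_spec(scan)
  n <- pop$n_molecules
  step <- max(pixel_size(scan), 0.75)

  mols <- vector("list", n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(molecule_seed(pop$seed, i))
    draw <- draw_molecule(pop)
    bb <- sample_backbone(draw$contour_length_nm, pop$persistence_length_nm,
                          min(step, draw$contour_length_nm / 12))
    mf <- add_features(bb, draw, pop, scan)
    mf$truth$molecule_id <- i
    mols[[i]] <- mf$geometry
    truths[[i]] <- mf$truth
  }

  per_field <- max(1L, pop$molecules_per_field)
  n_fields <- if (n == 0L) 1L else ceiling(n / per_field)
  fields <- vector("list", n_fields)
  for (f in seq_len(n_fields)) {
    idx <- if (n == 0L) integer(0) else
      seq.int((f - 1L) * per_field + 1L, min(f * per_field, n))
    set.seed(molecule_seed(pop$seed, 1000000L + f))
    pl <- place_geometries(mols[idx], scan)
    tr <- if (length(idx)) do.call(rbind, truths[idx]) else
      truths_prototype()
    for (k in seq_along(idx)) {
      tr$anchor_x_nm[k] <- pl$meta[[k]]$anchor[1]
      tr$anchor_y_nm[k] <- pl$meta[[k]]$anchor[2]
      tr$rot_rad[k] <- pl$meta[[k]]$rot
      tr$touches_border[k] <- pl$meta[[k]]$touches_border
      tr$overlaps_other[k] <- pl$meta[[k]]$overlaps_other
    }
    tr$field <- if (length(idx)) f else integer(0)
    fields[[f]] <- render_topograph(pl$geoms, scan, tr)
    # anchor = centroid of the ideal rasterized footprint (what a detected
    # mask centroid estimates), not the placement target
    px <- pixel_size(scan)
    for (k in seq_along(idx)) {
      fp <- fields[[f]]$footprints[[k]]
      if (length(fp)) {
        pp <- arrayInd(fp, c(scan$resolution_px, scan$resolution_px))
        fields[[f]]$truth$anchor_x_nm[k] <- (mean(pp[, 2]) - 0.5) * px
        fields[[f]]$truth$anchor_y_nm[k] <- (mean(pp[, 1]) - 0.5) * px
      }
    }
  }
  truth <- do.call(rbind, lapply(fields, function(x) x$truth))
  list(fields = fields, truth = truth)
}

# deterministic 31-bit substream seed for molecule i under root seed
molecule_seed <- function(seed, i) {
  (as.numeric(seed) * 100003 + 7919 * as.numeric(i)) %% 2147483647
}

truths_prototype <- function() {
  tibble::tibble(
    molecule_id = integer(0), true_contour_length_nm = numeric(0),
    n_splayed_ends = integer(0), arm_n1_nm = numeric(0),
    arm_n2_nm = numeric(0), arm_c1_nm = numeric(0), arm_c2_nm = numeric(0),
    has_bubble = logical(0), bubble_strand1_nm = numeric(0),
    bubble_strand2_nm = numeric(0), bubble_start_rel = numeric(0),
    bubble_end_rel = numeric(0), label_rel = numeric(0),
    class_label = character(0), anchor_x_nm = numeric(0),
    anchor_y_nm = numeric(0), rot_rad = numeric(0),
    touches_border = logical(0), overlaps_other = logical(0)
  )
}
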