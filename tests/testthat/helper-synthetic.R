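# shared fixtures: small scan geometries and single-shape renders

clean_scan <- function(resolution_px = 256L, field_size_nm = 600) {
  scan_spec(resolution_px = resolution_px, field_size_nm = field_size_nm,
            tip_radius_nm = 0, noise_sd_nm = 0, slant_row_sd_nm = 0,
            slant_plane_gradient_nm_per_px = 0)
}

default_scan_small <- function() {
  scan_spec(resolution_px = 256L, field_size_nm = 600)
}

# render a bare polyline (no caps) and trace it back to an anatomy
shape_anatomy <- function(xy, scan = clean_scan(), height = 1.5) {
  geom <- list(polylines = list(list(xy = xy, role = "stalk",
                                     height = height)),
               disks = list())
  out <- render_topograph(list(geom), scan)
  fl <- topograph(out$topograph$heights, out$topograph$pixel_size_nm,
                  provenance = "flattened")
  obj <- detect_objects(fl)
  i <- which.max(obj$area_px)
  identify_features(skeletonize_molecule(obj$mask[[i]], fl))
}

# independently coded two-pass median subtraction (row loop then col loop)
flatten_oracle <- function(h) {
  for (r in seq_len(nrow(h))) h[r, ] <- h[r, ] - stats::median(h[r, ])
  for (cc in seq_len(ncol(h))) h[, cc] <- h[, cc] - stats::median(h[, cc])
  h
}

# brute-force grayscale dilation: per-pixel max of height + tip profile,
# where the profile is b(u) = sqrt(R^2 - |u|^2) - R over the footprint
dilate_oracle <- function(h, px, R) {
  if (R == 0) return(h)
  k <- ceiling(R / px)
  nr <- nrow(h); nc <- ncol(h)
  out <- h
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    best <- h[i, j]
    for (di in -k:k) for (dj in -k:k) {
      r <- sqrt(di^2 + dj^2) * px
      if (r > R + 1e-12) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      b <- sqrt(max(R^2 - r^2, 0)) - R
      v <- h[ii, jj] + b
      if (v > best) best <- v
    }
    out[i, j] <- best
  }
  out
}
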