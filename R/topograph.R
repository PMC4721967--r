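#' Construct an AFM topograph
#'
#' A topograph is the basic image unit of the package: a rectangular grid of
#' surface heights in nanometres together with its lateral pixel size.
#' Rows correspond to scan lines (the slow axis), columns to the fast axis.
#'
#' @param heights Numeric matrix of heights in nm. All values must be finite.
#' @param pixel_size_nm Lateral size of one pixel in nm (> 0).
#' @param provenance Either `"raw"` (as scanned/simulated, before flattening)
#'   or `"flattened"`.
#' @param metadata Named list of free-form metadata carried along with the
#'   image (seed, spec echo, scan parameters, ...).
#'
#' @return An object of class `"topograph"`: a list with elements `heights`,
#'   `pixel_size_nm`, `provenance` and `metadata`.
#' @export
#' @examples
#' tp <- topograph(matrix(0, 16, 16), pixel_size_nm = 2.34)
#' dim(tp$heights)
topograph <- function(heights, pixel_size_nm, provenance = "raw",
                      metadata = list()) {
  if (!is.matrix(heights) || !is.numeric(heights)) {
    stop("`heights` must be a numeric matrix", call. = FALSE)
  }
  bad <- which(!is.finite(heights))
  if (length(bad)) {
    ij <- arrayInd(bad[seq_len(min(5L, length(bad)))], dim(heights))
    stop(sprintf(
      "non-finite heights at %d pixel(s), first offenders (row,col): %s",
      length(bad),
      paste(apply(ij, 1L, function(r) sprintf("(%d,%d)", r[1], r[2])),
            collapse = " ")
    ), call. = FALSE)
  }
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L ||
      !is.finite(pixel_size_nm) || pixel_size_nm <= 0) {
    stop("`pixel_size_nm` must be a single positive finite number",
         call. = FALSE)
  }
  provenance <- match.arg(provenance, c("raw", "flattened"))
  structure(
    list(heights = heights, pixel_size_nm = as.numeric(pixel_size_nm),
         provenance = provenance, metadata = metadata),
    class = "topograph"
  )
}

#' @export
print.topograph <- function(x, ...) {
  d <- dim(x$heights)
  cat(sprintf(
    "<topograph> %d x %d px, %.4g nm/px (%.3g x %.3g nm), %s\n",
    d[1], d[2], x$pixel_size_nm,
    d[2] * x$pixel_size_nm, d[1] * x$pixel_size_nm, x$provenance))
  cat(sprintf("  height range: [%.4g, %.4g] nm\n",
              min(x$heights), max(x$heights)))
  invisible(x)
}

is_topograph <- function(x) inherits(x, "topograph")

#' Read / write topographs as whitespace-delimited ASCII grids
#'
#' The ASCII grid dialect is one matrix row per line, values separated by
#' single spaces, written with 17 significant digits so that doubles
#' round-trip exactly. A sidecar JSON file (`<path>.json`) stores the pixel
#' size, provenance and metadata.
#'
#' @param x A [topograph()].
#' @param path File path for the grid; the sidecar is `<path>.json`.
#' @return `write_topograph_ascii()` returns `path` invisibly;
#'   `read_topograph_ascii()` returns a [topograph()].
#' @export
write_topograph_ascii <- function(x, path) {
  stopifnot(is_topograph(x))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(x$heights, 1L, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = " ")), con)
  side <- list(pixel_size_nm = x$pixel_size_nm, provenance = x$provenance,
               metadata = x$metadata, format = "ascii-grid")
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_topograph_ascii
#' @export
read_topograph_ascii <- function(path) {
  lines <- readLines(path)
  rows <- lapply(strsplit(trimws(lines), "[[:space:]]+"), as.numeric)
  n <- unique(lengths(rows))
  if (length(n) != 1L) stop("ragged ASCII grid in ", path, call. = FALSE)
  h <- do.call(rbind, rows)
  sidecar <- paste0(path, ".json")
  px <- 1
  prov <- "raw"
  meta <- list()
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(side$pixel_size_nm)) px <- side$pixel_size_nm
    if (!is.null(side$provenance)) prov <- side$provenance
    if (!is.null(side$metadata)) meta <- as.list(side$metadata)
  }
  topograph(h, px, provenance = prov, metadata = meta)
}

#' Read / write topographs as single-channel 32-bit float TIFF
#'
#' Heights (nm) are divided by a power-of-two z-scale before writing so the
#' stored samples fall in [0, 1] (the well-defined range for float TIFF in
#' the \pkg{tiff} package) and multiplied back on read; the scale and the
#' usual metadata live in the sidecar JSON. Values round-trip exactly at
#' binary32 precision.
#'
#' @inheritParams write_topograph_ascii
#' @param z_scale_nm Power-of-two height that maps to a stored sample of 1.0.
#' @return `write_topograph_tiff()` returns `path` invisibly;
#'   `read_topograph_tiff()` returns a [topograph()].
#' @export
write_topograph_tiff <- function(x, path, z_scale_nm = 64) {
  stopifnot(is_topograph(x))
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF output", call. = FALSE)
  }
  rng <- range(x$heights)
  if (rng[1] < 0 || rng[2] > z_scale_nm) {
    stop(sprintf("heights [%.3g, %.3g] outside [0, z_scale_nm = %g]",
                 rng[1], rng[2], z_scale_nm), call. = FALSE)
  }
  tiff::writeTIFF(x$heights / z_scale_nm, path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  side <- list(pixel_size_nm = x$pixel_size_nm, provenance = x$provenance,
               z_scale_nm = z_scale_nm, metadata = x$metadata,
               format = "float32-tiff")
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_topograph_tiff
#' @export
read_topograph_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF input", call. = FALSE)
  }
  h <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(h)) == 3L) h <- h[, , 1L]
  sidecar <- paste0(path, ".json")
  px <- 1; prov <- "raw"; meta <- list(); zs <- 1
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(side$pixel_size_nm)) px <- side$pixel_size_nm
    if (!is.null(side$provenance)) prov <- side$provenance
    if (!is.null(side$z_scale_nm)) zs <- side$z_scale_nm
    if (!is.null(side$metadata)) meta <- as.list(side$metadata)
  }
  topograph(h * zs, px, provenance = prov, metadata = meta)
}
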