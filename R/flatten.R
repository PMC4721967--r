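#' Flatten an AFM topograph by row- and column-wise median subtraction
#'
#' Raw AFM scans carry a sample slant (the mica plane is never perfectly
#' perpendicular to the z piezo) plus per-scan-line offsets. Because the
#' molecules of interest cover only a small fraction of each scan line, the
#' median of a line is an estimate of its local background, so subtracting
#' the median of every row and then the median of every column of the result
#' removes both the plane tilt and the line offsets without biasing the
#' sparse foreground.
#'
#' The median of an even-length line is the mean of the two central values
#' (the [stats::median()] convention). A single pass is made per axis, rows
#' first; the operation is idempotent on its own output and invariant to
#' adding a constant to the input.
#'
#' @param x A [topograph()] with `provenance = "raw"`.
#' @return A [topograph()] with `provenance = "flattened"`, same dimensions
#'   and pixel size.
#' @export
#' @examples
#' raw <- topograph(outer(0:3, 0:3, "+") * 1.0, 2.0)
#' flatten(raw)$heights   # additive row+column field flattens to all zeros
flatten <- function(x) {
  stopifnot(is_topograph(x))
  if (x$provenance != "raw") {
    stop("flatten() expects a raw topograph (provenance = \"raw\")",
         call. = FALSE)
  }
  h <- x$heights
  h <- sweep(h, 1L, apply(h, 1L, stats::median))
  h <- sweep(h, 2L, apply(h, 2L, stats::median))
  topograph(h, x$pixel_size_nm, provenance = "flattened",
            metadata = x$metadata)
}
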