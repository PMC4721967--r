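#' Sample a planar worm-like-chain backbone
#'
#' Surface-adsorbed coiled coils equilibrate in (approximately) two
#' dimensions on mica, so molecule backbones are modeled as discrete planar
#' worm-like chains: a polyline of fixed-length steps whose successive
#' turning angles are independent zero-mean Gaussians with variance
#' `step_nm / persistence_length_nm`. In the stiff limit the chain is a
#' straight segment; for the discrete chain the mean squared end-to-end
#' distance has the standard closed form in the per-step tangent correlation
#' `exp(-step / (2 Lp))` (see [wlc_mean_sq_end_to_end()]).
#'
#' @param contour_length_nm Total contour length in nm (> 0).
#' @param persistence_length_nm Persistence length in nm (> 0).
#' @param step_nm Discretization step in nm; must be at most
#'   `contour_length_nm / 10` so the chain is resolved.
#' @param start Numeric length-2 start point (nm), default origin.
#' @param heading0 Initial heading in radians; default drawn uniformly.
#' @return Matrix with columns `x`, `y` (nm); the ordered polyline vertices.
#'   Sum of segment lengths equals `contour_length_nm` within one step.
#' @export
#' @examples
#' set.seed(1)
#' b <- sample_backbone(100, 50, 2)
#' nrow(b)                    # 51 vertices, 50 steps
sample_backbone <- function(contour_length_nm, persistence_length_nm,
                            step_nm, start = c(0, 0), heading0 = NULL) {
  if (!is.finite(contour_length_nm) || contour_length_nm <= 0) {
    stop("`contour_length_nm` must be positive", call. = FALSE)
  }
  if (!is.finite(persistence_length_nm) || persistence_length_nm <= 0) {
    stop("`persistence_length_nm` must be positive", call. = FALSE)
  }
  if (!is.finite(step_nm) || step_nm <= 0 ||
      step_nm > contour_length_nm / 10) {
    stop("`step_nm` must be positive and at most contour_length_nm / 10",
         call. = FALSE)
  }
  n_full <- floor(contour_length_nm / step_nm)
  rem <- contour_length_nm - n_full * step_nm
  steps <- rep(step_nm, n_full)
  if (rem > 1e-9 * contour_length_nm) steps <- c(steps, rem)
  n <- length(steps)
  if (is.null(heading0)) heading0 <- stats::runif(1, 0, 2 * pi)
  # turning-angle variance proportional to arc length of the incoming step
  turns <- stats::rnorm(n, 0, sqrt(steps / persistence_length_nm))
  turns[1] <- 0
  theta <- heading0 + cumsum(turns)
  xy <- cbind(
    x = start[1] + cumsum(steps * cos(theta)),
    y = start[2] + cumsum(steps * sin(theta))
  )
  rbind(c(x = start[1], y = start[2]), xy)
}

#' Closed-form mean squared end-to-end distance of the discrete planar chain
#'
#' For a discrete chain of `n` steps of length `b` whose turning angles are
#' iid zero-mean Gaussian with variance `b / Lp`, the per-step tangent
#' correlation is `c = exp(-b / (2 Lp))` and
#' \deqn{\langle R^2\rangle = n b^2\left[\frac{1+c}{1-c}
#'   - \frac{2c(1-c^n)}{n(1-c)^2}\right].}
#' This is exact for the model simulated by [sample_backbone()] (with an
#' integer number of steps) and serves as its analytic reference.
#'
#' @param contour_length_nm,persistence_length_nm,step_nm As in
#'   [sample_backbone()]; `contour_length_nm` should be a multiple of
#'   `step_nm` for exactness.
#' @return Mean squared end-to-end distance in nm^2.
#' @export
wlc_mean_sq_end_to_end <- function(contour_length_nm, persistence_length_nm,
                                   step_nm) {
  n <- round(contour_length_nm / step_nm)
  b <- step_nm
  cc <- exp(-b / (2 * persistence_length_nm))
  n * b^2 * ((1 + cc) / (1 - cc) - 2 * cc * (1 - cc^n) / (n * (1 - cc)^2))
}

# polyline helpers ------------------------------------------------------

# cumulative arc length of a polyline (matrix with columns x, y)
polyline_arclength <- function(p) {
  if (nrow(p) < 2L) return(0)
  sum(sqrt(rowSums((p[-1L, , drop = FALSE] -
                    p[-nrow(p), , drop = FALSE])^2)))
}

# cumulative arc length at each vertex
polyline_cumlength <- function(p) {
  if (nrow(p) < 2L) return(0)
  c(0, cumsum(sqrt(rowSums((p[-1L, , drop = FALSE] -
                            p[-nrow(p), , drop = FALSE])^2))))
}

# point (and local tangent angle) at arc length s along polyline p
polyline_point_at <- function(p, s) {
  cl <- polyline_cumlength(p)
  s <- min(max(s, 0), cl[length(cl)])
  i <- findInterval(s, cl, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(p) - 1L)
  seg <- p[i + 1L, ] - p[i, ]
  len <- sqrt(sum(seg^2))
  f <- if (len > 0) (s - cl[i]) / len else 0
  list(point = p[i, ] + f * seg, angle = atan2(seg[2], seg[1]))
}

# sub-polyline between arc lengths s0 < s1 (includes interpolated endpoints)
polyline_slice <- function(p, s0, s1) {
  cl <- polyline_cumlength(p)
  total <- cl[length(cl)]
  s0 <- min(max(s0, 0), total)
  s1 <- min(max(s1, 0), total)
  a <- polyline_point_at(p, s0)$point
  b <- polyline_point_at(p, s1)$point
  keep <- which(cl > s0 & cl < s1)
  out <- rbind(a, p[keep, , drop = FALSE], b)
  colnames(out) <- c("x", "y")
  rownames(out) <- NULL
  out
}
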