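# Per-molecule metrics ---------------------------------------------------

#' Bubble size from the segment decomposition
#'
#' The bubble size of a molecule is the mean of its two strand lengths,
#' `(X4 + X5) / 2`; a molecule without a bubble has `X4 = X5 = 0` and a
#' bubble size of 0.
#'
#' @param xs Named numeric vector `X1`...`X8` from [measure_segments()] (or
#'   any vector with `X4`, `X5`).
#' @return Bubble size in nm.
#' @export
#' @examples
#' bubble_size(c(X4 = 30, X5 = 24))   # 27
bubble_size <- function(xs) {
  unname((xs[["X4"]] + xs[["X5"]])) / 2
}

#' Total molecule length from the segment decomposition
#'
#' Paired features (splay arms, bubble strands) are averaged, mirroring the
#' bubble-size formula, and the duplex stalks added:
#' `(X1+X2)/2 + X3 + (X4+X5)/2 + X6 + (X7+X8)/2`.
#'
#' @param xs Named numeric vector `X1`...`X8`.
#' @return Total length in nm.
#' @export
#' @examples
#' total_length(c(X1 = 20, X2 = 20, X3 = 40, X4 = 30, X5 = 24,
#'                X6 = 50, X7 = 10, X8 = 10))   # 147
total_length <- function(xs) {
  (xs[["X1"]] + xs[["X2"]]) / 2 + xs[["X3"]] +
    (xs[["X4"]] + xs[["X5"]]) / 2 + xs[["X6"]] +
    (xs[["X7"]] + xs[["X8"]]) / 2
}

#' Normalized splay-to-splay distance
#'
#' The Euclidean (chord) distance between the two splay junctions divided by
#' the traced backbone path length between them (for a bubble, the mean of
#' the two strand lengths enters the path). For molecules lacking a splay at
#' an end, the trimmed backbone terminus substitutes for the junction.
#' Rigid, elongated molecules approach 1; bent molecules fall below.
#'
#' @param anatomy Result of [identify_features()] with `status = "ok"`.
#' @return Fraction in (0, 1\] (up to discretization), or `NA` if the
#'   junctions coincide.
#' @export
normalized_splay_distance <- function(anatomy) {
  stopifnot(identical(anatomy$status, "ok"))
  xs <- measure_segments(anatomy)
  denom <- xs[["X3"]] + (xs[["X4"]] + xs[["X5"]]) / 2 + xs[["X6"]]
  if (denom <= 0) return(NA_real_)
  a <- anatomy$ends[[1]]$anchor
  b <- anatomy$ends[[2]]$anchor
  nd <- anatomy$graph$nodes
  chord <- sqrt((nd$row[a] - nd$row[b])^2 +
                (nd$col[a] - nd$col[b])^2) * anatomy$px
  if (chord <= 0) return(NA_real_)
  chord / denom
}

#' Relative positions of a feature along the molecule
#'
#' Path length from the GFP (N) end to the feature's start, centre and end,
#' divided by the total molecule length. The N-side arm pair contributes its
#' mean `(X1+X2)/2`, like the total-length formula. Positions are withheld
#' (`NA`) for orientation-ambiguous molecules.
#'
#' @param anatomy Result of [identify_features()] with `status = "ok"`.
#' @param feature `"bubble"` or `"antibody"`.
#' @return Numeric vector `(rel_begin, rel_center, rel_end)` in \[0, 1\]
#'   (or `NA`s when the feature is absent or orientation is unresolved).
#' @export
relative_positions <- function(anatomy, feature = c("bubble", "antibody")) {
  stopifnot(identical(anatomy$status, "ok"))
  feature <- match.arg(feature)
  nas <- c(rel_begin = NA_real_, rel_center = NA_real_, rel_end = NA_real_)
  if (anatomy$ambiguous) return(nas)
  xs <- measure_segments(anatomy)
  total <- total_length(xs)
  if (total <= 0) return(nas)
  n_arm <- (xs[["X1"]] + xs[["X2"]]) / 2
  if (feature == "bubble") {
    if (!anatomy$bubble$present) return(nas)
    begin <- n_arm + xs[["X3"]]
    end <- begin + (xs[["X4"]] + xs[["X5"]]) / 2
  } else {
    if (!isTRUE(anatomy$antibody$present)) return(nas)
    mp <- anatomy$main_path
    if (is.null(mp) || nrow(mp) < 2L) return(nas)
    steps <- ifelse(rowSums(abs(diff(mp))) == 2L, sqrt(2), 1) * anatomy$px
    cum <- c(0, cumsum(steps))
    # rescale the per-pixel arc coordinate onto the smoothed contour
    # metric used for all reported lengths
    sm_total <- contour_length(mp, anatomy$px)
    if (cum[length(cum)] > 0) cum <- cum * sm_total / cum[length(cum)]
    blob <- anatomy$antibody$blob_px
    arc <- vapply(seq_len(nrow(blob)), function(i) {
      d2 <- (mp[, 1] - blob[i, 1])^2 + (mp[, 2] - blob[i, 2])^2
      cum[which.min(d2)]
    }, numeric(1))
    begin <- n_arm + min(arc)
    end <- n_arm + max(arc)
  }
  out <- c(begin, (begin + end) / 2, end) / total
  out <- pmin(pmax(out, 0), 1)
  names(out) <- names(nas)
  out
}

#' Conformational class of a traced molecule
#'
#' One of eight classes from the three binary features: N-terminal splay,
#' C-terminal splay, central bubble. For orientation-ambiguous molecules the
#' N/C assignment follows the (tied) cap heights and should be interpreted
#' with care; the ambiguity flag is carried in the metrics table.
#'
#' @param anatomy Result of [identify_features()] with `status = "ok"`.
#' @return Class label string (see [class_label()]).
#' @export
classify_conformation <- function(anatomy) {
  stopifnot(identical(anatomy$status, "ok"))
  class_label(anatomy$ends[[1]]$splayed, anatomy$ends[[2]]$splayed,
              anatomy$bubble$present)
}

# assemble the one-row metrics record for a traced molecule
molecule_metrics_row <- function(object_id, anatomy) {
  if (!identical(anatomy$status, "ok")) {
    return(NULL)
  }
  xs <- measure_segments(anatomy)
  relb <- relative_positions(anatomy, "bubble")
  rela <- relative_positions(anatomy, "antibody")
  nd <- anatomy$graph$nodes
  a <- anatomy$ends[[1]]$anchor; b <- anatomy$ends[[2]]$anchor
  tibble::tibble(
    object_id = object_id,
    total_length_nm = total_length(xs),
    bubble_size_nm = bubble_size(xs),
    has_bubble = anatomy$bubble$present,
    splay_n = anatomy$ends[[1]]$splayed,
    splay_c = anatomy$ends[[2]]$splayed,
    n_splayed_ends = sum(anatomy$ends[[1]]$splayed,
                         anatomy$ends[[2]]$splayed),
    norm_splay_distance = normalized_splay_distance(anatomy),
    conformation_class = classify_conformation(anatomy),
    orientation_ambiguous = anatomy$ambiguous,
    rel_begin = relb[[1]], rel_center = relb[[2]], rel_end = relb[[3]],
    ab_rel_begin = rela[[1]], ab_rel_center = rela[[2]],
    ab_rel_end = rela[[3]],
    cap_h_n = anatomy$ends[[1]]$cap_h, cap_h_c = anatomy$ends[[2]]$cap_h,
    X1 = xs[["X1"]], X2 = xs[["X2"]], X3 = xs[["X3"]], X4 = xs[["X4"]],
    X5 = xs[["X5"]], X6 = xs[["X6"]], X7 = xs[["X7"]], X8 = xs[["X8"]],
    end1_row = nd$row[a], end1_col = nd$col[a],
    end2_row = nd$row[b], end2_col = nd$col[b]
  )
}
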