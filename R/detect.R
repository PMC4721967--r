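# Object detection and selection ----------------------------------------

#' Analysis parameters for detection, tracing and morphometry
#'
#' @param k_mad Threshold multiplier: foreground is above
#'   `median + k_mad * MAD` of the flattened image.
#' @param min_area_px Components smaller than this are set aside as
#'   `too_small` (noise speckle scale).
#' @param aggregate_area_factor Objects larger than this multiple of the
#'   median candidate area are rejected as aggregates.
#' @param spur_prune_nm Skeleton spur edges shorter than this are pruned;
#'   keep below the tip-broadened duplex width so true splay arms survive.
#' @param bubble_min_nm Minimum cycle contour for a skeleton cycle to count
#'   as a bubble (suppresses pixel-scale loops).
#' @param cap_trim_height_nm Terminal skeleton pixels whose (smoothed)
#'   height exceeds this are treated as globule cap and excluded from
#'   segment lengths.
#' @param height_tie_nm Minimum difference between terminal cap heights for
#'   an unambiguous N/C orientation call.
#' @param antibody_height_min_nm Minimum height of an off-backbone blob to
#'   be called an antibody label.
#' @param arm_max_nm Maximum length scale of a splay arm: a junction
#'   counts as a splay junction only within this distance of a backbone
#'   terminus, and only off-path terminal edges up to this length are arms.
#' @param hole_height_nm Enclosed regions of the object mask whose height
#'   stays below this are punched out before skeletonization (a bubble's
#'   inter-strand valley whose rim closed under tip broadening); default
#'   half the duplex ridge height. Set 0 to disable.
#' @return A list of class `"morph_params"`.
#' @export
morph_params <- function(k_mad = 3, min_area_px = 30L,
                         aggregate_area_factor = 2.5,
                         spur_prune_nm = 6, bubble_min_nm = 8,
                         cap_trim_height_nm = 1.95, height_tie_nm = 0.25,
                         antibody_height_min_nm = 3.2, arm_max_nm = 40,
                         hole_height_nm = 0.75) {
  structure(list(k_mad = k_mad, min_area_px = as.integer(min_area_px),
                 aggregate_area_factor = aggregate_area_factor,
                 spur_prune_nm = spur_prune_nm, bubble_min_nm = bubble_min_nm,
                 cap_trim_height_nm = cap_trim_height_nm,
                 height_tie_nm = height_tie_nm,
                 antibody_height_min_nm = antibody_height_min_nm,
                 arm_max_nm = arm_max_nm, hole_height_nm = hole_height_nm),
            class = "morph_params")
}

# connected components of a logical mask (8- or 4-connectivity);
# returns integer label matrix
label_components <- function(mask, connectivity = 8L) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (!length(idx)) return(lab)
  nr <- nrow(mask)
  pos <- arrayInd(idx, dim(mask))
  key <- (pos[, 2] - 1L) * nr + pos[, 1]
  lookup <- integer(nrow(mask) * ncol(mask))
  lookup[key] <- seq_along(key)
  # edges to forward neighbours among foreground pixels
  nbr <- if (connectivity == 8L) {
    list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(-1L, 1L))
  } else {
    list(c(0L, 1L), c(1L, 0L))
  }
  from <- integer(0); to <- integer(0)
  for (d in nbr) {
    r2 <- pos[, 1] + d[1]; c2 <- pos[, 2] + d[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncol(mask)
    k2 <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- lookup[k2] > 0L
    from <- c(from, which(ok)[hit])
    to <- c(to, lookup[k2][hit])
  }
  g <- igraph::make_graph(rbind(from, to), n = length(idx),
                          directed = FALSE)
  comp <- igraph::components(g)$membership
  lab[idx] <- comp
  lab
}

#' Detect candidate molecules in a flattened topograph
#'
#' Foreground pixels are those above `median + k_mad * MAD` of the image
#' (after flattening the background median is ~0 and the MAD estimates the
#' noise scale); objects are their 8-connected components. Components below
#' `min_area_px` are kept in the table with `rejection_reason = "too_small"`
#' so that every detected component is accounted for.
#'
#' @param x A flattened [topograph()].
#' @param params A [morph_params()].
#' @return A [tibble::tibble()] with one row per component: `object_id`,
#'   `area_px`, bounding box, `touches_border`, `mean_height_nm`,
#'   `rejection_reason` (`"none"` or `"too_small"`) and a `mask` list-column
#'   of linear pixel indices into the height matrix.
#' @export
detect_objects <- function(x, params = morph_params()) {
  stopifnot(is_topograph(x))
  if (x$provenance != "flattened") {
    stop("detect_objects() expects a flattened topograph", call. = FALSE)
  }
  h <- x$heights
  thr <- stats::median(h) + params$k_mad * stats::mad(h)
  mask <- h > thr
  lab <- label_components(mask)
  n_obj <- max(lab)
  if (n_obj == 0L) return(objects_prototype())
  nr <- nrow(h)
  idx <- which(lab > 0L)
  by_obj <- split(idx, lab[idx])
  rows <- lapply(seq_along(by_obj), function(i) {
    lin <- by_obj[[i]]
    pos <- arrayInd(lin, dim(h))
    tibble::tibble(
      object_id = i,
      area_px = length(lin),
      row_min = min(pos[, 1]), row_max = max(pos[, 1]),
      col_min = min(pos[, 2]), col_max = max(pos[, 2]),
      touches_border = min(pos) == 1L || max(pos[, 1]) == nr ||
        max(pos[, 2]) == ncol(h),
      mean_height_nm = mean(h[lin]),
      rejection_reason = if (length(lin) < params$min_area_px) "too_small"
        else "none",
      mask = list(lin)
    )
  })
  do.call(rbind, rows)
}

objects_prototype <- function() {
  tibble::tibble(object_id = integer(0), area_px = integer(0),
                 row_min = integer(0), row_max = integer(0),
                 col_min = integer(0), col_max = integer(0),
                 touches_border = logical(0), mean_height_nm = numeric(0),
                 rejection_reason = character(0), mask = list())
}

#' Apply the molecule selection criteria
#'
#' Mirrors the manual selection rules used on real scans: the whole object
#' must lie within the captured field (border-touching objects rejected) and
#' must be an isolated single molecule (components much larger than the
#' typical single-molecule area, or containing more than one ground-truth
#' molecule when truth is supplied, are rejected as aggregates).
#' Untraceable objects are flagged later, at the tracing stage.
#'
#' @param objects Table from [detect_objects()].
#' @param params A [morph_params()].
#' @param truth_anchors_px Optional matrix (row, col) of true molecule
#'   anchor pixels; objects containing more than one are aggregates.
#' @param img_dim Image dimensions `c(nrow, ncol)`; required when
#'   `truth_anchors_px` is supplied (to decode mask indices).
#' @return The object table with `rejection_reason` updated
#'   (`border` / `aggregate` where applicable).
#' @export
select_molecules <- function(objects, params = morph_params(),
                             truth_anchors_px = NULL, img_dim = NULL) {
  if (!nrow(objects)) return(objects)
  cand <- objects$rejection_reason == "none"
  objects$rejection_reason[cand & objects$touches_border] <- "border"
  cand <- objects$rejection_reason == "none"
  if (any(cand)) {
    med_area <- stats::median(objects$area_px[cand])
    big <- cand & objects$area_px > params$aggregate_area_factor * med_area
    objects$rejection_reason[big] <- "aggregate"
  }
  if (!is.null(truth_anchors_px) && nrow(truth_anchors_px)) {
    if (is.null(img_dim)) {
      stop("`img_dim` is required with `truth_anchors_px`", call. = FALSE)
    }
    nr <- img_dim[1]
    for (i in which(objects$rejection_reason == "none")) {
      # count anchors within the object's dilated mask
      lin <- objects$mask[[i]]
      pos <- cbind((lin - 1L) %% nr + 1L, (lin - 1L) %/% nr + 1L)
      hits <- sum(vapply(seq_len(nrow(truth_anchors_px)), function(a) {
        any(abs(pos[, 1] - truth_anchors_px[a, 1]) <= 2L &
            abs(pos[, 2] - truth_anchors_px[a, 2]) <= 2L)
      }, logical(1)))
      if (hits > 1L) objects$rejection_reason[i] <- "aggregate"
    }
  }
  objects
}

#' Retained fraction of molecule-scale objects
#'
#' The fraction of detected molecule-scale objects (i.e. excluding
#' noise-speckle components below the minimum area) that survive selection.
#' On typical preparations this covers 40-70% of the objects in a field; a
#' warning is emitted outside that band.
#'
#' @param objects Object table after selection (and tracing).
#' @return Fraction in \[0, 1\] (`NaN` if no molecule-scale objects).
#' @export
retained_fraction <- function(objects) {
  scale_obj <- objects$rejection_reason != "too_small"
  f <- sum(objects$rejection_reason == "none") / sum(scale_obj)
  if (is.finite(f) && (f < 0.4 || f > 0.7)) {
    warning(sprintf("retained fraction %.2f outside the typical 0.40-0.70 band",
                    f), call. = FALSE)
  }
  f
}
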