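# Molecule tracing: graph simplification, feature identification, and the
# eight-segment decomposition ------------------------------------------
#
# Segment convention (all lengths nm, 0 = feature absent):
#   X1, X2  N-terminal splay arms (X1 >= X2)
#   X3      N-side duplex stalk (whole stalk for bubble-free molecules)
#   X4, X5  bubble strands (X4 >= X5)
#   X6      C-side duplex stalk (0 for bubble-free molecules)
#   X7, X8  C-terminal splay arms (X7 >= X8)

# unit direction of edge `e` at node `n`, looking `look` pixels inward;
# NULL for degenerate paths
edge_dir_at <- function(e, n, look = 4L) {
  p <- e$path
  if (e$n1 == n) {
    a <- p[1L, ]; b <- p[min(nrow(p), look + 1L), ]
  } else {
    a <- p[nrow(p), ]; b <- p[max(1L, nrow(p) - look), ]
  }
  d <- b - a
  L <- sqrt(sum(d^2))
  if (L == 0) return(NULL)
  list(origin = a, dir = d / L)
}

# 3x3 maximum filter; robust local height for cap/blob calls (the maximum
# of a small window tracks feature peak height, unlike a mean, and adds
# only a small positive noise bias)
max_filter3 <- function(h) {
  nr <- nrow(h); nc <- ncol(h)
  M <- matrix(-Inf, nr + 2L, nc + 2L)
  M[2:(nr + 1L), 2:(nc + 1L)] <- h
  i <- 2:(nr + 1L); j <- 2:(nc + 1L)
  out <- M[i, j]
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    out <- pmax(out, M[i + di, j + dj])
  }
  out
}

# incidence list: for each node, indices of incident edges
edge_incidence <- function(g) {
  inc <- vector("list", nrow(g$nodes))
  for (k in seq_along(g$edges)) {
    e <- g$edges[[k]]
    inc[[e$n1]] <- c(inc[[e$n1]], k)
    if (e$n2 != e$n1) inc[[e$n2]] <- c(inc[[e$n2]], k)
  }
  inc
}

# absorb all degree-2 nodes (two distinct incident edges) by merging
absorb_degree2 <- function(g) {
  repeat {
    inc <- edge_incidence(g)
    deg <- skeleton_graph_degrees(g)
    cand <- which(deg == 2L & lengths(inc) == 2L)
    cand <- cand[vapply(cand, function(n) inc[[n]][1] != inc[[n]][2],
                        logical(1))]
    if (!length(cand)) return(g)
    n <- cand[1]
    ei <- inc[[n]]
    merged <- merge_edge_pair(g, n, ei[1], ei[2])
    g$edges[[ei[1]]] <- merged
    g$edges[[ei[2]]] <- NULL
  }
}

# remove pixel-scale loops (below the minimum bubble contour): short
# self-loop edges and parallel edge pairs with a short combined contour
drop_micro_loops <- function(g, bubble_min_nm) {
  repeat {
    drop <- integer(0)
    self_i <- which(vapply(g$edges, function(e)
      e$n1 == e$n2 && e$length_nm < bubble_min_nm, logical(1)))
    if (length(self_i)) {
      drop <- self_i[1]
    } else if (length(g$edges) >= 2L) {
      key <- vapply(g$edges, function(e)
        paste(sort(c(e$n1, e$n2)), collapse = "-"), character(1))
      for (dk in names(which(table(key) >= 2L))) {
        par_i <- which(key == dk)
        lens <- vapply(par_i, function(k) g$edges[[k]]$length_nm,
                       numeric(1))
        if (sum(sort(lens)[1:2]) < bubble_min_nm) {
          drop <- par_i[which.min(lens)]
          break
        }
      }
    }
    if (!length(drop)) return(absorb_degree2(g))
    g$edges[[drop]] <- NULL
  }
}

# remove terminal edges shorter than the spur threshold whose inner end is
# a junction; repeat with degree-2 absorption until stable. A junction
# carrying two or more terminal edges is a candidate splay fork, so its
# (paired) terminal edges are only pruned at pixel scale -- lone spurs are
# noise, twin short branches are anatomy.
prune_spurs <- function(g, spur_prune_nm) {
  repeat {
    g <- absorb_degree2(g)
    deg <- skeleton_graph_degrees(g)
    n_term_at <- integer(nrow(g$nodes))
    for (e in g$edges) {
      if (e$n1 == e$n2) next
      d1 <- deg[e$n1]; d2 <- deg[e$n2]
      if (xor(d1 == 1L, d2 == 1L)) {
        inner <- if (d1 == 1L) e$n2 else e$n1
        n_term_at[inner] <- n_term_at[inner] + 1L
      }
    }
    drop <- vapply(g$edges, function(e) {
      if (e$n1 == e$n2) return(FALSE)
      d1 <- deg[e$n1]; d2 <- deg[e$n2]
      is_term <- xor(d1 == 1L, d2 == 1L)
      if (!is_term) return(FALSE)
      inner <- if (d1 == 1L) e$n2 else e$n1
      if (deg[inner] < 3L) return(FALSE)
      limit <- if (n_term_at[inner] >= 2L) 0.3 * spur_prune_nm else
        spur_prune_nm
      e$length_nm < limit
    }, logical(1))
    if (!any(drop)) return(g)
    g$edges[drop] <- NULL
  }
}

# trim globule caps off terminal edge ends; records per-node cap height.
# The trim walk follows the raw ridge heights (skeleton pixels lie on the
# ridge crest, so the raw value is the feature height); the dilated
# max-filter heights are only used to record the cap height robustly.
trim_caps <- function(g, hraw, hmax, params) {
  deg <- skeleton_graph_degrees(g)
  inc <- edge_incidence(g)
  cap_h <- rep(NA_real_, nrow(g$nodes))
  max_trim_px <- ceiling(6 / g$px) + 1L
  for (n in which(deg == 1L)) {
    ei <- inc[[n]][1]
    e <- g$edges[[ei]]
    p <- e$path
    at_start <- e$n1 == n
    if (!at_start) p <- p[nrow(p):1, , drop = FALSE]
    hs <- hraw[p]
    cap_h[n] <- hmax[p][1]
    k <- 0L
    while (k < min(max_trim_px, nrow(p) - 2L) &&
           hs[k + 1L] > params$cap_trim_height_nm) {
      k <- k + 1L
      cap_h[n] <- max(cap_h[n], hmax[p][k])
    }
    if (k > 0L) {
      p <- p[(k + 1L):nrow(p), , drop = FALSE]
      if (!at_start) p <- p[nrow(p):1, , drop = FALSE]
      e$path <- p
      e$length_nm <- contour_length(p, g$px)
      # move the node's coordinate to the trimmed tip
      tip <- if (at_start) p[1L, ] else p[nrow(p), ]
      g$nodes$row[n] <- tip[1]
      g$nodes$col[n] <- tip[2]
      g$edges[[ei]] <- e
    }
  }
  g$cap_h <- cap_h
  g
}

#' Skeletonize a detected molecule into a pruned skeleton graph
#'
#' Crops the object, thins its mask to a medial skeleton, extracts the
#' node/edge graph, absorbs pass-through nodes, prunes spur edges below
#' `spur_prune_nm` and trims terminal globule caps (recording their heights
#' for N/C orientation). Objects whose skeleton keeps more than 2
#' independent cycles or more than 6 endpoints are flagged untraceable.
#'
#' @param mask_lin Linear pixel indices of the object in the image matrix.
#' @param x The flattened [topograph()].
#' @param params A [morph_params()].
#' @return List with `graph` (cropped coordinates), `crop` (row/col offsets
#'   and cropped max-filtered heights `hmax`, object mask `mask`), and
#'   `status` (`"ok"` or `"untraceable"`).
#' @export
skeletonize_molecule <- function(mask_lin, x, params = morph_params()) {
  stopifnot(is_topograph(x))
  h <- x$heights
  nr <- nrow(h)
  pos <- arrayInd(mask_lin, dim(h))
  r0 <- max(1L, min(pos[, 1]) - 2L); r1 <- min(nr, max(pos[, 1]) + 2L)
  c0 <- max(1L, min(pos[, 2]) - 2L); c1 <- min(ncol(h), max(pos[, 2]) + 2L)
  mask <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
  mask[cbind(pos[, 1] - r0 + 1L, pos[, 2] - c0 + 1L)] <- TRUE
  mask <- fill_small_holes(mask)
  hraw <- h[r0:r1, c0:c1, drop = FALSE]
  if (params$hole_height_nm > 0) {
    mask <- punch_enclosed_valleys(mask, hraw, params$hole_height_nm)
  }
  hmax <- max_filter3(hraw)
  skel <- thin_mask(mask)
  g <- skeleton_to_graph(skel, x$pixel_size_nm, heights = hmax)
  if (!length(g$edges)) {
    return(list(graph = g, crop = list(r0 = r0, c0 = c0, hmax = hmax,
                                       mask = mask),
                status = "untraceable"))
  }
  g <- drop_micro_loops(g, params$bubble_min_nm)
  g <- prune_spurs(g, params$spur_prune_nm)
  g <- drop_micro_loops(g, params$bubble_min_nm)
  g <- trim_caps(g, hraw, hmax, params)
  deg <- skeleton_graph_degrees(g)
  active <- sum(deg > 0L)
  n_end <- sum(deg == 1L)
  cycles <- length(g$edges) - active + 1L
  status <- if (cycles > 2L || n_end > 6L) "untraceable" else "ok"
  list(graph = g, crop = list(r0 = r0, c0 = c0, hmax = hmax, mask = mask),
       status = status)
}

#' Identify the structural anatomy of a traced molecule
#'
#' Labels the skeleton graph's edges as splay arms, duplex stalks and bubble
#' strands: the unique cycle (if its contour exceeds `bubble_min_nm`) is the
#' bubble and its two paths between the attachment junctions are the
#' strands; junctions carrying two terminal edges are splay junctions and
#' those terminal edges the arms. The N end is the end whose terminal
#' region is taller (GFP cap above GRIP cap); if the difference is below
#' `height_tie_nm` the molecule is kept but flagged orientation-ambiguous.
#' An off-backbone blob higher than `antibody_height_min_nm` is recorded as
#' the antibody label with its relative position along the backbone.
#'
#' @param skel Result of [skeletonize_molecule()].
#' @param params A [morph_params()].
#' @return An anatomy list (`status`, per-end arm lengths and cap heights,
#'   bubble strand lengths and junctions, stalk lengths, orientation,
#'   antibody position), or `status = "untraceable"` when the graph does
#'   not reduce to the canonical anatomy.
#' @export
identify_features <- function(skel, params = morph_params()) {
  if (skel$status != "ok") return(list(status = "untraceable"))
  g <- skel$graph
  px <- g$px
  hmax <- skel$crop$hmax

  # resolve pass-through spurs (junction with one terminal + two internal
  # edges): antibody attachment spurs and residual noise spurs are removed
  repeat {
    deg <- skeleton_graph_degrees(g)
    inc <- edge_incidence(g)
    removed <- FALSE
    for (n in which(deg == 3L)) {
      ei <- inc[[n]]
      term <- ei[vapply(ei, function(k) {
        e <- g$edges[[k]]
        other <- if (e$n1 == n) e$n2 else e$n1
        e$n1 != e$n2 && deg[other] == 1L
      }, logical(1))]
      if (length(term) != 1L) next
      e <- g$edges[[term]]
      is_blob <- !is.na(e$mean_height_nm) &&
        e$mean_height_nm >= params$antibody_height_min_nm
      if (is_blob || e$length_nm < 1.5 * params$spur_prune_nm) {
        g$edges[[term]] <- NULL
        removed <- TRUE
        break
      }
    }
    if (!removed) break
    g <- absorb_degree2(g)
  }

  deg <- skeleton_graph_degrees(g)
  active <- which(deg > 0L)
  n_end <- sum(deg == 1L)
  cycles <- length(g$edges) - length(active) + 1L
  if (cycles > 1L || n_end > 4L || !length(g$edges)) {
    return(list(status = "untraceable"))
  }

  # ---- bubble: the unique cycle --------------------------------------
  bubble <- list(present = FALSE, strands = c(0, 0), j1 = NA, j2 = NA)
  edge_pairs <- t(vapply(g$edges, function(e) c(e$n1, e$n2), numeric(2)))
  if (cycles == 1L) {
    self_i <- which(edge_pairs[, 1] == edge_pairs[, 2])
    par_i <- NULL
    if (!length(self_i)) {
      key <- apply(edge_pairs, 1L, function(r) paste(sort(r), collapse = "-"))
      dup <- names(which(table(key) >= 2L))[1]
      par_i <- which(key == dup)
    }
    if (length(self_i)) {
      # self-loop: both junctions merged; split the loop in half
      e <- g$edges[[self_i[1]]]
      bubble <- list(present = TRUE,
                     strands = rep(e$length_nm / 2, 2),
                     j1 = e$n1, j2 = e$n1)
      g$edges[[self_i[1]]] <- NULL
    } else if (length(par_i) >= 2L) {
      e1 <- g$edges[[par_i[1]]]; e2 <- g$edges[[par_i[2]]]
      raw <- c(e1$length_nm, e2$length_nm)
      # a bubble has two comparable strands; a grossly asymmetric cycle is
      # a self-contact of the backbone, not an unwound region
      if (max(raw) > 3 * max(min(raw), 1e-9)) {
        return(list(status = "untraceable"))
      }
      # near the chord endpoints the two strands run merged into a single
      # ridge, so the skeleton junction sits inside the true bubble span;
      # extrapolate each strand's end tangent to its intersection with the
      # stalk tangent to recover the hidden part of the arc
      cyc <- par_i[1:2]
      ext <- c(0, 0)
      for (jn in unique(c(e1$n1, e1$n2))) {
        inc_j <- which(vapply(g$edges, function(e)
          e$n1 == jn || e$n2 == jn, logical(1)))
        stalk_i <- setdiff(inc_j, cyc)
        if (!length(stalk_i)) next
        sd <- edge_dir_at(g$edges[[stalk_i[1]]], jn)
        if (is.null(sd)) next
        for (si in 1:2) {
          td <- edge_dir_at(g$edges[[cyc[si]]], jn)
          if (is.null(td)) next
          M <- cbind(-td$dir, -sd$dir)
          dt <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
          if (abs(dt) < 1e-6) next
          ab <- solve(M, sd$origin - td$origin)
          # the skeleton bends into the junction, so the raw intersection
          # overshoots; clip the recovered neck at one pixel per junction
          if (is.finite(ab[1]) && ab[1] > 0) {
            ext[si] <- ext[si] + min(ab[1], 1.0)
          }
        }
      }
      lens <- sort(raw + ext * px, decreasing = TRUE)
      bubble <- list(present = TRUE,
                     strands = lens,
                     j1 = e1$n1, j2 = e1$n2)
      # keep a single virtual stalk connection handled below
      g$edges[[par_i[2]]] <- NULL
      g$edges[[par_i[1]]]$virtual_bubble <- TRUE
      g$edges[[par_i[1]]]$length_nm <- mean(bubble$strands)
    } else {
      # a longer cycle through >2 junctions: not the canonical bubble
      return(list(status = "untraceable"))
    }
    if (sum(bubble$strands) < params$bubble_min_nm) {
      bubble <- list(present = FALSE, strands = c(0, 0), j1 = NA, j2 = NA)
      g <- absorb_degree2(g)
    }
  }

  deg <- skeleton_graph_degrees(g)
  inc <- edge_incidence(g)

  # ---- backbone = tree diameter between termini ----------------------
  # The longest terminus-to-terminus path is the molecule's backbone (a
  # splay arm is always shorter than the rest of the molecule); splays are
  # then read off the first junction within arm scale of each backbone
  # terminus.
  ig_edges <- do.call(rbind, lapply(seq_along(g$edges), function(k) {
    e <- g$edges[[k]]
    data.frame(from = e$n1, to = e$n2, k = k, w = max(e$length_nm, 1e-9))
  }))
  ig <- igraph::graph_from_data_frame(ig_edges, directed = FALSE,
                                      vertices = data.frame(
                                        name = seq_len(nrow(g$nodes))))
  termini <- which(deg == 1L)
  if (length(termini) < 2L) return(list(status = "untraceable"))
  D <- igraph::distances(ig, v = as.character(termini),
                         to = as.character(termini), weights = ig_edges$w)
  best <- which(D == max(D), arr.ind = TRUE)[1L, ]
  a1 <- termini[best[1]]; a2 <- termini[best[2]]
  sp <- igraph::shortest_paths(ig, from = as.character(a1),
                               to = as.character(a2), weights = ig_edges$w,
                               output = "both")
  path_eids <- ig_edges$k[as.integer(sp$epath[[1]])]
  path_vids <- as.integer(sp$vpath[[1]])
  if (!length(path_eids)) return(list(status = "untraceable"))

  resolve_end <- function(from_start) {
    vseq <- if (from_start) path_vids else rev(path_vids)
    eseq <- if (from_start) path_eids else rev(path_eids)
    terminus <- vseq[1]
    dist <- 0
    for (s in seq_along(eseq)) {
      dist <- dist + g$edges[[eseq[s]]]$length_nm
      v <- vseq[s + 1L]
      if (dist > params$arm_max_nm) break
      if (deg[v] >= 3L) {
        off <- setdiff(inc[[v]], eseq)
        offt <- off[vapply(off, function(k) {
          e <- g$edges[[k]]
          other <- if (e$n1 == v) e$n2 else e$n1
          e$n1 != e$n2 && deg[other] == 1L &&
            is.null(e$virtual_bubble) &&
            e$length_nm <= params$arm_max_nm
        }, logical(1))]
        if (length(offt)) {
          lens <- vapply(offt, function(k) g$edges[[k]]$length_nm,
                         numeric(1))
          ebest <- g$edges[[offt[which.max(lens)]]]
          tip2 <- if (deg[ebest$n1] == 1L) ebest$n1 else ebest$n2
          return(list(anchor = v,
                      arms = sort(c(dist, max(lens)), decreasing = TRUE),
                      cap_h = max(g$cap_h[c(terminus, tip2)], na.rm = TRUE),
                      splayed = TRUE, arm_eids = eseq[1:s]))
        }
        break  # first junction lacks arms (e.g., bubble): plain end
      }
    }
    list(anchor = terminus, arms = c(0, 0),
         cap_h = if (!is.na(g$cap_h[terminus])) g$cap_h[terminus]
           else NA_real_,
         splayed = FALSE, arm_eids = integer(0))
  }
  end_units <- list(resolve_end(TRUE), resolve_end(FALSE))
  if (length(intersect(end_units[[1]]$arm_eids,
                       end_units[[2]]$arm_eids))) {
    return(list(status = "untraceable"))
  }

  # ---- stalk partition along the backbone core -----------------------
  core_eids <- setdiff(path_eids, c(end_units[[1]]$arm_eids,
                                    end_units[[2]]$arm_eids))
  stalk1 <- 0; stalk2 <- 0   # before / after the bubble from end 1
  self_loop <- bubble$present && !is.na(bubble$j1) &&
    bubble$j1 == bubble$j2
  seen_bubble <- FALSE
  for (k in core_eids) {
    e <- g$edges[[k]]
    if (!is.null(e$virtual_bubble)) { seen_bubble <- TRUE; next }
    if (seen_bubble) stalk2 <- stalk2 + e$length_nm else
      stalk1 <- stalk1 + e$length_nm
    if (self_loop && (e$n1 == bubble$j1 || e$n2 == bubble$j1)) {
      seen_bubble <- TRUE
    }
  }

  # ---- orientation ---------------------------------------------------
  h1 <- end_units[[1]]$cap_h; h2 <- end_units[[2]]$cap_h
  h1 <- ifelse(is.na(h1), -Inf, h1); h2 <- ifelse(is.na(h2), -Inf, h2)
  ambiguous <- (!is.finite(h1) && !is.finite(h2)) ||
    (is.finite(h1) && is.finite(h2) &&
       abs(h1 - h2) < params$height_tie_nm)
  n_first <- h1 >= h2
  ends <- if (n_first) end_units else rev(end_units)
  stalks <- if (n_first) c(stalk1, stalk2) else c(stalk2, stalk1)

  # ---- backbone core pixels from the N end (for feature positions) ---
  main_path <- NULL
  if (length(core_eids)) {
    ordered <- list()
    cur <- end_units[[1]]$anchor
    for (k in core_eids) {
      e <- g$edges[[k]]
      p <- e$path
      if (e$n2 == cur && e$n1 != cur) p <- p[nrow(p):1, , drop = FALSE]
      cur <- if (e$n1 == cur) e$n2 else e$n1
      ordered[[length(ordered) + 1L]] <- p
    }
    main_path <- do.call(rbind, ordered)
    keep <- c(TRUE, rowSums(abs(diff(main_path))) > 0L)
    main_path <- main_path[keep, , drop = FALSE]
    if (!n_first) main_path <- main_path[nrow(main_path):1, , drop = FALSE]
  }

  # ---- antibody blob -------------------------------------------------
  antibody <- list(present = FALSE, rel = c(NA, NA, NA))
  blob <- which(hmax >= params$antibody_height_min_nm & skel$crop$mask,
                arr.ind = TRUE)
  if (nrow(blob) >= 3L && !is.null(main_path) && nrow(main_path) >= 2L) {
    antibody$present <- TRUE
    antibody$blob_px <- blob
  }

  list(status = "ok", graph = g, bubble = bubble, ends = ends,
       stalks = stalks, ambiguous = ambiguous, main_path = main_path,
       antibody = antibody, crop = skel$crop, px = px)
}

#' Measure the eight-segment decomposition of a traced molecule
#'
#' @param anatomy Result of [identify_features()] with `status = "ok"`.
#' @return Named numeric vector `X1`...`X8` (nm; 0 denotes absent
#'   features). For bubble-free molecules the entire stalk is reported as
#'   `X3` with `X6 = 0`.
#' @export
measure_segments <- function(anatomy) {
  stopifnot(identical(anatomy$status, "ok"))
  xs <- stats::setNames(numeric(8), paste0("X", 1:8))
  ne <- anatomy$ends[[1]]; ce <- anatomy$ends[[2]]
  if (ne$splayed) xs[c("X1", "X2")] <- ne$arms
  if (ce$splayed) xs[c("X7", "X8")] <- ce$arms
  if (anatomy$bubble$present) {
    xs[c("X4", "X5")] <- anatomy$bubble$strands
    xs["X3"] <- anatomy$stalks[1]
    xs["X6"] <- anatomy$stalks[2]
  } else {
    xs["X3"] <- sum(anatomy$stalks)
    xs["X6"] <- 0
  }
  xs
}
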