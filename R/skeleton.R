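# Skeletonization and skeleton-graph extraction --------------------------

#' Thin a binary mask to a 1-pixel skeleton (Guo-Hall)
#'
#' Iterative two-subcycle parallel thinning (Guo & Hall's algorithm), which
#' preserves 8-connectivity and topology (loops survive as cycles, so a
#' molecule with a central bubble keeps exactly one cycle) and, unlike
#' Zhang-Suen, does not leave two-pixel diagonal ladders, so curve pixels
#' of the result have exactly two neighbours. A final single-pass corner
#' cleanup removes residual staircase corner pixels.
#'
#' @param mask Logical matrix.
#' @return Logical matrix of the same size with the medial skeleton.
#' @export
thin_mask <- function(mask) {
  stopifnot(is.logical(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  M <- matrix(FALSE, nr + 2L, nc + 2L)
  M[2:(nr + 1L), 2:(nc + 1L)] <- mask
  i <- 2:(nr + 1L); j <- 2:(nc + 1L)
  repeat {
    changed <- FALSE
    for (sub in 0:1) {
      p2 <- M[i - 1L, j]; p3 <- M[i - 1L, j + 1L]; p4 <- M[i, j + 1L]
      p5 <- M[i + 1L, j + 1L]; p6 <- M[i + 1L, j]; p7 <- M[i + 1L, j - 1L]
      p8 <- M[i, j - 1L]; p9 <- M[i - 1L, j - 1L]
      C <- (!p2 & (p3 | p4)) + (!p4 & (p5 | p6)) +
        (!p6 & (p7 | p8)) + (!p8 & (p9 | p2))
      N1 <- (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8)
      N2 <- (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9)
      Nm <- pmin(N1, N2)
      m <- if (sub == 0L) ((p6 | p7 | !p9) & p8) else ((p2 | p3 | !p5) & p4)
      cond <- M[i, j] & C == 1L & Nm >= 2L & Nm <= 3L & !m
      if (any(cond)) {
        Mi <- M[i, j]
        Mi[cond] <- FALSE
        M[i, j] <- Mi
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  remove_staircase_corners(M[i, j])
}

# single parallel pass removing residual staircase corners: degree-2
# pixels whose two neighbours are mutually adjacent and themselves well
# connected (>= 3 neighbours), so chain tips are never eroded
remove_staircase_corners <- function(sk) {
  nb <- neighbour_count(sk)
  px <- which(sk & nb == 2L, arr.ind = TRUE)
  if (!nrow(px)) return(sk)
  nr <- nrow(sk); nc <- ncol(sk)
  drop <- logical(nrow(px))
  for (k in seq_len(nrow(px))) {
    r <- px[k, 1]; c <- px[k, 2]
    rr <- max(1L, r - 1L):min(nr, r + 1L)
    cc <- max(1L, c - 1L):min(nc, c + 1L)
    w <- which(sk[rr, cc, drop = FALSE], arr.ind = TRUE)
    nbp <- cbind(rr[w[, 1]], cc[w[, 2]])
    nbp <- nbp[!(nbp[, 1] == r & nbp[, 2] == c), , drop = FALSE]
    if (nrow(nbp) != 2L) next
    d <- abs(nbp[1, ] - nbp[2, ])
    if (max(d) <= 1L && nb[nbp[1, 1], nbp[1, 2]] >= 3L &&
        nb[nbp[2, 1], nbp[2, 2]] >= 3L) {
      drop[k] <- TRUE
    }
  }
  sk[px[drop, , drop = FALSE]] <- FALSE
  sk
}

# punch enclosed low-height valleys out of a mask: connected regions of
# pixels below `thr_nm` that do not leak to the crop border are unwound
# gaps whose above-threshold rim closed under tip broadening; removing
# them restores the cycle the skeleton needs to see a bubble
punch_enclosed_valleys <- function(mask, heights, thr_nm) {
  low <- heights < thr_nm
  comp <- label_components(low, connectivity = 4L)
  if (!max(comp)) return(mask)
  border_labs <- unique(c(comp[1, ], comp[nrow(comp), ], comp[, 1],
                          comp[, ncol(comp)]))
  enclosed <- low & !(comp %in% border_labs[border_labs > 0L] |
                        comp == 0L)
  mask & !enclosed
}

# fill enclosed background holes of up to max_area pixels (rasterization
# artifacts at junctions); background is 4-connected (dual of 8-connected
# foreground)
fill_small_holes <- function(mask, max_area = 3L) {
  bg <- !mask
  lab <- label_components(bg, connectivity = 4L)
  if (!max(lab)) return(mask)
  border_labs <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1],
                          lab[, ncol(lab)]))
  tab <- table(lab[lab > 0L])
  fill <- as.integer(names(tab))[tab <= max_area]
  fill <- setdiff(fill, border_labs)
  if (length(fill)) mask[lab %in% fill] <- TRUE
  mask
}

# 8-neighbour count for each pixel of a logical matrix
neighbour_count <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  M <- matrix(0L, nr + 2L, nc + 2L)
  M[2:(nr + 1L), 2:(nc + 1L)] <- mask
  i <- 2:(nr + 1L); j <- 2:(nc + 1L)
  M[i - 1L, j] + M[i - 1L, j + 1L] + M[i, j + 1L] + M[i + 1L, j + 1L] +
    M[i + 1L, j] + M[i + 1L, j - 1L] + M[i, j - 1L] + M[i - 1L, j - 1L]
}

#' Contour length of a traced pixel path via centerline smoothing
#'
#' The per-pixel chain metric of [path_length()] overestimates the length
#' of a smooth digitized curve by ~5% (the classical staircase bias), so
#' skeleton edge lengths are measured on a lightly smoothed copy of the
#' path: each interior vertex is replaced by the mean of a symmetric window
#' (half-width `half_window`, clipped near the ends so endpoints stay
#' fixed), and Euclidean step lengths are summed. A straight digital line
#' is measured exactly; this mirrors measuring a molecule contour with a
#' sparse segmented line rather than pixel by pixel.
#'
#' @param path Integer matrix with columns (row, col), ordered.
#' @param pixel_size_nm Pixel size (nm).
#' @param half_window Smoothing half-width in pixels.
#' @return Length in nm.
#' @export
contour_length <- function(path, pixel_size_nm, half_window = 1L) {
  n <- nrow(path)
  if (n < 2L) return(0)
  if (n <= 3L) return(path_length(path, pixel_size_nm))
  sm <- path
  for (i in 2:(n - 1L)) {
    hw <- min(half_window, i - 1L, n - i)
    if (hw > 0L) {
      sm[i, ] <- colMeans(path[(i - hw):(i + hw), , drop = FALSE])
    }
  }
  sum(sqrt(rowSums((sm[-1L, , drop = FALSE] -
                    sm[-n, , drop = FALSE])^2))) * pixel_size_nm
}

#' Physical length of an 8-connected pixel path
#'
#' Sums per-step distances along an ordered pixel path: one pixel size for
#' axial steps, sqrt(2) pixel sizes for diagonal steps. This is the digital
#' analogue of tracing the molecule contour with a segmented line after
#' setting the measuring scale.
#'
#' @param path Integer matrix with columns (row, col), ordered; consecutive
#'   pixels must be 8-adjacent.
#' @param pixel_size_nm Pixel size (nm).
#' @return Length in nm.
#' @export
#' @examples
#' path_length(cbind(1, 1:11), 2.0)            # 20 nm
#' path_length(cbind(1:11, 1:11), 2.0)         # 20 * sqrt(2) nm
path_length <- function(path, pixel_size_nm) {
  if (nrow(path) < 2L) return(0)
  d <- abs(diff(path))
  if (any(d > 1L) || any(rowSums(d) == 0L)) {
    stop("path contains non-adjacent or repeated consecutive pixels",
         call. = FALSE)
  }
  sum(ifelse(rowSums(d) == 2L, sqrt(2), 1)) * pixel_size_nm
}

# -- skeleton graph ------------------------------------------------------
# A skeleton graph is a list with:
#   nodes: tibble(id, row, col, kind)  (representative pixel, centroid-ish)
#   edges: list of list(n1, n2, path, length_nm, mean_height_nm)
#   px: pixel size; endpoints/junction ids derivable from edge degrees

skeleton_graph_degrees <- function(g) {
  deg <- integer(nrow(g$nodes))
  for (e in g$edges) {
    deg[e$n1] <- deg[e$n1] + 1L
    if (e$n2 == e$n1) deg[e$n1] <- deg[e$n1] + 1L else
      deg[e$n2] <- deg[e$n2] + 1L
  }
  deg
}

# number of independent cycles (assumes connected skeleton)
skeleton_cycle_count <- function(g) {
  length(g$edges) - nrow(g$nodes) + 1L
}

#' Convert a skeleton mask to a graph of endpoints, junctions and paths
#'
#' Node pixels are skeleton pixels with 1 neighbour (endpoints) or 3 or more
#' (junctions); 8-adjacent node pixels are merged into one node. Edges are
#' the degree-2 pixel chains between nodes, stored with their ordered pixel
#' path, physical length and mean underlying height.
#'
#' @param skel Logical skeleton matrix (from [thin_mask()]).
#' @param pixel_size_nm Pixel size (nm).
#' @param heights Optional height matrix (same size) for per-edge mean
#'   heights.
#' @return A skeleton graph (list with `nodes`, `edges`, `px`).
#' @export
skeleton_to_graph <- function(skel, pixel_size_nm, heights = NULL) {
  nb <- neighbour_count(skel)
  pix <- which(skel)
  if (!length(pix)) {
    return(list(nodes = tibble::tibble(id = integer(0), row = integer(0),
                                       col = integer(0)),
                edges = list(), px = pixel_size_nm))
  }
  nr <- nrow(skel)
  deg <- nb[pix]
  is_node_px <- deg != 2L
  if (!any(is_node_px)) {
    # pure cycle: make the first pixel a node
    is_node_px[1L] <- TRUE
  }
  node_lin <- pix[is_node_px]
  # cluster adjacent node pixels
  node_mask <- matrix(FALSE, nr, ncol(skel))
  node_mask[node_lin] <- TRUE
  clus <- label_components(node_mask)
  n_nodes <- max(clus)
  node_pos <- arrayInd(node_lin, dim(skel))
  node_id_of <- clus[node_lin]
  nodes <- tibble::tibble(
    id = seq_len(n_nodes),
    row = as.numeric(tapply(node_pos[, 1], node_id_of, mean)),
    col = as.numeric(tapply(node_pos[, 2], node_id_of, mean))
  )

  off <- expand.grid(dr = -1:1, dc = -1:1)
  off <- off[!(off$dr == 0 & off$dc == 0), ]
  nbrs_of <- function(r, c) {
    rr <- r + off$dr; cc <- c + off$dc
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= ncol(skel)
    cbind(rr[ok], cc[ok])[skel[cbind(rr[ok], cc[ok])], , drop = FALSE]
  }

  visited <- matrix(FALSE, nr, ncol(skel))   # degree-2 chain pixels
  edges <- list()
  seen_direct <- character(0)
  add_edge <- function(n1, n2, path) {
    mh <- if (is.null(heights)) NA_real_ else
      mean(heights[path])
    edges[[length(edges) + 1L]] <<- list(
      n1 = n1, n2 = n2, path = path,
      length_nm = contour_length(path, pixel_size_nm),
      mean_height_nm = mh)
  }

  for (k in seq_along(node_lin)) {
    r0 <- node_pos[k, 1]; c0 <- node_pos[k, 2]
    my_node <- node_id_of[k]
    for (q in seq_len(nrow(nbq <- nbrs_of(r0, c0)))) {
      r1 <- nbq[q, 1]; c1 <- nbq[q, 2]
      if (clus[r1, c1] > 0L) {
        # direct node-node adjacency (different clusters only)
        other <- clus[r1, c1]
        if (other != my_node) {
          key <- paste(sort(c((c0 - 1L) * nr + r0, (c1 - 1L) * nr + r1)),
                       collapse = "-")
          if (!(key %in% seen_direct)) {
            seen_direct <- c(seen_direct, key)
            add_edge(my_node, other, cbind(c(r0, r1), c(c0, c1)))
          }
        }
        next
      }
      if (visited[r1, c1]) next
      # walk the degree-2 chain
      path <- rbind(c(r0, c0), c(r1, c1))
      prev <- c(r0, c0); cur <- c(r1, c1)
      repeat {
        visited[cur[1], cur[2]] <- TRUE
        nxts <- nbrs_of(cur[1], cur[2])
        nxts <- nxts[!(nxts[, 1] == prev[1] & nxts[, 2] == prev[2]), ,
                     drop = FALSE]
        # prefer unvisited non-node continuation; a node pixel ends the walk
        node_hit <- which(clus[nxts] > 0L)
        if (nrow(nxts) == 0L) break               # isolated spur tip
        if (length(node_hit)) {
          # if multiple node pixels adjacent, take the first
          nx <- nxts[node_hit[1], ]
          path <- rbind(path, nx)
          cur <- nx
          break
        }
        free <- which(!visited[nxts])
        if (!length(free)) break
        nx <- nxts[free[1], ]
        path <- rbind(path, nx)
        prev <- cur; cur <- nx
      }
      end_clus <- clus[cur[1], cur[2]]
      if (end_clus > 0L) {
        add_edge(my_node, end_clus, path)
      }
      # else: dead-ended duplicate stub caused by a diagonal shortcut into
      # the node cluster on a previous walk; its pixels are already covered
      # by another edge, so the stub is silently discarded
    }
  }
  g <- list(nodes = nodes, edges = edges, px = pixel_size_nm,
            node_pixsets = split(node_lin, node_id_of))
  attr(g, "nr") <- nr
  g
}

# BFS path between two pixels within a pixel set (used to bridge through
# junction clusters when merging edges); returns ordered (row,col) matrix
bfs_bridge <- function(from, to, pixset_lin, nr) {
  if (all(from == to)) return(matrix(from, 1L))
  key <- function(p) (p[2] - 1L) * nr + p[1]
  inset <- new.env(hash = TRUE)
  for (l in pixset_lin) assign(as.character(l), TRUE, envir = inset)
  prev <- new.env(hash = TRUE)
  qq <- list(from)
  assign(as.character(key(from)), NA, envir = prev)
  off <- expand.grid(dr = -1:1, dc = -1:1)
  off <- off[!(off$dr == 0 & off$dc == 0), ]
  found <- FALSE
  while (length(qq) && !found) {
    cur <- qq[[1]]; qq <- qq[-1]
    for (o in seq_len(nrow(off))) {
      np <- c(cur[1] + off$dr[o], cur[2] + off$dc[o])
      kn <- as.character(key(np))
      if (!exists(kn, envir = inset, inherits = FALSE)) next
      if (exists(kn, envir = prev, inherits = FALSE)) next
      assign(kn, cur, envir = prev)
      if (all(np == to)) { found <- TRUE; break }
      qq[[length(qq) + 1L]] <- np
    }
  }
  if (!found) return(NULL)
  # reconstruct
  path <- list(to)
  cur <- to
  repeat {
    p <- get(as.character(key(cur)), envir = prev)
    if (length(p) == 1L && is.na(p)) break
    path[[length(path) + 1L]] <- p
    cur <- p
  }
  do.call(rbind, rev(path))
}

# merge two edges that meet at a degree-2 node into one edge, bridging
# through the node's pixel cluster when the two paths are not adjacent
merge_edge_pair <- function(g, node_id, e1_i, e2_i) {
  e1 <- g$edges[[e1_i]]; e2 <- g$edges[[e2_i]]
  nr <- attr(g, "nr")
  p1 <- e1$path
  if (e1$n1 == node_id && e1$n2 != node_id) p1 <- p1[nrow(p1):1, , drop = FALSE]
  p2 <- e2$path
  if (e2$n2 == node_id && e2$n1 != node_id) p2 <- p2[nrow(p2):1, , drop = FALSE]
  a <- p1[nrow(p1), ]; b <- p2[1L, ]
  if (all(a == b)) {
    p2 <- p2[-1L, , drop = FALSE]
  } else if (max(abs(a - b)) > 1L) {
    pixset <- c(g$node_pixsets[[node_id]],
                (a[2] - 1L) * nr + a[1], (b[2] - 1L) * nr + b[1])
    bridge <- bfs_bridge(a, b, unique(pixset), nr)
    if (!is.null(bridge) && nrow(bridge) > 2L) {
      p1 <- rbind(p1, bridge[2:(nrow(bridge) - 1L), , drop = FALSE])
    }
  }
  newpath <- rbind(p1, p2)
  keep <- c(TRUE, rowSums(abs(diff(newpath))) > 0L)
  newpath <- newpath[keep, , drop = FALSE]
  n_new1 <- if (e1$n1 == node_id) e1$n2 else e1$n1
  n_new2 <- if (e2$n1 == node_id) e2$n2 else e2$n1
  list(n1 = n_new1, n2 = n_new2, path = newpath,
       length_nm = contour_length(newpath, g$px),
       mean_height_nm = mean(c(e1$mean_height_nm, e2$mean_height_nm),
                             na.rm = TRUE))
}
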