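# Molecule geometry: backbone + splays + bubble + globules ---------------
#
# A molecule geometry is a list of planar polylines (each with a height and
# an anatomical role) plus disk features (spherical-cap globules). The
# anatomy mirrors what is segmented in the images: up to two N-arm
# polylines, an N-side duplex stalk, two laterally separated bubble strand
# arcs, a C-side stalk, up to two C-arms, GFP/GRIP caps and an optional
# antibody blob.

# truncated-normal draw by rejection (bounds far in the tail are never hit)
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) return(rep(min(max(mean, lower), upper), n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  tries <- 0L
  while (length(bad) && tries < 1000L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lower | out > upper)
    tries <- tries + 1L
  }
  out[out < lower] <- lower
  out[out > upper] <- upper
  out
}

#' Conformational class label from the three binary features
#'
#' Molecules are classified by N-terminal splay, C-terminal splay and the
#' presence of a central bubble, giving eight classes.
#'
#' @param n_splay,c_splay,bubble Logical flags (vectorized).
#' @return Character vector of class labels, e.g. `"rod"`,
#'   `"splay-N+bubble"`, `"splay-both"`.
#' @export
class_label <- function(n_splay, c_splay, bubble) {
  base <- c("rod", "splay-N", "splay-C", "splay-both")[
    1L + as.integer(n_splay) + 2L * as.integer(c_splay)]
  ifelse(bubble, paste0(base, "+bubble"), base)
}

# per-molecule random draw from a population spec (uses current RNG stream)
draw_molecule <- function(pop) {
  L <- rtrunc_norm(1, pop$contour_length_mean_nm, pop$contour_length_sd_nm,
                   lower = 0.6 * pop$contour_length_mean_nm)
  splay_n <- stats::runif(1) < pop$splay_prob_per_end
  splay_c <- stats::runif(1) < pop$splay_prob_per_end
  arms <- rtrunc_norm(4, pop$splay_arm_length_mean_nm,
                      pop$splay_arm_length_sd_nm, lower = 7)
  # feasibility on short constructs: arms may claim at most 55% of the
  # contour and the bubble span at most 45% (inactive for the full-length
  # molecule; keeps truncation fragments renderable)
  trim_n <- if (splay_n) mean(arms[1:2]) else 0
  trim_c <- if (splay_c) mean(arms[3:4]) else 0
  if (trim_n + trim_c > 0.55 * L) {
    arms <- arms * 0.55 * L / (trim_n + trim_c)
  }
  has_bubble <- stats::runif(1) < pop$bubble_prob
  m <- rtrunc_norm(1, pop$bubble_strand_length_mean_nm,
                   pop$bubble_strand_length_sd_nm, lower = 10)
  if (0.92 * m > 0.45 * L) m <- 0.45 * L / 0.92
  asym <- rtrunc_norm(1, 0, 0.08 * m, lower = -0.11 * m, upper = 0.11 * m)
  center_rel <- rtrunc_norm(1, pop$bubble_center_rel, 0.04,
                            lower = 0.38, upper = 0.62)
  list(
    contour_length_nm = L,
    splay_n = splay_n, splay_c = splay_c,
    arm_lengths = arms,                       # n1, n2, c1, c2
    arm_half_angle = rtrunc_norm(2, 0.61, 0.17, 0.45, 1.0),  # per end, rad
    has_bubble = has_bubble,
    strand_lengths = c(m + asym, m - asym),
    bubble_center_rel = center_rel,
    label_rel = pop$antibody_label_rel,
    label_side = sample(c(-1, 1), 1L)
  )
}

# circular arc from a to b with arc length s >= chord, bulging to `side`
# (+1 = left of a->b). Returns polyline (n_pts vertices).
arc_between <- function(a, b, s, side = 1, n_pts = 32L) {
  chord <- sqrt(sum((b - a)^2))
  if (chord <= 0) stop("degenerate arc chord", call. = FALSE)
  if (s <= chord * (1 + 1e-9)) {
    t <- seq(0, 1, length.out = n_pts)
    return(cbind(x = a[1] + t * (b[1] - a[1]), y = a[2] + t * (b[2] - a[2])))
  }
  ratio <- s / chord
  # solve phi / sin(phi) = ratio for half-angle phi in (0, pi)
  phi <- stats::uniroot(function(p) p / sin(p) - ratio,
                        lower = 1e-9, upper = pi - 1e-9, tol = 1e-12)$root
  R <- chord / (2 * sin(phi))
  mid <- (a + b) / 2
  u <- (b - a) / chord
  nrm <- c(-u[2], u[1]) * side                 # unit normal on bulge side
  centre <- mid - nrm * (R * cos(phi))
  ang0 <- atan2(a[2] - centre[2], a[1] - centre[1])
  ang1 <- atan2(b[2] - centre[2], b[1] - centre[1])
  # sweep from ang0 to ang1 the short way consistent with the bulge side
  d <- (ang1 - ang0) %% (2 * pi)
  if (side > 0) d <- d - 2 * pi                # clockwise for left bulge
  t <- seq(0, 1, length.out = n_pts)
  ang <- ang0 + t * d
  cbind(x = centre[1] + R * cos(ang), y = centre[2] + R * sin(ang))
}

# sagitta of the arc fitted between chord c and arc length s
arc_sagitta <- function(s, chord) {
  if (s <= chord) return(0)
  phi <- stats::uniroot(function(p) p / sin(p) - s / chord,
                        lower = 1e-9, upper = pi - 1e-9, tol = 1e-12)$root
  R <- chord / (2 * sin(phi))
  R * (1 - cos(phi))
}

#' Attach structural features to a sampled backbone
#'
#' Converts a bare backbone polyline plus a per-molecule draw into the
#' rendered anatomy: splayed termini are modeled by shortening the duplex by
#' the mean arm length and growing two diverging single-strand arms from the
#' junction; a bubble replaces a central sub-path with two circular-arc
#' strands bulging to opposite sides; globule caps (GFP tall, GRIP short) sit
#' at the termini and an optional antibody blob beside the backbone.
#'
#' @param backbone Polyline matrix (columns `x`, `y`, nm) from
#'   [sample_backbone()].
#' @param draw Per-molecule draw (internal; produced by the population
#'   sampler).
#' @param pop A [population_spec()].
#' @param scan A [scan_spec()] (feature heights and radii).
#' @return List with `geometry` (polylines + disks) and `truth` (one-row
#'   ground-truth [tibble::tibble()]).
#' @export
add_features <- function(backbone, draw, pop, scan = scan_spec()) {
  if (is.null(backbone) || nrow(backbone) < 2L) {
    stop("backbone must be a polyline with at least 2 vertices",
         call. = FALSE)
  }
  L <- polyline_arclength(backbone)
  h_bb <- scan$backbone_height_nm

  n_trim <- if (draw$splay_n) mean(draw$arm_lengths[1:2]) else 0
  c_trim <- if (draw$splay_c) mean(draw$arm_lengths[3:4]) else 0
  if (n_trim + c_trim > 0.7 * L) {
    stop("splay arms too long for backbone", call. = FALSE)
  }

  polylines <- list()
  disks <- list()
  add_poly <- function(xy, role, height = h_bb) {
    polylines[[length(polylines) + 1L]] <<- list(xy = xy, role = role,
                                                 height = height)
  }
  add_disk <- function(center, radius, height, role) {
    disks[[length(disks) + 1L]] <<- list(center = center, radius = radius,
                                         height = height, role = role)
  }

  # bubble span on the duplex [n_trim, L - c_trim]
  span <- NULL
  strands <- draw$strand_lengths
  if (draw$has_bubble) {
    r <- 0.92 * mean(strands)
    if (r > (L - n_trim - c_trim) - 10) {
      stop("bubble span longer than available backbone", call. = FALSE)
    }
    ctr <- draw$bubble_center_rel * L
    lo_lim <- n_trim + 5
    hi_lim <- L - c_trim - 5
    # shrink the removed sub-path until the two arcs are separated by at
    # least the configured lateral offset (bisection on r)
    for (k in 1:25) {
      s0 <- min(max(ctr - r / 2, lo_lim), hi_lim - r)
      s1 <- s0 + r
      a <- polyline_point_at(backbone, s0)$point
      b <- polyline_point_at(backbone, s1)$point
      chord <- sqrt(sum((b - a)^2))
      strands <- pmax(draw$strand_lengths, chord * 1.005)
      sep <- arc_sagitta(strands[1], chord) + arc_sagitta(strands[2], chord)
      if (sep >= pop$bubble_lateral_offset_nm || r < 0.55 * mean(strands)) {
        break
      }
      r <- r * 0.94
    }
    span <- c(s0, s1)
    add_poly(arc_between(a, b, strands[1], side = +1), "bubble-strand-1")
    add_poly(arc_between(a, b, strands[2], side = -1), "bubble-strand-2")
    add_poly(polyline_slice(backbone, n_trim, s0), "stalk-N")
    add_poly(polyline_slice(backbone, s1, L - c_trim), "stalk-C")
  } else {
    add_poly(polyline_slice(backbone, n_trim, L - c_trim), "stalk")
  }

  # splay arms: two gently curved strands from the junction, diverging
  # around the outward tangent
  grow_arms <- function(at_s, outward_sign, lengths, half_angle, roles) {
    jp <- polyline_point_at(backbone, at_s)
    heading <- jp$angle + if (outward_sign < 0) pi else 0
    tips <- list()
    for (i in 1:2) {
      sgn <- if (i == 1L) 1 else -1
      jitter <- stats::rnorm(1, 0, 0.08)
      # arms are short stiff single coiled-coil strands; rendered nearly
      # straight so a splay visible to the scorer is visible on the grid
      arm <- sample_backbone(lengths[i], 300, lengths[i] / 12,
                             start = jp$point,
                             heading0 = heading + sgn * half_angle + jitter)
      add_poly(arm, roles[i])
      tips[[i]] <- arm[nrow(arm), ]
    }
    tips
  }

  n_tips <- c_tips <- NULL
  if (draw$splay_n) {
    n_tips <- grow_arms(n_trim, -1, draw$arm_lengths[1:2],
                        draw$arm_half_angle[1], c("arm-N1", "arm-N2"))
  }
  if (draw$splay_c) {
    c_tips <- grow_arms(L - c_trim, +1, draw$arm_lengths[3:4],
                        draw$arm_half_angle[2], c("arm-C1", "arm-C2"))
  }

  # globule caps: GFP (tall) at the N terminus / both N arm tips, GRIP
  # (short) at the C terminus / both C arm tips
  if (pop$has_gfp) {
    if (draw$splay_n) {
      for (tp in n_tips) {
        add_disk(unlist(tp), 0.85 * scan$gfp_radius_nm,
                 scan$globule_height_nm_gfp, "gfp")
      }
    } else {
      add_disk(unlist(polyline_point_at(backbone, 0)$point),
               scan$gfp_radius_nm, scan$globule_height_nm_gfp, "gfp")
    }
  }
  if (pop$has_grip) {
    if (draw$splay_c) {
      for (tp in c_tips) {
        add_disk(unlist(tp), 0.85 * scan$grip_radius_nm,
                 scan$globule_height_nm_grip, "grip")
      }
    } else {
      add_disk(unlist(polyline_point_at(backbone, L)$point),
               scan$grip_radius_nm, scan$globule_height_nm_grip, "grip")
    }
  }

  label_rel <- draw$label_rel
  if (!is.na(label_rel)) {
    lp <- polyline_point_at(backbone, label_rel * L)
    nrm <- c(-sin(lp$angle), cos(lp$angle)) * draw$label_side
    add_disk(lp$point + nrm * scan$antibody_offset_nm,
             scan$antibody_radius_nm, scan$antibody_height_nm, "antibody")
  }

  n_splayed <- sum(draw$splay_n, draw$splay_c)
  truth <- tibble::tibble(
    molecule_id = NA_integer_,
    true_contour_length_nm = L,
    n_splayed_ends = n_splayed,
    arm_n1_nm = if (draw$splay_n) draw$arm_lengths[1] else NA_real_,
    arm_n2_nm = if (draw$splay_n) draw$arm_lengths[2] else NA_real_,
    arm_c1_nm = if (draw$splay_c) draw$arm_lengths[3] else NA_real_,
    arm_c2_nm = if (draw$splay_c) draw$arm_lengths[4] else NA_real_,
    has_bubble = draw$has_bubble,
    bubble_strand1_nm = if (draw$has_bubble) max(strands) else NA_real_,
    bubble_strand2_nm = if (draw$has_bubble) min(strands) else NA_real_,
    bubble_start_rel = if (draw$has_bubble) span[1] / L else NA_real_,
    bubble_end_rel = if (draw$has_bubble) span[2] / L else NA_real_,
    label_rel = label_rel,
    class_label = class_label(draw$splay_n, draw$splay_c, draw$has_bubble),
    anchor_x_nm = NA_real_, anchor_y_nm = NA_real_, rot_rad = NA_real_,
    touches_border = NA, overlaps_other = NA
  )
  list(geometry = list(polylines = polylines, disks = disks), truth = truth)
}

# all vertex coordinates of a geometry (for placement / bounding boxes)
geometry_points <- function(geom) {
  pts <- lapply(geom$polylines, function(p) p$xy)
  dk <- lapply(geom$disks, function(d) {
    rbind(d$center + c(d$radius, 0), d$center - c(d$radius, 0),
          d$center + c(0, d$radius), d$center - c(0, d$radius))
  })
  out <- do.call(rbind, c(pts, dk))
  colnames(out) <- c("x", "y")
  out
}

# rigid transform (rotation then translation) of a geometry
transform_geometry <- function(geom, rot, shift) {
  Rm <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2L)
  tr <- function(xy) {
    out <- xy %*% t(Rm)
    out[, 1] <- out[, 1] + shift[1]
    out[, 2] <- out[, 2] + shift[2]
    colnames(out) <- c("x", "y")
    out
  }
  geom$polylines <- lapply(geom$polylines, function(p) {
    p$xy <- tr(p$xy); p
  })
  geom$disks <- lapply(geom$disks, function(d) {
    d$center <- as.numeric(tr(matrix(d$center, 1L))); d
  })
  geom
}
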