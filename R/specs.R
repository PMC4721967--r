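#' Scan specification for synthetic topographs
#'
#' Collects the physical parameters of the simulated AFM scan: field size and
#' resolution, probe tip radius, the rendered heights of the molecular
#' features, and the imaging imperfections (plane slant, per-scan-line
#' offsets, additive noise). Defaults emulate 1.2 um x 1.2 um scans at
#' 512 x 512 px acquired in air with a sharp (2-5 nm) tip and a ~2.5 nm
#' height display range.
#'
#' @param field_size_nm Side length of the square scan field (nm).
#' @param resolution_px Pixels per side (>= 64).
#' @param tip_radius_nm Probe tip radius of curvature (nm, >= 0; 0 disables
#'   tip dilation).
#' @param backbone_height_nm Ridge height of the coiled-coil duplex (nm).
#' @param globule_height_nm_gfp,globule_height_nm_grip Cap heights of the
#'   N-terminal GFP and C-terminal GRIP globules (nm); the GFP cap must be
#'   the taller one for N/C orientation to be recoverable.
#' @param antibody_height_nm Cap height of the antibody label blob (nm).
#' @param noise_sd_nm SD of additive per-pixel Gaussian noise (nm).
#' @param slant_row_sd_nm SD of per-scan-line (row) height offsets (nm).
#' @param slant_plane_gradient_nm_per_px Plane tilt added across the field
#'   (nm per pixel, applied along both axes).
#' @param z_range_nm Display height range (metadata only; heights are not
#'   clipped).
#' @param ridge_halfwidth_nm Half-width of the rasterized duplex ridge (nm);
#'   the coiled-coil diameter is ~2 nm.
#' @param gfp_radius_nm,grip_radius_nm,antibody_radius_nm Globule footprint
#'   radii (nm).
#' @param antibody_offset_nm Lateral offset of the antibody blob centre from
#'   the backbone (nm).
#' @return A list of class `"scan_spec"`.
#' @export
scan_spec <- function(field_size_nm = 1200,
                      resolution_px = 512L,
                      tip_radius_nm = 3,
                      backbone_height_nm = 1.5,
                      globule_height_nm_gfp = 2.5,
                      globule_height_nm_grip = 2.0,
                      antibody_height_nm = 4.0,
                      noise_sd_nm = 0.1,
                      slant_row_sd_nm = 0.15,
                      slant_plane_gradient_nm_per_px = 0.004,
                      z_range_nm = 2.5,
                      ridge_halfwidth_nm = 1.0,
                      gfp_radius_nm = 3.0,
                      grip_radius_nm = 2.2,
                      antibody_radius_nm = 4.0,
                      antibody_offset_nm = 5.0) {
  spec <- list(
    field_size_nm = field_size_nm, resolution_px = as.integer(resolution_px),
    tip_radius_nm = tip_radius_nm, backbone_height_nm = backbone_height_nm,
    globule_height_nm_gfp = globule_height_nm_gfp,
    globule_height_nm_grip = globule_height_nm_grip,
    antibody_height_nm = antibody_height_nm, noise_sd_nm = noise_sd_nm,
    slant_row_sd_nm = slant_row_sd_nm,
    slant_plane_gradient_nm_per_px = slant_plane_gradient_nm_per_px,
    z_range_nm = z_range_nm, ridge_halfwidth_nm = ridge_halfwidth_nm,
    gfp_radius_nm = gfp_radius_nm, grip_radius_nm = grip_radius_nm,
    antibody_radius_nm = antibody_radius_nm,
    antibody_offset_nm = antibody_offset_nm
  )
  class(spec) <- "scan_spec"
  validate_scan_spec(spec)
  spec
}

validate_scan_spec <- function(s) {
  stopifnot(inherits(s, "scan_spec"))
  if (s$resolution_px < 64L) stop("resolution_px must be >= 64", call. = FALSE)
  if (!is.finite(s$field_size_nm) || s$field_size_nm <= 0) {
    stop("field_size_nm must be positive", call. = FALSE)
  }
  px <- s$field_size_nm / s$resolution_px
  if (!is.finite(px) || px <= 0) stop("invalid pixel size", call. = FALSE)
  if (s$tip_radius_nm < 0) stop("tip_radius_nm must be >= 0", call. = FALSE)
  hs <- c(s$backbone_height_nm, s$globule_height_nm_gfp,
          s$globule_height_nm_grip, s$antibody_height_nm)
  if (any(hs < 0)) stop("feature heights must be >= 0", call. = FALSE)
  if (s$noise_sd_nm < 0) stop("noise_sd_nm must be >= 0", call. = FALSE)
  invisible(s)
}

#' Pixel size of a scan spec (nm per pixel)
#' @param spec A [scan_spec()].
#' @return Pixel size in nm.
#' @export
pixel_size <- function(spec) spec$field_size_nm / spec$resolution_px

#' Molecule population specification
#'
#' Describes the distribution of simulated molecules: contour length,
#' flexibility, the probability and geometry of end splays and of the
#' central unwinding bubble, terminal globules, the optional antibody label,
#' and the surface density. Presets via [population_preset()] encode the
#' study conditions (wild type, hinge-deletion mutant, non-reducing buffer,
#' construct fragments).
#'
#' @param n_molecules Number of molecules to simulate.
#' @param contour_length_mean_nm,contour_length_sd_nm Contour length
#'   distribution (truncated normal, lower bound 60% of the mean).
#' @param persistence_length_nm Bend stiffness of the adsorbed backbone.
#' @param splay_prob_per_end Probability that each terminus is splayed,
#'   independently per end, in \[0,1\].
#' @param splay_arm_length_mean_nm,splay_arm_length_sd_nm Arm length
#'   distribution (truncated at 7 nm so arms exceed the spur-pruning scale).
#' @param bubble_prob Probability a molecule carries a central bubble.
#' @param bubble_strand_length_mean_nm,bubble_strand_length_sd_nm Bubble
#'   strand arc-length distribution (per molecule; the two strands share the
#'   molecule's draw up to a small asymmetry).
#' @param bubble_center_rel Mean relative position of the bubble centre along
#'   the backbone (fraction).
#' @param bubble_lateral_offset_nm Minimum rendered separation of the two
#'   bubble strands (nm).
#' @param has_gfp,has_grip Whether terminal globules are rendered.
#' @param antibody_label_rel Relative backbone position of an antibody label
#'   blob, or `NA` for unlabeled molecules.
#' @param molecules_per_field Surface density control: molecules placed per
#'   scan field.
#' @param seed Root integer seed; every molecule derives its own substream.
#' @return A list of class `"population_spec"`.
#' @export
population_spec <- function(n_molecules = 200L,
                            contour_length_mean_nm = 145,
                            contour_length_sd_nm = 12,
                            persistence_length_nm = 50,
                            splay_prob_per_end = 0.6164,
                            splay_arm_length_mean_nm = 15,
                            splay_arm_length_sd_nm = 4,
                            bubble_prob = 0.5,
                            bubble_strand_length_mean_nm = 27,
                            bubble_strand_length_sd_nm = 7,
                            bubble_center_rel = 0.5,
                            bubble_lateral_offset_nm = 8,
                            has_gfp = TRUE,
                            has_grip = TRUE,
                            antibody_label_rel = NA_real_,
                            molecules_per_field = 20L,
                            seed = 1L) {
  spec <- list(
    n_molecules = as.integer(n_molecules),
    contour_length_mean_nm = contour_length_mean_nm,
    contour_length_sd_nm = contour_length_sd_nm,
    persistence_length_nm = persistence_length_nm,
    splay_prob_per_end = splay_prob_per_end,
    splay_arm_length_mean_nm = splay_arm_length_mean_nm,
    splay_arm_length_sd_nm = splay_arm_length_sd_nm,
    bubble_prob = bubble_prob,
    bubble_strand_length_mean_nm = bubble_strand_length_mean_nm,
    bubble_strand_length_sd_nm = bubble_strand_length_sd_nm,
    bubble_center_rel = bubble_center_rel,
    bubble_lateral_offset_nm = bubble_lateral_offset_nm,
    has_gfp = isTRUE(has_gfp), has_grip = isTRUE(has_grip),
    antibody_label_rel = antibody_label_rel,
    molecules_per_field = as.integer(molecules_per_field),
    seed = as.integer(seed)
  )
  class(spec) <- "population_spec"
  validate_population_spec(spec)
  spec
}

validate_population_spec <- function(s) {
  stopifnot(inherits(s, "population_spec"))
  probs <- c(s$splay_prob_per_end, s$bubble_prob)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  lens <- c(s$contour_length_mean_nm, s$contour_length_sd_nm,
            s$splay_arm_length_mean_nm, s$splay_arm_length_sd_nm,
            s$bubble_strand_length_mean_nm, s$bubble_strand_length_sd_nm,
            s$bubble_lateral_offset_nm)
  if (any(!is.finite(lens)) || any(lens < 0)) {
    stop("lengths and SDs must be >= 0", call. = FALSE)
  }
  if (s$n_molecules < 0) stop("n_molecules must be >= 0", call. = FALSE)
  if (!is.na(s$antibody_label_rel) &&
      (s$antibody_label_rel < 0 || s$antibody_label_rel > 1)) {
    stop("antibody_label_rel must be in [0, 1] or NA", call. = FALSE)
  }
  if (s$bubble_center_rel <= 0 || s$bubble_center_rel >= 1) {
    stop("bubble_center_rel must be in (0, 1)", call. = FALSE)
  }
  invisible(s)
}

#' Population presets for the study conditions
#'
#' * `wt` — wild-type full-length construct: 145 nm mean contour, floppy
#'   (50 nm persistence length), per-end splay probability 0.6164 (so 85%
#'   of molecules have at least one splayed end and 38% both), bubble in
#'   half the molecules with 27 nm mean strand length.
#' * `dhinge` — hinge-deletion mutant: 103 residues shorter, stiffer
#'   (150 nm persistence length), bubbles in only 20% of molecules with
#'   17 nm mean strand length and a much sharper size distribution.
#' * `noDTT` — non-reducing buffer: rod-like molecules, few splays or
#'   bubbles, quasi-rigid backbone.
#' * `fragment:<name>` — truncation constructs `1_358`, `394_751`, `1_889`,
#'   `890_1684`; contour means scale with residue count at the canonical
#'   coiled-coil rise times the empirically observed ~0.69 compaction.
#'
#' @param preset Preset name (see Details).
#' @param ... Overrides passed on to [population_spec()].
#' @return A [population_spec()].
#' @export
population_preset <- function(preset = c("wt", "dhinge", "noDTT",
                                         "fragment:1_358", "fragment:394_751",
                                         "fragment:1_889",
                                         "fragment:890_1684"), ...) {
  preset <- match.arg(preset)
  base <- switch(
    preset,
    wt = list(),
    dhinge = list(contour_length_mean_nm = 145 * (1684 - 103) / 1684,
                  contour_length_sd_nm = 10,
                  persistence_length_nm = 150,
                  bubble_prob = 0.2,
                  bubble_strand_length_mean_nm = 17,
                  bubble_strand_length_sd_nm = 2.5),
    noDTT = list(splay_prob_per_end = 0.05, bubble_prob = 0.05,
                 persistence_length_nm = 1e4),
    `fragment:1_358` = fragment_preset(358),
    `fragment:394_751` = fragment_preset(358),
    `fragment:1_889` = fragment_preset(889),
    `fragment:890_1684` = fragment_preset(795, has_gfp = FALSE)
  )
  args <- utils::modifyList(base, list(...))
  do.call(population_spec, args)
}

# fragment contour mean: residues x canonical rise x observed compaction
fragment_preset <- function(n_residues, has_gfp = TRUE) {
  mean_nm <- n_residues * 0.1485 * (1 - 0.309)
  list(contour_length_mean_nm = mean_nm,
       contour_length_sd_nm = 12 * mean_nm / 145,
       bubble_prob = 0.1, has_gfp = has_gfp)
}
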