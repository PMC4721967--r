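# Pipeline: flatten -> detect -> select -> trace -> measure --------------

#' Analyze one topograph end to end
#'
#' Flattens (unless already flattened or `flatten = FALSE`), detects and
#' selects candidate molecules, traces each retained object to a skeleton
#' graph, identifies its anatomy and measures the segment decomposition and
#' derived metrics. Every detected object lands either in the metrics table
#' or in the rejection table, exactly once.
#'
#' @param x A [topograph()] (raw or flattened).
#' @param params A [morph_params()].
#' @param flatten_first Apply [flatten()] to raw input.
#' @param truth Optional ground-truth table for this field (rows of
#'   [generate_population()]'s `truth`); used for the multi-molecule
#'   aggregate check.
#' @return List: `metrics` (one row per traced molecule), `objects` (all
#'   detected components with final `rejection_reason`), `rejections`
#'   (object_id + reason for every non-retained object),
#'   `retained_fraction`.
#' @export
analyze_topograph <- function(x, params = morph_params(),
                              flatten_first = TRUE, truth = NULL) {
  stopifnot(is_topograph(x))
  if (x$provenance == "raw") {
    if (!flatten_first) {
      stop("raw topograph: flattening is required before detection ",
           "(or pass a flattened image)", call. = FALSE)
    }
    x <- flatten(x)
  }
  px <- x$pixel_size_nm
  objects <- detect_objects(x, params)
  anchors <- NULL
  if (!is.null(truth) && nrow(truth)) {
    anchors <- cbind(round(truth$anchor_y_nm / px + 0.5),
                     round(truth$anchor_x_nm / px + 0.5))
  }
  objects <- select_molecules(objects, params, truth_anchors_px = anchors,
                              img_dim = dim(x$heights))

  rows <- list()
  for (i in which(objects$rejection_reason == "none")) {
    skel <- skeletonize_molecule(objects$mask[[i]], x, params)
    anatomy <- identify_features(skel, params)
    if (!identical(anatomy$status, "ok")) {
      objects$rejection_reason[i] <- "untraceable"
      next
    }
    row <- molecule_metrics_row(objects$object_id[i], anatomy)
    pos <- arrayInd(objects$mask[[i]], dim(x$heights))
    row$centroid_x_nm <- (mean(pos[, 2]) - 0.5) * px
    row$centroid_y_nm <- (mean(pos[, 1]) - 0.5) * px
    rows[[length(rows) + 1L]] <- row
  }
  metrics <- if (length(rows)) do.call(rbind, rows) else NULL
  rej <- objects[objects$rejection_reason != "none",
                 c("object_id", "rejection_reason")]
  rf <- suppressWarnings(retained_fraction(objects))
  list(metrics = metrics, objects = objects, rejections = rej,
       retained_fraction = rf)
}

#' Analyze a simulated population and match molecules to ground truth
#'
#' Runs [analyze_topograph()] on every field of a [generate_population()]
#' result and greedily matches traced molecules to ground-truth records by
#' centroid-to-anchor proximity, appending the matched truth columns (with
#' a `true_` prefix) to the metrics table.
#'
#' @param sim Result of [generate_population()].
#' @param params A [morph_params()].
#' @param max_match_nm Maximum centroid-to-anchor distance for a match.
#' @return List: `metrics` (with matched truth columns), `objects`,
#'   `retained_fraction` (pooled), per-field `rejections`.
#' @export
analyze_population <- function(sim, params = morph_params(),
                               max_match_nm = 80) {
  all_metrics <- list()
  all_objects <- list()
  all_rej <- list()
  for (f in seq_along(sim$fields)) {
    fl <- sim$fields[[f]]
    res <- analyze_topograph(fl$topograph, params, truth = fl$truth)
    if (!is.null(res$metrics) && nrow(res$metrics)) {
      m <- res$metrics
      m$field <- f
      m <- match_truth(m, fl$truth, max_match_nm)
      all_metrics[[length(all_metrics) + 1L]] <- m
    }
    res$objects$field <- f
    all_objects[[length(all_objects) + 1L]] <- res$objects
    if (nrow(res$rejections)) {
      rj <- res$rejections
      rj$field <- f
      all_rej[[length(all_rej) + 1L]] <- rj
    }
  }
  objects <- do.call(rbind, all_objects)
  metrics <- if (length(all_metrics)) do.call(rbind, all_metrics) else NULL
  list(metrics = metrics, objects = objects,
       rejections = if (length(all_rej)) do.call(rbind, all_rej) else NULL,
       retained_fraction = suppressWarnings(retained_fraction(objects)))
}

# greedy nearest match of traced molecules to truth anchors
match_truth <- function(metrics, truth, max_match_nm = 80) {
  tcols <- c("molecule_id", "true_contour_length_nm", "n_splayed_ends",
             "has_bubble", "bubble_strand1_nm", "bubble_strand2_nm",
             "bubble_start_rel", "bubble_end_rel", "label_rel",
             "class_label")
  out_names <- paste0("true_", sub("^true_", "", tcols))
  add <- tibble::as_tibble(stats::setNames(lapply(tcols, function(cc) {
    if (is.numeric(truth[[cc]])) rep(NA_real_, nrow(metrics))
    else if (is.logical(truth[[cc]])) rep(NA, nrow(metrics))
    else rep(NA_character_, nrow(metrics))
  }), out_names))
  if (!nrow(truth)) return(cbind(metrics, add))
  d <- outer(metrics$centroid_x_nm, truth$anchor_x_nm, "-")^2 +
    outer(metrics$centroid_y_nm, truth$anchor_y_nm, "-")^2
  d <- sqrt(d)
  used <- logical(nrow(truth))
  ord <- order(apply(d, 1L, min))
  for (i in ord) {
    j <- which.min(ifelse(used, Inf, d[i, ]))
    if (is.finite(d[i, j]) && d[i, j] <= max_match_nm && !used[j]) {
      used[j] <- TRUE
      for (k in seq_along(tcols)) {
        add[[out_names[k]]][i] <- truth[[tcols[k]]][j]
      }
    }
  }
  cbind(metrics, add)
}

# I/O wrappers -----------------------------------------------------------

#' Simulate scan fields and write them to disk
#'
#' Wraps [generate_population()]: writes each field as an ASCII grid (and
#' optionally float TIFF), the combined ground-truth table as CSV, and a
#' JSON snapshot of every parameter so a run is fully reconstructible.
#'
#' @param pop A [population_spec()] or preset name for
#'   [population_preset()].
#' @param scan A [scan_spec()].
#' @param out_dir Output directory (created if missing).
#' @param write_tiff Also write float TIFF images (needs the \pkg{tiff}
#'   package).
#' @return Invisibly, the [generate_population()] result.
#' @export
simulate_fields <- function(pop, scan = scan_spec(), out_dir,
                            write_tiff = FALSE) {
  if (is.character(pop)) pop <- population_preset(pop)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_population(pop, scan)
  for (f in seq_along(sim$fields)) {
    tp <- sim$fields[[f]]$topograph
    base <- file.path(out_dir, sprintf("field_%03d", f))
    write_topograph_ascii(tp, paste0(base, ".txt"))
    if (write_tiff) {
      write_topograph_tiff(tp, paste0(base, ".tif"))
    }
  }
  utils::write.csv(sim$truth, file.path(out_dir, "ground_truth.csv"),
                   row.names = FALSE)
  snap <- list(population_spec = unclass(pop), scan_spec = unclass(scan))
  jsonlite::write_json(snap, file.path(out_dir, "config_snapshot.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(sim)
}

#' Analyze a directory of scan fields
#'
#' Reads every `*.txt` ASCII grid (and `*.tif` if present and readable) in
#' a directory, analyzes each field, and writes `metrics.csv` and
#' `rejections.csv`. Unreadable files are reported and skipped.
#'
#' @param in_dir Directory of field images (as written by
#'   [simulate_fields()]).
#' @param params A [morph_params()].
#' @param out_dir Optional output directory for the CSV tables.
#' @param flatten_first Flatten raw images before analysis.
#' @return List with combined `metrics` and `rejections` tables.
#' @export
analyze_fields <- function(in_dir, params = morph_params(), out_dir = NULL,
                           flatten_first = TRUE) {
  files <- sort(list.files(in_dir, pattern = "\\.(txt|tif|tiff)$",
                           full.names = TRUE))
  all_m <- list(); all_r <- list(); errors <- character(0)
  for (fp in files) {
    tp <- tryCatch(suppressWarnings({
      if (grepl("\\.txt$", fp)) read_topograph_ascii(fp) else
        read_topograph_tiff(fp)
    }), error = function(e) e)
    if (inherits(tp, "error")) {
      errors <- c(errors, sprintf("%s: %s", basename(fp),
                                  conditionMessage(tp)))
      next
    }
    res <- analyze_topograph(tp, params, flatten_first = flatten_first)
    if (!is.null(res$metrics) && nrow(res$metrics)) {
      m <- res$metrics
      m$file <- basename(fp)
      all_m[[length(all_m) + 1L]] <- m
    }
    if (nrow(res$rejections)) {
      rj <- res$rejections
      rj$file <- basename(fp)
      all_r[[length(all_r) + 1L]] <- rj
    }
  }
  if (length(errors)) {
    warning(sprintf("%d file(s) skipped:\n%s", length(errors),
                    paste(errors, collapse = "\n")), call. = FALSE)
  }
  metrics <- if (length(all_m)) do.call(rbind, all_m) else NULL
  rejections <- if (length(all_r)) do.call(rbind, all_r) else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(metrics)) {
      utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                       row.names = FALSE)
    }
    if (!is.null(rejections)) {
      utils::write.csv(rejections, file.path(out_dir, "rejections.csv"),
                       row.names = FALSE)
    }
  }
  list(metrics = metrics, rejections = rejections, errors = errors)
}

#' Summary report over one or more metrics tables
#'
#' Computes the population-level numbers: counts, splay fractions with
#' binomial CIs, bubble frequency and size, total length, normalized
#' splay-to-splay distance, conformation class table, and (for two or more
#' groups) Welch comparisons of bubble size and normalized distance plus a
#' proportion test of bubble frequency.
#'
#' @param metrics_by_group Named list of metrics tables (from
#'   [analyze_topograph()] / [analyze_population()]).
#' @return List of per-group summaries and pairwise comparisons;
#'   JSON-serializable.
#' @export
report_metrics <- function(metrics_by_group) {
  stopifnot(is.list(metrics_by_group),
            length(names(metrics_by_group)) == length(metrics_by_group))
  groups <- lapply(names(metrics_by_group), function(gname) {
    m <- metrics_by_group[[gname]]
    if (is.null(m) || !nrow(m)) return(list(group = gname, n = 0))
    sf <- splay_fraction_stats(m$conformation_class)
    bub <- m$bubble_size_nm[m$has_bubble]
    bf_ci <- stats::binom.test(sum(m$has_bubble), nrow(m))$conf.int
    list(
      group = gname, n = nrow(m),
      total_length_mean_nm = mean(m$total_length_nm),
      total_length_sd_nm = stats::sd(m$total_length_nm),
      splay_at_least_one = sf$fraction[1],
      splay_at_least_one_ci = c(sf$ci_lo[1], sf$ci_hi[1]),
      splay_both = sf$fraction[2],
      splay_both_ci = c(sf$ci_lo[2], sf$ci_hi[2]),
      bubble_frequency = mean(m$has_bubble),
      bubble_frequency_ci = as.numeric(bf_ci),
      bubble_size_mean_nm = if (length(bub)) mean(bub) else NA,
      bubble_size_sd_nm = if (length(bub) > 1) stats::sd(bub) else NA,
      norm_splay_distance_mean = mean(m$norm_splay_distance, na.rm = TRUE),
      class_table = as.list(table(m$conformation_class))
    )
  })
  names(groups) <- names(metrics_by_group)
  comparisons <- list()
  gn <- names(metrics_by_group)
  if (length(gn) >= 2L) {
    for (i in seq_along(gn)) for (j in seq_along(gn)) {
      if (i >= j) next
      a <- metrics_by_group[[gn[i]]]; b <- metrics_by_group[[gn[j]]]
      if (is.null(a) || is.null(b) || !nrow(a) || !nrow(b)) next
      key <- paste(gn[i], "vs", gn[j])
      pt <- suppressWarnings(
        stats::prop.test(c(sum(a$has_bubble), sum(b$has_bubble)),
                         c(nrow(a), nrow(b))))
      comparisons[[key]] <- list(
        bubble_size = compare_groups(a$bubble_size_nm[a$has_bubble],
                                     b$bubble_size_nm[b$has_bubble]),
        norm_splay_distance = compare_groups(a$norm_splay_distance,
                                             b$norm_splay_distance),
        bubble_frequency_p = pt$p.value
      )
    }
  }
  list(groups = groups, comparisons = comparisons)
}

#' Predicted-versus-measured shortfall table
#'
#' @param measured Named numeric vector of measured mean lengths (nm) whose
#'   names match the constructs of [prediction_params()].
#' @param params A [prediction_params()].
#' @return A [tibble::tibble()] with predicted lengths and percent
#'   shortfalls per construct.
#' @export
shortfall_table <- function(measured, params = prediction_params()) {
  cons <- intersect(names(measured), names(params$residues))
  pred <- unname(predicted_length(params$residues[cons], params))
  tibble::tibble(
    construct = cons,
    residues = as.integer(unname(params$residues[cons])),
    predicted_nm = pred,
    measured_nm = as.numeric(measured[cons]),
    shortfall_pct = percent_shortfall(as.numeric(measured[cons]), pred)
  )
}
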