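#' Run configuration for end-to-end pipelines
#'
#' A single document (R list, or a JSON file path) drives an end-to-end run:
#' simulate a cohort, censor frames, build templates, map every participant
#' with the chosen method, build the group atlas and region sets, and write
#' every artifact with a content hash.
#'
#' @param method One of `"tm"`, `"omni"`, `"im_consensus"`.
#' @param simulation A [cohort_spec()] (or list of its arguments) for the
#'   synthetic cohort; alternatively supply `input_dir` with a previously
#'   written cohort.
#' @param out_dir Output directory.
#' @param minutes Exact-duration sampling target in minutes (`NULL` to use all
#'   retained frames).
#' @param fd_threshold_mm,min_segment_frames Censoring parameters.
#' @param p_threshold ROI probability threshold (default 0.8).
#' @param izone_threshold Integration-zone mean-count threshold (default 2.2).
#' @param n_template Number of participants used to build templates (default
#'   half the cohort).
#' @param seed Pipeline seed for exact-duration sampling.
#' @return A `run_config` list.
#' @export
run_config <- function(method = c("tm", "omni", "im_consensus"),
                       simulation = cohort_spec(), out_dir,
                       minutes = NULL, fd_threshold_mm = 0.2,
                       min_segment_frames = 5L, p_threshold = 0.8,
                       izone_threshold = 2.2, n_template = NULL, seed = 1L) {
  method <- match.arg(method)
  if (!inherits(simulation, "cohort_spec")) {
    simulation <- do.call(cohort_spec, simulation)
  }
  structure(list(method = method, simulation = simulation, out_dir = out_dir,
                 minutes = minutes, fd_threshold_mm = fd_threshold_mm,
                 min_segment_frames = as.integer(min_segment_frames),
                 p_threshold = p_threshold, izone_threshold = izone_threshold,
                 n_template = n_template, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from JSON
#'
#' @param path JSON file with the fields of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$simulation$behavior$effects)) {
    cfg$simulation$behavior$effects <- as_tibble(cfg$simulation$behavior$effects)
  }
  if (!is.null(cfg$simulation$fractions)) {
    cfg$simulation$fractions <- as.numeric(cfg$simulation$fractions)
  }
  do.call(run_config, cfg)
}

#' Run the end-to-end precision-mapping pipeline
#'
#' Stages: simulate -> censor -> (optional exact-duration sampling) ->
#' templates -> per-participant mapping (`tm`, `omni`, or `im_consensus`) ->
#' group atlas and region sets. All artifacts are written in the plain-text
#' dialect under `config$out_dir`; the returned manifest lists every file
#' with its MD5 content hash, so an unchanged config reproduces byte-identical
#' artifacts.
#'
#' @param config A [run_config()].
#' @return A `run_manifest`: tibble with `stage`, `file`, `md5`, plus a
#'   `counters` tibble of per-stage diagnostics (censored frames, ties,
#'   threshold fallbacks).
#' @export
run_pipeline <- function(config) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  counters <- list()
  note <- function(stage, path) files[[length(files) + 1L]] <<-
    tibble(stage = stage, file = path)
  count <- function(stage, name, value) counters[[length(counters) + 1L]] <<-
    tibble(stage = stage, counter = name, value = as.numeric(value))

  # --- simulate ---------------------------------------------------------
  cohort <- generate_cohort(config$simulation)
  truth_path <- file.path(out, "group_truth.dlabel.txt")
  write_labels(cohort$truth$labels, truth_path)
  note("simulate", truth_path)
  ccfg <- censor_config(fd_threshold_mm = config$fd_threshold_mm,
                        min_segment_frames = config$min_segment_frames)

  # --- censor + sample --------------------------------------------------
  masks <- vector("list", length(cohort$participants))
  for (p in seq_along(cohort$participants)) {
    pt <- cohort$participants[[p]]
    fd <- compute_fd(pt$motion)
    bold_sd <- apply(pt$ts$values, 1L, sd)
    m <- censor_frames(fd, ccfg, bold_sd = bold_sd)
    count("censor", sprintf("p%02d_censored", p),
          length(m$retained) - m$retained_count)
    if (!is.null(config$minutes)) {
      m <- sample_exact_duration(m, pt$ts$tr_seconds, config$minutes,
                                 seed = config$seed + p)
    }
    masks[[p]] <- m
  }

  # --- templates --------------------------------------------------------
  n_tmpl <- config$n_template
  if (is.null(n_tmpl)) n_tmpl <- max(2L, length(cohort$participants) %/% 2L)
  tmpl_idx <- seq_len(n_tmpl)
  seed_maps <- lapply(tmpl_idx, function(p) {
    participant_seed_maps(cohort$participants[[p]]$ts, cohort$truth$labels,
                          masks[[p]])
  })
  templates <- build_templates(seed_maps, palette = cohort$palette)
  tmpl_path <- file.path(out, "templates.txt")
  write_templates(templates, tmpl_path)
  note("templates", tmpl_path)

  # --- per-participant mapping -----------------------------------------
  maps <- vector("list", length(cohort$participants))
  for (p in seq_along(cohort$participants)) {
    pt <- cohort$participants[[p]]
    if (config$method == "tm") {
      mp <- template_match(pt$ts, templates, masks[[p]])
      count("map", sprintf("p%02d_ties", p), attr(mp, "n_ties") %||% 0)
      path <- file.path(out, sprintf("sub-%02d_tm.dlabel.txt", p))
    } else if (config$method == "omni") {
      mp <- omni_map(pt$ts, templates, masks[[p]])
      th <- attr(mp, "thresholds")
      count("map", sprintf("p%02d_fallbacks", p), sum(th$fallback_used))
      path <- file.path(out, sprintf("sub-%02d_omni.dlabel.txt", p))
    } else {
      C <- dense_correlation(pt$ts, masks[[p]])
      mp <- infomap_consensus(C, cohort$truth$labels,
                              consensus_config(network_priority = cohort$palette))
      path <- file.path(out, sprintf("sub-%02d_im.dlabel.txt", p))
    }
    write_labels(mp, path)
    note("map", path)
    maps[[p]] <- mp
  }

  # --- group atlas ------------------------------------------------------
  atlas <- probability_maps(maps)
  atlas_path <- file.path(out, "atlas_probs.txt")
  write_plain_matrix(atlas$probs, atlas_path)
  jsonlite::write_json(list(palette = atlas$palette,
                            n_participants = atlas$n_participants,
                            source_mode = atlas$source_mode),
                       sidecar_path(atlas_path), auto_unbox = TRUE, digits = NA)
  note("atlas", atlas_path)
  if (config$method == "omni") {
    iz <- integration_zones(maps, threshold = config$izone_threshold)
    iz_path <- file.path(out, "integration_zones.dscalar.txt")
    write_scalar(iz$mean_count, iz_path)
    note("izones", iz_path)
    count("izones", "n_zones", length(iz$zones$members))
  } else {
    rois <- derive_roiset(atlas, p_threshold = config$p_threshold)
    roi_path <- file.path(out, "roiset.tsv")
    roi_tab <- rois$parcels
    roi_tab$grayordinates <- vapply(rois$members, function(m)
      paste(m - 1L, collapse = ","), character(1L))  # 0-based in files
    utils::write.table(roi_tab, roi_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note("roiset", roi_path)
    count("roiset", "n_parcels", length(rois$members))
  }

  manifest <- dplyr::bind_rows(files)
  manifest$md5 <- unname(tools::md5sum(manifest$file))
  structure(list(manifest = manifest,
                 counters = dplyr::bind_rows(counters)),
            class = "run_manifest")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> ", nrow(x$manifest), " artifacts across ",
      length(unique(x$manifest$stage)), " stages\n", sep = "")
  print(x$manifest, n = 20)
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `run_manifest`.
#' @param ... Unused.
#' @export
tidy.run_manifest <- function(x, ...) x$manifest
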