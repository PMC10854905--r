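# Configuration, orchestration and end-to-end runs:
# simulate -> measure -> statistics, with seeded substreams per stage and
# a manifest of produced artifacts.

.default_config <- function() {
  list(
    seed = 1L,
    stages = c("simulate", "measure", "stats"),
    out_dir = "fundusgeom-run",
    n_images = 10L,
    image = list(size = 512L, noise_sd = 5, av_contrast = 30),
    tree = list(n_roots = 2L, branching_depth = 2L,
                angle_range_deg = c(40, 110), width_root_px = c(9, 12),
                width_taper = 0.67, disc_diameter_px = c(60, 100)),
    cohort = list(n_subjects = c(BRVO = 34L, CRVO = 25L), effects = TRUE),
    measure = list(backend = "baseline", spur_len = 5, probe_len = 15,
                   zone = c(1.0, 1.5)),
    log_level = "info"
  )
}

#' Validate a pipeline configuration file
#'
#' Reads a YAML configuration, checks every key against the known schema
#' (unknown keys are rejected with the closest known key suggested),
#' fills defaults, and validates invariants (e.g. annulus bounds
#' 0 < lo < hi).
#'
#' @param path YAML file path, or a list already in memory.
#' @return fully-defaulted configuration list of class `run_config`.
#' @export
validate_config <- function(path) {
  user <- if (is.list(path)) path else yaml::read_yaml(path)
  def <- .default_config()
  merge_into <- function(base, upd, prefix = "") {
    for (k in names(upd)) {
      full <- paste0(prefix, k)
      if (!k %in% names(base)) {
        sugg <- names(base)[which.min(utils::adist(k, names(base)))]
        stop(sprintf("unknown config key '%s'; did you mean '%s'?", full, sugg),
             call. = FALSE)
      }
      if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
        if (!is.list(upd[[k]])) {
          stop(sprintf("config key '%s' must be a mapping", full), call. = FALSE)
        }
        base[[k]] <- merge_into(base[[k]], upd[[k]], paste0(full, "."))
      } else {
        if (is.numeric(base[[k]]) && !is.numeric(upd[[k]])) {
          stop(sprintf("config key '%s' must be numeric", full), call. = FALSE)
        }
        v <- upd[[k]]
        if (is.numeric(base[[k]])) v <- as.numeric(v)
        if (!is.null(names(base[[k]])) && is.null(names(v)) &&
              length(v) == length(base[[k]])) {
          names(v) <- names(base[[k]])
        }
        base[[k]] <- v
      }
    }
    base
  }
  cfg <- merge_into(def, user)
  z <- cfg$measure$zone
  check_that(length(z) == 2 && z[1] > 0 && z[1] < z[2], "measure.zone",
             "annulus bounds must satisfy 0 < lo < hi")
  check_that(cfg$n_images >= 0, "n_images", "must be >= 0")
  check_that(all(cfg$cohort$n_subjects >= 1), "cohort.n_subjects",
             "must be >= 1")
  check_that(cfg$tree$branching_depth >= 0, "tree.branching_depth",
             "must be >= 0")
  structure(cfg, class = c("run_config", "list"))
}

#' Measure one fundus image end to end
#'
#' Runs preprocessing, vessel segmentation, artery/vein classification,
#' disc segmentation, centerline extraction, diameter measurement, annulus
#' calibers and quadrant branching angles on a single image.
#'
#' @param image intensity matrix (0-255) or path to a PNG file.
#' @param laterality "OD" or "OS".
#' @param backend segmentation backend name ("truth" requires `mask`).
#' @param mask optional binary vessel mask for the "truth" backend.
#' @param spur_len,probe_len,zone measurement parameters (see
#'   [extract_centerline()], [branching_angle()], [annulus_calibers()]).
#' @return list of class `eye_measurement`: `disc` (optic_disc), `calibers`
#'   (caliber_summary), `angles` (quadrant_angles result), `graph`,
#'   `av_mask`, `n_bifurcations`, `n_crossings`.
#' @export
measure_fundus <- function(image, laterality = "OD", backend = "baseline",
                           mask = NULL, spur_len = 5, probe_len = 15,
                           zone = c(1.0, 1.5)) {
  if (is.character(image)) {
    image <- png::readPNG(image)
    if (length(dim(image)) == 3) image <- image[, , 1]
    image <- image * 255
  }
  pp <- preprocess(image)
  vmask <- if (backend == "truth") segment_vessels(pp, "truth", mask = mask)
  else segment_vessels(pp, backend)
  disc <- locate_and_segment_disc(pp)
  graph <- extract_centerline(vmask, spur_len = spur_len)
  av <- classify_arteries_veins(pp, vmask, graph)
  graph <- extract_centerline(vmask, spur_len = spur_len, av_mask = av)
  profile <- measure_diameters(vmask, graph, disc = disc)
  cal <- annulus_calibers(profile, disc, zone = zone)
  ang <- quadrant_angles(graph, disc, laterality = laterality,
                         vessel_mask = vmask, probe_len = probe_len)
  bif <- detect_bifurcations(graph)
  structure(list(disc = disc, calibers = cal, angles = ang, graph = graph,
                 av_mask = av, profile = profile,
                 n_bifurcations = nrow(bif),
                 n_crossings = attr(bif, "n_crossings")),
            class = "eye_measurement")
}

#' Run the full simulation-measurement-statistics pipeline
#'
#' Stages (each seeded from the global seed by a stable per-stage
#' substream): `simulate` renders `n_images` synthetic fundus images with
#' ground truth and draws a cohort; `measure` runs [measure_fundus()] on
#' every image; `stats` builds the comparison report from the cohort.
#' Artifacts are written under `config$out_dir` with a manifest carrying
#' the configuration hash.
#'
#' @param config a [validate_config()] result (or path to a YAML file).
#' @param write logical: write artifacts to disk (default TRUE).
#' @return list of class `study_report`: `manifest`, `config_hash`,
#'   `geometry` (per-image measurement summaries), `report` (comparison
#'   report), `errors`.
#' @export
run_pipeline <- function(config, write = TRUE) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  seed <- config$seed
  out_dir <- config$out_dir
  if (write) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)
  cfg_hash <- config_hash(config)
  errors <- character(0)
  geometry <- NULL
  report <- NULL

  cohort <- generate_cohort(cohort_spec(
    n_subjects = config$cohort$n_subjects,
    effects = isTRUE(config$cohort$effects),
    seed = derive_seed(seed, "simulate-cohort")))

  if ("simulate" %in% config$stages || "measure" %in% config$stages) {
    sims <- lapply(seq_len(config$n_images), function(i) {
      dd_range <- config$tree$disc_diameter_px
      dd <- if (length(dd_range) == 2) {
        dd_range[1] + (i - 1) * diff(dd_range) / max(1, config$n_images - 1)
      } else dd_range[1]
      sp <- vessel_tree_spec(
        n_roots = config$tree$n_roots,
        branching_depth = config$tree$branching_depth,
        angle_range_deg = config$tree$angle_range_deg,
        width_root_px = config$tree$width_root_px,
        width_taper = config$tree$width_taper,
        image_size = config$image$size,
        disc_diameter_px = dd,
        seed = derive_seed(seed, paste0("simulate-image-", i)))
      tr <- generate_vessel_tree(sp)
      rend <- render_fundus(tr, noise_sd = config$image$noise_sd,
                            av_contrast = config$image$av_contrast,
                            seed = derive_seed(seed, paste0("render-", i)))
      list(truth = tr, rendering = rend)
    })
    if (write) {
      cpath <- file.path(out_dir, "cohort.csv")
      utils::write.csv(cohort, cpath, row.names = FALSE)
      manifest <- c(manifest, cpath)
      for (i in seq_along(sims)) {
        ipath <- file.path(out_dir, sprintf("image_%02d.png", i))
        png::writePNG(sims[[i]]$rendering$image / 255, ipath)
        manifest <- c(manifest, ipath)
      }
    }
  }

  if ("measure" %in% config$stages) {
    rows <- list()
    for (i in seq_along(sims)) {
      res <- tryCatch(
        measure_fundus(sims[[i]]$rendering$image,
                       backend = config$measure$backend,
                       spur_len = config$measure$spur_len,
                       probe_len = config$measure$probe_len,
                       zone = config$measure$zone),
        error = function(e) e)
      if (inherits(res, "error")) {
        errors <- c(errors, sprintf("image %d: %s", i, conditionMessage(res)))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        image = i,
        dd_px = res$disc$dd,
        dd_truth_px = sims[[i]]$truth$disc$diameter_px,
        rel_arteriolar = res$calibers$rel_arteriolar,
        rel_venular = res$calibers$rel_venular,
        avr = res$calibers$avr,
        n_bifurcations = res$n_bifurcations,
        n_bif_truth = nrow(sims[[i]]$truth$bifurcations))
    }
    geometry <- if (length(rows)) do.call(rbind, rows) else NULL
    if (write && !is.null(geometry)) {
      gpath <- file.path(out_dir, "geometry.csv")
      utils::write.csv(geometry, gpath, row.names = FALSE)
      manifest <- c(manifest, gpath)
    }
  }

  if ("stats" %in% config$stages && length(errors) == 0) {
    report <- build_comparison_report(cohort)
    if (write) {
      spath <- file.path(out_dir, "report_per_eye.csv")
      utils::write.csv(report$per_eye, spath, row.names = FALSE)
      dpath <- file.path(out_dir, "report_demographics.csv")
      utils::write.csv(report$demographics, dpath, row.names = FALSE)
      mpath <- file.path(out_dir, "models.json")
      jsonlite::write_json(list(
        affected_vs_affected = report$model_affected_vs_affected$terms,
        crvo_affected_vs_contralateral =
          report$model_crvo_affected_vs_contralateral$terms),
        mpath, auto_unbox = TRUE, digits = NA)
      manifest <- c(manifest, spath, dpath, mpath)
    }
  } else if (length(errors) > 0) {
    errors <- c(errors, "stats stage skipped due to upstream failure")
  }

  if (write) {
    man <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(list(config_hash = cfg_hash, seed = seed,
                              files = manifest, errors = errors),
                         man, auto_unbox = TRUE)
    manifest <- c(manifest, man)
  }
  structure(list(manifest = manifest, config_hash = cfg_hash,
                 geometry = geometry, report = report, errors = errors,
                 failed = length(errors) > 0),
            class = "study_report")
}

# stable content hash of the scientific configuration (FNV-1a over its
# deparse); volatile fields (output location, log level) are excluded so
# reruns of the same analysis hash identically
config_hash <- function(config) {
  keep <- setdiff(sort(names(config)), c("out_dir", "log_level"))
  s <- paste(deparse(config[keep]), collapse = "\n")
  h <- 2166136261
  for (k in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), k)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
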