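#' Pipeline configuration
#'
#' One configuration object drives the whole analysis: input (either a
#' [phantom_spec()] or paths to a volume file and a seed table),
#' segmentation parameters, Purkinje-detection parameters, statistics
#' parameters, output directory and the global seed. The global seed fans
#' out to per-stage seeds by a fixed hash of the stage name, so stages are
#' independently reproducible.
#'
#' @param phantom a `phantom_spec`, or `NULL` when reading from files.
#' @param volume_path,seeds_path input files (exactly one input source:
#'   either `phantom` or both paths).
#' @param voxel_size_um optional voxel-size override for TIFF input.
#' @param segmentation list: `min_volume_um3` (default 150), `connectivity`,
#'   `bins`, `smooth_bins`, `prominence_frac`.
#' @param purkinje list: `enabled`, `scales_um`, `threshold`,
#'   `diameter_range_um`.
#' @param stats list: `hist_bin_deg`, `planes`, `group_by`.
#' @param mip list: `thickness_um` (default 25), `enabled`.
#' @param out_dir output directory (created if missing).
#' @param seed global integer seed.
#' @return List of class `cp_config`.
#' @export
pipeline_config <- function(
    phantom = NULL, volume_path = NULL, seeds_path = NULL,
    voxel_size_um = NULL,
    segmentation = list(), purkinje = list(), stats = list(), mip = list(),
    out_dir = tempfile("cereplaq_run_"), seed = 1L) {
  has_phantom <- !is.null(phantom)
  has_files <- !is.null(volume_path) || !is.null(seeds_path)
  if (has_phantom == has_files)
    stop("exactly one input source: a phantom spec, or volume and seed paths")
  if (has_files && (is.null(volume_path) || is.null(seeds_path)))
    stop("file input needs both volume_path and seeds_path")
  if (has_files) {
    for (p in c(volume_path, seeds_path))
      if (!file.exists(p)) stop("input path not resolvable: ", p)
  }
  seg <- utils::modifyList(
    list(min_volume_um3 = 150, connectivity = 26L, bins = 256L,
         smooth_bins = 5L, prominence_frac = 0.01), segmentation)
  pk <- utils::modifyList(
    list(enabled = TRUE, scales_um = c(6, 8, 10, 12), threshold = 0.5,
         diameter_range_um = c(12, 30)), purkinje)
  st <- utils::modifyList(
    list(hist_bin_deg = 10, planes = c("transverse", "coronal"),
         group_by = "region"), stats)
  mp <- utils::modifyList(list(enabled = TRUE, thickness_um = 25), mip)
  structure(list(
    phantom = phantom, volume_path = volume_path, seeds_path = seeds_path,
    voxel_size_um = voxel_size_um, segmentation = seg, purkinje = pk,
    stats = st, mip = mp, out_dir = out_dir, seed = as.integer(seed)
  ), class = "cp_config")
}

# fixed per-stage seed derivation (stays below 2^31)
.stage_seed <- function(seed, stage) {
  (as.numeric(seed) * 48271 + sum(utf8ToInt(stage)) * 9973) %% 2147483629
}

.summary_to_list <- function(s) {
  list(n = s$n, mean = s$mean, std = s$std, skewness = s$skewness,
       skewness_flag = s$skewness_flag, quantiles = as.list(s$quantiles))
}

#' Run the full analysis pipeline
#'
#' Phantom generation (or volume loading), cylindrical-VOI plaque
#' segmentation, Purkinje detection, per-object morphometry and population
#' statistics, with all results written under `config$out_dir`:
#' `plaque_labels.tif`, `purkinje_labels.tif`, `morph.csv`,
#' `threshold.json`, `stats.json`, per-plane MIP PNGs, and a
#' `manifest.json` listing every output with its MD5 checksum. For a fixed
#' configuration and seed the CSV/JSON outputs are byte-identical across
#' runs.
#'
#' @param config a [pipeline_config()].
#' @return Invisible list with the in-memory results (`volume`, `truth`,
#'   `plaques`, `purkinje`, `records`, `stats`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "cp_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  stage <- function(name, expr) {
    ts <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - ts, 3)
    res
  }

  truth <- NULL
  input <- stage("input", {
    if (!is.null(config$phantom)) {
      spec <- config$phantom
      spec$seed <- as.integer(.stage_seed(config$seed, "phantom") %%
                                .Machine$integer.max)
      ph <- generate_phantom(spec)
      truth <- ph$truth
      list(volume = ph$volume, seeds = seed_rois_from_truth(ph$truth),
           region_fun = region_tagger(ph$truth))
    } else {
      vol <- read_volume(config$volume_path,
                         voxel_size_um = config$voxel_size_um)
      seeds <- read_seed_rois(config$seeds_path)
      rf <- .region_from_seeds(seeds, vol$voxel_size_um)
      list(volume = vol, seeds = seeds, region_fun = rf)
    }
  })
  volume <- input$volume
  seeds <- input$seeds

  seg <- config$segmentation
  plaques <- stage("segment", {
    voi <- build_voi_mask(seeds, volume)
    thr <- find_bimodal_threshold(volume, voi, bins = seg$bins,
                                  smooth_bins = seg$smooth_bins,
                                  prominence_frac = seg$prominence_frac)
    jsonlite::write_json(
      list(threshold = thr$threshold, method = thr$method,
           bimodal = thr$bimodal,
           peaks_gray = as.list(thr$peaks_gray)),
      file.path(config$out_dir, "threshold.json"),
      auto_unbox = TRUE, digits = NA, na = "null")
    extract_plaques(volume, voi, thr$threshold,
                    min_volume_um3 = seg$min_volume_um3,
                    connectivity = seg$connectivity)
  })
  write_labels(plaques, file.path(config$out_dir, "plaque_labels.tif"))

  purk <- NULL
  if (isTRUE(config$purkinje$enabled)) {
    purk <- stage("purkinje", {
      bm <- hessian_blobness(volume, config$purkinje$scales_um)
      detect_purkinje(bm, volume, threshold = config$purkinje$threshold,
                      diameter_range_um = config$purkinje$diameter_range_um)
    })
    write_labels(purk, file.path(config$out_dir, "purkinje_labels.tif"))
  }

  records <- stage("measure", {
    rec_p <- measure_objects(plaques, class = "plaque",
                             region_fun = input$region_fun)
    if (!is.null(purk)) {
      rec_k <- measure_objects(purk, class = "purkinje",
                               region_fun = input$region_fun)
      if (nrow(rec_k) > 0) rec_p <- rbind(rec_p, rec_k)
    }
    rec_p
  })
  write_morph_records(records, file.path(config$out_dir, "morph.csv"))

  stats_out <- stage("stats", {
    pl <- records[records$class == "plaque", , drop = FALSE]
    pk <- records[records$class == "purkinje", , drop = FALSE]
    res <- list(n_plaques = nrow(pl), n_purkinje = nrow(pk))
    if (nrow(pl) == 0) {
      warning("no plaque records: statistics stage emits empty summaries")
    } else {
      ssum <- summarize_values(pl$sphericity)
      res$plaque_sphericity <- .summary_to_list(ssum)
      res$plaque_volume <- .summary_to_list(summarize_values(pl$volume_um3))
      if (nrow(pl) >= 10) {
        lc <- lognormal_check(pl$volume_um3)
        res$lognormal <- list(log_mean = lc$log_mean, log_sd = lc$log_sd,
                              ks_stat = lc$ks_stat)
      }
      el <- select_elongated(pl, ssum)
      res$n_elongated <- nrow(el)
      if (nrow(el) > 0) {
        os <- orientation_summary(el, group_by = config$stats$group_by,
                                  planes = config$stats$planes,
                                  hist_bin_deg = config$stats$hist_bin_deg)
        res$orientation <- lapply(os, function(o)
          list(n = o$n, mean_axis = o$mean_axis, p50_deg = o$p50_deg,
               p90_deg = o$p90_deg, plane_deviation = o$plane_deviation))
        for (rg in names(os)) {
          hh <- os[[rg]]$hist
          utils::write.csv(
            data.frame(azimuth_lo = rep(head(hh$azimuth_breaks, -1),
                                        ncol(hh$counts)),
                       elevation_lo = rep(head(hh$elevation_breaks, -1),
                                          each = nrow(hh$counts)),
                       count = as.vector(hh$counts)),
            file.path(config$out_dir,
                      paste0("orientation_hist_", rg, ".csv")),
            row.names = FALSE)
        }
      } else {
        warning("no elongated plaques: orientation stage skipped")
      }
    }
    if (nrow(pl) >= 3 && nrow(pk) >= 3) {
      cg <- compare_groups(pk$sphericity, pl$sphericity)
      res$purkinje_vs_plaque <- cg
      if (nrow(pk) > 0)
        res$purkinje_sphericity <- .summary_to_list(
          summarize_values(pk$sphericity))
    }
    jsonlite::write_json(res, file.path(config$out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
    res
  })

  if (isTRUE(config$mip$enabled)) {
    stage("mip", {
      for (pl in c("coronal", "sagittal", "transverse")) {
        ax <- switch(pl, coronal = 3L, sagittal = 2L, transverse = 1L)
        n_ax <- dim(volume$voxels)[ax]
        th <- min(config$mip$thickness_um,
                  n_ax * volume$voxel_size_um)
        start <- max(0, (n_ax * volume$voxel_size_um - th) / 2)
        img <- render_mip(volume, pl, thickness_um = th, start_um = start)
        rng <- range(img)
        img01 <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
        png::writePNG(img01, file.path(config$out_dir,
                                       paste0("mip_", pl, ".png")))
      }
      NULL
    })
  }

  manifest_path <- file.path(config$out_dir, "manifest.json")
  files <- setdiff(list.files(config$out_dir), basename(manifest_path))
  checksums <- as.list(tools::md5sum(file.path(config$out_dir, files)))
  names(checksums) <- files
  manifest <- list(
    package_version = as.character(utils::packageVersion("cereplaq")),
    seed = config$seed,
    n_seeds = nrow(seeds),
    n_plaques = sum(records$class == "plaque"),
    n_purkinje = sum(records$class == "purkinje"),
    stage_timings_s = timings,
    total_s = round(proc.time()[["elapsed"]] - t0, 3),
    files = checksums
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(volume = volume, truth = truth, plaques = plaques,
                 purkinje = purk, records = records, stats = stats_out,
                 manifest = manifest))
}

# region of a centroid = region of the nearest seed (in-plane distance plus
# distance to the seed's slice range), for file-based inputs where regions
# come from the seed table
.region_from_seeds <- function(seeds, voxel_size_um) {
  if (nrow(seeds) == 0) return(function(centroid_um) "all")
  function(centroid_um) {
    v <- centroid_um / voxel_size_um + 0.5  # back to 1-based voxel coords
    dz <- pmax(0, pmax(seeds$z_start - v[3], v[3] - seeds$z_end))
    d2 <- (seeds$cx - v[1])^2 + (seeds$cy - v[2])^2 + dz^2
    as.character(seeds$region[which.min(d2)])
  }
}
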