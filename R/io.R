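#' Read and write gray-level volumes
#'
#' Two on-disk formats are supported. HDF5 stores the voxel grid as a
#' `/volume` dataset with a `voxel_size_um` attribute and round-trips
#' float64 gray values bit-exactly. Multi-page TIFF stores one page per
#' coronal slice (page index = anterior-posterior slice index); because
#' baseline TIFF pages here are written as normalized 32-bit samples, gray
#' values are min-max scaled on write and restored on read using a JSON
#' sidecar (`<path>.json`) that also carries the voxel size. A TIFF without
#' its sidecar is readable only when `voxel_size_um` is passed explicitly;
#' otherwise reading fails naming the missing voxel-size metadata.
#'
#' @param path file path; format inferred from the extension
#'   (`.h5`/`.hdf5` vs `.tif`/`.tiff`) unless `format` is given.
#' @param format "hdf5" or "tiff".
#' @param voxel_size_um explicit voxel-size override for TIFF stacks
#'   lacking sidecar metadata.
#' @return `read_volume` returns a `cp_volume`; `write_volume` returns the
#'   path invisibly.
#' @name volume_io
NULL

.guess_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("tiff", "hdf5")))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) "tiff"
  else if (ext %in% c("h5", "hdf5")) "hdf5"
  else stop("cannot infer volume format from extension: ", path)
}

#' @rdname volume_io
#' @param volume a `cp_volume`.
#' @export
write_volume <- function(volume, path, format = NULL) {
  stopifnot(inherits(volume, "cp_volume"))
  format <- .guess_format(path, format)
  if (format == "hdf5") {
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(volume$voxels, path, "volume")
    fid <- rhdf5::H5Fopen(path)
    did <- rhdf5::H5Dopen(fid, "volume")
    rhdf5::h5writeAttribute(volume$voxel_size_um, did, "voxel_size_um")
    rhdf5::H5Dclose(did)
    rhdf5::H5Fclose(fid)
  } else {
    v <- volume$voxels
    g_min <- min(v)
    g_rng <- max(v) - g_min
    scale <- if (g_rng > 0) g_rng else 1
    pages <- lapply(seq_len(dim(v)[3]), function(k)
      (v[, , k] - g_min) / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                    compression = "none")
    jsonlite::write_json(
      list(voxel_size_um = volume$voxel_size_um, gray_min = g_min,
           gray_range = scale,
           axis_order = paste(volume$axis_names, collapse = ",")),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname volume_io
#' @export
read_volume <- function(path, format = NULL, voxel_size_um = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  format <- .guess_format(path, format)
  if (format == "hdf5") {
    vox <- rhdf5::h5read(path, "volume")
    at <- rhdf5::h5readAttributes(path, "volume")
    if (is.null(at$voxel_size_um)) {
      if (is.null(voxel_size_um))
        stop("HDF5 dataset has no 'voxel_size_um' attribute and no ",
             "explicit voxel size was given")
    } else voxel_size_um <- as.numeric(at$voxel_size_um)
    return(cp_volume(vox, voxel_size_um))
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d1 <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), d1), logical(1))))
    stop("ragged TIFF stack: pages differ in size")
  sidecar <- paste0(path, ".json")
  g_min <- 0; g_rng <- 1
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(voxel_size_um)) voxel_size_um <- meta$voxel_size_um
    if (!is.null(meta$gray_min)) g_min <- meta$gray_min
    if (!is.null(meta$gray_range)) g_rng <- meta$gray_range
  }
  if (is.null(voxel_size_um))
    stop("TIFF stack has no voxel-size metadata (sidecar '", sidecar,
         "' not found) and no explicit voxel_size_um was given")
  vox <- array(0, c(d1[1], d1[2], length(pages)))
  for (k in seq_along(pages)) vox[, , k] <- pages[[k]] * g_rng + g_min
  cp_volume(vox, voxel_size_um)
}

#' Write a label map as an integer TIFF stack
#'
#' Labels are stored as 16-bit pages (supports up to 65535 objects) with a
#' JSON sidecar holding the voxel size.
#'
#' @param labels a `cp_labelmap`.
#' @param path output `.tif` path.
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "cp_labelmap"))
  mx <- max(labels$labels)
  if (mx > 65535L) stop("more than 65535 labels cannot be stored as 16-bit")
  pages <- lapply(seq_len(dim(labels$labels)[3]), function(k)
    labels$labels[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(list(voxel_size_um = labels$voxel_size_um,
                            max_label = mx),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("label stack sidecar '", sidecar, "' not found")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  d1 <- dim(pages[[1]])
  lab <- array(0L, c(d1[1], d1[2], length(pages)))
  for (k in seq_along(pages))
    lab[, , k] <- as.integer(round(pages[[k]] * 65535))
  cp_labelmap(lab, meta$voxel_size_um)
}

#' Read seed regions of interest
#'
#' Seeds mark candidate plaques: a circular in-plane region (center in
#' voxel coordinates on the coronal plane, radius in um) extruded over an
#' inclusive coronal slice range. Accepted as CSV (columns `cx, cy,
#' z_start, z_end, radius_um, region`) or JSON (array of objects with the
#' same keys). Rows violating the invariants (`radius_um > 0`,
#' `z_start <= z_end`) are rejected with a warning naming the row numbers;
#' an empty file yields an empty seed table.
#'
#' @param path CSV or JSON file.
#' @return data.frame of valid seeds.
#' @export
read_seed_rois <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "json") {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    read.csv(path, stringsAsFactors = FALSE)
  }
  required <- c("cx", "cy", "z_start", "z_end", "radius_um")
  if (nrow(df) == 0) {
    if (!all(required %in% names(df)) && length(names(df)) > 0)
      stop("seed file lacks required columns: ",
           paste(setdiff(required, names(df)), collapse = ", "))
    df$region <- character(0)
    return(df[, c(required, "region"), drop = FALSE])
  }
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("seed file lacks required columns: ",
         paste(missing, collapse = ", "))
  if (is.null(df$region)) df$region <- "all"
  num_cols <- c("cx", "cy", "z_start", "z_end", "radius_um")
  for (cc in num_cols) {
    df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(!is.finite(df[[cc]]))
    if (length(bad) > 0)
      stop(sprintf("seed file: non-numeric '%s' in row(s) %s", cc,
                   paste(bad, collapse = ", ")))
  }
  bad_radius <- which(df$radius_um <= 0)
  bad_range <- which(df$z_start > df$z_end)
  bad <- sort(unique(c(bad_radius, bad_range)))
  if (length(bad) > 0) {
    why <- c(
      if (length(bad_radius)) sprintf("radius_um <= 0 (rows %s)",
                                      paste(bad_radius, collapse = ", ")),
      if (length(bad_range)) sprintf("z_start > z_end (rows %s)",
                                     paste(bad_range, collapse = ", ")))
    warning("rejecting ", length(bad), " seed row(s): ",
            paste(why, collapse = "; "))
    df <- df[-bad, , drop = FALSE]
  }
  rownames(df) <- NULL
  df[, c(required, "region")]
}

#' @rdname read_seed_rois
#' @param seeds data.frame of seeds.
#' @export
write_seed_rois <- function(seeds, path) {
  write.csv(seeds, path, row.names = FALSE)
  invisible(path)
}

#' Write and read per-object measurement tables
#'
#' Plain-CSV persistence for the table produced by [measure_objects()].
#'
#' @param records data.frame of per-object records.
#' @param path CSV path.
#' @export
write_morph_records <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_morph_records
#' @export
read_morph_records <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
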