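#' Construct a 3D gray-level volume
#'
#' A volume is a 3D numeric array of gray values on an isotropic grid with a
#' physical voxel size in micrometres. Grid axes map to anatomy in a fixed
#' order: axis 1 is dorso-ventral, axis 2 medio-lateral, axis 3
#' anterior-posterior (so axis-3 index is the coronal slice number).
#' Physical coordinates are voxel-center based: a voxel with 1-based grid
#' index `i` spans `[(i-1)*h, i*h]` and its center is `(i - 0.5) * h` for
#' voxel size `h`.
#'
#' @param voxels 3D numeric array of finite gray values.
#' @param voxel_size_um isotropic voxel edge length in micrometres (> 0).
#' @return An object of class `cp_volume` with elements `voxels`,
#'   `voxel_size_um` and `axis_names`.
#' @examples
#' v <- cp_volume(array(0, c(8, 8, 8)), voxel_size_um = 1.625)
#' dim(v$voxels)
#' @export
cp_volume <- function(voxels, voxel_size_um = 1.625) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array")
  if (any(dim(voxels) < 1L)) stop("all grid extents must be >= 1")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      !is.finite(voxel_size_um) || voxel_size_um <= 0)
    stop("voxel_size_um must be a single positive number")
  if (!all(is.finite(voxels))) stop("gray values must be finite")
  storage.mode(voxels) <- "double"
  structure(
    list(voxels = voxels, voxel_size_um = as.numeric(voxel_size_um),
         axis_names = .cp_axis_names),
    class = "cp_volume"
  )
}

#' @export
print.cp_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<cp_volume> %d x %d x %d voxels @ %.4g um (%s)\n",
              d[1], d[2], d[3], x$voxel_size_um,
              paste(x$axis_names, collapse = " / ")))
  cat(sprintf("  gray range [%.4g, %.4g]\n",
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Construct a label map congruent with a volume grid
#'
#' @param labels 3D array of non-negative integers; 0 is background.
#' @param voxel_size_um isotropic voxel size in micrometres.
#' @return An object of class `cp_labelmap`.
#' @export
cp_labelmap <- function(labels, voxel_size_um = 1.625) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("labels must be a 3D array")
  if (any(labels < 0)) stop("labels must be non-negative")
  storage.mode(labels) <- "integer"
  structure(
    list(labels = labels, voxel_size_um = as.numeric(voxel_size_um)),
    class = "cp_labelmap"
  )
}

#' @export
print.cp_labelmap <- function(x, ...) {
  d <- dim(x$labels)
  ids <- setdiff(unique(as.vector(x$labels)), 0L)
  cat(sprintf("<cp_labelmap> %d x %d x %d voxels @ %.4g um, %d object(s)\n",
              d[1], d[2], d[3], x$voxel_size_um, length(ids)))
  invisible(x)
}

#' Labels present in a label map
#' @param labels a `cp_labelmap`.
#' @return Sorted integer vector of positive label ids.
#' @export
label_ids <- function(labels) {
  stopifnot(inherits(labels, "cp_labelmap"))
  sort(setdiff(unique(as.vector(labels$labels)), 0L))
}

# voxel-center physical coordinate (um) of 1-based grid index
.voxel_center_um <- function(index1, voxel_size_um) {
  (index1 - 0.5) * voxel_size_um
}
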