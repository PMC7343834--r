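#' Multi-scale Hessian blobness map
#'
#' Shape-selective filter for bright, near-spherical objects (Purkinje
#' somata). At each smoothing scale s the volume is Gaussian-smoothed, the
#' per-voxel 3x3 Hessian is formed with gamma-normalized (s^2-multiplied)
#' second derivatives, and its eigenvalues are sorted by magnitude
#' |l1| <= |l2| <= |l3|. Bright blobs curve down in every direction, so
#' blobness is zero unless all three eigenvalues are negative; otherwise
#' \deqn{B = (|l1|/|l3|) (1 - exp(-(l1^2+l2^2+l3^2)/(2 c^2)))}
#' with c set to half the maximum Hessian Frobenius norm at that scale.
#' The first factor suppresses tubes (l1 ~ 0 along the axis) and plates;
#' the second suppresses low-contrast noise. The map is the per-voxel
#' maximum over scales.
#'
#' @param volume a `cp_volume`.
#' @param scales_um smoothing scales in micrometres, each larger than the
#'   voxel size (defaults match the soma radius range).
#' @return Object of class `cp_blobness`: `blobness` (array in `[0, 1]`),
#'   `scale_of_max_um`, `scales_um`, `voxel_size_um`.
#' @export
hessian_blobness <- function(volume, scales_um = c(6, 8, 10, 12)) {
  stopifnot(inherits(volume, "cp_volume"))
  h <- volume$voxel_size_um
  if (length(scales_um) == 0) stop("scales_um must be nonempty")
  if (any(scales_um <= h))
    stop("every scale must exceed the voxel size (", h, " um)")
  dims <- dim(volume$voxels)
  best <- array(0, dims)
  best_scale <- array(NA_real_, dims)
  for (s in scales_um) {
    sigma_vox <- s / h
    g <- gaussian_blur3_cpp(volume$voxels, dims, sigma_vox)
    eig <- hessian_eigenvalues_cpp(g, dims, sigma_vox^2)
    l1 <- eig$l1; l2 <- eig$l2; l3 <- eig$l3
    frob2 <- l1^2 + l2^2 + l3^2
    cmax <- 0.5 * sqrt(max(frob2))
    if (cmax > 0) {
      b <- (abs(l1) / pmax(abs(l3), .Machine$double.eps)) *
        (1 - exp(-frob2 / (2 * cmax^2)))
      b[!(l1 < 0 & l2 < 0 & l3 < 0)] <- 0
    } else {
      b <- array(0, dims)
    }
    upd <- b > best
    best[upd] <- b[upd]
    best_scale[upd] <- s
    rm(l1, l2, l3, frob2, b, upd, g, eig)
  }
  structure(list(blobness = best, scale_of_max_um = best_scale,
                 scales_um = scales_um, voxel_size_um = h),
            class = "cp_blobness")
}

#' Detect Purkinje somata from a blobness map
#'
#' Two-stage shape-based segmentation. First the blobness map is
#' thresholded and 26-connected candidate components are extracted; each
#' candidate marks one putative soma at its blobness peak. Because the
#' blobness super-level set concentrates near the soma center, the full
#' soma extent is then recovered by a local gray-level refinement: in a
#' cubic neighbourhood sized by the maximum expected diameter, a threshold
#' halfway between the soma gray at the peak and the local background
#' median separates the bright soma from tissue, and the connected bright
#' region containing the peak becomes the segmented cell.
#' Refined regions whose equivalent-sphere diameter falls outside
#' `diameter_range_um` are discarded. Labels are ordered by decreasing
#' peak blobness.
#'
#' @param blobness a `cp_blobness`.
#' @param volume the `cp_volume` the map was computed from; required for
#'   the gray-level refinement.
#' @param threshold blobness cutoff in (0, 1).
#' @param diameter_range_um inclusive equivalent-diameter range (um).
#' @return A `cp_labelmap` of detected somata.
#' @export
detect_purkinje <- function(blobness, volume, threshold = 0.5,
                            diameter_range_um = c(12, 30)) {
  stopifnot(inherits(blobness, "cp_blobness"),
            inherits(volume, "cp_volume"))
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)")
  h <- blobness$voxel_size_um
  dims <- dim(blobness$blobness)
  mask <- blobness$blobness > threshold
  lab <- label_components_cpp(mask, dims, 26L)
  nl <- max(lab)
  out <- array(0L, dims)
  if (nl == 0) return(cp_labelmap(out, h))
  # one candidate per component: its blobness peak
  peaks <- lapply(seq_len(nl), function(id) {
    sel <- which(lab == id)
    sel[which.max(blobness$blobness[sel])]
  })
  peak_b <- vapply(seq_len(nl), function(id)
    blobness$blobness[peaks[[id]]], numeric(1))
  half <- as.integer(ceiling(0.65 * diameter_range_um[2] / h)) + 3L
  next_label <- 0L
  for (id in order(-peak_b)) {
    p <- peaks[[id]] - 1L
    pi1 <- p %% dims[1] + 1L
    pj <- (p %/% dims[1]) %% dims[2] + 1L
    pk <- p %/% (dims[1] * dims[2]) + 1L
    i1 <- max(1L, pi1 - half); i2 <- min(dims[1], pi1 + half)
    j1 <- max(1L, pj - half); j2 <- min(dims[2], pj + half)
    k1 <- max(1L, pk - half); k2 <- min(dims[3], pk + half)
    crop <- volume$voxels[i1:i2, j1:j2, k1:k2, drop = FALSE]
    dc <- c(i2 - i1 + 1L, j2 - j1 + 1L, k2 - k1 + 1L)
    dim(crop) <- dc
    rng <- range(crop)
    if (diff(rng) <= 0) next
    # local threshold halfway between the soma gray (at the blobness peak)
    # and the background (crop median); robust to the layered background
    # being bimodal itself (molecular vs granular gray)
    g_peak <- volume$voxels[pi1, pj, pk]
    g_bg <- stats::median(crop)
    if (g_peak <= g_bg) next
    thr_g <- (g_peak + g_bg) / 2
    sub <- label_components_cpp(crop > thr_g, dc, 26L)
    own <- sub[pi1 - i1 + 1L, pj - j1 + 1L, pk - k1 + 1L]
    if (own == 0L) next
    sel <- which(sub == own)
    d_eq <- 2 * (3 * length(sel) * h^3 / (4 * pi))^(1 / 3)
    if (d_eq < diameter_range_um[1] || d_eq > diameter_range_um[2]) next
    # map crop-local indices back to the full grid, skip claimed voxels
    si <- (sel - 1L) %% dc[1] + i1
    sj <- ((sel - 1L) %/% dc[1]) %% dc[2] + j1
    sk <- (sel - 1L) %/% (dc[1] * dc[2]) + k1
    lin <- si + as.numeric(dims[1]) * (sj - 1) +
      as.numeric(dims[1]) * dims[2] * (sk - 1)
    free <- out[lin] == 0L
    if (!any(free)) next
    next_label <- next_label + 1L
    out[lin[free]] <- next_label
  }
  cp_labelmap(out, h)
}
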