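#' Build the cylindrical volume-of-interest mask from seeds
#'
#' Each seed defines a cylinder: voxels whose in-plane voxel-center
#' distance to the seed center is at most the seed radius, on coronal
#' slices within the seed's slice range. Overlapping cylinders union.
#' Cylinders are clipped to the grid; a seed entirely outside the grid is
#' skipped with a warning.
#'
#' @param seeds data.frame of seeds (see [read_seed_rois()]).
#' @param volume a `cp_volume`.
#' @return Object of class `cp_voimask`: `mask` (logical array),
#'   `provenance` (integer array, the first seed covering each voxel, 0
#'   outside), `seeds`, `voxel_size_um`.
#' @export
build_voi_mask <- function(seeds, volume) {
  stopifnot(inherits(volume, "cp_volume"))
  dims <- dim(volume$voxels)
  h <- volume$voxel_size_um
  mask <- array(FALSE, dims)
  prov <- array(0L, dims)
  if (nrow(seeds) > 0) for (s in seq_len(nrow(seeds))) {
    cx <- seeds$cx[s]; cy <- seeds$cy[s]
    r_vox <- seeds$radius_um[s] / h
    k1 <- max(1L, as.integer(seeds$z_start[s]))
    k2 <- min(dims[3], as.integer(seeds$z_end[s]))
    i1 <- max(1L, as.integer(ceiling(cx - r_vox)))
    i2 <- min(dims[1], as.integer(floor(cx + r_vox)))
    j1 <- max(1L, as.integer(ceiling(cy - r_vox)))
    j2 <- min(dims[2], as.integer(floor(cy + r_vox)))
    if (k1 > k2 || i1 > i2 || j1 > j2) {
      warning(sprintf("seed %d lies outside the grid; skipped", s))
      next
    }
    disc <- outer((i1:i2 - cx)^2, (j1:j2 - cy)^2, "+") <= r_vox^2
    for (k in k1:k2) {
      sub <- mask[i1:i2, j1:j2, k]
      psub <- prov[i1:i2, j1:j2, k]
      psub[disc & psub == 0L] <- s
      mask[i1:i2, j1:j2, k] <- sub | disc
      prov[i1:i2, j1:j2, k] <- psub
    }
  }
  structure(list(mask = mask, provenance = prov, seeds = seeds,
                 voxel_size_um = h),
            class = "cp_voimask")
}

# moving-average smoothing with edge renormalization
.smooth_counts <- function(counts, width) {
  if (width <= 1) return(counts)
  n <- length(counts)
  half <- floor(width / 2)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    out[i] <- mean(counts[lo:hi])
  }
  out
}

# peak prominence on a 1D profile; returns data.frame(index, height, prom)
.find_peaks <- function(y) {
  n <- length(y)
  # local maxima with plateau handling (plateau represented by its midpoint)
  is_peak <- logical(n)
  for (i in seq_len(n)) {
    left <- if (i == 1) -Inf else y[i - 1]
    right <- if (i == n) -Inf else y[i + 1]
    if (y[i] > left && y[i] >= right) {
      # extend over a plateau to its end; peak iff the plateau drops after
      j <- i
      while (j < n && y[j + 1] == y[i]) j <- j + 1
      if (j == n || y[j + 1] < y[i]) is_peak[floor((i + j) / 2)] <- TRUE
    }
  }
  idx <- which(is_peak)
  if (length(idx) == 0)
    return(data.frame(index = integer(), height = numeric(),
                      prom = numeric()))
  prom <- vapply(idx, function(p) {
    # walk left and right to the first strictly higher sample; the base on
    # each side is the path minimum. A side with no higher sample does not
    # constrain the prominence; a peak with no higher sample on either
    # side is keyed to the global minimum along both paths.
    i <- p; lmin <- Inf; higher_l <- FALSE
    while (i > 1) {
      i <- i - 1
      if (y[i] > y[p]) { higher_l <- TRUE; break }
      lmin <- min(lmin, y[i])
    }
    i <- p; rmin <- Inf; higher_r <- FALSE
    while (i < n) {
      i <- i + 1
      if (y[i] > y[p]) { higher_r <- TRUE; break }
      rmin <- min(rmin, y[i])
    }
    base <- if (higher_l && higher_r) max(lmin, rmin)
    else if (higher_l) lmin
    else if (higher_r) rmin
    else min(lmin, rmin)
    y[p] - base
  }, numeric(1))
  data.frame(index = idx, height = y[idx], prom = prom)
}

# Otsu threshold from histogram counts and bin centers; plateaus of equal
# between-class variance resolve to their midpoint
.otsu_from_hist <- function(counts, centers) {
  w <- counts / sum(counts)
  mu_total <- sum(w * centers)
  nb <- length(counts)
  sb <- rep(-Inf, nb - 1)
  w0 <- 0; mu0w <- 0
  for (t in seq_len(nb - 1)) {
    w0 <- w0 + w[t]
    mu0w <- mu0w + w[t] * centers[t]
    w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    mu0 <- mu0w / w0
    mu1 <- (mu_total - mu0w) / w1
    sb[t] <- w0 * w1 * (mu0 - mu1)^2
  }
  best <- which(sb >= max(sb) - 1e-12 * max(abs(sb), 1))
  t_mid <- (min(best) + max(best)) / 2
  lo <- floor(t_mid); hi <- ceiling(t_mid)
  ((centers[lo] + centers[lo + 1]) / 2 + (centers[hi] + centers[hi + 1]) / 2) / 2
}

#' Bimodal threshold from the pooled VOI gray histogram
#'
#' Pools the gray values of all voxels inside the VOI mask, histograms them
#' (256 bins over the VOI gray range), smooths the counts by a moving
#' average, and finds histogram peaks by prominence. When at least two
#' peaks survive the prominence filter, the two most prominent are assigned
#' to tissue background and plaque, and the threshold is the gray value of
#' the count minimum between them (midpoint of the minimal plateau on
#' ties). Otherwise Otsu's threshold on the pooled histogram is used and
#' flagged as a fallback.
#'
#' @param volume a `cp_volume`.
#' @param voi a `cp_voimask` (nonempty).
#' @param bins number of histogram bins.
#' @param smooth_bins moving-average width in bins.
#' @param prominence_frac minimum peak prominence as a fraction of the
#'   maximum smoothed count.
#' @return Object of class `cp_threshold`: `threshold`, `peaks_gray`
#'   (background, plaque; `NA` on fallback), `bimodal` (logical), `method`,
#'   `breaks`, `counts`, `smoothed`.
#' @export
find_bimodal_threshold <- function(volume, voi, bins = 256L,
                                   smooth_bins = 5L,
                                   prominence_frac = 0.01) {
  stopifnot(inherits(volume, "cp_volume"), inherits(voi, "cp_voimask"))
  vals <- volume$voxels[voi$mask]
  if (length(vals) == 0) stop("VOI mask is empty")
  rng <- range(vals)
  if (rng[1] == rng[2])
    stop("VOI gray values are constant; no contrast to threshold")
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  bin <- findInterval(vals, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(bin, nbins = bins)
  sm <- .smooth_counts(counts, smooth_bins)
  pk <- .find_peaks(sm)
  pk <- pk[pk$prom >= prominence_frac * max(sm), , drop = FALSE]
  if (nrow(pk) >= 2) {
    top2 <- pk[order(-pk$prom)[1:2], ]
    b1 <- min(top2$index); b2 <- max(top2$index)
    valley <- sm[(b1 + 1):(b2 - 1)]
    if (length(valley) == 0) {
      thr <- (centers[b1] + centers[b2]) / 2
    } else {
      vmin <- min(valley)
      at <- which(valley == vmin) + b1
      mid <- (min(at) + max(at)) / 2
      thr <- if (mid == floor(mid)) centers[mid] else
        (centers[floor(mid)] + centers[ceiling(mid)]) / 2
    }
    res <- list(threshold = thr,
                peaks_gray = c(background = centers[b1],
                               plaque = centers[b2]),
                bimodal = TRUE, method = "valley")
  } else {
    res <- list(threshold = .otsu_from_hist(counts, centers),
                peaks_gray = c(background = NA_real_, plaque = NA_real_),
                bimodal = FALSE, method = "otsu_fallback")
  }
  res$breaks <- breaks
  res$counts <- counts
  res$smoothed <- sm
  class(res) <- "cp_threshold"
  res
}

#' @export
print.cp_threshold <- function(x, ...) {
  cat(sprintf("<cp_threshold> %s: threshold %.4g (bimodal: %s)\n",
              x$method, x$threshold, x$bimodal))
  if (x$bimodal)
    cat(sprintf("  peaks: background %.4g, plaque %.4g\n",
                x$peaks_gray[1], x$peaks_gray[2]))
  invisible(x)
}

#' Extract plaque components above a gray threshold
#'
#' Foreground is every VOI voxel with gray strictly above the threshold.
#' Foreground components (26-connected by default) whose physical volume is
#' at most `min_volume_um3` are removed — the default 150 um^3 cutoff
#' excludes small structures not compatible with plaques. Surviving
#' components are renumbered contiguously from 1 in order of decreasing
#' volume.
#'
#' @param volume a `cp_volume`.
#' @param voi a `cp_voimask`.
#' @param threshold gray threshold (foreground is `> threshold`).
#' @param min_volume_um3 minimum retained physical volume (strict `>`).
#' @param connectivity 26 (default) or 6.
#' @return A `cp_labelmap` of retained plaque components.
#' @export
extract_plaques <- function(volume, voi, threshold, min_volume_um3 = 150,
                            connectivity = 26L) {
  stopifnot(inherits(volume, "cp_volume"), inherits(voi, "cp_voimask"))
  if (!connectivity %in% c(6L, 26L))
    stop("connectivity must be 6 or 26")
  dims <- dim(volume$voxels)
  h <- volume$voxel_size_um
  fg <- voi$mask & (volume$voxels > threshold)
  lab <- label_components_cpp(fg, dims, as.integer(connectivity))
  nl <- max(lab)
  if (nl == 0) return(cp_labelmap(array(0L, dims), h))
  sizes <- tabulate(lab[lab > 0], nbins = nl)
  keep <- which(sizes * h^3 > min_volume_um3)
  remap <- integer(nl)
  remap[keep[order(-sizes[keep])]] <- seq_along(keep)
  out <- array(0L, dims)
  nz <- lab > 0
  out[nz] <- remap[lab[nz]]
  cp_labelmap(out, h)
}
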