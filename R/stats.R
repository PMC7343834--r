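#' Summary statistics of a scalar sample
#'
#' Mean, sample standard deviation (n-1 denominator), adjusted
#' Fisher-Pearson skewness, and linear-interpolation quantiles (including
#' the median and 90th percentile). With fewer than three values or zero
#' spread the skewness is reported as 0 and flagged.
#'
#' @param values numeric vector, length >= 1.
#' @return List of class `cp_summary`: `n`, `mean`, `std`, `skewness`,
#'   `skewness_flag`, `quantiles`.
#' @export
summarize_values <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0) stop("cannot summarize an empty sample")
  if (any(!is.finite(values))) stop("values must be finite")
  n <- length(values)
  m <- mean(values)
  s <- if (n > 1) sd(values) else 0
  flag <- FALSE
  if (n >= 3 && s > 0) {
    sk <- e1071::skewness(values, type = 2)
  } else {
    sk <- 0
    flag <- TRUE
  }
  q <- quantile(values, probs = c(0.05, 0.1, 0.25, 0.5, 0.75, 0.9, 0.95),
                type = 7, names = TRUE)
  structure(list(n = n, mean = m, std = s, skewness = sk,
                 skewness_flag = flag, quantiles = q),
            class = "cp_summary")
}

#' @export
print.cp_summary <- function(x, ...) {
  cat(sprintf("<cp_summary> n=%d mean=%.4g std=%.4g skewness=%.4g%s\n",
              x$n, x$mean, x$std, x$skewness,
              if (x$skewness_flag) " (flagged)" else ""))
  print(round(x$quantiles, 4))
  invisible(x)
}

#' Select elongated objects for orientation analysis
#'
#' Keeps records with sphericity strictly below `mean + std` of the
#' sphericity distribution. Near-spherical objects are excluded because
#' their principal axis is poorly defined. Input order is preserved.
#'
#' @param records data.frame with a `sphericity` column.
#' @param summary a `cp_summary` computed from the same records'
#'   sphericities.
#' @return The subset of `records`.
#' @export
select_elongated <- function(records, summary) {
  stopifnot(inherits(summary, "cp_summary"))
  records[records$sphericity < summary$mean + summary$std, , drop = FALSE]
}

#' Log-normality check of a volume sample
#'
#' Compares the log-volumes with the Gaussian having the same mean and
#' standard deviation (moment matching, not a fitted MLE) via the
#' Kolmogorov-Smirnov statistic, and returns the area-normalized histogram
#' pair underlying the visual overlay.
#'
#' @param volumes_um3 positive volumes, n >= 10.
#' @param bins histogram bin count for the overlay.
#' @return List of class `cp_lognormal`: `log_mean`, `log_sd`, `ks_stat`,
#'   `hist` (data.frame: `mid`, `density`, `ref_density`).
#' @export
lognormal_check <- function(volumes_um3, bins = 20L) {
  volumes_um3 <- as.numeric(volumes_um3)
  if (any(!is.finite(volumes_um3)) || any(volumes_um3 <= 0))
    stop("volumes must be positive and finite")
  if (length(volumes_um3) < 10) stop("need at least 10 volumes")
  lv <- log(volumes_um3)
  m <- mean(lv)
  s <- sd(lv)
  if (s == 0) stop("degenerate sample: all volumes equal")
  ks <- as.numeric(suppressWarnings(
    ks.test(lv, "pnorm", mean = m, sd = s))$statistic)
  br <- seq(min(lv), max(lv), length.out = bins + 1L)
  hh <- hist(lv, breaks = br, plot = FALSE)
  structure(list(
    log_mean = m, log_sd = s, ks_stat = ks,
    hist = data.frame(mid = hh$mids, density = hh$density,
                      ref_density = dnorm(hh$mids, m, s))
  ), class = "cp_lognormal")
}

# Mann-Whitney U with midrank tie handling
.u_statistic <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Two-group comparison (Mann-Whitney U)
#'
#' Two-sided rank-sum comparison. For small samples (both n <= 8) the
#' p-value is computed by exact enumeration of all group assignments of the
#' pooled values (tie-aware, hence deterministic); otherwise the
#' tie-corrected normal approximation of `wilcox.test` is used.
#'
#' @param a,b numeric vectors, each n >= 3.
#' @return List: `statistic` (U for group `a`), `p_value`, `method`.
#' @export
compare_groups <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 3 || length(b) < 3)
    stop("each group needs at least 3 values")
  u_obs <- .u_statistic(a, b)
  na <- length(a); nb <- length(b)
  if (na <= 8 && nb <= 8) {
    pool <- c(a, b)
    combos <- utils::combn(na + nb, na)
    mid <- na * nb / 2
    dev_obs <- abs(u_obs - mid)
    devs <- apply(combos, 2, function(sel)
      abs(.u_statistic(pool[sel], pool[-sel]) - mid))
    p <- mean(devs >= dev_obs - 1e-12)
    list(statistic = u_obs, p_value = p, method = "exact enumeration")
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))
    list(statistic = u_obs, p_value = wt$p.value,
         method = "normal approximation")
  }
}

# plane normals in the anatomical frame
.plane_normal <- function(plane) {
  switch(plane,
         coronal = c(0, 0, 1),     # spanned by DV and ML
         sagittal = c(0, 1, 0),    # spanned by DV and AP
         transverse = c(1, 0, 0),  # spanned by ML and AP
         stop("unknown plane: ", plane))
}

#' Orientation statistics of undirected axes, per region
#'
#' Axes are undirected (a and -a are the same orientation), so the mean
#' axis is the principal eigenvector of the orientation tensor
#' T = mean(a a^T). Angular deviations are arccos|a . mean|; "cone
#' semi-angles" are their 50th and 90th percentiles, overall and after
#' projecting the axes into two named coordinate planes. The
#' azimuth-elevation histogram counts each axis at both antipodal angle
#' representations, reproducing the paired clusters seen when plotting
#' sign-ambiguous axes.
#'
#' @param records data.frame with axis columns `ax, ay, az`, a `tie_flag`
#'   column, and the grouping column.
#' @param group_by name of the region column (default "region").
#' @param planes two plane names among "coronal", "sagittal", "transverse"
#'   for the plane-resolved deviations.
#' @param hist_bin_deg bin width (degrees) of the 2D histogram.
#' @return Named list (one entry per region) of class `cp_orientation`
#'   elements: `n`, `mean_axis`, `p50_deg`, `p90_deg`, `plane_deviation`
#'   (per plane: `p50_deg`, `p90_deg`), `hist` (list: `azimuth_breaks`,
#'   `elevation_breaks`, `counts`).
#' @export
orientation_summary <- function(records, group_by = "region",
                                planes = c("transverse", "coronal"),
                                hist_bin_deg = 10) {
  stopifnot(group_by %in% names(records))
  ok <- !records$tie_flag & is.finite(records$ax)
  records <- records[ok, , drop = FALSE]
  groups <- split(records, records[[group_by]])
  out <- list()
  for (gname in names(groups)) {
    g <- groups[[gname]]
    if (nrow(g) == 0) {
      warning("empty region group '", gname, "' skipped")
      next
    }
    A <- as.matrix(g[, c("ax", "ay", "az")])
    A <- A / sqrt(rowSums(A^2))
    tens <- crossprod(A) / nrow(A)
    e <- eigen(tens, symmetric = TRUE)
    mean_axis <- e$vectors[, 1]
    k <- which.max(abs(mean_axis))
    if (mean_axis[k] < 0) mean_axis <- -mean_axis
    dev <- acos(pmin(1, abs(A %*% mean_axis))) * 180 / pi
    qd <- quantile(dev, c(0.5, 0.9), type = 7)
    plane_dev <- lapply(planes, function(pl) {
      nrm <- .plane_normal(pl)
      proj <- A - outer(as.numeric(A %*% nrm), nrm)
      pm <- mean_axis - sum(mean_axis * nrm) * nrm
      keep <- sqrt(rowSums(proj^2)) > 1e-9
      if (sum(pm^2) < 1e-18 || !any(keep))
        return(list(p50_deg = NA_real_, p90_deg = NA_real_))
      proj <- proj[keep, , drop = FALSE] / sqrt(rowSums(
        proj[keep, , drop = FALSE]^2))
      pm <- pm / sqrt(sum(pm^2))
      pd <- acos(pmin(1, abs(proj %*% pm))) * 180 / pi
      qq <- quantile(pd, c(0.5, 0.9), type = 7)
      list(p50_deg = as.numeric(qq[1]), p90_deg = as.numeric(qq[2]))
    })
    names(plane_dev) <- planes
    # antipodally doubled azimuth-elevation histogram
    az_br <- seq(-180, 180, by = hist_bin_deg)
    el_br <- seq(-90, 90, by = hist_bin_deg)
    cnt <- matrix(0L, length(az_br) - 1L, length(el_br) - 1L)
    for (sgn in c(1, -1)) {
      for (i in seq_len(nrow(A))) {
        ang <- axis_to_angles(sgn * A[i, ])
        ia <- findInterval(ang[1], az_br, rightmost.closed = TRUE,
                           all.inside = TRUE)
        ie <- findInterval(ang[2], el_br, rightmost.closed = TRUE,
                           all.inside = TRUE)
        cnt[ia, ie] <- cnt[ia, ie] + 1L
      }
    }
    out[[gname]] <- structure(
      list(n = nrow(g), mean_axis = as.numeric(mean_axis),
           p50_deg = as.numeric(qd[1]), p90_deg = as.numeric(qd[2]),
           plane_deviation = plane_dev,
           hist = list(azimuth_breaks = az_br, elevation_breaks = el_br,
                       counts = cnt)),
      class = "cp_orientation")
  }
  out
}
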