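# Geometric fixtures and brute-force oracles, all built in code.

# digitized solid ball of radius r (voxel units), centered on the grid
mk_ball <- function(r, pad = 4L) {
  n <- as.integer(2 * r + 2 * pad + 1)
  c0 <- (n + 1) / 2
  g <- seq_len(n)
  X <- array(g, c(n, n, n))
  Y <- array(rep(g, each = n), c(n, n, n))
  Z <- array(rep(g, each = n * n), c(n, n, n))
  (X - c0)^2 + (Y - c0)^2 + (Z - c0)^2 <= r^2
}

# digitized ellipsoid: major semi-axis a along unit vector w, minor b
mk_ellipsoid <- function(a, b, w = c(1, 0, 0), pad = 4L) {
  n <- as.integer(2 * a + 2 * pad + 1)
  c0 <- (n + 1) / 2
  g <- seq_len(n) - c0
  X <- array(g, c(n, n, n))
  Y <- array(rep(g, each = n), c(n, n, n))
  Z <- array(rep(g, each = n * n), c(n, n, n))
  U <- X * w[1] + Y * w[2] + Z * w[3]
  R2 <- X^2 + Y^2 + Z^2 - U^2
  (U / a)^2 + R2 / b^2 <= 1
}

# exact surface area of a prolate spheroid with semi-axes (c >= a = b)
prolate_area <- function(a, c) {
  e <- sqrt(1 - (a / c)^2)
  2 * pi * a^2 * (1 + (c / (a * e)) * asin(e))
}

# brute-force 3D connected-component labeling (BFS), reference oracle
brute_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  lab <- array(0L, d)
  offs <- expand.grid(a = -1:1, b = -1:1, c = -1:1)
  offs <- offs[!(offs$a == 0 & offs$b == 0 & offs$c == 0), ]
  if (connectivity == 6L)
    offs <- offs[abs(offs$a) + abs(offs$b) + abs(offs$c) == 1, ]
  nxt <- 0L
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!mask[i, j, k] || lab[i, j, k] != 0L) next
    nxt <- nxt + 1L
    queue <- matrix(c(i, j, k), 1, 3)
    lab[i, j, k] <- nxt
    while (nrow(queue) > 0) {
      p <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (t in seq_len(nrow(offs))) {
        q <- p + as.integer(offs[t, ])
        if (any(q < 1) || any(q > d)) next
        if (mask[q[1], q[2], q[3]] && lab[q[1], q[2], q[3]] == 0L) {
          lab[q[1], q[2], q[3]] <- nxt
          queue <- rbind(queue, q)
        }
      }
    }
  }
  lab
}

# canonical partition signature: list of sorted voxel-index sets per label
partition_sets <- function(lab) {
  ids <- setdiff(unique(as.vector(lab)), 0L)
  sets <- lapply(ids, function(id) sort(which(lab == id)))
  sets[order(vapply(sets, `[`, integer(1), 1))]
}

# brute-force volume / centroid / second central moment of one object
brute_moments <- function(labels_arr, id, h) {
  d <- dim(labels_arr)
  n <- 0L; sx <- c(0, 0, 0)
  pts <- NULL
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1]))
    if (labels_arr[i, j, k] == id) {
      p <- (c(i, j, k) - 0.5) * h
      pts <- rbind(pts, p)
      n <- n + 1L
      sx <- sx + p
    }
  cen <- sx / n
  M <- matrix(0, 3, 3)
  for (r in seq_len(n)) {
    dlt <- pts[r, ] - cen
    M <- M + outer(dlt, dlt)
  }
  list(n = n, volume = n * h^3, centroid = cen, moment = M / n)
}

# compact phantom spec for tests; counts and grid sized for speed
small_phantom_spec <- function(grid = c(160L, 128L, 96L), n_plaque = 20L,
                               n_purkinje = 0L, n_vessel = 0L,
                               noise = 5, seed = 1L, sdlog = 1.25, ...) {
  phantom_spec(
    grid_shape = grid,
    plaque_model = list(count = n_plaque, volume_median_um3 = 1000,
                        volume_sdlog = sdlog, aspect_range = c(1.5, 3.5),
                        corona_gray_offset = 60, core_gray_offset = 100,
                        core_fraction = 0.15),
    purkinje_model = list(count = n_purkinje,
                          diameter_range_um = c(15, 25), gray_offset = 70),
    vessel_model = list(count = n_vessel, radius_range_um = c(2.5, 4),
                        length_um = 80, gray_offset = 60),
    noise_sigma = noise, seed = seed, ...)
}

# volume with smooth analytic objects for blobness tests; obj is a list of
# lists(kind, center (vox), sigma_vox, amplitude, axis)
mk_smooth_volume <- function(n = 64L, objects, h = 1.625) {
  g <- seq_len(n)
  X <- array(g, c(n, n, n))
  Y <- array(rep(g, each = n), c(n, n, n))
  Z <- array(rep(g, each = n * n), c(n, n, n))
  v <- array(0, c(n, n, n))
  for (ob in objects) {
    dx <- X - ob$center[1]; dy <- Y - ob$center[2]; dz <- Z - ob$center[3]
    s2 <- ob$sigma_vox^2
    if (ob$kind == "blob") {
      v <- v + ob$amplitude * exp(-(dx^2 + dy^2 + dz^2) / (2 * s2))
    } else if (ob$kind == "tube") {
      w <- ob$axis / sqrt(sum(ob$axis^2))
      u <- dx * w[1] + dy * w[2] + dz * w[3]
      r2 <- dx^2 + dy^2 + dz^2 - u^2
      v <- v + ob$amplitude * exp(-r2 / (2 * s2))
    } else if (ob$kind == "plate") {
      w <- ob$axis / sqrt(sum(ob$axis^2))
      u <- dx * w[1] + dy * w[2] + dz * w[3]
      v <- v + ob$amplitude * exp(-u^2 / (2 * s2))
    }
  }
  cp_volume(v, h)
}
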