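#' Specification of a synthetic cerebellar phantom
#'
#' Bundles every parameter of the synthetic volume generator. The phantom
#' emulates the contrast structure of a phase-contrast tomogram of
#' cerebellar cortex: three gray-distinct layers (white matter, granular,
#' molecular, with the granular layer brighter than the molecular one) whose
#' interfaces are warped by a single sinusoidal fold; bright prolate plaques
#' (dense core plus fainter corona) confined to the molecular layer with a
#' region-dependent preferred axis; bright spheres at the
#' granular-molecular interface emulating Purkinje somata; tubular vessels
#' running in the coronal plane inside the molecular layer; additive
#' Gaussian noise.
#'
#' Layering runs along grid axis 1 (dorso-ventral): white matter at low
#' indices, then granular, then molecular up to the top of the grid. The
#' default region layout splits the grid along axis 2 (medio-lateral) into a
#' "hemisphere" half whose plaques prefer the dorso-ventral axis with an
#' isotropic 30 degree spread, and a "vermis" half whose plaques prefer the
#' medio-lateral axis with an anisotropic spread (60 degrees towards
#' anterior-posterior, i.e. within the transverse plane, and 30 degrees
#' towards dorso-ventral, i.e. within the coronal plane).
#'
#' @param grid_shape integer triple, voxels per axis.
#' @param voxel_size_um isotropic voxel size (um).
#' @param layer_model list with `means` (named gray means for `white`,
#'   `granular`, `molecular`) and `thickness_um` (named physical thicknesses
#'   for `white` and `granular`; the molecular layer takes the remainder).
#' @param fold_amplitude_um,fold_period_um sinusoidal displacement of the
#'   layer interfaces along the medio-lateral axis.
#' @param regions list of region definitions; each has `name`,
#'   `axis2_range` (1-based voxel index range on the medio-lateral axis),
#'   `preferred_axis` (unit vector), `spread_deg` (one angle for an
#'   isotropic cone, or two angles paired with `tangent1`/`tangent2`
#'   directions for an anisotropic cone).
#' @param plaque_model list: `count`, `volume_median_um3`, `volume_sdlog`
#'   (log-normal true volumes), `aspect_range` (prolate long/short ratio,
#'   uniform), `corona_gray_offset`, `core_gray_offset`, `core_fraction`
#'   (core / total volume).
#' @param purkinje_model list: `count`, `diameter_range_um`, `gray_offset`.
#' @param vessel_model list: `count`, `radius_range_um`, `length_um`,
#'   `gray_offset`.
#' @param noise_sigma additive Gaussian noise standard deviation.
#' @param seed integer RNG seed; the generator is fully deterministic given
#'   the spec.
#' @return A validated list of class `phantom_spec`.
#' @export
phantom_spec <- function(
    grid_shape = c(256L, 256L, 256L),
    voxel_size_um = 1.625,
    layer_model = list(
      means = c(white = 85, granular = 120, molecular = 100),
      thickness_um = c(white = 100, granular = 65)
    ),
    fold_amplitude_um = 20,
    fold_period_um = 300,
    regions = NULL,
    plaque_model = list(
      count = 120L, volume_median_um3 = 1000, volume_sdlog = 1.25,
      aspect_range = c(1.5, 3.5), corona_gray_offset = 60,
      core_gray_offset = 100, core_fraction = 0.15
    ),
    purkinje_model = list(
      count = 60L, diameter_range_um = c(15, 25), gray_offset = 70
    ),
    vessel_model = list(
      count = 8L, radius_range_um = c(2.5, 4), length_um = 100,
      gray_offset = 60
    ),
    noise_sigma = 5,
    seed = 1L) {
  if (is.null(regions)) {
    half <- floor(grid_shape[2] / 2)
    regions <- list(
      list(name = "hemisphere", axis2_range = c(1L, half),
           preferred_axis = c(1, 0, 0), spread_deg = 30),
      list(name = "vermis", axis2_range = c(half + 1L, grid_shape[2]),
           preferred_axis = c(0, 1, 0), spread_deg = c(60, 30),
           tangent1 = c(0, 0, 1), tangent2 = c(1, 0, 0))
    )
  }
  spec <- list(
    grid_shape = as.integer(grid_shape), voxel_size_um = voxel_size_um,
    layer_model = layer_model, fold_amplitude_um = fold_amplitude_um,
    fold_period_um = fold_period_um, regions = regions,
    plaque_model = plaque_model, purkinje_model = purkinje_model,
    vessel_model = vessel_model, noise_sigma = noise_sigma,
    seed = as.integer(seed)
  )
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

#' @rdname phantom_spec
#' @param spec a `phantom_spec`.
#' @export
validate_phantom_spec <- function(spec) {
  stopifnot(length(spec$grid_shape) == 3L)
  if (any(spec$grid_shape < 1L)) stop("grid_shape extents must be >= 1")
  if (spec$voxel_size_um <= 0) stop("voxel_size_um must be > 0")
  lm <- spec$layer_model
  if (!(lm$means[["granular"]] > lm$means[["molecular"]]))
    stop("granular gray mean must exceed molecular gray mean")
  if (!(lm$means[["molecular"]] > lm$means[["white"]]))
    stop("molecular gray mean must exceed white-matter gray mean")
  h <- spec$voxel_size_um
  depth_um <- spec$grid_shape[1] * h
  need <- sum(lm$thickness_um) + 2 * spec$fold_amplitude_um + 10 * h
  if (depth_um <= need)
    stop(sprintf(paste0("grid too small for the layer model: depth %.0f um ",
                        "but layers plus folding need > %.0f um"),
                 depth_um, need))
  pm <- spec$plaque_model
  if (pm$count < 0 || spec$purkinje_model$count < 0 ||
      spec$vessel_model$count < 0)
    stop("object counts must be >= 0")
  if (any(pm$aspect_range < 1)) stop("aspect ratio must be >= 1")
  for (r in spec$regions) {
    if (any(r$spread_deg < 0) || any(r$spread_deg > 90))
      stop("angular spread must lie in [0, 90] degrees")
  }
  if (spec$noise_sigma < 0) stop("noise_sigma must be >= 0")
  invisible(spec)
}

# orthonormal complement of a unit vector
.orthobasis <- function(w) {
  w <- w / sqrt(sum(w^2))
  a <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * w) * w
  u <- u / sqrt(sum(u^2))
  v <- c(w[2] * u[3] - w[3] * u[2],
         w[3] * u[1] - w[1] * u[3],
         w[1] * u[2] - w[2] * u[1])
  list(u = u, v = v, w = w)
}

# draw one unit axis within the (possibly anisotropic) spread of a region
.draw_axis <- function(region) {
  p <- region$preferred_axis / sqrt(sum(region$preferred_axis^2))
  s <- region$spread_deg
  if (length(s) == 1) {
    if (s <= 0) return(p)
    # uniform over the spherical cap of semi-angle s
    cosd <- runif(1, cos(s * pi / 180), 1)
    d <- acos(cosd)
    phi <- runif(1, 0, 2 * pi)
    b <- .orthobasis(p)
    t1 <- b$u; t2 <- b$v
    th1 <- d * cos(phi); th2 <- d * sin(phi)
  } else {
    # uniform over an elliptical cone: uniform in the unit disk scaled by
    # the two tangent-plane spreads
    repeat {
      x <- runif(2, -1, 1)
      if (sum(x^2) <= 1) break
    }
    t1 <- region$tangent1; t2 <- region$tangent2
    th1 <- x[1] * s[1] * pi / 180
    th2 <- x[2] * s[2] * pi / 180
  }
  d <- sqrt(th1^2 + th2^2)
  if (d == 0) return(p)
  tang <- (th1 * t1 + th2 * t2) / d
  a <- cos(d) * p + sin(d) * tang
  a / sqrt(sum(a^2))
}

# voxel indices (n x 3, 1-based) whose centers lie inside an ellipsoid
# with minor semi-axes a (x2) and major semi-axis c along unit vector w
.ellipsoid_voxels <- function(center_um, a_um, c_um, w, h, dims) {
  half <- max(a_um, c_um)
  lo <- pmax(1L, floor((center_um - half) / h - 0.5) + 1L)
  hi <- pmin(dims, ceiling((center_um + half) / h + 0.5))
  if (any(lo > hi)) return(matrix(integer(), 0, 3))
  gi <- lo[1]:hi[1]; gj <- lo[2]:hi[2]; gk <- lo[3]:hi[3]
  px <- .voxel_center_um(gi, h) - center_um[1]
  py <- .voxel_center_um(gj, h) - center_um[2]
  pz <- .voxel_center_um(gk, h) - center_um[3]
  nx <- length(px); ny <- length(py); nz <- length(pz)
  X <- array(px, c(nx, ny, nz))
  Y <- array(rep(py, each = nx), c(nx, ny, nz))
  Z <- array(rep(pz, each = nx * ny), c(nx, ny, nz))
  U <- X * w[1] + Y * w[2] + Z * w[3]
  R2 <- X^2 + Y^2 + Z^2 - U^2
  inside <- (U / c_um)^2 + R2 / a_um^2 <= 1
  idx <- which(inside, arr.ind = TRUE)
  if (nrow(idx) == 0) return(matrix(integer(), 0, 3))
  cbind(gi[idx[, 1]], gj[idx[, 2]], gk[idx[, 3]])
}

# voxel indices inside a finite cylinder (radius r, half-length L/2 along w)
.tube_voxels <- function(center_um, r_um, len_um, w, h, dims) {
  half <- sqrt(r_um^2 + (len_um / 2)^2)
  lo <- pmax(1L, floor((center_um - half) / h - 0.5) + 1L)
  hi <- pmin(dims, ceiling((center_um + half) / h + 0.5))
  if (any(lo > hi)) return(matrix(integer(), 0, 3))
  gi <- lo[1]:hi[1]; gj <- lo[2]:hi[2]; gk <- lo[3]:hi[3]
  px <- .voxel_center_um(gi, h) - center_um[1]
  py <- .voxel_center_um(gj, h) - center_um[2]
  pz <- .voxel_center_um(gk, h) - center_um[3]
  nx <- length(px); ny <- length(py); nz <- length(pz)
  X <- array(px, c(nx, ny, nz))
  Y <- array(rep(py, each = nx), c(nx, ny, nz))
  Z <- array(rep(pz, each = nx * ny), c(nx, ny, nz))
  U <- X * w[1] + Y * w[2] + Z * w[3]
  R2 <- X^2 + Y^2 + Z^2 - U^2
  inside <- abs(U) <= len_um / 2 & R2 <= r_um^2
  idx <- which(inside, arr.ind = TRUE)
  if (nrow(idx) == 0) return(matrix(integer(), 0, 3))
  cbind(gi[idx[, 1]], gj[idx[, 2]], gk[idx[, 3]])
}

.lin_index <- function(idx, dims) {
  idx[, 1] + as.numeric(dims[1]) * (idx[, 2] - 1) +
    as.numeric(dims[1]) * dims[2] * (idx[, 3] - 1)
}

#' Generate a seeded synthetic phantom volume with ground truth
#'
#' Renders the layered background, then places plaques, Purkinje spheres and
#' vessels by rejection sampling (objects may not overlap; up to 200 retries
#' per object, then a placement error naming the object class), and finally
#' adds Gaussian noise. Plaques are fully contained in the molecular layer
#' with a small clearance from the layer boundaries; Purkinje centers sit on
#' the granular-molecular interface; vessels run in the coronal plane inside
#' the molecular layer.
#'
#' @param spec a [phantom_spec()].
#' @return List with `volume` (a `cp_volume`) and `truth`, a ground-truth
#'   bundle holding `plaque_labels`, `purkinje_labels`, `vessel_labels`
#'   (each a `cp_labelmap`), `layer_map` (integer array: 1 white, 2
#'   granular, 3 molecular) and `records` (one row per object with true
#'   centroid, semi-axes, axis, region and analytic volume).
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  dims <- spec$grid_shape
  h <- spec$voxel_size_um
  lm <- spec$layer_model

  # layer geometry: interfaces displaced by a sinusoid along axis 2
  disp_vox <- (spec$fold_amplitude_um / h) *
    sin(2 * pi * .voxel_center_um(seq_len(dims[2]), h) /
          spec$fold_period_um)
  wb <- lm$thickness_um[["white"]] / h
  gb <- wb + lm$thickness_um[["granular"]] / h
  i_eff <- outer(seq_len(dims[1]), disp_vox, "-")  # dims[1] x dims[2]
  layer_plane <- matrix(3L, dims[1], dims[2])
  layer_plane[i_eff <= gb] <- 2L
  layer_plane[i_eff <= wb] <- 1L
  layer_map <- array(layer_plane, dims)  # constant along axis 3

  means <- c(lm$means[["white"]], lm$means[["granular"]],
             lm$means[["molecular"]])
  vox <- array(means[layer_map], dims)

  occ <- array(FALSE, dims)
  plaque_lab <- array(0L, dims)
  purk_lab <- array(0L, dims)
  vessel_lab <- array(0L, dims)

  region_of_j <- function(j) {
    for (r in spec$regions)
      if (j >= r$axis2_range[1] && j <= r$axis2_range[2]) return(r)
    spec$regions[[1]]
  }
  interface_i <- function(j) gb + disp_vox[j]  # in voxel units
  mol_top <- dims[1]

  records <- list()
  mol_mean <- lm$means[["molecular"]]

  extent_um <- dims * h
  aabb_ok <- function(cen, half) {
    all(cen - half >= 0) && all(cen + half <= extent_um)
  }

  place_object <- function(class_name, try_one) {
    for (attempt in seq_len(200)) {
      res <- try_one()
      if (!is.null(res)) return(res)
    }
    stop(sprintf("could not place a %s without overlap after 200 retries",
                 class_name))
  }

  # ---- plaques -------------------------------------------------------
  pm <- spec$plaque_model
  margin <- 1.5 * h  # clearance kept between objects and layer boundaries
  if (pm$count > 0) {
    for (n in seq_len(pm$count)) {
      v_true <- rlnorm(1, meanlog = log(pm$volume_median_um3),
                       sdlog = pm$volume_sdlog)
      ar <- runif(1, pm$aspect_range[1], pm$aspect_range[2])
      a_um <- (3 * v_true / (4 * pi * ar))^(1 / 3)
      c_um <- a_um * ar
      placed <- place_object("plaque", function() {
        j <- sample.int(dims[2], 1)
        k <- sample.int(dims[3], 1)
        reg <- region_of_j(j)
        w <- .draw_axis(reg)
        # dorso-ventral placement inside the molecular layer with clearance
        lo_i <- interface_i(j) + (c_um + margin) / h + 1
        hi_i <- mol_top - (c_um + margin) / h
        if (lo_i >= hi_i) return(NULL)
        i <- runif(1, lo_i, hi_i)
        cen <- .voxel_center_um(c(i, j, k), h)
        # ellipsoid AABB half-extents: object must lie fully in the grid
        halfext <- sqrt(a_um^2 + (c_um^2 - a_um^2) * w^2) + margin
        if (!aabb_ok(cen, halfext)) return(NULL)
        grown <- .ellipsoid_voxels(cen, a_um + margin, c_um + margin, w,
                                   h, dims)
        if (nrow(grown) == 0) return(NULL)
        lin_g <- .lin_index(grown, dims)
        if (any(layer_map[lin_g] != 3L) || any(occ[lin_g])) return(NULL)
        core <- .ellipsoid_voxels(cen, a_um * pm$core_fraction^(1 / 3),
                                  c_um * pm$core_fraction^(1 / 3), w, h,
                                  dims)
        body <- .ellipsoid_voxels(cen, a_um, c_um, w, h, dims)
        if (nrow(body) == 0) {
          # sub-resolution plaque: keep at least its center voxel
          ci <- pmin(pmax(round(c(i, j, k)), 1L), dims)
          body <- matrix(as.integer(ci), 1, 3)
        }
        list(cen = cen, w = w, body = body, core = core, grown = lin_g,
             region = reg$name)
      })
      lin_b <- .lin_index(placed$body, dims)
      vox[lin_b] <- mol_mean + pm$corona_gray_offset
      if (nrow(placed$core) > 0)
        vox[.lin_index(placed$core, dims)] <- mol_mean + pm$core_gray_offset
      plaque_lab[lin_b] <- n
      occ[placed$grown] <- TRUE
      records[[length(records) + 1]] <- data.frame(
        id = n, class = "plaque", region = placed$region,
        cx_um = placed$cen[1], cy_um = placed$cen[2], cz_um = placed$cen[3],
        a_um = a_um, b_um = a_um, c_um = c_um,
        ax = placed$w[1], ay = placed$w[2], az = placed$w[3],
        volume_um3 = v_true, n_voxels = nrow(placed$body)
      )
    }
  }

  # ---- Purkinje somata ----------------------------------------------
  km <- spec$purkinje_model
  if (km$count > 0) {
    for (n in seq_len(km$count)) {
      r_um <- runif(1, km$diameter_range_um[1], km$diameter_range_um[2]) / 2
      placed <- place_object("purkinje", function() {
        j <- sample.int(dims[2], 1)
        k <- sample.int(dims[3], 1)
        i <- interface_i(j)  # centroid on the granular-molecular interface
        cen <- .voxel_center_um(c(i, j, k), h)
        if (!aabb_ok(cen, rep(r_um + margin, 3))) return(NULL)
        grown <- .ellipsoid_voxels(cen, r_um + margin, r_um + margin,
                                   c(0, 0, 1), h, dims)
        if (nrow(grown) == 0) return(NULL)
        lin_g <- .lin_index(grown, dims)
        if (any(occ[lin_g])) return(NULL)
        body <- .ellipsoid_voxels(cen, r_um, r_um, c(0, 0, 1), h, dims)
        if (nrow(body) == 0) return(NULL)
        list(cen = cen, body = body, grown = lin_g,
             region = region_of_j(j)$name)
      })
      lin_b <- .lin_index(placed$body, dims)
      vox[lin_b] <- mol_mean + km$gray_offset
      purk_lab[lin_b] <- n
      occ[placed$grown] <- TRUE
      records[[length(records) + 1]] <- data.frame(
        id = n, class = "purkinje", region = placed$region,
        cx_um = placed$cen[1], cy_um = placed$cen[2], cz_um = placed$cen[3],
        a_um = r_um, b_um = r_um, c_um = r_um,
        ax = 0, ay = 0, az = 1,
        volume_um3 = 4 / 3 * pi * r_um^3, n_voxels = nrow(placed$body)
      )
    }
  }

  # ---- vessels -------------------------------------------------------
  vm <- spec$vessel_model
  if (vm$count > 0) {
    for (n in seq_len(vm$count)) {
      r_um <- runif(1, vm$radius_range_um[1], vm$radius_range_um[2])
      placed <- place_object("vessel", function() {
        theta <- runif(1, 0, pi)  # direction in the coronal plane
        w <- c(cos(theta), sin(theta), 0)
        j <- sample.int(dims[2], 1)
        k <- sample.int(dims[3], 1)
        lo_i <- interface_i(j) + (vm$length_um / 2 + margin) / h
        hi_i <- dims[1] - (vm$length_um / 2 + margin) / h
        if (lo_i >= hi_i) return(NULL)
        i <- runif(1, lo_i, hi_i)
        cen <- .voxel_center_um(c(i, j, k), h)
        halfext <- (vm$length_um / 2) * abs(w) +
          r_um * sqrt(pmax(0, 1 - w^2)) + margin
        if (!aabb_ok(cen, halfext)) return(NULL)
        grown <- .tube_voxels(cen, r_um + margin, vm$length_um + 2 * margin,
                              w, h, dims)
        if (nrow(grown) == 0) return(NULL)
        lin_g <- .lin_index(grown, dims)
        if (any(layer_map[lin_g] != 3L) || any(occ[lin_g])) return(NULL)
        body <- .tube_voxels(cen, r_um, vm$length_um, w, h, dims)
        if (nrow(body) == 0) return(NULL)
        list(cen = cen, w = w, body = body, grown = lin_g,
             region = region_of_j(j)$name)
      })
      lin_b <- .lin_index(placed$body, dims)
      vox[lin_b] <- mol_mean + vm$gray_offset
      vessel_lab[lin_b] <- n
      occ[placed$grown] <- TRUE
      records[[length(records) + 1]] <- data.frame(
        id = n, class = "vessel", region = placed$region,
        cx_um = placed$cen[1], cy_um = placed$cen[2], cz_um = placed$cen[3],
        a_um = r_um, b_um = r_um, c_um = vm$length_um / 2,
        ax = placed$w[1], ay = placed$w[2], az = placed$w[3],
        volume_um3 = pi * r_um^2 * vm$length_um, n_voxels = nrow(placed$body)
      )
    }
  }

  if (spec$noise_sigma > 0)
    vox <- vox + array(rnorm(prod(dims), 0, spec$noise_sigma), dims)

  rec <- if (length(records)) do.call(rbind, records) else data.frame(
    id = integer(), class = character(), region = character(),
    cx_um = numeric(), cy_um = numeric(), cz_um = numeric(),
    a_um = numeric(), b_um = numeric(), c_um = numeric(),
    ax = numeric(), ay = numeric(), az = numeric(),
    volume_um3 = numeric(), n_voxels = integer()
  )
  truth <- list(
    plaque_labels = cp_labelmap(plaque_lab, h),
    purkinje_labels = cp_labelmap(purk_lab, h),
    vessel_labels = cp_labelmap(vessel_lab, h),
    layer_map = layer_map,
    records = rec,
    spec = spec
  )
  class(truth) <- "phantom_truth"
  list(volume = cp_volume(vox, h), truth = truth)
}

#' Region tag of a physical point under a phantom's region layout
#'
#' @param truth a `phantom_truth` (or a `phantom_spec`).
#' @return A function mapping a centroid `c(cx_um, cy_um, cz_um)` to the
#'   region name, suitable for `measure_objects(region_fun = )`.
#' @export
region_tagger <- function(truth) {
  spec <- if (inherits(truth, "phantom_spec")) truth else truth$spec
  h <- spec$voxel_size_um
  regions <- spec$regions
  function(centroid_um) {
    j <- centroid_um[2] / h + 0.5
    for (r in regions)
      if (j >= r$axis2_range[1] - 0.5 && j <= r$axis2_range[2] + 0.5)
        return(r$name)
    regions[[1]]$name
  }
}

#' Maximum intensity projection over a physical slab
#'
#' Each output pixel is the maximum gray value along the projection axis
#' over `floor(thickness_um / voxel_size_um)` slices (minimum 1), starting
#' at offset `start_um` from the volume origin.
#'
#' @param volume a `cp_volume`.
#' @param axis projection plane: "coronal" (project along
#'   anterior-posterior), "sagittal" (along medio-lateral) or "transverse"
#'   (along dorso-ventral); alternatively the grid axis number 3, 2 or 1.
#' @param thickness_um slab thickness (>= voxel size).
#' @param start_um slab start offset from the origin (default 0).
#' @return 2D matrix of projected maxima over the remaining two axes, in
#'   their grid order.
#' @export
render_mip <- function(volume, axis = "coronal", thickness_um,
                       start_um = 0) {
  stopifnot(inherits(volume, "cp_volume"))
  h <- volume$voxel_size_um
  ax <- if (is.character(axis)) {
    switch(match.arg(axis, c("coronal", "sagittal", "transverse")),
           coronal = 3L, sagittal = 2L, transverse = 1L)
  } else as.integer(axis)
  if (!ax %in% 1:3) stop("axis must name a principal plane or be 1, 2 or 3")
  if (thickness_um < h)
    stop("thickness_um must be at least one voxel size")
  n_slices <- max(1L, floor(thickness_um / h))
  first <- floor(start_um / h) + 1L
  last <- first + n_slices - 1L
  if (first < 1L || last > dim(volume$voxels)[ax])
    stop(sprintf("slab [%d, %d] outside volume bounds along axis %d",
                 first, last, ax))
  idx <- list(TRUE, TRUE, TRUE)
  idx[[ax]] <- first:last
  slab <- do.call(`[`, c(list(volume$voxels), idx, list(drop = FALSE)))
  apply(slab, setdiff(1:3, ax), max)
}

#' Derive seed regions of interest from phantom ground truth
#'
#' Emulates the manual seeding step: one circular in-plane region per true
#' plaque, centered on the plaque and wide/tall enough to enclose it with a
#' two-voxel margin.
#'
#' @param truth a `phantom_truth`.
#' @return data.frame of seeds with columns `cx`, `cy` (in-plane voxel
#'   coordinates), `z_start`, `z_end` (coronal slice range), `radius_um`,
#'   `region`.
#' @export
seed_rois_from_truth <- function(truth) {
  lab <- truth$plaque_labels$labels
  h <- truth$plaque_labels$voxel_size_um
  idx <- which(lab > 0, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(cx = numeric(), cy = numeric(), z_start = integer(),
                      z_end = integer(), radius_um = numeric(),
                      region = character()))
  ids <- lab[lab > 0]
  rows <- lapply(split(seq_along(ids), ids), function(sel) {
    sub <- idx[sel, , drop = FALSE]
    ctr <- colMeans(sub)
    rad <- sqrt(max((sub[, 1] - ctr[1])^2 + (sub[, 2] - ctr[2])^2))
    data.frame(cx = ctr[1], cy = ctr[2],
               z_start = min(sub[, 3]), z_end = max(sub[, 3]),
               radius_um = (rad + 2) * h)
  })
  out <- do.call(rbind, rows)
  truth_rec <- truth$records[truth$records$class == "plaque", ]
  out$region <- truth_rec$region[match(as.integer(rownames(out)),
                                       truth_rec$id)]
  rownames(out) <- NULL
  out
}
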