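#' Deterministic well-spread gradient directions
#'
#' Generates `n` unit vectors spread over the sphere: a spherical Fibonacci
#' lattice refined by a fixed number of electrostatic-repulsion steps. The
#' construction is fully deterministic (no RNG), so the same `n` always yields
#' the same scheme -- a requirement for bitwise-reproducible phantoms.
#'
#' @param n number of directions (>= 6).
#' @param refine number of repulsion iterations (default 20).
#' @return an `n x 3` matrix of unit row vectors.
#' @export
gradient_scheme <- function(n, refine = 20L) {
  stopifnot(n >= 6)
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  golden <- pi * (3 - sqrt(5))
  theta <- golden * (seq_len(n) - 1)
  g <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  # antipodally-symmetric repulsion (diffusion directions are axes)
  for (it in seq_len(refine)) {
    force <- matrix(0, n, 3)
    for (j in seq_len(n)) {
      d <- sweep(g, 2, g[j, ])          # g - g_j
      d2 <- rowSums(d^2); d2[j] <- Inf
      da <- sweep(-g, 2, g[j, ])        # -g - g_j (antipodes)
      da2 <- rowSums(da^2)
      force[j, ] <- -colSums(d / d2^1.5) - colSums(da / da2^1.5)
    }
    g <- g + 0.002 * force
    g <- g / sqrt(rowSums(g^2))
  }
  g
}

#' Phantom configuration for the periventricular diffusion model
#'
#' Describes a synthetic DWI phantom: a ventricle (CSF) proxy flanked
#' bilaterally by projection-fiber bundles (principal axis z,
#' inferior-superior) and association-fiber bundles (principal axis y,
#' anterior-posterior), the geometry in which the perivascular (ALPS) index
#' is defined. Medullary veins run along x, so perivascular flow adds an
#' x-axis diffusivity component `perivascular_delta` inside the bundles'
#' periventricular shell.
#'
#' Voxel coordinates are 0-based throughout the pipeline; extents are
#' inclusive `c(lo, hi)` index ranges per axis. Diffusivities are in
#' um^2/ms (= 1e-3 mm^2/s); b-values in s/mm^2.
#'
#' @param grid_shape integer 3-vector of voxels per axis.
#' @param voxel_size_mm numeric 3-vector, mm per voxel.
#' @param bundles named list with entries `projection_L`, `projection_R`,
#'   `association_L`, `association_R`; each a list with `extent` (list of
#'   x/y/z inclusive 0-based ranges), `axis` ("z" or "y"), `lambda_par`,
#'   `lambda_perp`.
#' @param perivascular_delta additive x-axis diffusivity inside bundles;
#'   scalar, or named `c(L = , R = )` for hemisphere asymmetry.
#' @param background_d isotropic background diffusivity.
#' @param ventricle list with `extent` and isotropic diffusivity `d`
#'   (CSF, default 3.0).
#' @param b_values b-values, must include 0.
#' @param n_directions number of b>0 gradient directions.
#' @param s0 non-diffusion-weighted signal level.
#' @param snr Rician signal-to-noise ratio at b=0 (`Inf` = noiseless).
#' @param seed RNG seed for the noise draw.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(40L, 40L, 20L),
                           voxel_size_mm = c(2, 2, 2),
                           bundles = default_bundles(),
                           perivascular_delta = 0.24,
                           background_d = 0.8,
                           ventricle = list(extent = list(x = c(18, 21), y = c(10, 29), z = c(4, 15)), d = 3.0),
                           b_values = c(0, 1000),
                           n_directions = 64L,
                           s0 = 1000,
                           snr = Inf,
                           seed = 1L) {
  cfg <- structure(list(grid_shape = as.integer(grid_shape),
                        voxel_size_mm = as.numeric(voxel_size_mm),
                        bundles = bundles,
                        perivascular_delta = perivascular_delta,
                        background_d = background_d,
                        ventricle = ventricle,
                        b_values = b_values, n_directions = as.integer(n_directions),
                        s0 = s0, snr = snr, seed = as.integer(seed)),
                   class = "phantom_config")
  validate_phantom_config(cfg)
  cfg
}

#' @rdname phantom_config
#' @export
default_bundles <- function() {
  ext <- function(x) list(x = x, y = c(8, 31), z = c(1, 18))
  list(
    projection_L  = list(extent = ext(c(13, 16)), axis = "z", lambda_par = 1.2, lambda_perp = 0.3),
    projection_R  = list(extent = ext(c(23, 26)), axis = "z", lambda_par = 1.2, lambda_perp = 0.3),
    association_L = list(extent = ext(c(8, 11)),  axis = "y", lambda_par = 1.2, lambda_perp = 0.3),
    association_R = list(extent = ext(c(28, 31)), axis = "y", lambda_par = 1.2, lambda_perp = 0.3)
  )
}

delta_lr <- function(perivascular_delta) {
  if (length(perivascular_delta) == 1L && is.null(names(perivascular_delta)))
    c(L = unname(perivascular_delta), R = unname(perivascular_delta))
  else {
    stopifnot(all(c("L", "R") %in% names(perivascular_delta)))
    perivascular_delta[c("L", "R")]
  }
}

extent_overlaps <- function(e1, e2) {
  all(vapply(c("x", "y", "z"),
             function(ax) e1[[ax]][1] <= e2[[ax]][2] && e2[[ax]][1] <= e1[[ax]][2],
             logical(1)))
}

validate_phantom_config <- function(cfg) {
  stopifnot(length(cfg$grid_shape) == 3, all(cfg$grid_shape > 0),
            all(cfg$voxel_size_mm > 0),
            cfg$background_d > 0, cfg$ventricle$d > 0,
            any(cfg$b_values == 0), cfg$n_directions >= 6,
            cfg$s0 > 0, cfg$snr > 0)
  dl <- delta_lr(cfg$perivascular_delta)
  if (any(dl < 0)) stop("perivascular_delta must be >= 0")
  need <- c("projection_L", "projection_R", "association_L", "association_R")
  if (!all(need %in% names(cfg$bundles))) stop("bundles must name all four fiber populations")
  for (b in cfg$bundles) {
    if (!(b$lambda_par > b$lambda_perp)) stop("lambda_par must exceed lambda_perp inside bundles")
    if (b$lambda_perp <= 0) stop("diffusivities must be positive")
    for (ax in c("x", "y", "z")) {
      e <- b$extent[[ax]]
      n <- cfg$grid_shape[match(ax, c("x", "y", "z"))]
      if (e[1] < 0 || e[2] >= n || e[1] > e[2]) stop("bundle extent outside grid")
    }
  }
  regions <- c(cfg$bundles, list(ventricle = cfg$ventricle))
  nm <- names(regions)
  for (i in seq_along(regions)) for (j in seq_len(i - 1L)) {
    if (extent_overlaps(regions[[i]]$extent, regions[[j]]$extent))
      stop(sprintf("phantom geometry error: extents of '%s' and '%s' overlap", nm[i], nm[j]))
  }
  invisible(cfg)
}

extent_index <- function(extent, grid_shape) {
  # inclusive 0-based extent -> list of 1-based index vectors per axis
  lapply(c("x", "y", "z"), function(ax) {
    e <- extent[[ax]]
    seq.int(e[1] + 1L, e[2] + 1L)
  })
}

bundle_tensor_diag <- function(bundle, delta) {
  d <- c(x = bundle$lambda_perp, y = bundle$lambda_perp, z = bundle$lambda_perp)
  d[bundle$axis] <- bundle$lambda_par
  d["x"] <- d["x"] + delta
  d
}

#' Generate a synthetic DWI phantom with known ground truth
#'
#' Builds the per-voxel ground-truth tensor field from the configured
#' geometry and simulates the diffusion-weighted signal with the
#' Stejskal-Tanner forward model `S_i = S0 * exp(-b_i g_i' D g_i)`,
#' optionally corrupted by Rician noise (`snr = S0 / sigma`).
#'
#' @param config a [phantom_config()].
#' @return a list with `dwi` (a `dwi_volume`) and `truth` (a `phantom_truth`
#'   carrying exact tensors, 0-based ALPS ROI centers inside each bundle, the
#'   per-hemisphere ground-truth diagonal diffusivities, and the analytic
#'   ALPS value).
#' @export
generate_dwi_phantom <- function(config) {
  validate_phantom_config(config)
  gs <- config$grid_shape
  dl <- delta_lr(config$perivascular_delta)

  # per-voxel diagonal ground truth (all compartments are axis-aligned)
  dxx <- array(config$background_d, gs)
  dyy <- dxx; dzz <- dxx
  vi <- extent_index(config$ventricle$extent, gs)
  dxx[vi[[1]], vi[[2]], vi[[3]]] <- config$ventricle$d
  dyy[vi[[1]], vi[[2]], vi[[3]]] <- config$ventricle$d
  dzz[vi[[1]], vi[[2]], vi[[3]]] <- config$ventricle$d

  roi_centers <- list(); bundle_diff <- list()
  for (nm in names(config$bundles)) {
    b <- config$bundles[[nm]]
    hemi <- sub(".*_", "", nm)
    d <- bundle_tensor_diag(b, dl[[hemi]])
    bi <- extent_index(b$extent, gs)
    dxx[bi[[1]], bi[[2]], bi[[3]]] <- d["x"]
    dyy[bi[[1]], bi[[2]], bi[[3]]] <- d["y"]
    dzz[bi[[1]], bi[[2]], bi[[3]]] <- d["z"]
    roi_centers[[nm]] <- vapply(c("x", "y", "z"),
                                function(ax) floor(mean(b$extent[[ax]])), numeric(1))
    bundle_diff[[nm]] <- d
  }

  # gradient table: all b = 0 entries first, then the b > 0 shell(s)
  dirs <- gradient_scheme(config$n_directions)
  bpos <- config$b_values[config$b_values > 0]
  bvals <- c(rep(0, sum(config$b_values == 0)), rep(bpos, each = config$n_directions))
  bvecs <- rbind(matrix(0, sum(config$b_values == 0), 3),
                 dirs[rep(seq_len(config$n_directions), times = length(bpos)), , drop = FALSE])

  nv <- length(bvals)
  nvox <- prod(gs)
  Dmat <- cbind(as.vector(dxx), as.vector(dyy), as.vector(dzz))  # nvox x 3
  # exponent: -b * (gx^2 Dxx + gy^2 Dyy + gz^2 Dzz) * 1e-3 (b s/mm^2, D um^2/ms)
  G2 <- bvecs^2
  expo <- -1e-3 * (bvals * G2) %*% t(Dmat)                        # nv x nvox
  signal <- config$s0 * exp(expo)

  if (is.finite(config$snr)) {
    set.seed(config$seed)
    sigma <- config$s0 / config$snr
    n1 <- matrix(stats::rnorm(nv * nvox), nv, nvox)
    n2 <- matrix(stats::rnorm(nv * nvox), nv, nvox)
    signal <- sqrt((signal + sigma * n1)^2 + (sigma * n2)^2)
  }

  sig4d <- array(t(signal), c(gs, nv))
  dwi <- dwi_volume(sig4d, bvals, bvecs, config$voxel_size_mm)

  tensor <- array(0, c(gs, 6L))  # order: xx, yy, zz, xy, xz, yz
  tensor[, , , 1] <- dxx; tensor[, , , 2] <- dyy; tensor[, , , 3] <- dzz

  hemis <- lapply(c(L = "L", R = "R"), function(h) {
    list(dx_proj  = unname(bundle_diff[[paste0("projection_", h)]]["x"]),
         dx_assoc = unname(bundle_diff[[paste0("association_", h)]]["x"]),
         dy_proj  = unname(bundle_diff[[paste0("projection_", h)]]["y"]),
         dz_assoc = unname(bundle_diff[[paste0("association_", h)]]["z"]))
  })
  truth <- structure(list(tensor = tensor, roi_centers = roi_centers,
                          hemispheres = hemis, config = config),
                     class = "phantom_truth")
  truth$alps <- analytic_alps(truth)
  list(dwi = dwi, truth = truth)
}

#' Analytic ALPS index from ground-truth diffusivities
#'
#' The ALPS index is `mean(Dx_proj, Dx_assoc) / mean(Dy_proj, Dz_assoc)`:
#' x-axis diffusivity along the perivascular (medullary-vein) direction in
#' projection- and association-fiber regions, over the fiber-perpendicular
#' diffusivities. For a `phantom_truth` the index is computed per hemisphere
#' from the stored bundle diffusivities and averaged bilaterally; a plain
#' numeric 4-vector `(Dx_proj, Dx_assoc, Dy_proj, Dz_assoc)` is also
#' accepted.
#'
#' @param truth a `phantom_truth` or a numeric 4-vector.
#' @return the ALPS value; for phantom truth, with attribute `hemispheres`.
#' @export
analytic_alps <- function(truth) {
  ratio <- function(v) {
    den <- mean(v[3:4])
    if (den == 0) stop("ALPS denominator is zero")
    mean(v[1:2]) / den
  }
  if (inherits(truth, "phantom_truth")) {
    per <- vapply(truth$hemispheres,
                  function(h) ratio(c(h$dx_proj, h$dx_assoc, h$dy_proj, h$dz_assoc)),
                  numeric(1))
    structure(mean(per), hemispheres = per)
  } else {
    stopifnot(is.numeric(truth), length(truth) == 4)
    ratio(truth)
  }
}
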