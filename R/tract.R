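#' Tracking parameters for FACT deterministic tractography
#'
#' Defaults follow the study protocol where stated (FA threshold 0.2,
#' turning-angle threshold 45 degrees); step size, length window and seeding
#' density are explicit conventions: step = 1 mm (half the default voxel),
#' streamlines kept when 10 mm <= length <= 300 mm, one seed per voxel at
#' the voxel center (deterministic; jitter only when `seeds_per_voxel > 1`).
#'
#' @param fa_threshold FA stopping threshold, in (0, 1).
#' @param angle_threshold_deg maximum turning angle per step, in (0, 90].
#' @param step_mm step length, mm.
#' @param min_length_mm,max_length_mm retained-length window, mm.
#' @param seeds_per_voxel seeds per eligible voxel.
#' @param seed RNG seed for seed jitter (used only when `seeds_per_voxel > 1`).
#' @return an object of class `tracking_params`.
#' @export
tracking_params <- function(fa_threshold = 0.2, angle_threshold_deg = 45,
                            step_mm = 1.0, min_length_mm = 10,
                            max_length_mm = 300, seeds_per_voxel = 1L,
                            seed = 1L) {
  stopifnot(fa_threshold > 0, fa_threshold < 1,
            angle_threshold_deg > 0, angle_threshold_deg <= 90,
            step_mm > 0, min_length_mm >= 0, max_length_mm > min_length_mm,
            seeds_per_voxel >= 1)
  structure(list(fa_threshold = fa_threshold,
                 angle_threshold_deg = angle_threshold_deg,
                 step_mm = step_mm, min_length_mm = min_length_mm,
                 max_length_mm = max_length_mm,
                 seeds_per_voxel = as.integer(seeds_per_voxel),
                 seed = as.integer(seed)),
            class = "tracking_params")
}

#' Generate a tract phantom with known region adjacency
#'
#' Builds a tensor field containing tubular fiber bundles along given voxel
#' polylines (principal axis along the local path tangent, FA ~ 0.84 inside,
#' isotropic background FA = 0), plus a parcellation volume labeling the
#' bundle end-caps with the connected region ids, and the ground-truth
#' region adjacency.
#'
#' @param n_regions number of parcellation labels (>= max label used).
#' @param bundle_paths list; each element a list with `regions = c(a, b)`
#'   (positive integer labels) and `points` (k x 3 matrix of 0-based voxel
#'   coordinates tracing the bundle centerline).
#' @param grid_shape integer 3-vector.
#' @param voxel_size_mm numeric 3-vector.
#' @param radius_vox tube radius in voxels (default 1.2).
#' @param cap_mm end-cap length in mm labeled with each region (default 6).
#' @param seed unused placeholder for interface symmetry (construction is
#'   deterministic).
#' @return list with `tf` (a `tensor_field`), `parcellation` (3D integer
#'   array), and `truth_adjacency` (2-column matrix of connected pairs).
#' @export
generate_tract_phantom <- function(n_regions, bundle_paths,
                                   grid_shape = c(20L, 20L, 40L),
                                   voxel_size_mm = c(2, 2, 2),
                                   radius_vox = 1.2, cap_mm = 6, seed = 1L) {
  gs <- as.integer(grid_shape)
  lam_par <- 1.4; lam_perp <- 0.2; bg <- 0.8
  nvox <- prod(gs)
  tensor <- matrix(0, nvox, 6)
  tensor[, 1:3] <- bg
  fa <- numeric(nvox)
  e1 <- matrix(0, nvox, 3)
  parc <- integer(nvox)
  lin <- function(v) v[, 1] + gs[1] * (v[, 2] + gs[2] * v[, 3]) + 1L  # 0-based -> linear
  fa_bundle <- fa_from_eigenvalues(c(lam_par, lam_perp, lam_perp))

  adjacency <- matrix(integer(0), 0, 2)
  for (bp in bundle_paths) {
    pts <- as.matrix(bp$points)
    stopifnot(ncol(pts) == 3, nrow(pts) >= 2, length(bp$regions) == 2)
    if (any(pts < 0) || any(sweep(pts, 2, gs - 1) > 0))
      stop("bundle path exits the grid")
    if (any(bp$regions < 1) || any(bp$regions > n_regions))
      stop("region label outside 1..n_regions")
    seglen_mm <- sqrt(rowSums((sweep(diff(pts), 2, voxel_size_mm, "*"))^2))
    total_mm <- sum(seglen_mm)
    arc0 <- c(0, cumsum(seglen_mm))
    span <- ceiling(radius_vox)
    for (s in seq_len(nrow(pts) - 1)) {
      d <- pts[s + 1, ] - pts[s, ]
      tang <- d * voxel_size_mm
      tang <- tang / sqrt(sum(tang^2))
      nsub <- max(2L, ceiling(seglen_mm[s] / (0.25 * min(voxel_size_mm))))
      for (t in seq(0, 1, length.out = nsub)) {
        cpt <- pts[s, ] + t * d
        arc <- arc0[s] + t * seglen_mm[s]
        rng <- lapply(1:3, function(a)
          max(0, floor(cpt[a] - span)):min(gs[a] - 1, ceiling(cpt[a] + span)))
        vox <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
        keep <- rowSums(sweep(vox, 2, cpt)^2) <= radius_vox^2
        if (!any(keep)) next
        li <- lin(vox[keep, , drop = FALSE])
        D <- lam_perp * diag(3) + (lam_par - lam_perp) * tcrossprod(tang)
        tensor[li, ] <- matrix(c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3]),
                               length(li), 6, byrow = TRUE)
        fa[li] <- fa_bundle
        e1[li, ] <- matrix(sign_normalize_e1(tang), length(li), 3, byrow = TRUE)
        if (arc <= cap_mm) parc[li] <- bp$regions[1]
        else if (arc >= total_mm - cap_mm) parc[li] <- bp$regions[2]
      }
    }
    adjacency <- rbind(adjacency, sort(bp$regions))
  }

  ev <- matrix(0, nvox, 3)
  inb <- fa > 0
  ev[inb, ] <- matrix(c(lam_par, lam_perp, lam_perp), sum(inb), 3, byrow = TRUE)
  ev[!inb, ] <- matrix(bg, sum(!inb), 3)
  md <- rowMeans(ev)
  tf <- structure(list(
    tensor = array(tensor, c(gs, 6)),
    eigenvalues = array(ev, c(gs, 3)),
    e1 = array(e1, c(gs, 3)),
    fa = array(fa, gs), md = array(md, gs),
    dxx = array(tensor[, 1], gs), dyy = array(tensor[, 2], gs),
    dzz = array(tensor[, 3], gs),
    mask = array(TRUE, gs), voxel_size_mm = as.numeric(voxel_size_mm),
    qc = list()), class = "tensor_field")
  list(tf = tf, parcellation = array(parc, gs),
       truth_adjacency = unique(adjacency))
}

voxel_of <- function(p, voxel_size_mm) floor(p / voxel_size_mm)  # 0-based

#' FACT deterministic whole-volume tractography
#'
#' Fiber Assignment by Continuous Tracking: from each seed voxel with
#' FA >= `fa_threshold`, track bidirectionally, at each step following the
#' principal eigenvector of the voxel containing the current point
#' (nearest-neighbour lookup, sign-aligned with the current heading).
#' Tracking stops when the turning angle exceeds the threshold, or when the
#' next point would land outside the grid or in a voxel with FA below the
#' threshold -- so every retained point satisfies the FA criterion.
#' Streamlines outside the `[min_length_mm, max_length_mm]` window are
#' discarded.
#'
#' @param tf a `tensor_field`.
#' @param params a [tracking_params()].
#' @param seed_mask optional logical array restricting seeding.
#' @return an object of class `streamline_set`: a list of streamlines, each
#'   with `points` (n x 3, mm), `fa` (per-point samples), `length` (mm).
#' @export
fact_track <- function(tf, params = tracking_params(), seed_mask = NULL) {
  stopifnot(inherits(tf, "tensor_field"))
  gs <- dim(tf$fa); vs <- tf$voxel_size_mm
  eligible <- tf$fa >= params$fa_threshold
  if (!is.null(seed_mask)) eligible <- eligible & seed_mask
  seeds <- which(eligible, arr.ind = TRUE)  # 1-based
  if (nrow(seeds) == 0) {
    warning("empty seed mask: no voxel reaches the FA threshold")
    return(structure(list(), class = "streamline_set", n_seeds = 0L))
  }
  cos_thresh <- cos(params$angle_threshold_deg * pi / 180)
  max_steps <- ceiling(params$max_length_mm / params$step_mm)
  e1m <- matrix(tf$e1, ncol = 3)
  fav <- as.vector(tf$fa)
  linidx <- function(v) v[1] + gs[1] * (v[2] + gs[2] * v[3]) + 1L

  half_track <- function(p0, d0) {
    pts <- matrix(NA_real_, max_steps + 1L, 3)
    fas <- numeric(max_steps + 1L)
    p <- p0; prev <- d0; n <- 0L
    repeat {
      v <- voxel_of(p, vs)
      li <- linidx(v)
      d <- e1m[li, ]
      if (all(d == 0)) break
      if (sum(d * prev) < 0) d <- -d
      if (sum(d * prev) < cos_thresh - 1e-12) break  # strictly exceeding the angle stops
      pn <- p + params$step_mm * d
      vn <- voxel_of(pn, vs)
      if (any(vn < 0) || any(vn >= gs)) break
      lin_n <- linidx(vn)
      if (fav[lin_n] < params$fa_threshold) break
      n <- n + 1L
      pts[n, ] <- pn; fas[n] <- fav[lin_n]
      p <- pn; prev <- d
      if (n >= max_steps) break
    }
    list(pts = pts[seq_len(n), , drop = FALSE], fa = fas[seq_len(n)])
  }

  jitter <- params$seeds_per_voxel > 1L
  if (jitter) set.seed(params$seed)
  out <- vector("list", nrow(seeds) * params$seeds_per_voxel)
  k <- 0L
  for (i in seq_len(nrow(seeds))) {
    v0 <- seeds[i, ] - 1L
    li0 <- linidx(v0)
    d0 <- e1m[li0, ]
    if (all(d0 == 0)) next
    for (s in seq_len(params$seeds_per_voxel)) {
      off <- if (jitter) stats::runif(3, -0.49, 0.49) else c(0, 0, 0)
      p0 <- (v0 + 0.5 + off) * vs
      fwd <- half_track(p0, d0)
      bwd <- half_track(p0, -d0)
      pts <- rbind(bwd$pts[rev(seq_len(nrow(bwd$pts))), , drop = FALSE],
                   matrix(p0, 1, 3), fwd$pts)
      if (nrow(pts) < 2) next
      fas <- c(rev(bwd$fa), fav[li0], fwd$fa)
      len <- (nrow(pts) - 1L) * params$step_mm
      if (len < params$min_length_mm || len > params$max_length_mm) next
      k <- k + 1L
      out[[k]] <- list(points = pts, fa = fas, length = len)
    }
  }
  structure(out[seq_len(k)], class = "streamline_set", n_seeds = nrow(seeds))
}

#' Streamline length
#'
#' Sum of Euclidean segment lengths over the ordered point list.
#'
#' @param s a streamline (list with `points`), or an `n x 3` matrix.
#' @return length in mm.
#' @export
streamline_length <- function(s) {
  pts <- if (is.list(s)) s$points else s
  pts <- as.matrix(pts)
  if (nrow(pts) < 2) stop("a streamline needs at least 2 points")
  sum(sqrt(rowSums(diff(pts)^2)))
}

#' Build a parcellation-based structural connectome
#'
#' A streamline contributes to region pair (A, B), A != B, when its two
#' endpoints fall in voxels labeled A and B; streamlines with an unlabeled
#' endpoint contribute to no pair. Three symmetric matrices are assembled:
#' streamline count (`fiber_number`), mean of the streamlines' mean sampled
#' FA (`mean_fa`), and mean streamline length (`mean_length`).
#'
#' @param streamlines a `streamline_set`.
#' @param parcellation 3D integer array (0 = unlabeled), same grid as `tf`.
#' @param tf the `tensor_field` the streamlines were tracked on.
#' @param n_regions number of regions (default `max(parcellation)`).
#' @return an object of class `connectome`.
#' @export
build_connectome <- function(streamlines, parcellation, tf,
                             n_regions = max(parcellation)) {
  gs <- dim(tf$fa)
  if (!all(dim(parcellation) == gs)) stop("parcellation grid does not match tensor grid")
  vs <- tf$voxel_size_mm
  n <- n_regions
  fiber <- matrix(0L, n, n); sfa <- matrix(0, n, n); slen <- matrix(0, n, n)
  for (s in streamlines) {
    ep <- rbind(s$points[1, ], s$points[nrow(s$points), ])
    v <- voxel_of(ep, matrix(vs, 2, 3, byrow = TRUE)) + 1L
    a <- parcellation[v[1, 1], v[1, 2], v[1, 3]]
    b <- parcellation[v[2, 1], v[2, 2], v[2, 3]]
    if (a == 0 || b == 0 || a == b) next
    i <- min(a, b); j <- max(a, b)
    fiber[i, j] <- fiber[i, j] + 1L
    sfa[i, j] <- sfa[i, j] + mean(s$fa)
    slen[i, j] <- slen[i, j] + s$length
  }
  pos <- fiber > 0
  mfa <- ifelse(pos, sfa / pmax(fiber, 1L), 0)
  mlen <- ifelse(pos, slen / pmax(fiber, 1L), 0)
  fiber <- fiber + t(fiber); mfa <- mfa + t(mfa); mlen <- mlen + t(mlen)
  structure(list(region_ids = seq_len(n), fiber_number = fiber,
                 mean_fa = mfa, mean_length = mlen),
            class = "connectome")
}

#' Write / read connectome matrices as TSV
#'
#' One file per matrix (`fiber_number.tsv`, `mean_fa.tsv`,
#' `mean_length.tsv`), region ids as header.
#'
#' @param cn a `connectome`.
#' @param dir output directory.
#' @return the directory (write) or a `connectome` (read).
#' @export
write_connectome <- function(cn, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("fiber_number", "mean_fa", "mean_length")) {
    m <- cn[[nm]]
    colnames(m) <- cn$region_ids
    utils::write.table(m, file.path(dir, paste0(nm, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_connectome
#' @export
read_connectome <- function(dir) {
  m <- lapply(c("fiber_number", "mean_fa", "mean_length"), function(nm)
    as.matrix(utils::read.table(file.path(dir, paste0(nm, ".tsv")),
                                header = TRUE, sep = "\t", check.names = FALSE)))
  structure(list(region_ids = as.integer(colnames(m[[1]])),
                 fiber_number = unname(m[[1]]), mean_fa = unname(m[[2]]),
                 mean_length = unname(m[[3]])),
            class = "connectome")
}
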