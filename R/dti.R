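#' DWI volume container
#'
#' A validated 4D diffusion-weighted dataset: signal grid, per-volume
#' b-values (s/mm^2), per-volume unit gradient directions, and voxel
#' geometry. Requires at least one b=0 volume and at least 6 b>0 volumes
#' with non-collinear directions; b-values within 50 s/mm^2 of zero are
#' treated as b=0.
#'
#' @param signal 4D non-negative array `(x, y, z, volume)`.
#' @param bvals numeric vector, one b-value per volume.
#' @param bvecs `n_volumes x 3` matrix of gradient directions; rows for
#'   b>0 volumes must have unit norm (tolerance 1e-3).
#' @param voxel_size_mm numeric 3-vector.
#' @return an object of class `dwi_volume`.
#' @export
dwi_volume <- function(signal, bvals, bvecs, voxel_size_mm = c(2, 2, 2)) {
  stopifnot(length(dim(signal)) == 4)
  bvecs <- as.matrix(bvecs)
  nv <- dim(signal)[4]
  if (length(bvals) != nv || nrow(bvecs) != nv)
    stop(sprintf("volume-count mismatch: %d volumes, %d b-values, %d directions",
                 nv, length(bvals), nrow(bvecs)))
  if (min(signal) < 0) stop("signal must be non-negative")
  b0 <- is_b0(bvals)
  if (!any(b0)) stop("at least one b=0 volume is required")
  if (sum(!b0) < 6) stop("at least 6 diffusion-weighted (b>0) volumes are required")
  norms <- sqrt(rowSums(bvecs^2))
  bad <- which(!b0 & abs(norms - 1) > 1e-3)
  if (length(bad))
    stop("non-unit gradient direction(s) at volume(s): ", paste(bad, collapse = ", "))
  if (qr(bvecs[!b0, , drop = FALSE]^2)$rank < 3)
    stop("gradient directions are collinear; tensor is not identifiable")
  structure(list(signal = signal, bvals = as.numeric(bvals), bvecs = bvecs,
                 voxel_size_mm = as.numeric(voxel_size_mm)),
            class = "dwi_volume")
}

is_b0 <- function(bvals) abs(bvals) <= 50

#' Write / read DWI as NIfTI + FSL-style bvals/bvecs
#'
#' `write_dwi` writes `dwi.nii.gz`, `bvals` (one row) and `bvecs` (three
#' rows, FSL convention) into `dir`; `load_dwi` reads them back into a
#' validated [dwi_volume()].
#'
#' @param dwi a `dwi_volume`.
#' @param dir output directory (created if missing).
#' @return `write_dwi`: the directory, invisibly. `load_dwi`: a `dwi_volume`.
#' @export
write_dwi <- function(dwi, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img <- RNifti::asNifti(dwi$signal)
  RNifti::pixdim(img) <- c(dwi$voxel_size_mm, 1)
  RNifti::writeNifti(img, file.path(dir, "dwi.nii.gz"))
  writeLines(paste(format(dwi$bvals, scientific = FALSE, trim = TRUE), collapse = " "),
             file.path(dir, "bvals"))
  write(dwi$bvecs, file.path(dir, "bvecs"), ncolumns = nrow(dwi$bvecs), sep = " ")
  invisible(dir)
}

#' @rdname write_dwi
#' @param nifti_path,bval_path,bvec_path file paths; when `nifti_path` is a
#'   directory the conventional names `dwi.nii.gz`, `bvals`, `bvecs` inside
#'   it are used.
#' @export
load_dwi <- function(nifti_path, bval_path = NULL, bvec_path = NULL) {
  if (dir.exists(nifti_path)) {
    bval_path <- file.path(nifti_path, "bvals")
    bvec_path <- file.path(nifti_path, "bvecs")
    nifti_path <- file.path(nifti_path, "dwi.nii.gz")
  }
  for (p in c(nifti_path, bval_path, bvec_path))
    if (!file.exists(p)) stop("file not found: ", p)
  img <- RNifti::readNifti(nifti_path)
  sig <- array(as.numeric(img), dim(img))
  bvals <- scan(bval_path, quiet = TRUE)
  bv <- as.matrix(utils::read.table(bvec_path))
  if (nrow(bv) == 3 && ncol(bv) != 3) bv <- t(bv)
  vs <- attr(img, "pixdim")[1:3]
  if (is.null(vs) || any(!is.finite(vs)) || any(vs <= 0)) vs <- c(2, 2, 2)
  dwi_volume(sig, bvals, bv, vs)
}

#' Fit the diffusion tensor by log-linear least squares
#'
#' Per masked voxel, solves `ln(S_i / S0) = -b_i g_i' D g_i` for the six
#' unique tensor elements by ordinary least squares, with `S0` the mean of
#' the b=0 volumes. Zero or negative signals are floored at `1e-6 * S0`
#' before the log. Negative eigenvalues are clamped to zero and FA
#' recomputed. The returned axis diffusivities Dxx/Dyy/Dzz are the tensor
#' diagonal in image axes (the convention the ALPS literature's "x-axis
#' diffusivity map" denotes), not eigenvalue projections.
#'
#' @param dwi a [dwi_volume()].
#' @param mask logical 3D array (default: all voxels).
#' @return an object of class `tensor_field` with fields `tensor`
#'   (`(x,y,z,6)`, order xx,yy,zz,xy,xz,yz), `eigenvalues` (descending),
#'   `e1`, `fa`, `md`, `dxx`, `dyy`, `dzz`, `mask`, `voxel_size_mm`, and a
#'   `qc` list (voxels excluded for insufficient usable directions).
#' @export
fit_tensor <- function(dwi, mask = NULL) {
  gs <- dim(dwi$signal)[1:3]
  if (is.null(mask)) mask <- array(TRUE, gs)
  stopifnot(all(dim(mask) == gs))

  b0 <- is_b0(dwi$bvals)
  nv <- length(dwi$bvals)
  sig <- matrix(aperm(dwi$signal, c(4, 1, 2, 3)), nrow = nv)  # nv x nvox
  s0 <- colMeans(sig[b0, , drop = FALSE])

  idx <- which(as.vector(mask) & s0 > 0)
  n_bad_s0 <- sum(as.vector(mask) & s0 <= 0)

  g <- dwi$bvecs
  X <- -1e-3 * dwi$bvals * cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
                                 2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3],
                                 2 * g[, 2] * g[, 3])
  # usable direction count per voxel (finite positive signal among b>0 rows)
  usable <- colSums(is.finite(sig[!b0, idx, drop = FALSE]) & sig[!b0, idx, drop = FALSE] > 0)
  enough <- usable >= 6
  n_few <- sum(!enough)
  idx <- idx[enough]

  floorv <- 1e-6 * s0[idx]
  S <- sig[, idx, drop = FALSE]
  S <- pmax(S, rep(floorv, each = nv))
  Y <- log(sweep(S, 2, s0[idx], "/"))
  coef <- qr.coef(qr(X), Y)  # 6 x n

  nvox <- prod(gs)
  tensor <- matrix(0, nvox, 6)
  tensor[idx, ] <- t(coef)
  fa <- md <- numeric(nvox)
  ev <- matrix(0, nvox, 3)
  e1 <- matrix(0, nvox, 3)
  for (k in seq_along(idx)) {
    v <- idx[k]
    D <- matrix(c(tensor[v, 1], tensor[v, 4], tensor[v, 5],
                  tensor[v, 4], tensor[v, 2], tensor[v, 6],
                  tensor[v, 5], tensor[v, 6], tensor[v, 3]), 3, 3)
    e <- eigen(D, symmetric = TRUE)
    lam <- pmax(e$values, 0)
    ev[v, ] <- lam
    fa[v] <- fa_from_eigenvalues(lam)
    md[v] <- mean(lam)
    e1[v, ] <- sign_normalize_e1(e$vectors[, 1])
  }
  fitted <- logical(nvox); fitted[idx] <- TRUE

  structure(list(
    tensor = array(tensor, c(gs, 6)),
    eigenvalues = array(ev, c(gs, 3)),
    e1 = array(e1, c(gs, 3)),
    fa = array(fa, gs), md = array(md, gs),
    dxx = array(tensor[, 1], gs), dyy = array(tensor[, 2], gs),
    dzz = array(tensor[, 3], gs),
    mask = array(fitted, gs),
    voxel_size_mm = dwi$voxel_size_mm,
    qc = list(n_excluded_few_directions = n_few, n_excluded_zero_s0 = n_bad_s0)
  ), class = "tensor_field")
}

fa_from_eigenvalues <- function(lam) {
  ss <- sum(lam^2)
  if (ss == 0) return(0)
  min(1, sqrt(1.5 * sum((lam - mean(lam))^2) / ss))
}

sign_normalize_e1 <- function(v) {
  s <- if (v[3] != 0) sign(v[3]) else if (v[2] != 0) sign(v[2]) else if (v[1] != 0) sign(v[1]) else 1
  v * s
}

#' Scalar and vector maps derived from a tensor field
#'
#' @param tf a `tensor_field`.
#' @return list with `fa`, `md`, `dxx`, `dyy`, `dzz` (3D arrays) and `e1`
#'   (`(x,y,z,3)`), the principal eigenvector sign-normalized to
#'   non-negative z (then y, then x, for degenerate components).
#' @export
tensor_scalars <- function(tf) {
  stopifnot(inherits(tf, "tensor_field"))
  tf[c("fa", "md", "dxx", "dyy", "dzz", "e1")]
}

#' Direction-encoded color FA volume
#'
#' Standard radiological color coding: `RGB = FA * |e1|` with red = x
#' (right-left), green = y (anterior-posterior), blue = z
#' (inferior-superior). A pure projection-fiber (z) voxel is blue; a pure
#' association-fiber (y) voxel is green.
#'
#' @param tf a `tensor_field`.
#' @return array `(x, y, z, 3)` of RGB values in `[0, 1]`.
#' @export
color_fa <- function(tf) {
  stopifnot(inherits(tf, "tensor_field"))
  gs <- dim(tf$fa)
  rgb <- abs(tf$e1) * array(tf$fa, c(gs, 3))
  pmin(pmax(rgb, 0), 1)
}

#' Write tensor scalar maps as NIfTI
#'
#' @param tf a `tensor_field`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_tensor_maps <- function(tf, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("fa", "md", "dxx", "dyy", "dzz")) {
    img <- RNifti::asNifti(tf[[nm]])
    RNifti::pixdim(img) <- tf$voxel_size_mm
    RNifti::writeNifti(img, file.path(dir, paste0(nm, ".nii.gz")))
  }
  invisible(dir)
}
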