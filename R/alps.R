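#' Rasterize a spherical ROI onto the voxel grid
#'
#' Returns every voxel whose center lies within `diameter_mm / 2` (Euclidean,
#' in mm) of the ROI center. No partial-volume weighting: a voxel is in or
#' out by its center. ROIs clipped at the grid boundary are returned with a
#' QC warning attribute.
#'
#' @param center numeric 3-vector, 0-based voxel coordinates (may be
#'   fractional).
#' @param diameter_mm sphere diameter in mm (default 5).
#' @param voxel_size_mm numeric 3-vector.
#' @param grid_shape integer 3-vector.
#' @return integer matrix `n x 3` of 0-based voxel indices, with attribute
#'   `clipped` (logical).
#' @export
rasterize_roi <- function(center, diameter_mm = 5, voxel_size_mm = c(2, 2, 2),
                          grid_shape) {
  stopifnot(length(center) == 3, diameter_mm > 0)
  if (any(center < 0) || any(center > grid_shape - 1))
    stop("ROI center outside grid")
  r <- diameter_mm / 2
  span <- ceiling(r / voxel_size_mm)
  rng <- lapply(1:3, function(a) seq(floor(center[a] - span[a]), ceiling(center[a] + span[a])))
  vox <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  d2 <- sweep(vox, 2, center)
  d2 <- sweep(d2, 2, voxel_size_mm, "*")
  inside <- rowSums(d2^2) <= r^2 + 1e-12
  vox <- vox[inside, , drop = FALSE]
  in_grid <- vox[, 1] >= 0 & vox[, 1] < grid_shape[1] &
             vox[, 2] >= 0 & vox[, 2] < grid_shape[2] &
             vox[, 3] >= 0 & vox[, 3] < grid_shape[3]
  clipped <- any(!in_grid)
  vox <- vox[in_grid, , drop = FALSE]
  if (nrow(vox) == 0)
    stop("ROI rasterizes to an empty voxel set (diameter below voxel pitch?)")
  if (clipped) warning("ROI clipped at grid boundary")
  structure(unname(vox), clipped = clipped)
}

#' Construct the four ALPS ROIs
#'
#' ROI protocol: four spheres (default 5 mm diameter) on the projection and
#' association fibers at the level of the lateral ventricle body, one pair
#' per hemisphere. In phantom mode (`phantom_truth` input) the ground-truth
#' bundle centers are used; otherwise `centers` must name all four of
#' `proj_L`, `proj_R`, `assoc_L`, `assoc_R` (0-based voxel coordinates).
#' When a tensor field is supplied, ROIs whose mean FA falls below
#' `fa_floor` are flagged (a proxy for the manual check that ROIs avoid
#' ischemic lesions); flagged ROIs are reported, not excluded.
#'
#' @param truth_or_centers a `phantom_truth`, or a named list of four
#'   centers.
#' @param diameter_mm ROI diameter (default 5).
#' @param tf optional `tensor_field` used for the FA quality check.
#' @param fa_floor minimum acceptable mean ROI FA (default 0.15).
#' @return an object of class `roi_set`: list of entries with `center`,
#'   `diameter_mm`, `hemisphere`, `fiber_class`, plus `qc_flags`.
#' @export
place_default_rois <- function(truth_or_centers, diameter_mm = 5, tf = NULL,
                               fa_floor = 0.15) {
  keys <- c("proj_L", "proj_R", "assoc_L", "assoc_R")
  if (inherits(truth_or_centers, "phantom_truth")) {
    rc <- truth_or_centers$roi_centers
    centers <- list(proj_L = rc$projection_L, proj_R = rc$projection_R,
                    assoc_L = rc$association_L, assoc_R = rc$association_R)
  } else {
    centers <- truth_or_centers
    missing <- setdiff(keys, names(centers))
    if (length(missing))
      stop("missing ROI centers: ", paste(missing, collapse = ", "))
    centers <- centers[keys]
  }
  rois <- lapply(keys, function(k) {
    list(center = as.numeric(centers[[k]]), diameter_mm = diameter_mm,
         hemisphere = sub(".*_", "", k),
         fiber_class = if (startsWith(k, "proj")) "projection" else "association")
  })
  names(rois) <- keys
  qc <- character(0)
  if (!is.null(tf)) {
    for (k in keys) {
      vox <- rasterize_roi(rois[[k]]$center, diameter_mm, tf$voxel_size_mm, dim(tf$fa))
      mfa <- mean(tf$fa[vox + 1L])
      if (mfa < fa_floor)
        qc <- c(qc, sprintf("%s: mean ROI FA %.3f below floor %.2f", k, mfa, fa_floor))
    }
  }
  structure(list(rois = rois, qc_flags = qc), class = "roi_set")
}

roi_mean <- function(map, vox) {
  # vox: 0-based n x 3 -> mean of map at those voxels
  mean(map[vox[, c(1, 2, 3), drop = FALSE] + 1L])
}

#' Compute the bilateral ALPS index from a tensor field
#'
#' Per hemisphere: `Dx_proj` and `Dy_proj` are the mean Dxx and Dyy over the
#' projection-fiber ROI; `Dx_assoc` and `Dz_assoc` the mean Dxx and Dzz over
#' the association-fiber ROI; then
#' `alps = mean(Dx_proj, Dx_assoc) / mean(Dy_proj, Dz_assoc)`.
#' ROI means are taken first and the ratio applied to the means. `mean_alps`
#' is the average of the left and right indices.
#'
#' @param tf a `tensor_field`.
#' @param rois an `roi_set` from [place_default_rois()].
#' @return an object of class `alps_result`: per-hemisphere diffusivities
#'   and index, `mean_alps`, ROI voxel counts, and QC flags.
#' @export
compute_alps <- function(tf, rois) {
  stopifnot(inherits(tf, "tensor_field"), inherits(rois, "roi_set"))
  gs <- dim(tf$fa)
  out <- list(); counts <- integer(0)
  for (h in c("L", "R")) {
    pv <- rasterize_roi(rois$rois[[paste0("proj_", h)]]$center,
                        rois$rois[[paste0("proj_", h)]]$diameter_mm,
                        tf$voxel_size_mm, gs)
    av <- rasterize_roi(rois$rois[[paste0("assoc_", h)]]$center,
                        rois$rois[[paste0("assoc_", h)]]$diameter_mm,
                        tf$voxel_size_mm, gs)
    counts[paste0("proj_", h)] <- nrow(pv)
    counts[paste0("assoc_", h)] <- nrow(av)
    dx_proj <- roi_mean(tf$dxx, pv); dy_proj <- roi_mean(tf$dyy, pv)
    dx_assoc <- roi_mean(tf$dxx, av); dz_assoc <- roi_mean(tf$dzz, av)
    den <- mean(c(dy_proj, dz_assoc))
    if (den <= 0) stop("non-physical tensors: ALPS denominator <= 0")
    out[[h]] <- list(dx_proj = dx_proj, dy_proj = dy_proj,
                     dx_assoc = dx_assoc, dz_assoc = dz_assoc,
                     alps_index = mean(c(dx_proj, dx_assoc)) / den)
  }
  structure(list(hemispheres = out,
                 alps_L = out$L$alps_index, alps_R = out$R$alps_index,
                 mean_alps = (out$L$alps_index + out$R$alps_index) / 2,
                 roi_voxel_counts = counts,
                 qc_flags = rois$qc_flags),
            class = "alps_result")
}

#' @export
print.alps_result <- function(x, ...) {
  cat(sprintf("ALPS index: L = %.4f, R = %.4f, bilateral mean = %.4f\n",
              x$alps_L, x$alps_R, x$mean_alps))
  if (length(x$qc_flags)) cat("QC flags:\n ", paste(x$qc_flags, collapse = "\n  "), "\n")
  invisible(x)
}

#' Batch ALPS computation over a subject list
#'
#' Each subject entry supplies either a DWI directory (`dwi_dir`, as written
#' by [write_dwi()]) or an in-memory `dwi` object, plus ROI centers (or a
#' `phantom_truth` in `truth`). Per-subject failures are recorded in the
#' output, not fatal to the batch.
#'
#' @param subjects named list; names are subject IDs.
#' @return data.frame with one row per subject: `id`, `mean_alps`, `alps_L`,
#'   `alps_R`, `qc`, `error`.
#' @export
alps_batch <- function(subjects) {
  if (length(subjects) == 0) stop("empty subject list")
  ids <- names(subjects)
  if (is.null(ids) || anyDuplicated(ids)) stop("subjects must have unique IDs")
  rows <- lapply(ids, function(id) {
    s <- subjects[[id]]
    res <- tryCatch({
      dwi <- if (!is.null(s$dwi)) s$dwi else load_dwi(s$dwi_dir)
      tf <- fit_tensor(dwi)
      rois <- place_default_rois(if (!is.null(s$truth)) s$truth else s$centers, tf = tf)
      a <- compute_alps(tf, rois)
      data.frame(id = id, mean_alps = a$mean_alps, alps_L = a$alps_L,
                 alps_R = a$alps_R, qc = paste(a$qc_flags, collapse = "; "),
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(id = id, mean_alps = NA_real_, alps_L = NA_real_,
                 alps_R = NA_real_, qc = "", error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    res
  })
  do.call(rbind, rows)
}
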