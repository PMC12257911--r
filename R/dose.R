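#' A point-source dwell position
#'
#' Desk-scale stand-in for an HDR source dwell: an isotropic point source
#' whose dose falls off with the inverse-square law,
#' `dose(r) = strength / r^2`, so `strength` carries units Gy mm^2.
#'
#' @param position (x, y, z) in mm, in the voxel-centre coordinate frame
#'   (voxel `[1,1,1]` centre at the origin).
#' @param strength source strength in Gy mm^2, > 0.
#' @return object of class `source_dwell`.
#' @export
source_dwell <- function(position, strength) {
  position <- as.numeric(position)
  if (length(position) != 3L || any(!is.finite(position)))
    stop("`position` must be 3 finite coordinates in mm")
  if (!is.numeric(strength) || length(strength) != 1L || strength <= 0)
    stop("`strength` must be a single positive value (Gy mm^2)")
  structure(list(position = position, strength = strength),
            class = "source_dwell")
}

#' Superposed inverse-square dose grid
#'
#' Per-voxel dose from a set of point-source dwells by superposition:
#' `dose(v) = sum_k strength_k / max(r_vk, r_clamp)^2`, with `r_vk` the
#' physical distance from the voxel centre to dwell `k`. The clamp keeps
#' the dose finite for voxels on top of a source. A transparent surrogate
#' for a treatment-planning dose engine: first-approximation physics
#' only, no anisotropy or radial dose modifiers.
#'
#' @param dwells list of [source_dwell()] objects (one accepted bare).
#' @param grid a `labeled_volume`/`binary_mask` supplying shape and
#'   spacing, or `list(shape = , spacing = )`.
#' @param r_clamp clamp radius in mm, > 0; default the smallest voxel
#'   spacing.
#' @return object of class `dose_grid`: `dose` (3D array, Gy), `spacing`.
#' @export
compute_dose <- function(dwells, grid, r_clamp = NULL) {
  if (inherits(dwells, "source_dwell")) dwells <- list(dwells)
  if (length(dwells) < 1L) stop("need at least one source dwell")
  stopifnot(all(vapply(dwells, inherits, TRUE, "source_dwell")))
  if (inherits(grid, "labeled_volume") || inherits(grid, "binary_mask")) {
    shape <- grid_shape(grid); sp <- grid$spacing
  } else {
    shape <- as.integer(grid$shape); sp <- as.numeric(grid$spacing)
  }
  if (is.null(r_clamp)) r_clamp <- min(sp)
  if (r_clamp <= 0) stop("`r_clamp` must be positive (mm)")
  gx <- (seq_len(shape[1]) - 1) * sp[1]
  gy <- (seq_len(shape[2]) - 1) * sp[2]
  gz <- (seq_len(shape[3]) - 1) * sp[3]
  dose <- array(0, shape)
  for (dw in dwells) {
    r2 <- outer(outer((gx - dw$position[1])^2, (gy - dw$position[2])^2, "+"),
                (gz - dw$position[3])^2, "+")
    dose <- dose + dw$strength / pmax(r2, r_clamp^2)
  }
  structure(list(dose = dose, spacing = sp), class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat("dose_grid:", paste(dim(x$dose), collapse = "x"), "voxels; dose [",
      signif(min(x$dose), 4), ",", signif(max(x$dose), 4), "] Gy\n")
  invisible(x)
}

#' Cumulative dose-volume histogram
#'
#' For each dose level, the organ volume (cm^3) receiving at least that
#' dose. Monotone non-increasing; the value at dose 0 is the full organ
#' volume.
#'
#' @param dose a [compute_dose()] result.
#' @param organ non-empty [binary_mask()] on the dose grid.
#' @param n_bins number of dose bins between 0 and the organ maximum.
#' @return `data.frame` with columns `dose_gy`, `volume_cm3`.
#' @export
cumulative_dvh <- function(dose, organ, n_bins = 100L) {
  validate_pair(dose, organ)
  if (!any(organ$mask)) stop("DVH undefined for an empty organ")
  d <- dose$dose[organ$mask]
  vv <- voxel_volume(organ) / 1000  # cm^3 per voxel
  edges <- seq(0, max(d), length.out = n_bins + 1L)
  ds <- sort(d)
  # voxels with dose >= edge, via position in the sorted doses
  n_ge <- length(ds) - findInterval(edges, ds, left.open = TRUE)
  data.frame(dose_gy = edges, volume_cm3 = n_ge * vv)
}

#' Minimum dose to the hottest volume (D2cm3 by default)
#'
#' The organ's voxel doses are sorted in decreasing order and voxel
#' volumes accumulated until the requested volume (2 cm^3 for the
#' standard constraint) is reached; the dose of the voxel crossing the
#' threshold is returned. If the organ is smaller than the requested
#' volume, its minimum dose is returned with a warning. Voxel-resolution
#' extraction, no sub-voxel interpolation.
#'
#' @param dose a [compute_dose()] result.
#' @param organ non-empty [binary_mask()] on the dose grid.
#' @param volume_cm3 the hot-volume size in cm^3 (default 2).
#' @return dose in Gy.
#' @export
d2cc <- function(dose, organ, volume_cm3 = 2) {
  validate_pair(dose, organ)
  if (!any(organ$mask)) stop("D2cm3 undefined for an empty organ")
  d <- sort(dose$dose[organ$mask], decreasing = TRUE)
  vv <- voxel_volume(organ)  # mm^3
  target <- volume_cm3 * 1000
  if (length(d) * vv < target) {
    warning("organ volume ", signif(length(d) * vv / 1000, 4),
            " cm^3 is below ", volume_cm3, " cm^3; returning minimum dose")
    return(d[length(d)])
  }
  d[which(cumsum(rep(vv, length(d))) >= target)[1]]
}

#' Absolute D2cm3 difference between predicted and reference contours
#'
#' `|D2cm3(pred) - D2cm3(ref)|` on a common dose grid. A value close to
#' zero means the predicted contour reproduces the reference contour's
#' dose-constraint reading, regardless of where their shapes differ.
#'
#' @param pred_organ,ref_organ non-empty [binary_mask()]s on the dose
#'   grid.
#' @param dose a [compute_dose()] result.
#' @param organ structure name recorded in the report.
#' @return object of class `dose_report`: `organ`, `d2cc_pred`,
#'   `d2cc_ref`, `abs_diff` (all Gy).
#' @export
abs_d2cc_diff <- function(pred_organ, ref_organ, dose, organ = "organ") {
  validate_pair(pred_organ, ref_organ)
  dp <- d2cc(dose, pred_organ)
  dr <- d2cc(dose, ref_organ)
  structure(
    list(organ = organ, d2cc_pred = dp, d2cc_ref = dr,
         abs_diff = abs(dp - dr)),
    class = "dose_report"
  )
}

#' @export
print.dose_report <- function(x, ...) {
  cat(sprintf("%s: D2cm3 pred %.3f Gy, ref %.3f Gy, |diff| %.3f Gy\n",
              x$organ, x$d2cc_pred, x$d2cc_ref, x$abs_diff))
  invisible(x)
}
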