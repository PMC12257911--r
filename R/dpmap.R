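#' Euclidean distance map from a target structure
#'
#' Exact anisotropic Euclidean distance transform: for every voxel, the
#' physical distance in mm from its centre to the centre of the nearest
#' target voxel. Distance is zero inside the target (nearest non-zero
#' voxel, not the surface). Computed with a separable lower-envelope
#' transform, so it equals the brute-force minimum over all target voxels.
#'
#' @param target a [binary_mask()] of the target (CTV_HR), with at least
#'   one true voxel.
#' @param target_label integer tag recorded on the result (bookkeeping
#'   only).
#' @return object of class `distance_map`: `dist` (3D array, mm),
#'   `spacing`, `target_label`.
#' @export
euclidean_distance_map <- function(target, target_label = 1L) {
  stopifnot(inherits(target, "binary_mask"))
  if (!any(target$mask))
    stop("target mask is empty; distance map undefined")
  d2 <- cpp_edt_sq(as.vector(target$mask), dim(target$mask), target$spacing)
  structure(
    list(dist = array(sqrt(d2), dim(target$mask)),
         spacing = target$spacing,
         target_label = as.integer(target_label)),
    class = "distance_map"
  )
}

#' @export
print.distance_map <- function(x, ...) {
  cat("distance_map:", paste(dim(x$dist), collapse = "x"), "voxels @",
      paste(signif(x$spacing, 4), collapse = "x"), "mm; range [",
      signif(min(x$dist), 4), ",", signif(max(x$dist), 4), "] mm\n")
  invisible(x)
}

#' Inverse-square distance-penalty (DP) map
#'
#' Photon fluence from a brachytherapy source falls off to first
#' approximation as 1/R^2 with distance R from the source. The DP map
#' applies that law to the distance-to-target map and normalizes the
#' result into \[0, 1\], so voxels close to the CTV_HR carry penalty near 1
#' and remote voxels carry penalty near 0.
#'
#' 1/R^2 diverges on the target itself (R = 0), so R is clamped below at
#' `r_min` before inversion; after dividing by the resulting maximum
#' 1/r_min^2 the penalty is exactly
#' `penalty = (r_min / max(dist, r_min))^2`,
#' which equals 1 wherever `dist <= r_min` (in particular on the target)
#' and decays with the inverse-square law beyond.
#'
#' @param dmap a [euclidean_distance_map()] result.
#' @param r_min clamp radius in mm, > 0; default the smallest voxel
#'   spacing, the finest distance the grid resolves.
#' @return object of class `dp_map`: `penalty` (3D array in \[0,1\]),
#'   `r_min`, `spacing`.
#' @export
inverse_square_map <- function(dmap, r_min = min(dmap$spacing)) {
  stopifnot(inherits(dmap, "distance_map"))
  if (!is.numeric(r_min) || length(r_min) != 1L || r_min <= 0)
    stop("`r_min` must be a single positive value in mm")
  pen <- (r_min / pmax(dmap$dist, r_min))^2
  structure(
    list(penalty = array(pen, dim(dmap$dist)), r_min = r_min,
         spacing = dmap$spacing),
    class = "dp_map"
  )
}

#' @export
print.dp_map <- function(x, ...) {
  cat("dp_map:", paste(dim(x$penalty), collapse = "x"),
      "voxels; r_min =", signif(x$r_min, 4), "mm; penalty range [",
      signif(min(x$penalty), 4), ",", signif(max(x$penalty), 4), "]\n")
  invisible(x)
}

#' Export a distance or penalty map as a NIfTI float volume
#'
#' @param map a `distance_map`, `dp_map` or `dose_grid`.
#' @param path destination `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  arr <- if (inherits(map, "distance_map")) map$dist
  else if (inherits(map, "dp_map")) map$penalty
  else if (inherits(map, "dose_grid")) map$dose
  else stop("cannot export class ", paste(class(map), collapse = "/"))
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, map$spacing)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}
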