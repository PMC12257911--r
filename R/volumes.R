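#' Labeled volume: a 3D integer label map on a physical grid
#'
#' The common currency for ground-truth and predicted structure sets: a 3D
#' array of integer labels (0 = background, 1..C = structures, with label 1
#' conventionally the CTV_HR target) plus the voxel spacing in mm. All
#' structures for one case live in a single mutually exclusive label map;
#' overlapping contours must be supplied as separate one-label volumes.
#'
#' Voxel indices are 0-based internally for physical coordinates: the
#' centre of voxel `[i,j,k]` (1-based R index) sits at
#' `((i-1)*sx, (j-1)*sy, (k-1)*sz)` mm. Orientation beyond spacing is
#' ignored.
#'
#' @param labels 3D array of non-negative integers.
#' @param spacing numeric length-3, voxel spacing (sx, sy, sz) in mm, all > 0.
#' @param label_names optional named character vector or list mapping label
#'   values to structure names, e.g. `c("1" = "CTV_HR", "2" = "bladder")`.
#' @return An object of class `labeled_volume` with elements `labels`,
#'   `spacing`, `label_names`.
#' @examples
#' lab <- array(0L, c(4, 4, 4)); lab[2, 2, 2] <- 1L
#' v <- labeled_volume(lab, c(1, 1, 3), c("1" = "CTV_HR"))
#' @export
labeled_volume <- function(labels, spacing, label_names = NULL) {
  if (length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array, got ", length(dim(labels)), " axes")
  if (any(dim(labels) < 1L)) stop("all three axes must have extent >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values in mm")
  vals <- labels[is.finite(labels)]
  if (any(labels != round(labels)) || any(labels < 0))
    stop("labels must be non-negative integers")
  storage.mode(labels) <- "integer"
  if (!is.null(label_names)) label_names <- unlist(label_names)
  structure(
    list(labels = labels, spacing = spacing, label_names = label_names),
    class = "labeled_volume"
  )
}

#' Binary mask on a physical grid
#'
#' @param mask 3D logical array.
#' @param spacing voxel spacing (sx, sy, sz) in mm.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(mask, spacing) {
  if (length(dim(mask)) != 3L) stop("`mask` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values in mm")
  storage.mode(mask) <- "logical"
  if (anyNA(mask)) stop("mask contains NA")
  structure(list(mask = mask, spacing = spacing), class = "binary_mask")
}

#' @export
print.labeled_volume <- function(x, ...) {
  tab <- table(x$labels[x$labels > 0])
  cat("labeled_volume:", paste(dim(x$labels), collapse = "x"),
      "voxels @", paste(signif(x$spacing, 4), collapse = "x"), "mm\n")
  for (l in names(tab)) {
    nm <- if (!is.null(x$label_names) && l %in% names(x$label_names))
      x$label_names[[l]] else "?"
    cat(sprintf("  label %s (%s): %d voxels, %.2f cm^3\n", l, nm, tab[[l]],
                tab[[l]] * voxel_volume(x) / 1000))
  }
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("binary_mask:", paste(dim(x$mask), collapse = "x"), "voxels @",
      paste(signif(x$spacing, 4), collapse = "x"), "mm;",
      sum(x$mask), "foreground\n")
  invisible(x)
}

#' Volume of one voxel in mm^3
#' @param x a `labeled_volume`, `binary_mask` or spacing vector.
#' @return sx*sy*sz in mm^3.
#' @export
voxel_volume <- function(x) {
  sp <- if (is.numeric(x)) x else x$spacing
  prod(sp)
}

grid_shape <- function(x) {
  if (inherits(x, "labeled_volume")) dim(x$labels)
  else if (inherits(x, "binary_mask")) dim(x$mask)
  else if (inherits(x, "distance_map")) dim(x$dist)
  else if (inherits(x, "dp_map")) dim(x$penalty)
  else if (inherits(x, "dose_grid")) dim(x$dose)
  else stop("no grid for class ", paste(class(x), collapse = "/"))
}

#' Read a label map from a NIfTI file
#'
#' Voxel data must be integer-valued; the spacing is taken from the header
#' pixdim. If a JSON sidecar `<path minus extension>.json` exists it is read
#' as the label-name map. A non-diagonal orientation is ignored with a
#' warning, because every computation here depends only on relative
#' distances on the grid.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a [labeled_volume()].
#' @export
read_labelmap <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  dm <- dim(arr)
  if (length(dm) == 4L && dm[4] == 1L) dm <- dm[1:3]
  arr <- array(as.vector(arr), dm)  # plain array, no image attributes
  if (length(dim(arr)) != 3L)
    stop("expected a 3D image, got ", length(dim(arr)), " axes: ", path)
  if (any(arr != round(arr)))
    stop("non-integer voxel data; not a label map: ", path)
  xf <- try(RNifti::xform(img), silent = TRUE)
  if (!inherits(xf, "try-error")) {
    rot <- xf[1:3, 1:3]
    if (any(abs(rot[row(rot) != col(rot)]) > 1e-4))
      warning("non-diagonal NIfTI affine ignored; only pixdim spacing is used")
  }
  sp <- abs(RNifti::pixdim(img)[1:3])
  names <- NULL
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (side != path && file.exists(side)) {
    names <- unlist(jsonlite::read_json(side))
  }
  labeled_volume(arr, sp, names)
}

#' Write a label map to a NIfTI file
#'
#' Re-reading the file recovers the labels exactly and the spacing to
#' header float precision. Label names, if present, go to a JSON sidecar.
#'
#' @param vol a [labeled_volume()].
#' @param path destination `.nii` or `.nii.gz` path; parent must exist.
#' @param sidecar write the label-name JSON sidecar if `vol` has names.
#' @return `path`, invisibly.
#' @export
write_labelmap <- function(vol, path, sidecar = TRUE) {
  stopifnot(inherits(vol, "labeled_volume"))
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  img <- RNifti::asNifti(vol$labels)
  img <- RNifti::`pixdim<-`(img, vol$spacing)
  RNifti::writeNifti(img, path, datatype = "int16")
  if (sidecar && !is.null(vol$label_names)) {
    side <- sub("\\.nii(\\.gz)?$", ".json", path)
    jsonlite::write_json(as.list(vol$label_names), side, auto_unbox = TRUE)
  }
  invisible(path)
}

#' Extract one structure as a binary mask
#'
#' @param vol a [labeled_volume()].
#' @param label integer label value (or structure name if `vol` carries
#'   label names).
#' @param strict error if the label is absent from the map (default);
#'   `FALSE` returns an all-false mask.
#' @return a [binary_mask()] with the volume's spacing.
#' @export
extract_binary <- function(vol, label, strict = TRUE) {
  stopifnot(inherits(vol, "labeled_volume"))
  if (is.character(label)) {
    if (is.null(vol$label_names) || !(label %in% vol$label_names))
      stop("unknown structure name '", label, "'")
    label <- as.integer(names(vol$label_names)[match(label, vol$label_names)])
  }
  label <- as.integer(label)
  present <- sort(unique(as.vector(vol$labels)))
  if (strict && !(label %in% present))
    stop("label ", label, " not in map; available: ",
         paste(present, collapse = ", "))
  binary_mask(vol$labels == label, vol$spacing)
}

#' Check two volumes share a grid
#'
#' All metric, loss and dose operations require both inputs on one grid:
#' identical shapes and spacings equal within `tol` mm. No resampling is
#' provided.
#'
#' @param a,b `binary_mask` or `labeled_volume` objects.
#' @param tol spacing tolerance in mm.
#' @return `TRUE` invisibly; errors on mismatch.
#' @export
validate_pair <- function(a, b, tol = 1e-6) {
  da <- grid_shape(a); db <- grid_shape(b)
  sa <- a$spacing; sb <- b$spacing
  if (!identical(as.integer(da), as.integer(db)))
    stop("grid shapes differ: (", paste(da, collapse = ","), ") vs (",
         paste(db, collapse = ","), ")")
  if (any(abs(sa - sb) > tol))
    stop("voxel spacings differ beyond ", tol, " mm: (",
         paste(sa, collapse = ","), ") vs (", paste(sb, collapse = ","), ")")
  invisible(TRUE)
}
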