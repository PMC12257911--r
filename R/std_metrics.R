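shift3 <- function(m, axis, dir) {
  # shift a 3D logical array by one voxel along `axis`, padding with FALSE
  dm <- dim(m)
  out <- array(FALSE, dm)
  idx <- lapply(dm, seq_len)
  src <- idx; dst <- idx
  if (dir > 0) {
    src[[axis]] <- seq_len(dm[axis] - 1L)
    dst[[axis]] <- seq_len(dm[axis] - 1L) + 1L
  } else {
    src[[axis]] <- seq_len(dm[axis] - 1L) + 1L
    dst[[axis]] <- seq_len(dm[axis] - 1L)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

#' Extract the boundary surface of a binary mask
#'
#' The surface is the set of voxel faces separating a foreground voxel
#' from a background (or out-of-grid) voxel. Each face is represented by
#' its centre point in physical mm and carries its physical area, so that
#' surface metrics can weight by area on anisotropic grids.
#'
#' @param M a non-empty [binary_mask()].
#' @return object of class `surface_set`: `points` (n x 3 matrix, mm),
#'   `areas` (mm^2), `spacing`.
#' @export
extract_surface <- function(M) {
  stopifnot(inherits(M, "binary_mask"))
  if (!any(M$mask)) stop("cannot extract the surface of an empty mask")
  m <- M$mask
  sp <- M$spacing
  face_area <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  pts <- vector("list", 6L)
  areas <- vector("list", 6L)
  k <- 0L
  for (axis in 1:3) for (dir in c(-1L, 1L)) {
    k <- k + 1L
    # face present where the voxel is set and its `dir` neighbour is not
    nb_inside <- shift3(m, axis, -dir)  # neighbour value seen from each voxel
    face <- m & !nb_inside
    if (!any(face)) next
    idx <- which(face, arr.ind = TRUE)
    ctr <- sweep(idx - 1, 2, sp, "*")
    ctr[, axis] <- ctr[, axis] + dir * sp[axis] / 2
    pts[[k]] <- ctr
    areas[[k]] <- rep(face_area[axis], nrow(idx))
  }
  structure(
    list(points = do.call(rbind, pts[!vapply(pts, is.null, TRUE)]),
         areas = unlist(areas), spacing = sp),
    class = "surface_set"
  )
}

#' @export
print.surface_set <- function(x, ...) {
  cat("surface_set:", nrow(x$points), "faces, total area",
      signif(sum(x$areas), 5), "mm^2\n")
  invisible(x)
}

# directed nearest-surface distances between two masks, with face areas
surface_distances <- function(G, P) {
  sg <- extract_surface(G)
  sp_ <- extract_surface(P)
  list(
    d_gp = as.numeric(cpp_nn_dist(sg$points, sp_$points)),
    d_pg = as.numeric(cpp_nn_dist(sp_$points, sg$points)),
    a_g = sg$areas, a_p = sp_$areas
  )
}

# quantile of a weighted sample: tied values are merged (weights summed),
# then midpoint-cumulative linear interpolation; order-invariant
weighted_quantile <- function(x, w, p) {
  w <- vapply(split(w, x), sum, numeric(1))
  x <- sort(unique(x))
  if (length(x) == 1L) return(x)
  cw <- (cumsum(w) - w / 2) / sum(w)
  if (p <= cw[1]) return(x[1])
  if (p >= cw[length(cw)]) return(x[length(x)])
  unname(approx(cw, x, xout = p, ties = "ordered")$y)
}

#' Volumetric Dice similarity coefficient
#'
#' `2 |G n P| / (|G| + |P|)` over voxel counts. If exactly one mask is
#' empty the score is 0; two empty masks leave the coefficient undefined
#' and raise an error.
#'
#' @param G,P ground-truth and predicted [binary_mask()]s on one grid.
#' @return value in \[0, 1\].
#' @export
vdsc <- function(G, P) {
  validate_pair(G, P)
  ng <- sum(G$mask); np <- sum(P$mask)
  if (ng == 0L && np == 0L)
    stop("vDSC undefined: both masks are empty")
  if (ng == 0L || np == 0L) return(0)
  2 * sum(G$mask & P$mask) / (ng + np)
}

#' 95th-percentile Hausdorff distance (mm)
#'
#' The maximum of the two directed 95th-percentile nearest-surface
#' distances (G to P and P to G). Percentiles are taken over the
#' area-weighted distribution of boundary-face distances with linear
#' interpolation.
#'
#' @param G,P non-empty [binary_mask()]s on one grid.
#' @param probs percentile, default 0.95 (1 gives the plain Hausdorff
#'   distance).
#' @return distance in mm.
#' @export
hd95 <- function(G, P, probs = 0.95) {
  validate_pair(G, P)
  if (!any(G$mask) || !any(P$mask))
    stop("HD95 undefined for an empty mask")
  sd <- surface_distances(G, P)
  max(weighted_quantile(sd$d_gp, sd$a_g, probs),
      weighted_quantile(sd$d_pg, sd$a_p, probs))
}

#' Average symmetric surface distance (mm)
#'
#' Area-weighted mean of all directed nearest-surface distances pooled
#' over both directions.
#'
#' @param G,P non-empty [binary_mask()]s on one grid.
#' @return distance in mm.
#' @export
assd <- function(G, P) {
  validate_pair(G, P)
  if (!any(G$mask) || !any(P$mask))
    stop("ASSD undefined for an empty mask")
  sd <- surface_distances(G, P)
  (sum(sd$d_gp * sd$a_g) + sum(sd$d_pg * sd$a_p)) /
    (sum(sd$a_g) + sum(sd$a_p))
}

#' Surface Dice similarity coefficient at a distance tolerance
#'
#' The fraction of combined boundary area lying within `tol` mm of the
#' other boundary — the Dice formula applied to surfaces with an
#' agreement tolerance (default 1 mm).
#'
#' @param G,P non-empty [binary_mask()]s on one grid.
#' @param tol agreement tolerance in mm, > 0.
#' @return value in \[0, 1\].
#' @export
sdsc <- function(G, P, tol = 1.0) {
  validate_pair(G, P)
  if (tol <= 0) stop("`tol` must be positive (mm)")
  if (!any(G$mask) || !any(P$mask)) {
    if (!any(G$mask) && !any(P$mask)) stop("sDSC undefined: both masks empty")
    return(0)
  }
  sd <- surface_distances(G, P)
  (sum(sd$a_g[sd$d_gp <= tol]) + sum(sd$a_p[sd$d_pg <= tol])) /
    (sum(sd$a_g) + sum(sd$a_p))
}

# in-plane (axial) contour pixels: mask pixels with at least one of their
# 8 in-plane neighbours background or outside the grid
contour_pixels <- function(m) {
  dm <- dim(m)
  all_nb <- array(TRUE, dm)
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0L && dy == 0L) next
    sh <- m
    if (dx != 0L) sh <- shift3(sh, 1L, dx)
    if (dy != 0L) sh <- shift3(sh, 2L, dy)
    all_nb <- all_nb & sh
  }
  m & !all_nb
}

#' Added path length (cm)
#'
#' The length of ground-truth contour absent from the prediction: per
#' axial slice, the count of GT contour pixels (8-connected in-plane
#' boundary) whose position is not a prediction contour pixel, scaled by
#' the mean in-plane pixel size and reported in cm. A proxy for the
#' contour length a clinician must redraw; intentionally asymmetric
#' (GT-referenced). An empty prediction yields the full GT contour length.
#'
#' @param G non-empty ground-truth [binary_mask()].
#' @param P predicted [binary_mask()] on the same grid (may be empty).
#' @return length in cm.
#' @export
apl <- function(G, P) {
  validate_pair(G, P)
  if (!any(G$mask)) stop("APL undefined for an empty ground truth")
  cg <- contour_pixels(G$mask)
  cp <- if (any(P$mask)) contour_pixels(P$mask) else array(FALSE, dim(P$mask))
  n_missing <- sum(cg & !cp)
  n_missing * mean(G$spacing[1:2]) / 10
}

#' All five standard geometric metrics for one structure
#'
#' Computes vDSC, HD95, sDSC, APL and ASSD for a ground-truth/prediction
#' pair. If exactly one mask is empty, the bounded metrics degrade to 0
#' (vDSC, sDSC), APL to the full GT contour length, and the distance
#' metrics (HD95, ASSD) are reported `NA` (genuinely undefined).
#'
#' @param G,P [binary_mask()]s on one grid; `G` non-empty.
#' @param organ structure name recorded in the output row.
#' @param tol sDSC tolerance in mm.
#' @return one-row `data.frame` with columns `organ`, `vdsc`, `hd95`
#'   (mm), `sdsc`, `apl` (cm), `assd` (mm).
#' @export
metric_report <- function(G, P, organ = "organ", tol = 1.0) {
  validate_pair(G, P)
  if (!any(G$mask)) stop("metric_report requires a non-empty ground truth")
  if (!any(P$mask)) {
    return(data.frame(organ = organ, vdsc = 0, hd95 = NA_real_, sdsc = 0,
                      apl = apl(G, P), assd = NA_real_))
  }
  data.frame(
    organ = organ,
    vdsc = vdsc(G, P),
    hd95 = hd95(G, P),
    sdsc = sdsc(G, P, tol = tol),
    apl = apl(G, P),
    assd = assd(G, P)
  )
}
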