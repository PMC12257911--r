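# physical voxel-centre coordinate grids, mm
coord_grids <- function(shape, spacing) {
  list(x = (seq_len(shape[1]) - 1) * spacing[1],
       y = (seq_len(shape[2]) - 1) * spacing[2],
       z = (seq_len(shape[3]) - 1) * spacing[3])
}

rasterize_ellipsoid <- function(center, semi, shape, spacing) {
  g <- coord_grids(shape, spacing)
  q <- outer(outer(((g$x - center[1]) / semi[1])^2,
                   ((g$y - center[2]) / semi[2])^2, "+"),
             ((g$z - center[3]) / semi[3])^2, "+")
  q <= 1
}

rasterize_sphere <- function(center, radius, shape, spacing) {
  rasterize_ellipsoid(center, rep(radius, 3), shape, spacing)
}

# squared distance from every voxel centre to the segment p0-p1
seg_dist2 <- function(p0, p1, shape, spacing) {
  g <- coord_grids(shape, spacing)
  d <- p1 - p0
  len2 <- sum(d^2)
  X <- array(rep(g$x, times = shape[2] * shape[3]), shape)
  Y <- array(rep(rep(g$y, each = shape[1]), times = shape[3]), shape)
  Z <- array(rep(g$z, each = shape[1] * shape[2]), shape)
  if (len2 == 0) {
    return((X - p0[1])^2 + (Y - p0[2])^2 + (Z - p0[3])^2)
  }
  t <- ((X - p0[1]) * d[1] + (Y - p0[2]) * d[2] + (Z - p0[3]) * d[3]) / len2
  t <- pmin(pmax(t, 0), 1)
  (X - p0[1] - t * d[1])^2 + (Y - p0[2] - t * d[2])^2 +
    (Z - p0[3] - t * d[3])^2
}

# tube of given radius around a polyline (n x 3 matrix of mm points)
rasterize_tube <- function(points, radius, shape, spacing) {
  m <- array(FALSE, shape)
  for (i in seq_len(nrow(points) - 1L)) {
    m <- m | (seg_dist2(points[i, ], points[i + 1L, ], shape, spacing) <=
                radius^2)
  }
  m
}

rasterize_blobs <- function(centers, radius, shape, spacing) {
  m <- array(FALSE, shape)
  for (i in seq_len(nrow(centers)))
    m <- m | rasterize_sphere(centers[i, ], radius, shape, spacing)
  m
}

polyline_length <- function(points) {
  sum(sqrt(rowSums((points[-1, , drop = FALSE] -
                      points[-nrow(points), , drop = FALSE])^2)))
}

#' Specification of a pelvic-like synthetic phantom
#'
#' Defines a small target (CTV_HR analogue, an ellipsoid) surrounded by
#' geometric organ analogues: a spherical bladder and a straight rectal
#' tube abutting the target (~2 mm gap), a curved sigmoid tube at
#' intermediate distance, and a distant small-bowel blob chain. The
#' default grid is 80 x 80 x 28 voxels at 1 x 1 x 3 mm, echoing the
#' anisotropy of clinical pelvic MR while staying desk-scale. The seed
#' jitters organ positions by up to `jitter_mm` in-plane, so distinct
#' seeds give distinct but structurally identical cases.
#'
#' @param grid_shape 3 integers.
#' @param spacing voxel spacing mm.
#' @param seed integer driving the deterministic jitter.
#' @param jitter_mm maximum absolute in-plane organ displacement.
#' @param ctv list with `center` (mm) and `semi_axes` (mm); defaults to a
#'   10 x 10 x 14 mm ellipsoid at the grid centre.
#' @param n_dwells number of source dwells along the target axis.
#' @param dwell_strength per-dwell strength, Gy mm^2.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(80L, 80L, 28L),
                         spacing = c(1, 1, 3),
                         seed = 1L,
                         jitter_mm = 2,
                         ctv = NULL,
                         n_dwells = 5L,
                         dwell_strength = 500) {
  grid_shape <- as.integer(grid_shape)
  spacing <- as.numeric(spacing)
  ext <- (grid_shape - 1) * spacing
  if (is.null(ctv))
    ctv <- list(center = ext / 2, semi_axes = c(10, 10, 14))
  ctr <- ctv$center
  organs <- list(
    list(name = "bladder", primitive = "sphere", abutting = TRUE,
         params = list(center = ctr + c(0, 24, 0), radius = 12)),
    list(name = "rectum", primitive = "tube", abutting = TRUE,
         params = list(points = rbind(ctr + c(0, -19, -ext[3] / 2 + 6),
                                      ctr + c(0, -19, ext[3] / 2 - 6)),
                       radius = 7)),
    list(name = "sigmoid", primitive = "tube", abutting = FALSE,
         params = list(points = local({
           ang <- seq(150, 220, length.out = 5) * pi / 180
           cbind(ctr[1] + 26 * cos(ang), ctr[2] + 26 * sin(ang),
                 seq(ctr[3] + 6, ctr[3] + 24, length.out = 5))
         }), radius = 6)),
    list(name = "small_bowel", primitive = "blobs", abutting = FALSE,
         params = list(centers = rbind(ctr + c(26, 14, 26),
                                       ctr + c(30, 6, 30),
                                       ctr + c(26, -2, 26)),
                       radius = 7))
  )
  structure(
    list(grid_shape = grid_shape, spacing = spacing, seed = as.integer(seed),
         jitter_mm = jitter_mm, ctv = ctv, organs = organs,
         n_dwells = as.integer(n_dwells), dwell_strength = dwell_strength),
    class = "phantom_spec"
  )
}

# analytic volume of an organ primitive, mm^3 (rasterization target)
primitive_volume <- function(organ) {
  p <- organ$params
  switch(organ$primitive,
         sphere = 4 / 3 * pi * p$radius^3,
         tube = polyline_length(p$points) * pi * p$radius^2 +
           4 / 3 * pi * p$radius^3,  # hemispherical caps from segment dist
         blobs = nrow(p$centers) * 4 / 3 * pi * p$radius^3,
         stop("unknown primitive ", organ$primitive))
}

shift_organ <- function(organ, delta) {
  p <- organ$params
  if (!is.null(p$center)) p$center <- p$center + delta
  if (!is.null(p$points)) p$points <- sweep(p$points, 2, delta, "+")
  if (!is.null(p$centers)) p$centers <- sweep(p$centers, 2, delta, "+")
  organ$params <- p
  organ
}

rasterize_organ <- function(organ, shape, spacing) {
  p <- organ$params
  switch(organ$primitive,
         sphere = rasterize_sphere(p$center, p$radius, shape, spacing),
         tube = rasterize_tube(p$points, p$radius, shape, spacing),
         blobs = rasterize_blobs(p$centers, p$radius, shape, spacing))
}

#' Generate a synthetic phantom label map with source dwells
#'
#' Rasterizes the target (label 1) and organ analogues (labels 2..5) of a
#' [phantom_spec()] into one mutually exclusive label map and places
#' equally spaced source dwells along the target's superior-inferior
#' axis. Deterministic for a given spec (the spec's seed drives the organ
#' jitter). Voxels claimed by an earlier structure are never overwritten;
#' if that trimming removes more than 20% of a primitive, or the
#' rasterized volume strays more than 20% from the primitive's analytic
#' volume, generation fails naming the offending pair.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `phantom`: `volume` (a [labeled_volume()]),
#'   `dwells` (list of [source_dwell()]), `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$grid_shape; sp <- spec$spacing
  set.seed(spec$seed)
  labels <- array(0L, shape)
  ctv_mask <- rasterize_ellipsoid(spec$ctv$center, spec$ctv$semi_axes,
                                  shape, sp)
  if (!any(ctv_mask)) stop("CTV primitive does not fit the grid")
  labels[ctv_mask] <- 1L
  label_names <- c("1" = "CTV_HR")
  taken_by <- c("CTV_HR")
  for (i in seq_along(spec$organs)) {
    org <- spec$organs[[i]]
    delta <- c(runif(2, -spec$jitter_mm, spec$jitter_mm), 0)
    org <- shift_organ(org, delta)
    raw <- rasterize_organ(org, shape, sp)
    if (!any(raw)) stop("organ '", org$name, "' does not fit the grid")
    free <- raw & labels == 0L
    trim <- 1 - sum(free) / sum(raw)
    if (trim > 0.2) {
      clash <- names(which.max(table(labels[raw & labels != 0L])))
      stop("organ '", org$name, "' overlaps '",
           label_names[clash], "' beyond resolution (", round(trim * 100),
           "% trimmed)")
    }
    vol_mm3 <- sum(free) * prod(sp)
    target <- primitive_volume(org)
    if (abs(vol_mm3 - target) / target > 0.2)
      stop("organ '", org$name, "' rasterized volume ",
           round(vol_mm3), " mm^3 deviates > 20% from target ",
           round(target), " mm^3")
    lab <- i + 1L
    labels[free] <- lab
    label_names[as.character(lab)] <- org$name
  }
  vol <- labeled_volume(labels, sp, label_names)
  zc <- spec$ctv$center[3]
  span <- 0.6 * spec$ctv$semi_axes[3]
  zs <- if (spec$n_dwells == 1L) zc else
    seq(zc - span, zc + span, length.out = spec$n_dwells)
  dwells <- lapply(zs, function(z)
    source_dwell(c(spec$ctv$center[1:2], z), spec$dwell_strength))
  structure(list(volume = vol, dwells = dwells, spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat("phantom (seed", x$spec$seed, "):\n")
  print(x$volume)
  cat(" ", length(x$dwells), "dwells of", x$spec$dwell_strength,
      "Gy mm^2 along the target axis\n")
  invisible(x)
}

any_neighbor6 <- function(m) {
  out <- array(FALSE, dim(m))
  for (axis in 1:3) for (dir in c(-1L, 1L))
    out <- out | shift3(m, axis, dir)
  out
}

#' Specification of a contour perturbation
#'
#' Describes how to corrupt one organ of a ground-truth label map into a
#' synthetic "prediction": what fraction of the organ volume to flip,
#' whether the flipped voxels sit near to or far from the target (or
#' anywhere), and whether they are removed from the organ (`erode`),
#' added around it (`dilate`), or both in equal parts (`transfer`).
#'
#' @param error_volume_frac fraction of the organ's voxel count to flip,
#'   in \[0, 1).
#' @param band `"near"`, `"far"` or `"uniform"`: place errors at the
#'   candidate voxels closest to the target, farthest from it, or
#'   anywhere.
#' @param mode `"erode"`, `"dilate"` or `"transfer"`.
#' @param seed integer for the deterministic tie-break / sampling.
#' @return object of class `perturb_spec`.
#' @export
perturb_spec <- function(error_volume_frac = 0.05,
                         band = c("near", "far", "uniform"),
                         mode = c("erode", "dilate", "transfer"),
                         seed = 1L) {
  band <- match.arg(band)
  mode <- match.arg(mode)
  if (error_volume_frac < 0 || error_volume_frac >= 1)
    stop("`error_volume_frac` must be in [0, 1)")
  structure(list(error_volume_frac = error_volume_frac, band = band,
                 mode = mode, seed = as.integer(seed)),
            class = "perturb_spec")
}

# pick k flips from candidate linear indices ordered by distance band
pick_band <- function(cand_idx, dist_vals, k, band) {
  o <- switch(band,
              near = order(dist_vals, runif(length(cand_idx))),
              far = order(-dist_vals, runif(length(cand_idx))),
              uniform = sample.int(length(cand_idx)))
  cand_idx[o[seq_len(k)]]
}

#' Perturb one organ of a ground-truth label map
#'
#' Builds a synthetic predicted contour set: identical to the ground
#' truth except for the requested organ, where `error_volume_frac` of the
#' organ's voxels are flipped at its 6-connected boundary, inside the
#' requested distance band relative to the target (label 1). Erosion
#' removes organ boundary voxels; dilation adds adjacent background
#' voxels (never stealing another structure's voxels), growing ring by
#' ring if one ring holds too few candidates.
#'
#' @param gt ground-truth [labeled_volume()] with the target as label 1.
#' @param organ organ name (requires label names) or integer label.
#' @param pspec a [perturb_spec()].
#' @param dmap optional precomputed [euclidean_distance_map()] of the
#'   target.
#' @return list: `prediction` (a [labeled_volume()]), `organ`,
#'   `n_flipped`, `n_requested`, `mean_error_dist` (mm), `band`, `mode`.
#' @export
perturb_prediction <- function(gt, organ, pspec, dmap = NULL) {
  stopifnot(inherits(gt, "labeled_volume"), inherits(pspec, "perturb_spec"))
  if (is.character(organ)) {
    if (is.null(gt$label_names) || !(organ %in% gt$label_names))
      stop("unknown organ '", organ, "'")
    lab <- as.integer(names(gt$label_names)[match(organ, gt$label_names)])
  } else lab <- as.integer(organ)
  if (!any(gt$labels == lab)) stop("organ label ", lab, " absent from map")
  if (is.null(dmap))
    dmap <- euclidean_distance_map(extract_binary(gt, 1L))
  o <- gt$labels == lab
  n_org <- sum(o)
  k <- round(pspec$error_volume_frac * n_org)
  labels <- gt$labels
  set.seed(pspec$seed)
  flipped <- integer(0)
  flip_set <- function(mask_cand, k_want, band) {
    idx <- which(mask_cand)
    if (length(idx) < k_want)
      stop("band contains too few candidate voxels: need ", k_want,
           ", achievable maximum ", length(idx))
    pick_band(idx, dmap$dist[idx], k_want, band)
  }
  if (k > 0) {
    if (pspec$mode %in% c("erode", "transfer")) {
      ke <- if (pspec$mode == "erode") k else k %/% 2
      if (ke > 0) {
        cand <- o & !(
          shift3(o, 1, 1) & shift3(o, 1, -1) & shift3(o, 2, 1) &
            shift3(o, 2, -1) & shift3(o, 3, 1) & shift3(o, 3, -1))
        if (sum(cand) < ke) cand <- o  # fall back to the whole organ
        sel <- flip_set(cand, ke, pspec$band)
        labels[sel] <- 0L
        flipped <- c(flipped, sel)
      }
    }
    if (pspec$mode %in% c("dilate", "transfer")) {
      kd <- if (pspec$mode == "dilate") k else k - k %/% 2
      if (kd > 0) {
        ring <- labels == 0L & any_neighbor6(o)
        grown <- o
        tries <- 0L
        while (sum(ring) < kd && tries < 5L) {
          grown <- grown | ring
          ring <- ring | (labels == 0L & any_neighbor6(grown))
          tries <- tries + 1L
        }
        sel <- flip_set(ring, kd, pspec$band)
        labels[sel] <- lab
        flipped <- c(flipped, sel)
      }
    }
  }
  pred <- labeled_volume(labels, gt$spacing, gt$label_names)
  list(prediction = pred, organ = organ, n_flipped = length(flipped),
       n_requested = k,
       mean_error_dist = if (length(flipped)) mean(dmap$dist[flipped])
       else NA_real_,
       band = pspec$band, mode = pspec$mode)
}
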