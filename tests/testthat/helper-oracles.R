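# Independent brute-force oracles. Deliberately naive: explicit loops and
# set arithmetic, sharing no code with the package internals.

random_mask <- function(shape, p = 0.3, seed = 1) {
  set.seed(seed)
  array(runif(prod(shape)) < p, shape)
}

# a random blob-ish mask guaranteed non-empty
random_blob <- function(shape, seed = 1, n_seeds = 2, radius = 2) {
  set.seed(seed)
  m <- array(FALSE, shape)
  for (s in seq_len(n_seeds)) {
    c0 <- sapply(shape, function(n) sample.int(n, 1))
    for (i in seq_len(shape[1])) for (j in seq_len(shape[2]))
      for (k in seq_len(shape[3])) {
        if (sum((c(i, j, k) - c0)^2) <= radius^2) m[i, j, k] <- TRUE
      }
  }
  if (!any(m)) m[c0[1], c0[2], c0[3]] <- TRUE
  m
}

# exact EDT by all-pairs minimum over target voxels
bf_edt <- function(mask, spacing) {
  tg <- which(mask, arr.ind = TRUE)
  out <- array(NA_real_, dim(mask))
  for (i in seq_len(dim(mask)[1])) for (j in seq_len(dim(mask)[2]))
    for (k in seq_len(dim(mask)[3])) {
      d2 <- (tg[, 1] - i)^2 * spacing[1]^2 + (tg[, 2] - j)^2 * spacing[2]^2 +
        (tg[, 3] - k)^2 * spacing[3]^2
      out[i, j, k] <- sqrt(min(d2))
    }
  out
}

bf_vdsc <- function(g, p) {
  kg <- which(g); kp <- which(p)
  2 * length(intersect(kg, kp)) / (length(kg) + length(kp))
}

# boundary faces by explicit neighbour loops: rows (x, y, z, area)
bf_surface <- function(mask, spacing) {
  dm <- dim(mask)
  rows <- NULL
  farea <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
             spacing[1] * spacing[2])
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2]))
    for (k in seq_len(dm[3])) {
      if (!mask[i, j, k]) next
      for (ax in 1:3) for (dir in c(-1, 1)) {
        nb <- c(i, j, k); nb[ax] <- nb[ax] + dir
        outside <- nb[ax] < 1 || nb[ax] > dm[ax]
        if (outside || !mask[nb[1], nb[2], nb[3]]) {
          ctr <- (c(i, j, k) - 1) * spacing
          ctr[ax] <- ctr[ax] + dir * spacing[ax] / 2
          rows <- rbind(rows, c(ctr, farea[ax]))
        }
      }
    }
  rows
}

bf_nn <- function(a, b) {
  sapply(seq_len(nrow(a)), function(i) {
    sqrt(min((a[i, 1] - b[, 1])^2 + (a[i, 2] - b[, 2])^2 +
               (a[i, 3] - b[, 3])^2))
  })
}

bf_wquantile <- function(x, w, p) {
  # merge tied values by explicit accumulation, then interpolate
  xs <- sort(unique(x))
  ws <- numeric(length(xs))
  for (i in seq_along(xs)) ws[i] <- sum(w[x == xs[i]])
  x <- xs; w <- ws
  if (length(x) == 1) return(x)
  cf <- (cumsum(w) - w / 2) / sum(w)
  if (p <= cf[1]) return(x[1])
  if (p >= cf[length(cf)]) return(x[length(x)])
  hi <- which(cf >= p)[1]
  lo <- hi - 1
  x[lo] + (p - cf[lo]) / (cf[hi] - cf[lo]) * (x[hi] - x[lo])
}

bf_surface_metrics <- function(gm, pm, spacing, tol = 1) {
  sg <- bf_surface(gm, spacing)
  sp_ <- bf_surface(pm, spacing)
  dgp <- bf_nn(sg[, 1:3, drop = FALSE], sp_[, 1:3, drop = FALSE])
  dpg <- bf_nn(sp_[, 1:3, drop = FALSE], sg[, 1:3, drop = FALSE])
  ag <- sg[, 4]; ap <- sp_[, 4]
  list(
    hd95 = max(bf_wquantile(dgp, ag, 0.95), bf_wquantile(dpg, ap, 0.95)),
    assd = (sum(dgp * ag) + sum(dpg * ap)) / (sum(ag) + sum(ap)),
    sdsc = (sum(ag[dgp <= tol]) + sum(ap[dpg <= tol])) / (sum(ag) + sum(ap))
  )
}

# slice-wise APL with 8-connected contour pixels, in cm
bf_apl <- function(gm, pm, spacing) {
  dm <- dim(gm)
  is_contour <- function(m, i, j) {
    if (!m[i, j]) return(FALSE)
    for (dx in -1:1) for (dy in -1:1) {
      if (dx == 0 && dy == 0) next
      ii <- i + dx; jj <- j + dy
      if (ii < 1 || ii > nrow(m) || jj < 1 || jj > ncol(m)) return(TRUE)
      if (!m[ii, jj]) return(TRUE)
    }
    FALSE
  }
  count <- 0
  for (k in seq_len(dm[3])) {
    g2 <- gm[, , k]; p2 <- pm[, , k]
    for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) {
      if (is_contour(g2, i, j) && !is_contour(p2, i, j)) count <- count + 1
    }
  }
  count * mean(spacing[1:2]) / 10
}

# wDSC by materializing each nested crop explicitly
bf_wdsc <- function(gm, pm, dist, n_crops) {
  r_max <- max(dist)
  total <- 0
  for (i in seq_len(n_crops)) {
    ci <- if (i == 1) Inf else r_max * (n_crops - i + 1) / n_crops
    sel <- dist <= ci
    gi <- gm & sel; pi_ <- pm & sel
    v <- if (!any(gi) && !any(pi_)) 1
    else if (!any(gi) || !any(pi_)) 0
    else 2 * sum(gi & pi_) / (sum(gi) + sum(pi_))
    total <- total + (i / n_crops) * (1 - v)
  }
  1 - total / n_crops
}

bf_d2cc <- function(doses, vox_mm3, target_mm3 = 2000) {
  d <- sort(doses, decreasing = TRUE)
  acc <- 0
  for (i in seq_along(d)) {
    acc <- acc + vox_mm3
    if (acc >= target_mm3) return(d[i])
  }
  d[length(d)]
}

bf_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# exact two-sided signed-rank p by recursive sign enumeration
bf_wilcoxon_p <- function(a, b) {
  d <- (a - b)[a != b]
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  n <- length(d)
  vs <- numeric(0)
  enumerate <- function(i, acc) {
    if (i > n) { vs <<- c(vs, acc); return(invisible()) }
    enumerate(i + 1, acc)
    enumerate(i + 1, acc + r[i])
  }
  enumerate(1, 0)
  min(1, 2 * min(mean(vs >= v_obs), mean(vs <= v_obs)))
}
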