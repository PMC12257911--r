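#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length `n >= 3`, both
#'   non-constant.
#' @return correlation in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant input")
  cor(x, y)
}

#' Simple least-squares line fit
#'
#' @param x,y numeric vectors, `n >= 3`, `x` non-constant.
#' @return list with `slope`, `intercept`, `r_squared`, `n`. For a simple
#'   fit `r_squared` equals the squared Pearson correlation.
#' @export
ols_fit <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0) stop("degenerate fit: `x` is constant")
  fit <- lm(y ~ x)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = summary(fit)$r.squared, n = length(x))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped; ties receive mid-ranks. For up to
#' `exact_max` non-zero differences the p-value comes from the exact null
#' distribution (all `2^n` sign assignments of the observed ranks);
#' beyond that, a normal approximation with tie-corrected variance and a
#' continuity correction of 1/2 is used. The statistic is `V`, the rank
#' sum of the positive differences.
#'
#' @param a,b paired numeric vectors.
#' @param two_sided two-sided p (default); `FALSE` gives the one-sided
#'   p for the alternative `a > b`.
#' @param exact_max largest `n` for which the exact distribution is
#'   enumerated.
#' @return list with `statistic`, `p_value`, `n` (non-zero differences),
#'   `method`.
#' @export
wilcoxon_signed_rank <- function(a, b, two_sided = TRUE, exact_max = 12L) {
  if (length(a) != length(b)) stop("`a` and `b` must have equal length")
  d <- a - b
  d <- d[is.finite(d) & d != 0]
  n <- length(d)
  if (n == 0L) stop("all paired differences are zero; no information")
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_max) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- as.vector(signs %*% r)
    p_ge <- mean(w_all >= v)
    p_le <- mean(w_all <= v)
    p <- if (two_sided) min(1, 2 * min(p_ge, p_le)) else p_ge
    method <- "exact"
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2)) / 2
    cc <- 0.5 * sign(v - mu)
    z <- (v - mu - cc) / sigma
    p <- if (two_sided) 2 * pnorm(-abs(z)) else pnorm(-z)
    p <- min(1, p)
    method <- "normal approximation"
  }
  list(statistic = v, p_value = p, n = n, method = method)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha family-wise level in (0, 1).
#' @param m number of comparisons, >= 1.
#' @return `alpha / m` (0.05 over 8 comparisons gives 0.00625).
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 1L) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("`alpha` must be in (0, 1)")
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("`m` must be a positive integer")
  alpha / m
}

study_metrics <- c("wdsc", "vdsc", "hd95", "sdsc", "apl", "assd")

#' Run the synthetic metric-vs-dosimetry correlation study
#'
#' Generates a cohort of seeded phantoms; for each case and organ,
#' builds paired near-band and far-band predicted contours of matched
#' error volume, evaluates the six geometric metrics (wDSC + the five
#' standard ones) and the absolute D2cm3 difference under the surrogate
#' dose engine, then pools all records to correlate each metric with
#' dosimetric accuracy and runs paired Wilcoxon signed-rank tests
#' (near vs far condition) for wDSC and vDSC per organ, with a
#' Bonferroni threshold of 0.05 / 8.
#'
#' @param n_cases number of phantom cases (>= 3; 50 by default).
#' @param seed master seed; every downstream random draw derives from
#'   it.
#' @param base_spec the [phantom_spec()] shared by all cases (its seed
#'   field is replaced per case).
#' @param organs organ names to evaluate.
#' @param frac_range range of the per-record error volume fraction,
#'   drawn uniformly.
#' @param mode perturbation mode passed to [perturb_spec()].
#' @param n_crops wDSC crop count.
#' @param verbose print per-case progress to stderr.
#' @return object of class `study_report`: `records` (one row per case x
#'   organ x condition), `correlations` (per metric vs `abs_d2cc_diff`),
#'   `tests` (paired near/far Wilcoxon results), `alpha_threshold`,
#'   `settings`.
#' @export
run_study <- function(n_cases = 50L, seed = 1L, base_spec = phantom_spec(),
                      organs = c("bladder", "rectum", "sigmoid",
                                 "small_bowel"),
                      frac_range = c(0.02, 0.08), mode = "erode",
                      n_crops = 100L, verbose = FALSE) {
  n_cases <- as.integer(n_cases)
  if (n_cases < 3L) stop("need at least 3 cases")
  bands <- c("near", "far")
  set.seed(seed)
  case_seeds <- sample.int(2^20, n_cases)
  pert_seeds <- array(sample.int(2^20, n_cases * length(organs) *
                                   length(bands)),
                      c(n_cases, length(organs), length(bands)))
  fracs <- matrix(runif(n_cases * length(organs), frac_range[1],
                        frac_range[2]), n_cases, length(organs))
  rows <- vector("list", n_cases * length(organs) * length(bands))
  ri <- 0L
  for (ci in seq_len(n_cases)) {
    spec <- base_spec
    spec$seed <- case_seeds[ci]
    ph <- generate_phantom(spec)
    vol <- ph$volume
    dmap <- euclidean_distance_map(extract_binary(vol, 1L))
    dose <- compute_dose(ph$dwells, vol)
    if (verbose)
      message("case ", ci, "/", n_cases, " (seed ", spec$seed, ")")
    for (oi in seq_along(organs)) {
      gt_mask <- extract_binary(vol, organs[oi])
      for (bi in seq_along(bands)) {
        ps <- perturb_spec(error_volume_frac = fracs[ci, oi],
                           band = bands[bi], mode = mode,
                           seed = pert_seeds[ci, oi, bi])
        pert <- perturb_prediction(vol, organs[oi], ps, dmap = dmap)
        pm <- extract_binary(pert$prediction, organs[oi])
        met <- metric_report(gt_mask, pm, organ = organs[oi])
        wd <- wdsc(gt_mask, pm, dmap, n_crops = n_crops)
        dd <- abs_d2cc_diff(pm, gt_mask, dose, organ = organs[oi])
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          case_id = ci, organ = organs[oi], condition = bands[bi],
          wdsc = wd$wdsc, vdsc = met$vdsc, hd95 = met$hd95,
          sdsc = met$sdsc, apl = met$apl, assd = met$assd,
          abs_d2cc_diff = dd$abs_diff, d2cc_ref = dd$d2cc_ref,
          error_frac = fracs[ci, oi], n_flipped = pert$n_flipped,
          mean_error_dist = pert$mean_error_dist
        )
      }
    }
  }
  records <- do.call(rbind, rows)
  correlations <- do.call(rbind, lapply(study_metrics, function(mname) {
    x <- records[[mname]]
    y <- records$abs_d2cc_diff
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 20L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(data.frame(metric = mname, pearson_r = NA_real_,
                        slope = NA_real_, intercept = NA_real_,
                        r_squared = NA_real_, n = sum(ok)))
    fit <- ols_fit(x[ok], y[ok])
    data.frame(metric = mname, pearson_r = pearson_r(x[ok], y[ok]),
               slope = fit$slope, intercept = fit$intercept,
               r_squared = fit$r_squared, n = fit$n)
  }))
  thr <- bonferroni_threshold(0.05, 8L)
  tests <- do.call(rbind, lapply(c("wdsc", "vdsc"), function(mname) {
    do.call(rbind, lapply(organs, function(org) {
      sub <- records[records$organ == org, ]
      near <- sub[sub$condition == "near", ]
      far <- sub[sub$condition == "far", ]
      near <- near[order(near$case_id), ]
      far <- far[order(far$case_id), ]
      res <- tryCatch(wilcoxon_signed_rank(near[[mname]], far[[mname]]),
                      error = function(e) list(statistic = NA_real_,
                                               p_value = NA_real_,
                                               n = 0L, method = "degenerate"))
      data.frame(metric = mname, organ = org, statistic = res$statistic,
                 p_value = res$p_value, n = res$n, method = res$method,
                 significant = !is.na(res$p_value) & res$p_value < thr)
    }))
  }))
  structure(
    list(records = records, correlations = correlations, tests = tests,
         alpha_threshold = thr,
         settings = list(n_cases = n_cases, seed = seed, organs = organs,
                         bands = bands, frac_range = frac_range,
                         mode = mode, n_crops = n_crops,
                         grid_shape = base_spec$grid_shape,
                         spacing = base_spec$spacing)),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat("study_report:", nrow(x$records), "records (",
      x$settings$n_cases, "cases x", length(x$settings$organs),
      "organs x", length(x$settings$bands), "conditions)\n")
  cat("correlations with |D2cm3 difference|:\n")
  print(x$correlations, row.names = FALSE, digits = 3)
  cat("paired near/far Wilcoxon (threshold ", x$alpha_threshold, "):\n",
      sep = "")
  print(x$tests, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write a study report to CSV + JSON files
#'
#' @param report a [run_study()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(report$records, file.path(dir, "records.csv"),
            row.names = FALSE)
  write.csv(report$correlations, file.path(dir, "correlations.csv"),
            row.names = FALSE)
  write.csv(report$tests, file.path(dir, "tests.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(correlations = report$correlations, tests = report$tests,
         alpha_threshold = report$alpha_threshold,
         settings = report$settings),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE
  )
  invisible(dir)
}
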