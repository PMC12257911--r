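#' One-hot label field from a label map
#'
#' Expands an integer label map into a one-hot array with the class axis
#' last: `g[i, j, k, c+1] = 1` iff voxel `(i,j,k)` carries label `c`
#' (class 1 is background, label 0). All classes, background included,
#' enter the loss sums.
#'
#' @param vol a [labeled_volume()] or plain 3D integer array.
#' @param n_classes number of classes `C >= 2`; default `max(label) + 1`.
#' @return object of class `label_field`: `g` (4D 0/1 array), `n_vox`,
#'   `n_classes`.
#' @export
label_field <- function(vol, n_classes = NULL) {
  labs <- if (inherits(vol, "labeled_volume")) vol$labels else vol
  if (length(dim(labs)) != 3L) stop("labels must be a 3D array")
  cmax <- max(labs)
  if (is.null(n_classes)) n_classes <- cmax + 1L
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) stop("need at least 2 classes (background + 1)")
  if (cmax >= n_classes) stop("label ", cmax, " exceeds n_classes - 1")
  nv <- length(labs)
  g <- array(0, c(dim(labs), n_classes))
  g[seq_len(nv) + as.vector(as.numeric(labs)) * nv] <- 1
  structure(list(g = g, n_vox = nv, n_classes = n_classes),
            class = "label_field")
}

#' Per-class probability field
#'
#' Softmax-style per-voxel class probabilities with the class axis last.
#' Each voxel's class vector must sum to 1 within `tol`.
#'
#' @param p 4D array, last axis the `C >= 2` classes.
#' @param tol simplex tolerance.
#' @return object of class `probability_field`.
#' @export
probability_field <- function(p, tol = 1e-6) {
  if (length(dim(p)) != 4L) stop("`p` must be a 4D array (grid x classes)")
  if (dim(p)[4] < 2L) stop("need at least 2 classes")
  if (min(p) < -tol || max(p) > 1 + tol) stop("probabilities outside [0, 1]")
  nv <- prod(dim(p)[1:3])
  rs <- rowSums(matrix(p, nrow = nv))
  if (max(abs(rs - 1)) > tol)
    stop("per-voxel probabilities do not sum to 1 (max deviation ",
         signif(max(abs(rs - 1)), 3), ")")
  structure(list(p = p, n_vox = nv, n_classes = dim(p)[4]),
            class = "probability_field")
}

as_g <- function(x) {
  if (inherits(x, "label_field")) x$g
  else if (is.array(x) && length(dim(x)) == 4L) x
  else stop("expected a label_field or 4D one-hot array")
}

as_p <- function(x) {
  if (inherits(x, "probability_field")) x$p
  else if (is.array(x) && length(dim(x)) == 4L) x
  else stop("expected a probability_field or 4D array")
}

as_D <- function(x) {
  if (inherits(x, "dp_map")) x$penalty
  else if (is.array(x) && length(dim(x)) == 3L) x
  else stop("expected a dp_map or 3D penalty array")
}

check_gp <- function(g, p) {
  if (!identical(dim(g), dim(p)))
    stop("label and probability fields have different shapes")
}

# with the class axis last, a voxel-indexed 3D map recycles correctly
# over classes when multiplied elementwise against a 4D field
check_D <- function(D, g) {
  if (!identical(as.integer(dim(D)), as.integer(dim(g)[1:3])))
    stop("penalty map grid does not match the fields")
}

#' Cross-entropy loss
#'
#' `L_CE = -(1/N) sum_c sum_i g_ic log p_ic` over all voxels and classes.
#' Probabilities are clamped below at `eps` before the log so a confident
#' wrong prediction stays finite.
#'
#' @param g one-hot labels ([label_field()] or 4D array).
#' @param p class probabilities ([probability_field()] or 4D array).
#' @param eps clamp for `log`.
#' @return non-negative scalar.
#' @export
ce_loss <- function(g, p, eps = 1e-7) {
  g <- as_g(g); p <- as_p(p)
  check_gp(g, p)
  n <- prod(dim(g)[1:3])
  -sum(g * log(pmax(p, eps))) / n
}

#' Soft Dice loss (pooled over classes)
#'
#' `L_Dice = 1 - 2 sum_cis g p / (sum g + sum p)`, with the sums pooled
#' jointly over all classes (background included). Under the one-hot and
#' simplex constraints both denominator terms equal the voxel count, so
#' the denominator is `2N`.
#'
#' @inheritParams ce_loss
#' @param foreground_only drop the background class (class 1) from all
#'   sums; off by default to match the pooled definition.
#' @return value in \[0, 1\].
#' @export
dice_loss <- function(g, p, foreground_only = FALSE) {
  g <- as_g(g); p <- as_p(p)
  check_gp(g, p)
  if (foreground_only) {
    keep <- seq_len(dim(g)[4])[-1]
    g <- g[, , , keep, drop = FALSE]
    p <- p[, , , keep, drop = FALSE]
  }
  1 - 2 * sum(g * p) / (sum(g) + sum(p))
}

#' Dice + cross-entropy combo loss
#'
#' @inheritParams ce_loss
#' @return `dice_loss(g, p) + ce_loss(g, p)`.
#' @export
dicece_loss <- function(g, p, eps = 1e-7) {
  dice_loss(g, p) + ce_loss(g, p, eps = eps)
}

#' Distance-penalized cross-entropy loss
#'
#' Cross-entropy with every voxel's error term scaled by the
#' distance-penalty map:
#' `L_DPCE = -(1/N) sum_c sum_i D_i g_ic log p_ic`,
#' the same map `D` (built from the target) applied to every class.
#' Reduces exactly to [ce_loss()] when `D == 1` everywhere; errors close
#' to the target cost more than remote ones.
#'
#' @inheritParams ce_loss
#' @param D the penalty map ([inverse_square_map()] result or 3D array in
#'   \[0,1\]).
#' @return non-negative scalar.
#' @export
dpce_loss <- function(g, p, D, eps = 1e-7) {
  g <- as_g(g); p <- as_p(p); D <- as_D(D)
  check_gp(g, p); check_D(D, g)
  n <- prod(dim(g)[1:3])
  -sum(as.vector(D) * (g * log(pmax(p, eps)))) / n
}

#' Distance-penalized Dice + cross-entropy loss
#'
#' The soft-Dice numerator is distance-weighted while the denominator and
#' the added cross-entropy term are left unweighted:
#' `L_DPDiceCE = 1 - 2 sum D g p / (sum g + sum p) + L_CE`.
#' Reduces exactly to [dicece_loss()] when `D == 1`; since `D <= 1`
#' down-weights the overlap credit, it is always `>=` the unpenalized
#' combo loss.
#'
#' @inheritParams dpce_loss
#' @return scalar.
#' @export
dpdicece_loss <- function(g, p, D, eps = 1e-7) {
  g <- as_g(g); p <- as_p(p); D <- as_D(D)
  check_gp(g, p); check_D(D, g)
  1 - 2 * sum(as.vector(D) * (g * p)) / (sum(g) + sum(p)) +
    ce_loss(g, p, eps = eps)
}

#' Analytic gradient of a loss with respect to the probabilities
#'
#' The contract any training-framework port must satisfy: these partial
#' derivatives match central finite differences of the corresponding loss.
#' The clamp region of the log (`p < eps`) has zero CE gradient.
#'
#' @param g,p as in [ce_loss()].
#' @param loss one of `"ce"`, `"dice"`, `"dicece"`, `"dpce"`,
#'   `"dpdicece"`.
#' @param D penalty map, required for the DP losses.
#' @param eps log clamp.
#' @return 4D array `dL/dp` with the shape of `p`.
#' @export
loss_gradient <- function(g, p, loss = c("ce", "dice", "dicece", "dpce",
                                         "dpdicece"), D = NULL, eps = 1e-7) {
  loss <- match.arg(loss)
  g <- as_g(g); p <- as_p(p)
  check_gp(g, p)
  n <- prod(dim(g)[1:3])
  grad_ce <- function(w) {
    gr <- array(0, dim(p))
    act <- p >= eps  # below the clamp the loss is flat in p
    gr[act] <- -(w * g / pmax(p, eps))[act] / n
    gr
  }
  if (loss == "ce") return(grad_ce(1))
  if (loss == "dpce") {
    D <- as_D(D); check_D(D, g)
    return(grad_ce(as.vector(D)))
  }
  tot <- sum(g) + sum(p)  # d tot / d p_ic = 1
  if (loss == "dice")
    return(array(-2 * g / tot + 2 * sum(g * p) / tot^2, dim(p)))
  if (loss == "dicece")
    return(array(-2 * g / tot + 2 * sum(g * p) / tot^2, dim(p)) + grad_ce(1))
  # dpdicece
  D <- as_D(D); check_D(D, g)
  Dv <- as.vector(D)
  array(-2 * Dv * g / tot + 2 * sum(Dv * (g * p)) / tot^2, dim(p)) +
    grad_ce(1)
}
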