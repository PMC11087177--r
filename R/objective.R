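#' Loss configuration
#'
#' Settings for the combined Dice / cross-entropy training objective:
#' the Dice smoothing constant epsilon (1 by default), the equal 0.5/0.5
#' weighting of the two terms, and the probability floor used to keep the
#' logarithm finite.
#'
#' @param epsilon Dice smoothing constant added to numerator and
#'   denominator; rescues doubly-empty classes.
#' @param weights Length-2 nonnegative weights `(w_ce, w_dice)`.
#' @param prob_floor Lower clip applied to probabilities inside the log.
#' @return A list of class `loss_config`.
#' @export
loss_config <- function(epsilon = 1, weights = c(0.5, 0.5),
                        prob_floor = 1e-7) {
  if (epsilon <= 0) stop("epsilon must be > 0")
  if (length(weights) != 2 || any(weights < 0))
    stop("weights must be two nonnegative numbers")
  structure(list(epsilon = epsilon, weights = weights,
                 prob_floor = prob_floor), class = "loss_config")
}

check_py <- function(p, y) {
  dp <- dim(p)
  dy <- dim(y)
  if (is.null(dp) || is.null(dy) || !identical(dp, dy))
    stop("probability map and one-hot labels must share dimensions ",
         "(lattice and class count)")
  invisible(NULL)
}

#' Voxel-averaged cross-entropy loss
#'
#' `(1/N) sum_i sum_k -y_ik log(p_ik)` over the `N` voxels and `K`
#' classes, with probabilities clipped to `[prob_floor, 1]`.
#'
#' @param p Array of per-voxel class probabilities, class index last.
#' @param y One-hot label array of the same shape.
#' @param cfg A [loss_config()].
#' @return Nonnegative scalar.
#' @export
cross_entropy_loss <- function(p, y, cfg = loss_config()) {
  check_py(p, y)
  nd <- length(dim(p))
  n_vox <- prod(dim(p)[-nd])
  pc <- pmin(pmax(p, cfg$prob_floor), 1)
  sum(-y * log(pc)) / n_vox
}

#' Soft Dice loss
#'
#' `1 - (1/K) sum_k (2 sum_i p_ik y_ik + eps) / (sum_i p_ik + sum_i y_ik
#' + eps)`. With `eps = 1` a class that is empty in both prediction and
#' truth contributes a perfect ratio of 1.
#'
#' @inheritParams cross_entropy_loss
#' @return Scalar in `[0, 1)`.
#' @export
dice_loss <- function(p, y, cfg = loss_config()) {
  check_py(p, y)
  nd <- length(dim(p))
  K <- dim(p)[nd]
  pm <- matrix(p, ncol = K)
  ym <- matrix(y, ncol = K)
  num <- 2 * colSums(pm * ym) + cfg$epsilon
  den <- colSums(pm) + colSums(ym) + cfg$epsilon
  1 - mean(num / den)
}

#' Combined training objective
#'
#' Weighted sum `w_ce * Lce + w_dice * Ldice`, equal 0.5/0.5 by default.
#'
#' @inheritParams cross_entropy_loss
#' @return Scalar.
#' @export
total_loss <- function(p, y, cfg = loss_config()) {
  cfg$weights[1] * cross_entropy_loss(p, y, cfg) +
    cfg$weights[2] * dice_loss(p, y, cfg)
}

# Gradient of the combined objective with respect to the logits that
# produced p via softmax over the class axis. Used by the trainer.
loss_grad_logits <- function(p, y, cfg = loss_config()) {
  check_py(p, y)
  nd <- length(dim(p))
  K <- dim(p)[nd]
  n_vox <- prod(dim(p)[-nd])
  pm <- matrix(p, ncol = K)
  ym <- matrix(y, ncol = K)
  # dL/dp for the cross-entropy term (clip region has zero gradient)
  pc <- pmax(pm, cfg$prob_floor)
  dce <- -(ym / pc) / n_vox
  dce[pm < cfg$prob_floor] <- 0
  # dL/dp for the Dice term
  num <- 2 * colSums(pm * ym) + cfg$epsilon
  den <- colSums(pm) + colSums(ym) + cfg$epsilon
  ddice <- -(sweep(2 * ym, 2, den, "*") - matrix(num, nrow(pm), K,
                                                 byrow = TRUE)) /
    matrix(den^2, nrow(pm), K, byrow = TRUE) / K
  dp <- cfg$weights[1] * dce + cfg$weights[2] * ddice
  # chain through softmax: dlogit_k = p_k (dp_k - sum_j dp_j p_j)
  dot <- rowSums(dp * pm)
  dl <- pm * (dp - dot)
  array(dl, dim(p))
}
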