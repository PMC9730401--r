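#' Soft Dice (1 - DICE) segmentation loss
#'
#' For each channel `c` (and batch item), the soft Dice index is
#' `(2 * sum(p * t) + s) / (sum(p) + sum(t) + s)` where `p` are the model's
#' sigmoid probabilities, `t` the binary targets, and `s >= 0` a smoothing
#' constant; the loss is one minus the mean index over channels and batch.
#' With `smoothing = 0` and binary `p` this is exactly `1 - DICE` as computed
#' by [dice()]; the positive default smoothing keeps the loss defined and
#' differentiable on background-only channels.
#'
#' @param predictions array with channel and batch as the last two dims
#'   (`(H, W, C, N)`; 3D input is treated as a single-item batch), values in
#'   `[0, 1]`.
#' @param targets binary array, same shape.
#' @param smoothing nonnegative smoothing constant (default 1).
#' @return scalar loss in `[0, 1]`.
#' @export
soft_dice_loss <- function(predictions, targets, smoothing = 1) {
  soft_dice_terms(predictions, targets, smoothing)$loss
}

soft_dice_terms <- function(predictions, targets, smoothing) {
  if (length(dim(predictions)) == 3L) dim(predictions) <- c(dim(predictions), 1L)
  if (length(dim(targets)) == 3L) dim(targets) <- c(dim(targets), 1L)
  if (!identical(dim(predictions), dim(targets))) {
    stop("predictions and targets must have identical shape")
  }
  if (smoothing < 0) stop("smoothing must be nonnegative")
  d <- dim(predictions)
  hw <- d[1L] * d[2L]
  pm <- matrix(predictions, hw, d[3L] * d[4L])
  tm <- matrix(targets, hw, d[3L] * d[4L])
  num <- 2 * colSums(pm * tm) + smoothing
  den <- colSums(pm) + colSums(tm) + smoothing
  sd_cn <- num / den
  list(loss = 1 - mean(sd_cn), num = num, den = den, d = d)
}

# Gradient of soft_dice_loss with respect to the predictions.
soft_dice_loss_grad <- function(predictions, targets, smoothing = 1) {
  tr <- soft_dice_terms(predictions, targets, smoothing)
  d <- tr$d
  hw <- d[1L] * d[2L]
  ncn <- d[3L] * d[4L]
  if (length(dim(targets)) == 3L) dim(targets) <- c(dim(targets), 1L)
  tm <- matrix(targets, hw, ncn)
  # d(soft_dice)/dp = (2*t*den - num) / den^2, per (channel, batch) column
  gm <- -(sweep(2 * tm, 2L, tr$den, "*") - matrix(tr$num, hw, ncn, byrow = TRUE)) /
    matrix(tr$den^2, hw, ncn, byrow = TRUE) / ncn
  array(gm, d)
}
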