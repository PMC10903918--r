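#' Activation functions
#'
#' `logistic(x) = 1/(1 + exp(-x))` maps any real input to a probability in
#' (0, 1) and is used by the final layer of each decoder head;
#' `swish(x) = x * logistic(x)` is the smooth, non-monotone activation used
#' after every other convolution.
#'
#' @param x numeric vector/array.
#' @return numeric of the same shape.
#' @export
logistic <- function(x) 1 / (1 + exp(-x))

#' @rdname logistic
#' @export
swish <- function(x) x * logistic(x)

# d/dx swish(x) = s(x) * (1 + x * (1 - s(x)))
swish_grad <- function(x) {
  s <- logistic(x)
  s * (1 + x * (1 - s))
}

#' Dice loss for dendrite segmentation
#'
#' `L = 1 - 2 * sum(yhat * y) / (sum(yhat^2) + sum(y^2))`, computed over all
#' pixels, with an epsilon-guarded denominator so that two empty maps give
#' loss 0. Bounded in `[0, 1]`; 0 iff prediction and target agree on the
#' overlap metric.
#'
#' @param y binary target map.
#' @param yhat predicted map in `[0, 1]`, same shape as `y`.
#' @param eps denominator guard.
#' @return scalar loss.
#' @export
dice_loss <- function(y, yhat, eps = 1e-7) {
  if (!identical(dim2(y), dim2(yhat))) stop("shape mismatch in dice_loss")
  num <- 2 * sum(yhat * y)
  den <- sum(yhat^2) + sum(y^2)
  if (den == 0) return(0)
  1 - num / (den + eps)
}

dice_loss_grad <- function(y, yhat, eps = 1e-7) {
  den <- sum(yhat^2) + sum(y^2) + eps
  num <- 2 * sum(yhat * y)
  (-2 * y * den + num * 2 * yhat) / den^2
}

#' Mean-squared-error loss for spine segmentation
#'
#' Squared error between target and prediction, averaged over pixels (the
#' mean reduction keeps the loss invariant to tile size).
#'
#' @inheritParams dice_loss
#' @return scalar loss (>= 0).
#' @export
spine_loss <- function(y, yhat) {
  if (!identical(dim2(y), dim2(yhat))) stop("shape mismatch in spine_loss")
  mean((y - yhat)^2)
}

spine_loss_grad <- function(y, yhat) {
  2 * (yhat - y) / length(y)
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)
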