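# Training losses: summed cross-entropy over the augmented views and the
# local structure feature similarity measure (LSFSM), a sum of per-block
# Euclidean distances between predicted and true block indices.

#' Classification loss over the augmented views of one sample
#'
#' The summed cross-entropy \eqn{-\sum_k l \cdot \log\varphi(I_k)
#' - \sum_d l \cdot \log\varphi(S_d)} over the K1 + K2 views of one training
#' image; the epoch-level loss is the sum of this quantity over the training
#' set. True-class probabilities are floored at 1e-12 inside the log as a
#' numerical guard (with a warning), not as part of the model.
#'
#' @param distributions List of probability vectors, one per view; each must
#'   be non-negative and sum to 1 within 1e-6.
#' @param class_label One-hot numeric vector, or a single integer class.
#' @return Non-negative scalar loss in nats.
#' @export
classification_loss <- function(distributions, class_label) {
  if (!is.list(distributions)) distributions <- list(distributions)
  C <- length(distributions[[1L]])
  if (length(class_label) == 1L) {
    onehot <- numeric(C)
    onehot[as.integer(class_label)] <- 1
  } else {
    onehot <- as.numeric(class_label)
  }
  if (sum(onehot == 1) != 1 || any(!onehot %in% c(0, 1))) {
    stop("`class_label` must be one-hot")
  }
  true_class <- which(onehot == 1)
  total <- 0
  clamped <- FALSE
  for (phi in distributions) {
    if (length(phi) != C) stop("all distributions must have the same length")
    if (any(phi < -1e-9) || abs(sum(phi) - 1) > 1e-6) {
      stop("each distribution must be non-negative and sum to 1")
    }
    p <- phi[true_class]
    if (p < 1e-12) {
      p <- 1e-12
      clamped <- TRUE
    }
    total <- total - log(p)
  }
  if (clamped) warning("true-class probability clamped at 1e-12")
  total
}

#' Local structure feature similarity loss
#'
#' Sum over all views and all N^2 block positions of the per-block Euclidean
#' distance between the predicted and true index pair,
#' \eqn{\sqrt{(\tau - u)^2 + (\tau - v)^2}} — a sum of 2-D distances, not a
#' single global norm. Predictions and labels must be on the same
#' (normalised) scale; multiply by the constant from [label_norm_constant()]
#' to recover raw index units.
#'
#' @param predictions N x N x 2 array, or list of such arrays (one per view).
#' @param labels Matching array or list.
#' @return Non-negative scalar.
#' @export
lsfsm_loss <- function(predictions, labels) {
  if (!is.list(predictions)) predictions <- list(predictions)
  if (!is.list(labels)) labels <- list(labels)
  if (length(predictions) != length(labels)) {
    stop("`predictions` and `labels` must have the same number of views")
  }
  total <- 0
  for (v in seq_along(predictions)) {
    p <- predictions[[v]]; l <- labels[[v]]
    if (!identical(dim(p), dim(l))) stop("prediction/label shape mismatch")
    diff <- p - l
    total <- total + sum(sqrt(diff[, , 1L]^2 + diff[, , 2L]^2))
  }
  total
}

#' Combined training objective
#'
#' `total = L_c + lambda_sm * L_sm`, with `lambda_sm = 1` by default;
#' `lambda_sm = 0` ablates the similarity term and reduces training to plain
#' cross-entropy.
#'
#' @param L_c Classification loss.
#' @param L_sm Similarity loss.
#' @param lambda_sm Non-negative weight.
#' @return Scalar.
#' @export
total_objective <- function(L_c, L_sm, lambda_sm = 1) {
  if (lambda_sm < 0) stop("`lambda_sm` must be non-negative")
  L_c + lambda_sm * L_sm
}
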