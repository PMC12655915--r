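# Loss components and the composite objective.

#' Loss weights of the composite objective
#'
#' Defaults are the tuned values of the study configuration; the search
#' ranges used by [hyperparameterSearch()] are [0.5, 2.0] for the
#' reconstruction and task weights and [0.1, 0.5] for the adversarial
#' weight (an excessive adversarial weight disrupts task-relevant
#' encoding).
#'
#' @param lambda_rec reconstruction weight.
#' @param lambda_task task (classification) weight.
#' @param lambda_conf adversarial confounder weight.
#' @return A \code{LossWeights} record.
#' @export
lossWeights <- function(lambda_rec = 1.0, lambda_task = 1.5,
                        lambda_conf = 0.3) {
  if (any(c(lambda_rec, lambda_task, lambda_conf) < 0))
    stop("loss weights must be nonnegative")
  structure(list(lambda_rec = lambda_rec, lambda_task = lambda_task,
                 lambda_conf = lambda_conf), class = "LossWeights")
}

# hyperparameter search ranges (loss weights and learning rate)
search_ranges <- function() {
  list(lr = c(1e-4, 1e-2), lambda_rec = c(0.5, 2.0),
       lambda_task = c(0.5, 2.0), lambda_conf = c(0.1, 0.5))
}

#' Masked reconstruction loss
#'
#' Mean squared error between input and reconstruction over valid
#' (mask-TRUE) timesteps and all channels; padded positions are excluded.
#'
#' @param x input array (batch, L, C).
#' @param x_hat reconstruction, same shape.
#' @param mask logical (batch, L) validity mask.
#' @return Scalar loss.
#' @export
reconstructionLoss <- function(x, x_hat, mask) {
  if (!identical(dim(x), dim(x_hat))) stop("x and x_hat shapes differ")
  if (!any(mask)) stop("mask excludes every timestep")
  n_ch <- dim(x)[3]
  mexp <- array(mask, dim = dim(x))   # (B, L) recycled over channels
  sum(((x - x_hat)^2)[mexp]) / (sum(mask) * n_ch)
}

# gradient of reconstructionLoss w.r.t. x_hat
reconstruction_loss_grad <- function(x, x_hat, mask) {
  n_ch <- dim(x)[3]
  mexp <- array(mask, dim = dim(x))
  2 * (x_hat - x) * mexp / (sum(mask) * n_ch)
}

#' Class-weighted cross-entropy task loss
#'
#' Mean over the batch of \code{class_weight[y] * (-log p[y])}, with
#' probabilities clamped at 1e-12 so a zero probability at the true class
#' yields a large finite value.
#'
#' @param y integer labels in \code{1..n_classes}.
#' @param y_probs batch x n_classes probability matrix.
#' @param class_weight per-class weights (see [classWeights()]); defaults
#'   to 1.
#' @return Scalar loss.
#' @export
taskLoss <- function(y, y_probs, class_weight = NULL) {
  if (is.null(class_weight)) class_weight <- rep(1, ncol(y_probs))
  p <- pmax(y_probs[cbind(seq_along(y), y)], 1e-12)
  mean(class_weight[y] * (-log(p)))
}

# gradient of taskLoss w.r.t. logits (softmax + weighted CE combined)
task_loss_grad_logits <- function(y, y_probs, class_weight = NULL) {
  if (is.null(class_weight)) class_weight <- rep(1, ncol(y_probs))
  g <- y_probs
  g[cbind(seq_along(y), y)] <- g[cbind(seq_along(y), y)] - 1
  g * class_weight[y] / length(y)
}

#' Masked confounder (humidity) loss
#'
#' Mean squared error between the standardized humidity target and the
#' adversary's prediction over valid timesteps.
#'
#' @param c batch x L standardized humidity target.
#' @param c_hat batch x L prediction.
#' @param mask logical (batch, L) validity mask.
#' @return Scalar loss.
#' @export
confounderLoss <- function(c, c_hat, mask) {
  if (!identical(dim(c), dim(c_hat))) stop("c and c_hat shapes differ")
  if (!any(mask)) stop("mask excludes every timestep")
  sum(((c - c_hat)^2)[mask]) / sum(mask)
}

confounder_loss_grad <- function(c, c_hat, mask) {
  2 * (c_hat - c) * mask / sum(mask)
}

#' Composite objective
#'
#' \code{lambda_rec * l_rec + lambda_task * l_task - lambda_conf * l_conf}:
#' the adversarial term enters with a minus sign because the encoder is
#' trained to maximize the confounder loss.
#'
#' @param weights a [lossWeights()] record.
#' @param l_rec,l_task,l_conf the three component losses.
#' @return Scalar total loss.
#' @examples
#' totalLoss(lossWeights(), l_rec = 2, l_task = 1, l_conf = 1)  # 3.2
#' @export
totalLoss <- function(weights, l_rec, l_task, l_conf) {
  weights$lambda_rec * l_rec + weights$lambda_task * l_task -
    weights$lambda_conf * l_conf
}

#' Adaptive loss-weight update from gradient norms
#'
#' Sets each weight to the ratio of its component's encoder-gradient norm
#' to the total-objective gradient norm, then clips into that component's
#' search range. With a zero total-gradient norm the previous weights are
#' kept.
#'
#' @param grad_norms named list/vector with elements \code{rec},
#'   \code{task}, \code{conf} and \code{total}: encoder-parameter gradient
#'   norms of each loss component and of the composite objective.
#' @param weights the current [lossWeights()] (returned unchanged when the
#'   guard triggers).
#' @return An updated [lossWeights()] record.
#' @export
adaptiveLambda <- function(grad_norms, weights) {
  gn <- as.list(grad_norms)
  if (is.null(gn$total) || gn$total <= 0) return(weights)
  r <- search_ranges()
  clip <- function(v, rng) min(max(v, rng[1]), rng[2])
  lossWeights(lambda_rec = clip(gn$rec / gn$total, r$lambda_rec),
              lambda_task = clip(gn$task / gn$total, r$lambda_task),
              lambda_conf = clip(gn$conf / gn$total, r$lambda_conf))
}
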