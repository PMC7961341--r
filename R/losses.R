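# Loss terms and regularization schedules.

#' KL divergence of a diagonal Gaussian posterior from the standard normal
#'
#' Closed form `-0.5 * sum(1 + log_var - mu^2 - exp(log_var))`, i.e.
#' `KL(N(mu, sigma^2 I) || N(0, I))` in nats. Nonnegative by Gibbs'
#' inequality.
#'
#' @param mu Mean vector.
#' @param log_var Log-variance vector (`sigma^2 = exp(log_var)`).
#' @return Scalar KL divergence in nats.
#' @export
gaussian_kl <- function(mu, log_var) {
  if (!all(is.finite(mu)) || !all(is.finite(log_var)))
    stop("non-finite inputs to gaussian_kl")
  if (length(mu) != length(log_var)) stop("mu and log_var lengths differ")
  -0.5 * sum(1 + log_var - mu^2 - exp(log_var))
}

#' Mean squared error per pixel
#'
#' @param x,x_hat Arrays of identical shape with values in `[0, 1]`.
#' @return Mean over all elements of the squared difference.
#' @export
reconstruction_loss <- function(x, x_hat) {
  if (!identical(dim(x) %||% length(x), dim(x_hat) %||% length(x_hat)))
    stop("shape mismatch between x and x_hat")
  mean((x - x_hat)^2)
}

#' Beta-weighted VAE loss
#'
#' @param recon Reconstruction loss.
#' @param kl KL divergence.
#' @param beta Nonnegative KL weight; `beta = 1` recovers the standard VAE.
#' @return `recon + beta * kl`.
#' @export
beta_vae_loss <- function(recon, kl, beta) {
  if (beta < 0) stop("beta must be nonnegative")
  recon + beta * kl
}

#' Categorical cross-entropy in nats
#'
#' @param probs Probability vector (sums to 1).
#' @param label 1-based class index.
#' @param floor Lower clamp applied to the selected probability to avoid
#'   infinities from saturated softmax outputs.
#' @return `-log(probs[label])`.
#' @export
cross_entropy <- function(probs, label, floor = 1e-12) {
  if (abs(sum(probs) - 1) > 1e-6) stop("probs must sum to 1")
  if (label < 1 || label > length(probs)) stop("label out of range")
  -log(max(probs[label], floor))
}

#' Assemble a loss breakdown
#'
#' Holds the components of the combined objective
#' `recon_l + beta * kl_l + recon_r + beta * kl_r + emotion - lambda * domain`
#' and its total.
#'
#' @param recon_l,recon_r Per-hemisphere reconstruction MSE.
#' @param kl_l,kl_r Per-hemisphere KL divergences (nats).
#' @param emotion_loss,domain_loss Cross-entropies (nats).
#' @param beta,lambda Current regularization weights.
#' @return A `loss_breakdown` list including `total`.
#' @export
loss_breakdown <- function(recon_l, recon_r, kl_l, kl_r, emotion_loss,
                           domain_loss, beta, lambda) {
  parts <- list(recon_l = recon_l, recon_r = recon_r, kl_l = kl_l, kl_r = kl_r,
                emotion_loss = emotion_loss, domain_loss = domain_loss,
                beta = beta, lambda = lambda)
  parts$total <- bivdann_total(parts)
  structure(parts, class = "loss_breakdown")
}

#' Combined training objective
#'
#' @param parts A [loss_breakdown()] or plain list with the same fields.
#' @return The scalar total loss.
#' @export
bivdann_total <- function(parts) {
  parts$recon_l + parts$beta * parts$kl_l +
    parts$recon_r + parts$beta * parts$kl_r +
    parts$emotion_loss - parts$lambda * parts$domain_loss
}

#' Linear warm-up schedule
#'
#' Grows linearly from 0 at epoch 0 to `max_value` at `ramp_epochs`, constant
#' afterwards. Used for both the KL weight (beta, 100-epoch ramp) and the
#' adversarial weight (lambda, 50-epoch ramp).
#'
#' @param epoch Nonnegative integer epoch (0-based).
#' @param max_value Plateau value.
#' @param ramp_epochs Positive ramp length in epochs.
#' @return `min(epoch / ramp_epochs, 1) * max_value`.
#' @export
ramp <- function(epoch, max_value, ramp_epochs) {
  if (any(epoch < 0)) stop("epoch must be nonnegative")
  if (ramp_epochs <= 0) stop("ramp_epochs must be positive")
  pmin(epoch / ramp_epochs, 1) * max_value
}

#' Schedule configuration
#'
#' @param beta_max,lambda_max Plateau values for the KL and adversarial
#'   weights (both default 1).
#' @param beta_ramp_epochs,lambda_ramp_epochs Linear ramp lengths (100 and 50
#'   epochs).
#' @return A `schedule_config` list.
#' @export
schedule_config <- function(beta_max = 1, beta_ramp_epochs = 100,
                            lambda_max = 1, lambda_ramp_epochs = 50) {
  stopifnot(beta_max >= 0, lambda_max >= 0,
            beta_ramp_epochs > 0, lambda_ramp_epochs > 0)
  structure(list(beta_max = beta_max, beta_ramp_epochs = beta_ramp_epochs,
                 lambda_max = lambda_max, lambda_ramp_epochs = lambda_ramp_epochs),
            class = "schedule_config")
}
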