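# The package's reference scaled-down experiment: one fixed architecture and
# training configuration used by the validation suite, the acceptance script
# and the worked examples, so results are comparable everywhere.

#' Scaled-down reference architecture
#'
#' A reduced configuration sized for single-CPU experiments on the synthetic
#' generator defaults: latent 16, conv channels (4, 8, 8), dense 64,
#' bilateral embedding 8, heads (32, 32, 16), average-pooling stem 2. The
#' narrow bilateral embedding is deliberate: inactive embedding dimensions
#' are kept alive by batch normalization and are where residual subject
#' information accumulates, so the scaled model gives the adversary only as
#' much capacity as the 2-class task needs.
#'
#' @param n_classes,n_subjects Dataset dimensions.
#' @param hemi Hemisphere path (for the unilateral ablations).
#' @return An [arch_config()].
#' @export
experiment_arch <- function(n_classes = 2, n_subjects = 8, hemi = "both") {
  arch_config(latent_dim = 16, n_classes = n_classes,
              n_subjects = n_subjects, input = c(3, 64, 32),
              enc_channels = c(4, 8, 8), enc_strides = c(2, 2, 2),
              enc_dense = 64, ext_channels = c(8, 8), ext_dense = 8,
              head_dense = c(32, 32, 16), hemi = hemi, pool = 2)
}

#' Scaled-down reference training configuration
#'
#' 60 epochs, batch 64, Adam 1e-3, beta/lambda ramps of 40/20 epochs (the
#' reference 100/50-epoch warm-ups rescaled to a 60-epoch budget), beta plateau 0.05 on
#' the per-pixel loss scaling, lambda plateau 1.5, a 5x discriminator
#' learning rate with 10 inner iterations per batch, early-stopping
#' patience 15.
#'
#' @param variant Ablation variant name.
#' @param seed Integer seed.
#' @param max_epochs,patience Overrides for the epoch budget.
#' @param lambda_max Adversarial plateau (default 1.5).
#' @param beta_max KL plateau (default 0.05).
#' @return A [train_config()].
#' @export
experiment_config <- function(variant = "BiVDANN", seed = 1, max_epochs = 60,
                              patience = 15, lambda_max = 1.5,
                              beta_max = 0.05) {
  train_config(batch_size = 64, max_epochs = max_epochs, lr = 1e-3,
               disc_lr_mult = 5, disc_steps = 10, patience = patience,
               schedules = schedule_config(beta_max = beta_max,
                                           beta_ramp_epochs = 40,
                                           lambda_max = lambda_max,
                                           lambda_ramp_epochs = 20),
               seed = seed, variant = variant)
}
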