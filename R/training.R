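# Training: unsupervised VAE pretraining and the interleaved supervised
# procedure (per batch: reconstruction step, discriminator step, adversarial
# classification step), with ablation variants.

VARIANTS <- c("BiVDANN", "BiCNN", "BiVAE", "BiDANN", "L-VDANN", "R-VDANN")

#' Training configuration
#'
#' @param batch_size Mini-batch size (default 256, so adversarial batches
#'   contain a good spread of subjects).
#' @param max_epochs Maximum training epochs (default 300).
#' @param val_fraction Fraction of the training data held out for validation
#'   (default 0.15), stratified jointly by subject and class.
#' @param patience Early-stopping patience in epochs on the emotion
#'   validation accuracy (default 20).
#' @param lr Adam learning rate (default 1e-4).
#' @param disc_lr_mult Learning-rate multiplier for the subject
#'   discriminator step (default 1). Raising it keeps the discriminator
#'   strong relative to the shifting shared features (a two-time-scale
#'   update), which is what gives the reversed gradient its bite.
#' @param disc_steps Discriminator inner iterations per batch (default 1);
#'   more iterations let the discriminator track the shared features
#'   closely, so the reversed gradient keeps pointing at real subject
#'   information instead of a stale adversary.
#' @param schedules A [schedule_config()] with the beta and lambda ramps.
#' @param seed Integer seed controlling the split, weight initialization,
#'   shuffling and latent sampling.
#' @param variant One of `r paste(VARIANTS, collapse = ", ")`.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 256, max_epochs = 300,
                         val_fraction = 0.15, patience = 20, lr = 1e-4,
                         disc_lr_mult = 1, disc_steps = 1,
                         schedules = schedule_config(),
                         seed = 1, variant = "BiVDANN") {
  stopifnot(batch_size >= 2, max_epochs >= 1,
            val_fraction > 0, val_fraction < 1, patience >= 0, lr > 0,
            disc_lr_mult > 0, disc_steps >= 1)
  variant <- match.arg(variant, VARIANTS)
  structure(list(batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 val_fraction = val_fraction, patience = as.integer(patience),
                 lr = lr, disc_lr_mult = disc_lr_mult,
                 disc_steps = as.integer(disc_steps), schedules = schedules,
                 seed = as.integer(seed), variant = variant),
            class = "train_config")
}

#' Resolve a variant into component switches
#'
#' Ablation variants toggle the reconstruction path, the KL (variational)
#' regularizer, the subject discriminator, and the hemisphere input path.
#' Variants without the variational regularizer use deterministic embeddings
#' (no latent sampling).
#'
#' @param config A [train_config()].
#' @param variant Variant name; defaults to `config$variant`.
#' @return The config with `use_recon`, `use_kl`, `use_disc`, `hemi` set.
#' @export
make_variant <- function(config, variant = config$variant) {
  variant <- match.arg(variant, VARIANTS)
  sw <- switch(variant,
    "BiVDANN" = list(use_recon = TRUE,  use_kl = TRUE,  use_disc = TRUE,  hemi = "both"),
    "BiCNN"   = list(use_recon = FALSE, use_kl = FALSE, use_disc = FALSE, hemi = "both"),
    "BiVAE"   = list(use_recon = TRUE,  use_kl = TRUE,  use_disc = FALSE, hemi = "both"),
    "BiDANN"  = list(use_recon = TRUE,  use_kl = FALSE, use_disc = TRUE,  hemi = "both"),
    "L-VDANN" = list(use_recon = TRUE,  use_kl = TRUE,  use_disc = TRUE,  hemi = "left"),
    "R-VDANN" = list(use_recon = TRUE,  use_kl = TRUE,  use_disc = TRUE,  hemi = "right"))
  config$variant <- variant
  config[names(sw)] <- sw
  config
}

# run a function under a temporary RNG state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

as_prepared <- function(x) {
  if (inherits(x, "topograph_dataset")) prepare_hemis(x) else x
}

history_df <- function(h) {
  cols <- c("epoch", "beta", "lambda", "recon_l", "recon_r", "kl_l", "kl_r",
            "emotion_loss", "domain_loss", "total", "train_acc", "val_acc",
            "train_disc_acc", "val_disc_acc")
  df <- as.data.frame(h)
  names(df) <- cols[seq_len(ncol(df))]
  df
}

# stratified validation indices (0-based), one draw per subject x class cell
stratified_val_split <- function(y, s, val_fraction, seed) {
  with_seed(seed, {
    val <- integer(0)
    for (cell in split(seq_along(y), paste(s, y))) {
      k <- max(1L, round(length(cell) * val_fraction))
      if (k >= length(cell)) k <- length(cell) - 1L
      if (k > 0) val <- c(val, sample(cell, k))
    }
    sort(val) - 1L
  })
}

#' Unsupervised pretraining of the hemispheric VAEs
#'
#' Trains encoders and decoders on reconstruction + beta-weighted KL only;
#' labels are never consumed. The beta ramp is the same linear warm-up used
#' in supervised training.
#'
#' @param x A `topograph_dataset` or a [prepare_hemis()] list (labels, if
#'   present, are ignored).
#' @param arch An [arch_config()].
#' @param config A [train_config()]; `max_epochs`, `batch_size`, `lr`,
#'   `schedules$beta_*` and `seed` are used.
#' @return List with `params` (warm-start weights) and `history` (per-epoch
#'   beta, reconstruction and KL values).
#' @export
pretrain_vaes <- function(x, arch, config = train_config()) {
  p <- as_prepared(x)
  n <- ncol(p$x_left %||% p$x_right)
  if (is.null(n) || n < 2) stop("pretraining requires at least one batch of data")
  cfg <- if (is.null(config$use_recon)) make_variant(config) else config
  if (!cfg$use_recon) stop("variant without a reconstruction path cannot be pretrained")
  params <- init_model(arch, seed = cfg$seed)
  opts <- list(epochs = cfg$max_epochs, batch = cfg$batch_size, lr = cfg$lr,
               beta_max = if (cfg$use_kl) cfg$schedules$beta_max else 0,
               beta_ramp = cfg$schedules$beta_ramp_epochs,
               use_kl = cfg$use_kl, sample_z = cfg$use_kl, seed = cfg$seed)
  out <- .nn_pretrain(params, arch, p$x_left, p$x_right, opts)
  hist <- as.data.frame(out$history)
  names(hist) <- c("epoch", "beta", "recon_l", "recon_r", "kl_l", "kl_r")
  params <- structure(out$params, class = "model_params", arch = arch)
  list(params = params, history = hist)
}

#' Interleaved supervised training
#'
#' Per epoch and batch, three updates are applied in fixed order: (1) a
#' reconstruction step on the encoders/decoders (reconstruction +
#' beta-ramped KL), (2) a discriminator step on the subject cross-entropy
#' with the shared path frozen, and (3) an adversarial classification step
#' updating encoders, extractor and classifier on the emotion loss plus the
#' lambda-scaled reversed subject loss. A stratified validation split is
#' held out; early stopping monitors emotion validation accuracy and the
#' best checkpoint is restored.
#'
#' @param dataset A `topograph_dataset` or [prepare_hemis()] list with
#'   labels and subject codes.
#' @param arch An [arch_config()] whose `n_classes`/`n_subjects` match the
#'   data.
#' @param config A [train_config()]; the variant switches are resolved via
#'   [make_variant()].
#' @param warm_start Optional `model_params` (e.g. from [pretrain_vaes()]).
#' @return List with `params`, `history` (data frame, one row per epoch) and
#'   `best_epoch`.
#' @export
train_bivdann <- function(dataset, arch, config = train_config(),
                          warm_start = NULL) {
  p <- as_prepared(dataset)
  cfg <- if (is.null(config$use_recon)) make_variant(config) else config
  n <- length(p$y)
  n_subj <- length(unique(p$s))
  n_cls <- length(unique(p$y))
  if (n_cls < 2) stop("need at least 2 emotion classes")
  if (cfg$use_disc && n_subj < 2)
    stop("a variant with a subject discriminator requires at least 2 subjects")
  if (arch$n_classes != max(p$y) + 1L)
    stop("arch n_classes does not match the dataset")
  if (cfg$use_disc && arch$n_subjects != max(p$s) + 1L)
    stop("arch n_subjects does not match the dataset")
  if (arch$hemi != cfg$hemi) arch <- rebuild_arch(arch, hemi = cfg$hemi)
  if (cfg$batch_size < arch$n_subjects)
    warning("batch_size below the number of subjects; adversarial batches may be unbalanced")

  val <- stratified_val_split(p$y, p$s, cfg$val_fraction, cfg$seed)
  train_idx <- setdiff(seq_len(n) - 1L, val)
  params <- warm_start %||% init_model(arch, seed = cfg$seed)
  opts <- list(epochs = cfg$max_epochs, batch = cfg$batch_size, lr = cfg$lr,
               beta_max = if (cfg$use_kl) cfg$schedules$beta_max else 0,
               beta_ramp = cfg$schedules$beta_ramp_epochs,
               lambda_max = if (cfg$use_disc) cfg$schedules$lambda_max else 0,
               lambda_ramp = cfg$schedules$lambda_ramp_epochs,
               patience = cfg$patience, seed = cfg$seed,
               disc_lr_mult = cfg$disc_lr_mult, disc_steps = cfg$disc_steps,
               use_recon = cfg$use_recon, use_kl = cfg$use_kl,
               use_disc = cfg$use_disc, sample_z = cfg$use_kl)
  out <- .nn_train(params, arch, p$x_left, p$x_right,
                   as.integer(p$y), as.integer(p$s),
                   as.integer(train_idx), as.integer(val), opts)
  params <- structure(out$params, class = "model_params", arch = arch)
  list(params = params, history = history_df(out$history),
       best_epoch = out$best_epoch, config = cfg,
       val_idx = val + 1L, train_idx = train_idx + 1L)
}

#' Write a training history table
#'
#' @param history The `history` data frame from [train_bivdann()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_history <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}
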