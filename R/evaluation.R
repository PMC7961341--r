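# Leave-one-subject-out evaluation, accuracy summarization and embedding
# diagnostics (linear subject probe, per-dimension normality check).

#' Leave-one-subject-out folds
#'
#' One fold per subject: the fold's test set holds all samples of that
#' subject and its training set the rest, so the test sets partition the
#' dataset and no subject ever appears on both sides of a fold.
#'
#' @param ds A `topograph_dataset` (or data frame / list with a
#'   `subject_id` column in `$meta`).
#' @return List of folds, each with `subject`, `train_idx`, `test_idx`
#'   (1-based row indices).
#' @export
loso_splits <- function(ds) {
  subj <- if (inherits(ds, "topograph_dataset")) ds$meta$subject_id
          else ds$subject_id
  subjects <- sort(unique(subj))
  if (length(subjects) < 2) stop("leave-one-subject-out requires >= 2 subjects")
  lapply(subjects, function(s) {
    test <- which(subj == s)
    fold <- list(subject = s, train_idx = which(subj != s), test_idx = test)
    stopifnot(length(intersect(fold$train_idx, fold$test_idx)) == 0)
    fold
  })
}

#' Subset a topograph dataset by row index
#'
#' @param ds A `topograph_dataset`.
#' @param idx Row indices.
#' @return The reduced dataset.
#' @export
ds_subset <- function(ds, idx) {
  structure(list(images = ds$images[idx, , , , drop = FALSE],
                 meta = ds$meta[idx, , drop = FALSE],
                 band_edges = ds$band_edges),
            class = "topograph_dataset")
}

#' Run leave-one-subject-out cross-validation
#'
#' For every fold a fresh model is (optionally pre-) trained on the fold's
#' training subjects — with the validation split carved from those subjects
#' only — and top-1 emotion accuracy is measured on the held-out subject.
#'
#' @param ds A `topograph_dataset`.
#' @param arch_template An [arch_config()]; `n_subjects` is rebuilt per fold
#'   to the number of training subjects.
#' @param config A [train_config()] (the variant decides the component
#'   switches).
#' @param pretrain Run unsupervised VAE pretraining on each fold's training
#'   images before supervised training (default FALSE).
#' @param pretrain_epochs Epoch budget for the pretraining warm start
#'   (default 20).
#' @return A `loso_result`: data frame `per_subject`, plus `mean`, `sd` and
#'   `variant`.
#' @export
run_loso <- function(ds, arch_template, config = train_config(),
                     pretrain = FALSE, pretrain_epochs = 20) {
  cfg <- make_variant(config)
  folds <- loso_splits(ds)
  accs <- numeric(0)
  subjects <- character(0)
  failures <- character(0)
  for (fold in folds) {
    train_ds <- ds_subset(ds, fold$train_idx)
    test_ds <- ds_subset(ds, fold$test_idx)
    ptr <- prepare_hemis(train_ds)
    arch <- rebuild_arch(arch_template,
                         n_classes = length(unique(ptr$y)),
                         n_subjects = length(unique(ptr$s)),
                         hemi = cfg$hemi)
    res <- tryCatch({
      warm <- NULL
      if (pretrain && cfg$use_recon) {
        pcfg <- cfg
        pcfg$max_epochs <- as.integer(pretrain_epochs)
        warm <- pretrain_vaes(ptr, arch, pcfg)$params
      }
      fit <- train_bivdann(ptr, arch, cfg, warm_start = warm)
      pte <- prepare_hemis(test_ds)
      # class codes must follow the training fold's level order
      y_true <- match(test_ds$meta$label, ptr$classes) - 1L
      pred <- predict_bivdann(fit$params, pte$x_left, pte$x_right)
      mean(max.col(t(pred$probs)) - 1L == y_true)
    }, error = function(e) {
      warning("fold for subject ", fold$subject, " failed: ",
              conditionMessage(e))
      NA_real_
    })
    if (is.na(res)) failures <- c(failures, fold$subject)
    accs <- c(accs, res)
    subjects <- c(subjects, fold$subject)
  }
  ok <- !is.na(accs)
  structure(list(
    per_subject = data.frame(subject = subjects, accuracy = accs,
                             stringsAsFactors = FALSE),
    mean = mean(accs[ok]), sd = stats::sd(accs[ok]),
    variant = cfg$variant, failures = failures),
    class = "loso_result")
}

rebuild_arch <- function(a, n_classes = a$n_classes, n_subjects = a$n_subjects,
                         hemi = a$hemi) {
  arch_config(latent_dim = a$latent, n_classes = n_classes,
              n_subjects = n_subjects, input = a$input,
              enc_channels = a$enc_channels, enc_strides = a$enc_strides,
              enc_dense = a$enc_dense, ext_channels = a$ext_channels,
              ext_dense = a$ext_dense, head_dense = a$head_dense,
              hemi = hemi, pool = a$pool %||% 1, mc_samples = a$mc_samples)
}

#' @export
print.loso_result <- function(x, ...) {
  cat(sprintf("<loso_result> %s: mean %.3f sd %.3f over %d subjects\n",
              x$variant, x$mean, x$sd, nrow(x$per_subject)))
  invisible(x)
}

#' Embedding diagnostics
#'
#' Extracts the bilateral embeddings deterministically (inference mode,
#' z := mu), trains a post-hoc multinomial linear probe on subject identity
#' using the frozen embeddings with its own train/test split, and runs a
#' per-dimension Kolmogorov-Smirnov test against a Gaussian with that
#' dimension's sample mean and sd.
#'
#' @param params Trained `model_params`.
#' @param ds The `topograph_dataset` to embed.
#' @param probe_fraction Fraction of embeddings used to fit the probe
#'   (default 0.7; accuracy is reported on the rest).
#' @param alpha Significance level of the normality check (default 0.05).
#' @param seed Seed for the probe split.
#' @return An `embedding_report` with `embeddings` (N x D), `labels`,
#'   `subjects`, `probe_accuracy`, `ks_reject_fraction`.
#' @export
embedding_report <- function(params, ds, probe_fraction = 0.7, alpha = 0.05,
                             seed = 1) {
  p <- prepare_hemis(ds)
  pred <- predict_bivdann(params, p$x_left, p$x_right)
  emb <- t(pred$emb)                      # N x D
  subj <- factor(p$s)
  probe_acc <- with_seed(seed, {
    n <- nrow(emb)
    tr <- sort(sample(n, round(probe_fraction * n)))
    te <- setdiff(seq_len(n), tr)
    if (length(unique(subj[tr])) < 2) {
      NA_real_
    } else {
      fit <- nnet::multinom(y ~ ., data = data.frame(y = subj[tr], emb[tr, ]),
                            trace = FALSE, MaxNWts = 100000, maxit = 200)
      pr <- stats::predict(fit, newdata = data.frame(emb[te, , drop = FALSE]))
      mean(as.character(pr) == as.character(subj[te]))
    }
  })
  ks_rej <- mean(vapply(seq_len(ncol(emb)), function(j) {
    x <- emb[, j]
    if (stats::sd(x) < 1e-12) return(FALSE)
    suppressWarnings(
      stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value) < alpha
  }, logical(1)))
  structure(list(embeddings = emb, labels = p$y, subjects = p$s,
                 classes = p$classes, subject_ids = p$subjects,
                 probe_accuracy = probe_acc, ks_reject_fraction = ks_rej,
                 chance = 1 / length(unique(p$s))),
            class = "embedding_report")
}

#' @export
print.embedding_report <- function(x, ...) {
  cat(sprintf(
    "<embedding_report> %d x %d; subject probe %.3f (chance %.3f); KS reject %.2f\n",
    nrow(x$embeddings), ncol(x$embeddings), x$probe_accuracy, x$chance,
    x$ks_reject_fraction))
  invisible(x)
}

#' Export embeddings for external visualization
#'
#' Writes a CSV with one embedding dimension per column plus `subject` and
#' `class` metadata columns, for consumption by external t-SNE/MDS tooling.
#'
#' @param report An [embedding_report()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_embeddings <- function(report, path) {
  emb <- report$embeddings
  colnames(emb) <- sprintf("dim_%03d", seq_len(ncol(emb)))
  df <- data.frame(emb,
                   subject = report$subject_ids[report$subjects + 1L],
                   class = report$classes[report$labels + 1L],
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read back an embedding export
#'
#' @param path CSV written by [export_embeddings()].
#' @return List with `embeddings` matrix and `subject`, `class` vectors.
#' @export
read_embeddings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  dims <- grep("^dim_", names(df))
  list(embeddings = as.matrix(df[, dims]),
       subject = df$subject, class = df$class)
}

#' Summarize several variants into a results table
#'
#' @param results List of `loso_result` objects.
#' @return Data frame with variant, mean and sd columns (the layout of a
#'   cross-validation summary table).
#' @export
summarize_variants <- function(results) {
  data.frame(variant = vapply(results, function(r) r$variant, ""),
             mean = vapply(results, function(r) r$mean, 0),
             sd = vapply(results, function(r) r$sd, 0),
             stringsAsFactors = FALSE)
}
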