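# Training loops: variant switches, pretraining, schedules, reproducibility,
# and early stopping.

test_that("variants resolve to the documented component switches", {
  cfg <- train_config()
  b <- make_variant(cfg, "BiCNN")
  expect_false(b$use_recon); expect_false(b$use_kl); expect_false(b$use_disc)
  v <- make_variant(cfg, "BiVAE")
  expect_true(v$use_kl); expect_false(v$use_disc)
  d <- make_variant(cfg, "BiDANN")
  expect_false(d$use_kl); expect_true(d$use_disc)
  l <- make_variant(cfg, "L-VDANN")
  expect_identical(l$hemi, "left"); expect_true(l$use_kl); expect_true(l$use_disc)
  full <- make_variant(cfg, "BiVDANN")
  expect_true(full$use_recon && full$use_kl && full$use_disc)
  expect_identical(full$hemi, "both")
  expect_error(make_variant(cfg, "nope"))
})

test_that("pretraining is unsupervised and improves reconstruction", {
  arch <- tiny_arch()
  ds <- tiny_dataset()
  p <- prepare_hemis(ds)
  cfg <- train_config(batch_size = 32, max_epochs = 8, lr = 2e-3, seed = 3,
                      schedules = small_schedules())
  pre <- pretrain_vaes(p, arch, cfg)
  # beta ramp honored: recorded beta at the first epoch (epoch index 0) is 0
  expect_identical(pre$history$beta[1], 0)
  # labels are not consumed: stripping them changes nothing
  p_nolab <- p; p_nolab$y <- NULL; p_nolab$s <- NULL
  pre2 <- pretrain_vaes(p_nolab, arch, cfg)
  expect_equal(pre$params[["enc_l.c1.W"]], pre2$params[["enc_l.c1.W"]])
  # held-out reconstruction error beats a random initialization
  hold <- tiny_dataset(seed = 99)
  ph <- prepare_hemis(hold)
  recon_mse <- function(params) {
    code <- encode(ph$x_left, params, "left")
    xh <- decode(code$mu, params, "left")
    mean((xh - ph$x_left)^2)
  }
  expect_lt(recon_mse(pre$params), recon_mse(init_model(arch, seed = 3)))
  expect_error(pretrain_vaes(list(x_left = matrix(0, 10, 1)), arch, cfg),
               "at least one batch")
})

test_that("training records the ramped schedules and loss identity", {
  arch <- tiny_arch(n_subjects = 4)
  ds <- tiny_dataset()
  sch <- schedule_config(beta_max = 0.4, beta_ramp_epochs = 4,
                         lambda_max = 0.8, lambda_ramp_epochs = 2)
  cfg <- train_config(batch_size = 32, max_epochs = 6, lr = 1e-3, seed = 5,
                      patience = 10, schedules = sch)
  fit <- train_bivdann(ds, arch, cfg)
  h <- fit$history
  expect_identical(h$beta[1], 0)
  expect_identical(h$lambda[1], 0)
  expect_equal(h$beta, pmin((h$epoch - 1) / 4, 1) * 0.4)
  expect_equal(h$lambda, pmin((h$epoch - 1) / 2, 1) * 0.8)
  # lambda capped at its max from the ramp end onwards
  expect_true(all(h$lambda[h$epoch >= 3] == 0.8))
  # recorded total obeys the combined-loss identity
  expect_equal(h$total,
               h$recon_l + h$beta * h$kl_l + h$recon_r + h$beta * h$kl_r +
                 h$emotion_loss - h$lambda * h$domain_loss,
               tolerance = 1e-6)
  expect_true(all(h$val_acc >= 0 & h$val_acc <= 1))
})

test_that("identical seed, config and data give bitwise-identical history", {
  arch <- tiny_arch(n_subjects = 4)
  ds <- tiny_dataset()
  cfg <- train_config(batch_size = 32, max_epochs = 4, lr = 1e-3, seed = 11,
                      schedules = small_schedules())
  f1 <- train_bivdann(ds, arch, cfg)
  f2 <- train_bivdann(ds, arch, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params[["ext.d1.W"]], f2$params[["ext.d1.W"]])
  f3 <- train_bivdann(ds, arch, train_config(batch_size = 32, max_epochs = 4,
                                             lr = 1e-3, seed = 12,
                                             schedules = small_schedules()))
  expect_false(identical(f1$history, f3$history))
})

test_that("early stopping restores a checkpoint attaining the best accuracy", {
  arch <- tiny_arch(n_subjects = 4)
  ds <- tiny_dataset()
  cfg <- train_config(batch_size = 32, max_epochs = 12, lr = 2e-3, seed = 7,
                      patience = 3, schedules = small_schedules())
  fit <- train_bivdann(ds, arch, cfg)
  h <- fit$history
  expect_lte(nrow(h), 12)
  expect_equal(h$val_acc[fit$best_epoch], max(h$val_acc))
  # restored parameters produce the recorded best validation accuracy
  p <- prepare_hemis(ds)
  val <- fit$val_idx
  pred <- predict_bivdann(fit$params, p$x_left[, val], p$x_right[, val])
  acc <- mean(max.col(t(pred$probs)) - 1L == p$y[val])
  expect_equal(acc, max(h$val_acc), tolerance = 1e-6)
})

test_that("an easy linearly separable fixture is fit by the plain classifier", {
  ds <- generate_topographs(synthetic_spec(
    n_subjects = 4, samples_per_subject = 40, subject_effect = 0,
    noise_sd = 0.2, seed = 13))
  arch <- small_arch(n_subjects = 4)
  cfg <- train_config(batch_size = 64, max_epochs = 25, lr = 2e-3, seed = 2,
                      patience = 25, variant = "BiCNN",
                      schedules = small_schedules())
  fit <- train_bivdann(ds, arch, cfg)
  expect_gt(max(fit$history$train_acc), 0.95)
})

test_that("unilateral variants train on a single hemisphere path", {
  ds <- tiny_dataset()
  for (v in c("L-VDANN", "R-VDANN")) {
    cfg <- train_config(batch_size = 32, max_epochs = 2, lr = 1e-3, seed = 6,
                        variant = v, schedules = small_schedules())
    fit <- train_bivdann(ds, tiny_arch(n_subjects = 4), cfg)
    h <- fit$history
    side <- if (v == "L-VDANN") "recon_l" else "recon_r"
    other <- if (v == "L-VDANN") "recon_r" else "recon_l"
    expect_true(all(is.finite(h[[side]])))
    expect_true(all(is.nan(h[[other]])))
    p <- prepare_hemis(ds)
    pred <- predict_bivdann(fit$params, p$x_left, p$x_right)
    expect_identical(dim(pred$probs), c(2L, 96L))
    expect_equal(colSums(pred$probs), rep(1, 96), tolerance = 1e-5)
  }
})

test_that("configuration errors are caught before training", {
  arch <- tiny_arch(n_subjects = 4)
  ds <- tiny_dataset()
  one_subj <- ds_subset(ds, which(ds$meta$subject_id == "S01"))
  cfg <- train_config(batch_size = 16, max_epochs = 2,
                      schedules = small_schedules())
  expect_error(train_bivdann(one_subj, arch, cfg), "2 subjects")
  # BiCNN has no discriminator, so a single subject is fine
  fit <- train_bivdann(one_subj, tiny_arch(n_subjects = 1),
                       train_config(batch_size = 16, max_epochs = 2,
                                    variant = "BiCNN",
                                    schedules = small_schedules()))
  expect_s3_class(fit$history, "data.frame")
})
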