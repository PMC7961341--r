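# Synthetic multi-subject generator: determinism, the designed lateralized
# class effect, null behaviour, and the EEG mode end-to-end.

test_that("spec validation and the effect-ratio dial", {
  expect_error(synthetic_spec(n_subjects = 1), "n_subjects")
  expect_error(synthetic_spec(n_classes = 1), "n_classes")
  expect_identical(effect_ratio(synthetic_spec(class_effect = 1,
                                               subject_effect = 2)), 2)
  expect_identical(effect_ratio(synthetic_spec(class_effect = 0)), Inf)
})

test_that("the same seed reproduces the dataset bit for bit", {
  s <- synthetic_spec(n_subjects = 3, samples_per_subject = 6, seed = 21)
  a <- generate_topographs(s)
  b <- generate_topographs(s)
  expect_identical(a$images, b$images)
  expect_identical(a$meta, b$meta)
  c <- generate_topographs(synthetic_spec(n_subjects = 3,
                                          samples_per_subject = 6, seed = 22))
  expect_false(identical(a$images, c$images))
})

test_that("generated images satisfy the topograph invariants", {
  ds <- tiny_dataset()
  expect_true(all(ds$images >= 0L & ds$images <= 255L))
  expect_identical(dim(ds$images)[2:4], c(3L, 64L, 64L))
  expect_identical(nrow(ds$meta), dim(ds$images)[1])
  # labels balanced within each subject
  tab <- table(ds$meta$subject_id, ds$meta$label)
  expect_true(all(tab == tab[1, 1]))
})

test_that("the class effect is a lateralized alpha asymmetry", {
  s <- synthetic_spec(n_subjects = 2, samples_per_subject = 10,
                      subject_effect = 0, noise_sd = 0, seed = 5)
  ds <- generate_topographs(s)
  asym <- function(rows) {
    img <- apply(ds$images[rows, 1, , , drop = FALSE], c(3, 4), mean)
    mean(img[, 1:32]) - mean(img[, 33:64])
  }
  a1 <- asym(which(ds$meta$label == "class1"))
  a2 <- asym(which(ds$meta$label == "class2"))
  expect_true(sign(a1) != sign(a2))
  expect_gt(abs(a1 - a2), 1)
})

test_that("without a class effect, class labels carry no image information", {
  # permutation test on the difference between class-mean alpha images
  stat <- function(imgs, lab) {
    m1 <- apply(imgs[lab == "class1", 1, , , drop = FALSE], c(3, 4), mean)
    m2 <- apply(imgs[lab == "class2", 1, , , drop = FALSE], c(3, 4), mean)
    mean((m1 - m2)^2)
  }
  rejections <- 0L
  n_seeds <- 12L
  for (sd_ in seq_len(n_seeds)) {
    ds <- generate_topographs(synthetic_spec(
      n_subjects = 2, samples_per_subject = 20, class_effect = 0, seed = 100 + sd_))
    obs <- stat(ds$images, ds$meta$label)
    perms <- withr::with_seed(sd_, replicate(39, {
      stat(ds$images, sample(ds$meta$label))
    }))
    if (mean(c(obs, perms) >= obs) <= 0.05) rejections <- rejections + 1L
  }
  # at alpha = 0.05 false rejections should be rare
  expect_lte(rejections, 2L)
})

test_that("EEG mode reproduces the designed band-power structure end-to-end", {
  s <- synthetic_spec(n_subjects = 2, n_classes = 2, samples_per_subject = 4,
                      subject_effect = 0, noise_sd = 0.1, n_channels = 16,
                      fs = 128, window_s = 4, mode = "eeg", seed = 31)
  recs <- generate_eeg(s)
  expect_length(recs, 8)
  expect_s3_class(recs[[1]], "eeg_recording")
  expect_identical(dim(recs[[1]]$data), c(16L, 512L))
  mon <- standard_montage(n = 16)
  alpha_asym <- function(rec) {
    seg <- sliding_windows(rec, window_s = 4, overlap = 0)[[1]]
    seg$channel_names <- rec$channel_names
    t <- segment_topograph(seg, mon)
    mean(t$image[1, , 1:32]) - mean(t$image[1, , 33:64])
  }
  lab <- vapply(recs, function(r) r$label, "")
  a1 <- mean(vapply(recs[lab == "class1"], alpha_asym, 0))
  a2 <- mean(vapply(recs[lab == "class2"], alpha_asym, 0))
  # class 1 has the negative template sign, class 2 the positive one
  expect_gt(abs(a1 - a2), 5)
  expect_true(sign(a1) != sign(a2))
})

test_that("zero amplitudes give identically zero recordings and topographs", {
  s <- synthetic_spec(n_subjects = 2, samples_per_subject = 2,
                      class_effect = 0, subject_effect = 0, noise_sd = 0,
                      base_amp = 0, n_channels = 8, fs = 128, window_s = 2,
                      mode = "eeg", seed = 1)
  recs <- generate_eeg(s)
  expect_true(all(vapply(recs, function(r) all(r$data == 0), TRUE)))
  seg <- sliding_windows(recs[[1]], 2, 0)[[1]]
  seg$channel_names <- recs[[1]]$channel_names
  t <- segment_topograph(seg, standard_montage(n = 8))
  expect_true(all(t$image == 0L))  # degenerate bands encode to zero
})
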