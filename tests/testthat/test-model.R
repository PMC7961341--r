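# Compiled model components: shapes, determinism, the reparameterization
# trick, gradient reversal, and backward passes against finite differences.

test_that("the default configuration realizes the reference dimension chain", {
  arch <- arch_config(latent_dim = 64, n_classes = 3, n_subjects = 15)
  sh <- bivdann:::.nn_shapes(arch)
  expect_identical(sh$emb_dim, 128L)      # bilateral embedding width
  expect_identical(arch$latent, 64L)      # unilateral embedding width
  # three stride-2 stages: 64x32 -> 32x16 -> 16x8 -> 8x4
  expect_identical(sh$enc_stages, c(32L, 16L, 16L, 8L, 8L, 4L))
  expect_identical(sh$enc_flat, 8L * 4L * 128L)
})

test_that("encoding is deterministic with independent hemispheric weights", {
  arch <- tiny_arch()
  params <- init_model(arch, seed = 2)
  b <- tiny_batch(n = 2)
  c1 <- encode(b$xl, params, "left")
  c2 <- encode(b$xl, params, "left")
  expect_identical(c1$mu, c2$mu)
  expect_identical(c1$log_var, c2$log_var)
  expect_identical(nrow(c1$mu), arch$latent)
  # the same image through the other hemisphere's weights differs
  cr <- encode(b$xl, params, "right")
  expect_gt(max(abs(c1$mu - cr$mu)), 1e-6)
})

test_that("reparameterization follows z = mu + sigma * eps", {
  code <- list(mu = c(1, -2, 0), log_var = c(0, 0, 0))
  expect_equal(reparameterize(code, eps = c(0, 0, 0)), code$mu)
  code0 <- list(mu = c(0, 0), log_var = c(0, 0))
  expect_equal(reparameterize(code0, eps = c(1.3, -0.2)), c(1.3, -0.2))
  # mu = 1, sigma = 2, eps = 0.5 -> 2
  expect_equal(reparameterize(list(mu = 1, log_var = 2 * log(2)), eps = 0.5), 2)
})

test_that("decoding returns bounded images of the input shape", {
  arch <- tiny_arch()
  params <- init_model(arch, seed = 3)
  z <- stats::rnorm(arch$latent)
  x1 <- decode(z, params, "left")
  x2 <- decode(z, params, "left")
  expect_identical(dim(x1), c(3L, 64L, 32L))
  expect_identical(x1, x2)
  expect_true(all(x1 >= 0 & x1 <= 1))
})

test_that("the bilateral embedding mixes both hemispheres", {
  arch <- tiny_arch()
  params <- init_model(arch, seed = 4)
  withr::with_seed(1, {
    zl <- stats::rnorm(arch$latent)
    zr <- stats::rnorm(arch$latent)
  })
  e1 <- bilateral_features(zl, zr, params)
  expect_length(e1, arch$ext_dense)
  expect_identical(e1, bilateral_features(zl, zr, params))
  # swapping hemispheres changes the embedding for generic weights
  e2 <- bilateral_features(zr, zl, params)
  expect_gt(max(abs(e1 - e2)), 1e-6)
})

test_that("classifier heads return normalized probabilities", {
  arch <- tiny_arch(n_classes = 3, n_subjects = 5)
  params <- init_model(arch, seed = 5)
  emb <- stats::rnorm(arch$ext_dense)
  py <- classify_emotion(emb, params)
  ps <- classify_subject(emb, params)
  expect_length(py, 3)
  expect_length(ps, 5)
  expect_equal(sum(py), 1, tolerance = 1e-6)
  expect_equal(sum(ps), 1, tolerance = 1e-6)
  expect_true(all(py >= 0) && all(ps >= 0))
  # zeroed output layer -> uniform logits -> uniform probabilities
  p0 <- params
  p0[["cls.dout.W"]][] <- 0
  p0[["cls.dout.b"]][] <- 0
  attr(p0, "arch") <- arch
  expect_equal(as.numeric(classify_emotion(emb, p0)), rep(1 / 3, 3),
               tolerance = 1e-6)
})

test_that("gradient reversal is identity forward and -lambda backward", {
  x <- c(-1.5, 0.2, 3)
  expect_equal(as.numeric(grad_reverse(x, 1)), x)
  expect_equal(as.numeric(grad_reverse(x, 0)), x)
  g <- c(0.4, -2, 1)
  expect_equal(grad_reverse_backward(g, 1), -g)
  expect_equal(grad_reverse_backward(g, 0.5), -0.5 * g)
  expect_identical(grad_reverse_backward(g, 0), c(0, 0, 0))
  # composite scalar function: f(grad_reverse(x, l)); the gradient reaching
  # x must equal -l * f'(x), with f' taken by central finite differences
  f <- function(x) sum(sin(x) + 0.5 * x^2)
  fd <- vapply(seq_along(x), function(i) {
    h <- 1e-6
    xp <- x; xm <- x
    xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, 0)
  for (l in c(0, 0.5, 1)) {
    upstream <- grad_reverse_backward(cos(x) + x, l)  # analytic f'(x)
    expect_equal(upstream, -l * fd, tolerance = 1e-5)
  }
})

test_that("VAE parameter gradients match central finite differences", {
  arch <- tiny_arch()
  params <- init_model(arch, seed = 6)
  b <- tiny_batch(n = 3)
  out <- bivdann:::.nn_vae_grad(params, arch, b$xl, 0.3, FALSE)
  expect_gte(out$kl, 0)
  h <- 2e-3
  for (nm in c("enc_l.c1.W", "enc_l.bn2.gamma", "enc_l.dmu.b",
               "dec_l.t1.W", "dec_l.d0.W")) {
    w <- params[[nm]]
    idx <- which.max(abs(out$grads[[nm]]))  # check the steepest coordinate
    pp <- params; pp[[nm]][idx] <- w[idx] + h
    pm <- params; pm[[nm]][idx] <- w[idx] - h
    fp <- bivdann:::.nn_vae_grad(pp, arch, b$xl, 0.3, FALSE)$loss
    fm <- bivdann:::.nn_vae_grad(pm, arch, b$xl, 0.3, FALSE)$loss
    fd <- (fp - fm) / (2 * h)
    expect_equal(out$grads[[nm]][idx], fd, tolerance = 0.05,
                 label = paste("grad", nm))
  }
})

test_that("adversarial gradients realize the reversed subject loss", {
  arch <- tiny_arch()
  params <- init_model(arch, seed = 7)
  b <- tiny_batch(n = 4)
  lam <- 0.7
  out <- bivdann:::.nn_adv_grad(params, arch, b$xl, b$xr, b$y, b$s, lam)
  expect_equal(out$loss, out$loss_y - lam * out$loss_d, tolerance = 1e-6)
  # finite differences of (L_y - lambda * L_d) on shared parameters
  h <- 1e-3
  for (nm in c("enc_l.c1.W", "ext.d1.W", "cls.d1.W")) {
    idx <- which.max(abs(out$grads[[nm]]))
    pp <- params; pp[[nm]][idx] <- pp[[nm]][idx] + h
    pm <- params; pm[[nm]][idx] <- pm[[nm]][idx] - h
    op <- bivdann:::.nn_adv_grad(pp, arch, b$xl, b$xr, b$y, b$s, lam)
    om <- bivdann:::.nn_adv_grad(pm, arch, b$xl, b$xr, b$y, b$s, lam)
    fd <- (op$loss - om$loss) / (2 * h)
    expect_equal(out$grads[[nm]][idx], fd, tolerance = 0.05,
                 label = paste("adv grad", nm))
  }
  # with lambda = 0 the shared gradients lose the domain component entirely
  o0 <- bivdann:::.nn_adv_grad(params, arch, b$xl, b$xr, b$y, b$s, 0)
  idx <- which.max(abs(o0$grads[["ext.d1.W"]]))
  pp <- params; pp[["ext.d1.W"]][idx] <- pp[["ext.d1.W"]][idx] + h
  pm <- params; pm[["ext.d1.W"]][idx] <- pm[["ext.d1.W"]][idx] - h
  fd0 <- (bivdann:::.nn_adv_grad(pp, arch, b$xl, b$xr, b$y, b$s, 0)$loss_y -
          bivdann:::.nn_adv_grad(pm, arch, b$xl, b$xr, b$y, b$s, 0)$loss_y) / (2 * h)
  expect_equal(o0$grads[["ext.d1.W"]][idx], fd0, tolerance = 0.05)
})

test_that("interleaved sub-steps touch only their own parameter groups", {
  arch <- tiny_arch()
  params <- init_model(arch, seed = 8)
  b <- tiny_batch(n = 6)
  opts <- list(lr = 1e-3, beta = 0.1, lambda = 0.5,
               use_kl = TRUE, use_disc = TRUE, sample_z = TRUE)
  after_disc <- bivdann:::.nn_step(params, arch, b$xl, b$xr, b$y, b$s,
                                   opts, "disc", 1)
  expect_false(isTRUE(all.equal(param_hash(params, "^dsc\\."),
                                param_hash(after_disc, "^dsc\\."))))
  for (grp in c("^enc_", "^dec_", "^ext\\.", "^cls\\.")) {
    expect_equal(param_hash(params, paste0(grp, ".*(W|b|gamma|beta)$")),
                 param_hash(after_disc, paste0(grp, ".*(W|b|gamma|beta)$")),
                 tolerance = 1e-12, label = paste("disc step leaves", grp))
  }
  after_vae <- bivdann:::.nn_step(params, arch, b$xl, b$xr, b$y, b$s,
                                  opts, "vae", 1)
  expect_false(isTRUE(all.equal(param_hash(params, "^enc_l\\."),
                                param_hash(after_vae, "^enc_l\\."))))
  expect_false(isTRUE(all.equal(param_hash(params, "^dec_r\\."),
                                param_hash(after_vae, "^dec_r\\."))))
  for (grp in c("^ext\\.", "^cls\\.", "^dsc\\.")) {
    expect_equal(param_hash(params, paste0(grp, ".*(W|b|gamma|beta)$")),
                 param_hash(after_vae, paste0(grp, ".*(W|b|gamma|beta)$")),
                 tolerance = 1e-12, label = paste("vae step leaves", grp))
  }
  # the adversarial step must not move the discriminator or decoders
  after_adv <- bivdann:::.nn_step(params, arch, b$xl, b$xr, b$y, b$s,
                                  opts, "adv", 1)
  for (grp in c("^dsc\\.", "^dec_")) {
    expect_equal(param_hash(params, paste0(grp, ".*(W|b|gamma|beta)$")),
                 param_hash(after_adv, paste0(grp, ".*(W|b|gamma|beta)$")),
                 tolerance = 1e-12, label = paste("adv step leaves", grp))
  }
  expect_false(isTRUE(all.equal(param_hash(params, "^cls\\."),
                                param_hash(after_adv, "^cls\\."))))
})

test_that("hemisphere input shape is validated", {
  arch <- tiny_arch()
  params <- init_model(arch, seed = 9)
  expect_error(encode(matrix(0, 10, 1), params, "left"), "shape")
  expect_error(decode(rep(0, arch$latent + 1), params, "left"), "dimension")
})
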