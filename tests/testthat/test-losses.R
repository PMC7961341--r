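# Loss terms and schedules against closed-form and Monte-Carlo oracles.

test_that("gaussian_kl matches closed-form values", {
  expect_identical(gaussian_kl(0, 0), 0)
  expect_identical(gaussian_kl(rep(0, 64), rep(0, 64)), 0)
  # J = 1, mu = 1, sigma = 1: -1/2 (1 + 0 - 1 - 1) = 1/2
  expect_equal(gaussian_kl(1, 0), 0.5)
  # J = 1, mu = 0, sigma^2 = 4: 3/2 - log 2
  expect_equal(gaussian_kl(0, log(4)), 1.5 - log(2))
  # additivity over dimensions
  expect_equal(gaussian_kl(c(1, 0), c(0, log(4))), 0.5 + 1.5 - log(2))
})

test_that("gaussian_kl is nonnegative and agrees with Monte-Carlo estimates", {
  withr::with_seed(42, {
    for (i in 1:10) {
      mu <- stats::rnorm(1, 0, 1.5)
      lv <- stats::rnorm(1, 0, 0.8)
      kl <- gaussian_kl(mu, lv)
      expect_gte(kl, 0)
      # E_q[log q(z) - log p(z)] by simulation
      z <- stats::rnorm(1e6, mu, exp(lv / 2))
      mc <- mean(stats::dnorm(z, mu, exp(lv / 2), log = TRUE) -
                   stats::dnorm(z, 0, 1, log = TRUE))
      expect_equal(kl, mc, tolerance = 0.01)
    }
  })
})

test_that("gaussian_kl rejects pathological input", {
  expect_error(gaussian_kl(NaN, 0), "non-finite")
  expect_error(gaussian_kl(c(0, 0), 0), "lengths")
})

test_that("reconstruction loss is the mean squared pixel difference", {
  x <- array(0, c(3, 4, 4))
  expect_identical(reconstruction_loss(x, x), 0)
  expect_identical(reconstruction_loss(x, x + 1), 1)
  withr::with_seed(1, {
    a <- array(stats::runif(48), c(3, 4, 4))
    b <- array(stats::runif(48), c(3, 4, 4))
    expect_equal(reconstruction_loss(a, b), sum((a - b)^2) / 48,
                 tolerance = 1e-10)
  })
  expect_error(reconstruction_loss(a, array(0, c(3, 4, 5))), "shape")
})

test_that("beta-weighted VAE loss reduces correctly at the endpoints", {
  expect_identical(beta_vae_loss(0.3, 2, 0), 0.3)
  expect_identical(beta_vae_loss(0.3, 2, 1), 2.3)
  expect_gt(beta_vae_loss(0.3, 2, 1.5), beta_vae_loss(0.3, 2, 1))
  expect_error(beta_vae_loss(0.3, 2, -1), "nonnegative")
})

test_that("cross entropy matches hand-computed values", {
  expect_identical(cross_entropy(c(0, 1, 0), 2), 0)
  expect_equal(cross_entropy(rep(1 / 3, 3), 1), log(3))
  expect_equal(cross_entropy(rep(1 / 32, 32), 17), log(32))
  # a zero probability at the label is clamped, not infinite
  expect_true(is.finite(cross_entropy(c(1, 0), 2)))
  expect_error(cross_entropy(c(0.7, 0.7), 1), "sum")
})

test_that("the total loss obeys the combined-objective identity", {
  lb <- loss_breakdown(recon_l = 0, recon_r = 0, kl_l = 0, kl_r = 0,
                       emotion_loss = 0, domain_loss = 0, beta = 1, lambda = 1)
  expect_identical(lb$total, 0)
  withr::with_seed(8, {
    for (i in 1:20) {
      p <- stats::runif(8)
      lb <- loss_breakdown(p[1], p[2], p[3], p[4], p[5], p[6], p[7], p[8])
      expect_equal(lb$total,
                   p[1] + p[7] * p[3] + p[2] + p[7] * p[4] + p[5] - p[8] * p[6],
                   tolerance = 1e-12)
    }
  })
  # with lambda = 0 the total is independent of the domain loss
  a <- loss_breakdown(1, 1, 1, 1, 1, 0.2, 0.5, 0)
  b <- loss_breakdown(1, 1, 1, 1, 1, 9.9, 0.5, 0)
  expect_identical(a$total, b$total)
})

test_that("reversed updates realize the saddle-point dynamics on a quadratic toy", {
  # feature parameter f, discriminator parameter d:
  #   L_emotion = (f - 1)^2 / 2,  L_domain = (f - d)^2 / 2
  # total = L_emotion - lambda * L_domain; f descends the total (domain term
  # arriving through the reversal contract), d ascends it by minimizing its
  # own cross-entropy analogue
  f <- -2; d <- 3
  lambda <- 0.5; eta <- 0.05
  ly <- function(f) (f - 1)^2 / 2
  ld <- function(f, d) (f - d)^2 / 2
  ly_hist <- numeric(0)
  for (i in 1:200) {
    # discriminator step: minimize its own loss
    d <- d - eta * (d - f)
    # feature step: dL_emotion/df plus the reversed domain gradient
    g_dom <- grad_reverse_backward((f - d), lambda)
    g <- (f - 1) + g_dom
    # hand-computed total gradient: d/df [ly - lambda*ld]
    expect_equal(g, (f - 1) - lambda * (f - d), tolerance = 1e-12)
    # the reversed component is exactly the negated, scaled domain gradient:
    # it pushes f away from the discriminator's current target
    expect_equal(g_dom, -lambda * (f - d), tolerance = 1e-12)
    f <- f - eta * g
    ly_hist <- c(ly_hist, ly(f))
  }
  # emotion loss decreases to its optimum while the discriminator tracks
  expect_lt(ly_hist[200], ly_hist[1])
  expect_lt(ly_hist[200], 1e-2)
  expect_lt(ld(f, d), 1e-2)
})

test_that("linear warm-up schedule hits its anchor points", {
  expect_identical(ramp(0, 1, 100), 0)
  expect_identical(ramp(100, 1, 100), 1)
  expect_identical(ramp(150, 1, 100), 1)
  expect_identical(ramp(50, 1, 100), 0.5)
  expect_identical(ramp(25, 1, 50), 0.5)
  expect_identical(ramp(50, 2, 50), 2)
  expect_error(ramp(-1, 1, 100), "nonnegative")
  expect_error(ramp(10, 1, 0), "positive")
})
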