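# Closed-form divergences and the structure of the variational objectives.

test_that("diagonal Gaussian KL matches its closed form", {
  expect_equal(gaussian_kl_diag(c(1, -2), c(0.5, 2), c(1, -2), c(0.5, 2)), 0)
  expect_equal(gaussian_kl_diag(1, 1, 0, 1), 0.5, tolerance = 1e-12)
  expect_equal(gaussian_kl_diag(0, 4, 0, 1), 0.5 * (4 - 1 - log(4)),
               tolerance = 1e-12)
  expect_gte(gaussian_kl_diag(rnorm(3), runif(3, 0.1, 2), rnorm(3), runif(3, 0.1, 2)), 0)
  expect_error(gaussian_kl_diag(0, -1, 0, 1), "positive")
})

test_that("categorical KL matches direct evaluation", {
  expect_equal(categorical_kl(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(categorical_kl(c(1, 0), c(0.5, 0.5)), log(2), tolerance = 1e-12)
  p <- c(0.7, 0.1, 0.1, 0.1)
  expect_equal(categorical_kl(rep(0.25, 4), p), sum(0.25 * log(0.25 / p)),
               tolerance = 1e-12)
  expect_identical(categorical_kl(c(0.5, 0.5), c(1, 0)), Inf)
  expect_error(categorical_kl(c(0.5, 0.4), c(0.5, 0.5)), "simplices")
})

test_that("single-frame labeled bound matches a hand-coded VAE bound", {
  # K = 1, T = 1, linear 1-D emission: recon + log pi - KL(q(z1) || N(0,1))
  pp <- rslds_params(K = 1, Dz = 1, Dx = 1, pi0 = 1,
                     dyn_A = list(matrix(0.5)), dyn_b = list(0),
                     dyn_Q = list(matrix(1)), rec_R = list(matrix(0, 1, 1)),
                     rec_r = list(0), emission = list(C = matrix(2), d = 0.5),
                     emission_S = matrix(0.3))
  mu <- 0.4; lv <- log(0.6); x <- 1.1; seed <- 13
  fac <- posterior_factors(matrix(1, 1, 1), array(mu, c(1, 1, 1)),
                           array(lv, c(1, 1, 1)))
  got <- labeled_elbo(pp, fac, matrix(x, 1, 1), 0L, seed = seed)
  eps <- s3lds:::draw_eps(1, 1, 1, seed)[1, 1, 1]
  ztil <- mu + exp(0.5 * lv) * eps
  recon <- dnorm(x, 2 * ztil + 0.5, sqrt(0.3), log = TRUE)
  kl <- gaussian_kl_diag(mu, exp(lv), 0, 1)
  expect_equal(got$recon, recon, tolerance = 1e-10)
  expect_equal(got$kl_z_init, kl, tolerance = 1e-10)
  expect_equal(got$total, recon - kl + log(1), tolerance = 1e-10)
})

test_that("one-hot substitution reproduces the labeled bound term by term", {
  pp <- make_tiny_rslds(seed = 41, K = 2, Dz = 2, Dx = 3, recurrent = TRUE)
  traj <- sample_rslds(pp, 7, seed = 42)
  fac_free <- make_factors(7, 2, 2, seed = 43)
  fac <- posterior_factors(one_hot_rows(traj$y, 2), fac_free$z_mean,
                           fac_free$z_logvar)
  a <- unlabeled_elbo(pp, fac, traj$x, seed = 44)
  b <- labeled_elbo(pp, fac, traj$x, traj$y, seed = 44)
  for (nm in c("recon", "kl_z_init", "kl_z_dyn", "kl_y", "log_py1", "total")) {
    expect_equal(a[[nm]], b[[nm]], tolerance = 1e-6, label = nm)
  }
})

test_that("identical states make the bound permutation invariant", {
  pp <- make_tiny_rslds(seed = 45, K = 2, Dz = 1, Dx = 2)
  for (f in c("dyn_A", "dyn_b", "dyn_Q", "rec_R")) {
    pp[[f]][[2]] <- pp[[f]][[1]]
  }
  # destination-indexed quantities must themselves be exchangeable
  pp$rec_r <- list(c(0.2, 0.2), c(0.2, 0.2))
  pp$pi0 <- c(0.5, 0.5)
  traj <- sample_rslds(pp, 6, seed = 46)
  fac <- make_factors(6, 2, 1, seed = 47)
  # identical per-class encoders with vanishing variance (so the per-class
  # noise draws drop out) and swapped class columns
  zm <- fac$z_mean; zm[, 2, ] <- zm[, 1, ]
  zl <- fac$z_logvar * 0 - 80
  f1 <- posterior_factors(fac$class_probs, zm, zl)
  f2 <- posterior_factors(fac$class_probs[, 2:1], zm, zl)
  a <- unlabeled_elbo(pp, f1, traj$x, seed = 48)
  b <- unlabeled_elbo(pp, f2, traj$x, seed = 48)
  expect_equal(a$total, b$total, tolerance = 1e-9)
})

test_that("the mixed loss reduces to its labeled and unlabeled limits", {
  pp <- make_tiny_rslds(seed = 51, K = 2, Dz = 1, Dx = 2, recurrent = TRUE)
  traj <- sample_rslds(pp, 8, seed = 52)
  fac_free <- make_factors(8, 2, 1, seed = 53)
  cfg <- loss_config(alpha = 100, class_weights = c(0.8, 1.2))

  # fully labeled: labeled bound plus the weighted label log likelihood
  fac_hot <- posterior_factors(one_hot_rows(traj$y, 2) * 0.999998 + 1e-6,
                               fac_free$z_mean, fac_free$z_logvar)
  ss <- semisupervised_loss(pp, fac_hot, traj$x, traj$y, cfg, anneal_w = 1, seed = 54)
  lab <- labeled_elbo(pp, fac_hot, traj$x, traj$y, seed = 54)
  wll <- 100 * sum(c(0.8, 1.2)[traj$y + 1L] *
                     log(fac_hot$class_probs[cbind(1:8, traj$y + 1L)]))
  expect_equal(ss$classification, wll, tolerance = 1e-8)
  expect_equal(ss$total, lab$total + wll, tolerance = 1e-4)

  # fully unlabeled: exactly the unlabeled bound, classification term zero
  y_none <- rep(SEG_UNLABELED, 8)
  ss_u <- semisupervised_loss(pp, fac_free, traj$x, y_none, cfg, anneal_w = 1, seed = 54)
  un <- unlabeled_elbo(pp, fac_free, traj$x, seed = 54)
  expect_equal(ss_u$classification, 0)
  expect_equal(ss_u$total, un$total, tolerance = 1e-9)

  # background frames behave exactly like unlabeled frames
  y_bg <- rep(SEG_BACKGROUND, 8)
  ss_b <- semisupervised_loss(pp, fac_free, traj$x, y_bg, cfg, anneal_w = 1, seed = 54)
  expect_equal(ss_b$total, un$total, tolerance = 1e-9)

  # alpha = 0 removes the classification term only
  y_mix <- traj$y; y_mix[3:6] <- SEG_UNLABELED
  ss0 <- semisupervised_loss(pp, fac_free, traj$x, y_mix, loss_config(alpha = 0),
                             anneal_w = 1, seed = 54)
  expect_equal(ss0$classification, 0)
})

test_that("objective terms satisfy the sign and totalling invariants", {
  pp <- make_tiny_rslds(seed = 55, K = 3, Dz = 2, Dx = 2, recurrent = TRUE)
  traj <- sample_rslds(pp, 9, seed = 56)
  fac <- make_factors(9, 3, 2, seed = 57)
  y <- traj$y; y[c(2, 5, 8)] <- SEG_UNLABELED
  for (aw in c(0, 0.4, 1)) {
    ot <- semisupervised_loss(pp, fac, traj$x, y, loss_config(alpha = 50),
                              anneal_w = aw, seed = 58)
    expect_gte(ot$kl_z_init, -1e-9)
    expect_gte(ot$kl_z_dyn, -1e-9)
    expect_gte(ot$kl_y, -1e-9)
    expect_true(is.finite(ot$total))
    expect_equal(ot$total,
                 ot$recon - aw * (ot$kl_z_init + ot$kl_z_dyn + ot$kl_y) +
                   ot$classification,
                 tolerance = 1e-9)
  }
})

test_that("static mixture bound reduces correctly at one-hot and uniform q", {
  set.seed(61)
  pp <- gmdgm_params(K = 2, Dz = 1, Dx = 1, pi0 = c(0.5, 0.5),
                     cluster_mean = list(-1, 1), cluster_var = list(0.5, 0.5),
                     emission = list(C = matrix(1.5), d = 0),
                     emission_cov = matrix(0.4))
  x <- matrix(c(0.3, -0.8), 2, 1)
  mu <- array(c(0.2, -0.1, 0.4, 0.1), c(2, 2, 1))
  lv <- array(-40, c(2, 2, 1)) # variance ~ 0 so all class samples equal mu

  # one-hot q at class 1: unlabeled bound equals the labeled bound at class 1
  q_hot <- matrix(c(1, 1, 0, 0), 2, 2)
  fac_hot <- posterior_factors(q_hot, mu, lv)
  got <- gmdgm_elbo(pp, fac_hot, x, labels = NULL, seed = 62)
  ll_manual <- sum(dnorm(x[, 1], 1.5 * mu[, 1, 1], sqrt(0.4), log = TRUE)) +
    2 * log(0.5) -
    sum(vapply(1:2, function(t)
      gaussian_kl_diag(mu[t, 1, 1], exp(-40), -1, 0.5), 1))
  expect_equal(got$total, ll_manual, tolerance = 1e-6)

  # uniform q with identical clusters and encoders: total = L_l (entropy
  # cancels the log-prior term exactly)
  pp_id <- pp
  pp_id$cluster_mean <- list(0.5, 0.5); pp_id$cluster_var <- list(0.3, 0.3)
  mu_id <- mu; mu_id[, 2, ] <- mu_id[, 1, ]
  fac_u <- posterior_factors(matrix(0.5, 2, 2), mu_id, lv)
  got_u <- gmdgm_elbo(pp_id, fac_u, x, labels = NULL, seed = 63)
  ll_id <- sum(dnorm(x[, 1], 1.5 * mu_id[, 1, 1], sqrt(0.4), log = TRUE)) -
    sum(vapply(1:2, function(t)
      gaussian_kl_diag(mu_id[t, 1, 1], exp(-40), 0.5, 0.3), 1))
  expect_equal(got_u$total, ll_id, tolerance = 1e-6)
})
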