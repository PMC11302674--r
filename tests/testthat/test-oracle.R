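# Exact-inference oracles, validated bottom-up: the Kalman filter against
# dense joint Gaussians, then the enumeration marginal against numerical
# quadrature.

test_that("Kalman likelihood matches closed forms", {
  # T = 1: x1 ~ N(C*0 + d, C C' + S) under the standard-normal latent prior
  C <- matrix(c(1.2, -0.4), 2, 1); d <- c(0.1, 0.2); S <- diag(c(0.5, 0.3))
  x <- matrix(c(0.7, -0.2), 1, 2)
  ll <- kalman_loglik(x, matrix(0.9), 0, matrix(0.2), C, d, S)
  Sx <- C %*% t(C) + S
  expect_equal(ll, s3lds:::dmvnorm_log(x[1, ], d, Sx), tolerance = 1e-10)

  # T = 3, Dz = Dx = 1: against the explicitly assembled joint Gaussian
  A <- 0.8; b <- 0.3; Q <- 0.3; Cm <- 1.2; dm <- 0.1; Sm <- 0.4
  x3 <- matrix(c(0.5, -0.3, 0.9), 3, 1)
  ll3 <- kalman_loglik(x3, matrix(A), b, matrix(Q), matrix(Cm), dm, matrix(Sm))
  # z moments: mean (0, b, A b + b), cov by propagation
  mz <- c(0, b, A * b + b)
  Pz <- matrix(0, 3, 3)
  Pz[1, 1] <- 1
  Pz[2, 2] <- A^2 * Pz[1, 1] + Q
  Pz[3, 3] <- A^2 * Pz[2, 2] + Q
  Pz[1, 2] <- Pz[2, 1] <- A * Pz[1, 1]
  Pz[2, 3] <- Pz[3, 2] <- A * Pz[2, 2]
  Pz[1, 3] <- Pz[3, 1] <- A^2 * Pz[1, 1]
  Sx3 <- Cm^2 * Pz + diag(Sm, 3)
  expect_equal(ll3, s3lds:::dmvnorm_log(x3[, 1], Cm * mz + dm, Sx3),
               tolerance = 1e-9)

  # S -> large drives the per-frame likelihood to the flat-Gaussian value
  llb <- kalman_loglik(x3, matrix(A), b, matrix(Q), matrix(Cm), dm, matrix(1e6))
  expect_equal(llb, sum(dnorm(x3, dm, sqrt(1e6 + Cm^2 * diag(Pz)), log = TRUE)),
               tolerance = 1e-3)
})

test_that("enumeration reduces to the Kalman filter for trivial mixtures", {
  pp <- make_tiny_rslds(seed = 71, K = 1, Dz = 1, Dx = 1)
  x <- sample_rslds(pp, 4, seed = 72)$x
  en <- exact_log_marginal(pp, x)
  ll <- kalman_loglik(x, pp$dyn_A[[1]], pp$dyn_b[[1]], pp$dyn_Q[[1]],
                      pp$emission$C, pp$emission$d, pp$emission_S)
  expect_equal(en$log_marginal, ll, tolerance = 1e-10)
  expect_equal(s3lds:::logsumexp(en$log_weights), en$log_marginal,
               tolerance = 1e-9)

  # two identical states: mixture of identical components equals K = 1 value
  pp2 <- make_tiny_rslds(seed = 73, K = 2, Dz = 1, Dx = 1)
  for (f in c("dyn_A", "dyn_b", "dyn_Q")) pp2[[f]][[2]] <- pp2[[f]][[1]]
  en2 <- exact_log_marginal(pp2, x)
  ll2 <- kalman_loglik(x, pp2$dyn_A[[1]], pp2$dyn_b[[1]], pp2$dyn_Q[[1]],
                       pp2$emission$C, pp2$emission$d, pp2$emission_S)
  expect_equal(en2$log_marginal, ll2, tolerance = 1e-10)
})

test_that("enumeration agrees with 2-D numerical quadrature", {
  pp <- rslds_params(K = 2, Dz = 1, Dx = 1, pi0 = c(0.6, 0.4),
                     dyn_A = list(matrix(0.8), matrix(-0.5)),
                     dyn_b = list(0.3, -0.2),
                     dyn_Q = list(matrix(0.3), matrix(0.5)),
                     rec_R = list(matrix(0, 2, 1), matrix(0, 2, 1)),
                     rec_r = list(c(0.4, -0.4), c(-0.2, 0.2)),
                     emission = list(C = matrix(1.2), d = 0.1),
                     emission_S = matrix(0.4))
  x <- matrix(c(0.5, -0.3), 2, 1)
  en <- exact_log_marginal(pp, x)
  gr <- seq(-8, 8, length.out = 501); dg <- gr[2] - gr[1]
  tot <- 0
  for (y1 in 0:1) for (y2 in 0:1) {
    py <- pp$pi0[y1 + 1] * s3lds:::softmax_vec(pp$rec_r[[y1 + 1]])[y2 + 1]
    A <- c(0.8, -0.5)[y2 + 1]; b <- c(0.3, -0.2)[y2 + 1]; Q <- c(0.3, 0.5)[y2 + 1]
    f <- outer(gr, gr, function(z1, z2)
      dnorm(z1) * dnorm(z2, A * z1 + b, sqrt(Q)) *
        dnorm(x[1], 1.2 * z1 + 0.1, sqrt(0.4)) *
        dnorm(x[2], 1.2 * z2 + 0.1, sqrt(0.4)))
    tot <- tot + py * sum(f) * dg^2
  }
  expect_equal(en$log_marginal, log(tot), tolerance = 1e-4)
})

test_that("the oracle refuses inputs outside its validity domain", {
  pp <- make_tiny_rslds(seed = 74, K = 2, Dz = 1, Dx = 1, recurrent = TRUE)
  x <- matrix(rnorm(3), 3, 1)
  expect_error(exact_log_marginal(pp, x), "rec_R")
  pp2 <- make_tiny_rslds(seed = 75, K = 3, Dz = 1, Dx = 1)
  expect_error(exact_log_marginal(pp2, matrix(rnorm(20), 20, 1)), "budget")
})
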