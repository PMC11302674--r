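# Fixture builders shared across test files. Everything is generated in code;
# instances are tiny so exact oracles (enumeration, quadrature, numerical
# gradients) stay affordable.

# Random small switching model with diagonal covariances; non-recurrent by
# default so the enumeration oracle applies.
make_tiny_rslds <- function(seed = 1L, K = 2L, Dz = 1L, Dx = 1L,
                            recurrent = FALSE) {
  set.seed(seed)
  rand_pd_diag <- function(d, lo = 0.2, hi = 0.8) diag(runif(d, lo, hi), d)
  rslds_params(
    K = K, Dz = Dz, Dx = Dx,
    pi0 = as.numeric(prop.table(runif(K, 0.5, 1.5))),
    dyn_A = replicate(K, matrix(runif(Dz * Dz, -0.6, 0.6), Dz, Dz), simplify = FALSE),
    dyn_b = replicate(K, rnorm(Dz, 0, 0.4), simplify = FALSE),
    dyn_Q = replicate(K, rand_pd_diag(Dz), simplify = FALSE),
    rec_R = replicate(K, if (recurrent) matrix(rnorm(K * Dz, 0, 0.5), K, Dz)
                      else matrix(0, K, Dz), simplify = FALSE),
    rec_r = replicate(K, rnorm(K, 0, 0.5), simplify = FALSE),
    emission = list(C = matrix(rnorm(Dx * Dz, 0, 1), Dx, Dz), d = rnorm(Dx, 0, 0.3)),
    emission_S = rand_pd_diag(Dx, 0.3, 0.7)
  )
}

# Random valid posterior factors for T frames, K classes, Dz latents.
make_factors <- function(T_len, K, Dz, seed = 1L) {
  set.seed(seed)
  posterior_factors(
    s3lds:::softmax_rows(matrix(rnorm(T_len * K), T_len, K)),
    array(rnorm(T_len * K * Dz, 0, 0.6), c(T_len, K, Dz)),
    array(rnorm(T_len * K * Dz, -0.5, 0.4), c(T_len, K, Dz))
  )
}

one_hot_rows <- function(y, K) {
  m <- matrix(0, length(y), K)
  m[cbind(seq_along(y), y + 1L)] <- 1
  m
}

# Central-difference gradient of f at x (a numeric vector).
numeric_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# Tiny well-separated sessions from the documented preset.
make_preset_sessions <- function(T_train, labeled_fraction = 1, seed = 1L) {
  pre <- rslds_preset("two_state")
  traj <- sample_rslds(pre$params, T_train, seed = seed)
  lab <- mask_labels(traj$y, labeled_fraction, seed = seed + 1L)
  list(sessions = list(list(features = feature_sequence(traj$x),
                            labels = label_sequence(lab, pre$class_names))),
       traj = traj, preset = pre)
}

write_plain_csv <- function(m, path, names = paste0("f", seq_len(ncol(m)))) {
  df <- as.data.frame(m)
  colnames(df) <- names
  utils::write.csv(df, path, row.names = FALSE)
  path
}
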