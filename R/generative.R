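# Generative models and ancestral samplers.
#
# The temporal model is a recurrent switching (non)linear dynamical system:
# a discrete behavior state y_t with transitions conditioned on the previous
# state and the previous continuous latent z_(t-1); piecewise-linear (or
# one-hidden-layer MLP) latent dynamics per state; and a shared emission
# mapping z_t to the observed features x_t with Gaussian noise S. The static
# ablation is a Gaussian-mixture deep generative model (GMDGM) without
# temporal coupling. The samplers double as the synthetic-data generators
# used throughout the test suite.

# ---- one-hidden-layer MLP helpers ------------------------------------------

# Generative nonlinearities are one-hidden-layer dense networks whose hidden
# width always equals the continuous latent dimension.
mlp_params <- function(in_dim, hidden, out_dim) {
  list(W1 = init_mat(in_dim, hidden), b1 = matrix(0, 1L, hidden),
       W2 = init_mat(hidden, out_dim), b2 = matrix(0, 1L, out_dim))
}

mlp_fwd <- function(p, X) {
  h <- tanh(X %*% p$W1 + rep(as.numeric(p$b1), each = nrow(X)))
  h %*% p$W2 + rep(as.numeric(p$b2), each = nrow(X))
}

check_pd <- function(m, name) {
  if (!isSymmetric(unname(m), tol = 1e-8)) stop(sprintf("%s must be symmetric", name))
  ok <- tryCatch({ chol(m); TRUE }, error = function(e) FALSE)
  if (!ok) stop(sprintf("%s must be positive definite", name))
  invisible(m)
}

# ---- switching model parameters --------------------------------------------

#' Parameters of the (recurrent) switching dynamical system
#'
#' Defines the full generative model: initial state distribution `pi0`,
#' per-state latent dynamics (`dyn_A`, `dyn_b`, noise `dyn_Q`, or per-state
#' MLPs), per-state recurrent transition maps (`rec_R`, `rec_r`, or MLPs)
#' producing next-state logits from the previous latent, and a shared
#' emission (linear `C`, `d` or a one-hidden-layer MLP) with noise covariance
#' `emission_S`. With `rec_R = 0` the model reduces to a plain switching
#' linear dynamical system; MLP dynamics/recurrence give the nonlinear
#' variant. MLPs always have one hidden layer of `Dz` units.
#'
#' @param K number of discrete states
#' @param Dz,Dx continuous latent and observation dimensions
#' @param pi0 length-K initial state simplex
#' @param dyn_A,dyn_b lists of K dynamics matrices (Dz x Dz) and offsets
#'   (length Dz); ignored when `dynamics_kind = "mlp"`
#' @param dyn_Q list of K positive-definite Dz x Dz latent noise covariances
#' @param rec_R,rec_r lists of K recurrence weight matrices (K x Dz) and logit
#'   offsets (length K); ignored when `recurrence_kind = "mlp"`
#' @param emission list `(C, d)` for a linear map or MLP weights; see
#'   `emission_kind`
#' @param emission_S positive-definite Dx x Dx emission noise covariance,
#'   shared across states
#' @param dynamics_kind,recurrence_kind,emission_kind `"linear"` or `"mlp"`
#' @param dyn_mlp,rec_mlp lists of K MLP weight sets for the nonlinear variant
#' @return an `rslds_params` object
#' @export
rslds_params <- function(K, Dz, Dx, pi0, dyn_A = NULL, dyn_b = NULL, dyn_Q,
                         rec_R = NULL, rec_r = NULL, emission, emission_S,
                         dynamics_kind = c("linear", "mlp"),
                         recurrence_kind = c("linear", "mlp"),
                         emission_kind = c("linear", "mlp"),
                         dyn_mlp = NULL, rec_mlp = NULL) {
  dynamics_kind <- match.arg(dynamics_kind)
  recurrence_kind <- match.arg(recurrence_kind)
  emission_kind <- match.arg(emission_kind)
  stopifnot(K >= 1, Dz >= 1, Dx >= 1)
  if (length(pi0) != K || abs(sum(pi0) - 1) > 1e-8 || any(pi0 < 0)) {
    stop("pi0 must be a length-K simplex")
  }
  stopifnot(length(dyn_Q) == K)
  for (k in seq_len(K)) check_pd(dyn_Q[[k]], sprintf("dyn_Q[[%d]]", k))
  check_pd(emission_S, "emission_S")
  if (dynamics_kind == "linear") {
    stopifnot(length(dyn_A) == K, length(dyn_b) == K)
  } else {
    stopifnot(length(dyn_mlp) == K)
    for (m in dyn_mlp) stopifnot(ncol(m$W1) == Dz)
  }
  if (recurrence_kind == "linear") {
    stopifnot(length(rec_R) == K, length(rec_r) == K)
  } else {
    stopifnot(length(rec_mlp) == K)
    for (m in rec_mlp) stopifnot(ncol(m$W1) == Dz)
  }
  if (emission_kind == "mlp") stopifnot(ncol(emission$W1) == Dz)
  structure(list(K = as.integer(K), Dz = as.integer(Dz), Dx = as.integer(Dx),
                 pi0 = as.numeric(pi0), dyn_A = dyn_A, dyn_b = dyn_b,
                 dyn_Q = dyn_Q, rec_R = rec_R, rec_r = rec_r,
                 emission = emission, emission_S = emission_S,
                 dynamics_kind = dynamics_kind, recurrence_kind = recurrence_kind,
                 emission_kind = emission_kind, dyn_mlp = dyn_mlp,
                 rec_mlp = rec_mlp),
            class = "rslds_params")
}

# Per-state dynamics mean for a single latent vector (length Dz).
dyn_mean <- function(params, k, z) {
  if (params$dynamics_kind == "linear") {
    as.numeric(params$dyn_A[[k]] %*% z + params$dyn_b[[k]])
  } else {
    as.numeric(mlp_fwd(params$dyn_mlp[[k]], matrix(z, 1L)))
  }
}

# Emission mean for a T x Dz matrix of latents.
emission_mean <- function(params, Z) {
  Z <- as_mat(Z)
  if (params$emission_kind == "linear") {
    Z %*% t(params$emission$C) + rep(params$emission$d, each = nrow(Z))
  } else {
    mlp_fwd(params$emission, Z)
  }
}

#' Discrete-state transition distribution
#'
#' Probability over the next state given the previous state `y_prev` and the
#' previous continuous latent `z_prev`: the softmax of
#' `R[y_prev] z_prev + r[y_prev]` (or of the per-state MLP output).
#'
#' @param params an [rslds_params()]
#' @param y_prev previous state in `0..K-1`
#' @param z_prev previous latent (length Dz)
#' @return length-K probability vector
#' @export
transition_distribution <- function(params, y_prev, z_prev) {
  k <- as.integer(y_prev) + 1L
  if (k < 1L || k > params$K) stop("invalid state index")
  logits <- if (params$recurrence_kind == "linear") {
    as.numeric(params$rec_R[[k]] %*% z_prev + params$rec_r[[k]])
  } else {
    as.numeric(mlp_fwd(params$rec_mlp[[k]], matrix(z_prev, 1L)))
  }
  softmax_vec(logits)
}

#' Sampled trajectory container
#'
#' @param y length-T integer state sequence in `0..K-1`
#' @param z T x Dz latent matrix
#' @param x T x Dx observation matrix
#' @param seed the RNG seed used
#' @return a `sampled_trajectory` object
#' @export
sampled_trajectory <- function(y, z, x, seed = NA_integer_) {
  z <- as_mat(z); x <- as_mat(x)
  stopifnot(length(y) == nrow(z), nrow(z) == nrow(x), all(y >= 0L))
  structure(list(y = as.integer(y), z = z, x = x, seed = seed),
            class = "sampled_trajectory")
}

#' Ancestral sampling from the switching model
#'
#' Samples a trajectory in the generative order y1 -> z1 -> x1 -> y2 -> ...:
#' `y1 ~ Cat(pi0)`, `z1 ~ N(0, I)`, then per-state dynamics and recurrent
#' transitions. Identical seeds give identical trajectories.
#'
#' @param params an [rslds_params()]
#' @param T_len number of frames
#' @param seed integer RNG seed
#' @return a [sampled_trajectory()]
#' @export
sample_rslds <- function(params, T_len, seed = 1L) {
  stopifnot(T_len >= 1)
  K <- params$K; Dz <- params$Dz; Dx <- params$Dx
  chQ <- lapply(params$dyn_Q, chol)
  chS <- chol(params$emission_S)
  with_seed(seed, {
    y <- integer(T_len)
    z <- matrix(0, T_len, Dz)
    y[1L] <- sample.int(K, 1L, prob = params$pi0) - 1L
    z[1L, ] <- stats::rnorm(Dz)
    if (T_len > 1L) {
      for (t in 2:T_len) {
        p <- transition_distribution(params, y[t - 1L], z[t - 1L, ])
        y[t] <- sample.int(K, 1L, prob = p) - 1L
        k <- y[t] + 1L
        z[t, ] <- dyn_mean(params, k, z[t - 1L, ]) +
          as.numeric(crossprod(chQ[[k]], stats::rnorm(Dz)))
      }
    }
    eps <- matrix(stats::rnorm(T_len * Dx), T_len, Dx) %*% chS
    x <- emission_mean(params, z) + eps
    sampled_trajectory(y, z, x, seed)
  })
}

# ---- static Gaussian-mixture model ------------------------------------------

#' Parameters of the static Gaussian-mixture deep generative model
#'
#' Non-temporal ablation: `y ~ Cat(pi0)`, `z | y ~ N(cluster_mean[y],
#' diag(cluster_var[y]))`, `x | z ~ N(g(z), emission_cov)`. Conditioning z on
#' the class gives an explicit clustering mechanism even without labels.
#'
#' @param K,Dz,Dx dimensions as in [rslds_params()]
#' @param pi0 length-K class prior simplex
#' @param cluster_mean list of K mean vectors (length Dz)
#' @param cluster_var list of K strictly positive variance vectors
#' @param emission linear `(C, d)` or MLP weights
#' @param emission_cov positive-definite Dx x Dx observation noise covariance
#' @param emission_kind `"linear"` or `"mlp"`
#' @return a `gmdgm_params` object
#' @export
gmdgm_params <- function(K, Dz, Dx, pi0, cluster_mean, cluster_var, emission,
                         emission_cov, emission_kind = c("linear", "mlp")) {
  emission_kind <- match.arg(emission_kind)
  if (length(pi0) != K || abs(sum(pi0) - 1) > 1e-8 || any(pi0 < 0)) {
    stop("pi0 must be a length-K simplex")
  }
  stopifnot(length(cluster_mean) == K, length(cluster_var) == K)
  for (v in cluster_var) if (any(v <= 0)) stop("cluster variances must be positive")
  check_pd(emission_cov, "emission_cov")
  structure(list(K = as.integer(K), Dz = as.integer(Dz), Dx = as.integer(Dx),
                 pi0 = as.numeric(pi0), cluster_mean = cluster_mean,
                 cluster_var = cluster_var, emission = emission,
                 emission_cov = emission_cov, emission_kind = emission_kind),
            class = "gmdgm_params")
}

#' Sample i.i.d. draws from the static mixture model
#'
#' @param params a [gmdgm_params()]
#' @param N number of draws
#' @param seed integer RNG seed
#' @return a [sampled_trajectory()] (frames are i.i.d.; no temporal coupling)
#' @export
sample_gmdgm <- function(params, N, seed = 1L) {
  stopifnot(N >= 1)
  K <- params$K; Dz <- params$Dz; Dx <- params$Dx
  chR <- chol(params$emission_cov)
  with_seed(seed, {
    y <- sample.int(K, N, replace = TRUE, prob = params$pi0) - 1L
    mu <- do.call(rbind, params$cluster_mean)[y + 1L, , drop = FALSE]
    sd_ <- sqrt(do.call(rbind, params$cluster_var))[y + 1L, , drop = FALSE]
    z <- mu + matrix(stats::rnorm(N * Dz), N, Dz) * sd_
    gx <- if (params$emission_kind == "linear") {
      z %*% t(params$emission$C) + rep(params$emission$d, each = N)
    } else {
      mlp_fwd(params$emission, z)
    }
    x <- gx + matrix(stats::rnorm(N * Dx), N, Dx) %*% chR
    sampled_trajectory(y, z, x, seed)
  })
}

#' Log joint density of a trajectory under the switching model
#'
#' Sum of the log factors of the generative factorization evaluated at the
#' given (y, z, x).
#'
#' @param params an [rslds_params()]
#' @param traj a [sampled_trajectory()]
#' @return scalar log density
#' @export
log_joint <- function(params, traj) {
  T_len <- length(traj$y)
  stopifnot(ncol(traj$z) == params$Dz, ncol(traj$x) == params$Dx)
  lp <- log(params$pi0[traj$y[1L] + 1L]) +
    sum(stats::dnorm(traj$z[1L, ], 0, 1, log = TRUE))
  if (T_len > 1L) {
    for (t in 2:T_len) {
      k <- traj$y[t] + 1L
      p <- transition_distribution(params, traj$y[t - 1L], traj$z[t - 1L, ])
      lp <- lp + log(p[k]) +
        dmvnorm_log(traj$z[t, ], dyn_mean(params, k, traj$z[t - 1L, ]),
                    params$dyn_Q[[k]])
    }
  }
  mu_x <- emission_mean(params, traj$z)
  for (t in seq_len(T_len)) {
    lp <- lp + dmvnorm_log(traj$x[t, ], mu_x[t, ], params$emission_S)
  }
  lp
}

# ---- presets ----------------------------------------------------------------

#' Documented synthetic parameter presets
#'
#' `"two_state"`: a well-separated sticky two-state model (Dz = 2, Dx = 4)
#' with contractive dynamics toward distinct fixed points at +(1, 1) and
#' -(1, 1), latent noise 0.02 I, emission noise 0.1 I, and 0.98 self-sticking
#' transitions (mean dwell 50 frames, matching typical annotation bout
#' lengths). Ground-truth states are recoverable from the observations, which
#' is what makes the preset useful as a pipeline regression benchmark.
#'
#' @param name preset name
#' @return list with `params` (an [rslds_params()]) and `class_names`
#' @export
rslds_preset <- function(name = c("two_state")) {
  name <- match.arg(name)
  K <- 2L; Dz <- 2L; Dx <- 4L
  Cmat <- rbind(c(1, 0), c(0, 1), c(0.7, 0.7), c(0.7, -0.7))
  params <- rslds_params(
    K = K, Dz = Dz, Dx = Dx, pi0 = c(0.5, 0.5),
    dyn_A = list(0.9 * diag(Dz), 0.9 * diag(Dz)),
    dyn_b = list(c(0.1, 0.1), c(-0.1, -0.1)),
    dyn_Q = list(0.02 * diag(Dz), 0.02 * diag(Dz)),
    rec_R = list(matrix(0, K, Dz), matrix(0, K, Dz)),
    rec_r = list(log(c(0.98, 0.02)), log(c(0.02, 0.98))),
    emission = list(C = Cmat, d = rep(0, Dx)),
    emission_S = 0.1 * diag(Dx)
  )
  list(params = params, class_names = c("state_a", "state_b"))
}

#' Mask labels down to a target labeled fraction
#'
#' Keeps contiguous blocks of labels (annotators label bouts, not isolated
#' frames) until roughly `fraction` of frames remain labeled; all other
#' frames are set to the unlabeled sentinel.
#'
#' @param y full integer state sequence (0-based classes)
#' @param fraction target labeled fraction in `[0, 1]`
#' @param seed RNG seed for block placement
#' @param block_len labeled block length in frames
#' @return integer label vector with `-1` on masked frames
#' @export
mask_labels <- function(y, fraction, seed = 1L, block_len = 50L) {
  T_len <- length(y)
  if (fraction >= 1) return(as.integer(y))
  out <- rep(SEG_UNLABELED, T_len)
  target <- round(fraction * T_len)
  if (target <= 0) return(out)
  with_seed(seed, {
    n_blocks <- max(1L, ceiling(target / block_len))
    starts <- sort(sample.int(max(1L, T_len - block_len + 1L), n_blocks,
                              replace = n_blocks > T_len - block_len + 1L))
    for (s in starts) {
      idx <- s:min(T_len, s + block_len - 1L)
      out[idx] <- y[idx]
    }
  })
  out
}
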