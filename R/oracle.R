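# Exact-inference oracles for small switching models.
#
# For a frozen discrete sequence the model is a time-varying linear dynamical
# system, so the marginal likelihood of the observations is available from a
# Kalman filter. For a non-recurrent model (transition logits independent of
# z) the full marginal p(x) is the log-sum-exp over all K^T discrete
# sequences of prior + conditional Kalman likelihood. These provide
# independent ground truth for the variational-bound tests; the oracle
# deliberately excludes recurrence, where exact marginals are intractable.

#' Kalman-filter log likelihood of a linear-Gaussian state-space model
#'
#' Computes `log p(x_1..T)` exactly by the forward predict/update recursion on
#' Gaussian moments. The initial latent prior is `z1 ~ N(0, I)`. Dynamics may
#' be time varying: `A`, `b`, `Q` may each be a single value or a list of
#' length `T - 1` (entry t-1 governs the transition into frame t).
#'
#' @param x T x Dx observation matrix
#' @param A Dz x Dz dynamics matrix or list of them
#' @param b length-Dz offset or list
#' @param Q Dz x Dz PD covariance or list
#' @param C Dx x Dz emission matrix
#' @param d length-Dx emission offset
#' @param S Dx x Dx PD emission covariance
#' @return scalar log likelihood
#' @export
kalman_loglik <- function(x, A, b, Q, C, d, S) {
  x <- as_mat(x)
  T_len <- nrow(x)
  Dz <- ncol(C)
  get_t <- function(obj, t) if (is.list(obj)) obj[[t]] else obj
  m <- rep(0, Dz)
  P <- diag(Dz)
  ll <- 0
  for (t in seq_len(T_len)) {
    if (t > 1L) {
      At <- get_t(A, t - 1L); bt <- get_t(b, t - 1L); Qt <- get_t(Q, t - 1L)
      m <- as.numeric(At %*% m + bt)
      P <- At %*% P %*% t(At) + Qt
    }
    mean_x <- as.numeric(C %*% m + d)
    Sx <- C %*% P %*% t(C) + S
    Sx <- (Sx + t(Sx)) / 2
    ch <- tryCatch(chol(Sx), error = function(e) stop("non-PD innovation covariance"))
    ll <- ll + dmvnorm_log(x[t, ], mean_x, Sx)
    K_gain <- P %*% t(C) %*% chol2inv(ch)
    m <- m + as.numeric(K_gain %*% (x[t, ] - mean_x))
    P <- P - K_gain %*% C %*% P
    P <- (P + t(P)) / 2
  }
  ll
}

#' Exact log marginal likelihood by discrete-state enumeration
#'
#' Valid only for non-recurrent switching models with linear emission: the
#' transition logits must not depend on z (`rec_R = 0`), so the prior over a
#' discrete sequence factorizes, and each conditional likelihood is a Kalman
#' filter run. Enforces `K^T <= 1e6`.
#'
#' @param params an [rslds_params()] with `rec_R = 0` and linear emission
#' @param x T x Dx observation matrix
#' @return list with `log_marginal`, `log_weights` (one per sequence),
#'   `sequences` (K^T x T matrix of 0-based states), and `best` (the MAP
#'   sequence)
#' @export
exact_log_marginal <- function(params, x) {
  x <- as_mat(x)
  T_len <- nrow(x)
  K <- params$K
  if (params$emission_kind != "linear" || params$dynamics_kind != "linear" ||
      params$recurrence_kind != "linear") {
    stop("oracle requires linear dynamics, recurrence and emission")
  }
  if (any(vapply(params$rec_R, function(R) max(abs(R)), 1) > 0)) {
    stop("oracle invalid for recurrent transitions (rec_R must be 0)")
  }
  if (K^T_len > 1e6) stop("enumeration budget exceeded (K^T > 1e6)")
  trans_logp <- lapply(params$rec_r, function(r) log(softmax_vec(r)))
  seqs <- as.matrix(expand.grid(rep(list(0:(K - 1L)), T_len)))
  dimnames(seqs) <- NULL
  lw <- vapply(seq_len(nrow(seqs)), function(i) {
    ys <- seqs[i, ]
    lp <- log(params$pi0[ys[1L] + 1L])
    if (T_len > 1L) {
      for (t in 2:T_len) lp <- lp + trans_logp[[ys[t - 1L] + 1L]][ys[t] + 1L]
    }
    Alist <- lapply(seq_len(max(T_len - 1L, 0L)), function(t) params$dyn_A[[ys[t + 1L] + 1L]])
    blist <- lapply(seq_len(max(T_len - 1L, 0L)), function(t) params$dyn_b[[ys[t + 1L] + 1L]])
    Qlist <- lapply(seq_len(max(T_len - 1L, 0L)), function(t) params$dyn_Q[[ys[t + 1L] + 1L]])
    lp + kalman_loglik(x, Alist, blist, Qlist, params$emission$C,
                       params$emission$d, params$emission_S)
  }, 1)
  lm <- logsumexp(lw)
  list(log_marginal = lm, log_weights = lw, sequences = seqs,
       best = seqs[which.max(lw), ])
}
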