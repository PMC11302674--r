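# Variational objectives.
#
# The semi-supervised bound substitutes, at every labeled frame, a one-hot
# vector for the classifier posterior inside the unlabeled bound; each term
# of the unlabeled bound reduces to its labeled counterpart under one-hot
# weights, so a single graph covers fully labeled, fully unlabeled and mixed
# sequences. An alpha-weighted, class-weighted cross entropy over the labeled
# frames trains the classifier itself, which otherwise only appears in the
# unlabeled terms. All Gaussian factors are diagonal, so every KL divergence
# is analytic; the expectations over z use one reparameterized sample per
# (frame, class).

#' Analytic KL divergence between diagonal Gaussians
#'
#' `sum_i 0.5 * (log(var_p/var_q) + (var_q + (mu_q - mu_p)^2)/var_p - 1)`.
#'
#' @param mu_q,var_q,mu_p,var_p equal-length mean and variance vectors
#' @return non-negative scalar
#' @export
gaussian_kl_diag <- function(mu_q, var_q, mu_p, var_p) {
  if (any(var_q <= 0) || any(var_p <= 0)) stop("variances must be positive")
  sum(0.5 * (log(var_p / var_q) + (var_q + (mu_q - mu_p)^2) / var_p - 1))
}

#' KL divergence between categorical distributions
#'
#' `sum_k q_k log(q_k / p_k)` with the `0 * log 0 = 0` convention; returns
#' `Inf` where q puts mass outside p's support.
#'
#' @param q,p length-K probability vectors
#' @return non-negative scalar (possibly `Inf`)
#' @export
categorical_kl <- function(q, p) {
  if (abs(sum(q) - 1) > 1e-6 || abs(sum(p) - 1) > 1e-6 || any(q < 0) || any(p < 0)) {
    stop("q and p must be simplices")
  }
  pos <- q > 0
  if (any(pos & p == 0)) return(Inf)
  sum(q[pos] * log(q[pos] / p[pos]))
}

#' Loss configuration
#'
#' @param alpha weight on the supervised classification loss (the published
#'   setting is 100 across datasets)
#' @param anneal_epochs epochs over which the KL and discrete-state terms are
#'   linearly annealed from 0 to 1
#' @param class_weights length-K positive vector; defaults to uniform.
#'   Training derives inverse-frequency weights via [class_weights()].
#' @return a `loss_config` object
#' @export
loss_config <- function(alpha = 100, anneal_epochs = 100L, class_weights = NULL) {
  stopifnot(alpha >= 0, anneal_epochs >= 1)
  structure(list(alpha = alpha, anneal_epochs = as.integer(anneal_epochs),
                 class_weights = class_weights),
            class = "loss_config")
}

#' Itemized objective terms
#'
#' All KL components are reported as non-negative quantities; the total is
#' `recon - anneal_w * (kl_z_init + kl_z_dyn + kl_y) + classification`, which
#' at `anneal_w = 1` is the semi-supervised bound plus the weighted
#' classification term. `log_py1` (the initial-state log prior under the
#' substituted weights) is reported for logging; it is contained in `kl_y`.
#'
#' @param recon,kl_z_init,kl_z_dyn,kl_y,log_py1,classification,total scalars
#' @param anneal_w annealing weight used for the KL/discrete terms
#' @return an `objective_terms` object
#' @export
objective_terms <- function(recon, kl_z_init, kl_z_dyn, kl_y, log_py1,
                            classification, anneal_w, total) {
  structure(list(recon = recon, kl_z_init = kl_z_init, kl_z_dyn = kl_z_dyn,
                 kl_y = kl_y, log_py1 = log_py1, classification = classification,
                 anneal_w = anneal_w, total = total),
            class = "objective_terms")
}

#' @export
print.objective_terms <- function(x, ...) {
  cat(sprintf(paste0("<objective_terms: total=%.4f  recon=%.4f  kl_z_init=%.4f",
                     "  kl_z_dyn=%.4f  kl_y=%.4f  class=%.4f  anneal=%.2f>\n"),
              x$total, x$recon, x$kl_z_init, x$kl_z_dyn, x$kl_y,
              x$classification, x$anneal_w))
  invisible(x)
}

# ---- trainable parameterization of the generative models -------------------

diag_of <- function(m, name) {
  if (!is.matrix(m)) m <- diag(m, 1L)
  if (!is_diag_matrix(m)) {
    stop(sprintf("%s must be diagonal for the analytic objective", name))
  }
  diag(m)
}

# Flatten rslds parameters into named matrices with unconstrained
# parameterization (log-variances, logit prior); transposed maps so latents
# right-multiply.
gen_to_flat <- function(params) {
  fl <- list(pi = matrix(log(params$pi0), 1L))
  K <- params$K
  for (k in seq_len(K)) {
    if (params$dynamics_kind == "linear") {
      fl[[paste0("At", k)]] <- t(params$dyn_A[[k]])
      fl[[paste0("bd", k)]] <- matrix(params$dyn_b[[k]], 1L)
    } else {
      m <- params$dyn_mlp[[k]]
      fl[[paste0("dynW1_", k)]] <- m$W1; fl[[paste0("dynb1_", k)]] <- m$b1
      fl[[paste0("dynW2_", k)]] <- m$W2; fl[[paste0("dynb2_", k)]] <- m$b2
    }
    fl[[paste0("logQ", k)]] <- matrix(log(diag_of(params$dyn_Q[[k]], "dyn_Q")), 1L)
    if (params$recurrence_kind == "linear") {
      fl[[paste0("Rt", k)]] <- t(params$rec_R[[k]])
      fl[[paste0("rr", k)]] <- matrix(params$rec_r[[k]], 1L)
    } else {
      m <- params$rec_mlp[[k]]
      fl[[paste0("recW1_", k)]] <- m$W1; fl[[paste0("recb1_", k)]] <- m$b1
      fl[[paste0("recW2_", k)]] <- m$W2; fl[[paste0("recb2_", k)]] <- m$b2
    }
  }
  if (params$emission_kind == "linear") {
    fl$Ct <- t(params$emission$C)
    fl$ed <- matrix(params$emission$d, 1L)
  } else {
    fl$emW1 <- params$emission$W1; fl$emb1 <- params$emission$b1
    fl$emW2 <- params$emission$W2; fl$emb2 <- params$emission$b2
  }
  fl$logS <- matrix(log(diag_of(params$emission_S, "emission_S")), 1L)
  fl
}

# Rebuild numeric rslds_params from the flat representation.
flat_to_gen <- function(fl, template) {
  K <- template$K
  pi0 <- softmax_vec(as.numeric(fl$pi))
  dyn_A <- dyn_b <- dyn_mlp <- rec_R <- rec_r <- rec_mlp <- vector("list", K)
  dyn_Q <- vector("list", K)
  for (k in seq_len(K)) {
    if (template$dynamics_kind == "linear") {
      dyn_A[[k]] <- t(fl[[paste0("At", k)]])
      dyn_b[[k]] <- as.numeric(fl[[paste0("bd", k)]])
    } else {
      dyn_mlp[[k]] <- list(W1 = fl[[paste0("dynW1_", k)]], b1 = fl[[paste0("dynb1_", k)]],
                           W2 = fl[[paste0("dynW2_", k)]], b2 = fl[[paste0("dynb2_", k)]])
    }
    dyn_Q[[k]] <- diag(exp(as.numeric(fl[[paste0("logQ", k)]])), template$Dz)
    if (template$recurrence_kind == "linear") {
      rec_R[[k]] <- t(fl[[paste0("Rt", k)]])
      rec_r[[k]] <- as.numeric(fl[[paste0("rr", k)]])
    } else {
      rec_mlp[[k]] <- list(W1 = fl[[paste0("recW1_", k)]], b1 = fl[[paste0("recb1_", k)]],
                           W2 = fl[[paste0("recW2_", k)]], b2 = fl[[paste0("recb2_", k)]])
    }
  }
  emission <- if (template$emission_kind == "linear") {
    list(C = t(fl$Ct), d = as.numeric(fl$ed))
  } else {
    list(W1 = fl$emW1, b1 = fl$emb1, W2 = fl$emW2, b2 = fl$emb2)
  }
  rslds_params(K, template$Dz, template$Dx, pi0,
               dyn_A = if (template$dynamics_kind == "linear") dyn_A,
               dyn_b = if (template$dynamics_kind == "linear") dyn_b,
               dyn_Q = dyn_Q,
               rec_R = if (template$recurrence_kind == "linear") rec_R,
               rec_r = if (template$recurrence_kind == "linear") rec_r,
               emission = emission,
               emission_S = diag(exp(as.numeric(fl$logS)), template$Dx),
               dynamics_kind = template$dynamics_kind,
               recurrence_kind = template$recurrence_kind,
               emission_kind = template$emission_kind,
               dyn_mlp = if (template$dynamics_kind == "mlp") dyn_mlp,
               rec_mlp = if (template$recurrence_kind == "mlp") rec_mlp)
}

# ---- graph pieces -----------------------------------------------------------

mlp_graph <- function(tape, W1, b1, W2, b2, z) {
  h <- ad_tanh(tape, ad_addvec(tape, ad_matmul(tape, z, W1), b1))
  ad_addvec(tape, ad_matmul(tape, h, W2), b2)
}

emission_graph <- function(tape, genn, kind, z) {
  if (kind == "linear") {
    ad_addvec(tape, ad_matmul(tape, z, genn$Ct), genn$ed)
  } else {
    mlp_graph(tape, genn$emW1, genn$emb1, genn$emW2, genn$emb2, z)
  }
}

dynamics_graph <- function(tape, genn, kind, k, zprev) {
  if (kind == "linear") {
    ad_addvec(tape, ad_matmul(tape, zprev, genn[[paste0("At", k)]]),
              genn[[paste0("bd", k)]])
  } else {
    mlp_graph(tape, genn[[paste0("dynW1_", k)]], genn[[paste0("dynb1_", k)]],
              genn[[paste0("dynW2_", k)]], genn[[paste0("dynb2_", k)]], zprev)
  }
}

recurrence_graph <- function(tape, genn, kind, k, zprev) {
  if (kind == "linear") {
    ad_addvec(tape, ad_matmul(tape, zprev, genn[[paste0("Rt", k)]]),
              genn[[paste0("rr", k)]])
  } else {
    mlp_graph(tape, genn[[paste0("recW1_", k)]], genn[[paste0("recb1_", k)]],
              genn[[paste0("recW2_", k)]], genn[[paste0("recb2_", k)]], zprev)
  }
}

# Broadcast a 1x1 node to an n x 1 column.
bc_col <- function(tape, s, n) ad_matmul(tape, ad_const(tape, matrix(1, n, 1L)), s)

# Row log-likelihood of x rows under N(mean_rows, diag(exp(logv))) where
# logv is a 1 x D node.
gauss_rowll <- function(tape, x, mean_node, logv) {
  D <- ncol(x$value)
  diff <- ad_sub(tape, x, mean_node)
  sq <- ad_mul(tape, diff, diff)
  inv <- ad_exp(tape, ad_neg(tape, logv))
  rs <- ad_rowsums(tape, ad_mulvec(tape, sq, inv))
  slog <- bc_col(tape, ad_sum(tape, logv), nrow(x$value))
  ad_shift(tape, ad_scale(tape, ad_add(tape, rs, slog), -0.5),
           -0.5 * D * log(2 * pi))
}

# Row KL of N(mu, exp(lv)) (nodes, rows) from N(mean_node, diag(exp(logv)))
# with logv a 1 x D node. A 1-row prior mean broadcasts over the rows of mu.
gauss_rowkl <- function(tape, mu, lv, mean_node, logv) {
  diff <- if (nrow(mean_node$value) == 1L && nrow(mu$value) > 1L) {
    ad_addvec(tape, mu, ad_neg(tape, mean_node))
  } else {
    ad_sub(tape, mu, mean_node)
  }
  num <- ad_add(tape, ad_exp(tape, lv), ad_mul(tape, diff, diff))
  inv <- ad_exp(tape, ad_neg(tape, logv))
  a2 <- ad_mulvec(tape, num, inv)
  a1 <- ad_addvec(tape, ad_neg(tape, lv), logv)
  ad_scale(tape, ad_rowsums(tape, ad_shift(tape, ad_add(tape, a1, a2), -1)), 0.5)
}

zero_node <- function(tape) ad_const(tape, matrix(0, 1L, 1L))

# ---- the semi-supervised objective graph ------------------------------------

#' Build the semi-supervised objective graph
#'
#' Core graph shared by every objective entry point and by training. `q` is
#' the classifier posterior (node); at labeled frames the substituted weights
#' r are one-hot, elsewhere they equal q. `negent` is the per-frame
#' sum of `r log r` (zero at labeled frames). One reparameterized sample per
#' (frame, class) is formed from `eps`.
#'
#' @param tape an [ad_tape()]
#' @param genn named list of generative parameter nodes (flat layout)
#' @param kinds list with `dynamics_kind`, `recurrence_kind`, `emission_kind`,
#'   `K`, `Dz`, `Dx`
#' @param q T x K classifier-probability node
#' @param negent T x 1 node of `sum_k r log r` per frame
#' @param mus,lvs lists of K encoder mean / log-variance nodes (T x Dz)
#' @param x T x Dx constant observation node
#' @param labels integer label vector (sentinels allowed) or NULL for fully
#'   unlabeled
#' @param eps T x K x Dz noise array
#' @param anneal_w annealing weight on the KL / discrete-state terms
#' @param cls_node optional precomputed classification-term node; when NULL it
#'   is built as `alpha * sum_(labeled) w_y log q(y)` from `logq`
#' @param logq T x K log-probability node (needed when `cls_node` is NULL)
#' @param alpha,class_weights classification loss weighting
#' @return list of scalar nodes: recon, kl_z_init, kl_z_dyn, kl_y, log_py1,
#'   classification, total
#' @export
ss_objective_graph <- function(tape, genn, kinds, q, negent, mus, lvs, x,
                               labels, eps, anneal_w = 1, cls_node = NULL,
                               logq = NULL, alpha = 0, class_weights = NULL) {
  K <- kinds$K; Dz <- kinds$Dz
  T_len <- nrow(x$value)
  if (is.null(labels)) labels <- rep(SEG_UNLABELED, T_len)
  lab <- labels >= 0L
  U <- matrix(as.numeric(!lab), T_len, K)
  M <- matrix(0, T_len, K)
  if (any(lab)) M[cbind(which(lab), labels[lab] + 1L)] <- 1
  r <- ad_add(tape, ad_cmul(tape, q, U), ad_const(tape, M))
  rcols <- lapply(seq_len(K), function(k) ad_cols(tape, r, k))

  # reparameterized samples per class
  ztil <- lapply(seq_len(K), function(k) {
    sig <- ad_exp(tape, ad_scale(tape, lvs[[k]], 0.5))
    ad_add(tape, mus[[k]], ad_mul(tape, sig, ad_const(tape, slice3(eps, k))))
  })

  # reconstruction
  recon <- NULL
  for (k in seq_len(K)) {
    gk <- emission_graph(tape, genn, kinds$emission_kind, ztil[[k]])
    rowll <- gauss_rowll(tape, x, gk, genn$logS)
    term <- ad_sum(tape, ad_mul(tape, rcols[[k]], rowll))
    recon <- if (is.null(recon)) term else ad_add(tape, recon, term)
  }

  # KL of q(z_1 | ., k) from the standard-normal initial prior
  kl_z_init <- NULL
  zero_lv <- ad_const(tape, matrix(0, 1L, Dz))
  zero_mu <- ad_const(tape, matrix(0, 1L, Dz))
  for (k in seq_len(K)) {
    mu1 <- ad_rows(tape, mus[[k]], 1L)
    lv1 <- ad_rows(tape, lvs[[k]], 1L)
    kl1 <- gauss_rowkl(tape, mu1, lv1, zero_mu, zero_lv)
    term <- ad_sum(tape, ad_mul(tape, ad_rows(tape, rcols[[k]], 1L), kl1))
    kl_z_init <- if (is.null(kl_z_init)) term else ad_add(tape, kl_z_init, term)
  }

  # categorical terms at t = 1: KL(r_1 || pi)
  logpi <- ad_sub(tape, genn$pi,
                  ad_matmul(tape, ad_logsumexp_rows(tape, genn$pi),
                            ad_const(tape, matrix(1, 1L, K))))
  cross1 <- ad_sum(tape, ad_mul(tape, ad_rows(tape, r, 1L), logpi))
  kl_y <- ad_sub(tape, ad_rows(tape, negent, 1L), cross1)

  kl_z_dyn <- zero_node(tape)
  if (T_len > 1L) {
    prev_idx <- seq_len(T_len - 1L)
    cur_idx <- 2:T_len
    onesK <- ad_const(tape, matrix(1, 1L, K))
    rcur <- ad_rows(tape, r, cur_idx)
    negent_cur <- ad_rows(tape, negent, cur_idx)
    for (kp in seq_len(K)) {
      zprev <- ad_rows(tape, ztil[[kp]], prev_idx)
      rprev_kp <- ad_rows(tape, rcols[[kp]], prev_idx)
      # dynamics KL, weighted by r_t(k) r_(t-1)(k')
      for (k in seq_len(K)) {
        m <- dynamics_graph(tape, genn, kinds$dynamics_kind, k, zprev)
        kl <- gauss_rowkl(tape, ad_rows(tape, mus[[k]], cur_idx),
                          ad_rows(tape, lvs[[k]], cur_idx), m,
                          genn[[paste0("logQ", k)]])
        w <- ad_mul(tape, ad_rows(tape, rcols[[k]], cur_idx), rprev_kp)
        kl_z_dyn <- ad_add(tape, kl_z_dyn, ad_sum(tape, ad_mul(tape, w, kl)))
      }
      # transition KL: KL(r_t || p(y_t | y_(t-1)=k', ztil))
      tl <- recurrence_graph(tape, genn, kinds$recurrence_kind, kp, zprev)
      logp <- ad_sub(tape, tl, ad_matmul(tape, ad_logsumexp_rows(tape, tl), onesK))
      crossrow <- ad_rowsums(tape, ad_mul(tape, rcur, logp))
      klrow <- ad_sub(tape, negent_cur, crossrow)
      kl_y <- ad_add(tape, kl_y, ad_sum(tape, ad_mul(tape, rprev_kp, klrow)))
    }
  }

  if (is.null(cls_node)) {
    if (alpha > 0 && any(lab)) {
      if (is.null(class_weights)) class_weights <- rep(1, K)
      CW <- matrix(0, T_len, K)
      CW[cbind(which(lab), labels[lab] + 1L)] <- alpha * class_weights[labels[lab] + 1L]
      cls_node <- ad_sum(tape, ad_cmul(tape, logq, CW))
    } else {
      cls_node <- zero_node(tape)
    }
  }

  klsum <- ad_add(tape, ad_add(tape, kl_z_init, kl_z_dyn), kl_y)
  total <- ad_add(tape, ad_add(tape, recon, ad_scale(tape, klsum, -anneal_w)),
                  cls_node)
  list(recon = recon, kl_z_init = kl_z_init, kl_z_dyn = kl_z_dyn, kl_y = kl_y,
       log_py1 = cross1, classification = cls_node, total = total)
}

# Numeric preparation shared by the objective entry points: constant nodes
# for the posterior factors and observations.
ss_objective_numeric <- function(params, post, fs, labels, alpha = 0,
                                 class_weights = NULL, anneal_w = 1, seed = 1L) {
  stopifnot(inherits(post, "posterior_factors"))
  x <- if (inherits(fs, "feature_sequence")) fs$values else as.matrix(fs)
  T_len <- nrow(x)
  K <- ncol(post$class_probs)
  Dz <- dim(post$z_mean)[3L]
  stopifnot(nrow(post$class_probs) == T_len, params$K == K, params$Dz == Dz,
            params$Dx == ncol(x))
  if (!is.null(labels)) stopifnot(length(labels) == T_len)
  tape <- ad_tape()
  genn <- lapply(gen_to_flat(params), function(v) ad_const(tape, v))
  kinds <- list(dynamics_kind = params$dynamics_kind,
                recurrence_kind = params$recurrence_kind,
                emission_kind = params$emission_kind,
                K = K, Dz = Dz, Dx = params$Dx)
  p <- post$class_probs
  lab <- if (is.null(labels)) rep(FALSE, T_len) else labels >= 0L
  plogp <- ifelse(p > 0, p * log(p), 0)
  negent_v <- ifelse(lab, 0, rowSums(plogp))
  q <- ad_const(tape, p)
  negent <- ad_const(tape, matrix(negent_v, ncol = 1L))
  mus <- lapply(seq_len(K), function(k) ad_const(tape, slice3(post$z_mean, k)))
  lvs <- lapply(seq_len(K), function(k) ad_const(tape, slice3(post$z_logvar, k)))
  eps <- draw_eps(T_len, K, Dz, seed)
  cls_val <- 0
  if (alpha > 0 && any(lab)) {
    if (is.null(class_weights)) class_weights <- rep(1, K)
    yl <- labels[lab] + 1L
    cls_val <- alpha * sum(class_weights[yl] * log(p[cbind(which(lab), yl)]))
  }
  g <- ss_objective_graph(tape, genn, kinds, q, negent, mus, lvs,
                          ad_const(tape, x), labels, eps, anneal_w,
                          cls_node = ad_const(tape, matrix(cls_val, 1L, 1L)))
  objective_terms(
    recon = as.numeric(g$recon$value), kl_z_init = as.numeric(g$kl_z_init$value),
    kl_z_dyn = as.numeric(g$kl_z_dyn$value), kl_y = as.numeric(g$kl_y$value),
    log_py1 = as.numeric(g$log_py1$value),
    classification = as.numeric(g$classification$value),
    anneal_w = anneal_w, total = as.numeric(g$total$value)
  )
}

#' Labeled-frames evidence lower bound
#'
#' Direct implementation of the fully observed bound: reconstruction with one
#' reparameterized sample per frame, analytic KL of `q(z_1)` from the
#' standard-normal initial prior and of `q(z_t)` from the state-conditional
#' dynamics prior evaluated at the previous sample, plus the initial-state
#' and transition log probabilities. Every frame must carry a label. The
#' noise draw at frame t uses the class slice `y_t` of the shared
#' (frame, class) noise array, so the unlabeled machinery with one-hot
#' weights reproduces this bound term by term.
#'
#' @param params an [rslds_params()] with diagonal covariances
#' @param post a [posterior_factors()]
#' @param fs a [feature_sequence()] or T x Dx matrix
#' @param labels a [label_sequence()] or integer vector, all in `0..K-1`
#' @param seed seed for the reparameterization noise
#' @param anneal_w annealing weight applied to the KL/discrete terms
#' @return an [objective_terms()]
#' @export
labeled_elbo <- function(params, post, fs, labels, seed = 1L, anneal_w = 1) {
  y <- if (inherits(labels, "label_sequence")) labels$labels else as.integer(labels)
  if (any(y < 0L)) stop("labeled_elbo requires every frame to be labeled")
  x <- if (inherits(fs, "feature_sequence")) fs$values else as.matrix(fs)
  T_len <- nrow(x)
  K <- params$K; Dz <- params$Dz
  stopifnot(length(y) == T_len)
  eps <- draw_eps(T_len, K, Dz, seed)
  sdQ <- lapply(seq_len(K), function(k) diag_of(params$dyn_Q[[k]], "dyn_Q"))
  sdiag <- diag_of(params$emission_S, "emission_S")
  slice_y <- function(arr) {
    matrix(vapply(seq_len(Dz),
                  function(j) arr[cbind(seq_len(T_len), y + 1L, j)],
                  numeric(T_len)),
           T_len, Dz)
  }
  mu_y <- slice_y(post$z_mean)
  lv_y <- slice_y(post$z_logvar)
  eps_y <- slice_y(eps)
  ztil <- mu_y + exp(0.5 * lv_y) * eps_y
  gx <- emission_mean(params, ztil)
  recon <- sum(-0.5 * log(2 * pi * rep(sdiag, each = T_len)) -
                 0.5 * (x - gx)^2 / rep(sdiag, each = T_len))
  kl1 <- gaussian_kl_diag(mu_y[1L, ], exp(lv_y[1L, ]), rep(0, Dz), rep(1, Dz))
  log_py1 <- log(params$pi0[y[1L] + 1L])
  kldyn <- 0; trans <- 0
  if (T_len > 1L) {
    for (t in 2:T_len) {
      k <- y[t] + 1L
      m <- dyn_mean(params, k, ztil[t - 1L, ])
      kldyn <- kldyn + gaussian_kl_diag(mu_y[t, ], exp(lv_y[t, ]), m, sdQ[[k]])
      p <- transition_distribution(params, y[t - 1L], ztil[t - 1L, ])
      trans <- trans + log(p[k])
    }
  }
  kl_y <- -(log_py1 + trans)
  total <- recon - anneal_w * (kl1 + kldyn + kl_y)
  objective_terms(recon, kl1, kldyn, kl_y, log_py1, 0, anneal_w, total)
}

#' Unlabeled-frames evidence lower bound
#'
#' The bound with every frame unobserved: class-weighted reconstruction and
#' initial-latent KL, a categorical KL of the classifier posterior from the
#' state prior, the double class sum over dynamics KLs, and the expected
#' transition KL evaluated at the previous frame's per-class samples.
#'
#' @inheritParams labeled_elbo
#' @return an [objective_terms()]
#' @export
unlabeled_elbo <- function(params, post, fs, seed = 1L, anneal_w = 1) {
  ss_objective_numeric(params, post, fs, labels = NULL, alpha = 0,
                       anneal_w = anneal_w, seed = seed)
}

#' Mixed semi-supervised loss
#'
#' Substitutes a one-hot vector for the classifier posterior at every labeled
#' frame, evaluates the unlabeled bound with those weights, and adds the
#' alpha-weighted, class-weighted log probability of the observed labels.
#' Background frames count as unlabeled everywhere.
#'
#' @inheritParams labeled_elbo
#' @param labels a [label_sequence()] (sentinels allowed)
#' @param cfg a [loss_config()]
#' @return an [objective_terms()]
#' @export
semisupervised_loss <- function(params, post, fs, labels, cfg = loss_config(),
                                anneal_w = 1, seed = 1L) {
  y <- if (inherits(labels, "label_sequence")) labels$labels else as.integer(labels)
  cw <- cfg$class_weights %||% rep(1, params$K)
  ss_objective_numeric(params, post, fs, labels = y, alpha = cfg$alpha,
                       class_weights = cw, anneal_w = anneal_w, seed = seed)
}

# ---- static mixture objective ----------------------------------------------

gmdgm_to_flat <- function(params) {
  fl <- list(pi = matrix(log(params$pi0), 1L))
  for (k in seq_len(params$K)) {
    fl[[paste0("cmu", k)]] <- matrix(params$cluster_mean[[k]], 1L)
    fl[[paste0("clv", k)]] <- matrix(log(params$cluster_var[[k]]), 1L)
  }
  if (params$emission_kind == "linear") {
    fl$Ct <- t(params$emission$C); fl$ed <- matrix(params$emission$d, 1L)
  } else {
    fl$emW1 <- params$emission$W1; fl$emb1 <- params$emission$b1
    fl$emW2 <- params$emission$W2; fl$emb2 <- params$emission$b2
  }
  fl$logS <- matrix(log(diag_of(params$emission_cov, "emission_cov")), 1L)
  fl
}

flat_to_gmdgm <- function(fl, template) {
  K <- template$K
  emission <- if (template$emission_kind == "linear") {
    list(C = t(fl$Ct), d = as.numeric(fl$ed))
  } else {
    list(W1 = fl$emW1, b1 = fl$emb1, W2 = fl$emW2, b2 = fl$emb2)
  }
  gmdgm_params(K, template$Dz, template$Dx, softmax_vec(as.numeric(fl$pi)),
               cluster_mean = lapply(seq_len(K), function(k) as.numeric(fl[[paste0("cmu", k)]])),
               cluster_var = lapply(seq_len(K), function(k) exp(as.numeric(fl[[paste0("clv", k)]]))),
               emission = emission,
               emission_cov = diag(exp(as.numeric(fl$logS)), template$Dx),
               emission_kind = template$emission_kind)
}

#' Build the static-mixture objective graph
#'
#' Per-frame version of the semi-supervised bound for the static model:
#' labeled frames contribute the labeled bound plus the classification term;
#' unlabeled frames contribute the class-weighted labeled bound plus the
#' entropy of the classifier posterior (the entropy enters with a positive
#' sign, as the algebra of the marginalized bound requires).
#'
#' @inheritParams ss_objective_graph
#' @return list of scalar nodes as in [ss_objective_graph()] (`kl_z_dyn` is 0)
#' @export
gmdgm_objective_graph <- function(tape, genn, kinds, q, negent, mus, lvs, x,
                                  labels, eps, anneal_w = 1, cls_node = NULL,
                                  logq = NULL, alpha = 0, class_weights = NULL) {
  K <- kinds$K
  T_len <- nrow(x$value)
  if (is.null(labels)) labels <- rep(SEG_UNLABELED, T_len)
  lab <- labels >= 0L
  U <- matrix(as.numeric(!lab), T_len, K)
  M <- matrix(0, T_len, K)
  if (any(lab)) M[cbind(which(lab), labels[lab] + 1L)] <- 1
  r <- ad_add(tape, ad_cmul(tape, q, U), ad_const(tape, M))

  recon <- NULL; kl_z <- NULL
  for (k in seq_len(K)) {
    sig <- ad_exp(tape, ad_scale(tape, lvs[[k]], 0.5))
    ztil <- ad_add(tape, mus[[k]], ad_mul(tape, sig, ad_const(tape, slice3(eps, k))))
    gk <- emission_graph(tape, genn, kinds$emission_kind, ztil)
    rowll <- gauss_rowll(tape, x, gk, genn$logS)
    klrow <- gauss_rowkl(tape, mus[[k]], lvs[[k]], genn[[paste0("cmu", k)]],
                         genn[[paste0("clv", k)]])
    rk <- ad_cols(tape, r, k)
    tr <- ad_sum(tape, ad_mul(tape, rk, rowll))
    tk <- ad_sum(tape, ad_mul(tape, rk, klrow))
    recon <- if (is.null(recon)) tr else ad_add(tape, recon, tr)
    kl_z <- if (is.null(kl_z)) tk else ad_add(tape, kl_z, tk)
  }
  logpi <- ad_sub(tape, genn$pi,
                  ad_matmul(tape, ad_logsumexp_rows(tape, genn$pi),
                            ad_const(tape, matrix(1, 1L, K))))
  log_py <- ad_sum(tape, ad_mulvec(tape, r, logpi))
  kl_y <- ad_sub(tape, ad_sum(tape, negent), log_py)

  if (is.null(cls_node)) {
    if (alpha > 0 && any(lab)) {
      if (is.null(class_weights)) class_weights <- rep(1, K)
      CW <- matrix(0, T_len, K)
      CW[cbind(which(lab), labels[lab] + 1L)] <- alpha * class_weights[labels[lab] + 1L]
      cls_node <- ad_sum(tape, ad_cmul(tape, logq, CW))
    } else {
      cls_node <- zero_node(tape)
    }
  }
  klsum <- ad_add(tape, kl_z, kl_y)
  total <- ad_add(tape, ad_add(tape, recon, ad_scale(tape, klsum, -anneal_w)),
                  cls_node)
  list(recon = recon, kl_z_init = kl_z, kl_z_dyn = zero_node(tape), kl_y = kl_y,
       log_py1 = log_py, classification = cls_node, total = total)
}

#' Static-mixture semi-supervised bound
#'
#' Numeric entry point for the static model: evaluates the labeled bound plus
#' alpha-weighted classification on labeled frames and the marginalized bound
#' (class-weighted labeled bound plus posterior entropy) on unlabeled frames,
#' summed over the batch.
#'
#' @param params a [gmdgm_params()] with diagonal emission covariance
#' @param post a [posterior_factors()] (static: row t from frame t only)
#' @param x N x Dx observation matrix or [feature_sequence()]
#' @param labels integer labels with sentinels, or NULL for fully unlabeled
#' @param alpha classification loss weight
#' @param class_weights optional per-class weights
#' @param anneal_w annealing weight on the KL and prior terms
#' @param seed reparameterization seed
#' @return an [objective_terms()]
#' @export
gmdgm_elbo <- function(params, post, x, labels = NULL, alpha = 0,
                       class_weights = NULL, anneal_w = 1, seed = 1L) {
  stopifnot(inherits(post, "posterior_factors"))
  if (inherits(x, "feature_sequence")) x <- x$values
  x <- as.matrix(x)
  if (inherits(labels, "label_sequence")) labels <- labels$labels
  T_len <- nrow(x)
  K <- ncol(post$class_probs); Dz <- dim(post$z_mean)[3L]
  stopifnot(params$K == K, params$Dz == Dz, params$Dx == ncol(x))
  tape <- ad_tape()
  genn <- lapply(gmdgm_to_flat(params), function(v) ad_const(tape, v))
  kinds <- list(emission_kind = params$emission_kind, K = K, Dz = Dz, Dx = params$Dx)
  p <- post$class_probs
  lab <- if (is.null(labels)) rep(FALSE, T_len) else labels >= 0L
  plogp <- ifelse(p > 0, p * log(p), 0)
  negent <- ad_const(tape, matrix(ifelse(lab, 0, rowSums(plogp)), ncol = 1L))
  mus <- lapply(seq_len(K), function(k) ad_const(tape, slice3(post$z_mean, k)))
  lvs <- lapply(seq_len(K), function(k) ad_const(tape, slice3(post$z_logvar, k)))
  eps <- draw_eps(T_len, K, Dz, seed)
  cls_val <- 0
  if (alpha > 0 && any(lab)) {
    if (is.null(class_weights)) class_weights <- rep(1, K)
    yl <- labels[lab] + 1L
    cls_val <- alpha * sum(class_weights[yl] * log(p[cbind(which(lab), yl)]))
  }
  g <- gmdgm_objective_graph(tape, genn, kinds, ad_const(tape, p), negent,
                             mus, lvs, ad_const(tape, x), labels, eps, anneal_w,
                             cls_node = ad_const(tape, matrix(cls_val, 1L, 1L)))
  objective_terms(
    recon = as.numeric(g$recon$value), kl_z_init = as.numeric(g$kl_z_init$value),
    kl_z_dyn = 0, kl_y = as.numeric(g$kl_y$value),
    log_py1 = as.numeric(g$log_py1$value),
    classification = as.numeric(g$classification$value),
    anneal_w = anneal_w, total = as.numeric(g$total$value)
  )
}
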