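# Training loop for all model kinds: the supervised TCN classifier, the
# static mixture models (per-frame or TCN posteriors), and the switching
# dynamical systems (linear or MLP generative maps).
#
# Protocol: Adam, batches of contiguous fixed-length chunks, weighted cross
# entropy on labeled frames, and linear annealing of the KL / discrete-state
# terms over the first `anneal_epochs` epochs.

#' Training configuration
#'
#' Defaults follow the published protocol: Adam with learning rate 1e-4,
#' batches of 8 sequences of 1000 frames, 500 epochs, 100 annealing epochs.
#'
#' @param model_kind one of `"tcn_supervised"`, `"gmdgm"`, `"gmdgm_tcn"`,
#'   `"s3lds"`, `"s3nlds"`
#' @param learning_rate Adam learning rate
#' @param n_epochs training epochs (one epoch visits every training chunk)
#' @param batch_sequences chunks per optimizer step
#' @param sequence_length chunk length in frames (sessions are cut into
#'   contiguous non-overlapping chunks; shorter sessions are kept whole)
#' @param anneal_epochs linear KL annealing horizon
#' @param seed RNG seed controlling initialization, batching, dropout and
#'   reparameterization noise
#' @param val_fraction fraction of chunks held out for checkpoint selection
#' @param val_every validation cadence in epochs
#' @param latent_dim continuous latent dimension; when NULL it is chosen by
#'   the 95%-explained-variance rule ([choose_latent_dim()])
#' @return a `train_config` object
#' @export
train_config <- function(model_kind = c("tcn_supervised", "gmdgm", "gmdgm_tcn",
                                        "s3lds", "s3nlds"),
                         learning_rate = 1e-4, n_epochs = 500L,
                         batch_sequences = 8L, sequence_length = 1000L,
                         anneal_epochs = 100L, seed = 1L, val_fraction = 0.1,
                         val_every = 5L, latent_dim = NULL) {
  model_kind <- match.arg(model_kind)
  stopifnot(learning_rate > 0, n_epochs >= 1, batch_sequences >= 1,
            sequence_length >= 1, anneal_epochs >= 1)
  structure(list(model_kind = model_kind, learning_rate = learning_rate,
                 n_epochs = as.integer(n_epochs),
                 batch_sequences = as.integer(batch_sequences),
                 sequence_length = as.integer(sequence_length),
                 anneal_epochs = as.integer(anneal_epochs),
                 seed = as.integer(seed), val_fraction = val_fraction,
                 val_every = as.integer(val_every), latent_dim = latent_dim),
            class = "train_config")
}

#' Inverse-frequency class weights
#'
#' `w_k` proportional to the inverse class frequency among labeled frames,
#' normalized to mean 1. Errors if a class has no labeled frame.
#'
#' @param labels a [label_sequence()] or a list of them
#' @return length-K positive vector
#' @export
class_weights <- function(labels) {
  if (inherits(labels, "label_sequence")) labels <- list(labels)
  K <- labels[[1L]]$K
  cnt <- rep(0L, K)
  for (ls in labels) {
    idx <- labeled_frames(ls)
    cnt <- cnt + tabulate(ls$labels[idx] + 1L, nbins = K)
  }
  if (any(cnt == 0L)) {
    stop(sprintf("class '%s' absent from the labeled training frames",
                 labels[[1L]]$class_names[which(cnt == 0L)[1L]]))
  }
  w <- 1 / (cnt / sum(cnt))
  w / mean(w)
}

#' Linear KL annealing weight
#'
#' `min(epoch / anneal_epochs, 1)`: 0 at epoch 0, reaching 1 after
#' `anneal_epochs` epochs and staying there.
#'
#' @param epoch completed epochs (0-based)
#' @param cfg a [train_config()] or [loss_config()] carrying `anneal_epochs`
#' @return weight in `[0, 1]`
#' @export
anneal_weight <- function(epoch, cfg) {
  stopifnot(epoch >= 0)
  min(epoch / cfg$anneal_epochs, 1)
}

# Cut sessions into contiguous non-overlapping chunks.
chunk_sessions <- function(sessions, len) {
  chunks <- list()
  for (si in seq_along(sessions)) {
    x <- sessions[[si]]$features$values
    y <- sessions[[si]]$labels$labels
    T_len <- nrow(x)
    starts <- seq.int(1L, T_len, by = len)
    for (s in starts) {
      e <- min(T_len, s + len - 1L)
      chunks[[length(chunks) + 1L]] <- list(
        x = x[s:e, , drop = FALSE], y = y[s:e], session = si)
    }
  }
  chunks
}

# PCA-based linear emission initialization: columns of the top-Dz loading
# matrix (principal directions scaled by component standard deviations).
pca_emission_init <- function(xall, Dz) {
  pc <- stats::prcomp(xall, center = TRUE, scale. = FALSE)
  Dz <- min(Dz, ncol(pc$rotation))
  C <- pc$rotation[, seq_len(Dz), drop = FALSE] *
    rep(pc$sdev[seq_len(Dz)], each = ncol(xall))
  list(C = unname(C), d = as.numeric(colMeans(xall)))
}

init_rslds_for_training <- function(K, Dz, Dx, xall, nonlinear) {
  dyn_A <- replicate(K, 0.99 * diag(Dz), simplify = FALSE)
  dyn_b <- replicate(K, stats::rnorm(Dz, 0, 0.1), simplify = FALSE)
  dyn_Q <- replicate(K, 0.1 * diag(Dz), simplify = FALSE)
  rec_R <- replicate(K, matrix(0, K, Dz), simplify = FALSE)
  rec_r <- replicate(K, rep(0, K), simplify = FALSE)
  em <- pca_emission_init(xall, Dz)
  if (ncol(em$C) < Dz) Dz <- ncol(em$C)
  if (!nonlinear) {
    rslds_params(K, Dz, Dx, rep(1 / K, K), dyn_A, dyn_b, dyn_Q, rec_R, rec_r,
                 emission = em, emission_S = 0.1 * diag(Dx))
  } else {
    dyn_mlp <- replicate(K, mlp_params(Dz, Dz, Dz), simplify = FALSE)
    rec_mlp <- replicate(K, mlp_params(Dz, Dz, K), simplify = FALSE)
    rslds_params(K, Dz, Dx, rep(1 / K, K), dyn_Q = dyn_Q,
                 emission = em, emission_S = 0.1 * diag(Dx),
                 dynamics_kind = "mlp", recurrence_kind = "mlp",
                 dyn_mlp = dyn_mlp, rec_mlp = rec_mlp)
  }
}

init_gmdgm_for_training <- function(K, Dz, Dx, xall) {
  em <- pca_emission_init(xall, Dz)
  Dz <- ncol(em$C)
  gmdgm_params(K, Dz, Dx, rep(1 / K, K),
               cluster_mean = replicate(K, stats::rnorm(Dz, 0, 0.5), simplify = FALSE),
               cluster_var = replicate(K, rep(1, Dz), simplify = FALSE),
               emission = em, emission_cov = 0.1 * diag(Dx))
}

# Build the per-chunk loss graph; returns list(loss_node, terms, nodes).
chunk_loss_graph <- function(model, flat_nodes, chunk, anneal_w, loss_cfg,
                             training = TRUE) {
  tape <- attr(flat_nodes, "tape")
  x <- ad_const(tape, chunk$x)
  kind <- model$model_kind
  if (kind == "tcn_supervised") {
    logits <- tcn_graph(tape, model$cls_cfg, flat_nodes, x, training)
    T_len <- nrow(chunk$x); K <- model$K
    lab <- chunk$y >= 0L
    lse <- ad_logsumexp_rows(tape, logits)
    logq <- ad_sub(tape, logits, ad_matmul(tape, lse, ad_const(tape, matrix(1, 1L, K))))
    CW <- matrix(0, T_len, K)
    if (any(lab)) {
      CW[cbind(which(lab), chunk$y[lab] + 1L)] <- model$class_w[chunk$y[lab] + 1L]
    }
    ce <- ad_neg(tape, ad_sum(tape, ad_cmul(tape, logq, CW)))
    return(list(loss = ce,
                terms = list(classification = -ce$value, total = -ce$value)))
  }
  K <- model$K; Dz <- model$Dz
  wn_cls <- flat_nodes[startsWith(names(flat_nodes), "cls.")]
  names(wn_cls) <- sub("^cls\\.", "", names(wn_cls))
  wn_enc <- flat_nodes[startsWith(names(flat_nodes), "enc.")]
  names(wn_enc) <- sub("^enc\\.", "", names(wn_enc))
  genn <- flat_nodes[!grepl("^(cls|enc)\\.", names(flat_nodes))]
  pg <- posterior_graph(tape, model$post, wn_cls, wn_enc, x, training)
  T_len <- nrow(chunk$x)
  lse <- ad_logsumexp_rows(tape, pg$logits)
  logq <- ad_sub(tape, pg$logits, ad_matmul(tape, lse, ad_const(tape, matrix(1, 1L, K))))
  q <- ad_softmax_rows(tape, pg$logits)
  lab <- chunk$y >= 0L
  U <- matrix(as.numeric(!lab), T_len, K)
  negent <- ad_rowsums(tape, ad_cmul(tape, ad_mul(tape, q, logq), U))
  eps <- array(stats::rnorm(T_len * K * Dz), c(T_len, K, Dz))
  builder <- if (kind %in% c("s3lds", "s3nlds")) ss_objective_graph else gmdgm_objective_graph
  kinds <- list(dynamics_kind = model$gen_template$dynamics_kind,
                recurrence_kind = model$gen_template$recurrence_kind,
                emission_kind = model$gen_template$emission_kind,
                K = K, Dz = Dz, Dx = ncol(chunk$x))
  g <- builder(tape, genn, kinds, q, negent, pg$mu, pg$logvar, x, chunk$y, eps,
               anneal_w = anneal_w, logq = logq, alpha = loss_cfg$alpha,
               class_weights = model$class_w)
  list(loss = ad_neg(tape, g$total),
       terms = list(recon = as.numeric(g$recon$value),
                    kl_z_init = as.numeric(g$kl_z_init$value),
                    kl_z_dyn = as.numeric(g$kl_z_dyn$value),
                    kl_y = as.numeric(g$kl_y$value),
                    classification = as.numeric(g$classification$value),
                    total = as.numeric(g$total$value)))
}

#' Train an action-segmentation model
#'
#' Standardizes features on the training split, cuts sessions into
#' contiguous chunks, holds out a fraction of chunks for checkpoint
#' selection, and minimizes the negative objective by Adam. Aborts with a
#' diagnostic naming the offending term if the loss becomes non-finite.
#'
#' @param sessions list of sessions, each `list(features = , labels = )` with
#'   a [feature_sequence()] and [label_sequence()]
#' @param cfg a [train_config()]
#' @param loss_cfg a [loss_config()]; its `class_weights` default to the
#'   inverse-frequency weights of the training labels
#' @param tcn list of backbone options passed to [posterior_net()] /
#'   [tcn_config()] (e.g. `n_filters`)
#' @return a `train_state` with the fitted model, per-epoch term log, and the
#'   best-validation snapshot
#' @export
train <- function(sessions, cfg, loss_cfg = loss_config(), tcn = list()) {
  stopifnot(length(sessions) >= 1)
  set.seed(cfg$seed)
  kind <- cfg$model_kind
  class_names <- sessions[[1L]]$labels$class_names
  K <- length(class_names)
  std <- fit_standardizer(
    feature_sequence(do.call(rbind, lapply(sessions, function(s) s$features$values))))
  sessions <- lapply(sessions, function(s) {
    s$features <- apply_standardizer(s$features, std)
    s
  })
  xall <- do.call(rbind, lapply(sessions, function(s) s$features$values))
  Dx <- ncol(xall)
  cw <- class_weights(lapply(sessions, function(s) s$labels))
  Dz <- cfg$latent_dim %||%
    if (kind == "tcn_supervised") 0L else choose_latent_dim(feature_sequence(xall))

  tcn_args <- function(extra) {
    do.call(tcn_config, c(list(in_dim = Dx), extra, tcn))
  }
  model <- list(model_kind = kind, K = K, Dz = Dz, class_names = class_names,
                class_w = cw, std = std)
  if (kind == "tcn_supervised") {
    model$cls_cfg <- tcn_args(list(out_dim = K))
    flat <- tcn_init(model$cls_cfg)
  } else {
    pkind <- if (kind == "gmdgm") "dense" else "tcn"
    gen <- if (kind %in% c("s3lds", "s3nlds")) {
      init_rslds_for_training(K, Dz, Dx, xall, nonlinear = kind == "s3nlds")
    } else {
      init_gmdgm_for_training(K, Dz, Dx, xall)
    }
    model$Dz <- Dz <- gen$Dz
    model$post <- do.call(posterior_net, c(list(in_dim = Dx, K = K, Dz = Dz,
                                                kind = pkind), tcn))
    model$gen_template <- gen
    gflat <- if (kind %in% c("s3lds", "s3nlds")) gen_to_flat(gen) else gmdgm_to_flat(gen)
    flat <- c(post_to_flat(model$post), gflat)
  }

  chunks <- chunk_sessions(sessions, cfg$sequence_length)
  n_chunks <- length(chunks)
  n_val <- if (n_chunks >= 2L) max(1L, round(cfg$val_fraction * n_chunks)) else 0L
  val_idx <- if (n_val > 0L) sample.int(n_chunks, n_val) else integer(0)
  train_idx <- setdiff(seq_len(n_chunks), val_idx)
  if (!length(train_idx)) stop("no training chunks")

  opt <- adam_init(flat, lr = cfg$learning_rate)
  log_rows <- vector("list", cfg$n_epochs)
  best <- list(val = Inf, flat = flat, epoch = 0L)
  term_names <- c("recon", "kl_z_init", "kl_z_dyn", "kl_y", "classification", "total")

  eval_split <- function(flat_params, idx) {
    tot <- 0
    for (ci in idx) {
      tape <- ad_tape()
      fn <- lapply(flat_params, function(v) ad_const(tape, v))
      attr(fn, "tape") <- tape
      g <- with_seed(cfg$seed + 7919L,
                     chunk_loss_graph(model, fn, chunks[[ci]], anneal_w = 1,
                                      loss_cfg, training = FALSE))
      tot <- tot + as.numeric(g$loss$value)
    }
    tot / length(idx)
  }

  for (epoch in seq_len(cfg$n_epochs)) {
    aw <- anneal_weight(epoch - 1L, cfg)
    order_ <- sample(train_idx)
    batches <- split(order_, ceiling(seq_along(order_) / cfg$batch_sequences))
    esum <- stats::setNames(rep(0, length(term_names)), term_names)
    for (bt in batches) {
      grads <- NULL
      for (ci in bt) {
        tape <- ad_tape()
        fn <- params_to_nodes(tape, flat)
        attr(fn, "tape") <- tape
        g <- chunk_loss_graph(model, fn, chunks[[ci]], aw, loss_cfg, training = TRUE)
        if (!is.finite(g$loss$value)) {
          bad <- names(which(!vapply(g$terms, is.finite, TRUE)))
          stop(sprintf("non-finite loss at epoch %d (offending term: %s)",
                       epoch, paste(bad, collapse = ", ")))
        }
        ad_backward(tape, g$loss)
        gc_ <- nodes_to_grads(fn)
        grads <- if (is.null(grads)) gc_ else Map(`+`, grads, gc_)
        for (nm in names(g$terms)) {
          if (nm %in% term_names) esum[nm] <- esum[nm] + g$terms[[nm]]
        }
      }
      st <- adam_step(opt, flat, grads)
      flat <- st$params
      opt <- st$opt
    }
    val <- NA_real_
    if (n_val > 0L && (epoch %% cfg$val_every == 0L || epoch == cfg$n_epochs)) {
      val <- eval_split(flat, val_idx)
      if (val < best$val) best <- list(val = val, flat = flat, epoch = epoch)
    }
    log_rows[[epoch]] <- data.frame(epoch = epoch, anneal_w = aw,
                                    t(esum / length(train_idx)),
                                    val_loss = val)
  }
  if (n_val == 0L || !is.finite(best$val)) best <- list(val = NA_real_, flat = flat,
                                                        epoch = cfg$n_epochs)
  state <- list(model = model, flat = flat, best_flat = best$flat,
                best_epoch = best$epoch, cfg = cfg, loss_cfg = loss_cfg,
                log = do.call(rbind, log_rows))
  class(state) <- "train_state"
  state
}

#' @export
print.train_state <- function(x, ...) {
  cat(sprintf("<train_state: %s, %d epochs, best val epoch %d>\n",
              x$model$model_kind, nrow(x$log), x$best_epoch))
  invisible(x)
}

# Rebuild usable model weights from a flat parameter list.
state_weights <- function(state, use_best = TRUE) {
  flat <- if (use_best) state$best_flat else state$flat
  m <- state$model
  if (m$model_kind == "tcn_supervised") {
    list(cls_w = flat)
  } else {
    post <- flat_to_post(flat[grepl("^(cls|enc)\\.", names(flat))], m$post)
    gflat <- flat[!grepl("^(cls|enc)\\.", names(flat))]
    gen <- if (m$model_kind %in% c("s3lds", "s3nlds")) {
      flat_to_gen(gflat, m$gen_template)
    } else {
      flat_to_gmdgm(gflat, m$gen_template)
    }
    list(post = post, gen = gen)
  }
}

#' Predict class probabilities and states for a session
#'
#' Applies the stored feature standardization and the trained classifier
#' (best-validation checkpoint).
#'
#' @param state a `train_state` from [train()]
#' @param fs a [feature_sequence()]
#' @param use_best use the best-validation checkpoint (default) or the final
#'   parameters
#' @return list with `class_probs` (T x K) and `states` (length-T integers in
#'   `0..K-1`)
#' @export
predict_states <- function(state, fs, use_best = TRUE) {
  m <- state$model
  fsz <- apply_standardizer(fs, m$std)
  w <- state_weights(state, use_best)
  probs <- if (m$model_kind == "tcn_supervised") {
    softmax_rows(tcn_forward(m$cls_cfg, w$cls_w, fsz$values))
  } else {
    classify(w$post, fsz)
  }
  list(class_probs = probs, states = max.col(probs) - 1L)
}

#' Latent embedding of a session under a trained model
#'
#' For models with a class-conditional encoder, the posterior-mean embedding
#' `sum_k q(y=k|x) mu_k`; for the supervised TCN, the trunk activations
#' before the classification head.
#'
#' @inheritParams predict_states
#' @return T x D latent matrix
#' @export
embed_latents <- function(state, fs, use_best = TRUE) {
  m <- state$model
  fsz <- apply_standardizer(fs, m$std)
  w <- state_weights(state, use_best)
  if (m$model_kind == "tcn_supervised") {
    return(tcn_forward(m$cls_cfg, w$cls_w, fsz$values, head = FALSE))
  }
  f <- posterior_forward(w$post, fsz)
  q <- softmax_rows(f$logits)
  emb <- matrix(0, nrow(q), m$Dz)
  for (k in seq_len(m$K)) emb <- emb + q[, k] * slice3(f$mu, k)
  emb
}
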