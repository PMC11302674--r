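# Amortized approximate posteriors.
#
# Two networks share the factorized posterior q(y_t, z_t | x_window) =
# q(y_t | x) q(z_t | x, y_t): a classifier producing a K-way simplex per
# frame, and a class-conditional Gaussian encoder producing (mu, log var)
# for every class k at every frame. Both use the dilated TCN backbone (or a
# per-frame dense network for the static ablation). The encoder implements
# class conditioning as K parallel output heads on a shared trunk, so all K
# conditional distributions come out of one forward pass - exactly what the
# unlabeled objective's sums over classes need.

#' Construct an amortized posterior network pair
#'
#' @param in_dim input feature dimension
#' @param K number of behavior classes
#' @param Dz continuous latent dimension
#' @param kind `"tcn"` for the temporal backbone, `"dense"` for the static
#'   per-frame variant used by the static mixture ablation
#' @param n_blocks,n_sublayers_per_block,temporal_lags,n_filters,dropout_p
#'   backbone hyperparameters, see [tcn_config()]
#' @return a `posterior_net` object with freshly initialized weights (draws
#'   from the current RNG stream)
#' @export
posterior_net <- function(in_dim, K, Dz, kind = c("tcn", "dense"),
                          n_blocks = 2L, n_sublayers_per_block = 2L,
                          temporal_lags = 4L, n_filters = 32L, dropout_p = 0.10) {
  kind <- match.arg(kind)
  cls_cfg <- tcn_config(in_dim, K, n_blocks, n_sublayers_per_block,
                        temporal_lags, n_filters, dropout_p)
  enc_cfg <- tcn_config(in_dim, 2L * K * Dz, n_blocks, n_sublayers_per_block,
                        temporal_lags, n_filters, dropout_p)
  init <- if (kind == "tcn") tcn_init else dense_init
  structure(list(kind = kind, K = as.integer(K), Dz = as.integer(Dz),
                 cls_cfg = cls_cfg, enc_cfg = enc_cfg,
                 cls_w = init(cls_cfg), enc_w = init(enc_cfg)),
            class = "posterior_net")
}

backbone_graph <- function(kind) if (kind == "tcn") tcn_graph else dense_graph

# Flatten both networks' weights into one named list (training) and back.
post_to_flat <- function(post) {
  c(stats::setNames(post$cls_w, paste0("cls.", names(post$cls_w))),
    stats::setNames(post$enc_w, paste0("enc.", names(post$enc_w))))
}

flat_to_post <- function(flat, post) {
  cls_idx <- startsWith(names(flat), "cls.")
  post$cls_w <- stats::setNames(flat[cls_idx], sub("^cls\\.", "", names(flat)[cls_idx]))
  post$enc_w <- stats::setNames(flat[!cls_idx], sub("^enc\\.", "", names(flat)[!cls_idx]))
  post
}

# Column indices of the encoder head output for class k: mu then logvar.
enc_mu_cols <- function(K, Dz, k) (k - 1L) * Dz + seq_len(Dz)
enc_lv_cols <- function(K, Dz, k) K * Dz + (k - 1L) * Dz + seq_len(Dz)

#' Build posterior graphs on a tape
#'
#' Returns the classifier logits node and, per class, the encoder mean and
#' clamped log-variance nodes (log-variances are clamped to [-10, 10] for
#' numerical stability). Used by the training loop; numeric callers should
#' use [classify()] / [encode_z()].
#'
#' @param tape an [ad_tape()]
#' @param post a [posterior_net()]
#' @param wn_cls,wn_enc weight node lists for the two networks
#' @param x input node
#' @param training enable dropout
#' @return list with `logits`, `mu` (list of K nodes), `logvar` (list of K)
#' @export
posterior_graph <- function(tape, post, wn_cls, wn_enc, x, training = FALSE) {
  bg <- backbone_graph(post$kind)
  logits <- bg(tape, post$cls_cfg, wn_cls, x, training)
  enc_out <- bg(tape, post$enc_cfg, wn_enc, x, training)
  K <- post$K; Dz <- post$Dz
  mu <- lapply(seq_len(K), function(k) ad_cols(tape, enc_out, enc_mu_cols(K, Dz, k)))
  lv <- lapply(seq_len(K), function(k)
    ad_clamp(tape, ad_cols(tape, enc_out, enc_lv_cols(K, Dz, k)), -10, 10))
  list(logits = logits, mu = mu, logvar = lv)
}

#' Per-frame posterior factors
#'
#' Container for the classifier simplex and the class-conditional Gaussian
#' parameters at every frame.
#'
#' @param class_probs T x K row-stochastic matrix
#' @param z_mean,z_logvar T x K x Dz arrays
#' @return a `posterior_factors` object
#' @export
posterior_factors <- function(class_probs, z_mean, z_logvar) {
  class_probs <- as_mat(class_probs)
  if (any(class_probs < 0) || any(abs(rowSums(class_probs) - 1) > 1e-6)) {
    stop("class_probs rows must be simplices")
  }
  if (!all(is.finite(z_logvar))) stop("non-finite z_logvar")
  stopifnot(length(dim(z_mean)) == 3L, all(dim(z_mean) == dim(z_logvar)),
            dim(z_mean)[1L] == nrow(class_probs),
            dim(z_mean)[2L] == ncol(class_probs))
  structure(list(class_probs = class_probs, z_mean = z_mean, z_logvar = z_logvar),
            class = "posterior_factors")
}

# Numeric forward through both posterior networks.
posterior_forward <- function(post, x) {
  if (inherits(x, "feature_sequence")) x <- x$values
  x <- as.matrix(x)
  if (ncol(x) != post$cls_cfg$in_dim) {
    stop(sprintf("input has %d columns but the posterior expects %d",
                 ncol(x), post$cls_cfg$in_dim))
  }
  tape <- ad_tape()
  wn_cls <- lapply(post$cls_w, function(w) ad_const(tape, w))
  wn_enc <- lapply(post$enc_w, function(w) ad_const(tape, w))
  g <- posterior_graph(tape, post, wn_cls, wn_enc, ad_const(tape, x), training = FALSE)
  T_ <- nrow(x); K <- post$K; Dz <- post$Dz
  mu <- array(0, c(T_, K, Dz)); lv <- array(0, c(T_, K, Dz))
  for (k in seq_len(K)) {
    mu[, k, ] <- g$mu[[k]]$value
    lv[, k, ] <- g$logvar[[k]]$value
  }
  list(logits = g$logits$value, mu = mu, logvar = lv)
}

#' Frame-wise classification
#'
#' Softmax over the classifier head's K logits at every frame; the rows form
#' the approximate posterior over the discrete state and constitute the
#' model's frame classifier.
#'
#' @param post a [posterior_net()]
#' @param fs a [feature_sequence()] or numeric matrix
#' @return T x K matrix of class probabilities
#' @export
classify <- function(post, fs) {
  softmax_rows(posterior_forward(post, fs)$logits)
}

#' Full posterior factors for a sequence
#'
#' @inheritParams classify
#' @return a [posterior_factors()]
#' @export
infer_posterior <- function(post, fs) {
  f <- posterior_forward(post, fs)
  posterior_factors(softmax_rows(f$logits), f$mu, f$logvar)
}

# One shared reparameterization noise draw per (t, k): the same seeded
# epsilon array is used by every objective entry point so that one-hot
# substitution reproduces the labeled bound term by term.
draw_eps <- function(T_len, K, Dz, seed) {
  with_seed(seed, array(stats::rnorm(T_len * K * Dz), c(T_len, K, Dz)))
}

#' Reparameterized class-conditional encoding
#'
#' Evaluates the class-conditional Gaussian encoder and draws one
#' reparameterized sample `z = mu + sigma * eps`, `eps ~ N(0, I)`, per frame
#' and class (single-sample bound estimator). Identical seeds give identical
#' samples.
#'
#' @inheritParams classify
#' @param seed RNG seed for the noise draw
#' @return list with `factors` (a [posterior_factors()]) and `z_sample`
#'   (T x K x Dz array)
#' @export
encode_z <- function(post, fs, seed = 1L) {
  f <- infer_posterior(post, fs)
  dims <- dim(f$z_mean)
  eps <- draw_eps(dims[1L], dims[2L], dims[3L], seed)
  list(factors = f, z_sample = f$z_mean + exp(0.5 * f$z_logvar) * eps)
}
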