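# Dilated temporal convolutional network (TCN): the shared backbone of the
# supervised classifier and of the amortized posterior networks.
#
# Architecture: `n_blocks` dilation blocks, each a stack of
# `n_sublayers_per_block` sub-blocks (1-D convolution -> leaky ReLU ->
# dropout) with a residual connection around the block. Convolutions are
# symmetric with `temporal_lags` lags on each side (kernel width 2*lags + 1)
# and the dilation of block b is 2^(b-1), so depth widens the receptive
# field. Sequence edges are zero-padded so an output exists for every frame.

#' TCN configuration
#'
#' @param in_dim input feature dimension
#' @param out_dim output channels of the final width-1 head (logits or
#'   Gaussian parameters are produced downstream; the head has no
#'   nonlinearity)
#' @param n_blocks number of dilation blocks (dilation of block b is 2^(b-1))
#' @param n_sublayers_per_block convolution sub-blocks per dilation block
#' @param temporal_lags lags per convolution layer; kernel width is
#'   `2 * temporal_lags + 1`
#' @param n_filters channels of every internal convolution
#' @param dropout_p dropout probability inside sub-blocks (training only)
#' @return a `tcn_config` object
#' @export
tcn_config <- function(in_dim, out_dim, n_blocks = 2L, n_sublayers_per_block = 2L,
                       temporal_lags = 4L, n_filters = 32L, dropout_p = 0.10) {
  stopifnot(in_dim >= 1, out_dim >= 1, n_blocks >= 1, n_sublayers_per_block >= 1,
            temporal_lags >= 1, n_filters >= 1, dropout_p >= 0, dropout_p < 1)
  structure(list(in_dim = as.integer(in_dim), out_dim = as.integer(out_dim),
                 n_blocks = as.integer(n_blocks),
                 n_sublayers_per_block = as.integer(n_sublayers_per_block),
                 temporal_lags = as.integer(temporal_lags),
                 n_filters = as.integer(n_filters), dropout_p = dropout_p),
            class = "tcn_config")
}

#' Half-width of the TCN receptive field
#'
#' The output at frame t depends on input frames `t-tau ... t+tau` with
#' `tau = temporal_lags * n_sublayers_per_block * sum_b 2^(b-1)`. The default
#' configuration (2 blocks, 2 sub-layers, 4 lags) gives `tau = 24`, i.e. a
#' 49-frame window: 0.7 s at 70 Hz, 1.96 s at 25 Hz, 0.82 s at 60 Hz.
#'
#' @param cfg a [tcn_config()]
#' @return integer half-width in frames
#' @export
receptive_field_half_width <- function(cfg) {
  as.integer(cfg$temporal_lags * cfg$n_sublayers_per_block *
               sum(2^(seq_len(cfg$n_blocks) - 1L)))
}

# Fan-in uniform init for a (fan_in x fan_out) weight matrix.
init_mat <- function(fan_in, fan_out) {
  lim <- 1 / sqrt(fan_in)
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

#' Initialize TCN weights
#'
#' Fan-in uniform initialization; draws come from the current RNG stream, so
#' wrap in `set.seed()` (or pass seeds through the training config) for
#' reproducibility. When a block's input width differs from `n_filters` the
#' residual connection uses a learned width-1 convolution, otherwise the
#' identity.
#'
#' @param cfg a [tcn_config()]
#' @return named list of weight matrices
#' @export
tcn_init <- function(cfg) {
  w <- list()
  width <- 2L * cfg$temporal_lags + 1L
  cin_block <- cfg$in_dim
  for (b in seq_len(cfg$n_blocks)) {
    cin <- cin_block
    for (s in seq_len(cfg$n_sublayers_per_block)) {
      w[[sprintf("W%d_%d", b, s)]] <- init_mat(width * cin, cfg$n_filters)
      w[[sprintf("b%d_%d", b, s)]] <- matrix(0, 1L, cfg$n_filters)
      cin <- cfg$n_filters
    }
    if (cin_block != cfg$n_filters) {
      w[[sprintf("Wres%d", b)]] <- init_mat(cin_block, cfg$n_filters)
    }
    cin_block <- cfg$n_filters
  }
  w$Whead <- init_mat(cfg$n_filters, cfg$out_dim)
  w$bhead <- matrix(0, 1L, cfg$out_dim)
  w
}

# One dilated symmetric convolution as a single fused node: the kernel is a
# (width * Cin) x Cout matrix applied to shifted row blocks of the zero-padded
# input. Fusing forward and backward avoids materializing the im2col matrix
# on the tape.
conv1d_node <- function(tape, x, W, b, dilation, lags) {
  T_ <- nrow(x$value)
  Cin <- ncol(x$value)
  Cout <- ncol(W$value)
  width <- 2L * lags + 1L
  pad <- dilation * lags
  Xp <- rbind(matrix(0, pad, Cin), x$value, matrix(0, pad, Cin))
  out <- matrix(rep(as.numeric(b$value), each = T_), T_, Cout)
  blocks <- lapply(seq_len(width) - 1L, function(j) (j * Cin) + seq_len(Cin))
  for (j in seq_len(width) - 1L) {
    out <- out + Xp[seq_len(T_) + j * dilation, , drop = FALSE] %*%
      W$value[blocks[[j + 1L]], , drop = FALSE]
  }
  new_node(tape, out, list(x, W, b), function(g) {
    if (W$track) {
      gW <- matrix(0, width * Cin, Cout)
      for (j in seq_len(width) - 1L) {
        gW[blocks[[j + 1L]], ] <- crossprod(Xp[seq_len(T_) + j * dilation, , drop = FALSE], g)
      }
      accum(W, gW)
    }
    if (b$track) accum(b, matrix(colSums(g), 1L))
    if (x$track) {
      gXp <- matrix(0, T_ + 2L * pad, Cin)
      for (j in seq_len(width) - 1L) {
        idx <- seq_len(T_) + j * dilation
        gXp[idx, ] <- gXp[idx, ] + tcrossprod(g, W$value[blocks[[j + 1L]], , drop = FALSE])
      }
      accum(x, gXp[pad + seq_len(T_), , drop = FALSE])
    }
  })
}

#' Build the TCN forward graph on an autodiff tape
#'
#' Used internally by training; most callers want [tcn_forward()].
#'
#' @param tape an [ad_tape()]
#' @param cfg a [tcn_config()]
#' @param wn named list of weight nodes (from [params_to_nodes()])
#' @param x input node (T x in_dim)
#' @param training if TRUE, dropout masks are sampled and applied
#' @param head if FALSE, return the trunk activations (T x n_filters) without
#'   the final width-1 head
#' @return output node (T x out_dim)
#' @export
tcn_graph <- function(tape, cfg, wn, x, training = FALSE, head = TRUE) {
  h <- x
  for (b in seq_len(cfg$n_blocks)) {
    dil <- 2L^(b - 1L)
    block_in <- h
    for (s in seq_len(cfg$n_sublayers_per_block)) {
      h <- conv1d_node(tape, h, wn[[sprintf("W%d_%d", b, s)]],
                       wn[[sprintf("b%d_%d", b, s)]], dil, cfg$temporal_lags)
      h <- ad_leaky_relu(tape, h)
      if (training && cfg$dropout_p > 0) h <- ad_dropout(tape, h, cfg$dropout_p)
    }
    res <- if (!is.null(wn[[sprintf("Wres%d", b)]])) {
      ad_matmul(tape, block_in, wn[[sprintf("Wres%d", b)]])
    } else block_in
    h <- ad_add(tape, h, res)
  }
  if (!head) return(h)
  ad_addvec(tape, ad_matmul(tape, h, wn$Whead), wn$bhead)
}

#' Evaluate a TCN on a feature matrix
#'
#' Deterministic evaluation-mode forward pass (dropout disabled).
#'
#' @param cfg a [tcn_config()]
#' @param weights weight list from [tcn_init()]
#' @param x numeric T x in_dim matrix or a [feature_sequence()]
#' @param head if FALSE, return trunk activations instead of head output
#' @return numeric T x out_dim matrix
#' @export
tcn_forward <- function(cfg, weights, x, head = TRUE) {
  if (inherits(x, "feature_sequence")) x <- x$values
  x <- as.matrix(x)
  if (ncol(x) != cfg$in_dim) {
    stop(sprintf("input has %d columns but the TCN expects %d", ncol(x), cfg$in_dim))
  }
  tape <- ad_tape()
  wn <- lapply(weights, function(w) ad_const(tape, w))
  tcn_graph(tape, cfg, wn, ad_const(tape, x), training = FALSE, head = head)$value
}

#' Per-frame dense network (static variant)
#'
#' The non-temporal counterpart of the TCN used by the static Gaussian-mixture
#' ablation: one hidden layer of `n_filters` leaky-ReLU units applied
#' independently to every frame, so output row t depends only on input row t.
#'
#' @inheritParams tcn_init
#' @return named weight list (`dense_init`), or an output node (`dense_graph`)
#' @export
dense_init <- function(cfg) {
  list(
    W1 = init_mat(cfg$in_dim, cfg$n_filters),
    b1 = matrix(0, 1L, cfg$n_filters),
    Whead = init_mat(cfg$n_filters, cfg$out_dim),
    bhead = matrix(0, 1L, cfg$out_dim)
  )
}

#' @rdname dense_init
#' @inheritParams tcn_graph
#' @export
dense_graph <- function(tape, cfg, wn, x, training = FALSE) {
  h <- ad_leaky_relu(tape, ad_addvec(tape, ad_matmul(tape, x, wn$W1), wn$b1))
  if (training && cfg$dropout_p > 0) h <- ad_dropout(tape, h, cfg$dropout_p)
  ad_addvec(tape, ad_matmul(tape, h, wn$Whead), wn$bhead)
}
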