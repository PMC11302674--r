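# Minimal reverse-mode automatic differentiation over dense matrices.
#
# Every node holds a matrix value; scalars are 1x1 matrices. Nodes are recorded
# on a tape in creation order and gradients are propagated by walking the tape
# backwards. Operations are deliberately coarse (whole-matrix BLAS calls) so
# tape overhead stays negligible relative to the linear algebra.

#' Create a fresh autodiff tape
#'
#' A tape records every node created by the `ad_*` operations so that
#' [ad_backward()] can replay them in reverse. One tape corresponds to one
#' forward pass; build a new tape per gradient evaluation.
#'
#' @return An environment with internal node storage.
#' @export
ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

new_node <- function(tape, value, parents = list(), backfn = NULL, track = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  if (is.null(track)) {
    track <- FALSE
    for (p in parents) if (p$track) { track <- TRUE; break }
  }
  nd$track <- track
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

as_mat <- function(v) {
  if (is.matrix(v)) v else matrix(v, nrow = 1L)
}

#' @rdname ad_tape
#' @param tape a tape from [ad_tape()]
#' @param v numeric matrix (or vector, treated as a 1-row matrix)
#' @export
ad_const <- function(tape, v) new_node(tape, as_mat(v), track = FALSE)

#' @rdname ad_tape
#' @export
ad_param <- function(tape, v) new_node(tape, as_mat(v), track = TRUE)

accum <- function(p, g) {
  if (!p$track) return(invisible(NULL))
  p$grad <- if (is.null(p$grad)) g else p$grad + g
  invisible(NULL)
}

#' Run the backward pass
#'
#' Seeds the gradient of `node` (which must be scalar, i.e. 1x1) with 1 and
#' accumulates gradients into every tracked ancestor. Gradients are read off
#' param nodes via `$grad` (NULL means the node did not influence the loss).
#'
#' @param tape the tape on which the graph was built
#' @param node the scalar loss node
#' @export
ad_backward <- function(tape, node) {
  stopifnot(length(node$value) == 1L)
  node$grad <- matrix(1, 1L, 1L)
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backfn) && nd$track) nd$backfn(nd$grad)
  }
  invisible(NULL)
}

# ---- arithmetic -------------------------------------------------------------

#' Elementwise and linear-algebra autodiff operations
#'
#' Building blocks used by the TCN, the posterior networks and the ELBO graph.
#' All operate on matrix-valued nodes and record their backward rule on the
#' tape. `ad_addvec` broadcasts a 1-row bias over rows; `ad_cmul`/`ad_scale`
#' multiply by an untracked constant; `ad_rows`/`ad_cols` gather (with
#' duplicate-index accumulation in the backward pass).
#'
#' @param tape tape from [ad_tape()]
#' @param a,b nodes
#' @name ad-ops
NULL

#' @rdname ad-ops
#' @export
ad_add <- function(tape, a, b) {
  new_node(tape, a$value + b$value, list(a, b), function(g) { accum(a, g); accum(b, g) })
}

#' @rdname ad-ops
#' @export
ad_sub <- function(tape, a, b) {
  new_node(tape, a$value - b$value, list(a, b), function(g) { accum(a, g); accum(b, -g) })
}

#' @rdname ad-ops
#' @export
ad_neg <- function(tape, a) {
  new_node(tape, -a$value, list(a), function(g) accum(a, -g))
}

#' @rdname ad-ops
#' @export
ad_mul <- function(tape, a, b) {
  new_node(tape, a$value * b$value, list(a, b),
           function(g) { accum(a, g * b$value); accum(b, g * a$value) })
}

#' @rdname ad-ops
#' @param m constant numeric matrix (not differentiated through)
#' @export
ad_cmul <- function(tape, a, m) {
  new_node(tape, a$value * m, list(a), function(g) accum(a, g * m))
}

#' @rdname ad-ops
#' @param s constant scalar
#' @export
ad_scale <- function(tape, a, s) {
  new_node(tape, a$value * s, list(a), function(g) accum(a, g * s))
}

#' @rdname ad-ops
#' @export
ad_shift <- function(tape, a, s) {
  new_node(tape, a$value + s, list(a), function(g) accum(a, g))
}

#' @rdname ad-ops
#' @export
ad_matmul <- function(tape, a, b) {
  new_node(tape, a$value %*% b$value, list(a, b), function(g) {
    accum(a, tcrossprod(g, b$value))
    accum(b, crossprod(a$value, g))
  })
}

#' @rdname ad-ops
#' @export
ad_addvec <- function(tape, a, b) {
  nr <- nrow(a$value)
  val <- a$value + rep(as.numeric(b$value), each = nr)
  new_node(tape, val, list(a, b), function(g) {
    accum(a, g)
    accum(b, matrix(colSums(g), 1L))
  })
}

#' @rdname ad-ops
#' @export
ad_mulvec <- function(tape, a, b) {
  nr <- nrow(a$value)
  bv <- rep(as.numeric(b$value), each = nr)
  new_node(tape, a$value * bv, list(a, b), function(g) {
    accum(a, g * bv)
    accum(b, matrix(colSums(g * a$value), 1L))
  })
}

# ---- nonlinearities ---------------------------------------------------------

#' @rdname ad-ops
#' @export
ad_exp <- function(tape, a) {
  v <- exp(a$value)
  new_node(tape, v, list(a), function(g) accum(a, g * v))
}

#' @rdname ad-ops
#' @export
ad_log <- function(tape, a) {
  new_node(tape, log(a$value), list(a), function(g) accum(a, g / a$value))
}

#' @rdname ad-ops
#' @export
ad_tanh <- function(tape, a) {
  v <- tanh(a$value)
  new_node(tape, v, list(a), function(g) accum(a, g * (1 - v * v)))
}

#' @rdname ad-ops
#' @param slope negative-side slope of the leaky rectifier
#' @export
ad_leaky_relu <- function(tape, a, slope = 0.01) {
  d <- slope + (1 - slope) * (a$value > 0)
  new_node(tape, a$value * d, list(a), function(g) accum(a, g * d))
}

#' @rdname ad-ops
#' @param lo,hi clamp bounds; the gradient is zeroed outside (saturated entries)
#' @export
ad_clamp <- function(tape, a, lo, hi) {
  v <- pmin(pmax(a$value, lo), hi)
  d <- (a$value > lo & a$value < hi) * 1
  new_node(tape, v, list(a), function(g) accum(a, g * d))
}

# ---- shape ops --------------------------------------------------------------

#' @rdname ad-ops
#' @param idx integer row/column indices (duplicates allowed for rows)
#' @export
ad_rows <- function(tape, a, idx) {
  nr <- nrow(a$value); nc <- ncol(a$value)
  contig <- length(idx) == 1L || all(diff(idx) == 1L)
  new_node(tape, a$value[idx, , drop = FALSE], list(a), function(g) {
    gz <- matrix(0, nr, nc)
    if (contig) {
      gz[idx[1L]:idx[length(idx)], ] <- g
    } else {
      rs <- rowsum(g, group = idx)
      gz[as.integer(rownames(rs)), ] <- rs
    }
    accum(a, gz)
  })
}

#' @rdname ad-ops
#' @export
ad_cols <- function(tape, a, idx) {
  nc <- ncol(a$value)
  new_node(tape, a$value[, idx, drop = FALSE], list(a), function(g) {
    gz <- matrix(0, nrow(a$value), nc)
    gz[, idx] <- g
    accum(a, gz)
  })
}

#' @rdname ad-ops
#' @param xs list of nodes with equal row counts, bound column-wise
#' @export
ad_cbind <- function(tape, xs) {
  vals <- lapply(xs, function(x) x$value)
  widths <- vapply(vals, ncol, 1L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  new_node(tape, do.call(cbind, vals), xs, function(g) {
    for (j in seq_along(xs)) {
      accum(xs[[j]], g[, starts[j]:ends[j], drop = FALSE])
    }
  })
}

#' @rdname ad-ops
#' @param before,after number of zero rows added before/after
#' @export
ad_pad_rows <- function(tape, a, before, after) {
  nr <- nrow(a$value); nc <- ncol(a$value)
  val <- rbind(matrix(0, before, nc), a$value, matrix(0, after, nc))
  new_node(tape, val, list(a), function(g) {
    accum(a, g[(before + 1L):(before + nr), , drop = FALSE])
  })
}

# ---- reductions -------------------------------------------------------------

#' @rdname ad-ops
#' @export
ad_sum <- function(tape, a) {
  nr <- nrow(a$value); nc <- ncol(a$value)
  new_node(tape, matrix(sum(a$value), 1L, 1L), list(a), function(g) {
    accum(a, matrix(as.numeric(g), nr, nc))
  })
}

#' @rdname ad-ops
#' @export
ad_rowsums <- function(tape, a) {
  nc <- ncol(a$value)
  new_node(tape, matrix(rowSums(a$value), ncol = 1L), list(a), function(g) {
    accum(a, matrix(rep(g, nc), nrow(a$value), nc))
  })
}

#' @rdname ad-ops
#' @export
ad_logsumexp_rows <- function(tape, a) {
  m <- row_max(a$value)
  e <- exp(a$value - m)
  se <- rowSums(e)
  val <- matrix(m + log(se), ncol = 1L)
  p <- e / se
  new_node(tape, val, list(a), function(g) {
    accum(a, as.numeric(g) * p)
  })
}

#' @rdname ad-ops
#' @export
ad_softmax_rows <- function(tape, a) {
  m <- row_max(a$value)
  e <- exp(a$value - m)
  p <- e / rowSums(e)
  new_node(tape, p, list(a), function(g) {
    accum(a, p * (g - rowSums(g * p)))
  })
}

#' @rdname ad-ops
#' @param p dropout probability; the inverted-dropout mask is drawn from the
#'   current RNG stream at graph-construction time
#' @export
ad_dropout <- function(tape, a, p) {
  if (p <= 0) return(a)
  mask <- (matrix(stats::runif(length(a$value)), nrow(a$value)) >= p) / (1 - p)
  ad_cmul(tape, a, mask)
}

# ---- optimizer --------------------------------------------------------------

#' Adam optimizer over a flat list of parameter matrices
#'
#' @param params named list of numeric matrices
#' @param lr learning rate
#' @param beta1,beta2,eps Adam moment decay rates and stabilizer
#' @return an optimizer state; advance it with [adam_step()]
#' @export
adam_init <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(
    lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0)
  )
}

#' @rdname adam_init
#' @param opt optimizer state
#' @param grads named list of gradients matching `params`
#' @return list with updated `params` and `opt`
#' @export
adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  c1 <- 1 - opt$beta1^opt$t
  c2 <- 1 - opt$beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g * g
    mhat <- opt$m[[nm]] / c1
    vhat <- opt$v[[nm]] / c2
    params[[nm]] <- params[[nm]] - opt$lr * mhat / (sqrt(vhat) + opt$eps)
  }
  list(params = params, opt = opt)
}

# Turn a flat named list of matrices into param nodes on a tape.
params_to_nodes <- function(tape, params) {
  lapply(params, function(p) ad_param(tape, p))
}

# Collect gradients (zeros where a param never entered the graph).
nodes_to_grads <- function(nodes) {
  lapply(nodes, function(nd) if (is.null(nd$grad)) nd$value * 0 else nd$grad)
}
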