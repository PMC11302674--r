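# Evaluation metrics: per-class precision/recall/F1 and confusion matrix,
# predictive entropy split by true/false positives, majority-overlap matching
# of unsupervised states to labeled classes, and cluster homogeneity of
# latent embeddings. Only labeled frames (excluding background) are scored.

#' Sentinel for unsupervised states with no labeled overlap
#' @export
STATE_UNMATCHED <- -1L

#' Frame-wise classification report
#'
#' Scores predictions against the labeled frames (background frames are
#' excluded). Reports per-class precision, recall, F1 (zero when precision
#' and recall are both zero), unweighted macro-F1, and the K x K confusion
#' matrix with rows indexed by the true class.
#'
#' @param pred length-T integer predictions in `0..K-1`
#' @param labels a [label_sequence()]
#' @return list with `per_class` (data frame), `macro_f1`, `accuracy`,
#'   `confusion`
#' @export
f1_report <- function(pred, labels) {
  stopifnot(inherits(labels, "label_sequence"))
  K <- labels$K
  idx <- labeled_frames(labels)
  if (!length(idx)) stop("empty labeled set")
  y <- labels$labels[idx]
  p <- as.integer(pred)[idx]
  conf <- matrix(0L, K, K, dimnames = list(truth = labels$class_names,
                                           pred = labels$class_names))
  for (i in seq_along(y)) {
    if (p[i] >= 0L && p[i] < K) conf[y[i] + 1L, p[i] + 1L] <- conf[y[i] + 1L, p[i] + 1L] + 1L
  }
  tp <- diag(conf)
  prec <- ifelse(colSums(conf) > 0, tp / colSums(conf), 0)
  # predictions outside 0..K-1 (unmatched states) count against recall only
  rec <- tp / tabulate(y + 1L, nbins = K)
  rec[is.nan(rec)] <- 0
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  list(per_class = data.frame(class = labels$class_names, precision = prec,
                              recall = rec, f1 = f1, support = tabulate(y + 1L, K),
                              row.names = NULL),
       macro_f1 = mean(f1),
       accuracy = mean(p == y),
       confusion = conf)
}

#' Predictive entropy split by true/false positives
#'
#' For each class k, the mean Shannon entropy (natural log) of the
#' classifier's probability rows over the frames predicted as k, split into
#' true positives (label k) and false positives (label not k). Classes with
#' an empty TP or FP set get `NA` for that entry, never zero.
#'
#' @param class_probs T x K probability matrix
#' @param pred length-T integer predictions
#' @param labels a [label_sequence()]
#' @return data frame with columns `class`, `tp_entropy`, `fp_entropy`,
#'   `n_tp`, `n_fp`
#' @export
entropy_report <- function(class_probs, pred, labels) {
  stopifnot(inherits(labels, "label_sequence"))
  K <- labels$K
  idx <- labeled_frames(labels)
  y <- labels$labels[idx]
  p <- as.integer(pred)[idx]
  cp <- class_probs[idx, , drop = FALSE]
  ent <- apply(cp, 1L, function(row) {
    pos <- row > 0
    -sum(row[pos] * log(row[pos]))
  })
  out <- data.frame(class = labels$class_names,
                    tp_entropy = NA_real_, fp_entropy = NA_real_,
                    n_tp = 0L, n_fp = 0L)
  for (k in 0:(K - 1L)) {
    tp_set <- p == k & y == k
    fp_set <- p == k & y != k
    out$n_tp[k + 1L] <- sum(tp_set)
    out$n_fp[k + 1L] <- sum(fp_set)
    if (any(tp_set)) out$tp_entropy[k + 1L] <- mean(ent[tp_set])
    if (any(fp_set)) out$fp_entropy[k + 1L] <- mean(ent[fp_set])
  }
  out
}

#' Match unsupervised states to labeled classes by majority overlap
#'
#' Maps each predicted state (arbitrary integer alphabet) to the labeled
#' class with which it co-occurs most often on the labeled training frames.
#' Many states may map to one class; ties break to the lowest class index;
#' states never seen on a labeled frame map to [STATE_UNMATCHED].
#'
#' @param pred_states length-T integer state sequence (any alphabet)
#' @param labels a [label_sequence()] on the same frames (the training split)
#' @return named integer vector: for each state (name), the matched class
#' @export
match_states <- function(pred_states, labels) {
  stopifnot(inherits(labels, "label_sequence"))
  states <- sort(unique(as.integer(pred_states)))
  idx <- labeled_frames(labels)
  y <- labels$labels[idx]
  s <- as.integer(pred_states)[idx]
  out <- stats::setNames(rep(STATE_UNMATCHED, length(states)), states)
  for (st in states) {
    cnt <- tabulate(y[s == st] + 1L, nbins = labels$K)
    if (sum(cnt) > 0L) out[as.character(st)] <- which.max(cnt) - 1L
  }
  out
}

#' Apply a state-to-class mapping to a state sequence
#'
#' @param pred_states integer state sequence
#' @param mapping result of [match_states()]
#' @return integer class sequence ([STATE_UNMATCHED] where unmapped)
#' @export
apply_state_map <- function(pred_states, mapping) {
  out <- rep(STATE_UNMATCHED, length(pred_states))
  hit <- as.character(pred_states) %in% names(mapping)
  out[hit] <- mapping[as.character(pred_states)[hit]]
  as.integer(out)
}

#' Cluster homogeneity score
#'
#' `h = 1 - H(class | cluster) / H(class)` from the empirical joint counts
#' (natural log); 1 when every cluster contains a single class (and when the
#' class distribution is degenerate), 0 when clusters are uninformative.
#'
#' @param cluster_ids,class_ids equal-length integer vectors
#' @return scalar in `[0, 1]`
#' @export
homogeneity <- function(cluster_ids, class_ids) {
  stopifnot(length(cluster_ids) == length(class_ids), length(class_ids) >= 1)
  tab <- table(cluster_ids, class_ids)
  n <- sum(tab)
  pc <- colSums(tab) / n
  h_class <- -sum(ifelse(pc > 0, pc * log(pc), 0))
  if (h_class == 0) return(1)
  h_cond <- 0
  for (i in seq_len(nrow(tab))) {
    ni <- sum(tab[i, ])
    if (ni == 0) next
    pk <- tab[i, ] / ni
    h_cond <- h_cond - (ni / n) * sum(ifelse(pk > 0, pk * log(pk), 0))
  }
  max(0, min(1, 1 - h_cond / h_class))
}

#' Homogeneity of k-means clusters in a latent space
#'
#' Runs k-means (10 restarts, seeded) on the latent embedding for each
#' requested cluster count and scores the homogeneity of the resulting
#' clusters against the labels on labeled frames. Clustering uses all frames;
#' only labeled frames enter the score.
#'
#' @param latents T x D latent matrix
#' @param labels a [label_sequence()]
#' @param cluster_counts integer vector of k values
#' @param seed RNG seed for k-means initialization
#' @return data frame with `k` and `homogeneity`
#' @export
latent_cluster_scores <- function(latents, labels, cluster_counts, seed = 1L) {
  latents <- as.matrix(latents)
  stopifnot(inherits(labels, "label_sequence"), nrow(latents) == length(labels$labels))
  if (any(cluster_counts > nrow(latents))) stop("cluster count exceeds number of points")
  idx <- labeled_frames(labels)
  scores <- vapply(cluster_counts, function(k) {
    cl <- with_seed(seed, stats::kmeans(latents, centers = k, nstart = 10L,
                                        iter.max = 50L))
    homogeneity(cl$cluster[idx], labels$labels[idx])
  }, 1)
  data.frame(k = as.integer(cluster_counts), homogeneity = scores)
}
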