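# Metric identities and hand-computed cases.

test_that("F1 report matches closed forms", {
  ls <- label_sequence(c(0, 0, 1, 1, SEG_UNLABELED, SEG_BACKGROUND), c("a", "b"))
  # perfect prediction on the labeled frames
  r <- f1_report(c(0, 0, 1, 1, 0, 1), ls)
  expect_equal(r$macro_f1, 1)
  expect_equal(r$accuracy, 1)
  expect_equal(unname(diag(r$confusion)), c(2L, 2L))

  # binary case with precision 0.5, recall 1 for class a
  ls2 <- label_sequence(c(0, 1, 1, 1), c("a", "b"))
  r2 <- f1_report(c(0, 0, 1, 1), ls2)
  expect_equal(r2$per_class$precision[1], 0.5)
  expect_equal(r2$per_class$recall[1], 1)
  expect_equal(r2$per_class$f1[1], 2 / 3, tolerance = 1e-12)

  # a class never predicted gets F1 = 0
  ls3 <- label_sequence(c(0, 1, 0, 1), c("a", "b"))
  r3 <- f1_report(c(0, 0, 0, 0), ls3)
  expect_equal(r3$per_class$f1[2], 0)

  expect_error(f1_report(c(0, 1), label_sequence(c(-1, -1), c("a", "b"))),
               "empty labeled set")
})

test_that("confusion matrix conserves labeled frame counts and permutes", {
  set.seed(81)
  y <- sample(0:2, 300, replace = TRUE)
  y[sample(300, 40)] <- SEG_UNLABELED
  p <- sample(0:2, 300, replace = TRUE)
  ls <- label_sequence(y, c("a", "b", "c"))
  r <- f1_report(p, ls)
  expect_equal(unname(rowSums(r$confusion)), tabulate(y[y >= 0] + 1L, 3))

  # permuting class identities permutes the report consistently
  perm <- c(2L, 0L, 1L) # class k -> perm[k+1]
  y2 <- y
  y2[y >= 0] <- perm[y[y >= 0] + 1L]
  p2 <- perm[p + 1L]
  r2 <- f1_report(p2, label_sequence(y2, c("a", "b", "c")))
  expect_equal(sort(r$per_class$f1), sort(r2$per_class$f1), tolerance = 1e-12)
  expect_equal(r$macro_f1, r2$macro_f1, tolerance = 1e-12)
})

test_that("entropy report matches hand computation and bounds", {
  # one-hot rows: entropy 0; uniform rows: log K
  probs <- rbind(c(1, 0, 0, 0, 0), rep(0.2, 5))
  ls <- label_sequence(c(0L, 0L), rep(letters[1:5]))
  er <- entropy_report(probs, c(0L, 0L), ls)
  # both frames predicted class a with label a -> TP mean over {0, log 5}
  expect_equal(er$tp_entropy[1], mean(c(0, log(5))), tolerance = 1e-12)

  # six-frame toy case, hand computed
  cp <- rbind(c(0.9, 0.1), c(0.6, 0.4), c(0.5, 0.5),
              c(0.8, 0.2), c(0.3, 0.7), c(0.45, 0.55))
  pred <- c(0L, 0L, 0L, 0L, 1L, 1L)
  labs <- label_sequence(c(0L, 0L, 1L, 1L, 1L, 0L), c("a", "b"))
  h <- function(p) -sum(p * log(p))
  er2 <- entropy_report(cp, pred, labs)
  expect_equal(er2$tp_entropy[1], mean(c(h(cp[1, ]), h(cp[2, ]))), tolerance = 1e-12)
  expect_equal(er2$fp_entropy[1], mean(c(h(cp[3, ]), h(cp[4, ]))), tolerance = 1e-12)
  expect_equal(er2$tp_entropy[2], h(cp[5, ]), tolerance = 1e-12)
  expect_equal(er2$fp_entropy[2], h(cp[6, ]), tolerance = 1e-12)
  expect_true(all(er2$tp_entropy >= 0 & er2$tp_entropy <= log(2) + 1e-12))

  # empty sets are reported as absent (NA), not zero
  er3 <- entropy_report(cp[1:2, ], c(0L, 0L), label_sequence(c(0L, 0L), c("a", "b")))
  expect_true(is.na(er3$fp_entropy[1]))
  expect_true(is.na(er3$tp_entropy[2]))
})

test_that("majority-overlap state matching follows the count table", {
  # states s1, s2 over classes (A, B) with overlaps {s1: (10, 2), s2: (0, 7)}
  y <- c(rep(0L, 10), rep(1L, 2), rep(1L, 7))
  s <- c(rep(1L, 12), rep(2L, 7))
  map <- match_states(s, label_sequence(y, c("A", "B")))
  expect_equal(unname(map[c("1", "2")]), c(0L, 1L))

  # ties break to the lowest class index
  y2 <- c(0L, 1L)
  map2 <- match_states(c(5L, 5L), label_sequence(y2, c("A", "B")))
  expect_equal(unname(map2["5"]), 0L)

  # a state never seen on labeled frames is unmatched
  y3 <- c(0L, SEG_UNLABELED)
  map3 <- match_states(c(1L, 9L), label_sequence(y3, c("A", "B")))
  expect_equal(unname(map3["9"]), STATE_UNMATCHED)

  mapped <- apply_state_map(c(1L, 9L, 1L), map3)
  expect_equal(mapped, c(0L, STATE_UNMATCHED, 0L))
})

test_that("homogeneity matches direct entropy computation", {
  # pure clusters
  expect_equal(homogeneity(c(1, 1, 2, 2), c(0, 0, 1, 1)), 1)
  # one cluster with two equal classes
  expect_equal(homogeneity(c(1, 1, 1, 1), c(0, 0, 1, 1)), 0)
  # counts [[3, 1], [1, 3]]
  cl <- c(rep(1, 4), rep(2, 4))
  cs <- c(0, 0, 0, 1, 0, 1, 1, 1)
  h_cond <- -(3 / 4 * log(3 / 4) + 1 / 4 * log(1 / 4))
  expect_equal(homogeneity(cl, cs), 1 - h_cond / log(2), tolerance = 1e-12)
  # invariant to relabeling the cluster ids
  expect_equal(homogeneity(c(7, 7, 3, 3), c(0, 0, 1, 1)),
               homogeneity(c(1, 1, 2, 2), c(0, 0, 1, 1)))
  # degenerate class distribution
  expect_equal(homogeneity(c(1, 2), c(0, 0)), 1)
})

test_that("k-means latent scores behave at the extremes", {
  set.seed(82)
  y <- rep(0:2, each = 50)
  ls <- label_sequence(y, c("a", "b", "c"))
  onehot <- one_hot_rows(y, 3)
  sc <- latent_cluster_scores(onehot, ls, cluster_counts = 3, seed = 5)
  expect_equal(sc$homogeneity, 1)

  noise <- matrix(rnorm(3000 * 2), 3000, 2)
  yl <- label_sequence(sample(0:2, 3000, replace = TRUE), c("a", "b", "c"))
  sc2 <- latent_cluster_scores(noise, yl, cluster_counts = 3, seed = 5)
  expect_lt(sc2$homogeneity, 0.05)

  # duplicating every point leaves the score unchanged
  sc3 <- latent_cluster_scores(rbind(onehot, onehot),
                               label_sequence(c(y, y), c("a", "b", "c")),
                               cluster_counts = 3, seed = 5)
  expect_equal(sc3$homogeneity, sc$homogeneity, tolerance = 1e-12)

  expect_error(latent_cluster_scores(onehot, ls, cluster_counts = 1000),
               "exceeds")
})
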