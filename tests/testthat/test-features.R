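test_that("plain feature CSV round trip preserves values", {
  m <- matrix(rnorm(15), 5, 3)
  p <- withr::local_tempfile(fileext = ".csv")
  write_features(feature_sequence(m, 70, c("a", "b", "c")), p)
  fs <- read_features(p, "plain", frame_rate_hz = 70)
  expect_equal(fs$values, m, ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(fs$feature_names, c("a", "b", "c"))
  expect_equal(nrow(fs$values), 5L)
})

test_that("plain dialect rejects bad files", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines("a,b", p)
  expect_error(read_features(p, "plain"), "no data rows")
  writeLines(c("a,b", "1,x"), p)
  expect_error(read_features(p, "plain"), "non-numeric")
  expect_error(read_features(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("DeepLabCut dialect drops likelihood columns and keeps order", {
  p <- withr::local_tempfile(fileext = ".csv")
  n_kp <- 8
  hdr1 <- paste(c("scorer", rep("model", 3 * n_kp)), collapse = ",")
  hdr2 <- paste(c("bodyparts", rep(paste0("kp", 1:n_kp), each = 3)), collapse = ",")
  hdr3 <- paste(c("coords", rep(c("x", "y", "likelihood"), n_kp)), collapse = ",")
  rows <- vapply(1:4, function(i) {
    paste(c(i - 1, rep(c(i, 10 * i, 0.99), n_kp)), collapse = ",")
  }, "")
  writeLines(c(hdr1, hdr2, hdr3, rows), p)
  fs <- read_features(p, "dlc")
  expect_equal(ncol(fs$values), 2L * n_kp)
  expect_false(any(grepl("likelihood", fs$feature_names)))
  expect_equal(fs$feature_names[1:2], c("kp1_x", "kp1_y"))
  expect_equal(fs$values[2, 1:2], c(kp1_x = 2, kp1_y = 20))

  writeLines(c(hdr1, hdr2), p)
  expect_error(read_features(p, "dlc"), "fewer than 3")
})

test_that("add_velocity appends zero-padded first differences", {
  fs <- feature_sequence(rbind(c(1, 1), c(2, 3)), feature_names = c("u", "v"))
  out <- add_velocity(fs)
  expect_equal(unname(out$values), rbind(c(1, 1, 0, 0), c(2, 3, 1, 2)))
  expect_equal(out$feature_names, c("u", "v", "u_vel", "v_vel"))

  const <- add_velocity(feature_sequence(matrix(5, 10, 3)))
  expect_true(all(const$values[, 4:6] == 0))

  set.seed(9)
  base <- matrix(rnorm(32), 2, 16)
  wide <- add_velocity(feature_sequence(base))
  expect_equal(ncol(wide$values), 32L)
  # dropping the velocity block recovers the input exactly
  expect_identical(unname(wide$values[, 1:16]), base)
})

test_that("label reading maps sentinels and validates the class range", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("label", "0", "1", "-1", "2"), p)
  ls <- read_labels(p, c("a", "b", "c"))
  expect_equal(labeled_frames(ls), c(1L, 2L, 4L))
  expect_equal(unlabeled_frames(ls), 3L)

  writeLines(c("-1", "-1"), p)
  expect_length(labeled_frames(read_labels(p, c("a", "b", "c"))), 0L)

  writeLines(c("5"), p)
  expect_error(read_labels(p, c("a", "b", "c")), "outside")
  writeLines(c("0.5"), p)
  expect_error(read_labels(p, c("a", "b", "c")), "non-integer")
})

test_that("background frames are unlabeled for training purposes", {
  ls <- label_sequence(c(0L, SEG_BACKGROUND, 1L, SEG_UNLABELED), c("a", "b"))
  expect_equal(labeled_frames(ls), c(1L, 3L))
  expect_equal(unlabeled_frames(ls), c(2L, 4L))
})

test_that("latent dimension selection follows the explained-variance rule", {
  set.seed(3)
  # exact rank-2 data embedded in 5 dimensions
  basis <- matrix(rnorm(10), 5, 2)
  low <- matrix(rnorm(400), 200, 2) %*% t(basis)
  expect_equal(choose_latent_dim(feature_sequence(low)), 2L)

  # five i.i.d. columns of equal variance: four components explain ~0.8 < 0.95
  iid <- matrix(rnorm(5000 * 5), 5000, 5)
  expect_equal(choose_latent_dim(feature_sequence(iid)), 5L)

  # one dominant column
  dom <- cbind(rnorm(500, 0, 20), matrix(rnorm(1000, 0, 0.1), 500, 2))
  expect_equal(choose_latent_dim(feature_sequence(dom)), 1L)

  # monotone in the threshold
  d_lo <- choose_latent_dim(feature_sequence(iid), 0.5)
  d_hi <- choose_latent_dim(feature_sequence(iid), 0.99)
  expect_lte(d_lo, d_hi)

  expect_error(choose_latent_dim(feature_sequence(matrix(1, 10, 2) + 0)), "zero total variance")
})

test_that("standardization is invertible and stored statistics apply elsewhere", {
  set.seed(4)
  fs <- feature_sequence(matrix(rnorm(60, 5, 3), 20, 3))
  std <- fit_standardizer(fs)
  z <- apply_standardizer(fs, std)
  expect_equal(colMeans(z$values), rep(0, 3), ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(apply(z$values, 2, sd), rep(1, 3), ignore_attr = TRUE, tolerance = 1e-12)
})
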