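# Behavioral feature and label containers, file IO, and feature engineering:
# velocity concatenation and PCA-based choice of the continuous latent
# dimension.

#' Sentinel label values
#'
#' Frames labeled `-1` are unlabeled; frames labeled `-2` carry a background
#' ("other") annotation. Background frames are treated as unlabeled by every
#' objective and metric: models are never trained or scored on them.
#'
#' @export
SEG_UNLABELED <- -1L

#' @rdname SEG_UNLABELED
#' @export
SEG_BACKGROUND <- -2L

#' Per-session feature matrix
#'
#' Container for one session's T x D matrix of per-frame behavioral features
#' (pose coordinates, derived quantities, or inertial measurements), the
#' acquisition frame rate, and per-column names.
#'
#' @param values numeric T x D matrix, finite entries
#' @param frame_rate_hz positive acquisition rate in Hz
#' @param feature_names optional character vector of D unique names
#' @param session_id identifier string
#' @return an object of class `feature_sequence`
#' @export
feature_sequence <- function(values, frame_rate_hz = 1, feature_names = NULL,
                             session_id = "session") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L) stop("values must be a non-empty matrix")
  if (!all(is.finite(values))) stop("non-finite feature values")
  if (!is.numeric(frame_rate_hz) || frame_rate_hz <= 0) stop("frame_rate_hz must be positive")
  if (is.null(feature_names)) {
    feature_names <- colnames(values) %||% paste0("f", seq_len(ncol(values)))
  }
  if (length(feature_names) != ncol(values)) stop("feature_names length must equal D")
  if (anyDuplicated(feature_names)) stop("feature_names must be unique")
  colnames(values) <- feature_names
  structure(
    list(values = values, frame_rate_hz = frame_rate_hz,
         feature_names = feature_names, session_id = session_id),
    class = "feature_sequence"
  )
}

#' @export
print.feature_sequence <- function(x, ...) {
  cat(sprintf("<feature_sequence '%s': %d frames x %d features @ %g Hz>\n",
              x$session_id, nrow(x$values), ncol(x$values), x$frame_rate_hz))
  invisible(x)
}

#' Per-frame discrete behavior labels
#'
#' Integer labels in `0..K-1` plus the sentinels [SEG_UNLABELED] and
#' [SEG_BACKGROUND]. The labeled set is the frames carrying a class in
#' `0..K-1`; background frames belong to the unlabeled set for all training
#' objectives.
#'
#' @param labels integer vector
#' @param class_names character vector of K class names
#' @return an object of class `label_sequence`
#' @export
label_sequence <- function(labels, class_names) {
  labels <- as.integer(labels)
  K <- length(class_names)
  if (K < 1L) stop("need at least one class")
  bad <- labels[!(labels %in% c(SEG_UNLABELED, SEG_BACKGROUND)) &
                  (labels < 0L | labels >= K)]
  if (length(bad)) {
    stop(sprintf("label value %d outside 0..%d and not a sentinel", bad[1L], K - 1L))
  }
  structure(list(labels = labels, class_names = class_names, K = K),
            class = "label_sequence")
}

#' @export
print.label_sequence <- function(x, ...) {
  cat(sprintf("<label_sequence: %d frames, K=%d, %d labeled, %d background>\n",
              length(x$labels), x$K, length(labeled_frames(x)),
              sum(x$labels == SEG_BACKGROUND)))
  invisible(x)
}

#' Labeled / unlabeled frame index sets
#'
#' @param ls a [label_sequence()]
#' @return integer frame indices (1-based)
#' @export
labeled_frames <- function(ls) which(ls$labels >= 0L)

#' @rdname labeled_frames
#' @export
unlabeled_frames <- function(ls) which(ls$labels < 0L)

#' Read a feature CSV
#'
#' Two dialects are supported. `"plain"` is a single header row followed by
#' T x D numeric rows. `"dlc"` is the DeepLabCut pose export with three header
#' rows (scorer / bodyparts / coords) and x, y, likelihood triplets per
#' keypoint; likelihood columns are dropped, so D equals twice the number of
#' keypoints, and column order is preserved.
#'
#' @param path CSV file path
#' @param dialect `"plain"` or `"dlc"`
#' @param frame_rate_hz acquisition rate stored on the result
#' @param session_id session identifier (defaults to the file name)
#' @return a [feature_sequence()]
#' @export
read_features <- function(path, dialect = c("plain", "dlc"), frame_rate_hz = 1,
                          session_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("feature file not found: %s", path))
  session_id <- session_id %||% sub("\\.[^.]*$", "", basename(path))
  if (dialect == "plain") {
    df <- utils::read.csv(path, header = TRUE, check.names = FALSE)
    if (nrow(df) == 0L) stop("no data rows in feature file")
    m <- as.matrix(df)
    if (!is.numeric(m)) stop("non-numeric cell in feature file")
    return(feature_sequence(m, frame_rate_hz, colnames(df), session_id))
  }
  hdr <- readLines(path, n = 3L)
  if (length(hdr) < 3L) stop("malformed DeepLabCut header: fewer than 3 header rows")
  split1 <- strsplit(hdr, ",", fixed = TRUE)
  bodyparts <- split1[[2L]]
  coords <- split1[[3L]]
  if (!grepl("scorer", split1[[1L]][1L], ignore.case = TRUE) ||
      !grepl("coords", coords[1L], ignore.case = TRUE)) {
    stop("malformed DeepLabCut header: expected scorer/bodyparts/coords rows")
  }
  df <- utils::read.csv(path, header = FALSE, skip = 3L)
  if (nrow(df) == 0L) stop("no data rows in feature file")
  # first column is the frame index
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cell in feature file")
  coords <- coords[-1L]
  bodyparts <- bodyparts[-1L]
  if (length(coords) != ncol(m)) stop("malformed DeepLabCut header: column count mismatch")
  keep <- tolower(coords) != "likelihood"
  if (!any(keep)) stop("malformed DeepLabCut header: no coordinate columns")
  m <- m[, keep, drop = FALSE]
  nms <- paste(bodyparts[keep], coords[keep], sep = "_")
  feature_sequence(m, frame_rate_hz, nms, session_id)
}

#' Write a feature CSV (plain dialect)
#'
#' @param fs a [feature_sequence()]
#' @param path output CSV path
#' @export
write_features <- function(fs, path) {
  df <- as.data.frame(fs$values)
  names(df) <- fs$feature_names
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Concatenate velocities onto a feature sequence
#'
#' Appends the first difference of every feature column, turning the pose
#' vector x_t into the position-velocity representation
#' `[x_t; x_t - x_(t-1)]`. The first frame's velocity is the zero vector
#' (exact for a still start and keeps T unchanged). Feature names gain a
#' `"_vel"` suffix.
#'
#' @param fs a [feature_sequence()]
#' @return a [feature_sequence()] with 2D columns
#' @export
add_velocity <- function(fs) {
  v <- fs$values
  vel <- rbind(matrix(0, 1L, ncol(v)), diff(v))
  feature_sequence(cbind(v, vel), fs$frame_rate_hz,
                   c(fs$feature_names, paste0(fs$feature_names, "_vel")),
                   fs$session_id)
}

#' Read a per-frame label CSV
#'
#' Expects a single column of integers, one per frame: a class index in
#' `0..K-1`, `-1` for unlabeled, or `-2` for background frames.
#'
#' @param path CSV path (header optional, single column)
#' @param class_names K class names defining the valid label range
#' @return a [label_sequence()]
#' @export
read_labels <- function(path, class_names) {
  if (!file.exists(path)) stop(sprintf("label file not found: %s", path))
  raw <- readLines(path)
  raw <- raw[nzchar(trimws(raw))]
  if (length(raw) && is.na(suppressWarnings(as.numeric(raw[1L])))) raw <- raw[-1L]
  if (!length(raw)) stop("no data rows in label file")
  num <- suppressWarnings(as.numeric(raw))
  if (anyNA(num)) stop("non-integer entry in label file")
  if (any(num != round(num))) stop("non-integer entry in label file")
  label_sequence(as.integer(num), class_names)
}

#' Write a label CSV
#'
#' @param ls a [label_sequence()]
#' @param path output path
#' @export
write_labels <- function(ls, path) {
  utils::write.csv(data.frame(label = ls$labels), path, row.names = FALSE)
  invisible(path)
}

#' Choose the continuous latent dimension by explained variance
#'
#' Returns the smallest number of principal components of the column-centered
#' feature matrix whose cumulative explained variance reaches `threshold`
#' (default 95%), the rule used to size the switching model's continuous
#' latent space.
#'
#' @param fs a [feature_sequence()]
#' @param threshold explained-variance fraction in (0, 1]
#' @return a positive integer latent dimension
#' @export
choose_latent_dim <- function(fs, threshold = 0.95) {
  stopifnot(threshold > 0, threshold <= 1)
  x <- scale(fs$values, center = TRUE, scale = FALSE)
  sv <- svd(x, nu = 0L, nv = 0L)$d
  ev <- sv^2
  tot <- sum(ev)
  if (tot <= 0) stop("zero total variance")
  cum <- cumsum(ev) / tot
  as.integer(which(cum >= threshold - 1e-12)[1L])
}

#' Fit / apply per-column standardization
#'
#' Z-scores each feature column using statistics from a training split;
#' constant columns get unit scale. The fitted statistics are stored with
#' trained models so prediction applies the identical transform.
#'
#' @param fs a [feature_sequence()]
#' @return for `fit_standardizer`, a list with `center` and `scale`
#' @export
fit_standardizer <- function(fs) {
  center <- colMeans(fs$values)
  scl <- apply(fs$values, 2L, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = center, scale = scl)
}

#' @rdname fit_standardizer
#' @param std a fitted standardizer
#' @export
apply_standardizer <- function(fs, std) {
  if (ncol(fs$values) != length(std$center)) {
    stop(sprintf("features have %d columns but the standardizer was fitted on %d",
                 ncol(fs$values), length(std$center)))
  }
  v <- sweep(sweep(fs$values, 2L, std$center), 2L, std$scale, "/")
  feature_sequence(v, fs$frame_rate_hz, fs$feature_names, fs$session_id)
}
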