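#' Labeled classification datasets
#'
#' A `labeled_dataset` stores `samples` (one row per example, values in
#' [0, 1]), integer `labels` in `0 .. n_classes - 1`, and a `split` tag
#' (`"train"` / `"validation"`) per row.
#'
#' @param samples Numeric matrix, values in [0, 1].
#' @param labels Integer vector of class labels (0-based).
#' @param split Character vector of `"train"` / `"validation"` tags.
#' @return Object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(samples, labels, split) {
  samples <- as.matrix(samples)
  if (nrow(samples)) {
    if (min(samples) < 0 || max(samples) > 1) {
      stop_invalid("sample values must lie in [0, 1]")
    }
  }
  stopifnot(length(labels) == nrow(samples), length(split) == nrow(samples))
  structure(list(samples = samples, labels = as.integer(labels),
                 split = as.character(split)),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d x %d, %d classes (%d train / %d validation)\n",
              nrow(x$samples), ncol(x$samples),
              length(unique(x$labels)),
              sum(x$split == "train"), sum(x$split == "validation")))
  invisible(x)
}

#' Subset a dataset by split
#' @param dataset A [labeled_dataset()].
#' @param split `"train"` or `"validation"`.
#' @return List with `x` (matrix) and `y` (labels).
#' @export
dataset_split <- function(dataset, split = c("train", "validation")) {
  split <- match.arg(split)
  keep <- dataset$split == split
  list(x = dataset$samples[keep, , drop = FALSE], y = dataset$labels[keep])
}

#' Generate a prototype-plus-noise classification task
#'
#' Synthetic stand-in for a normalized image-classification dataset with
#' the same interface: `dim`-dimensional inputs in [0, 1] and `n_classes`
#' classes. Each class gets a random prototype in `[0, 1]^dim`; samples are
#' the prototype plus isotropic Gaussian noise, clipped back to [0, 1].
#' `noise_sd` controls the task difficulty (0 makes the task separable by a
#' nearest-prototype rule with accuracy 1). The split is stratified:
#' one sixth of each class (rounded) goes to validation, the rest to
#' training.
#'
#' @param n_per_class Samples per class.
#' @param noise_sd Noise standard deviation (default 0.3).
#' @param seed Integer seed; identical seed, identical dataset.
#' @param dim Input dimension (default 784).
#' @param n_classes Number of classes (default 10).
#' @return A [labeled_dataset()]; the class prototypes are attached as
#'   attribute `"prototypes"` (`n_classes` x `dim`).
#' @export
generate_classification_dataset <- function(n_per_class, noise_sd = 0.3,
                                            seed = NULL, dim = 784L,
                                            n_classes = 10L) {
  if (n_per_class < 1) stop_invalid("n_per_class must be >= 1")
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  with_seed(seed, {
    protos <- matrix(stats::runif(n_classes * dim), n_classes, dim)
    n <- n_per_class * n_classes
    labels <- rep(seq_len(n_classes) - 1L, each = n_per_class)
    x <- protos[labels + 1L, , drop = FALSE] +
      matrix(stats::rnorm(n * dim, 0, noise_sd), n, dim)
    x <- pmin(pmax(x, 0), 1)
    n_val <- round(n_per_class / 6)
    split <- rep("train", n)
    # per class, the last n_val samples go to validation
    for (k in seq_len(n_classes)) {
      rows <- which(labels == k - 1L)
      if (n_val > 0) split[utils::tail(rows, n_val)] <- "validation"
    }
    perm <- sample.int(n)
    out <- labeled_dataset(x[perm, , drop = FALSE], labels[perm], split[perm])
    attr(out, "prototypes") <- protos
    out
  })
}

#' Nearest-prototype classification accuracy
#'
#' Reference classifier for the synthetic task: assigns each sample to the
#' class of the closest prototype (Euclidean). Used as an independent
#' difficulty oracle for trained networks.
#' @param dataset A dataset from [generate_classification_dataset()].
#' @param split Which split to score.
#' @return Accuracy in [0, 1].
#' @export
prototype_accuracy <- function(dataset, split = "validation") {
  protos <- attr(dataset, "prototypes")
  if (is.null(protos)) stop_config("dataset carries no prototypes")
  d <- dataset_split(dataset, split)
  # squared distances to each prototype
  d2 <- outer(rowSums(d$x^2), rowSums(protos^2), "+") -
    2 * d$x %*% t(protos)
  pred <- max.col(-d2, ties.method = "first") - 1L
  mean(pred == d$y)
}

.read_idx <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  dtype <- bitwAnd(bitwShiftR(magic, 8L), 0xFF)
  ndim <- bitwAnd(magic, 0xFF)
  if (bitwAnd(bitwShiftR(magic, 16L), 0xFFFF) != 0L || dtype != 0x08) {
    stop_format("not an unsigned-byte IDX file: bad magic number")
  }
  dims <- readBin(con, "integer", n = ndim, size = 4L, endian = "big")
  n <- prod(dims)
  data <- if (n > 0) {
    as.integer(readBin(con, "raw", n = n))
  } else integer()
  list(dims = dims, data = data)
}

#' Read an IDX (MNIST-format) dataset from local files
#'
#' Parses the unsigned-byte IDX format used by the MNIST family. Pixel
#' values are scaled by 1/255 into [0, 1]. Files are never downloaded.
#'
#' @param images_path Path to the IDX image file (3-dimensional:
#'   items x rows x cols).
#' @param labels_path Path to the IDX label file (1-dimensional).
#' @param validation_fraction Fraction of items tagged `"validation"`
#'   (taken from the end; default 1/6).
#' @return A [labeled_dataset()].
#' @export
load_idx_dataset <- function(images_path, labels_path,
                             validation_fraction = 1 / 6) {
  img <- .read_idx(images_path)
  lab <- .read_idx(labels_path)
  if (length(img$dims) != 3L) stop_format("image file must be 3-dimensional")
  if (length(lab$dims) != 1L) stop_format("label file must be 1-dimensional")
  n <- img$dims[1L]
  if (lab$dims[1L] != n) stop_format("image/label item counts differ")
  d <- img$dims[2L] * img$dims[3L]
  x <- matrix(img$data, nrow = n, ncol = d, byrow = TRUE) / 255
  n_val <- round(n * validation_fraction)
  split <- c(rep("train", n - n_val), rep("validation", n_val))
  labeled_dataset(x, lab$data, split)
}

#' Write an IDX fixture file
#'
#' Test/fixture writer for the unsigned-byte IDX format ([load_idx_dataset()]
#' reads it back bit-identically).
#' @param data Integer array values in 0..255 (row-major item order for
#'   images: pass a matrix `items x pixels` with `dims = c(items, r, c)`).
#' @param dims Integer dimensions to record in the header.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_idx <- function(data, dims, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  magic <- bitwOr(bitwShiftL(0x08, 8L), length(dims))
  writeBin(as.integer(magic), con, size = 4L, endian = "big")
  writeBin(as.integer(dims), con, size = 4L, endian = "big")
  if (length(data)) {
    writeBin(as.raw(t(data)), con)
  }
  invisible(path)
}
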