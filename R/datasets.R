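#' Labelled image dataset container
#'
#' Bundles an image stack with true and (possibly corrupted) noisy labels.
#' Images live in `[0,1]` internally; uint8 only on disk.
#'
#' @param images numeric array `N x H x W x C` with intensities in `[0,1]`.
#' @param true_labels integer vector of length `N`, classes in `0..K-1`.
#' @param noisy_labels integer vector of length `N`; defaults to
#'   `true_labels` (no corruption).
#' @param n_classes total number of classes `K` (>= 2).
#' @param split `"train"` or `"test"` tag.
#' @return an object of class `labeled_image_dataset` with fields
#'   `images`, `true_labels`, `noisy_labels`, `n_classes`, `split`.
#' @export
labeled_image_dataset <- function(images, true_labels,
                                  noisy_labels = true_labels,
                                  n_classes = max(true_labels) + 1L,
                                  split = c("train", "test")) {
  split <- match.arg(split)
  if (length(dim(images)) != 4L)
    stop("`images` must be an N x H x W x C array")
  n <- dim(images)[1]
  true_labels <- as.integer(true_labels)
  noisy_labels <- as.integer(noisy_labels)
  n_classes <- as.integer(n_classes)
  if (length(true_labels) != n || length(noisy_labels) != n)
    stop("label/image count mismatch: ", n, " images, ",
         length(true_labels), "/", length(noisy_labels), " labels")
  if (n_classes < 2L) stop("need at least 2 classes")
  if (n > 0 && (max(true_labels, noisy_labels) >= n_classes ||
                min(true_labels, noisy_labels) < 0L))
    stop("labels must lie in 0..K-1")
  structure(list(images = images, true_labels = true_labels,
                 noisy_labels = noisy_labels, n_classes = n_classes,
                 split = split),
            class = "labeled_image_dataset")
}

#' @export
print.labeled_image_dataset <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<labeled_image_dataset> %d images %dx%dx%d, %d classes (%s)\n",
              d[1], d[2], d[3], d[4], x$n_classes, x$split))
  nn <- sum(x$noisy_labels != x$true_labels)
  if (nn > 0)
    cat(sprintf("  %d corrupted labels (%.1f%%)\n", nn, 100 * nn / d[1]))
  invisible(x)
}

n_samples <- function(dataset) dim(dataset$images)[1]

#' Flatten an image stack to a feature matrix
#'
#' @param dataset a [labeled_image_dataset()].
#' @return numeric matrix `N x (H*W*C)`.
#' @export
as_image_matrix <- function(dataset) {
  d <- dim(dataset$images)
  matrix(dataset$images, nrow = d[1])
}

# deterministic class appearance: hue-separated base colour plus a
# class-positioned disc in the complementary colour; `separability`
# scales template contrast around mid-grey.
class_template <- function(class, n_classes, image_size) {
  h <- class / n_classes
  base <- grDevices::col2rgb(grDevices::hsv(h, 0.6, 0.75)) / 255
  comp <- grDevices::col2rgb(grDevices::hsv((h + 0.5) %% 1, 0.9, 0.95)) / 255
  g <- seq(0, 1, length.out = image_size)
  xs <- matrix(g, image_size, image_size)
  ys <- t(xs)
  ang <- 2 * pi * class / n_classes
  cx <- 0.5 + 0.22 * cos(ang)
  cy <- 0.5 + 0.22 * sin(ang)
  disc <- (xs - cx)^2 + (ys - cy)^2 < 0.05
  tmpl <- array(0, dim = c(image_size, image_size, 3))
  for (ch in 1:3) {
    plane <- matrix(base[ch], image_size, image_size)
    plane[disc] <- comp[ch]
    if (class %% 2L == 1L)   # odd classes carry a texture band
      plane <- plane * (0.9 + 0.1 * sin(2 * pi * (class + 2) * ys))
    tmpl[, , ch] <- plane
  }
  tmpl
}

#' Generate a synthetic labelled image dataset
#'
#' Each class has a distinct parametric appearance (class-specific base
#' colour, a geometric primitive at a class-specific position, and a
#' texture band for odd classes) perturbed by per-sample translation,
#' brightness jitter and Gaussian pixel noise.  `separability` scales
#' the template contrast around mid-grey: at 1.0 a small trainable
#' backbone reaches >= 95% clean-label test accuracy.
#'
#' @param n_classes number of classes (>= 2).
#' @param n_per_class samples per class.
#' @param image_size side length in pixels (>= 8).
#' @param separability template contrast multiplier (> 0).
#' @param seed integer RNG seed; the generator is deterministic given it.
#' @param split `"train"` or `"test"`.
#' @param noise_sd pixel noise standard deviation.
#' @return a [labeled_image_dataset()].
#' @export
generate_synthetic_dataset <- function(n_classes, n_per_class,
                                       image_size = 32, separability = 1.0,
                                       seed = 1L, split = "train",
                                       noise_sd = 0.06) {
  if (n_classes < 2L) stop("n_classes must be >= 2")
  if (image_size < 8L) stop("image_size must be >= 8")
  if (n_per_class < 1L) stop("n_per_class must be >= 1")
  if (separability <= 0) stop("separability must be > 0")
  n <- n_classes * n_per_class
  labels <- rep(0:(n_classes - 1L), each = n_per_class)
  templates <- lapply(0:(n_classes - 1L), class_template,
                      n_classes = n_classes, image_size = image_size)
  imgs <- array(0, dim = c(n, image_size, image_size, 3))
  max_shift <- max(1L, round(0.1 * image_size))
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  shifts <- matrix(sample(-max_shift:max_shift, 2 * n, replace = TRUE), n, 2)
  bright <- stats::runif(n, -0.1, 0.1)
  for (i in seq_len(n)) {
    tmpl <- roll2d(templates[[labels[i] + 1L]], shifts[i, 1], shifts[i, 2])
    x <- 0.5 + separability * (tmpl - 0.5) + bright[i] +
      stats::rnorm(length(tmpl), 0, noise_sd)
    imgs[i, , , ] <- pmin(pmax(x, 0), 1)
  }
  labeled_image_dataset(imgs, labels, n_classes = n_classes, split = split)
}

# circular shift of the first two axes of an H x W x C array
roll2d <- function(a, dy, dx) {
  d <- dim(a)
  iy <- ((seq_len(d[1]) - 1L - dy) %% d[1]) + 1L
  ix <- ((seq_len(d[2]) - 1L - dx) %% d[2]) + 1L
  a[iy, ix, , drop = FALSE]
}

#' Inject symmetric label noise
#'
#' Corrupts exactly `round(rate * N)` labels chosen uniformly at random;
#' each corrupted label is redrawn uniformly from the `K - 1` other
#' classes, so it never equals the original.  True labels are untouched.
#'
#' @param dataset a [labeled_image_dataset()].
#' @param rate corruption fraction in `[0, 1)`.
#' @param seed integer RNG seed.
#' @return the dataset with updated `noisy_labels`.
#' @export
inject_symmetric_noise <- function(dataset, rate, seed = 1L) {
  stopifnot(inherits(dataset, "labeled_image_dataset"))
  if (rate < 0 || rate >= 1) stop("noise rate must lie in [0, 1)")
  k <- dataset$n_classes
  if (k < 2L) stop("need at least 2 classes to corrupt labels")
  n <- n_samples(dataset)
  m <- round(rate * n)
  if (m == 0L) {
    dataset$noisy_labels <- dataset$true_labels
    return(dataset)
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  idx <- sample.int(n, m)
  noisy <- dataset$true_labels
  # uniform over the K-1 other classes via an offset in 1..K-1
  offs <- sample.int(k - 1L, m, replace = TRUE)
  noisy[idx] <- (dataset$true_labels[idx] + offs) %% k
  dataset$noisy_labels <- noisy
  dataset
}

#' Split a dataset into disjoint class-incremental tasks
#'
#' Task membership follows the noisy label: a sample mislabelled into
#' class 3 appears in the task containing class 3 (noise is injected
#' before the split, so mislabelled samples enter the task their label
#' points to).
#'
#' @param dataset a [labeled_image_dataset()].
#' @param class_partition list of integer vectors of class ids; sets
#'   must be disjoint and reference existing classes.
#' @return object of class `task_sequence`: `tasks` (the class sets) and
#'   `indices` (per-task sample index lists into `dataset`).
#' @export
split_tasks <- function(dataset, class_partition) {
  stopifnot(inherits(dataset, "labeled_image_dataset"))
  classes <- unlist(class_partition)
  if (anyDuplicated(classes))
    stop("task class sets must be disjoint")
  if (any(classes < 0L | classes >= dataset$n_classes))
    stop("task classes must reference existing classes 0..K-1")
  indices <- unname(lapply(class_partition, function(k)
    which(dataset$noisy_labels %in% k)))
  structure(list(tasks = unname(lapply(class_partition, as.integer)),
                 indices = indices),
            class = "task_sequence")
}

#' @export
print.task_sequence <- function(x, ...) {
  cat(sprintf("<task_sequence> %d tasks\n", length(x$tasks)))
  for (t in seq_along(x$tasks))
    cat(sprintf("  task %d: classes {%s}, %d samples\n", t,
                paste(x$tasks[[t]], collapse = ","),
                length(x$indices[[t]])))
  invisible(x)
}

subset_dataset <- function(dataset, idx) {
  labeled_image_dataset(dataset$images[idx, , , , drop = FALSE],
                        dataset$true_labels[idx],
                        dataset$noisy_labels[idx],
                        n_classes = dataset$n_classes,
                        split = dataset$split)
}

#' Write / read an image stream as an NPZ archive
#'
#' The archive follows the MedMNIST key convention: `train_images`,
#' `train_labels`, `test_images`, `test_labels`, with images stored as
#' uint8 `N x H x W x C` stacks and labels as integer column vectors.
#' When the training split carries corrupted labels the additional key
#' `train_true_labels` preserves provenance; on read it defaults to the
#' stored labels when absent.
#'
#' @param stream a list with elements `train` and `test`, each a
#'   [labeled_image_dataset()].
#' @param path output `.npz` path.
#' @return `path`, invisibly (writer); the stream list (reader).
#' @export
write_npz_dataset <- function(stream, path) {
  stopifnot(inherits(stream$train, "labeled_image_dataset"),
            inherits(stream$test, "labeled_image_dataset"))
  to_u8 <- function(img) {
    a <- round(img * 255)
    attr(a, "npy_dtype") <- "u1"
    a
  }
  col <- function(v) {
    m <- matrix(as.integer(v), ncol = 1)
    attr(m, "npy_dtype") <- "i4"
    m
  }
  arrays <- list(train_images = to_u8(stream$train$images),
                 train_labels = col(stream$train$noisy_labels),
                 test_images = to_u8(stream$test$images),
                 test_labels = col(stream$test$noisy_labels))
  if (any(stream$train$noisy_labels != stream$train$true_labels))
    arrays$train_true_labels <- col(stream$train$true_labels)
  write_npz(arrays, path)
  invisible(path)
}

#' @rdname write_npz_dataset
#' @export
read_npz_dataset <- function(path) {
  a <- read_npz(path)
  need <- c("train_images", "train_labels", "test_images", "test_labels")
  miss <- setdiff(need, names(a))
  if (length(miss))
    stop("NPZ archive missing keys: ", paste(miss, collapse = ", "))
  k <- max(a$train_labels, a$test_labels) + 1L
  mk <- function(imgs, labels, true_labels = labels, split) {
    if (length(dim(imgs)) == 3L)          # greyscale: add channel axis
      dim(imgs) <- c(dim(imgs), 1L)
    labeled_image_dataset(imgs / 255, as.vector(true_labels),
                          as.vector(labels), n_classes = k, split = split)
  }
  true_tr <- if (!is.null(a$train_true_labels)) a$train_true_labels
             else a$train_labels
  list(train = mk(a$train_images, a$train_labels, true_tr, "train"),
       test = mk(a$test_images, a$test_labels, split = "test"))
}

#' Generate a full synthetic class-incremental stream
#'
#' Convenience wrapper: train and test splits from the same class
#' templates, symmetric noise on the training labels only (test labels
#' are never corrupted), and a disjoint task split.
#'
#' @inheritParams generate_synthetic_dataset
#' @param n_test_per_class test samples per class.
#' @param noise_rate symmetric corruption fraction for the train split.
#' @param class_partition list of class-id sets, one per task; default
#'   splits classes into consecutive pairs.
#' @return list with `train`, `test`, `tasks` (a `task_sequence`).
#' @export
synthetic_stream <- function(n_classes = 8, n_per_class = 200,
                             n_test_per_class = 50, image_size = 32,
                             separability = 1.0, noise_rate = 0,
                             class_partition = NULL, seed = 1L) {
  if (is.null(class_partition)) {
    if (n_classes %% 2L != 0L)
      stop("default partition needs an even class count")
    class_partition <- split(0:(n_classes - 1L),
                             rep(seq_len(n_classes / 2L), each = 2L))
  }
  train <- generate_synthetic_dataset(n_classes, n_per_class, image_size,
                                      separability, seed = seed,
                                      split = "train")
  test <- generate_synthetic_dataset(n_classes, n_test_per_class, image_size,
                                     separability, seed = seed + 900001L,
                                     split = "test")
  if (noise_rate > 0)
    train <- inject_symmetric_noise(train, noise_rate, seed = seed + 37L)
  list(train = train, test = test,
       tasks = split_tasks(train, class_partition))
}

#' Export a label manifest as CSV
#'
#' Columns: `index`, `true_label`, `noisy_label`, `task` (NA for samples
#' outside every task).
#'
#' @param dataset a [labeled_image_dataset()].
#' @param tasks a `task_sequence` from [split_tasks()].
#' @param path output CSV path.
#' @export
write_label_manifest <- function(dataset, tasks, path) {
  n <- n_samples(dataset)
  task_of <- rep(NA_integer_, n)
  for (t in seq_along(tasks$indices)) task_of[tasks$indices[[t]]] <- t
  utils::write.csv(data.frame(index = seq_len(n),
                              true_label = dataset$true_labels,
                              noisy_label = dataset$noisy_labels,
                              task = task_of),
                   path, row.names = FALSE)
  invisible(path)
}
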