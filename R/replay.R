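#' Compose a mixed-origin training batch
#'
#' Draws `batch_size` samples uniformly from the union of the current
#' task's clean subset and the replay buffer; with an empty buffer
#' (task 1) the batch is purely current-task.  Labels are one-hot over
#' the full unified class space.
#'
#' @param clean_x feature matrix of the clean subset (may have 0 rows).
#' @param clean_labels 0-based labels of the clean subset.
#' @param buffer_x feature matrix of buffer samples (may have 0 rows).
#' @param buffer_labels 0-based labels of buffer samples.
#' @param batch_size batch size (>= 2).
#' @param n_classes total class count (one-hot width).
#' @return list with `x`, `y` (one-hot matrix), `labels`, and `source`
#'   (`"current"` / `"memory"` per row).
#' @export
compose_batch <- function(clean_x, clean_labels, buffer_x, buffer_labels,
                          batch_size, n_classes) {
  if (batch_size < 2) stop("batch_size must be >= 2")
  n_c <- if (is.null(clean_x)) 0L else nrow(clean_x)
  n_b <- if (is.null(buffer_x)) 0L else nrow(buffer_x)
  if (n_c + n_b == 0L) stop("both sample sources are empty")
  pick <- sample.int(n_c + n_b, batch_size, replace = batch_size > n_c + n_b)
  from_buf <- pick > n_c
  x <- matrix(0, batch_size, if (n_c) ncol(clean_x) else ncol(buffer_x))
  labels <- integer(batch_size)
  if (any(!from_buf)) {
    x[!from_buf, ] <- clean_x[pick[!from_buf], , drop = FALSE]
    labels[!from_buf] <- clean_labels[pick[!from_buf]]
  }
  if (any(from_buf)) {
    x[from_buf, ] <- buffer_x[pick[from_buf] - n_c, , drop = FALSE]
    labels[from_buf] <- buffer_labels[pick[from_buf] - n_c]
  }
  list(x = x, y = one_hot(labels, n_classes), labels = labels,
       source = ifelse(from_buf, "memory", "current"))
}

#' Draw a mixup interpolation weight
#'
#' `lambda ~ Beta(alpha, alpha)` folded to `lambda' = max(lambda,
#' 1 - lambda)`, so the mixed sample is always dominated by its anchor
#' element (`lambda' >= 0.5`).
#'
#' @param alpha Beta concentration (> 0).
#' @return list with `lambda` and `lambda_prime`.
#' @export
sample_lambda <- function(alpha) {
  if (alpha <= 0) stop("alpha must be > 0")
  l <- stats::rbeta(1, alpha, alpha)
  list(lambda = l, lambda_prime = max(l, 1 - l))
}

#' Mix two samples and their labels
#'
#' Convex combination `x' = lambda' * x_i + (1 - lambda') * x_j` and the
#' same for the (probability-vector) labels, producing a virtual sample
#' with a soft label.
#'
#' @param x_i,x_j images or feature rows of identical shape.
#' @param y_i,y_j probability vectors (or matrices) over the same class
#'   space.
#' @param lambda_prime anchor weight in `[0.5, 1]` (see
#'   [sample_lambda()]).
#' @return list of class `mixup_draw` with `x`, `y`, `lambda_prime`.
#' @export
mixup_pair <- function(x_i, y_i, x_j, y_j, lambda_prime) {
  if (!identical(dim(x_i), dim(x_j)) || length(x_i) != length(x_j))
    stop("image shape mismatch in mixup pair")
  if (length(y_i) != length(y_j))
    stop("label space mismatch in mixup pair")
  structure(list(x = lambda_prime * x_i + (1 - lambda_prime) * x_j,
                 y = lambda_prime * y_i + (1 - lambda_prime) * y_j,
                 lambda_prime = lambda_prime),
            class = "mixup_draw")
}

#' Soft-label cross-entropy
#'
#' `-sum_c y'_c log p_c` averaged over the batch, with a probability
#' floor before the logarithm.
#'
#' @param probs `N x K` predicted probabilities.
#' @param y_soft `N x K` soft labels.
#' @return scalar loss.
#' @export
mix_loss <- function(probs, y_soft) {
  if (!is.matrix(probs)) probs <- matrix(probs, nrow = 1)
  if (!is.matrix(y_soft)) y_soft <- matrix(y_soft, nrow = 1)
  stopifnot(identical(dim(probs), dim(y_soft)))
  -mean(rowSums(y_soft * log(pmax(probs, 1e-12))))
}

#' Combined replay objective
#'
#' `L = L_ce + beta * L_mix`; with `beta = 0` the objective reduces to
#' plain experience replay.
#'
#' @param l_ce cross-entropy on the un-mixed composed batch.
#' @param l_mix soft-label cross-entropy on the mixed batch.
#' @param beta mix-loss weight (>= 0).
#' @return scalar combined loss.
#' @export
combined_loss <- function(l_ce, l_mix, beta) {
  if (beta < 0) stop("beta must be >= 0")
  l_ce + beta * l_mix
}
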