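#' Monte-Carlo prediction over augmented copies
#'
#' Averages the model's softmax outputs over the `S` augmented versions
#' of a sample, approximating its posterior class probabilities.
#'
#' @param model a [new_backbone()].
#' @param augmented an `S x H x W x C` array from [augment()].
#' @param classes_seen optional 0-based ids restricting the softmax.
#' @return a probability vector over all classes (sums to 1).
#' @export
mc_predict <- function(model, augmented, classes_seen = NULL) {
  s <- dim(augmented)[1]
  x <- matrix(augmented, nrow = s)
  colMeans(predict_backbone(model, x, classes_seen))
}

#' Augmentation-vote uncertainty
#'
#' Each augmented copy casts a vote for its argmax class; uncertainty is
#' one minus the modal vote fraction, so full agreement gives 0 and the
#' most dispersed vote over `S` copies gives `1 - 1/S`.
#'
#' @param probs an `S x K` matrix of per-augmentation class
#'   probabilities (rows on the simplex).
#' @return object of class `uncertainty_estimate`: `votes` (length `K`,
#'   summing to `S`), `uncertainty` in `[0, 1 - 1/S]`, and `mc_probs`
#'   (the Monte-Carlo averaged probabilities).
#' @export
vote_uncertainty <- function(probs) {
  if (!is.matrix(probs)) probs <- matrix(probs, nrow = 1)
  s <- nrow(probs)
  k <- ncol(probs)
  winners <- max.col(probs, ties.method = "first")
  votes <- tabulate(winners, nbins = k)
  structure(list(votes = votes,
                 uncertainty = 1 - max(votes) / s,
                 mc_probs = colMeans(probs)),
            class = "uncertainty_estimate")
}

#' Per-sample uncertainties for an image stack
#'
#' @param model a [new_backbone()].
#' @param images an `N x H x W x C` array.
#' @param spec an [augmentation_spec()].
#' @param classes_seen 0-based ids restricting the softmax.
#' @param seed integer seed for the stochastic augmentations.
#' @return numeric vector of uncertainties in `[0, 1 - 1/S]`.
#' @export
sample_uncertainties <- function(model, images, spec, classes_seen = NULL,
                                 seed = 1L) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  n <- dim(images)[1]
  vapply(seq_len(n), function(i) {
    aug <- augment(images[i, , , ], spec)
    p <- predict_backbone(model, matrix(aug, nrow = spec$S), classes_seen)
    vote_uncertainty(p)$uncertainty
  }, numeric(1))
}

#' Interval sampling over the uncertainty spectrum
#'
#' Sorts one class's samples by uncertainty (ties broken by original
#' index) and picks `quota` evenly spaced ranks spanning the full sorted
#' range, so the minimum- and maximum-uncertainty samples are always
#' included when `quota >= 2`.
#'
#' @param uncertainties numeric vector for one class.
#' @param quota number of samples to draw (>= 0).
#' @return integer indices into `uncertainties`; if `quota` exceeds the
#'   class size all indices are returned with attribute
#'   `shortfall = TRUE`.
#' @export
interval_sample <- function(uncertainties, quota) {
  n <- length(uncertainties)
  if (quota <= 0L) return(integer(0))
  ord <- order(uncertainties, seq_len(n))
  if (quota >= n) {
    out <- ord
    if (quota > n) attr(out, "shortfall") <- TRUE
    return(out)
  }
  ranks <- unique(round(seq(1, n, length.out = quota)))
  if (length(ranks) < quota)   # rounding collisions: top up
    ranks <- sort(c(ranks, setdiff(seq_len(n), ranks)[
      seq_len(quota - length(ranks))]))
  ord[ranks]
}

#' Fixed-capacity class-balanced replay buffer
#'
#' Stores `(image, label, uncertainty)` triples with an equal per-class
#' quota of `floor(capacity / classes seen)`; leftover slots go one each
#' to the earliest-seen classes.  Recorded-at-insertion uncertainties
#' are kept so quota shrinkage can re-apply interval sampling without a
#' forward pass.
#'
#' @param capacity maximum number of stored samples.
#' @return an empty `memory_buffer`.
#' @export
memory_buffer <- function(capacity) {
  stopifnot(capacity >= 1)
  structure(list(capacity = as.integer(capacity), entries = list(),
                 classes_seen = integer(0)),
            class = "memory_buffer")
}

#' @export
print.memory_buffer <- function(x, ...) {
  cat(sprintf("<memory_buffer> %d/%d used, %d classes\n",
              buffer_size(x), x$capacity, length(x$classes_seen)))
  invisible(x)
}

#' @rdname memory_buffer
#' @param buffer a `memory_buffer`.
#' @export
buffer_size <- function(buffer)
  sum(vapply(buffer$entries, function(e) length(e$labels), integer(1)))

buffer_quotas <- function(buffer, classes_seen) {
  k <- length(classes_seen)
  q <- rep(buffer$capacity %/% k, k)
  r <- buffer$capacity %% k
  if (r > 0) q[seq_len(r)] <- q[seq_len(r)] + 1L   # earliest-seen first
  stats::setNames(q, as.character(classes_seen))
}

take_entry <- function(entry, keep) {
  out <- lapply(entry[setdiff(names(entry), "images")],
                function(v) v[keep])
  out$images <- entry$images[keep, , , , drop = FALSE]
  out
}

shrink_entry <- function(entry, quota) {
  if (length(entry$labels) <= quota) return(entry)
  take_entry(entry, interval_sample(entry$uncertainty, quota))
}

#' Update the replay buffer after a task
#'
#' Recomputes per-class quotas over all classes seen so far, shrinks
#' already-stored classes to the new quota by interval sampling over
#' their recorded uncertainties, and fills the new task's classes by
#' interval sampling from the candidate set (normally the clean subset).
#' Classes with fewer candidates than quota keep everything and the
#' spare slots stay unused.
#'
#' @param buffer a [memory_buffer()].
#' @param images candidate `N x H x W x C` array.
#' @param labels candidate 0-based labels (their presumed-clean labels).
#' @param uncertainties candidate uncertainty scores.
#' @param strategy `"uncertainty"` (interval sampling), `"random"`
#'   (uniform without replacement) or `"reservoir"` (single-pass
#'   per-class reservoir).
#' @param seed integer seed (used by the stochastic strategies).
#' @param truth optional logical per candidate (label correctness, known
#'   in synthetic mode); carried with the stored entries so buffer
#'   purity can be reported.
#' @return the updated buffer.
#' @export
update_buffer <- function(buffer, images, labels, uncertainties,
                          strategy = c("uncertainty", "random",
                                       "reservoir"),
                          seed = 1L, truth = NULL) {
  stopifnot(inherits(buffer, "memory_buffer"))
  strategy <- match.arg(strategy)
  new_classes <- setdiff(sort(unique(labels)), buffer$classes_seen)
  classes_seen <- c(buffer$classes_seen, new_classes)
  quotas <- buffer_quotas(buffer, classes_seen)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  for (c in buffer$classes_seen) {   # shrink old classes to new quota
    key <- as.character(c)
    buffer$entries[[key]] <- shrink_entry(buffer$entries[[key]],
                                          quotas[[key]])
  }
  for (c in new_classes) {
    key <- as.character(c)
    idx <- which(labels == c)
    q <- quotas[[key]]
    take <- switch(strategy,
      uncertainty = idx[interval_sample(uncertainties[idx], q)],
      random = random_sample(idx, q),
      reservoir = idx[reservoir_sample(length(idx), q,
                                       seed = derive_seed(seed, c))])
    entry <- list(images = images[take, , , , drop = FALSE],
                  labels = labels[take],
                  uncertainty = uncertainties[take])
    if (!is.null(truth)) entry$truth <- truth[take]
    buffer$entries[[key]] <- entry
  }
  buffer$classes_seen <- classes_seen
  buffer
}

#' Flatten a buffer into training arrays
#'
#' @param buffer a [memory_buffer()].
#' @return list with `images`, `labels`, `uncertainty` (`NULL`s when
#'   empty).
#' @export
buffer_contents <- function(buffer) {
  if (buffer_size(buffer) == 0L)
    return(list(images = NULL, labels = integer(0),
                uncertainty = numeric(0), truth = NULL))
  imgs <- do.call(abind1, lapply(buffer$entries, `[[`, "images"))
  truths <- lapply(buffer$entries, `[[`, "truth")
  list(images = imgs,
       labels = unlist(lapply(buffer$entries, `[[`, "labels"),
                       use.names = FALSE),
       uncertainty = unlist(lapply(buffer$entries, `[[`, "uncertainty"),
                            use.names = FALSE),
       truth = if (any(vapply(truths, is.null, logical(1)))) NULL
               else unlist(truths, use.names = FALSE))
}

# bind N x H x W x C stacks along the first axis
abind1 <- function(...) {
  pieces <- list(...)
  d <- dim(pieces[[1]])
  n <- sum(vapply(pieces, function(p) dim(p)[1], integer(1)))
  out <- array(0, dim = c(n, d[-1]))
  at <- 0L
  for (p in pieces) {
    np <- dim(p)[1]
    if (np > 0) out[at + seq_len(np), , , ] <- p
    at <- at + np
  }
  out
}

#' Classic single-pass reservoir sampling
#'
#' Processes stream positions `1..n` once, keeping each with equal
#' probability `capacity / n`.
#'
#' @param n stream length.
#' @param capacity reservoir size (>= 1).
#' @param seed integer seed.
#' @return integer vector of selected stream positions.
#' @export
reservoir_sample <- function(n, capacity, seed = 1L) {
  stopifnot(capacity >= 1)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  if (capacity >= n) return(seq_len(n))
  res <- seq_len(capacity)
  for (i in (capacity + 1L):n) {
    j <- sample.int(i, 1L)
    if (j <= capacity) res[j] <- i
  }
  res
}

#' Uniform random subsampling without replacement
#'
#' @param indices candidate indices.
#' @param quota number to keep.
#' @param seed integer seed (optional; uses the caller's RNG stream when
#'   `NULL`).
#' @return selected indices (all of them if `quota` exceeds the count).
#' @export
random_sample <- function(indices, quota, seed = NULL) {
  if (!is.null(seed)) {
    old <- local_seed(seed)
    on.exit(restore_seed(old))
  }
  if (quota >= length(indices)) return(indices)
  sample(indices, quota)
}
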