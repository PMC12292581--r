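#' Create a trainable softmax backbone
#'
#' A single-hidden-layer perceptron (ReLU hidden layer, softmax output)
#' with an Adam optimiser, supporting soft-label cross-entropy and
#' single-head logit masking of unseen classes.  The output dimension is
#' fixed at the total class count of the benchmark so the output space
#' is unified across incremental tasks; during training the logits of
#' classes not yet seen are masked to an effectively `-Inf` value.
#'
#' @param input_dim flattened image dimension `H*W*C`.
#' @param n_classes total class count of the full benchmark.
#' @param hidden hidden layer width.
#' @param seed integer seed for weight initialisation.
#' @return an object of class `dscnl_backbone`.
#' @export
new_backbone <- function(input_dim, n_classes, hidden = 64, seed = 1L) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  init <- function(nr, nc, sc) matrix(stats::rnorm(nr * nc, 0, sc), nr, nc)
  w <- list(W1 = init(input_dim, hidden, sqrt(2 / input_dim)),
            b1 = numeric(hidden),
            W2 = init(hidden, n_classes, sqrt(2 / hidden)),
            b2 = numeric(n_classes))
  structure(list(par = w,
                 adam = list(m = lapply(w, function(p) p * 0),
                             v = lapply(w, function(p) p * 0),
                             t = 0L),
                 input_dim = input_dim, n_classes = n_classes,
                 hidden = hidden),
            class = "dscnl_backbone")
}

#' @export
print.dscnl_backbone <- function(x, ...) {
  cat(sprintf("<dscnl_backbone> %d -> %d -> %d (Adam steps: %d)\n",
              x$input_dim, x$hidden, x$n_classes, x$adam$t))
  invisible(x)
}

MASK_NEG <- -1e9

backbone_forward <- function(model, x, class_mask = NULL) {
  p <- model$par
  z1 <- sweep(x %*% p$W1, 2, p$b1, "+")
  a1 <- pmax(z1, 0)
  logits <- sweep(a1 %*% p$W2, 2, p$b2, "+")
  if (!is.null(class_mask)) logits[, !class_mask] <- MASK_NEG
  mx <- apply(logits, 1, max)
  e <- exp(logits - mx)
  list(probs = e / rowSums(e), a1 = a1, z1 = z1)
}

#' Predict class probabilities
#'
#' @param model a [new_backbone()] object.
#' @param x feature matrix `N x input_dim` (see [as_image_matrix()]).
#' @param classes_seen optional 0-based ids of classes available at
#'   inference; others get probability ~0.
#' @return `N x n_classes` matrix of row-stochastic probabilities.
#' @export
predict_backbone <- function(model, x, classes_seen = NULL) {
  mask <- if (is.null(classes_seen)) NULL
          else seq_len(model$n_classes) %in% (classes_seen + 1L)
  backbone_forward(model, x, mask)$probs
}

# cross-entropy gradient wrt logits for soft targets is (p - y)/N;
# masked logits carry ~zero probability and zero target, so their
# gradient vanishes without special casing
backbone_gradients <- function(model, x, fw, y_soft, weight = 1) {
  n <- nrow(x)
  dlogits <- weight * (fw$probs - y_soft) / n
  da1 <- dlogits %*% t(model$par$W2)
  dz1 <- da1 * (fw$z1 > 0)
  list(W1 = crossprod(x, dz1), b1 = colSums(dz1),
       W2 = crossprod(fw$a1, dlogits), b2 = colSums(dlogits))
}

add_gradients <- function(g1, g2) {
  if (is.null(g1)) return(g2)
  Map(`+`, g1, g2)
}

adam_step <- function(model, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st <- model$adam
  st$t <- st$t + 1L
  for (nm in names(grads)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * grads[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    model$par[[nm]] <- model$par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  model$adam <- st
  model
}

# one optimisation step over one or more loss components; each component
# is a list(x, y_soft, weight) and gradients are summed before the Adam
# update, which realises L = sum_k weight_k * CE_k
backbone_step <- function(model, components, class_mask, lr) {
  grads <- NULL
  for (cmp in components) {
    if (cmp$weight == 0 || nrow(cmp$x) == 0) next
    fw <- backbone_forward(model, cmp$x, class_mask)
    grads <- add_gradients(grads,
                           backbone_gradients(model, cmp$x, fw,
                                              cmp$y_soft, cmp$weight))
  }
  if (is.null(grads)) return(model)
  adam_step(model, grads, lr)
}

#' Train a backbone with plain cross-entropy
#'
#' Mini-batch Adam over shuffled epochs; targets may be hard 0-based
#' labels or a soft-label matrix.  Uses the caller's RNG stream for
#' shuffling (seed at the call site for reproducibility).
#'
#' @param model a [new_backbone()].
#' @param x feature matrix.
#' @param y integer labels (0-based) or `N x n_classes` soft labels.
#' @param classes_seen 0-based ids of classes allowed in the loss; all
#'   others are masked out of the softmax.
#' @param epochs,lr,batch_size optimisation settings.
#' @return the updated model.
#' @export
train_backbone <- function(model, x, y, classes_seen, epochs = 10,
                           lr = 1e-3, batch_size = 128) {
  y_soft <- if (is.matrix(y)) y else one_hot(y, model$n_classes)
  mask <- seq_len(model$n_classes) %in% (classes_seen + 1L)
  n <- nrow(x)
  for (e in seq_len(epochs)) {
    ord <- sample.int(n)
    for (b in split(ord, ceiling(seq_along(ord) / batch_size))) {
      model <- backbone_step(model,
                             list(list(x = x[b, , drop = FALSE],
                                       y_soft = y_soft[b, , drop = FALSE],
                                       weight = 1)),
                             mask, lr)
    }
  }
  model
}
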