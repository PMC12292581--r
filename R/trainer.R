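#' Run configuration for incremental training
#'
#' Desk-scale defaults (32 px images, one-hidden-layer backbone, 10
#' epochs per task, Adam at 1e-3); `paper_scale = TRUE` switches to the
#' reference benchmark settings (50 epochs per task, learning rate 1e-4,
#' batch 128) intended for full-resolution streams.
#'
#' @param epochs_per_task training epochs of the main backbone per task.
#' @param lr Adam learning rate.
#' @param batch_size mini-batch size.
#' @param buffer_size replay capacity `N_M` (typically 200, 500 or
#'   1000).
#' @param sampler replay selection strategy: `"uncertainty"`,
#'   `"reservoir"` or `"random"`.
#' @param S augmented copies per sample for uncertainty voting.
#' @param family augmentation family (see [augmentation_spec()]).
#' @param alpha Beta concentration of the mixup weight.
#' @param beta mix-loss weight in `L = L_ce + beta * L_mix`.
#' @param pairing mixup partner policy: `"permutation"` (random
#'   permutation of the composed batch) or `"memory_anchored"` (buffer
#'   samples always pair with current-task samples).
#' @param hidden backbone hidden width.
#' @param filter a [filter_config()].
#' @param paper_scale use the reference benchmark training settings.
#' @return a `dscnl_config` list.
#' @export
dscnl_config <- function(epochs_per_task = 10, lr = 1e-3,
                         batch_size = 128, buffer_size = 500,
                         sampler = c("uncertainty", "reservoir", "random"),
                         S = 10, family = "mix", alpha = 1, beta = 1,
                         pairing = c("permutation", "memory_anchored"),
                         hidden = 64, filter = filter_config(),
                         paper_scale = FALSE) {
  sampler <- match.arg(sampler)
  pairing <- match.arg(pairing)
  if (paper_scale) {
    epochs_per_task <- 50
    lr <- 1e-4
    batch_size <- 128
    filter$lr <- 1e-4
  }
  stopifnot(beta >= 0, alpha > 0, buffer_size >= 1)
  structure(list(epochs_per_task = epochs_per_task, lr = lr,
                 batch_size = batch_size, buffer_size = buffer_size,
                 sampler = sampler, S = S, family = family,
                 alpha = alpha, beta = beta, pairing = pairing,
                 hidden = hidden, filter = filter,
                 paper_scale = paper_scale),
            class = "dscnl_config")
}

#' Train the main backbone on one task with soft replay
#'
#' Optimises `L = L_ce + beta * L_mix` over composed batches drawn
#' uniformly from the union of the clean subset and the replay buffer.
#' `L_ce` uses the composed batch's stored hard labels; `L_mix` is the
#' soft-label cross-entropy of the mixup batch built by pairing the
#' composed batch with a partner draw.  Logits of classes not yet seen
#' are masked out of the loss.
#'
#' @param model a [new_backbone()].
#' @param clean_x,clean_labels clean-subset features and labels.
#' @param buffer a [memory_buffer()] (may be empty).
#' @param classes_seen 0-based ids of all classes seen so far.
#' @param config a [dscnl_config()].
#' @return the updated model, with an `epoch_loss` attribute (mean
#'   combined loss per epoch).
#' @export
train_task <- function(model, clean_x, clean_labels, buffer, classes_seen,
                       config) {
  if (is.null(clean_x) || nrow(clean_x) == 0L)
    stop("empty clean subset: filtering failed upstream")
  bc <- buffer_contents(buffer)
  buffer_x <- if (is.null(bc$images)) NULL
              else matrix(bc$images, nrow = dim(bc$images)[1])
  k <- model$n_classes
  mask <- seq_len(k) %in% (classes_seen + 1L)
  pool_n <- nrow(clean_x) + length(bc$labels)
  n_batches <- max(1L, ceiling(pool_n / config$batch_size))
  epoch_loss <- numeric(config$epochs_per_task)
  for (e in seq_len(config$epochs_per_task)) {
    losses <- numeric(n_batches)
    for (b in seq_len(n_batches)) {
      bt <- compose_batch(clean_x, clean_labels, buffer_x, bc$labels,
                          min(config$batch_size, pool_n), k)
      components <- list(list(x = bt$x, y_soft = bt$y, weight = 1))
      l_mix <- 0
      if (config$beta > 0) {
        lam <- sample_lambda(config$alpha)
        partner <- partner_permutation(bt$source, config$pairing)
        mixed <- mixup_pair(bt$x, bt$y,
                            bt$x[partner, , drop = FALSE],
                            bt$y[partner, , drop = FALSE],
                            lam$lambda_prime)
        components[[2]] <- list(x = mixed$x, y_soft = mixed$y,
                                weight = config$beta)
        l_mix <- mix_loss(backbone_forward(model, mixed$x, mask)$probs,
                          mixed$y)
      }
      l_ce <- mix_loss(backbone_forward(model, bt$x, mask)$probs, bt$y)
      losses[b] <- combined_loss(l_ce, l_mix, config$beta)
      model <- backbone_step(model, components, mask, config$lr)
    }
    epoch_loss[e] <- mean(losses)
  }
  attr(model, "epoch_loss") <- epoch_loss
  model
}

# mixup partner draw: a random permutation of the batch, or (memory
# anchored) buffer rows forced to pair with current-task rows
partner_permutation <- function(source, pairing) {
  n <- length(source)
  perm <- sample.int(n)
  if (pairing == "memory_anchored") {
    cur <- which(source == "current")
    mem <- which(source == "memory")
    if (length(cur) > 0 && length(mem) > 0)
      perm[mem] <- sample(cur, length(mem), replace = TRUE)
  }
  perm
}

#' Evaluate a model on the test splits of learned tasks
#'
#' Single-head class-incremental inference: argmax over the unified
#' output space restricted to classes seen so far, no task identifier.
#' Accuracy is measured against true test labels (test labels are never
#' corrupted).
#'
#' @param model a [new_backbone()].
#' @param test_data the test [labeled_image_dataset()].
#' @param task_classes list of 0-based class-id vectors, tasks `1..t`.
#' @param classes_seen 0-based ids of classes seen so far.
#' @return numeric vector of per-task accuracies in percent.
#' @export
evaluate_model <- function(model, test_data, task_classes, classes_seen) {
  x <- as_image_matrix(test_data)
  p <- predict_backbone(model, x, classes_seen)
  pred <- max.col(p, ties.method = "first") - 1L
  vapply(task_classes, function(k) {
    idx <- which(test_data$true_labels %in% k)
    100 * mean(pred[idx] == test_data$true_labels[idx])
  }, numeric(1))
}

#' Fit a class-incremental model on a noisy stream
#'
#' The main entry point.  For each task of the stream, in `"dscnl"`
#' mode: filter the task data down to a high-confidence clean subset
#' (per-class Gaussian-mixture over historical confidences), train the
#' single-head backbone on the clean subset jointly with replay-buffer
#' samples under the combined cross-entropy + mixup objective, score
#' the clean subset by augmentation-vote uncertainty, and refresh the
#' class-balanced replay buffer.  In `"finetune"` mode the backbone is
#' trained on the raw noisy task data with no filter, buffer or mixup
#' (the catastrophic-forgetting baseline).  After each task the model
#' is evaluated on the test split of every task learned so far.
#'
#' @param stream a list with `train`, `test`
#'   ([labeled_image_dataset()]s) and `tasks` (a `task_sequence`), as
#'   returned by [synthetic_stream()] or assembled from
#'   [read_npz_dataset()] + [split_tasks()].
#' @param mode `"dscnl"` or `"finetune"`.
#' @param config a [dscnl_config()].
#' @param seed integer seed; fixed seed plus single-threaded BLAS gives
#'   an identical accuracy matrix.
#' @return an object of class `dscnl`; see [summary.dscnl()].  Fields:
#'   `accuracy` (lower-triangular task-accuracy matrix in percent),
#'   `faa` (final average accuracy), `purity` (per-task selection and
#'   buffer purity, synthetic mode), `buffer`, `model`, `filter_diag`,
#'   `mode`, `config`, `seed`.
#' @export
dscnl <- function(stream, mode = c("dscnl", "finetune"),
                  config = dscnl_config(), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(stream$train, "labeled_image_dataset"),
            inherits(stream$tasks, "task_sequence"))
  run_incremental(stream$train, stream$test, stream$tasks, config, mode,
                  seed)
}

#' @rdname dscnl
#' @param train,test train and test [labeled_image_dataset()]s.
#' @param tasks a `task_sequence` from [split_tasks()].
#' @export
run_incremental <- function(train, test, tasks, config = dscnl_config(),
                            mode = c("dscnl", "finetune"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "dscnl_config"))
  n_tasks <- length(tasks$tasks)
  if (n_tasks < 1L) stop("need at least one task")
  k <- train$n_classes
  d <- prod(dim(train$images)[-1])
  model <- new_backbone(d, k, config$hidden, seed = derive_seed(seed, 0))
  buffer <- memory_buffer(config$buffer_size)
  acc <- matrix(NA_real_, n_tasks, n_tasks,
                dimnames = list(after_task = paste0("t", seq_len(n_tasks)),
                                on_task = paste0("t", seq_len(n_tasks))))
  purity_rows <- list()
  filter_diag <- list()
  classes_seen <- integer(0)
  for (t in seq_len(n_tasks)) {
    t_seed <- derive_seed(seed, t)
    task_classes <- tasks$tasks[[t]]
    task_data <- subset_dataset(train, tasks$indices[[t]])
    classes_seen <- c(classes_seen, task_classes)
    old <- local_seed(derive_seed(t_seed, 11))
    if (mode == "dscnl") {
      cs <- run_filtering_loop(task_data, task_classes, config$filter,
                               seed = derive_seed(t_seed, 1))
      filter_diag[[t]] <- cbind(task = t, cs$diagnostics)
      clean_x <- as_image_matrix(task_data)[cs$indices, , drop = FALSE]
      model <- train_task(model, clean_x, cs$labels, buffer,
                          classes_seen, config)
      spec <- augmentation_spec(config$S, config$family)
      u <- sample_uncertainties(model,
                                task_data$images[cs$indices, , , ,
                                                 drop = FALSE],
                                spec, classes_seen,
                                seed = derive_seed(t_seed, 2))
      truth <- (task_data$noisy_labels == task_data$true_labels)[cs$indices]
      buffer <- update_buffer(buffer,
                              task_data$images[cs$indices, , , ,
                                               drop = FALSE],
                              cs$labels, u, strategy = config$sampler,
                              seed = derive_seed(t_seed, 3),
                              truth = truth)
      bc <- buffer_contents(buffer)
      purity_rows[[t]] <- data.frame(
        task = t, n_task = n_samples(task_data), n_selected = cs$count,
        selection_purity = 100 * mean(
          (task_data$noisy_labels == task_data$true_labels)[cs$indices]),
        buffer_purity = if (is.null(bc$truth)) NA_real_
                        else 100 * mean(bc$truth),
        noise_rate_estimate = cs$noise_rate_estimate)
    } else {
      x <- as_image_matrix(task_data)
      model <- train_backbone(model, x, task_data$noisy_labels,
                              classes_seen,
                              epochs = config$epochs_per_task,
                              lr = config$lr,
                              batch_size = config$batch_size)
      purity_rows[[t]] <- data.frame(
        task = t, n_task = n_samples(task_data),
        n_selected = n_samples(task_data),
        selection_purity = 100 * mean(
          task_data$noisy_labels == task_data$true_labels),
        buffer_purity = NA_real_, noise_rate_estimate = NA_real_)
    }
    restore_seed(old)
    acc[t, seq_len(t)] <- evaluate_model(model, test,
                                         tasks$tasks[seq_len(t)],
                                         classes_seen)
  }
  structure(list(accuracy = acc,
                 faa = final_average_accuracy(acc),
                 purity = do.call(rbind, purity_rows),
                 buffer = buffer, model = model,
                 filter_diag = if (length(filter_diag))
                   do.call(rbind, filter_diag) else NULL,
                 mode = mode, config = config, seed = seed,
                 classes_seen = classes_seen),
            class = "dscnl")
}
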