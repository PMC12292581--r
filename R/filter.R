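#' Per-sample historical confidence accumulator
#'
#' Tracks the running sum, over training epochs, of the softmax
#' probability a model assigns to each sample's own (noisy) label.  Its
#' average over epochs is the selection statistic for the clean filter:
#' clean samples accumulate high average confidence early in training,
#' mislabelled samples do not.
#'
#' @param n number of tracked samples.
#' @return object of class `confidence_history` with fields
#'   `cumulative` (length-`n` sums) and `epochs` recorded.
#' @export
confidence_history <- function(n) {
  structure(list(cumulative = numeric(n), epochs = 0L),
            class = "confidence_history")
}

#' @rdname confidence_history
#' @param history a `confidence_history`.
#' @param label_probs per-sample probability of its own label, in `[0,1]`.
#' @export
update_history <- function(history, label_probs) {
  stopifnot(inherits(history, "confidence_history"))
  if (length(label_probs) != length(history$cumulative))
    stop("length mismatch: history tracks ", length(history$cumulative),
         " samples, got ", length(label_probs), " probabilities")
  if (any(label_probs < 0 | label_probs > 1))
    stop("label probabilities must lie in [0, 1]")
  history$cumulative <- history$cumulative + label_probs
  history$epochs <- history$epochs + 1L
  history
}

#' @rdname confidence_history
#' @export
average_confidence <- function(history) {
  stopifnot(inherits(history, "confidence_history"))
  if (history$epochs < 1L)
    stop("no epochs recorded yet; cannot average")
  history$cumulative / history$epochs
}

#' Fit a two-component univariate Gaussian mixture by EM
#'
#' Models the within-class distribution of average historical
#' confidences: the high-mean component captures easy-to-learn clean
#' samples, the low-mean component noisy or hard samples.  Initialised
#' from the 25th/75th percentile split, with a variance floor guarding
#' against singular components.  Components are ordered so
#' `mu[1] <= mu[2]`.
#'
#' @param values numeric vector of average confidences for one class.
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @param var_floor minimum component variance.
#' @return object of class `bgmm_fit`: `mu`, `sigma2`, `weight` (each
#'   length 2, low then high), `resp_high` (per-sample posterior of the
#'   high-mean component), `converged`, `degenerate`, `iterations`.
#' @export
fit_class_bgmm <- function(values, max_iter = 100, tol = 1e-6,
                           var_floor = 1e-4) {
  n <- length(values)
  if (n < 2L) stop("need at least 2 values to fit a mixture")
  if (diff(range(values)) < 1e-8) {
    return(structure(list(mu = rep(mean(values), 2),
                          sigma2 = rep(var_floor, 2),
                          weight = c(0.5, 0.5),
                          resp_high = rep(1, n), converged = TRUE,
                          degenerate = TRUE, iterations = 0L),
                     class = "bgmm_fit"))
  }
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE)
  mu <- q
  s2 <- rep(max(stats::var(values) / 4, var_floor), 2)
  w <- c(0.5, 0.5)
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(values, mu[1], sqrt(s2[1]))
    d2 <- w[2] * stats::dnorm(values, mu[2], sqrt(s2[2]))
    tot <- d1 + d2
    tot[tot < 1e-300] <- 1e-300
    r2 <- d2 / tot
    r1 <- 1 - r2
    n1 <- sum(r1); n2 <- sum(r2)
    if (n1 < 1e-8 || n2 < 1e-8) break   # component collapse
    mu <- c(sum(r1 * values) / n1, sum(r2 * values) / n2)
    s2 <- pmax(c(sum(r1 * (values - mu[1])^2) / n1,
                 sum(r2 * (values - mu[2])^2) / n2), var_floor)
    w <- c(n1, n2) / n
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (mu[1] > mu[2]) {      # order components low/high
    mu <- rev(mu); s2 <- rev(s2); w <- rev(w); r2 <- r1
  }
  structure(list(mu = mu, sigma2 = s2, weight = w, resp_high = r2,
                 converged = converged,
                 degenerate = abs(mu[2] - mu[1]) < 1e-6,
                 iterations = it),
            class = "bgmm_fit")
}

#' Select high-posterior clean samples
#'
#' Keeps samples whose posterior responsibility of the high-mean (clean)
#' component reaches the threshold `tau`.  A degenerate fit (single
#' effective component) passes all samples through.
#'
#' @param fit a [fit_class_bgmm()] result.
#' @param tau posterior cutoff in `(0, 1)`.
#' @return logical mask over the fitted values.
#' @export
select_clean <- function(fit, tau) {
  stopifnot(inherits(fit, "bgmm_fit"))
  if (fit$degenerate) return(rep(TRUE, length(fit$resp_high)))
  fit$resp_high >= tau
}

#' Expected clean-sample count
#'
#' @param noise_rate_estimate estimated corruption fraction in `[0, 1)`.
#' @param n task sample count.
#' @return `round((1 - rate) * n)`.
#' @export
expected_clean_count <- function(noise_rate_estimate, n) {
  if (noise_rate_estimate < 0 || noise_rate_estimate >= 1)
    stop("noise rate estimate must lie in [0, 1)")
  as.integer(round((1 - noise_rate_estimate) * n))
}

#' Estimate the task noise rate by cross-validation
#'
#' Trains fold models on the noisy labels of k-1 folds and measures
#' held-out disagreement between the predicted class and the stored
#' label.  Under symmetric noise on separable data the classifier
#' approximates the true class, so disagreement estimates the noise
#' rate; on hard classes it systematically overestimates, hence the clip
#' to `[0, 0.9]` and the known-rate override used in benchmark mode.
#'
#' @param task_data a [labeled_image_dataset()] restricted to one task.
#' @param task_classes 0-based class ids of the task.
#' @param folds number of folds (>= 2).
#' @param epochs,lr,batch_size,hidden fold-model training settings.
#' @param seed integer seed.
#' @param known_rate if supplied, returned unchanged (bypass).
#' @return estimated noise rate in `[0, 0.9]`.
#' @export
estimate_noise_rate <- function(task_data, task_classes, folds = 3,
                                epochs = 10, lr = 1e-3, batch_size = 128,
                                hidden = 64, seed = 1L, known_rate = NULL) {
  if (!is.null(known_rate)) return(known_rate)
  if (folds < 2L) stop("need at least 2 folds")
  x <- as_image_matrix(task_data)
  y <- task_data$noisy_labels
  if (any(table(y) < folds))
    stop("every class needs at least `folds` samples for stratification")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  fold_of <- integer(length(y))
  for (c in unique(y)) {          # stratified fold assignment
    idx <- which(y == c)
    fold_of[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  disagree <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold_of != f
    m <- new_backbone(ncol(x), task_data$n_classes, hidden,
                      seed = derive_seed(seed, f))
    m <- train_backbone(m, x[tr, , drop = FALSE], y[tr], task_classes,
                        epochs = epochs, lr = lr, batch_size = batch_size)
    p <- predict_backbone(m, x[!tr, , drop = FALSE], task_classes)
    pred <- max.col(p, ties.method = "first") - 1L
    disagree[f] <- mean(pred != y[!tr])
  }
  min(max(mean(disagree), 0), 0.9)
}

#' Filtering configuration
#'
#' @param warmup_epochs unfiltered warm-up epochs for the auxiliary
#'   network (confidence statistics only).
#' @param lr,batch_size auxiliary-network optimisation settings.
#' @param tau0 base posterior cutoff.
#' @param gamma amplification factor in `(0, 1)`: `1 - tau` is
#'   multiplied by `gamma` while the selection exceeds the expected
#'   clean count, divided by it otherwise.
#' @param noise_rate known corruption rate; `NULL` triggers
#'   cross-validated estimation.
#' @param max_iter filtering iteration cap.
#' @param min_class_size classes smaller than this bypass the mixture
#'   fit and pass through unfiltered.
#' @param hidden auxiliary-network hidden width.
#' @param cv_folds folds for noise-rate estimation.
#' @return a `filter_config` list.
#' @export
filter_config <- function(warmup_epochs = 5, lr = 1e-4, batch_size = 128,
                          tau0 = 0.5, gamma = 0.8, noise_rate = NULL,
                          max_iter = 10, min_class_size = 10,
                          hidden = 64, cv_folds = 3) {
  if (warmup_epochs < 1) stop("warmup_epochs must be >= 1")
  if (tau0 <= 0 || tau0 >= 1) stop("tau0 must lie in (0, 1)")
  if (gamma <= 0 || gamma >= 1) stop("gamma must lie in (0, 1)")
  structure(list(warmup_epochs = warmup_epochs, lr = lr,
                 batch_size = batch_size, tau0 = tau0, gamma = gamma,
                 noise_rate = noise_rate, max_iter = max_iter,
                 min_class_size = min_class_size, hidden = hidden,
                 cv_folds = cv_folds),
            class = "filter_config")
}

record_label_probs <- function(model, x, labels, task_classes) {
  p <- predict_backbone(model, x, task_classes)
  p[cbind(seq_along(labels), labels + 1L)]
}

#' Run the iterative clean-sample filtering loop
#'
#' Warm-up trains a fresh auxiliary network on all task data while
#' recording per-epoch label confidences; afterwards the loop
#' {fit per-class mixture on average confidences -> select clean ->
#' train the auxiliary net one epoch on the selection -> update history}
#' repeats until the selected count reaches the expected clean count or
#' the iteration cap.  When the selection overshoots the target the
#' threshold is amplified toward 1 and re-applied, shrinking it toward
#' the expected size.
#'
#' @param task_data a [labeled_image_dataset()] restricted to one task.
#' @param task_classes 0-based class ids of the task.
#' @param config a [filter_config()].
#' @param seed integer seed.
#' @return object of class `clean_subset`: `indices` (into `task_data`),
#'   `labels` (retained noisy labels), `count`, `converged`,
#'   `noise_rate_estimate`, `aux_model`, and a `diagnostics` data frame
#'   (iteration, class, mu_low, mu_high, tau, selected, purity).
#' @export
run_filtering_loop <- function(task_data, task_classes,
                               config = filter_config(), seed = 1L) {
  stopifnot(inherits(config, "filter_config"))
  n <- n_samples(task_data)
  if (n == 0L) stop("empty task dataset")
  x <- as_image_matrix(task_data)
  y <- task_data$noisy_labels
  clean_truth <- task_data$noisy_labels == task_data$true_labels
  old <- local_seed(derive_seed(seed, 1))
  on.exit(restore_seed(old))

  aux <- new_backbone(ncol(x), task_data$n_classes, config$hidden,
                      seed = derive_seed(seed, 2))
  history <- confidence_history(n)
  for (e in seq_len(config$warmup_epochs)) {
    aux <- train_backbone(aux, x, y, task_classes, epochs = 1,
                          lr = config$lr, batch_size = config$batch_size)
    history <- update_history(history,
                              record_label_probs(aux, x, y, task_classes))
  }

  rho <- estimate_noise_rate(task_data, task_classes,
                             folds = config$cv_folds,
                             batch_size = config$batch_size,
                             hidden = config$hidden,
                             seed = derive_seed(seed, 3),
                             known_rate = config$noise_rate)
  target <- expected_clean_count(rho, n)

  tau <- config$tau0
  diagnostics <- list()
  selection <- rep(TRUE, n)
  best <- NULL                 # best-so-far: count closest to target
  converged <- FALSE
  select_at <- function(avg, tau) {
    mask <- logical(n)
    rows <- list()
    for (c in task_classes) {
      idx <- which(y == c)
      if (length(idx) < config$min_class_size) {   # degenerate small class
        mask[idx] <- TRUE
        rows[[length(rows) + 1]] <-
          data.frame(class = c, mu_low = NA_real_, mu_high = NA_real_,
                     tau = tau, selected = length(idx))
        next
      }
      fit <- fit_class_bgmm(avg[idx])
      keep <- select_clean(fit, tau)
      mask[idx[keep]] <- TRUE
      rows[[length(rows) + 1]] <-
        data.frame(class = c, mu_low = fit$mu[1], mu_high = fit$mu[2],
                   tau = tau, selected = sum(keep))
    }
    list(mask = mask, rows = do.call(rbind, rows))
  }

  for (iter in seq_len(config$max_iter)) {
    avg <- average_confidence(history)
    sel <- select_at(avg, tau)
    # overshoot: amplify the threshold toward 1 and re-apply, driving
    # the selection size down toward the expected clean count
    amp <- 0L
    while (sum(sel$mask) > 1.02 * target && tau < 0.999 && amp < 25L) {
      tau <- 1 - (1 - tau) * config$gamma
      sel <- select_at(avg, tau)
      amp <- amp + 1L
    }
    count <- sum(sel$mask)
    sel$rows$iteration <- iter
    sel$rows$purity <- vapply(sel$rows$class, function(c) {
      s <- sel$mask & y == c
      if (!any(s)) NA_real_ else 100 * mean(clean_truth[s])
    }, numeric(1))
    diagnostics[[iter]] <- sel$rows
    selection <- sel$mask
    if (is.null(best) || abs(count - target) < abs(sum(best) - target))
      best <- selection
    if (count >= target) {
      converged <- TRUE
      break
    }
    # undershoot: relax toward 0; a fully relaxed threshold passes the
    # whole class through (the expected-count prior overrides the fit)
    tau <- max(1 - (1 - tau) / config$gamma, 0)
    if (count > 0) {
      keep <- which(selection)
      aux <- train_backbone(aux, x[keep, , drop = FALSE], y[keep],
                            task_classes, epochs = 1, lr = config$lr,
                            batch_size = config$batch_size)
    }
    history <- update_history(history,
                              record_label_probs(aux, x, y, task_classes))
  }
  if (!converged) {
    warning("filtering loop hit max_iter before reaching the expected ",
            "clean count; returning the best selection seen")
    selection <- best
    if (sum(selection) == 0L) selection <- rep(TRUE, n)
  }
  idx <- which(selection)
  structure(list(indices = idx, labels = y[idx], count = length(idx),
                 converged = converged, noise_rate_estimate = rho,
                 expected_count = target, tau = tau, aux_model = aux,
                 diagnostics = do.call(rbind, diagnostics)),
            class = "clean_subset")
}

#' @export
print.clean_subset <- function(x, ...) {
  cat(sprintf(
    "<clean_subset> %d samples kept (target %d, rho-hat %.3f, tau %.3f)%s\n",
    x$count, x$expected_count, x$noise_rate_estimate, x$tau,
    if (x$converged) "" else " [not converged]"))
  invisible(x)
}
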