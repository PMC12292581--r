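# Small desk-scale fixtures built in code.  `tiny_stream()` is the
# default unit-test stream (4 tasks over 8 classes, 16 px); the
# acceptance tests build the larger 32 px streams themselves.

tiny_stream <- function(noise_rate = 0.3, seed = 7, n_per_class = 60,
                        image_size = 16, n_classes = 8) {
  synthetic_stream(n_classes = n_classes, n_per_class = n_per_class,
                   n_test_per_class = 25, image_size = image_size,
                   separability = 1.0, noise_rate = noise_rate,
                   seed = seed)
}

# unit-test streams are an order of magnitude smaller than the
# benchmark, so the batch size comes down with them to keep the number
# of optimiser steps per epoch comparable
tiny_config <- function(noise_rate = 0.3, ...) {
  dscnl_config(batch_size = 16,
               filter = filter_config(noise_rate = noise_rate,
                                      batch_size = 16), ...)
}

tiny_filter <- function(noise_rate) {
  filter_config(noise_rate = noise_rate, batch_size = 16)
}

# fraction of a clean subset whose retained label is wrong
subset_noise_fraction <- function(task_data, cs) {
  mean((task_data$noisy_labels != task_data$true_labels)[cs$indices])
}

# draws from a two-component univariate Gaussian mixture with known
# assignments (the generating-label oracle for mixture-recovery tests)
bimodal_sample <- function(n, mu, sigma, weight = 0.5, seed = 1) {
  set.seed(seed)
  z <- stats::rbinom(n, 1, weight)           # 1 = high component
  list(values = stats::rnorm(n, ifelse(z == 1, mu[2], mu[1]),
                             sigma),
       assignment = z)
}
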