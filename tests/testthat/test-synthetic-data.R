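test_that("generator produces the requested shape with balanced classes", {
  d <- generate_synthetic_dataset(8, 100, 32, 1.0, seed = 7)
  expect_equal(dim(d$images), c(800, 32, 32, 3))
  expect_setequal(unique(d$true_labels), 0:7)
  expect_true(all(table(d$true_labels) == 100))
  expect_true(all(d$images >= 0 & d$images <= 1))

  m <- generate_synthetic_dataset(2, 1, 8, 1.0, seed = 1)
  expect_equal(sort(m$true_labels), c(0L, 1L))

  expect_error(generate_synthetic_dataset(1, 10), "n_classes")
  expect_error(generate_synthetic_dataset(4, 10, image_size = 4),
               "image_size")
  expect_error(generate_synthetic_dataset(4, 10, separability = 0),
               "separability")
})

test_that("generator is deterministic for a fixed seed", {
  a <- generate_synthetic_dataset(4, 10, 16, 1.0, seed = 42)
  b <- generate_synthetic_dataset(4, 10, 16, 1.0, seed = 42)
  expect_identical(a$images, b$images)
  c <- generate_synthetic_dataset(4, 10, 16, 1.0, seed = 43)
  expect_false(identical(a$images, c$images))
})

test_that("noise injection corrupts exactly round(rate*N) labels, never in place", {
  d <- generate_synthetic_dataset(5, 40, 16, seed = 3)
  n <- length(d$true_labels)
  same <- inject_symmetric_noise(d, 0, seed = 1)
  expect_identical(same$noisy_labels, same$true_labels)
  for (rate in c(0.1, 0.25, 0.3, 0.47)) {
    for (seed in 1:3) {
      nd <- inject_symmetric_noise(d, rate, seed = seed)
      flipped <- nd$noisy_labels != nd$true_labels
      expect_identical(sum(flipped), as.integer(round(rate * n)))
      expect_identical(nd$true_labels, d$true_labels)
      expect_true(all(nd$noisy_labels >= 0 & nd$noisy_labels < 5))
      # class-count conservation
      expect_identical(sum(tabulate(nd$noisy_labels + 1L, 5)), n)
    }
  }
  expect_error(inject_symmetric_noise(d, 1), "rate")
})

test_that("empirical label transitions are symmetric at rate rho/(K-1)", {
  k <- 4
  d <- generate_synthetic_dataset(k, 50, 16, seed = 5)
  rho <- 0.4
  trans <- matrix(0, k, k)
  n_seeds <- 120
  for (s in seq_len(n_seeds)) {
    nd <- inject_symmetric_noise(d, rho, seed = s)
    for (c in 0:(k - 1)) {
      idx <- d$true_labels == c
      trans[c + 1, ] <- trans[c + 1, ] +
        tabulate(nd$noisy_labels[idx] + 1L, k) / sum(idx)
    }
  }
  trans <- trans / n_seeds
  expect_equal(diag(trans), rep(1 - rho, k), tolerance = 0.05)
  off <- trans[row(trans) != col(trans)]
  expect_equal(off, rep(rho / (k - 1), length(off)), tolerance = 0.05)
})

test_that("mean corrupted class count matches the closed-form expectation", {
  # E[A_c] = (1-rho) B_c + rho (N - B_c) / (K-1), checked by Monte Carlo
  set.seed(11)
  k <- 5
  d <- generate_synthetic_dataset(k, 30, 16, seed = 2)
  extra <- sample(rep(0:(k - 1), times = c(40, 10, 25, 5, 20)))
  d <- labeled_image_dataset(
    array(0.5, dim = c(length(d$true_labels) + length(extra), 8, 8, 1)),
    c(d$true_labels, extra), n_classes = k)
  b <- tabulate(d$true_labels + 1L, k)
  n <- sum(b)
  rho <- 0.3
  counts <- replicate(200, {
    nd <- inject_symmetric_noise(d, rho, seed = sample.int(1e6, 1))
    tabulate(nd$noisy_labels + 1L, k)[1]
  })
  expected <- (1 - rho) * b[1] + rho * (n - b[1]) / (k - 1)
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 1e-9)
})

test_that("task splitting follows noisy labels and enforces disjointness", {
  st <- tiny_stream(noise_rate = 0.3, seed = 9)
  tasks <- st$tasks
  all_idx <- unlist(tasks$indices)
  expect_identical(sort(all_idx), seq_len(length(st$train$true_labels)))
  for (t in seq_along(tasks$tasks))
    expect_true(all(st$train$noisy_labels[tasks$indices[[t]]] %in%
                      tasks$tasks[[t]]))
  expect_error(split_tasks(st$train, list(0:1, 1:2)), "disjoint")
  expect_error(split_tasks(st$train, list(0:1, c(2L, 99L))), "existing")
  one <- split_tasks(st$train, list(0:7))
  expect_length(one$indices, 1)
  expect_identical(sort(one$indices[[1]]),
                   seq_len(length(st$train$true_labels)))
})

test_that("NPZ round trip preserves arrays and the uint8 convention", {
  st <- synthetic_stream(n_classes = 2, n_per_class = 5,
                         n_test_per_class = 3, image_size = 8,
                         noise_rate = 0.4, seed = 4)
  f <- tempfile(fileext = ".npz")
  write_npz_dataset(st, f)
  back <- read_npz_dataset(f)
  # on-disk uint8 quantisation: read-back equals round(255*x)/255 exactly
  expect_identical(back$train$images, round(st$train$images * 255) / 255)
  expect_identical(back$test$images, round(st$test$images * 255) / 255)
  expect_identical(back$train$noisy_labels, st$train$noisy_labels)
  expect_identical(back$train$true_labels, st$train$true_labels)
  expect_identical(back$test$true_labels, st$test$true_labels)
  # second round trip is bitwise stable
  f2 <- tempfile(fileext = ".npz")
  write_npz_dataset(back, f2)
  again <- read_npz_dataset(f2)
  expect_identical(again$train$images, back$train$images)
})

test_that("malformed archives and label mismatches are rejected", {
  lab <- matrix(0:3, ncol = 1)
  attr(lab, "npy_dtype") <- "i4"
  img <- array(runif(5 * 8 * 8 * 3), dim = c(5, 8, 8, 3))
  attr(img, "npy_dtype") <- "u1"
  f <- tempfile(fileext = ".npz")
  dscnl:::write_npz(list(train_images = img, train_labels = lab,
                         test_images = img, test_labels = lab),
                    f)
  expect_error(read_npz_dataset(f), "mismatch")
  f2 <- tempfile(fileext = ".npz")
  dscnl:::write_npz(list(train_images = img), f2)
  expect_error(read_npz_dataset(f2), "missing keys")
})

test_that("label manifest records task membership", {
  st <- tiny_stream(noise_rate = 0.2, seed = 3, n_per_class = 10,
                    image_size = 8)
  f <- tempfile(fileext = ".csv")
  write_label_manifest(st$train, st$tasks, f)
  man <- read.csv(f)
  expect_named(man, c("index", "true_label", "noisy_label", "task"))
  expect_equal(nrow(man), length(st$train$true_labels))
  for (t in seq_along(st$tasks$tasks))
    expect_true(all(man$noisy_label[man$task == t] %in%
                      st$tasks$tasks[[t]]))
})
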