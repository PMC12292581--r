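test_that("augmentation respects family contracts and determinism", {
  set.seed(4)
  x <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
  id <- augment(x, augmentation_spec(S = 1, family = "identity"))
  expect_equal(id[1, , , ], x)
  spec <- augmentation_spec(S = 6, family = "mix", seed = 99)
  a <- augment(x, spec)
  b <- augment(x, spec)
  expect_identical(a, b)                       # bitwise reproducible
  expect_equal(dim(a), c(6, 16, 16, 3))
  expect_true(all(a >= 0 & a <= 1))
  # mix family draws from affine, pixel and cutout transforms
  expect_setequal(augmentation_spec(family = "mix")$transforms,
                  c("tf_rotate", "tf_translate", "tf_scale", "tf_hflip",
                    "tf_brightness", "tf_contrast", "tf_noise",
                    "tf_color_jitter", "tf_cutout"))
  expect_error(augmentation_spec(family = "polar"), "unknown")
  expect_error(augmentation_spec(S = 0), "S must be")
})

test_that("Monte-Carlo prediction averages the simplex and preserves it", {
  st <- tiny_stream(noise_rate = 0, seed = 2, n_per_class = 10,
                    image_size = 8, n_classes = 2)
  m <- new_backbone(8 * 8 * 3, 2, hidden = 8, seed = 1)
  x <- st$train$images[1, , , ]
  id <- augment(x, augmentation_spec(S = 5, family = "identity"))
  p <- mc_predict(m, id, 0:1)
  single <- predict_backbone(m, matrix(x, nrow = 1), 0:1)
  expect_equal(p, as.numeric(single))        # identical copies, same model
  set.seed(10)
  aug <- augment(x, augmentation_spec(S = 7, family = "mix"))
  expect_equal(sum(mc_predict(m, aug, 0:1)), 1)
})

test_that("vote uncertainty matches hand counts and a brute-force oracle", {
  mk <- function(votes) {
    # probability rows whose argmax realises the requested vote counts
    k <- length(votes)
    do.call(rbind, lapply(which(votes > 0), function(c)
      matrix(diag(k)[c, ], nrow = votes[c], ncol = k, byrow = TRUE)))
  }
  u <- vote_uncertainty(mk(c(10, 0, 0)))
  expect_equal(u$uncertainty, 0)
  expect_equal(u$votes, c(10, 0, 0))
  expect_equal(vote_uncertainty(mk(c(7, 2, 1)))$uncertainty, 0.3)
  expect_equal(vote_uncertainty(mk(c(2, 2, 2, 2, 2)))$uncertainty, 0.8)
  # exhaustive small vote tables vs a brute-force recount
  set.seed(33)
  for (rep in 1:25) {
    s <- sample(1:6, 1); k <- sample(2:4, 1)
    probs <- matrix(stats::rexp(s * k), s, k)
    probs <- probs / rowSums(probs)
    est <- vote_uncertainty(probs)
    votes_bf <- integer(k)
    for (j in seq_len(s)) {
      w <- which(probs[j, ] == max(probs[j, ]))[1]
      votes_bf[w] <- votes_bf[w] + 1L
    }
    expect_identical(est$votes, votes_bf)
    expect_equal(est$uncertainty, 1 - max(votes_bf) / s)
    expect_equal(sum(est$votes), s)
    expect_true(est$uncertainty >= 0 && est$uncertainty <= 1 - 1 / s)
    expect_equal(est$mc_probs, colMeans(probs))
  }
})

test_that("interval sampling spans the uncertainty spectrum evenly", {
  u10 <- c(0.9, 0.1, 0.5, 0.3, 0.7, 0.2, 0.8, 0.4, 0.6, 0.0)
  sel <- interval_sample(u10, 2)
  expect_setequal(u10[sel], c(0.0, 0.9))   # endpoints always included
  expect_identical(sort(interval_sample(u10, 10)), 1:10)
  set.seed(12)
  u12 <- runif(12)
  sel4 <- interval_sample(u12, 4)
  ranks <- sort(match(sel4, order(u12, seq_along(u12))))
  expect_identical(ranks[1], 1L)
  expect_identical(ranks[4], 12L)
  gaps <- diff(ranks)
  expect_lte(max(gaps) - min(gaps), 1)     # even spacing
  short <- interval_sample(u10, 15)
  expect_true(isTRUE(attr(short, "shortfall")))
  expect_length(short, 10)
  expect_length(interval_sample(u10, 0), 0)
  # ties break by original index (stable)
  expect_identical(interval_sample(rep(0.5, 6), 2), c(1L, 6L))
})

test_that("buffer quotas follow floor division with earliest-seen remainder", {
  set.seed(5)
  imgs <- array(runif(600 * 4 * 4 * 3), dim = c(600, 4, 4, 3))
  labs <- rep(0:1, each = 300)
  u <- runif(600)
  buf <- memory_buffer(500)
  buf <- update_buffer(buf, imgs, labs, u, seed = 1)
  expect_equal(unname(vapply(buf$entries, function(e) length(e$labels),
                             integer(1))), c(250, 250))
  imgs2 <- array(runif(400 * 4 * 4 * 3), dim = c(400, 4, 4, 3))
  labs2 <- rep(2:3, each = 200)
  buf <- update_buffer(buf, imgs2, labs2, runif(400), seed = 2)
  expect_equal(unname(vapply(buf$entries, function(e) length(e$labels),
                             integer(1))), c(125, 125, 125, 125))
  expect_lte(buffer_size(buf), 500)
  # remainder slots go to earliest-seen classes
  q <- dscnl:::buffer_quotas(memory_buffer(200), 0:7)
  expect_true(all(q == 25))
  q2 <- dscnl:::buffer_quotas(memory_buffer(203), 0:7)
  expect_equal(unname(q2), c(26, 26, 26, 25, 25, 25, 25, 25))
})

test_that("buffer invariants hold across randomised task sequences", {
  set.seed(77)
  for (rep in 1:4) {
    cap <- sample(c(40, 60, 100), 1)
    buf <- memory_buffer(cap)
    classes_so_far <- integer(0)
    next_class <- 0L
    for (t in 1:4) {
      kt <- sample(1:3, 1)
      cls <- next_class + seq_len(kt) - 1L
      next_class <- next_class + kt
      n_c <- sample(10:40, kt, replace = TRUE)
      labs <- rep(cls, times = n_c)
      n <- length(labs)
      imgs <- array(runif(n * 4 * 4 * 1), dim = c(n, 4, 4, 1))
      u <- runif(n)
      buf <- update_buffer(buf, imgs, labs, u,
                           strategy = sample(c("uncertainty", "random",
                                               "reservoir"), 1),
                           seed = rep * 10 + t)
      classes_so_far <- c(classes_so_far, cls)
      expect_lte(buffer_size(buf), cap)
      quotas <- dscnl:::buffer_quotas(buf, classes_so_far)
      sizes <- vapply(buf$entries, function(e) length(e$labels),
                      integer(1))
      # per-class count never exceeds quota; equals it unless the class
      # ran short of candidates
      expect_true(all(sizes <= quotas[names(sizes)]))
      bc <- buffer_contents(buf)
      expect_identical(sort(unique(bc$labels)), sort(classes_so_far))
    }
  }
})

test_that("uncertainty-ordered shrinkage keeps both spectrum endpoints", {
  set.seed(9)
  imgs <- array(runif(100 * 4 * 4 * 1), dim = c(100, 4, 4, 1))
  u <- runif(100)
  buf <- memory_buffer(40)
  buf <- update_buffer(buf, imgs, rep(0L, 100), u, seed = 3)
  stored_u <- buf$entries[["0"]]$uncertainty
  expect_equal(min(stored_u), min(u))
  expect_equal(max(stored_u), max(u))
  # quota shrink from 40 to 20 on arrival of class 1
  buf <- update_buffer(buf, imgs, rep(1L, 100), u, seed = 4)
  kept <- buf$entries[["0"]]$uncertainty
  expect_length(kept, 20)
  expect_equal(range(kept), range(stored_u))
})

test_that("reservoir sampling is single-pass uniform", {
  expect_identical(reservoir_sample(5, 10, seed = 1), 1:5)
  n <- 400; cap <- 40
  counts <- integer(n)
  for (s in 1:300) {
    keep <- reservoir_sample(n, cap, seed = s)
    expect_length(keep, cap)
    expect_false(anyDuplicated(keep) > 0)
    counts[keep] <- counts[keep] + 1L
  }
  # each position retained with probability cap/n
  p <- stats::chisq.test(counts, p = rep(1 / n, n))$p.value
  expect_gt(p, 0.001)
})

test_that("random sampling ignores uncertainty by construction", {
  set.seed(1)
  idx <- 1:50
  a <- random_sample(idx, 10, seed = 5)
  b <- random_sample(idx, 10, seed = 5)
  expect_identical(a, b)
  expect_length(a, 10)
  expect_identical(random_sample(idx, 60, seed = 1), idx)
})

test_that("mislabelled samples carry higher vote uncertainty than clean ones", {
  diffs <- vapply(1:3, function(s) {
    st <- tiny_stream(noise_rate = 0.3, seed = 40 + s, n_per_class = 60,
                      n_classes = 4)
    td <- subset_dataset(st$train, st$tasks$indices[[1]])
    x <- as_image_matrix(td)
    set.seed(s)
    m <- new_backbone(ncol(x), 4, seed = s)
    m <- train_backbone(m, x, td$noisy_labels, st$tasks$tasks[[1]],
                        epochs = 10, lr = 1e-3)
    u <- sample_uncertainties(m, td$images,
                              augmentation_spec(S = 10, family = "mix"),
                              st$tasks$tasks[[1]], seed = s)
    clean <- td$noisy_labels == td$true_labels
    mean(u[!clean]) - mean(u[clean])
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})
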