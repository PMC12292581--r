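# Stochastic image transforms used for augmentation-vote uncertainty.
# All operate on an H x W x C array in [0,1] and clamp their output.
# Geometric transforms use nearest-neighbour resampling with
# edge-replicated (clamped) source indices.

geom_map <- function(img, src_y, src_x) {
  d <- dim(img)
  iy <- pmin(pmax(round(src_y), 1L), d[1])
  ix <- pmin(pmax(round(src_x), 1L), d[2])
  out <- img
  for (ch in seq_len(d[3]))
    out[, , ch] <- matrix(img[, , ch][cbind(iy, ix)], d[1], d[2])
  out
}

grid_coords <- function(d) {
  list(y = rep(seq_len(d[1]), times = d[2]),
       x = rep(seq_len(d[2]), each = d[1]))
}

tf_rotate <- function(img) {
  th <- stats::runif(1, -15, 15) * pi / 180
  d <- dim(img)
  g <- grid_coords(d)
  cy <- (d[1] + 1) / 2; cx <- (d[2] + 1) / 2
  dy <- g$y - cy; dx <- g$x - cx
  geom_map(img, cy + cos(th) * dy - sin(th) * dx,
           cx + sin(th) * dy + cos(th) * dx)
}

tf_translate <- function(img) {
  d <- dim(img)
  sy <- round(stats::runif(1, -0.1, 0.1) * d[1])
  sx <- round(stats::runif(1, -0.1, 0.1) * d[2])
  g <- grid_coords(d)
  geom_map(img, g$y - sy, g$x - sx)
}

tf_scale <- function(img) {
  s <- stats::runif(1, 0.9, 1.1)
  d <- dim(img)
  g <- grid_coords(d)
  cy <- (d[1] + 1) / 2; cx <- (d[2] + 1) / 2
  geom_map(img, cy + (g$y - cy) / s, cx + (g$x - cx) / s)
}

tf_hflip <- function(img) img[, rev(seq_len(dim(img)[2])), , drop = FALSE]

tf_brightness <- function(img) clamp01(img + stats::runif(1, -0.2, 0.2))

tf_contrast <- function(img) {
  f <- 1 + stats::runif(1, -0.2, 0.2)
  clamp01((img - mean(img)) * f + mean(img))
}

tf_noise <- function(img)
  clamp01(img + stats::rnorm(length(img), 0, stats::runif(1, 0, 0.05)))

tf_color_jitter <- function(img) {
  f <- 1 + stats::runif(dim(img)[3], -0.2, 0.2)
  clamp01(sweep(img, 3, f, "*"))
}

tf_cutout <- function(img) {
  d <- dim(img)
  # rectangle of at most 25% area: sides at most half the image
  hh <- sample.int(max(1L, floor(d[1] / 2)), 1)
  ww <- sample.int(max(1L, floor(d[2] / 2)), 1)
  y0 <- sample.int(d[1] - hh + 1L, 1)
  x0 <- sample.int(d[2] - ww + 1L, 1)
  img[y0:(y0 + hh - 1L), x0:(x0 + ww - 1L), ] <- 0.5
  img
}

tf_identity <- function(img) img

AFFINE_TRANSFORMS <- c("tf_rotate", "tf_translate", "tf_scale", "tf_hflip")
PIXEL_TRANSFORMS <- c("tf_brightness", "tf_contrast", "tf_noise",
                      "tf_color_jitter")

family_transforms <- function(family) {
  switch(family,
         affine = AFFINE_TRANSFORMS,
         pixel = PIXEL_TRANSFORMS,
         mix = c(AFFINE_TRANSFORMS, PIXEL_TRANSFORMS, "tf_cutout"),
         identity = "tf_identity",
         stop("unknown augmentation family: ", family))
}

#' Augmentation specification
#'
#' Defines the Monte-Carlo augmentation scheme for uncertainty
#' estimation: `S` stochastic copies, each produced by one transform
#' drawn uniformly from the family's transform set.  Families:
#' `affine` (rotation <= 15 deg, translation <= 10%, scale 0.9-1.1,
#' horizontal flip), `pixel` (brightness/contrast jitter <= 20%,
#' additive Gaussian noise sigma <= 0.05, per-channel colour jitter),
#' `mix` (affine and pixel plus CutOut of <= 25% area), and `identity`
#' (no-op, for calibration).
#'
#' @param S number of augmented copies (>= 1).
#' @param family one of `"affine"`, `"pixel"`, `"mix"`, `"identity"`.
#' @param seed optional integer seed; when set, [augment()] is
#'   bitwise-reproducible.
#' @return an `augmentation_spec` list.
#' @export
augmentation_spec <- function(S = 10, family = "mix", seed = NULL) {
  if (S < 1) stop("S must be >= 1")
  transforms <- family_transforms(family)
  structure(list(S = as.integer(S), family = family,
                 transforms = transforms, seed = seed),
            class = "augmentation_spec")
}

#' Generate S augmented copies of an image
#'
#' @param x an `H x W x C` image array in `[0,1]`.
#' @param spec an [augmentation_spec()].
#' @return an `S x H x W x C` array of augmented copies.
#' @export
augment <- function(x, spec) {
  stopifnot(inherits(spec, "augmentation_spec"))
  if (length(dim(x)) != 3L) stop("`x` must be an H x W x C array")
  if (!is.null(spec$seed)) {
    old <- local_seed(spec$seed)
    on.exit(restore_seed(old))
  }
  d <- dim(x)
  out <- array(0, dim = c(spec$S, d))
  picks <- sample(spec$transforms, spec$S, replace = TRUE)
  for (j in seq_len(spec$S))
    out[j, , , ] <- do.call(picks[j], list(x))
  out
}
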