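#' Latent face space with known geometry
#'
#' Draws a k-dimensional Gaussian embedding per exemplar. Pairwise Euclidean
#' distances over these embeddings define the ground-truth face-space geometry
#' that synthetic recordings and layer stacks are generated from, so that
#' downstream geometry-recovery analyses can be checked against a planted
#' truth.
#'
#' @param n_exemplars Number of face exemplars (default 10, one task set).
#' @param k Embedding dimension.
#' @param seed Integer seed.
#' @return Object of class `latent_face_space`: matrix `embeddings`
#'   (exemplars x k, rownames are exemplar ids), plus `k` and `seed`.
#' @export
latent_face_space <- function(n_exemplars = 10, k = 8, seed = 1L) {
  set.seed(seed)
  emb <- matrix(stats::rnorm(n_exemplars * k), n_exemplars, k)
  rownames(emb) <- sprintf("face_%02d", seq_len(n_exemplars))
  structure(list(embeddings = emb, k = k, seed = seed),
            class = "latent_face_space")
}

# smooth face-like base pattern in roughly [-2.5, 2.5], zero mean, unit sd
face_base_pattern <- function(side) {
  xs <- seq(-1, 1, length.out = side)
  gx <- matrix(xs, side, side, byrow = TRUE)
  gy <- matrix(xs, side, side)
  head_mask <- 1 - ((gx / 0.72)^2 + (gy / 0.92)^2)
  head_mask[head_mask < 0] <- 0
  blob <- function(cx, cy, s, a)
    a * exp(-(((gx - cx)^2 + (gy - cy)^2) / (2 * s^2)))
  jit <- function(s) stats::rnorm(1, 0, s)
  img <- 1.1 * sqrt(head_mask) +
    blob(-0.28 + jit(0.03), -0.22 + jit(0.03), 0.10 + abs(jit(0.02)), -0.9) +
    blob(0.28 + jit(0.03), -0.22 + jit(0.03), 0.10 + abs(jit(0.02)), -0.9) +
    blob(jit(0.02), 0.12 + jit(0.03), 0.08, 0.55) +
    blob(jit(0.03), 0.52 + jit(0.04), 0.14 + abs(jit(0.03)), -0.75)
  # low-frequency idiosyncratic field so exemplars differ beyond landmarks
  field <- matrix(stats::rnorm(64), 8, 8)
  img <- img + 0.35 * as.matrix(EBImage::resize(EBImage::Image(field),
                                                side, side))
  img <- (img - mean(img)) / stats::sd(img)
  img <- 2.6 * tanh(img / 2.6)        # bound the tails so 8-bit targets fit
  (img - mean(img)) / stats::sd(img)
}

#' Generate procedural face-like stimulus images
#'
#' Produces RGB images (values on the 8-bit 0-255 scale, stored as doubles)
#' whose measured low-level parameters - mean grayscale luminance, RMS
#' contrast and saturation, as defined in [image_params()] - hit the requested
#' targets. The image content is a smooth procedural "face" (head outline,
#' eyes, nose, mouth plus a per-exemplar random field); targets are achieved
#' by an exact affine mapping of the grayscale pattern followed by a
#' hue-preserving colorization, so measured luminance and contrast equal the
#' targets up to PNG quantization.
#'
#' @param n Number of images.
#' @param params Optional data.frame with columns `luminance`, `contrast`,
#'   `saturation` (recycled to `n` rows). Defaults emulate centred portrait
#'   photographs: luminance ~ N(128, 8), contrast ~ U(15, 28), saturation ~
#'   U(0.1, 0.3).
#' @param seed Integer seed.
#' @param side Image side in pixels.
#' @return List with `images` (list of side x side x 3 arrays, named by
#'   exemplar id) and `params` (data.frame of targets per image).
#' @export
generate_face_images <- function(n = 10, params = NULL, seed = 1L, side = 64) {
  set.seed(seed)
  if (is.null(params)) {
    params <- data.frame(luminance = stats::rnorm(n, 128, 8),
                         contrast = stats::runif(n, 15, 28),
                         saturation = stats::runif(n, 0.1, 0.3))
  }
  params <- params[rep_len(seq_len(nrow(params)), n), , drop = FALSE]
  rownames(params) <- params$exemplar_id <- sprintf("face_%02d", seq_len(n))
  imgs <- vector("list", n)
  for (i in seq_len(n)) {
    lum <- params$luminance[i]; con <- params$contrast[i]
    sat <- params$saturation[i]
    if (sat < 0 || sat > 1) stop("saturation target must lie in [0, 1]")
    base <- face_base_pattern(side)
    gray <- lum + con * base
    # colorization: R = g(1+a)/c0, G = g/c0, B = g(1-a)/c0 keeps the weighted
    # grayscale value exactly g and pixel saturation exactly 2a/(1+a)
    a <- sat / (2 - sat)
    c0 <- 1 + a * (0.299 - 0.114)
    top <- max(gray) * (1 + a) / c0
    if (min(gray) < 0 || top > 255)
      stop(sprintf(paste0("unreachable parameter combination for image %d: ",
                          "channel range [%.1f, %.1f] outside [0, 255]"),
                   i, min(gray) * (1 - a) / c0, top))
    img <- array(0, c(side, side, 3))
    img[, , 1] <- gray * (1 + a) / c0
    img[, , 2] <- gray / c0
    img[, , 3] <- gray * (1 - a) / c0
    imgs[[i]] <- img
  }
  names(imgs) <- params$exemplar_id
  list(images = imgs, params = params)
}

#' Write / read stimulus images as PNG
#'
#' @param images Named list of image arrays on the 0-255 scale.
#' @param dir Output directory (created if missing).
#' @return File paths, invisibly; `read_image_png` returns a 0-255 array.
#' @export
write_images_png <- function(images, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(images), function(id) {
    p <- file.path(dir, paste0(id, ".png"))
    png::writePNG(pmin(pmax(images[[id]] / 255, 0), 1), p)
    p
  }, character(1))
  invisible(paths)
}

#' @rdname write_images_png
#' @param path PNG file path.
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3 && dim(img)[3] == 4) img <- img[, , 1:3]
  img * 255
}
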