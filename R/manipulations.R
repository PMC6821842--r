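#' Match the mean luminance of an image set
#'
#' Shifts every image so that all share the set-mean grayscale luminance:
#' each image gets the difference between the set mean and its own luminance
#' added to all pixels. For color images the shift is carried on the value
#' plane of the HSV (hexcone) representation - value = max(R, G, B) - and
#' converted back, which preserves hue and saturation; grayscale images are
#' shifted directly. Pixels are clipped to [0, 255] afterwards; the clipped
#' fraction is recorded in the `clipped_fraction` attribute.
#'
#' @param images Named list of image arrays (0-255).
#' @return List of shifted images (same names) with a `clipped_fraction`
#'   attribute.
#' @export
match_luminance <- function(images) {
  stopifnot(length(images) >= 1)
  lums <- vapply(images, function(im) image_params(im)$luminance, numeric(1))
  target <- mean(lums)
  clipped <- 0; total <- 0
  out <- lapply(seq_along(images), function(i) {
    im <- images[[i]]
    if (length(dim(im)) == 3 && dim(im)[3] == 3) {
      # shifting the value plane changes grayscale-mean luminance by roughly the
      # luminance-to-value ratio, so solve for the value shift iteratively
      im2 <- im
      for (step in 1:3) {
        lum_now <- image_params(im2)$luminance
        v <- pmax(im2[, , 1], im2[, , 2], im2[, , 3])
        ratio <- lum_now / mean(v)
        d <- (target - lum_now) / ratio
        v_new <- v + d
        # scaling RGB by v_new / v keeps hue and hexcone saturation exact;
        # black pixels (v = 0) carry no hue and become neutral gray
        scale <- ifelse(v > 0, v_new / v, 0)
        for (ch in 1:3)
          im2[, , ch] <- ifelse(v > 0, im2[, , ch] * scale, pmax(v_new, 0))
      }
    } else {
      im2 <- im + (target - lums[i])
    }
    clipped <<- clipped + sum(im2 < 0 | im2 > 255)
    total <<- total + length(im2)
    pmin(pmax(im2, 0), 255)
  })
  names(out) <- names(images)
  attr(out, "clipped_fraction") <- clipped / total
  out
}

#' Convert an image to grayscale
#'
#' Applies the 0.299 R + 0.587 G + 0.114 B transformation and replicates the
#' result to three channels, so the image remains a valid network input.
#' Grayscale inputs are returned unchanged (replicated to three channels if
#' needed).
#'
#' @param img Image array (0-255).
#' @return h x w x 3 array with identical channels.
#' @export
to_grayscale <- function(img) {
  if (length(dim(img)) == 3 && dim(img)[3] == 3) {
    g <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  } else {
    g <- if (length(dim(img)) == 3) img[, , 1] else img
  }
  array(rep(g, 3), c(dim(g), 3))
}

#' Preprocess an image for network input
#'
#' Resizes (bilinear) to the network's declared square input side and
#' subtracts per-channel mean RGB values (as estimated from the network's
#' training set; 0 disables the subtraction).
#'
#' @param img Image array (0-255).
#' @param mean_rgb Length-3 numeric (or scalar) channel means.
#' @param side Target side in pixels (default 224).
#' @return side x side x 3 array.
#' @export
preprocess_for_network <- function(img, mean_rgb = 0, side = 224) {
  if (is.null(dim(img))) stop("input is not an image raster")
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  res <- as.array(EBImage::resize(EBImage::Image(img, colormode = "Color"),
                                  w = side, h = side))
  mean_rgb <- rep_len(mean_rgb, 3)
  for (ch in 1:3) res[, , ch] <- res[, , ch] - mean_rgb[ch]
  res
}

#' Impact of an image manipulation on the neural-to-layer match
#'
#' Quantifies how a manipulation of the input images changes a layer's
#' correlation to the neural distances: `delta = rho_original -
#' rho_manipulated`, with a permutation p-value (exemplar labels of the
#' neural representation shuffled, both correlations and their delta
#' recomputed; p = proportion of shuffled deltas at or above the observed
#' one, so an identical manipulation reads p = 1) and a 95 percent
#' bootstrap confidence interval over image pairs
#' around the original correlation, flagging whether the manipulated
#' correlation falls outside it.
#'
#' @param neural Neural distance vector.
#' @param layer_orig,layer_manip The layer's distance vectors for original
#'   and manipulated inputs (matched pair order).
#' @param n_perm Number of label shuffles.
#' @param n_boot Bootstrap resamples.
#' @param seed Integer seed.
#' @return List: `delta`, `rho_orig`, `rho_manip`, `p_perm`, `boot_ci`
#'   (length 2), `outside_ci`.
#' @export
manipulation_impact <- function(neural, layer_orig, layer_manip,
                                n_perm = 1000, n_boot = 1000, seed = 1L) {
  if (!inherits(neural, "distance_vector")) neural <- pairwise_distances(neural)
  if (length(layer_orig) != length(neural) ||
      length(layer_manip) != length(neural))
    stop("distance vectors must share the neural pair index")
  ro <- stats::cor(as.vector(neural), as.vector(layer_orig),
                   method = "spearman")
  rm_ <- stats::cor(as.vector(neural), as.vector(layer_manip),
                    method = "spearman")
  delta <- ro - rm_
  n <- attr(neural, "n_exemplars")
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(pm) {
    dv <- as.vector(permute_distance_vector(neural, sample.int(n)))
    stats::cor(dv, as.vector(layer_orig), method = "spearman") -
      stats::cor(dv, as.vector(layer_manip), method = "spearman")
  }, numeric(1))
  p_perm <- mean(null >= delta)
  x <- as.vector(neural); y <- as.vector(layer_orig)
  boots <- vapply(seq_len(n_boot), function(b) {
    i <- sample.int(length(x), replace = TRUE)
    if (stats::sd(x[i]) == 0 || stats::sd(y[i]) == 0) return(NA_real_)
    stats::cor(x[i], y[i], method = "spearman")
  }, numeric(1))
  ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  list(delta = delta, rho_orig = ro, rho_manip = rm_, p_perm = p_perm,
       boot_ci = ci, outside_ci = rm_ < ci[1] | rm_ > ci[2])
}

#' Self-correlation of a layer across an image manipulation
#'
#' Spearman correlation between a layer's pairwise distance vectors for the
#' original and the manipulated image set - near 1 when the manipulation
#' barely moves the layer's geometry.
#'
#' @param layer_orig,layer_manip Distance vectors over the same pairs.
#' @return Spearman's rho.
#' @export
layer_self_correlation <- function(layer_orig, layer_manip) {
  stats::cor(as.vector(layer_orig), as.vector(layer_manip),
             method = "spearman")
}

#' Nearest-neighbor identity decoding across manipulation conditions
#'
#' Pools activations of the same identities under several conditions,
#' repeatedly holds out one randomly chosen image per identity as the test
#' set, classifies each test image by the identity of its Euclidean nearest
#' neighbor among the remaining images, and averages accuracy over
#' repetitions.
#'
#' @param activations Named list of matrices (identities x units), one per
#'   condition, identical row order.
#' @param n_rep Number of hold-out repetitions.
#' @param seed Integer seed.
#' @return Mean classification accuracy.
#' @export
identity_nn_decoding <- function(activations, n_rep = 1000, seed = 1L) {
  stopifnot(length(activations) >= 2)
  n_id <- nrow(activations[[1]])
  for (a in activations)
    if (nrow(a) != n_id) stop("conditions differ in identity count")
  all_mat <- do.call(rbind, activations)
  ident <- rep(seq_len(n_id), times = length(activations))
  cond <- rep(seq_along(activations), each = n_id)
  set.seed(seed)
  acc <- vapply(seq_len(n_rep), function(rp) {
    test_rows <- vapply(seq_len(n_id), function(id) {
      rows <- which(ident == id)
      rows[sample.int(length(rows), 1L)]
    }, integer(1))
    train_rows <- setdiff(seq_along(ident), test_rows)
    d <- euclidean_cross(all_mat[test_rows, , drop = FALSE],
                         all_mat[train_rows, , drop = FALSE])
    pred <- ident[train_rows][apply(d, 1, which.min)]
    mean(pred == seq_len(n_id))
  }, numeric(1))
  mean(acc)
}

#' Cross-view distance matrix and view-invariance score
#'
#' Builds the full matrix of Euclidean distances between frontal-view and
#' profile-view activations of the same identities. The diagonal holds the
#' same-identity cross-view distances; the invariance score is the fraction
#' of identities whose diagonal entry is the minimum of its row (the
#' frontal view is closer to its own profile than to any other identity's).
#'
#' @param frontal,profile Matrices identities x units, same row order.
#' @return Object of class `viewpoint_matrix`: list with `distances`,
#'   `identities`, `invariance_score`.
#' @export
viewpoint_matrix <- function(frontal, profile) {
  if (nrow(frontal) != nrow(profile))
    stop("frontal and profile identity lists differ")
  d <- euclidean_cross(as.matrix(frontal), as.matrix(profile))
  score <- mean(apply(d, 1, which.min) == seq_len(nrow(d)))
  structure(list(distances = d,
                 identities = rownames(frontal) %||%
                   sprintf("id_%02d", seq_len(nrow(d))),
                 invariance_score = score),
            class = "viewpoint_matrix")
}

#' @export
print.viewpoint_matrix <- function(x, ...) {
  cat(sprintf("viewpoint_matrix: %d identities, invariance score %.2f\n",
              length(x$identities), x$invariance_score))
  invisible(x)
}
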