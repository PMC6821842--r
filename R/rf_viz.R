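#' Receptive-field reconstruction of a unit by deconvolution
#'
#' Feeds the image forward through the network (recording pooling switches
#' and ReLU activation masks), zeroes every unit in the target layer except
#' the chosen one (which keeps its actual activation), and propagates that
#' signal back to image space through transposed convolutions, switch-based
#' unpooling and ReLU masking. For a purely linear network the result is
#' exactly the adjoint-operator image; fully connected units are handled by
#' the transpose of their weight vector.
#'
#' @param net A [build_toy_convnet()] object.
#' @param image Input image (side x side x channels, or matrix).
#' @param layer Layer name or index.
#' @param unit Linear index of the target unit within the layer's output.
#' @return Object of class `rf_image`: list with `base`, `reconstruction`,
#'   `delta` (NULL here), `activation`.
#' @export
deconvolve_unit <- function(net, image, layer, unit) {
  li <- layer_index_by_name(net, layer)
  fw <- convnet_forward(net, image)
  out <- fw$outputs[[li]]
  if (unit < 1 || unit > length(out)) stop("unit index out of range")
  g <- array(0, dim(out) %||% length(out))
  g[unit] <- out[unit]
  recon <- convnet_backward(net, fw$cache, g, li)
  structure(list(base = image, reconstruction = recon, delta = NULL,
                 activation = out[unit]),
            class = "rf_image")
}

#' @export
print.rf_image <- function(x, ...) {
  cat(sprintf("rf_image: activation %.4g, reconstruction energy %.4g%s\n",
              x$activation, sum(x$reconstruction^2),
              if (!is.null(x$delta)) sprintf(", delta energy %.4g",
                                             sum(x$delta^2)) else ""))
  invisible(x)
}

#' Activation maximization of a unit by iterated deconvolution
#'
#' Iteratively alters the input image to drive the target unit: each
#' iteration reconstructs the unit's receptive field by deconvolution and
#' adds it, scaled by the learning rate, to the current image, which is then
#' fed forward again (default 300 iterations at learning rate 200). The
#' image is deliberately not re-clipped to [0, 255] during the ascent -
#' the delta visualization requires unbounded values; clip only on export.
#'
#' @param net A [build_toy_convnet()] object.
#' @param image Starting image.
#' @param layer Layer name or index.
#' @param unit Linear unit index in that layer.
#' @param n_iter Number of iterations.
#' @param lr Learning rate multiplying each reconstruction.
#' @return Object of class `rf_image` with `delta` (altered - original) and
#'   an `activation_trace` attribute (per-iteration activation of the
#'   unit).
#' @export
activation_maximization <- function(net, image, layer, unit, n_iter = 300,
                                    lr = 200) {
  li <- layer_index_by_name(net, layer)
  x <- image
  if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1L)
  trace <- numeric(n_iter)
  recon <- NULL
  for (it in seq_len(n_iter)) {
    fw <- convnet_forward(net, x)
    out <- fw$outputs[[li]]
    if (unit < 1 || unit > length(out)) stop("unit index out of range")
    trace[it] <- out[unit]
    g <- array(0, dim(out) %||% length(out))
    g[unit] <- out[unit]
    recon <- convnet_backward(net, fw$cache, g, li)
    x <- x + lr * recon
    if (!all(is.finite(x)))
      stop("numeric overflow during activation maximization at iteration ",
           it)
  }
  base <- image
  if (length(dim(base)) == 2) dim(base) <- c(dim(base), 1L)
  structure(list(base = image, reconstruction = recon, delta = x - base,
                 activation = trace[n_iter]),
            activation_trace = trace, class = "rf_image")
}

#' Export the panels of a receptive-field visualization as PNG
#'
#' Writes base image, reconstruction and (if present) delta. Display
#' normalization - stretching the active range to full contrast - is
#' applied at render time only; stored arrays are never modified.
#'
#' @param rf An `rf_image`.
#' @param dir Output directory.
#' @param stretch Contrast-stretch the reconstruction/delta for display.
#' @return Paths written, invisibly.
#' @export
write_rf_png <- function(rf, dir, stretch = TRUE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  norm01 <- function(a, stretch_it) {
    a <- drop(a)
    if (stretch_it && diff(range(a)) > 0)
      (a - min(a)) / diff(range(a))
    else pmin(pmax(a / 255, 0), 1)
  }
  paths <- c(base = file.path(dir, "base.png"),
             reconstruction = file.path(dir, "reconstruction.png"))
  png::writePNG(norm01(rf$base, FALSE), paths["base"])
  png::writePNG(norm01(rf$reconstruction, stretch), paths["reconstruction"])
  if (!is.null(rf$delta)) {
    paths["delta"] <- file.path(dir, "delta.png")
    png::writePNG(norm01(rf$delta, stretch), paths["delta"])
  }
  invisible(paths)
}
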