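# Minimal convolutional network with explicit forward/backward passes.
# Images are arrays h x w x channels; convolutions are "valid" (no padding)
# unless a pad is given; pooling is non-overlapping max pooling with recorded
# switch positions so the backward pass can unpool exactly.

#' Build a small convolutional network with computable receptive fields
#'
#' Constructs a reduced instance of the evaluation architecture: `depth`
#' stacked 3x3 stride-1 convolutions (ReLU optional), one 2x2 max-pooling
#' stage, and a final fully connected layer. Weights are reproducible from
#' the seed; `xavier_normal` draws them with variance 2 / (fan_in + fan_out),
#' `fixed` uses a deterministic separable pattern (useful for closed-form
#' checks).
#'
#' @param depth Number of convolution layers (>= 1).
#' @param seed Integer seed.
#' @param init `"xavier_normal"` or `"fixed"`.
#' @param input_size Input side in pixels.
#' @param in_channels Input channels (1 for grayscale, 3 for RGB).
#' @param channels Output channels per conv layer (recycled to `depth`).
#' @param relu Apply ReLU after each conv (set FALSE for a purely linear
#'   network).
#' @param pool Include the 2x2 max-pool stage after the last conv.
#' @param n_out Fully connected output units.
#' @return Object of class `toy_convnet`.
#' @export
build_toy_convnet <- function(depth = 3, seed = 1L, init = "xavier_normal",
                              input_size = 32, in_channels = 1,
                              channels = c(4, 8, 8), relu = TRUE,
                              pool = TRUE, n_out = 10) {
  init <- match.arg(init, c("xavier_normal", "fixed"))
  set.seed(seed)
  channels <- rep_len(channels, depth)
  k <- 3L
  draw <- function(kh, kw, cin, cout) {
    n_w <- kh * kw * cin * cout
    if (init == "xavier_normal") {
      fan_in <- kh * kw * cin; fan_out <- kh * kw * cout
      array(stats::rnorm(n_w, 0, sqrt(2 / (fan_in + fan_out))),
            c(kh, kw, cin, cout))
    } else {
      array(sin(seq_len(n_w)) / (kh * kw * cin), c(kh, kw, cin, cout))
    }
  }
  layers <- list()
  side <- input_size; cin <- in_channels
  for (d in seq_len(depth)) {
    layers[[length(layers) + 1L]] <-
      list(type = "conv", kernel = draw(k, k, cin, channels[d]),
           stride = 1L, relu = relu, name = sprintf("conv%d", d))
    side <- side - k + 1L
    cin <- channels[d]
  }
  if (pool) {
    layers[[length(layers) + 1L]] <-
      list(type = "pool", size = 2L, name = "pool1")
    side <- side %/% 2L
  }
  n_feat <- side * side * cin
  w_fc <- if (init == "xavier_normal") {
    matrix(stats::rnorm(n_out * n_feat, 0, sqrt(2 / (n_feat + n_out))),
           n_out, n_feat)
  } else {
    matrix(sin(seq_len(n_out * n_feat)) / n_feat, n_out, n_feat)
  }
  layers[[length(layers) + 1L]] <-
    list(type = "fc", weights = w_fc, relu = FALSE, name = "fc1")
  structure(list(layers = layers, input_size = input_size,
                 in_channels = in_channels, seed = seed, init = init),
            class = "toy_convnet")
}

#' @export
print.toy_convnet <- function(x, ...) {
  cat(sprintf("toy_convnet: %s on %dx%dx%d input (seed %d, %s init)\n",
              paste(vapply(x$layers, `[[`, "", "name"), collapse = " -> "),
              x$input_size, x$input_size, x$in_channels, x$seed, x$init))
  invisible(x)
}

# im2col for valid convolution: rows = output positions (row-major over the
# output grid with row varying fastest, matching R array order), cols =
# kh*kw*cin patch entries.
im2col <- function(x, kh, kw, stride = 1L) {
  h <- dim(x)[1]; w <- dim(x)[2]; cin <- dim(x)[3]
  oh <- (h - kh) %/% stride + 1L; ow <- (w - kw) %/% stride + 1L
  or_ <- rep(seq(1L, by = stride, length.out = oh), times = ow)
  oc_ <- rep(seq(1L, by = stride, length.out = ow), each = oh)
  idx <- matrix(0L, oh * ow, kh * kw * cin)
  col <- 1L
  for (ch in seq_len(cin)) for (j in seq_len(kw)) for (i in seq_len(kh)) {
    idx[, col] <- (ch - 1L) * h * w + (oc_ + j - 2L) * h + (or_ + i - 1L)
    col <- col + 1L
  }
  list(mat = matrix(x[idx], nrow = oh * ow), idx = idx, oh = oh, ow = ow)
}

conv_forward <- function(x, kernel, stride = 1L) {
  kh <- dim(kernel)[1]; kw <- dim(kernel)[2]
  cin <- dim(kernel)[3]; cout <- dim(kernel)[4]
  ic <- im2col(x, kh, kw, stride)
  wmat <- matrix(kernel, ncol = cout)          # (kh*kw*cin) x cout
  out <- ic$mat %*% wmat
  list(out = array(out, c(ic$oh, ic$ow, cout)), idx = ic$idx,
       oh = ic$oh, ow = ic$ow)
}

# adjoint of conv_forward: scatter-add patch contributions back to the input
conv_backward <- function(grad_out, kernel, idx, in_dim) {
  cout <- dim(kernel)[4]
  wmat <- matrix(kernel, ncol = cout)
  g2 <- matrix(grad_out, ncol = cout) %*% t(wmat)  # n_pos x (kh*kw*cin)
  gx <- numeric(prod(in_dim))
  for (col in seq_len(ncol(g2)))
    gx[idx[, col]] <- gx[idx[, col]] + g2[, col]
  array(gx, in_dim)
}

pool_forward <- function(x, size = 2L) {
  h <- dim(x)[1]; w <- dim(x)[2]; cin <- dim(x)[3]
  oh <- h %/% size; ow <- w %/% size
  out <- array(0, c(oh, ow, cin))
  switches <- array(0L, c(oh, ow, cin))
  for (ch in seq_len(cin)) for (j in seq_len(ow)) for (i in seq_len(oh)) {
    ri <- (i - 1L) * size + seq_len(size)
    cj <- (j - 1L) * size + seq_len(size)
    block <- x[ri, cj, ch]
    m <- which.max(block)
    out[i, j, ch] <- block[m]
    switches[i, j, ch] <- (ch - 1L) * h * w +
      (cj[(m - 1L) %/% size + 1L] - 1L) * h + ri[(m - 1L) %% size + 1L]
  }
  list(out = out, switches = switches)
}

pool_backward <- function(grad_out, switches, in_dim) {
  gx <- numeric(prod(in_dim))
  gx[as.vector(switches)] <- as.vector(grad_out)
  array(gx, in_dim)
}

#' Forward pass through a toy convnet
#'
#' Records per-layer outputs plus the pooling switches and ReLU masks needed
#' for an exact backward (deconvolution) pass.
#'
#' @param net A [build_toy_convnet()] object.
#' @param image Input array (side x side x in_channels, or a matrix for
#'   single-channel input).
#' @return List with `outputs` (per-layer activation arrays, named) and the
#'   recorded `cache`.
#' @export
convnet_forward <- function(net, image) {
  if (length(dim(image)) == 2) dim(image) <- c(dim(image), 1L)
  stopifnot(dim(image)[1] == net$input_size,
            dim(image)[3] == net$in_channels)
  x <- image
  outputs <- list(); cache <- list()
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    if (ly$type == "conv") {
      cf <- conv_forward(x, ly$kernel, ly$stride)
      pre <- cf$out
      mask <- NULL
      if (isTRUE(ly$relu)) {
        mask <- pre > 0
        pre[!mask] <- 0
      }
      cache[[l]] <- list(idx = cf$idx, in_dim = dim(x), mask = mask)
      x <- pre
    } else if (ly$type == "pool") {
      pf <- pool_forward(x, ly$size)
      cache[[l]] <- list(switches = pf$switches, in_dim = dim(x))
      x <- pf$out
    } else if (ly$type == "fc") {
      v <- as.vector(x)
      pre <- as.vector(ly$weights %*% v)
      mask <- NULL
      if (isTRUE(ly$relu)) {
        mask <- pre > 0
        pre[!mask] <- 0
      }
      cache[[l]] <- list(in_dim = dim(x), mask = mask)
      x <- pre
    }
    outputs[[ly$name]] <- x
  }
  list(outputs = outputs, cache = cache)
}

# backward (deconvolution) pass from layer `layer_index`, starting from
# signal `g` shaped like that layer's output; ReLU stages mask the backward
# signal by the forward activation pattern
convnet_backward <- function(net, cache, g, layer_index) {
  for (l in rev(seq_len(layer_index))) {
    ly <- net$layers[[l]]
    cc <- cache[[l]]
    if (!is.null(cc$mask)) g <- g * cc$mask
    if (ly$type == "conv") {
      g <- conv_backward(g, ly$kernel, cc$idx, cc$in_dim)
    } else if (ly$type == "pool") {
      g <- pool_backward(g, cc$switches, cc$in_dim)
    } else if (ly$type == "fc") {
      g <- array(as.vector(t(ly$weights) %*% as.vector(g)), cc$in_dim)
    }
  }
  g
}

layer_index_by_name <- function(net, layer) {
  if (is.numeric(layer)) return(as.integer(layer))
  i <- match(layer, vapply(net$layers, `[[`, "", "name"))
  if (is.na(i)) stop("no such layer: ", layer)
  i
}

#' Receptive-field arithmetic for toy convnet units
#'
#' Computes, for one unit of a convolution or pooling layer, the box of input
#' pixels that can influence it, from the kernel sizes and strides alone.
#' Fully connected units see the whole input.
#'
#' @param net A [build_toy_convnet()] object.
#' @param layer Layer name or index.
#' @param row,col Spatial position of the unit in that layer.
#' @return List with `rows` and `cols`, the inclusive input pixel ranges.
#' @export
receptive_field_box <- function(net, layer, row = 1L, col = 1L) {
  li <- layer_index_by_name(net, layer)
  start <- 1L; jump <- 1L; size <- 1L
  for (l in seq_len(li)) {
    ly <- net$layers[[l]]
    if (ly$type == "conv") {
      size <- size + (dim(ly$kernel)[1] - 1L) * jump
      jump <- jump * ly$stride
    } else if (ly$type == "pool") {
      size <- size + (ly$size - 1L) * jump
      jump <- jump * ly$size
    } else {
      return(list(rows = c(1L, net$input_size),
                  cols = c(1L, net$input_size)))
    }
  }
  r0 <- start + (row - 1L) * jump
  c0 <- start + (col - 1L) * jump
  list(rows = c(r0, min(r0 + size - 1L, net$input_size)),
       cols = c(c0, min(c0 + size - 1L, net$input_size)))
}
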