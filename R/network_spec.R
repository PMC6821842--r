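#' Architecture of the evaluation network family
#'
#' Structural description of the VGG-style face-recognition network the
#' layer-wise analyses are defined over: five convolutional blocks (2, 2, 3,
#' 3, 3 convolution layers, each ReLU-rectified, each block ending in max
#' pooling), followed by three fully connected layers, a 224-pixel square
#' input, and 2622 identity classes. Weights are out of scope; the object is
#' structural metadata used to enumerate evaluation layers and to scale down
#' toy instances.
#'
#' @param input_side Input image side in pixels.
#' @param n_classes Number of output identity classes.
#' @return Object of class `network_spec`.
#' @export
vgg_architecture <- function(input_side = 224, n_classes = 2622) {
  structure(list(
    conv_per_block = c(2L, 2L, 3L, 3L, 3L),
    channels = c(64L, 128L, 256L, 512L, 512L),
    fc_sizes = c(4096L, 4096L, n_classes),
    input_side = as.integer(input_side),
    n_classes = as.integer(n_classes)),
    class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf(paste0("network_spec: %d conv layers in %d blocks, %d fc ",
                     "layers, input %dx%d, %d classes\n"),
              sum(x$conv_per_block), length(x$conv_per_block),
              length(x$fc_sizes), x$input_side, x$input_side, x$n_classes))
  invisible(x)
}

#' Canonical ordered list of evaluation layers
#'
#' Enumerates the layers whose activation geometry is evaluated: the 13
#' rectified convolution outputs (`conv1_1` ... `conv5_3`), the 5 pooling
#' outputs (`pool1` ... `pool5`), the 3 fully connected outputs
#' (`fc6` ... `fc8`) and, by default, the final class-score `output`, for 22
#' entries in feedforward order.
#'
#' @param spec A [vgg_architecture()] object.
#' @param include_output Include the final class-score entry (default TRUE).
#' @return Character vector of layer names.
#' @export
enumerate_layers <- function(spec = vgg_architecture(),
                             include_output = TRUE) {
  if (!inherits(spec, "network_spec")) stop("malformed architecture spec")
  nm <- character(0)
  for (b in seq_along(spec$conv_per_block)) {
    nm <- c(nm, sprintf("conv%d_%d", b, seq_len(spec$conv_per_block[b])),
            sprintf("pool%d", b))
  }
  nm <- c(nm, sprintf("fc%d", 5 + seq_along(spec$fc_sizes)))
  if (include_output) nm <- c(nm, "output")
  nm
}

#' Save / load layer activation matrices
#'
#' Plain-text activation container: a directory holding `index.json` (ordered
#' layer names and exemplar ids) and one TSV matrix per layer (rows =
#' exemplars). `load_external_activations` validates exemplar ids against the
#' stimulus set, reorders rows to the requested id order and layers to the
#' canonical evaluation order, and tolerates missing layers with a warning -
#' the adapter for externally computed network activations.
#'
#' @param stack A `layer_stack` (or any list of `(name, activations)`).
#' @param dir Container directory.
#' @return `dir` invisibly; the loader returns a `layer_stack`.
#' @export
save_activations <- function(stack, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ids <- rownames(stack$layers[[1]]$activations)
  jsonlite::write_json(list(layers = names(stack$layers), exemplar_ids = ids),
                       file.path(dir, "index.json"))
  for (ly in stack$layers) {
    utils::write.table(ly$activations,
                       file.path(dir, paste0(ly$name, ".tsv")),
                       sep = "\t", quote = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' @rdname save_activations
#' @param exemplar_ids Expected exemplar ids (order is enforced).
#' @param canonical Canonical layer order (default [enumerate_layers()]).
#' @export
load_external_activations <- function(dir, exemplar_ids,
                                      canonical = enumerate_layers()) {
  idx <- jsonlite::read_json(file.path(dir, "index.json"),
                             simplifyVector = TRUE)
  if (!setequal(idx$exemplar_ids, exemplar_ids))
    stop("exemplar ids in activation container do not match the stimulus set")
  present <- intersect(canonical, idx$layers)
  extra <- setdiff(idx$layers, canonical)
  present <- c(present, extra)
  if (length(setdiff(canonical, idx$layers)))
    warning(sprintf("%d of %d canonical layers missing; proceeding with %d",
                    length(setdiff(canonical, idx$layers)), length(canonical),
                    length(present)))
  layers <- lapply(present, function(nm) {
    tab <- utils::read.delim(file.path(dir, paste0(nm, ".tsv")),
                             header = FALSE, row.names = 1)
    act <- as.matrix(tab)[exemplar_ids, , drop = FALSE]
    dimnames(act) <- list(exemplar_ids, NULL)
    list(name = nm, activations = act)
  })
  names(layers) <- present
  structure(list(layers = layers, match_profile = NULL, seed = NA),
            class = "layer_stack")
}
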