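#' Pairwise Euclidean distances of a representation
#'
#' Computes the Euclidean distance between all unordered row pairs of an
#' exemplars-by-features matrix, in the canonical (i < j, i varying slowest)
#' order; N exemplars give N(N-1)/2 values (45 at N = 10).
#'
#' @param x Numeric matrix, one row per exemplar (finite values, equal
#'   lengths), or a per-layer activation matrix.
#' @return Object of class `distance_vector`: numeric vector with
#'   `pair_index` (2-column matrix) and `n_exemplars` attributes.
#' @export
pairwise_distances <- function(x) {
  x <- as.matrix(x)
  stopifnot_finite(x, "representation")
  n <- nrow(x)
  if (n < 2) stop("need at least two exemplars")
  v <- as.vector(stats::dist(x))
  structure(v, pair_index = t(utils::combn(n, 2)), n_exemplars = n,
            class = "distance_vector")
}

# distance vector after relabelling exemplars by permutation `perm`
permute_distance_vector <- function(dv, perm) {
  n <- attr(dv, "n_exemplars")
  full <- matrix(0, n, n)
  pi_ <- attr(dv, "pair_index")
  full[pi_] <- dv
  full <- full + t(full)
  shuffled <- full[perm, perm]
  structure(shuffled[pi_], pair_index = pi_, n_exemplars = n,
            class = "distance_vector")
}

# coerce a layer_stack or list of matrices/distance vectors to a named list
# of distance vectors
layer_distance_list <- function(layers) {
  if (inherits(layers, "layer_stack"))
    layers <- lapply(layers$layers, `[[`, "activations")
  lapply(layers, function(l) {
    if (inherits(l, "distance_vector")) l else pairwise_distances(l)
  })
}

#' Correlate a neural distance vector with every network layer
#'
#' Spearman correlation between the neural pairwise-distance vector and each
#' layer's distance vector; significance per layer from a permutation null in
#' which exemplar labels of the neural representation are shuffled and its
#' distance vector recomputed (layer vectors stay fixed), p being the
#' proportion of null correlations exceeding the observed one;
#' Benjamini-Hochberg FDR across layers.
#'
#' @param neural A [pairwise_distances()] vector (or exemplars x features
#'   matrix).
#' @param layers A `layer_stack`, or a named list of activation matrices or
#'   distance vectors.
#' @param n_perm Number of exemplar-label shuffles.
#' @param seed Integer seed.
#' @param fdr_alpha Significance level applied to FDR-corrected p-values.
#' @return A `layer_profile` data.frame: `layer`, `rho`, `p_perm`, `p_fdr`,
#'   `significant`.
#' @export
correlate_profile <- function(neural, layers, n_perm = 1000, seed = 1L,
                              fdr_alpha = 0.05) {
  if (!inherits(neural, "distance_vector")) neural <- pairwise_distances(neural)
  if (stats::sd(neural) == 0)
    stop("neural distance vector is constant; rank correlation undefined")
  lds <- layer_distance_list(layers)
  if (any(vapply(lds, length, 1L) != length(neural)))
    stop("layer distance vectors do not match the neural pair index")
  lmat <- apply(vapply(lds, as.vector, numeric(length(neural))), 2, rank)
  rho <- spearman_vs_ranked(as.vector(neural), lmat)
  n <- attr(neural, "n_exemplars")
  set.seed(seed)
  null <- matrix(0, n_perm, length(lds))
  for (pm in seq_len(n_perm)) {
    dv <- permute_distance_vector(neural, sample.int(n))
    null[pm, ] <- spearman_vs_ranked(as.vector(dv), lmat)
  }
  p_perm <- colMeans(sweep(null, 2, rho, ">"))
  p_fdr <- stats::p.adjust(p_perm, method = "BH")
  structure(data.frame(layer = names(lds), rho = rho, p_perm = p_perm,
                       p_fdr = p_fdr, significant = p_fdr < fdr_alpha,
                       stringsAsFactors = FALSE),
            n_perm = n_perm, seed = seed,
            class = c("layer_profile", "data.frame"))
}

#' Fisher-z weighted average of layer profiles across sets
#'
#' Pools per-layer correlations across stimulus sets: each coefficient is
#' Fisher-z transformed, averaged with weights equal to the number of face
#' contacts in its set, given a weighted standard error, and both are
#' transformed back. A single-set input is returned unchanged (SE 0).
#'
#' @param profiles List of `layer_profile` objects over identical layers.
#' @param weights Positive numeric weights (face-contact counts per set).
#' @return A `weighted_profile` data.frame: `layer`, `rho`, `sem`.
#' @export
weighted_profile <- function(profiles, weights) {
  stopifnot(length(profiles) == length(weights), all(weights > 0))
  layers <- profiles[[1]]$layer
  for (p in profiles)
    if (!identical(p$layer, layers)) stop("profiles differ in layer lists")
  z <- vapply(profiles, function(p) fisher_z(p$rho), numeric(length(layers)))
  z <- matrix(z, nrow = length(layers))
  w <- weights
  rz_hat <- as.vector(z %*% w) / sum(w)
  n_sets <- length(w)
  se_z <- as.vector(((z - rz_hat)^2) %*% w) / (sqrt(n_sets) * sum(w))
  structure(data.frame(layer = layers, rho = fisher_z_inv(rz_hat),
                       sem = fisher_z_inv(se_z), stringsAsFactors = FALSE),
            weights = w, class = c("weighted_profile", "data.frame"))
}

#' Bootstrap s.e.m. of a layer correlation over image pairs
#'
#' Resamples the pair list with replacement, recomputes the Spearman
#' correlation per resample, and returns the SD across resamples. Resamples
#' in which either vector becomes constant (rank correlation undefined) are
#' dropped.
#'
#' @param neural,layer Distance vectors over the same pair index.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @return Bootstrap s.e.m. (scalar).
#' @export
bootstrap_sem_pairs <- function(neural, layer, n_boot = 1000, seed = 1L) {
  x <- as.vector(neural); y <- as.vector(layer)
  if (length(x) < 3) stop("need at least 3 pairs to bootstrap")
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(b) {
    i <- sample.int(length(x), replace = TRUE)
    if (stats::sd(x[i]) == 0 || stats::sd(y[i]) == 0) return(NA_real_)
    stats::cor(x[i], y[i], method = "spearman")
  }, numeric(1))
  stats::sd(reps[!is.na(reps)])
}

#' Trial-averaged neural representation from the grand matrix
#'
#' Averages the grand matrix G across the trials dimension (NA repetitions
#' ignored) and flattens to an exemplars x (contacts * timepoints) pattern
#' matrix; optionally restricted to a time window, a contact subset, or
#' collapsed to the temporal mean per cell.
#'
#' @param G A [build_response_matrix()] array.
#' @param window Optional half-open ms window within the response epoch.
#' @param time_average Collapse each cell to its temporal mean.
#' @param contacts Optional contact indices or ids.
#' @return Numeric matrix, rownames = exemplar ids.
#' @export
neural_patterns <- function(G, window = NULL, time_average = FALSE,
                            contacts = NULL) {
  time_ms <- attr(G, "time_ms")
  ci <- seq_len(dim(G)[2])
  if (!is.null(contacts)) {
    ci <- if (is.character(contacts)) match(contacts, attr(G, "contact_ids"))
          else contacts
  }
  tw <- if (is.null(window)) seq_along(time_ms)
        else which(time_ms >= window[1] & time_ms < window[2])
  if (!length(tw)) stop("window outside the response epoch")
  avg <- apply(G[, ci, , tw, drop = FALSE], c(1, 2, 4), mean, na.rm = TRUE)
  if (time_average) avg <- apply(avg, c(1, 2), mean)
  out <- matrix(avg, nrow = dim(G)[1])
  rownames(out) <- attr(G, "exemplar_ids")
  out
}

#' Layer correlation profiles in sliding time windows
#'
#' Rebuilds the neural representation in successive `[start, start +
#' window)` ms windows (stride `stride_ms`) and computes the full layer
#' profile per window, together with the maximally correlated layer.
#'
#' @param G A [build_response_matrix()] array over `[50, 500)` ms.
#' @param layers As in [correlate_profile()].
#' @param window_ms,stride_ms Window length and stride in ms.
#' @param n_perm,seed,fdr_alpha Passed to [correlate_profile()].
#' @return List with `profiles` (named by window start), `argmax_layer`, and
#'   `window_starts`.
#' @export
sliding_window_profile <- function(G, layers, window_ms = 200,
                                   stride_ms = 50, n_perm = 1000, seed = 1L,
                                   fdr_alpha = 0.05) {
  time_ms <- attr(G, "time_ms")
  t0 <- min(time_ms); t1 <- max(time_ms) + diff(time_ms)[1]
  if (window_ms > t1 - t0) stop("window longer than the response epoch")
  starts <- seq(t0, t1 - window_ms, by = stride_ms)
  profiles <- lapply(seq_along(starts), function(i) {
    rep_ <- neural_patterns(G, window = c(starts[i], starts[i] + window_ms))
    correlate_profile(pairwise_distances(rep_), layers, n_perm = n_perm,
                      seed = derive_seed(seed, i), fdr_alpha = fdr_alpha)
  })
  names(profiles) <- sprintf("t%d", starts)
  list(profiles = profiles,
       argmax_layer = vapply(profiles, function(p) p$layer[which.max(p$rho)],
                             character(1)),
       window_starts = starts)
}

#' Layer profile after averaging the response across time
#'
#' Collapses every cell of the grand matrix to its temporal mean before
#' computing distances, removing the information carried by the dynamic
#' response profile, then correlates with the layers as usual.
#'
#' @inheritParams sliding_window_profile
#' @return A `layer_profile`.
#' @export
time_averaged_profile <- function(G, layers, n_perm = 1000, seed = 1L,
                                  fdr_alpha = 0.05) {
  rep_ <- neural_patterns(G, time_average = TRUE)
  correlate_profile(pairwise_distances(rep_), layers, n_perm = n_perm,
                    seed = seed, fdr_alpha = fdr_alpha)
}

#' Low-level image parameters
#'
#' Measures, on the 0-255 scale: luminance (mean grayscale pixel), RMS
#' contrast (SD of grayscale pixels), gradient (sum over pixels of the
#' gradient magnitude, central differences), and saturation (mean over
#' pixels of (max - min) / max across RGB, zero where max = 0). RGB is
#' converted to grayscale as 0.299 R + 0.587 G + 0.114 B. For native
#' grayscale inputs the parameters are computed on the raw pixel values and
#' saturation is `NA` (not applicable).
#'
#' @param img Array h x w x 3 (RGB) or h x w (grayscale), values 0-255.
#' @return One-row data.frame: `luminance`, `rms_contrast`, `gradient`,
#'   `saturation`.
#' @export
image_params <- function(img) {
  if (length(img) == 0) stop("empty image")
  if (length(dim(img)) == 3 && dim(img)[3] == 3) {
    gray <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    mx <- pmax(img[, , 1], img[, , 2], img[, , 3])
    mn <- pmin(img[, , 1], img[, , 2], img[, , 3])
    sat_px <- ifelse(mx > 0, (mx - mn) / mx, 0)
    saturation <- mean(sat_px)
  } else {
    gray <- if (length(dim(img)) == 3) img[, , 1] else img
    saturation <- NA_real_
  }
  gr <- pracma::gradient(gray)
  data.frame(luminance = mean(gray), rms_contrast = stats::sd(gray),
             gradient = sum(sqrt(gr$X^2 + gr$Y^2)),
             saturation = saturation)
}

#' @rdname image_params
#' @param images Named list of images.
#' @export
image_params_table <- function(images) {
  out <- do.call(rbind, lapply(images, image_params))
  out$exemplar_id <- names(images)
  rownames(out) <- names(images)
  out
}

# covariate distance vectors (|param_i - param_j|) from an image-parameter
# table, in the canonical pair order; NA-only columns dropped
covariate_distances <- function(params, pair_index) {
  cols <- intersect(c("luminance", "rms_contrast", "gradient", "saturation"),
                    names(params))
  cols <- cols[vapply(cols, function(cl) !anyNA(params[[cl]]), TRUE)]
  vapply(cols, function(cl)
    abs(params[[cl]][pair_index[, 1]] - params[[cl]][pair_index[, 2]]),
    numeric(nrow(pair_index)))
}

# Spearman-consistent partial correlation: correlate the residuals of the
# ranked vectors after removing the ranked covariates by least squares
rank_partial_cor <- function(x, y, z) {
  if (is.null(z) || ncol(z) == 0)
    return(stats::cor(x, y, method = "spearman"))
  rx <- rank(x); ry <- rank(y); rz <- apply(z, 2, rank)
  qz <- qr(cbind(1, rz))
  stats::cor(qr.resid(qz, rx), qr.resid(qz, ry))
}

#' Layer profile controlling for low-level image parameters
#'
#' Partial (rank-based) correlation between the neural and each layer's
#' distance vector, partialing out the pairwise absolute differences in
#' luminance, RMS contrast, gradient and saturation; permutation and FDR
#' inference as in [correlate_profile()]. Collinear covariates are dropped
#' with a warning; with no covariates the result is exactly the plain
#' Spearman profile.
#'
#' @inheritParams correlate_profile
#' @param params Image-parameter table ([image_params_table()]) whose rows
#'   follow the exemplar order of the neural representation.
#' @return A `layer_profile`.
#' @export
partial_profile <- function(neural, layers, params, n_perm = 1000,
                            seed = 1L, fdr_alpha = 0.05) {
  if (!inherits(neural, "distance_vector")) neural <- pairwise_distances(neural)
  pi_ <- attr(neural, "pair_index")
  z <- covariate_distances(params, pi_)
  if (!is.null(z) && ncol(z) > 1) {
    qz <- qr(apply(z, 2, rank))
    if (qz$rank < ncol(z)) {
      drop_ <- colnames(z)[qz$pivot[(qz$rank + 1):ncol(z)]]
      warning("dropping collinear covariate(s): ",
              paste(drop_, collapse = ", "))
      z <- z[, setdiff(colnames(z), drop_), drop = FALSE]
    }
  }
  lds <- layer_distance_list(layers)
  rho <- vapply(lds, function(l) rank_partial_cor(as.vector(neural),
                                                  as.vector(l), z),
                numeric(1))
  n <- attr(neural, "n_exemplars")
  set.seed(seed)
  null <- matrix(0, n_perm, length(lds))
  for (pm in seq_len(n_perm)) {
    dv <- as.vector(permute_distance_vector(neural, sample.int(n)))
    null[pm, ] <- vapply(lds, function(l)
      rank_partial_cor(dv, as.vector(l), z), numeric(1))
  }
  p_perm <- colMeans(sweep(null, 2, rho, ">"))
  p_fdr <- stats::p.adjust(p_perm, method = "BH")
  structure(data.frame(layer = names(lds), rho = unname(rho),
                       p_perm = p_perm, p_fdr = p_fdr,
                       significant = p_fdr < fdr_alpha,
                       stringsAsFactors = FALSE),
            n_perm = n_perm, seed = seed,
            class = c("layer_profile", "data.frame"))
}

#' Average layer profile over individual patients
#'
#' Recomputes the layer correlation profile separately for every patient
#' with at least `min_contacts` face contacts (using only that patient's
#' contacts) and averages the per-patient correlation patterns without
#' weighting. Significance of the averaged pattern comes from exemplar-label
#' permutations applied identically to every patient within an iteration.
#'
#' @param G A [build_response_matrix()] array.
#' @param patient_map Named character vector: contact id -> patient id.
#' @param layers As in [correlate_profile()].
#' @param min_contacts Minimum face contacts for a patient to qualify.
#' @param n_perm,seed,fdr_alpha Permutation settings.
#' @return A `layer_profile` of averaged correlations with an `n_patients`
#'   attribute.
#' @export
per_patient_profiles <- function(G, patient_map, layers, min_contacts = 5,
                                 n_perm = 1000, seed = 1L,
                                 fdr_alpha = 0.05) {
  ids <- attr(G, "contact_ids")
  pats <- patient_map[ids]
  keep <- names(table(pats))[table(pats) >= min_contacts]
  if (!length(keep)) stop("no patient has enough face contacts")
  lds <- layer_distance_list(layers)
  lmat <- apply(vapply(lds, as.vector, numeric(length(lds[[1]]))), 2, rank)
  pat_dv <- lapply(keep, function(p)
    pairwise_distances(neural_patterns(G, contacts = which(pats == p))))
  rho_mat <- vapply(pat_dv, function(dv)
    spearman_vs_ranked(as.vector(dv), lmat), numeric(length(lds)))
  rho <- rowMeans(matrix(rho_mat, nrow = length(lds)))
  n <- dim(G)[1]
  set.seed(seed)
  null <- matrix(0, n_perm, length(lds))
  for (pm in seq_len(n_perm)) {
    perm <- sample.int(n)
    nr <- vapply(pat_dv, function(dv)
      spearman_vs_ranked(as.vector(permute_distance_vector(dv, perm)), lmat),
      numeric(length(lds)))
    null[pm, ] <- rowMeans(matrix(nr, nrow = length(lds)))
  }
  p_perm <- colMeans(sweep(null, 2, rho, ">"))
  p_fdr <- stats::p.adjust(p_perm, method = "BH")
  structure(data.frame(layer = names(lds), rho = rho, p_perm = p_perm,
                       p_fdr = p_fdr, significant = p_fdr < fdr_alpha,
                       stringsAsFactors = FALSE),
            n_perm = n_perm, seed = seed, n_patients = length(keep),
            class = c("layer_profile", "data.frame"))
}

#' Layer profiles for two anatomical contact clusters and their difference
#'
#' Computes the layer correlation profile separately for two regions of
#' interest (e.g. an inferior-occipital and a fusiform cluster) and tests
#' the per-layer correlation difference by shuffling the contacts' ROI
#' labels (cluster sizes preserved); the difference p-value is two-sided.
#'
#' @param G A [build_response_matrix()] array.
#' @param roi Named character vector: contact id -> cluster label (exactly
#'   two distinct labels; every cluster needs >= 2 contacts).
#' @param layers As in [correlate_profile()].
#' @param n_perm Number of label shuffles.
#' @param seed Integer seed.
#' @param n_perm_profile Permutations for the per-cluster profiles.
#' @return List with `profiles` (per cluster) and `difference` (data.frame
#'   layer, delta_rho, p).
#' @export
roi_profile <- function(G, roi, layers, n_perm = 1000, seed = 1L,
                        n_perm_profile = 1000) {
  ids <- attr(G, "contact_ids")
  lab <- roi[ids]
  lv <- unique(stats::na.omit(lab))
  if (length(lv) != 2) stop("roi must define exactly two clusters")
  if (any(table(factor(lab, lv)) < 2)) stop("each cluster needs >= 2 contacts")
  lds <- layer_distance_list(layers)
  lmat <- apply(vapply(lds, as.vector, numeric(length(lds[[1]]))), 2, rank)
  rho_of <- function(which_contacts)
    spearman_vs_ranked(
      as.vector(pairwise_distances(neural_patterns(G,
                                                   contacts = which_contacts))),
      lmat)
  in_cluster <- lapply(lv, function(l) which(lab == l))
  profiles <- lapply(seq_along(lv), function(i)
    correlate_profile(
      pairwise_distances(neural_patterns(G, contacts = in_cluster[[i]])),
      layers, n_perm = n_perm_profile, seed = derive_seed(seed, i)))
  names(profiles) <- lv
  obs <- rho_of(in_cluster[[1]]) - rho_of(in_cluster[[2]])
  assigned <- which(!is.na(lab))
  n_a <- length(in_cluster[[1]])
  set.seed(seed)
  null <- matrix(0, n_perm, length(lds))
  for (pm in seq_len(n_perm)) {
    pick <- sample(assigned, n_a)
    null[pm, ] <- rho_of(pick) - rho_of(setdiff(assigned, pick))
  }
  p <- colMeans(sweep(abs(null), 2, abs(obs), ">="))
  list(profiles = profiles,
       difference = data.frame(layer = names(lds), delta_rho = obs, p = p,
                               stringsAsFactors = FALSE))
}

#' Write a layer profile as TSV
#'
#' @param profile A `layer_profile` or `weighted_profile`.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
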