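#' Leave-one-out search for a single unit predicting a contact
#'
#' Searches one layer's units for a single artificial unit whose exemplar
#' tuning predicts a face contact's responses. Per leave-one-out fold, the
#' Pearson correlation of every unit with the N-1 retained responses is
#' computed and the best unit recorded (ties broken by lowest unit index;
#' near-constant units are skipped). Only if the same unit wins every fold
#' is a least-squares line fitted on each fold's N-1 points to predict the
#' held-out response; significance of the N held-out predictions is a
#' one-sided permutation test on the prediction-observation correlation.
#'
#' @param responses Numeric vector: the contact's mean response per exemplar
#'   (HFA percent signal change averaged over repetitions and time).
#' @param activations Matrix exemplars x units of one layer.
#' @param alpha Significance level for the held-out prediction test.
#' @param n_perm Label permutations for the prediction test.
#' @param seed Integer seed.
#' @return `NULL` if no unit wins all folds; otherwise a `model_unit_match`
#'   list: `unit`, `fold_winners`, `predictions`, `prediction_cor`, `p`,
#'   `significant`.
#' @export
loo_unit_search <- function(responses, activations, alpha = 0.05,
                            n_perm = 1000, seed = 1L) {
  n <- length(responses)
  if (n < 4) stop("need at least 4 exemplars")
  activations <- as.matrix(activations)
  if (nrow(activations) != n)
    stop("activations and responses disagree on exemplar count")
  usable <- apply(activations, 2, stats::sd) > 1e-12
  winners <- integer(n)
  for (i in seq_len(n)) {
    r <- suppressWarnings(
      stats::cor(responses[-i], activations[-i, , drop = FALSE]))
    r[!usable | is.na(r)] <- -Inf
    winners[i] <- which.max(r)           # which.max takes the lowest index
  }
  if (length(unique(winners)) != 1L) return(NULL)
  unit <- winners[1]
  preds <- vapply(seq_len(n), function(i) {
    fit <- stats::lm.fit(cbind(1, activations[-i, unit]), responses[-i])
    sum(fit$coefficients * c(1, activations[i, unit]))
  }, numeric(1))
  obs <- stats::cor(preds, responses)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(pm)
    stats::cor(preds, responses[sample.int(n)]), numeric(1))
  p <- mean(null >= obs)
  structure(list(unit = unit, fold_winners = winners, predictions = preds,
                 prediction_cor = obs, p = p, significant = p < alpha),
            class = "model_unit_match")
}

#' Cluster-level correction for model-unit counts
#'
#' Compares the observed number of model units detected in a layer with the
#' null distribution of counts obtained by re-running the search under
#' exemplar-label shuffles. The count is significant only if it strictly
#' exceeds the 95th percentile of the null counts.
#'
#' @param observed_count Observed model-unit count in the layer.
#' @param search_fn Closure taking a shuffled-label flag seed and returning
#'   a model-unit count (it should re-run the full search with exemplar
#'   labels of the neural responses shuffled).
#' @param n_perm Number of shuffles (>= 20).
#' @param seed Integer seed.
#' @param percentile Null percentile the count must exceed.
#' @return List: `threshold`, `significant`, `null_counts`.
#' @export
cluster_correction <- function(observed_count, search_fn, n_perm = 1000,
                               seed = 1L, percentile = 0.95) {
  if (n_perm < 20) stop("n_perm must be >= 20 for a 95th percentile")
  null <- vapply(seq_len(n_perm), function(pm)
    search_fn(derive_seed(seed, pm)), numeric(1))
  thr <- stats::quantile(null, percentile, type = 1, names = FALSE)
  list(threshold = thr,
       significant = observed_count > thr,
       null_counts = null)
}

#' Search all contacts of a layer for model units, with cluster correction
#'
#' Runs [loo_unit_search()] for every contact against one layer's
#' activations, counts the detected (fold-consistent and significantly
#' predictive) units, and applies [cluster_correction()] by re-running the
#' search over exemplar-label shuffles of the neural responses.
#'
#' @param response_matrix Matrix exemplars x contacts of mean responses
#'   (e.g. [neural_patterns()] with `time_average = TRUE`).
#' @param activations Matrix exemplars x units for the layer.
#' @param alpha Significance level per contact.
#' @param n_perm_fit Permutations for each held-out prediction test.
#' @param n_perm_cluster Shuffles for the cluster correction.
#' @param seed Integer seed.
#' @return List: `matches` (per detected contact: contact, unit, p),
#'   `observed_count`, `cluster` (the [cluster_correction()] result).
#' @export
model_unit_scan <- function(response_matrix, activations, alpha = 0.05,
                            n_perm_fit = 200, n_perm_cluster = 200,
                            seed = 1L) {
  count_units <- function(resp_mat, seed0) {
    hits <- list()
    for (j in seq_len(ncol(resp_mat))) {
      m <- loo_unit_search(resp_mat[, j], activations, alpha = alpha,
                           n_perm = n_perm_fit,
                           seed = derive_seed(seed0, j))
      if (!is.null(m) && m$significant)
        hits[[length(hits) + 1L]] <- data.frame(contact = j, unit = m$unit,
                                                p = m$p)
    }
    hits
  }
  obs_hits <- count_units(response_matrix, seed)
  observed <- length(obs_hits)
  n <- nrow(response_matrix)
  cl <- cluster_correction(observed, function(s) {
    set.seed(s)
    length(count_units(response_matrix[sample.int(n), , drop = FALSE],
                       derive_seed(s, 1)))
  }, n_perm = n_perm_cluster, seed = derive_seed(seed, 9999))
  list(matches = if (observed) do.call(rbind, obs_hits) else NULL,
       observed_count = observed, cluster = cl)
}
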