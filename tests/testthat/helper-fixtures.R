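# Shared fixture builders; everything generated in code at test time.

# minimal trial-level epoched_response from an array and a stimulus table
make_epoched <- function(arr, stimulus_id, category = "faces",
                         time_ms = seq(-200, 498, by = 2)) {
  stopifnot(dim(arr)[3] == length(time_ms))
  structure(arr,
            time_ms = time_ms,
            trials = data.frame(stimulus_id = stimulus_id,
                                category = rep_len(category, dim(arr)[1]),
                                stringsAsFactors = FALSE),
            baseline_window = c(-200, 0), units = "% signal change",
            channel_names = sprintf("ch%02d", seq_len(dim(arr)[2])),
            class = "epoched_response")
}

# pure-noise epoched response: n_trials trials over n_ex exemplars
noise_epoched <- function(n_ex = 10, reps = 4, n_ch = 20, seed = 1,
                          baseline_mean = 10) {
  set.seed(seed)
  n_tr <- n_ex * reps
  arr <- array(stats::rnorm(n_tr * n_ch * 350, baseline_mean, 2),
               c(n_tr, n_ch, 350))
  make_epoched(arr, rep(sprintf("face_%02d", seq_len(n_ex)), each = reps))
}

# response matrix of label-exchangeable noise
noise_G <- function(n_ex = 10, n_c = 5, reps = 4, n_t = 20, seed = 1) {
  set.seed(seed)
  as_response_matrix(array(stats::rnorm(n_ex * n_c * reps * n_t),
                           c(n_ex, n_c, reps, n_t)))
}

# response matrix with identical repetitions (noiseless decoding)
noiseless_G <- function(n_ex = 10, n_c = 5, reps = 4, n_t = 20, seed = 1) {
  set.seed(seed)
  base <- array(stats::rnorm(n_ex * n_c * n_t), c(n_ex, n_c, n_t))
  G <- array(NA_real_, c(n_ex, n_c, reps, n_t))
  for (k in seq_len(reps)) G[, , k, ] <- base
  as_response_matrix(G)
}

# independent random distance vectors over the same exemplar count
random_dv <- function(n_ex = 10, seed = 1) {
  set.seed(seed)
  pairwise_distances(matrix(stats::rnorm(n_ex * 6), n_ex))
}

# named list of layer distance-vector stand-ins
random_layers <- function(n_layers = 22, n_ex = 10, seed = 1) {
  lds <- lapply(seq_len(n_layers), function(l) random_dv(n_ex, seed * 100 + l))
  names(lds) <- sprintf("layer_%02d", seq_len(n_layers))
  lds
}

# uniform color image
flat_image <- function(r, g, b, side = 8) {
  img <- array(0, c(side, side, 3))
  img[, , 1] <- r; img[, , 2] <- g; img[, , 3] <- b
  img
}
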