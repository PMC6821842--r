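#' Per-channel configuration for the recording forward model
#'
#' Builds the channel table and exemplar-tuning weights consumed by
#' [simulate_recording()]. Each channel gets a face-selectivity gain (HFA
#' burst amplitude scale for face trials), a general visual gain (burst
#' amplitude for non-face trials), an exemplar-tuning weight vector in the
#' latent space, and nuisance amplitudes (broadband noise, 60 Hz line,
#' common-mode).
#'
#' @param n_channels Number of channels.
#' @param k Latent dimension (must match the face space used downstream).
#' @param face_gain,visual_gain Numeric scalars or length-`n_channels`
#'   vectors; `face_gain = 0` makes a channel face-unresponsive.
#' @param tuning_sd SD of the latent tuning drive `tuning . embedding`
#'   (weights are scaled by `1/sqrt(k)` so this holds regardless of the
#'   latent dimension); 0 gives an untuned (category-only) channel. The
#'   default of 1 grades face responses over roughly a ten-fold amplitude
#'   range while keeping every face above the non-face response level, as
#'   face-selective contacts do.
#' @param noise_sd Broadband noise SD (uV).
#' @param line_amp,cm_amp 60 Hz line and common-mode amplitudes (uV).
#' @param seed Integer seed for the tuning weights.
#' @return Object of class `contacts_config`: list with `table` (data.frame)
#'   and `tuning` (n_channels x k matrix).
#' @export
contacts_config <- function(n_channels, k = 8, face_gain = 8,
                            visual_gain = 2, tuning_sd = 1, noise_sd = 5,
                            line_amp = 2, cm_amp = 3, seed = 1L) {
  set.seed(seed)
  tab <- data.frame(channel = sprintf("ch%02d", seq_len(n_channels)),
                    face_gain = rep_len(face_gain, n_channels),
                    visual_gain = rep_len(visual_gain, n_channels),
                    tuning_sd = rep_len(tuning_sd, n_channels),
                    noise_sd = rep_len(noise_sd, n_channels),
                    line_amp = rep_len(line_amp, n_channels),
                    cm_amp = rep_len(cm_amp, n_channels),
                    stringsAsFactors = FALSE)
  tuning <- matrix(stats::rnorm(n_channels * k), n_channels, k) *
    tab$tuning_sd / sqrt(k)
  rownames(tuning) <- tab$channel
  structure(list(table = tab, tuning = tuning, k = k),
            class = "contacts_config")
}

# gamma-shaped burst kernel: rises 50 ms after onset, peaks at 200 ms
burst_kernel <- function(fs, rise_ms = 50, peak_ms = 200, len_ms = 700) {
  t <- seq(0, len_ms - 1000 / fs, by = 1000 / fs) - rise_ms
  theta <- (peak_ms - rise_ms) / 2       # shape 2, mode = 2*theta
  k <- ifelse(t <= 0, 0, (t / (2 * theta))^2 * exp(2 - t / theta))
  k / max(k)
}

# white noise band-passed by an FFT brick wall; unit RMS
bandlimited_carrier <- function(n, fs, lo, hi) {
  x <- stats::rnorm(n)
  f <- stats::fft(x)
  freq <- (seq_len(n) - 1) * fs / n
  freq <- pmin(freq, fs - freq)
  f[freq < lo | freq > hi] <- 0
  y <- Re(stats::fft(f, inverse = TRUE)) / n
  y / stats::sd(y)
}

brownian_noise <- function(n, sd_step) cumsum(stats::rnorm(n, 0, sd_step))

#' Simulate a continuous intracranial recording with planted tuning
#'
#' Forward model of the signals the analysis pipeline is built for. Each
#' channel is a sum of Brownian (1/f^2) background, broadband measurement
#' noise, a shared common-mode component, a 60 Hz line sinusoid, and
#' stimulus-locked high-gamma bursts: a 70-150 Hz band-limited carrier whose
#' envelope is a gamma-shaped kernel (rising 50 ms after image onset, peaking
#' at 200 ms) scaled, on face trials, by
#' `face_gain * softplus(tuning . embedding)` for the presented exemplar and,
#' on other trials, by `visual_gain`.
#'
#' @param protocol A [task_protocol()].
#' @param config A [contacts_config()].
#' @param space A [latent_face_space()] whose exemplar ids cover the
#'   protocol's face stimuli.
#' @param seed Integer seed.
#' @param fs Sampling rate in Hz (500, the pipeline's working rate).
#' @return Object of class `fs_recording` with a `ground_truth` attribute:
#'   the config table plus the per-channel tuning matrix.
#' @export
simulate_recording <- function(protocol, config, space, seed = 1L, fs = 500) {
  stopifnot(inherits(protocol, "task_protocol"),
            inherits(config, "contacts_config"),
            inherits(space, "latent_face_space"))
  if (config$k != space$k)
    stop("contacts_config and latent_face_space disagree on latent dimension")
  set.seed(seed)
  n <- ceiling((max(protocol$onset_ms) + 1500) * fs / 1000)
  tab <- config$table
  n_ch <- nrow(tab)
  kern <- burst_kernel(fs)
  cm <- brownian_noise(n, 0.02) + stats::rnorm(n, 0, 0.5)
  line_phase <- stats::runif(1, 0, 2 * pi)
  tt <- seq_len(n) / fs
  line <- sin(2 * pi * 60 * tt + line_phase)

  faces <- protocol$category == "faces"
  amp_tab <- matrix(0, nrow(protocol), n_ch)
  for (j in seq_len(n_ch)) {
    drive <- softplus(as.vector(space$embeddings %*% config$tuning[j, ]))
    names(drive) <- rownames(space$embeddings)
    amp_tab[, j] <- ifelse(faces,
                           tab$face_gain[j] *
                             drive[protocol$stimulus_id] / mean(drive),
                           tab$visual_gain[j])
  }
  if (any(faces & is.na(amp_tab[, 1])))
    stop("face stimuli in the protocol are missing from the latent space")

  onset_idx <- round(protocol$onset_ms * fs / 1000) + 1L
  data <- matrix(0, n_ch, n)
  for (j in seq_len(n_ch)) {
    env <- numeric(n)
    for (tr in seq_len(nrow(protocol))) {
      span <- onset_idx[tr]:min(onset_idx[tr] + length(kern) - 1L, n)
      env[span] <- env[span] + amp_tab[tr, j] * kern[seq_along(span)]
    }
    carrier <- bandlimited_carrier(n, fs, 70, 150)
    data[j, ] <- brownian_noise(n, 0.02 * tab$noise_sd[j]) +
      stats::rnorm(n, 0, tab$noise_sd[j]) +
      tab$cm_amp[j] * cm +
      tab$line_amp[j] * line +
      env * carrier
  }
  rec <- fs_recording(data, fs, tab$channel)
  attr(rec, "ground_truth") <- list(table = tab, tuning = config$tuning,
                                    seed = seed)
  rec
}

#' Simulate a stack of layer activations with controlled geometry match
#'
#' Builds one activation matrix per network layer. A layer with match level
#' `alpha` embeds `alpha * z_i + (1 - alpha) * eps_i` (latent embedding plus
#' independent Gaussian noise) through a layer-specific random isometric
#' projection, so `alpha = 1` reproduces the latent pairwise geometry exactly
#' (up to isometry) and `alpha = 0` is independent noise.
#'
#' @param space A [latent_face_space()].
#' @param match_profile Numeric vector of match levels in `[0, 1]`, one per
#'   layer; names become layer names (default: the canonical 22-layer
#'   evaluation list from [vgg_architecture()]).
#' @param dims Activation dimension per layer (scalar or vector).
#' @param seed Integer seed.
#' @return Object of class `layer_stack`: list of `(name, activations)` plus
#'   the match profile and seed.
#' @export
simulate_layer_stack <- function(space, match_profile = NULL, dims = 50,
                                 seed = 1L) {
  if (is.null(match_profile)) {
    nm <- enumerate_layers(vgg_architecture())
    match_profile <- stats::setNames(rep(0.5, length(nm)), nm)
  }
  if (is.null(names(match_profile)))
    names(match_profile) <- sprintf("layer_%02d", seq_along(match_profile))
  if (any(match_profile < 0 | match_profile > 1))
    stop("match_profile values must lie in [0, 1]")
  set.seed(seed)
  dims <- rep_len(dims, length(match_profile))
  z <- space$embeddings
  layers <- lapply(seq_along(match_profile), function(l) {
    a <- match_profile[l]
    eps <- matrix(stats::rnorm(length(z)), nrow(z), ncol(z))
    m <- qr.Q(qr(matrix(stats::rnorm(dims[l] * ncol(z)), dims[l], ncol(z))))
    act <- (a * z + (1 - a) * eps) %*% t(m)
    rownames(act) <- rownames(z)
    list(name = names(match_profile)[l], activations = act)
  })
  names(layers) <- names(match_profile)
  structure(list(layers = layers, match_profile = match_profile, seed = seed),
            class = "layer_stack")
}

#' @export
print.layer_stack <- function(x, ...) {
  cat(sprintf("layer_stack: %d layers, %d exemplars\n", length(x$layers),
              nrow(x$layers[[1]]$activations)))
  invisible(x)
}

#' Simulate trial-averaged contact response patterns from a latent space
#'
#' Direct generator of an exemplars-by-contacts response matrix whose
#' geometry matches the latent face space to a controllable degree, without
#' simulating continuous signals. Used for geometry-recovery analyses where
#' only the trial-averaged patterns matter.
#'
#' @param space A [latent_face_space()].
#' @param n_contacts Number of synthetic contacts.
#' @param alpha Match level in `[0, 1]` (as in [simulate_layer_stack()]).
#' @param baseline Positive offset added to all responses.
#' @param seed Integer seed.
#' @return Matrix exemplars x contacts (rownames = exemplar ids).
#' @export
simulate_response_patterns <- function(space, n_contacts = 40, alpha = 0.9,
                                       baseline = 1, seed = 1L) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  set.seed(seed)
  z <- space$embeddings
  eps <- matrix(stats::rnorm(length(z)), nrow(z), ncol(z))
  m <- qr.Q(qr(matrix(stats::rnorm(n_contacts * ncol(z)), n_contacts,
                      ncol(z))))
  p <- baseline + (alpha * z + (1 - alpha) * eps) %*% t(m)
  colnames(p) <- sprintf("c%03d", seq_len(n_contacts))
  p
}
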