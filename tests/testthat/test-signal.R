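test_that("common average reference removes the shared component", {
  x <- matrix(rnorm(4 * 100), 4, 100)
  rec <- fs_recording(x, 500)
  out <- common_average_reference(rec)
  expect_lt(max(abs(colMeans(out$data))), 1e-9)
  # identical channels cancel entirely
  same <- fs_recording(matrix(rep(sin(1:200), 3), 3, byrow = TRUE), 500)
  expect_lt(max(abs(common_average_reference(same)$data)), 1e-12)
  # antisymmetric pair is already zero-mean
  pair <- fs_recording(rbind(sin(1:200), -sin(1:200)), 500)
  expect_equal(common_average_reference(pair)$data, pair$data)
})

test_that("bad channels pass through and cannot all be bad", {
  x <- matrix(rnorm(3 * 50), 3, 50)
  rec <- fs_recording(x, 500, c("a", "b", "c"))
  out <- common_average_reference(rec, bad_channels = "c")
  expect_equal(out$data[3, ], x[3, ])
  expect_lt(max(abs(colMeans(out$data[1:2, ]))), 1e-9)
  expect_error(common_average_reference(rec, c("a", "b", "c")), "all channels")
  expect_error(common_average_reference(rec, "zz"), "subset")
})

test_that("512 Hz input is resampled to the 500 Hz working rate", {
  t512 <- seq(0, 2, by = 1 / 512)
  rec <- fs_recording(rbind(sin(2 * pi * 5 * t512)), 512)
  expect_equal(rec$sampling_rate_hz, 500)
  expect_lte(abs(ncol(rec$data) - length(t512) * 500 / 512), 1)
  # a pure tone survives resampling with frequency and amplitude intact
  # (allow an arbitrary phase from the resampler's group delay)
  t500 <- seq_len(ncol(rec$data)) / 500
  core <- 100:900
  fit <- stats::lm(rec$data[1, core] ~ sin(2 * pi * 5 * t500[core]) +
                     cos(2 * pi * 5 * t500[core]))
  expect_gt(summary(fit)$r.squared, 0.99)
  expect_equal(sqrt(sum(stats::coef(fit)[2:3]^2)), 1, tolerance = 0.02)
  expect_error(fs_recording(rbind(rnorm(10)), 1000), "500 or 512")
})

test_that("HFA uses nine sub-bands and normalizes to unit temporal mean", {
  expect_equal(nrow(hfa_bands()), 9)
  expect_true(all(hfa_bands() >= 48 & hfa_bands() <= 154))
  # bands avoid the line-noise ranges
  expect_false(any(hfa_bands()[, 1] < 61 & hfa_bands()[, 2] > 59))
  expect_false(any(hfa_bands()[, 1] < 121 & hfa_bands()[, 2] > 117))
  set.seed(1)
  rec <- fs_recording(matrix(rnorm(2 * 8000), 2), 500)
  h <- estimate_hfa(rec)
  expect_equal(rowMeans(h$data), c(1, 1), tolerance = 1e-6)
  expect_true(all(h$data >= 0))
})

test_that("HFA envelope tracks a known broadband amplitude modulation", {
  set.seed(2)
  fs <- 500; n <- 20000
  t <- seq_len(n) / fs
  carrier <- facespace:::bandlimited_carrier(n, fs, 70, 150)
  env <- 1 + 0.8 * sin(2 * pi * 2 * t)
  rec <- fs_recording(rbind(carrier * env + rnorm(n, 0, 0.05)), fs)
  h <- estimate_hfa(rec)
  core <- 1000:19000
  expect_gt(stats::cor(h$data[1, core], env[core]), 0.8)
})

test_that("epoching normalizes to percent change from the global baseline", {
  pr <- task_protocol(data.frame(onset_ms = c(2000, 4000),
                                 stimulus_id = c("a", "b"),
                                 category = "faces", is_repeat = FALSE),
                      1, 250, c(faces = 2))
  fs <- 500; n <- 4000
  x <- rep(2, n)                      # constant amplitude trace
  resp_idx <- function(on) (on * fs / 1000) + seq_len(125)
  rec <- fs_recording(rbind(x), fs)
  ep <- epoch_and_normalize(rec, pr)
  expect_true(all(abs(ep) < 1e-9))    # constant trace -> 0% everywhere
  # doubling during the response window reads +100%
  x2 <- x; x2[resp_idx(2000)] <- 4; x2[resp_idx(4000)] <- 4
  ep2 <- epoch_and_normalize(fs_recording(rbind(x2), fs), pr)
  tm <- attr(ep2, "time_ms")
  on_resp <- tm >= 0 & tm < 250
  expect_true(all(abs(ep2[, 1, on_resp] - 100) < 1e-6))
  bl <- tm >= -200 & tm < 0
  expect_lt(abs(mean(ep2[, 1, bl])), 1e-9)  # grand baseline mean is 0
})

test_that("epoching is shift-equivariant and excludes flagged trials", {
  set.seed(3)
  base <- data.frame(onset_ms = c(2000, 3000, 4000, 5000),
                     stimulus_id = c("a", "b", "a", "a"),
                     category = "faces",
                     is_repeat = c(FALSE, FALSE, FALSE, TRUE))
  pr <- task_protocol(base, 1, 250, c(faces = 2))
  x <- abs(rnorm(6000)) + 1
  ep <- epoch_and_normalize(fs_recording(rbind(x), 500), pr)
  expect_equal(dim(ep)[1], 3)         # repeat (hit/miss) trial dropped
  shift_ms <- 500
  base2 <- base; base2$onset_ms <- base2$onset_ms + shift_ms
  pr2 <- task_protocol(base2, 1, 250, c(faces = 2))
  x2 <- c(numeric(shift_ms / 2), x)   # 500 ms = 250 samples at 500 Hz
  ep2 <- epoch_and_normalize(fs_recording(rbind(x2), 500), pr2)
  expect_equal(as.vector(ep2), as.vector(ep))
  base$excluded <- c(FALSE, TRUE, FALSE, FALSE)
  pr3 <- task_protocol(base, 1, 250, c(faces = 2))
  ep3 <- epoch_and_normalize(fs_recording(rbind(x), 500), pr3)
  expect_equal(dim(ep3)[1], 2)
  expect_error(epoch_and_normalize(fs_recording(rbind(x[1:900]), 500), pr),
               "outside the recording")
})

test_that("ERP averages repetitions and records the analysis window", {
  set.seed(4)
  pr <- task_protocol(data.frame(onset_ms = seq(2000, by = 1000,
                                                length.out = 8),
                                 stimulus_id = rep(c("a", "b"), 4),
                                 category = "faces", is_repeat = FALSE),
                      2, 250, c(faces = 2))
  x <- rnorm(8000)
  erp <- extract_erp(fs_recording(rbind(x), 500), pr)
  expect_equal(dim(erp)[1], 2)
  expect_equal(attr(erp, "analysis_window"), c(125, 250))
  # identical trials: average equals any single trial
  y <- numeric(8000)
  patt <- sin(seq_len(350) / 10)
  for (on in pr$onset_ms) y[(on / 2 - 99):(on / 2 + 250)] <- patt
  erp2 <- extract_erp(fs_recording(rbind(y), 500), pr)
  expect_equal(as.vector(erp2[1, 1, ]), patt, tolerance = 1e-12)
})

test_that("ERP amplitude shrinks like 1/sqrt(n) for zero-mean noise", {
  rms_at <- function(reps, seed) {
    set.seed(seed)
    onsets <- seq(2000, by = 1000, length.out = reps)
    pr <- task_protocol(data.frame(onset_ms = onsets,
                                   stimulus_id = rep_len(c("a", "b"), reps),
                                   category = "faces", is_repeat = FALSE),
                        2, 250, c(faces = 2))
    x <- rnorm(max(onsets) / 2 + 1000)
    erp <- extract_erp(fs_recording(rbind(x), 500), pr)
    sqrt(mean(erp^2))
  }
  r <- sapply(c(4, 16, 64), function(n)
    mean(sapply(1:10, function(s) rms_at(n, s * 13))))
  expect_equal(r[1] / r[2], 2, tolerance = 0.35)
  expect_equal(r[2] / r[3], 2, tolerance = 0.35)
})

test_that("band-limited power recovers in-band amplitude and rejects out-of-band", {
  fs <- 500; n <- 20000
  t <- seq_len(n) / fs
  pr <- task_protocol(data.frame(onset_ms = seq(2000, by = 1000,
                                                length.out = 10),
                                 stimulus_id = rep_len(c("a", "b"), 10),
                                 category = "faces",
                                 is_repeat = FALSE), 2, 250, c(faces = 2))
  blp10 <- extract_low_freq_blp(fs_recording(rbind(3 * sin(2 * pi * 10 * t)),
                                             fs), pr)
  expect_equal(attr(blp10, "analysis_window"), c(125, 250))
  expect_lt(abs(mean(blp10) - 3) / 3, 0.05)
  blp50 <- extract_low_freq_blp(fs_recording(rbind(3 * sin(2 * pi * 50 * t)),
                                             fs), pr)
  expect_lt(mean(blp50), 0.15)        # < 5% of the out-of-band amplitude
  expect_true(all(blp10 >= 0))
})
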