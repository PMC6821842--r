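test_that("pairwise distances follow the canonical pair order", {
  x <- matrix(0, 10, 2)
  dv <- pairwise_distances(x)
  expect_length(dv, 45)
  expect_equal(attr(dv, "n_exemplars"), 10)
  y <- rbind(c(0, 0), c(3, 4), c(0, 0))
  dvy <- pairwise_distances(y)
  expect_equal(as.vector(dvy), c(5, 0, 5))   # (1,2), (1,3), (2,3)
  expect_error(pairwise_distances(rbind(c(1, NA))), "non-finite")
})

test_that("distance vectors are metric on random inputs", {
  set.seed(1)
  for (rep in 1:10) {
    x <- matrix(rnorm(8 * 4), 8, 4)
    dv <- pairwise_distances(x)
    full <- matrix(0, 8, 8)
    full[attr(dv, "pair_index")] <- dv
    full <- full + t(full)
    expect_true(all(full >= 0))
    for (i in 1:8) for (j in 1:8) for (k in 1:8)
      expect_lte(full[i, j], full[i, k] + full[k, j] + 1e-12)
  }
})

test_that("layer profile is rank-invariant and finds a planted layer", {
  neural <- random_dv(10, 3)
  layers <- list(mono = structure(exp(as.vector(neural) / 2),
                                  pair_index = attr(neural, "pair_index"),
                                  n_exemplars = 10,
                                  class = "distance_vector"),
                 noise = random_dv(10, 99))
  pr <- correlate_profile(neural, layers, n_perm = 200, seed = 1)
  expect_equal(pr$rho[1], 1)             # monotone transform keeps rho = 1
  expect_lt(pr$p_perm[1], 0.05)
  const <- structure(rep(1, 45), pair_index = attr(neural, "pair_index"),
                     n_exemplars = 10, class = "distance_vector")
  expect_error(correlate_profile(const, layers, n_perm = 10), "constant")
})

test_that("planted-layer recovery names the right layer across seeds", {
  hits <- 0
  for (seed in 1:5) {
    sp <- latent_face_space(10, 8, seed)
    mp <- stats::setNames(rep(0.15, 22), enumerate_layers())
    mp["conv4_2"] <- 0.95
    st <- simulate_layer_stack(sp, mp, dims = 40, seed = seed + 30)
    pats <- simulate_response_patterns(sp, 40, alpha = 0.9,
                                       seed = seed + 60)
    pr <- correlate_profile(pairwise_distances(pats), st, n_perm = 500,
                            seed = seed)
    ok <- pr$layer[which.max(pr$rho)] == "conv4_2" &&
      identical(pr$layer[pr$significant], "conv4_2")
    hits <- hits + ok
  }
  expect_gte(hits, 4)
})

test_that("permutation p-values are uniform under the null", {
  ps <- vapply(1:200, function(i) {
    neural <- random_dv(10, 5000 + i)
    layer <- list(l = random_dv(10, 9000 + i))
    correlate_profile(neural, layer, n_perm = 99, seed = i)$p_perm
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("weighted profile implements the Fisher-z pooling formulas", {
  mk <- function(rho) structure(data.frame(layer = "l", rho = rho,
                                           p_perm = 0.5, p_fdr = 0.5,
                                           significant = FALSE),
                                class = c("layer_profile", "data.frame"))
  single <- weighted_profile(list(mk(0.42)), 7)
  expect_equal(single$rho, 0.42, tolerance = 1e-12)
  both <- weighted_profile(list(mk(0.5), mk(0.5)), c(3, 11))
  expect_equal(both$rho, 0.5, tolerance = 1e-12)
  two <- weighted_profile(list(mk(0.3), mk(0.6)), c(10, 30))
  expect_equal(two$rho,
               tanh((10 * atanh(0.3) + 30 * atanh(0.6)) / 40),
               tolerance = 1e-12)
  expect_warning(weighted_profile(list(mk(1), mk(0.5)), c(1, 1)), "clipped")
})

test_that("pair bootstrap s.e.m. behaves and shrinks with set size", {
  neural <- random_dv(10, 4)
  mono <- structure(as.vector(neural) * 2 + 1,
                    pair_index = attr(neural, "pair_index"),
                    n_exemplars = 10, class = "distance_vector")
  expect_lt(bootstrap_sem_pairs(neural, mono, n_boot = 200, seed = 1), 1e-12)
  expect_equal(bootstrap_sem_pairs(neural, random_dv(10, 5), 100, seed = 2),
               bootstrap_sem_pairs(neural, random_dv(10, 5), 100, seed = 2))
  sems <- sapply(c(6, 10), function(n_ex) {
    mean(sapply(1:10, function(s) {
      sp <- latent_face_space(n_ex, 5, s)
      st <- simulate_layer_stack(sp, c(l = 0.8), dims = 20, seed = s + 40)
      bootstrap_sem_pairs(pairwise_distances(sp$embeddings),
                          pairwise_distances(st$layers[[1]]$activations),
                          n_boot = 200, seed = s)
    }))
  })
  expect_lt(sems[2], sems[1])
  expect_error(bootstrap_sem_pairs(1:2, 1:2), "3 pairs")
})

test_that("sliding windows tile the epoch and degenerate to the static profile", {
  set.seed(12)
  G <- noise_G(n_ex = 8, n_c = 3, reps = 2, n_t = 225, seed = 12)
  attr(G, "time_ms") <- seq(50, 498, by = 2)
  layers <- random_layers(4, 8, 77)
  sw <- sliding_window_profile(G, layers, window_ms = 200, stride_ms = 50,
                               n_perm = 20, seed = 1)
  expect_length(sw$window_starts, 6)    # floor((450 - 200) / 50) + 1
  full <- sliding_window_profile(G, layers, window_ms = 450,
                                 stride_ms = 500, n_perm = 20, seed = 1)
  static <- correlate_profile(pairwise_distances(neural_patterns(G)),
                              layers, n_perm = 20, seed = 1)
  expect_equal(full$profiles[[1]]$rho, static$rho)
  expect_error(sliding_window_profile(G, layers, window_ms = 500,
                                      stride_ms = 50, n_perm = 5),
               "longer than")
})

test_that("a stationary planted geometry keeps the same argmax layer over time", {
  sp <- latent_face_space(8, 6, 31)
  st <- simulate_layer_stack(sp, c(a = 0.1, b = 0.95, c = 0.1), dims = 30,
                             seed = 32)
  pats <- simulate_response_patterns(sp, 20, alpha = 0.95, seed = 33)
  n_t <- 225
  kern <- exp(-((seq_len(n_t) - 75) / 60)^2)   # shared temporal profile
  G <- array(NA_real_, c(8, 20, 2, n_t))
  set.seed(34)
  for (k in 1:2)
    for (tt in seq_len(n_t))
      G[, , k, tt] <- pats * kern[tt] + rnorm(160, sd = 0.01)
  G <- as_response_matrix(G, time_ms = seq(50, 498, by = 2))
  sw <- sliding_window_profile(G, st, window_ms = 200, stride_ms = 50,
                               n_perm = 20, seed = 2)
  expect_true(all(sw$argmax_layer == "b"))
  # geometry carried by amplitude alone survives time averaging
  ta <- time_averaged_profile(G, st, n_perm = 100, seed = 3)
  expect_equal(ta$layer[which.max(ta$rho)], "b")
  expect_equal(nrow(time_averaged_profile(
    G, simulate_layer_stack(sp, seed = 35), n_perm = 10, seed = 1)), 22)
  # time-constant responses: averaged profile equals the full-series one
  Gc <- array(NA_real_, c(8, 20, 2, 5))
  for (k in 1:2) for (tt in 1:5) Gc[, , k, tt] <- pats
  Gc <- as_response_matrix(Gc)
  expect_equal(time_averaged_profile(Gc, st, n_perm = 20, seed = 4)$rho,
               correlate_profile(pairwise_distances(neural_patterns(Gc)),
                                 st, n_perm = 20, seed = 4)$rho)
})

test_that("image parameters match closed-form values on simple rasters", {
  white <- flat_image(255, 255, 255)
  pw <- image_params(white)
  expect_equal(unlist(pw), c(luminance = 255, rms_contrast = 0,
                             gradient = 0, saturation = 0))
  red <- flat_image(255, 0, 0)
  pr <- image_params(red)
  expect_equal(pr$luminance, 76.245)
  expect_equal(pr$saturation, 1)
  checker <- matrix(c(0, 255), 8, 8)[, rep(1:2, 4)]
  checker <- 255 * ((row(matrix(0, 8, 8)) + col(matrix(0, 8, 8))) %% 2)
  pc <- image_params(checker)
  expect_equal(pc$luminance, 127.5)
  expect_equal(pc$rms_contrast, stats::sd(as.vector(checker)))
  expect_true(is.na(pc$saturation))    # grayscale: not applicable
  expect_error(image_params(numeric(0)), "empty")
})

test_that("partial correlation reduces to and departs from plain Spearman correctly", {
  neural <- random_dv(10, 41)
  layers <- random_layers(3, 10, 42)
  # no covariates: exactly the plain profile
  empty_params <- data.frame(luminance = rep(NA_real_, 10))
  plain <- correlate_profile(neural, layers, n_perm = 50, seed = 1)
  part0 <- partial_profile(neural, layers, empty_params, n_perm = 50,
                           seed = 1)
  expect_equal(part0$rho, plain$rho, tolerance = 1e-12)
  # covariate identical to a layer's distances explains it away
  params <- data.frame(luminance = rnorm(10))
  lay <- list(l = structure(
    abs(params$luminance[attr(neural, "pair_index")[, 1]] -
          params$luminance[attr(neural, "pair_index")[, 2]]),
    pair_index = attr(neural, "pair_index"), n_exemplars = 10,
    class = "distance_vector"))
  pp <- partial_profile(neural, lay, params, n_perm = 50, seed = 2)
  expect_lt(abs(pp$rho), 0.15)
  # independent covariates barely move the estimate
  deltas <- sapply(1:20, function(s) {
    nv <- random_dv(10, 300 + s)
    ly <- random_layers(1, 10, 400 + s)
    set.seed(500 + s)
    par_ind <- data.frame(luminance = rnorm(10), rms_contrast = rnorm(10))
    abs(partial_profile(nv, ly, par_ind, n_perm = 10, seed = s)$rho -
          correlate_profile(nv, ly, n_perm = 10, seed = s)$rho)
  })
  expect_lt(mean(deltas), 0.05)
})

test_that("per-patient averaging reduces to the individual profile", {
  sp <- latent_face_space(8, 6, 51)
  pats <- simulate_response_patterns(sp, 12, alpha = 0.9, seed = 52)
  G <- as_response_matrix(array(pats, c(8, 12, 1, 1)))
  # need >= 2 reps for nothing here; profiles only use trial means
  G <- as_response_matrix(array(rep(pats, 2), c(8, 12, 2, 1)))
  layers <- random_layers(3, 8, 53)
  pmap <- stats::setNames(rep(c("p1", "p2"), each = 6),
                          attr(G, "contact_ids"))
  # single qualifying patient (p1 has 8 contacts): equals its own profile
  pmap_uneven <- stats::setNames(rep(c("p1", "p2"), c(8, 4)),
                                 attr(G, "contact_ids"))
  one <- per_patient_profiles(G, pmap_uneven, layers, min_contacts = 5,
                              n_perm = 50, seed = 1)
  own <- correlate_profile(
    pairwise_distances(neural_patterns(G, contacts = 1:8)), layers,
    n_perm = 50, seed = 1)
  expect_equal(one$rho, own$rho, tolerance = 1e-12)
  expect_equal(attr(one, "n_patients"), 1)
  expect_error(per_patient_profiles(G, pmap, layers, min_contacts = 99,
                                    n_perm = 10), "no patient")
  # identical patients: average equals the individual pattern
  G2 <- as_response_matrix(array(rep(pats[, c(1:6, 1:6)], 2),
                                 c(8, 12, 2, 1)))
  both <- per_patient_profiles(G2, pmap, layers, min_contacts = 5,
                               n_perm = 50, seed = 2)
  ind <- correlate_profile(
    pairwise_distances(neural_patterns(G2, contacts = 1:6)), layers,
    n_perm = 50, seed = 3)
  expect_equal(both$rho, ind$rho, tolerance = 1e-12)
  expect_equal(attr(both, "n_patients"), 2)
})

test_that("ROI difference test is calibrated for shared geometry and detects planted splits", {
  sp <- latent_face_space(8, 6, 61)
  # both clusters sample the same latent geometry
  pats <- simulate_response_patterns(sp, 8, alpha = 0.9, seed = 62)
  G <- as_response_matrix(array(rep(pats, 2), c(8, 8, 2, 1)))
  roi <- stats::setNames(rep(c("occ", "fus"), each = 4),
                         attr(G, "contact_ids"))
  layers <- random_layers(4, 8, 63)
  rp <- roi_profile(G, roi, layers, n_perm = 100, seed = 1,
                    n_perm_profile = 50)
  expect_lte(sum(rp$difference$p < 0.05), 1)
  expect_named(rp$profiles, c("occ", "fus"))
  # clusters planted with different matching layers differ there
  sp2 <- latent_face_space(8, 6, 64)
  a <- simulate_response_patterns(sp, 6, alpha = 0.98, seed = 65)
  b <- simulate_response_patterns(sp2, 6, alpha = 0.98, seed = 66)
  G2 <- as_response_matrix(array(rep(cbind(a, b), 2), c(8, 12, 2, 1)))
  roi2 <- stats::setNames(rep(c("occ", "fus"), each = 6),
                          attr(G2, "contact_ids"))
  st <- list(match_a = pairwise_distances(sp$embeddings),
             match_b = pairwise_distances(sp2$embeddings))
  rp2 <- roi_profile(G2, roi2, st, n_perm = 200, seed = 2,
                     n_perm_profile = 50)
  expect_true(any(rp2$difference$p < 0.05))
  expect_error(roi_profile(G2, stats::setNames(rep("occ", 12),
                                               attr(G2, "contact_ids")),
                           st, n_perm = 10), "two clusters")
})
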