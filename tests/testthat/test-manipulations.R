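test_that("luminance matching equalizes the set mean luminance", {
  a <- flat_image(100, 100, 100)
  b <- flat_image(140, 140, 140)
  out <- match_luminance(list(a = a, b = b))
  expect_equal(image_params(out$a)$luminance, 120, tolerance = 1e-9)
  expect_equal(image_params(out$b)$luminance, 120, tolerance = 1e-9)
  # single image is left unchanged
  one <- match_luminance(list(x = a))
  expect_equal(one$x, a)
  # color set with clipping headroom: measured luminance SD collapses
  tgt <- data.frame(luminance = c(110, 135, 120, 128), contrast = 15,
                    saturation = 0.2)
  gi <- generate_face_images(4, params = tgt, seed = 3)
  matched <- match_luminance(gi$images)
  lum <- sapply(matched, function(im) image_params(im)$luminance)
  expect_lt(stats::sd(lum), 0.5)
  expect_equal(attr(matched, "clipped_fraction"), 0)
})

test_that("luminance matching preserves hue on the HSV value plane", {
  img <- flat_image(200, 100, 50)
  other <- flat_image(100, 100, 100)
  out <- match_luminance(list(a = img, b = other))
  # hue and hexcone saturation are scale-invariant; check ratios survive
  px <- c(out$a[1, 1, 1], out$a[1, 1, 2], out$a[1, 1, 3])
  expect_equal(px[2] / px[1], 100 / 200, tolerance = 1e-9)
  expect_equal(px[3] / px[1], 50 / 200, tolerance = 1e-9)
})

test_that("grayscale conversion uses the standard weights on three channels", {
  g <- to_grayscale(flat_image(255, 0, 0))
  expect_equal(g[1, 1, 1], 76.245)
  expect_equal(g[, , 1], g[, , 2])
  expect_equal(g[, , 2], g[, , 3])
  gray_in <- matrix(42, 4, 4)
  g2 <- to_grayscale(gray_in)
  expect_true(all(g2 == 42))
})

test_that("network preprocessing resizes and subtracts channel means", {
  img <- flat_image(100, 120, 140, side = 16)
  out <- preprocess_for_network(img, mean_rgb = 0)
  expect_equal(dim(out), c(224, 224, 3))
  expect_equal(mean(out[, , 1]), 100, tolerance = 1e-6)
  out2 <- preprocess_for_network(img, mean_rgb = c(10, 20, 30), side = 32)
  expect_equal(sapply(1:3, function(ch) mean(out2[, , ch])),
               c(90, 100, 110), tolerance = 1e-6)
  expect_error(preprocess_for_network("not an image"), "raster")
})

test_that("manipulation impact is null for geometry-preserving changes", {
  neural <- random_dv(10, 5)
  layer <- random_dv(10, 6)
  same <- manipulation_impact(neural, layer, layer, n_perm = 100,
                              n_boot = 100, seed = 1)
  expect_equal(same$delta, 0)
  expect_gt(same$p_perm, 0.5)
  expect_false(same$outside_ci)
  rescaled <- structure(as.vector(layer)^2 + 3,
                        pair_index = attr(layer, "pair_index"),
                        n_exemplars = 10, class = "distance_vector")
  mono <- manipulation_impact(neural, layer, rescaled, n_perm = 100,
                              n_boot = 100, seed = 2)
  expect_equal(mono$delta, 0)          # Spearman sees the same ranks
  expect_error(manipulation_impact(neural, layer, random_dv(6, 1),
                                   n_perm = 10, n_boot = 10), "pair index")
})

test_that("a geometry-re-randomizing manipulation produces significant deltas", {
  hits <- 0
  for (seed in 1:5) {
    sp <- latent_face_space(10, 8, seed)
    st <- simulate_layer_stack(sp, c(l = 0.95), dims = 40, seed = seed + 10)
    neural <- pairwise_distances(
      simulate_response_patterns(sp, 40, alpha = 0.9, seed = seed + 20))
    orig <- pairwise_distances(st$layers[[1]]$activations)
    sp2 <- latent_face_space(10, 8, seed + 500)   # re-drawn geometry
    st2 <- simulate_layer_stack(sp2, c(l = 0.95), dims = 40,
                                seed = seed + 30)
    manip <- pairwise_distances(st2$layers[[1]]$activations)
    mi <- manipulation_impact(neural, orig, manip, n_perm = 500,
                              n_boot = 200, seed = seed)
    hits <- hits + (mi$p_perm < 0.05)
  }
  expect_gte(hits, 4)
})

test_that("layer self-correlation reports geometry preservation", {
  dv <- random_dv(10, 7)
  expect_equal(layer_self_correlation(dv, dv), 1)
  anti <- structure(max(dv) - as.vector(dv),
                    pair_index = attr(dv, "pair_index"), n_exemplars = 10,
                    class = "distance_vector")
  expect_equal(layer_self_correlation(dv, anti), -1)
  rhos <- sapply(1:20, function(s)
    layer_self_correlation(random_dv(10, 100 + s), random_dv(10, 200 + s)))
  expect_lt(abs(mean(rhos)), 0.15)
})

test_that("identity decoding is perfect for invariant codes, chance otherwise", {
  set.seed(8)
  act <- matrix(rnorm(10 * 6, sd = 3), 10, 6)
  invariant <- list(orig = act, manip = act + rnorm(60, sd = 0.01))
  expect_equal(identity_nn_decoding(invariant, n_rep = 50, seed = 1), 1)
  onehot <- diag(10)
  expect_equal(identity_nn_decoding(list(a = onehot, b = onehot),
                                    n_rep = 50, seed = 2), 1)
  indep <- list(a = matrix(rnorm(10 * 6), 10),
                b = matrix(rnorm(10 * 6), 10),
                c = matrix(rnorm(10 * 6), 10))
  acc <- identity_nn_decoding(indep, n_rep = 500, seed = 3)
  expect_lt(abs(acc - 0.1), 0.08)
  expect_error(identity_nn_decoding(list(a = act)), "length")
})

test_that("viewpoint matrix scores cross-view identity preservation", {
  set.seed(9)
  f <- matrix(rnorm(8 * 5, sd = 2), 8, 5)
  vm <- viewpoint_matrix(f, f)
  expect_lt(max(diag(vm$distances)), 1e-6)
  expect_equal(vm$invariance_score, 1)
  scores <- sapply(1:20, function(s) {
    set.seed(s)
    viewpoint_matrix(matrix(rnorm(40), 8), matrix(rnorm(40), 8))$invariance_score
  })
  expect_lt(abs(mean(scores) - 1 / 8), 0.08)
  expect_true(all(scores >= 0 & scores <= 1))
  expect_error(viewpoint_matrix(f, f[1:3, ]), "differ")
})
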