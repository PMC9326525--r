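# leakage: plug-in MIS estimator, preprocessing, traces, rendering.

test_that("MIS reproduces closed-form binary cases", {
  expect_equal(mutual_information_score(c(0, 0, 1, 1), c(0, 0, 1, 1)),
               log(2), tolerance = 1e-12)
  expect_equal(mutual_information_score(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0,
               tolerance = 1e-12)
  expect_error(mutual_information_score(1:3, 1:4), "length")
  expect_error(mutual_information_score(numeric(0), numeric(0)))
})

test_that("MIS equals the exhaustive contingency oracle on random pairs", {
  for (seed in 1:20) {
    withr::with_seed(seed, {
      n <- sample(50:400, 1)
      x <- sample(5, n, replace = TRUE)
      y <- sample(4, n, replace = TRUE)
    })
    expect_equal(mutual_information_score(x, y), mis_brute(x, y),
                 tolerance = 1e-12)
  }
})

test_that("MIS is symmetric, non-negative, relabeling-invariant and
           reduces to entropy on identical arguments", {
  for (seed in 1:25) {
    withr::with_seed(seed, {
      n <- sample(20:300, 1)
      kx <- sample(2:8, 1); ky <- sample(2:8, 1)
      x <- sample(kx, n, replace = TRUE)
      y <- sample(ky, n, replace = TRUE)
      perm <- sample(kx)
    })
    i_xy <- mutual_information_score(x, y)
    expect_identical(i_xy, mutual_information_score(y, x))
    expect_gte(i_xy, 0)
    # bijective relabeling of x leaves the score unchanged
    expect_equal(mutual_information_score(perm[x], y), i_xy,
                 tolerance = 1e-12)
    expect_equal(mutual_information_score(x, x), entropy_plugin(x),
                 tolerance = 1e-12)
  }
  expect_equal(entropy_plugin(rep(7, 10)), 0)
  expect_equal(entropy_plugin(c(0, 0, 1, 1)), log(2), tolerance = 1e-12)
  expect_error(entropy_plugin(numeric(0)), "empty")
})

test_that("preprocess_pair handles identity, zero-padding and resizing", {
  cfg <- mis_config(quantize_decimals = NULL)
  # smashed already input-length: returned unchanged
  x <- sin(1:16)
  y <- cos(1:16)
  pp <- preprocess_pair(x, y, cfg)
  expect_identical(pp$x, x)
  expect_identical(pp$y, y)
  # 1-D input length 16, smashed length 12 under zero_pad: 4 trailing zeros
  cfg_zp <- mis_config(rescale_method = "zero_pad", quantize_decimals = NULL)
  pp2 <- preprocess_pair(x, cos(1:12), cfg_zp)
  expect_length(pp2$y, 16L)
  expect_identical(pp2$y[13:16], rep(0, 4))
  expect_error(preprocess_pair(sin(1:8), cos(1:12), cfg_zp), "zero_pad")
  # 2-D 8x8 input, 4x4 smashed, bilinear: a bilinear ramp resizes exactly
  ramp4 <- outer(seq(0, 3), seq(0, 3), function(a, b) 2 * a + 5 * b)
  target <- outer(seq(0, 3, length.out = 8), seq(0, 3, length.out = 8),
                  function(a, b) 2 * a + 5 * b)
  inp <- array(stats::runif(64), c(8, 8, 1))
  pp3 <- preprocess_pair(inp, array(ramp4, c(4, 4, 1)), cfg)
  expect_equal(pp3$y, as.vector(target), tolerance = 1e-12)
  # quantization rounds the smashed side only
  cfgq <- mis_config(quantize_decimals = 1L)
  pp4 <- preprocess_pair(x, y, cfgq)
  expect_identical(pp4$y, round(y, 1))
  expect_identical(pp4$x, x)
})

test_that("mis_epoch attains entropy under identity maps and zero for
           constant maps, and averages pairwise scores", {
  # identity client portion on quantized inputs: score = mean input entropy
  sp <- network_spec(list(block_spec("dense", 4L, activation = "none"),
                          block_spec("dense", 4L)),
                     input_shape = 4L, n_classes = 2L)
  p <- build_network(sp, 0L)
  p$blocks[[1L]]$W <- diag(4)
  p$blocks[[1L]]$b <- rep(0, 4)
  client <- splitsim:::split_params(p, split_network(sp, 1L))$client
  withr::with_seed(2L, {
    ex <- matrix(round(stats::runif(4 * 6), 1), 4, 6)
  })
  cfg <- mis_config(quantize_decimals = 6L)
  got <- mis_epoch(list(client), ex, cfg)
  want <- mean(vapply(1:6, function(i) entropy_plugin(ex[, i]), 0))
  expect_equal(got, want, tolerance = 1e-12)
  # constant map leaks nothing
  pz <- client
  pz$blocks[[1L]]$W[] <- 0
  expect_equal(mis_epoch(list(pz), ex, cfg), 0)
  # two clients, three samples: explicit average of the six pairwise scores
  sp2 <- toy_series_spec()
  pr <- splitsim:::split_params(build_network(sp2, 3L),
                                split_network(sp2, 1L))
  pr2 <- splitsim:::split_params(build_network(sp2, 4L),
                                 split_network(sp2, 1L))
  ex2 <- rand_batch(sp2, 3L, seed = 5L)
  cfg2 <- mis_config()
  scores <- c()
  for (cp in list(pr$client, pr2$client)) {
    sm <- forward_client(cp, ex2, training = FALSE)$activations
    for (i in 1:3) {
      pp <- preprocess_pair(as.vector(ex2[, 1, i]), sm[, , i], cfg2,
                            modality = "series")
      scores <- c(scores, mutual_information_score(pp$x, pp$y))
    }
  }
  expect_equal(mis_epoch(list(pr$client, pr2$client), ex2, cfg2),
               mean(scores), tolerance = 1e-12)
})

test_that("layerwise profiles recompute per-layer pairwise scores", {
  sp <- toy_series_spec()
  p <- build_network(sp, 8L)
  withr::with_seed(3L, sample_x <- array(stats::rnorm(16), c(16, 1)))
  prof <- layerwise_mis(p, sample_x)
  expect_length(prof, 3L)
  cfg <- mis_config()
  for (c_ in 1:3) {
    client <- splitsim:::split_params(p, split_network(sp, c_))$client
    sm <- forward_client(client, array(sample_x, c(16, 1, 1)),
                         training = FALSE)$activations
    pp <- preprocess_pair(as.vector(sample_x),
                          array(sm, dim(sm)[1:2]), cfg,
                          modality = "series")
    expect_equal(prof[c_], mutual_information_score(pp$x, pp$y),
                 tolerance = 1e-12)
  }
  # all-identity single-block model: profile sits at the input entropy
  spd <- network_spec(list(block_spec("dense", 4L, activation = "none"),
                           block_spec("dense", 4L, activation = "none")),
                      input_shape = 4L, n_classes = 2L)
  pd <- build_network(spd, 0L)
  for (i in 1:2) {
    pd$blocks[[i]]$W <- diag(4)
    pd$blocks[[i]]$b <- rep(0, 4)
  }
  xq <- round(stats::runif(4), 1)
  prof2 <- layerwise_mis(pd, xq, mis_config(quantize_decimals = 6L))
  expect_equal(prof2, rep(entropy_plugin(xq), 2L), tolerance = 1e-12)
})

test_that("render_smashed writes normalized grayscale PNGs that round-trip", {
  f <- tempfile(fileext = ".png")
  # constant activations map to uniform mid-gray
  m <- render_smashed(array(3, c(5, 5, 1)), f)
  expect_true(all(m == 0.5))
  expect_true(file.exists(f))
  # fixed random activations round-trip through the file
  withr::with_seed(4L, a <- array(stats::runif(6 * 6 * 2), c(6, 6, 2)))
  norm <- render_smashed(a, f, channel = 2L)
  reread <- png::readPNG(f)
  expect_equal(reread, round(norm * 255) / 255, tolerance = 1e-8)
  rng <- range(a[, , 2])
  expect_equal(norm, (a[, , 2] - rng[1]) / diff(rng), tolerance = 1e-12)
  expect_error(render_smashed(array(NaN, c(3, 3, 1)), f), "non-finite")
  # identity client portion: render equals the normalized input channel
  ds <- tiny_image_dataset()
  x1 <- splitsim:::slice_samples(ds$test_x, 1L)
  img <- splitsim:::drop_sample_axis(x1)
  norm2 <- render_smashed(img, f, channel = 1L)
  rng2 <- range(img[, , 1])
  expect_equal(norm2, (img[, , 1] - rng2[1]) / diff(rng2),
               tolerance = 1e-12)
})
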