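# model_core: specs, counting, splitting, forward/backward correctness.

test_that("build_network is deterministic under seed and seed-sensitive", {
  sp <- toy_dense_spec()
  p1 <- build_network(sp, seed = 0L)
  p2 <- build_network(sp, seed = 0L)
  p3 <- build_network(sp, seed = 1L)
  expect_identical(param_vec(p1), param_vec(p2))
  expect_gt(max(abs(param_vec(p1) - param_vec(p3))), 0)
})

test_that("parameter counts match hand-enumerated shape products", {
  # dense 4 -> 3 -> 3 with biases, head 3 -> 2 with bias
  sp <- toy_dense_spec(n_in = 4L, hidden = 3L, n_classes = 2L)
  expect_identical(count_parameters(sp), 4L * 3L + 3L + 3L * 3L + 3L +
                     3L * 2L + 2L)
  expect_identical(count_parameters(sp), length(param_vec(build_network(sp))))
  # conv 3 channels -> 8 channels, 3x3 kernel with bias: 3*8*9 + 8 = 224
  spc <- network_spec(list(block_spec("conv2d", 8L, kernel = 3L),
                           block_spec("conv2d", 4L, kernel = 3L)),
                      input_shape = c(6L, 6L, 3L), n_classes = 2L)
  blk1 <- 3L * 8L * 9L + 8L
  expect_identical(count_parameters(spc),
                   blk1 + 8L * 4L * 9L + 4L + 4L * 2L + 2L)
  # built arrays agree with the analytic walk for every toy spec
  for (sp_i in list(toy_4block_spec(), toy_series_spec())) {
    expect_identical(count_parameters(sp_i),
                     length(param_vec(build_network(sp_i, 1L))))
  }
})

test_that("the packaged 18-layer residual spec counts 11.7M parameters", {
  n <- count_parameters(resnet18_spec())
  expect_identical(n, 11689512L)
  expect_equal(round(n / 1e6, 1), 11.7)
  expect_identical(length(resnet18_spec()$blocks), 9L)
})

test_that("split_network partitions blocks and validates the cut range", {
  sp <- toy_4block_spec()
  s1 <- split_network(sp, 1)
  expect_length(s1$client$blocks, 1L)
  expect_length(s1$server$blocks, 3L)
  s3 <- split_network(sp, 3)
  expect_length(s3$client$blocks, 3L)
  expect_length(s3$server$blocks, 1L)
  # re-concatenation restores the original block order
  expect_identical(c(s3$client$blocks, s3$server$blocks), sp$blocks)
  expect_error(split_network(sp, 0), "cut_layer")
  expect_error(split_network(sp, 5), "cut_layer")
  # all nine cuts of the packaged residual spec are admissible
  r <- resnet18_spec()
  for (c_ in 1:9) expect_silent(split_network(r, c_))
})

test_that("identity-weight and zero-input client forwards behave exactly", {
  sp <- network_spec(list(block_spec("dense", 3L, activation = "relu"),
                          block_spec("dense", 2L, activation = "none")),
                     input_shape = 3L, n_classes = 2L)
  p <- build_network(sp, 0L)
  p$blocks[[1L]]$W <- diag(3)
  p$blocks[[1L]]$b <- rep(0, 3)
  spl <- split_network(sp, 1L)
  pr <- splitsim:::split_params(p, spl)
  x <- matrix(c(1, -2, 3, -4, 5, 6), 3, 2)
  sm <- forward_client(pr$client, x, training = FALSE)$activations
  expect_equal(sm, pmax(x, 0), ignore_attr = TRUE)
  # zero batch through bias-free relu blocks stays zero
  p$blocks[[1L]]$b <- rep(0, 3)
  z <- forward_client(pr$client, matrix(0, 3, 4),
                      training = FALSE)$activations
  expect_true(all(z == 0))
  # shape mismatch is rejected with a descriptive error
  expect_error(forward_client(pr$client, matrix(0, 4, 2), training = FALSE),
               "input_shape")
})

test_that("split forward equals un-split forward at every admissible cut", {
  for (sp in list(toy_4block_spec(), toy_series_spec())) {
    p <- build_network(sp, 5L)
    x <- rand_batch(sp, 6L, seed = 2L)
    ref <- evaluate_logits <- NULL
    fe <- splitsim:::forward_blocks(p, splitsim:::to_engine(x),
                                    training = FALSE)
    ref <- splitsim:::head_forward(p$head, fe$out)$logits
    for (c_ in seq_along(sp$blocks)) {
      spl <- split_network(sp, c_)
      pr <- splitsim:::split_params(p, spl)
      sm <- forward_client(pr$client, x, training = FALSE)$activations
      se <- splitsim:::forward_blocks(pr$server, splitsim:::to_engine(sm),
                                      training = FALSE)
      lg <- splitsim:::head_forward(p$head, se$out)$logits
      expect_lt(max(abs(lg - ref)), 1e-6)
    }
  }
})

test_that("server gradient at the cut matches central finite differences", {
  sp <- toy_dense_spec(n_in = 4L, hidden = 3L, n_classes = 2L)
  p <- build_network(sp, 3L)
  xb <- rand_batch(sp, 3L, seed = 4L)
  yb <- c(0L, 1L, 0L)
  spl <- split_network(sp, 1L)
  pr <- splitsim:::split_params(p, spl)
  fc <- forward_client(pr$client, xb, training = TRUE)
  sv <- forward_backward_server(pr$server, smashed_batch(fc$activations, yb),
                                lr = 0)
  lossfn <- function(a) {
    r <- splitsim:::forward_blocks(pr$server, splitsim:::to_engine(a),
                                   training = TRUE)
    splitsim:::softmax_ce(splitsim:::head_forward(pr$server$head, r$out)$logits,
                          yb)$loss
  }
  eps <- 1e-5
  num <- array(0, dim(fc$activations))
  for (i in seq_along(num)) {
    ap <- fc$activations; ap[i] <- ap[i] + eps
    am <- fc$activations; am[i] <- am[i] - eps
    num[i] <- (lossfn(ap) - lossfn(am)) / (2 * eps)
  }
  rel <- max(abs(num - sv$grad_at_cut)) / max(abs(num))
  expect_lt(rel, 1e-4)
})

test_that("lr = 0 and zero gradients leave parameters unchanged", {
  sp <- toy_dense_spec()
  p <- build_network(sp, 1L)
  xb <- rand_batch(sp, 3L)
  yb <- c(0L, 1L, 0L)
  spl <- split_network(sp, 1L)
  pr <- splitsim:::split_params(p, spl)
  fc <- forward_client(pr$client, xb, training = TRUE)
  sv <- forward_backward_server(pr$server, smashed_batch(fc$activations, yb),
                                lr = 0)
  expect_identical(param_vec(sv$params), param_vec(pr$server))
  cl0 <- backward_client(fc$params, fc$cache, sv$grad_at_cut, lr = 0)
  expect_identical(param_vec(cl0), param_vec(pr$client))
  clz <- backward_client(fc$params, fc$cache,
                         array(0, dim(fc$activations)), lr = 0.5)
  expect_identical(param_vec(clz), param_vec(pr$client))
  expect_error(backward_client(pr$client, NULL, sv$grad_at_cut, 0.1),
               "cache")
})

test_that("one split training step equals one un-split step at every cut", {
  for (sp in list(toy_4block_spec(), toy_series_spec(), toy_dense_spec())) {
    p <- build_network(sp, 9L)
    xb <- rand_batch(sp, 5L, seed = 3L)
    yb <- rep_len(0:(sp$n_classes - 1L), 5L)
    full_after <- splitsim:::train_step_full(p, xb, yb, 0.1)$params
    for (c_ in seq_along(sp$blocks)) {
      st <- split_step(p, sp, c_, xb, yb, 0.1)
      expect_lt(pmax_diff(st$full, full_after), 1e-6)
    }
  }
})

test_that("batch-accuracy is exact when labels equal the model's argmax", {
  sp <- toy_dense_spec(n_classes = 3L)
  p <- build_network(sp, 2L)
  xb <- rand_batch(sp, 8L, seed = 5L)
  spl <- split_network(sp, 1L)
  pr <- splitsim:::split_params(p, spl)
  fc <- forward_client(pr$client, xb, training = TRUE)
  se <- splitsim:::forward_blocks(pr$server,
                                  splitsim:::to_engine(fc$activations),
                                  training = FALSE)
  lg <- splitsim:::head_forward(pr$server$head, se$out)$logits
  self_labels <- max.col(lg, ties.method = "first") - 1L
  sv <- forward_backward_server(pr$server,
                                smashed_batch(fc$activations, self_labels),
                                lr = 0)
  expect_equal(sv$batch_accuracy, 1.0)
})

test_that("parameter trajectories are bitwise reproducible over epochs", {
  ds <- tiny_series_dataset()
  cfg <- train_config(mode = "SFL", K = 2L, cut_layer = 1L, epochs = 3L,
                      lr = 0.05, batch_size = 16L, seed = 9L,
                      mis_samples = 0L)
  r1 <- run_training(ds, toy_series_spec(), cfg)
  r2 <- run_training(ds, toy_series_spec(), cfg)
  expect_identical(param_vec(r1$final_model), param_vec(r2$final_model))
  expect_identical(r1$metrics, r2$metrics)
})

test_that("network specs round-trip through JSON and checkpoints reload", {
  sp <- toy_4block_spec()
  f <- tempfile(fileext = ".json")
  write_network_spec(sp, f)
  sp2 <- read_network_spec(f)
  expect_identical(count_parameters(sp2), count_parameters(sp))
  expect_identical(length(sp2$blocks), length(sp$blocks))
  p <- build_network(sp, 4L)
  d <- tempfile()
  save_checkpoint(p, d, seed = 4L, epoch = 0L)
  p2 <- load_checkpoint(d)
  expect_equal(param_vec(p2), param_vec(p), tolerance = 1e-12)
})
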