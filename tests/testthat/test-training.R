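# training: sharding, FedAvg, epoch mechanics, mode semantics.

test_that("shard_iid makes disjoint near-equal shards covering all indices", {
  s <- shard_iid(10L, 5L, seed = 1L)
  expect_length(s, 5L)
  expect_identical(sort(unlist(s)), 1:10)
  expect_true(all(lengths(s) == 2L))
  s2 <- shard_iid(11L, 5L, seed = 1L)
  expect_identical(sort(lengths(s2)), c(2L, 2L, 2L, 2L, 3L))
  expect_identical(sort(unlist(s2)), 1:11)
  expect_error(shard_iid(3L, 5L), "shard")
  expect_identical(shard_iid(100L, 4L, seed = 3L),
                   shard_iid(100L, 4L, seed = 3L))
})

test_that("IID shards keep class frequencies inside binomial 99% bounds", {
  # 100 samples, 10 balanced classes, 5 shards of 20: per-shard class count
  # is Hypergeometric(100, 10, 20); the Binomial(20, 0.1) 99% envelope
  # [qbinom(.005), qbinom(.995)] is wider, so it bounds the draw
  lab <- rep(0:9, each = 10L)
  lo <- qbinom(0.005, 20, 0.1)
  hi <- qbinom(0.995, 20, 0.1)
  bad <- 0L
  for (seed in 1:5) {
    sh <- shard_iid(100L, 5L, seed = seed)
    for (s in sh) {
      counts <- tabulate(lab[s] + 1L, 10L)
      bad <- bad + sum(counts < lo | counts > hi)
    }
  }
  # 250 class-by-shard cells at the 1% level: allow a small number of
  # boundary exceedances
  expect_lte(bad, 6L)
})

test_that("fedavg reproduces identity, midpoint and weighted-mean oracles", {
  sp <- toy_dense_spec()
  spl <- split_network(sp, 1L)
  mk <- function(val) {
    p <- splitsim:::split_params(build_network(sp, 0L), spl)$client
    p$blocks[[1L]]$W[] <- val
    p$blocks[[1L]]$b[] <- val
    p
  }
  # averaging identical portions is the identity
  p1 <- splitsim:::split_params(build_network(sp, 5L), spl)$client
  avg <- fedavg(list(p1, p1, p1), c(10, 20, 30))
  expect_equal(param_vec(avg), param_vec(p1), tolerance = 1e-15)
  # {1.0} and {3.0} with equal shards -> {2.0}
  avg2 <- fedavg(list(mk(1), mk(3)), c(5, 5))
  expect_true(all(param_vec(avg2) == 2))
  # three portions, shard sizes 1, 2, 3: explicit weighted-mean oracle
  ps <- list(mk(1), mk(2), mk(4))
  w <- c(1, 2, 3) / 6
  oracle <- w[1] * param_vec(ps[[1]]) + w[2] * param_vec(ps[[2]]) +
    w[3] * param_vec(ps[[3]])
  expect_equal(param_vec(fedavg(ps, c(1, 2, 3))), oracle, tolerance = 1e-15)
  # shape mismatch is an error
  q <- splitsim:::split_params(build_network(sp, 0L),
                               split_network(sp, 2L))$client
  expect_error(fedavg(list(p1, q)), "compatible")
})

test_that("SFL synchronizes client portions and MHSL leaves them apart", {
  ds <- tiny_series_dataset()
  sp <- toy_series_spec()
  for (mode in c("SFL", "MHSL")) {
    cfg <- train_config(mode = mode, K = 2L, cut_layer = 2L, epochs = 1L,
                        lr = 0.05, batch_size = 8L, seed = 2L,
                        mis_samples = 0L)
    run <- run_training(ds, sp, cfg)
    d <- pmax_diff(run$clients[[1L]]$params, run$clients[[2L]]$params)
    if (mode == "SFL") expect_identical(d, 0) else expect_gt(d, 0)
    expect_identical(unique(run$epochs$fedavg_invoked), mode == "SFL")
  }
})

test_that("MHSL clients initialized apart stay apart within an epoch", {
  ds <- tiny_series_dataset()
  sp <- toy_series_spec()
  cfg <- train_config(mode = "MHSL", K = 2L, cut_layer = 1L, epochs = 1L,
                      lr = 0.01, batch_size = 8L, seed = 3L,
                      client_seeds = c(11L, 22L), mis_samples = 0L)
  run <- run_training(ds, sp, cfg)
  expect_gt(pmax_diff(run$clients[[1L]]$params, run$clients[[2L]]$params), 0)
})

test_that("SFL and MHSL histories coincide exactly at K = 1", {
  ds <- tiny_series_dataset()
  sp <- toy_series_spec()
  runs <- lapply(c("SFL", "MHSL"), function(m) {
    run_training(ds, sp, train_config(mode = m, K = 1L, cut_layer = 2L,
                                      epochs = 2L, lr = 0.05,
                                      batch_size = 8L, seed = 4L))
  })
  expect_identical(runs[[1]]$metrics$train_loss, runs[[2]]$metrics$train_loss)
  expect_identical(runs[[1]]$metrics$test_acc, runs[[2]]$metrics$test_acc)
  expect_identical(param_vec(runs[[1]]$final_model),
                   param_vec(runs[[2]]$final_model))
})

test_that("each epoch consumes every shard exactly once", {
  ds <- tiny_series_dataset(n_train = 50L)
  cfg <- train_config(mode = "MHSL", K = 3L, cut_layer = 1L, epochs = 2L,
                      lr = 0.01, batch_size = 7L, seed = 5L,
                      mis_samples = 0L)
  run <- run_training(ds, toy_series_spec(), cfg)
  expect_true(all(run$epochs$samples_processed == 50L))
})

test_that("evaluate matches a manual recount and handles forced cases", {
  ds <- tiny_series_dataset()
  sp <- toy_series_spec()
  p <- build_network(sp, 6L)
  spl <- split_network(sp, 1L)
  pr <- splitsim:::split_params(p, spl)
  acc <- evaluate(pr$client, pr$server, ds$test_x, ds$test_labels)
  # manual recount sample by sample
  correct <- 0L
  for (i in seq_along(ds$test_labels)) {
    sm <- forward_client(pr$client,
                         splitsim:::slice_samples(ds$test_x, i),
                         training = FALSE)$activations
    fe <- splitsim:::forward_blocks(pr$server, splitsim:::to_engine(sm),
                                    training = FALSE)
    lg <- splitsim:::head_forward(pr$server$head, fe$out)$logits
    correct <- correct + ((which.max(lg) - 1L) == ds$test_labels[i])
  }
  expect_equal(acc, correct / length(ds$test_labels))
  # labels replaced by the model's own argmax give accuracy 1
  full <- assemble_full_model(pr$client, pr$server)
  fe <- splitsim:::forward_blocks(full, splitsim:::to_engine(ds$test_x),
                                  training = FALSE)
  own <- max.col(splitsim:::head_forward(full$head, fe$out)$logits,
                 ties.method = "first") - 1L
  expect_equal(evaluate(pr$client, pr$server, ds$test_x, own), 1.0)
  expect_error(evaluate(pr$client, pr$server,
                        splitsim:::slice_samples(ds$test_x, integer(0)),
                        integer(0)), "empty")
})

test_that("constant predictions on a balanced set score one over n_classes", {
  sp <- toy_series_spec()
  p <- build_network(sp, 1L)
  # zero head weights force identical logits for every class; argmax ties
  # resolve to class 0, so accuracy is the class-0 frequency
  p$head$W[] <- 0
  p$head$b[] <- 0
  n <- 30L
  x <- rand_batch(sp, n)
  y <- rep_len(0:2, n)
  expect_equal(evaluate(p, NULL, x, y), mean(y == 0L))
})

test_that("assembled full models reproduce the split pipeline and agree
           across clients after SFL aggregation", {
  ds <- tiny_series_dataset()
  sp <- toy_series_spec()
  run <- run_training(ds, sp, train_config(mode = "SFL", K = 3L,
                                           cut_layer = 2L, epochs = 1L,
                                           lr = 0.05, batch_size = 8L,
                                           seed = 6L, mis_samples = 0L))
  accs <- vapply(1:3, function(k) {
    evaluate(assemble_full_model(run$clients[[k]]$params, run$server_params),
             NULL, ds$test_x, ds$test_labels)
  }, 0)
  expect_identical(accs[1], accs[2])
  expect_identical(accs[1], accs[3])
  # round trip: assembled forward equals client-then-server pipeline
  full <- assemble_full_model(run$clients[[1L]]$params, run$server_params)
  for (i in 1:3) {
    x <- rand_batch(sp, 4L, seed = i)
    sm <- forward_client(run$clients[[1L]]$params, x,
                         training = FALSE)$activations
    fe <- splitsim:::forward_blocks(run$server_params,
                                    splitsim:::to_engine(sm),
                                    training = FALSE)
    l_pipe <- splitsim:::head_forward(run$server_params$head, fe$out)$logits
    ff <- splitsim:::forward_blocks(full, splitsim:::to_engine(x),
                                    training = FALSE)
    l_full <- splitsim:::head_forward(full$head, ff$out)$logits
    expect_lt(max(abs(l_pipe - l_full)), 1e-6)
  }
  # MHSL: three different heads give three (reported) accuracies;
  # the final model defaults to client 1's portion
  run2 <- run_training(ds, sp, train_config(mode = "MHSL", K = 3L,
                                            cut_layer = 2L, epochs = 1L,
                                            lr = 0.05, batch_size = 8L,
                                            seed = 6L, mis_samples = 0L))
  expect_length(run2$metrics$test_acc[run2$metrics$epoch == 1L], 3L)
  expect_identical(param_vec(run2$final_model),
                   param_vec(assemble_full_model(run2$clients[[1L]]$params,
                                                 run2$server_params)))
  expect_error(assemble_full_model(run2$server_params, run2$server_params))
})

test_that("a linearly separable task trains to high accuracy", {
  # wide-margin two-class signals; the centroid oracle already separates
  # them, and split training should reach it
  ds <- gen_timeseries(generator_config(n_train = 120L, n_test = 60L,
                                        n_classes = 2L, length = 16L,
                                        noise_sd = 0.05,
                                        class_separation = 2, seed = 11L))
  expect_equal(nearest_centroid_accuracy(ds), 1.0)
  sp <- network_spec(list(block_spec("conv1d", 4L, kernel = 5L),
                          block_spec("conv1d", 8L, kernel = 3L,
                                     stride = 2L)),
                     input_shape = c(16L, 1L), n_classes = 2L)
  run <- run_training(ds, sp, train_config(mode = "SFL", K = 2L,
                                           cut_layer = 1L, epochs = 20L,
                                           lr = 0.05, batch_size = 16L,
                                           seed = 12L, mis_samples = 0L))
  expect_gte(run$epochs$mean_test_acc[20L], 0.95)
})

test_that("tidy and glance summarize runs in tabular form", {
  ds <- tiny_series_dataset()
  run <- run_training(ds, toy_series_spec(),
                      train_config(mode = "SFL", K = 2L, cut_layer = 1L,
                                   epochs = 2L, lr = 0.01, batch_size = 8L,
                                   seed = 13L, mis_samples = 4L))
  td <- tidy(run)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 4L)  # epochs x clients
  expect_true(all(c("mode", "epoch", "client", "test_acc") %in% names(td)))
  gl <- glance(run)
  expect_identical(nrow(gl), 1L)
  expect_true(gl$final_test_acc >= 0 && gl$final_test_acc <= 1)
  expect_true(is.finite(gl$final_mis))
  files <- export_run(run, tempfile("exp_"))
  expect_true(all(file.exists(files)))
})
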