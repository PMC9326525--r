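# Shared fixtures: toy specs, tiny datasets, independent oracles.

toy_dense_spec <- function(n_in = 4L, hidden = 3L, n_classes = 2L) {
  network_spec(list(block_spec("dense", hidden, activation = "relu"),
                    block_spec("dense", hidden, activation = "relu")),
               input_shape = n_in, n_classes = n_classes,
               name = "toy_dense")
}

toy_4block_spec <- function() {
  network_spec(list(block_spec("conv2d", 4L, kernel = 3L),
                    block_spec("conv2d", 6L, kernel = 3L, stride = 2L),
                    block_spec("conv2d", 6L, kernel = 3L),
                    block_spec("conv2d", 8L, kernel = 3L)),
               input_shape = c(8L, 8L, 2L), n_classes = 3L,
               name = "toy4")
}

toy_series_spec <- function() {
  network_spec(list(block_spec("conv1d", 4L, kernel = 5L),
                    block_spec("conv1d", 6L, kernel = 3L, stride = 2L),
                    block_spec("conv1d", 6L, kernel = 3L)),
               input_shape = c(16L, 1L), n_classes = 3L,
               name = "toy1d")
}

tiny_series_dataset <- function(n_train = 60L, n_test = 30L, seed = 7L) {
  gen_timeseries(generator_config(n_train = n_train, n_test = n_test,
                                  n_classes = 3L, length = 16L,
                                  noise_sd = 0.1, seed = seed))
}

tiny_image_dataset <- function(n_train = 60L, n_test = 30L, seed = 7L,
                               channels = 3L) {
  gen_images(generator_config(n_train = n_train, n_test = n_test,
                              n_classes = 3L, channels = channels,
                              height = 8L, width = 8L, noise_sd = 0.05,
                              seed = seed, modality = "image"))
}

rand_batch <- function(spec, n, seed = 1L) {
  withr::with_seed(seed, array(stats::rnorm(prod(spec$input_shape) * n),
                               c(spec$input_shape, n)))
}

# exhaustive contingency-table mutual information (independent oracle)
mis_brute <- function(x, y) {
  N <- length(x)
  s <- 0
  for (a in unique(x)) for (b in unique(y)) {
    nij <- sum(x == a & y == b)
    if (nij > 0)
      s <- s + nij / N * log(N * nij / (sum(x == a) * sum(y == b)))
  }
  s
}

# run one split training step by hand through the public operations
split_step <- function(full_params, spec, cut, xb, yb, lr) {
  spl <- split_network(spec, cut)
  pr <- splitsim:::split_params(full_params, spl)
  fc <- forward_client(pr$client, xb, training = TRUE)
  sv <- forward_backward_server(pr$server,
                                smashed_batch(fc$activations, yb), lr)
  cl <- backward_client(fc$params, fc$cache, sv$grad_at_cut, lr)
  list(client = cl, server = sv$params,
       full = assemble_full_model(cl, sv$params),
       grad_at_cut = sv$grad_at_cut, activations = fc$activations,
       loss = sv$loss)
}

param_vec <- function(p) splitsim:::param_vector(p)
pmax_diff <- function(a, b) splitsim:::param_max_diff(a, b)
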