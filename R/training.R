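#' Training configuration for split runs
#'
#' Defaults follow the study setting: five clients, learning rate 1e-3,
#' plain mini-batch SGD.  `mode = "SFL"` is splitfedv2 (one server model,
#' client portions federated-averaged each epoch); `mode = "MHSL"` removes
#' the client-side synchronization so each client keeps an independent head.
#'
#' @param mode `"SFL"` or `"MHSL"`.
#' @param K Number of clients (>= 1).
#' @param cut_layer Block boundary at which the model is split.
#' @param epochs Number of global epochs.
#' @param lr Learning rate for plain SGD.
#' @param batch_size Mini-batch size.
#' @param seed Integer seed governing initialization, sharding, batch order
#'   and the leakage evaluation subset.
#' @param aggregation_weighting `"shard_size"` (FedAvg weights proportional
#'   to shard sizes) or `"uniform"`.
#' @param final_client Which client's portion forms the final full model
#'   (relevant for MHSL, where portions differ).
#' @param client_seeds Optional integer vector of length `K`: per-client
#'   initialization seeds.  Default `NULL` gives every client the same
#'   initial portion, i.e. a single full model is split and distributed.
#' @param mis_samples Evaluation samples per epoch for the leakage trace
#'   (0 disables the trace).
#' @param mis_config A [mis_config()] controlling leakage preprocessing.
#' @return A `train_config` list.
#' @export
train_config <- function(mode = c("SFL", "MHSL"), K = 5L, cut_layer = 1L,
                         epochs = 10L, lr = 1e-3, batch_size = 32L,
                         seed = 1L,
                         aggregation_weighting = c("shard_size", "uniform"),
                         final_client = 1L, client_seeds = NULL,
                         mis_samples = 32L, mis_config = NULL) {
  mode <- match.arg(mode)
  aggregation_weighting <- match.arg(aggregation_weighting)
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  if (epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  if (lr < 0) stop("lr must be >= 0", call. = FALSE)
  if (!is.null(client_seeds) && length(client_seeds) != K)
    stop("client_seeds must have length K", call. = FALSE)
  structure(list(mode = mode, K = as.integer(K),
                 cut_layer = as.integer(cut_layer),
                 epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 aggregation_weighting = aggregation_weighting,
                 final_client = as.integer(final_client),
                 client_seeds = client_seeds,
                 mis_samples = as.integer(mis_samples),
                 mis_config = mis_config %||% mis_config()),
            class = "train_config")
}

#' Partition sample indices into IID client shards
#'
#' A seeded uniform permutation is split into `K` disjoint shards whose
#' sizes differ by at most one, so shards share the data distribution.
#'
#' @param n Number of samples (or a dataset from [gen_timeseries()] /
#'   [gen_images()], whose training split size is used).
#' @param K Number of clients.
#' @param seed Integer seed.
#' @return List of `K` integer index vectors.
#' @export
shard_iid <- function(n, K, seed = 1L) {
  if (inherits(n, "sim_dataset")) n <- length(n$train_labels)
  n <- as.integer(n); K <- as.integer(K)
  if (K > n) stop("cannot shard ", n, " samples across ", K, " clients",
                  call. = FALSE)
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  sizes <- rep(n %/% K, K) + (seq_len(K) <= n %% K)
  unname(split(perm, rep(seq_len(K), times = sizes)))
}

#' Federated averaging of client-side model portions
#'
#' Element-wise weighted mean of shape-compatible parameter sets, with
#' weights proportional to shard sizes (or uniform).  Normalization running
#' statistics are averaged along with the trainable parameters, keeping the
#' aggregation a literal weight average.
#'
#' @param portions List of `param_set`s (the client portions).
#' @param shard_sizes Integer vector of per-client shard sizes; `NULL` means
#'   uniform weights.
#' @return A single averaged `param_set`.
#' @export
fedavg <- function(portions, shard_sizes = NULL) {
  K <- length(portions)
  if (K == 0L) stop("no portions to average", call. = FALSE)
  w <- if (is.null(shard_sizes)) rep(1 / K, K)
  else shard_sizes / sum(shard_sizes)
  sizes <- vapply(portions, function(p) length(param_vector(p)), 0)
  if (length(unique(sizes)) != 1L)
    stop("portions are not shape-compatible (",
         paste(sizes, collapse = ", "), " elements)", call. = FALSE)
  wavg <- function(xs) {
    if (is.list(xs[[1L]])) {
      out <- xs[[1L]]
      for (k in names(out))
        out[[k]] <- wavg(lapply(xs, `[[`, k))
      out
    } else {
      out <- xs[[1L]] * w[1L]
      for (i in seq_len(K)[-1L]) out <- out + xs[[i]] * w[i]
      out
    }
  }
  avg <- portions[[1L]]
  for (i in seq_along(avg$blocks))
    avg$blocks[[i]] <- wavg(lapply(portions, function(p) p$blocks[[i]]))
  if (!is.null(avg$head))
    avg$head <- wavg(lapply(portions, `[[`, "head"))
  avg
}

# deterministic round-robin batch schedule: client 1 batch 1, client 2
# batch 1, ..., client 1 batch 2, ...  Shard orders are shuffled with the
# epoch's derived seed before batching.
epoch_schedule <- function(shards, batch_size, epoch_seed) {
  K <- length(shards)
  batches <- withr::with_seed(epoch_seed, {
    lapply(shards, function(idx) {
      idx <- idx[sample.int(length(idx))]
      split(idx, ceiling(seq_along(idx) / batch_size))
    })
  })
  nb <- vapply(batches, length, 0L)
  sched <- list()
  for (b in seq_len(max(nb))) for (k in seq_len(K)) {
    if (b <= nb[k]) sched[[length(sched) + 1L]] <- list(client = k,
                                                        idx = batches[[k]][[b]])
  }
  sched
}

#' Run one global epoch of split training
#'
#' Every client's shard is consumed exactly once in mini-batches, with
#' client batches interleaved round-robin; the single server-side model is
#' updated on each smashed batch in that order.  In SFL the client portions
#' are replaced by their federated average at the epoch's end.
#'
#' @param clients List of client states (fields `client_id`, `params`,
#'   `shard`), as created by [run_training()].
#' @param server_params Server fragment `param_set`.
#' @param dataset A dataset from [gen_timeseries()] / [gen_images()].
#' @param config A [train_config()].
#' @param epoch Integer epoch number (drives the shuffle seed).
#' @return List: updated `clients`, `server_params`, a `metrics` tibble (one
#'   row per client), and communication counters in elements
#'   (`smashed_elements`, `sync_elements`).
#' @export
train_epoch <- function(clients, server_params, dataset, config, epoch = 1L) {
  K <- length(clients)
  shards <- lapply(clients, `[[`, "shard")
  sched <- epoch_schedule(shards, config$batch_size,
                          epoch_seed = config$seed + 1000L + epoch)
  loss_sum <- acc_sum <- n_sum <- numeric(K)
  smashed_elements <- 0
  for (job in sched) {
    k <- job$client
    xb <- slice_samples(dataset$train_x, job$idx)
    yb <- dataset$train_labels[job$idx]
    fc <- forward_client(clients[[k]]$params, xb, training = TRUE)
    clients[[k]]$params <- fc$params
    sb <- smashed_batch(fc$activations, yb, client_id = k, epoch = epoch)
    sv <- forward_backward_server(server_params, sb, config$lr)
    server_params <- sv$params
    clients[[k]]$params <- backward_client(clients[[k]]$params, fc$cache,
                                           sv$grad_at_cut, config$lr)
    nb <- length(yb)
    loss_sum[k] <- loss_sum[k] + sv$loss * nb
    acc_sum[k] <- acc_sum[k] + sv$batch_accuracy * nb
    n_sum[k] <- n_sum[k] + nb
    # activations up + gradients down
    smashed_elements <- smashed_elements + 2 * length(fc$activations)
  }
  sync_elements <- 0
  fedavg_invoked <- FALSE
  if (config$mode == "SFL") {
    sizes <- if (config$aggregation_weighting == "shard_size")
      vapply(shards, length, 0L)
    avg <- fedavg(lapply(clients, `[[`, "params"), sizes)
    portion_elems <- length(param_vector(avg))
    for (k in seq_len(K)) clients[[k]]$params <- avg
    # each client uploads its portion and downloads the average
    sync_elements <- 2 * K * portion_elems
    fedavg_invoked <- TRUE
  }
  # after SFL synchronization every client portion is identical, so one
  # evaluation serves all clients; MHSL portions differ and need their own
  test_acc <- if (fedavg_invoked) {
    rep(evaluate(clients[[1L]]$params, server_params,
                 dataset$test_x, dataset$test_labels), K)
  } else {
    vapply(seq_len(K), function(k) {
      evaluate(clients[[k]]$params, server_params,
               dataset$test_x, dataset$test_labels)
    }, 0)
  }
  metrics <- tibble::tibble(
    epoch = as.integer(epoch), client = seq_len(K),
    train_loss = loss_sum / n_sum, train_acc = acc_sum / n_sum,
    test_acc = test_acc)
  list(clients = clients, server_params = server_params, metrics = metrics,
       smashed_elements = smashed_elements, sync_elements = sync_elements,
       fedavg_invoked = fedavg_invoked,
       samples_processed = sum(n_sum))
}

#' Run a full split-training experiment
#'
#' Builds and splits the network, distributes the client portion, shards the
#' data IID, then runs `config$epochs` global epochs of [train_epoch()],
#' evaluating every client on the shared test set each epoch and recording
#' the leakage (mutual information) trace on a fixed seeded test subset.
#'
#' All randomness (initialization, sharding, shuffles, leakage subset) is
#' derived from `config$seed`, so identical calls give identical histories.
#'
#' @param dataset Dataset from [gen_timeseries()] / [gen_images()].
#' @param spec Full-network [network_spec()].
#' @param config A [train_config()].
#' @return A `split_run` object: `config`, tibbles `metrics` (per epoch x
#'   client), `epochs` (per-epoch summary incl. communication counters and
#'   leakage score), the `final_model` `param_set`, per-client portions and
#'   the server portion.
#' @export
run_training <- function(dataset, spec, config) {
  stopifnot(inherits(config, "train_config"))
  split <- split_network(spec, config$cut_layer)
  full0 <- build_network(spec, seed = config$seed)
  parts <- split_params(full0, split)
  server_params <- parts$server
  shards <- shard_iid(length(dataset$train_labels), config$K,
                      seed = config$seed + 1L)
  clients <- lapply(seq_len(config$K), function(k) {
    params <- if (is.null(config$client_seeds)) parts$client
    else split_params(build_network(spec, seed = config$client_seeds[k]),
                      split)$client
    list(client_id = k, params = params, shard = shards[[k]],
         shard_size = length(shards[[k]]))
  })
  n_eval <- min(config$mis_samples,
                length(dataset$test_labels))
  mis_idx <- if (n_eval > 0L)
    withr::with_seed(config$seed + 2L,
                     sample.int(length(dataset$test_labels), n_eval))
  metrics <- vector("list", config$epochs)
  epoch_rows <- vector("list", config$epochs)
  for (e in seq_len(config$epochs)) {
    r <- train_epoch(clients, server_params, dataset, config, epoch = e)
    clients <- r$clients
    server_params <- r$server_params
    metrics[[e]] <- r$metrics
    mis <- if (!is.null(mis_idx))
      mis_epoch(lapply(clients, `[[`, "params"),
                slice_samples(dataset$test_x, mis_idx),
                config$mis_config)
    else NA_real_
    epoch_rows[[e]] <- tibble::tibble(
      epoch = as.integer(e),
      mean_test_acc = mean(r$metrics$test_acc),
      mean_train_loss = stats::weighted.mean(
        r$metrics$train_loss,
        vapply(clients, `[[`, 0L, "shard_size")),
      smashed_elements = r$smashed_elements,
      sync_elements = r$sync_elements,
      fedavg_invoked = r$fedavg_invoked,
      samples_processed = r$samples_processed,
      mis = mis)
  }
  final_model <- assemble_full_model(clients[[config$final_client]]$params,
                                     server_params)
  structure(list(config = config, spec = spec,
                 metrics = dplyr::bind_rows(metrics),
                 epochs = dplyr::bind_rows(epoch_rows),
                 clients = clients, server_params = server_params,
                 final_model = final_model,
                 smashed_per_sample = smashed_elements(spec,
                                                       config$cut_layer)),
            class = "split_run")
}

#' @export
print.split_run <- function(x, ...) {
  cat("<split_run> ", x$config$mode, ", K=", x$config$K,
      ", cut=", x$config$cut_layer, ", ", x$config$epochs, " epoch(s)\n",
      sep = "")
  last <- x$epochs[nrow(x$epochs), ]
  cat(sprintf("  final mean test accuracy: %.4f\n", last$mean_test_acc))
  if (!is.na(last$mis))
    cat(sprintf("  final leakage score (nats): %.4f\n", last$mis))
  invisible(x)
}

#' Export a run's metrics and summary to disk
#'
#' Writes `metrics.csv` (one row per epoch per client), `epochs.csv`
#' (per-epoch summary incl. communication counters and leakage), and
#' `summary.json`.
#'
#' @param run A `split_run`.
#' @param dir Output directory (created if needed).
#' @param stem Filename stem, default the run's mode.
#' @return Invisible character vector of the files written.
#' @export
export_run <- function(run, dir, stem = tolower(run$config$mode)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f1 <- file.path(dir, paste0(stem, "_metrics.csv"))
  f2 <- file.path(dir, paste0(stem, "_epochs.csv"))
  f3 <- file.path(dir, paste0(stem, "_summary.json"))
  utils::write.csv(run$metrics, f1, row.names = FALSE)
  utils::write.csv(run$epochs, f2, row.names = FALSE)
  jsonlite::write_json(glance(run), f3, auto_unbox = TRUE, digits = NA)
  invisible(c(f1, f2, f3))
}
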