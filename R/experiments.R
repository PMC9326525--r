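#' Configuration for an experiment grid
#'
#' One config drives a grid of runs over modes, cut layers and seeds on a
#' single dataset and network, writing per-run metric CSVs, leakage CSVs
#' and a summary JSON (including the MHSL-minus-SFL accuracy delta) under
#' `output_dir`.
#'
#' @param dataset A `sim_dataset`, a [generator_config()] (the dataset is
#'   generated on demand), or a directory path for [load_dataset()].
#' @param spec A [network_spec()].
#' @param modes Subset of `c("SFL", "MHSL", "centralized")`.
#' @param cut_layers Integer vector of cut layers.
#' @param K Number of clients.
#' @param epochs Global epochs per run.
#' @param seeds Non-empty integer vector of run seeds.
#' @param lr Learning rate.
#' @param batch_size Mini-batch size.
#' @param output_dir Output directory.
#' @param best_epoch Report the best epoch's mean test accuracy instead of
#'   the final epoch's in summaries.
#' @param mis_samples Leakage evaluation samples per epoch (0 disables).
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(dataset, spec, modes = c("SFL", "MHSL"),
                              cut_layers = 1L, K = 5L, epochs = 10L,
                              seeds = 1L, lr = 1e-3, batch_size = 32L,
                              output_dir = tempfile("splitsim_"),
                              best_epoch = FALSE, mis_samples = 32L) {
  modes <- match.arg(modes, c("SFL", "MHSL", "centralized"),
                     several.ok = TRUE)
  if (!length(seeds)) stop("seeds must be non-empty", call. = FALSE)
  L <- length(spec$blocks)
  if (any(cut_layers < 1L | cut_layers > L))
    stop("cut_layers must lie in [1, ", L, "]", call. = FALSE)
  structure(list(dataset = dataset, spec = spec, modes = modes,
                 cut_layers = as.integer(cut_layers), K = as.integer(K),
                 epochs = as.integer(epochs), seeds = as.integer(seeds),
                 lr = lr, batch_size = as.integer(batch_size),
                 output_dir = output_dir, best_epoch = isTRUE(best_epoch),
                 mis_samples = as.integer(mis_samples)),
            class = "experiment_config")
}

resolve_dataset <- function(dataset) {
  if (inherits(dataset, "sim_dataset")) return(dataset)
  if (inherits(dataset, "generator_config")) {
    return(if (dataset$modality == "image") gen_images(dataset)
           else gen_timeseries(dataset))
  }
  if (is.character(dataset)) return(load_dataset(dataset))
  stop("unsupported dataset argument", call. = FALSE)
}

run_one <- function(ds, config, mode, cut, seed) {
  if (mode == "centralized")
    return(run_centralized(ds, config$spec,
                           epochs = config$epochs, lr = config$lr,
                           batch_size = config$batch_size, seed = seed))
  tc <- train_config(mode = mode, K = config$K, cut_layer = cut,
                     epochs = config$epochs, lr = config$lr,
                     batch_size = config$batch_size, seed = seed,
                     mis_samples = config$mis_samples)
  run_training(ds, config$spec, tc)
}

summary_acc <- function(run, best_epoch = FALSE) {
  if (best_epoch) max(run$epochs$mean_test_acc)
  else run$epochs$mean_test_acc[nrow(run$epochs)]
}

#' Run the full experiment grid
#'
#' For every (mode, cut layer, seed) combination: trains, writes
#' `metrics_<mode>_cut<k>_seed<s>.csv` and `mis_<...>.csv`, and collects a
#' summary tibble written as `summary.json` together with a manifest
#' (config hash, package version).  When both SFL and MHSL are present the
#' summary gains a `delta_mhsl_sfl` accuracy column (MHSL minus SFL, in
#' accuracy fractions).
#'
#' @param config An [experiment_config()].
#' @return The output directory, invisibly; the summary tibble is attached
#'   as attribute `"summary"`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  ds <- resolve_dataset(config$dataset)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (mode in config$modes) {
    cuts <- if (mode == "centralized") NA_integer_ else config$cut_layers
    for (cut in cuts) for (seed in config$seeds) {
      run <- run_one(ds, config, mode, cut, seed)
      stem <- if (mode == "centralized")
        sprintf("centralized_seed%d", seed)
      else sprintf("%s_cut%d_seed%d", tolower(mode), cut, seed)
      utils::write.csv(run$metrics,
                       file.path(config$output_dir,
                                 paste0("metrics_", stem, ".csv")),
                       row.names = FALSE)
      if (!is.null(run$epochs$mis) && !all(is.na(run$epochs$mis)))
        utils::write.csv(run$epochs[, c("epoch", "mis")],
                         file.path(config$output_dir,
                                   paste0("mis_", stem, ".csv")),
                         row.names = FALSE)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        mode = mode, cut_layer = cut, seed = seed,
        test_acc = summary_acc(run, config$best_epoch),
        final_mis = run$epochs$mis[nrow(run$epochs)] %||% NA_real_)
    }
  }
  summary <- dplyr::bind_rows(rows)
  if (all(c("SFL", "MHSL") %in% config$modes)) {
    wide <- tidyr::pivot_wider(
      dplyr::summarise(dplyr::group_by(
        dplyr::filter(summary, .data$mode %in% c("SFL", "MHSL")),
        .data$mode, .data$cut_layer, .data$seed),
        test_acc = mean(.data$test_acc), .groups = "drop"),
      names_from = "mode", values_from = "test_acc")
    wide$delta_mhsl_sfl <- wide$MHSL - wide$SFL
    utils::write.csv(wide, file.path(config$output_dir, "delta.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(summary, file.path(config$output_dir, "summary.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(config_hash = rlang::hash(config[setdiff(names(config),
                                                  "output_dir")]),
         package = "splitsim",
         version = as.character(utils::packageVersion("splitsim")),
         modes = config$modes, cut_layers = config$cut_layers,
         K = config$K, epochs = config$epochs, seeds = config$seeds),
    file.path(config$output_dir, "manifest.json"), auto_unbox = TRUE)
  structure(invisible(config$output_dir), summary = summary)
}

#' Cut-layer sweep table
#'
#' Mean final test accuracy over seeds for every (mode, cut layer) cell,
#' the desk-scale analogue of a split-position sweep.  Columns are labelled
#' `L1..Lmax`.
#'
#' @param config An [experiment_config()] with at least two cut layers.
#' @return A tibble: one row per mode, one `L<k>` column per cut layer
#'   (accuracy fractions); written to `sweep.csv` under `output_dir`.
#' @export
sweep_cut_layers <- function(config) {
  if (length(config$cut_layers) < 2L)
    stop("a sweep needs at least 2 cut layers", call. = FALSE)
  ds <- resolve_dataset(config$dataset)
  modes <- setdiff(config$modes, "centralized")
  cells <- list()
  for (mode in modes) for (cut in config$cut_layers) {
    accs <- vapply(config$seeds, function(seed) {
      summary_acc(run_one(ds, config, mode, cut, seed), config$best_epoch)
    }, 0)
    cells[[length(cells) + 1L]] <- tibble::tibble(
      mode = mode, cut_layer = cut, mean_test_acc = mean(accs))
  }
  long <- dplyr::bind_rows(cells)
  wide <- tidyr::pivot_wider(long, names_from = "cut_layer",
                             values_from = "mean_test_acc",
                             names_prefix = "L")
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(wide, file.path(config$output_dir, "sweep.csv"),
                   row.names = FALSE)
  wide
}

#' Centralized (un-split) training baseline
#'
#' Trains the full network on the pooled training data with the same seeded
#' shuffling discipline as the split runs: by construction it produces
#' exactly the metric sequence of an SFL run with `K = 1` and the same
#' seed.
#'
#' @param dataset A `sim_dataset`.
#' @param spec A [network_spec()].
#' @param epochs,lr,batch_size,seed Training settings.
#' @return A `split_run`-shaped object (mode `"centralized"`).
#' @export
run_centralized <- function(dataset, spec, epochs = 10L, lr = 1e-3,
                            batch_size = 32L, seed = 1L) {
  params <- build_network(spec, seed = seed)
  shard <- shard_iid(length(dataset$train_labels), 1L, seed = seed + 1L)[[1L]]
  metrics <- vector("list", epochs)
  epoch_rows <- vector("list", epochs)
  for (e in seq_len(epochs)) {
    sched <- epoch_schedule(list(shard), batch_size,
                            epoch_seed = seed + 1000L + e)
    loss_sum <- acc_sum <- n_sum <- 0
    for (job in sched) {
      xb <- slice_samples(dataset$train_x, job$idx)
      yb <- dataset$train_labels[job$idx]
      st <- train_step_full(params, xb, yb, lr)
      params <- st$params
      nb <- length(yb)
      loss_sum <- loss_sum + st$loss * nb
      acc_sum <- acc_sum + st$accuracy * nb
      n_sum <- n_sum + nb
    }
    acc <- evaluate(params, NULL, dataset$test_x, dataset$test_labels)
    metrics[[e]] <- tibble::tibble(epoch = as.integer(e), client = 1L,
                                   train_loss = loss_sum / n_sum,
                                   train_acc = acc_sum / n_sum,
                                   test_acc = acc)
    epoch_rows[[e]] <- tibble::tibble(epoch = as.integer(e),
                                      mean_test_acc = acc,
                                      mean_train_loss = loss_sum / n_sum,
                                      smashed_elements = 0,
                                      sync_elements = 0,
                                      fedavg_invoked = FALSE,
                                      samples_processed = n_sum,
                                      mis = NA_real_)
  }
  structure(list(config = list(mode = "centralized", K = 1L,
                               epochs = as.integer(epochs), lr = lr,
                               batch_size = as.integer(batch_size),
                               seed = as.integer(seed)),
                 spec = spec,
                 metrics = dplyr::bind_rows(metrics),
                 epochs = dplyr::bind_rows(epoch_rows),
                 final_model = params),
            class = "split_run")
}

#' Smashed-data gallery
#'
#' For a handful of test inputs, renders the input image alongside the SFL
#' and MHSL cut-layer activations of trained runs (the usual visual
#' leakage comparison, by default at cut layer 3 and the final epoch), plus
#' one contact sheet combining all panels.
#'
#' @param run_sfl,run_mhsl Trained `split_run`s for the two modes at the
#'   same cut layer.
#' @param dataset The `sim_dataset` the runs were trained on.
#' @param dir Output directory for the PNG files.
#' @param n_inputs Number of test inputs to render.
#' @param client Which client's portion produces the smashed data.
#' @param seed Seed for choosing the inputs.
#' @return Invisible character vector of files written
#'   (`3 * n_inputs` panels + 1 contact sheet).
#' @export
gallery <- function(run_sfl, run_mhsl, dataset, dir, n_inputs = 2L,
                    client = 1L, seed = 1L) {
  for (r in list(SFL = run_sfl, MHSL = run_mhsl)) {
    if (is.null(r$clients))
      stop("gallery needs trained split runs for both modes", call. = FALSE)
  }
  if (dataset$modality != "image")
    stop("gallery needs an image dataset", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- withr::with_seed(seed,
                          sample.int(length(dataset$test_labels), n_inputs))
  files <- character(0)
  panels <- list()
  for (i in seq_along(idx)) {
    x1 <- slice_samples(dataset$test_x, idx[i])
    input_img <- drop_sample_axis(x1)[, , 1L]
    f_in <- file.path(dir, sprintf("input_%02d.png", i))
    png::writePNG(pmin(pmax(input_img, 0), 1), target = f_in)
    files <- c(files, f_in)
    row <- list(input_img)
    for (mode in c("sfl", "mhsl")) {
      run <- if (mode == "sfl") run_sfl else run_mhsl
      sm <- forward_client(run$clients[[client]]$params, x1,
                           training = FALSE)$activations
      f <- file.path(dir, sprintf("%s_%02d.png", mode, i))
      norm <- render_smashed(sm, f)
      files <- c(files, f)
      row[[length(row) + 1L]] <- norm
    }
    panels[[i]] <- row
  }
  # contact sheet: inputs and renders resized-by-padding into one canvas
  H <- max(unlist(lapply(panels, function(r) vapply(r, nrow, 0L))))
  W <- max(unlist(lapply(panels, function(r) vapply(r, ncol, 0L))))
  sheet <- do.call(rbind, lapply(panels, function(r) {
    do.call(cbind, lapply(r, function(m) {
      out <- matrix(1, H + 2L, W + 2L)
      out[1L + seq_len(nrow(m)), 1L + seq_len(ncol(m))] <- m
      out
    }))
  }))
  f_sheet <- file.path(dir, "contact_sheet.png")
  png::writePNG(sheet, target = f_sheet)
  invisible(c(files, f_sheet))
}
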