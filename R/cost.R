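#' Deployment parameters of the communication/time cost model
#'
#' The analytic cost model for one global epoch.  Symbols: `K` clients, `p`
#' accumulated training samples across clients, `A_elems` smashed-data
#' elements per sample at the cut layer, `W_elems` full-model parameter
#' count, `beta` the client-side fraction of the model (client portion is
#' `beta * W_elems` elements), `R` the transfer rate in elements/second,
#' `T_fwdbwd` the seconds for one full forward+backward pass over the `p`
#' samples, and `T_fedavg` the fed-server aggregation time.  Counts are in
#' elements; multiply by `bytes_per_element` for bytes.
#'
#' @param K Integer number of clients.
#' @param p Accumulated training samples per epoch.
#' @param A_elems Smashed elements per sample.
#' @param W_elems Full-model element count.
#' @param beta Client-side fraction of the model, in (0, 1).
#' @param R Transfer rate, elements/second.
#' @param T_fwdbwd Forward+backward computation seconds over `p` samples.
#' @param T_fedavg Fed-server aggregation seconds.
#' @param bytes_per_element Bytes per transferred element (default 4).
#' @return A `cost_params` list.
#' @export
cost_params <- function(K, p, A_elems, W_elems, beta, R = 1e6,
                        T_fwdbwd = 0, T_fedavg = 0, bytes_per_element = 4L) {
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  if (any(c(p, A_elems, W_elems) < 0)) stop("counts must be >= 0",
                                            call. = FALSE)
  if (beta <= 0 || beta >= 1) stop("beta must lie in (0, 1)", call. = FALSE)
  structure(list(K = as.integer(K), p = p, A_elems = A_elems,
                 W_elems = W_elems, beta = beta, R = R,
                 T_fwdbwd = T_fwdbwd, T_fedavg = T_fedavg,
                 bytes_per_element = as.integer(bytes_per_element)),
            class = "cost_params")
}

#' Total communication size for one global epoch
#'
#' SFL moves the smashed data and gradients (`2 p |A|`) plus the per-epoch
#' client-portion synchronization (`2 beta K |W|`: each of the `K` clients
#' uploads its portion to the fed server and downloads the average).  MHSL
#' has no synchronization, so only `2 p |A|` crosses the network.
#'
#' @param mode `"SFL"` or `"MHSL"`.
#' @param cp A [cost_params()].
#' @return Elements transferred per epoch.
#' @export
comms_total <- function(mode = c("SFL", "MHSL"), cp) {
  mode <- match.arg(mode)
  base <- 2 * cp$p * cp$A_elems
  if (mode == "SFL") base + 2 * cp$beta * cp$K * cp$W_elems else base
}

#' Communication size per client for one global epoch
#'
#' Each client's share of the smashed traffic is `2 p |A| / K` (equal IID
#' shards); SFL adds `2 beta |W|` for the portion upload/download.
#' `K * comms_per_client()` equals [comms_total()] in both modes.
#'
#' @inheritParams comms_total
#' @return Elements transferred per client per epoch.
#' @export
comms_per_client <- function(mode = c("SFL", "MHSL"), cp) {
  mode <- match.arg(mode)
  base <- 2 * cp$p * cp$A_elems / cp$K
  if (mode == "SFL") base + 2 * cp$beta * cp$W_elems else base
}

#' Total model training time for one global epoch
#'
#' Computation time plus transfer time: the smashed traffic moves in
#' parallel across the `K` clients (`2 p |A| / (K R)` seconds); SFL adds the
#' portion transfer `2 beta |W| / R` and the fed-server aggregation time.
#'
#' @inheritParams comms_total
#' @return Seconds per epoch.
#' @export
training_time <- function(mode = c("SFL", "MHSL"), cp) {
  mode <- match.arg(mode)
  if (cp$R <= 0) stop("transfer rate R must be > 0", call. = FALSE)
  base <- cp$T_fwdbwd + 2 * cp$p * cp$A_elems / (cp$K * cp$R)
  if (mode == "SFL")
    base + 2 * cp$beta * cp$W_elems / cp$R + cp$T_fedavg
  else base
}

#' Side-by-side cost table for both modes
#'
#' @param cp A [cost_params()].
#' @return A tibble with one row per mode: per-client and total
#'   communication (elements and bytes) and training time per epoch.
#' @export
cost_table <- function(cp) {
  modes <- c("SFL", "MHSL")
  tibble::tibble(
    mode = modes,
    comms_per_client_elements = vapply(modes, comms_per_client, 0, cp = cp),
    comms_total_elements = vapply(modes, comms_total, 0, cp = cp),
    comms_total_bytes = comms_total_elements * cp$bytes_per_element,
    training_time_s = vapply(modes, training_time, 0, cp = cp))
}

#' Derive cost parameters from a finished run
#'
#' Fills the count symbols (`K`, `p`, `A_elems`, `W_elems`, `beta`) from a
#' [run_training()] result; the rate/time symbols stay as given.
#'
#' @param run A `split_run`.
#' @inheritParams cost_params
#' @return A [cost_params()].
#' @export
cost_params_from_run <- function(run, R = 1e6, T_fwdbwd = 0, T_fedavg = 0,
                                 bytes_per_element = 4L) {
  W <- count_parameters(run$spec)
  client_elems <- length(param_vector(run$clients[[1L]]$params))
  cost_params(K = run$config$K,
              p = run$epochs$samples_processed[1L],
              A_elems = run$smashed_per_sample,
              W_elems = W,
              beta = client_elems / W,
              R = R, T_fwdbwd = T_fwdbwd, T_fedavg = T_fedavg,
              bytes_per_element = bytes_per_element)
}

#' Reconcile the analytic cost model against a run's measured counters
#'
#' Every training run counts the elements actually moved: smashed
#' activations up, cut-layer gradients down, and (SFL) portion uploads and
#' downloads.  The report compares those counters, epoch by epoch, with the
#' closed-form predictions; agreement must be exact because both sides count
#' the same discrete quantities.
#'
#' @param run A `split_run` (its counters are always instrumented).
#' @param cp Optional [cost_params()]; default derives counts from the run.
#' @return A tibble with per-epoch measured/predicted smashed and sync
#'   traffic and logical `*_match` columns.
#' @export
reconcile <- function(run, cp = NULL) {
  if (is.null(run$epochs$smashed_elements))
    stop("run carries no communication counters", call. = FALSE)
  cp <- cp %||% cost_params_from_run(run)
  # element counts are integers; round away float noise from beta = |W_C|/|W|
  pred_smashed <- round(2 * cp$p * cp$A_elems)
  pred_sync <- if (run$config$mode == "SFL")
    round(2 * cp$beta * cp$K * cp$W_elems) else 0
  dplyr::mutate(
    dplyr::select(run$epochs, "epoch", "smashed_elements", "sync_elements"),
    predicted_smashed = pred_smashed,
    predicted_sync = pred_sync,
    smashed_match = .data$smashed_elements == .data$predicted_smashed,
    sync_match = .data$sync_elements == .data$predicted_sync)
}
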