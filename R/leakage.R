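#' Plug-in mutual information score between two categorical vectors
#'
#' The estimator treats the distinct values of each vector as category
#' labels, forms the empirical contingency table, and returns
#' \deqn{I(X,Y) = \sum_{i,j} \frac{n_{ij}}{N}\,
#'       \log\frac{N\, n_{ij}}{n_{i\cdot}\, n_{\cdot j}}}
#' in nats, summing only over non-empty joint cells.  This is the standard
#' plug-in estimate of mutual information from joint counts: symmetric,
#' non-negative, invariant under bijective relabeling of either argument,
#' and equal to the plug-in entropy when `x == y`.
#'
#' @param x,y Equal-length vectors; values are compared by identity, so any
#'   atomic type works.
#' @return Mutual information score in nats (non-negative).
#' @export
#' @examples
#' mutual_information_score(c(0, 0, 1, 1), c(0, 0, 1, 1))  # log(2)
#' mutual_information_score(c(0, 0, 1, 1), c(0, 1, 0, 1))  # 0
mutual_information_score <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have the same length (", length(x), " vs ",
         length(y), ")", call. = FALSE)
  N <- length(x)
  if (N == 0L) stop("empty input", call. = FALSE)
  xi <- match(x, unique(x))
  yi <- match(y, unique(y))
  nx <- max(xi)
  key <- xi + nx * (yi - 1)
  uk <- unique(key)
  nij <- tabulate(match(key, uk))
  ni <- tabulate(xi)
  nj <- tabulate(yi)
  i <- (uk - 1) %% nx + 1
  j <- (uk - 1) %/% nx + 1
  sum(nij / N * log(N * nij / (ni[i] * nj[j])))
}

#' Plug-in Shannon entropy of a categorical vector
#'
#' @param x Non-empty vector; distinct values are distinct categories.
#' @return Entropy in nats.
#' @export
#' @examples
#' entropy_plugin(c("a", "a", "b", "b"))  # log(2)
entropy_plugin <- function(x) {
  if (length(x) == 0L) stop("empty input", call. = FALSE)
  p <- tabulate(match(x, unique(x))) / length(x)
  -sum(p * log(p))
}

#' Configuration for leakage preprocessing
#'
#' Before scoring, one channel of the input is flattened and the smashed
#' data is brought to the same length: bilinear resizing for 2-D feature
#' maps, linear interpolation for 1-D signals, or trailing zero-padding
#' (the treatment used for 1-D signal data whose cut-layer output is
#' shorter than the input).  Continuous activations are made categorical by
#' rounding to `quantize_decimals` decimals.
#'
#' @param channel_index 1-based input/smashed channel to score (default 1).
#' @param rescale_method `"auto"` (bilinear for 2-D, linear interpolation
#'   for 1-D), `"bilinear_resize"`, `"linear_interp_1d"`, or `"zero_pad"`.
#' @param quantize_decimals Decimals to round the rescaled smashed values
#'   to, or `NULL` to disable quantization.
#' @param channel_reduce `"select"` (take `channel_index`) or `"mean"`
#'   (average the smashed channels).
#' @param samples_per_epoch Evaluation samples per epoch for traces.
#' @return A `mis_config` list.
#' @export
mis_config <- function(channel_index = 1L,
                       rescale_method = c("auto", "bilinear_resize",
                                          "linear_interp_1d", "zero_pad"),
                       quantize_decimals = 3L,
                       channel_reduce = c("select", "mean"),
                       samples_per_epoch = 32L) {
  rescale_method <- match.arg(rescale_method)
  channel_reduce <- match.arg(channel_reduce)
  if (!is.null(quantize_decimals) && quantize_decimals < 0)
    stop("quantize_decimals must be >= 0 or NULL", call. = FALSE)
  structure(list(channel_index = as.integer(channel_index),
                 rescale_method = rescale_method,
                 quantize_decimals = quantize_decimals,
                 channel_reduce = channel_reduce,
                 samples_per_epoch = as.integer(samples_per_epoch)),
            class = "mis_config")
}

# bilinear resize of a matrix to (H, W), corner-aligned: the four corner
# values are preserved and a bilinear ramp resizes exactly
bilinear_resize <- function(m, H, W) {
  interp_weights <- function(n_src, n_dst) {
    Wm <- matrix(0, n_dst, n_src)
    if (n_src == 1L) { Wm[, 1L] <- 1; return(Wm) }
    s <- (seq_len(n_dst) - 1) * (n_src - 1) / max(n_dst - 1, 1) + 1
    i0 <- pmin(floor(s), n_src - 1)
    f <- s - i0
    Wm[cbind(seq_len(n_dst), i0)] <- 1 - f
    Wm[cbind(seq_len(n_dst), i0 + 1)] <-
      Wm[cbind(seq_len(n_dst), i0 + 1)] + f
    Wm
  }
  interp_weights(nrow(m), H) %*% m %*% t(interp_weights(ncol(m), W))
}

# Pull one sample's selected channel out of an input / smashed array.
# Convention: vectors are 1-D signals; matrices are 2-D single-channel maps
# (H, W); rank-3 arrays are (H, W, C); multi-channel 1-D signals must be
# passed with modality = "series" as an (L, C) matrix.  A trailing
# singleton sample axis on rank-4 arrays is dropped.
select_channel <- function(a, config, modality = "auto") {
  d <- dim(a) %||% length(a)
  if (length(d) == 4L && d[4L] == 1L) { a <- array(a, d[1:3]); d <- d[1:3] }
  if (modality == "auto")
    modality <- if (length(d) == 1L) "series" else "image"
  if (modality == "series") {
    m <- matrix(a, d[1L], if (length(d) > 1L) d[2L] else 1L)
    v <- if (config$channel_reduce == "mean") rowMeans(m)
    else {
      if (config$channel_index > ncol(m))
        stop("channel_index ", config$channel_index, " exceeds ", ncol(m),
             " channels", call. = FALSE)
      m[, config$channel_index]
    }
    return(list(v = v, spatial = "1d"))
  }
  if (length(d) == 2L) { a <- array(a, c(d, 1L)); d <- dim(a) }
  if (length(d) != 3L)
    stop("cannot interpret a rank-", length(d), " array as (H, W, C)",
         call. = FALSE)
  v <- if (config$channel_reduce == "mean") {
    if (d[3L] == 1L) a[, , 1L] else apply(a, c(1L, 2L), mean)
  } else {
    if (config$channel_index > d[3L])
      stop("channel_index ", config$channel_index, " exceeds ", d[3L],
           " channels", call. = FALSE)
    a[, , config$channel_index]
  }
  list(v = v, spatial = "2d")
}

#' Preprocess an input/smashed pair for mutual-information scoring
#'
#' Flattens the selected channel of the input and brings the smashed data to
#' the same length using the configured rescaling (bilinear resize for 2-D
#' feature maps, linear interpolation or trailing zero-padding for 1-D),
#' then optionally rounds the smashed values to make categories explicit.
#'
#' @param input_sample One input sample: a vector or `(L, C)` matrix for
#'   1-D signals, an `(H, W)` or `(H, W, C)` array for images.
#' @param smashed_sample The corresponding cut-layer output for that sample.
#' @param config A [mis_config()].
#' @param modality `"auto"` (vectors are signals, matrices/arrays are
#'   images), `"series"`, or `"image"`; applies to both arguments.
#' @return List of equal-length vectors `x` (input) and `y` (smashed).
#' @export
preprocess_pair <- function(input_sample, smashed_sample,
                            config = mis_config(), modality = "auto") {
  xin <- select_channel(input_sample, config, modality)
  ysm <- select_channel(smashed_sample, config, modality)
  x <- as.vector(xin$v)
  method <- config$rescale_method
  if (method == "auto")
    method <- if (xin$spatial == "2d" && ysm$spatial == "2d")
      "bilinear_resize" else "linear_interp_1d"
  y <- switch(method,
    bilinear_resize = {
      if (xin$spatial != "2d" || ysm$spatial != "2d")
        stop("bilinear_resize needs 2-D input and smashed maps",
             call. = FALSE)
      as.vector(bilinear_resize(ysm$v, dim(xin$v)[1L], dim(xin$v)[2L]))
    },
    linear_interp_1d = {
      yv <- as.vector(ysm$v)
      if (length(yv) == length(x)) yv
      else stats::approx(seq_along(yv), yv,
                         xout = seq(1, length(yv),
                                    length.out = length(x)))$y
    },
    zero_pad = {
      yv <- as.vector(ysm$v)
      if (length(yv) > length(x))
        stop("smashed data (", length(yv), ") longer than input (",
             length(x), ") under zero_pad; choose a resize method instead",
             call. = FALSE)
      c(yv, numeric(length(x) - length(yv)))
    })
  if (!is.null(config$quantize_decimals))
    y <- round(y, config$quantize_decimals)
  list(x = x, y = y)
}

#' Mean leakage score of the current client portions
#'
#' Runs each client portion forward (inference mode) on the evaluation
#' samples, preprocesses every input/smashed pair and averages the mutual
#' information scores over samples and clients.
#'
#' @param client_params_list List of client-portion `param_set`s.
#' @param eval_x Evaluation input array, sample axis last.
#' @param config A [mis_config()].
#' @return Mean mutual information score in nats.
#' @export
mis_epoch <- function(client_params_list, eval_x, config = mis_config()) {
  d <- dim(eval_x)
  n <- d[length(d)]
  modality <- if (length(d) == 4L) "image" else "series"
  scores <- vapply(client_params_list, function(cp) {
    sm <- forward_client(cp, eval_x, training = FALSE)$activations
    mean(vapply(seq_len(n), function(i) {
      pp <- preprocess_pair(drop_sample_axis(slice_samples(eval_x, i)),
                            drop_sample_axis(slice_samples(sm, i)),
                            config, modality)
      mutual_information_score(pp$x, pp$y)
    }, 0))
  }, 0)
  mean(scores)
}

# (dims..., 1) -> (dims...)
drop_sample_axis <- function(a) {
  d <- dim(a)
  array(a, d[-length(d)])
}

#' Layer-wise leakage profile of a full model
#'
#' Mutual information between the input and every block's output for one
#' sample, in layer order.  Under the data-processing inequality the
#' population quantity is non-increasing through the layers; the plug-in
#' profile is a diagnostic, not a bound.
#'
#' @param params Full-model `param_set`.
#' @param sample One input sample (`(L, C)` / `(H, W, C)` array).
#' @param config A [mis_config()].
#' @return Numeric vector, one score per block.
#' @export
layerwise_mis <- function(params, sample, config = mis_config()) {
  spec <- param_spec(params)
  modality <- if (length(spec$input_shape) == 3L) "image" else "series"
  x <- array(sample, c(spec$input_shape, 1L))
  sample_full <- array(sample, spec$input_shape)
  r <- forward_blocks(params, to_engine(x), training = FALSE, collect = TRUE)
  vapply(r$outs, function(o) {
    pp <- preprocess_pair(sample_full, drop_sample_axis(to_public(o)),
                          config, modality)
    mutual_information_score(pp$x, pp$y)
  }, 0)
}

#' Render smashed data as a grayscale PNG
#'
#' Min-max normalizes one channel (or the channel mean, or a tiled layout of
#' all channels) of a 2-D-mappable smashed sample and writes an 8-bit
#' grayscale PNG.  Constant activations map to mid-gray.
#'
#' @param smashed_sample `(H, W, C)` activation array (trailing singleton
#'   sample axis tolerated).
#' @param file Output PNG path.
#' @param layout `"single"` (one channel) or `"tile"` (all channels in a
#'   row).
#' @param channel 1-based channel for `layout = "single"`.
#' @return The normalized matrix that was written, invisibly.
#' @export
render_smashed <- function(smashed_sample, file, layout = c("single", "tile"),
                           channel = 1L) {
  layout <- match.arg(layout)
  a <- smashed_sample
  d <- dim(a)
  if (length(d) == 4L) { a <- array(a, d[1:3]); d <- dim(a) }
  if (length(d) == 2L) { a <- array(a, c(d, 1L)); d <- dim(a) }
  if (length(d) != 3L)
    stop("smashed sample is not 2-D-mappable (dims: ",
         paste(d, collapse = "x"), ")", call. = FALSE)
  if (!all(is.finite(a))) stop("non-finite activations", call. = FALSE)
  m <- if (layout == "single") a[, , channel]
  else do.call(cbind, lapply(seq_len(d[3L]), function(c_) a[, , c_]))
  rng <- range(m)
  norm <- if (diff(rng) == 0) matrix(0.5, nrow(m), ncol(m))
  else (m - rng[1L]) / diff(rng)
  png::writePNG(norm, target = file)
  invisible(norm)
}
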