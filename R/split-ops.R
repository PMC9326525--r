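# Client/server halves of one training step.  The client forward-propagates
# its blocks and ships the cut-layer activations (smashed data); the server
# finishes the forward pass, computes softmax cross-entropy, back-propagates
# to the cut and returns the gradient there; the client then completes the
# backward pass.  Composing the two halves performs exactly one SGD step of
# the un-split network.

#' Bundle smashed data in transit from a client to the server
#'
#' @param activations Cut-layer activation array, sample axis last.
#' @param labels Integer labels (0-based), one per sample.
#' @param client_id Integer client label `k`.
#' @param epoch Integer epoch the batch belongs to.
#' @return A `smashed_batch` object.
#' @export
smashed_batch <- function(activations, labels, client_id = 1L, epoch = 1L) {
  d <- dim(activations)
  n <- d[length(d)]
  if (n != length(labels))
    stop("activations carry ", n, " samples but ", length(labels),
         " labels were given", call. = FALSE)
  structure(list(activations = activations, labels = as.integer(labels),
                 client_id = as.integer(client_id), epoch = as.integer(epoch)),
            class = "smashed_batch")
}

#' Client-side forward pass up to the cut layer
#'
#' @param client_params `param_set` for the client fragment (no head).
#' @param batch Input array with the sample axis last, matching the
#'   fragment's `input_shape`.
#' @param training Logical; train mode updates normalization statistics and
#'   retains the caches needed by [backward_client()].
#' @return List with `activations` (the smashed data), `cache` (pass to
#'   [backward_client()]), and `params` (client parameters; normalization
#'   statistics may have advanced).
#' @export
forward_client <- function(client_params, batch, training = TRUE) {
  spec <- param_spec(client_params)
  d <- dim(batch)
  expect <- spec$input_shape
  if (length(d) != length(expect) + 1L ||
      !all(d[-length(d)] == expect))
    stop("batch shape (", paste(d, collapse = "x"),
         ") does not match client input_shape (",
         paste(expect, collapse = "x"), " + samples)", call. = FALSE)
  r <- forward_blocks(client_params, to_engine(batch), training = training)
  list(activations = to_public(r$out), cache = if (training) r$caches,
       params = r$params)
}

#' Server-side forward and backward pass on a smashed batch
#'
#' Runs the server blocks and classifier head on the smashed activations,
#' computes softmax cross-entropy against the labels travelling with the
#' batch, applies one SGD step to the server parameters, and returns the
#' loss gradient at the cut layer for the owning client.
#'
#' @param server_params `param_set` for the server fragment (with head).
#' @param smashed A [smashed_batch()].
#' @param lr Learning rate (`lr = 0` leaves parameters untouched).
#' @param training Logical; train mode.
#' @return List: `loss`, `batch_accuracy`, `grad_at_cut` (same shape as the
#'   smashed activations), and the updated `params`.
#' @export
forward_backward_server <- function(server_params, smashed, lr,
                                    training = TRUE) {
  stopifnot(inherits(smashed, "smashed_batch"))
  fb <- forward_blocks(server_params, to_engine(smashed$activations),
                       training = training)
  hf <- head_forward(fb$params$head, fb$out)
  ce <- softmax_ce(hf$logits, smashed$labels)
  if (!is.finite(ce$loss))
    stop("non-finite loss at epoch ", smashed$epoch, ", client ",
         smashed$client_id, call. = FALSE)
  hb <- head_backward(fb$params$head, hf$cache, ce$dlogits, need_dx = TRUE)
  bb <- backward_blocks(fb$params, fb$caches, hb$dx, need_dx_first = TRUE)
  grads <- list(blocks = bb$grads, head = hb$grads)
  list(loss = ce$loss, batch_accuracy = ce$accuracy,
       grad_at_cut = to_public(bb$dx),
       params = sgd_step(fb$params, grads, lr))
}

#' Client-side backward pass from the cut-layer gradient
#'
#' @param client_params `param_set` for the client fragment.
#' @param cache Cache returned by [forward_client()] in train mode.
#' @param grad_at_cut Gradient array from [forward_backward_server()].
#' @param lr Learning rate.
#' @return Updated client `param_set`.
#' @export
backward_client <- function(client_params, cache, grad_at_cut, lr) {
  if (is.null(cache))
    stop("missing forward cache: run forward_client(training = TRUE) first",
         call. = FALSE)
  bb <- backward_blocks(client_params, cache, to_engine(grad_at_cut),
                        need_dx_first = FALSE)
  sgd_step(client_params, list(blocks = bb$grads, head = NULL), lr)
}

#' Concatenate a client portion with the server portion into one full model
#'
#' @param client_params Client fragment `param_set`.
#' @param server_params Server fragment `param_set` (owns the head).
#' @return Full-network `param_set` whose forward pass equals running the
#'   client then the server fragment.
#' @export
assemble_full_model <- function(client_params, server_params) {
  cs <- param_spec(client_params)
  ss <- param_spec(server_params)
  if (is.null(server_params$head))
    stop("server fragment has no classifier head", call. = FALSE)
  if (!is.null(client_params$head))
    stop("client fragment owns a classifier head; both modes need a "
         , "headless client portion", call. = FALSE)
  c_out <- if (length(cs$blocks))
    cs$blocks[[length(cs$blocks)]]$out_channels
  shapes <- spec_shapes(cs)
  if (length(shapes) && !all(shapes[[length(shapes)]] == ss$input_shape))
    stop("fragments do not fit together: client emits (",
         paste(shapes[[length(shapes)]], collapse = "x"),
         ") but server expects (", paste(ss$input_shape, collapse = "x"), ")",
         call. = FALSE)
  new_param_set(c(client_params$blocks, server_params$blocks),
                server_params$head, merge_specs(cs, ss))
}

# split a full param_set to match a split_network() result
split_params <- function(full_params, split) {
  c_ <- split$cut_layer
  L <- length(full_params$blocks)
  client <- new_param_set(full_params$blocks[seq_len(c_)], NULL, split$client)
  server <- new_param_set(if (c_ < L) full_params$blocks[(c_ + 1L):L]
                          else list(),
                          full_params$head, split$server)
  list(client = client, server = server)
}

#' Accuracy of an assembled (or full) model on a labelled set
#'
#' Fraction of samples whose arg-max class prediction matches the label.
#' Evaluation runs in inference mode (normalization uses running statistics)
#' and in chunks to bound memory.
#'
#' @param client_params Client fragment `param_set` (or a full model's
#'   `param_set`, with `server_params = NULL`).
#' @param server_params Server fragment `param_set`, or `NULL`.
#' @param x Input array, sample axis last.
#' @param y Integer labels (0-based).
#' @param chunk Samples per forward chunk.
#' @return Accuracy in `[0, 1]`.
#' @export
evaluate <- function(client_params, server_params, x, y, chunk = 256L) {
  n <- dim(x)[length(dim(x))]
  if (n == 0L || length(y) == 0L) stop("empty test set", call. = FALSE)
  full <- if (is.null(server_params)) client_params
  else assemble_full_model(client_params, server_params)
  correct <- 0L
  for (s in seq.int(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    xb <- slice_samples(x, idx)
    r <- forward_blocks(full, to_engine(xb), training = FALSE)
    hf <- head_forward(full$head, r$out)
    pred <- max.col(hf$logits, ties.method = "first") - 1L
    correct <- correct + sum(pred == y[idx])
  }
  correct / n
}

# one SGD step of the un-split reference network (the centralized path)
train_step_full <- function(params, x, y, lr) {
  fb <- forward_blocks(params, to_engine(x), training = TRUE)
  hf <- head_forward(params$head, fb$out)
  ce <- softmax_ce(hf$logits, y)
  hb <- head_backward(params$head, hf$cache, ce$dlogits, need_dx = TRUE)
  bb <- backward_blocks(fb$params, fb$caches, hb$dx, need_dx_first = FALSE)
  list(loss = ce$loss, accuracy = ce$accuracy,
       params = sgd_step(fb$params, list(blocks = bb$grads, head = hb$grads),
                         lr))
}

# subset the trailing sample axis of an array
slice_samples <- function(x, idx) {
  d <- dim(x)
  nd <- length(d)
  if (nd == 2L) return(x[, idx, drop = FALSE])
  if (nd == 3L) return(x[, , idx, drop = FALSE])
  x[, , , idx, drop = FALSE]
}
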