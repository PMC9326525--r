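# flatten every parameter array of a param_set into one numeric vector,
# in a fixed traversal order (used for comparisons and checkpoints)
param_vector <- function(params) {
  acc <- list()
  walk <- function(p) {
    if (is.list(p)) for (k in names(p)) walk(p[[k]])
    else acc[[length(acc) + 1L]] <<- as.numeric(p)
  }
  for (b in params$blocks) walk(b)
  if (!is.null(params$head)) walk(params$head)
  unlist(acc, use.names = FALSE) %||% numeric(0)
}

# largest absolute element-wise difference between two shape-compatible
# param_sets
param_max_diff <- function(a, b) {
  va <- param_vector(a); vb <- param_vector(b)
  if (length(va) != length(vb))
    stop("parameter sets have different sizes", call. = FALSE)
  if (!length(va)) return(0)
  max(abs(va - vb))
}

#' Save / load parameter checkpoints
#'
#' Parameters are stored as plain text: a manifest JSON (spec, seed, epoch,
#' element count) plus one CSV of flattened values, so checkpoints survive
#' text-only transports.  Intended for full-model parameter sets.
#'
#' @param params A `param_set` with a classifier head.
#' @param dir Directory to write into (created if missing).
#' @param seed,epoch Integers recorded in the manifest.
#' @return `save_checkpoint()` the directory, invisibly; `load_checkpoint()`
#'   a `param_set`.
#' @export
save_checkpoint <- function(params, dir, seed = NA_integer_,
                            epoch = NA_integer_) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- param_spec(params)
  write_network_spec(spec, file.path(dir, "spec.json"))
  v <- param_vector(params)
  jsonlite::write_json(list(seed = seed, epoch = epoch,
                            n_values = length(v),
                            has_head = !is.null(params$head)),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  utils::write.csv(data.frame(value = v),
                   file.path(dir, "values.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(dir) {
  spec <- read_network_spec(file.path(dir, "spec.json"))
  v <- utils::read.csv(file.path(dir, "values.csv"))$value
  template <- build_network(spec, seed = 0L)
  pos <- 0L
  fill <- function(p) {
    if (is.list(p)) {
      for (k in names(p)) p[[k]] <- fill(p[[k]])
      p
    } else {
      n <- length(p)
      out <- v[pos + seq_len(n)]
      pos <<- pos + n
      if (!is.null(dim(p))) dim(out) <- dim(p)
      out
    }
  }
  template$blocks <- lapply(template$blocks, fill)
  if (!is.null(template$head)) template$head <- fill(template$head)
  if (pos != length(v))
    stop("checkpoint carries ", length(v), " values but the spec needs ",
         pos, call. = FALSE)
  template
}
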