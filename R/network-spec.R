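#' Define one splittable network block
#'
#' A block is the unit at which a network can be cut between client and
#' server.  Convolutional blocks follow the common block idiom: convolution,
#' optional batch normalization, then an activation.  Residual blocks are
#' standard two-convolution basic blocks with an identity (or projected)
#' shortcut.  When `normalization` is `TRUE` the convolution carries no bias
#' (the normalization's shift absorbs it, the usual convention).
#'
#' @param kind One of `"conv1d"`, `"conv2d"`, `"residual2d"`, `"dense"`.
#' @param out_channels Positive integer; output channels (units for dense).
#' @param kernel Positive integer kernel size (scalar; square for 2-D kinds).
#'   Ignored for dense blocks.
#' @param activation `"relu"` or `"none"`.
#' @param normalization Logical; include batch normalization.
#' @param stride Positive integer spatial stride (1-D / 2-D kinds only).
#' @param pool `"none"` or `"max3s2"` (3-wide max pool, stride 2, applied
#'   after the activation; used by the residual image network's stem).
#' @return A `block_spec` list.
#' @export
#' @examples
#' block_spec("conv2d", 16, kernel = 3)
block_spec <- function(kind = c("conv1d", "conv2d", "residual2d", "dense"),
                       out_channels, kernel = 3L,
                       activation = c("relu", "none"),
                       normalization = FALSE, stride = 1L,
                       pool = c("none", "max3s2")) {
  kind <- match.arg(kind)
  activation <- match.arg(activation)
  pool <- match.arg(pool)
  if (!is.numeric(out_channels) || length(out_channels) != 1L || out_channels < 1)
    stop("`out_channels` must be a positive integer", call. = FALSE)
  if (!is.numeric(kernel) || any(kernel < 1))
    stop("`kernel` dimensions must be >= 1", call. = FALSE)
  if (stride < 1) stop("`stride` must be >= 1", call. = FALSE)
  structure(list(kind = kind, out_channels = as.integer(out_channels),
                 kernel = as.integer(kernel[1L]), activation = activation,
                 normalization = isTRUE(normalization),
                 stride = as.integer(stride), pool = pool),
            class = "block_spec")
}

#' Define a full block-structured network
#'
#' The full model is an ordered list of blocks followed by a classifier head
#' (global average pooling over any spatial dimensions, then a dense layer to
#' `n_classes`).  Cutting the network at block boundary `c` places blocks
#' `1..c` on the client and the remaining blocks plus the head on the server.
#'
#' @param blocks List of [block_spec()] objects, at least 2 for a full model.
#' @param input_shape Integer vector: `c(length, channels)` for 1-D inputs,
#'   `c(height, width, channels)` for images, or a scalar feature count for
#'   dense networks.
#' @param n_classes Positive integer number of classes.
#' @param name Optional label used in printing and manifests.
#' @return A `network_spec` object.
#' @export
#' @examples
#' network_spec(list(block_spec("dense", 8), block_spec("dense", 4)),
#'              input_shape = 6, n_classes = 3)
network_spec <- function(blocks, input_shape, n_classes, name = "network") {
  if (!is.list(blocks) || length(blocks) < 2L)
    stop("a full network needs at least 2 blocks (otherwise no cut exists)",
         call. = FALSE)
  for (i in seq_along(blocks)) {
    if (!inherits(blocks[[i]], "block_spec"))
      stop("blocks[[", i, "]] is not a block_spec", call. = FALSE)
  }
  if (n_classes < 2) stop("`n_classes` must be >= 2", call. = FALSE)
  first <- blocks[[1L]]$kind
  nd <- length(input_shape)
  ok <- switch(first, conv1d = nd == 2L, conv2d = nd == 3L,
               residual2d = nd == 3L, dense = TRUE)
  if (!ok)
    stop("input_shape (length ", nd, ") inconsistent with first block kind '",
         first, "'", call. = FALSE)
  ns <- structure(list(blocks = blocks, input_shape = as.integer(input_shape),
                       n_classes = as.integer(n_classes), name = name),
                  class = "network_spec")
  spec_shapes(ns)  # validates block chaining
  ns
}

# Fragment constructor used by split_network(); relaxes the >= 2 block rule
# and allows a missing head (client fragments) or zero blocks (server holds
# only the head when the cut is at the last block).
new_fragment <- function(blocks, input_shape, n_classes, name, has_head) {
  structure(list(blocks = blocks, input_shape = as.integer(input_shape),
                 n_classes = as.integer(n_classes), name = name,
                 fragment = TRUE, has_head = has_head),
            class = "network_spec")
}

spec_has_head <- function(spec) !isTRUE(spec$fragment) || isTRUE(spec$has_head)

#' @export
print.network_spec <- function(x, ...) {
  kindcol <- vapply(x$blocks, function(b) {
    paste0(b$kind, " ", b$out_channels,
           if (b$kind != "dense") paste0(" k", b$kernel) else "",
           if (b$stride > 1L) paste0(" s", b$stride) else "",
           if (b$normalization) " bn" else "",
           if (b$pool != "none") paste0(" ", b$pool) else "")
  }, character(1))
  cat("<network_spec> ", x$name,
      if (isTRUE(x$fragment)) " (fragment)" else "",
      "\n  input: ", paste(x$input_shape, collapse = "x"),
      "   classes: ", x$n_classes, "\n", sep = "")
  for (i in seq_along(kindcol)) cat(sprintf("  %2d. %s\n", i, kindcol[i]))
  if (spec_has_head(x))
    cat("  head: global pool + dense ->", x$n_classes, "\n")
  invisible(x)
}

# Output shape of every block (list of integer vectors, channels-last layout:
# (L, C), (H, W, C) or (d)).  Also the validation walk for channel chaining.
spec_shapes <- function(spec) {
  shp <- spec$input_shape
  out <- vector("list", length(spec$blocks))
  conv_out <- function(n, k, s) (n + 2L * ((k - 1L) %/% 2L) - k) %/% s + 1L
  for (i in seq_along(spec$blocks)) {
    b <- spec$blocks[[i]]
    shp <- switch(b$kind,
      dense = b$out_channels,
      conv1d = {
        if (length(shp) != 2L)
          stop("block ", i, " (conv1d) expects (length, channels) input",
               call. = FALSE)
        c(conv_out(shp[1L], b$kernel, b$stride), b$out_channels)
      },
      conv2d = ,
      residual2d = {
        if (length(shp) != 3L)
          stop("block ", i, " (", b$kind,
               ") expects (height, width, channels) input", call. = FALSE)
        h <- conv_out(shp[1L], b$kernel, b$stride)
        w <- conv_out(shp[2L], b$kernel, b$stride)
        if (b$pool == "max3s2") {
          h <- conv_out(h, 3L, 2L); w <- conv_out(w, 3L, 2L)
        }
        c(h, w, b$out_channels)
      })
    if (b$kind == "dense") shp <- b$out_channels
    out[[i]] <- as.integer(shp)
  }
  out
}

# Elements per sample of the cut-layer activations for a given cut.
smashed_elements <- function(spec, cut_layer) {
  prod(spec_shapes(spec)[[cut_layer]])
}

#' Count trainable parameters of a network
#'
#' Counts every trainable scalar: convolution and dense weights, biases
#' (absent where batch normalization follows a convolution), normalization
#' scale/shift pairs, residual-shortcut projections, and the classifier head.
#' Normalization running statistics are not trainable and are not counted.
#'
#' @param spec A [network_spec()].
#' @return Integer scalar count.
#' @export
#' @examples
#' sp <- network_spec(list(block_spec("dense", 2, activation = "none"),
#'                         block_spec("dense", 2)),
#'                    input_shape = 4, n_classes = 2)
#' count_parameters(sp)
count_parameters <- function(spec) {
  shp <- spec$input_shape
  in_ch <- function(s) s[length(s)]
  total <- 0
  shapes <- spec_shapes(spec)
  cin <- if (length(shp) == 1L) shp else in_ch(shp)
  for (i in seq_along(spec$blocks)) {
    b <- spec$blocks[[i]]
    cout <- b$out_channels
    total <- total + switch(b$kind,
      dense = {
        d_in <- if (i == 1L) prod(shp) else prod(shapes[[i - 1L]])
        d_in * cout + cout + if (b$normalization) 2 * cout else 0
      },
      conv1d = b$kernel * cin * cout +
        (if (b$normalization) 2 * cout else cout),
      conv2d = b$kernel^2 * cin * cout +
        (if (b$normalization) 2 * cout else cout),
      residual2d = {
        proj <- b$stride > 1L || cin != cout
        b$kernel^2 * cin * cout + 2 * cout +     # conv1 + bn1
          b$kernel^2 * cout * cout + 2 * cout +  # conv2 + bn2
          if (proj) cin * cout + 2 * cout else 0 # 1x1 projection + bn
      })
    cin <- cout
  }
  if (spec_has_head(spec)) {
    c_head <- in_ch(shapes[[length(shapes)]])
    total <- total + c_head * spec$n_classes + spec$n_classes
  }
  as.integer(round(total))
}

#' Split a network specification at a cut layer
#'
#' Blocks `1..cut_layer` form the client fragment; the remaining blocks plus
#' the classifier head form the server fragment.  `cut_layer` may equal the
#' number of blocks, in which case the server holds only the head.
#'
#' @param spec A [network_spec()].
#' @param cut_layer Integer cut position `c`, `1 <= c <= length(blocks)`.
#' @return List with elements `client` and `server`, both `network_spec`
#'   fragments whose blocks re-concatenate to the original order.
#' @export
split_network <- function(spec, cut_layer) {
  L <- length(spec$blocks)
  if (!is.numeric(cut_layer) || length(cut_layer) != 1L ||
      cut_layer < 1L || cut_layer > L)
    stop("cut_layer must be in [1, ", L, "]", call. = FALSE)
  c_ <- as.integer(cut_layer)
  shapes <- spec_shapes(spec)
  client <- new_fragment(spec$blocks[seq_len(c_)], spec$input_shape,
                         spec$n_classes, paste0(spec$name, "_client"),
                         has_head = FALSE)
  server <- new_fragment(if (c_ < L) spec$blocks[(c_ + 1L):L] else list(),
                         shapes[[c_]], spec$n_classes,
                         paste0(spec$name, "_server"), has_head = TRUE)
  list(client = client, server = server, cut_layer = c_)
}

# Reassemble a full spec from two fragments produced by split_network().
merge_specs <- function(client_spec, server_spec, name = "assembled") {
  structure(list(blocks = c(client_spec$blocks, server_spec$blocks),
                 input_shape = client_spec$input_shape,
                 n_classes = server_spec$n_classes, name = name),
            class = "network_spec")
}

#' Reference network: 18-layer residual image classifier
#'
#' The canonical 18-layer residual architecture: a 7x7 stride-2 stem
#' convolution with batch normalization and 3-wide stride-2 max pooling,
#' eight two-convolution residual blocks in four stages of widths
#' 64/128/256/512 (first block of stages 2-4 downsampling with a projected
#' shortcut), then global average pooling into a dense classifier.  With the
#' canonical 1000-way head this counts 11,689,512 trainable parameters
#' (11.7 million to one decimal).  Nine splittable blocks: the stem plus the
#' eight residual blocks.
#'
#' @param input_shape Image input shape, default `c(64, 64, 3)`.
#' @param n_classes Head width, default the canonical 1000.
#' @return A [network_spec()] with 9 blocks.
#' @export
resnet18_spec <- function(input_shape = c(64L, 64L, 3L), n_classes = 1000L) {
  widths <- c(64L, 64L, 128L, 128L, 256L, 256L, 512L, 512L)
  strides <- c(1L, 1L, 2L, 1L, 2L, 1L, 2L, 1L)
  blocks <- c(
    list(block_spec("conv2d", 64L, kernel = 7L, stride = 2L,
                    normalization = TRUE, pool = "max3s2")),
    purrr::map2(widths, strides,
                ~ block_spec("residual2d", .x, kernel = 3L, stride = .y,
                             normalization = TRUE)))
  network_spec(blocks, input_shape, n_classes, name = "resnet18")
}

#' Reference network: 8-block 1-D convolutional signal classifier
#'
#' Eight convolution + ReLU blocks for multi-class 1-D signal classification:
#' first kernel 7, remaining kernels 3, with stride-2 blocks interleaved to
#' reduce the sequence length.  Channel widths are a package choice.
#'
#' @param input_shape Signal shape `c(length, channels)`, default `c(128, 1)`.
#' @param n_classes Number of classes, default 5.
#' @return A [network_spec()] with 8 blocks.
#' @export
conv1d_ref_spec <- function(input_shape = c(128L, 1L), n_classes = 5L) {
  widths <- c(8L, 8L, 16L, 16L, 32L, 32L, 32L, 32L)
  kernels <- c(7L, rep(3L, 7L))
  strides <- c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 1L)
  blocks <- purrr::pmap(list(widths, kernels, strides),
                        function(w, k, s) block_spec("conv1d", w, kernel = k,
                                                     stride = s))
  network_spec(blocks, input_shape, n_classes, name = "conv1d_ref")
}

#' Desk-scale 6-block image network
#'
#' A compact all-convolutional network used by the packaged cut-layer sweep
#' experiments: six 3x3 convolution + ReLU blocks, stride 2 at blocks 2 and 4.
#'
#' @param input_shape Image shape, default `c(12, 12, 3)`.
#' @param n_classes Number of classes, default 10.
#' @return A [network_spec()] with 6 blocks.
#' @export
conv2d_small_spec <- function(input_shape = c(12L, 12L, 3L), n_classes = 10L) {
  widths <- c(8L, 16L, 16L, 32L, 32L, 32L)
  strides <- c(1L, 2L, 1L, 2L, 1L, 1L)
  blocks <- purrr::map2(widths, strides,
                        ~ block_spec("conv2d", .x, kernel = 3L, stride = .y))
  network_spec(blocks, input_shape, n_classes, name = "conv2d_small")
}

#' Serialize / deserialize a network specification
#'
#' Writes the ordered block list, input shape and head description as JSON
#' (or YAML if the path ends in `.yml`/`.yaml`).
#'
#' @param spec A [network_spec()].
#' @param path File path to write to / read from.
#' @return `write_network_spec()` returns `path` invisibly;
#'   `read_network_spec()` returns a [network_spec()].
#' @export
write_network_spec <- function(spec, path) {
  doc <- list(name = spec$name, input_shape = spec$input_shape,
              n_classes = spec$n_classes,
              blocks = lapply(spec$blocks, unclass))
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(doc, path)
  else jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_network_spec
#' @export
read_network_spec <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  blocks <- lapply(seq_len(if (is.data.frame(doc$blocks)) nrow(doc$blocks)
                           else length(doc$blocks)), function(i) {
    b <- if (is.data.frame(doc$blocks)) as.list(doc$blocks[i, ])
    else doc$blocks[[i]]
    block_spec(b$kind, b$out_channels, b$kernel, b$activation,
               isTRUE(b$normalization), b$stride %||% 1L, b$pool %||% "none")
  })
  network_spec(blocks, unlist(doc$input_shape), doc$n_classes,
               name = doc$name %||% "network")
}
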