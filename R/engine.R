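# Deterministic CPU engine for block-structured networks.
#
# Public arrays (datasets, smashed batches, cut-layer gradients) use the
# field's channels-then-sample layout: (L, C, N) signals, (H, W, C, N)
# images, (d, N) dense activations.  Internally the engine permutes once per
# batch to a channels-LAST layout — (L, N, C), (H, W, N, C), (N, d) — so
# that convolutions run as one im2col gather (compiled, see src/cols.cpp),
# one BLAS matrix product against the reshaped kernel, and one col2im
# scatter on the way back; "same" zero padding of floor((k-1)/2).  No
# operation here consumes RNG, so passes are bitwise reproducible.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

same_pad <- function(k) (k - 1L) %/% 2L

conv_out_len <- function(n, k, s) (n + 2L * same_pad(k) - k) %/% s + 1L

# public (channels-then-sample) -> engine (channels-last) layout
to_engine <- function(x) {
  d <- dim(x)
  nd <- length(d)
  if (nd == 2L) return(t(x))
  if (nd == 3L) return(aperm(x, c(1L, 3L, 2L)))
  aperm(x, c(1L, 2L, 4L, 3L))
}

# engine -> public layout
to_public <- function(x) {
  d <- dim(x)
  nd <- length(d)
  if (nd == 2L) return(t(x))
  if (nd == 3L) return(aperm(x, c(1L, 3L, 2L)))
  aperm(x, c(1L, 2L, 4L, 3L))
}

# ---- conv2d (engine layout: H, W, N, C) ------------------------------------

# weights reshaped to (kh*kw*Cin x Cout), row blocks ordered like the
# im2col column blocks (offset-major, channels within an offset)
conv2d_wmat <- function(W) {
  kh <- dim(W)[1L]; kw <- dim(W)[2L]; Cin <- dim(W)[3L]; Cout <- dim(W)[4L]
  Wm <- matrix(0, kh * kw * Cin, Cout)
  for (i in seq_len(kh)) for (j in seq_len(kw)) {
    o <- (i - 1L) * kw + j
    Wm[(o - 1L) * Cin + seq_len(Cin), ] <- matrix(W[i, j, , ], Cin, Cout)
  }
  Wm
}

conv2d_fwd <- function(x, W, b = NULL, stride = 1L) {
  d <- dim(x); H <- d[1L]; Wd <- d[2L]; N <- d[3L]; Cin <- d[4L]
  kh <- dim(W)[1L]; kw <- dim(W)[2L]; Cout <- dim(W)[4L]
  ph <- same_pad(kh); pw <- same_pad(kw)
  ho <- conv_out_len(H, kh, stride); wo <- conv_out_len(Wd, kw, stride)
  M <- ho * wo * N
  Xc <- im2col2d_cpp(x, H, Wd, N, Cin, kh, kw, stride, ph, pw, ho, wo)
  out <- Xc %*% conv2d_wmat(W)
  if (!is.null(b)) out <- out + rep(b, each = M)
  dim(out) <- c(ho, wo, N, Cout)
  list(out = out,
       cache = list(Xc = Xc, in_dim = d, out_hw = c(ho, wo),
                    stride = stride, k = c(kh, kw), pad = c(ph, pw)))
}

conv2d_bwd <- function(cache, W, dout, need_dx = TRUE, has_bias = TRUE) {
  d <- cache$in_dim; H <- d[1L]; Wd <- d[2L]; N <- d[3L]; Cin <- d[4L]
  kh <- cache$k[1L]; kw <- cache$k[2L]; ph <- cache$pad[1L]; pw <- cache$pad[2L]
  ho <- cache$out_hw[1L]; wo <- cache$out_hw[2L]; stride <- cache$stride
  Cout <- dim(dout)[4L]
  M <- ho * wo * N
  dmat <- matrix(dout, M, Cout)
  dWmat <- crossprod(cache$Xc, dmat)
  dW <- array(0, dim(W))
  for (i in seq_len(kh)) for (j in seq_len(kw)) {
    o <- (i - 1L) * kw + j
    dW[i, j, , ] <- dWmat[(o - 1L) * Cin + seq_len(Cin), ]
  }
  dx <- NULL
  if (need_dx) {
    dXc <- dmat %*% t(conv2d_wmat(W))
    dx <- col2im2d_cpp(dXc, H, Wd, N, Cin, kh, kw, stride, ph, pw, ho, wo)
    dim(dx) <- c(H, Wd, N, Cin)
  }
  list(dx = dx, dW = dW, db = if (has_bias) colSums(dmat))
}

# ---- conv1d (engine layout: L, N, C) ---------------------------------------

conv1d_wmat <- function(W) {
  k <- dim(W)[1L]; Cin <- dim(W)[2L]; Cout <- dim(W)[3L]
  Wm <- matrix(0, k * Cin, Cout)
  for (i in seq_len(k))
    Wm[(i - 1L) * Cin + seq_len(Cin), ] <- matrix(W[i, , ], Cin, Cout)
  Wm
}

conv1d_fwd <- function(x, W, b = NULL, stride = 1L) {
  d <- dim(x); L <- d[1L]; N <- d[2L]; Cin <- d[3L]
  k <- dim(W)[1L]; Cout <- dim(W)[3L]
  p <- same_pad(k)
  lo <- conv_out_len(L, k, stride)
  M <- lo * N
  Xc <- im2col2d_cpp(x, L, 1L, N, Cin, k, 1L, stride, p, 0L, lo, 1L)
  out <- Xc %*% conv1d_wmat(W)
  if (!is.null(b)) out <- out + rep(b, each = M)
  dim(out) <- c(lo, N, Cout)
  list(out = out,
       cache = list(Xc = Xc, in_dim = d, lo = lo, stride = stride,
                    k = k, pad = p))
}

conv1d_bwd <- function(cache, W, dout, need_dx = TRUE, has_bias = TRUE) {
  d <- cache$in_dim; L <- d[1L]; N <- d[2L]; Cin <- d[3L]
  k <- cache$k; p <- cache$pad; lo <- cache$lo; stride <- cache$stride
  Cout <- dim(dout)[3L]
  M <- lo * N
  dmat <- matrix(dout, M, Cout)
  dWmat <- crossprod(cache$Xc, dmat)
  dW <- array(0, dim(W))
  for (i in seq_len(k))
    dW[i, , ] <- dWmat[(i - 1L) * Cin + seq_len(Cin), ]
  dx <- NULL
  if (need_dx) {
    dXc <- dmat %*% t(conv1d_wmat(W))
    dx <- col2im2d_cpp(dXc, L, 1L, N, Cin, k, 1L, stride, p, 0L, lo, 1L)
    dim(dx) <- c(L, N, Cin)
  }
  list(dx = dx, dW = dW, db = if (has_bias) colSums(dmat))
}

# ---- batch normalization (per-channel over all other axes) -----------------

bn_fwd <- function(m, gamma, beta, running_mean, running_var, training) {
  M <- nrow(m)
  if (training) {
    mu <- colMeans(m)
    v <- colMeans(m * m) - mu^2
    v[v < 0] <- 0
    new_rm <- (1 - BN_MOMENTUM) * running_mean + BN_MOMENTUM * mu
    new_rv <- (1 - BN_MOMENTUM) * running_var + BN_MOMENTUM * v
  } else {
    mu <- running_mean; v <- running_var
    new_rm <- running_mean; new_rv <- running_var
  }
  invstd <- 1 / sqrt(v + BN_EPS)
  xhat <- (m - rep(mu, each = M)) * rep(invstd, each = M)
  out <- xhat * rep(gamma, each = M) + rep(beta, each = M)
  list(out = out,
       cache = list(xhat = xhat, invstd = invstd, training = training),
       running_mean = new_rm, running_var = new_rv)
}

bn_bwd <- function(cache, gamma, dout) {
  M <- nrow(dout)
  xhat <- cache$xhat
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- dout * rep(gamma, each = M)
  dx <- if (cache$training) {
    (dxhat - rep(colSums(dxhat) / M, each = M) -
       xhat * rep(colSums(dxhat * xhat) / M, each = M)) *
      rep(cache$invstd, each = M)
  } else {
    dxhat * rep(cache$invstd, each = M)
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# engine layout keeps channels last, so the (M x C) matrix view is free
to_mat <- function(x) {
  d <- dim(x)
  matrix(x, prod(d[-length(d)]), d[length(d)])
}

from_mat <- function(m, d) array(m, d)

# ---- max pool 3-wide stride 2 (2-D) ----------------------------------------

maxpool_fwd <- function(x) {
  d <- dim(x); H <- d[1L]; Wd <- d[2L]; N <- d[3L]; C <- d[4L]
  p <- 1L; k <- 3L; s <- 2L
  Hp <- H + 2L * p; Wp <- Wd + 2L * p
  ho <- (Hp - k) %/% s + 1L; wo <- (Wp - k) %/% s + 1L
  xpad <- array(-Inf, c(Hp, Wp, N, C))
  xpad[p + seq_len(H), p + seq_len(Wd), , ] <- x
  M <- ho * wo * N
  best <- matrix(-Inf, M, C)
  arg <- matrix(0L, M, C)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ys <- seq.int(i, by = s, length.out = ho)
    xs <- seq.int(j, by = s, length.out = wo)
    m <- matrix(xpad[ys, xs, , , drop = FALSE], M, C)
    upd <- m > best
    best[upd] <- m[upd]
    arg[upd] <- (i - 1L) * k + j
  }
  list(out = array(best, c(ho, wo, N, C)),
       cache = list(arg = arg, in_dim = d, out_hw = c(ho, wo)))
}

maxpool_bwd <- function(cache, dout) {
  d <- cache$in_dim; H <- d[1L]; Wd <- d[2L]; N <- d[3L]; C <- d[4L]
  p <- 1L; k <- 3L; s <- 2L
  ho <- cache$out_hw[1L]; wo <- cache$out_hw[2L]
  M <- ho * wo * N
  dmat <- matrix(dout, M, C)
  dxpad <- array(0, c(H + 2L * p, Wd + 2L * p, N, C))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    o <- (i - 1L) * k + j
    dm <- dmat * (cache$arg == o)
    ys <- seq.int(i, by = s, length.out = ho)
    xs <- seq.int(j, by = s, length.out = wo)
    dxpad[ys, xs, , ] <- dxpad[ys, xs, , ] + array(dm, c(ho, wo, N, C))
  }
  dxpad[p + seq_len(H), p + seq_len(Wd), , , drop = FALSE]
}

# ---- block-level dispatch ---------------------------------------------------

relu_fwd <- function(x) {
  mask <- x > 0
  list(out = x * mask, mask = mask)
}

# flatten an engine-layout tensor to (N, features) with (spatial, channel)
# feature ordering; dense blocks and their inverse use it
flatten_engine <- function(x) {
  d <- dim(x)
  nd <- length(d)
  if (nd == 2L) return(x)
  N <- d[nd - 1L]
  perm <- c(seq_len(nd - 2L), nd, nd - 1L)
  t(matrix(aperm(x, perm), prod(d[-(nd - 1L)]), N))
}

unflatten_engine <- function(m, d) {
  nd <- length(d)
  if (nd == 2L) return(m)
  N <- d[nd - 1L]
  a <- array(t(m), c(d[-(nd - 1L)], N))
  aperm(a, c(seq_len(nd - 2L), nd, nd - 1L))
}

# forward one block (engine layout); returns out, cache, updated params
block_forward <- function(bspec, params, x, training = TRUE) {
  kind <- bspec$kind
  if (kind == "residual2d") return(res_forward(bspec, params, x, training))
  if (kind == "dense") {
    in_dim <- dim(x)
    xf <- flatten_engine(x)
    out <- xf %*% params$W
    if (!bspec$normalization)
      out <- out + rep(params$b, each = nrow(out))
    cache <- list(xf = xf, in_dim = in_dim)
  } else {
    fwd <- if (kind == "conv1d") conv1d_fwd else conv2d_fwd
    r <- fwd(x, params$W, if (!bspec$normalization) params$b, bspec$stride)
    out <- r$out
    cache <- list(conv = r$cache)
  }
  if (bspec$normalization) {
    d <- dim(out)
    bn <- bn_fwd(to_mat(out), params$gamma, params$beta,
                 params$running_mean, params$running_var, training)
    out <- from_mat(bn$out, d)
    cache$bn <- bn$cache
    cache$bn_dim <- d
    params$running_mean <- bn$running_mean
    params$running_var <- bn$running_var
  }
  if (bspec$activation == "relu") {
    r <- relu_fwd(out)
    out <- r$out
    cache$relu_mask <- r$mask
  }
  if (bspec$pool == "max3s2") {
    mp <- maxpool_fwd(out)
    out <- mp$out
    cache$pool <- mp$cache
  }
  list(out = out, cache = cache, params = params)
}

# backward one block; returns dx (if requested) and grads mirroring params
block_backward <- function(bspec, params, cache, dout, need_dx = TRUE) {
  kind <- bspec$kind
  if (kind == "residual2d")
    return(res_backward(bspec, params, cache, dout, need_dx))
  if (!is.null(cache$pool)) dout <- maxpool_bwd(cache$pool, dout)
  if (!is.null(cache$relu_mask)) dout <- dout * cache$relu_mask
  grads <- list()
  if (bspec$normalization) {
    bb <- bn_bwd(cache$bn, params$gamma, to_mat(dout))
    dout <- from_mat(bb$dx, cache$bn_dim)
    grads$gamma <- bb$dgamma
    grads$beta <- bb$dbeta
  }
  if (kind == "dense") {
    grads$W <- crossprod(cache$xf, dout)
    if (!bspec$normalization) grads$b <- colSums(dout)
    dx <- if (need_dx) unflatten_engine(dout %*% t(params$W), cache$in_dim)
  } else {
    bwd <- if (kind == "conv1d") conv1d_bwd else conv2d_bwd
    r <- bwd(cache$conv, params$W, dout, need_dx,
             has_bias = !bspec$normalization)
    grads$W <- r$dW
    if (!bspec$normalization) grads$b <- r$db
    dx <- r$dx
  }
  list(dx = dx, grads = grads)
}

# ---- residual basic block ---------------------------------------------------

res_forward <- function(bspec, params, x, training) {
  c1 <- conv2d_fwd(x, params$conv1$W, NULL, bspec$stride)
  d1 <- dim(c1$out)
  bn1 <- bn_fwd(to_mat(c1$out), params$bn1$gamma, params$bn1$beta,
                params$bn1$running_mean, params$bn1$running_var, training)
  params$bn1$running_mean <- bn1$running_mean
  params$bn1$running_var <- bn1$running_var
  a1 <- relu_fwd(from_mat(bn1$out, d1))
  c2 <- conv2d_fwd(a1$out, params$conv2$W, NULL, 1L)
  d2 <- dim(c2$out)
  bn2 <- bn_fwd(to_mat(c2$out), params$bn2$gamma, params$bn2$beta,
                params$bn2$running_mean, params$bn2$running_var, training)
  params$bn2$running_mean <- bn2$running_mean
  params$bn2$running_var <- bn2$running_var
  main <- from_mat(bn2$out, d2)
  if (!is.null(params$proj)) {
    pc <- conv2d_fwd(x, params$proj$W, NULL, bspec$stride)
    bnp <- bn_fwd(to_mat(pc$out), params$bnp$gamma, params$bnp$beta,
                  params$bnp$running_mean, params$bnp$running_var, training)
    params$bnp$running_mean <- bnp$running_mean
    params$bnp$running_var <- bnp$running_var
    shortcut <- from_mat(bnp$out, d2)
    proj_cache <- list(conv = pc$cache, bn = bnp$cache)
  } else {
    shortcut <- x
    proj_cache <- NULL
  }
  r <- relu_fwd(main + shortcut)
  list(out = r$out,
       cache = list(c1 = c1$cache, bn1 = bn1$cache, relu1 = a1$mask, d1 = d1,
                    c2 = c2$cache, bn2 = bn2$cache, d2 = d2,
                    proj = proj_cache, relu_out = r$mask),
       params = params)
}

res_backward <- function(bspec, params, cache, dout, need_dx) {
  dsum <- dout * cache$relu_out
  b2 <- bn_bwd(cache$bn2, params$bn2$gamma, to_mat(dsum))
  r2 <- conv2d_bwd(cache$c2, params$conv2$W, from_mat(b2$dx, cache$d2),
                   TRUE, has_bias = FALSE)
  da1 <- r2$dx * cache$relu1
  b1 <- bn_bwd(cache$bn1, params$bn1$gamma, to_mat(da1))
  r1 <- conv2d_bwd(cache$c1, params$conv1$W, from_mat(b1$dx, cache$d1),
                   need_dx, has_bias = FALSE)
  grads <- list(conv1 = list(W = r1$dW),
                bn1 = list(gamma = b1$dgamma, beta = b1$dbeta),
                conv2 = list(W = r2$dW),
                bn2 = list(gamma = b2$dgamma, beta = b2$dbeta))
  if (!is.null(cache$proj)) {
    bp <- bn_bwd(cache$proj$bn, params$bnp$gamma, to_mat(dsum))
    rp <- conv2d_bwd(cache$proj$conv, params$proj$W,
                     from_mat(bp$dx, cache$d2), need_dx, has_bias = FALSE)
    grads$proj <- list(W = rp$dW)
    grads$bnp <- list(gamma = bp$dgamma, beta = bp$dbeta)
    dx <- if (need_dx) r1$dx + rp$dx
  } else {
    dx <- if (need_dx) r1$dx + dsum
  }
  list(dx = dx, grads = grads)
}

# ---- classifier head --------------------------------------------------------

# input engine layout; logits are (N, n_classes)
head_forward <- function(head_params, x) {
  d <- dim(x)
  nd <- length(d)
  if (nd > 2L) {
    spatial <- prod(d[seq_len(nd - 2L)])
    N <- d[nd - 1L]; C <- d[nd]
    pooled <- matrix(colMeans(matrix(x, spatial, N * C)), N, C)
  } else {
    pooled <- x
  }
  logits <- pooled %*% head_params$W +
    rep(head_params$b, each = nrow(pooled))
  list(logits = logits, cache = list(pooled = pooled, in_dim = d))
}

head_backward <- function(head_params, cache, dlogits, need_dx = TRUE) {
  grads <- list(W = crossprod(cache$pooled, dlogits),
                b = colSums(dlogits))
  dx <- NULL
  if (need_dx) {
    dpool <- dlogits %*% t(head_params$W)
    d <- cache$in_dim; nd <- length(d)
    dx <- if (nd > 2L) {
      spatial <- prod(d[seq_len(nd - 2L)])
      array(rep(as.vector(dpool), each = spatial) / spatial, d)
    } else dpool
  }
  list(dx = dx, grads = grads)
}

# softmax cross-entropy on logits (N x n_classes); labels 0-based
softmax_ce <- function(logits, labels) {
  N <- nrow(logits)
  shifted <- logits - apply(logits, 1L, max)
  e <- exp(shifted)
  p <- e / rowSums(e)
  idx <- cbind(seq_len(N), as.integer(labels) + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-300)))
  pred <- max.col(logits, ties.method = "first") - 1L
  acc <- mean(pred == as.integer(labels))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, accuracy = acc, dlogits = dlogits / N, pred = pred)
}

# ---- initialization ---------------------------------------------------------

init_block <- function(bspec, cin, in_flat = NULL) {
  he <- function(n, fan_in) array(stats::rnorm(n, 0, sqrt(2 / fan_in)))
  cout <- bspec$out_channels
  p <- switch(bspec$kind,
    dense = {
      d_in <- in_flat
      l <- list(W = matrix(he(d_in * cout, d_in), d_in, cout))
      if (!bspec$normalization) l$b <- numeric(cout)
      l
    },
    conv1d = {
      k <- bspec$kernel
      l <- list(W = array(he(k * cin * cout, k * cin), c(k, cin, cout)))
      if (!bspec$normalization) l$b <- numeric(cout)
      l
    },
    conv2d = {
      k <- bspec$kernel
      l <- list(W = array(he(k * k * cin * cout, k * k * cin),
                          c(k, k, cin, cout)))
      if (!bspec$normalization) l$b <- numeric(cout)
      l
    },
    residual2d = {
      k <- bspec$kernel
      l <- list(
        conv1 = list(W = array(he(k * k * cin * cout, k * k * cin),
                               c(k, k, cin, cout))),
        bn1 = bn_init(cout),
        conv2 = list(W = array(he(k * k * cout * cout, k * k * cout),
                               c(k, k, cout, cout))),
        bn2 = bn_init(cout))
      if (bspec$stride > 1L || cin != cout) {
        l$proj <- list(W = array(he(cin * cout, cin), c(1L, 1L, cin, cout)))
        l$bnp <- bn_init(cout)
      }
      l
    })
  if (bspec$normalization && bspec$kind != "residual2d")
    p <- c(p, bn_init(cout))
  p
}

bn_init <- function(c_) list(gamma = rep(1, c_), beta = numeric(c_),
                             running_mean = numeric(c_),
                             running_var = rep(1, c_))

#' Build (initialize) the parameters of a network
#'
#' Deterministic seeded He-style initialization: weights are drawn
#' `N(0, sqrt(2 / fan_in))` block by block in order, biases and
#' normalization shifts start at zero, normalization scales at one.
#' Identical `(spec, seed)` pairs give element-wise identical parameters.
#'
#' @param spec A [network_spec()] (full network or fragment).
#' @param seed Integer seed.
#' @return A `param_set`: per-block parameter arrays plus (for specs with a
#'   head) the classifier parameters, carrying the spec as an attribute.
#' @export
build_network <- function(spec, seed = 0L) {
  shapes <- spec_shapes(spec)
  withr::with_seed(as.integer(seed), {
    cin <- spec$input_shape[length(spec$input_shape)]
    if (length(spec$input_shape) == 1L) cin <- spec$input_shape
    blocks <- vector("list", length(spec$blocks))
    for (i in seq_along(spec$blocks)) {
      b <- spec$blocks[[i]]
      in_flat <- if (i == 1L) prod(spec$input_shape) else prod(shapes[[i - 1L]])
      blocks[[i]] <- init_block(b, cin, in_flat)
      cin <- b$out_channels
    }
    head <- NULL
    if (spec_has_head(spec)) {
      c_head <- if (length(spec$blocks) > 0L) {
        sh <- shapes[[length(shapes)]]
        sh[length(sh)]
      } else spec$input_shape[length(spec$input_shape)]
      head <- list(W = matrix(stats::rnorm(c_head * spec$n_classes, 0,
                                           sqrt(2 / c_head)),
                              c_head, spec$n_classes),
                   b = numeric(spec$n_classes))
    }
    new_param_set(blocks, head, spec)
  })
}

new_param_set <- function(blocks, head, spec) {
  structure(list(blocks = blocks, head = head),
            class = "param_set", spec = spec)
}

param_spec <- function(params) attr(params, "spec")

#' @export
print.param_set <- function(x, ...) {
  sp <- param_spec(x)
  cat("<param_set> ", sp$name, ": ", length(x$blocks), " block(s)",
      if (!is.null(x$head)) " + head", ", ",
      format(n_elements(x), big.mark = ","), " trainable elements\n",
      sep = "")
  invisible(x)
}

# total trainable scalars in a param_set (running stats excluded)
n_elements <- function(params) {
  cnt <- function(p, nm) {
    if (is.list(p)) return(sum(vapply(names(p), function(k) cnt(p[[k]], k), 0)))
    if (nm %in% c("running_mean", "running_var")) return(0)
    length(p)
  }
  total <- sum(vapply(seq_along(params$blocks),
                      function(i) cnt(params$blocks[[i]], "block"), 0))
  if (!is.null(params$head)) total <- total + cnt(params$head, "head")
  as.integer(total)
}

# ---- multi-block forward / SGD ---------------------------------------------

# Forward through all blocks of a fragment (engine layout in and out).
forward_blocks <- function(params, x, training = TRUE, collect = FALSE) {
  spec <- param_spec(params)
  keep <- training
  caches <- if (keep) vector("list", length(spec$blocks))
  outs <- if (collect) vector("list", length(spec$blocks))
  for (i in seq_along(spec$blocks)) {
    r <- block_forward(spec$blocks[[i]], params$blocks[[i]], x, training)
    x <- r$out
    if (keep) caches[[i]] <- r$cache
    params$blocks[[i]] <- r$params
    if (collect) outs[[i]] <- x
  }
  list(out = x, caches = caches, params = params, outs = outs)
}

backward_blocks <- function(params, caches, dout, need_dx_first = FALSE) {
  spec <- param_spec(params)
  L <- length(spec$blocks)
  grads <- vector("list", L)
  for (i in rev(seq_len(L))) {
    r <- block_backward(spec$blocks[[i]], params$blocks[[i]], caches[[i]],
                        dout, need_dx = (i > 1L) || need_dx_first)
    grads[[i]] <- r$grads
    dout <- r$dx
  }
  list(grads = grads, dx = dout)
}

# one plain-SGD step: params <- params - lr * grads (structure-matched)
sgd_step <- function(params, grads, lr) {
  upd <- function(p, g) {
    if (is.list(p)) {
      for (k in names(p)) if (!is.null(g[[k]])) p[[k]] <- upd(p[[k]], g[[k]])
      p
    } else p - lr * g
  }
  for (i in seq_along(grads$blocks))
    params$blocks[[i]] <- upd(params$blocks[[i]], grads$blocks[[i]])
  if (!is.null(grads$head))
    params$head <- upd(params$head, grads$head)
  params
}
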