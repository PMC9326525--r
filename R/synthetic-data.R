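#' Generator settings for synthetic datasets
#'
#' Desk-scale defaults: 2000 training and 500 test samples.  The 1-D
#' generator emulates a 5-class physiological-signal classification task
#' (length-128 single-channel traces); the image generator emulates 1- or
#' 3-channel 12x12 multi-class image tasks.  `class_separation` scales the
#' class templates relative to the noise, moving task difficulty; the
#' packaged image defaults (noise 0.35, separation 0.6) put a small CNN in
#' a non-saturated accuracy regime at the desk-scale training budget while
#' a nearest-centroid reference still classifies almost perfectly.
#'
#' @param n_train,n_test Split sizes (each >= `n_classes`).
#' @param n_classes Number of classes.
#' @param channels 1 or 3 (images); 1-D signals are single-channel.
#' @param length Signal length (1-D).
#' @param height,width Image dimensions.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param class_separation Positive template scale.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @param modality `"series1d"` or `"image"`; which generator the config is
#'   meant for (used when a config is handed to experiment drivers).
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_train = 2000L, n_test = 500L, n_classes = 5L,
                             channels = 1L, length = 128L, height = 12L,
                             width = 12L, noise_sd = 0.3,
                             class_separation = 1, seed = 1L,
                             modality = c("series1d", "image")) {
  modality <- match.arg(modality)
  if (n_train < n_classes || n_test < n_classes)
    stop("n_train and n_test must each be >= n_classes", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (class_separation <= 0) stop("class_separation must be > 0",
                                  call. = FALSE)
  if (!channels %in% c(1L, 3L)) stop("channels must be 1 or 3",
                                     call. = FALSE)
  structure(list(n_train = as.integer(n_train), n_test = as.integer(n_test),
                 n_classes = as.integer(n_classes),
                 channels = as.integer(channels), length = as.integer(length),
                 height = as.integer(height), width = as.integer(width),
                 noise_sd = noise_sd, class_separation = class_separation,
                 seed = as.integer(seed), modality = modality),
            class = "generator_config")
}

# near-balanced label vector (counts differ by <= 1), shuffled
balanced_labels <- function(n, n_classes) {
  sample(rep(seq_len(n_classes) - 1L, length.out = n))
}

new_dataset <- function(train_x, train_labels, test_x, test_labels,
                        n_classes, modality, config) {
  structure(list(train_x = train_x, train_labels = as.integer(train_labels),
                 test_x = test_x, test_labels = as.integer(test_labels),
                 n_classes = as.integer(n_classes), modality = modality,
                 config = config),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  d <- dim(x$train_x)
  cat("<sim_dataset> ", x$modality, ", ", x$n_classes, " classes, shape ",
      paste(d[-length(d)], collapse = "x"), "; train ",
      length(x$train_labels), " / test ", length(x$test_labels), "\n",
      sep = "")
  invisible(x)
}

#' Generate a synthetic multi-class 1-D signal dataset
#'
#' Each class is a fixed seeded waveform template — a sum of three
#' sinusoids with class-specific frequencies, phases and amplitudes, scaled
#' by `class_separation` — and each sample is its class template plus IID
#' Gaussian noise.  Labels are near-balanced; train and test are disjoint
#' draws by construction.  Mirrors the role of a 5-class ECG-beat
#' classification task at desk scale; no augmentation is ever applied to
#' this modality.
#'
#' @param config A [generator_config()].
#' @return A `sim_dataset` with `train_x` of shape `(length, 1, n_train)`.
#' @export
gen_timeseries <- function(config = generator_config()) {
  withr::with_seed(config$seed, {
    L <- config$length
    t_ <- seq_len(L)
    templates <- lapply(seq_len(config$n_classes), function(k) {
      f <- sample(1:8, 3L, replace = TRUE) + (k - 1L) %% 4L
      ph <- stats::runif(3L, 0, 2 * pi)
      amp <- stats::runif(3L, 0.4, 1)
      config$class_separation *
        colSums(amp * sin(outer(f, t_ / L * 2 * pi) + ph))
    })
    make_split <- function(n) {
      lab <- balanced_labels(n, config$n_classes)
      x <- array(0, c(L, 1L, n))
      noise <- array(stats::rnorm(L * n, 0, config$noise_sd), c(L, n))
      for (i in seq_len(n))
        x[, 1L, i] <- templates[[lab[i] + 1L]] + noise[, i]
      list(x = x, lab = lab)
    }
    tr <- make_split(config$n_train)
    te <- make_split(config$n_test)
    new_dataset(tr$x, tr$lab, te$x, te$lab, config$n_classes, "series1d",
                config)
  })
}

#' Generate a synthetic multi-class image dataset
#'
#' Each class (per channel) has a fixed seeded spatial pattern — a mixture
#' of three Gaussian blobs with class-specific centers, widths and
#' amplitudes — rescaled into `[0.1, 0.9]` and scaled by `class_separation`
#' around mid-gray.  Samples add pixel noise and are clipped to `[0, 1]`.
#'
#' @param config A [generator_config()]; set `channels = 3` for RGB-style
#'   tasks, `channels = 1` for grayscale-style tasks.
#' @return A `sim_dataset` with `train_x` of shape
#'   `(height, width, channels, n_train)`.
#' @export
gen_images <- function(config = generator_config(n_classes = 10L,
                                                 channels = 3L,
                                                 noise_sd = 0.35,
                                                 class_separation = 0.6,
                                                 modality = "image")) {
  withr::with_seed(config$seed, {
    H <- config$height; W <- config$width; C <- config$channels
    gy <- matrix(seq_len(H), H, W)
    gx <- matrix(seq_len(W), H, W, byrow = TRUE)
    blob_pattern <- function() {
      m <- matrix(0, H, W)
      for (b in 1:3) {
        cy <- stats::runif(1, 1, H); cx <- stats::runif(1, 1, W)
        s <- stats::runif(1, 2, 4); amp <- stats::runif(1, 0.5, 1)
        m <- m + amp * exp(-((gy - cy)^2 + (gx - cx)^2) / (2 * s^2))
      }
      rng <- range(m)
      0.1 + 0.8 * (m - rng[1]) / max(diff(rng), 1e-12)
    }
    templates <- lapply(seq_len(config$n_classes), function(k) {
      arr <- array(0, c(H, W, C))
      for (c_ in seq_len(C))
        arr[, , c_] <- 0.5 + config$class_separation *
          (blob_pattern() - 0.5)
      arr
    })
    make_split <- function(n) {
      lab <- balanced_labels(n, config$n_classes)
      x <- array(0, c(H, W, C, n))
      for (i in seq_len(n)) {
        s <- templates[[lab[i] + 1L]] +
          array(stats::rnorm(H * W * C, 0, config$noise_sd), c(H, W, C))
        x[, , , i] <- pmin(pmax(s, 0), 1)
      }
      list(x = x, lab = lab)
    }
    tr <- make_split(config$n_train)
    te <- make_split(config$n_test)
    new_dataset(tr$x, tr$lab, te$x, te$lab, config$n_classes, "image",
                config)
  })
}

#' Nearest-centroid accuracy on a dataset's test split
#'
#' Classifies each test sample by the nearest (Euclidean) class mean of the
#' training split.  Serves as a simple reference classifier for generated
#' data.
#'
#' @param dataset A `sim_dataset`.
#' @return Test accuracy in `[0, 1]`.
#' @export
nearest_centroid_accuracy <- function(dataset) {
  d <- dim(dataset$train_x)
  n_tr <- d[length(d)]
  p <- prod(d[-length(d)])
  xtr <- matrix(dataset$train_x, p, n_tr)
  xte <- matrix(dataset$test_x, p, length(dataset$test_labels))
  cents <- vapply(seq_len(dataset$n_classes) - 1L, function(k) {
    rowMeans(xtr[, dataset$train_labels == k, drop = FALSE])
  }, numeric(p))
  d2 <- -2 * crossprod(xte, cents) +
    matrix(colSums(cents^2), ncol(xte), dataset$n_classes, byrow = TRUE)
  pred <- max.col(-d2, ties.method = "first") - 1L
  mean(pred == dataset$test_labels)
}

# ---- augmentation -----------------------------------------------------------

#' Deterministic image-batch transforms
#'
#' Low-level transforms used by [augment()]: `flip_horizontal()` mirrors the
#' width axis (an involution); `rotate_images()` rotates each image about
#' its center by per-sample angles (degrees, nearest-neighbor resampling,
#' zero fill); `crop_jitter()` zero-pads by `pad` pixels and crops back to
#' the original size at per-sample offsets in `[-pad, pad]`.
#'
#' @param batch `(H, W, C, N)` image array.
#' @param angles Numeric vector of length N (degrees).
#' @param dy,dx Integer offset vectors of length N.
#' @param pad Padding for crop jitter.
#' @return Transformed batch of the same shape.
#' @export
flip_horizontal <- function(batch) {
  batch[, rev(seq_len(dim(batch)[2L])), , , drop = FALSE]
}

#' @rdname flip_horizontal
#' @export
rotate_images <- function(batch, angles) {
  d <- dim(batch)
  H <- d[1L]; W <- d[2L]; C <- d[3L]; N <- d[4L]
  stopifnot(length(angles) == N)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  gy <- matrix(seq_len(H), H, W) - cy
  gx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  out <- array(0, d)
  for (i in seq_len(N)) {
    th <- angles[i] * pi / 180
    # source coordinate = inverse rotation of the destination coordinate
    sy <- round(cos(th) * gy - sin(th) * gx + cy)
    sx <- round(sin(th) * gy + cos(th) * gx + cx)
    ok <- sy >= 1 & sy <= H & sx >= 1 & sx <= W
    idx <- cbind(as.vector(sy[ok]), as.vector(sx[ok]))
    for (c_ in seq_len(C)) {
      m <- matrix(0, H, W)
      m[ok] <- batch[, , c_, i][idx]
      out[, , c_, i] <- m
    }
  }
  out
}

#' @rdname flip_horizontal
#' @export
crop_jitter <- function(batch, dy, dx, pad = 2L) {
  d <- dim(batch)
  H <- d[1L]; W <- d[2L]; N <- d[4L]
  stopifnot(length(dy) == N, length(dx) == N, all(abs(dy) <= pad),
            all(abs(dx) <= pad))
  padded <- array(0, c(H + 2L * pad, W + 2L * pad, d[3L], N))
  padded[pad + seq_len(H), pad + seq_len(W), , ] <- batch
  out <- array(0, d)
  for (i in seq_len(N))
    out[, , , i] <- padded[pad + dy[i] + seq_len(H),
                           pad + dx[i] + seq_len(W), , i]
  out
}

#' Seeded stochastic augmentation of an image batch
#'
#' Applies the requested subset of the standard augmentations: horizontal
#' flipping (probability 1/2 per sample), random rotation (uniform in
#' `[-max_angle, max_angle]` degrees), random cropping (pad-and-crop with
#' offsets in `[-pad, pad]`), and per-channel normalization to zero mean /
#' unit standard deviation using training-split statistics.  Geometric
#' operations refuse 1-D signal batches: signal-style data bypasses
#' augmentation entirely.
#'
#' @param batch `(H, W, C, N)` image array (or `(L, C, N)`; only
#'   `"normalize"` is then legal).
#' @param ops Character subset of `c("hflip", "rotate", "crop",
#'   "normalize")`.
#' @param stats Optional list with per-channel `mean` and `sd` vectors
#'   (training-split statistics) for `"normalize"`; computed from `batch`
#'   when missing.
#' @param seed Integer seed for the stochastic draws.
#' @param max_angle,pad Rotation range (degrees) and crop padding.
#' @return List: transformed `batch` and the `stats` used (for reuse on the
#'   test split).
#' @export
augment <- function(batch, ops = c("hflip", "rotate", "crop", "normalize"),
                    stats = NULL, seed = 1L, max_angle = 15, pad = 2L) {
  ops <- match.arg(ops, several.ok = TRUE)
  d <- dim(batch)
  is_image <- length(d) == 4L
  geo <- intersect(ops, c("hflip", "rotate", "crop"))
  if (!is_image && length(geo))
    stop("geometric augmentation (", paste(geo, collapse = ", "),
         ") is not applicable to 1-D signal batches", call. = FALSE)
  N <- d[length(d)]
  withr::with_seed(as.integer(seed), {
    if ("hflip" %in% ops) {
      flip <- stats::runif(N) < 0.5
      if (any(flip)) {
        flipped <- flip_horizontal(batch)
        batch[, , , flip] <- flipped[, , , flip]
      }
    }
    if ("rotate" %in% ops)
      batch <- rotate_images(batch, stats::runif(N, -max_angle, max_angle))
    if ("crop" %in% ops)
      batch <- crop_jitter(batch, sample(-pad:pad, N, replace = TRUE),
                           sample(-pad:pad, N, replace = TRUE), pad)
  })
  if ("normalize" %in% ops) {
    C <- d[length(d) - 1L]
    if (is.null(stats)) {
      m <- matrix(aperm(batch, c(setdiff(seq_along(d), length(d) - 1L),
                                 length(d) - 1L)),
                  ncol = C)
      stats <- list(mean = colMeans(m), sd = apply(m, 2L, stats::sd))
    }
    for (c_ in seq_len(C)) {
      if (is_image)
        batch[, , c_, ] <- (batch[, , c_, ] - stats$mean[c_]) / stats$sd[c_]
      else
        batch[, c_, ] <- (batch[, c_, ] - stats$mean[c_]) / stats$sd[c_]
    }
  }
  list(batch = batch, stats = stats)
}

# ---- persistence ------------------------------------------------------------

#' Save / load a dataset as plain files
#'
#' Images are written as 8-bit PNG files in per-class subdirectories
#' (`train/class_<k>/`, `test/class_<k>/`) with a `labels.csv` manifest;
#' 1-D signal datasets are written as one delimited text file per split
#' (one row per sample, final column the label).  Loading inverts saving
#' exactly for signals and up to 8-bit quantization (1/255 per pixel) for
#' images.
#'
#' @param dataset A `sim_dataset`.
#' @param dir Directory to create/populate.
#' @return `save_dataset()` returns `dir` invisibly; `load_dataset()`
#'   returns a `sim_dataset`.
#' @export
save_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(modality = dataset$modality, n_classes = dataset$n_classes,
               dims = dim(dataset$train_x))
  meta$dims <- meta$dims[-length(meta$dims)]
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  if (dataset$modality == "series1d") {
    for (split in c("train", "test")) {
      x <- dataset[[paste0(split, "_x")]]
      lab <- dataset[[paste0(split, "_labels")]]
      d <- dim(x)
      m <- cbind(t(matrix(x, d[1L] * d[2L], d[3L])), lab)
      # %.17g round-trips doubles exactly through text
      mc <- matrix(sprintf("%.17g", m), nrow(m), ncol(m))
      mc[, ncol(mc)] <- as.character(lab)
      utils::write.table(mc, file.path(dir, paste0(split, ".tsv")),
                         sep = "\t", row.names = FALSE, col.names = FALSE,
                         quote = FALSE)
    }
  } else {
    rows <- list()
    for (split in c("train", "test")) {
      x <- dataset[[paste0(split, "_x")]]
      lab <- dataset[[paste0(split, "_labels")]]
      for (i in seq_along(lab)) {
        cls_dir <- file.path(dir, split, paste0("class_", lab[i]))
        dir.create(cls_dir, recursive = TRUE, showWarnings = FALSE)
        img <- drop_sample_axis(slice_samples(x, i))
        if (dim(img)[3L] == 1L) img <- img[, , 1L]
        f <- file.path(cls_dir, sprintf("img_%05d.png", i))
        png::writePNG(pmin(pmax(img, 0), 1), target = f)
        rows[[length(rows) + 1L]] <-
          data.frame(split = split, file = f, label = lab[i])
      }
    }
    utils::write.csv(do.call(rbind, rows), file.path(dir, "labels.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path))
    stop("not a dataset directory: missing meta.json in ", dir,
         call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (meta$modality == "series1d") {
    read_split <- function(split) {
      f <- file.path(dir, paste0(split, ".tsv"))
      if (!file.exists(f)) stop("missing ", f, call. = FALSE)
      m <- as.matrix(utils::read.table(f, sep = "\t"))
      n <- nrow(m)
      lab <- as.integer(m[, ncol(m)])
      x <- array(t(m[, -ncol(m), drop = FALSE]), c(meta$dims, n))
      list(x = x, lab = lab)
    }
    tr <- read_split("train"); te <- read_split("test")
  } else {
    lab_file <- file.path(dir, "labels.csv")
    if (!file.exists(lab_file)) stop("missing ", lab_file, call. = FALSE)
    labels <- utils::read.csv(lab_file)
    read_split <- function(split) {
      rows <- labels[labels$split == split, ]
      n <- nrow(rows)
      x <- array(0, c(meta$dims, n))
      for (i in seq_len(n)) {
        img <- png::readPNG(rows$file[i])
        if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
        x[, , , i] <- img[, , seq_len(meta$dims[3L])]
      }
      list(x = x, lab = as.integer(rows$label))
    }
    tr <- read_split("train"); te <- read_split("test")
  }
  new_dataset(tr$x, tr$lab, te$x, te$lab, meta$n_classes, meta$modality,
              config = NULL)
}
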