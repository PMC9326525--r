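#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a split run into per-epoch, per-client metrics
#'
#' @param x A `split_run` from [run_training()] or [run_centralized()].
#' @param ... Unused.
#' @return A tibble: `epoch`, `client`, `train_loss`, `train_acc`,
#'   `test_acc`, plus mode/cut columns.
#' @method tidy split_run
#' @export
tidy.split_run <- function(x, ...) {
  dplyr::mutate(x$metrics,
                mode = x$config$mode,
                cut_layer = x$config$cut_layer %||% NA_integer_,
                .before = 1L)
}

#' One-row summary of a split run
#'
#' @param x A `split_run`.
#' @param ... Unused.
#' @return A one-row tibble: mode, K, cut layer, epochs, final mean test
#'   accuracy, best mean test accuracy, final train loss, total
#'   communication in elements, and the final leakage score.
#' @method glance split_run
#' @export
glance.split_run <- function(x, ...) {
  last <- x$epochs[nrow(x$epochs), ]
  tibble::tibble(
    mode = x$config$mode,
    K = x$config$K,
    cut_layer = x$config$cut_layer %||% NA_integer_,
    epochs = nrow(x$epochs),
    final_test_acc = last$mean_test_acc,
    best_test_acc = max(x$epochs$mean_test_acc),
    final_train_loss = last$mean_train_loss,
    comms_elements_total = sum(x$epochs$smashed_elements +
                                 x$epochs$sync_elements),
    final_mis = last$mis)
}

#' Plot accuracy trajectories of one or more runs
#'
#' @param object A `split_run`.
#' @param ... Further `split_run`s to overlay (named arguments become
#'   legend labels).
#' @return A ggplot of mean test accuracy against epoch.
#' @method autoplot split_run
#' @export
autoplot.split_run <- function(object, ...) {
  runs <- c(list(object), list(...))
  labels <- names(runs) %||% rep("", length(runs))
  df <- dplyr::bind_rows(lapply(seq_along(runs), function(i) {
    r <- runs[[i]]
    lab <- if (nzchar(labels[i] %||% "")) labels[i] else r$config$mode
    dplyr::mutate(r$epochs[, c("epoch", "mean_test_acc")], run = lab)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$mean_test_acc,
                                   colour = .data$run)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "global epoch", y = "mean test accuracy",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the leakage (mutual information) trace of runs
#'
#' @param ... Named `split_run`s (names become legend labels).
#' @return A ggplot of the per-epoch mean mutual information score.
#' @export
plot_mis_trace <- function(...) {
  runs <- list(...)
  labels <- names(runs) %||% paste0("run", seq_along(runs))
  df <- dplyr::bind_rows(lapply(seq_along(runs), function(i) {
    r <- runs[[i]]
    lab <- if (nzchar(labels[i] %||% "")) labels[i] else r$config$mode
    dplyr::mutate(r$epochs[, c("epoch", "mis")], run = lab)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$mis,
                                   colour = .data$run)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "global epoch",
                  y = "mutual information score (nats)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
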