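# broom-style accessors and ggplot2 autoplot methods for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted model: one row per parameter bank
#'
#' @param x An `ngnn_fit`.
#' @param ... Unused.
#' @return A tibble with bank name, parameter count and norm summaries.
#' @method tidy ngnn_fit
#' @export
tidy.ngnn_fit <- function(x, ...) {
  p <- unclass(x$params)
  rows <- lapply(names(p), function(nm) {
    v <- unlist(p[[nm]])
    tibble::tibble(bank = nm, n_parameters = length(v),
                   l2_norm = sqrt(sum(v^2)), mean = mean(v),
                   sd = stats::sd(v))
  })
  dplyr::bind_rows(rows)
}

#' One-row summary of a fit
#'
#' @param x An `ngnn_fit`.
#' @param ... Unused.
#' @return A one-row tibble: epochs run, best epoch, final train MAE/RMSE/R2,
#'   best validation MAE, parameter count and wall time.
#' @method glance ngnn_fit
#' @export
glance.ngnn_fit <- function(x, ...) {
  tibble::tibble(
    epochs_run = x$epochs_run,
    best_epoch = x$best_epoch,
    train_mae = x$metrics_train$mae,
    train_rmse = x$metrics_train$rmse,
    train_r2 = x$metrics_train$r2,
    val_mae = if (x$n_validation > 0) min(x$traces$val_mae, na.rm = TRUE)
              else NA_real_,
    n_parameters = ngnn_param_count(x$params),
    wall_seconds = x$wall_seconds
  )
}

#' Learning-curve plot of a fit
#'
#' Per-epoch train (and validation) MAE in original target units.
#'
#' @param object An `ngnn_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ngnn_fit
#' @export
autoplot.ngnn_fit <- function(object, ...) {
  tr <- object$traces
  long <- dplyr::bind_rows(
    dplyr::transmute(tr, epoch = .data$epoch, set = "train",
                     mae = .data$train_mae),
    dplyr::transmute(tr, epoch = .data$epoch, set = "validation",
                     mae = .data$val_mae)
  )
  long <- dplyr::filter(long, !is.na(.data$mae))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$mae,
                                     colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "MAE (target units)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Per-run metric plot for a multi-run experiment
#'
#' @param object An `ngnn_multirun`.
#' @param metric Metric column to plot (`"mae"`, `"rmse"`, `"mre"`, `"r2"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ngnn_multirun
#' @export
autoplot.ngnn_multirun <- function(object, metric = "mae", ...) {
  ggplot2::ggplot(object$runs,
                  ggplot2::aes(x = factor(.data$run), y = .data[[metric]],
                               fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "run", y = metric, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
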