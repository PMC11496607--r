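# Training loop: standardized-target MSE minimised by Adam over shuffled
# mini-batches of disjoint graph unions, with an optional validation
# carve-out for early stopping. Random streams for the carve-out, parameter
# initialization and batch shuffling are independent sub-streams of the run
# seed.

# flat-leaf views of the nested parameter tree (the optimizer loops over
# ~35 tensors instead of recursing through nested lists every step)
collect_leaves <- function(x) {
  if (is.list(x)) {
    do.call(c, lapply(x, collect_leaves))
  } else {
    list(x)
  }
}

rebuild_from_leaves <- function(skel, leaves, pos = 1L) {
  if (is.list(skel)) {
    for (i in seq_along(skel)) {
      res <- rebuild_from_leaves(skel[[i]], leaves, pos)
      skel[[i]] <- res$node
      pos <- res$pos
    }
    list(node = skel, pos = pos)
  } else {
    list(node = leaves[[pos]], pos = pos + 1L)
  }
}

adam_init <- function(params) {
  lv <- collect_leaves(unclass(params))
  list(m = lapply(lv, function(x) x * 0),
       v = lapply(lv, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  p_lv <- collect_leaves(unclass(params))
  g_lv <- collect_leaves(grads)
  for (i in seq_along(p_lv)) {
    g <- g_lv[[i]]
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g * g
    p_lv[[i]] <- p_lv[[i]] -
      lr * (state$m[[i]] / bc1) / (sqrt(state$v[[i]] / bc2) + eps)
  }
  new_params <- rebuild_from_leaves(unclass(params), p_lv)$node
  for (bk in attr(params, "frozen")) new_params[[bk]] <- params[[bk]]
  params_out <- structure(new_params,
                          config = attr(params, "config"),
                          n_custom_flags = attr(params, "n_custom_flags"),
                          frozen = attr(params, "frozen"),
                          class = "ngnn_parameters")
  list(params = params_out, state = state)
}

predict_samples <- function(params, samples, standardize = NULL,
                            batch_size = 256L) {
  out <- numeric(length(samples))
  idx <- split(seq_along(samples), ceiling(seq_along(samples) / batch_size))
  for (ii in idx) {
    out[ii] <- forward_batch(params, build_batch(samples[ii]))$y
  }
  if (!is.null(standardize)) out <- out * standardize$sd + standardize$mean
  out
}

#' Train the network on featurized samples
#'
#' Minimises mean-squared error on z-scored targets (metrics are always
#' reported in original units) with Adam. A fraction of the training data is
#' carved out for early stopping on validation MAE, so test data is never
#' touched during training. Fully reproducible from `seed` on a fixed
#' platform.
#'
#' @param samples List of `dissolved_sample`s (the training set).
#' @param config An [ngnn_config()].
#' @param epochs Maximum number of epochs.
#' @param lr Adam learning rate.
#' @param batch_size Mini-batch size (graphs per disjoint union).
#' @param validation_fraction Fraction of `samples` carved out for early
#'   stopping; `0` disables early stopping (train on everything for `epochs`).
#' @param patience Epochs without validation-MAE improvement before stopping.
#' @param seed Run seed (defaults to the config seed); governs the carve-out,
#'   initialization and batch shuffling through independent sub-streams.
#' @param standardize Z-score targets on the training split (default TRUE).
#' @param engine `"cpp"` (default) runs the compiled training kernels;
#'   `"r"` runs the reference R implementation (identical math, slower).
#' @param verbose Print per-epoch progress lines to stderr.
#' @return An object of class `ngnn_fit`: best parameters, per-epoch traces,
#'   final train (and validation) metrics with per-sample predictions, and
#'   the configuration/seed provenance.
#' @export
ngnn_train <- function(samples, config = ngnn_config(), epochs = 300L,
                       lr = 1e-3, batch_size = 64L,
                       validation_fraction = 0.1, patience = 30L,
                       seed = config$seed, standardize = TRUE,
                       engine = c("cpp", "r"), verbose = FALSE) {
  engine <- match.arg(engine)
  stopifnot(length(samples) >= 1)
  t0 <- proc.time()[["elapsed"]]
  config$seed <- as.integer(seed)
  n_flags <- ncol(samples[[1]]$solute$custom_flags)
  marking_rules <- samples[[1]]$solute$marking_rules

  # validation carve-out
  val <- list()
  if (validation_fraction > 0 && length(samples) >= 10) {
    n_val <- max(1L, round(validation_fraction * length(samples)))
    val_idx <- with_seed(sub_seed(seed, 3L),
                         sort(sample.int(length(samples), n_val)))
    val <- samples[val_idx]
    samples <- samples[-val_idx]
  }

  y_raw <- vapply(samples, function(s) s$target, numeric(1))
  std <- if (standardize) {
    s <- stats::sd(y_raw)
    list(mean = mean(y_raw), sd = if (is.finite(s) && s > 0) s else 1)
  } else {
    list(mean = 0, sd = 1)
  }

  params <- ngnn_init(config, n_flags)
  n <- length(samples)
  n_batches <- ceiling(n / batch_size)

  if (engine == "cpp") {
    # fixed batch partition (drawn once from the shuffle stream); batch order
    # is re-shuffled every epoch inside the compiled loop via a seeded plan
    ord0 <- with_seed(sub_seed(seed, 4L), sample.int(n))
    parts <- split(ord0, ceiling(seq_along(ord0) / batch_size))
    ccfg <- cpp_config(params)
    batches <- lapply(parts, function(ii) cpp_batch(build_batch(samples[ii])))
    batch_targets <- lapply(parts, function(ii) {
      (vapply(samples[ii], function(s) s$target, numeric(1)) - std$mean) /
        std$sd
    })
    val_batches <- list(); val_targets <- list(); val_y_raw <- numeric(0)
    if (length(val)) {
      vparts <- split(seq_along(val), ceiling(seq_along(val) / 256L))
      val_batches <- lapply(vparts, function(ii)
        cpp_batch(build_batch(val[ii])))
      val_targets <- lapply(vparts, function(ii) numeric(length(ii)))
      val_y_raw <- unlist(lapply(vparts, function(ii)
        vapply(val[ii], function(s) s$target, numeric(1))))
    }
    plan <- vapply(seq_len(epochs), function(ep) {
      with_seed(sub_seed(seed, 4L) + ep, sample.int(length(batches)))
    }, integer(length(batches)))
    plan <- matrix(plan, nrow = length(batches))
    flat <- as.numeric(flatten_params(params))
    m <- numeric(length(flat)); v <- numeric(length(flat))
    fmask <- frozen_mask(params)
    res <- cpp_train(flat, ccfg, unname(batches), unname(batch_targets),
                     unname(val_batches), unname(val_targets), plan,
                     m, v, fmask, lr, as.integer(patience), std$sd,
                     val_y_raw, std$mean)
    final_params <- unflatten_params(params, res$best_flat)
    epochs_run <- res$epochs_run
    traces <- tibble::tibble(
      epoch = seq_len(epochs_run),
      train_mae = res$traces[seq_len(epochs_run), 1],
      val_mae = res$traces[seq_len(epochs_run), 2],
      lr = lr
    )
    if (verbose) {
      message(sprintf("compiled training: %d epochs, best epoch %d",
                      epochs_run, res$best_epoch))
    }
    y_raw_all <- vapply(samples, function(s) s$target, numeric(1))
    train_pred <- predict_samples(final_params, samples, std)
    return(structure(
      list(
        params = final_params,
        config = config,
        standardize = std,
        marking_rules = marking_rules,
        traces = traces,
        seed = as.integer(seed),
        epochs_run = epochs_run,
        best_epoch = res$best_epoch,
        predictions_train = tibble::tibble(
          sample_id = vapply(samples, function(s) as.character(s$sample_id),
                             character(1)),
          target = y_raw_all,
          prediction = train_pred
        ),
        metrics_train = compute_metrics(train_pred, y_raw_all),
        n_validation = length(val),
        wall_seconds = proc.time()[["elapsed"]] - t0
      ),
      class = "ngnn_fit"
    ))
  }

  state <- adam_init(params)

  best <- list(params = params, val_mae = Inf, epoch = 0L)
  traces <- vector("list", epochs)
  wait <- 0L
  epochs_run <- 0L

  shuffle_seed <- sub_seed(seed, 4L)
  for (epoch in seq_len(epochs)) {
    ord <- with_seed(shuffle_seed + epoch, sample.int(n))
    abs_err_sum <- 0
    for (bi in seq_len(n_batches)) {
      take <- ord[((bi - 1L) * batch_size + 1L):min(bi * batch_size, n)]
      batch <- build_batch(samples[take])
      y_std <- (batch$y - std$mean) / std$sd
      lg <- loss_and_grads(params, batch, y = y_std)
      if (!is.finite(lg$loss)) {
        ngnn_abort(sprintf("training diverged (non-finite loss) at epoch %d",
                           epoch))
      }
      abs_err_sum <- abs_err_sum + sum(abs(lg$y_hat - y_std)) * std$sd
      stepped <- adam_step(params, lg$grads, state, lr)
      params <- stepped$params
      state <- stepped$state
    }
    # running train MAE over the epoch's mini-batch predictions
    train_mae <- abs_err_sum / n
    val_mae <- NA_real_
    if (length(val)) {
      val_pred <- predict_samples(params, val, std)
      val_mae <- mean(abs(val_pred -
                            vapply(val, function(s) s$target, numeric(1))))
    }
    traces[[epoch]] <- tibble::tibble(epoch = epoch, train_mae = train_mae,
                                      val_mae = val_mae, lr = lr)
    if (verbose) {
      message(sprintf("epoch %3d  train MAE %.5f  val MAE %s  lr %g",
                      epoch, train_mae,
                      ifelse(is.na(val_mae), "-", sprintf("%.5f", val_mae)),
                      lr))
    }
    epochs_run <- epoch
    if (length(val)) {
      if (val_mae < best$val_mae - 1e-12) {
        best <- list(params = params, val_mae = val_mae, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
  }
  if (!length(val)) best <- list(params = params, val_mae = NA_real_,
                                 epoch = epochs_run)

  final_params <- best$params
  train_pred <- predict_samples(final_params, samples, std)
  fit <- structure(
    list(
      params = final_params,
      config = config,
      standardize = std,
      marking_rules = marking_rules,
      traces = dplyr::bind_rows(traces[seq_len(epochs_run)]),
      seed = as.integer(seed),
      epochs_run = epochs_run,
      best_epoch = best$epoch,
      predictions_train = tibble::tibble(
        sample_id = vapply(samples, function(s) as.character(s$sample_id),
                           character(1)),
        target = y_raw,
        prediction = train_pred
      ),
      metrics_train = compute_metrics(train_pred, y_raw),
      n_validation = length(val),
      wall_seconds = proc.time()[["elapsed"]] - t0
    ),
    class = "ngnn_fit"
  )
  fit
}

#' @export
print.ngnn_fit <- function(x, ...) {
  cat(sprintf(
    "<ngnn_fit> %d epochs (best %d), %d params, train MAE %.4g%s [%.1fs]\n",
    x$epochs_run, x$best_epoch, ngnn_param_count(x$params),
    x$metrics_train$mae,
    if (x$n_validation > 0)
      sprintf(", val MAE %.4g (n=%d)",
              min(x$traces$val_mae, na.rm = TRUE), x$n_validation)
    else "",
    x$wall_seconds
  ))
  invisible(x)
}

#' Predict on new samples with a fitted model
#'
#' @param object An `ngnn_fit`.
#' @param samples List of `dissolved_sample`s featurized with the same
#'   marking rules as the training data.
#' @param ... Unused.
#' @return A tibble `sample_id`, `target`, `prediction` (original units).
#' @export
predict.ngnn_fit <- function(object, samples, ...) {
  stopifnot(length(samples) >= 1)
  pred <- predict_samples(object$params, samples, object$standardize)
  tibble::tibble(
    sample_id = vapply(samples, function(s) as.character(s$sample_id),
                       character(1)),
    target = vapply(samples, function(s) s$target, numeric(1)),
    prediction = pred
  )
}

#' Evaluate a fitted model on a sample set
#'
#' @param fit An `ngnn_fit`.
#' @param samples Nonempty list of `dissolved_sample`s.
#' @return List with `metrics` (one-row tibble) and `predictions`
#'   (per-sample tibble).
#' @export
ngnn_evaluate <- function(fit, samples) {
  if (!length(samples)) ngnn_abort("cannot evaluate on an empty sample set")
  preds <- stats::predict(fit, samples)
  list(metrics = compute_metrics(preds$prediction, preds$target),
       predictions = preds)
}

#' Multi-run training protocol
#'
#' Repeats split/train/evaluate with seeds `base_seed + 0 ... n_runs - 1`
#' (fresh 80/20 splits each run) and reports per-run and mean metrics,
#' mirroring the "independent runs" averaging convention.
#'
#' @param samples Full featurized dataset.
#' @param config An [ngnn_config()].
#' @param n_runs Number of independent runs.
#' @param base_seed First run seed.
#' @param train_fraction Train fraction per split.
#' @param stratify_by_solvent Stratify splits by solvent.
#' @param ... Passed to [ngnn_train()].
#' @return An `ngnn_multirun`: tibble `runs` (per run and set), tibble
#'   `summary` (mean metrics per set) and the list of fits.
#' @export
ngnn_multirun <- function(samples, config = ngnn_config(), n_runs = 3L,
                          base_seed = 1L, train_fraction = 0.8,
                          stratify_by_solvent = FALSE, ...) {
  stopifnot(n_runs >= 1)
  rows <- list()
  fits <- list()
  for (r in seq_len(n_runs)) {
    seed <- base_seed + r - 1L
    sp <- tryCatch(
      split_dataset(samples, train_fraction, seed = seed,
                    stratify_by_solvent = stratify_by_solvent),
      error = function(e) ngnn_abort(sprintf("run with seed %d failed: %s",
                                             seed, conditionMessage(e)))
    )
    fit <- tryCatch(
      ngnn_train(sp$train, config, seed = seed, ...),
      error = function(e) ngnn_abort(sprintf("run with seed %d failed: %s",
                                             seed, conditionMessage(e)))
    )
    fits[[r]] <- fit
    for (set in c("train", "test")) {
      ev <- ngnn_evaluate(fit, sp[[set]])
      rows[[length(rows) + 1]] <- dplyr::mutate(
        ev$metrics, run = r, seed = seed, set = set, .before = 1
      )
    }
  }
  runs <- dplyr::bind_rows(rows)
  summary <- runs |>
    dplyr::group_by(.data$set) |>
    dplyr::summarise(dplyr::across(c("mae", "rmse", "mre", "r2"),
                                   ~ mean(.x)),
                     n_runs = dplyr::n(), .groups = "drop")
  structure(list(runs = runs, summary = summary, fits = fits),
            class = "ngnn_multirun")
}

#' @export
print.ngnn_multirun <- function(x, ...) {
  cat(sprintf("<ngnn_multirun> %d runs\n", length(x$fits)))
  print(x$summary)
  invisible(x)
}
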