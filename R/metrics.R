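#' Regression metrics: MAE, RMSE, MRE, R-squared
#'
#' `mae = mean|y - yhat|`, `rmse = sqrt(mean (y - yhat)^2)`,
#' `mre = mean(|y - yhat| / |y|)` (reported as `NA` if any target is zero),
#' `r2 = 1 - SS_res / SS_tot` with `SS_tot` about the target mean (`NA` for
#' zero-variance targets).
#'
#' @param predictions Numeric vector of predictions.
#' @param targets Numeric vector of observed values, same length.
#' @return A one-row tibble with columns `mae`, `rmse`, `mre`, `r2`, `n`.
#' @export
compute_metrics <- function(predictions, targets) {
  if (length(predictions) != length(targets) || length(targets) == 0) {
    ngnn_abort("predictions and targets must have equal nonzero length")
  }
  assert_finite(predictions, "predictions")
  assert_finite(targets, "targets")
  err <- predictions - targets
  mre <- if (any(targets == 0)) NA_real_ else mean(abs(err) / abs(targets))
  ss_tot <- sum((targets - mean(targets))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - sum(err^2) / ss_tot
  tibble::tibble(
    mae = mean(abs(err)),
    rmse = sqrt(mean(err^2)),
    mre = mre,
    r2 = r2,
    n = length(targets)
  )
}

#' Split samples into train and test sets
#'
#' Draws `round(train_fraction * n)` samples into the training set,
#' deterministically for a fixed seed. With `stratify_by_solvent`, the split
#' is performed within each solvent stratum (per-stratum rounding), so every
#' solvent keeps its 80/20 proportion.
#'
#' @param samples List of `dissolved_sample`s (or a dataset tibble with a
#'   `solvent` column; any list whose elements carry `$solvent_name` works).
#' @param train_fraction Fraction of data used for training.
#' @param seed Integer seed.
#' @param stratify_by_solvent Split within each solvent stratum.
#' @return List with elements `train` and `test` (same type as the input
#'   collection), and attribute `train_idx`.
#' @export
split_dataset <- function(samples, train_fraction = 0.8, seed = 1L,
                          stratify_by_solvent = FALSE) {
  is_df <- is.data.frame(samples)
  n <- if (is_df) nrow(samples) else length(samples)
  if (n < 5) ngnn_abort("need at least 5 samples to split")
  if (train_fraction <= 0 || train_fraction >= 1) {
    ngnn_abort("train_fraction must be in (0, 1)")
  }
  solvent_of <- function() {
    if (is_df) samples$solvent
    else vapply(samples, function(s) s$solvent_name, character(1))
  }
  train_idx <- with_seed(sub_seed(seed, 1L), {
    if (stratify_by_solvent) {
      sv <- solvent_of()
      idx <- integer(0)
      for (s in sort(unique(sv))) {
        members <- which(sv == s)
        if (length(members) < 2) {
          ngnn_abort(sprintf(
            "solvent stratum '%s' has fewer than 2 samples", s))
        }
        k <- round(train_fraction * length(members))
        idx <- c(idx, sample(members, k))
      }
      sort(idx)
    } else {
      sort(sample.int(n, round(train_fraction * n)))
    }
  })
  out <- if (is_df) {
    list(train = samples[train_idx, , drop = FALSE],
         test = samples[-train_idx, , drop = FALSE])
  } else {
    list(train = samples[train_idx], test = samples[-train_idx])
  }
  attr(out, "train_idx") <- train_idx
  out
}
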