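# Smoothed Dice coefficient/loss, the additive class-weight penalty, and
# the segmentation evaluation metrics (Dice, F1, Precision, Recall) with
# per-fold aggregation.

#' Loss configuration
#'
#' @param kappa Dice smoothing coefficient (> 0); with `kappa = 1` the Dice
#'   of two empty masks is 1 and the loss is finite everywhere.
#' @param alpha Offset of the logarithmic class-weight penalty, see
#'   [compute_class_weights()].
#' @param use_weight_penalty Add the class-weight penalty to each sample's
#'   loss (an additive constant per sample).
#' @return A `loss_config` list.
#' @export
loss_config <- function(kappa = 1, alpha = 1.1, use_weight_penalty = TRUE) {
  if (!is.numeric(kappa) || kappa <= 0) stop("kappa must be > 0")
  structure(list(kappa = kappa, alpha = alpha,
                 use_weight_penalty = isTRUE(use_weight_penalty)),
            class = "loss_config")
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)) ||
      (is.null(dim(a)) && length(a) != length(b))) {
    stop(sprintf("shape mismatch: %s vs %s",
                 paste(if (is.null(dim(a))) length(a) else dim(a),
                       collapse = "x"),
                 paste(if (is.null(dim(b))) length(b) else dim(b),
                       collapse = "x")))
  }
}

#' Smoothed Dice coefficient
#'
#' `DC = (kappa + 2*sum(t*p)) / (kappa + sum(t*t) + sum(p*p))` with the
#' squared-sum denominator; for binary masks this coincides with the count
#' form, and as `kappa -> 0` it converges to the classical
#' `2|A∩B| / (|A| + |B|)`.
#'
#' @param y_true,y_pred Same-shaped arrays with values in `[0, 1]` (soft
#'   predictions allowed).
#' @param kappa Smoothing coefficient (> 0).
#' @return A value in `(0, 1]`; 1 for identical masks (including two empty
#'   ones).
#' @export
dice_coefficient <- function(y_true, y_pred, kappa = 1) {
  check_same_shape(y_true, y_pred)
  if (kappa <= 0) stop("kappa must be > 0")
  (kappa + 2 * sum(y_true * y_pred)) /
    (kappa + sum(y_true * y_true) + sum(y_pred * y_pred))
}

#' Dice loss
#'
#' The complement `1 - DC` of [dice_coefficient()].
#'
#' @inheritParams dice_coefficient
#' @return A value in `[0, 1)`.
#' @export
dice_loss <- function(y_true, y_pred, kappa = 1) {
  1 - dice_coefficient(y_true, y_pred, kappa)
}

#' Class-weighted Dice loss
#'
#' Adds the sample's class-weight penalty to the Dice loss:
#' `DCLW = DCL + W`. Because `W` is constant for the sample, the gradient
#' with respect to the prediction equals that of the unweighted loss.
#'
#' @inheritParams dice_coefficient
#' @param W Penalty of the sample's class, from [compute_class_weights()].
#' @return `dice_loss(y_true, y_pred, kappa) + W`.
#' @export
weighted_dice_loss <- function(y_true, y_pred, kappa = 1, W = 0) {
  dice_loss(y_true, y_pred, kappa) + W
}

#' Confusion-matrix segmentation metrics
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, their harmonic mean F1, and
#' the smoothed Dice (`kappa = 1`) of the two binary masks. Undefined
#' ratios (zero denominators) yield 0 with a warning so batch evaluation
#' never aborts.
#'
#' @param y_true,y_pred_binary Same-shaped binary arrays.
#' @return A `metrics_report` list: `dice`, `f1`, `precision`, `recall`,
#'   `n_samples`.
#' @export
confusion_metrics <- function(y_true, y_pred_binary) {
  check_same_shape(y_true, y_pred_binary)
  if (!all(y_true %in% c(0, 1)) || !all(y_pred_binary %in% c(0, 1))) {
    stop("confusion_metrics requires binary masks")
  }
  tp <- sum(y_true == 1 & y_pred_binary == 1)
  fp <- sum(y_true == 0 & y_pred_binary == 1)
  fn <- sum(y_true == 1 & y_pred_binary == 0)
  safe_ratio <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator); returning 0", what))
      0
    } else {
      num / den
    }
  }
  precision <- safe_ratio(tp, tp + fp, "precision")
  recall <- safe_ratio(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  structure(
    list(dice = dice_coefficient(y_true, y_pred_binary, kappa = 1),
         f1 = f1, precision = precision, recall = recall, n_samples = 1L),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics: dice %.3f, f1 %.3f, precision %.3f, recall %.3f (n = %d)>\n",
    x$dice, x$f1, x$precision, x$recall, x$n_samples))
  invisible(x)
}

#' Aggregate per-fold metrics as mean +/- sd
#'
#' Cross-validation summary on the percent scale, one decimal, using the
#' sample standard deviation.
#'
#' @param per_fold List of `metrics_report` objects (>= 2 folds).
#' @return Data frame with columns `metric`, `mean`, `sd`, `formatted`
#'   (e.g. `"90.0 ± 0.0"`).
#' @export
aggregate_folds <- function(per_fold) {
  if (length(per_fold) < 2L) {
    stop("fold aggregation needs at least 2 folds")
  }
  metrics <- c("dice", "f1", "precision", "recall")
  rows <- lapply(metrics, function(m) {
    v <- vapply(per_fold, function(r) r[[m]], numeric(1))
    data.frame(metric = m, mean = mean(v) * 100, sd = stats::sd(v) * 100)
  })
  out <- do.call(rbind, rows)
  out$formatted <- sprintf("%.1f ± %.1f", out$mean, out$sd)
  out
}
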