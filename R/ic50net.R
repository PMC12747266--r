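# User-facing modelling interface: ic50net() fits the hybrid model on a
# cleaned activity table and returns a classed object with the usual
# methods (print, summary, coef, predict, plot, fitted, residuals).

#' Fit the hybrid graph-attention + descriptor IC50 model
#'
#' Takes a cleaned activity table (one row per unique compound-target pair,
#' log10 IC50 in nM as the response), featurizes it (molecular graphs over
#' the element-hybridization vocabulary plus 544-dimensional descriptor
#' vectors z-scored on the training data), optionally oversamples so every
#' target contributes equally, and trains the two-branch network with
#' smooth-L1 loss and Adam.
#'
#' @param data training samples: a `clean_dataset` from [clean_activities()]
#'   or a data.frame with columns `canonical_smiles`, `target_id`,
#'   `log_ic50`.
#' @param test optional held-out samples of the same shape, used for
#'   per-epoch curve logging and the stored test metrics (never for model
#'   selection).
#' @param config a [model_config()].
#' @param control a [train_control()].
#' @param vocab an `atom_vocab`.
#' @param init_seed seed for parameter initialization (training randomness
#'   is driven by `control$seed`).
#' @return an object of class `ic50net`: the trained model, vocabulary,
#'   descriptor normalizer (fitted on the un-oversampled training data),
#'   per-epoch history, final train/test metrics (overall and per target),
#'   and training predictions.
#' @seealso [predict.ic50net()], [evaluate_predictions()]
#' @export
ic50net <- function(data, test = NULL, config = model_config(),
                    control = train_control(), vocab = build_atom_vocab(),
                    init_seed = 1L) {
  samples <- if (inherits(data, "clean_dataset")) data$samples else data
  stopifnot(is.data.frame(samples),
            all(c("canonical_smiles", "target_id", "log_ic50") %in% names(samples)))
  if (nrow(samples) < 2L) stopf("need at least 2 training samples")
  cl <- match.call()

  feats_train <- featurize_dataset(samples, vocab)
  normalizer <- fit_normalizer(feats_train$desc)
  feats_train$desc <- apply_normalizer(normalizer, feats_train$desc)
  feats_train$normalizer <- normalizer

  fit_feats <- feats_train
  if (control$oversample && length(unique(samples$target_id)) > 1L) {
    os <- oversample_by_target(samples, seed = control$seed)
    key <- paste(samples$canonical_smiles, samples$target_id)
    fit_feats <- feats_subset(feats_train, match(paste(os$canonical_smiles, os$target_id), key))
  }

  feats_test <- NULL
  test_samples <- if (inherits(test, "clean_dataset")) test$samples else test
  if (!is.null(test_samples) && nrow(test_samples)) {
    feats_test <- featurize_dataset(test_samples, vocab, normalizer = normalizer)
  }

  model <- init_ic50net(config, vocab, seed = init_seed)
  tr <- train_ic50net(model, fit_feats, feats_test, control)

  train_pred <- model_predict_feats(tr$model, feats_train)
  train_metrics <- evaluate_predictions(train_pred, feats_train$y, feats_train$target)
  test_pred <- NULL
  test_metrics <- NULL
  if (!is.null(feats_test)) {
    test_pred <- model_predict_feats(tr$model, feats_test)
    test_metrics <- evaluate_predictions(test_pred, feats_test$y, feats_test$target)
  }

  structure(
    list(model = tr$model, vocab = vocab, normalizer = normalizer,
         config = config, control = control, history = tr$history,
         train_data = samples, train_pred = train_pred,
         train_metrics = train_metrics,
         test_data = test_samples, test_pred = test_pred,
         test_metrics = test_metrics,
         call = cl),
    class = "ic50net"
  )
}

#' Predict log10 IC50 for new molecules
#'
#' SMILES inputs are canonicalized, featurized with the fitted vocabulary,
#' standardized with the training normalizer, and pushed through the network
#' in eval mode (deterministic).
#'
#' @param object a fitted `ic50net`.
#' @param newdata character vector of SMILES, or a data.frame with a
#'   `canonical_smiles` (or `smiles`) column.
#' @param attention also return per-edge attention weights per layer/head.
#' @param ... unused.
#' @return numeric vector of predicted log10 IC50 (nM); with
#'   `attention = TRUE`, a list with `pred` and `attention`.
#' @export
predict.ic50net <- function(object, newdata, attention = FALSE, ...) {
  if (is.data.frame(newdata)) {
    col <- intersect(c("canonical_smiles", "smiles"), names(newdata))[1]
    if (is.na(col)) stopf("newdata needs a canonical_smiles or smiles column")
    newdata <- newdata[[col]]
  }
  stopifnot(is.character(newdata))
  canon <- canonicalize_smiles(newdata)
  feats <- featurize_dataset(canon, object$vocab, normalizer = object$normalizer)
  out <- model_predict_feats(object$model, feats, collect_attention = attention)
  if (attention) out else unname(out)
}

#' @export
print.ic50net <- function(x, ...) {
  cat("Hybrid graph-attention + descriptor IC50 model\n")
  cat(sprintf("  training samples: %d (%d targets)\n",
              nrow(x$train_data), length(unique(x$train_data$target_id))))
  cat(sprintf("  epochs: %d, batch size: %d, final train loss: %.4f\n",
              nrow(x$history), x$control$batch_size,
              x$history$train_loss[nrow(x$history)]))
  tm <- x$train_metrics[x$train_metrics$group == "overall", ]
  cat(sprintf("  train:  R2 = %.3f, RMSE = %.3f, MAE = %.3f (log10 nM)\n",
              tm$r2, tm$rmse, tm$mae))
  if (!is.null(x$test_metrics)) {
    te <- x$test_metrics[x$test_metrics$group == "overall", ]
    cat(sprintf("  test:   R2 = %.3f, RMSE = %.3f, MAE = %.3f (log10 nM)\n",
                te$r2, te$rmse, te$mae))
  }
  invisible(x)
}

#' @export
summary.ic50net <- function(object, ...) {
  structure(list(train = object$train_metrics, test = object$test_metrics,
                 history = object$history, call = object$call),
            class = "summary.ic50net")
}

#' @export
print.summary.ic50net <- function(x, ...) {
  cat("Call: "); print(x$call)
  cat("\nTraining metrics (log10 IC50, nM):\n")
  print(x$train, row.names = FALSE, digits = 3)
  if (!is.null(x$test)) {
    cat("\nTest metrics:\n")
    print(x$test, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' @export
coef.ic50net <- function(object, ...) {
  object$model$params
}

#' @export
fitted.ic50net <- function(object, ...) {
  object$train_pred
}

#' @export
residuals.ic50net <- function(object, ...) {
  object$train_data$log_ic50 - object$train_pred
}

#' Training-curve and fit plots
#'
#' `which = "history"` draws loss / R2 / RMSE against epoch for training and
#' test sets; `which = "fit"` draws predicted vs observed log10 IC50.
#'
#' @param x a fitted `ic50net`.
#' @param which `"history"` or `"fit"`.
#' @param ... passed to the underlying plotting calls.
#' @return invisibly, `x`.
#' @export
plot.ic50net <- function(x, which = c("history", "fit"), ...) {
  which <- match.arg(which)
  h <- x$history
  if (which == "history") {
    old <- graphics::par(mfrow = c(1, 3))
    on.exit(graphics::par(old))
    has_test <- any(is.finite(h$test_loss))
    graphics::plot(h$epoch, h$train_loss, type = "l", col = "steelblue",
                   xlab = "epoch", ylab = "smooth-L1 loss", main = "Loss", ...)
    if (has_test) graphics::lines(h$epoch, h$test_loss, col = "firebrick")
    ok <- is.finite(h$train_r2)
    graphics::plot(h$epoch[ok], h$train_r2[ok], type = "l", col = "steelblue",
                   xlab = "epoch", ylab = expression(R^2), main = "R2", ...)
    if (has_test) graphics::lines(h$epoch[ok], h$test_r2[ok], col = "firebrick")
    graphics::plot(h$epoch[ok], h$train_rmse[ok], type = "l", col = "steelblue",
                   xlab = "epoch", ylab = "RMSE", main = "RMSE", ...)
    if (has_test) graphics::lines(h$epoch[ok], h$test_rmse[ok], col = "firebrick")
  } else {
    truth <- x$train_data$log_ic50
    graphics::plot(truth, x$train_pred, xlab = "observed log10 IC50 (nM)",
                   ylab = "predicted log10 IC50 (nM)",
                   main = "Training fit", col = "steelblue", ...)
    if (!is.null(x$test_pred)) {
      graphics::points(x$test_data$log_ic50, x$test_pred, col = "firebrick")
    }
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}

#' Save / load a fitted model bundle
#'
#' The checkpoint bundles parameters, batch-norm state, configuration,
#' vocabulary and normalizer, so a reloaded model predicts from bare SMILES.
#'
#' @param object a fitted `ic50net`.
#' @param path file path (`.rds`).
#' @return `save_ic50net` invisibly returns `path`; `load_ic50net` the
#'   restored object.
#' @export
save_ic50net <- function(object, path) {
  stopifnot(inherits(object, "ic50net"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_ic50net
#' @export
load_ic50net <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "ic50net")) stopf("%s is not an ic50net checkpoint", path)
  obj
}
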