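# Training (smooth-L1 + Adam, seeded mini-batches) and the three-metric
# evaluation (R2 / RMSE / MAE), overall and per target.

#' Training hyperparameters
#'
#' Defaults reproduce the published procedure: smooth-L1 loss (transition
#' `beta = 1`), Adam with learning rate 1e-3 and L2 weight decay 1e-5,
#' batch size 32, 300 epochs, per-target oversampling of the training set
#' drawn once before training. No early stopping and no learning-rate
#' schedule; headline metrics are final-epoch metrics.
#'
#' @param learning_rate Adam step size.
#' @param weight_decay L2 penalty added to every gradient.
#' @param batch_size mini-batch size.
#' @param epochs number of passes over the (oversampled) training set.
#' @param beta smooth-L1 transition point, in log10 IC50 units.
#' @param oversample balance per-target counts before training.
#' @param init_output_bias start the output-layer bias at the training-label
#'   mean so optimization spends no steps locating the response intercept
#'   (log10 IC50 sits far from zero on the nM scale).
#' @param bn_refresh after training, recompute batch-normalization running
#'   statistics in one pass over the training set (dropout off), so
#'   eval-mode predictions use full-sample statistics instead of an
#'   exponential average lagging behind the last mini-batches.
#' @param eval_every record train/test metrics every this many epochs
#'   (loss is recorded every epoch regardless).
#' @param seed seed driving shuffling, dropout and oversampling.
#' @param verbose print a progress line every 10 epochs.
#' @return a `train_control` list.
#' @export
train_control <- function(learning_rate = 1e-3, weight_decay = 1e-5,
                          batch_size = 32L, epochs = 300L, beta = 1,
                          oversample = TRUE, init_output_bias = TRUE,
                          bn_refresh = TRUE, eval_every = 1L,
                          seed = 42L, verbose = FALSE) {
  stopifnot(learning_rate > 0 || learning_rate == 0, weight_decay >= 0,
            batch_size >= 2, epochs >= 1, beta > 0)
  structure(
    list(learning_rate = learning_rate, weight_decay = weight_decay,
         batch_size = as.integer(batch_size), epochs = as.integer(epochs),
         beta = beta, oversample = oversample,
         init_output_bias = init_output_bias, bn_refresh = bn_refresh,
         eval_every = as.integer(eval_every), seed = as.integer(seed),
         verbose = verbose),
    class = "train_control"
  )
}

batch_indices <- function(n, batch_size) {
  starts <- seq(1L, n, by = batch_size)
  out <- lapply(starts, function(s) s:min(s + batch_size - 1L, n))
  # a singleton batch breaks batch-norm statistics: fold it into the
  # previous batch
  k <- length(out)
  if (k > 1L && length(out[[k]]) == 1L) {
    out[[k - 1L]] <- c(out[[k - 1L]], out[[k]])
    out[[k]] <- NULL
  }
  out
}

#' Train a hybrid model on featurized data
#'
#' Seeded mini-batched optimization of the smooth-L1 loss on log10 IC50.
#' The per-epoch history records training loss and, at `eval_every`
#' intervals, eval-mode loss, R2 and RMSE on the training and test sets
#' (test evaluation is logging only; no model selection uses it).
#'
#' @param model an `ic50net_model` from [init_ic50net()].
#' @param train_feats a `mol_features` object with labels (`y` finite) and
#'   normalized descriptors.
#' @param test_feats optional held-out `mol_features` for curve logging.
#' @param control a [train_control()]. Oversampling is not applied here:
#'   pass an already-oversampled `train_feats` (see [ic50net()]).
#' @return list with `model` (trained), `history` (data.frame: epoch,
#'   train_loss, train_r2, train_rmse, test_loss, test_r2, test_rmse).
#' @export
train_ic50net <- function(model, train_feats, test_feats = NULL,
                          control = train_control()) {
  stopifnot(inherits(model, "ic50net_model"), inherits(train_feats, "mol_features"))
  n <- feats_n(train_feats)
  if (n == 0L) stopf("empty training set")
  if (any(!is.finite(train_feats$y))) stopf("training labels must be finite")

  if (isTRUE(control$init_output_bias)) {
    model$params$head.b2 <- mean(train_feats$y)
  }
  opt <- adam_init(model$params)
  hist_rows <- vector("list", control$epochs)

  with_seed(control$seed, {
    for (epoch in seq_len(control$epochs)) {
      perm <- sample.int(n)
      batches <- batch_indices(n, control$batch_size)
      epoch_loss <- 0
      for (bi in batches) {
        idx <- perm[bi]
        batch <- make_batch(train_feats, idx)
        fw <- net_forward(model, batch, training = TRUE)
        model$state <- fw$state
        losses <- smooth_l1(fw$pred, batch$y, control$beta)
        loss <- mean(losses)
        if (!is.finite(loss)) {
          stopf("non-finite training loss at epoch %d (predictions range %s)",
                epoch, paste(range(fw$pred), collapse = " .. "))
        }
        epoch_loss <- epoch_loss + loss * length(idx)
        dpred <- smooth_l1_grad(fw$pred, batch$y, control$beta) / length(idx)
        grads <- net_backward(model, batch, fw$cache, dpred)
        st <- adam_step(model$params, grads, opt,
                        lr = control$learning_rate,
                        weight_decay = control$weight_decay)
        model$params <- st$params
        opt <- st$opt
      }
      row <- data.frame(epoch = epoch, train_loss = epoch_loss / n,
                        train_r2 = NA_real_, train_rmse = NA_real_,
                        test_loss = NA_real_, test_r2 = NA_real_,
                        test_rmse = NA_real_)
      if (epoch %% control$eval_every == 0L || epoch == control$epochs) {
        ptr <- model_predict_feats(model, train_feats)
        row$train_loss_eval <- mean(smooth_l1(ptr, train_feats$y, control$beta))
        m <- metrics_one(ptr, train_feats$y)
        row$train_r2 <- m["r2"]; row$train_rmse <- m["rmse"]
        if (!is.null(test_feats)) {
          pte <- model_predict_feats(model, test_feats)
          row$test_loss <- mean(smooth_l1(pte, test_feats$y, control$beta))
          m <- metrics_one(pte, test_feats$y)
          row$test_r2 <- m["r2"]; row$test_rmse <- m["rmse"]
        }
      }
      hist_rows[[epoch]] <- row
      if (control$verbose && (epoch %% 10L == 0L || epoch == 1L)) {
        message(sprintf("epoch %4d  train loss %.4f  train R2 %.3f  test R2 %.3f",
                        epoch, row$train_loss, row$train_r2,
                        row$test_r2 %||% NA))
      }
    }
  })
  if (isTRUE(control$bn_refresh)) {
    model <- refresh_bn_stats(model, train_feats)
  }
  history <- do.call(rbind, lapply(hist_rows, function(r) {
    r$train_loss_eval <- r$train_loss_eval %||% NA_real_
    r
  }))
  list(model = model, history = history)
}

metrics_one <- function(pred, truth) {
  ss_res <- sum((truth - pred)^2)
  ss_tot <- sum((truth - mean(truth))^2)
  c(r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    rmse = sqrt(mean((truth - pred)^2)),
    mae = mean(abs(truth - pred)))
}

#' R2 / RMSE / MAE, overall and per target group
#'
#' R2 is `1 - SS_res / SS_tot` with `SS_tot` taken about the truth mean of
#' the evaluated group (per-target R2 is self-referential). Groups with
#' fewer than 2 samples are skipped; a group with zero truth variance gets
#' an undefined R2 (`NA`, `r2_defined = FALSE`) rather than a number.
#'
#' @param pred,truth numeric vectors of equal length (log10 IC50).
#' @param groups optional character vector of target ids; per-group rows are
#'   emitted in addition to `"overall"`.
#' @return data.frame with columns `group`, `n`, `r2`, `rmse`, `mae`,
#'   `r2_defined`.
#' @examples
#' evaluate_predictions(c(1, 2, 4), c(1, 2, 3))  # R2 0.5, MAE 1/3
#' @export
evaluate_predictions <- function(pred, truth, groups = NULL) {
  stopifnot(length(pred) == length(truth))
  if (length(pred) < 2L) stopf("need at least 2 samples to evaluate")
  one <- function(p, t, label) {
    m <- metrics_one(p, t)
    data.frame(group = label, n = length(p), r2 = unname(m["r2"]),
               rmse = unname(m["rmse"]), mae = unname(m["mae"]),
               r2_defined = is.finite(m["r2"]), stringsAsFactors = FALSE)
  }
  out <- one(pred, truth, "overall")
  if (!is.null(groups)) {
    stopifnot(length(groups) == length(pred))
    for (g in sort(unique(groups))) {
      ii <- which(groups == g)
      if (length(ii) >= 2L) out <- rbind(out, one(pred[ii], truth[ii], g))
    }
  }
  rownames(out) <- NULL
  out
}
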