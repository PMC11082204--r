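#' Training configuration
#'
#' Defaults follow the published recipe: Adam with learning rate 5e-6,
#' weight decay 1e-6, batch size 16, 100 epochs, 3 routing iterations.
#' Training shuffles batches per epoch under the configuration seed, tracks
#' validation OA/AA per epoch and retains the weights of the best
#' validation-OA epoch. Gradients are accumulated over `microbatch`-sample
#' slices of each batch to bound activation memory.
#'
#' @param learning_rate Adam step size.
#' @param weight_decay L2 penalty added to gradients.
#' @param batch_size samples per optimizer step.
#' @param epochs training epochs (>= 1).
#' @param routing_iters dynamic-routing iterations (recorded for the model).
#' @param seed integer seed for shuffling.
#' @param microbatch gradient-accumulation slice size.
#' @param shuffle reshuffle the training set each epoch.
#' @param stop_at_val_oa optional early-stop target: stop once validation
#'   OA reaches this value.
#' @param verbose print per-epoch progress.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 5e-6, weight_decay = 1e-6,
                         batch_size = 16, epochs = 100, routing_iters = 3,
                         seed = 1L, microbatch = 2, shuffle = TRUE,
                         stop_at_val_oa = NULL, verbose = FALSE) {
  if (learning_rate <= 0) stopf("learning_rate must be positive")
  if (weight_decay < 0) stopf("weight_decay must be nonnegative")
  if (!is_count(batch_size) || !is_count(epochs) || !is_count(microbatch))
    stopf("batch_size, epochs and microbatch must be positive integers")
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 routing_iters = as.integer(routing_iters),
                 seed = as.integer(seed), microbatch = as.integer(microbatch),
                 shuffle = isTRUE(shuffle), stop_at_val_oa = stop_at_val_oa,
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Fit a model
#'
#' @param object a model object.
#' @param ... passed to methods.
#' @export
fit <- function(object, ...) UseMethod("fit")

#' Train a network on a patch set
#'
#' Minimizes the margin loss (capsule heads) or cross-entropy (affine
#' heads) with Adam. When a validation set is given, OA and AA are computed
#' after every epoch and the weights with the best validation OA are
#' restored at the end.
#'
#' @param object a `dbsa_net`.
#' @param train training `patch_set` (or list with `data` and `label`).
#' @param val optional validation `patch_set`.
#' @param config a [train_config()].
#' @param ... unused.
#' @return The trained `dbsa_net`, with a `history` data frame (epoch,
#'   mean training loss, validation OA/AA) of class `dbsa_history`.
#' @export
fit.dbsa_net <- function(object, train, val = NULL, config = train_config(),
                         ...) {
  x <- as_input_array(object, train)
  y <- as.integer(factor(train$label, levels = object$classes)) - 1L
  n <- length(y)
  if (n == 0) stopf("training set is empty")
  if (anyNA(y)) stopf("training labels outside the model's classes")
  has_val <- !is.null(val) && length(val$label) > 0
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_oa = numeric(0), val_aa = numeric(0))
  best_oa <- -Inf; best_params <- NULL; best_buffers <- NULL
  for (epoch in seq_len(config$epochs)) {
    ord <- if (config$shuffle)
      with_seed(sub_seed(config$seed, epoch), sample.int(n)) else seq_len(n)
    losses <- numeric(0)
    for (i0 in seq(1, n, by = config$batch_size)) {
      idx <- ord[i0:min(n, i0 + config$batch_size - 1L)]
      l <- tryCatch(
        net_train_batch(object$ptr, x[, , , idx, drop = FALSE], y[idx],
                        config$learning_rate, config$weight_decay,
                        config$microbatch),
        error = function(e) stopf("epoch %d: %s", epoch, conditionMessage(e)))
      losses <- c(losses, l)
    }
    val_oa <- NA_real_; val_aa <- NA_real_
    if (has_val) {
      rep <- evaluate(object, val, microbatch = config$microbatch)
      val_oa <- rep$oa; val_aa <- rep$aa
      if (val_oa > best_oa) {
        best_oa <- val_oa
        best_params <- net_get_params(object$ptr)
        best_buffers <- net_get_buffers(object$ptr)
      }
    }
    history[epoch, ] <- list(epoch, mean(losses), val_oa, val_aa)
    if (config$verbose)
      message(sprintf("epoch %3d  loss %.5f  val OA %s", epoch,
                      mean(losses),
                      if (has_val) sprintf("%.4f", val_oa) else "-"))
    if (has_val && !is.null(config$stop_at_val_oa) &&
          val_oa >= config$stop_at_val_oa) break
  }
  if (!is.null(best_params)) {
    net_set_params(object$ptr, best_params)
    net_set_buffers(object$ptr, best_buffers)
  }
  object$trained <- TRUE
  class(history) <- c("dbsa_history", class(history))
  object$history <- history
  object
}

#' @rdname fit.dbsa_net
#' @export
dbsa_train <- function(object, train, val = NULL, config = train_config(),
                       ...) fit.dbsa_net(object, train, val, config, ...)

#' @export
plot.dbsa_history <- function(x, ...) {
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(x$epoch, x$loss, type = "l", xlab = "epoch", ylab = "training loss",
       main = "loss", ...)
  if (any(is.finite(x$val_oa))) {
    plot(x$epoch, x$val_oa, type = "l", ylim = c(0, 1), xlab = "epoch",
         ylab = "validation accuracy", main = "validation OA/AA")
    lines(x$epoch, x$val_aa, lty = 2)
    legend("bottomright", legend = c("OA", "AA"), lty = 1:2, bty = "n")
  }
  invisible(x)
}

#' Evaluate a model on a patch set
#'
#' Deterministic evaluation-mode predictions; the confusion matrix is built
#' from argmax predictions and summarized by [metrics_report()].
#'
#' @param model a `dbsa_net`.
#' @param data a `patch_set`.
#' @param microbatch forward-pass slice size.
#' @return A `metrics_report`.
#' @export
evaluate <- function(model, data, microbatch = 4) {
  if (length(data$label) == 0) stopf("evaluation set is empty")
  pred <- predict(model, data, type = "class", microbatch = microbatch)
  metrics_report(confusion_matrix(data$label, pred, model$classes))
}

#' Ablation study over network variants
#'
#' Builds, trains and evaluates each requested variant under one shared
#' configuration and reports one row per variant: parameter count, OA, AA,
#' per-class recalls and macro F1. A variant that fails to build or train
#' is marked failed and the run continues.
#'
#' @param variants character vector of [variant_names()].
#' @param train,val,test patch sets.
#' @param config a [train_config()].
#' @param input_size,bands model geometry (defaults from the data).
#' @param out_dir optional directory for `ablation.csv` / `ablation.json`.
#' @return Data frame with one row per variant; the full
#'   `metrics_report`s are attached as attribute `"reports"`.
#' @export
run_ablation <- function(variants, train, val, test, config = train_config(),
                         input_size = dim(train$data)[2],
                         bands = dim(train$data)[1], out_dir = NULL) {
  bad <- setdiff(variants, variant_names())
  if (length(bad)) stopf("unknown variants: %s", paste(bad, collapse = ", "))
  rows <- list(); reports <- list()
  for (v in variants) {
    row <- tryCatch({
      model <- dbsa_model(v, bands = bands, input_size = input_size,
                          routing_iters = config$routing_iters,
                          seed = config$seed)
      np <- count_parameters(model)
      model <- fit(model, train, val, config)
      rep <- evaluate(model, test, microbatch = config$microbatch)
      reports[[v]] <- rep
      c(list(variant = v, parameters = np, failed = FALSE),
        as_metrics_row(rep))
    }, error = function(e) {
      list(variant = v, parameters = NA_real_, failed = TRUE, oa = NA_real_,
           aa = NA_real_)
    })
    rows[[v]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    miss <- setdiff(names(rows[[which.max(lengths(rows))]]), names(r))
    for (m in miss) r[[m]] <- NA_real_
    r
  }))
  rownames(out) <- NULL
  attr(out, "reports") <- reports
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(out, file.path(out_dir, "ablation.csv"), row.names = FALSE)
    jsonlite::write_json(out, file.path(out_dir, "ablation.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Learning-rate sweep
#'
#' Trains a fresh model at each learning rate of the standard grid and
#' reports the best validation OA reached.
#'
#' @param variant network variant.
#' @param train,val patch sets.
#' @param rates learning rates to try.
#' @param config base [train_config()] (its learning rate is overridden).
#' @param ... passed to [dbsa_model()].
#' @return Data frame with columns `learning_rate` and `best_val_oa`.
#' @export
lr_sweep <- function(variant, train, val,
                     rates = c(1e-3, 1e-4, 1e-5, 5e-6),
                     config = train_config(), ...) {
  res <- lapply(rates, function(lr) {
    cfg <- config
    cfg$learning_rate <- lr
    model <- dbsa_model(variant, seed = cfg$seed, ...)
    model <- fit(model, train, val, cfg)
    data.frame(learning_rate = lr,
               best_val_oa = max(model$history$val_oa, na.rm = TRUE))
  })
  do.call(rbind, res)
}
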