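# Training (AdamW, early stopping), transfer fine-tuning, and the evaluation
# protocols: stratified k-fold splitting, repeated 90/10 train-test
# evaluation, RMSE and rank-based ROC-AUC.

#' Training configuration
#'
#' @param learning_rate AdamW learning rate (pretraining default `1e-4`; use
#'   `5e-5` for fine-tuning).
#' @param weight_decay decoupled weight decay applied to weight matrices.
#' @param patience early-stopping patience in epochs.
#' @param max_epochs maximum number of epochs.
#' @param batch_size molecules per mini-batch.
#' @param seed seed controlling shuffling, dropout and (for fine-tuning) head
#'   re-initialization.
#' @param validation_fraction fraction of records held out for early
#'   stopping.
#' @param freeze_bn keep pretrained batch-normalization statistics fixed
#'   during training (fine-tuning option; default updates them).
#' @return object of class `TrainConfig`.
#' @export
train_config <- function(learning_rate = 1e-4, weight_decay = 0.01,
                         patience = 10L, max_epochs = 100L, batch_size = 32L,
                         seed = 1L, validation_fraction = 0.1,
                         freeze_bn = FALSE) {
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (patience < 1L) stop("patience must be >= 1")
  if (validation_fraction <= 0 || validation_fraction >= 1) {
    stop("validation_fraction must be in (0, 1)")
  }
  structure(list(
    learning_rate = learning_rate, weight_decay = weight_decay,
    patience = as.integer(patience), max_epochs = as.integer(max_epochs),
    batch_size = as.integer(batch_size), seed = as.integer(seed),
    validation_fraction = validation_fraction, freeze_bn = freeze_bn
  ), class = "TrainConfig")
}

.featurize_records <- function(records) {
  lapply(records$smiles, featurize)
}

.loss_and_grad_scale <- function(kind, y, yhat) {
  if (kind == "regression") {
    list(loss = mean((yhat - y)^2), dy = 2 * (yhat - y) / length(y))
  } else {
    p <- stats::plogis(yhat)
    eps <- 1e-12
    list(loss = -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps)),
         dy = (p - y) / length(y))
  }
}

# core training loop; graphs/targets already split into train/val.
# kind: "regression" trains on standardized targets using state$y_stats.
.train_loop <- function(state, graphs_tr, y_tr, graphs_val, y_val, tcfg) {
  cfg <- state$config
  kind <- if (cfg$head_kind == "regression") "regression" else "classification"
  params <- state$params
  bn <- state$bn
  opt <- .adamw_init(params)
  n <- length(graphs_tr)
  nb <- max(1L, ceiling(n / tcfg$batch_size))
  val_batch <- .compile_batch(graphs_val)

  eval_val <- function(params, bn) {
    r <- .nn_forward(params, bn, cfg, val_batch, training = FALSE)
    .loss_and_grad_scale(kind, y_val, r$y)$loss
  }

  best_loss <- Inf
  best <- list(params = params, bn = bn)
  wait <- 0L
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  for (epoch in seq_len(tcfg$max_epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (b in seq_len(nb)) {
      idx <- ord[(((b - 1L) * tcfg$batch_size + 1L):min(b * tcfg$batch_size, n))]
      batch <- .compile_batch(graphs_tr[idx])
      r <- .nn_forward(params, bn, cfg, batch, training = TRUE)
      if (!tcfg$freeze_bn) bn <- r$bn
      lg <- .loss_and_grad_scale(kind, y_tr[idx], r$y)
      if (!is.finite(lg$loss)) {
        stop(sprintf(
          "non-finite training loss at epoch %d batch %d (lr %.2g); aborting",
          epoch, b, tcfg$learning_rate))
      }
      grads <- .nn_backward(params, cfg, batch, r$cache, lg$dy)
      upd <- .adamw_step(params, grads, opt, tcfg$learning_rate,
                         tcfg$weight_decay)
      params <- upd$params
      opt <- upd$opt
      ep_loss <- ep_loss + lg$loss * length(idx)
    }
    vl <- eval_val(params, bn)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = ep_loss / n,
                                         val_loss = vl))
    if (vl < best_loss - 1e-12) {
      best_loss <- vl
      best <- list(params = params, bn = bn)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= tcfg$patience) break
    }
  }
  state$params <- best$params
  state$bn <- best$bn
  state$history <- history
  state
}

.stratified_holdout <- function(y, fraction, classification) {
  n <- length(y)
  if (classification) {
    val <- integer(0)
    for (cl in unique(y)) {
      idx <- which(y == cl)
      k <- max(1L, round(length(idx) * fraction))
      val <- c(val, sample(idx, k))
    }
    sort(val)
  } else {
    sort(sample.int(n, max(1L, round(n * fraction))))
  }
}

#' Pretrain a regression model
#'
#' Trains on a `(smiles, value)` table with mean-squared-error loss on
#' internally standardized targets, AdamW, and early stopping on a held-out
#' validation split (best-validation weights are returned). The training
#' history (per-epoch train/validation loss) is attached as `$history`.
#'
#' @param dataset data.frame with columns `smiles`, `value` (e.g. from
#'   [read_smiles_table()] or [make_pretrain_set()]).
#' @param config a [model_config()] with `head_kind = "regression"`.
#' @param train a [train_config()].
#' @return trained `gat_model`.
#' @export
pretrain <- function(dataset, config = model_config(), train = train_config()) {
  if (nrow(dataset) < 2L) stop("need at least 2 records")
  if (!all(is.finite(dataset$value))) stop("targets must be finite")
  if (config$head_kind != "regression") {
    stop("pretraining requires a regression head")
  }
  if (stats::sd(dataset$value) == 0) {
    warning("all targets identical; model will learn a constant")
  }
  graphs <- .featurize_records(dataset)
  y <- dataset$value
  withr_seed(train$seed, {
    state <- init_model(config, seed = train$seed)
    mu <- mean(y); sdy <- max(stats::sd(y), 1e-8)
    state$y_stats <- list(mean = mu, sd = sdy)
    ys <- (y - mu) / sdy
    val <- .stratified_holdout(y, train$validation_fraction, FALSE)
    tr <- setdiff(seq_along(y), val)
    .train_loop(state, graphs[tr], ys[tr], graphs[val], ys[val], train)
  })
}

#' Fine-tune a pretrained model as a classifier
#'
#' The convolution and global-attention weights (and batch-normalization
#' statistics) are initialized from the pretrained state; the two fully
#' connected head layers are re-initialized as a classifier. All layers are
#' trainable at the (smaller) fine-tuning learning rate; set
#' `train$freeze_bn = TRUE` to keep pretrained normalization statistics
#' fixed.
#'
#' @param pretrained a regression `gat_model` from [pretrain()].
#' @param dataset data.frame with columns `smiles`, `label` (0/1).
#' @param train a [train_config()]; default learning rate `5e-5`.
#' @return trained classification `gat_model`.
#' @export
finetune <- function(pretrained, dataset,
                     train = train_config(learning_rate = 5e-5)) {
  stopifnot(inherits(pretrained, "gat_model"))
  if (pretrained$config$head_kind != "regression") {
    stop("finetune expects a pretrained regression model")
  }
  state <- pretrained
  state$config$head_kind <- "binary-classification"
  state$y_stats <- NULL
  withr_seed(train$seed, {
    fresh <- .init_params(state$config, state$n_node_features)
    state$params$head_W1 <- fresh$head_W1
    state$params$head_b1 <- fresh$head_b1
    state$params$head_W2 <- fresh$head_W2
    state$params$head_b2 <- fresh$head_b2
    .train_classifier(state, dataset, train)
  })
}

#' Train a classifier from scratch (no pretraining)
#'
#' The architecture twin of [finetune()] without transferred weights; serves
#' as the baseline in transfer-benefit comparisons.
#'
#' @inheritParams finetune
#' @param config a [model_config()].
#' @return trained classification `gat_model`.
#' @export
train_scratch <- function(dataset, config = model_config(
                            head_kind = "binary-classification"),
                          train = train_config()) {
  cfg <- config
  cfg$head_kind <- "binary-classification"
  withr_seed(train$seed, {
    state <- init_model(cfg, seed = train$seed)
    .train_classifier(state, dataset, train)
  })
}

# shared classifier training path (assumes RNG already seeded)
.train_classifier <- function(state, dataset, train) {
  y <- dataset$label
  if (length(unique(y)) < 2L) stop("need both classes present")
  graphs <- .featurize_records(dataset)
  val <- .stratified_holdout(y, train$validation_fraction, TRUE)
  tr <- setdiff(seq_along(y), val)
  .train_loop(state, graphs[tr], y[tr], graphs[val], y[val], train)
}

#' Stratified k-fold assignments
#'
#' Within each class, indices are shuffled and dealt round-robin, so per-fold
#' class counts differ by at most one from the balanced partition.
#'
#' @param labels binary (or categorical) label vector.
#' @param k number of folds.
#' @param seed shuffle seed.
#' @return integer vector of fold ids (1..k) per observation.
#' @export
stratified_kfold <- function(labels, k = 10L, seed = 1L) {
  k <- as.integer(k)
  tab <- table(labels)
  if (length(tab) < 2L) stop("labels contain a single class")
  if (k > min(tab)) {
    stop("k (", k, ") exceeds the smallest class count (", min(tab), ")")
  }
  folds <- integer(length(labels))
  withr_seed(seed, {
    for (cl in names(tab)) {
      idx <- sample(which(labels == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Root-mean-square error
#' @param predictions,targets numeric vectors of equal length.
#' @return RMSE.
#' @export
metric_rmse <- function(predictions, targets) {
  if (length(predictions) != length(targets)) stop("length mismatch")
  sqrt(mean((predictions - targets)^2))
}

#' ROC-AUC via the rank statistic (midranks for ties)
#' @param scores numeric scores (higher = more positive).
#' @param labels 0/1 labels.
#' @return area under the ROC curve.
#' @export
metric_roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("length mismatch")
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("ROC-AUC needs both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Repeated stratified train/test evaluation
#'
#' Repeats a stratified `1 - test_fraction` / `test_fraction` split, trains a
#' model with `builder` on the training portion and computes ROC-AUC on the
#' held-out test portion only.
#'
#' @param builder function `(train_records, seed)` returning a model usable
#'   with [predict_batch()].
#' @param dataset data.frame with `smiles` and `label`.
#' @param n_splits number of independent splits.
#' @param test_fraction held-out fraction per split.
#' @param seed base seed; split `s` uses `seed + s`.
#' @return object of class `EvalReport`: list with `metric`, `per_split`,
#'   `mean`, `sd`, `seeds`.
#' @export
repeated_split_eval <- function(builder, dataset, n_splits = 10L,
                                test_fraction = 0.1, seed = 1L) {
  y <- dataset$label
  if (length(unique(y)) < 2L) stop("dataset needs both classes")
  aucs <- numeric(n_splits)
  seeds <- seed + seq_len(n_splits)
  for (s in seq_len(n_splits)) {
    test_idx <- NULL
    for (try in 1:5) {
      cand <- withr_seed(seeds[s] + 1000L * (try - 1L),
                         .stratified_holdout(y, test_fraction, TRUE))
      if (length(unique(y[cand])) == 2L && length(cand) < length(y)) {
        test_idx <- cand
        break
      }
      warning("single-class test split; resampling")
    }
    if (is.null(test_idx)) stop("could not draw a two-class test split")
    train_rec <- dataset[-test_idx, , drop = FALSE]
    test_rec <- dataset[test_idx, , drop = FALSE]
    model <- builder(train_rec, seeds[s])
    scores <- predict_batch(model, .featurize_records(test_rec))
    aucs[s] <- metric_roc_auc(scores, test_rec$label)
  }
  if (n_splits == 1L) {
    warning("n_splits = 1: standard deviation reported as 0")
  }
  structure(list(
    metric = "roc_auc", per_split = aucs, mean = mean(aucs),
    sd = if (n_splits > 1L) stats::sd(aucs) else 0, seeds = seeds
  ), class = "EvalReport")
}

#' @export
print.EvalReport <- function(x, ...) {
  cat(sprintf("<EvalReport> %s over %d splits: %.3f +/- %.3f\n",
              x$metric, length(x$per_split), x$mean, x$sd))
  invisible(x)
}
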