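#' Sequence-labeller configuration
#'
#' Architecture and optimisation settings for the bidirectional LSTM
#' segmenter: a per-sample scalar input (z-scored per record) feeds two
#' stacked BiLSTM layers — the first acting as encoder, the second as
#' decoder — followed by a per-timestep affine map to three class logits
#' (background / systole / diastole) and a softmax. Trained with Adam on
#' mean per-sample cross-entropy.
#'
#' @param hidden_size LSTM units per direction (default 48; sized for
#'   CPU-scale training, see the methods vignette).
#' @param num_classes number of label classes (3).
#' @param dropout dropout fraction applied between the two BiLSTM layers
#'   during training (default 0.2).
#' @param lr initial Adam learning rate (default 0.001).
#' @param batch_size records per batch (default 16).
#' @param max_epochs training epoch budget (default 50).
#' @param early_stop_patience epochs without validation improvement before
#'   stopping (default 10).
#' @param grad_clip global gradient-norm ceiling (default 1); LSTM training
#'   on long sequences is prone to exploding gradients, and clipping is the
#'   standard remedy.
#' @param lr_decay_every epochs between halvings of the learning rate
#'   (default 15); `lr` is the initial rate.
#' @param seed integer seed controlling initialisation, dropout and batch
#'   order.
#' @return object of class `model_config`.
#' @export
model_config <- function(hidden_size = 48L, num_classes = 3L, dropout = 0.2,
                         lr = 0.001, batch_size = 16L, max_epochs = 50L,
                         early_stop_patience = 10L, grad_clip = 1,
                         lr_decay_every = 15L, seed = 1L) {
  if (hidden_size < 1L) stop("hidden_size must be >= 1")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (lr <= 0) stop("lr must be positive")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (max_epochs < 0L) stop("max_epochs must be >= 0")
  structure(list(hidden_size = as.integer(hidden_size),
                 num_bilstm_layers = 2L,
                 num_classes = as.integer(num_classes),
                 dropout = dropout, lr = lr,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 grad_clip = grad_clip,
                 lr_decay_every = as.integer(lr_decay_every),
                 seed = as.integer(seed)),
            class = "model_config")
}

# uniform(-1/sqrt(H), 1/sqrt(H)) init, the standard recurrent-net default
.init_mat <- function(nr, nc, H) {
  k <- 1 / sqrt(H)
  matrix(stats::runif(nr * nc, -k, k), nr, nc)
}

#' Build (initialise) a segmenter model
#'
#' Allocates all parameter matrices with seeded uniform initialisation.
#' The model is length-agnostic: any record length yields one class
#' distribution per sample.
#'
#' @param cfg a [model_config()].
#' @return object of class `bilstm_model` (config + parameter list).
#' @export
build_model <- function(cfg = model_config()) {
  stopifnot(inherits(cfg, "model_config"))
  H <- cfg$hidden_size; C <- cfg$num_classes
  set.seed(cfg$seed)
  params <- list()
  for (cell in c("l1f", "l1b", "l2f", "l2b")) {
    D <- if (substr(cell, 2, 2) == "1") 1L else 2L * H
    params[[paste0(cell, "_W")]] <- .init_mat(4L * H, D, H)
    params[[paste0(cell, "_U")]] <- .init_mat(4L * H, H, H)
    b <- numeric(4L * H)
    b[(H + 1L):(2L * H)] <- 1  # forget-gate bias 1: remember by default
    params[[paste0(cell, "_b")]] <- b
  }
  params$out_W <- .init_mat(C, 2L * H, H)
  params$out_b <- numeric(C)
  structure(list(config = cfg, params = params), class = "bilstm_model")
}

#' @export
print.bilstm_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<bilstm_model: 2 BiLSTM layers x %d units/direction, %d classes, %s parameters>\n",
              x$config$hidden_size, x$config$num_classes,
              format(n_par, big.mark = ",")))
  invisible(x)
}

# z-score one record's samples (the model's input normalisation)
.zscore <- function(x) {
  s <- stats::sd(x)
  if (s == 0) return(x - mean(x))
  (x - mean(x)) / s
}

# stack a list of equal-length records into T x B input / label matrices
.stack_batch <- function(signals, labels = NULL) {
  T_len <- unique(vapply(signals, length, integer(1)))
  if (length(T_len) != 1L) stop("all records in a batch must share one length")
  X <- vapply(signals, .zscore, numeric(T_len))
  if (is.null(labels)) return(list(X = X))
  Y <- vapply(labels, as.integer, integer(T_len))
  list(X = X, Y = Y)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}

.eval_loss <- function(params, signals, labels, batch_size) {
  tot_loss <- 0; tot_acc <- 0; n <- 0
  idx <- seq_along(signals)
  for (chunk in split(idx, ceiling(seq_along(idx) / batch_size))) {
    b <- .stack_batch(signals[chunk], labels[chunk])
    r <- cpp_bilstm_loss_grad(params, b$X, b$Y, matrix(0, 0, 0), FALSE)
    tot_loss <- tot_loss + r$loss * length(chunk)
    tot_acc <- tot_acc + r$accuracy * length(chunk)
    n <- n + length(chunk)
  }
  list(loss = tot_loss / n, accuracy = tot_acc / n)
}

#' Train the segmenter
#'
#' Minimises mean per-sample cross-entropy with Adam, evaluating the
#' validation loss every epoch, keeping the best-validation parameters, and
#' stopping early after `early_stop_patience` epochs without improvement.
#' With `max_epochs = 0` the initialised model is returned untouched with
#' an empty history.
#'
#' @param model a [build_model()] result (or a [model_config()], built on
#'   the fly).
#' @param train_signals,train_labels lists of equal-length numeric signals
#'   (preprocessed) and integer label vectors.
#' @param val_signals,val_labels validation set in the same shape.
#' @return list with `model` (best-validation parameters) and `history`
#'   (data.frame: epoch, train_loss, train_acc, val_loss, val_acc).
#' @export
train_segmenter <- function(model, train_signals, train_labels,
                            val_signals, val_labels) {
  if (inherits(model, "model_config")) model <- build_model(model)
  stopifnot(inherits(model, "bilstm_model"))
  cfg <- model$config
  if (length(train_signals) == 0 || length(val_signals) == 0) {
    stop("training and validation sets must be non-empty")
  }
  if (length(train_signals) != length(train_labels)) {
    stop("signals/labels length mismatch")
  }
  bad <- which(vapply(train_signals, length, integer(1)) !=
                 vapply(train_labels, length, integer(1)))
  if (length(bad)) {
    stop("label/signal length mismatch in training record(s) ",
         paste(bad, collapse = ", "))
  }
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        train_acc = numeric(0), val_loss = numeric(0),
                        val_acc = numeric(0))
  if (cfg$max_epochs == 0L) {
    return(list(model = model, history = history))
  }
  params <- model$params
  state <- list(t = 0L,
                m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))
  set.seed(cfg$seed + 1L)  # training stream: batch order + dropout masks
  best_val <- Inf; best_params <- params; wait <- 0L
  H2 <- 2L * cfg$hidden_size
  for (epoch in seq_len(cfg$max_epochs)) {
    lr_epoch <- cfg$lr * 0.5^((epoch - 1L) %/% cfg$lr_decay_every)
    ord <- sample.int(length(train_signals))
    ep_loss <- 0; ep_acc <- 0
    for (chunk in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
      b <- .stack_batch(train_signals[chunk], train_labels[chunk])
      mask <- if (cfg$dropout > 0) {
        matrix((stats::runif(H2 * length(chunk)) >= cfg$dropout) /
                 (1 - cfg$dropout), H2, length(chunk))
      } else matrix(0, 0, 0)
      r <- cpp_bilstm_loss_grad(params, b$X, b$Y, mask, TRUE)
      gnorm <- sqrt(sum(vapply(r$grads, function(g) sum(g^2), numeric(1))))
      if (is.finite(cfg$grad_clip) && gnorm > cfg$grad_clip) {
        r$grads <- lapply(r$grads, function(g) g * (cfg$grad_clip / gnorm))
      }
      upd <- .adam_step(params, r$grads, state, lr_epoch)
      params <- upd$params; state <- upd$state
      ep_loss <- ep_loss + r$loss * length(chunk)
      ep_acc <- ep_acc + r$accuracy * length(chunk)
    }
    val <- .eval_loss(params, val_signals, val_labels, cfg$batch_size)
    history <- rbind(history, data.frame(
      epoch = epoch,
      train_loss = ep_loss / length(train_signals),
      train_acc = ep_acc / length(train_signals),
      val_loss = val$loss, val_acc = val$accuracy))
    if (val$loss < best_val - 1e-6) {
      best_val <- val$loss; best_params <- params; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$early_stop_patience) break
    }
  }
  model$params <- best_params
  list(model = model, history = history)
}

#' Predict phase labels for one record
#'
#' Runs the forward pass (no dropout), takes the per-sample argmax, and
#' cleans the class sequence with [postprocess_classes()]. The record is
#' expected to be preprocessed; a `preprocessed` metadata flag, when
#' present, is recorded in the result.
#'
#' @param model a trained `bilstm_model`.
#' @param record a [pulse_record()].
#' @return a `segmentation_result`: `classes` (0/1/2 per sample), `probs`
#'   (samples x classes matrix, rows sum to 1), `segments` (interval
#'   data.frame).
#' @export
predict_segmenter <- function(model, record) {
  stopifnot(inherits(model, "bilstm_model"), inherits(record, "pulse_record"))
  if (!all(is.finite(record$samples))) stop("record contains non-finite samples")
  X <- matrix(.zscore(record$samples), ncol = 1)
  pr <- cpp_bilstm_probs(model$params, X)      # C x 1 x T
  probs <- t(pr[, 1, ])                        # T x C
  raw <- max.col(probs, ties.method = "first") - 1L
  classes <- postprocess_classes(raw, fs = record$fs)
  structure(list(classes = classes,
                 probs = probs,
                 segments = labels_to_intervals(classes, record$record_id),
                 flags = if (isTRUE(record$meta$preprocessed)) "preprocessed" else "raw",
                 onsets = NULL),
            class = "segmentation_result")
}

#' Clean a predicted class sequence
#'
#' Merges runs shorter than `min_run_s` into their longer neighbour, then
#' enforces phase alternation inside the labelled region: a systolic run
#' must be followed by a diastolic run before the next systolic one (a
#' repeated phase is merged into its predecessor).
#'
#' @param classes integer vector in `{0, 1, 2}`.
#' @param fs sampling rate in Hz.
#' @param min_run_s minimum credible run duration in seconds (default
#'   0.05 s, i.e. 36 samples at 720 Hz).
#' @return cleaned integer class vector.
#' @export
postprocess_classes <- function(classes, fs = 720, min_run_s = 0.05) {
  if (!all(classes %in% 0:2)) stop("classes must be in {0, 1, 2}")
  min_run <- round(min_run_s * fs)
  r <- rle(as.integer(classes))
  # absorb short runs into the longer neighbour, shortest first
  repeat {
    if (length(r$lengths) <= 1L) break
    short <- which(r$lengths < min_run)
    if (length(short) == 0L) break
    i <- short[which.min(r$lengths[short])]
    left <- if (i > 1L) r$lengths[i - 1L] else -1L
    right <- if (i < length(r$lengths)) r$lengths[i + 1L] else -1L
    into <- if (left >= right) i - 1L else i + 1L
    r$values[i] <- r$values[into]
    v <- inverse.rle(r)
    r <- rle(v)
  }
  # enforce systole -> diastole alternation within the labelled region:
  # two same-phase runs separated only by background are bridged into one
  v <- inverse.rle(r)
  r <- rle(v)
  nz <- which(r$values != 0L)
  if (length(nz) > 1L) {
    for (j in seq_len(length(nz) - 1L)) {
      a <- nz[j]; b <- nz[j + 1L]
      if (r$values[a] == r$values[b] && b > a + 1L) {
        r$values[(a + 1L):(b - 1L)] <- r$values[a]
      }
    }
    v <- inverse.rle(r)
  }
  v
}

#' Save / load a segmenter checkpoint
#'
#' The parameter container is written with `saveRDS`; a JSON sidecar
#' (`<path>.json`) records the model configuration and, when supplied, a
#' preprocessing fingerprint, so a checkpoint documents how its inputs were
#' prepared.
#'
#' @param model a `bilstm_model`.
#' @param path checkpoint path (e.g. `model.rds`).
#' @param preprocess_cfg optional [preprocess_config()] stored in the
#'   sidecar.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path, preprocess_cfg = NULL) {
  stopifnot(inherits(model, "bilstm_model"))
  saveRDS(model, path)
  sidecar <- list(config = unclass(model$config))
  if (!is.null(preprocess_cfg)) sidecar$preprocess <- unclass(preprocess_cfg)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "bilstm_model"))
  model
}
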