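#' Define one fine-tuning stage
#'
#' A stage bundles a dataset with the hyperparameters of one fine-tuning
#' pass. Data are in-memory tensors at desk scale: \code{x_train} and
#' \code{x_val} are \code{(s, s, channels, N)} arrays, labels are integers
#' in \code{1..n_classes}.
#'
#' @param x_train,y_train training tensor and labels.
#' @param x_val,y_val validation tensor and labels.
#' @param n_classes output class count of this stage.
#' @param epochs training epochs (0 = pass-through).
#' @param lr learning rate (default 0.1, chosen for convergence of this
#'   small backbone at desk scale).
#' @param batch_size mini-batch size (default 32).
#' @param momentum SGD momentum (default 0.9).
#' @param seed integer seed controlling shuffling and any head swap.
#' @param name stage label used in logs.
#' @return list classed \code{"training_stage"}.
#' @export
training_stage <- function(x_train, y_train, x_val, y_val, n_classes,
                           epochs = 20L, lr = 0.1, batch_size = 32L,
                           momentum = 0.9, seed = 1L, name = "stage") {
  if (n_classes < 2) stop("class count must be >= 2", call. = FALSE)
  if (epochs < 0) stop("epochs must be >= 0", call. = FALSE)
  structure(list(x_train = x_train, y_train = as.integer(y_train),
                 x_val = x_val, y_val = as.integer(y_val),
                 n_classes = as.integer(n_classes),
                 epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size), momentum = momentum,
                 seed = as.integer(seed), name = name),
            class = "training_stage")
}

empty_log <- function() {
  data.frame(stage = character(0), epoch = integer(0),
             train_loss = numeric(0), val_loss = numeric(0),
             val_acc = numeric(0), val_auc = numeric(0))
}

# validation metrics; AUC only meaningful for binary stages with both
# classes present in the validation set
validation_metrics <- function(model, x, y) {
  probs <- nn_predict(model, x)
  pred <- max.col(t(probs))
  p_true <- probs[cbind(y, seq_along(y))]
  vloss <- mean(-log(pmax(p_true, 1e-12)))
  vacc <- mean(pred == y)
  vauc <- NA_real_
  if (model$arch$n_classes == 2L && length(unique(y)) == 2L)
    vauc <- roc_auc(probs[2L, ], y == 2L)
  c(val_loss = vloss, val_acc = vacc, val_auc = vauc)
}

#' Run one fine-tuning stage
#'
#' Minimizes the mean cross-entropy loss by mini-batch SGD with momentum
#' for the stated number of epochs, logging the per-epoch mean training
#' loss and validation metrics. If the stage class count differs from the
#' model head, the head is swapped first (seeded by the stage seed). The
#' returned model carries the validation-best weights of the stage
#' (highest validation AUC for binary stages, else accuracy; ties broken by
#' lower validation loss).
#'
#' @param model a \code{"histostep_model"}.
#' @param stage a \code{\link{training_stage}}.
#' @return list with \code{model} and \code{log} (data.frame; attribute
#'   \code{"selected_epoch"} marks the checkpoint).
#' @export
run_stage <- function(model, stage) {
  stopifnot(inherits(stage, "training_stage"))
  if (stage$epochs == 0L)
    return(list(model = model, log = empty_log()))
  n <- dim(stage$x_train)[4]
  if (is.null(n) || n == 0L) stop("stage has an empty training set", call. = FALSE)
  if (model$arch$n_classes != stage$n_classes)
    model <- swap_head(model, stage$n_classes, seed = stage$seed)
  set.seed(stage$seed)
  state <- NULL
  log <- empty_log()
  best <- NULL
  for (epoch in seq_len(stage$epochs)) {
    perm <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1L, n, by = stage$batch_size)) {
      idx <- perm[start:min(start + stage$batch_size - 1L, n)]
      xb <- stage$x_train[, , , idx, drop = FALSE]
      lg <- nn_loss_grad(model, xb, stage$y_train[idx])
      if (any(!is.finite(lg$losses)))
        stop(sprintf("non-finite loss in stage '%s', epoch %d", stage$name, epoch),
             call. = FALSE)
      losses <- c(losses, lg$losses)
      upd <- nn_sgd_step(model, lg$grads, state, stage$lr, stage$momentum)
      model <- upd$model
      state <- upd$state
    }
    vm <- validation_metrics(model, stage$x_val, stage$y_val)
    log <- rbind(log, data.frame(stage = stage$name, epoch = epoch,
                                 train_loss = mean_loss(losses),
                                 val_loss = vm["val_loss"],
                                 val_acc = vm["val_acc"],
                                 val_auc = vm["val_auc"], row.names = NULL))
    score <- if (!is.na(vm["val_auc"])) vm["val_auc"] else vm["val_acc"]
    if (is.null(best) || score > best$score ||
        (score == best$score && vm["val_loss"] < best$val_loss)) {
      best <- list(model = model, score = score, val_loss = vm["val_loss"],
                   epoch = epoch)
    }
  }
  attr(log, "selected_epoch") <- best$epoch
  list(model = best$model, log = log)
}

#' Build a stepwise fine-tuning schedule
#'
#' A schedule is the t = 0 initialization plus one or two fine-tuning
#' stages: one stage is the conventional baseline (train directly on the
#' well-annotated set), two stages is the stepwise proposal (medium-level
#' stage first, then the benign/malignant stage).
#'
#' @param stages list of 1 or 2 \code{\link{training_stage}} objects, in
#'   execution order.
#' @param init_seed seed of the t = 0 weight initialization (any
#'   initialization is accepted at t = 0; at desk scale it is random).
#' @param input_size,in_channels,filters architecture of the desk backbone,
#'   see \code{\link{small_cnn}}.
#' @return list classed \code{"stage_schedule"}.
#' @export
stage_schedule <- function(stages, init_seed = 0L, input_size = 32L,
                           in_channels = 3L, filters = c(8L, 16L, 32L, 32L)) {
  if (!length(stages) %in% 1:2)
    stop("a schedule has 1 (baseline) or 2 (stepwise) fine-tuning stages",
         call. = FALSE)
  for (st in stages) stopifnot(inherits(st, "training_stage"))
  structure(list(stages = stages, init_seed = as.integer(init_seed),
                 input_size = as.integer(input_size),
                 in_channels = as.integer(in_channels),
                 filters = as.integer(filters)),
            class = "stage_schedule")
}

#' Execute a stepwise fine-tuning schedule
#'
#' Initializes the network (t = 0), then runs each stage in order; the head
#' is swapped whenever the stage class count differs from the current head
#' (each swap is recorded). The final model is the last stage's
#' validation-best checkpoint.
#'
#' @param schedule a \code{\link{stage_schedule}}.
#' @return list with \code{model}, \code{log} (stage-labelled rows; stage
#'   boundaries are where the \code{stage} column changes) and
#'   \code{head_swaps} (count of head replacements after t = 0).
#' @export
run_stepwise <- function(schedule) {
  stopifnot(inherits(schedule, "stage_schedule"))
  model <- small_cnn(input_size = schedule$input_size,
                     in_channels = schedule$in_channels,
                     filters = schedule$filters,
                     n_classes = schedule$stages[[1]]$n_classes,
                     seed = schedule$init_seed)
  log <- empty_log()
  head_swaps <- 0L
  for (st in schedule$stages) {
    if (model$arch$n_classes != st$n_classes) head_swaps <- head_swaps + 1L
    res <- run_stage(model, st)
    model <- res$model
    log <- rbind(log, res$log)
  }
  list(model = model, log = log, head_swaps = head_swaps)
}
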