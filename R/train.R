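#' Training configuration
#'
#' Defaults follow the study protocol: RMSprop with learning rate `1e-4`,
#' 200 epochs, a `1 - DICE` loss, and 10-fold patient-level cross-validation
#' (so each validation split holds 1/10 of the patients). Batch size and the
#' loss smoothing constant are artifact choices exposed here.
#'
#' @param learning_rate positive step size (default `1e-4`).
#' @param epochs number of passes over the training slices (default 200).
#' @param batch_size slices per optimization step (default 8).
#' @param loss_smoothing smoothing constant of [soft_dice_loss()] (default 1).
#' @param folds number of cross-validation folds (default 10); the validation
#'   fraction is `1/folds`.
#' @param seed integer seed controlling initialization, shuffling and
#'   augmentation draws; per-fold seeds are derived as `seed + fold_index`.
#' @param rmsprop_decay RMSprop squared-gradient decay (default 0.9).
#' @param keep_best retain the checkpoint with the best validation mean DICE
#'   instead of the final epoch (off by default: the study trains a fixed
#'   number of epochs).
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, epochs = 200L, batch_size = 8L,
                         loss_smoothing = 1, folds = 10L, seed = 1L,
                         rmsprop_decay = 0.9, keep_best = FALSE) {
  if (learning_rate < 0) stop("learning_rate must be nonnegative")
  if (epochs < 1L) stop("epochs must be >= 1")
  if (folds < 2L) stop("folds must be >= 2 (validation fraction 1/folds)")
  if (loss_smoothing < 0) stop("loss_smoothing must be nonnegative")
  structure(list(learning_rate = learning_rate, optimizer = "rmsprop",
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 loss_smoothing = loss_smoothing, folds = as.integer(folds),
                 validation_fraction = 1 / folds, seed = as.integer(seed),
                 rmsprop_decay = rmsprop_decay, keep_best = isTRUE(keep_best)),
            class = "train_config")
}

#' Patient-level k-fold split
#'
#' Randomly permutes the patient ids under `seed` and partitions them into
#' `folds` validation sets of near-equal size (differing by at most one).
#' All slices of a patient stay on one side of every split; each patient
#' validates exactly once across the folds.
#'
#' @param patient_ids character vector of unique patient ids.
#' @param folds number of folds.
#' @param seed integer seed.
#' @return list of fold splits, each with `fold_index`, `train_ids`,
#'   `validation_ids`.
#' @export
make_folds <- function(patient_ids, folds = 10L, seed = 1L) {
  if (anyDuplicated(patient_ids)) stop("duplicate patient ids")
  n <- length(patient_ids)
  if (n < folds) stop("need at least as many patients as folds")
  perm <- with_local_seed(seed, sample(patient_ids))
  sizes <- rep(n %/% folds, folds)
  if (n %% folds > 0L) sizes[seq_len(n %% folds)] <- sizes[seq_len(n %% folds)] + 1L
  stops <- cumsum(sizes)
  starts <- c(1L, head(stops, -1L) + 1L)
  lapply(seq_len(folds), function(k) {
    val <- perm[starts[k]:stops[k]]
    list(fold_index = k, train_ids = setdiff(patient_ids, val),
         validation_ids = val)
  })
}

rmsprop_init <- function(params) lapply(params, function(p) p * 0)

rmsprop_step <- function(params, grads, v, lr, rho = 0.9, eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    v[[nm]] <- rho * v[[nm]] + (1 - rho) * g^2
    params[[nm]] <- params[[nm]] - lr * g / (sqrt(v[[nm]]) + eps)
  }
  list(params = params, v = v)
}

# Stack a list of SliceSamples into (H, W, C, N) image / (H, W, 4, N) label
# batch tensors.
stack_samples <- function(samples) {
  d <- dim(samples[[1L]]$image)
  n <- length(samples)
  xb <- array(0, c(d[1L], d[2L], d[3L], n))
  yb <- array(0, c(d[1L], d[2L], dim(samples[[1L]]$label)[3L], n))
  for (i in seq_len(n)) {
    xb[, , , i] <- samples[[i]]$image
    yb[, , , i] <- samples[[i]]$label
  }
  list(x = xb, y = yb)
}

# Hard per-channel Dice of thresholded predictions against binary labels,
# pooled over all supplied samples; used for the per-epoch history.
hard_dice_by_channel <- function(model, samples, threshold = 0.5,
                                 batch_size = 8L) {
  n_ch <- dim(samples[[1L]]$label)[3L]
  inter <- num <- rep(0, n_ch)
  for (i in seq(1L, length(samples), by = batch_size)) {
    batch <- samples[i:min(i + batch_size - 1L, length(samples))]
    sb <- stack_samples(batch)
    pred <- unet_forward(model, sb$x, train = FALSE)$y >= threshold
    d <- dim(pred)
    pm <- matrix(pred, d[1L] * d[2L], d[3L] * d[4L])
    tm <- matrix(sb$y, d[1L] * d[2L], d[3L] * d[4L])
    inter <- inter + rowSums(matrix(colSums(pm * tm), d[3L], d[4L]))
    num <- num + rowSums(matrix(colSums(pm) + colSums(tm), d[3L], d[4L]))
  }
  ifelse(num == 0, 1, 2 * inter / pmax(num, .Machine$double.eps))
}

#' Train a model on one cross-validation fold
#'
#' Runs the RMSprop loop over the fold's training slices with on-the-fly
#' augmentation, recording per-epoch training loss and validation mean DICE.
#' With `keep_best` the returned model is the checkpoint with the highest
#' validation mean DICE, otherwise the final epoch.
#'
#' @param model a freshly built `parotid_unet` (its parameters are updated).
#' @param fold a fold split from [make_folds()].
#' @param dataset list of slice samples from [make_slice_dataset()].
#' @param config a [train_config()].
#' @param augment an [augment_config()], or `NULL` to disable augmentation.
#' @return list with `model` and `history` (data.frame: epoch, train_loss,
#'   val_dice).
#' @export
train_fold <- function(model, fold, dataset, config, augment = NULL) {
  ids <- vapply(dataset, function(s) s$patient_id, "")
  train_set <- dataset[ids %in% fold$train_ids]
  val_set <- dataset[ids %in% fold$validation_ids]
  if (length(train_set) == 0L) stop("empty training set for fold")
  with_local_seed(config$seed + fold$fold_index, {
    v <- rmsprop_init(model$params)
    history <- data.frame(epoch = integer(), train_loss = numeric(),
                          val_dice = numeric())
    best <- list(dice = -Inf, params = NULL, state = NULL)
    for (epoch in seq_len(config$epochs)) {
      order_idx <- sample(length(train_set))
      losses <- c()
      for (i in seq(1L, length(train_set), by = config$batch_size)) {
        take <- order_idx[i:min(i + config$batch_size - 1L, length(train_set))]
        batch <- train_set[take]
        if (!is.null(augment)) batch <- lapply(batch, augment_sample, config = augment)
        sb <- stack_samples(batch)
        fw <- unet_forward(model, sb$x, train = TRUE, keep = TRUE)
        losses <- c(losses, soft_dice_loss(fw$y, sb$y, config$loss_smoothing))
        dy <- soft_dice_loss_grad(fw$y, sb$y, config$loss_smoothing)
        bk <- unet_backward(model, fw, dy)
        upd <- rmsprop_step(model$params, bk$grads, v, config$learning_rate,
                            config$rmsprop_decay)
        model$params <- upd$params
        v <- upd$v
        model$state <- fw$ctx$state
      }
      val_dice <- if (length(val_set)) {
        mean(hard_dice_by_channel(model, val_set, batch_size = config$batch_size))
      } else NA_real_
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = mean(losses),
                                           val_dice = val_dice))
      if (config$keep_best && !is.na(val_dice) && val_dice > best$dice) {
        best <- list(dice = val_dice, params = model$params, state = model$state)
      }
    }
    if (config$keep_best && !is.null(best$params)) {
      model$params <- best$params
      model$state <- best$state
    }
    list(model = model, history = history)
  })
}

#' Patient-level k-fold cross-validation
#'
#' Trains one model per fold on the cohort's slices and evaluates every
#' patient with the model whose training never saw it, aggregating the
#' four-metric results across the cohort.
#'
#' @param cases list of phantom cases (or any list with `patient_id`,
#'   `volume`, `labels`).
#' @param model_config a [model_config()] (its `in_channels` must equal
#'   `length(sequences)`).
#' @param config a [train_config()].
#' @param augment optional [augment_config()].
#' @param sequences sequence subset used as input channels.
#' @param metric_opts list passed on to [case_metrics()].
#' @return a cohort report, as from [aggregate_metrics()], with the per-fold
#'   training histories attached as attribute `histories`.
#' @export
run_cross_validation <- function(cases, model_config, config, augment = NULL,
                                 sequences = SEQUENCE_NAMES,
                                 metric_opts = list()) {
  if (length(cases) == 0L) stop("empty cohort")
  dataset <- make_slice_dataset(cases, sequences = sequences,
                                input_size = model_config$input_size)
  ids <- vapply(cases, function(cs) cs$patient_id, "")
  folds <- make_folds(ids, folds = config$folds, seed = config$seed)
  per_case <- list()
  histories <- list()
  for (fold in folds) {
    model <- build_model(model_config, seed = config$seed + fold$fold_index)
    tr <- train_fold(model, fold, dataset, config, augment)
    histories[[fold$fold_index]] <- tr$history
    for (pid in fold$validation_ids) {
      cs <- cases[[match(pid, ids)]]
      pred <- predict_case(tr$model, cs, sequences = sequences)
      cm <- do.call(case_metrics,
                    c(list(pred = pred, truth = cs$labels, patient_id = pid),
                      metric_opts))
      per_case[[length(per_case) + 1L]] <- cm
    }
  }
  report <- aggregate_metrics(do.call(rbind, per_case))
  attr(report, "histories") <- histories
  report
}
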