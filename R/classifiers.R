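#' Classifier configuration
#'
#' One configuration object covers the four model families compared in the
#' pipeline: a fully connected baseline (`dnn`), recurrent models (`lstm`,
#' `bilstm`), and a 1-D convolutional network (`cnn1d`). Reference
#' architectures: `dnn` = two hidden dense layers (256, 128) on the
#' flattened input; `lstm` = one recurrent layer (64 units) with a
#' last-state head; `bilstm` = the bidirectional version with concatenated
#' end states; `cnn1d` = two convolution blocks (kernels 7 then 5, each
#' followed by max-pooling) plus global average pooling and a dense head.
#' All sizes are overridable.
#'
#' @param family one of `"dnn"`, `"lstm"`, `"bilstm"`, `"cnn1d"`.
#' @param input_channels 3 (acc or ypr alone) or 6 (acc + ypr).
#' @param input_len window length fed to the network (default 256).
#' @param n_classes number of motion classes (default 14).
#' @param class_levels the class labels, in index order
#'   (default `1:n_classes`).
#' @param hidden dense hidden sizes for `dnn`.
#' @param units recurrent units for `lstm`/`bilstm`.
#' @param filters the two convolution widths for `cnn1d`.
#' @param kernels the two convolution kernel lengths for `cnn1d`.
#' @param lr Adam learning rate.
#' @param epochs maximum training epochs.
#' @param batch_size minibatch size.
#' @param patience epochs without loss improvement before early stop.
#' @param min_delta minimum loss improvement that resets patience.
#' @param weight_decay decoupled (AdamW-style) weight decay coefficient
#'   applied to weight matrices (not biases); 0 disables it.
#' @param center subtract each window's per-channel mean before feeding
#'   the network (default TRUE); the offset of a normalized channel is a
#'   nuisance, not a class cue.
#' @return object of class `classifier_config`.
#' @export
classifier_config <- function(family = c("cnn1d", "dnn", "lstm", "bilstm"),
                              input_channels = 6, input_len = 256,
                              n_classes = 14,
                              class_levels = seq_len(n_classes),
                              hidden = c(256, 128), units = 64,
                              filters = c(16, 32), kernels = c(7, 5),
                              lr = 1e-3, epochs = 50, batch_size = 32,
                              patience = 4, min_delta = 5e-3,
                              weight_decay = 0, center = TRUE) {
  family <- match.arg(family)
  if (!input_channels %in% c(3, 6)) {
    abort("input_channels must be 3 or 6", class = "vbdtw_validation_error")
  }
  if (n_classes < 2) {
    abort("need at least 2 classes", class = "vbdtw_validation_error")
  }
  structure(
    list(family = family, input_channels = as.integer(input_channels),
         input_len = as.integer(input_len),
         n_classes = as.integer(n_classes),
         class_levels = as.integer(class_levels),
         hidden = hidden, units = units, filters = filters,
         kernels = kernels, lr = lr, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size),
         patience = as.integer(patience), min_delta = min_delta,
         weight_decay = weight_decay, center = isTRUE(center)),
    class = "classifier_config"
  )
}

config_arch <- function(cfg) {
  switch(cfg$family,
    lstm = list(list(type = "lstm", units = cfg$units)),
    bilstm = list(list(type = "bilstm", units = cfg$units)),
    cnn1d = c(
      unlist(lapply(seq_along(cfg$filters), function(i) {
        list(list(type = "conv1d", k = cfg$kernels[i],
                  filters = cfg$filters[i]),
             list(type = "relu"),
             list(type = "maxpool"))
      }), recursive = FALSE),
      list(list(type = "gap"))
    )
  )
}

build_arch <- function(cfg) {
  if (cfg$family == "dnn") {
    arch <- list(list(type = "flatten"))
    for (u in cfg$hidden) {
      arch <- c(arch, list(list(type = "dense", units = u),
                           list(type = "relu")))
    }
  } else {
    arch <- config_arch(cfg)
  }
  c(arch, list(list(type = "dense", units = cfg$n_classes)))
}

#' Channel-set column selection
#'
#' Maps the channel-set names used throughout the experiments (`"acc"`,
#' `"ypr"`, `"acc_ypr"`) to canonical channel names.
#'
#' @param channel_set one of `"acc"`, `"ypr"`, `"acc_ypr"`.
#' @return character vector of channel names.
#' @export
channel_set_names <- function(channel_set = c("acc_ypr", "acc", "ypr")) {
  channel_set <- match.arg(channel_set)
  switch(channel_set,
         acc = c("acc_x", "acc_y", "acc_z"),
         ypr = c("ypr_x", "ypr_y", "ypr_z"),
         acc_ypr = sensor_channels())
}

# Stack a list of augmented_set objects into training arrays. Windows
# are centered per channel by default: segment values live in [0, 1]
# after min-max normalization, and the channel offset (where the burst
# sits inside that range) is a nuisance that otherwise dominates what a
# ReLU network latches onto.
stack_augmented <- function(aug_sets, channels = sensor_channels(),
                            center = TRUE) {
  stopifnot(length(aug_sets) > 0)
  Ws <- lapply(aug_sets, function(a) {
    W <- a$windows[, , channels, drop = FALSE]
    if (center) {
      m <- apply(W, c(1, 3), mean)
      for (c in seq_len(dim(W)[3])) W[, , c] <- W[, , c] - m[, c]
    }
    W
  })
  nw <- vapply(Ws, function(w) dim(w)[1], integer(1))
  s <- dim(Ws[[1]])[2]
  C <- dim(Ws[[1]])[3]
  X <- array(NA_real_, dim = c(sum(nw), s, C))
  pos <- 0L
  for (w in Ws) {
    X[(pos + 1):(pos + dim(w)[1]), , ] <- w
    pos <- pos + dim(w)[1]
  }
  list(
    X = X,
    y = rep(vapply(aug_sets, function(a) a$label, integer(1)), nw),
    parent = rep(seq_along(aug_sets), nw),
    parent_label = vapply(aug_sets, function(a) a$label, integer(1))
  )
}

#' Train a classifier on augmented window sets
#'
#' Minimizes categorical cross-entropy with Adam over stride-1 windows;
#' every window is an independent training instance carrying its parent
#' segment's label. Training is deterministic for a given (config, data,
#' seed): the same seed reproduces the same initialization, shuffling, and
#' final loss. Stops early when the epoch loss has not improved by
#' `min_delta` for `patience` epochs.
#'
#' @param config a [classifier_config()].
#' @param train_set list of [window_slice()] results (one per parent
#'   segment).
#' @param seed integer seed for initialization and shuffling.
#' @param channels channel names to feed the network (default chosen to
#'   match `config$input_channels`).
#' @param verbose print per-epoch progress.
#' @return object of class `vbdtw_model` with the fitted layers, the
#'   config, and a per-epoch training log.
#' @export
train_classifier <- function(config, train_set, seed = 0,
                             channels = NULL, verbose = FALSE) {
  if (length(train_set) == 0) {
    abort("empty training set", class = "vbdtw_validation_error")
  }
  if (is.null(channels)) {
    channels <- if (config$input_channels == 6) sensor_channels()
                else channel_set_names("acc")
  }
  if (length(channels) != config$input_channels) {
    abort("channel selection does not match config$input_channels",
          class = "vbdtw_validation_error")
  }
  stacked <- stack_augmented(train_set, channels, center = config$center)
  labs <- sort(unique(stacked$y))
  if (length(labs) < 2) {
    abort("training data contains a single class",
          class = "vbdtw_validation_error")
  }
  missing <- setdiff(config$class_levels, labs)
  if (length(missing) > 0) {
    abort(paste0("class(es) absent from training data: ",
                 paste(missing, collapse = ", ")),
          class = "vbdtw_validation_error")
  }
  y_idx <- match(stacked$y, config$class_levels)
  if (anyNA(y_idx)) {
    abort("training labels outside config$class_levels",
          class = "vbdtw_validation_error")
  }
  n <- dim(stacked$X)[1]
  s <- dim(stacked$X)[2]
  if (s != config$input_len) {
    abort(paste0("window length ", s, " != config input_len ",
                 config$input_len),
          class = "vbdtw_validation_error")
  }

  withr::with_seed(seed, {
    layers <- nn_build(build_arch(config), config$input_len,
                       config$input_channels, config$n_classes)
    opt <- adam_init(layers)
    log <- list()
    best <- Inf
    stale <- 0L
    t_adam <- 0L
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      tot_loss <- 0
      tot_correct <- 0
      starts <- seq.int(1, n, by = config$batch_size)
      for (b0 in starts) {
        idx <- ord[b0:min(b0 + config$batch_size - 1, n)]
        Xb <- stacked$X[idx, , , drop = FALSE]
        fb <- nn_forward(layers, Xb, training = TRUE)
        ls <- xent_loss(fb$out, y_idx[idx])
        grads <- nn_backward(layers, fb$caches, ls$dlogits)
        t_adam <- t_adam + 1L
        upd <- adam_step(layers, grads, opt, config$lr, t_adam,
                         wd = config$weight_decay)
        layers <- upd$layers
        opt <- upd$opt
        tot_loss <- tot_loss + ls$loss * length(idx)
        tot_correct <- tot_correct + ls$correct
      }
      ep_loss <- tot_loss / n
      ep_acc <- tot_correct / n
      log[[epoch]] <- tibble::tibble(epoch = epoch, loss = ep_loss,
                                     window_accuracy = ep_acc)
      if (verbose) {
        message(sprintf("epoch %d: loss %.4f acc %.3f", epoch, ep_loss,
                        ep_acc))
      }
      if (ep_loss < best - config$min_delta) {
        best <- ep_loss
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= config$patience) break
      }
    }
    structure(
      list(config = config, channels = channels, layers = layers,
           seed = seed, training_log = dplyr::bind_rows(log)),
      class = "vbdtw_model"
    )
  })
}

#' @export
print.vbdtw_model <- function(x, ...) {
  lg <- x$training_log
  cat("<vbdtw_model>", x$config$family, "-",
      length(x$channels), "channels x", x$config$input_len, "samples ->",
      x$config$n_classes, "classes\n")
  cat("  trained", nrow(lg), "epochs; final loss",
      signif(lg$loss[nrow(lg)], 4), "window accuracy",
      signif(lg$window_accuracy[nrow(lg)], 4), "\n")
  invisible(x)
}

#' @export
tidy.vbdtw_model <- function(x, ...) x$training_log

#' @export
glance.vbdtw_model <- function(x, ...) {
  lg <- x$training_log
  tibble::tibble(
    family = x$config$family,
    n_channels = length(x$channels),
    epochs = nrow(lg),
    final_loss = lg$loss[nrow(lg)],
    final_window_accuracy = lg$window_accuracy[nrow(lg)],
    seed = x$seed
  )
}

# window-level class probabilities, batched
predict_window_probs <- function(model, X, batch = 256) {
  n <- dim(X)[1]
  P <- matrix(NA_real_, n, model$config$n_classes)
  for (b0 in seq.int(1, n, by = batch)) {
    idx <- b0:min(b0 + batch - 1, n)
    out <- nn_forward(model$layers, X[idx, , , drop = FALSE],
                      training = FALSE)$out
    P[idx, ] <- softmax_rows(out)
  }
  P
}

#' Predict segment labels by majority vote over windows
#'
#' @param model a trained [train_classifier()] model.
#' @param test_set list of [window_slice()] results.
#' @return tibble with one row per parent segment: `parent_id`, `truth`,
#'   `predicted`.
#' @export
predict_segments <- function(model, test_set) {
  if (length(test_set) == 0) {
    abort("empty test set", class = "vbdtw_validation_error")
  }
  stacked <- stack_augmented(test_set, model$channels,
                             center = model$config$center %||% TRUE)
  P <- predict_window_probs(model, stacked$X)
  cls_idx <- max.col(P, ties.method = "first")
  wp <- tibble::tibble(
    parent = stacked$parent,
    class = model$config$class_levels[cls_idx],
    score = P[cbind(seq_len(nrow(P)), cls_idx)]
  )
  voted <- vapply(split(wp[c("class", "score")], wp$parent), majority_vote,
                  integer(1))
  tibble::tibble(
    parent_id = vapply(test_set, function(a) a$parent_id, character(1)),
    truth = stacked$parent_label,
    predicted = voted[as.character(seq_along(test_set))]
  )
}

#' Segment-level accuracy of a trained model
#'
#' Majority-votes each test segment's window predictions and reports the
#' fraction of segments labeled correctly.
#'
#' @inheritParams predict_segments
#' @return numeric accuracy in `[0, 1]`.
#' @export
evaluate_classifier <- function(model, test_set) {
  pr <- predict_segments(model, test_set)
  segment_accuracy(pr$truth, pr$predicted)
}

#' Stratified parent-level train/test split
#'
#' Splits valid segments 80/20 (by default) within each class so that all
#' windows of one parent segment land on the same side (no augmentation
#' leakage). Every class keeps at least one test segment.
#'
#' @param segments list of [valid_segment()] objects.
#' @param prop training proportion (default 0.8).
#' @param seed integer seed.
#' @return list with elements `train` and `test` (lists of segments).
#' @export
split_segments <- function(segments, prop = 0.8, seed = 0) {
  labels <- vapply(segments, function(s) s$motion_class, integer(1))
  withr::with_seed(seed, {
    test_idx <- unlist(lapply(split(seq_along(segments), labels),
                              function(ix) {
      n_test <- max(1L, round((1 - prop) * length(ix)))
      sample(ix, n_test)
    }))
  })
  list(train = segments[-test_idx], test = segments[sort(test_idx)])
}

#' Compare model families across channel sets
#'
#' Trains and evaluates every (family, channel set) combination on the
#' same split and returns one accuracy per cell, the main-results table
#' shape of the pipeline.
#'
#' @param split a [split_segments()] result.
#' @param families character vector of families.
#' @param channel_sets character vector from
#'   `c("acc", "ypr", "acc_ypr")`.
#' @param seed integer seed shared by all cells.
#' @param s window length (default 256).
#' @param config_fn optional function `(family, n_channels, input_len)`
#'   returning a [classifier_config()]; defaults to the reference
#'   configurations.
#' @return tibble with columns `family`, `channels`, `accuracy`.
#' @export
compare_families <- function(split,
                             families = c("dnn", "lstm", "bilstm", "cnn1d"),
                             channel_sets = c("acc", "ypr", "acc_ypr"),
                             seed = 0, s = 256, config_fn = NULL) {
  families <- sort(unique(families))
  channel_sets <- sort(unique(channel_sets))
  train_aug <- lapply(split$train, window_slice, s = s)
  test_aug <- lapply(split$test, window_slice, s = s)
  class_levels <- sort(unique(vapply(split$train,
                                     function(x) x$motion_class,
                                     integer(1))))
  grid <- tidyr::expand_grid(family = families, channels = channel_sets)
  grid$accuracy <- purrr::pmap_dbl(grid, function(family, channels) {
    ch <- channel_set_names(channels)
    cfg <- if (is.null(config_fn)) {
      classifier_config(family, input_channels = length(ch), input_len = s,
                        n_classes = length(class_levels),
                        class_levels = class_levels)
    } else {
      config_fn(family, length(ch), s)
    }
    model <- train_classifier(cfg, train_aug, seed = seed, channels = ch)
    evaluate_classifier(model, test_aug)
  })
  grid
}
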