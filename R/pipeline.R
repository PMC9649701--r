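# End-to-end desk-scale training harness: configuration, the training loop
# over augmented sets (summed cross-entropy + LSFSM objective), head-only
# index training, evaluation, and feature-map export.

#' Experiment configuration
#'
#' Collects every knob of a training run. Defaults are the desk-scale toy
#' protocol; `lsi_fullscale_config()` returns the full-scale preset (N = 6,
#' 384 x 384 crops, 160 epochs, learning-rate decay every 60) for users with
#' real datasets and the compute to match.
#'
#' @param n_classes,n_per_class,image_size Toy dataset parameters (used when
#'   no dataset is supplied to [lsi_train()]).
#' @param n_blocks Blocks per side N.
#' @param angles_original,angles_shuffled Rotation schedule (radians); the
#'   default view set is `{I, I_pi/6, I_pi/4, S}`.
#' @param lambda_sm Weight of the similarity loss in the total objective.
#' @param epochs,batch_size,lr,momentum,lr_decay_every,lr_decay_factor
#'   Optimisation schedule (stochastic gradient descent with momentum).
#' @param backbone_lr_factor Multiplier on `lr` for the backbone parameter
#'   groups; the heads always use `lr` itself. The differential rate keeps
#'   the feature extractor quasi-stationary while the heads fit, the usual
#'   fine-tuning recipe.
#' @param head_warmup_epochs,head_warmup_lr Length and rate of the head
#'   warm-up phase: before joint training, both heads are fitted alone on
#'   the frozen initial backbone's cached features (computed once per view,
#'   so this phase is cheap). Set `head_warmup_epochs = 0` for pure joint
#'   training from the start.
#' @param grad_clip Global gradient-norm ceiling for the joint phase
#'   (`Inf` disables clipping).
#' @param widths Backbone stage widths.
#' @param seed Master seed for weights, shuffles, and batch order.
#' @return An object of class `"lsi_config"`.
#' @export
lsi_config <- function(n_classes = 5L, n_per_class = 10L, image_size = 64L,
                       n_blocks = 2L,
                       angles_original = c(0, pi / 6, pi / 4),
                       angles_shuffled = 0,
                       lambda_sm = 1,
                       epochs = 16L, batch_size = 8L,
                       lr = 0.001, momentum = 0.9,
                       backbone_lr_factor = 0.1,
                       head_warmup_epochs = 80L, head_warmup_lr = 0.05,
                       grad_clip = 5,
                       lr_decay_every = 8L, lr_decay_factor = 0.1,
                       widths = c(8L, 16L, 32L, 64L),
                       seed = 1L) {
  structure(
    list(n_classes = as.integer(n_classes),
         n_per_class = as.integer(n_per_class),
         image_size = as.integer(image_size),
         n_blocks = as.integer(n_blocks),
         angles_original = angles_original,
         angles_shuffled = angles_shuffled,
         lambda_sm = lambda_sm,
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         lr = lr, momentum = momentum,
         backbone_lr_factor = backbone_lr_factor,
         head_warmup_epochs = as.integer(head_warmup_epochs),
         head_warmup_lr = head_warmup_lr,
         grad_clip = grad_clip,
         lr_decay_every = as.integer(lr_decay_every),
         lr_decay_factor = lr_decay_factor,
         widths = as.integer(widths), seed = as.integer(seed)),
    class = "lsi_config"
  )
}

#' Full-scale configuration preset
#'
#' The benchmark-scale protocol: N = 6 blocks, 384 x 384 crops, batch 16,
#' learning rate 0.001 decayed by 10 every 60 epochs for 160 epochs. Shipped
#' for completeness; the desk-scale [lsi_config()] defaults are the tested
#' path.
#'
#' @param ... Overrides forwarded to [lsi_config()].
#' @export
lsi_fullscale_config <- function(...) {
  defaults <- list(image_size = 384L, n_blocks = 6L,
                   epochs = 160L, batch_size = 16L,
                   lr = 0.001, momentum = 0.9, backbone_lr_factor = 1,
                   head_warmup_epochs = 0L,
                   lr_decay_every = 60L, lr_decay_factor = 0.1)
  args <- utils::modifyList(defaults, list(...))
  do.call(lsi_config, args)
}

build_training_sets <- function(dataset, config) {
  schedule <- rotation_schedule(config$angles_original, config$angles_shuffled)
  train_idx <- which(dataset$split == "train")
  lapply(seq_along(train_idx), function(s) {
    i <- train_idx[s]
    build_augmented_set(dataset$images[[i]], dataset$class[i],
                        dataset$n_classes, schedule, config$n_blocks,
                        seed = config$seed + 1000L + s)
  })
}

#' Train the LSI model
#'
#' For every training image an augmented set (rotated originals + rotated
#' shuffled images with their continuous index labels) is built once, then
#' each epoch iterates minibatches of samples, runs the shared backbone
#' forward per view, both heads, both losses, and one SGD-with-momentum step
#' on the batch-averaged gradient of `L_c + lambda_sm * L_sm`. Fully
#' reproducible from the config seed.
#'
#' @param config An [lsi_config()].
#' @param dataset Optional `"toy_dataset"`; generated from the config when
#'   missing.
#' @param verbose Print one line per epoch.
#' @return An object of class `"lsi_run"`: the trained `model`, the `config`,
#'   the `dataset`, and `log` (a data frame with per-epoch `L_c`, `L_sm`,
#'   `total`, and train accuracy in percent).
#' @export
lsi_train <- function(config = lsi_config(), dataset = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "lsi_config"))
  if (is.null(dataset)) {
    dataset <- make_toy_dataset(config$n_classes, config$n_per_class,
                                config$image_size, seed = config$seed)
  }
  asets <- build_training_sets(dataset, config)
  n_train <- length(asets)
  model <- init_lsi_model(dataset$n_classes, config$n_blocks,
                          widths = config$widths, seed = config$seed)
  vel <- zero_like_grads(model$par)
  log <- data.frame(epoch = integer(), L_c = numeric(), L_sm = numeric(),
                    total = numeric(), train_acc = numeric(),
                    phase = character())
  train_images <- dataset$images[dataset$split == "train"]
  train_class <- dataset$class[dataset$split == "train"]

  # Phase 1 (head warm-up): both heads are fitted on the cached features of
  # the frozen initial backbone; one backbone pass per view, then cheap
  # head-only epochs.
  if (config$head_warmup_epochs > 0L) {
    feats <- lapply(asets, function(a) {
      lapply(a$images, function(im) backbone_forward(model, im)$feat)
    })
    plain_feats <- lapply(train_images, function(im) {
      backbone_forward(model, im)$feat
    })
    # Standardise the cached feature channels for the head fit; afterwards
    # the affine standardisation is folded back into the head weights, an
    # exact reparameterisation that leaves the heads operating on raw
    # backbone features. Without it the near-constant common component of
    # the features conditions the head optimisation hopelessly.
    F <- dim(feats[[1L]][[1L]])[3L]
    acc1 <- numeric(F); acc2 <- numeric(F); cnt <- 0
    for (fs in feats) {
      for (f in fs) {
        m <- matrix(f, ncol = F)
        acc1 <- acc1 + colSums(m)
        acc2 <- acc2 + colSums(m^2)
        cnt <- cnt + nrow(m)
      }
    }
    ch_mu <- acc1 / cnt
    ch_sd <- sqrt(pmax(acc2 / cnt - ch_mu^2, 0)) + 1e-8
    standardise <- function(f) {
      m <- sweep(sweep(matrix(f, ncol = F), 2L, ch_mu), 2L, ch_sd, "/")
      array(m, dim = dim(f))
    }
    feats <- lapply(feats, function(fs) lapply(fs, standardise))
    plain_feats <- lapply(plain_feats, standardise)
    head_par <- model$par[c("cls", "idx")]
    head_vel <- zero_like_grads(head_par)
    for (epoch in seq_len(config$head_warmup_epochs)) {
      ord <- with_local_seed(config$seed + epoch, sample.int(n_train))
      ep_lc <- 0; ep_lsm <- 0
      for (start in seq(1L, n_train, by = config$batch_size)) {
        batch <- ord[start:min(start + config$batch_size - 1L, n_train)]
        grads <- zero_like_grads(head_par)
        for (s in batch) {
          a <- asets[[s]]
          for (v in seq_along(a$images)) {
            feat <- feats[[s]][[v]]
            ch <- classification_head(feat, head_par$cls$W, head_par$cls$b)
            ih <- index_head(feat, head_par$idx$W, head_par$idx$b, a$N)
            lab_n <- a$labels[[v]] / a$Z
            ep_lc <- ep_lc - log(max(ch$phi[a$class_label], 1e-12))
            diff <- ih$pred - lab_n
            ep_lsm <- ep_lsm + sum(sqrt(diff[, , 1L]^2 + diff[, , 2L]^2))
            dlogits <- ch$phi
            dlogits[a$class_label] <- dlogits[a$class_label] - 1
            cb <- classification_head_backward(dlogits, ch$cache,
                                               head_par$cls$W)
            ib <- index_head_backward(
              config$lambda_sm * lsfsm_grad(ih$pred, lab_n), ih$cache,
              head_par$idx$W)
            grads$cls$W <- grads$cls$W + cb$dW / length(batch)
            grads$cls$b <- grads$cls$b + cb$db / length(batch)
            grads$idx$W <- grads$idx$W + ib$dW / length(batch)
            grads$idx$b <- grads$idx$b + ib$db / length(batch)
          }
        }
        upd <- sgd_step(head_par, grads, head_vel, config$head_warmup_lr,
                        config$momentum)
        head_par <- upd$par
        head_vel <- upd$vel
      }
      pred <- vapply(plain_feats, function(f) {
        which.max(classification_head(f, head_par$cls$W, head_par$cls$b)$phi)
      }, integer(1L))
      log <- rbind(log, data.frame(
        epoch = epoch, L_c = ep_lc, L_sm = ep_lsm,
        total = total_objective(ep_lc, ep_lsm, config$lambda_sm),
        train_acc = 100 * mean(pred == train_class), phase = "warmup"))
    }
    # fold the standardisation into the head parameters (exact):
    # W'(f, .) = W(f, .) / sd_f ; b' = b - t(W) %*% (mu / sd)
    fold <- function(h) {
      list(W = h$W / ch_sd,
           b = h$b - as.numeric(crossprod(h$W, ch_mu / ch_sd)))
    }
    model$par$cls <- fold(head_par$cls)
    model$par$idx <- fold(head_par$idx)
  }

  for (epoch in seq_len(config$epochs)) {
    lr <- config$lr *
      config$lr_decay_factor^((epoch - 1L) %/% config$lr_decay_every)
    ord <- with_local_seed(config$seed + config$head_warmup_epochs + epoch,
                           sample.int(n_train))
    ep_lc <- 0; ep_lsm <- 0
    for (start in seq(1L, n_train, by = config$batch_size)) {
      batch <- ord[start:min(start + config$batch_size - 1L, n_train)]
      grads <- zero_like_grads(model$par)
      for (s in batch) {
        out <- sample_pass(model, asets[[s]], config$lambda_sm,
                           backward = TRUE)
        if (!is.finite(out$total)) {
          stop(sprintf("non-finite loss at epoch %d, sample %d", epoch, s))
        }
        grads <- add_grads(grads, out$grads, scale = 1 / length(batch))
        ep_lc <- ep_lc + out$L_c
        ep_lsm <- ep_lsm + out$L_sm
      }
      grads <- clip_grads(grads, config$grad_clip)
      lr_groups <- list(conv1 = lr * config$backbone_lr_factor,
                        conv2 = lr * config$backbone_lr_factor,
                        conv3 = lr * config$backbone_lr_factor,
                        conv4 = lr * config$backbone_lr_factor,
                        cls = lr, idx = lr)
      upd <- sgd_step(model$par, grads, vel, lr_groups, config$momentum)
      model$par <- upd$par
      vel <- upd$vel
    }
    acc <- evaluate_images(model, train_images, train_class)$accuracy
    log <- rbind(log, data.frame(epoch = config$head_warmup_epochs + epoch,
                                 L_c = ep_lc, L_sm = ep_lsm,
                                 total = total_objective(ep_lc, ep_lsm,
                                                         config$lambda_sm),
                                 train_acc = acc, phase = "joint"))
    if (verbose) {
      message(sprintf("epoch %3d  L_c %8.3f  L_sm %8.3f  train acc %5.1f%%",
                      epoch, ep_lc, ep_lsm, acc))
    }
  }
  structure(list(model = model, config = config, dataset = dataset, log = log),
            class = "lsi_run")
}

#' @export
print.lsi_run <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  cat(sprintf(
    "LSI training run: %d epochs, final L_c %.3f, L_sm %.3f, train accuracy %.1f%%\n",
    nrow(x$log), last$L_c, last$L_sm, last$train_acc))
  invisible(x)
}

evaluate_images <- function(model, images, classes) {
  pred <- vapply(images, function(im) predict_class(model, im)$class,
                 integer(1L))
  acc <- 100 * mean(pred == classes)
  per_class <- vapply(sort(unique(classes)), function(c) {
    100 * mean(pred[classes == c] == c)
  }, numeric(1L))
  list(accuracy = acc, predictions = pred,
       per_class = stats::setNames(per_class, sort(unique(classes))))
}

#' Evaluate a trained model
#'
#' Top-1 accuracy on plain (unrotated, unshuffled) images; augmentation is
#' training-time only.
#'
#' @param run An [lsi_train()] result (or a bare `"lsi_model"`).
#' @param dataset A `"toy_dataset"`; defaults to the run's own dataset.
#' @param split `"test"`, `"train"`, or `"all"`.
#' @return List with `accuracy` (percent), `predictions`, and `per_class`
#'   accuracies.
#' @export
lsi_evaluate <- function(run, dataset = NULL, split = c("test", "train", "all")) {
  split <- match.arg(split)
  model <- if (inherits(run, "lsi_run")) run$model else run
  if (is.null(dataset)) {
    if (!inherits(run, "lsi_run")) stop("supply a dataset")
    dataset <- run$dataset
  }
  if (model$n_classes != dataset$n_classes) {
    stop("model and dataset class counts differ")
  }
  keep <- if (split == "all") rep(TRUE, length(dataset$images)) else
    dataset$split == split
  evaluate_images(model, dataset$images[keep], dataset$class[keep])
}

#' Train only the index-prediction head on fixed augmented sets
#'
#' Freezes the backbone at its (random) initial weights, precomputes the
#' feature grid of every view once, and fits the index head alone to the
#' normalised block-index labels with SGD on the LSFSM loss. Used to verify
#' that the head can recover the rotation-mapped and shuffle-matched labels.
#'
#' The Euclidean-distance loss has unit-magnitude gradients everywhere,
#' which conditions the tail of head-only optimisation poorly; training
#' therefore runs `warmup` epochs on the smooth squared-distance surrogate
#' first and then fine-tunes on the distance loss itself. The reported error
#' is always the true mean per-block distance.
#'
#' @param model An `"lsi_model"` (its backbone stays frozen).
#' @param asets List of [build_augmented_set()] results.
#' @param epochs,lr,momentum,batch_size Optimisation schedule for the
#'   distance-loss phase.
#' @param warmup Number of squared-distance warm-up epochs.
#' @param warmup_lr Learning rate of the warm-up phase.
#' @param seed Seed for the batch order.
#' @return List with `model` (updated head), `log` (per-epoch mean per-block
#'   distance in normalised units, warm-up included), and `mean_block_error`
#'   (final value).
#' @export
train_index_head <- function(model, asets, epochs = 300L, lr = 0.005,
                             momentum = 0.9, batch_size = 10L,
                             warmup = 0L, warmup_lr = lr, seed = 1L) {
  feats <- lapply(asets, function(aset) {
    lapply(aset$images, function(im) backbone_forward(model, im)$feat)
  })
  labs <- lapply(asets, function(aset) {
    lapply(aset$labels, function(l) l / aset$Z)
  })
  n <- length(asets)
  n_blocks_total <- sum(vapply(asets, function(a) {
    length(a$images) * a$N^2
  }, numeric(1L)))
  par <- model$par["idx"]
  vel <- zero_like_grads(par)
  total_epochs <- warmup + epochs
  log <- numeric(total_epochs)
  for (epoch in seq_len(total_epochs)) {
    squared <- epoch <= warmup
    rate <- if (squared) warmup_lr else lr
    ord <- with_local_seed(seed + epoch, sample.int(n))
    ep_lsm <- 0
    for (start in seq(1L, n, by = batch_size)) {
      batch <- ord[start:min(start + batch_size - 1L, n)]
      gW <- par$idx$W * 0; gb <- par$idx$b * 0
      for (s in batch) {
        for (v in seq_along(feats[[s]])) {
          ih <- index_head(feats[[s]][[v]], par$idx$W, par$idx$b,
                           asets[[s]]$N)
          diff <- ih$pred - labs[[s]][[v]]
          ep_lsm <- ep_lsm + sum(sqrt(diff[, , 1L]^2 + diff[, , 2L]^2))
          dpred <- if (squared) diff else lsfsm_grad(ih$pred, labs[[s]][[v]])
          ib <- index_head_backward(dpred, ih$cache, par$idx$W)
          gW <- gW + ib$dW / length(batch)
          gb <- gb + ib$db / length(batch)
        }
      }
      upd <- sgd_step(par, list(idx = list(W = gW, b = gb)), vel, rate,
                      momentum)
      par <- upd$par
      vel <- upd$vel
    }
    log[epoch] <- ep_lsm / n_blocks_total
  }
  model$par$idx <- par$idx
  list(model = model, log = log, mean_block_error = log[total_epochs])
}

#' Export the backbone feature map of an image
#'
#' Channel-averaged last backbone activation, min-max normalised to [0, 1];
#' a qualitative hook for inspecting where the trained network responds.
#'
#' @param model An `"lsi_model"` (or `"lsi_run"`).
#' @param image Numeric matrix.
#' @param file Optional PNG path to write.
#' @return The normalised feature map matrix, invisibly when writing.
#' @export
export_feature_map <- function(model, image, file = NULL) {
  if (inherits(model, "lsi_run")) model <- model$model
  feat <- backbone_forward(model, image)$feat
  m <- apply(feat, c(1L, 2L), mean)
  rng <- range(m)
  m <- if (rng[2L] > rng[1L]) (m - rng[1L]) / (rng[2L] - rng[1L]) else m * 0
  if (!is.null(file)) {
    png::writePNG(m, file)
    return(invisible(m))
  }
  m
}
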