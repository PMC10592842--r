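#' Training configuration
#'
#' Reproduces the published schedule at configurable scale: Adam
#' (learning rate `lr`), batches of `batch_size` patches, `pretrain_epochs`
#' supervised epochs on the labeled sections followed by `te_epochs` of
#' temporal-ensembling training that also uses unlabeled sections, early
#' stopping on the validation focal loss with the stated `patience`.
#'
#' The ablation switches mirror the published component study:
#' `loss = "ce"` (plain cross-entropy, i.e. focal with `gamma = 0` and no
#' class weight), `loss = "focal"`, plus `use_contrastive` and `use_te`.
#'
#' @param batch_size patches per optimization step (default 8).
#' @param pretrain_epochs supervised epochs `Np` (published value 100).
#' @param te_epochs temporal-ensembling epochs (published value 100).
#' @param ensemble_window ring-buffer length `r`; the pseudo-label is the
#'   thresholded mean of the predictions from the last `r` epochs
#'   (published value 3).
#' @param pseudo_label_threshold threshold on the averaged probability
#'   (strict `>`).
#' @param patience early-stopping patience in epochs (published value 25).
#' @param lr Adam learning rate.
#' @param loss `"focal"` or `"ce"`.
#' @param alpha,gamma focal-loss parameters (published: 0.25, 2).
#' @param use_contrastive train the classification arm with the NT-Xent
#'   contrastive loss.
#' @param use_te enable temporal ensembling in [train_model()].
#' @param tau contrastive temperature (published value 0.5).
#' @param lambda_con weight of the contrastive term in the total
#'   objective (package choice; the published work does not state one).
#' @param n_contrastive_pairs anchors per batch given two views each.
#' @param val_fraction held-out fraction of the labeled patches
#'   (published split 90:10).
#' @param pos_fraction fraction of sampled patches centred on labeled
#'   bundles; the remainder sample background tissue, which controls the
#'   fiber/background pixel imbalance the focal loss is meant to handle.
#' @param patch_size training patch side (pixels).
#' @param n_patches_per_section labeled patches sampled per section.
#' @param n_unlabeled_patches_per_section pseudo-labeled patches sampled
#'   per unlabeled section and epoch.
#' @param unlabeled_ratio unlabeled:labeled patch ratio within a TE epoch.
#' @param seed master seed; all stage seeds are derived from it.
#' @return `ft_train_config` list.
#' @export
train_config <- function(batch_size = 8L, pretrain_epochs = 100L,
                         te_epochs = 100L, ensemble_window = 3L,
                         pseudo_label_threshold = 0.5, patience = 25L,
                         lr = 1e-3, loss = c("focal", "ce"),
                         alpha = 0.25, gamma = 2,
                         use_contrastive = TRUE, use_te = TRUE,
                         tau = 0.5, lambda_con = 1.0,
                         n_contrastive_pairs = 4L,
                         val_fraction = 0.1, pos_fraction = 0.5,
                         patch_size = 256L,
                         n_patches_per_section = 40L,
                         n_unlabeled_patches_per_section = 10L,
                         unlabeled_ratio = 1.0, seed = 1L) {
  loss <- match.arg(loss)
  stopifnot(ensemble_window >= 1, patience >= 1,
            pseudo_label_threshold > 0, pseudo_label_threshold < 1)
  structure(as.list(environment()), class = "ft_train_config")
}

# focal parameters implied by the loss mode
loss_params <- function(config) {
  if (config$loss == "ce") {
    list(alpha = 0.25, gamma = 0, alpha_weighting = FALSE)
  } else {
    list(alpha = config$alpha, gamma = config$gamma, alpha_weighting = TRUE)
  }
}

# stack patches into the [H,W,3,N] input and [H,W,N] target arrays
assemble_batch <- function(patches) {
  sz <- dim(patches[[1]]$pixels)[1]
  n <- length(patches)
  x <- array(0, c(sz, sz, 3L, n))
  y <- array(0, c(sz, sz, n))
  for (i in seq_len(n)) {
    x[, , , i] <- patches[[i]]$pixels / 255
    tg <- patches[[i]]$target
    if (!is.null(tg)) y[, , i] <- (tg > 0) * 1
  }
  list(x = x, y = y)
}

# two contrastive views per anchor -> [H,W,3,2n] with consecutive pairs
assemble_contrastive <- function(anchors, sections, section_ids,
                                 augment_cfg) {
  sz <- dim(anchors[[1]]$pixels)[1]
  n <- length(anchors)
  xc <- array(0, c(sz, sz, 3L, 2L * n))
  for (i in seq_len(n)) {
    sec <- sections[[section_ids[i]]]
    v1 <- positive_crop(sec, anchors[[i]], augment_cfg)
    v2 <- perturb(anchors[[i]], augment_cfg)
    xc[, , , 2 * i - 1] <- v1$pixels / 255
    xc[, , , 2 * i] <- v2$pixels / 255
  }
  xc
}

# one optimization epoch over a patch pool; returns mean losses
run_epoch <- function(model, pool, sections, config, augment_cfg,
                      epoch_seed) {
  lp <- loss_params(config)
  with_seed(epoch_seed, {
    ord <- sample.int(length(pool$patches))
    n_batches <- max(1L, floor(length(ord) / config$batch_size))
    ls <- lc <- numeric(0)
    for (b in seq_len(n_batches)) {
      take <- ord[((b - 1) * config$batch_size + 1):(b * config$batch_size)]
      patches <- pool$patches[take]
      if (!is.null(augment_cfg)) {
        patches <- lapply(patches, geometric_augment, config = augment_cfg)
      }
      bt <- assemble_batch(patches)
      xc <- NULL
      if (config$use_contrastive) {
        n_anchor <- min(config$n_contrastive_pairs, length(take))
        sel <- take[seq_len(n_anchor)]
        xc <- assemble_contrastive(pool$patches[sel], sections,
                                   pool$section_id[sel],
                                   augment_cfg %||% augment_config())
      }
      res <- net_train_step(model$ptr, bt$x, bt$y, lp$alpha, lp$gamma,
                            lp$alpha_weighting, xc, config$tau,
                            config$lambda_con, NULL, NULL, 0,
                            config$lr, TRUE)
      if (!is.finite(res$loss_seg)) {
        abort("training diverged (non-finite loss)", class = "ft_divergence")
      }
      ls <- c(ls, res$loss_seg)
      if (!is.null(xc)) lc <- c(lc, res$loss_con)
    }
    list(loss_seg = mean(ls),
         loss_con = if (length(lc)) mean(lc) else NA_real_)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluation-mode focal loss over a patch pool
val_loss <- function(model, patches, config) {
  if (!length(patches)) return(NA_real_)
  lp <- loss_params(config)
  bt <- assemble_batch(patches)
  net_eval_focal(model$ptr, bt$x, bt$y, lp$alpha, lp$gamma,
                 lp$alpha_weighting)
}

# build the labeled patch pool with a train/validation split
build_pool <- function(sections, annotations, config, seed) {
  patches <- list()
  ids <- integer(0)
  for (i in seq_along(sections)) {
    if (is.null(annotations[[i]]) || !any(annotations[[i]] > 0)) next
    ps <- sample_training_patches(sections[[i]], annotations[[i]],
                                  config$n_patches_per_section,
                                  pos_fraction = config$pos_fraction,
                                  seed = seed + i,
                                  size = config$patch_size)
    patches <- c(patches, ps)
    ids <- c(ids, rep(i, length(ps)))
  }
  if (!length(patches)) {
    abort("no labeled patches available for training",
          class = "ft_validation_error")
  }
  n_val <- max(1L, round(config$val_fraction * length(patches)))
  val_idx <- with_seed(seed, sample.int(length(patches), n_val))
  list(train = list(patches = patches[-val_idx],
                    section_id = ids[-val_idx]),
       val = patches[val_idx])
}

#' Supervised pretraining on manually charted sections
#'
#' Optimizes the focal loss on `FSeg` and (optionally) the contrastive
#' loss on `FClass` for every batch, logs per-epoch training and
#' validation losses, keeps the best-validation parameters, and stops
#' early after `patience` epochs without improvement.
#'
#' @param model an `ft_model` (modified in place and returned).
#' @param sections list of labeled `ft_section`s.
#' @param annotations list of label matrices aligned to `sections`.
#' @param config an [train_config()].
#' @param augment_cfg an [augment_config()] (or `NULL` to disable
#'   geometric augmentation).
#' @return `list(model, history)` where `history` is a tibble of per-epoch
#'   losses.
#' @export
pretrain <- function(model, sections, annotations, config = train_config(),
                     augment_cfg = augment_config()) {
  pool <- build_pool(sections, annotations, config, config$seed)
  hist <- list()
  best <- list(loss = Inf, state = model_state(model), epoch = 0L)
  wait <- 0L
  for (e in seq_len(config$pretrain_epochs)) {
    tr <- run_epoch(model, pool$train, sections, config, augment_cfg,
                    epoch_seed = config$seed * 1000L + e)
    vl <- val_loss(model, pool$val, config)
    hist[[e]] <- tibble(epoch = e, phase = "pretrain",
                        loss_seg = tr$loss_seg, loss_con = tr$loss_con,
                        val_loss = vl)
    if (is.finite(vl) && vl < best$loss) {
      best <- list(loss = vl, state = model_state(model), epoch = e)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  model_restore(model, best$state)
  model$epoch <- model$epoch + length(hist)
  net_set_epoch(model$ptr, model$epoch)
  list(model = model, history = dplyr::bind_rows(hist))
}

#' Ring buffer of per-section prediction history
#'
#' Stores the probability maps of the last `r` epochs for one unlabeled
#' section; the temporal-ensembling pseudo-label is the thresholded
#' pixelwise mean of its contents.
#'
#' @param r window length (`>= 1`).
#' @return An `ft_pred_history`.
#' @export
pred_history <- function(r = 3L) {
  stopifnot(r >= 1)
  structure(list(maps = list(), r = as.integer(r)), class = "ft_pred_history")
}

#' @rdname pred_history
#' @param history an `ft_pred_history`.
#' @param map probability-map matrix to append (evicts the oldest entry
#'   once `r` maps are stored).
#' @export
push_prediction <- function(history, map) {
  if (length(history$maps) &&
      !identical(dim(history$maps[[1]]), dim(map))) {
    abort("prediction map shape differs from the buffered maps",
          class = "ft_validation_error")
  }
  history$maps <- c(history$maps, list(map))
  if (length(history$maps) > history$r) {
    history$maps <- history$maps[-1]
  }
  history
}

#' Build a temporal-ensembling pseudo-label
#'
#' Pixelwise arithmetic mean of the buffered probability maps, thresholded
#' with a strict `>` (a pixel whose averaged probability equals the
#' threshold exactly is labeled background).
#'
#' @param history an `ft_pred_history` with at least one map.
#' @param threshold probability threshold.
#' @return Binary (0/1) matrix.
#' @export
make_pseudo_label <- function(history, threshold = 0.5) {
  if (!length(history$maps)) {
    abort("empty prediction history", class = "ft_validation_error")
  }
  avg <- Reduce(`+`, history$maps) / length(history$maps)
  (avg > threshold) * 1
}

#' Semi-supervised temporal-ensembling training
#'
#' Each epoch: the current model's predictions on every unlabeled section
#' are refreshed and pushed into that section's ring buffer; pseudo-labels
#' are built (for the first three epochs after pretraining, directly from
#' the pretrained model's predictions); patches sampled from the
#' pseudo-labeled sections are mixed with labeled patches; and the focal
#' (+ contrastive) objective is optimized. Early stopping monitors the
#' labeled validation loss. With an empty unlabeled pool the procedure
#' reduces to continued supervised training.
#'
#' @inheritParams pretrain
#' @param unlabeled_sections list of `ft_section`s without annotations.
#' @return `list(model, history)`.
#' @export
train_temporal_ensembling <- function(model, sections, annotations,
                                      unlabeled_sections,
                                      config = train_config(),
                                      augment_cfg = augment_config()) {
  pool <- build_pool(sections, annotations, config, config$seed + 7919L)
  nu <- length(unlabeled_sections)
  buffers <- lapply(seq_len(nu), function(i) pred_history(config$ensemble_window))
  p_np <- lapply(unlabeled_sections, function(s) forward_seg(model, s$image))
  hist <- list()
  best <- list(loss = Inf, state = model_state(model), epoch = 0L)
  wait <- 0L
  for (e in seq_len(config$te_epochs)) {
    # refresh predictions and ring buffers
    if (nu > 0) {
      for (i in seq_len(nu)) {
        pred <- forward_seg(model, unlabeled_sections[[i]]$image)
        buffers[[i]] <- push_prediction(buffers[[i]], pred)
      }
    }
    # pseudo-labeled patch pool for this epoch
    epoch_pool <- pool$train
    if (nu > 0) {
      n_unl <- config$n_unlabeled_patches_per_section
      budget <- round(config$unlabeled_ratio * length(pool$train$patches))
      un_patches <- list(); un_ids <- integer(0)
      for (i in seq_len(nu)) {
        src <- if (e <= 3) p_np[[i]] else
          Reduce(`+`, buffers[[i]]$maps) / length(buffers[[i]]$maps)
        pl <- (src > config$pseudo_label_threshold) * 1
        if (!any(pl > 0)) next
        ps <- sample_training_patches(unlabeled_sections[[i]], pl, n_unl,
                                      pos_fraction = 0.5,
                                      size = config$patch_size,
                                      seed = config$seed + 31L * e + i)
        un_patches <- c(un_patches, ps)
        un_ids <- c(un_ids, rep(i, length(ps)))
      }
      if (length(un_patches) > budget) {
        keep <- with_seed(config$seed + e,
                          sample.int(length(un_patches), budget))
        un_patches <- un_patches[keep]
        un_ids <- un_ids[keep]
      }
      epoch_pool <- list(
        patches = c(pool$train$patches, un_patches),
        section_id = c(pool$train$section_id,
                       length(sections) + un_ids))
    }
    all_sections <- c(sections, unlabeled_sections)
    tr <- run_epoch(model, epoch_pool, all_sections, config, augment_cfg,
                    epoch_seed = config$seed * 2000L + e)
    vl <- val_loss(model, pool$val, config)
    hist[[e]] <- tibble(epoch = e, phase = "te",
                        loss_seg = tr$loss_seg, loss_con = tr$loss_con,
                        val_loss = vl)
    if (is.finite(vl) && vl < best$loss) {
      best <- list(loss = vl, state = model_state(model), epoch = e)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  model_restore(model, best$state)
  model$epoch <- model$epoch + length(hist)
  net_set_epoch(model$ptr, model$epoch)
  list(model = model, history = dplyr::bind_rows(hist))
}

#' Full training pipeline (pretraining + optional temporal ensembling)
#'
#' @inheritParams train_temporal_ensembling
#' @return `list(model, history)` with the concatenated phase histories.
#' @export
train_model <- function(model, sections, annotations,
                        unlabeled_sections = list(),
                        config = train_config(),
                        augment_cfg = augment_config()) {
  pre <- pretrain(model, sections, annotations, config, augment_cfg)
  model <- pre$model
  hist <- pre$history
  if (config$use_te && config$te_epochs > 0) {
    te <- train_temporal_ensembling(model, sections, annotations,
                                    unlabeled_sections, config, augment_cfg)
    model <- te$model
    hist <- dplyr::bind_rows(hist, te$history)
  }
  list(model = model, history = hist)
}
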