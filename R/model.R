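#' Configuration of the multi-task segmentation model
#'
#' The model couples a U-Net backbone (`FSeg`, per-pixel fiber-probability
#' maps through a two-class softmax) with an auxiliary classification/
#' embedding arm (`FClass`) that reads the encoder bottleneck, passes it
#' through two (max-pool + two 3x3 convolution) stages, flattens, and
#' applies two fully connected layers followed by a two-node output
#' (fiber bundle vs background). The penultimate fully connected
#' activation is the embedding used by the contrastive loss. Encoder
#' weights are shared between the two arms, which is what lets the
#' self-supervised loss shape the segmentation features.
#'
#' @param depth number of encoder levels (the last is the bottleneck).
#' @param base_channels channels of the first level; doubled per level.
#'   Reducible (down to 4) for CPU-scale training.
#' @param in_channels input channels (3 for RGB sections).
#' @param seg_classes segmentation classes (2: fiber vs background).
#' @param fc_sizes sizes of the two fully connected layers.
#' @param class_out classification output nodes.
#' @param patch_size training patch side; must be divisible by
#'   `2^(depth + 1)` so the classification arm's two extra poolings fit.
#' @param seed seed for parameter initialization.
#' @return `ft_model_config` list.
#' @export
model_config <- function(depth = 4L, base_channels = 64L, in_channels = 3L,
                         seg_classes = 2L, fc_sizes = c(1024L, 256L),
                         class_out = 2L, patch_size = 256L, seed = 1L) {
  if (depth < 2 || base_channels < 4 || any(fc_sizes < 1)) {
    abort("invalid model config (need depth >= 2, base_channels >= 4)",
          class = "ft_validation_error")
  }
  if (patch_size %% 2^(depth + 1) != 0) {
    abort(sprintf("patch_size must be divisible by 2^(depth+1) = %d",
                  2^(depth + 1)), class = "ft_validation_error")
  }
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 in_channels = as.integer(in_channels),
                 seg_classes = as.integer(seg_classes),
                 fc_sizes = as.integer(fc_sizes),
                 class_out = as.integer(class_out),
                 patch_size = as.integer(patch_size),
                 seed = as.integer(seed)),
            class = "ft_model_config")
}

#' Build the multi-task model
#'
#' Parameter initialization is fully seeded: two builds from the same
#' config are bit-identical.
#'
#' @param config an [model_config()].
#' @return An `ft_model` handle (opaque parameter container + config echo
#'   + training-epoch counter).
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "ft_model_config"))
  ptr <- net_create(config$depth, config$base_channels, config$in_channels,
                    config$seg_classes, config$patch_size,
                    config$fc_sizes[1], config$fc_sizes[2],
                    config$class_out, config$seed)
  structure(list(ptr = ptr, config = config, epoch = 0L),
            class = "ft_model")
}

#' @export
print.ft_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<ft_model> U-Net depth %d, base %d ch + class arm fc(%d,%d); %s params; epoch %d\n",
    cfg$depth, cfg$base_channels, cfg$fc_sizes[1], cfg$fc_sizes[2],
    format(net_n_params(x$ptr), big.mark = ","), x$epoch))
  invisible(x)
}

# coerce inputs to a [H,W,C,N] batch on the network's 0-1 scale
as_batch <- function(x, in_channels = 3L) {
  if (inherits(x, "ft_patch")) x <- x$pixels
  if (is.list(x)) {
    x <- vapply(x, function(p) {
      if (inherits(p, "ft_patch")) p <- p$pixels
      p
    }, FUN.VALUE = array(0, dim(if (inherits(x[[1]], "ft_patch"))
      x[[1]]$pixels else x[[1]])))
  }
  d <- dim(x)
  if (length(d) == 2) x <- array(x, c(d, 1L, 1L))
  else if (length(d) == 3 && d[3] == in_channels) x <- array(x, c(d, 1L))
  else if (length(d) == 3) {  # H x W x N grayscale stack
    x <- array(apply(x, 3, function(m) array(rep(m, in_channels),
                                             c(d[1:2], in_channels))),
               c(d[1:2], in_channels, d[3]))
  }
  if (max(x) > 1.5) x <- x / 255
  x
}

#' Segmentation forward pass
#'
#' Runs `FSeg` in evaluation mode (deterministic; normalization layers use
#' their running statistics) and returns the fiber-class probability
#' channel. The two softmax channels sum to one by construction.
#'
#' @param model an `ft_model`.
#' @param batch patches: one `H x W x 3` array, a list of patches, or a
#'   `[H, W, 3, N]` array. Values on the 0-255 or 0-1 scale.
#' @param train use batch statistics (training mode) instead of running
#'   statistics. Default `FALSE`.
#' @return `H x W` matrix (single input) or `H x W x N` array of fiber
#'   probabilities in `[0, 1]`.
#' @export
forward_seg <- function(model, batch, train = FALSE) {
  x <- as_batch(batch, model$config$in_channels)
  d <- dim(x)
  if (d[1] %% 2^(model$config$depth - 1) != 0 ||
      d[2] %% 2^(model$config$depth - 1) != 0) {
    abort(sprintf("input size must be divisible by 2^(depth-1) = %d",
                  2^(model$config$depth - 1)), class = "ft_validation_error")
  }
  p <- net_forward_seg(model$ptr, x, train)
  fiber <- p[, , 2, , drop = FALSE]
  if (d[4] == 1) matrix(fiber, d[1], d[2]) else array(fiber, c(d[1], d[2], d[4]))
}

#' Classification-arm forward pass
#'
#' @inheritParams forward_seg
#' @return `list(logits = N x 2 matrix, embedding = N x fc2 matrix)`; the
#'   embedding row is the penultimate fully connected activation used by
#'   the contrastive loss.
#' @export
forward_class <- function(model, batch, train = FALSE) {
  x <- as_batch(batch, model$config$in_channels)
  if (dim(x)[1] != model$config$patch_size ||
      dim(x)[2] != model$config$patch_size) {
    abort("classification arm requires patches of the configured patch_size",
          class = "ft_validation_error")
  }
  net_forward_class(model$ptr, x, train)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single serialized container (format version 1)
#' holding the config echo, the flat parameter vector, the normalization
#' layers' running statistics, and the epoch counter.
#'
#' @param model an `ft_model`.
#' @param path checkpoint file path (`.rds`).
#' @return `path` / the restored `ft_model`.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(format = 1L, config = unclass(model$config),
               params = net_get_params(model$ptr),
               bn_stats = net_get_bn_stats(model$ptr),
               epoch = model$epoch),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, 1L)) {
    abort("unknown checkpoint format", class = "ft_io_error")
  }
  cfg <- structure(ck$config, class = "ft_model_config")
  model <- build_model(cfg)
  net_set_params(model$ptr, ck$params)
  net_set_bn_stats(model$ptr, ck$bn_stats)
  model$epoch <- ck$epoch
  model
}

# snapshot/restore parameters in memory (best-model bookkeeping)
model_state <- function(model) {
  list(params = net_get_params(model$ptr),
       bn_stats = net_get_bn_stats(model$ptr))
}

model_restore <- function(model, state) {
  net_set_params(model$ptr, state$params)
  net_set_bn_stats(model$ptr, state$bn_stats)
  invisible(model)
}
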