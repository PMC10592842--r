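#' Augmentation configuration
#'
#' Houses the two contrastive augmentations — (i) an anatomy-constrained
#' nearby crop (centre displaced by less than `crop_max_offset_um`,
#' accepted only if the crop's mean intensity falls inside the
#' white-matter band, with iterative resampling) and (ii) noise injection
#' followed by Gaussian blurring — plus the geometric augmentation ranges
#' used for segmentation training.
#'
#' The blur sigma is interpreted in pixels, and the white-matter mean
#' intensity band is calibrated per dataset (the default suits the
#' synthetic dark-field profile: anything clearly above slide background).
#'
#' @param crop_max_offset_um maximum centre displacement of the positive
#'   crop (micrometres).
#' @param wm_mean_intensity_range `(lo, hi)` acceptance band for the mean
#'   patch intensity (0-255 scale).
#' @param max_crop_retries resampling attempts before falling back to the
#'   anchor patch itself.
#' @param blur_sigma_range Gaussian blur sigma range (pixels).
#' @param noise_sd zero-mean Gaussian noise s.d. on the 0-1 intensity
#'   scale.
#' @param translation_range_px,rotation_range_deg,scale_range,flips
#'   geometric augmentation ranges for segmentation training.
#' @return `ft_augment_config` list.
#' @export
augment_config <- function(crop_max_offset_um = 20,
                           wm_mean_intensity_range = c(12, 200),
                           max_crop_retries = 10L,
                           blur_sigma_range = c(0.05, 0.3),
                           noise_sd = 0.05,
                           translation_range_px = c(-50, 50),
                           rotation_range_deg = c(-20, 20),
                           scale_range = c(0.9, 1.2),
                           flips = TRUE) {
  stopifnot(crop_max_offset_um > 0, max_crop_retries >= 1,
            blur_sigma_range[1] <= blur_sigma_range[2],
            wm_mean_intensity_range[1] <= wm_mean_intensity_range[2],
            scale_range[1] <= scale_range[2])
  structure(as.list(environment()), class = "ft_augment_config")
}

#' Sample training patches from an annotated section
#'
#' `pos_fraction` of the patches are centred on randomly chosen labeled
#' bundle pixels (class label `"fiber"`); the rest are centred on
#' unlabeled tissue (`"background"`). Patch origins are clamped so every
#' patch lies fully inside the section. Deterministic given `seed`.
#'
#' @param section an `ft_section`.
#' @param annotation integer label matrix on the section grid (0 =
#'   background), or `NULL` for unlabeled sections (requires
#'   `pos_fraction = 0`).
#' @param n number of patches.
#' @param pos_fraction fraction of fiber-centred patches.
#' @param size patch side length (pixels).
#' @param seed integer seed.
#' @return List of `ft_patch` with `target` (binary) and `class_label`
#'   set.
#' @export
sample_training_patches <- function(section, annotation, n,
                                    pos_fraction = 0.5, size = 256L,
                                    seed = 1L) {
  d <- dim(section$image)
  if (d[1] < size || d[2] < size) {
    abort("section smaller than patch size", class = "ft_range_error")
  }
  n_pos <- round(n * pos_fraction)
  if (n_pos > 0 && (is.null(annotation) || !any(annotation > 0))) {
    abort("pos_fraction > 0 requires labeled pixels",
          class = "ft_validation_error")
  }
  tissue <- section$tissue_mask
  if (is.null(tissue)) tissue <- compute_tissue_mask(section)
  bg_ok <- tissue & (if (is.null(annotation)) TRUE else annotation == 0)
  target <- if (is.null(annotation)) matrix(0, d[1], d[2])
            else (annotation > 0) * 1
  with_seed(seed, {
    pos_idx <- if (n_pos > 0) which(annotation > 0, arr.ind = TRUE)
    bg_idx <- which(bg_ok, arr.ind = TRUE)
    out <- vector("list", n)
    for (i in seq_len(n)) {
      pos <- i <= n_pos
      src <- if (pos) pos_idx else bg_idx
      ctr <- src[sample.int(nrow(src), 1L), ]
      r0 <- min(max(ctr[1] - size %/% 2, 1L), d[1] - size + 1L) - 1L
      c0 <- min(max(ctr[2] - size %/% 2, 1L), d[2] - size + 1L) - 1L
      p <- extract_patch(section, c(r0, c0), size, target = target)
      p$class_label <- if (pos) "fiber" else "background"
      out[[i]] <- p
    }
    out
  })
}

#' Anatomy-constrained positive crop
#'
#' Draws a patch whose centre lies within `crop_max_offset_um` of the
#' anchor's centre and whose mean intensity falls inside the configured
#' white-matter band, resampling up to `max_crop_retries` times and then
#' falling back to the anchor itself (the fallback is recorded in the
#' `"fallback"` attribute, so acceptance statistics can be audited).
#'
#' @param section the `ft_section` the anchor came from.
#' @param anchor_patch an `ft_patch`.
#' @param config an [augment_config()].
#' @return An `ft_patch`; attribute `"fallback"` is `TRUE` when the
#'   anchor was returned.
#' @export
positive_crop <- function(section, anchor_patch, config = augment_config()) {
  size <- dim(anchor_patch$pixels)[1]
  d <- dim(section$image)
  max_off_px <- config$crop_max_offset_um / section$um_per_px
  band <- config$wm_mean_intensity_range
  for (t in seq_len(config$max_crop_retries)) {
    ang <- runif(1, 0, 2 * pi)
    rad <- max_off_px * sqrt(runif(1))
    # truncate toward zero so the pixel-grid displacement never exceeds
    # the physical bound
    dr <- trunc(rad * cos(ang)); dc <- trunc(rad * sin(ang))
    r0 <- anchor_patch$origin[["row"]] + dr
    c0 <- anchor_patch$origin[["col"]] + dc
    r0 <- min(max(r0, 0L), d[1] - size)
    c0 <- min(max(c0, 0L), d[2] - size)
    cand <- extract_patch(section, c(r0, c0), size)
    m <- mean(cand$pixels)
    if (m >= band[1] && m <= band[2]) {
      attr(cand, "fallback") <- FALSE
      return(cand)
    }
  }
  out <- anchor_patch
  attr(out, "fallback") <- TRUE
  out
}

#' Noise-then-blur perturbation
#'
#' Adds zero-mean Gaussian noise (s.d. `noise_sd` on the 0-1 scale), then
#' Gaussian-blurs with a sigma drawn uniformly from `blur_sigma_range`
#' (pixels) — in exactly that order, so the blur partially smooths the
#' injected noise. Output is clipped to the valid intensity range.
#'
#' @param patch an `ft_patch`.
#' @param config an [augment_config()].
#' @return The perturbed `ft_patch`.
#' @export
perturb <- function(patch, config = augment_config()) {
  px <- patch$pixels / 255
  d <- dim(px)
  if (config$noise_sd > 0) {
    px <- px + array(rnorm(prod(d), 0, config$noise_sd), d)
  }
  sigma <- runif(1, config$blur_sigma_range[1], config$blur_sigma_range[2])
  if (sigma > 0.01) {
    for (ch in seq_len(d[3])) {
      px[, , ch] <- gaussian_blur(px[, , ch], sigma)
    }
  }
  px <- pmin(pmax(px, 0), 1)
  patch$pixels <- px * 255
  patch
}

# separable Gaussian blur with reflective boundaries
gaussian_blur <- function(m, sigma) {
  rad <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-rad, rad))^2 / (2 * sigma^2))
  k <- k / sum(k)
  n <- nrow(m); p <- ncol(m)
  ext_r <- reflect_index(seq.int(1 - rad, n + rad), n)
  ext_c <- reflect_index(seq.int(1 - rad, p + rad), p)
  me <- m[ext_r, , drop = FALSE]
  v <- matrix(0, n, p)
  for (j in seq_along(k)) v <- v + k[j] * me[j:(j + n - 1), , drop = FALSE]
  ve <- v[, ext_c, drop = FALSE]
  out <- matrix(0, n, p)
  for (j in seq_along(k)) out <- out + k[j] * ve[, j:(j + p - 1), drop = FALSE]
  out
}

#' Geometric augmentation for segmentation training
#'
#' Applies one random rigid + scale transform (translation, rotation,
#' horizontal/vertical flips, isotropic scaling) identically to the patch
#' and its target mask. The image is resampled bilinearly; the mask with
#' nearest neighbour, so it stays strictly binary. The drawn parameters
#' are recorded in the `"transform"` attribute.
#'
#' @param patch an `ft_patch` (its `target` is transformed alongside when
#'   present).
#' @param config an [augment_config()].
#' @return The augmented `ft_patch`.
#' @export
geometric_augment <- function(patch, config = augment_config()) {
  d <- dim(patch$pixels)
  tr <- list(
    dr = round(runif(1, config$translation_range_px[1],
                     config$translation_range_px[2])),
    dc = round(runif(1, config$translation_range_px[1],
                     config$translation_range_px[2])),
    theta = runif(1, config$rotation_range_deg[1],
                  config$rotation_range_deg[2]) * pi / 180,
    scale = runif(1, config$scale_range[1], config$scale_range[2]),
    flip_h = config$flips && runif(1) < 0.5,
    flip_v = config$flips && runif(1) < 0.5)
  img <- apply_geom(patch$pixels, tr, bilinear = TRUE)
  patch$pixels <- img
  if (!is.null(patch$target)) {
    tg <- apply_geom(array(patch$target, c(d[1], d[2], 1L)), tr,
                     bilinear = FALSE)
    patch$target <- (tg[, , 1] > 0.5) * 1
  }
  attr(patch, "transform") <- tr
  patch
}

# centre-anchored affine resampling (rotation+scale+translation+flips);
# inverse mapping with bilinear or nearest interpolation, zero fill
apply_geom <- function(arr, tr, bilinear = TRUE) {
  warp_affine_cpp(arr, tr$dr, tr$dc, tr$theta, tr$scale,
                  tr$flip_h, tr$flip_v, bilinear)
}
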