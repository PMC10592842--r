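#' Inference and post-processing configuration
#'
#' @param tile_size side of the square inference tiles used for sections
#'   larger than one tile (published value 1024).
#' @param tile_overlap overlap between adjacent tiles (pixels);
#'   probabilities are averaged where tiles overlap.
#' @param prob_threshold probability threshold for binarization, strict
#'   `>` (published operating point 0.4).
#' @param connectivity connected-component connectivity (8).
#' @param min_area_mm2 regions strictly smaller than this are rejected
#'   (published value 2 mm^2).
#' @param border_margin_mm regions strictly closer than this to the brain
#'   outline are rejected (published value 0.5 mm).
#' @param continuity_max_dist_mm regions strictly farther than this from
#'   the averaged neighbouring-section bundle masks are rejected
#'   (published value 0.5 mm).
#' @param lowres_factor downsampling factor of the continuity prior
#'   (published value 10).
#' @param align_max_shift_px translation search radius (low-resolution
#'   pixels) of the coarse stack alignment.
#' @param dense_quantile the model-based low-resolution segmenter keeps
#'   regions whose mean probability reaches this quantile (selecting the
#'   main dense bundles).
#' @return `ft_inference_config` list.
#' @export
inference_config <- function(tile_size = 1024L, tile_overlap = 64L,
                             prob_threshold = 0.4, connectivity = 8L,
                             min_area_mm2 = 2.0, border_margin_mm = 0.5,
                             continuity_max_dist_mm = 0.5,
                             lowres_factor = 10L,
                             align_max_shift_px = 8L,
                             dense_quantile = 0.5) {
  stopifnot(prob_threshold > 0, prob_threshold < 1,
            connectivity %in% c(4L, 8L), tile_size > tile_overlap)
  structure(as.list(environment()), class = "ft_inference_config")
}

# pad a matrix/array to target dims by mirror reflection
pad_reflect <- function(img, H2, W2) {
  d <- dim(img)
  rows <- reflect_index(seq_len(H2), d[1])
  cols <- reflect_index(seq_len(W2), d[2])
  if (length(d) == 2) img[rows, cols] else img[rows, cols, , drop = FALSE]
}

#' Whole-section tiled inference
#'
#' Applies the segmentation arm to the whole section, or to overlapping
#' square tiles when the section exceeds `tile_size`; probabilities are
#' averaged in tile overlaps, so stitching introduces no seams. Sections
#' are reflection-padded to the U-Net's stride multiple and cropped back.
#' Deterministic in evaluation mode.
#'
#' @param model trained `ft_model`.
#' @param section an `ft_section`.
#' @param config an [inference_config()].
#' @return `H x W` fiber-probability matrix.
#' @export
segment_section <- function(model, section, config = inference_config()) {
  img <- section$image / 255
  d <- dim(img)
  mult <- 2^(model$config$depth - 1)
  H2 <- ceiling(d[1] / mult) * mult
  W2 <- ceiling(d[2] / mult) * mult
  padded <- pad_reflect(img, H2, W2)
  if (H2 <= config$tile_size && W2 <= config$tile_size) {
    prob <- forward_seg(model, padded)
  } else {
    stride <- config$tile_size - config$tile_overlap
    starts <- function(total) {
      if (total <= config$tile_size) return(0L)
      s <- seq(0L, total - config$tile_size, by = stride)
      if (s[length(s)] + config$tile_size < total) {
        s <- c(s, total - config$tile_size)
      }
      unique(s)
    }
    acc <- matrix(0, H2, W2)
    wgt <- matrix(0, H2, W2)
    for (r0 in starts(H2)) {
      for (c0 in starts(W2)) {
        rows <- (r0 + 1):(r0 + config$tile_size)
        cols <- (c0 + 1):(c0 + config$tile_size)
        tile <- padded[rows, cols, , drop = FALSE]
        p <- forward_seg(model, tile)
        acc[rows, cols] <- acc[rows, cols] + p
        wgt[rows, cols] <- wgt[rows, cols] + 1
      }
    }
    prob <- acc / wgt
  }
  prob[seq_len(d[1]), seq_len(d[2])]
}

#' Extract candidate bundle regions from a probability map
#'
#' Binarizes at `prob_threshold` (strict `>`), labels connected components
#' under the configured connectivity, and tabulates one region per
#' component. The pixel-level label map travels in the `"label_map"`
#' attribute; filter provenance flags start out all-`FALSE` so each
#' subsequent filter annotates rather than deletes (regions are never
#' dropped from the audit trail).
#'
#' @param prob_map probability matrix in `[0, 1]`.
#' @param section the `ft_section` the map belongs to (for physical scale).
#' @param config an [inference_config()].
#' @return A tibble of class `ft_regions`: `region_id`, `section_index`,
#'   `n_px`, `area_mm2`, `centroid_r`, `centroid_c` (0-based pixels),
#'   `mean_prob`, and logical flags `filtered_area`, `filtered_border`,
#'   `filtered_continuity`.
#' @export
extract_regions <- function(prob_map, section, config = inference_config()) {
  stopifnot(min(prob_map) >= 0, max(prob_map) <= 1)
  bin <- prob_map > config$prob_threshold
  lab <- label_components(bin, config$connectivity)
  k <- max(lab)
  rows <- vector("list", k)
  for (i in seq_len(k)) {
    idx <- which(lab == i, arr.ind = TRUE)
    rows[[i]] <- tibble(
      region_id = i,
      section_index = section$section_index,
      n_px = nrow(idx),
      area_mm2 = px_to_mm2(nrow(idx), section$um_per_px),
      centroid_r = mean(idx[, 1]) - 1,
      centroid_c = mean(idx[, 2]) - 1,
      mean_prob = mean(prob_map[idx]),
      filtered_area = FALSE,
      filtered_border = FALSE,
      filtered_continuity = FALSE)
  }
  out <- if (k > 0) dplyr::bind_rows(rows) else
    tibble(region_id = integer(), section_index = integer(),
           n_px = integer(), area_mm2 = numeric(), centroid_r = numeric(),
           centroid_c = numeric(), mean_prob = numeric(),
           filtered_area = logical(), filtered_border = logical(),
           filtered_continuity = logical())
  attr(out, "label_map") <- lab
  attr(out, "um_per_px") <- section$um_per_px
  class(out) <- c("ft_regions", class(out))
  out
}

#' Surviving regions after all filters
#'
#' @param regions an `ft_regions` tibble.
#' @return The subset with no filter flag set (label map attribute
#'   restricted accordingly).
#' @export
regions_kept <- function(regions) {
  keep <- !(regions$filtered_area | regions$filtered_border |
              regions$filtered_continuity)
  out <- regions[keep, ]
  lab <- attr(regions, "label_map")
  if (!is.null(lab)) {
    lab[!(lab %in% regions$region_id[keep])] <- 0L
    attr(out, "label_map") <- lab
  }
  attr(out, "um_per_px") <- attr(regions, "um_per_px")
  class(out) <- class(regions)
  out
}

# Euclidean distance (pixels) from every pixel to the support of `mask`
dist_to_mask <- function(mask) {
  if (!any(mask)) return(matrix(Inf, nrow(mask), ncol(mask)))
  d <- EBImage::distmap(1 - (mask > 0), metric = "euclidean")
  matrix(as.numeric(d), nrow(mask), ncol(mask))
}

#' Area and brain-outline false-positive filters
#'
#' Flags regions with area strictly below `min_area_mm2`, and regions
#' whose minimum distance to the tissue-mask boundary is strictly below
#' `border_margin_mm` (predictions hugging the brain outline are mostly
#' edge artifacts). Both filters are evaluated on the unfiltered region
#' set, so they commute with the continuity filter.
#'
#' @param regions an `ft_regions` tibble (carrying its label map).
#' @param tissue_mask logical tissue mask on the section grid.
#' @param config an [inference_config()].
#' @return The tibble with `filtered_area` / `filtered_border` updated.
#' @export
size_and_border_filter <- function(regions, tissue_mask,
                                   config = inference_config()) {
  if (!nrow(regions)) return(regions)
  lab <- attr(regions, "label_map")
  um <- attr(regions, "um_per_px")
  regions$filtered_area <- regions$area_mm2 < config$min_area_mm2
  dist_px <- matrix(as.numeric(EBImage::distmap(tissue_mask * 1,
                                                metric = "euclidean")),
                    nrow(tissue_mask), ncol(tissue_mask))
  margin_px <- mm_to_px(config$border_margin_mm, um)
  for (i in seq_len(nrow(regions))) {
    idx <- lab == regions$region_id[i]
    regions$filtered_border[i] <- min(dist_px[idx]) < margin_px
  }
  regions
}

#' Across-section continuity filter
#'
#' A region is kept iff the minimum Euclidean distance from any of its
#' pixels to the support of the averaged neighbouring-section bundle mask
#' is at most `continuity_max_dist_mm` (strictly greater removes; a region
#' at exactly the bound survives). Distance is measured at native
#' resolution via a distance transform of the reference support. Removed
#' regions are flagged, never deleted.
#'
#' @param regions an `ft_regions` tibble.
#' @param reference_mask numeric/logical reference mask on the section
#'   grid (support = any positive value). An empty reference removes all
#'   regions with a warning.
#' @param config an [inference_config()].
#' @return The tibble with `filtered_continuity` updated.
#' @export
continuity_filter <- function(regions, reference_mask,
                              config = inference_config()) {
  if (!nrow(regions)) return(regions)
  lab <- attr(regions, "label_map")
  um <- attr(regions, "um_per_px")
  if (!any(reference_mask > 0)) {
    warn("empty continuity reference: all regions removed")
    regions$filtered_continuity <- TRUE
    return(regions)
  }
  dmap <- dist_to_mask(reference_mask > 0)
  max_px <- mm_to_px(config$continuity_max_dist_mm, um)
  for (i in seq_len(nrow(regions))) {
    idx <- lab == regions$region_id[i]
    regions$filtered_continuity[i] <- min(dmap[idx]) > max_px
  }
  regions
}

# downsample a matrix by integer factor (block mean)
downsample <- function(m, f) {
  H <- floor(nrow(m) / f)
  W <- floor(ncol(m) / f)
  m <- m[seq_len(H * f), seq_len(W * f)]
  rmean <- matrix(colMeans(matrix(m, nrow = f)), H, W * f)
  t(matrix(colMeans(matrix(t(rmean), nrow = f)), W, H))
}

# nearest-neighbour upsample back to native dims
upsample_to <- function(m, H, W) {
  ri <- pmin(floor((seq_len(H) - 1) * nrow(m) / H) + 1, nrow(m))
  ci <- pmin(floor((seq_len(W) - 1) * ncol(m) / W) + 1, ncol(m))
  m[ri, ci]
}

#' Low-resolution segmenters for the continuity prior
#'
#' The continuity prior needs a coarse dense-bundle mask per section. Two
#' pluggable implementations are bundled: `make_model_lowres_segmenter()`
#' applies the package's own segmentation arm to the downsampled section
#' and keeps the regions whose mean probability reaches the configured
#' quantile (the main dense bundles); `make_gt_lowres_segmenter()` injects
#' known label maps — used to test the filter's own logic in isolation.
#'
#' Both return a function `f(section, index)` yielding a low-resolution
#' binary mask.
#'
#' @param model trained `ft_model`.
#' @param config an [inference_config()].
#' @return A segmenter closure.
#' @export
make_model_lowres_segmenter <- function(model, config = inference_config()) {
  function(section, index) {
    f <- config$lowres_factor
    d <- dim(section$image)
    low <- array(0, c(floor(d[1] / f), floor(d[2] / f), 3L))
    for (ch in 1:3) low[, , ch] <- downsample(section$image[, , ch], f)
    # bypass the constructor's minimum-size check: the downsampled
    # intermediate may legitimately be tiny
    lowsec <- structure(
      list(image = pmax(low, 0), um_per_px = section$um_per_px * f,
           section_index = section$section_index,
           spacing_mm = section$spacing_mm, tissue_mask = NULL),
      class = "ft_section")
    prob <- segment_section(model, lowsec, config)
    bin <- prob > config$prob_threshold
    if (!any(bin)) return(bin)
    lab <- label_components(bin, config$connectivity)
    scores <- vapply(seq_len(max(lab)),
                     function(i) mean(prob[lab == i]), numeric(1))
    keep <- which(scores >= quantile(scores, config$dense_quantile))
    matrix(lab %in% keep, nrow(bin), ncol(bin))
  }
}

#' @rdname make_model_lowres_segmenter
#' @param label_maps list of native-resolution label maps (one per
#'   section, in stack order).
#' @param lowres_factor downsampling factor.
#' @export
make_gt_lowres_segmenter <- function(label_maps, lowres_factor = 10L) {
  function(section, index) {
    downsample((label_maps[[index]] > 0) * 1, lowres_factor) > 0.25
  }
}

# translation (low-res px) aligning mask b onto mask a by maximizing
# normalized cross-correlation, brute force over +/- max_shift
align_translation <- function(a, b, max_shift) {
  best <- c(0L, 0L); best_score <- -Inf
  av <- a - mean(a)
  for (dr in -max_shift:max_shift) {
    for (dc in -max_shift:max_shift) {
      bs <- shift_matrix(b, dr, dc)
      bv <- bs - mean(bs)
      den <- sqrt(sum(av^2) * sum(bv^2))
      sc <- if (den > 0) sum(av * bv) / den else 0
      if (sc > best_score) { best_score <- sc; best <- c(dr, dc) }
    }
  }
  best
}

shift_matrix <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  sr <- max(1, 1 - dr):min(H, H - dr)
  sc <- max(1, 1 - dc):min(W, W - dc)
  out[sr + dr, sc + dc] <- m[sr, sc]
  out
}

#' Build per-section continuity reference masks
#'
#' Downsamples every section by `lowres_factor`, coarsely aligns the stack
#' by translation (maximizing the normalized cross-correlation of the
#' downsampled tissue masks against the middle section), zero-pads smaller
#' sections to the stack's maximum dimensions, obtains a low-resolution
#' dense-bundle mask per section from the pluggable segmenter, averages
#' the masks of each section's available rostral/caudal neighbours (end
#' sections use their single neighbour), and upsamples the averages to
#' native resolution.
#'
#' @param sections list of `ft_section`s in stack order (`>= 2`; a single
#'   section disables the continuity prior with a warning and yields
#'   `NULL`).
#' @param segmenter a segmenter closure from
#'   [make_model_lowres_segmenter()] or [make_gt_lowres_segmenter()].
#' @param config an [inference_config()].
#' @param manual_offsets optional `n x 2` matrix of per-section low-res
#'   translation overrides.
#' @return List of native-resolution numeric reference masks (values in
#'   `[0, 1]`; support = positive entries), or `NULL`.
#' @export
build_reference_masks <- function(sections, segmenter,
                                  config = inference_config(),
                                  manual_offsets = NULL) {
  n <- length(sections)
  if (n < 2) {
    warn("continuity prior disabled: stack has fewer than 2 sections")
    return(NULL)
  }
  f <- config$lowres_factor
  low_masks <- vector("list", n)
  low_tissue <- vector("list", n)
  dims <- matrix(0L, n, 2)
  for (i in seq_len(n)) {
    low_masks[[i]] <- segmenter(sections[[i]], i)
    tm <- sections[[i]]$tissue_mask
    if (is.null(tm)) tm <- compute_tissue_mask(sections[[i]])
    low_tissue[[i]] <- downsample(tm * 1, f) > 0.5
    dims[i, ] <- dim(low_masks[[i]])
  }
  Hm <- max(dims[, 1]); Wm <- max(dims[, 2])
  pad_center <- function(m) {
    out <- matrix(0, Hm, Wm)
    r0 <- floor((Hm - nrow(m)) / 2); c0 <- floor((Wm - ncol(m)) / 2)
    out[r0 + seq_len(nrow(m)), c0 + seq_len(ncol(m))] <- m
    out
  }
  low_masks <- lapply(low_masks, function(m) pad_center(m * 1))
  low_tissue <- lapply(low_tissue, function(m) pad_center(m * 1))
  ref_i <- ceiling(n / 2)
  offsets <- matrix(0L, n, 2)
  for (i in seq_len(n)) {
    if (!is.null(manual_offsets)) {
      offsets[i, ] <- manual_offsets[i, ]
    } else if (i != ref_i) {
      offsets[i, ] <- align_translation(low_tissue[[ref_i]],
                                        low_tissue[[i]],
                                        config$align_max_shift_px)
    }
  }
  aligned <- lapply(seq_len(n), function(i) {
    shift_matrix(low_masks[[i]], offsets[i, 1], offsets[i, 2])
  })
  out <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- c(i - 1, i + 1)
    nb <- nb[nb >= 1 & nb <= n]
    avg <- Reduce(`+`, aligned[nb]) / length(nb)
    # back into section i's frame, then up to native resolution
    avg_i <- shift_matrix(avg, -offsets[i, 1], -offsets[i, 2])
    d <- dim(sections[[i]]$image)
    r0 <- floor((Hm - floor(d[1] / f)) / 2)
    c0 <- floor((Wm - floor(d[2] / f)) / 2)
    crop <- avg_i[r0 + seq_len(floor(d[1] / f)), c0 + seq_len(floor(d[2] / f))]
    out[[i]] <- upsample_to(crop, d[1], d[2])
  }
  out
}
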