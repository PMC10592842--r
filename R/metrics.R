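#' Fiber-density configuration
#'
#' Fiber density (FD) is estimated by enhancing the grayscale section with
#' contrast-limited adaptive histogram equalization (CLAHE) and
#' binarizing at a percentile of the enhanced intensities; FD is the
#' percentage of a bundle's pixels above the threshold.
#'
#' The percentile population defaults to all tissue pixels of the section
#' (`"section_tissue"`): a bundle-local 95th percentile would pin FD near
#' 5% by construction, which cannot reproduce the observed spread of
#' densities across bundles. The bundle-local variant is retained as an
#' option (`"bundle_local"`); being rank-based, it is invariant to
#' monotone intensity rescalings of the input.
#'
#' @param percentile percentile of enhanced intensities used as threshold
#'   (default 95).
#' @param clahe_clip_limit CLAHE clip limit (default 2).
#' @param clahe_tile_px CLAHE tile side in pixels (default 64).
#' @param percentile_domain `"section_tissue"` or `"bundle_local"`.
#' @return `ft_density_config` list.
#' @export
density_config <- function(percentile = 95, clahe_clip_limit = 2,
                           clahe_tile_px = 64L,
                           percentile_domain = c("section_tissue",
                                                 "bundle_local")) {
  percentile_domain <- match.arg(percentile_domain)
  stopifnot(percentile > 0, percentile < 100)
  structure(as.list(environment()), class = "ft_density_config")
}

# standard luminance grayscale on the 0-255 scale
to_gray <- function(image) {
  0.2126 * image[, , 1] + 0.7152 * image[, , 2] + 0.0722 * image[, , 3]
}

# CLAHE-enhanced grayscale of a section (0-1 scale); falls back to global
# histogram equalization when the grid would be degenerate
enhance_section <- function(section, config) {
  g <- to_gray(section$image) / 255
  nx <- max(2L, floor(ncol(g) / config$clahe_tile_px))
  ny <- max(2L, floor(nrow(g) / config$clahe_tile_px))
  enh <- tryCatch(
    EBImage::clahe(g, nx = nx, ny = ny, limit = config$clahe_clip_limit),
    error = function(e) EBImage::equalize(g))
  matrix(pmin(pmax(as.numeric(enh), 0), 1), nrow(g), ncol(g))
}

#' Binary fiber map within a segmented bundle
#'
#' Grayscale conversion (luminance weights), CLAHE enhancement, and
#' thresholding at the configured percentile of the enhanced intensities
#' over the configured domain; the output is restricted to the region's
#' pixels. Regions smaller than one CLAHE tile fall back to global
#' histogram equalization (recorded in the `"fallback"` attribute).
#' Deterministic.
#'
#' @param section an `ft_section`.
#' @param region_mask logical matrix selecting the bundle area.
#' @param config an [density_config()].
#' @param tissue_mask optional tissue mask (computed when missing and the
#'   domain is `"section_tissue"`).
#' @return Logical matrix: fiber pixels within the region.
#' @export
fiber_binary_map <- function(section, region_mask,
                             config = density_config(),
                             tissue_mask = NULL) {
  fallback <- sum(region_mask) < config$clahe_tile_px^2 &&
    config$percentile_domain == "bundle_local"
  enh <- if (fallback) {
    g <- to_gray(section$image) / 255
    matrix(as.numeric(EBImage::equalize(g)), nrow(g), ncol(g))
  } else {
    enhance_section(section, config)
  }
  domain <- if (config$percentile_domain == "section_tissue") {
    tm <- tissue_mask %||% section$tissue_mask %||%
      compute_tissue_mask(section)
    enh[tm]
  } else {
    enh[region_mask]
  }
  thr <- quantile(domain, config$percentile / 100, names = FALSE)
  out <- enh > thr & region_mask
  attr(out, "fallback") <- fallback
  attr(out, "threshold") <- thr
  out
}

#' Fiber density of a bundle
#'
#' `FD = 100 * (fiber pixels) / (bundle-area pixels)`, in percent.
#'
#' @param binary_map logical fiber map (restricted to the region).
#' @param region_mask logical bundle-area mask.
#' @return FD in percent.
#' @export
fiber_density <- function(binary_map, region_mask) {
  n <- sum(region_mask)
  if (n == 0) abort("empty region", class = "ft_validation_error")
  100 * sum(binary_map & region_mask) / n
}

#' Fiber densities of all regions in a table
#'
#' @param section an `ft_section`.
#' @param regions an `ft_regions` tibble (or any tibble with a
#'   `"label_map"` attribute and `region_id` column).
#' @param config an [density_config()].
#' @return `regions` with an `fd` column appended.
#' @export
region_fiber_density <- function(section, regions,
                                 config = density_config()) {
  lab <- attr(regions, "label_map")
  tm <- section$tissue_mask %||% compute_tissue_mask(section)
  enh <- enhance_section(section, config)
  dom_thr <- quantile(enh[tm], config$percentile / 100, names = FALSE)
  fd <- vapply(regions$region_id, function(id) {
    m <- lab == id
    if (config$percentile_domain == "bundle_local") {
      thr <- quantile(enh[m], config$percentile / 100, names = FALSE)
      100 * sum(enh[m] > thr) / sum(m)
    } else {
      100 * sum(enh[m] > dom_thr) / sum(m)
    }
  }, numeric(1))
  regions$fd <- fd
  regions
}

#' Match predicted regions against true bundles
#'
#' A true bundle counts as detected (TP) when some predicted region
#' overlaps it by at least `min_overlap_frac` of the smaller of the two
#' areas; predicted regions matching no true bundle are false positives.
#' Matching is greedy and one-to-many in the bundle direction: one
#' prediction may cover several true bundles (each counts as a TP), and
#' several predictions on one true bundle yield one TP with the extras not
#' counted as FPs.
#'
#' The overlap criterion is a package choice — bundle-level counting needs
#' a region-correspondence rule and none is prescribed by the published
#' evaluation; it is configurable and surfaced here deliberately.
#'
#' @param pred_label_map integer label map of predicted regions.
#' @param true_label_map integer label map of true bundles.
#' @param min_overlap_frac minimum intersection as a fraction of the
#'   smaller region's area (default 0.25).
#' @return A tibble of class `ft_match`: per true bundle `detected`,
#'   matched prediction id; per prediction `is_fp`; plus a `role` column
#'   (`"true"` / `"pred"`).
#' @export
match_detections <- function(pred_label_map, true_label_map,
                             min_overlap_frac = 0.25) {
  pids <- setdiff(sort(unique(as.integer(pred_label_map))), 0L)
  tids <- setdiff(sort(unique(as.integer(true_label_map))), 0L)
  p_area <- vapply(pids, function(i) sum(pred_label_map == i), numeric(1))
  t_area <- vapply(tids, function(i) sum(true_label_map == i), numeric(1))
  # co-occurrence counts
  inter <- matrix(0, length(tids), length(pids),
                  dimnames = list(tids, pids))
  both <- pred_label_map > 0 & true_label_map > 0
  if (any(both)) {
    tb <- table(true = true_label_map[both], pred = pred_label_map[both])
    inter[rownames(tb), colnames(tb)] <- tb
  }
  detected <- logical(length(tids))
  matched_pred <- rep(NA_integer_, length(tids))
  pred_used <- logical(length(pids))
  for (ti in seq_along(tids)) {
    if (!length(pids)) break
    frac <- inter[ti, ] / pmin(t_area[ti], p_area)
    best <- which.max(frac)
    if (length(best) && frac[best] >= min_overlap_frac) {
      detected[ti] <- TRUE
      matched_pred[ti] <- pids[best]
      pred_used[best] <- TRUE
    }
  }
  # any prediction overlapping some detected bundle enough is not an FP
  for (pi in seq_along(pids)) {
    if (pred_used[pi]) next
    if (length(tids)) {
      frac <- inter[, pi] / pmin(t_area, p_area[pi])
      if (any(frac >= min_overlap_frac)) pred_used[pi] <- TRUE
    }
  }
  dplyr::bind_rows(
    tibble(role = "true", id = tids, area_px = t_area,
           detected = detected, matched_pred = matched_pred,
           is_fp = NA),
    tibble(role = "pred", id = pids, area_px = p_area,
           detected = NA, matched_pred = NA_integer_,
           is_fp = !pred_used)) -> out
  class(out) <- c("ft_match", class(out))
  out
}

#' Bundle-level evaluation report
#'
#' Aggregates per-section match tables into the published metrics: the
#' true positive rate (detected bundles over all charted bundles), the
#' average number of false positives per section, and the fiber-density
#' difference `dFD = mean(FD_manual - FD_predicted)` over TP pairs, in
#' percentage points (negative means the predicted bundles are denser,
#' the expected signature of tighter predicted boundaries). The mean
#' absolute difference is reported alongside.
#'
#' @param match_tables list of `ft_match` tibbles (one per section).
#' @param fd_pairs optional tibble with columns `fd_manual`,
#'   `fd_predicted` (one row per TP pair).
#' @return An `ft_eval` list: `tpr`, `fp_avg`, `delta_fd`,
#'   `delta_fd_abs`, `n_true`, `n_tp`, `n_fp`, `n_sections`,
#'   `per_section` tibble.
#' @export
compute_metrics <- function(match_tables, fd_pairs = NULL) {
  stopifnot(length(match_tables) >= 1)
  per <- purrr::map_dfr(seq_along(match_tables), function(i) {
    m <- match_tables[[i]]
    tr <- dplyr::filter(m, .data$role == "true")
    pr <- dplyr::filter(m, .data$role == "pred")
    tibble(section = i, n_true = nrow(tr), n_tp = sum(tr$detected),
           n_fp = sum(pr$is_fp))
  })
  n_true <- sum(per$n_true)
  tpr <- if (n_true > 0) sum(per$n_tp) / n_true else NA_real_
  out <- list(
    tpr = tpr,
    fp_avg = sum(per$n_fp) / nrow(per),
    delta_fd = if (!is.null(fd_pairs) && nrow(fd_pairs)) {
      mean(fd_pairs$fd_manual - fd_pairs$fd_predicted)
    } else NA_real_,
    delta_fd_abs = if (!is.null(fd_pairs) && nrow(fd_pairs)) {
      mean(abs(fd_pairs$fd_manual - fd_pairs$fd_predicted))
    } else NA_real_,
    n_true = n_true, n_tp = sum(per$n_tp), n_fp = sum(per$n_fp),
    n_sections = nrow(per), per_section = per)
  class(out) <- "ft_eval"
  out
}

#' @export
print.ft_eval <- function(x, ...) {
  cat(sprintf(
    "<ft_eval> TPR %.3f (%d/%d bundles), FPavg %.2f/section (%d sections)",
    x$tpr, x$n_tp, x$n_true, x$fp_avg, x$n_sections))
  if (is.finite(x$delta_fd)) {
    cat(sprintf(", dFD %+.2f pp (|dFD| %.2f)", x$delta_fd, x$delta_fd_abs))
  }
  cat("\n")
  invisible(x)
}

#' Free-response ROC for bundle detection
#'
#' Sweeps the probability threshold, re-extracts candidate regions at each
#' value, applies the configured post-processing filters, matches against
#' the ground truth, and records `(threshold, TPR, FP/section)`. The
#' elbow is the threshold maximizing `TPR - FP/max(FP)` (a standard
#' normalized-FP heuristic).
#'
#' @param prob_maps list of probability matrices (one per section).
#' @param true_label_maps list of ground-truth label maps.
#' @param sections list of `ft_section`s.
#' @param thresholds strictly increasing probability thresholds.
#' @param config an [inference_config()].
#' @param reference_masks optional continuity references (from
#'   [build_reference_masks()]); `NULL` skips the continuity filter.
#' @param apply_filters apply the area/border (and continuity) filters at
#'   each threshold; `FALSE` gives the raw curve.
#' @param min_overlap_frac matching criterion (see [match_detections()]).
#' @return A tibble of class `ft_froc` (`threshold`, `tpr`, `fp_per_section`)
#'   with the elbow threshold in the `"elbow"` attribute.
#' @export
froc_curve <- function(prob_maps, true_label_maps, sections, thresholds,
                       config = inference_config(),
                       reference_masks = NULL, apply_filters = TRUE,
                       min_overlap_frac = 0.25) {
  stopifnot(all(diff(thresholds) > 0))
  tissues <- lapply(sections, function(s) {
    s$tissue_mask %||% compute_tissue_mask(s)
  })
  rows <- purrr::map_dfr(thresholds, function(th) {
    cfg <- config
    cfg$prob_threshold <- th
    matches <- lapply(seq_along(prob_maps), function(i) {
      reg <- extract_regions(prob_maps[[i]], sections[[i]], cfg)
      if (apply_filters && nrow(reg)) {
        reg <- size_and_border_filter(reg, tissues[[i]], cfg)
        if (!is.null(reference_masks)) {
          reg <- suppressWarnings(
            continuity_filter(reg, reference_masks[[i]], cfg))
        }
      }
      kept <- regions_kept(reg)
      match_detections(attr(kept, "label_map") %||%
                         matrix(0L, nrow(prob_maps[[i]]),
                                ncol(prob_maps[[i]])),
                       true_label_maps[[i]], min_overlap_frac)
    })
    ev <- compute_metrics(matches)
    tibble(threshold = th, tpr = ev$tpr, fp_per_section = ev$fp_avg)
  })
  fpmax <- max(rows$fp_per_section, 1e-12)
  elbow <- rows$threshold[which.max(rows$tpr - rows$fp_per_section / fpmax)]
  attr(rows, "elbow") <- elbow
  class(rows) <- c("ft_froc", class(rows))
  rows
}

#' Assign a region to a white-matter pathway
#'
#' A region is assigned to the pathway whose ROI covers strictly more
#' than `min_overlap` of the region's area; ties go to the larger
#' overlap, and a region qualifying nowhere gets `"none"`. Pathway masks
#' must be mutually disjoint.
#'
#' @param region_mask logical region mask.
#' @param pathway_masks named list of logical ROI masks (e.g. IC/CC/UF).
#' @param min_overlap minimum covered fraction (strict `>`; published
#'   criterion 40%).
#' @return Pathway name or `"none"`.
#' @export
assign_pathway <- function(region_mask, pathway_masks, min_overlap = 0.40) {
  overlap_sum <- Reduce(`+`, lapply(pathway_masks, function(m) m * 1))
  if (any(overlap_sum > 1)) {
    abort("pathway masks overlap", class = "ft_validation_error")
  }
  area <- sum(region_mask)
  fr <- vapply(pathway_masks, function(m) sum(region_mask & m) / area,
               numeric(1))
  if (all(fr <= min_overlap)) return("none")
  names(pathway_masks)[which.max(fr)]
}

#' Compare fiber density across white-matter pathways
#'
#' Per-pathway mean and standard error of FD, and a one-way ANOVA with FD
#' as the dependent variable and pathway as the factor.
#'
#' @param fd_table tibble with columns `fd` (percent) and `pathway`.
#' @return An `ft_pathway_report`: `summary` tibble (pathway, n, mean_fd,
#'   se_fd), `f_statistic`, `p_value`, `df`.
#' @export
pathway_fd_comparison <- function(fd_table) {
  fd_table <- dplyr::filter(fd_table, .data$pathway != "none",
                            !is.na(.data$pathway))
  counts <- table(fd_table$pathway)
  if (sum(counts >= 2) < 2) {
    abort("need at least two pathways with two or more regions each",
          class = "ft_validation_error")
  }
  smry <- fd_table %>%
    group_by(.data$pathway) %>%
    summarise(n = n(), mean_fd = mean(.data$fd),
              se_fd = sd(.data$fd) / sqrt(n()), .groups = "drop")
  fit <- stats::lm(fd ~ pathway, data = fd_table)
  av <- stats::anova(fit)
  out <- list(summary = smry,
              f_statistic = av$`F value`[1],
              p_value = av$`Pr(>F)`[1],
              df = c(av$Df[1], av$Df[2]))
  class(out) <- "ft_pathway_report"
  out
}

#' @export
print.ft_pathway_report <- function(x, ...) {
  cat("<ft_pathway_report> one-way ANOVA of FD by pathway\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  cat(sprintf("F(%d, %d) = %.3f, p = %.3g\n", x$df[1], x$df[2],
              x$f_statistic, x$p_value))
  invisible(x)
}
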