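#' Configuration of the synthetic dark-field section generator
#'
#' The generator emulates the appearance of dark-field tracer sections at
#' desk scale: a near-black slide, a dimly textured tissue region, bright
#' anti-aliased curvilinear strokes (labeled fibers) clustered into
#' elliptical bundle areas with a shared mean orientation, diffuse
#' isotropic terminal fields (a principal false-positive source), and
#' saturated glare/dust artifacts. Physical units are respected through
#' `um_per_px`, so the mm-denominated detection filters are exercised on
#' realistic scales.
#'
#' @param image_size `(H, W)` in pixels.
#' @param um_per_px in-plane resolution of the synthetic sections.
#' @param n_bundles number of fiber bundles per section.
#' @param bundle_axes_mm range of ellipse semi-axes (mm).
#' @param coverage_dense,coverage_moderate target stroke-coverage fraction
#'   of a bundle's area for the two density classes
#'   (`0 < moderate < dense < 1`).
#' @param coverage_jitter s.d. of per-bundle jitter around the class target.
#' @param stroke_length_um,stroke_width_um stroke geometry ranges.
#' @param orientation_jitter_deg s.d. of per-stroke deviation from the
#'   bundle's mean orientation.
#' @param stroke_peak intensity range (0-255) of stroke peaks.
#' @param n_terminal_fields,n_artifacts confounder counts per section.
#' @param background_mean,background_noise_sd tissue background intensity.
#' @param glare_value artifact intensity (saturation).
#' @param drift_mm_per_section maximum centroid drift between consecutive
#'   sections of a stack.
#' @param n_spurious number of single-section spurious regions injected
#'   per stack (for continuity-filter testing).
#' @param spurious_min_dist_mm minimum distance between a spurious region
#'   and any true bundle.
#' @param test_bg_shift background-intensity shift applied to the held-out
#'   "test brain" stacks written by [write_fixture_suite()].
#' @param seed default seed used when none is passed explicitly.
#' @return A list of class `ft_synth_config`.
#' @export
synth_config <- function(image_size = c(384L, 384L),
                         um_per_px = 20,
                         n_bundles = 3L,
                         bundle_axes_mm = c(0.85, 1.15),
                         coverage_dense = 0.20,
                         coverage_moderate = 0.10,
                         coverage_jitter = 0.02,
                         stroke_length_um = c(300, 700),
                         stroke_width_um = c(30, 60),
                         orientation_jitter_deg = 12,
                         stroke_peak = c(140, 220),
                         n_terminal_fields = 2L,
                         n_artifacts = 2L,
                         background_mean = 20,
                         background_noise_sd = 8,
                         glare_value = 255,
                         drift_mm_per_section = 0.2,
                         n_spurious = 0L,
                         spurious_min_dist_mm = 2.0,
                         test_bg_shift = 6,
                         seed = 1L) {
  cfg <- as.list(environment())
  if (!(coverage_moderate > 0 && coverage_moderate < coverage_dense &&
        coverage_dense < 1)) {
    abort("need 0 < coverage_moderate < coverage_dense < 1",
          class = "ft_validation_error")
  }
  if (um_per_px <= 0 || any(image_size < 64)) {
    abort("invalid synthetic geometry", class = "ft_validation_error")
  }
  class(cfg) <- "ft_synth_config"
  cfg
}

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# ---- low-level rendering ---------------------------------------------------

# stamp a Gaussian-profile quadratic Bezier stroke onto canvas (max blend);
# returns updated canvas. p0/p1/p2 are (row, col), 1-based continuous.
render_stroke <- function(canvas, p0, p1, p2, width_px, peak) {
  H <- nrow(canvas); W <- ncol(canvas)
  sigma <- width_px / 2
  rad <- max(1L, ceiling(2.5 * sigma))
  len <- sqrt(sum((p2 - p0)^2))
  nstep <- max(4L, ceiling(len / 0.5))
  tt <- seq(0, 1, length.out = nstep)
  pts_r <- (1 - tt)^2 * p0[1] + 2 * (1 - tt) * tt * p1[1] + tt^2 * p2[1]
  pts_c <- (1 - tt)^2 * p0[2] + 2 * (1 - tt) * tt * p1[2] + tt^2 * p2[2]
  off <- seq(-rad, rad)
  for (k in seq_len(nstep)) {
    r <- pts_r[k]; c <- pts_c[k]
    ri <- round(r) + off
    ci <- round(c) + off
    ok_r <- ri >= 1 & ri <= H
    ok_c <- ci >= 1 & ci <= W
    if (!any(ok_r) || !any(ok_c)) next
    rr <- ri[ok_r]; cc <- ci[ok_c]
    d2 <- outer((rr - r)^2, (cc - c)^2, "+")
    stamp <- peak * exp(-d2 / (2 * sigma^2))
    blk <- canvas[rr, cc, drop = FALSE]
    canvas[rr, cc] <- pmax(blk, stamp)
  }
  canvas
}

# logical mask of an ellipse (center 1-based, axes px, angle rad)
ellipse_mask <- function(H, W, center, a, b, theta) {
  r <- matrix(seq_len(H), H, W) - center[1]
  c <- matrix(seq_len(W), H, W, byrow = TRUE) - center[2]
  x <- r * cos(theta) + c * sin(theta)
  y <- -r * sin(theta) + c * cos(theta)
  (x / a)^2 + (y / b)^2 <= 1
}

disc_mask <- function(H, W, center, radius) {
  ellipse_mask(H, W, center, radius, radius, 0)
}

# fill a bundle ellipse with oriented strokes until the rendered stroke
# coverage reaches `target`; returns list(canvas, mask, coverage)
render_bundle_strokes <- function(canvas, bmask, center, a, b, theta,
                                  target, cfg) {
  px <- cfg$um_per_px
  area <- sum(bmask)
  stroke_cut <- 0.5                    # fraction of peak that counts as stroke
  idx <- which(bmask, arr.ind = TRUE)
  local <- matrix(0, nrow(canvas), ncol(canvas))
  for (s in seq_len(500L)) {
    cov <- sum(local[bmask] > stroke_cut * cfg$stroke_peak[1]) / area
    if (cov >= target) break
    start <- idx[sample.int(nrow(idx), 1L), ]
    ang <- theta + rnorm(1, 0, cfg$orientation_jitter_deg * pi / 180)
    len <- runif(1, cfg$stroke_length_um[1], cfg$stroke_length_um[2]) / px
    wid <- runif(1, cfg$stroke_width_um[1], cfg$stroke_width_um[2]) / px
    peak <- runif(1, cfg$stroke_peak[1], cfg$stroke_peak[2])
    dir <- c(cos(ang), sin(ang))
    p0 <- c(start[1], start[2]) - dir * len / 2
    p2 <- c(start[1], start[2]) + dir * len / 2
    perp <- c(-dir[2], dir[1])
    p1 <- (p0 + p2) / 2 + perp * rnorm(1, 0, len / 8)
    local <- render_stroke(local, p0, p1, p2, wid, peak)
  }
  local[!bmask] <- 0                   # strokes clipped to the bundle area
  cov <- sum(local[bmask] > stroke_cut * cfg$stroke_peak[1]) / area
  list(canvas = pmax(canvas, local),
       stroke_mask = local > stroke_cut * cfg$stroke_peak[1],
       coverage = cov)
}

# isotropic puncta field inside a disc (terminal-field confounder)
render_terminal_field <- function(canvas, H, W, center, radius, cfg) {
  n_dots <- round(0.10 * pi * radius^2 / 3)
  for (k in seq_len(n_dots)) {
    ang <- runif(1, 0, 2 * pi)
    rr <- radius * sqrt(runif(1))
    pos <- center + rr * c(cos(ang), sin(ang))
    peak <- runif(1, cfg$stroke_peak[1], cfg$stroke_peak[2]) * 0.9
    sig <- runif(1, 0.6, 1.2)
    canvas <- render_stroke(canvas, pos, pos, pos, 2 * sig, peak)
  }
  canvas
}

# ---- single-section generation --------------------------------------------

# internal: renders one section from a fixed layout (bundle parameters),
# so serial sections share bundle identity while strokes re-randomize.
render_section_from_layout <- function(layout, cfg, section_index,
                                       bg_shift = 0) {
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  canvas <- matrix(0, H, W)
  stroke_mask <- matrix(FALSE, H, W)
  label_map <- matrix(0L, H, W)
  bundles <- list()
  for (i in seq_len(nrow(layout))) {
    L <- layout[i, ]
    bmask <- ellipse_mask(H, W, c(L$center_r, L$center_c), L$a_px, L$b_px,
                          L$theta)
    res <- render_bundle_strokes(canvas, bmask, c(L$center_r, L$center_c),
                                 L$a_px, L$b_px, L$theta, L$coverage, cfg)
    canvas <- res$canvas
    stroke_mask <- stroke_mask | res$stroke_mask
    label_map[bmask] <- L$id
    ctr <- which(bmask, arr.ind = TRUE)
    bundles[[i]] <- tibble(
      id = L$id, section_index = section_index,
      centroid_r = mean(ctr[, 1]) - 1, centroid_c = mean(ctr[, 2]) - 1,
      class = L$class, coverage_target = L$coverage,
      coverage_rendered = res$coverage,
      area_px = sum(bmask), pathway = L$pathway,
      is_spurious = L$is_spurious)
  }
  # confounders: terminal fields + glare artifacts, placed off the bundles
  terminal_mask <- matrix(FALSE, H, W)
  artifact_mask <- matrix(FALSE, H, W)
  tissue <- ellipse_mask(H, W, c(H / 2, W / 2), 0.47 * H, 0.47 * W, 0)
  occupied <- label_map > 0
  for (k in seq_len(cfg$n_terminal_fields)) {
    radius <- mm_to_px(runif(1, 0.4, 0.7), cfg$um_per_px)
    pos <- place_disc(tissue, occupied, radius, margin = 4)
    if (is.null(pos)) next
    canvas <- render_terminal_field(canvas, H, W, pos, radius, cfg)
    tm <- disc_mask(H, W, pos, radius)
    terminal_mask <- terminal_mask | tm
    occupied <- occupied | tm
  }
  for (k in seq_len(cfg$n_artifacts)) {
    radius <- runif(1, 1.5, 4)
    pos <- place_disc(tissue, occupied, radius, margin = 2)
    if (is.null(pos)) next
    am <- disc_mask(H, W, pos, radius)
    canvas[am] <- cfg$glare_value
    artifact_mask <- artifact_mask | am
    occupied <- occupied | am
  }
  # compose: slide background, tissue texture, strokes, per-channel tint
  bg <- matrix(2, H, W)
  bg[tissue] <- cfg$background_mean + bg_shift +
    rnorm(sum(tissue), 0, cfg$background_noise_sd)
  base <- pmax(bg, canvas * as.numeric(tissue | artifact_mask))
  tint <- c(1, 0.96, 0.88)
  img <- array(0, c(H, W, 3))
  for (ch in 1:3) img[, , ch] <- base * tint[ch]
  img <- round(pmin(pmax(img, 0), 255))
  section <- ft_section(img, cfg$um_per_px, section_index,
                        spacing_mm = 1.2, tissue_mask = tissue)
  truth <- list(label_map = label_map,
                bundles = dplyr::bind_rows(bundles),
                stroke_mask = stroke_mask,
                terminal_mask = terminal_mask,
                artifact_mask = artifact_mask,
                tissue_mask = tissue)
  list(section = section, truth = truth)
}

# rejection-sample a disc centre inside tissue avoiding occupied pixels
place_disc <- function(tissue, occupied, radius, margin = 2,
                       retries = 100L) {
  H <- nrow(tissue); W <- ncol(tissue)
  for (t in seq_len(retries)) {
    r <- runif(1, radius + 1, H - radius - 1)
    c <- runif(1, radius + 1, W - radius - 1)
    m <- disc_mask(H, W, c(r, c), radius + margin)
    if (all(tissue[m]) && !any(occupied[m])) return(c(r, c))
  }
  NULL
}

# sample the per-stack bundle layout (positions, axes, classes, pathways)
sample_layout <- function(cfg, pathway_rois = NULL) {
  # whole-layout rejection sampling: one crowded draw does not doom a
  # feasible configuration
  for (attempt in seq_len(20L)) {
    lay <- tryCatch(sample_layout_once(cfg, pathway_rois),
                    ft_overcrowded = function(e) NULL)
    if (!is.null(lay)) return(lay)
  }
  abort("bundle placement failed: configuration over-crowded",
        class = "ft_overcrowded")
}

sample_layout_once <- function(cfg, pathway_rois = NULL) {
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  px <- cfg$um_per_px
  border_px <- mm_to_px(0.8, px)       # keep clear of the outline filter
  tissue <- ellipse_mask(H, W, c(H / 2, W / 2), 0.47 * H, 0.47 * W, 0)
  # distance (px) from every tissue pixel to the tissue boundary
  tissue_dist <- matrix(as.numeric(EBImage::distmap(tissue * 1,
                                                    metric = "euclidean")),
                        H, W)
  rows <- list()
  placed <- list()
  classes <- rep(c("dense", "moderate"), length.out = cfg$n_bundles)
  pw_names <- if (!is.null(pathway_rois)) names(pathway_rois)
  for (i in seq_len(cfg$n_bundles)) {
    a <- mm_to_px(runif(1, cfg$bundle_axes_mm[1], cfg$bundle_axes_mm[2]), px)
    b <- mm_to_px(runif(1, cfg$bundle_axes_mm[1], cfg$bundle_axes_mm[2]), px)
    theta <- runif(1, 0, pi)
    pw <- if (!is.null(pw_names)) pw_names[(i - 1) %% length(pw_names) + 1]
          else NA_character_
    rmax <- max(a, b)
    eligible <- tissue_dist >= rmax + border_px
    if (!is.na(pw)) eligible <- eligible & pathway_rois[[pw]]
    cand <- which(eligible, arr.ind = TRUE)
    if (!nrow(cand)) {
      abort("bundle placement failed: configuration over-crowded",
            class = "ft_overcrowded")
    }
    ok <- FALSE
    for (t in seq_len(300L)) {
      p <- cand[sample.int(nrow(cand), 1L), ]
      ctr <- c(p[1], p[2])
      clash <- FALSE
      for (pp in placed) {
        if (sqrt(sum((ctr - pp$ctr)^2)) < rmax + pp$rmax + 6) clash <- TRUE
      }
      if (clash) next
      ok <- TRUE
      break
    }
    if (!ok) {
      abort("bundle placement failed: configuration over-crowded",
            class = "ft_overcrowded")
    }
    placed[[length(placed) + 1]] <- list(ctr = ctr, rmax = max(a, b))
    # with pathway ROIs, density class follows the pathway (internal-
    # capsule bundles dense, callosal/uncinate moderate — the ordering
    # reported for real material); otherwise classes alternate
    cls <- if (!is.na(pw)) {
      if (pw == "IC") "dense" else "moderate"
    } else classes[i]
    cov_target <- if (cls == "dense") cfg$coverage_dense else cfg$coverage_moderate
    cov <- max(0.02, rnorm(1, cov_target, cfg$coverage_jitter))
    rows[[i]] <- tibble(id = i, center_r = ctr[1], center_c = ctr[2],
                        a_px = a, b_px = b, theta = theta, class = cls,
                        coverage = cov, pathway = pw, is_spurious = FALSE)
  }
  dplyr::bind_rows(rows)
}

#' Generate one synthetic tracer section with ground truth
#'
#' Deterministic given `(config, seed)`. Bundles are clusters of bright
#' anti-aliased strokes sharing a mean orientation inside an elliptical
#' area; the true rendered stroke-coverage fraction of every bundle is
#' recorded in the ground-truth table.
#'
#' @param config an [synth_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return `list(section = ft_section, truth = list(label_map, bundles,
#'   stroke_mask, terminal_mask, artifact_mask, tissue_mask))`; `bundles`
#'   is a tibble with one row per bundle (id, centroid, density class,
#'   target and rendered coverage, pathway tag, spurious flag).
#' @export
generate_section <- function(config, seed = config$seed) {
  with_seed(seed, {
    layout <- sample_layout(config)
    render_section_from_layout(layout, config, section_index = 1L)
  })
}

#' Generate a serial stack of synthetic sections
#'
#' Every true bundle persists across all sections with a per-section
#' centroid drift of at most `drift_mm_per_section`; strokes re-randomize
#' per section (fibers vary, areas persist). Optionally injects
#' single-section "spurious" regions at least `spurious_min_dist_mm` away
#' from every true bundle — these violate across-section continuity by
#' construction and are flagged `is_spurious` in the ground truth, giving
#' the continuity filter something to remove.
#'
#' @param config an [synth_config()].
#' @param n_sections number of sections (`>= 2`).
#' @param seed integer seed.
#' @param pathway_rois optional named list of logical ROI masks; bundle
#'   centres are then drawn inside the ROIs (cycled) and tagged.
#' @return List of `list(section, truth)` of length `n_sections`.
#' @export
generate_stack <- function(config, n_sections, seed = config$seed,
                           pathway_rois = NULL) {
  stopifnot(n_sections >= 2)
  with_seed(seed, {
    drift_px <- mm_to_px(config$drift_mm_per_section, config$um_per_px)
    H <- config$image_size[1]; W <- config$image_size[2]
    # sample bundle layout and spurious-region plan jointly; the distance
    # constraint between spurious regions and bundles can make a given
    # bundle layout infeasible, so re-draw the whole layout on failure
    layout <- NULL; spur <- NULL
    for (attempt in seq_len(25L)) {
      layout <- tryCatch(sample_layout(config, pathway_rois),
                         ft_overcrowded = function(e) NULL)
      if (is.null(layout)) next
      spur <- plan_spurious(layout, config, n_sections)
      if (!is.null(spur)) break
      spur <- NULL
    }
    if (is.null(layout) || is.null(spur)) {
      abort("bundle/spurious placement failed: configuration over-crowded",
            class = "ft_overcrowded")
    }
    out <- vector("list", n_sections)
    cur <- layout
    for (s in seq_len(n_sections)) {
      if (s > 1) {
        for (i in seq_len(nrow(cur))) {
          # bounded random walk: at most drift_px per step, confined to a
          # 2*drift_px disc around the initial position so bundles drift
          # smoothly without wandering across the section
          for (t in seq_len(50L)) {
            ang <- runif(1, 0, 2 * pi)
            step <- drift_px * sqrt(runif(1))
            nr <- cur$center_r[i] + step * cos(ang)
            nc <- cur$center_c[i] + step * sin(ang)
            excur <- sqrt((nr - layout$center_r[i])^2 +
                          (nc - layout$center_c[i])^2)
            if (excur <= 2 * drift_px) break
          }
          rmax <- max(cur$a_px[i], cur$b_px[i]) + 4
          cur$center_r[i] <- min(max(nr, rmax + 1), H - rmax - 1)
          cur$center_c[i] <- min(max(nc, rmax + 1), W - rmax - 1)
        }
      }
      lay_s <- cur
      for (sp in spur) {
        if (sp$section == s) {
          lay_s <- dplyr::bind_rows(lay_s, dplyr::select(sp, -"section"))
        }
      }
      out[[s]] <- render_section_from_layout(lay_s, config, s)
      out[[s]]$section$section_index <- s
      out[[s]]$truth$bundles$section_index <- s
    }
    out
  })
}

# plan single-section spurious regions far from every bundle; NULL if the
# layout leaves no room
plan_spurious <- function(layout, config, n_sections) {
  spur <- list()
  if (config$n_spurious == 0) return(spur)
  H <- config$image_size[1]; W <- config$image_size[2]
  min_d <- mm_to_px(config$spurious_min_dist_mm, config$um_per_px)
  border_px <- mm_to_px(0.8, config$um_per_px)
  secs <- sample.int(n_sections, config$n_spurious, replace = TRUE)
  for (k in seq_len(config$n_spurious)) {
    a <- mm_to_px(0.55, config$um_per_px)
    ok <- FALSE
    for (t in seq_len(300L)) {
      ctr <- c(runif(1, a + border_px, H - a - border_px),
               runif(1, a + border_px, W - a - border_px))
      # bundle centroids drift within 2 steps of their initial position
      # (see generate_stack), so add that allowance to the clearance
      dmin <- min(sqrt((ctr[1] - layout$center_r)^2 +
                       (ctr[2] - layout$center_c)^2) -
                  pmax(layout$a_px, layout$b_px)) -
        2 * mm_to_px(config$drift_mm_per_section, config$um_per_px)
      clash <- any(vapply(spur, function(s) {
        sqrt(sum((ctr - c(s$center_r, s$center_c))^2)) < 2.2 * a
      }, logical(1)))
      if (dmin - a >= min_d && !clash) { ok <- TRUE; break }
    }
    if (!ok) return(NULL)
    spur[[k]] <- tibble(id = nrow(layout) + k,
                        center_r = ctr[1], center_c = ctr[2],
                        a_px = a, b_px = a * 0.8,
                        theta = runif(1, 0, pi), class = "moderate",
                        coverage = config$coverage_moderate,
                        pathway = NA_character_, is_spurious = TRUE,
                        section = secs[k])
  }
  spur
}

# fixed, disjoint pathway ROI polygons (three discs) for one stack
make_pathway_rois <- function(config) {
  H <- config$image_size[1]; W <- config$image_size[2]
  r <- 0.17 * min(H, W)
  list(
    IC = disc_mask(H, W, c(0.33 * H, 0.28 * W), r),
    CC = disc_mask(H, W, c(0.30 * H, 0.72 * W), r),
    UF = disc_mask(H, W, c(0.72 * H, 0.50 * W), r))
}

#' Write a complete synthetic fixture suite
#'
#' Emits a small labeled "training brain", an unlabeled pool, and two
#' "test brains" whose tissue background intensity is shifted by
#' `config$test_bg_shift` (emulating train/test appearance differences
#' between animals), plus per-stack pathway ROI masks, ground-truth label
#' masks, a per-bundle ground-truth CSV, and YAML stack manifests.
#'
#' @param outdir output directory (created if missing).
#' @param profile `"tiny"` (256 px sections, short stacks) or `"small"`
#'   (the config's native size).
#' @param seed integer seed.
#' @param config optional [synth_config()] override.
#' @return Path of the suite manifest (YAML listing the stack manifests),
#'   invisibly.
#' @export
write_fixture_suite <- function(outdir, profile = c("tiny", "small"),
                                seed = 1L, config = NULL) {
  profile <- match.arg(profile)
  if (is.null(config)) {
    config <- if (profile == "tiny") {
      # 256 px at 30 um/px: the default field of view scaled down, with
      # bundle areas still comfortably above the 2 mm^2 area filter
      synth_config(image_size = c(256L, 256L), um_per_px = 30,
                   n_bundles = 3L, n_terminal_fields = 1L,
                   n_artifacts = 1L, seed = seed)
    } else {
      synth_config(seed = seed)
    }
  }
  n_per_stack <- if (profile == "tiny") 4L else 6L
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stacks <- list(
    train = list(seed = seed, labeled = TRUE, shift = 0),
    unlabeled = list(seed = seed + 1L, labeled = FALSE, shift = 0),
    test1 = list(seed = seed + 2L, labeled = TRUE, shift = config$test_bg_shift),
    test2 = list(seed = seed + 3L, labeled = TRUE, shift = -config$test_bg_shift))
  gt_all <- list()
  manifests <- list()
  for (nm in names(stacks)) {
    st <- stacks[[nm]]
    cfg <- config
    cfg$background_mean <- config$background_mean + st$shift
    rois <- with_seed(st$seed, make_pathway_rois(cfg))
    stack <- generate_stack(cfg, n_per_stack, seed = st$seed,
                            pathway_rois = rois)
    sdir <- file.path(outdir, nm)
    dir.create(sdir, showWarnings = FALSE)
    entries <- list()
    for (s in seq_along(stack)) {
      ip <- sprintf("section_%02d.png", s)
      save_section(stack[[s]]$section, file.path(sdir, ip))
      entry <- list(path = ip)
      if (st$labeled) {
        mp <- sprintf("mask_%02d.png", s)
        save_mask(stack[[s]]$truth$label_map, file.path(sdir, mp))
        entry$mask <- mp
      }
      entries[[s]] <- entry
      gt_all[[length(gt_all) + 1]] <-
        dplyr::mutate(stack[[s]]$truth$bundles, stack = nm)
    }
    pw_files <- list()
    for (pn in names(rois)) {
      pf <- sprintf("pathway_%s.png", pn)
      save_mask(rois[[pn]] * 1L, file.path(sdir, pf))
      pw_files[[pn]] <- pf
    }
    man <- list(um_per_px = cfg$um_per_px, spacing_mm = 1.2,
                sections = entries, pathways = pw_files)
    mp <- file.path(sdir, "stack.yaml")
    write_manifest(man, mp)
    manifests[[nm]] <- file.path(nm, "stack.yaml")
  }
  gt <- dplyr::bind_rows(gt_all)
  write.csv(gt, file.path(outdir, "ground_truth.csv"), row.names = FALSE)
  suite <- list(profile = profile, seed = seed, stacks = manifests,
                ground_truth = "ground_truth.csv")
  sp <- file.path(outdir, "suite.yaml")
  yaml::write_yaml(suite, sp)
  invisible(sp)
}

#' Gradient-orientation entropy of a masked image region
#'
#' Shannon entropy (nats) of the gradient-orientation histogram, weighted
#' by gradient magnitude. Bundles (coherent stroke orientation) score low;
#' terminal fields (isotropic puncta) score high — this is what makes the
#' terminal-field confounder a genuine confounder rather than a bundle in
#' disguise.
#'
#' @param image grayscale matrix (0-255).
#' @param mask logical matrix selecting the region.
#' @param n_bins orientation bins over `[0, pi)`.
#' @return Entropy in nats.
#' @export
orientation_entropy <- function(image, mask, n_bins = 12L) {
  H <- nrow(image); W <- ncol(image)
  gr <- matrix(0, H, W); gc <- matrix(0, H, W)
  gr[2:(H - 1), ] <- (image[3:H, ] - image[1:(H - 2), ]) / 2
  gc[, 2:(W - 1)] <- (image[, 3:W] - image[, 1:(W - 2)]) / 2
  mag <- sqrt(gr^2 + gc^2)
  sel <- mask & mag > 1
  if (!any(sel)) return(log(n_bins))
  ang <- atan2(gr[sel], gc[sel]) %% pi
  bin <- pmin(floor(ang / pi * n_bins) + 1, n_bins)
  w <- tapply(mag[sel], factor(bin, levels = seq_len(n_bins)), sum)
  w[is.na(w)] <- 0
  p <- w / sum(w)
  -sum(p[p > 0] * log(p[p > 0]))
}
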