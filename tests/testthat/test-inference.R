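test_that("region extraction labels components and respects the threshold", {
  g <- tiny_section()
  s <- g$section
  prob <- matrix(0, 100, 100)
  prob[10:20, 10:20] <- 0.9
  prob[50:70, 50:80] <- 0.7
  sec <- section_from(array(rep(prob * 255, 3), c(100, 100, 3)))
  reg <- extract_regions(prob, sec, inference_config(prob_threshold = 0.4))
  expect_equal(nrow(reg), 2)
  expect_equal(sort(reg$n_px), c(11 * 11, 21 * 31))
  expect_equal(reg$area_mm2, px_to_mm2(reg$n_px, sec$um_per_px))
  # threshold at/above the maximum -> nothing (strict >)
  reg2 <- extract_regions(prob, sec, inference_config(prob_threshold = 0.9))
  expect_equal(nrow(reg2), 0)
  # diagonal blobs merge under 8-connectivity, split under 4
  pd <- matrix(0, 100, 100)
  pd[10, 10] <- 1; pd[11, 11] <- 1
  r8 <- extract_regions(pd, sec, inference_config(connectivity = 8))
  r4 <- extract_regions(pd, sec, inference_config(connectivity = 4))
  expect_equal(nrow(r8), 1)
  expect_equal(nrow(r4), 2)
})

test_that("area and border filters apply strict published bounds", {
  # 50 um/px -> 1 mm = 20 px, 1 mm^2 = 400 px
  um <- 50
  H <- 200
  tissue <- matrix(FALSE, H, H)
  tissue[2:(H - 1), 2:(H - 1)] <- TRUE
  lab <- matrix(0L, H, H)
  lab[30:49, 30:49] <- 1L     # 400 px = 1.0 mm^2 -> filtered (area)
  lab[80:119, 60:84] <- 2L    # 1000 px = 2.5 mm^2 -> kept
  lab[130:169, 100:129] <- 3L # 1200 px = 3.0 mm^2 -> kept
  prob <- (lab > 0) * 0.9
  sec <- section_from(array(rep(tissue * 30, 3), c(H, H, 3)), um_per_px = um)
  reg <- extract_regions(prob, sec, inference_config())
  reg <- size_and_border_filter(reg, tissue, inference_config())
  expect_equal(sum(!reg$filtered_area & !reg$filtered_border), 2)
  expect_equal(reg$filtered_area, c(TRUE, FALSE, FALSE))
  # region of exactly 2.0 mm^2 is kept (strict <)
  lab2 <- matrix(0L, H, H)
  lab2[50:89, 50:69] <- 1L    # 800 px = 2.0 mm^2 exactly
  reg2 <- extract_regions((lab2 > 0) * 0.9, sec, inference_config())
  reg2 <- size_and_border_filter(reg2, tissue, inference_config())
  expect_false(reg2$filtered_area[1])
  # interior region 0.3 mm from the outline is removed by the border rule
  lab3 <- matrix(0L, H, H)
  lab3[8:47, 60:119] <- 1L    # 6 px = 0.3 mm from the tissue edge at row 2
  reg3 <- extract_regions((lab3 > 0) * 0.9, sec, inference_config())
  reg3 <- size_and_border_filter(reg3, tissue, inference_config())
  expect_true(reg3$filtered_border[1])
  expect_false(reg3$filtered_area[1])  # 2400 px = 6 mm^2
})

test_that("continuity filter removes regions beyond the distance bound", {
  um <- 50                             # 0.5 mm = 10 px
  H <- 120
  lab <- matrix(0L, H, H)
  lab[10:19, 10:19] <- 1L              # overlaps the reference
  lab[10:19, 60:69] <- 2L              # 1.5 mm away from reference edge
  lab[60:69, 10:19] <- 3L              # exactly 0.5 mm away
  ref <- matrix(0, H, H)
  ref[10:19, 10:29] <- 1               # columns up to 29
  # region 2 starts at col 60: gap of 30 px = 1.5 mm -> removed
  # region 3 starts at row 60; nearest reference pixel at row 50
  # -> distance exactly 10 px = 0.5 mm -> kept under the strict rule
  ref[41:50, 10:19] <- 1
  sec <- section_from(array(20, c(H, H, 3)), um_per_px = um)
  reg <- extract_regions((lab > 0) * 0.9, sec, inference_config())
  reg <- continuity_filter(reg, ref, inference_config())
  # identify regions by centroid (label ids follow raster order)
  overlapping <- which(reg$centroid_r < 30 & reg$centroid_c < 30)
  far <- which(reg$centroid_c > 50)
  boundary <- which(reg$centroid_r > 50)
  expect_false(reg$filtered_continuity[overlapping])  # distance 0
  expect_true(reg$filtered_continuity[far])           # > 0.5 mm
  expect_false(reg$filtered_continuity[boundary])     # exactly 0.5 mm (strict >)
  # empty reference removes everything, with a warning
  expect_warning(reg0 <- continuity_filter(reg, matrix(0, H, H),
                                           inference_config()))
  expect_true(all(reg0$filtered_continuity))
})

test_that("filters commute on flags (evaluated on the unfiltered set)", {
  um <- 50; H <- 150
  tissue <- matrix(FALSE, H, H); tissue[2:(H - 1), 2:(H - 1)] <- TRUE
  lab <- matrix(0L, H, H)
  lab[30:59, 30:59] <- 1L
  lab[100:104, 100:104] <- 2L
  ref <- matrix(0, H, H); ref[30:59, 30:59] <- 1
  sec <- section_from(array(rep(tissue * 30, 3), c(H, H, 3)), um_per_px = um)
  cfg <- inference_config()
  r1 <- extract_regions((lab > 0) * 0.9, sec, cfg)
  a <- continuity_filter(size_and_border_filter(r1, tissue, cfg), ref, cfg)
  b <- size_and_border_filter(continuity_filter(r1, ref, cfg), tissue, cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("single-pass inference equals the model's forward pass", {
  m <- tiny_model()
  g <- tiny_section()
  s <- g$section
  cfg <- inference_config(tile_size = 1024L)
  prob <- segment_section(m, s, cfg)
  expect_equal(dim(prob), dim(s))
  expect_equal(prob, forward_seg(m, s$image / 255), tolerance = 1e-12)
})

test_that("tiled inference is continuous and close to whole-image inference", {
  m <- tiny_model()
  g <- tiny_section()
  s <- g$section
  whole <- segment_section(m, s, inference_config(tile_size = 1024L))
  tiled <- segment_section(m, s,
                           inference_config(tile_size = 256L,
                                            tile_overlap = 128L))
  expect_equal(dim(tiled), dim(whole))
  # tiles carry their own reflection-padded context, so blended overlap
  # zones differ from the whole-image pass by a small residual; the map
  # must stay close overall and free of seam discontinuities
  d <- abs(tiled - whole)
  expect_lt(mean(d), 0.01)
  expect_lt(max(d), 0.1)
  # no jump across the tile boundary beyond natural pixel-to-pixel change
  jump <- abs(tiled[, 128] - tiled[, 129])
  expect_lt(max(jump), 0.25)
})

test_that("reference masks average the available neighbours", {
  cfg <- synth_config(image_size = c(128L, 128L), um_per_px = 30,
                      n_bundles = 1L, bundle_axes_mm = c(0.5, 0.7),
                      n_terminal_fields = 0L, n_artifacts = 0L,
                      drift_mm_per_section = 0.0001)
  st <- generate_stack(cfg, 3, seed = 13)
  sections <- lapply(st, `[[`, "section")
  labs <- lapply(st, function(s) s$truth$label_map)
  seg <- make_gt_lowres_segmenter(labs, lowres_factor = 4L)
  icfg <- inference_config(lowres_factor = 4L)
  refs <- build_reference_masks(sections, seg, icfg)
  expect_length(refs, 3)
  # with (nearly) identical masks in both neighbours, the middle section's
  # reference support matches the bundle area closely
  bundle <- labs[[2]] > 0
  support <- refs[[2]] > 0
  dice <- 2 * sum(bundle & support) / (sum(bundle) + sum(support))
  expect_gt(dice, 0.8)
  # end sections use their single neighbour: binary reference
  expect_true(all(refs[[1]] %in% c(0, 1)))
  expect_warning(expect_null(
    build_reference_masks(sections[1], seg, icfg)))
})

test_that("kept regions restrict the label map to the survivors", {
  um <- 50; H <- 150
  tissue <- matrix(FALSE, H, H); tissue[2:(H - 1), 2:(H - 1)] <- TRUE
  lab <- matrix(0L, H, H)
  lab[30:69, 30:59] <- 1L          # 3 mm^2, interior
  lab[100:104, 100:104] <- 2L      # tiny -> area-filtered
  sec <- section_from(array(rep(tissue * 30, 3), c(H, H, 3)), um_per_px = um)
  reg <- extract_regions((lab > 0) * 0.9, sec, inference_config())
  reg <- size_and_border_filter(reg, tissue, inference_config())
  kept <- regions_kept(reg)
  expect_equal(nrow(kept), 1)
  km <- attr(kept, "label_map")
  expect_equal(sort(unique(as.integer(km))), c(0L, 1L))
})
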