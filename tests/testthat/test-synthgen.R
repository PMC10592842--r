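test_that("generation is deterministic under a fixed seed", {
  cfg <- synth_config(image_size = c(128L, 128L), um_per_px = 30,
                      n_bundles = 1L,
                      bundle_axes_mm = c(0.4, 0.5), n_terminal_fields = 1L,
                      n_artifacts = 1L)
  a <- generate_section(cfg, seed = 9)
  b <- generate_section(cfg, seed = 9)
  expect_identical(a$section$image, b$section$image)
  expect_identical(a$truth$label_map, b$truth$label_map)
  c <- generate_section(cfg, seed = 10)
  expect_false(identical(a$section$image, c$section$image))
})

test_that("n_bundles = 0 yields background and confounders only", {
  cfg <- synth_config(image_size = c(128L, 128L), n_bundles = 0L,
                      n_terminal_fields = 1L, n_artifacts = 1L)
  g <- generate_section(cfg, seed = 1)
  expect_equal(max(g$truth$label_map), 0)
  expect_equal(nrow(g$truth$bundles), 0)
  expect_true(any(g$truth$terminal_mask) || any(g$truth$artifact_mask))
})

test_that("rendered stroke coverage tracks the requested fraction", {
  g <- tiny_section()
  expect_true(all(abs(g$truth$bundles$coverage_rendered -
                        g$truth$bundles$coverage_target) <= 0.05))
  # and a 0.4 request lands within +/- 0.05
  cfg <- synth_config(n_bundles = 1L, coverage_dense = 0.4,
                      coverage_moderate = 0.39, coverage_jitter = 0,
                      n_terminal_fields = 0L, n_artifacts = 0L)
  g2 <- generate_section(cfg, seed = 5)
  expect_lt(abs(g2$truth$bundles$coverage_rendered - 0.4), 0.05)
})

test_that("rendered coverage increases monotonically with the request", {
  covs <- seq(0.05, 0.4, by = 0.05)
  rend <- vapply(seq_along(covs), function(i) {
    cfg <- synth_config(n_bundles = 1L, coverage_dense = covs[i] + 1e-9,
                        coverage_moderate = covs[i], coverage_jitter = 0,
                        n_terminal_fields = 0L, n_artifacts = 0L)
    generate_section(cfg, seed = 50 + i)$truth$bundles$coverage_rendered
  }, numeric(1))
  expect_gt(cor(covs, rend, method = "spearman"), 0.9)
})

test_that("bundles lie inside tissue and regions are disjoint", {
  g <- tiny_section()
  expect_true(all(g$truth$tissue_mask[g$truth$label_map > 0]))
  # label map is single-valued by construction; bundle ids contiguous
  expect_equal(sort(unique(as.integer(g$truth$label_map))),
               c(0L, g$truth$bundles$id))
})

test_that("terminal fields are isotropic confounders (orientation entropy)", {
  g <- tiny_section()
  gray <- fibertrace:::to_gray(g$section$image)
  ent_b <- vapply(g$truth$bundles$id, function(id) {
    orientation_entropy(gray, g$truth$label_map == id)
  }, numeric(1))
  ent_t <- orientation_entropy(gray, g$truth$terminal_mask)
  expect_true(all(ent_t > ent_b))
})

test_that("stacks drift within bound and tag spurious single-section regions", {
  cfg <- synth_config(image_size = c(512L, 512L), n_bundles = 2L,
                      bundle_axes_mm = c(0.6, 1.0), n_spurious = 3L,
                      drift_mm_per_section = 0.2)
  st <- generate_stack(cfg, 5, seed = 21)
  gt <- dplyr::bind_rows(lapply(st, function(s) s$truth$bundles))
  drift_lim <- mm_to_px(0.2, cfg$um_per_px)
  real <- dplyr::filter(gt, !is_spurious)
  for (id in unique(real$id)) {
    tr <- dplyr::arrange(dplyr::filter(real, id == !!id), section_index)
    steps <- sqrt(diff(tr$centroid_r)^2 + diff(tr$centroid_c)^2)
    expect_true(all(steps <= drift_lim + 1))  # +1 px centroid discretization
    expect_equal(nrow(tr), 5)                 # persists across the stack
  }
  spur <- dplyr::filter(gt, is_spurious)
  expect_equal(nrow(spur), 3)                 # exactly as requested
  expect_equal(length(unique(paste(spur$id, spur$section_index))), 3)
  # different seeds give different stacks
  st2 <- generate_stack(cfg, 5, seed = 22)
  expect_false(identical(st[[1]]$section$image, st2[[1]]$section$image))
})

test_that("over-crowded configurations fail loudly", {
  cfg <- synth_config(image_size = c(128L, 128L), n_bundles = 12L,
                      bundle_axes_mm = c(0.9, 1.1))
  expect_error(generate_section(cfg, seed = 1), class = "ft_overcrowded")
})

test_that("fixture suite writes loadable stacks with the configured shift", {
  out <- withr::local_tempdir()
  sp <- write_fixture_suite(out, "tiny", seed = 2)
  suite <- yaml::read_yaml(sp)
  expect_named(suite$stacks, c("train", "unlabeled", "test1", "test2"))
  train <- load_stack(file.path(out, suite$stacks$train))
  test1 <- load_stack(file.path(out, suite$stacks$test1))
  # test brain background differs from train by the configured shift
  bg_of <- function(st) {
    s <- st$sections[[1]]
    tm <- compute_tissue_mask(s)
    lab <- st$annotations[[1]]
    sel <- tm & (if (is.null(lab)) TRUE else lab == 0)
    median(s$image[, , 1][sel])
  }
  shift <- bg_of(test1) - bg_of(train)
  expect_gt(shift, 2)
  # unlabeled stack has no masks
  unl <- load_stack(file.path(out, suite$stacks$unlabeled))
  expect_true(all(vapply(unl$annotations, is.null, logical(1))))
})
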