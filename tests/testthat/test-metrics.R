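test_that("fiber density is the exact pixel ratio", {
  mask <- matrix(FALSE, 20, 20)
  mask[1:10, 1:20] <- TRUE            # 200 region pixels
  bin <- matrix(FALSE, 20, 20)
  bin[1, 1:10] <- TRUE                # 10 above threshold
  expect_equal(fiber_density(bin, mask), 5.0)
  expect_equal(fiber_density(mask, mask), 100)
  expect_equal(fiber_density(bin & FALSE, mask), 0)
  expect_error(fiber_density(bin, mask & FALSE),
               class = "ft_validation_error")
})

test_that("fiber maps recover the rendered strokes of a dense bundle", {
  g <- tiny_section()
  id <- g$truth$bundles$id[g$truth$bundles$class == "dense"][1]
  m <- g$truth$label_map == id
  bm <- fiber_binary_map(g$section, m, density_config())
  strokes <- g$truth$stroke_mask & m
  dice <- 2 * sum(bm & strokes) / (sum(bm) + sum(strokes))
  expect_gt(dice, 0.6)
  # determinism
  expect_identical(bm, fiber_binary_map(g$section, m, density_config()))
  # uniform region -> near-empty map (nothing exceeds the percentile)
  flat <- section_from(array(60, c(128, 128, 3)))
  fm <- matrix(FALSE, 128, 128); fm[40:80, 40:80] <- TRUE
  bmf <- fiber_binary_map(flat, fm, density_config(),
                          tissue_mask = matrix(TRUE, 128, 128))
  expect_lt(mean(bmf[fm]), 0.05)
})

test_that("bundle-local FD is invariant to monotone intensity rescaling", {
  g <- tiny_section()
  id <- g$truth$bundles$id[1]
  m <- g$truth$label_map == id
  cfg <- density_config(percentile_domain = "bundle_local")
  fd1 <- fiber_density(fiber_binary_map(g$section, m, cfg), m)
  s2 <- g$section
  s2$image <- 255 * (s2$image / 255)^0.7    # monotone rescaling
  fd2 <- fiber_density(fiber_binary_map(s2, m, cfg), m)
  expect_equal(fd1, fd2, tolerance = 0.02 * max(fd1, 1))
})

test_that("detection matching applies the overlap rule", {
  H <- 60
  tlab <- matrix(0L, H, H)
  tlab[10:29, 10:29] <- 1L
  tlab[40:49, 40:49] <- 2L
  # identical sets: all TP, no FP
  m <- match_detections(tlab, tlab)
  expect_true(all(dplyr::filter(m, role == "true")$detected))
  expect_false(any(dplyr::filter(m, role == "pred")$is_fp))
  # disjoint sets: no TP, all predictions FP
  plab <- matrix(0L, H, H); plab[50:59, 1:9] <- 1L
  m2 <- match_detections(plab, tlab)
  expect_false(any(dplyr::filter(m2, role == "true")$detected))
  expect_true(all(dplyr::filter(m2, role == "pred")$is_fp))
  # one prediction covering both true bundles: 2 TPs, 0 FP
  pboth <- matrix(0L, H, H); pboth[5:55, 5:55] <- 1L
  m3 <- match_detections(pboth, tlab)
  expect_true(all(dplyr::filter(m3, role == "true")$detected))
  expect_false(any(dplyr::filter(m3, role == "pred")$is_fp))
  # two predictions on one bundle: one TP, the extra is not an FP
  ptwo <- matrix(0L, H, H)
  ptwo[10:29, 10:19] <- 1L
  ptwo[10:29, 21:29] <- 2L
  m4 <- match_detections(ptwo, tlab)
  tr <- dplyr::filter(m4, role == "true")
  expect_true(tr$detected[tr$id == 1])
  expect_false(any(dplyr::filter(m4, role == "pred")$is_fp))
  # below the 25% overlap criterion: no match
  psmall <- matrix(0L, H, H)
  psmall[10:29, 28:47] <- 1L   # 2/20 columns overlap -> 10% of smaller
  m5 <- match_detections(psmall, tlab)
  expect_false(dplyr::filter(m5, role == "true")$detected[1])
})

test_that("evaluation metrics aggregate as defined", {
  mk <- function(n_true, n_tp, n_fp) {
    dplyr::bind_rows(
      tibble::tibble(role = "true", id = seq_len(n_true),
                     area_px = 100, detected = seq_len(n_true) <= n_tp,
                     matched_pred = NA_integer_, is_fp = NA),
      tibble::tibble(role = "pred", id = seq_len(n_fp),
                     area_px = 100, detected = NA,
                     matched_pred = NA_integer_, is_fp = TRUE))
  }
  # 8 TP of 10 true; 6 FP over 3 sections
  ev <- compute_metrics(list(mk(4, 3, 1), mk(3, 2, 2), mk(3, 3, 3)))
  expect_equal(ev$tpr, 0.8)
  expect_equal(ev$fp_avg, 2.0)
  # dFD oracle: pairs (10,12), (8,9) -> -1.5
  fd <- tibble::tibble(fd_manual = c(10, 8), fd_predicted = c(12, 9))
  ev2 <- compute_metrics(list(mk(2, 2, 0)), fd)
  expect_equal(ev2$delta_fd, -1.5)
  expect_equal(ev2$delta_fd_abs, 1.5)
  # no true bundles: TPR reported missing
  ev3 <- compute_metrics(list(mk(0, 0, 2)))
  expect_true(is.na(ev3$tpr))
  # tidiers
  expect_equal(nrow(tidy(ev)), 3)
  expect_equal(glance(ev)$tpr, 0.8)
})

test_that("dFD is negative when predictions fit the fibers more tightly", {
  g <- tiny_section()
  id <- g$truth$bundles$id[g$truth$bundles$class == "dense"][1]
  manual <- g$truth$label_map == id
  # predicted region: the same strokes with a tighter boundary (erosion)
  er <- EBImage::erode(manual * 1, EBImage::makeBrush(9, "disc"))
  pred <- matrix(as.logical(er > 0), nrow(manual), ncol(manual))
  cfg <- density_config()
  fd_m <- fiber_density(fiber_binary_map(g$section, manual, cfg), manual)
  fd_p <- fiber_density(fiber_binary_map(g$section, pred, cfg), pred)
  expect_lt(fd_m - fd_p, 0)
})

test_that("pathway assignment uses a strict 40% overlap with tie handling", {
  H <- 100
  ic <- matrix(FALSE, H, H); ic[1:50, 1:50] <- TRUE
  cc <- matrix(FALSE, H, H); cc[1:50, 51:100] <- TRUE
  masks <- list(IC = ic, CC = cc)
  r1 <- matrix(FALSE, H, H); r1[10:19, 10:19] <- TRUE        # 100% in IC
  expect_equal(assign_pathway(r1, masks), "IC")
  # exactly 40%: not assigned (strict >)
  # rows 47..50 of 47..56 fall in IC (4 of 10 rows); the rest is outside
  # both masks
  r2 <- matrix(FALSE, H, H); r2[47:56, 10:19] <- TRUE
  expect_equal(sum(r2 & ic) / sum(r2), 0.4)
  expect_equal(assign_pathway(r2, masks), "none")
  # 30/30 split across two pathways -> none
  r3 <- matrix(FALSE, H, H)
  r3[60:69, 41:70] <- TRUE    # 300 px fully outside both? rows 60+ outside
  r3 <- matrix(FALSE, H, H)
  r3[41:50, 36:65] <- TRUE    # 10x30: cols 36..50 IC (150), 51..65 CC (150)
  r3[51:60, 36:65] <- TRUE    # plus 300 px outside both
  expect_equal(assign_pathway(r3, masks), "none")
  # overlapping masks are rejected
  bad <- list(IC = ic, CC = ic)
  expect_error(assign_pathway(r1, bad), class = "ft_validation_error")
})

test_that("pathway ANOVA matches the hand computation", {
  tab <- tibble::tibble(fd = c(1, 2, 3, 4, 5, 6),
                        pathway = rep(c("IC", "CC"), each = 3))
  pr <- pathway_fd_comparison(tab)
  expect_equal(pr$f_statistic, 13.5, tolerance = 1e-9)
  expect_equal(pr$f_statistic, anova_brute(tab$fd, tab$pathway),
               tolerance = 1e-9)
  expect_equal(pr$summary$n, c(3, 3))
  # identical groups -> F = 0
  tab0 <- tibble::tibble(fd = rep(c(2, 4, 6), 2),
                         pathway = rep(c("IC", "CC"), each = 3))
  expect_equal(pathway_fd_comparison(tab0)$f_statistic, 0, tolerance = 1e-12)
  # random inputs agree with the textbook formula
  set.seed(11)
  tabr <- tibble::tibble(fd = rnorm(30, 10, 2),
                         pathway = sample(c("IC", "CC", "UF"), 30, TRUE))
  expect_equal(pathway_fd_comparison(tabr)$f_statistic,
               anova_brute(tabr$fd, tabr$pathway), tolerance = 1e-9)
  expect_error(pathway_fd_comparison(tibble::tibble(fd = 1:3,
                                                    pathway = "IC")),
               class = "ft_validation_error")
})

test_that("FD estimates increase with the generator's coverage", {
  covs <- seq(0.05, 0.4, by = 0.05)
  fds <- vapply(seq_along(covs), function(i) {
    cfg <- synth_config(n_bundles = 1L, coverage_dense = covs[i] + 1e-9,
                        coverage_moderate = covs[i], coverage_jitter = 0,
                        n_terminal_fields = 0L, n_artifacts = 0L)
    g <- generate_section(cfg, seed = 300 + i)
    m <- g$truth$label_map == 1
    fiber_density(fiber_binary_map(g$section, m, density_config()), m)
  }, numeric(1))
  expect_gt(cor(covs, fds, method = "spearman"), 0.9)
})
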