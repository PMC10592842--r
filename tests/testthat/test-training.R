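# small shared training fixture: 2 labeled sections, tiny model
train_fixture <- function() {
  cached("train_fixture", {
    cfg <- synth_config(image_size = c(128L, 128L), um_per_px = 30,
                        n_bundles = 1L, bundle_axes_mm = c(0.5, 0.7),
                        n_terminal_fields = 0L, n_artifacts = 0L)
    st <- generate_stack(cfg, 3, seed = 77)
    list(sections = lapply(st, `[[`, "section"),
         annotations = lapply(st, function(s) s$truth$label_map))
  })
}

fast_tcfg <- function(...) {
  train_config(pretrain_epochs = 3L, te_epochs = 3L, patch_size = 64L,
               n_patches_per_section = 8L, n_contrastive_pairs = 2L,
               n_unlabeled_patches_per_section = 4L, seed = 5L, ...)
}

test_that("pretraining logs per-epoch losses and is seed-reproducible", {
  fx <- train_fixture()
  m <- tiny_model(patch = 64L, seed = 2L)
  r <- pretrain(m, fx$sections, fx$annotations, fast_tcfg(),
                augment_config())
  expect_equal(nrow(r$history), 3)
  expect_true(all(is.finite(r$history$loss_seg)))
  expect_true(all(is.finite(r$history$val_loss)))
  expect_true(all(is.finite(r$history$loss_con)))
  # same seeds -> identical trajectory
  m2 <- tiny_model(patch = 64L, seed = 2L)
  r2 <- pretrain(m2, fx$sections, fx$annotations, fast_tcfg(),
                 augment_config())
  expect_equal(r$history$loss_seg, r2$history$loss_seg, tolerance = 1e-12)
  # empty labeled set errors
  expect_error(pretrain(tiny_model(patch = 64L), fx$sections,
                        list(NULL, NULL, NULL), fast_tcfg()),
               class = "ft_validation_error")
})

test_that("pseudo-labels are the thresholded mean with a strict tie rule", {
  h <- pred_history(3)
  maps <- list(matrix(0.2, 2, 2), matrix(0.4, 2, 2), matrix(0.9, 2, 2))
  for (m in maps) h <- push_prediction(h, m)
  # mean = 0.5 exactly -> label 0 under strict >
  expect_equal(make_pseudo_label(h, 0.5), matrix(0, 2, 2))
  expect_equal(make_pseudo_label(h, 0.49), matrix(1, 2, 2))
  # identical maps -> the thresholded map itself
  h2 <- pred_history(3)
  mp <- matrix(c(0.1, 0.6, 0.5, 0.8), 2, 2)
  for (i in 1:3) h2 <- push_prediction(h2, mp)
  expect_equal(make_pseudo_label(h2, 0.5), (mp > 0.5) * 1)
  # window 1 reduces to thresholding the last prediction
  h3 <- push_prediction(pred_history(1), mp)
  expect_equal(make_pseudo_label(h3, 0.5), (mp > 0.5) * 1)
  expect_error(make_pseudo_label(pred_history(2)),
               class = "ft_validation_error")
  expect_error(push_prediction(h3, matrix(0, 3, 3)),
               class = "ft_validation_error")
})

test_that("the ring buffer never exceeds its window", {
  h <- pred_history(3)
  for (i in 1:10) {
    h <- push_prediction(h, matrix(i / 10, 2, 2))
    expect_lte(length(h$maps), 3)
  }
  # keeps the three most recent maps
  expect_equal(h$maps[[3]][1, 1], 1.0)
  expect_equal(h$maps[[1]][1, 1], 0.8)
})

test_that("averaging predictions reduces noise variance", {
  set.seed(9)
  truth <- matrix(0.5, 16, 16)
  maps <- lapply(1:3, function(i) {
    pmin(pmax(truth + matrix(rnorm(256, 0, 0.15), 16, 16), 0), 1)
  })
  h <- pred_history(3)
  for (m in maps) h <- push_prediction(h, m)
  avg <- Reduce(`+`, h$maps) / 3
  expect_lte(var(as.numeric(avg)), max(vapply(maps, function(m)
    var(as.numeric(m)), numeric(1))))
})

test_that("temporal ensembling with an empty unlabeled pool degenerates to supervised training", {
  fx <- train_fixture()
  m <- tiny_model(patch = 64L, seed = 3L)
  r <- train_temporal_ensembling(m, fx$sections, fx$annotations, list(),
                                 fast_tcfg(), augment_config())
  expect_equal(nrow(r$history), 3)
  expect_true(all(r$history$phase == "te"))
  expect_true(all(is.finite(r$history$loss_seg)))
})

test_that("temporal ensembling consumes unlabeled sections and stays finite", {
  fx <- train_fixture()
  m <- tiny_model(patch = 64L, seed = 3L)
  pre <- pretrain(m, fx$sections[1:2], fx$annotations[1:2], fast_tcfg())
  r <- train_temporal_ensembling(pre$model, fx$sections[1:2],
                                 fx$annotations[1:2],
                                 fx$sections[3], fast_tcfg())
  expect_equal(nrow(r$history), 3)
  expect_true(all(is.finite(r$history$loss_seg)))
})

test_that("ablation modes flip exactly the intended switches", {
  base <- train_config()
  ce <- apply_ablation_mode(base, "ce")
  expect_equal(ce$loss, "ce")
  expect_false(ce$use_contrastive); expect_false(ce$use_te)
  fo <- apply_ablation_mode(base, "focal")
  expect_equal(fo$loss, "focal")
  expect_false(fo$use_contrastive); expect_false(fo$use_te)
  fc <- apply_ablation_mode(base, "focal_con")
  expect_true(fc$use_contrastive); expect_false(fc$use_te)
  ft <- apply_ablation_mode(base, "focal_con_te")
  expect_true(ft$use_contrastive); expect_true(ft$use_te)
  # the CE mode evaluates the plain cross-entropy objective
  lp <- fibertrace:::loss_params(ce)
  expect_equal(lp$gamma, 0)
  expect_false(lp$alpha_weighting)
})
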