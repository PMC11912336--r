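test_that("metrics behave at the boundaries", {
  expect_equal(metric_rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(metric_rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  expect_error(metric_rmse(1:3, 1:2), "length")
  expect_equal(metric_roc_auc(c(0.9, 0.1), c(1, 0)), 1.0)
  expect_equal(metric_roc_auc(c(0.1, 0.9), c(1, 0)), 0.0)
  expect_equal(metric_roc_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(metric_roc_auc(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("stratified k-fold preserves class balance", {
  labels <- rep(c(1, 0), c(172, 116))
  folds <- stratified_kfold(labels, k = 10, seed = 1)
  expect_setequal(unique(folds), 1:10)
  for (f in 1:10) {
    expect_true(sum(labels == 1 & folds == f) %in% c(17L, 18L))
    expect_true(sum(labels == 0 & folds == f) %in% c(11L, 12L))
  }
  expect_error(stratified_kfold(rep(1, 10), k = 2), "single class")
  expect_error(stratified_kfold(labels, k = 117), "smallest class")
  # k = min class count degenerate case on a balanced 4-sample set
  lab4 <- c(0, 0, 1, 1)
  f4 <- stratified_kfold(lab4, k = 2, seed = 1)
  expect_equal(sort(tabulate(f4)), c(2L, 2L))
  for (f in 1:2) expect_equal(sum(lab4 == 1 & f4 == f), 1L)
})

test_that("training respects max_epochs and early-stopping patience", {
  ds <- make_pretrain_set(40, seed = 5)
  cfg <- small_config(embed = 8)
  one <- pretrain(ds, cfg, train_config(learning_rate = 1e-3, max_epochs = 1,
                                        batch_size = 16, seed = 1))
  expect_equal(nrow(one$history), 1)
  # infinitesimal learning rate + frozen normalization statistics: validation
  # loss never improves after the first epoch, so training halts after
  # exactly `patience` further epochs
  flat <- pretrain(ds, cfg, train_config(learning_rate = 1e-30,
                                         max_epochs = 50, patience = 4,
                                         batch_size = 16, seed = 1,
                                         freeze_bn = TRUE))
  expect_equal(nrow(flat$history), 1 + 4)
})

test_that("pretraining errors and warnings", {
  ds <- make_pretrain_set(40, seed = 5)
  bad <- ds; bad$value[1] <- Inf
  expect_error(pretrain(bad, small_config(embed = 8)), "finite")
  same <- ds; same$value <- 1.0
  expect_warning(
    pretrain(same, small_config(embed = 8),
             train_config(learning_rate = 1e-3, max_epochs = 1,
                          batch_size = 16)),
    "identical")
  expect_error(pretrain(ds[1, , drop = FALSE], small_config(embed = 8)),
               "at least 2")
})

test_that("pretraining fits the additive surrogate to near the noise floor", {
  # scaled-down model (embed 32) and elevated learning rate for desk-scale
  # compute; data sizes and noise are the generator defaults (n = 2000,
  # noise_sd = 0.2)
  st <- get_cached_pretrained()
  val_rmse <- sqrt(min(st$history$val_loss)) * st$y_stats$sd
  expect_lt(val_rmse, 2 * synthetic_config()$noise_sd)
})

test_that("finetune replaces the head and transfers the trunk", {
  pre <- get_cached_pretrained()
  task <- make_task_set(60, seed = 3)
  expect_error(finetune(init_model(small_config("binary-classification")),
                        task), "regression")
  ft <- finetune(pre, task, train_config(learning_rate = 5e-4, max_epochs = 1,
                                         batch_size = 16, seed = 2,
                                         validation_fraction = 1 / 9))
  expect_equal(ft$config$head_kind, "binary-classification")
  # same parameter shapes everywhere (architecture preserved)
  expect_identical(lapply(ft$params, dim), lapply(pre$params, dim))
  # head re-initialized: far from pretrained head
  expect_gt(norm(ft$params$head_W1 - pre$params$head_W1, "F"), 0.1)
  # trunk moved, but by a small amount after one epoch at small lr
  drift <- norm(ft$params$conv1_W - pre$params$conv1_W, "F") /
    norm(pre$params$conv1_W, "F")
  expect_gt(drift, 0)
  expect_lt(drift, 0.1)
  # zero learning rate is rejected; infinitesimal rate leaves trunk unchanged
  fr <- finetune(pre, task,
                 train_config(learning_rate = 1e-300, max_epochs = 1,
                              batch_size = 16, seed = 2,
                              validation_fraction = 1 / 9))
  expect_equal(fr$params$conv1_W, pre$params$conv1_W, tolerance = 1e-12)
})

test_that("repeated_split_eval scores held-out molecules only", {
  cfgS <- synthetic_config(task_noise_sd = 0,
                           alert_patterns = list(
                             list(smarts = "NC(=S)N", effect = 0)))
  task <- make_task_set(200, config = cfgS, seed = 9)
  # oracle: the exact generating score -> perfect AUC with zero spread
  oracle_builder <- function(train_rec, seed) additive_mock_model(cfgS)
  rep_o <- repeated_split_eval(oracle_builder, task, n_splits = 3, seed = 1)
  expect_equal(rep_o$mean, 1.0)
  expect_equal(rep_o$sd, 0.0)
  # label-independent scores -> AUC near 0.5
  rand_builder <- function(train_rec, seed) hash_score_model()
  big <- make_task_set(1000, config = cfgS, seed = 10)
  rep_r <- repeated_split_eval(rand_builder, big, n_splits = 5, seed = 2)
  expect_lt(abs(rep_r$mean - 0.5), 0.1)
  expect_warning(
    repeated_split_eval(oracle_builder, task, n_splits = 1, seed = 1),
    "n_splits = 1")
})
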