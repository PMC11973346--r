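# small epoch sets + scaled-down architecture keep these protocol tests fast
tiny_sets <- function(n_per = 6L, seed = 2L) {
  ep <- generate_epochs(synth_config(
    n_trials_per_class = n_per, n_classes = 2L, n_channels = 4L,
    sfreq = 250, duration_s = 0.4,
    class_bands = list(c(8, 12), c(20, 24)),
    class_channels = list(1:2, 3:4),
    modulation_depth = 4, seed = seed))
  split_epochs(ep, split_spec(0.5, 0.25, 0.25, seed = seed))
}

tiny_train_cfg <- function(...) {
  defaults <- list(batch_size = 8L, max_epochs_stage1 = 4L, patience = 3L,
                   max_epochs_stage2 = 2L, seed = 5L)
  args <- utils::modifyList(defaults, list(...))
  do.call(train_config, args)
}

tiny_arch <- function(parts, drop = "none") {
  glcnet_config(n_channels = 4L, n_times = 100L, n_bands = 9L,
                n_classes = 2L, temporal_conv_filters = 4L,
                pool_factor = 10L, gcn_dims = c(6L, 5L),
                spatial_filters = 18L, spatial_groups = 9L,
                avg_window = 20L, lstm_hidden = 4L, dropout_p = 0.1,
                adjacency = pli_adjacency(parts$train), drop = drop)
}

test_that("stage 1 stops by patience when accuracy is frozen", {
  parts <- tiny_sets()
  set_global_seed(1)
  model <- build_glcnet(tiny_arch(parts))
  # learning rate too small to change predictions: epoch 1 sets the best,
  # epochs 2..(1+patience) fail to improve, then training stops
  res <- train_two_stage(model, parts$train, parts$val,
                         tiny_train_cfg(learning_rate = 1e-30, patience = 2L,
                                        max_epochs_stage1 = 10L,
                                        max_epochs_stage2 = 1L))
  s1 <- res$history$records[res$history$records$stage == 1L, ]
  expect_identical(nrow(s1), 3L)
  expect_identical(res$history$best_epoch, 1L)
})

test_that("restored weights re-achieve the recorded best validation accuracy", {
  parts <- tiny_sets()
  set_global_seed(1)
  model <- build_glcnet(tiny_arch(parts))
  cfgt <- tiny_train_cfg(max_epochs_stage1 = 5L, patience = 5L,
                         max_epochs_stage2 = 0L)
  cfgt$max_epochs_stage2 <- 0L
  res <- train_two_stage(model, parts$train, parts$val, cfgt)
  rep_ <- evaluate(res$model, parts$val)
  expect_equal(rep_$accuracy, res$history$best_val_accuracy,
               tolerance = 1e-12)
})

test_that("stage 2 stops once the monitored loss beats the stage-1 best", {
  parts <- tiny_sets(n_per = 8L)
  set_global_seed(4)
  model <- build_glcnet(tiny_arch(parts))
  res <- train_two_stage(model, parts$train, parts$val,
                         tiny_train_cfg(max_epochs_stage1 = 6L,
                                        patience = 6L,
                                        max_epochs_stage2 = 40L))
  h <- res$history
  s2 <- h$records[h$records$stage == 2L, ]
  if (h$stage2_stopped) {
    expect_lt(s2$val_loss[nrow(s2)], h$stage1_best_val_loss)
    if (nrow(s2) > 1L)
      expect_true(all(s2$val_loss[-nrow(s2)] >= h$stage1_best_val_loss))
  } else {
    expect_identical(nrow(s2), 40L)
  }
})

test_that("training histories are bit-identical under a repeated seed", {
  parts <- tiny_sets()
  set_global_seed(1)
  m1 <- build_glcnet(tiny_arch(parts))
  r1 <- train_two_stage(m1, parts$train, parts$val, tiny_train_cfg())
  set_global_seed(1)
  m2 <- build_glcnet(tiny_arch(parts))
  r2 <- train_two_stage(m2, parts$train, parts$val, tiny_train_cfg())
  expect_identical(r1$history$records, r2$history$records)
  expect_equal(r1$model$params, r2$model$params)
  set_global_seed(2)
  m3 <- build_glcnet(tiny_arch(parts))
  expect_false(identical(m3$params$cl_W, m2$params$cl_W))
})

test_that("training loss decreases on a fixed batch under Adam descent", {
  parts <- tiny_sets(n_per = 8L)
  set_global_seed(6)
  model <- build_glcnet(tiny_arch(parts))
  bank <- filter_bank()
  bt <- apply_filterbank(parts$train, bank)
  cfgt <- tiny_train_cfg(batch_size = 24L, max_epochs_stage1 = 10L,
                         patience = 10L)
  opt <- glcnet:::adam_init(model$params)
  losses <- numeric(10)
  for (e in 1:10) {
    stepped <- glcnet:::train_epoch(model, bt$data, parts$train$labels,
                                    cfgt, opt)
    model <- stepped$model; opt <- stepped$opt
    losses[e] <- stepped$loss
  }
  expect_lt(mean(losses[8:10]), mean(losses[1:3]))
})

test_that("ECE is bounded by CE at identical weights", {
  parts <- tiny_sets()
  set_global_seed(1)
  model <- build_glcnet(tiny_arch(parts))
  bt <- apply_filterbank(parts$train)
  logp <- glcnet:::glc_predict_logp(model, bt)
  expect_lte(batch_loss(t(logp), parts$train$labels, "ece"),
             batch_loss(t(logp), parts$train$labels, "ce"))
})

test_that("evaluation is deterministic, conserves n, and sits at chance for
           an untrained model on unstructured data", {
  set.seed(7)
  null_ep <- generate_epochs(synth_config(
    n_trials_per_class = 25L, n_classes = 4L, n_channels = 4L,
    sfreq = 250, duration_s = 0.4, class_channels = as.list(1:4),
    modulation_depth = 0, seed = 8L))
  set_global_seed(7)
  cfg <- glcnet_config(n_channels = 4L, n_times = 100L, n_bands = 9L,
                       n_classes = 4L, temporal_conv_filters = 4L,
                       pool_factor = 10L, gcn_dims = c(6L, 5L),
                       spatial_filters = 18L, spatial_groups = 9L,
                       avg_window = 20L, lstm_hidden = 4L,
                       adjacency = random_adjacency(4L))
  model <- build_glcnet(cfg)
  r1 <- evaluate(model, null_ep)
  r2 <- evaluate(model, null_ep)
  expect_identical(r1$accuracy, r2$accuracy)
  expect_identical(r1$n, 100L)
  # binomial 95% band around chance for n = 100
  expect_gt(r1$accuracy, 0.25 - 1.96 * sqrt(0.25 * 0.75 / 100) - 1e-9)
  expect_lt(r1$accuracy, 0.25 + 1.96 * sqrt(0.25 * 0.75 / 100) + 1e-9)
  wide <- epoch_set(array(rnorm(4 * 6 * 100), c(4, 6, 100)), 0:3, 250)
  expect_error(evaluate(model, wide), "channel")
})
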