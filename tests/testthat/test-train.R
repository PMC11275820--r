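test_that("nested configuration overrides merge without clobbering", {
  cfg <- run_config(pretrain = list(iterations = 10),
                    graph = list(alpha = 0.01))
  expect_equal(cfg$pretrain$iterations, 10)
  expect_equal(cfg$pretrain$batch_size, 32L)  # untouched sibling survives
  expect_equal(cfg$graph$alpha, 0.01)
  expect_equal(cfg$graph$theta, 6)
  expect_equal(cfg$temperature, 0.1)
})

test_that("pretraining logs a loss trajectory and is reproducible", {
  ses <- tiny_session()
  cfg <- tiny_config()
  ck1 <- pretrain(ses, cfg)
  expect_s3_class(ck1, "eeg_checkpoint")
  expect_equal(nrow(ck1$history), 4)
  expect_true(all(is.finite(ck1$history$l_total)))
  expect_equal(ck1$history$l_total, ck1$history$l_s + ck1$history$l_t)

  ck2 <- pretrain(ses, cfg)
  expect_equal(ck1$history, ck2$history)  # same config + seed, same losses
  expect_equal(ck1$spatial, ck2$spatial)
})

test_that("branch ablations remove exactly the named component", {
  ses <- tiny_session()
  ck_s <- pretrain(ses, tiny_config(ablation = list(spatial_off = TRUE)))
  expect_null(ck_s$spatial)
  expect_false(is.null(ck_s$temporal))
  expect_true(all(ck_s$history$l_s == 0))
  expect_true(all(ck_s$history$l_t > 0))

  ck_t <- pretrain(ses, tiny_config(ablation = list(temporal_off = TRUE)))
  expect_null(ck_t$temporal)
  expect_true(all(ck_t$history$l_t == 0))
})

test_that("augmentation and attention ablations run end to end", {
  ses <- tiny_session()
  for (abl in list(list(mask_instead_of_denoise = TRUE),
                   list(vanilla_attention = TRUE),
                   list(random_edge_drop = TRUE))) {
    ck <- pretrain(ses, tiny_config(ablation = abl))
    expect_true(all(is.finite(ck$history$l_total)))
  }
})

test_that("the memory queue adds negatives without breaking training", {
  ses <- tiny_session()
  ck <- pretrain(ses, tiny_config(queue_size = 8))
  expect_true(all(is.finite(ck$history$l_total)))
})

test_that("cross-validation partitions segments and keeps trials intact", {
  ses <- tiny_session(n_subjects = 2, n_videos = 4)
  cfg <- tiny_config()
  ck <- pretrain(ses, cfg)
  rep <- finetune_and_evaluate(ses, ck, cfg)
  expect_s3_class(rep, "eval_report")
  # partition: every segment in exactly one test fold
  expect_equal(sort(unique(rep$fold_of)), 1:2)
  expect_equal(length(rep$fold_of), nrow(ses$meta))
  # trial split: all windows of a trial share a fold
  per_trial <- tapply(rep$fold_of,
                      paste(ses$meta$subject, ses$meta$video),
                      function(f) length(unique(f)))
  expect_true(all(per_trial == 1))
  # confusion-matrix row sums equal per-class test counts
  expect_equal(sum(rep$confusion), nrow(ses$meta))
  expect_equal(unname(rowSums(rep$confusion)),
               unname(as.vector(table(ses$meta$class))))
  expect_equal(rep$mean_accuracy, mean(rep$per_fold$accuracy))
})

test_that("zero noise reproduces the clean evaluation exactly", {
  ses <- tiny_session()
  cfg <- tiny_config()
  ck <- pretrain(ses, cfg)
  rep <- finetune_and_evaluate(ses, ck, cfg, keep_models = TRUE)
  nz <- noise_perturbation_eval(ses, rep, levels = c(0, 0.1), cfg)
  pooled <- sum(rep$per_fold$accuracy * rep$per_fold$n_test) /
    sum(rep$per_fold$n_test)
  expect_equal(nz$accuracy[nz$level == 0], pooled)
  expect_equal(nrow(nz), 2)
})

test_that("tidiers and plots expose the fitted objects' content", {
  ses <- tiny_session()
  cfg <- tiny_config()
  ck <- pretrain(ses, cfg)
  expect_equal(tidy(ck), ck$history)
  expect_equal(glance(ck)$steps, 4)
  rep <- finetune_and_evaluate(ses, ck, cfg)
  expect_equal(tidy(rep), rep$per_fold)
  expect_equal(glance(rep)$mean_accuracy, rep$mean_accuracy)
  cm <- tidy_confusion(rep)
  expect_equal(sum(cm$n), nrow(ses$meta))
  out <- withr::local_tempdir()
  write_eval_report(rep, out)
  expect_true(file.exists(file.path(out, "report.json")))
  expect_true(file.exists(file.path(out, "confusion.csv")))
  expect_s3_class(autoplot(ck), "ggplot")
  expect_s3_class(autoplot(rep), "ggplot")
  g <- channel_graph(ring_layout(4))
  expect_s3_class(autoplot(g), "ggplot")
  expect_s3_class(plot_degree_flow(degree_flow(g$base_adjacency)), "ggplot")
})
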