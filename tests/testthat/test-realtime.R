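# Streaming session loop, thermometer, ROC, cross-validation,
# experiments and channel t-maps.

test_that("thermometer rises, falls, clamps to 20 levels, resets", {
  expect_equal(step_thermometer(0, TRUE, TRUE), 1L)
  expect_equal(step_thermometer(3, FALSE, TRUE), 2L)
  expect_equal(step_thermometer(10, TRUE, TRUE), 10L)     # clamp top
  expect_equal(step_thermometer(-10, FALSE, TRUE), -10L)  # clamp bottom
  expect_equal(step_thermometer(7, TRUE, TRUE, block_ended = TRUE), 0L)
  expect_equal(step_thermometer(5, TRUE, in_task = FALSE), 0L)
})

make_session <- function(seed = 31, params = hemo_params(),
                         layout = default_layout(), task_type = "ME") {
  s1 <- make_run_spec(6, task_type, run_index = 1, seed = seed)
  s2 <- make_run_spec(6, task_type, run_index = 2, seed = seed + 1)
  r1 <- generate_run(s1, layout, params, seed = seed + 2)
  r2 <- generate_run(s2, layout, params, seed = seed + 3)
  fit <- fit_run_model(r1, layout)
  list(run = r2, fit = fit,
       res = run_online_session(r2, fit$selector, fit$model))
}

test_that("noise-free synthetic run is classified perfectly", {
  s <- make_session(params = clean_params())
  task <- s$res$trace$kind == "task"
  # first task second carries almost no response; all others separate
  expect_gte(s$res$accuracy_pct, 95)
  expect_equal(s$res$roc$auc, 1, tolerance = 0.01)
})

test_that("session accuracy equals its stored confusion-derived accuracy", {
  s <- make_session()
  tr <- s$res$trace[s$res$trace$kind == "task", ]
  expect_equal(s$res$accuracy_pct, 100 * mean(tr$pred == tr$label))
  expect_equal(s$res$n_task_seconds, nrow(tr))
  # rest seconds never scored
  expect_true(all(is.na(s$res$trace$pred[s$res$trace$kind == "rest"])))
})

test_that("online replay equals batch application of model plus per-block bias", {
  s <- make_session(seed = 41)
  fset <- extract_features(s$run)
  xsel <- fset$features[, s$fit$selector$selected, drop = FALSE]
  vals <- decision_value(s$fit$model, xsel)
  # batch bias: mean of each rest block's decisions, applied to the next block
  blocks <- s$run$spec$blocks
  bias <- numeric(nrow(fset$features))
  for (b in which(blocks$kind == "task")) {
    rest_secs <- fset$block == b - 1L
    bias[fset$block == b] <- mean(vals[rest_secs])
  }
  task <- fset$kind == "task"
  batch_pred <- ifelse(vals[task] - bias[task] >= 0, "right", "left")
  expect_identical(batch_pred, s$res$trace$pred[task])
  expect_equal(vals[task] - bias[task], s$res$trace$corrected[task])
})

test_that("bias correction within a block is a pure shift of decision values", {
  s <- make_session(seed = 43)
  tr <- s$res$trace
  for (b in unique(tr$block[tr$kind == "task"])) {
    sel <- tr$block == b
    expect_equal(length(unique(round(tr$raw[sel] - tr$corrected[sel], 9))), 1L)
    expect_equal(order(tr$raw[sel]), order(tr$corrected[sel]))
  }
})

test_that("thermometer trace is a pure function of correctness and blocks", {
  s <- make_session(seed = 44)
  tr <- s$res$trace
  grade <- 0L
  prev_block <- tr$block[1]
  replay <- integer(nrow(tr))
  for (k in seq_len(nrow(tr))) {
    if (tr$block[k] != prev_block) {
      if (tr$kind[k] != "task") grade <- 0L
      prev_block <- tr$block[k]
    }
    if (tr$kind[k] == "task") {
      grade <- step_thermometer(grade, tr$correct[k], TRUE)
    } else {
      grade <- 0L
    }
    replay[k] <- grade
  }
  expect_identical(replay, tr$thermometer)
  expect_true(all(abs(tr$thermometer) <= 10))
  expect_true(all(tr$thermometer[tr$kind == "rest"] == 0))
})

test_that("permuted labels and zero activation both score at chance", {
  # post-hoc permutation of the task-second labels
  s <- make_session(seed = 45)
  tr <- s$res$trace[s$res$trace$kind == "task", ]
  n <- nrow(tr)
  half <- 1.96 * sqrt(0.25 / n)
  accs <- with_seed_local(7, replicate(10, mean(tr$pred == sample(tr$label))))
  expect_lt(abs(mean(accs) - 0.5), half)
  # a world with no activation at all
  s0 <- make_session(seed = 46, params = hemo_params(hbo_amp = 0))
  expect_gt(s0$res$accuracy_pct, 50 - 100 * half)
  expect_lt(s0$res$accuracy_pct, 50 + 100 * half)
})

test_that("model/layout mismatches and leakage are refused", {
  s <- make_session(seed = 47)
  other <- quick_run(layout = tiny_layout())
  expect_error(run_online_session(other, s$fit$selector, s$fit$model),
               class = "fnirsbci_invalid")
  # a model trained on run 2 must not classify run 2
  expect_error(run_online_session(s$run, s$fit$selector,
                                  fit_run_model(s$run, default_layout())$model),
               class = "fnirsbci_invalid")
})

test_that("ROC: perfect ordering, hand-enumerated 4-point case, chance scores", {
  expect_equal(evaluate_roc(c(3, 2, -1, -2), c(1, 1, -1, -1))$auc, 1)
  # thresholds enumerated by hand: TP ordering [+ - + -] gives AUC 3/4
  r <- evaluate_roc(c(0.9, 0.8, 0.3, 0.1), c(1, -1, 1, -1))
  expect_equal(r$auc, 0.75)
  expect_equal(unname(r$operating_point), c(1, 1))  # all scores >= 0
  # signed scores realize the ideal operating point
  r2 <- evaluate_roc(c(0.9, -0.8, 0.3, -0.1), c(1, -1, 1, -1))
  expect_equal(unname(r2$operating_point), c(0, 1))
  set.seed(48)
  scores <- rnorm(1000)
  y <- rep(c(1, -1), 500)
  ra <- evaluate_roc(scores, y)
  expect_gt(ra$auc, 0.45)
  expect_lt(ra$auc, 0.55)
  # trapezoid AUC agrees with the rank-statistic oracle on random sets
  for (seed in 1:5) {
    set.seed(seed)
    sc <- rnorm(30)
    yy <- sign(rnorm(30)); yy[yy == 0] <- 1
    expect_equal(evaluate_roc(sc, yy)$auc, auc_oracle(sc, yy), tolerance = 1e-12)
  }
  expect_error(evaluate_roc(1:3, c(1, 1, 1)), class = "fnirsbci_invalid")
})

test_that("5-fold CV partitions evenly, is deterministic, aces separable data", {
  lay <- default_layout()
  run <- generate_run(make_run_spec(6, "ME", 20, 20, seed = 51), lay,
                      clean_params(), seed = 52)
  fset <- extract_features(run)
  cv <- crossvalidate_5fold(fset, lay, seed = 1)
  cv2 <- crossvalidate_5fold(fset, lay, seed = 1)
  expect_equal(cv, cv2)
  expect_gte(cv$mean_pct, 95)
  # fold sizes: K = 120 task seconds -> 24 per fold
  fold_sizes <- with_seed_local(1, table(sample(rep_len(1:5, 120))))
  expect_true(all(fold_sizes == 24))
  short <- fset
  expect_error(crossvalidate_5fold(
    structure(list(features = fset$features[1:5, ], second = 1:5,
                   kind = rep("task", 5), label = rep(c("left", "right"), 3)[1:5],
                   block = rep(2L, 5), since_onset_s = 0:4,
                   n_channels = 48, layout = lay, run_index = 1L,
                   task_type = "ME"), class = "feature_set"), lay),
    class = "fnirsbci_invalid")
})

test_that("experiments follow the adaptation schedule without leakage", {
  lay <- tiny_layout()
  p <- hemo_params(noise_sd = 0.2)
  subj <- generate_subject(experiment_plan(1), lay, p, seed = 61,
                           n_task_blocks = 2, task_dur_s = 8, rest_dur_s = 8)
  res1 <- run_experiment(experiment_plan(1), subj, lay, n_select = 4)
  expect_named(res1, c("run3", "run4", "run5"))
  expect_equal(res1$run3$model_runs, c(1L, 2L))
  expect_equal(res1$run4$model_runs, c(2L, 3L))
  expect_equal(res1$run5$model_runs, c(3L, 4L))

  subj2 <- generate_subject(experiment_plan(2), lay, p, seed = 62,
                            n_task_blocks = 2, task_dur_s = 8, rest_dur_s = 8)
  res2 <- run_experiment(experiment_plan(2), subj2, lay, n_select = 4)
  expect_equal(res2$run2$model_runs, 1L)
  expect_equal(res2$run5$model_runs, c(3L, 4L))  # ME run scored by MI model

  expect_error(run_experiment(experiment_plan(3), subj, lay),
               class = "fnirsbci_invalid")
  pool <- lapply(c(63, 64), function(sd) {
    generate_subject(experiment_plan(1), lay, p, seed = sd,
                     n_task_blocks = 2, task_dur_s = 8, rest_dur_s = 8)[1:3]
  })
  sic <- build_subject_independent_model(pool, lay, n_select = 4)
  res3 <- run_experiment(experiment_plan(3), subj, lay, sic = sic,
                         n_select = 4)
  expect_named(res3, c("run2", "run3", "run4", "run5"))
  # frozen model: identical weights used in every run
  expect_true(all(vapply(res3, function(r)
    identical(r$model_runs, sic$model$training_runs), logical(1))))
})

test_that("channel t-map flags strong activations, NAs constants, spares nulls", {
  lay <- tiny_layout()
  run <- quick_run(seed = 71, n_task = 4, dur = 10,
                   params = hemo_params(noise_sd = 0.2, mayer_amp = 0,
                                        cardiac_amp = 0, resp_amp = 0,
                                        drift_slope = 0))
  tmap <- channel_tmap(run, alpha = 0.001)
  act <- unlist(active_channels(lay, hemo_params(), "ME"))
  expect_true(any(tmap$flagged[tmap$channel %in% act]))
  # constant channel: NA, no crash
  run$hbo[, 1] <- 5
  tmap2 <- channel_tmap(run)
  expect_true(all(is.na(tmap2$t[tmap2$channel == 1])))
  expect_false(any(tmap2$flagged[tmap2$channel == 1]))
  # run without task blocks is rejected
  runr <- quick_run(n_task = 0)
  expect_error(channel_tmap(runr), class = "fnirsbci_invalid")
})

test_that("cross-modal transfer: ME-trained models decode MI and vice versa", {
  lay <- default_layout()
  p <- hemo_params()
  n <- 0
  for (seed in c(81, 82)) {
    sME <- make_run_spec(6, "ME", run_index = 1, seed = seed)
    sMI <- make_run_spec(6, "MI", run_index = 2, seed = seed + 1)
    rME <- generate_run(sME, lay, p, seed = seed + 2)
    rMI <- generate_run(sMI, lay, p, seed = seed + 3)
    me_fit <- fit_run_model(rME, lay)
    mi_res <- run_online_session(rMI, me_fit$selector, me_fit$model)
    sMI1 <- make_run_spec(6, "MI", run_index = 1, seed = seed + 4)
    rMI1 <- generate_run(sMI1, lay, p, seed = seed + 5)
    sME2 <- make_run_spec(6, "ME", run_index = 2, seed = seed + 6)
    rME2 <- generate_run(sME2, lay, p, seed = seed + 7)
    mi_fit <- fit_run_model(rMI1, lay)
    me_res <- run_online_session(rME2, mi_fit$selector, mi_fit$model)
    # above the 95% binomial chance bound for 120 task seconds (~59%)
    expect_gt(mi_res$accuracy_pct, 59)
    expect_gt(me_res$accuracy_pct, 59)
  }
})
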