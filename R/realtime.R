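# Streaming session loop: per-second classification with rest-bias
# correction, thermometer neurofeedback, evaluation (ROC, 5-fold CV,
# channel t-maps) and the three experiment paradigms.

#' Thermometer feedback state update
#'
#' One step of the graded feedback display: during a task second the
#' grade rises by one for a correct classification and falls by one for
#' an incorrect one, clamped to `[-10, 10]` (a dynamic range of 20
#' levels).  During rest, and at the end of every task block, the grade
#' returns to the 0 baseline.
#'
#' @param grade current integer grade in `[-10, 10]`.
#' @param correct was the classification of this second correct?
#' @param in_task is this second inside a task block?
#' @param block_ended did a task block just end?
#' @return the new grade.
#' @export
step_thermometer <- function(grade, correct, in_task, block_ended = FALSE) {
  if (block_ended || !in_task) return(0L)
  g <- grade + if (isTRUE(correct)) 1L else -1L
  max(min(g, 10L), -10L)
}

#' Fit a subject-dependent model from training runs
#'
#' Channel selection (Parzen MI, hemisphere balanced) and SVM training
#' on the pooled task seconds of the given runs.
#'
#' @param runs a `run_data` or list of them.
#' @param layout the shared `channel_layout`.
#' @param n_select channels kept by the selector.
#' @param c_param SVM penalty.
#' @return list with `selector` and `model` (its `training_runs` record
#'   the provenance).
#' @export
fit_run_model <- function(runs, layout, n_select = 12L, c_param = 1) {
  if (inherits(runs, "run_data")) runs <- list(runs)
  fsets <- lapply(runs, extract_features)
  selector <- fit_selector(fsets, layout, n_select)
  pooled <- pool_task_samples(fsets)
  ts <- training_set(pooled$x[, selector$selected, drop = FALSE], pooled$y,
                     runs = pooled$runs)
  list(selector = selector, model = train_linear_svm(ts, c_param = c_param))
}

#' Replay a run through the real-time classification loop
#'
#' Processes the run second by second, exactly as the online system
#' would: features are extracted for each elapsed second; during rest
#' blocks the SVM decision values accumulate and their mean becomes the
#' bias offset of the following task block; during task blocks the
#' bias-corrected decision is thresholded at zero, correctness is
#' scored, and the thermometer is updated (reset at each block end).
#' Accuracy is the percentage of correctly classified task seconds; rest
#' seconds are never scored.
#'
#' @param run a `run_data`.
#' @param selector a `selector_model` for the run's layout.
#' @param model the `svm_model` trained on the selector's channels.
#' @param feedback logical; when `FALSE` the thermometer stays at 0
#'   (training-run display), the classifications are unchanged.
#' @return An object of class `session_result`: `trace` data frame
#'   (`second`, `kind`, `label`, `block`, `since_onset_s`, `raw`,
#'   `bias`, `corrected`, `pred`, `correct`, `thermometer`),
#'   `accuracy_pct`, `n_task_seconds`, `roc` (from [evaluate_roc()]) and
#'   `model_runs` (training provenance).
#' @export
run_online_session <- function(run, selector, model, feedback = TRUE) {
  stopifnot(inherits(run, "run_data"))
  if (!identical(selector$layout_hash, layout_hash(run$layout))) {
    stop_invalid("selector was fitted on a different layout")
  }
  if (length(model$W) != selector$n_select) {
    stop_invalid("model dimension does not match the selector")
  }
  if (run$run_index %in% model$training_runs) {
    stop_invalid("model was trained on run ", run$run_index,
                 "; refusing to test on its own training data")
  }
  fset <- extract_features(run)
  xsel <- fset$features[, selector$selected, drop = FALSE]
  n <- nrow(xsel)

  raw <- numeric(n)
  bias <- numeric(n)
  corrected <- numeric(n)
  pred <- rep(NA_character_, n)
  correct <- rep(NA, n)
  thermo <- integer(n)

  grade <- 0L
  cur_bias <- 0
  rest_acc <- numeric(0)
  prev_block <- fset$block[1]
  for (k in seq_len(n)) {
    if (fset$block[k] != prev_block) {
      if (fset$kind[k] == "task") {
        # task block begins: freeze the bias from the rest block just ended
        if (length(rest_acc)) cur_bias <- rest_bias(rest_acc)
      } else {
        # task block ended: thermometer resets, rest accumulator restarts
        grade <- 0L
        rest_acc <- numeric(0)
      }
      prev_block <- fset$block[k]
    }
    v <- decision_value(model, xsel[k, ])
    raw[k] <- v
    if (fset$kind[k] == "rest") {
      rest_acc <- c(rest_acc, v)
      bias[k] <- cur_bias
      corrected[k] <- v - cur_bias
      grade <- 0L
    } else {
      bias[k] <- cur_bias
      corrected[k] <- v - cur_bias
      pred[k] <- if (corrected[k] >= 0) "right" else "left"
      correct[k] <- pred[k] == fset$label[k]
      if (feedback) grade <- step_thermometer(grade, correct[k], TRUE)
    }
    thermo[k] <- grade
  }

  task <- fset$kind == "task"
  acc <- 100 * mean(correct[task])
  roc <- evaluate_roc(corrected[task],
                      ifelse(fset$label[task] == "right", 1, -1))
  structure(list(
    trace = data.frame(second = fset$second, kind = fset$kind,
                       label = fset$label, block = fset$block,
                       since_onset_s = fset$since_onset_s,
                       raw = raw, bias = bias, corrected = corrected,
                       pred = pred, correct = correct, thermometer = thermo),
    accuracy_pct = acc,
    n_task_seconds = sum(task),
    roc = roc,
    feedback = feedback,
    run_index = run$run_index,
    task_type = run$task_type,
    model_runs = model$training_runs), class = "session_result")
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf("<session_result> run %d (%s): %.1f%% over %d task second(s), AUC %.3f\n",
              x$run_index, x$task_type, x$accuracy_pct, x$n_task_seconds,
              x$roc$auc))
  invisible(x)
}

#' ROC curve, AUC and the deployed operating point
#'
#' Sweeps the decision threshold over all observed values ("right" = +1
#' is the positive class), computes the true/false positive rates,
#' integrates the area under the curve by the trapezoid rule, and
#' reports the operating point realized at the deployed threshold of 0.
#'
#' @param decision_values numeric scores, larger meaning more "right".
#' @param labels +1/-1 (or `"right"`/`"left"`); both classes required.
#' @return list with `points` (data frame `threshold`, `fpr`, `tpr`),
#'   `auc` and `operating_point` (`fpr`, `tpr` at threshold 0).
#' @export
evaluate_roc <- function(decision_values, labels) {
  y <- label_to_y(labels)
  if (length(unique(y)) < 2L) stop_invalid("both classes required for a ROC")
  pos <- y > 0
  thr <- c(Inf, sort(unique(decision_values), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(b) mean(decision_values[pos] >= b), numeric(1))
  fpr <- vapply(thr, function(b) mean(decision_values[!pos] >= b), numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
       auc = auc,
       operating_point = c(fpr = mean(decision_values[!pos] >= 0),
                           tpr = mean(decision_values[pos] >= 0)))
}

#' Five-fold cross-validation of selector + SVM
#'
#' Randomly partitions the task seconds into five near-equal folds
#' (seeded); in each fold the channel selector and the SVM are fitted on
#' the other four folds and scored on the held-out one.  Splitting is at
#' the sample (second) level by default, mirroring the online training
#' pipeline; `by_block = TRUE` splits whole task blocks instead, which
#' avoids the temporal-autocorrelation leakage of sample-level folds.
#'
#' @param fset a `feature_set` (or list pooled together).
#' @param layout the `channel_layout`.
#' @param seed fold-assignment seed.
#' @param n_select,c_param selector size and SVM penalty.
#' @param by_block split whole blocks instead of seconds.
#' @return list with `mean_pct`, `sd_pct` and `fold_pct`.
#' @export
crossvalidate_5fold <- function(fset, layout, seed = 1L, n_select = 12L,
                                c_param = 1, by_block = FALSE) {
  if (inherits(fset, "feature_set")) fset <- list(fset)
  parts <- lapply(fset, task_samples)
  x <- do.call(rbind, lapply(parts, `[[`, "x"))
  y <- unlist(lapply(parts, `[[`, "y"))
  blk <- unlist(mapply(function(i, p) paste0(i, ":", p$block),
                       seq_along(parts), parts, SIMPLIFY = FALSE))
  K <- length(y)
  if (K < 10L) stop_invalid("need at least 10 task seconds for 5-fold CV")
  fold <- with_seed(seed, {
    if (by_block) {
      ub <- unique(blk)
      bf <- sample(rep_len(seq_len(5L), length(ub)))
      bf[match(blk, ub)]
    } else {
      sample(rep_len(seq_len(5L), K))
    }
  })
  accs <- vapply(seq_len(5L), function(f) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L) {
      return(NA_real_)
    }
    mi <- apply(x[tr, , drop = FALSE], 2L, parzen_mi, labels = y[tr])
    sel <- select_channels(mi, layout, n_select)
    m <- train_linear_svm(x[tr, sel$selected, drop = FALSE], labels = y[tr],
                          c_param = c_param)
    p <- classify(m, x[!tr, sel$selected, drop = FALSE])
    100 * mean(p == y[!tr])
  }, numeric(1))
  list(mean_pct = mean(accs, na.rm = TRUE),
       sd_pct = stats::sd(accs[!is.na(accs)]),
       fold_pct = accs)
}

#' Run a full experiment
#'
#' Executes the session loop over a subject's runs according to the
#' experiment plan: for the subject-dependent designs (1 and 2) each
#' test run `r` is classified by a model retrained on the adaptation
#' schedule of [training_runs_for()] (run 2 uses run 1; later runs use
#' the two preceding runs), so the model never sees its own test run.
#' For the subject-independent design (3) the supplied frozen `sic`
#' model classifies every test run; only the rest-bias correction
#' adapts.
#'
#' @param plan an `experiment_plan`.
#' @param subject_runs list of `run_data`, one per plan row.
#' @param layout the `channel_layout`.
#' @param sic an `sic_model` (required for experiment 3).
#' @param n_select,c_param selector size and SVM penalty for the
#'   subject-dependent designs.
#' @return named list of `session_result`, one per test run
#'   (`"run3"`, ...).
#' @export
run_experiment <- function(plan, subject_runs, layout, sic = NULL,
                           n_select = 12L, c_param = 1) {
  stopifnot(inherits(plan, "experiment_plan"))
  if (length(subject_runs) != nrow(plan$runs)) {
    stop_invalid("need one run per plan row (got ", length(subject_runs), ")")
  }
  if (plan$id == 3L && is.null(sic)) {
    stop_invalid("experiment 3 requires a subject-independent model (`sic`)")
  }
  test_runs <- plan$runs$run[plan$runs$role == "test"]
  out <- list()
  for (r in test_runs) {
    if (plan$id == 3L) {
      selector <- sic$selector
      model <- sic$model
    } else {
      tr_idx <- training_runs_for(r)
      fitted <- fit_run_model(subject_runs[tr_idx], layout,
                              n_select = n_select, c_param = c_param)
      selector <- fitted$selector
      model <- fitted$model
    }
    out[[paste0("run", r)]] <- run_online_session(
      subject_runs[[r]], selector, model,
      feedback = plan$runs$feedback[plan$runs$run == r])
  }
  out
}

#' Per-channel task-versus-rest t statistics
#'
#' For each channel and each task class, a two-sample Welch t statistic
#' of the per-second mean HbO (the per-second feature sums normalized by
#' their window sample counts, so the 7/8-sample alternation of the
#' non-integer sampling rate adds no spurious variance) during that
#' class's task seconds against all rest seconds, with flags at a
#' Bonferroni-adjusted significance level (set `adjust = "none"` for the
#' raw level).  Channels with (near-)constant series yield `NA` rather
#' than an error.
#'
#' @param run a `run_data`.
#' @param alpha significance level before adjustment.
#' @param adjust `"bonferroni"` (over channels) or `"none"`.
#' @return data frame with `channel`, `class`, `t`, `p`, `flagged`.
#' @export
channel_tmap <- function(run, alpha = 0.05,
                         adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  fset <- extract_features(run)
  if (!any(fset$kind == "task") || !any(fset$kind == "rest")) {
    stop_invalid("run must contain both task and rest samples")
  }
  nt <- fset$n_channels
  thr <- if (adjust == "bonferroni") alpha / nt else alpha
  counts <- tabulate(floor(run$time_s) + 1L)
  means <- fset$features / counts[fset$second]
  rest <- means[fset$kind == "rest", , drop = FALSE]
  out <- list()
  for (cls in c("left", "right")) {
    task <- means[fset$kind == "task" & fset$label == cls, , drop = FALSE]
    tt <- vapply(seq_len(nt), function(ch) {
      a <- task[, ch]; b <- rest[, ch]
      if (stats::sd(a) < 1e-12 && stats::sd(b) < 1e-12) {
        return(c(NA_real_, NA_real_))
      }
      ht <- stats::t.test(a, b)
      c(unname(ht$statistic), ht$p.value)
    }, numeric(2))
    out[[cls]] <- data.frame(channel = seq_len(nt), class = cls,
                             t = tt[1, ], p = tt[2, ],
                             flagged = !is.na(tt[2, ]) & tt[2, ] < thr)
  }
  rbind(out$left, out$right)
}

#' Trial-averaged decision trace and its peak latency
#'
#' Aligns the bias-corrected decision magnitude of every task block to
#' its cue onset, averages across blocks on the per-second grid, and
#' reads off the latency of the maximum.  The classifier emits one
#' output per second, each aggregating the signal of the window
#' `[k-1, k)` after the cue, so the peak is only localized to a one
#' second window; `peak_latency_s` is the number of whole seconds
#' elapsed before the peak window begins (the natural reading of "the
#' output peaks after n seconds" from a per-second trace).
#'
#' With a handful of blocks the raw argmax of the averaged trace is a
#' noisy peak estimator, so the standard robust readout for averaged
#' physiological traces is used instead: the trace is lightly smoothed
#' with a `[1, 2, 1]/4` kernel and the peak window is the first one
#' reaching `frac` (default 90 percent) of the smoothed maximum (a
#' fractional-peak latency).
#'
#' @param session a `session_result` from [run_online_session()] (or a
#'   list of them, averaged together).
#' @param frac fraction of the smoothed maximum that defines the peak
#'   window.
#' @return list with `seconds_since_onset` (window start times),
#'   `mean_abs_decision` (unsmoothed), `n_blocks` and `peak_latency_s`.
#' @export
decision_peak_latency <- function(session, frac = 0.9) {
  sessions <- if (inherits(session, "session_result")) list(session)
              else session
  traces <- lapply(sessions, function(s) {
    tr <- s$trace[s$trace$kind == "task", ]
    tr$rel <- floor(tr$since_onset_s) + 1L   # second within block, 1-based
    tr
  })
  tr <- do.call(rbind, traces)
  rel <- sort(unique(tr$rel))
  m <- vapply(rel, function(k) mean(abs(tr$corrected[tr$rel == k])),
              numeric(1))
  n_blocks <- sum(vapply(traces, function(t) length(unique(t$block)),
                         numeric(1)))
  starts <- rel - 1L
  nm <- length(m)
  ms <- if (nm >= 3L) {
    c(m[1L], (2 * m[2:(nm - 1L)] + m[1:(nm - 2L)] + m[3:nm]) / 4, m[nm])
  } else m
  peak_k <- which(ms >= frac * max(ms))[1L]
  list(seconds_since_onset = starts, mean_abs_decision = m,
       n_blocks = n_blocks, peak_latency_s = starts[peak_k])
}
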