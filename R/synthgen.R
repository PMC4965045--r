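# Synthetic multi-channel fNIRS generator: task-locked contralateral
# HbO rises with inverted HbR dips, physiological oscillations, white
# noise and slow drift, reproducible from a single seed.

#' Channels carrying the task response ("motor area")
#'
#' Selects, per hemisphere, the channels whose emitter-detector
#' midpoints lie closest to a target point: the grid centre for motor
#' execution, or one optode spacing anterior (and a slightly broader
#' set) for motor imagery, reflecting the more anterior, less focal
#' activations typical of imagery.  `offset_xy` (mm) shifts the target,
#' which is how inter-subject variability in functional anatomy enters.
#'
#' @param layout a `channel_layout`.
#' @param params a `hemo_params` (uses `active_channel_fraction`).
#' @param task_type `"ME"` or `"MI"`.
#' @param offset_xy numeric length-2 shift of the target point in mm.
#' @return list with integer vectors `left` and `right` (channel indices).
#' @export
active_channels <- function(layout, params = hemo_params(),
                            task_type = c("ME", "MI"),
                            offset_xy = c(0, 0)) {
  task_type <- match.arg(task_type)
  ch <- layout$channels
  mid_x <- (ch$emitter_x_mm + ch$detector_x_mm) / 2
  mid_y <- (ch$emitter_y_mm + ch$detector_y_mm) / 2
  out <- list()
  for (h in unique(ch$hemisphere)) {
    idx <- which(ch$hemisphere == h)
    m <- max(1L, round(params$active_channel_fraction * length(idx)))
    target <- c(mean(mid_x[idx]), mean(mid_y[idx])) + offset_xy
    if (task_type == "MI") {
      target[2] <- target[2] + layout$spacing_mm  # anterior shift
      m <- min(length(idx), m + 2L)               # broader focus
    }
    d <- (mid_x[idx] - target[1])^2 + (mid_y[idx] - target[2])^2
    out[[h]] <- ch$channel[idx[order(d, idx)[seq_len(m)]]]
  }
  out
}

#' Generate one synthetic run
#'
#' Simulates per-channel HbO and HbR concentration-change series (in
#' micromolar) for a block-design run.  For each task block, the active
#' channels of the hemisphere contralateral to the cued hand receive the
#' evoked response (see [hemo_params()]); their ipsilateral homologues
#' receive the same response scaled by `ipsi_gain`.  Motor-imagery runs
#' are attenuated by `mi_gain`.  HbR mirrors HbO inverted, scaled by
#' `hbr_ratio` and lagged by `hbr_lag`.  All channels additionally carry
#' seeded white noise, Mayer-wave/respiratory/cardiac sinusoids with
#' per-channel random phase, and a per-channel linear drift.
#'
#' Timestamps are exactly `j / fs` for `j = 0, 1, ...`; no resampling is
#' performed at the non-integer default rate.
#'
#' @param spec a `run_spec` block schedule.
#' @param layout a `channel_layout`.
#' @param params a `hemo_params`.
#' @param seed integer seed; identical inputs give identical output.
#' @param subject optional list with `offset_xy` (mm shift of the active
#'   area) and `amp_gain` (amplitude multiplier), as produced by
#'   [generate_subject()].
#' @return An object of class `run_data`: list with `time_s`, `kind` and
#'   `label` per sample, `hbo` and `hbr` matrices (samples x channels),
#'   the layout, `fs`, `task_type`, the spec, params, seed and the
#'   active-channel sets used.
#' @export
generate_run <- function(spec, layout, params = hemo_params(), seed = 1L,
                         subject = NULL) {
  stopifnot(inherits(spec, "run_spec"), inherits(layout, "channel_layout"))
  if (is.null(subject)) subject <- list(offset_xy = c(0, 0), amp_gain = 1)

  fs <- params$fs
  total <- run_duration(spec)
  n <- as.integer(ceiling(total * fs - 1e-9))
  t <- (seq_len(n) - 1L) / fs
  nt <- layout$n_channels

  blocks <- spec$blocks
  bi <- findInterval(t, blocks$onset_s)
  kind <- blocks$kind[bi]
  label <- blocks$class[bi]

  act <- active_channels(layout, params, spec$task_type, subject$offset_xy)
  gain_task <- if (spec$task_type == "MI") params$mi_gain else 1
  amp <- params$hbo_amp * gain_task * subject$amp_gain

  hbo_sig <- matrix(0, n, nt)
  hbr_sig <- matrix(0, n, nt)
  task_rows <- which(blocks$kind == "task")
  for (b in task_rows) {
    onset <- blocks$onset_s[b]
    dur <- blocks$duration_s[b]
    shape <- block_response(t - onset, dur, params)
    shape_lag <- block_response(t - onset - params$hbr_lag, dur, params)
    contra <- if (blocks$class[b] == "left") "right" else "left"
    ipsi <- setdiff(c("left", "right"), contra)
    for (side in c(contra, ipsi)) {
      chans <- act[[side]]
      if (is.null(chans) || !length(chans)) next
      g <- if (side == contra) params$contra_gain else params$ipsi_gain
      hbo_sig[, chans] <- hbo_sig[, chans] + amp * g * shape
      hbr_sig[, chans] <- hbr_sig[, chans] - params$hbr_ratio * amp * g * shape_lag
    }
  }

  out <- with_seed(seed, {
    osc <- function() {
      m <- matrix(0, n, nt)
      for (comp in list(c(params$mayer_amp, params$mayer_freq),
                        c(params$resp_amp, params$resp_freq),
                        c(params$cardiac_amp, params$cardiac_freq))) {
        if (comp[1] <= 0) next
        phases <- stats::runif(nt, 0, 2 * pi)
        m <- m + comp[1] * sin(outer(2 * pi * comp[2] * t, phases, `+`))
      }
      m
    }
    drift <- function() {
      slopes <- stats::runif(nt, -1, 1) * params$drift_slope
      outer(t, slopes)
    }
    noise <- function() {
      matrix(stats::rnorm(n * nt, sd = params$noise_sd), n, nt)
    }
    list(hbo = hbo_sig + osc() + drift() + noise(),
         hbr = hbr_sig + osc() + drift() + noise())
  })

  structure(list(time_s = t, kind = kind, label = label,
                 hbo = out$hbo, hbr = out$hbr,
                 layout = layout, fs = fs, task_type = spec$task_type,
                 spec = spec, params = params, seed = as.integer(seed),
                 active = act, run_index = spec$run_index),
            class = "run_data")
}

#' @export
print.run_data <- function(x, ...) {
  cat(sprintf("<run_data> run %d (%s): %d samples x %d channels @ %g Hz, %g s\n",
              x$run_index, x$task_type, length(x$time_s),
              ncol(x$hbo), x$fs, max(x$time_s) + 1 / x$fs))
  invisible(x)
}

#' @export
as.data.frame.run_data <- function(x, ...) {
  nt <- ncol(x$hbo)
  df <- data.frame(time_s = x$time_s, block = x$kind, label = x$label)
  hbo <- as.data.frame(x$hbo)
  names(hbo) <- sprintf("ch%02d_hbo", seq_len(nt))
  hbr <- as.data.frame(x$hbr)
  names(hbr) <- sprintf("ch%02d_hbr", seq_len(nt))
  cbind(df, hbo, hbr)
}

#' Generate all runs of one synthetic subject
#'
#' Draws subject-level variability once -- an active-area jitter of up
#' to half an optode spacing (12.5 mm by default) in each direction,
#' about the scale of inter-subject motor-cortex localization
#' variability, and an amplitude gain uniform in [0.8, 1.25] -- and then
#' generates one run per row of the experiment plan, each with its own
#' derived seed.  A full-spacing jitter would displace the compact
#' active set onto entirely disjoint channels for some subjects, which
#' no pooled classifier could bridge.
#'
#' @param plan an `experiment_plan`.
#' @param layout a `channel_layout`.
#' @param params a `hemo_params`.
#' @param seed integer subject seed.
#' @param n_task_blocks,task_dur_s,rest_dur_s forwarded to
#'   [make_run_spec()].
#' @return list of `run_data`, one per run, with the subject draw
#'   attached as attribute `"subject"`.
#' @export
generate_subject <- function(plan, layout, params = hemo_params(), seed = 1L,
                             n_task_blocks = 6L, task_dur_s = 20,
                             rest_dur_s = 20) {
  stopifnot(inherits(plan, "experiment_plan"))
  n_runs <- nrow(plan$runs)
  draw <- with_seed(seed, {
    list(offset_xy = sample(c(-1, 0, 1), 2, replace = TRUE) *
           layout$spacing_mm / 2,
         amp_gain = stats::runif(1, 0.8, 1.25),
         run_seeds = sample.int(.Machine$integer.max - 1L, 2L * n_runs))
  })
  subject <- list(offset_xy = draw$offset_xy, amp_gain = draw$amp_gain)
  runs <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    spec <- make_run_spec(n_task_blocks, plan$runs$task_type[i],
                          task_dur_s, rest_dur_s, run_index = i,
                          seed = draw$run_seeds[2L * i - 1L])
    runs[[i]] <- generate_run(spec, layout, params,
                              seed = draw$run_seeds[2L * i], subject = subject)
  }
  attr(runs, "subject") <- subject
  runs
}
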