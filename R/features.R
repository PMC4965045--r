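# Per-second feature extraction and mutual-information channel
# selection with Parzen-window class-conditional densities.

#' Extract per-second features from a run
#'
#' For every elapsed whole second `k` of the run, the feature of channel
#' `n` is the sum of that channel's HbO samples with timestamps in
#' `[k-1, k)`.  At the default 7.69 Hz a window holds 7 or 8 samples, so
#' the sum is proportional to the one-second average concentration
#' change without any resampling.  Each feature vector carries the block
#' kind and class label in force at the start of its window, the block
#' it falls in, and the elapsed time since that block's onset.
#'
#' @param run a `run_data`.
#' @return An object of class `feature_set`: list with `features`
#'   (seconds x channels matrix), `second` (k = 1, 2, ...), `kind`,
#'   `label`, `block` (schedule row index) and `since_onset_s`.
#' @export
extract_features <- function(run) {
  stopifnot(inherits(run, "run_data"))
  grp <- floor(run$time_s) + 1L          # window k covers [k-1, k)
  k_max <- max(grp)
  feats <- rowsum(run$hbo, grp, reorder = TRUE)
  seconds <- as.integer(rownames(feats))
  # per-window metadata taken at the window start time k-1
  starts <- seconds - 1L
  blocks <- run$spec$blocks
  bi <- findInterval(starts, blocks$onset_s)
  structure(list(features = unname(feats),
                 second = seconds,
                 kind = blocks$kind[bi],
                 label = blocks$class[bi],
                 block = bi,
                 since_onset_s = starts - blocks$onset_s[bi],
                 n_channels = ncol(run$hbo),
                 layout = run$layout,
                 run_index = run$run_index,
                 task_type = run$task_type),
            class = "feature_set")
  }

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d second(s) x %d channel(s) (%d task seconds)\n",
              nrow(x$features), x$n_channels, sum(x$kind == "task")))
  invisible(x)
}

# task-second subset as (matrix, label) ready for selection/training
task_samples <- function(fset) {
  keep <- fset$kind == "task" & fset$label %in% c("left", "right")
  list(x = fset$features[keep, , drop = FALSE],
       y = fset$label[keep],
       block = fset$block[keep],
       second = fset$second[keep],
       since_onset_s = fset$since_onset_s[keep])
}

# pool task samples from several feature sets (run provenance retained)
pool_task_samples <- function(fsets) {
  parts <- lapply(fsets, task_samples)
  list(x = do.call(rbind, lapply(parts, `[[`, "x")),
       y = unlist(lapply(parts, `[[`, "y")),
       runs = unlist(mapply(function(f, p) rep(f$run_index, length(p$y)),
                            fsets, parts, SIMPLIFY = FALSE)))
}

#' Parzen-window mutual information between one feature and the class
#'
#' Estimates `I(F; omega) = H(omega) - H(omega | F)` in bits for a
#' scalar feature and binary labels.  Class priors come from label
#' frequencies; class-conditional densities are Gaussian-kernel Parzen
#' estimates with a per-class bandwidth (Silverman's rule via
#' [stats::bw.nrd0()]); the conditional entropy is the sample average of
#' the pointwise entropy of the posterior `p(omega | f)` over all
#' samples.  The estimate is clipped to `[0, H(omega)]`.
#'
#' For very large samples the kernel sums are evaluated on an evenly
#' thinned subset of at most `max_per_class` reference points per class,
#' which leaves the estimate unchanged to well within its own
#' statistical error while bounding the quadratic cost.
#'
#' @param x numeric feature values.
#' @param labels vector with exactly two distinct values, >= 2 samples
#'   per class.
#' @param max_per_class cap on Parzen reference points per class.
#' @return mutual information in bits, with attributes `H_class` and
#'   `bandwidths`.
#' @export
parzen_mi <- function(x, labels, max_per_class = 800L) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2L) {
    stop_invalid("`labels` must contain exactly two classes (got ",
                 length(classes), ")")
  }
  if (length(x) != length(labels)) stop_invalid("length mismatch")
  if (any(table(labels) < 2L)) stop_invalid("need >= 2 samples per class")

  prior <- as.numeric(table(labels)[classes]) / length(labels)
  h_class <- -sum(prior * log2(prior))

  dens <- matrix(0, length(x), 2L)
  bw <- numeric(2L)
  for (i in 1:2) {
    xc <- x[labels == classes[i]]
    if (length(xc) > max_per_class) {
      xc <- xc[round(seq(1L, length(xc), length.out = max_per_class))]
    }
    b <- stats::bw.nrd0(xc)
    if (!is.finite(b) || b <= 0) b <- max(stats::sd(x) * 1e-3, 1e-12)
    bw[i] <- b
    # mean kernel density of every sample under class i
    dens[, i] <- rowMeans(stats::dnorm(outer(x, xc, `-`), sd = b))
  }
  joint <- sweep(dens, 2L, prior, `*`)
  tot <- rowSums(joint)
  tot[tot <= 0] <- .Machine$double.xmin
  post <- joint / tot
  plogp <- post * log2(post)
  plogp[post <= 0] <- 0
  h_cond <- mean(-rowSums(plogp))
  mi <- h_class - h_cond
  mi <- min(max(mi, 0), h_class)
  attr(mi, "H_class") <- h_class
  attr(mi, "bandwidths") <- stats::setNames(bw, classes)
  mi
}

#' Per-channel mutual information of a feature set
#'
#' Applies [parzen_mi()] to every channel over the task seconds
#' (left/right labels only; rest seconds never enter the
#' class-conditional estimates).
#'
#' @param x a `feature_set`, or a samples-by-channels matrix together
#'   with `labels`.
#' @param labels binary labels (ignored when `x` is a `feature_set`).
#' @return numeric vector of per-channel MI scores in bits.
#' @export
channel_mi <- function(x, labels = NULL) {
  if (inherits(x, "feature_set")) {
    ts <- task_samples(x)
    x <- ts$x
    labels <- ts$y
  }
  apply(x, 2L, parzen_mi, labels = labels)
}

#' Select the most informative channels, balanced across hemispheres
#'
#' Keeps the `N/2` highest-scoring channels in each hemisphere (ties
#' broken toward the lower channel index), the hemisphere balance the
#' montage calls for.
#'
#' @param mi_scores numeric vector, one score per channel.
#' @param layout the `channel_layout` the scores refer to.
#' @param n_select even number of channels to keep (default 12).
#' @return An object of class `selector_model`: list with `selected`
#'   (sorted channel indices), `mi_score`, `n_select` and the layout
#'   hash.
#' @export
select_channels <- function(mi_scores, layout, n_select = 12L) {
  if (!is_count(n_select, min = 0L) || n_select %% 2L != 0L) {
    stop_invalid("`n_select` must be an even count")
  }
  if (length(mi_scores) != layout$n_channels) {
    stop_invalid("`mi_scores` length must equal the channel count")
  }
  half <- n_select / 2L
  sel <- integer(0)
  for (h in c("left", "right")) {
    idx <- hemisphere_channels(layout, h)
    if (length(idx) < half) {
      stop_invalid("hemisphere '", h, "' has fewer than N/2 channels")
    }
    ord <- idx[order(-mi_scores[idx], idx)]
    sel <- c(sel, ord[seq_len(half)])
  }
  structure(list(selected = sort(sel),
                 mi_score = as.numeric(mi_scores),
                 n_select = as.integer(n_select),
                 layout_hash = layout_hash(layout)),
            class = "selector_model")
}

#' Fit a channel selector from task-labelled features
#'
#' Convenience wrapper: per-channel Parzen MI over the task seconds of
#' one or more feature sets, then hemisphere-balanced selection.
#'
#' @param fsets a `feature_set` or list of them (pooled).
#' @param layout the shared `channel_layout`.
#' @param n_select even number of channels to keep.
#' @return a `selector_model`.
#' @export
fit_selector <- function(fsets, layout, n_select = 12L) {
  if (inherits(fsets, "feature_set")) fsets <- list(fsets)
  pooled <- pool_task_samples(fsets)
  mi <- apply(pooled$x, 2L, parzen_mi, labels = pooled$y)
  select_channels(mi, layout, n_select)
}

#' @export
print.selector_model <- function(x, ...) {
  cat(sprintf("<selector_model> %d of %d channels selected: %s\n",
              x$n_select, length(x$mi_score),
              paste(x$selected, collapse = ", ")))
  invisible(x)
}

#' Spatial table of mutual-information scores
#'
#' One row per channel with its midpoint grid position, hemisphere, MI
#' score and whether it was selected -- the tabular form of a spatial MI
#' map with selected channels highlighted.
#'
#' @param selector a `selector_model`.
#' @param layout the matching `channel_layout`.
#' @return data frame with columns `channel`, `hemisphere`, `x_mm`,
#'   `y_mm`, `score`, `selected`.
#' @export
mi_map <- function(selector, layout) {
  ch <- layout$channels
  data.frame(channel = ch$channel,
             hemisphere = ch$hemisphere,
             x_mm = (ch$emitter_x_mm + ch$detector_x_mm) / 2,
             y_mm = (ch$emitter_y_mm + ch$detector_y_mm) / 2,
             score = selector$mi_score,
             selected = ch$channel %in% selector$selected)
}
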