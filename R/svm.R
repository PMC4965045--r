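# Linear soft-margin support-vector machine, the between-run
# adaptation schedule, and the rest-block bias correction.
#
# The trainer solves the standard C-SVM dual exactly with sequential
# minimal optimization (pairwise analytic updates under the equality
# constraint), so on small problems the objective matches a
# quadratic-programming oracle to numerical precision.

label_to_y <- function(labels) {
  if (is.numeric(labels)) {
    if (!all(labels %in% c(-1, 1))) stop_invalid("numeric labels must be -1/+1")
    return(as.numeric(labels))
  }
  labels <- as.character(labels)
  if (!all(labels %in% c("left", "right"))) {
    stop_invalid("labels must be 'left'/'right' or -1/+1")
  }
  ifelse(labels == "right", 1, -1)   # right = +1, left = -1
}

#' Assemble a training set
#'
#' @param x samples-by-features numeric matrix.
#' @param labels `"left"`/`"right"` strings or -1/+1 numerics
#'   (right = +1).
#' @param runs optional integer vector tagging the source run of each
#'   sample (training provenance).
#' @return list of class `training_set` with `x`, `y` (+/-1) and `runs`.
#' @export
training_set <- function(x, labels, runs = NULL) {
  x <- as.matrix(x)
  y <- label_to_y(labels)
  if (nrow(x) != length(y)) stop_invalid("sample/label count mismatch")
  if (length(y) < 2L || length(unique(y)) < 2L) {
    stop_invalid("training data must contain both classes")
  }
  if (is.null(runs)) runs <- rep(NA_integer_, length(y))
  structure(list(x = x, y = y, runs = as.integer(runs)),
            class = "training_set")
}

#' Train a linear soft-margin SVM
#'
#' Minimizes `0.5 * ||W||^2 + C * sum(xi)` subject to
#' `y_k (W' s_k - b) >= 1 - xi_k`, via SMO on the dual.  The decision
#' function is `W' s - b`; on separable data with large enough `C` the
#' canonical unit-margin solution is recovered.
#'
#' @param data a `training_set` (or matrix, with `labels` given).
#' @param c_param soft-margin penalty C (> 0), default 1.
#' @param labels labels when `data` is a bare matrix.
#' @param tol KKT violation tolerance of the solver.  The default
#'   (1e-3) is the usual practical stopping rule; pass a tighter value
#'   (e.g. 1e-8) when exact agreement with a reference quadratic
#'   program matters.
#' @return An object of class `svm_model`: `W`, `b`, `c_param`, `alpha`,
#'   `objective` (primal soft-margin cost), `margin_norm`
#'   (`0.5 * ||W||^2`), `n_sv` and `training_runs`.
#' @export
train_linear_svm <- function(data, c_param = 1, labels = NULL,
                             tol = 1e-3) {
  if (!inherits(data, "training_set")) data <- training_set(data, labels)
  if (!is_number(c_param) || c_param <= 0) stop_invalid("`c_param` must be > 0")
  x <- data$x
  y <- data$y
  K <- nrow(x)
  C <- c_param

  xsq <- rowSums(x * x)           # kernel diagonal
  alpha <- numeric(K)
  w <- numeric(ncol(x))
  Fv <- -y                         # F_i = w.x_i - y_i (bias-free cache)

  # maximal-violating-pair SMO (Keerthi working-set selection): optimal
  # when max_{I_low} F - min_{I_up} F <= 2 tol; the violating pair is
  # updated analytically under the box and equality constraints.
  step_pair <- function(i, j) {
    # analytic pair update under box and equality constraints; returns
    # TRUE if the alphas moved
    yi <- y[i]; yj <- y[j]
    s <- yi * yj
    if (s > 0) {
      L <- max(0, alpha[i] + alpha[j] - C)
      H <- min(C, alpha[i] + alpha[j])
    } else {
      L <- max(0, alpha[j] - alpha[i])
      H <- min(C, C + alpha[j] - alpha[i])
    }
    if (H - L < 1e-14) return(FALSE)
    kij <- sum(x[i, ] * x[j, ])
    eta <- xsq[i] + xsq[j] - 2 * kij
    aj_new <- if (eta > 1e-12) {
      min(max(alpha[j] + yj * (Fv[i] - Fv[j]) / eta, L), H)
    } else {
      # coincident points: slide to whichever box end lowers the objective
      if (yj * (Fv[i] - Fv[j]) > 0) H else L
    }
    daj <- aj_new - alpha[j]
    if (abs(daj) < 1e-14) return(FALSE)
    dai <- -s * daj
    dw <- yi * dai * x[i, ] + yj * daj * x[j, ]
    w <<- w + dw
    Fv <<- Fv + as.numeric(x %*% dw)
    alpha[i] <<- alpha[i] + dai
    alpha[j] <<- aj_new
    TRUE
  }

  max_iter <- max(200L * K, 20000L)
  iter <- 0L
  excluded <- logical(K)     # up-candidates that cannot progress right now
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) {
      warning("SMO iteration cap reached; solution may be inexact")
      break
    }
    up <- (y > 0 & alpha < C - 1e-12) | (y < 0 & alpha > 1e-12)
    lo <- (y > 0 & alpha > 1e-12) | (y < 0 & alpha < C - 1e-12)
    if (!any(up) || !any(lo)) break
    if (max(Fv[lo]) - min(Fv[up]) < 2 * tol) break   # KKT satisfied
    cand <- up & !excluded
    if (!any(cand)) break
    i <- which(cand)[which.min(Fv[cand])]
    # second-order partner choice (largest decrease of the dual
    # objective, LIBSVM-style), falling back through the ranking until a
    # partner moves
    partners <- which(lo & Fv > Fv[i] + 2 * tol)
    if (length(partners)) {
      ki <- as.numeric(x[partners, , drop = FALSE] %*% x[i, ])
      gain <- (Fv[partners] - Fv[i])^2 /
        pmax(xsq[i] + xsq[partners] - 2 * ki, 1e-12)
      partners <- partners[order(-gain)]
    }
    moved <- FALSE
    for (j in partners) {
      if (j != i && step_pair(i, j)) {
        moved <- TRUE
        break
      }
    }
    if (moved) {
      excluded[] <- FALSE
    } else {
      excluded[i] <- TRUE    # blocked for now; revisit after progress
    }
  }

  # final bias from free support vectors (fallback: feasibility midpoint)
  free <- which(alpha > 1e-10 & alpha < C - 1e-10)
  margins <- as.numeric(x %*% w)
  if (length(free)) {
    b0 <- mean(y[free] - margins[free])
  } else {
    lo <- suppressWarnings(max((y - margins)[(y > 0 & alpha <= 1e-10) |
                                             (y < 0 & alpha >= C - 1e-10)]))
    hi <- suppressWarnings(min((y - margins)[(y > 0 & alpha >= C - 1e-10) |
                                             (y < 0 & alpha <= 1e-10)]))
    if (is.finite(lo) && is.finite(hi)) b0 <- (lo + hi) / 2
  }

  slack <- pmax(0, 1 - y * (margins + b0))
  structure(list(W = as.numeric(w), b = -b0, c_param = C,
                 alpha = alpha,
                 objective = 0.5 * sum(w * w) + C * sum(slack),
                 margin_norm = 0.5 * sum(w * w),
                 n_sv = sum(alpha > 1e-10),
                 training_runs = sort(unique(data$runs[!is.na(data$runs)]))),
            class = "svm_model")
}

#' @export
print.svm_model <- function(x, ...) {
  cat(sprintf("<svm_model> %d feature(s), C = %g, %d SV(s), J = %.4g\n",
              length(x$W), x$c_param, x$n_sv, x$objective))
  invisible(x)
}

#' SVM decision value and label
#'
#' `decision_value` evaluates `W' s - b`; `classify` applies an optional
#' additive bias offset and maps the sign to a hand label, assigning the
#' boundary itself to "right" (the `>=` convention of the discriminant
#' rule).
#'
#' @param model an `svm_model`.
#' @param s feature vector (length `|W|`) or samples-by-features matrix.
#' @param bias offset subtracted from the decision value before
#'   thresholding (the rest-block bias).
#' @return `decision_value`: numeric; `classify`: `"left"`/`"right"`.
#' @export
decision_value <- function(model, s) {
  if (is.null(dim(s))) {
    if (length(s) != length(model$W)) {
      stop_invalid("feature vector length ", length(s),
                   " does not match model dimension ", length(model$W))
    }
    return(sum(model$W * s) - model$b)
  }
  if (ncol(s) != length(model$W)) {
    stop_invalid("feature matrix has ", ncol(s),
                 " columns; model expects ", length(model$W))
  }
  as.numeric(s %*% model$W) - model$b
}

#' @rdname decision_value
#' @export
classify <- function(model, s, bias = 0) {
  v <- decision_value(model, s) - bias
  ifelse(v >= 0, "right", "left")
}

#' Which runs train the model used in run r
#'
#' The between-run adaptation schedule: the model applied during run 2
#' is trained on run 1; from run 3 onward it is retrained on the two
#' preceding runs.  The model for run `r` therefore never sees run `r`.
#'
#' @param r run index, >= 2.
#' @return integer vector of training run indices.
#' @examples
#' training_runs_for(2)  # 1
#' training_runs_for(5)  # 3 4
#' @export
training_runs_for <- function(r) {
  if (!is_count(r) || r < 2L) {
    stop_invalid("no training data exists before run 2 (r = ", r, ")")
  }
  r <- as.integer(r)
  if (r == 2L) 1L else c(r - 2L, r - 1L)
}

#' Rest-block bias offset
#'
#' The mean SVM output over a rest block, to be subtracted from every
#' decision value of the following task block (a pure shift: within-block
#' value rankings are unchanged).
#'
#' @param decision_values_during_rest numeric vector of decision values
#'   collected during the rest block.
#' @return scalar offset.
#' @export
rest_bias <- function(decision_values_during_rest) {
  if (length(decision_values_during_rest) == 0L) {
    stop_invalid("rest trace is empty; no bias can be estimated")
  }
  mean(decision_values_during_rest)
}

#' Build a subject-independent classifier from pooled runs
#'
#' Pools the task seconds of several subjects' (typically motor
#' execution) runs, fits the channel selector once on the ensemble, and
#' trains a single SVM on the selected features.  The resulting model is
#' frozen: it is applied to new subjects without between-run retraining,
#' while the within-run rest-bias correction stays active.
#'
#' @param subject_runs list of subjects, each a list of `run_data`
#'   sharing one layout.
#' @param layout the common `channel_layout`.
#' @param n_select channels kept by the selector.
#' @param c_param SVM penalty.
#' @return list of class `sic_model` with `selector`, `model`,
#'   `n_subjects` and `n_samples`.
#' @export
build_subject_independent_model <- function(subject_runs, layout,
                                            n_select = 12L, c_param = 1) {
  runs <- do.call(c, subject_runs)
  nts <- vapply(runs, function(r) ncol(r$hbo), integer(1))
  if (length(unique(nts)) != 1L || nts[1] != layout$n_channels) {
    stop_invalid("all pooled runs must share the layout's channel count")
  }
  fsets <- lapply(runs, extract_features)
  # provenance: scope run indices by source subject so a frozen model is
  # never mistaken for one trained on the new subject's runs
  subj_of <- rep(seq_along(subject_runs),
                 vapply(subject_runs, length, integer(1)))
  for (i in seq_along(fsets)) {
    fsets[[i]]$run_index <- 1000L * subj_of[i] + fsets[[i]]$run_index
  }
  selector <- fit_selector(fsets, layout, n_select)
  pooled <- pool_task_samples(fsets)
  ts <- training_set(pooled$x[, selector$selected, drop = FALSE], pooled$y,
                     runs = pooled$runs)
  model <- train_linear_svm(ts, c_param = c_param)
  structure(list(selector = selector, model = model,
                 n_subjects = length(subject_runs),
                 n_samples = length(pooled$y)),
            class = "sic_model")
}
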