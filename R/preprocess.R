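# Offline signal conditioning: baseline correction, hemodynamic
# pre-coloring (HRF low-pass), and wavelet-MDL trend removal.
#
# These steps serve the offline analysis path; the real-time loop works
# on raw concentration changes and relies on the classifier-level bias
# correction instead.

#' Preprocessing configuration
#'
#' @param baseline `"preceding_rest"` (subtract the mean of the rest
#'   block immediately before each task block) or `"leading_rest"`
#'   (subtract the mean of the run's first rest block everywhere).
#' @param precolor_len_s length of the HRF pre-coloring kernel, seconds.
#' @param wavelet wavelet family for detrending (only `"db4"` is built
#'   in).
#' @param depth decomposition depth, or `NULL` for the default
#'   `floor(log2(n)) - 4` of the (padded) series length.
#' @param mdl logical; if `FALSE` the coarsest approximation is always
#'   removed instead of letting the MDL criterion decide.
#' @return list of class `preproc_config`.
#' @export
preproc_config <- function(baseline = c("preceding_rest", "leading_rest"),
                           precolor_len_s = 30, wavelet = "db4",
                           depth = NULL, mdl = TRUE) {
  baseline <- match.arg(baseline)
  if (!is_number(precolor_len_s) || precolor_len_s <= 0) {
    stop_invalid("`precolor_len_s` must be positive")
  }
  if (!identical(wavelet, "db4")) stop_invalid("only the db4 wavelet is built in")
  if (!is.null(depth) && !is_count(depth)) stop_invalid("`depth` must be a count")
  structure(list(baseline = baseline, precolor_len_s = precolor_len_s,
                 wavelet = wavelet, depth = depth, mdl = isTRUE(mdl)),
            class = "preproc_config")
}

#' Baseline-correct a series
#'
#' Subtracts, per channel, the mean over a reference sample window.
#'
#' @param x numeric vector or samples-by-channels matrix.
#' @param window integer indices of the baseline window (within `x`).
#' @return same shape as `x`.
#' @export
baseline_correct <- function(x, window) {
  if (length(window) == 0L) stop_invalid("baseline window is empty")
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1L)
  if (any(window < 1L) || any(window > nrow(x))) {
    stop_invalid("baseline window outside the series")
  }
  mu <- colMeans(x[window, , drop = FALSE])
  out <- sweep(x, 2L, mu)
  if (vec) out <- drop(out)
  out
}

#' Pre-color with a hemodynamic low-pass kernel
#'
#' Convolves each channel with the canonical HRF sampled at `fs` and
#' normalized to unit sum, so constant signals pass unchanged (unit DC
#' gain) while high frequencies are attenuated.  Alignment is causal
#' "same": output sample `t` uses input samples up to `t`, with the
#' kernel renormalized over its available support near the start of the
#' series to avoid a startup ramp.
#'
#' @param x numeric vector or samples-by-channels matrix.
#' @param fs sampling rate, Hz.
#' @param params `hemo_params` supplying the HRF shape.
#' @param len_s kernel length in seconds.
#' @return filtered series, same shape and length as `x`.
#' @export
hrf_precolor <- function(x, fs, params = hemo_params(), len_s = 30) {
  if (!is_number(fs) || fs <= 0) stop_invalid("`fs` must be positive")
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1L)
  kern <- canonical_hrf(seq(0, len_s, by = 1 / fs), params)
  kern <- kern / sum(kern)
  m <- length(kern)
  n <- nrow(x)
  if (n < m) {
    warning("series shorter than the pre-coloring kernel; returning input unchanged")
    out <- x
    if (vec) out <- drop(out)
    return(out)
  }
  out <- apply(x, 2L, function(col) {
    full <- as.numeric(stats::filter(col, kern, method = "convolution",
                                     sides = 1))
    # startup region: renormalize the truncated kernel over its support
    for (t in seq_len(m - 1L)) {
      w <- kern[seq_len(t)]
      sw <- sum(w)
      full[t] <- if (sw < 1e-12) col[t] else sum(w * col[t:1]) / sw
    }
    full
  })
  out <- matrix(out, nrow = n)
  if (vec) out <- drop(out)
  out
}

# ---- discrete wavelet transform (db4, periodized) -----------------------
#
# No wavelet package ships with the target environment, so a minimal
# pyramid DWT is implemented here.  Daubechies-4 (8-tap, extremal phase)
# scaling filter; the wavelet filter is its quadrature mirror.

db4_filters <- function() {
  h <- c(0.230377813308855, 0.714846570552542, 0.630880767929590,
         -0.027983769416984, -0.187034811718881, 0.030841381835987,
         0.032883011666983, -0.010597401784997)
  g <- rev(h) * (-1)^(seq_along(h) - 1L)
  list(lo = h, hi = g)
}

# one level of periodized analysis: x (even length) -> list(approx, detail)
dwt_step <- function(x, f) {
  n <- length(x)
  m <- length(f$lo)
  idx <- outer(seq(1L, n, by = 2L) - 1L, seq_len(m) - 1L, `+`) %% n + 1L
  xm <- matrix(x[idx], ncol = m)
  list(a = as.numeric(xm %*% f$lo), d = as.numeric(xm %*% f$hi))
}

# inverse of dwt_step
idwt_step <- function(a, d, f) {
  n <- 2L * length(a)
  m <- length(f$lo)
  x <- numeric(n)
  for (k in seq_along(a)) {
    pos <- ((2L * (k - 1L)) + seq_len(m) - 1L) %% n + 1L
    x[pos] <- x[pos] + a[k] * f$lo + d[k] * f$hi
  }
  x
}

dwt_decompose <- function(x, depth) {
  f <- db4_filters()
  details <- vector("list", depth)
  a <- x
  for (j in seq_len(depth)) {
    s <- dwt_step(a, f)
    details[[j]] <- s$d
    a <- s$a
  }
  list(approx = a, details = details, depth = depth)
}

dwt_reconstruct <- function(dec) {
  f <- db4_filters()
  a <- dec$approx
  for (j in rev(seq_len(dec$depth))) {
    a <- idwt_step(a, dec$details[[j]], f)
  }
  a
}

#' Remove slow trends by wavelet decomposition with an MDL model choice
#'
#' Decomposes each channel with a periodized db4 wavelet transform
#' (after reflection-padding to a power-of-two length) to depth
#' `floor(log2(n)) - 4`.  Candidate trend models are: no trend, the
#' coarsest approximation band, or the approximation plus the coarsest
#' detail band.  The retained model minimizes a two-part minimum
#' description length: `1.5 * k * log2(n)` bits for `k` trend
#' coefficients plus `n/2 * log2(RSS / n)` bits for the residual.  The
#' selected trend is reconstructed and subtracted, so a pure drift is
#' removed while oscillations faster than roughly `fs * 16 / n` Hz (for
#' the default depth) are untouched.
#'
#' @param x numeric vector or samples-by-channels matrix.
#' @param depth decomposition depth; default `floor(log2(n)) - 4` of the
#'   padded length (minimum 1).
#' @param mdl if `FALSE`, skip the MDL comparison and always remove the
#'   coarsest approximation band.
#' @return detrended series, same shape as `x`.
#' @export
wavelet_mdl_detrend <- function(x, depth = NULL, mdl = TRUE) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  if (n < 2L) stop_invalid("series too short to detrend")
  np <- 2L^ceiling(log2(n))
  if (is.null(depth)) depth <- max(1L, floor(log2(np)) - 4L)
  if (np < 2L^depth) stop_invalid("series shorter than 2^depth")
  out <- apply(x, 2L, function(col) {
    col - wavelet_trend(col, np, depth, mdl)
  })
  out <- matrix(out, nrow = n)
  if (vec) out <- drop(out)
  out
}

# estimate the trend component of one channel (returns a length-n vector)
wavelet_trend <- function(col, np, depth, mdl) {
  n <- length(col)
  if (all(abs(col) < 1e-12)) return(numeric(n))
  # reflection padding to length np
  pad <- np - n
  padded <- if (pad > 0L) {
    c(col, rev(col)[seq_len(min(pad, n))],
      rep(col[1L], max(0L, pad - n)))  # degenerate very-short case
  } else col
  dec <- dwt_decompose(padded, depth)
  # candidate m = number of coarse bands treated as trend:
  # 0 none, 1 approximation, 2 approximation + coarsest detail
  trend_of <- function(m) {
    if (m == 0L) return(numeric(np))
    d2 <- dec
    d2$details <- lapply(dec$details, function(d) numeric(length(d)))
    if (m < 2L) d2$approx <- dec$approx
    if (m == 2L) d2$details[[depth]] <- dec$details[[depth]]
    dwt_reconstruct(d2)
  }
  k_of <- c(0L, length(dec$approx),
            length(dec$approx) + length(dec$details[[depth]]))
  cands <- if (mdl) 0:2 else 1L
  best <- NULL
  best_dl <- Inf
  for (m in cands) {
    tr <- trend_of(m)
    rss <- sum((padded - tr)^2)
    dl <- 1.5 * k_of[m + 1L] * log2(np) +
      (np / 2) * log2(max(rss, 1e-300) / np)
    if (dl < best_dl) {
      best_dl <- dl
      best <- tr
    }
  }
  best[seq_len(n)]
}
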