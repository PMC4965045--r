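# Shared fixtures and independent oracles.  Everything is generated in
# code; nothing is read from disk.

# small bilateral montage: two 2x2 grids -> 8 channels, 4 per hemisphere
tiny_layout <- function() build_checkerboard_layout(2, 2, 2, 25)

default_layout <- function() build_checkerboard_layout()

# a short, cheap world for structural tests (signal content irrelevant)
quick_run <- function(seed = 1L, task_type = "ME", n_task = 2L,
                      dur = 6, layout = tiny_layout(),
                      params = hemo_params()) {
  spec <- make_run_spec(n_task, task_type, dur, dur, run_index = 1L,
                        seed = seed)
  generate_run(spec, layout, params, seed = seed + 1000L)
}

# deterministic noise-free world with a strong response
clean_params <- function(...) {
  hemo_params(noise_sd = 0, mayer_amp = 0, cardiac_amp = 0, resp_amp = 0,
              drift_slope = 0, ...)
}

# default-scale subject-dependent train/test pair (runs 1 and 2)
train_test_pair <- function(seed, task_type = "ME", params = hemo_params(),
                            layout = default_layout()) {
  s1 <- make_run_spec(6, task_type, run_index = 1L, seed = seed * 10L + 1L)
  s2 <- make_run_spec(6, task_type, run_index = 2L, seed = seed * 10L + 2L)
  list(train = generate_run(s1, layout, params, seed = seed * 10L + 3L),
       test = generate_run(s2, layout, params, seed = seed * 10L + 4L))
}

# ---- independent oracles -------------------------------------------------

# Exact soft-margin linear SVM by KKT active-set enumeration: every
# point is assigned to {alpha = 0, free, alpha = C}; the free alphas and
# the intercept solve the linear KKT system; feasible solutions are
# screened and the minimal primal objective returned.  Exponential in n,
# usable for n <= 8.
svm_qp_oracle <- function(x, y, C = 1) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(n <= 8)
  K <- x %*% t(x)
  best <- NULL
  assign <- rep(0L, n)
  states <- as.matrix(expand.grid(rep(list(0:2), n)))  # 0 = O, 1 = F, 2 = B
  for (s in seq_len(nrow(states))) {
    st <- states[s, ]
    Fr <- which(st == 1L)
    Bd <- which(st == 2L)
    alpha <- numeric(n)
    alpha[Bd] <- C
    nf <- length(Fr)
    # unknowns: alpha_F, b0 ; eqs: y_i f(x_i) = 1 (i in F), sum alpha*y = 0
    A <- matrix(0, nf + 1L, nf + 1L)
    rhs <- numeric(nf + 1L)
    if (nf > 0) {
      for (r in seq_len(nf)) {
        i <- Fr[r]
        A[r, seq_len(nf)] <- y[Fr] * K[Fr, i]
        A[r, nf + 1L] <- 1
        rhs[r] <- y[i] - sum(C * y[Bd] * K[Bd, i])
      }
    }
    A[nf + 1L, ] <- c(y[Fr], 0)
    rhs[nf + 1L] <- -sum(C * y[Bd])
    sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    alpha[Fr] <- sol[seq_len(nf)]
    b0 <- sol[nf + 1L]
    if (any(alpha < -1e-9) || any(alpha > C + 1e-9)) next
    w <- colSums(alpha * y * x)
    f <- as.numeric(x %*% w) + b0
    marg <- y * f
    ok <- all(marg[st == 0L] >= 1 - 1e-7) && all(marg[Bd] <= 1 + 1e-7)
    if (!ok) next
    obj <- 0.5 * sum(w^2) + C * sum(pmax(0, 1 - marg))
    if (is.null(best) || obj < best$objective - 1e-12) {
      best <- list(W = w, b = -b0, objective = obj, alpha = alpha)
    }
  }
  best
}

# Plug-in mutual information from an equal-width histogram of the
# feature (default 32 bins) jointly with the binary label, with the
# standard Miller-Madow debiasing of the plug-in estimate (the raw
# plug-in is biased up by ~(bins-1)(classes-1)/(2 n ln 2) bits, a tenth
# of a bit at n = 200).
hist_mi_oracle <- function(x, labels, bins = 32L) {
  br <- seq(min(x), max(x), length.out = bins + 1L)
  br[1] <- br[1] - 1e-9
  bin <- cut(x, br, labels = FALSE)
  joint <- table(bin, labels) / length(x)
  px <- rowSums(joint)
  py <- colSums(joint)
  mi <- 0
  for (i in seq_along(px)) {
    for (j in seq_along(py)) {
      p <- joint[i, j]
      if (p > 0) mi <- mi + p * log2(p / (px[i] * py[j]))
    }
  }
  n <- length(x)
  correction <- ((sum(joint > 0) - 1) - (sum(px > 0) - 1) -
                   (sum(py > 0) - 1)) / (2 * n * log(2))
  mi - correction
}

# trapezoid AUC by explicit threshold enumeration (for tiny examples)
auc_oracle <- function(scores, y) {
  pos <- scores[y > 0]
  neg <- scores[y < 0]
  (sum(outer(pos, neg, `>`)) + 0.5 * sum(outer(pos, neg, `==`))) /
    (length(pos) * length(neg))
}

# localized seeded RNG for test-side randomness
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
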