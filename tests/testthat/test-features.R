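# Per-second feature extraction and mutual-information selection.

test_that("feature windows sum the samples of each elapsed second", {
  # constant signal: each window sums c times its sample count
  p <- clean_params(hbo_amp = 0, fs = 8)
  run <- quick_run(params = p)
  run$hbo[] <- 0.25
  f <- extract_features(run)
  expect_true(all(abs(f$features - 0.25 * 8) < 1e-12))
  # zero signal -> all-zero features
  run$hbo[] <- 0
  expect_true(all(extract_features(run)$features == 0))
})

test_that("7.69 Hz windows hold 7 or 8 samples and 769 over 100 s", {
  counts <- table(floor((0:768) / 7.69))   # j with t_j < 100 s
  expect_equal(sum(counts), 769L)
  expect_setequal(as.integer(counts), c(7L, 8L))
  expect_equal(length(counts), 100L)
  # the extractor reproduces this window rule on real run data
  p <- clean_params(hbo_amp = 0)
  run <- quick_run(params = p, dur = 25)
  run$hbo[] <- 1
  f <- extract_features(run)
  expect_setequal(unique(f$features[, 1]), c(7, 8))
})

test_that("extraction is linear and additive in the signal", {
  run <- quick_run(seed = 8)
  f1 <- extract_features(run)$features
  run2 <- run
  run2$hbo <- 2 * run$hbo
  expect_equal(extract_features(run2)$features, 2 * f1)
  run3 <- run
  run3$hbo <- run$hbo + run$hbo[, c(2:ncol(run$hbo), 1)]
  expect_equal(extract_features(run3)$features,
               f1 + f1[, c(2:ncol(f1), 1)])
})

test_that("feature labels follow the block schedule", {
  run <- quick_run(seed = 2, n_task = 2, dur = 6)
  f <- extract_features(run)
  blocks <- run$spec$blocks
  for (b in seq_len(nrow(blocks))) {
    secs <- f$second > blocks$onset_s[b] & f$second <= blocks$offset_s[b]
    expect_true(all(f$kind[secs] == blocks$kind[b]))
    expect_true(all(f$label[secs] == blocks$class[b]))
  }
})

test_that("Parzen MI saturates, vanishes, and matches the histogram oracle", {
  # widely separated clusters: MI -> class entropy (1 bit, balanced)
  set.seed(11)
  x <- c(rnorm(250, -10), rnorm(250, 10))
  lab <- rep(c("left", "right"), each = 250)
  expect_gt(parzen_mi(x, lab), 0.99)
  expect_lte(parzen_mi(x, lab), 1)
  # label-independent feature: MI ~ 0 (within 0.05 bits at n = 500)
  for (seed in 1:5) {
    set.seed(seed)
    expect_lt(parzen_mi(rnorm(500), rep(c("left", "right"), 250)), 0.05)
  }
  # two-class Gaussian at n = 200: within 0.1 bits of the histogram plug-in
  for (seed in 1:5) {
    set.seed(seed)
    x <- c(rnorm(100, -1), rnorm(100, 1))
    lab <- rep(c("left", "right"), each = 100)
    expect_lt(abs(parzen_mi(x, lab) - hist_mi_oracle(x, lab)), 0.1)
  }
  expect_error(parzen_mi(rnorm(10), rep("left", 10)), class = "fnirsbci_invalid")
  expect_error(parzen_mi(c(1, 2, 3), c("left", "right", "right")),
               class = "fnirsbci_invalid")
})

test_that("label permutation destroys MI in >= 95% of seeds", {
  hits <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    x <- c(rnorm(250, -1), rnorm(250, 1))
    lab <- sample(rep(c("left", "right"), each = 250))  # break the link
    hits <- hits + (parzen_mi(x, lab) < 0.05)
  }
  expect_gte(hits / 20, 0.95)
})

test_that("MI is invariant under monotone affine rescaling of the feature", {
  set.seed(3)
  x <- c(rnorm(200, -0.8), rnorm(200, 0.8))
  lab <- rep(c("left", "right"), each = 200)
  base <- parzen_mi(x, lab)
  expect_lt(abs(parzen_mi(5 * x + 100, lab) - base), 0.02)
  expect_lt(abs(parzen_mi(-0.3 * x + 2, lab) - base), 0.02)
})

test_that("selection keeps the top N/2 per hemisphere with index tie-breaks", {
  lay <- default_layout()
  # strictly ordered scores: selection must equal an independent sort
  set.seed(4)
  scores <- sample(seq(0.01, 1, length.out = 48))
  sel <- select_channels(scores, lay, 12)
  left <- hemisphere_channels(lay, "left")
  right <- hemisphere_channels(lay, "right")
  oracle <- sort(c(left[order(-scores[left])][1:6],
                   right[order(-scores[right])][1:6]))
  expect_equal(sel$selected, oracle)
  expect_equal(sel$n_select, 12L)
  expect_equal(sum(sel$selected %in% left), 6L)
  expect_equal(sum(sel$selected %in% right), 6L)
  # all-equal scores: the N/2 lowest-indexed channels per hemisphere
  tie <- select_channels(rep(0.5, 48), lay, 12)
  expect_equal(tie$selected, sort(c(left[1:6], right[1:6])))
  # selection depends only on the within-hemisphere ranking
  sel2 <- select_channels(rank(scores) / 100, lay, 12)
  expect_equal(sel2$selected, sel$selected)
  expect_error(select_channels(scores, lay, 13), class = "fnirsbci_invalid")
  expect_error(select_channels(scores[1:10], lay, 12), class = "fnirsbci_invalid")
})

test_that("mi_map tabulates all channels and flags exactly the selection", {
  lay <- default_layout()
  set.seed(5)
  scores <- runif(48)
  sel <- select_channels(scores, lay, 12)
  map <- mi_map(sel, lay)
  expect_equal(nrow(map), 48L)
  expect_equal(sum(map$selected), 12L)
  expect_equal(map$channel[map$selected], sel$selected)
  # empty selection edge
  map0 <- mi_map(select_channels(scores, lay, 0), lay)
  expect_equal(sum(map0$selected), 0L)
})

test_that("fit_selector finds the active channels in a clean world", {
  lay <- default_layout()
  p <- hemo_params(noise_sd = 0.1, mayer_amp = 0, cardiac_amp = 0,
                   resp_amp = 0, drift_slope = 0)
  spec <- make_run_spec(6, "ME", 20, 20, seed = 6)
  run <- generate_run(spec, lay, p, seed = 7)
  sel <- fit_selector(extract_features(run), lay, 12)
  act <- unlist(active_channels(lay, p, "ME"))
  expect_gte(length(intersect(sel$selected, act)), 10L)
})
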