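test_that("location RDM matches hand computation and a brute-force oracle", {
  expect_equal(as.numeric(location_rdm(c(0, 3, 7))), c(3, 7, 4))
  expect_equal(as.numeric(location_rdm(rep(2, 5))), rep(0, 10))
  set.seed(1)
  v <- rnorm(50)
  oracle <- c()
  for (i in 1:49) for (j in (i + 1):50) oracle <- c(oracle, abs(v[i] - v[j]))
  expect_equal(as.numeric(location_rdm(v)), oracle, tolerance = 1e-12)
  expect_error(location_rdm(c(1, NA, 3)), "trial 2")
  expect_error(location_rdm(1), "at least 2")
})

test_that("condensed pair indexing is a bijection", {
  for (n in c(2, 5, 37, 200)) {
    pr <- serialdep:::condensed_pairs(n)
    expect_equal(nrow(pr), n * (n - 1) / 2)
    idx <- serialdep:::condensed_index(pr[, 1], pr[, 2], n)
    expect_equal(idx, seq_len(nrow(pr)))
  }
})

test_that("pattern vectors pool channels x samples inside the 50 ms window", {
  set.seed(2)
  ep <- make_epochs(array(rnorm(3 * 64 * 61), c(3, 64, 61)), sfreq = 100,
                    t0 = -100)
  # interior point at 100 Hz: 5 samples in a 50 ms window, 64 channels
  expect_length(pattern_vector(ep, 1, 200, window_ms = 50), 64 * 5)
  # window smaller than one sample period collapses to a single sample
  expect_length(pattern_vector(ep, 1, 200, window_ms = 5), 64)
  # at the first time point the window truncates to the causal half
  expect_length(pattern_vector(ep, 1, -100, window_ms = 50), 64 * 3)
  expect_error(pattern_vector(ep, 1, 203, window_ms = 50), "not on the time grid")
})

test_that("neural cosine dissimilarities hit the canonical values and bounds", {
  v <- c(1, 2, -1, 0.5)
  dat <- array(0, c(4, 4, 1))
  dat[1, , 1] <- v
  dat[2, , 1] <- 2 * v          # parallel
  dat[3, , 1] <- -v             # anti-parallel
  dat[4, , 1] <- c(2, -1, 0, 0) # orthogonal to v
  ep <- make_epochs(dat, sfreq = 100)
  rdm <- neural_rdm(ep, 0, window_ms = 5)
  pr <- serialdep:::condensed_pairs(4)
  expect_equal(rdm[pr[, 1] == 1 & pr[, 2] == 2], 0, tolerance = 1e-12)
  expect_equal(rdm[pr[, 1] == 1 & pr[, 2] == 3], 2, tolerance = 1e-12)
  expect_equal(rdm[pr[, 1] == 1 & pr[, 2] == 4], 1, tolerance = 1e-12)
  set.seed(3)
  ep2 <- make_epochs(array(rnorm(30 * 8 * 5), c(30, 8, 5)))
  r2 <- neural_rdm(ep2, 20, window_ms = 50)
  expect_true(all(r2 >= -1e-12 & r2 <= 2 + 1e-12))
  dat[2, , 1] <- 0
  expect_error(neural_rdm(make_epochs(dat), 0, 5), "trial 2")
})

test_that("neural RDM matches a double-loop brute-force oracle", {
  set.seed(4)
  ep <- make_epochs(array(rnorm(12 * 6 * 7), c(12, 6, 7)))
  rdm <- neural_rdm(ep, 30, window_ms = 50)
  pr <- serialdep:::condensed_pairs(12)
  for (k in seq_len(nrow(pr))) {
    a <- pattern_vector(ep, pr[k, 1], 30, 50)
    b <- pattern_vector(ep, pr[k, 2], 30, 50)
    expect_equal(as.numeric(rdm[k]),
                 1 - sum(a * b) / sqrt(sum(a^2) * sum(b^2)),
                 tolerance = 1e-10)
  }
})

test_that("PCA reduction keeps the smallest count reaching the variance target", {
  set.seed(5)
  # full-rank data at var_target = 1 keeps every channel
  ep <- make_epochs(array(rnorm(10 * 6 * 8), c(10, 6, 8)))
  expect_equal(pca_reduce(ep, var_target = 1)$n_components, 6)
  # true rank 3 plus tiny jitter: 3 components at 0.99
  base <- matrix(rnorm(10 * 8 * 3), 10 * 8, 3)
  mix <- matrix(rnorm(3 * 12), 3, 12)
  X <- base %*% mix + matrix(rnorm(10 * 8 * 12, sd = 1e-4), 10 * 8, 12)
  arr <- aperm(array(X, c(10, 8, 12)), c(1, 3, 2))
  ep3 <- make_epochs(arr)
  red <- pca_reduce(ep3, var_target = 0.99)
  expect_equal(red$n_components, 3)
  expect_equal(dim(red$data)[2], 3)
  expect_error(pca_reduce(ep, var_target = 0), "0, 1")
  expect_error(pca_reduce(ep, var_target = 1.5), "0, 1")
})

test_that("decode_strength is the OLS slope with an absorbed intercept", {
  loc <- location_rdm(c(0, 1, 3, 6, 10))
  neural <- structure(0.5 + 2 * as.numeric(loc), class = "condensed_rdm",
                      n_trials = 5)
  expect_equal(decode_strength(neural, loc), 2, tolerance = 1e-12)
  # invariant under adding a constant to the neural RDM
  shifted <- structure(as.numeric(neural) + 5, class = "condensed_rdm",
                       n_trials = 5)
  expect_equal(decode_strength(shifted, loc), 2, tolerance = 1e-12)
  # matches lm() on random instances
  set.seed(6)
  for (i in 1:30) {
    x <- runif(45); y <- rnorm(45)
    expect_equal(decode_strength(y, x), unname(coef(lm(y ~ x))[2]),
                 tolerance = 1e-10)
  }
  expect_error(decode_strength(rnorm(3), rep(1, 3)), "zero-variance")
  expect_error(decode_strength(rnorm(3), rnorm(4)), "different lengths")
})

test_that("decoding finds the planted signal only inside its gain window", {
  px <- planted_exp1(noise_sd = 0.3, seed = 7)
  dec <- decode_timecourse(px$epochs, px$trials, "current_stimulus")
  tin <- in_window(dec$time_ms, c(150, 350))
  tout <- dec$time_ms < 0
  expect_gt(mean(dec$beta[tin]), 10 * max(1e-6, abs(mean(dec$beta[tout]))))
  expect_lt(abs(mean(dec$beta[tout])), 0.005)
})

test_that("decoding is invariant to global channel rescaling", {
  px <- planted_exp1(n_trials_per_block = 15, noise_sd = 0.5, seed = 8)
  scaled <- px$epochs
  scaled$data <- scaled$data * 3.7
  d1 <- decode_timecourse(px$epochs, px$trials, "current_stimulus")
  d2 <- decode_timecourse(scaled, px$trials, "current_stimulus")
  expect_equal(d1$beta, d2$beta, tolerance = 1e-10)
})

test_that("residualization removes the current predictor but keeps the past one", {
  px <- planted_exp1(axis_angle = 90, noise_sd = 0.3, seed = 9)
  res <- residualize_current(px$epochs, px$trials,
                             c("current_stimulus", "current_start"))
  dec_cur_before <- decode_timecourse(px$epochs, px$trials, "current_stimulus")
  dec_cur_after <- decode_timecourse(res, px$trials, "current_stimulus")
  tin <- in_window(dec_cur_before$time_ms, c(150, 350))
  expect_lt(max(abs(dec_cur_after$beta)),
            0.1 * max(abs(dec_cur_before$beta[tin])))
  # the past signal lives on an orthogonal axis and survives
  dec_past <- decode_timecourse(res, px$trials, "previous_report")
  expect_gt(mean(dec_past$beta[tin]), 0.005)
  # collinear removal set errors out
  tr2 <- as.data.frame(px$trials)
  tr2$dup_x <- tr2$current_stimulus_x; tr2$dup_y <- tr2$current_stimulus_y
  expect_error(residualize_current(px$epochs, tr2,
                                   c("current_stimulus", "dup")),
               "singular")
})
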