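test_that("sign permutation test is deterministic and flip-symmetric", {
  set.seed(1)
  x <- matrix(rnorm(8 * 30), 8, 30)
  a <- sign_permutation_test(x, n_perm = 500, seed = 3)
  b <- sign_permutation_test(x, n_perm = 500, seed = 3)
  expect_identical(a$p, b$p)
  neg <- sign_permutation_test(-x, n_perm = 500, seed = 3)
  expect_equal(neg$p, a$p, tolerance = 1e-12)
  ca <- cluster_correction(a); cn <- cluster_correction(neg)
  expect_equal(cn$clusters$mass, -ca$clusters$mass, tolerance = 1e-12)
  expect_equal(cn$clusters$p_corrected, ca$clusters$p_corrected)
  expect_error(sign_permutation_test(matrix(1, 1, 5)), "2 subjects")
  expect_warning(sign_permutation_test(x, n_perm = 50, seed = 1), "unstable")
})

test_that("Monte-Carlo p-values agree with exhaustive sign-flip enumeration", {
  set.seed(2)
  ns <- 8; nt <- 5
  x <- matrix(rnorm(ns * nt, mean = 0.4), ns, nt)
  obs <- colMeans(x)
  # exhaustive oracle over all 2^ns flip patterns
  flips <- as.matrix(expand.grid(rep(list(c(-1, 1)), ns)))
  null_ex <- (flips %*% x) / ns
  p_ex <- vapply(seq_len(nt), function(t)
    mean(abs(null_ex[, t]) >= abs(obs[t])), numeric(1))
  mc <- sign_permutation_test(x, n_perm = 4000, seed = 5)
  se <- sqrt(p_ex * (1 - p_ex) / 4000)
  expect_true(all(abs(mc$p - p_ex) <= 3 * se + 2 / 4000))
})

test_that("a strong common effect attains the permutation floor", {
  x <- matrix(rnorm(10 * 20, sd = 0.1), 10, 20)
  x[, 7] <- 5
  pm <- sign_permutation_test(x, n_perm = 2000, seed = 6)
  expect_lt(pm$p[7], 0.02)
  expect_gte(pm$p[7], 1 / 2001)
})

test_that("pointwise p-values are monotone in effect size", {
  set.seed(3)
  x <- matrix(rnorm(12 * 40, mean = 0.2), 12, 40)
  p1 <- sign_permutation_test(x, n_perm = 1000, seed = 9)$p
  p2 <- sign_permutation_test(3 * x, n_perm = 1000, seed = 9)$p
  expect_true(all(p2 <= p1 + 1e-12))
})

test_that("cluster correction recovers a planted temporal window", {
  set.seed(4)
  x <- matrix(rnorm(12 * 100, sd = 0.4), 12, 100)
  x[, 40:60] <- x[, 40:60] + 1
  pm <- sign_permutation_test(x, n_perm = 1000, seed = 10,
                              times = seq(0, 990, by = 10))
  cl <- cluster_correction(pm)
  sig <- cl$clusters[cl$clusters$p_corrected < 0.05, ]
  expect_equal(nrow(sig), 1)
  expect_lte(sig$start_ms, 400)
  expect_gte(sig$end_ms, 580)
  expect_gt(sig$mass, 0)
  # an unreachable threshold yields an empty cluster list, not an error
  expect_equal(nrow(cluster_correction(pm, cluster_alpha = 1e-6)$clusters), 0)
})

test_that("single-region spatial correction reduces to the temporal one", {
  set.seed(5)
  x <- matrix(rnorm(10 * 50, mean = 0.25), 10, 50)
  pm <- sign_permutation_test(x, n_perm = 500, seed = 11)
  cl <- cluster_correction(pm)
  sp <- spatial_correction(list(only = cl))$only
  expect_equal(sp$clusters$p_corrected, cl$clusters$p_corrected)
})

test_that("spatial correction is conservative and validates schedules", {
  set.seed(6)
  make_region <- function(seed, effect) {
    x <- matrix(rnorm(10 * 60, mean = effect, sd = 0.5), 10, 60)
    cluster_correction(sign_permutation_test(x, n_perm = 500, seed = seed))
  }
  regions <- list(a = make_region(21, 0.4), b = make_region(21, 0.4),
                  c = make_region(21, 0.4))
  corrected <- spatial_correction(regions)
  for (nm in names(regions)) {
    if (nrow(regions[[nm]]$clusters))
      expect_true(all(corrected[[nm]]$clusters$p_corrected >=
                      corrected[[nm]]$clusters$p_temporal - 1e-12))
  }
  bad <- list(a = regions$a,
              b = make_region(99, 0.4))
  expect_error(spatial_correction(bad), "seed schedules")
})

test_that("an effect planted in one region survives spatial correction", {
  set.seed(7)
  null_region <- function(seed) {
    x <- matrix(rnorm(12 * 60, sd = 0.5), 12, 60)
    cluster_correction(sign_permutation_test(x, n_perm = 500, seed = 77))
  }
  eff <- matrix(rnorm(12 * 60, sd = 0.5), 12, 60)
  eff[, 20:35] <- eff[, 20:35] + 1.2
  regions <- c(list(hit = cluster_correction(
    sign_permutation_test(eff, n_perm = 500, seed = 77))),
    stats::setNames(lapply(1:6, null_region), paste0("null", 1:6)))
  corrected <- spatial_correction(regions)
  expect_true(any(corrected$hit$clusters$p_corrected < 0.05))
  fp <- vapply(corrected[-1], function(r)
    nrow(r$clusters) > 0 && any(r$clusters$p_corrected < 0.05), logical(1))
  expect_lte(sum(fp), 1)
})
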