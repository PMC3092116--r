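make_profile <- function(x, chrom = "chr1") {
  data.frame(chrom = chrom, pos = seq_along(x) * 100L, logratio = x)
}

test_that("segmentation leaves constant profiles whole and finds clean steps", {
  set.seed(1)
  # constant noiseless profile -> one segment
  seg <- segment_profile(make_profile(rep(0.2, 60)), nperm = 200)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$n_probes, 60L)
  expect_equal(seg$seg_mean, 0.2)

  # noiseless step 0 -> 1 at probe 50 of 100: breakpoint forced at 50
  x <- c(rep(0, 50), rep(1, 50))
  seg2 <- segment_profile(make_profile(x), nperm = 500)
  expect_equal(nrow(seg2), 2L)
  expect_equal(seg2$n_probes, c(50L, 50L))
  expect_equal(seg2$seg_mean, c(0, 1))

  expect_error(segment_profile(data.frame(chrom = "chr1", pos = c(2, 1),
                                          logratio = c(0, 1))),
               "sorted")
})

test_that("segment means conserve the chromosome mean", {
  set.seed(4)
  x <- c(rnorm(70, 0, 0.2), rnorm(30, 1, 0.2), rnorm(50, -0.5, 0.2))
  seg <- segment_profile(make_profile(x), nperm = 300)
  expect_equal(sum(seg$seg_mean * seg$n_probes) / sum(seg$n_probes),
               mean(x), tolerance = 1e-10)
})

test_that("thresholds are mean +/- 2 SD of pooled controls, with safe fallbacks", {
  th <- estimate_thresholds(c(-0.3, -0.1, 0.1, 0.3))
  expect_equal(th$upper, 2 * sd(c(-0.3, -0.1, 0.1, 0.3)))
  expect_equal(th$upper, 0.5163978, tolerance = 1e-6)
  expect_equal(th$lower, -th$upper)

  set.seed(9)
  pooled <- list(rnorm(100, 0.02, 0.1), rnorm(80, -0.01, 0.12))
  th2 <- estimate_thresholds(pooled)
  all_p <- unlist(pooled)
  expect_equal(th2$upper, mean(all_p) + 2 * sd(all_p))
  expect_equal(th2$lower, mean(all_p) - 2 * sd(all_p))

  expect_warning(th3 <- estimate_thresholds(rep(0, 10)), "zero spread")
  expect_equal(th3$upper, 0.632)
  expect_warning(th4 <- estimate_thresholds(numeric(0)), "default")
  expect_equal(th4, list(upper = 0.632, lower = -0.632))
})

test_that("aberration calls use strict inequalities at the thresholds", {
  segs <- data.frame(sample = "s", chrom = "chr1", start = 1,
                     end = 10, n_probes = 5,
                     seg_mean = c(0.7, -0.7, 0.632, -0.632, 0))
  called <- call_aberrations(segs, list(upper = 0.632, lower = -0.632))
  expect_equal(called$call, c("gain", "loss", "neutral", "neutral", "neutral"))
  expect_error(call_aberrations(segs, list(upper = -1, lower = -2)),
               "lower < 0 < upper")
})

test_that("raising the gain threshold never increases the gain count", {
  set.seed(10)
  segs <- data.frame(sample = "s", chrom = "chr1", start = 1, end = 10,
                     n_probes = 5, seg_mean = rnorm(200, 0, 0.5))
  counts <- vapply(c(0.3, 0.5, 0.7, 0.9), function(u) {
    sum(call_aberrations(segs, list(upper = u, lower = -u))$call == "gain")
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("aberration frequencies follow the any-overlap rule", {
  segs <- rbind(
    data.frame(sample = sprintf("s%02d", 1:54), chrom = "chr1", start = 1,
               end = 1000, call = "gain"),
    data.frame(sample = sprintf("s%02d", 55:100), chrom = "chr1", start = 1,
               end = 1000, call = "neutral"))
  feat <- data.frame(feature = "G1", chrom = "chr1", start = 100, end = 200)
  fr <- aberration_frequencies(segs, feat, n_samples = 100)
  expect_equal(fr$gain_freq, 0.54)
  expect_equal(fr$loss_freq, 0)

  # feature spanning a gain and a neutral segment in one sample -> gain
  segs2 <- data.frame(sample = "s1", chrom = "chr1",
                      start = c(1, 500), end = c(499, 1000),
                      call = c("gain", "neutral"))
  feat2 <- data.frame(feature = "G2", chrom = "chr1", start = 400, end = 600)
  fr2 <- aberration_frequencies(segs2, feat2, n_samples = 1)
  expect_equal(fr2$gain_freq, 1)

  # gain and loss both overlapping -> ambiguous, excluded from both counts
  segs3 <- data.frame(sample = "s1", chrom = "chr1",
                      start = c(1, 500), end = c(499, 1000),
                      call = c("gain", "loss"))
  fr3 <- aberration_frequencies(segs3, feat2, n_samples = 1)
  expect_equal(fr3$gain_freq, 0)
  expect_equal(fr3$loss_freq, 0)
  expect_equal(fr3$n_ambiguous, 1L)

  # no aberrated samples
  fr4 <- aberration_frequencies(
    data.frame(sample = "s1", chrom = "chr1", start = 1, end = 1000,
               call = "neutral"), feat, n_samples = 1)
  expect_equal(c(fr4$gain_freq, fr4$loss_freq), c(0, 0))
})

test_that("null profiles rarely produce called aberrations", {
  set.seed(21)
  th <- list(upper = 0.632, lower = -0.632)
  frac_aberrant <- vapply(1:10, function(i) {
    seg <- segment_profile(make_profile(rnorm(100, 0, 0.3)), nperm = 300)
    called <- call_aberrations(seg, th)
    sum(called$n_probes[called$call != "neutral"]) / sum(called$n_probes)
  }, 0.0)
  expect_lt(mean(frac_aberrant), 0.05)
})
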