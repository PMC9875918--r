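test_that("high-SNR mask matches a sort-and-interpolate percentile oracle", {
  # uniform image: threshold 0.2*c, everything included
  uni <- array(5, c(4, 4, 2, 3))
  m <- computeHighSnrMask(uni)
  expect_true(all(m))

  # temporal means 1..100: oracle P98 = 98.02, threshold 19.604 -> 81 voxels
  vals <- 1:100
  a <- array(rep(vals, 2), c(10, 10, 1, 2))
  m2 <- computeHighSnrMask(a)
  p98 <- percentileOracle(vals, 0.98)
  expect_equal(sum(m2), sum(vals > 0.2 * p98))
  expect_equal(sum(m2), 81)

  # bright cluster among dim voxels: dim voxels fall below 0.2 * P98
  vals3 <- c(rep(1000, 50), rep(1, 950))   # bright voxels fill slice 1 first
  a3 <- array(rep(vals3, 2), c(10, 10, 10, 2))
  m3 <- computeHighSnrMask(a3)
  p983 <- percentileOracle(vals3, 0.98)
  expect_equal(sum(m3), sum(vals3 > 0.2 * p983))
  expect_equal(sum(m3), 50)
  expect_true(all(m3[, , 1][1:50]))
  expect_equal(attr(m3, "emptySlices"), 2:10)

  expect_error(computeHighSnrMask(array(0, c(2, 2, 2, 3))), "all-zero")
})

test_that("threshold mask applies a fixed intensity cut", {
  a <- array(rep(c(1000, 4000), each = 8), c(4, 4, 1, 2))
  m <- computeThresholdMask(a, threshold = 3000)
  expect_equal(sum(m), 8)
})

test_that("temporal unwrapping restores ramps and respects offsets", {
  # no wraps: unchanged
  x <- array(sin(seq(0, 3, length.out = 20)), c(1, 1, 1, 20))
  expect_equal(unwrapPhaseTemporal(x), x)

  # wrapped linear ramp 0.5*t is restored exactly
  t <- 0:20
  ramp <- 0.5 * t
  wrapped <- array((ramp + pi) %% (2 * pi) - pi, c(1, 1, 1, 21))
  out <- unwrapPhaseTemporal(wrapped)
  expect_equal(as.vector(out), ramp - ramp[1] + as.vector(wrapped)[1],
               tolerance = 1e-12)

  # adding 2*pi to every sample shifts the output by a constant
  shifted <- wrapped + 2 * pi
  out2 <- unwrapPhaseTemporal(shifted)
  expect_equal(diff(as.vector(out2)), diff(as.vector(out)), tolerance = 1e-12)
  expect_equal(as.vector(out2) - as.vector(out), rep(2 * pi, 21),
               tolerance = 1e-12)
})

test_that("slice averaging uses magnitude weights for phase", {
  p <- acquisitionParams(1, 1, 1, 1)
  mag <- array(c(3, 1), c(2, 1, 1, 1))
  ph <- array(c(0, pi / 2), c(2, 1, 1, 1))
  series <- epiSeries(mag, ph, p)
  mask <- array(TRUE, c(2, 1, 1))
  avg <- sliceAverage(series, mask)
  expect_equal(avg$magnitude@values[1, 1], 2)
  expect_equal(avg$phase@values[1, 1], (3 * 0 + 1 * pi / 2) / 4)  # pi/8

  # uniform magnitudes: weighted mean equals plain mean
  mag2 <- array(7, c(2, 1, 1, 1))
  avg2 <- sliceAverage(epiSeries(mag2, ph, p), mask)
  expect_equal(avg2$phase@values[1, 1], mean(ph))
})

test_that("slice averaging matches an explicit double-loop oracle", {
  set.seed(11)
  p <- acquisitionParams(1, 2, 1, 10)
  mag <- array(runif(4 * 4 * 2 * 10, 1, 10), c(4, 4, 2, 10))
  ph <- array(rnorm(4 * 4 * 2 * 10), c(4, 4, 2, 10))
  mask <- array(runif(4 * 4 * 2) > 0.3, c(4, 4, 2))
  avg <- sliceAverage(epiSeries(mag, ph, p), mask)
  for (s in 1:2) for (tt in c(1, 5, 10)) {
    num <- 0; den <- 0; msum <- 0; cnt <- 0
    for (i in 1:4) for (j in 1:4) if (mask[i, j, s]) {
      num <- num + mag[i, j, s, tt] * ph[i, j, s, tt]
      den <- den + mag[i, j, s, tt]
      msum <- msum + mag[i, j, s, tt]; cnt <- cnt + 1
    }
    expect_equal(avg$magnitude@values[s, tt], msum / cnt, tolerance = 1e-12)
    expect_equal(avg$phase@values[s, tt], num / den, tolerance = 1e-12)
  }
})

test_that("empty-mask slices are filled from the nearest slice with warning", {
  p <- acquisitionParams(1, 3, 1, 4)
  mag <- array(rep(c(1, 2, 3), each = 4), c(2, 2, 3, 4))
  mask <- array(TRUE, c(2, 2, 3)); mask[, , 2] <- FALSE
  expect_warning(avg <- sliceAverage(epiSeries(mag, NULL, p), mask),
                 "no masked voxels")
  expect_equal(avg$magnitude@values[2, ], avg$magnitude@values[1, ])
})

test_that("cubic detrending is exact on cubics and orthogonal to the basis", {
  nt <- 50
  t <- seq_len(nt)
  cubic <- 2 + 0.5 * t - 0.01 * t^2 + 1e-4 * t^3
  sig <- new("SliceSignal", values = rbind(cubic, cubic + 5), trVol = 1,
             source = "magnitude", detrended = FALSE)
  out <- detrendSliceSignals(sig)
  expect_true(out@detrended)
  expect_lt(max(abs(out@values)) / max(abs(cubic)), 1e-8)

  # residual of cubic + sinusoid is orthogonal to {1, t, t^2, t^3}
  y <- cubic + sin(2 * pi * 0.3 * t)
  sig2 <- new("SliceSignal", values = rbind(y), trVol = 1,
              source = "magnitude", detrended = FALSE)
  r <- detrendSliceSignals(sig2)@values[1, ]
  basis <- cbind(1, t, t^2, t^3)
  basis <- sweep(basis, 2, sqrt(colSums(basis^2)), "/")
  expect_lt(max(abs(crossprod(basis, r))), 1e-10 * sqrt(sum(y^2)))

  # matches a normal-equations oracle
  B <- cbind(1, t, t^2, t^3)
  beta <- solve(t(B) %*% B, t(B) %*% y)
  oracle <- y - as.vector(B %*% beta)
  expect_equal(r, oracle, tolerance = 1e-9)

  expect_error(detrendSliceSignals(
    new("SliceSignal", values = matrix(1:4, 1), trVol = 1,
        source = "magnitude", detrended = FALSE)), "at least")
})

test_that("sub-TR reordering interleaves and averages SMS groups", {
  # MB = 1, N = 3, NR = 2: pure interleave
  vals <- rbind(c(10, 11), c(20, 21), c(30, 31))
  sig <- new("SliceSignal", values = vals, trVol = 3, source = "magnitude",
             detrended = TRUE)
  p <- acquisitionParams(3, 3, 1, 2)
  sub <- reorderToSubTr(sig, p)
  expect_equal(samples(sub), c(10, 20, 30, 11, 21, 31))
  expect_equal(sampleTimes(sub), c(0, 1, 2, 3, 4, 5))
  expect_equal(sampleRate(sub), 1)

  # MB = 2, N = 4, groups {1,3}, {2,4}: group means, hand enumeration
  vals2 <- rbind(c(1, 5), c(2, 6), c(3, 7), c(4, 8))
  sig2 <- new("SliceSignal", values = vals2, trVol = 1, source = "phase",
              detrended = TRUE)
  p2 <- acquisitionParams(1, 4, 2, 2, sliceOrder = list(c(1, 3), c(2, 4)))
  sub2 <- reorderToSubTr(sig2, p2)
  expect_equal(samples(sub2), c((1 + 3) / 2, (2 + 4) / 2,
                                (5 + 7) / 2, (6 + 8) / 2))

  # N = 48, MB = 8: length NR*6 and rate 6/0.7 Hz
  p3 <- acquisitionParams(0.7, 48, 8, 5)
  sig3 <- new("SliceSignal", values = matrix(rnorm(48 * 5), 48), trVol = 0.7,
              source = "magnitude", detrended = TRUE)
  sub3 <- reorderToSubTr(sig3, p3)
  expect_length(samples(sub3), 5 * 6)
  expect_equal(sampleRate(sub3), 6 / 0.7)
})

test_that("MB=1 ascending reordering is a bijection", {
  set.seed(21)
  p <- acquisitionParams(1.5, 5, 1, 12)
  vals <- matrix(rnorm(60), 5)
  sig <- new("SliceSignal", values = vals, trVol = 1.5, source = "magnitude",
             detrended = TRUE)
  back <- unreorderFromSubTr(reorderToSubTr(sig, p), p)
  expect_equal(back@values, vals, tolerance = 0)
})

test_that("constant per-slice offsets put power at 1/TR which detrending removes", {
  # rows differing only by constant offsets -> sub-TR carrier at k/TRvol
  p <- acquisitionParams(1, 8, 1, 64)
  offs <- sin(2 * pi * (1:8) / 8)
  vals <- matrix(rep(offs, 64), 8)
  sig <- new("SliceSignal", values = vals, trVol = 1, source = "magnitude",
             detrended = FALSE)
  sub <- reorderToSubTr(sig, p)
  spec <- subTrPeriodogram(sub)
  carrier <- which.min(abs(spec@freqs - 1))   # 1/TRvol = 1 Hz
  expect_gt(spec@power[carrier], 0.99 * sum(spec@power))

  # after detrending the per-slice means are gone and so is the carrier
  sub2 <- reorderToSubTr(detrendSliceSignals(sig), p)
  spec2 <- subTrPeriodogram(sub2)
  expect_lt(spec2@power[carrier], 1e-10 * spec@power[carrier])
})
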