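test_that("band prefilter passes the band center and rejects out-of-band lines", {
  rate <- 6
  t <- (0:1799) / rate
  bands <- defaultBands()
  expect_equal(bands$resp, c(0.15, 0.5))
  expect_equal(bands$cardiac, c(0.7, 1.6))

  # pure sinusoid at band center: amplitude preserved, no phase shift
  center <- mean(bands$resp)
  x <- makeSubTr(sin(2 * pi * center * t), rate)
  y <- bandPrefilter(x, bands$resp, "resp")
  mid <- 300:1500
  expect_lt(abs(max(abs(samples(y)[mid])) - 1), 0.05)
  cc <- laggedCorrelation(samples(y)[mid], samples(x)[mid], maxLag = 1,
                          rate = rate)
  expect_equal(cc$lag, 0, tolerance = 1 / rate)
  expect_gt(cc$corr, 0.999)

  # 0.3 + 1.2 Hz mixture through the resp band: 1.2 Hz down >= 20 dB
  mix <- makeSubTr(sin(2 * pi * 0.3 * t) + sin(2 * pi * 1.2 * t), rate)
  f <- bandPrefilter(mix, bands$resp, "resp")
  amp <- function(sig, freq) {
    X <- fft(samples(sig) - mean(samples(sig)))
    k <- round(freq * length(samples(sig)) / rate) + 1
    Mod(X[k])
  }
  expect_gt(20 * log10(amp(mix, 1.2) / amp(f, 1.2)), 20)
  expect_lt(abs(amp(f, 0.3) / amp(mix, 0.3) - 1), 0.05)

  expect_error(bandPrefilter(x, c(2.5, 3.5), "cardiac"), "Nyquist")
})

test_that("periodogram satisfies Fourier identities", {
  rate <- 5
  n <- 500
  t <- (0:(n - 1)) / rate
  # exact-bin sinusoid: single dominant bin
  x <- makeSubTr(sin(2 * pi * (10 * rate / n) * t), rate)
  spec <- subTrPeriodogram(x)
  expect_equal(spec@resolution, rate / n)
  expect_gt(max(spec@power) / sum(spec@power), 0.99)
  expect_equal(spec@freqs[which.max(spec@power)], 10 * rate / n)

  # Parseval: total power equals the population variance, two seeds
  for (seed in c(1, 2)) {
    set.seed(seed)
    w <- rnorm(n)
    sp <- subTrPeriodogram(makeSubTr(w, rate))
    expect_equal(sum(sp@power), mean((w - mean(w))^2), tolerance = 0.01)
  }

  # off-bin sinusoid: quadratic interpolation recovers f within 0.25 bin
  fTrue <- (20.4) * rate / n
  xo <- makeSubTr(sin(2 * pi * fTrue * t), rate)
  so <- subTrPeriodogram(xo)
  est <- findFundamental(so, c(0.1, 0.4), NULL, "resp")
  expect_lt(abs(est@f0 - fTrue), 0.25 * so@resolution)
})

test_that("sideband prediction enumerates k/TR +/- f_m inside the band", {
  # TRvol = 0.7 s, pump 0.13 Hz: f1 ~ 1.43 Hz, sidebands 1.30 and 1.56 Hz
  sb <- sidebandFrequencies(0.7, 0.13, band = c(0.7, 1.6), kMax = 1)
  expect_equal(sb, c(1 / 0.7 - 0.13, 1 / 0.7 + 0.13), tolerance = 1e-12)
  expect_equal(round(sb, 2), c(1.30, 1.56))

  # resp 0.25 Hz: lower sideband 1.18 Hz kept, upper 1.68 Hz outside band
  sb2 <- sidebandFrequencies(0.7, 0.25, band = c(0.7, 1.6), kMax = 1)
  expect_equal(round(sb2, 2), 1.18)

  expect_equal(sidebandFrequencies(0.7, numeric(), c(0.7, 1.6)), numeric())
})

test_that("pump line detection is prominence-gated and notch-aware", {
  rate <- 6
  n <- 1800
  t <- (0:(n - 1)) / rate
  set.seed(5)
  noise <- rnorm(n, 0, 0.2)
  # clear pump line at 0.13 Hz
  x <- makeSubTr(sin(2 * pi * 0.13 * t) + noise, rate, source = "phase")
  f <- estimatePumpFrequency(x)
  expect_false(is.null(f))
  expect_lt(abs(f - 0.13), rate / n)

  # no pump injected: nothing found
  x0 <- makeSubTr(noise, rate, source = "phase")
  expect_null(estimatePumpFrequency(x0))

  # pump at 0.13 with respiration at 0.14: resp notch excluded, pump found
  x2 <- makeSubTr(sin(2 * pi * 0.13 * t) + 2 * sin(2 * pi * 0.14 * t) + noise,
                  rate, source = "phase")
  f2 <- estimatePumpFrequency(x2, fResp = 0.14, respHalfwidth = 0.005)
  expect_lt(abs(f2 - 0.13), 2 * rate / n)
})

test_that("fundamental search zeroes exclusion notches iteratively", {
  rate <- 6
  n <- 1800
  t <- (0:(n - 1)) / rate
  # single line, no exclusions
  x1 <- makeSubTr(sin(2 * pi * 1.2 * t), rate)
  s1 <- subTrPeriodogram(x1)
  e1 <- findFundamental(s1, c(0.7, 1.6), NULL, "cardiac")
  expect_lt(abs(e1@f0 - 1.2), 0.25 * s1@resolution)
  expect_equal(e1@nIterations, 1L)

  # strong line at an excluded sideband + weaker true line
  x2 <- makeSubTr(3 * sin(2 * pi * 1.30 * t) + sin(2 * pi * 0.96 * t), rate)
  s2 <- subTrPeriodogram(x2)
  e2 <- findFundamental(s2, c(0.7, 1.6),
                        exclusions = cbind(1.30, 0.01), kind = "cardiac")
  expect_lt(abs(e2@f0 - 0.96), 0.25 * s2@resolution)
  expect_equal(e2@nIterations, 2L)
  expect_equal(nrow(e2@excluded), 1)

  # all in-band power inside notches: exhaustion error
  x3 <- makeSubTr(sin(2 * pi * 1.30 * t), rate)
  s3 <- subTrPeriodogram(x3)
  s3@power[s3@freqs < 1.25 | s3@freqs > 1.35] <- 0
  expect_error(findFundamental(s3, c(0.7, 1.6), cbind(1.30, 0.06), "cardiac"),
               "widen")
})

test_that("narrowband extraction keeps f0 and attenuates monotonically", {
  rate <- 6
  n <- 3600
  t <- (0:(n - 1)) / rate
  est <- makeEstimate(1.17, c(0.7, 1.6), "cardiac")
  hw <- 6.5 / 60

  x <- makeSubTr(sin(2 * pi * 1.17 * t), rate)
  w <- narrowbandExtract(x, est)
  expect_equal(w@band, c(1.17 - hw, 1.17 + hw))
  expect_lt(abs(max(abs(samples(w)[500:3000])) - 1), 0.05)
  expect_gt(inBandPowerFraction(w), 0.95)

  # a line at f0 + 3*halfwidth is attenuated >= 20 dB
  atten <- function(df) {
    xi <- makeSubTr(sin(2 * pi * (1.17 + df) * t), rate)
    wi <- narrowbandExtract(xi, est)
    k <- round((1.17 + df) * n / rate) + 1
    a0 <- Mod(fft(samples(xi))[k]); a1 <- Mod(fft(samples(wi))[k])
    20 * log10(a0 / a1)
  }
  a3 <- atten(3 * hw)
  expect_gt(a3, 20)
  # attenuation non-decreasing beyond the transition band
  a4 <- atten(4 * hw); a6 <- atten(6 * hw)
  expect_true(a4 >= a3 - 1e-6 && a6 >= a4 - 1e-6)

  # clipping at Nyquist warns
  estHigh <- makeEstimate(2.95, c(2.0, 2.99), "cardiac")
  expect_warning(narrowbandExtract(x, estHigh), "Nyquist")
})

test_that("in-band power invariant holds for noisy extracted waveforms", {
  rate <- 6
  n <- 1800
  t <- (0:(n - 1)) / rate
  set.seed(8)
  x <- makeSubTr(sin(2 * pi * 0.25 * t) + rnorm(n, 0, 0.5), rate)
  est <- makeEstimate(0.25, c(0.15, 0.5), "resp")
  w <- narrowbandExtract(x, est)
  expect_gt(inBandPowerFraction(w), 0.95)
})

test_that("an aliased cardiac line is recovered at the sub-TR rate", {
  # cardiac 1.25 Hz, TRvol = 2 s (volume Nyquist 0.25 Hz), NS = 10.
  # Respiration is set to 0.3 Hz: at 0.25 Hz the predicted reordering
  # sideband 2/TR + f_R would coincide exactly with the cardiac line, a
  # degenerate collision the method cannot disambiguate (fundamentals too
  # close to carrier-harmonic sidebands are a documented failure mode).
  cfg <- synthConfig(grid = c(16, 16, 10), trVol = 2, mbFactor = 1L,
                     nReps = 150L, cardiacHz = 1.25, respHz = 0.3,
                     seed = 31L)
  sim <- simulateEpi(cfg)
  mask <- computeHighSnrMask(sim$series)
  avg <- sliceAverage(sim$series, mask)
  sub <- reorderToSubTr(detrendSliceSignals(avg$magnitude),
                        sim$series@params)
  ident <- identifyPhysio(sub, trVol = 2)
  binw <- sampleRate(sub) / length(samples(sub))
  expect_lt(abs(ident$cardiacEstimate@f0 - 1.25), binw)
  # exclusion soundness: f0 outside every zeroed notch
  ex <- ident$cardiacEstimate@excluded
  if (nrow(ex) > 0)
    expect_true(all(abs(ident$cardiacEstimate@f0 - ex[, 1]) >= ex[, 2]))
})

test_that("identification is deterministic", {
  rate <- 6
  t <- (0:1799) / rate
  set.seed(4)
  x <- makeSubTr(sin(2 * pi * 0.27 * t) + sin(2 * pi * 1.1 * t) +
                   rnorm(1800, 0, 0.3), rate)
  a <- identifyPhysio(x, trVol = 1)
  b <- identifyPhysio(x, trVol = 1)
  expect_identical(a$respEstimate@f0, b$respEstimate@f0)
  expect_identical(a$cardiacEstimate@f0, b$cardiacEstimate@f0)
  expect_identical(samples(a$cardiac), samples(b$cardiac))
})
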