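test_that("normalization applies the background-ratio, offset and baseline steps", {
  ## pre-bleach F_BL = F_REF = 90 over background 10 -> baseline ratio 1;
  ## the first post-bleach frame (ratio 0) is subtracted, so the frame with
  ## F_BL = 50 lands at (50-10)/(90-10) = 0.5
  raw <- mkRawTrace(c(90, 90, 90, 10, 50), bleachEnd = 4L,
                    background = 10, reference = 90)
  nt <- normalizeTrace(raw, nBaseline = 3L)
  expect_equal(nt@f, c(1, 1, 1, 0, 0.5))
  expect_equal(nt@t, raw@time - raw@time[4])

  ## F_BL = F_REF, F_BKG = 0 -> all-ones baseline
  raw2 <- mkRawTrace(c(1, 1, 1, 1, 0, 0.4), bleachEnd = 5L)
  nt2 <- normalizeTrace(raw2, nBaseline = 4L)
  expect_equal(nt2@f[1:4], rep(1, 4))
  expect_identical(nt2@f[5], 0)
})

test_that("normalization enforces its preconditions", {
  raw <- mkRawTrace(c(1, 1, 0, 0.4), bleachEnd = 3L)
  expect_error(normalizeTrace(raw, nBaseline = 40L), "pre-bleach",
               class = "mfValidationError")
  rawBad <- mkRawTrace(c(1, 1, 0, 0.4), bleachEnd = 3L,
                       background = 2, reference = 1)
  expect_error(normalizeTrace(rawBad, nBaseline = 2L), "reference",
               class = "mfValidationError")
})

test_that("normalization is invariant to affine rescaling of raw intensities", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 60L
    fb <- c(rep(1, 40), 0.05 + 0.2 * stats::runif(20))
    bkg <- stats::runif(n, 0.05, 0.1)
    ref <- 1 + stats::runif(n, 0, 0.1)
    raw <- memFRAP:::newRoiTraceSet(seq_len(n) - 1, fb * ref, bkg, ref, 41L)
    g <- stats::runif(1, 0.5, 5); o <- stats::runif(1, 0, 3)
    rawAff <- memFRAP:::newRoiTraceSet(
      seq_len(n) - 1, g * (fb * ref) + o, g * bkg + o, g * ref + o, 41L)
    f1 <- normalizeTrace(raw)@f
    f2 <- normalizeTrace(rawAff)@f
    expect_equal(f1, f2, tolerance = 1e-9)
  }
})

test_that("generator raw channels normalize back to the closed-form model", {
  raw <- simulateTurnoverTrace(Cin = 0.3, k1 = 0.045, rawChannels = TRUE)
  nt <- normalizeTrace(raw)
  post <- nt@t >= 0
  expect_lt(max(abs(nt@f[post] - turnoverCurve(nt@t[post], 0.3, 0.045))),
            1e-6)
  expect_equal(mean(nt@f[utils::tail(which(nt@t < 0), 40)]), 1,
               tolerance = 1e-12)
})

test_that("paired-trial correction cancels planted multiplicative drift", {
  t <- 0.14832 * (0:120)
  treat <- soumpasisCurve(t, 0.8, 2)
  ctrl <- soumpasisCurve(t, 0.7, 1.5)
  drift <- 1 + 0.3 * (1 - exp(-t / 10))
  t1 <- mkNormTrace(t, treat)
  t2 <- mkNormTrace(t, treat * drift)
  c1 <- mkNormTrace(t, ctrl)
  c2 <- mkNormTrace(t, ctrl * drift)

  ## identical control trials: identity map
  same <- pairCorrect(t1, t2, c1, c1)
  expect_equal(same@f, t2@f, tolerance = 1e-12)

  corr <- pairCorrect(t1, t2, c1, c2)
  ok <- !corr@flag & corr@t > 0
  expect_gt(sum(ok), 100)
  expect_lt(max(abs(corr@f[ok] - treat[match(corr@t[ok], t)])), 1e-6)
})

test_that("near-zero drift denominators are flagged, not corrected", {
  t <- 0.5 * (0:40)
  treat <- soumpasisCurve(t, 0.9, 2)
  ctrl <- 0.01 * c(0, rep(1, 40))  # control stuck near zero: unusable ratio
  t1 <- mkNormTrace(t, treat); t2 <- mkNormTrace(t, treat)
  c1 <- mkNormTrace(t, ctrl); c2 <- mkNormTrace(t, ctrl * 2)
  corr <- pairCorrect(t1, t2, c1, c2)
  post <- corr@t >= 0
  expect_true(all(corr@flag[post]))
  expect_equal(corr@f[post], t2@f[post])  # values untouched where flagged
  ## difference mode has no denominator and applies everywhere
  corrD <- pairCorrect(t1, t2, c1, c2, method = "difference")
  expect_false(any(corrD@flag[corrD@t > 0]))
})

test_that("trace averaging reports mean, SEM and a calibrated bootstrap band", {
  t <- 1.644 * (0:50)
  f <- turnoverCurve(t, 0.3, 0.045)
  a <- mkNormTrace(t, f)
  avg2 <- averageTraces(list(a, a), nBoot = 50)
  expect_equal(avg2@f, a@f)
  expect_equal(avg2@sem, rep(0, length(a@f)))

  ## {0.2, 0.4} at a frame: mean 0.3, SEM 0.1
  b1 <- mkNormTrace(t, replace(f, 10, 0.2))
  b2 <- mkNormTrace(t, replace(f, 10, 0.4))
  avg <- averageTraces(list(b1, b2), nBoot = 0)
  i <- which(avg@t == t[10])
  expect_equal(avg@f[i], 0.3)
  expect_equal(avg@sem[i], 0.1)

  ## single trace: dispersion undefined, flagged
  single <- averageTraces(list(a), nBoot = 0)
  expect_true(all(single@flag))
  expect_true(all(is.na(single@sem)))

  ## 27 noisy replicates: bootstrap CI covers the generating curve
  reps <- lapply(1:27, function(s)
    simulateTurnoverTrace(noiseSd = 0.01, seed = 500 + s))
  avg27 <- averageTraces(reps, nBoot = 500, seed = 9)
  post <- avg27@t > 0
  truth <- turnoverCurve(avg27@t[post], 0.3, 0.045)
  covered <- truth >= avg27@ciLow[post] & truth <= avg27@ciHigh[post]
  expect_gte(mean(covered), 0.9)
})
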