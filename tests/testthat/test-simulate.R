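test_that("turnover trace generator reproduces the closed form and its seeds", {
  nt <- simulateTurnoverTrace(Cin = 0.3, k1 = 0.045)
  post <- nt@t >= 0
  expect_lt(max(abs(nt@f[post] - turnoverCurve(nt@t[post], 0.3, 0.045))),
            1e-12)
  ## seed determinism
  a <- simulateTurnoverTrace(noiseSd = 0.01, seed = 5)
  b <- simulateTurnoverTrace(noiseSd = 0.01, seed = 5)
  c <- simulateTurnoverTrace(noiseSd = 0.01, seed = 6)
  expect_identical(a@f, b@f)
  expect_false(identical(a@f, c@f))
  ## short-duration warning
  expect_warning(simulateTurnoverTrace(duration = 30), "plateau")
})

test_that("puff trace generator round-trips the surface fraction", {
  sim <- simulatePuffTrace(0.72)
  est <- surfaceFractionFromTrace(sim$trace, sim$epochs)
  expect_equal(est$R, 0.72)

  ## fully surface-resident: acid epoch dark, NH4Cl equals baseline
  simFull <- simulatePuffTrace(1)
  v <- simFull$trace@bleach[, 1]
  expect_equal(unique(v[61:100]), 0)
  expect_equal(mean(v[141:180]), mean(v[1:40]))

  ## noisy replicates stay centred on the truth
  rhat <- vapply(1:20, function(s) {
    noisy <- simulatePuffTrace(0.72, noiseSd = 0.02, seed = s)
    surfaceFractionFromTrace(noisy$trace, noisy$epochs)$R
  }, numeric(1))
  expect_lt(abs(mean(rhat) - 0.72), 0.02)
})

test_that("Brownian FRAP simulation is seed-deterministic and conserves mass", {
  a <- simulateBrownianFrap(D = 0.1, immobileFraction = 0.2,
                            nParticles = 2000, duration = 5, seed = 3)
  b <- simulateBrownianFrap(D = 0.1, immobileFraction = 0.2,
                            nParticles = 2000, duration = 5, seed = 3)
  expect_identical(a$trace@f, b$trace@f)
  c <- simulateBrownianFrap(D = 0.1, immobileFraction = 0.2,
                            nParticles = 2000, duration = 5, seed = 4)
  expect_false(identical(a$trace@f, c$trace@f))

  ## exchange with fully fluorescent replacements: the readout occupancy
  ## recovers to its stationary pre-bleach level (mass conserved, uniform
  ## reinsertion)
  ex <- simulateBrownianFrap(D = 0, immobileFraction = 1, k1 = 0.1,
                             unbleachedFraction = 1,
                             nParticles = 20000, dt = 0.05, duration = 60,
                             bleachRadius = 1, readoutRadius = 2,
                             domainSize = 10, bleachTime = 40,
                             frameInterval = 1, seed = 9)
  counts <- ex$truth$counts
  early <- mean(counts[1:40])
  late <- mean(counts[(length(counts) - 19):length(counts)])
  expect_lt(abs(late - early) / early, 0.05)
})

test_that("simulation guards reject unresolvable configurations", {
  expect_error(simulateBrownianFrap(D = 0.152, dt = 1, frameInterval = 2,
                                    duration = 5),
               "guard", class = "mfValidationError")
  expect_error(simulateBrownianFrap(D = 0.01, domainSize = 5, duration = 5),
               "domain", class = "mfValidationError")
  expect_error(simulateBrownianFrap(D = 0.01, dt = 0.5, frameInterval = 0.1,
                                    duration = 5),
               "frameInterval", class = "mfValidationError")
})

test_that("frozen mobile molecules show no recovery", {
  sim <- simulateBrownianFrap(D = 0, immobileFraction = 1,
                              nParticles = 5000, domainSize = 12,
                              duration = 10, seed = 2)
  post <- sim$trace@t > 0
  expect_true(all(abs(sim$trace@f[post]) < 1e-12))
})

test_that("pure-diffusion particle traces converge to the Soumpasis curve", {
  sim <- simulateBrownianFrap(D = 0.152, immobileFraction = 0,
                              nParticles = 50000, domainSize = 12,
                              duration = 20, seed = 5)
  tr <- sim$trace
  sel <- tr@t >= 0.2 & tr@t <= 20
  pred <- soumpasisCurve(tr@t[sel], Cmob = 1, tauD = 1.03^2 / (4 * 0.152))
  expect_lt(mean(abs(tr@f[sel] - pred)), 0.03)
})

test_that("whole-field bleach with exchange follows the turnover model", {
  ## membrane exit at k1 with partially fluorescent replacements: the trace
  ## must reproduce the closed-form turnover kinetics at the exit rate
  ex <- simulateBrownianFrap(D = 0, immobileFraction = 1, k1 = 0.045,
                             nParticles = 5000, dt = 0.05, duration = 150,
                             bleachRadius = Inf, readoutRadius = Inf,
                             bleachTime = 60, frameInterval = 1.644,
                             seed = 2)
  fit <- fitTurnover(ex$trace, nBoot = 0)
  expect_lt(abs(coef(fit)[["k1"]] - 0.045) / 0.045, 0.15)
})

test_that("point-pattern generators hit their target intensities", {
  counts <- vapply(1:10, function(s)
    length(simulatePointPattern("poisson", area = 4, lambda = 67,
                                seed = s)$map@x), numeric(1))
  expect_lt(abs(mean(counts) - 268), 3 * sqrt(268 / 10))

  ## determinism across all modes
  for (m in c("poisson", "thomas", "associated", "repulsive")) {
    a <- simulatePointPattern(m, seed = 7)
    b <- simulatePointPattern(m, seed = 7)
    expect_identical(a$map@x, b$map@x)
    expect_identical(a$map@channel, b$map@channel)
  }

  ## repulsive mode leaves no channel-2 point inside the exclusion radius
  simR <- simulatePointPattern("repulsive", area = 4, lambda = 40,
                               lambda2 = 40, exclusionRadius = 100, seed = 2)
  p1 <- cbind(simR$map@x, simR$map@y)[simR$map@channel == "chan1", ]
  p2 <- cbind(simR$map@x, simR$map@y)[simR$map@channel == "chan2", ]
  expect_equal(length(nnDistances(p2, p1, cutoff = 100)), 0L)
})
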