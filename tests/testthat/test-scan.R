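# Bootstrap estimation, bin aggregation, cumulative track, crossover
# detection and skipped-extremum recovery.

test_that("bootstrap mean and variance follow the subsample LLRs", {
  set.seed(41)
  pan <- syntheticPanel(nHaplotypes = 100, nSites = 200, chromLength = 2e4)
  comp <- AncestryComposition(c(POP1 = 1))
  pos <- panelPositions(pan)
  mk <- function(i) obs1(pos[i], haplotypeMatrix(pan)[1, i])
  mono <- lapply(seq(1, 24, by = 2), mk)
  di <- lapply(seq(2, 48, by = 2), mk)
  set.seed(99)
  b1 <- bootstrapWindow(mono, di, pan, comp, m = 40L)
  set.seed(99)
  b2 <- bootstrapWindow(mono, di, pan, comp, m = 40L)
  # determinism under a fixed seed
  expect_identical(b1, b2)
  expect_false(b1$flagged)
  expect_gte(b1$gammaVar, 0)
  expect_error(bootstrapWindow(mono, di, pan, comp, m = 1L), "m must be")
  # every subsample identical (counts below the caps) -> variance 0
  small <- bootstrapWindow(mono[1:3], di[1:4], pan, comp, m = 10L)
  expect_equal(small$gammaVar, 0)
})

test_that("bin aggregation follows the additive formulas", {
  a <- aggregateBin(c(1, 2, 3), c(0.1, 0.1, 0.1))
  expect_equal(a$Gamma, 6)
  expect_equal(a$VarGamma, 0.3)
  expect_equal(a$gammaBin, 2)
  expect_equal(a$varBin, 0.3 / 9)
  one <- aggregateBin(1.5, 0.2)
  expect_equal(one$Gamma, 1.5)
  # splitting a bin and summing the parts reproduces the whole
  whole <- aggregateBin(c(1, -1, 2, 0.5), c(0.1, 0.2, 0.3, 0.4))
  p1 <- aggregateBin(c(1, -1), c(0.1, 0.2))
  p2 <- aggregateBin(c(2, 0.5), c(0.3, 0.4))
  expect_equal(p1$Gamma + p2$Gamma, whole$Gamma)
  expect_equal(p1$VarGamma + p2$VarGamma, whole$VarGamma)
  expect_error(aggregateBin(numeric(), numeric()), "empty")
})

test_that("bin classification uses the confidence interval sides", {
  expect_equal(classifyBin(0, 0.5), "ambiguous")
  expect_equal(classifyBin(1, 0.01, z = 1.96), "unmatched")
  expect_equal(classifyBin(-1, 0.01, z = 1.96), "matched")
  expect_equal(classifyBin(-0.01, 0.04, z = 0), "matched")  # point interval
  expect_equal(classifyBin(NA_real_, NA_real_), "ambiguous")
})

test_that("cumulative track is the pair of prefix sums", {
  est <- data.frame(window = 1:3, chrom = "c", start = c(0, 100, 200),
                    end = c(100, 200, 300), gamma_mean = c(1, -1, 1),
                    gamma_var = c(0.1, 0.2, 0.3), m = 10L)
  tr <- cumulativeTrack(est)
  expect_equal(tr$y, c(1, 0, 1))
  expect_equal(tr$v, c(0.1, 0.3, 0.6))
  expect_true(all(diff(tr$v) >= 0))
  # partial-sum identity
  expect_equal(tr$y[3] - tr$y[1], sum(est$gamma_mean[2:3]))
  expect_error(cumulativeTrack(est[c(2, 1, 3), ]), "sorted")
})

test_that("the step-track example yields exactly one call at the extremum", {
  tr <- stepTrack(c(rep(0.5, 20), rep(-0.5, 20)))
  calls <- detectCrossovers(tr, z = 1.96, delta = 15L)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$window, 20L)
  expect_equal(calls$direction, "unmatched_to_matched")
  expect_gte(calls$kappa, 1.96)
  # flat track: no calls
  expect_equal(nrow(detectCrossovers(stepTrack(rep(0, 40)))), 0L)
  # alternating segments shorter than delta: no calls
  zig <- stepTrack(rep(c(0.5, -0.5), each = 5, times = 4))
  expect_equal(nrow(detectCrossovers(zig, z = 1.96, delta = 15L)), 0L)
  # fewer than 2*delta + 1 windows: empty, no error
  expect_equal(nrow(detectCrossovers(stepTrack(rep(0.5, 20)), delta = 15L)), 0L)
})

test_that("detector candidates match the exhaustive (i,j,k) oracle", {
  set.seed(43)
  for (rep in 1:6) {
    gam <- rnorm(40, mean = rep(c(0.6, -0.6), each = 20), sd = 0.4)
    tr <- stepTrack(gam, vars = runif(40, 0.05, 0.3))
    calls <- detectCrossovers(tr, z = 1.96, delta = 10L)
    want <- oracleDetect(tr, z = 1.96, delta = 10L)
    got <- calls[!calls$recovered, ]
    expect_setequal(got$window, want$window)
  }
})

test_that("a skipped extremum between two same-type calls is recovered", {
  # two clear maxima with a shallow dip: the dip itself is below threshold
  gam <- c(rep(0.6, 16), rep(-0.12, 16), rep(0.6, 16), rep(-0.6, 16))
  tr <- stepTrack(gam, vars = rep(0.04, 64))
  calls <- detectCrossovers(tr, z = 1.96, delta = 15L)
  # directions alternate along the chromosome
  expect_true(all(abs(diff(match(calls$direction,
                                 c("unmatched_to_matched",
                                   "matched_to_unmatched")))) == 1))
  if (any(calls$recovered)) {
    rec <- calls[calls$recovered, ]
    expect_equal(rec$direction, "matched_to_unmatched")
    expect_true(rec$window > 16 && rec$window <= 33)
  }
  # recoverSkipped against brute force on the printed objective
  y <- tr$y; v <- tr$v
  i <- 16L; k <- 48L
  nn <- (i + 1L):(k - 1L)
  obj <- (y[k] - y[nn]) / sqrt(v[k] - v[nn]) -
    (y[nn] - y[i]) / sqrt(v[nn] - v[i])
  expect_equal(recoverSkipped(tr, i, k, "max"), nn[which.max(obj)])
  expect_error(recoverSkipped(tr, 5L, 6L, "max"), "interior")
})

test_that("scan is deterministic and its estimates drive reproducible calls", {
  set.seed(44)
  pan <- syntheticPanel(nHaplotypes = 200, chromLength = 1.2e6, seed = 45)
  pair <- simulatePair(pan, "matched", coverage = 0.05, seed = 46)
  spec <- windowSpec(b = 8L)
  s1 <- scanChromosome(pair$mono, pair$di, pan, pair$composition,
                       spec = spec, m = 20L, seed = 47)
  s2 <- scanChromosome(pair$mono, pair$di, pan, pair$composition,
                       spec = spec, m = 20L, seed = 47)
  expect_identical(s1$estimates, s2$estimates)
  expect_true(all(s1$estimates$gamma_var >= 0))
  # matched truth: predominantly negative LLRs
  expect_lt(mean(s1$estimates$gamma_mean), 0)
})

test_that("richer windows estimate the mean LLR more stably", {
  set.seed(48)
  pan <- syntheticPanel(nHaplotypes = 100, nSites = 3000, chromLength = 3e5)
  comp <- AncestryComposition(c(POP1 = 1))
  pos <- panelPositions(pan)
  mk <- function(i, row) obs1(pos[i], haplotypeMatrix(pan)[row, i])
  meansAt <- function(nReads) {
    vapply(1:30, function(r) {
      idx <- sort(sample.int(nSites(pan), 3 * nReads))
      mono <- lapply(idx[seq_len(nReads)], mk, row = 1)
      di <- lapply(idx[nReads + seq_len(2 * nReads)],
                   function(i) mk(i, row = sample(1:2, 1)))
      bootstrapWindow(mono, di, pan, comp, m = 40L)$gammaMean
    }, 0)
  }
  # the mean LLR of a window averages over subsampled read sets, so the
  # between-window spread shrinks as the read pool per window grows
  expect_lt(sd(meansAt(24L)), sd(meansAt(8L)))
})
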