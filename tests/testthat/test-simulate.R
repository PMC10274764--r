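# The synthetic panel / trio / read generators.

test_that("synthetic panels have the requested shape and are seeded", {
  pan <- syntheticPanel(nHaplotypes = 200, nSites = 5000,
                        chromLength = 5e5, seed = 91)
  expect_equal(nHaplotypes(pan), 200L)
  expect_equal(nSites(pan), 5000L)
  expect_true(all(diff(panelPositions(pan)) > 0))
  expect_true(all(haplotypeMatrix(pan) %in% 0:1))
  pan2 <- syntheticPanel(nHaplotypes = 200, nSites = 5000,
                         chromLength = 5e5, seed = 91)
  expect_identical(haplotypeMatrix(pan2), haplotypeMatrix(pan))
  expect_error(syntheticPanel(nHaplotypes = 5), "even")
})

test_that("pairwise LD decays with inter-site distance", {
  pan <- syntheticPanel(nHaplotypes = 300, nSites = 2000,
                        chromLength = 2e6, seed = 92)
  hap <- haplotypeMatrix(pan)
  pos <- panelPositions(pan)
  set.seed(93)
  idx <- sample.int(2000, 400)
  r2 <- c(); d <- c()
  for (i in idx) {
    j <- i + sample(c(1:5, 150:250), 1)
    if (j > 2000) next
    a <- hap[, i]; b <- hap[, j]
    if (sd(a) == 0 || sd(b) == 0) next
    r2 <- c(r2, cor(a, b)^2)
    d <- c(d, pos[j] - pos[i])
  }
  near <- mean(r2[d < 1e4])
  far <- mean(r2[d > 1e5])
  expect_gt(near, far)
})

test_that("density profiles thin the requested interval", {
  prof <- data.frame(start = 4e5, end = 6e5, weight = 0.1)
  pan <- syntheticPanel(nHaplotypes = 20, nSites = 5000, chromLength = 1e6,
                        densityProfile = prof, seed = 94)
  pos <- panelPositions(pan)
  inside <- sum(pos > 4e5 & pos <= 6e5) / 2e5
  outside <- sum(pos <= 4e5 | pos > 6e5) / 8e5
  expect_lt(inside, 0.3 * outside)
})

test_that("trio draws respect relatedness and population structure", {
  pan <- syntheticPanel(nHaplotypes = 40, nSites = 50, chromLength = 5e3,
                        populations = c(A = 20, B = 20), seed = 95)
  set.seed(96)
  t1 <- drawTrio(pan, "non-admixed")
  rows <- c(t1$parent, t1$offspring[2], t1$unrelated)
  expect_equal(length(unique(rows)), 3L)
  expect_equal(t1$offspring[1], t1$parent)   # offspring carries the parent
  expect_equal(length(unique(panelPopulations(pan)[rows])), 1L)
  t2 <- drawTrio(pan, "recent-admixed")
  expect_equal(length(unique(panelPopulations(pan)[t2$offspring])), 2L)
})

test_that("read counts and haplotype balance follow the generative model", {
  pan <- syntheticPanel(nHaplotypes = 20, nSites = 1000, chromLength = 1e6,
                        seed = 97)
  set.seed(98)
  mono <- simulateReads(pan, 1L, 1, coverage = 0.05, chromLength = 1e6,
                        readLen = 75L, ploidy = 1L)
  expect_equal(nrow(readTable(mono)), round(0.05 * 1e6 / 75))
  # p1 = 1: every observation equals haplotype 1's allele
  o <- obsTable(mono)
  idx <- match(o$pos, panelPositions(pan))
  expect_equal(o$allele, unname(haplotypeMatrix(pan)[1L, idx]))
  expect_error(simulateReads(pan, 1:2, c(0.7, 0.6), 0.05, 1e6), "sum to 1")

  # disomy: haplotype 1 drawn in about half the reads
  panD <- syntheticPanel(nHaplotypes = 20, nSites = 2e4, chromLength = 1e6,
                         seed = 970)
  set.seed(99)
  di <- simulateReads(panD, c(1L, 2L), c(0.5, 0.5), coverage = 0.38,
                      chromLength = 1e6, ploidy = 2L)
  o <- obsTable(di)
  idx <- match(o$pos, panelPositions(panD))
  h1 <- haplotypeMatrix(panD)[1L, idx]
  h2 <- haplotypeMatrix(panD)[2L, idx]
  inf <- h1 != h2
  # classify each read by its first informative site
  perRead <- tapply(seq_len(nrow(o))[inf], o$read_id[inf], function(ii) {
    o$allele[ii[1]] == h1[ii[1]]
  })
  fromH1 <- mean(unlist(perRead))
  expect_lt(abs(fromH1 - 0.5), 0.02)
})

test_that("pair truth tracks the scenario and its breakpoints", {
  pan <- syntheticPanel(nHaplotypes = 60, nSites = 600, chromLength = 6e5,
                        seed = 100)
  m <- simulatePair(pan, "matched", coverage = 0.02, seed = 101)
  expect_equal(m$truth$label, "matched")
  expect_equal(samplePloidy(m$mono), 1L)
  expect_equal(samplePloidy(m$di), 2L)
  u <- simulatePair(pan, "unmatched", coverage = 0.02, seed = 102)
  expect_equal(u$truth$label, "unmatched")
  b <- simulatePair(pan, "matched", coverage = 0.02, breakpoints = 3e5,
                    seed = 103)
  expect_equal(b$truth$label, c("matched", "unmatched"))
  expect_equal(b$truth$end[1], 3e5)
  # determinism of whole datasets
  b2 <- simulatePair(pan, "matched", coverage = 0.02, breakpoints = 3e5,
                     seed = 103)
  expect_identical(obsTable(b2$di), obsTable(b$di))
})

test_that("separation between matched and unmatched grows with coverage", {
  pan <- syntheticPanel(nHaplotypes = 300, chromLength = 2e6, seed = 104)
  spec <- windowSpec(b = 12L)
  sep <- vapply(c(0.013, 0.05), function(cov) {
    gms <- vapply(1:2, function(k) {
      scn <- c("matched", "unmatched")[k]
      pair <- simulatePair(pan, scn, coverage = cov, seed = 105 + k)
      sc <- scanChromosome(pair$mono, pair$di, pan, pair$composition,
                           spec = spec, m = 25L, seed = 107 + k)
      mean(sc$estimates$gamma_mean)
    }, 0)
    gms[2] - gms[1]
  }, 0)
  expect_true(all(sep > 0))
  expect_gt(sep[2], sep[1])
})
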