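# Matched/unmatched hypothesis likelihoods and their log ratio.

# 4 haplotypes, 2 sites in perfect LD; f(A)=f(B)=0.5, f(A,B)=0.5
ldPanel <- makePanel(rbind(c(0, 0), c(0, 0), c(1, 1), c(1, 1)))
ldComp <- AncestryComposition(c(P = 1))
readA <- list(obs1(100, 0))
readB <- list(obs1(200, 0))

test_that("the two-read worked example reproduces the closed forms", {
  expect_equal(matchedLikelihood(readA, readB, ldPanel, ldComp), 0.375)
  expect_equal(unmatchedLikelihood(readA, readB, ldPanel, ldComp), 0.25)
  llr <- windowLlr(readA, readB, ldPanel, ldComp)
  expect_equal(llr$gamma, log(0.25 / 0.375))
  expect_false(llr$uninformative)
})

test_that("linkage equilibrium gives gamma = 0", {
  # 4 haplotypes, independent sites: joint factorizes exactly
  pan <- makePanel(rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1)))
  llr <- windowLlr(readA, readB, pan, ldComp)
  expect_equal(llr$gamma, 0)
})

test_that("disomy likelihood has the marginalization structure", {
  pan <- ldPanel
  # n = 0: empty product
  expect_equal(disomyLikelihood(list(), pan, ldComp), 1)
  # n = 1: (1/2) f(B) + (1/2) f(B) = f(B)
  expect_equal(disomyLikelihood(readB, pan, ldComp), 0.5)
  # n = 2 against hand enumeration: 1/2 f(B1,B2) + 1/2 f(B1) f(B2)
  b2 <- list(obs1(100, 0), obs1(200, 0))
  expect_equal(disomyLikelihood(b2, pan, ldComp), 0.5 * 0.5 + 0.5 * 0.25)
})

test_that("a monomorphic monosomy span reduces unmatched to the disomy model", {
  hap <- rbind(c(0, 0, 0), c(0, 0, 1), c(0, 1, 0), c(0, 1, 1))
  pan <- makePanel(hap)
  a <- list(obs1(100, 0))         # F(A) = 1
  b <- list(obs1(200, 0), obs1(300, 1))
  expect_equal(unmatchedLikelihood(a, b, pan, ldComp),
               disomyLikelihood(b, pan, ldComp))
})

test_that("read-count preconditions are enforced", {
  expect_error(matchedLikelihood(list(), readB, ldPanel, ldComp),
               "at least one monosomy read")
  many <- rep(readA, 7)
  expect_error(matchedLikelihood(many, readB, ldPanel, ldComp), "more than 6")
  expect_error(matchedLikelihood(readA, rep(readB, 13), ldPanel, ldComp),
               "more than 12")
})

test_that("likelihoods equal exhaustive homolog-assignment enumeration", {
  set.seed(11)
  for (rep in 1:25) {
    H <- sample(c(4, 6, 8), 1)
    hap <- matrix(rbinom(H * 5, 1, 0.5), nrow = H)
    pan <- makePanel(hap)
    m <- sample.int(3, 1)
    n <- sample.int(3, 1)
    a <- randomReads(pan, m)
    b <- randomReads(pan, n)
    got <- list(matched = matchedLikelihood(a, b, pan, ldComp),
                unmatched = unmatchedLikelihood(a, b, pan, ldComp))
    want <- oracleLikelihoods(a, b, pan, c(P = 1))
    expect_equal(got$matched, want$matched, tolerance = 1e-12)
    expect_equal(got$unmatched, want$unmatched, tolerance = 1e-12)
  }
})

test_that("admixture: one-population composition collapses and mixtures match the oracle", {
  set.seed(12)
  pan <- syntheticPanel(nHaplotypes = 24, nSites = 12, chromLength = 1200,
                        populations = c(A = 12, B = 12))
  a <- randomReads(pan, 2)
  b <- randomReads(pan, 2)
  # distant admixture: every frequency replaced by the alpha-mixture
  mix <- AncestryComposition(c(A = 0.3, B = 0.7))
  got <- matchedLikelihood(a, b, pan, mix)
  want <- oracleLikelihoods(a, b, pan, c(A = 0.3, B = 0.7))
  expect_equal(got, want$matched, tolerance = 1e-12)
  # recent admixture: homolog-specific distributions
  rec <- list(AncestryComposition(c(A = 1)), AncestryComposition(c(B = 1)))
  gotR <- list(matched = matchedLikelihood(a, b, pan, rec),
               unmatched = unmatchedLikelihood(a, b, pan, rec))
  wantR <- oracleLikelihoods(a, b, pan, c(A = 1), c(B = 1))
  expect_equal(gotR$matched, wantR$matched, tolerance = 1e-12)
  expect_equal(gotR$unmatched, wantR$unmatched, tolerance = 1e-12)
  # both parents from the same population: equals the non-admixed case
  recSame <- list(AncestryComposition(c(A = 1)), AncestryComposition(c(A = 1)))
  expect_equal(matchedLikelihood(a, b, pan, recSame),
               matchedLikelihood(a, b, pan, AncestryComposition(c(A = 1))))
})

test_that("likelihoods are exchangeable in the reads", {
  set.seed(13)
  pan <- syntheticPanel(nHaplotypes = 30, nSites = 10, chromLength = 1000,
                        populations = c(P = 30))
  a <- randomReads(pan, 3)
  b <- randomReads(pan, 3)
  comp <- AncestryComposition(c(P = 1))
  for (f in c(matchedLikelihood, unmatchedLikelihood)) {
    expect_equal(f(a, b, pan, comp),
                 f(a[c(2, 3, 1)], b[c(3, 1, 2)], pan, comp))
  }
})

test_that("gamma saturates at +/- log(2N) instead of diverging", {
  # B's allele combination absent from the panel given A: matched = 0
  hap <- rbind(c(0, 0), c(0, 0), c(1, 1), c(1, 0))
  pan <- makePanel(hap)
  comp <- AncestryComposition(c(P = 1))
  a <- list(obs1(c(100, 200), c(0, 1)))    # haplotype (0,1): absent
  b <- list(obs1(100, 1))
  llr <- windowLlr(a, b, pan, comp)
  expect_true(llr$uninformative)           # F(A) = 0 kills both hypotheses
  # A present, B reads individually present, but every matched-assignment
  # term zero: gamma saturates exactly at log(2N)
  pan2 <- makePanel(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 1, 0), c(1, 0, 1)))
  a2 <- list(obs1(100, 0))
  b2 <- list(obs1(200, 1), obs1(300, 1))
  llr2 <- windowLlr(a2, b2, pan2, comp)
  expect_false(llr2$uninformative)
  expect_equal(llr2$pMatched, 0)
  expect_gt(llr2$pUnmatched, 0)
  expect_equal(llr2$gamma, log(2 * nHaplotypes(pan2)))
})
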