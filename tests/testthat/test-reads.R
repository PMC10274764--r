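# Read reduction and priority scoring.

test_that("priority score matches the single-SNP MAF rule", {
  # site with MAF 0.25 and site with MAF 0.02
  hap <- cbind(c(rep(0, 75), rep(1, 25)), c(rep(0, 98), rep(1, 2)))
  pan <- makePanel(hap, positions = c(500L, 1500L))
  comp <- AncestryComposition(c(P = 1))
  expect_equal(priorityScore(pan, 450, 550, comp, f0 = 0.05), 2L)
  expect_equal(priorityScore(pan, 1450, 1550, comp, f0 = 0.05), 0L)
  expect_equal(priorityScore(pan, 10, 60, comp), 0L)   # spans no SNP
})

test_that("multi-SNP enumeration counts common haplotypes", {
  # two sites, all four haplotypes at frequency 1/4
  hap <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  pan <- makePanel(hap, positions = c(100L, 150L))
  comp <- AncestryComposition(c(P = 1))
  expect_equal(priorityScore(pan, 50, 200, comp, f0 = 0.05), 4L)
  # enumeration cap is an error, not a truncation
  many <- makePanel(matrix(0L, nrow = 4, ncol = 20),
                    positions = seq(10L, 200L, by = 10L))
  expect_error(priorityScore(many, 0, 250, comp, cap = 16L), "cap")
})

test_that("score ignores observed alleles, decreases in f0, and is 0/2 for one SNP", {
  set.seed(21)
  pan <- syntheticPanel(nHaplotypes = 100, nSites = 40, chromLength = 4000)
  comp <- AncestryComposition(c(POP1 = 1))
  pos <- panelPositions(pan)
  reads <- data.frame(read_id = sprintf("r%02d", 1:15),
                      start = sample(0:3900, 15), end = 0L)
  reads$end <- reads$start + 75L
  sr <- SampleReads("s", "chrS", 1L, reads,
                    data.frame(read_id = character(), pos = integer(),
                               allele = integer()))
  scored <- scoreReads(sr, pan, comp, f0 = 0.05)
  # flipping observed alleles cannot matter: the score never reads them
  for (i in seq_len(nrow(reads))) {
    s <- priorityScore(pan, reads$start[i], reads$end[i], comp, f0 = 0.05)
    expect_identical(readTable(scored)$score[readTable(scored)$read_id ==
                                               reads$read_id[i]], s)
    sBig <- priorityScore(pan, reads$start[i], reads$end[i], comp, f0 = 0.2)
    expect_lte(sBig, s)
    nSnp <- sum(pos > reads$start[i] & pos <= reads$end[i])
    if (nSnp == 1L) expect_true(s %in% c(0L, 2L))
  }
})

test_that("selectInformative filters by threshold preserving order", {
  reads <- data.frame(read_id = c("a", "b", "c"), start = c(0, 100, 200),
                      end = c(75, 175, 275), score = c(0L, 2L, 4L))
  obs <- data.frame(read_id = c("b", "c"), pos = c(150L, 250L),
                    allele = c(0L, 1L))
  sr <- SampleReads("s", "c1", 2L, reads, obs)
  expect_equal(nrow(readTable(selectInformative(sr, 0L))), 3L)
  kept <- selectInformative(sr, 2L)
  expect_equal(readTable(kept)$read_id, c("b", "c"))
  expect_equal(nrow(readTable(selectInformative(sr, 5L))), 0L)
  unscored <- SampleReads("s", "c1", 2L,
                          transform(reads, score = NA_integer_), obs)
  expect_error(selectInformative(unscored), "unscored")
})

test_that("BAM extraction reduces alignments to panel-site alleles", {
  hap <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  pan <- makePanel(hap, positions = c(105L, 125L), chrom = "chrT")
  # panel ref allele is A, alt is G at both sites
  sam <- c("@HD\tVN:1.6\tSO:coordinate",
           "@SQ\tSN:chrT\tLN:1000",
           # spans both sites; G at 105, A at 125
           paste("r1", 0, "chrT", 101, 60, "30M", "*", 0, 0,
                 paste0(strrep("C", 4), "G", strrep("C", 19), "A",
                        strrep("C", 5)),
                 strrep("I", 30), sep = "\t"),
           # T at site 105: matches neither allele -> dropped, read kept
           paste("r2", 0, "chrT", 101, 60, "10M", "*", 0, 0,
                 paste0(strrep("C", 4), "T", strrep("C", 5)),
                 strrep("I", 10), sep = "\t"),
           # duplicate flag (1024): excluded entirely
           paste("r3", 1024, "chrT", 101, 60, "10M", "*", 0, 0,
                 paste0(strrep("C", 4), "A", strrep("C", 5)),
                 strrep("I", 10), sep = "\t"),
           # low base quality at the site: observation dropped
           paste("r4", 0, "chrT", 121, 60, "10M", "*", 0, 0,
                 paste0(strrep("C", 4), "G", strrep("C", 5)),
                 paste0(strrep("I", 4), "#", strrep("I", 5)), sep = "\t"))
  samFile <- tempfile(fileext = ".sam")
  writeLines(sam, samFile)
  bam <- Rsamtools::asBam(samFile, tempfile(), overwrite = TRUE,
                          indexDestination = TRUE)
  sr <- extractObservations(bam, pan, "emb1", ploidy = 2L)
  tab <- readTable(sr)
  expect_setequal(tab$read_id, c("r1", "r2", "r4"))
  o <- obsTable(sr)
  expect_equal(o$pos[o$read_id == "r1"], c(105L, 125L))
  expect_equal(o$allele[o$read_id == "r1"], c(1L, 0L))
  expect_equal(sum(o$read_id == "r2"), 0L)   # mismatching base dropped
  expect_equal(sum(o$read_id == "r4"), 0L)   # low-quality base dropped
  # chromosome mismatch is an error
  panBad <- makePanel(hap, positions = c(105L, 125L), chrom = "chrZ")
  expect_error(extractObservations(bam, panBad, "emb1"), "chrZ")
})

test_that("paired-end mates merge into one molecule", {
  hap <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  pan <- makePanel(hap, positions = c(105L, 305L), chrom = "chrT")
  sam <- c("@HD\tVN:1.6\tSO:coordinate",
           "@SQ\tSN:chrT\tLN:1000",
           paste("p1", 99, "chrT", 101, 60, "10M", "=", 301, 210,
                 paste0(strrep("C", 4), "G", strrep("C", 5)),
                 strrep("I", 10), sep = "\t"),
           paste("p1", 147, "chrT", 301, 60, "10M", "=", 101, -210,
                 paste0(strrep("C", 4), "A", strrep("C", 5)),
                 strrep("I", 10), sep = "\t"))
  samFile <- tempfile(fileext = ".sam")
  writeLines(sam, samFile)
  bam <- Rsamtools::asBam(samFile, tempfile(), overwrite = TRUE,
                          indexDestination = TRUE)
  sr <- extractObservations(bam, pan, "emb2", ploidy = 2L)
  tab <- readTable(sr)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$start, 100L)
  expect_equal(tab$end, 310L)
  o <- obsTable(sr)
  expect_equal(o$pos, c(105L, 305L))
  expect_equal(o$allele, c(1L, 0L))
})
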