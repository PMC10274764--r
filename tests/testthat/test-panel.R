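# Reference-panel loading and exact frequency queries.

toyVcf <- system.file("extdata", "toy_panel.vcf", package = "meioscan")
toyPops <- system.file("extdata", "toy_populations.tsv", package = "meioscan")

test_that("a phased diploid VCF yields two haplotype rows per sample", {
  pan <- loadPanelVcf(toyVcf, chrom = "chr1", populations = toyPops)
  expect_equal(nHaplotypes(pan), 6L)
  expect_equal(nSites(pan), 10L)
  expect_equal(panelChrom(pan), "chr1")
  expect_equal(sort(unique(panelPopulations(pan))), c("EAS", "EUR"))
  expect_true(all(diff(panelPositions(pan)) > 0))
  # spot-check the phased alleles at the first site: S1=0|1, S2=1|1, S3=0|0
  expect_equal(unname(haplotypeMatrix(pan)[, 1]), c(0L, 1L, 1L, 1L, 0L, 0L))
})

test_that("interval loading is 1-based and inclusive at both endpoints", {
  pan <- loadPanelVcf(toyVcf, chrom = "chr1", start = 2000, end = 9000)
  expect_equal(range(panelPositions(pan)), c(2000L, 9000L))
  expect_equal(nSites(pan), 6L)
  expect_error(loadPanelVcf(toyVcf, chrom = "chr1", start = 90000, end = 95000),
               "no sites")
})

test_that("non-biallelic and unphased records are handled per contract", {
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chr9,length=50000>",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "Sa", "Sb", sep = "\t"))
  row <- function(pos, ref, alt, g1, g2) {
    paste("chr9", pos, ".", ref, alt, ".", "PASS", ".", "GT", g1, g2,
          sep = "\t")
  }
  tmp <- tempfile(fileext = ".vcf")
  writeLines(c(hdr, row(100, "A", "G", "0|1", "1|1"),
               row(200, "C", "T,G", "0|1", "0|2"),   # triallelic: excluded
               row(300, "G", "A", "0|0", "1|0")), tmp)
  expect_message(pan <- loadPanelVcf(tmp, chrom = "chr9"), "excluded 1")
  expect_equal(panelPositions(pan), c(100L, 300L))

  tmp2 <- tempfile(fileext = ".vcf")
  writeLines(c(hdr, row(100, "A", "G", "0|1", "1|1"),
               row(300, "G", "A", "0/1", "1|0")), tmp2)
  expect_error(loadPanelVcf(tmp2, chrom = "chr9"), "unphased")
})

test_that("panel cache round-trips losslessly", {
  pan <- loadPanelVcf(toyVcf, chrom = "chr1", populations = toyPops)
  f <- tempfile()
  writePanelCache(pan, f)
  pan2 <- readPanelCache(f)
  expect_equal(panelPositions(pan2), panelPositions(pan))
  expect_equal(haplotypeMatrix(pan2), haplotypeMatrix(pan))
  expect_equal(panelPopulations(pan2), panelPopulations(pan))
  expect_equal(panelAlleles(pan2), panelAlleles(pan))
})

test_that("joint frequencies are exact haplotype counts", {
  hap <- rbind(c(0, 0), c(0, 0), c(0, 1), c(1, 1), c(1, 1), c(1, 0))
  pan <- makePanel(hap)
  # empty conjunction
  expect_identical(jointFrequency(pan, "P", obs1(integer(), integer())), 1)
  # single allele carried by 3 of 6 rows
  expect_equal(jointFrequency(pan, "P", obs1(100, 0)), 0.5)
  # perfect LD: joint equals the single-allele frequency
  hapLD <- rbind(c(0, 0), c(0, 0), c(1, 1), c(1, 1))
  panLD <- makePanel(hapLD)
  expect_equal(jointFrequency(panLD, "P", obs1(c(100, 200), c(1, 1))),
               jointFrequency(panLD, "P", obs1(100, 1)))
  expect_error(jointFrequency(pan, "Q", obs1(100, 0)), "population")
  expect_error(jointFrequency(pan, "P", obs1(999, 0)), "not in panel")
})

test_that("joint frequency is non-increasing under conjunction and alleles sum to 1", {
  set.seed(42)
  pan <- syntheticPanel(nHaplotypes = 60, nSites = 30, chromLength = 3e4)
  pos <- panelPositions(pan)
  for (rep in 1:20) {
    idx <- sort(sample.int(30, 3))
    alleles <- sample(0:1, 3, replace = TRUE)
    f1 <- jointFrequency(pan, "POP1", obs1(pos[idx[1]], alleles[1]))
    f2 <- jointFrequency(pan, "POP1", obs1(pos[idx[1:2]], alleles[1:2]))
    f3 <- jointFrequency(pan, "POP1", obs1(pos[idx], alleles))
    expect_true(f1 >= f2 && f2 >= f3)
  }
  for (i in sample.int(30, 5)) {
    expect_equal(jointFrequency(pan, "POP1", obs1(pos[i], 0)) +
                   jointFrequency(pan, "POP1", obs1(pos[i], 1)), 1)
  }
})

test_that("effective frequency is the ancestry-weighted mixture", {
  hap <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1),   # pop1: f(alt@100) = 0.5
               c(1, 1), c(0, 0), c(0, 0), c(0, 0),
               c(0, 0), c(0, 0), c(0, 1), c(0, 1),
               c(0, 0), c(0, 1))                     # pop2: f(alt@100) = 0.1
  pops <- rep(c("pop1", "pop2"), c(4, 10))
  pan <- makePanel(hap, pops)
  comp <- AncestryComposition(c(pop1 = 0.3, pop2 = 0.7))
  expect_equal(effectiveFrequency(pan, comp, obs1(100, 1)),
               0.3 * 0.5 + 0.7 * 0.1)
  one <- AncestryComposition(c(pop1 = 1))
  expect_equal(effectiveFrequency(pan, one, obs1(100, 1)),
               jointFrequency(pan, "pop1", obs1(100, 1)))
  expect_error(AncestryComposition(c(pop1 = 0.5, pop2 = 0.6)), "sum to 1")
})

test_that("synthetic and oracle joint frequencies agree on random queries", {
  set.seed(7)
  pan <- syntheticPanel(nHaplotypes = 40, nSites = 25, chromLength = 2.5e4,
                        populations = c(A = 20, B = 20))
  pos <- panelPositions(pan)
  for (rep in 1:15) {
    idx <- sort(sample.int(25, sample.int(3, 1)))
    o <- obs1(pos[idx], sample(0:1, length(idx), replace = TRUE))
    p <- sample(c("A", "B"), 1)
    expect_equal(jointFrequency(pan, p, o), oracleJointFrequency(pan, p, o))
  }
})
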