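test_that("read lengths reproduce the 408 +/- 48 bp profile", {
  set.seed(1)
  x <- sampleReadLengths(1e5, simConfig())
  expect_true(abs(mean(x) - 408) < 1.0)
  expect_true(abs(sd(x) - 48) < 1.0)
  expect_true(all(x >= 50))

  set.seed(1)
  expect_true(all(sampleReadLengths(100, simConfig(readLenSd = 0)) == 408L))
  expect_length(sampleReadLengths(0), 0L)
})

test_that("exon depth follows the GC-dropout Poisson model", {
  set.seed(2)
  d <- sampleExonDepth(1e4, 0.4, simConfig())
  expect_true(abs(mean(d) - 17) < 0.5)

  expect_true(all(sampleExonDepth(100, 0.9,
                                  simConfig(gcDropoutFactor = 0)) == 0L))

  set.seed(3)
  d2 <- sampleExonDepth(1e4, 0.75, simConfig(gcDropoutFactor = 0.2))
  expect_true(abs(mean(d2) - 3.4) < 0.3)
})

test_that("variant read fractions match zygosity expectations", {
  set.seed(4)
  het <- sampleVariantReads(rep(47L, 1e5), "het", simConfig())
  expect_true(abs(mean(het$variant_reads / het$total_reads) - 0.5) < 0.01)

  z <- sampleVariantReads(0L, "het")
  expect_equal(z$variant_reads, 0L)
  expect_equal(z$total_reads, 0L)

  set.seed(5)
  hom <- sampleVariantReads(rep(30L, 1e5), "hom", simConfig())
  expect_true(abs(mean(hom$variant_reads / hom$total_reads) - 0.99) < 0.005)
})

test_that("a trio cohort carries a het truth variant only in its carriers", {
  g <- tiled_gene(n_exons = 3, exon_len = 120, first_start = 301)
  ref <- random_reference(1200, seed = 11)
  targets <- buildTargets(list(TOY = g), flankBp = 20, promoterBp = 100)
  pos <- 360L
  refb <- as.character(Biostrings::subseq(ref[["chr1"]], pos, pos))
  altb <- setdiff(c("A", "C", "G", "T"), refb)[1L]
  tv <- truthVariant("chr1", pos, refb, altb, kind = "SNV",
                     zygosity = "het", carriers = c("child", "mother"))
  sim <- simulateCohort(targets, list(TOY = g), ref,
                        truthSet(list(tv),
                                 samples = c("child", "mother", "father")),
                        quiet_config(seed = 3))
  child <- sim$child$variants
  expect_equal(nrow(child), 1L)
  expect_equal(child$start, pos)
  expect_gte(child$total_reads, 10L)
  expect_true(child$fraction >= 0.2 && child$fraction <= 0.8)
  expect_equal(nrow(sim$mother$variants), 1L)
  expect_equal(nrow(sim$father$variants), 0L)
})

test_that("multi-exon deletion carriers are zero only across deleted exons", {
  g <- tiled_gene(n_exons = 50)
  ref <- random_reference(max(IRanges::end(geneExons(g))) + 200, seed = 12)
  targets <- buildTargets(list(g), flankBp = 10, promoterBp = 100)
  del <- truthVariant(kind = "multi_exon_deletion", gene = "TOY",
                      exonFirst = 45, exonLast = 47, carriers = "P9")
  sim <- simulateCohort(targets, list(TOY = g), ref,
                        truthSet(list(del), samples = "P9"),
                        quiet_config(seed = 9))
  s <- summarizeExons(sim$P9$coverage, list(TOY = g))
  expect_equal(s$exon_index[s$zero_covered], 45:47)
  # non-deleted exons essentially never all-zero at 17-fold
  expect_true(all(s$mean_depth[!s$zero_covered] > 5))
})

test_that("with error rates zero the variant table equals the carried truth", {
  g <- tiled_gene(n_exons = 4, exon_len = 100, first_start = 401)
  ref <- random_reference(1400, seed = 13)
  targets <- buildTargets(list(g), flankBp = 10, promoterBp = 50)
  mkvar <- function(pos, zyg, carriers) {
    rb <- as.character(Biostrings::subseq(ref[["chr1"]], pos, pos))
    truthVariant("chr1", pos, rb, setdiff(c("A", "C", "G", "T"), rb)[1L],
                 kind = "SNV", zygosity = zyg, carriers = carriers)
  }
  truth <- truthSet(list(mkvar(430L, "hom", "S1"), mkvar(550L, "het", "S1"),
                         mkvar(700L, "hom", "S2")),
                    samples = c("S1", "S2"))
  sim <- simulateCohort(targets, list(TOY = g), ref, truth,
                        quiet_config(seed = 21))
  expect_equal(sort(sim$S1$variants$start), c(430L, 550L))
  expect_equal(sim$S2$variants$start, 700L)

  empty <- simulateCohort(targets, list(TOY = g), ref,
                          truthSet(samples = "S1"), quiet_config(seed = 2))
  expect_equal(nrow(empty$S1$variants), 0L)
})

test_that("coverage files enumerate exactly the panel bases", {
  g <- tiled_gene(n_exons = 5, exon_len = 80, first_start = 301)
  ref <- random_reference(1200, seed = 14)
  targets <- buildTargets(list(g), flankBp = 15, promoterBp = 60)
  sim <- simulateCohort(targets, list(TOY = g), ref,
                        truthSet(samples = c("A", "B")),
                        quiet_config(seed = 5))
  panel_bp <- sum(GenomicRanges::width(targets))
  for (s in sim) {
    expect_equal(nrow(s$coverage), panel_bp)
    expect_false(any(duplicated(paste(s$coverage$contig,
                                      s$coverage$position))))
  }
})

test_that("truth variants outside the panel are rejected", {
  g <- tiled_gene(n_exons = 2, exon_len = 50, first_start = 501)
  ref <- random_reference(1000, seed = 15)
  targets <- buildTargets(list(g), flankBp = 5, promoterBp = 20)
  tv <- truthVariant("chr1", 10L, "A", "C", kind = "SNV",
                     zygosity = "het", carriers = "S1")
  expect_error(
    simulateCohort(targets, list(TOY = g), ref,
                   truthSet(list(tv), samples = "S1"), quiet_config()),
    "outside the panel")
  expect_error(truthSet(list(tv), samples = "S2"), "not in cohort")
})

test_that("homopolymer indel error rate grows with run length", {
  # one target that is a pure 8-base run plus mixed sequence
  chr <- paste0(strrep("T", 50), "AAAAAAAA", strrep("ACGT", 40),
                strrep("T", 50))
  ref <- Biostrings::DNAStringSet(c(chr1 = chr))
  g <- geneModel("TOY", "chr1", "+", IRanges::IRanges(51, 218))
  targets <- buildTargets(list(g), flankBp = 0, promoterBp = 0)
  cfg <- simConfig(seed = 1, subErrorRate = 0, homopolymerIndelSlope = 0.07)
  hits <- 0L
  for (i in 1:40) {
    sim <- simulateCohort(targets, list(TOY = g), ref,
                          truthSet(samples = "S1"),
                          simConfig(seed = i, subErrorRate = 0,
                                    homopolymerIndelSlope = 0.07))
    v <- sim$S1$variants
    hits <- hits + sum(v$start == 51L)  # the 8-run start
    # every emitted row is an indel at a run of length >= 2
    if (nrow(v) > 0) expect_true(all(v$ref_allele == "-" | v$alt_allele == "-"))
  }
  # run of 8: p = min(0.5, 0.07 * 7) = 0.49; expect roughly 40 * 0.49 hits
  expect_gt(hits, 8)
  expect_lt(hits, 33)
})

test_that("variant and coverage dialects round-trip through files", {
  df <- data.frame(contig = "chr1", start = c(5L, 9L), end = c(5L, 9L),
                   ref_allele = c("A", "-"), alt_allele = c("G", "T"),
                   total_reads = c(20L, 30L), variant_reads = c(10L, 3L))
  tf <- withr::local_tempfile(fileext = ".txt")
  writeHCDiffs(df, tf)
  expect_true(startsWith(readLines(tf, n = 1L), ">"))
  back <- readHCDiffs(tf)
  expect_equal(back$start, df$start)
  expect_equal(back$variant_pct, c(50.0, 10.0))
  expect_equal(back$fraction, c(0.5, 0.1))

  cov <- data.frame(contig = "chr1", position = 1:5, ref_base = "A",
                    avg_quality = 28L, unique_depth = c(0L, 3L, 5L, 2L, 9L))
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  writeAlignmentInfo(cov, tf2)
  back2 <- readAlignmentInfo(tf2)
  expect_equal(back2$unique_depth, cov$unique_depth)
  # unique depth must sit in column 5, quality in column 4
  hdr <- strsplit(readLines(tf2, n = 1L), "\t")[[1L]]
  expect_equal(hdr[4:5], c("avg_quality", "unique_depth"))
})
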