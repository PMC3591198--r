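test_that("single-base coding changes are classified and named correctly", {
  cg <- coding_gene("ATGGAGGATTAA")
  # codon 2 GAG -> TAG: nonsense, named with X
  res <- classifyConsequence(list(contig = "chr1", position = 64,
                                  ref = "G", alt = "T"), cg$gene, cg$ref)
  expect_equal(res$effect, "nonsense")
  expect_equal(res$protein_change, "p.TOY-E2X")

  # TAA -> TAG: stop to stop, synonymous
  res2 <- classifyConsequence(list(contig = "chr1", position = 72,
                                   ref = "A", alt = "G"), cg$gene, cg$ref)
  expect_equal(res2$effect, "synonymous")

  # GAT -> GTT: missense with a Grantham score
  res3 <- classifyConsequence(list(contig = "chr1", position = 68,
                                   ref = "A", alt = "T"), cg$gene, cg$ref)
  expect_equal(res3$effect, "missense")
  expect_equal(res3$protein_change, "p.TOY-D3V")
  expect_equal(res3$grantham, granthamScore("D", "V"))

  # reference mismatch is reported with the position
  expect_error(classifyConsequence(list(contig = "chr1", position = 64,
                                        ref = "A", alt = "T"),
                                   cg$gene, cg$ref),
               "reference mismatch at chr1:64")
})

test_that("consequences match the exhaustive codon-table oracle", {
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1L,
                  paste, collapse = "")
  n_checked <- 0L
  for (codon in codons) {
    cg <- coding_gene(paste0("ATG", codon, "TAA"))
    for (k in 1:3) for (alt in setdiff(bases, substr(codon, k, k))) {
      mut <- codon
      substr(mut, k, k) <- alt
      res <- classifyConsequence(
        list(contig = "chr1", position = 63L + k,
             ref = substr(codon, k, k), alt = alt), cg$gene, cg$ref)
      expect_equal(res$effect, oracle_effect(codon, mut),
                   label = paste(codon, "->", mut))
      n_checked <- n_checked + 1L
    }
  }
  expect_equal(n_checked, 576L)
})

test_that("minus-strand classification equals the plus-strand mirror", {
  # same CDS read off the minus strand: reverse-complement the contig
  cds <- "ATGGAGGATCGCTAA"
  plus <- coding_gene(cds)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(paste0(strrep("T", 60), cds, strrep("T", 60)))))
  minus_ref <- Biostrings::DNAStringSet(c(chr1 = rc))
  iv <- IRanges::IRanges(61, 60 + nchar(cds))
  minus <- geneModel("TOY", "chr1", "-", iv, cds = iv)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  L <- nchar(rc)
  for (off in c(4L, 8L, 11L)) {  # CDS positions to probe
    pos_plus <- 60L + off
    base_plus <- substr(cds, off, off)
    alt_plus <- setdiff(c("A", "C", "G", "T"), base_plus)[1L]
    res_p <- classifyConsequence(list(contig = "chr1", position = pos_plus,
                                      ref = base_plus, alt = alt_plus),
                                 plus$gene, plus$ref)
    pos_minus <- L - pos_plus + 1L
    res_m <- classifyConsequence(list(contig = "chr1", position = pos_minus,
                                      ref = comp[[base_plus]],
                                      alt = comp[[alt_plus]]),
                                 minus, minus_ref)
    expect_equal(res_m, res_p)
  }
})

test_that("in-frame and frameshift indels are classified and named", {
  # CDS: M F S A stop ; duplicate the 6 bp coding F2 and S3
  cg <- coding_gene("ATGTTCTCAGCGTAA")
  dup <- classifyConsequence(
    list(contig = "chr1", position = 69, ref = "-", alt = "TTCTCA"),
    cg$gene, cg$ref)
  expect_equal(dup$effect, "inframe_indel")
  expect_equal(dup$protein_change, "p.TOY-F2_S3dup")

  del <- classifyConsequence(
    list(contig = "chr1", position = 64, ref = "TTC", alt = "-"),
    cg$gene, cg$ref)
  expect_equal(del$effect, "inframe_indel")
  expect_equal(del$protein_change, "p.TOY-F2del")

  fs <- classifyConsequence(
    list(contig = "chr1", position = 64, ref = "T", alt = "-"),
    cg$gene, cg$ref)
  expect_equal(fs$effect, "frameshift")
  expect_match(fs$protein_change, "fs$")

  ins <- classifyConsequence(
    list(contig = "chr1", position = 69, ref = "-", alt = "GGGCCCAAA"),
    cg$gene, cg$ref)
  expect_equal(ins$effect, "inframe_indel")
  expect_match(ins$protein_change, "_ins9bp$")
})

test_that("non-coding regions are labelled and never given an effect", {
  cds <- "ATGGAGGATTAA"
  chr <- paste0(strrep("C", 2000), "GATTC", cds, "AGGTA", strrep("C", 200))
  ref <- Biostrings::DNAStringSet(c(chr1 = chr))
  ex <- IRanges::IRanges(2001, 2000 + 10 + nchar(cds))
  g <- geneModel("TOY", "chr1", "+", ex,
                 cds = IRanges::IRanges(2006, 2005 + nchar(cds)),
                 utr5 = IRanges::IRanges(2001, 2005),
                 utr3 = IRanges::IRanges(2006 + nchar(cds), 2010 + nchar(cds)))
  cc <- function(pos) classifyConsequence(
    list(contig = "chr1", position = pos,
         ref = as.character(Biostrings::subseq(ref[["chr1"]], pos, pos)),
         alt = "N" ), g, ref)
  # N is not a real alt; use a differing base instead
  cc <- function(pos) {
    rb <- as.character(Biostrings::subseq(ref[["chr1"]], pos, pos))
    classifyConsequence(list(contig = "chr1", position = pos, ref = rb,
                             alt = setdiff(c("A", "C", "G", "T"), rb)[1L]),
                        g, ref)
  }
  expect_equal(cc(2003)$region, "utr5")
  expect_equal(cc(2008 + nchar(cds))$region, "utr3")
  expect_equal(cc(1500)$region, "promoter")
  expect_equal(cc(900)$region, "intronic_flank")
  for (r in c(2003, 1500, 900))
    expect_equal(cc(r)$effect, "none")
})

test_that("known-SNP membership is an exact allele match", {
  catalog <- data.frame(contig = "chr1", position = c(100L, 200L),
                        ref = c("A", "G"), alt = c("T", "C"),
                        id = c("rs1", "rs2"))
  v <- data.frame(contig = "chr1", start = c(100L, 100L, 200L),
                  ref_allele = c("A", "A", "G"),
                  alt_allele = c("T", "C", "C"))
  expect_equal(isKnownSnp(v, catalog), c(TRUE, FALSE, TRUE))

  set.seed(5)
  rand_key <- function(n) data.frame(
    contig = "chr1", position = sample.int(500, n, replace = TRUE),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = sample(c("A", "C", "G", "T"), n, replace = TRUE))
  cat2 <- rand_key(300); cat2$id <- paste0("rs", seq_len(300))
  v2 <- rand_key(1000)
  names(v2)[2:4] <- c("start", "ref_allele", "alt_allele")
  got <- isKnownSnp(v2, cat2)
  exp <- mapply(function(p, r, a) any(cat2$position == p & cat2$ref == r &
                                        cat2$alt == a),
                v2$start, v2$ref_allele, v2$alt_allele)
  expect_equal(got, unname(exp))
})

test_that("repeat flags agree with a brute-force homopolymer scan", {
  v1 <- data.frame(contig = "chr1", start = 4L, ref_allele = "A",
                   alt_allele = "-")
  ref1 <- Biostrings::DNAStringSet(c(chr1 = "GGAAAAAAAGG"))
  expect_true(repeatFlag(v1, ref1))
  ref2 <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGTACG"))
  v2 <- data.frame(contig = "chr1", start = 4L, ref_allele = "T",
                   alt_allele = "C")
  expect_false(repeatFlag(v2, ref2))

  ref3 <- random_reference(10000, seed = 9)
  s <- as.character(ref3[["chr1"]])
  expected <- oracle_repeat_positions(s, 6L)
  pos <- seq(5L, 9995L, by = 7L)
  v3 <- data.frame(contig = "chr1", start = pos,
                   ref_allele = substring(s, pos, pos),
                   alt_allele = "-")
  expect_equal(repeatFlag(v3, ref3, maxRun = 6), expected[pos])
})

test_that("the Grantham table is symmetric with its canonical extremes", {
  expect_equal(granthamScore("C", "W"), 215)
  expect_equal(granthamScore("L", "I"), 5)
  expect_equal(granthamScore("R", "C"), granthamScore("C", "R"))
  aa <- c("S", "R", "L", "P", "T", "A", "V", "G", "I", "F",
          "Y", "C", "H", "Q", "N", "K", "D", "E", "M", "W")
  m <- outer(aa, aa, granthamScore)
  expect_true(isSymmetric(m))
  expect_true(is.na(granthamScore("*", "A")))
})

test_that("protein changes parse back to (ref, pos, alt) for point effects", {
  cg <- coding_gene("ATGGAGGATCGCTGCTAA")
  set.seed(31)
  for (i in 1:20) {
    off <- sample(4:15, 1L)
    pos <- 60L + off
    rb <- as.character(Biostrings::subseq(cg$ref[["chr1"]], pos, pos))
    alt <- sample(setdiff(c("A", "C", "G", "T"), rb), 1L)
    res <- classifyConsequence(list(contig = "chr1", position = pos,
                                    ref = rb, alt = alt), cg$gene, cg$ref)
    if (res$effect %in% c("missense", "nonsense")) {
      m <- regmatches(res$protein_change,
                      regexec("^p\\.TOY-([A-Z])(\\d+)([A-Z])$",
                              res$protein_change))[[1L]]
      expect_length(m, 4L)
      expect_equal(as.integer(m[3L]), (off - 1L) %/% 3L + 1L)
    }
  }
})

test_that("annotateVariants assembles the triage inputs", {
  cg <- coding_gene("ATGGAGGATTAA")
  v <- data.frame(contig = "chr1", start = c(64L, 30L),
                  ref_allele = c("G", "T"), alt_allele = c("T", "G"),
                  total_reads = c(40L, 40L), variant_reads = c(20L, 4L))
  catalog <- data.frame(contig = "chr1", position = 30L, ref = "T",
                        alt = "G", id = "rs9")
  ann <- annotateVariants(v, list(TOY = cg$gene), cg$ref, catalog)
  expect_equal(ann$gene_symbol, c("TOY", "TOY"))
  expect_equal(ann$effect[1L], "nonsense")
  expect_equal(ann$score[1L], 255)
  expect_equal(ann$known_snp, c(FALSE, TRUE))
  expect_equal(ann$region[2L], "promoter")
})
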