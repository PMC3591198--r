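# shared builders for toy panels, references and cohorts

random_reference <- function(len, contig = "chr1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
             collapse = "")
  Biostrings::DNAStringSet(stats::setNames(s, contig))
}

# a gene of n_exons exons of exon_len bp separated by intron_len bp
tiled_gene <- function(symbol = "TOY", contig = "chr1", strand = "+",
                       n_exons = 50, exon_len = 100, intron_len = 20,
                       first_start = 201) {
  starts <- first_start + (seq_len(n_exons) - 1L) * (exon_len + intron_len)
  geneModel(symbol, contig, strand,
            IRanges::IRanges(starts, starts + exon_len - 1L))
}

# a simple coding gene: CDS given explicitly, embedded in T-padding
coding_gene <- function(cds_seq, symbol = "TOY", strand = "+", pad = 60) {
  chr <- paste0(strrep("T", pad), cds_seq, strrep("T", pad))
  ref <- Biostrings::DNAStringSet(c(chr1 = chr))
  iv <- IRanges::IRanges(pad + 1L, pad + nchar(cds_seq))
  list(gene = geneModel(symbol, "chr1", strand, iv, cds = iv), ref = ref)
}

# error-free simulator configuration used by deterministic tests
quiet_config <- function(seed = 1L, ...) {
  simConfig(seed = seed, subErrorRate = 0, homopolymerIndelSlope = 0, ...)
}

# simulate one cohort with a single implanted multi-exon deletion and
# summarize coverage per sample; returns summaries + the implanted span
deletion_cohort <- function(seed, n_samples = 10, n_exons = 50,
                            exon_len = 100) {
  set.seed(seed)
  g <- tiled_gene(n_exons = n_exons, exon_len = exon_len)
  span_total <- max(IRanges::end(geneExons(g))) + 200L
  ref <- random_reference(span_total, seed = seed + 500000L)
  targets <- buildTargets(list(g), flankBp = 10, promoterBp = 100)
  samples <- sprintf("S%02d", seq_len(n_samples))
  carrier <- sample(samples, 1L)
  n_del <- sample(2:5, 1L)
  first <- sample.int(n_exons - n_del + 1L, 1L)
  del <- truthVariant(kind = "multi_exon_deletion", gene = "TOY",
                      exonFirst = first, exonLast = first + n_del - 1L,
                      carriers = carrier)
  sim <- simulateCohort(targets, list(TOY = g), ref,
                        truthSet(list(del), samples = samples),
                        quiet_config(seed = seed))
  summaries <- lapply(sim, function(s) summarizeExons(s$coverage,
                                                      list(TOY = g)))
  list(summaries = summaries, carrier = carrier, first = first,
       last = first + n_del - 1L, samples = samples)
}
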