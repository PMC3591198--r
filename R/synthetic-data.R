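#' @importFrom stats rnorm rpois rnbinom rbinom runif median sd setNames
#' @importFrom Biostrings DNAStringSet subseq letterFrequency
NULL

#' Sample pyrosequencing read lengths
#'
#' Draws from Normal(\code{readLenMean}, \code{readLenSd}) truncated
#' below at \code{readLenMin} and rounded to integer bp, matching the
#' long-read profile of 454-style pyrosequencing (408 +/- 48 bp by
#' default).  Uses the current RNG state; seed with [set.seed()] or let
#' [simulateCohort()] manage substreams.
#'
#' @param n number of reads.
#' @param config a \linkS4class{SimulationConfig}.
#' @return integer vector of read lengths (bp).
#' @examples
#' set.seed(1); mean(sampleReadLengths(1e4, simConfig()))
#' @export
sampleReadLengths <- function(n, config = simConfig()) {
  stopifnot(n >= 0)
  if (n == 0L) return(integer())
  out <- rnorm(n, config@readLenMean, config@readLenSd)
  low <- out < config@readLenMin
  while (any(low)) {  # rejection step for the truncation at readLenMin
    out[low] <- rnorm(sum(low), config@readLenMean, config@readLenSd)
    low <- out < config@readLenMin
  }
  as.integer(round(out))
}

.target_lambda <- function(gcFraction, config) {
  stopifnot(all(gcFraction >= 0 & gcFraction <= 1))
  config@meanExonDepth *
    ifelse(gcFraction > config@gcDropoutThreshold, config@gcDropoutFactor, 1)
}

#' Sample per-base sequencing depth for a target
#'
#' Depth is Poisson with mean \code{meanExonDepth}, scaled down by
#' \code{gcDropoutFactor} when the target's GC fraction exceeds
#' \code{gcDropoutThreshold} (GC-rich targets capture poorly); with
#' \code{depthDispersion > 0} a negative-binomial with the same mean is
#' used instead.
#'
#' @param n number of draws.
#' @param gcFraction GC fraction of the target, in \code{[0, 1]}.
#' @param config a \linkS4class{SimulationConfig}.
#' @return integer vector of depths (fold).
#' @examples
#' set.seed(1); mean(sampleExonDepth(1e4, 0.4, simConfig()))
#' @export
sampleExonDepth <- function(n, gcFraction, config = simConfig()) {
  lambda <- .target_lambda(gcFraction, config)
  if (config@depthDispersion > 0)
    rnbinom(n, size = 1 / config@depthDispersion, mu = lambda)
  else
    rpois(n, lambda)
}

#' Sample variant-supporting read counts at a site
#'
#' Variant reads are Binomial(depth, p) with p the heterozygous allele
#' fraction (0.5) for \code{het} and the homozygous fraction (0.99) for
#' \code{hom} and \code{hemi} (a hemizygous X-linked male has a single
#' allele and behaves like a homozygote).
#'
#' @param depth integer vector of total read depths.
#' @param zygosity \code{"het"}, \code{"hom"} or \code{"hemi"} (recycled).
#' @param config a \linkS4class{SimulationConfig}.
#' @return data.frame with columns \code{variant_reads},
#'   \code{total_reads}.
#' @examples
#' set.seed(1); sampleVariantReads(c(47, 30), c("het", "hom"))
#' @export
sampleVariantReads <- function(depth, zygosity, config = simConfig()) {
  stopifnot(all(depth >= 0), all(zygosity %in% c("het", "hom", "hemi")))
  zygosity <- rep_len(zygosity, length(depth))
  p <- ifelse(zygosity == "het", config@hetAltFraction, config@homAltFraction)
  data.frame(variant_reads = rbinom(length(depth), depth, p),
             total_reads = as.integer(depth))
}

#' Define a truth variant for simulation
#'
#' Point variants (\code{SNV}, \code{insertion}, \code{deletion}) carry a
#' 1-based position and explicit alleles (\code{"-"} for the empty side
#' of an indel).  A \code{multi_exon_deletion} is defined by gene symbol
#' and an inclusive exon index span (transcription order, exon 1 being
#' 5'-most, as in [summarizeExons()]); its carriers receive zero depth
#' across the deleted exons and no variant-table row, so it is only
#' discoverable from coverage.
#'
#' @param contig,position,ref,alt point-variant description (1-based).
#' @param kind one of \code{SNV}, \code{insertion}, \code{deletion},
#'   \code{multi_exon_deletion}.
#' @param zygosity \code{het}, \code{hom} or \code{hemi}.
#' @param carriers character vector of carrier sample ids.
#' @param gene,exonFirst,exonLast multi-exon-deletion description.
#' @return a list of class \code{truth_variant}.
#' @export
truthVariant <- function(contig = NA_character_, position = NA_integer_,
                         ref = NA_character_, alt = NA_character_,
                         kind = c("SNV", "insertion", "deletion",
                                  "multi_exon_deletion"),
                         zygosity = c("het", "hom", "hemi"),
                         carriers = character(),
                         gene = NA_character_, exonFirst = NA_integer_,
                         exonLast = NA_integer_) {
  kind <- match.arg(kind)
  zygosity <- match.arg(zygosity)
  if (kind == "multi_exon_deletion") {
    stopifnot(!is.na(gene), !is.na(exonFirst), !is.na(exonLast),
              exonFirst <= exonLast)
  } else {
    stopifnot(!is.na(contig), !is.na(position), !is.na(ref), !is.na(alt))
  }
  structure(list(contig = contig, position = as.integer(position),
                 ref = ref, alt = alt, kind = kind, zygosity = zygosity,
                 carriers = as.character(carriers), gene = gene,
                 exonFirst = as.integer(exonFirst),
                 exonLast = as.integer(exonLast)),
            class = "truth_variant")
}

#' Bundle truth variants with a pedigree
#'
#' @param variants list of [truthVariant()] objects.
#' @param ped a \linkS4class{Pedigree} (defines the simulated samples),
#'   or \code{NULL} with explicit \code{samples}.
#' @param samples sample ids to simulate; defaults to pedigree members.
#' @return a list of class \code{truth_set}.
#' @export
truthSet <- function(variants = list(), ped = NULL, samples = NULL) {
  if (is.null(samples)) {
    if (is.null(ped)) stop("either a pedigree or explicit samples required")
    samples <- pedMembers(ped)$sample_id
  }
  for (v in variants) {
    bad <- setdiff(v$carriers, samples)
    if (length(bad))
      stop("carrier sample(s) not in cohort: ", paste(bad, collapse = ", "))
  }
  structure(list(variants = variants, pedigree = ped,
                 samples = as.character(samples)), class = "truth_set")
}

.as_dnastringset <- function(reference) {
  if (is(reference, "DNAStringSet")) return(reference)
  if (is.character(reference)) return(DNAStringSet(reference))
  stop("reference must be a DNAStringSet or named character vector")
}

.substream_seed <- function(seed, i) {
  as.integer((as.double(seed) * 1000003 + i * 7919) %% 2147483647)
}

# per-sample pileup over the panel: coverage rows + variant rows
.simulate_sample <- function(sample_id, targets, genes, ref, truth, config) {
  tg_contig <- as.character(seqnames(targets))
  tg_start <- GenomicRanges::start(targets)
  tg_end <- GenomicRanges::end(targets)
  tg_seq <- mapply(function(ct, s, e)
    as.character(subseq(ref[[ct]], s, e)), tg_contig, tg_start, tg_end)
  gc <- vapply(tg_seq, function(s) {
    b <- strsplit(s, "")[[1L]]
    mean(b %in% c("G", "C", "g", "c"))
  }, numeric(1L))
  lambda <- .target_lambda(gc, config)
  widths <- tg_end - tg_start + 1L

  position <- unlist(mapply(seq.int, tg_start, tg_end, SIMPLIFY = FALSE),
                     use.names = FALSE)
  contig <- rep(tg_contig, widths)
  ref_base <- unlist(strsplit(tg_seq, ""), use.names = FALSE)
  depth <- if (config@depthDispersion > 0)
    rnbinom(length(position), size = 1 / config@depthDispersion,
            mu = rep(lambda, widths))
  else rpois(length(position), rep(lambda, widths))

  # multi-exon deletion carriers: zero depth across the deleted exons
  for (v in truth$variants) {
    if (v$kind != "multi_exon_deletion" || !sample_id %in% v$carriers) next
    g <- genes[[v$gene]]
    if (is.null(g)) stop("deletion names unknown gene: ", v$gene)
    # exon indices are in transcription order (exon 1 = 5'-most)
    tx_order <- if (g@strand == "+") seq_along(g@exons)
                else rev(seq_along(g@exons))
    del <- g@exons[tx_order[v$exonFirst:v$exonLast]]
    hit <- contig == g@contig &
      position >= min(start(del)) & position <= max(end(del))
    # zero only exon bases, not intervening intron bases in the panel
    in_exon <- rep(FALSE, length(position))
    for (k in seq_along(del))
      in_exon <- in_exon | (position >= start(del)[k] &
                              position <= end(del)[k])
    depth[hit & in_exon] <- 0L
  }

  coverage <- data.frame(contig = contig, position = position,
                         ref_base = ref_base, avg_quality = 28L,
                         unique_depth = as.integer(depth),
                         stringsAsFactors = FALSE)
  key <- paste(contig, position)

  rows <- list()
  for (v in truth$variants) {
    if (v$kind == "multi_exon_deletion" || !sample_id %in% v$carriers) next
    i <- match(paste(v$contig, v$position), key)
    if (is.na(i))
      stop("truth variant at ", v$contig, ":", v$position,
           " lies outside the panel")
    d <- depth[i]
    vr <- sampleVariantReads(d, v$zygosity, config)$variant_reads
    if (vr >= 1L) {
      end_pos <- if (v$kind == "deletion")
        v$position + nchar(v$ref) - 1L else v$position
      rows[[length(rows) + 1L]] <- data.frame(
        contig = v$contig, start = v$position, end = end_pos,
        ref_allele = v$ref, alt_allele = v$alt,
        total_reads = as.integer(d), variant_reads = as.integer(vr),
        stringsAsFactors = FALSE)
    }
  }

  # spurious substitution rows at subErrorRate per covered base
  if (config@subErrorRate > 0) {
    idx <- which(runif(length(position)) < config@subErrorRate & depth > 0)
    if (length(idx)) {
      alts <- vapply(ref_base[idx], function(b)
        sample(setdiff(c("A", "C", "G", "T"), toupper(b)), 1L),
        character(1L))
      vr <- pmax(1L, rbinom(length(idx), depth[idx], 0.1))
      rows[[length(rows) + 1L]] <- data.frame(
        contig = contig[idx], start = position[idx], end = position[idx],
        ref_allele = toupper(ref_base[idx]), alt_allele = alts,
        total_reads = as.integer(depth[idx]), variant_reads = as.integer(vr),
        stringsAsFactors = FALSE)
    }
  }

  # homopolymer-associated indel rows: per single-base run of length L,
  # an error row with probability min(0.5, slope * (L - 1))
  if (config@homopolymerIndelSlope > 0) {
    for (t in seq_along(tg_seq)) {
      r <- rle(strsplit(toupper(tg_seq[[t]]), "")[[1L]])
      run_start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
      long <- which(r$lengths >= 2L)
      if (!length(long)) next
      p_err <- pmin(0.5, config@homopolymerIndelSlope *
                           (r$lengths[long] - 1L))
      hit <- long[runif(length(long)) < p_err]
      for (h in hit) {
        pos <- tg_start[t] + run_start[h] - 1L
        i <- match(paste(tg_contig[t], pos), key)
        d <- depth[i]
        if (is.na(d) || d == 0L) next
        base <- r$values[h]
        del <- runif(1L) < 0.5
        vr <- pmax(1L, rbinom(1L, d, 0.1))
        rows[[length(rows) + 1L]] <- data.frame(
          contig = tg_contig[t], start = pos, end = pos,
          ref_allele = if (del) base else "-",
          alt_allele = if (del) "-" else base,
          total_reads = as.integer(d), variant_reads = as.integer(vr),
          stringsAsFactors = FALSE)
      }
    }
  }

  variants <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(), start = integer(), end = integer(),
               ref_allele = character(), alt_allele = character(),
               total_reads = integer(), variant_reads = integer(),
               stringsAsFactors = FALSE)
  variants <- variants[order(variants$contig, variants$start), ,
                       drop = FALSE]
  rownames(variants) <- NULL
  variants$fraction <- ifelse(variants$total_reads > 0,
                              variants$variant_reads / variants$total_reads,
                              0)

  n_reads <- max(1L, round(sum(depth) / config@readLenMean))
  rl <- sampleReadLengths(n_reads, config)
  run <- list(total_seq_mb = sum(as.double(rl)) / 1e6,
              read_length_bp = mean(rl))

  list(variants = variants, coverage = coverage, run = run)
}

#' Simulate a sequencing cohort over a capture panel
#'
#' Pileup-level simulation of targeted pyrosequencing for every sample
#' named in the truth set: per-base unique depths over every panel base
#' (zero-depth rows included), variant-table rows for each carried truth
#' variant with binomially sampled supporting reads, spurious
#' substitution rows at the configured error rate, homopolymer-run indel
#' error rows, and zero coverage across multi-exon-deletion spans.  No
#' read alignment is performed; the simulator emulates the mapper's
#' per-base output directly.
#'
#' Randomness is fully reproducible: each sample uses a substream derived
#' from \code{config@seed} and the sample's index.
#'
#' @param targets merged capture targets ([buildTargets()]).
#' @param genes named list of \linkS4class{GeneModel} (names = symbols).
#' @param reference named \link[Biostrings]{DNAStringSet} (or named
#'   character vector) covering the panel contigs.
#' @param truth a [truthSet()].
#' @param config a \linkS4class{SimulationConfig}.
#' @param outDir optional directory; when given, per-sample
#'   \code{<id>_hcdiffs.txt} and \code{<id>_alignmentinfo.tsv} files are
#'   written in the two dialects.
#' @return named list (one element per sample) of lists with
#'   \code{variants} (variant table with \code{fraction}),
#'   \code{coverage} (per-base depth rows) and \code{run} (total
#'   megabases and mean read length of the simulated run).
#' @examples
#' g <- geneModel("TOY", "chr1", "+", IRanges::IRanges(201, 400))
#' ref <- Biostrings::DNAStringSet(c(chr1 = paste(
#'   rep("ACGT", 250), collapse = "")))
#' tg <- buildTargets(list(g), flankBp = 10, promoterBp = 50)
#' ts <- truthSet(samples = "S1")
#' sim <- simulateCohort(tg, list(TOY = g), ref, ts,
#'                       simConfig(seed = 1, subErrorRate = 0,
#'                                 homopolymerIndelSlope = 0))
#' head(sim$S1$coverage)
#' @export
simulateCohort <- function(targets, genes, reference, truth,
                           config = simConfig(), outDir = NULL) {
  ref <- .as_dnastringset(reference)
  if (!all(as.character(seqnames(targets)) %in% names(ref)))
    stop("reference does not cover all panel contigs")
  if (is.null(names(genes)))
    names(genes) <- vapply(genes, geneSymbol, character(1L))
  samples <- truth$samples
  out <- vector("list", length(samples))
  names(out) <- samples
  for (i in seq_along(samples)) {
    set.seed(.substream_seed(config@seed, i))
    out[[i]] <- .simulate_sample(samples[i], targets, genes, ref, truth,
                                 config)
  }
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    for (s in samples) {
      writeHCDiffs(out[[s]]$variants,
                   file.path(outDir, paste0(s, "_hcdiffs.txt")))
      writeAlignmentInfo(out[[s]]$coverage,
                         file.path(outDir, paste0(s, "_alignmentinfo.tsv")))
    }
  }
  out
}
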