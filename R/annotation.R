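#' @importFrom Biostrings GENETIC_CODE DNAString reverseComplement
NULL

# Grantham (1974) physicochemical distance between amino acids.
# Row/column order follows the original table.
.grantham_order <- c("S", "R", "L", "P", "T", "A", "V", "G", "I", "F",
                     "Y", "C", "H", "Q", "N", "K", "D", "E", "M", "W")
.grantham_upper <- c(
  110, 145,  74,  58,  99, 124,  56, 142, 155, 144, 112,  89,  68,  46, 121,  65,  80, 135, 177,
       102, 103,  71, 112,  96, 125,  97,  97,  77, 180,  29,  43,  86,  26,  96,  54,  91, 101,
             98,  92,  96,  32, 138,   5,  22,  36, 198,  99, 113, 153, 107, 172, 138,  15,  61,
                  38,  27,  68,  42,  95, 114, 110, 169,  77,  76,  91, 103, 108,  93,  87, 147,
                       58,  69,  59,  89, 103,  92, 149,  47,  42,  65,  78,  85,  65,  81, 128,
                            64,  60,  94, 113, 112, 195,  86,  91, 111, 106, 126, 107,  84, 148,
                                109,  29,  50,  55, 192,  84,  96, 133,  97, 152, 121,  21,  88,
                                     135, 153, 147, 159,  98,  87,  80, 127,  94,  98, 127, 184,
                                           21,  33, 198,  94, 109, 149, 102, 168, 134,  10,  61,
                                                22, 205, 100, 116, 158, 102, 177, 140,  28,  40,
                                                    194,  83,  99, 143,  85, 160, 122,  36,  37,
                                                         174, 154, 139, 202, 154, 170, 196, 215,
                                                               24,  68,  32,  81,  40,  87, 115,
                                                                    46,  53,  61,  29, 101, 130,
                                                                         94,  23,  42, 142, 174,
                                                                             101,  56,  95, 110,
                                                                                   45, 160, 181,
                                                                                       126, 152,
                                                                                             67)

.grantham_matrix <- local({
  n <- length(.grantham_order)
  m <- matrix(0, n, n, dimnames = list(.grantham_order, .grantham_order))
  k <- 1L
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    m[i, j] <- m[j, i] <- .grantham_upper[k]
    k <- k + 1L
  }
  m
})

#' Grantham distance between two amino acids
#'
#' Physicochemical distance (composition, polarity, molecular volume)
#' used as the default deleteriousness score for missense changes; the
#' scale runs from 5 (Leu/Ile) to 215 (Cys/Trp).
#'
#' @param refAa,altAa one-letter amino acid codes (vectors recycled).
#' @return numeric distances; \code{NA} for stops or identical residues
#'   outside the 20-residue table.
#' @examples
#' granthamScore("C", "W")  # 215
#' @export
granthamScore <- function(refAa, altAa) {
  refAa <- toupper(refAa); altAa <- toupper(altAa)
  ok <- refAa %in% .grantham_order & altAa %in% .grantham_order
  out <- rep(NA_real_, length(ok))
  out[ok] <- .grantham_matrix[cbind(refAa[ok], altAa[ok])]
  out
}

.aa_letter <- function(aa) ifelse(aa == "*", "X", aa)

.revcomp_chr <- function(s) {
  if (!nzchar(s)) return(s)
  as.character(reverseComplement(DNAString(s)))
}

.complement_base <- function(b)
  c(A = "T", C = "G", G = "C", T = "A")[[toupper(b)]]

.norm_allele <- function(a) {
  a <- toupper(a)
  if (a %in% c("-", ".", "")) "" else a
}

# CDS scaffolding: genomic positions in transcription order + tx-strand bases
.cds_layout <- function(gene, reference) {
  cds <- gene@cds
  pos <- unlist(mapply(seq.int, start(cds), end(cds), SIMPLIFY = FALSE),
                use.names = FALSE)
  seqs <- paste(vapply(seq_along(cds), function(i)
    as.character(subseq(reference[[gene@contig]], start(cds)[i],
                        end(cds)[i])), character(1L)), collapse = "")
  bases <- strsplit(toupper(seqs), "")[[1L]]
  if (gene@strand == "-") {
    pos <- rev(pos)
    bases <- rev(vapply(bases, .complement_base, character(1L),
                        USE.NAMES = FALSE))
  }
  list(pos = pos, bases = bases)
}

.translate_codon <- function(codon) {
  unname(GENETIC_CODE[paste(codon, collapse = "")])
}

.codon_of <- function(layout, cdsPos) {
  idx <- ((cdsPos - 1L) %/% 3L) * 3L + 1:3
  layout$bases[idx]
}

#' Classify the consequence of a variant on a gene
#'
#' Determines the gene region hit (coding, 5'/3'-UTR, promoter,
#' intronic/flank) and, for coding variants, the amino acid consequence:
#' the affected codon(s) are translated before and after the change with
#' the standard genetic code, strand-aware; indels are classified by
#' length mod 3 (frameshift vs in-frame).  Protein changes are named in
#' short panel style, \code{p.<GENE>-<ref><pos><alt>} with \code{X} for
#' a stop (e.g. \code{p.RP2-E20X}), \code{del}/\code{dup} suffixes for
#' single- or multi-codon in-frame losses and duplications, and
#' \code{_ins<n>bp} for other in-frame insertions.
#'
#' @param variant a list or one-row data.frame with \code{contig},
#'   \code{position} (1-based), \code{ref_allele}/\code{ref},
#'   \code{alt_allele}/\code{alt} (\code{"-"} for the empty indel side).
#' @param gene the \linkS4class{GeneModel} containing the variant.
#' @param reference named \link[Biostrings]{DNAStringSet}.
#' @param flankBp,promoterBp extents used to label non-exonic regions.
#' @return a list with \code{region}, \code{effect},
#'   \code{protein_change} and \code{grantham} (\code{NA} unless
#'   missense).  Effects: \code{synonymous}, \code{missense},
#'   \code{nonsense}, \code{stoploss}, \code{frameshift},
#'   \code{inframe_indel}, \code{none}.
#' @examples
#' ref <- Biostrings::DNAStringSet(c(chr1 = paste0(
#'   strrep("T", 100), "ATGGAGGATTAA", strrep("T", 100))))
#' g <- geneModel("TOY", "chr1", "+", IRanges::IRanges(101, 112),
#'                cds = IRanges::IRanges(101, 112))
#' classifyConsequence(list(contig = "chr1", position = 104,
#'                          ref = "G", alt = "T"), g, ref)
#' @export
classifyConsequence <- function(variant, gene, reference,
                                flankBp = 50, promoterBp = 1000) {
  reference <- .as_dnastringset(reference)
  v <- as.list(variant)
  ref_allele <- .norm_allele(v$ref_allele %||% v$ref)
  alt_allele <- .norm_allele(v$alt_allele %||% v$alt)
  if (ref_allele == alt_allele)
    stop("ref and alt alleles must differ")
  pos <- as.integer(v$position %||% v$start)
  contig <- as.character(v$contig)
  if (contig != gene@contig)
    stop("variant contig does not match gene contig")

  span_len <- max(nchar(ref_allele), 1L)
  span <- IRanges::IRanges(pos, pos + span_len - 1L)

  if (nchar(ref_allele) > 0L) {
    obs <- toupper(as.character(subseq(reference[[contig]], pos,
                                       pos + nchar(ref_allele) - 1L)))
    if (obs != ref_allele)
      stop("reference mismatch at ", contig, ":", pos, " (expected ",
           ref_allele, ", found ", obs, ")")
  }

  none <- function(region) list(region = region, effect = "none",
                                protein_change = "", grantham = NA_real_)

  exon_u <- reduce(gene@exons)
  ov_exon <- sum(width(IRanges::intersect(span, exon_u)))
  if (ov_exon > 0L && ov_exon < width(span))
    return(none("intronic_flank"))  # spans a splice boundary

  if (ov_exon == 0L) {
    first <- if (gene@strand == "+") start(exon_u)[1L]
             else end(exon_u)[length(exon_u)]
    upstream <- if (gene@strand == "+")
      pos < first && pos >= first - promoterBp
    else pos > first && pos <= first + promoterBp
    return(none(if (upstream) "promoter" else "intronic_flank"))
  }

  cds <- gene@cds
  in_cds <- length(cds) > 0L &&
    sum(width(IRanges::intersect(span, cds))) == width(span)
  if (!in_cds) {
    if (length(gene@utr5) &&
        sum(width(IRanges::intersect(span, gene@utr5))) > 0L)
      return(none("utr5"))
    if (length(gene@utr3) &&
        sum(width(IRanges::intersect(span, gene@utr3))) > 0L)
      return(none("utr3"))
    if (length(cds) == 0L) {
      # unannotated toy model: treat the whole exon as coding
      cds <- exon_u
      in_cds <- TRUE
    } else {
      # exonic but outside CDS: side relative to CDS decides the UTR
      five_prime <- if (gene@strand == "+") pos < min(start(cds))
                    else pos > max(end(cds))
      return(none(if (five_prime) "utr5" else "utr3"))
    }
  }

  layout <- .cds_layout(if (identical(cds, gene@cds)) gene else {
    g2 <- gene; g2@cds <- cds; g2
  }, reference)
  gsym <- gene@geneSymbol
  indel_len <- abs(nchar(ref_allele) - nchar(alt_allele))

  if (indel_len == 0L) {  # SNV
    cds_pos <- match(pos, layout$pos)
    alt_tx <- if (gene@strand == "-") .complement_base(alt_allele)
              else alt_allele
    ref_codon <- .codon_of(layout, cds_pos)
    within <- (cds_pos - 1L) %% 3L + 1L
    alt_codon <- ref_codon
    alt_codon[within] <- alt_tx
    ref_aa <- .translate_codon(ref_codon)
    alt_aa <- .translate_codon(alt_codon)
    codon_idx <- (cds_pos - 1L) %/% 3L + 1L
    effect <-
      if (ref_aa == alt_aa) "synonymous"
      else if (alt_aa == "*") "nonsense"
      else if (ref_aa == "*") "stoploss"
      else "missense"
    pc <- sprintf("p.%s-%s%d%s", gsym, .aa_letter(ref_aa), codon_idx,
                  .aa_letter(alt_aa))
    return(list(region = "coding", effect = effect, protein_change = pc,
                grantham = if (effect == "missense")
                  granthamScore(ref_aa, alt_aa) else NA_real_))
  }

  if (indel_len %% 3L != 0L) {  # frameshift
    cds_pos <- min(match(seq(pos, pos + span_len - 1L), layout$pos),
                   na.rm = TRUE)
    codon_idx <- (cds_pos - 1L) %/% 3L + 1L
    aa <- .translate_codon(.codon_of(layout, cds_pos))
    pc <- sprintf("p.%s-%s%dfs", gsym, .aa_letter(aa), codon_idx)
    return(list(region = "coding", effect = "frameshift",
                protein_change = pc, grantham = NA_real_))
  }

  # in-frame indel
  if (nchar(ref_allele) > nchar(alt_allele)) {  # deletion
    cds_idx <- match(seq(pos, pos + nchar(ref_allele) - 1L), layout$pos)
    codons <- sort(unique((cds_idx - 1L) %/% 3L + 1L))
    c1 <- codons[1L]; c2 <- codons[length(codons)]
    aa1 <- .aa_letter(.translate_codon(.codon_of(layout, (c1 - 1L) * 3L + 1L)))
    aa2 <- .aa_letter(.translate_codon(.codon_of(layout, (c2 - 1L) * 3L + 1L)))
    pc <- if (c1 == c2) sprintf("p.%s-%s%ddel", gsym, aa1, c1)
          else sprintf("p.%s-%s%d_%s%ddel", gsym, aa1, c1, aa2, c2)
  } else {  # insertion
    ins_tx <- if (gene@strand == "-") .revcomp_chr(alt_allele) else alt_allele
    anchor <- match(pos, layout$pos)
    len <- nchar(ins_tx)
    is_dup <- !is.na(anchor) && anchor >= len &&
      paste(layout$bases[(anchor - len + 1L):anchor], collapse = "") ==
        ins_tx
    if (is_dup) {
      c1 <- (anchor - len) %/% 3L + 1L
      c2 <- (anchor - 1L) %/% 3L + 1L
      aa1 <- .aa_letter(.translate_codon(.codon_of(layout,
                                                   (c1 - 1L) * 3L + 1L)))
      aa2 <- .aa_letter(.translate_codon(.codon_of(layout,
                                                   (c2 - 1L) * 3L + 1L)))
      pc <- if (c1 == c2) sprintf("p.%s-%s%ddup", gsym, aa1, c1)
            else sprintf("p.%s-%s%d_%s%ddup", gsym, aa1, c1, aa2, c2)
    } else {
      codon_idx <- (anchor - 1L) %/% 3L + 1L
      aa <- .aa_letter(.translate_codon(.codon_of(layout, anchor)))
      pc <- sprintf("p.%s-%s%d_ins%dbp", gsym, aa, codon_idx, len)
    }
  }
  list(region = "coding", effect = "inframe_indel", protein_change = pc,
       grantham = NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Exact known-SNP membership
#'
#' A variant is "known" only on an exact (contig, position, ref, alt)
#' match against the catalog; a different allele at a catalogued
#' position is still novel.
#'
#' @param variants data.frame with \code{contig}, \code{start} (or
#'   \code{position}), \code{ref_allele}/\code{ref},
#'   \code{alt_allele}/\code{alt}.
#' @param catalog data.frame from [readSnpCatalog()] (or with the same
#'   columns).
#' @return logical vector, one element per variant row.
#' @export
isKnownSnp <- function(variants, catalog) {
  if (is.null(catalog) || nrow(catalog) == 0L)
    return(rep(FALSE, nrow(variants)))
  vpos <- variants$start %||% variants$position
  vref <- variants$ref_allele %||% variants$ref
  valt <- variants$alt_allele %||% variants$alt
  key_v <- paste(variants$contig, vpos, toupper(vref), toupper(valt),
                 sep = "\r")
  key_c <- paste(catalog$contig, catalog$position, toupper(catalog$ref),
                 toupper(catalog$alt), sep = "\r")
  key_v %in% key_c
}

#' Flag variants in or adjoining long homopolymer runs
#'
#' Pyrosequencing is error-prone inside single-base runs; a variant is
#' flagged when it lies in, or immediately adjoins, a run of one base
#' of length >= \code{maxRun}.
#'
#' @param variants data.frame as in [isKnownSnp()].
#' @param reference named \link[Biostrings]{DNAStringSet}.
#' @param maxRun minimum run length to flag (bp).
#' @return logical vector, one element per variant row.
#' @export
repeatFlag <- function(variants, reference, maxRun = 6) {
  reference <- .as_dnastringset(reference)
  vpos <- as.integer(variants$start %||% variants$position)
  vref <- as.character(variants$ref_allele %||% variants$ref)
  vapply(seq_len(nrow(variants)), function(i) {
    contig <- as.character(variants$contig[i])
    L <- length(reference[[contig]])
    span_len <- max(nchar(.norm_allele(vref[i])), 1L)
    pos_end <- vpos[i] + span_len - 1L
    # window wide enough that any qualifying run touching the variant
    # vicinity shows >= maxRun of its bases
    w0 <- max(1L, vpos[i] - maxRun - 1L)
    w1 <- min(L, pos_end + maxRun + 1L)
    s <- strsplit(toupper(as.character(subseq(reference[[contig]], w0, w1))),
                  "")[[1L]]
    r <- rle(s)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    g_start <- w0 + run_start - 1L
    g_end <- w0 + run_end - 1L
    any(r$lengths >= maxRun &
          g_end >= vpos[i] - 1L & g_start <= pos_end + 1L)
  }, logical(1L))
}

.default_score <- function(effect, grantham) {
  ifelse(effect %in% c("nonsense", "frameshift", "stoploss"), 255,
  ifelse(effect == "missense", ifelse(is.na(grantham), 0, grantham),
  ifelse(effect == "inframe_indel", 100, 0)))
}

#' Annotate a variant table against gene models
#'
#' Assigns each variant its gene (by overlap with the gene's targeted
#' span), region and amino acid consequence
#' ([classifyConsequence()]), known-SNP membership ([isKnownSnp()]),
#' homopolymer-repeat context ([repeatFlag()]), a deleteriousness score,
#' and membership in an optional known-reported-mutation table.  The
#' scorer is pluggable: the default uses the Grantham distance for
#' missense changes and the maximal score for truncating ones.
#'
#' @param variants variant data.frame ([readHCDiffs()] shape).
#' @param genes named list of \linkS4class{GeneModel}.
#' @param reference named \link[Biostrings]{DNAStringSet}.
#' @param snpCatalog optional known-SNP catalog.
#' @param knownMutations optional data.frame of reported mutations with
#'   \code{contig}, \code{position}, \code{ref}, \code{alt}.
#' @param flankBp,promoterBp extents used for gene assignment and region
#'   labels.
#' @param scorer function(effect, grantham) -> numeric deleteriousness.
#' @return the input data.frame with appended columns
#'   \code{gene_symbol}, \code{region}, \code{effect},
#'   \code{protein_change}, \code{grantham}, \code{known_snp},
#'   \code{repeat_flag}, \code{score}, \code{known_reported}.
#' @export
annotateVariants <- function(variants, genes, reference, snpCatalog = NULL,
                             knownMutations = NULL, flankBp = 50,
                             promoterBp = 1000, scorer = .default_score) {
  reference <- .as_dnastringset(reference)
  if (is.null(names(genes)))
    names(genes) <- vapply(genes, geneSymbol, character(1L))
  n <- nrow(variants)
  gene_symbol <- rep(NA_character_, n)
  region <- rep("intronic_flank", n)
  effect <- rep("none", n)
  protein_change <- rep("", n)
  grantham <- rep(NA_real_, n)
  pad <- max(flankBp, promoterBp)
  spans <- lapply(genes, function(g) {
    ex <- reduce(g@exons)
    c(min(start(ex)) - pad, max(end(ex)) + pad)
  })
  vpos <- as.integer(variants$start %||% variants$position)
  for (i in seq_len(n)) {
    for (g in genes) {
      sp <- spans[[g@geneSymbol]]
      if (as.character(variants$contig[i]) == g@contig &&
          vpos[i] >= sp[1L] && vpos[i] <= sp[2L]) {
        cons <- classifyConsequence(variants[i, , drop = FALSE], g,
                                    reference, flankBp, promoterBp)
        gene_symbol[i] <- g@geneSymbol
        region[i] <- cons$region
        effect[i] <- cons$effect
        protein_change[i] <- cons$protein_change
        grantham[i] <- cons$grantham
        break
      }
    }
  }
  out <- variants
  out$gene_symbol <- gene_symbol
  out$region <- region
  out$effect <- effect
  out$protein_change <- protein_change
  out$grantham <- grantham
  out$known_snp <- isKnownSnp(variants, snpCatalog)
  out$repeat_flag <- if (n > 0L) repeatFlag(variants, reference)
                     else logical()
  out$score <- scorer(effect, grantham)
  out$known_reported <- if (is.null(knownMutations)) rep(FALSE, n)
    else isKnownSnp(variants, data.frame(
      contig = knownMutations$contig, position = knownMutations$position,
      ref = knownMutations$ref, alt = knownMutations$alt))
  out
}
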