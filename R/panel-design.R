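#' @importFrom GenomicRanges GRanges seqnames
#' @importFrom S4Vectors Rle
NULL

.collapse_labels <- function(x) paste(sort(unique(unlist(strsplit(
  x[nzchar(x)], ",", fixed = TRUE)))), collapse = ",")

#' Build capture targets from gene models
#'
#' Implements the panel design rules: every exon is extended by
#' \code{flankBp} on both sides (covering intron-exon boundaries; the
#' complete 3'-UTR sits inside the last exon, so it is covered and the
#' flank applies beyond it), and one promoter interval of
#' \code{promoterBp} is placed immediately 5' of the transcription-start
#' exon of each gene, strand-aware (lower coordinates on \code{+}, higher
#' on \code{-}), so that the proximal promoter and complete 5'-UTR are
#' captured.  Intervals extending below the first base are clipped with a
#' warning; when \code{contigLengths} is given, intervals are clipped at
#' the contig end.  The result is merged into a minimal disjoint sorted
#' cover per contig, with origin labels and gene symbols unioned on
#' merge (overlapping targets of different genes are merged).
#'
#' @param genes list of \linkS4class{GeneModel}.
#' @param flankBp flank added on both sides of each exon (bp).
#' @param promoterBp promoter extent placed 5' of the first exon (bp).
#' @param contigLengths optional named integer vector of contig lengths
#'   used for right-clipping.
#' @return a merged \link[GenomicRanges]{GRanges} with metadata columns
#'   \code{gene_symbol} and \code{origin} (comma-joined subsets of
#'   \code{exon_flank}, \code{promoter_5utr}, \code{utr3}).
#' @examples
#' g <- geneModel("TOY", "chr1", "+", IRanges::IRanges(1001, 1200))
#' buildTargets(list(g), contigLengths = c(chr1 = 5000))
#' @export
buildTargets <- function(genes, flankBp = 50, promoterBp = 1000,
                         contigLengths = NULL) {
  stopifnot(flankBp >= 0, promoterBp >= 0)
  pieces <- lapply(genes, function(g) {
    ex <- g@exons
    if (length(ex) == 0L) return(NULL)
    starts <- start(ex) - flankBp
    ends <- end(ex) + flankBp
    origin <- rep("exon_flank", length(ex))
    if (promoterBp > 0) {
      if (g@strand == "+") {
        p_end <- start(ex)[1L] - 1L
        p_start <- p_end - promoterBp + 1L
      } else {
        p_start <- end(ex)[length(ex)] + 1L
        p_end <- p_start + promoterBp - 1L
      }
      starts <- c(starts, p_start)
      ends <- c(ends, p_end)
      origin <- c(origin, "promoter_5utr")
    }
    if (length(g@utr3) > 0L) {
      starts <- c(starts, start(g@utr3))
      ends <- c(ends, end(g@utr3))
      origin <- c(origin, rep("utr3", length(g@utr3)))
    }
    if (any(starts < 1L)) {
      warning("targets of ", g@geneSymbol,
              " extend below the start of contig ", g@contig, "; clipped")
      starts <- pmax(starts, 1L)
    }
    if (!is.null(contigLengths) && g@contig %in% names(contigLengths)) {
      ends <- pmin(ends, contigLengths[[g@contig]])
    }
    keep <- starts <= ends
    GRanges(g@contig, IRanges::IRanges(starts[keep], ends[keep]),
            gene_symbol = g@geneSymbol, origin = origin[keep])
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1L))]
  if (length(pieces) == 0L)
    return(GRanges(gene_symbol = character(), origin = character()))
  mergeTargets(do.call(c, unname(pieces)))
}

#' Merge capture targets into a disjoint sorted cover
#'
#' Overlapping or bookended intervals on the same contig are merged;
#' gene symbols and origin labels are unioned (comma-joined) on merge.
#'
#' @param targets a \link[GenomicRanges]{GRanges} with metadata columns
#'   \code{gene_symbol} and \code{origin} (either may be absent).
#' @return merged \code{GRanges}, disjoint and sorted per contig.
#' @export
mergeTargets <- function(targets) {
  if (length(targets) == 0L) return(targets)
  mc <- mcols(targets)
  gene <- if ("gene_symbol" %in% names(mc)) as.character(mc$gene_symbol)
          else rep("", length(targets))
  orig <- if ("origin" %in% names(mc)) as.character(mc$origin)
          else rep("", length(targets))
  red <- reduce(GenomicRanges::sort(targets), with.revmap = TRUE,
                ignore.strand = TRUE)
  revmap <- mcols(red)$revmap
  srt <- GenomicRanges::sort(targets)
  mc2 <- mcols(srt)
  gene_s <- if ("gene_symbol" %in% names(mc2)) as.character(mc2$gene_symbol)
            else rep("", length(srt))
  orig_s <- if ("origin" %in% names(mc2)) as.character(mc2$origin)
            else rep("", length(srt))
  mcols(red) <- NULL
  mcols(red)$gene_symbol <- vapply(revmap, function(i)
    .collapse_labels(gene_s[i]), character(1L))
  mcols(red)$origin <- vapply(revmap, function(i)
    .collapse_labels(orig_s[i]), character(1L))
  red
}

#' Panel bookkeeping statistics
#'
#' Counts genes and exons and, when merged targets are supplied, the size
#' of the base-set union of all capture targets.  Promoter targets count
#' toward \code{totalTargetBp} but never toward \code{nExons}.
#'
#' \code{genes} may be a list of \linkS4class{GeneModel} objects (exons
#' are counted from the models) or a catalog \code{data.frame} with an
#' \code{n_exons} column, as returned by [panelGeneCatalog()].
#'
#' @param genes gene models or a panel gene catalog.
#' @param targets optional merged targets from [buildTargets()].
#' @return a \linkS4class{PanelStats}.
#' @examples
#' panelStats(panelGeneCatalog())
#' @export
panelStats <- function(genes, targets = NULL) {
  if (is.data.frame(genes)) {
    n_genes <- nrow(genes)
    n_exons <- sum(as.integer(genes$n_exons))
  } else {
    n_genes <- length(genes)
    n_exons <- sum(vapply(genes, function(g) length(g@exons), integer(1L)))
  }
  bp <- if (is.null(targets)) NA_integer_
        else as.integer(sum(width(reduce(targets, ignore.strand = TRUE))))
  new("PanelStats", nGenes = as.integer(n_genes),
      nExons = as.integer(n_exons), totalTargetBp = bp)
}

#' Write capture targets as 6-column BED
#'
#' Emits \code{chrom, start, end, name, score, strand} with 0-based
#' half-open coordinates; \code{name} is \code{gene|origin} and
#' \code{score} is 0.
#'
#' @param targets merged targets ([buildTargets()]).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTargetsBed <- function(targets, path) {
  df <- data.frame(
    chrom = as.character(seqnames(targets)),
    start = GenomicRanges::start(targets) - 1L,
    end = GenomicRanges::end(targets),
    name = paste(mcols(targets)$gene_symbol, mcols(targets)$origin,
                 sep = "|"),
    score = 0L, strand = ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read capture targets from 6-column BED
#'
#' @param path BED path written by [writeTargetsBed()].
#' @return a \link[GenomicRanges]{GRanges} with \code{gene_symbol} and
#'   \code{origin} metadata columns.
#' @export
readTargetsBed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  name <- strsplit(df$V4, "|", fixed = TRUE)
  GRanges(df$V1, IRanges::IRanges(df$V2 + 1L, df$V3),
          gene_symbol = vapply(name, `[`, character(1L), 1L),
          origin = vapply(name, function(x)
            if (length(x) > 1L) x[2L] else "", character(1L)))
}
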