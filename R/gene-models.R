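#' Read gene models from a feature TSV
#'
#' The expected dialect has one row per feature interval with columns
#' \code{gene_symbol}, \code{contig}, \code{strand}, \code{start},
#' \code{end}, \code{feature} (one of \code{exon}, \code{CDS},
#' \code{5UTR}, \code{3UTR}) and \code{inheritance} (comma-separated
#' subset of AD/AR/XL, may be empty).  Coordinates in the file are
#' 0-based half-open (BED convention) and are converted to the package's
#' internal 1-based closed intervals here, at the I/O boundary.
#'
#' Records with an unknown strand are rejected with a warning.  Rows for
#' the same gene are pooled; exons from alternative transcripts are
#' unioned.
#'
#' @param path path to the TSV file.
#' @return a named list of \linkS4class{GeneModel} objects.
#' @seealso [geneModel()], [buildTargets()]
#' @export
readGeneModels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("gene_symbol", "contig", "strand", "start", "end", "feature")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("gene model file lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  bad <- !df$strand %in% c("+", "-")
  if (any(bad)) {
    warning(sum(bad), " record(s) with unknown strand rejected")
    df <- df[!bad, , drop = FALSE]
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(df$start >= df$end))
    stop("gene model intervals must satisfy start < end (0-based half-open)")
  out <- lapply(split(df, df$gene_symbol), function(g) {
    pick <- function(feat) {
      rows <- g[g$feature == feat, , drop = FALSE]
      if (nrow(rows) == 0L) return(IRanges::IRanges())
      # 0-based half-open -> 1-based closed, then union across transcripts
      reduce(IRanges::IRanges(rows$start + 1L, rows$end))
    }
    inh <- character()
    if ("inheritance" %in% names(g)) {
      inh <- unique(unlist(strsplit(g$inheritance, "[,;]\\s*")))
      inh <- inh[nzchar(inh)]
    }
    geneModel(g$gene_symbol[1L], g$contig[1L], g$strand[1L],
              exons = pick("exon"), cds = pick("CDS"),
              utr5 = pick("5UTR"), utr3 = pick("3UTR"),
              inheritance = inh)
  })
  out[order(names(out))]
}

#' Write gene models to the feature TSV dialect
#'
#' Inverse of [readGeneModels()]; intervals are emitted 0-based
#' half-open.
#'
#' @param genes list of \linkS4class{GeneModel}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGeneModels <- function(genes, path) {
  rows <- lapply(genes, function(g) {
    feat <- function(ir, label) {
      if (length(ir) == 0L) return(NULL)
      data.frame(gene_symbol = g@geneSymbol, contig = g@contig,
                 strand = g@strand, start = start(ir) - 1L, end = end(ir),
                 feature = label,
                 inheritance = paste(g@inheritance, collapse = ","),
                 stringsAsFactors = FALSE)
    }
    do.call(rbind, c(list(feat(g@exons, "exon")),
                     list(feat(g@cds, "CDS")),
                     list(feat(g@utr5, "5UTR")),
                     list(feat(g@utr3, "3UTR"))))
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
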