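#' Read and write the tab-delimited variant-table dialect
#'
#' The "HCDiffs" dialect is the high-confidence difference table emitted
#' by the 454 reference mapper: a header line starting with \code{">"},
#' then tab-separated columns \code{contig}, \code{start} (1-based),
#' \code{end} (1-based), \code{ref_allele}, \code{alt_allele},
#' \code{total_reads}, \code{variant_reads}, \code{variant_pct} (one
#' decimal).  Deleted/inserted alleles use \code{"-"} for the empty side.
#'
#' @param variants data.frame with the columns above (except
#'   \code{variant_pct}, recomputed on write).
#' @param path file path.
#' @return \code{readHCDiffs}: a data.frame with the dialect columns plus
#'   a derived \code{fraction} column; \code{writeHCDiffs}: \code{path},
#'   invisibly.
#' @export
writeHCDiffs <- function(variants, path) {
  v <- variants
  v$variant_pct <- sprintf("%.1f", ifelse(v$total_reads > 0,
                                          100 * v$variant_reads / v$total_reads, 0))
  cols <- c("contig", "start", "end", "ref_allele", "alt_allele",
            "total_reads", "variant_reads", "variant_pct")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", paste(cols, collapse = "\t")), con)
  if (nrow(v) > 0)
    utils::write.table(v[, cols], con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeHCDiffs
#' @export
readHCDiffs <- function(path) {
  lines <- readLines(path)
  header <- sub("^>", "", lines[1L])
  cols <- strsplit(header, "\t", fixed = TRUE)[[1L]]
  body <- lines[-1L]
  if (length(body) == 0L) {
    df <- as.data.frame(setNames(rep(list(character()), length(cols)), cols))
  } else {
    df <- utils::read.delim(text = body, header = FALSE,
                            col.names = cols, stringsAsFactors = FALSE)
  }
  for (nm in c("start", "end", "total_reads", "variant_reads"))
    df[[nm]] <- as.integer(df[[nm]])
  df$variant_pct <- as.numeric(df$variant_pct)
  df$fraction <- ifelse(df$total_reads > 0,
                        df$variant_reads / df$total_reads, 0)
  df
}

#' Read and write the per-base coverage dialect
#'
#' The "AlignmentInfo" dialect carries one row per targeted base:
#' tab-separated columns \code{contig}, \code{position} (1-based),
#' \code{ref_base}, \code{avg_quality} (column 4), \code{unique_depth}
#' (column 5).  The column positions of quality and unique depth are
#' fixed; downstream coverage analysis reads unique depth from column 5.
#'
#' @param coverage data.frame with the columns above.
#' @param path file path.
#' @return \code{readAlignmentInfo}: a data.frame with the dialect
#'   columns; \code{writeAlignmentInfo}: \code{path}, invisibly.
#' @export
writeAlignmentInfo <- function(coverage, path) {
  cols <- c("contig", "position", "ref_base", "avg_quality", "unique_depth")
  utils::write.table(coverage[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname writeAlignmentInfo
#' @export
readAlignmentInfo <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$position <- as.integer(df$position)
  df$unique_depth <- as.integer(df$unique_depth)
  df
}

#' Read a known-SNP catalog
#'
#' TSV with columns \code{contig}, \code{position} (1-based),
#' \code{ref}, \code{alt}, \code{id} — the shape of a dbSNP-style
#' single-nucleotide polymorphism dump restricted to the panel.
#'
#' @param path TSV path.
#' @return a data.frame with those columns.
#' @seealso [isKnownSnp()]
#' @export
readSnpCatalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig", "position", "ref", "alt", "id")
  if (!all(need %in% names(df)))
    stop("SNP catalog must have columns ", paste(need, collapse = ", "))
  df$position <- as.integer(df$position)
  df
}

#' Read a PED-like pedigree file with genotype columns
#'
#' Six leading columns \code{family}, \code{sample}, \code{father},
#' \code{mother}, \code{sex} (1 = male, 2 = female), \code{affected}
#' (2 = affected, 1 = unaffected); any further columns are per-variant
#' genotype calls in \code{ref/het/hom/hemi/missing}.
#'
#' @param path TSV path.
#' @return a \linkS4class{Pedigree}.
#' @export
readPedigree <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 6L)
    stop("pedigree file must have at least 6 columns")
  members <- data.frame(
    sample_id = df[[2L]], father_id = df[[3L]], mother_id = df[[4L]],
    sex = ifelse(df[[5L]] %in% c("1", "M"), "M", "F"),
    affected = df[[6L]] %in% c("2", "TRUE"),
    stringsAsFactors = FALSE)
  geno <- df[, -(1:6), drop = FALSE]
  rownames(geno) <- members$sample_id
  pedigree(members, geno)
}
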