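.depth_lookup <- function(coverage) {
  setNames(coverage$unique_depth, paste(coverage$contig, coverage$position))
}

#' Per-exon coverage summaries
#'
#' Computes mean and median unique depth over the bases of every exon of
#' every gene (the +/-50 bp capture flanks are excluded, so "exon
#' coverage" means the exon itself), and flags exons in which every base
#' has zero depth.  Panel bases missing from the coverage table are
#' treated as depth 0 with a warning.
#'
#' @param coverage per-base coverage data.frame
#'   ([readAlignmentInfo()] shape: \code{contig}, \code{position},
#'   \code{unique_depth}).
#' @param genes named list of \linkS4class{GeneModel}.
#' @return data.frame with columns \code{gene_symbol},
#'   \code{exon_index}, \code{n_bp}, \code{mean_depth},
#'   \code{median_depth}, \code{zero_covered}.  Exons are indexed in
#'   transcription order (exon 1 is 5'-most).
#' @export
summarizeExons <- function(coverage, genes) {
  lookup <- .depth_lookup(coverage)
  missing_any <- FALSE
  rows <- lapply(genes, function(g) {
    ex <- g@exons
    idx_order <- if (g@strand == "+") seq_along(ex) else rev(seq_along(ex))
    out <- lapply(seq_along(ex), function(k) {
      i <- idx_order[k]
      pos <- seq.int(start(ex)[i], end(ex)[i])
      d <- lookup[paste(g@contig, pos)]
      if (anyNA(d)) {
        missing_any <<- TRUE
        d[is.na(d)] <- 0L
      }
      data.frame(gene_symbol = g@geneSymbol, exon_index = k,
                 n_bp = length(pos), mean_depth = mean(d),
                 median_depth = median(d), zero_covered = all(d == 0L),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
  if (missing_any)
    warning("panel bases missing from coverage treated as depth 0")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cumulative coverage curve over targeted bases
#'
#' For every integer fold x from 0 to the maximum observed depth (plus
#' one), the percentage of targeted bases with depth >= x.  Only rows at
#' targeted positions contribute; coverage of off-target reference used
#' for alignment is dropped when a panel is supplied.
#'
#' @param coverage per-base coverage data.frame.
#' @param targets optional merged panel \link[GenomicRanges]{GRanges};
#'   rows outside it are removed before the curve is computed.
#' @return data.frame with columns \code{fold} and \code{pct_bp}; the
#'   curve starts at 100 for fold 0, is non-increasing, and reaches 0
#'   one fold beyond the maximum depth.
#' @export
cumulativeCurve <- function(coverage, targets = NULL) {
  d <- .restrict_to_targets(coverage, targets)$unique_depth
  if (length(d) == 0L)
    return(data.frame(fold = integer(), pct_bp = numeric()))
  folds <- 0L:(max(d) + 1L)
  # tabulate once; survival = reverse cumulative sum
  counts <- tabulate(d + 1L, nbins = max(d) + 1L)
  surv <- rev(cumsum(rev(counts)))
  pct <- 100 * c(surv, 0L) / length(d)
  data.frame(fold = folds, pct_bp = pct)
}

.restrict_to_targets <- function(coverage, targets) {
  if (is.null(targets)) return(coverage)
  gr <- GRanges(coverage$contig,
                IRanges::IRanges(coverage$position, coverage$position))
  hits <- GenomicRanges::findOverlaps(gr, targets)
  coverage[unique(S4Vectors::queryHits(hits)), , drop = FALSE]
}

#' Median unique depth over targeted bases for one patient
#'
#' @param coverage per-base coverage data.frame.
#' @param targets optional merged panel; rows outside it are dropped.
#' @return the median fold coverage.
#' @export
patientMedianDepth <- function(coverage, targets = NULL) {
  median(.restrict_to_targets(coverage, targets)$unique_depth)
}

#' Classify zero-coverage exons: deletion candidates vs technical failures
#'
#' An exon with zero coverage in one patient can mean either a capture
#' failure of the assay or a genomic deletion in that patient.  The two
#' are separated by the rest of the cohort: an exon zero-covered in the
#' focal sample is a deletion-candidate exon when at least
#' \code{minSupport} of the other samples cover it at median depth >=
#' \code{minCohortDepth} (the panel works there, so absence is
#' patient-specific); exons zero-covered in every sample are reported as
#' technical failures of the panel.  Maximal runs of consecutive
#' candidate exons within one gene are merged into a single
#' multi-exon deletion candidate.
#'
#' @param summaries named list of per-sample exon summary data.frames
#'   from [summarizeExons()] (identical exon ordering).
#' @param sampleId the focal sample (a name of \code{summaries}).
#' @param minSupport minimum fraction of other samples covering the
#'   exon.
#' @param minCohortDepth minimum median depth for an "other sample" to
#'   count as covering.
#' @return list with \code{candidates} (data.frame: \code{sample_id},
#'   \code{gene_symbol}, \code{exon_first}, \code{exon_last},
#'   \code{n_exons}, \code{cohort_support}) and
#'   \code{technical_failures} (data.frame: \code{gene_symbol},
#'   \code{exon_index}).
#' @export
detectDeletions <- function(summaries, sampleId, minSupport = 0.8,
                            minCohortDepth = 5) {
  if (length(summaries) < 2L)
    stop("deletion classification needs a cohort of at least 2 samples")
  if (!sampleId %in% names(summaries))
    stop("unknown focal sample: ", sampleId)
  focal <- summaries[[sampleId]]
  others <- summaries[names(summaries) != sampleId]
  n_exons <- nrow(focal)
  med <- vapply(others, function(s) s$median_depth, numeric(n_exons))
  zero <- vapply(summaries, function(s) s$zero_covered, logical(n_exons))
  support <- rowMeans(med >= minCohortDepth)
  tech <- rowSums(!zero) == 0L  # zero-covered in every sample
  cand <- focal$zero_covered & !tech & support >= minSupport

  tech_df <- focal[tech, c("gene_symbol", "exon_index"), drop = FALSE]
  rownames(tech_df) <- NULL

  cand_rows <- list()
  if (any(cand)) {
    for (g in unique(focal$gene_symbol[cand])) {
      sel <- which(cand & focal$gene_symbol == g)
      idx <- focal$exon_index[sel]
      o <- order(idx)
      idx <- idx[o]; sel <- sel[o]
      run_id <- cumsum(c(1L, diff(idx) != 1L))
      for (r in split(seq_along(idx), run_id)) {
        cand_rows[[length(cand_rows) + 1L]] <- data.frame(
          sample_id = sampleId, gene_symbol = g,
          exon_first = idx[r[1L]], exon_last = idx[r[length(r)]],
          n_exons = length(r),
          cohort_support = min(support[sel[r]]),
          stringsAsFactors = FALSE)
      }
    }
  }
  candidates <- if (length(cand_rows)) do.call(rbind, cand_rows) else
    data.frame(sample_id = character(), gene_symbol = character(),
               exon_first = integer(), exon_last = integer(),
               n_exons = integer(), cohort_support = numeric(),
               stringsAsFactors = FALSE)
  list(candidates = candidates, technical_failures = tech_df)
}
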