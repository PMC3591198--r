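#' @import methods
#' @importFrom IRanges IRanges start end width reduce
#' @importFrom S4Vectors mcols mcols<-
NULL

#' GeneModel: a single gene with its exon structure
#'
#' Container for one gene on one reference contig: ordered exon intervals,
#' the coding sequence (CDS) sub-intervals, untranslated regions, and the
#' inheritance modes reported for the gene (autosomal dominant \code{AD},
#' autosomal recessive \code{AR}, X-linked \code{XL}).  All intervals are
#' 1-based closed \link[IRanges]{IRanges} in contig coordinates; files using
#' 0-based half-open (BED-style) coordinates are converted on read/write.
#'
#' Where a gene has several transcripts, a model may carry the union of
#' their exons; capture targets are built from that union.
#'
#' @slot geneSymbol character(1), HGNC-style symbol.
#' @slot contig character(1), reference contig name.
#' @slot strand \code{"+"} or \code{"-"}.
#' @slot exons \code{IRanges} of exon intervals, sorted and disjoint.
#' @slot cds \code{IRanges} of coding intervals, each inside an exon; total
#'   width must be a multiple of 3 when non-empty.
#' @slot utr5,utr3 \code{IRanges} of untranslated intervals inside exons.
#' @slot inheritance character vector, subset of \code{c("AD","AR","XL")}.
#'
#' @seealso [geneModel()], [readGeneModels()], [buildTargets()]
#' @export
setClass("GeneModel",
  representation(
    geneSymbol  = "character",
    contig      = "character",
    strand      = "character",
    exons       = "IRanges",
    cds         = "IRanges",
    utr5        = "IRanges",
    utr3        = "IRanges",
    inheritance = "character"
  )
)

.within_union <- function(q, s) {
  # every base of q covered by the union of s
  if (length(q) == 0L) return(TRUE)
  gaps <- IRanges::setdiff(q, s)
  length(gaps) == 0L
}

setValidity("GeneModel", function(object) {
  msg <- character()
  if (length(object@geneSymbol) != 1L || !nzchar(object@geneSymbol))
    msg <- c(msg, "geneSymbol must be a single non-empty string")
  if (length(object@strand) != 1L || !object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be '+' or '-'")
  ex <- object@exons
  if (length(ex) > 1L) {
    if (is.unsorted(start(ex)))
      msg <- c(msg, "exons must be sorted by start")
    if (any(start(ex)[-1L] <= end(ex)[-length(ex)]))
      msg <- c(msg, "exons must be non-overlapping")
  }
  if (!.within_union(object@cds, ex))
    msg <- c(msg, "cds intervals must lie within the exon union")
  if (!.within_union(object@utr5, ex))
    msg <- c(msg, "utr5 intervals must lie within the exon union")
  if (!.within_union(object@utr3, ex))
    msg <- c(msg, "utr3 intervals must lie within the exon union")
  if (length(object@cds) > 0L && sum(width(object@cds)) %% 3L != 0L)
    msg <- c(msg, "total CDS length must be divisible by 3")
  bad <- setdiff(object@inheritance, c("AD", "AR", "XL"))
  if (length(bad) > 0L)
    msg <- c(msg, paste0("unknown inheritance mode(s): ",
                         paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a GeneModel
#'
#' @param geneSymbol gene symbol.
#' @param contig contig name.
#' @param strand \code{"+"} or \code{"-"}.
#' @param exons exon intervals (\code{IRanges}, 1-based closed).
#' @param cds,utr5,utr3 optional sub-intervals.
#' @param inheritance character vector of inheritance modes.
#' @return a validated \linkS4class{GeneModel}.
#' @examples
#' geneModel("TOY", "chr1", "+", IRanges::IRanges(1001, 1200))
#' @export
geneModel <- function(geneSymbol, contig, strand, exons,
                      cds = IRanges::IRanges(), utr5 = IRanges::IRanges(),
                      utr3 = IRanges::IRanges(),
                      inheritance = character()) {
  new("GeneModel", geneSymbol = as.character(geneSymbol),
      contig = as.character(contig), strand = as.character(strand),
      exons = exons, cds = cds, utr5 = utr5, utr3 = utr3,
      inheritance = inheritance)
}

setMethod("show", "GeneModel", function(object) {
  cat("GeneModel", object@geneSymbol, "on", object@contig,
      paste0("(", object@strand, ")"), "\n")
  cat("  ", length(object@exons), "exon(s),",
      sum(width(object@exons)), "bp;",
      length(object@cds), "CDS interval(s),",
      sum(width(object@cds)), "bp\n")
  if (length(object@inheritance))
    cat("  inheritance:", paste(object@inheritance, collapse = ", "), "\n")
  invisible(NULL)
})

#' @rdname GeneModel-accessors
#' @param x a \linkS4class{GeneModel}.
#' @export
geneSymbol <- function(x) x@geneSymbol

#' Accessors for GeneModel slots
#'
#' @name GeneModel-accessors
#' @param x a \linkS4class{GeneModel}.
#' @return the corresponding slot value.
#' @export
geneExons <- function(x) x@exons

#' @rdname GeneModel-accessors
#' @export
geneCds <- function(x) x@cds

#' @rdname GeneModel-accessors
#' @export
geneStrand <- function(x) x@strand

#' @rdname GeneModel-accessors
#' @export
geneInheritance <- function(x) x@inheritance

#' PanelStats: bookkeeping totals for a capture panel
#'
#' @slot nGenes number of genes on the panel.
#' @slot nExons total number of exons across genes (promoter targets are
#'   not counted as exons).
#' @slot totalTargetBp size of the base-set union of all merged capture
#'   targets, in bp; \code{NA} when targets were not supplied.
#' @export
setClass("PanelStats",
  representation(nGenes = "integer", nExons = "integer",
                 totalTargetBp = "integer"))

setMethod("show", "PanelStats", function(object) {
  cat("Capture panel:", object@nGenes, "genes,", object@nExons, "exons,",
      if (is.na(object@totalTargetBp)) "target size not computed"
      else paste(object@totalTargetBp, "targeted bp"), "\n")
  invisible(NULL)
})

#' @rdname PanelStats-accessors
#' @param x a \linkS4class{PanelStats}.
#' @export
nGenes <- function(x) x@nGenes

#' Accessors for PanelStats
#' @name PanelStats-accessors
#' @param x a \linkS4class{PanelStats}.
#' @return the corresponding count.
#' @export
nExons <- function(x) x@nExons

#' @rdname PanelStats-accessors
#' @export
totalTargetBp <- function(x) x@totalTargetBp

#' SimulationConfig: parameters of the pyrosequencing panel simulator
#'
#' Defaults reproduce the run characteristics of a 454 GS Junior benchtop
#' sequencer on a capture panel: read lengths 408 +/- 48 bp, a median
#' exon depth of 17-fold, near-complete dropout of very GC-rich targets,
#' homopolymer-associated indel errors, and allele read fractions of ~50%
#' for heterozygous and ~99% for homozygous calls.
#'
#' @slot seed integer master seed; per-sample substreams are derived from
#'   it by sample index.
#' @slot readLenMean,readLenSd,readLenMin read-length distribution (bp):
#'   Normal, truncated below at \code{readLenMin}, rounded to integers.
#' @slot meanExonDepth expected per-base depth (fold) for a well-captured
#'   exon.
#' @slot depthDispersion non-negative; 0 gives Poisson depths, values > 0
#'   give negative-binomial depths with size \code{1/depthDispersion}.
#' @slot gcDropoutThreshold,gcDropoutFactor targets with GC fraction above
#'   the threshold have their expected depth multiplied by the factor.
#' @slot subErrorRate per-base probability of a spurious substitution row.
#' @slot homopolymerIndelSlope per-run indel error probability increment:
#'   a run of length L yields an error row with probability
#'   \code{min(0.5, slope * (L - 1))}.
#' @slot homAltFraction,hetAltFraction expected variant-read fraction for
#'   homozygous/hemizygous and heterozygous genotypes.
#' @seealso [simConfig()], [simulateCohort()]
#' @export
setClass("SimulationConfig",
  representation(
    seed = "integer",
    readLenMean = "numeric", readLenSd = "numeric", readLenMin = "numeric",
    meanExonDepth = "numeric", depthDispersion = "numeric",
    gcDropoutThreshold = "numeric", gcDropoutFactor = "numeric",
    subErrorRate = "numeric", homopolymerIndelSlope = "numeric",
    homAltFraction = "numeric", hetAltFraction = "numeric"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  probs <- c(gcDropoutThreshold = object@gcDropoutThreshold,
             gcDropoutFactor = object@gcDropoutFactor,
             subErrorRate = object@subErrorRate,
             homAltFraction = object@homAltFraction,
             hetAltFraction = object@hetAltFraction)
  bad <- probs < 0 | probs > 1
  if (any(bad))
    msg <- c(msg, paste0("must lie in [0,1]: ",
                         paste(names(probs)[bad], collapse = ", ")))
  if (object@readLenMin > object@readLenMean)
    msg <- c(msg, "readLenMin must not exceed readLenMean")
  if (object@readLenSd < 0) msg <- c(msg, "readLenSd must be >= 0")
  if (object@meanExonDepth < 0) msg <- c(msg, "meanExonDepth must be >= 0")
  if (object@depthDispersion < 0)
    msg <- c(msg, "depthDispersion must be >= 0")
  if (object@homopolymerIndelSlope < 0)
    msg <- c(msg, "homopolymerIndelSlope must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a simulator configuration
#'
#' @param seed integer master seed.
#' @param readLenMean,readLenSd,readLenMin read length distribution (bp).
#' @param meanExonDepth expected fold depth of a well-captured exon.
#' @param depthDispersion extra-Poisson dispersion (0 = Poisson).
#' @param gcDropoutThreshold,gcDropoutFactor GC-dropout model.
#' @param subErrorRate per-base spurious substitution probability.
#' @param homopolymerIndelSlope per-run indel error slope.
#' @param homAltFraction,hetAltFraction allele read fractions.
#' @return a validated \linkS4class{SimulationConfig}.
#' @examples
#' simConfig(seed = 7, meanExonDepth = 20)
#' @export
simConfig <- function(seed = 1L, readLenMean = 408, readLenSd = 48,
                      readLenMin = 50, meanExonDepth = 17,
                      depthDispersion = 0, gcDropoutThreshold = 0.70,
                      gcDropoutFactor = 0.2, subErrorRate = 1e-3,
                      homopolymerIndelSlope = 0.01,
                      homAltFraction = 0.99, hetAltFraction = 0.5) {
  new("SimulationConfig", seed = as.integer(seed),
      readLenMean = readLenMean, readLenSd = readLenSd,
      readLenMin = readLenMin, meanExonDepth = meanExonDepth,
      depthDispersion = depthDispersion,
      gcDropoutThreshold = gcDropoutThreshold,
      gcDropoutFactor = gcDropoutFactor, subErrorRate = subErrorRate,
      homopolymerIndelSlope = homopolymerIndelSlope,
      homAltFraction = homAltFraction, hetAltFraction = hetAltFraction)
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig (seed", object@seed, ")\n")
  cat("  read length:", object@readLenMean, "+/-", object@readLenSd,
      "bp (min", object@readLenMin, ")\n")
  cat("  exon depth:", object@meanExonDepth, "fold; GC dropout x",
      object@gcDropoutFactor, "above GC", object@gcDropoutThreshold, "\n")
  cat("  error rates: sub", object@subErrorRate, "; homopolymer slope",
      object@homopolymerIndelSlope, "\n")
  cat("  allele fractions: het", object@hetAltFraction, ", hom",
      object@homAltFraction, "\n")
  invisible(NULL)
})

#' ThresholdPolicy: read-fraction threshold for variant triage
#'
#' Three modes are supported: \code{fixed} (default 20% of reads must
#' support the variant), \code{stringent} (35%), and \code{dynamic}
#' (start high and lower the threshold stepwise until one or two
#' candidate mutations survive, never below a floor).
#'
#' @slot mode one of \code{"fixed"}, \code{"stringent"}, \code{"dynamic"}.
#' @slot fixedValue,stringentValue fractions for the two fixed modes.
#' @slot dynamicStart,dynamicStep,dynamicFloor descent parameters.
#' @slot dynamicTarget integer range of acceptable survivor counts.
#' @seealso [thresholdPolicy()], [filterCascade()], [dynamicThreshold()]
#' @export
setClass("ThresholdPolicy",
  representation(mode = "character", fixedValue = "numeric",
                 stringentValue = "numeric", dynamicStart = "numeric",
                 dynamicStep = "numeric", dynamicFloor = "numeric",
                 dynamicTarget = "integer"))

setValidity("ThresholdPolicy", function(object) {
  msg <- character()
  if (!object@mode %in% c("fixed", "stringent", "dynamic"))
    msg <- c(msg, "mode must be fixed, stringent or dynamic")
  if (object@dynamicFloor > object@dynamicStart)
    msg <- c(msg, "dynamicFloor must not exceed dynamicStart")
  if (object@dynamicStep <= 0) msg <- c(msg, "dynamicStep must be > 0")
  if (length(object@dynamicTarget) != 2L ||
      object@dynamicTarget[1L] > object@dynamicTarget[2L])
    msg <- c(msg, "dynamicTarget must be an increasing integer pair")
  if (length(msg)) msg else TRUE
})

#' Construct a threshold policy
#'
#' @param mode \code{"fixed"}, \code{"stringent"} or \code{"dynamic"}.
#' @param fixedValue,stringentValue read-fraction cutoffs.
#' @param dynamicStart,dynamicStep,dynamicFloor dynamic descent control.
#' @param dynamicTarget acceptable survivor count range (length-2).
#' @return a validated \linkS4class{ThresholdPolicy}.
#' @examples
#' thresholdPolicy("stringent")
#' thresholdPolicy("dynamic", dynamicStart = 0.5)
#' @export
thresholdPolicy <- function(mode = c("fixed", "stringent", "dynamic"),
                            fixedValue = 0.20, stringentValue = 0.35,
                            dynamicStart = 0.50, dynamicStep = 0.05,
                            dynamicFloor = 0.20, dynamicTarget = c(1L, 2L)) {
  mode <- match.arg(mode)
  new("ThresholdPolicy", mode = mode, fixedValue = fixedValue,
      stringentValue = stringentValue, dynamicStart = dynamicStart,
      dynamicStep = dynamicStep, dynamicFloor = dynamicFloor,
      dynamicTarget = as.integer(dynamicTarget))
}

#' FilterTrace: per-stage counts of the triage cascade
#'
#' Records how many variants survive each stage of the triage cascade
#' (all variants, coding, not in the known-SNP catalog, protein-changing,
#' above the read-fraction threshold, prioritized) together with the
#' threshold actually applied and the ranked survivors.
#'
#' @slot nTotal,nCoding,nAfterSnpRemoval,nProteinChanging,nAfterFraction,nPrioritized
#'   stage counts, non-increasing in this order.
#' @slot thresholdUsed the read-fraction threshold applied.
#' @slot survivors ranked \code{data.frame} of surviving variants.
#' @seealso [filterCascade()]
#' @export
setClass("FilterTrace",
  representation(nTotal = "integer", nCoding = "integer",
                 nAfterSnpRemoval = "integer", nProteinChanging = "integer",
                 nAfterFraction = "integer", nPrioritized = "integer",
                 thresholdUsed = "numeric", survivors = "data.frame"))

setValidity("FilterTrace", function(object) {
  counts <- c(object@nTotal, object@nCoding, object@nAfterSnpRemoval,
              object@nProteinChanging, object@nAfterFraction,
              object@nPrioritized)
  if (any(diff(counts) > 0L))
    "stage counts must be non-increasing along the cascade"
  else TRUE
})

setMethod("show", "FilterTrace", function(object) {
  cat("Triage cascade (threshold", object@thresholdUsed, "):\n")
  cat(sprintf("  %5d total\n  %5d coding\n  %5d after known-SNP removal\n",
              object@nTotal, object@nCoding, object@nAfterSnpRemoval))
  cat(sprintf("  %5d protein-changing\n  %5d above read-fraction threshold\n",
              object@nProteinChanging, object@nAfterFraction))
  cat(sprintf("  %5d prioritized\n", object@nPrioritized))
  invisible(NULL)
})

#' @rdname FilterTrace-accessors
#' @export
traceCounts <- function(x)
  c(total = x@nTotal, coding = x@nCoding,
    after_snp_removal = x@nAfterSnpRemoval,
    protein_changing = x@nProteinChanging,
    after_fraction = x@nAfterFraction, prioritized = x@nPrioritized)

#' Accessors for FilterTrace
#' @name FilterTrace-accessors
#' @param x a \linkS4class{FilterTrace}.
#' @return \code{traceCounts}: named integer vector of stage counts;
#'   \code{traceSurvivors}: ranked \code{data.frame};
#'   \code{traceThreshold}: numeric threshold applied.
#' @export
traceSurvivors <- function(x) x@survivors

#' @rdname FilterTrace-accessors
#' @export
traceThreshold <- function(x) x@thresholdUsed

#' Pedigree: family structure plus genotypes at candidate variants
#'
#' @slot members \code{data.frame} with columns \code{sample_id},
#'   \code{father_id}, \code{mother_id} (\code{"0"} for founders),
#'   \code{sex} (\code{"M"}/\code{"F"}), \code{affected} (logical).
#' @slot genotypes \code{data.frame}, one row per member (rownames =
#'   sample ids), one column per variant id, entries in
#'   \code{c("ref","het","hom","hemi","missing")}.
#' @seealso [pedigree()], [readPedigree()], [cosegregates()]
#' @export
setClass("Pedigree",
  representation(members = "data.frame", genotypes = "data.frame"))

setValidity("Pedigree", function(object) {
  msg <- character()
  m <- object@members
  need <- c("sample_id", "father_id", "mother_id", "sex", "affected")
  if (!all(need %in% names(m)))
    msg <- c(msg, paste("members must have columns",
                        paste(need, collapse = ", ")))
  else {
    ids <- c("0", m$sample_id)
    if (!all(m$father_id %in% ids) || !all(m$mother_id %in% ids))
      msg <- c(msg, "parent ids must resolve to members or '0' (founder)")
    if (!all(m$sex %in% c("M", "F")))
      msg <- c(msg, "sex must be 'M' or 'F'")
  }
  g <- object@genotypes
  if (nrow(g) > 0L) {
    if (!setequal(rownames(g), m$sample_id))
      msg <- c(msg, "genotype rows must match member sample ids")
    vals <- unlist(g, use.names = FALSE)
    if (!all(vals %in% c("ref", "het", "hom", "hemi", "missing")))
      msg <- c(msg, "genotypes must be ref/het/hom/hemi/missing")
    # males are never het on the X under the no-pseudoautosomal assumption;
    # hemi encodes a male carrier there, so 'hemi' in a female is an error
    sex <- m$sex[match(rownames(g), m$sample_id)]
    if (any(g[sex == "F", , drop = FALSE] == "hemi"))
      msg <- c(msg, "female members cannot be hemizygous")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Pedigree
#'
#' @param members data.frame of family members (see
#'   \linkS4class{Pedigree}).
#' @param genotypes data.frame of genotype calls, rownames = sample ids.
#' @return a validated \linkS4class{Pedigree}.
#' @export
pedigree <- function(members, genotypes = NULL) {
  members$sample_id <- as.character(members$sample_id)
  members$father_id <- as.character(members$father_id)
  members$mother_id <- as.character(members$mother_id)
  if (is.null(genotypes)) {
    genotypes <- data.frame(row.names = members$sample_id)
  }
  new("Pedigree", members = members, genotypes = as.data.frame(genotypes))
}

setMethod("show", "Pedigree", function(object) {
  m <- object@members
  cat("Pedigree:", nrow(m), "member(s),", sum(m$affected), "affected;",
      ncol(object@genotypes), "genotyped variant(s)\n")
  invisible(NULL)
})

#' @rdname Pedigree-accessors
#' @export
pedMembers <- function(x) x@members

#' Accessors for Pedigree
#' @name Pedigree-accessors
#' @param x a \linkS4class{Pedigree}.
#' @return \code{pedMembers}: member table; \code{pedGenotypes}: genotype
#'   table.
#' @export
pedGenotypes <- function(x) x@genotypes
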