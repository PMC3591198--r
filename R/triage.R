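.protein_changing <- c("missense", "nonsense", "frameshift", "inframe_indel")

.fraction_col <- function(variants) {
  fr <- variants$fraction
  if (is.null(fr)) {
    if (!all(c("variant_reads", "total_reads") %in% names(variants)))
      stop("variants need a 'fraction' column or read counts")
    fr <- ifelse(variants$total_reads > 0,
                 variants$variant_reads / variants$total_reads, 0)
  }
  fr
}

#' Lower a read-fraction threshold until few candidates survive
#'
#' Starting at \code{dynamicStart}, the threshold is decreased by
#' \code{dynamicStep} while no variant reaches it, stopping at the first
#' threshold with one or two survivors (the expected number of causal
#' alleles) and never descending below \code{dynamicFloor}; if the floor
#' is reached, the floor and whatever survives there are returned.
#' Variants pass at fraction >= threshold.
#'
#' @param variants data.frame with a \code{fraction} column (or read
#'   counts from which it is derived).
#' @param policy a \linkS4class{ThresholdPolicy} with
#'   \code{mode = "dynamic"}.
#' @return list with \code{threshold} and \code{survivors} (data.frame).
#' @examples
#' v <- data.frame(fraction = c(0.42, 0.38, 0.22))
#' dynamicThreshold(v, thresholdPolicy("dynamic"))$threshold  # 0.40
#' @export
dynamicThreshold <- function(variants, policy = thresholdPolicy("dynamic")) {
  if (policy@mode != "dynamic")
    stop("dynamicThreshold requires a dynamic policy")
  fr <- .fraction_col(variants)
  thr <- policy@dynamicStart
  eps <- 1e-9  # guard against 0.50 - 6*0.05 style float drift
  repeat {
    n <- sum(fr >= thr - eps)
    if (n >= policy@dynamicTarget[1L]) break
    if (thr <= policy@dynamicFloor + eps) break
    thr <- thr - policy@dynamicStep
    if (thr < policy@dynamicFloor - eps) thr <- policy@dynamicFloor
  }
  thr <- round(thr, 9)
  list(threshold = thr,
       survivors = variants[fr >= thr - eps, , drop = FALSE])
}

#' Rank surviving candidate variants
#'
#' Sort key, in decreasing priority: presence in a known-reported
#' mutation table; compatibility with the inheritance hint (a recessive
#' hint requires a homozygous call or at least two heterozygous calls in
#' the same gene — a compound-heterozygote candidate; dominant and
#' X-linked hints accept heterozygous/hemizygous calls); deleteriousness
#' score; read fraction.  Ties are broken by (contig, position) so the
#' ranking is deterministic.
#'
#' Zygosity is taken from a \code{zygosity} column when present,
#' otherwise inferred from the read fraction (>= 0.75 is treated as
#' homozygous).
#'
#' @param survivors annotated data.frame ([annotateVariants()]).
#' @param inheritanceHint \code{"AD"}, \code{"AR"}, \code{"XL"} or
#'   \code{NULL}.
#' @return the same data.frame, reordered.
#' @export
prioritizeVariants <- function(survivors, inheritanceHint = NULL) {
  n <- nrow(survivors)
  if (n <= 1L) return(survivors)
  fr <- .fraction_col(survivors)
  known <- if (!is.null(survivors$known_reported)) survivors$known_reported
           else rep(FALSE, n)
  score <- if (!is.null(survivors$score)) survivors$score else rep(0, n)
  zyg <- if (!is.null(survivors$zygosity)) survivors$zygosity
         else ifelse(fr >= 0.75, "hom", "het")
  compat <- rep(TRUE, n)
  if (!is.null(inheritanceHint) && inheritanceHint == "AR") {
    gene <- if (!is.null(survivors$gene_symbol)) survivors$gene_symbol
            else rep(NA_character_, n)
    per_gene <- table(gene[!is.na(gene)])
    compat <- zyg %in% c("hom", "hemi") |
      (!is.na(gene) & gene %in% names(per_gene)[per_gene >= 2L])
  }
  pos <- as.integer(survivors$start %||% survivors$position)
  ord <- order(-as.integer(known), -as.integer(compat), -score, -fr,
               as.character(survivors$contig), pos)
  survivors[ord, , drop = FALSE]
}

#' Apply the variant triage cascade
#'
#' Stages, in order: (1) restrict to coding-region variants; (2) remove
#' variants present in the known-SNP catalog; (3) keep protein-changing
#' effects (missense, nonsense, frameshift, in-frame indel — truncating
#' and in-frame events are retained alongside substitutions because
#' validated panel mutations include duplications and insertions);
#' (4) apply the read-fraction threshold of the policy (fixed 20%,
#' stringent 35%, or dynamic descent); (5) rank the survivors
#' ([prioritizeVariants()]).  Every stage count is recorded in the
#' returned \linkS4class{FilterTrace}.
#'
#' @param variants annotated data.frame ([annotateVariants()]): columns
#'   \code{region}, \code{effect}, \code{known_snp}, plus read counts or
#'   \code{fraction}.
#' @param policy a \linkS4class{ThresholdPolicy}.
#' @param inheritanceHint optional inheritance mode for prioritization.
#' @return a \linkS4class{FilterTrace}.
#' @examples
#' v <- data.frame(region = c("coding", "utr3"),
#'                 effect = c("missense", "none"),
#'                 known_snp = c(FALSE, FALSE),
#'                 fraction = c(0.45, 0.5),
#'                 contig = "chr1", start = c(10, 20))
#' traceCounts(filterCascade(v))
#' @export
filterCascade <- function(variants, policy = thresholdPolicy("fixed"),
                          inheritanceHint = NULL) {
  n_total <- nrow(variants)
  coding <- variants[variants$region == "coding", , drop = FALSE]
  novel <- coding[!coding$known_snp, , drop = FALSE]
  prot <- novel[novel$effect %in% .protein_changing, , drop = FALSE]
  if (policy@mode == "dynamic") {
    dt <- dynamicThreshold(prot, policy)
    thr <- dt$threshold
    passed <- dt$survivors
  } else {
    thr <- if (policy@mode == "fixed") policy@fixedValue
           else policy@stringentValue
    fr <- .fraction_col(prot)
    passed <- prot[fr >= thr, , drop = FALSE]
  }
  ranked <- prioritizeVariants(passed, inheritanceHint)
  new("FilterTrace",
      nTotal = as.integer(n_total), nCoding = nrow(coding),
      nAfterSnpRemoval = nrow(novel), nProteinChanging = nrow(prot),
      nAfterFraction = nrow(passed), nPrioritized = nrow(ranked),
      thresholdUsed = thr, survivors = ranked)
}
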