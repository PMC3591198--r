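.carries <- function(g) g %in% c("het", "hom", "hemi")

#' Does a candidate variant cosegregate with disease in a family?
#'
#' Cosegregation under full penetrance and no phenocopies:
#' \describe{
#'   \item{AD}{yes iff every genotyped affected member carries at least
#'     one variant allele and no genotyped unaffected member carries
#'     any.}
#'   \item{AR}{yes iff every genotyped affected member is homozygous
#'     (or, when two variant ids are supplied — a compound-heterozygote
#'     candidate pair in one gene — carries both) and no genotyped
#'     unaffected member is.}
#'   \item{XL}{yes iff affected males are hemizygous carriers,
#'     unaffected males carry no variant allele, affected females are
#'     homozygous, and unaffected females are at most heterozygous
#'     carriers.}
#' }
#' Any violation returns \code{"no"}; if no non-proband member is
#' genotyped the answer is \code{"unknown"} (no family information).
#' A homozygous genotyped child of two reference-homozygous genotyped
#' parents is flagged as a Mendelian inconsistency (warning).
#'
#' @param ped a \linkS4class{Pedigree}.
#' @param variant a variant id (column of the genotype table), or a
#'   pair of ids for a compound-heterozygote test under AR.
#' @param mode \code{"AD"}, \code{"AR"} or \code{"XL"}.
#' @param proband sample id of the index patient (excluded when
#'   deciding whether family information exists); defaults to the first
#'   affected member.
#' @return \code{"yes"}, \code{"no"} or \code{"unknown"}.
#' @export
cosegregates <- function(ped, variant, mode = c("AD", "AR", "XL"),
                         proband = NULL) {
  mode <- match.arg(mode)
  m <- pedMembers(ped)
  g <- pedGenotypes(ped)
  if (!all(variant %in% names(g)))
    stop("variant id(s) not genotyped: ",
         paste(setdiff(variant, names(g)), collapse = ", "))
  if (is.null(proband)) proband <- m$sample_id[m$affected][1L]

  geno <- function(s, v) {
    x <- g[s, v]
    if (is.na(x)) "missing" else x
  }
  informative <- vapply(m$sample_id, function(s)
    any(vapply(variant, function(v) geno(s, v) != "missing", logical(1L))),
    logical(1L))
  if (!any(informative & m$sample_id != proband)) return("unknown")

  # Mendelian sanity: hom child of two genotyped ref parents
  for (v in variant) {
    for (i in seq_len(nrow(m))) {
      f <- m$father_id[i]; mo <- m$mother_id[i]
      if (f != "0" && mo != "0" && geno(m$sample_id[i], v) == "hom" &&
          geno(f, v) == "ref" && geno(mo, v) == "ref")
        warning("mendelian inconsistency: ", m$sample_id[i],
                " homozygous for ", v, " but both parents reference")
    }
  }

  ok <- TRUE
  for (i in seq_len(nrow(m))) {
    s <- m$sample_id[i]
    gt <- vapply(variant, function(v) geno(s, v), character(1L))
    if (all(gt == "missing")) next
    aff <- m$affected[i]
    sex <- m$sex[i]
    if (mode == "AD") {
      carry <- any(.carries(gt))
      if (aff && !carry) ok <- FALSE
      if (!aff && carry) ok <- FALSE
    } else if (mode == "AR") {
      if (length(variant) >= 2L) {
        both <- all(.carries(gt))
        if (aff && !both) ok <- FALSE
        if (!aff && both) ok <- FALSE
      } else {
        if (aff && gt != "hom") ok <- FALSE
        if (!aff && gt == "hom") ok <- FALSE
      }
    } else {  # XL
      gt1 <- gt[1L]
      if (sex == "M") {
        if (aff && !gt1 %in% c("hemi", "hom")) ok <- FALSE
        if (!aff && .carries(gt1)) ok <- FALSE
      } else {
        if (aff && gt1 != "hom") ok <- FALSE
        if (!aff && gt1 == "hom") ok <- FALSE
      }
    }
    if (!ok) break
  }
  if (ok) "yes" else "no"
}

.evidence_categories <- c("cosegregates", "family_unavailable",
                          "digenic_candidate",
                          "reported_dominant_unconfirmed",
                          "healthy_carrier_relative", "non_segregating",
                          "single_het_recessive", "none_found")

.class_map <- c(cosegregates = "definite",
                family_unavailable = "potential",
                digenic_candidate = "potential",
                reported_dominant_unconfirmed = "questionable",
                healthy_carrier_relative = "questionable",
                non_segregating = "unsolved",
                single_het_recessive = "unsolved",
                none_found = "unsolved")

#' Diagnostic class from a patient's evidence category
#'
#' Deterministic decision table mapping the family-evidence category of
#' a patient's candidate variants to a diagnostic class:
#' a validated cosegregating mutation is \code{definite}; a candidate
#' without available family confirmation (including a digenic
#' two-gene hypothesis) is \code{potential}; contradictory family
#' evidence — a previously reported dominant mutation that could not be
#' confirmed, or a healthy relative carrying the candidate — is
#' \code{questionable}; non-segregating candidates, a single
#' heterozygous hit in a recessive-only gene, or no candidate at all are
#' \code{unsolved}.
#'
#' @param evidenceCategory character vector of evidence categories (see
#'   Details for the eight values).
#' @return character vector of classes: \code{definite},
#'   \code{potential}, \code{questionable}, \code{unsolved}.
#' @examples
#' classifyPatient(c("cosegregates", "none_found"))
#' @export
classifyPatient <- function(evidenceCategory) {
  bad <- setdiff(unique(evidenceCategory), .evidence_categories)
  if (length(bad))
    stop("unknown evidence category: ", paste(bad, collapse = ", "))
  unname(.class_map[evidenceCategory])
}

.round_half_up <- function(x) floor(x + 0.5)

#' Diagnostic yield of a cohort
#'
#' @param classes character vector of diagnostic classes
#'   ([classifyPatient()]).
#' @return list with \code{counts} and \code{percentages} (rounded half
#'   away from zero), both named by class in the fixed order definite,
#'   potential, questionable, unsolved.
#' @examples
#' cohortYield(classifyPatient(cohortRunTable()$evidence_category))
#' @export
cohortYield <- function(classes) {
  stopifnot(length(classes) >= 1L)
  lv <- c("definite", "potential", "questionable", "unsolved")
  bad <- setdiff(unique(classes), lv)
  if (length(bad)) stop("unknown class: ", paste(bad, collapse = ", "))
  counts <- table(factor(classes, levels = lv))
  counts <- setNames(as.integer(counts), lv)
  pct <- setNames(.round_half_up(100 * counts / length(classes)), lv)
  list(counts = counts, percentages = pct)
}
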