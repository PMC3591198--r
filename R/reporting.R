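.fixture_path <- function(file)
  system.file("extdata", file, package = "RetinoPanel", mustWork = TRUE)

.check_fixture <- function(path) {
  sums <- utils::read.table(
    .fixture_path("checksums.md5"), header = FALSE,
    col.names = c("md5", "file"), stringsAsFactors = FALSE)
  expected <- sums$md5[sums$file == basename(path)]
  if (length(expected) != 1L)
    stop("no checksum recorded for ", basename(path))
  got <- unname(tools::md5sum(path))
  if (!identical(got, expected))
    stop("fixture checksum mismatch for ", basename(path),
         " — transcription drift?")
  invisible(TRUE)
}

.parse_inheritance <- function(pathology) {
  toks <- regmatches(pathology, gregexpr("\\b(AD|AR|X)[A-Z]+\\b",
                                         pathology))[[1L]]
  modes <- unique(ifelse(startsWith(toks, "AD"), "AD",
                  ifelse(startsWith(toks, "AR"), "AR", "XL")))
  modes
}

#' The packaged 63-gene retinal-dystrophy panel catalog
#'
#' One row per gene of the capture panel: symbol, aliases, chromosome,
#' genomic span, strand, exon count and reported retinopathy
#' associations.  60 genes are linked to retinitis pigmentosa, Leber
#' congenital amaurosis and related dystrophies; three are candidate
#' genes.  An \code{inheritance} column (comma-joined subset of
#' AD/AR/XL) is derived from the pathology annotations.  The file's MD5
#' checksum is verified on load to guard against transcription drift.
#'
#' @param check verify the fixture checksum (default \code{TRUE}).
#' @return data.frame with 63 rows; \code{sum(n_exons)} is 942.
#' @examples
#' panelStats(panelGeneCatalog())
#' @export
panelGeneCatalog <- function(check = TRUE) {
  path <- .fixture_path("panel_genes.tsv")
  if (check) .check_fixture(path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$n_exons <- as.integer(df$n_exons)
  df$inheritance <- vapply(df$pathology, function(p)
    paste(.parse_inheritance(p), collapse = ","), character(1L),
    USE.NAMES = FALSE)
  df
}

#' The packaged 23-patient diagnostic run synopsis
#'
#' One row per patient of the diagnostic cohort: run metrics (total
#' megabases sequenced, mean read length, median fold coverage), the
#' variant counts at each triage stage (total, coding, protein-changing
#' filter, prioritized), Sanger testing outcomes, the candidate
#' mutation(s) with their coverage and variant-read percentage, the
#' family cosegregation call, and the patient's evidence category
#' feeding [classifyPatient()].  Cells holding two values (patients
#' with two candidate mutations) are semicolon-joined; the numeric
#' \code{mut_cvg} and \code{mut_read_pct} columns carry the first
#' mutation's value, with the full strings in \code{*_all} columns.
#'
#' @param check verify the fixture checksum (default \code{TRUE}).
#' @return data.frame with 23 rows.
#' @examples
#' cohortSummary(cohortRunTable())$mean_mb
#' @export
cohortRunTable <- function(check = TRUE) {
  path <- .fixture_path("cohort_runs.tsv")
  if (check) .check_fixture(path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = ".")
  int_cols <- c("patient_id", "read_length_bp", "n_total_var", "n_cds_var",
                "n_filtered_var", "n_prioritized_var", "n_tested",
                "n_validated")
  for (nm in int_cols) df[[nm]] <- as.integer(df[[nm]])
  first_num <- function(x) as.numeric(vapply(strsplit(
    ifelse(is.na(x), "NA", x), ";", fixed = TRUE), `[`, character(1L), 1L))
  df$mut_cvg_all <- df$mut_cvg
  df$mut_read_pct_all <- df$mut_read_pct
  df$mut_cvg <- suppressWarnings(first_num(df$mut_cvg_all))
  df$mut_read_pct <- suppressWarnings(first_num(df$mut_read_pct_all))
  chain <- with(df, n_validated <= n_tested & n_tested <= n_prioritized_var &
                  n_prioritized_var <= n_filtered_var &
                  n_filtered_var <= n_cds_var & n_cds_var <= n_total_var)
  if (!all(chain))
    stop("count invariant violated in cohort fixture at patient(s) ",
         paste(df$patient_id[!chain], collapse = ", "))
  df
}

#' Cohort-level summary statistics
#'
#' Arithmetic means, sample standard deviations (n - 1 denominator),
#' and ranges of the per-patient run metrics and triage-stage variant
#' counts, plus the diagnostic-class tally obtained by applying
#' [classifyPatient()] to each patient's evidence category.
#'
#' @param runs data.frame as returned by [cohortRunTable()] (or
#'   assembled from [patientReport()] rows).
#' @return list with elements \code{n_patients}; \code{mean_mb},
#'   \code{sd_mb}; \code{mean_read_len}, \code{sd_read_len};
#'   \code{mean_total_var}, \code{sd_total_var}, \code{min_total_var},
#'   \code{max_total_var}; \code{mean_cds_var}, \code{sd_cds_var};
#'   \code{mean_filtered_var}, \code{sd_filtered_var};
#'   \code{class_counts}, \code{class_percentages}.
#' @examples
#' s <- cohortSummary(cohortRunTable())
#' round(s$mean_total_var, 1)
#' @export
cohortSummary <- function(runs) {
  stopifnot(nrow(runs) >= 2L)
  classes <- classifyPatient(runs$evidence_category)
  yield <- cohortYield(classes)
  list(
    n_patients = nrow(runs),
    mean_mb = mean(runs$total_seq_mb), sd_mb = sd(runs$total_seq_mb),
    mean_read_len = mean(runs$read_length_bp),
    sd_read_len = sd(runs$read_length_bp),
    mean_total_var = mean(runs$n_total_var),
    sd_total_var = sd(runs$n_total_var),
    min_total_var = min(runs$n_total_var),
    max_total_var = max(runs$n_total_var),
    mean_cds_var = mean(runs$n_cds_var), sd_cds_var = sd(runs$n_cds_var),
    mean_filtered_var = mean(runs$n_filtered_var),
    sd_filtered_var = sd(runs$n_filtered_var),
    class_counts = yield$counts,
    class_percentages = yield$percentages)
}

#' Assemble one patient's diagnostic report row
#'
#' Combines the triage trace, coverage statistics and family evidence
#' for one sample into a synopsis row of the same shape as the packaged
#' cohort table, enforcing the count invariant chain
#' validated <= tested <= prioritized <= filtered <= coding <= total.
#'
#' @param sampleId sample identifier.
#' @param trace the sample's \linkS4class{FilterTrace}.
#' @param medianDepth the sample's median targeted depth
#'   ([patientMedianDepth()]).
#' @param evidenceCategory the sample's evidence category
#'   ([classifyPatient()] input).
#' @param nTested,nValidated Sanger follow-up counts; default: every
#'   prioritized variant tested, none yet validated.
#' @param totalSeqMb,readLengthBp optional run metrics (e.g. from the
#'   simulator's \code{run} element).
#' @param mutationLabel optional label of the retained candidate(s).
#' @param mutCvg,mutReadPct optional coverage and read percentage of the
#'   retained candidate.
#' @return one-row data.frame with the cohort-synopsis columns plus
#'   \code{diagnostic_class}.
#' @export
patientReport <- function(sampleId, trace, medianDepth, evidenceCategory,
                          nTested = NULL, nValidated = 0L,
                          totalSeqMb = NA_real_, readLengthBp = NA_real_,
                          mutationLabel = NA_character_,
                          mutCvg = NA_real_, mutReadPct = NA_real_) {
  counts <- traceCounts(trace)
  if (is.null(nTested)) nTested <- counts[["prioritized"]]
  chain <- c(n_validated = as.integer(nValidated),
             n_tested = as.integer(nTested),
             n_prioritized_var = counts[["prioritized"]],
             n_filtered_var = counts[["protein_changing"]],
             n_cds_var = counts[["coding"]],
             n_total_var = counts[["total"]])
  if (any(diff(chain) < 0L)) {
    i <- which(diff(chain) < 0L)[1L]
    stop("count invariant violated: ", names(chain)[i], " (",
         chain[i], ") > ", names(chain)[i + 1L], " (", chain[i + 1L], ")")
  }
  data.frame(
    patient_id = sampleId, total_seq_mb = totalSeqMb,
    read_length_bp = readLengthBp, median_fold_cvg = medianDepth,
    n_total_var = chain[["n_total_var"]],
    n_cds_var = chain[["n_cds_var"]],
    n_filtered_var = chain[["n_filtered_var"]],
    n_prioritized_var = chain[["n_prioritized_var"]],
    n_tested = chain[["n_tested"]], n_validated = chain[["n_validated"]],
    mutation_label = mutationLabel, mut_cvg = mutCvg,
    mut_read_pct = mutReadPct, evidence_category = evidenceCategory,
    diagnostic_class = classifyPatient(evidenceCategory),
    stringsAsFactors = FALSE)
}
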