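test_that("the packaged cohort synopsis loads and checksums", {
  runs <- cohortRunTable()
  expect_equal(nrow(runs), 23L)
  expect_equal(runs$median_fold_cvg[runs$patient_id == 16], 28.4)
  expect_equal(runs$mut_cvg[runs$patient_id == 9], 0)
  expect_true(all(runs$n_validated <= runs$n_tested))
  expect_true(all(runs$evidence_category %in%
                    c("cosegregates", "family_unavailable",
                      "digenic_candidate", "reported_dominant_unconfirmed",
                      "healthy_carrier_relative", "non_segregating",
                      "single_het_recessive", "none_found")))
})

test_that("fixture checksum failures are detected", {
  src <- system.file("extdata", "cohort_runs.tsv", package = "RetinoPanel")
  tmpdir <- withr::local_tempdir()
  # a doctored copy under the same name must be rejected
  fake_extdata <- file.path(tmpdir, "extdata")
  dir.create(fake_extdata)
  lines <- readLines(src)
  lines[2] <- sub("^1\t47", "1\t48", lines[2])
  writeLines(lines, file.path(fake_extdata, "cohort_runs.tsv"))
  expect_error(
    RetinoPanel:::.check_fixture(file.path(fake_extdata, "cohort_runs.tsv")),
    "checksum mismatch")
})

test_that("the gene catalog derives inheritance modes from pathology", {
  cat <- panelGeneCatalog()
  expect_equal(nrow(cat), 63L)
  expect_equal(cat$inheritance[cat$gene_symbol == "RP2"], "XL")
  expect_equal(cat$inheritance[cat$gene_symbol == "PRPF31"], "AD")
  modes <- strsplit(cat$inheritance[cat$gene_symbol == "ABCA4"], ",")[[1L]]
  expect_setequal(modes, c("AD", "AR"))
  expect_equal(cat$inheritance[cat$gene_symbol == "CNGA2"], "")
})

test_that("cohort statistics reproduce the synopsis at printed precision", {
  s <- cohortSummary(cohortRunTable())
  expect_equal(round(s$mean_mb, 1), 39.6)
  expect_equal(round(s$sd_mb, 1), 14.1)
  expect_equal(round(s$mean_total_var, 1), 1111.7)
  expect_equal(round(s$sd_total_var, 1), 222.2)
  expect_equal(s$min_total_var, 736L)
  expect_equal(s$max_total_var, 1826L)
  expect_equal(round(s$mean_cds_var, 1), 90.1)
  expect_equal(round(s$mean_filtered_var, 1), 42.1)
  expect_equal(round(s$sd_filtered_var, 1), 4.7)
  expect_equal(round(s$sd_read_len, 0), 48)

  two <- cohortRunTable()[c(1, 1), ]
  s2 <- cohortSummary(two)
  expect_equal(s2$sd_mb, 0)
  expect_equal(s2$sd_total_var, 0)
})

test_that("patient reports enforce the count invariant chain", {
  tr <- new("FilterTrace", nTotal = 100L, nCoding = 40L,
            nAfterSnpRemoval = 20L, nProteinChanging = 10L,
            nAfterFraction = 3L, nPrioritized = 3L, thresholdUsed = 0.2,
            survivors = data.frame())
  row <- patientReport("S1", tr, medianDepth = 17,
                       evidenceCategory = "cosegregates",
                       nTested = 2L, nValidated = 1L)
  expect_equal(row$diagnostic_class, "definite")
  expect_equal(row$n_filtered_var, 10L)
  expect_error(
    patientReport("S1", tr, 17, "cosegregates", nTested = 5L,
                  nValidated = 6L),
    "n_validated")
})

test_that("an empty variant table gives an all-zero unsolved report", {
  tr <- filterCascade(data.frame(region = character(),
                                 known_snp = logical(),
                                 effect = character(),
                                 fraction = numeric())[0, ])
  row <- patientReport("S0", tr, medianDepth = 0,
                       evidenceCategory = "none_found")
  expect_equal(row$n_total_var, 0L)
  expect_equal(row$diagnostic_class, "unsolved")
})

test_that("the pipeline runs end to end on a toy panel", {
  # design -> simulate -> annotate -> filter -> coverage -> classify -> report
  cg <- coding_gene(paste0("ATG", strrep("GAG", 30), "TAA"), pad = 300)
  g <- cg$gene; ref <- cg$ref
  targets <- buildTargets(list(g), flankBp = 20, promoterBp = 100)
  tv <- truthVariant("chr1", 310L, "G", "T", kind = "SNV",
                     zygosity = "het", carriers = c("P1", "M1"))
  sim <- simulateCohort(targets, list(TOY = g), ref,
                        truthSet(list(tv), samples = c("P1", "M1", "F1")),
                        quiet_config(seed = 15, meanExonDepth = 50))
  reports <- lapply(names(sim), function(s) {
    ann <- annotateVariants(sim[[s]]$variants, list(TOY = g), ref)
    tr <- filterCascade(ann, thresholdPolicy("fixed"))
    n_surv <- traceCounts(tr)[["prioritized"]]
    patientReport(s, tr,
                  medianDepth = patientMedianDepth(sim[[s]]$coverage,
                                                   targets),
                  evidenceCategory = if (n_surv > 0) "cosegregates"
                                     else "none_found",
                  nTested = n_surv, nValidated = n_surv,
                  totalSeqMb = sim[[s]]$run$total_seq_mb,
                  readLengthBp = sim[[s]]$run$read_length_bp)
  })
  report <- do.call(rbind, reports)
  expect_equal(nrow(report), 3L)
  expect_equal(report$diagnostic_class[report$patient_id == "P1"],
               "definite")
  expect_equal(report$n_validated[report$patient_id == "P1"], 1L)
  expect_equal(report$diagnostic_class[report$patient_id == "F1"],
               "unsolved")
  expect_true(all(report$median_fold_cvg > 20))
})

test_that("report invariants hold across fuzzed simulated patients", {
  cg <- coding_gene(paste0("ATG", strrep("GAG", 10), "TAA"), pad = 80)
  targets <- buildTargets(list(cg$gene), flankBp = 10, promoterBp = 40)
  for (i in 1:60) {
    cfg <- simConfig(seed = i, subErrorRate = 0.02,
                     homopolymerIndelSlope = 0.05, meanExonDepth = 25)
    sim <- simulateCohort(targets, list(TOY = cg$gene), cg$ref,
                          truthSet(samples = "S"), cfg)
    ann <- annotateVariants(sim$S$variants, list(TOY = cg$gene), cg$ref)
    tr <- filterCascade(ann)
    counts <- traceCounts(tr)
    expect_true(all(diff(unname(counts)) <= 0L))
    row <- patientReport("S", tr, patientMedianDepth(sim$S$coverage),
                         evidenceCategory = "none_found")
    expect_true(row$n_total_var >= row$n_cds_var)
  }
})

test_that("variant percentages in the synopsis are internally coherent", {
  runs <- cohortRunTable()
  # the zero-coverage structural deletion has zero supporting reads
  p9 <- runs[runs$patient_id == 9, ]
  expect_equal(p9$mut_read_pct, 0)
  expect_equal(p9$mutation_label, "g.ABCA4-ex45-47del")
  # the below-threshold candidate that motivated the stringent policy
  expect_true(any(abs(runs$mut_read_pct - 39.1) < 1e-9, na.rm = TRUE))
})
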