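toy_psms <- function() {
  data.frame(
    peptide = c("GSFKYAWV", "TPEHAPSK", "AAAAAAAAAA", "VLHLLSVAR"),
    modifications = c("Trimethyl (K)@4", "", "", "Hydroxylation (P)@1"),
    annotated_residues = c(5L, 4L, 0L, 9L),
    cell_type = c("CT01", "CT02", "CT01", "CT03"),
    accessions = c("P1", "P1", "P2", "P3"),
    category = "canonical",
    protein_start = c(10L, 30L, 1L, 5L)
  )
}

test_that("the registry holds 39 classes split 27 biological / 12 post-isolation", {
  reg <- ptm_registry()
  expect_equal(nrow(reg), 39)
  expect_equal(sum(reg$class == "biological"), 27)
  expect_equal(sum(reg$class == "post_isolation"), 12)
  expect_false(anyDuplicated(reg$name) > 0)
  expect_true(all(reg$delta_mass != 0))
  # a registry with a broken partition is rejected
  dir <- withr::local_tempdir()
  bad <- reg[-1, ]
  write.table(bad, file.path(dir, "bad.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(ptm_registry(file.path(dir, "bad.tsv")), "39")
})

test_that("coverage filter is strict at the boundary and partitions exhaustively", {
  psms <- toy_psms()
  f <- coverage_filter(psms)
  # 5/8 = 0.625 kept; 4/8 = 0.5 rejected (strict >); 0/10 rejected; 9/9 kept
  expect_setequal(f$kept$peptide, c("GSFKYAWV", "VLHLLSVAR"))
  expect_setequal(f$rejected$peptide, c("TPEHAPSK", "AAAAAAAAAA"))
  expect_equal(f$kept$coverage[f$kept$peptide == "GSFKYAWV"], 0.625)
  # partitions are disjoint and exhaustive
  expect_equal(nrow(f$kept) + nrow(f$rejected), nrow(psms))
  expect_length(intersect(rownames(f$kept), rownames(f$rejected)), 0)
  # corrupt record: annotated_residues beyond the peptide length
  bad <- psms; bad$annotated_residues[1] <- 9L
  expect_error(coverage_filter(bad), "corrupt")
})

test_that("modification class labels follow the registry with a mixed rule", {
  psms <- data.frame(
    peptide = c("APKAAR", "MMKAAR", "APMKAR", "AAKAAR"),
    modifications = c("Hydroxylation (P)@2", "Oxidation (M)@1",
                      "Hydroxylation (P)@2;Oxidation (M)@3", ""),
    annotated_residues = 6L, cell_type = "CT01", accessions = "P1",
    category = "canonical", protein_start = 1L
  )
  got <- classify_modifications(psms)
  expect_equal(got$mod_class,
               c("biological", "post_isolation", "mixed", "unmodified"))
  bad <- psms; bad$modifications[1] <- "NotAMod@2"
  expect_error(classify_modifications(bad), "NotAMod")
})

test_that("site frequency counts distinct sites once regardless of PSM multiplicity", {
  psms <- data.frame(
    peptide = c("APSKAR", "APSKAR", "SAPSKAR"),
    modifications = c("Phospho (S)@3", "Phospho (S)@3", "Phospho (S)@4"),
    annotated_residues = 6L, cell_type = c("CT01", "CT02", "CT01"),
    accessions = "P1", category = "canonical",
    protein_start = c(10L, 10L, 9L)  # all three report protein position 12
  )
  sf <- site_frequency(psms)
  expect_equal(nrow(sf$sites), 1)
  expect_equal(sf$sites$position, 12)
  expect_equal(sf$by_residue$n_sites, 1)
  expect_equal(unname(sf$class_totals[["biological"]]), 1)
  # duplication idempotence on the full synthetic table
  ps <- default_psms()
  sf1 <- site_frequency(ps$psms)
  sf2 <- site_frequency(rbind(ps$psms, ps$psms))
  expect_equal(sf1$sites[order(sf1$sites$protein, sf1$sites$position,
                               sf1$sites$name), ],
               sf2$sites[order(sf2$sites$protein, sf2$sites$position,
                               sf2$sites$name), ],
               ignore_attr = TRUE)
})

test_that("planted site table and dioxidation ratio are recovered exactly", {
  ps <- default_psms()
  kept <- classify_modifications(coverage_filter(ps$psms)$kept)
  sf <- site_frequency(kept)
  got <- sf$sites[order(sf$sites$protein, sf$sites$position, sf$sites$name), ]
  want <- ps$truth$ptm_sites[order(ps$truth$ptm_sites$protein,
                                   ps$truth$ptm_sites$position,
                                   ps$truth$ptm_sites$name), ]
  expect_equal(got, want, ignore_attr = TRUE)
  w <- sf$by_residue$n_sites[sf$by_residue$name == "Dioxidation (W)"]
  m <- sf$by_residue$n_sites[sf$by_residue$name == "Dioxidation (M)"]
  cfg <- synthetic_config()
  expect_equal(w, cfg$n_trp_diox)
  expect_equal(m, cfg$n_met_diox)
  expect_equal(w / m, cfg$n_trp_diox / cfg$n_met_diox)
})

test_that("per-protein PTM summaries count sites and types independently", {
  psms <- data.frame(
    peptide = c("GSFKYAWV", "GSFKYAWV", "APSKAR"),
    modifications = c("Methyl (K)@4", "Trimethyl (K)@4", "Phospho (S)@3"),
    annotated_residues = c(8L, 8L, 6L), cell_type = "CT01",
    accessions = c("P1", "P1", "P2"), category = "canonical",
    protein_start = c(1L, 1L, 1L)
  )
  pps <- protein_ptm_summary(psms)
  p1 <- pps$summary[pps$summary$protein == "P1", ]
  expect_equal(p1$n_sites, 1)  # one position, two types
  expect_equal(p1$n_types, 2)
  p2 <- pps$summary[pps$summary$protein == "P2", ]
  expect_equal(c(p2$n_sites, p2$n_types), c(1, 1))
  # post-isolation modifications are excluded from this summary
  psms2 <- psms
  psms2$modifications[3] <- "Oxidation (M)@1"
  psms2$peptide[3] <- "MPSKAR"
  pps2 <- protein_ptm_summary(psms2)
  expect_false("P2" %in% pps2$summary$protein)
})

test_that("the multi-PTM showcase protein reports 26 sites and 13 types", {
  ps <- default_psms()
  kept <- classify_modifications(coverage_filter(ps$psms)$kept)
  pps <- protein_ptm_summary(kept)
  mp <- pps$summary[pps$summary$protein == ps$truth$multiptm$accession, ]
  expect_equal(mp$n_sites, 26)
  expect_equal(mp$n_types, 13)
})

test_that("readthrough plausibility keeps exactly the single-substitution events", {
  ps <- default_psms()
  kept <- classify_modifications(coverage_filter(ps$psms)$kept)
  rt <- readthrough_plausibility(kept)
  expect_true(all(rt$kept$min_sub == 1))
  expect_true(all(rt$rejected$min_sub >= 2))
  truth <- ps$truth$readthrough_psms
  # kept set equals the planted events with codon distance 1
  want <- truth[truth$min_sub == 1, c("transcript_id", "residue")]
  got <- unique(data.frame(
    transcript_id = vapply(strsplit(rt$kept$accessions, "|", fixed = TRUE),
                           `[`, character(1), 3),
    residue = rt$kept$residue))
  expect_equal(got[order(got$transcript_id), ],
               unique(want)[order(unique(want)$transcript_id), ],
               ignore_attr = TRUE)
  # the diagnostic UGA -> Trp event is among the kept ones
  expect_true("DLWLVSSR" %in% rt$kept$peptide)
  expect_true("UGA" %in% names(rt$stop_frequency))
})

test_that("missing-protein evidence tiers match the planted ledger", {
  ps <- default_psms()
  kept <- classify_modifications(coverage_filter(ps$psms)$kept)
  rep <- missing_protein_report(kept, ps$pe_levels, default_entries())
  pe2 <- rep[rep$pe_level == "PE2", ]
  truth <- ps$truth$missing
  expect_equal(pe2$tier[pe2$accession == truth$two_unique], "2+ unique")
  expect_equal(pe2$n_unique_peptides[pe2$accession == truth$two_unique], 2)
  for (acc in names(truth$one_unique)) {
    expect_equal(pe2$tier[pe2$accession == acc], "1 unique")
  }
  # the shared-only proteins never enter the report
  expect_false(any(truth$shared_only %in% rep$accession))
  expect_setequal(pe2$accession, c(truth$two_unique, names(truth$one_unique)))
})
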