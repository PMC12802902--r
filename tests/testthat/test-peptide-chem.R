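test_that("tryptic digestion follows the Keil rule with missed cleavages", {
  # K before P is not cleaved; terminal R gives a single peptide
  d <- digest("MKPR", min_len = 1)
  expect_equal(d$sequence, "MKPR")
  expect_equal(d$missed_cleavages, 0)
  # GSFKYAWVLDK carries one internal cleavable K
  prot <- paste0("MGDK", "GSFKYAWVLDK", "TPER")
  d2 <- digest(prot, min_len = 1)
  row <- d2[d2$sequence == "GSFKYAWVLDK", ]
  expect_equal(nrow(row), 1)
  expect_equal(row$missed_cleavages, 1)
  expect_equal(row$preceded_by, "K")
  # trypsin_p switch removes the proline exclusion
  d3 <- digest("MKPR", min_len = 1, trypsin_p = TRUE)
  expect_setequal(d3$sequence[d3$missed_cleavages == 0], c("MK", "PR"))
})

test_that("digestion equals the boundary-pair brute-force oracle", {
  set.seed(202)
  for (k in 1:100) {
    prot <- random_protein(sample(40:90, 1))
    for (mm in 0:2) {
      got <- digest(prot, max_missed = mm, min_len = 1, max_len = 1000)
      want <- oracle_digest(prot, mm, 1, 1000)
      got <- got[order(got$start, got$end), c("sequence", "start", "end",
                                              "missed_cleavages")]
      want <- want[order(want$start, want$end), ]
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want, info = paste("protein", k, "missed", mm))
    }
  }
})

test_that("N-terminal Met excision adds peptides for small second residues", {
  d <- digest("MAGTSLVKDDDR", min_len = 1, nterm_met_excision = TRUE)
  expect_true("AGTSLVK" %in% d$sequence)
  expect_true("MAGTSLVK" %in% d$sequence)
  ex <- d[d$sequence == "AGTSLVK", ]
  expect_equal(ex$preceded_by, "M")
  expect_true(ex$is_protein_nterm)
  # bulky second residue: no excision
  d2 <- digest("MWGTSLVKDDDR", min_len = 1, nterm_met_excision = TRUE)
  expect_false("WGTSLVK" %in% d2$sequence)
})

test_that("peptide masses match hand sums and the elemental-composition oracle", {
  expect_equal(peptide_mass("G"), 75.0320, tolerance = 1e-4)
  set.seed(303)
  for (k in 1:100) {
    p <- random_protein(sample(5:25, 1))
    expect_equal(peptide_mass(p), oracle_peptide_mass(p), tolerance = 1e-6)
  }
  # modification additivity
  reg <- ptm_registry()
  mods <- data.frame(name = "Phospho (S)", site = 2L)
  expect_equal(peptide_mass("ASK", mods) - peptide_mass("ASK"),
               reg$delta_mass[reg$name == "Phospho (S)"], tolerance = 1e-9)
  expect_error(peptide_mass("AZK"), "unknown residue")
  expect_error(peptide_mass("ASK", data.frame(name = "Phospho (S)", site = 1)),
               "does not target")
})

test_that("fragment series close to the peptide mass and shift with modifications", {
  p <- "GSFKYAWVLDK"
  fr <- fragment_ions(p)
  const <- mass_constants()
  b <- fr$mz[fr$series == "b"]            # b_1 .. b_{n-1}
  y <- fr$mz[fr$series == "y"]            # y_{n-1} .. y_1
  n <- nchar(p)
  # b_i + y_{n-i} = peptide mass + 2 protons (singly charged)
  for (i in seq_len(n - 1)) {
    expect_equal(b[i] + y[i], peptide_mass(p) + 2 * const[["proton"]],
                 tolerance = 1e-6)
  }
  # trimethyl vs methyl on K4 separates every b_i with i >= 4 by 2 x 14.0157
  fr_tri <- fragment_ions(p, data.frame(name = "Trimethyl (K)", site = 4))
  fr_me <- fragment_ions(p, data.frame(name = "Methyl (K)", site = 4))
  b4_diff <- fr_tri$mz[fr_tri$ion == "b4"] - fr_me$mz[fr_me$ion == "b4"]
  expect_equal(b4_diff, 2 * 14.015650, tolerance = 1e-5)
  b3_diff <- fr_tri$mz[fr_tri$ion == "b3"] - fr_me$mz[fr_me$ion == "b3"]
  expect_equal(b3_diff, 0, tolerance = 1e-9)
  # y-series of a peptide equals b-series of its reversal up to terminal
  # groups (water + nothing): check via the closure above instead of
  # re-deriving; here assert y1 is the C-terminal residue + water + proton
  expect_equal(fr$mz[fr$ion == "y1"],
               residue_masses()[["K"]] + const[["water"]] + const[["proton"]],
               tolerance = 1e-9)
})

test_that("immonium ions derive from residue mass minus CO plus proton", {
  expect_equal(round(immonium_mz("H", "Methyl (H)"), 2), 124.09)
  expect_equal(round(immonium_mz("H"), 2), 110.07)
  reg <- ptm_registry()
  # additivity across residues and modifications
  for (r in c("K", "W", "F")) {
    expect_equal(immonium_mz(r, 14.01565) - immonium_mz(r), 14.01565,
                 tolerance = 1e-9)
  }
  expect_error(immonium_mz("Z"), "unknown residue")
})

test_that("novelty classification collapses I/L and gives canonical precedence", {
  canonical <- c(P1 = "MAAKDLWLVSSRTTT")
  custom <- rbind(
    data.frame(accession = "nc|readthrough|T1|residue=W", category = "readthrough",
               transcript_id = "T1", sequence = "MGGKDLWLVSSRQQQ",
               detail = "residue=W", flagged = FALSE),
    data.frame(accession = "nc|uorf|T2|p=1", category = "uorf",
               transcript_id = "T2", sequence = "MVLHLLSVAR",
               detail = "p=1", flagged = FALSE)
  )
  # present only in the readthrough entry
  got <- classify_peptides("GGKDLW", canonical, custom)
  expect_equal(got$category, "readthrough")
  # canonical takes precedence even when a custom entry also matches
  got2 <- classify_peptides("DLWLVSSR", canonical, custom)
  expect_equal(got2$category, "canonical")
  # I/L equivalence: ISSR matches canonical LSSR positionally
  got3 <- classify_peptides("DIWIVSSR", canonical, custom)
  expect_equal(got3$category, "canonical")
  got4 <- classify_peptides("DIWIVSSR", canonical, custom,
                            il_equivalent = FALSE)
  expect_equal(got4$category, "unmapped")
  # multi-category tie
  custom2 <- rbind(custom, data.frame(
    accession = "nc|junction|T3|j=1", category = "junction",
    transcript_id = "T3", sequence = "AAKDLWLVSSRQ", detail = "j=1",
    flagged = FALSE))
  got5 <- classify_peptides("DLWLVSSRQ", canonical, custom2)
  expect_equal(got5$category, "multi-category")
  expect_setequal(strsplit(got5$categories, ";")[[1]],
                  c("readthrough", "junction"))
})

test_that("novelty classification is monotone in the canonical database", {
  set.seed(404)
  custom <- data.frame(accession = "nc|uorf|T|p=0", category = "uorf",
                       transcript_id = "T", sequence = random_protein(60),
                       detail = "p=0", flagged = FALSE)
  small <- c(A = random_protein(80))
  large <- c(small, B = random_protein(80))
  peps <- vapply(1:40, function(i) {
    src <- sample(c(small, custom$sequence), 1)
    s <- sample(nchar(src) - 8, 1)
    substr(src, s, s + 7)
  }, character(1))
  cat_small <- classify_peptides(peps, small, custom)$category
  cat_large <- classify_peptides(peps, large, custom)$category
  expect_true(all(!(cat_small == "canonical" & cat_large != "canonical")))
})
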