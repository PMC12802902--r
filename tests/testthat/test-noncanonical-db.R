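# Toy transcripts mirror the published noncanonical cases: an in-frame
# upstream ACG giving an N-terminal extension whose first tryptic peptide is
# MESDPER, a uORF encoding VLHLLSVAR, and a UGA readthrough whose tryptophan
# entry carries DLWLVSSR.

hm13_like <- function() {
  # 5' UTR: background, then in-frame ACG + ESDPER codons, then in-frame
  # background codons up to the annotated ATG
  u5 <- paste0("CCAACCCCACCA", "CC",           # 14 nt background
               "ACG", "GAGTCCGACCCCGAGCGC",    # ACG + ESDPER codons
               "ACCCCAACC")                    # in-frame T-P-T background
  cds <- "ATGGCTGCAAAGTGGGCATTCCGCTAA"
  toy_transcript(utr5 = u5, cds = cds, utr3 = "GCAGCATAACCA", id = "HM13L")
}

test_that("in-frame upstream starts yield N-terminal extensions ending in the protein", {
  tx <- hm13_like()
  ext <- build_nterm_extensions(tx)
  expect_equal(nrow(ext), 1)
  expect_equal(ext$category, "nterm_extension")
  prot <- protein_sequence(tx)
  # annotated protein is a strict suffix
  expect_true(endsWith(ext$sequence, prot))
  expect_gt(nchar(ext$sequence), nchar(prot))
  # initiator is methionine even at the non-AUG codon; first tryptic peptide
  # is MESDPER
  peps <- digest(ext$sequence, min_len = 1)
  expect_true("MESDPER" %in% peps$sequence[peps$is_protein_nterm])
  expect_match(ext$detail, "tis_codon=ACG")
})

test_that("an in-frame stop between a candidate start and the CDS blocks the extension", {
  # CTG in frame with the CDS, but UAA sits between it and the start
  u5 <- paste0("CCAACC", "CTG", "CCATAACCA")  # CTG at 6, TAA in frame at 12
  tx <- toy_transcript(utr5 = u5, cds = "ATGAAGCGCTAA", utr3 = "CCAACC")
  expect_equal(nrow(build_nterm_extensions(tx)), 0)
  # empty 5' UTR is an empty result, not an error
  tx2 <- toy_transcript(utr5 = "", cds = "ATGAAGCGCTAA", utr3 = "CCA")
  expect_equal(nrow(build_nterm_extensions(tx2)), 0)
})

test_that("uORFs are found in all three frames and filtered by length", {
  # out-of-frame ATG + VLHLLSVAR + TAA inside the 5' UTR
  body <- "GTCCTCCACCTCCTCTCCGTCGCCCGC"
  u5 <- paste0("CCAACCCCAC", "CC", "ATG", body, "TAA", "CCAC")
  tx <- toy_transcript(utr5 = u5, cds = "ATGAAGCGCTAA", utr3 = "CCAACC",
                       id = "TRMT1LL")
  orfs <- build_uorfs(tx, min_length_aa = 6)
  expect_equal(nrow(orfs), 1)
  expect_equal(orfs$sequence, "MVLHLLSVAR")
  expect_false(orfs$flagged)
  expect_match(orfs$detail, "cds_overlap=0")
  # Met excision exposes the VLHLLSVAR tryptic peptide
  peps <- digest(orfs$sequence, min_len = 1, nterm_met_excision = TRUE)
  expect_true("VLHLLSVAR" %in% peps$sequence)
  # raising the floor above the ORF length drops it
  expect_equal(nrow(build_uorfs(tx, min_length_aa = 11)), 0)
  # no start codon in any frame -> empty
  tx2 <- toy_transcript(utr5 = "CCAACCCCACCAACC", cds = "ATGAAGCGCTAA",
                        utr3 = "CCA")
  expect_equal(nrow(build_uorfs(tx2)), 0)
})

test_that("uORFs without a UTR stop continue into the CDS and are flagged overlapping", {
  # ATG near the UTR end, no stop before the CDS: reads through into it
  u5 <- paste0("CCAACCCCA", "CC", "ATG", "AAACAC")
  tx <- toy_transcript(utr5 = u5, cds = "ATGAAGAAACACAAGCGCTAA",
                       utr3 = "CCAACC")
  orfs <- build_uorfs(tx, min_length_aa = 4)
  expect_equal(nrow(orfs), 1)
  expect_match(orfs$detail, "cds_overlap=1")
  # translation continued into the CDS up to the annotated stop
  expect_equal(orfs$sequence, paste0("M", "KH", "MKKHKR"))
})

test_that("readthrough entries substitute all 20 residues ahead of the 3' UTR extension", {
  # protein ends ...KDL, stop UGA, extension LVSSRTAE before the next stop
  cds <- paste0("ATG", "GCA", "AAA", "GAC", "CTC", "TGA")
  u3 <- paste0("CTCGTCTCCTCCCGCACCGCCGAG", "TAA", "CCAACC")
  tx <- toy_transcript(utr5 = "CCAACC", cds = cds, utr3 = u3, id = "LDHBL")
  ents <- build_readthrough_entries(tx)
  expect_equal(nrow(ents), 20)
  prot <- protein_sequence(tx)
  expect_true(all(startsWith(ents$sequence, prot)))
  expect_true(all(!ents$flagged))
  w <- ents[grepl("residue=W", ents$detail), ]
  expect_equal(w$sequence, paste0(prot, "W", "LVSSRTAE"))
  expect_match(w$detail, "stop_codon=UGA")
  expect_match(w$detail, "min_sub=1")
  peps <- digest(w$sequence, min_len = 1)
  expect_true("DLWLVSSR" %in% peps$sequence)
})

test_that("an immediate in-frame stop in the 3' UTR gives single-residue extensions", {
  tx <- toy_transcript(utr5 = "CCAACC", cds = "ATGAAGCGCTAA",
                       utr3 = "TAACCAACC")
  ents <- build_readthrough_entries(tx)
  expect_equal(nrow(ents), 20)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  expect_setequal(ents$sequence, paste0("MKR", aas))
  # incomplete CDS: readthrough undefined
  inc <- toy_transcript(cds = "ATGAAGAAA", utr3 = "CCAACC")
  expect_error(build_readthrough_entries(inc), "stop")
})

test_that("codon-distance table equals the exhaustive oracle for all 60 pairs", {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (sc in c("UAG", "UAA", "UGA")) {
    for (aa in aas) {
      expect_equal(min_substitutions(sc, aa), oracle_min_substitutions(sc, aa),
                   info = paste(sc, aa))
    }
  }
  expect_equal(min_substitutions("UGA", "W"), 1)
  expect_equal(min_substitutions("UGA", "F"), 2)
  expect_error(min_substitutions("AAA", "W"), "stop")
  expect_error(min_substitutions("UGA", "B"), "amino acid")
})

test_that("junction entries appear only for boundaries absent from the reference", {
  g <- default_genome()
  ref <- reference_junction_set(g$transcripts)
  ents <- build_junction_entries(g$novel_transcripts, ref)
  expect_equal(nrow(ents), length(g$novel_transcripts))
  # all junctions annotated -> nothing; single exon -> nothing
  ents0 <- build_junction_entries(g$transcripts[1:10], ref)
  expect_equal(nrow(ents0), 0)
  # every planted junction yields exactly one entry spanning its peptide
  jt <- g$truth$junctions
  for (r in seq_len(nrow(jt))) {
    sub <- ents[ents$transcript_id == jt$novel_transcript_id[r], ]
    expect_equal(nrow(sub), 1)
    expect_match(sub$sequence, jt$insert_peptide[r], fixed = TRUE)
    expect_match(sub$detail, paste0("donor_end=", jt$donor_end[r]), fixed = TRUE)
  }
})

test_that("database FASTA writing is deterministic and round-trips all fields", {
  tx <- hm13_like()
  entries <- rbind(canonical_entries(list(tx)),
                   build_nterm_extensions(tx),
                   build_readthrough_entries(tx))
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "a.fasta"); p2 <- file.path(dir, "b.fasta")
  write_database(entries, p1)
  write_database(entries, p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- read_database(p1)
  expect_equal(nrow(back), nrow(entries))
  reord <- entries[match(back$accession, entries$accession), ]
  rownames(back) <- rownames(reord) <- NULL
  expect_equal(back, reord)
  # duplicate accessions error; empty input -> empty file
  expect_error(write_database(rbind(entries, entries[1, ]), p1), "duplicate")
  write_database(entries[0, ], p1)
  expect_equal(nrow(read_database(p1)), 0)
})

test_that("extension entries contain the annotated protein as suffix/prefix everywhere", {
  g <- default_genome()
  entries <- default_entries()
  canon <- entries[entries$category == "canonical", ]
  prot_of <- setNames(canon$sequence, canon$transcript_id)
  nterm <- entries[entries$category == "nterm_extension", ]
  expect_true(all(mapply(function(s, t) endsWith(s, prot_of[[t]]) &&
                           nchar(s) > nchar(prot_of[[t]]),
                         nterm$sequence, nterm$transcript_id)))
  rt <- entries[entries$category == "readthrough", ]
  expect_true(all(mapply(function(s, t) startsWith(s, prot_of[[t]]) &&
                           nchar(s) > nchar(prot_of[[t]]),
                         rt$sequence, rt$transcript_id)))
})
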