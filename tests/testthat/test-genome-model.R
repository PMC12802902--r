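test_that("translation handles direct lookup, stops and partial codons", {
  expect_equal(translate_nt("AUGGAUCUG", 0), "MDL")
  expect_equal(translate_nt("UGGUGA", 0), "W")        # stop terminates
  expect_equal(translate_nt("ATGGATCTG", 0), "MDL")   # T/U interchangeable
  expect_equal(translate_nt("AATGGGA", 1), "MG")      # frame offset
  expect_equal(translate_nt("ATGGA", 0), "M")         # trailing partial codon
  expect_equal(translate_nt("ATNGGG", 0), "XG")       # N -> X
  expect_error(translate_nt("ATGQ", 0), "outside")
})

test_that("translation matches the independent code-table oracle in all frames", {
  set.seed(101)
  for (k in 1:60) {
    s <- random_dna(300)
    for (f in 0:2) {
      expect_equal(translate_nt(s, f), oracle_translate(s, f),
                   info = sprintf("frame %d", f))
    }
  }
})

test_that("UTR extraction respects CDS boundaries (stop codon in CDS)", {
  tx <- toy_transcript(utr5 = "CCAACCCCA", cds = "ATGAAGCGCTAA",
                       utr3 = "GTTCCA")
  expect_equal(nchar(utr5(tx)), 9)
  expect_equal(utr5(tx), "CCAACCCCA")
  expect_equal(utr3(tx), "GTTCCA")
  expect_equal(protein_sequence(tx), "MKR")
  # empty 3' UTR when the CDS runs to the transcript end
  tx2 <- toy_transcript(utr5 = "CCAACC", cds = "ATGAAGTAA", utr3 = "")
  expect_equal(utr3(tx2), "")
  # non-coding transcript errors
  nc <- transcript_model("NC1", "gNC1", "chrNC1", "+",
                         data.frame(start = 0, end = 12), "ACCACCACCACC")
  expect_error(utr5(nc), "no CDS")
})

test_that("transcript invariants are enforced", {
  expect_error(transcript_model("T", "g", "c", "+",
                                data.frame(start = 10, end = 5), "AAAAA"),
               "start < end")
  expect_error(transcript_model("T", "g", "c", "+",
                                data.frame(start = 0, end = 4), "AAAAA"),
               "length")
  # CDS length not a multiple of 3 -> flagged invalid, treated non-coding
  tx <- transcript_model("T", "g", "c", "+", data.frame(start = 0, end = 10),
                         "ATGAAGTAAC", cds_start = 0, cds_end = 10)
  expect_true(tx$cds_invalid)
  expect_true(is.na(tx$cds_start))
  # CDS without terminal stop -> incomplete
  tx2 <- toy_transcript(cds = "ATGAAGAAA")
  expect_false(tx2$cds_complete)
})

test_that("minus-strand annotation reverse-complements the locus", {
  # genomic "AAAC" on the minus strand splices to "GTTT" (GUUU in RNA)
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fa")
  write_genome_fasta(c(chrM = "AAAC"), fa)
  tx <- transcript_model("M1", "gM", "chrM", "-",
                         data.frame(start = 0, end = 4), "GTTT")
  gtf <- file.path(dir, "m.gtf")
  write_annotation(list(tx), gtf)
  back <- suppressMessages(read_annotation(gtf, fa))
  expect_equal(back$M1$spliced_sequence, "GTTT")

  # translating a minus-strand CDS equals the plus-strand construction of
  # the reverse-complemented locus
  cds <- "ATGGATAAGTGGCGCTAA"
  spliced <- paste0("CCAACC", cds, "GTTCCA")
  plus <- transcript_model("P", "g", "c", "+",
                           data.frame(start = 0, end = nchar(spliced)),
                           spliced, 6, 6 + nchar(cds))
  dirm <- withr::local_tempdir()
  contig_m <- setNames(
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(spliced))),
    "chrRC")
  write_genome_fasta(contig_m, file.path(dirm, "g.fa"))
  minus <- transcript_model("Mx", "g", "chrRC", "-",
                            data.frame(start = 0, end = nchar(spliced)),
                            spliced, 6, 6 + nchar(cds))
  write_annotation(list(minus), file.path(dirm, "m.gtf"))
  back_m <- suppressMessages(read_annotation(file.path(dirm, "m.gtf"),
                                             file.path(dirm, "g.fa")))
  expect_equal(protein_sequence(back_m$Mx), protein_sequence(plus))
})

test_that("GTF round-trip reproduces transcript models exactly", {
  cfg <- synthetic_config(n_transcripts = 40)
  dir <- withr::local_tempdir()
  g <- suppressMessages(generate_genome(cfg, dir))
  back <- suppressMessages(read_annotation(file.path(dir, "annotation.gtf"),
                                           file.path(dir, "genome.fasta")))
  expect_setequal(names(back), names(g$transcripts))
  for (id in names(g$transcripts)) {
    a <- g$transcripts[[id]]
    b <- back[[id]]
    expect_equal(a$spliced_sequence, b$spliced_sequence)
    expect_equal(a$exons, b$exons)
    expect_equal(a$cds_start, b$cds_start)
    expect_equal(a$cds_end, b$cds_end)
    expect_equal(a$strand, b$strand)
    expect_equal(a$cds_complete, b$cds_complete)
  }
})

test_that("missing contigs are a hard error naming the contig", {
  dir <- withr::local_tempdir()
  write_genome_fasta(c(chrA = "ACCACCACCACCACC"), file.path(dir, "g.fa"))
  tx <- transcript_model("T1", "g1", "chrB", "+",
                         data.frame(start = 0, end = 6), "ACCACC")
  write_annotation(list(tx), file.path(dir, "a.gtf"))
  expect_error(read_annotation(file.path(dir, "a.gtf"), file.path(dir, "g.fa")),
               "chrB")
})
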