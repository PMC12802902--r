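# Independent oracles and shared fixtures for the test suite. The oracles
# deliberately take different routes than the package implementation:
# translation uses Biostrings' GENETIC_CODE table, digestion enumerates all
# boundary pairs, masses are summed from elemental compositions.

# -- translation oracle ------------------------------------------------------

oracle_translate <- function(seq, frame) {
  seq <- chartr("Uu", "Tt", toupper(seq))
  code <- Biostrings::GENETIC_CODE
  out <- character()
  i <- frame + 1
  while (i + 2 <= nchar(seq)) {
    codon <- substr(seq, i, i + 2)
    if (grepl("N", codon)) {
      out <- c(out, "X")
    } else {
      aa <- code[[codon]]
      if (aa == "*") break
      out <- c(out, aa)
    }
    i <- i + 3
  }
  paste(out, collapse = "")
}

# -- digestion oracle: all (start, end) pairs with valid tryptic boundaries --

oracle_digest <- function(seq, max_missed, min_len, max_len) {
  res <- strsplit(seq, "")[[1]]
  n <- length(res)
  cleavable <- which(res %in% c("K", "R"))
  cleavable <- cleavable[cleavable < n & res[pmin(cleavable + 1, n)] != "P"]
  ok_start <- c(1, cleavable + 1)
  ok_end <- c(cleavable, n)
  out <- list()
  for (s in ok_start) {
    for (e in ok_end) {
      if (e < s) next
      len <- e - s + 1
      if (len < min_len || len > max_len) next
      missed <- sum(cleavable >= s & cleavable < e)
      if (missed > max_missed) next
      out[[length(out) + 1]] <- data.frame(
        sequence = substr(seq, s, e), start = s, end = e,
        missed_cleavages = missed
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(sequence = character(), start = integer(),
                      end = integer(), missed_cleavages = integer()))
  }
  do.call(rbind, out)
}

# -- codon-distance oracle over Biostrings' code table -----------------------

oracle_min_substitutions <- function(stop_codon, aa) {
  stop_codon <- chartr("U", "T", stop_codon)
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)[code == aa]
  sc <- strsplit(stop_codon, "")[[1]]
  min(vapply(codons, function(cc) {
    sum(strsplit(cc, "")[[1]] != sc)
  }, numeric(1)))
}

# -- elemental-composition mass oracle ---------------------------------------

oracle_peptide_mass <- function(seq) {
  atoms <- c(H = 1.00782503207, C = 12, N = 14.0030740048,
             O = 15.9949146196, S = 31.97207100)
  comp <- list(  # residue compositions C,H,N,O,S
    G = c(2, 3, 1, 1, 0), A = c(3, 5, 1, 1, 0), S = c(3, 5, 1, 2, 0),
    P = c(5, 7, 1, 1, 0), V = c(5, 9, 1, 1, 0), T = c(4, 7, 1, 2, 0),
    C = c(3, 5, 1, 1, 1), L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
    N = c(4, 6, 2, 2, 0), D = c(4, 5, 1, 3, 0), Q = c(5, 8, 2, 2, 0),
    K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0), M = c(5, 9, 1, 1, 1),
    H = c(6, 7, 3, 1, 0), F = c(9, 9, 1, 1, 0), R = c(6, 12, 4, 1, 0),
    Y = c(9, 9, 1, 2, 0), W = c(11, 10, 2, 1, 0)
  )
  total <- c(C = 0, H = 2, N = 0, O = 1, S = 0)  # water
  for (r in strsplit(seq, "")[[1]]) {
    cc <- comp[[r]]
    total <- total + c(C = cc[1], H = cc[2], N = cc[3], O = cc[4], S = cc[5])
  }
  sum(total * atoms[c("C", "H", "N", "O", "S")])
}

# -- random sequence helpers -------------------------------------------------

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, TRUE),
        collapse = "")
}

# -- toy coding transcript built in code -------------------------------------
# utr5 | CDS (ATG ... stop) | utr3, single exon, plus strand

toy_transcript <- function(utr5 = "CCAACC", cds = "ATGGATAAGCGCTAA",
                           utr3 = "GTTTGCTAAACC", strand = "+",
                           id = "TOY1") {
  spliced <- paste0(utr5, cds, utr3)
  exons <- data.frame(start = 0L, end = nchar(spliced))
  transcript_model(id, paste0("g", id), paste0("chr", id), strand, exons,
                   spliced, nchar(utr5), nchar(utr5) + nchar(cds))
}

# -- shared default synthetic bundle (expensive; built once per test run) ----

.fixture_env <- new.env(parent = emptyenv())

default_genome <- function() {
  if (is.null(.fixture_env$genome)) {
    .fixture_env$genome <- suppressMessages(generate_genome(synthetic_config()))
  }
  .fixture_env$genome
}

default_entries <- function() {
  if (is.null(.fixture_env$entries)) {
    g <- default_genome()
    .fixture_env$entries <- suppressMessages(
      build_custom_db(g$transcripts, g$novel_transcripts)
    )
  }
  .fixture_env$entries
}

default_psms <- function() {
  if (is.null(.fixture_env$psms)) {
    .fixture_env$psms <- suppressMessages(
      generate_psms(synthetic_config(), default_entries(),
                    default_genome()$truth)
    )
  }
  .fixture_env$psms
}
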