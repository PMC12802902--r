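# Seeded generator of every input the pipeline consumes, with a
# machine-readable truth ledger: a toy genome + GTF with planted noncanonical
# events (near-cognate TIS extensions, uORFs, readthrough tracts, novel
# junctions), PSM tables with planted modification sites, and paired
# expression matrices with controllable mRNA-protein correlation.
#
# Sequence design makes planted events exactly recoverable: 5' UTR background
# is drawn from the {A, C} alphabet, which can contain no start codon (all
# permitted starts carry G or T) and no stop codon in any frame, so the only
# start-codon occurrences in a UTR are the planted ones. Planted inserts are
# encoded with codons chosen so that no start codon arises at any frame
# across codon boundaries, and the generator asserts this after assembly.

# Fixed codon per amino acid for encoding designed peptides. Codons avoid
# creating AUG/ACG/CUG/GUG/UUG at shifted frames when concatenated (checked
# by the generator's start-codon scan after assembly).
CODON_FOR <- c(
  A = "GCC", C = "TGC", D = "GAC", E = "GAG", F = "TTC", G = "GGC",
  H = "CAC", I = "ATC", K = "AAG", L = "CTC", M = "ATG", N = "AAC",
  P = "CCC", Q = "CAG", R = "CGC", S = "TCC", T = "ACC", V = "GTC",
  W = "TGG", Y = "TAC"
)

# Safe residues for random uORF bodies: their codons use only {A, C} letters,
# so uORF inserts cannot create spurious starts/stops in any frame.
SAFE_UORF_CODONS <- c(K = "AAA", N = "AAC", T = "ACC", Q = "CAA", H = "CAC",
                      P = "CCC")

encode_peptide <- function(aa) {
  paste(CODON_FOR[str_chars(aa)], collapse = "")
}

rand_bg <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C"), n, replace = TRUE), collapse = "")
}

rand_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rand_sense_codons <- function(n) {
  paste(sample(sense_codons(), n, replace = TRUE), collapse = "")
}

# Designed proteins planted in every default genome -------------------------

# A multi-PTM showcase protein: hosts an N-terminal acetylation site, a
# lysine carrying six acyl/methyl modification types, and enough P/S/T/Y/H/K
# residues for 26 distinct modified sites across 13 modification types.
DESIGNED_MULTIPTM <-
  "MGDHAPKGSFKYAWVLDKTPEHAPSKSSPYTPKPLPPGHKTAPVPSKAYSAPTKWNPQMLKVADLPGR"

# A "missing protein" with two unique tryptic peptides (the long one survives
# digestion intact because its internal arginine precedes a proline).
DESIGNED_MISSING <-
  "MAGTSLVKQHLAHGALPVATVDRPDFYPPAYEESLEVEKLTDNVSEGWFNKGITR"

# Shared tryptic segment planted into two distinct proteins so that its
# peptide maps ambiguously (0 unique peptides for either parent).
DESIGNED_SHARED_SEGMENT <- "ESTVAGDLNQFVR"

# Diagnostic peptides for planted events.
DIAG_TIS_PEPTIDE <- "MESDPER"          # N-terminal extension
DIAG_UORF_PEPTIDE <- "VLHLLSVAR"       # upstream ORF (after Met excision)
DIAG_JUNCTION_PEPTIDE <- "SQQTLDTTSSVPAPK"  # novel splice junction
DIAG_READTHROUGH_PEPTIDE <- "DLWLVSSR" # stop-codon readthrough (UGA -> Trp)

#' Generator configuration
#'
#' Captures every tunable of the synthetic-data generator. Event rates are
#' fractions of transcripts carrying each planted 5'/junction event; every
#' complete transcript additionally carries a defined readthrough extension
#' tract (the tract is a property of the 3' UTR, not a planted rate).
#' A fixed `seed` makes every emitted file byte-identical across runs.
#'
#' @param n_transcripts number of annotated transcripts (default 300).
#' @param tis_rate,uorf_rate,junction_rate,incomplete_rate event rates in
#'   `[0, 1]`.
#' @param min_uorf_aa minimum uORF length used downstream; the generator
#'   plants most uORFs at or above it and some below to exercise the filter.
#' @param n_cell_types number of cell types (default 28).
#' @param n_genes,n_enriched,enrichment_lfc expression-matrix scale, number
#'   of planted group-specific genes and their log2 effect.
#' @param latent_correlation planted latent (Gaussian-copula) correlation
#'   between the mRNA and protein layers.
#' @param n_low_coverage,n_boundary genes planted below / exactly at the 25%
#'   joint-coverage rule.
#' @param n_canonical_psms unmodified canonical PSMs emitted.
#' @param coverage_below_fraction fraction of unmodified PSMs drawn at or
#'   below the 0.5 fragment-coverage boundary.
#' @param n_trp_diox,n_met_diox planted tryptophan/methionine dioxidation
#'   sites (defaults preserve the roughly 3.9:1 excess of tryptophan over
#'   methionine dioxidation at a desk scale).
#' @param n_single_site_proteins,n_multi_site_proteins proteins planted with
#'   one, respectively several, biological PTM sites.
#' @param n_readthrough_events planted readthrough PSM events (mixture of
#'   single- and multi-substitution recodings).
#' @param seed integer random seed (default 17).
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_transcripts = 300, tis_rate = 0.10,
                             uorf_rate = 0.10, junction_rate = 0.05,
                             incomplete_rate = 0.02, min_uorf_aa = 6,
                             n_cell_types = 28, n_genes = 5000,
                             n_enriched = 200, enrichment_lfc = 3,
                             latent_correlation = 0.4, n_low_coverage = 50,
                             n_boundary = 10, n_canonical_psms = 600,
                             coverage_below_fraction = 0.3,
                             n_trp_diox = 394, n_met_diox = 102,
                             n_single_site_proteins = 100,
                             n_multi_site_proteins = 50,
                             n_readthrough_events = 12, seed = 17) {
  rates <- c(tis_rate, uorf_rate, junction_rate, incomplete_rate,
             coverage_below_fraction)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (abs(latent_correlation) > 1) stop("latent_correlation must be in [-1, 1]")
  cfg <- list(
    n_transcripts = n_transcripts, tis_rate = tis_rate, uorf_rate = uorf_rate,
    junction_rate = junction_rate, incomplete_rate = incomplete_rate,
    min_uorf_aa = min_uorf_aa, n_cell_types = n_cell_types,
    n_genes = n_genes, n_enriched = n_enriched,
    enrichment_lfc = enrichment_lfc,
    latent_correlation = latent_correlation,
    n_low_coverage = n_low_coverage, n_boundary = n_boundary,
    n_canonical_psms = n_canonical_psms,
    coverage_below_fraction = coverage_below_fraction,
    n_trp_diox = n_trp_diox, n_met_diox = n_met_diox,
    n_single_site_proteins = n_single_site_proteins,
    n_multi_site_proteins = n_multi_site_proteins,
    n_readthrough_events = n_readthrough_events, seed = as.integer(seed)
  )
  class(cfg) <- "synthetic_config"
  cfg
}

# Lay a spliced transcript onto a contig. `cuts` are transcript-space exon
# boundaries (strictly inside the transcript). The layout is built in
# transcript orientation and reverse-complemented for minus-strand
# transcripts; returned exon coordinates are genomic (0-based half-open) in
# transcript order, together with the layout (pre-flip) coordinates.
place_transcript <- function(spliced, cuts, strand, intron_len = 80,
                             flank_len = 50, intron_tail = "") {
  n_ex <- length(cuts) + 1L
  bounds <- c(0L, cuts, nchar(spliced))
  ex_seqs <- substring(spliced, bounds[-(n_ex + 1L)] + 1L, bounds[-1L])
  parts <- rand_nt(flank_len)
  fwd <- matrix(0L, nrow = n_ex, ncol = 2)
  pos <- flank_len
  for (i in seq_len(n_ex)) {
    fwd[i, ] <- c(pos, pos + nchar(ex_seqs[i]))
    parts <- c(parts, ex_seqs[i])
    pos <- pos + nchar(ex_seqs[i])
    if (i < n_ex) {
      intron <- paste0(rand_nt(intron_len),
                       if (i == n_ex - 1L) intron_tail else "")
      parts <- c(parts, intron)
      pos <- pos + nchar(intron)
    }
  }
  parts <- c(parts, rand_nt(flank_len))
  layout <- paste(parts, collapse = "")
  L <- nchar(layout)
  if (strand == "+") {
    exons <- data.frame(start = fwd[, 1], end = fwd[, 2])
    contig <- layout
  } else {
    exons <- data.frame(start = L - fwd[, 2], end = L - fwd[, 1])
    contig <- revcomp(layout)
  }
  list(contig = contig, exons = exons, fwd = fwd, layout_len = L)
}

flip_interval <- function(L, s, e) c(L - e, L - s)

assert_planted_starts <- function(u5, planted_pos, txid) {
  found <- scan_start_codons(u5, default_start_codons())
  if (!identical(sort(found), sort(as.integer(planted_pos)))) {
    stop("internal generator error: unplanned start codon in 5' UTR of ",
         txid, " (found ", paste(found, collapse = ","), "; planted ",
         paste(planted_pos, collapse = ","), ")")
  }
}

#' Generate the toy genome, annotation and planted-event truth ledger
#'
#' Emits a genome FASTA (one contig per gene), an annotation GTF, a GTF of
#' novel (junction-carrying) transcripts and the truth ledger. Transcripts
#' have 5'UTR/CDS/3'UTR structure on both strands; planted events are
#' in-frame near-cognate TIS, uORFs (including some below the length floor),
#' readthrough extension tracts with a known next stop, and novel exon-exon
#' junctions. Designed proteins (a multi-PTM showcase, a missing-protein
#' mirror with two unique peptides, a shared-peptide pair and a readthrough
#' diagnostic) are always included.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory; created if needed. When `NULL`, nothing is
#'   written and only in-memory objects are returned.
#' @return list with `transcripts`, `novel_transcripts` (transcript models),
#'   `contigs` (named sequences), `truth` (ledger list) and, when written,
#'   the file `paths`.
#' @export
generate_genome <- function(config = synthetic_config(), dir = NULL) {
  set.seed(derive_seed(config$seed, 1L))
  n <- config$n_transcripts
  n_tis <- round(config$tis_rate * n)
  n_uorf <- round(config$uorf_rate * n)
  n_junc <- round(config$junction_rate * n)
  n_inc <- round(config$incomplete_rate * n)
  n_special <- 5L  # multi-PTM, missing, shared pair (2), readthrough diag
  if (n_tis + n_uorf + n_junc + n_inc + n_special > n) {
    stop("config demands more events than transcripts")
  }
  types <- c(rep("tis", n_tis), rep("uorf", n_uorf), rep("junction", n_junc),
             rep("incomplete", n_inc),
             rep("plain", n - n_tis - n_uorf - n_junc - n_inc))
  # designed transcripts occupy the first plain slots
  plain_idx <- which(types == "plain")
  special_roles <- c("multiptm", "missing", "sharedA", "sharedB", "rtdiag")
  roles <- setNames(rep("", n), NULL)
  roles[plain_idx[seq_len(n_special)]] <- special_roles

  transcripts <- list()
  novel_transcripts <- list()
  contigs <- list()
  tis_rows <- list(); uorf_rows <- list(); implied_rows <- list()
  rt_rows <- list(); junc_rows <- list(); tx_rows <- list()
  special <- list()

  stops <- STOP_CODONS
  for (i in seq_len(n)) {
    type <- types[i]
    role <- roles[i]
    tid <- sprintf("TX%04d", i)
    gid <- sprintf("G%04d", i)
    chrom <- paste0("chr", tid)
    strand <- sample(c("+", "-"), 1)
    diag <- FALSE

    # ---- CDS ----
    if (role == "multiptm") {
      cds_body <- encode_peptide(substr(DESIGNED_MULTIPTM, 2,
                                        nchar(DESIGNED_MULTIPTM)))
      cds <- paste0("ATG", cds_body, sample(stops, 1))
    } else if (role == "missing") {
      cds_body <- encode_peptide(substr(DESIGNED_MISSING, 2,
                                        nchar(DESIGNED_MISSING)))
      cds <- paste0("ATG", cds_body, sample(stops, 1))
    } else if (role %in% c("sharedA", "sharedB")) {
      prot <- paste0("M", translate_nt(rand_sense_codons(40), 0),
                     "K", DESIGNED_SHARED_SEGMENT,
                     translate_nt(rand_sense_codons(30), 0), "R")
      cds <- paste0(encode_peptide(prot), sample(stops, 1))
    } else if (role == "rtdiag") {
      # protein ends ...K D L; readthrough as W then extension LVSSR...
      body <- paste0(rand_sense_codons(90), "AAA", "GAC", "CTC")
      cds <- paste0("ATG", body, "TGA")
    } else {
      n_body <- sample(80:200, 1)
      cds <- paste0("ATG", rand_sense_codons(n_body),
                    if (type == "incomplete") "" else sample(stops, 1))
    }

    # ---- 5' UTR ----
    planted_start_pos <- integer()
    if (type == "tis") {
      diag <- i == which(types == "tis")[1]
      tis_codon <- if (diag) "ACG" else sample(default_start_codons(), 1)
      head_len <- sample(15:60, 1)
      insert <- if (diag) paste0(tis_codon, encode_peptide("ESDPER"))
                else tis_codon
      # the first in-frame codon after the diagnostic insert is threonine so
      # no proline blocks tryptic cleavage after the ...ESDPER arginine
      tail_len <- 3L * sample(3:15, 1)
      tail_bg <- if (diag) paste0("ACC", rand_bg(tail_len - 3L))
                 else rand_bg(tail_len)
      # the fixed CC linker before the insert keeps the background/insert
      # boundary free of spurious start codons in every frame
      u5 <- paste0(rand_bg(head_len - 2L), "CC", insert, tail_bg)
      tis_pos <- head_len
      planted_start_pos <- tis_pos
    } else if (type == "uorf") {
      diag <- i == which(types == "uorf")[1]
      below_min <- !diag && (i %% 3 == 0) && config$min_uorf_aa >= 5
      start_codon <- if (diag) "ATG" else sample(default_start_codons(), 1)
      if (diag) {
        body_aa <- DIAG_UORF_PEPTIDE
      } else {
        len_aa <- if (below_min) config$min_uorf_aa - 3L
                  else sample(config$min_uorf_aa:15, 1) - 1L
        body_aa <- paste(sample(names(SAFE_UORF_CODONS), len_aa,
                                replace = TRUE), collapse = "")
      }
      body_nt <- if (diag) encode_peptide(body_aa)
                 else paste(SAFE_UORF_CODONS[str_chars(body_aa)],
                            collapse = "")
      # stop restricted to TAA/TAG: a TGA stop after a body ending in A or C
      # would create an unplanned ATG/CTG across the codon boundary
      insert <- paste0(start_codon, body_nt, sample(c("TAA", "TAG"), 1))
      head_len <- sample(10:40, 1)
      tail_len <- 3L * sample(4:12, 1) + sample(1:2, 1)  # out of CDS frame
      u5 <- paste0(rand_bg(head_len - 2L), "CC", insert, rand_bg(tail_len))
      planted_start_pos <- head_len
    } else {
      u5 <- rand_bg(sample(60:150, 1))
    }

    # ---- 3' UTR ----
    if (type == "incomplete") {
      u3 <- rand_bg(sample(30:90, 1))
      ext_aa <- NA_character_
    } else if (role == "rtdiag") {
      ext_aa <- "LVSSRTAE"
      u3 <- paste0(encode_peptide(ext_aa), "TAA", rand_bg(sample(30:60, 1)))
    } else {
      n_ext <- sample(2:15, 1)
      ext_nt <- rand_sense_codons(n_ext)
      ext_aa <- translate_nt(ext_nt, 0)
      u3 <- paste0(ext_nt, sample(stops, 1), rand_bg(sample(30:90, 1)))
    }

    assert_planted_starts(u5, planted_start_pos, tid)

    spliced <- paste0(u5, cds, u3)
    cds_start <- nchar(u5)
    cds_end <- cds_start + nchar(cds)

    # ---- exon structure & contig ----
    if (type == "junction") {
      diag <- i == which(types == "junction")[1]
      insert_aa <- if (diag) DIAG_JUNCTION_PEPTIDE else {
        paste0(paste(sample(c("A", "D", "E", "G", "H", "N", "Q", "S", "T",
                              "V"), sample(9:14, 1), replace = TRUE),
                     collapse = ""), "K")
      }
      insert_nt <- encode_peptide(insert_aa)
      # junction placed at a codon boundary right after a designed R codon
      m <- sample(20:50, 1)
      cut <- cds_start + 3L * m
      # rebuild the CDS so the codon before the cut is R and the codon after
      # is D (cleavable boundary, no proline block)
      body1 <- rand_sense_codons(m - 2L)
      body2 <- rand_sense_codons(sample(40:120, 1))
      cds <- paste0("ATG", body1, "CGC", "GAC", body2, sample(stops, 1))
      spliced <- paste0(u5, cds, u3)
      cds_end <- cds_start + nchar(cds)
      placed <- place_transcript(spliced, cut, strand,
                                 intron_len = sample(60:120, 1),
                                 intron_tail = insert_nt)
      tx <- transcript_model(tid, gid, chrom, strand, placed$exons, spliced,
                             cds_start, cds_end)
      # novel transcript: acceptor exon extended 5' by the insert
      fwd2 <- placed$fwd[2, ]
      L <- placed$layout_len
      ins_len <- nchar(insert_nt)
      if (strand == "+") {
        nov_exons <- data.frame(
          start = c(placed$exons$start[1], placed$exons$start[2] - ins_len),
          end = placed$exons$end)
      } else {
        nov_exons <- data.frame(
          start = placed$exons$start,
          end = c(placed$exons$end[1], placed$exons$end[2] + ins_len))
      }
      nov_spliced <- paste0(substr(spliced, 1, cut), insert_nt,
                            substr(spliced, cut + 1, nchar(spliced)))
      nov <- transcript_model(paste0(tid, "N"), gid, chrom, strand,
                              nov_exons, nov_spliced, cds_start,
                              cds_end + ins_len)
      novel_transcripts[[nov$transcript_id]] <- nov
      njs <- transcript_junctions(nov)
      junc_rows[[length(junc_rows) + 1L]] <- data.frame(
        novel_transcript_id = nov$transcript_id, base_transcript_id = tid,
        chrom = njs$chrom[1], donor_end = njs$donor_end[1],
        acceptor_start = njs$acceptor_start[1], strand = strand,
        insert_peptide = insert_aa,
        diagnostic = diag
      )
      contigs[[chrom]] <- placed$contig
    } else {
      n_ex <- sample(1:3, 1)
      cuts <- if (n_ex > 1) sort(sample(seq_len(nchar(spliced) - 1L),
                                        n_ex - 1L)) else integer()
      placed <- place_transcript(spliced, cuts, strand)
      tx <- transcript_model(tid, gid, chrom, strand, placed$exons, spliced,
                             cds_start, cds_end)
      contigs[[chrom]] <- placed$contig
    }
    transcripts[[tid]] <- tx

    # ---- truth rows ----
    tx_rows[[i]] <- data.frame(
      transcript_id = tid, gene_id = gid, chrom = chrom, strand = strand,
      type = type, role = role, utr5_len = nchar(u5),
      cds_start = cds_start, cds_end = nchar(u5) + nchar(cds),
      cds_complete = type != "incomplete", spliced_len = nchar(tx$spliced_sequence)
    )
    if (type == "tis") {
      p <- planted_start_pos
      seq_aa <- paste0("M", translate_nt(substr(tx$spliced_sequence, p + 4L,
                                                tx$cds_end), 0))
      tis_rows[[length(tis_rows) + 1L]] <- data.frame(
        transcript_id = tid, tis_codon = to_rna(substr(u5, p + 1L, p + 3L)),
        tis_pos = p, sequence = seq_aa,
        diagnostic_peptide = if (diag) DIAG_TIS_PEPTIDE else NA_character_
      )
      # the same in-frame start is also emitted by the 3-frame uORF scan
      implied_rows[[length(implied_rows) + 1L]] <- data.frame(
        transcript_id = tid,
        start_codon = to_rna(substr(u5, p + 1L, p + 3L)),
        utr_pos = p, sequence = seq_aa
      )
    }
    if (type == "uorf") {
      p <- planted_start_pos
      orf_aa <- paste0("M", if (diag) DIAG_UORF_PEPTIDE else body_aa)
      uorf_rows[[length(uorf_rows) + 1L]] <- data.frame(
        transcript_id = tid,
        start_codon = to_rna(substr(u5, p + 1L, p + 3L)),
        utr_pos = p, length_aa = nchar(orf_aa),
        below_min = if (diag) FALSE else below_min, sequence = orf_aa,
        diagnostic_peptide = if (diag) DIAG_UORF_PEPTIDE else NA_character_
      )
    }
    if (type != "incomplete") {
      rt_rows[[length(rt_rows) + 1L]] <- data.frame(
        transcript_id = tid,
        stop_codon = to_rna(substr(cds, nchar(cds) - 2L, nchar(cds))),
        extension = ext_aa,
        diagnostic = role == "rtdiag"
      )
    }
    if (role != "") special[[role]] <- tid
  }

  truth <- list(
    seed = config$seed,
    transcripts = do.call(rbind, tx_rows),
    tis = if (length(tis_rows)) do.call(rbind, tis_rows) else NULL,
    uorfs = if (length(uorf_rows)) do.call(rbind, uorf_rows) else NULL,
    implied_uorfs = if (length(implied_rows)) do.call(rbind, implied_rows)
                    else NULL,
    readthrough = if (length(rt_rows)) do.call(rbind, rt_rows) else NULL,
    junctions = if (length(junc_rows)) do.call(rbind, junc_rows) else NULL,
    special = special
  )

  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      genome_fasta = file.path(dir, "genome.fasta"),
      annotation_gtf = file.path(dir, "annotation.gtf"),
      novel_gtf = file.path(dir, "novel.gtf")
    )
    write_genome_fasta(unlist(contigs), paths$genome_fasta)
    write_annotation(transcripts, paths$annotation_gtf)
    if (length(novel_transcripts)) {
      write_annotation(novel_transcripts, paths$novel_gtf)
    }
  }
  list(transcripts = transcripts, novel_transcripts = novel_transcripts,
       contigs = contigs, truth = truth, paths = paths)
}

# Peptide index of a protein: digested peptides with coordinates, preferring
# low missed-cleavage counts for site coverage lookups.
peptide_index <- function(sequence) {
  digest(sequence, max_missed = 2, min_len = 7, max_len = 40)
}

covering_peptide <- function(pidx, pos) {
  hit <- pidx[pidx$start <= pos & pidx$end >= pos, , drop = FALSE]
  if (nrow(hit) == 0) return(NULL)
  hit[order(hit$missed_cleavages, hit$end - hit$start), ][1, , drop = FALSE]
}

#' Generate a PSM table with planted modification sites
#'
#' Draws PSMs from tryptic digests of the database built over the synthetic
#' genome and plants: (i) the multi-PTM showcase protein with 26 modified
#' sites across 13 biological modification types, (ii) tryptophan and
#' methionine dioxidation sites at the configured counts, (iii) proteins
#' with single and multiple biological PTM sites, (iv) readthrough PSMs
#' mixing single- and multi-substitution recodings, (v) missing-protein
#' evidence (two unique peptides, single unique peptides, and one
#' shared-only protein), and (vi) unmodified canonical PSMs with
#' fragment-ion coverage drawn on both sides of the 0.5 boundary. Planted
#' site PSMs always pass the coverage filter. Some sites are reported by
#' several PSMs to exercise site de-duplication.
#'
#' @param config a [synthetic_config()].
#' @param entries database entries built over the same genome (see
#'   [build_custom_db()]).
#' @param truth ledger from [generate_genome()]; extended and returned.
#' @param dir optional output directory for `psms.tsv` and `pe_levels.tsv`.
#' @return list with `psms`, `pe_levels` and the extended `truth`.
#' @export
generate_psms <- function(config, entries, truth, dir = NULL) {
  set.seed(derive_seed(config$seed, 2L))
  canon <- entries[entries$category == "canonical", , drop = FALSE]
  proteins <- setNames(canon$sequence, canon$accession)
  tx_of <- setNames(canon$transcript_id, canon$accession)
  acc_of_tx <- setNames(canon$accession, canon$transcript_id)
  cts <- sprintf("CT%02d", seq_len(config$n_cell_types))
  registry <- ptm_registry()

  special_accs <- vapply(truth$special, function(t) acc_of_tx[[t]],
                         character(1))
  pidx <- lapply(proteins, peptide_index)

  high_cov <- function(len) sample(seq.int(floor(len * 0.6) + 1L, len), 1)

  psm_rows <- list()
  site_rows <- list()
  add_site_psms <- function(acc, pos, mod_name, n_psm = 1L) {
    pep <- covering_peptide(pidx[[acc]], pos)
    if (is.null(pep)) return(FALSE)
    for (k in seq_len(n_psm)) {
      psm_rows[[length(psm_rows) + 1L]] <<- data.frame(
        peptide = pep$sequence,
        modifications = sprintf("%s@%d", mod_name, pos - pep$start + 1L),
        annotated_residues = high_cov(nchar(pep$sequence)),
        cell_type = sample(cts, 1), accessions = acc,
        category = "canonical", protein_start = pep$start
      )
    }
    site_rows[[length(site_rows) + 1L]] <<- data.frame(
      protein = acc, position = pos,
      residue = if (grepl("N-term", registry$targets[
        match(mod_name, registry$name)], fixed = TRUE) && pos == 1L) "N-term"
        else substr(proteins[[acc]], pos, pos),
      name = mod_name,
      class = registry$class[match(mod_name, registry$name)]
    )
    TRUE
  }

  # (i) multi-PTM showcase: 26 sites / 13 types
  mp_acc <- special_accs[["multiptm"]]
  mp_seq <- proteins[[mp_acc]]
  res_pos <- function(res, n) {
    p <- which(str_chars(mp_seq) == res)
    stopifnot(length(p) >= n)
    p[seq_len(n)]
  }
  k_all <- which(str_chars(mp_seq) == "K")
  k_show <- k_all[2]  # the K of GSFKYAWVLDK (second K overall)
  stopifnot(substr(mp_seq, k_show - 3, k_show) == "GSFK")
  mp_plan <- rbind(
    data.frame(pos = 1L, name = "Acetyl (Protein N-term)"),
    data.frame(pos = k_show,
               name = c("Methyl (K)", "Dimethyl (K)", "Trimethyl (K)",
                        "Propionyl (K)", "Butyryl (K)", "Lactyl (K)")),
    data.frame(pos = res_pos("P", 10), name = "Hydroxylation (P)"),
    data.frame(pos = res_pos("S", 4), name = "Phospho (S)"),
    data.frame(pos = res_pos("T", 3), name = "Phospho (T)"),
    data.frame(pos = res_pos("Y", 2), name = "Phospho (Y)"),
    data.frame(pos = res_pos("H", 3), name = "Methyl (H)"),
    data.frame(pos = setdiff(k_all, k_show)[1:2],
               name = "Hydroxylation (K)")
  )
  for (r in seq_len(nrow(mp_plan))) {
    ok <- add_site_psms(mp_acc, mp_plan$pos[r], mp_plan$name[r],
                        n_psm = 1L + (r %% 2L))
    if (!ok) stop("internal: multi-PTM site not covered by any peptide")
  }

  # (ii) dioxidation sites on W and M across ordinary proteins
  pool_accs <- setdiff(names(proteins), special_accs)
  residue_pool <- function(res) {
    out <- list()
    for (acc in pool_accs) {
      pos <- which(str_chars(proteins[[acc]]) == res)
      pos <- pos[vapply(pos, function(p) {
        !is.null(covering_peptide(pidx[[acc]], p))
      }, logical(1))]
      if (length(pos)) out[[acc]] <- pos
    }
    do.call(rbind, lapply(names(out), function(a) {
      data.frame(acc = a, pos = out[[a]])
    }))
  }
  w_pool <- residue_pool("W")
  m_pool <- residue_pool("M")
  if (is.null(w_pool) || nrow(w_pool) < config$n_trp_diox ||
      is.null(m_pool) || nrow(m_pool) < config$n_met_diox) {
    stop("config demands more dioxidation sites than the proteome can host")
  }
  w_sel <- w_pool[sample(nrow(w_pool), config$n_trp_diox), , drop = FALSE]
  m_sel <- m_pool[sample(nrow(m_pool), config$n_met_diox), , drop = FALSE]
  for (r in seq_len(nrow(w_sel))) {
    add_site_psms(w_sel$acc[r], w_sel$pos[r], "Dioxidation (W)",
                  n_psm = 1L + (r %% 3L == 0L))
  }
  for (r in seq_len(nrow(m_sel))) {
    add_site_psms(m_sel$acc[r], m_sel$pos[r], "Dioxidation (M)")
  }

  # (iii) single- and multi-site proteins (biological PTMs)
  bio <- registry[registry$class == "biological" &
                    !grepl("N-term", registry$targets), ]
  target_map <- strsplit(bio$targets, ",", fixed = TRUE)
  mods_for_residue <- function(res) {
    bio$name[vapply(target_map, function(t) res %in% t, logical(1))]
  }
  modifiable <- c("K", "S", "T", "Y", "R", "H", "E", "P")
  site_hosts <- sample(pool_accs,
                       config$n_single_site_proteins +
                         config$n_multi_site_proteins)
  for (h in seq_along(site_hosts)) {
    acc <- site_hosts[h]
    chars <- str_chars(proteins[[acc]])
    cand <- which(chars %in% modifiable)
    cand <- cand[vapply(cand, function(p) {
      !is.null(covering_peptide(pidx[[acc]], p))
    }, logical(1))]
    if (length(cand) == 0) next
    n_sites <- if (h <= config$n_single_site_proteins) 1L
               else min(length(cand), sample(2:6, 1))
    pos <- sample(cand, n_sites)
    for (p in pos) {
      add_site_psms(acc, p, sample(mods_for_residue(chars[p]), 1))
    }
  }

  # (iv) readthrough PSMs: diagnostic + mixed plausibility events
  rt_entries <- entries[entries$category == "readthrough", , drop = FALSE]
  rt_detail <- lapply(rt_entries$detail, parse_detail)
  rt_res <- vapply(rt_detail, `[[`, character(1), "residue")
  rt_stop <- vapply(rt_detail, `[[`, character(1), "stop_codon")
  rt_truth_rows <- list()
  add_rt_psm <- function(row_idx, n_ct = 1L) {
    ent <- rt_entries[row_idx, ]
    prot_len <- nchar(proteins[[acc_of_tx[[ent$transcript_id]]]])
    pep <- covering_peptide(peptide_index(ent$sequence), prot_len + 1L)
    if (is.null(pep)) return(FALSE)
    for (ct in sample(cts, n_ct)) {
      psm_rows[[length(psm_rows) + 1L]] <<- data.frame(
        peptide = pep$sequence, modifications = "",
        annotated_residues = high_cov(nchar(pep$sequence)),
        cell_type = ct, accessions = ent$accession,
        category = "readthrough", protein_start = pep$start
      )
    }
    rt_truth_rows[[length(rt_truth_rows) + 1L]] <<- data.frame(
      transcript_id = ent$transcript_id,
      stop_codon = rt_stop[row_idx], residue = rt_res[row_idx],
      min_sub = min_substitutions(rt_stop[row_idx], rt_res[row_idx]),
      peptide = pep$sequence
    )
    TRUE
  }
  diag_idx <- which(rt_entries$transcript_id == truth$special$rtdiag &
                      rt_res == "W")
  stopifnot(length(diag_idx) == 1)
  add_rt_psm(diag_idx, n_ct = 2L)
  cand_tx <- setdiff(unique(rt_entries$transcript_id),
                     unlist(truth$special))
  cand_tx <- sample(cand_tx)
  want_single <- ceiling(config$n_readthrough_events / 2)
  got_single <- 0L; got_multi <- 0L
  for (t in cand_tx) {
    if (got_single + got_multi >= config$n_readthrough_events) break
    rows_t <- which(rt_entries$transcript_id == t)
    subs <- vapply(rows_t, function(r) {
      min_substitutions(rt_stop[r], rt_res[r])
    }, integer(1))
    pick_single <- got_single < want_single
    pool <- rows_t[if (pick_single) subs == 1L else subs >= 2L]
    if (length(pool) == 0) next
    if (add_rt_psm(pool[sample(length(pool), 1)])) {
      if (pick_single) got_single <- got_single + 1L
      else got_multi <- got_multi + 1L
    }
  }

  # (v) missing-protein evidence
  ms_acc <- special_accs[["missing"]]
  ms_pep <- digest(proteins[[ms_acc]], max_missed = 0, min_len = 7,
                   max_len = 40)
  stopifnot("QHLAHGALPVATVDRPDFYPPAYEESLEVEK" %in% ms_pep$sequence)
  unique_ms <- ms_pep[ms_pep$sequence %in%
                        c("QHLAHGALPVATVDRPDFYPPAYEESLEVEK",
                          "LTDNVSEGWFNK"), , drop = FALSE]
  for (r in seq_len(nrow(unique_ms))) {
    psm_rows[[length(psm_rows) + 1L]] <- data.frame(
      peptide = unique_ms$sequence[r], modifications = "",
      annotated_residues = high_cov(nchar(unique_ms$sequence[r])),
      cell_type = cts[1], accessions = ms_acc, category = "canonical",
      protein_start = unique_ms$start[r]
    )
  }
  single_unique_accs <- sample(setdiff(pool_accs,
                                       c(w_sel$acc, m_sel$acc, site_hosts)),
                               3)
  su_rows <- list()
  for (acc in single_unique_accs) {
    pep <- pidx[[acc]][pidx[[acc]]$missed_cleavages == 0, , drop = FALSE]
    pep <- pep[sample(nrow(pep), 1), , drop = FALSE]
    psm_rows[[length(psm_rows) + 1L]] <- data.frame(
      peptide = pep$sequence, modifications = "",
      annotated_residues = high_cov(nchar(pep$sequence)),
      cell_type = sample(cts, 1), accessions = acc, category = "canonical",
      protein_start = pep$start
    )
    su_rows[[acc]] <- pep$sequence
  }
  shA <- special_accs[["sharedA"]]; shB <- special_accs[["sharedB"]]
  sh_start <- regexpr(DESIGNED_SHARED_SEGMENT, proteins[[shA]], fixed = TRUE)
  psm_rows[[length(psm_rows) + 1L]] <- data.frame(
    peptide = DESIGNED_SHARED_SEGMENT, modifications = "",
    annotated_residues = high_cov(nchar(DESIGNED_SHARED_SEGMENT)),
    cell_type = cts[2], accessions = paste(shA, shB, sep = ","),
    category = "canonical", protein_start = as.integer(sh_start)
  )
  pe_levels <- data.frame(
    accession = names(proteins),
    pe_level = ifelse(names(proteins) %in%
                        c(ms_acc, single_unique_accs, shA, shB),
                      "PE2", "PE1")
  )

  # (vi) unmodified canonical PSMs either side of the coverage boundary;
  # PE2 (missing-protein) accessions are excluded so their unique-peptide
  # counts stay exactly as planted
  n_can <- config$n_canonical_psms
  below <- runif(n_can) < config$coverage_below_fraction
  can_accs <- sample(setdiff(names(proteins),
                             c(ms_acc, single_unique_accs, shA, shB)),
                     n_can, replace = TRUE)
  for (k in seq_len(n_can)) {
    acc <- can_accs[k]
    px <- pidx[[acc]]
    if (nrow(px) == 0) next
    pep <- px[sample(nrow(px), 1), , drop = FALSE]
    len <- nchar(pep$sequence)
    ann <- if (below[k]) sample(seq.int(0L, floor(len / 2)), 1)
           else high_cov(len)
    psm_rows[[length(psm_rows) + 1L]] <- data.frame(
      peptide = pep$sequence, modifications = "", annotated_residues = ann,
      cell_type = sample(cts, 1), accessions = acc, category = "canonical",
      protein_start = pep$start
    )
  }

  psms <- do.call(rbind, psm_rows)
  psms <- psms[sample(nrow(psms)), , drop = FALSE]
  rownames(psms) <- NULL

  sites <- unique(do.call(rbind, site_rows))
  rownames(sites) <- NULL
  truth$ptm_sites <- sites
  truth$readthrough_psms <- do.call(rbind, rt_truth_rows)
  truth$missing <- list(
    two_unique = ms_acc,
    one_unique = setNames(unlist(su_rows), single_unique_accs),
    shared_only = c(shA, shB)
  )
  truth$multiptm <- list(accession = mp_acc, n_sites = 26L, n_types = 13L)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_psms(psms, file.path(dir, "psms.tsv"))
    write.table(pe_levels, file.path(dir, "pe_levels.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(psms = psms, pe_levels = pe_levels, truth = truth)
}

#' Generate paired mRNA/protein expression matrices
#'
#' Per gene, mRNA (TPM-like) and protein (LFQ-like) abundances share a latent
#' Gaussian signal with the configured correlation on the log scale; the
#' protein layer is emitted as three replicate columns per cell type (small
#' replicate noise) to be averaged before analysis. Planted features: genes
#' with protein missingness below the 25% joint-coverage rule, genes at
#' exactly the boundary, and group-specific genes with a known log2 effect
#' on the mRNA layer.
#'
#' @param config a [synthetic_config()].
#' @param truth optional ledger to extend.
#' @param dir optional output directory for `mrna.tsv`, `protein.tsv`,
#'   `groups.tsv`.
#' @return list with `mrna` (matrix), `protein` (replicate matrix),
#'   `groups` (named vector), and the extended `truth`.
#' @export
generate_expression <- function(config, truth = list(), dir = NULL) {
  set.seed(derive_seed(config$seed, 3L))
  n_g <- config$n_genes
  n_ct <- config$n_cell_types
  rho <- config$latent_correlation
  genes <- sprintf("G%05d", seq_len(n_g))
  cts <- sprintf("CT%02d", seq_len(n_ct))
  group_names <- c("endothelial", "epithelial", "mesenchymal")
  groups <- setNames(group_names[(seq_len(n_ct) - 1L) %% 3L + 1L], cts)

  mu_m <- rnorm(n_g, mean = 5, sd = 1.5)
  mu_p <- rnorm(n_g, mean = 8, sd = 1.5)
  z1 <- matrix(rnorm(n_g * n_ct), n_g, n_ct)
  z2 <- matrix(rnorm(n_g * n_ct), n_g, n_ct)
  y <- rho * z1 + sqrt(1 - rho^2) * z2

  enriched <- NULL
  log2_mrna <- mu_m + z1
  if (config$n_enriched > 0) {
    idx <- seq_len(config$n_enriched)
    grp <- group_names[(idx - 1L) %% 3L + 1L]
    for (k in idx) {
      log2_mrna[k, groups[cts] == grp[k]] <-
        log2_mrna[k, groups[cts] == grp[k]] + config$enrichment_lfc
    }
    enriched <- data.frame(gene = genes[idx], group = grp,
                           log2_fold_change = config$enrichment_lfc)
  }
  mrna <- round(2^log2_mrna, 4)
  dimnames(mrna) <- list(genes, cts)

  log2_prot <- mu_p + y
  reps <- lapply(1:3, function(r) {
    round(2^(log2_prot + matrix(rnorm(n_g * n_ct, sd = 0.1), n_g, n_ct)), 4)
  })
  protein <- do.call(cbind, lapply(seq_len(n_ct), function(j) {
    m <- cbind(reps[[1]][, j], reps[[2]][, j], reps[[3]][, j])
    colnames(m) <- paste0(cts[j], ".r", 1:3)
    m
  }))
  rownames(protein) <- genes

  # planted missingness: low-coverage genes keep 5/28 cell types (< 25%),
  # boundary genes keep exactly ceiling(0.25 * n_ct)
  n_low <- config$n_low_coverage
  n_bnd <- config$n_boundary
  low_ids <- bnd_ids <- character()
  mask_gene <- function(g, n_keep) {
    keep_ct <- sample(cts, n_keep)
    drop_cols <- !sub("\\.r[0-9]+$", "", colnames(protein)) %in% keep_ct
    protein[g, drop_cols] <<- NA_real_
  }
  if (n_low + n_bnd > 0) {
    pool <- genes[seq.int(config$n_enriched + 1L,
                          config$n_enriched + n_low + n_bnd)]
    low_ids <- pool[seq_len(n_low)]
    bnd_ids <- pool[n_low + seq_len(n_bnd)]
    n_quarter <- ceiling(0.25 * n_ct)
    for (g in low_ids) mask_gene(g, max(3L, floor(0.18 * n_ct)))
    for (g in bnd_ids) mask_gene(g, n_quarter)
  }

  truth$expression <- list(
    latent_correlation = rho, enriched = enriched,
    low_coverage_genes = low_ids, boundary_genes = bnd_ids,
    groups = as.list(groups)
  )

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_expression_matrix(mrna, file.path(dir, "mrna.tsv"), "gene")
    write_expression_matrix(protein, file.path(dir, "protein.tsv"), "protein")
    write.table(data.frame(cell_type = cts, group = unname(groups)),
                file.path(dir, "groups.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  list(mrna = mrna, protein = protein, groups = groups, truth = truth)
}

#' Write / read a truth ledger as JSON
#'
#' @param truth ledger list.
#' @param path JSON path.
#' @return `path` / the ledger list.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Generate the complete synthetic input bundle
#'
#' Runs the genome, PSM and expression generators under one configuration
#' (the database needed to draw PSMs is built internally with default
#' builder settings) and writes every pipeline input plus `truth.json` to
#' `dir`.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory.
#' @return list with the generators' outputs, the built `entries` and the
#'   combined `truth`.
#' @export
simulate_bundle <- function(config = synthetic_config(), dir = NULL) {
  gen <- generate_genome(config, dir)
  entries <- build_custom_db(gen$transcripts, gen$novel_transcripts,
                             min_uorf_aa = config$min_uorf_aa)
  ps <- generate_psms(config, entries, gen$truth, dir)
  ex <- generate_expression(config, ps$truth, dir)
  truth <- ex$truth
  if (!is.null(dir)) write_truth(truth, file.path(dir, "truth.json"))
  list(genome = gen, entries = entries, psms = ps$psms,
       pe_levels = ps$pe_levels, mrna = ex$mrna, protein = ex$protein,
       groups = ex$groups, truth = truth)
}
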