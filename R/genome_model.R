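# Transcript/annotation data model, genetic code machinery, and GTF/FASTA I/O.
#
# Coordinate conventions: internally all coordinates are 0-based half-open
# (both genomic exon intervals and transcript-space CDS offsets). GTF I/O
# converts to/from the 1-based inclusive convention at the boundary. The CDS
# span includes the stop codon; GTF files that annotate the stop codon as a
# separate stop_codon feature have it merged into the CDS on import.

#' The standard genetic code
#'
#' Returns the nuclear genetic code as a named character vector mapping the 64
#' DNA codons to one-letter amino acids, with `"*"` for the three stop codons
#' (TAG, TAA, TGA; UAG/UAA/UGA in RNA convention). Only the standard code is
#' supported.
#'
#' @return named character vector of length 64.
#' @export
#' @examples
#' genetic_code()[["ATG"]]
genetic_code <- function() {
  c(
    TTT = "F", TTC = "F", TTA = "L", TTG = "L",
    CTT = "L", CTC = "L", CTA = "L", CTG = "L",
    ATT = "I", ATC = "I", ATA = "I", ATG = "M",
    GTT = "V", GTC = "V", GTA = "V", GTG = "V",
    TCT = "S", TCC = "S", TCA = "S", TCG = "S",
    CCT = "P", CCC = "P", CCA = "P", CCG = "P",
    ACT = "T", ACC = "T", ACA = "T", ACG = "T",
    GCT = "A", GCC = "A", GCA = "A", GCG = "A",
    TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
    CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
    AAT = "N", AAC = "N", AAA = "K", AAG = "K",
    GAT = "D", GAC = "D", GAA = "E", GAG = "E",
    TGT = "C", TGC = "C", TGA = "*", TGG = "W",
    CGT = "R", CGC = "R", CGA = "R", CGG = "R",
    AGT = "S", AGC = "S", AGA = "R", AGG = "R",
    GGT = "G", GGC = "G", GGA = "G", GGG = "G"
  )
}

STOP_CODONS <- c("TAG", "TAA", "TGA")

# Sense codons (61) as a character vector.
sense_codons <- function() {
  code <- genetic_code()
  names(code)[code != "*"]
}

# Codons encoding a given one-letter amino acid.
codons_for <- function(aa) {
  code <- genetic_code()
  names(code)[code == aa]
}

#' Translate a nucleotide sequence
#'
#' Translates `nucleotides` starting at reading-frame offset `frame`,
#' terminating at (and excluding) the first stop codon. A trailing incomplete
#' codon is ignored. Codons containing `N` translate to `X`.
#'
#' @param nucleotides nucleotide string (DNA or RNA alphabet; U and T are
#'   interchangeable).
#' @param frame reading-frame offset, one of 0, 1, 2.
#' @return amino-acid string.
#' @export
#' @examples
#' translate_nt("AUGGAUCUG", 0)  # "MDL"
translate_nt <- function(nucleotides, frame = 0) {
  stopifnot(length(nucleotides) == 1, frame %in% 0:2)
  s <- norm_dna(nucleotides)
  if (grepl("[^ACGTN]", s)) {
    stop("sequence contains characters outside {A,C,G,U/T,N}")
  }
  n <- nchar(s)
  if (n - frame < 3) return("")
  starts <- seq.int(frame + 1L, n - 2L, by = 3L)
  codons <- substring(s, starts, starts + 2L)
  aa <- unname(genetic_code()[codons])
  aa[is.na(aa)] <- "X"  # codons containing N
  stop_at <- match("*", aa)
  if (!is.na(stop_at)) aa <- aa[seq_len(stop_at - 1L)]
  paste(aa, collapse = "")
}

#' Construct a transcript model
#'
#' A spliced transcript with strand, exon coordinates and (optionally) CDS
#' boundaries in transcript space. Exons are stored in transcript (5'->3')
#' order as 0-based half-open genomic intervals; for minus-strand transcripts
#' that order is genomically descending. The CDS span includes the stop codon,
#' so for a complete annotation the codon at `cds_end - 3` is a stop.
#'
#' @param transcript_id,gene_id identifiers.
#' @param chrom contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with 0-based half-open `start`, `end` columns, in
#'   transcript order.
#' @param spliced_sequence nucleotide string in transcript orientation.
#' @param cds_start,cds_end transcript-space 0-based half-open CDS offsets, or
#'   `NA` for non-coding transcripts.
#' @return object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             spliced_sequence, cds_start = NA_integer_,
                             cds_end = NA_integer_) {
  stopifnot(strand %in% c("+", "-"))
  spliced_sequence <- norm_dna(spliced_sequence)
  exons <- as.data.frame(exons)[, c("start", "end")]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  rownames(exons) <- NULL
  if (any(exons$start >= exons$end)) stop("exon intervals must satisfy start < end")
  if (nrow(exons) > 1) {
    gsorted <- exons[order(exons$start), ]
    if (any(gsorted$end[-nrow(gsorted)] > gsorted$start[-1])) {
      stop("exons overlap")
    }
    tx_ord <- if (strand == "+") order(exons$start) else order(-exons$start)
    if (!identical(tx_ord, seq_len(nrow(exons)))) {
      stop("exons must be given in transcript (5'->3') order")
    }
  }
  if (sum(exons$end - exons$start) != nchar(spliced_sequence)) {
    stop("spliced sequence length must equal the sum of exon lengths")
  }
  cds_complete <- NA
  cds_invalid <- FALSE
  if (!is.na(cds_start)) {
    len <- cds_end - cds_start
    if (len <= 0 || len %% 3 != 0) {
      cds_invalid <- TRUE
    } else {
      cds_complete <- substr(spliced_sequence, cds_end - 2, cds_end) %in% STOP_CODONS
    }
  }
  structure(
    list(
      transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
      strand = strand, exons = exons, spliced_sequence = spliced_sequence,
      cds_start = if (isTRUE(cds_invalid)) NA_integer_ else as.integer(cds_start),
      cds_end = if (isTRUE(cds_invalid)) NA_integer_ else as.integer(cds_end),
      cds_complete = cds_complete, cds_invalid = cds_invalid
    ),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf(
    "<transcript_model> %s (%s) %s%s, %d exon(s), %d nt%s\n",
    x$transcript_id, x$gene_id, x$chrom, x$strand, nrow(x$exons),
    nchar(x$spliced_sequence),
    if (is.na(x$cds_start)) ", non-coding"
    else sprintf(", CDS [%d,%d)%s", x$cds_start, x$cds_end,
                 if (isTRUE(x$cds_complete)) "" else " (incomplete)")
  ))
  invisible(x)
}

has_cds <- function(tx) !is.na(tx$cds_start)

#' 5' and 3' untranslated regions of a coding transcript
#'
#' `utr5()` returns `spliced_sequence[0, cds_start)`; `utr3()` returns
#' `spliced_sequence[cds_end, end)`. The stop codon belongs to the CDS span,
#' so the 3' UTR starts immediately after it.
#'
#' @param tx a [transcript_model()].
#' @return nucleotide string (possibly empty).
#' @export
utr5 <- function(tx) {
  if (!has_cds(tx)) stop("transcript ", tx$transcript_id, " has no CDS")
  substr(tx$spliced_sequence, 1, tx$cds_start)
}

#' @rdname utr5
#' @export
utr3 <- function(tx) {
  if (!has_cds(tx)) stop("transcript ", tx$transcript_id, " has no CDS")
  substr(tx$spliced_sequence, tx$cds_end + 1, nchar(tx$spliced_sequence))
}

#' CDS nucleotide sequence and annotated protein of a transcript
#'
#' `cds_sequence()` returns the CDS span (including the stop codon);
#' `protein_sequence()` its translation up to the stop.
#'
#' @param tx a [transcript_model()].
#' @return character string.
#' @export
cds_sequence <- function(tx) {
  if (!has_cds(tx)) stop("transcript ", tx$transcript_id, " has no CDS")
  substr(tx$spliced_sequence, tx$cds_start + 1, tx$cds_end)
}

#' @rdname cds_sequence
#' @export
protein_sequence <- function(tx) translate_nt(cds_sequence(tx), 0)

# Map a genomic position (0-based) to transcript-space offset (0-based).
genomic_to_transcript <- function(tx, gpos) {
  offset <- 0L
  for (i in seq_len(nrow(tx$exons))) {
    s <- tx$exons$start[i]; e <- tx$exons$end[i]
    if (gpos >= s && gpos < e) {
      return(offset + if (tx$strand == "+") gpos - s else (e - 1L) - gpos)
    }
    offset <- offset + (e - s)
  }
  stop("genomic position ", gpos, " is not exonic in ", tx$transcript_id)
}

#' Read transcript models from a GTF annotation and genome FASTA
#'
#' Assembles each transcript's spliced sequence in transcript orientation
#' (reverse-complemented for minus-strand transcripts) and converts genomic
#' CDS coordinates to transcript-space offsets. `stop_codon` features, when
#' present, are merged into the CDS span. Transcripts whose CDS length is not
#' a positive multiple of 3 are flagged invalid (treated as non-coding for
#' database building) with a warning; transcripts with a CDS that does not end
#' in a stop codon are marked incomplete.
#'
#' @param gtf_path GTF file (1-based inclusive coordinates; `gene_id` and
#'   `transcript_id` attributes required).
#' @param fasta_path genome FASTA containing every referenced contig.
#' @return named list of [transcript_model()] objects.
#' @export
read_annotation <- function(gtf_path, fasta_path) {
  gr <- rtracklayer::import(gtf_path)
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*", "", names(genome))

  gr <- gr[gr$type %in% c("exon", "CDS", "stop_codon")]
  tx_ids <- unique(gr$transcript_id)
  out <- vector("list", length(tx_ids))
  names(out) <- tx_ids

  for (txid in tx_ids) {
    sub <- gr[gr$transcript_id == txid]
    chrom <- as.character(GenomicRanges::seqnames(sub))[1]
    strand <- as.character(GenomicRanges::strand(sub))[1]
    if (!chrom %in% names(genome)) {
      stop("contig '", chrom, "' referenced by ", txid, " is missing from the FASTA")
    }
    ex <- sub[sub$type == "exon"]
    exdf <- data.frame(
      start = GenomicRanges::start(ex) - 1L,  # to 0-based half-open
      end = GenomicRanges::end(ex)
    )
    exdf <- exdf[order(exdf$start), ]
    if (strand == "-") exdf <- exdf[rev(seq_len(nrow(exdf))), ]
    rownames(exdf) <- NULL
    pieces <- substring(
      as.character(genome[[chrom]]),
      if (strand == "+") exdf$start + 1L else exdf$start + 1L,
      exdf$end
    )
    if (strand == "-") pieces <- vapply(pieces, revcomp, character(1))
    spliced <- paste(pieces, collapse = "")

    cds_start <- cds_end <- NA_integer_
    cds_feats <- sub[sub$type %in% c("CDS", "stop_codon")]
    if (length(cds_feats) > 0) {
      g_lo <- min(GenomicRanges::start(cds_feats)) - 1L
      g_hi <- max(GenomicRanges::end(cds_feats))  # 0-based half-open span
      tmp <- transcript_model(txid, "tmp", chrom, strand, exdf, spliced)
      if (strand == "+") {
        cds_start <- genomic_to_transcript(tmp, g_lo)
        cds_end <- genomic_to_transcript(tmp, g_hi - 1L) + 1L
      } else {
        cds_start <- genomic_to_transcript(tmp, g_hi - 1L)
        cds_end <- genomic_to_transcript(tmp, g_lo) + 1L
      }
    }
    gene_id <- sub$gene_id[1]
    tx <- transcript_model(txid, gene_id, chrom, strand, exdf, spliced,
                           cds_start, cds_end)
    if (tx$cds_invalid) {
      log_warn("transcript ", txid, " has a CDS whose length is not a positive ",
               "multiple of 3; flagged and excluded from database building")
    } else if (isFALSE(tx$cds_complete)) {
      log_warn("transcript ", txid, " has an annotated CDS without a terminal ",
               "stop codon; retained for TIS/uORF building, excluded from ",
               "readthrough building")
    }
    out[[txid]] <- tx
  }
  out
}

#' Write transcript models to a GTF file
#'
#' Emits `exon` and `CDS` features (the CDS features span through the stop
#' codon, matching this package's import convention) with 1-based inclusive
#' coordinates. Re-reading the file with [read_annotation()] against the same
#' genome FASTA reproduces the models.
#'
#' @param transcripts list of [transcript_model()] objects.
#' @param path output GTF path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(transcripts, path) {
  rows <- list()
  for (tx in transcripts) {
    exdf <- tx$exons
    n <- nrow(exdf)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = tx$chrom, start = exdf$start + 1L, end = exdf$end,
      strand = tx$strand, type = "exon", phase = NA_integer_,
      gene_id = tx$gene_id, transcript_id = tx$transcript_id
    )
    if (has_cds(tx)) {
      # Transcript-space CDS -> genomic CDS pieces per exon, with phase.
      offset <- 0L
      cds_sofar <- 0L
      for (i in seq_len(n)) {
        w <- exdf$end[i] - exdf$start[i]
        lo_t <- max(tx$cds_start, offset)
        hi_t <- min(tx$cds_end, offset + w)
        if (lo_t < hi_t) {
          if (tx$strand == "+") {
            gs <- exdf$start[i] + (lo_t - offset)
            ge <- exdf$start[i] + (hi_t - offset)
          } else {
            ge <- exdf$end[i] - (lo_t - offset)
            gs <- exdf$end[i] - (hi_t - offset)
          }
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = tx$chrom, start = gs + 1L, end = ge,
            strand = tx$strand, type = "CDS",
            phase = (3L - cds_sofar %% 3L) %% 3L,
            gene_id = tx$gene_id, transcript_id = tx$transcript_id
          )
          cds_sofar <- cds_sofar + (hi_t - lo_t)
        }
        offset <- offset + w
      }
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand
  )
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$phase <- df$phase
  S4Vectors::mcols(gr)$gene_id <- df$gene_id
  S4Vectors::mcols(gr)$transcript_id <- df$transcript_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Write a named set of nucleotide sequences as FASTA
#'
#' @param seqs named character vector of DNA sequences.
#' @param path output path; lines wrap at 60 columns.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(unlist(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}
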