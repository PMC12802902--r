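# Construction of the custom protein sequence database: N-terminal extensions
# from near-cognate translation-initiation sites (TIS), upstream ORFs,
# translational-readthrough C-terminal extensions, and novel splice-junction
# windows. Entries are plain data.frames with one row per database entry and a
# machine-parseable accession dialect:
#
#   nc|<category>|<transcript_id>|<detail>
#
# where <detail> is a semicolon-separated key=value list. Codons inside
# details are reported in RNA letters (UAG/UAA/UGA etc.).

#' Default near-cognate start-codon set
#'
#' AUG plus the four near-cognate codons differing from AUG by one base that
#' are commonly used at alternative translation-initiation sites.
#'
#' @return character vector of codons (DNA alphabet).
#' @export
default_start_codons <- function() c("ATG", "ACG", "CTG", "GTG", "TTG")

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

new_entries <- function(accession = character(), category = character(),
                        transcript_id = character(), sequence = character(),
                        detail = character(), flagged = logical()) {
  data.frame(
    accession = accession, category = category, transcript_id = transcript_id,
    sequence = sequence, detail = detail, flagged = flagged,
    stringsAsFactors = FALSE
  )
}

make_accession <- function(category, transcript_id, detail, flagged) {
  d <- if (flagged) paste0(detail, ";flagged=1") else detail
  paste("nc", category, transcript_id, d, sep = "|")
}

entry_row <- function(category, transcript_id, sequence, detail,
                      flagged = FALSE) {
  new_entries(
    accession = make_accession(category, transcript_id, detail, flagged),
    category = category, transcript_id = transcript_id, sequence = sequence,
    detail = detail, flagged = flagged
  )
}

# Parse a detail string "k=v;k=v" into a named character vector.
parse_detail <- function(detail) {
  if (is.na(detail) || detail == "") return(character())
  kv <- strsplit(strsplit(detail, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  setNames(vapply(kv, `[`, character(1), 2), vapply(kv, `[`, character(1), 1))
}

# All start-codon positions (0-based) within a nucleotide string.
scan_start_codons <- function(s, start_codons) {
  n <- nchar(s)
  if (n < 3) return(integer())
  pos <- seq_len(n - 2L)
  codons <- substring(s, pos, pos + 2L)
  pos[codons %in% start_codons] - 1L
}

#' Build N-terminal extension entries from in-frame upstream start sites
#'
#' Scans the 5' UTR for permitted start codons that are in frame with the
#' annotated CDS and have no in-frame stop codon between them and the
#' annotated start. Each hit yields one entry whose sequence is `M` followed
#' by the translation from the codon after the TIS through the annotated
#' protein: the initiator residue is always methionine, also at non-AUG
#' codons. The annotated protein is therefore a strict suffix of every entry.
#'
#' @param tx a coding [transcript_model()] (invalid-CDS transcripts yield an
#'   error).
#' @param start_codons permitted TIS codons (default
#'   [default_start_codons()]); U/T interchangeable.
#' @return entries data.frame, ordered 5'->3'; empty for an empty 5' UTR.
#' @export
build_nterm_extensions <- function(tx, start_codons = default_start_codons()) {
  start_codons <- norm_dna(start_codons)
  u5 <- utr5(tx)
  out <- new_entries()
  if (nchar(u5) < 3) return(out)
  cs <- tx$cds_start
  spliced <- tx$spliced_sequence
  cand <- scan_start_codons(u5, start_codons)
  cand <- cand[cand %% 3 == cs %% 3 & cand + 3L <= cs]
  for (p in sort(cand)) {
    # in-frame stop between the candidate TIS and the annotated start?
    between <- substr(spliced, p + 4L, cs)
    if (nchar(between) >= 3) {
      bp <- seq.int(1L, nchar(between) - 2L, by = 3L)
      if (any(substring(between, bp, bp + 2L) %in% STOP_CODONS)) next
    }
    seq_aa <- paste0("M", translate_nt(substr(spliced, p + 4L, tx$cds_end), 0))
    detail <- sprintf("tis_codon=%s;tis_pos=%d",
                      to_rna(substr(u5, p + 1L, p + 3L)), p)
    out <- rbind(out, entry_row("nterm_extension", tx$transcript_id, seq_aa,
                                detail))
  }
  out
}

#' Build upstream ORF entries by three-frame scanning of the 5' UTR
#'
#' Every occurrence of a permitted start codon in the 5' UTR (any frame)
#' starts a candidate ORF: `M` plus the downstream translation up to the first
#' stop codon, continuing into the CDS region when no stop occurs within the
#' UTR (such entries are flagged CDS-overlapping in their detail). ORFs
#' shorter than `min_length_aa` are dropped. An ORF that runs off the
#' transcript without reaching a stop is flagged.
#'
#' @param tx a coding [transcript_model()].
#' @param start_codons permitted start codons.
#' @param min_length_aa minimum ORF length in amino acids, initiator included
#'   (default 6).
#' @return entries data.frame ordered 5'->3'.
#' @export
build_uorfs <- function(tx, start_codons = default_start_codons(),
                        min_length_aa = 6) {
  start_codons <- norm_dna(start_codons)
  u5 <- utr5(tx)
  out <- new_entries()
  if (nchar(u5) < 3) return(out)
  spliced <- tx$spliced_sequence
  for (p in scan_start_codons(u5, start_codons)) {
    body <- translate_nt(substr(spliced, p + 4L, nchar(spliced)), 0)
    orf <- paste0("M", body)
    if (nchar(orf) < min_length_aa) next
    consumed <- 3L + 3L * nchar(body)           # start codon + body
    stop_pos <- p + consumed                    # 0-based position of stop codon
    has_stop <- stop_pos + 3L <= nchar(spliced) &&
      substr(spliced, stop_pos + 1L, stop_pos + 3L) %in% STOP_CODONS
    end_nt <- if (has_stop) stop_pos + 3L else p + consumed
    cds_overlap <- end_nt > tx$cds_start
    detail <- sprintf(
      "start_codon=%s;utr_pos=%d;frame=%d;cds_overlap=%d",
      to_rna(substr(u5, p + 1L, p + 3L)), p, p %% 3L, as.integer(cds_overlap)
    )
    out <- rbind(out, entry_row("uorf", tx$transcript_id, orf, detail,
                                flagged = !has_stop))
  }
  out
}

#' Minimum nucleotide substitutions turning a stop codon into a sense codon
#'
#' The minimum Hamming distance between `stop_codon` and any codon encoding
#' `amino_acid`. A distance of 1 means the recoding event is reachable by a
#' single nucleotide change (e.g. UGA -> UGG, tryptophan).
#'
#' @param stop_codon one of UAG, UAA, UGA (U/T interchangeable).
#' @param amino_acid one-letter amino-acid code.
#' @return integer in 1..3.
#' @export
#' @examples
#' min_substitutions("UGA", "W")  # 1
min_substitutions <- function(stop_codon, amino_acid) {
  sc <- norm_dna(stop_codon)
  if (!sc %in% STOP_CODONS) stop("'", stop_codon, "' is not a stop codon")
  if (!amino_acid %in% AA20) stop("'", amino_acid, "' is not a standard amino acid")
  sc_chars <- str_chars(sc)
  min(vapply(codons_for(amino_acid), function(codon) {
    sum(str_chars(codon) != sc_chars)
  }, integer(1)))
}

#' Build translational-readthrough entries (20 per transcript)
#'
#' The stop codon is recoded as each of the 20 amino acids; the C-terminal
#' extension is the translation of the 3' UTR in the CDS frame up to (not
#' including) the next in-frame stop codon. When the 3' UTR holds no in-frame
#' stop, the extension runs to the last complete codon and the entries are
#' flagged; an empty 3' UTR gives flagged single-residue extensions. The
#' annotated protein is a strict prefix of every entry. Details record the
#' recoded stop codon, the substituted residue and its minimum substitution
#' distance.
#'
#' @param tx a coding [transcript_model()] with a complete CDS (terminal stop
#'   codon present); incomplete transcripts raise an error because
#'   readthrough is undefined without a stop.
#' @return entries data.frame with one row per amino acid (20 rows).
#' @export
build_readthrough_entries <- function(tx) {
  if (!has_cds(tx)) stop("transcript ", tx$transcript_id, " has no CDS")
  if (!isTRUE(tx$cds_complete)) {
    stop("transcript ", tx$transcript_id,
         " has no terminal stop codon; readthrough is undefined")
  }
  stop_codon <- substr(tx$spliced_sequence, tx$cds_end - 2L, tx$cds_end)
  prot <- protein_sequence(tx)
  u3 <- utr3(tx)
  ext <- if (nchar(u3) >= 3) translate_nt(u3, 0) else ""
  has_next_stop <- FALSE
  if (nchar(u3) >= 3) {
    spos <- 3L * nchar(ext)
    has_next_stop <- spos + 3L <= nchar(u3) &&
      substr(u3, spos + 1L, spos + 3L) %in% STOP_CODONS
  }
  flagged <- !has_next_stop
  out <- lapply(AA20, function(aa) {
    detail <- sprintf("stop_codon=%s;residue=%s;min_sub=%d",
                      to_rna(stop_codon), aa, min_substitutions(stop_codon, aa))
    entry_row("readthrough", tx$transcript_id, paste0(prot, aa, ext), detail,
              flagged = flagged)
  })
  do.call(rbind, out)
}

#' Exon-exon junctions of a transcript
#'
#' Junction coordinates are genomic and 0-based half-open: `donor_end` is the
#' end of the genomically left exon and `acceptor_start` the start of the
#' genomically right exon, independent of strand.
#'
#' @param tx a [transcript_model()].
#' @return data.frame with columns chrom, donor_end, acceptor_start, strand.
#' @export
transcript_junctions <- function(tx) {
  n <- nrow(tx$exons)
  if (n < 2) {
    return(data.frame(chrom = character(), donor_end = integer(),
                      acceptor_start = integer(), strand = character()))
  }
  a <- tx$exons[-n, , drop = FALSE]
  b <- tx$exons[-1, , drop = FALSE]
  if (tx$strand == "+") {
    data.frame(chrom = tx$chrom, donor_end = a$end, acceptor_start = b$start,
               strand = tx$strand, row.names = NULL)
  } else {
    data.frame(chrom = tx$chrom, donor_end = b$end, acceptor_start = a$start,
               strand = tx$strand, row.names = NULL)
  }
}

#' Reference junction set of an annotated transcript collection
#'
#' @param transcripts list of [transcript_model()] objects.
#' @return data.frame of distinct junctions (see [transcript_junctions()]).
#' @export
reference_junction_set <- function(transcripts) {
  js <- do.call(rbind, lapply(transcripts, transcript_junctions))
  if (is.null(js) || nrow(js) == 0) {
    return(data.frame(chrom = character(), donor_end = integer(),
                      acceptor_start = integer(), strand = character()))
  }
  unique(js)
}

junction_key <- function(j) {
  paste(j$chrom, j$donor_end, j$acceptor_start, j$strand, sep = ":")
}

#' Read/write a junction table (BED-like TSV, 0-based half-open)
#'
#' @param path TSV with columns chrom, donor_end, acceptor_start, strand.
#' @return data.frame of junctions.
#' @export
read_junction_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c("character", "integer", "integer", "character"))
}

#' @rdname read_junction_table
#' @param junctions junction data.frame to write.
#' @export
write_junction_table <- function(junctions, path) {
  write.table(junctions, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build junction entries for novel exon-exon boundaries
#'
#' For each junction of a novel transcript absent from the reference set, a
#' window of up to `window_nt` nucleotides on each side of the junction is
#' translated: in the transcript's annotated CDS frame (window clipped to the
#' CDS) when a CDS is present, otherwise in all three frames. Details carry
#' the genomic junction coordinates.
#'
#' @param novel_transcripts list of [transcript_model()] objects carrying the
#'   novel exon structures.
#' @param reference_junctions reference junction data.frame (all annotated
#'   exon-exon boundaries); see [reference_junction_set()].
#' @param window_nt window half-width in nucleotides (default 96, covering
#'   tryptic peptides up to ~32 aa across the junction).
#' @return entries data.frame (single-exon transcripts contribute nothing).
#' @export
build_junction_entries <- function(novel_transcripts, reference_junctions,
                                   window_nt = 96) {
  ref_keys <- junction_key(reference_junctions)
  out <- new_entries()
  for (tx in novel_transcripts) {
    js <- transcript_junctions(tx)
    if (nrow(js) == 0) next
    novel <- which(!junction_key(js) %in% ref_keys)
    cum <- cumsum(tx$exons$end - tx$exons$start)
    for (i in novel) {
      j <- cum[i]  # transcript-space junction offset
      coord <- sprintf("chrom=%s;donor_end=%d;acceptor_start=%d;strand=%s",
                       js$chrom[i], js$donor_end[i], js$acceptor_start[i],
                       js$strand[i])
      if (has_cds(tx)) {
        ws <- max(tx$cds_start, j - window_nt)
        ws <- ws + (3L - (ws - tx$cds_start) %% 3L) %% 3L  # snap in frame
        we <- min(tx$cds_end, j + window_nt)
        if (we - ws < 3) next
        aa <- translate_nt(substr(tx$spliced_sequence, ws + 1L, we), 0)
        if (nchar(aa) == 0) next
        out <- rbind(out, entry_row(
          "junction", tx$transcript_id, aa,
          paste0(coord, sprintf(";frame=cds;window_start=%d", ws))
        ))
      } else {
        ws <- max(0L, j - window_nt)
        we <- min(nchar(tx$spliced_sequence), j + window_nt)
        for (f in 0:2) {
          aa <- translate_nt(substr(tx$spliced_sequence, ws + 1L, we), f)
          if (nchar(aa) == 0) next
          out <- rbind(out, entry_row(
            "junction", tx$transcript_id, aa,
            paste0(coord, sprintf(";frame=%d;window_start=%d", f, ws))
          ))
        }
      }
    }
  }
  out
}

#' Canonical proteome entries of a transcript collection
#'
#' One entry per coding transcript with a valid CDS; the sequence is the
#' annotated protein.
#'
#' @param transcripts list of [transcript_model()] objects.
#' @return entries data.frame with category `"canonical"`.
#' @export
canonical_entries <- function(transcripts) {
  out <- lapply(transcripts, function(tx) {
    if (!has_cds(tx)) return(NULL)
    entry_row("canonical", tx$transcript_id, protein_sequence(tx),
              sprintf("gene=%s", tx$gene_id))
  })
  res <- do.call(rbind, out)
  if (is.null(res)) new_entries() else res
}

#' Build the full custom database over a transcript collection
#'
#' Runs the per-category builders over every eligible transcript. Transcripts
#' with an invalid CDS are skipped entirely; transcripts without a terminal
#' stop codon are skipped for readthrough (with a warning) but used for TIS
#' and uORF building.
#'
#' @param transcripts annotated coding transcripts (list of
#'   [transcript_model()]).
#' @param novel_transcripts transcripts carrying candidate novel junctions
#'   (default none).
#' @param categories subset of
#'   `c("canonical", "nterm_extension", "uorf", "readthrough", "junction")`.
#' @param start_codons,min_uorf_aa,window_nt tuning knobs passed through to
#'   the builders.
#' @param reference_junctions reference junction set; computed from
#'   `transcripts` when `NULL`.
#' @return entries data.frame across all requested categories.
#' @export
build_custom_db <- function(transcripts, novel_transcripts = list(),
                            categories = c("canonical", "nterm_extension",
                                           "uorf", "readthrough", "junction"),
                            start_codons = default_start_codons(),
                            min_uorf_aa = 6, window_nt = 96,
                            reference_junctions = NULL) {
  coding <- Filter(function(tx) has_cds(tx) && !tx$cds_invalid, transcripts)
  parts <- list()
  if ("canonical" %in% categories) {
    parts$canonical <- canonical_entries(coding)
  }
  if ("nterm_extension" %in% categories) {
    parts$tis <- do.call(rbind, lapply(coding, build_nterm_extensions,
                                       start_codons = start_codons))
  }
  if ("uorf" %in% categories) {
    parts$uorf <- do.call(rbind, lapply(coding, build_uorfs,
                                        start_codons = start_codons,
                                        min_length_aa = min_uorf_aa))
  }
  if ("readthrough" %in% categories) {
    complete <- Filter(function(tx) isTRUE(tx$cds_complete), coding)
    n_skipped <- length(coding) - length(complete)
    if (n_skipped > 0) {
      log_warn(n_skipped, " transcript(s) without a terminal stop codon ",
               "skipped for readthrough building")
    }
    parts$rt <- do.call(rbind, lapply(complete, build_readthrough_entries))
  }
  if ("junction" %in% categories && length(novel_transcripts) > 0) {
    if (is.null(reference_junctions)) {
      reference_junctions <- reference_junction_set(transcripts)
    }
    parts$junction <- build_junction_entries(novel_transcripts,
                                             reference_junctions, window_nt)
  }
  res <- do.call(rbind, Filter(Negate(is.null), parts))
  if (is.null(res)) return(new_entries())
  rownames(res) <- NULL
  res
}

CATEGORY_ORDER <- c("canonical", "nterm_extension", "uorf", "readthrough",
                    "junction")

#' Write a protein entry database as FASTA
#'
#' Records are ordered deterministically (category, then transcript, then
#' detail) and headers use the accession dialect
#' `nc|<category>|<transcript_id>|<detail>`. Duplicate accessions are an
#' error.
#'
#' @param entries entries data.frame.
#' @param path output FASTA path (wrapped at 60 columns).
#' @return `path`, invisibly.
#' @export
write_database <- function(entries, path) {
  if (anyDuplicated(entries$accession)) {
    dup <- unique(entries$accession[duplicated(entries$accession)])
    stop("duplicate accession(s): ", paste(head(dup, 3), collapse = ", "))
  }
  ord <- order(match(entries$category, CATEGORY_ORDER), entries$transcript_id,
               entries$detail, method = "radix")
  entries <- entries[ord, , drop = FALSE]
  set <- Biostrings::AAStringSet(entries$sequence)
  names(set) <- entries$accession
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a protein entry database written by [write_database()]
#'
#' @param path FASTA path.
#' @return entries data.frame with all fields reconstructed from the headers.
#' @export
read_database <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) return(new_entries())
  acc <- names(set)
  parts <- strsplit(acc, "|", fixed = TRUE)
  detail <- vapply(parts, `[`, character(1), 4)
  detail[is.na(detail)] <- ""
  flagged <- grepl("(^|;)flagged=1($|;)", detail)
  new_entries(
    accession = unname(acc),
    category = vapply(parts, `[`, character(1), 2),
    transcript_id = vapply(parts, `[`, character(1), 3),
    sequence = unname(as.character(set)),
    detail = sub(";flagged=1", "", detail, fixed = TRUE),
    flagged = flagged
  )
}

#' Write a TSV manifest of database entries
#'
#' @param entries entries data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_entry_manifest <- function(entries, path) {
  write.table(
    entries[, c("accession", "category", "transcript_id", "detail", "flagged")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
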