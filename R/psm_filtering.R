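# Post-search analysis of peptide-spectrum matches (PSMs): the fragment-ion
# coverage filter, the 39-class modification registry, PTM landscape
# summaries (site frequencies, multi-PTM proteins), readthrough plausibility
# filtering and missing-protein evidence reports.
#
# PSM tables are plain TSVs with columns: peptide, modifications (encoded
# "name@pos;name@pos", empty for unmodified), annotated_residues, cell_type,
# accessions (comma-separated; entry accessions embed semicolons in their
# detail field), category and, when known, protein_start (1-based start of
# the peptide within its parent protein).

#' The modification registry
#'
#' Loads the registry of the 39 modification classes considered during the
#' database search: 27 biologically relevant PTMs and 12 post-isolation
#' modifications introduced during sample handling. The registry ships as an
#' editable plain-text table (`name`, `delta_mass` in Da, comma-separated
#' `targets` — residues or `N-term` —, and `class`) whose partition is
#' asserted at load time.
#'
#' @param path optional path to a custom registry TSV; default is the table
#'   shipped with the package.
#' @param strict assert the 39 = 27 + 12 partition (default TRUE; disable for
#'   user-edited registries of different composition).
#' @return data.frame with columns `name`, `delta_mass`, `targets`, `class`.
#' @export
ptm_registry <- function(path = NULL, strict = TRUE) {
  if (is.null(path)) {
    path <- system.file("extdata", "modifications.tsv", package = "proteomapr")
  }
  reg <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "delta_mass", "targets", "class") %in% names(reg)))
  if (anyDuplicated(reg$name)) stop("registry names must be unique")
  if (!all(reg$class %in% c("biological", "post_isolation"))) {
    stop("registry class must be 'biological' or 'post_isolation'")
  }
  if (strict) {
    n_bio <- sum(reg$class == "biological")
    n_post <- sum(reg$class == "post_isolation")
    if (nrow(reg) != 39 || n_bio != 27 || n_post != 12) {
      stop("registry must hold 39 modification classes ",
           "(27 biological + 12 post-isolation); got ", nrow(reg), " (",
           n_bio, " + ", n_post, ")")
    }
  }
  reg
}

#' Parse a modification string into a (name, site) data.frame
#'
#' @param x string of the form `"name@pos;name@pos"`; empty/NA means
#'   unmodified.
#' @return data.frame with columns `name`, `site` (1-based within peptide).
#' @export
parse_modifications <- function(x) {
  if (is.na(x) || x == "") {
    return(data.frame(name = character(), site = integer()))
  }
  parts <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], "@", fixed = TRUE)
  data.frame(
    name = vapply(parts, `[`, character(1), 1),
    site = as.integer(vapply(parts, `[`, character(1), 2))
  )
}

format_modifications <- function(mods) {
  if (nrow(mods) == 0) return("")
  paste(sprintf("%s@%d", mods$name, mods$site), collapse = ";")
}

#' Read/write a PSM table
#'
#' @param path TSV path.
#' @return data.frame of PSM records.
#' @export
read_psms <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA"),
             comment.char = "#")
}

#' @rdname read_psms
#' @param psms PSM data.frame to write.
#' @export
write_psms <- function(psms, path) {
  write.table(psms, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fragment-ion coverage filter
#'
#' Keeps PSMs whose annotated fragment ions cover more than `threshold` of
#' the peptide sequence: the coverage fraction is the number of annotated
#' residues divided by the peptide length, and the comparison is strictly
#' greater-than, so a record at exactly the threshold is rejected.
#'
#' @param psms PSM data.frame with `peptide` and `annotated_residues`.
#' @param threshold coverage threshold (default 0.5).
#' @return list with elements `kept` and `rejected`, both carrying a
#'   `coverage` column; the two partitions are disjoint and exhaustive.
#' @export
coverage_filter <- function(psms, threshold = 0.5) {
  len <- nchar(psms$peptide)
  ann <- psms$annotated_residues
  if (any(ann < 0 | ann > len)) {
    bad <- which(ann < 0 | ann > len)
    stop("corrupt record(s): annotated_residues outside [0, peptide length] ",
         "at row(s) ", paste(head(bad, 5), collapse = ", "))
  }
  psms$coverage <- ann / len
  keep <- psms$coverage > threshold
  list(kept = psms[keep, , drop = FALSE],
       rejected = psms[!keep, , drop = FALSE])
}

#' Label PSMs by the class of their modifications
#'
#' Each PSM is labelled `biological`, `post_isolation` or `mixed` according
#' to the registry classes of its modifications (`unmodified` when it has
#' none). Unknown modification names are an error.
#'
#' @param psms PSM data.frame.
#' @param registry modification registry (default [ptm_registry()]).
#' @return `psms` with an added `mod_class` column.
#' @export
classify_modifications <- function(psms, registry = ptm_registry()) {
  cls <- vapply(psms$modifications, function(m) {
    mods <- parse_modifications(m)
    if (nrow(mods) == 0) return("unmodified")
    idx <- match(mods$name, registry$name)
    if (anyNA(idx)) {
      stop("unknown modification name(s): ",
           paste(unique(mods$name[is.na(idx)]), collapse = ", "))
    }
    classes <- unique(registry$class[idx])
    if (length(classes) == 1) classes else "mixed"
  }, character(1), USE.NAMES = FALSE)
  psms$mod_class <- cls
  psms
}

# Map PSM-level modification sites to protein coordinates. Returns one row
# per (PSM x modification x parent accession).
psm_sites <- function(psms, registry, proteins = NULL) {
  rows <- list()
  for (i in seq_len(nrow(psms))) {
    mods <- parse_modifications(psms$modifications[i])
    if (nrow(mods) == 0) next
    accs <- strsplit(psms$accessions[i] %||% "", ",", fixed = TRUE)[[1]]
    accs <- accs[accs != ""]
    if (length(accs) == 0 || all(is.na(accs))) {
      log_warn("PSM without parent accession excluded from site mapping (row ",
               i, ")")
      next
    }
    for (acc in accs) {
      start <- if ("protein_start" %in% names(psms) &&
                   !is.na(psms$protein_start[i])) {
        psms$protein_start[i]
      } else if (!is.null(proteins) && acc %in% names(proteins)) {
        s <- regexpr(psms$peptide[i], proteins[[acc]], fixed = TRUE)
        if (s < 0) NA_integer_ else as.integer(s)
      } else {
        NA_integer_
      }
      if (is.na(start)) {
        log_warn("peptide position within '", acc, "' unknown; PSM row ", i,
                 " excluded from site mapping")
        next
      }
      idx <- match(mods$name, registry$name)
      if (anyNA(idx)) {
        stop("unknown modification name(s): ",
             paste(unique(mods$name[is.na(idx)]), collapse = ", "))
      }
      targets <- registry$targets[idx]
      residue <- substring(psms$peptide[i], mods$site, mods$site)
      residue[grepl("N-term", targets, fixed = TRUE) & mods$site == 1L] <-
        "N-term"
      rows[[length(rows) + 1L]] <- data.frame(
        protein = acc, position = start + mods$site - 1L,
        residue = residue, name = mods$name, class = registry$class[idx]
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(protein = character(), position = integer(),
                      residue = character(), name = character(),
                      class = character()))
  }
  do.call(rbind, rows)
}

#' Site-frequency table of modifications
#'
#' A modified site is the triple (protein, protein position, modification
#' name) and is counted once regardless of how many PSMs report it; site
#' positions are 1-based in protein space. Residues are taken from the
#' peptide sequence (protein-N-terminal modifications are tabulated under
#' `"N-term"`).
#'
#' @param psms PSM data.frame carrying `accessions` and either a
#'   `protein_start` column or parent sequences via `proteins`.
#' @param registry modification registry.
#' @param proteins optional named character vector of parent protein
#'   sequences, used to locate peptides when `protein_start` is absent.
#' @return list with `sites` (distinct modified sites), `by_residue`
#'   (counts keyed by residue and modification name) and `class_totals`
#'   (distinct sites per registry class).
#' @export
site_frequency <- function(psms, registry = ptm_registry(), proteins = NULL) {
  sites <- unique(psm_sites(psms, registry, proteins))
  by_residue <- as.data.frame(
    table(residue = sites$residue, name = sites$name),
    stringsAsFactors = FALSE
  )
  by_residue <- by_residue[by_residue$Freq > 0, , drop = FALSE]
  names(by_residue)[3] <- "n_sites"
  by_residue$class <- registry$class[match(by_residue$name, registry$name)]
  by_residue <- by_residue[order(by_residue$name, by_residue$residue), ,
                           drop = FALSE]
  rownames(by_residue) <- NULL
  class_totals <- vapply(c("biological", "post_isolation"), function(cl) {
    sum(sites$class == cl)
  }, numeric(1))
  list(sites = sites, by_residue = by_residue, class_totals = class_totals)
}

#' Per-protein PTM summary (sites and modification types)
#'
#' Counts, for every protein with at least one biological PTM, the number of
#' distinct modified positions (`n_sites`) and distinct modification names
#' (`n_types`); post-isolation modifications are excluded. A site carrying
#' several modification types contributes once to `n_sites` and each type
#' once to `n_types`.
#'
#' @inheritParams site_frequency
#' @return list with `summary` (protein, n_sites, n_types), `site_histogram`
#'   and `type_histogram` (named count tables over the two axes).
#' @export
protein_ptm_summary <- function(psms, registry = ptm_registry(),
                                proteins = NULL) {
  sites <- unique(psm_sites(psms, registry, proteins))
  sites <- sites[sites$class == "biological", , drop = FALSE]
  if (nrow(sites) == 0) {
    return(list(summary = data.frame(protein = character(),
                                     n_sites = integer(),
                                     n_types = integer()),
                site_histogram = table(integer()),
                type_histogram = table(integer())))
  }
  split_sites <- split(sites, sites$protein)
  summary <- data.frame(
    protein = names(split_sites),
    n_sites = vapply(split_sites, function(s) length(unique(s$position)),
                     integer(1)),
    n_types = vapply(split_sites, function(s) length(unique(s$name)),
                     integer(1)),
    row.names = NULL
  )
  summary <- summary[order(summary$protein), , drop = FALSE]
  rownames(summary) <- NULL
  list(summary = summary,
       site_histogram = table(summary$n_sites),
       type_histogram = table(summary$n_types))
}

#' Plausibility filter for translational-readthrough PSMs
#'
#' Keeps readthrough events whose recoded stop codon can reach a codon of the
#' substituted residue by a single nucleotide change
#' ([min_substitutions()] equal to 1), excluding events that would require
#' multiple substitutions. The recoding detail (stop codon, substituted
#' residue) is taken from the parent readthrough entry accession.
#'
#' @param psms PSM data.frame whose readthrough records carry parent
#'   readthrough accessions (dialect `nc|readthrough|<tx>|stop_codon=..;
#'   residue=..;...`).
#' @return list with `kept`, `rejected` (both annotated with `stop_codon`,
#'   `residue`, `min_sub`) and `stop_frequency`, the per-stop-codon count of
#'   kept events.
#' @export
readthrough_plausibility <- function(psms) {
  rt <- psms[psms$category == "readthrough", , drop = FALSE]
  if (nrow(rt) == 0) {
    return(list(kept = rt, rejected = rt,
                stop_frequency = table(character())))
  }
  info <- lapply(strsplit(rt$accessions, ",", fixed = TRUE), function(accs) {
    det <- parse_detail(sub("^nc\\|[^|]*\\|[^|]*\\|", "", accs[1]))
    if (!all(c("stop_codon", "residue") %in% names(det))) {
      stop("readthrough PSM parent entry lacks recoding detail: ", accs[1])
    }
    det
  })
  rt$stop_codon <- vapply(info, `[[`, character(1), "stop_codon")
  rt$residue <- vapply(info, `[[`, character(1), "residue")
  rt$min_sub <- mapply(min_substitutions, rt$stop_codon, rt$residue)
  keep <- rt$min_sub == 1L
  kept <- rt[keep, , drop = FALSE]
  list(kept = kept, rejected = rt[!keep, , drop = FALSE],
       stop_frequency = table(kept$stop_codon))
}

#' Missing-protein evidence report
#'
#' For proteins lacking prior protein-level evidence (protein-existence level
#' PE2 or higher, or unknown), counts distinct unique peptides — peptides
#' mapping to exactly one protein of the combined canonical + custom database
#' with I/L collapsed — and the number of cell types with a detection, and
#' assigns an evidence tier (`"2+ unique"` versus `"1 unique"`). Proteins
#' whose every peptide is shared are excluded. Because the custom database
#' derives several entries from one transcript (the 20 readthrough variants
#' all contain the annotated protein), uniqueness is assessed at the parent
#' transcript level: a peptide is unique when all entries containing it come
#' from a single transcript.
#'
#' @param psms PSM data.frame.
#' @param pe_levels data.frame mapping `accession` to `pe_level` (integer 1-5
#'   or strings like `"PE2"`).
#' @param entries combined database entries data.frame used for the
#'   uniqueness check.
#' @param il_equivalent collapse I/L when mapping peptides (default TRUE).
#' @return data.frame with columns `accession`, `pe_level`, `n_unique_peptides`,
#'   `n_cell_types`, `tier`, ordered by decreasing evidence.
#' @export
missing_protein_report <- function(psms, pe_levels, entries,
                                   il_equivalent = TRUE) {
  pe <- pe_levels
  pe$pe_level_num <- suppressWarnings(as.integer(gsub("[^0-9]", "",
                                                      as.character(pe$pe_level))))
  peptides <- unique(psms$peptide)
  hits <- map_peptides(peptides, entries, il_equivalent)
  tx_of_acc <- setNames(entries$transcript_id, entries$accession)
  n_parents <- vapply(hits, function(h) {
    length(unique(tx_of_acc[h]))
  }, integer(1))
  unique_pep <- setNames(n_parents == 1L, peptides)

  rows <- list()
  for (i in seq_len(nrow(psms))) {
    accs <- strsplit(psms$accessions[i] %||% "", ",", fixed = TRUE)[[1]]
    for (acc in accs[accs != ""]) {
      rows[[length(rows) + 1L]] <- data.frame(
        accession = acc, peptide = psms$peptide[i],
        cell_type = psms$cell_type[i]
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(accession = character(), pe_level = character(),
                      n_unique_peptides = integer(), n_cell_types = integer(),
                      tier = character()))
  }
  ev <- do.call(rbind, rows)
  idx <- match(ev$accession, pe$accession)
  ev$pe_level_num <- pe$pe_level_num[idx]
  ev$pe_level <- as.character(pe$pe_level[idx])
  ev$pe_level[is.na(idx)] <- "unknown"
  # targets: PE >= 2 or unknown level
  ev <- ev[is.na(ev$pe_level_num) | ev$pe_level_num >= 2, , drop = FALSE]
  if (nrow(ev) == 0) {
    return(data.frame(accession = character(), pe_level = character(),
                      n_unique_peptides = integer(), n_cell_types = integer(),
                      tier = character()))
  }
  out <- do.call(rbind, lapply(split(ev, ev$accession), function(e) {
    uniq <- unique(e$peptide[unique_pep[e$peptide]])
    data.frame(
      accession = e$accession[1], pe_level = e$pe_level[1],
      n_unique_peptides = length(uniq),
      n_cell_types = length(unique(e$cell_type)),
      tier = if (length(uniq) >= 2) "2+ unique" else "1 unique"
    )
  }))
  out <- out[out$n_unique_peptides > 0, , drop = FALSE]
  out <- out[order(-out$n_unique_peptides, out$accession), , drop = FALSE]
  rownames(out) <- NULL
  out
}
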