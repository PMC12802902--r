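# In-silico proteolysis, peptide-to-database mapping with novelty
# classification, and monoisotopic mass arithmetic (peptide, fragment and
# immonium masses). Masses are standard monoisotopic values carried at full
# double precision internally; display rounding is left to callers.

#' Monoisotopic residue masses and mass constants
#'
#' `residue_masses()` returns the 20 standard monoisotopic amino-acid residue
#' masses (Da). `mass_constants()` returns the proton, water and CO masses
#' used in peptide, fragment and immonium arithmetic.
#'
#' @return named numeric vector.
#' @export
residue_masses <- function() {
  c(
    G = 57.02146374, A = 71.03711379, S = 87.03202841, P = 97.05276385,
    V = 99.06841391, T = 101.04767847, C = 103.00918448, L = 113.08406398,
    I = 113.08406398, N = 114.04292744, D = 115.02694302, Q = 128.05857751,
    K = 128.09496302, E = 129.04259309, M = 131.04048461, H = 137.05891186,
    F = 147.06841391, R = 156.10111102, Y = 163.06332853, W = 186.07931295
  )
}

#' @rdname residue_masses
#' @export
mass_constants <- function() {
  c(proton = 1.00727646688, water = 18.01056468403, co = 27.99491461957)
}

resolve_mod_deltas <- function(sequence, modifications, registry = NULL) {
  if (is.null(modifications) || length(modifications) == 0) {
    return(numeric(nchar(sequence)))
  }
  deltas <- numeric(nchar(sequence))
  if (is.numeric(modifications)) {
    # named by 1-based site, or a bare vector of site-less deltas applied at
    # the N terminus
    if (!is.null(names(modifications))) {
      sites <- as.integer(names(modifications))
    } else {
      sites <- rep(1L, length(modifications))
    }
    vals <- unname(modifications)
    names(vals) <- NULL
  } else {
    mods <- as.data.frame(modifications)
    if (is.null(registry)) registry <- ptm_registry()
    idx <- match(mods$name, registry$name)
    if (anyNA(idx)) {
      stop("unknown modification(s): ",
           paste(unique(mods$name[is.na(idx)]), collapse = ", "))
    }
    sites <- as.integer(mods$site)
    vals <- registry$delta_mass[idx]
    # residue compatibility: a site must carry a residue the modification
    # targets (terminal modifications are checked against position instead)
    targets <- registry$targets[idx]
    for (k in seq_along(sites)) {
      tg <- strsplit(targets[k], ",", fixed = TRUE)[[1]]
      if ("N-term" %in% tg && sites[k] == 1L) next
      res <- substr(sequence, sites[k], sites[k])
      if (!res %in% tg) {
        stop("modification '", mods$name[k], "' does not target residue '",
             res, "' at site ", sites[k])
      }
    }
  }
  if (any(sites < 1L | sites > nchar(sequence))) {
    stop("modification site outside the peptide")
  }
  for (k in seq_along(sites)) deltas[sites[k]] <- deltas[sites[k]] + vals[k]
  deltas
}

#' Monoisotopic peptide mass
#'
#' Sum of residue masses plus water plus any modification delta masses.
#' Modifications may be given as a data.frame with `name` and `site` columns
#' (deltas resolved through the registry) or as a numeric vector of deltas
#' named by 1-based site.
#'
#' @param sequence amino-acid string.
#' @param modifications optional modifications (see Details).
#' @param registry modification registry (default [ptm_registry()]).
#' @return neutral monoisotopic mass in Da.
#' @export
#' @examples
#' peptide_mass("G")  # 75.0320
peptide_mass <- function(sequence, modifications = NULL, registry = NULL) {
  res <- str_chars(sequence)
  m <- residue_masses()[res]
  if (anyNA(m)) {
    stop("unknown residue(s): ", paste(unique(res[is.na(m)]), collapse = ", "))
  }
  deltas <- resolve_mod_deltas(sequence, modifications, registry)
  sum(m) + mass_constants()[["water"]] + sum(deltas)
}

#' Singly/multiply charged b- and y-series fragment ions
#'
#' All b_i and y_i ions for 1 <= i <= n-1, with modification delta masses
#' applied to the residues each fragment contains. For charge z the m/z is
#' (fragment neutral-series mass + z protons) / z.
#'
#' @param sequence amino-acid string of length >= 2.
#' @param modifications optional modifications (see [peptide_mass()]).
#' @param series which ion series to emit (subset of `c("b", "y")`).
#' @param charge fragment charge (default 1).
#' @param registry modification registry.
#' @return data.frame with columns `ion` (e.g. `"b4"`), `series`, `index`,
#'   `mz`.
#' @export
fragment_ions <- function(sequence, modifications = NULL,
                          series = c("b", "y"), charge = 1, registry = NULL) {
  n <- nchar(sequence)
  stopifnot(n >= 2)
  const <- mass_constants()
  res <- str_chars(sequence)
  m <- residue_masses()[res] + resolve_mod_deltas(sequence, modifications,
                                                  registry)
  out <- list()
  idx <- seq_len(n - 1L)
  if ("b" %in% series) {
    b <- (cumsum(m)[idx] + charge * const[["proton"]]) / charge
    out$b <- data.frame(ion = paste0("b", idx), series = "b", index = idx,
                        mz = unname(b))
  }
  if ("y" %in% series) {
    y <- (rev(cumsum(rev(m)))[idx + 1L] + const[["water"]] +
            charge * const[["proton"]]) / charge
    out$y <- data.frame(ion = paste0("y", n - idx), series = "y",
                        index = n - idx, mz = unname(y))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Immonium ion m/z of a (possibly modified) residue
#'
#' Residue monoisotopic mass minus CO plus a proton, plus the modification
#' delta mass. The methylated-histidine immonium ion, a diagnostic for
#' histidine methylation, computes to 124.09 m/z (2-decimal display).
#'
#' @param residue one-letter amino-acid code.
#' @param modification optional: a registry modification name or a numeric
#'   delta mass.
#' @param registry modification registry.
#' @return m/z at full precision (round to 2 decimals for display).
#' @export
#' @examples
#' round(immonium_mz("H", "Methyl (H)"), 2)  # 124.09
immonium_mz <- function(residue, modification = NULL, registry = NULL) {
  m <- residue_masses()[residue]
  if (is.na(m)) stop("unknown residue '", residue, "'")
  delta <- 0
  if (!is.null(modification)) {
    if (is.numeric(modification)) {
      delta <- modification
    } else {
      if (is.null(registry)) registry <- ptm_registry()
      idx <- match(modification, registry$name)
      if (is.na(idx)) stop("unknown modification '", modification, "'")
      delta <- registry$delta_mass[idx]
    }
  }
  const <- mass_constants()
  unname(m - const[["co"]] + const[["proton"]] + delta)
}

# Cleavage positions: cut after K/R not followed by P (Keil rule); with
# trypsin_p = TRUE the proline exclusion is dropped.
tryptic_boundaries <- function(sequence, trypsin_p = FALSE) {
  res <- str_chars(sequence)
  n <- length(res)
  if (n == 0) return(integer())
  cut <- which(res %in% c("K", "R"))
  cut <- cut[cut < n]
  if (!trypsin_p) cut <- cut[res[cut + 1L] != "P"]
  cut
}

#' In-silico tryptic digestion
#'
#' Cleaves after K or R, not before P (the proline exclusion can be switched
#' off with `trypsin_p = TRUE`), and emits all peptides with at most
#' `max_missed` internal uncut K/R sites within the `[min_len, max_len]`
#' length window. When `nterm_met_excision` is on and the second residue is
#' one of A, C, G, P, S, T, V, N-terminal peptides are additionally emitted
#' without the initiator methionine.
#'
#' @param protein_sequence amino-acid string.
#' @param max_missed maximum missed cleavages (default 2).
#' @param min_len,max_len peptide length bounds (defaults 7 and 40, the
#'   typical detectable range).
#' @param nterm_met_excision also emit Met-excised N-terminal peptides.
#' @param trypsin_p drop the proline exclusion.
#' @return data.frame with columns `sequence`, `start`, `end` (1-based
#'   inclusive protein coordinates), `missed_cleavages`, `is_protein_nterm`,
#'   `preceded_by` (`"-"` at the protein N terminus).
#' @export
digest <- function(protein_sequence, max_missed = 2, min_len = 7,
                   max_len = 40, nterm_met_excision = FALSE,
                   trypsin_p = FALSE) {
  n <- nchar(protein_sequence)
  empty <- data.frame(sequence = character(), start = integer(),
                      end = integer(), missed_cleavages = integer(),
                      is_protein_nterm = logical(), preceded_by = character())
  if (n == 0) return(empty)
  cuts <- tryptic_boundaries(protein_sequence, trypsin_p)
  bounds <- c(0L, cuts, n)
  nseg <- length(bounds) - 1L
  rows <- list()
  for (i in seq_len(nseg)) {
    for (j in i:min(nseg, i + max_missed)) {
      s <- bounds[i] + 1L
      e <- bounds[j + 1L]
      len <- e - s + 1L
      if (len < min_len || len > max_len) next
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = substr(protein_sequence, s, e), start = s, end = e,
        missed_cleavages = j - i, is_protein_nterm = (s == 1L),
        preceded_by = if (s == 1L) "-" else substr(protein_sequence, s - 1L,
                                                   s - 1L)
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  if (nterm_met_excision && n >= 2 && substr(protein_sequence, 1, 1) == "M" &&
      substr(protein_sequence, 2, 2) %in% c("A", "C", "G", "P", "S", "T", "V")) {
    nterm <- out[out$start == 1L & out$end >= 2L, , drop = FALSE]
    if (nrow(nterm) > 0) {
      excised <- nterm
      excised$start <- 2L
      excised$sequence <- substring(protein_sequence, 2L, nterm$end)
      excised$preceded_by <- "M"
      ok <- nchar(excised$sequence) >= min_len
      out <- rbind(out, excised[ok, , drop = FALSE])
    }
  }
  rownames(out) <- NULL
  out
}

collapse_il <- function(x) chartr("L", "I", x)

# TRUE for each peptide that occurs as a substring of any sequence in `seqs`.
peptides_in_any <- function(peptides, seqs, il_equivalent = TRUE) {
  if (length(seqs) == 0) return(rep(FALSE, length(peptides)))
  hay <- paste(seqs, collapse = "\x01")
  if (il_equivalent) {
    hay <- collapse_il(hay)
    peptides <- collapse_il(peptides)
  }
  vapply(peptides, function(p) grepl(p, hay, fixed = TRUE), logical(1),
         USE.NAMES = FALSE)
}

#' Classify peptides against the canonical and custom databases
#'
#' A peptide is canonical when it occurs in any canonical protein (with I and
#' L treated as equivalent by default, as they are isobaric); canonical
#' matching takes precedence over any custom-entry match. Novel peptides
#' inherit the category of the custom entries containing them; a novel
#' peptide matched by entries of several categories is reported as
#' `"multi-category"`. Peptides absent from both databases are `"unmapped"`.
#'
#' @param peptides character vector of peptide sequences.
#' @param canonical_seqs canonical protein sequences (character vector), or an
#'   entries data.frame whose canonical rows are used.
#' @param custom_entries noncanonical entries data.frame.
#' @param il_equivalent collapse I/L before matching (default TRUE).
#' @return data.frame with columns `peptide`, `category`, `categories`
#'   (semicolon-joined custom categories that matched).
#' @export
classify_peptides <- function(peptides, canonical_seqs, custom_entries,
                              il_equivalent = TRUE) {
  if (is.data.frame(canonical_seqs)) {
    canonical_seqs <- canonical_seqs$sequence[
      canonical_seqs$category == "canonical"]
  }
  is_canon <- peptides_in_any(peptides, canonical_seqs, il_equivalent)
  cats <- setdiff(unique(custom_entries$category), "canonical")
  hit_mat <- vapply(cats, function(cat) {
    peptides_in_any(peptides,
                    custom_entries$sequence[custom_entries$category == cat],
                    il_equivalent)
  }, logical(length(peptides)))
  if (length(peptides) == 1) hit_mat <- matrix(hit_mat, nrow = 1,
                                               dimnames = list(NULL, cats))
  category <- character(length(peptides))
  categories <- character(length(peptides))
  for (k in seq_along(peptides)) {
    hits <- cats[hit_mat[k, ]]
    categories[k] <- paste(hits, collapse = ";")
    category[k] <- if (is_canon[k]) "canonical"
      else if (length(hits) == 0) "unmapped"
      else if (length(hits) == 1) hits
      else "multi-category"
  }
  data.frame(peptide = peptides, category = category, categories = categories)
}

#' Map peptides to every database entry containing them
#'
#' @param peptides character vector of peptide sequences.
#' @param entries entries data.frame (canonical and/or custom).
#' @param il_equivalent collapse I/L before matching.
#' @return list (one element per peptide) of matching accessions.
#' @export
map_peptides <- function(peptides, entries, il_equivalent = TRUE) {
  seqs <- entries$sequence
  if (il_equivalent) {
    seqs <- collapse_il(seqs)
    peptides_m <- collapse_il(peptides)
  } else {
    peptides_m <- peptides
  }
  lapply(peptides_m, function(p) {
    entries$accession[grepl(p, seqs, fixed = TRUE)]
  })
}
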