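#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor.test p.adjust rnorm runif setNames wilcox.test
#' @importFrom utils head read.delim write.table
NULL

# Logging helpers: level-prefixed messages to standard error.
log_info <- function(...) message("[INFO] ", ...)
log_warn <- function(...) message("[WARN] ", ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a nucleotide string to the DNA alphabet
#'
#' U and T are accepted interchangeably on input; internally every sequence is
#' held in upper-case DNA letters (A, C, G, T, N).
#'
#' @param x character vector of nucleotide strings.
#' @return character vector in the DNA alphabet.
#' @keywords internal
norm_dna <- function(x) {
  x <- chartr("u", "t", x)
  x <- toupper(x)
  chartr("U", "T", x)
}

# Display helper: DNA -> RNA letters (codons are reported in RNA convention).
to_rna <- function(x) chartr("Tt", "Uu", toupper(x))

# Reverse complement of a DNA string (thin wrapper over Biostrings).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Split a string into single characters.
str_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Deterministic sub-seed derivation; keeps seeds within 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * offset) %% .Machine$integer.max)
}
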