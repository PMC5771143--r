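#' The 64 RNA codons in canonical order
#'
#' Order follows the standard codon-table layout used by
#' [Biostrings::getGeneticCode()] (UUU, UUC, UUA, UUG, UCU, ...), with T
#' transliterated to U. All per-codon vectors in this package (usage profiles,
#' fractional footprint profiles, test tables) are keyed by this order.
#'
#' @return Character vector of length 64.
#' @export
codons <- function() {
  chartr("T", "U", names(Biostrings::getGeneticCode("1")))
}

#' Vertebrate mitochondrial genetic code
#'
#' The translation table used by mammalian mitochondria (NCBI transl_table 2):
#' UGA is recoded from stop to Trp, AUA is read as Met, and AGA/AGG are stops.
#' Mitochondrial initiation additionally accepts AUA and AUU as start codons,
#' all translated as initiator Met.
#'
#' @param start_codons Codons treated as initiator Met by [translate_prefix()].
#' @return A list with elements `table` (named character vector of length 64
#'   mapping RNA codons to amino-acid letters, `"*"` for stop) and
#'   `start_codons` (character vector of RNA codons).
#' @export
mito_genetic_code <- function(start_codons = c("AUG", "AUA", "AUU")) {
  tab <- Biostrings::getGeneticCode("2")
  names(tab) <- chartr("T", "U", names(tab))
  tab <- tab[codons()]
  stopifnot(length(tab) == 64L, all(start_codons %in% names(tab)))
  list(table = tab, start_codons = start_codons)
}

#' Read a genetic-code override file
#'
#' Two-column TSV (codon, amino_acid) with 64 rows; `"*"` marks stops. Used in
#' tests to exercise non-default codes.
#'
#' @param path TSV file path.
#' @param start_codons Passed through to the returned code object.
#' @return Same structure as [mito_genetic_code()].
#' @export
read_genetic_code <- function(path, start_codons = c("AUG", "AUA", "AUU")) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("codon", "amino_acid") %in% names(df))) {
    stop("genetic code file must have columns 'codon' and 'amino_acid'")
  }
  tab <- stats::setNames(df$amino_acid, chartr("T", "U", df$codon))
  if (!setequal(names(tab), codons())) stop("genetic code file must define all 64 codons")
  list(table = tab[codons()], start_codons = start_codons)
}

# stop codons of a code object
stop_codons <- function(code) names(code$table)[code$table == "*"]

# reverse complement of a DNA character string
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

dna_to_rna <- function(x) chartr("T", "U", x)

# zero-filled named numeric over the 64 codons
codon_vector <- function() stats::setNames(numeric(64), codons())
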