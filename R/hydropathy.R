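#' Kyte-Doolittle hydropathy scale
#'
#' The published Kyte & Doolittle (1982) per-residue hydropathy values
#' (Ile 4.5 ... Arg -4.5); positive values indicate hydrophobicity.
#'
#' @return Named numeric vector over the 20 amino-acid letters.
#' @export
kyte_doolittle <- function() {
  c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
    L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
}

#' Read a hydropathy-scale override file
#'
#' Two-column TSV (`residue`, `value`) with one row per amino-acid letter.
#'
#' @param path TSV file path.
#' @return Named numeric vector over 20 residues.
#' @export
read_hydropathy_scale <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("residue", "value") %in% names(df))) {
    stop("hydropathy scale file must have columns 'residue' and 'value'")
  }
  sc <- stats::setNames(as.numeric(df$value), df$residue)
  if (length(sc) != 20L) stop("hydropathy scale must define exactly 20 residues")
  sc
}

#' Grand average of hydropathy (GRAVY) of a peptide
#'
#' Arithmetic mean of per-residue hydropathy values; positive scores indicate
#' hydrophobic peptides.
#'
#' @param peptide Peptide string (one-letter residues).
#' @param scale Named hydropathy scale, see [kyte_doolittle()].
#' @return GRAVY score (numeric scalar).
#' @export
gravy <- function(peptide, scale = kyte_doolittle()) {
  if (!nzchar(peptide)) stop("peptide is empty")
  res <- strsplit(peptide, "")[[1]]
  unknown <- setdiff(res, names(scale))
  if (length(unknown)) {
    stop("unknown residue(s) in peptide: ", paste(unknown, collapse = ", "))
  }
  mean(scale[res])
}

#' Amino-terminal hydropathy table for a set of ORFs
#'
#' Translates the first `n` residues of each ORF (initiator recoding applied:
#' AUA/AUU start codons score as Met) and reports the GRAVY of the leading
#' peptide. ORFs shorter than `n` codons, or with a premature stop within the
#' first `n` codons, are flagged and their score is `NA`.
#'
#' @param ref [genome_reference()].
#' @param orfs `orf_annotation` data.frame.
#' @param n Number of amino-terminal residues to score (default 10).
#' @param code Genetic code, see [mito_genetic_code()].
#' @param scale Hydropathy scale, see [kyte_doolittle()].
#' @return Data.frame with columns `gene_id`, `peptide`, `gravy`, `flag`
#'   (`"ok"`, `"short_orf"` or `"premature_stop"`).
#' @export
leader_hydropathy_table <- function(ref, orfs, n = 10L,
                                    code = mito_genetic_code(),
                                    scale = kyte_doolittle()) {
  rows <- lapply(seq_len(nrow(orfs)), function(i) {
    orf <- orfs[i, ]
    if (n_codons(orf) < n) {
      return(data.frame(gene_id = orf$gene_id, peptide = NA_character_,
                        gravy = NA_real_, flag = "short_orf"))
    }
    pep <- tryCatch(translate_prefix(ref, orf, n, code), error = function(e) NULL)
    if (is.null(pep)) {
      return(data.frame(gene_id = orf$gene_id, peptide = NA_character_,
                        gravy = NA_real_, flag = "premature_stop"))
    }
    data.frame(gene_id = orf$gene_id, peptide = pep,
               gravy = gravy(pep, scale), flag = "ok")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
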