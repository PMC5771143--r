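#' Per-ORF fractional footprint distributions
#'
#' Normalizes a codon count matrix by the grand total over all ORFs, giving
#' each gene/codon position's share of the footprints found over all ORFs in
#' the library (the fractional-abundance traces plotted per transcript).
#' Single-assignment (`asite_offset`) counting is assumed for interpretable
#' proportions.
#'
#' @param counts A `codon_count_matrix` from [codon_counts()].
#' @return Data.frame with columns `gene_id`, `codon_index`, `fraction`; the
#'   fractions sum to 1 over all genes.
#' @export
orf_fractional_distribution <- function(counts) {
  df <- as.data.frame(counts)
  total <- sum(df$count)
  if (total == 0) stop("all-zero count matrix; no footprints mapped to CDS codons")
  data.frame(gene_id = df$gene_id, codon_index = df$codon_index,
             fraction = df$count / total, stringsAsFactors = FALSE)
}

#' Write per-ORF distributions as TSV
#' @param dist Result of [orf_fractional_distribution()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_orf_distribution_tsv <- function(dist, path) {
  utils::write.table(dist, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
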