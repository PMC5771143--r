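#' Construct a genome reference
#'
#' Container for a single-contig (mitochondrial-style) DNA reference. The
#' sequence alphabet is restricted to A, C, G, T; ambiguity codes are rejected
#' at load time. Circularity is recorded for footprint mapping, but ORFs that
#' wrap the origin are not supported.
#'
#' @param id Contig label (matched against footprint files).
#' @param sequence DNA string over ACGT.
#' @param circular Logical; is the molecule circular?
#' @return An object of class `genome_reference` with fields `id`, `sequence`,
#'   `circular` and `length`.
#' @export
genome_reference <- function(id, sequence, circular = FALSE) {
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) == 0L) stop("reference sequence is empty")
  if (grepl("[^ACGT]", sequence)) {
    stop("reference sequence contains characters outside {A,C,G,T}")
  }
  structure(
    list(id = as.character(id), sequence = sequence,
         circular = isTRUE(circular), length = nchar(sequence)),
    class = "genome_reference"
  )
}

#' @export
print.genome_reference <- function(x, ...) {
  cat(sprintf("<genome_reference> %s: %d bp%s\n", x$id, x$length,
              if (x$circular) " (circular)" else ""))
  invisible(x)
}

orf_columns <- c("gene_id", "transcript_id", "strand", "cds_start", "cds_end",
                 "leader_length", "incomplete_stop_nt", "transcript_5p")

# Normalise an annotation data.frame: types, derived transcript_5p.
# Internal coordinates are 0-based half-open on the forward genome axis.
as_orf_annotation <- function(df) {
  missing_cols <- setdiff(setdiff(orf_columns, "transcript_5p"), names(df))
  if (length(missing_cols)) {
    stop("annotation is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df$gene_id <- as.character(df$gene_id)
  df$transcript_id <- as.character(df$transcript_id)
  df$strand <- as.character(df$strand)
  for (col in c("cds_start", "cds_end", "leader_length", "incomplete_stop_nt")) {
    df[[col]] <- as.integer(df[[col]])
  }
  if (is.null(df$transcript_5p)) {
    df$transcript_5p <- ifelse(df$strand == "+",
                               df$cds_start - df$leader_length,
                               df$cds_end - 1L + df$leader_length)
  }
  df$transcript_5p <- as.integer(df$transcript_5p)
  df <- df[, orf_columns]
  class(df) <- c("orf_annotation", "data.frame")
  df
}

#' Validate ORF annotations against a reference
#'
#' Checks, per record: coordinates inside the genome, `cds_start < cds_end`,
#' strand in {+,-}, frame closure `(cds_end - cds_start + incomplete_stop_nt)
#' %% 3 == 0`, `incomplete_stop_nt` in {0,1,2}, and consistency of
#' `leader_length` with `transcript_5p` in transcript orientation. Errors name
#' the offending record.
#'
#' @param orfs An `orf_annotation` data.frame.
#' @param ref A [genome_reference()].
#' @return `orfs`, invisibly, if valid.
#' @export
validate_orfs <- function(orfs, ref) {
  for (i in seq_len(nrow(orfs))) {
    o <- orfs[i, ]
    fail <- function(msg) stop(sprintf("annotation record '%s': %s", o$gene_id, msg))
    if (!o$strand %in% c("+", "-")) fail("strand must be '+' or '-'")
    if (is.na(o$cds_start) || is.na(o$cds_end)) fail("missing CDS coordinates")
    if (o$cds_start < 0L || o$cds_end > ref$length) fail("CDS coordinates out of genome range")
    if (o$cds_start >= o$cds_end) fail("cds_start must be < cds_end")
    if (!o$incomplete_stop_nt %in% 0:2) fail("incomplete_stop_nt must be 0, 1 or 2")
    if ((o$cds_end - o$cds_start + o$incomplete_stop_nt) %% 3L != 0L) {
      fail("CDS length plus incomplete_stop_nt is not a multiple of 3")
    }
    if (o$leader_length < 0L) fail("negative leader_length")
    implied <- if (o$strand == "+") o$cds_start - o$leader_length else o$cds_end - 1L + o$leader_length
    if (implied != o$transcript_5p) {
      fail("leader_length inconsistent with transcript_5p")
    }
    if (o$strand == "+" && o$transcript_5p < 0L) fail("transcript 5' end before genome start")
    if (o$strand == "-" && o$transcript_5p >= ref$length) fail("transcript 5' end past genome end")
  }
  invisible(orfs)
}

#' Load a reference genome and its ORF annotations
#'
#' Reads a single-contig FASTA plus annotations in GFF3 (CDS features with
#' attributes `gene_id`, `transcript_id`, `leader_length`,
#' `incomplete_stop_nt`; 1-based inclusive coordinates, converted on load) or
#' an 8-column TSV already in internal convention (0-based half-open).
#' Overlapping ORFs sharing a transcript (bicistronic units) are both retained.
#'
#' @param fasta_path Path to the FASTA file.
#' @param annotation_path Path to a `.gff3`/`.gff` or `.tsv` annotation file.
#' @param circular Is the genome circular?
#' @return A list with elements `ref` ([genome_reference()]) and `orfs`
#'   (an `orf_annotation` data.frame).
#' @export
load_reference <- function(fasta_path, annotation_path, circular = TRUE) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) != 1L) stop("expected a single-contig FASTA, found ", length(seqs))
  id <- sub("\\s.*$", "", names(seqs)[1])
  ref <- genome_reference(id, as.character(seqs[[1]]), circular = circular)
  orfs <- if (grepl("\\.gff3?$", annotation_path, ignore.case = TRUE)) {
    read_orf_gff3(annotation_path)
  } else {
    read_orf_tsv(annotation_path)
  }
  validate_orfs(orfs, ref)
  list(ref = ref, orfs = orfs)
}

read_orf_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  if (length(gr) == 0L) stop("no CDS records in ", path)
  df <- data.frame(
    gene_id = as.character(gr$gene_id),
    transcript_id = as.character(gr$transcript_id),
    strand = as.character(GenomicRanges::strand(gr)),
    # GFF3 is 1-based inclusive; internal is 0-based half-open
    cds_start = GenomicRanges::start(gr) - 1L,
    cds_end = GenomicRanges::end(gr),
    leader_length = as.integer(gr$leader_length),
    incomplete_stop_nt = as.integer(gr$incomplete_stop_nt),
    stringsAsFactors = FALSE
  )
  as_orf_annotation(df)
}

read_orf_tsv <- function(path) {
  as_orf_annotation(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write ORF annotations as GFF3
#'
#' @param orfs `orf_annotation` data.frame.
#' @param ref [genome_reference()] providing the contig name.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_orf_gff3 <- function(orfs, ref, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = ref$id,
    ranges = IRanges::IRanges(start = orfs$cds_start + 1L, end = orfs$cds_end),
    strand = orfs$strand
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "mitoriboseq", type = "CDS", phase = 0L,
    gene_id = orfs$gene_id, transcript_id = orfs$transcript_id,
    leader_length = orfs$leader_length,
    incomplete_stop_nt = orfs$incomplete_stop_nt
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write ORF annotations as TSV (internal 0-based half-open convention)
#' @param orfs `orf_annotation` data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_orf_tsv <- function(orfs, path) {
  utils::write.table(as.data.frame(orfs)[, orf_columns], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract the codons of an ORF
#'
#' Returns the ordered RNA codons of the coding sequence in translation order:
#' on '+' consecutive genomic triplets with T transliterated to U; on '-' the
#' reverse complement of the genomic slice is taken first. A trailing partial
#' codon (when `incomplete_stop_nt > 0`; completed by polyadenylation on the
#' transcript, absent from the genome) is excluded, so the list has
#' `floor((cds_end - cds_start) / 3)` entries.
#'
#' @param ref [genome_reference()].
#' @param orf One row of an `orf_annotation` data.frame.
#' @return Character vector of RNA codons.
#' @export
extract_orf_codons <- function(ref, orf) {
  cds <- substr(ref$sequence, orf$cds_start + 1L, orf$cds_end)
  if (orf$strand == "-") cds <- revcomp(cds)
  n <- nchar(cds) %/% 3L
  if (n == 0L) return(character(0))
  starts <- 3L * (seq_len(n) - 1L) + 1L
  dna_to_rna(substring(cds, starts, starts + 2L))
}

n_codons <- function(orf) (orf$cds_end - orf$cds_start) %/% 3L

#' Genomic codon-usage (fractional abundance) profile
#'
#' Tallies codon occurrences over the coding regions of all ORFs (overlapping
#' ORFs are each counted in their own frame, so shared nucleotides contribute
#' once per ORF) and normalizes so the fractions sum to 1. This is the
#' fractional abundance profile that footprint profiles are compared against.
#'
#' @param orf_codons List of codon vectors, one per ORF (from
#'   [extract_orf_codons()]); codons not in the tally may be pre-masked by the
#'   caller.
#' @param include_stops Keep stop-codon occurrences in the tally (default) or
#'   drop them before normalizing. The genomic tally is over all 64 triplets
#'   either way; only the counts change.
#' @param code Genetic code used to identify stop codons when
#'   `include_stops = FALSE`.
#' @return A list of class `codon_usage` with `counts` and `fractions`, both
#'   named numeric vectors over the 64 codons.
#' @export
codon_usage_profile <- function(orf_codons, include_stops = TRUE,
                                code = mito_genetic_code()) {
  all_codons <- unlist(orf_codons, use.names = FALSE)
  if (!include_stops) all_codons <- all_codons[!all_codons %in% stop_codons(code)]
  if (length(all_codons) == 0L) stop("no coding codons")
  counts <- codon_vector()
  tab <- table(factor(all_codons, levels = codons()))
  counts[] <- as.numeric(tab)
  structure(list(counts = counts, fractions = counts / sum(counts)),
            class = "codon_usage")
}

#' Write a codon-usage profile as TSV
#' @param usage A `codon_usage` object.
#' @param path Output file.
#' @param code Genetic code supplying the amino-acid column.
#' @return `path`, invisibly.
#' @export
write_codon_usage_tsv <- function(usage, path, code = mito_genetic_code()) {
  utils::write.table(
    data.frame(codon = codons(), amino_acid = unname(code$table[codons()]),
               count = unname(usage$counts), fraction = unname(usage$fractions)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Translate the first residues of an ORF
#'
#' The first codon is rendered as initiator Met (`M`) whenever it is one of the
#' code's start codons (AUG, AUA, AUU by default), even if its elongation
#' meaning differs; subsequent codons are translated by the code table. A stop
#' codon before `n_residues` is an error naming the position.
#'
#' @param ref [genome_reference()].
#' @param orf One annotation row.
#' @param n_residues Number of residues to translate.
#' @param code Genetic code, see [mito_genetic_code()].
#' @return Peptide string of length `n_residues`.
#' @export
translate_prefix <- function(ref, orf, n_residues, code = mito_genetic_code()) {
  cods <- extract_orf_codons(ref, orf)
  if (length(cods) < n_residues) {
    stop(sprintf("ORF '%s' has %d codons, fewer than %d requested",
                 orf$gene_id, length(cods), n_residues))
  }
  cods <- cods[seq_len(n_residues)]
  aa <- unname(code$table[cods])
  if (cods[1] %in% code$start_codons) aa[1] <- "M"
  premature <- which(aa == "*")
  if (length(premature)) {
    stop(sprintf("ORF '%s': stop codon at residue position %d before %d residues",
                 orf$gene_id, premature[1], n_residues))
  }
  paste(aa, collapse = "")
}
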