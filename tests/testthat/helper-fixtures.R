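# Hand-built fixtures, independent of the simulator, used across test files.

# 90-nt genome with one '+' ORF of 10 codons at [10, 40).
# ORF codons: ATG AAA CCC GGG TTT ACA CAT GAT TGG TAA (no internal stops).
tiny_plus_orf_dna <- "ATGAAACCCGGGTTTACACATGATTGGTAA"

tiny_ref <- function() {
  bg <- strsplit(paste(rep("ACGTCTGAAC", 9), collapse = ""), "")[[1]]
  bg[11:40] <- strsplit(tiny_plus_orf_dna, "")[[1]]
  genome_reference("chrM_test", paste(bg, collapse = ""))
}

tiny_orf <- function(leader = 0L) {
  as_tiny_annotation(data.frame(
    gene_id = "G1", transcript_id = "T1", strand = "+",
    cds_start = 10L, cds_end = 40L, leader_length = leader,
    incomplete_stop_nt = 0L, transcript_5p = 10L - leader))
}

# 120-nt genome holding the same ORF on both strands:
# '+' copy at [10, 40), '-' copy (reverse complement) at [70, 100).
tiny_ref_both <- function() {
  bg <- strsplit(paste(rep("ACGTCTGAAC", 12), collapse = ""), "")[[1]]
  bg[11:40] <- strsplit(tiny_plus_orf_dna, "")[[1]]
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(tiny_plus_orf_dna)))
  bg[71:100] <- strsplit(rc, "")[[1]]
  genome_reference("chrM_test", paste(bg, collapse = ""))
}

tiny_orf_minus <- function(leader = 0L) {
  as_tiny_annotation(data.frame(
    gene_id = "G2", transcript_id = "T2", strand = "-",
    cds_start = 70L, cds_end = 100L, leader_length = leader,
    incomplete_stop_nt = 0L, transcript_5p = 99L + leader))
}

as_tiny_annotation <- function(df) {
  class(df) <- c("orf_annotation", "data.frame")
  df
}

# quick footprint library from parallel vectors
make_lib <- function(five, len, strand = "+", replicate_id = "r1",
                     condition = "control", total_reads = NULL) {
  n <- max(length(five), length(len))
  fp <- data.frame(five_prime_pos = as.integer(rep_len(five, n)),
                   length = as.integer(rep_len(len, n)),
                   strand = rep_len(strand, n), stringsAsFactors = FALSE)
  if (is.null(total_reads)) total_reads <- n
  mitoriboseq:::new_footprint_library(replicate_id, condition, fp, total_reads)
}

# independent textbook formulas used as statistical oracles
oracle_one_sample_t <- function(x, mu0) {
  t <- (mean(x) - mu0) / (stats::sd(x) / sqrt(length(x)))
  list(t = t, p = 2 * stats::pt(-abs(t), df = length(x) - 1))
}

oracle_welch_t <- function(x, y) {
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df = df))
}

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# brute-force codon tally over the coding regions of a reference
oracle_codon_tally <- function(ref, orfs) {
  tally <- stats::setNames(numeric(64), codons())
  for (i in seq_len(nrow(orfs))) {
    orf <- orfs[i, ]
    cds <- substr(ref$sequence, orf$cds_start + 1, orf$cds_end)
    if (orf$strand == "-") {
      cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
    }
    n <- nchar(cds) %/% 3
    for (j in seq_len(n)) {
      cod <- chartr("T", "U", substr(cds, 3 * j - 2, 3 * j))
      tally[cod] <- tally[cod] + 1
    }
  }
  tally
}

# default observability-masked abundance for a simulated study
masked_abundance <- function(ref, orfs, offset = 14L) {
  mask <- observable_codon_mask(orfs, offset)
  lists <- lapply(seq_len(nrow(orfs)), function(i) {
    extract_orf_codons(ref, orfs[i, ])[mask[[orfs$gene_id[i]]]]
  })
  codon_usage_profile(lists)
}
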