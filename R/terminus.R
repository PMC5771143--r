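#' Admissible 5'-end window for initiation-proximal footprints
#'
#' For a terminal start (leader of 0–3 nt) the window runs from the transcript
#' 5' terminus through 5 nt downstream of the first nucleotide of the start
#' codon. For an internal start (bicistronic downstream ORF, long leader) the
#' same window shape is used with the terminus replaced by
#' `start - leader_context`.
#'
#' @param orf One annotation row.
#' @param leader_context Upstream context (nt) for internal starts.
#' @return Integer vector `c(lo, hi)` of admissible footprint 5'-end positions
#'   in transcript coordinates (0 = transcript 5' end), inclusive.
#' @export
terminus_window <- function(orf, leader_context = 40L) {
  start_t <- orf$leader_length  # transcript coord of the start codon's first nt
  lo <- if (orf$leader_length <= 3L) 0L else max(0L, start_t - as.integer(leader_context))
  c(lo, start_t + 5L)
}

#' Select initiation-proximal footprints
#'
#' Retains footprints on the ORF's strand whose 5'-end position falls inside
#' the [terminus_window()] (inclusive): from the very 5' terminus to 5 nt
#' downstream of the start codon.
#'
#' @param lib `footprint_library`.
#' @param orf One annotation row.
#' @param leader_context Passed to [terminus_window()].
#' @return Data.frame of retained footprints (columns `five_prime_pos`,
#'   `length`, `strand`, plus `tpos`, the 5' end in transcript coordinates).
#' @export
select_terminal_footprints <- function(lib, orf, leader_context = 40L) {
  w <- terminus_window(orf, leader_context)
  fp <- lib$footprints[lib$footprints$strand == orf$strand, , drop = FALSE]
  tpos <- genome_to_transcript(orf, fp$five_prime_pos)
  keep <- tpos >= w[1] & tpos <= w[2]
  out <- fp[keep, , drop = FALSE]
  out$tpos <- tpos[keep]
  rownames(out) <- NULL
  out
}

#' Footprint block fractions by 5'-start position
#'
#' Groups an initiation-proximal footprint subset by identical 5'-start
#' position; each group's depth (fraction) is its share of the subset, so the
#' fractions sum to 1. Per group a length histogram and the modal length are
#' reported; the first 20 nt of each group define its plotted extent against
#' reference coordinates.
#'
#' @param subset Data.frame from [select_terminal_footprints()].
#' @param gene_id Label carried on the result.
#' @return Object of class `block_set`: list with `gene_id`, `groups` (a
#'   data.frame with `position` (genome coord of the 5' start), `count`,
#'   `fraction`, `modal_length`) and `length_hist` (named list of length
#'   tables, keyed by position). Empty subset gives an empty `block_set` with a
#'   warning.
#' @export
block_fractions <- function(subset, gene_id = NA_character_) {
  if (nrow(subset) == 0L) {
    warning("empty footprint subset; returning empty block set")
    return(structure(list(gene_id = gene_id,
                          groups = data.frame(position = integer(0), count = integer(0),
                                              fraction = numeric(0), modal_length = integer(0)),
                          length_hist = list()),
                     class = "block_set"))
  }
  sp <- split(subset$length, subset$five_prime_pos)
  pos <- as.integer(names(sp))
  counts <- vapply(sp, length, integer(1))
  hist <- lapply(sp, function(l) table(l))
  modal <- vapply(hist, function(h) as.integer(names(h))[which.max(h)], integer(1))
  ord <- order(pos)
  structure(
    list(gene_id = gene_id,
         groups = data.frame(position = pos[ord], count = unname(counts[ord]),
                             fraction = unname(counts[ord]) / nrow(subset),
                             modal_length = unname(modal[ord])),
         length_hist = hist[ord]),
    class = "block_set"
  )
}

#' @export
print.block_set <- function(x, ...) {
  cat(sprintf("<block_set> %s: %d blocks over %d footprints\n", x$gene_id,
              nrow(x$groups), sum(x$groups$count)))
  invisible(x)
}

#' Fraction of initiation-proximal footprints covering the start (or leader)
#'
#' `includes_start_first_nt`: fraction of the subset whose aligned interval
#' contains the first nucleotide of the start codon and whose 5' end lies at or
#' before it (in transcript orientation) — the footprints that "include the 5'
#' start codon". `covers_leader`: fraction whose 5' end is strictly upstream of
#' the start codon (covering the non-coding leader nucleotides); an error when
#' the ORF has no leader.
#'
#' @param subset Data.frame from [select_terminal_footprints()].
#' @param orf One annotation row.
#' @param metric `"includes_start_first_nt"` or `"covers_leader"`.
#' @return Fraction in [0, 1].
#' @export
start_coverage_fraction <- function(subset, orf,
                                    metric = c("includes_start_first_nt", "covers_leader")) {
  metric <- match.arg(metric)
  if (metric == "covers_leader" && orf$leader_length == 0L) {
    stop(sprintf("ORF '%s' has no leader; covers_leader is undefined", orf$gene_id))
  }
  if (nrow(subset) == 0L) return(NaN)
  start_t <- orf$leader_length
  tpos <- if ("tpos" %in% names(subset)) subset$tpos else genome_to_transcript(orf, subset$five_prime_pos)
  if (metric == "includes_start_first_nt") {
    mean(tpos <= start_t & tpos + subset$length - 1L >= start_t)
  } else {
    mean(tpos < start_t)
  }
}

#' Per-nucleotide footprint coverage over a genomic interval
#'
#' `coverage[i]` is the number of strand-matching footprints whose aligned span
#' contains position i; used for raw pileup views of bicistronic stop/start
#' overlap regions.
#'
#' @param lib `footprint_library`.
#' @param interval Integer `c(from, to)`: 0-based half-open genomic interval.
#' @param strand Strand to count (`"+"`, `"-"`, or `"*"` for both).
#' @return Numeric coverage vector of length `to - from`, named by genome
#'   position.
#' @export
region_pileup <- function(lib, interval, strand = "+") {
  from <- as.integer(interval[1]); to <- as.integer(interval[2])
  stopifnot(from < to)
  fp <- lib$footprints
  if (strand != "*") fp <- fp[fp$strand == strand, , drop = FALSE]
  n <- to - from
  cov <- numeric(n)
  if (nrow(fp)) {
    a <- ifelse(fp$strand == "+", fp$five_prime_pos, fp$five_prime_pos - fp$length + 1L)
    b <- a + fp$length  # half-open
    a <- pmax(a, from); b <- pmin(b, to)
    keep <- b > a
    if (any(keep)) {
      d <- numeric(n + 1L)
      inc <- tabulate(a[keep] - from + 1L, nbins = n + 1L)
      dec <- tabulate(b[keep] - from + 1L, nbins = n + 1L)
      cov <- cumsum(inc - dec)[seq_len(n)]
    }
  }
  names(cov) <- from:(to - 1L)
  cov
}

#' Write a block set as TSV
#' @param blocks `block_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_blocks_tsv <- function(blocks, path) {
  df <- blocks$groups
  df <- cbind(gene_id = blocks$gene_id, df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
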