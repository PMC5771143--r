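# Transcript-coordinate helpers. Transcript coordinate t counts 5'->3' along
# the mRNA, with t = 0 at transcript_5p; on '-' ORFs the genome axis runs
# opposite to the transcript.
transcript_to_genome <- function(orf, t) {
  if (orf$strand == "+") orf$transcript_5p + t else orf$transcript_5p - t
}
genome_to_transcript <- function(orf, g) {
  if (orf$strand == "+") g - orf$transcript_5p else orf$transcript_5p - g
}

new_footprint_library <- function(replicate_id, condition, footprints,
                                  total_reads, skipped = 0L) {
  stopifnot(all(c("five_prime_pos", "length", "strand") %in% names(footprints)))
  if (total_reads < nrow(footprints)) {
    stop("total_reads must be >= number of stored footprints")
  }
  structure(
    list(replicate_id = as.character(replicate_id),
         condition = as.character(condition),
         footprints = footprints,
         total_reads = as.integer(total_reads),
         skipped = as.integer(skipped)),
    class = "footprint_library"
  )
}

#' @export
print.footprint_library <- function(x, ...) {
  cat(sprintf("<footprint_library> %s (%s): %d footprints, total_reads=%d\n",
              x$replicate_id, x$condition, nrow(x$footprints), x$total_reads))
  invisible(x)
}

check_footprint_sanity <- function(len, where) {
  bad <- which(len < 15L | len > 50L)
  if (length(bad)) {
    stop(sprintf("%s: footprint length %d at record %d outside sanity bounds [15, 50]",
                 where, len[bad[1]], bad[1]))
  }
}

#' Read an aligned footprint library
#'
#' Reads BED6 or SAM/BAM alignments into a footprint library. Each footprint is
#' stored by the genome coordinate of its 5'-most nucleotide in transcript
#' orientation (`five_prime_pos`, 0-based; for '-'-strand records this is the
#' rightmost aligned base), its aligned length, and strand. Unmapped and
#' secondary records are skipped and counted. `total_reads` — the denominator
#' for fractional profiles — is the number of retained primary alignments
#' before any length filtering. Footprint lengths outside the hard sanity
#' bounds 15–50 nt are a parse error.
#'
#' @param path Alignment file.
#' @param format `"auto"` (by extension), `"bed"`, `"sam"` or `"bam"`.
#' @param replicate_id Replicate label.
#' @param condition Condition label (e.g. `"control"`, `"mutant"`).
#' @param ref Optional [genome_reference()]; when given, records on a contig
#'   other than `ref$id` are an error.
#' @return A `footprint_library` object.
#' @export
read_footprints <- function(path, format = c("auto", "bed", "sam", "bam"),
                            replicate_id, condition, ref = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     bed = "bed", sam = "sam", bam = "bam",
                     stop("cannot infer format from extension of ", path))
  }
  if (format == "bed") {
    read_footprints_bed(path, replicate_id, condition, ref)
  } else {
    read_footprints_sam(path, format, replicate_id, condition, ref)
  }
}

read_footprints_bed <- function(path, replicate_id, condition, ref) {
  df <- tryCatch(
    utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                      col.names = c("chrom", "start", "end", "name", "score", "strand")),
    error = function(e) stop("malformed BED file ", path, ": ", conditionMessage(e))
  )
  bad <- which(!df$strand %in% c("+", "-") | !is.finite(df$start) |
                 !is.finite(df$end) | df$end <= df$start)
  if (length(bad)) stop(sprintf("malformed BED record at line %d of %s", bad[1], path))
  if (!is.null(ref) && any(df$chrom != ref$id)) {
    stop(sprintf("unknown contig '%s' in %s (expected '%s')",
                 setdiff(df$chrom, ref$id)[1], path, ref$id))
  }
  len <- as.integer(df$end - df$start)
  check_footprint_sanity(len, path)
  fp <- data.frame(
    five_prime_pos = as.integer(ifelse(df$strand == "+", df$start, df$end - 1L)),
    length = len,
    strand = df$strand,
    stringsAsFactors = FALSE
  )
  new_footprint_library(replicate_id, condition, fp, total_reads = nrow(fp))
}

read_footprints_sam <- function(path, format, replicate_id, condition, ref) {
  bam <- if (format == "sam") {
    Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  } else {
    path
  }
  all_n <- Rsamtools::countBam(bam)$records
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE))
  aln <- GenomicAlignments::readGAlignments(bam, param = param)
  skipped <- all_n - length(aln)
  if (skipped > 0) message(sprintf("%s: skipped %d unmapped/secondary records", path, skipped))
  if (!is.null(ref) && length(aln) &&
      any(as.character(GenomicAlignments::seqnames(aln)) != ref$id)) {
    stop(sprintf("unknown contig in %s (expected '%s')", path, ref$id))
  }
  st <- as.character(GenomicAlignments::strand(aln))
  start0 <- GenomicAlignments::start(aln) - 1L
  end <- GenomicAlignments::end(aln)
  len <- as.integer(end - start0)
  check_footprint_sanity(len, path)
  fp <- data.frame(
    five_prime_pos = as.integer(ifelse(st == "+", start0, end - 1L)),
    length = len, strand = st, stringsAsFactors = FALSE
  )
  new_footprint_library(replicate_id, condition, fp,
                        total_reads = nrow(fp), skipped = skipped)
}

#' Write a footprint library as BED6
#' @param lib `footprint_library`.
#' @param path Output file.
#' @param chrom Contig name for column 1.
#' @return `path`, invisibly.
#' @export
write_footprints_bed <- function(lib, path, chrom) {
  fp <- lib$footprints
  start <- ifelse(fp$strand == "+", fp$five_prime_pos, fp$five_prime_pos - fp$length + 1L)
  df <- data.frame(chrom = chrom, start = start, end = start + fp$length,
                   name = sprintf("fp%06d", seq_len(nrow(fp))), score = 0L,
                   strand = fp$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Filter a footprint library by fragment length
#'
#' Retains footprints with lengths in `[min_len, max_len]`; the default 24–37
#' nt window matches the observed mitoribosome protected-fragment sizes. The
#' `total_reads` denominator is by default left at its parse-time value
#' (`"parsed"` policy); `"filtered"` recomputes it as the retained count.
#'
#' @param lib `footprint_library`.
#' @param min_len,max_len Inclusive length bounds (nt).
#' @param denominator Denominator policy for downstream fractional profiles.
#' @return A filtered `footprint_library`.
#' @export
filter_by_length <- function(lib, min_len = 24L, max_len = 37L,
                             denominator = c("parsed", "filtered")) {
  denominator <- match.arg(denominator)
  stopifnot(min_len <= max_len)
  keep <- lib$footprints$length >= min_len & lib$footprints$length <= max_len
  fp <- data.frame(five_prime_pos = lib$footprints$five_prime_pos[keep],
                   length = lib$footprints$length[keep],
                   strand = lib$footprints$strand[keep],
                   stringsAsFactors = FALSE)
  total <- if (denominator == "parsed") lib$total_reads else nrow(fp)
  new_footprint_library(lib$replicate_id, lib$condition, fp,
                        total_reads = max(total, nrow(fp)), skipped = lib$skipped)
}

#' Assign footprint counts to ORF codons
#'
#' Two assignment rules are provided. `asite_offset` (default): each footprint
#' increments exactly one codon per ORF — the codon containing the position
#' `offset` nt downstream (in transcript orientation) of its 5' end,
#' interpreted as the ribosomal A-site; footprints whose A-site falls outside
#' the CDS, or that are shorter than the offset, are skipped (the latter with a
#' warning counter). `coverage`: each footprint increments every codon whose
#' three nucleotides all lie inside the aligned interval. Footprints are
#' assigned only to strand-matching ORFs; a footprint over a bicistronic
#' overlap can contribute to both ORFs.
#'
#' @param lib `footprint_library`.
#' @param ref [genome_reference()].
#' @param orfs `orf_annotation` data.frame.
#' @param mode `"asite_offset"` or `"coverage"`.
#' @param offset A-site offset from the 5' end, nt (asite_offset mode).
#' @return A data.frame of class `codon_count_matrix` with columns `gene_id`,
#'   `codon_index` (0-based), `codon`, `count`, and attributes `mode`,
#'   `offset`, `total_reads`, `n_short_skipped`.
#' @export
codon_counts <- function(lib, ref, orfs, mode = c("asite_offset", "coverage"),
                         offset = 14L) {
  mode <- match.arg(mode)
  fp5 <- lib$footprints$five_prime_pos
  flen <- lib$footprints$length
  fstr <- lib$footprints$strand
  n_short <- 0L
  gene_col <- idx_col <- codon_col <- count_col <- vector("list", nrow(orfs))
  for (i in seq_len(nrow(orfs))) {
    orf <- orfs[i, ]
    nc <- n_codons(orf)
    counts <- numeric(nc)
    sel <- fstr == orf$strand
    p5 <- fp5[sel]; ln <- flen[sel]
    if (length(p5)) {
      if (mode == "asite_offset") {
        ok <- ln > offset
        n_short <- n_short + sum(!ok)
        p5 <- p5[ok]
        if (orf$strand == "+") {
          asite <- p5 + offset
          idx <- (asite - orf$cds_start) %/% 3L
          inside <- asite >= orf$cds_start & asite < orf$cds_start + 3L * nc
        } else {
          asite <- p5 - offset
          idx <- (orf$cds_end - 1L - asite) %/% 3L
          inside <- asite <= orf$cds_end - 1L & asite > orf$cds_end - 3L * nc - 1L
        }
        if (any(inside)) counts <- tabulate(idx[inside] + 1L, nbins = nc)
      } else {
        a <- if (orf$strand == "+") p5 else p5 - ln + 1L
        b <- a + ln  # half-open genomic interval [a, b)
        if (orf$strand == "+") {
          j0 <- ceiling((a - orf$cds_start) / 3)
          j1 <- floor((b - orf$cds_start) / 3) - 1
        } else {
          j0 <- ceiling((orf$cds_end - b) / 3)
          j1 <- floor((orf$cds_end - a) / 3) - 1
        }
        j0 <- pmax(as.integer(j0), 0L)
        j1 <- pmin(as.integer(j1), nc - 1L)
        keep <- j1 >= j0
        if (any(keep)) {
          # difference-array accumulation of [j0, j1] increments
          inc <- tabulate(j0[keep] + 1L, nbins = nc + 1L)
          dec <- tabulate(j1[keep] + 2L, nbins = nc + 1L)
          counts <- cumsum(inc - dec)[seq_len(nc)]
        }
      }
    }
    gene_col[[i]] <- rep.int(orf$gene_id, nc)
    idx_col[[i]] <- seq_len(nc) - 1L
    codon_col[[i]] <- extract_orf_codons(ref, orf)
    count_col[[i]] <- as.numeric(counts)
  }
  if (n_short > 0) warning(sprintf("%d footprints shorter than offset %d skipped", n_short, offset))
  res <- data.frame(
    gene_id = unlist(gene_col, use.names = FALSE),
    codon_index = unlist(idx_col, use.names = FALSE),
    codon = unlist(codon_col, use.names = FALSE),
    count = unlist(count_col, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  attr(res, "mode") <- mode
  attr(res, "offset") <- as.integer(offset)
  attr(res, "total_reads") <- lib$total_reads
  attr(res, "n_short_skipped") <- n_short
  class(res) <- c("codon_count_matrix", "data.frame")
  res
}

#' Which codons are observable by A-site assignment?
#'
#' With footprints that cannot extend upstream of the transcript 5' terminus
#' and a fixed 5'-anchored A-site offset, codon `i` of an ORF can only host an
#' A-site when `3*i + leader_length >= offset`; earlier codons are structural
#' zeros of the observation process. Codons whose nucleotides overlap another
#' annotated CDS (bicistronic overlaps, where one read is counted in two
#' frames) can optionally be excluded as well. The resulting mask is applied to
#' both footprint tallies and the abundance profile in pause testing, so the
#' two sides of the comparison cover the same codon set.
#'
#' @param orfs `orf_annotation` data.frame.
#' @param offset A-site offset (nt).
#' @param exclude_overlaps Mask codons overlapping a different ORF's CDS.
#' @return Named list (by `gene_id`) of logical vectors over each ORF's codons;
#'   `TRUE` = retained.
#' @export
observable_codon_mask <- function(orfs, offset = 14L, exclude_overlaps = TRUE) {
  masks <- vector("list", nrow(orfs))
  names(masks) <- orfs$gene_id
  for (i in seq_len(nrow(orfs))) {
    orf <- orfs[i, ]
    idx <- seq_len(n_codons(orf)) - 1L
    m <- (3L * idx + orf$leader_length) >= offset
    if (exclude_overlaps && nrow(orfs) > 1L) {
      others <- orfs[-i, , drop = FALSE]
      cod_start <- if (orf$strand == "+") orf$cds_start + 3L * idx else orf$cds_end - 3L * idx - 3L
      cod_end <- cod_start + 3L  # half-open
      for (k in seq_len(nrow(others))) {
        o2 <- others[k, ]
        m <- m & !(cod_start < o2$cds_end & cod_end > o2$cds_start)
      }
    }
    masks[[i]] <- m
  }
  masks
}

#' Write a codon count matrix as TSV
#' @param counts `codon_count_matrix`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_codon_counts_tsv <- function(counts, path) {
  utils::write.table(as.data.frame(counts), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
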