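#' Build a per-codon dwell-factor vector
#'
#' Convenience constructor: all 64 codons default to 1 (uniform dwell), with
#' named overrides, e.g. `dwell_factors(AGA = 5)`.
#'
#' @param ... Named overrides (RNA codons).
#' @param default Baseline dwell factor.
#' @return Named numeric vector over the 64 codons; all values > 0 enforced.
#' @export
dwell_factors <- function(..., default = 1) {
  v <- stats::setNames(rep(default, 64), codons())
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), codons())
    if (length(bad)) stop("unknown codon(s): ", paste(bad, collapse = ", "))
    v[names(ov)] <- unlist(ov)
  }
  if (any(v <= 0)) stop("dwell factors must be positive")
  v
}

#' Simulation configuration
#'
#' Describes a synthetic mitochondrial-style study: a compact genome carrying
#' `n_orfs` reading frames (leaders of 3, 1 and 0 nt; one minus-strand ORF; one
#' ORF with an incomplete stop codon completed by polyadenylation; optionally a
#' bicistronic unit whose downstream ORF initiates internally, its start
#' displaced by `bicistronic_displacement` nt from the upstream stop), and
#' footprint libraries of `reads_per_replicate` fragments of 24-37 nt for
#' `replicates_per_condition` replicates per condition. Elongation reads place
#' a dwell-weighted codon in the A-site at `asite_offset` nt from the 5' end;
#' initiation reads (mass controlled by `initiation_weight`) start within the
#' 5'-terminus window, reproducing initiation-proximal pileups. The seed fully
#' determines all output.
#'
#' @param seed Integer seed; drives genome layout and read sampling.
#' @param genome_length Genome size (nt).
#' @param n_orfs Number of ORFs (>= 4 when `include_bicistronic`).
#' @param orf_length_range Range of ORF lengths (codons, including stop).
#' @param leader_lengths Leader lengths assigned to the first transcription
#'   units (recycled with 0 for the remainder); defaults to one 3-nt and one
#'   1-nt leader with the rest leaderless.
#' @param include_bicistronic Include one bicistronic transcription unit.
#' @param bicistronic_displacement Distance (nt) between the downstream ORF's
#'   start codon and the upstream ORF's stop codon.
#' @param n_minus_strand How many ORFs sit on the '-' strand.
#' @param incomplete_stop_orfs How many ORFs carry an incomplete stop
#'   (genomic CDS ending 1 nt short of the stop codon).
#' @param conditions Named list of 64-long dwell-factor vectors, one per
#'   condition (see [dwell_factors()]).
#' @param gene_expression Optional positive per-gene weights (recycled);
#'   default equal.
#' @param initiation_weight Per-position sampling mass of 5'-window initiation
#'   reads, relative to the unit elongation weight; 0 disables pileups.
#' @param reads_per_replicate Footprints per replicate library.
#' @param replicates_per_condition Replicates per condition.
#' @param length_probs Named probability vector over fragment lengths 24-37.
#' @param asite_offset A-site offset (nt) used for read placement.
#' @param leader_context Upstream window context for internal starts (nt).
#' @param dispersion Dirichlet-multinomial overdispersion; `Inf` = multinomial.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              genome_length = 14000L,
                              n_orfs = 13L,
                              orf_length_range = c(80L, 300L),
                              leader_lengths = c(3L, 1L),
                              include_bicistronic = TRUE,
                              bicistronic_displacement = 40L,
                              n_minus_strand = 1L,
                              incomplete_stop_orfs = 1L,
                              conditions = list(control = dwell_factors()),
                              gene_expression = NULL,
                              initiation_weight = 1,
                              reads_per_replicate = 100000L,
                              replicates_per_condition = 3L,
                              length_probs = NULL,
                              asite_offset = 14L,
                              leader_context = 40L,
                              dispersion = Inf) {
  if (is.null(length_probs)) {
    lens <- 24:37
    length_probs <- stats::setNames(stats::dnorm(lens, mean = 31, sd = 3), lens)
    length_probs <- length_probs / sum(length_probs)
  }
  stopifnot(abs(sum(length_probs) - 1) < 1e-9,
            all(names(length_probs) == as.character(24:37)))
  conditions <- lapply(conditions, function(d) {
    stopifnot(length(d) == 64L, all(d > 0))
    if (is.null(names(d))) names(d) <- codons()
    d[codons()]
  })
  if (is.null(names(conditions))) stop("conditions must be a named list")
  cfg <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
              n_orfs = as.integer(n_orfs), orf_length_range = as.integer(orf_length_range),
              leader_lengths = as.integer(leader_lengths),
              include_bicistronic = isTRUE(include_bicistronic),
              bicistronic_displacement = as.integer(bicistronic_displacement),
              n_minus_strand = as.integer(n_minus_strand),
              incomplete_stop_orfs = as.integer(incomplete_stop_orfs),
              conditions = conditions, gene_expression = gene_expression,
              initiation_weight = initiation_weight,
              reads_per_replicate = as.integer(reads_per_replicate),
              replicates_per_condition = as.integer(replicates_per_condition),
              length_probs = length_probs, asite_offset = as.integer(asite_offset),
              leader_context = as.integer(leader_context), dispersion = dispersion)
  class(cfg) <- "simulation_config"
  cfg
}

# DNA codon alphabets under the vertebrate mitochondrial code
mito_sense_dna_codons <- function() {
  tab <- Biostrings::getGeneticCode("2")
  names(tab)[tab != "*"]
}

# random ORF body: start + sense codons + optionally (in)complete stop
random_orf_dna <- function(n_codons, start_codon = NULL, incomplete_stop_nt = 0L,
                           stop_codon = "TAA") {
  sense <- mito_sense_dna_codons()
  if (is.null(start_codon)) start_codon <- sample(c("ATG", "ATA", "ATT"), 1L)
  if (incomplete_stop_nt > 0L) stop_codon <- "TAA"  # polyadenylation completes UAA
  body <- c(start_codon, sample(sense, n_codons - 2L, replace = TRUE))
  stop_part <- substr(stop_codon, 1L, 3L - incomplete_stop_nt)
  paste0(paste(body, collapse = ""), stop_part)
}

#' Simulate a reference genome with annotations
#'
#' Lays the configured ORFs on a random background with intergenic spacers,
#' honouring all annotation invariants: frame closure, leader consistency, a
#' minus-strand ORF, an incomplete-stop ORF, and (when configured) a
#' bicistronic unit whose two ORFs share a transcript with out-of-frame
#' overlapping coordinates and an internal AUG start. ORF bodies contain no
#' premature in-frame stop codons (both frames are checked in the overlap).
#' Output is fully determined by `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return List with `ref` ([genome_reference()]) and `orfs`
#'   (`orf_annotation` data.frame).
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  n <- config$n_orfs
  if (config$include_bicistronic && n < 4L) stop("need >= 4 ORFs for a bicistronic layout")
  lens <- sample(seq(config$orf_length_range[1], config$orf_length_range[2]), n, replace = TRUE)
  # transcription units: the bicistronic pair (ORFs 2 and 3) shares unit 2
  unit_of <- seq_len(n)
  if (config$include_bicistronic) unit_of[3L] <- 2L
  n_units <- length(unique(unit_of))
  leaders_unit <- rep(0L, n_units)
  leaders_unit[seq_along(config$leader_lengths)] <- config$leader_lengths
  strand <- rep("+", n)
  if (config$n_minus_strand > 0L) {
    strand[seq(n, by = -1L, length.out = config$n_minus_strand)] <- "-"
  }
  if (config$include_bicistronic && any(strand[2:3] == "-")) {
    stop("bicistronic unit must lie on the '+' strand")
  }
  incomplete <- rep(0L, n)
  if (config$incomplete_stop_orfs > 0L) {
    # incomplete stops go to the last plus-strand monocistronic ORFs
    mono_plus <- which(strand == "+" & !(config$include_bicistronic & seq_len(n) %in% 2:3))
    pick <- utils::tail(mono_plus, config$incomplete_stop_orfs)
    incomplete[pick] <- 1L
  }

  seq_chars <- sample(c("A", "C", "G", "T"), config$genome_length, replace = TRUE)
  pos <- 150L
  rows <- list()
  i <- 1L
  while (i <= n) {
    gap <- sample(40:90, 1L)
    if (config$include_bicistronic && i == 2L) {
      unit <- simulate_bicistronic_unit(lens[2L], lens[3L], config$bicistronic_displacement)
      leader <- leaders_unit[2L]
      cds_start_u <- pos + gap + leader
      useq <- unit$sequence
      substr_range <- cds_start_u + seq_len(nchar(useq))  # 1-based indices for 0-based coords
      if (max(substr_range) > config$genome_length - 150L) stop("infeasible layout: genome_length too small")
      seq_chars[substr_range] <- strsplit(useq, "")[[1]]
      t5p <- cds_start_u - leader
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = sprintf("ORF%02d", 2L), transcript_id = "TU02", strand = "+",
        cds_start = cds_start_u, cds_end = cds_start_u + unit$len_u_nt,
        leader_length = leader, incomplete_stop_nt = 0L, transcript_5p = t5p)
      d_start <- cds_start_u + unit$d_start_rel
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = sprintf("ORF%02d", 3L), transcript_id = "TU02", strand = "+",
        cds_start = d_start, cds_end = d_start + unit$len_d_nt,
        leader_length = d_start - t5p, incomplete_stop_nt = 0L, transcript_5p = t5p)
      pos <- d_start + unit$len_d_nt
      i <- i + 2L
    } else {
      unit_id <- unit_of[i]
      leader <- if (unit_id <= n_units) leaders_unit[unit_id] else 0L
      # cycle through the four mitochondrial stops so every stop identity
      # occurs in the genome (as in real mtDNA, where AGA/AGG terminate ORFs)
      stop_codon <- c("TAA", "TAG", "AGA", "AGG")[(i - 1L) %% 4L + 1L]
      orf_dna <- random_orf_dna(lens[i], incomplete_stop_nt = incomplete[i],
                                stop_codon = stop_codon)
      len_nt <- nchar(orf_dna)
      if (strand[i] == "+") {
        cds_start <- pos + gap + leader
        cds_end <- cds_start + len_nt
        if (cds_end > config$genome_length - 150L) stop("infeasible layout: genome_length too small")
        seq_chars[cds_start + seq_len(len_nt)] <- strsplit(orf_dna, "")[[1]]
        t5p <- cds_start - leader
      } else {
        cds_start <- pos + gap
        cds_end <- cds_start + len_nt
        if (cds_end + leader > config$genome_length - 150L) stop("infeasible layout: genome_length too small")
        seq_chars[cds_start + seq_len(len_nt)] <- strsplit(revcomp(orf_dna), "")[[1]]
        t5p <- cds_end - 1L + leader
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = sprintf("ORF%02d", i), transcript_id = sprintf("TU%02d", unit_of[i]),
        strand = strand[i], cds_start = cds_start, cds_end = cds_end,
        leader_length = leader, incomplete_stop_nt = incomplete[i], transcript_5p = t5p)
      pos <- cds_end + leader
      i <- i + 1L
    }
  }
  orfs <- as_orf_annotation(do.call(rbind, rows))
  ref <- genome_reference("chrM_sim", paste(seq_chars, collapse = ""), circular = TRUE)
  validate_orfs(orfs, ref)
  list(ref = ref, orfs = orfs)
}

# Bicistronic unit builder: upstream ORF of len_u codons, downstream ORF of
# len_d codons starting `displacement` nt upstream of the upstream stop codon.
# Both frames are kept free of premature stops (the downstream overlap codons
# by rejection sampling of the upstream tail).
simulate_bicistronic_unit <- function(len_u, len_d, displacement = 40L) {
  stops <- c("TAA", "TAG", "AGA", "AGG")
  sense <- mito_sense_dna_codons()
  len_u_nt <- 3L * len_u
  d_start_rel <- 3L * (len_u - 1L) - displacement
  if (d_start_rel %% 3L == 0L) stop("displacement must put the downstream ORF out of frame")
  if (d_start_rel <= 3L) stop("upstream ORF too short for the requested displacement")
  overlap_nt <- len_u_nt - d_start_rel
  n_tail_codons <- ceiling((overlap_nt + 3L) / 3L)  # upstream codons to resample
  head_codons <- c("ATG", sample(sense, len_u - 1L - n_tail_codons, replace = TRUE))
  for (attempt in 1:10000) {
    tail_codons <- c(sample(sense, n_tail_codons - 1L, replace = TRUE), "TAA")
    u_seq <- paste(c(head_codons, tail_codons), collapse = "")
    substr(u_seq, d_start_rel + 1L, d_start_rel + 3L) <- "ATG"
    u_codons <- substring(u_seq, seq(1L, len_u_nt - 2L, 3L), seq(3L, len_u_nt, 3L))
    if (any(u_codons[-len_u] %in% stops) || u_codons[len_u] != "TAA") next
    n_full_d <- (overlap_nt - 1L) %/% 3L  # full downstream codons inside the overlap
    d_over <- substring(u_seq, d_start_rel + 1L + 3L * (seq_len(n_full_d) - 1L),
                        d_start_rel + 3L * seq_len(n_full_d))
    if (any(d_over[-1L] %in% stops)) next
    # complete the downstream codon straddling the upstream 3' end
    partial <- substr(u_seq, d_start_rel + 3L * n_full_d + 1L, len_u_nt)
    need <- 3L - nchar(partial)
    repeat {
      fill <- paste(sample(c("A", "C", "G", "T"), need, replace = TRUE), collapse = "")
      if (!(paste0(partial, fill) %in% stops)) break
    }
    if (len_d < n_full_d + 3L) stop("downstream ORF too short for the overlap")
    rest <- c(sample(sense, len_d - n_full_d - 2L, replace = TRUE), "TAA")
    full_seq <- paste0(u_seq, fill, paste(rest, collapse = ""))
    len_d_nt <- 3L * len_d
    stopifnot(nchar(full_seq) == d_start_rel + len_d_nt)
    return(list(sequence = full_seq, len_u_nt = len_u_nt, len_d_nt = len_d_nt,
                d_start_rel = d_start_rel))
  }
  stop("could not satisfy bicistronic overlap constraints")
}

# Per-position sampling table shared by all conditions: elongation rows (one
# per observable codon) and initiation rows (one per admissible 5'-end
# position in the terminus window).
build_position_table <- function(config, ref, orfs) {
  expr <- config$gene_expression
  if (is.null(expr)) expr <- rep(1, nrow(orfs))
  expr <- rep_len(expr, nrow(orfs))
  if (any(expr <= 0)) stop("gene_expression weights must be positive")
  out <- vector("list", nrow(orfs))
  for (i in seq_len(nrow(orfs))) {
    orf <- orfs[i, ]
    cods <- extract_orf_codons(ref, orf)
    idx <- seq_along(cods) - 1L
    observable <- (3L * idx + orf$leader_length) >= config$asite_offset
    tpos5 <- 3L * idx + orf$leader_length - config$asite_offset
    elong <- data.frame(
      gene_id = orf$gene_id, type = "elongation",
      codon_index = idx[observable], codon = cods[observable],
      five_prime_pos = transcript_to_genome(orf, tpos5[observable]),
      strand = orf$strand, expression = expr[i], stringsAsFactors = FALSE)
    w <- terminus_window(orf, config$leader_context)
    wpos <- seq.int(w[1], w[2])
    init <- data.frame(
      gene_id = orf$gene_id, type = "initiation",
      codon_index = NA_integer_, codon = NA_character_,
      five_prime_pos = transcript_to_genome(orf, wpos),
      strand = orf$strand, expression = expr[i], stringsAsFactors = FALSE)
    out[[i]] <- rbind(elong, init)
  }
  do.call(rbind, out)
}

#' Simulate footprint libraries with known ground truth
#'
#' Each read is drawn from a per-position weight table: elongation positions
#' (one per A-site-observable codon) carry weight
#' `expression * dwell_factor[codon identity]`; initiation positions (5'-end
#' positions inside the terminus window) carry weight
#' `expression * initiation_weight`. Fragment lengths are drawn independently
#' from `length_probs`. Replicate counts are multinomial, or
#' Dirichlet-multinomial when `dispersion` is finite. Reads never extend past
#' the transcript 5' terminus (elongation reads are only placed at observable
#' codons; initiation reads start inside the window); 3' extension past the
#' CDS emulates reads running into the 3' UTR / poly(A) tail. Output is fully
#' determined by `config$seed`.
#'
#' @param config A [simulation_config()].
#' @param ref,orfs Reference and annotations from [simulate_genome()].
#' @param record_reads Keep the per-read truth records (needed by
#'   [write_fixture()]); disable to save memory in large simulation sweeps.
#' @return List with `libraries` (list of `footprint_library`, conditions x
#'   replicates, each with `total_reads = reads_per_replicate`) and `truth`
#'   (class `simulation_truth`: the position table, per-condition dwell
#'   factors, gene expression, and the per-read `(gene, codon, length)`
#'   records, `NULL` when `record_reads = FALSE`).
#' @export
simulate_footprints <- function(config, ref, orfs, record_reads = TRUE) {
  set.seed(config$seed + 77003L)
  tab <- build_position_table(config, ref, orfs)
  lens <- as.integer(names(config$length_probs))
  libraries <- list()
  reads_records <- list()
  for (cond in names(config$conditions)) {
    dwell <- config$conditions[[cond]]
    w <- tab$expression * ifelse(tab$type == "elongation",
                                 dwell[tab$codon], config$initiation_weight)
    if (sum(w) <= 0) stop("all sampling weights are zero")
    p <- w / sum(w)
    for (k in seq_len(config$replicates_per_condition)) {
      p_rep <- if (is.finite(config$dispersion)) {
        g <- stats::rgamma(length(p), shape = config$dispersion * p, rate = 1)
        if (sum(g) == 0) p else g / sum(g)
      } else p
      counts <- as.vector(stats::rmultinom(1L, config$reads_per_replicate, p_rep))
      row_idx <- rep.int(seq_along(counts), counts)
      n_reads <- length(row_idx)
      read_len <- sample(lens, n_reads, replace = TRUE, prob = config$length_probs)
      rep_id <- sprintf("%s_rep%d", cond, k)
      fp <- data.frame(five_prime_pos = tab$five_prime_pos[row_idx],
                       length = read_len, strand = tab$strand[row_idx],
                       stringsAsFactors = FALSE)
      libraries[[rep_id]] <- new_footprint_library(
        rep_id, cond, fp, total_reads = config$reads_per_replicate)
      if (record_reads) {
        reads_records[[rep_id]] <- data.frame(
          condition = cond, replicate_id = rep_id,
          gene_id = tab$gene_id[row_idx], type = tab$type[row_idx],
          codon_index = tab$codon_index[row_idx], codon = tab$codon[row_idx],
          five_prime_pos = tab$five_prime_pos[row_idx], length = read_len,
          stringsAsFactors = FALSE)
      }
    }
  }
  truth <- structure(
    list(position_table = tab, conditions = config$conditions,
         gene_expression = tab$expression[!duplicated(tab$gene_id)],
         reads = if (record_reads) do.call(rbind, reads_records) else NULL),
    class = "simulation_truth")
  list(libraries = libraries, truth = truth)
}

#' Write a simulated study as a file fixture
#'
#' Emits FASTA + GFF3 for the reference, one BED6 file per replicate library,
#' a per-read truth TSV and the configuration as YAML, all re-loadable by
#' [load_reference()] and [read_footprints()].
#'
#' @param ref,orfs Reference and annotations.
#' @param sim Result of [simulate_footprints()].
#' @param out_dir Output directory (created if needed).
#' @param config The [simulation_config()] used.
#' @return Named list of written paths, invisibly.
#' @export
write_fixture <- function(ref, orfs, sim, out_dir, config) {
  if (is.null(sim$truth$reads)) {
    stop("write_fixture needs per-read records; rerun simulate_footprints with record_reads = TRUE")
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  fasta <- file.path(out_dir, "genome.fasta")
  seqs <- Biostrings::DNAStringSet(stats::setNames(ref$sequence, ref$id))
  Biostrings::writeXStringSet(seqs, fasta)
  gff <- file.path(out_dir, "annotation.gff3")
  write_orf_gff3(orfs, ref, gff)
  beds <- character(0)
  for (lib in sim$libraries) {
    bed <- file.path(out_dir, paste0(lib$replicate_id, ".bed"))
    write_footprints_bed(lib, bed, chrom = ref$id)
    beds[lib$replicate_id] <- bed
  }
  truth_tsv <- file.path(out_dir, "truth_reads.tsv")
  utils::write.table(sim$truth$reads, truth_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg_yaml <- file.path(out_dir, "config.yaml")
  cfg <- unclass(config)
  cfg$conditions <- lapply(cfg$conditions, function(d) as.list(d))
  cfg$length_probs <- as.list(cfg$length_probs)
  yaml::write_yaml(cfg, cfg_yaml)
  invisible(list(fasta = fasta, gff3 = gff, beds = beds,
                 truth = truth_tsv, config = cfg_yaml))
}
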