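test_that("load_reference parses FASTA plus TSV and GFF3 annotations", {
  ref <- tiny_ref()
  fasta <- tempfile(fileext = ".fasta")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(ref$sequence, ref$id)), fasta)
  orfs <- tiny_orf()

  tsv <- tempfile(fileext = ".tsv")
  write_orf_tsv(orfs, tsv)
  loaded <- load_reference(fasta, tsv)
  expect_equal(loaded$ref$length, 90L)
  expect_equal(nrow(loaded$orfs), 1L)
  expect_equal(mitoriboseq:::n_codons(loaded$orfs[1, ]), 10L)

  gff <- tempfile(fileext = ".gff3")
  write_orf_gff3(orfs, ref, gff)
  loaded2 <- load_reference(fasta, gff)
  expect_equal(as.data.frame(loaded2$orfs), as.data.frame(orfs))
})

test_that("annotation validation enforces bounds, frame and leader invariants", {
  ref <- tiny_ref()
  # CDS length 31 with 2 missing stop nucleotides closes the frame
  ok <- as_tiny_annotation(data.frame(
    gene_id = "G", transcript_id = "T", strand = "+", cds_start = 5L,
    cds_end = 36L, leader_length = 0L, incomplete_stop_nt = 2L, transcript_5p = 5L))
  expect_silent(validate_orfs(ok, ref))

  out_of_range <- ok
  out_of_range$cds_end <- 95L  # past the 90-nt genome
  out_of_range$incomplete_stop_nt <- 0L
  expect_error(validate_orfs(out_of_range, ref), "out of genome range")

  frame_violation <- ok
  frame_violation$incomplete_stop_nt <- 0L
  expect_error(validate_orfs(frame_violation, ref), "multiple of 3")

  bad_leader <- ok
  bad_leader$leader_length <- 3L  # transcript_5p not updated
  expect_error(validate_orfs(bad_leader, ref), "leader_length")
})

test_that("genome references reject empty or ambiguous sequences", {
  expect_error(genome_reference("x", ""), "empty")
  expect_error(genome_reference("x", "ACGTN"), "outside")
})

test_that("extract_orf_codons handles strand, frame and incomplete stops", {
  # '+' CDS ATGAAATAA
  seq <- paste0("CC", "ATGAAATAA", "GG")
  ref <- genome_reference("c", seq)
  orf <- as_tiny_annotation(data.frame(
    gene_id = "G", transcript_id = "T", strand = "+", cds_start = 2L,
    cds_end = 11L, leader_length = 0L, incomplete_stop_nt = 0L, transcript_5p = 2L))
  expect_equal(extract_orf_codons(ref, orf), c("AUG", "AAA", "UAA"))

  # '-' CDS whose forward-genome sequence is TTACATTTT
  seq2 <- paste0("CC", "TTACATTTT", "GG")
  ref2 <- genome_reference("c", seq2)
  orf2 <- orf
  orf2$strand <- "-"
  orf2$transcript_5p <- 10L
  expect_equal(extract_orf_codons(ref2, orf2), c("AAA", "AUG", "UAA"))

  # trailing partial codon is excluded
  orf3 <- orf
  orf3$cds_end <- 10L
  orf3$incomplete_stop_nt <- 1L
  expect_equal(extract_orf_codons(ref, orf3), c("AUG", "AAA"))
})

test_that("extract_orf_codons matches a brute-force 3-mer slicing oracle", {
  set.seed(7)
  cds <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  ref <- genome_reference("c", paste0("AAAA", cds, "TTTT"))
  orf <- as_tiny_annotation(data.frame(
    gene_id = "G", transcript_id = "T", strand = "+", cds_start = 4L,
    cds_end = 64L, leader_length = 0L, incomplete_stop_nt = 0L, transcript_5p = 4L))
  oracle <- chartr("T", "U", substring(cds, seq(1, 58, 3), seq(3, 60, 3)))
  expect_equal(extract_orf_codons(ref, orf), oracle)
})

test_that("minus-strand extraction equals plus-strand extraction on the mirrored genome", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 120L
    seq <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    ref <- genome_reference("c", seq)
    s <- 10L + 3L * rep
    e <- s + 30L
    minus <- as_tiny_annotation(data.frame(
      gene_id = "G", transcript_id = "T", strand = "-", cds_start = s,
      cds_end = e, leader_length = 0L, incomplete_stop_nt = 0L, transcript_5p = e - 1L))
    ref_rc <- genome_reference("c", mitoriboseq:::revcomp(seq))
    plus_mirror <- as_tiny_annotation(data.frame(
      gene_id = "G", transcript_id = "T", strand = "+", cds_start = n - e,
      cds_end = n - s, leader_length = 0L, incomplete_stop_nt = 0L, transcript_5p = n - e))
    expect_equal(extract_orf_codons(ref, minus), extract_orf_codons(ref_rc, plus_mirror))
  }
})

test_that("codon usage fractions follow counts and sum to one", {
  single <- codon_usage_profile(list(c("AUG", "AAA", "UAA")))
  expect_equal(unname(single$fractions[c("AUG", "AAA", "UAA")]), rep(1 / 3, 3))
  expect_equal(sum(single$fractions), 1, tolerance = 1e-12)

  two <- codon_usage_profile(list(c("AUG", "AAA"), c("AAA", "UAA")))
  expect_equal(unname(two$fractions["AAA"]), 0.5)

  expect_error(codon_usage_profile(list(character(0))), "no coding codons")
})

test_that("codon usage of a 13-ORF synthetic genome matches an independent tally", {
  cfg <- simulation_config(seed = 42)
  g <- simulate_genome(cfg)
  lists <- lapply(seq_len(nrow(g$orfs)), function(i) extract_orf_codons(g$ref, g$orfs[i, ]))
  usage <- codon_usage_profile(lists)
  oracle <- oracle_codon_tally(g$ref, g$orfs)
  expect_equal(usage$counts, oracle)
  expect_equal(usage$fractions, oracle / sum(oracle), tolerance = 1e-12)
  # total codons conserved across the ORF lists
  expect_equal(sum(usage$counts), sum(lengths(lists)))
  # reordering ORFs leaves the profile unchanged
  usage_rev <- codon_usage_profile(rev(lists))
  expect_equal(usage_rev$fractions, usage$fractions)
  # dropping stop codons removes exactly the stop-codon mass
  no_stops <- codon_usage_profile(lists, include_stops = FALSE)
  stopc <- c("UAA", "UAG", "AGA", "AGG")
  expect_equal(unname(no_stops$counts[stopc]), rep(0, 4))
  expect_equal(sum(no_stops$fractions), 1, tolerance = 1e-12)
})

test_that("translate_prefix applies initiator recoding and stop checks", {
  make_ref_orf <- function(cds) {
    ref <- genome_reference("c", paste0("GG", cds, "CC"))
    orf <- as_tiny_annotation(data.frame(
      gene_id = "G", transcript_id = "T", strand = "+", cds_start = 2L,
      cds_end = 2L + nchar(cds), leader_length = 0L, incomplete_stop_nt = 0L,
      transcript_5p = 2L))
    list(ref = ref, orf = orf)
  }
  x <- make_ref_orf("ATGAAATAA")
  expect_equal(translate_prefix(x$ref, x$orf, 2), "MK")
  y <- make_ref_orf("ATTAAATAA")  # non-canonical AUU start reads as Met
  expect_equal(translate_prefix(y$ref, y$orf, 2), "MK")
  z <- make_ref_orf("ATGTAAAAA")
  expect_error(translate_prefix(z$ref, z$orf, 3), "stop codon at residue position 2")
  expect_error(translate_prefix(x$ref, x$orf, 5), "fewer than")
  # without initiator recoding AUU would be Ile
  code <- mito_genetic_code(start_codons = "AUG")
  expect_equal(translate_prefix(y$ref, y$orf, 2, code), "IK")
})

test_that("the mitochondrial code has the expected reassignments", {
  code <- mito_genetic_code()
  expect_equal(unname(code$table[c("UGA", "AUA", "AGA", "AGG")]), c("W", "M", "*", "*"))
  expect_true(all(c("AUG", "AUA", "AUU") %in% code$start_codons))
  expect_length(code$table, 64L)
})
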