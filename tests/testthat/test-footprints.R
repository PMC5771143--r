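write_bed_lines <- function(lines) {
  f <- tempfile(fileext = ".bed")
  writeLines(lines, f)
  f
}

test_that("BED parsing applies half-open arithmetic and strand mirroring", {
  f <- write_bed_lines(c("chrM\t100\t130\t.\t0\t+", "chrM\t100\t130\t.\t0\t-"))
  lib <- read_footprints(f, replicate_id = "r1", condition = "control")
  expect_equal(lib$footprints$five_prime_pos, c(100L, 129L))
  expect_equal(lib$footprints$length, c(30L, 30L))
  expect_equal(lib$total_reads, 2L)
})

test_that("malformed records, bad contigs and insane lengths are load errors", {
  bad <- write_bed_lines("chrM\t130\t100\t.\t0\t+")
  expect_error(read_footprints(bad, replicate_id = "r", condition = "c"),
               "malformed BED record at line 1")
  wrong <- write_bed_lines("chrX\t100\t130\t.\t0\t+")
  expect_error(
    read_footprints(wrong, replicate_id = "r", condition = "c", ref = tiny_ref()),
    "unknown contig")
  long <- write_bed_lines("chrM\t100\t151\t.\t0\t+")
  expect_error(read_footprints(long, replicate_id = "r", condition = "c"),
               "sanity bounds")
})

test_that("SAM reading skips unmapped/secondary records and mirrors strand", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chrM_test\tLN:90",
    "r1\t0\tchrM_test\t11\t42\t30M\t*\t0\t0\t*\t*",
    "r2\t16\tchrM_test\t21\t42\t30M\t*\t0\t0\t*\t*",
    "r3\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*",
    "r4\t256\tchrM_test\t11\t42\t30M\t*\t0\t0\t*\t*"
  ), sam)
  lib <- suppressMessages(
    read_footprints(sam, replicate_id = "r", condition = "c", ref = tiny_ref()))
  expect_equal(lib$skipped, 2L)
  expect_equal(lib$total_reads, 2L)
  # SAM pos is 1-based: plus read 5' end at 10; minus read 5' at rightmost base
  expect_equal(lib$footprints$five_prime_pos, c(10L, 49L))
  expect_equal(lib$footprints$strand, c("+", "-"))
})

test_that("length filtering keeps the 24-37 nt window and honours denominators", {
  lib <- make_lib(five = 100, len = c(23, 24, 37, 38))
  flt <- filter_by_length(lib)
  expect_equal(sort(flt$footprints$length), c(24L, 37L))
  expect_equal(flt$total_reads, 4L)  # parsed policy keeps the original denominator
  expect_equal(filter_by_length(lib, denominator = "filtered")$total_reads, 2L)

  empty <- filter_by_length(make_lib(integer(0), integer(0)))
  expect_equal(nrow(empty$footprints), 0L)

  set.seed(5)
  lens <- sample(15:50, 10000, replace = TRUE)
  big <- make_lib(five = 100, len = lens)
  expect_equal(nrow(filter_by_length(big)$footprints), sum(lens >= 24 & lens <= 37))
})

test_that("codon assignment matches the containment and A-site rules", {
  ref <- tiny_ref()
  orfs <- tiny_orf()
  # one 30-nt footprint exactly covering codons 0-9 of the [10,40) ORF
  lib <- make_lib(five = 10, len = 30)
  cov <- codon_counts(lib, ref, orfs, mode = "coverage")
  expect_equal(cov$count, rep(1, 10))
  asite <- codon_counts(lib, ref, orfs, mode = "asite_offset", offset = 14)
  expect_equal(asite$count, as.numeric(seq_len(10) == 5))  # position 14 lies in codon 4
  expect_equal(asite$codon, extract_orf_codons(ref, orfs[1, ]))
})

test_that("codon counting agrees with a per-footprint re-scan oracle on both strands", {
  ref <- tiny_ref_both()
  orfs <- rbind(tiny_orf(), tiny_orf_minus())
  set.seed(13)
  n <- 500
  strands <- sample(c("+", "-"), n, replace = TRUE)
  five <- ifelse(strands == "+", sample(0:60, n, replace = TRUE),
                 sample(40:119, n, replace = TRUE))
  lens <- sample(24:37, n, replace = TRUE)
  lib <- make_lib(five, lens, strands)

  # exhaustive per-footprint oracle
  oracle <- function(mode, offset = 14L) {
    res <- list()
    for (i in 1:2) {
      orf <- orfs[i, ]
      nc <- (orf$cds_end - orf$cds_start) %/% 3
      counts <- numeric(nc)
      for (k in seq_len(n)) {
        if (strands[k] != orf$strand) next
        a <- if (strands[k] == "+") five[k] else five[k] - lens[k] + 1L
        b <- a + lens[k] - 1L  # inclusive span
        if (mode == "asite_offset") {
          if (lens[k] <= offset) next
          asite <- if (strands[k] == "+") five[k] + offset else five[k] - offset
          for (j in seq_len(nc)) {
            cs <- if (orf$strand == "+") orf$cds_start + 3 * (j - 1) else orf$cds_end - 3 * j
            if (asite >= cs && asite <= cs + 2) counts[j] <- counts[j] + 1
          }
        } else {
          for (j in seq_len(nc)) {
            cs <- if (orf$strand == "+") orf$cds_start + 3 * (j - 1) else orf$cds_end - 3 * j
            if (a <= cs && b >= cs + 2) counts[j] <- counts[j] + 1
          }
        }
      }
      res[[i]] <- counts
    }
    unlist(res)
  }
  for (mode in c("asite_offset", "coverage")) {
    got <- codon_counts(lib, ref, orfs, mode = mode, offset = 14L)
    expect_equal(got$count, oracle(mode), info = mode)
  }
})

test_that("codon counting respects the spec count bounds", {
  ref <- tiny_ref()
  orfs <- tiny_orf()
  set.seed(3)
  n <- 200
  lib <- make_lib(sample(0:50, n, TRUE), sample(24:37, n, TRUE))
  asite <- codon_counts(lib, ref, orfs, mode = "asite_offset")
  expect_lte(sum(asite$count), n)
  cov <- codon_counts(lib, ref, orfs, mode = "coverage")
  expect_lte(sum(cov$count), n * ceiling(37 / 3))
})

test_that("counting is invariant under genome mirroring", {
  ref <- tiny_ref()
  orfs <- tiny_orf()
  set.seed(23)
  n <- 300
  five <- sample(0:60, n, TRUE)
  lens <- sample(24:37, n, TRUE)
  lib <- make_lib(five, lens, "+")
  L <- ref$length
  ref_rc <- genome_reference(ref$id, mitoriboseq:::revcomp(ref$sequence))
  orfs_rc <- orfs
  orfs_rc$strand <- "-"
  orfs_rc$cds_start <- L - orfs$cds_end
  orfs_rc$cds_end <- L - orfs$cds_start
  orfs_rc$transcript_5p <- L - 1L - orfs$transcript_5p
  lib_rc <- make_lib(L - 1L - five, lens, "-")
  for (mode in c("asite_offset", "coverage")) {
    expect_equal(codon_counts(lib_rc, ref_rc, orfs_rc, mode = mode)$count,
                 codon_counts(lib, ref, orfs, mode = mode)$count, info = mode)
  }
})

test_that("footprints shorter than the A-site offset are skipped with a warning", {
  lib <- make_lib(five = 10, len = c(30, 16), strand = "+")
  expect_warning(
    cc <- codon_counts(lib, tiny_ref(), tiny_orf(), mode = "asite_offset", offset = 20),
    "shorter than offset")
  expect_equal(sum(cc$count), 1)
})

test_that("the observability mask follows the A-site feasibility rule", {
  cfg <- simulation_config(seed = 9)
  g <- simulate_genome(cfg)
  mask <- observable_codon_mask(g$orfs, offset = 14L)
  for (i in seq_len(nrow(g$orfs))) {
    orf <- g$orfs[i, ]
    idx <- seq_len(mitoriboseq:::n_codons(orf)) - 1L
    feasible <- (3L * idx + orf$leader_length) >= 14L
    # masked codons are never observable; observable codons are masked only
    # when they overlap another CDS
    expect_true(all(mask[[orf$gene_id]] <= feasible))
    others <- g$orfs[-i, ]
    cod_start <- if (orf$strand == "+") orf$cds_start + 3L * idx else orf$cds_end - 3L * idx - 3L
    overlaps <- rep(FALSE, length(idx))
    for (k in seq_len(nrow(others))) {
      overlaps <- overlaps | (cod_start < others$cds_end[k] & cod_start + 3L > others$cds_start[k])
    }
    expect_equal(mask[[orf$gene_id]], feasible & !overlaps)
  }
})
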