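test_that("genome simulation is deterministic and honours the layout contract", {
  cfg <- simulation_config(seed = 1, reads_per_replicate = 1000)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1$ref$sequence, g2$ref$sequence)
  expect_identical(as.data.frame(g1$orfs), as.data.frame(g2$orfs))

  orfs <- g1$orfs
  expect_equal(nrow(orfs), 13L)
  expect_silent(validate_orfs(orfs, g1$ref))
  expect_true(any(orfs$strand == "-"))
  expect_true(any(orfs$incomplete_stop_nt > 0))
  # the three leader classes of the real system are present
  expect_true(all(c(0L, 1L, 3L) %in% orfs$leader_length))
})

test_that("the bicistronic unit overlaps out of frame with an internal AUG start", {
  cfg <- simulation_config(seed = 2)
  g <- simulate_genome(cfg)
  tu <- g$orfs[g$orfs$transcript_id == "TU02", ]
  expect_equal(nrow(tu), 2L)
  up <- tu[1, ]; down <- tu[2, ]
  expect_lt(down$cds_start, up$cds_end)   # overlapping coordinates
  expect_gt(down$cds_end, up$cds_end)
  expect_true((down$cds_start - up$cds_start) %% 3 != 0)  # out of frame
  # downstream start displaced 40 nt from the upstream stop codon
  expect_equal((up$cds_end - 3L) - down$cds_start, 40L)
  expect_equal(extract_orf_codons(g$ref, down)[1], "AUG")
  # both frames are free of premature stops
  stops <- c("UAA", "UAG", "AGA", "AGG")
  for (i in 1:2) {
    cods <- extract_orf_codons(g$ref, tu[i, ])
    expect_false(any(cods[-length(cods)] %in% stops))
  }
})

test_that("footprint simulation is seed-deterministic down to BED bytes", {
  cfg <- simulation_config(seed = 5, reads_per_replicate = 2000,
                           replicates_per_condition = 2)
  g <- simulate_genome(cfg)
  f1 <- tempfile(fileext = ".bed"); f2 <- tempfile(fileext = ".bed")
  s1 <- simulate_footprints(cfg, g$ref, g$orfs)
  s2 <- simulate_footprints(cfg, g$ref, g$orfs)
  write_footprints_bed(s1$libraries[[1]], f1, g$ref$id)
  write_footprints_bed(s2$libraries[[1]], f2, g$ref$id)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("read counts are conserved across replicates and conditions", {
  cfg <- simulation_config(seed = 6, reads_per_replicate = 3000,
                           replicates_per_condition = 3,
                           conditions = list(control = dwell_factors(),
                                             mutant = dwell_factors(GAA = 2)))
  g <- simulate_genome(cfg)
  sim <- simulate_footprints(cfg, g$ref, g$orfs)
  expect_length(sim$libraries, 6L)
  sizes <- vapply(sim$libraries, function(l) nrow(l$footprints), integer(1))
  expect_equal(unname(sizes), rep(3000L, 6L))
  expect_equal(nrow(sim$truth$reads), 3000L * 6L)
  # all simulated lengths live in the configured 24-37 nt support
  lens <- unlist(lapply(sim$libraries, function(l) l$footprints$length))
  expect_true(all(lens >= 24 & lens <= 37))
})

test_that("uniform dwell yields occupancy proportional to abundance", {
  cfg <- simulation_config(seed = 7, reads_per_replicate = 200000,
                           replicates_per_condition = 1, initiation_weight = 0)
  g <- simulate_genome(cfg)
  sim <- simulate_footprints(cfg, g$ref, g$orfs, record_reads = FALSE)
  mask <- observable_codon_mask(g$orfs)
  prof <- occupancy_profiles(sim$libraries, g$ref, g$orfs, mask = mask)[, 1]
  usage <- masked_abundance(g$ref, g$orfs)
  present <- usage$counts > 0
  observed <- prof[present] * 200000
  expected <- usage$fractions[present] * sum(observed)
  chisq <- sum((observed - expected)^2 / expected)
  p <- stats::pchisq(chisq, df = sum(present) - 1, lower.tail = FALSE)
  expect_gt(p, 0.001)
})

test_that("a configured dwell factor is recovered from occupancy ratios", {
  cfg <- simulation_config(seed = 9, reads_per_replicate = 500000,
                           replicates_per_condition = 1, initiation_weight = 0,
                           conditions = list(control = dwell_factors(AGA = 5)))
  g <- simulate_genome(cfg)
  sim <- simulate_footprints(cfg, g$ref, g$orfs, record_reads = FALSE)
  mask <- observable_codon_mask(g$orfs)
  prof <- occupancy_profiles(sim$libraries, g$ref, g$orfs, mask = mask)[, 1]
  usage <- masked_abundance(g$ref, g$orfs)
  rel <- (prof / sum(prof)) / usage$fractions
  ratio <- rel["AGA"] / stats::median(rel[usage$counts > 0], na.rm = TRUE)
  expect_lt(abs(ratio - 5) / 5, 0.1)
})

test_that("expected occupancy increases monotonically in the dwell factor", {
  occ <- vapply(c(1, 2, 4), function(f) {
    cfg <- simulation_config(seed = 10, reads_per_replicate = 100000,
                             replicates_per_condition = 1, initiation_weight = 0,
                             conditions = list(control = dwell_factors(GCA = f)))
    g <- simulate_genome(cfg)
    sim <- simulate_footprints(cfg, g$ref, g$orfs, record_reads = FALSE)
    occupancy_profiles(sim$libraries, g$ref, g$orfs)["GCA", 1]
  }, numeric(1))
  expect_true(all(diff(occ) > 0))
})

test_that("fixtures round-trip through FASTA/GFF3/BED files", {
  cfg <- simulation_config(seed = 11, reads_per_replicate = 1000,
                           replicates_per_condition = 1)
  g <- simulate_genome(cfg)
  sim <- simulate_footprints(cfg, g$ref, g$orfs)
  out <- file.path(tempfile(), "fixture")
  paths <- write_fixture(g$ref, g$orfs, sim, out, cfg)

  loaded <- load_reference(paths$fasta, paths$gff3)
  expect_equal(loaded$ref$sequence, g$ref$sequence)
  reorder_df <- function(df) {
    df <- as.data.frame(df)[order(df$gene_id), ]
    rownames(df) <- NULL
    df
  }
  expect_equal(reorder_df(loaded$orfs), reorder_df(g$orfs))

  lib0 <- sim$libraries[[1]]
  lib <- read_footprints(paths$beds[[1]], replicate_id = lib0$replicate_id,
                         condition = lib0$condition, ref = loaded$ref)
  # parsed multiset equals the simulated footprints
  key <- function(fp) sort(paste(fp$five_prime_pos, fp$length, fp$strand))
  expect_equal(key(lib$footprints), key(lib0$footprints))
  expect_equal(lib$total_reads, 1000L)

  truth <- utils::read.delim(paths$truth)
  expect_equal(nrow(truth), 1000L)
  cfg2 <- yaml::read_yaml(paths$config)
  expect_equal(cfg2$seed, cfg$seed)
})

test_that("dirichlet-multinomial dispersion widens replicate scatter", {
  make_sd <- function(disp) {
    cfg <- simulation_config(seed = 15, reads_per_replicate = 50000,
                             replicates_per_condition = 3, initiation_weight = 0,
                             dispersion = disp)
    g <- simulate_genome(cfg)
    sim <- simulate_footprints(cfg, g$ref, g$orfs, record_reads = FALSE)
    profs <- occupancy_profiles(sim$libraries, g$ref, g$orfs)
    mean(apply(profs, 1, stats::sd))
  }
  expect_gt(make_sd(50), 2 * make_sd(Inf))
})
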