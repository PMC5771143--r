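#' Default pipeline configuration
#'
#' Fills a pipeline configuration list with defaults: A-site counting at offset
#' 14, 24-37 nt length bounds, parse-time denominator, observability masking
#' for pause tests, q < 0.05 significance, complete linkage. See
#' [run_pipeline()] for the field reference.
#'
#' @param config Partial configuration list (or path to a YAML file).
#' @return Completed configuration list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    reference = list(fasta = NULL, annotation = NULL, circular = TRUE),
    libraries = list(),            # each: path, format, replicate_id, condition
    mode = "asite_offset", offset = 14L,
    min_len = 24L, max_len = 37L, denominator = "parsed",
    use_observability_mask = TRUE,
    fdr_threshold = 0.05, linkage = "complete",
    leader_context = 40L,
    out_dir = "mitoriboseq_out", seed = 1L,
    simulation = list()
  )
  cfg <- utils::modifyList(defaults, config)
  # modifyList drops unnamed entries; the library manifest is one
  if (!is.null(config$libraries)) cfg$libraries <- config$libraries
  if (!is.numeric(cfg$fdr_threshold) || cfg$fdr_threshold <= 0 || cfg$fdr_threshold >= 1) {
    stop("fdr_threshold must lie in (0, 1)")
  }
  ok_cond <- vapply(cfg$libraries, function(l) is.character(l$condition) && nzchar(l$condition),
                    logical(1))
  if (length(ok_cond) && !all(ok_cond)) stop("every library needs a condition label")
  cfg
}

pipeline_load <- function(cfg) {
  if (is.null(cfg$reference$fasta) || is.null(cfg$reference$annotation)) {
    stop("config must provide reference$fasta and reference$annotation")
  }
  loaded <- load_reference(cfg$reference$fasta, cfg$reference$annotation,
                           circular = isTRUE(cfg$reference$circular))
  libs <- lapply(cfg$libraries, function(l) {
    read_footprints(l$path, format = if (is.null(l$format)) "auto" else l$format,
                    replicate_id = l$replicate_id, condition = l$condition,
                    ref = loaded$ref)
  })
  names(libs) <- vapply(libs, function(l) l$replicate_id, character(1))
  c(loaded, list(libs = libs))
}

pipeline_profiles <- function(cfg, st, mask, denominator = cfg$denominator) {
  by_cond <- split(st$libs, vapply(st$libs, function(l) l$condition, character(1)))
  lapply(by_cond, function(libs) {
    occupancy_profiles(libs, st$ref, st$orfs, mode = cfg$mode, offset = cfg$offset,
                       min_len = cfg$min_len, max_len = cfg$max_len,
                       denominator = denominator, mask = mask)
  })
}

pipeline_mask <- function(cfg, st) {
  if (isTRUE(cfg$use_observability_mask)) {
    observable_codon_mask(st$orfs, offset = cfg$offset)
  } else NULL
}

masked_codon_lists <- function(ref, orfs, mask) {
  lst <- lapply(seq_len(nrow(orfs)), function(i) extract_orf_codons(ref, orfs[i, ]))
  names(lst) <- orfs$gene_id
  if (is.null(mask)) return(lst)
  lapply(names(lst), function(g) lst[[g]][mask[[g]]])
}

save_figure <- function(path, expr, width = 900, height = 500) {
  ok <- tryCatch({
    grDevices::png(path, width = width, height = height, type = "cairo")
    on.exit(grDevices::dev.off(), add = TRUE)
    eval.parent(substitute(expr))
    TRUE
  }, error = function(e) {
    message("figure skipped (", conditionMessage(e), "): ", path)
    FALSE
  })
  invisible(ok)
}

codon_test_barplot <- function(tests, mean_cols, main) {
  m <- t(as.matrix(tests[, mean_cols]))
  colnames(m) <- tests$codon
  bp <- graphics::barplot(m, beside = TRUE, las = 2, cex.names = 0.5,
                          col = c("red", "cyan3"), main = main,
                          ylab = "fraction of reads")
  sig <- which(tests$significant)
  if (length(sig)) {
    graphics::points(colMeans(bp)[sig], rep(0, length(sig)), pch = 4,
                     col = "blue", xpd = NA, cex = 0.8)
  }
  graphics::legend("topright", legend = mean_cols, fill = c("red", "cyan3"), bty = "n")
}

#' Run the mitoribosome-profiling pipeline
#'
#' Orchestrates the analysis stages behind subcommands, writing TSV artifacts,
#' figures and a machine-readable run log into `out_dir`. Subcommands:
#' `simulate` (generate a synthetic study fixture from `config$simulation`),
#' `codon-usage`, `occupancy` (per-replicate fractional profiles), `pauses`
#' (one-sample tests vs genomic abundance, per condition), `compare`
#' (two-sample control-vs-mutant tests), `terminus` (5'-block structure and
#' region pileups), `profiles` (per-ORF distributions), `cluster`
#' (1-Pearson distances, dendrogram, Newick), `hydropathy`, and `all`.
#'
#' Configuration fields (YAML file or list; see [pipeline_config()] for
#' defaults): `reference` (`fasta`, `annotation`, `circular`), `libraries`
#' (list of `path`/`format`/`replicate_id`/`condition`), `mode`, `offset`,
#' `min_len`/`max_len`, `denominator`, `use_observability_mask`,
#' `fdr_threshold`, `linkage`, `leader_context`, `out_dir`, `seed`,
#' `simulation`.
#'
#' @param subcommand One of the subcommands above.
#' @param config Configuration list or YAML path.
#' @return Named list of written artifact paths, invisibly.
#' @export
run_pipeline <- function(subcommand, config) {
  subcommands <- c("simulate", "codon-usage", "occupancy", "pauses", "compare",
                   "terminus", "profiles", "cluster", "hydropathy", "all")
  if (!subcommand %in% subcommands) {
    stop("unknown subcommand '", subcommand, "'; expected one of: ",
         paste(subcommands, collapse = ", "))
  }
  cfg <- pipeline_config(config)
  out <- cfg$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  artifacts <- list()

  if (subcommand %in% c("simulate", "all") && length(cfg$simulation) ||
      subcommand == "simulate") {
    sim_cfg <- do.call(simulation_config, c(list(seed = cfg$seed), cfg$simulation))
    g <- simulate_genome(sim_cfg)
    sim <- simulate_footprints(sim_cfg, g$ref, g$orfs)
    paths <- write_fixture(g$ref, g$orfs, sim, file.path(out, "fixture"), sim_cfg)
    artifacts$fixture <- paths
    if (subcommand == "all" && is.null(cfg$reference$fasta)) {
      cfg$reference$fasta <- paths$fasta
      cfg$reference$annotation <- paths$gff3
      cfg$libraries <- lapply(sim$libraries, function(l) {
        list(path = paths$beds[[l$replicate_id]], format = "bed",
             replicate_id = l$replicate_id, condition = l$condition)
      })
    }
  }
  if (subcommand == "simulate") {
    write_run_log(cfg, subcommand, out)
    return(invisible(artifacts))
  }

  st <- pipeline_load(cfg)
  mask <- pipeline_mask(cfg, st)
  code <- mito_genetic_code()
  steps <- if (subcommand == "all") {
    c("codon-usage", "occupancy", "pauses", "compare", "terminus",
      "profiles", "cluster", "hydropathy")
  } else subcommand

  if ("codon-usage" %in% steps) {
    lists <- masked_codon_lists(st$ref, st$orfs, NULL)
    for (variant in c("with_stops", "without_stops")) {
      usage <- codon_usage_profile(lists, include_stops = variant == "with_stops")
      f <- file.path(out, paste0("codon_usage_", variant, ".tsv"))
      write_codon_usage_tsv(usage, f)
      artifacts[[paste0("codon_usage_", variant)]] <- f
    }
  }

  if (any(c("occupancy", "cluster") %in% steps)) {
    profs <- pipeline_profiles(cfg, st, mask)
  }
  if (any(c("pauses", "compare") %in% steps)) {
    # pause testing compares compositions against the masked usage profile,
    # so both sides normalize over the same codon family
    profs_test <- pipeline_profiles(cfg, st, mask, denominator = "cds")
    usage_masked <- codon_usage_profile(masked_codon_lists(st$ref, st$orfs, mask))
  }

  if ("occupancy" %in% steps) {
    f <- file.path(out, "fractional_profiles.tsv")
    allp <- do.call(cbind, unname(profs))
    utils::write.table(data.frame(codon = codons(), allp, check.names = FALSE),
                       f, sep = "\t", quote = FALSE, row.names = FALSE)
    artifacts$fractional_profiles <- f
  }

  if ("pauses" %in% steps) {
    for (cond in names(profs_test)) {
      tests <- one_sample_codon_tests(profs_test[[cond]], usage_masked,
                                      alpha = cfg$fdr_threshold, code = code)
      f <- file.path(out, paste0("pauses_", cond, ".tsv"))
      write_codon_tests_tsv(tests, f)
      artifacts[[paste0("pauses_", cond)]] <- f
      save_figure(file.path(out, paste0("pauses_", cond, ".png")),
                  codon_test_barplot(tests, c("abundance_fraction", "mean_fraction"),
                                     paste("codon occupancy vs abundance:", cond)))
    }
  }

  if ("compare" %in% steps) {
    if (all(c("control", "mutant") %in% names(profs_test))) {
      tests <- two_sample_codon_tests(profs_test$control, profs_test$mutant,
                                      alpha = cfg$fdr_threshold, code = code)
      f <- file.path(out, "compare_control_vs_mutant.tsv")
      write_codon_tests_tsv(tests, f)
      artifacts$compare <- f
      save_figure(file.path(out, "compare_control_vs_mutant.png"),
                  codon_test_barplot(tests, c("mean_control", "mean_treated"),
                                     "codon occupancy: control vs mutant"))
    } else if (subcommand == "compare") {
      stop("compare requires libraries labelled 'control' and 'mutant'")
    }
  }

  if ("terminus" %in% steps) {
    for (lib in st$libs) {
      flt <- filter_by_length(lib, cfg$min_len, cfg$max_len, cfg$denominator)
      rows <- list()
      for (i in seq_len(nrow(st$orfs))) {
        orf <- st$orfs[i, ]
        sel <- select_terminal_footprints(flt, orf, cfg$leader_context)
        if (nrow(sel) == 0L) next
        blocks <- block_fractions(sel, gene_id = orf$gene_id)
        rows[[orf$gene_id]] <- cbind(gene_id = orf$gene_id, blocks$groups)
      }
      if (length(rows)) {
        f <- file.path(out, paste0("terminus_blocks_", lib$replicate_id, ".tsv"))
        utils::write.table(do.call(rbind, rows), f, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        artifacts[[paste0("terminus_", lib$replicate_id)]] <- f
      }
    }
    # raw pileup views over internal-start (bicistronic overlap) regions
    internal <- st$orfs[st$orfs$leader_length > 3L, , drop = FALSE]
    for (i in seq_len(nrow(internal))) {
      orf <- internal[i, ]
      iv <- c(max(0L, orf$cds_start - 60L), min(st$ref$length, orf$cds_start + 60L))
      piles <- lapply(st$libs, function(lib) region_pileup(lib, iv, orf$strand))
      f <- file.path(out, paste0("pileup_", orf$gene_id, ".tsv"))
      utils::write.table(
        data.frame(position = iv[1]:(iv[2] - 1L), do.call(cbind, piles),
                   check.names = FALSE),
        f, sep = "\t", quote = FALSE, row.names = FALSE)
      artifacts[[paste0("pileup_", orf$gene_id)]] <- f
    }
  }

  if ("profiles" %in% steps) {
    for (lib in st$libs) {
      flt <- filter_by_length(lib, cfg$min_len, cfg$max_len, cfg$denominator)
      cc <- codon_counts(flt, st$ref, st$orfs, mode = "asite_offset",
                         offset = cfg$offset)
      dist <- orf_fractional_distribution(cc)
      f <- file.path(out, paste0("orf_distribution_", lib$replicate_id, ".tsv"))
      write_orf_distribution_tsv(dist, f)
      artifacts[[paste0("profiles_", lib$replicate_id)]] <- f
    }
  }

  if ("cluster" %in% steps) {
    usage_all <- codon_usage_profile(masked_codon_lists(st$ref, st$orfs, mask))
    mat <- do.call(cbind, unname(profs))
    mat <- cbind(mat, abundance = usage_all$fractions)
    D <- pearson_distance_matrix(mat)
    hc <- hierarchical_cluster(D, linkage = cfg$linkage)
    f1 <- file.path(out, "profile_distances.tsv")
    write_distance_tsv(D, f1)
    f2 <- file.path(out, "profile_dendrogram.nwk")
    write_newick(hc, f2)
    artifacts$cluster <- c(f1, f2)
    save_figure(file.path(out, "profile_dendrogram.png"),
                plot(hc, main = "1 - Pearson profile clustering",
                     ylab = "1 - r"))
  }

  if ("hydropathy" %in% steps) {
    tab <- leader_hydropathy_table(st$ref, st$orfs, n = 10L, code = code)
    f <- file.path(out, "hydropathy.tsv")
    utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
    artifacts$hydropathy <- f
  }

  write_run_log(cfg, subcommand, out)
  invisible(artifacts)
}

write_run_log <- function(cfg, subcommand, out) {
  log <- list(
    package = "mitoriboseq",
    version = as.character(utils::packageVersion("mitoriboseq")),
    r_version = R.version.string,
    subcommand = subcommand,
    seed = cfg$seed,
    parameters = cfg[c("mode", "offset", "min_len", "max_len", "denominator",
                       "use_observability_mask", "fdr_threshold", "linkage",
                       "leader_context")],
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(log, file.path(out, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(NULL)
}
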