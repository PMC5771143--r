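#' Fractional footprint profile over the 64 codons
#'
#' Sums codon-assigned counts by codon identity and divides by the replicate's
#' total read count, giving the per-replicate fractional footprint profile.
#' An optional codon mask (see [observable_codon_mask()]) drops
#' initiation-proximal or overlap codons from the tally before summing.
#'
#' @param counts A `codon_count_matrix` from [codon_counts()].
#' @param total_reads Denominator; defaults to the matrix's recorded
#'   `total_reads`.
#' @param mask Optional named list of per-gene logical vectors.
#' @param replicate_id Label attached to the profile.
#' @return Named numeric vector of length 64 (fractions), with attribute
#'   `replicate_id`.
#' @export
fractional_footprint_profile <- function(counts, total_reads = attr(counts, "total_reads"),
                                         mask = NULL, replicate_id = NULL) {
  if (is.null(total_reads) || total_reads <= 0) stop("total_reads must be > 0")
  df <- as.data.frame(counts)
  if (!is.null(mask)) {
    mask_keys <- unlist(lapply(names(mask), function(g) {
      paste(g, seq_along(mask[[g]]) - 1L)
    }), use.names = FALSE)
    mask_vals <- unlist(mask, use.names = FALSE)
    keep_vec <- mask_vals[match(paste(df$gene_id, df$codon_index), mask_keys)]
    keep_vec[is.na(keep_vec)] <- TRUE  # genes absent from the mask are retained
    df <- df[keep_vec, , drop = FALSE]
  }
  prof <- codon_vector()
  s <- tapply(df$count, factor(df$codon, levels = codons()), sum, default = 0)
  prof[] <- as.numeric(s) / total_reads
  attr(prof, "replicate_id") <- replicate_id
  prof
}

#' Build fractional codon profiles for a set of libraries
#'
#' Convenience wrapper: length-filters each library, assigns counts to codons,
#' and builds its fractional profile. Returns a 64-row matrix with one column
#' per library, suitable for [one_sample_codon_tests()],
#' [two_sample_codon_tests()] and [pearson_distance_matrix()].
#'
#' @param libs List of `footprint_library` objects.
#' @param ref,orfs Reference and annotations.
#' @param mode,offset Passed to [codon_counts()].
#' @param min_len,max_len Passed to [filter_by_length()].
#' @param denominator Normalization policy: `"parsed"` (retained primary
#'   alignments at parse time, the default), `"filtered"` (footprints left
#'   after length filtering), or `"cds"` (reads assigned to the tallied —
#'   masked — codon set, so fractions sum to 1 over the same codon family as
#'   a usage profile computed on that set; this is the policy the pause tests
#'   use, since their null compares compositions over a common family).
#' @param mask Optional codon mask, see [fractional_footprint_profile()].
#' @return 64 x n numeric matrix; columns named by replicate id.
#' @export
occupancy_profiles <- function(libs, ref, orfs, mode = "asite_offset",
                               offset = 14L, min_len = 24L, max_len = 37L,
                               denominator = c("parsed", "filtered", "cds"),
                               mask = NULL) {
  denominator <- match.arg(denominator)
  profs <- vapply(libs, function(lib) {
    flt <- filter_by_length(lib, min_len, max_len,
                            if (denominator == "filtered") "filtered" else "parsed")
    cc <- codon_counts(flt, ref, orfs, mode = mode, offset = offset)
    prof <- fractional_footprint_profile(cc, total_reads = flt$total_reads,
                                         mask = mask,
                                         replicate_id = lib$replicate_id)
    if (denominator == "cds") {
      s <- sum(prof)
      if (s == 0) stop(sprintf("library '%s' has no reads on the tallied codons",
                               lib$replicate_id))
      prof <- prof / s
    }
    prof
  }, numeric(64))
  colnames(profs) <- vapply(libs, function(l) l$replicate_id, character(1))
  rownames(profs) <- codons()
  profs
}

# internal: fold a per-codon test into the standard result data.frame
codon_test_table <- function(mean_a, mean_b, tstat, pval, alpha, code) {
  q <- bh_fdr(pval)
  sig <- !is.na(q) & q < alpha
  direction <- rep("none", 64)
  direction[sig & mean_a > mean_b] <- "enriched"
  direction[sig & mean_a < mean_b] <- "depleted"
  data.frame(
    codon = codons(), amino_acid = unname(code$table[codons()]),
    t_statistic = tstat, p_value = pval, q_value = q,
    significant = sig, direction = direction,
    flagged = is.nan(pval), stringsAsFactors = FALSE
  )
}

#' One-sample per-codon pause tests against genomic abundance
#'
#' For each of the 64 codons, a two-tailed one-sample t-test compares the
#' replicate fractional footprint values with the genomic fractional abundance
#' at that codon (`t = (xbar - mu0) / (s / sqrt(n))`, n-1 df), followed by
#' Benjamini-Hochberg FDR correction over the 64-codon family; codons with
#' `q < alpha` are called significant. Degenerate codons with zero replicate
#' variance: if the mean equals the null value, `p = 1`; otherwise `p = NaN`,
#' the codon is flagged and excluded from the FDR family (m reduced).
#'
#' @param profiles 64 x n matrix of replicate fractional profiles (n >= 2),
#'   e.g. from [occupancy_profiles()].
#' @param abundance Named numeric vector of 64 abundance fractions, or a
#'   `codon_usage` object.
#' @param alpha Significance threshold on q (default 0.05).
#' @param code Genetic code used for the amino-acid column.
#' @return Data.frame with one row per codon: `codon`, `amino_acid`,
#'   `mean_fraction`, `abundance_fraction`, `t_statistic`, `p_value`,
#'   `q_value`, `significant`, `direction`, `flagged`.
#' @export
one_sample_codon_tests <- function(profiles, abundance, alpha = 0.05,
                                   code = mito_genetic_code()) {
  profiles <- as.matrix(profiles)
  if (ncol(profiles) < 2L) stop("insufficient replicates: need >= 2 profiles")
  if (inherits(abundance, "codon_usage")) abundance <- abundance$fractions
  abundance <- abundance[codons()]
  if (anyNA(abundance)) stop("abundance fractions missing for some codons")
  n <- ncol(profiles)
  tstat <- pval <- numeric(64)
  for (i in 1:64) {
    x <- profiles[i, ]
    mu0 <- abundance[i]
    if (stats::sd(x) == 0) {
      if (isTRUE(all.equal(mean(x), unname(mu0))) || mean(x) == mu0) {
        tstat[i] <- 0; pval[i] <- 1
      } else {
        tstat[i] <- sign(mean(x) - mu0) * Inf; pval[i] <- NaN
      }
    } else {
      tt <- stats::t.test(x, mu = mu0, alternative = "two.sided")
      tstat[i] <- unname(tt$statistic); pval[i] <- tt$p.value
    }
  }
  res <- codon_test_table(rowMeans(profiles), abundance, tstat, pval, alpha, code)
  res <- cbind(res[1:2],
               data.frame(mean_fraction = rowMeans(profiles),
                          abundance_fraction = unname(abundance)),
               res[-(1:2)])
  rownames(res) <- NULL
  res
}

#' Two-sample per-codon tests between conditions
#'
#' Per codon, a two-tailed two-sample t-test (Welch by default, matching the
#' default of `t.test`; pooled variance via `var_equal = TRUE`) compares
#' replicate fractional profiles between two conditions, with BH-FDR over the
#' 64-codon family. Zero-variance degeneracies are handled as in
#' [one_sample_codon_tests()] (equal group means give `p = 1`).
#'
#' @param control,treated 64 x n matrices of replicate profiles (n >= 2 each).
#' @param var_equal Use pooled-variance t instead of Welch.
#' @param alpha Significance threshold on q.
#' @param code Genetic code used for the amino-acid column.
#' @return Data.frame as in [one_sample_codon_tests()], with per-group means
#'   `mean_control` and `mean_treated`; `direction` is relative to control
#'   (`"enriched"` = higher in control).
#' @export
two_sample_codon_tests <- function(control, treated, var_equal = FALSE,
                                   alpha = 0.05, code = mito_genetic_code()) {
  control <- as.matrix(control); treated <- as.matrix(treated)
  if (ncol(control) < 2L || ncol(treated) < 2L) {
    stop("insufficient replicates: need >= 2 profiles per group")
  }
  tstat <- pval <- numeric(64)
  for (i in 1:64) {
    x <- control[i, ]; y <- treated[i, ]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      if (mean(x) == mean(y)) {
        tstat[i] <- 0; pval[i] <- 1
      } else {
        tstat[i] <- sign(mean(x) - mean(y)) * Inf; pval[i] <- NaN
      }
    } else {
      tt <- stats::t.test(x, y, var.equal = var_equal, alternative = "two.sided")
      tstat[i] <- unname(tt$statistic); pval[i] <- tt$p.value
    }
  }
  res <- codon_test_table(rowMeans(control), rowMeans(treated), tstat, pval, alpha, code)
  res <- cbind(res[1:2],
               data.frame(mean_control = rowMeans(control),
                          mean_treated = rowMeans(treated)),
               res[-(1:2)])
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg step-up FDR correction
#'
#' Step-up adjustment `q_(i) = min_{j >= i}(p_(j) * m / j)` capped at 1, with
#' the original order restored. `NaN`/`NA` entries are excluded from the family
#' (m reduced) and returned as-is. Values outside [0, 1] are an error.
#'
#' @param p_values Numeric vector of p-values (NaN/NA allowed).
#' @return Vector of q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  q <- p_values
  q[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  q
}

#' Write a codon test table as TSV
#' @param tests Result of [one_sample_codon_tests()] or
#'   [two_sample_codon_tests()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_codon_tests_tsv <- function(tests, path) {
  utils::write.table(tests, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
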