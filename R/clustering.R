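#' 1 - Pearson distance matrix between codon profiles
#'
#' Profile dissimilarity is defined as `1 - r_ij`, where `r_ij` is the Pearson
#' correlation between profiles i and j; distances lie in [0, 2] with a zero
#' diagonal. A profile with zero variance has no defined correlation and is an
#' error naming the profile.
#'
#' @param profiles 64 x n matrix (columns are profiles, e.g. replicate
#'   fractional profiles plus the abundance profile).
#' @return Symmetric n x n matrix of class `pearson_dist` with dimnames from
#'   the column names.
#' @export
pearson_distance_matrix <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (ncol(profiles) < 2L) stop("need at least 2 profiles")
  sds <- apply(profiles, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(profiles)[which(sds == 0)[1]]
    if (is.null(bad)) bad <- as.character(which(sds == 0)[1])
    stop(sprintf("profile '%s' has zero variance; Pearson distance undefined", bad))
  }
  D <- 1 - stats::cor(profiles)
  diag(D) <- 0
  class(D) <- c("pearson_dist", class(D))
  D
}

#' Agglomerative hierarchical clustering of a distance matrix
#'
#' Standard agglomerative clustering implemented directly (not delegated):
#' at each step the pair of clusters at minimal linkage distance is merged,
#' with deterministic tie-breaking by smallest label index; inter-cluster
#' distances are updated by the Lance-Williams rules for complete (max),
#' average (size-weighted mean, UPGMA) and single (min) linkage. The result
#' uses the standard `hclust` structure (negative entries in `merge` are
#' singletons), so `cutree`, `cophenetic`, `plot` and Newick export all apply.
#'
#' @param D Square symmetric distance matrix (e.g. from
#'   [pearson_distance_matrix()]).
#' @param linkage `"complete"` (default), `"average"` or `"single"`.
#' @return An object of class `hclust`.
#' @export
hierarchical_cluster <- function(D, linkage = c("complete", "average", "single")) {
  linkage <- match.arg(linkage)
  D <- unclass(as.matrix(D))
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 items to cluster")
  labels <- rownames(D)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  active <- seq_len(n)          # indices into D rows still live
  id <- -seq_len(n)             # hclust id: negative singleton, positive merge step
  size <- rep(1L, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  d <- D
  diag(d) <- Inf
  for (step in seq_len(n - 1L)) {
    sub <- d[active, active, drop = FALSE]
    min_d <- min(sub)
    # smallest label index tie-break: first (i, j) in row-major order of
    # active indices with i < j
    hit <- which(sub == min_d, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- active[hit[1, 1]]; j <- active[hit[1, 2]]
    # hclust row convention: singletons (by index) before clusters (by step)
    pair <- c(id[i], id[j])
    merge[step, ] <- pair[order(pair >= 0, abs(pair))]
    height[step] <- min_d
    others <- setdiff(active, c(i, j))
    for (k in others) {
      d[i, k] <- d[k, i] <- switch(
        linkage,
        complete = max(d[i, k], d[j, k]),
        single = min(d[i, k], d[j, k]),
        average = (size[i] * d[i, k] + size[j] * d[j, k]) / (size[i] + size[j])
      )
    }
    size[i] <- size[i] + size[j]
    id[i] <- step
    active <- setdiff(active, j)
  }
  structure(
    list(merge = merge, height = height, order = dendrogram_order(merge),
         labels = labels, method = linkage,
         call = match.call(), dist.method = "1-pearson"),
    class = "hclust"
  )
}

# leaf order for plotting: left-to-right traversal of the merge tree
dendrogram_order <- function(merge) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand(nrow(merge))
}

#' Leaf membership of the top dendrogram split
#'
#' Cuts the dendrogram at its root, returning the two-cluster membership
#' (equivalent to `cutree(hc, k = 2)`); used to ask whether replicate
#' conditions separate at the top split.
#'
#' @param hc An `hclust` object.
#' @return Named integer vector of cluster labels in {1, 2}.
#' @export
top_split <- function(hc) stats::cutree(hc, k = 2)

#' Export a dendrogram as Newick text
#' @param hc An `hclust` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Write a distance matrix as TSV
#' @param D Square distance matrix.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(D, path) {
  utils::write.table(as.data.frame(unclass(as.matrix(D))), path, sep = "\t",
                     quote = FALSE, row.names = TRUE, col.names = NA)
  invisible(path)
}
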