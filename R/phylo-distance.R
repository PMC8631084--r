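#' Pairwise identity-by-state distances
#'
#' For each pair of samples, the mean over co-called diploid autosomal sites
#' of `|dosage_i - dosage_j| / 2` — i.e. 1 minus the proportion of alleles
#' shared identical-by-state (the PLINK `--distance 1-ibs` metric, often
#' labelled an IBD distance in practice). X sites are excluded by default
#' because mixed male/female ploidy puts per-site sharing on an inhomogeneous
#' scale; `include_x = TRUE` enables ploidy-normalised sharing
#' `|d_i/p_i - d_j/p_j|` instead.
#'
#' @param gm A [geno_matrix()].
#' @param include_x Include X sites with ploidy-normalised sharing.
#' @return A `dist`-compatible symmetric matrix (class `swampx_dist`) with a
#'   `n_sites` attribute matrix of per-pair co-called site counts.
#' @export
ibs_distance <- function(gm, include_x = FALSE) {
  keep <- gm$sites$chrom_class == "autosome" |
    (include_x & gm$sites$chrom_class == "X")
  d <- gm$dosage[keep, , drop = FALSE] / gm$ploidy[keep, , drop = FALSE] * 2
  ns <- n_samples(gm)
  ids <- gm$samples$sample_id
  D <- matrix(0, ns, ns, dimnames = list(ids, ids))
  cnt <- matrix(0L, ns, ns, dimnames = list(ids, ids))
  for (i in seq_len(ns)) {
    for (j in seq_len(ns)) {
      if (j <= i) next
      ok <- !is.na(d[, i]) & !is.na(d[, j])
      if (!any(ok)) {
        abort(sprintf("no co-called sites for pair (%s, %s)", ids[i], ids[j]))
      }
      D[i, j] <- D[j, i] <- mean(abs(d[ok, i] - d[ok, j]) / 2)
      cnt[i, j] <- cnt[j, i] <- sum(ok)
    }
  }
  attr(D, "n_sites") <- cnt
  class(D) <- c("swampx_dist", class(D))
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via \pkg{ape}); on an additive distance
#' matrix the generating topology and branch lengths are recovered exactly.
#' Negative branch lengths, which NJ can produce on non-additive input, are
#' clamped to zero with a warning.
#'
#' @param D Symmetric nonnegative distance matrix with labelled rows.
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(D) {
  D <- unclass(D)
  if (nrow(D) < 3L) abort("neighbor joining needs at least 3 taxa")
  if (!isSymmetric(unname(D))) abort("distance matrix must be symmetric")
  if (any(D < 0)) abort("distance matrix must be nonnegative")
  tree <- ape::nj(stats::as.dist(D))
  if (any(tree$edge.length < 0)) {
    warn(sprintf("%d negative NJ branch length(s) clamped to 0",
                 sum(tree$edge.length < 0)))
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Root a tree on an outgroup leaf
#'
#' @param tree A `phylo` tree.
#' @param label Leaf label to use as outgroup.
#' @return A rooted `phylo` tree.
#' @export
root_by_outgroup <- function(tree, label) {
  if (!label %in% tree$tip.label) abort(sprintf("leaf '%s' not in tree", label))
  ape::root(tree, outgroup = label, resolve.root = TRUE)
}

#' Write a distance matrix as TSV
#'
#' Square headered matrix, rows in the same (sample sheet) order as columns.
#'
#' @param D Distance matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dist_tsv <- function(D, path) {
  tb <- as_tibble(unclass(D), rownames = "sample_id")
  readr::write_tsv(tb, path)
  invisible(path)
}
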