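#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble is_tibble
NULL

CHROM_CLASSES <- c("autosome", "X", "mito")
SEXES <- c("male", "female", "unknown")

#' Construct a genotype matrix
#'
#' The central data container: an ordered table of biallelic sites, a sample
#' sheet, and two sites-by-samples integer matrices holding the derived-allele
#' dosage and the called copy number (ploidy) of every entry. Ploidy encodes
#' the chromosome-class semantics: 2 on autosomes, 1 for males and 2 for
#' females on the X, and 1 for everyone on the mitochondrial genome. Missing
#' genotypes are `NA` in `dosage`.
#'
#' @param sites Tibble with columns `chrom`, `pos` (1-based), `ref`, `alt`
#'   (single characters), `chrom_class` (one of `"autosome"`, `"X"`, `"mito"`).
#' @param samples Tibble with columns `sample_id`, `population`, `sex`
#'   (`"male"`, `"female"`, or `"unknown"`). Sex must be known for every
#'   sample whenever X or mitochondrial sites are present.
#' @param dosage Integer matrix, `nrow(sites)` x `nrow(samples)`; `NA` marks a
#'   missing call.
#' @param ploidy Optional integer matrix of called copy numbers. If `NULL` it
#'   is derived from `chrom_class` and sex.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(sites, samples, dosage, ploidy = NULL) {
  sites <- as_tibble(sites)
  samples <- as_tibble(samples)
  req_site_cols <- c("chrom", "pos", "ref", "alt", "chrom_class")
  if (!all(req_site_cols %in% names(sites))) {
    abort(paste0("`sites` must have columns ", paste(req_site_cols, collapse = ", ")))
  }
  if (!all(c("sample_id", "population", "sex") %in% names(samples))) {
    abort("`samples` must have columns sample_id, population, sex")
  }
  if (anyDuplicated(samples$sample_id)) abort("duplicated sample_id in sample sheet")
  if (any(!samples$sex %in% SEXES)) abort("sex must be male, female or unknown")
  if (any(is.na(samples$population) | samples$population == "")) {
    abort("every sample needs a population label")
  }
  if (any(!sites$chrom_class %in% CHROM_CLASSES)) {
    abort("chrom_class must be autosome, X or mito")
  }
  if (any(sites$pos < 1)) abort("site positions are 1-based and must be >= 1")
  if (anyDuplicated(sites[, c("chrom", "pos")])) abort("duplicated (chrom, pos) site")
  if (any(nchar(sites$ref) != 1L) || any(nchar(sites$alt) != 1L)) {
    abort("only biallelic SNVs are supported (single-character ref and alt)")
  }
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (nrow(dosage) != nrow(sites) || ncol(dosage) != nrow(samples)) {
    abort("dosage must be a sites x samples matrix")
  }
  sex_needed <- any(sites$chrom_class %in% c("X", "mito"))
  if (sex_needed && any(samples$sex == "unknown")) {
    abort("sex must be known for all samples when X or mito sites are present")
  }
  if (is.null(ploidy)) {
    ploidy <- ploidy_matrix(sites$chrom_class, samples$sex)
  } else {
    ploidy <- as.matrix(ploidy)
    storage.mode(ploidy) <- "integer"
    if (!identical(dim(ploidy), dim(dosage))) abort("ploidy and dosage dimensions differ")
  }
  bad <- !is.na(dosage) & (dosage < 0L | dosage > ploidy)
  if (any(bad)) abort("dosage outside [0, ploidy] at some called entries")
  dimnames(dosage) <- list(NULL, samples$sample_id)
  dimnames(ploidy) <- list(NULL, samples$sample_id)
  structure(
    list(sites = sites, samples = samples, dosage = dosage, ploidy = ploidy),
    class = "geno_matrix"
  )
}

# expected copy number by chromosome class and sex
ploidy_matrix <- function(chrom_class, sex) {
  n_sites <- length(chrom_class)
  out <- matrix(2L, n_sites, length(sex))
  x_rows <- chrom_class == "X"
  mito_rows <- chrom_class == "mito"
  if (any(x_rows)) out[x_rows, sex == "male"] <- 1L
  if (any(mito_rows)) out[mito_rows, ] <- 1L
  out
}

#' @export
print.geno_matrix <- function(x, ...) {
  cls <- table(factor(x$sites$chrom_class, levels = CHROM_CLASSES))
  cat(sprintf(
    "<geno_matrix> %d sites (%d autosomal, %d X, %d mito) x %d samples, %d populations\n",
    nrow(x$sites), cls[["autosome"]], cls[["X"]], cls[["mito"]],
    nrow(x$samples), length(unique(x$samples$population))
  ))
  n_miss <- sum(is.na(x$dosage))
  cat(sprintf("  missing entries: %d (%.2f%%)\n", n_miss,
              100 * n_miss / max(1L, length(x$dosage))))
  invisible(x)
}

#' Number of sites / samples in a genotype matrix
#' @param gm A `geno_matrix`.
#' @return Integer count.
#' @export
n_sites <- function(gm) nrow(gm$sites)

#' @rdname n_sites
#' @export
n_samples <- function(gm) nrow(gm$samples)

# row-subset a geno_matrix, preserving site order
gm_subset_sites <- function(gm, idx) {
  geno_matrix(gm$sites[idx, , drop = FALSE], gm$samples,
              gm$dosage[idx, , drop = FALSE], gm$ploidy[idx, , drop = FALSE])
}

#' Build a region mask
#'
#' Masks are BED-style: 0-based, half-open `[start, end)` intervals. A site at
#' 1-based position `pos` lies inside the interval when
#' `start <= pos - 1 < end`.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Numeric vectors, 0-based half-open bounds (`start < end`).
#' @param label Single label for the mask.
#' @return Tibble of class `region_mask` with columns `chrom`, `start`, `end`,
#'   `label`.
#' @export
region_mask <- function(chrom, start, end, label = "mask") {
  if (length(start) != length(chrom) || length(end) != length(chrom)) {
    abort("chrom, start and end must have equal length")
  }
  if (any(start >= end)) abort("malformed interval: start >= end")
  if (any(start < 0)) abort("mask coordinates are 0-based and must be >= 0")
  out <- tibble(chrom = as.character(chrom), start = as.numeric(start),
                end = as.numeric(end), label = label)
  class(out) <- c("region_mask", class(out))
  out
}

#' Named preset masks for the X chromosome
#'
#' Presets follow the olive-baboon assembly convention used throughout the
#' package documentation: PAR1 at chrX:1-133703 and PAR2 at
#' chrX:143394134-143691637 (1-based inclusive), plus the 10-Mb window
#' proximal to the PAR1 boundary that shows anomalous differentiation and is
#' excluded from X-specific f-statistics. `"x_default"` is the union of all
#' three, the default exclusion applied before computing X-linked
#' f-statistics. Assembly-specific constants live here as data, not in the
#' estimators.
#'
#' @param name One of `"par1"`, `"par2"`, `"par1_proximal_10mb"`,
#'   `"x_default"`.
#' @param chrom Chromosome name carrying the PARs (default `"chrX"`).
#' @return A [region_mask()] tibble.
#' @export
preset_mask <- function(name = c("x_default", "par1", "par2", "par1_proximal_10mb"),
                        chrom = "chrX") {
  name <- match.arg(name)
  par1 <- region_mask(chrom, 0, 133703, "par1")
  par2 <- region_mask(chrom, 143394133, 143691637, "par2")
  prox <- region_mask(chrom, 133703, 10133703, "par1_proximal_10mb")
  out <- switch(name,
    par1 = par1, par2 = par2, par1_proximal_10mb = prox,
    x_default = dplyr::bind_rows(par1, par2, prox)
  )
  out$label <- name
  class(out) <- c("region_mask", setdiff(class(out), "region_mask"))
  out
}

# logical vector: which sites fall inside any mask interval
sites_in_mask <- function(sites, mask) {
  if (any(mask$start >= mask$end)) abort("malformed interval: start >= end")
  inside <- rep(FALSE, nrow(sites))
  for (k in seq_len(nrow(mask))) {
    hit <- sites$chrom == mask$chrom[k] &
      (sites$pos - 1) >= mask$start[k] & (sites$pos - 1) < mask$end[k]
    inside <- inside | hit
  }
  inside
}

#' Exclude or restrict a genotype matrix to masked regions
#'
#' @param gm A `geno_matrix`.
#' @param mask A [region_mask()] tibble (or anything with `chrom`, `start`,
#'   `end` in 0-based half-open convention).
#' @param mode `"exclude"` drops sites inside the mask; `"restrict"` keeps
#'   only sites inside it. The two modes partition the site set.
#' @return A `geno_matrix` with site order preserved.
#' @export
apply_region_mask <- function(gm, mask, mode = c("exclude", "restrict")) {
  mode <- match.arg(mode)
  inside <- sites_in_mask(gm$sites, mask)
  keep <- if (mode == "exclude") !inside else inside
  gm_subset_sites(gm, keep)
}

#' Keep only sites genotyped in every sample
#'
#' Complete-case filtering: the default missing-data policy for all
#' f-statistics downstream, mirroring analyses that restrict to sites
#' successfully genotyped in all individuals.
#'
#' @param gm A `geno_matrix`.
#' @return A `geno_matrix` with no missing entries.
#' @export
filter_complete_cases <- function(gm) {
  keep <- rowSums(is.na(gm$dosage)) == 0L
  if (!any(keep)) warn("no complete-case sites remain")
  gm_subset_sites(gm, keep)
}

#' Per-population allele counts
#'
#' Collapses a genotype matrix into the substrate of all f-statistics: for
#' every population and site, the number of derived-allele copies and the
#' total number of called copies (the sum of ploidies over called samples, so
#' hemizygous males contribute one copy on the X). Singleton populations are
#' legal; one diploid individual stands in for its population's allele
#' frequency.
#'
#' @param gm A `geno_matrix`.
#' @param populations Optional character subset of populations to keep.
#' @return An object of class `allele_counts`: site table plus
#'   sites-by-populations `derived` and `total` integer matrices.
#' @export
allele_counts_by_population <- function(gm, populations = NULL) {
  pops <- populations %||% unique(gm$samples$population)
  missing_pop <- setdiff(pops, gm$samples$population)
  if (length(missing_pop)) {
    abort(paste0("population(s) with no samples: ", paste(missing_pop, collapse = ", ")))
  }
  derived <- matrix(0L, n_sites(gm), length(pops), dimnames = list(NULL, pops))
  total <- derived
  for (p in pops) {
    cols <- which(gm$samples$population == p)
    d <- gm$dosage[, cols, drop = FALSE]
    pl <- gm$ploidy[, cols, drop = FALSE]
    pl[is.na(d)] <- 0L
    d[is.na(d)] <- 0L
    derived[, p] <- as.integer(rowSums(d))
    total[, p] <- as.integer(rowSums(pl))
  }
  structure(
    list(sites = gm$sites, populations = pops, derived = derived, total = total),
    class = "allele_counts"
  )
}

#' @export
print.allele_counts <- function(x, ...) {
  cat(sprintf("<allele_counts> %d sites x %d populations (%s)\n",
              nrow(x$sites), length(x$populations),
              paste(x$populations, collapse = ", ")))
  invisible(x)
}

# row-subset an allele_counts table
ac_subset <- function(ac, idx) {
  structure(
    list(sites = ac$sites[idx, , drop = FALSE], populations = ac$populations,
         derived = ac$derived[idx, , drop = FALSE],
         total = ac$total[idx, , drop = FALSE]),
    class = "allele_counts"
  )
}

#' Per-sample heterozygosity
#'
#' The number of heterozygous sites divided by the number of called sites per
#' sample, over autosomal diploid sites only (X and mito entries are not on a
#' comparable ploidy scale and are dropped).
#'
#' @param gm A `geno_matrix`.
#' @return Tibble with `sample_id`, `n_called`, `n_het`, `heterozygosity`
#'   (`NA` when a sample has no called autosomal site).
#' @export
per_sample_heterozygosity <- function(gm) {
  auto <- gm$sites$chrom_class == "autosome"
  d <- gm$dosage[auto, , drop = FALSE]
  pl <- gm$ploidy[auto, , drop = FALSE]
  called <- !is.na(d) & pl == 2L
  n_called <- colSums(called)
  n_het <- colSums(called & !is.na(d) & d == 1L)
  tibble(
    sample_id = gm$samples$sample_id,
    n_called = as.integer(n_called),
    n_het = as.integer(n_het),
    heterozygosity = ifelse(n_called > 0, n_het / n_called, NA_real_)
  )
}

#' Assign sites to jackknife blocks
#'
#' Partitions sites into non-overlapping per-chromosome windows
#' `[k*B, (k+1)*B)` on the 0-based position (so 1-based positions 1 and
#' `B` share block 0 and position `B + 1` starts block 1). Empty blocks never
#' appear; block identity is a pure function of (chrom, pos), hence invariant
#' to site order.
#'
#' @param sites Site tibble with `chrom`, `pos`, `chrom_class` columns (an
#'   `allele_counts` or `geno_matrix` is also accepted).
#' @param block_size Block width in bp; default 5 Mb.
#' @param classes Chromosome classes to include; sites outside get `NA`
#'   (and are excluded from any statistic using the partition).
#' @return Character vector of block ids aligned with the rows of `sites`.
#' @export
assign_blocks <- function(sites, block_size = 5e6, classes = c("autosome", "X")) {
  if (inherits(sites, c("geno_matrix", "allele_counts"))) sites <- sites$sites
  if (block_size <= 0) abort("block_size must be positive")
  id <- paste0(sites$chrom, ":", floor((sites$pos - 1) / block_size))
  id[!sites$chrom_class %in% classes] <- NA_character_
  id
}
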