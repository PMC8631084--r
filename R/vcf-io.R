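#' Read a sample sheet
#'
#' Headered TSV with columns `sample_id`, `population`, `sex`.
#'
#' @param path File path.
#' @return Tibble sample sheet.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  need <- c("sample_id", "population", "sex")
  if (!all(need %in% names(sheet))) {
    abort("sample sheet needs columns sample_id, population, sex")
  }
  if (anyDuplicated(sheet$sample_id)) abort("duplicated sample_id in sample sheet")
  if (any(!sheet$sex %in% SEXES)) abort("sex must be male, female or unknown")
  sheet[, need]
}

#' Read a chromosome-class map
#'
#' Two-column headered TSV (`chrom`, `chrom_class`) assigning each chromosome
#' to `autosome`, `X` or `mito`.
#'
#' @param path File path.
#' @return Named character vector chrom -> class.
#' @export
read_class_map <- function(path) {
  map <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("chrom", "chrom_class") %in% names(map))) {
    abort("class map needs columns chrom, chrom_class")
  }
  if (any(!map$chrom_class %in% CHROM_CLASSES)) {
    abort("chrom_class must be autosome, X or mito")
  }
  stats::setNames(map$chrom_class, map$chrom)
}

# parse GT strings ("0/1", "1|1", "0", ".", "./.") into dosage + called ploidy
parse_gt <- function(gt) {
  gt <- sub(":.*$", "", gt)
  alleles <- strsplit(gt, "[/|]", fixed = FALSE)
  dosage <- vapply(alleles, function(a) {
    if (any(a == "." | is.na(a))) return(NA_integer_)
    sum(a == "1")
  }, integer(1))
  called_ploidy <- vapply(alleles, length, integer(1))
  list(dosage = dosage, called_ploidy = called_ploidy)
}

#' Read genotypes from a VCF file
#'
#' Ingests a multi-sample VCF (GT field only), keeps biallelic SNV rows, and
#' applies the ploidy semantics of each chromosome class: on the X, male calls
#' are coerced to a single copy (a homozygous diploid call becomes the
#' corresponding haploid call; a heterozygous male X call is set missing under
#' the default policy or raises an error under `male_het_x = "error"`).
#' Mitochondrial calls are handled the same way for every sample. Rows dropped
#' as non-SNV or multi-allelic are reported with a message.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param sheet Sample sheet tibble; every `sample_id` must be present in the
#'   VCF header. Extra VCF samples are ignored.
#' @param class_map Named character vector chrom -> chrom_class; VCF rows on
#'   chromosomes absent from the map are dropped with a message.
#' @param male_het_x `"missing"` (default) or `"error"`: policy for
#'   heterozygous male X (or heterozygous mito) calls.
#' @return A [geno_matrix()].
#' @export
read_vcf <- function(path, sheet, class_map, male_het_x = c("missing", "error")) {
  male_het_x <- match.arg(male_het_x)
  sheet <- as_tibble(sheet)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt_raw <- v@gt
  vcf_samples <- colnames(gt_raw)[-1]
  missing_samples <- setdiff(sheet$sample_id, vcf_samples)
  if (length(missing_samples)) {
    abort(paste0("samples absent from VCF: ", paste(missing_samples, collapse = ", ")))
  }
  is_snv <- !is.na(fix$REF) & !is.na(fix$ALT) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  known_chrom <- fix$CHROM %in% names(class_map)
  keep <- is_snv & known_chrom
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    inform(sprintf("read_vcf: dropped %d non-biallelic-SNV or unmapped-chromosome row(s)", n_drop))
  }
  fix <- fix[keep, , drop = FALSE]
  gt_raw <- gt_raw[keep, , drop = FALSE]

  sites <- tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    chrom_class = unname(class_map[fix$CHROM])
  )
  ns <- nrow(sites)
  np <- nrow(sheet)
  dosage <- matrix(NA_integer_, ns, np)
  exp_ploidy <- ploidy_matrix(sites$chrom_class, sheet$sex)
  for (j in seq_len(np)) {
    parsed <- parse_gt(gt_raw[, sheet$sample_id[j]])
    d <- parsed$dosage
    haplo <- exp_ploidy[, j] == 1L & !is.na(d) & parsed$called_ploidy == 2L
    het <- haplo & d == 1L
    if (any(het)) {
      if (male_het_x == "error") {
        abort(sprintf("heterozygous call at haploid entry (sample %s, e.g. %s:%d)",
                      sheet$sample_id[j], sites$chrom[which(het)[1]], sites$pos[which(het)[1]]))
      }
      warn(sprintf("read_vcf: %d heterozygous haploid-context call(s) in sample %s set to missing",
                   sum(het), sheet$sample_id[j]))
      d[het] <- NA_integer_
    }
    hom <- haplo & !is.na(d) & d != 1L
    d[hom] <- d[hom] %/% 2L
    dosage[, j] <- d
  }
  geno_matrix(sites, sheet, dosage, exp_ploidy)
}

#' Write a genotype matrix as VCF
#'
#' Emits a plain-text VCF 4.2 file with GT-only genotypes. Haploid entries
#' (male X, mitochondria) are written as haploid GT (`0`/`1`); missing entries
#' as `./.` or `.` according to ploidy. `read_vcf()` of the output restores
#' the matrix exactly.
#'
#' @param gm A [geno_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=swampx",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  ), con)
  for (ch in unique(gm$sites$chrom)) {
    len <- max(gm$sites$pos[gm$sites$chrom == ch]) + 1L
    writeLines(sprintf("##contig=<ID=%s,length=%d>", ch, len), con)
  }
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", gm$samples$sample_id), collapse = "\t"), con)
  gt_of <- function(d, pl) {
    ifelse(pl == 1L,
           ifelse(is.na(d), ".", as.character(d)),
           ifelse(is.na(d), "./.", c("0/0", "0/1", "1/1")[d + 1L]))
  }
  if (n_sites(gm) > 0L) {
    gt <- matrix("", n_sites(gm), n_samples(gm))
    for (j in seq_len(n_samples(gm))) {
      gt[, j] <- gt_of(gm$dosage[, j], gm$ploidy[, j])
    }
    lines <- paste(
      gm$sites$chrom, gm$sites$pos, ".", gm$sites$ref, gm$sites$alt,
      ".", "PASS", ".", "GT",
      apply(gt, 1L, paste, collapse = "\t"),
      sep = "\t"
    )
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write a sample sheet / class map
#'
#' @param gm A [geno_matrix()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(gm, path) {
  readr::write_tsv(gm$samples, path)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
write_class_map <- function(gm, path) {
  map <- dplyr::distinct(gm$sites[, c("chrom", "chrom_class")])
  readr::write_tsv(map, path)
  invisible(path)
}
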