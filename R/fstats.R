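#' f-statistic configuration
#'
#' @param kind `"f2"`, `"f3_outgroup"` or `"f4"`.
#' @param pops Ordered population labels: `c(A, B)` for f2, `c(A, B, C)` for
#'   outgroup f3 (C is the outgroup whose heterozygosity correction is
#'   applied), `c(A, B, C, D)` for f4. Labels must be distinct.
#' @param bias_correction Subtract finite-sample heterozygosity terms
#'   (f2/f3 only; f4 needs none).
#' @return An `fstat_config` object.
#' @export
fstat_config <- function(kind = c("f2", "f3_outgroup", "f4"), pops,
                         bias_correction = TRUE) {
  kind <- match.arg(kind)
  n_need <- c(f2 = 2L, f3_outgroup = 3L, f4 = 4L)[[kind]]
  pops <- as.character(pops)
  if (length(pops) != n_need) {
    abort(sprintf("%s needs %d populations, got %d", kind, n_need, length(pops)))
  }
  if (anyDuplicated(pops)) abort("population labels must be distinct within a configuration")
  structure(list(kind = kind, pops = pops, bias_correction = bias_correction),
            class = "fstat_config")
}

#' @export
format.fstat_config <- function(x, ...) {
  p <- x$pops
  switch(x$kind,
    f2 = sprintf("f2(%s, %s)", p[1], p[2]),
    f3_outgroup = sprintf("f3(%s, %s; %s)", p[1], p[2], p[3]),
    f4 = sprintf("f4(%s, %s; %s, %s)", p[1], p[2], p[3], p[4])
  )
}

#' @export
print.fstat_config <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# unbiased per-population heterozygosity term: p(1-p) * n/(n-1); NA when n < 2
h_term <- function(d, n) {
  p <- d / n
  out <- p * (1 - p) * n / (n - 1)
  out[n < 2] <- NA_real_
  out
}

#' Per-site f-statistic kernels
#'
#' Vectorised estimators on aligned per-site allele counts
#' (derived copies `d`, total called copies `n` per population):
#' * f2: `(pA - pB)^2 - hA/nA - hB/nB`
#' * outgroup f3 (C outgroup): `(pC - pA)(pC - pB) - hC/nC`
#' * f4: `(pA - pB)(pC - pD)` (no correction needed)
#'
#' with `h = p(1-p) n/(n-1)` the unbiased within-population heterozygosity.
#' Correction terms are subtracted only where defined (`n >= 2`); with
#' correction on, a site whose correction is undefined yields `NA` and is
#' skipped (and counted) by [f_statistic()].
#'
#' @param dA,nA,dB,nB,dC,nC,dD,nD Integer vectors of derived / total copies.
#' @param bias_correction Apply the h-term correction (f2/f3).
#' @return Numeric vector of per-site values.
#' @export
per_site_f2 <- function(dA, nA, dB, nB, bias_correction = TRUE) {
  pA <- dA / nA
  pB <- dB / nB
  v <- (pA - pB)^2
  if (bias_correction) v <- v - h_term(dA, nA) / nA - h_term(dB, nB) / nB
  v
}

#' @rdname per_site_f2
#' @export
per_site_f3_outgroup <- function(dA, nA, dB, nB, dC, nC, bias_correction = TRUE) {
  pA <- dA / nA
  pB <- dB / nB
  pC <- dC / nC
  v <- (pC - pA) * (pC - pB)
  if (bias_correction) v <- v - h_term(dC, nC) / nC
  v
}

#' @rdname per_site_f2
#' @export
per_site_f4 <- function(dA, nA, dB, nB, dC, nC, dD, nD) {
  (dA / nA - dB / nB) * (dC / nC - dD / nD)
}

#' Weighted delete-one block jackknife
#'
#' Pools per-site values into a global mean and derives its standard error by
#' the weighted delete-one-block jackknife with block weights equal to site
#' counts (Busing-style weighting). With equal block sizes this reduces
#' exactly to the textbook unweighted delete-one jackknife.
#'
#' @param values Numeric per-site values (must be finite).
#' @param blocks Block id per site (character/factor); at least 2 distinct
#'   blocks are required for a defined standard error.
#' @return List with `estimate` (global mean), `se`, `z` (`NA` with
#'   `zero_se = TRUE` when the standard error degenerates to 0), `n_sites`,
#'   `n_blocks`, and a `per_block` tibble (block id, raw within-block mean
#'   `estimate`, weight `n`, leave-one-out estimate `loo`, `pseudovalue`).
#' @export
block_jackknife <- function(values, blocks) {
  if (length(values) != length(blocks)) abort("values and blocks differ in length")
  if (any(!is.finite(values))) {
    abort(sprintf("non-finite per-site value at index %d", which(!is.finite(values))[1]))
  }
  blocks <- as.character(blocks)
  n <- length(values)
  tot <- sum(values)
  bsum <- tapply(values, blocks, sum)
  bn <- tapply(values, blocks, length)
  g <- length(bsum)
  if (g < 2L) abort("block jackknife needs at least 2 non-empty blocks")
  est <- tot / n
  loo <- (tot - bsum) / (n - bn)
  hj <- n / bn
  tau <- hj * est - (hj - 1) * loo
  theta_j <- g * est - sum((1 - bn / n) * loo)
  var_j <- sum((tau - theta_j)^2 / (hj - 1)) / g
  se <- sqrt(var_j)
  zero_se <- se <= 0 || !is.finite(se)
  list(
    estimate = est,
    se = se,
    z = if (zero_se) NA_real_ else est / se,
    zero_se = zero_se,
    n_sites = n,
    n_blocks = g,
    per_block = tibble(
      block = names(bsum),
      estimate = as.numeric(bsum / bn),
      n = as.integer(bn),
      loo = as.numeric(loo),
      pseudovalue = as.numeric(tau)
    )
  )
}

#' Compute an f-statistic with block-jackknife uncertainty
#'
#' Evaluates the configured f2 / outgroup-f3 / f4 statistic on a
#' per-population allele-count table, pooling per-site values over jackknife
#' blocks. Sites with a `NA` block id are outside the partition and ignored.
#' Sites where an involved population has no called copies, or where a
#' requested bias correction is undefined (fewer than 2 copies), are skipped
#' and counted in `n_skipped`. Mitochondrial sites are refused.
#'
#' @param table An [allele_counts_by_population()] table.
#' @param config An [fstat_config()].
#' @param partition Block ids aligned with `table` sites (see
#'   [assign_blocks()]).
#' @return An object of class `swampx_fstat` with fields `config`,
#'   `estimate`, `se`, `z`, `zero_se`, `n_sites`, `n_blocks`, `n_skipped`
#'   and `per_block`.
#' @export
f_statistic <- function(table, config, partition) {
  if (!inherits(config, "fstat_config")) abort("`config` must be an fstat_config")
  missing_pop <- setdiff(config$pops, table$populations)
  if (length(missing_pop)) {
    abort(paste0("populations absent from table: ", paste(missing_pop, collapse = ", ")))
  }
  if (length(partition) != nrow(table$sites)) {
    abort("partition must align with the site table")
  }
  in_part <- !is.na(partition)
  if (any(in_part & table$sites$chrom_class == "mito")) {
    abort("f-statistics refuse mitochondrial sites; exclude them from the partition")
  }
  d <- lapply(config$pops, function(p) table$derived[, p])
  n <- lapply(config$pops, function(p) table$total[, p])
  called <- Reduce(`&`, lapply(n, function(x) x > 0L))
  v <- switch(config$kind,
    f2 = per_site_f2(d[[1]], n[[1]], d[[2]], n[[2]], config$bias_correction),
    f3_outgroup = per_site_f3_outgroup(d[[1]], n[[1]], d[[2]], n[[2]],
                                       d[[3]], n[[3]], config$bias_correction),
    f4 = per_site_f4(d[[1]], n[[1]], d[[2]], n[[2]], d[[3]], n[[3]], d[[4]], n[[4]])
  )
  use <- in_part & called & !is.na(v)
  n_skipped <- sum(in_part & !use)
  jk <- block_jackknife(v[use], partition[use])
  structure(
    c(list(config = config), jk, list(n_skipped = as.integer(n_skipped))),
    class = "swampx_fstat"
  )
}

#' @export
print.swampx_fstat <- function(x, ...) {
  cat(sprintf("%s = %.6g  (SE %.3g, Z %s; %d sites in %d blocks)\n",
              format(x$config), x$estimate, x$se,
              if (x$zero_se) "undefined [zero SE]" else sprintf("%.3g", x$z),
              x$n_sites, x$n_blocks))
  invisible(x)
}

#' Welch's unequal-variance t-test
#'
#' Thin wrapper around [stats::t.test()] returning a one-row tibble, with an
#' explicit degenerate path: when both samples have zero variance the test is
#' flagged and `p = 1` is reported for equal means (`p = 0`, infinite `t`,
#' otherwise).
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return Tibble with `t`, `df`, `p_value`, `mean_x`, `mean_y`,
#'   `degenerate`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) abort("welch_t needs at least 2 values per sample")
  vx <- stats::var(x)
  vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    d0 <- mean(x) - mean(y)
    return(tibble(t = if (d0 == 0) 0 else sign(d0) * Inf, df = NA_real_,
                  p_value = if (d0 == 0) 1 else 0,
                  mean_x = mean(x), mean_y = mean(y), degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, mean_x = mean(x), mean_y = mean(y),
         degenerate = FALSE)
}

#' Compare two outgroup-f3 statistics
#'
#' Welch's t-test on the per-block f3 estimates of two configurations sharing
#' the same outgroup, asking whether one pair of populations shares
#' significantly more drift than the other.
#'
#' @param table An allele-count table.
#' @param config1,config2 Two `f3_outgroup` [fstat_config()]s with identical
#'   third (outgroup) population.
#' @param partition Block ids aligned with the table sites.
#' @return One-row tibble: the two configurations, their pooled estimates,
#'   `t`, `df`, `p_value`, `larger` (which configuration has the larger
#'   block-mean f3) and `degenerate`.
#' @export
compare_f3 <- function(table, config1, config2, partition) {
  if (config1$kind != "f3_outgroup" || config2$kind != "f3_outgroup") {
    abort("compare_f3 expects two f3_outgroup configurations")
  }
  if (config1$pops[3] != config2$pops[3]) {
    abort("the two configurations must share the outgroup")
  }
  r1 <- f_statistic(table, config1, partition)
  r2 <- f_statistic(table, config2, partition)
  w <- welch_t(r1$per_block$estimate, r2$per_block$estimate)
  tibble(
    config1 = format(config1), config2 = format(config2),
    estimate1 = r1$estimate, estimate2 = r2$estimate,
    t = w$t, df = w$df, p_value = w$p_value,
    larger = if (w$mean_x == w$mean_y) NA_character_
             else if (w$mean_x > w$mean_y) format(config1) else format(config2),
    degenerate = w$degenerate
  )
}

#' Contrast an f4 statistic between autosomes and the X chromosome
#'
#' The sex-bias test: computes the same f4 configuration on autosomal and
#' X-chromosomal blocks and compares the two sets of raw per-block estimates
#' with Welch's t-test. Under sustained male-biased introgression the X
#' retains more of the recipient's original ancestry, so the f4 statistic is
#' expected to be more strongly negative on the X than on the autosomes.
#' Pass an X partition built after masking PARs and the PAR1-proximal window
#' (see [preset_mask()]).
#'
#' @param table An allele-count table spanning both chromosome classes.
#' @param config An `f4` [fstat_config()].
#' @param partition_a Block ids covering autosomal sites (`NA` elsewhere).
#' @param partition_x Block ids covering (masked) X sites (`NA` elsewhere).
#' @return An object of class `swampx_contrast`: the two `swampx_fstat`
#'   results, `t`, `df`, `p_value`, and `direction` (`"x_more_negative"`,
#'   `"x_less_negative"`, or `"none"` when the block means are equal).
#' @export
contrast_autosome_x <- function(table, config, partition_a, partition_x) {
  if (config$kind != "f4") abort("contrast_autosome_x expects an f4 configuration")
  res_a <- f_statistic(table, config, partition_a)
  res_x <- f_statistic(table, config, partition_x)
  w <- welch_t(res_x$per_block$estimate, res_a$per_block$estimate)
  diff <- w$mean_x - w$mean_y
  structure(list(
    config = config, autosome = res_a, x = res_x,
    t = w$t, df = w$df, p_value = w$p_value,
    diff = diff,
    direction = if (diff == 0) "none" else if (diff < 0) "x_more_negative" else "x_less_negative",
    degenerate = w$degenerate
  ), class = "swampx_contrast")
}

#' @export
print.swampx_contrast <- function(x, ...) {
  cat(sprintf("%s  autosome %.6g  X %.6g\n", format(x$config),
              x$autosome$estimate, x$x$estimate))
  cat(sprintf("  Welch t = %.3f, df = %.1f, p = %.4g, direction = %s\n",
              x$t, x$df, x$p_value, x$direction))
  invisible(x)
}

#' Enumerate f4 statistics over all population triples
#'
#' With the outgroup fixed in the A slot, every unordered triple {B, C, D} of
#' remaining populations admits three tree hypotheses. For each triple the
#' orientation with the smallest |Z| (the best-fitting topology, ties broken
#' lexicographically) is reported and its residual deviation from treeness is
#' tested, with Bonferroni correction across the enumeration.
#'
#' @param table An allele-count table.
#' @param outgroup Outgroup population label (slot A of every test).
#' @param partition Block ids aligned with the table sites.
#' @param alpha Significance level applied to the corrected p-value
#'   (default 1e-4).
#' @param correction Multiple-testing correction; only `"bonferroni"`.
#' @return Tibble with one row per triple: `pop_b`, `pop_c`, `pop_d` (chosen
#'   orientation), `estimate`, `se`, `z`, `n_sites`, `n_blocks`, `p_value`,
#'   `p_adj`, `significant`.
#' @export
enumerate_f4 <- function(table, outgroup, partition, alpha = 1e-4,
                         correction = "bonferroni") {
  correction <- match.arg(correction, "bonferroni")
  others <- sort(setdiff(table$populations, outgroup))
  if (!outgroup %in% table$populations) abort("outgroup not in table")
  if (length(others) < 3L) abort("enumerate_f4 needs at least 3 non-outgroup populations")
  triples <- utils::combn(others, 3L, simplify = FALSE)
  rows <- purrr::map(triples, function(tr) {
    orients <- list(tr, tr[c(2L, 1L, 3L)], tr[c(3L, 1L, 2L)])
    fits <- purrr::map(orients, function(o) {
      f_statistic(table, fstat_config("f4", c(outgroup, o)), partition)
    })
    zs <- abs(purrr::map_dbl(fits, function(f) if (f$zero_se) 0 else f$z))
    best <- fits[[which.min(zs)]]  # which.min is first-minimum: lexicographic tie-break
    tibble(
      pop_b = best$config$pops[2], pop_c = best$config$pops[3],
      pop_d = best$config$pops[4],
      estimate = best$estimate, se = best$se,
      z = if (best$zero_se) NA_real_ else best$z,
      n_sites = best$n_sites, n_blocks = best$n_blocks
    )
  })
  out <- dplyr::bind_rows(rows)
  out$p_value <- 2 * stats::pnorm(-abs(out$z))
  out$p_adj <- pmin(1, out$p_value * nrow(out))
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  out
}

#' Scan an f4 statistic along a chromosome
#'
#' Per-site (or per-window mean) f4 values in positional order, for locating
#' regions of anomalous differentiation such as the PAR1-proximal window of
#' the X.
#'
#' @param table An allele-count table.
#' @param config An `f4` [fstat_config()].
#' @param class Chromosome class (`"autosome"`, `"X"`) or a chromosome name
#'   present in the table.
#' @param window `NULL` for per-site values, or a window width in bp for
#'   within-window means.
#' @return Tibble `chrom`, `pos` (`window_start`/`window_end` and `n_sites`
#'   in windowed mode), `value`.
#' @export
f4_scan <- function(table, config, class = "X", window = NULL) {
  if (config$kind != "f4") abort("f4_scan expects an f4 configuration")
  sel <- if (class %in% CHROM_CLASSES) table$sites$chrom_class == class
         else table$sites$chrom == class
  if (!any(sel)) abort(sprintf("no sites in class '%s'", class))
  tab <- ac_subset(table, sel)
  ord <- order(tab$sites$chrom, tab$sites$pos)
  tab <- ac_subset(tab, ord)
  p <- config$pops
  v <- per_site_f4(tab$derived[, p[1]], tab$total[, p[1]],
                   tab$derived[, p[2]], tab$total[, p[2]],
                   tab$derived[, p[3]], tab$total[, p[3]],
                   tab$derived[, p[4]], tab$total[, p[4]])
  out <- tibble(chrom = tab$sites$chrom, pos = tab$sites$pos, value = v)
  out <- out[!is.na(out$value), ]
  if (is.null(window)) return(out)
  out |>
    dplyr::mutate(win = floor((.data$pos - 1) / window)) |>
    dplyr::group_by(.data$chrom, .data$win) |>
    dplyr::summarise(
      window_start = .data$win[1] * window,
      window_end = (.data$win[1] + 1) * window,
      value = mean(.data$value), n_sites = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::select(!"win")
}

#' Enumerate within-population individual pairs
#'
#' Pairs of distinct samples drawn from the same population — the
#' configurations used to gauge the baseline (treeness-null) deviation of the
#' f4 test, by placing the two individuals of one population in the C and D
#' slots.
#'
#' @param sheet A sample sheet tibble.
#' @return Tibble `population`, `sample1`, `sample2`, one row per unordered
#'   pair.
#' @export
within_population_pairs <- function(sheet) {
  sheet <- as_tibble(sheet)
  pops <- split(sheet$sample_id, sheet$population)
  rows <- purrr::imap(pops, function(ids, pop) {
    if (length(ids) < 2L) return(NULL)
    prs <- utils::combn(sort(ids), 2L)
    tibble(population = pop, sample1 = prs[1, ], sample2 = prs[2, ])
  })
  dplyr::bind_rows(rows)
}
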