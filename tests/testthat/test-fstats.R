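test_that("per-site f2 matches hand arithmetic and fixed-site identities", {
  # both populations fixed at the same allele -> 0 (with or without correction)
  expect_equal(per_site_f2(2L, 2L, 2L, 2L), 0)
  expect_equal(per_site_f2(0L, 2L, 0L, 2L), 0)
  # counts (1,2) vs (0,2): (0.5)^2 - [0.5*0.5*2/1]/2 - 0 = 0
  expect_equal(per_site_f2(1L, 2L, 0L, 2L), 0)
  expect_equal(per_site_f2(1L, 2L, 0L, 2L, bias_correction = FALSE), 0.25)
  # undefined correction (n < 2) yields NA
  expect_true(is.na(per_site_f2(1L, 1L, 0L, 2L)))
})

test_that("outgroup f3 reduces to squared difference when A = B", {
  dA <- c(3L, 1L, 0L); nA <- c(4L, 4L, 4L)
  dC <- c(1L, 2L, 4L); nC <- c(4L, 4L, 4L)
  v <- per_site_f3_outgroup(dA, nA, dA, nA, dC, nC, bias_correction = FALSE)
  expect_equal(v, (dC / nC - dA / nA)^2)
  expect_true(all(v >= 0))
  # pC = pA contributes 0 without correction
  expect_equal(per_site_f3_outgroup(2L, 4L, 1L, 4L, 2L, 4L,
                                    bias_correction = FALSE)[1],
               0)
})

test_that("per-site f4 equals the frequency product", {
  expect_equal(per_site_f4(2L, 2L, 0L, 2L, 2L, 2L, 0L, 2L), 1)
  expect_equal(per_site_f4(1L, 2L, 1L, 2L, 2L, 2L, 0L, 2L), 0)
})

test_that("f4 antisymmetry and exchange identities hold exactly", {
  rc <- rand_counts(1)
  part <- rc$blocks
  f <- function(pops) f_statistic(rc$table, fstat_config("f4", pops), part)
  base <- f(c("O", "B", "C", "D"))
  swap_cd <- f(c("O", "B", "D", "C"))
  swap_ab <- f(c("B", "O", "C", "D"))
  exch <- f(c("C", "D", "O", "B"))
  expect_equal(swap_cd$estimate, -base$estimate)
  expect_equal(swap_cd$z, -base$z)
  expect_equal(swap_ab$estimate, -base$estimate)
  expect_equal(exch$estimate, base$estimate)
  expect_equal(exch$se, base$se)
})

test_that("block jackknife matches the brute-force delete-one oracle", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(50:200, 1)
    vals <- stats::rnorm(n)
    blocks <- paste0("b", sample.int(sample(3:12, 1), n, replace = TRUE))
    jk <- block_jackknife(vals, blocks)
    or <- jackknife_oracle(vals, blocks)
    expect_equal(jk$estimate, or$estimate, tolerance = 1e-12)
    expect_equal(jk$se, or$se, tolerance = 1e-12)
    expect_equal(sort(jk$per_block$pseudovalue), sort(or$pseudovalues),
                 tolerance = 1e-12)
  }
})

test_that("equal block sizes reduce to the textbook unweighted jackknife", {
  set.seed(12)
  vals <- stats::rnorm(120)
  blocks <- rep(paste0("b", 1:6), each = 20)
  jk <- block_jackknife(vals, blocks)
  g <- 6
  loo <- vapply(unique(blocks), function(b) mean(vals[blocks != b]), numeric(1))
  se_txt <- sqrt((g - 1) / g * sum((loo - mean(loo))^2))
  expect_equal(jk$se, se_txt, tolerance = 1e-12)
})

test_that("degenerate jackknife inputs are flagged or refused", {
  jk <- block_jackknife(rep(2.5, 40), rep(c("a", "b"), 20))
  expect_equal(jk$estimate, 2.5)
  expect_equal(jk$se, 0)
  expect_true(jk$zero_se)
  expect_true(is.na(jk$z))
  expect_error(block_jackknife(rnorm(10), rep("a", 10)), "at least 2")
  expect_error(block_jackknife(c(1, Inf), c("a", "b")), "non-finite")
})

test_that("f_statistic validates configurations and refuses mito sites", {
  rc <- rand_counts(2)
  expect_error(fstat_config("f4", c("O", "B", "B", "D")), "distinct")
  expect_error(f_statistic(rc$table, fstat_config("f2", c("O", "ZZ")), rc$blocks),
               "absent")
  tab <- rc$table
  tab$sites$chrom_class[1] <- "mito"
  expect_error(f_statistic(tab, fstat_config("f2", c("O", "B")), rc$blocks),
               "mito")
})

test_that("welch_t agrees with the textbook formula and handles degeneracy", {
  x <- c(0.1, 0.2, 0.15, 0.05)
  y <- c(0.3, 0.4, 0.35)
  w <- welch_t(x, y)
  sx <- var(x) / length(x); sy <- var(y) / length(y)
  t_ref <- (mean(x) - mean(y)) / sqrt(sx + sy)
  df_ref <- (sx + sy)^2 / (sx^2 / (length(x) - 1) + sy^2 / (length(y) - 1))
  p_ref <- 2 * pt(-abs(t_ref), df_ref)
  expect_equal(w$t, t_ref, tolerance = 1e-10)
  expect_equal(w$df, df_ref, tolerance = 1e-10)
  expect_equal(w$p_value, p_ref, tolerance = 1e-10)
  # identical samples: t = 0, p = 1; swapping inputs negates t
  id <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(id$t, 0)
  expect_equal(id$p_value, 1)
  w2 <- welch_t(y, x)
  expect_equal(w2$t, -w$t)
  expect_equal(w2$p_value, w$p_value)
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("compare_f3 flags degenerate comparisons and identical configs", {
  rc <- rand_counts(3)
  c1 <- fstat_config("f3_outgroup", c("B", "C", "O"))
  same <- compare_f3(rc$table, c1, c1, rc$blocks)
  expect_equal(same$p_value, 1)
  expect_equal(same$t, 0)
  # zero-variance blocks with equal means are flagged as degenerate
  expect_true(welch_t(rep(0.2, 5), rep(0.2, 4))$degenerate)
  c2 <- fstat_config("f3_outgroup", c("B", "D", "O"))
  expect_s3_class(compare_f3(rc$table, c1, c2, rc$blocks), "tbl_df")
  c3 <- fstat_config("f3_outgroup", c("B", "D", "C"))
  expect_error(compare_f3(rc$table, c1, c3, rc$blocks), "outgroup")
})

test_that("identical allele counts on both classes give a null contrast", {
  rc <- rand_counts(4, n_sites = 200)
  tab <- rc$table
  # duplicate the sites as an X copy with identical counts
  tab2 <- tab
  tab2$sites <- dplyr::bind_rows(
    tab$sites,
    dplyr::mutate(tab$sites, chrom = "chrX", chrom_class = "X"))
  tab2$derived <- rbind(tab$derived, tab$derived)
  tab2$total <- rbind(tab$total, tab$total)
  part_a <- assign_blocks(tab2$sites, 5e4, classes = "autosome")
  part_x <- assign_blocks(tab2$sites, 5e4, classes = "X")
  ctr <- contrast_autosome_x(tab2, fstat_config("f4", c("O", "B", "C", "D")),
                             part_a, part_x)
  expect_equal(ctr$p_value, 1)
  expect_equal(ctr$direction, "none")
  expect_equal(ctr$autosome$estimate, ctr$x$estimate)
})

test_that("enumerate_f4 counts triples and reports the best-fitting topology", {
  rc <- rand_counts(5, pops = c("O", "P1", "P2", "P3", "P4"))
  tb <- enumerate_f4(rc$table, "O", rc$blocks)
  expect_equal(nrow(tb), choose(4, 3))
  # reported |z| is minimal among the three orientations of each triple
  for (k in seq_len(nrow(tb))) {
    tr <- sort(c(tb$pop_b[k], tb$pop_c[k], tb$pop_d[k]))
    zs <- sapply(list(tr, tr[c(2, 1, 3)], tr[c(3, 1, 2)]), function(o) {
      abs(f_statistic(rc$table, fstat_config("f4", c("O", o)), rc$blocks)$z)
    })
    expect_equal(abs(tb$z[k]), min(zs), tolerance = 1e-12)
  }
  expect_error(enumerate_f4(rc$table, "ZZ", rc$blocks), "not in table")
})

test_that("f4 scan is flat for constant frequencies and consistent when pooled", {
  n <- 120
  sites <- tibble::tibble(chrom = "chrX", pos = seq_len(n) * 1000L, ref = "A",
                          alt = "T", chrom_class = "X")
  pops <- c("O", "B", "C", "D")
  derived <- matrix(rep(c(8L, 6L, 4L, 2L), each = n), n, 4,
                    dimnames = list(NULL, pops))
  tab <- structure(list(sites = sites, populations = pops, derived = derived,
                        total = matrix(10L, n, 4, dimnames = list(NULL, pops))),
                   class = "allele_counts")
  sc <- f4_scan(tab, fstat_config("f4", pops), class = "X")
  expect_equal(length(unique(sc$value)), 1L)
  # whole-chromosome window equals the pooled estimate
  rc <- rand_counts(6)
  tab2 <- rc$table
  tab2$sites$chrom_class <- "X"
  tab2$sites$chrom <- "chrX"
  win <- f4_scan(tab2, fstat_config("f4", c("O", "B", "C", "D")), class = "X",
                 window = 1e9)
  pooled <- f_statistic(tab2, fstat_config("f4", c("O", "B", "C", "D")),
                        rc$blocks)
  expect_equal(win$value, pooled$estimate)
  expect_error(f4_scan(rc$table, fstat_config("f4", c("O", "B", "C", "D")),
                       class = "mito"), "no sites")
})

test_that("within-population pairs enumerate multi-individual groups", {
  sheet <- tibble::tibble(
    sample_id = c("a1", "a2", "a3", "b1", "b2", "c1"),
    population = c("A", "A", "A", "B", "B", "C"),
    sex = "unknown")
  prs <- within_population_pairs(sheet)
  expect_equal(nrow(prs), 4L)  # C(3,2) + C(2,2)
  expect_true(all(prs$sample1 < prs$sample2))
})

test_that("tidy and glance methods return the documented shapes", {
  rc <- rand_counts(7)
  r <- f_statistic(rc$table, fstat_config("f4", c("O", "B", "C", "D")), rc$blocks)
  expect_equal(nrow(tidy(r)), r$n_blocks)
  expect_equal(nrow(glance(r)), 1L)
  expect_equal(glance(r)$estimate, r$estimate)
})
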