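test_that("geno_matrix enforces its invariants", {
  gm <- toy_gm()
  expect_s3_class(gm, "geno_matrix")
  # ploidy semantics: autosome 2; X male 1 / female 2; mito 1
  x_rows <- gm$sites$chrom_class == "X"
  expect_true(all(gm$ploidy[!x_rows & gm$sites$chrom_class != "mito", ] == 2L))
  expect_true(all(gm$ploidy[x_rows, "P1_M"] == 1L))
  expect_true(all(gm$ploidy[x_rows, "P1_F"] == 2L))
  expect_true(all(gm$ploidy[gm$sites$chrom_class == "mito", ] == 1L))

  bad_sites <- gm$sites
  bad_sites$pos[2] <- bad_sites$pos[1]
  bad_sites$chrom[2] <- bad_sites$chrom[1]
  expect_error(geno_matrix(bad_sites, gm$samples, gm$dosage), "duplicated")
  d <- gm$dosage
  d[7, 2] <- 2L  # dosage 2 at male X (ploidy 1)
  expect_error(geno_matrix(gm$sites, gm$samples, d), "ploidy")
  s <- gm$samples
  s$sex[1] <- "unknown"
  expect_error(geno_matrix(gm$sites, s, gm$dosage), "sex must be known")
  # unknown sex is fine for a purely autosomal matrix
  auto <- gm$sites$chrom_class == "autosome"
  expect_silent(geno_matrix(gm$sites[auto, ], s, gm$dosage[auto, ]))
})

test_that("region masks exclude/restrict with BED semantics", {
  gm <- toy_gm()
  # vacuous mask leaves the matrix untouched
  m0 <- region_mask("chr9", 0, 100)
  expect_identical(apply_region_mask(gm, m0, "exclude")$dosage, gm$dosage)
  # PAR1-style mask on chrX:0-133703 removes pos 100 but keeps pos 200000
  par1 <- preset_mask("par1")
  kept <- apply_region_mask(gm, par1, "exclude")
  expect_false(any(kept$sites$chrom == "chrX" & kept$sites$pos == 100))
  expect_true(any(kept$sites$chrom == "chrX" & kept$sites$pos == 200000))
  # boundary: 1-based position 133703 is the last base inside [0, 133703)
  sx <- tibble::tibble(chrom = "chrX", pos = c(133703L, 133704L), ref = "A",
                       alt = "C", chrom_class = "X")
  gmx <- geno_matrix(sx, gm$samples, matrix(0L, 2, 3))
  expect_identical(apply_region_mask(gmx, par1, "exclude")$sites$pos, 133704L)
  expect_error(apply_region_mask(gm, tibble::tibble(chrom = "chr1", start = 5,
                                                    end = 5, label = "x")),
               "start >= end")
  expect_error(region_mask("chr1", 10, 4), "start >= end")
})

test_that("exclude and restrict partition the sites; membership matches a linear scan", {
  set.seed(42)
  for (rep in 1:5) {
    gm <- rand_gm(rep, n_sites = 80)
    ivs <- tibble::tibble(
      chrom = sample(c("chr1", "chr2"), 6, replace = TRUE),
      start = sample.int(2e7, 6))
    ivs$end <- ivs$start + sample.int(5e6, 6)
    mask <- region_mask(ivs$chrom, ivs$start, ivs$end)
    ex <- apply_region_mask(gm, mask, "exclude")
    re <- apply_region_mask(gm, mask, "restrict")
    expect_equal(n_sites(ex) + n_sites(re), n_sites(gm))
    expect_equal(dplyr::bind_rows(ex$sites, re$sites) |>
                   dplyr::arrange(chrom, pos),
                 gm$sites |> dplyr::arrange(chrom, pos))
    # brute-force per-site membership oracle
    inside <- vapply(seq_len(n_sites(gm)), function(i) {
      any(gm$sites$chrom[i] == ivs$chrom &
            gm$sites$pos[i] - 1 >= ivs$start & gm$sites$pos[i] - 1 < ivs$end)
    }, logical(1))
    expect_identical(re$sites$pos, gm$sites$pos[inside])
  }
})

test_that("complete-case filtering matches a per-site any-missing oracle", {
  gm <- toy_gm()
  expect_identical(filter_complete_cases(gm)$dosage, gm$dosage)
  d <- gm$dosage
  d[3, 2] <- NA_integer_
  gm2 <- geno_matrix(gm$sites, gm$samples, d, gm$ploidy)
  expect_equal(n_sites(filter_complete_cases(gm2)), n_sites(gm) - 1L)
  for (rep in 1:4) {
    gmr <- rand_gm(100 + rep, miss_rate = 0.1)
    cc <- filter_complete_cases(gmr)
    keep <- !apply(gmr$dosage, 1, anyNA)
    expect_identical(cc$sites, gmr$sites[keep, ])
  }
  all_miss <- geno_matrix(gm$sites, gm$samples,
                          matrix(NA_integer_, n_sites(gm), 3))
  expect_warning(filter_complete_cases(all_miss), "no complete-case")
})

test_that("allele counts sum dosages and ploidies per population", {
  gm <- toy_gm()
  ac <- allele_counts_by_population(gm)
  # one diploid sample with dosage 1 -> (1, 2)
  expect_equal(unname(ac$derived[2, "P2"]), 1L)
  expect_equal(unname(ac$total[2, "P2"]), 2L)
  # X site, female dosage 2 + hemizygous male dosage 1 -> (3, 3)
  expect_equal(unname(ac$derived[7, "P1"]), 3L)
  expect_equal(unname(ac$total[7, "P1"]), 3L)
  expect_error(allele_counts_by_population(gm, populations = c("P1", "ZZ")),
               "no samples")
  # randomized matrices against a naive double loop, plus copy conservation
  for (rep in 1:4) {
    gmr <- rand_gm(200 + rep, miss_rate = 0.15)
    acr <- allele_counts_by_population(gmr)
    for (p in acr$populations) {
      cols <- which(gmr$samples$population == p)
      for (i in seq_len(min(20, n_sites(gmr)))) {
        der <- 0L; tot <- 0L
        for (j in cols) {
          if (!is.na(gmr$dosage[i, j])) {
            der <- der + gmr$dosage[i, j]
            tot <- tot + gmr$ploidy[i, j]
          }
        }
        expect_identical(unname(acr$derived[i, p]), unname(der))
        expect_identical(unname(acr$total[i, p]), unname(tot))
      }
    }
    called_ploidy <- gmr$ploidy
    called_ploidy[is.na(gmr$dosage)] <- 0L
    expect_equal(unname(rowSums(acr$total)), unname(rowSums(called_ploidy)))
  }
})

test_that("per-sample heterozygosity counts dosage-1 diploid calls", {
  sites <- tibble::tibble(chrom = "chr1", pos = 1:4 * 100L, ref = "A", alt = "T",
                          chrom_class = "autosome")
  samples <- tibble::tibble(sample_id = c("s1", "s2"), population = "P",
                            sex = "female")
  dos <- cbind(c(0L, 1L, 1L, 2L), c(0L, 0L, 0L, 0L))
  het <- per_sample_heterozygosity(geno_matrix(sites, samples, dos))
  expect_equal(het$heterozygosity, c(0.5, 0))
  # no called sites -> NA
  dos2 <- cbind(c(0L, 1L, 1L, 2L), rep(NA_integer_, 4))
  het2 <- per_sample_heterozygosity(geno_matrix(sites, samples, dos2))
  expect_true(is.na(het2$heterozygosity[2]))
})

test_that("simulated panmictic heterozygosity matches the binomial expectation", {
  model <- demographic_model(
    tibble::tibble(name = "P", N = 1000),
    NULL, end_time = 20,
    tibble::tibble(population = "P", n_females = 10, n_males = 10))
  sim <- simulate_genotypes(model, auto_plan(4000), seed = 99)
  expected <- mean(2 * sim$truth$freq$P$autosome * (1 - sim$truth$freq$P$autosome))
  het <- per_sample_heterozygosity(sim$genotypes)
  expect_equal(mean(het$heterozygosity), expected, tolerance = 0.02)
})

test_that("block assignment uses half-open 5-Mb windows on 0-based positions", {
  sites <- tibble::tibble(chrom = "chr1",
                          pos = c(1L, 4999999L, 5000000L, 5000001L),
                          ref = "A", alt = "T", chrom_class = "autosome")
  b <- assign_blocks(sites, 5e6)
  expect_equal(b[1], b[2])
  expect_equal(b[2], b[3])  # 1-based 5,000,000 is 0-based 4,999,999: block 0
  expect_false(b[3] == b[4])
  # floor((pos-1)/B) oracle on random positions, and order invariance
  set.seed(7)
  pos <- sample.int(1e8, 200)
  s2 <- tibble::tibble(chrom = sample(c("c1", "c2"), 200, TRUE), pos = pos,
                       ref = "A", alt = "T", chrom_class = "autosome")
  expect_identical(assign_blocks(s2, 7e5),
                   paste0(s2$chrom, ":", floor((s2$pos - 1) / 7e5)))
  perm <- sample.int(200)
  expect_identical(assign_blocks(s2, 7e5)[perm], assign_blocks(s2[perm, ], 7e5))
  # class filter
  expect_true(all(is.na(assign_blocks(toy_gm(), classes = character()))))
  expect_error(assign_blocks(s2, 0), "positive")
})
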