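# Shared fixture builders. Everything is generated in code at test time.

# small deterministic genotype matrix: 6 autosomal + 3 X + 1 mito site,
# 2 populations (P1: 1 female + 1 male, P2: 1 female)
toy_gm <- function() {
  sites <- tibble::tibble(
    chrom = c(rep("chr1", 4), rep("chr2", 2), rep("chrX", 3), "chrM"),
    pos = c(10L, 200L, 5000010L, 9000000L, 50L, 70L, 100L, 200000L, 11000000L, 5L),
    ref = "A", alt = "G",
    chrom_class = c(rep("autosome", 6), rep("X", 3), "mito")
  )
  samples <- tibble::tibble(
    sample_id = c("P1_F", "P1_M", "P2_F"),
    population = c("P1", "P1", "P2"),
    sex = c("female", "male", "female")
  )
  dosage <- matrix(c(
    0L, 1L, 2L,
    1L, 0L, 1L,
    2L, 2L, 0L,
    1L, 1L, 1L,
    0L, 0L, 2L,
    2L, 1L, 1L,
    2L, 1L, 0L,   # X: male hemizygous
    1L, 0L, 2L,
    0L, 1L, 1L,
    1L, 0L, 1L    # mito
  ), nrow = 10, byrow = TRUE)
  swampx::geno_matrix(sites, samples, dosage)
}

# random genotype matrix over k diploid populations (autosomes only),
# optionally with missing entries
rand_gm <- function(seed, n_sites = 60, pops = c("A", "B", "C"),
                    n_per_pop = 2, miss_rate = 0) {
  set.seed(seed)
  samples <- tibble::tibble(
    sample_id = paste0(rep(pops, each = n_per_pop), "_", seq_len(n_per_pop)),
    population = rep(pops, each = n_per_pop),
    sex = "female"
  )
  sites <- tibble::tibble(
    chrom = sample(c("chr1", "chr2"), n_sites, replace = TRUE),
    pos = integer(n_sites), ref = "A", alt = "T", chrom_class = "autosome"
  )
  sites <- sites[order(sites$chrom), ]
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    sites$pos[idx] <- sort(sample.int(2e7, length(idx)))
  }
  p <- stats::runif(n_sites, 0.1, 0.9)
  dosage <- matrix(stats::rbinom(n_sites * nrow(samples), 2, p),
                   n_sites, nrow(samples))
  if (miss_rate > 0) {
    dosage[stats::runif(length(dosage)) < miss_rate] <- NA_integer_
  }
  swampx::geno_matrix(sites, samples, dosage)
}

# random per-population allele-count table with simple block structure
rand_counts <- function(seed, n_sites = 300, pops = c("O", "B", "C", "D"),
                        copies = 10, n_blocks = 6) {
  set.seed(seed)
  derived <- sapply(pops, function(p) stats::rbinom(n_sites, copies,
                                                    stats::runif(n_sites, 0.1, 0.9)))
  sites <- tibble::tibble(
    chrom = "chr1",
    pos = seq_len(n_sites) * 1000L,
    ref = "A", alt = "T", chrom_class = "autosome"
  )
  tab <- structure(list(sites = sites, populations = pops,
                        derived = derived,
                        total = matrix(as.integer(copies), n_sites, length(pops),
                                       dimnames = list(NULL, pops))),
                   class = "allele_counts")
  blocks <- paste0("b", rep_len(seq_len(n_blocks), n_sites))
  list(table = tab, blocks = blocks)
}

# independent brute-force weighted delete-one jackknife (explicit loop)
jackknife_oracle <- function(values, blocks) {
  ids <- unique(blocks)
  g <- length(ids)
  n <- length(values)
  est <- mean(values)
  loo <- vapply(ids, function(b) mean(values[blocks != b]), numeric(1))
  m <- vapply(ids, function(b) sum(blocks == b), numeric(1))
  h <- n / m
  tau <- h * est - (h - 1) * loo
  theta_j <- g * est - sum((1 - m / n) * loo)
  se <- sqrt(sum((tau - theta_j)^2 / (h - 1)) / g)
  list(estimate = est, se = se, pseudovalues = unname(tau))
}

# no-admixture 5-population tree model: (O,(B,(C,D))) shape with outgroup O
null_tree_model <- function(N = 500, n_females = 3, n_males = 2) {
  swampx::demographic_model(
    tibble::tibble(name = c("ROOT", "O", "R1", "B", "CD", "C", "D"), N = N),
    dplyr::bind_rows(
      swampx::ev_split(0, "ROOT", c("O", "R1")),
      swampx::ev_split(20, "R1", c("B", "CD")),
      swampx::ev_split(60, "CD", c("C", "D"))
    ),
    end_time = 100,
    tibble::tibble(population = c("O", "B", "C", "D"),
                   n_females = n_females, n_males = n_males)
  )
}

# same tree plus continuous sex-unbiased migration from B into C or D
gene_flow_model <- function(recipient = c("C", "D"), m = 0.05,
                            N = 500, n_females = 3, n_males = 2) {
  recipient <- match.arg(recipient)
  swampx::demographic_model(
    tibble::tibble(name = c("ROOT", "O", "R1", "B", "CD", "C", "D"), N = N),
    dplyr::bind_rows(
      swampx::ev_split(0, "ROOT", c("O", "R1")),
      swampx::ev_split(20, "R1", c("B", "CD")),
      swampx::ev_split(60, "CD", c("C", "D")),
      swampx::ev_migration(70, 100, "B", recipient, m_f = m, m_m = m)
    ),
    end_time = 100,
    tibble::tibble(population = c("O", "B", "C", "D"),
                   n_females = n_females, n_males = n_males)
  )
}

# compact autosome-only locus plan for replicated simulations
auto_plan <- function(n = 10000) {
  swampx::locus_plan(n_autosomal = n, n_x = 0, n_mito = 0)
}

# Gaussian Monte Carlo oracle for graph covariance propagation: frequencies
# evolve by independent increments of variance = edge length
mc_cov_oracle <- function(graph, n_rep = 20000, seed = 1) {
  set.seed(seed)
  Z <- matrix(0, n_rep, length(graph$nodes), dimnames = list(NULL, graph$nodes))
  for (nd in graph$nodes) {
    if (nd == graph$root) next
    ai <- match(nd, graph$admix$node)
    if (!is.na(ai)) {
      a <- graph$admix$alpha[ai]
      Z[, nd] <- a * Z[, graph$admix$parent1[ai]] +
        (1 - a) * Z[, graph$admix$parent2[ai]]
    } else {
      ei <- which(graph$edges$child == nd)
      Z[, nd] <- Z[, graph$edges$parent[ei]] +
        stats::rnorm(n_rep, 0, sqrt(graph$edges$length[ei]))
    }
  }
  stats::cov(Z[, graph$leaves, drop = FALSE])
}

# exact f-statistic basis computed from a fully parameterised graph
analytic_basis <- function(graph, outgroup, se = 1e-4) {
  V <- swampx::expected_covariance(graph)
  pops <- sort(graph$leaves)
  prs <- utils::combn(pops, 2, simplify = FALSE)
  f2 <- purrr::map(prs, function(p) tibble::tibble(
    kind = "f2", pop1 = p[1], pop2 = p[2], pop3 = NA_character_,
    estimate = V[p[1], p[1]] + V[p[2], p[2]] - 2 * V[p[1], p[2]], se = se))
  inner <- setdiff(pops, outgroup)
  f3 <- purrr::map(utils::combn(inner, 2, simplify = FALSE), function(p)
    tibble::tibble(kind = "f3_outgroup", pop1 = p[1], pop2 = p[2], pop3 = outgroup,
                   estimate = V[outgroup, outgroup] - V[outgroup, p[1]] -
                     V[outgroup, p[2]] + V[p[1], p[2]], se = se))
  dplyr::bind_rows(c(f2, f3))
}

swamp_skeleton_tree <- function() {
  swampx::admix_graph(tibble::tibble(
    parent = c("root", "root", "R1", "R1", "D0", "D0", "BC", "BC"),
    child = c("A", "R1", "D0", "BC", "D", "Dp", "B", "C"),
    length = NA_real_))
}
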