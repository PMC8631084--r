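test_that("admix_graph validates structure", {
  expect_error(admix_graph(tibble::tibble(parent = c("a", "b"), child = c("b", "a"))),
               "cycle|root")
  expect_error(admix_graph(tibble::tibble(parent = c("r", "s"),
                                          child = c("a", "b"))),
               "exactly one root")
  expect_error(admix_graph(tibble::tibble(parent = "r", child = "a",
                                          length = -0.1)), ">= 0")
  expect_error(admix_graph(
    tibble::tibble(parent = c("r", "r"), child = c("a", "b"), length = 0.1),
    tibble::tibble(node = "m", parent1 = "a", parent2 = "b", alpha = 1.2)),
    "alpha")
  g <- admix_graph(
    tibble::tibble(parent = c("r", "r", "m"), child = c("a", "b", "c"),
                   length = 0.1),
    tibble::tibble(node = "m", parent1 = "a", parent2 = "b", alpha = 0.4))
  expect_setequal(g$leaves, c("c"))
  expect_equal(g$root, "r")
})

two_leaf_graph <- function(a, b) {
  admix_graph(tibble::tibble(parent = c("r", "r"), child = c("x", "y"),
                             length = c(a, b)))
}

test_that("expected covariance obeys path additivity and the alpha = 1 limit", {
  V <- expected_covariance(two_leaf_graph(0.07, 0.11))
  expect_equal(V["x", "x"] + V["y", "y"] - 2 * V["x", "y"], 0.18)
  # admixture with alpha = 1 collapses onto the first parent
  edges <- tibble::tibble(
    parent = c("r", "r", "p1", "p1", "r2", "ADM"),
    child = c("p1", "r2", "u", "m1", "v", "w"),
    length = c(0.02, 0.05, 0.03, 0.01, 0.04, 0.06))
  g1 <- admix_graph(edges, tibble::tibble(node = "ADM", parent1 = "m1",
                                          parent2 = "v", alpha = 1))
  # deleting the second parent: w hangs below m1 with the same drift
  edges2 <- tibble::tibble(
    parent = c("r", "r", "p1", "p1", "r2", "m1"),
    child = c("p1", "r2", "u", "m1", "v", "w"),
    length = c(0.02, 0.05, 0.03, 0.01, 0.04, 0.06))
  g2 <- admix_graph(edges2)
  common <- intersect(g1$leaves, g2$leaves)
  expect_equal(expected_covariance(g1)[common, common],
               expected_covariance(g2)[common, common])
  expect_error(expected_covariance(two_leaf_graph(NA, 1)), "unset")
})

test_that("expected covariance matches a Monte Carlo propagation oracle", {
  set.seed(90)
  for (rep in 1:3) {
    g <- admix_graph(
      tibble::tibble(
        parent = c("r", "r", "R1", "R1", "D0", "D0", "BC", "BC", "ADM"),
        child = c("A", "R1", "D0", "BC", "D", "Dpm", "B", "C0", "C"),
        length = runif(9, 0.005, 0.1)),
      tibble::tibble(node = "ADM", parent1 = "Dpm", parent2 = "C0",
                     alpha = runif(1, 0.1, 0.9)))
    V <- expected_covariance(g)
    n_rep <- 40000
    Vmc <- mc_cov_oracle(g, n_rep = n_rep, seed = rep)
    # elementwise MC standard error of a covariance is ~ sqrt(Vii Vjj / n)
    for (i in g$leaves) for (j in g$leaves) {
      se <- sqrt((V[i, i] * V[j, j] + V[i, j]^2) / n_rep) + 1e-12
      expect_lt(abs(V[i, j] - Vmc[i, j]), 3.5 * se)
    }
    expect_true(all(eigen(V, symmetric = TRUE, only.values = TRUE)$values > -1e-12))
  }
})

test_that("a fitted tree predicts exactly zero f4 for separating configurations", {
  g <- admix_graph(tibble::tibble(
    parent = c("r", "r", "s", "s", "t", "t"),
    child = c("a", "s", "b", "t", "c", "d"),
    length = c(0.02, 0.03, 0.05, 0.01, 0.04, 0.07)))
  V <- expected_covariance(g)
  # tree ((c,d),b),a: {a,b} vs {c,d} is a separating split
  expect_equal(V["a", "c"] - V["a", "d"] - V["b", "c"] + V["b", "d"], 0)
})

test_that("fit_graph recovers parameters from exact data", {
  true <- admix_graph(
    tibble::tibble(
      parent = c("root", "root", "R1", "R1", "D0", "D0", "Dpm", "BC", "BC", "ADM"),
      child = c("A", "R1", "D0", "BC", "D", "Dpm", "Dp", "B", "C0", "C"),
      length = c(0.00, 0.030, 0.020, 0.015, 0.040, 0.010, 0.020, 0.030, 0.020, 0.015)),
    tibble::tibble(node = "ADM", parent1 = "Dpm", parent2 = "C0", alpha = 0.3))
  basis <- analytic_basis(true, "A")
  fit <- fit_graph(swamping_graph_skeleton(), basis, n_starts = 8, seed = 4)
  expect_lt(fit$score, 1e-10)
  expect_equal(fit$par$value[fit$par$type == "alpha"], 0.3, tolerance = 1e-3)
  # permuting the basis rows leaves the fit equivalent: same alpha and the
  # same predicted covariance (raw edge vectors may differ along the known
  # pre-/post-admixture drift ridge of the recipient lineage)
  fit2 <- fit_graph(swamping_graph_skeleton(), basis[rev(seq_len(nrow(basis))), ],
                    n_starts = 8, seed = 4)
  expect_equal(fit2$par$value[fit2$par$type == "alpha"],
               fit$par$value[fit$par$type == "alpha"], tolerance = 1e-4)
  expect_equal(expected_covariance(fit2$graph), expected_covariance(fit$graph),
               tolerance = 1e-6)
})

test_that("alpha pinned at a bound in truth is recovered at the bound", {
  for (a_true in c(0, 1)) {
    true <- admix_graph(
      tibble::tibble(
        parent = c("root", "root", "R1", "R1", "D0", "D0", "Dpm", "BC", "BC", "ADM"),
        child = c("A", "R1", "D0", "BC", "D", "Dpm", "Dp", "B", "C0", "C"),
        length = c(0.00, 0.030, 0.020, 0.015, 0.040, 0.010, 0.020, 0.030, 0.020, 0.015)),
      tibble::tibble(node = "ADM", parent1 = "Dpm", parent2 = "C0", alpha = a_true))
    fit <- fit_graph(swamping_graph_skeleton(), analytic_basis(true, "A"),
                     n_starts = 6, seed = 5)
    expect_equal(fit$par$value[fit$par$type == "alpha"], a_true, tolerance = 0.02)
  }
})

test_that("worst_residual is near zero on perfect data and flip-invariant", {
  true <- admix_graph(
    tibble::tibble(
      parent = c("root", "root", "R1", "R1", "D0", "D0", "Dpm", "BC", "BC", "ADM"),
      child = c("A", "R1", "D0", "BC", "D", "Dpm", "Dp", "B", "C0", "C"),
      length = c(0.00, 0.030, 0.020, 0.015, 0.040, 0.010, 0.020, 0.030, 0.020, 0.015)),
    tibble::tibble(node = "ADM", parent1 = "Dpm", parent2 = "C0", alpha = 0.3))
  sim <- admixture_pulse_scenario(alpha = 0.3, seed = 71,
                                  plan = auto_plan(6000))
  tab <- allele_counts_by_population(sim$genotypes)
  part <- assign_blocks(tab, classes = "autosome")
  basis <- fstat_basis(tab, part, "A")
  fit <- fit_graph(swamping_graph_skeleton(), basis, n_starts = 8, seed = 6)
  wr <- worst_residual(fit, tab, part)
  expect_lt(abs(wr$worst$z), 4)
  # |z| identical for antisymmetric orientation pairs: recompute one flipped
  row <- wr$all[1, ]
  pops <- regmatches(row$config, gregexpr("[A-Za-z0-9]+", row$config))[[1]][-1]
  flipped <- f_statistic(tab, fstat_config("f4", pops[c(2, 1, 3, 4)]), part)
  V <- expected_covariance(fit$graph)
  pred <- swampx:::predict_fstat(V, "f4", pops[c(2, 1, 3, 4)])
  expect_equal(abs((flipped$estimate - pred) / flipped$se), abs(row$z),
               tolerance = 1e-10)
})

test_that("greedy search is inert on tree data and respects max_edges", {
  sim <- simulate_genotypes(null_tree_model(), auto_plan(6000), seed = 81)
  tab <- allele_counts_by_population(sim$genotypes)
  part <- assign_blocks(tab, classes = "autosome")
  skel <- admix_graph(tibble::tibble(
    parent = c("r", "r", "R1", "R1", "CD", "CD"),
    child = c("O", "R1", "B", "CD", "C", "D"), length = NA_real_))
  g0 <- greedy_edge_addition(skel, tab, part, "O", max_edges = 0, seed = 7)
  expect_equal(nrow(g0$graph$admix), 0L)
  expect_equal(nrow(g0$log), 1L)
  g1 <- greedy_edge_addition(skel, tab, part, "O", max_edges = 2, z_stop = 3,
                             seed = 7)
  expect_equal(nrow(g1$graph$admix), 0L)  # no admixture simulated
})

test_that("refit on matching X data reproduces the autosomal proportion", {
  # X loci generated from the same parameters as the autosomes: alpha_X ~ alpha_A
  sim <- admixture_pulse_scenario(alpha = 0.3, seed = 91)
  tab <- allele_counts_by_population(sim$genotypes)
  pa <- assign_blocks(tab, classes = "autosome")
  px <- assign_blocks(tab, classes = "X")
  fit <- fit_graph(swamping_graph_skeleton(), fstat_basis(tab, pa, "A"),
                   n_starts = 8, seed = 8)
  rf <- refit_admixture_on_x(fit, tab, px, "A", seed = 9)
  expect_lt(abs(rf$comparison$alpha_x - rf$comparison$alpha_autosome), 0.15)
  # default mode freezes drift at the autosomal estimates
  drift_x <- rf$fit_x$par$value[rf$fit_x$par$type == "drift"]
  drift_a <- fit$par$value[fit$par$type == "drift"]
  expect_equal(drift_x, drift_a, tolerance = 1e-12)
  # sensitivity mode refits drift too and still returns a proportion in [0,1]
  rf2 <- refit_admixture_on_x(fit, tab, px, "A", mode = "alpha_and_drift",
                              seed = 9)
  expect_true(rf2$comparison$alpha_x >= 0 && rf2$comparison$alpha_x <= 1)
  expect_false(isTRUE(all.equal(
    rf2$fit_x$par$value[rf2$fit_x$par$type == "drift"], drift_a)))
})

test_that("graph edge-list and DOT serialisation round-trip", {
  g <- admix_graph(
    tibble::tibble(
      parent = c("r", "r", "s", "s", "ADM"),
      child = c("o", "s", "a", "m", "b"),
      length = c(0.01, 0.02, 0.03, 0.04, 0.05)),
    tibble::tibble(node = "ADM", parent1 = "a", parent2 = "m", alpha = 0.25))
  path <- tempfile(fileext = ".tsv")
  write_graph(g, path)
  g2 <- read_graph(path)
  expect_setequal(g2$leaves, g$leaves)
  expect_equal(dplyr::arrange(g2$edges, parent, child),
               dplyr::arrange(g$edges, parent, child))
  expect_equal(g2$admix$alpha, 0.25)
  dot <- tempfile(fileext = ".dot")
  write_graph_dot(g, dot)
  expect_true(any(grepl("style=dashed", readLines(dot))))
})
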