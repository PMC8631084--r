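#' Construct an admixture graph
#'
#' A rooted directed acyclic graph in which every non-root node has either a
#' single drift-weighted parent edge (tree node) or exactly two admixture
#' parents with a mixing proportion `alpha` toward the first parent. Drift
#' lengths are on the f2 scale (variance of allele-frequency difference
#' accumulated along the edge); admixture edges carry no drift of their own.
#' Leaf node names double as population labels.
#'
#' @param edges Tibble of drift edges: `parent`, `child`, `length`
#'   (nonnegative, `NA` = free parameter to be fitted).
#' @param admix Optional tibble of admixture nodes: `node`, `parent1`,
#'   `parent2`, `alpha` (in `[0, 1]` toward `parent1`, `NA` = free).
#' @return An `admix_graph` object with derived `root`, `leaves` and
#'   topological node order.
#' @export
admix_graph <- function(edges, admix = NULL) {
  edges <- as_tibble(edges)
  if (!all(c("parent", "child") %in% names(edges))) abort("edges needs parent, child")
  if (!"length" %in% names(edges)) edges$length <- NA_real_
  admix <- if (is.null(admix)) {
    tibble(node = character(), parent1 = character(), parent2 = character(),
           alpha = numeric())
  } else as_tibble(admix)
  if (nrow(admix) && !all(c("node", "parent1", "parent2") %in% names(admix))) {
    abort("admix needs node, parent1, parent2")
  }
  if (nrow(admix) && !"alpha" %in% names(admix)) admix$alpha <- NA_real_
  nodes <- unique(c(edges$parent, edges$child, admix$node, admix$parent1, admix$parent2))
  n_parents <- stats::setNames(integer(length(nodes)), nodes)
  for (ch in edges$child) n_parents[ch] <- n_parents[ch] + 1L
  for (nd in admix$node) n_parents[nd] <- n_parents[nd] + 2L
  if (any(n_parents > 2L) || any(n_parents == 2L & !nodes %in% admix$node)) {
    abort("every node needs 1 drift parent or 2 admixture parents")
  }
  if (any(nodes %in% admix$node & nodes %in% edges$child)) {
    abort("admixture nodes cannot also have a drift parent")
  }
  roots <- nodes[n_parents == 0L]
  if (length(roots) != 1L) abort(sprintf("graph must have exactly one root, found %d", length(roots)))
  if (any(!is.na(edges$length) & edges$length < 0)) abort("drift lengths must be >= 0")
  if (any(!is.na(admix$alpha) & (admix$alpha < 0 | admix$alpha > 1))) {
    abort("alpha must lie in [0, 1]")
  }
  order <- topo_order(nodes, edges, admix)
  has_child <- nodes %in% c(edges$parent, admix$parent1, admix$parent2)
  leaves <- nodes[!has_child]
  structure(list(edges = edges, admix = admix, nodes = nodes[order],
                 root = roots, leaves = leaves),
            class = "admix_graph")
}

# Kahn topological sort; errors on cycles
topo_order <- function(nodes, edges, admix) {
  parents_of <- function(nd) {
    c(edges$parent[edges$child == nd],
      unlist(admix[admix$node == nd, c("parent1", "parent2")], use.names = FALSE))
  }
  placed <- character()
  order <- integer()
  remaining <- nodes
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(nd) all(parents_of(nd) %in% placed),
                              logical(1))]
    if (!length(ready)) abort("graph contains a cycle")
    placed <- c(placed, ready)
    order <- c(order, match(ready, nodes))
    remaining <- setdiff(remaining, ready)
  }
  order
}

#' @export
print.admix_graph <- function(x, ...) {
  cat(sprintf("<admix_graph> %d nodes, %d drift edges, %d admixture node(s); root %s\n",
              length(x$nodes), nrow(x$edges), nrow(x$admix), x$root))
  cat("  leaves:", paste(x$leaves, collapse = ", "), "\n")
  invisible(x)
}

graph_n_par <- function(graph) nrow(graph$edges) + nrow(graph$admix)

graph_get_par <- function(graph) {
  c(graph$edges$length, graph$admix$alpha)
}

graph_set_par <- function(graph, par) {
  ne <- nrow(graph$edges)
  graph$edges$length <- par[seq_len(ne)]
  if (nrow(graph$admix)) graph$admix$alpha <- par[ne + seq_len(nrow(graph$admix))]
  graph
}

graph_par_names <- function(graph) {
  c(paste0("len:", graph$edges$parent, "->", graph$edges$child),
    if (nrow(graph$admix)) paste0("alpha:", graph$admix$node))
}

# descendants of a node (including itself) under drift + admixture edges
graph_descendants <- function(graph, node) {
  out <- node
  frontier <- node
  while (length(frontier)) {
    kids <- c(graph$edges$child[graph$edges$parent %in% frontier],
              graph$admix$node[graph$admix$parent1 %in% frontier |
                               graph$admix$parent2 %in% frontier])
    kids <- setdiff(unique(kids), out)
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

#' Expected allele-frequency covariance of an admixture graph
#'
#' Propagates covariance from the root: a tree child inherits its parent's
#' covariance with every earlier node and adds its drift length to its own
#' variance; an admixture child's row/column is the `(alpha, 1 - alpha)`
#' combination of its parents', with its variance combined bilinearly. The
#' result restricted to the leaves determines every f-statistic:
#' `f2(i, j) = V_ii + V_jj - 2 V_ij`,
#' `f3(A, B; C) = V_CC - V_CA - V_CB + V_AB`,
#' `f4(A, B; C, D) = V_AC - V_AD - V_BC + V_BD`.
#'
#' @param graph An [admix_graph()] with all lengths and alphas set.
#' @return Symmetric positive semidefinite leaf-by-leaf matrix.
#' @export
expected_covariance <- function(graph) {
  par <- graph_get_par(graph)
  if (any(is.na(par))) abort("graph has unset parameters (NA length or alpha)")
  nodes <- graph$nodes
  V <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (nd in nodes) {
    if (nd == graph$root) next
    ai <- match(nd, graph$admix$node)
    if (!is.na(ai)) {
      p1 <- graph$admix$parent1[ai]
      p2 <- graph$admix$parent2[ai]
      a <- graph$admix$alpha[ai]
      V[nd, ] <- a * V[p1, ] + (1 - a) * V[p2, ]
      V[, nd] <- V[nd, ]
      V[nd, nd] <- a^2 * V[p1, p1] + 2 * a * (1 - a) * V[p1, p2] +
        (1 - a)^2 * V[p2, p2]
    } else {
      ei <- which(graph$edges$child == nd)
      p <- graph$edges$parent[ei]
      V[nd, ] <- V[p, ]
      V[, nd] <- V[p, ]
      V[nd, nd] <- V[p, p] + graph$edges$length[ei]
    }
  }
  V[graph$leaves, graph$leaves, drop = FALSE]
}

# predicted f-statistics from a leaf covariance matrix
predict_fstat <- function(V, kind, pops) {
  p <- pops
  switch(kind,
    f2 = V[p[1], p[1]] + V[p[2], p[2]] - 2 * V[p[1], p[2]],
    f3_outgroup = V[p[3], p[3]] - V[p[3], p[1]] - V[p[3], p[2]] + V[p[1], p[2]],
    f4 = V[p[1], p[3]] - V[p[1], p[4]] - V[p[2], p[3]] + V[p[2], p[4]]
  )
}

#' Observed f-statistic basis for graph fitting
#'
#' All pairwise f2 statistics among the populations plus all outgroup-f3
#' statistics (pairs among the non-outgroup populations, with the given
#' outgroup in the C slot), each with its block-jackknife standard error.
#' Diagonal 1/SE^2 weighting of this basis carries the information a
#' qpGraph-class fit uses without requiring a stable inverse of the full
#' jackknife covariance on small block counts.
#'
#' @param table An allele-count table.
#' @param partition Block ids aligned with the table sites.
#' @param outgroup Outgroup population label.
#' @param populations Populations to include (default: all in the table).
#' @return Tibble `kind`, `pop1`, `pop2`, `pop3`, `estimate`, `se`.
#' @export
fstat_basis <- function(table, partition, outgroup, populations = NULL) {
  pops <- populations %||% table$populations
  if (!outgroup %in% pops) abort("outgroup must be among the populations")
  pairs <- utils::combn(sort(pops), 2L, simplify = FALSE)
  f2_rows <- purrr::map(pairs, function(pr) {
    r <- f_statistic(table, fstat_config("f2", pr), partition)
    tibble(kind = "f2", pop1 = pr[1], pop2 = pr[2], pop3 = NA_character_,
           estimate = r$estimate, se = r$se)
  })
  inner <- sort(setdiff(pops, outgroup))
  f3_rows <- if (length(inner) >= 2L) {
    purrr::map(utils::combn(inner, 2L, simplify = FALSE), function(pr) {
      r <- f_statistic(table, fstat_config("f3_outgroup", c(pr, outgroup)), partition)
      tibble(kind = "f3_outgroup", pop1 = pr[1], pop2 = pr[2], pop3 = outgroup,
             estimate = r$estimate, se = r$se)
    })
  } else list()
  dplyr::bind_rows(c(f2_rows, f3_rows))
}

basis_objective <- function(graph, basis) {
  w <- 1 / pmax(basis$se, 1e-9)^2
  nl <- length(graph$leaves)
  li <- function(i, j) (match(j, graph$leaves) - 1L) * nl + match(i, graph$leaves)
  # each statistic is a fixed linear combination of <= 4 leaf-covariance entries
  terms <- purrr::pmap(basis[, c("kind", "pop1", "pop2", "pop3")],
                       function(kind, pop1, pop2, pop3) {
    switch(kind,
      f2 = list(idx = c(li(pop1, pop1), li(pop2, pop2), li(pop1, pop2), 1L),
                coef = c(1, 1, -2, 0)),
      f3_outgroup = list(idx = c(li(pop3, pop3), li(pop3, pop1),
                                 li(pop3, pop2), li(pop1, pop2)),
                         coef = c(1, -1, -1, 1)))
  })
  idx_m <- do.call(rbind, purrr::map(terms, "idx"))
  coef_m <- do.call(rbind, purrr::map(terms, "coef"))
  obs <- basis$estimate
  function(par) {
    g <- graph_set_par(graph, par)
    V <- expected_covariance(g)
    pred <- rowSums(coef_m * matrix(V[idx_m], nrow(idx_m)))
    sum(w * (obs - pred)^2)
  }
}

# ancestry-weight matrix: leaves x drift edges, entry = total mixture weight
# of the paths from the leaf up through that edge; V = sum_e len_e a_e a_e^T
ancestry_weights <- function(graph, alphas) {
  nodes <- graph$nodes
  ne <- nrow(graph$edges)
  A <- matrix(0, length(nodes), ne, dimnames = list(nodes, NULL))
  edge_of_child <- match(nodes, graph$edges$child)
  admix_of <- match(nodes, graph$admix$node)
  for (k in seq_along(nodes)) {
    nd <- nodes[k]
    if (nd == graph$root) next
    ai <- admix_of[k]
    if (!is.na(ai)) {
      a <- alphas[ai]
      A[nd, ] <- a * A[graph$admix$parent1[ai], ] +
        (1 - a) * A[graph$admix$parent2[ai], ]
    } else {
      ei <- edge_of_child[k]
      A[nd, ] <- A[graph$edges$parent[ei], ]
      A[nd, ei] <- A[nd, ei] + 1
    }
  }
  A[graph$leaves, , drop = FALSE]
}

# per-edge design matrix of the basis: statistic k is design %*% lengths
basis_design <- function(graph, basis, alphas) {
  A <- ancestry_weights(graph, alphas)
  X <- matrix(0, nrow(basis), ncol(A))
  for (k in seq_len(nrow(basis))) {
    if (basis$kind[k] == "f2") {
      d <- A[basis$pop1[k], ] - A[basis$pop2[k], ]
      X[k, ] <- d * d
    } else {
      X[k, ] <- (A[basis$pop3[k], ] - A[basis$pop1[k], ]) *
        (A[basis$pop3[k], ] - A[basis$pop2[k], ])
    }
  }
  X
}

# Profiled multistart fit: for fixed admixture weights the statistics are
# linear in the drift lengths, so free lengths are solved exactly by
# nonnegative least squares and only the alphas need nonlinear search.
multistart_fit <- function(graph, basis, n_starts, seed, free = NULL,
                           extra_starts = list()) {
  np <- graph_n_par(graph)
  ne <- nrow(graph$edges)
  na <- np - ne
  free <- free %||% rep(TRUE, np)
  base_par <- graph_get_par(graph)
  default_par <- ifelse(is.na(base_par), c(rep(0.01, ne), rep(0.5, na)), base_par)
  # f-statistics only see the sum of the two root-child drift lengths; pin the
  # first at 0 (folding any stored value into its sibling) to remove the ridge
  root_edges <- which(graph$edges$parent == graph$root)
  if (length(root_edges) == 2L && free[root_edges[1]]) {
    i0 <- root_edges[1]
    if (!is.na(base_par[i0]) && base_par[i0] > 0) {
      default_par[root_edges[2]] <- default_par[root_edges[2]] + base_par[i0]
    }
    default_par[i0] <- 0
    free[i0] <- FALSE
  }
  free_len <- free[seq_len(ne)]
  free_alpha <- if (na > 0) free[ne + seq_len(na)] else logical()
  sw <- 1 / pmax(basis$se, 1e-9)
  d0 <- sw * basis$estimate
  # nonnegative LS with a fallback for the exactly-collinear designs that
  # arise when an alpha sits at 0 or 1 (minimum-norm solution, clipped)
  nn_ls <- function(C, d) {
    sol <- tryCatch(pracma::lsqnonneg(C, d)$x, error = function(e) NULL)
    if (is.null(sol)) {
      co <- qr.coef(qr(C), d)
      co[is.na(co)] <- 0
      sol <- pmax(co, 0)
    }
    sol
  }
  # given alphas: solve lengths, return score (+ lengths)
  solve_lengths <- function(alphas, want_par = FALSE) {
    X <- sw * basis_design(graph, basis, alphas)
    len <- default_par[seq_len(ne)]
    rhs <- d0 - if (any(!free_len)) X[, !free_len, drop = FALSE] %*% len[!free_len]
                else 0
    if (any(free_len)) {
      sol <- nn_ls(X[, free_len, drop = FALSE], as.numeric(rhs))
      len[free_len] <- sol
      score <- sum((rhs - X[, free_len, drop = FALSE] %*% sol)^2)
    } else {
      score <- sum(rhs^2)
    }
    if (want_par) list(len = len, score = score) else score
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  alpha_starts <- list(default_par[ne + seq_len(na)])
  for (st in extra_starts) {
    if (length(st) == np) alpha_starts <- c(alpha_starts, list(st[ne + seq_len(na)]))
  }
  n_random <- max(0L, n_starts - length(alpha_starts))
  for (k in seq_len(n_random)) {
    alpha_starts <- c(alpha_starts, list(stats::runif(na, 0.05, 0.95)))
  }
  best_alphas <- default_par[ne + seq_len(na)]
  if (any(free_alpha)) {
    obj_a <- function(av) {
      al <- best_alphas
      al[free_alpha] <- av
      solve_lengths(al)
    }
    fixed_alphas <- default_par[ne + seq_len(na)]
    best <- NULL
    for (st in alpha_starts) {
      fit <- tryCatch(
        stats::nlminb(st[free_alpha],
                      function(av) {
                        al <- fixed_alphas
                        al[free_alpha] <- av
                        solve_lengths(al)
                      },
                      lower = rep(0, sum(free_alpha)),
                      upper = rep(1, sum(free_alpha)),
                      control = list(iter.max = 300, rel.tol = 1e-12)),
        error = function(e) NULL)
      if (is.null(fit)) next
      if (is.null(best) || fit$objective < best$objective) best <- fit
    }
    if (is.null(best)) abort("graph fit failed from every start")
    best_alphas <- fixed_alphas
    best_alphas[free_alpha] <- best$par
  }
  sol <- solve_lengths(best_alphas, want_par = TRUE)
  par <- c(sol$len, best_alphas)
  list(par = par, score = sol$score, n_starts = length(alpha_starts))
}

#' Fit an admixture graph to observed f-statistics
#'
#' Bounded weighted least squares: drift lengths on `[0, Inf)` and admixture
#' proportions on `[0, 1]` are chosen to minimise the 1/SE^2-weighted sum of
#' squared residuals over the observed basis, with seeded multi-start
#' optimisation (the stored graph parameters, where set, form one start).
#' Deterministic given `seed`. Parameters whose individual perturbation
#' leaves the score flat are flagged `unconstrained` (note that ridge
#' directions involving several parameters jointly — e.g. the split of drift
#' between the two root edges, which f-statistics can never resolve — are
#' not detected by this per-parameter check).
#'
#' @param graph An [admix_graph()] skeleton (parameters may be `NA`).
#' @param basis An [fstat_basis()] tibble covering the graph leaves.
#' @param n_starts Number of optimisation starts (default 20).
#' @param seed Integer seed for the random starts.
#' @return An object of class `swampx_graph_fit`: fitted `graph`, `score`,
#'   parameter table `par` (with `unconstrained` flags), `n_restarts_used`,
#'   `seed`, and the `basis` used.
#' @export
fit_graph <- function(graph, basis, n_starts = 20, seed = 1) {
  leaves_needed <- graph$leaves
  got <- unique(c(basis$pop1, basis$pop2))
  missing_pop <- setdiff(leaves_needed, got)
  if (length(missing_pop)) {
    abort(paste0("basis does not cover leaf population(s): ",
                 paste(missing_pop, collapse = ", ")))
  }
  res <- multistart_fit(graph, basis, n_starts, seed)
  fitted <- graph_set_par(graph, res$par)
  obj <- basis_objective(graph, basis)
  delta <- pmax(abs(res$par) * 0.05, 1e-3)
  flat <- vapply(seq_along(res$par), function(i) {
    up <- res$par; up[i] <- up[i] + delta[i]
    dn <- res$par; dn[i] <- max(0, dn[i] - delta[i])
    if (i > nrow(graph$edges)) up[i] <- min(1, up[i])
    max(abs(obj(up) - res$score), abs(obj(dn) - res$score)) < 1e-8 * (1 + res$score)
  }, logical(1))
  structure(list(
    graph = fitted,
    score = res$score,
    par = tibble(
      name = graph_par_names(graph),
      type = c(rep("drift", nrow(graph$edges)), rep("alpha", nrow(graph$admix))),
      value = res$par,
      unconstrained = flat
    ),
    n_restarts_used = res$n_starts,
    seed = seed,
    basis = basis
  ), class = "swampx_graph_fit")
}

#' @export
print.swampx_graph_fit <- function(x, ...) {
  cat(sprintf("<swampx_graph_fit> score %.4g over %d statistics (%d starts)\n",
              x$score, nrow(x$basis), x$n_restarts_used))
  if (any(x$par$type == "alpha")) {
    a <- x$par[x$par$type == "alpha", ]
    cat("  admixture:", paste(sprintf("%s = %.3f", a$name, a$value), collapse = ", "), "\n")
  }
  if (any(x$par$unconstrained)) {
    cat("  unconstrained:", paste(x$par$name[x$par$unconstrained], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Worst f4 residual of a fitted graph
#'
#' Enumerates every f4 configuration among the fitted leaves (one orientation
#' per pairing; |z| is invariant under orientation flips), computes
#' observed minus predicted, standardises by the jackknife SE, and returns
#' the largest |z| alongside the full residual table.
#'
#' @param fit A `swampx_graph_fit`.
#' @param table An allele-count table.
#' @param partition Block ids aligned with the table sites.
#' @return List with `worst` (one-row tibble `config`, `observed`,
#'   `predicted`, `residual`, `se`, `z`) and `all` residual rows.
#' @export
worst_residual <- function(fit, table, partition) {
  graph <- fit$graph
  V <- expected_covariance(graph)
  pops <- intersect(graph$leaves, table$populations)
  if (length(pops) < 4L) abort("worst_residual needs at least 4 fitted leaf populations")
  quads <- utils::combn(sort(pops), 4L, simplify = FALSE)
  rows <- purrr::map(quads, function(q) {
    pairings <- list(q, q[c(1, 3, 2, 4)], q[c(1, 4, 2, 3)])
    purrr::map(pairings, function(pp) {
      r <- f_statistic(table, fstat_config("f4", pp), partition)
      pred <- predict_fstat(V, "f4", pp)
      tibble(config = format(r$config), observed = r$estimate, predicted = pred,
             residual = r$estimate - pred, se = r$se,
             z = if (r$zero_se) NA_real_ else (r$estimate - pred) / r$se)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  list(worst = rows[which.max(abs(rows$z)), ], all = rows)
}

# insert an admixture event from the midpoint of edge `src` into edge `dst`
insert_admixture <- function(graph, src, dst, tag) {
  stopifnot(length(src) == 2L, length(dst) == 2L)
  m1 <- paste0("mid", tag, "a")
  m2 <- paste0("mid", tag, "b")
  adm <- paste0("adm", tag)
  e <- graph$edges
  i_src <- which(e$parent == src[1] & e$child == src[2])
  i_dst <- which(e$parent == dst[1] & e$child == dst[2])
  if (!length(i_src) || !length(i_dst)) abort("edge not found")
  l_src <- e$length[i_src]
  l_dst <- e$length[i_dst]
  e <- e[-c(i_src, i_dst), ]
  e <- dplyr::bind_rows(e, tibble(
    parent = c(src[1], m1, dst[1], adm),
    child = c(m1, src[2], m2, dst[2]),
    length = c(l_src / 2, l_src / 2, l_dst / 2, l_dst / 2)
  ))
  admix <- dplyr::bind_rows(graph$admix,
                            tibble(node = adm, parent1 = m1, parent2 = m2,
                                   alpha = NA_real_))
  admix_graph(e, admix)
}

#' Greedy admixture-edge search
#'
#' Starting from a fitted tree (or graph), repeatedly considers inserting an
#' admixture event between the midpoints of every ordered pair of drift
#' edges that preserves acyclicity, refits each candidate, and keeps the one
#' that most reduces the worst |z| residual. Stops when the worst |z| drops
#' below `z_stop`, when `max_edges` is reached, or when no candidate improves
#' the fit. The incumbent parameters seed each candidate's optimisation, so
#' the score never increases along the accepted sequence.
#'
#' @param graph Starting [admix_graph()] (typically a tree skeleton).
#' @param table An allele-count table.
#' @param partition Block ids aligned with the table sites.
#' @param outgroup Outgroup label for the f3 basis.
#' @param max_edges Maximum admixture edges to add.
#' @param z_stop Stop once the worst |z| is below this (default 3).
#' @param seed Integer seed.
#' @param n_starts Starts for the final refit of each accepted model.
#' @param search_starts Starts used while screening candidates.
#' @return The final `swampx_graph_fit`, with a `log` tibble of accepted and
#'   considered steps attached.
#' @export
greedy_edge_addition <- function(graph, table, partition, outgroup,
                                 max_edges = 2, z_stop = 3, seed = 1,
                                 n_starts = 20, search_starts = 6) {
  basis <- fstat_basis(table, partition, outgroup, populations = graph$leaves)
  fit <- fit_graph(graph, basis, n_starts = n_starts, seed = seed)
  wr <- worst_residual(fit, table, partition)
  log <- tibble(step = 0L, action = "initial fit", score = fit$score,
                worst_z = wr$worst$z, worst_config = wr$worst$config)
  step <- 0L
  while (step < max_edges && abs(wr$worst$z) >= z_stop) {
    step <- step + 1L
    e <- fit$graph$edges
    best_cand <- NULL
    for (i in seq_len(nrow(e))) {
      for (j in seq_len(nrow(e))) {
        if (i == j) next
        # cycle guard: the donor midpoint must not sit below the recipient edge
        desc_j <- graph_descendants(fit$graph, e$child[j])
        if (e$parent[i] %in% desc_j) next
        cand_graph <- insert_admixture(fit$graph, c(e$parent[i], e$child[i]),
                                       c(e$parent[j], e$child[j]),
                                       tag = sprintf("%d_%d_%d", step, i, j))
        warm <- graph_get_par(cand_graph)
        warm[is.na(warm)] <- c(rep(0.01, sum(is.na(warm[seq_len(nrow(cand_graph$edges))]))),
                               rep(0.5, sum(is.na(warm[-seq_len(nrow(cand_graph$edges))]))))
        res <- tryCatch(
          multistart_fit(cand_graph, basis, search_starts, seed + 1000L * step + j,
                         extra_starts = list(warm)),
          error = function(err) NULL)
        if (is.null(res)) next
        cand_fitted <- graph_set_par(cand_graph, res$par)
        cand_fit <- structure(list(graph = cand_fitted, score = res$score,
                                   basis = basis), class = "swampx_graph_fit")
        cand_wr <- worst_residual(cand_fit, table, partition)
        if (is.null(best_cand) || abs(cand_wr$worst$z) < abs(best_cand$worst_z)) {
          best_cand <- list(graph = cand_graph, worst_z = cand_wr$worst$z,
                            score = res$score,
                            src = sprintf("%s->%s", e$parent[i], e$child[i]),
                            dst = sprintf("%s->%s", e$parent[j], e$child[j]))
        }
      }
    }
    if (is.null(best_cand) ||
        (abs(best_cand$worst_z) >= abs(wr$worst$z) && best_cand$score >= fit$score)) {
      log <- dplyr::bind_rows(log, tibble(step = step, action = "no improving candidate",
                                          score = fit$score, worst_z = wr$worst$z,
                                          worst_config = wr$worst$config))
      break
    }
    fit <- fit_graph(best_cand$graph, basis, n_starts = n_starts,
                     seed = seed + step)
    wr <- worst_residual(fit, table, partition)
    log <- dplyr::bind_rows(log, tibble(
      step = step,
      action = sprintf("added admixture %s => %s", best_cand$src, best_cand$dst),
      score = fit$score, worst_z = wr$worst$z, worst_config = wr$worst$config))
  }
  fit$log <- log
  fit$worst_f4 <- wr$worst
  fit
}

#' Refit admixture proportions on X-chromosome data
#'
#' Freezes the autosomally fitted graph and re-estimates the admixture
#' proportions on an X-linked f-statistic basis. The default (`"alpha_only"`)
#' keeps topology and drift lengths at their autosomal estimates and refits
#' only the mixing proportions, so every autosome-X difference is attributed
#' to the admixed fractions — the fixed-graph comparison that an admixture
#' graph annotated with one drift scale and per-class fractions implies.
#' `"alpha_and_drift"` additionally refits drift lengths (X drift differs
#' from autosomal drift because the X effective size is about 3/4 of the
#' autosomal one) as a sensitivity analysis; it is noisier on X-sized panels
#' because the extra free drift trades off against the proportions. Under
#' sustained male-biased gene flow the donor-side proportion is expected to
#' be smaller on the X than on the autosomes.
#'
#' @param fit Autosomal `swampx_graph_fit`.
#' @param table_x Allele-count table restricted/partitioned to (masked) X
#'   sites.
#' @param partition_x Block ids for the X sites.
#' @param outgroup Outgroup label.
#' @param mode `"alpha_only"` (default) or `"alpha_and_drift"`.
#' @param n_starts,seed Optimisation controls.
#' @return An object of class `swampx_refit`: `comparison` tibble (`node`,
#'   `alpha_autosome`, `alpha_x`, `unconstrained_x`), the X-side fit, and the
#'   mode.
#' @export
refit_admixture_on_x <- function(fit, table_x, partition_x, outgroup,
                                 mode = c("alpha_only", "alpha_and_drift"),
                                 n_starts = 20, seed = 1) {
  mode <- match.arg(mode)
  graph <- fit$graph
  if (!nrow(graph$admix)) abort("fitted graph has no admixture nodes to refit")
  basis_x <- fstat_basis(table_x, partition_x, outgroup,
                         populations = graph$leaves)
  np <- graph_n_par(graph)
  ne <- nrow(graph$edges)
  free <- if (mode == "alpha_only") c(rep(FALSE, ne), rep(TRUE, np - ne))
          else rep(TRUE, np)
  res <- multistart_fit(graph, basis_x, n_starts, seed, free = free,
                        extra_starts = list(graph_get_par(graph)))
  fitted_x <- graph_set_par(graph, res$par)
  obj <- basis_objective(graph, basis_x)
  alpha_idx <- ne + seq_len(nrow(graph$admix))
  flat <- vapply(alpha_idx, function(i) {
    up <- res$par; up[i] <- min(1, up[i] + 0.02)
    dn <- res$par; dn[i] <- max(0, dn[i] - 0.02)
    max(abs(obj(up) - res$score), abs(obj(dn) - res$score)) < 1e-8 * (1 + res$score)
  }, logical(1))
  if (any(flat)) {
    warn(paste0("X basis leaves admixture proportion(s) unconstrained: ",
                paste(graph$admix$node[flat], collapse = ", ")))
  }
  structure(list(
    comparison = tibble(
      node = graph$admix$node,
      alpha_autosome = fit$graph$admix$alpha,
      alpha_x = fitted_x$admix$alpha,
      unconstrained_x = flat
    ),
    fit_x = structure(list(graph = fitted_x, score = res$score, basis = basis_x,
                           n_restarts_used = res$n_starts, seed = seed,
                           par = tibble(name = graph_par_names(graph),
                                        type = c(rep("drift", ne),
                                                 rep("alpha", np - ne)),
                                        value = res$par,
                                        unconstrained = NA)),
                      class = "swampx_graph_fit"),
    mode = mode
  ), class = "swampx_refit")
}

#' @export
print.swampx_refit <- function(x, ...) {
  cat(sprintf("<swampx_refit> mode %s\n", x$mode))
  print(x$comparison)
  invisible(x)
}

#' Read / write an admixture graph as a plain-text edge list
#'
#' TSV with columns `child`, `parent`, `type` (`drift`/`admix`), `value`
#' (drift length, or alpha on the first admix row of a node).
#'
#' @param path File path.
#' @param graph An [admix_graph()].
#' @return `read_graph` returns an `admix_graph`; `write_graph` returns
#'   `path` invisibly.
#' @export
read_graph <- function(path) {
  tb <- readr::read_tsv(path, col_types = readr::cols(
    child = readr::col_character(), parent = readr::col_character(),
    type = readr::col_character(), value = readr::col_double()))
  drift <- tb[tb$type == "drift", ]
  adm <- tb[tb$type == "admix", ]
  admix <- NULL
  if (nrow(adm)) {
    admix <- adm |>
      dplyr::group_by(.data$child) |>
      dplyr::summarise(parent1 = .data$parent[1], parent2 = .data$parent[2],
                       alpha = .data$value[1], .groups = "drop") |>
      dplyr::rename(node = "child")
  }
  admix_graph(tibble(parent = drift$parent, child = drift$child,
                     length = drift$value), admix)
}

#' @rdname read_graph
#' @export
write_graph <- function(graph, path) {
  rows <- tibble(child = graph$edges$child, parent = graph$edges$parent,
                 type = "drift", value = graph$edges$length)
  if (nrow(graph$admix)) {
    rows <- dplyr::bind_rows(rows,
      tibble(child = rep(graph$admix$node, each = 2),
             parent = as.vector(rbind(graph$admix$parent1, graph$admix$parent2)),
             type = "admix",
             value = as.vector(rbind(graph$admix$alpha, NA_real_))))
  }
  readr::write_tsv(rows, path)
  invisible(path)
}

#' Export a graph as Graphviz DOT
#'
#' Solid edges carry drift lengths; dashed edges mark admixture with the
#' mixing percentage.
#'
#' @param graph An [admix_graph()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graph_dot <- function(graph, path) {
  lines <- c("digraph admixture {", "  node [shape=plaintext];")
  for (i in seq_len(nrow(graph$edges))) {
    lab <- if (is.na(graph$edges$length[i])) "" else sprintf(" [label=\"%.4g\"]",
                                                             graph$edges$length[i])
    lines <- c(lines, sprintf("  %s -> %s%s;", graph$edges$parent[i],
                              graph$edges$child[i], lab))
  }
  for (i in seq_len(nrow(graph$admix))) {
    a <- graph$admix$alpha[i]
    lines <- c(lines,
      sprintf("  %s -> %s [style=dashed,label=\"%s\"];", graph$admix$parent1[i],
              graph$admix$node[i], if (is.na(a)) "?" else sprintf("%.0f%%", 100 * a)),
      sprintf("  %s -> %s [style=dashed,label=\"%s\"];", graph$admix$parent2[i],
              graph$admix$node[i], if (is.na(a)) "?" else sprintf("%.0f%%", 100 * (1 - a))))
  }
  writeLines(c(lines, "}"), path)
  invisible(path)
}
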