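#' Pipeline configuration
#'
#' Bundles the inputs and settings for [run_full()]. Provide either a
#' ready-made [geno_matrix()] or the triplet of file paths (VCF, sample
#' sheet, chromosome-class map).
#'
#' @param genotypes Optional [geno_matrix()].
#' @param vcf,sample_sheet,class_map Input paths (used when `genotypes` is
#'   `NULL`).
#' @param outgroup Outgroup population label.
#' @param block_size Jackknife block width in bp (default 5 Mb).
#' @param x_mask Region mask excluded from X analyses (default: PARs plus
#'   the 10-Mb PAR1-proximal window, [preset_mask()]).
#' @param enumerate Run the full f4 enumeration.
#' @param alpha Significance level for the Bonferroni-corrected enumeration.
#' @param contrasts List of length-4 population vectors (A, B, C, D with A
#'   the outgroup) to contrast between autosomes and X.
#' @param graph `NULL`, an [admix_graph()] skeleton, a graph file path, or
#'   `"greedy"` to search for admixture edges from the NJ-style tree is not
#'   attempted automatically — pass a skeleton for greedy search.
#' @param max_edges,z_stop Greedy-search controls.
#' @param refit_x Refit admixture proportions on the X when the fitted graph
#'   has admixture nodes.
#' @param seed Master seed; per-stage seeds are derived deterministically.
#' @param out_dir Output directory for the report bundle.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(genotypes = NULL, vcf = NULL, sample_sheet = NULL,
                            class_map = NULL, outgroup, block_size = 5e6,
                            x_mask = preset_mask("x_default"),
                            enumerate = TRUE, alpha = 1e-4,
                            contrasts = list(), graph = NULL,
                            max_edges = 2, z_stop = 3, refit_x = TRUE,
                            seed = 1, out_dir = tempfile("swampx_run_")) {
  if (is.null(genotypes)) {
    for (p in c(vcf, sample_sheet, class_map)) {
      if (!file.exists(p)) abort(sprintf("input file not found: %s", p))
    }
  }
  structure(list(genotypes = genotypes, vcf = vcf, sample_sheet = sample_sheet,
                 class_map = class_map, outgroup = outgroup,
                 block_size = block_size, x_mask = x_mask,
                 enumerate = enumerate, alpha = alpha, contrasts = contrasts,
                 graph = graph, max_edges = max_edges, z_stop = z_stop,
                 refit_x = refit_x, seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

stage_seed <- function(seed, label) {
  (seed + sum(utf8ToInt(label)) * 131L) %% .Machine$integer.max
}

run_stage <- function(log_env, name, expr) {
  res <- tryCatch(force(expr), error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
  log_env$lines <- c(log_env$lines, sprintf("[%s] ok", name))
  res
}

#' Run the full analysis pipeline
#'
#' Load -> complete-case filter -> X mask -> NJ tree -> outgroup-f3 table ->
#' f4 enumeration -> autosome-vs-X contrasts -> admixture-graph fit (+ X
#' refit). Every stage writes its table into the output directory
#' (TSV / Newick / JSON / DOT) together with a run log of QC counts, so each
#' reported number is recomputable from the persisted intermediates.
#' Deterministic given `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all stage results and `out_dir`.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logv <- new.env()
  logv$lines <- character()
  note <- function(...) logv$lines <- c(logv$lines, sprintf(...))

  gm <- run_stage(logv, "load", {
    if (!is.null(config$genotypes)) config$genotypes
    else read_vcf(config$vcf, read_sample_sheet(config$sample_sheet),
                  read_class_map(config$class_map))
  })
  note("sites loaded: %d", n_sites(gm))
  gm <- run_stage(logv, "complete_cases", filter_complete_cases(gm))
  note("complete-case sites: %d", n_sites(gm))
  gm <- run_stage(logv, "x_mask", apply_region_mask(gm, config$x_mask, "exclude"))
  note("sites after X mask: %d", n_sites(gm))

  het <- per_sample_heterozygosity(gm)
  readr::write_tsv(het, file.path(out_dir, "heterozygosity.tsv"))

  tree <- run_stage(logv, "nj_tree", {
    D <- ibs_distance(gm)
    write_dist_tsv(D, file.path(out_dir, "ibs_distance.tsv"))
    tr <- neighbor_joining(D)
    og_samples <- gm$samples$sample_id[gm$samples$population == config$outgroup]
    if (length(og_samples)) tr <- root_by_outgroup(tr, og_samples[1])
    ape::write.tree(tr, file.path(out_dir, "nj_tree.nwk"))
    tr
  })

  table <- allele_counts_by_population(gm)
  part_a <- assign_blocks(table, config$block_size, classes = "autosome")
  part_x <- assign_blocks(table, config$block_size, classes = "X")

  f3_tbl <- run_stage(logv, "f3_table", {
    inner <- sort(setdiff(table$populations, config$outgroup))
    rows <- purrr::map(utils::combn(inner, 2L, simplify = FALSE), function(pr) {
      glance(f_statistic(table, fstat_config("f3_outgroup", c(pr, config$outgroup)),
                         part_a))
    }) |> dplyr::bind_rows()
    readr::write_tsv(rows, file.path(out_dir, "f3_outgroup.tsv"))
    rows
  })

  enum <- NULL
  if (isTRUE(config$enumerate)) {
    enum <- run_stage(logv, "enumerate_f4", {
      tb <- enumerate_f4(table, config$outgroup, part_a, alpha = config$alpha)
      readr::write_tsv(tb, file.path(out_dir, "f4_enumeration.tsv"))
      tb
    })
    note("f4 enumeration: %d triples, %d significant", nrow(enum), sum(enum$significant))
  }

  contrasts <- NULL
  if (length(config$contrasts)) {
    contrasts <- run_stage(logv, "contrast_autosome_x", {
      res <- purrr::map(config$contrasts, function(p) {
        contrast_autosome_x(table, fstat_config("f4", p), part_a, part_x)
      })
      tb <- purrr::map(res, glance) |> dplyr::bind_rows()
      readr::write_tsv(tb, file.path(out_dir, "contrasts.tsv"))
      res
    })
  }

  fit <- NULL
  refit <- NULL
  graph_in <- config$graph
  if (!is.null(graph_in)) {
    if (is.character(graph_in)) graph_in <- read_graph(graph_in)
    fit <- run_stage(logv, "graph_fit", {
      g <- greedy_edge_addition(graph_in, table, part_a, config$outgroup,
                                max_edges = config$max_edges,
                                z_stop = config$z_stop,
                                seed = stage_seed(config$seed, "graph_fit"))
      write_graph(g$graph, file.path(out_dir, "graph_fitted.tsv"))
      write_graph_dot(g$graph, file.path(out_dir, "graph_fitted.dot"))
      readr::write_tsv(g$log, file.path(out_dir, "graph_log.tsv"))
      g
    })
    note("graph score %.4g, worst |z| %.3g", fit$score, abs(fit$worst_f4$z))
    if (isTRUE(config$refit_x) && nrow(fit$graph$admix)) {
      refit <- run_stage(logv, "refit_x", {
        r <- refit_admixture_on_x(fit, table, part_x, config$outgroup,
                                  seed = stage_seed(config$seed, "refit_x"))
        readr::write_tsv(r$comparison, file.path(out_dir, "admixture_x_refit.tsv"))
        r
      })
    }
  }

  writeLines(logv$lines, file.path(out_dir, "run_log.txt"))
  jsonlite::write_json(
    list(seed = config$seed, outgroup = config$outgroup,
         block_size = config$block_size, n_sites = n_sites(gm),
         stages = logv$lines),
    file.path(out_dir, "run_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(genotypes = gm, tree = tree, f3 = f3_tbl, enumeration = enum,
                 contrasts = contrasts, graph_fit = fit, x_refit = refit,
                 out_dir = out_dir, log = logv$lines))
}

#' Admixture-graph skeleton matching the simulated admixture scenarios
#'
#' The true topology of [nuclear_swamping_scenario()] /
#' [admixture_pulse_scenario()] with all parameters free: outgroup A; the
#' donor-side sister pair D and Dp; B sister to the original C lineage C0;
#' sampled C an admixture of C0 and a midpoint Dpm on the Dp lineage, with
#' `alpha` the donor-side proportion. Both donor-side leaves must be sampled
#' for `alpha` to be identifiable from f-statistics.
#'
#' @return An [admix_graph()] skeleton.
#' @export
swamping_graph_skeleton <- function() {
  admix_graph(
    edges = tibble(
      parent = c("root", "root", "R1", "R1", "D0", "D0", "Dpm", "BC", "BC", "ADM"),
      child = c("A", "R1", "D0", "BC", "D", "Dpm", "Dp", "B", "C0", "C"),
      length = NA_real_
    ),
    admix = tibble(node = "ADM", parent1 = "Dpm", parent2 = "C0", alpha = NA_real_)
  )
}

#' One-command synthetic demonstration
#'
#' Simulates the nuclear-swamping preset, writes the VCF / sample sheet /
#' truth record, runs the full pipeline with the true graph skeleton, and
#' renders a small figure set (f4 forest plot, fitted graph DOT).
#'
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @param strength,duration Scenario controls (see
#'   [nuclear_swamping_scenario()]).
#' @return Invisibly, the [run_full()] result with the simulation truth
#'   attached.
#' @export
run_demo <- function(seed = 1, out_dir = tempfile("swampx_demo_"),
                     strength = 0.05, duration = 30) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  # donor sister sampled: the graph stage needs the identifiable configuration
  sim <- nuclear_swamping_scenario(strength = strength, duration = duration,
                                   seed = stage_seed(seed, "simulate"),
                                   sample_donor_sister = TRUE)
  write_vcf(sim$genotypes, file.path(out_dir, "simulated.vcf"))
  write_sample_sheet(sim$genotypes, file.path(out_dir, "samples.tsv"))
  jsonlite::write_json(sim$truth$ancestry, file.path(out_dir, "truth_ancestry.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- pipeline_config(
    genotypes = sim$genotypes, outgroup = "A",
    contrasts = list(c("A", "B", "C", "D")),
    graph = swamping_graph_skeleton(), max_edges = 0,
    seed = seed, out_dir = out_dir
  )
  res <- run_full(cfg)
  fig <- plot_f4_forest(res$contrasts)
  ggplot2::ggsave(file.path(out_dir, "f4_forest.png"), fig,
                  width = 6, height = 3, dpi = 120)
  res$truth <- sim$truth
  invisible(res)
}
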