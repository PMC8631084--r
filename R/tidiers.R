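#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy per-block detail of an f-statistic
#'
#' @param x A `swampx_fstat`.
#' @param ... Unused.
#' @return Tibble with one row per jackknife block (`statistic`, `block`,
#'   `estimate`, `n`, `loo`, `pseudovalue`).
#' @export
tidy.swampx_fstat <- function(x, ...) {
  dplyr::mutate(x$per_block, statistic = format(x$config), .before = 1)
}

#' One-row summary of an f-statistic
#'
#' @param x A `swampx_fstat`.
#' @param ... Unused.
#' @return One-row tibble: `statistic`, `estimate`, `se`, `z`, `n_sites`,
#'   `n_blocks`, `n_skipped`.
#' @export
glance.swampx_fstat <- function(x, ...) {
  tibble(statistic = format(x$config), estimate = x$estimate, se = x$se,
         z = if (x$zero_se) NA_real_ else x$z,
         n_sites = x$n_sites, n_blocks = x$n_blocks, n_skipped = x$n_skipped)
}

#' Tidy an autosome-vs-X contrast
#'
#' @param x A `swampx_contrast`.
#' @param ... Unused.
#' @return Two-row tibble (one per chromosome class) with estimate, SE, Z
#'   and block counts.
#' @export
tidy.swampx_contrast <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(glance(x$autosome), class = "autosome", .before = 1),
    dplyr::mutate(glance(x$x), class = "X", .before = 1)
  )
}

#' One-row summary of an autosome-vs-X contrast
#'
#' @param x A `swampx_contrast`.
#' @param ... Unused.
#' @return One-row tibble: configuration, class estimates, Welch `t`, `df`,
#'   `p_value`, `direction`.
#' @export
glance.swampx_contrast <- function(x, ...) {
  tibble(statistic = format(x$config),
         estimate_autosome = x$autosome$estimate, estimate_x = x$x$estimate,
         t = x$t, df = x$df, p_value = x$p_value, direction = x$direction)
}

#' Tidy fitted graph parameters
#'
#' @param x A `swampx_graph_fit`.
#' @param ... Unused.
#' @return The parameter tibble (`name`, `type`, `value`, `unconstrained`).
#' @export
tidy.swampx_graph_fit <- function(x, ...) x$par

#' One-row summary of a graph fit
#'
#' @param x A `swampx_graph_fit`.
#' @param ... Unused.
#' @return One-row tibble: `score`, `n_parameters`, `n_statistics`,
#'   `n_admixture_nodes`, plus the worst f4 residual when recorded.
#' @export
glance.swampx_graph_fit <- function(x, ...) {
  out <- tibble(score = x$score,
                n_parameters = nrow(x$par %||% tibble()),
                n_statistics = nrow(x$basis),
                n_admixture_nodes = nrow(x$graph$admix))
  if (!is.null(x$worst_f4)) {
    out$worst_f4_config <- x$worst_f4$config
    out$worst_f4_residual <- x$worst_f4$residual
    out$worst_f4_z <- x$worst_f4$z
  }
  out
}

#' Tidy an X-chromosome admixture refit
#'
#' @param x A `swampx_refit`.
#' @param ... Unused.
#' @return The `comparison` tibble (per admixture node, autosomal vs X
#'   proportion).
#' @export
tidy.swampx_refit <- function(x, ...) x$comparison
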