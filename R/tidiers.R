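# broom-style tidiers for the package's result objects

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a co-expression null result
#'
#' One row per null simulation.
#'
#' @param x A `chiahub_coexpr` object.
#' @param ... Unused.
#' @return Tibble `sim`, `null_mean_pcc`.
#' @method tidy chiahub_coexpr
#' @export
tidy.chiahub_coexpr <- function(x, ...) {
  tibble(sim = seq_along(x$null_means), null_mean_pcc = x$null_means)
}

#' @rdname tidy.chiahub_coexpr
#' @return For `glance`: a one-row summary with the observed mean PCC, the
#'   null mean and sd, the empirical p value and the run parameters.
#' @method glance chiahub_coexpr
#' @export
glance.chiahub_coexpr <- function(x, ...) {
  tibble(observed_mean_pcc = x$observed_mean_pcc,
         null_mean = mean(x$null_means), null_sd = sd(x$null_means),
         p_value = x$p_value, n_pairs = x$n_pairs, n_sim = x$n_sim,
         null_mode = x$null_mode, seed = x$seed)
}

#' Tidy a connectivity network
#'
#' @param x A `chiahub_network`.
#' @param ... Unused.
#' @return For `tidy`: the node table. For `glance`: one row with node,
#'   edge, seed and component counts per category.
#' @method tidy chiahub_network
#' @export
tidy.chiahub_network <- function(x, ...) x$nodes

#' @rdname tidy.chiahub_network
#' @method glance chiahub_network
#' @export
glance.chiahub_network <- function(x, ...) {
  s <- network_summary(x)
  cnt <- setNames(s$seed_counts$n, paste0("seeds_", s$seed_counts$category))
  dplyr::bind_cols(
    tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
           n_components = length(s$component_sizes), hops = x$hops),
    as_tibble(as.list(cnt)))
}
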