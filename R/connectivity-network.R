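# Anchor-gene assignment and seed-gene connectivity networks. An anchor is
# assigned to the gene(s) whose region (1 kb upstream of TSS through TTS)
# contains at least half of the anchor; for active marks the single
# highest-FPKM candidate wins, for H3K27me3 all candidates are kept.

#' Assign anchor genes to loop anchors
#'
#' Candidate genes are those whose gene region (1 kb upstream of the TSS
#' through the TTS) covers at least `min_frac` of the anchor's own length.
#' For `mark_category = "active"` the single candidate with the highest
#' FPKM is returned (ties broken by longer overlap, then lexicographic gene
#' id); for `"repressive"` (H3K27me3) all candidates are returned.
#'
#' @param anchors Tibble with `chrom`, `start`, `end` (one row per anchor).
#' @param genes Gene tibble.
#' @param expr Optional expression tibble; FPKM is taken from `fpkm_column`
#'   (default: a column named `seedling` when present, otherwise the first
#'   tissue column). Genes missing from the table count as FPKM 0.
#' @param mark_category `"active"` or `"repressive"`.
#' @param min_frac Minimal fraction of the anchor length inside the gene
#'   region.
#' @param fpkm_column Tissue column used for the highest-FPKM rule.
#' @return List (one element per anchor row) of character vectors of gene
#'   ids; empty when no candidate.
#' @export
assign_anchor_genes <- function(anchors, genes, expr = NULL,
                                mark_category = c("active", "repressive"),
                                min_frac = 0.5, fpkm_column = NULL) {
  mark_category <- match.arg(mark_category)
  regions <- gene_regions_of(genes)
  out <- vector("list", nrow(anchors))
  for (i in seq_along(out)) out[[i]] <- character()
  if (!nrow(anchors) || !nrow(regions)) return(out)

  hits <- overlap_pairs(anchors, regions)
  if (!nrow(hits)) return(out)
  ov <- overlap_bp(anchors[hits$a_idx, ], regions[hits$b_idx, ])
  frac <- ov / (anchors$end[hits$a_idx] - anchors$start[hits$a_idx])
  hits <- hits[frac >= min_frac, ]
  ov <- ov[frac >= min_frac]
  if (!nrow(hits)) return(out)

  fpkm <- rep(0, nrow(genes))
  if (!is.null(expr)) {
    col <- fpkm_column %||% (if ("seedling" %in% names(expr)) "seedling"
                             else names(expr)[2])
    fpkm <- expr[[col]][match(genes$gene_id, expr$gene_id)]
    fpkm[is.na(fpkm)] <- 0
  }
  cand <- tibble(a_idx = hits$a_idx,
                 gene_id = regions$gene_id[hits$b_idx],
                 fpkm = fpkm[match(regions$gene_id[hits$b_idx], genes$gene_id)],
                 ov = ov)
  if (mark_category == "repressive") {
    by_a <- cand %>% dplyr::group_by(.data$a_idx) %>%
      dplyr::summarise(g = list(sort(unique(.data$gene_id))), .groups = "drop")
  } else {
    by_a <- cand %>%
      dplyr::arrange(.data$a_idx, dplyr::desc(.data$fpkm),
                     dplyr::desc(.data$ov), .data$gene_id) %>%
      dplyr::group_by(.data$a_idx) %>%
      dplyr::summarise(g = list(.data$gene_id[1]), .groups = "drop")
  }
  out[by_a$a_idx] <- by_a$g
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Per-loop anchor-gene sets, with the rule chosen by each loop's mark.
loop_gene_pairs <- function(loops, genes, expr, min_frac = 0.5,
                            fpkm_column = NULL) {
  side_genes <- function(side) {
    anchors <- tibble(chrom = loops[[paste0("chrom_", side)]],
                      start = loops[[paste0("start_", side)]],
                      end = loops[[paste0("end_", side)]])
    g <- vector("list", nrow(loops))
    for (cat in c("active", "repressive")) {
      sel <- if (cat == "active") loops$mark != "H3K27me3" else loops$mark == "H3K27me3"
      if (any(sel)) {
        g[sel] <- assign_anchor_genes(anchors[sel, ], genes, expr,
                                      mark_category = cat,
                                      min_frac = min_frac,
                                      fpkm_column = fpkm_column)
      }
    }
    g
  }
  tibble(loop_id = loops$loop_id, mark = loops$mark,
         genes_a = side_genes("a"), genes_b = side_genes("b"))
}

#' Build a seed-gene connectivity network
#'
#' Hop 1 collects every loop with at least one anchor assigned to a seed
#' gene; hop 2 additionally collects loops touching any gene reached at hop
#' 1. Edges connect the anchor genes of the two sides of each collected
#' loop. Each node's category reflects its incident edge marks: `active`,
#' `repressive` (H3K27me3) or `mixed` when both occur.
#'
#' @param seed_genes Character vector of seed gene ids.
#' @param loops Loop tibble (active marks and/or H3K27me3).
#' @param genes Gene tibble.
#' @param expr Optional expression tibble for the anchor-gene rule.
#' @param hops 1 or 2.
#' @param min_frac,fpkm_column Passed to [assign_anchor_genes()].
#' @return Object of class `chiahub_network`: list with `nodes` (tibble
#'   `gene_id`, `role`, `category`, `component`), `edges` (tibble `gene_a`,
#'   `gene_b`, `mark`, `loop_id`), `hops`, `seed_genes`.
#' @export
build_network <- function(seed_genes, loops, genes, expr = NULL, hops = 1L,
                          min_frac = 0.5, fpkm_column = NULL) {
  if (!hops %in% c(1L, 2L)) stop("hops must be 1 or 2", call. = FALSE)
  if (!length(seed_genes)) stop("seed list is empty", call. = FALSE)
  unknown <- setdiff(seed_genes, genes$gene_id)
  if (length(unknown)) {
    warning("unknown seed gene id(s) skipped: ",
            paste(head(unknown, 3), collapse = ", "), call. = FALSE)
    seed_genes <- intersect(seed_genes, genes$gene_id)
  }
  lg <- loop_gene_pairs(loops, genes, expr, min_frac, fpkm_column)
  loop_genes <- purrr::map2(lg$genes_a, lg$genes_b, ~ unique(c(.x, .y)))

  touches <- function(gene_set) {
    vapply(loop_genes, function(g) any(g %in% gene_set), logical(1))
  }
  sel <- touches(seed_genes)
  if (hops == 2L) {
    reached <- unique(unlist(loop_genes[sel]))
    sel <- sel | touches(reached)
  }
  picked <- lg[sel, ]
  edges <- purrr::pmap_dfr(
    list(picked$genes_a, picked$genes_b, picked$mark, picked$loop_id),
    function(ga, gb, mark, id) {
      if (!length(ga) || !length(gb)) return(NULL)
      grid <- expand.grid(gene_a = ga, gene_b = gb,
                          stringsAsFactors = FALSE)
      grid <- grid[grid$gene_a != grid$gene_b, , drop = FALSE]
      if (!nrow(grid)) return(NULL)
      tibble(gene_a = pmin(grid$gene_a, grid$gene_b),
             gene_b = pmax(grid$gene_a, grid$gene_b),
             mark = mark, loop_id = id)
    })
  if (is.null(edges) || !nrow(edges)) {
    edges <- tibble(gene_a = character(), gene_b = character(),
                    mark = character(), loop_id = character())
  }
  node_ids <- sort(unique(c(edges$gene_a, edges$gene_b)))
  incident_marks <- function(g) {
    unique(edges$mark[edges$gene_a == g | edges$gene_b == g])
  }
  category <- vapply(node_ids, function(g) {
    mk <- incident_marks(g)
    act <- any(mk != "H3K27me3"); rep_ <- any(mk == "H3K27me3")
    if (act && rep_) "mixed" else if (rep_) "repressive" else "active"
  }, character(1), USE.NAMES = FALSE)
  comp <- components_of(node_ids, edges)
  nodes <- tibble(gene_id = node_ids,
                  role = ifelse(node_ids %in% seed_genes, "seed", "connecting"),
                  category = category, component = comp)
  structure(list(nodes = nodes, edges = edges, hops = hops,
                 seed_genes = seed_genes),
            class = "chiahub_network")
}

# connected component id per node (union-find, small graphs)
components_of <- function(node_ids, edges) {
  parent <- seq_along(node_ids)
  idx <- setNames(seq_along(node_ids), node_ids)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(edges))) {
    a <- find(idx[[edges$gene_a[k]]]); b <- find(idx[[edges$gene_b[k]]])
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_along(node_ids), find, integer(1))
  as.integer(factor(roots))
}

#' @export
print.chiahub_network <- function(x, ...) {
  cat(sprintf("Connectivity network (%d hop%s): %d nodes, %d edges, %d component(s)\n",
              x$hops, if (x$hops > 1) "s" else "", nrow(x$nodes),
              nrow(x$edges), max(c(x$nodes$component, 0L))))
  invisible(x)
}

#' Summarise a connectivity network
#'
#' @param network A `chiahub_network`.
#' @return List with `seed_counts` (tibble of seed-gene counts per
#'   category), `node_counts`, `component_sizes`, and a `membership`
#'   tibble suitable for export to graph tools.
#' @export
network_summary <- function(network) {
  nodes <- network$nodes
  seeds <- nodes[nodes$role == "seed", ]
  count_by <- function(df) {
    full <- tibble(category = c("active", "repressive", "mixed"))
    got <- dplyr::count(df, .data$category, name = "n")
    dplyr::left_join(full, got, by = "category") %>%
      dplyr::mutate(n = ifelse(is.na(.data$n), 0L, .data$n))
  }
  list(seed_counts = count_by(seeds),
       node_counts = count_by(nodes),
       component_sizes = as.integer(table(nodes$component)),
       membership = nodes)
}

#' Write a network as an edge-list TSV
#'
#' @param network A `chiahub_network`.
#' @param path Output path (columns source, target, mark, loop_id).
#' @export
write_network <- function(network, path) {
  readr::write_tsv(
    dplyr::rename(network$edges, source = "gene_a", target = "gene_b"),
    path, progress = FALSE)
  invisible(path)
}
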