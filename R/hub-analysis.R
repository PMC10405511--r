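# Chromatin hubs: merged loop anchors from which >= 5 interactions emanate.
# The gene at the node anchor is the node gene; genes at the far anchors are
# the connecting genes. Between two conditions a hub is classified from the
# connecting-gene change Ns = Nc - Nm as stable / partially disassembled
# (PDH) / entirely disassembled (EDH) / newly formed or grown (FH).

#' Detect chromatin hubs
#'
#' Overlapping loop anchors are merged into candidate node anchors; a node's
#' degree is the number of member loops touching it, and nodes with degree
#' at or above `min_degree` (default 5) are hubs. The node gene and the
#' connecting genes at the far anchors are assigned with the anchor-gene
#' rule of [assign_anchor_genes()] (highest-FPKM candidate for active marks).
#'
#' @param loops Loop tibble of one mark (or a deliberate union).
#' @param genes Gene tibble.
#' @param expr Expression tibble used for anchor-gene tie-breaking (optional;
#'   missing genes count as FPKM 0).
#' @param min_degree Minimal degree for a hub.
#' @param mark_category `"active"` (single best gene per anchor) or
#'   `"repressive"` (all candidate genes).
#' @param min_frac Anchor-in-gene-region overlap fraction for gene
#'   assignment.
#' @return Tibble `hub_id`, `chrom`, `start`, `end`, `degree`, `node_gene`,
#'   list-columns `connecting_genes`, `member_loops`.
#' @export
detect_hubs <- function(loops, genes, expr = NULL, min_degree = 5L,
                        mark_category = c("active", "repressive"),
                        min_frac = 0.5) {
  mark_category <- match.arg(mark_category)
  if (min_degree < 1) stop("min_degree must be >= 1", call. = FALSE)
  empty <- tibble(hub_id = character(), chrom = character(),
                  start = integer(), end = integer(), degree = integer(),
                  node_gene = character(),
                  connecting_genes = list(), member_loops = list())
  if (!nrow(loops)) return(empty)

  anchors <- loops_to_anchors(loops)
  merged_gr <- GenomicRanges::reduce(as_granges(anchors))
  merged <- tibble(chrom = as.character(GenomicRanges::seqnames(merged_gr)),
                   start = GenomicRanges::start(merged_gr) - 1L,
                   end = GenomicRanges::end(merged_gr))
  hit <- overlap_pairs(anchors, merged)
  anchors$node <- NA_integer_
  anchors$node[hit$a_idx] <- hit$b_idx

  anchor_gene <- assign_anchor_genes(anchors, genes, expr,
                                     mark_category = mark_category,
                                     min_frac = min_frac)

  per_node <- anchors %>%
    dplyr::group_by(node = .data$node) %>%
    dplyr::summarise(member_loops = list(sort(unique(.data$loop_id))),
                     degree = length(unique(.data$loop_id)), .groups = "drop")
  per_node <- per_node[per_node$degree >= min_degree, ]
  if (!nrow(per_node)) return(empty)

  far_genes <- function(node_idx, members) {
    rows <- anchors$loop_id %in% members & anchors$node != node_idx
    sort(unique(unlist(anchor_gene[rows])))
  }
  node_gene_of <- function(node_idx) {
    g <- sort(unique(unlist(anchor_gene[which(anchors$node == node_idx)])))
    if (length(g)) g[1] else NA_character_
  }
  out <- merged[per_node$node, ]
  out$degree <- per_node$degree
  out$node_gene <- vapply(per_node$node, node_gene_of, character(1))
  out$connecting_genes <- purrr::map2(per_node$node, per_node$member_loops,
                                      far_genes)
  out$member_loops <- per_node$member_loops
  out <- dplyr::arrange(out, .data$chrom, .data$start)
  out$hub_id <- sprintf("hub_%04d", seq_len(nrow(out)))
  dplyr::relocate(out, "hub_id")
}

#' TF-target enrichment of hubs
#'
#' One-sided (greater) Fisher exact test on the 2x2 table of in-hub versus
#' out-of-hub against TF-target versus not, per hub. A hub is enriched when
#' the raw p is below `alpha`; BH-adjusted p values are reported alongside
#' but do not drive the flag.
#'
#' @param hubs Hub tibble from [detect_hubs()].
#' @param tf_targets Character vector of TF target gene ids (subset of the
#'   universe).
#' @param gene_universe Character vector of all genes considered.
#' @param alpha Enrichment threshold on the raw p value.
#' @return Tibble `hub_id`, `n_hub`, `n_hub_targets`, `p_value`, `p_adj`,
#'   `enriched`.
#' @export
hub_enrichment <- function(hubs, tf_targets, gene_universe, alpha = 0.05) {
  if (!length(gene_universe)) stop("empty gene universe", call. = FALSE)
  tf_targets <- intersect(tf_targets, gene_universe)
  res <- purrr::map2_dfr(hubs$hub_id, hubs$connecting_genes, function(id, cg) {
    hub_genes <- intersect(unique(cg), gene_universe)
    k <- sum(hub_genes %in% tf_targets)
    tab <- matrix(c(k, length(hub_genes) - k,
                    length(tf_targets) - k,
                    length(gene_universe) - length(hub_genes) -
                      length(tf_targets) + k), nrow = 2)
    p <- fisher.test(tab, alternative = "greater")$p.value
    tibble(hub_id = id, n_hub = length(hub_genes), n_hub_targets = k,
           p_value = p)
  })
  res$p_adj <- p.adjust(res$p_value, method = "BH")
  res$enriched <- res$p_value < alpha
  res
}

#' Randomised hub control for TF-target enrichment
#'
#' For each round, a size-matched random gene set is drawn without
#' replacement from the anchor-gene pool for every observed hub, screened
#' for enrichment at `alpha`, and the TF targets inside enriched random
#' hubs are counted — the control distribution against which the observed
#' in-hub target count is compared.
#'
#' @inheritParams hub_enrichment
#' @param anchor_gene_pool Character vector to sample from (all anchor
#'   genes).
#' @param n_rounds Number of control rounds.
#' @param seed Integer seed.
#' @return List with `observed_count` (targets in enriched observed hubs),
#'   `control_counts` (length `n_rounds`).
#' @export
random_hub_control <- function(hubs, anchor_gene_pool, tf_targets,
                               gene_universe, n_rounds = 100, alpha = 0.05,
                               seed = 1L) {
  if (n_rounds < 1) stop("n_rounds must be >= 1", call. = FALSE)
  sizes <- lengths(hubs$connecting_genes)
  if (length(sizes) && max(sizes) > length(anchor_gene_pool)) {
    stop("anchor gene pool smaller than the largest hub", call. = FALSE)
  }
  obs <- hub_enrichment(hubs, tf_targets, gene_universe, alpha)
  observed_count <- sum(obs$n_hub_targets[obs$enriched])
  set.seed(seed)
  control_counts <- vapply(seq_len(n_rounds), function(r) {
    cnt <- 0L
    for (s in sizes) {
      hub_genes <- sample(anchor_gene_pool, s)
      k <- sum(hub_genes %in% tf_targets)
      tab <- matrix(c(k, s - k, length(tf_targets) - k,
                      length(gene_universe) - s - length(tf_targets) + k),
                    nrow = 2)
      if (fisher.test(tab, alternative = "greater")$p.value < alpha) {
        cnt <- cnt + k
      }
    }
    cnt
  }, integer(1))
  list(observed_count = observed_count, control_counts = control_counts)
}

#' Classify hub change between two conditions
#'
#' Given the connecting-gene counts in condition 1 (`Nc`) and condition 2
#' (`Nm`), with `Ns = Nc - Nm`:
#' \itemize{
#'   \item EDH (entirely disassembled): `Ns/Nc >= 0.7` and `Ns >= 3`;
#'   \item PDH (partially disassembled): `0.3 <= Ns/Nc < 0.7` and `Ns >= 3`;
#'   \item FH (newly formed / markedly grown): `-Ns/Nm >= 0.3` and
#'     `Nc - Nm <= -3`;
#'   \item stable otherwise.
#' }
#' Conditions within each rule are conjunctions, evaluated in the order
#' EDH, PDH, FH.
#'
#' @param Nc,Nm Nonnegative integer vectors (recycled), not both zero.
#' @return Character vector of categories.
#' @export
classify_hub_change <- function(Nc, Nm) {
  n <- max(length(Nc), length(Nm))
  Nc <- rep_len(Nc, n); Nm <- rep_len(Nm, n)
  if (any(Nc < 0 | Nm < 0)) stop("Nc and Nm must be nonnegative", call. = FALSE)
  if (any(Nc == 0 & Nm == 0)) {
    stop("hub change undefined for Nc = Nm = 0", call. = FALSE)
  }
  Ns <- Nc - Nm
  r_c <- ifelse(Nc > 0, Ns / Nc, -Inf)   # loss ratio needs Nc > 0
  r_m <- ifelse(Nm > 0, -Ns / Nm, -Inf)  # gain ratio needs Nm > 0
  dplyr::case_when(
    r_c >= 0.7 & Ns >= 3 ~ "EDH",
    r_c >= 0.3 & r_c < 0.7 & Ns >= 3 ~ "PDH",
    r_m >= 0.3 & (Nc - Nm) <= -3 ~ "FH",
    TRUE ~ "stable"
  )
}

#' Compare hubs between two conditions
#'
#' Hubs sharing the same node gene are the same hub; hubs lacking a node
#' gene are matched by reciprocal node-anchor overlap as a fallback.
#' Unmatched hubs enter with `Nm = 0` (condition 1 only) or `Nc = 0`
#' (condition 2 only). For each disassembled (EDH/PDH) hub the condition-1
#' connecting genes are partitioned into aggregated (kept in condition 2)
#' and separated (lost).
#'
#' @param hubs_1,hubs_2 Hub tibbles from [detect_hubs()] for the two
#'   conditions.
#' @return Tibble `node_gene`, `Nc`, `Nm`, `Ns`, `category`, list-columns
#'   `aggregated`, `separated`, plus `matched_by` (`"node_gene"` or
#'   `"anchor_overlap"`).
#' @export
compare_conditions <- function(hubs_1, hubs_2) {
  collapse_dups <- function(h, cond) {
    keyed <- h[!is.na(h$node_gene), ]
    if (anyDuplicated(keyed$node_gene)) {
      warning("duplicate node genes within condition ", cond,
              "; merging their connecting sets", call. = FALSE)
      keyed <- keyed %>%
        dplyr::group_by(node_gene = .data$node_gene) %>%
        dplyr::summarise(
          connecting_genes = list(sort(unique(unlist(.data$connecting_genes)))),
          chrom = dplyr::first(.data$chrom),
          start = min(.data$start), end = max(.data$end), .groups = "drop")
    }
    keyed
  }
  h1 <- collapse_dups(hubs_1, 1L)
  h2 <- collapse_dups(hubs_2, 2L)
  all_nodes <- union(h1$node_gene, h2$node_gene)
  i1 <- match(all_nodes, h1$node_gene)
  i2 <- match(all_nodes, h2$node_gene)
  g1 <- purrr::map(i1, function(i) if (is.na(i)) character() else h1$connecting_genes[[i]])
  g2 <- purrr::map(i2, function(i) if (is.na(i)) character() else h2$connecting_genes[[i]])
  out <- tibble(node_gene = all_nodes,
                Nc = lengths(g1), Nm = lengths(g2),
                matched_by = "node_gene")

  # fallback: gene-less hubs matched by reciprocal node-anchor overlap
  a1 <- hubs_1[is.na(hubs_1$node_gene), ]
  a2 <- hubs_2[is.na(hubs_2$node_gene), ]
  if (nrow(a1) || nrow(a2)) {
    hits <- overlap_pairs(a1, a2)
    used2 <- hits$b_idx
    extra <- dplyr::bind_rows(
      purrr::map_dfr(seq_len(nrow(a1)), function(i) {
        j <- hits$b_idx[hits$a_idx == i][1]
        cg2 <- if (is.na(j)) character() else a2$connecting_genes[[j]]
        tibble(node_gene = paste0("node@", a1$chrom[i], ":", a1$start[i]),
               Nc = length(a1$connecting_genes[[i]]), Nm = length(cg2),
               matched_by = "anchor_overlap",
               g1 = list(a1$connecting_genes[[i]]), g2 = list(cg2))
      }),
      purrr::map_dfr(setdiff(seq_len(nrow(a2)), used2), function(j) {
        tibble(node_gene = paste0("node@", a2$chrom[j], ":", a2$start[j]),
               Nc = 0L, Nm = length(a2$connecting_genes[[j]]),
               matched_by = "anchor_overlap",
               g1 = list(character()), g2 = list(a2$connecting_genes[[j]]))
      })
    )
    if (nrow(extra)) {
      g1 <- c(g1, extra$g1); g2 <- c(g2, extra$g2)
      out <- dplyr::bind_rows(out, extra[, c("node_gene", "Nc", "Nm", "matched_by")])
    }
  }

  keep <- !(out$Nc == 0 & out$Nm == 0)
  out <- out[keep, ]; g1 <- g1[keep]; g2 <- g2[keep]
  out$Ns <- out$Nc - out$Nm
  out$category <- classify_hub_change(out$Nc, out$Nm)
  out$aggregated <- purrr::map2(g1, g2, intersect)
  out$separated <- purrr::map2(g1, g2, setdiff)
  dplyr::relocate(out, "node_gene", "Nc", "Nm", "Ns", "category")
}
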