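# Accessible-region (CRE) annotation: genomic class (PRE / DRE /
# intragenic), chromatin state (active / poised / poiAct) and interaction
# status (anchor / basal), plus nearest and long-range target genes and the
# expression-comparison groups built from them.
#
# PREs sit in promoters (1 kb upstream to 0.5 kb downstream of a TSS), DREs
# in intergenic space, and the gene body from 0.5 kb downstream of the TSS
# to the TTS is intragenic. Poised elements are flanked by H3K27me3 only;
# poiAct (bivalent) PREs carry H3K27me3 together with active marks.

# gene-body space: 0.5 kb downstream of the TSS through the TTS
gene_bodies_of <- function(genes, downstream = 500L) {
  g <- tss_of(genes)
  plus <- g$strand == "+"
  start <- ifelse(plus, g$tss + downstream, g$start)
  end <- ifelse(plus, g$end, g$tss - downstream + 1L)
  keep <- start < end
  tibble(gene_id = g$gene_id[keep], chrom = g$chrom[keep],
         start = as.integer(start[keep]), end = as.integer(end[keep]))
}

# bp of each query interval covered by the union of subject intervals
covered_bp <- function(query, subject) {
  out <- rep(0L, nrow(query))
  if (!nrow(query) || !nrow(subject)) return(out)
  red <- GenomicRanges::reduce(as_granges(subject))
  ov <- GenomicRanges::findOverlaps(as_granges(query), red)
  if (!length(ov)) return(out)
  w <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(as_granges(query)[S4Vectors::queryHits(ov)]),
    IRanges::ranges(red[S4Vectors::subjectHits(ov)])))
  agg <- tapply(w, S4Vectors::queryHits(ov), sum)
  out[as.integer(names(agg))] <- as.integer(agg)
  out
}

#' Genomic classification of accessible regions
#'
#' Each CRE is classified as `PRE` (promoter), `DRE` (intergenic) or
#' `intragenic` (gene body). A category qualifies when at least `min_frac`
#' (default 50%) of the CRE's length overlaps that category's space; among
#' qualifying categories the priority PRE > DRE > intragenic decides. When
#' no category reaches the threshold, the maximal overlap decides (ties by
#' the same priority) and the row is flagged `sub_threshold`.
#'
#' @param cres Tibble with `chrom`, `start`, `end` (accessible regions).
#' @param genes Gene tibble.
#' @param min_frac Qualification threshold on the CRE-length fraction.
#' @param chrom_sizes Optional chromosome sizes.
#' @return `cres` with `cre_id`, `genomic_class`, `frac_pre`, `frac_dre`,
#'   `frac_intragenic`, `sub_threshold`.
#' @export
classify_cre_genomic <- function(cres, genes, min_frac = 0.5,
                                 chrom_sizes = NULL) {
  validate_intervals(cres, "CREs", chrom_sizes)
  cres <- dplyr::mutate(cres, cre_id = sprintf("cre_%05d", dplyr::row_number()))
  width <- cres$end - cres$start
  proms <- promoters_of(genes, chrom_sizes = chrom_sizes)
  regions <- gene_regions_of(genes, chrom_sizes = chrom_sizes)
  bodies <- gene_bodies_of(genes)
  frac_pre <- covered_bp(cres, proms) / width
  frac_intra <- covered_bp(cres, bodies) / width
  # intergenic space is the complement of the gene regions
  frac_dre <- 1 - covered_bp(cres, regions) / width
  fr <- cbind(PRE = frac_pre, DRE = frac_dre, intragenic = frac_intra)
  pick <- apply(fr, 1, function(f) {
    qual <- which(f >= min_frac)
    if (length(qual)) colnames(fr)[qual[1]]          # columns are in priority order
    else colnames(fr)[which(f == max(f))[1]]
  })
  dplyr::mutate(cres,
                genomic_class = unname(pick),
                frac_pre = frac_pre, frac_dre = frac_dre,
                frac_intragenic = frac_intra,
                sub_threshold = apply(fr, 1, max) < min_frac)
}

#' Chromatin state and interaction status of PREs and DREs
#'
#' Implements the rule-based decision tree on top of precomputed
#' anchor/basal peak and gene statuses.
#'
#' DRE branch: the peaks within `near_bp` (default 500 bp, edge-to-edge) are
#' inspected; when they are H3K27me3-only the DRE is poised, anchor or basal
#' following the peaks' status; otherwise the DRE is active, anchor when its
#' nearest protein-coding gene is an anchor gene and basal otherwise.
#'
#' PRE branch: overlapping an H3K27me3 anchor peak only makes a poised
#' anchor PRE; overlapping H3K27me3 and an active-mark anchor peak
#' simultaneously makes a poiAct (bivalent) anchor PRE; a PRE whose linked
#' gene (the gene whose promoter it overlaps) is basal is a basal PRE with
#' its state read from the overlapping marks; the remainder are active
#' anchor PREs.
#'
#' Intragenic CREs are carried through with `NA` state and status.
#'
#' @param cres_classified Output of [classify_cre_genomic()].
#' @param peaks_status Output of [classify_anchor_peaks()] covering all
#'   marks.
#' @param gene_status Output of [classify_anchor_genes()].
#' @param genes Gene tibble.
#' @param near_bp Edge-to-edge proximity for the DRE rule.
#' @param active_marks Marks counted as active.
#' @param chrom_sizes Optional chromosome sizes.
#' @return Input tibble with added `state`, `interaction_status`,
#'   `nearest_gene`, `nearest_distance`.
#' @export
classify_cre_state <- function(cres_classified, peaks_status, gene_status,
                               genes, near_bp = 500L,
                               active_marks = ACTIVE_MARKS,
                               chrom_sizes = NULL) {
  cres <- cres_classified
  g <- tss_of(genes)
  status_of_gene <- setNames(gene_status$status, gene_status$gene_id)

  # nearest protein-coding gene by |CRE midpoint - TSS| (ties: lower gene id)
  mid <- (cres$start + cres$end) / 2
  nearest <- purrr::map_dfr(seq_len(nrow(cres)), function(i) {
    on_chrom <- g[g$chrom == cres$chrom[i], ]
    if (!nrow(on_chrom)) {
      return(tibble(nearest_gene = NA_character_, nearest_distance = NA_real_))
    }
    d <- abs(on_chrom$tss - mid[i])
    best <- which(d == min(d))
    best <- best[order(on_chrom$gene_id[best])][1]
    tibble(nearest_gene = on_chrom$gene_id[best], nearest_distance = d[best])
  })
  cres <- dplyr::bind_cols(cres, nearest)

  # linked gene for the PRE branch: the gene whose promoter overlaps the
  # PRE (maximal overlap wins); falls back to the nearest gene
  proms <- promoters_of(genes, chrom_sizes = chrom_sizes)
  ph <- overlap_pairs(cres, proms)
  linked_gene <- cres$nearest_gene
  if (nrow(ph)) {
    ph$ov <- overlap_bp(cres[ph$a_idx, ], proms[ph$b_idx, ])
    best <- ph %>% dplyr::arrange(.data$a_idx, dplyr::desc(.data$ov)) %>%
      dplyr::distinct(.data$a_idx, .keep_all = TRUE)
    linked_gene[best$a_idx] <- proms$gene_id[best$b_idx]
  }

  # peak context: overlaps (>= 1 bp) and proximity (< near_bp edge-to-edge)
  ov <- overlap_pairs(cres, peaks_status)
  grc <- as_granges(cres); grp <- as_granges(peaks_status)
  near_hits <- GenomicRanges::findOverlaps(grc, grp, maxgap = near_bp - 1L)
  near <- tibble(a_idx = S4Vectors::queryHits(near_hits),
                 b_idx = S4Vectors::subjectHits(near_hits))

  peak_ctx <- function(idx, hits) {
    rows <- hits$b_idx[hits$a_idx == idx]
    peaks_status[rows, c("mark", "status")]
  }

  n <- nrow(cres)
  state <- rep(NA_character_, n)
  istatus <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    cls <- cres$genomic_class[i]
    if (cls == "intragenic") next
    if (cls == "DRE") {
      px <- peak_ctx(i, near)
      k27_only <- nrow(px) > 0 && all(px$mark == "H3K27me3")
      if (k27_only) {
        state[i] <- "poised"
        istatus[i] <- if (any(px$status == "anchor")) "anchor" else "basal"
      } else {
        state[i] <- "active"
        ng <- cres$nearest_gene[i]
        istatus[i] <- if (!is.na(ng) &&
                          identical(unname(status_of_gene[ng]), "anchor"))
          "anchor" else "basal"
      }
    } else { # PRE
      px <- peak_ctx(i, ov)
      k27_anchor <- any(px$mark == "H3K27me3" & px$status == "anchor")
      act_anchor <- any(px$mark %in% active_marks & px$status == "anchor")
      linked <- linked_gene[i]
      linked_basal <- !is.na(linked) &&
        identical(unname(status_of_gene[linked]), "basal")
      if (k27_anchor && !act_anchor) {
        state[i] <- "poised"; istatus[i] <- "anchor"
      } else if (k27_anchor && act_anchor) {
        state[i] <- "poiAct"; istatus[i] <- "anchor"
      } else if (linked_basal) {
        state[i] <- if (any(px$mark == "H3K27me3")) "poised" else "active"
        istatus[i] <- "basal"
      } else {
        state[i] <- "active"; istatus[i] <- "anchor"
      }
    }
  }
  dplyr::mutate(cres, state = state, interaction_status = istatus)
}

#' Link CREs to their target genes through loops
#'
#' The long-range connecting genes of a CRE are the anchor genes at the far
#' anchors of every loop whose near anchor overlaps the CRE (by at least
#' 1 bp), excluding the nearest gene. Basal CREs get an empty connecting
#' set. Single- versus multi-loop participation is recorded.
#'
#' @param cres_annotated Output of [classify_cre_state()].
#' @param loops Loop tibble.
#' @param genes Gene tibble.
#' @param expr Optional expression tibble for the anchor-gene rule.
#' @return Input with list-column `connecting_genes` and integer `n_loops`.
#' @export
link_cre_targets <- function(cres_annotated, loops, genes, expr = NULL) {
  cres <- cres_annotated
  anchors <- loops_to_anchors(loops)
  anchor_gene <- assign_anchor_genes(anchors, genes, expr,
                                     mark_category = "active")
  hits <- overlap_pairs(cres, anchors)
  connecting <- vector("list", nrow(cres))
  n_loops <- integer(nrow(cres))
  for (i in seq_len(nrow(cres))) {
    rows <- hits$b_idx[hits$a_idx == i]
    if (!length(rows) ||
        identical(cres$interaction_status[i], "basal")) {
      connecting[[i]] <- character()
      next
    }
    ids <- anchors$loop_id[rows]
    n_loops[i] <- length(unique(ids))
    far <- anchors$loop_id %in% ids &
      !(seq_len(nrow(anchors)) %in% rows)
    cg <- sort(unique(unlist(anchor_gene[far])))
    connecting[[i]] <- setdiff(cg, cres$nearest_gene[i])
  }
  dplyr::mutate(cres, connecting_genes = connecting, n_loops = n_loops)
}

#' Full CRE annotation
#'
#' Convenience wrapper running [classify_cre_genomic()],
#' [classify_cre_state()] and [link_cre_targets()] in order.
#'
#' @inheritParams classify_cre_genomic
#' @inheritParams classify_cre_state
#' @inheritParams link_cre_targets
#' @return One row per CRE with all annotation fields.
#' @export
annotate_cres <- function(cres, genes, peaks_status, gene_status, loops,
                          expr = NULL, min_frac = 0.5, near_bp = 500L,
                          active_marks = ACTIVE_MARKS, chrom_sizes = NULL) {
  cres %>%
    classify_cre_genomic(genes, min_frac = min_frac,
                         chrom_sizes = chrom_sizes) %>%
    classify_cre_state(peaks_status, gene_status, genes, near_bp = near_bp,
                       active_marks = active_marks,
                       chrom_sizes = chrom_sizes) %>%
    link_cre_targets(loops, genes, expr)
}

#' Expression-comparison gene groups from CRE annotations
#'
#' Emits the gene groups compared by rank-sum tests: per CRE class and
#' state, the nearest genes of basal CREs (`nearest_basal`), the nearest
#' genes of anchor CREs (`nearest_anchor`), the long-range connecting genes
#' (`connecting`, with `connecting_single`/`connecting_multi` strata by
#' loop participation), plus a `without_cre` control per class (genes never
#' nearest to, nor connected by, a CRE of that class). Groups are not
#' exclusive: a gene connected to CREs of two states appears in both.
#'
#' @param annotations Output of [link_cre_targets()] / [annotate_cres()].
#' @param genes Gene tibble (universe for the controls).
#' @return Tibble `group`, `genomic_class`, `state`, `gene_id`.
#' @export
build_expression_categories <- function(annotations, genes) {
  ann <- annotations[annotations$genomic_class %in% c("PRE", "DRE") &
                       !is.na(annotations$state), ]
  rows <- list()
  add <- function(group, class, state, ids) {
    ids <- unique(ids[!is.na(ids)])
    if (!length(ids)) {
      warning(sprintf("empty group: %s %s %s", class, state, group),
              call. = FALSE)
      return()
    }
    rows[[length(rows) + 1L]] <<- tibble(group = group, genomic_class = class,
                                         state = state, gene_id = ids)
  }
  for (cls in unique(ann$genomic_class)) {
    sub_c <- ann[ann$genomic_class == cls, ]
    for (st in unique(sub_c$state)) {
      sub <- sub_c[sub_c$state == st, ]
      add("nearest_basal", cls, st,
          sub$nearest_gene[sub$interaction_status == "basal"])
      add("nearest_anchor", cls, st,
          sub$nearest_gene[sub$interaction_status == "anchor"])
      conn <- unlist(sub$connecting_genes)
      add("connecting", cls, st, conn)
      add("connecting_single", cls, st,
          unlist(sub$connecting_genes[sub$n_loops == 1]))
      add("connecting_multi", cls, st,
          unlist(sub$connecting_genes[sub$n_loops > 1]))
    }
    touched <- unique(c(sub_c$nearest_gene, unlist(sub_c$connecting_genes)))
    add("without_cre", cls, "any", setdiff(genes$gene_id, touched))
  }
  dplyr::bind_rows(rows)
}
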