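# Anchor/basal classification and loop categorisation. An "anchor" peak is a
# ChIP-seq peak that participates in at least one chromatin loop of its mark;
# everything else is "basal". Genes inherit anchor status from the peaks that
# overlap their association window.

ACTIVE_MARKS <- c("H3K4me3", "RNAPII", "H3K4me1")

# Long form: one row per loop anchor, with side "a"/"b".
loops_to_anchors <- function(loops) {
  dplyr::bind_rows(
    tibble(loop_id = loops$loop_id, side = "a", chrom = loops$chrom_a,
           start = loops$start_a, end = loops$end_a, mark = loops$mark),
    tibble(loop_id = loops$loop_id, side = "b", chrom = loops$chrom_b,
           start = loops$start_b, end = loops$end_b, mark = loops$mark)
  )
}

#' Classify peaks as anchor or basal
#'
#' A peak is an anchor when it overlaps (by at least `min_bp` bp, default 1)
#' any loop anchor — of the same mark when `same_mark_only` is set. The
#' anchor/basal partition is exhaustive and disjoint.
#'
#' @param peaks Peak tibble (see [read_bed()]).
#' @param loops Loop tibble (see [read_bedpe()]).
#' @param same_mark_only Only loops of the peak's own mark can confer anchor
#'   status (default `TRUE`).
#' @param min_bp Minimal peak/anchor overlap in bp.
#' @return `peaks` with added columns `status` (`"anchor"`/`"basal"`),
#'   `n_supporting` and list-column `supporting_loops` (loop ids).
#' @export
classify_anchor_peaks <- function(peaks, loops, same_mark_only = TRUE,
                                  min_bp = 1L) {
  if (same_mark_only && nrow(peaks) && nrow(loops) &&
      !length(intersect(unique(peaks$mark), unique(loops$mark)))) {
    stop("no shared marks between peaks and loops under same_mark_only",
         call. = FALSE)
  }
  anchors <- loops_to_anchors(loops)
  hits <- overlap_pairs(peaks, anchors, min_bp = min_bp)
  if (same_mark_only && nrow(hits)) {
    hits <- hits[peaks$mark[hits$a_idx] == anchors$mark[hits$b_idx], ]
  }
  support <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) support[[i]] <- character()
  if (nrow(hits)) {
    by_peak <- split(anchors$loop_id[hits$b_idx], hits$a_idx)
    for (k in names(by_peak)) support[[as.integer(k)]] <- sort(unique(by_peak[[k]]))
  }
  dplyr::mutate(peaks,
                n_supporting = lengths(support),
                status = ifelse(.data$n_supporting > 0, "anchor", "basal"),
                supporting_loops = support)
}

#' Classify genes as anchor or basal
#'
#' A gene is an anchor gene when an anchor peak overlaps its association
#' window (default: 1 kb upstream of the TSS through the TTS); basal when
#' only basal peaks do (anchor dominates when both are present). Genes
#' touched by no peak carry no status and are dropped.
#'
#' @param genes Gene tibble.
#' @param peaks_status Output of [classify_anchor_peaks()].
#' @param upstream Association-window extension upstream of the TSS (bp).
#' @param min_bp Minimal overlap in bp.
#' @param chrom_sizes Optional chromosome sizes for window clipping.
#' @return Tibble `gene_id`, `status` for marked genes only.
#' @export
classify_anchor_genes <- function(genes, peaks_status, upstream = 1000L,
                                  min_bp = 1L, chrom_sizes = NULL) {
  regions <- gene_regions_of(genes, upstream = upstream,
                             chrom_sizes = chrom_sizes)
  hits <- overlap_pairs(regions, peaks_status, min_bp = min_bp)
  if (!nrow(hits)) return(tibble(gene_id = character(), status = character()))
  tibble(gene_id = regions$gene_id[hits$a_idx],
         peak_status = peaks_status$status[hits$b_idx]) %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(status = if (any(.data$peak_status == "anchor"))
      "anchor" else "basal", .groups = "drop")
}

#' Categorise loops by anchor composition and span
#'
#' Each anchor is labelled `promoter` when it overlaps any promoter window
#' (1 kb upstream to 0.5 kb downstream of a TSS), else `intergenic` when it
#' reaches outside the union of gene regions (1 kb upstream of TSS through
#' TTS), else `genic`. Loop categories: `PP`, `PI`, `II`; any pair involving
#' a genic anchor is `other`. Span is measured midpoint-to-midpoint and
#' classed as `lt1Mb` (< 1 Mb), `1to10Mb` (1 Mb to 10 Mb inclusive),
#' `gt10Mb` (> 10 Mb) or `inter` for interchromosomal loops.
#'
#' @param loops Loop tibble.
#' @param genes Gene tibble.
#' @param chrom_sizes Optional chromosome sizes.
#' @return `loops` with added `label_a`, `label_b`, `category`, `span_bp`,
#'   `span_class`.
#' @export
categorize_loops <- function(loops, genes, chrom_sizes = NULL) {
  anchors <- loops_to_anchors(loops)
  proms <- promoters_of(genes, chrom_sizes = chrom_sizes)
  regions <- gene_regions_of(genes, chrom_sizes = chrom_sizes)
  is_prom <- rep(FALSE, nrow(anchors))
  hitp <- overlap_pairs(anchors, proms)
  is_prom[unique(hitp$a_idx)] <- TRUE
  # an anchor touches intergenic space iff the union of gene regions does not
  # cover it entirely
  covered <- rep(0L, nrow(anchors))
  if (nrow(anchors) && nrow(regions)) {
    red <- GenomicRanges::reduce(as_granges(regions))
    ov <- GenomicRanges::findOverlaps(as_granges(anchors), red)
    if (length(ov)) {
      qa <- as_granges(anchors)[S4Vectors::queryHits(ov)]
      sa <- red[S4Vectors::subjectHits(ov)]
      w <- IRanges::width(IRanges::pintersect(IRanges::ranges(qa),
                                              IRanges::ranges(sa)))
      covered <- as.integer(tapply(w, factor(S4Vectors::queryHits(ov),
                                             levels = seq_len(nrow(anchors))),
                                   sum, default = 0L))
      covered[is.na(covered)] <- 0L
    }
  }
  touches_intergenic <- covered < (anchors$end - anchors$start)
  anchors$label <- dplyr::case_when(is_prom ~ "promoter",
                                    touches_intergenic ~ "intergenic",
                                    TRUE ~ "genic")
  lab <- tidyr::pivot_wider(anchors[, c("loop_id", "side", "label")],
                            names_from = "side", values_from = "label",
                            names_prefix = "label_")
  out <- dplyr::left_join(loops, lab, by = "loop_id")
  pair <- paste(pmin(out$label_a, out$label_b), pmax(out$label_a, out$label_b))
  out$category <- dplyr::case_when(
    pair == "promoter promoter" ~ "PP",
    pair == "intergenic promoter" ~ "PI",
    pair == "intergenic intergenic" ~ "II",
    TRUE ~ "other"
  )
  mid_a <- (out$start_a + out$end_a) / 2
  mid_b <- (out$start_b + out$end_b) / 2
  intra <- out$chrom_a == out$chrom_b
  out$span_bp <- ifelse(intra, abs(mid_b - mid_a), NA_real_)
  out$span_class <- dplyr::case_when(
    !intra ~ "inter",
    out$span_bp < 1e6 ~ "lt1Mb",
    out$span_bp <= 1e7 ~ "1to10Mb",
    TRUE ~ "gt10Mb"
  )
  out
}

#' Fraction of SNPs falling in loop anchors per mark group
#'
#' Loops are grouped as active (H3K4me3, RNAPII, H3K4me1), repressive
#' (H3K27me3) and inactive (H3K9me2). A SNP counts for a group when it lies
#' inside any loop anchor of that group (anchors, not the intervening span);
#' groups may overlap. The residual `not_involved` fraction collects SNPs in
#' no group's anchors.
#'
#' @param snps Tibble with `chrom`, `start`, `end` (1 bp intervals).
#' @param loops Loop tibble covering one or more marks.
#' @param groups Named list mapping group label to mark vector.
#' @return Tibble `group`, `n_snps`, `fraction` (of all SNPs), including the
#'   `not_involved` row.
#' @export
snps_in_loops <- function(snps, loops,
                          groups = list(active = ACTIVE_MARKS,
                                        repressive = "H3K27me3",
                                        inactive = "H3K9me2")) {
  anchors <- loops_to_anchors(loops)
  n <- nrow(snps)
  in_any <- rep(FALSE, n)
  rows <- purrr::imap(groups, function(marks, label) {
    sub <- anchors[anchors$mark %in% marks, ]
    hit <- rep(FALSE, n)
    hit[unique(overlap_pairs(snps, sub)$a_idx)] <- TRUE
    in_any <<- in_any | hit
    tibble(group = label, n_snps = sum(hit), fraction = sum(hit) / max(n, 1))
  })
  dplyr::bind_rows(dplyr::bind_rows(rows),
                   tibble(group = "not_involved", n_snps = sum(!in_any),
                          fraction = sum(!in_any) / max(n, 1)))
}
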