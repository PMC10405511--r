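# Seeded synthetic datasets with planted structure: a toy multi-chromosome
# genome with centromeric blocks, mark-specific peaks and loops with known
# promoter/intergenic composition and span laws, expression with planted
# anchor boost and pair co-expression, TF targets clustered into hubs, a
# second condition with planted hub disassembly, CREs with known states,
# and SNPs planted into loop anchors. Truth tables are first-class outputs
# so downstream tests never re-derive ground truth.

#' Simulation configuration
#'
#' Builds and validates the configuration driving all generators. Defaults
#' describe the toy study conditions: 2 chromosomes of 20 Mb with a central
#' 10% centromeric block, 2,000 genes, 43 tissues, 1,000 active + 300
#' H3K27me3 + 200 H3K9me2 loops whose promoter-promoter /
#' promoter-intergenic / intergenic-intergenic mix is >= 96% P-P for the
#' active mark and ~88% I-I for H3K9me2 (H3K9me2 spans log-normal with a
#' 105 kb median), a 2x anchor-gene expression boost, planted pair
#' co-expression of 0.5, and hub disassembly fractions (0.10, 0.20, 0.05)
#' for entirely / partially disassembled and newly-grown hubs.
#'
#' @param seed Integer master seed; component generators derive their own
#'   seeds from it by fixed offsets.
#' @param ... Overrides for any default listed above (see the returned
#'   list's names).
#' @return A validated list of class `chiahub_sim_config`.
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    n_chroms = 2L, chrom_length = 20e6, centromere_span = c(0.45, 0.55),
    n_genes = 2000L, gene_length_range = c(1000L, 3000L), min_gene_gap = 3000L,
    n_tissues = 43L,
    loop_counts = c(H3K4me3 = 1000L, H3K27me3 = 300L, H3K9me2 = 200L),
    category_mix = list(
      H3K4me3 = c(PP = 0.96, PI = 0.03, II = 0.01),
      H3K27me3 = c(PP = 0.40, PI = 0.30, II = 0.30),
      H3K9me2 = c(PP = 0.02, PI = 0.10, II = 0.88)),
    span_laws = list(
      H3K9me2 = c(meanlog = log(105e3), sdlog = 0.55),
      default = c(meanlog = log(5e4), sdlog = 0.8)),
    anchor_width = 400L, pet_range = c(3L, 10L),
    n_planted_pairs = 200L, planted_pair_pcc = 0.5,
    anchor_expression_boost = 2,
    expr_meanlog = log(5), expr_gene_sdlog = 1, expr_tissue_sdlog = 0.5,
    detection_threshold = 1,
    n_anchor_pool = 500L, n_basal_genes = 520L, n_k27_pool = 160L,
    n_k9_pool = 30L, n_bivalent = 24L, n_k27_basal = 60L,
    n_hubs = 20L, hub_size_range = c(8L, 12L),
    tf_configs = list(list(name = "MYC2", n_targets = 150L,
                           hub_concentration = 0.8)),
    hub_disassembly_fractions = c(f_EDH = 0.10, f_PDH = 0.20, f_FH = 0.05),
    separated_fc = 0.5,
    n_cres = 300L,
    cre_state_fractions = c(active = 0.80, poised = 0.13, poiAct = 0.07),
    n_snps = 100L,
    snp_fractions = c(active = 0.23, repressive = 0.11, inactive = 0.11),
    seed = as.integer(seed)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  counts <- c(cfg$n_chroms, cfg$n_genes, cfg$n_tissues, cfg$loop_counts,
              cfg$n_hubs, cfg$n_cres, cfg$n_snps)
  if (any(counts <= 0)) stop("all counts must be positive", call. = FALSE)
  for (mk in names(cfg$category_mix)) {
    if (abs(sum(cfg$category_mix[[mk]]) - 1) > 1e-9) {
      stop("category mix for ", mk, " does not sum to 1", call. = FALSE)
    }
  }
  f <- cfg$hub_disassembly_fractions
  if (any(f < 0) || sum(f) > 1) {
    stop("hub disassembly fractions must be in [0,1] and sum to <= 1",
         call. = FALSE)
  }
  if (cfg$planted_pair_pcc <= -1 || cfg$planted_pair_pcc >= 1) {
    stop("planted_pair_pcc must lie in (-1, 1)", call. = FALSE)
  }
  structure(cfg, class = "chiahub_sim_config")
}

# log-scale correlation that yields the target Pearson correlation after
# exponentiation of equal-variance log-normals:
#   cor(e^X, e^Y) = (e^{rho s^2} - 1) / (e^{s^2} - 1)
lognormal_rho <- function(target, sigma) {
  if (target == 0) return(0)
  arg <- 1 + target * expm1(sigma^2)
  if (arg <= 0) stop("target correlation unattainable at this sigma", call. = FALSE)
  log(arg) / sigma^2
}

#' Generate the toy genome
#'
#' Places non-overlapping genes on the chromosome arms (outside the
#' centromeric block), with uniform random strand, deterministically under
#' the config seed.
#'
#' @param config A [sim_config()].
#' @return List with `chrom_sizes` and `genes` tibbles.
#' @export
generate_genome <- function(config) {
  set.seed(config$seed + 1L)
  chrom_sizes <- tibble(chrom = paste0("chr", seq_len(config$n_chroms)),
                        length = as.integer(config$chrom_length))
  per_chrom <- rep(config$n_genes %/% config$n_chroms, config$n_chroms)
  per_chrom[seq_len(config$n_genes %% config$n_chroms)] <-
    per_chrom[seq_len(config$n_genes %% config$n_chroms)] + 1L
  cen <- round(config$centromere_span * config$chrom_length)
  arms <- list(c(0, cen[1]), c(cen[2], config$chrom_length))
  gid <- 0L
  genes <- purrr::map_dfr(seq_len(config$n_chroms), function(ci) {
    n <- per_chrom[ci]
    arm_len <- vapply(arms, function(a) a[2] - a[1], numeric(1))
    n_arm <- round(n * arm_len / sum(arm_len))
    n_arm[1] <- n - n_arm[2]
    purrr::map_dfr(1:2, function(ai) {
      na <- n_arm[ai]
      if (na == 0) return(NULL)
      lens <- sample(seq(config$gene_length_range[1],
                         config$gene_length_range[2]), na, replace = TRUE)
      need <- sum(lens) + (na + 1L) * config$min_gene_gap
      space <- arms[[ai]][2] - arms[[ai]][1]
      if (need > space) {
        stop("infeasible gene density: ", na, " genes need ", need,
             " bp but arm has ", space, call. = FALSE)
      }
      u <- runif(na + 1L)
      extra <- floor((space - need) * u / sum(u))
      gaps <- config$min_gene_gap + extra
      starts <- arms[[ai]][1] + cumsum(gaps[seq_len(na)]) +
        c(0L, cumsum(lens))[seq_len(na)]
      ids <- sprintf("g%05d", gid + seq_len(na))
      gid <<- gid + na
      tibble(gene_id = ids, chrom = chrom_sizes$chrom[ci],
             start = as.integer(starts), end = as.integer(starts + lens),
             strand = sample(c("+", "-"), na, replace = TRUE),
             biotype = "protein_coding")
    })
  })
  list(chrom_sizes = chrom_sizes, genes = genes)
}

# intergenic gaps on the arms (outside gene regions and the centromere)
arm_gaps <- function(genes, chrom_sizes, centromere_span, min_width = 2000L) {
  regions <- gene_regions_of(genes)
  purrr::map_dfr(seq_len(nrow(chrom_sizes)), function(ci) {
    chrom <- chrom_sizes$chrom[ci]
    len <- chrom_sizes$length[ci]
    cen <- round(centromere_span * len)
    occ <- regions[regions$chrom == chrom, ]
    occ <- dplyr::bind_rows(occ[, c("start", "end")],
                            tibble(start = cen[1], end = cen[2]))
    occ <- occ[order(occ$start), ]
    gap_start <- c(0L, occ$end)
    gap_end <- c(occ$start, len)
    keep <- gap_end - gap_start >= min_width
    tibble(chrom = chrom, start = as.integer(gap_start[keep]),
           end = as.integer(gap_end[keep]))
  })
}

#' Generate peaks and loops with planted structure
#'
#' Active-mark loops connect promoter anchors with the configured category
#' mix (planted co-expression pairs and hub loops fill part of the P-P
#' quota); H3K9me2 intergenic-intergenic loops live in the centromeric
#' block with log-normal spans (105 kb median by default); H3K27me3 loops
#' span all three categories. Anchor peaks are the loop anchors; basal
#' peaks are placed at the promoters of a dedicated basal gene set (and in
#' intergenic space), so the anchor/basal partition is known exactly.
#'
#' @param config A [sim_config()].
#' @param genome Output of [generate_genome()].
#' @return List with `peaks`, `loops`, `tf_targets` and a `truth` list
#'   (`loop_categories`, `gene_status`, `pairs`, `hubs`, `pools`).
#' @export
generate_peaks_and_loops <- function(config, genome) {
  set.seed(config$seed + 2L)
  genes <- genome$genes
  chrom_sizes <- genome$chrom_sizes
  proms <- promoters_of(genes, chrom_sizes = chrom_sizes)
  prom_of <- function(ids) proms[match(ids, proms$gene_id), ]
  gaps <- arm_gaps(genes, chrom_sizes, config$centromere_span)

  # per-chromosome pools of unused genes
  pool <- lapply(split(genes$gene_id, genes$chrom), sample)
  take <- function(chrom, k) {
    avail <- pool[[chrom]]
    if (length(avail) < k) stop("gene pool exhausted on ", chrom, call. = FALSE)
    out <- avail[seq_len(k)]
    pool[[chrom]] <<- avail[-seq_len(k)]
    out
  }
  chrom_cycle <- function(i) chrom_sizes$chrom[(i - 1L) %% nrow(chrom_sizes) + 1L]

  rand_pet <- function(n) sample(seq(config$pet_range[1], config$pet_range[2]),
                                 n, replace = TRUE)
  loop_row <- function(a, b, mark) {
    tibble(chrom_a = a$chrom, start_a = a$start, end_a = a$end,
           chrom_b = b$chrom, start_b = b$start, end_b = b$end,
           mark = mark, pet_count = rand_pet(nrow(a)),
           fdr = round(runif(nrow(a), 0, 0.04), 4))
  }
  intergenic_anchor <- function(chrom, n = 1L) {
    g <- gaps[gaps$chrom == chrom, ]
    gi <- sample.int(nrow(g), n, replace = TRUE, prob = g$end - g$start)
    start <- as.integer(g$start[gi] +
                          floor(runif(n) * (g$end[gi] - g$start[gi] -
                                              config$anchor_width)))
    tibble(chrom = chrom, start = start,
           end = start + config$anchor_width)
  }

  # ---- hubs (H3K4me3 P-P loops sharing a node promoter) ----
  hub_rows <- list()
  truth_hubs <- list()
  for (h in seq_len(config$n_hubs)) {
    chrom <- chrom_cycle(h)
    size <- sample(seq(config$hub_size_range[1], config$hub_size_range[2]), 1L)
    ids <- take(chrom, size + 1L)
    node <- ids[1]; conn <- ids[-1]
    hub_rows[[h]] <- loop_row(prom_of(rep(node, size)), prom_of(conn), "H3K4me3")
    truth_hubs[[h]] <- tibble(hub_id = sprintf("planted_hub_%03d", h),
                              node_gene = node, size = size,
                              connecting = list(sort(conn)))
  }
  hub_loops <- dplyr::bind_rows(hub_rows)
  truth_hubs <- dplyr::bind_rows(truth_hubs)

  # ---- planted co-expression pairs (disjoint genes, H3K4me3 P-P) ----
  pair_rows <- purrr::map(seq_len(config$n_planted_pairs), function(i) {
    chrom <- chrom_cycle(i)
    ids <- sort(take(chrom, 2L))
    loop_row(prom_of(ids[1]), prom_of(ids[2]), "H3K4me3") %>%
      dplyr::mutate(gene_a = ids[1], gene_b = ids[2])
  })
  pair_loops <- dplyr::bind_rows(pair_rows)
  truth_pairs <- pair_loops[, c("gene_a", "gene_b")]
  pair_loops <- dplyr::select(pair_loops, -"gene_a", -"gene_b")

  # ---- bivalent genes: P-P loops in both H3K4me3 and H3K27me3 ----
  n_biv <- config$n_bivalent
  biv <- character()
  biv_k4 <- biv_k27 <- NULL
  if (n_biv >= 2) {
    per <- rep(n_biv %/% config$n_chroms, config$n_chroms)
    per[seq_len(n_biv %% config$n_chroms)] <- per[seq_len(n_biv %% config$n_chroms)] + 1L
    per <- per + per %% 2L    # even count per chromosome so pairs stay intra
    biv <- unlist(purrr::map(seq_len(config$n_chroms),
                             function(ci) take(chrom_sizes$chrom[ci], per[ci])))
    pair_up <- function(ids) {
      m <- matrix(ids, ncol = 2, byrow = TRUE)
      list(a = m[, 1], b = m[, 2])
    }
    by_chrom <- split(biv, genes$chrom[match(biv, genes$gene_id)])
    mk_rows <- function(mark) dplyr::bind_rows(purrr::map(by_chrom, function(ids) {
      p <- pair_up(ids)
      loop_row(prom_of(p$a), prom_of(p$b), mark)
    }))
    biv_k4 <- mk_rows("H3K4me3")
    biv_k27 <- mk_rows("H3K27me3")
  }

  # ---- dedicated pools ----
  n_per <- function(total) {
    per <- rep(total %/% config$n_chroms, config$n_chroms)
    per[seq_len(total %% config$n_chroms)] <- per[seq_len(total %% config$n_chroms)] + 1L
    per
  }
  take_pool <- function(total) {
    per <- n_per(total)
    unlist(purrr::map(seq_len(config$n_chroms),
                      function(ci) take(chrom_sizes$chrom[ci], per[ci])))
  }
  anchor_pool <- take_pool(config$n_anchor_pool)
  basal_genes <- take_pool(config$n_basal_genes)
  k27_pool <- take_pool(config$n_k27_pool)
  k9_pool <- take_pool(config$n_k9_pool)

  pool_by_chrom <- function(ids) split(ids, genes$chrom[match(ids, genes$gene_id)])

  # sample n same-chromosome gene pairs from a pool, no duplicate pair
  sample_pairs <- function(ids, n) {
    byc <- pool_by_chrom(ids)
    byc <- byc[lengths(byc) >= 2]
    seen <- character()
    out <- vector("list", n)
    i <- 1L
    guard <- 0L
    while (i <= n) {
      guard <- guard + 1L
      if (guard > 50L * n) stop("cannot sample enough distinct pairs", call. = FALSE)
      ids_c <- byc[[sample.int(length(byc), 1L)]]
      p <- sort(sample(ids_c, 2L))
      key <- paste(p, collapse = "|")
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[i]] <- p
      i <- i + 1L
    }
    out
  }

  # ---- remaining loops per mark to satisfy the category mix ----
  build_mark_loops <- function(mark, n_total, already_pp, gene_pool,
                               intergenic_fun) {
    mix <- config$category_mix[[mark]]
    n_pp <- round(mix[["PP"]] * n_total)
    n_pi <- round(mix[["PI"]] * n_total)
    n_ii <- n_total - n_pp - n_pi
    n_pp_todo <- n_pp - already_pp
    if (n_pp_todo < 0) {
      stop("planted P-P loops for ", mark, " exceed the P-P quota", call. = FALSE)
    }
    rows <- list()
    if (n_pp_todo > 0) {
      pairs <- sample_pairs(gene_pool, n_pp_todo)
      rows$pp <- dplyr::bind_rows(purrr::map(pairs, function(p) {
        loop_row(prom_of(p[1]), prom_of(p[2]), mark)
      }))
    }
    if (n_pi > 0) {
      byc <- pool_by_chrom(gene_pool)
      rows$pi <- dplyr::bind_rows(purrr::map(seq_len(n_pi), function(i) {
        chrom <- chrom_cycle(i)
        gid <- sample(byc[[chrom]], 1L)
        loop_row(prom_of(gid), intergenic_anchor(chrom), mark)
      }))
    }
    if (n_ii > 0) {
      rows$ii <- dplyr::bind_rows(purrr::map(seq_len(n_ii), function(i) {
        chrom <- chrom_cycle(i)
        loop_row(intergenic_fun(chrom), intergenic_fun(chrom), mark)
      }))
    }
    dplyr::bind_rows(rows)
  }

  active_planted_pp <- nrow(hub_loops) + nrow(pair_loops) +
    (if (is.null(biv_k4)) 0L else nrow(biv_k4))
  active_rest <- build_mark_loops("H3K4me3", config$loop_counts[["H3K4me3"]],
                                  active_planted_pp, anchor_pool,
                                  function(ch) intergenic_anchor(ch))
  k27_rest <- build_mark_loops("H3K27me3", config$loop_counts[["H3K27me3"]],
                               if (is.null(biv_k27)) 0L else nrow(biv_k27),
                               k27_pool, function(ch) intergenic_anchor(ch))

  # H3K9me2: I-I anchors inside the centromeric block, spans from the law
  centro_anchor_pair <- function(chrom) {
    len <- chrom_sizes$length[chrom_sizes$chrom == chrom]
    cen <- round(config$centromere_span * len)
    law <- config$span_laws$H3K9me2
    s <- round(rlnorm(1, law[["meanlog"]], law[["sdlog"]]))
    s <- min(s, cen[2] - cen[1] - 2L * config$anchor_width - 2L)
    a_start <- cen[1] + floor(runif(1) * (cen[2] - cen[1] - s -
                                            config$anchor_width))
    list(a = tibble(chrom = chrom, start = as.integer(a_start),
                    end = as.integer(a_start + config$anchor_width)),
         b = tibble(chrom = chrom, start = as.integer(a_start + s),
                    end = as.integer(a_start + s + config$anchor_width)))
  }
  k9_mix <- config$category_mix$H3K9me2
  n_k9 <- config$loop_counts[["H3K9me2"]]
  n_k9_ii <- n_k9 - round(k9_mix[["PP"]] * n_k9) - round(k9_mix[["PI"]] * n_k9)
  k9_ii <- dplyr::bind_rows(purrr::map(seq_len(n_k9_ii), function(i) {
    p <- centro_anchor_pair(chrom_cycle(i))
    loop_row(p$a, p$b, "H3K9me2")
  }))
  n_k9_pp <- round(k9_mix[["PP"]] * n_k9)
  n_k9_pi <- n_k9 - n_k9_ii - n_k9_pp
  k9_pp <- if (n_k9_pp > 0) {
    dplyr::bind_rows(purrr::map(sample_pairs(k9_pool, n_k9_pp), function(p) {
      loop_row(prom_of(p[1]), prom_of(p[2]), "H3K9me2")
    }))
  } else NULL
  k9_pi <- if (n_k9_pi > 0) {
    byc <- pool_by_chrom(k9_pool)
    dplyr::bind_rows(purrr::map(seq_len(n_k9_pi), function(i) {
      chrom <- chrom_cycle(i)
      loop_row(prom_of(sample(byc[[chrom]], 1L)),
               intergenic_anchor(chrom), "H3K9me2")
    }))
  } else NULL

  loops_raw <- dplyr::bind_rows(hub_loops, pair_loops, biv_k4, active_rest,
                                biv_k27, k27_rest, k9_ii, k9_pp, k9_pi)
  loops <- normalize_loops(loops_raw, chrom_sizes)

  # ---- truth: loop categories by construction ----
  count_cat <- function(mark) {
    mix <- config$category_mix[[mark]]
    n <- config$loop_counts[[mark]]
    n_pp <- round(mix[["PP"]] * n); n_pi <- round(mix[["PI"]] * n)
    tibble(mark = mark, category = c("PP", "PI", "II"),
           n = c(n_pp, n_pi, n - n_pp - n_pi))
  }
  truth_categories <- dplyr::bind_rows(purrr::map(names(config$loop_counts),
                                                  count_cat))

  # ---- peaks: anchors become anchor peaks, basal sets basal peaks ----
  anchors <- loops_to_anchors(loops)
  anchor_peaks <- anchors %>%
    dplyr::distinct(.data$chrom, .data$start, .data$end, .data$mark) %>%
    dplyr::mutate(intensity = round(rlnorm(dplyr::n(), log(8), 0.4), 3),
                  summit = NA_integer_)
  basal_prom <- prom_of(basal_genes)
  basal_peak_rows <- tibble(chrom = basal_prom$chrom, start = basal_prom$start,
                            end = basal_prom$end, mark = "H3K4me3",
                            intensity = round(rlnorm(nrow(basal_prom),
                                                     log(4), 0.4), 3),
                            summit = NA_integer_)
  # a few basal H3K27me3 promoter peaks and basal intergenic peaks
  k27_basal_genes <- take_pool(config$n_k27_basal)
  k27_basal_prom <- prom_of(k27_basal_genes)
  k27_basal <- tibble(chrom = k27_basal_prom$chrom,
                      start = k27_basal_prom$start, end = k27_basal_prom$end,
                      mark = "H3K27me3",
                      intensity = round(rlnorm(nrow(k27_basal_prom),
                                               log(4), 0.4), 3),
                      summit = NA_integer_)
  peaks <- dplyr::bind_rows(
    anchor_peaks[, c("chrom", "start", "end", "mark", "intensity", "summit")],
    basal_peak_rows, k27_basal)

  # ---- gene anchor/basal truth ----
  prom_key <- paste(proms$chrom, proms$start, proms$end)
  anchor_key <- paste(anchors$chrom, anchors$start, anchors$end)
  anchor_gene_ids <- proms$gene_id[prom_key %in% anchor_key]
  truth_gene_status <- tibble(
    gene_id = genes$gene_id,
    status = dplyr::case_when(
      genes$gene_id %in% anchor_gene_ids ~ "anchor",
      genes$gene_id %in% c(basal_genes, k27_basal_genes) ~ "basal",
      TRUE ~ "none"))

  # ---- TF targets clustered into hubs ----
  hub_gene_union <- sort(unique(c(truth_hubs$node_gene,
                                  unlist(truth_hubs$connecting))))
  tf_targets <- purrr::map(config$tf_configs, function(tc) {
    n_in_hub <- round(tc$hub_concentration * tc$n_targets)
    n_in_hub <- min(n_in_hub, length(hub_gene_union))
    in_hub <- sample(hub_gene_union, n_in_hub)
    outside <- setdiff(anchor_gene_ids, hub_gene_union)
    rest <- sample(outside, min(tc$n_targets - n_in_hub, length(outside)))
    sort(c(in_hub, rest))
  })
  names(tf_targets) <- vapply(config$tf_configs, `[[`, character(1), "name")

  list(peaks = peaks, loops = loops, tf_targets = tf_targets,
       truth = list(loop_categories = truth_categories,
                    gene_status = truth_gene_status,
                    pairs = truth_pairs, hubs = truth_hubs,
                    pools = list(anchor_pool = anchor_pool,
                                 basal_genes = basal_genes,
                                 k27_pool = k27_pool, k9_pool = k9_pool,
                                 bivalent = biv,
                                 anchor_genes = sort(anchor_gene_ids),
                                 unused = unlist(pool, use.names = FALSE))))
}

#' Generate the expression table
#'
#' Baseline FPKM is log-normal per gene and tissue; planted anchor genes
#' are multiplied by the configured boost; planted interacting pairs share
#' a latent log-scale factor tuned analytically so the expected Pearson
#' correlation of the FPKM profiles equals `planted_pair_pcc`.
#'
#' @param config A [sim_config()].
#' @param genes Gene tibble.
#' @param truth Truth list from [generate_peaks_and_loops()].
#' @return Expression tibble (`gene_id` + tissue columns; first tissue is
#'   `seedling`).
#' @export
generate_expression <- function(config, genes, truth) {
  set.seed(config$seed + 3L)
  n_g <- nrow(genes); n_t <- config$n_tissues
  mu <- rnorm(n_g, config$expr_meanlog, config$expr_gene_sdlog)
  status <- truth$gene_status$status[match(genes$gene_id,
                                           truth$gene_status$gene_id)]
  mu <- mu + ifelse(status == "anchor", log(config$anchor_expression_boost), 0)
  z <- matrix(rnorm(n_g * n_t), n_g, n_t)
  rho <- lognormal_rho(config$planted_pair_pcc, config$expr_tissue_sdlog)
  if (nrow(truth$pairs)) {
    ia <- match(truth$pairs$gene_a, genes$gene_id)
    ib <- match(truth$pairs$gene_b, genes$gene_id)
    for (k in seq_along(ia)) {
      f <- rnorm(n_t)
      z[ia[k], ] <- sqrt(abs(rho)) * f + sqrt(1 - abs(rho)) * rnorm(n_t)
      z[ib[k], ] <- sign(rho) * sqrt(abs(rho)) * f +
        sqrt(1 - abs(rho)) * rnorm(n_t)
    }
  }
  fpkm <- exp(mu + config$expr_tissue_sdlog * z)
  tissues <- c("seedling", sprintf("tissue_%02d", seq_len(n_t - 1L) + 1L))
  out <- as_tibble(setNames(as.data.frame(round(fpkm, 4)), tissues))
  dplyr::bind_cols(tibble(gene_id = genes$gene_id), out)
}

#' Generate a two-condition pair with planted hub changes
#'
#' Starting from the base loops, a planted fraction of hubs is entirely
#' disassembled (all member loops removed), partially disassembled (enough
#' connecting genes removed to satisfy the PDH rule while the hub stays
#' above the detection degree), or grown (enough new connecting genes added
#' to satisfy the FH rule); the rest stay untouched. Condition-2 expression
#' multiplies the separated genes by `separated_fc`.
#'
#' @param config A [sim_config()].
#' @param base Output of [generate_peaks_and_loops()].
#' @param genes Gene tibble.
#' @param expr Base expression tibble (condition 1).
#' @return List with `loops_1`, `loops_2`, `expr_1`, `expr_2` and
#'   `truth_changes` (per planted hub: `node_gene`, `category`, `Nc`,
#'   `Nm_expected`, list-columns `separated`, `aggregated`).
#' @export
generate_condition_pair <- function(config, base, genes, expr) {
  set.seed(config$seed + 4L)
  hubs <- base$truth$hubs
  n <- nrow(hubs)
  f <- config$hub_disassembly_fractions
  n_edh <- round(f[["f_EDH"]] * n)
  n_pdh <- round(f[["f_PDH"]] * n)
  n_fh <- round(f[["f_FH"]] * n)
  if (n_edh + n_pdh + n_fh > n) {
    stop("disassembly fractions exceed available hubs", call. = FALSE)
  }
  ord <- sample.int(n)
  category <- rep("stable", n)
  category[ord[seq_len(n_edh)]] <- "EDH"
  if (n_pdh) category[ord[n_edh + seq_len(n_pdh)]] <- "PDH"
  if (n_fh) category[ord[n_edh + n_pdh + seq_len(n_fh)]] <- "FH"

  loops <- base$loops
  proms <- promoters_of(genes)
  prom_key <- function(ids) {
    p <- proms[match(ids, proms$gene_id), ]
    paste(p$chrom, p$start, p$end)
  }
  far_key <- paste(loops$chrom_b, loops$start_b, loops$end_b)
  near_key <- paste(loops$chrom_a, loops$start_a, loops$end_a)
  unused_by_chrom <- split(base$truth$pools$unused,
                           genes$chrom[match(base$truth$pools$unused,
                                             genes$gene_id)])

  drop_ids <- character()
  add_rows <- list()
  changes <- purrr::map_dfr(seq_len(n), function(h) {
    node <- hubs$node_gene[h]
    conn <- hubs$connecting[[h]]
    Nc <- length(conn)
    node_k <- prom_key(node)
    member <- loops$mark == "H3K4me3" &
      (near_key == node_k | far_key == node_k)
    cat_h <- category[h]
    if (cat_h == "EDH") {
      drop_ids <<- c(drop_ids, loops$loop_id[member])
      sep <- conn; Nm <- 0L
    } else if (cat_h == "PDH") {
      k <- max(3L, ceiling(0.3 * Nc))
      sep <- sample(conn, k)
      sep_k <- prom_key(sep)
      drop_ids <<- c(drop_ids,
                     loops$loop_id[member & (near_key %in% sep_k |
                                               far_key %in% sep_k)])
      Nm <- Nc - k
    } else if (cat_h == "FH") {
      g_add <- max(3L, ceiling(3 * Nc / 7))
      chrom <- genes$chrom[match(node, genes$gene_id)]
      avail <- unused_by_chrom[[chrom]]
      if (length(avail) < g_add) stop("unused gene pool exhausted", call. = FALSE)
      new_ids <- avail[seq_len(g_add)]
      unused_by_chrom[[chrom]] <<- avail[-seq_len(g_add)]
      pn <- proms[match(rep(node, g_add), proms$gene_id), ]
      pc <- proms[match(new_ids, proms$gene_id), ]
      add_rows[[length(add_rows) + 1L]] <<- tibble(
        chrom_a = pn$chrom, start_a = pn$start, end_a = pn$end,
        chrom_b = pc$chrom, start_b = pc$start, end_b = pc$end,
        mark = "H3K4me3",
        pet_count = sample(seq(config$pet_range[1], config$pet_range[2]),
                           g_add, replace = TRUE),
        fdr = round(runif(g_add, 0, 0.04), 4))
      sep <- character(); Nm <- Nc + g_add
    } else {
      sep <- character(); Nm <- Nc
    }
    tibble(node_gene = node, category = cat_h, Nc = Nc,
           Nm_expected = as.integer(Nm),
           separated = list(sort(sep)),
           aggregated = list(sort(setdiff(conn, sep))))
  })

  loops_2 <- loops[!loops$loop_id %in% drop_ids, ]
  if (length(add_rows)) {
    loops_2 <- normalize_loops(
      dplyr::bind_rows(loops_2[, setdiff(names(loops_2), "loop_id")],
                       dplyr::bind_rows(add_rows)))
  }
  separated_all <- unique(unlist(changes$separated))
  expr_2 <- expr
  sel <- expr_2$gene_id %in% separated_all
  expr_2[sel, -1] <- expr_2[sel, -1] * config$separated_fc
  list(loops_1 = loops, loops_2 = loops_2, expr_1 = expr, expr_2 = expr_2,
       truth_changes = changes)
}

#' Generate accessible regions (CREs) with known states
#'
#' Places CREs in contexts whose class, state and interaction status are
#' known by construction: active anchor/basal PREs at active anchor/basal
#' gene promoters, poised PREs at H3K27me3 anchor-gene promoters, poiAct
#' PREs at bivalent-gene promoters, active DREs next to anchor/basal gene
#' regions, and poised DREs beside H3K27me3 intergenic anchor peaks. The
#' truth table is derived by direct application of the classification rules
#' to the planted context (independent of the annotation code).
#'
#' @param config A [sim_config()].
#' @param genome Output of [generate_genome()].
#' @param base Output of [generate_peaks_and_loops()].
#' @return List with `cres` (tibble `chrom`, `start`, `end`) and
#'   `truth` (`genomic_class`, `state`, `interaction_status` per CRE).
#' @export
generate_cres <- function(config, genome, base) {
  set.seed(config$seed + 6L)
  genes <- genome$genes
  proms <- promoters_of(genes, chrom_sizes = genome$chrom_sizes)
  fr <- config$cre_state_fractions
  n <- config$n_cres
  n_poiact <- round(fr[["poiAct"]] * n)
  n_poised <- round(fr[["poised"]] * n)
  n_active <- n - n_poiact - n_poised

  pools <- base$truth$pools
  status <- base$truth$gene_status
  anchor_active <- setdiff(intersect(pools$anchor_genes,
                                     c(pools$anchor_pool,
                                       unlist(base$truth$hubs$connecting),
                                       base$truth$hubs$node_gene,
                                       base$truth$pairs$gene_a,
                                       base$truth$pairs$gene_b)),
                           c(pools$k27_pool, pools$bivalent, pools$k9_pool))
  k27_anchor <- intersect(pools$anchor_genes, pools$k27_pool)
  bivalent <- pools$bivalent
  basal <- pools$basal_genes

  prom_cre <- function(ids) {
    p <- proms[match(ids, proms$gene_id), ]
    # shrink inside the promoter so the window is 100% promoter space
    tibble(chrom = p$chrom, start = p$start + 100L, end = p$end - 100L)
  }
  n_poiact <- min(n_poiact, length(bivalent))
  cre_poiact <- prom_cre(sample(bivalent, n_poiact))
  truth_poiact <- tibble(genomic_class = "PRE", state = "poiAct",
                         interaction_status = "anchor")[rep(1, n_poiact), ]

  n_poised_pre <- min(ceiling(n_poised / 2), length(k27_anchor))
  cre_poised_pre <- prom_cre(sample(k27_anchor, n_poised_pre))
  # poised DREs: 200 bp windows placed 100 bp beyond an H3K27me3
  # intergenic anchor peak, at least 500 bp from any other peak
  k27_anchors <- loops_to_anchors(base$loops[base$loops$mark == "H3K27me3", ])
  prom_key <- paste(proms$chrom, proms$start, proms$end)
  k27_ig <- k27_anchors[!(paste(k27_anchors$chrom, k27_anchors$start,
                                k27_anchors$end) %in% prom_key), ]
  other_peaks <- base$peaks[base$peaks$mark != "H3K27me3", ]
  n_poised_dre <- n_poised - n_poised_pre
  cand <- k27_ig[sample.int(nrow(k27_ig)), ]
  regions <- gene_regions_of(genes)
  gr_regions <- as_granges(regions)
  gr_other <- as_granges(other_peaks)
  gr_k27p <- as_granges(base$peaks[base$peaks$mark == "H3K27me3", ])
  dist1 <- function(w, gr) {
    if (!length(gr)) return(NA_real_)
    hits <- GenomicRanges::distanceToNearest(as_granges(w), gr)
    if (!length(hits)) NA_real_ else S4Vectors::mcols(hits)$distance
  }
  picked <- list()
  for (i in seq_len(nrow(cand))) {
    if (length(picked) >= n_poised_dre) break
    w <- tibble(chrom = cand$chrom[i], start = cand$end[i] + 100L,
                end = cand$end[i] + 300L)
    if (length(GenomicRanges::findOverlaps(as_granges(w), gr_regions)))
      next  # must stay fully intergenic
    near_other <- dist1(w, gr_other)
    near_k27 <- dist1(w, gr_k27p)
    if ((is.na(near_other) || near_other >= 500) &&
        !is.na(near_k27) && near_k27 < 500) picked[[length(picked) + 1L]] <- w
  }
  cre_poised_dre <- dplyr::bind_rows(picked)
  n_poised_dre <- nrow(cre_poised_dre)
  truth_poised <- dplyr::bind_rows(
    tibble(genomic_class = "PRE", state = "poised",
           interaction_status = "anchor")[rep(1, n_poised_pre), ],
    tibble(genomic_class = "DRE", state = "poised",
           interaction_status = "anchor")[rep(1, n_poised_dre), ])

  # active PREs: anchor-gene and basal-gene promoters
  n_act_pre_anchor <- ceiling(n_active * 0.5)
  n_act_pre_basal <- ceiling(n_active * 0.25)
  n_act_pre_anchor <- min(n_act_pre_anchor, length(anchor_active))
  n_act_pre_basal <- min(n_act_pre_basal, length(basal))
  cre_act_anchor <- prom_cre(sample(anchor_active, n_act_pre_anchor))
  cre_act_basal <- prom_cre(sample(basal, n_act_pre_basal))
  # active DREs: windows in intergenic gaps far from all peaks; status from
  # the nearest gene's truth status
  n_act_dre <- n_active - n_act_pre_anchor - n_act_pre_basal
  gaps <- arm_gaps(genes, genome$chrom_sizes, config$centromere_span,
                   min_width = 4000L)
  g <- tss_of(genes)
  gr_all_peaks <- as_granges(base$peaks)
  # batch candidate windows, filter vectorised, keep the first valid ones
  n_prop <- 20L * n_act_dre
  gi <- sample.int(nrow(gaps), n_prop, replace = TRUE,
                   prob = gaps$end - gaps$start)
  pos <- gaps$start[gi] + 1000L +
    floor(runif(n_prop) * pmax(gaps$end[gi] - gaps$start[gi] - 2400L, 1))
  cand_w <- tibble(chrom = gaps$chrom[gi], start = as.integer(pos),
                   end = as.integer(pos + 400L))
  hits <- GenomicRanges::distanceToNearest(as_granges(cand_w), gr_all_peaks)
  pdist <- rep(NA_real_, n_prop)
  pdist[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  ok <- is.na(pdist) | pdist >= 500
  # nearest gene per candidate (ties: lower gene id)
  mid_w <- (cand_w$start + cand_w$end) / 2
  nearest_id <- vapply(seq_len(n_prop), function(i) {
    if (!ok[i]) return(NA_character_)
    on_chrom <- g[g$chrom == cand_w$chrom[i], ]
    d <- abs(on_chrom$tss - mid_w[i])
    best <- which(d == min(d))
    on_chrom$gene_id[best[order(on_chrom$gene_id[best])][1]]
  }, character(1))
  st <- status$status[match(nearest_id, status$gene_id)]
  ok <- ok & st %in% c("anchor", "basal")
  keep <- head(which(ok), n_act_dre)
  cre_act_dre <- cand_w[keep, ]
  dre_truth <- purrr::map(st[keep], function(s)
    tibble(genomic_class = "DRE", state = "active", interaction_status = s))
  truth_active <- dplyr::bind_rows(
    tibble(genomic_class = "PRE", state = "active",
           interaction_status = "anchor")[rep(1, n_act_pre_anchor), ],
    tibble(genomic_class = "PRE", state = "active",
           interaction_status = "basal")[rep(1, n_act_pre_basal), ],
    dplyr::bind_rows(dre_truth))

  cres <- dplyr::bind_rows(cre_poiact, cre_poised_pre, cre_poised_dre,
                           cre_act_anchor, cre_act_basal, cre_act_dre)
  truth <- dplyr::bind_rows(truth_poiact, truth_poised, truth_active)
  ord <- order(cres$chrom, cres$start)
  list(cres = cres[ord, ], truth = truth[ord, ])
}

#' Generate SNPs planted into loop anchors
#'
#' Plants the configured fractions of SNPs into anchors that belong
#' exclusively to the active, repressive (H3K27me3) or inactive (H3K9me2)
#' loop groups; the remainder land outside all anchors.
#'
#' @param config A [sim_config()].
#' @param genome Output of [generate_genome()].
#' @param loops Loop tibble across marks.
#' @return List with `snps` (tibble `chrom`, `start`, `end`) and `truth`
#'   (per-SNP `group`).
#' @export
generate_snps <- function(config, genome, loops) {
  set.seed(config$seed + 5L)
  anchors <- loops_to_anchors(loops)
  grp <- function(mark) {
    if (mark %in% ACTIVE_MARKS) "active"
    else if (mark == "H3K27me3") "repressive"
    else "inactive"
  }
  anchors$group <- vapply(anchors$mark, grp, character(1))
  exclusive <- function(g) {
    own <- anchors[anchors$group == g, ]
    other <- anchors[anchors$group != g, ]
    hit <- overlap_pairs(own, other)
    own[!seq_len(nrow(own)) %in% hit$a_idx, ]
  }
  n <- config$n_snps
  fr <- config$snp_fractions
  counts <- round(fr * n)
  rows <- purrr::imap(counts, function(k, g) {
    own <- exclusive(g)
    pick <- own[sample.int(nrow(own), k, replace = k > nrow(own)), ]
    pos <- as.integer(floor((pick$start + pick$end) / 2))
    tibble(chrom = pick$chrom, start = pos, end = pos + 1L, group = g)
  })
  n_out <- n - sum(vapply(rows, nrow, integer(1)))
  gr_anchors <- as_granges(anchors)
  out_rows <- list()
  guard <- 0L
  while (length(out_rows) < n_out && guard < 1000L * n_out) {
    guard <- guard + 1L
    ci <- sample.int(nrow(genome$chrom_sizes), 1L)
    pos <- as.integer(floor(runif(1) * (genome$chrom_sizes$length[ci] - 1L)))
    w <- tibble(chrom = genome$chrom_sizes$chrom[ci], start = pos,
                end = pos + 1L)
    if (length(GenomicRanges::findOverlaps(as_granges(w), gr_anchors))) next
    out_rows[[length(out_rows) + 1L]] <- w
  }
  outside <- dplyr::bind_rows(out_rows) %>%
    dplyr::mutate(group = "not_involved")
  all_rows <- dplyr::bind_rows(dplyr::bind_rows(rows), outside)
  list(snps = all_rows[, c("chrom", "start", "end")],
       truth = all_rows[, c("chrom", "start", "end", "group")])
}

#' Simulate a complete dataset
#'
#' Runs all generators in dependency order and optionally writes every
#' output (and truth table) as plain-text files that the package's readers
#' consume. Identical configurations produce byte-identical files.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory (created if missing).
#' @return List with `chrom_sizes`, `genes`, `peaks`, `loops`, `expr`,
#'   `tf_targets`, `condition` (two-condition pair), `cres`, `snps`,
#'   `truth` (all truth tables), and `files` (paths, when `dir` is given).
#' @export
simulate_dataset <- function(config = sim_config(), dir = NULL) {
  genome <- generate_genome(config)
  base <- generate_peaks_and_loops(config, genome)
  expr <- generate_expression(config, genome$genes, base$truth)
  cond <- generate_condition_pair(config, base, genome$genes, expr)
  cres <- generate_cres(config, genome, base)
  snps <- generate_snps(config, genome, base$loops)
  out <- list(chrom_sizes = genome$chrom_sizes, genes = genome$genes,
              peaks = base$peaks, loops = base$loops, expr = expr,
              tf_targets = base$tf_targets, condition = cond,
              cres = cres$cres, snps = snps$snps,
              truth = c(base$truth, list(hub_changes = cond$truth_changes,
                                         cre = cres$truth,
                                         snp = snps$truth)))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    p <- function(...) file.path(dir, ...)
    files <- c(
      chrom_sizes = write_chrom_sizes(out$chrom_sizes, p("genome.chrom.sizes")),
      genes = write_gff3(out$genes, p("genes.gff3")),
      expr = write_expression(out$expr, p("expression.tsv")),
      expr_2 = write_expression(cond$expr_2, p("expression_cond2.tsv")))
    for (mk in unique(out$peaks$mark)) {
      files[paste0("peaks_", mk)] <-
        write_bed(out$peaks[out$peaks$mark == mk, ],
                  p(sprintf("peaks_%s.narrowPeak", mk)))
    }
    for (mk in unique(out$loops$mark)) {
      files[paste0("loops_", mk)] <-
        write_bedpe(out$loops[out$loops$mark == mk, ],
                    p(sprintf("loops_%s.bedpe", mk)))
    }
    files["loops_cond2"] <- write_bedpe(
      cond$loops_2[cond$loops_2$mark == "H3K4me3", ],
      p("loops_cond2_H3K4me3.bedpe"))
    files["cres"] <- p("cres.bed")
    writeLines(sprintf("%s\t%d\t%d", out$cres$chrom, out$cres$start,
                       out$cres$end), files["cres"])
    files["snps"] <- p("snps.bed")
    writeLines(sprintf("%s\t%d\t%d", out$snps$chrom, out$snps$start,
                       out$snps$end), files["snps"])
    readr::write_tsv(out$truth$loop_categories, p("truth_loop_categories.tsv"),
                     progress = FALSE)
    readr::write_tsv(out$truth$gene_status, p("truth_gene_status.tsv"),
                     progress = FALSE)
    readr::write_tsv(out$truth$pairs, p("truth_pairs.tsv"), progress = FALSE)
    readr::write_tsv(
      dplyr::mutate(out$truth$hubs,
                    connecting = vapply(.data$connecting, paste,
                                        character(1), collapse = ",")),
      p("truth_hubs.tsv"), progress = FALSE)
    readr::write_tsv(
      dplyr::mutate(out$truth$hub_changes,
                    separated = vapply(.data$separated, paste, character(1),
                                       collapse = ","),
                    aggregated = vapply(.data$aggregated, paste, character(1),
                                        collapse = ",")),
      p("truth_hub_changes.tsv"), progress = FALSE)
    readr::write_tsv(out$truth$snp, p("truth_snps.tsv"), progress = FALSE)
    out$files <- files
  }
  out
}
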