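# The generators and their planted-structure guarantees.

test_that("identical configurations produce byte-identical files", {
  cfg <- sim_small_config(seed = 5)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_dataset(cfg, dir = d1)
  simulate_dataset(cfg, dir = d2)
  f1 <- sort(list.files(d1, full.names = TRUE))
  f2 <- sort(list.files(d2, full.names = TRUE))
  expect_equal(basename(f1), basename(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("genome generation respects arms and rejects infeasible density", {
  cfg <- sim_small_config(seed = 2)
  gen <- generate_genome(cfg)
  expect_equal(nrow(gen$genes), cfg$n_genes)
  cen <- round(cfg$centromere_span * cfg$chrom_length)
  expect_true(all(gen$genes$end <= cen[1] | gen$genes$start >= cen[2]))
  # non-overlap within each chromosome
  for (ch in unique(gen$genes$chrom)) {
    g <- gen$genes[gen$genes$chrom == ch, ]
    g <- g[order(g$start), ]
    expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  }
  expect_error(generate_genome(sim_config(seed = 1, n_genes = 50000L,
                                          chrom_length = 2e6)),
               "infeasible")
})

test_that("planted loop categories and spans match the configuration", {
  ds <- sim_shared()
  cfg <- sim_config(seed = 42)
  truth <- ds$truth$loop_categories
  k4 <- truth[truth$mark == "H3K4me3", ]
  expect_equal(k4$n[k4$category == "PP"],
               round(0.96 * cfg$loop_counts[["H3K4me3"]]))
  # recomputation from the emitted records reproduces the truth table
  lc <- categorize_loops(ds$loops, ds$genes, ds$chrom_sizes)
  obs <- dplyr::count(lc, mark, category)
  for (i in seq_len(nrow(truth))) {
    got <- obs$n[obs$mark == truth$mark[i] & obs$category == truth$category[i]]
    expect_equal(if (length(got)) got else 0L, truth$n[i],
                 label = paste(truth$mark[i], truth$category[i]))
  }
  # H3K9me2 II anchors sit inside the centromeric block
  k9 <- ds$loops[ds$loops$mark == "H3K9me2", ]
  cats <- lc[match(k9$loop_id, lc$loop_id), ]
  ii <- k9[cats$category == "II", ]
  cen <- round(cfg$centromere_span * cfg$chrom_length)
  expect_true(all(ii$start_a >= cen[1] & ii$end_b <= cen[2]))
  # median span near the configured 105 kb log-normal median
  med <- median(cats$span_bp[cats$category == "II"])
  expect_gt(med, 105e3 * 0.8)
  expect_lt(med, 105e3 * 1.25)
})

test_that("config validation catches bad mixes, fractions and correlations", {
  expect_error(sim_config(category_mix = list(H3K4me3 = c(PP = .5, PI = .2, II = .2),
                                              H3K27me3 = c(PP = .4, PI = .3, II = .3),
                                              H3K9me2 = c(PP = .02, PI = .1, II = .88))),
               "sum to 1")
  expect_error(sim_config(hub_disassembly_fractions =
                            c(f_EDH = .5, f_PDH = .4, f_FH = .2)), "sum")
  expect_error(sim_config(planted_pair_pcc = 1), "planted_pair_pcc")
  expect_error(sim_config(nonsense_key = 1), "unknown config key")
})

test_that("expression planting recovers the boost and the pair correlation", {
  ds <- sim_shared()
  tg <- ds$truth$gene_status
  e <- ds$expr
  med <- function(ids) median(e$seedling[e$gene_id %in% ids])
  ratio <- med(tg$gene_id[tg$status == "anchor"]) /
    med(tg$gene_id[tg$status == "basal"])
  expect_gt(ratio, 2 * 0.9)
  expect_lt(ratio, 2 * 1.1)
  pcc <- mean_pair_pcc(ds$truth$pairs, e)
  expect_equal(pcc$mean_pcc, 0.5, tolerance = 0.1)

  # null case: planted correlation 0 gives mean pair PCC near 0
  cfg0 <- sim_small_config(seed = 9, pcc = 0)
  gen <- generate_genome(cfg0)
  base <- generate_peaks_and_loops(cfg0, gen)
  e0 <- generate_expression(cfg0, gen$genes, base$truth)
  pcc0 <- mean_pair_pcc(base$truth$pairs, e0)
  expect_lt(abs(pcc0$mean_pcc), 3 / sqrt(cfg0$n_tissues * nrow(base$truth$pairs)) * 3)
})

test_that("boost of 1 leaves anchor and basal FPKM indistinguishable", {
  cfg <- sim_small_config(seed = 13, anchor_expression_boost = 1)
  gen <- generate_genome(cfg)
  base <- generate_peaks_and_loops(cfg, gen)
  e <- generate_expression(cfg, gen$genes, base$truth)
  tg <- base$truth$gene_status
  p <- group_rank_test(e$seedling[e$gene_id %in% tg$gene_id[tg$status == "anchor"]],
                       e$seedling[e$gene_id %in% tg$gene_id[tg$status == "basal"]],
                       "two.sided")$p_value
  expect_gt(p, 0.001)
})

test_that("condition pair plants the exact hub-change counts", {
  ds <- sim_shared()
  tc <- ds$truth$hub_changes
  cfg <- sim_config(seed = 42)
  f <- cfg$hub_disassembly_fractions
  expect_equal(sum(tc$category == "EDH"), round(f[["f_EDH"]] * cfg$n_hubs))
  expect_equal(sum(tc$category == "PDH"), round(f[["f_PDH"]] * cfg$n_hubs))
  expect_equal(sum(tc$category == "FH"), round(f[["f_FH"]] * cfg$n_hubs))
  # all-zero fractions leave the loop set untouched
  cfg0 <- sim_small_config(seed = 3,
                           hub_disassembly_fractions =
                             c(f_EDH = 0, f_PDH = 0, f_FH = 0))
  gen <- generate_genome(cfg0)
  base <- generate_peaks_and_loops(cfg0, gen)
  e <- generate_expression(cfg0, gen$genes, base$truth)
  cond <- generate_condition_pair(cfg0, base, gen$genes, e)
  expect_identical(cond$loops_1, cond$loops_2)
  expect_identical(cond$expr_1, cond$expr_2)
  # per-category counts that round past the hub count are rejected
  # (6 hubs: round(0.42*6) + round(0.42*6) + round(0.16*6) = 3 + 3 + 1)
  expect_error(generate_condition_pair(
    sim_small_config(seed = 3, hub_disassembly_fractions =
                       c(f_EDH = 0.42, f_PDH = 0.42, f_FH = 0.16)),
    base, gen$genes, e), "exceed")
})

test_that("every emitted file passes the package validators", {
  cfg <- sim_small_config(seed = 8)
  dir <- withr::local_tempdir()
  ds <- simulate_dataset(cfg, dir = dir)
  sizes <- read_chrom_sizes(file.path(dir, "genome.chrom.sizes"))
  expect_equal(sizes, ds$chrom_sizes)
  genes <- read_gff3(file.path(dir, "genes.gff3"))
  expect_equal(nrow(genes), cfg$n_genes)
  for (mk in unique(ds$loops$mark)) {
    lp <- read_bedpe(file.path(dir, sprintf("loops_%s.bedpe", mk)), mk,
                     chrom_sizes = sizes)
    expect_equal(nrow(lp), sum(ds$loops$mark == mk))
  }
  for (mk in unique(ds$peaks$mark)) {
    pk <- read_bed(file.path(dir, sprintf("peaks_%s.narrowPeak", mk)), mk,
                   chrom_sizes = sizes)
    expect_gt(nrow(pk), 0)
  }
  expect_equal(read_expression(file.path(dir, "expression.tsv")), ds$expr)
})
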