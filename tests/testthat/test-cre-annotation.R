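# CRE genomic classification and the anchor/basal x active/poised/poiAct
# decision tree, checked against an independently coded truth table.

cre_genes <- function() {
  mk_genes(~gene_id, ~chrom, ~start, ~end, ~strand,
           "g1", "chr1", 100000L, 110000L, "+",
           "g2", "chr1", 200000L, 210000L, "+")
}

test_that("genomic classification follows the 50% rule with priority", {
  genes <- cre_genes()
  tss <- 100000
  cres <- tibble::tibble(
    chrom = "chr1",
    start = as.integer(c(tss - 900,     # fully inside the promoter
                         tss - 100,     # 600 bp promoter / 400 bp body
                         tss + 50,      # 450 promoter / 550 body
                         tss + 2000,    # fully intragenic
                         tss - 5000,    # fully intergenic
                         tss - 1300)),  # 300 intergenic / 700 promoter
    end = as.integer(c(tss - 200, tss + 900, tss + 1050, tss + 3000,
                       tss - 4000, tss - 300)))
  got <- classify_cre_genomic(cres, genes)
  expect_equal(got$genomic_class,
               c("PRE", "PRE", "intragenic", "intragenic", "DRE", "PRE"))
  expect_equal(got$frac_pre[2], 0.6)
  expect_equal(got$frac_intragenic[2], 0.4)
  expect_equal(got$frac_pre[3], 0.45)
  expect_equal(got$frac_intragenic[3], 0.55)
  expect_false(any(got$sub_threshold))
})

# truth table written straight from the printed rules, structured as a
# feature lookup rather than the package's branch code
cre_truth_oracle <- function(case) {
  with(case, {
    if (class == "intragenic") return(c(NA_character_, NA_character_))
    if (class == "DRE") {
      near_marks <- peaks_near_marks
      if (length(near_marks) > 0 && all(near_marks == "H3K27me3")) {
        status <- if (any(peaks_near_status == "anchor")) "anchor" else "basal"
        return(c("poised", status))
      }
      return(c("active",
               if (identical(nearest_status, "anchor")) "anchor" else "basal"))
    }
    # PRE branch
    k27a <- any(peaks_over_marks == "H3K27me3" & peaks_over_status == "anchor")
    acta <- any(peaks_over_marks %in% c("H3K4me3", "RNAPII", "H3K4me1") &
                  peaks_over_status == "anchor")
    if (k27a && !acta) return(c("poised", "anchor"))
    if (k27a && acta) return(c("poiAct", "anchor"))
    if (identical(linked_status, "basal")) {
      return(c(if (any(peaks_over_marks == "H3K27me3")) "poised" else "active",
               "basal"))
    }
    c("active", "anchor")
  })
}

test_that("the decision tree matches the truth table on every branch", {
  # one gene per case keeps contexts independent; cases place a CRE, a peak
  # configuration and gene statuses, then compare against the oracle
  gene_at <- function(i, id) {
    start <- 100000L + i * 50000L
    tibble::tibble(gene_id = id, chrom = "chr1", start = start,
                   end = start + 5000L, strand = "+",
                   biotype = "protein_coding")
  }
  peak_at <- function(chrom, start, end, mark, status) {
    tibble::tibble(chrom = chrom, start = as.integer(start),
                   end = as.integer(end), mark = mark, intensity = 1,
                   summit = NA_integer_, n_supporting = (status == "anchor") * 1L,
                   status = status, supporting_loops = list(character()))
  }
  cases <- list()
  add_case <- function(label, class, cre_off_start, cre_off_end, peaks_fun,
                       gene_status) {
    cases[[length(cases) + 1L]] <<- list(label = label, class = class,
                                         off = c(cre_off_start, cre_off_end),
                                         peaks_fun = peaks_fun,
                                         gene_status = gene_status)
  }
  no_peaks <- function(tss) NULL
  # DRE cases: CRE placed 5-6 kb upstream of the TSS (intergenic space)
  add_case("DRE k27-only anchor 300bp", "DRE", -6000, -5600,
           function(tss) peak_at("chr1", tss - 5300, tss - 4900,
                                 "H3K27me3", "anchor"), "anchor")
  add_case("DRE k27-only basal 300bp", "DRE", -6000, -5600,
           function(tss) peak_at("chr1", tss - 5300, tss - 4900,
                                 "H3K27me3", "basal"), "anchor")
  add_case("DRE k27 at exactly 500bp -> active", "DRE", -6000, -5600,
           function(tss) peak_at("chr1", tss - 5100, tss - 4700,
                                 "H3K27me3", "anchor"), "anchor")
  add_case("DRE mixed peaks nearby", "DRE", -6000, -5600,
           function(tss) dplyr::bind_rows(
             peak_at("chr1", tss - 5300, tss - 4900, "H3K27me3", "anchor"),
             peak_at("chr1", tss - 6500, tss - 6200, "H3K4me3", "anchor")),
           "anchor")
  add_case("DRE no peak, nearest anchor", "DRE", -6000, -5600, no_peaks,
           "anchor")
  add_case("DRE no peak, nearest basal", "DRE", -6000, -5600, no_peaks,
           "basal")
  # PRE cases: CRE inside the promoter [tss-1000, tss+500)
  add_case("PRE k27 anchor only", "PRE", -800, -200,
           function(tss) peak_at("chr1", tss - 700, tss - 300,
                                 "H3K27me3", "anchor"), "anchor")
  add_case("PRE k27 + active anchor", "PRE", -800, -200,
           function(tss) dplyr::bind_rows(
             peak_at("chr1", tss - 700, tss - 300, "H3K27me3", "anchor"),
             peak_at("chr1", tss - 600, tss - 250, "H3K4me3", "anchor")),
           "anchor")
  add_case("PRE linked basal, active marks", "PRE", -800, -200,
           function(tss) peak_at("chr1", tss - 700, tss - 300,
                                 "H3K4me3", "basal"), "basal")
  add_case("PRE linked basal, k27 basal", "PRE", -800, -200,
           function(tss) peak_at("chr1", tss - 700, tss - 300,
                                 "H3K27me3", "basal"), "basal")
  add_case("PRE no peaks, linked anchor", "PRE", -800, -200, no_peaks,
           "anchor")
  add_case("PRE active anchor only", "PRE", -800, -200,
           function(tss) peak_at("chr1", tss - 700, tss - 300,
                                 "H3K4me3", "anchor"), "anchor")
  # intragenic: carried through unannotated
  add_case("intragenic skip", "intragenic", 2000, 2600, no_peaks, "anchor")

  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    genes <- gene_at(1, "gX")
    tss <- genes$start
    cre <- tibble::tibble(chrom = "chr1",
                          start = as.integer(tss + cs$off[1]),
                          end = as.integer(tss + cs$off[2]))
    peaks <- cs$peaks_fun(tss)
    if (is.null(peaks)) {
      peaks <- peak_at("chr1", 1, 2, "H3K4me3", "basal")[0, ]
    }
    gstat <- tibble::tibble(gene_id = "gX", status = cs$gene_status)
    ann <- classify_cre_state(classify_cre_genomic(cre, genes),
                              peaks, gstat, genes)
    # derive the oracle's feature view of the same case
    gap_near <- function(p) {
      d <- pmax(p$start - cre$end, cre$start - p$end, 0)
      d < 500
    }
    overl <- function(p) p$start < cre$end & p$end > cre$start
    near <- peaks[gap_near(peaks), ]
    over <- peaks[overl(peaks), ]
    want <- cre_truth_oracle(list(
      class = cs$class,
      peaks_near_marks = near$mark, peaks_near_status = near$status,
      peaks_over_marks = over$mark, peaks_over_status = over$status,
      nearest_status = cs$gene_status, linked_status = cs$gene_status))
    expect_equal(ann$genomic_class, cs$class, label = cs$label)
    expect_equal(ann$state, want[1], label = paste(cs$label, "state"))
    expect_equal(ann$interaction_status, want[2],
                 label = paste(cs$label, "status"))
  }
})

test_that("nearest-gene ties break lexicographically and targets link", {
  genes <- mk_genes(~gene_id, ~chrom, ~start, ~end, ~strand,
                    "gb", "chr1", 100000L, 104000L, "+",
                    "ga", "chr1", 116000L, 120000L, "-")
  # TSSs at 100000 and 119999; midpoint 109999.5 is 9999.5 from each:
  # shift the CRE so distances tie exactly at 10000 from both
  cre <- tibble::tibble(chrom = "chr1", start = 109800L, end = 110200L)
  # midpoint 110000: d(gb) = 10000, d(ga) = 9999 -> ga; move to tie:
  cre2 <- tibble::tibble(chrom = "chr1", start = 109799L, end = 110200L)
  # midpoint 109999.5: equidistant 9999.5 -> lexicographically first = "ga"
  ann <- classify_cre_state(classify_cre_genomic(cre2, genes),
                            tibble::tibble(chrom = character(),
                                           start = integer(), end = integer(),
                                           mark = character(),
                                           intensity = numeric(),
                                           summit = integer(),
                                           n_supporting = integer(),
                                           status = character(),
                                           supporting_loops = list()),
                            tibble::tibble(gene_id = c("ga", "gb"),
                                           status = c("anchor", "anchor")),
                            genes)
  expect_equal(ann$nearest_gene, "ga")

  # CRE inside the single anchor of one loop whose far anchor is g2's
  # promoter: connecting genes = the far anchor's gene
  genes2 <- cre_genes()
  proms <- promoters_of(genes2)
  far <- proms[proms$gene_id == "g2", ]
  loop <- mk_loop("chr1", 50000, 50400, far$start, far$end, id = "L9")
  cre3 <- tibble::tibble(chrom = "chr1", start = 50050L, end = 50350L)
  ann3 <- classify_cre_genomic(cre3, genes2)
  ann3$state <- "active"; ann3$interaction_status <- "anchor"
  ann3$nearest_gene <- "g1"
  linked <- link_cre_targets(ann3, loop, genes2,
                             tibble::tibble(gene_id = c("g1", "g2"),
                                            seedling = c(1, 2)))
  expect_equal(linked$connecting_genes[[1]], "g2")
  expect_equal(linked$n_loops, 1L)
  # basal CREs get no connecting genes
  ann3$interaction_status <- "basal"
  expect_length(link_cre_targets(ann3, loop, genes2)$connecting_genes[[1]], 0)
})

test_that("annotation on planted CREs matches the generator truth exactly", {
  ds <- sim_shared()
  ann_layers <- sim_shared_ann()
  ann <- annotate_cres(ds$cres, ds$genes, ann_layers$peaks_status,
                       ann_layers$gene_status, ds$loops, ds$expr,
                       chrom_sizes = ds$chrom_sizes)
  tr <- ds$truth$cre
  expect_identical(ann$genomic_class, tr$genomic_class)
  expect_identical(ann$state, tr$state)
  expect_identical(ann$interaction_status, tr$interaction_status)
  # poised CREs never sit on an active-mark anchor peak
  act_anchor <- ann_layers$peaks_status[
    ann_layers$peaks_status$mark %in% c("H3K4me3", "RNAPII", "H3K4me1") &
      ann_layers$peaks_status$status == "anchor", ]
  poised <- ann[!is.na(ann$state) & ann$state == "poised", ]
  expect_equal(nrow(overlap_pairs(poised, act_anchor)), 0L)
  # planted state fractions recovered exactly in noise-free mode
  cfg <- sim_config(seed = 42)
  got <- table(ann$state[!is.na(ann$state)])
  want <- table(tr$state[!is.na(tr$state)])
  expect_identical(got, want)
})

test_that("expression categories group genes as planted", {
  ds <- sim_shared()
  ann_layers <- sim_shared_ann()
  ann <- annotate_cres(ds$cres, ds$genes, ann_layers$peaks_status,
                       ann_layers$gene_status, ds$loops, ds$expr,
                       chrom_sizes = ds$chrom_sizes)
  groups <- suppressWarnings(build_expression_categories(ann, ds$genes))
  expect_true(all(c("nearest_basal", "nearest_anchor", "connecting",
                    "without_cre") %in% groups$group))
  # connecting genes of active CREs (anchor genes, planted boost) express
  # above the without-CRE control
  e <- ds$expr
  conn <- groups$gene_id[groups$group == "connecting" &
                           groups$state == "active"]
  ctrl <- groups$gene_id[groups$group == "without_cre"]
  res <- group_rank_test(e$seedling[e$gene_id %in% conn],
                         e$seedling[e$gene_id %in% ctrl], "greater")
  expect_lt(res$p_value, 0.01)
  # a gene connected to CREs of two states appears in both groups
  two_state <- ann[!is.na(ann$state), ]
  both <- intersect(
    unlist(two_state$connecting_genes[two_state$state == "active"]),
    unlist(two_state$connecting_genes[two_state$state == "poised"]))
  if (length(both)) {
    g <- both[1]
    sub <- groups[groups$group == "connecting" & groups$gene_id == g, ]
    expect_gte(nrow(sub), 2L)
  }
})
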