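# Hub detection, enrichment, and the two-condition change classifier.

# independent brute-force reading of the three printed rule blocks
brute_hub_category <- function(Nc, Nm) {
  Ns <- Nc - Nm
  if (Nc > 0 && Ns / Nc >= 0.7 && Ns >= 3) return("EDH")
  if (Nc > 0 && Ns / Nc >= 0.3 && Ns / Nc < 0.7 && Ns >= 3) return("PDH")
  if (Nm > 0 && (-Ns) / Nm >= 0.3 && (Nc - Nm) <= -3) return("FH")
  "stable"
}

test_that("hub detection applies the degree threshold after anchor merging", {
  genes <- mk_genes(~gene_id, ~chrom, ~start, ~end, ~strand,
                    "node", "chr1", 100000L, 103000L, "+",
                    "c1", "chr1", 200000L, 203000L, "+",
                    "c2", "chr1", 300000L, 303000L, "+",
                    "c3", "chr1", 400000L, 403000L, "+",
                    "c4", "chr1", 500000L, 503000L, "+",
                    "c5", "chr1", 600000L, 603000L, "+")
  node_anchor <- function(i, s, e) mk_loop("chr1", s, e,
                                           (i + 1) * 100000 - 1000,
                                           (i + 1) * 100000 + 500,
                                           id = paste0("L", i))
  # five loops sharing the node promoter anchor -> one hub of degree 5
  loops5 <- dplyr::bind_rows(lapply(1:5, function(i)
    node_anchor(i, 99000, 100500)))
  h <- detect_hubs(loops5, genes)
  expect_equal(nrow(h), 1L)
  expect_equal(h$degree, 5L)
  expect_equal(h$node_gene, "node")
  expect_setequal(h$connecting_genes[[1]], paste0("c", 1:5))
  # four loops -> no hub
  expect_equal(nrow(detect_hubs(loops5[1:4, ], genes)), 0L)
  # two overlapping anchors with 3 loops each merge into a degree-6 node
  loops33 <- dplyr::bind_rows(
    lapply(1:3, function(i) node_anchor(i, 99000, 100000)),
    lapply(4:5, function(i) node_anchor(i, 99800, 100500)),
    node_anchor(6, 99800, 100500))
  h2 <- detect_hubs(loops33, genes)
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$degree, 6L)
  expect_error(detect_hubs(loops5, genes, min_degree = 0), "min_degree")
})

test_that("Fisher enrichment equals the hypergeometric tail exactly", {
  set.seed(6)
  universe <- sprintf("g%04d", 1:1000)
  for (i in 1:100) {
    K <- sample(20:300, 1)          # targets in the universe
    n <- sample(5:40, 1)            # hub size
    k <- sample(0:min(n, K), 1)     # targets in the hub
    targets <- sample(universe, K)
    hub_genes <- c(sample(targets, k),
                   sample(setdiff(universe, targets), n - k))
    hubs <- tibble::tibble(hub_id = "h1", chrom = "chr1", start = 0L,
                           end = 1L, degree = n, node_gene = NA_character_,
                           connecting_genes = list(hub_genes),
                           member_loops = list(character()))
    res <- hub_enrichment(hubs, targets, universe)
    expect_equal(res$p_value,
                 phyper(k - 1, K, 1000 - K, n, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
  # all genes are targets: no enrichment possible
  hubs <- tibble::tibble(hub_id = "h1", chrom = "chr1", start = 0L, end = 1L,
                         degree = 10L, node_gene = NA_character_,
                         connecting_genes = list(universe[1:10]),
                         member_loops = list(character()))
  expect_equal(hub_enrichment(hubs, universe, universe)$p_value, 1)
  expect_equal(hub_enrichment(hubs, universe[900:1000], universe)$p_value, 1)
  expect_error(hub_enrichment(hubs, universe, character()), "universe")
})

test_that("random hub control exposes planted target clustering", {
  ds <- sim_shared()
  ann <- sim_shared_ann()
  active <- ds$loops[ds$loops$mark == "H3K4me3", ]
  hubs <- detect_hubs(active, ds$genes, ds$expr)
  pool <- ann$gene_status$gene_id[ann$gene_status$status == "anchor"]
  targets <- ds$tf_targets[[1]]
  ctrl <- random_hub_control(hubs, pool, targets, ds$genes$gene_id,
                             n_rounds = 40, seed = 3)
  expect_gt(ctrl$observed_count,
            quantile(ctrl$control_counts, 0.975))
  # no targets at all: control counts identically zero
  ctrl0 <- random_hub_control(hubs, pool, character(), ds$genes$gene_id,
                              n_rounds = 3, seed = 1)
  expect_true(all(ctrl0$control_counts == 0))
  expect_error(random_hub_control(hubs, pool, targets, ds$genes$gene_id,
                                  n_rounds = 0), "n_rounds")
})

test_that("hub-change classifier matches brute force on the full grid", {
  grid <- expand.grid(Nc = 0:50, Nm = 0:50)
  grid <- grid[!(grid$Nc == 0 & grid$Nm == 0), ]
  got <- classify_hub_change(grid$Nc, grid$Nm)
  want <- mapply(brute_hub_category, grid$Nc, grid$Nm)
  expect_identical(got, unname(want))
  expect_true(all(got %in% c("stable", "PDH", "EDH", "FH")))
  # printed-formula spot checks
  expect_equal(classify_hub_change(10, 2), "EDH")
  expect_equal(classify_hub_change(10, 7), "PDH")   # ratio exactly 0.3
  expect_equal(classify_hub_change(4, 2), "stable") # Ns = 2 < 3
  expect_equal(classify_hub_change(5, 10), "FH")
  expect_equal(classify_hub_change(7, 7), "stable")
  expect_error(classify_hub_change(0, 0), "undefined")
})

test_that("condition comparison matches, partitions and labels hubs", {
  ds <- sim_shared()
  active1 <- ds$condition$loops_1[ds$condition$loops_1$mark == "H3K4me3", ]
  active2 <- ds$condition$loops_2[ds$condition$loops_2$mark == "H3K4me3", ]
  h1 <- detect_hubs(active1, ds$genes, ds$expr)
  h2 <- detect_hubs(active2, ds$genes, ds$expr)
  d <- compare_conditions(h1, h2)
  # identical inputs: all stable, nothing separated
  d0 <- compare_conditions(h1, h1)
  expect_true(all(d0$category == "stable"))
  expect_true(all(lengths(d0$separated) == 0))
  # planted truth recovered hub by hub
  tc <- ds$truth$hub_changes
  m <- dplyr::inner_join(d, tc, by = "node_gene", suffix = c("", "_t"))
  expect_equal(nrow(m), nrow(tc))
  expect_identical(m$category, m$category_t)
  expect_equal(m$Nm, m$Nm_expected)
  for (i in which(m$category %in% c("EDH", "PDH"))) {
    expect_setequal(m$separated[[i]], m$separated_t[[i]])
    expect_setequal(c(m$separated[[i]], m$aggregated[[i]]),
                    unlist(tc$separated[tc$node_gene == m$node_gene[i]]) |>
                      union(unlist(tc$aggregated[tc$node_gene == m$node_gene[i]])))
    expect_length(intersect(m$separated[[i]], m$aggregated[[i]]), 0)
  }
  # hub present only in condition 1 is an EDH with everything separated
  only1 <- h1[1, ]
  d1 <- compare_conditions(only1, h1[0, ])
  expect_equal(d1$category, "EDH")
  expect_equal(d1$Nm, 0L)
  expect_setequal(d1$separated[[1]], only1$connecting_genes[[1]])
})

test_that("separated genes fall in expression relative to aggregated genes", {
  ds <- sim_shared()
  tc <- ds$truth$hub_changes
  sep <- unique(unlist(tc$separated[tc$category %in% c("EDH", "PDH")]))
  agg <- unique(unlist(tc$aggregated[tc$category %in% c("EDH", "PDH")]))
  e1 <- ds$condition$expr_1; e2 <- ds$condition$expr_2
  fc <- function(ids) {
    i <- match(ids, e1$gene_id)
    log2(e2$seedling[i] + 0.01) - log2(e1$seedling[i] + 0.01)
  }
  res <- group_rank_test(fc(sep), fc(agg), alternative = "less")
  expect_lt(res$p_value, 0.05)
})
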