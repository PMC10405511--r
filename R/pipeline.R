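# End-to-end orchestration: simulate -> annotate loops -> architecture ->
# CREs -> hubs -> network -> co-expression -> report, with a machine-
# readable manifest. Reruns with the same configuration and seed reproduce
# identical output hashes.

#' Pipeline configuration
#'
#' @param seed Master seed, fanned out to every stage.
#' @param sim List of overrides passed to [sim_config()].
#' @param resolution Contact-map resolution in bp.
#' @param domain_bin Domain segmentation bin in bp.
#' @param n_sim Simulations for the co-expression null.
#' @param coexpr_mode `"A"` or `"B"` null mode.
#' @param hops Network expansion hops (1 or 2).
#' @param min_degree Hub detection threshold.
#' @param alpha Enrichment threshold.
#' @return Validated configuration list.
#' @export
pipeline_config <- function(seed = 1L, sim = list(), resolution = 100e3,
                            domain_bin = 10e3, n_sim = 200L,
                            coexpr_mode = "A", hops = 1L, min_degree = 5L,
                            alpha = 0.05) {
  if (!hops %in% c(1L, 2L)) stop("hops must be 1 or 2", call. = FALSE)
  if (!coexpr_mode %in% c("A", "B")) stop("coexpr_mode must be A or B", call. = FALSE)
  list(seed = as.integer(seed), sim = sim, resolution = resolution,
       domain_bin = domain_bin, n_sim = n_sim, coexpr_mode = coexpr_mode,
       hops = hops, min_degree = min_degree, alpha = alpha)
}

#' Run the full toy pipeline
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory; stage outputs and a JSON manifest with
#'   per-file MD5 hashes are written there.
#' @return The manifest tibble (`stage`, `file`, `md5`), invisibly the full
#'   result list as attribute `"results"`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  p <- function(...) file.path(outdir, ...)

  cfg <- do.call(sim_config, c(list(seed = config$seed), config$sim))
  ds <- simulate_dataset(cfg, dir = p("data"))

  # --- loop annotation ---
  peaks_status <- classify_anchor_peaks(ds$peaks, ds$loops)
  gene_status <- classify_anchor_genes(ds$genes, peaks_status,
                                       chrom_sizes = ds$chrom_sizes)
  loop_cats <- categorize_loops(ds$loops, ds$genes, ds$chrom_sizes)
  snp_tab <- snps_in_loops(ds$snps, ds$loops)
  readr::write_tsv(dplyr::select(peaks_status, -"supporting_loops"),
                   p("anchor_status_peaks.tsv"), progress = FALSE)
  readr::write_tsv(gene_status, p("anchor_status_genes.tsv"), progress = FALSE)
  readr::write_tsv(
    dplyr::select(loop_cats, "loop_id", "mark", "category", "span_bp",
                  "span_class"),
    p("loop_categories.tsv"), progress = FALSE)
  readr::write_tsv(snp_tab, p("snp_loop_overlap.tsv"), progress = FALSE)

  # --- contact architecture ---
  cms <- bin_contacts(ds$loops, ds$chrom_sizes, config$resolution)
  comp <- purrr::map(cms, function(cm) {
    bal <- ice_balance(cm)
    track <- gene_density_track(ds$genes, cm)
    call_compartments(bal, track)
  })
  purrr::iwalk(comp, function(cc, chrom) {
    readr::write_tsv(as_tibble(cc), p(sprintf("compartments_%s.tsv", chrom)),
                     progress = FALSE)
  })
  doms <- segment_domains(ds$loops, ds$chrom_sizes, bin = config$domain_bin)
  write_domains_bed(doms, p("domains.bed"))
  readr::write_tsv(doms$coverage, p("domain_coverage.tsv"), progress = FALSE)

  # --- CRE annotation ---
  cre_ann <- annotate_cres(ds$cres, ds$genes, peaks_status, gene_status,
                           ds$loops, ds$expr, chrom_sizes = ds$chrom_sizes)
  readr::write_tsv(
    dplyr::mutate(cre_ann,
                  connecting_genes = vapply(.data$connecting_genes, paste,
                                            character(1), collapse = ",")),
    p("cre_annotations.tsv"), progress = FALSE)

  # --- hubs, two conditions ---
  active1 <- ds$condition$loops_1[ds$condition$loops_1$mark == "H3K4me3", ]
  active2 <- ds$condition$loops_2[ds$condition$loops_2$mark == "H3K4me3", ]
  hubs1 <- detect_hubs(active1, ds$genes, ds$expr,
                       min_degree = config$min_degree)
  hubs2 <- detect_hubs(active2, ds$genes, ds$expr,
                       min_degree = config$min_degree)
  deltas <- compare_conditions(hubs1, hubs2)
  readr::write_tsv(dplyr::select(deltas, "node_gene", "Nc", "Nm", "Ns",
                                 "category", "matched_by"),
                   p("hub_deltas.tsv"), progress = FALSE)
  enr <- hub_enrichment(hubs1, ds$tf_targets[[1]], ds$genes$gene_id,
                        alpha = config$alpha)
  readr::write_tsv(enr, p("hub_enrichment.tsv"), progress = FALSE)

  # --- network from the first hub node genes ---
  seeds <- head(stats::na.omit(hubs1$node_gene), 5L)
  net <- build_network(seeds, ds$loops[ds$loops$mark %in%
                                         c(ACTIVE_MARKS, "H3K27me3"), ],
                       ds$genes, ds$expr, hops = config$hops)
  write_network(net, p("network_edges.tsv"))

  # --- co-expression ---
  pairs <- ds$truth$pairs
  cx <- distance_matched_null(pairs, ds$genes, ds$expr,
                              n_sim = config$n_sim, mode = config$coexpr_mode,
                              anchor_genes = gene_status$gene_id[
                                gene_status$status == "anchor"],
                              seed = config$seed + 10L)
  jsonlite::write_json(
    list(observed_mean_pcc = cx$observed_mean_pcc, p_value = cx$p_value,
         n_pairs = cx$n_pairs, n_sim = cx$n_sim, mode = cx$null_mode,
         null_mean = mean(cx$null_means), seed = cx$seed),
    p("coexpression.json"), auto_unbox = TRUE, digits = NA)

  files <- sort(list.files(outdir, recursive = TRUE, full.names = TRUE))
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- tibble(stage = "all",
                     file = sub(paste0("^", outdir, "/?"), "", files),
                     md5 = unname(tools::md5sum(files)))
  jsonlite::write_json(manifest, p("manifest.json"), dataframe = "rows")
  attr(manifest, "results") <- list(
    dataset = ds, peaks_status = peaks_status, gene_status = gene_status,
    loop_categories = loop_cats, snps = snp_tab, compartments = comp,
    domains = doms, cres = cre_ann, hubs = list(hubs1, hubs2),
    deltas = deltas, enrichment = enr, network = net, coexpr = cx)
  manifest
}

# per-bin gene density used to orient compartment eigenvectors
gene_density_track <- function(genes, cm) {
  n <- nrow(cm$matrix)
  track <- numeric(n)
  sub <- genes[genes$chrom == cm$chrom, ]
  if (nrow(sub)) {
    b <- pmin(floor(((sub$start + sub$end) / 2) / cm$resolution) + 1L, n)
    tabs <- table(b)
    track[as.integer(names(tabs))] <- as.integer(tabs)
  }
  track
}

#' Summarise a pipeline run as Markdown
#'
#' @param outdir Directory written by [run_pipeline()].
#' @return Character vector of Markdown lines (also written to
#'   `report.md` inside `outdir`).
#' @export
pipeline_report <- function(outdir) {
  rd <- function(f) {
    path <- file.path(outdir, f)
    if (file.exists(path)) readr::read_tsv(path, show_col_types = FALSE,
                                           progress = FALSE) else NULL
  }
  lines <- c("# Pipeline report", "")
  lc <- rd("loop_categories.tsv")
  if (!is.null(lc)) {
    tab <- lc %>% dplyr::count(.data$mark, .data$category) %>%
      tidyr::pivot_wider(names_from = "category", values_from = "n",
                         values_fill = 0L)
    lines <- c(lines, "## Loop categories", "",
               paste(utils::capture.output(print(as.data.frame(tab))),
                     collapse = "\n"), "")
  } else lines <- c(lines, "## Loop categories", "", "_absent_", "")
  hd <- rd("hub_deltas.tsv")
  if (!is.null(hd) && nrow(hd)) {
    lines <- c(lines, "## Hub changes", "",
               paste(utils::capture.output(print(table(hd$category))),
                     collapse = "\n"), "")
  } else lines <- c(lines, "## Hub changes", "",
                    "no hubs at the configured minimum degree", "")
  cov <- rd("domain_coverage.tsv")
  if (!is.null(cov)) {
    lines <- c(lines, "## Domain coverage", "",
               paste(utils::capture.output(print(as.data.frame(cov))),
                     collapse = "\n"), "")
  }
  cj <- file.path(outdir, "coexpression.json")
  if (file.exists(cj)) {
    cx <- jsonlite::read_json(cj)
    lines <- c(lines, "## Co-expression", "",
               sprintf("observed mean PCC %.4f over %d pairs; empirical p %.4g (mode %s, %d simulations)",
                       cx$observed_mean_pcc, cx$n_pairs, cx$p_value,
                       cx$mode, cx$n_sim), "")
  }
  writeLines(lines, file.path(outdir, "report.md"))
  invisible(lines)
}
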