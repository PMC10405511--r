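# Shared fixtures, generated once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# default-scale dataset with planted structure (seed fixed for the suite)
sim_shared <- function() {
  if (is.null(.fixtures$ds)) {
    .fixtures$ds <- simulate_dataset(sim_config(seed = 42))
  }
  .fixtures$ds
}

# anchor/basal annotation layers on the shared dataset
sim_shared_ann <- function() {
  if (is.null(.fixtures$ann)) {
    ds <- sim_shared()
    ps <- classify_anchor_peaks(ds$peaks, ds$loops)
    gs <- classify_anchor_genes(ds$genes, ps, chrom_sizes = ds$chrom_sizes)
    .fixtures$ann <- list(peaks_status = ps, gene_status = gs)
  }
  .fixtures$ann
}

# small, fast configuration for replicate-heavy statistics
sim_small_config <- function(seed, pcc = 0, ...) {
  sim_config(seed = seed,
             n_genes = 400L, chrom_length = 6e6,
             loop_counts = c(H3K4me3 = 120L, H3K27me3 = 30L, H3K9me2 = 20L),
             n_planted_pairs = 50L, planted_pair_pcc = pcc,
             n_hubs = 6L, n_anchor_pool = 80L, n_basal_genes = 80L,
             n_k27_pool = 30L, n_k9_pool = 10L, n_bivalent = 4L,
             n_k27_basal = 10L, n_cres = 40L, n_snps = 30L, ...)
}

# toy gene table helpers for constructed cases
mk_genes <- function(...) {
  g <- tibble::tribble(...)
  g$biotype <- "protein_coding"
  g
}

mk_loop <- function(chrom, s1, e1, s2, e2, mark = "H3K4me3", pet = 5L,
                    fdr = 0.01, id = "L1") {
  tibble::tibble(loop_id = id, chrom_a = chrom, start_a = as.integer(s1),
                 end_a = as.integer(e1), chrom_b = chrom,
                 start_b = as.integer(s2), end_b = as.integer(e2),
                 mark = mark, pet_count = pet, fdr = fdr)
}
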