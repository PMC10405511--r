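# Binning, balancing, compartments, ACA and domain segmentation.

test_that("binning increments symmetric cells by PET weight", {
  sizes <- tibble::tibble(chrom = "chr1", length = 100000L)
  loops <- mk_loop("chr1", 25000, 25400, 65000, 65400, pet = 4L)
  cm <- bin_contacts(loops, sizes, resolution = 10000)[[1]]
  expect_equal(cm$matrix[3, 7], 4)
  expect_equal(cm$matrix[7, 3], 4)
  expect_equal(sum(cm$matrix), 8)
  expect_equal(sum(cm$mask), 2)
  # empty input: all-masked zero matrix
  cm0 <- bin_contacts(loops[0, ], sizes, 10000)[[1]]
  expect_true(all(cm0$matrix == 0))
  expect_false(any(cm0$mask))
  # resolution larger than the chromosome collapses to one bin
  cm1 <- bin_contacts(loops, sizes, 1e6)[[1]]
  expect_equal(dim(cm1$matrix), c(1L, 1L))
})

test_that("total matrix mass equals a hand count over random loops", {
  set.seed(4)
  sizes <- tibble::tibble(chrom = "chr1", length = 1000000L)
  n <- 20
  s1 <- sample.int(9e5, n); s2 <- sample.int(9e5, n)
  loops <- tibble::tibble(
    loop_id = sprintf("l%02d", 1:n),
    chrom_a = "chr1", start_a = pmin(s1, s2), end_a = pmin(s1, s2) + 400L,
    chrom_b = "chr1", start_b = pmax(s1, s2), end_b = pmax(s1, s2) + 400L,
    mark = "H3K4me3", pet_count = sample(1:9, n, TRUE), fdr = 0.01)
  cm <- bin_contacts(loops, sizes, 50000)[[1]]
  bin_of <- function(s, e) min(floor(((s + e) / 2) / 50000) + 1, nrow(cm$matrix))
  diag_w <- 0; off_w <- 0
  for (i in 1:n) {
    bi <- bin_of(loops$start_a[i], loops$end_a[i])
    bj <- bin_of(loops$start_b[i], loops$end_b[i])
    if (bi == bj) diag_w <- diag_w + loops$pet_count[i]
    else off_w <- off_w + loops$pet_count[i]
  }
  expect_equal(sum(cm$matrix), 2 * off_w + diag_w)
  expect_equal(cm$matrix, t(cm$matrix))
})

test_that("ICE balancing equalises marginals and factorises the raw matrix", {
  # constant matrix: already balanced, biases equal
  cm <- contact_matrix("c", 1000, matrix(2, 5, 5))
  bal <- ice_balance(cm)
  expect_true(bal$converged)
  expect_equal(max(bal$bias) / min(bal$bias), 1, tolerance = 1e-6)
  expect_equal(bal$matrix / bal$matrix[1, 1], cm$matrix / cm$matrix[1, 1])

  # diagonally dominant 3x3 with unequal marginals
  m <- diag(c(1, 2, 4)) + 0.5
  cm2 <- contact_matrix("c", 1000, m)
  bal2 <- ice_balance(cm2, tol = 1e-8, max_iter = 1000)
  s <- rowSums(bal2$matrix)
  expect_lt(sd(s) / mean(s), 1e-8)
  rec <- outer(bal2$bias, bal2$bias) * bal2$matrix
  expect_equal(rec, m, tolerance = 1e-8)

  # isolated zero row is masked, the rest balanced
  m3 <- matrix(1, 4, 4); m3[2, ] <- 0; m3[, 2] <- 0
  bal3 <- ice_balance(contact_matrix("c", 1000, m3))
  expect_false(bal3$mask[2])
  expect_true(is.na(bal3$bias[2]))
  expect_true(all(bal3$matrix[2, ] == 0))
  expect_error(ice_balance(contact_matrix("c", 1000, matrix(0, 3, 3))),
               "masked")
})

test_that("O/E strata each average to one", {
  set.seed(8)
  m <- matrix(runif(40 * 40, 1, 5), 40)
  m <- m + t(m)
  cm <- contact_matrix("c", 1000, m)
  oe <- chiahub:::observed_expected(cm)
  d <- abs(outer(1:40, 1:40, `-`))
  for (k in c(0, 1, 5, 20)) {
    expect_equal(mean(oe[d == k]), 1, tolerance = 1e-9)
  }
})

test_that("compartments recover a planted two-block checkerboard", {
  n <- 200
  block <- rep(1:2, each = n / 2)
  m <- matrix(1, n, n)
  m[block == 1, block == 1] <- 5
  m[block == 2, block == 2] <- 5
  cm <- contact_matrix("chr1", 1e5, m * 3)
  track <- ifelse(block == 1, 8, 1)   # block 1 is gene dense
  cc <- call_compartments(cm, track)
  expect_true(all(cc$label[block == 1] == "A"))
  expect_true(all(cc$label[block == 2] == "B"))
  # inverting the track flips every label
  cc2 <- call_compartments(cm, max(track) - track)
  expect_true(all(cc2$label[block == 1] == "B"))
  # a monotone transform preserving the ordering flips nothing
  cc3 <- call_compartments(cm, track^2)
  expect_identical(cc3$label, cc$label)
  expect_error(call_compartments(contact_matrix("c", 1, matrix(1, 5, 5)),
                                 rep(1, 5)), "10 retained")
})

test_that("ACA is linear, order-invariant and mass-conserving", {
  set.seed(9)
  mk <- function(n) {
    m <- matrix(runif(n * n), n); m <- m + t(m)
    contact_matrix(paste0("c", n), 1000, m)
  }
  a <- mk(30); b <- mk(50)
  g <- aggregate_chromosome_analysis(list(a, b), grid = 10)
  expect_equal(g, t(g))
  expect_equal(g, aggregate_chromosome_analysis(list(b, a), grid = 10))
  # two identical chromosomes double the single map
  expect_equal(aggregate_chromosome_analysis(list(a, a), grid = 10),
               2 * aggregate_chromosome_analysis(list(a), grid = 10))
  # a grid-sized chromosome passes through unchanged
  c10 <- mk(10)
  expect_equal(aggregate_chromosome_analysis(list(c10), grid = 10), c10$matrix)
  # block-size-weighted mean of grid cells equals the matrix mean
  g1 <- aggregate_chromosome_analysis(list(b), grid = 10)
  blocks <- pmin(floor((seq_len(50) - 1) * 10 / 50) + 1, 10)
  w <- as.vector(table(blocks))
  expect_equal(sum(g1 * outer(w, w)) / sum(outer(w, w)), mean(b$matrix))
  expect_error(aggregate_chromosome_analysis(list(a), grid = 1), "grid")
})

test_that("domain segmentation tiles the genome with the planted layout", {
  sizes <- tibble::tibble(chrom = "chr1", length = 200000L)
  active <- mk_loop("chr1", 10000, 10400, 50000, 50400, id = "a1")
  only_active <- segment_domains(active, sizes, bin = 10000,
                                 gap_tolerance_bins = 0)
  expect_true(all(only_active$segments$label %in% c("AID", "gap")))
  # same bin covered by two groups becomes MID
  k27 <- mk_loop("chr1", 10000, 10400, 120000, 120400, mark = "H3K27me3",
                 id = "r1")
  both <- segment_domains(dplyr::bind_rows(active, k27), sizes, bin = 10000,
                          gap_tolerance_bins = 0)
  seg_at <- function(res, pos) {
    s <- res$segments
    s$label[s$start <= pos & s$end > pos]
  }
  expect_equal(seg_at(both, 10000), "MID")
  expect_equal(seg_at(both, 50000), "AID")
  expect_equal(seg_at(both, 120000), "RID")
  # segments tile each chromosome exactly
  s <- both$segments
  expect_equal(s$start[1], 0L)
  expect_equal(s$end[nrow(s)], 200000L)
  expect_true(all(s$start[-1] == s$end[-nrow(s)]))
  expect_equal(sum(s$end - s$start), 200000L)

  # on the full synthetic layout, HID stays inside the centromeric block
  ds <- sim_shared()
  cfg <- sim_config(seed = 42)
  dom <- segment_domains(ds$loops, ds$chrom_sizes)
  cen <- round(cfg$centromere_span * cfg$chrom_length)
  hid <- dom$segments[dom$segments$label == "HID", ]
  arms_hid <- hid[hid$end <= cen[1] - 10000 | hid$start >= cen[2] + 10000, ]
  # H3K9me2 I-I loops (88%) are centromeric; only the small P-P/P-I
  # remainder can touch the arms
  expect_lt(sum(arms_hid$end - arms_hid$start),
            0.2 * sum(hid$end - hid$start))
  expect_true(all(dom$segments$label %in% c("AID", "RID", "HID", "MID", "gap")))
})
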