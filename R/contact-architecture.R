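# Binned contact matrices from loop calls, iterative-correction balancing,
# A/B compartment calls from the leading eigenvector of the O/E correlation
# matrix, the aggregate chromosome map, and interacting-domain segmentation.

#' Construct a contact-matrix object
#'
#' @param chrom Chromosome name.
#' @param resolution Bin size in bp.
#' @param matrix Symmetric nonnegative bin x bin matrix.
#' @param mask Logical vector, `TRUE` for retained bins; defaults to bins
#'   with a nonzero marginal.
#' @return Object of class `chiahub_contact_matrix`.
#' @export
contact_matrix <- function(chrom, resolution, matrix, mask = NULL) {
  if (!isTRUE(all.equal(matrix, t(matrix), tolerance = 1e-8))) {
    stop("contact matrix must be symmetric", call. = FALSE)
  }
  if (any(matrix < 0)) stop("contact matrix must be nonnegative", call. = FALSE)
  if (is.null(mask)) mask <- rowSums(matrix) > 0
  matrix[!mask, ] <- 0; matrix[, !mask] <- 0
  structure(list(chrom = chrom, resolution = resolution,
                 matrix = matrix, mask = mask),
            class = "chiahub_contact_matrix")
}

#' @export
print.chiahub_contact_matrix <- function(x, ...) {
  cat(sprintf("Contact matrix %s: %d bins @ %s bp (%d retained), total weight %g\n",
              x$chrom, nrow(x$matrix), format(x$resolution, big.mark = ","),
              sum(x$mask), sum(x$matrix)))
  invisible(x)
}

#' Bin loops into per-chromosome contact matrices
#'
#' Each intrachromosomal loop adds its PET count to the cell indexed by its
#' two anchor-midpoint bins (and the transpose cell; the diagonal is
#' allowed). Bins with zero marginal are masked.
#'
#' @param loops Loop tibble.
#' @param chrom_sizes Chromosome-size tibble.
#' @param resolution Bin size in bp.
#' @return Named list of [contact_matrix()] objects, one per chromosome.
#' @export
bin_contacts <- function(loops, chrom_sizes, resolution) {
  if (resolution <= 0) stop("resolution must be positive", call. = FALSE)
  intra <- loops[loops$chrom_a == loops$chrom_b, ]
  out <- purrr::map(seq_len(nrow(chrom_sizes)), function(ci) {
    chrom <- chrom_sizes$chrom[ci]
    n <- max(1L, as.integer(ceiling(chrom_sizes$length[ci] / resolution)))
    m <- matrix(0, n, n)
    sub <- intra[intra$chrom_a == chrom, ]
    if (nrow(sub)) {
      bi <- pmin(floor(((sub$start_a + sub$end_a) / 2) / resolution) + 1L, n)
      bj <- pmin(floor(((sub$start_b + sub$end_b) / 2) / resolution) + 1L, n)
      for (k in seq_len(nrow(sub))) {
        m[bi[k], bj[k]] <- m[bi[k], bj[k]] + sub$pet_count[k]
        if (bi[k] != bj[k]) m[bj[k], bi[k]] <- m[bj[k], bi[k]] + sub$pet_count[k]
      }
    }
    contact_matrix(chrom, resolution, m)
  })
  setNames(out, chrom_sizes$chrom)
}

#' Iterative-correction (ICE) balancing
#'
#' Repeatedly divides rows and columns by their marginals (renormalised to
#' mean 1 over retained bins each round) until the coefficient of variation
#' of the retained-bin marginals drops below `tol`. Biases are accumulated
#' so that `raw[i, j] = bias[i] * bias[j] * balanced[i, j]`.
#'
#' @param cm A `chiahub_contact_matrix`.
#' @param tol Convergence tolerance on the marginal CV.
#' @param max_iter Iteration cap; non-convergence warns and returns the
#'   current state with `converged = FALSE`.
#' @return A `chiahub_contact_matrix` with extra fields `bias` (NA for
#'   masked bins), `converged`, `n_iter`.
#' @export
ice_balance <- function(cm, tol = 1e-4, max_iter = 100L) {
  keep <- cm$mask & rowSums(cm$matrix) > 0
  if (!any(keep)) stop("all bins are masked", call. = FALSE)
  w <- cm$matrix[keep, keep, drop = FALSE]
  bias <- rep(1, sum(keep))
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    s <- rowSums(w)
    cv <- sd(s) / mean(s)
    if (is.na(cv)) cv <- 0
    if (cv < tol) { converged <- TRUE; break }
    s <- s / mean(s)
    w <- w / outer(s, s)
    bias <- bias * s
  }
  if (!converged) {
    warning("ICE did not converge in ", max_iter, " iterations", call. = FALSE)
  }
  balanced <- matrix(0, nrow(cm$matrix), ncol(cm$matrix))
  balanced[keep, keep] <- w
  full_bias <- rep(NA_real_, nrow(cm$matrix))
  full_bias[keep] <- bias
  out <- contact_matrix(cm$chrom, cm$resolution, balanced, mask = keep)
  out$bias <- full_bias
  out$converged <- converged
  out$n_iter <- it
  out
}

# observed / expected: each cell divided by the mean retained-bin contact at
# its exact bin distance (so each distance stratum has mean 1)
observed_expected <- function(cm) {
  keep <- which(cm$mask)
  m <- cm$matrix
  n <- nrow(m)
  oe <- matrix(NA_real_, n, n)
  d_keep <- abs(outer(keep, keep, `-`))
  sub <- m[keep, keep, drop = FALSE]
  for (d in unique(as.vector(d_keep))) {
    cells <- d_keep == d
    mu <- mean(sub[cells])
    if (mu > 0) sub[cells] <- sub[cells] / mu
  }
  oe[keep, keep] <- sub
  oe
}

#' Call A/B compartments
#'
#' Computes the observed/expected matrix of a balanced contact matrix, the
#' Pearson correlation matrix of its retained rows, and the leading
#' eigenvector. The eigenvector's sign is oriented so that positive bins
#' have the higher mean `orientation_track` (gene density or active-mark
#' coverage); positive bins are labelled `A`, negative `B`, masked bins
#' `masked`.
#'
#' @param cm Balanced `chiahub_contact_matrix`.
#' @param orientation_track Numeric per-bin track used to orient the
#'   eigenvector sign.
#' @return Tibble `bin`, `start`, `end`, `eigenvector`, `label` of class
#'   `chiahub_compartments` (attribute `chrom`).
#' @export
call_compartments <- function(cm, orientation_track) {
  keep <- which(cm$mask)
  if (length(keep) < 10) {
    stop("fewer than 10 retained bins: eigenvector unstable", call. = FALSE)
  }
  if (length(orientation_track) != nrow(cm$matrix)) {
    stop("orientation track length must equal bin count", call. = FALSE)
  }
  oe <- observed_expected(cm)[keep, keep]
  cc <- suppressWarnings(cor(oe))
  cc[!is.finite(cc)] <- 0
  ev <- eigen(cc, symmetric = TRUE)$vectors[, 1]
  pos <- ev > 0
  if (any(pos) && any(!pos)) {
    if (mean(orientation_track[keep][pos]) <
        mean(orientation_track[keep][!pos])) ev <- -ev
  }
  n <- nrow(cm$matrix)
  eig <- rep(NA_real_, n); eig[keep] <- ev
  out <- tibble(bin = seq_len(n),
                start = (seq_len(n) - 1L) * cm$resolution,
                end = seq_len(n) * cm$resolution,
                eigenvector = eig,
                label = dplyr::case_when(is.na(eig) ~ "masked",
                                         eig > 0 ~ "A", TRUE ~ "B"))
  attr(out, "chrom") <- cm$chrom
  class(out) <- c("chiahub_compartments", class(out))
  out
}

#' Aggregate chromosome analysis (ACA)
#'
#' Each chromosome's contact matrix is rescaled onto a common `grid x grid`
#' lattice by block-averaging its cells, then the rescaled maps are summed
#' across chromosomes.
#'
#' @param matrices List of `chiahub_contact_matrix` objects.
#' @param grid Lattice size (>= 2).
#' @return A symmetric `grid x grid` matrix.
#' @export
aggregate_chromosome_analysis <- function(matrices, grid = 100L) {
  if (grid < 2) stop("grid must be >= 2", call. = FALSE)
  if (!length(matrices)) stop("at least one matrix required", call. = FALSE)
  rescale_one <- function(cm) {
    m <- cm$matrix
    n <- nrow(m)
    # averaging operator: grid cell g collects bins with floor(i*grid/n) == g
    block <- pmin(floor((seq_len(n) - 1L) * grid / n) + 1L, grid)
    p <- matrix(0, grid, n)
    for (g in seq_len(grid)) {
      idx <- which(block == g)
      if (length(idx)) p[g, idx] <- 1 / length(idx)
    }
    p %*% m %*% t(p)
  }
  Reduce(`+`, lapply(matrices, rescale_one))
}

#' Segment the genome into interacting domains
#'
#' Bins covered by loop anchors of exactly one mark group become AID
#' (active), RID (H3K27me3) or HID (H3K9me2) after closing gaps of at most
#' `gap_tolerance_bins` uncovered bins inside a group's run; bins covered
#' by two or more groups become MID; uncovered bins are gaps. Segments tile
#' every chromosome.
#'
#' @param loops Loop tibble across marks.
#' @param chrom_sizes Chromosome-size tibble.
#' @param bin Bin size in bp (default 10 kb).
#' @param gap_tolerance_bins Maximal uncovered run bridged within a group.
#' @param groups Named list mapping group label to mark vector, in the
#'   order active, repressive, heterochromatic.
#' @return List with `segments` (tibble `chrom`, `start`, `end`, `label`)
#'   and `coverage` (tibble `label`, `bp`, `mb`, `percent`).
#' @export
segment_domains <- function(loops, chrom_sizes, bin = 10000L,
                            gap_tolerance_bins = 1L,
                            groups = list(AID = ACTIVE_MARKS,
                                          RID = "H3K27me3",
                                          HID = "H3K9me2")) {
  anchors <- loops_to_anchors(loops)
  close_gaps <- function(cov, tol) {
    if (tol < 1 || !any(cov)) return(cov)
    r <- rle(cov)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (!r$values[k] && r$lengths[k] <= tol &&
          k > 1 && k < length(r$values)) {
        cov[starts[k]:ends[k]] <- TRUE
      }
    }
    cov
  }
  segs <- purrr::map_dfr(seq_len(nrow(chrom_sizes)), function(ci) {
    chrom <- chrom_sizes$chrom[ci]
    len <- chrom_sizes$length[ci]
    n <- as.integer(ceiling(len / bin))
    covs <- purrr::map(groups, function(marks) {
      sub <- anchors[anchors$mark %in% marks & anchors$chrom == chrom, ]
      cov <- rep(FALSE, n)
      if (nrow(sub)) {
        for (k in seq_len(nrow(sub))) {
          b1 <- floor(sub$start[k] / bin) + 1L
          b2 <- min(floor((sub$end[k] - 1L) / bin) + 1L, n)
          cov[b1:b2] <- TRUE
        }
      }
      close_gaps(cov, gap_tolerance_bins)
    })
    hit <- Reduce(`+`, covs)
    label <- rep("gap", n)
    for (lab in names(groups)) label[covs[[lab]] & hit == 1L] <- lab
    label[hit >= 2L] <- "MID"
    r <- rle(label)
    ends <- pmin(cumsum(r$lengths) * bin, len)
    starts <- (cumsum(r$lengths) - r$lengths) * bin
    tibble(chrom = chrom, start = as.integer(starts),
           end = as.integer(ends), label = r$values)
  })
  coverage <- segs %>%
    dplyr::group_by(label = .data$label) %>%
    dplyr::summarise(bp = sum(.data$end - .data$start), .groups = "drop") %>%
    dplyr::mutate(mb = .data$bp / 1e6,
                  percent = 100 * .data$bp / sum(chrom_sizes$length))
  list(segments = segs, coverage = coverage)
}

#' Write domain segments as BED
#'
#' @param domains Output of [segment_domains()].
#' @param path Output path (label in column 4).
#' @export
write_domains_bed <- function(domains, path) {
  s <- domains$segments
  writeLines(sprintf("%s\t%d\t%d\t%s", s$chrom, s$start, s$end, s$label), path)
  invisible(path)
}
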