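# Readers and writers for the plain-text genomics formats the pipeline
# consumes. Column contracts (all tibbles, 0-based half-open coordinates):
#
#   genes:  gene_id, chrom, start, end, strand ("+"/"-"), biotype
#   peaks:  chrom, start, end, mark, intensity, summit (offset in peak or NA)
#   loops:  loop_id, chrom_a, start_a, end_a, chrom_b, start_b, end_b,
#           mark, pet_count, fdr
#   expression: gene_id plus one numeric column per tissue (wide, FPKM)
#   chrom_sizes: chrom, length

read_tsv_bare <- function(path, n_cols_min, what) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track |browser )", lines) & nzchar(lines)]
  if (!length(lines)) return(NULL)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < n_cols_min)
  if (length(bad)) {
    stop(sprintf("%s: malformed line %d (expected >= %d fields, got %d)",
                 what, bad[1], n_cols_min, nf[bad[1]]), call. = FALSE)
  }
  fields
}

num_or_stop <- function(x, what, field) {
  out <- suppressWarnings(as.numeric(x))
  if (anyNA(out)) {
    stop(sprintf("%s: non-numeric %s at line %d", what, field,
                 which(is.na(out))[1]), call. = FALSE)
  }
  out
}

#' Read gene models from GFF3
#'
#' Parses `gene` features from a GFF3 file into the package's gene tibble.
#' GFF3 1-based closed coordinates are converted to the internal 0-based
#' half-open convention. Biotype is taken from the `biotype` (or
#' `locus_type`) attribute and defaults to `"protein_coding"` when absent.
#'
#' @param path Path to a GFF3 file.
#' @param feature Feature type (column 3) to keep. Default `"gene"`.
#' @param protein_coding_only Keep only protein-coding genes. Default `TRUE`.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `biotype`, sorted by position.
#' @seealso [write_gff3()], [promoters_of()]
#' @export
read_gff3 <- function(path, feature = "gene", protein_coding_only = TRUE) {
  fields <- read_tsv_bare(path, 9L, "GFF3")
  empty <- tibble(gene_id = character(), chrom = character(),
                  start = integer(), end = integer(),
                  strand = character(), biotype = character())
  if (is.null(fields)) return(empty)
  keep <- vapply(fields, function(f) f[3] == feature, logical(1))
  fields <- fields[keep]
  if (!length(fields)) return(empty)
  attr_get <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]+)"), attrs))[[1]]
    if (length(m) == 2) m[2] else NA_character_
  }
  rows <- purrr::map(fields, function(f) {
    id <- attr_get(f[9], "ID")
    if (is.na(id)) stop("GFF3: gene feature without ID attribute", call. = FALSE)
    bt <- attr_get(f[9], "biotype")
    if (is.na(bt)) bt <- attr_get(f[9], "locus_type")
    if (is.na(bt)) bt <- "protein_coding"
    tibble(gene_id = id, chrom = f[1],
           start = as.integer(num_or_stop(f[4], "GFF3", "start")) - 1L,
           end = as.integer(num_or_stop(f[5], "GFF3", "end")),
           strand = f[7], biotype = bt)
  })
  genes <- dplyr::bind_rows(rows)
  if (anyDuplicated(genes$gene_id)) {
    stop("GFF3: duplicate gene ID: ",
         genes$gene_id[duplicated(genes$gene_id)][1], call. = FALSE)
  }
  if (protein_coding_only) {
    genes <- dplyr::filter(genes, .data$biotype == "protein_coding")
  }
  validate_intervals(genes, "genes")
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("GFF3: strand must be '+' or '-' for gene features", call. = FALSE)
  }
  dplyr::arrange(genes, .data$chrom, .data$start)
}

#' Write gene models to GFF3
#'
#' @param genes Gene tibble (see [read_gff3()] for the column contract).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  validate_intervals(genes, "genes")
  lines <- sprintf("%s\t.\tgene\t%d\t%d\t.\t%s\t.\tID=%s;biotype=%s",
                   genes$chrom, genes$start + 1L, genes$end,
                   genes$strand, genes$gene_id, genes$biotype)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read peaks (or SNPs) from BED / narrowPeak
#'
#' Accepts BED3/BED6 and the 10-column narrowPeak dialect. For narrowPeak the
#' intensity is the signalValue (column 7) and the summit offset comes from
#' column 10 (`-1` becomes `NA`); for BED6 the score column is the intensity.
#'
#' @param path Input file.
#' @param mark Mark label stored in the `mark` column (e.g. `"H3K4me3"`,
#'   `"ATAC"`, `"TF:MYC2"`, `"SNP"`).
#' @param chrom_sizes Optional chromosome-size tibble; when given, records on
#'   unknown chromosomes raise an error.
#' @return Peak tibble: `chrom`, `start`, `end`, `mark`, `intensity`, `summit`.
#' @export
read_bed <- function(path, mark, chrom_sizes = NULL) {
  fields <- read_tsv_bare(path, 3L, "BED")
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  mark = character(), intensity = numeric(), summit = integer())
  if (is.null(fields)) return(empty)
  nf <- lengths(fields)
  get_col <- function(i) vapply(fields, function(f) {
    if (length(f) >= i) f[i] else NA_character_
  }, character(1))
  peaks <- tibble(
    chrom = get_col(1),
    start = as.integer(num_or_stop(get_col(2), "BED", "start")),
    end = as.integer(num_or_stop(get_col(3), "BED", "end")),
    mark = mark,
    intensity = dplyr::case_when(
      nf >= 10 ~ suppressWarnings(as.numeric(get_col(7))),
      nf >= 5 ~ suppressWarnings(as.numeric(get_col(5))),
      TRUE ~ 0
    ),
    summit = if (all(nf >= 10)) {
      s <- as.integer(num_or_stop(get_col(10), "narrowPeak", "summit"))
      ifelse(s < 0, NA_integer_, s)
    } else NA_integer_
  )
  peaks$intensity[is.na(peaks$intensity)] <- 0
  if (any(peaks$intensity < 0)) stop("BED: negative intensity", call. = FALSE)
  ok <- is.na(peaks$summit) | peaks$summit < (peaks$end - peaks$start)
  if (!all(ok)) stop("narrowPeak: summit offset outside peak", call. = FALSE)
  validate_intervals(peaks, "peaks", chrom_sizes)
  peaks
}

#' Write peaks to narrowPeak
#'
#' Always emits the 10-column narrowPeak dialect so that intensity and summit
#' survive a round trip; `NA` summit is written as `-1`.
#'
#' @inheritParams write_gff3
#' @param peaks Peak tibble.
#' @export
write_bed <- function(peaks, path) {
  validate_intervals(peaks, "peaks")
  summit <- ifelse(is.na(peaks$summit), -1L, peaks$summit)
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t.\t%s\t-1\t-1\t%d",
                   peaks$chrom, peaks$start, peaks$end, peaks$mark,
                   format(peaks$intensity, trim = TRUE, scientific = FALSE),
                   summit)
  writeLines(lines, path)
  invisible(path)
}

#' Read chromatin loops from BEDPE
#'
#' Columns 1-6 are the two anchors; by default column 8 holds the PET count
#' and column 11 the loop FDR (both configurable — ChIA-PET exports have no
#' single BEDPE dialect). Anchors are normalised so `anchor_a <= anchor_b`
#' (by chromosome, then start), loops failing the FDR filter are dropped,
#' and duplicates on (anchors, mark) keep the maximal PET count.
#'
#' @inheritParams read_bed
#' @param pet_col,fdr_col 1-based column indices of the PET count and FDR
#'   (`NA` to skip; missing FDR defaults to 0).
#' @param fdr_max Keep loops with `fdr < fdr_max`; `NA` disables filtering.
#' @return Loop tibble: `loop_id`, `chrom_a`, `start_a`, `end_a`, `chrom_b`,
#'   `start_b`, `end_b`, `mark`, `pet_count`, `fdr`.
#' @export
read_bedpe <- function(path, mark, pet_col = 8L, fdr_col = 11L,
                       fdr_max = 0.05, chrom_sizes = NULL) {
  fields <- read_tsv_bare(path, 6L, "BEDPE")
  empty <- tibble(loop_id = character(),
                  chrom_a = character(), start_a = integer(), end_a = integer(),
                  chrom_b = character(), start_b = integer(), end_b = integer(),
                  mark = character(), pet_count = integer(), fdr = numeric())
  if (is.null(fields)) return(empty)
  get_col <- function(i) vapply(fields, function(f) {
    if (!is.na(i) && length(f) >= i) f[i] else NA_character_
  }, character(1))
  pet <- suppressWarnings(as.numeric(get_col(pet_col)))
  pet[is.na(pet)] <- 1
  fdr <- suppressWarnings(as.numeric(get_col(fdr_col)))
  fdr[is.na(fdr)] <- 0
  loops <- tibble(
    chrom_a = get_col(1),
    start_a = as.integer(num_or_stop(get_col(2), "BEDPE", "start1")),
    end_a = as.integer(num_or_stop(get_col(3), "BEDPE", "end1")),
    chrom_b = get_col(4),
    start_b = as.integer(num_or_stop(get_col(5), "BEDPE", "start2")),
    end_b = as.integer(num_or_stop(get_col(6), "BEDPE", "end2")),
    mark = mark, pet_count = as.integer(pet), fdr = fdr
  )
  if (any(loops$pet_count < 1)) stop("BEDPE: pet_count must be >= 1", call. = FALSE)
  if (any(loops$fdr < 0 | loops$fdr > 1)) stop("BEDPE: fdr outside [0, 1]", call. = FALSE)
  if (!is.na(fdr_max)) loops <- dplyr::filter(loops, .data$fdr < fdr_max)
  normalize_loops(loops, chrom_sizes)
}

# Sort anchors within each loop, deduplicate on (anchors, mark) keeping max
# pet_count, validate both anchor tables, and assign stable loop ids.
normalize_loops <- function(loops, chrom_sizes = NULL) {
  if (nrow(loops)) {
    flip <- loops$chrom_a > loops$chrom_b |
      (loops$chrom_a == loops$chrom_b & loops$start_a > loops$start_b)
    if (any(flip)) {
      tmp <- loops[flip, c("chrom_a", "start_a", "end_a")]
      loops[flip, c("chrom_a", "start_a", "end_a")] <-
        loops[flip, c("chrom_b", "start_b", "end_b")]
      loops[flip, c("chrom_b", "start_b", "end_b")] <- tmp
    }
    loops <- loops %>%
      dplyr::group_by(.data$chrom_a, .data$start_a, .data$end_a,
                      .data$chrom_b, .data$start_b, .data$end_b, .data$mark) %>%
      dplyr::summarise(pet_count = max(.data$pet_count),
                       fdr = min(.data$fdr), .groups = "drop") %>%
      dplyr::arrange(.data$chrom_a, .data$start_a, .data$chrom_b, .data$start_b)
  }
  validate_intervals(
    dplyr::rename(loops[, c("chrom_a", "start_a", "end_a")],
                  chrom = "chrom_a", start = "start_a", end = "end_a"),
    "loop anchor A", chrom_sizes)
  validate_intervals(
    dplyr::rename(loops[, c("chrom_b", "start_b", "end_b")],
                  chrom = "chrom_b", start = "start_b", end = "end_b"),
    "loop anchor B", chrom_sizes)
  loops$loop_id <- if (nrow(loops)) sprintf("loop_%06d", seq_len(nrow(loops))) else character()
  dplyr::relocate(loops, "loop_id")
}

#' Write loops to BEDPE
#'
#' Emits the dialect [read_bedpe()] reads by default: anchors in columns 1-6,
#' loop id in 7, PET count in 8, strands (`.`) in 9-10, FDR in 11.
#'
#' @param loops Loop tibble.
#' @param path Output path.
#' @export
write_bedpe <- function(loops, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s\t%d\t.\t.\t%s",
                   loops$chrom_a, loops$start_a, loops$end_a,
                   loops$chrom_b, loops$start_b, loops$end_b,
                   loops$loop_id, loops$pet_count,
                   format(loops$fdr, trim = TRUE, scientific = FALSE))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a gene-by-tissue FPKM table
#'
#' TSV with a header row `gene_id<TAB><tissue>...`; values must be
#' nonnegative and finite, and gene/tissue labels unique.
#'
#' @param path File path.
#' @return Wide tibble: `gene_id` plus one numeric column per tissue.
#' @export
read_expression <- function(path) {
  expr <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(expr)[1] <- "gene_id"
  validate_expression(expr)
}

validate_expression <- function(expr) {
  if (anyDuplicated(expr$gene_id)) stop("expression: duplicate gene_id", call. = FALSE)
  if (anyDuplicated(names(expr))) stop("expression: duplicate tissue label", call. = FALSE)
  vals <- as.matrix(expr[, -1, drop = FALSE])
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("expression: FPKM values must be nonnegative and finite", call. = FALSE)
  }
  as_tibble(expr)
}

#' @rdname read_expression
#' @param expr Expression tibble.
#' @export
write_expression <- function(expr, path) {
  readr::write_tsv(expr, path, progress = FALSE)
  invisible(path)
}

#' Read a two-column chromosome-size table
#'
#' @param path TSV with columns chromosome name and length (bp), no header.
#' @return Tibble with columns `chrom`, `length`.
#' @export
read_chrom_sizes <- function(path) {
  fields <- read_tsv_bare(path, 2L, "chrom sizes")
  tibble(chrom = vapply(fields, `[`, character(1), 1),
         length = as.integer(num_or_stop(vapply(fields, `[`, character(1), 2),
                                         "chrom sizes", "length")))
}

#' @rdname read_chrom_sizes
#' @param chrom_sizes Chromosome-size tibble.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  writeLines(sprintf("%s\t%d", chrom_sizes$chrom, chrom_sizes$length), path)
  invisible(path)
}

#' Transcription start sites
#'
#' TSS is the 5' end of the gene: `start` on the plus strand, `end - 1` on
#' the minus strand (0-based).
#'
#' @param genes Gene tibble.
#' @return `genes` with an added integer `tss` column.
#' @export
tss_of <- function(genes) {
  dplyr::mutate(genes,
                tss = ifelse(.data$strand == "+", .data$start, .data$end - 1L))
}

#' Strand-aware promoter windows
#'
#' The promoter is the window from `upstream` bp upstream to `downstream` bp
#' downstream of the TSS (defaults 1 kb / 0.5 kb), clipped at chromosome
#' bounds so edge genes stay classifiable.
#'
#' @param genes Gene tibble.
#' @param upstream,downstream Window extents in bp around the TSS.
#' @param chrom_sizes Optional chromosome-size tibble used for right-clipping.
#' @return Tibble `gene_id`, `chrom`, `start`, `end` of promoter windows.
#' @export
promoters_of <- function(genes, upstream = 1000L, downstream = 500L,
                         chrom_sizes = NULL) {
  g <- tss_of(genes)
  plus <- g$strand == "+"
  start <- ifelse(plus, g$tss - upstream, g$tss - downstream + 1L)
  end <- ifelse(plus, g$tss + downstream, g$tss + upstream + 1L)
  start <- pmax(start, 0L)
  if (!is.null(chrom_sizes)) {
    len <- chrom_sizes$length[match(g$chrom, chrom_sizes$chrom)]
    end <- pmin(end, len)
  }
  tibble(gene_id = g$gene_id, chrom = g$chrom,
         start = as.integer(start), end = as.integer(end))
}

# Gene association region used for anchor-gene assignment and anchor/basal
# gene status: 1 kb upstream of the TSS through the TTS.
gene_regions_of <- function(genes, upstream = 1000L, chrom_sizes = NULL) {
  g <- tss_of(genes)
  plus <- g$strand == "+"
  start <- ifelse(plus, g$start - upstream, g$start)
  end <- ifelse(plus, g$end, g$end + upstream)
  start <- pmax(start, 0L)
  if (!is.null(chrom_sizes)) {
    len <- chrom_sizes$length[match(g$chrom, chrom_sizes$chrom)]
    end <- pmin(end, len)
  }
  tibble(gene_id = g$gene_id, chrom = g$chrom,
         start = as.integer(start), end = as.integer(end))
}
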