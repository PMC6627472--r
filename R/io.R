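#' Read a Bismark-style per-cytosine report
#'
#' Reads the six-column cytosine report TSV (chrom, 1-based position, strand,
#' methylated read count, unmethylated read count, context) emitted by
#' bisulfite aligners. Only CG-context rows are kept; other contexts are
#' skipped with a message giving the count. Positions are converted to the
#' package-wide 0-based convention.
#'
#' @param path Path to the TSV (gzip transparently supported).
#' @param stage Optional stage label recorded in a `stage` column.
#' @param merge_symmetric_cpg If `TRUE`, the plus-strand cytosine at `pos` and
#'   the minus-strand cytosine at `pos + 1` of one CpG dyad are pooled into a
#'   single plus-strand record at the dyad start. Default `FALSE` (per-strand
#'   records are kept, since symmetric pooling is an analysis choice).
#' @return A tibble of cytosine sites with columns `chrom`, `pos` (0-based),
#'   `strand`, `context`, `meth_reads`, `total_reads`, `level` and, when
#'   `stage` is given, `stage`.
#' @export
read_cytosine_report <- function(path, stage = NULL, merge_symmetric_cpg = FALSE) {
  stopifnot(file.exists(path))
  raw <- readr::read_tsv(
    path,
    col_names = c("chrom", "pos1", "strand", "meth_reads", "unmeth_reads", "context"),
    col_types = readr::cols(
      chrom = readr::col_character(), pos1 = readr::col_integer(),
      strand = readr::col_character(), meth_reads = readr::col_integer(),
      unmeth_reads = readr::col_integer(), context = readr::col_character()
    ),
    progress = FALSE
  )
  probs <- readr::problems(raw)
  if (nrow(probs) > 0L) {
    stop(sprintf("malformed cytosine report line %d in %s: expected %s, got %s",
                 probs$row[1L], path, probs$expected[1L], probs$actual[1L]),
         call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    out <- tibble::tibble(
      chrom = character(), pos = integer(), strand = character(),
      context = character(), meth_reads = integer(), total_reads = integer(),
      level = double()
    )
    if (!is.null(stage)) out$stage <- character()
    return(out)
  }
  bad <- which(is.na(raw$pos1) | is.na(raw$meth_reads) | is.na(raw$unmeth_reads) |
                 !(raw$strand %in% c("+", "-")))
  if (length(bad) > 0L) {
    stop(sprintf("malformed cytosine report line %d in %s", bad[1L], path),
         call. = FALSE)
  }
  n_skipped <- sum(raw$context != "CG")
  if (n_skipped > 0L) {
    message(sprintf("read_cytosine_report: skipped %d non-CG context site(s)", n_skipped))
  }
  out <- raw |>
    dplyr::filter(.data$context == "CG") |>
    dplyr::transmute(
      chrom = .data$chrom,
      pos = .data$pos1 - 1L,
      strand = .data$strand,
      context = .data$context,
      meth_reads = .data$meth_reads,
      total_reads = .data$meth_reads + .data$unmeth_reads
    )
  if (merge_symmetric_cpg) {
    out <- out |>
      dplyr::mutate(pos = dplyr::if_else(.data$strand == "-", .data$pos - 1L, .data$pos)) |>
      dplyr::group_by(.data$chrom, .data$pos) |>
      dplyr::summarise(
        strand = "+", context = "CG",
        meth_reads = sum(.data$meth_reads),
        total_reads = sum(.data$total_reads),
        .groups = "drop"
      )
  }
  out <- out |>
    dplyr::mutate(level = ifelse(.data$total_reads > 0,
                                 .data$meth_reads / .data$total_reads, NA_real_)) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$strand)
  if (!is.null(stage)) out$stage <- stage
  out
}

#' Write a per-cytosine report
#'
#' Inverse of [read_cytosine_report()]: writes the six-column 1-based TSV.
#'
#' @param sites Site tibble with `chrom`, `pos`, `strand`, `meth_reads`,
#'   `total_reads` (and `context`, defaulting to CG).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(sites, path) {
  assert_columns(sites, c("chrom", "pos", "strand", "meth_reads", "total_reads"))
  tibble::tibble(
    chrom = sites$chrom,
    pos1 = sites$pos + 1L,
    strand = sites$strand,
    meth = sites$meth_reads,
    unmeth = sites$total_reads - sites$meth_reads,
    context = if ("context" %in% names(sites)) sites$context else "CG"
  ) |>
    readr::write_tsv(path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

new_genome_annotation <- function(features, chrom_lengths) {
  structure(
    list(features = features, chrom_lengths = as_chrom_lengths(chrom_lengths)),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("<genome_annotation>\n")
  cat(sprintf("  %d chromosome(s), %s bp total\n",
              nrow(x$chrom_lengths), format(sum(x$chrom_lengths$length), big.mark = ",")))
  counts <- table(x$features$kind)
  cat("  features:", paste(sprintf("%s=%d", names(counts), counts), collapse = ", "), "\n")
  invisible(x)
}

#' Read genome annotation from GFF3 and a TE BED file
#'
#' Genes and exons come from a GFF3 file (parsed with \pkg{rtracklayer});
#' transposable elements from a BED6+1 file whose seventh column carries one of
#' the five TE class labels (Gypsy, Copia, LTR-other, LINE, DNA) or a label
#' mapped onto them via `te_class_map`. All coordinates are converted to
#' 0-based half-open.
#'
#' @param gff_path Path to GFF3 with `gene` and `exon` features.
#' @param te_bed_path Optional path to the TE BED6+1 file; `NULL` means an
#'   annotation without TEs (downstream TE analyses then return empty results).
#' @param chrom_lengths Chromosome lengths: a two-column TSV path
#'   (chrom, length), a tibble, or a named vector. If `NULL`, lengths are
#'   inferred from the furthest annotated end (with a message).
#' @param te_class_map Optional named character vector mapping foreign TE
#'   labels to the five-way vocabulary.
#' @return A `genome_annotation`: a list with a `features` tibble (`chrom`,
#'   `start`, `end`, `strand`, `kind`, `id`, `parent`, `te_class`) and a
#'   `chrom_lengths` tibble.
#' @export
read_annotation <- function(gff_path, te_bed_path = NULL, chrom_lengths = NULL,
                            te_class_map = NULL) {
  gff <- rtracklayer::import(gff_path, format = "gff3")
  type <- as.character(gff$type)
  genes_gr <- gff[type == "gene"]
  exons_gr <- gff[type == "exon"]
  gene_ids <- as.character(genes_gr$ID)
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene IDs in GFF: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  }
  genes <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(genes_gr)),
    start = GenomicRanges::start(genes_gr) - 1L,
    end = GenomicRanges::end(genes_gr),
    strand = as.character(GenomicRanges::strand(genes_gr)),
    kind = "gene", id = gene_ids, parent = NA_character_,
    te_class = NA_character_
  )
  exon_parent <- vapply(exons_gr$Parent, function(p) as.character(p)[1L], character(1))
  exons <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(exons_gr)),
    start = GenomicRanges::start(exons_gr) - 1L,
    end = GenomicRanges::end(exons_gr),
    strand = as.character(GenomicRanges::strand(exons_gr)),
    kind = "exon",
    id = if (!is.null(exons_gr$ID)) as.character(exons_gr$ID) else
      paste0(exon_parent, "_exon", seq_along(exon_parent)),
    parent = exon_parent, te_class = NA_character_
  )
  tes <- tibble::tibble(
    chrom = character(), start = integer(), end = integer(), strand = character(),
    kind = character(), id = character(), parent = character(), te_class = character()
  )
  if (!is.null(te_bed_path)) {
    bed <- readr::read_tsv(
      te_bed_path,
      col_names = c("chrom", "start", "end", "id", "score", "strand", "te_class"),
      col_types = "ciicdcc", progress = FALSE
    )
    if (nrow(bed) > 0L) {
      cls <- bed$te_class
      if (!is.null(te_class_map)) {
        mapped <- cls %in% names(te_class_map)
        cls[mapped] <- te_class_map[cls[mapped]]
      }
      unknown <- setdiff(unique(cls), TE_CLASSES)
      if (length(unknown) > 0L) {
        stop("TE class label(s) outside the five-way vocabulary and not mapped: ",
             paste(unknown, collapse = ", "), call. = FALSE)
      }
      tes <- tibble::tibble(
        chrom = bed$chrom, start = bed$start, end = bed$end,
        strand = ifelse(bed$strand %in% c("+", "-"), bed$strand, "."),
        kind = "TE", id = bed$id, parent = NA_character_, te_class = cls
      )
    }
  }
  features <- dplyr::bind_rows(genes, exons, tes)
  # exons must lie within their gene
  if (nrow(exons) > 0L) {
    chk <- exons |>
      dplyr::left_join(genes |> dplyr::select("id", gstart = "start", gend = "end"),
                       by = c("parent" = "id"))
    if (any(is.na(chk$gstart)) || any(chk$start < chk$gstart | chk$end > chk$gend)) {
      stop("exon outside its parent gene interval (or orphan exon)", call. = FALSE)
    }
  }
  if (is.null(chrom_lengths)) {
    message("read_annotation: chromosome lengths inferred from annotation extent")
    chrom_lengths <- features |>
      dplyr::group_by(chrom = .data$chrom) |>
      dplyr::summarise(length = max(.data$end), .groups = "drop")
  } else if (is.character(chrom_lengths) && length(chrom_lengths) == 1L) {
    chrom_lengths <- readr::read_tsv(chrom_lengths, col_names = c("chrom", "length"),
                                     col_types = "ci", progress = FALSE)
  }
  new_genome_annotation(features, chrom_lengths)
}

#' Write gene/exon annotation to GFF3 and TEs to BED6+1
#'
#' @param annotation A `genome_annotation`.
#' @param gff_path Output GFF3 path for genes and exons.
#' @param te_bed_path Optional output BED6+1 path for TEs.
#' @param chrom_lengths_path Optional output two-column TSV of chromosome lengths.
#' @return `gff_path`, invisibly.
#' @export
write_annotation <- function(annotation, gff_path, te_bed_path = NULL,
                             chrom_lengths_path = NULL) {
  stopifnot(inherits(annotation, "genome_annotation"))
  f <- annotation$features
  gx <- f |> dplyr::filter(.data$kind %in% c("gene", "exon"))
  attr_col <- ifelse(gx$kind == "gene",
                     paste0("ID=", gx$id),
                     paste0("ID=", gx$id, ";Parent=", gx$parent))
  lines <- sprintf("%s\tmethdev\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   gx$chrom, gx$kind, gx$start + 1L, gx$end, gx$strand, attr_col)
  writeLines(c("##gff-version 3", lines), gff_path)
  if (!is.null(te_bed_path)) {
    te <- f |> dplyr::filter(.data$kind == "TE")
    readr::write_tsv(
      tibble::tibble(chrom = te$chrom, start = te$start, end = te$end, id = te$id,
                     score = 0, strand = ifelse(te$strand %in% c("+", "-"), te$strand, "."),
                     te_class = te$te_class),
      te_bed_path, col_names = FALSE, progress = FALSE
    )
  }
  if (!is.null(chrom_lengths_path)) {
    readr::write_tsv(annotation$chrom_lengths, chrom_lengths_path,
                     col_names = FALSE, progress = FALSE)
  }
  invisible(gff_path)
}

#' Write regions to BED6
#'
#' Writes 0-based half-open BED6 with `name` = status and
#' `score = round(1000 * delta)` clamped to `[0, 1000]`.
#'
#' @param regions Tibble with `chrom`, `start`, `end`, `status` and optionally
#'   `delta` (defaults to 0).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  assert_columns(regions, c("chrom", "start", "end", "status"))
  if (nrow(regions) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  delta <- if ("delta" %in% names(regions)) regions$delta else rep(0, nrow(regions))
  chrom <- as.character(regions$chrom)
  ord <- order(chrom, regions$start, method = "radix")
  score <- pmin(pmax(round(1000 * delta), 0), 1000)
  readr::write_tsv(
    tibble::tibble(chrom = chrom, start = regions$start, end = regions$end,
                   name = regions$status, score = score, strand = ".")[ord, ],
    path, col_names = FALSE, progress = FALSE
  )
  invisible(path)
}

#' Read a BED6 region file written by [write_regions_bed()]
#'
#' @param path Path to a BED6 file.
#' @return A tibble with `chrom`, `start`, `end`, `status`, `score`, `strand`.
#' @export
read_regions_bed <- function(path) {
  if (file.size(path) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer(),
                          status = character(), score = double(), strand = character()))
  }
  readr::read_tsv(path,
                  col_names = c("chrom", "start", "end", "status", "score", "strand"),
                  col_types = "ciicdc", progress = FALSE) |>
    dplyr::mutate(score = as.double(.data$score))
}

#' Read a raw count matrix with feature lengths
#'
#' @param path TSV with columns `feature_id`, `length`, then one column per
#'   sample of non-negative integer counts.
#' @return A tibble in the same layout.
#' @export
read_count_matrix <- function(path) {
  counts <- readr::read_tsv(path, col_types = readr::cols(
    feature_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  assert_columns(counts, c("feature_id", "length"), "count matrix")
  if (any(counts$length <= 0)) stop("all feature lengths must be > 0", call. = FALSE)
  if (anyDuplicated(names(counts))) stop("duplicate sample columns", call. = FALSE)
  counts
}

#' Read an ortholog pair table
#'
#' @param path TSV with columns `gene_a`, `gene_b`, `consensus_fraction`,
#'   `consensus_length_bp`.
#' @return A tibble.
#' @export
read_ortholog_pairs <- function(path) {
  readr::read_tsv(path, col_types = "ccdi", progress = FALSE) |>
    assert_columns(c("gene_a", "gene_b", "consensus_fraction", "consensus_length_bp"),
                   "ortholog pair table")
}
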