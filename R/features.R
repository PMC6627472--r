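# Feature geography: promoters, introns, downstream flanks, intergenic space,
# site-to-feature assignment, MP/MGB identification, metaprofiles and
# TE-distance analyses.

# Precedence used when a site overlaps several feature kinds.
CATEGORY_PRECEDENCE <- c("exon", "intron", "promoter", "downstream1kb", "TE", "intergenic")

#' Derive promoters, introns, downstream flanks and intergenic space
#'
#' Promoter = 1 kb upstream of the TSS respecting strand, truncated at
#' chromosome bounds; downstream1kb analogous at the TES; introns = gene minus
#' its exons; intergenic = genome minus (genes, promoters, downstream flanks).
#' TEs may lie inside intergenic space; they are not subtracted.
#'
#' @param annotation A `genome_annotation` with genes and exons.
#' @param promoter_bp Promoter length in bp (default 1000).
#' @param downstream_bp Downstream flank length in bp (default 1000).
#' @return A `genome_annotation` whose features tibble gains `promoter`,
#'   `downstream1kb`, `intron` and `intergenic` rows.
#' @export
derive_features <- function(annotation, promoter_bp = 1000L, downstream_bp = 1000L) {
  stopifnot(inherits(annotation, "genome_annotation"))
  f <- annotation$features
  cl <- annotation$chrom_lengths
  genes <- f |> dplyr::filter(.data$kind == "gene")
  exons <- f |> dplyr::filter(.data$kind == "exon")
  if (nrow(genes) > 0L && nrow(exons) > 0L) {
    no_exon <- setdiff(genes$id, exons$parent)
    if (length(no_exon) > 0L) {
      warning(sprintf("%d gene(s) without exons; gene body treated as a single exon",
                      length(no_exon)))
      exons <- dplyr::bind_rows(exons, genes |>
        dplyr::filter(.data$id %in% no_exon) |>
        dplyr::mutate(kind = "exon", parent = .data$id,
                      id = paste0(.data$id, "_exon1")))
    }
  } else if (nrow(genes) > 0L) {
    exons <- genes |>
      dplyr::mutate(kind = "exon", parent = .data$id, id = paste0(.data$id, "_exon1"))
  }

  chrom_len <- setNames(cl$length, cl$chrom)
  plus <- genes$strand == "+"
  promoters <- genes |>
    dplyr::mutate(
      pstart = ifelse(plus, pmax(0L, .data$start - promoter_bp), .data$end),
      pend = ifelse(plus, .data$start,
                    pmin(chrom_len[.data$chrom], .data$end + promoter_bp)),
      start = as.integer(.data$pstart), end = as.integer(.data$pend),
      kind = "promoter", parent = .data$id, id = paste0(.data$id, "_promoter")
    ) |>
    dplyr::select(-"pstart", -"pend") |>
    dplyr::filter(.data$end > .data$start)
  downstream <- genes |>
    dplyr::mutate(
      dstart = ifelse(plus, .data$end, pmax(0L, .data$start - downstream_bp)),
      dend = ifelse(plus, pmin(chrom_len[.data$chrom], .data$end + downstream_bp),
                    .data$start),
      start = as.integer(.data$dstart), end = as.integer(.data$dend),
      kind = "downstream1kb", parent = .data$id, id = paste0(.data$id, "_down1kb")
    ) |>
    dplyr::select(-"dstart", -"dend") |>
    dplyr::filter(.data$end > .data$start)

  introns <- tibble::tibble(chrom = character(), start = integer(), end = integer(),
                            strand = character(), kind = character(), id = character(),
                            parent = character(), te_class = character())
  if (nrow(genes) > 0L) {
    gene_gr <- tbl_to_granges(genes)
    names(gene_gr) <- genes$id
    exon_by_gene <- split(tbl_to_granges(exons), exons$parent)
    intron_list <- purrr::imap(as.list(exon_by_gene), function(ex, gid) {
      gi <- which(genes$id == gid)
      ir <- GenomicRanges::setdiff(gene_gr[gi], GenomicRanges::reduce(ex),
                                   ignore.strand = TRUE)
      if (length(ir) == 0L) return(NULL)
      tibble::tibble(
        chrom = as.character(GenomicRanges::seqnames(ir)),
        start = GenomicRanges::start(ir) - 1L,
        end = GenomicRanges::end(ir),
        strand = genes$strand[gi], kind = "intron",
        id = sprintf("%s_intron%d", gid, seq_along(ir)),
        parent = gid, te_class = NA_character_
      )
    })
    introns <- dplyr::bind_rows(purrr::compact(intron_list))
  }

  occupied <- dplyr::bind_rows(
    genes |> dplyr::select("chrom", "start", "end"),
    promoters |> dplyr::select("chrom", "start", "end"),
    downstream |> dplyr::select("chrom", "start", "end")
  )
  intergenic_list <- purrr::map2(cl$chrom, cl$length, function(ch, L) {
    occ <- occupied |> dplyr::filter(.data$chrom == ch)
    chrom_ir <- IRanges::IRanges(1L, L)
    occ_ir <- if (nrow(occ) > 0L) {
      IRanges::reduce(IRanges::IRanges(occ$start + 1L, occ$end))
    } else IRanges::IRanges()
    gap <- IRanges::setdiff(chrom_ir, occ_ir)
    if (length(gap) == 0L) return(NULL)
    tibble::tibble(
      chrom = ch, start = IRanges::start(gap) - 1L, end = IRanges::end(gap),
      strand = ".", kind = "intergenic",
      id = sprintf("%s_intergenic%d", ch, seq_along(gap)),
      parent = NA_character_, te_class = NA_character_
    )
  })
  intergenic <- dplyr::bind_rows(purrr::compact(intergenic_list))

  new_genome_annotation(
    dplyr::bind_rows(
      f |> dplyr::filter(!.data$kind %in% c("promoter", "downstream1kb",
                                            "intron", "intergenic")),
      promoters, downstream, introns, intergenic
    ),
    cl
  )
}

#' Assign cytosine sites to genomic feature categories
#'
#' Each site gets exactly one category under the fixed precedence
#' exon > intron > promoter > downstream1kb > TE > intergenic, so category
#' counts always sum to the number of sites.
#'
#' @param sites Cytosine site tibble.
#' @param annotation A derived `genome_annotation` (see [derive_features()]).
#' @return The site tibble with a `category` column.
#' @export
assign_sites_to_features <- function(sites, annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  f <- annotation$features
  category <- rep(NA_character_, nrow(sites))
  if (nrow(sites) > 0L) {
    site_gr <- sites_to_granges(sites)
    for (kind in setdiff(CATEGORY_PRECEDENCE, "intergenic")) {
      fk <- f |> dplyr::filter(.data$kind == !!kind)
      if (nrow(fk) == 0L) next
      un <- which(is.na(category))
      if (length(un) == 0L) break
      hits <- GenomicRanges::findOverlaps(site_gr[un], tbl_to_granges(fk))
      category[un[unique(S4Vectors::queryHits(hits))]] <- kind
    }
    category[is.na(category)] <- "intergenic"
  }
  sites$category <- category
  sites
}

#' Identify methylated promoters and gene bodies
#'
#' A promoter (1 kb upstream) or gene body qualifies as methylated (MP/MGB)
#' when it carries at least `min_density` mCGs per kb in at least one stage.
#' Levels are pooled read fractions over all covered CG sites of the region.
#'
#' @param sites_by_stage Named list of called site tibbles, one per stage.
#' @param annotation A derived `genome_annotation`.
#' @param min_density Minimum mCG density per kb (default 10).
#' @return A tibble with one row per promoter/gene-body region: `region_kind`
#'   (`promoter` or `gene_body`), `gene_id`, coordinates, per-stage mCG counts
#'   (`n_mcg_<stage>`), densities, pooled levels (`level_<stage>`),
#'   `max_density`, `mean_level` and `qualifies`.
#' @export
identify_mp_mgb <- function(sites_by_stage, annotation, min_density = 10) {
  stopifnot(inherits(annotation, "genome_annotation"), length(sites_by_stage) >= 1L,
            !is.null(names(sites_by_stage)))
  f <- annotation$features
  regions <- dplyr::bind_rows(
    f |> dplyr::filter(.data$kind == "promoter") |>
      dplyr::transmute(region_kind = "promoter", gene_id = .data$parent,
                       chrom = .data$chrom, start = .data$start, end = .data$end),
    f |> dplyr::filter(.data$kind == "gene") |>
      dplyr::transmute(region_kind = "gene_body", gene_id = .data$id,
                       chrom = .data$chrom, start = .data$start, end = .data$end)
  )
  if (nrow(regions) == 0L) {
    return(tibble::tibble(region_kind = character(), gene_id = character(),
                          chrom = character(), start = integer(), end = integer(),
                          max_density = double(), mean_level = double(),
                          qualifies = logical()))
  }
  kb <- (regions$end - regions$start) / 1000
  densities <- list()
  levels <- list()
  for (st in names(sites_by_stage)) {
    pooled <- pool_in_windows(
      regions,
      dplyr::mutate(sites_by_stage[[st]], mcg = as.integer(.data$is_mcg)),
      c("meth_reads", "total_reads", "mcg"))
    regions[[paste0("n_mcg_", st)]] <- as.integer(pooled[, "mcg"])
    densities[[st]] <- pooled[, "mcg"] / kb
    regions[[paste0("density_", st)]] <- densities[[st]]
    levels[[st]] <- ifelse(pooled[, "total_reads"] > 0,
                           pooled[, "meth_reads"] / pooled[, "total_reads"], NA_real_)
    regions[[paste0("level_", st)]] <- levels[[st]]
  }
  regions$max_density <- do.call(pmax, densities)
  regions$mean_level <- rowMeans(do.call(cbind, levels), na.rm = TRUE)
  regions$qualifies <- regions$max_density >= min_density
  regions
}

#' Methylation metaprofile over a region set
#'
#' Each region is rescaled to `n_bins` body bins with `flank_bins` fixed-width
#' bins on each side covering `flank_bp`; minus-strand regions are reversed so
#' bin 1 is always the 5' flank. Bin means are site levels weighted by total
#' read counts; bins without coverage are `NA`.
#'
#' @param regions Region tibble with `chrom`, `start`, `end` and optionally
#'   `strand`.
#' @param sites Cytosine site tibble (one stage).
#' @param n_bins Body bins (default 20).
#' @param flank_bp Flank width in bp (default 1000).
#' @param flank_bins Bins per flank (default 10).
#' @return A tibble of class `methdev_metaprofile` with `bin`, `zone`
#'   (upstream/body/downstream), `mean_level`, `n_sites`.
#' @export
metaprofile <- function(regions, sites, n_bins = 20L, flank_bp = 1000L,
                        flank_bins = 10L) {
  if (nrow(regions) == 0L) stop("metaprofile: empty region set", call. = FALSE)
  strand <- if ("strand" %in% names(regions)) regions$strand else rep("+", nrow(regions))
  ext <- tibble::tibble(chrom = regions$chrom,
                        start = pmax(0L, regions$start - flank_bp),
                        end = regions$end + flank_bp)
  hits <- GenomicRanges::findOverlaps(sites_to_granges(sites), tbl_to_granges(ext))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  total_bins <- n_bins + 2L * flank_bins
  if (length(qi) == 0L) {
    return(structure(tibble::tibble(
      bin = seq_len(total_bins),
      zone = rep(c("upstream", "body", "downstream"), c(flank_bins, n_bins, flank_bins)),
      mean_level = NA_real_, n_sites = 0L
    ), class = c("methdev_metaprofile", "tbl_df", "tbl", "data.frame")))
  }
  pos <- sites$pos[qi]
  rs <- regions$start[si]
  re <- regions$end[si]
  bin <- integer(length(qi))
  before <- pos < rs
  after <- pos >= re
  body <- !before & !after
  # flank offsets measured from the region edge
  bin[before] <- flank_bins - pmin(flank_bins - 1L, (rs[before] - pos[before] - 1L) %/%
                                     ceiling(flank_bp / flank_bins))
  bin[body] <- flank_bins + 1L +
    pmin(n_bins - 1L, ((pos[body] - rs[body]) * n_bins) %/% pmax(1L, re[body] - rs[body]))
  bin[after] <- flank_bins + n_bins + 1L +
    pmin(flank_bins - 1L, (pos[after] - re[after]) %/% ceiling(flank_bp / flank_bins))
  minus <- strand[si] == "-"
  bin[minus] <- total_bins + 1L - bin[minus]
  prof <- tibble::tibble(bin = bin, level = sites$level[qi],
                         w = as.numeric(sites$total_reads[qi])) |>
    dplyr::filter(!is.na(.data$level)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean_level = sum(.data$level * .data$w) / sum(.data$w),
                     n_sites = dplyr::n(), .groups = "drop")
  out <- tibble::tibble(bin = seq_len(total_bins)) |>
    dplyr::left_join(prof, by = "bin") |>
    dplyr::mutate(
      zone = rep(c("upstream", "body", "downstream"), c(flank_bins, n_bins, flank_bins)),
      n_sites = dplyr::coalesce(.data$n_sites, 0L)
    ) |>
    dplyr::select("bin", "zone", "mean_level", "n_sites")
  structure(out, class = c("methdev_metaprofile", class(out)))
}

#' Classify promoters by methylation level
#'
#' `none` = promoter that does not qualify as MP; qualifying MPs are split
#' into `low` / `medium` / `high` tertiles of the mean mCG level averaged
#' over stages (ties broken deterministically by gene id).
#'
#' @param mp_mgb Output of [identify_mp_mgb()].
#' @return Tibble of promoters with `gene_id`, coordinates, `mean_level` and
#'   `mclass` (none/low/medium/high).
#' @export
classify_promoter_methylation <- function(mp_mgb) {
  prom <- mp_mgb |> dplyr::filter(.data$region_kind == "promoter")
  mp <- prom |> dplyr::filter(.data$qualifies) |> dplyr::arrange(.data$gene_id)
  cls <- rep("none", nrow(prom))
  if (nrow(mp) > 0L) {
    r <- rank(mp$mean_level, ties.method = "first")
    tert <- cut(r, breaks = quantile(r, c(0, 1/3, 2/3, 1)),
                labels = c("low", "medium", "high"), include.lowest = TRUE)
    cls[match(mp$gene_id, prom$gene_id)] <- as.character(tert)
  }
  prom |>
    dplyr::transmute(gene_id = .data$gene_id, chrom = .data$chrom,
                     start = .data$start, end = .data$end,
                     mean_level = .data$mean_level, mclass = cls)
}

#' Distance from promoters to their nearest TE
#'
#' Distance is 0 for an overlap, otherwise the gap in bp to the nearest TE on
#' the same chromosome; `NA` when the chromosome carries no TE.
#'
#' @param promoters Tibble from [classify_promoter_methylation()] (any region
#'   tibble with `chrom`, `start`, `end` works).
#' @param annotation A `genome_annotation` holding the TEs.
#' @return The promoter tibble with a `dist_te` column.
#' @export
distance_to_nearest_te <- function(promoters, annotation) {
  tes <- annotation$features |> dplyr::filter(.data$kind == "TE")
  promoters$dist_te <- NA_real_
  if (nrow(tes) == 0L || nrow(promoters) == 0L) return(promoters)
  nearest <- GenomicRanges::distanceToNearest(tbl_to_granges(promoters),
                                              tbl_to_granges(tes))
  promoters$dist_te[S4Vectors::queryHits(nearest)] <-
    as.double(S4Vectors::mcols(nearest)$distance)
  promoters
}

#' Methylation level by expression class
#'
#' Genes carrying a qualifying methylated region of the requested kind are
#' split into low/medium/high tertiles of `log10(mean TPM + 1)` (ties broken
#' by gene id), and their region methylation levels are compared across the
#' classes with Games-Howell post-hoc tests.
#'
#' @param mp_mgb Output of [identify_mp_mgb()].
#' @param tpm TPM tibble (`feature_id`, `length`, sample columns).
#' @param region_kind `"promoter"` or `"gene_body"`.
#' @return A list with `genes` (gene, expression class, mean methylation
#'   level, mean TPM) and `tests` (Games-Howell pairwise results), or an empty
#'   `genes` tibble with a warning when no region qualifies.
#' @export
methylation_by_expression_class <- function(mp_mgb, tpm, region_kind = "promoter") {
  sel <- mp_mgb |>
    dplyr::filter(.data$region_kind == !!region_kind, .data$qualifies)
  if (nrow(sel) == 0L) {
    warning("methylation_by_expression_class: no qualifying region")
    return(list(genes = tibble::tibble(gene_id = character(), expr_class = character(),
                                       mean_level = double(), mean_tpm = double()),
                tests = NULL))
  }
  sample_cols <- setdiff(names(tpm), c("feature_id", "length"))
  expr <- tibble::tibble(
    gene_id = tpm$feature_id,
    mean_tpm = rowMeans(as.matrix(tpm[, sample_cols]), na.rm = TRUE)
  )
  genes <- sel |>
    dplyr::inner_join(expr, by = "gene_id") |>
    dplyr::arrange(.data$gene_id)
  if (nrow(genes) < 3L) {
    stop("methylation_by_expression_class: fewer than 3 genes", call. = FALSE)
  }
  r <- rank(log10(genes$mean_tpm + 1), ties.method = "first")
  genes$expr_class <- as.character(cut(r, quantile(r, c(0, 1/3, 2/3, 1)),
                                       labels = c("low", "medium", "high"),
                                       include.lowest = TRUE))
  genes <- genes |>
    dplyr::select("gene_id", "expr_class", "mean_level", "mean_tpm")
  tests <- tryCatch(
    games_howell(split(genes$mean_level, genes$expr_class)),
    error = function(e) NULL
  )
  list(genes = genes, tests = tests)
}
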