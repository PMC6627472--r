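test_that("derived features respect strand arithmetic and clamp at bounds", {
  ann <- derive_features(make_tiny_annotation())
  f <- ann$features
  # plus-strand gene [5000,8000): promoter upstream, downstream after TES
  expect_equal(f[f$id == "g1_promoter", c("start", "end")],
               tibble::tibble(start = 4000L, end = 5000L))
  expect_equal(f[f$id == "g1_down1kb", c("start", "end")],
               tibble::tibble(start = 8000L, end = 9000L))
  # minus-strand gene [12000,15000): promoter after the 3' coordinate end
  expect_equal(f[f$id == "g2_promoter", c("start", "end")],
               tibble::tibble(start = 15000L, end = 16000L))
  expect_equal(f[f$id == "g2_down1kb", c("start", "end")],
               tibble::tibble(start = 11000L, end = 12000L))
  # intron of g1 = gene minus exons
  expect_equal(f[f$kind == "intron" & f$parent == "g1", c("start", "end")],
               tibble::tibble(start = 6000L, end = 6500L))
  # clamping at chromosome start
  near_edge <- methdev:::new_genome_annotation(
    tibble::tibble(chrom = "chr1", start = 300L, end = 1300L, strand = "+",
                   kind = "gene", id = "gx", parent = NA, te_class = NA),
    c(chr1 = 2000L))
  fe <- suppressWarnings(derive_features(near_edge))$features
  expect_equal(fe[fe$kind == "promoter", c("start", "end")],
               tibble::tibble(start = 0L, end = 300L))
  # non-negative lengths everywhere; intergenic complements the rest
  expect_true(all(ann$features$end > ann$features$start))
  ig <- f[f$kind == "intergenic", ]
  occupied <- f[f$kind %in% c("gene", "promoter", "downstream1kb"), ]
  expect_false(any(purrr::map_lgl(seq_len(nrow(ig)), function(i) {
    any(occupied$start < ig$end[i] & occupied$end > ig$start[i])
  })))
})

test_that("site assignment partitions sites under the documented precedence", {
  ann <- derive_features(make_tiny_annotation())
  sites <- make_sites(pos = c(5500, 6200, 4500, 8500, 2500, 100, 15500),
                      meth = 5, total = 10)
  got <- assign_sites_to_features(sites, ann)
  expect_equal(got$category,
               c("exon", "intron", "promoter", "downstream1kb", "TE",
                 "intergenic", "promoter"))
  # partition: counts sum to the number of sites
  expect_equal(sum(table(got$category)), nrow(sites))
})

test_that("MP/MGB identification applies the density rule per kb", {
  ann <- derive_features(make_tiny_annotation())
  # g1 promoter [4000,5000): 10 mCGs in MY only -> MP
  # g1 gene body [5000,8000) = 3 kb: 15 mCGs -> 5/kb -> not MGB
  mk <- function(pos, mcg) {
    s <- make_sites(pos = pos, meth = 9, total = 10)
    s$is_mcg <- mcg
    s
  }
  my <- mk(c(seq(4010, 4910, by = 100), seq(5010, 7810, by = 200)),
           c(rep(TRUE, 10), rep(TRUE, 15)))
  fb <- mk(c(seq(4010, 4910, by = 100)), rep(FALSE, 10))
  mm <- identify_mp_mgb(list(MY = my, FB = fb), ann)
  g1p <- mm[mm$region_kind == "promoter" & mm$gene_id == "g1", ]
  expect_true(g1p$qualifies)
  expect_equal(g1p$n_mcg_MY, 10L)
  g1b <- mm[mm$region_kind == "gene_body" & mm$gene_id == "g1", ]
  expect_false(g1b$qualifies)
  expect_equal(g1b$density_MY, 5)
  # 9 mCGs in every stage -> not MP
  my9 <- mk(seq(4010, 4810, by = 100), rep(TRUE, 9))
  mm9 <- identify_mp_mgb(list(MY = my9, FB = my9), ann)
  expect_false(mm9$qualifies[mm9$region_kind == "promoter" & mm9$gene_id == "g1"])
  # monotone: adding mCGs never revokes qualification
  extra <- dplyr::bind_rows(my, mk(seq(4020, 4920, by = 100), rep(TRUE, 10)))
  mm2 <- identify_mp_mgb(list(MY = extra, FB = fb), ann)
  expect_true(mm2$qualifies[mm2$region_kind == "promoter" & mm2$gene_id == "g1"])
})

test_that("metaprofiles are flat for uniform methylomes and reverse with strand", {
  regions <- tibble::tibble(chrom = "chr1", start = c(2000L, 9000L),
                            end = c(4000L, 12000L), strand = c("+", "+"))
  sites <- make_sites(pos = seq(500, 14500, by = 40), meth = 5, total = 10)
  prof <- metaprofile(regions, sites)
  expect_s3_class(prof, "methdev_metaprofile")
  expect_equal(nrow(prof), 40L)
  expect_true(all(abs(prof$mean_level - 0.5) < 1e-12, na.rm = TRUE))

  # asymmetric methylome: left flank high, rest low
  lv <- ifelse(seq(500, 14500, by = 40) < 2000, 0.9, 0.1)
  sites2 <- make_sites(pos = seq(500, 14500, by = 40),
                       meth = round(lv * 10), total = 10)
  p_plus <- metaprofile(regions[1, ], sites2)
  p_minus <- metaprofile(dplyr::mutate(regions[1, ], strand = "-"), sites2)
  expect_equal(p_minus$mean_level, rev(p_plus$mean_level))

  # empty flank coverage -> NA bins, no crash
  sparse <- make_sites(pos = seq(2000, 3990, by = 40), meth = 5, total = 10)
  p3 <- metaprofile(regions[1, ], sparse)
  expect_true(all(is.na(p3$mean_level[p3$zone == "upstream"])))
  expect_error(metaprofile(regions[0, ], sites), "empty")
})

test_that("promoter methylation classes and TE distances behave as defined", {
  mp <- tibble::tibble(
    region_kind = "promoter",
    gene_id = sprintf("g%d", 1:7),
    chrom = "chr1",
    start = c(1000L, 3000L, 5000L, 7000L, 9000L, 11000L, 13000L),
    end = c(2000L, 4000L, 6000L, 8000L, 10000L, 12000L, 14000L),
    mean_level = c(0.1, 0.3, 0.5, 0.6, 0.8, 0.9, 0.2),
    qualifies = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  cls <- classify_promoter_methylation(mp)
  expect_equal(cls$mclass[cls$gene_id == "g7"], "none")
  expect_equal(sum(cls$mclass == "low"), 2L)
  expect_equal(sum(cls$mclass == "high"), 2L)
  expect_equal(cls$mclass[cls$gene_id == "g6"], "high")

  ann <- make_tiny_annotation()  # TEs at [2000,3000) and [16000,17000)
  d <- distance_to_nearest_te(cls, ann)
  expect_equal(d$dist_te[d$gene_id == "g1"], 0)     # overlaps te1 boundary region
  expect_equal(d$dist_te[d$gene_id == "g3"], 2000)  # [5000,6000) to [2000,3000)
  no_te <- methdev:::new_genome_annotation(
    ann$features[ann$features$kind != "TE", ], ann$chrom_lengths)
  expect_true(all(is.na(distance_to_nearest_te(cls, no_te)$dist_te)))
})

test_that("expression tertiles split deterministically and compare levels", {
  mp <- tibble::tibble(
    region_kind = "promoter", gene_id = sprintf("g%02d", 1:9),
    chrom = "chr1", start = 0L, end = 1000L,
    mean_level = c(0.9, 0.8, 0.7, 0.5, 0.4, 0.45, 0.1, 0.15, 0.05),
    qualifies = TRUE
  )
  tpm <- tibble::tibble(feature_id = sprintf("g%02d", 1:9), length = 1000L,
                        s1 = c(1, 2, 3, 10, 20, 30, 100, 200, 300))
  res <- methylation_by_expression_class(mp, tpm)
  expect_equal(as.vector(table(res$genes$expr_class)), c(3L, 3L, 3L))
  agg <- tapply(res$genes$mean_level, res$genes$expr_class, mean)
  expect_true(agg["low"] > agg["medium"] && agg["medium"] > agg["high"])
  expect_equal(nrow(res$tests), 3L)  # three pairwise comparisons
  # ties split classes to equal sizes by deterministic rank
  tpm2 <- dplyr::mutate(tpm, s1 = 7)
  res2 <- methylation_by_expression_class(mp, tpm2)
  expect_equal(as.vector(table(res2$genes$expr_class)[c("low", "medium", "high")]),
               c(3L, 3L, 3L))
  expect_warning(methylation_by_expression_class(mp[0, ], tpm), "no qualifying")
})
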