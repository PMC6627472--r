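# End-to-end orchestration: simulate (or ingest) -> call mCGs per stage ->
# DMRs per transition -> features/MP-MGB -> expression & divergence ->
# enrichment -> manifest.

#' Pipeline configuration
#'
#' All thresholds default to the study values: non-conversion background
#' 0.003, depth >= 5, mCG q < 0.01 and level > 5%, 1 kb / 200 bp windows,
#' >= 10 mCG eligibility, DMR q < 0.01 and |delta| >= 0.15, MP/MGB >= 10
#' mCG/kb, TPM > 1 expressed, DEG q < 0.01 and |log2FC| > 1, ortholog
#' consensus > 70% and > 300 bp, GO q < 0.05 with >= 5 genes.
#'
#' @param out_dir Output directory for all tables and the manifest.
#' @param seed Global seed; per-stage seeds derive from it.
#' @param sim A [sim_config()] used when no external inputs are given
#'   (its seed is overridden by `seed`).
#' @param stages Ordered stage labels (earlier < later).
#' @param species Two species tags.
#' @param mcg An [mcg_params()].
#' @param dmr A [dmr_params()].
#' @param mp_mgb_density MP/MGB density threshold per kb.
#' @param tpm_threshold Expressed threshold.
#' @param de_q,de_lfc DEG thresholds.
#' @param ortholog_fraction,ortholog_length_bp Ortholog filter thresholds.
#' @param go_q,go_min_genes Enrichment thresholds.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, sim = sim_config(seed = seed),
                            stages = DEFAULT_STAGES, species = c("Pt", "Pe"),
                            mcg = mcg_params(), dmr = dmr_params(),
                            mp_mgb_density = 10, tpm_threshold = 1,
                            de_q = 0.01, de_lfc = 1,
                            ortholog_fraction = 0.70, ortholog_length_bp = 300L,
                            go_q = 0.05, go_min_genes = 5L) {
  sim$seed <- seed
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 stages = stages, species = species, mcg = mcg, dmr = dmr,
                 mp_mgb_density = mp_mgb_density, tpm_threshold = tpm_threshold,
                 de_q = de_q, de_lfc = de_lfc,
                 ortholog_fraction = ortholog_fraction,
                 ortholog_length_bp = ortholog_length_bp,
                 go_q = go_q, go_min_genes = go_min_genes),
            class = "pipeline_config")
}

#' Run the full pipeline on simulated data
#'
#' Simulates the two-species three-stage study from `config$sim`, then runs
#' every analysis stage and writes all tables (TSV/BED) plus a JSON manifest
#' (thresholds, seed, md5 checksum of every output) into `config$out_dir`.
#' Deterministic: identical config (including seed) yields byte-identical
#' outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of class `methdev_run` with the in-memory
#'   results of every stage.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  stages <- config$stages
  species <- config$species
  transitions <- purrr::map(seq_len(length(stages) - 1L),
                            ~ c(stages[.x], stages[.x + 1L]))

  study <- simulate_study(config$sim, species = species, stages = stages)

  # ingest-format inputs written for reference / re-use
  for (sp in species) {
    write_annotation(study$annotations[[sp]],
                     out(sprintf("%s_genes.gff3", sp)),
                     out(sprintf("%s_tes.bed", sp)),
                     out(sprintf("%s_chroms.tsv", sp)))
    for (st in stages) {
      write_cytosine_report(study$methylomes[[sp]]$stages[[st]],
                            out(sprintf("%s_%s_cytosine_report.tsv", sp, st)))
    }
    readr::write_tsv(study$expression$counts[[sp]],
                     out(sprintf("%s_gene_counts.tsv", sp)), progress = FALSE)
    readr::write_tsv(study$expression$te_counts[[sp]],
                     out(sprintf("%s_te_counts.tsv", sp)), progress = FALSE)
    readr::write_tsv(study$methylomes[[sp]]$truth_dmrs,
                     out(sprintf("%s_truth_dmrs.tsv", sp)), progress = FALSE)
  }
  readr::write_tsv(study$expression$pairs, out("ortholog_pairs.tsv"), progress = FALSE)
  readr::write_tsv(study$expression$truth_classes, out("truth_classes.tsv"),
                   progress = FALSE)
  readr::write_tsv(study$go_map, out("go_map.tsv"), progress = FALSE)

  # mCG calling + summaries
  called <- purrr::map(setNames(species, species), function(sp) {
    purrr::map(study$methylomes[[sp]]$stages, call_mcgs, params = config$mcg)
  })
  derived <- purrr::map(study$annotations, derive_features)
  summaries <- purrr::imap_dfr(called, function(by_stage, sp) {
    purrr::imap_dfr(by_stage, function(sites, st) {
      methylome_summary(sites) |> dplyr::mutate(species = sp, stage = st)
    })
  })
  readr::write_tsv(summaries, out("methylome_summary.tsv"), progress = FALSE)
  for (sp in species) {
    for (st in stages) {
      readr::write_tsv(called[[sp]][[st]], out(sprintf("%s_%s_mcg.tsv", sp, st)),
                       progress = FALSE)
    }
  }

  # DMRs per species and transition, evaluated against the planted truth
  dmr_results <- purrr::map(setNames(species, species), function(sp) {
    purrr::map(setNames(seq_along(transitions), paste0("transition", seq_along(transitions))),
               function(t) {
                 tr <- transitions[[t]]
                 res <- call_dmrs(called[[sp]][[tr[1L]]], called[[sp]][[tr[2L]]],
                                  study$annotations[[sp]]$chrom_lengths, config$dmr)
                 readr::write_tsv(res$windows,
                                  out(sprintf("%s_t%d_windows.tsv", sp, t)),
                                  progress = FALSE)
                 write_regions_bed(res$dmrs, out(sprintf("%s_t%d_dmrs.bed", sp, t)))
                 res
               })
  })
  dmr_eval <- purrr::imap_dfr(dmr_results, function(by_t, sp) {
    purrr::imap_dfr(by_t, function(res, tname) {
      t <- as.integer(sub("transition", "", tname))
      truth <- study$methylomes[[sp]]$truth_dmrs |>
        dplyr::filter(.data$transition == t)
      evaluate_dmrs(res$dmrs, truth) |>
        dplyr::mutate(species = sp, transition = t)
    })
  })
  readr::write_tsv(dmr_eval, out("dmr_evaluation.tsv"), progress = FALSE)

  # MP/MGB and differential methylation of MPs/MGBs
  mp_mgb <- purrr::map(setNames(species, species), function(sp) {
    tbl <- identify_mp_mgb(called[[sp]], derived[[sp]], config$mp_mgb_density)
    readr::write_tsv(tbl, out(sprintf("%s_mp_mgb.tsv", sp)), progress = FALSE)
    tbl
  })

  # expression: TPM, DE per phase, divergence
  tpm <- purrr::map(study$expression$counts, compute_tpm)
  te_tpm <- purrr::map(study$expression$te_counts, compute_tpm)
  samples <- study$expression$samples
  de <- purrr::map(setNames(species, species), function(sp) {
    smp <- samples |> dplyr::filter(.data$species == sp)
    purrr::map(setNames(seq_along(transitions), paste0("phase", seq_along(transitions))),
               function(t) {
                 res <- de_test(study$expression$counts[[sp]], smp,
                                transitions[[t]][1L], transitions[[t]][2L],
                                q_threshold = config$de_q, lfc_threshold = config$de_lfc)
                 readr::write_tsv(res, out(sprintf("%s_phase%d_de.tsv", sp, t)),
                                  progress = FALSE)
                 res
               })
  })
  pairs <- filter_orthologs(study$expression$pairs,
                            config$ortholog_fraction, config$ortholog_length_bp)
  divergence <- ortholog_divergence(pairs, de[[species[1L]]], de[[species[2L]]])
  readr::write_tsv(divergence, out("divergence_classes.tsv"), progress = FALSE)
  fc_cor <- purrr::map_dfr(unique(divergence$phase), function(ph) {
    dplyr::bind_rows(foldchange_correlation(divergence, ph, "all"),
                     foldchange_correlation(divergence, ph, "non-DE0"))
  })
  readr::write_tsv(fc_cor, out("foldchange_correlations.tsv"), progress = FALSE)

  # TE methylation vs expression
  te_summary <- purrr::imap_dfr(setNames(species, species), function(sp, nm) {
    tes <- study$annotations[[sp]]$features |> dplyr::filter(.data$kind == "TE")
    te_expression_summary(tes, te_tpm[[sp]], samples |>
                            dplyr::filter(.data$species == sp),
                          config$tpm_threshold) |>
      dplyr::mutate(species = sp)
  })
  readr::write_tsv(te_summary, out("te_expression_summary.tsv"), progress = FALSE)

  te_meth_cor <- purrr::map_dfr(setNames(species, species), function(sp) {
    tes <- study$annotations[[sp]]$features |> dplyr::filter(.data$kind == "TE")
    lev <- te_mean_mcg_level(called[[sp]], tes)
    smp <- samples |> dplyr::filter(.data$species == sp)
    mean_tpm <- rowMeans(as.matrix(te_tpm[[sp]][, smp$sample]), na.rm = TRUE)
    methylation_expression_correlation(
      lev$mean_level[match(te_tpm[[sp]]$feature_id, lev$id)], mean_tpm) |>
      dplyr::mutate(species = sp)
  })
  readr::write_tsv(te_meth_cor, out("te_methylation_expression_correlation.tsv"),
                   progress = FALSE)

  # promoter methylation classes and TE distances
  te_dist <- purrr::map_dfr(setNames(species, species), function(sp) {
    classify_promoter_methylation(mp_mgb[[sp]]) |>
      distance_to_nearest_te(study$annotations[[sp]]) |>
      dplyr::mutate(species = sp)
  })
  readr::write_tsv(te_dist, out("promoter_te_distance.tsv"), progress = FALSE)

  # GO enrichment of divergent orthologs (expressed-ortholog universe)
  expressed <- expressed_mask(tpm[[species[1L]]],
                              samples |> dplyr::filter(.data$species == species[1L]),
                              config$tpm_threshold)
  universe <- intersect(pairs$gene_a[pairs$kept],
                        expressed$feature_id[expressed$expressed])
  divergent <- divergence |>
    dplyr::filter(.data$class %in% c("DE1-Pt", "DE1-Pe", "DE2-opposite")) |>
    dplyr::pull("gene_a") |> unique()
  enr <- hypergeom_enrichment(divergent, universe, study$go_map,
                              config$go_q, config$go_min_genes)
  readr::write_tsv(enr, out("go_enrichment.tsv"), progress = FALSE)

  # manifest
  files <- sort(list.files(config$out_dir, full.names = FALSE))
  files <- setdiff(files, "manifest.json")
  checksums <- tools::md5sum(file.path(config$out_dir, files))
  manifest <- list(
    seed = config$seed,
    stages = stages,
    species = species,
    thresholds = list(
      p0 = config$mcg$p0, min_reads = config$mcg$min_reads,
      mcg_q = config$mcg$q_threshold, mcg_level = config$mcg$level_threshold,
      window_size = config$dmr$size, window_step = config$dmr$step,
      min_mcg = config$dmr$min_mcg, dmr_q = config$dmr$q_threshold,
      dmr_delta = config$dmr$delta_threshold,
      mp_mgb_density = config$mp_mgb_density,
      tpm_threshold = config$tpm_threshold,
      de_q = config$de_q, de_lfc = config$de_lfc,
      ortholog_fraction = config$ortholog_fraction,
      ortholog_length_bp = config$ortholog_length_bp,
      go_q = config$go_q, go_min_genes = config$go_min_genes
    ),
    files = as.list(setNames(unname(checksums), files))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(structure(
    list(study = study, called = called, summaries = summaries,
         dmr_results = dmr_results, dmr_eval = dmr_eval, mp_mgb = mp_mgb,
         tpm = tpm, te_tpm = te_tpm, de = de, pairs = pairs,
         divergence = divergence, fc_cor = fc_cor, te_summary = te_summary,
         te_meth_cor = te_meth_cor, te_dist = te_dist, enrichment = enr,
         config = config),
    class = "methdev_run"))
}

# Mean observed mCG level per TE across stages (pooled reads per stage,
# averaged over stages).
te_mean_mcg_level <- function(called_by_stage, tes) {
  levels <- purrr::map(called_by_stage, function(sites) {
    pooled <- pool_in_windows(tes, sites, c("meth_reads", "total_reads"))
    ifelse(pooled[, "total_reads"] > 0,
           pooled[, "meth_reads"] / pooled[, "total_reads"], NA_real_)
  })
  tibble::tibble(id = tes$id,
                 mean_level = rowMeans(do.call(cbind, levels), na.rm = TRUE))
}
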