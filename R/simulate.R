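#' Simulation configuration
#'
#' Bundles every parameter of the synthetic two-species, three-stage study:
#' genome geometry, TE class mixture, CpG density, sequencing depth, the
#' bimodal latent methylation mixture, TE methylation spreading, planted DMRs,
#' negative-binomial expression with planted divergence classes, and the
#' methylation-repression coupling between the methylome and expression.
#' The seed fully determines all generated data.
#'
#' @param seed Integer seed; child seeds for each generation stage are derived
#'   from it with [derive_seed()].
#' @param n_chroms,chrom_length_bp Genome geometry.
#' @param n_genes,n_tes Features per species.
#' @param te_class_proportions Named 5-vector over Gypsy/Copia/LTR-other/LINE/
#'   DNA summing to 1; default puts ~62% of repeat content in Gypsy + Copia.
#' @param cpg_spacing_bp Mean spacing between simulated CpG sites.
#' @param depth_mean Mean per-stage read depth (depth is 1 + Poisson(mean-1)).
#' @param nonconversion_rate Bisulfite non-conversion rate (default 0.003,
#'   the background of the binomial mCG test).
#' @param low_mode,high_mode Centres of the low/high latent Beta components.
#'   A mode of exactly 0 or 1 is treated as a point mass.
#' @param beta_concentration Concentration (shape1 + shape2) of the Beta
#'   components.
#' @param low_weight Named mixing weight of the low component per feature kind
#'   (`genic`, `intergenic`, `TE`).
#' @param te_weight_concentration Concentration of the per-element Beta draw
#'   of each TE's own low-component weight around `low_weight["TE"]`; small
#'   values give heterogeneous elements (old, silenced elements nearly fully
#'   methylated; young ones lowly methylated).
#' @param te_spread_bp,te_spread_boost Methylation spreading from TEs: the
#'   probability a non-TE site draws the high component gains
#'   `boost * exp(-distance/te_spread_bp)`.
#' @param n_planted_dmrs,dmr_delta,dmr_length_bp Planted DMRs per transition:
#'   count, latent level shift, interval length.
#' @param n_replicates RNA-seq replicates per species and stage.
#' @param nb_dispersion Negative-binomial dispersion of expression counts.
#' @param class_counts Named planted counts per phase for the divergence
#'   classes `DE1-Pt`, `DE1-Pe`, `DE2-identical`, `DE2-opposite`; remaining
#'   genes are DE0.
#' @param planted_lfc Planted absolute log2 fold change for divergent genes.
#' @param mu_meanlog,mu_sdlog Log-normal distribution of gene baseline means.
#' @param te_mu_meanlog,te_mu_sdlog Log-normal baseline means for TEs.
#' @param methylation_repression Coefficient k of the repressive coupling:
#'   expression means are multiplied by `exp(-k * latent mCG level)` of the
#'   promoter (genes, plus half-weight gene body) or the element itself (TEs).
#' @param libsize_sdlog Log-normal sd of per-sample library-size factors.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_length_bp = 400000L,
                       n_genes = 150L,
                       n_tes = 150L,
                       te_class_proportions = c(Gypsy = 0.37, Copia = 0.25,
                                                `LTR-other` = 0.14, LINE = 0.10,
                                                DNA = 0.14),
                       cpg_spacing_bp = 25,
                       depth_mean = 20,
                       nonconversion_rate = 0.003,
                       low_mode = 0.02,
                       high_mode = 0.90,
                       beta_concentration = 50,
                       low_weight = c(genic = 0.97, intergenic = 0.30, TE = 0.30),
                       te_weight_concentration = 2,
                       te_spread_bp = 600,
                       te_spread_boost = 0.55,
                       n_planted_dmrs = 8L,
                       dmr_delta = 0.30,
                       dmr_length_bp = 2000L,
                       n_replicates = 3L,
                       nb_dispersion = 0.05,
                       class_counts = c(`DE1-Pt` = 30L, `DE1-Pe` = 30L,
                                        `DE2-identical` = 20L, `DE2-opposite` = 15L),
                       planted_lfc = 2,
                       mu_meanlog = log(200),
                       mu_sdlog = 0.8,
                       te_mu_meanlog = log(5),
                       te_mu_sdlog = 1.2,
                       methylation_repression = 2.5,
                       libsize_sdlog = 0.08) {
  te_class_proportions <- te_class_proportions[TE_CLASSES]
  stopifnot(
    !any(is.na(te_class_proportions)),
    abs(sum(te_class_proportions) - 1) < 1e-6,
    all(te_class_proportions >= 0),
    cpg_spacing_bp > 0, depth_mean >= 1,
    nonconversion_rate >= 0, nonconversion_rate < 1,
    low_mode >= 0, low_mode <= 1, high_mode >= 0, high_mode <= 1,
    all(c("genic", "intergenic", "TE") %in% names(low_weight)),
    all(low_weight >= 0 & low_weight <= 1),
    n_replicates >= 2, dmr_delta >= 0, dmr_delta <= 1
  )
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0", call. = FALSE)
  if (sum(class_counts) > n_genes) {
    stop("planted divergence class counts exceed n_genes", call. = FALSE)
  }
  structure(as.list(environment()), class = "sim_config")
}

# Non-overlapping placement of features on one chromosome by stick breaking:
# gaps between features are a Dirichlet split of the unoccupied space, so
# placement always succeeds when the features fit at all.
place_on_chrom <- function(lengths, chrom_len) {
  n <- length(lengths)
  if (n == 0L) return(integer(0))
  free <- chrom_len - sum(lengths)
  if (free < n + 1L) {
    stop(sprintf(
      "cannot place %d features of total length %d on a %d bp chromosome; reduce feature density",
      n, sum(lengths), chrom_len), call. = FALSE)
  }
  g <- rexp(n + 1L)
  gaps <- floor(g / sum(g) * free)
  starts <- cumsum(gaps[seq_len(n)]) + c(0L, cumsum(lengths[-n]))
  as.integer(starts)
}

#' Simulate a genome annotation
#'
#' Places non-overlapping genes (each with 1-5 exons) and classified TEs on
#' `n_chroms` chromosomes. Placement uses a stick-breaking split of the free
#' space, so it fails only when the requested features cannot fit at all.
#'
#' @param config A [sim_config()].
#' @param prefix Feature-id prefix (species tag).
#' @return A `genome_annotation` with genes, exons and TEs.
#' @export
simulate_annotation <- function(config, prefix = "Pt") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, paste0("annotation-", prefix)))
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  # round-robin assignment of features to chromosomes
  gene_chrom <- chroms[(seq_len(config$n_genes) - 1L) %% config$n_chroms + 1L]
  te_chrom <- chroms[(seq_len(config$n_tes) - 1L) %% config$n_chroms + 1L]
  gene_len <- as.integer(round(runif(config$n_genes, 1000, 3000)))
  te_len <- as.integer(round(runif(config$n_tes, 300, 1500)))
  te_class <- if (config$n_tes > 0L) {
    sample(TE_CLASSES, config$n_tes, replace = TRUE, prob = config$te_class_proportions)
  } else character(0)

  rows <- list()
  for (ch in chroms) {
    gi <- which(gene_chrom == ch)
    ti <- which(te_chrom == ch)
    lens <- c(gene_len[gi], te_len[ti])
    is_gene <- c(rep(TRUE, length(gi)), rep(FALSE, length(ti)))
    idx <- c(gi, ti)
    ord <- sample.int(length(lens))
    starts <- place_on_chrom(lens[ord], config$chrom_length_bp)
    rows[[ch]] <- tibble::tibble(
      chrom = ch, start = starts, end = starts + lens[ord],
      is_gene = is_gene[ord], fidx = idx[ord]
    )
  }
  placed <- dplyr::bind_rows(rows)

  genes <- placed |>
    dplyr::filter(.data$is_gene) |>
    dplyr::arrange(.data$fidx) |>
    dplyr::mutate(
      strand = sample(c("+", "-"), dplyr::n(), replace = TRUE),
      kind = "gene",
      id = sprintf("%s_g%04d", prefix, .data$fidx),
      parent = NA_character_, te_class = NA_character_
    ) |>
    dplyr::select("chrom", "start", "end", "strand", "kind", "id", "parent", "te_class")

  exons <- purrr::pmap_dfr(
    genes |> dplyr::select("chrom", "start", "end", "strand", gene_id = "id"),
    function(chrom, start, end, strand, gene_id) {
      k <- sample.int(5L, 1L)
      len <- end - start
      if (k == 1L || len < 2L * (2L * k - 1L)) {
        seg_start <- start
        seg_end <- end
      } else {
        brk <- sort(sample.int(len - 1L, 2L * (k - 1L)))
        bounds <- c(0L, brk, len)
        seg <- seq(1L, 2L * k - 1L, by = 2L)  # odd segments are exons
        seg_start <- start + bounds[seg]
        seg_end <- start + bounds[seg + 1L]
      }
      tibble::tibble(
        chrom = chrom, start = as.integer(seg_start), end = as.integer(seg_end),
        strand = strand, kind = "exon",
        id = sprintf("%s_exon%d", gene_id, seq_along(seg_start)),
        parent = gene_id, te_class = NA_character_
      )
    }
  )

  tes <- placed |>
    dplyr::filter(!.data$is_gene) |>
    dplyr::arrange(.data$fidx) |>
    dplyr::mutate(
      strand = ".", kind = "TE",
      id = sprintf("%s_te%04d", prefix, .data$fidx),
      parent = NA_character_, te_class = te_class[.data$fidx]
    ) |>
    dplyr::select("chrom", "start", "end", "strand", "kind", "id", "parent", "te_class")

  new_genome_annotation(
    dplyr::bind_rows(genes, exons, tes),
    tibble::tibble(chrom = chroms, length = as.integer(config$chrom_length_bp))
  )
}

# Clone an annotation for the second species: same gene order and geometry,
# TE positions jittered (jitters causing overlap with genes/TEs are dropped).
jitter_annotation <- function(annotation, config, prefix = "Pe") {
  set.seed(derive_seed(config$seed, paste0("annotation-jitter-", prefix)))
  f <- annotation$features
  f$id <- sub("^[^_]+_", paste0(prefix, "_"), f$id)
  f$parent <- ifelse(is.na(f$parent), NA_character_,
                     sub("^[^_]+_", paste0(prefix, "_"), f$parent))
  te_idx <- which(f$kind == "TE")
  if (length(te_idx) > 0L) {
    len_tbl <- annotation$chrom_lengths
    other <- f[f$kind == "gene", c("chrom", "start", "end")]
    for (i in te_idx) {
      w <- f$end[i] - f$start[i]
      L <- len_tbl$length[match(f$chrom[i], len_tbl$chrom)]
      new_start <- f$start[i] + as.integer(round(rnorm(1, 0, 300)))
      new_start <- max(0L, min(L - w, new_start))
      clash <- any(other$chrom == f$chrom[i] &
                     other$start < new_start + w & other$end > new_start) ||
        any(f$kind == "TE" & f$chrom == f$chrom[i] & seq_len(nrow(f)) != i &
              f$start < new_start + w & f$end > new_start)
      if (!clash) {
        f$start[i] <- new_start
        f$end[i] <- new_start + w
      }
    }
  }
  new_genome_annotation(f, annotation$chrom_lengths)
}

# Latent Beta draw centred on `mode` with given concentration; modes of 0/1
# are point masses.
draw_component_level <- function(n, mode, concentration) {
  if (mode <= 0) return(rep(0, n))
  if (mode >= 1) return(rep(1, n))
  rbeta(n, mode * concentration, (1 - mode) * concentration)
}

#' Simulate a three-stage CG methylome with planted DMRs
#'
#' CpG sites are laid down at roughly `cpg_spacing_bp` intervals. Each site
#' draws a latent methylation level from a two-component Beta mixture whose
#' low-component weight depends on the feature kind at the site (genic,
#' intergenic or TE); for non-TE sites the high-component probability gains a
#' spreading boost decaying with distance to the nearest TE. Latent levels are
#' shared across stages except inside planted DMR intervals, where the later
#' stage of the affected transition is shifted by `±dmr_delta` (hyper where
#' the local latent mean is low, hypo where it is high). Observed counts are
#' binomial draws at depth `1 + Poisson(depth_mean - 1)` with success
#' probability `level*(1-eps) + (1-level)*eps`, `eps` the non-conversion rate.
#'
#' @param annotation A `genome_annotation` (from [simulate_annotation()] or
#'   [read_annotation()]).
#' @param config A [sim_config()].
#' @param stages Ordered stage labels; consecutive pairs are the transitions.
#' @param seed_tag Extra tag mixed into the derived seed (one per species).
#' @return A list of class `sim_methylome`: `stages` (named list of cytosine
#'   site tibbles), `truth_sites` (per-site kind, mixture component, the
#'   configured high-component probability `p_high`, distance to nearest TE
#'   and latent level per stage) and `truth_dmrs` (planted intervals with
#'   transition, direction and delta).
#' @export
simulate_methylome <- function(annotation, config, stages = DEFAULT_STAGES,
                               seed_tag = "") {
  stopifnot(inherits(annotation, "sim_config") == FALSE,
            inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, paste0("methylome-", seed_tag)))
  lens <- annotation$chrom_lengths
  f <- annotation$features

  # site positions
  site_list <- purrr::map2(lens$chrom, lens$length, function(ch, L) {
    n0 <- ceiling(L / config$cpg_spacing_bp * 1.7) + 10L
    gaps <- pmax(2L, round(rexp(n0, 1 / config$cpg_spacing_bp)))
    pos <- cumsum(gaps)
    tibble::tibble(chrom = ch, pos = as.integer(pos[pos < L]))
  })
  sites <- dplyr::bind_rows(site_list)
  n <- nrow(sites)

  # feature kind at each site: TE > genic (gene +/- 1kb) > intergenic
  site_gr <- sites_to_granges(sites)
  kind <- rep("intergenic", n)
  genes <- f[f$kind == "gene", ]
  if (nrow(genes) > 0L) {
    genic <- genes
    genic$start <- pmax(0L, genic$start - 1000L)
    genic$end <- genic$end + 1000L
    hit <- GenomicRanges::findOverlaps(site_gr, tbl_to_granges(genic))
    kind[unique(S4Vectors::queryHits(hit))] <- "genic"
  }
  tes <- f[f$kind == "TE", ]
  dist_te <- rep(NA_real_, n)
  te_of_site <- rep(NA_integer_, n)
  if (nrow(tes) > 0L) {
    te_gr <- tbl_to_granges(tes)
    hit <- GenomicRanges::findOverlaps(site_gr, te_gr)
    kind[unique(S4Vectors::queryHits(hit))] <- "TE"
    te_of_site[S4Vectors::queryHits(hit)] <- S4Vectors::subjectHits(hit)
    nearest <- GenomicRanges::distanceToNearest(site_gr, te_gr)
    dist_te[S4Vectors::queryHits(nearest)] <- S4Vectors::mcols(nearest)$distance
  }

  # latent mixture; each TE draws its own low-component weight around the
  # configured mean (element-to-element heterogeneity)
  p_high <- 1 - unname(config$low_weight[ifelse(kind == "TE", "TE",
                                                ifelse(kind == "genic", "genic", "intergenic"))])
  if (nrow(tes) > 0L) {
    w_low_te <- config$low_weight[["TE"]]
    cc <- config$te_weight_concentration
    te_p_high <- if (w_low_te <= 0) rep(1, nrow(tes)) else if (w_low_te >= 1) {
      rep(0, nrow(tes))
    } else rbeta(nrow(tes), cc * (1 - w_low_te), cc * w_low_te)
    is_te_site <- !is.na(te_of_site)
    p_high[is_te_site] <- te_p_high[te_of_site[is_te_site]]
  }
  boost <- ifelse(kind != "TE" & !is.na(dist_te),
                  config$te_spread_boost * exp(-dist_te / config$te_spread_bp), 0)
  p_high <- pmin(0.98, p_high + boost)
  component <- ifelse(rbinom(n, 1L, p_high) == 1L, "high", "low")
  latent <- numeric(n)
  latent[component == "low"] <- draw_component_level(sum(component == "low"),
                                                     config$low_mode,
                                                     config$beta_concentration)
  latent[component == "high"] <- draw_component_level(sum(component == "high"),
                                                      config$high_mode,
                                                      config$beta_concentration)

  # planted DMRs: per transition, non-overlapping intervals
  n_trans <- length(stages) - 1L
  truth_dmrs <- tibble::tibble(transition = integer(), chrom = character(),
                               start = integer(), end = integer(),
                               direction = character(), delta = double())
  shift <- matrix(0, nrow = n, ncol = n_trans)
  if (config$n_planted_dmrs > 0L && config$dmr_delta > 0) {
    taken <- tibble::tibble(chrom = character(), start = integer(), end = integer())
    for (t in seq_len(n_trans)) {
      planted <- 0L
      tries <- 0L
      while (planted < config$n_planted_dmrs && tries < 200L * config$n_planted_dmrs) {
        tries <- tries + 1L
        ch <- sample(lens$chrom, 1L)
        L <- lens$length[match(ch, lens$chrom)]
        s <- as.integer(sample.int(L - config$dmr_length_bp, 1L))
        e <- s + config$dmr_length_bp
        if (any(taken$chrom == ch & taken$start < e & taken$end > s)) next
        in_reg <- which(sites$chrom == ch & sites$pos >= s & sites$pos < e)
        if (length(in_reg) < 15L) next
        dir <- if (mean(latent[in_reg]) < 0.5) "hyper" else "hypo"
        d <- if (dir == "hyper") config$dmr_delta else -config$dmr_delta
        shift[in_reg, t] <- d
        taken <- dplyr::bind_rows(taken, tibble::tibble(chrom = ch, start = s, end = e))
        truth_dmrs <- dplyr::bind_rows(truth_dmrs, tibble::tibble(
          transition = t, chrom = ch, start = s, end = e,
          direction = dir, delta = abs(d)))
        planted <- planted + 1L
      }
      if (planted < config$n_planted_dmrs) {
        stop("could not place all planted DMRs; genome too small/dense", call. = FALSE)
      }
    }
  }

  # per-stage latent levels: shifts accumulate along transitions
  latent_stage <- matrix(latent, nrow = n, ncol = length(stages))
  for (t in seq_len(n_trans)) {
    for (s2 in (t + 1L):length(stages)) {
      latent_stage[, s2] <- latent_stage[, s2] + shift[, t]
    }
  }
  n_clamped <- sum(latent_stage < 0 | latent_stage > 1)
  if (n_clamped > 0L) {
    warning(sprintf("clamped %d latent level(s) outside [0,1] after DMR planting", n_clamped))
    latent_stage <- pmin(pmax(latent_stage, 0), 1)
  }
  colnames(latent_stage) <- stages

  eps <- config$nonconversion_rate
  stage_sites <- purrr::map(setNames(stages, stages), function(st) {
    depth <- 1L + rpois(n, config$depth_mean - 1)
    p <- latent_stage[, st] * (1 - eps) + (1 - latent_stage[, st]) * eps
    meth <- rbinom(n, depth, p)
    tibble::tibble(
      chrom = sites$chrom, pos = sites$pos, strand = "+", context = "CG",
      meth_reads = meth, total_reads = depth,
      level = ifelse(depth > 0, meth / depth, NA_real_),
      stage = st
    )
  })

  truth_sites <- dplyr::bind_cols(
    sites,
    tibble::tibble(kind = kind, component = component, dist_te = dist_te,
                   p_high = p_high),
    tibble::as_tibble(latent_stage) |>
      rlang::set_names(paste0("latent_", stages))
  )

  structure(list(stages = stage_sites, truth_sites = truth_sites,
                 truth_dmrs = truth_dmrs, stage_order = stages),
            class = "sim_methylome")
}

#' Simulate two-species expression counts with planted divergence classes
#'
#' Draws shared log-normal baseline means for the 1:1 orthologs, plants
#' per-phase log2 shifts according to the configured divergence class counts
#' (`DE1-Pt` shifts only species 1, `DE1-Pe` only species 2, `DE2-identical`
#' the same random sign in both, `DE2-opposite` opposite signs), applies the
#' repressive methylation coupling when methylomes are supplied, and emits
#' negative-binomial counts for `n_replicates` replicates per species and
#' stage, for genes and TEs. Also emits the ortholog pair table with simulated
#' consensus statistics and the ground-truth class table.
#'
#' @param config A [sim_config()].
#' @param annotations Optional named list of two `genome_annotation`s
#'   (feature lengths and TE classes are taken from them). If `NULL`, feature
#'   geometry is invented.
#' @param methylomes Optional named list of two `sim_methylome`s aligned with
#'   `annotations`; enables the methylation-repression coupling.
#' @param species Character vector of the two species tags.
#' @param stages Ordered stage labels.
#' @return A list of class `sim_expression` with `counts` and `te_counts`
#'   (named per-species tibbles: `feature_id`, `length`, sample columns),
#'   `samples` (sample metadata), `pairs` (ortholog table) and
#'   `truth_classes` (gene x phase planted class).
#' @export
simulate_expression <- function(config, annotations = NULL, methylomes = NULL,
                                species = c("Pt", "Pe"), stages = DEFAULT_STAGES) {
  stopifnot(inherits(config, "sim_config"))
  if (config$nb_dispersion <= 0) stop("nb_dispersion must be > 0", call. = FALSE)
  set.seed(derive_seed(config$seed, "expression"))
  n_genes <- config$n_genes
  n_phases <- length(stages) - 1L

  gene_ids <- purrr::map(setNames(species, species), function(sp) {
    if (!is.null(annotations)) {
      g <- annotations[[sp]]$features
      g$id[g$kind == "gene"]
    } else sprintf("%s_g%04d", sp, seq_len(n_genes))
  })
  gene_len <- purrr::map(setNames(species, species), function(sp) {
    if (!is.null(annotations)) {
      g <- annotations[[sp]]$features
      g <- g[g$kind == "gene", ]
      as.integer(g$end - g$start)
    } else as.integer(round(runif(n_genes, 1000, 3000)))
  })

  # planted per-phase shifts
  classes <- c("DE1-Pt", "DE1-Pe", "DE2-identical", "DE2-opposite")
  shift <- array(0, dim = c(n_genes, n_phases, 2L),
                 dimnames = list(NULL, NULL, species))
  truth_classes <- purrr::map_dfr(seq_len(n_phases), function(ph) {
    cls <- rep("DE0", n_genes)
    pick <- sample.int(n_genes, sum(config$class_counts))
    splits <- rep(classes, times = config$class_counts[classes])
    cls[pick] <- splits
    sgn <- sample(c(-1, 1), n_genes, replace = TRUE)
    lfc <- config$planted_lfc
    shift[cls == "DE1-Pt", ph, 1L] <<- sgn[cls == "DE1-Pt"] * lfc
    shift[cls == "DE1-Pe", ph, 2L] <<- sgn[cls == "DE1-Pe"] * lfc
    shift[cls == "DE2-identical", ph, 1L] <<- sgn[cls == "DE2-identical"] * lfc
    shift[cls == "DE2-identical", ph, 2L] <<- sgn[cls == "DE2-identical"] * lfc
    shift[cls == "DE2-opposite", ph, 1L] <<- sgn[cls == "DE2-opposite"] * lfc
    shift[cls == "DE2-opposite", ph, 2L] <<- -sgn[cls == "DE2-opposite"] * lfc
    tibble::tibble(gene_a = gene_ids[[1L]], gene_b = gene_ids[[2L]],
                   phase = paste0("phase", ph), class = cls)
  })

  base_mu <- rlnorm(n_genes, config$mu_meanlog, config$mu_sdlog)

  # repressive coupling: mean latent promoter (+ half gene-body) mCG level
  repress <- purrr::map(setNames(species, species), function(sp) {
    if (is.null(methylomes) || is.null(annotations)) return(rep(1, n_genes))
    ann <- annotations[[sp]]$features
    genes <- ann[ann$kind == "gene", ]
    meth <- methylomes[[sp]]
    lat <- rowMeans(as.matrix(
      meth$truth_sites[, paste0("latent_", stages)]))
    sgr <- sites_to_granges(meth$truth_sites)
    prom <- genes
    up <- prom$strand == "+"
    ps <- ifelse(up, pmax(0, prom$start - 1000L), prom$end)
    pe <- ifelse(up, prom$start, prom$end + 1000L)
    prom_gr <- GenomicRanges::GRanges(prom$chrom, IRanges::IRanges(ps + 1L, pe))
    body_gr <- tbl_to_granges(genes)
    mean_over <- function(gr) {
      hit <- GenomicRanges::findOverlaps(sgr, gr)
      v <- rep(0, length(gr))
      agg <- tapply(lat[S4Vectors::queryHits(hit)], S4Vectors::subjectHits(hit), mean)
      v[as.integer(names(agg))] <- agg
      v
    }
    exp(-config$methylation_repression * (mean_over(prom_gr) + 0.5 * mean_over(body_gr)))
  })

  sample_tbl <- tidyr::expand_grid(species = species, stage = stages,
                                   replicate = seq_len(config$n_replicates)) |>
    dplyr::mutate(sample = sprintf("%s_%s_%d", .data$species, .data$stage, .data$replicate))

  draw_counts <- function(mu_stage, ids, lens, sp) {
    smp <- sample_tbl |> dplyr::filter(.data$species == sp)
    out <- tibble::tibble(feature_id = ids, length = lens)
    for (i in seq_len(nrow(smp))) {
      f <- rlnorm(1, 0, config$libsize_sdlog)
      mu <- mu_stage[, smp$stage[i]] * f
      out[[smp$sample[i]]] <- rnbinom(length(ids), mu = mu, size = 1 / config$nb_dispersion)
    }
    out
  }

  counts <- purrr::imap(setNames(seq_along(species), species), function(si, sp) {
    mu_stage <- matrix(base_mu * repress[[sp]], nrow = n_genes, ncol = length(stages),
                       dimnames = list(NULL, stages))
    for (ph in seq_len(n_phases)) {
      for (s2 in (ph + 1L):length(stages)) {
        mu_stage[, s2] <- mu_stage[, s2] * 2^shift[, ph, si]
      }
    }
    draw_counts(mu_stage, gene_ids[[sp]], gene_len[[sp]], sp)
  })

  # TE expression: low baseline, repressed by the element's own latent level
  te_counts <- purrr::map(setNames(species, species), function(sp) {
    if (!is.null(annotations)) {
      te <- annotations[[sp]]$features
      te <- te[te$kind == "TE", ]
      ids <- te$id
      lens <- as.integer(te$end - te$start)
    } else {
      ids <- sprintf("%s_te%04d", sp, seq_len(config$n_tes))
      lens <- as.integer(round(runif(config$n_tes, 300, 1500)))
    }
    n_te <- length(ids)
    mu0 <- rlnorm(n_te, config$te_mu_meanlog, config$te_mu_sdlog)
    if (!is.null(methylomes) && !is.null(annotations)) {
      meth <- methylomes[[sp]]
      lat <- rowMeans(as.matrix(meth$truth_sites[, paste0("latent_", stages)]))
      te <- annotations[[sp]]$features
      te <- te[te$kind == "TE", ]
      hit <- GenomicRanges::findOverlaps(sites_to_granges(meth$truth_sites),
                                         tbl_to_granges(te))
      lev <- rep(0, n_te)
      agg <- tapply(lat[S4Vectors::queryHits(hit)], S4Vectors::subjectHits(hit), mean)
      lev[as.integer(names(agg))] <- agg
      mu0 <- mu0 * exp(-config$methylation_repression * lev)
    }
    mu_stage <- matrix(mu0, nrow = n_te, ncol = length(stages),
                       dimnames = list(NULL, stages))
    draw_counts(mu_stage, ids, lens, sp)
  })

  pairs <- tibble::tibble(
    gene_a = gene_ids[[1L]], gene_b = gene_ids[[2L]],
    consensus_fraction = rbeta(n_genes, 14, 3),
    consensus_length_bp = as.integer(round(
      rbeta(n_genes, 14, 3) * pmin(gene_len[[1L]], gene_len[[2L]])))
  )

  structure(list(counts = counts, te_counts = te_counts, samples = sample_tbl,
                 pairs = pairs, truth_classes = truth_classes,
                 stage_order = stages, species = species),
            class = "sim_expression")
}

#' Simulate the full two-species, three-stage study
#'
#' Convenience wrapper: annotation for species 1, a TE-jittered clone for
#' species 2, one methylome per species, coupled expression counts, ortholog
#' pairs, planted truth tables, and a random GO annotation map (each gene gets
#' 1-4 of 40 terms).
#'
#' @param config A [sim_config()].
#' @param species Two species tags.
#' @param stages Ordered stage labels.
#' @return A list of class `sim_study` with elements `annotations`,
#'   `methylomes`, `expression`, `go_map` and `config`.
#' @export
simulate_study <- function(config, species = c("Pt", "Pe"), stages = DEFAULT_STAGES) {
  ann1 <- simulate_annotation(config, prefix = species[1L])
  ann2 <- jitter_annotation(ann1, config, prefix = species[2L])
  annotations <- setNames(list(ann1, ann2), species)
  methylomes <- purrr::imap(annotations, function(ann, sp) {
    simulate_methylome(ann, config, stages = stages, seed_tag = sp)
  })
  expr <- simulate_expression(config, annotations = annotations,
                              methylomes = methylomes, species = species,
                              stages = stages)
  set.seed(derive_seed(config$seed, "go-map"))
  terms <- sprintf("GO:%07d", seq_len(40L))
  gene_a <- expr$pairs$gene_a
  go_map <- purrr::map_dfr(gene_a, function(g) {
    tibble::tibble(gene = g, term = sample(terms, sample.int(4L, 1L)))
  })
  structure(list(annotations = annotations, methylomes = methylomes,
                 expression = expr, go_map = go_map, config = config,
                 species = species, stage_order = stages),
            class = "sim_study")
}
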