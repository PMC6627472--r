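# Expression quantification, NB differential-expression testing, ortholog
# filtering and five-class divergence classification.

DIVERGENCE_CLASSES <- c("DE0", "DE1-Pt", "DE1-Pe", "DE2-identical", "DE2-opposite")

#' Transcripts per million
#'
#' Per sample: `rate_i = count_i / length_i`, `TPM_i = 1e6 * rate_i / sum(rate)`.
#' Columns therefore sum to one million; an all-zero column becomes all-`NA`
#' with a warning.
#'
#' @param counts Count tibble (`feature_id`, `length` in bp, sample columns).
#' @return A tibble of the same shape with TPM values.
#' @export
compute_tpm <- function(counts) {
  assert_columns(counts, c("feature_id", "length"))
  if (any(counts$length <= 0)) stop("feature lengths must be > 0", call. = FALSE)
  out <- counts
  for (col in setdiff(names(counts), c("feature_id", "length"))) {
    rate <- counts[[col]] / counts$length
    tot <- sum(rate)
    if (tot == 0) {
      warning(sprintf("compute_tpm: all-zero column %s", col))
      out[[col]] <- NA_real_
    } else {
      out[[col]] <- 1e6 * rate / tot
    }
  }
  out
}

#' Expressed-feature mask
#'
#' A feature counts as expressed when its replicate-mean TPM exceeds
#' `threshold` in at least one stage.
#'
#' @param tpm TPM tibble (`feature_id`, `length`, sample columns).
#' @param samples Sample metadata tibble (`sample`, `stage`; a `species`
#'   column, if present, must be unique or pre-filtered).
#' @param threshold TPM threshold (strict `>`, default 1).
#' @return A tibble `feature_id`, `expressed`.
#' @export
expressed_mask <- function(tpm, samples, threshold = 1) {
  assert_columns(samples, c("sample", "stage"))
  samples <- samples |> dplyr::filter(.data$sample %in% names(tpm))
  if (nrow(samples) == 0L || nrow(tpm) == 0L) {
    return(tibble::tibble(feature_id = tpm$feature_id %||% character(),
                          expressed = logical(nrow(tpm))))
  }
  stage_means <- purrr::map(split(samples$sample, samples$stage), function(cols) {
    rowMeans(as.matrix(tpm[, cols, drop = FALSE]), na.rm = TRUE)
  })
  tibble::tibble(
    feature_id = tpm$feature_id,
    expressed = purrr::reduce(purrr::map(stage_means, ~ .x > threshold), `|`)
  )
}

#' Negative-binomial Wald differential-expression test
#'
#' A self-contained DE test for one stage transition: median-of-ratios size
#' factors, per-feature method-of-moments NB dispersion shrunk by taking the
#' maximum of the feature estimate, a trimmed-mean ensemble estimate and a
#' floor of 0.01 (the shrinkage keeps 3-vs-3 designs from anticonservative
#' Wald statistics), then a Wald test on the log2 fold change (later vs
#' earlier stage) with BH adjustment over all tested features. Status follows
#' the DEG rule: `up` when `q < q_threshold` and `log2fc > lfc_threshold`,
#' `down` for the mirrored condition, `none` otherwise. Features with zero
#' counts in every sample are untested (`status = "none"`, `qvalue = NA`).
#'
#' @param counts Count tibble (`feature_id`, `length`, sample columns).
#' @param samples Sample metadata (`sample`, `stage`).
#' @param stage_a Earlier stage label.
#' @param stage_b Later stage label.
#' @param q_threshold,lfc_threshold DEG thresholds (defaults 0.01 and 1).
#' @param dispersion_floor Lower bound of the dispersion estimate.
#' @return A tibble of class `methdev_de` with `feature_id`, `base_mean`,
#'   `log2fc`, `se`, `dispersion`, `pvalue`, `qvalue`, `status`.
#' @export
de_test <- function(counts, samples, stage_a, stage_b, q_threshold = 0.01,
                    lfc_threshold = 1, dispersion_floor = 0.01) {
  assert_columns(samples, c("sample", "stage"))
  cols_a <- samples$sample[samples$stage == stage_a]
  cols_b <- samples$sample[samples$stage == stage_b]
  cols_a <- intersect(cols_a, names(counts))
  cols_b <- intersect(cols_b, names(counts))
  if (length(cols_a) < 2L || length(cols_b) < 2L) {
    stop("de_test needs >= 2 replicates per condition", call. = FALSE)
  }
  mat <- as.matrix(counts[, c(cols_a, cols_b)])
  storage.mode(mat) <- "double"

  # median-of-ratios size factors (features with all-positive counts)
  pos <- rowSums(mat == 0) == 0
  if (sum(pos) >= 10L) {
    loggeo <- rowMeans(log(mat[pos, , drop = FALSE]))
    sf <- apply(mat[pos, , drop = FALSE], 2, function(x) {
      exp(median(log(x) - loggeo))
    })
  } else {
    sf <- colSums(mat) / mean(colSums(mat))
  }
  norm <- sweep(mat, 2, sf, "/")
  ia <- seq_along(cols_a)
  ib <- length(cols_a) + seq_along(cols_b)
  mu_a <- rowMeans(norm[, ia, drop = FALSE])
  mu_b <- rowMeans(norm[, ib, drop = FALSE])
  v_a <- apply(norm[, ia, drop = FALSE], 1, var)
  v_b <- apply(norm[, ib, drop = FALSE], 1, var)
  n_a <- length(ia)
  n_b <- length(ib)

  # method-of-moments dispersion pooled over both groups
  mom <- ((v_a + v_b) / 2 - (mu_a + mu_b) / 2) / pmax((mu_a + mu_b) / 2, 1e-8)^2
  tested <- rowSums(mat) > 0
  ens <- mean(pmax(mom[tested], 0), trim = 0.1, na.rm = TRUE)
  disp <- pmax(mom, ens, dispersion_floor)
  disp[is.na(disp)] <- max(ens, dispersion_floor)

  pseudo <- 0.5
  log2fc <- log2((mu_b + pseudo) / (mu_a + pseudo))
  se <- sqrt((1 / n_b) * (1 / (mu_b + pseudo) + disp) +
               (1 / n_a) * (1 / (mu_a + pseudo) + disp)) / log(2)
  z <- log2fc / se
  pvalue <- 2 * stats::pnorm(-abs(z))
  pvalue[!tested] <- NA_real_
  qvalue <- rep(NA_real_, length(pvalue))
  qvalue[tested] <- bh_adjust(pvalue[tested])
  status <- rep("none", length(pvalue))
  status[tested & qvalue < q_threshold & log2fc > lfc_threshold] <- "up"
  status[tested & qvalue < q_threshold & log2fc < -lfc_threshold] <- "down"
  out <- tibble::tibble(
    feature_id = counts$feature_id,
    base_mean = (mu_a + mu_b) / 2,
    log2fc = log2fc, se = se, dispersion = disp,
    pvalue = pvalue, qvalue = qvalue, status = status
  )
  structure(out, class = c("methdev_de", class(out)),
            stages = c(stage_a, stage_b))
}

#' Filter ortholog pairs by alignment consensus
#'
#' Keeps pairs with consensus fraction strictly above 0.70 and consensus
#' length strictly above 300 bp.
#'
#' @param pairs Ortholog tibble (`gene_a`, `gene_b`, `consensus_fraction`,
#'   `consensus_length_bp`).
#' @param min_fraction,min_length_bp Thresholds (defaults 0.70 / 300).
#' @return The tibble with a logical `kept` column.
#' @export
filter_orthologs <- function(pairs, min_fraction = 0.70, min_length_bp = 300L) {
  assert_columns(pairs, c("gene_a", "gene_b", "consensus_fraction", "consensus_length_bp"))
  dplyr::mutate(pairs, kept = .data$consensus_fraction > min_fraction &
                  .data$consensus_length_bp > min_length_bp)
}

#' Classify ortholog expression divergence
#'
#' Maps the two species' DE statuses for one phase onto the five divergence
#' classes: `(none, none) -> DE0`; DE in species A only -> `DE1-Pt`; species B
#' only -> `DE1-Pe`; both with the same direction -> `DE2-identical`; both
#' with opposite directions -> `DE2-opposite`.
#'
#' @param status_a,status_b Character vectors of DE statuses
#'   (`up`/`down`/`none`) for species A (Pt) and B (Pe).
#' @return Character vector of divergence classes.
#' @export
classify_divergence <- function(status_a, status_b) {
  stopifnot(length(status_a) == length(status_b),
            all(status_a %in% c("up", "down", "none")),
            all(status_b %in% c("up", "down", "none")))
  dplyr::case_when(
    status_a == "none" & status_b == "none" ~ "DE0",
    status_b == "none" ~ "DE1-Pt",
    status_a == "none" ~ "DE1-Pe",
    status_a == status_b ~ "DE2-identical",
    TRUE ~ "DE2-opposite"
  )
}

#' Per-pair, per-phase divergence table
#'
#' Joins kept ortholog pairs with the two species' DE results for each phase
#' and classifies every pair.
#'
#' @param pairs Filtered ortholog tibble (uses rows with `kept = TRUE` when a
#'   `kept` column is present).
#' @param de_a,de_b Named lists of [de_test()] results per phase
#'   (names `phase1`, `phase2`, ...), for species A and B.
#' @return A long tibble `gene_a`, `gene_b`, `phase`, `status_a`, `status_b`,
#'   `log2fc_a`, `log2fc_b`, `class`.
#' @export
ortholog_divergence <- function(pairs, de_a, de_b) {
  stopifnot(identical(names(de_a), names(de_b)))
  if ("kept" %in% names(pairs)) pairs <- dplyr::filter(pairs, .data$kept)
  purrr::imap_dfr(de_a, function(da, ph) {
    db <- de_b[[ph]]
    pairs |>
      dplyr::inner_join(da |> dplyr::select("feature_id", status_a = "status",
                                            log2fc_a = "log2fc"),
                        by = c("gene_a" = "feature_id")) |>
      dplyr::inner_join(db |> dplyr::select("feature_id", status_b = "status",
                                            log2fc_b = "log2fc"),
                        by = c("gene_b" = "feature_id")) |>
      dplyr::mutate(phase = ph,
                    class = classify_divergence(.data$status_a, .data$status_b)) |>
      dplyr::select("gene_a", "gene_b", "phase", "status_a", "status_b",
                    "log2fc_a", "log2fc_b", "class")
  })
}

#' Correlation of ortholog fold changes between species
#'
#' Pearson correlation of the two species' log2 fold changes for one phase,
#' optionally restricted to non-DE0 pairs or a user gene set.
#'
#' @param divergence Output of [ortholog_divergence()].
#' @param phase Phase label to correlate.
#' @param subset `"all"`, `"non-DE0"`, or a character vector of `gene_a` ids.
#' @return One-row tibble `phase`, `subset`, `n`, `estimate`, `p.value`.
#' @export
foldchange_correlation <- function(divergence, phase, subset = "all") {
  d <- divergence |> dplyr::filter(.data$phase == !!phase)
  lab <- if (length(subset) == 1L && subset %in% c("all", "non-DE0")) subset else "gene-set"
  if (lab == "non-DE0") {
    d <- d |> dplyr::filter(.data$class != "DE0")
  } else if (lab == "gene-set") {
    d <- d |> dplyr::filter(.data$gene_a %in% subset)
  }
  if (nrow(d) < 3L) stop("foldchange_correlation: fewer than 3 pairs", call. = FALSE)
  ct <- pearson_test(d$log2fc_a, d$log2fc_b)
  tibble::tibble(phase = phase, subset = lab, n = nrow(d),
                 estimate = ct$estimate, p.value = ct$p.value)
}

#' Correlation between methylation level and expression
#'
#' Pearson correlation between per-feature average mCG level and
#' `log10(average TPM)` on the stated subset (default: features with
#' TPM > 0).
#'
#' @param meth_level Numeric vector of per-feature average mCG levels.
#' @param mean_tpm Numeric vector of per-feature average TPM (same order).
#' @param min_tpm Subset threshold: features with `mean_tpm > min_tpm` enter
#'   the correlation (default 0).
#' @return One-row tibble `n`, `estimate`, `p.value` (`NA` with a warning for
#'   degenerate input).
#' @export
methylation_expression_correlation <- function(meth_level, mean_tpm, min_tpm = 0) {
  stopifnot(length(meth_level) == length(mean_tpm))
  keep <- !is.na(meth_level) & !is.na(mean_tpm) & mean_tpm > min_tpm
  x <- meth_level[keep]
  y <- log10(mean_tpm[keep])
  if (length(x) < 3L || sd(x) == 0 || sd(y) == 0) {
    warning("methylation_expression_correlation: degenerate subset")
    return(tibble::tibble(n = length(x), estimate = NA_real_, p.value = NA_real_))
  }
  ct <- pearson_test(x, y)
  tibble::tibble(n = length(x), estimate = ct$estimate, p.value = ct$p.value)
}

#' Expressed-TE summary by class and stage
#'
#' Per TE class and stage: total elements, elements expressed (replicate-mean
#' TPM > `threshold`) and the expressed proportion. Classes absent from the
#' annotation are omitted.
#'
#' @param te_annotation Tibble of TEs (`id`, `te_class`), e.g.
#'   `annotation$features` filtered to `kind == "TE"`.
#' @param tpm TE TPM tibble (`feature_id`, `length`, sample columns).
#' @param samples Sample metadata (`sample`, `stage`).
#' @param threshold Expression threshold (default 1).
#' @return A tibble `te_class`, `stage`, `n_total`, `n_expressed`, `proportion`.
#' @export
te_expression_summary <- function(te_annotation, tpm, samples, threshold = 1) {
  assert_columns(te_annotation, c("id", "te_class"))
  samples <- samples |> dplyr::filter(.data$sample %in% names(tpm))
  purrr::map_dfr(split(samples$sample, samples$stage), function(cols) {
    means <- rowMeans(as.matrix(tpm[, cols, drop = FALSE]), na.rm = TRUE)
    tibble::tibble(feature_id = tpm$feature_id, mean_tpm = means)
  }, .id = "stage") |>
    dplyr::inner_join(te_annotation |> dplyr::select(feature_id = "id", "te_class"),
                      by = "feature_id") |>
    dplyr::group_by(.data$te_class, .data$stage) |>
    dplyr::summarise(
      n_total = dplyr::n(),
      n_expressed = sum(.data$mean_tpm > threshold),
      proportion = .data$n_expressed / .data$n_total,
      .groups = "drop"
    )
}
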