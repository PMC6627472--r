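# Internal helpers shared across modules.

# Five-way transposable-element vocabulary used throughout.
TE_CLASSES <- c("Gypsy", "Copia", "LTR-other", "LINE", "DNA")

# Default ordered developmental stages: mycelium < primordium < fruit body.
DEFAULT_STAGES <- c("MY", "PR", "FB")

#' Derive a child seed from a global seed and a stage label
#'
#' A fixed arithmetic derivation so pipeline stages can be re-run in isolation
#' while a single global seed determines every source of randomness. The
#' result is always a valid 32-bit integer seed.
#'
#' @param seed Integer global seed.
#' @param what Character label of the consuming stage.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, what) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(what))
  h <- sum(utf8ToInt(what) * seq_along(utf8ToInt(what)))
  as.integer((abs(seed) + h * 97003) %% 2147483629L)
}

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# Convert a 0-based half-open interval tibble to GRanges (1-based closed).
tbl_to_granges <- function(tbl, seqlengths = NULL) {
  assert_columns(tbl, c("chrom", "start", "end"))
  strand <- if ("strand" %in% names(tbl)) {
    ifelse(tbl$strand %in% c("+", "-"), tbl$strand, "*")
  } else "*"
  GenomicRanges::GRanges(
    seqnames = tbl$chrom,
    ranges = IRanges::IRanges(start = tbl$start + 1L, end = tbl$end),
    strand = strand
  )
}

# Point positions (0-based) to width-1 GRanges.
sites_to_granges <- function(sites) {
  assert_columns(sites, c("chrom", "pos"))
  GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$pos + 1L, width = 1L)
  )
}

# Normalise chromosome lengths input (tibble or named vector) to a tibble.
as_chrom_lengths <- function(x) {
  if (is.data.frame(x)) {
    assert_columns(x, c("chrom", "length"), "chrom_lengths")
    tibble::tibble(chrom = as.character(x$chrom), length = as.integer(x$length))
  } else if (!is.null(names(x))) {
    tibble::tibble(chrom = names(x), length = as.integer(x))
  } else {
    stop("chrom_lengths must be a tibble with columns chrom/length or a named vector",
         call. = FALSE)
  }
}
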