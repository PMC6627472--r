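# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a DMR result
#'
#' @param x A `dmr_result` from [call_dmrs()].
#' @param what `"windows"` (default) or `"dmrs"`.
#' @param ... Unused.
#' @return A tibble of window tests or merged DMRs.
#' @export
tidy.dmr_result <- function(x, what = c("windows", "dmrs"), ...) {
  what <- match.arg(what)
  tibble::as_tibble(x[[what]])
}

#' One-row summary of a DMR result
#'
#' @param x A `dmr_result`.
#' @param ... Unused.
#' @return A one-row tibble: windows tested, eligible, significant, DMR
#'   counts by direction.
#' @export
glance.dmr_result <- function(x, ...) {
  w <- x$windows
  tibble::tibble(
    n_windows = nrow(w),
    n_eligible = sum(w$eligible),
    n_significant = sum(w$status != "none"),
    n_dmrs = nrow(x$dmrs),
    n_hyper = sum(x$dmrs$status == "hyper"),
    n_hypo = sum(x$dmrs$status == "hypo")
  )
}

#' Tidy a differential-expression result
#'
#' @param x A `methdev_de` tibble from [de_test()].
#' @param ... Unused.
#' @return A plain tibble of per-feature results.
#' @export
tidy.methdev_de <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-row summary of a differential-expression result
#'
#' @param x A `methdev_de` tibble.
#' @param ... Unused.
#' @return A one-row tibble: features tested, up, down.
#' @export
glance.methdev_de <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x),
    n_tested = sum(!is.na(x$qvalue)),
    n_up = sum(x$status == "up"),
    n_down = sum(x$status == "down")
  )
}
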