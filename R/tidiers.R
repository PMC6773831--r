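#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a coverage-loss sweep
#'
#' @param x A `loss_sweep`.
#' @param ... Unused.
#' @return A plain tibble, one row per audited variant.
#' @export
tidy.loss_sweep <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a coverage-loss sweep
#'
#' @param x A `loss_sweep`.
#' @param ... Unused.
#' @return A tibble with the number of variants audited, the number (and
#'   distinct positions) losing coverage, and loss extremes.
#' @export
glance.loss_sweep <- function(x, ...) {
  lost <- x$loss_pct > 0
  tibble::tibble(
    n_variants = nrow(x),
    n_lost = sum(lost),
    n_positions_lost = length(unique(x$pos[lost])),
    max_loss = if (nrow(x)) max(x$loss_pct) else NA_real_,
    mean_loss = if (nrow(x)) mean(x$loss_pct) else NA_real_,
    n_total_loss = sum(x$loss_pct == 100))
}

#' Tidy an alignment set
#' @param x An `alignment_set`.
#' @param ... Unused.
#' @return A plain tibble of alignment records.
#' @export
tidy.alignment_set <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of an alignment run
#' @param x An `alignment_set`.
#' @param ... Unused.
#' @return A tibble with read, mapped, ambiguous and unmapped counts.
#' @export
glance.alignment_set <- function(x, ...) {
  tibble::tibble(
    n_reads = nrow(x),
    n_mapped = sum(x$mapped),
    n_ambiguous = sum(x$ambiguous),
    n_unmapped = sum(!x$mapped))
}

#' Tidy a background-SNP scan
#' @param x A `background_scan`.
#' @param ... Unused.
#' @return A plain tibble with the background SNV attached as a column.
#' @export
tidy.background_scan <- function(x, ...) {
  out <- tibble::as_tibble(x)
  bg <- attr(x, "background")
  if (!is.null(bg) && nrow(out) > 0) out$background <- format_snv(bg)
  out
}

#' One-row summary of a background-SNP scan
#' @param x A `background_scan`.
#' @param ... Unused.
#' @return A tibble with focal counts and delta extremes.
#' @export
glance.background_scan <- function(x, ...) {
  tibble::tibble(
    background = format_snv(attr(x, "background")),
    n_focal = nrow(x),
    n_delta_pos = sum(x$delta > 0),
    max_delta = if (nrow(x)) max(x$delta) else NA_real_,
    mean_delta = if (nrow(x)) mean(x$delta) else NA_real_)
}
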