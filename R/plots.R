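#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_hline geom_abline labs theme_minimal scale_colour_manual
NULL

#' Plot a coverage profile
#'
#' Depth against position; nuMT-homologous regions appear as dips below the
#' flat interior maximum.
#'
#' @param object A `coverage_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coverage_profile <- function(object, ...) {
  ggplot(tibble::as_tibble(object), aes(x = .data$pos, y = .data$depth)) +
    geom_line(linewidth = 0.3) +
    labs(x = sprintf("position on %s (bp)", attr(object, "contig")),
         y = "depth (x)") +
    theme_minimal()
}

#' Compare reference and mutated coverage profiles
#'
#' Overlay of the unaltered reference profile (black) and the profile after
#' introducing a variant (red), the classic view of allele-specific coverage
#' loss around a confounded position.
#'
#' @param ref_profile,mut_profile `coverage_profile`s on the same contig.
#' @param zoom Optional `c(from, to)` positions to restrict the x-axis.
#' @return A ggplot.
#' @export
plot_coverage_comparison <- function(ref_profile, mut_profile, zoom = NULL) {
  d <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(ref_profile), allele = "reference"),
    dplyr::mutate(tibble::as_tibble(mut_profile), allele = "alternative"))
  if (!is.null(zoom)) d <- d[d$pos >= zoom[1] & d$pos <= zoom[2], ]
  ggplot(d, aes(x = .data$pos, y = .data$depth, colour = .data$allele)) +
    geom_line(linewidth = 0.4) +
    scale_colour_manual(values = c(reference = "black", alternative = "red")) +
    labs(x = "position (bp)", y = "depth (x)", colour = NULL) +
    theme_minimal()
}

#' Plot a coverage-loss sweep
#'
#' Percent loss against mitochondrial position, one point per variant with
#' loss above `floor` (up to three per position).
#'
#' @param object A `loss_sweep`.
#' @param floor Plot only variants with loss strictly above this percent
#'   (default 0; use 3 for paired-end sweeps).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.loss_sweep <- function(object, floor = 0, ...) {
  d <- tibble::as_tibble(object)
  d <- d[d$loss_pct > floor, , drop = FALSE]
  ggplot(d, aes(x = .data$pos, y = .data$loss_pct)) +
    geom_point(size = 0.6, alpha = 0.7) +
    labs(x = "mitochondrial position (bp)", y = "coverage loss (%)") +
    theme_minimal()
}

#' Plot observed versus nominal minor allele frequency
#'
#' Reference bias pulls points below the identity line: alternative-allele
#' reads captured by nuMTs depress the observed MAF below the true
#' heteroplasmy.
#'
#' @param object A `bias_report` (or any tibble with `nominal_maf` and
#'   `observed_maf`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bias_report <- function(object, ...) {
  ggplot(tibble::as_tibble(object),
         aes(x = .data$nominal_maf, y = .data$observed_maf)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    geom_point(alpha = 0.7) +
    labs(x = "nominal MAF (true heteroplasmy)", y = "observed MAF") +
    theme_minimal()
}

#' Plot a background-SNP scan
#'
#' Loss of each focal variant with and without the background SNP, against
#' distance from the background position.
#'
#' @param object A `background_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.background_scan <- function(object, ...) {
  bg <- attr(object, "background")
  d <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("loss_without", "loss_with"),
    names_to = "background_state", values_to = "loss_pct")
  d$background_state <- ifelse(d$background_state == "loss_with",
                               "with background SNP", "reference background")
  ggplot(d, aes(x = .data$pos, y = .data$loss_pct,
                colour = .data$background_state)) +
    geom_point(size = 0.7, alpha = 0.8) +
    labs(x = "mitochondrial position (bp)", y = "coverage loss (%)",
         colour = NULL,
         title = sprintf("Background %s", format_snv(bg))) +
    theme_minimal()
}
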