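#' Relative isoform abundance from qPCR Ct values
#'
#' Delta-Ct quantification assuming perfect primer efficiency (exact doubling
#' per cycle): `ratio(target) = 2^(mean Ct_ref - mean Ct_target)` relative to
#' the reference target (the linear mRNA by default), so the reference's
#' ratio is exactly 1. The SD of the ratio is propagated from the replicate
#' Ct SDs in quadrature on the log2 scale
#' (`sd_log2 = sqrt(sd_ref^2 + sd_target^2)`, `sd_ratio = ratio ln(2)
#' sd_log2`). Replicates with Ct above `max_ct` cycles are treated as
#' non-detected and propagate a below-detection flag (NA ratio).
#'
#' @param ct Ct table: data frame with columns `target` and `ct` (one row per
#'   replicate; filter to one sample/treatment first if the table mixes them).
#' @param reference_target Reference target name (default `"linear"`).
#' @param max_ct Detection limit in cycles (default 40).
#' @return Tibble per target: `n`, `mean_ct`, `sd_ct`, `ratio`, `sd_ratio`,
#'   `below_detection`.
#' @examples
#' ct <- tibble::tibble(target = c("linear", "circle"), ct = c(20, 23))
#' relative_abundance(ct)  # circle at one-eighth of linear
#' @export
relative_abundance <- function(ct, reference_target = "linear", max_ct = 40) {
  stopifnot(all(c("target", "ct") %in% names(ct)))
  if (!reference_target %in% ct$target) {
    abort(sprintf("reference target '%s' absent from Ct table",
                  reference_target))
  }
  if (any(!is.finite(ct$ct) | ct$ct <= 0)) abort("Ct values must be finite and positive")
  per <- ct |>
    as_tibble() |>
    dplyr::group_by(.data$target) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_ct = mean(.data$ct),
      sd_ct = ifelse(dplyr::n() > 1, sd(.data$ct), 0),
      below_detection = any(.data$ct > .env$max_ct)
    )
  ref <- per[per$target == reference_target, ]
  per |>
    dplyr::mutate(
      ratio = dplyr::if_else(
        .data$below_detection | ref$below_detection,
        NA_real_,
        2^(ref$mean_ct - .data$mean_ct)
      ),
      ratio = dplyr::if_else(.data$target == reference_target & !.data$below_detection,
                             1, .data$ratio),
      sd_log2 = sqrt(ref$sd_ct^2 + .data$sd_ct^2),
      sd_ratio = .data$ratio * log(2) * .data$sd_log2
    )
}

#' RNase R enrichment / depletion on the log2 scale
#'
#' `log2` fold change of each target after treatment relative to mock,
#' computed directly from mean Ct values (`mean Ct_mock - mean Ct_treated`
#' under perfect primer efficiency). Positive values are enrichment,
#' negative values depletion -- circular and lariat species are enriched by
#' RNase R while linear RNA is depleted.
#'
#' @param treated,mock Ct tables (columns `target`, `ct`).
#' @param target Targets to report; default all targets present in both.
#' @return Tibble: `target`, `log2_enrichment`, `sd` (quadrature of replicate
#'   Ct SDs).
#' @export
enrichment_log2 <- function(treated, mock, target = NULL) {
  shared <- intersect(unique(treated$target), unique(mock$target))
  if (is.null(target)) target <- shared
  if (!all(target %in% shared)) {
    abort(sprintf("target(s) %s missing from one of the tables",
                  paste(setdiff(target, shared), collapse = ", ")))
  }
  summarise_ct <- function(tab) {
    tab |>
      as_tibble() |>
      dplyr::filter(.data$target %in% .env$target) |>
      dplyr::group_by(.data$target) |>
      dplyr::summarise(
        mean_ct = mean(.data$ct),
        sd_ct = ifelse(dplyr::n() > 1, sd(.data$ct), 0)
      )
  }
  tr <- summarise_ct(treated)
  mo <- summarise_ct(mock)
  dplyr::inner_join(tr, mo, by = "target", suffix = c("_treated", "_mock")) |>
    dplyr::transmute(
      target = .data$target,
      log2_enrichment = .data$mean_ct_mock - .data$mean_ct_treated,
      sd = sqrt(.data$sd_ct_treated^2 + .data$sd_ct_mock^2)
    )
}
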