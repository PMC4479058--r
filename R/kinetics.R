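#' Steady-state levels under the two-step splicing kinetic model
#'
#' Minimal first-order scheme for circle biogenesis through an
#' exon-containing lariat: the pre-mRNA source produces the skipped-exon
#' lariat at rate `k1`; the lariat is consumed by decay (`d_l`, debranching
#' and downstream turnover) and by the second splicing step (`k2`), which
#' excises the circle; the circle decays at `d_c`. At steady state,
#'
#' \deqn{L = k_1 \cdot source / (d_L + k_2), \quad C = k_2 L / d_C}
#'
#' so the circle:lariat ratio is `C/L = k2/d_c` -- directly proportional to
#' the second-step rate when decay is unchanged. Rows with `dbr1_null = TRUE`
#' (lariat debranching off) use `dbr1_null_d_l` in place of `d_l`.
#'
#' @param scenarios Data frame with columns `k1`, `k2`, `d_l`, `d_c`
#'   (first-order rate constants, same time unit throughout) and optionally
#'   `dbr1_null` (logical).
#' @param source_level Pre-mRNA source level; an arbitrary positive constant,
#'   since only ratios are ever reported (default 1).
#' @param dbr1_null_d_l Lariat decay rate to use for `dbr1_null` rows.
#' @return `scenarios` with added steady-state `lariat` and `circle` columns.
#' @examples
#' steady_state(tibble::tibble(k1 = 1, k2 = 0.5, d_l = 0.2, d_c = 0.1))
#' @export
steady_state <- function(scenarios, source_level = 1, dbr1_null_d_l = NULL) {
  stopifnot(all(c("k1", "k2", "d_l", "d_c") %in% names(scenarios)),
            source_level > 0)
  sc <- as_tibble(scenarios)
  if (!"dbr1_null" %in% names(sc)) sc$dbr1_null <- FALSE
  d_l <- sc$d_l
  if (any(sc$dbr1_null)) {
    if (is.null(dbr1_null_d_l)) {
      abort("dbr1_null rows need `dbr1_null_d_l`")
    }
    d_l[sc$dbr1_null] <- dbr1_null_d_l
  }
  rates <- c(sc$k1, sc$k2, d_l, sc$d_c)
  if (any(rates < 0)) abort("rate constants must be non-negative")
  if (any(d_l + sc$k2 <= 0) || any(sc$d_c <= 0)) {
    abort("steady state requires d_l + k2 > 0 and d_c > 0")
  }
  sc |>
    dplyr::mutate(
      lariat = .data$k1 * source_level / (d_l + .data$k2),
      circle = .data$k2 * .data$lariat / .data$d_c
    )
}

#' Predicted log2 relative circle:lariat ratio for a second-step mutant
#'
#' Under the steady-state model with decay rates unchanged between mutant
#' and wild-type, the mutant:wild-type circle-to-lariat ratio equals the
#' fold change of the second splicing step, so its log2 is
#' `log2(k2_mut / k2_wt)`: 0 for deletions that leave the second step intact
#' and negative for deletions that impair it. A mutant with `k2_mut = 0`
#' produces no circle and is reported as below detection (NA) rather than
#' `-Inf`.
#'
#' @param k2_mut,k2_wt Second-step rate constants (vectorised).
#' @return Numeric vector of log2 ratios (NA where below detection).
#' @export
predicted_log2_ratio <- function(k2_mut, k2_wt) {
  if (any(k2_wt <= 0)) abort("k2_wt must be positive")
  if (any(k2_mut < 0)) abort("k2_mut must be non-negative")
  out <- rep(NA_real_, length(k2_mut))
  pos <- k2_mut > 0
  out[pos] <- log2(k2_mut[pos] / k2_wt[if (length(k2_wt) == 1) 1 else pos])
  if (any(!pos)) warn("k2_mut = 0: below-detection sentinel (NA) reported")
  out
}

#' Infer the second-step fold change from circle and lariat abundances
#'
#' The observable counterpart of [predicted_log2_ratio()]:
#' `log2[(circle_mut/lariat_mut) / (circle_wt/lariat_wt)]`, with SD
#' propagated from the input SDs in log2 space (quadrature of
#' `sd_x / (x ln 2)` terms).
#'
#' @param circle_mut,lariat_mut,circle_wt,lariat_wt Abundances (all
#'   positive; vectorised).
#' @param sd_circle_mut,sd_lariat_mut,sd_circle_wt,sd_lariat_wt Optional SDs
#'   (default 0).
#' @return Tibble: `log2_fold_change`, `sd`.
#' @export
infer_k2_fold_change <- function(circle_mut, lariat_mut, circle_wt, lariat_wt,
                                 sd_circle_mut = 0, sd_lariat_mut = 0,
                                 sd_circle_wt = 0, sd_lariat_wt = 0) {
  vals <- c(circle_mut, lariat_mut, circle_wt, lariat_wt)
  if (any(!is.finite(vals) | vals <= 0)) {
    abort("all four abundances must be positive and finite")
  }
  lfc <- log2((circle_mut / lariat_mut) / (circle_wt / lariat_wt))
  rel <- function(sd, x) (sd / (x * log(2)))^2
  sd <- sqrt(rel(sd_circle_mut, circle_mut) + rel(sd_lariat_mut, lariat_mut) +
               rel(sd_circle_wt, circle_wt) + rel(sd_lariat_wt, lariat_wt))
  tibble(log2_fold_change = lfc, sd = sd)
}
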