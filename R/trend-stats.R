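#' Exon length vs circularization efficiency trend
#'
#' Summarises the relationship between remaining exon length and CE with
#' (i) a Spearman rank correlation -- the assumption-light headline statistic,
#' since no functional form is imposed by the data -- and (ii) a weighted
#' log-linear fit of `ln(CE)` on `remaining_length` (weights `1/sd_ln^2` by
#' default). A robust (Tukey-biweight) weighted loess smooth of `ln(CE)` is
#' fitted alongside and used as the default reference curve for outlier
#' flagging, so that curvature of the length response is not converted into
#' spurious outliers; with fewer than 10 usable records the smooth falls back
#' to the log-linear fit.
#'
#' @param data CE records: data frame with `remaining_length`, `ce` and
#'   (for weighting/flagging) `sd_ln`, `ci_low`, `ci_high`.
#' @param weights `"inverse_variance"` (default) or `"none"`.
#' @param span Loess span for the smooth reference curve (default 0.85).
#' @return A `ce_trend` object. `glance()` gives a one-row summary
#'   (`rho`, `p_value`, `slope`, `intercept`, `n`), `tidy()` the log-linear
#'   coefficient table, and `autoplot()` the CE-vs-length scatter.
#' @export
length_trend <- function(data, weights = c("inverse_variance", "none"),
                         span = 0.85) {
  weights <- match.arg(weights)
  stopifnot(all(c("remaining_length", "ce") %in% names(data)))
  usable <- data |>
    as_tibble() |>
    dplyr::filter(!is.na(.data$ce), .data$ce > 0)
  if (nrow(usable) < 3) abort("need at least 3 records with CE > 0")
  w <- if (weights == "inverse_variance") {
    if (!"sd_ln" %in% names(usable)) {
      abort("inverse-variance weighting needs an sd_ln column")
    }
    1 / usable$sd_ln^2
  } else {
    rep(1, nrow(usable))
  }
  usable$.w <- w

  if (sd(usable$ce) == 0 || sd(usable$remaining_length) == 0) {
    sp <- list(estimate = c(rho = 0), p.value = 1)  # no rank variation
  } else {
    sp <- suppressWarnings(
      cor.test(usable$remaining_length, usable$ce, method = "spearman",
               exact = FALSE)
    )
  }
  fit <- lm(log(ce) ~ remaining_length, data = usable, weights = .w)
  smooth <- NULL
  if (nrow(usable) >= 10) {
    smooth <- tryCatch(
      loess(log(ce) ~ remaining_length, data = usable, weights = .w,
            span = span, degree = 2, family = "symmetric",
            control = loess.control(surface = "direct")),
      error = function(e) NULL
    )
  }
  structure(
    list(
      data = usable,
      spearman = list(rho = unname(sp$estimate), p_value = sp$p.value),
      fit = fit,
      smooth = smooth,
      weights = weights,
      n = nrow(usable)
    ),
    class = "ce_trend"
  )
}

#' @export
print.ce_trend <- function(x, ...) {
  cat(sprintf(
    "<ce_trend> n = %d; Spearman rho = %.3f (p = %.3g); ln(CE) slope = %.4f /nt\n",
    x$n, x$spearman$rho, x$spearman$p_value, coef(x$fit)[2]
  ))
  invisible(x)
}

#' @export
glance.ce_trend <- function(x, ...) {
  tibble(
    rho = x$spearman$rho,
    p_value = x$spearman$p_value,
    slope = unname(coef(x$fit)[2]),
    intercept = unname(coef(x$fit)[1]),
    n = x$n
  )
}

#' @export
tidy.ce_trend <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = rownames(s),
    estimate = s[, 1], std_error = s[, 2],
    statistic = s[, 3], p_value = s[, 4]
  )
}

#' Fitted CE at given lengths
#'
#' @param trend A `ce_trend` object.
#' @param remaining_length Lengths (nt) at which to evaluate the fit.
#' @param curve `"smooth"` (robust loess; default, falling back to the linear
#'   fit when no smooth was fitted) or `"linear"` (weighted log-linear fit).
#' @return Fitted CE values (natural scale).
#' @export
fitted_ce <- function(trend, remaining_length, curve = c("smooth", "linear")) {
  curve <- match.arg(curve)
  stopifnot(inherits(trend, "ce_trend"))
  newdata <- tibble(remaining_length = remaining_length)
  obj <- if (curve == "smooth" && !is.null(trend$smooth)) trend$smooth else trend$fit
  exp(unname(predict(obj, newdata = newdata)))
}

#' Flag CE outliers against the fitted length trend
#'
#' A record is a high outlier when its whole 95% CI lies above the fitted
#' curve at its length (`ci_low > fitted`), and a low outlier symmetrically
#' (`ci_high < fitted`) -- the same reading one applies visually to error
#' bars against a trend line. Records whose CI straddles the curve are never
#' flagged.
#'
#' @param data CE records with `remaining_length`, `ce`, `ci_low`, `ci_high`.
#' @param trend A `ce_trend` fitted to (a superset of) these records.
#' @param curve Reference curve, see [fitted_ce()].
#' @return `data` with added `fitted` and `outlier`
#'   (`"high"`/`"low"`/`"none"`).
#' @export
flag_outliers <- function(data, trend, curve = c("smooth", "linear")) {
  curve <- match.arg(curve)
  stopifnot(all(c("remaining_length", "ci_low", "ci_high") %in% names(data)))
  data |>
    as_tibble() |>
    dplyr::mutate(
      fitted = fitted_ce(trend, .data$remaining_length, curve = curve),
      outlier = dplyr::case_when(
        is.na(.data$ci_low) | is.na(.data$ci_high) ~ "none",
        .data$ci_low > .data$fitted ~ "high",
        .data$ci_high < .data$fitted ~ "low",
        TRUE ~ "none"
      )
    )
}

#' Per-nucleotide deletion profile
#'
#' For every exon position, the number of deletions covering it and the mean
#' CE of those deletions -- the per-position view of where high- and
#' low-efficiency deletions fall along the exon.
#'
#' @param data CE records with `del_start`, `del_end`, `ce`.
#' @param exon_length Exon length (nt).
#' @return Tibble with one row per position 1..`exon_length`: `position`,
#'   `n_deletions`, `mean_ce` (NA where no deletion covers the position).
#' @export
positional_profile <- function(data, exon_length) {
  stopifnot(exon_length >= 1)
  out <- tibble(position = seq_len(exon_length), n_deletions = 0L,
                mean_ce = NA_real_)
  if (nrow(data) == 0) return(out)
  stopifnot(all(data$del_start >= 1), all(data$del_end <= exon_length))
  cover <- purrr::pmap_dfr(
    list(data$del_start, data$del_end, data$ce),
    function(s, e, ce) tibble(position = seq.int(s, e), ce = ce)
  )
  agg <- cover |>
    dplyr::group_by(.data$position) |>
    dplyr::summarise(n_deletions = dplyr::n(), mean_ce = mean(.data$ce))
  out |>
    dplyr::rows_update(agg, by = "position")
}

#' Notched-boxplot statistics for a length sample
#'
#' The notch half-width is `1.57 * IQR / sqrt(n)`, an approximate 95%
#' confidence interval for the median; the IQR uses the linear-interpolation
#' quantile convention (R type 7).
#'
#' @param x Numeric sample (e.g. exon lengths, nt).
#' @return One-row tibble: `n`, `median`, `q1`, `q3`, `iqr`,
#'   `notch_halfwidth`, `notch_low`, `notch_high`.
#' @export
notch_stats <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) abort("empty sample")
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  half <- 1.57 * iqr / sqrt(length(x))
  tibble(
    n = length(x), median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
    notch_halfwidth = half,
    notch_low = q[2] - half, notch_high = q[2] + half
  )
}

#' Wilcoxon rank sum test between two length samples
#'
#' Exact two-sided p-value when both samples are tie-free and
#' `n * m <= 10^4`; otherwise the tie-corrected normal approximation with
#' continuity correction.
#'
#' @param x,y Numeric samples.
#' @return One-row tibble: `statistic` (rank-sum W), `p_value`, `method`.
#' @export
ranksum_test <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) * length(y) <= 1e4
  ht <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE)
  )
  tibble(
    statistic = unname(ht$statistic),
    p_value = min(1, ht$p.value),
    method = if (exact) "exact" else "normal approximation (tie-corrected)"
  )
}

#' Exon-size cohort statistics
#'
#' Notch statistics per cohort plus all pairwise Wilcoxon rank sum tests --
#' the comparison of internal-exon, circle-forming-exon and skipped
#' uncircularized exon length distributions.
#'
#' @param data Data frame with a numeric `length` column and a `cohort`
#'   column.
#' @return List with `cohorts` (per-cohort [notch_stats()]) and `tests`
#'   (pairwise [ranksum_test()] results).
#' @export
cohort_stats <- function(data) {
  stopifnot(all(c("length", "cohort") %in% names(data)))
  groups <- split(data$length, data$cohort)
  cohorts <- purrr::imap_dfr(groups, function(v, nm) {
    dplyr::mutate(notch_stats(v), cohort = nm, .before = 1)
  })
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  tests <- purrr::map_dfr(pairs, function(p) {
    dplyr::mutate(ranksum_test(groups[[p[1]]], groups[[p[2]]]),
                  cohort_a = p[1], cohort_b = p[2], .before = 1)
  })
  list(cohorts = cohorts, tests = tests)
}
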