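#' Circularization efficiency point estimate
#'
#' For each isoform, CE compares the per-plasmid-copy circle output of the
#' deletion isoform with the per-copy output of the wild-type gene:
#'
#' \deqn{CE = \frac{n_c / (n_{wt} \cdot s)}{n_v / n_{vtot}}}
#'
#' where `n_c` is the RNA-library read count of the isoform's circle
#' junction, `n_wt` the RNA-library count matching the wild-type circle
#' (endogenous genomic background), `n_v` the DNA-library count of the
#' isoform's plasmid junction, `n_vtot` the total DNA-library count after
#' removal of wild-type-matching reads, and `s` the plasmid:genome copy-number
#' scaling factor (19 in wild-type *S. pombe*). CE = 1 means wild-type-level
#' circularization per gene copy. Equivalently CE = f(A) g(B) with
#' A = n_v/n_vtot, B = n_c/(n_c + n_wt), f(A) = 1/A and g(B) = B/((1-B) s).
#'
#' @param data Data frame with columns `n_c`, `n_wt`, `n_v`, `n_vtot`.
#' @param s Plasmid copy-number scaling factor (default 19).
#' @return `data` with added columns `a`, `b`, `ce` and logical
#'   `flag_no_plasmid` (`n_v == 0`: CE undefined, isoform absent from the
#'   plasmid library).
#' @export
compute_ce <- function(data, s = 19) {
  stopifnot(all(c("n_c", "n_wt", "n_v", "n_vtot") %in% names(data)), s > 0)
  check_counts(data)
  data |>
    as_tibble() |>
    dplyr::mutate(
      a = .data$n_v / .data$n_vtot,
      b = .data$n_c / (.data$n_c + .data$n_wt),
      ce = dplyr::if_else(
        .data$n_v > 0,
        (.data$n_c / (.data$n_wt * .env$s)) / .data$a,
        NA_real_
      ),
      flag_no_plasmid = .data$n_v == 0
    )
}

check_counts <- function(data) {
  cols <- c("n_c", "n_wt", "n_v", "n_vtot")
  vals <- unlist(data[cols], use.names = FALSE)
  if (any(vals < 0) || any(is.na(vals))) abort("counts must be non-negative")
  if (any(data$n_v > data$n_vtot)) abort("n_v cannot exceed n_vtot")
  if (any(data$n_wt == 0 & data$n_c > 0)) {
    warn("n_wt = 0: CE is undefined without a zero-count correction")
  }
  invisible(data)
}

#' Delta-method variance of ln(CE)
#'
#' `n_wt` and `n_c` are treated as independent Poisson counts, so
#' `B = n_c/(n_c + n_wt)` is a binomial proportion with
#' `var(B) = B(1-B)/(n_c + n_wt)`, and `var(A) = A(1-A)/n_vtot`. The delta
#' method (`var h(x) = var(x) h'(x)^2`) then gives
#' `var(ln f(A)) = var(A)/A^2` and `var(ln g(B)) = var(B)/(B(1-B))^2`; the
#' two library contributions add:
#' `var(ln CE) = var(ln f(A)) + var(ln g(B))`. The copy-number factor `s` is
#' a known constant and contributes no variance. Undefined at the boundaries
#' `A, B` in `{0, 1}`; [estimate_ce()] optionally applies a Haldane-style
#' +0.5 correction there.
#'
#' @param data Data frame with columns `n_c`, `n_wt`, `n_v`, `n_vtot` (and
#'   optionally precomputed `a`, `b`).
#' @return `data` with added `var_ln_a`, `var_ln_b`, `sd_ln` (NA at
#'   boundaries, flagged in `flag_boundary`).
#' @export
ln_ce_variance <- function(data) {
  data <- as_tibble(data)
  if (!all(c("a", "b") %in% names(data))) {
    data <- dplyr::mutate(
      data,
      a = .data$n_v / .data$n_vtot,
      b = .data$n_c / (.data$n_c + .data$n_wt)
    )
  }
  data |>
    dplyr::mutate(
      flag_boundary = .data$a <= 0 | .data$a >= 1 | .data$b <= 0 | .data$b >= 1,
      var_ln_a = dplyr::if_else(
        !.data$flag_boundary,
        (1 - .data$a) / (.data$a * .data$n_vtot),
        NA_real_
      ),
      var_ln_b = dplyr::if_else(
        !.data$flag_boundary,
        1 / (.data$b * (1 - .data$b) * (.data$n_c + .data$n_wt)),
        NA_real_
      ),
      sd_ln = sqrt(.data$var_ln_a + .data$var_ln_b)
    )
}

#' 95% confidence interval for CE
#'
#' The approximate 95% CI for ln(CE) is the point estimate plus or minus
#' 2 standard deviations; exponentiating gives a multiplicatively symmetric
#' interval on the CE scale: `ci_high/ce == ce/ci_low` exactly.
#'
#' @param data Data frame with columns `ce` and `sd_ln`.
#' @return `data` with added `ci_low`, `ci_high`.
#' @export
ce_interval <- function(data) {
  stopifnot(all(c("ce", "sd_ln") %in% names(data)))
  data |>
    as_tibble() |>
    dplyr::mutate(
      ci_low = .data$ce * exp(-2 * .data$sd_ln),
      ci_high = .data$ce * exp(2 * .data$sd_ln)
    )
}

#' Full CE estimation: point estimate, variance, interval, flags
#'
#' Point estimates always use the raw counts. When `zero_correction = TRUE`
#' (the default) and `n_c` or `n_wt` is zero, the variance and interval are
#' computed from Haldane-corrected counts (`n_c + 0.5`, `n_wt + 0.5`) around
#' the corrected estimate, and the row is flagged `zero_corrected`; with the
#' correction off such rows get an undefined (NA) interval.
#'
#' @inheritParams compute_ce
#' @param zero_correction Apply +0.5 to `n_c` and `n_wt` for the interval
#'   when either is zero (default `TRUE`).
#' @return Tibble with `a`, `b`, `ce`, `var_ln_a`, `var_ln_b`, `sd_ln`,
#'   `ci_low`, `ci_high` and flag columns.
#' @examples
#' estimate_ce(tibble::tibble(n_c = 950, n_wt = 1000, n_v = 5000, n_vtot = 1e5))
#' @export
estimate_ce <- function(data, s = 19, zero_correction = TRUE) {
  est <- compute_ce(data, s = s)
  zero_rna <- est$n_c == 0 | est$n_wt == 0
  if (zero_correction && any(zero_rna)) {
    corr <- est |>
      dplyr::mutate(
        n_c = .data$n_c + ifelse(zero_rna, 0.5, 0),
        n_wt = .data$n_wt + ifelse(zero_rna, 0.5, 0)
      ) |>
      compute_ce(s = s) |>
      ln_ce_variance() |>
      ce_interval()
    est <- est |>
      ln_ce_variance() |>
      dplyr::mutate(
        sd_ln = dplyr::if_else(zero_rna, corr$sd_ln, .data$sd_ln),
        var_ln_a = dplyr::if_else(zero_rna, corr$var_ln_a, .data$var_ln_a),
        var_ln_b = dplyr::if_else(zero_rna, corr$var_ln_b, .data$var_ln_b),
        flag_boundary = dplyr::if_else(zero_rna, corr$flag_boundary,
                                       .data$flag_boundary)
      ) |>
      ce_interval() |>
      dplyr::mutate(
        ci_low = dplyr::if_else(zero_rna, corr$ci_low, .data$ci_low),
        ci_high = dplyr::if_else(zero_rna, corr$ci_high, .data$ci_high),
        zero_corrected = zero_rna
      )
  } else {
    est <- est |>
      ln_ce_variance() |>
      ce_interval() |>
      dplyr::mutate(zero_corrected = FALSE)
  }
  est
}

#' Remove isoforms with insufficient plasmid (DNA-library) coverage
#'
#' Isoforms with fewer than `min_plasmid_reads` DNA-library reads are removed
#' (the boundary is kept: `n_v == min_plasmid_reads` survives).
#'
#' @param data Data frame with column `n_v`.
#' @param min_plasmid_reads Coverage threshold (default 200).
#' @return Filtered tibble; removals are reported by message, and the number
#'   removed is stored in attribute `n_removed`.
#' @export
filter_low_coverage <- function(data, min_plasmid_reads = 200) {
  stopifnot("n_v" %in% names(data))
  keep <- data$n_v >= min_plasmid_reads
  out <- as_tibble(data)[keep, , drop = FALSE]
  if (nrow(out) == 0 && nrow(data) > 0) {
    warn("all isoforms fall below the plasmid coverage threshold")
  }
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Join RNA and DNA assignment tables into a per-isoform CE table
#'
#' Computes, per isoform, `n_c` (RNA junction reads), `n_wt` (RNA wild-type
#' reads), `n_v` (DNA junction reads) and `n_vtot` (all DNA-library reads
#' passing the length filter minus those aligning to the wild-type sequence,
#' i.e. assigned + ambiguous + unassigned), then applies [estimate_ce()].
#'
#' @param rna,dna `read_assignment` objects for the RNA (circle) and plasmid
#'   DNA libraries, built from the same index.
#' @param s Plasmid copy-number scaling factor (default 19).
#' @param zero_correction See [estimate_ce()].
#' @return Tibble with one row per isoform shared by both tables:
#'   `del_start`, `del_end`, `isoform`, counts and all [estimate_ce()]
#'   columns, ordered by `(del_start, del_end)`.
#' @export
ce_table <- function(rna, dna, s = 19, zero_correction = TRUE) {
  stopifnot(inherits(rna, "read_assignment"), inherits(dna, "read_assignment"))
  if (!identical(attr(rna, "exon_name"), attr(dna, "exon_name"))) {
    abort("RNA and DNA assignments come from different exons")
  }
  n_wt <- assignment_summary_n(rna, "wildtype")
  n_vtot <- assignment_summary_n(dna, "total") -
    assignment_summary_n(dna, "filtered_short") -
    assignment_summary_n(dna, "wildtype")
  joined <- dplyr::inner_join(
    dplyr::rename(rna$counts, n_c = "n"),
    dplyr::rename(dna$counts, n_v = "n"),
    by = c("del_start", "del_end", "remaining_length")
  )
  if (nrow(joined) == 0) {
    warn("RNA and DNA assignment tables share no isoforms")
    return(joined)
  }
  joined |>
    dplyr::mutate(
      isoform = isoform_label(.data$del_start, .data$del_end),
      n_wt = n_wt, n_vtot = n_vtot
    ) |>
    estimate_ce(s = s, zero_correction = zero_correction) |>
    dplyr::arrange(.data$del_start, .data$del_end)
}

#' Per-copy fold reduction from a bulk fold change
#'
#' An ectopic gene carried on a multi-copy plasmid that shows an `x`-fold
#' bulk depletion relative to the single-copy endogenous gene is depleted
#' `x * copy_number`-fold per gene copy (e.g. an eightfold bulk depletion at
#' plasmid copy number 10 is at least an 80-fold per-copy reduction).
#'
#' @param bulk_fold Bulk fold reduction (relative to the endogenous copy).
#' @param copy_number Plasmid copies per genome.
#' @return Per-copy fold reduction.
#' @export
per_copy_reduction <- function(bulk_fold, copy_number) {
  stopifnot(all(bulk_fold > 0), all(copy_number > 0))
  bulk_fold * copy_number
}
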