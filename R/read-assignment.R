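#' Length-filter a read set
#'
#' Retains reads strictly longer than `min_read_len` (the filter is strict:
#' a read of exactly `min_read_len` nucleotides is removed).
#'
#' @param reads Tibble with columns `read_id` and `sequence` (see
#'   [as_read_set()]).
#' @param min_read_len Length threshold in nt (default 40).
#' @return The retained reads, with attribute `n_removed` giving the number
#'   of reads filtered out (also reported by message).
#' @export
length_filter <- function(reads, min_read_len = 40) {
  reads <- as_read_set(reads)
  keep <- nchar(reads$sequence) > min_read_len
  out <- reads[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Coerce reads to the canonical read-set tibble
#'
#' Accepts a tibble/data frame with `read_id` + `sequence` columns, a named
#' (or unnamed) character vector, or a `Biostrings::DNAStringSet`.
#'
#' @param reads Reads in any accepted form.
#' @return A tibble with columns `read_id` and `sequence`.
#' @export
as_read_set <- function(reads) {
  if (is.data.frame(reads)) {
    stopifnot(all(c("read_id", "sequence") %in% names(reads)))
    out <- as_tibble(reads[, c("read_id", "sequence")])
  } else if (inherits(reads, "DNAStringSet")) {
    ids <- names(reads)
    if (is.null(ids)) ids <- sprintf("read_%06d", seq_along(reads))
    out <- tibble(read_id = ids, sequence = as.character(reads))
  } else if (is.character(reads)) {
    ids <- names(reads)
    if (is.null(ids)) ids <- sprintf("read_%06d", seq_along(reads))
    out <- tibble(read_id = ids, sequence = unname(reads))
  } else {
    abort("`reads` must be a data frame, character vector or DNAStringSet")
  }
  bad <- grepl("[^ACGTN]", out$sequence)
  if (any(bad)) abort("read sequences may contain only A, C, G, T, N")
  out
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Minimum-Hamming placement of each read across references, optionally also
# trying the reverse complement (the better orientation wins; an equal-distance
# hit on a *different* reference in the other orientation is still a tie).
scan_reads <- function(sequences, refs, max_mismatches, match_reverse_complement) {
  fwd <- hamming_scan_cpp(sequences, refs, max_mismatches)
  if (!match_reverse_complement) {
    return(tibble(ref = fwd$ref, mismatches = fwd$mismatches, tie = fwd$tie))
  }
  rc <- hamming_scan_cpp(revcomp_chr(sequences), refs, max_mismatches)
  mf <- ifelse(is.na(fwd$mismatches), Inf, fwd$mismatches)
  mr <- ifelse(is.na(rc$mismatches), Inf, rc$mismatches)
  use_rc <- mr < mf
  tie <- ifelse(use_rc, rc$tie, fwd$tie) |
    (mf == mr & is.finite(mf) & fwd$ref != rc$ref)
  tibble(
    ref = ifelse(use_rc, rc$ref, fwd$ref),
    mismatches = as.integer(ifelse(use_rc, rc$mismatches, fwd$mismatches)),
    tie = tie & !is.na(ifelse(use_rc, rc$ref, fwd$ref))
  )
}

#' Best ungapped match of a read among references
#'
#' Scans every placement of the read fully inside each reference and returns
#' the reference and offset minimising the Hamming distance; `N` bases always
#' count as mismatches. Reads whose minimum exceeds `max_mismatches` (or that
#' fit inside no reference) return an NA row.
#'
#' @param read A single read sequence.
#' @param references Named character vector of reference sequences.
#' @param max_mismatches Mismatch budget (default 3).
#' @return A one-row tibble: `reference` (name or `NA`), `mismatches`,
#'   `offset` (1-based start inside the reference), `tie` (`TRUE` when a
#'   different reference achieves the same minimal distance).
#' @export
hamming_best_match <- function(read, references, max_mismatches = 3) {
  stopifnot(length(read) == 1, length(references) >= 1)
  nms <- names(references)
  if (is.null(nms)) nms <- as.character(seq_along(references))
  res <- hamming_scan_cpp(read, unname(references), max_mismatches)
  tibble(
    reference = ifelse(is.na(res$ref), NA_character_, nms[res$ref]),
    mismatches = res$mismatches,
    offset = res$offset,
    tie = res$tie
  )
}

#' Assign reads hierarchically to wild-type or deletion-junction references
#'
#' Reads are first length-filtered (strictly longer than `min_read_len`),
#' then matched against the unmutated wild-type exon; only reads that fail
#' the wild-type budget are matched against the deletion-junction index.
#' Matching is ungapped (deletions are encoded in the reference set) with at
#' most `max_mismatches` mismatches, mirroring a `-v`-style aligner contract.
#' Reads tying between two junction references at the minimal distance are
#' discarded as ambiguous by default (`ambiguous = "discard"`), avoiding
#' double counting of near-identical truncation variants;
#' `ambiguous = "best"` deterministically keeps the first reference in
#' `(del_start, del_end)` order.
#'
#' @param reads Reads (see [as_read_set()]).
#' @param exon Wild-type [exon_template()]; must be the exon the index was
#'   built from.
#' @param index A `deletion_index` from [build_deletion_index()].
#' @param max_mismatches Mismatch budget (default 3).
#' @param min_read_len Length-filter threshold, nt (default 40, strict).
#' @param ambiguous `"discard"` or `"best"`.
#' @param match_reverse_complement Also try each read's reverse complement.
#' @return A `read_assignment` object: list with `counts` (tibble
#'   `del_start`, `del_end`, `n`), `summary` (tallies per category) and
#'   `details` (per-read status). `tidy()` returns the counts, `glance()` the
#'   summary in wide form.
#' @export
assign_reads <- function(reads, exon, index,
                         max_mismatches = 3, min_read_len = 40,
                         ambiguous = c("discard", "best"),
                         match_reverse_complement = FALSE) {
  ambiguous <- match.arg(ambiguous)
  exon <- as_exon(exon)
  reads <- as_read_set(reads)
  if (!identical(exon$name, index_exon_name(index))) {
    abort(sprintf("index was built from exon '%s', not '%s'",
                  index_exon_name(index), exon$name))
  }
  if (index_flank(index) < min_read_len) {
    abort("index flank_len is below min_read_len; junction-spanning reads could not be fully contained")
  }

  total <- nrow(reads)
  kept <- length_filter(reads, min_read_len)
  n_short <- attr(kept, "n_removed")

  status <- rep(NA_character_, nrow(kept))
  iso <- rep(NA_integer_, nrow(kept))
  mm <- rep(NA_integer_, nrow(kept))

  if (nrow(kept) > 0) {
    wt <- scan_reads(kept$sequence, exon$sequence, max_mismatches,
                     match_reverse_complement)
    is_wt <- !is.na(wt$ref)
    status[is_wt] <- "wildtype"
    mm[is_wt] <- wt$mismatches[is_wt]

    rest <- which(!is_wt)
    if (length(rest) > 0) {
      jn <- scan_reads(kept$sequence[rest], index$junction, max_mismatches,
                       match_reverse_complement)
      hit <- !is.na(jn$ref)
      amb <- hit & jn$tie & ambiguous == "discard"
      status[rest[amb]] <- "ambiguous"
      ok <- hit & !amb
      status[rest[ok]] <- "assigned"
      iso[rest[ok]] <- jn$ref[ok]
      mm[rest] <- jn$mismatches
      status[rest[!hit]] <- "unassigned"
    }
  }

  details <- tibble(
    read_id = kept$read_id,
    status = status,
    del_start = index$del_start[iso],
    del_end = index$del_end[iso],
    mismatches = mm
  )
  counts <- index |>
    as_tibble() |>
    dplyr::select("del_start", "del_end", "remaining_length") |>
    dplyr::left_join(
      details |>
        dplyr::filter(.data$status == "assigned") |>
        dplyr::count(.data$del_start, .data$del_end),
      by = c("del_start", "del_end")
    ) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  summary <- tibble(
    category = c("total", "filtered_short", "wildtype", "assigned",
                 "ambiguous", "unassigned"),
    n = c(total, n_short,
          sum(status == "wildtype", na.rm = TRUE),
          sum(status == "assigned", na.rm = TRUE),
          sum(status == "ambiguous", na.rm = TRUE),
          sum(status == "unassigned", na.rm = TRUE))
  )
  stopifnot(summary$n[1] == sum(summary$n[-1]))

  structure(
    list(counts = counts, summary = summary, details = details),
    exon_name = exon$name, flank_len = index_flank(index),
    max_mismatches = max_mismatches, min_read_len = min_read_len,
    class = "read_assignment"
  )
}

#' @export
print.read_assignment <- function(x, ...) {
  s <- setNames(x$summary$n, x$summary$category)
  cat(sprintf(
    "<read_assignment> exon %s: %d reads (%d wild-type, %d assigned to %d isoforms, %d ambiguous, %d unassigned, %d short)\n",
    attr(x, "exon_name"), s[["total"]], s[["wildtype"]], s[["assigned"]],
    nrow(x$counts), s[["ambiguous"]], s[["unassigned"]], s[["filtered_short"]]
  ))
  invisible(x)
}

#' @export
tidy.read_assignment <- function(x, ...) x$counts

#' @export
glance.read_assignment <- function(x, ...) {
  tidyr::pivot_wider(x$summary, names_from = "category", values_from = "n")
}

assignment_summary_n <- function(assignment, category) {
  assignment$summary$n[assignment$summary$category == category]
}
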