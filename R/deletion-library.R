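#' Exon template
#'
#' A circle-forming exon given on the sense (mRNA) strand. All coordinates in
#' the package are 1-based and inclusive, with position 1 the first nucleotide
#' of the exon, matching the `(x, y)` deletion notation used throughout: `x`
#' is the first and `y` the last deleted nucleotide.
#'
#' @param sequence Nucleotide string, uppercase A/C/G/T only.
#' @param name Identifier for the exon.
#' @return An object of class `exon_template`: a list with `name`, `sequence`
#'   and `length` (nt).
#' @examples
#' exon_template("ACGTACGTACGT", name = "toy")
#' @export
exon_template <- function(sequence, name = "exon") {
  stopifnot(is.character(sequence), length(sequence) == 1)
  sequence <- toupper(sequence)
  if (!grepl("^[ACGT]+$", sequence)) {
    abort("exon sequence must contain only A, C, G, T")
  }
  structure(
    list(name = name, sequence = sequence, length = nchar(sequence)),
    class = "exon_template"
  )
}

#' @export
print.exon_template <- function(x, ...) {
  cat(sprintf("<exon_template> %s: %d nt\n", x$name, x$length))
  invisible(x)
}

as_exon <- function(exon) {
  if (inherits(exon, "exon_template")) return(exon)
  if (is.character(exon) && length(exon) == 1) return(exon_template(exon))
  abort("`exon` must be an exon_template or a single nucleotide string")
}

#' Primer scheme for a combinatorial inverse-PCR deletion library
#'
#' An outward-facing primer pair deletes the sequence between the two primer
#' 5' ends: the reverse primer retains the exon *through* its boundary
#' position (the last retained nucleotide upstream of the deletion) and the
#' forward primer retains the exon *from* its boundary position (the first
#' retained nucleotide downstream of the deletion).
#'
#' @param forward 1-based exon positions of the first retained nucleotide for
#'   each forward primer.
#' @param reverse 1-based exon positions of the last retained nucleotide for
#'   each reverse primer.
#' @return A tibble with columns `primer_id`, `orientation` (`"fwd"`/`"rev"`)
#'   and `position`.
#' @examples
#' primer_scheme(forward = 101, reverse = 40)
#' @export
primer_scheme <- function(forward, reverse) {
  if (length(forward) < 1 || length(reverse) < 1) {
    abort("primer scheme needs at least one forward and one reverse primer")
  }
  if (any(forward != as.integer(forward)) || any(reverse != as.integer(reverse))) {
    abort("primer positions must be whole numbers")
  }
  dplyr::bind_rows(
    tibble(
      primer_id = sprintf("fwd_%02d", seq_along(forward)),
      orientation = "fwd", position = as.integer(forward)
    ),
    tibble(
      primer_id = sprintf("rev_%02d", seq_along(reverse)),
      orientation = "rev", position = as.integer(reverse)
    )
  )
}

scheme_positions <- function(scheme, orientation) {
  stopifnot(is.data.frame(scheme),
            all(c("orientation", "position") %in% names(scheme)))
  sort(unique(scheme$position[scheme$orientation == orientation]))
}

#' Enumerate all deletion isoforms producible by a primer scheme
#'
#' Every forward/reverse primer pair yields the deletion `(rev + 1, fwd - 1)`.
#' Because primers are used unpurified, incomplete (5'-truncated) synthesis
#' products are also present: a truncation of `t` nucleotides on a boundary
#' primer moves that deletion boundary `t` nt outward, enlarging the deletion.
#' All combinations of truncations `0..max_truncation` on both primers are
#' enumerated and duplicate `(del_start, del_end)` pairs collapsed, since the
#' junction -- not the provenance -- identifies the molecule. Deletions are
#' restricted to the strict interior of the exon (positions `2..length-1`),
#' as the scheme deletes exonic sequence only and never touches a splice site.
#'
#' @param scheme A [primer_scheme()] tibble.
#' @param exon An [exon_template()] (or nucleotide string).
#' @param max_truncation Maximum modelled 5' primer truncation, nt (default 3).
#' @return A tibble with one row per isoform, columns `del_start`, `del_end`,
#'   `deleted_len`, `remaining_length`, sorted by `(del_start, del_end)`.
#' @examples
#' exon <- exon_template(strrep("ACGT", 50))
#' enumerate_deletions(primer_scheme(101, 40), exon, max_truncation = 0)
#' @export
enumerate_deletions <- function(scheme, exon, max_truncation = 3) {
  exon <- as_exon(exon)
  stopifnot(max_truncation >= 0)
  fwd <- scheme_positions(scheme, "fwd")
  rev <- scheme_positions(scheme, "rev")
  if (length(fwd) == 0 || length(rev) == 0) {
    abort("scheme must contain both forward and reverse primers")
  }
  if (any(c(fwd, rev) < 1) || any(c(fwd, rev) > exon$length)) {
    abort(sprintf("primer positions must lie within [1, %d]", exon$length))
  }
  tr <- 0:max_truncation
  grid <- tidyr::expand_grid(f = fwd, r = rev, t_f = tr, t_r = tr)
  cand <- tibble(
    del_start = grid$r + 1L - grid$t_r,
    del_end = grid$f - 1L + grid$t_f
  )
  cand <- dplyr::filter(
    cand,
    .data$del_start >= 2L,
    .data$del_end <= exon$length - 1L,
    .data$del_start <= .data$del_end
  )
  if (nrow(cand) == 0) {
    abort("primer scheme yields no valid deletion (empty index)")
  }
  cand |>
    dplyr::distinct() |>
    dplyr::arrange(.data$del_start, .data$del_end) |>
    dplyr::mutate(
      deleted_len = .data$del_end - .data$del_start + 1L,
      remaining_length = exon$length - .data$deleted_len
    )
}

#' Junction reference sequence for one deletion isoform
#'
#' Concatenates up to `flank_len` retained nucleotides ending at
#' `del_start - 1` with up to `flank_len` retained nucleotides starting at
#' `del_end + 1`; flanks are clipped at the exon ends.
#'
#' @param del_start,del_end 1-based inclusive deletion bounds.
#' @param exon An [exon_template()] (or nucleotide string).
#' @param flank_len Retained nucleotides kept on each side of the junction.
#' @return A nucleotide string (vectorised over `del_start`/`del_end`).
#' @examples
#' junction_reference(5, 12, "AAAACCCCGGGGTTTT", flank_len = 4)
#' @export
junction_reference <- function(del_start, del_end, exon, flank_len) {
  exon <- as_exon(exon)
  if (flank_len < 1) abort("`flank_len` must be >= 1")
  stopifnot(all(del_start >= 1), all(del_end <= exon$length),
            all(del_start <= del_end))
  left_from <- pmax(1L, del_start - flank_len)
  right_to <- pmin(exon$length, del_end + flank_len)
  left <- substr(rep(exon$sequence, length(del_start)), left_from, del_start - 1L)
  right <- substr(rep(exon$sequence, length(del_start)), del_end + 1L, right_to)
  paste0(left, right)
}

#' Build a junction reference index for a set of deletion isoforms
#'
#' @param exon An [exon_template()] (or nucleotide string).
#' @param deletions Tibble of isoforms as from [enumerate_deletions()].
#' @param flank_len Retained nucleotides on each side of each junction. Must
#'   be at least the read length for junction-spanning reads to be fully
#'   contained at assignment time.
#' @return A `deletion_index`: a tibble with `del_start`, `del_end`,
#'   `deleted_len`, `remaining_length`, `junction` (the reference sequence)
#'   and `junction_pos` (1-based position of the last nucleotide before the
#'   junction within `junction`), with attributes `exon_name` and `flank_len`.
#' @export
build_deletion_index <- function(exon, deletions, flank_len) {
  exon <- as_exon(exon)
  if (nrow(deletions) == 0) abort("cannot build an index from 0 isoforms")
  idx <- deletions |>
    dplyr::arrange(.data$del_start, .data$del_end) |>
    dplyr::mutate(
      deleted_len = .data$del_end - .data$del_start + 1L,
      remaining_length = exon$length - .data$deleted_len,
      junction = junction_reference(.data$del_start, .data$del_end,
                                    exon, flank_len),
      junction_pos = pmin(.data$del_start - 1L, as.integer(flank_len))
    )
  attr(idx, "exon_name") <- exon$name
  attr(idx, "flank_len") <- as.integer(flank_len)
  class(idx) <- c("deletion_index", class(idx))
  idx
}

index_exon_name <- function(index) attr(index, "exon_name")
index_flank <- function(index) attr(index, "flank_len")

#' Write a deletion index as FASTA
#'
#' One record per isoform; the header encodes the deletion in `(x,y)`
#' notation together with the source exon, remaining length and flank, so
#' that [read_index()] round-trips the index exactly.
#'
#' @param index A `deletion_index` from [build_deletion_index()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_index <- function(index, path) {
  if (nrow(index) == 0) abort("refusing to write an empty index")
  headers <- sprintf(
    "%s|del=(%d,%d)|remaining=%d|flank=%d",
    index_exon_name(index), index$del_start, index$del_end,
    index$remaining_length, index_flank(index)
  )
  seqs <- Biostrings::DNAStringSet(index$junction)
  names(seqs) <- headers
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}

#' Read a deletion index written by [write_index()]
#'
#' @param path FASTA path.
#' @return A `deletion_index` tibble.
#' @export
read_index <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  hdr <- names(seqs)
  m <- regmatches(hdr, regexec(
    "^(.*)\\|del=\\((\\d+),(\\d+)\\)\\|remaining=(\\d+)\\|flank=(\\d+)$", hdr
  ))
  if (any(lengths(m) != 6)) abort("not a circef index FASTA: malformed header")
  fields <- do.call(rbind, m)
  flank <- unique(as.integer(fields[, 6]))
  exon_name <- unique(fields[, 2])
  if (length(flank) != 1 || length(exon_name) != 1) {
    abort("index FASTA mixes exons or flank lengths")
  }
  del_start <- as.integer(fields[, 3])
  del_end <- as.integer(fields[, 4])
  remaining <- as.integer(fields[, 5])
  idx <- tibble(
    del_start = del_start, del_end = del_end,
    deleted_len = del_end - del_start + 1L,
    remaining_length = remaining,
    junction = unname(as.character(seqs)),
    junction_pos = pmin(del_start - 1L, flank)
  )
  attr(idx, "exon_name") <- exon_name
  attr(idx, "flank_len") <- flank
  class(idx) <- c("deletion_index", class(idx))
  idx
}

#' Isoform label in the parenthetical `(x,y)` notation
#'
#' @param del_start,del_end Deletion bounds.
#' @return Character vector like `"(41,100)"`.
#' @export
isoform_label <- function(del_start, del_end) {
  sprintf("(%d,%d)", del_start, del_end)
}
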