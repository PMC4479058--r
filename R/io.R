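#' Read a read set from FASTQ or FASTA
#'
#' @param path File path.
#' @param format `"fastq"` or `"fasta"` (guessed from the extension by
#'   default).
#' @return Read tibble (`read_id`, `sequence`); qualities are not retained
#'   (matching ignores them).
#' @export
read_reads <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  }
  seqs <- Biostrings::readDNAStringSet(path, format = format)
  # FASTQ ids may carry descriptions; keep the first token
  tibble(
    read_id = sub("\\s.*$", "", names(seqs)),
    sequence = unname(as.character(seqs))
  )
}

write_fastq <- function(reads, path, quality_char = "I") {
  reads <- as_read_set(reads)
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  names(seqs) <- reads$read_id
  quals <- Biostrings::PhredQuality(strrep(quality_char, nchar(reads$sequence)))
  qs <- Biostrings::QualityScaledDNAStringSet(seqs, quals)
  Biostrings::writeQualityScaledXStringSet(qs, filepath = path)
  invisible(path)
}

#' Read a primer scheme TSV
#'
#' Expected columns: `primer_id`, `orientation` (`fwd`/`rev`), `position`
#' (1-based retained-boundary position).
#'
#' @param path TSV path.
#' @return Primer-scheme tibble.
#' @export
read_primer_scheme <- function(path) {
  scheme <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("primer_id", "orientation", "position")
  if (!all(need %in% names(scheme))) {
    abort(sprintf("scheme TSV must have columns %s",
                  paste(need, collapse = ", ")))
  }
  if (!all(scheme$orientation %in% c("fwd", "rev"))) {
    abort("orientation must be 'fwd' or 'rev'")
  }
  scheme$position <- as.integer(scheme$position)
  as_tibble(scheme[, need])
}

#' Read a qPCR Ct table TSV
#'
#' Expected columns: `target`, `sample`, `treatment`, `replicate`, `ct`.
#'
#' @param path TSV path.
#' @return Ct tibble.
#' @export
read_ct_table <- function(path) {
  ct <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("target", "sample", "treatment", "replicate", "ct")
  if (!all(need %in% names(ct))) {
    abort(sprintf("Ct TSV must have columns %s", paste(need, collapse = ", ")))
  }
  if (any(!is.finite(ct$ct) | ct$ct <= 0)) {
    abort("Ct values must be finite and positive")
  }
  as_tibble(ct[, need])
}

#' Read an exon template from FASTA
#'
#' @param path FASTA path (first record is used).
#' @return An [exon_template()].
#' @export
read_exon_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) abort("no FASTA records found")
  exon_template(as.character(seqs[[1]]),
                name = sub("\\s.*$", "", names(seqs)[1]))
}
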