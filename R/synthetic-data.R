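#' Simulation configuration for a deletion-scanning qRNA-seq experiment
#'
#' Bundles every knob of the synthetic experiment: the exon, the
#' combinatorial primer scheme, the plasmid pool composition, the paired
#' DNA-seq/RNA-seq read libraries and the length-dependent true
#' circularization efficiency.
#'
#' @param seed Integer seed; every generator consuming the config is fully
#'   deterministic given it.
#' @param exon_length Exon length, nt (default 181).
#' @param n_fwd,n_rev Numbers of forward / reverse primers (default 8 each).
#' @param max_truncation Modelled 5' primer truncation in the simulated pool
#'   (default 0: full-length primer products only, keeping junctions well
#'   separated; truncation enumeration is exercised at index-building time).
#' @param library_alpha Symmetric Dirichlet concentration for the isoform
#'   proportions in the plasmid pool (default 5: the moderate skew of a
#'   ~1500-colony pool; large values approach uniform representation).
#' @param s Plasmid:genome copy-number factor (default 19).
#' @param dna_depth,rna_depth Expected total read counts of the DNA and RNA
#'   libraries (default 2e5 each).
#' @param read_len Read length, nt (default 75; reads from junctions shorter
#'   than this are truncated to the junction reference width).
#' @param flank Junction flank retained on each side in the index (default
#'   equal to `read_len`).
#' @param error_rate Per-base substitution probability (default 0.002,
#'   Illumina-like; must be <= 0.1).
#' @param ce_model True CE as a function of remaining exon length: a list
#'   with `type` one of `"logistic"` (`ce_max / (1 + exp(-k (L - l50)))`;
#'   defaults `l50 = 190` nt, `k = 0.045` per nt, `ce_max = 1`), `"flat"`
#'   (constant `ce`), or `"step"` (`ce_low` below `threshold` nt, `ce_high`
#'   at or above it).
#' @param wt_background_fraction Expected fraction of RNA reads from the
#'   endogenous wild-type circle. Default `NULL`: the fraction implied by
#'   per-copy consistency (one genomic wild-type copy at CE 1 sequenced at
#'   the same per-copy depth as the plasmid isoforms), which makes the CE
#'   estimator recover the true CE without rescaling. If set explicitly, the
#'   truth table records the implied calibration factor linking estimates to
#'   the model CE.
#' @param dna_wt_fraction Expected fraction of DNA-library reads from
#'   residual wild-type template (default 0.01); these are removed from
#'   `n_vtot` at analysis time.
#' @param n_outliers Number of isoforms planted as high outliers (default 0).
#' @param outlier_fold Multiplier applied to the planted isoforms' model CE
#'   (default 4).
#' @param max_mismatches Mismatch budget the analysis will use; junction
#'   reads are drawn with at least `max_mismatches + 1` nt of overhang on
#'   each side of the junction and are resampled if they fall within the
#'   wild-type budget, so that every emitted junction read is informative.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(seed = 1, exon_length = 181,
                              n_fwd = 8, n_rev = 8, max_truncation = 0,
                              library_alpha = 5, s = 19,
                              dna_depth = 2e5, rna_depth = 2e5,
                              read_len = 75, flank = read_len,
                              error_rate = 0.002,
                              ce_model = list(type = "logistic", l50 = 190,
                                              k = 0.045, ce_max = 1),
                              wt_background_fraction = NULL,
                              dna_wt_fraction = 0.01,
                              n_outliers = 0, outlier_fold = 4,
                              max_mismatches = 3) {
  stopifnot(dna_depth > 0, rna_depth >= 0, error_rate >= 0, error_rate <= 0.1,
            exon_length >= 50, library_alpha > 0, s > 0, flank >= 1)
  structure(
    list(
      seed = seed, exon_length = exon_length, n_fwd = n_fwd, n_rev = n_rev,
      max_truncation = max_truncation, library_alpha = library_alpha, s = s,
      dna_depth = dna_depth, rna_depth = rna_depth, read_len = read_len,
      flank = flank, error_rate = error_rate, ce_model = ce_model,
      wt_background_fraction = wt_background_fraction,
      dna_wt_fraction = dna_wt_fraction,
      n_outliers = n_outliers, outlier_fold = outlier_fold,
      max_mismatches = max_mismatches
    ),
    class = "sim_config"
  )
}

#' Reproducible pseudo-random exon template
#'
#' @param length Exon length, nt (at least 50, so junction flanks fit).
#' @param seed Optional seed; same seed, same sequence.
#' @param name Exon name.
#' @return An [exon_template()].
#' @export
make_exon <- function(length, seed = NULL, name = "synthetic_exon") {
  if (length < 50) abort("exon must be at least 50 nt")
  draw <- function() {
    exon_template(paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                        collapse = ""), name = name)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' True CE under a length model
#'
#' @param model `ce_model` list (see [simulation_config()]).
#' @param remaining_length Remaining exon lengths, nt.
#' @return True CE values.
#' @export
ce_model_value <- function(model, remaining_length) {
  switch(
    model$type,
    logistic = model$ce_max /
      (1 + exp(-model$k * (remaining_length - model$l50))),
    flat = rep(model$ce, length(remaining_length)),
    step = ifelse(remaining_length >= model$threshold,
                  model$ce_high, model$ce_low),
    abort(sprintf("unknown ce_model type '%s'", model$type))
  )
}

#' Random primer scheme over an exon
#'
#' Reverse-primer boundaries are drawn from the upstream ~quarter-to-half of
#' the exon and forward-primer boundaries from the downstream mirror region,
#' so every primer pair yields a valid interior deletion and every junction
#' reference is at least as wide as the read length.
#'
#' @param exon_length Exon length, nt.
#' @param n_fwd,n_rev Primer counts.
#' @param seed Optional seed.
#' @return A [primer_scheme()] tibble.
#' @export
simulate_scheme <- function(exon_length, n_fwd = 8, n_rev = 8, seed = NULL) {
  draw <- function() {
    rev_lo <- max(2L, round(0.22 * exon_length))
    rev_hi <- round(0.47 * exon_length)
    fwd_lo <- round(0.53 * exon_length)
    fwd_hi <- min(exon_length - 1L, round(0.78 * exon_length))
    stopifnot(rev_hi - rev_lo + 1 >= n_rev, fwd_hi - fwd_lo + 1 >= n_fwd)
    primer_scheme(
      forward = sample(fwd_lo:fwd_hi, n_fwd),
      reverse = sample(rev_lo:rev_hi, n_rev)
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate the plasmid deletion library with known truth
#'
#' Builds the exon, scheme and junction index, draws isoform proportions
#' from a symmetric Dirichlet(`library_alpha`), assigns each isoform its
#' true CE from the configured length model, and optionally plants high
#' outliers (isoforms whose CE is `outlier_fold` times their length-model
#' value).
#'
#' @param config A [simulation_config()].
#' @return List of class `sim_library`: `exon`, `scheme`, `index`, `truth`
#'   (tibble with per-isoform `proportion`, `true_ce`, `is_outlier`,
#'   `expected_n_v`, `expected_n_c`) and `config`.
#' @export
simulate_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    exon <- make_exon(config$exon_length)
    scheme <- simulate_scheme(config$exon_length, config$n_fwd, config$n_rev)
    deletions <- enumerate_deletions(scheme, exon, config$max_truncation)
    index <- build_deletion_index(exon, deletions, config$flank)
    n_iso <- nrow(index)
    if (n_iso == 0) abort("degenerate scheme: no isoforms")
    g <- rgamma(n_iso, shape = config$library_alpha)
    p <- g / sum(g)
    true_ce <- ce_model_value(config$ce_model, index$remaining_length)
    is_outlier <- rep(FALSE, n_iso)
    if (config$n_outliers > 0) {
      planted <- sample(n_iso, min(config$n_outliers, n_iso))
      true_ce[planted] <- true_ce[planted] * config$outlier_fold
      is_outlier[planted] <- TRUE
    }
    expected <- expected_counts(p, true_ce, config)
    truth <- tibble(
      del_start = index$del_start, del_end = index$del_end,
      isoform = isoform_label(index$del_start, index$del_end),
      remaining_length = index$remaining_length,
      proportion = p, true_ce = true_ce, is_outlier = is_outlier,
      expected_n_v = expected$n_v, expected_n_c = expected$n_c
    )
    attr(truth, "expected_n_wt") <- expected$n_wt
    attr(truth, "calibration") <- expected$calibration
    attr(truth, "s") <- config$s
    attr(truth, "seed") <- config$seed
    structure(
      list(exon = exon, scheme = scheme, index = index, truth = truth,
           config = config),
      class = "sim_library"
    )
  })
}

# Expected library composition. With the default (NULL) wt fraction the RNA
# library is calibrated so one genomic wild-type copy at CE 1 is sequenced at
# the same per-copy depth as the s plasmid copies per cell: the CE estimator
# is then consistent for the model CE (calibration factor 1). An explicit
# wt_background_fraction overrides this; the factor linking estimates to the
# model CE is recorded.
expected_counts <- function(p, true_ce, config) {
  n_v <- config$dna_depth * (1 - config$dna_wt_fraction) * p
  load <- config$s * sum(p * true_ce)  # plasmid circle output per wt-copy unit
  if (is.null(config$wt_background_fraction)) {
    unit <- config$rna_depth / (1 + load)
    n_wt <- unit
    n_c <- unit * config$s * p * true_ce
    calibration <- 1
  } else {
    w <- config$wt_background_fraction
    stopifnot(w > 0, w < 1)
    n_wt <- config$rna_depth * w
    n_c <- config$rna_depth * (1 - w) * (p * true_ce) / sum(p * true_ce)
    # CE_hat estimates true_ce * calibration under this composition
    calibration <- (1 - w) / (w * load)
  }
  list(n_v = n_v, n_c = n_c, n_wt = n_wt, calibration = calibration)
}

# Apply iid substitution errors to reads (character vector).
apply_errors <- function(seqs, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0) return(seqs)
  lens <- nchar(seqs)
  n_err <- rbinom(length(seqs), lens, error_rate)
  hit <- which(n_err > 0)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample.int(lens[i], n_err[i])
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

# Draw n junction-spanning reads from one junction reference. Reads overlap
# the junction by at least min_ov nt on each side and are rejection-resampled
# (offsets and errors redrawn) while they still align to the wild-type exon
# within the mismatch budget: a junction read inside the wild-type budget is
# uninformative because the hierarchical aligner must absorb it.
draw_junction_reads <- function(n, junction, junction_pos, wt_seq, config) {
  if (n == 0) return(character(0))
  w <- nchar(junction)
  len <- min(config$read_len, w)
  min_ov <- config$max_mismatches + 1
  j <- junction_pos
  lo <- max(1, j + min_ov - len + 1)
  hi <- min(j - min_ov + 1, w - len + 1)
  if (lo > hi) { lo <- 1; hi <- w - len + 1 }  # junction too near an end
  draw <- function(k) {
    starts <- if (lo == hi) rep(lo, k) else sample(lo:hi, k, replace = TRUE)
    apply_errors(substr(rep(junction, k), starts, starts + len - 1),
                 config$error_rate)
  }
  reads <- draw(n)
  for (round in 1:25) {
    hit <- hamming_scan_cpp(reads, wt_seq, config$max_mismatches)$ref
    bad <- which(!is.na(hit))
    if (length(bad) == 0) break
    reads[bad] <- draw(length(bad))
  }
  reads
}

draw_wt_reads <- function(n, wt_seq, config) {
  if (n == 0) return(character(0))
  len <- min(config$read_len, nchar(wt_seq))
  starts <- sample.int(nchar(wt_seq) - len + 1, n, replace = TRUE)
  apply_errors(substr(rep(wt_seq, n), starts, starts + len - 1),
               config$error_rate)
}

#' Simulate paired DNA-seq and RNA-seq read libraries
#'
#' Per-isoform read counts are Poisson around the expected composition in
#' the truth table (DNA: plasmid representation; RNA: representation times
#' true CE times copy number, plus the wild-type circle background).
#' Junction reads are uniform over informative junction-spanning windows;
#' substitution errors are applied at `error_rate`; the true origin of every
#' read is recorded.
#'
#' @param lib A `sim_library` from [simulate_library()].
#' @param seed Optional seed (defaults to `config$seed + 1`).
#' @return List of class `sim_reads`: `dna` and `rna` read tibbles
#'   (`read_id`, `sequence`) and `labels` (`read_id`, `library`,
#'   `del_start`, `del_end`, `origin`).
#' @export
simulate_reads <- function(lib, seed = NULL) {
  stopifnot(inherits(lib, "sim_library"))
  config <- lib$config
  if (is.null(seed)) seed <- config$seed + 1
  withr::with_seed(seed, {
    truth <- lib$truth
    idx <- lib$index
    wt_seq <- lib$exon$sequence

    n_v <- rpois(nrow(truth), truth$expected_n_v)
    n_v_wt <- rpois(1, config$dna_depth * config$dna_wt_fraction)
    n_c <- rpois(nrow(truth), truth$expected_n_c)
    n_wt <- if (config$rna_depth > 0) {
      rpois(1, attr(truth, "expected_n_wt"))
    } else 0L

    junct_batch <- function(counts) {
      purrr::map(seq_along(counts), function(i) {
        draw_junction_reads(counts[i], idx$junction[i], idx$junction_pos[i],
                            wt_seq, config)
      })
    }
    dna_iso <- junct_batch(n_v)
    rna_iso <- junct_batch(n_c)
    dna_wt <- draw_wt_reads(n_v_wt, wt_seq, config)
    rna_wt <- draw_wt_reads(n_wt, wt_seq, config)

    build <- function(iso_reads, wt_reads, counts, prefix) {
      seqs <- c(unlist(iso_reads), wt_reads)
      n <- length(seqs)
      ids <- sprintf("%s_%07d", prefix, seq_len(n))
      reads <- tibble(read_id = ids, sequence = seqs)
      labels <- tibble(
        read_id = ids,
        library = prefix,
        del_start = c(rep(truth$del_start, counts),
                      rep(NA_integer_, length(wt_reads))),
        del_end = c(rep(truth$del_end, counts),
                    rep(NA_integer_, length(wt_reads))),
        origin = c(rep(truth$isoform, counts),
                   rep("wt", length(wt_reads)))
      )
      list(reads = reads, labels = labels)
    }
    dna <- build(dna_iso, dna_wt, n_v, "dna")
    rna <- build(rna_iso, rna_wt, n_c, "rna")
    structure(
      list(dna = dna$reads, rna = rna$reads,
           labels = dplyr::bind_rows(dna$labels, rna$labels)),
      class = "sim_reads"
    )
  })
}

#' Simulate a complete qRNA-seq experiment
#'
#' @param config A [simulation_config()].
#' @return List of class `qrnaseq_sim` combining [simulate_library()] and
#'   [simulate_reads()] output: `exon`, `scheme`, `index`, `truth`, `dna`,
#'   `rna`, `labels`, `config`.
#' @export
simulate_qrnaseq <- function(config) {
  lib <- simulate_library(config)
  reads <- simulate_reads(lib)
  structure(
    c(lib[c("exon", "scheme", "index", "truth")],
      reads[c("dna", "rna", "labels")],
      list(config = config)),
    class = "qrnaseq_sim"
  )
}

#' Simulate replicate qPCR Ct values
#'
#' `Ct_target = ct_reference - log2(ratio) + N(0, noise_sd)` per replicate,
#' under perfect primer efficiency.
#'
#' @param true_ratios Named vector of true abundances relative to the
#'   reference target (the reference itself has ratio 1 and need not be
#'   included).
#' @param ct_reference Mean Ct of the reference target (default 20).
#' @param noise_sd Gaussian Ct noise SD in cycles (default 0.1).
#' @param replicates Replicates per target (default 3).
#' @param seed Optional seed.
#' @param reference_target Name of the reference target (default `"linear"`).
#' @return Ct table tibble: `target`, `sample`, `treatment`, `replicate`,
#'   `ct`.
#' @export
simulate_ct <- function(true_ratios, ct_reference = 20, noise_sd = 0.1,
                        replicates = 3, seed = NULL,
                        reference_target = "linear") {
  if (any(true_ratios <= 0)) abort("true ratios must be positive")
  stopifnot(replicates >= 1)
  if (!reference_target %in% names(true_ratios)) {
    true_ratios <- c(setNames(1, reference_target), true_ratios)
  }
  draw <- function() {
    purrr::imap_dfr(true_ratios, function(r, nm) {
      tibble(
        target = nm, sample = "sim", treatment = "none",
        replicate = seq_len(replicates),
        ct = ct_reference - log2(r) + rnorm(replicates, 0, noise_sd)
      )
    })
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Write a simulated experiment to a run directory
#'
#' Writes the exon FASTA, primer-scheme TSV, junction index FASTA, DNA and
#' RNA FASTQ files, truth and label TSVs, and a manifest JSON recording the
#' configuration and seed.
#'
#' @param sim A `qrnaseq_sim` from [simulate_qrnaseq()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "qrnaseq_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  exon_set <- Biostrings::DNAStringSet(setNames(sim$exon$sequence,
                                                sim$exon$name))
  Biostrings::writeXStringSet(exon_set, p("exon.fasta"))
  readr::write_tsv(sim$scheme, p("scheme.tsv"))
  write_index(sim$index, p("index.fasta"))
  write_fastq(sim$dna, p("reads_dna.fastq"))
  write_fastq(sim$rna, p("reads_rna.fastq"))
  readr::write_tsv(sim$truth, p("truth.tsv"))
  readr::write_tsv(sim$labels, p("labels.tsv"))
  cfg <- unclass(sim$config)
  cfg$wt_background_fraction <- cfg$wt_background_fraction %||% NA
  jsonlite::write_json(cfg, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
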