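# One full-scale simulated experiment (base depths, planted outliers),
# computed once per test session and shared by the tests that need it.
.e2e_cache <- new.env(parent = emptyenv())

e2e_fixture <- function() {
  if (is.null(.e2e_cache$result)) {
    config <- simulation_config(seed = 7, n_outliers = 3)
    sim <- simulate_qrnaseq(config)
    rna <- assign_reads(sim$rna, sim$exon, sim$index)
    dna <- assign_reads(sim$dna, sim$exon, sim$index)
    ce <- filter_low_coverage(ce_table(rna, dna, s = config$s),
                              min_plasmid_reads = 200)
    trend <- length_trend(ce)
    flagged <- flag_outliers(ce, trend)
    joined <- dplyr::inner_join(flagged, sim$truth,
                                by = c("del_start", "del_end"))
    .e2e_cache$result <- list(sim = sim, rna = rna, dna = dna, ce = ce,
                              trend = trend, joined = joined)
  }
  .e2e_cache$result
}
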