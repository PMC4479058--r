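test_that("exon generation is deterministic and seed-sensitive", {
  a <- make_exon(181, seed = 42)
  b <- make_exon(181, seed = 42)
  expect_identical(a$sequence, b$sequence)
  expect_equal(a$length, 181)
  expect_equal(nchar(a$sequence), 181)
  expect_error(make_exon(49), "at least 50")

  c_ <- make_exon(500, seed = 1)
  d_ <- make_exon(500, seed = 2)
  diff_frac <- mean(strsplit(c_$sequence, "")[[1]] !=
                      strsplit(d_$sequence, "")[[1]])
  expect_gt(diff_frac, 0.4)   # expectation 0.75 for uniform bases
})

test_that("CE length models behave as declared", {
  flat <- list(type = "flat", ce = 0.3)
  expect_equal(ce_model_value(flat, c(60, 120, 180)), rep(0.3, 3))
  logistic <- list(type = "logistic", l50 = 190, k = 0.045, ce_max = 1)
  vals <- ce_model_value(logistic, 60:180)
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals > 0 & vals < 1))
  step <- list(type = "step", threshold = 100, ce_low = 0.01, ce_high = 0.4)
  expect_equal(ce_model_value(step, c(99, 100)), c(0.01, 0.4))
})

test_that("library proportions are Dirichlet with the configured spread", {
  cfg <- simulation_config(seed = 191, n_fwd = 4, n_rev = 5,
                           library_alpha = 1e4)
  lib <- simulate_library(cfg)
  expect_equal(nrow(lib$truth), 20)
  expect_equal(sum(lib$truth$proportion), 1, tolerance = 1e-12)
  expect_lt(max(lib$truth$proportion) / min(lib$truth$proportion), 1.5)

  flat_cfg <- simulation_config(seed = 193, n_fwd = 3, n_rev = 3,
                                ce_model = list(type = "flat", ce = 0.3))
  flat_lib <- simulate_library(flat_cfg)
  expect_true(all(flat_lib$truth$true_ce == 0.3))

  logi <- simulate_library(simulation_config(seed = 197))
  ord <- order(logi$truth$remaining_length)
  expect_true(all(diff(logi$truth$true_ce[ord]) >= 0))
})

test_that("expected counts make the estimator exactly consistent", {
  lib <- simulate_library(simulation_config(seed = 199))
  truth <- lib$truth
  est <- compute_ce(tibble::tibble(
    n_c = truth$expected_n_c,
    n_wt = attr(truth, "expected_n_wt"),
    n_v = truth$expected_n_v,
    n_vtot = sum(truth$expected_n_v)
  ), s = attr(truth, "s"))
  # n_v/n_vtot equals the true proportion and everything cancels to true CE
  expect_equal(est$ce, truth$true_ce, tolerance = 1e-10)
  expect_equal(attr(truth, "calibration"), 1)
})

test_that("an explicit wild-type fraction rescales estimates by the recorded factor", {
  cfg <- simulation_config(seed = 211, wt_background_fraction = 0.3)
  lib <- simulate_library(cfg)
  truth <- lib$truth
  expect_equal(attr(truth, "expected_n_wt"), 0.3 * cfg$rna_depth)
  est <- compute_ce(tibble::tibble(
    n_c = truth$expected_n_c,
    n_wt = attr(truth, "expected_n_wt"),
    n_v = truth$expected_n_v,
    n_vtot = sum(truth$expected_n_v)
  ), s = cfg$s)
  expect_equal(est$ce, truth$true_ce * attr(truth, "calibration"),
               tolerance = 1e-10)
})

test_that("error-free reads round-trip through assignment exactly", {
  cfg <- simulation_config(seed = 223, n_fwd = 4, n_rev = 4,
                           dna_depth = 8000, rna_depth = 8000,
                           error_rate = 0)
  sim <- simulate_qrnaseq(cfg)
  label_counts <- function(lab, which_lib) {
    lab <- lab[lab$library == which_lib, ]
    list(
      iso = dplyr::count(lab[lab$origin != "wt", ], del_start, del_end),
      wt = sum(lab$origin == "wt")
    )
  }
  for (side in c("rna", "dna")) {
    res <- assign_reads(sim[[side]], sim$exon, sim$index)
    want <- label_counts(sim$labels, side)
    got <- dplyr::inner_join(res$counts, want$iso,
                             by = c("del_start", "del_end"))
    expect_equal(got$n.x, got$n.y)
    expect_equal(sum(res$counts$n), sum(want$iso$n))
    s <- setNames(res$summary$n, res$summary$category)
    expect_equal(s[["wildtype"]], want$wt)
    expect_equal(s[["ambiguous"]] + s[["unassigned"]], 0L)
  }
})

test_that("read simulation is deterministic and respects zero depth", {
  cfg <- simulation_config(seed = 227, n_fwd = 3, n_rev = 3,
                           dna_depth = 1500, rna_depth = 1500)
  s1 <- simulate_qrnaseq(cfg)
  s2 <- simulate_qrnaseq(cfg)
  expect_identical(s1$rna, s2$rna)
  expect_identical(s1$dna, s2$dna)
  expect_identical(s1$truth$proportion, s2$truth$proportion)

  quiet <- simulate_qrnaseq(
    simulation_config(seed = 229, n_fwd = 3, n_rev = 3,
                      dna_depth = 1500, rna_depth = 1e-9)
  )
  expect_equal(nrow(quiet$rna), 0)
})

test_that("simulated Ct tables encode ratios as cycle differences", {
  noiseless <- simulate_ct(c(circle = 0.125), noise_sd = 0, seed = 233)
  gap <- mean(noiseless$ct[noiseless$target == "circle"]) -
    mean(noiseless$ct[noiseless$target == "linear"])
  expect_equal(gap, 3)

  expect_identical(simulate_ct(c(a = 0.5), seed = 239),
                   simulate_ct(c(a = 0.5), seed = 239))
  expect_error(simulate_ct(c(a = -1)), "positive")

  # delta-Ct recovery is unbiased to within 1% under replicate noise
  withr::local_seed(241)
  est <- replicate(1000, {
    ct <- simulate_ct(c(circle = 0.2), noise_sd = 0.1, replicates = 3)
    ra <- relative_abundance(ct)
    ra$ratio[ra$target == "circle"]
  })
  expect_lt(abs(mean(est) / 0.2 - 1), 0.01)
})

test_that("Poisson count draws give near-nominal CI coverage of the truth", {
  lib <- simulate_library(simulation_config(seed = 251, n_fwd = 3, n_rev = 3,
                                            dna_depth = 5e4, rna_depth = 5e4))
  truth <- lib$truth
  i <- which.max(truth$expected_n_c)  # a well-covered isoform
  n_vtot <- sum(truth$expected_n_v)
  withr::local_seed(257)
  hits <- replicate(500, {
    est <- estimate_ce(tibble::tibble(
      n_c = rpois(1, truth$expected_n_c[i]),
      n_wt = rpois(1, attr(truth, "expected_n_wt")),
      n_v = rpois(1, truth$expected_n_v[i]),
      n_vtot = n_vtot
    ), s = attr(truth, "s"))
    est$ci_low <= truth$true_ce[i] && truth$true_ce[i] <= est$ci_high
  })
  expect_gte(mean(hits), 0.93)
})

test_that("a full simulated experiment recovers truth at base depth", {
  fx <- e2e_fixture()
  joined <- fx$joined

  # per-isoform CE estimates track the generating model closely
  honest <- joined[!joined$is_outlier, ]
  expect_gt(nrow(honest), 50)
  expect_true(all(abs(log(honest$ce / honest$true_ce)) < 4 * honest$sd_ln))
  expect_lt(median(abs(honest$ce / honest$true_ce - 1)), 0.05)

  # false flags stay consistent with the nominal ~4.6% two-sided
  # exclusion rate of a 2-sd CI versus a well-fitted curve
  false_flags <- sum(honest$outlier != "none")
  expect_lte(false_flags, ceiling(0.12 * nrow(honest)))

  # truth bookkeeping: proportions and expectations
  expect_equal(sum(fx$sim$truth$proportion), 1, tolerance = 1e-12)
  expect_true(all(fx$sim$truth$expected_n_v >= 0))
})

test_that("simulation runs round-trip through the run directory", {
  cfg <- simulation_config(seed = 263, n_fwd = 3, n_rev = 3,
                           dna_depth = 800, rna_depth = 800)
  sim <- simulate_qrnaseq(cfg)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "exon.fasta", "scheme.tsv", "index.fasta", "reads_dna.fastq",
    "reads_rna.fastq", "truth.tsv", "labels.tsv", "manifest.json"
  )))))
  back_exon <- read_exon_fasta(file.path(dir, "exon.fasta"))
  expect_identical(back_exon$sequence, sim$exon$sequence)
  back_idx <- read_index(file.path(dir, "index.fasta"))
  expect_equal(back_idx$junction, sim$index$junction)
  back_rna <- read_reads(file.path(dir, "reads_rna.fastq"))
  expect_identical(back_rna$sequence, sim$rna$sequence)
  back_scheme <- read_primer_scheme(file.path(dir, "scheme.tsv"))
  expect_equal(back_scheme$position, sim$scheme$position)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$seed, 263)
})
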