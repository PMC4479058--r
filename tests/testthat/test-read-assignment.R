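assignment_wt <- function(x) x$summary$n[x$summary$category == "wildtype"]

make_test_index <- function(seed = 31, flank = 20, n_fwd = 3, n_rev = 3,
                            exon_len = 181) {
  exon <- make_exon(exon_len, seed = seed)
  scheme <- simulate_scheme(exon_len, n_fwd = n_fwd, n_rev = n_rev,
                            seed = seed + 1)
  index <- build_deletion_index(exon, enumerate_deletions(scheme, exon, 0),
                                flank)
  list(exon = exon, index = index)
}

test_that("the length filter is strictly greater-than", {
  reads <- tibble::tibble(
    read_id = c("a", "b", "c"),
    sequence = c(strrep("A", 41), strrep("C", 40), strrep("G", 39))
  )
  kept <- length_filter(reads, 40)
  expect_equal(kept$read_id, "a")
  expect_equal(attr(kept, "n_removed"), 2L)
  empty <- length_filter(reads[0, ], 40)
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "n_removed"), 0L)
})

test_that("hamming_best_match finds the minimal-distance placement", {
  withr::local_seed(41)
  refs <- c(r1 = random_dna(60), r2 = random_dna(60))
  read <- substr(refs["r1"], 11, 40)
  hit <- hamming_best_match(read, refs)
  expect_equal(hit$reference, "r1")
  expect_equal(hit$mismatches, 0L)
  expect_equal(hit$offset, 11L)
  expect_false(hit$tie)

  mutated <- mutate_seq(read, c(5, 20))
  expect_equal(hamming_best_match(mutated, refs, 3)$mismatches, 2L)
  expect_true(is.na(hamming_best_match(mutated, refs, 1)$reference))

  # equal distance to two references is reported as a tie
  dup <- c(a = refs[["r1"]], b = refs[["r1"]])
  expect_true(hamming_best_match(read, dup)$tie)

  # N counts as a mismatch
  n_read <- sub("^.", "N", read)
  expect_equal(hamming_best_match(n_read, refs)$mismatches, 1L)

  # read longer than every reference: no match, not an error
  expect_true(is.na(hamming_best_match(strrep("A", 100), refs)$reference))
})

test_that("hamming_best_match agrees with the exhaustive scan oracle", {
  withr::local_seed(43)
  for (i in 1:30) {
    refs <- vapply(seq_len(sample(2:5, 1)),
                   function(j) random_dna(sample(30:60, 1)), "")
    base <- refs[[sample(length(refs), 1)]]
    start <- sample(nchar(base) - 24, 1)
    read <- substr(base, start, start + 24)
    if (runif(1) < 0.7) read <- mutate_seq(read, sample(25, sample(0:5, 1)))
    got <- hamming_best_match(read, setNames(refs, seq_along(refs)), 3)
    want <- oracle_best_match(read, refs, 3)
    expect_equal(is.na(got$reference), is.na(want$ref))
    if (!is.na(want$ref)) {
      expect_equal(got$mismatches, want$mm)
      expect_equal(got$tie, want$tie)
      if (!want$tie) expect_equal(got$reference, as.character(want$ref))
    }
  }
})

test_that("reads drawn from the wild-type exon all count as wild-type", {
  fx <- make_test_index(flank = 45)
  withr::local_seed(47)
  starts <- sample(fx$exon$length - 44, 200, replace = TRUE)
  reads <- tibble::tibble(
    read_id = sprintf("r%03d", 1:200),
    sequence = substr(rep(fx$exon$sequence, 200), starts, starts + 44)
  )
  res <- assign_reads(reads, fx$exon, fx$index, min_read_len = 40)
  expect_equal(assignment_wt(res), 200L)
  expect_true(all(res$counts$n == 0))
})

test_that("error-free junction reads are recovered at exact known counts", {
  fx <- make_test_index(seed = 53, flank = 45)
  idx <- fx$index[1:3, ]
  withr::local_seed(59)
  n_per <- c(100, 200, 300)
  # overhangs of >= 12 nt on each side keep every read outside the
  # wild-type mismatch budget, so counts must round-trip exactly
  seqs <- unlist(lapply(1:3, function(i) {
    j <- idx$junction_pos[i]
    starts <- sample(max(1, j - 32):(j - 12), n_per[i], replace = TRUE)
    substr(rep(idx$junction[i], n_per[i]), starts, starts + 44)
  }))
  reads <- tibble::tibble(read_id = sprintf("r%03d", seq_along(seqs)),
                          sequence = seqs)
  res <- assign_reads(reads, fx$exon, fx$index, min_read_len = 40)
  got <- res$counts$n[match(
    paste(idx$del_start, idx$del_end),
    paste(res$counts$del_start, res$counts$del_end)
  )]
  expect_equal(got, c(100L, 200L, 300L))
  expect_equal(sum(res$counts$n), 600L)
})

test_that("a read that matches wild-type is never assigned to an isoform", {
  fx <- make_test_index(seed = 61, flank = 45)
  # a read entirely within a left flank is also a perfect wild-type substring
  j <- fx$index$junction_pos[1]
  read <- substr(fx$index$junction[1], 1, j)
  res <- assign_reads(tibble::tibble(read_id = "r1", sequence = read),
                      fx$exon, fx$index, min_read_len = 30)
  expect_equal(assignment_wt(res), 1L)
  expect_equal(sum(res$counts$n), 0L)
})

test_that("assign_reads agrees with the brute-force hierarchical oracle", {
  withr::local_seed(67)
  for (rep in 1:3) {
    fx <- make_test_index(seed = 70 + rep, flank = 25,
                          n_fwd = 3, n_rev = 3)
    idx <- fx$index
    seqs <- character(0)
    for (k in 1:50) {
      kind <- sample(c("wt", "junction", "junk", "short"), 1,
                     prob = c(0.3, 0.45, 0.15, 0.1))
      seqs <- c(seqs, switch(
        kind,
        wt = {
          st <- sample(fx$exon$length - 23, 1)
          substr(fx$exon$sequence, st, st + 23)
        },
        junction = {
          i <- sample(nrow(idx), 1)
          st <- sample(nchar(idx$junction[i]) - 23, 1)
          s <- substr(idx$junction[i], st, st + 23)
          if (runif(1) < 0.5) s <- mutate_seq(s, sample(24, sample(0:4, 1)))
          s
        },
        junk = random_dna(24),
        short = random_dna(sample(5:20, 1))
      ))
    }
    reads <- tibble::tibble(read_id = sprintf("r%02d", seq_along(seqs)),
                            sequence = seqs)
    got <- assign_reads(reads, fx$exon, fx$index,
                        max_mismatches = 3, min_read_len = 20)
    want <- oracle_assign(seqs, fx$exon$sequence, idx$junction, 3, 20)
    expect_equal(got$counts$n, want$counts)
    expect_equal(assignment_wt(got), want$wildtype)
    s <- setNames(got$summary$n, got$summary$category)
    expect_equal(s[["ambiguous"]], want$ambiguous)
    expect_equal(s[["unassigned"]], want$unassigned)
    expect_equal(s[["filtered_short"]], want$filtered_short)
  }
})

test_that("counts are conserved and assignment grows with the budget", {
  fx <- make_test_index(seed = 83, flank = 25)
  withr::local_seed(89)
  seqs <- replicate(120, {
    i <- sample(nrow(fx$index), 1)
    st <- sample(nchar(fx$index$junction[i]) - 23, 1)
    mutate_seq(substr(fx$index$junction[i], st, st + 23),
               sample(24, sample(0:5, 1)))
  })
  reads <- tibble::tibble(read_id = sprintf("r%03d", 1:120), sequence = seqs)
  prev_assigned <- -1
  for (budget in 0:4) {
    res <- assign_reads(reads, fx$exon, fx$index,
                        max_mismatches = budget, min_read_len = 20)
    s <- setNames(res$summary$n, res$summary$category)
    expect_equal(s[["total"]],
                 s[["filtered_short"]] + s[["wildtype"]] + s[["assigned"]] +
                   s[["ambiguous"]] + s[["unassigned"]])
    assigned <- s[["wildtype"]] + s[["assigned"]]
    expect_gte(assigned, prev_assigned)
    prev_assigned <- assigned
  }
})

test_that("sequencing errors rarely defeat assignment at the default budget", {
  config <- simulation_config(seed = 97, n_fwd = 3, n_rev = 3,
                              dna_depth = 2000, rna_depth = 2000,
                              error_rate = 0.005)
  sim <- simulate_qrnaseq(config)
  res <- assign_reads(sim$rna, sim$exon, sim$index)
  truth <- sim$labels[sim$labels$library == "rna" & sim$labels$origin != "wt", ]
  detail <- merge(res$details, truth, by = "read_id")
  correct <- sum(detail$status == "assigned" &
                   detail$del_start.x == detail$del_start.y &
                   detail$del_end.x == detail$del_end.y)
  expect_gte(correct / nrow(truth), 0.99)
})

test_that("reverse-complement reads match only when the flag is on", {
  fx <- make_test_index(seed = 101, flank = 45)
  read <- substr(fx$exon$sequence, 20, 64)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  reads <- tibble::tibble(read_id = "r1", sequence = rc)
  plain <- assign_reads(reads, fx$exon, fx$index, min_read_len = 40)
  expect_equal(assignment_wt(plain), 0L)
  flipped <- assign_reads(reads, fx$exon, fx$index, min_read_len = 40,
                          match_reverse_complement = TRUE)
  expect_equal(assignment_wt(flipped), 1L)
})

test_that("mismatched exon names and short flanks are rejected", {
  fx <- make_test_index(seed = 103, flank = 45)
  other <- exon_template(fx$exon$sequence, name = "other_exon")
  reads <- tibble::tibble(read_id = "r1", sequence = strrep("A", 45))
  expect_error(assign_reads(reads, other, fx$index), "built from exon")
  expect_error(assign_reads(reads, fx$exon, fx$index, min_read_len = 50),
               "flank_len")
})
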