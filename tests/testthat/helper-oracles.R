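# Independent brute-force oracles, deliberately written as plain nested
# loops so they share no code path with the package implementation.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_seq <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1]]
  for (p in positions) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  }
  paste(ch, collapse = "")
}

# Exhaustive loop over (forward, reverse, t_f, t_r) tuples.
oracle_enumerate <- function(fwd, rev, max_trunc, exon_len) {
  seen <- character(0)
  rows <- list()
  for (f in fwd) for (r in rev) {
    for (t_f in 0:max_trunc) for (t_r in 0:max_trunc) {
      ds <- r + 1 - t_r
      de <- f - 1 + t_f
      if (ds >= 2 && de <= exon_len - 1 && ds <= de) {
        key <- paste(ds, de)
        if (!key %in% seen) {
          seen <- c(seen, key)
          rows[[length(rows) + 1]] <- c(ds, de)
        }
      }
    }
  }
  if (length(rows) == 0) return(data.frame(del_start = integer(), del_end = integer()))
  m <- do.call(rbind, rows)
  out <- data.frame(del_start = m[, 1], del_end = m[, 2])
  out[order(out$del_start, out$del_end), ]
}

# All-offsets Hamming scan of one read against a set of references.
oracle_best_match <- function(read, refs, max_mm) {
  best <- Inf; best_ref <- NA_integer_; tie <- FALSE
  q <- strsplit(read, "")[[1]]
  for (j in seq_along(refs)) {
    s <- strsplit(refs[j], "")[[1]]
    if (length(s) < length(q)) next
    for (off in 0:(length(s) - length(q))) {
      mm <- sum(q != s[(off + 1):(off + length(q))])
      if (mm < best) {
        best <- mm; best_ref <- j; tie <- FALSE
      } else if (mm == best && j != best_ref) {
        tie <- TRUE
      }
    }
  }
  if (!is.finite(best) || best > max_mm) {
    list(ref = NA_integer_, mm = NA_integer_, tie = FALSE)
  } else {
    list(ref = best_ref, mm = best, tie = tie)
  }
}

# Hierarchical assignment mirroring the documented contract, independently.
oracle_assign <- function(sequences, wt_seq, junctions, max_mm, min_len) {
  counts <- integer(length(junctions))
  n_wt <- 0L; n_amb <- 0L; n_un <- 0L; n_short <- 0L
  for (s in sequences) {
    if (nchar(s) <= min_len) { n_short <- n_short + 1L; next }
    wt_hit <- oracle_best_match(s, wt_seq, max_mm)
    if (!is.na(wt_hit$ref)) { n_wt <- n_wt + 1L; next }
    hit <- oracle_best_match(s, junctions, max_mm)
    if (is.na(hit$ref)) {
      n_un <- n_un + 1L
    } else if (hit$tie) {
      n_amb <- n_amb + 1L
    } else {
      counts[hit$ref] <- counts[hit$ref] + 1L
    }
  }
  list(counts = counts, wildtype = n_wt, ambiguous = n_amb,
       unassigned = n_un, filtered_short = n_short)
}
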