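# Independent oracles and random-instance generators shared across tests.
# These deliberately avoid the package's search machinery: containment is
# checked by direct substring slicing and fragment sets by enumerating all
# boundary pairs.

# All 0-based starts of `needle` in `hay` by sliding-window comparison.
naive_offsets <- function(needle, hay) {
  k <- nchar(needle)
  n <- nchar(hay)
  if (k > n) return(integer())
  starts <- seq_len(n - k + 1L)
  as.integer(starts[substring(hay, starts, starts + k - 1L) == needle] - 1L)
}

# Field-for-field reference implementation of classify_matches(): a plain
# double loop over all (peptide row, db entry) pairs.
naive_classify <- function(p, db) {
  rows <- list()
  for (i in seq_len(nrow(p))) {
    s <- p$sequence[i]
    for (j in seq_len(nrow(db))) {
      d <- db$sequence[j]
      if (s == d) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          sample = p$sample[i], fraction = p$fraction[i], mode = "exact",
          sample_sequence = s, db_sequence = d, db_name = db$name[j],
          activities = db$activities[j], offsets = list(0L),
          n_occurrences = 1L)
      } else if (nchar(s) < nchar(d)) {
        off <- naive_offsets(s, d)
        if (length(off) > 0L) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            sample = p$sample[i], fraction = p$fraction[i], mode = "partial",
            sample_sequence = s, db_sequence = d, db_name = db$name[j],
            activities = db$activities[j], offsets = list(off),
            n_occurrences = length(off))
        }
      } else {
        off <- naive_offsets(d, s)
        if (length(off) > 0L) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            sample = p$sample[i], fraction = p$fraction[i], mode = "cryptide",
            sample_sequence = s, db_sequence = d, db_name = db$name[j],
            activities = db$activities[j], offsets = list(off),
            n_occurrences = length(off))
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(classify_matches(peptidome(), bioactive_db()))
  }
  out <- do.call(rbind, rows)
  out[order(out$sample, out$fraction, out$mode, out$sample_sequence,
            out$db_sequence), , drop = FALSE]
}

# Random peptide sequences over a small alphabet (small alphabets make
# containments common enough to exercise every mode).
random_seqs <- function(n, min_len = 2L, max_len = 12L,
                        alphabet = c("A", "G", "P", "V")) {
  vapply(sample(min_len:max_len, n, replace = TRUE), function(l)
    paste(sample(alphabet, l, replace = TRUE), collapse = ""), character(1))
}

random_instance <- function(max_pep = 25L, max_db = 20L) {
  np <- sample.int(max_pep + 1L, 1L) - 1L
  nd <- sample.int(max_db + 1L, 1L) - 1L
  p <- suppressMessages(peptidome(random_seqs(np), sample = "S",
                                  fraction = "other"))
  db <- suppressMessages(bioactive_db(random_seqs(nd),
                                      name = "x", activity = "act",
                                      source = "rand"))
  list(p = p, db = db)
}

# Brute-force fragment enumeration over all boundary pairs, independent of
# digest_sequence()'s vectorized indexing.
brute_fragments <- function(seq, sites, params) {
  bounds <- c(0L, sites, nchar(seq))
  rows <- list()
  for (a in seq_along(bounds)) {
    for (b in seq_along(bounds)) {
      if (b <= a) next
      n_missed <- b - a - 1L
      len <- bounds[b] - bounds[a]
      if (n_missed > params$max_missed) next
      if (len < params$min_len || len > params$max_len) next
      rows[[length(rows) + 1L]] <- data.frame(
        start = bounds[a], end = bounds[b],
        sequence = substr(seq, bounds[a] + 1L, bounds[b]),
        n_missed = n_missed, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      sequence = character(), n_missed = integer()))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$end), , drop = FALSE]
}

expect_same_records <- function(got, want) {
  expect_equal(nrow(got), nrow(want))
  for (col in c("sample", "fraction", "mode", "sample_sequence",
                "db_sequence", "db_name", "n_occurrences")) {
    expect_equal(got[[col]], want[[col]], ignore_attr = TRUE)
  }
  expect_equal(unname(lapply(got$offsets, as.integer)),
               unname(lapply(want$offsets, as.integer)))
}
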