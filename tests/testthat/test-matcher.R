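fixture <- bioactive_fixture_db()

test_that("worked-example matches reproduce with correct offsets", {
  p <- velvet_free_peptides()
  partial <- partial_matches(p, fixture)
  one <- function(s, d) {
    r <- partial[partial$sample == "FDVA" & partial$sample_sequence == s &
                   partial$db_sequence == d, ]
    expect_equal(nrow(r), 1L)
    r$offsets[[1]]
  }
  expect_equal(one("VVYPWTQR", "LVVYPWTQR"), 1L)
  expect_equal(one("TYFPH", "FLSFPTTKTYFPHFDLSHGSAQVKGHGAK"), 8L)
  expect_equal(one("SRAGLQFPVGRVH", "TRSSRAGLQFPVGRVHRLLRK"), 3L)
  # a peptide identical to an entry is never reported as partial
  expect_false(any(partial$sample_sequence == partial$db_sequence))
  expect_true("LVVYPW" %in% exact_matches(p, fixture)$sample_sequence)
})

test_that("cryptide occurrences count every start position, overlaps included", {
  db <- generate_db(list(GP = "ACE inhibitor", VGAPG = "chemotactic",
                         AGA = "x"))
  p <- peptidome(c("GPAGPR", "KVGAPGK", "AGAGA"), "S", "other")
  rec <- find_cryptides(p, db)
  gp <- rec[rec$db_sequence == "GP", ]
  expect_equal(gp$offsets[[1]], c(0L, 3L))
  expect_equal(gp$n_occurrences, 2L)
  expect_equal(rec$n_occurrences[rec$db_sequence == "VGAPG"], 1L)
  # overlapping occurrences of AGA in AGAGA both count
  expect_equal(rec$offsets[[which(rec$db_sequence == "AGA")]], c(0L, 2L))
  # an entry longer than every peptide matches nothing
  long_db <- generate_db(list(AAAAAAAAAAAAAAAA = "x"))
  expect_equal(nrow(find_cryptides(p, long_db)), 0L)
})

test_that("every reported offset verifies by direct slicing", {
  p <- velvet_free_peptides()
  rec <- classify_matches(p, fixture)
  for (i in seq_len(nrow(rec))) {
    contained <- if (rec$mode[i] == "cryptide") rec$db_sequence[i]
                 else rec$sample_sequence[i]
    containing <- if (rec$mode[i] == "cryptide") rec$sample_sequence[i]
                  else rec$db_sequence[i]
    for (off in rec$offsets[[i]]) {
      expect_identical(substr(containing, off + 1L, off + nchar(contained)),
                       contained)
    }
  }
})

test_that("modes are mutually exclusive per (peptide, entry) pair", {
  set.seed(101)
  for (rep in 1:25) {
    inst <- random_instance()
    rec <- classify_matches(inst$p, inst$db)
    key <- paste(rec$sample, rec$fraction, rec$sample_sequence,
                 rec$db_sequence)
    expect_false(any(duplicated(key)))
  }
})

test_that("adding entries or peptides never disturbs existing records", {
  set.seed(202)
  inst <- random_instance(20, 15)
  extra_db <- suppressMessages(
    bioactive_db(c(inst$db$sequence, "GPGPGP"), name = "x", activity = "a"))
  rec1 <- classify_matches(inst$p, inst$db)
  rec2 <- classify_matches(inst$p, extra_db)
  key <- function(r) paste(r$sample_sequence, r$db_sequence, r$mode)
  expect_true(all(key(rec1) %in% key(rec2)))
  p2 <- suppressMessages(peptidome(c(inst$p$sequence, "PPPPGA"),
                                   "S", "other"))
  rec3 <- classify_matches(p2, inst$db)
  old <- rec3[rec3$sample_sequence %in% inst$p$sequence, ]
  expect_same_records(old, rec1)
})

test_that("cryptide summaries follow the distinct-sequence convention", {
  db <- generate_db(list(GP = "ACE inhibitor"))
  p <- peptidome("GPGP", "S", "other")
  s <- cryptide_summary(find_cryptides(p, db), by = character())
  expect_equal(s$n_individual, 1L)
  expect_equal(s$total_hits, 2L)
  expect_equal(s$mean_length, 2)
  expect_equal(s$sd_length, 0)
  # no hits -> zero counts, absent statistics
  s0 <- cryptide_summary(find_cryptides(peptidome(), db), by = character())
  expect_equal(s0$n_individual, 0L)
  expect_equal(s0$total_hits, 0L)
  expect_true(is.na(s0$mean_length) && is.na(s0$sd_length))
  # hit-weighted alternative weights each sequence by its occurrences
  db2 <- generate_db(list(GP = "a", VGAPG = "b"))
  p2 <- peptidome(c("GPGPA", "KVGAPGK"), "S", "other")
  sw <- cryptide_summary(find_cryptides(p2, db2), by = character(),
                         weight = "hits")
  expect_equal(sw$mean_length, (2 + 2 + 5) / 3)
})

test_that("activity frequencies expand multi-activity sequences per category", {
  db <- generate_db(list(GP = c("ACE inhibitor", "antiamnestic"),
                         LL = "stimulating"))
  p <- peptidome(c("AGPAGPA", "ALLA"), "S", "other")
  rec <- find_cryptides(p, db)
  freq <- activity_frequency(rec, db)
  expect_equal(freq$n_hits[freq$activity == "ACE inhibitor"], 2L)
  expect_equal(freq$n_hits[freq$activity == "antiamnestic"], 2L)
  expect_equal(freq$n_hits[freq$activity == "stimulating"], 1L)
  # per-category expansion can exceed the total hit count
  expect_gte(sum(freq$n_hits), sum(rec$n_occurrences))
  # records referring to sequences outside the database are an error
  rec_bad <- rec
  rec_bad$db_sequence[1] <- "WWWW"
  expect_error(activity_frequency(rec_bad, db), "absent")
  expect_equal(nrow(activity_frequency(rec[0, ], db)), 0L)
})

test_that("matching equals the naive all-pairs oracle on random instances", {
  set.seed(7)
  for (rep in 1:60) {
    inst <- random_instance()
    expect_same_records(classify_matches(inst$p, inst$db),
                        naive_classify(inst$p, inst$db))
  }
})
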