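# The probe panel (helper-probes.R) holds hand-derived expected sites.

test_that("site prediction matches the hand-derived probe panel", {
  rules <- pepsin_rules()
  for (seq in names(probe_panel)) {
    expect_equal(find_cleavage_sites(seq, rules), probe_panel[[seq]],
                 label = paste("sites of", seq))
  }
})

test_that("terminal bonds are never sites and bad residues are named", {
  rules <- pepsin_rules()
  for (seq in c("FF", "WY", "AAFAA")) {
    sites <- find_cleavage_sites(seq, rules)
    expect_true(all(sites >= 1L & sites <= nchar(seq) - 1L))
  }
  expect_error(find_cleavage_sites("AAXAA", rules), "position 3")
})

test_that("rule tables are data and can be swapped", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("enzyme\trule_id\tposition\tconstraint_type\tresidues",
               "toy\tr1\t-1\tallowed\tK",
               "toy\tr1\t1\tforbidden\tP"), f)
  toy <- cleavage_rules("toy", path = f)
  expect_equal(find_cleavage_sites("AKAKPA", toy), 2L)
  expect_error(cleavage_rules("trypsin", path = f), "no rules")
})

test_that("fragment sets equal brute-force boundary enumeration", {
  rules <- pepsin_rules()
  set.seed(11)
  seqs <- c(names(probe_panel),
            random_seqs(40, min_len = 5, max_len = 25,
                        alphabet = c("A", "G", "F", "L", "P", "K", "W", "Y")))
  for (seq in seqs) {
    if (nchar(seq) < 2) next
    sites <- find_cleavage_sites(seq, rules)
    for (params in list(digest_params(), digest_params(1, 3, 8),
                        digest_params(0, 1, nchar(seq)))) {
      got <- digest_sequence(seq, rules, params)
      want <- brute_fragments(seq, sites, params)
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$sequence, want$sequence)
      expect_equal(got$n_missed, want$n_missed)
    }
  }
})

test_that("unfiltered fragment counts follow the closed form", {
  rules <- pepsin_rules()
  set.seed(12)
  seqs <- random_seqs(60, min_len = 4, max_len = 30,
                      alphabet = c("A", "F", "L", "W", "Y", "G", "P", "K"))
  tested_k <- integer()
  for (seq in seqs) {
    k <- length(find_cleavage_sites(seq, rules))
    tested_k <- c(tested_k, k)
    for (m in 0:4) {
      params <- digest_params(m, 1, nchar(seq))
      expected <- sum((k + 1) - 0:min(m, k))
      expect_equal(nrow(digest_sequence(seq, rules, params)), expected)
    }
  }
  expect_gte(max(tested_k), 5L)   # the panel really exercises multi-site cases
})

test_that("zero-missed fragments reconstruct the parent in order", {
  rules <- pepsin_rules()
  set.seed(13)
  for (seq in random_seqs(25, min_len = 4, max_len = 30,
                          alphabet = c("A", "F", "L", "G", "P", "W"))) {
    frags <- digest_sequence(seq, rules,
                             digest_params(0, 1, nchar(seq)))
    expect_identical(paste(frags$sequence, collapse = ""), seq)
  }
})

test_that("relaxing the limits never removes a fragment", {
  rules <- pepsin_rules()
  set.seed(14)
  key <- function(f) paste(f$start, f$end)
  for (seq in random_seqs(20, min_len = 6, max_len = 25,
                          alphabet = c("A", "F", "L", "G", "W", "Y"))) {
    base <- digest_sequence(seq, rules, digest_params(1, 3, 8))
    more_missed <- digest_sequence(seq, rules, digest_params(3, 3, 8))
    wider <- digest_sequence(seq, rules, digest_params(1, 2, 12))
    expect_true(all(key(base) %in% key(more_missed)))
    expect_true(all(key(base) %in% key(wider)))
  }
})

test_that("survival reduces to the site-count and length conditions", {
  expect_true(all(survives_digestion(c("LVVYPW", "LVVYPWTQ", "VVYPWTQ"))))
  # a 14-residue peptide exceeds the 13-residue window regardless of sites
  expect_false(survives_digestion(strrep("AG", 7)))
  # more internal sites than allowed missed cleavages
  expect_false(survives_digestion("AFAFAFAFA", params = digest_params(3)))
  expect_equal(length(find_cleavage_sites("AFAFAFAFA")), 8L)
  # target = parent is the same question as survival
  for (seq in c("LVVYPW", "VVYPWTQ", "AFAFAFAFA")) {
    expect_equal(released_by_digestion(seq, seq), survives_digestion(seq))
  }
})

test_that("release requires fragment boundaries, not mere containment", {
  # GP inside an uncleavable parent stays encrypted
  expect_false(released_by_digestion("GP", "AGPA"))
  # a C-terminal GP preceded by a cleavage site (after the F) is released
  expect_true(released_by_digestion("GP", "AFGP"))
  expect_true("GP" %in% digest_sequence("AFGP")$sequence)
  # GP ends in proline, so no rule can cut immediately after it: an
  # internal GP is never released even next to cleavable residues
  expect_false(released_by_digestion("GP", "AFGPWA"))
  # not a substring -> FALSE, not an error
  expect_false(released_by_digestion("WW", "AGPA"))
})
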