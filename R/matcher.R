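#' Three-mode matching of sample peptides against a bioactive database
#'
#' The screen distinguishes three mutually exclusive relations between a
#' sample peptide `s` and a database sequence `d`:
#'
#' * **exact** — `s == d`: the sample peptide *is* a known bioactive peptide;
#' * **partial** — `s` is a proper substring of `d`: the sample peptide is a
#'   fragment of a longer known bioactive sequence;
#' * **cryptide** — `d` is a proper substring of `s`: a short bioactive
#'   peptide is encrypted within the sample peptide and could be released by
#'   proteolysis.
#'
#' Exclusivity holds per (sample peptide, database sequence) pair: a peptide
#' identical to one entry may still match other entries partially or contain
#' others as cryptides. Offsets are 0-based starts of the contained sequence
#' within the containing one; cryptide records list *every* occurrence,
#' overlapping ones included, because within-peptide multiplicity is part of
#' the hit counts. Records are ordered lexicographically by
#' (sample, fraction, sample_sequence, db_sequence) so reports are
#' byte-stable.
#'
#' @param p A [peptidome()].
#' @param db A [bioactive_db()].
#' @return A tibble of match records with columns `sample`, `fraction`,
#'   `mode`, `sample_sequence`, `db_sequence`, `db_name`, `activities`
#'   (list-column), `offsets` (list-column of 0-based integer starts) and
#'   `n_occurrences`.
#' @seealso [classify_matches()] for all three modes at once,
#'   [cryptide_summary()] and [activity_frequency()] for the summaries.
#' @export
#' @examples
#' db <- generate_db(list(GP = "ACE inhibitor"))
#' p <- peptidome("GPAGPR", "demo", "other")
#' find_cryptides(p, db)$offsets[[1]]   # 0 and 3: both occurrences count
exact_matches <- function(p, db) {
  match_mode(p, db, mode = "exact")
}

#' @rdname exact_matches
#' @export
partial_matches <- function(p, db) {
  match_mode(p, db, mode = "partial")
}

#' @rdname exact_matches
#' @export
find_cryptides <- function(p, db) {
  match_mode(p, db, mode = "cryptide")
}

#' Classify all matches between a peptidome and a database
#'
#' Runs the exact, partial and cryptide searches and returns one record
#' table. Modes are mutually exclusive per (sample peptide, database
#' sequence) pair by construction.
#'
#' @inheritParams exact_matches
#' @return A tibble as in [exact_matches()], all modes combined, ordered by
#'   (sample, fraction, mode, sample_sequence, db_sequence).
#' @export
classify_matches <- function(p, db) {
  out <- rbind(exact_matches(p, db), partial_matches(p, db),
               find_cryptides(p, db))
  out <- out[order(out$sample, out$fraction, out$mode, out$sample_sequence,
                   out$db_sequence), , drop = FALSE]
  as_tibble(out)
}

# Shared engine. Containment is located with stringi fixed-pattern search
# (overlap allowed); one vectorized call per pattern over all subjects.
match_mode <- function(p, db, mode) {
  stopifnot(inherits(p, "peptidome"), inherits(db, "bioactive_db"))
  empty <- tibble(sample = character(), fraction = character(),
                  mode = character(), sample_sequence = character(),
                  db_sequence = character(), db_name = character(),
                  activities = list(), offsets = list(),
                  n_occurrences = integer())
  if (nrow(p) == 0L || nrow(db) == 0L) return(empty)

  if (mode == "exact") {
    hit <- match(p$sequence, db$sequence)
    keep <- which(!is.na(hit))
    if (length(keep) == 0L) return(empty)
    out <- tibble(sample = p$sample[keep], fraction = p$fraction[keep],
                  mode = "exact", sample_sequence = p$sequence[keep],
                  db_sequence = p$sequence[keep],
                  db_name = db$name[hit[keep]],
                  activities = db$activities[hit[keep]],
                  offsets = rep(list(0L), length(keep)),
                  n_occurrences = 1L)
    return(order_records(out))
  }

  if (mode == "partial") {
    # sample sequence contained in a strictly longer db sequence
    pat <- unique(p$sequence)
    rec <- locate_patterns(patterns = pat, subjects = db$sequence)
    rec <- rec[nchar(pat[rec$pat]) < nchar(db$sequence[rec$sub]), ,
               drop = FALSE]
    if (nrow(rec) == 0L) return(empty)
    prow <- split(seq_len(nrow(p)), p$sequence)
    out <- do.call(rbind, lapply(seq_len(nrow(rec)), function(k) {
      i <- rec$sub[k]
      rows <- prow[[pat[rec$pat[k]]]]
      data.frame(row = rows, db = i, k = k)
    }))
    res <- tibble(sample = p$sample[out$row], fraction = p$fraction[out$row],
                  mode = "partial", sample_sequence = p$sequence[out$row],
                  db_sequence = db$sequence[out$db],
                  db_name = db$name[out$db],
                  activities = db$activities[out$db],
                  offsets = rec$starts[out$k],
                  n_occurrences = lengths(rec$starts[out$k]))
    return(order_records(res))
  }

  # cryptide: db sequence contained in a strictly longer sample sequence
  useq <- unique(p$sequence)
  rec <- locate_patterns(patterns = db$sequence, subjects = useq)
  rec <- rec[nchar(db$sequence[rec$pat]) < nchar(useq[rec$sub]), ,
             drop = FALSE]
  if (nrow(rec) == 0L) return(empty)
  prow <- split(seq_len(nrow(p)), p$sequence)
  out <- do.call(rbind, lapply(seq_len(nrow(rec)), function(k) {
    rows <- prow[[useq[rec$sub[k]]]]
    data.frame(row = rows, db = rec$pat[k], k = k)
  }))
  res <- tibble(sample = p$sample[out$row], fraction = p$fraction[out$row],
                mode = "cryptide", sample_sequence = p$sequence[out$row],
                db_sequence = db$sequence[out$db],
                db_name = db$name[out$db],
                activities = db$activities[out$db],
                offsets = rec$starts[out$k],
                n_occurrences = lengths(rec$starts[out$k]))
  order_records(res)
}

# For each pattern, find all (possibly overlapping) occurrences in each
# subject. Returns a data.frame with columns pat (pattern index), sub
# (subject index) and starts (list of 0-based starts, strictly increasing).
locate_patterns <- function(patterns, subjects) {
  hits <- vector("list", length(patterns))
  for (j in seq_along(patterns)) {
    loc <- stringi::stri_locate_all_fixed(
      subjects, patterns[j],
      opts_fixed = stringi::stri_opts_fixed(overlap = TRUE))
    found <- which(vapply(loc, function(m) !is.na(m[1, 1]), logical(1)))
    if (length(found) > 0L) {
      hits[[j]] <- data.frame(
        pat = j, sub = found,
        starts = I(lapply(loc[found], function(m) as.integer(m[, 1]) - 1L)))
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(pat = integer(), sub = integer(),
                      starts = I(list()))
  }
  out
}

order_records <- function(res) {
  res[order(res$sample, res$fraction, res$sample_sequence, res$db_sequence), ,
      drop = FALSE]
}

#' Count partial matches both ways
#'
#' Partial matching has two natural counts and published summaries use both
#' phrasings: the number of (sample peptide, database entry) *pairs*, and the
#' number of unique sample peptides with at least one partial match. Both are
#' reported per sample.
#'
#' @param records Match records from [partial_matches()] or
#'   [classify_matches()] (non-partial rows are ignored).
#' @return A tibble with columns `sample`, `n_pairs`, `n_peptides`,
#'   `min_peptide_length`, `max_peptide_length`.
#' @export
partial_match_counts <- function(records) {
  records <- records[records$mode == "partial", , drop = FALSE]
  if (nrow(records) == 0L) {
    return(tibble(sample = character(), n_pairs = integer(),
                  n_peptides = integer(), min_peptide_length = integer(),
                  max_peptide_length = integer()))
  }
  by <- split(seq_len(nrow(records)), records$sample)
  tibble(
    sample = names(by),
    n_pairs = unname(vapply(by, length, integer(1))),
    n_peptides = unname(vapply(by, function(i)
      length(unique(records$sample_sequence[i])), integer(1))),
    min_peptide_length = unname(vapply(by, function(i)
      min(nchar(unique(records$sample_sequence[i]))), integer(1))),
    max_peptide_length = unname(vapply(by, function(i)
      max(nchar(unique(records$sample_sequence[i]))), integer(1))))
}

#' Summarize cryptide content
#'
#' For each group, reports the number of distinct matched database sequences
#' (`n_individual`), the mean and standard deviation of their residue
#' lengths, and the total occurrence count over all records (`total_hits`).
#' By default the length statistics are unweighted over the distinct matched
#' sequences, pairing naturally with `n_individual`; `weight = "hits"`
#' weights each sequence by its occurrence count instead.
#'
#' @param records Cryptide match records ([find_cryptides()] output, or
#'   [classify_matches()] output — non-cryptide rows are dropped).
#' @param by Grouping columns, default `"sample"`; use `character()` for one
#'   overall summary.
#' @param weight `"distinct"` (default) or `"hits"`.
#' @return A tibble with the grouping columns plus `n_individual`,
#'   `mean_length`, `sd_length`, `total_hits`. With no hits the counts are 0
#'   and the length statistics `NA`; a single distinct sequence has
#'   `sd_length` 0.
#' @export
cryptide_summary <- function(records, by = "sample",
                             weight = c("distinct", "hits")) {
  weight <- match.arg(weight)
  records <- records[records$mode == "cryptide", , drop = FALSE]
  summarize_one <- function(idx) {
    seqs <- records$db_sequence[idx]
    occ <- records$n_occurrences[idx]
    useq <- unique(seqs)
    if (length(useq) == 0L) {
      return(c(n_individual = 0L, mean_length = NA_real_,
               sd_length = NA_real_, total_hits = 0L))
    }
    len <- if (weight == "distinct") nchar(useq)
           else rep(nchar(seqs), occ)
    c(n_individual = length(useq),
      mean_length = mean(len),
      sd_length = if (length(len) > 1L) sd(len) else 0,
      total_hits = sum(occ))
  }
  if (length(by) == 0L) {
    stats <- summarize_one(seq_len(nrow(records)))
    return(tibble(n_individual = as.integer(stats[["n_individual"]]),
                  mean_length = stats[["mean_length"]],
                  sd_length = stats[["sd_length"]],
                  total_hits = as.integer(stats[["total_hits"]])))
  }
  if (nrow(records) == 0L) {
    cols <- c(setNames(rep(list(character()), length(by)), by),
              list(n_individual = integer(), mean_length = numeric(),
                   sd_length = numeric(), total_hits = integer()))
    return(as_tibble(cols))
  }
  key <- interaction(records[by], drop = TRUE, lex.order = TRUE, sep = "\r")
  groups <- split(seq_len(nrow(records)), key)
  keys <- do.call(rbind, strsplit(names(groups), "\r", fixed = TRUE))
  stats <- t(vapply(groups, summarize_one, numeric(4)))
  out <- as_tibble(as.data.frame(keys, stringsAsFactors = FALSE))
  names(out) <- by
  out$n_individual <- as.integer(stats[, "n_individual"])
  out$mean_length <- stats[, "mean_length"]
  out$sd_length <- stats[, "sd_length"]
  out$total_hits <- as.integer(stats[, "total_hits"])
  out
}

#' Tally cryptide hits by bioactivity category
#'
#' Each cryptide record contributes its full occurrence count to *every*
#' activity category of its database sequence, so the column sum over
#' categories can exceed the total hit count when multi-activity sequences
#' are involved — one peptide listed under several categories counts once
#' per category. Activity labels are compared case-insensitively after
#' trimming; the database's spelling is reported.
#'
#' @param records Cryptide match records; every `db_sequence` must be present
#'   in `db` or an error is raised.
#' @param db The [bioactive_db()] the records were matched against.
#' @param by Extra grouping columns from `records` (e.g. `"sample"`);
#'   `NULL` for one overall table.
#' @return A tibble with the grouping columns plus `activity` and `n_hits`,
#'   sorted by decreasing `n_hits` within group. Categories with no hits are
#'   absent.
#' @export
activity_frequency <- function(records, db, by = NULL) {
  stopifnot(inherits(db, "bioactive_db"))
  records <- records[records$mode == "cryptide", , drop = FALSE]
  missing <- setdiff(records$db_sequence, db$sequence)
  if (length(missing) > 0L) {
    stop("match records refer to sequence(s) absent from the database: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  if (nrow(records) == 0L) {
    cols <- c(setNames(rep(list(character()), length(by)), by),
              list(activity = character(), n_hits = integer()))
    return(as_tibble(cols))
  }
  i <- match(records$db_sequence, db$sequence)
  acts <- db$activities[i]
  n_per <- lengths(acts)
  long <- data.frame(activity = unlist(acts, use.names = FALSE),
                     n = rep(records$n_occurrences, n_per),
                     stringsAsFactors = FALSE)
  long$key <- tolower(trimws(long$activity))
  if (!is.null(by)) {
    for (b in by) long[[b]] <- rep(records[[b]], n_per)
    agg <- stats::aggregate(n ~ ., data = long[c(by, "key", "n")], FUN = sum)
  } else {
    agg <- stats::aggregate(n ~ key, data = long, FUN = sum)
  }
  # report the database's first spelling for each case-folded label
  spell <- long$activity[!duplicated(long$key)]
  names(spell) <- long$key[!duplicated(long$key)]
  agg$activity <- unname(spell[agg$key])
  agg$key <- NULL
  names(agg)[names(agg) == "n"] <- "n_hits"
  ord <- if (!is.null(by)) {
    do.call(order, c(unname(agg[by]), list(-agg$n_hits, agg$activity)))
  } else {
    order(-agg$n_hits, agg$activity)
  }
  agg <- agg[ord, c(by, "activity", "n_hits"), drop = FALSE]
  agg$n_hits <- as.integer(agg$n_hits)
  rownames(agg) <- NULL
  as_tibble(agg)
}
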