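#' Run the matching pipeline and write its reports
#'
#' Matches a peptidome against a database in all three modes and writes
#' deterministic, machine-readable reports: the full match table, the
#' partial-match counts, and — for two scopes per sample — the cryptide
#' summary and the per-category activity frequencies. The *free-peptide*
#' scope covers the ultrafiltrate fraction only; the *all-peptide* scope
#' pools every fraction of a sample into one list of unique sequences before
#' matching. Identical inputs produce byte-identical files.
#'
#' @param p A [peptidome()].
#' @param db A [bioactive_db()].
#' @param out_dir Output directory (created if needed); `NULL` skips writing
#'   and just returns the tables.
#' @param free_fraction Fraction label defining the free-peptide scope.
#' @return Invisibly, a list with `matches`, `partial_counts`,
#'   `cryptide_summary`, `activity_frequency` tibbles and `paths` (when
#'   written). Summary tables carry a `scope` column (`"free"`/`"all"`).
#' @export
#' @examples
#' res <- run_match(velvet_free_peptides(), bioactive_fixture_db())
#' res$partial_counts
run_match <- function(p, db, out_dir = NULL,
                      free_fraction = "ultrafiltrate") {
  stopifnot(inherits(p, "peptidome"), inherits(db, "bioactive_db"))
  if (nrow(p) == 0L) warning("empty peptidome: reports will have zero rows")
  matches <- classify_matches(p, db)
  scopes <- list(
    free = {
      sub <- p[p$fraction == free_fraction, , drop = FALSE]
      class(sub) <- unique(c("peptidome", class(sub)))
      sub
    },
    all = pool_fractions(p))
  summaries <- list()
  freqs <- list()
  for (sc in names(scopes)) {
    rec <- find_cryptides(scopes[[sc]], db)
    s <- cryptide_summary(rec, by = "sample")
    f <- activity_frequency(rec, db, by = "sample")
    if (nrow(s) > 0L) s <- cbind(scope = sc, s)
    else s <- cbind(tibble(scope = character()), s)
    if (nrow(f) > 0L) f <- cbind(scope = sc, f)
    else f <- cbind(tibble(scope = character()), f)
    summaries[[sc]] <- s
    freqs[[sc]] <- f
  }
  out <- list(matches = matches,
              partial_counts = partial_match_counts(matches),
              cryptide_summary = as_tibble(do.call(rbind, summaries)),
              activity_frequency = as_tibble(do.call(rbind, freqs)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(matches = file.path(out_dir, "matches.tsv"),
               partial_counts = file.path(out_dir, "partial_counts.tsv"),
               cryptide_summary = file.path(out_dir, "cryptide_summary.tsv"),
               activity_frequency = file.path(out_dir,
                                              "activity_frequency.tsv"),
               summary_json = file.path(out_dir, "summary.json"))
    write_tsv_stable(flatten_activities(out$matches), paths[["matches"]])
    write_tsv_stable(out$partial_counts, paths[["partial_counts"]])
    write_tsv_stable(out$cryptide_summary, paths[["cryptide_summary"]])
    write_tsv_stable(out$activity_frequency, paths[["activity_frequency"]])
    jsonlite::write_json(
      list(partial_counts = out$partial_counts,
           cryptide_summary = out$cryptide_summary,
           activity_frequency = out$activity_frequency),
      paths[["summary_json"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out$paths <- paths
  }
  invisible(out)
}

flatten_activities <- function(m) {
  m$activities <- vapply(m$activities, paste, character(1), collapse = ";")
  m$offsets <- vapply(m$offsets, paste, character(1), collapse = ";")
  m
}

#' Screen matched bioactives against in silico gastric digestion
#'
#' For every match record, asks the digestion question appropriate to its
#' mode: an exact match is a free bioactive peptide, so the question is
#' whether it *survives* pepsin digestion intact; a cryptide sits inside a
#' sample peptide, so the question is whether it can be *released* by
#' digesting that peptide; a partial match is a fragment of a longer
#' bioactive sequence, so the question is whether digesting that database
#' sequence would release the observed peptide.
#'
#' @param matches Match records from [classify_matches()] (or any subset).
#' @param rules A [cleavage_rules()] set.
#' @param params A [digest_params()].
#' @param out_dir Optional output directory for `digestion_screen.tsv`.
#' @return Invisibly, a tibble with columns `sample`, `fraction`, `mode`,
#'   `target` (the sequence whose fate is assessed), `parent` (the sequence
#'   being digested; equal to `target` for exact matches) and `flag`
#'   (survives/released).
#' @export
run_digest_screen <- function(matches, rules = pepsin_rules(),
                              params = digest_params(), out_dir = NULL) {
  if (nrow(matches) == 0L) {
    out <- tibble(sample = character(), fraction = character(),
                  mode = character(), target = character(),
                  parent = character(), flag = logical())
  } else {
    target <- ifelse(matches$mode == "cryptide", matches$db_sequence,
                     matches$sample_sequence)
    parent <- ifelse(matches$mode == "cryptide", matches$sample_sequence,
                     matches$db_sequence)
    flag <- vapply(seq_along(target), function(i) {
      if (matches$mode[i] == "exact") {
        survives_digestion(target[i], rules, params)
      } else {
        released_by_digestion(target[i], parent[i], rules, params)
      }
    }, logical(1))
    out <- tibble(sample = matches$sample, fraction = matches$fraction,
                  mode = matches$mode, target = target, parent = parent,
                  flag = flag)
    out <- out[order(out$sample, out$fraction, out$mode, out$target,
                     out$parent), , drop = FALSE]
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_stable(out, file.path(out_dir, "digestion_screen.tsv"))
  }
  invisible(out)
}
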