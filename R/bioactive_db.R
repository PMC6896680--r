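#' Construct a bioactive-peptide database
#'
#' A `bioactive_db` is a tibble with one row per unique peptide sequence and
#' columns `sequence`, `name`, `activities` (a list-column of category
#' labels) and `source`. Rows supplied with the same sequence are folded into
#' a single entry holding the union of their activity labels, mirroring how
#' curated collections list one peptide several times under different
#' bioactivity categories. Activity labels are free strings; they are trimmed
#' and compared case-insensitively when folding (the first spelling seen is
#' kept), but no controlled vocabulary is enforced (see
#' [activity_categories()]).
#'
#' @param sequence Character vector of peptide sequences (case-folded to
#'   uppercase; must be >= 2 residues of the 20 standard one-letter codes).
#' @param name Character vector of free-text labels, recycled if length 1.
#' @param activity Character vector of activity-category labels, one per row
#'   (a peptide with several activities is supplied as several rows).
#' @param source Character vector of provenance tags, recycled if length 1.
#' @return A `bioactive_db` tibble, unique by `sequence`, sorted by
#'   `sequence`, with attributes `n_rows` (activity rows before folding) and
#'   `n_rejected` (invalid rows dropped).
#' @seealso [read_bioactive_db()], [bioactive_fixture_db()]
#' @export
#' @examples
#' db <- bioactive_db(c("GP", "GP", "PGP"),
#'                    name = "dipeptide",
#'                    activity = c("ACE inhibitor", "antiamnestic", "regulating"),
#'                    source = "example")
#' db$activities[[1]]
bioactive_db <- function(sequence = character(), name = "", activity = "",
                         source = "") {
  n <- length(sequence)
  df <- data.frame(sequence = normalize_sequence(as.character(sequence)),
                   name = rep_len(as.character(name), n),
                   activity = trimws(rep_len(as.character(activity), n)),
                   source = rep_len(as.character(source), n),
                   stringsAsFactors = FALSE)
  ok <- is_valid_sequence(df$sequence) & nchar(df$sequence) >= 2L &
    nzchar(df$activity)
  n_rejected <- sum(!ok)
  if (n_rejected > 0L) {
    bad <- unique(df$sequence[!ok])
    message("bioactive_db: rejected ", n_rejected, " row(s) with invalid ",
            "sequence or empty activity: ",
            paste(utils::head(bad, 5L), collapse = ", "),
            if (length(bad) > 5L) ", ..." else "")
  }
  df <- df[ok, , drop = FALSE]
  out <- fold_db_rows(df)
  attr(out, "n_rows") <- nrow(df)
  attr(out, "n_rejected") <- n_rejected
  out
}

# Fold one-activity-per-row records into entries unique by sequence. Row
# order must not affect the result: entries are sorted by sequence and the
# activity union keeps the first spelling of each case-folded label in
# sequence-major, row order.
fold_db_rows <- function(df) {
  if (nrow(df) == 0L) {
    out <- tibble(sequence = character(), name = character(),
                  activities = list(), source = character())
  } else {
    idx <- split(seq_len(nrow(df)), df$sequence)   # split() sorts keys
    out <- tibble(
      sequence = names(idx),
      name = unname(vapply(idx, function(i)
        df$name[i][nzchar(df$name[i])][1] %||% "", character(1))),
      activities = unname(lapply(idx, function(i) {
        acts <- df$activity[i]
        acts[!duplicated(tolower(acts))]
      })),
      source = unname(vapply(idx, function(i) {
        s <- unique(df$source[i][nzchar(df$source[i])])
        paste(s, collapse = ";")
      }, character(1)))
    )
  }
  class(out) <- c("bioactive_db", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a

#' Read a bioactive-peptide database from a delimited table
#'
#' Reads a TSV or CSV file (delimiter sniffed from the header) with required
#' columns `sequence`, `name`, `activity`, `source` and one activity per row.
#' Rows sharing a sequence are folded into one entry with the union of their
#' activity labels; row order does not affect the result. Sequences are
#' case-folded to uppercase before validation. A row whose sequence contains
#' a character outside the 20-letter alphabet (or is shorter than 2 residues)
#' is rejected with a message, not an error; an empty table yields an empty
#' database with a warning.
#'
#' @param path Path to the delimited file.
#' @return A `bioactive_db` (see [bioactive_db()]); attribute `n_rejected`
#'   records dropped rows and `n_rows` the surviving activity rows.
#' @export
read_bioactive_db <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read_delim_auto(path)
  required <- c("sequence", "name", "activity", "source")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("bioactive database is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    warning("empty bioactive database table: ", path)
    return(bioactive_db())
  }
  bioactive_db(df$sequence, df$name, df$activity, df$source)
}

#' Write a bioactive-peptide database to a TSV file
#'
#' Inverse of [read_bioactive_db()]: entries are expanded back to one
#' activity per row, so loading, writing and reloading round-trips to an
#' identical database.
#'
#' @param db A `bioactive_db`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bioactive_db <- function(db, path) {
  stopifnot(inherits(db, "bioactive_db"))
  n_per <- lengths(db$activities)
  acts <- unlist(db$activities, use.names = FALSE)
  if (is.null(acts)) acts <- character()
  out <- data.frame(
    sequence = rep(db$sequence, n_per),
    name = rep(db$name, n_per),
    activity = acts,
    source = rep(db$source, n_per),
    stringsAsFactors = FALSE)
  write_tsv_stable(out, path)
}

#' Database size both ways
#'
#' Curated collections can be counted as unique sequences or as
#' sequence-by-activity rows (one peptide listed under several categories
#' counts once per category). Both counts are reported because published
#' totals rarely say which convention they use.
#'
#' @param db A `bioactive_db`.
#' @return Named integer vector with `n_entries` (unique sequences) and
#'   `n_activity_rows` (sum of per-entry activity counts).
#' @export
db_counts <- function(db) {
  stopifnot(inherits(db, "bioactive_db"))
  c(n_entries = nrow(db),
    n_activity_rows = sum(lengths(db$activities)))
}

#' Index database entries by sequence length
#'
#' @param db A `bioactive_db`.
#' @return A named list mapping residue length (as character) to the
#'   sequences of that length; every entry appears in exactly one bin.
#' @export
db_length_index <- function(db) {
  stopifnot(inherits(db, "bioactive_db"))
  split(db$sequence, nchar(db$sequence))
}

#' Controlled vocabulary of bioactivity categories
#'
#' The category labels used by the bundled database. Provided for reference
#' and tidy reporting; [bioactive_db()] does not enforce it.
#'
#' @return Character vector of category labels.
#' @export
activity_categories <- function() {
  c("ACE inhibitor", "antimicrobial", "opioid", "antithrombotic",
    "antiamnestic", "regulating", "chemotactic", "anorectic",
    "antioxidative", "stimulating", "inhibitor",
    "wound healing/immunomodulatory")
}

#' Bundled database of deer-velvet bioactive peptides
#'
#' The curated bioactive peptides reported in a peptidomic study of deer
#' velvet antler (DVA) and its fermented derivative (FDVA): the long
#' haemoglobin-derived antimicrobial/opioid/ACE-inhibitor sequences and
#' wound-healing peptides that sample peptides partially matched, the three
#' free bioactive peptides found intact in FDVA (myelopeptide MP-2 `LVVYPW`
#' and the extended hemorphin-5 peptides `LVVYPWTQ` and `VVYPWTQ`), and the
#' short di-/tri-/penta-peptide cryptide motifs (e.g. `GP`, `PG`, `AG`,
#' `PGP`, `VGAPG`) with their reported activity categories. Hemorphin-4 and
#' hemorphin-5 are included under their field-standard sequences `YPWT` and
#' `YPWTQ`.
#'
#' The table ships as plain TSV under `inst/extdata` and is loaded through
#' [read_bioactive_db()], so it also exercises the loader.
#'
#' @return A `bioactive_db` with 29 entries.
#' @export
#' @examples
#' db <- bioactive_fixture_db()
#' db_counts(db)
bioactive_fixture_db <- function() {
  path <- system.file("extdata", "velvet_bioactive_db.tsv",
                      package = "cryptides", mustWork = TRUE)
  suppressWarnings(read_bioactive_db(path))
}
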