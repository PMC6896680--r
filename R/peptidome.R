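#' Construct a peptidome
#'
#' A `peptidome` is a tibble of sample peptide sequences, unique by
#' `(sample, fraction, sequence)`, with one row per peptide. It models the
#' deduplicated peptide list of an LC-MS/MS experiment: free peptides from
#' ultrafiltrates, tryptic fragments from retentates, and saline-extract
#' fragments, each tagged with its sample and fraction label.
#'
#' Modified-residue annotations (parenthesised or bracketed tags, lowercase
#' decorations) are stripped to bare sequence before validation, since all
#' matching is sequence-level. Peptides shorter than 2 residues or containing
#' non-standard codes are rejected with a message; they could never carry the
#' shortest database entries (dipeptides).
#'
#' @param sequence Character vector of peptide sequences.
#' @param sample Sample label(s), recycled if length 1 (e.g. `"FDVA"`).
#' @param fraction Fraction label(s), recycled if length 1; conventionally
#'   one of `"ultrafiltrate"`, `"retentate"`, `"pbs"`, `"other"`.
#' @return A `peptidome` tibble sorted by (sample, fraction, sequence), with
#'   attributes `n_duplicates` (collapsed repeats) and `n_rejected`.
#' @export
#' @examples
#' peptidome(c("VVYPWTQR", "VVYPWTQR", "TYFPH"), sample = "FDVA",
#'           fraction = "ultrafiltrate")
peptidome <- function(sequence = character(), sample = "sample",
                      fraction = "other") {
  n <- length(sequence)
  seqs <- strip_modifications(as.character(sequence))
  df <- data.frame(sequence = seqs,
                   sample = rep_len(as.character(sample), n),
                   fraction = rep_len(as.character(fraction), n),
                   stringsAsFactors = FALSE)
  ok <- is_valid_sequence(df$sequence) & nchar(df$sequence) >= 2L
  n_rejected <- sum(!ok)
  if (n_rejected > 0L) {
    message("peptidome: rejected ", n_rejected,
            " record(s) with invalid residues or length < 2")
  }
  df <- df[ok, , drop = FALSE]
  dup <- duplicated(df)
  n_dup <- sum(dup)
  if (n_dup > 0L) {
    message("peptidome: collapsed ", n_dup, " duplicate record(s)")
  }
  df <- df[!dup, , drop = FALSE]
  df <- df[order(df$sample, df$fraction, df$sequence), , drop = FALSE]
  out <- as_tibble(df)
  class(out) <- c("peptidome", class(out))
  attr(out, "n_duplicates") <- n_dup
  attr(out, "n_rejected") <- n_rejected
  out
}

# Remove identification-export decorations: bracketed/parenthesised tags,
# terminal dots (X.PEPTIDE.X notation), digits and other non-letters; then
# uppercase.
strip_modifications <- function(x) {
  x <- stringi::stri_replace_all_regex(x, "\\([^)]*\\)|\\[[^\\]]*\\]", "")
  x <- stringi::stri_replace_all_regex(x, "[^A-Za-z]", "")
  stringi::stri_trans_toupper(x)
}

#' Read a peptide list from FASTA or a delimited table
#'
#' FASTA input (extensions `.fa`, `.fasta`, `.faa`, or `format = "fasta"`) is
#' read with `Biostrings::readAAStringSet()`, one peptide per record.
#' Delimited input needs a header with at least a `sequence` column; optional
#' `sample` and `fraction` columns are used unless overridden by the
#' arguments. Records with invalid residues are rejected and counted;
#' duplicates are collapsed; an empty file yields an empty peptidome with a
#' warning.
#'
#' @param path Input file.
#' @param sample,fraction Labels applied to every record (for tables, `NULL`
#'   keeps the file's own columns when present).
#' @param format `"auto"` (by extension), `"fasta"` or `"table"`.
#' @return A `peptidome`.
#' @export
read_peptidome <- function(path, sample = NULL, fraction = NULL,
                           format = c("auto", "fasta", "table")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta|faa)$", path, ignore.case = TRUE))
      "fasta" else "table"
  }
  if (format == "fasta") {
    seqs <- as.character(Biostrings::readAAStringSet(path))
    if (length(seqs) == 0L) warning("empty peptide list: ", path)
    return(peptidome(unname(seqs),
                     sample = sample %||% "sample",
                     fraction = fraction %||% "other"))
  }
  df <- read_delim_auto(path)
  if (!"sequence" %in% names(df)) {
    stop("peptide table is missing required column: sequence")
  }
  if (nrow(df) == 0L) {
    warning("empty peptide list: ", path)
    return(peptidome())
  }
  smp <- sample %||% (if ("sample" %in% names(df)) df$sample else "sample")
  frc <- fraction %||%
    (if ("fraction" %in% names(df)) df$fraction else "other")
  peptidome(df$sequence, sample = smp, fraction = frc)
}

#' Combine peptidomes by set union
#'
#' Union by `(sample, fraction, sequence)`; commutative, associative and
#' idempotent, mirroring how identifications from all runs of a sample's
#' fractions are combined into one list of unique sequences.
#'
#' @param ... `peptidome` objects (or a single list of them).
#' @return A `peptidome`.
#' @export
#' @examples
#' a <- peptidome(c("GPAG", "TYFPH"), "S1", "ultrafiltrate")
#' b <- peptidome(c("TYFPH", "LVVYPW"), "S1", "retentate")
#' nrow(combine_peptidomes(a, b))
combine_peptidomes <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && !inherits(parts[[1]], "peptidome")) {
    parts <- parts[[1]]
  }
  stopifnot(all(vapply(parts, inherits, logical(1), "peptidome")))
  if (length(parts) == 0L) return(peptidome())
  df <- do.call(rbind, lapply(parts, as.data.frame))
  suppressMessages(peptidome(df$sequence, df$sample, df$fraction))
}

#' Unique-sequence counts per sample and fraction
#'
#' @param p A `peptidome`.
#' @return A list with `per_fraction` (tibble: sample, fraction, n) and
#'   `per_sample` (tibble: sample, n unique sequences across fractions).
#'   The per-sample count is at most the sum of the per-fraction counts.
#' @export
peptidome_counts <- function(p) {
  stopifnot(inherits(p, "peptidome"))
  pf <- stats::aggregate(sequence ~ sample + fraction, data = as.data.frame(p),
                         FUN = function(x) length(unique(x)))
  names(pf)[3] <- "n"
  ps <- stats::aggregate(sequence ~ sample, data = as.data.frame(p),
                         FUN = function(x) length(unique(x)))
  names(ps)[2] <- "n"
  list(per_fraction = as_tibble(pf[order(pf$sample, pf$fraction), ]),
       per_sample = as_tibble(ps[order(ps$sample), ]))
}

#' Collapse a peptidome to unique sequences per sample
#'
#' Pools all fractions of each sample into one list of unique sequences
#' (fraction label set to `"all"`). This is the "all peptides" scope of the
#' cryptide summaries, as opposed to the free-peptide (ultrafiltrate) scope.
#'
#' @param p A `peptidome`.
#' @return A `peptidome` with one row per (sample, sequence).
#' @export
pool_fractions <- function(p) {
  stopifnot(inherits(p, "peptidome"))
  suppressMessages(peptidome(p$sequence, p$sample, "all"))
}

#' Bundled free-peptide lists of the deer velvet samples
#'
#' The ultrafiltrate (free-peptide) sequences of the fermented (FDVA, 22
#' peptides) and unfermented (DVA, 9 peptides) deer velvet antler samples
#' that matched bioactive peptides in the source study: the partially
#' matching peptides plus, for FDVA, the three intact bioactive peptides
#' `LVVYPW`, `LVVYPWTQ` and `VVYPWTQ`. These lists power the worked examples
#' and are matched against [bioactive_fixture_db()].
#'
#' @param sample `"both"` (default), `"FDVA"` or `"DVA"`.
#' @return A `peptidome`.
#' @export
velvet_free_peptides <- function(sample = c("both", "FDVA", "DVA")) {
  sample <- match.arg(sample)
  path <- system.file("extdata", "velvet_free_peptides.tsv",
                      package = "cryptides", mustWork = TRUE)
  p <- read_peptidome(path, format = "table")
  if (sample != "both") {
    p <- p[p$sample == sample, , drop = FALSE]
    class(p) <- unique(c("peptidome", class(p)))
  }
  p
}

#' Write a peptidome to FASTA
#'
#' @param p A `peptidome`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_peptidome_fasta <- function(p, path) {
  stopifnot(inherits(p, "peptidome"))
  ids <- sprintf("%s|%s|%03d", p$sample, p$fraction, seq_len(nrow(p)))
  set <- Biostrings::AAStringSet(setNames(p$sequence, ids))
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}
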