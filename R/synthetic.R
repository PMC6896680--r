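#' Specify a synthetic peptidome
#'
#' Describes a random peptidome with known planted structure, emulating an
#' LC-MS/MS-derived peptide list: a few thousand unique sequences of 5-30
#' residues with uneven amino-acid composition. Background peptides are drawn
#' residue-wise from `aa_frequencies`; each planted motif is then written
#' over a random stretch of a random peptide until the requested number of
#' insertions has been made. Because insertions can create or destroy chance
#' occurrences, ground truth is always re-derived by scanning the final
#' peptidome (see [generate_peptidome()]), never taken from insertion
#' bookkeeping.
#'
#' @param n_peptides Number of background peptides to draw (default 1500,
#'   the scale of a single-sample peptide list).
#' @param min_length,max_length Peptide length window, uniform by default
#'   over 5-30 residues (identification pipelines rarely report shorter
#'   peptides; free peptides are rarely longer).
#' @param aa_frequencies `NULL` for uniform over the 20 standard residues,
#'   the string `"vertebrate"` for an average vertebrate protein composition
#'   (more realistic chance-hit rates for G/P-rich motifs), or a named
#'   probability vector over [aa_alphabet()].
#' @param planted Named list or vector mapping motif sequence to the number
#'   of insertions to plant, e.g. `c(GP = 50)`. Motifs must fit within
#'   `max_length`.
#' @param seed Integer seed; the same spec and seed give byte-identical
#'   output.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_peptides = 1500L, min_length = 5L,
                           max_length = 30L, aa_frequencies = NULL,
                           planted = NULL, seed = 1L) {
  n_peptides <- as.integer(n_peptides)
  if (n_peptides < 0L) stop("n_peptides must be >= 0")
  if (min_length < 2L || min_length > max_length) {
    stop("need 2 <= min_length <= max_length")
  }
  probs <- resolve_aa_frequencies(aa_frequencies)
  planted <- unlist(planted)
  if (length(planted) > 0L) {
    motifs <- normalize_sequence(names(planted))
    if (any(!is_valid_sequence(motifs))) {
      stop("planted motifs must use the 20 standard residues")
    }
    if (any(nchar(motifs) > max_length)) {
      stop("planted motif longer than max_length cannot be inserted")
    }
    if (any(planted < 0)) stop("planted counts must be >= 0")
    planted <- setNames(as.integer(planted), motifs)
  } else {
    planted <- setNames(integer(), character())
  }
  structure(list(n_peptides = n_peptides, min_length = as.integer(min_length),
                 max_length = as.integer(max_length), aa_frequencies = probs,
                 planted = planted, seed = as.integer(seed)),
            class = "synthetic_spec")
}

resolve_aa_frequencies <- function(x) {
  if (is.null(x)) {
    return(setNames(rep(1 / 20, 20), AA_ALPHABET))
  }
  if (identical(x, "vertebrate")) {
    # average composition of vertebrate proteins (UniProtKB/Swiss-Prot
    # release statistics, per cent), renormalized
    comp <- c(A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.37, Q = 3.93,
              E = 6.75, G = 7.07, H = 2.27, I = 5.96, L = 9.66, K = 5.84,
              M = 2.42, F = 3.86, P = 4.70, S = 6.56, T = 5.34, W = 1.08,
              Y = 2.92, V = 6.87)
    return(comp[AA_ALPHABET] / sum(comp))
  }
  if (!is.numeric(x) || is.null(names(x)) ||
      !setequal(names(x), AA_ALPHABET)) {
    stop("aa_frequencies must be NULL, \"vertebrate\", or a named vector ",
         "over the 20 standard residues")
  }
  x <- x[AA_ALPHABET]
  if (any(x < 0) || abs(sum(x) - 1) > 1e-8) {
    stop("aa_frequencies must be non-negative and sum to 1")
  }
  x
}

#' Generate a peptidome with known planted cryptides
#'
#' Draws the background peptides, plants the motifs, deduplicates, and scans
#' the final peptide list for every occurrence of every planted motif
#' (including chance occurrences created by the background or by other
#' insertions). The scan is an independent sliding-window comparison, so it
#' can serve as ground truth for the matcher.
#'
#' @param spec A [synthetic_spec()].
#' @param sample,fraction Labels for the generated peptidome.
#' @return A list with elements:
#'   * `peptidome` — the generated [peptidome()];
#'   * `ground_truth` — a list with `occurrences` (tibble: `sequence`,
#'     `motif`, `offsets` list-column of 0-based starts, `n_occurrences`)
#'     and `per_motif` (tibble: `motif`, `n_peptides`, `total_hits`; planted
#'     motifs with zero surviving occurrences keep a zero row).
#' @export
#' @examples
#' sim <- generate_peptidome(synthetic_spec(50, planted = c(GP = 10), seed = 7))
#' sim$ground_truth$per_motif
generate_peptidome <- function(spec, sample = "synthetic",
                               fraction = "other") {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(spec$seed)
  motifs <- names(spec$planted)
  if (spec$n_peptides == 0L) {
    return(list(
      peptidome = peptidome(character(), sample, fraction),
      ground_truth = list(
        occurrences = tibble(sequence = character(), motif = character(),
                             offsets = list(), n_occurrences = integer()),
        per_motif = tibble(motif = motifs, n_peptides = 0L,
                           total_hits = 0L))))
  }
  lens <- sample(spec$min_length:spec$max_length, spec$n_peptides,
                 replace = TRUE)
  seqs <- vapply(lens, function(l) {
    paste(sample(AA_ALPHABET, l, replace = TRUE,
                 prob = spec$aa_frequencies), collapse = "")
  }, character(1))
  # plant by overwriting a random stretch of a random peptide (length kept)
  for (m in motifs) {
    k <- nchar(m)
    eligible <- which(lens >= k)
    if (length(eligible) == 0L) {
      stop("no generated peptide can hold planted motif ", m)
    }
    n_insert <- spec$planted[[m]]
    if (n_insert == 0L) next
    at <- sample(eligible, n_insert, replace = TRUE)
    for (i in at) {
      off <- sample.int(lens[i] - k + 1L, 1L)
      substr(seqs[i], off, off + k - 1L) <- m
    }
  }
  p <- suppressMessages(peptidome(seqs, sample, fraction))
  list(peptidome = p, ground_truth = scan_ground_truth(p, motifs))
}

# Independent occurrence scan: for each motif, compare every window of every
# unique peptide by direct substring slicing. Intentionally avoids the
# matcher's search machinery.
scan_ground_truth <- function(p, motifs) {
  useq <- unique(p$sequence)
  rows <- list()
  per_n_pep <- setNames(integer(length(motifs)), motifs)
  per_hits <- setNames(integer(length(motifs)), motifs)
  for (m in motifs) {
    k <- nchar(m)
    for (s in useq) {
      n <- nchar(s)
      if (k >= n) next   # cryptide containment must be proper
      starts <- seq_len(n - k + 1L)
      hit <- substring(s, starts, starts + k - 1L) == m
      if (any(hit)) {
        offs <- as.integer(starts[hit] - 1L)
        rows[[length(rows) + 1L]] <-
          tibble(sequence = s, motif = m, offsets = list(offs),
                 n_occurrences = length(offs))
        per_n_pep[m] <- per_n_pep[m] + 1L
        per_hits[m] <- per_hits[m] + length(offs)
      }
    }
  }
  occurrences <- if (length(rows) > 0L) {
    out <- do.call(rbind, rows)
    out[order(out$sequence, out$motif), , drop = FALSE]
  } else {
    tibble(sequence = character(), motif = character(), offsets = list(),
           n_occurrences = integer())
  }
  list(occurrences = occurrences,
       per_motif = tibble(motif = motifs,
                          n_peptides = unname(per_n_pep),
                          total_hits = unname(per_hits)))
}

#' Build a small database from motif/activity pairs
#'
#' Convenience constructor for validation databases: duplicate sequences are
#' merged with the union of their activities.
#'
#' @param motifs A named list mapping sequence to a character vector of
#'   activities, e.g. `list(GP = c("ACE inhibitor", "antiamnestic"))`.
#' @param source Provenance tag for all entries.
#' @return A [bioactive_db()].
#' @export
generate_db <- function(motifs, source = "synthetic") {
  if (length(motifs) == 0L) return(bioactive_db())
  seqs <- rep(names(motifs), lengths(motifs))
  acts <- unlist(motifs, use.names = FALSE)
  bioactive_db(seqs, name = names(motifs)[match(seqs, names(motifs))],
               activity = acts, source = source)
}

#' Write a simulation to files
#'
#' Emits the generated peptidome as FASTA, the validation database as TSV,
#' and the ground truth as JSON, for use outside R.
#'
#' @param spec A [synthetic_spec()].
#' @param db A [bioactive_db()] to write alongside (e.g. [generate_db()] of
#'   the planted motifs); `NULL` to skip.
#' @param out_dir Output directory (created if needed).
#' @param sample,fraction Labels for the peptidome.
#' @return Invisibly, the named vector of written paths.
#' @export
simulate_to_files <- function(spec, out_dir, db = NULL,
                              sample = "synthetic", fraction = "other") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_peptidome(spec, sample, fraction)
  paths <- c(peptidome = file.path(out_dir, "peptidome.fasta"),
             ground_truth = file.path(out_dir, "ground_truth.json"))
  write_peptidome_fasta(sim$peptidome, paths[["peptidome"]])
  gt <- sim$ground_truth
  jsonlite::write_json(
    list(per_motif = gt$per_motif,
         occurrences = gt$occurrences[c("sequence", "motif", "offsets",
                                        "n_occurrences")]),
    paths[["ground_truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(db)) {
    paths <- c(paths, db = file.path(out_dir, "database.tsv"))
    write_bioactive_db(db, paths[["db"]])
  }
  invisible(paths)
}
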