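#' Positional cleavage rules
#'
#' Protease specificity is expressed as positional-constraint rules around
#' the scissile bond, in P4..P1 / P1'..P4' nomenclature (offsets -4..-1 for
#' the N-terminal side, +1..+4 for the C-terminal side). Each rule is a set
#' of constraints, one per position, of type `allowed` (the residue must be
#' in the set) or `forbidden` (it must not be). A bond is a predicted
#' cleavage site when at least one rule is fully satisfied. Positions falling
#' outside the sequence near a terminus satisfy `forbidden` constraints and
#' fail `allowed` constraints.
#'
#' Rule tables are data, not code: they ship as a TSV with columns `enzyme`,
#' `rule_id`, `position`, `constraint_type`, `residues` and can be audited or
#' swapped without touching the engine. The packaged table encodes pepsin at
#' pH > 2, which cleaves next to the bulky hydrophobic residues F, L, W and Y
#' with proline and positively charged neighbours blocking cleavage:
#' structurally, a bond is cut when either P1 is one of F/L/W/Y with P1' not
#' proline and P2 not H/K/R, or P1' is one of F/L/W/Y with P1 not proline,
#' P2 not H/K/R and P2' not proline.
#'
#' @param enzyme Enzyme name; the packaged table defines `"pepsin_pH_gt2"`.
#' @param path Optional path to a custom rule table in the same format.
#' @return A `cleavage_rule_set`: list with elements `enzyme` and `rules`
#'   (a named list of data frames with columns `position`, `constraint_type`,
#'   `residues`).
#' @export
#' @examples
#' rules <- pepsin_rules()
#' find_cleavage_sites("AAFAA", rules)   # both sides of the F
cleavage_rules <- function(enzyme = "pepsin_pH_gt2", path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cleavage_rules.tsv",
                        package = "cryptides", mustWork = TRUE)
  }
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  required <- c("enzyme", "rule_id", "position", "constraint_type", "residues")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop("rule table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  tab <- tab[tab$enzyme == enzyme, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no rules for enzyme: ", enzyme)
  tab$position <- as.integer(tab$position)
  if (any(abs(tab$position) > 4L | tab$position == 0L)) {
    stop("rule positions must lie in -4..-1 or 1..4")
  }
  if (!all(tab$constraint_type %in% c("allowed", "forbidden"))) {
    stop("constraint_type must be 'allowed' or 'forbidden'")
  }
  rules <- lapply(split(tab, tab$rule_id), function(r) {
    data.frame(position = r$position, constraint_type = r$constraint_type,
               residues = toupper(r$residues), stringsAsFactors = FALSE)
  })
  structure(list(enzyme = enzyme, rules = rules),
            class = "cleavage_rule_set")
}

#' @rdname cleavage_rules
#' @export
pepsin_rules <- function() cleavage_rules("pepsin_pH_gt2")

#' Digestion parameters
#'
#' The missed-cleavage and fragment-length window applied after fragment
#' enumeration. Defaults are the gastric-digestion screening settings used
#' throughout the package: at most 3 missed cleavages and fragments of 2-13
#' residues.
#'
#' @param max_missed Maximum internal (uncut) cleavage sites per fragment.
#' @param min_len,max_len Fragment residue-count window.
#' @return A `digest_params` list.
#' @export
digest_params <- function(max_missed = 3L, min_len = 2L, max_len = 13L) {
  max_missed <- as.integer(max_missed)
  min_len <- as.integer(min_len)
  max_len <- as.integer(max_len)
  if (max_missed < 0L) stop("max_missed must be >= 0")
  if (min_len < 1L || min_len > max_len) {
    stop("need 1 <= min_len <= max_len")
  }
  structure(list(max_missed = max_missed, min_len = min_len,
                 max_len = max_len), class = "digest_params")
}

#' Predict cleavage sites in a sequence
#'
#' Bond `i` (1-based, `i` in `1..nchar(seq)-1`) is the peptide bond after
#' residue `i`; the terminal "bonds" before the first and after the last
#' residue are never sites. A bond is reported when at least one rule of the
#' set is satisfied (see [cleavage_rules()] for the window semantics at
#' termini).
#'
#' @param seq A single amino-acid sequence (length >= 2).
#' @param rules A `cleavage_rule_set`.
#' @return Sorted integer vector of bond indices.
#' @export
find_cleavage_sites <- function(seq, rules = pepsin_rules()) {
  stopifnot(inherits(rules, "cleavage_rule_set"), length(seq) == 1L)
  seq <- normalize_sequence(seq)
  res <- strsplit(seq, "")[[1]]
  bad <- which(!res %in% AA_ALPHABET)
  if (length(bad) > 0L) {
    stop("invalid residue '", res[bad[1]], "' at position ", bad[1])
  }
  n <- length(res)
  if (n < 2L) stop("sequence must have at least 2 residues")
  sites <- integer(0)
  for (i in seq_len(n - 1L)) {
    for (rule in rules$rules) {
      ok <- TRUE
      for (k in seq_len(nrow(rule))) {
        o <- rule$position[k]
        idx <- if (o < 0L) i + o + 1L else i + o
        set <- strsplit(rule$residues[k], "")[[1]]
        inside <- idx >= 1L && idx <= n
        pass <- if (rule$constraint_type[k] == "allowed") {
          inside && res[idx] %in% set
        } else {
          !inside || !(res[idx] %in% set)
        }
        if (!pass) { ok <- FALSE; break }
      }
      if (ok) { sites <- c(sites, i); break }
    }
  }
  sites
}

#' Enumerate digestion fragments
#'
#' Fragments are exactly the substrings whose boundaries are cleavage sites
#' or the parent's termini, that span at most `max_missed` internal sites,
#' filtered to the `min_len..max_len` residue window. For `k` sites and
#' missed-cleavage limit `m`, the pre-filter fragment count is
#' `sum_{j=0..min(m,k)} (k+1-j)`; the zero-missed fragments concatenate in
#' order to reconstruct the parent. Positions are 0-based half-open, so
#' identical subsequences at different loci are distinct fragments.
#'
#' @param seq Parent amino-acid sequence.
#' @param rules A `cleavage_rule_set`.
#' @param params A [digest_params()].
#' @return A tibble with columns `parent`, `start`, `end`, `sequence`,
#'   `n_missed`, ordered by (start, end).
#' @export
#' @examples
#' digest_sequence("VVYPWTQ")   # one site after the W
digest_sequence <- function(seq, rules = pepsin_rules(),
                            params = digest_params()) {
  stopifnot(inherits(params, "digest_params"))
  seq <- normalize_sequence(seq)
  sites <- find_cleavage_sites(seq, rules)
  n <- nchar(seq)
  bounds <- c(0L, sites, n)
  nb <- length(bounds)
  a <- rep(seq_len(nb - 1L), times = (nb - 1L):1L)
  b <- unlist(lapply(seq_len(nb - 1L), function(i) (i + 1L):nb))
  n_missed <- b - a - 1L
  keep <- n_missed <= params$max_missed
  start <- bounds[a[keep]]
  end <- bounds[b[keep]]
  n_missed <- n_missed[keep]
  len <- end - start
  keep2 <- len >= params$min_len & len <= params$max_len
  start <- start[keep2]
  end <- end[keep2]
  frag_seq <- if (length(start) > 0L) substring(seq, start + 1L, end)
              else character()
  out <- tibble(parent = rep_len(seq, length(start)), start = start,
                end = end, sequence = frag_seq,
                n_missed = n_missed[keep2])
  out[order(out$start, out$end), , drop = FALSE]
}

#' Does a peptide survive digestion intact?
#'
#' TRUE when the full peptide appears among its own digestion fragments,
#' i.e. its internal cleavage-site count is within the missed-cleavage limit
#' and its length within the fragment window.
#'
#' @param peptide Character vector of peptide sequences (vectorized).
#' @inheritParams digest_sequence
#' @return Logical vector.
#' @export
#' @examples
#' survives_digestion(c("LVVYPW", "LVVYPWTQ", "VVYPWTQ"))
survives_digestion <- function(peptide, rules = pepsin_rules(),
                               params = digest_params()) {
  stopifnot(inherits(params, "digest_params"))
  vapply(peptide, function(p) {
    p <- normalize_sequence(p)
    len <- nchar(p)
    if (len < params$min_len || len > params$max_len) return(FALSE)
    if (len < 2L) return(TRUE)   # a single residue has no internal bond
    length(find_cleavage_sites(p, rules)) <= params$max_missed
  }, logical(1), USE.NAMES = FALSE)
}

#' Can a target peptide be released by digesting a parent?
#'
#' TRUE when the target's sequence equals some fragment of
#' `digest_sequence(parent, ...)`. A target that is not a substring of the
#' parent simply returns FALSE. When `target == parent` this reduces to
#' [survives_digestion()].
#'
#' @param target Target peptide sequence (single string).
#' @param parent Parent sequence to digest (single string).
#' @inheritParams digest_sequence
#' @return Single logical.
#' @export
released_by_digestion <- function(target, parent, rules = pepsin_rules(),
                                  params = digest_params()) {
  target <- normalize_sequence(target)
  parent <- normalize_sequence(parent)
  if (!grepl(target, parent, fixed = TRUE)) return(FALSE)
  frags <- digest_sequence(parent, rules, params)
  target %in% frags$sequence
}
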