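# Three-criterion screen of residues differing between two ancestral
# receptor sequences, to nominate columns for chimeric/point-mutant
# receptors: (a) radical physicochemical change, (b) BLOSUM62 score <= 0,
# (c) conservation of the younger ancestor's residue across all extant
# sequences.

# cache for the 20x20 standard BLOSUM62 block
.blosum_env <- new.env(parent = emptyenv())

blosum62_matrix <- function() {
  if (is.null(.blosum_env$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosum_env$m <- e$BLOSUM62[CANONICAL_AA, CANONICAL_AA]
  }
  .blosum_env$m
}

#' BLOSUM62 substitution score
#'
#' @param aa1,aa2 single canonical amino-acid letters.
#' @return integer score from the standard BLOSUM62 matrix.
#' @export
blosum62_score <- function(aa1, aa2) {
  check_aa(aa1); check_aa(aa2)
  as.integer(blosum62_matrix()[aa1, aa2])
}

check_aa <- function(aa) {
  if (!is_string(aa) || !aa %in% CANONICAL_AA) {
    stop2("'", aa, "' is not a canonical amino-acid letter")
  }
}

#' Classify an amino-acid substitution
#'
#' A substitution is *radical* when the two residues fall in different
#' physicochemical classes under the partition hydrophobic (AVLIMFWY),
#' polar (STNQ), positive (KRH), negative (DE), special (GCP); the class
#' map is configurable so alternative radical-change definitions can be
#' swapped in. The BLOSUM62 score measures how often the substitution is
#' observed in homologous proteins (<= 0 means relatively infrequent).
#'
#' @param aa1,aa2 distinct canonical amino-acid letters.
#' @param class_map named character vector mapping residues to class
#'   labels; defaults to the partition above.
#' @return list with `radical` (logical) and `blosum` (integer).
#' @export
classify_substitution <- function(aa1, aa2, class_map = AA_CLASSES) {
  check_aa(aa1); check_aa(aa2)
  if (aa1 == aa2) stop2("classify_substitution needs two distinct residues")
  list(radical = unname(class_map[aa1] != class_map[aa2]),
       blosum = blosum62_score(aa1, aa2))
}

#' Check evolutionary conservation of an alignment column
#'
#' TRUE iff every extant residue equals the reference state; gaps in the
#' extant sequences count as mismatches.
#'
#' @param column_states character vector of extant residues (may include
#'   `"-"`).
#' @param reference_state single reference residue.
#' @return logical.
#' @export
conservation_check <- function(column_states, reference_state) {
  if (length(column_states) == 0L) stop2("empty extant column")
  check_aa(reference_state)
  all(column_states == reference_state)
}

split_seq <- function(x) strsplit(toupper(x), "")[[1]]

#' Screen ancestral sequence differences for chimera candidates
#'
#' Walks the alignment columns where the two ancestral sequences differ
#' and evaluates the three candidate criteria at each: radical
#' physicochemical change, BLOSUM62 score of 0 or below, and conservation
#' of `anc2`'s residue across all extant sequences. Columns where either
#' ancestor has a gap are skipped (an indel column cannot be nominated as
#' a point mutation) and counted.
#'
#' @param anc1,anc2 aligned ancestral protein sequences (strings of equal
#'   length).
#' @param extant_alignment character vector (or `Biostrings::AAStringSet`)
#'   of aligned extant sequences, same length.
#' @param domain_ranges optional named list of `c(start, end)` 1-based
#'   inclusive column intervals (e.g. VFT/CRD/TMD); must be disjoint.
#'   Columns outside every range get domain `"unassigned"`.
#' @param require which criteria `passes_all` must satisfy; subset of
#'   `c("radical", "blosum", "conserved")` (default all three).
#' @param class_map residue class map for the radical criterion.
#' @return data.frame of class `chimera_screen`, sorted by column, with
#'   columns `column`, `domain`, `res_anc1`, `res_anc2`, `radical`,
#'   `blosum`, `conserved`, `passes_all`; attribute `n_gap_columns`
#'   counts skipped ancestral-gap columns.
#' @export
screen_candidates <- function(anc1, anc2, extant_alignment,
                              domain_ranges = NULL,
                              require = c("radical", "blosum", "conserved"),
                              class_map = AA_CLASSES) {
  require <- match.arg(require, several.ok = TRUE)
  if (inherits(extant_alignment, "AAStringSet")) {
    extant_alignment <- as.character(extant_alignment)
  }
  s1 <- split_seq(anc1); s2 <- split_seq(anc2)
  ext <- lapply(extant_alignment, split_seq)
  L <- length(s1)
  if (length(s2) != L || any(lengths(ext) != L)) {
    stop2("aligned sequences differ in length")
  }
  domain_of <- rep("unassigned", L)
  if (!is.null(domain_ranges)) {
    covered <- integer(0)
    for (nm in names(domain_ranges)) {
      rg <- domain_ranges[[nm]]
      idx <- seq(rg[1], rg[2])
      if (length(intersect(idx, covered))) {
        stop2("overlapping domain ranges at '", nm, "'")
      }
      covered <- c(covered, idx)
      domain_of[idx] <- nm
    }
  }
  ext_mat <- do.call(rbind, ext)
  diff_cols <- which(s1 != s2)
  gap_cols <- diff_cols[s1[diff_cols] == "-" | s2[diff_cols] == "-"]
  diff_cols <- setdiff(diff_cols, gap_cols)
  rows <- lapply(diff_cols, function(j) {
    cls <- classify_substitution(s1[j], s2[j], class_map = class_map)
    conserved <- if (length(ext)) all(ext_mat[, j] == s2[j]) else NA
    flags <- c(radical = cls$radical, blosum = cls$blosum <= 0,
               conserved = isTRUE(conserved))
    data.frame(column = j, domain = domain_of[j],
               res_anc1 = s1[j], res_anc2 = s2[j],
               radical = cls$radical, blosum = cls$blosum,
               conserved = conserved,
               passes_all = all(flags[require]),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(column = integer(0), domain = character(0),
               res_anc1 = character(0), res_anc2 = character(0),
               radical = logical(0), blosum = integer(0),
               conserved = logical(0), passes_all = logical(0))
  rownames(out) <- NULL
  attr(out, "n_gap_columns") <- length(gap_cols)
  class(out) <- c("chimera_screen", "data.frame")
  out
}
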