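# File input: Newick trees, plate CSVs, bout CSVs, FASTA alignments.

#' Read a rooted Newick tree with branch lengths
#'
#' Wraps `ape::read.tree` with the validation the trait methods need:
#' labelled unique tips and a branch length on every edge.
#'
#' @param path Newick file.
#' @return a rooted `phylo` tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop2("tree file not found: ", path)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop2("could not parse Newick in ", path)
  if (is.null(tree$tip.label) || any(!nzchar(tree$tip.label))) {
    stop2("tree has unlabeled tips")
  }
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) {
    stop2("duplicate tip label(s): ", paste(dup, collapse = ", "))
  }
  if (is.null(tree$edge.length) || anyNA(tree$edge.length) ||
      length(tree$edge.length) != nrow(tree$edge)) {
    stop2("tree in ", path, " lacks branch lengths on some edges; ",
          "Brownian-motion methods require them")
  }
  tree
}

#' Write a tree as Newick
#'
#' @param tree `phylo` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

PLATE_SCHEMA <- c("receptor_id", "ligand_1", "conc_1_mM", "ligand_2",
                  "conc_2_mM", "replicate", "batch", "response")

#' Read plate-assay records from CSV
#'
#' Expected header: `receptor_id, ligand_1, conc_1_mM, ligand_2,
#' conc_2_mM, replicate, batch, response`. Blank ligand fields denote a
#' no-ligand control well (both blank) or a single-ligand mix (`ligand_2`
#' blank). Non-numeric responses or concentrations are reported with
#' their line number.
#'
#' @param path CSV file (comma-separated, UTF-8, header required).
#' @return plate-record data.frame (as from [simulate_plate_data()]).
#' @export
read_plate_csv <- function(path) {
  if (!file.exists(path)) stop2("plate CSV not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  na.strings = character(0))
  if (!identical(names(raw), PLATE_SCHEMA)) {
    stop2("plate CSV header must be exactly: ",
          paste(PLATE_SCHEMA, collapse = ","))
  }
  blank <- function(v) !nzchar(trimws(v))
  num <- function(col) {
    v <- trimws(raw[[col]])
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!blank(v) & is.na(out))
    if (length(bad)) {
      stop2("non-numeric ", col, " at line ", bad[1] + 1L, ": '",
            v[bad[1]], "'")
    }
    out
  }
  out <- data.frame(
    receptor_id = raw$receptor_id,
    ligand_1 = ifelse(blank(raw$ligand_1), NA_character_, raw$ligand_1),
    conc_1_mM = num("conc_1_mM"),
    ligand_2 = ifelse(blank(raw$ligand_2), NA_character_, raw$ligand_2),
    conc_2_mM = num("conc_2_mM"),
    replicate = num("replicate"),
    batch = num("batch"),
    response = num("response"),
    stringsAsFactors = FALSE)
  bad_resp <- which(is.na(out$response))
  if (length(bad_resp)) {
    stop2("missing response at line ", bad_resp[1] + 1L)
  }
  mismatch <- which(is.na(out$ligand_1) != is.na(out$conc_1_mM) |
                      is.na(out$ligand_2) != is.na(out$conc_2_mM))
  if (length(mismatch)) {
    stop2("ligand named without concentration (or vice versa) at line ",
          mismatch[1] + 1L)
  }
  out
}

#' Write plate records to CSV
#'
#' Inverse of [read_plate_csv()] (blank fields for NA ligands).
#'
#' @param records plate-record data.frame.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(records, path) {
  out <- records[, PLATE_SCHEMA]
  write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE,
              na = "")
  invisible(path)
}

#' Read frame-scored bout events from CSV
#'
#' Expected header: `stimulus, start_frame, end_frame`.
#'
#' @param path CSV file.
#' @return data.frame suitable for [extract_bouts()].
#' @export
read_bouts_csv <- function(path) {
  if (!file.exists(path)) stop2("bouts CSV not found: ", path)
  out <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("stimulus", "start_frame", "end_frame")
  if (!all(need %in% names(out))) {
    stop2("bouts CSV needs columns ", paste(need, collapse = ", "))
  }
  for (col in c("start_frame", "end_frame")) {
    if (!is.numeric(out[[col]])) {
      stop2("non-numeric ", col, " in ", path)
    }
  }
  out
}

#' Read an aligned protein FASTA
#'
#' @param path FASTA file of equal-length aligned protein sequences.
#' @return named character vector of sequences.
#' @export
read_alignment_fasta <- function(path) {
  if (!file.exists(path)) stop2("alignment FASTA not found: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  out <- setNames(as.character(seqs), names(seqs))
  if (length(unique(nchar(out))) != 1L) {
    stop2("sequences in ", path, " are not aligned (unequal lengths)")
  }
  out
}

#' Write an aligned protein FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(seqs, path) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  invisible(path)
}
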