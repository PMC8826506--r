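#' Define a ligand panel
#'
#' A panel is the set of ligands presented to a receptor, each with a class
#' (sugar, sweetener, amino acid, or control) and the concentration at which
#' it is tested by default.
#'
#' @param name character vector of ligand names (unique).
#' @param ligand_class character vector, one of `"sugar"`, `"sweetener"`,
#'   `"amino_acid"`, `"control"`.
#' @param default_concentration numeric vector, mM; must be positive for
#'   non-control ligands.
#' @return A `data.frame` of class `ligand_panel` with columns `name`,
#'   `ligand_class`, `default_concentration`.
#' @seealso [default_ligand_panel()]
#' @export
ligand_panel <- function(name, ligand_class, default_concentration) {
  classes <- c("sugar", "sweetener", "amino_acid", "control")
  if (anyDuplicated(name)) {
    stop2("ligand names must be unique within a panel: ",
          paste(unique(name[duplicated(name)]), collapse = ", "))
  }
  if (!all(ligand_class %in% classes)) {
    stop2("unknown ligand_class; must be one of ",
          paste(classes, collapse = ", "))
  }
  non_control <- ligand_class != "control"
  if (any(!is.finite(default_concentration[non_control])) ||
      any(default_concentration[non_control] <= 0)) {
    stop2("default_concentration must be > 0 for non-control ligands")
  }
  out <- data.frame(name = as.character(name),
                    ligand_class = as.character(ligand_class),
                    default_concentration = as.numeric(default_concentration),
                    stringsAsFactors = FALSE)
  class(out) <- c("ligand_panel", "data.frame")
  out
}

#' Standard hummingbird taste-assay ligand panel
#'
#' The carbohydrate and amino-acid panel used for heterologous T1R1-T1R3
#' assays: sugars and the amino acids alanine, serine, glycine, arginine,
#' methionine, valine and proline at 100 mM; all other amino acids at 50 mM
#' except leucine at 25 mM; sucralose (the normalization reference) at
#' 100 mM.
#'
#' @return A [ligand_panel()] data frame.
#' @export
default_ligand_panel <- function() {
  sugars <- c("ribose", "glucose", "mannose", "melibiose", "xylose",
              "galactose", "trehalose", "raffinose", "maltose",
              "melezitose", "arabinose", "fructose", "sucrose")
  aa_100 <- c("alanine", "serine", "glycine", "arginine", "methionine",
              "valine", "proline")
  aa_50 <- c("histidine", "glutamine", "asparagine", "threonine", "lysine",
             "phenylalanine", "tryptophan", "isoleucine", "glutamate",
             "aspartate", "cysteine", "tyrosine")
  ligand_panel(
    name = c(sugars, "sucralose", aa_100, aa_50, "leucine"),
    ligand_class = c(rep("sugar", length(sugars)), "sweetener",
                     rep("amino_acid", length(aa_100) + length(aa_50) + 1L)),
    default_concentration = c(rep(100, length(sugars)), 100,
                              rep(100, length(aa_100)),
                              rep(50, length(aa_50)), 25)
  )
}
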