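# A self-contained demo dataset: all four pipeline inputs written from the
# synthetic generators, plus a matching config.

#' Write a complete synthetic input set for the pipeline
#'
#' Generates and writes the four input files [run_pipeline()] needs —
#' plate CSV, Newick tree, ancestral-pair protein alignment, bout CSV —
#' for a small panel (three sugars, sucralose, four amino acids) over six
#' receptor "species" on a simulated rate-heterogeneous tree. Receptors
#' grade from strongly sugar-biased to amino-acid-retaining, one
#' sucrose + alanine mix carries planted synergy, and the alignment
#' plants one column passing all three chimera criteria. Returns a config
#' list ready for [run_pipeline()].
#'
#' @param dir directory to write into (created if needed).
#' @param seed integer seed.
#' @return config list (see [validate_config()]), invisibly.
#' @export
write_demo_inputs <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(seed))
  tree <- simulate_tree(6, seed = seed + 1L, rate_sd = 0.3)
  species <- tree$tip.label
  panel <- ligand_panel(
    name = c("sucrose", "fructose", "glucose", "sucralose",
             "alanine", "serine", "proline", "histidine"),
    ligand_class = c("sugar", "sugar", "sugar", "sweetener",
                     rep("amino_acid", 4)),
    default_concentration = c(100, 100, 100, 100, 100, 100, 100, 50))
  # amino-acid responsiveness declines across species; sugars strong in all
  amino_frac <- seq(0.9, 0.05, length.out = length(species))
  params <- setNames(lapply(seq_along(species), function(i) {
    receptor_params(
      ligands = data.frame(
        ligand = panel$name,
        E_max = c(400, 320, 280, 450,
                  amino_frac[i] * c(300, 260, 0, 120)),
        EC50 = c(30, 35, 40, 5, 40, 45, 50, 60),
        h = 1.5),
      B = 5,
      synergy = data.frame(ligand_a = "sucrose", ligand_b = "alanine",
                           gamma = if (i <= 2) 150 else 0),
      batch_scale_sd = 0.2, noise_sd = 12)
  }), species)
  mixes <- c(lapply(seq_len(nrow(panel)), function(i) {
    setNames(panel$default_concentration[i], panel$name[i])
  }), list(numeric(0), c(alanine = 25), c(sucrose = 100, alanine = 25)))
  records <- simulate_plate_data(panel, params, n_replicates = 6,
                                 n_batches = 2, seed = seed + 2L,
                                 mixes = mixes)
  fix <- simulate_alignment_fixture(
    n_extant = length(species), length = 60,
    planted_sites = list(
      list(pos = 12, anc1 = "D", anc2 = "K", extant = "K"),
      list(pos = 30, anc1 = "I", anc2 = "V", extant = "V"),
      list(pos = 47, anc1 = "S", anc2 = "T", extant = "T")),
    seed = seed + 3L)
  bouts <- simulate_bouts(c("sucrose", "fructose", "water"),
                          mix_weights = c(0.5, 0.2, 0.05),
                          n_bouts = 150, fps = 60, seed = seed + 4L)
  events <- do.call(rbind, lapply(bouts, function(b) {
    frames <- round(b$durations * b$fps)
    start <- cumsum(c(1, frames[-length(frames)] + 30))
    data.frame(stimulus = b$stimulus_id, start_frame = start,
               end_frame = start + frames)
  }))
  rownames(events) <- NULL

  paths <- list(plate_csv = file.path(dir, "plate.csv"),
                tree_newick = file.path(dir, "tree.nwk"),
                alignment_fasta = file.path(dir, "alignment.fasta"),
                bouts_csv = file.path(dir, "bouts.csv"))
  write_plate_csv(records, paths$plate_csv)
  write_newick(tree, paths$tree_newick)
  seqs <- c(anc1 = fix$anc1, anc2 = fix$anc2,
            setNames(fix$extant, species))
  write_alignment_fasta(seqs, paths$alignment_fasta)
  write.table(events, paths$bouts_csv, sep = ",", row.names = FALSE,
              quote = FALSE)
  config <- c(paths, list(
    out_dir = file.path(dir, "out"), seed = as.integer(seed),
    domain_ranges = list(VFT = c(1, 40), CRD = c(41, 50), TMD = c(51, 60)),
    bout_pairs = list(c("sucrose", "water"), c("fructose", "water"),
                      c("sucrose", "fructose"))))
  invisible(config)
}
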