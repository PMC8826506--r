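# One simulated synergy experiment: sugar + amino acid singles, their mix,
# and untransfected no-ligand controls, with planted interaction gamma.
synergy_records <- function(gamma, seed, noise_sd = 10, n = 6,
                            amino_EC50 = 40, amino_conc = 100,
                            amino_Emax = 150, extra_mix_conc = NULL) {
  panel <- ligand_panel(c("sucrose", "alanine"), c("sugar", "amino_acid"),
                        c(100, amino_conc))
  params <- list(R1 = receptor_params(
    ligands = data.frame(ligand = c("sucrose", "alanine"),
                         E_max = c(300, amino_Emax), EC50 = c(30, amino_EC50),
                         h = 1.5),
    B = 20,
    synergy = data.frame(ligand_a = "sucrose", ligand_b = "alanine",
                         gamma = gamma),
    batch_scale_sd = 0, noise_sd = noise_sd))
  concs <- unique(c(amino_conc, extra_mix_conc))
  mixes <- c(list(c(sucrose = 100), numeric(0)),
             lapply(concs, function(cc) c(alanine = cc)),
             lapply(concs, function(cc) c(sucrose = 100, alanine = cc)))
  simulate_plate_data(panel, params, n_replicates = n, n_batches = 1,
                      seed = seed, mixes = mixes, background = 20)
}

# Split a synergy experiment into the four groups test_synergy() takes.
split_groups <- function(rec) {
  rec$mix <- t1revo:::mix_label(rec$ligand_1, rec$conc_1_mM, rec$ligand_2,
                                rec$conc_2_mM)
  tr <- rec[rec$receptor_id == "R1", ]
  list(mix = tr[grepl("\\+", tr$mix), ],
       a = tr[tr$ligand_1 == "alanine" & !is.na(tr$ligand_1) &
                is.na(tr$ligand_2), ],
       s = tr[tr$ligand_1 == "sucrose" & !is.na(tr$ligand_1) &
                is.na(tr$ligand_2), ],
       bg = rec[rec$receptor_id == "UNTRANSFECTED" & rec$mix == "none", ])
}
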