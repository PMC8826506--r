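# End-to-end pipeline: reads the four input files, runs every analysis
# stage, and writes a manifest of TSV/JSON outputs. Reruns with an
# identical config are bit-identical for the deterministic stages.

#' Validate and normalize a pipeline configuration
#'
#' A config is a named list (or a YAML file holding one) with input paths
#' (`plate_csv`, `tree_newick`, `alignment_fasta`, `bouts_csv`), an
#' output directory `out_dir`, and optional analysis settings:
#' `reference_ligand` ("sucralose"), `sugar_set` / `amino_set` (default:
#' panel carbohydrates vs amino acids, sweeteners excluded), `alpha`
#' (0.05, agonist calls), `alpha_synergy` (0.01, panel screen),
#' `ancestor_ids` (`c("anc1", "anc2")`), `domain_ranges`, `bout_pairs`
#' (default: all stimulus pairs), `pca_mode` ("covariance"), `seed` (1).
#'
#' @param config named list or path to a YAML file.
#' @return validated config list.
#' @export
validate_config <- function(config) {
  if (is_string(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop2("config must be a list or a YAML path")
  for (p in c("plate_csv", "tree_newick", "alignment_fasta", "bouts_csv")) {
    if (is.null(config[[p]])) stop2("config is missing '", p, "'")
    if (!file.exists(config[[p]])) {
      stop2("config path '", p, "' does not exist: ", config[[p]])
    }
  }
  if (is.null(config$out_dir)) stop2("config is missing 'out_dir'")
  config$reference_ligand <- config$reference_ligand %||% "sucralose"
  config$alpha <- config$alpha %||% 0.05
  config$alpha_synergy <- config$alpha_synergy %||% 0.01
  config$ancestor_ids <- config$ancestor_ids %||% c("anc1", "anc2")
  config$pca_mode <- config$pca_mode %||% "covariance"
  config$seed <- as.integer(config$seed %||% 1L)
  config
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(config[order(names(config))],
                              auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Stages: read inputs; summarize plate records; agonist calling
#' (Welch one-tailed + Holm per receptor); sucralose-normalized profiles
#' and their grand mean; synergy screen of every two-ligand mix against
#' the additive proxy; response index per receptor, Brownian-motion
#' ancestral states and edge interpolation on the tree; phylogenetic PCA
#' of the profile matrix; chimera-residue screen of the ancestral pair;
#' bout extraction and pairwise KS comparisons. Any stage failure aborts
#' with the stage name; outputs written so far are flagged incomplete in
#' the manifest.
#'
#' @param config see [validate_config()].
#' @return the manifest (named list of output paths plus `config_hash`,
#'   `seed`, `complete`), invisibly.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  logf <- function(...) writeLines(sprintf(...), log_con)
  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   complete = FALSE, outputs = list())
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  stage <- function(name, expr) {
    logf("stage %s: start", name)
    res <- tryCatch(expr, error = function(e) {
      logf("stage %s: FAILED: %s", name, conditionMessage(e))
      write_manifest()
      stop2("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
    logf("stage %s: ok", name)
    res
  }
  emit <- function(key, filename) {
    manifest$outputs[[key]] <<- filename
    file.path(out_dir, filename)
  }
  tsv <- function(df, path) {
    write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }

  records <- stage("read_plate", read_plate_csv(config$plate_csv))
  tree <- stage("read_tree", read_newick(config$tree_newick))
  aln <- stage("read_alignment", read_alignment_fasta(config$alignment_fasta))
  events <- stage("read_bouts", read_bouts_csv(config$bouts_csv))
  logf("inputs: %d wells, %d tips, %d sequences, %d events",
       nrow(records), length(tree$tip.label), length(aln), nrow(events))

  summ <- stage("summarize", summarize_responses(records))
  un <- summ[summ$receptor_id == RECEPTOR_UNTRANSFECTED, , drop = FALSE]
  tr <- summ[summ$receptor_id != RECEPTOR_UNTRANSFECTED, , drop = FALSE]
  calls <- stage("agonists", test_agonists(tr, un, alpha = config$alpha))
  tsv(calls, emit("agonist_calls", "agonist_calls.tsv"))
  logf("agonists: %d calls of %d testable mixes", sum(calls$is_agonist),
       sum(calls$testable))

  receptors <- setdiff(unique(tr$receptor_id), RECEPTOR_UNTRANSFECTED)
  profiles <- stage("profiles", {
    setNames(lapply(receptors, function(r) {
      normalize_profile(tr[tr$receptor_id == r, , drop = FALSE], un,
                        reference_ligand = config$reference_ligand)
    }), receptors)
  })
  prof_df <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(receptor_id = p$receptor_id, ligand = names(p$values),
               value = unname(p$values), stringsAsFactors = FALSE)
  }))
  rownames(prof_df) <- NULL
  tsv(prof_df, emit("normalized_profiles", "normalized_profiles.tsv"))
  if (length(profiles) >= 2) {
    gm <- grand_mean_profile(profiles)
    tsv(gm, emit("grand_mean_profile", "grand_mean_profile.tsv"))
  }

  panel <- default_ligand_panel()
  syn_df <- stage("synergy", synergy_screen(records, panel,
                                            alpha = config$alpha_synergy))
  tsv(syn_df, emit("synergy_report", "synergy_report.tsv"))

  sugar_set <- config$sugar_set %||%
    intersect(panel$name[panel$ligand_class == "sugar"], prof_df$ligand)
  amino_set <- config$amino_set %||%
    intersect(panel$name[panel$ligand_class == "amino_acid"], prof_df$ligand)
  trait <- stage("trait_map", {
    idx <- vapply(profiles[tree$tip.label], response_index, numeric(1),
                  sugar_set = sugar_set, amino_set = amino_set)
    tm <- bm_ancestral_states(tree, idx)
    samples <- edge_trait_interpolation(tm, n_points = 11)
    list(index = idx, map = tm, samples = samples)
  })
  jsonlite::write_json(
    list(index = as.list(trait$index),
         node_states = as.list(trait$map$node_states),
         sigma2 = trait$map$sigma2,
         edge_samples = trait$samples),
    emit("response_index", "response_index.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  pca <- stage("phylo_pca", {
    ligs <- Reduce(intersect, lapply(profiles, function(p) names(p$values)))
    X <- do.call(rbind, lapply(profiles[tree$tip.label],
                               function(p) p$values[ligs]))
    rownames(X) <- tree$tip.label
    colnames(X) <- ligs
    phylo_pca(tree, X, mode = config$pca_mode)
  })
  jsonlite::write_json(
    list(mode = pca$mode, mean = as.list(pca$mean),
         eigenvalues = pca$eigenvalues,
         loadings = apply(pca$loadings, 2, as.list),
         scores = apply(pca$scores, 2, as.list)),
    emit("phylo_pca", "phylo_pca.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  chim <- stage("chimera", {
    anc <- config$ancestor_ids
    absent <- setdiff(anc, names(aln))
    if (length(absent)) {
      stop2("ancestor sequence(s) missing from alignment: ",
            paste(absent, collapse = ", "))
    }
    screen_candidates(aln[[anc[1]]], aln[[anc[2]]],
                      aln[setdiff(names(aln), anc)],
                      domain_ranges = config$domain_ranges)
  })
  tsv(as.data.frame(chim), emit("chimera_candidates",
                                "chimera_candidates.tsv"))
  logf("chimera: %d differing columns, %d pass all criteria, %d gap columns",
       nrow(chim), sum(chim$passes_all), attr(chim, "n_gap_columns"))

  behav <- stage("behavior", {
    samples <- extract_bouts(events, fps = config$fps %||% 60)
    pairs <- config$bout_pairs %||% {
      ids <- names(samples)
      if (length(ids) >= 2) combn(ids, 2, simplify = FALSE) else list()
    }
    compare_stimuli(samples, pairs)
  })
  tsv(behav, emit("behavior_report", "behavior_report.tsv"))

  manifest$complete <- TRUE
  write_manifest()
  logf("pipeline complete: %d outputs", length(manifest$outputs))
  invisible(manifest)
}

# Screen every two-ligand mix present in the records for synergy against
# the additive proxy; sugar/amino roles assigned from the panel classes.
synergy_screen <- function(records, panel, alpha = 0.01) {
  un <- records[records$receptor_id == RECEPTOR_UNTRANSFECTED, , drop = FALSE]
  bg <- un[is.na(un$ligand_1) & is.na(un$ligand_2), , drop = FALSE]
  mixes <- records[!is.na(records$ligand_1) & !is.na(records$ligand_2) &
                     records$receptor_id != RECEPTOR_UNTRANSFECTED, ,
                   drop = FALSE]
  if (nrow(mixes) == 0L) {
    return(data.frame(receptor_id = character(0), sugar = character(0),
                      sugar_mM = numeric(0), amino_acid = character(0),
                      amino_mM = numeric(0), observed_mean = numeric(0),
                      additive_estimate = numeric(0), excess = numeric(0),
                      p = numeric(0), synergistic = logical(0)))
  }
  mixes$mix <- mix_label(mixes$ligand_1, mixes$conc_1_mM, mixes$ligand_2,
                         mixes$conc_2_mM)
  keys <- unique(mixes[, c("receptor_id", "mix")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    g <- mixes[mixes$receptor_id == keys$receptor_id[i] &
                 mixes$mix == keys$mix[i], , drop = FALSE]
    rec <- records[records$receptor_id == keys$receptor_id[i], , drop = FALSE]
    solo <- function(lig, conc) {
      rec[!is.na(rec$ligand_1) & rec$ligand_1 == lig &
            abs(rec$conc_1_mM - conc) < 1e-9 & is.na(rec$ligand_2), ,
          drop = FALSE]
    }
    s1 <- solo(g$ligand_1[1], g$conc_1_mM[1])
    s2 <- solo(g$ligand_2[1], g$conc_2_mM[1])
    if (nrow(s1) < 2L || nrow(s2) < 2L || nrow(bg) < 2L) {
      warning("mix ", keys$mix[i], " skipped: missing solo/background wells",
              call. = FALSE)
      return(NULL)
    }
    cls1 <- panel$ligand_class[match(g$ligand_1[1], panel$name)]
    if (identical(cls1, "sugar")) { ss <- s1; aa <- s2 } else { ss <- s2; aa <- s1 }
    res <- test_synergy(g, aa, ss, bg, alpha = alpha)
    data.frame(receptor_id = keys$receptor_id[i],
               sugar = res$sugar$name, sugar_mM = res$sugar$conc,
               amino_acid = res$amino_acid$name,
               amino_mM = res$amino_acid$conc,
               observed_mean = res$observed_mean,
               additive_estimate = res$additive_estimate,
               excess = res$excess, p = res$p,
               synergistic = res$synergistic, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  out
}

#' Family-wise error rate of agonist calling under a global null
#'
#' Simulates assay panels in which every receptor is dead (all `E_max`
#' zero, no batch effect), so transfected and untransfected wells share
#' one Gaussian distribution, then runs the full agonist-calling path
#' (summaries, Welch one-tailed tests, Holm step-down) on each panel and
#' reports the fraction of panels with at least one adjusted rejection.
#' Holm's procedure bounds this family-wise error rate by `alpha`.
#'
#' @param n_panels number of simulated panels.
#' @param n_mixes ligand mixes per panel.
#' @param n_replicates wells per group.
#' @param alpha family-wise level.
#' @param seed integer seed.
#' @return list: `fwer` (fraction of panels with any call), `n_panels`,
#'   `n_mixes`, `alpha`.
#' @export
fwer_null_simulation <- function(n_panels = 2000, n_mixes = 20,
                                 n_replicates = 6, alpha = 0.05, seed = 1) {
  panel <- ligand_panel(name = sprintf("aa%02d", seq_len(n_mixes)),
                        ligand_class = rep("amino_acid", n_mixes),
                        default_concentration = rep(50, n_mixes))
  params <- list(R1 = receptor_params(
    ligands = data.frame(ligand = panel$name, E_max = 0, EC50 = 50, h = 1),
    B = 20, batch_scale_sd = 0, noise_sd = 10))
  set.seed(as.integer(seed))
  panel_seeds <- sample.int(.Machine$integer.max - 1L, n_panels)
  any_call <- vapply(panel_seeds, function(s) {
    rec <- simulate_plate_data(panel, params, n_replicates = n_replicates,
                               n_batches = 1, seed = s, background = 20)
    summ <- summarize_responses(rec)
    un <- summ[summ$receptor_id == RECEPTOR_UNTRANSFECTED, , drop = FALSE]
    tr <- summ[summ$receptor_id == "R1" & summ$mix != "none", , drop = FALSE]
    calls <- test_agonists(tr, un, alpha = alpha)
    any(calls$is_agonist)
  }, logical(1))
  list(fwer = mean(any_call), n_panels = n_panels, n_mixes = n_mixes,
       alpha = alpha)
}
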