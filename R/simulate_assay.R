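# Synthetic plate-assay generator: Hill-type dose-response per ligand,
# multiplicative per-batch transfection-efficiency scaling, Gaussian well
# noise, optional planted sugar x amino-acid synergy, and the small
# untransfected artifact seen for histidine and very concentrated mixes.

#' Simulation parameters for one receptor
#'
#' Encodes the generative model used by [simulate_plate_data()]: each ligand
#' drives the receptor through a Hill curve `E_max * c^h / (EC50^h + c^h)`
#' on top of a baseline `B`; a sugar/amino-acid pair may carry a synergy
#' coefficient `gamma` (response units) that adds
#' `gamma * min(occupancy_a, occupancy_b)` for mixes; a lognormal
#' transfection-efficiency factor (sd `batch_scale_sd` on the log scale)
#' multiplies all transfected wells of a batch; wells get additive Gaussian
#' noise with sd `noise_sd`.
#'
#' @param ligands data.frame with columns `ligand`, `E_max` (>= 0), `EC50`
#'   (> 0, mM), `h` (Hill coefficient in `[0.5, 10]`).
#' @param B baseline response (response units, >= 0).
#' @param synergy optional data.frame with columns `ligand_a`, `ligand_b`,
#'   `gamma` (>= 0); rows with `gamma = 0` mean no interaction.
#' @param batch_scale_sd sd of the log batch scale (dimensionless, >= 0).
#' @param noise_sd well noise sd (response units, > 0).
#' @return an object of class `receptor_sim_params`.
#' @export
receptor_params <- function(ligands, B = 0, synergy = NULL,
                            batch_scale_sd = 0.25, noise_sd = 10) {
  need <- c("ligand", "E_max", "EC50", "h")
  if (!is.data.frame(ligands) || !all(need %in% names(ligands))) {
    stop2("ligands must be a data.frame with columns ",
          paste(need, collapse = ", "))
  }
  if (anyDuplicated(ligands$ligand)) stop2("duplicate ligand in params")
  if (any(ligands$E_max < 0)) stop2("E_max must be >= 0")
  if (any(ligands$EC50 <= 0)) stop2("EC50 must be > 0")
  if (any(ligands$h < 0.5 | ligands$h > 10)) {
    stop2("Hill coefficient h must be in [0.5, 10]")
  }
  if (B < 0) stop2("baseline B must be >= 0")
  if (batch_scale_sd < 0) stop2("batch_scale_sd must be >= 0")
  if (!is.numeric(noise_sd) || noise_sd <= 0) stop2("noise_sd must be > 0")
  if (!is.null(synergy)) {
    if (!all(c("ligand_a", "ligand_b", "gamma") %in% names(synergy))) {
      stop2("synergy needs columns ligand_a, ligand_b, gamma")
    }
    if (any(synergy$gamma < 0)) stop2("synergy gamma must be >= 0")
  }
  structure(list(ligands = ligands, B = B, synergy = synergy,
                 batch_scale_sd = batch_scale_sd, noise_sd = noise_sd),
            class = "receptor_sim_params")
}

# Fractional receptor occupancy of one ligand at concentration conc (mM).
hill_occupancy <- function(conc, EC50, h) conc^h / (EC50^h + conc^h)

# Deterministic (noise-free, batch-free) response of a receptor to a mix
# given as a named concentration vector; mixes have length 0 (control),
# 1, or 2.
receptor_mean_response <- function(params, mix) {
  y <- params$B
  if (length(mix) == 0L) return(y)
  tab <- params$ligands
  idx <- match(names(mix), tab$ligand)
  if (anyNA(idx)) {
    stop2("no simulation parameters for ligand(s): ",
          paste(names(mix)[is.na(idx)], collapse = ", "))
  }
  occ <- hill_occupancy(unname(mix), tab$EC50[idx], tab$h[idx])
  y <- y + sum(tab$E_max[idx] * occ)
  if (length(mix) == 2L && !is.null(params$synergy)) {
    syn <- params$synergy
    hit <- (syn$ligand_a == names(mix)[1] & syn$ligand_b == names(mix)[2]) |
           (syn$ligand_a == names(mix)[2] & syn$ligand_b == names(mix)[1])
    if (any(hit)) y <- y + syn$gamma[which(hit)[1]] * min(occ)
  }
  y
}

#' Simulate a plate-assay dataset
#'
#' Generates transfected wells for each receptor and mix, plus matched
#' untransfected control wells. Transfected wells follow
#' `batch_scale * (B + sum of Hill terms + synergy term) + noise`;
#' untransfected wells are background plus noise, with a small artifact
#' bump (10% of the largest `E_max` in the panel) added only for histidine
#' and for mixes whose total concentration exceeds 175 mM.
#'
#' @param panel a [ligand_panel()].
#' @param params named list of [receptor_params()], one per receptor id.
#' @param n_replicates replicates per (receptor, mix, batch); >= 2.
#' @param n_batches independent transfection batches; >= 1.
#' @param seed integer seed; identical seeds and inputs reproduce identical
#'   output.
#' @param mixes optional list of named concentration vectors (each length
#'   0-2, at most one sugar and one amino acid). Defaults to every panel
#'   ligand alone at its default concentration plus the no-ligand control.
#' @param background untransfected background level (response units).
#' @param untransfected_noise_sd noise sd for untransfected wells.
#' @return data.frame of well records with columns `receptor_id`,
#'   `ligand_1`, `conc_1_mM`, `ligand_2`, `conc_2_mM`, `replicate`,
#'   `batch`, `response`.
#' @export
simulate_plate_data <- function(panel, params, n_replicates = 6,
                                n_batches = 2, seed = 1, mixes = NULL,
                                background = 20,
                                untransfected_noise_sd = NULL) {
  if (n_replicates < 2) stop2("n_replicates must be >= 2 (tests need variance)")
  if (n_batches < 1) stop2("n_batches must be >= 1")
  if (is.null(names(params)) || any(!nzchar(names(params)))) {
    stop2("params must be a named list keyed by receptor id")
  }
  for (p in params) {
    missing <- setdiff(panel$name[panel$ligand_class != "control"],
                       p$ligands$ligand)
    if (length(missing)) {
      stop2("missing simulation parameters for panel ligand(s): ",
            paste(missing, collapse = ", "))
    }
  }
  if (is.null(mixes)) {
    lig <- panel[panel$ligand_class != "control", ]
    mixes <- c(lapply(seq_len(nrow(lig)), function(i) {
      setNames(lig$default_concentration[i], lig$name[i])
    }), list(numeric(0)))
  }
  for (m in mixes) {
    if (length(m) > 2L) stop2("a mix has at most two ligands")
    if (any(m <= 0)) stop2("mix concentrations must be > 0")
    cls <- panel$ligand_class[match(names(m), panel$name)]
    if (sum(cls == "sugar", na.rm = TRUE) > 1L ||
        sum(cls == "amino_acid", na.rm = TRUE) > 1L) {
      stop2("a mix holds at most one sugar and one amino acid")
    }
  }
  set.seed(as.integer(seed))
  artifact <- 0.1 * max(c(0, vapply(params, function(p) max(p$ligands$E_max),
                                    numeric(1))))
  receptors <- names(params)
  rows <- vector("list", 0)
  # per-receptor, per-batch lognormal transfection-efficiency factor
  batch_scale <- lapply(params, function(p) {
    exp(rnorm(n_batches, mean = 0, sd = p$batch_scale_sd))
  })
  emit <- function(receptor_id, mix, mu, noise_sd, scale_by_batch) {
    for (b in seq_len(n_batches)) {
      s <- if (scale_by_batch) batch_scale[[receptor_id]][b] else 1
      resp <- s * mu + rnorm(n_replicates, 0, noise_sd)
      rows[[length(rows) + 1L]] <<- data.frame(
        receptor_id = receptor_id,
        ligand_1 = if (length(mix) >= 1L) names(mix)[1] else NA_character_,
        conc_1_mM = if (length(mix) >= 1L) unname(mix[1]) else NA_real_,
        ligand_2 = if (length(mix) == 2L) names(mix)[2] else NA_character_,
        conc_2_mM = if (length(mix) == 2L) unname(mix[2]) else NA_real_,
        replicate = seq_len(n_replicates),
        batch = b,
        response = resp,
        stringsAsFactors = FALSE)
    }
  }
  for (r in receptors) {
    for (m in mixes) emit(r, m, receptor_mean_response(params[[r]], m),
                          params[[r]]$noise_sd, scale_by_batch = TRUE)
  }
  un_sd <- untransfected_noise_sd %||%
    min(vapply(params, function(p) p$noise_sd, numeric(1)))
  for (m in mixes) {
    mu <- background
    if ("histidine" %in% names(m) || sum(m) > 175) mu <- mu + artifact
    emit(RECEPTOR_UNTRANSFECTED, m, mu, un_sd, scale_by_batch = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
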