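# Sugar x amino-acid synergy testing against an additive-response proxy.

#' Additive-response proxy for a two-ligand mix
#'
#' The expected response of a mix under no interaction: the sum of each
#' ligand's individual response minus the untransfected no-ligand
#' background (counted once, so the estimate sits on the same raw-signal
#' scale as a single observed well).
#'
#' @param mean_a,mean_s mean responses to each ligand alone.
#' @param background mean untransfected response to no-ligand controls.
#' @return `mean_a + mean_s - background`.
#' @export
additive_estimate <- function(mean_a, mean_s, background) {
  stopifnot(is.finite(mean_a), is.finite(mean_s), is.finite(background))
  mean_a + mean_s - background
}

# Pair single-ligand replicates for the additive pseudo-sample: within each
# batch, match replicates in sorted replicate order; truncate to the
# shorter group with a warning.
pair_replicates <- function(a, s) {
  batches <- union(a$batch, s$batch)
  pairs <- list()
  for (b in batches) {
    av <- a$response[a$batch == b][order(a$replicate[a$batch == b])]
    sv <- s$response[s$batch == b][order(s$replicate[s$batch == b])]
    k <- min(length(av), length(sv))
    if (length(av) != length(sv)) {
      warning(sprintf(
        "batch %s: unequal replicate counts (%d vs %d); paired first %d",
        b, length(av), length(sv), k), call. = FALSE)
    }
    if (k > 0) pairs[[length(pairs) + 1L]] <- cbind(av[seq_len(k)],
                                                    sv[seq_len(k)])
  }
  do.call(rbind, pairs)
}

#' Test a ligand mix for synergy against the additive proxy
#'
#' Builds an additive pseudo-sample by replicate-wise pairing of the two
#' single-ligand samples (within batch, then by sorted replicate order):
#' `a_i + s_i - bg_i`, the background wells paired the same way (when
#' fewer background than paired wells exist, the background mean is
#' subtracted instead). Per-replicate background subtraction keeps the
#' pseudo-sample's replicates independent, so Welch's two-tailed t-test
#' of the observed mix sample against it holds its nominal size; a shared
#' background mean would add variance the test cannot see. The mix is
#' flagged The mix is flagged
#' synergistic only when the test rejects *and* the excess (observed mean
#' minus additive estimate) is positive; significant sub-additive mixes
#' are reported but not flagged.
#'
#'
#' @param mix_records plate records of the mix (two-ligand) wells.
#' @param single_a_records,single_s_records plate records of each ligand
#'   alone (roles are interchangeable).
#' @param background_records untransfected no-ligand control records.
#' @param alpha significance level; default 0.01 (panel screen).
#' @param method `"paired-pseudo"` (default) tests mix wells against the
#'   paired pseudo-sample; `"vs-constant"` tests the mix sample against
#'   the additive estimate as a fixed value (one-sample Welch/t test).
#' @return object of class `synergy_result`.
#' @export
test_synergy <- function(mix_records, single_a_records, single_s_records,
                         background_records, alpha = 0.01,
                         method = c("paired-pseudo", "vs-constant")) {
  method <- match.arg(method)
  for (d in list(mix_records, single_a_records, single_s_records,
                 background_records)) {
    if (nrow(d) < 2L) stop2("each group needs >= 2 replicates")
  }
  bg <- mean(background_records$response)
  mean_a <- mean(single_a_records$response)
  mean_s <- mean(single_s_records$response)
  add_est <- additive_estimate(mean_a, mean_s, bg)
  obs <- mix_records$response
  if (method == "paired-pseudo") {
    pairs <- pair_replicates(single_a_records, single_s_records)
    bg_sorted <- background_records$response[
      order(background_records$batch, background_records$replicate)]
    bg_term <- if (length(bg_sorted) >= nrow(pairs)) {
      bg_sorted[seq_len(nrow(pairs))]
    } else {
      bg
    }
    pseudo <- pairs[, 1] + pairs[, 2] - bg_term
    if (length(pseudo) < 2L) stop2("fewer than 2 paired pseudo-replicates")
    p <- stats::t.test(obs, pseudo, alternative = "two.sided",
                       var.equal = FALSE)$p.value
    n_comp <- length(pseudo)
  } else {
    p <- stats::t.test(obs, mu = add_est, alternative = "two.sided")$p.value
    n_comp <- min(nrow(single_a_records), nrow(single_s_records))
  }
  excess <- mean(obs) - add_est
  lab <- function(d) {
    list(name = d$ligand_1[1],
         conc = d$conc_1_mM[1])
  }
  structure(list(
    sugar = lab(single_s_records), amino_acid = lab(single_a_records),
    observed_mean = mean(obs), additive_estimate = add_est,
    excess = excess, p = p, n_obs = length(obs), n_components = n_comp,
    alpha = alpha, method = method,
    synergistic = (p < alpha) && (excess > 0)),
    class = "synergy_result")
}

#' @export
print.synergy_result <- function(x, ...) {
  cat(sprintf(
    "Synergy test %s@%g + %s@%g mM: observed %.3g vs additive %.3g (excess %.3g), p = %.3g -> %s\n",
    x$sugar$name, x$sugar$conc, x$amino_acid$name, x$amino_acid$conc,
    x$observed_mean, x$additive_estimate, x$excess, x$p,
    if (x$synergistic) "SYNERGISTIC" else "not synergistic"))
  invisible(x)
}

#' Synergy dose profile along an amino-acid concentration ladder
#'
#' For a fixed sugar concentration and an ascending ladder of amino-acid
#' concentrations, tests each mix for synergy against the additive proxy
#' and, separately, whether the amino acid alone is an agonist at that
#' level (Welch one-tailed versus untransfected no-ligand controls, Holm
#' adjustment across ladder levels). Querying levels where `synergistic`
#' is true while `solo_agonist` is false exposes synergy at
#' sub-activating amino-acid concentrations.
#'
#' @param records plate records containing, for one receptor: the mix
#'   wells at each ladder level, the amino acid alone at each level, the
#'   sugar alone, and untransfected no-ligand controls.
#' @param receptor_id receptor to analyse.
#' @param sugar,sugar_conc sugar name and fixed concentration (mM).
#' @param amino_acid amino-acid name.
#' @param levels ascending amino-acid concentrations (mM), >= 3 values.
#' @param alpha significance level per level; default 0.05 (dose curves).
#' @return data.frame with one row per level: `conc_mM`, `observed_mean`,
#'   `additive_estimate`, `excess`, `p`, `synergistic`, `solo_p_adj`,
#'   `solo_agonist`.
#' @export
synergy_dose_profile <- function(records, receptor_id, sugar, sugar_conc,
                                 amino_acid, levels, alpha = 0.05) {
  if (length(levels) < 3L) stop2("concentration ladder needs >= 3 levels")
  if (is.unsorted(levels, strictly = TRUE)) {
    stop2("ladder must be sorted ascending")
  }
  rec <- records[records$receptor_id == receptor_id, , drop = FALSE]
  un <- records[records$receptor_id == RECEPTOR_UNTRANSFECTED, , drop = FALSE]
  bg_rec <- un[is.na(un$ligand_1) & is.na(un$ligand_2), , drop = FALSE]
  if (nrow(bg_rec) < 2L) stop2("need untransfected no-ligand control wells")
  sel_single <- function(d, lig, conc) {
    d[!is.na(d$ligand_1) & d$ligand_1 == lig &
        abs(d$conc_1_mM - conc) < 1e-9 & is.na(d$ligand_2), , drop = FALSE]
  }
  sugar_solo <- sel_single(rec, sugar, sugar_conc)
  if (nrow(sugar_solo) < 2L) stop2("missing solo records for ", sugar)
  mixlab <- function(conc) mix_label(sugar, sugar_conc, amino_acid, conc)
  rec$mix <- mix_label(rec$ligand_1, rec$conc_1_mM, rec$ligand_2,
                       rec$conc_2_mM)
  rows <- list(); solo_p <- rep(NA_real_, length(levels))
  for (i in seq_along(levels)) {
    cl <- levels[i]
    aa_solo <- sel_single(rec, amino_acid, cl)
    mix <- rec[rec$mix == mixlab(cl), , drop = FALSE]
    if (nrow(aa_solo) < 2L || nrow(mix) < 2L) {
      warning("level ", cl, " mM skipped: missing solo or mix records",
              call. = FALSE)
      next
    }
    syn <- test_synergy(mix, aa_solo, sugar_solo, bg_rec, alpha = alpha)
    solo_p[i] <- stats::t.test(aa_solo$response, bg_rec$response,
                               alternative = "greater",
                               var.equal = FALSE)$p.value
    rows[[length(rows) + 1L]] <- data.frame(
      conc_mM = cl, observed_mean = syn$observed_mean,
      additive_estimate = syn$additive_estimate, excess = syn$excess,
      p = syn$p, synergistic = syn$synergistic, solo_p_adj = NA_real_,
      solo_agonist = NA)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop2("no usable ladder levels")
  adj <- p.adjust(solo_p[!is.na(solo_p)], method = "holm")
  out$solo_p_adj <- adj[match(out$conc_mM, levels[!is.na(solo_p)])]
  out$solo_agonist <- out$solo_p_adj < alpha
  rownames(out) <- NULL
  out
}
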