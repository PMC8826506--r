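# Agonist calling and response normalization for plate-luminescence data.

#' Summarize plate records by receptor and ligand mix
#'
#' Collapses well-level records to group means and standard errors
#' (sample SD / sqrt(n)). Groups with a single replicate are kept but
#' flagged untestable (their SE is undefined) and are excluded from
#' downstream significance testing.
#'
#' @param records plate-record data.frame as returned by
#'   [simulate_plate_data()] or [read_plate_csv()].
#' @return data.frame with one row per (receptor, mix): `receptor_id`,
#'   `mix`, `ligand_1`, `conc_1_mM`, `ligand_2`, `conc_2_mM`, `n`, `mean`,
#'   `se`, `testable`.
#' @export
summarize_responses <- function(records) {
  cols <- c("receptor_id", "ligand_1", "conc_1_mM", "ligand_2", "conc_2_mM",
            "response")
  if (nrow(records) == 0L) {
    return(data.frame(receptor_id = character(0), mix = character(0),
                      ligand_1 = character(0), conc_1_mM = numeric(0),
                      ligand_2 = character(0), conc_2_mM = numeric(0),
                      n = integer(0), mean = numeric(0), se = numeric(0),
                      testable = logical(0)))
  }
  if (!all(cols %in% names(records))) {
    stop2("records must have columns ", paste(cols, collapse = ", "))
  }
  records$mix <- mix_label(records$ligand_1, records$conc_1_mM,
                           records$ligand_2, records$conc_2_mM)
  key <- interaction(records$receptor_id, records$mix, drop = TRUE)
  groups <- split(records, key)
  out <- do.call(rbind, lapply(groups, function(g) {
    n <- nrow(g)
    data.frame(receptor_id = g$receptor_id[1], mix = g$mix[1],
               ligand_1 = g$ligand_1[1], conc_1_mM = g$conc_1_mM[1],
               ligand_2 = g$ligand_2[1], conc_2_mM = g$conc_2_mM[1],
               n = n, mean = mean(g$response),
               se = if (n >= 2) sd(g$response) / sqrt(n) else NA_real_,
               testable = n >= 2,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$receptor_id, out$mix), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Welch's unequal-variance t-test from summary statistics (mean, se, n),
# with Satterthwaite degrees of freedom. Vectorized; one-sided
# "group 1 mean > group 2 mean" when alternative = "greater".
welch_from_summary <- function(mean1, se1, n1, mean2, se2, n2,
                               alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  v1 <- se1^2; v2 <- se2^2        # se^2 = var/n already
  sed2 <- v1 + v2
  t <- (mean1 - mean2) / sqrt(sed2)
  df <- sed2^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- if (alternative == "greater") pt(t, df, lower.tail = FALSE) else
    2 * pt(abs(t), df, lower.tail = FALSE)
  list(t = t, df = df, p = p)
}

#' Call receptor agonists against untransfected controls
#'
#' For every ligand mix of a receptor, runs Welch's one-tailed t-test of
#' transfected responses being greater than the untransfected responses to
#' the same mix, then Holm step-down adjustment within the family of all
#' mixes tested for that receptor. A mix is called an agonist when its
#' adjusted p-value is below `alpha`.
#'
#' @param transfected summaries (from [summarize_responses()]) of
#'   receptor-transfected wells; may span several receptors.
#' @param untransfected summaries of untransfected control wells for the
#'   same mixes.
#' @param alpha family-wise significance level, in (0, 1); default 0.05.
#' @return the `transfected` summaries with columns `p_raw`, `p_adj`,
#'   `is_agonist` appended. Mixes lacking an untransfected counterpart are
#'   skipped (NA p-values) with a warning.
#' @export
test_agonists <- function(transfected, untransfected, alpha = 0.05) {
  if (!(alpha > 0 && alpha < 1)) stop2("alpha must lie in (0, 1)")
  un <- untransfected[untransfected$testable, , drop = FALSE]
  idx <- match(transfected$mix, un$mix)
  missing <- is.na(idx) & transfected$testable
  if (any(missing)) {
    warning("no untransfected counterpart for mix(es): ",
            paste(unique(transfected$mix[missing]), collapse = ", "),
            "; skipped", call. = FALSE)
  }
  ok <- !is.na(idx) & transfected$testable
  p_raw <- rep(NA_real_, nrow(transfected))
  p_raw[ok] <- welch_from_summary(
    transfected$mean[ok], transfected$se[ok], transfected$n[ok],
    un$mean[idx[ok]], un$se[idx[ok]], un$n[idx[ok]],
    alternative = "greater")$p
  out <- transfected
  out$p_raw <- p_raw
  out$p_adj <- NA_real_
  # Holm family: all mixes tested for one receptor
  for (r in unique(out$receptor_id)) {
    sel <- out$receptor_id == r & !is.na(out$p_raw)
    out$p_adj[sel] <- p.adjust(out$p_raw[sel], method = "holm")
  }
  out$is_agonist <- !is.na(out$p_adj) & out$p_adj < alpha
  out
}

#' Sucralose-normalized response profile for one receptor
#'
#' Divides each ligand's background-subtracted mean response by the
#' background-subtracted mean response to a reference ligand (sucralose by
#' default), cancelling multiplicative transfection-efficiency differences
#' between experiments. Background is the untransfected mean for the same
#' ligand when available, else the untransfected no-ligand control mean.
#' Only single-ligand mixes enter the profile; negative normalized values
#' are preserved.
#'
#' @param summaries summaries (from [summarize_responses()]) for one
#'   receptor's transfected wells.
#' @param untransfected_summaries summaries of untransfected wells.
#' @param reference_ligand name of the normalization reference.
#' @return object of class `normalized_profile`: list with `receptor_id`,
#'   `values` (named numeric, reference ligand exactly 1),
#'   `reference_ligand`.
#' @export
normalize_profile <- function(summaries, untransfected_summaries,
                              reference_ligand = "sucralose") {
  receptor <- unique(summaries$receptor_id)
  if (length(receptor) != 1L) {
    stop2("summaries must describe exactly one receptor")
  }
  singles <- summaries[!is.na(summaries$ligand_1) &
                         is.na(summaries$ligand_2), , drop = FALSE]
  if (!reference_ligand %in% singles$ligand_1) {
    stop2("reference ligand '", reference_ligand,
          "' absent from profile for receptor ", receptor)
  }
  un <- untransfected_summaries
  ctrl_mean <- un$mean[un$mix == "none"]
  bg_for <- function(mix, ligand) {
    hit <- un$mean[un$mix == mix]
    if (length(hit)) hit[1]
    else if (length(ctrl_mean)) ctrl_mean[1]
    else stop2("no untransfected background available for ", ligand)
  }
  bg <- mapply(bg_for, singles$mix, singles$ligand_1)
  net <- singles$mean - bg
  ref_net <- net[singles$ligand_1 == reference_ligand][1]
  if (!is.finite(ref_net) || ref_net <= 0) {
    stop2("cannot normalize receptor ", receptor, ": background-subtracted ",
          reference_ligand, " response is not positive (", signif(ref_net, 4),
          ")")
  }
  values <- setNames(net / ref_net, singles$ligand_1)
  values[reference_ligand] <- 1
  structure(list(receptor_id = receptor, values = values,
                 reference_ligand = reference_ligand),
            class = "normalized_profile")
}

#' @export
print.normalized_profile <- function(x, ...) {
  cat("Normalized response profile:", x$receptor_id,
      sprintf("(reference: %s)\n", x$reference_ligand))
  print(round(x$values, 3))
  invisible(x)
}

#' Grand mean normalized profile across receptors
#'
#' Unweighted per-ligand mean (and SE) of normalized responses across a
#' collection of receptor profiles; ligands missing from some profiles are
#' averaged over the profiles that have them, with the count reported.
#'
#' @param profiles list of [normalize_profile()] objects (>= 2).
#' @return data.frame with columns `ligand`, `grand_mean`, `se`, `n`.
#' @export
grand_mean_profile <- function(profiles) {
  if (length(profiles) < 2L) stop2("need at least 2 profiles")
  panels <- lapply(profiles, function(p) names(p$values))
  if (length(Reduce(intersect, panels)) == 0L) {
    stop2("profiles share no ligands")
  }
  ligands <- sort(unique(unlist(panels)))
  rows <- lapply(ligands, function(l) {
    v <- unlist(lapply(profiles, function(p)
      if (l %in% names(p$values)) p$values[[l]] else NULL))
    data.frame(ligand = l, grand_mean = mean(v),
               se = if (length(v) >= 2) sd(v) / sqrt(length(v)) else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
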