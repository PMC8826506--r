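# Synthetic trees, alignment fixtures, and drinking-bout tables.

#' Simulate a rooted tree with rate-heterogeneous branch lengths
#'
#' A pure-birth topology whose branch lengths are time multiplied by an
#' independent lognormal rate multiplier per branch, giving the
#' non-ultrametric, substitution-rate-like (e.g. dS) branch lengths that
#' the trait methods expect. `rate_sd = 0` recovers the ultrametric clock
#' tree.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed integer seed.
#' @param rate_sd sd of the per-branch log rate multiplier (>= 0).
#' @param birth speciation rate of the pure-birth process.
#' @return an [ape::ape-package] `phylo` tree, rooted, with positive
#'   branch lengths and tip labels `t1..tn`.
#' @export
simulate_tree <- function(n_tips, seed = 1, rate_sd = 0.3, birth = 1) {
  if (n_tips < 2) stop2("n_tips must be >= 2")
  if (rate_sd < 0) stop2("rate_sd must be >= 0")
  set.seed(as.integer(seed))
  tree <- ape::rphylo(n_tips, birth = birth, death = 0)
  mult <- exp(rnorm(nrow(tree$edge), mean = -rate_sd^2 / 2, sd = rate_sd))
  tree$edge.length <- pmax(tree$edge.length * mult, .Machine$double.eps)
  tree
}

# residue classes used for the "radical change" criterion
AA_CLASSES <- c(
  A = "hydrophobic", V = "hydrophobic", L = "hydrophobic", I = "hydrophobic",
  M = "hydrophobic", F = "hydrophobic", W = "hydrophobic", Y = "hydrophobic",
  S = "polar", T = "polar", N = "polar", Q = "polar",
  K = "positive", R = "positive", H = "positive",
  D = "negative", E = "negative",
  G = "special", C = "special", P = "special")

CANONICAL_AA <- names(AA_CLASSES)

#' Simulate an ancestral-pair alignment fixture with planted candidate sites
#'
#' Builds two ancestral protein sequences plus an extant alignment in which
#' chosen columns are planted to differ between the ancestors, together
#' with a truth table stating which columns satisfy the chimera-screen
#' criteria: (a) radical physicochemical change, (b) BLOSUM62 score <= 0,
#' (c) conservation of the second ancestor's residue across all extant
#' sequences. The truth flags are computed directly from the residue class
#' map and the BLOSUM62 matrix, independently of the screening code, so
#' they can serve as an oracle.
#'
#' @param n_extant number of extant sequences (>= 1).
#' @param length alignment length in columns.
#' @param planted_sites list of site specs, each a list with elements
#'   `pos` (1-based column), `anc1`, `anc2` (single residues), and
#'   `extant` (one residue recycled to all extant sequences, or a vector
#'   of `n_extant` residues; `"-"` allowed to plant a gap).
#' @param seed integer seed.
#' @return list with `anc1`, `anc2` (strings), `extant` (named character
#'   vector of aligned sequences), and `truth` (data.frame `column`,
#'   `res_anc1`, `res_anc2`, `radical`, `blosum`, `conserved`,
#'   `passes_all`).
#' @export
simulate_alignment_fixture <- function(n_extant, length, planted_sites = list(),
                                       seed = 1) {
  if (n_extant < 1) stop2("n_extant must be >= 1")
  for (s in planted_sites) {
    if (s$pos < 1 || s$pos > length) stop2("planted site outside [1, length]")
    res <- c(s$anc1, s$anc2, s$extant)
    bad <- setdiff(res, c(CANONICAL_AA, "-"))
    if (length(bad)) {
      stop2("planted residue not a canonical amino acid: ",
            paste(bad, collapse = ", "))
    }
  }
  set.seed(as.integer(seed))
  cons <- sample(CANONICAL_AA, length, replace = TRUE)
  anc1 <- cons
  anc2 <- cons
  extant <- matrix(rep(cons, each = n_extant), nrow = n_extant)
  # sprinkle extant-only variation in non-planted columns (anc1 == anc2
  # there, so these columns can never become candidates)
  planted_pos <- vapply(planted_sites, `[[`, numeric(1), "pos")
  free <- setdiff(seq_len(length), planted_pos)
  n_var <- min(length(free), max(0L, round(0.1 * length)))
  if (n_var > 0 && n_extant > 0) {
    for (j in sample(free, n_var)) {
      i <- sample.int(n_extant, 1)
      extant[i, j] <- sample(CANONICAL_AA, 1)
    }
  }
  truth <- list()
  b62 <- blosum62_matrix()
  for (s in planted_sites) {
    j <- s$pos
    anc1[j] <- s$anc1
    anc2[j] <- s$anc2
    extant[, j] <- rep(s$extant, length.out = n_extant)
    if (s$anc1 != s$anc2 && s$anc1 != "-" && s$anc2 != "-") {
      radical <- AA_CLASSES[[s$anc1]] != AA_CLASSES[[s$anc2]]
      blosum <- b62[s$anc1, s$anc2]
      conserved <- all(extant[, j] == s$anc2)
      truth[[length(truth) + 1L]] <- data.frame(
        column = j, res_anc1 = s$anc1, res_anc2 = s$anc2,
        radical = radical, blosum = blosum, conserved = conserved,
        passes_all = radical && blosum <= 0 && conserved)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(column = integer(0), res_anc1 = character(0),
               res_anc2 = character(0), radical = logical(0),
               blosum = integer(0), conserved = logical(0),
               passes_all = logical(0))
  truth <- truth[order(truth$column), , drop = FALSE]
  rownames(truth) <- NULL
  list(anc1 = paste(anc1, collapse = ""),
       anc2 = paste(anc2, collapse = ""),
       extant = setNames(apply(extant, 1, paste, collapse = ""),
                         paste0("extant", seq_len(n_extant))),
       truth = truth)
}

#' Simulate drinking-bout durations
#'
#' Bout lengths are drawn from a two-component lognormal mixture: a short
#' "sampling" component (mode near 0.2 s) and a long "appetitive"
#' component (mode near 1.5 s), with per-stimulus probability `mix_weights`
#' of the long component. Durations are quantized to the video frame
#' interval `1/fps` (and floored at one frame), matching frame-scored
#' behavioral data.
#'
#' @param stimuli character vector of stimulus ids.
#' @param mix_weights per-stimulus probability of a long bout, in `[0, 1]`,
#'   recycled to `length(stimuli)`.
#' @param n_bouts bouts per stimulus (0 gives an empty sample).
#' @param fps frames per second (> 0).
#' @param seed integer seed.
#' @return named list of `bout_sample` objects (one per stimulus), each
#'   with fields `stimulus_id`, `durations` (seconds), `fps`.
#' @export
simulate_bouts <- function(stimuli, mix_weights, n_bouts = 200, fps = 60,
                           seed = 1) {
  if (fps <= 0) stop2("fps must be > 0")
  mix_weights <- rep(mix_weights, length.out = length(stimuli))
  if (any(mix_weights < 0 | mix_weights > 1)) {
    stop2("mix_weights must lie in [0, 1]")
  }
  set.seed(as.integer(seed))
  out <- lapply(seq_along(stimuli), function(i) {
    long <- rbinom(n_bouts, 1, mix_weights[i]) == 1
    dur <- numeric(n_bouts)
    dur[!long] <- rlnorm(sum(!long), meanlog = log(0.2), sdlog = 0.4)
    dur[long] <- rlnorm(sum(long), meanlog = log(1.5), sdlog = 0.3)
    dur <- pmax(round(dur * fps), 1) / fps
    structure(list(stimulus_id = stimuli[i], durations = dur, fps = fps),
              class = "bout_sample")
  })
  setNames(out, stimuli)
}
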