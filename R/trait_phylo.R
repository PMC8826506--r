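# Continuous-trait phylogenetics: the sugar-vs-amino-acid response index,
# Brownian-motion ancestral states, within-edge interpolation, and
# phylogenetic PCA with a GLS phylogenetic mean and evolutionary
# covariance.

#' Relative sugar-vs-amino-acid response index
#'
#' `I = (S - A) / (S + A)` where `S` and `A` are the sums of a receptor's
#' normalized responses over a sugar set and an amino-acid set. Negative
#' normalized values are clipped to 0 before summation, confining the
#' index to `[-1, 1]`: +1 means a purely sugar-responsive receptor, -1 a
#' purely amino-acid-responsive one.
#'
#' @param profile a [normalize_profile()] object, or a named numeric
#'   vector of normalized responses.
#' @param sugar_set,amino_set disjoint, non-empty character vectors of
#'   ligand names, all present in the profile.
#' @return the index, a number in `[-1, 1]`.
#' @export
response_index <- function(profile, sugar_set, amino_set) {
  values <- if (inherits(profile, "normalized_profile")) profile$values
            else profile
  if (length(sugar_set) == 0L || length(amino_set) == 0L) {
    stop2("sugar_set and amino_set must be non-empty")
  }
  both <- intersect(sugar_set, amino_set)
  if (length(both)) {
    stop2("ligand(s) in both sets: ", paste(both, collapse = ", "))
  }
  absent <- setdiff(c(sugar_set, amino_set), names(values))
  if (length(absent)) {
    stop2("ligand(s) absent from profile: ", paste(absent, collapse = ", "))
  }
  S <- sum(pmax(values[sugar_set], 0))
  A <- sum(pmax(values[amino_set], 0))
  if (S + A == 0) {
    stop2("response index undefined: clipped sugar and amino sums are both 0")
  }
  (S - A) / (S + A)
}

check_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop2("tree must be an ape 'phylo' object")
  # a star tree (one internal node) is rooted by construction; otherwise a
  # basal multifurcation signals an unrooted tree
  if (!ape::is.rooted(tree) && tree$Nnode > 1L) {
    stop2("tree is unrooted; root it (e.g. ape::root) before trait analysis")
  }
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop2("tree must carry branch lengths on every edge")
  }
  if (any(tree$edge.length < 0)) stop2("negative branch lengths")
  if (anyDuplicated(tree$tip.label)) stop2("duplicate tip labels")
  invisible(tree)
}

#' Phylogenetic variance-covariance matrix
#'
#' Under Brownian motion the trait covariance of two tips equals the
#' branch length shared by their root-to-tip paths; the diagonal is each
#' tip's root-to-tip distance.
#'
#' @param tree rooted `phylo` tree with branch lengths.
#' @return symmetric positive semi-definite matrix (tips x tips), rows and
#'   columns named by tip labels.
#' @export
phylo_vcv <- function(tree) {
  check_tree(tree)
  ape::vcv.phylo(tree)
}

# Replace zero-length edges with eps so C and the edge-weight system stay
# invertible.
perturb_zero_edges <- function(tree, eps = 1e-9) {
  tree$edge.length[tree$edge.length < eps] <- eps
  tree
}

#' Maximum-likelihood ancestral states under Brownian motion
#'
#' Estimates the state at every internal node of a rooted tree for a
#' continuous trait evolving by Brownian motion. The estimates are the
#' generalized-least-squares (re-rooting) reconstruction: each node's
#' state is the GLS mean of the tips computed with that node treated as
#' the root. They are obtained in one pass by solving the equivalent
#' sparse normal equations of the edge-wise quadratic form
#' `sum_e (x_child - x_parent)^2 / b_e` for the internal states, with the
#' tip states fixed. The ML rate is
#' `sigma2 = (x - a)' C^-1 (x - a) / n` with `a` the root estimate and
#' `C` from [phylo_vcv()]. Zero-length branches are perturbed by 1e-9
#' before inversion.
#'
#' @param tree rooted `phylo` tree with branch lengths.
#' @param tip_values named numeric vector, one value per tip label.
#' @return object of class `trait_map`: list with `tree`, `tip_values`,
#'   `node_states` (named by internal node number, root first), `sigma2`,
#'   and `root_state`.
#' @export
bm_ancestral_states <- function(tree, tip_values) {
  check_tree(tree)
  n <- length(tree$tip.label)
  if (!all(tree$tip.label %in% names(tip_values))) {
    stop2("tip_values must name every tip")
  }
  x <- as.numeric(tip_values[tree$tip.label])
  if (anyNA(x) || n < 2) stop2("need finite values for at least 2 tips")
  tree <- perturb_zero_edges(tree)
  m <- tree$Nnode
  A <- matrix(0, m, m)
  rhs <- numeric(m)
  parent <- tree$edge[, 1]; child <- tree$edge[, 2]
  w <- 1 / tree$edge.length
  for (e in seq_along(w)) {
    p <- parent[e] - n; ch <- child[e]
    A[p, p] <- A[p, p] + w[e]
    if (ch > n) {
      c2 <- ch - n
      A[c2, c2] <- A[c2, c2] + w[e]
      A[p, c2] <- A[p, c2] - w[e]
      A[c2, p] <- A[c2, p] - w[e]
    } else {
      rhs[p] <- rhs[p] + w[e] * x[ch]
    }
  }
  states <- tryCatch(solve(A, rhs), error = function(e) {
    stop2("singular edge-weight system; tree has ", m, " internal nodes, ",
          sum(tree$edge.length <= 1e-9), " near-zero branch length(s): ",
          conditionMessage(e))
  })
  names(states) <- as.character(seq_len(m) + n)
  C <- phylo_vcv(tree)
  a <- states[[1]]  # root is node n + 1
  r <- x - a
  sigma2 <- as.numeric(crossprod(r, solve(C, r))) / n
  structure(list(tree = tree, tip_values = setNames(x, tree$tip.label),
                 node_states = states, sigma2 = sigma2, root_state = a),
            class = "trait_map")
}

#' @export
print.trait_map <- function(x, ...) {
  cat(sprintf(
    "BM trait map: %d tips, %d internal nodes; root state %.4g, sigma2 %.4g\n",
    length(x$tip_values), length(x$node_states), x$root_state, x$sigma2))
  invisible(x)
}

#' Interpolate trait states along tree edges
#'
#' Linear interpolation between the parent and child states of each edge
#' at `n_points` equally spaced positions (position 0 = parent, 1 =
#' child), for painting a reconstructed trait onto a tree.
#'
#' @param trait_map a [bm_ancestral_states()] result.
#' @param n_points points per edge (>= 2; endpoints included).
#' @return data.frame with columns `edge` (row of `tree$edge`), `parent`,
#'   `child`, `fraction`, `state`.
#' @export
edge_trait_interpolation <- function(trait_map, n_points = 11) {
  if (n_points < 2) stop2("n_points must be >= 2")
  tree <- trait_map$tree
  n <- length(tree$tip.label)
  node_state <- function(id) {
    if (id <= n) trait_map$tip_values[[tree$tip.label[id]]]
    else trait_map$node_states[[as.character(id)]]
  }
  frac <- seq(0, 1, length.out = n_points)
  rows <- lapply(seq_len(nrow(tree$edge)), function(e) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    sp <- node_state(p); sc <- node_state(ch)
    data.frame(edge = e, parent = p, child = ch, fraction = frac,
               state = sp + frac * (sc - sp))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Phylogenetic principal components analysis
#'
#' PCA that accounts for phylogenetic non-independence: traits are
#' centered on the GLS phylogenetic mean
#' `a = (1' C^-1 1)^-1 1' C^-1 X` and the evolutionary covariance
#' `R = (X - 1a')' C^-1 (X - 1a') / (n - 1)` is eigendecomposed, with `C`
#' the tree's variance-covariance matrix. Scores are the centered traits
#' projected on the loadings (no whitening of the scores). Sign
#' convention: the largest-magnitude entry of each loading column is
#' positive.
#'
#' @param tree rooted `phylo` tree with branch lengths.
#' @param X numeric matrix, taxa x traits, rownames matching tip labels;
#'   no missing values, >= 2 traits.
#' @param mode `"covariance"` (default) or `"correlation"` (R rescaled to
#'   unit diagonal).
#' @return object of class `phylo_pca`: list with `mean` (phylogenetic
#'   mean per trait), `R`, `eigenvalues` (descending), `loadings`,
#'   `scores`, `mode`.
#' @export
phylo_pca <- function(tree, X, mode = c("covariance", "correlation")) {
  mode <- match.arg(mode)
  check_tree(tree)
  X <- as.matrix(X)
  if (is.null(rownames(X)) || !setequal(rownames(X), tree$tip.label)) {
    stop2("rownames(X) must match the tree's tip labels")
  }
  if (ncol(X) < 2L) stop2("need >= 2 traits")
  if (anyNA(X)) stop2("X must have no missing values")
  X <- X[tree$tip.label, , drop = FALSE]
  tree <- perturb_zero_edges(tree)
  C <- phylo_vcv(tree)
  n <- nrow(X)
  Cinv1 <- solve(C, rep(1, n))
  a <- as.numeric(crossprod(Cinv1, X)) / sum(Cinv1)
  names(a) <- colnames(X)
  Xc <- sweep(X, 2, a)
  R <- crossprod(Xc, solve(C, Xc)) / (n - 1)
  if (mode == "correlation") {
    d <- diag(R)
    if (any(d <= .Machine$double.eps)) {
      stop2("constant trait(s) in correlation mode: ",
            paste(colnames(X)[d <= .Machine$double.eps], collapse = ", "))
    }
    R <- cov2cor(R)
  }
  R <- (R + t(R)) / 2
  eig <- eigen(R, symmetric = TRUE)
  V <- eig$vectors
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- colnames(X)
  colnames(V) <- paste0("PC", seq_len(ncol(V)))
  scores <- Xc %*% V
  structure(list(mean = a, R = R, eigenvalues = eig$values, loadings = V,
                 scores = scores, mode = mode),
            class = "phylo_pca")
}

#' @export
print.phylo_pca <- function(x, ...) {
  ev <- x$eigenvalues
  prop <- ev / sum(ev)
  cat(sprintf("Phylogenetic PCA (%s mode): %d traits, %d taxa\n",
              x$mode, nrow(x$loadings), nrow(x$scores)))
  k <- min(5, length(ev))
  cat("  eigenvalues:", paste(signif(ev[seq_len(k)], 4), collapse = ", "),
      if (length(ev) > k) "..." else "", "\n")
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * prop[seq_len(k)]), collapse = ", "),
      "\n")
  invisible(x)
}
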