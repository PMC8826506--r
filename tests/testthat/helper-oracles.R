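# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: matrix solves are explicit, path lengths come
# from tree traversal, Holm is its closed-form definition.

# Shared path length matrix from node `root_node`, by walking ape nodepaths;
# used as the re-rooted GLS oracle for BM ancestral states.
path_vcv_from <- function(tree, root_node) {
  n <- length(tree$tip.label)
  paths <- lapply(seq_len(n), function(i) {
    p <- ape::nodepath(tree, root_node, i)
    lens <- vapply(seq_len(length(p) - 1L), function(k) {
      e <- which((tree$edge[, 1] == p[k] & tree$edge[, 2] == p[k + 1]) |
                   (tree$edge[, 2] == p[k] & tree$edge[, 1] == p[k + 1]))
      tree$edge.length[e]
    }, numeric(1))
    list(nodes = p, lens = lens)
  })
  C <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) {
        C[i, j] <- sum(paths[[i]]$lens)
      } else {
        pi <- paths[[i]]; pj <- paths[[j]]
        k <- 1; shared <- 0
        while (k < length(pi$nodes) && k < length(pj$nodes) &&
               pi$nodes[k + 1] == pj$nodes[k + 1]) {
          shared <- shared + pi$lens[k]
          k <- k + 1
        }
        C[i, j] <- shared
      }
    }
  }
  C
}

# GLS mean of tip values with the tree re-rooted at `node`: the textbook
# estimate (1' C^-1 1)^-1 1' C^-1 x with an explicit inverse.
gls_state_at_node <- function(tree, tip_values, node) {
  x <- as.numeric(tip_values[tree$tip.label])
  C <- path_vcv_from(tree, node)
  Ci <- solve(C)
  one <- rep(1, nrow(C))
  as.numeric((t(one) %*% Ci %*% x) / (t(one) %*% Ci %*% one))
}

# Holm step-down from its definition: p_(i) -> max_{j<=i} min(1, (m-j+1) p_(j)).
holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- cummax(pmin(1, (m - seq_len(m) + 1) * p[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Ordinary (non-phylogenetic) PCA oracle: column-mean centering, sample
# covariance, eigendecomposition, same sign convention as phylo_pca.
ordinary_pca_oracle <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  S <- crossprod(Xc) / (nrow(X) - 1)
  eig <- eigen((S + t(S)) / 2, symmetric = TRUE)
  V <- eig$vectors
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  list(eigenvalues = eig$values, loadings = V, scores = Xc %*% V)
}

# Star tree with given tip count and terminal branch lengths.
star_tree <- function(n, lengths = rep(1, n)) {
  tree <- ape::stree(n, type = "star")
  tree$edge.length <- lengths
  tree$tip.label <- paste0("t", seq_len(n))
  tree
}

# Simulate one BM realization of tip values on a tree (independent of the
# package's estimators).
sim_bm_tips <- function(tree, root_state, sigma2 = 1) {
  C <- ape::vcv.phylo(tree)
  z <- rnorm(nrow(C))
  setNames(root_state + t(chol(sigma2 * C)) %*% z, rownames(C))[, 1]
}

# Null assay panel: dead receptor, matched baseline/background, no batch
# effect, so transfected and untransfected wells share one distribution.
null_panel_records <- function(n_mixes = 20, n_replicates = 6, seed = 1,
                               noise_sd = 10) {
  panel <- ligand_panel(sprintf("aa%02d", seq_len(n_mixes)),
                        rep("amino_acid", n_mixes), rep(50, n_mixes))
  params <- list(R1 = receptor_params(
    ligands = data.frame(ligand = panel$name, E_max = 0, EC50 = 50, h = 1),
    B = 20, batch_scale_sd = 0, noise_sd = noise_sd))
  simulate_plate_data(panel, params, n_replicates = n_replicates,
                      n_batches = 1, seed = seed, background = 20)
}

# Small two-receptor panel used by several assay tests.
demo_panel <- function() {
  ligand_panel(c("sucrose", "sucralose", "alanine", "proline"),
               c("sugar", "sweetener", "amino_acid", "amino_acid"),
               c(100, 100, 100, 100))
}

demo_params <- function(batch_scale_sd = 0.2, noise_sd = 1e-9, amino = 150) {
  receptor_params(
    ligands = data.frame(ligand = c("sucrose", "sucralose", "alanine",
                                    "proline"),
                         E_max = c(300, 400, amino, 0),
                         EC50 = c(30, 5, 40, 50), h = 1.5),
    B = 20, batch_scale_sd = batch_scale_sd, noise_sd = noise_sd)
}
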