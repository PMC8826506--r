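# Response index, BM ancestral reconstruction, edge interpolation, and
# phylogenetic PCA.

test_that("the response index follows its closed form and bounds", {
  prof <- c(sucrose = 1.2, fructose = 0.6, alanine = 0, serine = 0)
  expect_equal(response_index(prof, c("sucrose", "fructose"),
                              c("alanine", "serine")), 1)
  prof2 <- c(sucrose = 2, alanine = 2)
  expect_equal(response_index(prof2, "sucrose", "alanine"), 0)
  prof3 <- c(sucrose = 3, alanine = 1)
  expect_equal(response_index(prof3, "sucrose", "alanine"), 0.5)
  # scale invariance
  expect_equal(response_index(prof3 * 7.3, "sucrose", "alanine"), 0.5)
  # negatives clipped before summation
  prof4 <- c(sucrose = 1, alanine = -2)
  expect_equal(response_index(prof4, "sucrose", "alanine"), 1)

  expect_error(response_index(prof3, c("sucrose", "alanine"), "alanine"),
               "both sets")
  expect_error(response_index(c(sucrose = 0, alanine = -1),
                              "sucrose", "alanine"), "undefined")
  expect_error(response_index(prof3, "sucrose", "ribose"), "absent")
})

test_that("the index stays within [-1, 1] on random profiles", {
  set.seed(8)
  for (i in 1:200) {
    v <- setNames(runif(6, -1, 3), letters[1:6])
    idx <- tryCatch(response_index(v, letters[1:3], letters[4:6]),
                    error = function(e) NA_real_)
    if (!is.na(idx)) expect_true(idx >= -1 && idx <= 1)
  }
})

test_that("phylo_vcv equals shared path lengths", {
  st <- star_tree(4, rep(2.5, 4))
  expect_equal(phylo_vcv(st), 2.5 * diag(4), ignore_attr = TRUE)

  tr <- ape::read.tree(text = "((A:1,B:1):2,Cc:3);")
  C <- phylo_vcv(tr)
  expect_equal(C["A", "B"], 2)
  expect_equal(C["A", "A"], 3)
  expect_equal(C["B", "B"], 3)
  expect_equal(C["A", "Cc"], 0)

  set.seed(2)
  rt <- simulate_tree(10, seed = 14, rate_sd = 0.5)
  C2 <- phylo_vcv(rt)
  expect_equal(C2, path_vcv_from(rt, length(rt$tip.label) + 1L),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_true(all(C2 <= pmin(outer(diag(C2), diag(C2), pmin)) + 1e-12))

  un <- ape::unroot(simulate_tree(5, seed = 3))
  expect_error(phylo_vcv(un), "unrooted|root")
})

test_that("BM ancestral states match closed forms on simple trees", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  tm <- bm_ancestral_states(tr, c(A = 0.2, B = 0.8))
  expect_equal(unname(tm$root_state), 0.5)

  st <- star_tree(3, c(1, 1, 2))
  tm2 <- bm_ancestral_states(st, c(t1 = 0, t2 = 0, t3 = 1))
  expect_equal(unname(tm2$root_state), 0.5 / 2.5)  # 1/length-weighted mean
})

test_that("every node state equals the brute-force re-rooted GLS solve", {
  set.seed(91)
  for (i in 1:10) {
    tr <- simulate_tree(sample(4:8, 1), seed = 100 + i, rate_sd = 0.4)
    x <- setNames(rnorm(length(tr$tip.label)), tr$tip.label)
    tm <- bm_ancestral_states(tr, x)
    n <- length(tr$tip.label)
    for (node in (n + 1):(n + tr$Nnode)) {
      expect_equal(unname(tm$node_states[[as.character(node)]]),
                   gls_state_at_node(tr, x, node), tolerance = 1e-8)
    }
  }
})

test_that("states are invariant to tip order and branch rescaling", {
  tr <- simulate_tree(8, seed = 55, rate_sd = 0.4)
  x <- setNames(rnorm(8), tr$tip.label)
  tm <- bm_ancestral_states(tr, x)
  tm_perm <- bm_ancestral_states(tr, x[sample(names(x))])
  expect_equal(tm$node_states, tm_perm$node_states)

  scaled <- tr
  scaled$edge.length <- scaled$edge.length * 4
  tm_s <- bm_ancestral_states(scaled, x)
  expect_equal(tm$node_states, tm_s$node_states, tolerance = 1e-10)
  expect_equal(tm_s$sigma2, tm$sigma2 / 4, tolerance = 1e-10)
})

test_that("edge interpolation is linear with matching endpoints", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  tm <- bm_ancestral_states(tr, c(A = 1, B = 0))
  tm$node_states[1] <- 0  # force parent 0 -> child 1 on edge to A
  sam <- edge_trait_interpolation(tm, n_points = 3)
  edgeA <- sam[sam$child == 1, ]
  expect_equal(edgeA$state, c(0, 0.5, 1))

  tm2 <- bm_ancestral_states(tr, c(A = 0.4, B = 0.4))
  sam2 <- edge_trait_interpolation(tm2, n_points = 5)
  expect_true(all(abs(sam2$state - 0.4) < 1e-12))

  tr3 <- simulate_tree(6, seed = 9)
  x3 <- setNames(rnorm(6), tr3$tip.label)
  tm3 <- bm_ancestral_states(tr3, x3)
  sam3 <- edge_trait_interpolation(tm3, n_points = 4)
  state_of <- function(id) {
    if (id <= 6) tm3$tip_values[[tr3$tip.label[id]]]
    else tm3$node_states[[as.character(id)]]
  }
  for (e in unique(sam3$edge)) {
    seg <- sam3[sam3$edge == e, ]
    expect_equal(seg$state[1], state_of(seg$parent[1]))
    expect_equal(seg$state[nrow(seg)], state_of(seg$child[1]))
  }
  expect_error(edge_trait_interpolation(tm3, n_points = 1), "n_points")
})

test_that("phyloPCA on a unit star tree is ordinary PCA", {
  set.seed(17)
  st <- star_tree(9, rep(1, 9))
  X <- matrix(rnorm(9 * 5), 9, 5,
              dimnames = list(st$tip.label, paste0("lig", 1:5)))
  res <- phylo_pca(st, X)
  oracle <- ordinary_pca_oracle(X)
  expect_equal(unname(res$mean), colMeans(X), ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_equal(res$eigenvalues, oracle$eigenvalues, tolerance = 1e-8)
  expect_equal(unname(res$loadings), oracle$loadings, tolerance = 1e-8)
  expect_equal(unname(res$scores), unname(oracle$scores), tolerance = 1e-8)
})

test_that("phyloPCA satisfies its spectral and orthogonality identities", {
  set.seed(23)
  tr <- simulate_tree(8, seed = 77, rate_sd = 0.3)
  X <- matrix(rnorm(8 * 20), 8, 20,
              dimnames = list(tr$tip.label, paste0("v", 1:20)))
  res <- phylo_pca(tr, X)
  expect_equal(sum(res$eigenvalues), sum(diag(res$R)), tolerance = 1e-10)
  expect_true(all(diff(res$eigenvalues) <= 1e-12))
  expect_equal(crossprod(res$loadings), diag(20), ignore_attr = TRUE,
               tolerance = 1e-10)
  Xc <- sweep(X[tr$tip.label, ], 2, res$mean)
  expect_equal(res$scores %*% t(res$loadings), Xc, ignore_attr = TRUE,
               tolerance = 1e-8)
})

test_that("phyloPCA agrees with an independent implementation", {
  skip_if_not_installed("phytools")
  tr <- simulate_tree(8, seed = 5, rate_sd = 0.3)
  set.seed(1)
  X <- matrix(rnorm(8 * 4), 8, 4,
              dimnames = list(tr$tip.label, paste0("v", 1:4)))
  mine <- phylo_pca(tr, X)
  ref <- phytools::phyl.pca(tr, X, method = "BM", mode = "cov")
  expect_equal(mine$eigenvalues, unname(diag(ref$Eval)), tolerance = 1e-8)
  expect_equal(abs(unname(mine$loadings)), abs(unname(ref$Evec)),
               tolerance = 1e-8)
  expect_equal(abs(unname(mine$scores)), abs(unname(ref$S)),
               tolerance = 1e-8)
})

test_that("constant traits are rejected in correlation mode by name", {
  tr <- simulate_tree(5, seed = 2)
  X <- cbind(flat = rep(1, 5), var1 = rnorm(5), var2 = rnorm(5))
  rownames(X) <- tr$tip.label
  expect_error(phylo_pca(tr, X, mode = "correlation"), "flat")
})
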