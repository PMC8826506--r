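# The synthetic generators: determinism, null soundness, and the shape
# contracts the downstream stages rely on.

test_that("all generators are deterministic given seed and inputs", {
  panel <- demo_panel()
  params <- list(R1 = demo_params(noise_sd = 10))
  a <- simulate_plate_data(panel, params, seed = 11)
  b <- simulate_plate_data(panel, params, seed = 11)
  expect_identical(a, b)

  expect_identical(simulate_tree(12, seed = 3), simulate_tree(12, seed = 3))

  sites <- list(list(pos = 4, anc1 = "D", anc2 = "K", extant = "K"))
  expect_identical(simulate_alignment_fixture(5, 20, sites, seed = 9),
                   simulate_alignment_fixture(5, 20, sites, seed = 9))

  expect_identical(simulate_bouts("s", 0.3, 50, seed = 2),
                   simulate_bouts("s", 0.3, 50, seed = 2))
})

test_that("dead receptors produce wells indistinguishable from controls", {
  # all E_max = 0, matched baseline: two-sample p-values should be uniform
  p <- vapply(1:100, function(s) {
    rec <- null_panel_records(n_mixes = 1, seed = s)
    t.test(rec$response[rec$receptor_id == "R1" & !is.na(rec$ligand_1)],
           rec$response[rec$receptor_id == "UNTRANSFECTED" &
                          !is.na(rec$ligand_1)])$p.value
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("plate generator rejects bad designs", {
  panel <- demo_panel()
  params <- list(R1 = demo_params())
  expect_error(simulate_plate_data(panel, params, n_replicates = 1),
               "n_replicates")
  short <- params
  short$R1$ligands <- short$R1$ligands[-1, ]
  expect_error(simulate_plate_data(panel, short), "missing simulation")
  expect_error(
    simulate_plate_data(panel, params,
                        mixes = list(c(sucrose = 100, sucralose = 50,
                                       alanine = 10))),
    "at most two")
})

test_that("untransfected artifact appears only for histidine and >175 mM mixes", {
  panel <- ligand_panel(c("sucrose", "histidine", "alanine"),
                        c("sugar", "amino_acid", "amino_acid"),
                        c(100, 50, 100))
  params <- list(R1 = receptor_params(
    ligands = data.frame(ligand = panel$name, E_max = c(300, 100, 100),
                         EC50 = 40, h = 1.5),
    B = 20, batch_scale_sd = 0, noise_sd = 1e-9))
  mixes <- list(c(sucrose = 100), c(histidine = 50),
                c(sucrose = 100, alanine = 100),  # 200 mM total
                c(sucrose = 100, alanine = 50))   # 150 mM total
  rec <- simulate_plate_data(panel, params, seed = 1, mixes = mixes,
                             background = 20)
  un <- rec[rec$receptor_id == "UNTRANSFECTED", ]
  mean_of <- function(l1, c2) {
    sel <- un$ligand_1 == l1 &
      (if (is.na(c2)) is.na(un$conc_2_mM)
       else !is.na(un$conc_2_mM) & un$conc_2_mM == c2)
    mean(un$response[sel])
  }
  bump <- 0.1 * 300
  expect_equal(mean_of("sucrose", NA), 20, tolerance = 1e-6)
  expect_equal(mean_of("histidine", NA), 20 + bump, tolerance = 1e-6)
  expect_equal(mean_of("sucrose", 100), 20 + bump, tolerance = 1e-6) # 200 mM
  expect_equal(mean_of("sucrose", 50), 20, tolerance = 1e-6)         # 150 mM
})

test_that("pure-birth trees have the right shape and rate behavior", {
  t2 <- simulate_tree(2, seed = 1)
  expect_equal(length(t2$tip.label), 2L)
  expect_equal(nrow(t2$edge), 2L)

  t9 <- simulate_tree(9, seed = 4)
  expect_equal(t9$Nnode, 8L)          # n - 1 internal nodes incl. root
  expect_equal(nrow(t9$edge), 16L)    # 2n - 2 edges for rooted binary
  expect_true(all(t9$edge.length > 0))

  clock <- simulate_tree(10, seed = 5, rate_sd = 0)
  depths <- ape::node.depth.edgelength(clock)[1:10]
  expect_lt(diff(range(depths)), 1e-9)

  expect_error(simulate_tree(1), "n_tips")
})

test_that("alignment fixtures plant candidate columns with a correct truth table", {
  empty <- simulate_alignment_fixture(4, 30, list(), seed = 1)
  expect_identical(empty$anc1, empty$anc2)
  expect_equal(nrow(empty$truth), 0L)

  fix <- simulate_alignment_fixture(
    4, 30,
    planted_sites = list(
      list(pos = 5, anc1 = "D", anc2 = "K", extant = "K"),
      list(pos = 9, anc1 = "I", anc2 = "V", extant = "V")),
    seed = 2)
  tt <- fix$truth
  dk <- tt[tt$column == 5, ]
  expect_true(dk$radical)             # acidic -> basic
  expect_equal(dk$blosum, -1)         # standard BLOSUM62 D/K
  expect_true(dk$conserved)
  expect_true(dk$passes_all)
  iv <- tt[tt$column == 9, ]
  expect_false(iv$radical)            # both hydrophobic
  expect_equal(iv$blosum, 3)          # standard BLOSUM62 I/V
  expect_false(iv$passes_all)

  expect_error(
    simulate_alignment_fixture(4, 30, list(
      list(pos = 2, anc1 = "B", anc2 = "K", extant = "K"))),
    "canonical")
  expect_error(
    simulate_alignment_fixture(4, 30, list(
      list(pos = 99, anc1 = "D", anc2 = "K", extant = "K"))),
    "outside")
})

test_that("bout durations are frame-quantized mixtures with the right scale", {
  s <- simulate_bouts("short", mix_weights = 0, n_bouts = 500, fps = 60,
                      seed = 7)[[1]]
  expect_true(all(s$durations > 0))
  expect_lt(median(s$durations), 0.5)  # short component mode ~0.2 s
  frames <- s$durations * 60
  expect_equal(frames, round(frames), tolerance = 1e-12)

  long <- simulate_bouts("long", 1, 200, seed = 8)[[1]]
  shrt <- simulate_bouts("shrt", 0, 200, seed = 9)[[1]]
  expect_lt(ks_two_sample(long$durations, shrt$durations)$p, 0.05)

  empty <- simulate_bouts("none", 0.5, 0, seed = 1)[[1]]
  expect_length(empty$durations, 0)
  expect_error(simulate_bouts("x", 1.5, 10), "mix_weights")
})
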