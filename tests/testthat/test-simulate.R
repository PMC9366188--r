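test_that("end-to-end simulation has the right shape and is reproducible", {
  st <- fig_tree()
  cm <- clock2_iid_G()
  sim <- simulate_dataset(st, cm, L = 10, nsites = 500, nseq = 1, seed = 31)
  expect_length(sim$alignments, 10)
  for (a in sim$alignments) expect_equal(dim(a), c(4L, 500L))
  expect_equal(nrow(sim$truth), 10)
  ## identical seed => byte-identical outputs
  sim2 <- simulate_dataset(st, cm, L = 10, nsites = 500, nseq = 1, seed = 31)
  expect_identical(sim$alignments, sim2$alignments)
  expect_identical(sim$truth, sim2$truth)
  ## latent moments: mu_i ~ G(5,5) mean 1 across loci
  big <- simulate_dataset(st, cm, L = 400, nsites = 1, nseq = 1, seed = 5)
  expect_equal(mean(big$truth$mu), 1, tolerance = 0.06)
})

test_that("vanishing population sizes collapse gene trees onto the species tree", {
  st <- species_tree("(((A,B):0.1,C):0.105,O):0.2;",
                     theta = c(A = 1e-7, B = 1e-7, C = 1e-7, O = 1e-7,
                               "A,B" = 1e-7, "A,B,C" = 1e-7, "A,B,C,O" = 1e-7))
  sim <- simulate_dataset(st, clock_model(1), L = 5, nsites = 1, nseq = 1,
                          subst_sim = subst_model("JC"), seed = 2)
  for (gt in sim$gene_trees) {
    expect_equal(sort(gt$age[gt$age > 0]), c(0.1, 0.105, 0.2), tolerance = 1e-4)
  }
})

test_that("expected outgroup divergence matches 2*tauR + thetaR", {
  ## the deepest split: expected pairwise distance between O and any ingroup
  ## sequence is 2*tauR + thetaR = 0.41 substitutions/site on the
  ## simulation tree (coalescent mean thetaR above the root age)
  st <- fig_tree()
  set.seed(77)
  sim <- simulate_dataset(st, clock_model(1), L = 250, nsites = 300,
                          nseq = 1, subst_sim = subst_model("JC"))
  dv <- vapply(sim$alignments, function(a) {
    p <- mean(a["O1^O", ] != a["A1^A", ])
    -3 / 4 * log(1 - 4 * p / 3)
  }, 0)
  expect_equal(mean(dv), 2 * 0.2 + 0.01, tolerance = 0.035)
  ## ingroup-only maximal divergence ~ 2*tauS + thetaS = 0.22
  dv2 <- vapply(sim$alignments, function(a) {
    p <- mean(a["C1^C", ] != a["A1^A", ])
    -3 / 4 * log(1 - 4 * p / 3)
  }, 0)
  expect_equal(mean(dv2), 2 * 0.105 + 0.01, tolerance = 0.035)
})
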