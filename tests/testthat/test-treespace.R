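test_that("annotated Newick round-trips exactly", {
  txt <- "(((A#0.02,B#0.02):0.1#0.05,C#0.02):0.105#0.01,O#0.02):0.2#0.01;"
  st <- species_tree(txt)
  expect_equal(st$s, 4L)
  expect_identical(write_newick(species_tree(write_newick(st))), write_newick(st))
  ## tau/theta land on the right clades
  expect_equal(st$tau[match("A,B", st$clade)], 0.1)
  expect_equal(st$theta[match("A,B", st$clade)], 0.05)
  expect_equal(st$tau[st$root], 0.2)
})

test_that("constructor overrides and invariants", {
  st <- species_tree("((A,B):0.01,C):0.02;",
                     theta = c(A = 0.01, B = 0.01, C = 0.01,
                               "A,B" = 0.02, "A,B,C" = 0.03))
  expect_equal(st$theta[match("A,B", st$clade)], 0.02)
  expect_error(species_tree("((A,B):0.03,C):0.02;"), "parent age")
  expect_error(species_tree("((A,B):0.01#-1,C):0.02;"), "positive")
  expect_error(species_tree("((A,B):0.01,C):0.02;",
                            constraints = list(c("A", "C"))), "incompatible")
  ## outgroup declares the ingroup clade
  st2 <- species_tree("(((A,B):0.1,C):0.105,O):0.2;", outgroup = "O")
  expect_true(coalclock:::clade_in_tree(st2, c("A", "B", "C")))
})

test_that("coalescent-unit branch lengths", {
  st <- fig_tree()
  expect_equal(coalescent_unit_length(st, "A,B"), 0.2)   # 2*(0.105-0.1)/0.05
  st2 <- species_tree("((A,B):0.1#0.01,C):0.2;")
  expect_equal(coalescent_unit_length(st2, "A,B"), 2 * 0.1 / 0.01)
  expect_error(coalescent_unit_length(st, "A"), "tip")
  expect_error(coalescent_unit_length(st, "A,B,C,O"), "root stem")
})

test_that("gene-tree compatibility checks and segment maps", {
  st <- abc_tree(tau_ab = 0.01, tau_abc = 0.02)
  gt <- gt_abc(0.015, 0.03, st)
  expect_true(validate_compatibility(gt, st)$ok)
  ## node below its population floor
  bad <- gt_abc(0.005, 0.03, st)   # a-b coalescence below tau_AB... allowed?
  ## 0.005 < tau_AB = 0.01, but a and b are different species: floor violated
  res <- validate_compatibility(bad, st)
  expect_false(res$ok)
  expect_match(res$message, "below the floor")
  ## corrupted segment map is caught
  gt2 <- gt
  gt2$segments[[1]][1, "to"] <- gt2$segments[[1]][1, "to"] * 0.5
  expect_false(validate_compatibility(gt2, st)$ok)
  ## segments partition each edge exactly and regenerate deterministically
  seg <- coalclock:::segment_map(gt, st)
  for (id in seq_len(gt$nnode)) {
    if (is.null(seg[[id]])) next
    expect_equal(sum(seg[[id]][, "to"] - seg[[id]][, "from"]),
                 gt$age[gt$parent[id]] - gt$age[id])
  }
  expect_identical(seg, coalclock:::segment_map(coalclock:::refresh_embedding(gt, st), st))
})
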