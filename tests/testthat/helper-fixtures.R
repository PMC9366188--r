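## Shared fixtures: small species trees used throughout the suite.

## four-species simulation tree: short internal branch of 0.2 coalescent units
fig_tree <- function() {
  species_tree("(((A#0.02,B#0.02):0.1#0.05,C#0.02):0.105#0.01,O#0.02):0.2#0.01;")
}

## three-species tree used by the validation harnesses
abc_tree <- function(tau_ab = 0.01, tau_abc = 0.02, theta = 0.01) {
  species_tree(sprintf("((A#%g,B#%g):%g#%g,C#%g):%g#%g;",
                       theta, theta, tau_ab, theta, theta, tau_abc, theta))
}

## two-species tree (everything coalesces in the root population)
ab_tree <- function(tau0 = 0.05, theta = 0.01) {
  species_tree(sprintf("(A#%g,B#%g):%g#%g;", theta, theta, tau0, theta))
}

default_prior <- function() {
  msc_prior(tau = list("gamma", 2, 20), theta = list("invgamma", 3, 0.002))
}

clock2_iid_G <- function() {
  clock_model(2, "G", mu = list("iid", 5, 0, 0), nu = list("iid", 5, 2, 20))
}

## manually built 3-tip gene tree on abc_tree-like species trees:
## tips a (species 1), b (2), c (3); (a,b) coalesce at t1, root at t2
gt_abc <- function(t1, t2, st) {
  gene_tree(parent = c(4L, 4L, 5L, 5L, 0L), age = c(0, 0, 0, t1, t2),
            species = 1:3, tip.label = c("a^A", "b^B", "c^C"), st = st)
}
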